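#' One-way deterministic sensitivity analysis for one parameter
#'
#' Clones the specification, sets the parameter to its low and then its high
#' bound (probabilities and utilities are capped to \[0,1\]; costs floored at
#' 0), re-runs the full model each time, and records the ICER of the
#' comparator versus the reference at each bound.
#'
#' @param spec A `tki_spec`.
#' @param id Parameter id (see [spec_get()]); must have a row in
#'   `spec$ranges`, otherwise the plus/minus 50\% fallback range is applied
#'   via [default_range()].
#' @param comparator,reference Strategy names for the ICER.
#' @return One-row data frame: `id`, `low`, `high`, `icer_low`, `icer_high`,
#'   `spread` (absolute difference).
#' @export
one_way <- function(spec, id, comparator, reference = "imatinib") {
  rng <- spec_range(spec, id)
  if (is.null(rng)) {
    fam <- if (grepl("incidence|ccyr|os_|\\.os$|p_apbp|p_receive|utilities\\.|discount_rate", id))
      "beta" else "gamma"
    rng <- default_range(spec, id, fam)
  }
  icer_at <- function(v) {
    v <- cap_value(v, rng$family, id)
    s <- spec_set(spec, id, v)
    run <- run_model(s)$summary
    comparison_icer(run, comparator, reference)
  }
  lo <- icer_at(rng$low)
  hi <- icer_at(rng$high)
  data.frame(id = id, low = rng$low, high = rng$high,
             icer_low = lo, icer_high = hi,
             spread = abs(hi - lo), stringsAsFactors = FALSE)
}

cap_value <- function(v, family, id) {
  if (family == "gamma") return(max(0, v))
  # probabilities, utilities and rates: capped to [0, 1]
  min(1, max(0, v))
}

comparison_icer <- function(summary_df, comparator, reference) {
  rc <- summary_df[summary_df$strategy == comparator, ]
  rr <- summary_df[summary_df$strategy == reference, ]
  if (nrow(rc) != 1 || nrow(rr) != 1)
    stop("unknown strategy in comparison: ", comparator, " vs ", reference)
  dq <- rc$total_qalys - rr$total_qalys
  if (dq == 0) return(NA_real_)
  (rc$total_cost - rr$total_cost) / dq
}

#' Tornado analysis
#'
#' Runs [one_way()] for every ranged parameter and sorts rows by descending
#' ICER spread (ties broken lexicographically by parameter id), the order in
#' which a tornado diagram is drawn.
#'
#' @inheritParams one_way
#' @return A `tki_dsa` data frame of one-way rows, sorted.
#' @examples
#' \donttest{
#' tornado(builtin_basecase(), "nilotinib")
#' }
#' @export
tornado <- function(spec, comparator, reference = "imatinib") {
  rows <- lapply(spec$ranges$id, function(id)
    one_way(spec, id, comparator, reference))
  out <- do.call(rbind, rows)
  out <- out[order(-out$spread, out$id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "comparator") <- comparator
  attr(out, "reference") <- reference
  base <- comparison_icer(run_model(spec)$summary, comparator, reference)
  attr(out, "base_icer") <- base
  class(out) <- c("tki_dsa", "data.frame")
  out
}

#' Sweep the first-line imatinib switch split
#'
#' Varies the proportion of imatinib failures switched to nilotinib (the
#' remainder switching to dasatinib) across a grid spanning 0 to 1, re-runs
#' the model, and records the ICER of each second-generation strategy versus
#' imatinib at every grid point.
#'
#' @param spec A `tki_spec` containing an `imatinib` strategy.
#' @param nilotinib_props Grid of nilotinib proportions in \[0,1\].
#' @param reference Reference strategy (default `"imatinib"`).
#' @return Data frame: `prop_nilotinib`, `prop_dasatinib`, and one ICER
#'   column per non-reference strategy.
#' @export
switch_split_sweep <- function(spec, nilotinib_props = seq(0, 1, by = 0.1),
                               reference = "imatinib") {
  if (!reference %in% names(spec$strategies))
    stop("strategy '", reference, "' not present")
  if (any(nilotinib_props < 0 | nilotinib_props > 1))
    stop("proportions outside [0,1]")
  comps <- setdiff(names(spec$strategies), reference)
  rows <- lapply(nilotinib_props, function(p) {
    s <- spec
    s$strategies[[reference]]$switch <- list(nilotinib = p,
                                             dasatinib = 1 - p)
    run <- run_model(s)$summary
    vals <- vapply(comps, function(cmp)
      comparison_icer(run, cmp, reference), numeric(1))
    cbind(data.frame(prop_nilotinib = p, prop_dasatinib = 1 - p),
          as.data.frame(as.list(setNames(vals, paste0("icer_", comps)))))
  })
  do.call(rbind, rows)
}

#' Sweep the discount rate
#'
#' Re-runs the model at each discount rate (applied to costs and effects
#' alike) and records per-strategy totals and ICERs versus the reference.
#'
#' @param spec A `tki_spec`.
#' @param rates Discount rates to evaluate (default 0 to 10\%).
#' @param reference Reference strategy.
#' @return Data frame with one row per (rate, strategy): totals and ICER
#'   (NA for the reference).
#' @export
discount_sweep <- function(spec, rates = seq(0, 0.10, by = 0.01),
                           reference = "imatinib") {
  rows <- lapply(rates, function(r) {
    s <- spec_set(spec, "econ.discount_rate", r)
    run <- run_model(s)$summary
    run$discount_rate <- r
    run$icer_vs_reference <- vapply(run$strategy, function(st)
      if (st == reference) NA_real_ else
        comparison_icer(run, st, reference), numeric(1))
    run
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
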