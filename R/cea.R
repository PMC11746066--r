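#' Incremental cost-effectiveness ratio
#'
#' @param delta_cost Incremental cost (US$).
#' @param delta_qalys Incremental effect (QALYs); must be non-zero.
#' @return `delta_cost / delta_qalys` in US$ per QALY.
#' @examples
#' icer(100, 2)
#' @export
icer <- function(delta_cost, delta_qalys) {
  if (any(delta_qalys == 0))
    stop("ICER undefined for zero QALY difference; report dominance instead")
  delta_cost / delta_qalys
}

#' Willingness-to-pay threshold from GDP per capita
#'
#' The WHO-style threshold used in the analysis: a multiple of GDP per
#' capita, rounded to the nearest 10 US$.
#'
#' @param gdp_per_capita GDP per capita in US$ (> 0).
#' @param multiplier Threshold multiple (default 3).
#' @return List with `value` (US$ per QALY), `gdp_per_capita` and
#'   `multiplier`.
#' @examples
#' derive_wtp(6253.20, 3)$value
#' @export
derive_wtp <- function(gdp_per_capita, multiplier = 3) {
  stopifnot(gdp_per_capita > 0, multiplier >= 0)
  list(value = round(gdp_per_capita * multiplier / 10) * 10,
       gdp_per_capita = gdp_per_capita, multiplier = multiplier)
}

#' Net monetary benefit
#'
#' `NMB = wtp x QALYs - cost`: the decision rule underlying
#' cost-effectiveness acceptability curves.
#'
#' @param result A `tki_result`, or a list with `total_cost` and
#'   `total_qalys`.
#' @param wtp Willingness-to-pay in US$ per QALY (a number or the list
#'   returned by [derive_wtp()]).
#' @return Net monetary benefit in US$.
#' @examples
#' nmb(list(total_cost = 120719.55, total_qalys = 5.93), 18760)
#' @export
nmb <- function(result, wtp) {
  w <- if (is.list(wtp)) wtp$value else wtp
  w * result$total_qalys - result$total_cost
}

#' Incremental cost-effectiveness table
#'
#' Sorts strategies by ascending total cost and computes incremental costs,
#' incremental QALYs, dominance flags and ICERs. Two modes:
#' \describe{
#'   \item{`"paper"`}{every non-reference strategy is compared directly to
#'     the fixed reference strategy (the layout used for reporting first-line
#'     comparisons against the standard of care).}
#'   \item{`"frontier"`}{textbook efficiency-frontier analysis: strategies
#'     strongly dominated (more costly, no more effective) are flagged and
#'     excluded; remaining strategies are compared sequentially and
#'     extendedly dominated ones (ICER higher than that of the next more
#'     effective option) are iteratively removed, so surviving ICERs are
#'     non-decreasing.}
#' }
#'
#' @param run A `tki_run` from [run_model()], or a data frame with columns
#'   `strategy`, `total_cost`, `total_qalys`.
#' @param reference Reference strategy name (default: the least costly).
#' @param mode `"paper"` (default) or `"frontier"`.
#' @return A `tki_icer_table` data frame with columns `strategy`,
#'   `total_cost`, `total_qalys`, `incremental_cost`, `incremental_qalys`,
#'   `icer`, `dominance` (`"none"`, `"dominated"`, `"extendedly_dominated"`,
#'   or `"dominant"` for cost-saving, more effective comparators).
#' @examples
#' build_incremental_table(run_model(builtin_basecase()),
#'                         reference = "imatinib")
#' @export
build_incremental_table <- function(run, reference = NULL,
                                    mode = c("paper", "frontier")) {
  mode <- match.arg(mode)
  tab <- if (is.data.frame(run)) run else run$summary
  if (nrow(tab) < 2) stop("need at least two strategies")
  tab <- tab[order(tab$total_cost, tab$strategy), , drop = FALSE]
  if (is.null(reference)) reference <- tab$strategy[1]
  if (!reference %in% tab$strategy) stop("unknown reference: ", reference)

  tab$incremental_cost <- NA_real_
  tab$incremental_qalys <- NA_real_
  tab$icer <- NA_real_
  tab$dominance <- "none"

  if (mode == "paper") {
    ref <- tab[tab$strategy == reference, ]
    for (i in seq_len(nrow(tab))) {
      if (tab$strategy[i] == reference) next
      dc <- tab$total_cost[i] - ref$total_cost
      dq <- tab$total_qalys[i] - ref$total_qalys
      tab$incremental_cost[i] <- dc
      tab$incremental_qalys[i] <- dq
      if (dc >= 0 && dq < 0) {
        tab$dominance[i] <- "dominated"
      } else if (dc < 0 && dq >= 0) {
        tab$dominance[i] <- "dominant"
      } else if (dq != 0) {
        tab$icer[i] <- dc / dq
      }
    }
  } else {
    # strong dominance: more costly and no more effective than another option
    for (i in seq_len(nrow(tab))) {
      others <- tab[-i, ]
      if (any(others$total_cost <= tab$total_cost[i] &
                others$total_qalys >= tab$total_qalys[i] &
                (others$total_cost < tab$total_cost[i] |
                   others$total_qalys > tab$total_qalys[i])))
        tab$dominance[i] <- "dominated"
    }
    repeat {
      live <- which(tab$dominance == "none")
      if (length(live) < 2) break
      icers <- rep(NA_real_, length(live))
      for (j in seq_along(live)[-1]) {
        i <- live[j]; prev <- live[j - 1]
        dq <- tab$total_qalys[i] - tab$total_qalys[prev]
        icers[j] <- (tab$total_cost[i] - tab$total_cost[prev]) / dq
      }
      ext <- which(diff(icers[-1]) < 0)
      if (length(ext) == 0) {
        for (j in seq_along(live)[-1]) {
          i <- live[j]; prev <- live[j - 1]
          tab$incremental_cost[i] <- tab$total_cost[i] - tab$total_cost[prev]
          tab$incremental_qalys[i] <- tab$total_qalys[i] - tab$total_qalys[prev]
          tab$icer[i] <- icers[j]
        }
        break
      }
      tab$dominance[live[ext[1] + 1]] <- "extendedly_dominated"
    }
  }
  attr(tab, "reference") <- reference
  attr(tab, "mode") <- mode
  class(tab) <- c("tki_icer_table", "data.frame")
  tab
}

#' @export
print.tki_icer_table <- function(x, digits = 2, ...) {
  cat(sprintf("Incremental cost-effectiveness (%s mode, reference: %s)\n",
              attr(x, "mode"), attr(x, "reference")))
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Write an incremental table as CSV
#'
#' Monetary columns are written both rounded to 2 decimals and at full
#' precision (suffix `_full`).
#'
#' @param tab A `tki_icer_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_icer_table <- function(tab, path) {
  y <- as.data.frame(tab)
  for (col in c("total_cost", "incremental_cost", "icer")) {
    y[[paste0(col, "_full")]] <- y[[col]]
    y[[col]] <- round(y[[col]], 2)
  }
  write.csv(y, path, row.names = FALSE)
  invisible(path)
}
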