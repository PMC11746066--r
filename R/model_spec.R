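#' tkicea: cost-effectiveness of first-line TKI strategies in CML
#'
#' A Markov cohort state-transition model of chronic myeloid leukemia (CML)
#' treatment sequencing under three first-line tyrosine kinase inhibitor
#' (TKI) strategies, with incremental cost-effectiveness, deterministic and
#' probabilistic sensitivity analysis, and an individual-level
#' microsimulation used as an independent verification oracle.
#'
#' @keywords internal
#' @importFrom stats rbeta rgamma qchisq cov runif setNames
#' @importFrom utils write.csv modifyList packageVersion
"_PACKAGE"

DRUG_FIELDS <- c("annual_cost", "ccyr", "os_cp", "p_apbp")

#' Packaged base-case model specification
#'
#' Returns the complete base-case parameterization of the CML treatment
#' sequencing model: three first-line strategies (imatinib, nilotinib,
#' dasatinib), annual transition probabilities, 2024 US$ costs, health-state
#' utilities, economic settings (5\% discounting, 20 annual cycles,
#' willingness-to-pay threshold of three times South Africa's GDP per
#' capita), and the low/high sensitivity-analysis range for every varied
#' parameter.
#'
#' Structure switching rules: on first-line imatinib failure (complement of
#' the 12-month complete cytogenetic response probability) patients switch
#' to nilotinib or dasatinib in equal proportions; on failure of a
#' second-generation TKI, 15\% switch to imatinib (intolerance) and 85\% to
#' the other second-generation drug (resistance).
#'
#' @param apbp_range_reading Reading of the imatinib progression-probability
#'   sensitivity range: `"corrected"` (default, 0.042--0.054, consistent with
#'   the relative widths used for the other drugs) or `"printed"`
#'   (0.42--0.54).
#' @return A `tki_spec` object: a named list with elements `drugs`,
#'   `strategies`, `transplant`, `apbp`, `costs`, `utilities`, `econ`,
#'   `conventions` and `ranges`.
#' @examples
#' spec <- builtin_basecase()
#' spec$drugs$imatinib$ccyr
#' spec$econ$wtp
#' @export
builtin_basecase <- function(apbp_range_reading = c("corrected", "printed")) {
  apbp_range_reading <- match.arg(apbp_range_reading)
  drugs <- list(
    imatinib = list(name = "imatinib", annual_cost = 4634.40,
                    ccyr = 0.67, os_cp = 0.977, p_apbp = 0.048),
    nilotinib = list(name = "nilotinib", annual_cost = 24517.94,
                     ccyr = 0.76, os_cp = 0.933, p_apbp = 0.019),
    dasatinib = list(name = "dasatinib", annual_cost = 10790.80,
                     ccyr = 0.80, os_cp = 0.931, p_apbp = 0.043)
  )
  strategies <- list(
    imatinib = list(name = "imatinib", first_line = "imatinib",
                    switch = list(nilotinib = 0.5, dasatinib = 0.5)),
    nilotinib = list(name = "nilotinib", first_line = "nilotinib",
                     switch = list(imatinib = 0.15, dasatinib = 0.85)),
    dasatinib = list(name = "dasatinib", first_line = "dasatinib",
                     switch = list(imatinib = 0.15, nilotinib = 0.85))
  )
  transplant <- list(p_receive = 0.038, os_y1 = 0.429,
                     cost_initial = 14722.43, cost_y1 = 543.55,
                     cost_post = 427.80)
  apbp <- list(os = 0.052)
  costs <- list(
    consult = 94.91, monitoring = 806.25,
    adverse_events = list(
      list(name = "non_haematological", cost = 23.53, incidence = 0.05),
      list(name = "neutropenia", cost = 358.50, incidence = 0.05),
      list(name = "thrombocytopenia", cost = 1164.28, incidence = 0.05),
      list(name = "anaemia", cost = 799.39, incidence = 0.05)
    )
  )
  utilities <- list(u_cp1 = 0.89, u_cp2 = 0.75, u_apbp = 0.22,
                    u_sct_y1 = 0.60, u_sct_post = 0.85, u_death = 0)
  gdp <- 6253.20
  econ <- list(discount_rate = 0.05, horizon_cycles = 20L,
               cycle_length_years = 1, gdp_per_capita = gdp,
               wtp_multiplier = 3, wtp = derive_wtp(gdp, 3)$value,
               cohort_size = 1000)
  conventions <- list(
    switch_mode = "per_cycle",          # or "first_cycle_only"
    discount_timing = "mid_cycle",      # or "end_of_cycle"
    apbp_drug_cost = "continue",        # or "none"
    os_post_mode = "first_line_os",     # or "constant_y1"
    range_interpretation = "ci95",      # or "minmax_uniform"
    apbp_range_reading = apbp_range_reading
  )
  p_apbp_im_range <- if (apbp_range_reading == "corrected") {
    c(0.042, 0.054)
  } else {
    c(0.42, 0.54)
  }
  ranges <- rbind(
    range_row("drugs.imatinib.ccyr", 0.60, 0.81, "beta"),
    range_row("drugs.nilotinib.ccyr", 0.63, 0.85, "beta"),
    range_row("drugs.dasatinib.ccyr", 0.68, 0.92, "beta"),
    range_row("drugs.imatinib.p_apbp", p_apbp_im_range[1],
              p_apbp_im_range[2], "beta"),
    range_row("drugs.nilotinib.p_apbp", 0.017, 0.021, "beta"),
    range_row("drugs.dasatinib.p_apbp", 0.037, 0.049, "beta"),
    range_row("drugs.imatinib.os_cp", 0.83, 1, "beta"),
    range_row("drugs.nilotinib.os_cp", 0.79, 1, "beta"),
    range_row("drugs.dasatinib.os_cp", 0.81, 1, "beta"),
    range_row("apbp.os", 0.046, 0.060, "beta"),
    range_row("transplant.p_receive", 0, 1, "beta"),
    range_row("transplant.os_y1", 0.354, 0.504, "beta"),
    range_row("drugs.imatinib.annual_cost", 2317.20, 6951.60, "gamma"),
    range_row("drugs.nilotinib.annual_cost", 12258.97, 36776.91, "gamma"),
    range_row("drugs.dasatinib.annual_cost", 5395.40, 16186.20, "gamma"),
    range_row("costs.consult", 47.46, 142.37, "gamma"),
    range_row("costs.monitoring", 403.12, 1209.38, "gamma"),
    range_row("transplant.cost_y1", 271.78, 815.32, "gamma"),
    range_row("transplant.cost_post", 213.90, 641.70, "gamma"),
    range_row("transplant.cost_initial", 7361.21, 22083.64, "gamma"),
    range_row("costs.ae.non_haematological", 11.75, 35.29, "gamma"),
    range_row("costs.ae.neutropenia", 179.25, 537.75, "gamma"),
    range_row("costs.ae.thrombocytopenia", 582.14, 1746.42, "gamma"),
    range_row("costs.ae.anaemia", 399.70, 1199.08, "gamma"),
    range_row("utilities.u_cp1", 0.78, 0.94, "beta"),
    range_row("utilities.u_cp2", 0.57, 0.85, "beta"),
    range_row("utilities.u_apbp", 0.07, 0.34, "beta"),
    range_row("utilities.u_sct_y1", 0.51, 0.69, "beta"),
    range_row("utilities.u_sct_post", 0.723, 0.978, "beta"),
    # swept in DSA only; never sampled in the PSA
    range_row("econ.discount_rate", 0, 0.10, "fixed")
  )
  new_tki_spec(list(drugs = drugs, strategies = strategies,
                    transplant = transplant, apbp = apbp, costs = costs,
                    utilities = utilities, econ = econ,
                    conventions = conventions, ranges = ranges))
}

range_row <- function(id, low, high, family) {
  data.frame(id = id, low = low, high = high, family = family,
             stringsAsFactors = FALSE)
}

new_tki_spec <- function(x) {
  structure(x, class = "tki_spec")
}

#' @export
print.tki_spec <- function(x, ...) {
  cat("<tki_spec> CML TKI treatment-sequencing model\n")
  cat("  strategies:", paste(names(x$strategies), collapse = ", "), "\n")
  cat("  drugs:     ", paste(names(x$drugs), collapse = ", "), "\n")
  cat(sprintf("  horizon %d cycles of %g year(s), discount %.1f%%, WTP %s/QALY\n",
              x$econ$horizon_cycles, x$econ$cycle_length_years,
              100 * x$econ$discount_rate, format(x$econ$wtp, big.mark = ",")))
  cat(sprintf("  conventions: switch=%s, discount=%s, AP/BP drug cost=%s, post-SCT OS=%s\n",
              x$conventions$switch_mode, x$conventions$discount_timing,
              x$conventions$apbp_drug_cost, x$conventions$os_post_mode))
  n_issue <- length(validate_spec(x))
  cat("  validation:", if (n_issue == 0) "OK" else
    sprintf("%d issue(s) - see validate_spec()", n_issue), "\n")
  invisible(x)
}

#' Validate a model specification
#'
#' Checks every structural invariant of a `tki_spec`: probabilities within
#' \[0,1\], non-negative costs, utilities within \[0,1\] with death anchored
#' at 0, switch-rule proportions summing to one and excluding the source
#' drug, referenced drugs existing, one switch rule per first-line drug, and
#' sensitivity ranges bracketing their base value.
#'
#' @param spec A `tki_spec` object.
#' @param check_ranges Whether to require each sensitivity range to bracket
#'   its base value (default TRUE; the probabilistic sensitivity analysis
#'   disables this, since sampled values legitimately fall outside the 95\%
#'   interval the range encodes).
#' @return A character vector of human-readable issues; `character(0)` when
#'   the specification is valid. Issues are data, not errors.
#' @examples
#' validate_spec(builtin_basecase())
#' @export
validate_spec <- function(spec, check_ranges = TRUE) {
  issues <- character(0)
  add <- function(msg) issues <<- c(issues, msg)
  chk_prob <- function(v, what) {
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      add(sprintf("%s: probability out of range [0,1] (got %s)", what,
                  format(v)))
  }
  chk_cost <- function(v, what) {
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      add(sprintf("%s: cost < 0 (got %s)", what, format(v)))
  }

  for (dn in names(spec$drugs)) {
    d <- spec$drugs[[dn]]
    chk_cost(d$annual_cost, paste0("drugs.", dn, ".annual_cost"))
    chk_prob(d$ccyr, paste0("drugs.", dn, ".ccyr"))
    chk_prob(d$os_cp, paste0("drugs.", dn, ".os_cp"))
    chk_prob(d$p_apbp, paste0("drugs.", dn, ".p_apbp"))
  }

  first_lines <- character(0)
  for (sn in names(spec$strategies)) {
    s <- spec$strategies[[sn]]
    if (!s$first_line %in% names(spec$drugs))
      add(sprintf("strategies.%s: unknown first-line drug '%s'", sn,
                  s$first_line))
    first_lines <- c(first_lines, s$first_line)
    if (length(s$switch) == 0) {
      add(sprintf("strategies.%s: empty switch rule", sn))
    } else {
      if (abs(sum(unlist(s$switch)) - 1) > 1e-9)
        add(sprintf("strategies.%s: switch splits sum != 1 (got %.12g)", sn,
                    sum(unlist(s$switch))))
      if (s$first_line %in% names(s$switch))
        add(sprintf("strategies.%s: switch destinations include the first-line drug", sn))
      for (dest in names(s$switch)) {
        if (!dest %in% names(spec$drugs))
          add(sprintf("strategies.%s: unknown switch destination '%s'", sn, dest))
        if (s$switch[[dest]] < 0 || s$switch[[dest]] > 1)
          add(sprintf("strategies.%s: switch proportion to %s out of [0,1]",
                      sn, dest))
      }
    }
  }
  if (anyDuplicated(first_lines))
    add("strategies: more than one switch rule for the same first-line drug")

  chk_prob(spec$transplant$p_receive, "transplant.p_receive")
  chk_prob(spec$transplant$os_y1, "transplant.os_y1")
  chk_cost(spec$transplant$cost_initial, "transplant.cost_initial")
  chk_cost(spec$transplant$cost_y1, "transplant.cost_y1")
  chk_cost(spec$transplant$cost_post, "transplant.cost_post")
  chk_prob(spec$apbp$os, "apbp.os")

  chk_cost(spec$costs$consult, "costs.consult")
  chk_cost(spec$costs$monitoring, "costs.monitoring")
  for (ae in spec$costs$adverse_events) {
    chk_cost(ae$cost, paste0("costs.ae.", ae$name))
    chk_prob(ae$incidence, paste0("costs.ae.", ae$name, ".incidence"))
  }

  for (un in c("u_cp1", "u_cp2", "u_apbp", "u_sct_y1", "u_sct_post",
               "u_death")) {
    chk_prob(spec$utilities[[un]], paste0("utilities.", un))
  }
  if (!identical(as.numeric(spec$utilities$u_death), 0))
    add("utilities.u_death: must equal 0 (death anchors the utility scale)")

  e <- spec$econ
  if (e$discount_rate < 0 || e$discount_rate > 1)
    add("econ.discount_rate: out of [0,1]")
  if (e$horizon_cycles < 1)
    add("econ.horizon_cycles: must be >= 1")
  if (e$wtp < 0) add("econ.wtp: must be >= 0")

  if (nrow(spec$ranges) > 0) {
    for (i in seq_len(nrow(spec$ranges))) {
      r <- spec$ranges[i, ]
      if (!r$family %in% c("beta", "gamma", "fixed")) {
        add(sprintf("ranges[%s]: unknown distribution family '%s'", r$id,
                    r$family))
        next
      }
      base <- tryCatch(spec_get(spec, r$id), error = function(e) NA_real_)
      if (is.na(base)) {
        add(sprintf("ranges[%s]: unknown parameter id", r$id))
      } else if (check_ranges && (r$low > base + 1e-12 || r$high < base - 1e-12)) {
        add(sprintf("ranges[%s]: base %.6g outside [low, high] = [%.6g, %.6g]",
                    r$id, base, r$low, r$high))
      }
      if (r$low > r$high) add(sprintf("ranges[%s]: low > high", r$id))
    }
  }
  issues
}
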