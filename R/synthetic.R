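#' Configuration for the random model generator
#'
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @param n_drugs Inclusive bounds on the number of drugs (2--4).
#' @param prob_bounds Named list of `c(low, high)` supports for the sampled
#'   probability classes (`ccyr`, `os_cp`, `p_apbp`, `os_apbp`, `p_receive`,
#'   `os_y1`). Probabilities are drawn from a beta(2, 2) rescaled into the
#'   support, stressing both central and near-boundary regimes.
#' @param cost_log10 Bounds of the log10-uniform scale for annual and
#'   one-time costs.
#' @param range_width Relative half-width factor of generated sensitivity
#'   ranges (0 gives degenerate ranges and hence a degenerate PSA).
#' @param horizon Inclusive bounds on the cycle horizon.
#' @param discount Bounds on the annual discount rate.
#' @return A `tki_genconfig` list.
#' @export
generator_config <- function(seed = 1,
                             n_drugs = c(2L, 4L),
                             prob_bounds = list(
                               ccyr = c(0.3, 0.95),
                               os_cp = c(0.7, 0.995),
                               p_apbp = c(0.005, 0.2),
                               os_apbp = c(0.01, 0.3),
                               p_receive = c(0.005, 0.3),
                               os_y1 = c(0.2, 0.8)),
                             cost_log10 = c(2, 4.5),
                             range_width = 0.3,
                             horizon = c(5L, 30L),
                             discount = c(0, 0.1)) {
  stopifnot(n_drugs[1] >= 2, n_drugs[2] <= 26, range_width >= 0,
            horizon[1] >= 1)
  structure(list(seed = seed, n_drugs = n_drugs, prob_bounds = prob_bounds,
                 cost_log10 = cost_log10, range_width = range_width,
                 horizon = horizon, discount = discount),
            class = "tki_genconfig")
}

rprob <- function(bounds) bounds[1] + diff(bounds) * rbeta(1, 2, 2)
rcost <- function(b) 10^runif(1, b[1], b[2])

#' Generate a random valid model specification
#'
#' Draws a complete specification with the same structure as the packaged
#' base case: 2--4 drugs, one strategy per first-line drug with random
#' switch splits over the remaining drugs, transplant/AP-BP parameters,
#' costs, utilities (death fixed at 0), economic settings, and a coherent
#' sensitivity range for every drug, cost and utility parameter. Every
#' generated specification passes [validate_spec()] with zero issues, and
#' identical seeds give identical specifications.
#'
#' @param config A `tki_genconfig` from [generator_config()].
#' @return A valid `tki_spec`.
#' @examples
#' spec <- random_model(generator_config(seed = 42))
#' validate_spec(spec)
#' @export
random_model <- function(config = generator_config()) {
  local_seed(config$seed, {
    nd <- sample(seq(config$n_drugs[1], config$n_drugs[2]), 1)
    drug_names <- paste0("drug_", letters[seq_len(nd)])
    pb <- config$prob_bounds
    drugs <- lapply(drug_names, function(dn)
      list(name = dn, annual_cost = rcost(config$cost_log10),
           ccyr = rprob(pb$ccyr), os_cp = rprob(pb$os_cp),
           p_apbp = rprob(pb$p_apbp)))
    names(drugs) <- drug_names
    strategies <- lapply(drug_names, function(dn) {
      others <- setdiff(drug_names, dn)
      w <- runif(length(others), 0.05, 1)
      w <- w / sum(w)
      list(name = dn, first_line = dn,
           switch = as.list(setNames(w, others)))
    })
    names(strategies) <- drug_names
    transplant <- list(p_receive = rprob(pb$p_receive),
                       os_y1 = rprob(pb$os_y1),
                       cost_initial = rcost(config$cost_log10),
                       cost_y1 = rcost(config$cost_log10),
                       cost_post = rcost(config$cost_log10))
    apbp <- list(os = rprob(pb$os_apbp))
    costs <- list(consult = rcost(config$cost_log10),
                  monitoring = rcost(config$cost_log10),
                  adverse_events = list(
                    list(name = "ae_1", cost = rcost(config$cost_log10),
                         incidence = runif(1, 0, 0.3))))
    # keep the clinical ordering of health-state utilities
    u <- sort(runif(5, 0.05, 0.98))
    utilities <- list(u_cp1 = u[5], u_cp2 = u[4], u_apbp = u[1],
                      u_sct_y1 = u[2], u_sct_post = u[3], u_death = 0)
    gdp <- rcost(c(3, 4.5))
    econ <- list(discount_rate = runif(1, config$discount[1],
                                       config$discount[2]),
                 horizon_cycles = sample(seq(config$horizon[1],
                                             config$horizon[2]), 1),
                 cycle_length_years = 1, gdp_per_capita = gdp,
                 wtp_multiplier = 3, wtp = derive_wtp(gdp, 3)$value,
                 cohort_size = 1000)
    conventions <- list(switch_mode = "per_cycle",
                        discount_timing = "mid_cycle",
                        apbp_drug_cost = "continue",
                        os_post_mode = "first_line_os",
                        range_interpretation = "ci95",
                        apbp_range_reading = "corrected")
    spec <- new_tki_spec(list(drugs = drugs, strategies = strategies,
                              transplant = transplant, apbp = apbp,
                              costs = costs, utilities = utilities,
                              econ = econ, conventions = conventions,
                              ranges = range_row("econ.discount_rate",
                                                 0, 0.1, "fixed")[0, ]))
    spec$ranges <- build_synthetic_ranges(spec, config$range_width)
    spec
  })
}

build_synthetic_ranges <- function(spec, width) {
  prob_ids <- c(
    paste0("drugs.", names(spec$drugs), ".ccyr"),
    paste0("drugs.", names(spec$drugs), ".os_cp"),
    paste0("drugs.", names(spec$drugs), ".p_apbp"),
    "apbp.os", "transplant.p_receive", "transplant.os_y1",
    "utilities.u_cp1", "utilities.u_cp2", "utilities.u_apbp",
    "utilities.u_sct_y1", "utilities.u_sct_post")
  cost_ids <- c(
    paste0("drugs.", names(spec$drugs), ".annual_cost"),
    "costs.consult", "costs.monitoring", "transplant.cost_initial",
    "transplant.cost_y1", "transplant.cost_post", "costs.ae.ae_1")
  rows <- lapply(prob_ids, function(id) {
    base <- spec_get(spec, id)
    range_row(id, max(1e-6, base * (1 - width)),
              min(1 - 1e-6, base * (1 + width)), "beta")
  })
  rows <- c(rows, lapply(cost_ids, function(id) {
    base <- spec_get(spec, id)
    range_row(id, base * (1 - width), base * (1 + width), "gamma")
  }))
  out <- do.call(rbind, rows)
  # guard against caps inverting an interval around a near-boundary base
  bad <- out$low > out$high
  if (any(bad)) {
    base <- vapply(out$id[bad], function(id) spec_get(spec, id), numeric(1))
    out$low[bad] <- base
    out$high[bad] <- base
  }
  out
}

#' Perturb one parameter of a specification
#'
#' Clone-and-modify helper for monotonicity property tests: returns a copy
#' with `delta` added to the parameter, erroring if the result leaves the
#' parameter's support (probabilities and utilities must stay in \[0,1\],
#' costs non-negative).
#'
#' @inheritParams spec_get
#' @param delta Additive change.
#' @return A new `tki_spec`; the input is untouched.
#' @export
perturb <- function(spec, id, delta) {
  value <- spec_get(spec, id) + delta
  rng <- spec_range(spec, id)
  is_prob <- !is.null(rng) && rng$family == "beta" ||
    grepl("ccyr|os_|p_apbp|p_receive|utilities|incidence|discount_rate", id)
  if (value < 0 || (is_prob && value > 1))
    stop("perturbed value ", value, " outside the support of ", id)
  spec_set(spec, id, value)
}
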