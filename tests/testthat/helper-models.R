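# Shared fixtures, built in code.

basecase <- builtin_basecase()

# A spec in which every drug has identical parameters, so expanded
# second-line states are interchangeable (used for aggregation oracles).
uniform_drug_spec <- function(ccyr = 0.7, os_cp = 0.95, p_apbp = 0.05,
                              cost = 1000) {
  spec <- builtin_basecase()
  for (d in names(spec$drugs)) {
    spec$drugs[[d]]$ccyr <- ccyr
    spec$drugs[[d]]$os_cp <- os_cp
    spec$drugs[[d]]$p_apbp <- p_apbp
    spec$drugs[[d]]$annual_cost <- cost
  }
  spec$ranges <- spec$ranges[spec$ranges$id == "econ.discount_rate", ]
  spec
}

# A fake PSA object with prescribed per-iteration outcomes, for testing the
# decision layer (CEAC, pairwise acceptability, ellipse) in isolation.
fake_psa <- function(cost, qalys, seed = 0) {
  stopifnot(identical(dim(cost), dim(qalys)))
  structure(list(n = nrow(cost), seed = seed,
                 strategies = colnames(cost),
                 draws = data.frame(row.names = seq_len(nrow(cost))),
                 cost = cost, qalys = qalys),
            class = "tki_psa")
}

# Degenerate single-state model: everyone stays in first-line CP forever.
immortal_spec <- function(discount_rate = 0, horizon = 2) {
  spec <- builtin_basecase()
  for (d in names(spec$drugs)) {
    spec$drugs[[d]]$os_cp <- 1
    spec$drugs[[d]]$ccyr <- 1
  }
  spec$econ$discount_rate <- discount_rate
  spec$econ$horizon_cycles <- as.integer(horizon)
  spec
}
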