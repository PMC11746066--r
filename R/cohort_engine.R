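#' Expanded state space for one strategy
#'
#' The clinical model has five mutually exclusive health states: chronic
#' phase on first-line TKI, chronic phase on second-line TKI, progression to
#' the merged accelerated/blast phase (AP/BP), allogeneic stem-cell
#' transplantation (SCT), and death. For computation the second-line and
#' AP/BP states are expanded per second-line drug (the drug determines both
#' the transition probabilities and the drug-cost accrual), and SCT is split
#' into a first-year tunnel state and a post-first-year state. Summing the
#' expanded states back recovers the five clinical states exactly.
#'
#' @param spec A `tki_spec`.
#' @param strategy Strategy name present in `spec$strategies`.
#' @return Character vector of state names in fixed order: `CP1`, one
#'   `CP2[d]` and one `APBP[d]` per switch destination `d`, `SCT_Y1`,
#'   `SCT_POST`, `DEATH`; with attributes `first_line` and `destinations`.
#' @examples
#' build_state_space(builtin_basecase(), "imatinib")
#' @export
build_state_space <- function(spec, strategy) {
  strat <- spec$strategies[[strategy]]
  if (is.null(strat)) stop("unknown strategy: ", strategy)
  dests <- names(strat$switch)
  if (length(dests) == 0)
    stop("strategy '", strategy, "' has an empty switch rule")
  states <- c("CP1",
              paste0("CP2[", dests, "]"),
              paste0("APBP[", dests, "]"),
              "SCT_Y1", "SCT_POST", "DEATH")
  attr(states, "first_line") <- strat$first_line
  attr(states, "destinations") <- dests
  states
}

#' Per-cycle transition matrix for one strategy
#'
#' Builds the annual transition matrix over the expanded state space.
#' Within each cycle death is applied first and clinical events (treatment
#' switch, progression, SCT receipt) are applied to survivors, so each row
#' is a proper probability distribution without rescaling:
#' \itemize{
#'   \item CP1: death with `1 - os_cp(first-line drug)`; surviving patients
#'     switch with probability `1 - ccyr(first-line drug)`, divided across
#'     destinations per the strategy's switch rule, otherwise remain.
#'   \item CP2\[d\]: death with `1 - os_cp(d)`; survivors progress to
#'     APBP\[d\] with `p_apbp(d)`, otherwise remain.
#'   \item APBP\[d\]: SCT receipt with `p_receive`; non-transplanted
#'     patients die with `1 - os(AP/BP)`, otherwise remain.
#'   \item SCT_Y1: to SCT_POST with the first-year post-SCT survival
#'     probability, otherwise death.
#'   \item SCT_POST: annual survival per the `os_post_mode` convention
#'     (default: the strategy's first-line chronic-phase survival as proxy;
#'     `"constant_y1"` re-applies the first-year post-SCT probability).
#'   \item DEATH: absorbing.
#' }
#'
#' Under the `"first_cycle_only"` switch convention, `phase = "post_switch"`
#' returns the matrix used from cycle 2 onwards, in which CP1 survivors no
#' longer switch.
#'
#' @inheritParams build_state_space
#' @param phase `"switch"` (default; the cycle-1 matrix) or `"post_switch"`.
#' @return Square numeric matrix with state dimnames; rows sum to 1.
#' @export
build_transition_matrix <- function(spec, strategy,
                                    phase = c("switch", "post_switch")) {
  phase <- match.arg(phase)
  states <- build_state_space(spec, strategy)
  first <- attr(states, "first_line")
  dests <- attr(states, "destinations")
  strat <- spec$strategies[[strategy]]
  S <- length(states)
  snames <- as.character(states)
  P <- matrix(0, S, S, dimnames = list(snames, snames))

  switching <- phase == "switch" || spec$conventions$switch_mode == "per_cycle"

  fl <- spec$drugs[[first]]
  p_die <- 1 - fl$os_cp
  p_switch_tot <- if (switching) (1 - fl$ccyr) else 0
  P["CP1", "DEATH"] <- p_die
  P["CP1", "CP1"] <- fl$os_cp * (1 - p_switch_tot)
  for (d in dests) {
    P["CP1", paste0("CP2[", d, "]")] <-
      fl$os_cp * p_switch_tot * strat$switch[[d]]
  }

  for (d in dests) {
    dd <- spec$drugs[[d]]
    cp2 <- paste0("CP2[", d, "]")
    ap <- paste0("APBP[", d, "]")
    P[cp2, "DEATH"] <- 1 - dd$os_cp
    P[cp2, ap] <- dd$os_cp * dd$p_apbp
    P[cp2, cp2] <- dd$os_cp * (1 - dd$p_apbp)
    pr <- spec$transplant$p_receive
    P[ap, "SCT_Y1"] <- pr
    P[ap, "DEATH"] <- (1 - pr) * (1 - spec$apbp$os)
    P[ap, ap] <- (1 - pr) * spec$apbp$os
  }

  P["SCT_Y1", "SCT_POST"] <- spec$transplant$os_y1
  P["SCT_Y1", "DEATH"] <- 1 - spec$transplant$os_y1
  os_post <- switch(spec$conventions$os_post_mode,
                    first_line_os = fl$os_cp,
                    constant_y1 = spec$transplant$os_y1,
                    stop("unknown os_post_mode: ",
                         spec$conventions$os_post_mode))
  P["SCT_POST", "SCT_POST"] <- os_post
  P["SCT_POST", "DEATH"] <- 1 - os_post
  P["DEATH", "DEATH"] <- 1

  bad <- abs(rowSums(P) - 1) > 1e-9
  if (any(bad))
    stop("internal consistency error: transition row(s) do not sum to 1: ",
         paste(states[bad], collapse = ", "))
  P
}

#' Run the cohort trace
#'
#' Propagates the cohort through the transition matrix for `horizon` cycles,
#' starting (by default) with the whole cohort in the first state. Records
#' both occupancy at every cycle boundary and, for one-time cost
#' accounting, the fraction of the cohort newly entering each state during
#' each cycle (inflow from other states; the initial occupancy counts as
#' entry during cycle 1).
#'
#' @param matrix A transition matrix, or a list of two matrices
#'   `list(first, rest)` when the first cycle differs (treatment switching
#'   applied in cycle 1 only).
#' @param horizon Number of cycles, at least 1.
#' @param init Optional initial occupancy vector (defaults to all mass in
#'   state 1).
#' @return A `tki_trace`: list with `occupancy` ((horizon+1) x S matrix,
#'   rows t = 0..horizon) and `entrants` (horizon x S matrix, rows = cycles).
#' @examples
#' P <- matrix(c(0.5, 0.5, 0, 1), 2, byrow = TRUE,
#'             dimnames = list(c("A", "B"), c("A", "B")))
#' run_trace(P, 2)$occupancy
#' @export
run_trace <- function(matrix, horizon, init = NULL) {
  mats <- if (is.list(matrix)) matrix else list(matrix, matrix)
  P1 <- mats[[1]]
  P <- mats[[2]]
  stopifnot(horizon >= 1, nrow(P1) == ncol(P1),
            identical(dim(P1), dim(P)))
  S <- nrow(P1)
  states <- rownames(P1)
  if (is.null(init)) init <- c(1, rep(0, S - 1))
  occ <- matrix(0, horizon + 1, S,
                dimnames = list(paste0("t", 0:horizon), states))
  ent <- matrix(0, horizon, S,
                dimnames = list(paste0("cycle", seq_len(horizon)), states))
  occ[1, ] <- init
  ent[1, ] <- init  # cohort entry counts as entry during cycle 1
  for (k in seq_len(horizon)) {
    Pk <- if (k == 1) P1 else P
    prev <- occ[k, ]
    occ[k + 1, ] <- as.numeric(prev %*% Pk)
    inflow <- as.numeric(prev %*% (Pk - diag(diag(Pk), S)))
    ent[k, ] <- ent[k, ] + inflow
  }
  structure(list(occupancy = occ, entrants = ent, horizon = horizon),
            class = "tki_trace")
}

strategy_matrices <- function(spec, strategy) {
  if (spec$conventions$switch_mode == "per_cycle") {
    P <- build_transition_matrix(spec, strategy, "switch")
    list(P, P)
  } else {
    list(build_transition_matrix(spec, strategy, "switch"),
         build_transition_matrix(spec, strategy, "post_switch"))
  }
}

state_values <- function(spec, strategy) {
  states <- build_state_space(spec, strategy)
  first <- attr(states, "first_line")
  dests <- attr(states, "destinations")
  u <- spec$utilities
  S <- length(states)
  drug_cost <- setNames(numeric(S), states)
  followup <- setNames(numeric(S), states)
  sct_cost <- setNames(numeric(S), states)
  util <- setNames(numeric(S), states)
  fu <- spec$costs$consult + spec$costs$monitoring

  drug_cost["CP1"] <- spec$drugs[[first]]$annual_cost
  followup["CP1"] <- fu
  util["CP1"] <- u$u_cp1
  for (d in dests) {
    cp2 <- paste0("CP2[", d, "]")
    ap <- paste0("APBP[", d, "]")
    drug_cost[cp2] <- spec$drugs[[d]]$annual_cost
    followup[cp2] <- fu
    util[cp2] <- u$u_cp2
    if (spec$conventions$apbp_drug_cost == "continue")
      drug_cost[ap] <- spec$drugs[[d]]$annual_cost
    followup[ap] <- fu
    util[ap] <- u$u_apbp
  }
  sct_cost["SCT_Y1"] <- spec$transplant$cost_y1
  sct_cost["SCT_POST"] <- spec$transplant$cost_post
  util["SCT_Y1"] <- u$u_sct_y1
  util["SCT_POST"] <- u$u_sct_post
  util["DEATH"] <- u$u_death

  ae_bundle <- sum(vapply(spec$costs$adverse_events,
                          function(a) a$cost * a$incidence, numeric(1)))
  line_states <- c("CP1", paste0("CP2[", dests, "]"))
  list(states = states, drug_cost = drug_cost, followup = followup,
       sct_cost = sct_cost, util = util, ae_bundle = ae_bundle,
       line_states = line_states)
}

discount_factors <- function(spec, horizon) {
  r <- spec$econ$discount_rate
  k <- seq_len(horizon)
  expo <- switch(spec$conventions$discount_timing,
                 mid_cycle = k - 0.5,
                 end_of_cycle = k,
                 stop("unknown discount_timing: ",
                      spec$conventions$discount_timing))
  (1 + r)^(-expo)
}

#' Accumulate discounted costs and QALYs over a trace
#'
#' Applies the half-cycle correction (state membership in cycle k is the
#' mean of the occupancies at its two boundaries), accrues recurring annual
#' costs (drug, consultation + monitoring, SCT follow-up) and utilities on
#' the corrected occupancy, applies one-time costs (SCT initial cost,
#' adverse-event bundle at each treatment-line initiation) to entrant
#' counts, and discounts each cycle at the configured timing (default:
#' mid-cycle, `(1+r)^-(k-0.5)`, consistent with the half-cycle correction).
#'
#' @inheritParams build_state_space
#' @param trace A `tki_trace` produced from this strategy's matrices.
#' @return A `tki_result`: list with `strategy`, `total_cost`,
#'   `total_qalys` (both discounted, per patient) and `cycles`, a per-cycle
#'   data frame of cost components (`cost_drug`, `cost_followup`,
#'   `cost_sct`, `cost_ae`) and QALY contributions.
#' @export
accumulate <- function(spec, strategy, trace) {
  sv <- state_values(spec, strategy)
  states <- sv$states
  occ <- trace$occupancy
  if (!identical(colnames(occ), as.character(states)))
    stop("trace states do not match strategy '", strategy, "'")
  H <- trace$horizon
  df <- discount_factors(spec, H)

  eff <- (occ[seq_len(H), , drop = FALSE] +
            occ[seq_len(H) + 1, , drop = FALSE]) / 2
  cost_drug <- as.numeric(eff %*% sv$drug_cost) * df
  cost_followup <- as.numeric(eff %*% sv$followup) * df
  cost_sct_rec <- as.numeric(eff %*% sv$sct_cost) * df
  qaly <- as.numeric(eff %*% sv$util) * df

  ent <- trace$entrants
  cost_sct_once <- ent[, "SCT_Y1"] * spec$transplant$cost_initial * df
  line_entrants <- rowSums(ent[, sv$line_states, drop = FALSE])
  cost_ae <- line_entrants * sv$ae_bundle * df

  cycles <- data.frame(
    cycle = seq_len(H),
    discount = df,
    cost_drug = cost_drug,
    cost_followup = cost_followup,
    cost_sct = cost_sct_rec + cost_sct_once,
    cost_ae = cost_ae,
    qaly = qaly
  )
  cycles$cost_total <- with(cycles, cost_drug + cost_followup + cost_sct +
                              cost_ae)
  structure(list(strategy = strategy,
                 total_cost = sum(cycles$cost_total),
                 total_qalys = sum(cycles$qaly),
                 cycles = cycles),
            class = "tki_result")
}

#' @export
print.tki_result <- function(x, ...) {
  cat(sprintf("<tki_result> %s: discounted cost $%s, %.4f QALYs per patient\n",
              x$strategy, format(round(x$total_cost, 2), big.mark = ","),
              x$total_qalys))
  invisible(x)
}

#' Run one strategy end to end
#'
#' Builds the strategy's transition matrices, runs the cohort trace over the
#' configured horizon, and accumulates discounted costs and QALYs.
#'
#' @inheritParams build_state_space
#' @return A `tki_result` (see [accumulate()]) with the `tki_trace` attached
#'   as element `trace`.
#' @examples
#' run_strategy(builtin_basecase(), "imatinib")
#' @export
run_strategy <- function(spec, strategy) {
  mats <- strategy_matrices(spec, strategy)
  trace <- run_trace(mats, spec$econ$horizon_cycles)
  res <- accumulate(spec, strategy, trace)
  res$trace <- trace
  res
}

#' Run every strategy in a specification
#'
#' @param spec A `tki_spec`.
#' @return A `tki_run`: named list of `tki_result` objects (one per
#'   strategy) with a `summary` data frame (`strategy`, `total_cost`,
#'   `total_qalys`).
#' @examples
#' run_model(builtin_basecase())$summary
#' @export
run_model <- function(spec) {
  results <- lapply(names(spec$strategies), function(s)
    run_strategy(spec, s))
  names(results) <- names(spec$strategies)
  summary <- data.frame(
    strategy = names(results),
    total_cost = vapply(results, `[[`, numeric(1), "total_cost"),
    total_qalys = vapply(results, `[[`, numeric(1), "total_qalys"),
    row.names = NULL
  )
  structure(list(results = results, summary = summary, spec = spec),
            class = "tki_run")
}

#' @export
print.tki_run <- function(x, ...) {
  cat("<tki_run> discounted per-patient totals\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Aggregate an expanded trace to the five clinical states
#'
#' Sums second-line chronic-phase and AP/BP occupancy across second-line
#' drugs and the two SCT states into the model's five clinical states:
#' first-line CP, second-line CP, AP/BP, SCT, death.
#'
#' @param trace A `tki_trace`.
#' @return Occupancy matrix with columns `CP1`, `CP2`, `APBP`, `SCT`,
#'   `DEATH`.
#' @export
aggregate_trace <- function(trace) {
  occ <- trace$occupancy
  nm <- colnames(occ)
  grp <- ifelse(nm == "CP1", "CP1",
         ifelse(startsWith(nm, "CP2"), "CP2",
         ifelse(startsWith(nm, "APBP"), "APBP",
         ifelse(nm %in% c("SCT_Y1", "SCT_POST"), "SCT", "DEATH"))))
  out <- sapply(c("CP1", "CP2", "APBP", "SCT", "DEATH"), function(g)
    rowSums(occ[, grp == g, drop = FALSE]))
  out
}

#' Export a trace as a long data frame
#'
#' @param trace A `tki_trace`.
#' @return Data frame with columns `cycle` (boundary index t = 0..horizon),
#'   `state`, `occupancy`.
#' @export
trace_as_df <- function(trace) {
  occ <- trace$occupancy
  data.frame(
    cycle = rep(0:trace$horizon, times = ncol(occ)),
    state = rep(colnames(occ), each = nrow(occ)),
    occupancy = as.numeric(occ),
    row.names = NULL
  )
}
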