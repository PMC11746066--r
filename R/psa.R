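Z975 <- 1.959964

#' Fit a beta distribution from a base value and a range
#'
#' The range is interpreted as a 95\% interval, giving
#' `sd = (high - low) / (2 * 1.959964)`; shape parameters follow by the
#' method of moments, so the fitted mean equals the base value. When the
#' implied variance is infeasible for a beta distribution
#' (`sd^2 >= mean * (1 - mean)`), a flagged minimal-information fit is used:
#' the mean is preserved and the effective sample size is shrunk so that the
#' smaller shape parameter equals 0.5.
#'
#' @param mean Base-case probability or utility, strictly inside (0, 1).
#' @param low,high Range bounds, `low < high`.
#' @return A `tki_dist`: list with `family = "beta"`, `shape1`, `shape2`,
#'   `mean`, `sd`, `fallback` flag.
#' @examples
#' fit_beta(0.5, 0.30401, 0.69599)  # alpha = beta = 12
#' @export
fit_beta <- function(mean, low, high) {
  if (mean <= 0 || mean >= 1) stop("beta fit requires mean in (0, 1)")
  if (low >= high) stop("beta fit requires low < high")
  sd <- (high - low) / (2 * Z975)
  v <- sd^2
  fallback <- v >= mean * (1 - mean)
  if (!fallback) {
    nu <- mean * (1 - mean) / v - 1
    shape1 <- mean * nu
    shape2 <- (1 - mean) * nu
  } else {
    nu <- 0.5 / min(mean, 1 - mean)
    shape1 <- mean * nu
    shape2 <- (1 - mean) * nu
  }
  structure(list(family = "beta", shape1 = shape1, shape2 = shape2,
                 mean = mean, sd = sqrt(shape1 * shape2 /
                   ((shape1 + shape2)^2 * (shape1 + shape2 + 1))),
                 fallback = fallback),
            class = "tki_dist")
}

#' Fit a gamma distribution from a base value and a range
#'
#' The range is interpreted as a 95\% interval, giving
#' `sd = (high - low) / (2 * 1.959964)`; method of moments then yields
#' `shape = (mean/sd)^2`, `scale = sd^2/mean`, so the fitted mean equals the
#' base value exactly.
#'
#' @param mean Base-case cost, > 0.
#' @param low,high Range bounds, `low < high`.
#' @return A `tki_dist`: list with `family = "gamma"`, `shape`, `scale`,
#'   `mean`, `sd`.
#' @examples
#' fit_gamma(100, 100 - 50 * 1.959964, 100 + 50 * 1.959964)  # shape 4, scale 25
#' @export
fit_gamma <- function(mean, low, high) {
  if (mean <= 0) stop("gamma fit requires mean > 0")
  if (low >= high) stop("gamma fit requires low < high")
  sd <- (high - low) / (2 * Z975)
  structure(list(family = "gamma", shape = (mean / sd)^2,
                 scale = sd^2 / mean, mean = mean, sd = sd,
                 fallback = FALSE),
            class = "tki_dist")
}

#' @export
print.tki_dist <- function(x, ...) {
  if (x$family == "beta") {
    cat(sprintf("<tki_dist> beta(%.4g, %.4g), mean %.4g, sd %.4g%s\n",
                x$shape1, x$shape2, x$mean, x$sd,
                if (x$fallback) " [minimal-information fallback]" else ""))
  } else {
    cat(sprintf("<tki_dist> gamma(shape %.4g, scale %.4g), mean %.4g, sd %.4g\n",
                x$shape, x$scale, x$mean, x$sd))
  }
  invisible(x)
}

#' Fit sampling distributions for every ranged parameter
#'
#' Probabilities and utilities get beta fits, costs get gamma fits
#' (method-of-moments, range read as a 95\% interval by default, or as the
#' support of a uniform under the `"minmax_uniform"` convention). Parameters
#' whose range is degenerate (`low == high`) or marked `fixed` are held at
#' their base value in the PSA.
#'
#' @param spec A `tki_spec`.
#' @return Named list of `tki_dist` objects (or `list(family =
#'   "degenerate", value = base)` entries), one per sampled parameter id.
#' @export
fit_ranges <- function(spec) {
  out <- list()
  for (i in seq_len(nrow(spec$ranges))) {
    r <- spec$ranges[i, ]
    if (r$family == "fixed") next
    base <- spec_get(spec, r$id)
    if (r$low == r$high) {
      out[[r$id]] <- list(family = "degenerate", value = base)
    } else if (spec$conventions$range_interpretation == "minmax_uniform") {
      out[[r$id]] <- list(family = "uniform", low = r$low, high = r$high)
    } else if (r$family == "beta") {
      out[[r$id]] <- fit_beta(base, r$low, r$high)
    } else {
      out[[r$id]] <- fit_gamma(base, r$low, r$high)
    }
  }
  out
}

draw_params <- function(fits, n) {
  cols <- lapply(fits, function(f) {
    switch(f$family,
           degenerate = rep(f$value, n),
           uniform = runif(n, f$low, f$high),
           beta = rbeta(n, f$shape1, f$shape2),
           gamma = rgamma(n, shape = f$shape, scale = f$scale))
  })
  as.data.frame(cols, check.names = FALSE, optional = TRUE)
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo over parameter uncertainty: every ranged parameter is drawn
#' independently from its fitted distribution (switch-split proportions have
#' no printed range and stay fixed), the full cohort model is evaluated for
#' all strategies on each shared draw, and per-iteration (cost, QALY) pairs
#' are recorded. All randomness flows from `seed`: the same seed gives a
#' bitwise-identical sample.
#'
#' @param spec A `tki_spec`.
#' @param n Number of iterations (default 1000).
#' @param seed Integer seed.
#' @return A `tki_psa`: list with `n`, `seed`, `strategies`, `draws` (n x
#'   parameters data frame, for audit), `cost` and `qalys` (n x strategies
#'   matrices).
#' @examples
#' psa <- run_psa(builtin_basecase(), n = 25, seed = 1)
#' colMeans(psa$cost)
#' @export
run_psa <- function(spec, n = 1000, seed = 1) {
  stopifnot(n >= 1)
  issues <- validate_spec(spec)
  if (length(issues) > 0)
    stop("invalid spec:\n  ", paste(issues, collapse = "\n  "))
  fits <- fit_ranges(spec)
  draws <- local_seed(seed, draw_params(fits, n))
  strategies <- names(spec$strategies)
  cost <- matrix(NA_real_, n, length(strategies),
                 dimnames = list(NULL, strategies))
  qalys <- cost
  for (it in seq_len(n)) {
    s <- spec
    for (id in names(draws)) s <- spec_set(s, id, draws[[id]][it])
    iss <- validate_spec(s, check_ranges = FALSE)
    if (length(iss) > 0)
      stop("iteration ", it, " produced an invalid spec:\n  ",
           paste(iss, collapse = "\n  "))
    for (st in strategies) {
      res <- run_strategy(s, st)
      cost[it, st] <- res$total_cost
      qalys[it, st] <- res$total_qalys
    }
  }
  structure(list(n = n, seed = seed, strategies = strategies,
                 draws = draws, cost = cost, qalys = qalys),
            class = "tki_psa")
}

#' @export
print.tki_psa <- function(x, ...) {
  cat(sprintf("<tki_psa> %d iterations (seed %s), %d parameters sampled\n",
              x$n, format(x$seed), ncol(x$draws)))
  m <- data.frame(strategy = x$strategies,
                  mean_cost = colMeans(x$cost),
                  mean_qalys = colMeans(x$qalys), row.names = NULL)
  print(m, row.names = FALSE)
  invisible(x)
}

#' Default willingness-to-pay grid
#'
#' 0 to 60,000 US$/QALY in steps of 500, always including the
#' specification's configured threshold as an exact grid point.
#'
#' @param spec A `tki_spec`.
#' @return Sorted numeric vector.
#' @export
default_wtp_grid <- function(spec) {
  sort(unique(c(seq(0, 60000, by = 500), spec$econ$wtp)))
}

#' Cost-effectiveness acceptability curves
#'
#' At each willingness-to-pay value, each strategy's probability of being
#' cost-effective is the fraction of PSA iterations in which its net
#' monetary benefit is the strict maximum (ties, measure-zero under
#' continuous draws, go to the earliest strategy in the specification's
#' fixed order).
#'
#' @param psa A `tki_psa`.
#' @param wtp_grid Numeric vector of thresholds (US$/QALY).
#' @return A `tki_ceac` data frame: `wtp`, `strategy`, `probability`.
#' @export
ceac <- function(psa, wtp_grid) {
  if (length(wtp_grid) == 0) stop("empty WTP grid")
  S <- length(psa$strategies)
  rows <- lapply(wtp_grid, function(w) {
    nmb <- w * psa$qalys - psa$cost
    win <- max.col(nmb, ties.method = "first")
    data.frame(wtp = w, strategy = psa$strategies,
               probability = tabulate(win, nbins = S) / psa$n)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("tki_ceac", "data.frame")
  out
}

#' Pairwise probability of cost-effectiveness
#'
#' Fraction of PSA iterations in which the comparator's incremental
#' (cost, effect) point lies on the cost-effective side of the
#' willingness-to-pay line: `delta_cost - wtp * delta_qalys < 0`.
#'
#' @param psa A `tki_psa`.
#' @param reference,comparator Strategy names.
#' @param wtp Willingness-to-pay (US$/QALY).
#' @return A fraction in \[0, 1\].
#' @export
pairwise_acceptability <- function(psa, reference, comparator, wtp) {
  d <- psa_deltas(psa, reference, comparator)
  mean(d$dc - wtp * d$de < 0)
}

psa_deltas <- function(psa, reference, comparator) {
  if (!all(c(reference, comparator) %in% psa$strategies))
    stop("unknown strategy")
  data.frame(de = psa$qalys[, comparator] - psa$qalys[, reference],
             dc = psa$cost[, comparator] - psa$cost[, reference])
}

#' 95\% confidence ellipse on the cost-effectiveness plane
#'
#' Sample mean and covariance of the per-iteration incremental
#' (effect, cost) pairs; the boundary is the ellipse of Mahalanobis radius
#' squared equal to the chi-square(2 df) quantile (5.9915 at 95\%).
#'
#' @param psa A `tki_psa` with at least 3 iterations.
#' @param reference,comparator Strategy names.
#' @param level Coverage level (default 0.95).
#' @return A `tki_ellipse`: list with `center` (dE, dC), `cov`, `radius2`,
#'   `axes` (half-axis lengths), `angle` (radians, orientation of the major
#'   axis), and `degenerate` flag for singular covariance.
#' @export
confidence_ellipse <- function(psa, reference, comparator, level = 0.95) {
  if (psa$n < 3) stop("need at least 3 iterations")
  d <- psa_deltas(psa, reference, comparator)
  m <- c(dE = mean(d$de), dC = mean(d$dc))
  V <- cov(cbind(d$de, d$dc))
  r2 <- qchisq(level, df = 2)
  eig <- eigen(V, symmetric = TRUE)
  degenerate <- any(eig$values <= .Machine$double.eps * max(1, eig$values[1]))
  axes <- sqrt(pmax(eig$values, 0) * r2)
  angle <- atan2(eig$vectors[2, 1], eig$vectors[1, 1])
  structure(list(center = m, cov = V, radius2 = r2, axes = axes,
                 angle = angle, level = level, degenerate = degenerate),
            class = "tki_ellipse")
}

#' Points on a confidence ellipse boundary
#'
#' @param ellipse A `tki_ellipse`.
#' @param n_points Number of boundary points.
#' @return Data frame `de`, `dc` tracing the boundary.
#' @export
ellipse_points <- function(ellipse, n_points = 181) {
  th <- seq(0, 2 * pi, length.out = n_points)
  u <- rbind(ellipse$axes[1] * cos(th), ellipse$axes[2] * sin(th))
  R <- matrix(c(cos(ellipse$angle), sin(ellipse$angle),
                -sin(ellipse$angle), cos(ellipse$angle)), 2, 2)
  xy <- t(R %*% u)
  data.frame(de = xy[, 1] + ellipse$center[1],
             dc = xy[, 2] + ellipse$center[2])
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
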