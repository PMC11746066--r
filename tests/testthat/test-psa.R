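test_that("beta fits recover mean and variance by method of moments", {
  # symmetric range built from sd = 0.1 treated as a 95% interval
  f <- fit_beta(0.5, 0.5 - 0.1 * 1.959964, 0.5 + 0.1 * 1.959964)
  expect_equal(f$shape1, 12, tolerance = 1e-9)
  expect_equal(f$shape2, 12, tolerance = 1e-9)
  expect_false(f$fallback)
  # the printed-precision version of the same range
  f2 <- fit_beta(0.5, 0.30401, 0.69599)
  expect_equal(f2$shape1, 12, tolerance = 1e-3)
  expect_equal(f2$shape1, f2$shape2)  # symmetry

  # analytic mean/sd match the inputs when no clamping occurs
  cases <- list(c(0.67, 0.60, 0.81), c(0.22, 0.07, 0.34),
                c(0.429, 0.354, 0.504), c(0.85, 0.723, 0.978))
  for (cs in cases) {
    f <- fit_beta(cs[1], cs[2], cs[3])
    expect_false(f$fallback)
    m <- f$shape1 / (f$shape1 + f$shape2)
    v <- f$shape1 * f$shape2 /
      ((f$shape1 + f$shape2)^2 * (f$shape1 + f$shape2 + 1))
    expect_equal(m, cs[1], tolerance = 1e-9)
    expect_equal(sqrt(v), (cs[3] - cs[2]) / (2 * 1.959964), tolerance = 1e-9)
  }
  expect_error(fit_beta(1.0, 0, 1), "mean in")
  expect_error(fit_beta(0.5, 0.6, 0.4), "low < high")
})

test_that("infeasible beta variance triggers the flagged minimal-information fallback", {
  # SCT receipt: base 0.038 with printed range (0, 1)
  f <- fit_beta(0.038, 0, 1)
  expect_true(f$fallback)
  expect_equal(min(f$shape1, f$shape2), 0.5, tolerance = 1e-12)
  expect_equal(f$shape1 / (f$shape1 + f$shape2), 0.038, tolerance = 1e-12)
})

test_that("gamma fits recover mean and sd exactly", {
  f <- fit_gamma(100, 100 - 50 * 1.959964, 100 + 50 * 1.959964)
  expect_equal(f$shape, 4, tolerance = 1e-9)
  expect_equal(f$scale, 25, tolerance = 1e-9)
  expect_equal(f$shape * f$scale, 100, tolerance = 1e-12)

  # first-line imatinib drug cost from its published bounds
  f <- fit_gamma(4634.40, 2317.20, 6951.60)
  expect_equal(f$shape * f$scale, 4634.40, tolerance = 1e-9)
  expect_equal(f$shape, 15.36584, tolerance = 1e-4)
  expect_equal(f$sd, 4634.40 / (2 * 1.959964), tolerance = 1e-9)
  expect_error(fit_gamma(-5, 1, 2), "mean > 0")
})

test_that("fit_ranges covers every sampled parameter with the right family", {
  fits <- fit_ranges(basecase)
  expect_false("econ.discount_rate" %in% names(fits))  # DSA-only
  expect_equal(length(fits),
               sum(basecase$ranges$family != "fixed"))
  fam <- vapply(fits, `[[`, character(1), "family")
  expect_equal(unname(fam["drugs.imatinib.ccyr"]), "beta")
  expect_equal(unname(fam["costs.monitoring"]), "gamma")
  # uniform interpretation by convention flag
  s <- basecase
  s$conventions$range_interpretation <- "minmax_uniform"
  expect_equal(fit_ranges(s)[["costs.monitoring"]]$family, "uniform")
})

test_that("PSA is deterministic under seed and independent of RNG state", {
  p1 <- run_psa(basecase, n = 40, seed = 11)
  set.seed(999)  # perturb global RNG state
  p2 <- run_psa(basecase, n = 40, seed = 11)
  expect_identical(p1$cost, p2$cost)
  expect_identical(p1$qalys, p2$qalys)
  expect_identical(p1$draws, p2$draws)
  p3 <- run_psa(basecase, n = 40, seed = 12)
  expect_false(identical(p1$cost, p3$cost))
  # all drawn probabilities in [0,1], all costs >= 0
  beta_ids <- basecase$ranges$id[basecase$ranges$family == "beta"]
  for (id in intersect(beta_ids, names(p1$draws)))
    expect_true(all(p1$draws[[id]] >= 0 & p1$draws[[id]] <= 1))
  expect_true(all(p1$cost >= 0))
})

test_that("degenerate ranges collapse the PSA onto the base case", {
  s <- basecase
  base_vals <- vapply(s$ranges$id, function(id) spec_get(s, id), numeric(1))
  s$ranges$low <- base_vals
  s$ranges$high <- base_vals
  p <- run_psa(s, n = 5, seed = 1)
  det <- run_model(s)$summary
  for (st in det$strategy) {
    expect_equal(unname(p$cost[, st]),
                 rep(det$total_cost[det$strategy == st], 5))
    expect_equal(unname(p$qalys[, st]),
                 rep(det$total_qalys[det$strategy == st], 5))
  }
})

test_that("CEAC probabilities sum to one and concentrate correctly at WTP 0", {
  p <- run_psa(basecase, n = 60, seed = 3)
  grid <- c(0, 500, 18760, 60000)
  cc <- ceac(p, grid)
  sums <- tapply(cc$probability, cc$wtp, sum)
  expect_equal(as.numeric(sums), rep(1, length(grid)))
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))
  # at WTP 0 the winner of each iteration is its cheapest strategy
  at0 <- cc[cc$wtp == 0, ]
  cheapest <- apply(p$cost, 1, which.min)
  expect_equal(at0$probability,
               unname(tabulate(cheapest, 3) / p$n))
  expect_error(ceac(p, numeric(0)), "empty")
})

test_that("a strategy dominating every draw has CEAC identically one", {
  n <- 50
  cost <- cbind(a = runif(n, 100, 200), b = runif(n, 300, 400))
  q <- cbind(a = runif(n, 2, 3), b = runif(n, 1, 1.5))
  p <- fake_psa(cost, q)
  cc <- ceac(p, c(0, 1000, 50000))
  expect_true(all(cc$probability[cc$strategy == "a"] == 1))
  expect_true(all(cc$probability[cc$strategy == "b"] == 0))
})

test_that("pairwise acceptability counts points below the WTP line", {
  cost <- cbind(ref = rep(100, 4), cmp = c(90, 150, 150, 120))
  q <- cbind(ref = rep(1, 4), cmp = c(1.2, 1.1, 0.9, 1.0))
  p <- fake_psa(cost, q)
  # dC - w*dE < 0: draws 1 (dC<0, dE>0) always; draw 2 iff 50 < w*0.1
  expect_equal(pairwise_acceptability(p, "ref", "cmp", 0), 0.25)
  expect_equal(pairwise_acceptability(p, "ref", "cmp", 1000), 0.5)
  # all cost-saving & more effective -> 1
  p2 <- fake_psa(cbind(ref = rep(100, 3), cmp = rep(50, 3)),
                 cbind(ref = rep(1, 3), cmp = rep(2, 3)))
  expect_equal(pairwise_acceptability(p2, "ref", "cmp", 500), 1)
  expect_error(pairwise_acceptability(p, "ref", "nope", 0), "unknown")
})

test_that("confidence ellipse matches the chi-square geometry of a normal cloud", {
  set.seed(42)
  n <- 4000
  de <- rnorm(n, 1, 0.5)
  dc <- rnorm(n, 5000, 800)
  p <- fake_psa(cbind(ref = rep(0, n), cmp = dc),
                cbind(ref = rep(0, n), cmp = de))
  el <- confidence_ellipse(p, "ref", "cmp")
  expect_false(el$degenerate)
  expect_equal(unname(el$center), c(1, 5000), tolerance = 0.05)
  expect_equal(el$radius2, qchisq(0.95, 2))
  # coverage: ~95% of points inside the Mahalanobis boundary
  X <- sweep(cbind(de, dc), 2, el$center)
  d2 <- rowSums((X %*% solve(el$cov)) * X)
  expect_equal(mean(d2 <= el$radius2), 0.95, tolerance = 0.02)

  # isotropic cloud: axis ratio near 1
  p_iso <- fake_psa(cbind(ref = rep(0, n), cmp = rnorm(n)),
                    cbind(ref = rep(0, n), cmp = rnorm(n)))
  el_iso <- confidence_ellipse(p_iso, "ref", "cmp")
  expect_equal(max(el_iso$axes) / min(el_iso$axes), 1, tolerance = 0.1)

  # identical iterations: degenerate zero-area ellipse at the point
  p_same <- fake_psa(cbind(ref = rep(0, 5), cmp = rep(10, 5)),
                     cbind(ref = rep(0, 5), cmp = rep(1, 5)))
  el0 <- confidence_ellipse(p_same, "ref", "cmp")
  expect_true(el0$degenerate)
  expect_equal(unname(el0$center), c(1, 10))
  expect_equal(unname(el0$axes), c(0, 0))
  expect_error(confidence_ellipse(fake_psa(cbind(a = 1, b = 2),
                                           cbind(a = 1, b = 2)),
                                  "a", "b"), "at least 3")

  # boundary points satisfy the quadratic form
  bp <- ellipse_points(el, 37)
  Xb <- sweep(as.matrix(bp), 2, el$center)
  d2b <- rowSums((Xb %*% solve(el$cov)) * Xb)
  expect_equal(d2b, rep(el$radius2, 37), tolerance = 1e-8)
})

test_that("sample means of PSA draws match fitted distribution means within 3 SE", {
  p <- run_psa(basecase, n = 1000, seed = 5)
  fits <- fit_ranges(basecase)
  for (id in names(fits)) {
    f <- fits[[id]]
    if (f$family == "degenerate") next
    se <- f$sd / sqrt(p$n)
    expect_lt(abs(mean(p$draws[[id]]) - f$mean), 3 * se + 1e-12)
  }
})
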