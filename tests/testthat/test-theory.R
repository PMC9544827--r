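test_that("Gaussian-shift p-value CDF: boundaries, null identity, dominance", {
  expect_equal(gaussian_p_cdf(0.5, snr = 0), 0.5)
  expect_equal(gaussian_p_cdf(c(0, 1), snr = 3), c(0, 1))
  expect_equal(gaussian_p_cdf(0.005, snr = 2), 0.2823653, tolerance = 1e-6)
  u <- seq(0.01, 0.99, by = 0.01)
  expect_equal(gaussian_p_cdf(u, snr = 0), u)        # uniform null
  expect_true(all(gaussian_p_cdf(u, snr = 1.5) > u)) # strict dominance
  expect_error(gaussian_p_cdf(1.2, snr = 1), "\\[0, 1\\]")
  expect_error(gaussian_p_cdf(0.5, snr = -1), "nonnegative")
})

test_that("conditional max-p distributions are valid CDFs, continuous at c", {
  set.seed(51)
  u <- c(0, sort(runif(60)), 1)
  for (i in 1:12) {
    cc <- runif(1, 1e-4, 0.9)
    snr <- runif(1, 0, 5)
    for (vals in list(cond_cdf_mixed(u, c = cc, snr = snr),
                      cond_cdf_doublenull(u, c = cc))) {
      expect_true(all(diff(vals) >= -1e-12))
      expect_equal(vals[1], 0)
      expect_equal(vals[length(vals)], 1)
    }
    # both branches agree at the junction u = c
    Fc <- gaussian_p_cdf(cc, snr)
    D <- Fc + cc - cc * Fc
    expect_equal(cond_cdf_mixed(cc, cc, snr), cc * Fc / D)
    expect_equal(cond_cdf_doublenull(cc, cc), cc / (2 - cc))
    eps <- 1e-10
    expect_equal(cond_cdf_mixed(cc - eps, cc, snr),
                 cond_cdf_mixed(cc + eps, cc, snr), tolerance = 1e-6)
  }
  expect_error(cond_cdf_mixed(0.5, c = 0, snr = 1), "\\(0, 1\\)")
})

test_that("conditional CDFs match Monte-Carlo on retained pairs", {
  set.seed(52)
  # one-false pair, the setting of the exact error-rate counterexample
  cc <- 0.005; snr <- 2
  for (u in c(0.002, 0.05 / c(1, 3, 10))) {
    mc <- mc_cond_cdf_mixed(u, cc, snr, n = 4e5)
    theo <- cond_cdf_mixed(u, cc, snr)
    expect_lt(abs(mc$est - theo), 3 * binom_se(theo, mc$n_kept) + 1e-9)
  }
  # double-null pair: closed form u^2 / (c(2-c)) below the threshold
  cc <- 0.05
  expect_equal(cond_cdf_doublenull(0.01, cc), 1e-4 / (0.05 * 1.95))
  p1 <- runif(1e6); p2 <- runif(1e6)
  keep <- pmin(p1, p2) <= cc
  est <- mean(pmax(p1, p2)[keep] <= 0.01)
  expect_lt(abs(est - cond_cdf_doublenull(0.01, cc)),
            3 * binom_se(cond_cdf_doublenull(0.01, cc), sum(keep)))
})

test_that("equal-threshold conditional null level never exceeds the threshold", {
  # P0(c, c) <= c: the property that makes the single-threshold variants safe
  for (snr in c(0, 0.5, 1, 2, 4, 8))
    for (cc in seq(0.001, 0.999, length.out = 200))
      expect_lte(cond_cdf_mixed(cc, cc, snr), cc + 1e-12)
})

test_that("low thresholds inflate the conditional 5% level at weak signal", {
  cc <- 5e-4
  # weak signal: the conditional p-value is anticonservative at u = 0.05 ...
  expect_gt(cond_cdf_mixed(0.05, cc, snr = 0.5), 0.05)
  # ... and the distortion vanishes as the signal grows
  expect_equal(cond_cdf_mixed(0.05, cc, snr = 10), 0.05, tolerance = 1e-6)
  strong <- vapply(c(2, 4, 6, 8),
                   function(s) abs(cond_cdf_mixed(0.05, cc, s) - 0.05),
                   numeric(1))
  expect_true(all(diff(strong) <= 1e-12))
})

test_that("selection probabilities: closed forms and the 0.29 benchmark", {
  expect_equal(round(selection_prob("01", c = 0.005, snr = 2), 2), 0.29)
  cc <- 0.04
  expect_equal(selection_prob("00", cc), 2 * cc - cc^2)
  expect_equal(selection_prob("00", cc), 1 - (1 - cc)^2)
  expect_equal(selection_prob("11", cc, snr = 0), 2 * cc - cc^2)
  Fc <- gaussian_p_cdf(cc, 3)
  expect_equal(selection_prob("11", cc, snr = 3), 1 - (1 - Fc)^2)
})

test_that("selected-set size law: binomial case, mean identity, MC check", {
  # single pair type: plain binomial
  mod <- mixture_model(m1 = 10, snr = 2)
  pmf <- selection_size_pmf(mod, c = 0.005)
  psel <- selection_prob("01", 0.005, snr = 2)
  expect_equal(pmf$prob, dbinom(0:10, 10, psel))
  expect_equal(pmf$mean, expected_selection_size(mod, 0.005),
               tolerance = 1e-9)

  # near-certain selection: mass concentrates at m
  allin <- selection_size_pmf(mixture_model(m0 = 4), c = 0.999999)
  expect_gt(allin$prob[5], 1 - 1e-4)

  # mixed family against simulation
  mod3 <- mixture_model(m0 = 5, m1 = 5, m2 = 5, snr = 3)
  pmf3 <- selection_size_pmf(mod3, c = 0.01)
  expect_equal(pmf3$mean, expected_selection_size(mod3, 0.01),
               tolerance = 1e-9)
  expect_equal(sum(pmf3$prob), 1, tolerance = 1e-12)
  set.seed(53)
  cfg <- sim_config(m0 = 5, m1 = 5, m2 = 5, snr1 = 3, reps = 1, seed = 53)
  nrep <- 4e4
  sizes <- tabulate(rowSums(
    screenmin:::sim_pvalue_matrices(cfg, nrep)$pmin <= 0.01) + 1L,
    nbins = 16L)
  emp <- sizes / nrep
  for (s in 0:15) {
    tol <- 3 * binom_se(pmf3$prob[s + 1], nrep) + 1e-9
    expect_lt(abs(emp[s + 1] - pmf3$prob[s + 1]), tol)
  }

  # expected size closed forms
  expect_equal(expected_selection_size(mixture_model(m0 = 7), 0.2),
               7 * (2 * 0.2 - 0.2^2))
  expect_equal(expected_selection_size(mixture_model(m0 = 4), 0.999999), 4,
               tolerance = 1e-4)
})

test_that("familywise error bound reproduces the exact 10-pair error rate", {
  mod <- mixture_model(m1 = 10, snr = 2)
  fw <- fwer_bound(mod, c = 0.005, alpha = 0.05)
  expect_equal(fw, 0.05452084, tolerance = 1e-6)
  expect_gt(fw, 0.05)   # the default threshold is anticonservative here
  # overwhelming signal: the false component is always tiny, the selected
  # max-p is the uniform null one, and the error rate settles at the
  # Bonferroni-type limit 1 - (1 - alpha/m)^m <= alpha
  lim <- fwer_bound(mixture_model(m1 = 10, snr = 20), 1e-6, 0.05)
  expect_lte(lim, 0.05)
  expect_equal(lim, 1 - (1 - 0.005)^10, tolerance = 0.05)
})

test_that("conditional power: reductions, boundaries, Monte-Carlo", {
  # uniform reduction: F = identity
  cc <- 0.001; alpha <- 0.05
  for (s in c(2, 10)) {
    expect_equal(conditional_power(s, cc, alpha, snr = 0),
                 2 * cc * (alpha / s) - cc^2)
  }
  expect_equal(conditional_power(0, cc, alpha, snr = 3), 0)
  # branch switch at cs = alpha
  expect_equal(conditional_power(60, cc, alpha, snr = 3),
               gaussian_p_cdf(alpha / 60, 3)^2)

  set.seed(54)
  s <- 10; snr <- 3
  n <- 1e6
  pa <- pnorm(-(rnorm(n) + snr)); pb <- pnorm(-(rnorm(n) + snr))
  est <- mean(pmax(pa, pb) <= alpha / s & pmin(pa, pb) <= cc)
  theo <- conditional_power(s, cc, alpha, snr)
  expect_lt(abs(est - theo), 3 * binom_se(theo, n))
})

test_that("unconditional power: single pair, focal accounting, c -> 1 limit", {
  mod1 <- mixture_model(m2 = 1, snr = 2)
  expect_equal(power_exact(mod1, c = 0.01, alpha = 0.05),
               conditional_power(1, 0.01, 0.05, 2))

  # the two focal-pair accountings agree for a large family
  big <- mixture_model(m0 = 140, m1 = 50, m2 = 10, snr = 2)
  con <- power_exact(big, c = 0.002, alpha = 0.05, focal = "conditioned")
  dec <- power_exact(big, c = 0.002, alpha = 0.05, focal = "decomposed")
  expect_equal(con, dec, tolerance = 0.05)

  # selection certain: power collapses to the max-p Bonferroni term
  mod <- mixture_model(m0 = 95, m2 = 5, snr = 3)
  expect_equal(power_exact(mod, c = 0.999999, alpha = 0.05),
               gaussian_p_cdf(0.05 / 100, 3)^2, tolerance = 1e-4)

  expect_error(power_exact(mixture_model(m1 = 3, snr = 1), 0.01, 0.05),
               "\\(1,1\\)")
})

test_that("mean-size error approximation tracks the exact expectation", {
  mod <- mixture_model(m1 = 10, snr = 2)
  exact <- fwer_bound(mod, c = 0.005, alpha = 0.05)
  approx <- approx_fwer(mod, c = 0.005, alpha = 0.05)
  expect_equal(approx, exact, tolerance = 0.1)   # close ...
  expect_false(isTRUE(all.equal(approx, exact, tolerance = 1e-6))) # not equal

  # strong signal at the default threshold: every pair is selected and the
  # approximation settles at the Bonferroni-type limit, just under alpha
  strong <- mixture_model(m1 = 200, snr = 8)
  expect_equal(approx_fwer(strong, c = 0.05 / 200, alpha = 0.05),
               1 - (1 - 0.05 / 200)^200, tolerance = 1e-3)

  # power analogue evaluated at the mean size
  mod2 <- mixture_model(m0 = 70, m1 = 25, m2 = 5, snr = 2)
  Ehat <- expected_selection_size(mod2, 0.002)
  expect_equal(approx_power(mod2, 0.002, 0.05),
               conditional_power(Ehat, 0.002, 0.05, 2))
})

test_that("size-threshold calibration g(c) is strictly increasing", {
  set.seed(55)
  for (i in 1:8) {
    counts <- sample(0:60, 3)
    if (sum(counts) == 0) counts[1] <- 10
    mod <- mixture_model(counts[1], counts[2], counts[3],
                         snr = runif(1, 0, 5))
    cs <- seq(1e-5, 0.999, length.out = 300)
    g <- vapply(cs, function(cc) cc * expected_selection_size(mod, cc),
                numeric(1))
    expect_true(all(diff(g) > 0))
  }
})

test_that("calibration-equation root: bisection vs dense grid, capping", {
  # all-null family: c * m(2c - c^2) = alpha, checkable against a grid scan
  mod <- mixture_model(m0 = 100)
  root <- approx_oracle_threshold(mod, alpha = 0.05)
  cs <- seq(1e-6, 0.05, length.out = 2e5)
  g <- cs * 100 * (2 * cs - cs^2)
  expect_equal(as.numeric(root), cs[which.min(abs(g - 0.05))],
               tolerance = 1e-6)
  expect_false(attr(root, "capped"))
  expect_equal(as.numeric(root) * expected_selection_size(mod, as.numeric(root)),
               0.05, tolerance = 1e-8)

  # single pair: the product never reaches alpha, root capped at alpha
  tiny <- approx_oracle_threshold(mixture_model(m1 = 1, snr = 1), 0.05)
  expect_equal(as.numeric(tiny), 0.05)
  expect_true(attr(tiny, "capped"))
})

test_that("oracle threshold solves the constrained problem", {
  # mixed family with moderate signal: the constraint binds
  mod <- mixture_model(m0 = 70, m1 = 25, m2 = 5, snr = 2)
  cstar <- oracle_threshold(mod, alpha = 0.05)
  expect_false(attr(cstar, "unconstrained_feasible"))
  expect_equal(approx_fwer(mod, as.numeric(cstar), 0.05), 0.05,
               tolerance = 1e-6)   # active constraint
  expect_true(attr(cstar, "power_maximal"))
  # any smaller threshold is infeasible
  expect_gt(approx_fwer(mod, as.numeric(cstar) * 0.9, 0.05), 0.05)

  # 10-pair one-false family: the default threshold alpha/m is infeasible
  mod2 <- mixture_model(m1 = 10, snr = 2)
  c2 <- oracle_threshold(mod2, alpha = 0.05)
  expect_gt(as.numeric(c2), 0.005)
  expect_gt(approx_fwer(mod2, 0.005, 0.05), 0.05)
  # and the two solvers agree up to the approximation gap
  r2 <- approx_oracle_threshold(mod2, 0.05)
  expect_equal(as.numeric(c2), as.numeric(r2), tolerance = 0.35)

  # no true nulls and overwhelming signal: constraint never binds
  pure <- mixture_model(m2 = 50, snr = 12)
  cp <- oracle_threshold(pure, alpha = 0.05)
  expect_true(attr(cp, "unconstrained_feasible"))
  expect_lt(as.numeric(cp), 0.001)
})
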