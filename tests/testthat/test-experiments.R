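test_that("endpoint ensembles are seeded and track the stationary law", {
  m <- preset_model("no_feedback", 6)
  e1 <- ensemble_endpoint(m, init = "fixed", n0 = 0, n_runs = 4000, seed = 5)
  e2 <- ensemble_endpoint(m, init = "fixed", n0 = 0, n_runs = 4000, seed = 5)
  expect_identical(e1$counts, e2$counts)
  expect_equal(sum(e1$counts), 4000)
  # constant f: empirical mean matches b/delta within 4 s.e.
  se <- sqrt(e1$variance / e1$n_runs)
  expect_lt(abs(e1$mean - 20), 4 * se)
  # histogram close to the recursion PMF (sampling-error scale)
  pm <- stationary_pmf(m)
  expect_lt(tv_distance(ensemble_pmf(e1), pm$p), 0.05)
})

test_that("the cross-initial-condition stationarity check flags short horizons", {
  m <- preset_model("no_feedback", 1)
  expect_warning(
    ensemble_endpoint(m, init = "fixed", n0 = 60, t_f = 0.05, n_runs = 500,
                      seed = 2, check_stationarity = TRUE),
    "stationarity")
  expect_silent(
    ensemble_endpoint(m, init = "fixed", n0 = 0, t_f = 40, n_runs = 4000,
                      seed = 2, check_stationarity = TRUE))
})

test_that("system scaling preserves the deterministic picture exactly", {
  m <- sharp_bistable_model(6)
  fp1 <- find_fixed_points(m)
  expect_identical(scale_system(m, 1)$f$K, m$f$K)  # s = 1 is the identity
  for (s in c(10, 50)) {
    ms <- scale_system(m, s)
    expect_equal(ms$volume, s * m$volume)
    fps <- find_fixed_points(ms)
    expect_equal(fps$c_star, fp1$c_star, tolerance = 1e-9)
    # production function transforms as f_s(n) = s f(n/s)
    n <- c(0, 17, 120, 3000)
    expect_equal(feedback_eval(ms$f, n), s * feedback_eval(m$f, n / s),
                 tolerance = 1e-12)
  }
})

test_that("modes converge to stable fixed points at rate (mu*+1)/(sV)", {
  tab <- thermodynamic_convergence(sharp_bistable_model(6), c(1, 10, 50))
  expect_true(all(tab$within_bound))
  expect_true(all(!tab$flagged))
  # both stable branches are matched at every size
  expect_equal(unname(table(tab$s)), rep(2L, 3), ignore_attr = TRUE)
  # the s = 50 system sits ~50x closer (upper branch, concentration scale)
  up <- tab[tab$c_star > 30, ]
  expect_lt(up$deviation[up$s == 50], up$deviation[up$s == 1] / 25)
  # larger system is relatively narrower: sd/mean of the scaled PMF shrinks
  cv <- vapply(c(1, 50), function(s) {
    ms <- stationary_moments(stationary_pmf(scale_system(
      sharp_bistable_model(6), s)))
    sqrt(ms$variance) / ms$mean
  }, numeric(1))
  expect_lt(cv[2], cv[1] / 3)
})

test_that("constant production with integer mean pins the mode within 1/(sV)", {
  m <- bursty_gene_model(feedback_constant(20), 1, 1)
  tab <- thermodynamic_convergence(m, c(1, 10))
  expect_true(all(tab$deviation <= 1 / (tab$s * 1) + 1e-12))
})

test_that("the preset catalogue certifies all four regime quadrants", {
  cert <- certify_presets()
  expect_setequal(
    unique(cert$label),
    c("monostable-unimodal", "monostable-bimodal",
      "bistable-unimodal", "bistable-bimodal"))
  # the cooperative monostable-bimodal case has both modes positive
  rl <- classify_regime(preset_model("coop_monostable_bimodal", 6))
  expect_equal(rl$label, "monostable-bimodal")
  expect_true(all(rl$modes > 0))
  # the non-cooperative bimodal case peaks at zero and at a positive value
  rl2 <- classify_regime(preset_model("noncoop", 6))
  expect_equal(rl2$label, "monostable-bimodal")
  expect_true(0 %in% rl2$modes && any(rl2$modes > 0))
  # strong bursts turn the bistable system unimodal
  rl3 <- classify_regime(preset_model("coop_bistable", 11))
  expect_equal(rl3$label, "bistable-unimodal")
})
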