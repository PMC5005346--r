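test_that("constant production gives Poisson / negative-binomial stationary laws", {
  m1 <- bursty_gene_model(feedback_constant(20), 1, 1)
  p1 <- stationary_pmf(m1, tail_tol = 1e-12)
  expect_lt(tv_distance(p1$p, dpois(0:p1$n_max, 20)), 1e-12)
  for (mu in c(6, 11)) {
    m <- bursty_gene_model(feedback_constant(20), mu, 1)
    pm <- stationary_pmf(m, tail_tol = 1e-12)
    r <- 20 / (mu - 1)
    nb <- dnbinom(0:pm$n_max, size = r, prob = 1 / mu)
    expect_lt(tv_distance(pm$p, nb), 1e-12)
  }
})

test_that("the PMF is a valid distribution with controlled tail", {
  set.seed(3)
  for (i in 1:10) {
    m <- random_model()
    pm <- stationary_pmf(m, tail_tol = 1e-10)
    expect_true(all(pm$p >= 0))
    expect_equal(sum(pm$p), 1, tolerance = 1e-12)
    expect_lt(pm$tail_mass, 1e-10)
    # recursion ratio holds at every point of the support
    n <- 0:(pm$n_max - 1)
    ratio <- (feedback_eval(m$f, n) / (m$delta * m$mu_star) +
                n * (m$mu_star - 1) / m$mu_star) / (n + 1)
    ok <- pm$p[n + 1] > 1e-280
    expect_lt(max(abs(pm$p[n + 2][ok] / pm$p[n + 1][ok] - ratio[ok])), 1e-9)
  }
})

test_that("no basal production collapses the stationary law onto extinction", {
  m <- bursty_gene_model(feedback_mm(0, 50, 10), 6, 1)
  pm <- stationary_pmf(m)
  expect_identical(pm$p, 1)
  expect_identical(pm$n_max, 0L)
})

test_that("a too-small support cap is reported, not silently truncated", {
  m <- bursty_gene_model(feedback_constant(200), 11, 1)
  expect_error(stationary_pmf(m, tail_tol = 1e-12, n_cap = 50), "n_cap")
})

test_that("recursion agrees with the generator null-space oracle", {
  set.seed(19)
  for (i in 1:8) {
    m <- random_model(max_mu = 5)
    pm <- stationary_pmf(m, tail_tol = 1e-13)
    n_cap <- min(max(pm$n_max + 10, 50), 300)
    expect_lt(tv_distance(pm$p, generator_stationary(m, n_cap)), 1e-8)
  }
})

test_that("stationary moments obey the steady-state balance identities", {
  for (m in burst_presets()) {
    pm <- stationary_pmf(m)
    ms <- stationary_moments(pm)
    # production/degradation balance E[N] = E[f(N)]/delta
    expect_lt(abs(ms$mean - ms$mean_f / m$delta), 1e-9 * ms$mean)
    # variance decomposition sigma^2 = mu* E[N] + Cov(N, f(N))/delta
    expect_lt(abs(ms$variance -
                    (m$mu_star * ms$mean + ms$cov_nf / m$delta)),
              1e-8 * ms$variance)
    expect_gte(ms$variance, 0)
    expect_equal(ms$central_moments[2], ms$variance)
  }
})

test_that("constant feedback has Fano factor mu* and zero rate covariance", {
  for (mu in c(1, 6, 11)) {
    m <- bursty_gene_model(feedback_constant(20), mu, 1)
    ms <- stationary_moments(stationary_pmf(m, tail_tol = 1e-12))
    expect_equal(ms$variance / ms$mean, mu, tolerance = 1e-8)
    expect_equal(ms$cov_nf, 0)
  }
})

test_that("relative-slope profile reproduces the PMF increments", {
  for (nm in c("noncoop", "coop_bistable")) {
    m <- preset_model(nm, 6)
    pm <- stationary_pmf(m)
    pp <- precision_profile(m, pm)
    inc <- (pm$p[-1] - pm$p[-length(pm$p)]) / pm$p[-length(pm$p)]
    ok <- pm$p[-length(pm$p)] > 1e-300
    expect_lt(max(abs(inc[ok] - pp$s[ok])), 1e-9)
    # s changes sign at each interior extremum of the PMF
    ex <- find_extrema(pm)
    interior <- rbind(ex$maxima[ex$maxima$n_lo > 0, ], ex$minima)
    for (k in seq_len(nrow(interior))) {
      i <- interior$n_lo[k]
      if (i > 0 && i < pm$n_max)
        expect_lt(pp$s[i] * pp$s[i + 1], 0)
    }
  }
})

test_that("Taylor expansion of E[f(N)] is exact for low-degree polynomials", {
  m <- bursty_gene_model(feedback_linear(5, 0.4), 4, 1)
  pm <- stationary_pmf(m)
  for (R in 1:3)
    expect_equal(taylor_mean_expansion(m, pm, R)$abs_error, 0,
                 tolerance = 1e-9)
  # concave quadratic custom f: exact once curvature is included (R >= 2)
  qf <- feedback_custom(function(n) 10 + 0.5 * n - 0.002 * n^2,
                        deriv = function(n, r)
                          switch(r, 0.5 - 0.004 * n, -0.004, 0))
  mq <- bursty_gene_model(qf, 3, 1)
  pq <- stationary_pmf(mq, n_cap = 300)
  expect_gt(taylor_mean_expansion(mq, pq, 1)$abs_error, 1e-4)
  expect_equal(taylor_mean_expansion(mq, pq, 2)$abs_error, 0,
               tolerance = 1e-9)
  # saturating feedback on a unimodal preset: the series helps
  mh <- preset_model("coop_monostable_bimodal", 1)
  ph <- stationary_pmf(mh)
  errs <- vapply(c(1, 2, 4), function(R)
    taylor_mean_expansion(mh, ph, R)$abs_error, numeric(1))
  expect_lt(errs[2], errs[1])
  expect_lt(errs[3], errs[1])
})
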