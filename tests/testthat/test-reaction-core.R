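test_that("stochastic constants follow the volume/stoichiometry conversion", {
  # first order: kappa == k for any volume
  net1 <- reaction_network("X", list(list(educts = c(X = 1), products = NULL,
                                          k = 3.7)), volume = 13)
  expect_equal(stochastic_constant(net1, 1), 3.7)
  # zero order: kappa = k * V
  net0 <- reaction_network("X", list(list(educts = NULL, products = c(X = 1),
                                          k = 2)), volume = 5)
  expect_equal(stochastic_constant(net0, 1), 10)
  # dimerization 2X: kappa = k * V * 2! / V^2 = 3 * 2 * 2 / 4
  net2 <- reaction_network("X", list(list(educts = c(X = 2), products = NULL,
                                          k = 3)), volume = 2)
  expect_equal(stochastic_constant(net2, 1), 3)
  expect_error(stochastic_constant(net2, 2), "index")
})

test_that("kappa <-> k conversion round-trips", {
  set.seed(41)
  for (i in 1:20) {
    V <- runif(1, 0.1, 50)
    b <- sample(0:3, 2, replace = TRUE)
    k <- runif(1, 0.01, 20)
    net <- reaction_network(c("A", "B"), list(
      list(educts = c(A = b[1], B = b[2])[c(A = b[1], B = b[2]) > 0],
           products = NULL, k = k)), volume = V)
    if (sum(b) == 0) net <- reaction_network("A",
      list(list(educts = NULL, products = c(A = 1), k = k)), volume = V)
    kap <- stochastic_constant(net, 1)
    beta <- net$beta[, 1]
    k_back <- kap / (V * prod(factorial(beta) / V^beta))
    expect_equal(k_back, k, tolerance = 1e-12)
    expect_gt(kap, 0)
  }
})

test_that("propensities use binomial educt counting and vanish when educts lack", {
  dimer <- reaction_network("X", list(list(educts = c(X = 2), products = NULL,
                                           k = 1)), volume = 1)
  # kappa = 2, C(5, 2) = 10
  expect_equal(propensity(dimer, c(X = 5), 1), 20)
  expect_equal(propensity(dimer, c(X = 1), 1), 0)
  death <- reaction_network("X", list(list(educts = c(X = 1), products = NULL,
                                           k = 1)))
  expect_equal(propensity(death, c(X = 0), 1), 0)
  birth <- reaction_network("X", list(list(educts = NULL,
                                           products = c(X = 1), k = 4)),
                            volume = 3)
  expect_equal(propensity(birth, c(X = 99), 1), 12)  # independent of state
})

test_that("binomial and factorial/volume propensity forms agree", {
  set.seed(7)
  for (i in 1:30) {
    V <- runif(1, 0.5, 20)
    beta <- sample(0:3, 2, replace = TRUE)
    k <- runif(1, 0.1, 5)
    educts <- c(A = beta[1], B = beta[2])
    educts <- educts[educts > 0]
    net <- if (length(educts))
      reaction_network(c("A", "B"), list(list(educts = educts,
                                              products = NULL, k = k)),
                       volume = V)
    else reaction_network(c("A", "B"),
      list(list(educts = NULL, products = c(A = 1), k = k)), volume = V)
    n <- sample(0:30, 2)
    w_binom <- propensity(net, n, 1)
    b <- net$beta[, 1]
    w_fact <- if (any(n < b)) 0 else
      k * V^(1 - sum(b)) * prod(factorial(n) / factorial(n - b))
    expect_equal(w_binom, w_fact, tolerance = 1e-12)
  }
})

test_that("mass-action RHS matches hand-built rate laws", {
  bd <- birth_death_network(b = 8, delta = 2)
  expect_equal(unname(mass_action_rhs(bd, c(X = 0))), 8)
  expect_equal(unname(mass_action_rhs(bd, c(X = 4))), 0)       # c = k/delta
  dimer <- reaction_network(c("X", "X2"), list(
    list(educts = c(X = 2), products = c(X2 = 1), k = 1)))
  expect_equal(unname(mass_action_rhs(dimer, c(X = 3, X2 = 0))), c(-18, 9))
  expect_error(mass_action_rhs(bd, c(X = -1)), "nonnegative")
})

test_that("SSA is frozen without reactions and reproducible under a seed", {
  net <- reaction_network("X", list(list(educts = c(X = 1), products = NULL,
                                         k = 1)))
  sim <- simulate_ssa(net, n0 = 0, t_end = 5, seed = 1)
  expect_true(all(sim$X == 0))
  bd <- birth_death_network()
  s1 <- simulate_ssa(bd, 0, 20, seed = 99)
  s2 <- simulate_ssa(bd, 0, 20, seed = 99)
  expect_identical(s1, s2)
  s3 <- simulate_ssa(bd, 0, 20, seed = 100)
  expect_false(isTRUE(all.equal(s1$X, s3$X)))
})

test_that("SSA reproduces the birth-death stationary law", {
  bd <- birth_death_network(b = 10, delta = 1)
  set.seed(1234)
  ends <- vapply(1:2000, function(i) {
    simulate_ssa(bd, 0, 12, t_record = 12)$X
  }, numeric(1))
  se_mean <- sqrt(10 / 2000)
  expect_lt(abs(mean(ends) - 10), 4 * se_mean)
  # Poisson: variance == mean; estimator s.e. ~ sqrt((mu4 - sigma^4)/n)
  se_var <- sqrt((10 + 3 * 100 + 10 - 100) / 2000)
  expect_lt(abs(var(ends) - 10), 4 * se_var)
})

test_that("pure-death extinction times average 1/delta", {
  m <- bursty_gene_model(feedback_constant(0), 1, delta = 1)
  res <- mfpt(m, start = 1, target = 0, method = "ssa", n_runs = 1e4,
              seed = 21)
  expect_lt(abs(res$mfpt - 1), 4 * res$se)
  expect_equal(mfpt(m, 1, 0, method = "exact", n_cap = 5)$mfpt, 1,
               tolerance = 1e-12)
})
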