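# Shared fixtures: all inputs are generated in code.

# A random burst model with bounded production (support stays modest).
random_model <- function(max_mu = 6, b_range = c(1, 20), v_range = c(0, 50)) {
  variant <- sample(c("constant", "mm", "hill"), 1)
  b <- runif(1, b_range[1], b_range[2])
  v <- runif(1, v_range[1], v_range[2])
  Kh <- runif(1, 5, 50)
  h <- sample(2:4, 1)
  f <- switch(variant,
    constant = feedback_constant(b),
    mm = feedback_mm(b, v, Kh),
    hill = feedback_hill(b, v, K_half = Kh, h = h))
  bursty_gene_model(f, sample(seq_len(max_mu), 1), delta = 1)
}

# Stationary PMF from the null space of the truncated generator: the
# independent oracle for the recursive solution.
generator_stationary <- function(model, n_cap) {
  Q <- burstmodes:::burst_generator(model, n_cap, leak = FALSE)
  A <- rbind(Q, rep(1, n_cap + 1))
  p <- qr.solve(A, c(rep(0, n_cap + 1), 1))
  p <- pmax(p, 0)
  p / sum(p)
}

# simple birth-death network fixture: 0 -> X at rate b, X -> 0 at rate delta
birth_death_network <- function(b = 10, delta = 1, volume = 1) {
  reaction_network("X", list(
    list(educts = NULL, products = c(X = 1), k = b),
    list(educts = c(X = 1), products = NULL, k = delta)
  ), volume = volume)
}
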