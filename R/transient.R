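#' Transient solution of the burst master equation
#'
#' Integrates the truncated master equation
#' \deqn{\dot p_n = \sum_{\mu=1}^{n} g_{\mu^*}(\mu)\frac{f(n-\mu)}{\mu^*}
#'   p_{n-\mu} - \frac{f(n)}{\mu^*} p_n + \delta(n+1)p_{n+1} - \delta n p_n}
#' on the lattice `0..n_cap` with [deSolve::ode()] (lsoda, stiff-capable).
#' Burst mass that would jump past `n_cap` flows into an absorbing leak bin,
#' so total probability (lattice + leak) is conserved exactly; the leaked
#' mass is tracked per output time and an error is raised if it exceeds
#' `leak_tol` at the final time.
#'
#' @param model a [bursty_gene_model].
#' @param p0 initial distribution: either a probability vector over
#'   `0..n_cap` (shorter vectors are zero-padded) or a single nonnegative
#'   integer state.
#' @param t_grid increasing output times starting at 0.
#' @param n_cap truncation cap (the lattice is `0..n_cap`).
#' @param leak_tol maximum tolerated leaked mass at the final time.
#' @param ... passed to [deSolve::ode()].
#' @return A `transient_cme`: list with `t`, `p` (matrix, one row per output
#'   time, columns `n = 0..n_cap`), `leak` (vector), `model`.
#' @export
transient_cme <- function(model, p0, t_grid, n_cap = 400, leak_tol = 1e-8,
                          ...) {
  stopifnot(inherits(model, "bursty_gene_model"), !is.unsorted(t_grid),
            n_cap >= 2)
  if (length(p0) == 1 && p0 == floor(p0) && p0 >= 0) {
    v <- numeric(n_cap + 1); v[p0 + 1] <- 1; p0 <- v
  }
  if (length(p0) > n_cap + 1) stop("p0 must be supported within 0..n_cap")
  p0 <- c(p0, numeric(n_cap + 1 - length(p0)))
  if (abs(sum(p0) - 1) > 1e-10) stop("p0 must sum to 1")
  Q <- burst_generator(model, n_cap, leak = TRUE)
  rhs <- function(t, y, parms) list(as.vector(Q %*% y))
  sol <- deSolve::ode(y = c(p0, 0), times = t_grid, func = rhs, parms = NULL,
                      rtol = 1e-10, atol = 1e-12, ...)
  if (attr(sol, "istate")[1] < 0) stop("master-equation integration failed")
  P <- unname(sol[, 2:(n_cap + 2), drop = FALSE])
  leak <- unname(sol[, n_cap + 3])
  if (leak[length(leak)] > leak_tol)
    stop(sprintf("leaked mass %.3e exceeds leak_tol = %.1e; increase n_cap (currently %d)",
                 leak[length(leak)], leak_tol, n_cap))
  structure(list(t = t_grid, p = P, leak = leak, model = model,
                 n_cap = n_cap), class = "transient_cme")
}

# Dense generator of the truncated burst master equation, acting on column
# probability vectors: dp/dt = Q p. With leak = TRUE an extra absorbing row
# collects burst mass that would jump past n_cap (columns then sum to zero,
# i.e. probability is conserved on lattice + leak).
burst_generator <- function(model, n_cap, leak = FALSE) {
  f <- model$f; mu <- model$mu_star; delta <- model$delta
  N <- n_cap + 1L
  fn <- feedback_eval(f, 0:n_cap)
  wb <- fn / mu                      # burst-event propensity per state
  # with a leak bin the matrix is square with an absorbing (zero) last column
  Q <- matrix(0, N + leak, N + leak)
  if (mu == 1) {
    g <- function(m) as.numeric(m == 1)
  } else {
    g <- function(m) (1 / mu) * (1 - 1 / mu)^(m - 1)
  }
  for (n in 0:n_cap) {
    col <- n + 1L
    # burst jumps n -> n + m
    if (n < n_cap) {
      m <- seq_len(n_cap - n)
      Q[cbind(n + m + 1L, col)] <- wb[col] * g(m)
    }
    # death n -> n - 1
    if (n > 0) Q[n, col] <- delta * n
    # overshoot mass beyond the cap
    over <- if (mu == 1) {
      if (n == n_cap) wb[col] else 0
    } else wb[col] * (1 - 1 / mu)^(n_cap - n)
    if (leak) Q[N + 1L, col] <- over
    # leak = FALSE censors overshooting bursts (they do not fire), keeping
    # the truncated chain conservative -- appropriate for stationary solves
    # where the tail mass beyond n_cap is negligible
    Q[col, col] <- -(wb[col] + delta * n) + if (leak) 0 else over
  }
  Q
}

#' Moment-equation residuals of a transient CME solution
#'
#' The burst master equation implies exact ODEs for the mean and variance:
#' \deqn{\frac{dE[N]}{dt} = E[f(N)] - \delta E[N]}
#' \deqn{\frac{d\sigma^2}{dt} = 2\,Cov(N, f(N)) - (E[f(N)] - \delta E[N])
#'   + 2\mu^* E[f(N)] - 2\delta\sigma^2.}
#' This function differentiates the empirical moment series of a
#' [transient_cme()] solution numerically (central differences on the
#' interior of `t_grid`) and compares with the right-hand sides evaluated
#' from the same PMFs, returning the residual series and their maxima.
#' Residuals at the level of the integrator tolerance confirm the
#' consistency of the transient solver with the moment dynamics.
#'
#' @param model a [bursty_gene_model].
#' @param transient a [transient_cme()] result on a reasonably fine grid.
#' @return List with data frame `series` (columns `t`, `dmean_dt`,
#'   `rhs_mean`, `resid_mean`, `dvar_dt`, `rhs_var`, `resid_var`) and
#'   scalars `max_resid_mean`, `max_resid_var` (absolute), plus
#'   `rel_resid_mean`, `rel_resid_var` (scaled by the peak RHS magnitude).
#' @export
moment_ode_residuals <- function(model, transient) {
  stopifnot(inherits(transient, "transient_cme"))
  tt <- transient$t
  P <- transient$p
  n <- 0:(ncol(P) - 1L)
  fv <- feedback_eval(model$f, n)
  rows <- nrow(P)
  mean_t <- as.vector(P %*% n)
  meanf_t <- as.vector(P %*% fv)
  m2 <- as.vector(P %*% (n^2))
  var_t <- m2 - mean_t^2
  covnf <- as.vector(P %*% (n * fv)) - mean_t * meanf_t
  mu <- model$mu_star; delta <- model$delta
  rhs_mean <- meanf_t - delta * mean_t
  rhs_var <- 2 * covnf - (meanf_t - delta * mean_t) + 2 * mu * meanf_t -
    2 * delta * var_t
  h <- diff(tt)
  uniform <- max(abs(h - h[1])) < 1e-9 * h[1]
  if (uniform && rows >= 7) {
    # fourth-order five-point stencil on the deep interior
    i <- 3:(rows - 2L)
    d4 <- function(y) (y[i - 2] - 8 * y[i - 1] + 8 * y[i + 1] - y[i + 2]) /
      (12 * h[1])
    dmean <- d4(mean_t)
    dvar <- d4(var_t)
  } else {
    i <- 2:(rows - 1L)
    dmean <- (mean_t[i + 1] - mean_t[i - 1]) / (tt[i + 1] - tt[i - 1])
    dvar <- (var_t[i + 1] - var_t[i - 1]) / (tt[i + 1] - tt[i - 1])
  }
  resid_mean <- dmean - rhs_mean[i]
  resid_var <- dvar - rhs_var[i]
  series <- data.frame(t = tt[i], dmean_dt = dmean, rhs_mean = rhs_mean[i],
                       resid_mean = resid_mean, dvar_dt = dvar,
                       rhs_var = rhs_var[i], resid_var = resid_var)
  list(series = series,
       max_resid_mean = max(abs(resid_mean)),
       max_resid_var = max(abs(resid_var)),
       rel_resid_mean = max(abs(resid_mean)) / max(abs(rhs_mean), 1e-12),
       rel_resid_var = max(abs(resid_var)) / max(abs(rhs_var), 1e-12))
}

#' Taylor approximation of the stationary mean production rate
#'
#' Approximates \eqn{E[f(N)]} by the Taylor expansion of `f` around the
#' mean: \eqn{f(E[N]) + \sum_{r=2}^{R} z_r f^{(r)}(E[N])/r!} with central
#' moments \eqn{z_r}. Exact for polynomials of degree `<= R`; for saturating
#' feedback the truncation error reflects how strongly the distribution's
#' spread interacts with the curvature of `f` (for broad or multimodal
#' distributions the series need not improve monotonically with `R`).
#'
#' @param model a [bursty_gene_model].
#' @param pmf a [stationary_pmf()] for the same model.
#' @param order truncation order `R >= 1` (`R = 1` is plain `f(E[N])`).
#' @return List with `approx`, the truncated series value; `exact`,
#'   \eqn{E[f(N)]} by direct summation; and `abs_error`.
#' @export
taylor_mean_expansion <- function(model, pmf, order = 2) {
  stopifnot(inherits(pmf, "stationary_pmf"), order >= 1)
  ms <- stationary_moments(pmf, model, order = max(order, 2))
  approx <- feedback_eval(model$f, ms$mean)
  if (order >= 2) {
    for (r in 2:order) {
      approx <- approx +
        ms$central_moments[r] * feedback_deriv(model$f, ms$mean, r) /
          factorial(r)
    }
  }
  list(approx = approx, exact = ms$mean_f,
       abs_error = abs(approx - ms$mean_f))
}
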