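#' Exact stationary distribution of the burst model
#'
#' Builds the stationary probability mass function of the protein copy
#' number from the recursive steady-state solution of the burst master
#' equation:
#' \deqn{p_1 = \frac{f(0)}{\delta\mu^*} p_0, \qquad
#'       (n+1)\,p_{n+1} = \frac{f(n)}{\delta\mu^*} p_n +
#'       \frac{\mu^*-1}{\mu^*}\, n\, p_n.}
#' The recursion is carried in log space (the unnormalized weights span
#' hundreds of orders of magnitude for large \eqn{f/\delta}), then
#' normalized.
#'
#' Truncation: the support is extended until (a) `n` exceeds every analytic
#' mode candidate (guaranteed once \eqn{n > \sup f/\delta}, where the ratio
#' \eqn{p_{n+1}/p_n} is permanently below 1) and (b) the geometric tail
#' bound \eqn{p_n r/(1-r) < } `tail_tol` with \eqn{r = p_{n+1}/p_n < 1}.
#'
#' @param model a [bursty_gene_model].
#' @param tail_tol requested bound on the truncated tail mass, in `(0, 1e-3]`.
#' @param n_cap hard cap on the support; if the tail criterion is not met
#'   before `n_cap` an error names the cap that was reached.
#' @return A `stationary_pmf`: list with `p` (probabilities for
#'   `n = 0..n_max`), `n_max`, `tail_mass` (estimated truncated mass),
#'   `model` and `fingerprint` (parameter string identifying the generator).
#' @examples
#' m <- bursty_gene_model(feedback_constant(20), 1, 1)
#' pmf <- stationary_pmf(m)
#' sum(pmf$p)  # 1
#' @export
stationary_pmf <- function(model, tail_tol = 1e-12, n_cap = 2^20) {
  stopifnot(inherits(model, "bursty_gene_model"),
            tail_tol > 0, tail_tol <= 1e-3, n_cap >= 10)
  f <- model$f; mu <- model$mu_star; delta <- model$delta
  f0 <- feedback_eval(f, 0)
  if (f0 == 0) {
    # no basal production: n = 0 is absorbing and carries all stationary mass
    return(new_stationary_pmf(1, 0, model))
  }
  fsup <- feedback_sup(f, n_hint = n_cap)
  n_floor <- if (is.finite(fsup)) ceiling(fsup / delta) else 10
  lw <- numeric(1024)  # log unnormalized weights, grown as needed
  lw[1] <- 0
  n <- 0L
  tail_est <- NA_real_
  repeat {
    ratio <- (feedback_eval(f, n) / (delta * mu) + n * (mu - 1) / mu) / (n + 1)
    if (ratio <= 0) { tail_est <- 0; break }
    if (n + 2L > length(lw)) lw <- c(lw, numeric(length(lw)))
    lw[n + 2L] <- lw[n + 1L] + log(ratio)
    n <- n + 1L
    if (n >= n_floor && ratio < 1) {
      m <- max(lw[seq_len(n + 1L)])
      tot <- sum(exp(lw[seq_len(n + 1L)] - m))
      tail <- exp(lw[n + 1L] - m) * ratio / (1 - ratio) / tot
      if (tail < tail_tol) { tail_est <- tail; break }
    }
    if (n >= n_cap)
      stop("stationary support exceeds n_cap = ", n_cap,
           " before reaching tail_tol = ", tail_tol,
           "; increase n_cap")
  }
  lw <- lw[seq_len(n + 1L)]
  p <- exp(lw - max(lw))
  new_stationary_pmf(p / sum(p), tail_est, model)
}

new_stationary_pmf <- function(p, tail_mass, model) {
  structure(list(p = p, n_max = length(p) - 1L, tail_mass = tail_mass,
                 model = model, fingerprint = model_fingerprint(model)),
            class = "stationary_pmf")
}

model_fingerprint <- function(model) {
  f <- model$f
  paste(f$variant, f$b, f$v, f$K, f$h, model$mu_star, model$delta,
        model$volume, sep = "|")
}

#' @export
print.stationary_pmf <- function(x, ...) {
  cat("<stationary_pmf> support 0..", x$n_max,
      sprintf("  tail mass < %.2e\n", x$tail_mass + 1e-300))
  ms <- stationary_moments(x)
  cat(sprintf("  mean %.4f  variance %.4f  (Fano %.4f)\n",
              ms$mean, ms$variance, ms$variance / ms$mean))
  invisible(x)
}

#' Stationary moments of a protein copy-number PMF
#'
#' Mean, variance, \eqn{Cov(N, f(N))}, \eqn{E[f(N)]} and central moments up
#' to `order`, by direct summation over the truncated support. At steady
#' state these obey \eqn{E[N] = E[f(N)]/\delta} and
#' \eqn{\sigma^2 = \mu^* E[N] + Cov(N, f(N))/\delta}.
#'
#' @param pmf a [stationary_pmf()] result (its generating model supplies `f`).
#' @param model optionally, a different [bursty_gene_model] whose feedback
#'   is used for the `f`-dependent summaries.
#' @param order highest central-moment order to report (`>= 2`).
#' @return A `moment_summary`: list with `mean`, `variance`, `cov_nf`,
#'   `mean_f` and `central_moments` (orders `1..order`; entry 2 equals the
#'   variance).
#' @export
stationary_moments <- function(pmf, model = pmf$model, order = 4) {
  stopifnot(inherits(pmf, "stationary_pmf"), order >= 2)
  n <- 0:pmf$n_max
  p <- pmf$p
  fv <- feedback_eval(model$f, n)
  m1 <- sum(n * p)
  mean_f <- sum(fv * p)
  cov_nf <- sum((n - m1) * (fv - mean_f) * p)
  z <- vapply(seq_len(order), function(r) sum((n - m1)^r * p), numeric(1))
  structure(list(mean = m1, variance = z[2], cov_nf = cov_nf,
                 mean_f = mean_f, central_moments = z),
            class = "moment_summary")
}

#' @export
print.moment_summary <- function(x, ...) {
  cat(sprintf("<moment_summary> mean %.6g  variance %.6g  E[f(N)] %.6g  Cov(N,f(N)) %.6g\n",
              x$mean, x$variance, x$mean_f, x$cov_nf))
  invisible(x)
}

#' Relative-slope (precision) profile of the stationary PMF
#'
#' The recursion implies
#' \eqn{(p_{n+1}-p_n)/p_n = s(n) = \frac{f(n)/\delta - (n+\mu^*)}
#' {\mu^*(n+1)}}: the local change of the PMF relative to its height. Large
#' \eqn{|s(n)|} (large discrepancy, small burst size) makes the distribution
#' locally sharp; `s` changes sign at each interior extremum.
#'
#' @param model a [bursty_gene_model].
#' @param pmf optional [stationary_pmf()]; determines the reported range
#'   (`n = 0 .. n_max - 1`), else supply `n`.
#' @param n integer vector of states at which to evaluate `s(n)`.
#' @return Data frame with columns `n` and `s`.
#' @export
precision_profile <- function(model, pmf = NULL, n = NULL) {
  stopifnot(inherits(model, "bursty_gene_model"))
  if (is.null(n)) {
    if (is.null(pmf)) stop("supply either `pmf` or `n`")
    n <- 0:(pmf$n_max - 1L)
  }
  d <- feedback_eval(model$f, n) / model$delta - (n + model$mu_star)
  data.frame(n = n, s = d / (model$mu_star * (n + 1)))
}
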