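#' Bursty autoregulated gene-expression model
#'
#' The reduced protein-only description of autoregulated gene expression:
#' protein is produced in bursts of geometrically distributed size with mean
#' `mu_star`, fired with propensity \eqn{f(n)/\mu^*}, and degraded in single
#' steps with propensity \eqn{\delta n}. The \eqn{1/\mu^*} scaling of the
#' burst frequency keeps the mean production flux \eqn{f(n)} fixed when the
#' burst size is varied, so models with different `mu_star` are directly
#' comparable.
#'
#' @param f a [feedback] object: the production rate \eqn{f(n)}.
#' @param mu_star mean burst size (molecules/burst), real `>= 1`.
#' @param delta first-order degradation rate (1/time), positive.
#' @param volume system volume (volume units), positive; concentrations are
#'   always derived as `n / volume`, never stored.
#' @return An object of class `bursty_gene_model`.
#' @examples
#' m <- bursty_gene_model(feedback_constant(20), mu_star = 6, delta = 1)
#' burst_event_propensity(m, 0:3)
#' @export
bursty_gene_model <- function(f, mu_star, delta, volume = 1) {
  stopifnot(inherits(f, "feedback_fn"), mu_star >= 1, delta > 0, volume > 0)
  structure(list(f = f, mu_star = mu_star, delta = delta, volume = volume),
            class = "bursty_gene_model")
}

#' @export
print.bursty_gene_model <- function(x, ...) {
  cat("<bursty_gene_model> mu* =", x$mu_star, " delta =", x$delta,
      " V =", x$volume, "\n  ")
  print(x$f)
  invisible(x)
}

#' Geometric burst-size distribution
#'
#' Probability mass function of the burst size \eqn{\mu \ge 1}:
#' \eqn{g_{\mu^*}(\mu) = (1/\mu^*)(1 - 1/\mu^*)^{\mu-1}}, with mean
#' \eqn{\mu^*}. For `mu_star = 1` the distribution degenerates to a point
#' mass at 1.
#'
#' @param mu_star mean burst size, real `>= 1`.
#' @param mu integer burst sizes (`>= 1`), vectorized.
#' @return Probabilities `g(mu)`.
#' @export
geometric_pmf <- function(mu_star, mu) {
  stopifnot(mu_star >= 1)
  if (any(mu < 1) || any(mu != floor(mu)))
    stop("burst sizes must be integers >= 1")
  if (mu_star == 1) return(as.numeric(mu == 1))
  p <- 1 / mu_star
  p * (1 - p)^(mu - 1)
}

#' Sample geometric burst sizes
#'
#' Inverse-CDF sampler: \eqn{\mu = 1 + \lfloor \ln u / \ln(1 - 1/\mu^*)
#' \rfloor} with \eqn{u \sim U(0,1)}; the degenerate `mu_star = 1` branch
#' returns 1 directly. Uses R's RNG stream; set `seed` (or call
#' [set.seed()]) for reproducibility.
#'
#' @param mu_star mean burst size, real `>= 1`.
#' @param n number of draws.
#' @param seed optional integer seed applied locally (the global RNG state is
#'   restored on exit).
#' @return Integer vector of burst sizes (`>= 1`).
#' @export
sample_burst <- function(mu_star, n = 1, seed = NULL) {
  if (mu_star < 1) stop("mu_star must be >= 1")
  with_seed(seed, {
    if (mu_star == 1) rep_len(1L, n)
    else {
      u <- stats::runif(n)
      as.integer(1 + floor(log(u) / log(1 - 1 / mu_star)))
    }
  })
}

#' Burst-event propensity
#'
#' The rate at which burst events fire in state `n`: \eqn{f(n)/\mu^*}. The
#' mean production flux, propensity times mean burst size, equals \eqn{f(n)}
#' independent of `mu_star`.
#'
#' @param model a [bursty_gene_model].
#' @param n copy numbers (nonnegative), vectorized.
#' @return Burst propensities (1/time).
#' @export
burst_event_propensity <- function(model, n) {
  stopifnot(inherits(model, "bursty_gene_model"))
  feedback_eval(model$f, n) / model$mu_star
}

#' Simulate a sample path of the burst model
#'
#' Exact direct-method Gillespie simulation of the two-channel burst model
#' (burst events with geometric sizes, single-molecule degradation). The
#' trajectory is piecewise constant; identical seeds give identical paths.
#'
#' @param model a [bursty_gene_model].
#' @param n0 initial copy number (nonnegative integer).
#' @param t_end simulation horizon (> 0).
#' @param seed optional integer seed (applied locally).
#' @param max_events safety cap on the number of events.
#' @return A `burst_trajectory`: data frame columns `t`, `n` plus attributes.
#' @export
simulate_burst_ssa <- function(model, n0, t_end, seed = NULL,
                               max_events = 1e7) {
  stopifnot(inherits(model, "bursty_gene_model"), n0 >= 0, t_end > 0)
  code <- feedback_code(model$f)
  res <- with_seed(seed, {
    if (is.na(code)) {
      r_burst_path(model, n0, t_end, max_events)
    } else {
      ssa_burst_path_cpp(code, feedback_par(model$f), model$mu_star,
                         model$delta, as.integer(n0), t_end,
                         as.integer(max_events))
    }
  })
  out <- data.frame(t = res$t, n = res$n)
  structure(out, class = c("burst_trajectory", "data.frame"),
            t_end = t_end, seed = seed, frozen = isTRUE(res$frozen == 1))
}

# Pure-R fallback path simulator for custom feedback functions.
r_burst_path <- function(model, n0, t_end, max_events) {
  f <- model$f; mu <- model$mu_star; delta <- model$delta
  n <- as.integer(n0); t <- 0
  tv <- numeric(0); nv <- integer(0)
  tv[1] <- 0; nv[1] <- n
  frozen <- 0L
  for (ev in seq_len(max_events)) {
    wb <- feedback_eval(f, n) / mu
    wd <- delta * n
    wt <- wb + wd
    if (wt <= 0) { frozen <- 1L; break }
    tau <- stats::rexp(1, wt)
    if (t + tau > t_end) break
    t <- t + tau
    if (stats::runif(1) * wt < wb) n <- n + sample_burst(mu) else n <- n - 1L
    tv <- c(tv, t); nv <- c(nv, n)
  }
  list(t = tv, n = nv, frozen = frozen)
}
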