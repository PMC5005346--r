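#' Endpoint ensembles of burst-model simulations
#'
#' Runs `n_runs` independent exact simulations of the burst model and records
#' the copy number at the final time `t_f`, emulating the protocol behind
#' histogram comparisons of stochastic and analytic results: many
#' trajectories, one endpoint each. Approximate stationarity is checked, as
#' in that protocol, by repeating the ensemble from a second, different
#' initial condition and comparing the two histograms; a total-variation
#' distance above `stat_tol` triggers a warning carrying both histograms.
#'
#' @param model a [bursty_gene_model].
#' @param init initial-condition rule: `"random"` (uniform on
#'   `0..ceiling(2 sup f/delta)`), `"fixed"` (all runs start at `n0`), or
#'   `"stationary"` (sampled from the exact stationary PMF).
#' @param t_f final time; defaults to `40 / delta`.
#' @param n_runs number of independent trajectories.
#' @param seed integer seed (applied locally; same seed, same histogram).
#' @param n0 starting state for `init = "fixed"`.
#' @param check_stationarity run the cross-initial-condition check.
#' @param stat_tol TV threshold for the stationarity warning.
#' @return An `ensemble_summary`: list with `counts` (named by `n`,
#'   summing to `n_runs`), `mean`, `variance`, `n_runs`, `t_f`, `seed`.
#' @export
ensemble_endpoint <- function(model, init = c("random", "fixed", "stationary"),
                              t_f = NULL, n_runs = 5e4, seed = NULL, n0 = 0,
                              check_stationarity = FALSE, stat_tol = 0.05) {
  stopifnot(inherits(model, "bursty_gene_model"))
  init <- match.arg(init)
  if (is.null(t_f)) t_f <- 40 / model$delta
  code <- feedback_code(model$f)
  if (is.na(code)) stop("ensemble simulation requires an analytic feedback variant")
  run_once <- function(rule, fixed_n0) {
    starts <- switch(rule,
      fixed = rep.int(as.integer(fixed_n0), n_runs),
      random = {
        hi <- ceiling(2 * feedback_sup(model$f) / model$delta)
        sample.int(hi + 1L, n_runs, replace = TRUE) - 1L
      },
      stationary = {
        pmf <- stationary_pmf(model, tail_tol = 1e-10)
        sample.int(length(pmf$p), n_runs, replace = TRUE, prob = pmf$p) - 1L
      })
    ssa_burst_ends_cpp(code, feedback_par(model$f), model$mu_star,
                       model$delta, starts, t_f)
  }
  ends <- with_seed(seed, {
    main <- run_once(init, n0)
    alt <- if (check_stationarity)
      run_once(if (init == "fixed") "random" else "fixed", n0) else NULL
    list(main = main, alt = alt)
  })
  counts <- tabulate(ends$main + 1L)
  names(counts) <- 0:(length(counts) - 1L)
  if (check_stationarity) {
    alt_counts <- tabulate(ends$alt + 1L)
    tv <- tv_distance(counts / n_runs, alt_counts / n_runs)
    if (tv > stat_tol)
      warning(sprintf(paste0(
        "endpoint histograms from two initial conditions differ by TV = %.3f",
        " (> %.3f): t_f = %g may be too short for stationarity"),
        tv, stat_tol, t_f))
  }
  structure(list(counts = counts, n_runs = n_runs,
                 mean = mean(ends$main), variance = stats::var(ends$main),
                 t_f = t_f, seed = seed, init = init),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("<ensemble_summary> %d runs to t_f = %g  mean %.3f  var %.3f\n",
              x$n_runs, x$t_f, x$mean, x$variance))
  invisible(x)
}

#' Empirical PMF of an endpoint ensemble
#'
#' @param ens an [ensemble_endpoint()] result.
#' @return Probability vector over `n = 0, 1, ...`.
#' @export
ensemble_pmf <- function(ens) {
  stopifnot(inherits(ens, "ensemble_summary"))
  unname(ens$counts) / ens$n_runs
}

#' Scale a burst model toward the thermodynamic limit
#'
#' Returns the `s`-fold larger system: volume `s V` and production function
#' \eqn{f_s(n) = s f(n/s)}, so that the deterministic concentration-scale
#' ODE -- and with it every fixed-point concentration -- is unchanged, while
#' copy numbers grow in proportion to `s`. For the analytic feedback
#' variants the transformation stays within the family
#' (e.g. Hill: \eqn{b \to sb}, \eqn{v \to sv}, \eqn{K \to s^h K}).
#'
#' @param model a [bursty_gene_model].
#' @param s positive scale factor (`s = 1` is the identity).
#' @return The scaled [bursty_gene_model].
#' @export
scale_system <- function(model, s) {
  stopifnot(inherits(model, "bursty_gene_model"), s > 0)
  f <- model$f
  fs <- switch(f$variant,
    constant = feedback_constant(s * f$b),
    linear = feedback_linear(s * f$b, f$v),
    michaelis_menten = feedback_mm(s * f$b, s * f$v, s * f$K),
    hill = feedback_hill(s * f$b, s * f$v, K = s^f$h * f$K, h = f$h),
    custom = feedback_custom(function(n) s * f$fun(n / s))
  )
  bursty_gene_model(fs, model$mu_star, model$delta, volume = s * model$volume)
}

#' Mode convergence toward deterministic fixed points under system scaling
#'
#' For each scale factor `s`, computes the modes of the scaled system's
#' stationary PMF, pairs each mode with the nearest stable deterministic
#' fixed-point concentration (nearest-neighbour on the concentration axis),
#' and reports the deviation `|mode/(sV) - c*|` against the ceiling-condition
#' bound \eqn{(\mu^*+1)/(sV)}. The deviation shrinks as `1/s`: in the
#' thermodynamic limit modes and stable fixed points coincide.
#'
#' @param model a [bursty_gene_model] (the `s = 1` reference).
#' @param s_list increasing positive scale factors.
#' @param tail_tol passed to [stationary_pmf()].
#' @param peak_frac modes whose peak probability falls below this fraction
#'   of the global maximum are dropped as numerically insignificant; set to
#'   0 to keep all.
#' @return Data frame with columns `s`, `mode_n` (plateau left edge),
#'   `mode_conc`, `c_star`, `deviation`, `bound`, `within_bound`, `flagged`
#'   (`TRUE` when mode and stable-fixed-point counts differ at that `s`).
#' @export
thermodynamic_convergence <- function(model, s_list = c(1, 10, 50),
                                      tail_tol = 1e-12, peak_frac = 0) {
  stopifnot(inherits(model, "bursty_gene_model"), all(s_list > 0),
            !is.unsorted(s_list))
  fps <- find_fixed_points(model)
  c_stable <- fps$c_star[fps$stability == "stable"]
  if (!length(c_stable)) stop("model has no stable fixed point")
  rows <- list()
  for (s in s_list) {
    ms <- scale_system(model, s)
    pmf <- stationary_pmf(ms, tail_tol = tail_tol)
    ex <- find_extrema(pmf)
    modes <- ex$maxima$n_lo
    if (peak_frac > 0 && length(modes)) {
      pk <- pmf$p[modes + 1]
      modes <- modes[pk >= peak_frac * max(pk)]
    }
    flag <- length(modes) != length(c_stable)
    for (m in modes) {
      conc <- m / (s * model$volume)
      cs <- c_stable[which.min(abs(c_stable - conc))]
      dev <- abs(conc - cs)
      bound <- (model$mu_star + 1) / (s * model$volume)
      rows[[length(rows) + 1L]] <-
        data.frame(s = s, mode_n = m, mode_conc = conc, c_star = cs,
                   deviation = dev, bound = bound,
                   within_bound = dev <= bound, flagged = flag)
    }
  }
  do.call(rbind, rows)
}

#' Classify the stability/modality regime of a model
#'
#' Combines the count of stable deterministic fixed points
#' ([find_fixed_points()]) with the count of stationary modes
#' ([find_extrema()] on the exact PMF) into one of the four regime labels.
#' Maxima whose peak probability is below `peak_frac` of the global maximum
#' are ignored, suppressing floating-point phantom modes in flat tails.
#'
#' @param model a [bursty_gene_model] with nonzero basal production.
#' @param tail_tol passed to [stationary_pmf()].
#' @param peak_frac significance threshold for counting a mode.
#' @return A `regime_label`: list with `n_stable_fixed_points`, `n_modes`,
#'   `label` in `{"monostable-unimodal", "monostable-bimodal",
#'   "bistable-unimodal", "bistable-bimodal", "other"}`, plus `modes`
#'   (plateau left edges) and `fixed_points`.
#' @export
classify_regime <- function(model, tail_tol = 1e-12, peak_frac = 1e-6) {
  stopifnot(inherits(model, "bursty_gene_model"))
  if (feedback_eval(model$f, 0) <= 0)
    stop("regime classification requires nonzero basal production")
  fps <- find_fixed_points(model)
  n_stable <- sum(fps$stability == "stable")
  pmf <- stationary_pmf(model, tail_tol = tail_tol)
  ex <- find_extrema(pmf)
  modes <- ex$maxima$n_lo
  pk <- pmf$p[modes + 1]
  modes <- modes[pk >= peak_frac * max(pk)]
  n_modes <- length(modes)
  label <- if (n_stable == 1 && n_modes == 1) "monostable-unimodal"
    else if (n_stable == 1 && n_modes == 2) "monostable-bimodal"
    else if (n_stable == 2 && n_modes == 1) "bistable-unimodal"
    else if (n_stable == 2 && n_modes == 2) "bistable-bimodal"
    else "other"
  structure(list(n_stable_fixed_points = n_stable, n_modes = n_modes,
                 label = label, modes = modes,
                 fixed_points = fps), class = "regime_label")
}

#' @export
print.regime_label <- function(x, ...) {
  cat(sprintf("<regime_label> %s (%d stable fixed point(s), %d mode(s) at %s)\n",
              x$label, x$n_stable_fixed_points, x$n_modes,
              paste(x$modes, collapse = ", ")))
  invisible(x)
}
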