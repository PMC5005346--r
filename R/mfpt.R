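#' Mean first-passage time of the burst model
#'
#' Expected time for a trajectory started at `start` to first reach the
#' target set. Two methods:
#'
#' * `"exact"`: solves the linear hitting-time system
#'   \eqn{Q_T \tau = -1} on the transient states of the truncated
#'   burst-death chain (`0..n_cap` minus the target), where rows carry the
#'   geometric burst jumps and single-molecule death steps. Bursts that
#'   would overshoot `n_cap` into a non-target state are lumped at `n_cap`;
#'   the truncation is validated by requiring the stationary mass beyond
#'   `n_cap` to be below `trunc_tol`.
#' * `"ssa"`: averages first-hitting times over `n_runs` exact simulations
#'   and reports a standard error. Requires the target to be one-sided or
#'   two-sided contiguous (`{n <= lo}` and/or `{n >= hi}`), which covers
#'   inter-mode transitions.
#'
#' @param model a [bursty_gene_model].
#' @param start starting copy number.
#' @param target integer vector of target states (nonempty).
#' @param method `"exact"` or `"ssa"`.
#' @param n_cap truncation cap for the exact method (default: past the
#'   stationary support).
#' @param n_runs number of SSA replicates.
#' @param t_max horizon per SSA replicate; replicates that do not hit in
#'   time raise an error (the estimate would be biased).
#' @param seed integer seed for the SSA method.
#' @param trunc_tol maximum tolerated stationary mass beyond `n_cap`.
#' @return An `mfpt_result`: list with `mfpt`, `se` (`NA` for exact),
#'   `method`, `n` (cap or replicate count).
#' @examples
#' m <- bursty_gene_model(feedback_constant(0.0), 1, 1)  # pure death
#' # f == 0 admits no bursts; from n = 1, absorption at 0 takes 1/delta
#' @export
mfpt <- function(model, start, target, method = c("exact", "ssa"),
                 n_cap = NULL, n_runs = 1e4, t_max = 1e7, seed = NULL,
                 trunc_tol = 1e-10) {
  stopifnot(inherits(model, "bursty_gene_model"), length(target) >= 1,
            start >= 0)
  method <- match.arg(method)
  target <- sort(unique(as.integer(target)))
  if (start %in% target)
    return(structure(list(mfpt = 0, se = 0, method = method, n = 0L),
                     class = "mfpt_result"))
  if (method == "exact") mfpt_exact(model, start, target, n_cap, trunc_tol)
  else mfpt_ssa(model, start, target, n_runs, t_max, seed)
}

mfpt_exact <- function(model, start, target, n_cap, trunc_tol) {
  f <- model$f; mu <- model$mu_star; delta <- model$delta
  if (feedback_eval(f, 0) > 0) {
    # validate the truncation against the stationary support: essentially no
    # stationary mass may sit beyond the cap, else hitting times are distorted
    pmf <- stationary_pmf(model, tail_tol = 1e-13)
    if (is.null(n_cap))
      n_cap <- max(pmf$n_max + ceiling(5 * mu), max(target), start) + 10L
    if (pmf$n_max > n_cap) {
      beyond <- sum(pmf$p[(n_cap + 2):length(pmf$p)])
      if (beyond > trunc_tol)
        stop(sprintf(
          "stationary mass %.2e beyond n_cap = %d exceeds trunc_tol; raise n_cap",
          beyond, n_cap))
    }
  } else if (is.null(n_cap)) {
    fsup <- feedback_sup(f)
    if (!is.finite(fsup)) stop("n_cap is required for unbounded feedback")
    n_cap <- max(ceiling(fsup / delta) + ceiling(20 * mu) + 50,
                 max(target), start) + 10L
  }
  states <- 0:n_cap
  transient <- setdiff(states, target)
  if (!(start %in% transient)) stop("start must lie inside 0..n_cap")
  idx <- match(transient, states)
  NT <- length(transient)
  pos <- integer(n_cap + 1L); pos[transient + 1L] <- seq_len(NT)
  fn <- feedback_eval(f, transient)
  wb <- fn / mu
  Q <- matrix(0, NT, NT)
  for (r in seq_len(NT)) {
    n <- transient[r]
    out_rate <- wb[r] + delta * n
    if (out_rate <= 0 && !(n %in% target))
      stop("state ", n, " is absorbing outside the target: MFPT is infinite")
    Q[r, r] <- -out_rate
    if (n > 0 && pos[n] > 0) Q[r, pos[n]] <- Q[r, pos[n]] + delta * n
    if (wb[r] > 0) {
      if (mu == 1) {
        dest <- min(n + 1L, n_cap)
        if (pos[dest + 1L] > 0) Q[r, pos[dest + 1L]] <- Q[r, pos[dest + 1L]] + wb[r]
      } else {
        jumps <- seq_len(n_cap - n)
        if (length(jumps)) {
          pr <- (1 / mu) * (1 - 1 / mu)^(jumps - 1)
          dest <- n + jumps
          keep <- pos[dest + 1L] > 0
          if (any(keep))
            Q[r, pos[dest[keep] + 1L]] <- Q[r, pos[dest[keep] + 1L]] +
              wb[r] * pr[keep]
        }
        # overshoot past the cap lumped at n_cap (validated small)
        over <- wb[r] * (1 - 1 / mu)^(n_cap - n)
        if (pos[n_cap + 1L] > 0)
          Q[r, pos[n_cap + 1L]] <- Q[r, pos[n_cap + 1L]] + over
      }
    }
  }
  tau <- solve(Q, rep(-1, NT))
  structure(list(mfpt = tau[pos[start + 1L]], se = NA_real_,
                 method = "exact", n = n_cap, tau = tau,
                 states = transient),
            class = "mfpt_result")
}

mfpt_ssa <- function(model, start, target, n_runs, t_max, seed) {
  code <- feedback_code(model$f)
  if (is.na(code)) stop("SSA method requires an analytic feedback variant")
  # The SSA path interprets the target as {n <= lo} U {n >= hi}. Downward
  # moves are single death steps, so hitting {n <= max(below-start targets)}
  # equals hitting the highest below-start target exactly; upward bursts can
  # overshoot, so above-start targets are treated as the upward-closed set
  # beyond their smallest member.
  lo <- -1L; hi <- .Machine$integer.max
  below <- target[target < start]; above <- target[target > start]
  if (length(below)) lo <- max(below)
  if (length(above)) hi <- min(above)
  times <- with_seed(seed,
    ssa_burst_hitting_cpp(code, feedback_par(model$f), model$mu_star,
                          model$delta, as.integer(start), lo, hi,
                          t_max, as.integer(n_runs)))
  if (anyNA(times))
    stop(sum(is.na(times)), " of ", n_runs,
         " trajectories did not hit the target within t_max = ", t_max)
  structure(list(mfpt = mean(times), se = stats::sd(times) / sqrt(n_runs),
                 method = "ssa", n = n_runs),
            class = "mfpt_result")
}

#' @export
print.mfpt_result <- function(x, ...) {
  if (is.na(x$se))
    cat(sprintf("<mfpt_result> %.6g (exact, cap %d)\n", x$mfpt, x$n))
  else
    cat(sprintf("<mfpt_result> %.6g +/- %.3g s.e. (SSA, %d runs)\n",
                x$mfpt, x$se, x$n))
  invisible(x)
}

#' Inter-mode mean first-passage time
#'
#' Operationalizes switching between the "inactive" (lower) and "active"
#' (upper) expression states of a bimodal model: start at one mode of the
#' stationary PMF and hit the first state beyond the interior minimum, i.e.
#' cross into the other basin. This is the standard basin construction for
#' hitting-time robustness measures; the minimum plateau's far edge is used
#' as the crossing point.
#'
#' @param model a bimodal [bursty_gene_model].
#' @param from `"lower"` (lower mode to upper basin) or `"upper"`.
#' @param ... passed to [mfpt()] (`method`, `n_runs`, `seed`, ...).
#' @return An `mfpt_result` with attributes `start` and `target_threshold`.
#' @export
mfpt_between_modes <- function(model, from = c("lower", "upper"), ...) {
  from <- match.arg(from)
  pmf <- stationary_pmf(model)
  ex <- find_extrema(pmf)
  if (nrow(ex$maxima) < 2 || nrow(ex$minima) < 1)
    stop("model is not bimodal: inter-mode MFPT undefined")
  modes <- ex$maxima$n_lo
  # interior minimum separating the outermost modes
  sep <- ex$minima[ex$minima$n_lo > min(modes) & ex$minima$n_hi < max(modes), ,
                   drop = FALSE]
  if (!nrow(sep)) stop("no interior minimum between the modes")
  n_cap_default <- pmf$n_max + ceiling(5 * model$mu_star)
  if (from == "lower") {
    start <- min(modes)
    thr <- sep$n_hi[1] + 1L
    target <- thr:(n_cap_default)
  } else {
    start <- max(modes)
    thr <- sep$n_lo[1] - 1L
    target <- 0:thr
  }
  res <- mfpt(model, start, target, ...)
  attr(res, "start") <- start
  attr(res, "target_threshold") <- thr
  res
}
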