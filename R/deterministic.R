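#' Deterministic fixed points of the burst model
#'
#' All analysis is carried out on the molecule scale, where the mass-action
#' ODE of the burst model reads \eqn{\dot n = f(n) - \delta n} (the mean
#' burst size cancels because the burst frequency is scaled by
#' \eqn{1/\mu^*}). Fixed points solve \eqn{f(n) = \delta n}; graphically they
#' are the intersections of \eqn{f(n)/\delta} with the identity line. A
#' point is stable iff \eqn{f'(n^*) < \delta}.
#'
#' Roots are located by sign-change bracketing on a 2048-point grid over
#' `[0, n_max]` with two rounds of adaptive refinement near sign changes,
#' then polished by [stats::uniroot()].
#'
#' @param model a [bursty_gene_model].
#' @param n_max search bound; must exceed \eqn{\sup f/\delta} so all
#'   intersections are bracketed. Defaults to `2 * sup(f)/delta + 50` for
#'   bounded variants.
#' @param tol root tolerance (molecules).
#' @return A `fixed_point_set`: data frame with columns `n_star`, `c_star`
#'   (`= n_star / volume`), `stability` (`"stable"`, `"unstable"` or
#'   `"marginal"`).
#' @examples
#' m <- bursty_gene_model(feedback_constant(20), 6, 1)
#' find_fixed_points(m)
#' @export
find_fixed_points <- function(model, n_max = NULL, tol = 1e-9) {
  stopifnot(inherits(model, "bursty_gene_model"))
  fsup <- feedback_sup(model$f, n_hint = if (!is.null(n_max)) n_max)
  if (is.null(n_max)) {
    if (!is.finite(fsup)) stop("n_max is required for unbounded feedback variants")
    n_max <- 2 * fsup / model$delta + 50
  }
  if (is.finite(fsup) && n_max <= fsup / model$delta)
    stop("n_max must exceed sup f / delta = ", fsup / model$delta,
         " so that every intersection is bracketed")
  g <- function(n) feedback_eval(model$f, n) - model$delta * n
  roots <- bracketed_roots(g, 0, n_max, n_grid = 2048, tol = tol)
  if (!length(roots)) {
    out <- data.frame(n_star = numeric(0), c_star = numeric(0),
                      stability = character(0))
    return(structure(out, class = c("fixed_point_set", "data.frame"),
                     tol = tol))
  }
  roots <- sort(roots)
  stab <- vapply(roots, function(r) classify_stability(model, r), character(1))
  out <- data.frame(n_star = roots, c_star = roots / model$volume,
                    stability = stab)
  structure(out, class = c("fixed_point_set", "data.frame"), tol = tol)
}

# Sign-change bracketing with adaptive refinement: returns all roots of g on
# [lo, hi]. Close root pairs that a coarse grid straddles are separated by
# two rounds of 32x refinement inside flagged cells.
bracketed_roots <- function(g, lo, hi, n_grid = 2048, tol = 1e-9,
                            rounds = 2) {
  x <- seq(lo, hi, length.out = n_grid)
  gv <- g(x)
  roots <- numeric(0)
  cells <- which(gv[-length(gv)] * gv[-1] < 0)
  zero_idx <- which(gv == 0)
  roots <- c(roots, x[zero_idx])
  for (i in cells) {
    r <- stats::uniroot(g, c(x[i], x[i + 1]), tol = tol)$root
    roots <- c(roots, r)
  }
  # refinement: a cell may hide an even number of crossings (local dip that
  # touches and re-crosses); look for interior extrema of |g| changing sign
  for (round in seq_len(rounds)) {
    step <- (hi - lo) / (n_grid - 1) / 32^round
    if (step <= tol) break
    xr <- seq(lo, hi, by = (hi - lo) / (n_grid - 1) / 32^round)
    gvr <- g(xr)
    cells <- which(gvr[-length(gvr)] * gvr[-1] < 0)
    cand <- vapply(cells, function(i)
      stats::uniroot(g, c(xr[i], xr[i + 1]), tol = tol)$root, numeric(1))
    cand <- c(cand, xr[gvr == 0])
    roots <- c(roots, cand)
  }
  if (!length(roots)) return(numeric(0))
  roots <- sort(roots)
  # deduplicate roots found at several refinement levels
  keep <- c(TRUE, diff(roots) > max(tol * 10, 1e-7 * (hi - lo)))
  roots[keep]
}

#' Linear stability of a fixed point
#'
#' Stability of \eqn{\dot n = f(n) - \delta n} at `n_star` from the sign of
#' \eqn{f'(n^*) - \delta} (derivative by central difference for smooth
#' variants). When \eqn{|f'(n^*) - \delta| < 10^{-9}\delta}, below the
#' accuracy of the numeric derivative, the point is flagged `"marginal"`
#' rather than force-labelled.
#'
#' @param model a [bursty_gene_model].
#' @param n_star a fixed point (molecules).
#' @return `"stable"`, `"unstable"` or `"marginal"`.
#' @export
classify_stability <- function(model, n_star) {
  stopifnot(inherits(model, "bursty_gene_model"), n_star >= 0)
  fp <- deriv1(model$f, n_star)
  if (abs(fp - model$delta) < 1e-9 * model$delta) "marginal"
  else if (fp < model$delta) "stable" else "unstable"
}

# first derivative: analytic where available, else central difference
deriv1 <- function(f, x) {
  if (f$variant %in% c("constant", "linear", "michaelis_menten"))
    return(feedback_deriv(f, x, 1))
  h <- max(1e-6, 1e-7 * max(x, 1))
  lo <- max(x - h, 0)
  (feedback_eval(f, x + h) - feedback_eval(f, lo)) / (x + h - lo)
}

#' Integrate the deterministic rate equation
#'
#' Solves \eqn{\dot n = f(n) - \delta n} from `n0` over `t_grid` with
#' [deSolve::ode()] (lsoda). On the concentration scale this is the
#' mass-action ODE \eqn{\dot c = \tilde f(c)/V - \delta c} with
#' \eqn{\tilde f(c) = f(cV)}; working in molecules keeps the result directly
#' comparable with copy-number modes and means.
#'
#' @param model a [bursty_gene_model].
#' @param n0 initial molecule count (real, >= 0).
#' @param t_grid increasing vector of output times starting at 0.
#' @param ... passed to [deSolve::ode()] (e.g. `rtol`, `atol`).
#' @return Data frame with columns `t` and `n`.
#' @export
integrate_ode <- function(model, n0, t_grid, ...) {
  stopifnot(inherits(model, "bursty_gene_model"), n0 >= 0,
            !is.unsorted(t_grid))
  rhs <- function(t, y, parms) {
    list(feedback_eval(model$f, max(y, 0)) - model$delta * y)
  }
  sol <- deSolve::ode(y = c(n = n0), times = t_grid, func = rhs, parms = NULL,
                      rtol = 1e-10, atol = 1e-10, ...)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed for model with delta = ", model$delta)
  data.frame(t = sol[, "time"], n = pmax(sol[, "n"], 0))
}

#' @export
print.fixed_point_set <- function(x, ...) {
  cat("<fixed_point_set>", nrow(x), "fixed point(s)\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
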