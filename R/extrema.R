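#' Extrema (modes and antimodes) of a stationary PMF
#'
#' Scans the sign changes of \eqn{p_{n+1} - p_n}. Consecutive probabilities
#' equal within a relative tolerance of 1e-12 are merged into plateaus, so
#' each extremum is reported as an interval `{n_lo, n_hi}` (exact ties arise
#' whenever \eqn{f(n)/\delta - (n+\mu^*)} hits zero at an integer, e.g. a
#' Poisson PMF with integer mean). One extremum necessarily sits at the
#' boundary `n = 0`: a maximum iff \eqn{p_0 > p_1} strictly; a tie joins the
#' first plateau.
#'
#' @param pmf a [stationary_pmf()] result, or a bare probability vector over
#'   `n = 0, 1, ...`.
#' @param rtol relative tie tolerance for plateau merging.
#' @return An `extrema_set`: list with data frames `maxima` and `minima`
#'   (columns `n_lo`, `n_hi`) and `boundary` (`"maximum"` or `"minimum"`
#'   at `n = 0`). Maxima and minima alternate in `n`.
#' @examples
#' m <- bursty_gene_model(feedback_constant(20), 1, 1)
#' find_extrema(stationary_pmf(m))  # Poisson(20): plateau mode {19, 20}
#' @export
find_extrema <- function(pmf, rtol = 1e-12) {
  p <- if (inherits(pmf, "stationary_pmf")) pmf$p else as.numeric(pmf)
  stopifnot(length(p) >= 1, all(p >= 0))
  N <- length(p)
  if (N == 1) {
    return(new_extrema_set(data.frame(n_lo = 0, n_hi = 0),
                           data.frame(n_lo = numeric(0), n_hi = numeric(0)),
                           "maximum", p))
  }
  d <- p[-1] - p[-N]
  s <- ifelse(abs(d) <= rtol * pmax(p[-1], p[-N]), 0L, ifelse(d > 0, 1L, -1L))
  extrema_from_signs(s, p)
}

# Shared scan: s[k] is the sign of p_{k} - p_{k-1} comparison shifted --
# here s[k] = sign(p[k+1] - p[k]) for k = 1..N-1 (0-based states k-1 -> k).
# Plateaus are maximal runs of zeros; an extremum is the closed interval
# between a rise and a fall (maximum) or a fall and a rise (minimum).
extrema_from_signs <- function(s, p = NULL) {
  N <- length(s) + 1L
  nz <- which(s != 0L)
  maxima <- minima <- list()
  if (!length(nz)) {
    # completely flat: single plateau maximum spanning everything
    return(new_extrema_set(data.frame(n_lo = 0, n_hi = N - 1),
                           data.frame(n_lo = numeric(0), n_hi = numeric(0)),
                           "maximum", p))
  }
  # boundary at 0
  first_sign <- s[nz[1]]
  boundary <- if (first_sign < 0L) "maximum" else "minimum"
  if (first_sign < 0L)
    maxima[[length(maxima) + 1L]] <- c(0L, nz[1] - 1L)
  else
    minima[[length(minima) + 1L]] <- c(0L, nz[1] - 1L)
  # interior: transitions between consecutive nonzero signs
  for (k in seq_len(length(nz) - 1L)) {
    a <- nz[k]; b <- nz[k + 1L]
    if (s[a] == 1L && s[b] == -1L)
      maxima[[length(maxima) + 1L]] <- c(a, b - 1L)
    else if (s[a] == -1L && s[b] == 1L)
      minima[[length(minima) + 1L]] <- c(a, b - 1L)
  }
  # right boundary: a terminal rise ends in a maximum plateau at the top
  if (s[nz[length(nz)]] == 1L)
    maxima[[length(maxima) + 1L]] <- c(nz[length(nz)], N - 1L)
  to_df <- function(lst) {
    if (!length(lst)) return(data.frame(n_lo = numeric(0), n_hi = numeric(0)))
    m <- do.call(rbind, lst)
    data.frame(n_lo = m[, 1], n_hi = m[, 2])
  }
  new_extrema_set(to_df(maxima), to_df(minima), boundary, p)
}

new_extrema_set <- function(maxima, minima, boundary, p = NULL) {
  peak_p <- if (!is.null(p) && nrow(maxima)) p[maxima$n_lo + 1L] else NULL
  structure(list(maxima = maxima, minima = minima, boundary = boundary,
                 peak_probs = peak_p),
            class = "extrema_set")
}

#' @export
print.extrema_set <- function(x, ...) {
  fmt <- function(df) if (!nrow(df)) "none" else
    paste(sprintf("{%d,%d}", df$n_lo, df$n_hi), collapse = " ")
  cat("<extrema_set> boundary at n=0:", x$boundary, "\n")
  cat("  maxima:", fmt(x$maxima), "\n  minima:", fmt(x$minima), "\n")
  invisible(x)
}

#' Analytic extrema via the discrepancy function
#'
#' Locates the extrema of the stationary PMF without computing it, from the
#' sign of the discrepancy \eqn{d(n) = f(n)/\delta - (n + \mu^*)}: the
#' recursion gives \eqn{p_{n+1} \gtrless p_n \iff d(n) \gtrless 0}, so
#' downward crossings of zero are maxima (the ceiling condition
#' \eqn{n = \lceil f(n)/\delta - \mu^* \rceil}) and upward crossings are
#' minima. Integer zeros of `d` produce exact plateaus; the ceiling value
#' maps to the plateau's left edge.
#'
#' @param model a [bursty_gene_model].
#' @param n_range highest state to scan; must cover the PMF support
#'   (defaults to past \eqn{\sup f/\delta} for bounded variants).
#' @return An `extrema_set`, directly comparable with [find_extrema()].
#' @export
analytic_extrema <- function(model, n_range = NULL) {
  stopifnot(inherits(model, "bursty_gene_model"))
  fsup <- feedback_sup(model$f, n_hint = n_range)
  if (is.null(n_range)) {
    if (!is.finite(fsup)) stop("n_range is required for unbounded feedback variants")
    n_range <- ceiling(fsup / model$delta) + 10
  }
  n <- 0:(n_range - 1L)
  d <- feedback_eval(model$f, n) / model$delta - (n + model$mu_star)
  tol <- 1e-12 * pmax(1, abs(n + model$mu_star))
  s <- ifelse(abs(d) <= tol, 0L, ifelse(d > 0, 1L, -1L))
  extrema_from_signs(s)
}

#' Do two extrema sets agree?
#'
#' Plateau-aware comparison: same boundary classification and identical
#' maxima/minima intervals.
#'
#' @param a,b `extrema_set` objects.
#' @return Logical.
#' @export
extrema_agree <- function(a, b) {
  same <- function(u, v) nrow(u) == nrow(v) &&
    (nrow(u) == 0 || (all(u$n_lo == v$n_lo) && all(u$n_hi == v$n_hi)))
  a$boundary == b$boundary && same(a$maxima, b$maxima) && same(a$minima, b$minima)
}
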