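#' Feedback (production-rate) functions
#'
#' Constructors for the protein production rate \eqn{f(n)}, a smooth,
#' monotonically nondecreasing function of the current protein copy number
#' \eqn{n}. The variants cover the standard autoregulation motifs:
#' no feedback (constant), linear activation, non-cooperative saturation
#' (Michaelis-Menten) and cooperative sigmoid activation (Hill).
#'
#' The Hill variant is parameterized as
#' \eqn{f(n) = b + v\, n^h / (n^h + K)} with \eqn{K} in molecules\eqn{^h};
#' the convenience argument `K_half` (a half-saturation point in molecules)
#' stores \eqn{K = K_{half}^h}.
#'
#' @param b basal production rate (molecules/time), nonnegative.
#' @param v maximal feedback-driven production rate (molecules/time) for the
#'   saturating variants; the slope (1/time) for the linear variant.
#' @param K half-saturation constant: molecules for `feedback_mm`,
#'   molecules^h for `feedback_hill`.
#' @param K_half alternative Hill parameterization: half-saturation point in
#'   molecules (exactly one of `K`, `K_half` must be given).
#' @param h Hill coefficient (> 1, dimensionless).
#' @param slope slope of the linear variant (1/time), nonnegative.
#' @param fun for `feedback_custom`: a vectorized function of `n >= 0`,
#'   monotone nondecreasing and nonnegative.
#' @param deriv optional function `(n, order)` returning derivatives of `fun`;
#'   numeric differentiation is used when absent.
#'
#' @return An object of class `feedback_fn`.
#' @examples
#' f <- feedback_hill(b = 1, v = 10, K_half = 10, h = 2)
#' feedback_eval(f, c(0, 10, 1e6))
#' @name feedback
NULL

new_feedback <- function(variant, b = 0, v = 0, K = 1, h = 1, fun = NULL,
                         deriv = NULL) {
  stopifnot(b >= 0, v >= 0, K > 0)
  structure(list(variant = variant, b = b, v = v, K = K, h = h,
                 fun = fun, deriv = deriv),
            class = "feedback_fn")
}

#' @rdname feedback
#' @export
feedback_constant <- function(b) new_feedback("constant", b = b)

#' @rdname feedback
#' @export
feedback_linear <- function(b, slope) {
  stopifnot(slope >= 0)
  new_feedback("linear", b = b, v = slope)
}

#' @rdname feedback
#' @export
feedback_mm <- function(b, v, K) new_feedback("michaelis_menten", b = b, v = v, K = K)

#' @rdname feedback
#' @export
feedback_hill <- function(b, v, K = NULL, K_half = NULL, h) {
  stopifnot(h > 1)
  if (is.null(K) == is.null(K_half))
    stop("supply exactly one of `K` (molecules^h) or `K_half` (molecules)")
  if (is.null(K)) K <- K_half^h
  new_feedback("hill", b = b, v = v, K = K, h = h)
}

#' @rdname feedback
#' @export
feedback_custom <- function(fun, deriv = NULL) {
  stopifnot(is.function(fun))
  new_feedback("custom", fun = fun, deriv = deriv)
}

#' Evaluate a feedback function
#'
#' @param f a [feedback] object.
#' @param n copy numbers (nonnegative, real or integer), vectorized.
#' @return Production rates \eqn{f(n)} (molecules/time).
#' @export
feedback_eval <- function(f, n) {
  stopifnot(inherits(f, "feedback_fn"))
  if (any(n < 0)) stop("feedback functions are defined for n >= 0 only")
  switch(f$variant,
    constant = rep_len(f$b, length(n)),
    linear = f$b + f$v * n,
    michaelis_menten = f$b + f$v * n / (n + f$K),
    hill = {
      nh <- n^f$h
      f$b + f$v * nh / (nh + f$K)
    },
    custom = f$fun(n)
  )
}

#' Derivatives of a feedback function
#'
#' Analytic for the constant, linear and Michaelis-Menten variants (the latter
#' via \eqn{f^{(r)}(n) = (-1)^{r+1} r!\, vK/(n+K)^{r+1}}); numeric
#' (Richardson-extrapolated central differences) for Hill and custom variants
#' without a supplied derivative.
#'
#' @param f a [feedback] object.
#' @param n evaluation point (scalar, >= 0).
#' @param order derivative order (>= 1).
#' @return The derivative value (scalar).
#' @export
feedback_deriv <- function(f, n, order = 1) {
  stopifnot(inherits(f, "feedback_fn"), length(n) == 1, n >= 0, order >= 1)
  switch(f$variant,
    constant = 0,
    linear = if (order == 1) f$v else 0,
    michaelis_menten =
      (-1)^(order + 1) * factorial(order) * f$v * f$K / (n + f$K)^(order + 1),
    hill = pracma::fderiv(function(x) feedback_eval(f, pmax(x, 0)), n,
                          n = order, h = max(1e-2, 1e-3 * max(n, 1))),
    custom = if (!is.null(f$deriv)) f$deriv(n, order)
             else pracma::fderiv(function(x) f$fun(pmax(x, 0)), n, n = order,
                                 h = max(1e-2, 1e-3 * max(n, 1)))
  )
}

# Upper bound on sup_n f(n) for truncation heuristics; Inf for unbounded
# variants (linear, unknown custom).
feedback_sup <- function(f, n_hint = NULL) {
  switch(f$variant,
    constant = f$b,
    linear = if (f$v == 0) f$b else Inf,
    michaelis_menten = f$b + f$v,
    hill = f$b + f$v,
    custom = if (!is.null(n_hint)) max(f$fun(seq(0, n_hint, length.out = 512)))
             else Inf
  )
}

# Encoding used by the C++ SSA kernels; custom functions have no native path.
feedback_code <- function(f) {
  switch(f$variant, constant = 0L, linear = 1L, michaelis_menten = 2L,
         hill = 3L, custom = NA_integer_)
}

feedback_par <- function(f) c(f$b, f$v, f$K, f$h)

#' @export
print.feedback_fn <- function(x, ...) {
  desc <- switch(x$variant,
    constant = sprintf("f(n) = %g", x$b),
    linear = sprintf("f(n) = %g + %g n", x$b, x$v),
    michaelis_menten = sprintf("f(n) = %g + %g n/(n + %g)", x$b, x$v, x$K),
    hill = sprintf("f(n) = %g + %g n^%g/(n^%g + %g)", x$b, x$v, x$h, x$h, x$K),
    custom = "user-supplied f(n)")
  cat("<feedback_fn> [", x$variant, "] ", desc, "\n", sep = "")
  invisible(x)
}
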