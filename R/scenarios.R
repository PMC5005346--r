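#' Matched-model scenario: shifted basal rate, common discrepancy
#'
#' Pairs a base system `(f1, mu1)` with `(f2, mu2)`, `mu2 > mu1`, where
#' \eqn{f_2 = f_1 + \delta(\mu_2^* - \mu_1^*)}. The discrepancy functions
#' \eqn{f_i(n)/\delta - (n + \mu_i^*)} are then identical pointwise, so both
#' systems place their extrema at exactly the same copy numbers while the
#' relative slope \eqn{s(n)} of the larger-burst system is uniformly damped
#' by its bigger \eqn{\mu^*}: its stationary distribution is broader.
#'
#' @param f1 base [feedback] function.
#' @param mu1,mu2 mean burst sizes with `mu2 > mu1 >= 1`.
#' @param delta degradation rate.
#' @param volume system volume.
#' @return A `scenario_pair`: list with models `a` (`mu1`) and `b` (`mu2`),
#'   `construction = "shifted_basal"`, and the post-check grid.
#' @export
scenario_shifted_basal <- function(f1, mu1, mu2, delta, volume = 1) {
  stopifnot(inherits(f1, "feedback_fn"), mu2 > mu1, mu1 >= 1, delta > 0)
  shift <- delta * (mu2 - mu1)
  f2 <- switch(f1$variant,
    constant = feedback_constant(f1$b + shift),
    linear = feedback_linear(f1$b + shift, f1$v),
    michaelis_menten = feedback_mm(f1$b + shift, f1$v, f1$K),
    hill = feedback_hill(f1$b + shift, f1$v, K = f1$K, h = f1$h),
    custom = feedback_custom(function(n) f1$fun(n) + shift)
  )
  a <- bursty_gene_model(f1, mu1, delta, volume)
  b <- bursty_gene_model(f2, mu2, delta, volume)
  grid <- scenario_grid(a, b)
  da <- discrepancy(a, grid)
  db <- discrepancy(b, grid)
  if (max(abs(da - db)) > 1e-9 * max(1, max(abs(da))))
    stop("internal error: shifted-basal discrepancies do not coincide")
  new_scenario_pair(a, b, "shifted_basal", "identical discrepancy functions",
                    data.frame(n = grid, d_a = da, d_b = db))
}

#' Matched-model scenario: cooperative vs non-cooperative feedback
#'
#' Compares a Hill system `f3` against a Michaelis-Menten system `f4` with
#' the same basal rate and the same burst size, with `(v4, K4)` solved so
#' that \eqn{f_4/\delta} passes through the same two intersection points
#' \eqn{(n_a, n_a+\mu^*)}, \eqn{(n_b, n_b+\mu^*)} with the shifted identity
#' line as \eqn{f_3/\delta}: both stationary distributions place their
#' interior extrema at the same copy numbers. Between and around the
#' intersections the saturating curve hugs the line more closely than the
#' sigmoid, \eqn{|f_4/\delta - (n+\mu^*)| < |f_3/\delta - (n+\mu^*)|}, so
#' the cooperative system's peaks are sharper. The construction verifies
#' this inequality on the integer grid (excluding the intersection points
#' and `n = 0`, where the basal rates tie) and errors if it fails.
#'
#' @param f3 a Hill [feedback] whose \eqn{f_3/\delta} crosses the line
#'   \eqn{n + \mu^*} at two or more points (the last two are used).
#' @param mu_star shared mean burst size.
#' @param delta degradation rate.
#' @param volume system volume.
#' @return A `scenario_pair` with models `a` (Hill) and `b`
#'   (Michaelis-Menten), `construction = "hill_vs_mm"`, the intersection
#'   points and the post-check grid.
#' @export
scenario_hill_vs_mm <- function(f3, mu_star, delta, volume = 1) {
  stopifnot(inherits(f3, "feedback_fn"), f3$variant == "hill",
            mu_star >= 1, delta > 0)
  a <- bursty_gene_model(f3, mu_star, delta, volume)
  xs <- discrepancy_roots(a)
  if (length(xs) < 2)
    stop("f3/delta must intersect the line n + mu* at two points; found ",
         length(xs))
  n_a <- xs[length(xs) - 1]; n_b <- xs[length(xs)]
  y_a <- delta * (n_a + mu_star) - f3$b
  y_b <- delta * (n_b + mu_star) - f3$b
  sol <- solve_mm_through(n_a, y_a, n_b, y_b)
  f4 <- feedback_mm(f3$b, sol$v, sol$K)
  b <- bursty_gene_model(f4, mu_star, delta, volume)
  # construction constraints
  for (x in c(n_a, n_b)) {
    gap <- abs(feedback_eval(f4, x) / delta - (x + mu_star))
    if (gap > 1e-9 * max(1, x)) stop("MM through-point constraint violated")
  }
  grid <- scenario_grid(a, b)
  da <- discrepancy(a, grid); db <- discrepancy(b, grid)
  chk <- check_dominance(grid, abs(da), abs(db), roots = c(n_a, n_b))
  if (!chk$ok)
    stop("discrepancy dominance |d_mm| < |d_hill| fails at n = ",
         paste(utils::head(chk$fail_n, 5), collapse = ", "))
  new_scenario_pair(a, b, "hill_vs_mm",
                    "shared basal rate and intersection points",
                    data.frame(n = grid, d_a = da, d_b = db),
                    intersections = c(n_a, n_b))
}

#' Matched-model scenario: two non-cooperative systems, shared modes
#'
#' Constructs two Michaelis-Menten systems with the same basal rate `b` and
#' mode-determining intersection points `n_a < n_b`, but different burst
#' sizes `mu5 > mu6`: `(v_i, K_i)` are solved so that each
#' \eqn{f_i/\delta} meets its own shifted line \eqn{n + \mu_i^*} at
#' \eqn{\{n_a, n_b\}}. The larger-burst system then has the pointwise larger
#' discrepancy magnitude, which counteracts its broader-burst noise -- which
#' effect prevails in the stationary distribution requires explicit
#' computation, so both PMFs should be compared numerically.
#'
#' @param b shared basal production rate.
#' @param n_a,n_b intersection points, `0 < n_a < n_b`.
#' @param mu5,mu6 burst sizes with `mu5 > mu6 >= 1`.
#' @param delta degradation rate.
#' @param volume system volume.
#' @return A `scenario_pair` with models `a` (burst size `mu5`) and `b`
#'   (`mu6`), `construction = "mm_vs_mm"`.
#' @export
scenario_mm_vs_mm <- function(b, n_a, n_b, mu5, mu6, delta, volume = 1) {
  stopifnot(mu5 > mu6, mu6 >= 1, 0 < n_a, n_a < n_b, delta > 0, b >= 0)
  mk <- function(mu) {
    y_a <- delta * (n_a + mu) - b
    y_b <- delta * (n_b + mu) - b
    if (y_a <= 0 || y_b <= 0)
      stop("infeasible: basal rate already exceeds the target line at an intersection")
    sol <- solve_mm_through(n_a, y_a, n_b, y_b)
    bursty_gene_model(feedback_mm(b, sol$v, sol$K), mu, delta, volume)
  }
  a <- mk(mu5); b_model <- mk(mu6)
  grid <- scenario_grid(a, b_model)
  da <- discrepancy(a, grid); db <- discrepancy(b_model, grid)
  chk <- check_dominance(grid, abs(da), abs(db), roots = c(n_a, n_b))
  if (!chk$ok)
    stop("discrepancy dominance |d_mu5| > |d_mu6| fails at n = ",
         paste(utils::head(chk$fail_n, 5), collapse = ", "))
  new_scenario_pair(a, b_model, "mm_vs_mm",
                    "shared basal rate and mode locations",
                    data.frame(n = grid, d_a = da, d_b = db),
                    intersections = c(n_a, n_b))
}

# ---- scenario internals ----

discrepancy <- function(model, n) {
  feedback_eval(model$f, n) / model$delta - (n + model$mu_star)
}

# positive roots of the discrepancy function, by bracketing
discrepancy_roots <- function(model) {
  fsup <- feedback_sup(model$f)
  if (!is.finite(fsup)) stop("discrepancy root search needs bounded feedback")
  hi <- fsup / model$delta + model$mu_star + 10
  g <- function(n) discrepancy(model, n)
  sort(bracketed_roots(g, 0, hi, n_grid = 4096, tol = 1e-10))
}

# Dense integer grid covering both models' stationary supports.
scenario_grid <- function(a, b) {
  hi <- max(feedback_sup(a$f) / a$delta + 4 * a$mu_star,
            feedback_sup(b$f) / b$delta + 4 * b$mu_star)
  0:ceiling(hi)
}

# |big| must exceed |small| strictly everywhere except near the shared
# intersection points and n = 0 (shared basal rate forces a tie there).
check_dominance <- function(grid, big, small, roots, atol = 1e-9) {
  near_root <- Reduce(`|`, lapply(roots, function(r) abs(grid - r) < 1))
  excl <- near_root | grid == 0
  bad <- !excl & (big <= small + atol)
  list(ok = !any(bad), fail_n = grid[bad])
}

new_scenario_pair <- function(a, b, construction, matched, grid_df,
                              intersections = NULL) {
  structure(list(a = a, b = b, construction = construction,
                 matched_property = matched, grid = grid_df,
                 intersections = intersections),
            class = "scenario_pair")
}

#' @export
print.scenario_pair <- function(x, ...) {
  cat("<scenario_pair>", x$construction, "--", x$matched_property, "\n")
  cat("  a: mu* =", x$a$mu_star, "; b: mu* =", x$b$mu_star, "\n")
  if (!is.null(x$intersections))
    cat("  matched intersections at n =",
        paste(signif(x$intersections, 6), collapse = ", "), "\n")
  invisible(x)
}

# 2x2 linear solve for an MM curve v*n/(n+K) through (n_a, y_a), (n_b, y_b):
# v*n - y*K = y*n for each point.
solve_mm_through <- function(n_a, y_a, n_b, y_b) {
  A <- rbind(c(n_a, -y_a), c(n_b, -y_b))
  if (abs(det(A)) < 1e-12 * max(abs(A)))
    stop("singular system: intersection points do not determine an MM curve")
  sol <- solve(A, c(y_a * n_a, y_b * n_b))
  if (sol[1] <= 0 || sol[2] <= 0)
    stop("no valid MM curve through the requested points (v or K nonpositive)")
  list(v = sol[1], K = sol[2])
}
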