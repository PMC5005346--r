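# Run `expr` under a local RNG seed, restoring the caller's RNG state.
# `seed = NULL` uses (and advances) the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Total-variation distance between two PMFs
#'
#' Both arguments are probability vectors over `n = 0, 1, ...`; the shorter
#' one is zero-padded.
#'
#' @param p,q probability vectors.
#' @return `0.5 * sum(|p - q|)`.
#' @export
tv_distance <- function(p, q) {
  L <- max(length(p), length(q))
  p <- c(p, numeric(L - length(p)))
  q <- c(q, numeric(L - length(q)))
  0.5 * sum(abs(p - q))
}

#' @useDynLib burstmodes, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @keywords internal
"_PACKAGE"
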