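#' Serialize and restore model configurations
#'
#' Models round-trip through plain config lists
#' `{feedback: {variant, b, v, K, h}, mu_star, delta, volume}` written as
#' YAML (`.yaml`/`.yml`) or JSON (`.json`). Custom feedback closures cannot
#' be serialized.
#'
#' @param model a [bursty_gene_model].
#' @param path output/input file; the extension selects the format.
#' @return `read_model_config()` returns a [bursty_gene_model];
#'   `model_to_config()`/`model_from_config()` convert to/from plain lists.
#' @export
write_model_config <- function(model, path) {
  cfg <- model_to_config(model)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  model_from_config(cfg)
}

#' @rdname write_model_config
#' @export
model_to_config <- function(model) {
  stopifnot(inherits(model, "bursty_gene_model"))
  f <- model$f
  if (f$variant == "custom")
    stop("custom feedback functions cannot be serialized")
  fb <- list(variant = f$variant, b = f$b)
  if (f$variant != "constant") fb$v <- f$v
  if (f$variant %in% c("michaelis_menten", "hill")) fb$K <- f$K
  if (f$variant == "hill") fb$h <- f$h
  list(feedback = fb, mu_star = model$mu_star, delta = model$delta,
       volume = model$volume)
}

#' @rdname write_model_config
#' @param cfg a config list.
#' @export
model_from_config <- function(cfg) {
  need <- function(x, field, where) {
    if (is.null(x)) stop("malformed config: missing field `", where, field, "`")
    x
  }
  fb <- need(cfg$feedback, "feedback", "")
  variant <- need(fb$variant, "variant", "feedback.")
  required <- switch(variant,
    constant = "b", linear = c("b", "v"), michaelis_menten = c("b", "v", "K"),
    hill = c("b", "v", "K", "h"),
    stop("malformed config: unknown feedback variant `", variant, "`"))
  for (fld in required) need(fb[[fld]], fld, "feedback.")
  f <- switch(variant,
    constant = feedback_constant(fb$b),
    linear = feedback_linear(fb$b, fb$v),
    michaelis_menten = feedback_mm(fb$b, fb$v, fb$K),
    hill = feedback_hill(fb$b, fb$v, K = fb$K, h = fb$h)
  )
  bursty_gene_model(f, need(cfg$mu_star, "mu_star", ""),
                    need(cfg$delta, "delta", ""),
                    volume = if (is.null(cfg$volume)) 1 else cfg$volume)
}

#' Tab-separated writers and readers
#'
#' Diff-friendly TSV (header row, `.` decimal separator) for PMFs
#' (columns `n`, `p`), trajectories (`t`, `n`) and generic tables. Written
#' files round-trip exactly: values are printed with full precision
#' (17 significant digits).
#'
#' @param pmf a [stationary_pmf()] result or probability vector.
#' @param path file path.
#' @name tsv_io
#' @export
write_pmf_tsv <- function(pmf, path) {
  p <- if (inherits(pmf, "stationary_pmf")) pmf$p else as.numeric(pmf)
  df <- data.frame(n = 0:(length(p) - 1L), p = p)
  write_tsv_full(df, path)
}

#' @rdname tsv_io
#' @return `read_pmf_tsv()` returns the probability vector.
#' @export
read_pmf_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  stopifnot(all(c("n", "p") %in% names(df)))
  df$p[order(df$n)]
}

#' @rdname tsv_io
#' @param traj a `burst_trajectory` (or any data frame with `t`, `n`).
#' @export
write_trajectory_tsv <- function(traj, path) {
  write_tsv_full(as.data.frame(traj)[, c("t", "n")], path)
}

#' @rdname tsv_io
#' @export
read_trajectory_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE)
}

# full-precision TSV write shared by all writers
write_tsv_full <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  for (j in which(num)) df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
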