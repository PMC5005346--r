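#' Canonical model presets
#'
#' Four feedback families, each at the three canonical burst sizes
#' \eqn{\mu^* \in \{1, 6, 11\}} (no burst, medium, strong), chosen by a
#' regime-certification search so that together they realize every
#' stability-by-modality quadrant:
#'
#' * `no_feedback` -- constant production `f = 20`, the Poisson /
#'   negative-binomial reference; monostable-unimodal at every burst size.
#' * `noncoop` -- Michaelis-Menten feedback `2 + 100 n/(n+30)`; monostable,
#'   but medium and strong bursts make it bimodal with one mode at `n = 0`.
#' * `coop_bistable` -- Hill feedback `4 + 60 n^4/(n^4 + 30^4)`; bistable,
#'   bimodal at small and medium bursts, and unimodal (peak at 0) under
#'   strong bursts.
#' * `coop_monostable_bimodal` -- Hill feedback `10 + 80 n^4/(n^4 + 25^4)`;
#'   monostable, yet bimodal with both modes at positive copy numbers at
#'   the medium burst size.
#'
#' All presets use `delta = 1` (time is measured in protein lifetimes) and
#' `volume = 1`.
#'
#' @param family one of the four family names.
#' @param mu_star one of 1, 6, 11.
#' @return `preset_model()` returns a single [bursty_gene_model];
#'   `burst_presets()` returns a named list of all 12 (names
#'   `"<family>.mu<mu>"`).
#' @export
preset_model <- function(family = c("no_feedback", "noncoop", "coop_bistable",
                                    "coop_monostable_bimodal"),
                         mu_star = 1) {
  family <- match.arg(family)
  stopifnot(mu_star %in% c(1, 6, 11))
  f <- switch(family,
    no_feedback = feedback_constant(20),
    noncoop = feedback_mm(2, 100, 30),
    coop_bistable = feedback_hill(4, 60, K_half = 30, h = 4),
    coop_monostable_bimodal = feedback_hill(10, 80, K_half = 25, h = 4)
  )
  bursty_gene_model(f, mu_star, delta = 1, volume = 1)
}

#' @rdname preset_model
#' @export
burst_presets <- function() {
  fams <- c("no_feedback", "noncoop", "coop_bistable",
            "coop_monostable_bimodal")
  out <- list()
  for (fam in fams) for (mu in c(1, 6, 11))
    out[[sprintf("%s.mu%d", fam, mu)]] <- preset_model(fam, mu)
  out
}

#' Sharp bistable reference model
#'
#' A steeper cooperative system, `f(n) = 4 + 60 n^6/(n^6 + 30^6)` with
#' `mu_star = 6`, whose stable fixed points sit where the feedback is nearly
#' saturated (small `f'`), so stochastic modes track the deterministic
#' fixed points tightly. Used for the system-size scaling experiment, where
#' the mode-to-fixed-point deviation is compared against the
#' \eqn{(\mu^*+1)/(sV)} bound.
#'
#' @param mu_star mean burst size.
#' @return A [bursty_gene_model].
#' @export
sharp_bistable_model <- function(mu_star = 6) {
  bursty_gene_model(feedback_hill(4, 60, K_half = 30, h = 6), mu_star,
                    delta = 1, volume = 1)
}

# Quadrant claims each preset is certified against.
preset_claims <- function() {
  data.frame(
    name = c("no_feedback.mu1", "noncoop.mu6", "coop_bistable.mu1",
             "coop_bistable.mu11", "coop_monostable_bimodal.mu6"),
    label = c("monostable-unimodal", "monostable-bimodal",
              "bistable-bimodal", "bistable-unimodal", "monostable-bimodal"),
    stringsAsFactors = FALSE
  )
}

#' Certify the preset catalogue
#'
#' Runs [classify_regime()] on every preset and checks the quadrant claims:
#' the catalogue must realize all four stability-by-modality combinations,
#' including a bistable-unimodal model and a monostable-bimodal model with
#' both modes at positive copy numbers.
#'
#' @return Data frame with one row per preset: `name`, `label`, `n_stable`,
#'   `n_modes`, `modes`.
#' @export
certify_presets <- function() {
  presets <- burst_presets()
  rows <- lapply(names(presets), function(nm) {
    rl <- classify_regime(presets[[nm]])
    data.frame(name = nm, label = rl$label,
               n_stable = rl$n_stable_fixed_points, n_modes = rl$n_modes,
               modes = paste(rl$modes, collapse = "/"),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  claims <- preset_claims()
  for (i in seq_len(nrow(claims))) {
    got <- tab$label[tab$name == claims$name[i]]
    if (got != claims$label[i])
      stop(sprintf("preset %s certifies as %s, expected %s",
                   claims$name[i], got, claims$label[i]))
  }
  # the positive-modes claim for the monostable-bimodal cooperative preset
  rl <- classify_regime(preset_model("coop_monostable_bimodal", 6))
  if (any(rl$modes == 0))
    stop("coop_monostable_bimodal.mu6 should have both modes positive")
  tab
}

#' Write the preset catalogue to disk
#'
#' Serializes all 12 presets as YAML model configs plus a JSON certification
#' table from [certify_presets()].
#'
#' @param output_dir directory (created if missing).
#' @return Invisibly, the certification table.
#' @export
generate_presets <- function(output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  cert <- certify_presets()
  presets <- burst_presets()
  for (nm in names(presets))
    write_model_config(presets[[nm]], file.path(output_dir, paste0(nm, ".yaml")))
  jsonlite::write_json(cert, file.path(output_dir, "certification.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(cert)
}
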