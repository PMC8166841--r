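ODORANTS_MD5 <- "a6217ea563e4a49eaaf9e3692a7e245f"

#' Bundled reference set of 20 odorant molecules
#'
#' Twenty odorant molecules spanning six perceptual (odour) classes —
#' Aromatic, Roasted Coffee, Moth-ball, Fruity, Musk and Garlicky — each
#' with the wavenumbers (cm^-1) of its dominant vibrational modes, as
#' obtained by peak decomposition of DFT-derived EVA pseudo-spectra.
#' Perceptual subclasses ("Strong"/"Weak" for the aromatics,
#' "natural"/"artificial" for the garlic-smelling sulfur compounds) are
#' retained so that subclass recovery by clustering can be checked
#' against ground truth.
#'
#' The bundled CSV is checksummed at load time.
#'
#' @return Data frame with one row per molecule: `molecule`,
#'   `perceptual_class`, `perceptual_subclass`, and a list-column
#'   `modes` of ascending wavenumbers; band labels per mode (by
#'   [mode_bands()]) are in list-column `mode_bands`.
#' @examples
#' od <- load_odorants()
#' od$modes[[which(od$molecule == "Furan")]]
#' @export
load_odorants <- function() {
  path <- system.file("extdata", "odorants.csv", package = "pdeva",
                      mustWork = TRUE)
  if (unname(tools::md5sum(path)) != ODORANTS_MD5) {
    stop("bundled odorant table failed its checksum; reinstall the package")
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$modes <- lapply(strsplit(d$wavenumbers, ";"), as.numeric)
  bands <- mode_bands()
  d$mode_bands <- lapply(d$modes, function(m) {
    bands$label[findInterval(m, bands$lo)]
  })
  d$wavenumbers <- NULL
  d
}

#' Generate synthetic odorant classes
#'
#' Emulates K odour classes as per-class template mode sets: each
#' synthetic molecule inherits its class template with independent
#' Gaussian jitter (`jitter_sd`, cm^-1) on every mode and optional
#' per-mode dropout.  The default templates mimic the band-occupancy
#' patterns of aromatic-, fruity-, musk- and sulfurous-smelling
#' molecules.  Reproducible for a fixed `seed`.
#'
#' A preset is "recoverable" when `jitter_sd` is below half the minimum
#' gap between any two template modes of different classes; violating
#' presets are generated with a warning.
#'
#' @param n_classes number of classes (defaults to the template count).
#' @param molecules_per_class molecules per class.
#' @param template_modes list of per-class numeric mode vectors
#'   (cm^-1); pairwise distinct.
#' @param jitter_sd per-mode Gaussian jitter SD, cm^-1.
#' @param mode_dropout_prob probability of dropping each mode, in
#'   `[0, 1)`; a molecule always keeps at least one mode.
#' @param seed RNG seed.
#' @return Data frame like [load_odorants()] (`perceptual_class` holds
#'   the planted class label `class1`, `class2`, ...) with a list-column
#'   `modes`; attribute `truth` repeats the planted integer labels.
#' @export
synthetic_odorants <- function(n_classes = length(template_modes),
                               molecules_per_class = 5,
                               template_modes = default_templates(),
                               jitter_sd = 15, mode_dropout_prob = 0,
                               seed = 1) {
  if (n_classes > length(template_modes)) {
    stop("only ", length(template_modes), " templates for ", n_classes,
         " classes")
  }
  template_modes <- template_modes[seq_len(n_classes)]
  if (anyDuplicated(lapply(template_modes, sort))) {
    stop("template mode sets must be pairwise distinct")
  }
  if (!(mode_dropout_prob >= 0 && mode_dropout_prob < 1)) {
    stop("mode_dropout_prob must be in [0, 1)")
  }
  gap <- min_template_gap(template_modes)
  if (jitter_sd >= gap / 2) {
    warning(sprintf(paste0("jitter_sd = %g is not below half the minimum ",
                           "between-template mode gap (%g); planted classes ",
                           "may not be recoverable"), jitter_sd, gap))
  }
  set.seed(seed)
  rows <- list()
  for (k in seq_len(n_classes)) {
    for (r in seq_len(molecules_per_class)) {
      m <- template_modes[[k]] + stats::rnorm(length(template_modes[[k]]),
                                              0, jitter_sd)
      keep <- stats::runif(length(m)) >= mode_dropout_prob
      if (!any(keep)) keep[sample.int(length(m), 1)] <- TRUE
      rows[[length(rows) + 1]] <- list(
        molecule = sprintf("class%d_mol%d", k, r),
        perceptual_class = paste0("class", k),
        perceptual_subclass = "",
        modes = sort(pmax(m[keep], 0)), truth = k)
    }
  }
  out <- data.frame(
    molecule = vapply(rows, `[[`, "", "molecule"),
    perceptual_class = vapply(rows, `[[`, "", "perceptual_class"),
    perceptual_subclass = vapply(rows, `[[`, "", "perceptual_subclass"),
    stringsAsFactors = FALSE)
  out$modes <- lapply(rows, `[[`, "modes")
  attr(out, "truth") <- vapply(rows, `[[`, 0L, "truth")
  out
}

#' @rdname synthetic_odorants
#' @export
default_templates <- function() {
  # Evenly staggered lattice: within-class mode spacing 600 cm^-1,
  # class-to-class offset 150 cm^-1, so every pair of classes has the
  # same minimum inter-template mode gap (150 cm^-1, 2.5x the default
  # PD-EVA broadening sigma of 60).  Classes are then equally distinct
  # under the Hodgkin similarity, which is what makes the preset
  # recoverable by the eigengap criterion.
  lapply(0:3, function(k) seq(200, 3200, by = 600) + 150 * k)
}

min_template_gap <- function(templates) {
  K <- length(templates)
  g <- Inf
  for (a in seq_len(K - 1)) {
    for (b in (a + 1):K) {
      g <- min(g, min(abs(outer(templates[[a]], templates[[b]], `-`))))
    }
  }
  g
}
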