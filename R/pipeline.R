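#' Classify odorants into physical (vibrational) classes
#'
#' The end-to-end pipeline: dominant vibrational modes per molecule are
#' broadened into PD-EVA pseudo-spectra (unit-area Gaussians, default
#' `sigma = 60` cm^-1), all pairs are compared with the Hodgkin
#' similarity index, and the molecules are spectrally clustered on the
#' similarity matrix.  With `m = "auto"` the cluster count is chosen by
#' the eigengap heuristic over `m_range` (mean silhouette reported as a
#' secondary diagnostic).  The result records, for each perceptual
#' (odour) class in the input, how its members distribute over the
#' physical clusters, exposing any perceptual class that the vibrational
#' clustering splits into subclasses.
#'
#' @param records data frame as returned by [load_odorants()] or
#'   [synthetic_odorants()]: columns `molecule`, `perceptual_class` and
#'   list-column `modes`.
#' @param sigma PD-EVA broadening, cm^-1.
#' @param grid a [wavenumber_grid()].
#' @param m cluster count, or `"auto"` for eigengap selection.
#' @param m_range candidate range scanned when `m = "auto"`.
#' @param seed k-means seed.
#' @param variant Laplacian embedding variant, see [spectral_cluster()].
#' @return An object of class `odor_classification`: list with
#'   `records`, `spectra`, `similarity`, `clustering`
#'   (a [spectral_cluster()] result), `m`, `m_diagnostics`, `splits`
#'   (per-perceptual-class cluster occupancy), `n_split_classes`, and
#'   the pipeline `params`.
#' @examples
#' \donttest{
#' fit <- classify_odorants(load_odorants())
#' fit
#' summary(fit)
#' }
#' @export
classify_odorants <- function(records = load_odorants(), sigma = 60,
                              grid = wavenumber_grid(), m = "auto",
                              m_range = c(2, 12), seed = 0,
                              variant = c("symmetric", "random-walk")) {
  variant <- match.arg(variant)
  stopifnot(is.data.frame(records), "modes" %in% names(records))
  truncated <- character()
  spectra <- lapply(seq_len(nrow(records)), function(r) {
    withCallingHandlers(
      pd_eva(records$modes[[r]], sigma = sigma, grid = grid,
             molecule = records$molecule[r]),
      warning = function(w) {
        if (grepl("kernel mass will be truncated", conditionMessage(w))) {
          truncated <<- c(truncated, records$molecule[r])
          invokeRestart("muffleWarning")
        }
      })
  })
  if (length(truncated)) {
    warning("kernel tails truncated at the grid edge for: ",
            paste(truncated, collapse = ", "))
  }
  S <- similarity_matrix(spectra)
  m_diag <- NULL
  if (identical(m, "auto")) {
    m_sel <- choose_m(S, m_range = m_range, seed = seed, variant = variant)
    m_diag <- attr(m_sel, "diagnostics")
    m <- as.integer(m_sel)
  }
  cl <- spectral_cluster(S, m, seed = seed, variant = variant)
  splits <- split(cl$assignment, records$perceptual_class)
  split_tab <- data.frame(
    perceptual_class = names(splits),
    n_molecules = vapply(splits, length, 0L),
    n_clusters = vapply(splits, function(z) length(unique(z)), 0L),
    clusters = vapply(splits, function(z)
      paste(sort(unique(z)), collapse = ","), ""),
    row.names = NULL)
  structure(list(
    records = records, spectra = spectra, similarity = S,
    clustering = cl, m = m, m_diagnostics = m_diag, splits = split_tab,
    n_split_classes = sum(split_tab$n_clusters > 1L),
    params = list(sigma = sigma, grid = grid, m_range = m_range,
                  seed = seed, variant = variant)),
    class = "odor_classification")
}

#' @export
print.odor_classification <- function(x, ...) {
  cat(sprintf(
    "Odorant classification: %d molecules -> %d physical classes\n",
    nrow(x$records), x$m))
  cat(sprintf("  (PD-EVA sigma = %g cm^-1, %s Laplacian, seed %d%s)\n",
              x$params$sigma, x$params$variant, x$params$seed,
              if (!is.null(x$m_diagnostics)) ", m by eigengap" else ""))
  print(x$clustering)
  cat(sprintf("Perceptual classes split across clusters: %d\n",
              x$n_split_classes))
  invisible(x)
}

#' @export
summary.odor_classification <- function(object, ...) {
  print(object)
  cat("\nPer-perceptual-class cluster occupancy:\n")
  print(object$splits, row.names = FALSE)
  if (!is.null(object$m_diagnostics)) {
    cat("\nCluster-count diagnostics (eigengap primary):\n")
    print(object$m_diagnostics, row.names = FALSE, digits = 4)
  }
  invisible(object)
}

#' @export
plot.odor_classification <- function(x, ...) {
  ord <- order(x$clustering$assignment)
  S <- unclass(x$similarity)[ord, ord]
  n <- nrow(S)
  graphics::image(seq_len(n), seq_len(n), t(S[n:1, ]),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "",
                  main = "PD-EVA similarity, ordered by cluster", ...)
  graphics::axis(1, seq_len(n), colnames(S), las = 2, cex.axis = 0.6)
  graphics::axis(2, seq_len(n), rev(rownames(S)), las = 2, cex.axis = 0.6)
  invisible(x)
}

#' Write a classification report
#'
#' Emits a TSV of memberships (`molecule`, `perceptual_class`,
#' `physical_cluster`), the similarity matrix as labelled CSV (heatmap
#' data), and a JSON summary (`m`, Laplacian eigenvalues, selection
#' diagnostics, split report, parameters).
#'
#' @param x an `odor_classification`.
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_classification <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(molecule = x$records$molecule,
               perceptual_class = x$records$perceptual_class,
               physical_cluster = x$clustering$assignment),
    file.path(dir, "memberships.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  write_similarity(x$similarity, file.path(dir, "similarity.csv"))
  jsonlite::write_json(list(
    m = x$m,
    n_split_classes = x$n_split_classes,
    splits = x$splits,
    laplacian_eigenvalues = x$clustering$laplacian_eigenvalues,
    m_diagnostics = x$m_diagnostics,
    params = list(sigma = x$params$sigma,
                  grid = x$params$grid[c("min", "max", "step")],
                  m_range = x$params$m_range, seed = x$params$seed,
                  variant = x$params$variant)),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
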