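#' Discrete vibrational spectrum
#'
#' A molecule's list of vibrational mode wavenumbers (cm^-1).
#'
#' @param molecule molecule name.
#' @param wavenumbers numeric, finite and >= 0; stored sorted ascending.
#' @param source one of `"dft_import"`, `"graph_model"`, `"reference"`,
#'   `"synthetic"`.
#' @param n_atoms optional atom count; when supplied for a whole
#'   (nonlinear) molecule, the mode count is checked against `3A - 6`.
#' @return An object of class `discrete_spectrum` (numeric vector with
#'   `molecule` and `source` attributes).
#' @export
discrete_spectrum <- function(molecule, wavenumbers,
                              source = c("dft_import", "graph_model",
                                         "reference", "synthetic"),
                              n_atoms = NULL) {
  source <- match.arg(source)
  wavenumbers <- as.numeric(wavenumbers)
  if (any(!is.finite(wavenumbers)) || any(wavenumbers < 0)) {
    stop("wavenumbers must be finite and >= 0")
  }
  if (!is.null(n_atoms) && length(wavenumbers) != 3L * n_atoms - 6L) {
    stop("expected 3A - 6 = ", 3L * n_atoms - 6L, " modes for A = ",
         n_atoms, " atoms, got ", length(wavenumbers))
  }
  structure(sort(wavenumbers), molecule = molecule, source = source,
            class = "discrete_spectrum")
}

#' @export
print.discrete_spectrum <- function(x, ...) {
  cat("Discrete spectrum:", attr(x, "molecule"),
      sprintf("(%d modes, source %s)\n", length(x), attr(x, "source")))
  print(as.numeric(x))
  invisible(x)
}

#' Wavenumber evaluation grid
#'
#' The abscissa on which pseudo-spectra are evaluated.  The default
#' (0 to 4000 cm^-1, 1 cm^-1 step) spans the full mid-infrared range of
#' molecular fundamentals with headroom for Gaussian tails.
#'
#' @param min,max grid bounds in cm^-1, `min < max`.
#' @param step grid spacing in cm^-1, > 0.
#' @return An object of class `wavenumber_grid`.
#' @export
wavenumber_grid <- function(min = 0, max = 4000, step = 1) {
  if (!(min < max) || step <= 0) stop("need min < max and step > 0")
  structure(list(min = min, max = max, step = step),
            class = "wavenumber_grid")
}

#' @export
print.wavenumber_grid <- function(x, ...) {
  cat(sprintf("Wavenumber grid %g:%g:%g cm^-1 (%d points)\n",
              x$min, x$max, x$step, length(grid_points(x))))
  invisible(x)
}

#' Grid points of a wavenumber grid
#' @param grid a [wavenumber_grid()].
#' @return Numeric vector `min, min+step, ..., <= max`.
#' @export
grid_points <- function(grid) seq(grid$min, grid$max, by = grid$step)

same_grid <- function(a, b) {
  isTRUE(all.equal(unlist(a[c("min", "max", "step")]),
                   unlist(b[c("min", "max", "step")]))
  )
}

# Shared kernel-sum core for EVA and PD-EVA.
kernel_sum <- function(centers, sigma, grid, molecule, kind) {
  if (length(centers) < 1L) stop("empty spectrum: no modes to broaden")
  if (sigma <= 0) stop("sigma must be > 0")
  x <- grid_points(grid)
  lo <- min(centers) - 4 * sigma
  hi <- max(centers) + 4 * sigma
  if (grid$min > lo || grid$max < hi) {
    warning(sprintf(
      "grid [%g, %g] does not cover [%g, %g] (modes +/- 4 sigma); kernel mass will be truncated",
      grid$min, grid$max, lo, hi))
  }
  v <- numeric(length(x))
  for (ct in centers) v <- v + stats::dnorm(x, mean = ct, sd = sigma)
  structure(list(molecule = molecule, grid = grid, values = v,
                 sigma = sigma, kind = kind, n_modes = length(centers)),
            class = "pseudospectrum")
}

#' EVA pseudo-spectrum
#'
#' Places a unit-area Gaussian kernel of standard deviation `sigma` on
#' each discrete vibrational wavenumber and sums them on the grid:
#' `EVA(x) = sum_i dnorm(x, lambda_i, sigma)`.  All stems have equal
#' magnitude (unit kernel area); no intensity weighting is applied.
#' The default `sigma = 100` cm^-1 corresponds to room-temperature
#' broadening of inelastic-tunneling peaks ("300 K EVA").
#'
#' @param x a [discrete_spectrum()] or a numeric vector of wavenumbers.
#' @param sigma Gaussian standard deviation in cm^-1.
#' @param grid a [wavenumber_grid()].
#' @param molecule molecule name (taken from `x` when available).
#' @return An object of class `pseudospectrum` with `kind = "eva"`.
#' @export
eva <- function(x, sigma = 100, grid = wavenumber_grid(),
                molecule = NULL) {
  if (is.null(molecule)) {
    molecule <- attr(x, "molecule")
    if (is.null(molecule)) molecule <- "molecule"
  }
  kernel_sum(as.numeric(x), sigma, grid, molecule, "eva")
}

#' PD-EVA pseudo-spectrum
#'
#' Applies the same unit-area Gaussian kernel sum as [eva()], but to the
#' centers of the broad peaks obtained by peak decomposition, with a
#' smaller default broadening (`sigma = 60` cm^-1) for finer resolution.
#' Fitted amplitudes and widths are deliberately discarded: the
#' peak-decomposed stems all have equal magnitude.
#'
#' @param x a `peak_fit` (its peak centers are used), a
#'   [discrete_spectrum()], or a numeric vector of peak centers.
#' @inheritParams eva
#' @return An object of class `pseudospectrum` with `kind = "pd_eva"`.
#' @export
pd_eva <- function(x, sigma = 60, grid = wavenumber_grid(),
                   molecule = NULL) {
  if (inherits(x, "peak_fit")) {
    if (is.null(molecule)) molecule <- x$molecule
    x <- x$peaks$center
  }
  if (is.null(molecule)) {
    molecule <- attr(x, "molecule")
    if (is.null(molecule)) molecule <- "molecule"
  }
  kernel_sum(as.numeric(x), sigma, grid, molecule, "pd_eva")
}

#' @export
print.pseudospectrum <- function(x, ...) {
  cat(sprintf("%s pseudo-spectrum: %s (%d modes, sigma = %g cm^-1)\n",
              toupper(gsub("_", "-", x$kind)), x$molecule, x$n_modes,
              x$sigma))
  cat(sprintf("  grid %g:%g:%g; kernel mass on grid = %.4f of %d\n",
              x$grid$min, x$grid$max, x$grid$step,
              x$grid$step * sum(x$values), x$n_modes))
  invisible(x)
}

#' @export
plot.pseudospectrum <- function(x, ...) {
  graphics::plot(grid_points(x$grid), x$values, type = "l",
                 xlab = expression(paste("wavenumber (", cm^-1, ")")),
                 ylab = "intensity",
                 main = sprintf("%s: %s", toupper(gsub("_", "-", x$kind)),
                                x$molecule), ...)
  invisible(x)
}

#' Write / read a pseudo-spectrum
#'
#' Two-column CSV (`wavenumber_cm1`, `intensity`) plus a JSON sidecar
#' (`<path>.json`) recording molecule, sigma, kind and grid.
#'
#' @param x a `pseudospectrum`.
#' @param path CSV output path.
#' @return `write_pseudospectrum` returns `path` invisibly;
#'   `read_pseudospectrum` returns a `pseudospectrum`.
#' @export
write_pseudospectrum <- function(x, path) {
  utils::write.csv(data.frame(wavenumber_cm1 = grid_points(x$grid),
                              intensity = x$values),
                   path, row.names = FALSE)
  jsonlite::write_json(list(molecule = x$molecule, sigma = x$sigma,
                            kind = x$kind,
                            grid = x$grid[c("min", "max", "step")]),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pseudospectrum
#' @export
read_pseudospectrum <- function(path) {
  d <- utils::read.csv(path)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  g <- wavenumber_grid(meta$grid$min, meta$grid$max, meta$grid$step)
  structure(list(molecule = meta$molecule, grid = g,
                 values = d$intensity, sigma = meta$sigma,
                 kind = meta$kind, n_modes = NA_integer_),
            class = "pseudospectrum")
}

#' Read discrete spectra from CSV
#'
#' Two dialects are accepted.  Long format: columns `molecule`,
#' `wavenumber_cm1`, one row per mode.  Wide format: columns `molecule`,
#' optionally `class`, and `wavenumbers` holding semicolon-separated
#' values (`"633;816;1011"`).
#'
#' @param path CSV file.
#' @param source stored in each spectrum's `source` attribute.
#' @return Named list of [discrete_spectrum()] objects.
#' @export
read_spectra <- function(path, source = "dft_import") {
  d <- utils::read.csv(path, check.names = FALSE)
  if ("wavenumbers" %in% names(d)) {
    out <- lapply(seq_len(nrow(d)), function(r) {
      wn <- as.numeric(strsplit(as.character(d$wavenumbers[r]), ";")[[1]])
      discrete_spectrum(d$molecule[r], wn, source = source)
    })
    names(out) <- d$molecule
  } else if ("wavenumber_cm1" %in% names(d)) {
    sp <- split(d$wavenumber_cm1, d$molecule)
    out <- lapply(names(sp), function(m)
      discrete_spectrum(m, sp[[m]], source = source))
    names(out) <- names(sp)
  } else {
    stop("unrecognized spectrum CSV: need `wavenumbers` or `wavenumber_cm1`")
  }
  out
}

#' Write discrete spectra as two-column CSV
#'
#' @param x a [discrete_spectrum()].
#' @param path output path.
#' @return `path`, invisibly. Columns: `mode_index`, `wavenumber_cm1`.
#' @export
write_spectrum <- function(x, path) {
  utils::write.csv(data.frame(mode_index = seq_along(x),
                              wavenumber_cm1 = as.numeric(x)),
                   path, row.names = FALSE)
  invisible(path)
}
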