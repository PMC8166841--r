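#' Default vibrational mode-type bands
#'
#' Frequency intervals (half-open, `[lo, hi)`) associating broad spectral
#' peaks with vibrational motion classes: low-frequency torsion (A, B),
#' ring torsion / C-H rocking (C, D), ring deformation / C-H wagging /
#' C-C stretch (E, F), C=C stretch (G), C=O stretch (H), S-H stretch (I)
#' and C-H stretch (J).  The numeric boundaries are a convention of this
#' package (band names carry the physics; precise cut points are not
#' standardized) and are fully user-overridable via [read_bands()].
#'
#' @return Data frame with columns `label`, `lo`, `hi`, `description`.
#' @export
mode_bands <- function() {
  data.frame(
    label = c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J"),
    lo = c(0, 200, 350, 650, 950, 1200, 1600, 1750, 1900, 2800),
    hi = c(200, 350, 650, 950, 1200, 1600, 1750, 1900, 2800, 4000),
    description = c(
      "Low-frequency torsional modes", "Low-frequency torsional modes",
      "Ring torsion and C-H rocking", "Ring torsion and C-H rocking",
      "Ring deformation, C-H wagging, C-C stretch",
      "Ring deformation, C-H wagging, C-C stretch",
      "C=C stretch", "C=O stretch", "S-H stretch", "C-H stretch"),
    stringsAsFactors = FALSE)
}

validate_bands <- function(bands) {
  stopifnot(all(c("label", "lo", "hi") %in% names(bands)))
  if (anyDuplicated(bands$label)) stop("duplicate band labels")
  o <- order(bands$lo)
  bands <- bands[o, , drop = FALSE]
  if (any(bands$hi <= bands$lo)) stop("band with hi <= lo")
  if (nrow(bands) > 1 &&
      any(abs(bands$lo[-1] - bands$hi[-nrow(bands)]) > 1e-9)) {
    stop("bands must be contiguous")
  }
  bands
}

#' Read a mode-type band table from YAML or JSON
#'
#' The file holds a list of records with fields `label`, `lo`, `hi` and
#' optionally `description`; see [mode_bands()] for the shipped default.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return Data frame in [mode_bands()] layout.
#' @export
read_bands <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (!is.data.frame(x)) {
    x <- if (all(c("label", "lo", "hi") %in% names(x))) {
      as.data.frame(x)                         # column-wise layout
    } else {
      do.call(rbind, lapply(x, as.data.frame)) # list of records
    }
  }
  validate_bands(x)
}

# Gaussian mixture model curve: peaks parameterized as (center, width,
# amplitude) with amplitude = height of the component.
gaussian_mix <- function(x, center, width, amplitude) {
  v <- numeric(length(x))
  for (p in seq_along(center)) {
    v <- v + amplitude[p] * exp(-(x - center[p])^2 / (2 * width[p]^2))
  }
  v
}

# Deterministic seeding: centers at local maxima of a lightly smoothed
# curve, strongest first.
seed_centers <- function(x, y, k, smooth_pts = 5L) {
  ys <- stats::filter(y, rep(1 / smooth_pts, smooth_pts), sides = 2)
  ys[is.na(ys)] <- y[is.na(ys)]
  n <- length(ys)
  is_max <- c(FALSE, ys[2:(n - 1)] > ys[1:(n - 2)] &
                     ys[2:(n - 1)] >= ys[3:n], FALSE)
  is_max <- is_max & ys > 0.01 * max(ys)
  cand <- x[is_max][order(ys[is_max], decreasing = TRUE)]
  if (length(cand) >= k) return(sort(cand[1:k]))
  # fewer maxima than components: add centers at intensity-mass quantiles
  extra <- stats::approx(cumsum(y) / sum(y), x,
                         xout = (seq_len(k) - 0.5) / k, ties = "ordered")$y
  sort(c(cand, setdiff(round(extra), round(cand)))[1:k])
}

#' Fit a fixed-count Gaussian sum to a pseudo-spectrum
#'
#' Bounded Levenberg-Marquardt least squares of a `k`-component Gaussian
#' sum against the curve.  Initialization is deterministic: centers are
#' seeded at local maxima of the lightly smoothed curve (strongest
#' first), amplitudes at the curve height there, widths at 1.5 times
#' `sigma0`.
#'
#' @param pseudo a `pseudospectrum`.
#' @param k number of Gaussian components.
#' @param width_bounds allowed component sigma range, cm^-1.
#' @param sigma0 initial width scale; defaults to the spectrum's
#'   broadening sigma.
#' @param init optional data frame (`center`, `width`, `amplitude`,
#'   `k` rows) overriding the default seeding.
#' @return An object of class `peak_fit`; see [peak_decompose()].
#' @export
fit_gaussians <- function(pseudo, k, width_bounds = c(30, 400),
                          sigma0 = pseudo$sigma, init = NULL) {
  x <- grid_points(pseudo$grid)
  y <- pseudo$values
  if (max(y) <= 0) stop("pseudo-spectrum has no positive values")
  w0 <- min(max(1.5 * sigma0, width_bounds[1]), width_bounds[2])
  if (is.null(init)) {
    ctr <- seed_centers(x, y, k)
    hgt <- stats::approx(x, y, xout = ctr)$y
    par0 <- c(ctr, rep(w0, k), pmax(hgt, 1e-8))
  } else {
    stopifnot(nrow(init) == k)
    par0 <- c(init$center,
              pmin(pmax(init$width, width_bounds[1]), width_bounds[2]),
              pmax(init$amplitude, 1e-10))
  }
  lower <- c(rep(pseudo$grid$min, k), rep(width_bounds[1], k), rep(1e-10, k))
  upper <- c(rep(pseudo$grid$max, k), rep(width_bounds[2], k),
             rep(2 * max(y), k))
  res_fn <- function(p) {
    gaussian_mix(x, p[1:k], p[(k + 1):(2 * k)], p[(2 * k + 1):(3 * k)]) - y
  }
  fit <- minpack.lm::nls.lm(par0, lower, upper, res_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200))
  p <- fit$par
  peaks <- data.frame(center = p[1:k], width = p[(k + 1):(2 * k)],
                      amplitude = p[(2 * k + 1):(3 * k)],
                      mode_type = NA_character_)
  peaks <- peaks[order(peaks$center), , drop = FALSE]
  rownames(peaks) <- NULL
  fitted_v <- gaussian_mix(x, peaks$center, peaks$width, peaks$amplitude)
  rms <- sqrt(mean((fitted_v - y)^2))
  structure(list(molecule = pseudo$molecule, peaks = peaks, k = k,
                 grid = pseudo$grid, observed = y, fitted = fitted_v,
                 fit_residual = rms, rel_residual = rms / max(y),
                 trace = data.frame(k = k, rel_residual = rms / max(y))),
            class = "peak_fit")
}

#' Decompose a pseudo-spectrum into a few broad Gaussian peaks
#'
#' Selects the smallest component count `k <= max_components` whose
#' bounded Gaussian-sum least-squares fit ([fit_gaussians()]) achieves a
#' relative RMS residual (RMS of model minus data, over the curve
#' maximum) at or below `residual_tol`.  Ties break toward fewer peaks
#' by construction, mirroring the goal of "a few broad peaks" — far
#' fewer than the discrete modes that built the curve.
#'
#' Each count is fitted twice, deterministically: once seeded fresh at
#' local maxima and once by augmenting the previous best fit with a
#' component at its largest positive residual (which resolves pairs of
#' modes merged into a single bump); the better fit is kept.
#'
#' @param pseudo a `pseudospectrum` with at least one positive value.
#' @param max_components largest component count to try.
#' @param residual_tol acceptable relative RMS residual.
#' @param width_bounds allowed component sigma range, cm^-1.
#' @param bands optional [mode_bands()] table; when supplied the
#'   accepted peaks are labelled via [assign_mode_types()].
#' @return An object of class `peak_fit`: list with `molecule`, `peaks`
#'   (data frame `center`, `width`, `amplitude`, `mode_type`, sorted by
#'   center), `fit_residual` (RMS), `rel_residual`, `trace` (residual per
#'   tried count), `observed`, `fitted`, `grid`.
#' @seealso [fit_gaussians()] for a fixed component count.
#' @export
peak_decompose <- function(pseudo, max_components = 8L,
                           residual_tol = 0.02, width_bounds = c(30, 400),
                           bands = NULL) {
  stopifnot(inherits(pseudo, "pseudospectrum"))
  trace <- data.frame(k = integer(), rel_residual = numeric())
  best <- NULL
  prev <- NULL
  x <- grid_points(pseudo$grid)
  w0 <- min(max(1.5 * pseudo$sigma, width_bounds[1]), width_bounds[2])
  for (k in seq_len(max_components)) {
    fit <- fit_gaussians(pseudo, k, width_bounds)
    if (!is.null(prev)) {
      res <- pseudo$values - prev$fitted
      aug <- rbind(prev$peaks[c("center", "width", "amplitude")],
                   data.frame(center = x[which.max(res)], width = w0,
                              amplitude = max(max(res), 1e-10)))
      fit2 <- fit_gaussians(pseudo, k, width_bounds, init = aug)
      if (fit2$rel_residual < fit$rel_residual) fit <- fit2
    }
    prev <- fit
    trace <- rbind(trace, data.frame(k = k, rel_residual = fit$rel_residual))
    if (is.null(best) || fit$rel_residual < best$rel_residual) best <- fit
    if (fit$rel_residual <= residual_tol) {
      fit$trace <- trace
      if (!is.null(bands)) fit <- assign_mode_types(fit, bands)
      return(fit)
    }
  }
  stop(sprintf(paste0("no Gaussian-sum fit with <= %d components reached ",
                      "relative residual %g (best: %.4g with k = %d)"),
               max_components, residual_tol, best$rel_residual, best$k))
}

#' Label fitted peaks with vibrational mode types
#'
#' Each peak is assigned the unique band whose half-open interval
#' `[lo, hi)` contains its center; a center exactly at a boundary `lo`
#' belongs to that band.  Peak order is preserved.  Idempotent.
#'
#' @param fit a `peak_fit`, or a data frame with a `center` column.
#' @param bands a band table as from [mode_bands()].
#' @return The input with `mode_type` filled in.
#' @export
assign_mode_types <- function(fit, bands = mode_bands()) {
  bands <- validate_bands(bands)
  peaks <- if (inherits(fit, "peak_fit")) fit$peaks else fit
  idx <- findInterval(peaks$center, bands$lo)
  outside <- idx < 1 | peaks$center >= bands$hi[pmax(idx, 1)]
  if (any(outside)) {
    stop("peak center(s) outside band coverage: ",
         paste(signif(peaks$center[outside], 6), collapse = ", "))
  }
  peaks$mode_type <- bands$label[idx]
  if (inherits(fit, "peak_fit")) {
    fit$peaks <- peaks
    fit
  } else {
    peaks
  }
}

#' @export
print.peak_fit <- function(x, ...) {
  cat(sprintf("Peak decomposition: %s (%d components, rel. residual %.4f)\n",
              x$molecule, x$k, x$rel_residual))
  print(x$peaks, digits = 5)
  invisible(x)
}

#' @export
summary.peak_fit <- function(object, ...) {
  print(object)
  cat("\nResidual trace over tried component counts:\n")
  print(object$trace, digits = 4)
  invisible(object)
}

#' @export
coef.peak_fit <- function(object, ...) {
  as.matrix(object$peaks[c("center", "width", "amplitude")])
}

#' @export
fitted.peak_fit <- function(object, ...) object$fitted

#' @export
residuals.peak_fit <- function(object, ...) object$fitted - object$observed

#' @export
predict.peak_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) grid_points(object$grid) else as.numeric(newdata)
  gaussian_mix(x, object$peaks$center, object$peaks$width,
               object$peaks$amplitude)
}

#' @export
plot.peak_fit <- function(x, ...) {
  xs <- grid_points(x$grid)
  graphics::plot(xs, x$observed, type = "l", col = "grey40",
                 xlab = expression(paste("wavenumber (", cm^-1, ")")),
                 ylab = "intensity",
                 main = sprintf("Peak decomposition: %s", x$molecule), ...)
  for (p in seq_len(nrow(x$peaks))) {
    graphics::lines(xs, gaussian_mix(xs, x$peaks$center[p], x$peaks$width[p],
                                     x$peaks$amplitude[p]),
                    col = "steelblue", lty = 2)
  }
  graphics::lines(xs, x$fitted, col = "firebrick")
  invisible(x)
}

#' Write fitted peaks as CSV
#'
#' @param fit a `peak_fit`.
#' @param path output path. Columns: `molecule`, `center`, `width`,
#'   `amplitude`, `mode_type`.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(fit, path) {
  utils::write.csv(cbind(molecule = fit$molecule, fit$peaks),
                   path, row.names = FALSE)
  invisible(path)
}
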