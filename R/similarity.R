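#' Hodgkin similarity index between two pseudo-spectra
#'
#' The overlap ratio `S = 2 * sum(a * b) / (sum(a^2) + sum(b^2))`, with
#' sums over grid points.  For nonnegative spectra `S` lies in `[0, 1]`
#' and equals 1 exactly when the two curves coincide pointwise
#' (Cauchy-Schwarz plus the arithmetic-geometric mean inequality).  The
#' ratio is invariant to the grid step (both sums scale identically), so
#' grid-point sums and continuum integrals agree in the limit.
#'
#' Both spectra must live on the identical grid and be of the same kind;
#' no silent resampling is performed.
#'
#' @param a,b `pseudospectrum` objects on the same [wavenumber_grid()].
#' @return A number in `[0, 1]`.
#' @export
similarity_index <- function(a, b) {
  stopifnot(inherits(a, "pseudospectrum"), inherits(b, "pseudospectrum"))
  if (!same_grid(a$grid, b$grid)) {
    stop("spectra are on different grids; resample explicitly first")
  }
  if (!identical(a$kind, b$kind)) {
    stop("spectra are of different kinds (", a$kind, " vs ", b$kind, ")")
  }
  if (sum(a$values) <= 0 || sum(b$values) <= 0) {
    stop("all-zero spectrum has no defined similarity")
  }
  2 * sum(a$values * b$values) / (sum(a$values^2) + sum(b$values^2))
}

#' Pairwise similarity matrix
#'
#' Assembles the n x n matrix of pairwise Hodgkin similarity indices.
#' Only the upper triangle is computed; symmetry and a unit diagonal are
#' exact by construction.
#'
#' @param spectra list of `pseudospectrum` objects on one grid, with
#'   unique molecule names.
#' @return A symmetric matrix of class `similarity_matrix` with molecule
#'   names as dimnames, unit diagonal, entries in `[0, 1]`.
#' @export
similarity_matrix <- function(spectra) {
  n <- length(spectra)
  if (n < 2L) stop("need at least 2 spectra")
  labels <- unname(vapply(spectra, function(s) s$molecule, ""))
  if (anyDuplicated(labels)) {
    stop("duplicate molecule labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  S <- diag(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      S[i, j] <- S[j, i] <- similarity_index(spectra[[i]], spectra[[j]])
    }
  }
  dimnames(S) <- list(labels, labels)
  structure(S, class = c("similarity_matrix", "matrix", "array"))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("Similarity matrix,", nrow(x), "molecules\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Write / read a similarity matrix as labelled CSV
#'
#' Header row and first column hold molecule names; round-trips through
#' [read_similarity()].
#'
#' @param x a `similarity_matrix`.
#' @param path CSV path.
#' @return `write_similarity` returns `path` invisibly;
#'   `read_similarity` returns a `similarity_matrix`.
#' @export
write_similarity <- function(x, path) {
  utils::write.csv(as.data.frame(unclass(x)), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_similarity
#' @export
read_similarity <- function(path) {
  d <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  S <- as.matrix(d)
  if (nrow(S) != ncol(S)) stop("similarity CSV is not square")
  dimnames(S) <- list(rownames(d), colnames(d))
  structure(S, class = c("similarity_matrix", "matrix", "array"))
}
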