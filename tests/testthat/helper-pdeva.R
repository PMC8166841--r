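# Shared fixtures, all built in code.

AMU <- 1.66053906660e-27   # kg; independent copy for unit-conversion oracles
CCM <- 2.99792458e10       # cm/s

# Random connected-ish molecular graph: a random spanning tree plus a few
# extra edges, random masses and stiffnesses.
random_graph <- function(n, extra = 2L) {
  bonds <- data.frame(i = 2:n, j = vapply(2:n, function(v)
    sample.int(v - 1L, 1L), 1L), stiffness = runif(n - 1, 100, 2000))
  for (e in seq_len(extra)) {
    ij <- sort(sample.int(n, 2))
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (!(paste(ij[1], ij[2]) %in% key)) {
      bonds <- rbind(bonds, data.frame(i = ij[1], j = ij[2],
                                       stiffness = runif(1, 100, 2000)))
    }
  }
  molecular_graph(runif(n, 1, 40), bonds, name = "random")
}

# Union of several disjoint random graphs (disconnected overall).
random_forest_graph <- function(sizes) {
  atoms <- numeric(0); bonds <- NULL; off <- 0L
  for (n in sizes) {
    g <- random_graph(n, extra = 0L)
    atoms <- c(atoms, g$atoms$mass)
    b <- g$bonds; b$i <- b$i + off; b$j <- b$j + off
    bonds <- rbind(bonds, b)
    off <- off + n
  }
  molecular_graph(atoms, bonds, name = "forest")
}

# A pseudospectrum with arbitrary values (bypasses the kernel sum); used
# to feed synthetic Gaussian mixtures to the peak fitter.
manual_pseudospectrum <- function(values, grid = wavenumber_grid(),
                                  sigma = 100, kind = "eva",
                                  molecule = "synthetic") {
  structure(list(molecule = molecule, grid = grid, values = values,
                 sigma = sigma, kind = kind, n_modes = NA_integer_),
            class = "pseudospectrum")
}

gauss_curve <- function(x, centers, amps, sigmas) {
  v <- numeric(length(x))
  for (p in seq_along(centers)) {
    v <- v + amps[p] * exp(-(x - centers[p])^2 / (2 * sigmas[p]^2))
  }
  v
}

# Block similarity matrix with planted clusters.
block_similarity <- function(sizes, within = 1, between = 0.05) {
  n <- sum(sizes)
  S <- matrix(between, n, n)
  off <- 0L
  for (s in sizes) {
    S[(off + 1):(off + s), (off + 1):(off + s)] <- within
    off <- off + s
  }
  diag(S) <- 1
  dimnames(S) <- list(paste0("mol", seq_len(n)), paste0("mol", seq_len(n)))
  structure(S, class = c("similarity_matrix", "matrix", "array"))
}

planted_labels <- function(sizes) rep(seq_along(sizes), sizes)

adjusted_rand <- function(a, b) {
  e1071::classAgreement(table(a, b))$crand
}
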