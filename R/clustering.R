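#' Effective adjacency matrix from a similarity matrix
#'
#' Copies the off-diagonal similarities and zeroes the diagonal, turning
#' the similarity matrix into the weighted adjacency of a complete graph
#' over the molecules.
#'
#' @param sim a [similarity_matrix()].
#' @return A symmetric weighted adjacency matrix (attribute
#'   `disconnected` flags any zero-degree vertex).
#' @export
to_adjacency <- function(sim) {
  A <- unclass(as.matrix(sim))
  if (!isTRUE(all.equal(A, t(A)))) stop("similarity matrix not symmetric")
  diag(A) <- 0
  attr(A, "disconnected") <- any(rowSums(A) == 0)
  A
}

#' Symmetric normalized graph Laplacian
#'
#' `L = I - D^(-1/2) A D^(-1/2)` with `D` the diagonal degree (row-sum)
#' matrix.  Eigenvalues lie in `[0, 2]`; the multiplicity of eigenvalue
#' 0 equals the number of connected components.
#'
#' @param adj symmetric nonnegative adjacency matrix.
#' @return A symmetric matrix.
#' @export
normalized_laplacian <- function(adj) {
  A <- unclass(as.matrix(adj))
  d <- rowSums(A)
  if (any(d == 0)) {
    iso <- rownames(A)[d == 0]
    if (is.null(iso)) iso <- which(d == 0)
    stop("isolated vertex (zero degree): ", paste(iso, collapse = ", "))
  }
  s <- 1 / sqrt(d)
  L <- diag(nrow(A)) - (s * A) %*% diag(s)   # s*A scales rows; diag(s) columns
  L <- (L + t(L)) / 2                        # kill round-off asymmetry
  dimnames(L) <- dimnames(A)
  L
}

# Spectral embedding shared by spectral_cluster() and choose_m().
# Returns eigenvalues ascending and the full eigenvector matrix in the
# same order.
laplacian_eigen <- function(sim, variant = c("symmetric", "random-walk")) {
  variant <- match.arg(variant)
  A <- to_adjacency(sim)
  L <- normalized_laplacian(A)
  e <- eigen(L, symmetric = TRUE)
  n <- nrow(L)
  ord <- n:1                                # eigen() returns descending
  list(values = e$values[ord], vectors = e$vectors[, ord, drop = FALSE],
       degrees = rowSums(A), variant = variant)
}

embed_rows <- function(eig, m) {
  V <- eig$vectors[, seq_len(m), drop = FALSE]
  if (eig$variant == "random-walk") {
    # recover random-walk eigenvectors: u_rw = D^(-1/2) u_sym
    V <- V / sqrt(eig$degrees)
  } else {
    nr <- sqrt(rowSums(V^2))
    nr[nr == 0] <- 1                         # degenerate rows left at origin
    V <- V / nr
  }
  V
}

#' Spectral clustering of molecules from a similarity matrix
#'
#' Zero-diagonal adjacency, symmetric normalized Laplacian, embedding of
#' each molecule as the row of the eigenvector matrix for the `m`
#' smallest eigenvalues (rows normalized to unit length in the default
#' `"symmetric"` variant; degree-rescaled for `"random-walk"`), then
#' k-means with `nstart` restarts.  Deterministic for a fixed `seed`.
#'
#' @param sim a [similarity_matrix()].
#' @param m number of clusters, `2 <= m <= n - 1`.
#' @param seed RNG seed for k-means restarts.
#' @param nstart number of k-means restarts (best inertia kept).
#' @param variant `"symmetric"` (default) or `"random-walk"` embedding.
#' @return An object of class `spectral_clustering`: list with `labels`
#'   (molecule names), `assignment` (cluster id 1..m per molecule), `m`,
#'   `laplacian_eigenvalues` (ascending), `seed`, `variant`.
#' @export
spectral_cluster <- function(sim, m, seed = 0, nstart = 50,
                             variant = c("symmetric", "random-walk")) {
  n <- nrow(sim)
  if (!(m >= 2 && m <= n - 1)) stop("need 2 <= m <= n - 1 (n = ", n, ")")
  offd <- sim[upper.tri(sim)]
  if (diff(range(offd)) < 1e-12) {
    warning("all pairwise similarities are equal; the cluster assignment ",
            "is arbitrary (ties broken by input order)")
  }
  eig <- laplacian_eigen(sim, variant)
  V <- embed_rows(eig, m)
  if (nrow(unique(round(V, 12))) < m) {
    warning("embedding has fewer than m distinct rows; ",
            "ties broken by input order")
    V <- V + outer(seq_len(n) * 1e-9, rep(1, m))
  }
  # Hartigan-Wong stalls on exactly coincident points; Lloyd does not.
  # Individual restarts may draw coincident initial centers ("empty
  # cluster"); those restarts are simply discarded by kmeans, so the
  # per-restart warnings carry no information.
  algo <- if (anyDuplicated(round(V, 12))) "Lloyd" else "Hartigan-Wong"
  quiet_kmeans <- function(...) withCallingHandlers(
    stats::kmeans(...),
    warning = function(w) {
      if (grepl("empty cluster", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  set.seed(seed)
  km <- tryCatch(
    quiet_kmeans(V, centers = m, nstart = nstart, iter.max = 100,
                 algorithm = algo),
    error = function(e) {
      set.seed(seed)
      quiet_kmeans(V, centers = m, nstart = nstart, iter.max = 100,
                   algorithm = "Lloyd")
    })
  structure(list(labels = rownames(sim), assignment = unname(km$cluster),
                 m = m, laplacian_eigenvalues = eig$values, seed = seed,
                 variant = eig$variant, inertia = km$tot.withinss),
            class = "spectral_clustering")
}

#' @export
print.spectral_clustering <- function(x, ...) {
  cat(sprintf("Spectral clustering: %d molecules in %d clusters (%s, seed %d)\n",
              length(x$assignment), x$m, x$variant, x$seed))
  for (g in seq_len(x$m)) {
    cat(sprintf("  [%d] %s\n", g,
                paste(x$labels[x$assignment == g], collapse = ", ")))
  }
  invisible(x)
}

#' Choose the cluster count by the eigengap heuristic
#'
#' Scans `m` in `m_range` and returns the `m` maximizing the eigengap
#' `lambda[m+1] - lambda[m]` of the symmetric normalized Laplacian
#' (eigenvalues ascending); ties break toward smaller `m`.  The mean
#' silhouette width of the `m`-cluster solution, computed against the
#' dissimilarity `1 - S`, is reported alongside as a secondary
#' diagnostic — it does not influence the choice.
#'
#' @param sim a [similarity_matrix()].
#' @param m_range integer vector `c(m_min, m_max)`,
#'   `2 <= m_min <= m_max <= n - 1`.
#' @param seed k-means seed for the silhouette diagnostics.
#' @param diagnostics compute silhouettes?  Disable for speed in
#'   simulation sweeps (the eigengap needs a single eigendecomposition).
#' @param variant Laplacian embedding variant, see [spectral_cluster()].
#' @return The chosen `m` (integer) with attribute `diagnostics`, a data
#'   frame of `m`, `eigengap` and (if requested) `silhouette`.
#' @export
choose_m <- function(sim, m_range = c(2, 12), seed = 0,
                     diagnostics = TRUE,
                     variant = c("symmetric", "random-walk")) {
  n <- nrow(sim)
  m_min <- m_range[1]; m_max <- m_range[length(m_range)]
  if (!(2 <= m_min && m_min <= m_max && m_max <= n - 1)) {
    stop("need 2 <= m_min <= m_max <= n - 1")
  }
  eig <- laplacian_eigen(sim, variant)
  ms <- m_min:m_max
  gap <- eig$values[ms + 1] - eig$values[ms]
  diag_df <- data.frame(m = ms, eigengap = gap)
  if (diagnostics) {
    dd <- stats::as.dist(1 - unclass(sim))
    diag_df$silhouette <- vapply(ms, function(m) {
      cl <- spectral_cluster(sim, m, seed = seed, variant = eig$variant)
      mean(cluster::silhouette(cl$assignment, dd)[, "sil_width"])
    }, 0)
  }
  m_star <- ms[which.max(gap)]              # which.max: first max = smaller m
  structure(as.integer(m_star), diagnostics = diag_df)
}
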