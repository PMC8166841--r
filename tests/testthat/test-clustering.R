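test_that("adjacency copies off-diagonals and zeroes the diagonal", {
  S <- block_similarity(c(1, 1), within = 1, between = 1)
  expect_equal(unclass(to_adjacency(S)),
               matrix(c(0, 1, 1, 0), 2), ignore_attr = TRUE)
  A <- to_adjacency(block_similarity(c(1, 1, 1), between = 0))
  expect_true(attr(A, "disconnected"))
  S4 <- block_similarity(c(2, 2), between = 0.3)
  expect_equal(to_adjacency(S4), t(to_adjacency(S4)))
})

test_that("normalized Laplacian has the known spectral structure", {
  # two nodes, any weight: eigenvalues {0, 2}
  for (w in c(0.1, 1, 7)) {
    A <- matrix(c(0, w, w, 0), 2)
    expect_equal(sort(eigen(normalized_laplacian(A))$values), c(0, 2),
                 tolerance = 1e-12)
  }

  # k disconnected complete blocks: eigenvalue 0 with multiplicity k;
  # oracle = union of per-block eigendecompositions
  sizes <- c(3, 4, 2)
  A <- to_adjacency(block_similarity(sizes, between = 0))
  L <- normalized_laplacian(A)
  lam <- sort(eigen(L, symmetric = TRUE)$values)
  per_block <- sort(unlist(lapply(sizes, function(s) {
    Ab <- matrix(1, s, s); diag(Ab) <- 0
    eigen(normalized_laplacian(Ab), symmetric = TRUE)$values
  })))
  expect_equal(lam, per_block, tolerance = 1e-10)
  expect_equal(sum(abs(lam) < 1e-10), length(sizes))

  # eigenvalue range [0, 2] on random affinities
  set.seed(5)
  for (r in 1:10) {
    n <- sample(4:15, 1)
    A <- matrix(runif(n * n), n); A <- (A + t(A)) / 2; diag(A) <- 0
    lam <- eigen(normalized_laplacian(A), symmetric = TRUE)$values
    expect_true(all(lam >= -1e-10 & lam <= 2 + 1e-10))
  }

  A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- 1
  rownames(A) <- colnames(A) <- c("x", "y", "lonely")
  expect_error(normalized_laplacian(A), "lonely")
})

test_that("planted blocks are recovered and eigenvalues are reported", {
  S <- block_similarity(c(5, 4), within = 1, between = 0)
  cl <- spectral_cluster(S, 2, seed = 0)
  expect_equal(adjusted_rand(cl$assignment, planted_labels(c(5, 4))), 1)

  # brute force over all 2-partitions: the planted one maximizes
  # within-cluster similarity
  n <- 9
  best <- NULL; best_val <- -Inf
  for (code in 1:(2^(n - 1) - 1)) {
    part <- as.integer(intToBits(code))[1:n]
    if (length(unique(part)) < 2) next
    val <- sum(unclass(S)[outer(part, part, "==")])
    if (val > best_val) { best_val <- val; best <- part }
  }
  expect_equal(adjusted_rand(best, cl$assignment), 1)

  # reported Laplacian eigenvalues match an independent dense solve
  A <- unclass(S); diag(A) <- 0
  d <- rowSums(A)
  L <- diag(n) - diag(1 / sqrt(d)) %*% A %*% diag(1 / sqrt(d))
  expect_equal(cl$laplacian_eigenvalues,
               sort(eigen((L + t(L)) / 2, symmetric = TRUE)$values),
               tolerance = 1e-8)
  expect_lt(abs(cl$laplacian_eigenvalues[1]), 1e-10)
})

test_that("cluster labels are invariant to input permutation", {
  set.seed(9)
  S <- block_similarity(c(4, 3, 5), between = 0.1)
  base <- spectral_cluster(S, 3, seed = 1)
  for (r in 1:5) {
    p <- sample(nrow(S))
    Sp <- structure(unclass(S)[p, p],
                    class = c("similarity_matrix", "matrix", "array"))
    clp <- spectral_cluster(Sp, 3, seed = 1)
    expect_equal(adjusted_rand(clp$assignment, base$assignment[p]), 1)
  }
})

test_that("noisy planted partitions are recovered across seeds", {
  set.seed(13)
  for (r in 1:20) {
    sizes <- sample(3:8, sample(2:4, 1), replace = TRUE)
    S <- unclass(block_similarity(sizes, within = 0.9, between = 0.15))
    noise <- matrix(runif(length(S), -0.05, 0.05), nrow(S))
    S <- S + (noise + t(noise)) / 2
    diag(S) <- 1
    S <- structure(pmin(pmax(S, 0), 1),
                   class = c("similarity_matrix", "matrix", "array"))
    cl <- spectral_cluster(S, length(sizes), seed = r)
    expect_equal(adjusted_rand(cl$assignment, planted_labels(sizes)), 1)
  }
})

test_that("eigengap selection finds planted counts; ties go small", {
  expect_identical(as.integer(choose_m(block_similarity(c(5, 5),
                                                        between = 0),
                                       c(2, 8), diagnostics = FALSE)), 2L)
  m3 <- choose_m(block_similarity(c(5, 5, 5), between = 0.05), c(2, 12))
  expect_identical(as.integer(m3), 3L)
  d <- attr(m3, "diagnostics")
  expect_named(d, c("m", "eigengap", "silhouette"))
  expect_equal(d$m[which.max(d$eigengap)], 3)
  expect_equal(d$m[which.max(d$silhouette)], 3)
})

test_that("range validation and degenerate embeddings are handled", {
  S <- block_similarity(c(3, 3))
  expect_error(spectral_cluster(S, 1), "2 <= m")
  expect_error(spectral_cluster(S, 6), "2 <= m")
  expect_error(choose_m(S, c(1, 3)), "m_min")
  # identical molecules: a structureless matrix is flagged and ties are
  # broken by input order rather than erroring
  ident <- block_similarity(c(4), within = 1)
  expect_warning(cl <- spectral_cluster(ident, 2, seed = 0), "arbitrary")
  expect_length(unique(cl$assignment), 2L)
})
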