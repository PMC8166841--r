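test_that("diatomic, chain and ring spectra match closed forms", {
  # two equal masses m, stiffness k: eigenvalues {0, 2k/m}
  m <- 12; k <- 500
  g <- molecular_graph(c(m, m), data.frame(i = 1, j = 2, stiffness = k))
  lam <- eigen(unclass(dynamical_matrix(g)), symmetric = TRUE)$values
  expect_equal(sort(lam), c(0, 2 * k / (m * AMU)), tolerance = 1e-8)

  # linear 3-chain, equal m and k: {0, k/m, 3k/m}
  g3 <- molecular_graph(rep(m, 3),
                        data.frame(i = c(1, 2), j = c(2, 3), stiffness = k))
  lam3 <- sort(eigen(unclass(dynamical_matrix(g3)), symmetric = TRUE)$values)
  expect_equal(lam3, c(0, 1, 3) * k / (m * AMU), tolerance = 1e-8)

  # 6-cycle: circulant Laplacian spectrum 2 - 2cos(2 pi j / 6)
  g6 <- molecular_graph(rep(m, 6),
                        data.frame(i = 1:6, j = c(2:6, 1), stiffness = k))
  lam6 <- sort(eigen(unclass(dynamical_matrix(g6)), symmetric = TRUE)$values)
  circ <- sort(2 - 2 * cos(2 * pi * (0:5) / 6)) * k / (m * AMU)
  expect_equal(lam6, circ, tolerance = 1e-8)
  expect_equal(lam6 / (k / (m * AMU)), c(0, 1, 1, 3, 3, 4), tolerance = 1e-8)
})

test_that("wavenumber conversion matches an independent closed form", {
  g <- molecular_graph(c(12, 12), data.frame(i = 1, j = 2, stiffness = 500))
  sp <- vibrational_frequencies(g)
  # oracle: omega = sqrt(2k/m) in SI, nu = omega / (2 pi c)
  nu <- sqrt(2 * 500 / (12 * AMU)) / (2 * pi * CCM)
  expect_equal(as.numeric(sp), nu, tolerance = 1e-10)
  expect_identical(attr(sp, "n_zero_dropped"), 1L)
})

test_that("zero modes count connected components and can be dropped", {
  # two disjoint diatomics: 2 zero modes
  g <- random_forest_graph(c(2, 2))
  sp <- vibrational_frequencies(g)
  expect_identical(attr(sp, "n_zero_dropped"), 2L)
  expect_length(sp, 2L)

  # property: zero-mode count equals igraph's component count
  set.seed(7)
  for (r in 1:20) {
    sizes <- sample(2:5, sample(1:3, 1), replace = TRUE)
    g <- random_forest_graph(sizes)
    sp <- vibrational_frequencies(g)
    ig <- igraph::graph_from_edgelist(
      as.matrix(g$bonds[c("i", "j")]), directed = FALSE)
    ig <- igraph::add_vertices(ig, nrow(g$atoms) - igraph::vcount(ig))
    expect_identical(attr(sp, "n_zero_dropped"),
                     as.integer(igraph::components(ig)$no))
  }
})

test_that("dynamical matrix is symmetric PSD and scales homogeneously", {
  set.seed(11)
  for (r in 1:15) {
    g <- random_graph(sample(3:12, 1))
    D <- unclass(dynamical_matrix(g))
    expect_equal(D, t(D))
    lam <- sort(eigen(D, symmetric = TRUE)$values)
    expect_true(all(lam > -1e-9 * max(lam)))

    # multiplying all stiffnesses by c multiplies eigenvalues by c
    cc <- runif(1, 0.5, 5)
    g2 <- molecular_graph(g$atoms, transform(g$bonds,
                                             stiffness = stiffness * cc))
    lam2 <- sort(eigen(unclass(dynamical_matrix(g2)),
                       symmetric = TRUE)$values)
    expect_equal(lam2, cc * lam, tolerance = 1e-8)

    # brute-force dense Laplacian assembled independently
    n <- nrow(g$atoms)
    L <- matrix(0, n, n)
    for (b in seq_len(nrow(g$bonds))) {
      i <- g$bonds$i[b]; j <- g$bonds$j[b]; k <- g$bonds$stiffness[b]
      L[i, j] <- L[i, j] - k; L[j, i] <- L[j, i] - k
      L[i, i] <- L[i, i] + k; L[j, j] <- L[j, j] + k
    }
    expect_equal(max(abs(rowSums(L))), 0, tolerance = 1e-9)  # row sums zero
    Minv <- diag(1 / sqrt(g$atoms$mass * AMU))
    expect_equal(unclass(dynamical_matrix(g)), Minv %*% L %*% Minv,
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("mass scaling halves wavenumbers", {
  g <- random_graph(6)
  g4 <- molecular_graph(transform(g$atoms, mass = mass * 4), g$bonds)
  expect_equal(as.numeric(vibrational_frequencies(g4)),
               as.numeric(vibrational_frequencies(g)) / 2,
               tolerance = 1e-10)
})

test_that("graph validation names the offender", {
  expect_error(molecular_graph(c(-1, 2), data.frame(i = 1, j = 2,
                                                    stiffness = 1)),
               "mass")
  expect_error(molecular_graph(c(1, 2), data.frame(i = 1, j = 1,
                                                   stiffness = 1)),
               "self-bond")
  expect_error(molecular_graph(c(1, 2), data.frame(i = c(1, 2), j = c(2, 1),
                                                   stiffness = 1)),
               "duplicate")
  expect_error(molecular_graph(c(1, 2), data.frame(i = 1, j = 2,
                                                   stiffness = -5)),
               "stiffness")
  g1 <- molecular_graph(5, data.frame(i = integer(), j = integer(),
                                      stiffness = numeric()))
  expect_error(dynamical_matrix(g1), "at least 2 atoms")
})

test_that("JSON and MOL-style readers build the same toy molecule", {
  jf <- tempfile(fileext = ".json")
  writeLines('{"name":"ethene-ish","atoms":[{"label":"C1","mass":12.011},
    {"label":"C2","mass":12.011}],"bonds":[{"i":0,"j":1,"k":1000}]}', jf)
  gj <- read_graph_json(jf)
  expect_equal(nrow(gj$atoms), 2)
  expect_equal(gj$bonds$stiffness, 1000)

  mf <- tempfile(fileext = ".mol")
  writeLines(c("2 1", "C", "C", "1 2 2"), mf)
  gm <- read_mol_graph(mf)
  expect_equal(gm$atoms$mass, c(12.011, 12.011))
  expect_equal(gm$bonds$stiffness, 1000)  # double bond default
  expect_equal(as.numeric(vibrational_frequencies(gm)),
               as.numeric(vibrational_frequencies(gj)), tolerance = 1e-12)
})
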