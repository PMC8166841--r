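# Physical constants (CODATA 2018), full precision.
# Masses are in unified atomic mass units, stiffnesses in N/m, wavenumbers
# in cm^-1 throughout the package.
AMU_KG <- 1.66053906660e-27   # unified atomic mass unit, kg
C_CM_S <- 2.99792458e10       # speed of light, cm/s

# Standard atomic weights (amu) for the minimal MOL-style reader.
ELEMENT_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904
)

# Illustrative bond stiffnesses by bond order (N/m).  Not fitted to any
# data; a convenience default for exploratory graphs.
BOND_STIFFNESS_BY_ORDER <- c(`1` = 500, `2` = 1000, `3` = 1500)

#' Construct a molecular ball-and-spring graph
#'
#' A molecule is modelled as a graph whose nodes are atoms (carrying a
#' mass in amu) and whose edges are bonds (carrying a mechanical
#' stiffness in N/m).  This is the scalar harmonic model: each atom has a
#' single displacement coordinate, so an N-atom molecule has N normal
#' modes, one of which (per connected component) is the zero-frequency
#' translation.
#'
#' @param atoms data frame with columns `label` (character) and `mass`
#'   (amu, strictly positive), or a numeric vector of masses (labels are
#'   then invented).
#' @param bonds data frame with columns `i`, `j` (1-based atom indices)
#'   and `stiffness` (N/m, strictly positive).
#' @param name molecule name.
#' @return An object of class `molecular_graph`.
#' @examples
#' g <- molecular_graph(c(12, 12), data.frame(i = 1, j = 2, stiffness = 500),
#'                      name = "C2 toy")
#' vibrational_frequencies(g)
#' @export
molecular_graph <- function(atoms, bonds, name = "molecule") {
  if (is.numeric(atoms)) {
    atoms <- data.frame(label = paste0("a", seq_along(atoms)), mass = atoms)
  }
  atoms <- as.data.frame(atoms)
  if (!all(c("label", "mass") %in% names(atoms))) {
    stop("`atoms` needs columns `label` and `mass`")
  }
  if (nrow(atoms) < 1L) stop("graph has no atoms")
  bad <- which(!is.finite(atoms$mass) | atoms$mass <= 0)
  if (length(bad)) {
    stop("nonpositive or non-finite mass for atom(s): ",
         paste(atoms$label[bad], collapse = ", "))
  }
  bonds <- as.data.frame(bonds)
  if (nrow(bonds)) {
    if (!all(c("i", "j", "stiffness") %in% names(bonds))) {
      stop("`bonds` needs columns `i`, `j` and `stiffness`")
    }
    n <- nrow(atoms)
    if (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n)) {
      stop("bond index out of range")
    }
    selfb <- which(bonds$i == bonds$j)
    if (length(selfb)) stop("self-bond at atom index ", bonds$i[selfb[1]])
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key)) stop("duplicate bond between atoms ",
                                 key[duplicated(key)][1])
    bad <- which(!is.finite(bonds$stiffness) | bonds$stiffness <= 0)
    if (length(bad)) {
      stop("nonpositive or non-finite stiffness for bond(s): ",
           paste(bonds$i[bad], "-", bonds$j[bad], collapse = ", "))
    }
  }
  structure(list(atoms = atoms, bonds = bonds, name = name),
            class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat("Molecular graph:", x$name, "\n")
  cat("  ", nrow(x$atoms), "atoms,", nrow(x$bonds), "bonds\n")
  invisible(x)
}

# Connected components by breadth-first search over the bond list.
# Returns an integer component id per atom.
graph_components <- function(graph) {
  n <- nrow(graph$atoms)
  adj <- vector("list", n)
  for (r in seq_len(nrow(graph$bonds))) {
    i <- graph$bonds$i[r]; j <- graph$bonds$j[r]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- adj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

#' Mass-weighted dynamical matrix of a molecular graph
#'
#' The stiffness-weighted graph Laplacian, mass-weighted to the dynamical
#' matrix of the coupled-oscillator equations of motion:
#' off-diagonal `D[i,j] = -k_ij / sqrt(m_i m_j)` for bonded pairs and
#' diagonal `D[i,i] = sum_j k_ij / m_i`.  Entries are returned in
#' SI angular-frequency-squared units, (rad/s)^2, after converting masses
#' from amu to kg.  The matrix is symmetric positive semidefinite with
#' one zero eigenvalue per connected component.
#'
#' @param graph a [molecular_graph()].
#' @return A symmetric numeric matrix of class `dynamical_matrix` with
#'   atom labels as dimnames.
#' @export
dynamical_matrix <- function(graph) {
  stopifnot(inherits(graph, "molecular_graph"))
  n <- nrow(graph$atoms)
  if (n < 2L || nrow(graph$bonds) < 1L) {
    stop("graph needs at least 2 atoms and 1 bond")
  }
  m <- graph$atoms$mass * AMU_KG
  D <- matrix(0, n, n, dimnames = list(graph$atoms$label, graph$atoms$label))
  for (r in seq_len(nrow(graph$bonds))) {
    i <- graph$bonds$i[r]; j <- graph$bonds$j[r]
    k <- graph$bonds$stiffness[r]
    D[i, j] <- D[i, j] - k / sqrt(m[i] * m[j])
    D[j, i] <- D[i, j]
    D[i, i] <- D[i, i] + k / m[i]
    D[j, j] <- D[j, j] + k / m[j]
  }
  structure(D, class = c("dynamical_matrix", "matrix", "array"))
}

#' Vibrational frequencies of a molecular graph
#'
#' Eigen-decomposes the dynamical matrix and converts the eigenvalues
#' (squared angular frequencies) to wavenumbers,
#' `nu_tilde = sqrt(lambda) / (2 pi c)` in cm^-1, sorted ascending.
#'
#' In the scalar model every connected component contributes exactly one
#' zero mode (uniform translation); with `drop_zero_modes = TRUE`
#' (the default) eigenvalues with `|lambda| < zero_tol * max(lambda)` are
#' removed and their count is recorded in the `n_zero_dropped` attribute.
#'
#' @param graph a [molecular_graph()].
#' @param drop_zero_modes drop near-zero eigenvalues?
#' @param zero_tol relative tolerance for the numerical null space.
#' @return A [discrete_spectrum()] with `source = "graph_model"` and
#'   attribute `n_zero_dropped`.
#' @export
vibrational_frequencies <- function(graph, drop_zero_modes = TRUE,
                                    zero_tol = 1e-9) {
  D <- dynamical_matrix(graph)
  lambda <- eigen(unclass(D), symmetric = TRUE, only.values = TRUE)$values
  lambda <- sort(lambda)
  tol <- zero_tol * max(lambda)
  if (any(lambda < -tol)) {
    stop("dynamical matrix has a negative eigenvalue beyond tolerance; ",
         "internal inconsistency")
  }
  zero <- abs(lambda) < tol
  n_zero <- sum(zero)
  if (drop_zero_modes) lambda <- lambda[!zero] else lambda <- pmax(lambda, 0)
  wn <- sqrt(lambda) / (2 * pi * C_CM_S)
  out <- discrete_spectrum(graph$name, wn, source = "graph_model")
  attr(out, "n_zero_dropped") <- if (drop_zero_modes) n_zero else 0L
  attr(out, "n_zero_modes") <- n_zero
  out
}

#' Read a molecular graph from JSON
#'
#' Expected layout: `{"name": ..., "atoms": [{"label","mass"}, ...],
#' "bonds": [{"i","j","k"}, ...]}` with 0-based atom indices in the bond
#' block (converted to 1-based internally).
#'
#' @param path file path.
#' @return A [molecular_graph()].
#' @export
read_graph_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  bonds <- as.data.frame(x$bonds)
  names(bonds)[names(bonds) == "k"] <- "stiffness"
  bonds$i <- bonds$i + 1L
  bonds$j <- bonds$j + 1L
  molecular_graph(as.data.frame(x$atoms), bonds,
                  name = if (is.null(x$name)) "molecule" else x$name)
}

#' Read a minimal MOL-style connection table
#'
#' Parses a stripped-down connection table: a counts line (`natoms
#' nbonds`), then one line per atom (element symbol), then one line per
#' bond (`i j order`, 1-based).  Masses come from a bundled standard
#' atomic-weight table and stiffnesses from an illustrative per-bond-order
#' table (single/double/triple about 500/1000/1500 N/m) that is not
#' fitted to data.
#'
#' @param path file path.
#' @param name molecule name; defaults to the file name.
#' @param stiffness_by_order named numeric, stiffness per bond order.
#' @return A [molecular_graph()].
#' @export
read_mol_graph <- function(path, name = basename(path),
                           stiffness_by_order = BOND_STIFFNESS_BY_ORDER) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  counts <- as.integer(strsplit(lines[1], "\\s+")[[1]])
  na <- counts[1]; nb <- counts[2]
  sym <- vapply(lines[2:(1 + na)],
                function(l) strsplit(l, "\\s+")[[1]][1], "")
  unknown <- setdiff(sym, names(ELEMENT_MASSES))
  if (length(unknown)) stop("unknown element symbol(s): ",
                            paste(unknown, collapse = ", "))
  atoms <- data.frame(label = paste0(sym, seq_len(na)),
                      mass = unname(ELEMENT_MASSES[sym]))
  bonds <- do.call(rbind, lapply(lines[(2 + na):(1 + na + nb)], function(l) {
    v <- as.integer(strsplit(l, "\\s+")[[1]])
    data.frame(i = v[1], j = v[2], order = v[3])
  }))
  bonds$stiffness <- unname(stiffness_by_order[as.character(bonds$order)])
  if (anyNA(bonds$stiffness)) stop("bond order without a stiffness entry")
  molecular_graph(atoms, bonds[c("i", "j", "stiffness")], name = name)
}
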