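#' Construct a molecular graph
#'
#' A molecular graph holds atoms as vertices and bonds as unweighted,
#' unordered edges (connectivity only: no bond orders, no lengths).
#' Optional 3D coordinates (Angstrom) are carried for distance-decayed
#' featurization; an optional `nb` vector records each atom's bond count in
#' a parent structure (used so that ligand subgraphs can retain the degree
#' the atom had in the assembled complex).
#'
#' @param elements character vector of chemical symbols, one per atom.
#' @param bonds two-column integer matrix of 1-based atom index pairs, or a
#'   list of length-2 vectors. May have zero rows for a single atom.
#' @param coords optional numeric matrix (n x 3) of coordinates in Angstrom.
#' @param nb optional numeric vector of parent-structure bond counts.
#' @return object of class `molgraph`.
#' @export
molecular_graph <- function(elements, bonds, coords = NULL, nb = NULL) {
  stopifnot(is.character(elements), length(elements) >= 1)
  if (is.list(bonds)) bonds <- do.call(rbind, bonds)
  if (is.null(bonds) || length(bonds) == 0) {
    bonds <- matrix(integer(0), ncol = 2)
  }
  bonds <- matrix(as.integer(bonds), ncol = 2)
  n <- length(elements)
  if (nrow(bonds) > 0) {
    if (any(bonds < 1 | bonds > n)) stop("bond index out of range")
    if (any(bonds[, 1] == bonds[, 2])) stop("self-bonds are not allowed")
    # canonical order, drop duplicates
    bonds <- t(apply(bonds, 1, sort))
    bonds <- unique(bonds)
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    stopifnot(nrow(coords) == n, ncol(coords) == 3)
  }
  if (!is.null(nb)) stopifnot(length(nb) == n)
  g <- structure(
    list(elements = elements, bonds = bonds, coords = coords, nb = nb),
    class = "molgraph"
  )
  if (n > 1 && !graph_is_connected(g)) stop("molecular graph must be connected")
  g
}

#' @export
print.molgraph <- function(x, ...) {
  cat("<molgraph> ", length(x$elements), " atoms, ", nrow(x$bonds), " bonds",
      if (!is.null(x$coords)) ", 3D" else "", "\n", sep = "")
  invisible(x)
}

#' Number of bonds incident to each atom
#' @param graph a `molgraph`.
#' @return integer vector of degrees.
#' @export
graph_degree <- function(graph) {
  n <- length(graph$elements)
  deg <- integer(n)
  if (nrow(graph$bonds) > 0) {
    tb <- tabulate(c(graph$bonds[, 1], graph$bonds[, 2]), nbins = n)
    deg <- tb
  }
  deg
}

#' All-pairs shortest-path (bond-count) distances
#'
#' Unweighted breadth-first-search distances on the molecular graph, via
#' igraph. Entry (i, j) is the number of bonds on the shortest path.
#'
#' @param graph a `molgraph`.
#' @return integer matrix n x n (Inf for disconnected pairs).
#' @export
graph_distances <- function(graph) {
  n <- length(graph$elements)
  if (n == 1) return(matrix(0, 1, 1))
  ig <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(graph$bonds) > 0) {
    ig <- igraph::add_edges(ig, t(graph$bonds))
  }
  igraph::distances(ig)
}

graph_is_connected <- function(graph) {
  n <- length(graph$elements)
  if (n <= 1) return(TRUE)
  if (nrow(graph$bonds) == 0) return(FALSE)
  ig <- igraph::make_empty_graph(n, directed = FALSE)
  ig <- igraph::add_edges(ig, t(graph$bonds))
  igraph::is_connected(ig)
}

#' Neighbor lists of a molecular graph
#' @keywords internal
graph_neighbors <- function(graph) {
  n <- length(graph$elements)
  nb <- vector("list", n)
  for (i in seq_len(n)) nb[[i]] <- integer(0)
  if (nrow(graph$bonds) > 0) {
    for (r in seq_len(nrow(graph$bonds))) {
      a <- graph$bonds[r, 1]; b <- graph$bonds[r, 2]
      nb[[a]] <- c(nb[[a]], b)
      nb[[b]] <- c(nb[[b]], a)
    }
  }
  nb
}

#' Extract the induced subgraph on a set of atoms
#'
#' Retains coordinates and records each atom's original degree in `nb` so
#' that parent-structure bond counts survive subsetting.
#'
#' @param graph a `molgraph`.
#' @param atoms integer vector of atom indices to keep.
#' @return a `molgraph` on the selected atoms.
#' @export
subgraph_atoms <- function(graph, atoms) {
  atoms <- sort(unique(as.integer(atoms)))
  map <- match(seq_along(graph$elements), atoms)
  keep <- graph$bonds[, 1] %in% atoms & graph$bonds[, 2] %in% atoms
  bonds <- graph$bonds[keep, , drop = FALSE]
  bonds <- cbind(map[bonds[, 1]], map[bonds[, 2]])
  molecular_graph(
    elements = graph$elements[atoms],
    bonds = bonds,
    coords = if (!is.null(graph$coords)) graph$coords[atoms, , drop = FALSE],
    nb = graph_degree(graph)[atoms]
  )
}

#' Embed a molecular graph in 3D from its topology
#'
#' Produces deterministic idealized coordinates by classical
#' multidimensional scaling of the bond-count distance matrix, scaled so a
#' bond is about `bond_length` Angstrom. These template geometries are
#' sufficient for distance-decayed featurization, not for quantitative
#' structural work.
#'
#' @param graph a `molgraph`.
#' @param bond_length target bond length in Angstrom (default 1.5).
#' @return the graph with a `coords` matrix attached.
#' @export
embed_graph <- function(graph, bond_length = 1.5) {
  n <- length(graph$elements)
  if (n == 1) {
    graph$coords <- matrix(0, 1, 3)
    return(graph)
  }
  d <- graph_distances(graph) * bond_length
  xy <- suppressWarnings(stats::cmdscale(d, k = min(3, n - 1)))
  co <- matrix(0, n, 3)
  co[, seq_len(ncol(xy))] <- xy
  # deterministic perturbation breaks exact degeneracies between
  # topologically equivalent atoms so pairwise distances are nonzero
  co <- co + 1e-3 * sin(outer(seq_len(n), 1:3, function(i, j) i * j + i^2))
  graph$coords <- co
  graph
}
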