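# hand-built toy structures and independent oracles used across tests

# water: H-O-H
water_graph <- function() {
  molecular_graph(c("H", "O", "H"), rbind(c(1, 2), c(2, 3)))
}

# minimal protonated CN ligand: H3C-NH2-like chain won't classify; build a
# small ring-free toy with a C donor carrying an H and an N donor.
#   H-C(-H)=N pattern as a graph: C(1)-N(2), C-H(3), C-H(4), N-... keep N
#   with one H? donors: C1 (has H) and N2.
toy_cn_ligand <- function(id = "tCN") {
  g <- molecular_graph(c("C", "N", "H", "H", "C", "H", "H", "H"),
                       rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 5),
                             c(5, 6), c(5, 7), c(5, 8)))
  ligand_record(id, g, c(1, 2))
}

toy_nn_ligand <- function(id = "tNN") {
  g <- molecular_graph(c("N", "C", "N", "H", "H", "H", "H"),
                       rbind(c(1, 2), c(2, 3), c(1, 4), c(2, 5),
                             c(3, 6), c(3, 7)))
  ligand_record(id, g, c(1, 3))
}

# independent BFS distances (Floyd-Warshall, no igraph)
oracle_distances <- function(elements, bonds) {
  n <- length(elements)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  if (nrow(bonds) > 0) {
    for (r in seq_len(nrow(bonds))) {
      D[bonds[r, 1], bonds[r, 2]] <- 1
      D[bonds[r, 2], bonds[r, 1]] <- 1
    }
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

# brute-force ordered-pair autocorrelation oracle (independent double loop)
oracle_autocorrelation <- function(graph, start_set, operation, property,
                                   depth) {
  P <- atom_properties(graph, property)
  D <- oracle_distances(graph$elements, graph$bonds)
  total <- 0
  for (i in start_set) {
    for (j in seq_along(P)) {
      if (D[i, j] == depth) {
        total <- total +
          if (operation == "product") P[i] * P[j] else P[i] - P[j]
      }
    }
  }
  total
}

# random connected molecular graph with <= n_max atoms (tree + maybe a cycle)
random_molgraph <- function(n_max = 8) {
  n <- sample(2:n_max, 1)
  els <- sample(c("H", "C", "N", "O", "F", "S", "Cl"), n, replace = TRUE)
  bonds <- cbind(2:n, vapply(2:n, function(i) sample(i - 1, 1), integer(1)))
  if (n >= 4 && stats::runif(1) < 0.4) {
    extra <- sample(n, 2)
    if (!any(bonds[, 1] == max(extra) & bonds[, 2] == min(extra))) {
      bonds <- rbind(bonds, extra)
    }
  }
  molecular_graph(els, bonds)
}

# a deterministic small library for split/similarity tests
small_library <- function(n_cn = 4, n_nn = 3, seed = 11) {
  gen_ligand_library(n_cn, n_nn, seed)
}
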