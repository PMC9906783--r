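#' Assemble an [Ir(CN)2(NN)]+ complex from one CN and one NN ligand
#'
#' Builds the whole-complex molecular graph: one iridium vertex bonded to
#' the four donor atoms of two identical copies of the CN ligand and the two
#' donor nitrogens of the NN ligand. CN ligands are supplied in neutral
#' protonated form; the proton on each coordinating carbon is removed during
#' assembly, so the overall charge is `3 + 2*(cn_charge - 1) + nn_charge`
#' (+1 for neutral inputs).
#'
#' @param cn a `ligand` with role `"CN"`.
#' @param nn a `ligand` with role `"NN"`.
#' @param embed if `TRUE` and both ligands lack coordinates, attach an
#'   idealized 3D embedding to the assembled graph (see [embed_graph()]).
#' @return object of class `ir_complex` with fields `complex_id`, `cn_id`,
#'   `nn_id`, `overall_charge`, `whole_graph`, `ir_index`,
#'   `ligand_atom_sets` and `donor_sets`.
#' @export
assemble_complex <- function(cn, nn, embed = FALSE) {
  if (!inherits(cn, "ligand") || cn$role != "CN")
    stop("'cn' must be a ligand with role CN")
  if (!inherits(nn, "ligand") || nn$role != "NN")
    stop("'nn' must be a ligand with role NN")

  deprot <- deprotonate_cn(cn)

  elements <- "Ir"
  bonds <- matrix(integer(0), ncol = 2)
  nbs <- list()
  lig_atoms <- list()
  donors <- list()
  offset <- 1L
  pieces <- list(deprot, deprot, nn_piece(nn))
  for (k in 1:3) {
    p <- pieces[[k]]
    g <- p$graph
    idx <- offset + seq_along(g$elements)
    elements <- c(elements, g$elements)
    if (nrow(g$bonds) > 0) bonds <- rbind(bonds, g$bonds + offset)
    don <- p$coordinating_atoms + offset
    bonds <- rbind(bonds, cbind(1L, don))
    lig_atoms[[k]] <- idx
    donors[[k]] <- don
    offset <- offset + length(g$elements)
  }
  whole <- molecular_graph(elements, bonds)
  overall_charge <- 3L + 2L * (cn$formal_charge - 1L) + nn$formal_charge
  if (embed) whole <- embed_graph(whole)
  structure(
    list(
      complex_id = complex_id(cn$ligand_id, nn$ligand_id, overall_charge),
      cn_id = cn$ligand_id, nn_id = nn$ligand_id,
      overall_charge = overall_charge,
      whole_graph = whole, ir_index = 1L,
      ligand_atom_sets = lig_atoms, donor_sets = donors,
      ligand_roles = c("CN", "CN", "NN")
    ),
    class = "ir_complex"
  )
}

#' @export
print.ir_complex <- function(x, ...) {
  cat("<ir_complex> ", x$complex_id, ", ",
      length(x$whole_graph$elements), " atoms\n", sep = "")
  invisible(x)
}

# remove the proton on the coordinating carbon of a protonated CN ligand
deprotonate_cn <- function(cn) {
  g <- cn$graph
  don <- cn$coordinating_atoms
  c_idx <- don[g$elements[don] == "C"][1]
  nbrs <- graph_neighbors(g)[[c_idx]]
  h <- nbrs[g$elements[nbrs] == "H"]
  if (length(h) == 0) {
    stop("CN ligand '", cn$ligand_id,
         "' has no proton on the coordinating carbon to remove")
  }
  keep <- setdiff(seq_along(g$elements), h[1])
  sub <- subgraph_atoms(g, keep)
  # degrees in the deprotonated ligand itself (NB recomputed on assembly)
  sub$nb <- NULL
  don_new <- match(don, keep)
  list(graph = sub, coordinating_atoms = don_new)
}

nn_piece <- function(nn) {
  list(graph = nn$graph, coordinating_atoms = nn$coordinating_atoms)
}

#' Human-readable deterministic complex identifier
#' @param cn_id,nn_id ligand ids.
#' @param charge integer overall charge.
#' @return string of the form `[Ir(<cn>)2(<nn>)]<+charge>`.
#' @export
complex_id <- function(cn_id, nn_id, charge = 1L) {
  sgn <- if (charge > 0) paste0("+", charge) else as.character(charge)
  paste0("[Ir(", cn_id, ")2(", nn_id, ")]", sgn)
}

#' Enumerate the combinatorial complex library
#'
#' Pairs every CN ligand with every NN ligand (CN index major, NN index
#' minor), yielding `|CN| x |NN|` complexes. Returns a light-weight
#' data.frame of pairings; call [assemble_complex()] for the full graph of
#' any row.
#'
#' @param library a `ligand_library`.
#' @return data.frame with columns `complex_id`, `cn_id`, `nn_id`,
#'   `overall_charge`.
#' @export
enumerate_combinatorial <- function(library) {
  cn_ids <- names(library$cn)
  nn_ids <- names(library$nn)
  if (length(cn_ids) == 0 || length(nn_ids) == 0) {
    return(data.frame(complex_id = character(0), cn_id = character(0),
                      nn_id = character(0), overall_charge = integer(0),
                      stringsAsFactors = FALSE))
  }
  grid <- expand.grid(nn_id = nn_ids, cn_id = cn_ids,
                      stringsAsFactors = FALSE)[, c("cn_id", "nn_id")]
  charge <- vapply(seq_len(nrow(grid)), function(i) {
    3L + 2L * (library$cn[[grid$cn_id[i]]]$formal_charge - 1L) +
      library$nn[[grid$nn_id[i]]]$formal_charge
  }, integer(1))
  data.frame(
    complex_id = mapply(complex_id, grid$cn_id, grid$nn_id, charge,
                        USE.NAMES = FALSE),
    cn_id = grid$cn_id, nn_id = grid$nn_id, overall_charge = charge,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Enumerate hypothetical complexes containing at least one novel ligand
#'
#' All CN/NN pairings over the union of a reference (high-throughput ligand
#' set, HLS) library and a novel library, minus the pairings formed from
#' reference ligands alone. The count is
#' `(|CN_hls|+|CN_new|)(|NN_hls|+|NN_new|) - |CN_hls||NN_hls|`.
#'
#' @param hls reference `ligand_library`.
#' @param novel `ligand_library` of new ligands; ids must not collide with
#'   `hls`.
#' @return data.frame as in [enumerate_combinatorial()].
#' @export
enumerate_hypothetical <- function(hls, novel) {
  all_lib <- merge_libraries(hls, novel)
  full <- enumerate_combinatorial(all_lib)
  old <- full$cn_id %in% names(hls$cn) & full$nn_id %in% names(hls$nn)
  full[!old, , drop = FALSE]
}
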