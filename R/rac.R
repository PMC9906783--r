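#' Graph autocorrelation of heuristic atomic properties
#'
#' The elementary descriptor: the sum over ordered atom pairs (i, j), with i
#' in the start set and j at shortest-path (bond count) distance exactly `d`
#' from i, of either the product `P_i * P_j` or the difference `P_i - P_j`
#' of a heuristic atomic property P. Distances are breadth-first-search
#' distances on the unweighted molecular graph, so full-scope products count
#' each unordered pair twice and every atom pairs with itself at depth 0.
#'
#' With `decay = TRUE` the Coulomb-decay variant is computed: each pair term
#' with i != j is divided by the Euclidean interatomic distance r_ij (in
#' Angstrom), encoding 3D geometry; depth-0 self terms are left undecayed.
#'
#' @param graph a `molgraph` (with coordinates when `decay = TRUE`).
#' @param start_set integer atom indices used as starting atoms.
#' @param operation `"product"` or `"difference"`.
#' @param property one of the seven heuristic properties (see
#'   [atom_properties()]).
#' @param depth non-negative integer bond-count depth d.
#' @param decay logical; apply 1/r Coulomb decay to pair terms.
#' @return scalar descriptor value.
#' @export
autocorrelation <- function(graph, start_set, operation, property, depth,
                            decay = FALSE) {
  operation <- match.arg(operation, c("product", "difference"))
  stopifnot(depth >= 0, length(start_set) >= 1)
  P <- atom_properties(graph, property)
  D <- graph_distances(graph)
  if (decay) {
    if (is.null(graph$coords)) stop("Coulomb-decay autocorrelation requires coordinates")
    R <- as.matrix(stats::dist(graph$coords))
  }
  start_set <- as.integer(start_set)
  mask <- D[start_set, , drop = FALSE] == depth
  if (!any(mask)) return(0)
  W <- matrix(1, nrow = length(start_set), ncol = length(P))
  if (decay && depth >= 1) {
    W <- 1 / R[start_set, , drop = FALSE]
  }
  if (operation == "product") {
    terms <- outer(P[start_set], P)
  } else {
    terms <- outer(P[start_set], P, `-`)
  }
  sum(terms[mask] * W[mask])
}

#' Ligand-only revised autocorrelation features
#'
#' Full-scope product autocorrelations (all atoms as starting atoms) over
#' the seven heuristic properties at depths 0..`d_max`, computed on the
#' isolated CN and NN ligand graphs (CN in its stored neutral protonated
#' form) and concatenated CN block first. Length `2 * 7 * (d_max + 1)`
#' (70 at the default `d_max = 4`).
#'
#' @param cn,nn `ligand` objects.
#' @param d_max maximum depth (default 4).
#' @return named numeric feature vector.
#' @export
ligand_racs <- function(cn, nn, d_max = 4) {
  blocks <- lapply(list(cn = cn, nn = nn), function(l) {
    g <- l$graph
    vals <- numeric(0)
    for (p in .rac_properties) {
      for (d in 0:d_max) {
        v <- autocorrelation(g, seq_along(g$elements), "product", p, d)
        names(v) <- paste0(tolower(l$role), "_prod_", p, "_d", d)
        vals <- c(vals, v)
      }
    }
    vals
  })
  c(blocks$cn, blocks$nn)
}

#' Axial/equatorial ligand plane assignment
#'
#' A fixed idealized octahedral coordination template: the two donor
#' nitrogens of the NN ligand and one donor of each CN ligand span the
#' equatorial plane (4 sites); the remaining donor of each CN ligand
#' occupies an axial site (2 sites). Each ligand's class weight is the
#' fraction of that class's sites occupied by its donors, so a ligand with
#' one axial and one equatorial donor belongs to both classes, and the
#' weights within each class sum to 1.
#'
#' @param complex an `ir_complex`.
#' @return data.frame with columns `ligand` (1..3), `role`, `ax_weight`,
#'   `eq_weight`.
#' @export
assign_ligand_planes <- function(complex) {
  # donors per ligand: CN ligands contribute (1 ax, 1 eq); NN (0 ax, 2 eq)
  ax_donors <- c(1, 1, 0)
  eq_donors <- c(1, 1, 2)
  data.frame(
    ligand = 1:3,
    role = complex$ligand_roles,
    ax_weight = ax_donors / 2,
    eq_weight = eq_donors / 4
  )
}

# scope definitions shared by complex_racs and cd_racs ----------------------

.complex_rac_scopes <- function(complex) {
  planes <- assign_ligand_planes(complex)
  lig_sub <- lapply(complex$ligand_atom_sets, function(a)
    subgraph_atoms(complex$whole_graph, c(a)))
  lig_start_all <- lapply(lig_sub, function(g) seq_along(g$elements))
  lig_start_don <- lapply(1:3, function(k) {
    match(complex$donor_sets[[k]], sort(unique(complex$ligand_atom_sets[[k]])))
  })
  list(planes = planes, lig_sub = lig_sub,
       lig_start_all = lig_start_all, lig_start_don = lig_start_don)
}

.ligand_avg_ac <- function(ctx, weights, starts, operation, property, depth,
                           decay = FALSE) {
  num <- 0
  for (k in 1:3) {
    if (weights[k] == 0) next
    num <- num + weights[k] *
      autocorrelation(ctx$lig_sub[[k]], starts[[k]], operation, property,
                      depth, decay = decay)
  }
  num
}

#' Whole-complex revised autocorrelation (RAC) features
#'
#' The 196-feature complex descriptor set: for each of the seven heuristic
#' atomic properties at depths 0..3,
#' \itemize{
#'   \item full-scope products on the whole complex graph,
#'   \item metal-centered products and differences (iridium as start atom),
#'   \item axial- and equatorial-averaged full-ligand-scope products
#'     (full-scope products on each ligand subgraph, averaged with the
#'     plane weights of [assign_ligand_planes()]),
#'   \item axial- and equatorial-averaged ligand-centered products (donor
#'     atoms as start atoms on each ligand subgraph, same averaging).
#' }
#' That is 7 scope/operation blocks of 7 x 4 = 28 descriptors each.
#' Ligand subgraphs retain parent-structure bond counts for the NB property.
#'
#' @param complex an `ir_complex`.
#' @return named numeric vector of length 196 in a fixed, stable order.
#' @export
complex_racs <- function(complex) {
  g <- complex$whole_graph
  if (g$elements[complex$ir_index] != "Ir") stop("complex lacks an Ir vertex")
  ctx <- .complex_rac_scopes(complex)
  ax_w <- ctx$planes$ax_weight
  eq_w <- ctx$planes$eq_weight
  out <- numeric(0)
  for (p in .rac_properties) {
    for (d in 0:3) {
      v <- c(
        autocorrelation(g, seq_along(g$elements), "product", p, d),
        autocorrelation(g, complex$ir_index, "product", p, d),
        autocorrelation(g, complex$ir_index, "difference", p, d),
        .ligand_avg_ac(ctx, ax_w, ctx$lig_start_all, "product", p, d),
        .ligand_avg_ac(ctx, eq_w, ctx$lig_start_all, "product", p, d),
        .ligand_avg_ac(ctx, ax_w, ctx$lig_start_don, "product", p, d),
        .ligand_avg_ac(ctx, eq_w, ctx$lig_start_don, "product", p, d)
      )
      names(v) <- paste0(
        c("f_all_prod", "mc_prod", "mc_diff",
          "ax_f_prod", "eq_f_prod", "ax_lc_prod", "eq_lc_prod"),
        "_", p, "_d", d)
      out <- c(out, v)
    }
  }
  out
}

#' Coulomb-decay RAC (CD-RAC) features
#'
#' Distance-decayed analogue of the complex RAC set: every pair term between
#' distinct atoms is divided by the interatomic Euclidean distance (1/r
#' decay), while depth-0 self terms keep the undecayed atomic value. The set
#' comprises the six product scopes of [complex_racs()] over the seven
#' properties at depths 0..3 (168 descriptors) plus decayed differences for
#' the metal-centered and the axial/equatorial ligand-centered scopes over
#' the six non-identity properties at depths 1..3 (54 descriptors), 222 in
#' total. Requires 3D coordinates on every atom.
#'
#' @param complex an `ir_complex` whose `whole_graph` carries coordinates.
#' @return named numeric vector of length 222.
#' @export
cd_racs <- function(complex) {
  g <- complex$whole_graph
  if (is.null(g$coords)) stop("CD-RACs require coordinates for every atom")
  ctx <- .complex_rac_scopes(complex)
  ax_w <- ctx$planes$ax_weight
  eq_w <- ctx$planes$eq_weight
  out <- numeric(0)
  for (p in .rac_properties) {
    for (d in 0:3) {
      v <- c(
        autocorrelation(g, seq_along(g$elements), "product", p, d, decay = TRUE),
        autocorrelation(g, complex$ir_index, "product", p, d, decay = TRUE),
        .ligand_avg_ac(ctx, ax_w, ctx$lig_start_all, "product", p, d, decay = TRUE),
        .ligand_avg_ac(ctx, eq_w, ctx$lig_start_all, "product", p, d, decay = TRUE),
        .ligand_avg_ac(ctx, ax_w, ctx$lig_start_don, "product", p, d, decay = TRUE),
        .ligand_avg_ac(ctx, eq_w, ctx$lig_start_don, "product", p, d, decay = TRUE)
      )
      names(v) <- paste0(
        c("f_all_prod", "mc_prod", "ax_f_prod", "eq_f_prod",
          "ax_lc_prod", "eq_lc_prod"),
        "_", p, "_d", d, "_cd")
      out <- c(out, v)
    }
  }
  for (p in setdiff(.rac_properties, "I")) {
    for (d in 1:3) {
      v <- c(
        autocorrelation(g, complex$ir_index, "difference", p, d, decay = TRUE),
        .ligand_avg_ac(ctx, ax_w, ctx$lig_start_don, "difference", p, d, decay = TRUE),
        .ligand_avg_ac(ctx, eq_w, ctx$lig_start_don, "difference", p, d, decay = TRUE)
      )
      names(v) <- paste0(c("mc_diff", "ax_lc_diff", "eq_lc_diff"),
                         "_", p, "_d", d, "_cd")
      out <- c(out, v)
    }
  }
  out
}
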