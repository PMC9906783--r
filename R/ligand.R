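#' Classify a bidentate ligand as cyclometalating (CN) or ancillary (NN)
#'
#' The role is determined purely by the identities of the two
#' iridium-coordinating atoms: one carbon plus one nitrogen gives a
#' cyclometalating (CN) ligand; two nitrogens give an ancillary (NN) ligand.
#' Any other donor-atom pair is outside the supported chemistry.
#'
#' @param graph a `molgraph`.
#' @param coordinating_atoms integer vector of exactly two distinct atom
#'   indices.
#' @return `"CN"` or `"NN"`.
#' @export
classify_ligand_role <- function(graph, coordinating_atoms) {
  stopifnot(inherits(graph, "molgraph"))
  if (length(coordinating_atoms) != 2 ||
      coordinating_atoms[1] == coordinating_atoms[2]) {
    stop("exactly two distinct coordinating atoms are required")
  }
  el <- sort(graph$elements[coordinating_atoms])
  if (identical(el, c("C", "N"))) return("CN")
  if (identical(el, c("N", "N"))) return("NN")
  stop("unsupported donor-atom pair {", paste(el, collapse = ","),
       "}: only C^N (cyclometalating) and N^N (ancillary) bidentate ",
       "ligands are supported")
}

#' Create a ligand record
#'
#' A ligand record bundles a ligand's molecular graph, its role, the two
#' metal-coordinating atom indices and the formal charge. CN ligands are
#' stored in their neutral protonated form (a proton on the coordinating
#' carbon); the proton is removed on complex assembly.
#'
#' @param ligand_id unique identifier string.
#' @param graph a `molgraph`.
#' @param coordinating_atoms two distinct atom indices.
#' @param formal_charge integer formal charge of the stored (protonated for
#'   CN) ligand; default 0.
#' @param role optional role; if omitted it is derived from the donor atoms
#'   and otherwise checked for consistency.
#' @return object of class `ligand`.
#' @export
ligand_record <- function(ligand_id, graph, coordinating_atoms,
                          formal_charge = 0L, role = NULL) {
  derived <- classify_ligand_role(graph, coordinating_atoms)
  if (!is.null(role) && !identical(role, derived)) {
    stop("declared role '", role, "' contradicts donor atoms (", derived, ")")
  }
  structure(
    list(ligand_id = as.character(ligand_id), role = derived, graph = graph,
         coordinating_atoms = as.integer(coordinating_atoms),
         formal_charge = as.integer(formal_charge)),
    class = "ligand"
  )
}

#' @export
print.ligand <- function(x, ...) {
  cat("<ligand> ", x$ligand_id, " [", x$role, "], ",
      length(x$graph$elements), " atoms, charge ", x$formal_charge, "\n",
      sep = "")
  invisible(x)
}

#' Create a ligand library
#'
#' @param ligands list of `ligand` objects (both roles mixed is fine).
#' @return object of class `ligand_library` with `$cn` and `$nn` lists keyed
#'   by ligand id.
#' @export
ligand_library <- function(ligands) {
  ids <- vapply(ligands, function(l) l$ligand_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate ligand ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  roles <- vapply(ligands, function(l) l$role, character(1))
  cn <- ligands[roles == "CN"]
  nn <- ligands[roles == "NN"]
  names(cn) <- ids[roles == "CN"]
  names(nn) <- ids[roles == "NN"]
  structure(list(cn = cn, nn = nn), class = "ligand_library")
}

#' @export
print.ligand_library <- function(x, ...) {
  cat("<ligand_library> ", length(x$cn), " CN + ", length(x$nn),
      " NN ligands\n", sep = "")
  invisible(x)
}

#' Look up a ligand in a library by id
#' @param library a `ligand_library`.
#' @param ligand_id id string.
#' @return the `ligand`, or an error if absent.
#' @export
get_ligand <- function(library, ligand_id) {
  l <- library$cn[[ligand_id]]
  if (is.null(l)) l <- library$nn[[ligand_id]]
  if (is.null(l)) stop("ligand '", ligand_id, "' not found in library")
  l
}

#' Merge two ligand libraries
#' @param a,b `ligand_library` objects with disjoint ids.
#' @return merged `ligand_library`.
#' @export
merge_libraries <- function(a, b) {
  overlap <- intersect(c(names(a$cn), names(a$nn)), c(names(b$cn), names(b$nn)))
  if (length(overlap)) stop("ligand id collision: ",
                            paste(overlap, collapse = ", "))
  ligand_library(c(unname(a$cn), unname(a$nn), unname(b$cn), unname(b$nn)))
}
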