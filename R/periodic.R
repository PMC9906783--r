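#' Heuristic atomic property table
#'
#' Per-element values used by the autocorrelation featurizers: nuclear charge
#' (Z), Pauling electronegativity (chi), Cordero covalent radius (S, in
#' Angstrom) and IUPAC group number (G). Coverage spans the elements that
#' occur in cyclometalating/ancillary ligand chemistry plus iridium.
#'
#' @format data.frame with one row per element and columns
#'   `element`, `Z`, `chi`, `S`, `G`.
#' @keywords internal
.atom_property_table <- data.frame(
  element = c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I", "Ir"),
  Z       = c(1,   5,   6,   7,   8,   9,   14,   15,  16,  17,   35,   53,  77),
  chi     = c(2.20, 2.04, 2.55, 3.04, 3.44, 3.98, 1.90, 2.19, 2.58, 3.16, 2.96, 2.66, 2.20),
  S       = c(0.31, 0.84, 0.76, 0.71, 0.66, 0.57, 1.11, 1.07, 1.05, 1.02, 1.20, 1.39, 1.41),
  G       = c(1,   13,  14,  15,  16,  17,  14,   15,  16,  17,   17,   17,  9),
  stringsAsFactors = FALSE
)

#' Look up heuristic atomic properties for a vector of elements
#'
#' Returns the per-atom values of one of the seven heuristic properties used
#' in autocorrelation descriptors: identity `I` (constant 1), nuclear charge
#' `Z`, Pauling electronegativity `chi`, topology `T` (graph degree),
#' covalent radius `S`, group number `G`, and bond count `NB` (degree in the
#' parent structure, falling back to `T` when no parent is recorded).
#'
#' @param graph a `molgraph` object.
#' @param property one of `"I"`, `"Z"`, `"chi"`, `"T"`, `"S"`, `"G"`, `"NB"`.
#' @return numeric vector, one value per atom.
#' @export
atom_properties <- function(graph, property) {
  stopifnot(inherits(graph, "molgraph"))
  property <- match.arg(property, c("I", "Z", "chi", "T", "S", "G", "NB"))
  n <- length(graph$elements)
  if (property == "I") return(rep(1, n))
  if (property == "T") return(graph_degree(graph))
  if (property == "NB") {
    if (!is.null(graph$nb)) return(graph$nb)
    return(graph_degree(graph))
  }
  idx <- match(graph$elements, .atom_property_table$element)
  if (anyNA(idx)) {
    stop("atomic property '", property, "' undefined for element(s): ",
         paste(unique(graph$elements[is.na(idx)]), collapse = ", "))
  }
  .atom_property_table[[property]][idx]
}

.rac_properties <- c("I", "Z", "chi", "T", "S", "G", "NB")

#' Physical constants used in radiative-rate post-processing
#'
#' CODATA values: the atomic unit of time t0 = (4 pi eps0)^2 hbar^3/(m_e e^4),
#' the fine-structure constant alpha0, the Boltzmann constant in hartree/K,
#' and the hartree<->eV conversion.
#' @keywords internal
.phys <- list(
  t0_s          = 2.4188843265857e-17,
  alpha0        = 7.2973525693e-3,
  kB_hartree    = 3.166811563e-6,
  hartree_eV    = 27.2114
)

#' Convert energies between eV and hartree
#'
#' @param x numeric energies.
#' @return converted numeric vector.
#' @export
ev_to_hartree <- function(x) x / .phys$hartree_eV

#' @rdname ev_to_hartree
#' @export
hartree_to_ev <- function(x) x * .phys$hartree_eV
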