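#' Electronic descriptor table for ligands
#'
#' Per-ligand frontier-orbital and charge descriptors: HOMO and LUMO
#' energies (eV), vertical ionization potential IP and electron affinity EA
#' (eV), and the Mulliken partial charges of the two metal-coordinating
#' atoms (a.u.). For CN ligands the donor charges are ordered carbon then
#' nitrogen; for NN ligands N1 then N2 by canonical (ascending atom index)
#' order. The `provenance` tag records the electronic-structure source
#' (e.g. `"xtb"`, `"b3lyp"`, `"wpbeh"`, `"synthetic"`).
#'
#' @param df data.frame with columns `ligand_id`, `role`, `homo_eV`,
#'   `lumo_eV`, `ip_eV`, `ea_eV`, `donor1_charge_au`, `donor2_charge_au`,
#'   `provenance`.
#' @return the validated data.frame with class `electronic_table`.
#' @export
electronic_table <- function(df) {
  req <- c("ligand_id", "role", "homo_eV", "lumo_eV", "ip_eV", "ea_eV",
           "donor1_charge_au", "donor2_charge_au", "provenance")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("electronic table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$ligand_id)) stop("duplicate ligand ids in table")
  class(df) <- c("electronic_table", "data.frame")
  df
}

#' Validate an electronic table against a ligand library
#'
#' Checks coverage (every ligand in the library has an entry), the
#' HOMO < LUMO ordering, and finiteness of all numeric fields.
#'
#' @param table an `electronic_table`.
#' @param library a `ligand_library` (optional; coverage skipped if NULL).
#' @param strict if TRUE, any violation is an error.
#' @return (invisibly for strict) a list report with character vectors
#'   `missing_ligands`, `ordering_violations`, `nonfinite`.
#' @export
validate_electronic_table <- function(table, library = NULL, strict = FALSE) {
  report <- list(missing_ligands = character(0),
                 ordering_violations = character(0),
                 nonfinite = character(0))
  if (!is.null(library)) {
    need <- c(names(library$cn), names(library$nn))
    report$missing_ligands <- setdiff(need, table$ligand_id)
  }
  bad_order <- table$homo_eV >= table$lumo_eV
  report$ordering_violations <- table$ligand_id[which(bad_order)]
  num <- c("homo_eV", "lumo_eV", "ip_eV", "ea_eV",
           "donor1_charge_au", "donor2_charge_au")
  fin <- apply(is.finite(as.matrix(table[num])), 1, all)
  report$nonfinite <- table$ligand_id[!fin]
  if (strict && any(lengths(report) > 0)) {
    stop("electronic table validation failed: ",
         paste(unlist(report), collapse = ", "))
  }
  report
}

#' Electronic feature vector of one complex
#'
#' The 12 ligand electronic descriptors of a complex, CN block first:
#' `cn_homo, cn_lumo, cn_ip, cn_ea, cn_c_charge, cn_n_charge`, then
#' `nn_homo, nn_lumo, nn_ip, nn_ea, nn_n1_charge, nn_n2_charge`. A pure
#' function of `(cn_id, nn_id)` given the table.
#'
#' @param cn_id,nn_id ligand ids.
#' @param table an `electronic_table` covering both ligands.
#' @return named numeric vector of length 12.
#' @export
complex_electronic_features <- function(cn_id, nn_id, table) {
  row_of <- function(id) {
    i <- match(id, table$ligand_id)
    if (is.na(i)) stop("ligand '", id, "' missing from electronic table")
    table[i, ]
  }
  rc <- row_of(cn_id); rn <- row_of(nn_id)
  v <- c(rc$homo_eV, rc$lumo_eV, rc$ip_eV, rc$ea_eV,
         rc$donor1_charge_au, rc$donor2_charge_au,
         rn$homo_eV, rn$lumo_eV, rn$ip_eV, rn$ea_eV,
         rn$donor1_charge_au, rn$donor2_charge_au)
  names(v) <- electronic_feature_names()
  v
}

#' Canonical names of the 12 electronic features
#' @return character vector of length 12 (CN block then NN block).
#' @export
electronic_feature_names <- function() {
  c("cn_homo", "cn_lumo", "cn_ip", "cn_ea", "cn_c_charge", "cn_n_charge",
    "nn_homo", "nn_lumo", "nn_ip", "nn_ea", "nn_n1_charge", "nn_n2_charge")
}

#' Electronic feature matrix for a set of complexes
#'
#' @param complexes data.frame with `cn_id` and `nn_id` columns (as from
#'   [enumerate_combinatorial()]).
#' @param table an `electronic_table`.
#' @return numeric matrix, one row per complex, 12 named columns, rownames
#'   set to `complex_id` when present.
#' @export
electronic_feature_matrix <- function(complexes, table) {
  m <- t(vapply(seq_len(nrow(complexes)), function(i)
    complex_electronic_features(complexes$cn_id[i], complexes$nn_id[i], table),
    numeric(12)))
  if (!is.null(complexes$complex_id)) rownames(m) <- complexes$complex_id
  m
}

#' Ingest raw electronic-structure engine records into a table
#'
#' Boundary contract for external tight-binding / DFT output: each record
#' is a list with `ligand_id`, `role`, `unit` (`"eV"` or `"hartree"`, for
#' the orbital/IP/EA energies), `homo`, `lumo`, `ip`, `ea`, a numeric
#' vector `atom_charges` (a.u.) over all atoms, and
#' `coordinating_atom_indices` (1-based, length 2, ordered as the ligand's
#' donor convention). Energies in hartree are converted at 27.2114
#' eV/hartree; charges are mapped to donor1/donor2 via the indices.
#'
#' @param records list of such records.
#' @param provenance tag stored on the resulting table.
#' @return an `electronic_table`.
#' @export
ingest_electronic_records <- function(records, provenance = "xtb") {
  rows <- lapply(records, function(r) {
    if (is.null(r$unit)) stop("record for '", r$ligand_id,
                              "' lacks an energy unit tag")
    conv <- switch(r$unit, eV = 1, hartree = .phys$hartree_eV,
                   stop("unknown energy unit '", r$unit, "'"))
    idx <- r$coordinating_atom_indices
    if (any(idx < 1 | idx > length(r$atom_charges))) {
      stop("coordinating atom index out of range for '", r$ligand_id, "'")
    }
    data.frame(ligand_id = r$ligand_id, role = r$role,
               homo_eV = r$homo * conv, lumo_eV = r$lumo * conv,
               ip_eV = r$ip * conv, ea_eV = r$ea * conv,
               donor1_charge_au = r$atom_charges[idx[1]],
               donor2_charge_au = r$atom_charges[idx[2]],
               provenance = provenance, stringsAsFactors = FALSE)
  })
  electronic_table(do.call(rbind, rows))
}

#' Read/write an electronic table as CSV
#' @param path file path.
#' @return an `electronic_table` (for the reader).
#' @export
read_electronic_table <- function(path) {
  electronic_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_electronic_table
#' @param table table to write.
#' @export
write_electronic_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
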