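#' Read a ligand from an XYZ file plus a bond-list sidecar
#'
#' Standard XYZ dialect (atom count, comment line, then `element x y z`
#' rows, Angstrom) with connectivity supplied as a sidecar text file of one
#' bond per line, two whitespace-separated 0-based atom indices. Bond
#' perception from coordinates is deliberately not attempted.
#'
#' @param ligand_id id for the resulting ligand.
#' @param xyz_path XYZ file path.
#' @param bonds_path sidecar path.
#' @param coordinating_atoms two 1-based donor atom indices.
#' @param formal_charge integer charge (default 0).
#' @return a `ligand` with coordinates attached.
#' @export
read_xyz_ligand <- function(ligand_id, xyz_path, bonds_path,
                            coordinating_atoms, formal_charge = 0L) {
  lines <- readLines(xyz_path)
  n <- as.integer(trimws(lines[1]))
  rows <- strsplit(trimws(lines[2 + seq_len(n)]), "\\s+")
  elements <- vapply(rows, `[[`, character(1), 1)
  coords <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  braw <- strsplit(trimws(readLines(bonds_path)), "\\s+")
  braw <- braw[lengths(braw) > 0]
  bonds <- t(vapply(braw, function(r) as.integer(r[1:2]) + 1L, integer(2)))
  g <- molecular_graph(elements, bonds, coords = coords)
  ligand_record(ligand_id, g, coordinating_atoms, formal_charge)
}

#' Read an experimental property table
#'
#' CSV with columns `complex_id`, `em5050_eV`, `lifetime_us`,
#' `spectral_integral_counts`; all property values must be non-negative.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_property_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("complex_id", "em5050_eV", "lifetime_us",
           "spectral_integral_counts")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("property table missing column(s): ",
                         paste(miss, collapse = ", "))
  num <- as.matrix(df[, req[-1]])
  if (any(num < 0, na.rm = TRUE)) stop("negative property values")
  df
}
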