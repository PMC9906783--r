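#' Circular (Morgan-style) fingerprint of a ligand
#'
#' A hashed circular substructure fingerprint computed directly on the
#' explicit-hydrogen molecular graph. Each atom starts from an invariant
#' built from its element and degree; `radius` rounds of neighborhood
#' hashing (each round folds the sorted neighbor identifiers into the
#' atom's identifier) enumerate circular environments of bond radius
#' 0..`radius`, and every environment identifier is hashed onto one of
#' `nbits` bits. The scheme is deterministic and platform-independent.
#'
#' @param ligand a `ligand` object (fingerprinted in its stored, neutral
#'   protonated form), or a bare `molgraph`.
#' @param radius circular environment radius in bonds (default 3).
#' @param nbits fingerprint length in bits (default 2048).
#' @return object of class `fingerprint`: logical vector with attributes
#'   `radius` and `nbits`.
#' @export
morgan_fingerprint <- function(ligand, radius = 3, nbits = 2048) {
  g <- if (inherits(ligand, "ligand")) ligand$graph else ligand
  stopifnot(inherits(g, "molgraph"))
  n <- length(g$elements)
  if (n == 0) stop("cannot fingerprint an empty molecule")
  deg <- graph_degree(g)
  z <- atom_properties(g, "Z")
  nbrs <- graph_neighbors(g)
  inv <- .fp_hash_rows(cbind(z, deg))
  bits <- rep(FALSE, nbits)
  set_bits <- function(ids) {
    idx <- (ids %% nbits) + 1L
    bits[idx] <<- TRUE
  }
  set_bits(inv)
  if (radius >= 1) {
    for (r in seq_len(radius)) {
      inv <- vapply(seq_len(n), function(i) {
        .fp_hash_int(c(inv[i], sort(inv[nbrs[[i]]])))
      }, numeric(1))
      set_bits(inv)
    }
  }
  structure(bits, radius = radius, nbits = nbits, class = "fingerprint")
}

# deterministic 31-bit polynomial hash of an integer vector
.fp_hash_int <- function(v) {
  h <- 17
  m <- 2147483647
  for (x in v) h <- (h * 31 + (x %% m)) %% m
  h
}

.fp_hash_rows <- function(mat) {
  apply(mat, 1, .fp_hash_int)
}

#' @export
print.fingerprint <- function(x, ...) {
  cat("<fingerprint> ", attr(x, "nbits"), " bits, radius ", attr(x, "radius"),
      ", popcount ", sum(x), "\n", sep = "")
  invisible(x)
}

.check_fp_pair <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint lengths differ")
}

#' Dice similarity of two fingerprints
#'
#' `2|a AND b| / (|a| + |b|)`, in `[0, 1]`. The degenerate all-zero pair
#' returns 1 when both fingerprints are empty and 0 when only one is
#' (documented convention).
#'
#' @param a,b fingerprints (logical vectors) of equal length.
#' @return similarity in `[0, 1]`.
#' @export
dice_similarity <- function(a, b) {
  .check_fp_pair(a, b)
  pa <- sum(a); pb <- sum(b)
  if (pa + pb == 0) return(1)
  2 * sum(a & b) / (pa + pb)
}

#' Tanimoto similarity of two fingerprints
#'
#' `|a AND b| / |a OR b|`. Same degenerate conventions as
#' [dice_similarity()]. For any pair, Dice = 2T/(1 + T) >= Tanimoto.
#'
#' @inheritParams dice_similarity
#' @return similarity in `[0, 1]`.
#' @export
tanimoto_similarity <- function(a, b) {
  .check_fp_pair(a, b)
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Build a similarity feature schema from reference ligands
#'
#' Fixes the ordered reference CN and NN ligand ids (typically the
#' training-set portion of the high-throughput ligand set) and precomputes
#' their fingerprints. The resulting feature length is
#' `|reference CN| + |reference NN|` and is independent of later queries;
#' in grouped splits, held-out ligands are excluded from the schema so no
#' information about them leaks into the representation.
#'
#' @param library a `ligand_library`.
#' @param cn_ids,nn_ids ordered reference ids (defaults: all ids of each
#'   role in the library).
#' @param radius,nbits fingerprint parameters.
#' @return object of class `similarity_schema`.
#' @export
similarity_schema <- function(library, cn_ids = names(library$cn),
                              nn_ids = names(library$nn),
                              radius = 3, nbits = 2048) {
  fp <- function(ids) lapply(ids, function(id)
    morgan_fingerprint(get_ligand(library, id), radius, nbits))
  structure(
    list(cn_ids = cn_ids, nn_ids = nn_ids,
         cn_fps = stats::setNames(fp(cn_ids), cn_ids),
         nn_fps = stats::setNames(fp(nn_ids), nn_ids),
         radius = radius, nbits = nbits),
    class = "similarity_schema"
  )
}

#' Dice similarity features of a complex against a reference schema
#'
#' The complex's CN ligand fingerprint is compared to every reference CN
#' fingerprint and its NN ligand to every reference NN fingerprint, CN block
#' first, giving `|reference CN| + |reference NN|` features.
#'
#' @param cn,nn `ligand` objects of the complex.
#' @param schema a `similarity_schema`.
#' @param metric `"dice"` (default) or `"tanimoto"`.
#' @return named numeric feature vector.
#' @export
dice_features <- function(cn, nn, schema, metric = c("dice", "tanimoto")) {
  metric <- match.arg(metric)
  simfun <- if (metric == "dice") dice_similarity else tanimoto_similarity
  fcn <- morgan_fingerprint(cn, schema$radius, schema$nbits)
  fnn <- morgan_fingerprint(nn, schema$radius, schema$nbits)
  v <- c(
    vapply(schema$cn_fps, function(r) simfun(fcn, r), numeric(1)),
    vapply(schema$nn_fps, function(r) simfun(fnn, r), numeric(1))
  )
  names(v) <- c(paste0("cn_", metric, "_", schema$cn_ids),
                paste0("nn_", metric, "_", schema$nn_ids))
  v
}

#' Concatenated Morgan fingerprint features of a complex
#'
#' CN ligand fingerprint bits followed by NN ligand bits (`2 * nbits`
#' columns).
#'
#' @inheritParams dice_features
#' @param radius,nbits fingerprint parameters.
#' @return named 0/1 numeric vector of length `2 * nbits`.
#' @export
morgan_features <- function(cn, nn, radius = 3, nbits = 2048) {
  v <- c(as.numeric(morgan_fingerprint(cn, radius, nbits)),
         as.numeric(morgan_fingerprint(nn, radius, nbits)))
  names(v) <- c(paste0("cn_bit", seq_len(nbits)), paste0("nn_bit", seq_len(nbits)))
  v
}
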