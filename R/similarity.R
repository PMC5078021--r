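#' Compute circular fingerprints for a compound set
#'
#' Computes hashed extended-connectivity fingerprints (ECFP, Morgan
#' algorithm) with a circular atom-neighborhood diameter of 4 by default,
#' through OpenBabel.  The hash space is 4096 bits.  Fingerprinting is
#' deterministic: the same structure (under any SMILES canonicalization)
#' always maps to the same bit set.
#'
#' @param compounds Data frame from [read_compounds()] (columns
#'   `compound_id`, `smiles`) or a named character vector of SMILES.
#' @param diameter Circular neighborhood diameter (an even integer; 4 gives
#'   ECFP_4).
#' @return An object of class `"tlsea_fp_set"`: a list with `bits` (per
#'   compound, the sorted 0-based on-bit indices), `nbits`, `diameter` and
#'   `compound_id`.
#' @examples
#' \donttest{
#' fps <- compound_fingerprints(c(benzene = "c1ccccc1", pyridine = "c1ccncc1"))
#' tanimoto(fps[[1]], fps[[2]])
#' }
#' @export
compound_fingerprints <- function(compounds, diameter = 4) {
  stopifnot(diameter %% 2 == 0, diameter >= 0)
  if (is.data.frame(compounds)) {
    smi <- stats::setNames(compounds$smiles, compounds$compound_id)
  } else {
    smi <- compounds
    if (is.null(names(smi))) names(smi) <- sprintf("cmpd%05d", seq_along(smi))
  }
  sdf <- tryCatch(ChemmineR::smiles2sdf(smi), error = function(e)
    stop("unparseable structure among: ", paste(names(smi), collapse = ", ")))
  valid <- ChemmineR::validSDF(sdf)
  if (!all(valid))
    stop("unparseable structure for compound_id: ",
         paste(names(smi)[!valid], collapse = ", "))
  fp <- ChemmineR::fingerprintOB(sdf, sprintf("ECFP%d", diameter))
  m <- fp@fpma
  bits <- lapply(seq_len(nrow(m)), function(i) which(m[i, ] != 0) - 1L)
  structure(list(bits = bits, nbits = ncol(m), diameter = as.integer(diameter),
                 compound_id = names(smi)),
            class = "tlsea_fp_set")
}

#' @export
print.tlsea_fp_set <- function(x, ...) {
  cat(sprintf("ECFP_%d fingerprint set: %d compounds, %d-bit hash space\n",
              x$diameter, length(x$bits), x$nbits))
  invisible(x)
}

#' @export
length.tlsea_fp_set <- function(x) length(x$bits)

#' Extract one fingerprint from a fingerprint set
#'
#' @param fps A `"tlsea_fp_set"` object.
#' @param i Index or compound identifier.
#' @return A list with `compound_id`, `bits`, `nbits`, `diameter`.
#' @export
fingerprint <- function(fps, i) {
  if (is.character(i)) i <- match(i, fps$compound_id)
  if (is.na(i) || i < 1L || i > length(fps$bits)) stop("unknown fingerprint index")
  list(compound_id = fps$compound_id[i], bits = fps$bits[[i]],
       nbits = fps$nbits, diameter = fps$diameter)
}

#' Tanimoto similarity of two fingerprints
#'
#' Implements S_t = C / (A + B - C), where A and B are the on-bit counts of
#' the two fingerprints and C the number of shared on bits.  Two empty bit
#' sets have similarity 0 by convention.
#'
#' @param a,b Fingerprints as returned by [fingerprint()] (lists with
#'   `bits`, `nbits`, `diameter`), or plain integer vectors of on-bit
#'   indices.
#' @return Similarity in [0, 1].
#' @examples
#' tanimoto(c(1, 2, 3, 4), c(3, 4, 5))  # C=2, A=4, B=3 -> 0.4
#' @export
tanimoto <- function(a, b) {
  if (is.list(a) || is.list(b)) {
    stopifnot(is.list(a), is.list(b))
    if (a$nbits != b$nbits || a$diameter != b$diameter)
      stop("mismatched fingerprint parameters (nbits/diameter)")
    a <- a$bits; b <- b$bits
  }
  A <- length(a); B <- length(b)
  C <- length(intersect(a, b))
  if (A + B - C == 0L) return(0)
  C / (A + B - C)
}

# Dense 0/1 bit matrix (rows = compounds) from a fingerprint set.
bit_matrix <- function(fps) {
  m <- matrix(0, nrow = length(fps$bits), ncol = fps$nbits)
  for (i in seq_along(fps$bits)) m[i, fps$bits[[i]] + 1L] <- 1
  m
}

#' Build a Tanimoto similarity matrix
#'
#' Computes the full pairwise Tanimoto matrix between two fingerprint sets;
#' rows correspond to the target library, columns to the phenotype actives.
#' Entries agree exactly with element-wise [tanimoto()] calls; the matrix is
#' computed in double precision via blocked bit-matrix products.
#'
#' @param rows,cols `"tlsea_fp_set"` objects with identical `nbits` and
#'   `diameter`.
#' @param block_rows Number of rows per computation block (memory control;
#'   identical numeric results for any blocking).
#' @return Numeric matrix `length(rows)` x `length(cols)` with compound
#'   identifiers as dimnames.
#' @export
build_similarity_matrix <- function(rows, cols, block_rows = 1024L) {
  stopifnot(inherits(rows, "tlsea_fp_set"), inherits(cols, "tlsea_fp_set"))
  if (length(rows) == 0L || length(cols) == 0L)
    stop("build_similarity_matrix: empty fingerprint set")
  if (rows$nbits != cols$nbits || rows$diameter != cols$diameter)
    stop("mismatched fingerprint parameters (nbits/diameter)")
  Bc <- bit_matrix(cols)
  nb <- vapply(cols$bits, length, 0L)
  S <- matrix(0, length(rows), length(cols),
              dimnames = list(rows$compound_id, cols$compound_id))
  idx <- split(seq_len(length(rows)),
               ceiling(seq_len(length(rows)) / block_rows))
  for (chunk in idx) {
    Ar <- bit_matrix(list(bits = rows$bits[chunk], nbits = rows$nbits))
    na <- vapply(rows$bits[chunk], length, 0L)
    C <- tcrossprod(Ar, Bc)                       # shared on-bit counts
    denom <- outer(na, nb, `+`) - C
    Sc <- C / denom
    Sc[denom == 0] <- 0
    S[chunk, ] <- Sc
  }
  S
}

#' Slice the rows of a similarity matrix for one protein's ligand set
#'
#' Extracts the row vectors of a full target-vs-phenotype similarity matrix
#' that correspond to one protein's ligands, giving the per-protein
#' sub-matrix the initial scores are computed from.
#'
#' @param M Similarity matrix with row names.
#' @param ligands Character vector of ligand compound identifiers (or a
#'   list with a `compound_ids` field).
#' @return The row slice of `M`, all columns, in ligand order.
#' @export
slice_target_matrix <- function(M, ligands) {
  if (is.list(ligands) && !is.null(ligands$compound_ids))
    ligands <- ligands$compound_ids
  missing <- setdiff(ligands, rownames(M))
  if (length(missing) > 0L)
    stop("ligand ids missing from similarity matrix: ",
         paste(missing, collapse = ", "))
  M[ligands, , drop = FALSE]
}

#' Build the random background similarity matrix
#'
#' Samples `n_rows` compounds from a background library (already filtered by
#' the same property window as the target library) and computes their
#' similarities against the phenotype actives.  Row selection is
#' reproducible under `seed`.
#'
#' @param background `"tlsea_fp_set"` of the background library, or a
#'   compound data frame (then `window_mw`/`window_alogp` are applied and
#'   fingerprints computed).
#' @param cols `"tlsea_fp_set"` of the phenotype actives.
#' @param n_rows Number of background rows to sample; `NULL` uses the whole
#'   background.
#' @param seed Integer seed for the row selection.
#' @param window_mw,window_alogp Property windows applied when `background`
#'   is a compound data frame.
#' @param diameter Fingerprint diameter used when fingerprints must be
#'   computed.
#' @return Similarity matrix (`n_rows` x `length(cols)`).
#' @export
build_random_matrix <- function(background, cols, n_rows = NULL, seed = 1L,
                                window_mw = NULL, window_alogp = NULL,
                                diameter = 4) {
  if (is.data.frame(background)) {
    if (!is.null(window_mw) && !is.null(window_alogp))
      background <- property_filter(background, window_mw, window_alogp)
    background <- compound_fingerprints(background, diameter = diameter)
  }
  n <- length(background)
  if (is.null(n_rows)) n_rows <- n
  if (n_rows > n)
    stop("background smaller than requested sample (", n, " < ", n_rows, ")")
  set.seed(substream_seed(seed, "random_matrix"))
  pick <- sort(sample.int(n, n_rows))
  sub <- structure(list(bits = background$bits[pick], nbits = background$nbits,
                        diameter = background$diameter,
                        compound_id = background$compound_id[pick]),
                   class = "tlsea_fp_set")
  build_similarity_matrix(sub, cols)
}
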