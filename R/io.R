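#' Read a compound library from a SMILES table or SDF file
#'
#' SMILES tables are whitespace-delimited with two columns, SMILES string and
#' compound identifier, no header.  SDF input is V2000, with the identifier
#' taken from the molecule title block.  Every structure is parsed and
#' sanitized with OpenBabel (via ChemmineR); records that fail to parse, or
#' that repeat an identifier already seen in the same file, are rejected with
#' a logged reason rather than aborting the read.  Molecular weight and AlogP
#' are computed for each accepted structure.
#'
#' @param path Path to the input file.
#' @param format `"smiles"` or `"sdf"`.
#' @param library Which library the compounds belong to: `"phenotype"`,
#'   `"target"` or `"random_background"`.  Identifiers are unique within a
#'   library only; the same structure may legitimately occur in more than one
#'   library.
#' @param compute_properties Compute `mol_weight` and `alogp` (default TRUE).
#' @return A data frame with columns `compound_id`, `smiles`, `library`,
#'   `mol_weight`, `alogp`, plus an attribute `"rejected"` (data frame of
#'   `compound_id`, `reason`).
#' @seealso [read_activities()], [compound_fingerprints()]
#' @export
read_compounds <- function(path, format = c("smiles", "sdf"),
                           library = c("phenotype", "target", "random_background"),
                           compute_properties = TRUE) {
  format <- match.arg(format)
  library <- match.arg(library)
  if (!file.exists(path)) stop("compound file not found: ", path)

  rejected <- data.frame(compound_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  reject <- function(id, reason) {
    rejected[nrow(rejected) + 1L, ] <<- list(id, reason)
  }

  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("zero parseable structures in ", path)
    parts <- strsplit(trimws(lines), "[[:space:]]+")
    smi <- vapply(parts, `[`, "", 1L)
    ids <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else NA_character_, "")
    ids[is.na(ids)] <- sprintf("cmpd%05d", which(is.na(ids)))
    parses <- function(s, id) {
      m <- tryCatch(ChemmineR::smiles2sdf(stats::setNames(s, id)),
                    error = function(e) NULL)
      !is.null(m) && length(m) == 1L && ChemmineR::validSDF(m)
    }
    keep <- logical(length(smi))
    seen <- character()
    for (i in seq_along(smi)) {
      if (ids[i] %in% seen) { reject(ids[i], "duplicate compound_id"); next }
      if (!parses(smi[i], ids[i])) { reject(ids[i], "unparseable SMILES"); next }
      keep[i] <- TRUE
      seen <- c(seen, ids[i])
    }
    if (!any(keep)) stop("zero parseable structures in ", path)
    sdfset <- ChemmineR::smiles2sdf(stats::setNames(smi[keep], ids[keep]))
    out_ids <- ids[keep]
    out_smiles <- smi[keep]
  } else {
    sdfset <- ChemmineR::read.SDFset(path)
    if (length(sdfset) == 0L) stop("zero parseable structures in ", path)
    ids <- ChemmineR::sdfid(sdfset)
    valid <- ChemmineR::validSDF(sdfset)
    dup <- duplicated(ids)
    for (i in which(!valid)) reject(ids[i], "invalid SDF record")
    for (i in which(dup & valid)) reject(ids[i], "duplicate compound_id")
    keep <- valid & !dup
    if (!any(keep)) stop("zero parseable structures in ", path)
    sdfset <- sdfset[keep]
    out_ids <- ids[keep]
    out_smiles <- as.character(ChemmineR::sdf2smiles(sdfset))
  }

  mw <- alogp <- rep(NA_real_, length(out_ids))
  if (compute_properties) {
    props <- ChemmineR::propOB(sdfset)
    mw <- as.numeric(props$MW)
    alogp <- as.numeric(props$logP)
  }
  if (nrow(rejected) > 0L)
    tlsea_log("read_compounds(%s): %d accepted, %d rejected", basename(path),
              length(out_ids), nrow(rejected))
  out <- data.frame(compound_id = out_ids, smiles = out_smiles,
                    library = library, mol_weight = mw, alogp = alogp,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

ENDPOINTS <- c("GI50", "Ki", "IC50", "Kd", "EC50")
PROTEIN_ENDPOINTS <- c("Ki", "IC50", "Kd", "EC50")

#' Read an activity table
#'
#' Reads a CSV or TSV table with columns `compound_id`, `target_id`,
#' `endpoint` and `value_mol_per_L`.  Endpoints must be one of GI50 (cell
#' lines) or Ki/IC50/Kd/EC50 (proteins); values must be positive reals in
#' mol/L.  Rows violating either rule are rejected with a logged reason; if
#' every row is rejected the read fails.
#'
#' @param path Path to the table; the delimiter is taken from the extension
#'   (`.csv` means comma, anything else tab).
#' @return A data frame of typed activity records with an attribute
#'   `"rejected"` counting discarded rows.
#' @export
read_activities <- function(path) {
  if (!file.exists(path)) stop("activity file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", quote = "",
                           stringsAsFactors = FALSE, comment.char = "")
  need <- c("compound_id", "target_id", "endpoint", "value_mol_per_L")
  if (!all(need %in% names(raw)))
    stop("activity table must have columns: ", paste(need, collapse = ", "))
  raw <- raw[, need]
  val <- suppressWarnings(as.numeric(raw$value_mol_per_L))
  bad_value <- is.na(val) | val <= 0
  bad_endpoint <- !(raw$endpoint %in% ENDPOINTS)
  bad <- bad_value | bad_endpoint
  if (any(bad))
    tlsea_log("read_activities(%s): rejected %d of %d rows (%d bad value, %d unknown endpoint)",
              basename(path), sum(bad), nrow(raw), sum(bad_value), sum(bad_endpoint))
  out <- data.frame(compound_id = raw$compound_id[!bad],
                    target_id = raw$target_id[!bad],
                    endpoint = raw$endpoint[!bad],
                    value_mol_per_L = val[!bad],
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0L) stop("all activity rows rejected in ", path)
  rownames(out) <- NULL
  attr(out, "rejected") <- sum(bad)
  out
}

#' Write an activity table
#'
#' Writes records in the exact format [read_activities()] reads, with full
#' numeric precision so that a write/read round trip reproduces the records
#' exactly.
#'
#' @param activities Data frame as returned by [read_activities()].
#' @param path Output path (`.csv` for comma-separated, else tab).
#' @return `path`, invisibly.
#' @export
write_activities <- function(activities, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- activities
  out$value_mol_per_L <- sprintf("%.17g", out$value_mol_per_L)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the per-protein association table
#'
#' Writes a TSV with columns `protein_id`, `O`, `P_O`, `rank`, ordered by
#' ascending `P_O` with ties broken by protein identifier, so rank 1 is the
#' strongest association.
#'
#' @param result A fitted [tlsea()] object, or its `$scores` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(result, path) {
  scores <- if (inherits(result, "tlsea")) result$scores else result
  cols <- c("protein_id", "O", "P_O", "rank")
  if (nrow(scores) > 0L) {
    stopifnot(all(cols %in% names(scores)))
    scores <- scores[order(scores$P_O, scores$protein_id), cols]
    scores$O <- sprintf("%.17g", scores$O)
    scores$P_O <- sprintf("%.17g", scores$P_O)
  } else {
    scores <- data.frame(protein_id = character(), O = character(),
                         P_O = character(), rank = integer())
  }
  utils::write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write dense similarity matrices
#'
#' Matrices are stored as TSV with column identifiers in the header and row
#' identifiers in the first column, at full double precision (a write/read
#' round trip is exact).
#'
#' @param M Numeric matrix with row and column names (rows: target-library
#'   compounds; columns: phenotype actives).
#' @param path File path.
#' @return `write_similarity_matrix()` returns `path` invisibly;
#'   `read_similarity_matrix()` returns the matrix.
#' @export
write_similarity_matrix <- function(M, path) {
  stopifnot(is.matrix(M), !is.null(rownames(M)), !is.null(colnames(M)))
  df <- data.frame(compound_id = rownames(M),
                   matrix(sprintf("%.17g", M), nrow = nrow(M),
                          dimnames = list(NULL, colnames(M))),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_similarity_matrix
#' @export
read_similarity_matrix <- function(path) {
  if (!file.exists(path)) stop("similarity matrix file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(M) <- "double"
  rownames(M) <- df[[1]]
  if (any(M < 0 | M > 1)) stop("similarity entries outside [0, 1] in ", path)
  M
}
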