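#' Select phenotype-active compounds by pGI50
#'
#' A compound is phenotype-active when its pGI50 (= -log10 of the GI50 in
#' mol/L) is strictly greater than `pgi50_min`.  When a compound has several
#' GI50 measurements they are first aggregated; the default policy keeps the
#' most potent value (smallest GI50), so a compound is active if any
#' measurement qualifies.
#'
#' @param activities Data frame of activity records, all with endpoint GI50.
#' @param pgi50_min Activity threshold on the pGI50 scale (default 6, i.e.
#'   GI50 below 1e-6 mol/L).
#' @param aggregate How to combine repeated measurements per compound:
#'   `"most_potent"` (minimum GI50) or `"mean"` (arithmetic mean GI50).
#' @return Character vector of active compound identifiers, in first-seen
#'   order.
#' @examples
#' acts <- data.frame(compound_id = c("a", "b"), target_id = "CELL",
#'                    endpoint = "GI50", value_mol_per_L = c(1e-7, 1e-6))
#' phenotype_active_filter(acts)  # "a" only: pGI50 must exceed 6 strictly
#' @export
phenotype_active_filter <- function(activities, pgi50_min = 6,
                                    aggregate = c("most_potent", "mean")) {
  aggregate <- match.arg(aggregate)
  if (nrow(activities) == 0L) return(character())
  if (!all(activities$endpoint == "GI50"))
    stop("phenotype_active_filter: all records must have endpoint GI50")
  stopifnot(all(activities$value_mol_per_L > 0))
  f <- switch(aggregate, most_potent = min, mean = mean)
  agg <- tapply(activities$value_mol_per_L, activities$compound_id, f)
  pgi50 <- -log10(agg)
  active <- names(agg)[pgi50 > pgi50_min]
  # restore first-seen input order
  active[order(match(active, activities$compound_id))]
}

#' Select active compound-protein pairs from binding data
#'
#' A (compound, protein) pair is active when any of its endpoint values
#' (Ki, IC50, Kd or EC50) is strictly smaller than `threshold_mol_per_L`.
#'
#' @param activities Data frame of activity records with protein endpoints.
#' @param threshold_mol_per_L Activity cutoff in mol/L (default 1e-6).
#' @return Data frame with columns `compound_id`, `protein_id`, one row per
#'   active pair, in first-seen order.
#' @export
target_active_filter <- function(activities, threshold_mol_per_L = 1e-6) {
  if (nrow(activities) == 0L)
    return(data.frame(compound_id = character(), protein_id = character(),
                      stringsAsFactors = FALSE))
  if (any(activities$endpoint == "GI50"))
    stop("target_active_filter: GI50 records are phenotype endpoints")
  if (!all(activities$endpoint %in% PROTEIN_ENDPOINTS))
    stop("target_active_filter: unknown endpoint")
  hit <- activities$value_mol_per_L < threshold_mol_per_L
  pairs <- unique(activities[hit, c("compound_id", "target_id")])
  names(pairs)[2] <- "protein_id"
  rownames(pairs) <- NULL
  pairs
}

#' Filter compounds by physicochemical property windows
#'
#' Keeps compounds whose molecular weight and AlogP both fall inside closed
#' intervals (the published windows were MW [150, 750] / AlogP [2, 7] for
#' K562 and MW [200, 800] / AlogP [-3, 8] for MCF7 and A549).  Compounds
#' with a missing (uncomputable) property are rejected with a logged count.
#'
#' @param compounds Data frame from [read_compounds()] (needs `mol_weight`
#'   and `alogp` columns).
#' @param mw_window Closed interval `[min, max]` in daltons.
#' @param alogp_window Closed interval `[min, max]`, unitless.
#' @return The filtered compound data frame.
#' @export
property_filter <- function(compounds, mw_window = c(150, 750),
                            alogp_window = c(2, 7)) {
  stopifnot(length(mw_window) == 2L, mw_window[1] < mw_window[2],
            length(alogp_window) == 2L, alogp_window[1] < alogp_window[2])
  missing_prop <- is.na(compounds$mol_weight) | is.na(compounds$alogp)
  if (any(missing_prop))
    tlsea_log("property_filter: %d compounds rejected (uncomputable property)",
              sum(missing_prop))
  keep <- !missing_prop &
    compounds$mol_weight >= mw_window[1] & compounds$mol_weight <= mw_window[2] &
    compounds$alogp >= alogp_window[1] & compounds$alogp <= alogp_window[2]
  out <- compounds[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble protein ligand sets
#'
#' Groups active (compound, protein) pairs into per-protein ligand sets,
#' optionally restricted to a filtered compound universe, and drops proteins
#' with fewer than `min_ligands` distinct ligands (10 in the published
#' protocol).
#'
#' @param pairs Data frame with columns `compound_id`, `protein_id` (from
#'   [target_active_filter()]).
#' @param compounds Optional data frame (or character vector) of allowed
#'   compound identifiers; pairs outside it are dropped first.
#' @param min_ligands Minimum distinct ligands per retained protein.
#' @return Named list (protein_id -> character vector of compound ids, in
#'   first-seen order, no duplicates), sorted by protein identifier.
#' @export
build_ligand_sets <- function(pairs, compounds = NULL, min_ligands = 10) {
  if (!is.null(compounds)) {
    ids <- if (is.data.frame(compounds)) compounds$compound_id else compounds
    pairs <- pairs[pairs$compound_id %in% ids, , drop = FALSE]
  }
  pairs <- unique(pairs[, c("compound_id", "protein_id")])
  sets <- split(pairs$compound_id, pairs$protein_id)
  small <- vapply(sets, length, 0L) < min_ligands
  if (any(small))
    tlsea_log("build_ligand_sets: dropped %d proteins with fewer than %d ligands",
              sum(small), min_ligands)
  sets <- sets[!small]
  sets[order(names(sets))]
}
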