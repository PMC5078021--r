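#' Simulate a similarity-matrix study with known ground truth
#'
#' Generates the statistical layer of a target-deconvolution study directly
#' at the similarity-matrix level, bypassing chemistry, so the ensemble
#' statistics can be exercised fast and with exact ground truth.  The null
#' similarity model emulates what is seen between unrelated drug-like
#' compounds under ECFP4/Tanimoto: the bulk of pairwise similarities sits
#' well below the 0.15 noise threshold (Beta(`shape1`, `shape2`), by default
#' mean 0.07), with a thin tail of moderately similar pairs (with
#' probability `tail_prob` an entry is replaced by a uniform draw from
#' `tail_range`).  Under these defaults the fitted background slope k (the
#' mean thresholded similarity contribution per random ligand) is about
#' 0.009, the order of the published background constants.
#'
#' Planted associations emulate ligand sets that genuinely overlap the
#' phenotype's chemistry: for a planted protein with overlap fraction f,
#' `round(f * m)` of its m ligand rows are near-duplicates of one phenotype
#' compound each, i.e. that row/column cell is drawn from `mimic_range`
#' (high Tanimoto, as between close analogues or identical structures).
#'
#' @param n_phenotype Number of phenotype-active compounds (columns).
#' @param n_proteins Number of proteins (their ligand rows are disjoint).
#' @param ligand_size_range Integer range of ligand-set sizes.
#' @param planted Named numeric vector: protein identifier (must be one of
#'   the generated `PR..` ids) -> overlap fraction in [0, 1].  `NULL` for a
#'   null-only universe.
#' @param n_background Number of random background rows (M_r).
#' @param baseline List with `shape1`, `shape2`, `tail_prob`, `tail_range`
#'   describing the null similarity distribution.
#' @param mimic_range Similarity range for planted near-duplicate cells.
#' @param seed Integer seed; the whole universe is reproducible from it.
#' @return A list of class `"tlsea_simulation"`: `M` (target rows x
#'   phenotype columns), `M_r`, `ligand_sets` (named list of row ids), and
#'   `manifest` (planted cells, parameters, seed).
#' @examples
#' sim <- simulate_similarity_study(n_phenotype = 30, n_proteins = 4,
#'                                  planted = c(PR01 = 0.4), seed = 1)
#' sapply(sim$ligand_sets, length)
#' @export
simulate_similarity_study <- function(n_phenotype = 100,
                                      n_proteins = 20,
                                      ligand_size_range = c(10, 30),
                                      planted = NULL,
                                      n_background = 500,
                                      baseline = list(shape1 = 3, shape2 = 40,
                                                      tail_prob = 0.01,
                                                      tail_range = c(0.15, 0.40)),
                                      mimic_range = c(0.85, 1.0),
                                      seed = 1L) {
  stopifnot(n_phenotype >= 1, n_proteins >= 1, n_background >= 1,
            length(ligand_size_range) == 2L,
            ligand_size_range[1] >= 1,
            ligand_size_range[2] >= ligand_size_range[1])
  if (!is.null(planted)) {
    stopifnot(!is.null(names(planted)), all(planted >= 0), all(planted <= 1))
  }
  set.seed(substream_seed(seed, "fixture"))
  rnull <- function(n) {
    x <- rbeta(n, baseline$shape1, baseline$shape2)
    tail <- runif(n) < baseline$tail_prob
    x[tail] <- runif(sum(tail), baseline$tail_range[1], baseline$tail_range[2])
    x
  }
  proteins <- sprintf("PR%02d", seq_len(n_proteins))
  if (!is.null(planted) && !all(names(planted) %in% proteins))
    stop("planted protein ids must be among: ", proteins[1], " .. ",
         proteins[n_proteins])
  span <- seq.int(ligand_size_range[1], ligand_size_range[2])
  sizes <- span[sample.int(length(span), n_proteins, replace = TRUE)]
  n_rows <- sum(sizes)
  row_ids <- sprintf("BD%05d", seq_len(n_rows))
  col_ids <- sprintf("NC%05d", seq_len(n_phenotype))
  blocks <- split(row_ids, rep(seq_len(n_proteins), sizes))
  ligand_sets <- stats::setNames(blocks, proteins)

  M <- matrix(rnull(n_rows * n_phenotype), n_rows, n_phenotype,
              dimnames = list(row_ids, col_ids))
  mimic_cells <- data.frame(protein_id = character(), row = character(),
                            col = character(), stringsAsFactors = FALSE)
  for (pid in names(planted)) {
    m <- length(ligand_sets[[pid]])
    n_mimic <- round(planted[[pid]] * m)
    if (n_mimic == 0L) next
    if (n_mimic > m || n_mimic > n_phenotype)
      stop("infeasible planted overlap for ", pid,
           ": more mimics than rows or columns")
    rows <- sample(ligand_sets[[pid]], n_mimic)
    cols <- sample(col_ids, n_mimic)
    M[cbind(rows, cols)] <- runif(n_mimic, mimic_range[1], mimic_range[2])
    mimic_cells <- rbind(mimic_cells,
                         data.frame(protein_id = pid, row = rows, col = cols,
                                    stringsAsFactors = FALSE))
  }
  M_r <- matrix(rnull(n_background * n_phenotype), n_background, n_phenotype,
                dimnames = list(sprintf("RB%05d", seq_len(n_background)),
                                col_ids))
  structure(list(M = M, M_r = M_r, ligand_sets = ligand_sets,
                 manifest = list(planted = planted,
                                 mimic_cells = mimic_cells,
                                 baseline = baseline,
                                 mimic_range = mimic_range,
                                 ligand_sizes = stats::setNames(sizes, proteins),
                                 seed = seed)),
            class = "tlsea_simulation")
}

#' @export
print.tlsea_simulation <- function(x, ...) {
  cat(sprintf("simulated similarity study: %d x %d target matrix, %d x %d background\n",
              nrow(x$M), ncol(x$M), nrow(x$M_r), ncol(x$M_r)))
  cat(sprintf("  %d proteins (ligand sets of %d-%d); planted: %s\n",
              length(x$ligand_sets), min(x$manifest$ligand_sizes),
              max(x$manifest$ligand_sizes),
              if (length(x$manifest$planted))
                paste(names(x$manifest$planted), collapse = ", ")
              else "none"))
  invisible(x)
}

# -- structure-level generator ------------------------------------------------

# Small fragment grammar over chain and ring units; every assembled string
# is valid SMILES (ring-closure digits are allocated per molecule).
random_smiles <- function(n_units) {
  chain <- c("C", "CC", "CCC", "O", "N", "C(C)", "C(=O)", "C(=O)O", "S",
             "C(F)", "C(Cl)")
  ring <- c("c%dccccc%d", "c%dccncc%d", "C%dCCCCC%d", "C%dCCNCC%d")
  ring_no <- 0L
  units <- character(n_units)
  for (i in seq_len(n_units)) {
    if (runif(1) < 0.25 && ring_no < 8L) {
      ring_no <- ring_no + 1L
      units[i] <- sprintf(sample(ring, 1L), ring_no, ring_no)
    } else {
      units[i] <- sample(chain, 1L)
    }
  }
  paste(units, collapse = "")
}

#' Simulate a structure-level compound universe with known ground truth
#'
#' Generates two compound libraries (phenotype screen and protein-ligand
#' database) as valid SMILES from a small fragment grammar, together with
#' activity tables whose pass/fail status under the standard filters is
#' known by construction, and a manifest recording the ground truth.  This
#' is the end-to-end fixture: it exercises parsing, property computation,
#' fingerprints and filtering, not just the statistics.
#'
#' Phenotype activities are GI50 values planted so that exactly
#' `n_phenotype_active` compounds have pGI50 strictly above 6.  Protein
#' ligands get one active endpoint (Ki/IC50/Kd/EC50 below 1e-6 mol/L) each;
#' for a planted protein with overlap fraction f, `round(f * m)` of its m
#' ligands reuse the structure of a phenotype-active compound (under a new
#' target-library identifier), giving Tanimoto 1 pairs.  Optionally a count
#' of malformed activity rows (non-numeric, non-positive, or unknown
#' endpoint) is appended for exercising the I/O rejection paths.
#'
#' @param n_phenotype Total phenotype-library size.
#' @param n_phenotype_active Number of planted phenotype actives.
#' @param n_proteins Number of proteins.
#' @param ligand_size_range Integer range of ligand-set sizes.
#' @param planted Named numeric vector of overlap fractions, names in
#'   `PR01..`; `NULL` for none.
#' @param n_background Size of the random background library.
#' @param n_malformed Number of malformed rows appended to the target
#'   activity table.
#' @param seed Integer seed.
#' @param dir If non-`NULL`, the universe is also written there as plain
#'   files: `phenotype.smi`, `target.smi`, `background.smi` (SMILES tables),
#'   `phenotype_activities.tsv`, `target_activities.tsv`, and
#'   `manifest.yaml`.
#' @return A list of class `"tlsea_universe"`: `phenotype`, `target`,
#'   `background` (data frames with `compound_id`, `smiles`),
#'   `phenotype_activities`, `target_activities`, and `manifest` (active
#'   ids, ligand sets, planted copies, malformed count, seed).
#' @export
simulate_compound_universe <- function(n_phenotype = 60,
                                       n_phenotype_active = 30,
                                       n_proteins = 5,
                                       ligand_size_range = c(10, 15),
                                       planted = NULL,
                                       n_background = 80,
                                       n_malformed = 0,
                                       seed = 1L,
                                       dir = NULL) {
  stopifnot(n_phenotype_active <= n_phenotype, n_proteins >= 1)
  if (!is.null(planted))
    stopifnot(!is.null(names(planted)), all(planted >= 0), all(planted <= 1))
  set.seed(substream_seed(seed, "fixture_structures"))

  gen_lib <- function(n, prefix) {
    data.frame(compound_id = sprintf("%s%05d", prefix, seq_len(n)),
               smiles = vapply(seq_len(n),
                               function(i) random_smiles(sample(4:10, 1L)), ""),
               stringsAsFactors = FALSE)
  }
  pheno <- gen_lib(n_phenotype, "NC")
  background <- gen_lib(n_background, "RB")

  active_ids <- sample(pheno$compound_id, n_phenotype_active)
  gi50 <- ifelse(pheno$compound_id %in% active_ids,
                 10^-runif(n_phenotype, 6.2, 7.5),
                 10^-runif(n_phenotype, 4.5, 5.8))
  pheno_acts <- data.frame(compound_id = pheno$compound_id,
                           target_id = "CELL1", endpoint = "GI50",
                           value_mol_per_L = gi50, stringsAsFactors = FALSE)

  proteins <- sprintf("PR%02d", seq_len(n_proteins))
  if (!is.null(planted) && !all(names(planted) %in% proteins))
    stop("planted protein ids must be among ", proteins[1], " .. ",
         proteins[n_proteins])
  size_span <- seq.int(ligand_size_range[1], ligand_size_range[2])
  sizes <- size_span[sample.int(length(size_span), n_proteins, replace = TRUE)]
  target <- NULL
  target_acts <- NULL
  ligand_sets <- list()
  planted_copies <- data.frame(target_id = character(), source_id = character(),
                               protein_id = character(), stringsAsFactors = FALSE)
  next_id <- 1L
  for (j in seq_along(proteins)) {
    m <- sizes[j]
    f <- if (!is.null(planted) && proteins[j] %in% names(planted))
      planted[[proteins[j]]] else 0
    n_copy <- round(f * m)
    if (n_copy > length(active_ids))
      stop("infeasible planted overlap for ", proteins[j])
    ids <- sprintf("BD%05d", next_id:(next_id + m - 1L))
    next_id <- next_id + m
    smiles <- vapply(seq_len(m), function(i) random_smiles(sample(4:10, 1L)), "")
    if (n_copy > 0L) {
      src <- sample(active_ids, n_copy)
      smiles[seq_len(n_copy)] <-
        pheno$smiles[match(src, pheno$compound_id)]
      planted_copies <- rbind(planted_copies,
                              data.frame(target_id = ids[seq_len(n_copy)],
                                         source_id = src,
                                         protein_id = proteins[j],
                                         stringsAsFactors = FALSE))
    }
    target <- rbind(target, data.frame(compound_id = ids, smiles = smiles,
                                       stringsAsFactors = FALSE))
    target_acts <- rbind(target_acts, data.frame(
      compound_id = ids, target_id = proteins[j],
      endpoint = sample(PROTEIN_ENDPOINTS, m, replace = TRUE),
      value_mol_per_L = 10^-runif(m, 6.1, 8),
      stringsAsFactors = FALSE))
    ligand_sets[[proteins[j]]] <- ids
  }
  if (n_malformed > 0L) {
    bad <- data.frame(
      compound_id = sprintf("BAD%03d", seq_len(n_malformed)),
      target_id = "PR01",
      endpoint = rep(c("Ki", "XX50", "IC50"), length.out = n_malformed),
      value_mol_per_L = rep(c("-1", "1e-7", "oops"), length.out = n_malformed),
      stringsAsFactors = FALSE)
    # every malformed row violates at least one rule
    ok <- bad$endpoint %in% ENDPOINTS &
      !is.na(suppressWarnings(as.numeric(bad$value_mol_per_L))) &
      suppressWarnings(as.numeric(bad$value_mol_per_L)) > 0
    bad$value_mol_per_L[ok] <- "not_a_number"
    target_acts$value_mol_per_L <- sprintf("%.17g", target_acts$value_mol_per_L)
    target_acts <- rbind(target_acts, bad)
  }

  manifest <- list(seed = as.integer(seed),
                   phenotype_active = sort(active_ids),
                   ligand_sets = ligand_sets,
                   planted = as.list(planted),
                   planted_copies = planted_copies,
                   n_malformed = as.integer(n_malformed),
                   sizes = stats::setNames(as.integer(sizes), proteins))
  out <- structure(list(phenotype = pheno, target = target,
                        background = background,
                        phenotype_activities = pheno_acts,
                        target_activities = target_acts,
                        manifest = manifest),
                   class = "tlsea_universe")
  if (!is.null(dir)) write_universe(out, dir)
  out
}

#' @export
print.tlsea_universe <- function(x, ...) {
  cat(sprintf("simulated compound universe: %d phenotype (%d active), %d target, %d background compounds\n",
              nrow(x$phenotype), length(x$manifest$phenotype_active),
              nrow(x$target), nrow(x$background)))
  cat(sprintf("  %d proteins; planted overlaps: %s\n",
              length(x$manifest$ligand_sets),
              if (length(x$manifest$planted))
                paste(names(x$manifest$planted), collapse = ", ")
              else "none"))
  invisible(x)
}

# Write a simulated universe as the plain-text formats the readers consume.
write_universe <- function(universe, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_smi <- function(df, name)
    writeLines(sprintf("%s %s", df$smiles, df$compound_id),
               file.path(dir, name))
  write_smi(universe$phenotype, "phenotype.smi")
  write_smi(universe$target, "target.smi")
  write_smi(universe$background, "background.smi")
  pa <- universe$phenotype_activities
  pa$value_mol_per_L <- sprintf("%.17g", pa$value_mol_per_L)
  utils::write.table(pa, file.path(dir, "phenotype_activities.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ta <- universe$target_activities
  if (is.numeric(ta$value_mol_per_L))
    ta$value_mol_per_L <- sprintf("%.17g", ta$value_mol_per_L)
  utils::write.table(ta, file.path(dir, "target_activities.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  man <- universe$manifest
  man$planted_copies <- as.list(man$planted_copies)
  yaml::write_yaml(man, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
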