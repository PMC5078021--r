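#' Run configuration for the two-layer similarity ensemble statistic
#'
#' Collects every tunable parameter of the pipeline in one validated object.
#' The defaults are the published operating point of the method: similarity
#' noise threshold 0.15, layer-one significance level 0.01 for the Z
#' threshold \code{c}, network cutoff \code{P_Z < 1e-4}, ligand sets of at
#' least 10 compounds, phenotype actives defined by pGI50 strictly above 6,
#' and protein actives by any endpoint strictly below 1e-6 mol/L.
#'
#' Two sampling scales are provided.  \code{scale = "desk"} (default) uses
#' 200 sampling lengths with 500 repetitions each (a 1e5 null pool), which
#' resolves empirical p-values down to 1e-5 and runs in minutes on one CPU.
#' \code{scale = "paper"} uses 2000 lengths times 5000 repetitions (a 1e7
#' pool), the scale used for the published cell-line analyses.
#'
#' @param scale `"desk"` or `"paper"`; presets for `n_lengths` and
#'   `reps_per_length` (explicit values override the preset).
#' @param sim_threshold Similarity noise threshold; only Tanimoto values
#'   strictly above it enter the initial score.  In (0, 1).
#' @param alpha_z Significance level used to derive the Z threshold `c`.
#' @param network_pz_cutoff Strict upper bound on `P_Z` for network edges.
#' @param n_lengths Number of distinct sampling lengths for the null pools.
#' @param reps_per_length Repetitions per sampling length.
#' @param length_range Integer range `[min, max]` the sampling lengths are
#'   drawn from (published analyses used 1 to 10000).
#' @param min_ligands Minimum ligand-set size; smaller proteins are dropped.
#' @param pgi50_min Phenotype activity threshold; active means pGI50 strictly
#'   greater than this.
#' @param target_activity_threshold Protein activity threshold in mol/L;
#'   active means any endpoint value strictly smaller.
#' @param fresh_z_pool If `TRUE`, the Z pool used for `P_Z` is resampled
#'   independently of the pool used to fit the background; by default one
#'   background sampling serves both, mirroring the single 10-million-set
#'   sampling of the original protocol.
#' @param seed Integer master seed; all stage-level randomness is derived
#'   from it through named substreams.
#'
#' @return An object of class `"tlsea_config"` (a validated list).
#' @examples
#' cfg <- tlsea_config(n_lengths = 50, reps_per_length = 100,
#'                     length_range = c(1, 50))
#' cfg$n_lengths * cfg$reps_per_length  # null pool size
#' @export
tlsea_config <- function(scale = c("desk", "paper"),
                         sim_threshold = 0.15,
                         alpha_z = 0.01,
                         network_pz_cutoff = 1e-4,
                         n_lengths = NULL,
                         reps_per_length = NULL,
                         length_range = c(1, 10000),
                         min_ligands = 10,
                         pgi50_min = 6,
                         target_activity_threshold = 1e-6,
                         fresh_z_pool = FALSE,
                         seed = 1L) {
  scale <- match.arg(scale)
  preset <- switch(scale,
    desk  = c(n_lengths = 200L,  reps_per_length = 500L),
    paper = c(n_lengths = 2000L, reps_per_length = 5000L))
  if (is.null(n_lengths)) n_lengths <- preset[["n_lengths"]]
  if (is.null(reps_per_length)) reps_per_length <- preset[["reps_per_length"]]

  stopifnot(
    sim_threshold > 0, sim_threshold < 1,
    alpha_z > 0, alpha_z < 1,
    network_pz_cutoff > 0, network_pz_cutoff < 1,
    length(length_range) == 2L, length_range[1] >= 1,
    length_range[2] >= length_range[1],
    n_lengths >= 1, reps_per_length >= 1,
    min_ligands >= 1, pgi50_min > 0, target_activity_threshold > 0
  )
  cfg <- list(
    scale = scale,
    sim_threshold = sim_threshold,
    alpha_z = alpha_z,
    network_pz_cutoff = network_pz_cutoff,
    n_lengths = as.integer(n_lengths),
    reps_per_length = as.integer(reps_per_length),
    length_range = as.integer(length_range),
    min_ligands = as.integer(min_ligands),
    pgi50_min = pgi50_min,
    target_activity_threshold = target_activity_threshold,
    fresh_z_pool = isTRUE(fresh_z_pool),
    seed = as.integer(seed)
  )
  class(cfg) <- "tlsea_config"
  cfg
}

#' @export
print.tlsea_config <- function(x, ...) {
  cat("TL-SEA run configuration (", x$scale, " scale)\n", sep = "")
  cat(sprintf("  sim_threshold: %g   alpha_z: %g   network P_Z cutoff: %g\n",
              x$sim_threshold, x$alpha_z, x$network_pz_cutoff))
  cat(sprintf("  null pools: %d lengths x %d reps = %d samples, lengths in [%d, %d]\n",
              x$n_lengths, x$reps_per_length, x$n_lengths * x$reps_per_length,
              x$length_range[1], x$length_range[2]))
  cat(sprintf("  min ligand-set size: %d   pGI50 min: %g   target threshold: %g mol/L\n",
              x$min_ligands, x$pgi50_min, x$target_activity_threshold))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Named RNG substreams derived from one master seed so each stage is
# independently reproducible.  Offsets are arbitrary fixed constants; the
# result stays a valid 32-bit integer seed.
substream_seed <- function(seed, stream) {
  offsets <- c(background_columns = 101L, background_rows = 211L,
               opool_rows = 307L, random_matrix = 401L,
               fixture = 503L, fixture_structures = 601L)
  if (!stream %in% names(offsets)) stop("unknown RNG substream: ", stream)
  (as.integer(seed) %% 1000003L) * 1009L + offsets[[stream]]
}

# Package-level logging: informative, suppressible, never fatal.
tlsea_log <- function(fmt, ...) {
  message("tlsea: ", sprintf(fmt, ...))
}
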