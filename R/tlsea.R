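#' Fit the two-layer similarity ensemble statistic
#'
#' Runs the full association analysis between a phenotype's active compounds
#' (the columns of the similarity matrices) and a collection of protein
#' ligand sets (row subsets of `M`):
#' \enumerate{
#'   \item samples random compound sets from the background matrix `M_r` and
#'     fits the background model mu_m = k*m, sigma_m = a*m^b
#'     ([sample_background_scores()], [fit_background()]);
#'   \item for every protein, slices its ligand rows out of `M`, computes
#'     initial scores (similarity sums above the noise threshold),
#'     standardizes them, and converts them to empirical significances
#'     `P_Z` against the Z pool;
#'   \item determines the Z threshold `c` at level `alpha_z`, sums the
#'     significant Z values into the original score `O`, and converts `O`
#'     to the association score `P_O` against a second, row-sampling null
#'     ([sample_background_original_scores()]).
#' }
#' Small `P_O` means the phenotype's chemistry is enriched for the protein's
#' ligands relative to random compound sets.  A protein whose ligand set is
#' smaller than `config$min_ligands`, or that fails any stage, is dropped
#' with a logged reason rather than aborting the fit.
#'
#' @param M Full similarity matrix (target-library rows x phenotype-active
#'   columns) with compound identifiers as dimnames.
#' @param ligand_sets Named list: protein identifier -> character vector of
#'   ligand compound identifiers (rows of `M`), e.g. from
#'   [build_ligand_sets()].
#' @param M_r Random background similarity matrix over the same phenotype
#'   columns.
#' @param config A [tlsea_config()] object.
#' @param seed Master seed (defaults to `config$seed`); every stage draws
#'   from its own named substream.
#' @return An object of class `"tlsea"`: a list with
#'   \describe{
#'     \item{scores}{data frame `protein_id`, `m`, `O`, `P_O`,
#'       `P_O_censored`, `rank` (rank 1 = smallest `P_O`, ties broken by
#'       identifier).}
#'     \item{pz}{matrix of `P_Z` values, phenotype compounds x proteins.}
#'     \item{z, i}{matching matrices of standardized and initial scores.}
#'     \item{pz_censored}{logical matrix marking `P_Z` values below the pool
#'       resolution (reported at the placeholder 0.5/N).}
#'     \item{background}{the fitted `"tlsea_background"`.}
#'     \item{c}{the Z threshold at `alpha_z`.}
#'     \item{pools}{the Z and O null pools.}
#'     \item{dropped}{data frame of proteins dropped and why.}
#'   }
#' @examples
#' sim <- simulate_similarity_study(n_phenotype = 40, n_proteins = 5,
#'                                  n_background = 120, seed = 7)
#' cfg <- tlsea_config(n_lengths = 50, reps_per_length = 40,
#'                     length_range = c(1, 50), seed = 7)
#' fit <- tlsea(sim$M, sim$ligand_sets, sim$M_r, config = cfg)
#' fit$scores
#' @export
tlsea <- function(M, ligand_sets, M_r, config = tlsea_config(),
                  seed = config$seed) {
  stopifnot(is.matrix(M), is.matrix(M_r), inherits(config, "tlsea_config"))
  if (is.null(colnames(M)) || is.null(rownames(M)))
    stop("tlsea: M must carry compound identifiers as dimnames")
  if (!is.null(colnames(M_r))) {
    if (!identical(sort(colnames(M)), sort(colnames(M_r))))
      stop("tlsea: M and M_r must cover the same phenotype compounds")
    M_r <- M_r[, colnames(M), drop = FALSE]
  } else if (ncol(M_r) != ncol(M)) {
    stop("tlsea: M and M_r must have the same number of phenotype columns")
  }
  if (length(ligand_sets) == 0L) {
    warning("tlsea: empty ligand_sets; returning an empty result")
    return(empty_tlsea(M, config))
  }

  samples <- sample_background_scores(M_r, config, seed = seed)
  fit <- fit_background(samples)
  zpool <- if (config$fresh_z_pool) {
    build_z_pool(sample_background_scores(M_r, config, seed = seed + 1L), fit)
  } else {
    build_z_pool(samples, fit)
  }
  c_thr <- z_threshold(zpool, config$alpha_z)
  opool <- sample_background_original_scores(M_r, fit, c_thr, config,
                                             seed = seed)

  proteins <- names(ligand_sets)
  n_pheno <- ncol(M)
  pz <- zmat <- imat <- matrix(NA_real_, n_pheno, length(proteins),
                               dimnames = list(colnames(M), proteins))
  pzc <- matrix(FALSE, n_pheno, length(proteins),
                dimnames = dimnames(pz))
  mvec <- Ovec <- rep(NA_real_, length(proteins))
  dropped <- data.frame(protein_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  for (j in seq_along(proteins)) {
    res <- tryCatch({
      ligs <- ligand_sets[[j]]
      if (length(ligs) < config$min_ligands)
        stop("fewer than ", config$min_ligands, " ligands")
      M_t <- slice_target_matrix(M, ligs)
      I <- initial_score(M_t, config$sim_threshold)
      z <- z_transform(I, fit)
      p <- p_z(z, zpool)
      list(I = I, z = z, p = p, m = nrow(M_t),
           O = original_score(z, c_thr))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      tlsea_log("protein %s dropped: %s", proteins[j], conditionMessage(res))
      dropped[nrow(dropped) + 1L, ] <- list(proteins[j], conditionMessage(res))
      next
    }
    imat[, j] <- res$I
    zmat[, j] <- res$z
    pz[, j] <- res$p
    pzc[, j] <- attr(res$p, "censored")
    mvec[j] <- res$m
    Ovec[j] <- res$O
  }
  keep <- !is.na(Ovec)
  proteins <- proteins[keep]
  pz <- pz[, keep, drop = FALSE]
  zmat <- zmat[, keep, drop = FALSE]
  imat <- imat[, keep, drop = FALSE]
  pzc <- pzc[, keep, drop = FALSE]
  mvec <- mvec[keep]; Ovec <- Ovec[keep]

  po <- p_o(Ovec, opool)
  ord <- order(po, proteins)
  rank <- integer(length(po)); rank[ord] <- seq_along(ord)
  scores <- data.frame(protein_id = proteins, m = as.integer(mvec),
                       O = Ovec, P_O = as.numeric(po),
                       P_O_censored = attr(po, "censored"),
                       rank = rank, stringsAsFactors = FALSE)
  scores <- scores[order(scores$rank), ]
  rownames(scores) <- NULL

  structure(list(scores = scores, pz = pz, z = zmat, i = imat,
                 pz_censored = pzc, background = fit, c = c_thr,
                 pools = list(z = zpool, o = opool),
                 dropped = dropped, config = config, seed = seed,
                 n_phenotype = n_pheno),
            class = "tlsea")
}

empty_tlsea <- function(M, config) {
  structure(list(scores = data.frame(protein_id = character(), m = integer(),
                                     O = numeric(), P_O = numeric(),
                                     P_O_censored = logical(),
                                     rank = integer()),
                 pz = matrix(numeric(), ncol(M), 0,
                             dimnames = list(colnames(M), NULL)),
                 z = NULL, i = NULL, pz_censored = NULL, background = NULL,
                 c = NA_real_, pools = NULL,
                 dropped = data.frame(protein_id = character(),
                                      reason = character()),
                 config = config, seed = config$seed,
                 n_phenotype = ncol(M)),
            class = "tlsea")
}

#' @export
print.tlsea <- function(x, n = 6L, ...) {
  cat("Two-layer similarity ensemble fit\n")
  cat(sprintf("  %d proteins scored against %d phenotype compounds\n",
              nrow(x$scores), x$n_phenotype))
  if (!is.null(x$background))
    cat(sprintf("  background: k = %.4g, a = %.4g, b = %.4g;  c(alpha=%g) = %.4g\n",
                x$background$k_hat, x$background$a_hat, x$background$b_hat,
                x$config$alpha_z, x$c))
  if (!is.null(x$pools))
    cat(sprintf("  null pools: %d (Z), %d (O); p-value resolution %.3g\n",
                x$pools$z$n, x$pools$o$n, 1 / x$pools$o$n))
  if (nrow(x$scores) > 0L) {
    cat("  top associations:\n")
    print(utils::head(x$scores, n), row.names = FALSE)
  }
  if (nrow(x$dropped) > 0L)
    cat(sprintf("  (%d proteins dropped)\n", nrow(x$dropped)))
  invisible(x)
}

#' @export
summary.tlsea <- function(object, pz_cutoff = object$config$network_pz_cutoff,
                          ...) {
  edges <- if (length(object$pz)) sum(object$pz < pz_cutoff) else 0L
  structure(list(scores = object$scores,
                 background = object$background, c = object$c,
                 n_phenotype = object$n_phenotype,
                 n_edges = edges, pz_cutoff = pz_cutoff,
                 resolution = if (!is.null(object$pools)) 1 / object$pools$o$n
                              else NA_real_,
                 dropped = object$dropped),
            class = "summary.tlsea")
}

#' @export
print.summary.tlsea <- function(x, ...) {
  cat("TL-SEA association summary\n")
  if (!is.null(x$background)) print(x$background)
  cat(sprintf("  Z threshold c = %.4g;  p-value resolution %.3g\n",
              x$c, x$resolution))
  cat(sprintf("  %d chemical-protein pairs with P_Z < %g\n",
              x$n_edges, x$pz_cutoff))
  cat("  association table (P_O ascending):\n")
  print(x$scores, row.names = FALSE)
  invisible(x)
}

#' @export
coef.tlsea <- function(object, ...) {
  if (is.null(object$background))
    return(c(k = NA_real_, a = NA_real_, b = NA_real_, c = NA_real_))
  c(coef(object$background), c = object$c)
}

#' Score additional ligand sets against a fitted background
#'
#' Reuses the background model, null pools and Z threshold of an existing
#' fit to score new protein ligand sets (rows of `M`), without re-sampling.
#'
#' @param object A fitted `"tlsea"` object.
#' @param ligand_sets Named list of ligand identifier vectors.
#' @param M Similarity matrix holding the ligand rows, over the same
#'   phenotype columns as the original fit.
#' @param ... Unused.
#' @return A data frame like `object$scores` (ranks within the new sets).
#' @export
predict.tlsea <- function(object, ligand_sets, M, ...) {
  stopifnot(!is.null(object$background), ncol(M) == object$n_phenotype)
  proteins <- names(ligand_sets)
  O <- m <- numeric(length(proteins))
  for (j in seq_along(proteins)) {
    M_t <- slice_target_matrix(M, ligand_sets[[j]])
    I <- initial_score(M_t, object$config$sim_threshold)
    z <- z_transform(I, object$background)
    O[j] <- original_score(z, object$c)
    m[j] <- nrow(M_t)
  }
  po <- p_o(O, object$pools$o)
  ord <- order(po, proteins)
  rank <- integer(length(po)); rank[ord] <- seq_along(ord)
  out <- data.frame(protein_id = proteins, m = as.integer(m), O = O,
                    P_O = as.numeric(po),
                    P_O_censored = attr(po, "censored"), rank = rank,
                    stringsAsFactors = FALSE)
  out[order(out$rank), ]
}

#' @export
plot.tlsea <- function(x, which = c("background", "po"), ...) {
  which <- match.arg(which)
  if (which == "background") {
    plot(x$background)
  } else {
    graphics::hist(x$scores$P_O, breaks = 20, main = "association scores",
                   xlab = expression(P[O]), col = "grey")
  }
  invisible(x)
}
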