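#' Initial score of a protein's ligand set against each phenotype compound
#'
#' For each column (phenotype compound) of the per-protein similarity slice,
#' sums the similarity values strictly greater than `sim_threshold`:
#' I_i = sum_j S_ji over S_ji > threshold.  The threshold (0.15 by default)
#' removes the bulk of weak random similarity noise.
#'
#' @param M_t Per-protein similarity slice (ligand rows x phenotype
#'   columns).
#' @param sim_threshold Strict lower bound for a similarity to count.
#' @return Named numeric vector of initial scores (one per column) with
#'   attributes `m` (ligand-set size, the row count) and `sim_threshold`.
#' @examples
#' M <- matrix(c(0.2, 0.1, 0.3), ncol = 1)
#' initial_score(M)  # 0.5: the 0.1 entry is below the 0.15 threshold
#' @export
initial_score <- function(M_t, sim_threshold = 0.15) {
  stopifnot(is.matrix(M_t), nrow(M_t) >= 1)
  I <- colSums(M_t * (M_t > sim_threshold))
  attr(I, "m") <- nrow(M_t)
  attr(I, "sim_threshold") <- sim_threshold
  I
}

# Draw the sampling lengths for a null pool: distinct values when the range
# allows it (the protocol calls for different lengths), with replacement
# otherwise.
draw_lengths <- function(n_lengths, length_range) {
  span <- seq.int(length_range[1], length_range[2])
  replace <- length(span) < n_lengths
  span[sample.int(length(span), n_lengths, replace = replace)]
}

# One random row subset of an n-row matrix as a count vector: without
# replacement when m <= n, with replacement (multinomial counts) otherwise.
row_counts <- function(n, m) {
  if (m <= n) {
    cnt <- integer(n)
    cnt[sample.int(n, m)] <- 1L
    cnt
  } else {
    as.integer(stats::rmultinom(1L, m, rep.int(1, n)))
  }
}

#' Sample random-set initial scores from the background matrix
#'
#' Builds the column-sampling null: for each of `n_lengths` random set sizes
#' m (drawn from `length_range`), and for each of `reps_per_length`
#' repetitions, picks one random column of the background matrix `M_r` and m
#' random rows, and records the initial score of that random compound set.
#' Rows are drawn without replacement when m does not exceed the number of
#' background rows, with replacement otherwise.  The published protocol used
#' 2000 lengths x 5000 repetitions (a 1e7 pool) with lengths in [1, 10000].
#'
#' @param M_r Random background similarity matrix.
#' @param config A [tlsea_config()] object (uses `n_lengths`,
#'   `reps_per_length`, `length_range`, `sim_threshold`).
#' @param seed Master seed; this stage uses its own substream.
#' @return Data frame with columns `m` (set size) and `I` (initial score),
#'   `n_lengths * reps_per_length` rows.
#' @export
sample_background_scores <- function(M_r, config = tlsea_config(),
                                     seed = config$seed) {
  stopifnot(is.matrix(M_r), nrow(M_r) >= 1, ncol(M_r) >= 1)
  V <- M_r * (M_r > config$sim_threshold)
  n <- nrow(V); p <- ncol(V)
  reps <- config$reps_per_length
  set.seed(substream_seed(seed, "background_columns"))
  lengths <- draw_lengths(config$n_lengths, config$length_range)
  if (config$length_range[2] > n)
    tlsea_log("background sampling: lengths above %d rows use sampling with replacement", n)
  I <- numeric(length(lengths) * reps)
  mm <- rep(lengths, each = reps)
  k <- 0L
  for (m in lengths) {
    cols <- sample.int(p, reps, replace = TRUE)
    if (m <= n) {
      for (r in seq_len(reps)) {
        k <- k + 1L
        I[k] <- sum(V[sample.int(n, m), cols[r]])
      }
    } else {
      for (r in seq_len(reps)) {
        k <- k + 1L
        cnt <- stats::rmultinom(1L, m, rep.int(1, n))
        I[k] <- sum(cnt * V[, cols[r]])
      }
    }
  }
  data.frame(m = mm, I = I)
}

#' Fit the background model of random initial scores
#'
#' The mean and standard deviation of the random-set initial score grow with
#' the set size m as mu_m = k * m and sigma_m = a * m^b.  The constants are
#' estimated from the sampled null: k by least squares of the per-length
#' means against m through the origin, and (a, b) by ordinary least squares
#' of log(sigma_m) on log(m) over lengths with positive sigma.  For the
#' published K562 background the estimates were a = 0.0088, b = 0.9950,
#' k = 0.0088.
#'
#' @param samples Data frame with columns `m` and `I`, as produced by
#'   [sample_background_scores()]; needs at least two distinct lengths with
#'   at least two repetitions each.
#' @return An object of class `"tlsea_background"` with elements `k_hat`,
#'   `a_hat`, `b_hat`, `lengths` (per-length m, mu, sigma, n) and
#'   `n_samples`.
#' @seealso [z_transform()], [build_z_pool()]
#' @export
fit_background <- function(samples) {
  stopifnot(is.data.frame(samples), all(c("m", "I") %in% names(samples)))
  mu <- tapply(samples$I, samples$m, mean)
  sigma <- tapply(samples$I, samples$m, sd)
  n_per <- tapply(samples$I, samples$m, length)
  m <- as.numeric(names(mu))
  if (length(m) < 2L)
    stop("fit_background: need at least two distinct sampling lengths")
  if (any(n_per < 2L))
    stop("fit_background: need at least two repetitions per length")
  if (all(sigma == 0))
    stop("degenerate background (no supra-threshold similarity)")
  pos <- sigma > 0
  if (mean(pos) < 0.5)
    stop("fit_background: more than half of the length groups have zero spread")
  if (any(!pos))
    tlsea_log("fit_background: %d of %d length groups excluded from the sigma fit (zero spread)",
              sum(!pos), length(pos))
  k_hat <- sum(m * mu) / sum(m * m)
  fit_sigma <- stats::lm(log(sigma[pos]) ~ log(m[pos]))
  a_hat <- exp(unname(coef(fit_sigma)[1]))
  b_hat <- unname(coef(fit_sigma)[2])
  structure(list(k_hat = k_hat, a_hat = a_hat, b_hat = b_hat,
                 lengths = data.frame(m = m, mu = as.numeric(mu),
                                      sigma = as.numeric(sigma),
                                      n = as.integer(n_per)),
                 n_samples = nrow(samples)),
            class = "tlsea_background")
}

#' @export
print.tlsea_background <- function(x, ...) {
  cat("TL-SEA background model of random initial scores\n")
  cat(sprintf("  mu_m = k*m, sigma_m = a*m^b over %d lengths (%d samples)\n",
              nrow(x$lengths), x$n_samples))
  cat(sprintf("  k = %.6g   a = %.6g   b = %.6g\n", x$k_hat, x$a_hat, x$b_hat))
  invisible(x)
}

#' @export
coef.tlsea_background <- function(object, ...) {
  c(k = object$k_hat, a = object$a_hat, b = object$b_hat)
}

#' Predicted background mean and spread at given set sizes
#'
#' @param object A fitted `"tlsea_background"`.
#' @param m Integer set sizes.
#' @param ... Unused.
#' @return Data frame with columns `m`, `mu`, `sigma`.
#' @export
predict.tlsea_background <- function(object, m, ...) {
  data.frame(m = m, mu = object$k_hat * m,
             sigma = object$a_hat * m^object$b_hat)
}

#' @export
plot.tlsea_background <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  with(x$lengths, {
    plot(m, mu, pch = 16, cex = 0.5, xlab = "set size m",
         ylab = expression(mu[m]), main = "background mean")
    graphics::abline(0, x$k_hat, col = 2)
    plot(m, sigma, pch = 16, cex = 0.5, log = "xy", xlab = "set size m",
         ylab = expression(sigma[m]), main = "background spread")
    graphics::curve(x$a_hat * t^x$b_hat, xname = "t", add = TRUE, col = 2)
  })
  invisible(x)
}

#' Standardize initial scores against the background model
#'
#' Z = (I - k*m) / (a * m^b), making scores comparable across ligand-set
#' sizes.
#'
#' @param I Numeric vector of initial scores (if it carries an `m`
#'   attribute, as from [initial_score()], `m` may be omitted).
#' @param fit A `"tlsea_background"` object.
#' @param m Ligand-set size(s); scalar or a vector matching `I`.
#' @return Numeric vector of standardized scores.
#' @export
z_transform <- function(I, fit, m = attr(I, "m")) {
  stopifnot(inherits(fit, "tlsea_background"), !is.null(m), all(m >= 1))
  denom <- fit$a_hat * m^fit$b_hat
  if (any(denom == 0)) stop("z_transform: zero background spread (a * m^b = 0)")
  z <- (as.numeric(I) - fit$k_hat * m) / denom
  names(z) <- names(I)
  z
}

# Empirical pool object: sorted values + size, so tail counts are O(log N).
new_pool <- function(values) {
  structure(list(sorted = sort(values), n = length(values)),
            class = "tlsea_pool")
}

#' @export
print.tlsea_pool <- function(x, ...) {
  cat(sprintf("empirical null pool: %d values in [%.4g, %.4g], resolution %.3g\n",
              x$n, x$sorted[1], x$sorted[x$n], 1 / x$n))
  invisible(x)
}

# Number of pool values >= each element of x.
pool_tail_count <- function(pool, x) {
  pool$n - findInterval(x, pool$sorted, left.open = TRUE)
}

#' Build the standardized null pool (Z pool)
#'
#' Transforms every sampled background initial score with the fitted model,
#' each using its own set size m, yielding the empirical null population the
#' layer-one significance P_Z is computed against.
#'
#' @param samples Data frame from [sample_background_scores()].
#' @param fit The `"tlsea_background"` fitted on (typically) the same
#'   samples.
#' @return A `"tlsea_pool"` object.
#' @export
build_z_pool <- function(samples, fit) {
  new_pool(z_transform(samples$I, fit, m = samples$m))
}

#' Empirical tail probability of a standardized score (P_Z)
#'
#' P_Z = N(Z_r >= z) / N(Z_r): the fraction of the null pool at or above the
#' observed score (ties inclusive).  A score beyond the pool maximum has an
#' empty numerator; it is reported as below the pool resolution 1/N, with
#' the numeric placeholder 0.5/N so downstream ordering and network weights
#' stay finite (the `censored` attribute marks such scores).
#'
#' @param z Numeric vector of standardized scores.
#' @param pool A `"tlsea_pool"` (or plain numeric vector) of null scores.
#' @return Numeric vector of empirical p-values in (0, 1], with attribute
#'   `censored` (logical: true where the score exceeded the pool maximum).
#' @export
p_z <- function(z, pool) {
  if (!inherits(pool, "tlsea_pool")) pool <- new_pool(pool)
  stopifnot(pool$n >= 1)
  cnt <- pool_tail_count(pool, z)
  p <- cnt / pool$n
  censored <- cnt == 0L
  p[censored] <- 0.5 / pool$n
  attr(p, "censored") <- censored
  p
}

#' Z threshold at a given confidence level
#'
#' Returns c, the smallest null-pool value whose empirical tail probability
#' P_Z is at most `alpha_z`.  Standardized scores at or above c are deemed
#' significant and enter the original score.
#'
#' @param pool A `"tlsea_pool"` (or numeric vector); must hold at least
#'   `1/alpha_z` values.
#' @param alpha_z Confidence level (0.01 in the published protocol).
#' @return The threshold c.
#' @export
z_threshold <- function(pool, alpha_z = 0.01) {
  if (!inherits(pool, "tlsea_pool")) pool <- new_pool(pool)
  if (pool$n < 1 / alpha_z)
    stop("z_threshold: pool too small to resolve alpha_z = ", alpha_z)
  first <- which(!duplicated(pool$sorted))
  u <- pool$sorted[first]
  p <- (pool$n - first + 1) / pool$n
  ok <- which(p <= alpha_z)
  if (length(ok) == 0L)
    stop("z_threshold: ties at the pool maximum prevent resolving alpha_z = ",
         alpha_z)
  u[min(ok)]
}

#' Original score: sum of significant standardized scores
#'
#' O = sum of Z values greater than or equal to the threshold c.
#'
#' @param z Numeric vector of standardized scores (one phenotype compound
#'   each).
#' @param c Z threshold from [z_threshold()].
#' @return The original score (0 when nothing reaches c).
#' @export
original_score <- function(z, c) {
  stopifnot(is.finite(c))
  sum(z[z >= c])
}

#' Sample the null population of original scores (O pool)
#'
#' The row-sampling null of layer two: for each random set size m and
#' repetition, extracts m random rows of the background matrix as a pseudo
#' ligand set, computes the initial score of every phenotype column, the
#' standardized scores, and their original score.  Because every original
#' score (observed or null) aggregates over the same full set of phenotype
#' columns, no further standardization is needed.
#'
#' @param M_r Random background similarity matrix.
#' @param fit Fitted `"tlsea_background"` (from the same background run).
#' @param c Z threshold from [z_threshold()].
#' @param config A [tlsea_config()] object.
#' @param seed Master seed; this stage uses its own substream.
#' @return A `"tlsea_pool"` of `n_lengths * reps_per_length` null original
#'   scores.
#' @export
sample_background_original_scores <- function(M_r, fit, c,
                                              config = tlsea_config(),
                                              seed = config$seed) {
  stopifnot(is.matrix(M_r), inherits(fit, "tlsea_background"))
  V <- M_r * (M_r > config$sim_threshold)
  n <- nrow(V)
  reps <- config$reps_per_length
  set.seed(substream_seed(seed, "opool_rows"))
  lengths <- draw_lengths(config$n_lengths, config$length_range)
  O <- numeric(length(lengths) * reps)
  k <- 0L
  for (m in lengths) {
    C <- matrix(0, reps, n)
    if (m <= n) {
      rows <- vapply(seq_len(reps), function(r) sample.int(n, m), integer(m))
      C[cbind(rep(seq_len(reps), each = m), as.vector(rows))] <- 1
    } else {
      C <- t(stats::rmultinom(reps, m, rep.int(1, n)))
    }
    W <- C %*% V                                    # reps x n_pheno initial scores
    Z <- (W - fit$k_hat * m) / (fit$a_hat * m^fit$b_hat)
    O[k + seq_len(reps)] <- rowSums(Z * (Z >= c))
    k <- k + reps
  }
  new_pool(O)
}

#' Association score: empirical tail probability of an original score
#'
#' P_O = N(O_r >= O) / N(O_r), ties inclusive; the association score (AS) of
#' a protein with the phenotype.  Scores beyond the pool maximum are
#' reported at the placeholder 0.5/N with the `censored` attribute set, as
#' in [p_z()].
#'
#' @param O Numeric vector of original scores.
#' @param pool A `"tlsea_pool"` (or numeric vector) of null original scores.
#' @return Empirical p-values in (0, 1] with attribute `censored`.
#' @export
p_o <- function(O, pool) {
  p_z(O, pool)
}
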