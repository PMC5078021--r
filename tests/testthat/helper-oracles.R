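# Brute-force reference implementations, kept deliberately independent of
# the package internals: plain double loops and naive counting only.

bf_initial_score <- function(M, thr = 0.15) {
  out <- numeric(ncol(M))
  for (i in seq_len(ncol(M))) {
    s <- 0
    for (j in seq_len(nrow(M))) if (M[j, i] > thr) s <- s + M[j, i]
    out[i] <- s
  }
  names(out) <- colnames(M)
  out
}

bf_z <- function(I, m, k, a, b) (I - k * m) / (a * m^b)

bf_tail_p <- function(x, pool) {
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    cnt <- 0
    for (v in pool) if (v >= x[i]) cnt <- cnt + 1
    out[i] <- cnt / length(pool)
  }
  out
}

bf_original <- function(z, c) {
  s <- 0
  for (v in z) if (v >= c) s <- s + v
  s
}

bf_tanimoto <- function(a, b) {
  C <- 0
  for (x in a) if (x %in% b) C <- C + 1
  A <- length(a); B <- length(b)
  if (A + B - C == 0) 0 else C / (A + B - C)
}

# Random similarity-like matrix with entries straddling the 0.15 threshold.
random_sim_matrix <- function(n, p, seed) {
  set.seed(seed)
  matrix(runif(n * p, 0, 0.6), n, p,
         dimnames = list(sprintf("r%03d", 1:n), sprintf("c%03d", 1:p)))
}

desk_cfg <- function(...) {
  tlsea_config(n_lengths = 50, reps_per_length = 100,
               length_range = c(1, 50), ...)
}
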