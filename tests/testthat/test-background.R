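test_that("initial scores sum only similarities strictly above threshold", {
  M <- matrix(c(0.2, 0.1, 0.3), ncol = 1)
  I <- initial_score(M)
  expect_equal(as.numeric(I), 0.5)
  expect_equal(attr(I, "m"), 3L)
  expect_equal(as.numeric(initial_score(matrix(c(0.15, 0.10, 0.0), ncol = 1))), 0)
  M2 <- random_sim_matrix(50, 20, seed = 13)
  expect_equal(as.numeric(initial_score(M2)), unname(bf_initial_score(M2)))
})

test_that("background sampling honours count, degeneracy and seed contracts", {
  M_r <- random_sim_matrix(40, 8, seed = 2)
  cfg <- tlsea_config(n_lengths = 10, reps_per_length = 20,
                      length_range = c(1, 30))
  s1 <- sample_background_scores(M_r, cfg, seed = 5)
  expect_equal(nrow(s1), 200L)
  expect_equal(length(unique(s1$m)), 10L)
  s2 <- sample_background_scores(M_r, cfg, seed = 5)
  expect_identical(s1, s2)
  s3 <- sample_background_scores(M_r, cfg, seed = 6)
  expect_false(identical(s1, s3))

  zeros <- matrix(0, 30, 5)
  sz <- sample_background_scores(zeros, cfg, seed = 5)
  expect_true(all(sz$I == 0))
  expect_error(fit_background(sz), "degenerate background")
})

test_that("lengths above the row count sample with replacement", {
  M_r <- random_sim_matrix(10, 4, seed = 3)
  cfg <- tlsea_config(n_lengths = 5, reps_per_length = 10,
                      length_range = c(50, 100))
  s <- suppressMessages(sample_background_scores(M_r, cfg, seed = 1))
  expect_equal(nrow(s), 50L)
  # a sampled set of 50+ rows from a 10-row matrix must exceed any
  # without-replacement sum of all 10 rows
  V <- M_r * (M_r > 0.15)
  expect_true(all(s$I > 0))
  expect_true(max(s$I) > max(colSums(V)))
})

test_that("background fit recovers closed-form least squares", {
  # two lengths, scores exactly 2*m plus tiny jitter: k_hat ~ 2
  set.seed(1)
  samples <- data.frame(m = rep(c(10, 20), each = 50),
                        I = rep(c(20, 40), each = 50) +
                          rnorm(100, 0, 1e-6))
  fit <- fit_background(samples)
  expect_equal(fit$k_hat, 2, tolerance = 1e-4)
  expect_error(fit_background(data.frame(m = rep(5, 10), I = rnorm(10))),
               "two distinct")
})

test_that("background fit recovers generating constants within 10%", {
  set.seed(81)
  m <- sample(1:10000, 200)
  k <- 0.0088; a <- 0.0088; b <- 0.9950
  samples <- data.frame(m = rep(m, each = 500))
  samples$I <- rnorm(nrow(samples), k * samples$m, a * samples$m^b)
  fit <- fit_background(samples)
  expect_lt(abs(fit$k_hat - k) / k, 0.10)
  expect_lt(abs(fit$a_hat - a) / a, 0.10)
  expect_lt(abs(fit$b_hat - b) / b, 0.10)
  pred <- predict(fit, m = c(10, 100))
  expect_equal(pred$mu, fit$k_hat * c(10, 100))
})

test_that("z transformation centres and scales by the fitted background", {
  samples <- data.frame(m = rep(c(5, 10, 20, 40), each = 100))
  set.seed(3)
  samples$I <- rnorm(nrow(samples), 0.2 * samples$m, 0.05 * samples$m^0.8)
  fit <- fit_background(samples)
  m <- 12
  expect_equal(z_transform(fit$k_hat * m, fit, m = m), 0)
  expect_equal(z_transform(fit$k_hat * m + fit$a_hat * m^fit$b_hat, fit, m = m), 1)
  I <- runif(10, 0, 5)
  expect_equal(z_transform(I, fit, m = m),
               bf_z(I, m, fit$k_hat, fit$a_hat, fit$b_hat))
})

test_that("the z pool from its own background is approximately standard", {
  set.seed(19)
  m <- sample(1:1000, 100)
  samples <- data.frame(m = rep(m, each = 200))
  samples$I <- rnorm(nrow(samples), 0.01 * samples$m, 0.01 * samples$m^0.9)
  fit <- fit_background(samples)
  pool <- build_z_pool(samples, fit)
  expect_equal(pool$n, nrow(samples))
  expect_lt(abs(mean(pool$sorted)), 0.05)
  expect_lt(abs(sd(pool$sorted) - 1), 0.05)
})

test_that("empirical tail probabilities count ties inclusively", {
  pool <- c(0, 1, 2, 3)
  expect_equal(as.numeric(p_z(2, pool)), 0.5)
  expect_equal(as.numeric(p_z(-1, pool)), 1)      # below the minimum
  expect_equal(as.numeric(p_z(0, pool)), 1)       # ties at the minimum count
  beyond <- p_z(10, pool)
  expect_equal(as.numeric(beyond), 0.5 / 4)       # placeholder below 1/N
  expect_true(attr(beyond, "censored"))
  x <- rnorm(50); big_pool <- rnorm(1000)
  expect_equal(as.numeric(p_z(x, big_pool)), bf_tail_p(x, big_pool))
})

test_that("tail probabilities are monotone nonincreasing in the score", {
  set.seed(6)
  pool <- rnorm(2000)
  z <- sort(runif(100, -4, 4))
  p <- as.numeric(p_z(z, pool))
  expect_true(all(diff(p) <= 0))
  expect_true(all(p > 0 & p <= 1))
})

test_that("z threshold is the smallest value with tail mass at most alpha", {
  expect_equal(z_threshold(as.numeric(1:100), alpha_z = 0.01), 100)
  expect_equal(z_threshold(as.numeric(1:100), alpha_z = 1), 1)
  expect_error(z_threshold(as.numeric(1:10), alpha_z = 0.01), "too small")
  set.seed(33)
  pool <- rnorm(1e5)
  c_hat <- z_threshold(pool, 0.01)
  expect_equal(c_hat, qnorm(0.99), tolerance = 0.05)
  # definitional property on the pool itself
  expect_lte(as.numeric(p_z(c_hat, pool)), 0.01)
})

test_that("original scores sum the significant z values inclusively", {
  expect_equal(original_score(c(3, 1, 5), c = 2), 8)
  expect_equal(original_score(c(1, 0.5), c = 2), 0)
  expect_equal(original_score(c(2, 3), c = 2), 5)  # boundary inclusive
  set.seed(12)
  z <- rnorm(200); cc <- 0.7
  expect_equal(original_score(z, cc), bf_original(z, cc))
})

test_that("the O pool has the configured size and is seed-stable", {
  M_r <- random_sim_matrix(60, 10, seed = 14)
  cfg <- tlsea_config(n_lengths = 10, reps_per_length = 20,
                      length_range = c(1, 40))
  samples <- sample_background_scores(M_r, cfg, seed = 7)
  fit <- fit_background(samples)
  cc <- z_threshold(build_z_pool(samples, fit), 0.01)
  o1 <- sample_background_original_scores(M_r, fit, cc, cfg, seed = 7)
  o2 <- sample_background_original_scores(M_r, fit, cc, cfg, seed = 7)
  expect_equal(o1$n, 200L)
  expect_identical(o1, o2)
  expect_true(all(is.finite(o1$sorted)))
})
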