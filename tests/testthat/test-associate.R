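test_that("a planted protein outranks null proteins", {
  sim <- simulate_similarity_study(n_phenotype = 60, n_proteins = 10,
                                   planted = c(PR03 = 0.4),
                                   n_background = 300, seed = 17)
  fit <- suppressMessages(tlsea(sim$M, sim$ligand_sets, sim$M_r,
                                config = desk_cfg(seed = 17)))
  top <- fit$scores[fit$scores$rank == 1, ]
  expect_equal(top$protein_id, "PR03")
  expect_lt(top$P_O, min(fit$scores$P_O[fit$scores$protein_id != "PR03"]))
})

test_that("the fit carries consistent per-stage matrices", {
  sim <- simulate_similarity_study(n_phenotype = 25, n_proteins = 4,
                                   n_background = 150, seed = 23)
  cfg <- desk_cfg(seed = 23)
  fit <- suppressMessages(tlsea(sim$M, sim$ligand_sets, sim$M_r, config = cfg))
  expect_equal(dim(fit$pz), c(25L, 4L))
  # recompute one protein by hand through the exported stage functions
  pid <- "PR02"
  M_t <- slice_target_matrix(sim$M, sim$ligand_sets[[pid]])
  I <- initial_score(M_t, cfg$sim_threshold)
  z <- z_transform(I, fit$background)
  expect_equal(unname(fit$i[, pid]), unname(as.numeric(I)))
  expect_equal(unname(fit$z[, pid]), unname(z))
  expect_equal(unname(fit$pz[, pid]), unname(as.numeric(p_z(z, fit$pools$z))))
  O <- original_score(z, fit$c)
  row <- fit$scores[fit$scores$protein_id == pid, ]
  expect_equal(row$O, O)
  expect_equal(row$P_O, as.numeric(p_o(O, fit$pools$o)))
})

test_that("ranks are a permutation consistent with P_O and identifiers", {
  sim <- simulate_similarity_study(n_phenotype = 30, n_proteins = 12,
                                   n_background = 150, seed = 29)
  fit <- suppressMessages(tlsea(sim$M, sim$ligand_sets, sim$M_r,
                                config = desk_cfg(seed = 29)))
  s <- fit$scores
  expect_setequal(s$rank, seq_len(nrow(s)))
  ord <- order(s$P_O, s$protein_id)
  expect_equal(s$rank[ord], seq_len(nrow(s)))
})

test_that("undersized or broken ligand sets are dropped, not fatal", {
  sim <- simulate_similarity_study(n_phenotype = 20, n_proteins = 3,
                                   n_background = 100, seed = 31)
  sets <- sim$ligand_sets
  sets$PR01 <- sets$PR01[1:5]              # below min_ligands
  sets$ghost <- c("nope1", "nope2", sets$PR02)
  fit <- suppressMessages(tlsea(sim$M, sets, sim$M_r,
                                config = desk_cfg(seed = 31)))
  expect_setequal(fit$scores$protein_id, c("PR02", "PR03"))
  expect_setequal(fit$dropped$protein_id, c("PR01", "ghost"))
})

test_that("empty ligand sets yield an empty result with a warning", {
  sim <- simulate_similarity_study(n_phenotype = 15, n_proteins = 2,
                                   n_background = 50, seed = 37)
  expect_warning(fit <- tlsea(sim$M, list(), sim$M_r, config = desk_cfg()),
                 "empty")
  expect_equal(nrow(fit$scores), 0L)
})

test_that("the whole fit is reproducible from the master seed", {
  sim <- simulate_similarity_study(n_phenotype = 20, n_proteins = 4,
                                   n_background = 100, seed = 41)
  f1 <- suppressMessages(tlsea(sim$M, sim$ligand_sets, sim$M_r,
                               config = desk_cfg(seed = 41)))
  f2 <- suppressMessages(tlsea(sim$M, sim$ligand_sets, sim$M_r,
                               config = desk_cfg(seed = 41)))
  expect_identical(f1$scores, f2$scores)
  expect_identical(f1$pz, f2$pz)
  expect_identical(f1$pools$o$sorted, f2$pools$o$sorted)
})

test_that("predict scores new ligand sets against the stored background", {
  sim <- simulate_similarity_study(n_phenotype = 20, n_proteins = 6,
                                   n_background = 100, seed = 43)
  fit <- suppressMessages(tlsea(sim$M, sim$ligand_sets[1:3], sim$M_r,
                                config = desk_cfg(seed = 43)))
  pred <- predict(fit, sim$ligand_sets[4:6], sim$M)
  full <- suppressMessages(tlsea(sim$M, sim$ligand_sets, sim$M_r,
                                 config = desk_cfg(seed = 43)))
  for (pid in names(sim$ligand_sets)[4:6]) {
    expect_equal(pred$O[pred$protein_id == pid],
                 full$scores$O[full$scores$protein_id == pid])
    expect_equal(pred$P_O[pred$protein_id == pid],
                 full$scores$P_O[full$scores$protein_id == pid])
  }
})

test_that("coef and summary expose the background constants and threshold", {
  sim <- simulate_similarity_study(n_phenotype = 15, n_proteins = 3,
                                   n_background = 80, seed = 47)
  fit <- suppressMessages(tlsea(sim$M, sim$ligand_sets, sim$M_r,
                                config = desk_cfg(seed = 47)))
  co <- coef(fit)
  expect_named(co, c("k", "a", "b", "c"))
  expect_equal(unname(co[1:3]), unname(coef(fit$background)))
  expect_equal(unname(co["c"]), fit$c)
  sm <- summary(fit)
  expect_s3_class(sm, "summary.tlsea")
  expect_output(print(sm), "association table")
})
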