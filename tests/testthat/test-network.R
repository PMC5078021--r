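make_pz_matrix <- function() {
  pz <- matrix(c(1e-5, 1e-4, 0.5,
                 1e-8, 2e-1, 9e-5,
                 5e-5, 1e-6, 0.99),
               nrow = 3, byrow = TRUE,
               dimnames = list(c("cA", "cB", "cC"), c("P1", "P2", "P3")))
  pz
}

test_that("network keeps exactly the cells strictly below the cutoff", {
  net <- build_network(make_pz_matrix(), pz_cutoff = 1e-4)
  # 1e-4 exactly is excluded
  expect_equal(nrow(net$edges), 5L)
  expect_false(any(net$edges$compound_id == "cA" & net$edges$protein_id == "P2"))
  expect_true(all(net$edges$p_z < 1e-4))
  got <- net$edges[net$edges$compound_id == "cB" & net$edges$protein_id == "P1", ]
  expect_equal(got$weight, 0.125)   # 1/(-log10(1e-8))
})

test_that("edge weight is the reciprocal negative log10, strictly decreasing", {
  expect_equal(edge_weight(1e-4), 0.25)
  expect_equal(edge_weight(1e-8), 0.125)
  p <- sort(10^-runif(100, 0.5, 9.5))
  w <- edge_weight(p)
  expect_true(all(diff(w) >= 0))           # increasing p -> increasing weight
  expect_true(all(diff(edge_weight(sort(p, decreasing = TRUE))) <= 0))
  expect_error(edge_weight(0))
})

test_that("networks stay bipartite through construction and extraction", {
  sim <- simulate_similarity_study(n_phenotype = 40, n_proteins = 8,
                                   planted = c(PR01 = 0.5, PR05 = 0.5),
                                   n_background = 200, seed = 53)
  fit <- suppressMessages(tlsea(sim$M, sim$ligand_sets, sim$M_r,
                                config = desk_cfg(seed = 53)))
  net <- suppressMessages(build_network(fit, pz_cutoff = 1e-2))
  expect_gt(nrow(net$edges), 0L)
  types <- igraph::V(net$graph)$type
  ends <- igraph::ends(net$graph, igraph::E(net$graph))
  tmap <- setNames(types, igraph::V(net$graph)$name)
  expect_true(all(tmap[ends[, 1]] != tmap[ends[, 2]]))
})

test_that("degree table uses a strict more-than threshold", {
  edges <- expand.grid(compound_id = sprintf("c%02d", 1:16),
                       protein_id = c("P16", "P15"),
                       stringsAsFactors = FALSE)
  edges <- edges[!(edges$protein_id == "P15" & edges$compound_id == "c16"), ]
  pz <- matrix(1, 16, 2, dimnames = list(sprintf("c%02d", 1:16), c("P15", "P16")))
  pz[cbind(edges$compound_id, edges$protein_id)] <- 1e-6
  net <- build_network(pz, pz_cutoff = 1e-4)
  tab <- protein_degree_table(net, min_degree = 15)
  expect_equal(tab$protein_id, "P16")       # degree 15 excluded, 16 kept
  expect_equal(tab$degree, 16L)
  empty <- suppressMessages(build_network(matrix(0.5, 2, 2,
                dimnames = list(c("a", "b"), c("P", "Q")))))
  expect_equal(nrow(protein_degree_table(empty)), 0L)
})

test_that("sub-network extraction returns the induced star of the seed", {
  pz <- matrix(1, 10, 3, dimnames = list(sprintf("c%02d", 1:10),
                                         c("P1", "P2", "P3")))
  pz[1:7, "P1"] <- 1e-6
  pz[7:10, "P2"] <- 1e-6
  net <- build_network(pz, pz_cutoff = 1e-4)
  sub <- extract_subnetwork(net, "P1")
  expect_equal(nrow(sub$edges), 7L)
  expect_equal(igraph::vcount(sub$graph), 8L)   # one protein + 7 compounds
  expect_true(all(sub$edges$protein_id == "P1"))
  sub2 <- extract_subnetwork(net, "c07")        # compound linked to P1 and P2
  expect_setequal(sub2$edges$protein_id, c("P1", "P2"))
  expect_error(extract_subnetwork(net, "ghost"), "unknown node")
})

test_that("condition overlays annotate membership by set algebra", {
  pzA <- matrix(1, 3, 2, dimnames = list(c("c1", "c2", "c3"), c("P1", "P2")))
  pzB <- pzA
  pzA[c(1, 2), 1] <- 1e-6          # A: c1-P1, c2-P1
  pzB[c(2, 3), 1] <- 1e-6          # B: c2-P1, c3-P1
  pzB[1, 2] <- 1e-6                # B: c1-P2
  ov <- overlay_networks(list(A = build_network(pzA), B = build_network(pzB)))
  em <- setNames(ov$edges$membership,
                 paste(ov$edges$compound_id, ov$edges$protein_id))
  expect_equal(em[["c1 P1"]], "A")
  expect_equal(em[["c2 P1"]], "A,B")
  expect_equal(em[["c3 P1"]], "B")
  nm <- setNames(ov$nodes$membership, ov$nodes$name)
  expect_equal(nm[["c1"]], "A,B")
  expect_equal(nm[["P2"]], "B")
  # identical networks: every membership is the full condition set
  ov2 <- overlay_networks(list(X = build_network(pzA), Y = build_network(pzA)))
  expect_true(all(ov2$edges$membership == "X,Y"))
  expect_true(all(ov2$nodes$membership == "X,Y"))
})

test_that("SIF, GraphML and edge-attribute exports are readable", {
  net <- build_network(make_pz_matrix(), pz_cutoff = 1e-4)
  sif <- withr::local_tempfile(fileext = ".sif")
  gml <- withr::local_tempfile(fileext = ".graphml")
  att <- withr::local_tempfile(fileext = ".tsv")
  write_network_sif(net, sif)
  write_network_graphml(net, gml)
  write_edge_attributes(net, att)
  expect_equal(length(readLines(sif)), nrow(net$edges))
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), nrow(net$edges))
  back <- read.table(att, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(net$edges))
  expect_equal(back$weight, net$edges$weight)
})
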