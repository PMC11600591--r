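test_that("demo tree matches the study design and validates", {
  demo <- build_demo_tree(seed = 5)
  expect_equal(length(demo$tree$tip.label), 43L)
  expect_equal(sum(demo$species$limb_status == "limbless"), 12L)
  expect_setequal(names(lineage_members(demo$species)),
                  c("caecilian", "snake", "lizard_A", "lizard_B"))
  expect_true(ape::is.ultrametric(demo$tree, tol = 1e-6))
  expect_true(ape::is.binary(demo$tree))
  expect_true("tetrapod_ancestor" %in% demo$tree$node.label)
  expect_true("anc_snake" %in% demo$tree$node.label)
  # determinism: same seed, same newick
  expect_identical(ape::write.tree(build_demo_tree(seed = 5)$tree),
                   ape::write.tree(demo$tree))
  expect_error(build_demo_tree(lineage_spec = list(snake = list(n = 0, loss = 170))),
               ">= 1 species")
  expect_error(build_demo_tree(n_limbed = 10L), ">= 29")
})

test_that("zero branch lengths copy the root to every node", {
  sp <- tiny_species()
  tree <- tiny_tree(sp)
  tree$edge.length[] <- 0
  alns <- simulate_cne_set(tree, sp, n_cnes = 2, length_range = c(50, 50), seed = 1)
  for (a in alns) {
    root <- a$anc[["tetrapod_ancestor"]]
    expect_true(all(a$seqs == root))
    expect_true(all(a$anc == root))
  }
})

test_that("JC identity decay matches the closed form and long branches mix", {
  # identity after branch d under JC: 1/4 + 3/4 exp(-4d/3)
  anc <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE), collapse = "")
  sim <- simulate_neutral_descendants(anc, rate = 1, time_myr = 0.1,
                                      n_replicates = 10, seed = 2)
  expected <- 0.25 + 0.75 * exp(-4 * 0.1 / 3)
  se <- sqrt(expected * (1 - expected) / 10000)
  expect_lt(abs(mean(sim$identity) - expected), 3 * se)

  # long branch: composition approaches stationarity of a skewed GTR
  g <- gtr_params(base_frequencies = c(0.1, 0.2, 0.3, 0.4))
  sim2 <- simulate_neutral_descendants(anc, rate = 1, time_myr = 5, gtr = g,
                                       n_replicates = 1, seed = 3)
  comp <- table(factor(strsplit(sim2$replicates[1], "")[[1]],
                       levels = c("A", "C", "G", "T"))) / 10000
  for (i in 1:4) {
    se_i <- sqrt(g$base_frequencies[i] * (1 - g$base_frequencies[i]) / 10000)
    expect_lt(abs(comp[[i]] - g$base_frequencies[i]), 4 * se_i)
  }
})

test_that("GTR machinery is a proper reversible substitution model", {
  g <- gtr_params(exchangeabilities = c(1, 4, 1, 1, 4, 1),
                  base_frequencies = c(0.35, 0.15, 0.2, 0.3))
  Q <- gtr_rate_matrix(g)
  expect_equal(rowSums(Q), rep(0, 4), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(-sum(g$base_frequencies * diag(Q)), 1, tolerance = 1e-12)
  P <- gtr_prob_matrix(g, 0.3)
  expect_equal(rowSums(P), rep(1, 4), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(gtr_prob_matrix(g, 0), diag(4), ignore_attr = TRUE, tolerance = 1e-12)
  # detailed balance of P(t): pi_i P_ij = pi_j P_ji
  flux <- diag(g$base_frequencies) %*% P
  expect_equal(flux, t(flux), ignore_attr = TRUE, tolerance = 1e-12)
  # empirical flux symmetry on a long simulated branch
  anc <- paste(sample(c("A", "C", "G", "T"), 50000, replace = TRUE,
                      prob = g$base_frequencies), collapse = "")
  sim <- simulate_neutral_descendants(anc, rate = 1, time_myr = 0.3, gtr = g,
                                      n_replicates = 1, seed = 4)
  a <- strsplit(anc, "")[[1]]; b <- strsplit(sim$replicates[1], "")[[1]]
  counts <- table(a, b)
  for (i in 1:3) for (j in (i + 1):4) {
    cij <- counts[i, j]; cji <- counts[j, i]
    expect_lt(abs(cij - cji), 4 * sqrt(cij + cji + 1))
  }
})

test_that("simulation is reproducible and invalid ranges are rejected", {
  sp <- tiny_species(); tree <- tiny_tree(sp)
  a1 <- simulate_cne_set(tree, sp, 3, length_range = c(40, 80), seed = 11)
  a2 <- simulate_cne_set(tree, sp, 3, length_range = c(40, 80), seed = 11)
  expect_identical(lapply(a1, `[[`, "seqs"), lapply(a2, `[[`, "seqs"))
  a3 <- simulate_cne_set(tree, sp, 3, length_range = c(40, 80), seed = 12)
  expect_false(identical(lapply(a1, `[[`, "seqs"), lapply(a3, `[[`, "seqs")))
  expect_error(simulate_cne_set(tree, sp, 3, length_range = c(5, 50)), "length_range")
  expect_error(simulate_cne_set(tree, sp, 3, length_range = c(50, 20000)), "length_range")
})

test_that("planted degeneration is exact, measurable, and conservative", {
  sp <- tiny_species(); tree <- tiny_tree(sp)
  alns <- simulate_cne_set(tree, sp, 2, length_range = c(100, 100), seed = 21)
  spec <- data.frame(cne_id = c("CNE00001", "CNE00002"),
                     target = c("pair", "solo_1"),
                     mode = c("substitution_burst", "deletion"),
                     start = 10L, end = 70L,
                     identity = c(0.7, NA), stringsAsFactors = FALSE)
  out <- plant_degeneration(alns, sp, spec, seed = 1)
  # burst: both lineage members rewritten to the exact target identity
  burst <- out$truth[out$truth$mode == "substitution_burst", ]
  expect_setequal(burst$species, c("pair_1", "pair_2"))
  expect_equal(burst$post_identity, rep(0.7, 2))
  # independent re-measurement against the true ancestor
  anc <- out$cne_set[["CNE00001"]]$anc[["tetrapod_ancestor"]]
  got <- window_identity(out$cne_set[["CNE00001"]]$seqs[["pair_1"]], anc, 11, 60)
  expect_equal(got$matches, 42L)  # 0.7 * 60
  # deletion: gaps, frame intact
  del <- out$cne_set[["CNE00002"]]$seqs[["solo_1"]]
  expect_equal(nchar(del), 100L)
  expect_equal(substr(del, 11, 70), strrep("-", 60))
  # untouched species bit-identical
  expect_identical(out$cne_set[["CNE00001"]]$seqs[["limbed_01"]],
                   alns[["CNE00001"]]$seqs[["limbed_01"]])
  # empty/none spec leaves everything untouched
  none <- plant_degeneration(alns, sp, data.frame(
    cne_id = "CNE00001", target = "pair", mode = "none",
    start = 0L, end = 60L, identity = NA_real_), seed = 1)
  expect_identical(none$cne_set[["CNE00001"]]$seqs, alns[["CNE00001"]]$seqs)
  # interval shorter than the short window is rejected
  expect_error(plant_degeneration(alns, sp, data.frame(
    cne_id = "CNE00001", target = "pair", mode = "deletion",
    start = 0L, end = 15L, identity = NA_real_)), "short")
})

test_that("feature fixtures self-verify and encode the planned ground truth", {
  sp <- tiny_species(); tree <- tiny_tree(sp)
  alns <- simulate_cne_set(tree, sp, 10, length_range = c(80, 120), seed = 31)
  truth <- data.frame(cne_id = names(alns)[1:3], target = "pair",
                      mode = "substitution_burst", start = 0L, end = 60L,
                      identity = 0.6, stringsAsFactors = FALSE)
  planted <- plant_degeneration(alns, sp, truth, seed = 31)
  fx <- generate_feature_fixtures(planted$cne_set, planted$truth, seed = 31,
                                  limited_sizes = c(sp_a = 30L, sp_b = 40L, sp_c = 50L),
                                  shared_limited = 12L, n_ortholog_genes = 200L)
  expect_setequal(fx$limb_genes, paste0("gene_", names(alns)[1:3]))
  expect_equal(length(fx$shared_limited), 12L)
  expect_true(all(rowSums(fx$activity_truth[names(alns)[1:3], ]) >= 1))
  # boundary genes sit at exactly 999,999 and 1,000,001 bp from element 1
  b <- fx$genes[grepl("boundary", fx$genes$gene_id), ]
  e1 <- alns[[1]]$end - 1L
  expect_equal(sort(b$tss - e1), c(999999L, 1000001L))
  # origin truth ranks map onto ladder labels
  expect_true(all(fx$origin_truth$origin[fx$origin_truth$depth_rank == 0] ==
                    "tetrapod_ancestor"))
  # written bundle is readable back through the package readers
  dir <- withr::local_tempdir()
  write_fixture_bundle(fx, dir)
  tss <- read_intervals(file.path(dir, "genes.gff3"), "gff_tss")
  expect_setequal(tss$name, fx$genes$gene_id)
  expect_equal(sort(tss$start), sort(fx$genes$tss))
  orth <- utils::read.delim(file.path(dir, "orthologs.tsv"))
  expect_equal(nrow(orth), nrow(fx$orthologs))
})
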