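# Independent two-sided Fisher oracle: full hypergeometric enumeration over
# all tables with the observed margins, summing probabilities <= observed.
enum_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  ks <- max(0L, c1 - (n - r1)):min(r1, c1)
  prob <- function(k) choose(c1, k) * choose(n - c1, r1 - k) / choose(n, r1)
  p_obs <- prob(a)
  sum(vapply(ks, prob, numeric(1))[vapply(ks, prob, numeric(1)) <= p_obs * (1 + 1e-7)])
}

test_that("fisher_exact matches exhaustive enumeration on small margins", {
  expect_equal(fisher_exact(5, 0, 0, 5)$p_value, 2 / 252, tolerance = 1e-12)
  r <- fisher_exact(10, 90, 100, 900)
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$p_value, 1)
  r0 <- fisher_exact(0, 10, 10, 0)
  expect_equal(r0$odds_ratio, 0)
  expect_equal(r0$p_value, enum_fisher_p(0, 10, 10, 0), tolerance = 1e-9)
  expect_false(is.na(r0$odds_ratio_haldane))
  set.seed(5)
  for (i in 1:100) {
    t <- sample(0:15, 4, replace = TRUE)  # margins <= 30
    expect_equal(fisher_exact(t[1], t[2], t[3], t[4])$p_value,
                 enum_fisher_p(t[1], t[2], t[3], t[4]), tolerance = 1e-9,
                 info = paste(t, collapse = ","))
  }
  expect_error(fisher_exact(-1, 2, 3, 4), "nonnegative")
})

test_that("BH step-up reproduces the hand-computed q-values", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(1.0), 1.0)
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  # permutation invariance after un-permuting; q >= p elementwise
  set.seed(8)
  p <- runif(20)
  q <- bh_fdr(p)
  perm <- sample(20)
  expect_equal(bh_fdr(p[perm])[order(perm)], q)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
})

test_that("term enrichment equals the direct hypergeometric tail", {
  # universe 100, term 10, set 10, overlap 5
  direct <- sum(vapply(5:10, function(k)
    choose(10, k) * choose(90, 10 - k) / choose(100, 10), numeric(1)))
  uni <- sprintf("g%03d", 1:100)
  term <- list(T1 = uni[1:10])
  set <- c(uni[1:5], uni[51:55])
  res <- term_enrichment(set, term, uni)
  expect_equal(res$p_value, direct, tolerance = 1e-12)
  # cross-check identity with the CDF complement
  expect_equal(res$p_value, 1 - phyper(4, 10, 90, 10), tolerance = 1e-12)
  # zero overlap gives p ~ 1; set = universe gives p = 1
  expect_equal(term_enrichment(uni[51:60], term, uni)$p_value,
               1 - phyper(-1, 10, 90, 10), tolerance = 1e-12)
  expect_equal(term_enrichment(uni, term, uni)$p_value, 1)
  expect_warning(term_enrichment(set, list(T0 = "nowhere"), uni), "skipped")
})

test_that("limb-gene overlap test recovers a planted association", {
  # 200 CNEs; limb-gene-linked CNEs degenerate 5x more often
  set.seed(31)
  ids <- sprintf("c%03d", 1:200)
  linked <- ids[1:60]
  deg_p <- ifelse(ids %in% linked, 0.5, 0.1)
  conv <- runif(200) < deg_p
  records <- data.frame(cne_id = ids,
                        degenerated_lineages = ifelse(conv, "caecilian+snake", ""),
                        n_lineages = ifelse(conv, 2L, 0L),
                        klass = ifelse(conv, "convergent_2", "none"),
                        stringsAsFactors = FALSE)
  links <- data.frame(cne_id = linked, gene_id = "limbgene_1",
                      distance = 1000L, same_chrom = TRUE, stringsAsFactors = FALSE)
  res <- dcne_limb_gene_test(records, links, "limbgene_1")
  expect_equal(res$label, "caecilian+snake")
  expect_lt(res$q_value, 0.01)
  expect_gt(res$odds_ratio, 1)
  # empty foreground yields p = 1 with a warning
  expect_warning(
    res0 <- dcne_limb_gene_test(records, links, "limbgene_1",
                                combinations = "lizard_A+lizard_B"), "empty")
  expect_equal(res0$p_value, 1)
  # foreground = background: odds ratio 1, p 1
  rec_all <- records; rec_all$degenerated_lineages <- "caecilian+snake"
  rec_all$n_lineages <- 2L
  res1 <- dcne_limb_gene_test(rec_all, links, "limbgene_1")
  expect_equal(res1$p_value, 1)
})

test_that("region-set enrichment ranks the planted track first", {
  set.seed(17)
  n <- 150
  uni <- interval_set("chr1", (1:n) * 1000L, (1:n) * 1000L + 200L,
                      name = sprintf("c%03d", 1:n))
  fg <- uni[1:30, ]
  cover <- function(rows) interval_set("chr1", uni$start[rows], uni$end[rows])
  db <- list(
    planted = cover(c(1:24, sample(31:n, 12))),     # 80% of fg, ~10% of bg
    noise1 = cover(sample(n, 30)),
    noise2 = cover(sample(n, 30)),
    everything = cover(1:n),
    empty = interval_set())
  res <- region_set_enrichment(fg, uni, db)
  expect_equal(res$label[1], "planted")
  expect_lt(res$q_value[res$label == "planted"], 0.01)
  expect_equal(res$p_value[res$label == "everything"], 1)
  expect_equal(res$p_value[res$label == "empty"], 1)
  # splitting a track interval into abutting pieces changes nothing
  sp <- db$planted
  half <- floor((sp$start + sp$end) / 2)
  split_set <- interval_set(rep(sp$chrom, 2), c(sp$start, half), c(half, sp$end))
  res2 <- region_set_enrichment(fg, uni, list(planted = split_set))
  expect_equal(res2$p_value, res$p_value[res$label == "planted"])
  # foreground must be a subset of the universe
  rogue <- interval_set("chr9", 5L, 10L)
  expect_error(region_set_enrichment(rogue, uni, db), "absent from the universe")
})

test_that("null fixtures keep the q < 0.05 false-positive fraction in check", {
  set.seed(23)
  n_rep <- 200L
  hits <- 0L; total <- 0L
  for (r in seq_len(n_rep)) {
    # 4 independent null 2x2 tables per replicate (one BH family)
    p <- vapply(1:4, function(i) {
      x <- rbinom(2, size = c(40L, 160L), prob = 0.2)
      fisher_exact(x[1], 40L - x[1], x[2], 160L - x[2])$p_value
    }, numeric(1))
    q <- bh_fdr(p)
    hits <- hits + sum(q < 0.05)
    total <- total + 4L
  }
  mc_err <- sqrt(0.05 * 0.95 / total)
  expect_lte(hits / total, 0.05 + 3 * mc_err)
})

test_that("Welch comparisons behave on degenerate and separated groups", {
  g_same <- list(a = rep(0.5, 10), b = rep(0.5, 10))
  res <- compare_identity_groups(g_same)
  expect_equal(res$tests$t, 0)
  expect_equal(res$tests$p_value, 1)
  set.seed(12)
  g_sep <- list(hi = rnorm(100, 0.9, 0.01), lo = rnorm(100, 0.7, 0.01))
  expect_lt(compare_identity_groups(g_sep)$tests$p_value, 1e-10)
  three <- compare_identity_groups(list(a = rnorm(20), b = rnorm(20), c = rnorm(20)))
  expect_equal(nrow(three$tests), 3L)
  expect_error(compare_identity_groups(list(a = 1, b = rnorm(5))), "n >= 2")
  # histogram counts cover every observation
  expect_equal(sum(res$histograms$count), 20L)
})
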