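# Boundary constructors: 31 limbed species identical to a known ancestor
# (full support everywhere) unless individually weakened.
boundary_setup <- function(len = 60L) {
  sp <- tiny_species(31L)
  anc <- paste(rep(c("A", "C", "G", "T"), length.out = len), collapse = "")
  list(sp = sp, anc = anc, aln = flat_alignment(sp, anc))
}

test_that("criterion (i) fires at 14/20 focal matches and not at 15/20", {
  bs <- boundary_setup()
  cfg <- detection_config()
  aln14 <- bs$aln
  aln14$seqs[["pair_1"]] <- mutate_positions(bs$anc, 1, 6)   # 14/20 in window 1
  call <- scan_species(aln14, "pair_1", bs$sp, cfg)
  expect_true(call$degenerated)
  expect_true("short_identity" %in% call$evidence$criterion)
  expect_equal(min(call$evidence$focal_matches), 14L)

  aln15 <- bs$aln
  aln15$seqs[["pair_1"]] <- mutate_positions(bs$anc, 1, 5)   # never below 15/20
  expect_false(scan_species(aln15, "pair_1", bs$sp, cfg)$degenerated)
})

test_that("limbed support counts at 18/20 and not at 17/20", {
  bs <- boundary_setup()
  cfg <- detection_config()
  weaken <- function(aln, k_limbed, n_mismatch) {
    for (s in sprintf("limbed_%02d", seq_len(k_limbed)))
      aln$seqs[[s]] <- mutate_positions(bs$anc, 1, n_mismatch)
    aln$seqs[["pair_1"]] <- mutate_positions(bs$anc, 1, 6)
    aln
  }
  # 3 limbed species at 18/20 still support: 31 supporters >= 29 -> fires
  expect_true(scan_species(weaken(bs$aln, 3L, 2L), "pair_1", bs$sp, cfg)$degenerated)
  # 3 limbed species at 17/20 do not support: 28 < 29 -> silent
  expect_false(scan_species(weaken(bs$aln, 3L, 3L), "pair_1", bs$sp, cfg)$degenerated)
  # but with only 2 weakened (29 supporters) it fires again
  expect_true(scan_species(weaken(bs$aln, 2L, 3L), "pair_1", bs$sp, cfg)$degenerated)
})

test_that("criterion (ii) fires at 30/50 limbed support with an all-gap focal", {
  bs <- boundary_setup(len = 50L)   # exactly one long window
  cfg <- detection_config()
  mutate_at <- function(seq, pos) {
    ch <- strsplit(seq, "")[[1]]
    rot <- c(A = "C", C = "G", G = "T", T = "A")
    ch[pos] <- rot[ch[pos]]
    paste(ch, collapse = "")
  }
  # mismatches spread 2-per-5 so every 20 bp window holds >= 8 of them:
  # the short criterion can never gain limbed support
  spread20 <- which(seq_len(50) %% 5 %in% c(1, 2))
  gap_all <- function(extra_pos) {
    aln <- bs$aln
    for (s in bs$sp$name[bs$sp$limb_status == "limbed"])
      aln$seqs[[s]] <- mutate_at(bs$anc, c(spread20, extra_pos))
    aln$seqs[["pair_1"]] <- strrep("-", 50L)
    aln
  }
  # 20 mismatches -> 30/50 matches: limbed support holds; focal fully absent
  call30 <- scan_species(gap_all(integer()), "pair_1", bs$sp, cfg)
  expect_true(call30$degenerated)
  expect_equal(unique(call30$evidence$criterion), "long_absence")
  # 21 mismatches -> 29/50 < 30: no support, silent
  expect_false(scan_species(gap_all(3L), "pair_1", bs$sp, cfg)$degenerated)
  # focal absent from the element entirely counts as absent
  aln_missing <- gap_all(integer())
  aln_missing$seqs <- aln_missing$seqs[names(aln_missing$seqs) != "pair_1"]
  expect_true(scan_species(aln_missing, "pair_1", bs$sp, cfg)$degenerated)
  # a partially gapped focal (49 of 50) does not satisfy "absent"
  aln49 <- gap_all(integer())
  aln49$seqs[["pair_1"]] <- gap_positions(bs$anc, 1, 49L)
  expect_false(scan_species(aln49, "pair_1", bs$sp, cfg)$degenerated)
})

test_that("windows are laid on ancestor ungapped coordinates", {
  sp <- tiny_species(31L)
  # ancestor has a 10-column gap inserted mid-element; species sequences carry
  # bases there (an insertion relative to the ancestor), which must be skipped
  left <- strrep("ACGT", 5); right <- strrep("TGCA", 5)
  anc <- paste0(left, strrep("-", 10), right)
  seqs <- stats::setNames(rep(paste0(left, strrep("A", 10), right), nrow(sp)), sp$name)
  aln <- cne_alignment("cg", "chr1", 0, 40, seqs, anc = c(tetrapod_ancestor = anc))
  # focal: 6 mismatches spread over ancestor positions 15..21 -- which span
  # the alignment gap; only a window on ungapped coordinates sees all 6
  foc <- strsplit(paste0(left, strrep("A", 10), right), "")[[1]]
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  for (p in c(16:20, 31)) foc[p] <- rot[[foc[p]]]
  aln$seqs[["pair_1"]] <- paste(foc, collapse = "")
  call <- scan_species(aln, "pair_1", sp, detection_config())
  expect_true(call$degenerated)
  expect_equal(min(call$evidence$focal_matches), 14L)
})

test_that("lineage calls flip at the published minima", {
  sp6 <- data.frame(
    name = c(sprintf("limbed_%02d", 1:2), sprintf("snake_%d", 1:6),
             sprintf("caecilian_%d", 1:4), "lizard_A_1"),
    limb_status = c(rep("limbed", 2), rep("limbless", 11)),
    lineage = c(rep(NA, 2), rep("snake", 6), rep("caecilian", 4), "lizard_A"),
    time_since_limb_loss = c(rep(NA, 2), rep(170, 6), rep(192, 4), 40),
    substitution_rate = 1e-3, stringsAsFactors = FALSE)
  cfg <- detection_config()
  mk_calls <- function(n_snake, n_cae, n_liz) {
    deg <- c(sprintf("snake_%d", seq_len(n_snake)),
             sprintf("caecilian_%d", seq_len(n_cae)),
             if (n_liz) "lizard_A_1")
    data.frame(cne_id = "c1", species = sp6$name[sp6$limb_status == "limbless"],
               degenerated = sp6$name[sp6$limb_status == "limbless"] %in% deg,
               stringsAsFactors = FALSE)
  }
  lc <- function(...) call_lineages(mk_calls(...), sp6, cfg)
  get <- function(l, lin) l$degenerated[l$lineage == lin]
  expect_false(get(lc(2, 0, 0), "snake"))   # 2 of 6 snakes: below minimum
  expect_true(get(lc(3, 0, 0), "snake"))    # 3 of 6: called
  expect_false(get(lc(0, 1, 0), "caecilian"))
  expect_true(get(lc(0, 2, 0), "caecilian"))
  expect_true(get(lc(0, 0, 1), "lizard_A")) # single-species lineage: minimum 1
  expect_equal(lc(3, 2, 1)$n_species_degenerated[lc(3, 2, 1)$lineage == "snake"], 3L)
})

test_that("convergence classes follow the lineage-combination count", {
  lcalls <- rbind(
    data.frame(cne_id = "c1", lineage = c("caecilian", "snake", "lizard_A", "lizard_B"),
               n_species_degenerated = 0L, degenerated = FALSE),
    data.frame(cne_id = "c2", lineage = c("caecilian", "snake", "lizard_A", "lizard_B"),
               n_species_degenerated = c(2L, 0L, 0L, 0L),
               degenerated = c(TRUE, FALSE, FALSE, FALSE)),
    data.frame(cne_id = "c3", lineage = c("caecilian", "snake", "lizard_A", "lizard_B"),
               n_species_degenerated = c(2L, 3L, 0L, 0L),
               degenerated = c(TRUE, TRUE, FALSE, FALSE)),
    data.frame(cne_id = "c4", lineage = c("caecilian", "snake", "lizard_A", "lizard_B"),
               n_species_degenerated = c(2L, 3L, 1L, 1L), degenerated = TRUE))
  out <- classify_convergence(lcalls)
  k <- stats::setNames(out$records$klass, out$records$cne_id)
  expect_equal(unname(k[c("c1", "c2", "c3", "c4")]),
               c("none", "lineage_specific", "convergent_2", "convergent_4"))
  expect_equal(out$records$degenerated_lineages[out$records$cne_id == "c3"],
               "caecilian+snake")
  comb <- out$summary$by_combination
  expect_equal(comb$n[comb$combination == "caecilian+snake"], 1L)
})

test_that("convergence rates divide species counts by limb-loss time", {
  sp <- data.frame(
    name = c("limbed_01", "glassy_1", "sandy_1"),
    limb_status = c("limbed", "limbless", "limbless"),
    lineage = c(NA, "glassy", "sandy"),
    time_since_limb_loss = c(NA, 40, 35),
    substitution_rate = NA_real_, stringsAsFactors = FALSE)
  n_conv <- 300L
  ids <- sprintf("c%03d", seq_len(n_conv))
  records <- data.frame(cne_id = ids, degenerated_lineages = "glassy+sandy",
                        n_lineages = 2L, klass = "convergent_2",
                        stringsAsFactors = FALSE)
  calls <- rbind(
    data.frame(cne_id = ids, species = "glassy_1",
               degenerated = seq_len(n_conv) <= 219L),
    data.frame(cne_id = ids, species = "sandy_1",
               degenerated = seq_len(n_conv) <= 267L))
  rates <- convergence_rate(records, calls, sp)
  expect_equal(rates$rate_per_myr[rates$species == "glassy_1"], 5.475)
  expect_equal(round(rates$rate_per_myr[rates$species == "sandy_1"], 2), 7.63)
  # zero qualifying elements -> rate 0
  calls$degenerated <- FALSE
  expect_equal(convergence_rate(records, calls, sp)$rate_per_myr, c(0, 0))
})

test_that("identity profiles use lineage ancestors with gap-as-mismatch", {
  sp <- tiny_species(4L); tree <- tiny_tree(sp)
  len <- 100L
  anc <- paste(rep(c("A", "C", "G", "T"), length.out = len), collapse = "")
  seqs <- stats::setNames(rep(anc, nrow(sp)), sp$name)
  seqs[["pair_2"]] <- mutate_positions(anc, 1, 25)
  seqs[["solo_1"]] <- strrep("-", len)
  aln <- cne_alignment("c1", "chr1", 0, len, seqs)
  aln <- reconstruct_ancestors(aln, tree)
  records <- data.frame(cne_id = "c1", degenerated_lineages = "",
                        n_lineages = 0L, klass = "none", stringsAsFactors = FALSE)
  prof <- identity_profiles(list(c1 = aln), sp, records)
  get <- function(s) prof$identity[prof$species == s]
  expect_equal(get("pair_1"), 1.0)     # identical to its lineage ancestor
  expect_equal(get("pair_2"), 0.75)    # 25 mismatches over 100 columns
  expect_equal(get("solo_1"), 0.0)     # fully gapped, comparable everywhere
})

test_that("detector equals the brute-force window oracle on random instances", {
  sp <- tiny_species(6L)
  cfg <- detection_config(min_limbed_species = 5L,
                          lineage_minima = c(pair = 2L))
  set.seed(99)
  n_checked <- 0L
  for (i in 1:150) {
    aln <- random_instance(sp)
    fast <- vapply(sp$name[sp$limb_status == "limbless"], function(f)
      scan_species(aln, f, sp, cfg)$degenerated, logical(1))
    slow <- oracle_scan_element(aln, sp, cfg)
    expect_identical(fast[names(slow)], slow, info = paste("instance", i))
    n_checked <- n_checked + length(slow)
  }
  expect_gte(n_checked, 450L)
})

test_that("detection is monotone in thresholds and order-invariant", {
  sp <- tiny_species(6L)
  set.seed(7)
  for (i in 1:25) {
    aln <- random_instance(sp)
    for (thr in c(10L, 12L, 14L)) {
      cfg_lo <- detection_config(min_limbed_species = 5L,
                                 limbless_identity_max_short = thr)
      cfg_hi <- detection_config(min_limbed_species = 5L,
                                 limbless_identity_max_short = thr + 2L)
      lo <- scan_species(aln, "pair_1", sp, cfg_lo)$degenerated
      hi <- scan_species(aln, "pair_1", sp, cfg_hi)$degenerated
      # lowering the focal ceiling can never create a call the higher one missed
      expect_true(!lo || hi)
    }
  }
  # species iteration order does not change calls
  demo <- build_demo_tree(seed = 13)
  alns <- simulate_cne_set(demo$tree, demo$species, 4, seed = 13)
  truth <- make_demo_truth(alns, demo$species, seed = 13,
                           scenarios = c(`caecilian+snake` = 1))
  planted <- plant_degeneration(alns, demo$species, truth, seed = 13)
  shuffled <- demo$species[rev(seq_len(nrow(demo$species))), ]
  a <- scan_all(planted$cne_set, demo$species, detection_config())$calls
  b <- scan_all(planted$cne_set, shuffled, detection_config())$calls
  key <- function(x) x[order(x$cne_id, x$species), c("cne_id", "species", "degenerated")]
  ka <- key(a); kb <- key(b)
  rownames(ka) <- rownames(kb) <- NULL
  expect_identical(ka, kb)
})
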