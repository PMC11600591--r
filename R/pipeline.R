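#' Build a demonstration plant-truth specification
#'
#' Assigns each element a degeneration scenario: none (the majority),
#' lineage-specific decay, or convergent decay in a chosen lineage
#' combination; each planted lineage receives either a substitution burst to
#' 55% identity or a deletion, over a 60 bp interval, in every member species
#' (so lineage minima are met by construction).
#'
#' @param cne_set Named list of `cne_alignment`.
#' @param species Validated species data.frame.
#' @param seed Integer seed.
#' @param scenarios Named numeric vector of scenario weights; names are
#'   "+"-joined lineage combinations, `"none"` for untouched elements.
#' @param span Planted interval width (default 60).
#' @param burst_identity Target identity of substitution bursts (default 0.55).
#' @return A truth-spec data.frame for [plant_degeneration()].
#' @export
make_demo_truth <- function(cne_set, species, seed = 1L,
                            scenarios = c(none = 0.60, caecilian = 0.10,
                                          snake = 0.10, `caecilian+snake` = 0.10,
                                          `lizard_A+snake` = 0.05,
                                          `caecilian+lizard_A+lizard_B+snake` = 0.05),
                            span = 60L, burst_identity = 0.55) {
  ids <- names(cne_set)
  with_seed(derive_seed(seed, "make_demo_truth"), {
    pick <- sample(names(scenarios), length(ids), replace = TRUE,
                   prob = scenarios / sum(scenarios))
    rows <- list()
    for (i in seq_along(ids)) {
      if (pick[i] == "none") next
      L <- aln_ncol(cne_set[[ids[i]]])
      if (L < span) next
      s <- sample.int(L - span + 1L, 1L) - 1L
      for (lin in strsplit(pick[i], "+", fixed = TRUE)[[1L]]) {
        mode <- if (stats::runif(1) < 0.5) "substitution_burst" else "deletion"
        rows[[length(rows) + 1L]] <- data.frame(
          cne_id = ids[i], target = lin, mode = mode,
          start = s, end = s + span,
          identity = if (mode == "substitution_burst") burst_identity else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
    if (!length(rows)) return(data.frame(cne_id = character(), target = character(),
      mode = character(), start = integer(), end = integer(), identity = numeric()))
    do.call(rbind, rows)
  })
}

#' Run the whole demonstration pipeline in memory
#'
#' simulate -> plant -> catalog -> ancestors -> detect -> converge -> rates ->
#' identity profiles -> neutral contrast -> limb-gene enrichment -> region-set
#' enrichment -> intron screen -> annotation -> report. Everything is driven
#' by one seed and one configuration; the returned list carries every
#' intermediate product plus a compact `report`.
#'
#' @param seed Integer run seed.
#' @param n_cnes Number of simulated elements (default 120).
#' @param cfg A [detection_config()].
#' @param rate_scale Conservation damping for the CNE simulation.
#' @param n_neutral_replicates Neutral replicates per element (default 10; the
#'   neutral stage caps work at `max_neutral_cnes` elements per group).
#' @param max_neutral_cnes Elements per identity group entering the neutral
#'   simulation (keeps the demo fast; default 40).
#' @param mc_trials Monte Carlo trials for the intron overlap test.
#' @param keep_evidence Keep per-window evidence rows.
#' @return List with all stage outputs and `report` (plain-list summary).
#' @export
run_demo <- function(seed = 1L, n_cnes = 120L, cfg = detection_config(),
                     rate_scale = 0.03, n_neutral_replicates = 10L,
                     max_neutral_cnes = 40L, mc_trials = 20000L,
                     keep_evidence = TRUE) {
  log_run("run_demo", cfg, seed)
  demo <- build_demo_tree(seed = seed)
  species <- demo$species; tree <- demo$tree

  cnes <- simulate_cne_set(tree, species, n_cnes = n_cnes, seed = seed,
                           rate_scale = rate_scale)
  truth_spec <- make_demo_truth(cnes, species, seed = seed)
  planted <- plant_degeneration(cnes, species, truth_spec, seed = seed)
  cnes <- planted$cne_set

  # catalog: clip two elements with a synthetic coding mask, then filter
  b1 <- cnes[[1L]]; b2 <- cnes[[2L]]
  coding_mask <- interval_set(
    chrom = b1$chrom,
    start = c(b1$start + 10L, b2$start),
    end = c(b1$start + 40L, b2$end))
  blocks <- lapply(cnes, function(a) cne_alignment(a$cne_id, a$chrom, a$start,
                                                   a$end, a$seqs))
  flt <- filter_cnes(blocks, coding_mask, species, cfg)

  recon <- reconstruct_all(flt$retained, tree)
  scans <- scan_all(recon, species, cfg, keep_evidence = keep_evidence)
  lcalls <- call_lineages(scans$calls, species, cfg)
  conv <- classify_convergence(lcalls)
  rates <- convergence_rate(conv$records, scans$calls, species)
  profiles <- identity_profiles(recon, species, conv$records)

  # neutral contrast on a capped subset of elements per group
  grp_ids <- function(g) unique(profiles$cne_id[profiles$group == g])
  sub_ids <- c(utils::head(grp_ids("non_dcne"), max_neutral_cnes),
               utils::head(grp_ids("convergent_dcne"), max_neutral_cnes))
  neutral <- neutral_identity_set(recon[intersect(names(recon), sub_ids)],
                                  species, tree,
                                  n_replicates = n_neutral_replicates, seed = seed)
  contrast <- neutral_contrast(profiles[profiles$cne_id %in% sub_ids, ], neutral)

  fixtures <- generate_feature_fixtures(cnes, planted$truth, seed = seed)
  tss <- interval_set(fixtures$genes$chrom, fixtures$genes$tss,
                      fixtures$genes$tss + 1L, name = fixtures$genes$gene_id)
  links <- associate_genes(recon, tss, cfg)
  limb_test <- suppressWarnings(
    dcne_limb_gene_test(conv$records, links, fixtures$limb_genes))

  cne_iv <- interval_set(vapply(recon, `[[`, "", "chrom"),
                         vapply(recon, `[[`, 0L, "start"),
                         vapply(recon, `[[`, 0L, "end"),
                         name = names(recon))
  conv_ids <- conv$records$cne_id[conv$records$n_lineages >= 2L]
  region <- if (length(conv_ids) >= 2L)
    region_set_enrichment(cne_iv[cne_iv$name %in% conv_ids, ], cne_iv,
                          fixtures$tracks) else NULL

  orth_flt <- suppressWarnings(filter_ortholog_set(
    fixtures$orthologs, fixtures$ref_species, fixtures$focal_species))
  lim <- limited_expansion_genes(
    fixtures$orthologs[fixtures$orthologs$gene_id %in% orth_flt$retained, ],
    orth_flt$medians, fixtures$focal_species)
  mc <- mc_overlap_test(length(orth_flt$retained),
                        set_sizes = lengths(lim$per_species),
                        observed_overlap = length(lim$intersection),
                        n_trials = mc_trials, seed = seed)

  cne_map <- data.frame(cne_id = names(recon),
                        chrom = vapply(recon, `[[`, "", "chrom"),
                        start = vapply(recon, `[[`, 0L, "start"),
                        end = vapply(recon, `[[`, 0L, "end"),
                        stringsAsFactors = FALSE)
  act <- enhancer_activity(cne_map, fixtures$tracks)
  # pleiotropy is reported for the convergent elements (the cohort of interest)
  act_conv <- structure(list(active = act$active[rownames(act$active) %in% conv_ids, ,
                                                 drop = FALSE],
                             unmapped = act$unmapped), class = "activity_matrix")
  pleio <- pleiotropy_summary(act_conv)
  origins <- assign_origin(fixtures$presence[rownames(fixtures$presence) %in% conv_ids, ,
                                             drop = FALSE], fixtures$ladder)

  report <- list(
    seed = seed, n_simulated = n_cnes,
    n_retained_cnes = length(recon),
    n_rejected_blocks = nrow(flt$rejections),
    n_dcnes = sum(conv$records$n_lineages >= 1L),
    n_lineage_specific = sum(conv$records$klass == "lineage_specific"),
    n_convergent = sum(conv$records$n_lineages >= 2L),
    combinations = conv$summary$by_combination,
    rates = rates[, c("species", "lineage", "n_convergent_dcnes", "rate_per_myr")],
    neutral_means = contrast$means,
    neutral_max_p = max(contrast$tests$p_value),
    limb_gene_min_q = if (nrow(limb_test)) min(limb_test$q_value) else NA_real_,
    region_top = if (!is.null(region)) region$label[1L] else NA_character_,
    n_limited_shared = length(lim$intersection),
    mc_z = mc$z_score, mc_p = mc$empirical_p,
    fraction_pleiotropic = pleio$fraction_pleiotropic,
    origin_counts = as.list(table(origins$origin)))

  list(species = species, tree = tree, truth = planted$truth,
       coding_mask = coding_mask, filtered = flt, alignments = recon,
       scans = scans, lineage_calls = lcalls, convergence = conv,
       rates = rates, profiles = profiles, neutral = neutral,
       contrast = contrast, fixtures = fixtures, links = links,
       limb_test = limb_test, region = region, ortholog_filter = orth_flt,
       limited = lim, mc = mc, activity = act, pleiotropy = pleio,
       origins = origins, config = cfg, report = report)
}

#' Write the demo report as JSON
#' @param demo Output of [run_demo()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_demo_report <- function(demo, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(demo$report, path, auto_unbox = TRUE, digits = 10,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}
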