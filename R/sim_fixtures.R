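#' Generate gene, enhancer, ortholog and outgroup-presence fixtures
#'
#' Produces every downstream feature input with known ground truth, keyed to a
#' simulated CNE set:
#' \itemize{
#' \item a gene table (written as GFF3) with one gene per element at a
#'   controlled TSS distance, plus two boundary genes at exactly 999,999 and
#'   1,000,001 bp from the first element;
#' \item a limb-related gene subset: the genes of planted (degenerate-truth)
#'   elements, so the limb-gene overlap test has a planted effect to recover;
#' \item per-pseudo-tissue enhancer tracks with -log10 p scores straddling the
#'   activity threshold of 2 (planted-active intervals score > 2; decoys at
#'   exactly 2.0 and below), with the true activity matrix retained;
#' \item a 17-species ortholog intron/exon table in which designated gene sets
#'   of chosen sizes show limited intron expansion per focal species, with a
#'   chosen triple intersection (defaults 127/323/327, shared 49);
#' \item an outgroup presence/absence matrix with known origin labels.
#' }
#' Fixtures self-verify before being returned: the limited-expansion sets are
#' re-measured from the emitted table and must equal the plan exactly.
#'
#' @param cne_set Named list of `cne_alignment`.
#' @param truth Plant-truth table from [plant_degeneration()].
#' @param seed Integer seed.
#' @param tissues Pseudo-tissue names for the enhancer tracks.
#' @param limited_sizes Per-focal-species limited-expansion set sizes.
#' @param shared_limited Size of the triple intersection.
#' @param n_ortholog_genes Universe size of the ortholog table before the
#'   filter-violating decoys are added.
#' @return A fixture bundle (list); see the elements in the code below.
#' @export
generate_feature_fixtures <- function(cne_set, truth, seed = 1L,
                                      tissues = c("limb_E11", "forebrain",
                                                  "heart", "liver", "midbrain"),
                                      limited_sizes = c(lungfish = 127L,
                                                        banna_caecilian = 323L,
                                                        axolotl = 327L),
                                      shared_limited = 49L,
                                      n_ortholog_genes = 1000L) {
  ids <- names(cne_set)
  chrom <- cne_set[[1L]]$chrom
  planted_ids <- unique(truth$cne_id)
  with_seed(derive_seed(seed, "generate_feature_fixtures"), {
    ## -- genes: one per element at a controlled distance, plus boundary pair
    starts <- vapply(cne_set, `[[`, 0L, "start")
    ends <- vapply(cne_set, `[[`, 0L, "end")
    dist <- sample(1000:20000, length(ids), replace = TRUE)
    tss <- ends - 1L + dist    # downstream of the element, within spacing
    genes <- data.frame(gene_id = paste0("gene_", ids), chrom = chrom,
                        tss = as.integer(tss), strand = "+",
                        stringsAsFactors = FALSE)
    boundary <- data.frame(
      gene_id = c("gene_boundary_in", "gene_boundary_out"), chrom = chrom,
      tss = as.integer(c(ends[1L] - 1L + 999999L, ends[1L] - 1L + 1000001L)),
      strand = "+", stringsAsFactors = FALSE)
    genes <- rbind(genes, boundary)
    limb_genes <- paste0("gene_", planted_ids)

    ## -- enhancer tracks with planted activity
    active_truth <- matrix(FALSE, length(ids), length(tissues),
                           dimnames = list(ids, tissues))
    # planted elements: always active in the limb tissue, plus 0-2 further
    # tissues (so most, not all, are pleiotropic); a third of the rest active
    # in exactly 1 tissue; the rest silent
    for (id in ids) {
      if (id %in% planted_ids) {
        k <- sample(0:2, 1L, prob = c(0.3, 0.4, 0.3))
        on <- c(1L, if (k) sample(2:length(tissues), k))
        active_truth[id, on] <- TRUE
      } else if (stats::runif(1) < 1 / 3) {
        active_truth[id, sample(length(tissues), 1L)] <- TRUE
      }
    }
    tracks <- lapply(tissues, function(t) {
      on_ids <- ids[active_truth[, t]]
      s <- unname(starts[on_ids]); e <- unname(ends[on_ids])
      iv <- if (length(on_ids)) data.frame(
        chrom = chrom,
        start = pmax(0L, s - sample(0:10, length(on_ids), TRUE)),
        end = e + sample(0:10, length(on_ids), TRUE),
        score = round(stats::runif(length(on_ids), 2.5, 6), 3))
      else NULL
      # decoys: overlapping but sub-threshold (one at exactly 2.0), and
      # hot intervals that overlap nothing
      off_ids <- utils::head(setdiff(ids, on_ids), 5L)
      dec <- if (length(off_ids)) data.frame(
        chrom = chrom, start = unname(starts[off_ids]), end = unname(ends[off_ids]),
        score = c(2.0, round(stats::runif(length(off_ids) - 1L, 0.5, 1.9), 3))[seq_along(off_ids)])
      else NULL
      gap <- data.frame(chrom = chrom, start = max(ends) + 100000L + 1:3 * 1000L,
                        end = max(ends) + 100000L + 1:3 * 1000L + 200L,
                        score = 5)
      all <- rbind(iv, dec, gap)
      interval_set(all$chrom, all$start, all$end, score = all$score)
    })
    names(tracks) <- tissues

    ## -- ortholog intron/exon table with planted limited-expansion sets
    ref_species <- sprintf("ref_%02d", 1:14)
    focal <- names(limited_sizes)
    gene_ids <- sprintf("og%04d", seq_len(n_ortholog_genes))
    shared <- gene_ids[seq_len(shared_limited)]
    pool <- setdiff(gene_ids, shared)
    lim_sets <- list(); used <- character()
    for (sp in focal) {
      extra <- setdiff(pool, used)[seq_len(limited_sizes[[sp]] - shared_limited)]
      used <- c(used, extra)
      lim_sets[[sp]] <- sort(c(shared, extra))
    }
    med_true <- exp(stats::rnorm(n_ortholog_genes, log(2e4), 0.8))
    exon_true <- exp(stats::rnorm(n_ortholog_genes, log(1500), 0.4))
    rows <- list()
    for (i in seq_along(ref_species)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gene_ids, species = ref_species[i],
        intron_len = round(med_true * stats::runif(n_ortholog_genes, 0.85, 1.18)),
        exon_len = round(exon_true), stringsAsFactors = FALSE)
    }
    for (sp in focal) {
      lim <- gene_ids %in% lim_sets[[sp]]
      fac <- ifelse(lim, stats::runif(n_ortholog_genes, 0.3, 1.8),
                    stats::runif(n_ortholog_genes, 2.6, 8))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gene_ids, species = sp,
        intron_len = round(med_true * fac),
        exon_len = round(exon_true * stats::runif(n_ortholog_genes, 0.92, 1.08)),
        stringsAsFactors = FALSE)
    }
    orth <- do.call(rbind, rows)
    # filter-violating decoys: exon deviation > 40% in a focal species, and
    # genes with introns absent in 7 species
    dev_ids <- sprintf("dev%03d", 1:20)
    abs_ids <- sprintf("abs%03d", 1:15)
    for (g in dev_ids) {
      e <- 1200
      orth <- rbind(orth,
        data.frame(gene_id = g, species = ref_species, intron_len = 30000,
                   exon_len = e, stringsAsFactors = FALSE),
        data.frame(gene_id = g, species = focal, intron_len = 35000,
                   exon_len = round(e * 1.6), stringsAsFactors = FALSE))
    }
    for (g in abs_ids) {
      has <- c(ref_species[1:8], focal[1:2])   # introns absent in the other 7
      orth <- rbind(orth,
        data.frame(gene_id = g, species = has, intron_len = 25000,
                   exon_len = 1400, stringsAsFactors = FALSE),
        data.frame(gene_id = g, species = c(ref_species[9:14], focal[3]),
                   intron_len = 0L, exon_len = 1400, stringsAsFactors = FALSE))
    }
    # self-verify: re-measure the planted sets from the emitted table
    flt <- suppressWarnings(filter_ortholog_set(orth, ref_species, focal))
    lim <- limited_expansion_genes(orth[orth$gene_id %in% flt$retained, ],
                                   flt$medians, focal)
    for (sp in focal) {
      if (!identical(lim$per_species[[sp]], lim_sets[[sp]]))
        stop("fixture self-check failed: limited set mismatch for ", sp)
    }
    if (!identical(lim$intersection, sort(shared)))
      stop("fixture self-check failed: shared limited set mismatch")

    ## -- outgroup presence/absence with known origins
    ladder <- default_origin_ladder()
    true_rank <- sample(0:max(ladder$depth_rank), length(ids), replace = TRUE)
    presence <- matrix(FALSE, length(ids), nrow(ladder),
                       dimnames = list(ids, ladder$species))
    for (i in seq_along(ids)) {
      r <- true_rank[i]
      if (r == 0L) next
      at <- ladder$species[ladder$depth_rank == r]
      presence[i, sample(at, 1L)] <- TRUE
      shallower <- ladder$species[ladder$depth_rank < r]
      if (length(shallower))
        presence[i, shallower] <- stats::runif(length(shallower)) < 0.7
    }
    rank_label <- c("tetrapod_ancestor",
                    ladder$origin[match(1:max(ladder$depth_rank), ladder$depth_rank)])
    origin_truth <- data.frame(cne_id = ids, depth_rank = true_rank,
                               origin = rank_label[true_rank + 1L],
                               stringsAsFactors = FALSE)

    list(genes = genes, limb_genes = limb_genes,
         tracks = tracks, activity_truth = active_truth,
         orthologs = orth, ref_species = ref_species, focal_species = focal,
         limited_truth = lim_sets, shared_limited = sort(shared),
         presence = presence, origin_truth = origin_truth, ladder = ladder)
  })
}

#' Write a fixture bundle to disk in the pipeline's exchange formats
#'
#' Genes as GFF3, limb genes and orthologs and the origin ladder as TSV,
#' enhancer tracks as BED5, outgroup presence as TSV.
#'
#' @param bundle From [generate_feature_fixtures()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- bundle$genes
  gff <- sprintf("%s\tcnedegen\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                 g$chrom, g$tss + 1L, g$tss + 1000L, g$strand, g$gene_id)
  writeLines(c("##gff-version 3", gff), file.path(dir, "genes.gff3"))
  writeLines(bundle$limb_genes, file.path(dir, "limb_genes.txt"))
  trdir <- file.path(dir, "tracks")
  dir.create(trdir, showWarnings = FALSE)
  for (t in names(bundle$tracks)) {
    iv <- bundle$tracks[[t]]
    iv$name <- paste0(t, "_", seq_len(nrow(iv)))
    write_bed(iv, file.path(trdir, paste0(t, ".bed")))
  }
  utils::write.table(bundle$orthologs, file.path(dir, "orthologs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pres <- data.frame(cne_id = rownames(bundle$presence),
                     bundle$presence + 0L, check.names = FALSE)
  utils::write.table(pres, file.path(dir, "outgroup_presence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$ladder, file.path(dir, "origin_ladder.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
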