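#' Per-gene reference medians of intron and exon length
#'
#' Medians are computed only over the designated reference species with
#' non-missing values (the published design uses 14 reference vertebrates,
#' excluding the three large-genome focal species).
#'
#' @param tbl Long-format ortholog table: gene_id, species, intron_len,
#'   exon_len (NA = missing ortholog).
#' @param ref_species Character vector of reference species names.
#' @return Data.frame: gene_id, median_intron, median_exon, n_ref.
#' @export
ortholog_medians <- function(tbl, ref_species) {
  stopifnot(all(c("gene_id", "species", "intron_len", "exon_len") %in% names(tbl)))
  ref <- tbl[tbl$species %in% ref_species & !is.na(tbl$intron_len), ]
  sp <- split(ref, ref$gene_id)
  data.frame(gene_id = names(sp),
             median_intron = vapply(sp, function(x) stats::median(x$intron_len), numeric(1)),
             median_exon = vapply(sp, function(x) stats::median(x$exon_len, na.rm = TRUE), numeric(1)),
             n_ref = vapply(sp, nrow, integer(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter the ortholog set before the intron-expansion screen
#'
#' A gene is rejected if, in any evaluated focal species, its exon length
#' deviates from the reference median exon length by strictly more than 40%,
#' or if the number of species (over the whole table) with no introns
#' (missing or zero intron length) is strictly more than `max_absent`.
#'
#' @param tbl Long-format ortholog table (see [ortholog_medians()]).
#' @param ref_species Reference species for medians.
#' @param focal_species Species whose exon deviation is evaluated.
#' @param max_exon_dev Maximum tolerated relative exon deviation (default 0.40).
#' @param max_absent Maximum tolerated count of intron-less species (default 6).
#' @return List: `retained` (gene ids), `medians` (for retained genes),
#'   `rejections` (gene_id, rule).
#' @export
filter_ortholog_set <- function(tbl, ref_species, focal_species,
                                max_exon_dev = 0.40, max_absent = 6L) {
  med <- ortholog_medians(tbl, ref_species)
  all_species <- unique(tbl$species)
  rej <- list()
  reject <- function(g, rule)
    rej[[length(rej) + 1L]] <<- data.frame(gene_id = g, rule = rule,
                                           stringsAsFactors = FALSE)
  keep <- character()
  for (g in med$gene_id) {
    row <- med[med$gene_id == g, ]
    sub <- tbl[tbl$gene_id == g, ]
    if (is.na(row$median_exon) || row$median_exon == 0) {
      warning("gene with zero/undefined median exon length rejected: ", g)
      reject(g, "zero_median_exon"); next
    }
    foc <- sub[sub$species %in% focal_species & !is.na(sub$exon_len), ]
    if (nrow(foc) && any(abs(foc$exon_len - row$median_exon) / row$median_exon > max_exon_dev)) {
      reject(g, "exon_deviation"); next
    }
    # species missing from the table for this gene count as intron-less too
    vals <- sub$intron_len[match(all_species, sub$species)]
    n_absent <- sum(is.na(vals) | vals == 0)
    if (n_absent > max_absent) { reject(g, "introns_absent"); next }
    keep <- c(keep, g)
  }
  rejections <- if (length(rej)) do.call(rbind, rej) else
    data.frame(gene_id = character(), rule = character())
  list(retained = keep, medians = med[med$gene_id %in% keep, , drop = FALSE],
       rejections = rejections)
}

#' Intron expansion length and rate for one gene in one species
#'
#' Expansion length = species intron length minus the reference median;
#' expansion rate = species intron length divided by the reference median.
#'
#' @param intron_len Total intron length of the gene in the species (bp).
#' @param median_intron Reference median intron length (bp, > 0).
#' @return List: `expansion_length` (bp, may be negative), `expansion_rate`.
#' @export
expansion_metrics <- function(intron_len, median_intron) {
  if (is.na(median_intron) || median_intron <= 0) stop("median intron length must be > 0")
  list(expansion_length = intron_len - median_intron,
       expansion_rate = intron_len / median_intron)
}

#' Genes with limited intron expansion in focal large-genome species
#'
#' A gene is "limited" in a focal species when its intron length there is
#' strictly less than `multiplier` (default 2) times the reference median.
#' Returns per-species gene sets and their k-way intersection — the candidate
#' set of genes under selective pressure against intron growth.
#'
#' @param tbl Long-format ortholog table.
#' @param medians Data.frame from [ortholog_medians()] (or the `medians`
#'   element of [filter_ortholog_set()]).
#' @param focal_species Nonempty character vector.
#' @param multiplier Expansion bound (default 2).
#' @return List: `per_species` (named list of gene-id vectors),
#'   `intersection` (character vector).
#' @export
limited_expansion_genes <- function(tbl, medians, focal_species, multiplier = 2) {
  if (!length(focal_species)) stop("focal species list is empty")
  per <- lapply(focal_species, function(sp) {
    sub <- tbl[tbl$species == sp & !is.na(tbl$intron_len), ]
    m <- medians$median_intron[match(sub$gene_id, medians$gene_id)]
    ok <- !is.na(m) & m > 0 & sub$intron_len < multiplier * m
    sort(sub$gene_id[ok])
  })
  names(per) <- focal_species
  list(per_species = per, intersection = sort(Reduce(intersect, per)))
}

#' Monte Carlo test for multi-set gene overlap
#'
#' Null model: each species' limited-expansion gene set is an independent
#' uniform draw without replacement from the universe of filtered orthologs;
#' the statistic is the size of the k-way intersection. Reports the trial
#' mean and SD, `z = (observed - mean)/sd`, the add-one-smoothed upper-tail
#' empirical p `(x + 1)/(n + 1)` where `x` counts trials with overlap >=
#' observed, and the trial histogram.
#'
#' @param universe_size Number of genes in the filtered universe.
#' @param set_sizes Integer vector of per-species set sizes (default the
#'   published 127, 323, 327).
#' @param observed_overlap Observed intersection size (default the published 49).
#' @param n_trials Number of trials (default 100000).
#' @param seed Integer seed.
#' @return List of class `mc_overlap`: mean, sd, z_score, empirical_p,
#'   n_exceedances, n_trials, expected (n1 n2 n3 / N^2 for 3 sets), histogram
#'   (data.frame overlap, count), degenerate_sd flag.
#' @export
mc_overlap_test <- function(universe_size, set_sizes = c(127L, 323L, 327L),
                            observed_overlap = 49L, n_trials = 100000L, seed = 1L) {
  N <- as.integer(universe_size)
  if (any(set_sizes > N)) stop("set sizes must not exceed the universe size")
  if (observed_overlap > min(set_sizes)) stop("observed overlap exceeds smallest set")
  k <- length(set_sizes)
  overlaps <- with_seed(derive_seed(seed, "mc_overlap_test"), {
    vapply(seq_len(n_trials), function(i) {
      counts <- integer(N)
      for (s in set_sizes) {
        idx <- sample.int(N, s)
        counts[idx] <- counts[idx] + 1L
      }
      sum(counts == k)
    }, integer(1))
  })
  mu <- mean(overlaps); sdv <- stats::sd(overlaps)
  degenerate <- !is.na(sdv) && sdv == 0
  z <- if (degenerate) {
    if (observed_overlap == mu) 0 else sign(observed_overlap - mu) * Inf
  } else (observed_overlap - mu) / sdv
  x <- sum(overlaps >= observed_overlap)
  expected <- prod(as.numeric(set_sizes)) / as.numeric(N)^(k - 1L)
  h <- as.data.frame(table(overlap = overlaps), stringsAsFactors = FALSE)
  h$overlap <- as.integer(h$overlap); names(h)[2] <- "count"
  structure(list(mean = mu, sd = sdv, z_score = z,
                 empirical_p = (x + 1) / (n_trials + 1),
                 n_exceedances = x, n_trials = n_trials,
                 expected = expected, histogram = h,
                 degenerate_sd = degenerate), class = "mc_overlap")
}

#' @export
print.mc_overlap <- function(x, ...) {
  cat(sprintf("<mc_overlap> mean=%.3f sd=%.3f z=%.2f p=%.3g (%d/%d trials >= observed)\n",
              x$mean, x$sd, x$z_score, x$empirical_p, x$n_exceedances, x$n_trials))
  invisible(x)
}
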