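#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Rows: in foreground / not; columns: has property / not. The two-sided p
#' sums hypergeometric probabilities no larger than the observed table's (the
#' R convention). Reports the sample odds ratio `ad/bc` and, whenever any
#' cell is 0, the Haldane-Anscombe (+0.5) corrected ratio alongside.
#'
#' @param a,b,c,d Nonnegative counts.
#' @param label Optional result label.
#' @return Data.frame of class `enrichment_result`: label, a..d, odds_ratio,
#'   odds_ratio_haldane, p_value, q_value (NA until [bh_fdr()] is applied).
#' @export
fisher_exact <- function(a, b, c, d, label = NA_character_) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) stop("counts must be nonnegative integers")
  m <- matrix(as.integer(cells), 2, 2, byrow = TRUE)
  p <- stats::fisher.test(m, alternative = "two.sided")$p.value
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  or_h <- ((a + .5) * (d + .5)) / ((b + .5) * (c + .5))
  if (a * d == 0 && b * c == 0) or <- NaN
  if (a * d == 0 && b * c > 0) or <- 0
  res <- data.frame(label = label, a = a, b = b, c = c, d = d,
                    odds_ratio = or,
                    odds_ratio_haldane = if (any(cells == 0)) or_h else NA_real_,
                    p_value = min(1, p), q_value = NA_real_,
                    stringsAsFactors = FALSE)
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `q_i = min_{j >= i} m * p_(j) / j`, returned in input order and capped at 1.
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Overlap of convergent dCNEs with limb-related genes (Fisher, CNE units)
#'
#' For each lineage combination: foreground = convergent elements degenerated
#' in exactly that combination of limbless lineages, background = the entire
#' CNE set; property = linked (within the TSS radius) to at least one
#' limb-related gene. BH adjustment runs across combinations.
#'
#' @param records Data.frame from [classify_convergence()]`$records`.
#' @param links Data.frame from [associate_genes()].
#' @param limb_genes Character vector of limb-related gene ids.
#' @param combinations Character vector of "+"-joined lineage combinations to
#'   test; default: every convergent combination observed.
#' @param unit `"cne"` (default; background = all CNEs) or `"gene"`
#'   (foreground/background counted over linked genes).
#' @return `enrichment_result` data.frame, one row per combination.
#' @export
dcne_limb_gene_test <- function(records, links, limb_genes,
                                combinations = NULL, unit = c("cne", "gene")) {
  unit <- match.arg(unit)
  if (is.null(combinations)) {
    combinations <- sort(unique(records$degenerated_lineages[records$n_lineages >= 2L]))
  }
  out <- list()
  for (comb in combinations) {
    fg_ids <- records$cne_id[records$degenerated_lineages == comb]
    if (unit == "cne") {
      linked <- unique(links$cne_id[links$gene_id %in% limb_genes])
      bg_ids <- records$cne_id
      a <- sum(fg_ids %in% linked)
      b <- length(fg_ids) - a
      c_ <- sum(bg_ids %in% linked) - a
      d <- length(bg_ids) - length(fg_ids) - c_
    } else {
      fg_genes <- unique(links$gene_id[links$cne_id %in% fg_ids])
      bg_genes <- unique(links$gene_id)
      a <- sum(fg_genes %in% limb_genes)
      b <- length(fg_genes) - a
      c_ <- sum(bg_genes %in% limb_genes) - a
      d <- length(bg_genes) - length(fg_genes) - c_
    }
    r <- if (length(fg_ids) == 0L) {
      warning("empty foreground for combination '", comb, "'")
      fisher_exact(0L, 0L, c_, d, label = comb)
    } else fisher_exact(a, b, c_, d, label = comb)
    out[[comb]] <- r
  }
  res <- do.call(rbind, out)
  res$q_value <- bh_fdr(res$p_value)
  rownames(res) <- NULL
  res
}

#' Region-set enrichment of a foreground interval set against a universe
#'
#' LOLA-style: per named region set, a 2x2 table over universe elements
#' (overlaps the set by >= 1 bp or not, crossed with membership in the
#' foreground), Fisher-tested and BH-adjusted across sets. Element-level
#' counting (each universe element counts once).
#'
#' @param foreground `interval_set`; must be a subset of `universe` (matched
#'   by chrom/start/end identity).
#' @param universe `interval_set` of all elements.
#' @param region_db Named list of `interval_set` (e.g. per-tissue tracks), or
#'   a directory of `.bed` files read as such.
#' @return `enrichment_result` data.frame, one row per region set, sorted by p.
#' @export
region_set_enrichment <- function(foreground, universe, region_db) {
  if (is.character(region_db)) {
    files <- list.files(region_db, pattern = "\\.bed$", full.names = TRUE)
    region_db <- stats::setNames(lapply(files, read_intervals),
                                 sub("\\.bed$", "", basename(files)))
  }
  key <- function(x) paste(x$chrom, x$start, x$end)
  in_fg <- key(universe) %in% key(foreground)
  if (sum(in_fg) < nrow(foreground))
    stop("foreground contains elements absent from the universe")
  out <- list()
  for (nm in names(region_db)) {
    set <- region_db[[nm]]
    ov <- vapply(seq_len(nrow(universe)), function(i)
      overlaps_any(universe$chrom[i], universe$start[i], universe$end[i], set),
      logical(1))
    r <- fisher_exact(sum(in_fg & ov), sum(in_fg & !ov),
                      sum(!in_fg & ov), sum(!in_fg & !ov), label = nm)
    out[[nm]] <- r
  }
  res <- do.call(rbind, out)
  res$q_value <- bh_fdr(res$p_value)
  res <- res[order(res$p_value), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Hypergeometric term enrichment over flat annotation sets
#'
#' Per term, the upper-tail hypergeometric probability of an overlap at least
#' as large as observed between `gene_set` and the term's genes, over
#' `universe_genes`; BH across terms; `significant` flags q < `fdr`.
#'
#' @param gene_set Character vector (subset of the universe).
#' @param term_annotations Named list: term -> character vector of genes.
#' @param universe_genes Character vector.
#' @param fdr Significance threshold on q (default 0.01).
#' @return Data.frame: term, n_term, n_set, overlap, p_value, q_value,
#'   significant.
#' @export
term_enrichment <- function(gene_set, term_annotations, universe_genes, fdr = 0.01) {
  if (!all(gene_set %in% universe_genes)) stop("gene_set must lie in the universe")
  N <- length(unique(universe_genes)); n <- length(unique(gene_set))
  rows <- list()
  for (term in names(term_annotations)) {
    tg <- intersect(term_annotations[[term]], universe_genes)
    K <- length(tg)
    if (K == 0L) { warning("term with no universe genes skipped: ", term); next }
    x <- length(intersect(gene_set, tg))
    p <- stats::phyper(x - 1L, K, N - K, n, lower.tail = FALSE)
    rows[[term]] <- data.frame(term = term, n_term = K, n_set = n, overlap = x,
                               p_value = p, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(data.frame(term = character(), n_term = integer(),
    n_set = integer(), overlap = integer(), p_value = numeric(),
    q_value = numeric(), significant = logical()))
  res <- do.call(rbind, rows)
  res$q_value <- bh_fdr(res$p_value)
  res$significant <- res$q_value < fdr
  rownames(res) <- NULL
  res[order(res$p_value), , drop = FALSE]
}

#' Pairwise Welch t-tests between groups of identity fractions
#'
#' Used for the three-way contrast of non-dCNEs, convergent dCNEs and
#' neutrally simulated sequences. Also emits a binned histogram summary per
#' group for plotting.
#'
#' @param groups Named list: label -> numeric vector of identity fractions.
#' @param breaks Histogram breaks over `[0, 1]`.
#' @return List with `tests` (group_a, group_b, mean_a, mean_b, t, df,
#'   p_value) and `histograms` (group, bin_lo, bin_hi, count).
#' @export
compare_identity_groups <- function(groups, breaks = seq(0, 1, by = 0.05)) {
  if (length(groups) < 2L) stop("need >= 2 groups")
  ns <- lengths(groups)
  if (any(ns < 2L)) stop("every group needs n >= 2: ",
                         paste(names(groups)[ns < 2L], collapse = ", "))
  labs <- names(groups)
  rows <- list()
  for (i in seq_along(labs)) for (j in seq_along(labs)) {
    if (j <= i) next
    x <- groups[[i]]; y <- groups[[j]]
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      eq <- isTRUE(all.equal(mean(x), mean(y)))
      tt <- list(statistic = if (eq) 0 else Inf, parameter = NA_real_,
                 p.value = if (eq) 1 else 0)
    } else tt <- stats::t.test(x, y, var.equal = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      group_a = labs[i], group_b = labs[j], mean_a = mean(x), mean_b = mean(y),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value, stringsAsFactors = FALSE)
  }
  hists <- do.call(rbind, lapply(labs, function(l) {
    h <- graphics::hist(pmin(pmax(groups[[l]], 0), 1), breaks = breaks, plot = FALSE)
    data.frame(group = l, bin_lo = utils::head(h$breaks, -1),
               bin_hi = h$breaks[-1], count = h$counts, stringsAsFactors = FALSE)
  }))
  list(tests = do.call(rbind, rows), histograms = hists)
}
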