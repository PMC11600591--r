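#' Apply CNE retention filters to candidate conserved blocks
#'
#' Reproduces the published post-filters on precomputed conserved blocks:
#' coding reference positions are subtracted (a block is split when the mask
#' bisects it), and each surviving piece is retained iff its ungapped
#' reference length strictly exceeds `min_cne_length` (the ">30 bp" rule) and
#' at least `min_limbed_species` limbed species are present (>= 1 non-gap,
#' non-N column). Blocks on chromosomes absent from the mask are kept with a
#' warning. Split pieces get suffixed ids (`<id>.1`, `<id>.2`, ...).
#'
#' @param blocks Named list of `cne_alignment` (columns in register with the
#'   reference interval: one column per reference bp).
#' @param coding_mask An `interval_set` of coding regions on the reference.
#' @param species Validated species data.frame.
#' @param cfg A [detection_config()].
#' @return List with `retained` (named list of `cne_alignment`) and
#'   `rejections` (data.frame cne_id, rule).
#' @export
filter_cnes <- function(blocks, coding_mask, species, cfg = detection_config()) {
  limbed <- species$name[species$limb_status == "limbed"]
  retained <- list(); rej <- list()
  reject <- function(id, rule)
    rej[[length(rej) + 1L]] <<- data.frame(cne_id = id, rule = rule,
                                           stringsAsFactors = FALSE)
  for (b in blocks) {
    if (aln_ncol(b) != b$end - b$start)
      stop("block '", b$cne_id, "' columns not in register with reference interval")
    mask <- coding_mask[coding_mask$chrom == b$chrom, , drop = FALSE]
    if (!nrow(mask) && !b$chrom %in% coding_mask$chrom && nrow(coding_mask))
      warning("block '", b$cne_id, "' on chromosome absent from coding mask: ", b$chrom)
    pieces <- subtract_interval(b$start, b$end, mask$start, mask$end)
    if (!nrow(pieces)) { reject(b$cne_id, "fully_coding"); next }
    multi <- nrow(pieces) > 1L
    for (i in seq_len(nrow(pieces))) {
      s <- pieces$start[i]; e <- pieces$end[i]
      id <- if (multi || s != b$start || e != b$end)
        sprintf("%s.%d", b$cne_id, i) else b$cne_id
      cols <- (s - b$start + 1L):(e - b$start)
      len <- e - s
      if (len <= cfg$min_cne_length) { reject(id, "min_length"); next }
      seqs <- vapply(b$seqs, function(x) paste(strsplit(x, "")[[1L]][cols], collapse = ""), "")
      piece <- cne_alignment(id, b$chrom, s, e, seqs)
      present <- vapply(piece$seqs[names(piece$seqs) %in% limbed],
                        function(x) grepl("[ACGT]", x), logical(1))
      if (sum(present) < cfg$min_limbed_species) { reject(id, "min_limbed_species"); next }
      retained[[id]] <- piece
    }
  }
  rejections <- if (length(rej)) do.call(rbind, rej) else
    data.frame(cne_id = character(), rule = character())
  list(retained = retained, rejections = rejections)
}

#' Link CNEs to genes within a TSS radius
#'
#' Every (CNE, gene) pair on the same chromosome whose minimum distance from
#' the CNE span to the gene's TSS point is at most `gene_link_distance`
#' (default 1 Mb) is a link; distance is 0 when the TSS lies inside the CNE.
#'
#' @param cnes Named list of `cne_alignment`, or an `interval_set` whose
#'   `name` column carries cne_ids.
#' @param tss_points An `interval_set` of one-bp TSS intervals named by gene.
#' @param cfg A [detection_config()].
#' @return Data.frame: cne_id, gene_id, distance, same_chrom (always TRUE).
#' @export
associate_genes <- function(cnes, tss_points, cfg = detection_config()) {
  if (inherits(cnes, "interval_set")) {
    iv <- cnes
  } else {
    iv <- interval_set(vapply(cnes, `[[`, "", "chrom"),
                       vapply(cnes, `[[`, 0L, "start"),
                       vapply(cnes, `[[`, 0L, "end"),
                       name = vapply(cnes, `[[`, "", "cne_id"))
  }
  rows <- list()
  for (i in seq_len(nrow(iv))) {
    same <- tss_points[tss_points$chrom == iv$chrom[i], , drop = FALSE]
    if (!nrow(same)) next
    p <- same$start   # TSS point position
    d <- pmax(0L, iv$start[i] - p, p - (iv$end[i] - 1L))
    keep <- d <= cfg$gene_link_distance
    if (any(keep)) rows[[length(rows) + 1L]] <- data.frame(
      cne_id = iv$name[i], gene_id = same$name[keep], distance = d[keep],
      same_chrom = TRUE, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cne_id = character(), gene_id = character(),
               distance = integer(), same_chrom = logical())
  out <- out[order(out$cne_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
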