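#' Construct an interval set
#'
#' Interval sets carry BED-style records: `chrom`, `start`, `end` (0-based
#' half-open), optional `name` and `score`. All genomic coordinates in this
#' package use the 0-based half-open convention; GFF input is shifted at the
#' boundary.
#'
#' @param chrom,start,end Vectors of equal length.
#' @param name,score Optional vectors.
#' @return A sorted data.frame of class `interval_set`.
#' @export
interval_set <- function(chrom = character(), start = integer(), end = integer(),
                         name = NULL, score = NULL) {
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), stringsAsFactors = FALSE)
  df$name <- if (is.null(name)) rep(NA_character_, nrow(df)) else as.character(name)
  df$score <- if (is.null(score)) rep(NA_real_, nrow(df)) else as.numeric(score)
  bad <- which(df$start >= df$end)
  if (length(bad)) stop("start >= end at record(s): ", paste(bad, collapse = ", "))
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("interval_set", "data.frame")
  df
}

#' Read genomic intervals from BED or GFF3
#'
#' BED3/4/5 is read as-is (already 0-based half-open). GFF3 is accepted for
#' gene/TSS extraction: gene records are reduced to one-bp TSS intervals
#' honoring strand (TSS = `start` for `+`, `end` for `-`, both converted to
#' the internal 0-based convention, i.e. start shifts by exactly 1).
#'
#' @param path BED or GFF3 file.
#' @param format `"bed"` or `"gff_tss"`.
#' @param scored For BED: if TRUE, require a numeric score column (BED5).
#' @return An `interval_set`; for `gff_tss`, one-bp intervals named by gene ID.
#' @export
read_intervals <- function(path, format = c("bed", "gff_tss"), scored = FALSE) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty interval file: ", path)
    return(interval_set())
  }
  if (format == "bed") {
    f <- strsplit(lines, "\t| +")
    ncol <- unique(lengths(f))
    if (length(ncol) != 1L) stop("ragged BED file: ", path)
    if (scored && ncol < 5L) stop("scored intervals require BED5: ", path)
    chrom <- vapply(f, `[`, "", 1L)
    start <- suppressWarnings(as.integer(vapply(f, `[`, "", 2L)))
    end <- suppressWarnings(as.integer(vapply(f, `[`, "", 3L)))
    bad <- which(is.na(start) | is.na(end) | start >= end)
    if (length(bad)) stop("invalid BED record (start >= end or non-numeric) at line ",
                          bad[1L], " of ", path)
    nm <- if (ncol >= 4L) vapply(f, `[`, "", 4L) else NULL
    sc <- if (ncol >= 5L) as.numeric(vapply(f, `[`, "", 5L)) else NULL
    return(interval_set(chrom, start, end, name = nm, score = sc))
  }
  # GFF3 gene records -> TSS points
  f <- strsplit(lines, "\t")
  if (any(lengths(f) < 9L)) stop("malformed GFF3 (needs 9 columns): ", path)
  m <- do.call(rbind, f)
  keep <- m[, 3] == "gene"
  m <- m[keep, , drop = FALSE]
  if (!nrow(m)) {
    warning("no gene records in ", path)
    return(interval_set())
  }
  start1 <- as.integer(m[, 4]); end1 <- as.integer(m[, 5]); strand <- m[, 7]
  if (any(!strand %in% c("+", "-")))
    stop("unknown strand for TSS extraction at gene record(s): ",
         paste(which(!strand %in% c("+", "-")), collapse = ", "))
  gid <- sub('.*(?:ID=|gene_id[= ]"?)([^;"]+).*', "\\1", m[, 9])
  # 1-based inclusive -> 0-based half-open: TSS position is start1-1 on '+',
  # end1-1 on '-'; represent the point as a one-bp interval.
  tss0 <- ifelse(strand == "+", start1 - 1L, end1 - 1L)
  interval_set(m[, 1], tss0, tss0 + 1L, name = gid)
}

#' Write an interval set as BED
#'
#' Emits BED3, BED4 or BED5 depending on which optional columns are present.
#' @param x An `interval_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  stopifnot(inherits(x, "interval_set"))
  cols <- c("chrom", "start", "end")
  if (any(!is.na(x$name)) || any(!is.na(x$score))) cols <- c(cols, "name")
  if (any(!is.na(x$score))) cols <- c(cols, "score")
  df <- as.data.frame(x)[, cols, drop = FALSE]
  if ("name" %in% cols) df$name[is.na(df$name)] <- "."
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Subtract mask intervals from a single interval on one chromosome.
# Returns a data.frame of surviving (start, end) pieces, possibly empty.
subtract_interval <- function(start, end, mask_starts, mask_ends) {
  if (!length(mask_starts)) return(data.frame(start = start, end = end))
  o <- order(mask_starts)
  ms <- mask_starts[o]; me <- mask_ends[o]
  pieces <- list(); cur <- start
  for (i in seq_along(ms)) {
    if (me[i] <= cur || ms[i] >= end) next
    if (ms[i] > cur) pieces[[length(pieces) + 1L]] <- c(cur, min(ms[i], end))
    cur <- max(cur, me[i])
    if (cur >= end) break
  }
  if (cur < end) pieces[[length(pieces) + 1L]] <- c(cur, end)
  if (!length(pieces)) return(data.frame(start = integer(), end = integer()))
  m <- do.call(rbind, pieces)
  data.frame(start = m[, 1], end = m[, 2])
}

# 1 bp overlap test between one interval and an interval_set, per set row.
overlaps_any <- function(chrom, start, end, set) {
  any(set$chrom == chrom & set$start < end & set$end > start)
}
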