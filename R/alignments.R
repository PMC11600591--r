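#' Construct a CNE alignment
#'
#' The unit of analysis: one conserved noncoding element's gapped per-species
#' sequences over a common column frame (alphabet `A,C,G,T,N,-`), its
#' reference coordinates (0-based half-open), and — once reconstruction has
#' run — per-internal-node ancestor sequences over the same frame.
#'
#' @param cne_id Element identifier.
#' @param chrom,start,end Reference interval.
#' @param seqs Named character vector of gapped species sequences (equal
#'   nchar); absent species are simply not listed.
#' @param anc Optional named character vector of internal-node sequences.
#' @return A list of class `cne_alignment`.
#' @export
cne_alignment <- function(cne_id, chrom, start, end, seqs, anc = NULL) {
  seqs <- toupper(unlist(seqs))
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named by species")
  w <- unique(nchar(seqs))
  if (length(w) != 1L)
    stop("ragged alignment in element '", cne_id, "': column counts ",
         paste(sort(w), collapse = ", "))
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad)) stop("invalid characters in element '", cne_id, "' for: ",
                     paste(names(seqs)[bad], collapse = ", "))
  ref_len <- as.integer(end) - as.integer(start)
  if (ref_len < 1L) stop("element '", cne_id, "' has non-positive reference length")
  x <- list(cne_id = as.character(cne_id), chrom = as.character(chrom),
            start = as.integer(start), end = as.integer(end),
            seqs = seqs, anc = if (is.null(anc)) character() else toupper(unlist(anc)))
  class(x) <- "cne_alignment"
  x
}

#' @export
print.cne_alignment <- function(x, ...) {
  cat(sprintf("<cne_alignment> %s %s:%d-%d  %d species x %d columns, %d ancestor nodes\n",
              x$cne_id, x$chrom, x$start, x$end, length(x$seqs),
              if (length(x$seqs)) nchar(x$seqs[[1]]) else 0L, length(x$anc)))
  invisible(x)
}

aln_ncol <- function(aln) if (length(aln$seqs)) nchar(aln$seqs[[1L]]) else 0L

# Character matrix: rows = named sequences (species and/or ancestors), cols = columns.
aln_matrix <- function(seqs) {
  if (!length(seqs)) return(matrix(character(), 0, 0))
  m <- do.call(rbind, strsplit(unname(seqs), ""))
  rownames(m) <- names(seqs)
  m
}

#' Read a directory of per-CNE multi-FASTA files
#'
#' Each element is one `<cne_id>.fa` whose records are species (and,
#' optionally, internal-node) sequences over a common gapped frame. Reference
#' coordinates come from a sidecar BED4 file (`chrom start end cne_id`).
#' Species names are cross-checked against the manifest; internal-node records
#' are recognised by the tree's node labels.
#'
#' @param dir Directory of `.fa` files.
#' @param coords_bed BED4 file mapping `cne_id` to reference coordinates.
#' @param species Validated species data.frame (the manifest).
#' @param node_labels Optional character vector of internal-node labels to
#'   accept as ancestor records.
#' @return Named list of `cne_alignment` objects, ordered by `cne_id`.
#' @export
read_alignment_set <- function(dir, coords_bed, species, node_labels = character()) {
  coords <- read_intervals(coords_bed, "bed")
  if (anyDuplicated(coords$name)) stop("duplicate cne_id in coordinates: ",
    paste(unique(coords$name[duplicated(coords$name)]), collapse = ", "))
  files <- sort(list.files(dir, pattern = "\\.fa$", full.names = TRUE))
  if (!length(files)) stop("no .fa files under ", dir)
  out <- lapply(files, function(f) {
    cid <- sub("\\.fa$", "", basename(f))
    ss <- Biostrings::readBStringSet(f)
    seqs <- stats::setNames(as.character(ss), names(ss))
    is_anc <- names(seqs) %in% node_labels
    unknown <- setdiff(names(seqs)[!is_anc], species$name)
    if (length(unknown)) stop("unknown species in ", basename(f), ": ",
                              paste(unknown, collapse = ", "))
    k <- match(cid, coords$name)
    if (is.na(k)) stop("no coordinates for element '", cid, "'")
    cne_alignment(cid, coords$chrom[k], coords$start[k], coords$end[k],
                  seqs[!is_anc], anc = if (any(is_anc)) seqs[is_anc] else NULL)
  })
  ids <- vapply(out, `[[`, "", "cne_id")
  if (anyDuplicated(ids)) stop("duplicate cne_id: ",
    paste(unique(ids[duplicated(ids)]), collapse = ", "))
  stats::setNames(out, ids)
}

#' Write a set of CNE alignments as per-CNE multi-FASTA plus a coordinates BED
#'
#' Inverse of [read_alignment_set()]. Ancestor records, when present, are
#' written after the species records under their node labels.
#'
#' @param alns List of `cne_alignment`.
#' @param dir Output directory (created if needed).
#' @param coords_bed Output BED4 path.
#' @param with_ancestors Write reconstructed/true ancestor records too.
#' @return `dir`, invisibly.
#' @export
write_alignment_set <- function(alns, dir, coords_bed, with_ancestors = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (a in alns) {
    seqs <- a$seqs
    if (with_ancestors && length(a$anc)) seqs <- c(seqs, a$anc)
    Biostrings::writeXStringSet(Biostrings::BStringSet(seqs),
                                file.path(dir, paste0(a$cne_id, ".fa")), width = 80L)
  }
  iv <- interval_set(vapply(alns, `[[`, "", "chrom"),
                     vapply(alns, `[[`, 0L, "start"),
                     vapply(alns, `[[`, 0L, "end"),
                     name = vapply(alns, `[[`, "", "cne_id"))
  write_bed(iv, coords_bed)
  invisible(dir)
}
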