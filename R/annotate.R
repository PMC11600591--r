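#' Enhancer activity of CNEs over scored signal tracks
#'
#' A CNE is active in a track when at least one track interval whose score
#' (-log10 signal p-value) strictly exceeds `threshold` overlaps the CNE's
#' mapped interval by >= 1 bp. CNEs without a mapped coordinate get an
#' all-inactive row flagged `unmapped`.
#'
#' @param cne_map Data.frame: cne_id, chrom, start, end — CNE coordinates on
#'   the signal assembly (mapping produced upstream; coordinate lifting itself
#'   is out of scope here).
#' @param signal_tracks Named list of scored `interval_set` (one per
#'   tissue/stage).
#' @param threshold Score cutoff, strict (default 2.0).
#' @return List of class `activity_matrix`: `active` (logical matrix cne x
#'   track), `unmapped` (character vector of cne_ids).
#' @export
enhancer_activity <- function(cne_map, signal_tracks, threshold = 2.0) {
  stopifnot(all(c("cne_id", "chrom", "start", "end") %in% names(cne_map)))
  tracks <- names(signal_tracks)
  act <- matrix(FALSE, nrow(cne_map), length(tracks),
                dimnames = list(cne_map$cne_id, tracks))
  unmapped <- cne_map$cne_id[is.na(cne_map$chrom) | is.na(cne_map$start)]
  for (t in tracks) {
    tr <- signal_tracks[[t]]
    if (!nrow(tr)) next
    if (all(is.na(tr$score))) stop("track '", t, "' has no scores")
    hot <- tr[!is.na(tr$score) & tr$score > threshold, , drop = FALSE]
    for (i in seq_len(nrow(cne_map))) {
      if (cne_map$cne_id[i] %in% unmapped) next
      act[i, t] <- overlaps_any(cne_map$chrom[i], cne_map$start[i],
                                cne_map$end[i], hot)
    }
  }
  structure(list(active = act, unmapped = unmapped), class = "activity_matrix")
}

#' Pleiotropy summary from an activity matrix
#'
#' A CNE is pleiotropic when active in at least `pleiotropy_min` tissues. The
#' cohort fraction is computed among CNEs active somewhere (elements with no
#' signal at all are excluded from the denominator).
#'
#' @param matrix An `activity_matrix` from [enhancer_activity()].
#' @param pleiotropy_min Minimum active tissues (default 2).
#' @return List: `per_cne` (data.frame cne_id, n_active_tissues, pleiotropic),
#'   `n_active_anywhere`, `n_pleiotropic`, `fraction_pleiotropic`.
#' @export
pleiotropy_summary <- function(matrix, pleiotropy_min = 2L) {
  stopifnot(inherits(matrix, "activity_matrix"))
  n_active <- rowSums(matrix$active)
  per <- data.frame(cne_id = rownames(matrix$active),
                    n_active_tissues = as.integer(n_active),
                    pleiotropic = n_active >= pleiotropy_min,
                    stringsAsFactors = FALSE)
  anywhere <- per$n_active_tissues > 0L
  list(per_cne = per,
       n_active_anywhere = sum(anywhere),
       n_pleiotropic = sum(per$pleiotropic),
       fraction_pleiotropic = if (any(anywhere))
         sum(per$pleiotropic) / sum(anywhere) else NA_real_)
}

#' Default outgroup ladder for dating CNE origins
#'
#' Maps each outgroup species to the clade ancestor shared with tetrapods,
#' ordered by increasing depth (rank 0 = tetrapod ancestor itself, used when
#' no outgroup carries the element).
#'
#' @return Data.frame: species, origin, depth_rank.
#' @export
default_origin_ladder <- function() {
  data.frame(
    species = c("lungfish", "coelacanth",
                "bichir", "spotted_gar", "bowfin", "zebrafish",
                "elephant_shark", "thorny_skate", "white_shark",
                "hagfish", "lamprey", "amphioxus"),
    origin = c("lungfish_tetrapod_ancestor", "sarcopterygian_ancestor",
               rep("osteichthyan_ancestor", 4),
               rep("gnathostome_ancestor", 3),
               rep("vertebrate_ancestor", 2), "chordate_ancestor"),
    depth_rank = c(1L, 2L, rep(3L, 4), rep(4L, 3), rep(5L, 2), 6L),
    stringsAsFactors = FALSE)
}

#' Assign the evolutionary origin of each CNE from outgroup presence
#'
#' The origin is the divergence node of the most distantly related outgroup
#' in which homologous sequence was detected (the MRCA of tetrapods and the
#' deepest hit-bearing outgroup); elements with no outgroup hit are assigned
#' to the tetrapod ancestor.
#'
#' @param presence Data.frame or matrix: rows = cne_id (rownames or a
#'   `cne_id` column), columns = outgroup species, cells = logical/0-1 hits.
#' @param ladder Data.frame as [default_origin_ladder()].
#' @return Data.frame: cne_id, origin, depth_rank, supporting_outgroups.
#' @export
assign_origin <- function(presence, ladder = default_origin_ladder()) {
  df <- as.data.frame(presence)
  if ("cne_id" %in% names(df)) {
    rownames(df) <- df$cne_id
    df$cne_id <- NULL
  }
  unknown <- setdiff(colnames(df), ladder$species)
  if (length(unknown)) stop("species not on ladder: ", paste(unknown, collapse = ", "))
  ranks <- ladder$depth_rank[match(colnames(df), ladder$species)]
  out <- lapply(rownames(df), function(id) {
    hits <- which(as.logical(unlist(df[id, ])))
    if (!length(hits)) {
      data.frame(cne_id = id, origin = "tetrapod_ancestor", depth_rank = 0L,
                 supporting_outgroups = "", stringsAsFactors = FALSE)
    } else {
      r <- max(ranks[hits])
      data.frame(cne_id = id,
                 origin = ladder$origin[match(r, ladder$depth_rank)],
                 depth_rank = r,
                 supporting_outgroups = paste(colnames(df)[hits], collapse = ","),
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Scan a protein alignment for convergent amino-acid sites
#'
#' Reports columns where (a) every limbed species shares one residue (no gaps),
#' (b) in each lineage of `lineage_pair`, every member carries a residue
#' different from that limbed consensus, and (c) at least `min_flank_conserved`
#' of the 10 flanking columns (5 each side, counted jointly) are fully
#' conserved across limbed species. Columns within 5 of an alignment edge are
#' skipped. `identical_derived` records whether both lineages are each
#' unanimous and share the same derived residue.
#'
#' @param protein_aln Named character vector: aligned protein sequences
#'   (species names; `-` for gaps), equal lengths.
#' @param species Validated species data.frame.
#' @param lineage_pair Two limbless lineage labels (default snake + caecilian).
#' @param flank Flank width each side (default 5).
#' @param min_flank_conserved Minimum conserved flanking columns (default 7).
#' @return Data.frame: column, limbed_consensus, one `derived_<lineage>`
#'   column per lineage ("/"-joined when not unanimous), flank_conserved,
#'   identical_derived.
#' @export
aa_convergence_scan <- function(protein_aln, species,
                                lineage_pair = c("snake", "caecilian"),
                                flank = 5L, min_flank_conserved = 7L) {
  if (length(unique(nchar(protein_aln))) != 1L) stop("ragged protein alignment")
  M <- aln_matrix(toupper(protein_aln))
  limbed <- intersect(rownames(M), species$name[species$limb_status == "limbed"])
  if (!length(limbed)) stop("no limbed species in the alignment")
  members <- lineage_members(species)
  miss <- setdiff(lineage_pair, names(members))
  if (length(miss)) stop("unknown lineage(s): ", paste(miss, collapse = ", "))
  lin_rows <- lapply(lineage_pair, function(l) intersect(rownames(M), members[[l]]))
  names(lin_rows) <- lineage_pair
  if (any(lengths(lin_rows) == 0L)) stop("lineage with no species in the alignment")
  L <- ncol(M)
  # a column is "conserved" when all limbed species share one non-gap residue
  lim <- M[limbed, , drop = FALSE]
  consensus <- lim[1L, ]
  conserved <- colSums(lim == matrix(consensus, nrow(lim), L, byrow = TRUE)) == nrow(lim) &
    consensus != "-" & consensus != "X"
  rows <- list()
  for (j in seq_len(L)) {
    if (j <= flank || j > L - flank) next
    if (!conserved[j]) next
    cons <- consensus[j]
    derived <- vapply(lineage_pair, function(l) {
      res <- M[lin_rows[[l]], j]
      if (any(res == cons) || any(res == "-") || any(res == "X")) return(NA_character_)
      paste(sort(unique(res)), collapse = "/")
    }, "")
    if (any(is.na(derived))) next
    fl <- c((j - flank):(j - 1L), (j + 1L):(j + flank))
    n_cons <- sum(conserved[fl])
    if (n_cons < min_flank_conserved) next
    unanimous <- !grepl("/", derived)
    row <- data.frame(column = j, limbed_consensus = cons,
                      flank_conserved = n_cons,
                      identical_derived = all(unanimous) &&
                        length(unique(derived)) == 1L,
                      stringsAsFactors = FALSE)
    for (l in lineage_pair) row[[paste0("derived_", l)]] <- derived[[l]]
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) {
    out <- data.frame(column = integer(), limbed_consensus = character(),
                      flank_conserved = integer(), identical_derived = logical())
    for (l in lineage_pair) out[[paste0("derived_", l)]] <- character()
    return(out)
  }
  do.call(rbind, rows)
}
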