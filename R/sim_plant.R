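#' Plant degeneration into simulated CNE alignments
#'
#' Rewrites chosen species' sequences so that downstream detection has exact
#' ground truth. Two modes:
#' \describe{
#'   \item{substitution_burst}{the affected interval is rewritten to an exact
#'     target identity against the true tetrapod-ancestor sequence: matching
#'     positions are copied from the ancestor, and `round((1-identity)*len)`
#'     positions are substituted to a different base. Sequence length is
#'     conserved.}
#'   \item{deletion}{the affected interval is replaced by gap columns (the
#'     column frame survives, as an aligner would show a loss).}
#'   \item{none}{alignments returned bit-identical.}
#' }
#'
#' @param cne_set Named list of `cne_alignment` with true ancestors (from
#'   [simulate_cne_set()]).
#' @param species Validated species data.frame.
#' @param truth_spec Data.frame with columns `cne_id`, `target` (a lineage
#'   label or a species name), `mode`, `start`, `end` (element columns,
#'   0-based half-open), `identity` (target fraction for bursts; ignored for
#'   deletions).
#' @param seed Integer seed (positions of burst substitutions).
#' @param min_span Minimum interval width (default: the short window, 20).
#' @return List with `cne_set` (modified) and `truth` (per-species expanded
#'   plant-truth table with re-measured post-plant identity).
#' @export
plant_degeneration <- function(cne_set, species, truth_spec, seed = 1L,
                               min_span = 20L) {
  stopifnot(all(c("cne_id", "target", "mode", "start", "end") %in% names(truth_spec)))
  if (!"identity" %in% names(truth_spec)) truth_spec$identity <- NA_real_
  members <- lineage_members(species)
  rows <- list()
  with_seed(derive_seed(seed, "plant_degeneration"), {
    for (r in seq_len(nrow(truth_spec))) {
      tr <- truth_spec[r, ]
      if (tr$mode == "none") next
      aln <- cne_set[[tr$cne_id]]
      if (is.null(aln)) stop("unknown cne_id in truth_spec: ", tr$cne_id)
      L <- aln_ncol(aln)
      s <- as.integer(tr$start); e <- as.integer(tr$end)
      if (s < 0L || e > L || s >= e) stop("plant interval outside element bounds: ", tr$cne_id)
      if (e - s < min_span)
        stop("plant interval shorter than the short window (", min_span, " bp): ", tr$cne_id)
      targets <- if (tr$target %in% names(members)) members[[tr$target]] else tr$target
      unknown <- setdiff(targets, species$name)
      if (length(unknown)) stop("unknown plant target(s): ", paste(unknown, collapse = ", "))
      anc <- strsplit(aln$anc[[tetrapod_ancestor_label]], "")[[1L]]
      for (sp in targets) {
        if (!sp %in% names(aln$seqs)) next
        cur <- strsplit(aln$seqs[[sp]], "")[[1L]]
        if (tr$mode == "deletion") {
          cur[(s + 1L):e] <- "-"
        } else if (tr$mode == "substitution_burst") {
          if (is.na(tr$identity) || tr$identity < 0 || tr$identity > 1)
            stop("substitution_burst needs identity in [0,1]: ", tr$cne_id)
          n <- e - s
          k <- round((1 - tr$identity) * n)
          win <- anc[(s + 1L):e]
          if (k > 0L) {
            pos <- sample.int(n, k)
            win[pos] <- DNA_STATES[(match(win[pos], DNA_STATES)) %% 4L + 1L]
          }
          cur[(s + 1L):e] <- win
        } else stop("unknown plant mode: ", tr$mode)
        aln$seqs[[sp]] <- paste(cur, collapse = "")
        post <- mean(strsplit(aln$seqs[[sp]], "")[[1L]][(s + 1L):e] == anc[(s + 1L):e])
        rows[[length(rows) + 1L]] <- data.frame(
          cne_id = tr$cne_id, lineage_or_species = tr$target, species = sp,
          mode = tr$mode, start = s, end = e,
          target_identity = tr$identity, post_identity = post,
          stringsAsFactors = FALSE)
      }
      cne_set[[tr$cne_id]] <- aln
    }
  })
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cne_id = character(), lineage_or_species = character(),
               species = character(), mode = character(), start = integer(),
               end = integer(), target_identity = numeric(),
               post_identity = numeric(), stringsAsFactors = FALSE)
  list(cne_set = cne_set, truth = truth)
}
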