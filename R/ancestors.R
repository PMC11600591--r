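# State encoding for parsimony: bitmasks over the five states A,C,G,T,-.
# N is "any base" (not gap); absent or fully-gapped species are uninformative
# (universal set), which reproduces exact per-element pruning without
# re-indexing tree nodes.
STATE_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L, `-` = 16L)
ANY_BASE <- 15L
ANY_STATE <- 31L

char_to_bits <- function(chars) {
  b <- STATE_BITS[chars]
  b[chars == "N"] <- ANY_BASE
  unname(b)
}

bits_to_char <- function(bits) {
  # lowest set bit, i.e. alphabetical-first in the order A,C,G,T,-
  names(STATE_BITS)[match(bitwAnd(bits, -bits), STATE_BITS)]
}

#' Reconstruct ancestral sequences by Fitch parsimony with a gap state
#'
#' Fills every internal node of the tree (tetrapod ancestor, lineage
#' ancestors, all others) with a gapped sequence over the element's column
#' frame. Gaps are a fifth character state; `N` is treated as "any base";
#' species absent from the element or consisting entirely of gaps enter as
#' uninformative leaves, which is equivalent to pruning them. Ties in the
#' top-down pass are broken deterministically: the parent's state is kept if
#' it lies in the child's candidate set, otherwise the alphabetically first
#' state in `A,C,G,T,-` is taken (the root uses the same first-state rule).
#'
#' @param aln A `cne_alignment`.
#' @param tree Rooted binary [ape::phylo] with `node.label` filled (see
#'   [label_ancestor_nodes()]); leaves are a superset of the element's species.
#' @param keep_existing If TRUE and `aln$anc` is already filled (e.g. true
#'   simulated ancestors, or an external override file), return unchanged.
#' @return The alignment with `$anc` filled for all internal nodes, plus an
#'   attribute `"parsimony_score"` (total column changes).
#' @export
reconstruct_ancestors <- function(aln, tree, keep_existing = FALSE) {
  if (keep_existing && length(aln$anc)) return(aln)
  if (!ape::is.binary(tree)) stop("reconstruction requires a binary tree")
  n_tip <- length(tree$tip.label)
  if (is.null(tree$node.label)) stop("tree needs node labels; see label_ancestor_nodes()")
  L <- aln_ncol(aln)
  present <- names(aln$seqs)[vapply(aln$seqs, function(s) grepl("[ACGT]", s), logical(1))]
  if (length(present) < 2L)
    stop("element '", aln$cne_id, "' unreconstructable: fewer than 2 species present")
  extra <- setdiff(names(aln$seqs), tree$tip.label)
  if (length(extra)) stop("species not in tree: ", paste(extra, collapse = ", "))

  sets <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) {
    sp <- tree$tip.label[i]
    sets[[i]] <- if (sp %in% present)
      char_to_bits(strsplit(aln$seqs[[sp]], "")[[1L]])
    else rep(ANY_STATE, L)
  }
  post <- ape::reorder.phylo(tree, "postorder")
  score <- 0L
  # bottom-up: binary Fitch per column, vectorised over columns; children are
  # folded into the parent as their edges appear (postorder guarantees a
  # child's subtree is finished before the parent's own edge is reached)
  for (k in seq_len(nrow(post$edge))) {
    p <- post$edge[k, 1]; ch <- post$edge[k, 2]
    if (is.null(sets[[p]])) {
      sets[[p]] <- sets[[ch]]
    } else {
      inter <- bitwAnd(sets[[p]], sets[[ch]])
      un <- bitwOr(sets[[p]], sets[[ch]])
      empty <- inter == 0L
      sets[[p]] <- ifelse(empty, un, inter)
      score <- score + sum(empty)
    }
  }
  # top-down: assign states, preferring the parent's state
  assigned <- vector("list", n_tip + tree$Nnode)
  root <- n_tip + 1L
  assigned[[root]] <- bitwAnd(sets[[root]], -sets[[root]])
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(pre$edge))) {
    p <- pre$edge[k, 1]; ch <- pre$edge[k, 2]
    if (ch <= n_tip) next
    keep <- bitwAnd(assigned[[p]], sets[[ch]])
    first <- bitwAnd(sets[[ch]], -sets[[ch]])
    assigned[[ch]] <- ifelse(keep != 0L, keep, first)
  }
  anc <- vapply(seq_len(tree$Nnode), function(j)
    paste(bits_to_char(assigned[[n_tip + j]]), collapse = ""), "")
  names(anc) <- tree$node.label
  aln$anc <- anc
  attr(aln, "parsimony_score") <- score
  aln
}

#' Reconstruct ancestors for a whole alignment set
#'
#' Elements with fewer than two present species are flagged unreconstructable,
#' logged, and excluded from the returned set.
#'
#' @param alns Named list of `cne_alignment`.
#' @param tree Labeled binary tree.
#' @param ancestor_override Optional directory of per-CNE multi-FASTA files
#'   whose record names are internal-node labels; elements found there skip
#'   parsimony (externally produced ancestors, e.g. from a probabilistic
#'   method, can be injected this way).
#' @return Named list of reconstructed alignments (possibly shorter than the
#'   input), with attribute `"excluded"` naming dropped elements.
#' @export
reconstruct_all <- function(alns, tree, ancestor_override = NULL) {
  out <- list(); excluded <- character()
  for (a in alns) {
    if (!is.null(ancestor_override)) {
      f <- file.path(ancestor_override, paste0(a$cne_id, ".fa"))
      if (file.exists(f)) {
        ss <- Biostrings::readBStringSet(f)
        a$anc <- stats::setNames(toupper(as.character(ss)), names(ss))
        out[[a$cne_id]] <- a
        next
      }
    }
    res <- tryCatch(reconstruct_ancestors(a, tree), error = function(e) e)
    if (inherits(res, "error")) {
      message("excluding ", a$cne_id, ": ", conditionMessage(res))
      excluded <- c(excluded, a$cne_id)
    } else out[[a$cne_id]] <- res
  }
  attr(out, "excluded") <- excluded
  out
}

#' Window identity between two aligned sequences
#'
#' The primitive all detection thresholds apply to. Counts columns where both
#' sequences carry the same unambiguous base; a gap or `N` in either sequence
#' makes the column comparable but non-matching. Counts, never ratios: the
#' published thresholds are absolute match counts (18/20, 14/20, 30/50).
#'
#' @param seq_a,seq_b Aligned sequences over the same column frame.
#' @param start_col First window column (1-based).
#' @param width Window width in columns.
#' @return List with `matches`, `comparable_columns` (= `width`) and
#'   `window_offset` (= `start_col`).
#' @export
window_identity <- function(seq_a, seq_b, start_col, width) {
  la <- nchar(seq_a); lb <- nchar(seq_b)
  if (la != lb) stop("sequences do not share a column frame")
  if (start_col < 1L || start_col + width - 1L > la) stop("window out of range")
  a <- substring(seq_a, start_col, start_col + width - 1L)
  b <- substring(seq_b, start_col, start_col + width - 1L)
  ca <- strsplit(toupper(a), "")[[1L]]; cb <- strsplit(toupper(b), "")[[1L]]
  m <- sum(ca == cb & ca %in% DNA_STATES)
  list(matches = as.integer(m), comparable_columns = as.integer(width),
       window_offset = as.integer(start_col))
}

# Full-length identity fraction of one species sequence against an ancestor,
# over the ancestor's non-gap columns (gap/N = mismatch).
element_identity <- function(sp_seq, anc_seq) {
  a <- strsplit(toupper(anc_seq), "")[[1L]]
  s <- strsplit(toupper(sp_seq), "")[[1L]]
  keep <- a %in% DNA_STATES
  if (!any(keep)) return(NA_real_)
  mean(s[keep] == a[keep] & s[keep] %in% DNA_STATES)
}
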