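# Age (Myr before present) of a node of an ultrametric tree in Myr units.
node_age_myr <- function(tree, node) {
  d <- ape::node.depth.edgelength(tree)   # root-to-node path lengths
  max(d[seq_along(tree$tip.label)]) - d[node]
}

#' Simulate neutral identity for elements and limbless species
#'
#' For each element and limbless species, evolves the compared ancestor
#' sequence (default: the species' lineage ancestor, the node the observed
#' identity profiles use) forward for the ancestor's age at the species'
#' substitution rate, with `n_replicates` GTR replicates per element, and
#' records each replicate's identity to the ancestor — the neutral-drift
#' expectation at the matched timescale.
#'
#' @param alns Named list of reconstructed `cne_alignment`.
#' @param species Validated species data.frame (needs `substitution_rate`).
#' @param tree Labeled ultrametric tree in Myr.
#' @param gtr A [gtr_params()].
#' @param n_replicates Replicates per element (default 10).
#' @param seed Integer seed.
#' @param node `"lineage"` (default) or `"tetrapod"`: which ancestor the
#'   simulation starts from.
#' @return Data.frame: cne_id, species, replicate, identity.
#' @export
neutral_identity_set <- function(alns, species, tree, gtr = gtr_params(),
                                 n_replicates = 10L, seed = 1L,
                                 node = c("lineage", "tetrapod")) {
  node <- match.arg(node)
  ll <- species[species$limb_status == "limbless", ]
  if (any(is.na(ll$substitution_rate)))
    stop("missing substitution rate for: ",
         paste(ll$name[is.na(ll$substitution_rate)], collapse = ", "))
  ages <- stats::setNames(vapply(unique(ll$lineage), function(lin) {
    lab <- if (node == "tetrapod") tetrapod_ancestor_label else lineage_ancestor_label(lin)
    node_age_myr(tree, node_index_of(tree, lab))
  }, numeric(1)), unique(ll$lineage))
  rows <- list()
  for (aln in alns) {
    for (j in seq_len(nrow(ll))) {
      lab <- if (node == "tetrapod") tetrapod_ancestor_label
             else lineage_ancestor_label(ll$lineage[j])
      anc <- aln$anc[[lab]]
      if (is.null(anc)) next
      sim <- simulate_neutral_descendants(
        anc, rate = ll$substitution_rate[j], time_myr = ages[[ll$lineage[j]]],
        gtr = gtr, n_replicates = n_replicates,
        seed = derive_seed(seed, paste0(aln$cne_id, ":", ll$name[j])))
      rows[[length(rows) + 1L]] <- data.frame(
        cne_id = aln$cne_id, species = ll$name[j],
        replicate = seq_len(n_replicates), identity = sim$identity,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Contrast observed identity with the neutral expectation
#'
#' Three-group comparison of full-element identity fractions: non-dCNEs,
#' convergent dCNEs, and neutrally simulated sequences at the matched
#' timescale. Delegates the pairwise Welch t-tests and histogram summary to
#' [compare_identity_groups()].
#'
#' @param profiles Data.frame from [identity_profiles()] (groups `non_dcne`,
#'   `convergent_dcne`).
#' @param neutral Data.frame from [neutral_identity_set()].
#' @return List: `means` (named group means), `tests`, `histograms`.
#' @export
neutral_contrast <- function(profiles, neutral) {
  groups <- list(
    non_dcne = profiles$identity[profiles$group == "non_dcne"],
    convergent_dcne = profiles$identity[profiles$group == "convergent_dcne"],
    neutral = neutral$identity)
  empty <- lengths(groups) == 0L
  if (any(empty)) stop("empty group(s): ", paste(names(groups)[empty], collapse = ", "))
  cmp <- compare_identity_groups(groups)
  list(means = vapply(groups, mean, numeric(1)), tests = cmp$tests,
       histograms = cmp$histograms)
}
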