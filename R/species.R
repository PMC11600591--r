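#' Validate a species table
#'
#' A species table is a data.frame with columns `name`, `limb_status`
#' (`"limbed"`/`"limbless"`), `lineage` (label, required iff limbless),
#' `time_since_limb_loss` (Myr, required iff limbless, > 0) and
#' `substitution_rate` (substitutions/site/Myr, optional, > 0 when present).
#'
#' @param species A data.frame as above.
#' @return The validated data.frame, invisibly.
#' @export
validate_species <- function(species) {
  need <- c("name", "limb_status", "lineage", "time_since_limb_loss", "substitution_rate")
  miss <- setdiff(need, names(species))
  if (length(miss)) stop("species table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(species$name)) stop("duplicate species names: ",
    paste(unique(species$name[duplicated(species$name)]), collapse = ", "))
  if (!all(species$limb_status %in% c("limbed", "limbless")))
    stop("limb_status must be 'limbed' or 'limbless'")
  ll <- species$limb_status == "limbless"
  if (any(ll & (is.na(species$lineage) | species$lineage == "")))
    stop("limbless species without lineage: ",
         paste(species$name[ll & (is.na(species$lineage) | species$lineage == "")], collapse = ", "))
  if (any(ll & (is.na(species$time_since_limb_loss) | species$time_since_limb_loss <= 0)))
    stop("limbless species need time_since_limb_loss > 0")
  if (any(!ll & !(is.na(species$lineage) | species$lineage == "")))
    stop("limbed species must not carry a lineage label: ",
         paste(species$name[!ll & !(is.na(species$lineage) | species$lineage == "")], collapse = ", "))
  if (any(!ll & !is.na(species$time_since_limb_loss)))
    stop("limbed species must not carry time_since_limb_loss")
  ok_rate <- is.na(species$substitution_rate) | species$substitution_rate > 0
  if (!all(ok_rate)) stop("substitution_rate must be > 0 when present")
  invisible(species)
}

#' Read a species manifest and its newick tree
#'
#' The manifest is a TSV with header columns `name`, `limb_status`, `lineage`,
#' `time_since_limb_loss`, `substitution_rate`; empty cells mean "not
#' applicable". The tree is rooted newick whose leaves must match the manifest
#' exactly. Branch lengths are in the declared unit (`"Myr"` for the demo
#' trees; `"subs"` for trees already scaled to expected substitutions).
#'
#' @param manifest_path Path to the TSV manifest.
#' @param tree_path Path to the newick tree.
#' @param unit Branch-length unit, one of `"Myr"`, `"subs"`.
#' @return A list with elements `species` (validated data.frame) and `tree`
#'   (an [ape::phylo] with attribute `"unit"`).
#' @export
read_species_manifest <- function(manifest_path, tree_path, unit = c("Myr", "subs")) {
  unit <- match.arg(unit)
  sp <- utils::read.delim(manifest_path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  sp$lineage <- as.character(sp$lineage)
  validate_species(sp)
  tree <- ape::read.tree(tree_path)
  if (is.null(tree)) stop("could not parse newick tree: ", tree_path)
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  extra_tree <- setdiff(tree$tip.label, sp$name)
  extra_manifest <- setdiff(sp$name, tree$tip.label)
  if (length(extra_tree) || length(extra_manifest))
    stop("leaf/manifest mismatch; only in tree: [",
         paste(extra_tree, collapse = ", "), "]; only in manifest: [",
         paste(extra_manifest, collapse = ", "), "]")
  attr(tree, "unit") <- unit
  list(species = sp, tree = tree)
}

#' Write a species manifest and newick tree
#'
#' Inverse of [read_species_manifest()]; `NA` cells are written empty.
#'
#' @param species Validated species data.frame.
#' @param tree An [ape::phylo].
#' @param manifest_path,tree_path Output paths.
#' @return `manifest_path`, invisibly.
#' @export
write_species_manifest <- function(species, tree, manifest_path, tree_path) {
  validate_species(species)
  utils::write.table(species, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  ape::write.tree(tree, tree_path)
  invisible(manifest_path)
}

#' Limbless lineages and their member species
#' @param species Validated species data.frame.
#' @return Named list mapping each lineage label to its member species names.
#' @export
lineage_members <- function(species) {
  ll <- species[species$limb_status == "limbless", ]
  split(ll$name, ll$lineage)
}

#' Per-lineage minimum degenerated-species counts
#'
#' Lineages named in `cfg$lineage_minima` use that value; all others (the
#' single-species limbless-lizard lineages in the demo design) default to 1.
#'
#' @param species Validated species data.frame.
#' @param cfg A [detection_config()].
#' @return Named integer vector over all limbless lineages present.
#' @export
lineage_minima_for <- function(species, cfg) {
  lins <- names(lineage_members(species))
  mins <- stats::setNames(rep(1L, length(lins)), lins)
  known <- intersect(names(cfg$lineage_minima), lins)
  mins[known] <- as.integer(cfg$lineage_minima[known])
  mins
}

# Internal-node label of the MRCA of all tetrapods (the root of the demo tree).
tetrapod_ancestor_label <- "tetrapod_ancestor"

lineage_ancestor_label <- function(lineage) paste0("anc_", lineage)

#' Label the tetrapod-ancestor and lineage-ancestor nodes of a tree
#'
#' Ensures every internal node has a unique label, names the root
#' `tetrapod_ancestor`, and names each limbless lineage's MRCA
#' (`anc_<lineage>`). For single-species lineages the ancestor is the parent
#' node of the leaf; if that node already carries a lineage label the leaf's
#' lineage is reported against the nearer labeled ancestor.
#'
#' @param tree An [ape::phylo].
#' @param species Validated species data.frame.
#' @return The tree with `node.label` filled.
#' @export
label_ancestor_nodes <- function(tree, species) {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  lab <- tree$node.label
  if (is.null(lab) || length(lab) != n_node) lab <- rep("", n_node)
  root <- n_tip + 1L
  lab[root - n_tip] <- tetrapod_ancestor_label
  for (lin in names(lineage_members(species))) {
    mem <- lineage_members(species)[[lin]]
    idx <- match(mem, tree$tip.label)
    node <- if (length(idx) >= 2L) ape::getMRCA(tree, idx) else
      tree$edge[tree$edge[, 2] == idx, 1]
    target <- lineage_ancestor_label(lin)
    cur <- strsplit(lab[node - n_tip], "|", fixed = TRUE)[[1L]]
    if (node == root || target %in% cur) next      # idempotent relabeling
    lab[node - n_tip] <- if (lab[node - n_tip] == "" ||
                             grepl("^node[0-9]+$", lab[node - n_tip])) target
                         else paste(lab[node - n_tip], target, sep = "|")
  }
  blank <- which(lab == "")
  lab[blank] <- paste0("node", blank)
  tree$node.label <- lab
  tree
}

# Resolve the node index (ape numbering: n_tip + i) carrying a label.
node_index_of <- function(tree, label) {
  hits <- which(vapply(strsplit(tree$node.label, "|", fixed = TRUE),
                       function(x) label %in% x, logical(1)))
  if (!length(hits)) stop("no internal node labeled '", label, "'")
  length(tree$tip.label) + hits[1L]
}

# Per-branch substitution rate (subs/site/Myr): mean over the rates of the
# leaves descending from the branch's child; tree-wide mean rate as fallback.
branch_rates <- function(tree, species) {
  rates <- species$substitution_rate[match(tree$tip.label, species$name)]
  fallback <- mean(rates, na.rm = TRUE)
  if (is.nan(fallback)) fallback <- 1e-3
  n_tip <- length(tree$tip.label)
  desc <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) desc[[i]] <- i
  post <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(post$edge))) {
    p <- post$edge[k, 1]; ch <- post$edge[k, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  vapply(seq_len(nrow(tree$edge)), function(k) {
    r <- rates[desc[[tree$edge[k, 2]]]]
    if (all(is.na(r))) fallback else mean(r, na.rm = TRUE)
  }, numeric(1))
}
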