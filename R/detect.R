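# Internal: per-element scan machinery shared by all limbless species.
#
# Windows are laid on the comparison ancestor's ungapped coordinates (the
# thresholds are in bp of the ancestral element; alignment-column windows
# would be diluted by gaps contributed by unrelated species) and mapped back
# to alignment columns. Match counts per window are cumulative-sum window
# sums over the ungapped positions.
element_scan_data <- function(aln, species, cfg, ref_label = tetrapod_ancestor_label) {
  ref <- aln$anc[[ref_label]]
  if (is.null(ref) || !nzchar(ref))
    stop("element '", aln$cne_id, "' lacks ancestor '", ref_label,
         "'; run reconstruct_ancestors() first")
  refc <- strsplit(ref, "")[[1L]]
  ug <- which(refc %in% DNA_STATES)        # ancestor ungapped columns
  sp_names <- names(aln$seqs)
  M <- aln_matrix(aln$seqs)
  limbed <- intersect(sp_names, species$name[species$limb_status == "limbed"])
  n_ug <- length(ug)
  match_m <- matrix(FALSE, length(sp_names), n_ug, dimnames = list(sp_names, NULL))
  absent_m <- matrix(TRUE, length(sp_names), n_ug, dimnames = list(sp_names, NULL))
  if (n_ug) {
    refu <- refc[ug]
    sub <- M[, ug, drop = FALSE]
    ref_rep <- matrix(refu, nrow(sub), n_ug, byrow = TRUE)
    match_m <- (sub == ref_rep) & matrix(sub %in% DNA_STATES, nrow(sub), n_ug)
    rownames(match_m) <- sp_names
    absent_m <- matrix(sub %in% c("-", "N"), length(sp_names), n_ug,
                       dimnames = list(sp_names, NULL))
  }
  list(ug = ug, match = match_m, absent = absent_m, limbed = limbed)
}

# Window sums of a logical vector: positions k..k+w-1 for all k (step handled
# by caller). Returns integer vector of length n-w+1 (empty if n < w).
win_sums <- function(x, w) {
  n <- length(x)
  if (n < w) return(integer(0))
  cs <- cumsum(as.integer(x))
  cs[w:n] - c(0L, cs)[1:(n - w + 1L)]
}

# Per-window count of limbed species meeting `thr` matches in width-w windows.
limbed_support <- function(scan, w, thr) {
  n_ug <- ncol(scan$match)
  if (n_ug < w) return(integer(0))
  counts <- integer(n_ug - w + 1L)
  for (sp in scan$limbed)
    counts <- counts + as.integer(win_sums(scan$match[sp, ], w) >= thr)
  counts
}

#' Scan one limbless species of one element for degeneration
#'
#' Slides both published windows over the comparison ancestor's ungapped
#' coordinates. Criterion (i): in a 20 bp window, at least
#' `min_limbed_species` limbed species keep >= 18/20 matches to the tetrapod
#' ancestor while the focal limbless species drops to <= 14/20. Criterion
#' (ii): in a 50 bp window, at least `min_limbed_species` limbed species keep
#' >= 30/50 while the focal sequence is absent (all gap/N). One firing window
#' suffices; every firing window is recorded as evidence.
#'
#' @param aln Reconstructed `cne_alignment`.
#' @param focal Name of a limbless species.
#' @param species Validated species data.frame.
#' @param cfg A [detection_config()].
#' @param scan Optional precomputed result of the internal per-element scan
#'   (reused across species by [scan_all()]).
#' @return List of class `degeneration_call`: `cne_id`, `species`,
#'   `degenerated` flag, `evidence` data.frame (criterion, window_offset in
#'   ancestor-ungapped coordinates (1-based), limbed_support, focal_matches).
#' @export
scan_species <- function(aln, focal, species, cfg = detection_config(), scan = NULL) {
  st <- species$limb_status[match(focal, species$name)]
  if (is.na(st) || st != "limbless") stop("focal species must be limbless: ", focal)
  ref_label <- if (cfg$comparison_node == "lineage")
    lineage_ancestor_label(species$lineage[match(focal, species$name)])
  else tetrapod_ancestor_label
  if (is.null(scan)) scan <- element_scan_data(aln, species, cfg, ref_label)
  ev <- list()
  if (focal %in% rownames(scan$match)) {
    step_idx <- function(n) if (n >= 1L) seq(1L, n, by = cfg$step) else integer(0)
    # criterion (i): short-window identity drop
    sup_s <- limbed_support(scan, cfg$window_short, cfg$limbed_conserved_min_short)
    if (length(sup_s)) {
      foc_s <- win_sums(scan$match[focal, ], cfg$window_short)
      k <- step_idx(length(sup_s))
      hit <- k[sup_s[k] >= cfg$min_limbed_species &
               foc_s[k] <= cfg$limbless_identity_max_short]
      if (length(hit)) ev[[length(ev) + 1L]] <- data.frame(
        criterion = "short_identity", window_offset = hit,
        limbed_support = sup_s[hit], focal_matches = foc_s[hit])
    }
    # criterion (ii): long-window absence
    sup_l <- limbed_support(scan, cfg$window_long, cfg$limbed_conserved_min_long)
    if (length(sup_l)) {
      foc_abs <- win_sums(scan$absent[focal, ], cfg$window_long)
      foc_l <- win_sums(scan$match[focal, ], cfg$window_long)
      k <- step_idx(length(sup_l))
      hit <- k[sup_l[k] >= cfg$min_limbed_species &
               foc_abs[k] >= ceiling(cfg$absent_fraction * cfg$window_long)]
      if (length(hit)) ev[[length(ev) + 1L]] <- data.frame(
        criterion = "long_absence", window_offset = hit,
        limbed_support = sup_l[hit], focal_matches = foc_l[hit])
    }
  } else {
    # species entirely absent from the element: counted as absent everywhere
    sup_l <- limbed_support(scan, cfg$window_long, cfg$limbed_conserved_min_long)
    if (length(sup_l)) {
      k <- if (length(sup_l) >= 1L) seq(1L, length(sup_l), by = cfg$step) else integer(0)
      hit <- k[sup_l[k] >= cfg$min_limbed_species]
      if (length(hit)) ev[[length(ev) + 1L]] <- data.frame(
        criterion = "long_absence", window_offset = hit,
        limbed_support = sup_l[hit], focal_matches = 0L)
    }
  }
  evidence <- if (length(ev)) do.call(rbind, ev) else
    data.frame(criterion = character(), window_offset = integer(),
               limbed_support = integer(), focal_matches = integer())
  structure(list(cne_id = aln$cne_id, species = focal,
                 degenerated = nrow(evidence) > 0L, evidence = evidence),
            class = "degeneration_call")
}

#' Scan every limbless species of every element
#'
#' @param alns Named list of reconstructed `cne_alignment`.
#' @param species Validated species data.frame.
#' @param cfg A [detection_config()].
#' @param keep_evidence Keep per-window evidence rows (set FALSE for large
#'   cohorts where only the flags matter).
#' @return List with `calls` (data.frame cne_id, species, degenerated,
#'   n_windows) and `evidence` (data.frame with per-window rows, or NULL).
#' @export
scan_all <- function(alns, species, cfg = detection_config(), keep_evidence = TRUE) {
  limbless <- species$name[species$limb_status == "limbless"]
  rows <- vector("list", length(alns)); evs <- list()
  same_ref <- cfg$comparison_node == "tetrapod"
  for (i in seq_along(alns)) {
    aln <- alns[[i]]
    scan <- if (same_ref) element_scan_data(aln, species, cfg) else NULL
    cl <- lapply(limbless, function(sp) scan_species(aln, sp, species, cfg, scan = scan))
    rows[[i]] <- data.frame(
      cne_id = aln$cne_id, species = limbless,
      degenerated = vapply(cl, `[[`, logical(1), "degenerated"),
      n_windows = vapply(cl, function(x) nrow(x$evidence), integer(1)),
      stringsAsFactors = FALSE)
    if (keep_evidence) {
      for (x in cl) if (nrow(x$evidence)) {
        e <- x$evidence; e$cne_id <- x$cne_id; e$species <- x$species
        evs[[length(evs) + 1L]] <- e
      }
    }
  }
  calls <- do.call(rbind, rows)
  rownames(calls) <- NULL
  list(calls = calls,
       evidence = if (keep_evidence && length(evs)) do.call(rbind, evs) else NULL)
}

#' Aggregate species calls into lineage-level degeneration calls
#'
#' A lineage is called degenerated in an element when at least its minimum
#' number of member species are degenerated (3 snakes, 2 caecilians, 1 for
#' single-species lineages — a guard against assembly-quality artifacts).
#' Species absent from an element count as not degenerated.
#'
#' @param calls Data.frame from [scan_all()]`$calls`.
#' @param species Validated species data.frame.
#' @param cfg A [detection_config()].
#' @return Data.frame: cne_id, lineage, n_species_degenerated, degenerated.
#' @export
call_lineages <- function(calls, species, cfg = detection_config()) {
  members <- lineage_members(species)
  unknown <- setdiff(unique(species$lineage[species$limb_status == "limbless"]),
                     names(members))
  if (length(unknown)) stop("unknown lineage(s): ", paste(unknown, collapse = ", "))
  mins <- lineage_minima_for(species, cfg)
  ids <- unique(calls$cne_id)
  out <- expand.grid(cne_id = ids, lineage = names(members),
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  deg <- calls[calls$degenerated, c("cne_id", "species")]
  sp_lin <- species$lineage[match(deg$species, species$name)]
  tab <- table(factor(deg$cne_id, levels = ids),
               factor(sp_lin, levels = names(members)))
  out$n_species_degenerated <- as.integer(tab[cbind(match(out$cne_id, ids),
                                                    match(out$lineage, names(members)))])
  out$degenerated <- out$n_species_degenerated >= mins[out$lineage]
  out[order(out$cne_id, out$lineage), , drop = FALSE]
}

#' Classify per-element convergence from lineage calls
#'
#' @param lineage_calls Data.frame from [call_lineages()].
#' @return List with `records` (cne_id, degenerated_lineages "+"-joined,
#'   n_lineages, klass in none/lineage_specific/convergent_k) and `summary`
#'   (counts per klass and per lineage combination, the UpSet-style table).
#' @export
classify_convergence <- function(lineage_calls) {
  ids <- unique(lineage_calls$cne_id)
  deg <- lineage_calls[lineage_calls$degenerated, ]
  combs <- vapply(ids, function(id) {
    l <- sort(deg$lineage[deg$cne_id == id])
    paste(l, collapse = "+")
  }, "")
  n_lin <- lengths(strsplit(combs, "+", fixed = TRUE))
  n_lin[combs == ""] <- 0L
  klass <- ifelse(n_lin == 0L, "none",
           ifelse(n_lin == 1L, "lineage_specific", paste0("convergent_", n_lin)))
  records <- data.frame(cne_id = ids, degenerated_lineages = combs,
                        n_lineages = n_lin, klass = klass, stringsAsFactors = FALSE)
  by_class <- as.data.frame(table(klass = records$klass), stringsAsFactors = FALSE)
  nonempty <- records$degenerated_lineages != ""
  by_comb <- as.data.frame(table(combination = records$degenerated_lineages[nonempty]),
                           stringsAsFactors = FALSE)
  names(by_class)[2] <- "n"; if (nrow(by_comb)) names(by_comb)[2] <- "n"
  list(records = records,
       summary = list(by_class = by_class,
                      by_combination = by_comb[order(-by_comb$n), , drop = FALSE]))
}

#' Per-species convergent-dCNE accumulation rates
#'
#' For each limbless species, the number of convergent elements (degenerated
#' in >= 2 lineages) in which the species is itself degenerated, divided by
#' its time since limb loss — dCNEs per Myr.
#'
#' @param records Data.frame from [classify_convergence()]`$records`.
#' @param calls Data.frame from [scan_all()]`$calls`.
#' @param species Validated species data.frame.
#' @return Data.frame: species, lineage, n_convergent_dcnes,
#'   time_since_limb_loss, rate_per_myr.
#' @export
convergence_rate <- function(records, calls, species) {
  conv_ids <- records$cne_id[records$n_lineages >= 2L]
  ll <- species[species$limb_status == "limbless", ]
  if (any(is.na(ll$time_since_limb_loss) | ll$time_since_limb_loss <= 0))
    stop("every limbless species needs time_since_limb_loss > 0")
  deg <- calls[calls$degenerated & calls$cne_id %in% conv_ids, ]
  n <- vapply(ll$name, function(sp) sum(deg$species == sp), integer(1))
  data.frame(species = ll$name, lineage = ll$lineage,
             n_convergent_dcnes = as.integer(n),
             time_since_limb_loss = ll$time_since_limb_loss,
             rate_per_myr = as.numeric(n) / ll$time_since_limb_loss,
             stringsAsFactors = FALSE)
}

#' Full-element identity of limbless species against their lineage ancestor
#'
#' Identity fraction (matches / comparable columns over the ancestor's
#' ungapped positions, gap/N = mismatch) per element and limbless species,
#' against the reconstructed ancestor of the species' own lineage. Elements
#' are grouped `convergent_dcne` / `non_dcne` for the neutral-drift contrast.
#'
#' @param alns Named list of reconstructed `cne_alignment`.
#' @param species Validated species data.frame.
#' @param records Data.frame from [classify_convergence()]`$records`.
#' @return Data.frame: cne_id, species, lineage, identity, group.
#' @export
identity_profiles <- function(alns, species, records) {
  ll <- species[species$limb_status == "limbless", ]
  conv <- records$cne_id[records$n_lineages >= 2L]
  none <- records$cne_id[records$n_lineages == 0L]
  rows <- list()
  for (aln in alns) {
    grp <- if (aln$cne_id %in% conv) "convergent_dcne"
           else if (aln$cne_id %in% none) "non_dcne" else NA_character_
    if (is.na(grp)) next
    for (j in seq_len(nrow(ll))) {
      lab <- lineage_ancestor_label(ll$lineage[j])
      anc <- aln$anc[[lab]]
      if (is.null(anc)) next
      sp_seq <- aln$seqs[[ll$name[j]]]
      if (is.null(sp_seq)) sp_seq <- strrep("-", aln_ncol(aln))
      rows[[length(rows) + 1L]] <- data.frame(
        cne_id = aln$cne_id, species = ll$name[j], lineage = ll$lineage[j],
        identity = element_identity(sp_seq, anc), group = grp,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cne_id = character(), species = character(), lineage = character(),
               identity = numeric(), group = character())
  out[!is.na(out$identity), , drop = FALSE]
}
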