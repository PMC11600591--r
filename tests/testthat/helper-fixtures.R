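# Shared fixtures and independent oracles for the test suite.

# A small hand-built species set: n_limbed limbed species plus two limbless
# lineages (pair = 2 species, solo = 1), enough to exercise lineage minima.
tiny_species <- function(n_limbed = 4L) {
  data.frame(
    name = c(sprintf("limbed_%02d", seq_len(n_limbed)),
             "pair_1", "pair_2", "solo_1"),
    limb_status = c(rep("limbed", n_limbed), "limbless", "limbless", "limbless"),
    lineage = c(rep(NA_character_, n_limbed), "pair", "pair", "solo"),
    time_since_limb_loss = c(rep(NA_real_, n_limbed), 100, 100, 40),
    substitution_rate = 1e-3,
    stringsAsFactors = FALSE)
}

tiny_tree <- function(species) {
  limbed <- species$name[species$limb_status == "limbed"]
  bal <- function(labels, age) {
    if (length(labels) == 1L) return(list(s = labels, a = 0))
    h <- ceiling(length(labels) / 2)
    a <- bal(labels[seq_len(h)], age * 0.6); b <- bal(labels[-seq_len(h)], age * 0.6)
    list(s = sprintf("(%s:%g,%s:%g)", a$s, age - a$a, b$s, age - b$a), a = age)
  }
  lim <- bal(limbed, 200)
  nwk <- sprintf("(((pair_1:80,pair_2:80):170,solo_1:250):100,%s:%g);",
                 lim$s, 350 - lim$a)
  tree <- ape::read.tree(text = nwk)
  label_ancestor_nodes(tree, species)
}

# Build an alignment where every species starts identical to a given ancestor
# string; the tetrapod-ancestor record is attached directly so detection runs
# on a known reference.
flat_alignment <- function(species, anc_seq, cne_id = "cneT", start = 1000L) {
  seqs <- stats::setNames(rep(anc_seq, nrow(species)), species$name)
  cne_alignment(cne_id, "chr1", start, start + nchar(anc_seq), seqs,
                anc = c(tetrapod_ancestor = anc_seq))
}

# Substitute `k` positions of `seq` within columns [from, to] (1-based),
# deterministically (the first k positions), to a different base.
mutate_positions <- function(seq, from, k) {
  ch <- strsplit(seq, "")[[1L]]
  rot <- c(A = "C", C = "G", G = "T", T = "A", `-` = "A", N = "A")
  idx <- seq(from, length.out = k)
  ch[idx] <- rot[ch[idx]]
  paste(ch, collapse = "")
}

gap_positions <- function(seq, from, k) {
  ch <- strsplit(seq, "")[[1L]]
  ch[seq(from, length.out = k)] <- "-"
  paste(ch, collapse = "")
}

# ---------------------------------------------------------------------------
# Independent brute-force detection oracle: explicit window enumeration with
# per-window index sets and a matrix product, no cumulative sums, no shared
# code with scan_species().
oracle_scan_element <- function(aln, species, cfg) {
  ref <- strsplit(aln$anc[["tetrapod_ancestor"]], "")[[1L]]
  ug <- which(ref %in% c("A", "C", "G", "T"))
  limbed <- intersect(names(aln$seqs), species$name[species$limb_status == "limbed"])
  limbless <- intersect(species$name[species$limb_status == "limbless"],
                        union(names(aln$seqs), species$name))
  chars <- lapply(aln$seqs, function(s) strsplit(s, "")[[1L]])
  is_match <- function(sp, cols) {
    x <- chars[[sp]][cols]
    sum(x == ref[cols] & x %in% c("A", "C", "G", "T"))
  }
  is_absent <- function(sp, cols) {
    if (!sp %in% names(chars)) return(TRUE)   # species missing from element
    all(chars[[sp]][cols] %in% c("-", "N"))
  }
  windows <- function(w) {
    if (length(ug) < w) return(list())
    lapply(seq_len(length(ug) - w + 1L), function(k) ug[k:(k + w - 1L)])
  }
  win_s <- windows(cfg$window_short)
  win_l <- windows(cfg$window_long)
  sup_s <- vapply(win_s, function(cols) sum(vapply(limbed, function(sp)
    is_match(sp, cols) >= cfg$limbed_conserved_min_short, logical(1))), integer(1))
  sup_l <- vapply(win_l, function(cols) sum(vapply(limbed, function(sp)
    is_match(sp, cols) >= cfg$limbed_conserved_min_long, logical(1))), integer(1))
  res <- list()
  for (foc in limbless) {
    hit <- FALSE
    if (foc %in% names(chars)) {
      for (k in seq_along(win_s)) {
        if (sup_s[k] >= cfg$min_limbed_species &&
            is_match(foc, win_s[[k]]) <= cfg$limbless_identity_max_short) {
          hit <- TRUE; break
        }
      }
    }
    if (!hit) {
      for (k in seq_along(win_l)) {
        if (sup_l[k] >= cfg$min_limbed_species && is_absent(foc, win_l[[k]])) {
          hit <- TRUE; break
        }
      }
    }
    res[[foc]] <- hit
  }
  unlist(res)
}

# Random alignment with an attached random ancestor, gaps and Ns sprinkled in.
random_instance <- function(species, n_col = sample(30:120, 1L)) {
  bases <- c("A", "C", "G", "T")
  anc <- sample(c(bases, "-"), n_col, replace = TRUE, prob = c(rep(0.23, 4), 0.08))
  mk <- function(p_mut, p_gap) {
    ch <- anc
    mut <- runif(n_col) < p_mut
    ch[mut] <- sample(c(bases, "-", "N"), sum(mut), replace = TRUE)
    g <- runif(n_col) < p_gap
    ch[g] <- "-"
    paste(ch, collapse = "")
  }
  limbed <- species$name[species$limb_status == "limbed"]
  limbless <- species$name[species$limb_status == "limbless"]
  seqs <- c(
    stats::setNames(vapply(limbed, function(x) mk(runif(1, 0, 0.12), 0.01), ""), limbed),
    stats::setNames(vapply(limbless, function(x) {
      if (runif(1) < 0.25) {
        # occasional long deletion to exercise criterion (ii)
        s <- mk(runif(1, 0, 0.1), 0)
        from <- sample(max(1L, n_col - 60L), 1L)
        gap_positions(s, from, min(60L, n_col - from + 1L))
      } else mk(runif(1, 0, 0.5), 0.02)
    }, ""), limbless))
  cne_alignment("rand", "chr1", 0L, n_col, seqs,
                anc = c(tetrapod_ancestor = paste(anc, collapse = "")))
}

# Exhaustive small-tree parsimony minimum: enumerate all internal labelings
# over the 5 states and count changes (oracle for Fitch).
exhaustive_parsimony <- function(tree, leaf_states) {
  states <- c("A", "C", "G", "T", "-")
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  grid <- do.call(expand.grid, c(rep(list(states), n_int),
                                 list(stringsAsFactors = FALSE)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    lab <- c(leaf_states[tree$tip.label], unlist(grid[r, ], use.names = FALSE))
    cost <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    best <- min(best, cost)
  }
  best
}
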