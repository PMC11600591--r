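#' General time-reversible substitution model parameters
#'
#' @param exchangeabilities Nonnegative reals for the six unordered pairs, in
#'   the order AC, AG, AT, CG, CT, GT.
#' @param base_frequencies Stationary frequencies of A, C, G, T; must sum to 1.
#' @return A list of class `gtr_params`. Defaults are Jukes-Cantor.
#' @export
gtr_params <- function(exchangeabilities = rep(1, 6),
                       base_frequencies = rep(0.25, 4)) {
  stopifnot(length(exchangeabilities) == 6L, length(base_frequencies) == 4L)
  if (any(exchangeabilities < 0) || all(exchangeabilities == 0))
    stop("exchangeabilities must be nonnegative with at least one > 0")
  if (abs(sum(base_frequencies) - 1) > 1e-9)
    stop("base_frequencies must sum to 1")
  if (any(base_frequencies <= 0)) stop("base_frequencies must be positive")
  structure(list(exchangeabilities = as.numeric(exchangeabilities),
                 base_frequencies = as.numeric(base_frequencies)),
            class = "gtr_params")
}

DNA_STATES <- c("A", "C", "G", "T")

#' GTR rate matrix, scaled to one expected substitution per site per unit time
#' @param g A [gtr_params()].
#' @return 4x4 rate matrix with rows/cols A,C,G,T.
#' @export
gtr_rate_matrix <- function(g) {
  stopifnot(inherits(g, "gtr_params"))
  ex <- g$exchangeabilities; pi_ <- g$base_frequencies
  R <- matrix(0, 4, 4, dimnames = list(DNA_STATES, DNA_STATES))
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in 1:6) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    R[i, j] <- ex[k] * pi_[j]
    R[j, i] <- ex[k] * pi_[i]
  }
  diag(R) <- -rowSums(R)
  mu <- -sum(pi_ * diag(R))          # expected substitutions per unit time
  R / mu
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Uses the symmetrised eigendecomposition available for any reversible Q.
#' @param g A [gtr_params()].
#' @param t Branch length in expected substitutions per site.
#' @return 4x4 row-stochastic matrix.
#' @export
gtr_prob_matrix <- function(g, t) {
  stopifnot(t >= 0)
  Q <- gtr_rate_matrix(g)
  pi_ <- g$base_frequencies
  d <- sqrt(pi_)
  B <- diag(d) %*% Q %*% diag(1 / d)          # symmetric
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  P <- diag(1 / d) %*% e$vectors %*% diag(exp(e$values * t)) %*% t(e$vectors) %*% diag(d)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(DNA_STATES, DNA_STATES)
  P
}

# Evolve integer-coded sequence (1..4) along one branch under P.
evolve_states <- function(states, P) {
  out <- integer(length(states))
  for (s in 1:4) {
    w <- which(states == s)
    if (length(w)) out[w] <- sample.int(4L, length(w), replace = TRUE, prob = P[s, ])
  }
  out
}

states_to_seq <- function(states) paste(DNA_STATES[states], collapse = "")
seq_to_states <- function(s) match(strsplit(s, "")[[1L]], DNA_STATES)

#' Simulate a set of CNE alignments on a tree, retaining true ancestors
#'
#' The root sequence is drawn from the stationary base frequencies; every
#' branch evolves by the matrix exponential of the (scaled) GTR rate matrix.
#' Branch lengths in Myr are converted to expected substitutions with the
#' per-branch rates from the species manifest, damped by `rate_scale` to
#' emulate the purifying selection that keeps CNEs conserved. Elements are
#' spaced along a synthetic reference chromosome; the default spacing exceeds
#' the 1 Mb gene-link radius so each element has its own gene neighborhood.
#'
#' @param tree Rooted [ape::phylo] with branch lengths in Myr and labeled
#'   internal nodes (see [label_ancestor_nodes()]).
#' @param species Validated species data.frame.
#' @param n_cnes Number of elements.
#' @param length_range Integer length range, within `[10, 10000]`. Lengths are
#'   drawn log-uniformly (real CNE lengths are strongly right-skewed).
#' @param gtr A [gtr_params()].
#' @param rate_scale Multiplier on the neutral substitution rate (default 0.03,
#'   i.e. CNEs evolve at 3% of the neutral rate).
#' @param seed Integer seed.
#' @param chrom Synthetic chromosome name.
#' @param spacing Gap between consecutive elements on the chromosome (bp).
#' @return Named list of `cne_alignment` with true internal-node sequences in
#'   `$anc`.
#' @export
simulate_cne_set <- function(tree, species, n_cnes, length_range = c(80L, 400L),
                             gtr = gtr_params(), rate_scale = 0.03, seed = 1L,
                             chrom = "chrS", spacing = 2100000L) {
  if (length_range[1] < 10L || length_range[2] > 10000L || length_range[1] > length_range[2])
    stop("length_range must lie within [10, 10000]")
  n_tip <- length(tree$tip.label)
  if (is.null(tree$node.label)) tree <- label_ancestor_nodes(tree, species)
  node_names <- c(tree$tip.label, tree$node.label)
  rates <- branch_rates(tree, species)
  bl_subs <- tree$edge.length * rates * rate_scale
  Pm <- lapply(bl_subs, function(d) gtr_prob_matrix(gtr, d))
  pre <- ape::reorder.phylo(tree, "cladewise")   # parent-before-child order
  edge_order <- match(paste(pre$edge[, 1], pre$edge[, 2]),
                      paste(tree$edge[, 1], tree$edge[, 2]))
  root <- n_tip + 1L

  with_seed(derive_seed(seed, "simulate_cne_set"), {
    lens <- round(exp(stats::runif(n_cnes, log(length_range[1]), log(length_range[2]))))
    starts <- 100000L + (seq_len(n_cnes) - 1L) * as.integer(spacing)
    alns <- vector("list", n_cnes)
    for (i in seq_len(n_cnes)) {
      L <- lens[i]
      node_states <- vector("list", n_tip + tree$Nnode)
      node_states[[root]] <- sample.int(4L, L, replace = TRUE, prob = gtr$base_frequencies)
      for (k in edge_order) {
        p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
        node_states[[ch]] <- evolve_states(node_states[[p]], Pm[[k]])
      }
      seqs <- vapply(seq_len(n_tip), function(j) states_to_seq(node_states[[j]]), "")
      names(seqs) <- tree$tip.label
      anc <- vapply(seq_len(tree$Nnode), function(j) states_to_seq(node_states[[n_tip + j]]), "")
      names(anc) <- tree$node.label
      alns[[i]] <- cne_alignment(sprintf("CNE%05d", i), chrom, starts[i],
                                 starts[i] + L, seqs, anc = anc)
    }
    stats::setNames(alns, vapply(alns, `[[`, "", "cne_id"))
  })
}

#' Simulate neutral descendants of an ancestor sequence
#'
#' For one limbless species, evolves the compared ancestor sequence forward
#' under GTR over branch length `d = substitution_rate x elapsed_time` (no
#' rate damping: this is the neutral-drift expectation), and reports each
#' replicate's identity to the ancestor.
#'
#' @param ancestor_seq Ungapped ancestor sequence (character scalar; gaps and
#'   N are dropped before simulation).
#' @param rate Substitution rate, subs/site/Myr.
#' @param time_myr Elapsed time in Myr from the ancestor node to the present.
#' @param gtr A [gtr_params()].
#' @param n_replicates Number of replicates (default 10).
#' @param seed Integer seed.
#' @return List with `replicates` (character vector) and `identity` (numeric
#'   vector of per-replicate identity fractions to the ancestor).
#' @export
simulate_neutral_descendants <- function(ancestor_seq, rate, time_myr,
                                         gtr = gtr_params(), n_replicates = 10L,
                                         seed = 1L) {
  if (is.na(rate) || is.null(rate)) stop("missing substitution rate")
  stopifnot(rate > 0, time_myr >= 0, n_replicates >= 1L)
  anc <- gsub("[-N]", "", toupper(ancestor_seq))
  if (!nchar(anc)) stop("ancestor sequence empty after removing gaps/N")
  states <- seq_to_states(anc)
  P <- gtr_prob_matrix(gtr, rate * time_myr)
  with_seed(derive_seed(seed, "simulate_neutral_descendants"), {
    reps <- vapply(seq_len(n_replicates), function(r) {
      states_to_seq(evolve_states(states, P))
    }, "")
    ident <- vapply(reps, function(s) {
      mean(strsplit(s, "")[[1L]] == strsplit(anc, "")[[1L]])
    }, numeric(1), USE.NAMES = FALSE)
    list(replicates = reps, identity = ident)
  })
}
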