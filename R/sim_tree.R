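#' Build the demonstration species set and ultrametric tree
#'
#' Emulates the study design: 31 limbed tetrapods plus 12 limbless species in
#' 4 lineages — 4 caecilians (limb loss ~192 Mya), 6 snakes (~170 Mya), and
#' two single-species limbless-lizard lineages (40 and 35 Mya). Caecilians
#' attach inside the amphibian clade and snakes/limbless lizards inside the
#' squamates, so each limbless lineage is an independent origin. Branch
#' lengths are Myr; the tree is ultrametric with the tetrapod crown at
#' `depth` Mya. Per-species substitution rates (subs/site/Myr) are drawn
#' log-normally around 1e-3.
#'
#' @param n_limbed Number of limbed species (>= `min_limbed`; default 31).
#' @param lineage_spec Named list: per limbless lineage, `list(n = count,
#'   loss = limb-loss time in Mya)`.
#' @param depth Root (tetrapod crown) age in Mya.
#' @param seed Integer seed (rates only; topology and node ages are fixed by
#'   the design).
#' @param min_limbed Lower bound on `n_limbed`.
#' @return List with `species` (validated data.frame) and `tree` (labeled
#'   [ape::phylo], unit `"Myr"`).
#' @export
build_demo_tree <- function(n_limbed = 31L,
                            lineage_spec = list(
                              caecilian = list(n = 4L, loss = 192),
                              snake     = list(n = 6L, loss = 170),
                              lizard_A  = list(n = 1L, loss = 40),
                              lizard_B  = list(n = 1L, loss = 35)),
                            depth = 352, seed = 1L, min_limbed = 29L) {
  if (n_limbed < min_limbed) stop("n_limbed must be >= ", min_limbed)
  counts <- vapply(lineage_spec, function(x) as.integer(x$n), integer(1))
  if (any(counts < 1L)) stop("every limbless lineage needs >= 1 species")
  losses <- vapply(lineage_spec, function(x) as.numeric(x$loss), numeric(1))
  if (any(losses <= 0)) stop("limb-loss times must be > 0 Mya")

  # allocate limbed species: amphibians, limbed squamates, other amniotes
  n_amph <- max(2L, round(n_limbed * 5 / 31))
  n_squa <- max(2L, round(n_limbed * 5 / 31))
  n_amni <- n_limbed - n_amph - n_squa
  if (n_amni < 1L) stop("n_limbed too small to populate all limbed clades")
  limbed <- sprintf("limbed_%02d", seq_len(n_limbed))
  amph_sp <- limbed[seq_len(n_amph)]
  squa_sp <- limbed[n_amph + seq_len(n_squa)]
  amni_sp <- limbed[n_amph + n_squa + seq_len(n_amni)]

  lin_names <- names(lineage_spec)
  lin_sp <- lapply(lin_names, function(l)
    if (counts[[l]] == 1L) paste0(l, "_1") else sprintf("%s_%d", l, seq_len(counts[[l]])))
  names(lin_sp) <- lin_names

  # balanced ultrametric clade: newick fragment with crown age `age`
  clade <- function(labels, age) {
    if (length(labels) == 1L) return(list(str = labels, age = 0))
    h <- ceiling(length(labels) / 2)
    a <- clade(labels[seq_len(h)], age * 0.66)
    b <- clade(labels[-seq_len(h)], age * 0.66)
    list(str = sprintf("(%s:%.6g,%s:%.6g)", a$str, age - a$age, b$str, age - b$age),
         age = age)
  }
  pair <- function(a, b, age)
    list(str = sprintf("(%s:%.6g,%s:%.6g)", a$str, age - a$age, b$str, age - b$age),
         age = age)

  cae <- if ("caecilian" %in% lin_names) clade(lin_sp$caecilian, 80) else NULL
  amph <- clade(amph_sp, 250)
  amph_side <- if (is.null(cae)) amph else pair(cae, amph, 328)

  snk <- if ("snake" %in% lin_names) clade(lin_sp$snake, 65) else NULL
  liz <- lapply(setdiff(lin_names, c("caecilian", "snake")), function(l) clade(lin_sp[[l]], 50))
  sq <- clade(squa_sp, 150)
  if (!is.null(snk)) sq <- pair(snk, sq, 180)
  ages <- seq(190, 200, length.out = max(1L, length(liz)))
  for (i in seq_along(liz)) sq <- pair(liz[[i]], sq, ages[i])
  amni <- pair(sq, clade(amni_sp, 280), 320)
  nwk <- sprintf("(%s:%.6g,%s:%.6g);", amph_side$str, depth - amph_side$age,
                 amni$str, depth - amni$age)
  tree <- ape::read.tree(text = nwk)

  all_names <- c(limbed, unlist(lin_sp))
  ll <- all_names %in% unlist(lin_sp)
  lin_of <- rep(NA_character_, length(all_names))
  loss_of <- rep(NA_real_, length(all_names))
  for (l in lin_names) {
    idx <- all_names %in% lin_sp[[l]]
    lin_of[idx] <- l
    loss_of[idx] <- losses[[l]]
  }
  rates <- with_seed(derive_seed(seed, "build_demo_tree"),
                     stats::rlnorm(length(all_names), log(1e-3), 0.15))
  species <- data.frame(name = all_names,
                        limb_status = ifelse(ll, "limbless", "limbed"),
                        lineage = lin_of,
                        time_since_limb_loss = loss_of,
                        substitution_rate = round(rates, 6),
                        stringsAsFactors = FALSE)
  validate_species(species)
  tree <- label_ancestor_nodes(tree, species)
  attr(tree, "unit") <- "Myr"
  list(species = species, tree = tree)
}
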