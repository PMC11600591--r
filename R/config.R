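#' Detection configuration
#'
#' Bundles every threshold used by the CNE retention filters and the
#' degeneration detector. Defaults are the published criteria: a 20 bp window
#' (1 bp step) must keep >= 18/20 matches to the reconstructed tetrapod
#' ancestor in at least 29 limbed species while a limbless species drops to
#' <= 14/20 (criterion i), or a 50 bp window keeps >= 30/50 matches in >= 29
#' limbed species while the limbless sequence is absent (criterion ii).
#'
#' @param window_short Short window width in ancestor bp (default 20).
#' @param step Window step in bp (default 1).
#' @param limbed_conserved_min_short Minimum matches for a limbed species to
#'   count as conserved in the short window (default 18).
#' @param limbless_identity_max_short Maximum matches for a limbless species to
#'   count as degenerated in the short window (default 14).
#' @param window_long Long window width in ancestor bp (default 50).
#' @param limbed_conserved_min_long Minimum matches for a limbed species in the
#'   long window (default 30).
#' @param min_limbed_species Minimum number of limbed species that must meet
#'   their conservation threshold in a window (default 29).
#' @param lineage_minima Named integer vector: minimum number of degenerated
#'   member species for a lineage-level call. Defaults snake = 3, caecilian = 2;
#'   lineages not named here default to 1 (single-species lineages).
#' @param min_cne_length Minimum element length in bp, strict: retained length
#'   must exceed this (default 30).
#' @param gene_link_distance Maximum CNE-to-TSS distance in bp for a gene link
#'   (default 1e6).
#' @param absent_fraction Fraction of focal window positions that must be gap/N
#'   for criterion (ii) "absent" (default 1.0 = fully absent).
#' @param comparison_node Ancestor node the limbless identity is measured
#'   against: `"tetrapod"` (default) or `"lineage"`.
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(window_short = 20L, step = 1L,
                             limbed_conserved_min_short = 18L,
                             limbless_identity_max_short = 14L,
                             window_long = 50L,
                             limbed_conserved_min_long = 30L,
                             min_limbed_species = 29L,
                             lineage_minima = c(snake = 3L, caecilian = 2L),
                             min_cne_length = 30L,
                             gene_link_distance = 1000000L,
                             absent_fraction = 1.0,
                             comparison_node = c("tetrapod", "lineage")) {
  comparison_node <- match.arg(comparison_node)
  cfg <- list(
    window_short = as.integer(window_short), step = as.integer(step),
    limbed_conserved_min_short = as.integer(limbed_conserved_min_short),
    limbless_identity_max_short = as.integer(limbless_identity_max_short),
    window_long = as.integer(window_long),
    limbed_conserved_min_long = as.integer(limbed_conserved_min_long),
    min_limbed_species = as.integer(min_limbed_species),
    lineage_minima = lineage_minima,
    min_cne_length = as.integer(min_cne_length),
    gene_link_distance = as.integer(gene_link_distance),
    absent_fraction = absent_fraction,
    comparison_node = comparison_node)
  validate_detection_config(cfg)
  class(cfg) <- "detection_config"
  cfg
}

validate_detection_config <- function(cfg) {
  with(cfg, {
    if (step < 1L) stop("step must be >= 1")
    if (limbed_conserved_min_short <= 0L || limbed_conserved_min_short > window_short)
      stop("limbed_conserved_min_short must be in (0, window_short]")
    if (limbless_identity_max_short <= 0L || limbless_identity_max_short > window_short)
      stop("limbless_identity_max_short must be in (0, window_short]")
    if (limbed_conserved_min_long <= 0L || limbed_conserved_min_long > window_long)
      stop("limbed_conserved_min_long must be in (0, window_long]")
    if (min_limbed_species < 1L || min_cne_length < 1L || gene_link_distance < 1L)
      stop("counts must be positive integers")
    if (absent_fraction <= 0 || absent_fraction > 1) stop("absent_fraction must be in (0, 1]")
    if (any(lineage_minima < 1L)) stop("lineage minima must be >= 1")
  })
  invisible(cfg)
}

#' Read or write a detection configuration as YAML
#'
#' `read_config` loads a YAML key-value file and overlays it on the defaults;
#' unknown keys are an error. `write_config` serialises a config so that
#' `read_config(write_config(cfg))` round-trips.
#'
#' @param path File path.
#' @param cfg A `detection_config`.
#' @return `read_config`: a `detection_config`; `write_config`: `path`, invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  base <- detection_config()
  known <- setdiff(names(unclass(base)), NULL)
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(vals$lineage_minima)) vals$lineage_minima <- unlist(vals$lineage_minima)
  args <- utils::modifyList(unclass(base), vals)
  do.call(detection_config, args)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "detection_config"))
  out <- unclass(cfg)
  out$lineage_minima <- as.list(out$lineage_minima)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Hash a configuration for run logging
#' @param cfg A `detection_config`.
#' @return Character scalar: a short deterministic digest of the config values.
#' @export
config_hash <- function(cfg) {
  s <- paste(deparse(unclass(cfg)), collapse = "")
  h <- 0; m <- 2147483647
  for (k in utf8ToInt(s)) h <- (h * 131 + k) %% m
  sprintf("%08x", as.integer(h))
}

#' Log a run header (version, config hash, seed)
#'
#' Every pipeline driver calls this once so stochastic stages are replayable.
#' @param stage Character stage name.
#' @param cfg A `detection_config` or NULL.
#' @param seed Integer seed or NULL.
#' @export
log_run <- function(stage, cfg = NULL, seed = NULL) {
  ver <- as.character(utils::packageVersion("cnedegen"))
  msg <- sprintf("[cnedegen %s] stage=%s%s%s", ver, stage,
                 if (!is.null(cfg)) paste0(" config=", config_hash(cfg)) else "",
                 if (!is.null(seed)) paste0(" seed=", seed) else "")
  message(msg)
  invisible(msg)
}
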