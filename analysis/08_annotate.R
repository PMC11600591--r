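#!/usr/bin/env Rscript
# Stage 8 — functional annotation of convergent dCNEs.
# Enhancer activity per tissue track (score -log10 p > 2, >= 1 bp overlap),
# pleiotropy (active in >= 2 tissues, among elements active anywhere), and
# evolutionary origin from the outgroup presence/absence matrix.
source("analysis/00_setup.R")

inp <- load_inputs()
log_run("annotate", inp$cfg, seed)
records <- utils::read.delim(paths$convergence)
conv_ids <- records$cne_id[records$n_lineages >= 2L]
cnes_iv <- read_intervals(paths$anc_bed)

track_dir <- file.path(paths$fixtures, "tracks")
tracks <- stats::setNames(
  lapply(list.files(track_dir, full.names = TRUE), read_intervals, scored = TRUE),
  sub("\\.bed$", "", list.files(track_dir)))
cne_map <- data.frame(cne_id = cnes_iv$name, chrom = cnes_iv$chrom,
                      start = cnes_iv$start, end = cnes_iv$end,
                      stringsAsFactors = FALSE)
act <- enhancer_activity(cne_map, tracks)
write_tsv(data.frame(cne_id = rownames(act$active), act$active + 0L,
                     check.names = FALSE), paths$activity)

conv_act <- structure(list(active = act$active[rownames(act$active) %in% conv_ids, ,
                                               drop = FALSE],
                           unmapped = act$unmapped), class = "activity_matrix")
pleio <- pleiotropy_summary(conv_act)
write_tsv(pleio$per_cne, paths$pleiotropy)

pres <- utils::read.delim(file.path(paths$fixtures, "outgroup_presence.tsv"),
                          check.names = FALSE)
ladder <- utils::read.delim(file.path(paths$fixtures, "origin_ladder.tsv"))
origins <- assign_origin(pres[pres$cne_id %in% conv_ids, , drop = FALSE], ladder)
write_tsv(origins, paths$origins)

message(sprintf("pleiotropic: %d/%d active convergent elements (%.0f%%); origin mode: %s",
                pleio$n_pleiotropic, pleio$n_active_anywhere,
                100 * pleio$fraction_pleiotropic,
                names(sort(table(origins$origin), decreasing = TRUE))[1]))
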