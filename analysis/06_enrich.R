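#!/usr/bin/env Rscript
# Stage 6 — enrichment tests.
# Fisher's exact test of convergent dCNEs against limb-related genes per
# lineage combination (background: all retained CNEs), and element-level
# region-set enrichment of convergent dCNEs over the enhancer tracks, both
# BH-adjusted.
source("analysis/00_setup.R")

inp <- load_inputs()
log_run("enrich", inp$cfg, seed)
records <- utils::read.delim(paths$convergence)
records$degenerated_lineages[is.na(records$degenerated_lineages)] <- ""
links <- utils::read.delim(paths$links)
limb_genes <- readLines(file.path(paths$fixtures, "limb_genes.txt"))

limb_test <- suppressWarnings(dcne_limb_gene_test(records, links, limb_genes))
write_tsv(limb_test, paths$limb_test)

cnes_iv <- read_intervals(paths$anc_bed)
conv_ids <- records$cne_id[records$n_lineages >= 2L]
if (length(conv_ids) >= 2L) {
  region <- region_set_enrichment(cnes_iv[cnes_iv$name %in% conv_ids, ],
                                  cnes_iv, file.path(paths$fixtures, "tracks"))
  write_tsv(region, paths$region)
  message(sprintf("top region set: %s (q = %.3g); min limb-gene q = %.3g",
                  region$label[1], region$q_value[1], min(limb_test$q_value)))
} else {
  message("fewer than 2 convergent elements; region enrichment skipped")
}
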