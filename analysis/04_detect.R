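#!/usr/bin/env Rscript
# Stage 4 — dCNE detection, lineage calls, convergence, rates.
# Slides the published 20 bp / 50 bp windows over each element, calls species
# then lineages (>= 3 snakes, >= 2 caecilians, 1 for single-species lineages),
# classifies convergence by the number of degenerated lineages, and divides
# per-species convergent counts by time since limb loss.
source("analysis/00_setup.R")

inp <- load_inputs()
log_run("detect", inp$cfg, seed)
cnes <- read_alignment_set(paths$anc_dir, paths$anc_bed, inp$species,
                           node_labels = inp$tree$node.label)
scans <- scan_all(cnes, inp$species, inp$cfg)
write_tsv(scans$calls, paths$calls)
if (!is.null(scans$evidence)) write_tsv(scans$evidence, paths$evidence)

lcalls <- call_lineages(scans$calls, inp$species, inp$cfg)
write_tsv(lcalls, paths$lineage_calls)
conv <- classify_convergence(lcalls)
write_tsv(conv$records, paths$convergence)
write_tsv(conv$summary$by_combination, paths$combinations)
rates <- convergence_rate(conv$records, scans$calls, inp$species)
write_tsv(rates, paths$rates)

message(sprintf("dCNEs: %d (lineage-specific %d, convergent %d); rate range %.2f-%.2f /Myr",
                sum(conv$records$n_lineages >= 1),
                sum(conv$records$klass == "lineage_specific"),
                sum(conv$records$n_lineages >= 2),
                min(rates$rate_per_myr), max(rates$rate_per_myr)))
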