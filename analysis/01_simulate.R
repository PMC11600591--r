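#!/usr/bin/env Rscript
# Stage 1 — synthetic study inputs.
# Builds the 43-species demo tree (31 limbed; 4 caecilians, 6 snakes and two
# single-species limbless-lizard lineages), simulates conserved elements under
# damped GTR with true ancestors retained, plants degeneration with known
# ground truth, and emits every downstream fixture (genes, enhancer tracks,
# ortholog tables, outgroup presence).
source("analysis/00_setup.R")

cfg <- detection_config()
log_run("simulate", cfg, seed)
write_config(cfg, paths$config)

demo <- build_demo_tree(seed = seed)
write_species_manifest(demo$species, demo$tree, paths$manifest, paths$tree)

cnes <- simulate_cne_set(demo$tree, demo$species, n_cnes = n_cnes, seed = seed)
truth_spec <- make_demo_truth(cnes, demo$species, seed = seed)
planted <- plant_degeneration(cnes, demo$species, truth_spec, seed = seed)
write_alignment_set(planted$cne_set, paths$aln_dir, paths$aln_bed)
write_tsv(planted$truth, paths$truth)

fx <- generate_feature_fixtures(planted$cne_set, planted$truth, seed = seed)
write_fixture_bundle(fx, paths$fixtures)

# synthetic coding mask clipping the first two elements (exercises the
# subtraction/split path of the catalog stage)
b1 <- planted$cne_set[[1]]; b2 <- planted$cne_set[[2]]
write_bed(interval_set(b1$chrom, c(b1$start + 10L, b2$start),
                       c(b1$start + 40L, b2$end)), paths$coding_mask)

message(sprintf("simulated %d elements (%d planted rows) for %d species",
                length(planted$cne_set), nrow(planted$truth),
                nrow(demo$species)))
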