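#!/usr/bin/env Rscript
# Stage 3 — ancestral reconstruction.
# Fills every internal node (tetrapod ancestor, lineage ancestors) of each
# retained element by Fitch parsimony with gap as a fifth state; elements with
# fewer than two present species are logged and dropped.
source("analysis/00_setup.R")

inp <- load_inputs()
log_run("ancestors", inp$cfg, seed)
cnes <- read_alignment_set(paths$retained_dir, paths$retained_bed, inp$species,
                           node_labels = inp$tree$node.label)
recon <- reconstruct_all(cnes, inp$tree)
write_alignment_set(recon, paths$anc_dir, paths$anc_bed, with_ancestors = TRUE)

excl <- attr(recon, "excluded")
message(sprintf("reconstructed %d elements (%d excluded: %s)",
                length(recon), length(excl),
                if (length(excl)) paste(excl, collapse = ",") else "none"))
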