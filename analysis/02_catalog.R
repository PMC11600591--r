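#!/usr/bin/env Rscript
# Stage 2 — CNE retention filters and gene links.
# Subtracts the coding mask from the candidate blocks, keeps pieces longer
# than 30 bp present in >= 29 limbed species, and links retained elements to
# genes with a TSS within 1 Mb.
source("analysis/00_setup.R")

inp <- load_inputs()
log_run("catalog", inp$cfg, seed)
blocks <- read_alignment_set(paths$aln_dir, paths$aln_bed, inp$species,
                             node_labels = inp$tree$node.label)
blocks <- lapply(blocks, function(a)
  cne_alignment(a$cne_id, a$chrom, a$start, a$end, a$seqs))
mask <- read_intervals(paths$coding_mask)
flt <- filter_cnes(blocks, mask, inp$species, inp$cfg)
write_alignment_set(flt$retained, paths$retained_dir, paths$retained_bed)
write_tsv(flt$rejections, paths$rejections)

tss <- read_intervals(file.path(paths$fixtures, "genes.gff3"), "gff_tss")
links <- associate_genes(flt$retained, tss, inp$cfg)
write_tsv(links, paths$links)

message(sprintf("retained %d/%d blocks (%d rejected); %d CNE-gene links",
                length(flt$retained), length(blocks), nrow(flt$rejections),
                nrow(links)))
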