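# Shared settings for the analysis drivers. Each numbered script sources this
# file, then reads its inputs from `out_dir` (written by the earlier stages)
# and writes its own tables there. Run them in order from the repo root:
#   Rscript analysis/01_simulate.R && Rscript analysis/02_catalog.R && ...
suppressPackageStartupMessages(library(cnedegen))

seed <- as.integer(Sys.getenv("CNEDEGEN_SEED", "42"))
out_dir <- Sys.getenv("CNEDEGEN_OUT", "results/demo")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

n_cnes <- 120L

paths <- list(
  config = file.path(out_dir, "config.yaml"),
  manifest = file.path(out_dir, "species.tsv"),
  tree = file.path(out_dir, "species.nwk"),
  aln_dir = file.path(out_dir, "alignments"),
  aln_bed = file.path(out_dir, "alignments.bed"),
  truth = file.path(out_dir, "plant_truth.tsv"),
  fixtures = file.path(out_dir, "fixtures"),
  coding_mask = file.path(out_dir, "coding_mask.bed"),
  retained_dir = file.path(out_dir, "cnes"),
  retained_bed = file.path(out_dir, "cnes.bed"),
  rejections = file.path(out_dir, "cne_rejections.tsv"),
  links = file.path(out_dir, "gene_links.tsv"),
  anc_dir = file.path(out_dir, "cnes_with_ancestors"),
  anc_bed = file.path(out_dir, "cnes_with_ancestors.bed"),
  calls = file.path(out_dir, "species_calls.tsv"),
  evidence = file.path(out_dir, "window_evidence.tsv"),
  lineage_calls = file.path(out_dir, "lineage_calls.tsv"),
  convergence = file.path(out_dir, "convergence.tsv"),
  combinations = file.path(out_dir, "combination_counts.tsv"),
  rates = file.path(out_dir, "rates.tsv"),
  profiles = file.path(out_dir, "identity_profiles.tsv"),
  neutral = file.path(out_dir, "neutral_identity.tsv"),
  contrast = file.path(out_dir, "neutral_contrast.json"),
  limb_test = file.path(out_dir, "limb_gene_enrichment.tsv"),
  region = file.path(out_dir, "region_enrichment.tsv"),
  introns = file.path(out_dir, "intron_screen.json"),
  limited = file.path(out_dir, "limited_expansion_genes.tsv"),
  activity = file.path(out_dir, "enhancer_activity.tsv"),
  pleiotropy = file.path(out_dir, "pleiotropy.tsv"),
  origins = file.path(out_dir, "origins.tsv"),
  report = file.path(out_dir, "report.json"))

write_tsv <- function(x, path)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)

load_inputs <- function() {
  man <- read_species_manifest(paths$manifest, paths$tree)
  man$tree <- label_ancestor_nodes(man$tree, man$species)
  man$cfg <- read_config(paths$config)
  man
}
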