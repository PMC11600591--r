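#!/usr/bin/env Rscript
# Stage 7 — limited-intron-expansion screen.
# Filters the 17-species ortholog table (exon deviation > 40%, introns absent
# in > 6 species), finds genes whose intron length in each large-genome focal
# species stays under twice the 14-species reference median, intersects the
# three sets, and tests the overlap with a seeded Monte Carlo null.
source("analysis/00_setup.R")

inp <- load_inputs()
log_run("introns", inp$cfg, seed)
orth <- utils::read.delim(file.path(paths$fixtures, "orthologs.tsv"))
ref_species <- sprintf("ref_%02d", 1:14)
focal <- setdiff(unique(orth$species), ref_species)

flt <- suppressWarnings(filter_ortholog_set(orth, ref_species, focal))
lim <- limited_expansion_genes(orth[orth$gene_id %in% flt$retained, ],
                               flt$medians, focal)
per <- do.call(rbind, lapply(names(lim$per_species), function(sp)
  data.frame(species = sp, gene_id = lim$per_species[[sp]],
             stringsAsFactors = FALSE)))
write_tsv(rbind(per, data.frame(species = "shared", gene_id = lim$intersection)),
          paths$limited)

mc <- mc_overlap_test(length(flt$retained), set_sizes = lengths(lim$per_species),
                      observed_overlap = length(lim$intersection),
                      n_trials = 100000L, seed = seed)
jsonlite::write_json(
  list(universe = length(flt$retained),
       set_sizes = as.list(lengths(lim$per_species)),
       observed_overlap = length(lim$intersection),
       mean = mc$mean, sd = mc$sd, z_score = mc$z_score,
       empirical_p = mc$empirical_p, n_exceedances = mc$n_exceedances,
       n_trials = mc$n_trials, seed = seed),
  paths$introns, auto_unbox = TRUE, digits = 10, pretty = TRUE)

message(sprintf("limited in all %d focal species: %d genes; MC z = %.2f (p = %.3g%s)",
                length(focal), length(lim$intersection), mc$z_score,
                mc$empirical_p,
                if (mc$n_exceedances == 0L)
                  sprintf("; no exceedances in %d trials", mc$n_trials) else ""))
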