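#!/usr/bin/env Rscript
# Stage 9 — collate the run into one JSON report.
source("analysis/00_setup.R")

inp <- load_inputs()
log_run("report", inp$cfg, seed)
records <- utils::read.delim(paths$convergence)
records$degenerated_lineages[is.na(records$degenerated_lineages)] <- ""
combos <- utils::read.delim(paths$combinations)
rates <- utils::read.delim(paths$rates)
contrast <- jsonlite::read_json(paths$contrast)
introns <- jsonlite::read_json(paths$introns)
pleio <- utils::read.delim(paths$pleiotropy)
origins <- utils::read.delim(paths$origins)
limb_test <- utils::read.delim(paths$limb_test)

active <- pleio$n_active_tissues > 0
report <- list(
  seed = seed,
  n_retained_cnes = nrow(records),
  n_dcnes = sum(records$n_lineages >= 1),
  n_lineage_specific = sum(records$klass == "lineage_specific"),
  n_convergent = sum(records$n_lineages >= 2),
  combinations = combos,
  rate_range_per_myr = range(rates$rate_per_myr),
  neutral_means = contrast$means,
  neutral_max_p = max(unlist(lapply(contrast$tests$p_value, as.numeric))),
  limb_gene_min_q = min(limb_test$q_value),
  mc_z = introns$z_score,
  n_limited_shared = introns$observed_overlap,
  fraction_pleiotropic = if (any(active)) mean(pleio$pleiotropic[active]) else NA,
  origin_counts = as.list(table(origins$origin)))
jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = 10,
                     dataframe = "columns", pretty = TRUE)
message("report written to ", paths$report)
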