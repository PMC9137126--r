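#!/usr/bin/env Rscript
# Step 6 — call differentiation-delaying candidates: T0 representation
# filter, per-replicate DDE ratios at T3/T6, decile thresholds, the
# identical-designs-in-both-replicates rule, and the control-concordance
# QC that contrasts positive controls with intergenic nulls.
#
# Reads:  results/counts/counts.tsv, results/library/library.tsv
# Writes: results/dde/{dde_table.tsv, thresholds.tsv, mean_thresholds.tsv,
#         candidate_calls.tsv, control_concordance.tsv}

suppressPackageStartupMessages(library(pgdecko))
outdir <- "results/dde"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

counts <- read_counts("results/counts/counts.tsv")
lib <- read_library("results/library/library.tsv")
info <- read.delim("results/screen/sample_sheet.tsv")

retained <- t0_filter(counts, info, min_t0 = 5)
cat(sprintf("T0 filter (>= 5 counts): %d / %d constructs retained in rep1, %d in rep2\n",
            length(retained[["1"]]), nrow(counts), length(retained[["2"]])))

dde <- compute_dde(counts, info, retained, lib)
write.table(dde, file.path(outdir, "dde_table.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

hits <- decile_hits(dde, pct = 90)
write.table(hits$thresholds, file.path(outdir, "thresholds.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(mean_dde_thresholds(dde), file.path(outdir, "mean_thresholds.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("90th-percentile DDE thresholds per replicate/timepoint:\n")
print(hits$thresholds, row.names = FALSE)

calls <- call_candidates(hits, lib, min_designs = 2)
write.table(calls, file.path(outdir, "candidate_calls.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
called <- calls[calls$final_call, ]
cat(sprintf("\ncandidates called (>= 2 identical hit designs in both replicates): %d\n",
            nrow(called)))
if (nrow(called)) print(called, row.names = FALSE)

cc <- control_concordance(dde, list(
  positive = lib$construct_id[lib$class == "positive_control"],
  intergenic = lib$construct_id[lib$class == "intergenic_control"]))
write.table(cc, file.path(outdir, "control_concordance.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\ncontrol QC (replicate Spearman of DDE):\n")
print(cc, row.names = FALSE)
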