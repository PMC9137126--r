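#!/usr/bin/env Rscript
# Step 1 — generate every input of the screen pipeline: a toy genome with
# coding and lncRNA gene models, and two-replicate FPKM time courses with
# planted expression-profile classes.
#
# Writes: results/sim/{genome.fa, annotation.gtf, fpkm_rep{1,2}.tsv,
#         timecourse_truth.tsv}

suppressPackageStartupMessages(library(pgdecko))
outdir <- "results/sim"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 1, genome_length = 120000, n_pc_genes = 4,
                  n_lnc_genes = 4)
ann <- make_toy_annotation(cfg)
write_annotation(ann, file.path(outdir, "genome.fa"),
                 file.path(outdir, "annotation.gtf"))
cat(sprintf("genome: 1 chromosome, %d bp; %d gene models (%d coding, %d lncRNA)\n",
            cfg$genome_length, nrow(ann$models$genes),
            sum(ann$models$genes$biotype == "protein_coding"),
            sum(ann$models$genes$biotype == "lncRNA")))

tc <- make_timecourse(cfg)   # defaults: 40 genes/class, noise_sd = 0.1
write_fpkm(tc$rep1, file.path(outdir, "fpkm_rep1.tsv"))
write_fpkm(tc$rep2, file.path(outdir, "fpkm_rep2.tsv"))
write.table(tc$truth, file.path(outdir, "timecourse_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("time courses: %d genes x %d timepoints x 2 replicates (classes: %s)\n",
            nrow(tc$rep1), length(cfg$timepoints_h),
            paste(names(table(tc$truth$class)), table(tc$truth$class),
                  sep = "=", collapse = ", ")))
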