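#!/usr/bin/env Rscript
# Step 3 — design the paired-guide deletion library against the toy genome:
# ORF-directed pairs for coding genes, TSS-straddling pairs for lncRNAs,
# positive-control designs and intergenic negative controls, each with its
# 165-nt cloning oligo.
#
# Reads:  results/sim/{genome.fa, annotation.gtf}
# Writes: results/library/{library.tsv, oligos.fa, reference.fa}

suppressPackageStartupMessages(library(pgdecko))
outdir <- "results/library"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

genome <- as.character(Biostrings::readDNAStringSet("results/sim/genome.fa"))
models <- read_gene_models("results/sim/annotation.gtf")
genes <- models$genes

# screen 2 coding + 2 lncRNA targets; 1 coding gene doubles as the
# positive control with extra designs
targets <- rbind(
  genes[genes$biotype == "protein_coding", ][1:2, c("gene_id", "biotype")],
  genes[genes$biotype == "lncRNA", ][1:2, c("gene_id", "biotype")])
pos_gene <- genes[genes$biotype == "protein_coding", ]$gene_id[3]

lib <- suppressWarnings(build_library(
  targets, models, genome,
  controls = control_spec(
    positive = data.frame(gene_id = pos_gene, n_designs = 6),
    n_intergenic = 4, intergenic_designs = 3),
  n_designs = 4, seed = 1))
write_library(lib, file.path(outdir, "library.tsv"))
write_oligo_fasta(lib, file.path(outdir, "oligos.fa"))
ref <- build_reference(lib)
write_reference_fasta(ref, file.path(outdir, "reference.fa"))

cat(sprintf("library: %d constructs (%s)\n", nrow(lib),
            paste(names(table(lib$class)), table(lib$class), sep = "=",
                  collapse = ", ")))
cat(sprintf("artificial reference: %d records, all %d bp; oligos all %d nt\n",
            nrow(ref$records), unique(nchar(ref$records$sequence)),
            unique(nchar(lib$insert1))))
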