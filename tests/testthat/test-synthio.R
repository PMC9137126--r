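test_that("sim_config validates its invariants", {
  expect_error(sim_config(timepoints_h = c(0, 3, 3, 9)), "increasing")
  expect_error(sim_config(noise_sd = -0.1), "non-negative")
  expect_error(sim_config(nb_dispersion = 0), "positive")
  expect_identical(sim_config()$timepoints_h,
                   c(0, 3, 6, 9, 12, 18, 24, 36, 48, 72, 120, 168))
})

test_that("toy annotation satisfies its structural postconditions", {
  ann <- fixture_annotation()
  genes <- ann$models$genes
  exons <- ann$models$exons
  expect_equal(sum(genes$biotype == "protein_coding"), 4)
  expect_equal(sum(genes$biotype == "lncRNA"), 4)
  expect_setequal(unique(genes$strand), c("+", "-"))
  # all exons within genome bounds
  expect_true(all(exons$start >= 0 & exons$end <= nchar(ann$genome[["chr1"]])))
  # CDS length divisible by 3, multi-exon coding models
  for (g in genes$gene_id[genes$biotype == "protein_coding"]) {
    ex <- exons[exons$gene_id == g, ]
    expect_gte(nrow(ex), 2)
    cds_len <- sum(ex$cds_end - ex$cds_start, na.rm = TRUE)
    expect_identical(cds_len %% 3L, 0L)
  }
  # >= 1 kb annotation-free stretch exists
  gaps <- genes$start[-1] - genes$end[-nrow(genes)]
  expect_true(any(gaps >= 1000) || genes$start[1] >= 1000)
})

test_that("annotation generation is byte-deterministic and errors on tiny genomes", {
  cfg <- sim_config(seed = 3, genome_length = 120000)
  a1 <- make_toy_annotation(cfg)
  a2 <- make_toy_annotation(cfg)
  expect_identical(a1$genome, a2$genome)
  expect_identical(a1$models, a2$models)
  d1 <- withr::local_tempdir()
  write_annotation(a1, file.path(d1, "g1.fa"), file.path(d1, "a1.gtf"))
  write_annotation(a2, file.path(d1, "g2.fa"), file.path(d1, "a2.gtf"))
  expect_identical(readLines(file.path(d1, "g1.fa")),
                   readLines(file.path(d1, "g2.fa")))
  expect_identical(readLines(file.path(d1, "a1.gtf")),
                   readLines(file.path(d1, "a2.gtf")))
  expect_error(make_toy_annotation(sim_config(genome_length = 5000)), "10 kb")
  expect_error(make_toy_annotation(sim_config(genome_length = 20000,
                                              n_pc_genes = 4, n_lnc_genes = 4)),
               "cannot place")
})

test_that("gene models round-trip through GTF", {
  ann <- fixture_annotation()
  d <- withr::local_tempdir()
  write_annotation(ann, file.path(d, "g.fa"), file.path(d, "a.gtf"))
  back <- read_gene_models(file.path(d, "a.gtf"))
  expect_equal(back$genes[order(back$genes$gene_id),
                          c("gene_id", "biotype", "strand", "start", "end", "tss")],
               ann$models$genes[order(ann$models$genes$gene_id),
                          c("gene_id", "biotype", "strand", "start", "end", "tss")],
               ignore_attr = TRUE)
  ex1 <- back$exons[order(back$exons$gene_id, back$exons$exon_number), ]
  ex2 <- ann$models$exons[order(ann$models$exons$gene_id,
                                ann$models$exons$exon_number), ]
  expect_equal(ex1$start, ex2$start)
  expect_equal(ex1$cds_start, ex2$cds_start)
  expect_equal(ex1$cds_end, ex2$cds_end)
})

test_that("noise-free time-course templates pass/fail the expression filters as planted", {
  cfg <- sim_config(seed = 1, noise_sd = 0,
                    n_genes_per_class = c(peaking = 2, upregulated = 2,
                                          flat = 2, down = 2))
  tc <- make_timecourse(cfg)
  expect_identical(tc$rep1[, -(1:2)], tc$rep2[, -(1:2)])
  m <- as.matrix(tc$rep1[, -(1:2)])
  fold <- apply(m, 1, max) / apply(m, 1, min)
  up <- tc$truth$class == "upregulated"
  expect_true(all(fold[up] >= 4))           # 0.5 -> 4.0 is an 8-fold rise
  expect_true(all(abs(fold[tc$truth$class == "flat"] - 1) < 1e-9))
  # upregulated template is monotone; peaking peaks at 36 h internally
  expect_true(all(apply(m[up, , drop = FALSE], 1, function(x) all(diff(x) > 0))))
  pk <- which(tc$truth$class == "peaking")
  expect_true(all(apply(m[pk, , drop = FALSE], 1, which.max) ==
                  which(cfg$timepoints_h == 36)))
  sel <- select_expressed(tc$rep1)
  expect_true(all(tc$truth$gene_id[up] %in% sel))
  expect_false(any(tc$truth$gene_id[tc$truth$class == "flat"] %in% sel))
})

test_that("time courses are deterministic under a fixed config and error on bad noise", {
  cfg <- sim_config(seed = 5)
  expect_identical(make_timecourse(cfg), make_timecourse(cfg))
  expect_error(sim_config(noise_sd = -1), "non-negative")
})

test_that("simulated reads carry anchors with staggered offsets and conserve counts", {
  lib <- make_toy_library(sim_config(seed = 2), n_targets = 5,
                          designs_per_target = 4)
  cfg <- sim_config(seed = 2, depth = 40, error_rate = 0)
  sim <- make_screen_reads(lib, cfg)
  expect_identical(names(sim$samples), sim$sample_info$sample_id)
  # read totals match the truth counts per sample
  for (s in sim$sample_info$sample_id) {
    expect_identical(length(sim$samples[[s]]$read1), sum(sim$counts[, s]))
    expect_identical(length(sim$samples[[s]]$read2), sum(sim$counts[, s]))
  }
  r2 <- sim$samples[[1]]$read2
  a1 <- regexpr("ACCG", substr(r2, 15, 58), fixed = TRUE)
  starts <- 14 + as.integer(a1)
  expect_true(all(a1 > 0))
  expect_gte(length(unique(starts)), 4)     # stagger spreads the anchor start
  expect_true(all(starts >= 15 & starts <= 55))
  r1 <- sim$samples[[1]]$read1
  a2 <- regexpr("AAAC", substr(r1, 100, 153), fixed = TRUE)
  expect_true(all(a2 > 0))
  expect_true(all(99 + as.integer(a2) >= 100))
  expect_error(make_screen_reads(lib, sim_config(read_len_1 = 50)),
               "too short")
})

test_that("spiked constructs are enriched in the delayed fraction as configured", {
  lib <- make_toy_library(sim_config(seed = 9), n_targets = 40,
                          designs_per_target = 10)
  cfg <- sim_config(seed = 9, depth = 200, spike_cv = 0, error_rate = 0,
                    spike_targets = data.frame(target_id = "TGT001", fold = 5))
  cs <- make_screen_counts(lib, cfg)
  spiked <- lib$target_id == "TGT001"
  expect_true(all(cs$construct_truth$delayed_fold[spiked] == 5))
  expect_true(all(cs$construct_truth$delayed_fold[!spiked] == 1))
  ratio <- function(rows) {
    sum(cs$counts[rows, "T3_delayed_rep1"]) /
      sum(cs$counts[rows, "T3_differentiated_rep1"])
  }
  # 100 spiked vs 3900 null construct-draws at depth 200: the empirical
  # delayed/differentiated ratio contrast sits near the planted 5-fold
  expect_gt(ratio(spiked) / ratio(!spiked), 3.5)
  expect_lt(ratio(spiked) / ratio(!spiked), 6.5)
})

test_that("FASTQ output round-trips through the file-based quantifier", {
  lib <- make_toy_library(sim_config(seed = 4), n_targets = 4,
                          designs_per_target = 3)
  cfg <- sim_config(seed = 4, depth = 15, error_rate = 0)
  sim <- make_screen_reads(lib, cfg)
  d <- withr::local_tempdir()
  sheet <- write_screen_fastq(sim, d)
  expect_true(all(file.exists(sheet$fastq1, sheet$fastq2)))
  res <- quantify(sheet, lib, max_mm = 0)
  expect_identical(res$counts[rownames(sim$counts), colnames(sim$counts)],
                   sim$counts)
  truth <- read_counts(file.path(d, "counts_truth.tsv"))
  expect_identical(truth, sim$counts)
  sheet_bad <- sheet
  sheet_bad$fastq1[1] <- file.path(d, "absent.fastq.gz")
  expect_error(quantify(sheet_bad, lib), "missing FASTQ")
})
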