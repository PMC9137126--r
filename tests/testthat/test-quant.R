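test_that("the artificial reference has 41-nt records and collapses duplicates", {
  lib <- tiny_library()
  ref <- build_reference(lib)
  expect_equal(nrow(ref$records), 3)
  expect_true(all(nchar(ref$records$sequence) == 41))
  expect_identical(ref$records$sequence[ref$records$ref_id == "tgtA_pg01"],
                   paste0("G", strrep("A", 20), strrep("A", 20)))
  # two constructs sharing a guide pair -> one record with both source ids
  dup <- rbind(lib, transform(lib[1, ], construct_id = "tgtC_pg01",
                              target_id = "tgtC"))
  ref2 <- build_reference(dup)
  expect_equal(nrow(ref2$records), 3)
  merged <- ref2$records[ref2$records$n_sources == 2, ]
  expect_identical(merged$source_ids, "tgtA_pg01;tgtC_pg01")
  bad <- lib; bad$guide2_seq[2] <- "ACGT"
  expect_error(build_reference(bad), "tgtA_pg02")
})

test_that("anchor windows gate extraction exactly", {
  g1 <- paste0("G", random_dna_str(1, 20, seed = 1))
  g2 <- random_dna_str(1, 20, seed = 2)
  rp <- synth_read_pair(g1, g2)
  ex <- extract_fused_guides(rp$read1, rp$read2)
  expect_identical(ex$status, "fused")
  expect_identical(ex$fused, paste0(g1, revcomp_chr(g2)))
  # anchor before the window start on read 2 -> no_anchor1
  low <- paste0(strrep("T", 9), "ACCG", g1, strrep("T", 120))
  ex2 <- extract_fused_guides(rp$read1, substr(low, 1, 150))
  expect_identical(ex2$status, "no_anchor1")
  # anchor exactly at window edge positions 15 and 55 is accepted
  for (pos in c(15L, 55L)) {
    r2 <- paste0(strrep("T", pos - 1L), "ACCG", g1, strrep("T", 120))
    exe <- extract_fused_guides(rp$read1, substr(r2, 1, 170))
    expect_identical(exe$status, "fused")
  }
  # missing AAAC in read 1 window -> no_anchor2
  ex3 <- extract_fused_guides(strrep("G", 150), rp$read2)
  expect_identical(ex3$status, "no_anchor2")
})

test_that("read-end truncation is kept down to 20 nt of fused sequence", {
  g1 <- paste0("G", random_dna_str(1, 20, seed = 3))
  g2 <- random_dna_str(1, 20, seed = 4)
  rp <- synth_read_pair(g1, g2, stagger1 = 0L)
  # read 1 ends 5 nt into the guide-2 segment: fused = 21 + 15 = 36 >= 20
  ex <- extract_fused_guides(substr(rp$read1, 1, 100 + 4 + 15), rp$read2)
  expect_identical(ex$status, "fused")
  expect_identical(nchar(ex$fused), 36L)
  # truncate read 2 so the guide-1 segment leaves fused < 20 -> too_short
  r2cut <- substr(rp$read2, 1, 19 + 4 + 8)   # 8 nt of guide 1
  ex2 <- extract_fused_guides(substr(rp$read1, 1, 108), r2cut)
  expect_identical(ex2$status, "too_short")
})

test_that("assignment matches the brute-force scan and applies the tie rule", {
  set.seed(11)
  lib <- make_toy_library(sim_config(seed = 11), n_targets = 30,
                          designs_per_target = 4)
  ref <- build_reference(lib)
  base <- ref$records$sequence
  mutate <- function(s, k) {
    pos <- sample(nchar(s), k)
    ch <- strsplit(s, "")[[1]]
    ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(c("A","C","G","T"), b), 1),
                      character(1))
    paste(ch, collapse = "")
  }
  fused <- c(base[1:20],
             vapply(base[21:60], mutate, character(1), k = 1),
             vapply(base[61:90], mutate, character(1), k = 3),
             substr(base[91:110], 1, 30),
             random_dna_str(10, 41))
  got <- assign_reads(fused, ref, max_mm = 2)
  want <- oracle_assign(fused, ref$records$ref_id, base, max_mm = 2)
  expect_identical(got$ref_id, want[, 1])
  expect_identical(got$status, want[, 2])
  # distance 3 from the nearest record: unmapped at 2, assigned at 13
  far <- mutate(base[1], 3)
  expect_identical(assign_reads(far, ref, max_mm = 2)$status, "unmapped")
  a13 <- assign_reads(far, ref, max_mm = 13)
  expect_identical(a13$status, "assigned")
  expect_identical(a13$ref_id, ref$records$ref_id[1])
})

test_that("a read equidistant from two references is multimapped", {
  lib <- tiny_library()[1:2, ]
  lib$guide1_seq <- c(paste0("G", strrep("A", 20)), paste0("G", strrep("A", 20)))
  lib$guide2_seq <- c(strrep("T", 20),
                      paste0("C", strrep("T", 18), "C"))
  ref <- build_reference(lib)   # records differ at exactly two positions
  probe <- paste0("G", strrep("A", 20), "G", strrep("A", 19))
  d <- vapply(ref$records$sequence, function(r) oracle_hamming(probe, r),
              numeric(1))
  expect_true(all(d == 1))
  expect_identical(assign_reads(probe, ref, max_mm = 2)$status, "multimapped")
})

test_that("assigned + multimapped is non-decreasing in the mismatch allowance", {
  set.seed(12)
  lib <- make_toy_library(sim_config(seed = 12), n_targets = 20,
                          designs_per_target = 3)
  cfg <- sim_config(seed = 12, depth = 20, error_rate = 0.02)
  sim <- make_screen_reads(lib, cfg)
  ex <- extract_fused_guides(sim$samples[[1]]$read1, sim$samples[[1]]$read2)
  fused <- ex$fused[ex$status == "fused"]
  ref <- build_reference(lib)
  prev <- -1L
  for (mm in c(0L, 1L, 2L, 4L, 8L)) {
    a <- assign_reads(fused, ref, max_mm = mm)
    cur <- sum(a$status %in% c("assigned", "multimapped"))
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("error-free quantification reproduces the truth counts exactly", {
  lib <- make_toy_library(sim_config(seed = 13), n_targets = 25,
                          designs_per_target = 4)
  cfg <- sim_config(seed = 13, depth = 30, error_rate = 0)
  sim <- make_screen_reads(lib, cfg)
  res <- quantify_reads(sim$samples, lib, max_mm = 2)
  expect_identical(res$counts[rownames(sim$counts), colnames(sim$counts)],
                   sim$counts)
  acc <- res$accounting
  expect_true(all(acc$fused == acc$n_pairs))
  expect_true(all(acc$assigned + acc$unmapped + acc$multimapped == acc$fused))
})

test_that("accounting is conserved and counts are order-invariant under errors", {
  lib <- make_toy_library(sim_config(seed = 14), n_targets = 15,
                          designs_per_target = 4)
  cfg <- sim_config(seed = 14, depth = 25, error_rate = 0.005)
  sim <- make_screen_reads(lib, cfg)
  res <- quantify_reads(sim$samples, lib, max_mm = 2)
  acc <- res$accounting
  expect_true(all(acc$n_pairs ==
    acc$fused + acc$no_anchor1 + acc$no_anchor2 + acc$too_short))
  expect_true(all(acc$fused == acc$assigned + acc$unmapped + acc$multimapped))
  # permuting read order leaves the count matrix unchanged
  perm_samples <- lapply(sim$samples, function(s) {
    set.seed(1); i <- sample(length(s$read1))
    list(read1 = s$read1[i], read2 = s$read2[i])
  })
  res2 <- quantify_reads(perm_samples, lib, max_mm = 2)
  expect_identical(res$counts, res2$counts)
})

test_that("duplicate-construct counts can be split per source construct", {
  lib <- tiny_library()
  dup <- rbind(lib, transform(lib[1, ], construct_id = "tgtC_pg01",
                              target_id = "tgtC"))
  g1 <- dup$guide1_seq[1]; g2 <- dup$guide2_seq[1]
  rp <- synth_read_pair(g1, g2)
  res <- quantify_reads(list(s1 = list(read1 = rep(rp$read1, 3),
                                       read2 = rep(rp$read2, 3))), dup)
  merged_id <- "tgtA_pg01;tgtC_pg01"
  expect_identical(unname(res$counts[merged_id, "s1"]), 3L)
  split <- pgdecko:::split_duplicate_counts(res)
  expect_identical(unname(split["tgtA_pg01", "s1"]), 3L)
  expect_identical(unname(split["tgtC_pg01", "s1"]), 3L)
})
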