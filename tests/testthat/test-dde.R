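# Minimal count matrix covering both replicates at T3/T6 plus per-replicate T0.
dde_fixture <- function(n = 12, seed = 51, depth = 50) {
  set.seed(seed)
  info <- screen_samples()
  counts <- matrix(rpois(n * nrow(info), depth), nrow = n,
                   dimnames = list(sprintf("c%02d", seq_len(n)),
                                   info$sample_id))
  storage.mode(counts) <- "integer"
  list(counts = counts, info = info)
}

test_that("the T0 filter applies the boundary at 5 counts per replicate", {
  fx <- dde_fixture()
  fx$counts[1, "T0_initial_rep1"] <- 4L
  fx$counts[1, "T0_initial_rep2"] <- 12L
  fx$counts[2, c("T0_initial_rep1", "T0_initial_rep2")] <- c(5L, 12L)
  fx$counts[3, ] <- 0L
  ret <- t0_filter(fx$counts, fx$info, min_t0 = 5)
  expect_false("c01" %in% ret[["1"]])
  expect_true("c01" %in% ret[["2"]])       # each replicate uses its own T0
  expect_true("c02" %in% ret[["1"]])
  expect_false("c03" %in% ret[["1"]] || "c03" %in% ret[["2"]])
  info_no_t0 <- fx$info[fx$info$timepoint != "T0", ]
  expect_error(t0_filter(fx$counts[, info_no_t0$sample_id], info_no_t0),
               "no T0 sample")
})

test_that("DDE ratios and zero policies follow their definitions", {
  fx <- dde_fixture(n = 4)
  fx$counts["c01", "T3_delayed_rep1"] <- 10L
  fx$counts["c01", "T3_differentiated_rep1"] <- 5L
  fx$counts["c02", "T3_delayed_rep1"] <- 0L
  fx$counts["c02", "T3_differentiated_rep1"] <- 7L
  fx$counts["c03", "T3_delayed_rep1"] <- 3L
  fx$counts["c03", "T3_differentiated_rep1"] <- 0L
  ret <- rownames(fx$counts)
  dde <- compute_dde(fx$counts, fx$info, ret)
  r1t3 <- dde[dde$replicate == 1 & dde$timepoint == "T3", ]
  expect_identical(r1t3$dde[r1t3$construct_id == "c01"], 2.0)
  expect_identical(r1t3$dde[r1t3$construct_id == "c02"], 0.0)
  expect_identical(r1t3$dde[r1t3$construct_id == "c03"], Inf)
  pc <- compute_dde(fx$counts, fx$info, ret, zero_policy = "pseudocount",
                    pseudocount = 1)
  p1t3 <- pc[pc$replicate == 1 & pc$timepoint == "T3", ]
  expect_identical(p1t3$dde[p1t3$construct_id == "c03"], 4.0)
  expect_error(compute_dde(fx$counts - 100L, fx$info, ret), "non-negative")
})

test_that("DDE is invariant to per-sample scaling of counts", {
  fx <- dde_fixture(n = 20, seed = 52)
  ret <- rownames(fx$counts)
  base <- compute_dde(fx$counts, fx$info, ret)
  scaled <- fx$counts
  scaled[, "T3_delayed_rep1"] <- scaled[, "T3_delayed_rep1"] * 7L
  scaled[, "T3_differentiated_rep1"] <-
    scaled[, "T3_differentiated_rep1"] * 7L
  got <- compute_dde(scaled, fx$info, ret)
  expect_equal(got$dde, base$dde)
})

test_that("decile thresholds use linear interpolation and strict exceedance", {
  fx <- dde_fixture(n = 10, seed = 53)
  info <- fx$info
  # engineer rep1/T3 DDE values exactly 1..10
  fx$counts[, "T3_differentiated_rep1"] <- 1L
  fx$counts[, "T3_delayed_rep1"] <- 1:10
  dde <- compute_dde(fx$counts, info, rownames(fx$counts))
  h <- decile_hits(dde, pct = 90)
  thr <- h$thresholds
  t13 <- thr[thr$replicate == 1 & thr$timepoint == "T3", ]
  expect_equal(t13$threshold, 9.1)
  expect_equal(t13$threshold, oracle_percentile(1:10, 0.9))
  hits <- h$table[h$table$replicate == 1 & h$table$timepoint == "T3" &
                  h$table$hit, ]
  expect_identical(hits$construct_id, "c10")
  # all-equal stratum: nothing strictly above the threshold
  fx$counts[, "T6_delayed_rep1"] <- 5L
  fx$counts[, "T6_differentiated_rep1"] <- 5L
  h2 <- decile_hits(compute_dde(fx$counts, info, rownames(fx$counts)))
  t16 <- h2$thresholds
  expect_identical(t16$n_hits[t16$replicate == 1 & t16$timepoint == "T6"], 0L)
})

test_that("infinite DDE values are hits and hit fractions are near 10 percent", {
  fx <- dde_fixture(n = 100, seed = 54)
  rownames(fx$counts)[1] <- "inf1"
  fx$counts["inf1", "T3_delayed_rep1"] <- 9L
  fx$counts["inf1", "T3_differentiated_rep1"] <- 0L
  dde <- compute_dde(fx$counts, fx$info, rownames(fx$counts))
  h <- decile_hits(dde)
  tab <- h$table
  expect_true(tab$hit[tab$construct_id == "inf1" & tab$replicate == 1 &
                      tab$timepoint == "T3"])
  # tie-free strata: hits within one construct of 10% of finite values
  thr <- h$thresholds
  expect_true(all(abs(thr$n_hits - 0.1 * thr$n_finite) <= 1 + 1))
})

test_that("candidate calling demands identical hit designs in both replicates", {
  info <- screen_samples()
  lib <- data.frame(construct_id = sprintf("T%d_pg%d", rep(1:3, each = 3), 1:3),
                    target_id = rep(c("tA", "tB", "tC"), each = 3),
                    class = "pc", stringsAsFactors = FALSE)
  mk_hits <- function(hit_sets) {
    grid <- expand.grid(construct_id = lib$construct_id, replicate = 1:2,
                        timepoint = c("T3", "T6"), stringsAsFactors = FALSE)
    grid$dde <- 1; grid$hit <- FALSE
    for (h in hit_sets) {
      sel <- grid$construct_id %in% h$ids & grid$replicate == h$rep &
             grid$timepoint == h$tp
      grid$hit[sel] <- TRUE
    }
    list(table = grid, thresholds = NULL)
  }
  # tA: 3 shared designs at T3 -> called; tB: 2 hits rep1 but only a
  # different single design in rep2 -> not called
  h <- mk_hits(list(
    list(ids = paste0("T1_pg", 1:3), rep = 1, tp = "T3"),
    list(ids = paste0("T1_pg", 1:3), rep = 2, tp = "T3"),
    list(ids = c("T2_pg1", "T2_pg2"), rep = 1, tp = "T3"),
    list(ids = "T2_pg3", rep = 2, tp = "T3")))
  calls <- call_candidates(h, lib)
  expect_true(calls$final_call[calls$target_id == "tA"])
  expect_match(calls$called_at[calls$target_id == "tA"], "T3")
  expect_false(calls$final_call[calls$target_id == "tB"])
  # monotonicity: adding hit designs never un-calls a target
  h2 <- mk_hits(list(
    list(ids = paste0("T1_pg", 1:3), rep = 1, tp = "T3"),
    list(ids = paste0("T1_pg", 1:3), rep = 2, tp = "T3"),
    list(ids = paste0("T2_pg", 1:3), rep = 1, tp = "T3"),
    list(ids = paste0("T2_pg", 1:3), rep = 2, tp = "T3")))
  calls2 <- call_candidates(h2, lib)
  expect_true(all(calls2$final_call[calls$final_call]))
  # union vs intersection across timepoints
  h3 <- mk_hits(list(
    list(ids = paste0("T1_pg", 1:2), rep = 1, tp = "T3"),
    list(ids = paste0("T1_pg", 1:2), rep = 2, tp = "T3")))
  expect_true(call_candidates(h3, lib)$final_call[1])
  expect_false(call_candidates(h3, lib, combine = "intersection")$final_call[1])
  h_bad <- h
  h_bad$table$construct_id[1] <- "unknown_pg1"
  expect_error(call_candidates(h_bad, lib), "absent from the library")
})

test_that("identical replicate DDE vectors give perfect rank concordance", {
  info <- screen_samples()
  ids <- sprintf("c%02d", 1:10)
  tab <- expand.grid(construct_id = ids, replicate = 1:2,
                     timepoint = c("T3", "T6"), stringsAsFactors = FALSE)
  tab$dde <- rep(seq(0.2, 2, length.out = 10), 4)
  cc <- control_concordance(tab, list(ctrl = ids))
  expect_equal(cc$spearman, rep(1, 2))
  expect_identical(cc$n, rep(10L, 2))
  # fewer than 3 constructs: correlation omitted
  cc2 <- control_concordance(tab[tab$construct_id %in% ids[1:2], ],
                             list(ctrl = ids[1:2]))
  expect_true(all(is.na(cc2$spearman)))
})

test_that("replicate-mean decile thresholds are reported per timepoint", {
  fx <- dde_fixture(n = 40, seed = 55)
  dde <- compute_dde(fx$counts, fx$info, rownames(fx$counts))
  mt <- mean_dde_thresholds(dde)
  expect_identical(mt$timepoint, c("T3", "T6"))
  expect_true(all(is.finite(mt$threshold)))
  expect_true(all(mt$n <= 40))
})

test_that("stain index and ddCt quantification compute their closed forms", {
  expect_identical(stain_index(100, 10, 5), 9)
  expect_identical(stain_index(10, 10, 5), 0)
  expect_identical(stain_index(100, 10, 10), 4.5)   # doubling SD halves it
  expect_error(stain_index(1, 0, 0), "strictly positive")
  # ddCt = 0, 1, -2 -> fold 1, 0.5, 4
  expect_identical(relative_quant(5, 5, 7, 7), 1)
  expect_identical(relative_quant(6, 5, 7, 7), 0.5)
  expect_identical(relative_quant(5, 5, 9, 7), 4)
  # strictly decreasing in ddCt
  dd <- seq(-3, 3, by = 0.5)
  fc <- vapply(dd, function(d) relative_quant(10 + d, 10, 8, 8), numeric(1))
  expect_true(all(diff(fc) < 0))
  expect_error(relative_quant(Inf, 5, 7, 7), "finite")
})
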