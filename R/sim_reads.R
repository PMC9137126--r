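# Fixed synthetic vector-context constants of the read simulator. Only the
# ACCG/AAAC anchors and the window geometry are contractual; these
# placeholder sequences are chosen free of in-window anchor matches.
# Read 2: [stagger 0-7 nt][VEC2 16 nt][ACCG][guide1 21 nt][FILL...]
#   -> anchor start in 17..24, inside the 15..55 search window.
# Read 1: [stagger 0-7 nt][VEC1 100 nt][AAAC][rc(guide2) 20 nt][FILL...]
#   -> anchor start in 101..108, inside the 100..150 search window.
SIM_VEC2 <- "TGGAAAGGTCGGTGCT"
SIM_VEC1 <- paste0("CTTGTGGAGAGGACGTTTCGTCCGGGTGTTTCGTCCTTTCCTCAAG",
                   "GTATTAGGCTTAGGTGGATGGCTGTTCGCCATTTGTCGGTGGAATCGTGGCTCG")
SIM_FILL <- paste0("TGCTATGCTGTTTCCAGCTTAGCTCTTAAACGCTATGCTGGATTCCAGCTTGGC",
                   "TCTTACTGCTATGCTGTCTCCAGCTTAGCTCTTACGGCTATGCTGTTTGCAGCT",
                   "TAGCTCTTATGGCTATGCTGATTCCAGCTTAGCTCTTACC")

#' Enumerate the screen's sample grid
#'
#' One initial (T0) sample per replicate, plus delayed and differentiated
#' sorted fractions at T3 and T6 for both replicates (10 samples).
#'
#' @return data.frame with `sample_id`, `timepoint`, `fraction`,
#'   `replicate`.
#' @export
screen_samples <- function() {
  grid <- expand.grid(fraction = c("delayed", "differentiated"),
                      timepoint = c("T3", "T6"),
                      replicate = 1:2, stringsAsFactors = FALSE)
  sorted <- data.frame(
    sample_id = sprintf("%s_%s_rep%d", grid$timepoint, grid$fraction,
                        grid$replicate),
    timepoint = grid$timepoint, fraction = grid$fraction,
    replicate = grid$replicate, stringsAsFactors = FALSE)
  t0 <- data.frame(sample_id = sprintf("T0_initial_rep%d", 1:2),
                   timepoint = "T0", fraction = "initial", replicate = 1:2,
                   stringsAsFactors = FALSE)
  rbind(t0, sorted)
}

#' Simulate per-construct screen counts
#'
#' Per construct and sample, the read-pair count is negative-binomial with
#' mean `depth` times the construct's fraction fold, and dispersion
#' `nb_dispersion` (variance = mu + dispersion * mu^2). Constructs of
#' spiked targets have their delayed-fraction mean multiplied by a
#' per-construct fold: the configured target fold (the median) times a
#' lognormal guide-efficiency factor with log-sd `spike_cv`, drawn once per
#' construct and shared across replicates and timepoints — emulating
#' construct-to-construct cutting-efficiency spread, which is what makes
#' control DDE values reproducible between replicates.
#'
#' @param lib Library data.frame.
#' @param config A [sim_config()] (`depth`, `nb_dispersion`,
#'   `spike_targets`, `spike_cv`, `seed`).
#' @return List with `counts` (integer matrix constructs x samples, the
#'   truth table of the simulated screen) and `construct_truth`
#'   (data.frame: `construct_id`, `target_id`, `delayed_fold`).
#' @export
make_screen_counts <- function(lib, config = sim_config()) {
  samples <- screen_samples()
  with_seed(config$seed + 202L, {
    fold_c <- rep(1, nrow(lib))
    if (!is.null(config$spike_targets)) {
      spiked <- lib$target_id %in% config$spike_targets$target_id
      f <- config$spike_targets$fold[match(lib$target_id,
                                           config$spike_targets$target_id)]
      fold_c[spiked] <- f[spiked] *
        exp(rnorm(sum(spiked), mean = 0, sd = config$spike_cv))
    }
    fold <- matrix(1, nrow = nrow(lib), ncol = nrow(samples),
                   dimnames = list(lib$construct_id, samples$sample_id))
    fold[, samples$fraction == "delayed"] <- fold_c
    mu <- config$depth * fold
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
                     nrow = nrow(mu), dimnames = dimnames(mu))
    storage.mode(counts) <- "integer"
    list(counts = counts,
         construct_truth = data.frame(construct_id = lib$construct_id,
                                      target_id = lib$target_id,
                                      delayed_fold = fold_c,
                                      stringsAsFactors = FALSE))
  })
}

#' Fabricate a screen-scale library table with random guides
#'
#' Generates a library-contract table (construct ids, 21/20-nt guide
#' sequences, target ids, classes) from random distinct guide pairs,
#' without reference to a genome — the fast path for simulating large
#' screens where the designs' genomic provenance is irrelevant.
#'
#' @param config A [sim_config()] (only `seed` is used).
#' @param n_targets Number of screen targets (class `pc`).
#' @param designs_per_target Constructs per target.
#' @param n_positive,positive_designs Positive-control targets and designs
#'   each (class `positive_control`).
#' @param n_intergenic,intergenic_designs Intergenic negative-control
#'   regions and designs each (class `intergenic_control`).
#' @return A library data.frame compatible with [build_reference()],
#'   [make_screen_reads()] and the DDE caller.
#' @export
make_toy_library <- function(config = sim_config(), n_targets = 20L,
                             designs_per_target = 10L,
                             n_positive = 0L, positive_designs = 50L,
                             n_intergenic = 0L, intergenic_designs = 10L) {
  target_id <- c(
    rep(sprintf("TGT%03d", seq_len(n_targets)), each = designs_per_target),
    rep(sprintf("POS%02d", seq_len(n_positive)), each = positive_designs),
    rep(sprintf("IGR%03d", seq_len(n_intergenic)), each = intergenic_designs))
  class <- c(
    rep("pc", n_targets * designs_per_target),
    rep("positive_control", n_positive * positive_designs),
    rep("intergenic_control", n_intergenic * intergenic_designs))
  n <- length(target_id)
  with_seed(config$seed + 404L, {
    repeat {
      g1 <- random_dna(n, 20L)
      g2 <- random_dna(n, 20L)
      if (!anyDuplicated(paste0(g1, g2))) break
    }
    idx <- stats::ave(seq_len(n), target_id, FUN = seq_along)
    data.frame(construct_id = sprintf("%s_pg%02d", target_id, idx),
               target_id = target_id, class = class,
               guide1_seq = paste0("G", g1), guide2_seq = g2,
               stringsAsFactors = FALSE)
  })
}

# Vectorised per-base substitution errors: for reads with k > 0 error
# positions, apply them in rounds so `substr<-` stays vectorised.
apply_substitutions <- function(reads, error_rate) {
  if (error_rate <= 0 || !length(reads)) return(reads)
  lens <- nchar(reads)
  k <- rbinom(length(reads), lens, error_rate)
  hit <- which(k > 0L)
  if (!length(hit)) return(reads)
  pos <- lapply(hit, function(i) sample.int(lens[i], k[i]))
  maxk <- max(k)
  bases <- c("A", "C", "G", "T")
  for (round in seq_len(maxk)) {
    sel <- which(lengths(pos) >= round)
    idx <- hit[sel]
    p <- vapply(pos[sel], `[`, integer(1), round)
    old <- substr(reads[idx], p, p)
    # substitute with one of the three other bases, uniformly
    new <- vapply(old, function(b) sample(setdiff(bases, b), 1L), character(1),
                  USE.NAMES = FALSE)
    substr(reads[idx], p, p) <- new
  }
  reads
}

#' Simulate sorted-population screen reads
#'
#' Draws per-construct counts with [make_screen_counts()] and emits paired
#' reads for every sample: read 2 carries a random stagger prefix, a
#' vector-context segment, the `ACCG` anchor and the 21-nt guide-1 segment;
#' read 1 carries a longer context, the `AAAC` anchor and the
#' reverse-complemented 20-nt guide-2 protospacer. Substitution errors are
#' applied at `error_rate` per base. With `error_rate = 0` quantification
#' recovers the truth counts exactly.
#'
#' @param lib Library data.frame.
#' @param config A [sim_config()].
#' @return A list of class `pg_sim_reads`: `samples` (named list with
#'   `read1`, `read2`, `construct` per read), `counts` (truth matrix) and
#'   `sample_info`.
#' @export
make_screen_reads <- function(lib, config = sim_config()) {
  max_stag <- config$stagger_range[2]
  if (config$read_len_2 < max_stag + nchar(SIM_VEC2) + 4L ||
      config$read_len_1 < max_stag + nchar(SIM_VEC1) + 4L)
    stopf("read lengths too short to contain the anchor windows")
  cs <- make_screen_counts(lib, config)
  counts <- cs$counts
  info <- screen_samples()
  g1 <- lib$guide1_seq
  g2rc <- revcomp(lib$guide2_seq)
  samples <- with_seed(config$seed + 303L, {
    lapply(seq_len(nrow(info)), function(si) {
      nread <- counts[, si]
      total <- sum(nread)
      construct <- rep(lib$construct_id, nread)
      ci <- rep(seq_len(nrow(lib)), nread)
      stag <- sample(config$stagger_range[1]:config$stagger_range[2],
                     total, replace = TRUE)
      stag_seq <- substring(SIM_FILL, 1L, stag)
      r2 <- paste0(stag_seq, SIM_VEC2, "ACCG", g1[ci], SIM_FILL)
      stag1 <- sample(config$stagger_range[1]:config$stagger_range[2],
                      total, replace = TRUE)
      r1 <- paste0(substring(SIM_FILL, 1L, stag1), SIM_VEC1, "AAAC",
                   g2rc[ci], SIM_FILL)
      r2 <- substr(r2, 1L, config$read_len_2)
      r1 <- substr(r1, 1L, config$read_len_1)
      r1 <- apply_substitutions(r1, config$error_rate)
      r2 <- apply_substitutions(r2, config$error_rate)
      list(read1 = r1, read2 = r2, construct = construct)
    })
  })
  names(samples) <- info$sample_id
  structure(list(samples = samples, counts = counts,
                 construct_truth = cs$construct_truth, sample_info = info),
            class = "pg_sim_reads")
}

#' Write simulated reads as gzipped paired FASTQ plus truth tables
#'
#' Emits `<sample>_R1.fastq.gz` / `<sample>_R2.fastq.gz` per sample, a
#' `sample_sheet.tsv` pointing at them, a per-construct truth count matrix
#' and a per-read source-construct table.
#'
#' @param sim A [make_screen_reads()] result.
#' @param outdir Output directory (created if needed).
#' @return The sample sheet data.frame, invisibly.
#' @export
write_screen_fastq <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sheet <- sim$sample_info
  sheet$fastq1 <- file.path(outdir, paste0(sheet$sample_id, "_R1.fastq.gz"))
  sheet$fastq2 <- file.path(outdir, paste0(sheet$sample_id, "_R2.fastq.gz"))
  for (i in seq_len(nrow(sheet))) {
    s <- sim$samples[[sheet$sample_id[i]]]
    ids <- sprintf("%s_%06d", sheet$sample_id[i], seq_along(s$read1))
    write_fastq(ids, s$read1, sheet$fastq1[i])
    write_fastq(ids, s$read2, sheet$fastq2[i])
    write.table(data.frame(read_id = ids, construct_id = s$construct),
                file.path(outdir, paste0(sheet$sample_id[i], "_truth.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_counts(sim$counts, file.path(outdir, "counts_truth.tsv"))
  sheet_path <- file.path(outdir, "sample_sheet.tsv")
  write.table(sheet, sheet_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(sheet)
}

write_fastq <- function(ids, seqs, path) {
  con <- gzfile(path, "w")
  on.exit(close(con))
  qual <- vapply(nchar(seqs), function(l) strrep("I", l), character(1))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), con)
  invisible(path)
}
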