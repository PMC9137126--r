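# Independent brute-force oracles, deliberately written as naive loops so
# they share no code path with the package implementations they check.

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(x, function(s) {
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Every 20-mer + NGG, both strands, by checking each offset explicitly.
oracle_protospacers <- function(s, region_start = 0L) {
  s <- toupper(s)
  n <- nchar(s)
  rows <- list()
  for (i in seq_len(n - 22L)) {
    w <- substr(s, i, i + 22L)
    if (grepl("[^ACGT]", w)) next
    if (substr(w, 22L, 23L) == "GG") {
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = substr(w, 1L, 20L), strand = "+",
        start = region_start + i - 1L,
        cut_site = region_start + i - 1L + 17L, stringsAsFactors = FALSE)
    }
    if (substr(w, 1L, 2L) == "CC") {
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = oracle_revcomp(substr(w, 4L, 23L)), strand = "-",
        start = region_start + i + 2L,
        cut_site = region_start + i + 2L + 3L, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(sequence = character(),
                                      strand = character(), start = integer(),
                                      cut_site = integer()))
  out[order(out$cut_site, out$strand, out$start), , drop = FALSE]
}

oracle_hamming <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  sum(x != head(y, length(x)))
}

# Off-target counts of a query against a genome, scanning every position.
oracle_offtarget_counts <- function(query, genome_seq, exclude = NULL) {
  sites <- oracle_protospacers(genome_seq)
  counts <- integer(5)
  for (i in seq_len(nrow(sites))) {
    if (!is.null(exclude) &&
        sites$strand[i] == exclude$strand && sites$start[i] == exclude$start)
      next
    d <- oracle_hamming(query, sites$sequence[i])
    if (d <= 4L) counts[d + 1L] <- counts[d + 1L] + 1L
  }
  names(counts) <- paste0("d", 0:4)
  counts
}

# Ranking oracle: selection sort with an explicit pairwise comparator.
oracle_rank_pairs <- function(pairs) {
  before <- function(i, j) {
    if (pairs$orf_pos[i] != pairs$orf_pos[j])
      return(pairs$orf_pos[i] < pairs$orf_pos[j])
    if (pairs$pair_score[i] != pairs$pair_score[j])
      return(pairs$pair_score[i] > pairs$pair_score[j])
    fi <- pairs$frame_status[i] == "in_frame"
    fj <- pairs$frame_status[j] == "in_frame"
    if (fi != fj) return(!fi)
    if (pairs$g1_start[i] != pairs$g1_start[j])
      return(pairs$g1_start[i] < pairs$g1_start[j])
    pairs$g2_start[i] < pairs$g2_start[j]
  }
  idx <- seq_len(nrow(pairs))
  out <- integer(0)
  while (length(idx)) {
    best <- idx[1]
    for (k in idx[-1]) if (before(k, best)) best <- k
    out <- c(out, best)
    idx <- setdiff(idx, best)
  }
  pairs[out, , drop = FALSE]
}

# Assignment oracle: per-read loop over every reference record.
oracle_assign <- function(fused, ref_ids, ref_seqs, max_mm) {
  t(vapply(fused, function(q) {
    d <- vapply(ref_seqs, function(r) oracle_hamming(q, r), numeric(1))
    dmin <- min(d)
    if (dmin > max_mm) return(c(NA_character_, "unmapped"))
    if (sum(d == dmin) > 1L) return(c(NA_character_, "multimapped"))
    c(ref_ids[which.min(d)], "assigned")
  }, character(2), USE.NAMES = FALSE))
}

# Linear-interpolation percentile oracle (order statistics by hand).
oracle_percentile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}
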