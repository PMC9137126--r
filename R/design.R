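#' Default DECKO-style insert-1 template
#'
#' Fixed 5' arm, central cloning-site segment and 3' arm whose lengths plus
#' the two 20-nt protospacers total 165 nt. The arms and cloning segment
#' are synthetic placeholder sequences (structurally faithful: the cloning
#' segment carries unique EcoRI/BamHI sites used to counter-select empty
#' backbone during library cloning); only the geometry is contractual.
#'
#' @param total Declared total oligo length (165 by default).
#' @return List with `arm5`, `cloning_site`, `arm3`, `total`.
#' @export
insert1_template <- function(total = 165L) {
  list(
    arm5 = "TATCTTGTGGAAAGGACGAAACACCGGTCTCTAC",                  # 34 nt
    cloning_site = paste0("GTTTAAGAGCGAATTCAAGTTAAAATAAGGCT",     # 57 nt
                          "GGATCCGTCGACTAGGGTGCTTCGG"),
    arm3 = "GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGG",                  # 34 nt
    total = as.integer(total)
  )
}

#' Emit the cloning oligo (insert-1) for a guide pair
#'
#' `oligo = arm5 + protospacer1 + cloning_site + protospacer2 + arm3`; with
#' the default template and two 20-nt protospacers the oligo is exactly
#' 165 nt. Both protospacers are recoverable from the oligo by template
#' coordinates ([parse_insert1()]).
#'
#' @param protospacer1,protospacer2 20-nt protospacer sequences.
#' @param template An [insert1_template()].
#' @return The oligo sequence (character).
#' @export
emit_insert1 <- function(protospacer1, protospacer2,
                         template = insert1_template()) {
  fixed <- nchar(template$arm5) + nchar(template$cloning_site) +
    nchar(template$arm3)
  if (fixed + 40L != template$total)
    stopf("template fixed segments (%d nt) + 40 nt of protospacers != declared total %d",
          fixed, template$total)
  if (any(nchar(c(protospacer1, protospacer2)) != 20L))
    stopf("protospacers must be 20 nt")
  paste0(template$arm5, protospacer1, template$cloning_site,
         protospacer2, template$arm3)
}

#' @rdname emit_insert1
#' @param oligo An emitted insert-1 oligo.
#' @return `parse_insert1` returns `list(protospacer1, protospacer2)`.
#' @export
parse_insert1 <- function(oligo, template = insert1_template()) {
  a5 <- nchar(template$arm5); cs <- nchar(template$cloning_site)
  list(protospacer1 = substr(oligo, a5 + 1L, a5 + 20L),
       protospacer2 = substr(oligo, a5 + 20L + cs + 1L, a5 + 20L + cs + 20L))
}

# Map a genomic cut-site coordinate to its position in the spliced ORF
# (0-based offset from the start codon), used for pair ranking. Sites
# outside the CDS map to NA.
orf_position <- function(cut_site, exons) {
  cds <- exons[!is.na(exons$cds_start), , drop = FALSE]
  cds <- cds[order(cds$exon_number), , drop = FALSE]
  cum <- cumsum(c(0L, cds$cds_end - cds$cds_start))
  vapply(cut_site, function(x) {
    for (i in seq_len(nrow(cds))) {
      if (x >= cds$cds_start[i] && x <= cds$cds_end[i]) {
        off <- if (cds$strand[i] == "+") x - cds$cds_start[i]
               else cds$cds_end[i] - x
        return(cum[i] + off)
      }
    }
    NA_integer_
  }, integer(1))
}

#' Enumerate and rank candidate guide pairs
#'
#' Candidate pairs are all combinations of two scored protospacers with
#' `cut_site1 < cut_site2`. The sort key is: (1) position of the deletion
#' start in the ORF (earlier first; genomic position when no ORF mapping is
#' given), (2) pair score = sum of the two guide scores (higher first),
#' (3) predicted out-of-frame deletions before in-frame ones, then a
#' deterministic tie-break on (guide1 start, guide2 start). The sort is
#' stable, so the ranking is a total order.
#'
#' @param ps Scored protospacer table ([score_protospacer()]).
#' @param exons Optional exon table with CDS columns: enables ORF-position
#'   ranking and frame-status calls (`class = "pc"`).
#' @param class Construct class recorded on the pairs (`frame_status` is
#'   `"n/a"` unless `class == "pc"`).
#' @return data.frame of ranked pairs (best first) with guide columns
#'   prefixed `g1_`/`g2_`, plus `deletion_start`, `deletion_end`,
#'   `deletion_len`, `frame_status`, `pair_score`, `orf_pos`.
#' @export
rank_pairs <- function(ps, exons = NULL, class = "pc") {
  if (nrow(ps) < 2L) return(empty_pairs())
  idx <- which(upper.tri(matrix(TRUE, nrow(ps), nrow(ps))), arr.ind = TRUE)
  # order each combination by cut site
  a <- idx[, "row"]; b <- idx[, "col"]
  swap <- ps$cut_site[a] > ps$cut_site[b]
  i1 <- ifelse(swap, b, a); i2 <- ifelse(swap, a, b)
  keep <- ps$cut_site[i1] < ps$cut_site[i2]   # identical cut sites: no deletion
  i1 <- i1[keep]; i2 <- i2[keep]
  if (!length(i1)) return(empty_pairs())
  g1 <- ps[i1, , drop = FALSE]; g2 <- ps[i2, , drop = FALSE]
  del_len <- g2$cut_site - g1$cut_site
  frame <- if (class == "pc") {
    ifelse(del_len %% 3L != 0L, "out_of_frame", "in_frame")
  } else "n/a"
  orf_pos <- if (!is.null(exons) && class == "pc") {
    pmin(orf_position(g1$cut_site, exons), orf_position(g2$cut_site, exons))
  } else g1$cut_site
  pairs <- data.frame(
    g1_seq = g1$sequence, g1_strand = g1$strand, g1_start = g1$start,
    g1_cut = g1$cut_site, g1_score = g1$score,
    g2_seq = g2$sequence, g2_strand = g2$strand, g2_start = g2$start,
    g2_cut = g2$cut_site, g2_score = g2$score,
    chrom = g1$chrom,
    deletion_start = g1$cut_site, deletion_end = g2$cut_site,
    deletion_len = del_len, frame_status = frame,
    pair_score = g1$score + g2$score, orf_pos = orf_pos,
    stringsAsFactors = FALSE)
  frame_rank <- ifelse(pairs$frame_status == "in_frame", 1L, 0L)
  ord <- order(pairs$orf_pos, -pairs$pair_score, frame_rank,
               pairs$g1_start, pairs$g2_start, method = "radix")
  pairs <- pairs[ord, , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

empty_pairs <- function() {
  data.frame(g1_seq = character(), g1_strand = character(),
             g1_start = integer(), g1_cut = integer(), g1_score = numeric(),
             g2_seq = character(), g2_strand = character(),
             g2_start = integer(), g2_cut = integer(), g2_score = numeric(),
             chrom = character(), deletion_start = integer(),
             deletion_end = integer(), deletion_len = integer(),
             frame_status = character(), pair_score = numeric(),
             orf_pos = integer(), stringsAsFactors = FALSE)
}

# Greedy selection of ranked pairs under the minimum-separation rules.
# `across`: every two cut sites among the accepted designs must differ by
# >= min_sep (prevents redundant designs); `within`: the two cuts of one
# pair must be >= min_sep apart. Both rules are on by default.
accept_pairs <- function(pairs, n, min_sep = 50L, accepted = NULL,
                         enforce_across = TRUE, enforce_within = TRUE) {
  taken <- accepted
  cuts <- if (!is.null(taken) && nrow(taken)) c(taken$g1_cut, taken$g2_cut)
          else integer(0)
  for (i in seq_len(nrow(pairs))) {
    if (!is.null(taken) && nrow(taken) >= n) break
    p <- pairs[i, ]
    if (enforce_within && p$deletion_len < min_sep) next
    if (!is.null(taken) && nrow(taken) &&
        any(taken$g1_cut == p$g1_cut & taken$g2_cut == p$g2_cut)) next
    if (enforce_across && length(cuts) &&
        (min(abs(cuts - p$g1_cut)) < min_sep ||
         min(abs(cuts - p$g2_cut)) < min_sep)) next
    taken <- rbind(taken, p)
    cuts <- c(cuts, p$g1_cut, p$g2_cut)
  }
  taken
}

#' Design paired-guide deletion constructs for a coding gene
#'
#' Enumerates, scores and off-target-filters protospacers in the first
#' coding exon, then greedily accepts ranked pairs under the 50-bp
#' minimum-separation rules; if fewer than `n` designs fit, the search
#' window is extended to the second and then third coding exons (already
#' accepted designs are kept).
#'
#' @param gene One row of a gene-model `genes` table.
#' @param exons The gene's exon table (transcription-ordered, CDS columns).
#' @param genome Named character vector of chromosome sequences.
#' @param ot_index An [offtarget_index()] of the genome.
#' @param n Maximum designs per target (10, the screen's per-target cap).
#' @param min_sep Minimum guide separation in bp.
#' @param thresholds Off-target thresholds (see [count_offtargets()]).
#' @param scorer On-target scorer.
#' @param enforce_across,enforce_within Which readings of the 50-bp rule to
#'   enforce (see [accept_pairs()] internals; both by default).
#' @return data.frame of up to `n` designs with `rank`, `target_id`,
#'   `class`, guide/deletion columns and `insert1`. Zero rows (with a
#'   warning) if no protospacer survives filtering.
#' @export
design_pc_target <- function(gene, exons, genome, ot_index, n = 10L,
                             min_sep = 50L,
                             thresholds = c(0, 0, 0, Inf, Inf),
                             scorer = surrogate_scorer,
                             enforce_across = TRUE, enforce_within = TRUE) {
  ex <- exons[exons$gene_id == gene$gene_id & !is.na(exons$cds_start), ,
              drop = FALSE]
  ex <- ex[order(ex$exon_number), , drop = FALSE]
  chrom_seq <- genome[[gene$chrom]]
  accepted <- NULL
  for (stage in seq_len(min(3L, nrow(ex)))) {
    if (!is.null(accepted) && nrow(accepted) >= n) break
    cand <- do.call(rbind, lapply(seq_len(stage), function(j) {
      exon_protospacers(chrom_seq, ex[j, ], gene$chrom)
    }))
    if (is.null(cand) || nrow(cand) < 2L) next
    cand <- score_protospacer(cand, scorer)
    cand <- cand[offtarget_pass(cand, ot_index, thresholds), , drop = FALSE]
    if (nrow(cand) < 2L) next
    pairs <- rank_pairs(cand, exons = ex, class = "pc")
    accepted <- accept_pairs(pairs, n, min_sep, accepted,
                             enforce_across, enforce_within)
  }
  finish_designs(accepted, gene$gene_id, "pc", n)
}

# Protospacers fully contained (incl. PAM) in one exon's CDS span.
exon_protospacers <- function(chrom_seq, exon, chrom) {
  lo <- exon$cds_start; hi <- exon$cds_end
  if (hi - lo < 23L) return(NULL)
  ps <- enumerate_protospacers(substr(chrom_seq, lo + 1L, hi), lo, chrom)
  ps
}

#' Design TSS-deletion constructs for a lncRNA
#'
#' Pairs must straddle the TSS (`guide1 cut < TSS < guide2 cut`). The
#' symmetric window around the TSS grows through total widths 500, 1000,
#' 2000, 3000, 4000, 5000 bp until `n` designs are found; off-target
#' thresholds relax one step per expansion (the allowance at Hamming
#' distance 2 grows by one per step). Candidate guides overlapping any
#' protein-coding gene body are discarded.
#'
#' @inheritParams design_pc_target
#' @param pc_genes `genes` table rows of protein-coding genes (exclusion
#'   zones).
#' @param window_steps Total window widths (bp) tried in order.
#' @return data.frame of up to `n` designs; fewer (with a warning) if the
#'   5,000-bp window cannot supply them.
#' @export
design_lnc_target <- function(gene, genome, ot_index, pc_genes = NULL,
                              n = 10L, min_sep = 50L,
                              window_steps = c(500, 1000, 2000, 3000, 4000, 5000),
                              thresholds = c(0, 0, 0, Inf, Inf),
                              scorer = surrogate_scorer,
                              enforce_across = TRUE, enforce_within = TRUE) {
  chrom_seq <- genome[[gene$chrom]]
  tss <- gene$tss
  accepted <- NULL
  for (step in seq_along(window_steps)) {
    if (!is.null(accepted) && nrow(accepted) >= n) break
    half <- window_steps[step] / 2
    lo <- max(0L, as.integer(tss - half))
    hi <- min(nchar(chrom_seq), as.integer(tss + half))
    thr <- thresholds
    thr[3] <- thresholds[3] + (step - 1L)   # relax distance-2 allowance
    cand <- enumerate_protospacers(substr(chrom_seq, lo + 1L, hi), lo,
                                   gene$chrom)
    if (!is.null(pc_genes) && nrow(pc_genes) && nrow(cand)) {
      bad <- vapply(seq_len(nrow(cand)), function(i) {
        any(pc_genes$chrom == cand$chrom[i] &
            pc_genes$start < cand$start[i] + 23L &
            pc_genes$end > cand$start[i])
      }, logical(1))
      cand <- cand[!bad, , drop = FALSE]
    }
    if (nrow(cand) < 2L) next
    cand <- score_protospacer(cand, scorer)
    cand <- cand[offtarget_pass(cand, ot_index, thr), , drop = FALSE]
    if (nrow(cand) < 2L) next
    pairs <- rank_pairs(cand, class = "lnc")
    pairs <- pairs[pairs$g1_cut < tss & pairs$g2_cut > tss, , drop = FALSE]
    accepted <- accept_pairs(pairs, n, min_sep, accepted,
                             enforce_across, enforce_within)
  }
  if (is.null(accepted) || nrow(accepted) < n)
    warnf("target %s: only %d/%d designs found within the 5 kb window",
          gene$gene_id, if (is.null(accepted)) 0L else nrow(accepted), n)
  finish_designs(accepted, gene$gene_id, "lnc", n)
}

# Attach target metadata, ranks, 21-nt guide-1 (leading transcription G)
# and the insert-1 oligo to accepted pairs.
finish_designs <- function(accepted, target_id, class, n) {
  if (is.null(accepted) || !nrow(accepted)) {
    if (class %in% c("pc", "lnc"))
      warnf("target %s: no passing protospacer pair", target_id)
    out <- empty_pairs()
    out$target_id <- character(0); out$class <- character(0)
    out$rank <- integer(0); out$construct_id <- character(0)
    out$guide1_seq <- character(0); out$guide2_seq <- character(0)
    out$insert1 <- character(0)
    return(out)
  }
  accepted <- utils::head(accepted, n)
  accepted$target_id <- target_id
  accepted$class <- class
  accepted$rank <- seq_len(nrow(accepted))
  accepted$construct_id <- sprintf("%s_pg%02d", target_id, accepted$rank)
  accepted$guide1_seq <- paste0("G", accepted$g1_seq)   # 21 nt, leading G
  accepted$guide2_seq <- accepted$g2_seq                # 20 nt
  accepted$insert1 <- mapply(emit_insert1, accepted$g1_seq, accepted$g2_seq,
                             USE.NAMES = FALSE)
  rownames(accepted) <- NULL
  accepted
}
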