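#' Control specification for library construction
#'
#' @param positive data.frame (`gene_id`, `n_designs`): protein-coding
#'   genes used as positive controls and the number of designs each (the
#'   screen used 50 designs per positive-control gene).
#' @param n_intergenic Number of intergenic negative-control regions (100
#'   in the screen, 10 designs each).
#' @param intergenic_designs Designs per intergenic region.
#' @param intergenic_len Length (bp) of each sampled intergenic region.
#' @return A list of class `control_spec`.
#' @export
control_spec <- function(positive = NULL, n_intergenic = 0L,
                         intergenic_designs = 10L, intergenic_len = 1000L) {
  structure(list(positive = positive,
                 n_intergenic = as.integer(n_intergenic),
                 intergenic_designs = as.integer(intergenic_designs),
                 intergenic_len = as.integer(intergenic_len)),
            class = "control_spec")
}

# Sample annotation-free regions >= 1 kb away from every gene body.
sample_intergenic_regions <- function(models, genome_len, n, region_len,
                                      margin = 1000L) {
  genes <- models$genes
  free <- rep(TRUE, genome_len)
  for (i in seq_len(nrow(genes))) {
    lo <- max(1L, genes$start[i] - margin + 1L)
    hi <- min(genome_len, genes$end[i] + margin)
    free[lo:hi] <- FALSE
  }
  # maximal free runs able to host a region
  r <- rle(free)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  runs <- runs[runs$end - runs$start + 1L >= region_len, , drop = FALSE]
  out <- list()
  for (k in seq_len(n)) {
    if (!nrow(runs)) break
    j <- sample(nrow(runs), 1L)
    s <- sample(runs$start[j]:(runs$end[j] - region_len + 1L), 1L)
    out[[k]] <- data.frame(start = s - 1L, end = s - 1L + region_len)  # 0-based
    # split the run so sampled regions do not overlap
    left <- data.frame(start = runs$start[j], end = s - 1L)
    right <- data.frame(start = s + region_len, end = runs$end[j])
    runs <- rbind(runs[-j, , drop = FALSE],
                  left[left$end - left$start + 1L >= region_len, , drop = FALSE],
                  right[right$end - right$start + 1L >= region_len, , drop = FALSE])
  }
  if (length(out) < n)
    warnf("only %d of %d intergenic regions could be placed", length(out), n)
  do.call(rbind, out)
}

# Paired designs inside one intergenic region: ranked by pair score alone,
# deletion confined to the region.
design_intergenic_region <- function(region_id, region, genome, ot_index,
                                     n = 10L, min_sep = 50L,
                                     thresholds = c(0, 0, 0, Inf, Inf),
                                     scorer = surrogate_scorer, chrom = "chr1") {
  chrom_seq <- genome[[chrom]]
  cand <- enumerate_protospacers(substr(chrom_seq, region$start + 1L,
                                        region$end), region$start, chrom)
  if (nrow(cand) >= 2L) {
    cand <- score_protospacer(cand, scorer)
    cand <- cand[offtarget_pass(cand, ot_index, thresholds), , drop = FALSE]
  }
  if (nrow(cand) < 2L) return(finish_designs(NULL, region_id, "intergenic_control", n))
  pairs <- rank_pairs(cand, class = "intergenic_control")
  pairs <- pairs[order(-pairs$pair_score, pairs$g1_start, pairs$g2_start), ,
                 drop = FALSE]
  finish_designs(accept_pairs(pairs, n, min_sep), region_id,
                 "intergenic_control", n)
}

#' Build the full paired-guide construct library
#'
#' Concatenates target designs (coding genes via [design_pc_target()],
#' lncRNAs via [design_lnc_target()]) with positive-control designs (extra
#' designs on designated coding genes) and seeded intergenic
#' negative-control designs sampled from annotation-free stretches >= 1 kb
#' from any gene.
#'
#' @param targets data.frame (`gene_id`, `biotype`) of screen targets; ids
#'   must exist in `models`.
#' @param models Gene-model list.
#' @param genome Named character vector of chromosome sequences.
#' @param controls A [control_spec()].
#' @param n_designs Designs per (non-positive-control) target.
#' @param min_sep Minimum guide separation (bp).
#' @param thresholds Off-target thresholds for the first design pass.
#' @param scorer On-target scorer.
#' @param seed Seed for intergenic-region sampling.
#' @return A library data.frame (one row per construct) of class
#'   `pg_library`, with unique `construct_id`s and a `params` attribute.
#' @export
build_library <- function(targets, models, genome, controls = control_spec(),
                          n_designs = 10L, min_sep = 50L,
                          thresholds = c(0, 0, 0, Inf, Inf),
                          scorer = surrogate_scorer, seed = 1L) {
  ot_index <- offtarget_index(genome)
  genes <- models$genes
  pc_genes <- genes[genes$biotype == "protein_coding", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(targets))) {
    g <- genes[genes$gene_id == targets$gene_id[i], , drop = FALSE]
    if (!nrow(g)) stopf("target %s not in the gene models", targets$gene_id[i])
    d <- if (g$biotype == "protein_coding") {
      design_pc_target(g, models$exons, genome, ot_index, n = n_designs,
                       min_sep = min_sep, thresholds = thresholds,
                       scorer = scorer)
    } else {
      design_lnc_target(g, genome, ot_index, pc_genes = pc_genes,
                        n = n_designs, min_sep = min_sep,
                        thresholds = thresholds, scorer = scorer)
    }
    rows[[length(rows) + 1L]] <- d
  }
  if (!is.null(controls$positive)) {
    for (i in seq_len(nrow(controls$positive))) {
      g <- genes[genes$gene_id == controls$positive$gene_id[i], , drop = FALSE]
      if (!nrow(g)) stopf("positive control %s not in the gene models",
                          controls$positive$gene_id[i])
      d <- design_pc_target(g, models$exons, genome, ot_index,
                            n = controls$positive$n_designs[i],
                            min_sep = min_sep, thresholds = thresholds,
                            scorer = scorer)
      d$class <- "positive_control"
      d$construct_id <- sprintf("pos_%s_pg%02d", g$gene_id, d$rank)
      d$target_id <- paste0("pos_", g$gene_id)
      rows[[length(rows) + 1L]] <- d
    }
  }
  if (controls$n_intergenic > 0L) {
    regions <- with_seed(seed, {
      sample_intergenic_regions(models, nchar(genome[[1]]),
                                controls$n_intergenic, controls$intergenic_len)
    })
    for (i in seq_len(nrow(regions))) {
      rows[[length(rows) + 1L]] <- design_intergenic_region(
        sprintf("IGR%03d", i), regions[i, ], genome, ot_index,
        n = controls$intergenic_designs, min_sep = min_sep,
        thresholds = thresholds, scorer = scorer)
    }
  }
  lib <- do.call(rbind, rows)
  if (anyDuplicated(lib$construct_id))
    stopf("construct ids are not unique")
  rownames(lib) <- NULL
  attr(lib, "params") <- list(n_designs = n_designs, min_sep = min_sep,
                              thresholds = thresholds, seed = seed)
  class(lib) <- c("pg_library", class(lib))
  lib
}

#' Read / write a library design table
#'
#' TSV columns mirror the design output: construct id, target, class, both
#' guide sequences (21/20 nt), coordinates, deletion geometry, frame
#' status, pair score, rank and the 165-nt insert-1 oligo.
#'
#' @param lib Library data.frame.
#' @param path File path.
#' @return `read_library` returns the data.frame; writers return the path,
#'   invisibly.
#' @export
write_library <- function(lib, path) {
  cols <- c("construct_id", "target_id", "class", "guide1_seq", "guide2_seq",
            "chrom", "g1_strand", "g2_strand", "g1_cut", "g2_cut",
            "deletion_len", "frame_status", "pair_score", "rank", "insert1")
  write.table(lib[, cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  lib <- read.delim(path, stringsAsFactors = FALSE)
  class(lib) <- c("pg_library", class(lib))
  lib
}

#' @rdname write_library
#' @export
write_oligo_fasta <- function(lib, path) {
  seqs <- Biostrings::DNAStringSet(lib$insert1)
  names(seqs) <- lib$construct_id
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
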