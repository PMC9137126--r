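#' Generate a toy genome and gene annotation
#'
#' Builds a random single-chromosome genome carrying multi-exon
#' protein-coding gene models (with CDS whose length is a multiple of 3),
#' single-exon lncRNA models, and annotation-free intergenic stretches of at
#' least 1 kb. Genes are spaced so that every lncRNA TSS is isolated (no
#' other gene body within 5 kb on the same strand or 50 bp on the opposite
#' strand), mirroring GENCODE-style input. Coordinates are 0-based
#' half-open internally.
#'
#' @param config A [sim_config()].
#' @return A list with `genome` (a named character vector of chromosome
#'   sequences) and `models` (a gene-model list with `genes` and `exons`
#'   data frames, see Details).
#'
#' @details `models$genes` has columns `gene_id`, `biotype`
#'   (`protein_coding`/`lncRNA`), `chrom`, `strand`, `start`, `end`, `tss`
#'   (0-based position of the first transcribed base). `models$exons` adds
#'   per-exon rows with `exon_number` (in transcription order), `start`,
#'   `end` and, for coding exons, `cds_start`/`cds_end` (NA otherwise).
#' @export
make_toy_annotation <- function(config = sim_config()) {
  if (config$genome_length < 10000L)
    stopf("genome_length must be at least 10 kb")
  n_pc <- config$n_pc_genes
  n_lnc <- config$n_lnc_genes
  # footprint per gene slot: gene body (<= 2 kb) + 10 kb isolation gap
  slot <- 12000L
  needed <- (n_pc + n_lnc) * slot + 2000L
  if (config$genome_length < needed)
    stopf("genome of %d bp cannot place %d genes (needs >= %d bp)",
          config$genome_length, n_pc + n_lnc, needed)
  with_seed(config$seed, {
    genome <- c(chr1 = random_dna(1, config$genome_length))
    ids <- c(sprintf("PCG%02d", seq_len(n_pc)), sprintf("LNC%02d", seq_len(n_lnc)))
    biotypes <- c(rep("protein_coding", n_pc), rep("lncRNA", n_lnc))
    ord <- sample(length(ids))           # interleave biotypes along the genome
    strands <- rep_len(c("+", "-"), length(ids))
    genes <- list(); exons <- list()
    pos <- 1500L                          # leave a >= 1 kb intergenic margin
    for (k in seq_along(ord)) {
      i <- ord[k]
      if (biotypes[i] == "protein_coding") {
        m <- place_pc_gene(ids[i], pos, strands[k])
      } else {
        m <- place_lnc_gene(ids[i], pos, strands[k])
      }
      genes[[k]] <- m$gene
      exons[[k]] <- m$exons
      pos <- pos + slot
    }
    genes <- do.call(rbind, genes)
    exons <- do.call(rbind, exons)
    models <- list(genes = genes[order(genes$start), , drop = FALSE],
                   exons = exons[order(exons$start), , drop = FALSE])
    rownames(models$genes) <- NULL
    rownames(models$exons) <- NULL
    list(genome = genome, models = models)
  })
}

# Three-exon coding gene: 50 nt 5'UTR, CDS across all exons (length % 3 == 0),
# 3'UTR absorbing the frame remainder. 0-based half-open coordinates.
place_pc_gene <- function(gene_id, start, strand) {
  ex_len <- c(400L, 320L, 420L)
  intron <- 420L
  s1 <- start
  s2 <- s1 + ex_len[1] + intron
  s3 <- s2 + ex_len[2] + intron
  ex_start <- c(s1, s2, s3)
  ex_end <- ex_start + ex_len
  utr5 <- 50L
  coding <- sum(ex_len) - utr5         # provisional, trim 3' end to frame
  utr3 <- 40L + (coding - 40L) %% 3L   # CDS length becomes a multiple of 3
  if (strand == "+") {
    cds_start <- c(s1 + utr5, s2, s3)
    cds_end <- c(ex_end[1], ex_end[2], ex_end[3] - utr3)
    exon_number <- 1:3
    tss <- s1
  } else {
    cds_start <- c(s1 + utr3, s2, s3)
    cds_end <- c(ex_end[1], ex_end[2], ex_end[3] - utr5)
    exon_number <- 3:1                 # transcription order runs right-to-left
    tss <- ex_end[3] - 1L
  }
  gene <- data.frame(gene_id = gene_id, biotype = "protein_coding",
                     chrom = "chr1", strand = strand,
                     start = s1, end = ex_end[3], tss = tss,
                     stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = gene_id, chrom = "chr1", strand = strand,
                      exon_number = exon_number,
                      start = ex_start, end = ex_end,
                      cds_start = cds_start, cds_end = cds_end,
                      stringsAsFactors = FALSE)
  list(gene = gene, exons = exons[order(exons$exon_number), , drop = FALSE])
}

place_lnc_gene <- function(gene_id, start, strand) {
  len <- 700L
  tss <- if (strand == "+") start else start + len - 1L
  gene <- data.frame(gene_id = gene_id, biotype = "lncRNA",
                     chrom = "chr1", strand = strand,
                     start = start, end = start + len, tss = tss,
                     stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = gene_id, chrom = "chr1", strand = strand,
                      exon_number = 1L, start = start, end = start + len,
                      cds_start = NA_integer_, cds_end = NA_integer_,
                      stringsAsFactors = FALSE)
  list(gene = gene, exons = exons)
}

#' Write a toy genome and annotation to FASTA / GTF
#'
#' GTF output is 1-based inclusive (converted from the 0-based half-open
#' internal representation) and carries `gene`, `exon` and `CDS` features.
#'
#' @param annotation Result of [make_toy_annotation()].
#' @param fasta,gtf Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_annotation <- function(annotation, fasta, gtf) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(annotation$genome), fasta)
  models <- annotation$models
  gr <- c(
    GenomicRanges::GRanges(models$genes$chrom,
      IRanges::IRanges(models$genes$start + 1L, models$genes$end),
      strand = models$genes$strand, type = "gene",
      gene_id = models$genes$gene_id, gene_biotype = models$genes$biotype),
    GenomicRanges::GRanges(models$exons$chrom,
      IRanges::IRanges(models$exons$start + 1L, models$exons$end),
      strand = models$exons$strand, type = "exon",
      gene_id = models$exons$gene_id,
      gene_biotype = models$genes$biotype[match(models$exons$gene_id,
                                                models$genes$gene_id)])
  )
  cds <- models$exons[!is.na(models$exons$cds_start), , drop = FALSE]
  if (nrow(cds)) {
    cds <- cds[order(cds$gene_id, cds$exon_number), , drop = FALSE]
    seg_len <- cds$cds_end - cds$cds_start
    before <- stats::ave(seg_len, cds$gene_id,
                         FUN = function(x) cumsum(c(0L, x))[seq_along(x)])
    cds_gr <- GenomicRanges::GRanges(cds$chrom,
      IRanges::IRanges(cds$cds_start + 1L, cds$cds_end),
      strand = cds$strand, type = "CDS",
      gene_id = cds$gene_id, gene_biotype = "protein_coding")
    cds_gr$phase <- as.integer((3L - before %% 3L) %% 3L)
    gr <- c(gr, cds_gr)
  }
  rtracklayer::export(gr, gtf, format = "gtf")
  invisible(c(fasta = fasta, gtf = gtf))
}

#' Read gene models from a GTF file
#'
#' Inverse of [write_annotation()]: imports `gene`/`exon`/`CDS` features and
#' rebuilds the internal 0-based half-open gene-model representation.
#'
#' @param gtf Path to a GTF file.
#' @return A gene-model list (`genes` + `exons` data frames).
#' @export
read_gene_models <- function(gtf) {
  gr <- rtracklayer::import(gtf, format = "gtf")
  df <- as.data.frame(gr)
  g <- df[df$type == "gene", , drop = FALSE]
  genes <- data.frame(gene_id = g$gene_id, biotype = g$gene_biotype,
                      chrom = as.character(g$seqnames),
                      strand = as.character(g$strand),
                      start = g$start - 1L, end = g$end,
                      stringsAsFactors = FALSE)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  e <- df[df$type == "exon", , drop = FALSE]
  cds <- df[df$type == "CDS", , drop = FALSE]
  exons <- data.frame(gene_id = e$gene_id, chrom = as.character(e$seqnames),
                      strand = as.character(e$strand),
                      start = e$start - 1L, end = e$end,
                      stringsAsFactors = FALSE)
  # match CDS segments to their containing exon
  exons$cds_start <- NA_integer_; exons$cds_end <- NA_integer_
  if (nrow(cds)) {
    for (i in seq_len(nrow(cds))) {
      j <- which(exons$gene_id == cds$gene_id[i] &
                 exons$start <= cds$start[i] - 1L & exons$end >= cds$end[i])
      if (length(j)) {
        exons$cds_start[j[1]] <- cds$start[i] - 1L
        exons$cds_end[j[1]] <- cds$end[i]
      }
    }
  }
  # transcription-order exon numbers
  exons <- do.call(rbind, lapply(split(exons, exons$gene_id), function(ee) {
    ord <- order(ee$start)
    if (ee$strand[1] == "-") ord <- rev(ord)
    ee <- ee[ord, , drop = FALSE]
    ee$exon_number <- seq_len(nrow(ee))
    ee
  }))
  rownames(exons) <- NULL
  genes <- genes[order(genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  list(genes = genes, exons = exons)
}
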