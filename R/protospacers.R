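#' Enumerate Cas9 protospacers (20-mer + NGG) in a sequence
#'
#' Finds every position, on the requested strands, where a 20-nt protospacer
#' is immediately followed by an NGG PAM. The cut site is placed between
#' protospacer positions 17 and 18 (3 bp 5' of the PAM), the universal
#' SpCas9 blunt-cut convention. Coordinates are 0-based: `start` is the
#' first protospacer base on the forward strand; `cut_site` is the boundary
#' coordinate (number of forward-strand bases to its left).
#'
#' @param seq A single DNA sequence (character or `DNAString`).
#' @param region_start 0-based genomic offset of `seq`'s first base, added
#'   to all reported coordinates.
#' @param chrom Chromosome name recorded in the output.
#' @param strand_policy `"both"`, `"+"` or `"-"`.
#' @return data.frame sorted by `cut_site`: `chrom`, `sequence` (20 nt, the
#'   protospacer as read 5'->3' on its own strand), `strand`, `start`,
#'   `pam`, `cut_site`, `context` (30-nt scoring context, NA-padded with `N`
#'   near sequence ends).
#' @export
enumerate_protospacers <- function(seq, region_start = 0L, chrom = "chr1",
                                   strand_policy = c("both", "+", "-")) {
  strand_policy <- match.arg(strand_policy)
  s <- toupper(as.character(seq))
  n <- nchar(s)
  if (n < 23L) stopf("sequence must be at least 23 nt")
  if (grepl("[^ACGT]", s)) {
    warnf("sequence contains non-ACGT characters; affected positions skipped")
  }
  hits <- list()
  if (strand_policy != "-") {
    # forward: protospacer [i-21, i-2], PAM [i-1, i+1] (1-based), "GG" at i..i+1
    gg <- as.integer(gregexpr("(?=GG)", s, perl = TRUE)[[1]])
    gg <- gg[gg >= 22L & gg + 1L <= n]
    if (length(gg) && gg[1] != -1L) {
      proto <- substring(s, gg - 21L, gg - 2L)
      pam <- substring(s, gg - 1L, gg + 1L)
      ok <- !grepl("[^ACGT]", proto) & !grepl("[^ACGT]", pam)
      if (any(ok)) {
        gg <- gg[ok]
        start0 <- region_start + gg - 22L          # 0-based protospacer start
        ctx <- substring(paste0(strrep("N", 4), s, strrep("N", 3)),
                         gg - 21L, gg + 8L)        # 4 up + 20 + PAM + 3 down
        hits[["+"]] <- data.frame(chrom = chrom, sequence = proto[ok],
                                  strand = "+", start = start0,
                                  pam = pam[ok],
                                  cut_site = start0 + 17L,
                                  context = ctx,
                                  stringsAsFactors = FALSE)
      }
    }
  }
  if (strand_policy != "+") {
    # reverse: forward-strand "CCN" at [j, j+2] then 20-mer at [j+3, j+22];
    # the protospacer is the reverse complement of that 20-mer
    cc <- as.integer(gregexpr("(?=CC)", s, perl = TRUE)[[1]])
    cc <- cc[cc >= 1L & cc + 22L <= n]
    if (length(cc) && cc[1] != -1L) {
      fwd20 <- substring(s, cc + 3L, cc + 22L)
      pam_f <- substring(s, cc, cc + 2L)           # forward CCN = rc(NGG)
      ok <- !grepl("[^ACGT]", fwd20) & !grepl("[^ACGT]", pam_f)
      if (any(ok)) {
        cc <- cc[ok]
        start0 <- region_start + cc + 2L           # 0-based fwd start of 20-mer
        padded <- paste0(strrep("N", 3), s, strrep("N", 4))
        ctx_f <- substring(padded, cc, cc + 29L)   # 3 dn + PAM + 20 + 4 up (fwd)
        hits[["-"]] <- data.frame(chrom = chrom,
                                  sequence = revcomp(fwd20[ok]),
                                  strand = "-", start = start0,
                                  pam = revcomp(pam_f[ok]),
                                  cut_site = start0 + 3L,
                                  context = revcomp(ctx_f),
                                  stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out))
    return(data.frame(chrom = character(), sequence = character(),
                      strand = character(), start = integer(),
                      pam = character(), cut_site = integer(),
                      context = character(), stringsAsFactors = FALSE))
  out <- out[order(out$cut_site, out$strand, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genome-wide protospacer index for off-target scanning
#'
#' Enumerates every NGG-adjacent 20-mer on both strands of every chromosome
#' once, and caches a character matrix for fast Hamming comparisons.
#'
#' @param genome Named character vector (or `DNAStringSet`) of chromosome
#'   sequences.
#' @return A list of class `offtarget_index` with `sites` (data.frame) and
#'   a 20 x n character matrix `mat`.
#' @export
offtarget_index <- function(genome) {
  genome <- as.character(genome)
  if (is.null(names(genome))) names(genome) <- paste0("chr", seq_along(genome))
  sites <- do.call(rbind, lapply(names(genome), function(ch) {
    enumerate_protospacers(genome[[ch]], 0L, chrom = ch)
  }))
  mat <- matrix(unlist(strsplit(sites$sequence, ""), use.names = FALSE),
                nrow = 20L)
  structure(list(sites = sites[, c("chrom", "strand", "start", "sequence")],
                 mat = mat),
            class = "offtarget_index")
}

#' Count and threshold off-target sites by Hamming distance
#'
#' Counts genomic NGG-adjacent sites within Hamming distance 0..4 of a
#' protospacer (both strands), excluding the on-target locus, and tests the
#' counts against per-distance thresholds. The default `c(0, 0, 0, Inf,
#' Inf)` allows no additional site with up to 2 mismatches and ignores
#' distances 3-4.
#'
#' @param p One-row protospacer data.frame (needs `sequence`, and `chrom`/
#'   `strand`/`start` to identify the on-target locus) or a bare 20-nt
#'   sequence.
#' @param index An [offtarget_index()]; required (off-target filtering
#'   without a genome is an error).
#' @param thresholds Numeric vector of 5 maxima for distances 0..4 (`Inf`
#'   for unlimited).
#' @return List with `pass` (logical) and `counts` (named integer vector,
#'   distances 0..4).
#' @export
count_offtargets <- function(p, index, thresholds = c(0, 0, 0, Inf, Inf)) {
  if (missing(index) || is.null(index))
    stopf("off-target counting requires a genome index")
  if (length(thresholds) != 5L) stopf("thresholds must have length 5")
  if (is.character(p)) p <- data.frame(sequence = p, chrom = NA, strand = NA,
                                       start = NA, stringsAsFactors = FALSE)
  q <- strsplit(toupper(p$sequence[1]), "")[[1]]
  if (length(q) != 20L) stopf("protospacer must be 20 nt")
  d <- colSums(index$mat != q)
  on_target <- !is.na(p$chrom[1]) &
    index$sites$chrom == p$chrom[1] &
    index$sites$strand == p$strand[1] &
    index$sites$start == p$start[1]
  d <- d[!on_target]
  counts <- vapply(0:4, function(k) sum(d == k), integer(1))
  names(counts) <- paste0("d", 0:4)
  list(pass = all(counts <= thresholds), counts = counts)
}

# Vectorised off-target pass/fail over a protospacer table.
offtarget_pass <- function(ps, index, thresholds = c(0, 0, 0, Inf, Inf)) {
  if (!nrow(ps)) return(logical(0))
  vapply(seq_len(nrow(ps)), function(i) {
    count_offtargets(ps[i, ], index, thresholds)$pass
  }, logical(1))
}
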