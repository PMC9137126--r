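#' Build the 41-bp artificial reference from a library
#'
#' Each construct is represented by the 41-nt fusion of its 21-nt guide-1
#' segment and the reverse-complemented 20-nt guide-2 protospacer — the
#' same sequence the read extractor produces. Constructs sharing an
#' identical fused sequence collapse to one reference record carrying all
#' source construct ids.
#'
#' @param lib Library data.frame with `construct_id`, `guide1_seq` (21 nt)
#'   and `guide2_seq` (20 nt).
#' @return A list of class `pg_reference`: `records` data.frame (`ref_id`,
#'   `sequence`, `source_ids` semicolon-collapsed, `n_sources`) and a
#'   lookup environment.
#' @export
build_reference <- function(lib) {
  bad1 <- nchar(lib$guide1_seq) != 21L
  bad2 <- nchar(lib$guide2_seq) != 20L
  if (any(bad1 | bad2))
    stopf("guide length mismatch for construct(s): %s",
          paste(lib$construct_id[bad1 | bad2], collapse = ", "))
  fused <- paste0(lib$guide1_seq, revcomp(lib$guide2_seq))
  grp <- split(lib$construct_id, fused)
  records <- data.frame(
    sequence = names(grp),
    source_ids = vapply(grp, paste, character(1), collapse = ";"),
    n_sources = lengths(grp),
    stringsAsFactors = FALSE)
  # merged record id: the collapsed source ids (single-source records keep
  # their construct id)
  records$ref_id <- records$source_ids
  records <- records[order(records$ref_id),
                     c("ref_id", "sequence", "source_ids", "n_sources")]
  rownames(records) <- NULL
  stopifnot(all(nchar(records$sequence) == 41L))
  structure(list(records = records,
                 mat = matrix(unlist(strsplit(records$sequence, ""),
                                     use.names = FALSE), nrow = 41L)),
            class = "pg_reference")
}

#' @rdname build_reference
#' @param ref A `pg_reference`.
#' @param path FASTA output path.
#' @export
write_reference_fasta <- function(ref, path) {
  seqs <- Biostrings::DNAStringSet(ref$records$sequence)
  names(seqs) <- ref$records$ref_id
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Extract fused guide sequences from read pairs
#'
#' Guide 1 is the 21 nt following the first `ACCG` anchor whose match start
#' (1-based) lies in `window2` of read 2; guide 2 is the 20 nt following
#' the first `AAAC` anchor whose start lies in `window1` of read 1. The
#' read-1 segment is sequenced in reference orientation (the reference
#' stores guide 2 reverse-complemented), so the fused sequence is the
#' direct concatenation of the two extracts. Pairs missing an anchor get
#' status `no_anchor1`/`no_anchor2` (anchor 1 checked first); pairs whose
#' fused sequence is shorter than 20 nt (read-end truncation) are
#' `too_short`; the rest are `fused`.
#'
#' @param read1,read2 Character vectors of read sequences (equal length).
#' @param window1,window2 1-based inclusive anchor-start windows, default
#'   `c(100, 150)` on read 1 and `c(15, 55)` on read 2.
#' @return data.frame with `status` and `fused` (NA unless fused).
#' @export
extract_fused_guides <- function(read1, read2,
                                 window1 = c(100L, 150L),
                                 window2 = c(15L, 55L)) {
  stopifnot(length(read1) == length(read2))
  find_anchor <- function(reads, anchor, window) {
    sub <- substr(reads, window[1], window[2] + nchar(anchor) - 1L)
    m <- regexpr(anchor, sub, fixed = TRUE)
    ifelse(m > 0L, window[1] - 1L + as.integer(m), NA_integer_)
  }
  a1 <- find_anchor(read2, "ACCG", window2)
  a2 <- find_anchor(read1, "AAAC", window1)
  g1 <- substr(read2, a1 + 4L, a1 + 24L)   # 21 nt (possibly truncated)
  g2 <- substr(read1, a2 + 4L, a2 + 23L)   # 20 nt (possibly truncated)
  fused <- paste0(g1, g2)
  status <- rep("fused", length(read1))
  status[is.na(a1)] <- "no_anchor1"
  status[!is.na(a1) & is.na(a2)] <- "no_anchor2"
  short <- status == "fused" & nchar(fused) < 20L
  status[short] <- "too_short"
  fused[status != "fused"] <- NA_character_
  data.frame(status = status, fused = fused, stringsAsFactors = FALSE)
}

#' Assign fused sequences to reference records by Hamming distance
#'
#' Each fused sequence is compared, without indels, against every
#' reference record; it is assigned to the unique record at minimal
#' distance when that distance is at most `max_mm`, `multimapped` when two
#' or more records tie at the minimum, and `unmapped` when the minimum
#' exceeds `max_mm`. Sequences shorter than 41 nt are compared over their
#' length against reference prefixes.
#'
#' @param fused Character vector of fused sequences (20-41 nt).
#' @param ref A [build_reference()] object.
#' @param max_mm Maximum mismatches. 2 is the synthetic-data default; 13
#'   mirrors the saturation setting used on real screen data.
#' @return data.frame with `ref_id` (NA unless assigned) and `status`
#'   (`assigned` / `unmapped` / `multimapped`).
#' @export
assign_reads <- function(fused, ref, max_mm = 2L) {
  n <- length(fused)
  out_id <- rep(NA_character_, n)
  out_status <- rep(NA_character_, n)
  refseq <- ref$records$sequence
  # fast path: exact full-length matches
  exact <- match(fused, refseq)
  hit <- !is.na(exact)
  out_id[hit] <- ref$records$ref_id[exact[hit]]
  out_status[hit] <- "assigned"
  todo <- which(!hit)
  if (length(todo)) {
    uq <- unique(fused[todo])
    res_id <- rep(NA_character_, length(uq))
    res_status <- character(length(uq))
    for (L in unique(nchar(uq))) {
      sel <- which(nchar(uq) == L)
      # queries as an L x m character matrix; scan reference records,
      # tracking the running minimum distance and its multiplicity
      Q <- matrix(unlist(strsplit(uq[sel], ""), use.names = FALSE), nrow = L)
      m <- length(sel)
      dmin <- rep(L + 1L, m); nmin <- integer(m); best <- integer(m)
      for (r in seq_len(nrow(ref$records))) {
        d <- colSums(Q != ref$mat[seq_len(L), r])
        tie <- d == dmin
        nmin[tie] <- nmin[tie] + 1L
        upd <- d < dmin
        dmin[upd] <- d[upd]; best[upd] <- r; nmin[upd] <- 1L
      }
      status <- ifelse(dmin > max_mm, "unmapped",
                       ifelse(nmin > 1L, "multimapped", "assigned"))
      res_status[sel] <- status
      res_id[sel] <- ifelse(status == "assigned",
                            ref$records$ref_id[best], NA_character_)
    }
    m <- match(fused[todo], uq)
    out_id[todo] <- res_id[m]
    out_status[todo] <- res_status[m]
  }
  data.frame(ref_id = out_id, status = out_status, stringsAsFactors = FALSE)
}

#' Quantify guide pairs across in-memory samples
#'
#' Runs extraction and assignment per sample and tallies counts per
#' reference record. Conservation holds per sample: input pairs = fused +
#' no_anchor1 + no_anchor2 + too_short, and fused = assigned + unmapped +
#' multimapped.
#'
#' @param samples Named list; each element a list with `read1` and `read2`
#'   character vectors.
#' @param lib Library data.frame (used to build the reference).
#' @param max_mm Maximum mismatches for assignment.
#' @return A list of class `pg_counts`: `counts` (integer matrix, reference
#'   records x samples), `accounting` (per-sample totals) and `reference`.
#' @export
quantify_reads <- function(samples, lib, max_mm = 2L) {
  ref <- build_reference(lib)
  nrec <- nrow(ref$records)
  counts <- matrix(0L, nrow = nrec, ncol = length(samples),
                   dimnames = list(ref$records$ref_id, names(samples)))
  acc <- list()
  for (s in names(samples)) {
    ex <- extract_fused_guides(samples[[s]]$read1, samples[[s]]$read2)
    keep <- ex$status == "fused"
    asg <- assign_reads(ex$fused[keep], ref, max_mm)
    tab <- table(factor(asg$ref_id[asg$status == "assigned"],
                        levels = ref$records$ref_id))
    counts[, s] <- as.integer(tab)
    acc[[s]] <- data.frame(
      sample_id = s, n_pairs = nrow(ex),
      fused = sum(keep),
      no_anchor1 = sum(ex$status == "no_anchor1"),
      no_anchor2 = sum(ex$status == "no_anchor2"),
      too_short = sum(ex$status == "too_short"),
      assigned = sum(asg$status == "assigned"),
      unmapped = sum(asg$status == "unmapped"),
      multimapped = sum(asg$status == "multimapped"),
      stringsAsFactors = FALSE)
  }
  structure(list(counts = counts, accounting = do.call(rbind, acc),
                 reference = ref),
            class = "pg_counts")
}

#' Quantify guide pairs from FASTQ files
#'
#' File-based front end of [quantify_reads()]: reads gzipped paired FASTQ
#' per the sample sheet and returns the count matrix plus per-sample
#' accounting. Duplicate constructs are counted at merged-record
#' granularity by default (`split_duplicates = TRUE` divides nothing —
#' every source construct receives the full record count, flagged).
#'
#' @param sample_sheet data.frame with `sample_id`, `fastq1`, `fastq2` and
#'   the metadata columns `timepoint`, `fraction`, `replicate`.
#' @param lib Library data.frame.
#' @param max_mm Maximum mismatches.
#' @param split_duplicates If TRUE, expand merged duplicate records to one
#'   row per source construct (each carrying the record count).
#' @return A `pg_counts` list; `sample_info` carries the sheet metadata.
#' @export
quantify <- function(sample_sheet, lib, max_mm = 2L, split_duplicates = FALSE) {
  missing_files <- !file.exists(c(sample_sheet$fastq1, sample_sheet$fastq2))
  if (any(missing_files))
    stopf("missing FASTQ file(s): %s",
          paste(c(sample_sheet$fastq1, sample_sheet$fastq2)[missing_files],
                collapse = ", "))
  samples <- lapply(seq_len(nrow(sample_sheet)), function(i) {
    list(read1 = as.character(Biostrings::readDNAStringSet(
           sample_sheet$fastq1[i], format = "fastq")),
         read2 = as.character(Biostrings::readDNAStringSet(
           sample_sheet$fastq2[i], format = "fastq")))
  })
  names(samples) <- sample_sheet$sample_id
  res <- quantify_reads(samples, lib, max_mm)
  if (split_duplicates) res$counts <- split_duplicate_counts(res)
  res$sample_info <- sample_sheet[, setdiff(names(sample_sheet),
                                            c("fastq1", "fastq2"))]
  res
}

# Expand merged duplicate-construct records into per-source rows.
split_duplicate_counts <- function(res) {
  rec <- res$reference$records
  src <- strsplit(rec$source_ids, ";", fixed = TRUE)
  idx <- rep(seq_len(nrow(rec)), lengths(src))
  m <- res$counts[idx, , drop = FALSE]
  rownames(m) <- unlist(src)
  m
}

#' Write / read a count matrix TSV
#'
#' Constructs x samples, with the record id in the first column.
#'
#' @param counts Integer matrix (rownames = record ids).
#' @param path File path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(construct_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}
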