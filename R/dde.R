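#' Initial-representation (T0) filter
#'
#' Retains, per replicate, the constructs with at least `min_t0` counts in
#' that replicate's initial (T0) sample — ensuring a minimum representation
#' at the start of the screen. A single pooled T0 sample is applied to both
#' replicates.
#'
#' @param counts Integer matrix constructs x samples.
#' @param sample_info data.frame (`sample_id`, `timepoint`, `fraction`,
#'   `replicate`) describing the columns of `counts`.
#' @param min_t0 Minimum T0 count (5 in the screen).
#' @return Named list (`"1"`, `"2"`, ...) of retained construct-id vectors,
#'   one per replicate.
#' @export
t0_filter <- function(counts, sample_info, min_t0 = 5L) {
  t0 <- sample_info[sample_info$timepoint == "T0", , drop = FALSE]
  if (!nrow(t0)) stopf("no T0 sample in the sample sheet")
  reps <- sort(unique(sample_info$replicate[sample_info$timepoint != "T0"]))
  out <- lapply(reps, function(r) {
    col <- t0$sample_id[t0$replicate == r]
    if (!length(col)) col <- t0$sample_id[1]   # pooled T0
    rownames(counts)[counts[, col[1]] >= min_t0]
  })
  names(out) <- as.character(reps)
  out
}

#' Compute the differentiation-delaying effect (DDE) per construct
#'
#' DDE is the ratio of a construct's counts in the FACS-sorted delayed
#' fraction over its counts in the differentiated fraction, computed
#' independently per replicate at each post-induction timepoint. Under the
#' default `raw` zero policy, `del > 0 / dif = 0` yields `+Inf` (reported,
#' excluded from percentile computation) and `0 / 0` yields `NA`; the
#' `pseudocount` policy adds `pseudocount` to both numerator and
#' denominator.
#'
#' @param counts Integer matrix constructs x samples.
#' @param sample_info Sample metadata (see [t0_filter()]).
#' @param retained Result of [t0_filter()] (per-replicate construct sets),
#'   or a single character vector applied to every replicate.
#' @param lib Optional library table used to annotate `target_id`/`class`
#'   (merged duplicate records are annotated by their first source id).
#' @param zero_policy `"raw"` or `"pseudocount"`.
#' @param pseudocount Added to numerator and denominator under the
#'   pseudocount policy.
#' @return data.frame with `construct_id`, `target_id`, `class`,
#'   `replicate`, `timepoint`, `del_count`, `dif_count`, `dde`; metadata
#'   attribute `zero_policy`.
#' @export
compute_dde <- function(counts, sample_info, retained, lib = NULL,
                        zero_policy = c("raw", "pseudocount"),
                        pseudocount = 1) {
  zero_policy <- match.arg(zero_policy)
  if (any(counts < 0)) stopf("counts must be non-negative")
  if (!is.list(retained)) {
    reps <- sort(unique(sample_info$replicate[sample_info$timepoint != "T0"]))
    retained <- rep(list(retained), length(reps))
    names(retained) <- as.character(reps)
  }
  strata <- unique(sample_info[sample_info$timepoint != "T0",
                               c("timepoint", "replicate")])
  out <- lapply(seq_len(nrow(strata)), function(i) {
    tp <- strata$timepoint[i]; r <- strata$replicate[i]
    pick <- function(frac) {
      id <- sample_info$sample_id[sample_info$timepoint == tp &
                                  sample_info$replicate == r &
                                  sample_info$fraction == frac]
      if (length(id) != 1L)
        stopf("expected one %s sample for %s replicate %s", frac, tp, r)
      counts[, id]
    }
    del <- pick("delayed"); dif <- pick("differentiated")
    ids <- intersect(rownames(counts), retained[[as.character(r)]])
    del <- del[ids]; dif <- dif[ids]
    dde <- if (zero_policy == "raw") {
      ifelse(del == 0 & dif == 0, NA_real_, del / dif)
    } else {
      (del + pseudocount) / (dif + pseudocount)
    }
    data.frame(construct_id = ids, replicate = r, timepoint = tp,
               del_count = unname(del), dif_count = unname(dif),
               dde = unname(dde), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (!is.null(lib)) {
    first_id <- vapply(strsplit(out$construct_id, ";", fixed = TRUE), `[`,
                       character(1), 1L)
    m <- match(first_id, lib$construct_id)
    out$target_id <- lib$target_id[m]
    out$class <- lib$class[m]
  }
  attr(out, "zero_policy") <- zero_policy
  out
}

#' Decile thresholding of DDE values
#'
#' Within each (replicate, timepoint) stratum the threshold is the
#' linear-interpolation `pct`-th percentile of the finite DDE values; hits
#' are the constructs strictly above it. `+Inf` DDE values are always
#' hits. Strata with fewer than 10 finite values are skipped with a
#' warning.
#'
#' @param dde_table Result of [compute_dde()].
#' @param pct Percentile (90 in the screen: the highest decile).
#' @return List with `thresholds` (data.frame: `replicate`, `timepoint`,
#'   `threshold`, `n_finite`, `n_hits`) and `table` (`dde_table` with a
#'   logical `hit` column).
#' @export
decile_hits <- function(dde_table, pct = 90) {
  key <- interaction(dde_table$replicate, dde_table$timepoint, drop = TRUE)
  dde_table$hit <- FALSE
  thr <- list()
  for (k in levels(key)) {
    idx <- which(key == k)
    v <- dde_table$dde[idx]
    finite <- idx[is.finite(v)]
    if (length(finite) < 10L) {
      warnf("stratum %s has %d finite DDE values (< 10); skipped",
            k, length(finite))
      next
    }
    threshold <- unname(quantile(dde_table$dde[finite], pct / 100, type = 7))
    hits <- idx[(is.finite(dde_table$dde[idx]) & dde_table$dde[idx] > threshold) |
                (is.infinite(dde_table$dde[idx]) & dde_table$dde[idx] > 0)]
    dde_table$hit[hits] <- TRUE
    thr[[k]] <- data.frame(replicate = dde_table$replicate[idx[1]],
                           timepoint = dde_table$timepoint[idx[1]],
                           threshold = threshold,
                           n_finite = length(finite), n_hits = length(hits),
                           stringsAsFactors = FALSE)
  }
  list(thresholds = do.call(rbind, c(thr, list(make.row.names = FALSE))),
       table = dde_table)
}

#' Call candidate targets from decile hits
#'
#' A target is called at a timepoint iff at least `min_designs` of its
#' constructs are in the upper decile in replicate 1 AND the same identical
#' constructs are in the upper decile in replicate 2. The final call is the
#' union of the per-timepoint calls by default (`combine =
#' "intersection"` requires both).
#'
#' @param hits Result of [decile_hits()].
#' @param lib Library table (construct -> target/class map). Every
#'   construct in the DDE table must belong to a library target.
#' @param min_designs Minimum shared hit designs (2 in the screen).
#' @param combine `"union"` or `"intersection"` across timepoints.
#' @return data.frame per target: `target_id`, `class`, per-timepoint
#'   shared-hit counts (`shared_T3`, `shared_T6`), `called_at`
#'   (comma-separated), `final_call`.
#' @export
call_candidates <- function(hits, lib, min_designs = 2L,
                            combine = c("union", "intersection")) {
  combine <- match.arg(combine)
  tab <- hits$table
  first_id <- vapply(strsplit(tab$construct_id, ";", fixed = TRUE), `[`,
                     character(1), 1L)
  m <- match(first_id, lib$construct_id)
  if (anyNA(m))
    stopf("construct(s) absent from the library: %s",
          paste(utils::head(tab$construct_id[is.na(m)]), collapse = ", "))
  tab$target_id <- lib$target_id[m]
  tab$class <- lib$class[m]
  timepoints <- sort(unique(tab$timepoint))
  targets <- unique(lib[, c("target_id", "class")])
  targets <- targets[targets$target_id %in% tab$target_id, , drop = FALSE]
  res <- targets
  for (tp in timepoints) {
    shared <- vapply(targets$target_id, function(tg) {
      h1 <- tab$construct_id[tab$target_id == tg & tab$timepoint == tp &
                             tab$replicate == 1 & tab$hit]
      h2 <- tab$construct_id[tab$target_id == tg & tab$timepoint == tp &
                             tab$replicate == 2 & tab$hit]
      length(intersect(h1, h2))
    }, integer(1))
    res[[paste0("shared_", tp)]] <- unname(shared)
  }
  called <- res[, paste0("shared_", timepoints), drop = FALSE] >= min_designs
  res$called_at <- apply(called, 1, function(x)
    paste(timepoints[x], collapse = ","))
  res$final_call <- if (combine == "union") apply(called, 1, any)
                    else apply(called, 1, all)
  rownames(res) <- NULL
  res
}

#' Replicate concordance of control DDE values
#'
#' Per control set and timepoint: Spearman correlation of DDE between the
#' two replicates (rank-based, so infinite ratios are handled naturally)
#' over constructs with a defined DDE in both, plus per-replicate medians.
#' Sets with fewer than 3 paired constructs get `NA` correlation.
#'
#' @param dde_table Result of [compute_dde()].
#' @param control_sets Named list of construct-id vectors.
#' @return data.frame: `set`, `timepoint`, `n`, `spearman`,
#'   `median_dde_rep1`, `median_dde_rep2`.
#' @export
control_concordance <- function(dde_table, control_sets) {
  timepoints <- sort(unique(dde_table$timepoint))
  out <- list()
  for (set in names(control_sets)) {
    ids <- control_sets[[set]]
    for (tp in timepoints) {
      sub <- dde_table[dde_table$timepoint == tp &
                       dde_table$construct_id %in% ids, , drop = FALSE]
      d1 <- sub$dde[sub$replicate == 1][match(ids, sub$construct_id[sub$replicate == 1])]
      d2 <- sub$dde[sub$replicate == 2][match(ids, sub$construct_id[sub$replicate == 2])]
      ok <- !is.na(d1) & !is.na(d2)
      rho <- if (sum(ok) >= 3L) {
        suppressWarnings(cor(d1[ok], d2[ok], method = "spearman"))
      } else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        set = set, timepoint = tp, n = sum(ok), spearman = rho,
        median_dde_rep1 = stats::median(d1[ok]),
        median_dde_rep2 = stats::median(d2[ok]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Replicate-mean DDE decile thresholds
#'
#' Complementary report: DDE computed on replicate-averaged ratios, and its
#' `pct`-th percentile per timepoint — the scale on which screen-wide
#' decile cutoffs are usually quoted.
#'
#' @param dde_table Result of [compute_dde()].
#' @param pct Percentile.
#' @return data.frame: `timepoint`, `threshold`, `n`.
#' @export
mean_dde_thresholds <- function(dde_table, pct = 90) {
  out <- list()
  for (tp in sort(unique(dde_table$timepoint))) {
    sub <- dde_table[dde_table$timepoint == tp, , drop = FALSE]
    w <- stats::reshape(sub[, c("construct_id", "replicate", "dde")],
                 idvar = "construct_id", timevar = "replicate",
                 direction = "wide")
    mean_dde <- rowMeans(w[, -1, drop = FALSE])
    mean_dde <- mean_dde[is.finite(mean_dde)]
    out[[tp]] <- data.frame(timepoint = tp,
                            threshold = unname(quantile(mean_dde, pct / 100,
                                                        type = 7)),
                            n = length(mean_dde), stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
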