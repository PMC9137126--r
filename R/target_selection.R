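#' Parameters for time-course target selection
#'
#' Defaults follow the screen's nomination procedure: protein-coding genes
#' need mean expression >= 1 FPKM and a >= 4-fold change between the highest
#' and lowest value of the temporal profile; lncRNAs need mean >= 0.1 FPKM,
#' >= 2-fold change, and >= 1 FPKM in at least one timepoint, plus TSS
#' isolation (no other gene within 5 kb on the same strand or 50 bp on the
#' opposite strand). Profiles are clustered per replicate with k-means
#' (k = 36 for protein-coding, 16 for lncRNA) on z-scored log10 FPKM.
#'
#' @param min_mean_fpkm Named (`pc`, `lnc`) minimum mean FPKM.
#' @param min_fold Named (`pc`, `lnc`) minimum max/min fold change.
#' @param lnc_min_peak_fpkm Minimum FPKM a lncRNA must reach in >= 1
#'   timepoint.
#' @param k_clusters Named (`pc`, `lnc`) k-means cluster counts.
#' @param isolation Named (`same_strand_bp`, `opposite_strand_bp`) window
#'   half-widths around the lncRNA TSS.
#' @param fpkm_log_pseudocount Pseudocount for log10 transforms and for
#'   clamping a zero minimum in fold-change ratios.
#' @param delta_up,delta_down Z-score rise/fall thresholds used to label
#'   cluster centroids (see [classify_profiles()]).
#' @param kmeans_restarts Number of k-means restarts.
#' @param seed Seed for k-means.
#' @return A list of class `selection_params`.
#' @export
selection_params <- function(min_mean_fpkm = c(pc = 1.0, lnc = 0.1),
                             min_fold = c(pc = 4, lnc = 2),
                             lnc_min_peak_fpkm = 1.0,
                             k_clusters = c(pc = 36L, lnc = 16L),
                             isolation = c(same_strand_bp = 5000L,
                                           opposite_strand_bp = 50L),
                             fpkm_log_pseudocount = 0.01,
                             delta_up = 1.0, delta_down = 1.0,
                             kmeans_restarts = 10L,
                             seed = 1L) {
  if (any(min_fold <= 1)) stopf("min_fold values must exceed 1")
  if (any(isolation < 0)) stopf("isolation windows must be non-negative")
  structure(list(min_mean_fpkm = min_mean_fpkm, min_fold = min_fold,
                 lnc_min_peak_fpkm = lnc_min_peak_fpkm,
                 k_clusters = k_clusters, isolation = isolation,
                 fpkm_log_pseudocount = fpkm_log_pseudocount,
                 delta_up = delta_up, delta_down = delta_down,
                 kmeans_restarts = as.integer(kmeans_restarts),
                 seed = as.integer(seed)),
            class = "selection_params")
}

fpkm_columns <- function(mat) grep("^h[0-9]+$", names(mat), value = TRUE)

#' Expression and fold-change filter
#'
#' Retains protein-coding genes with mean FPKM >= 1 and max/min >= 4, and
#' lncRNAs with mean >= 0.1, max/min >= 2 and >= 1 FPKM in at least one
#' timepoint. When the profile minimum is exactly 0 the fold-change
#' denominator is clamped to the pseudocount.
#'
#' @param mat FPKM data.frame (`gene_id`, `biotype`, `h*` columns).
#' @param params A [selection_params()].
#' @return Character vector of retained gene ids.
#' @export
select_expressed <- function(mat, params = selection_params()) {
  known <- c("protein_coding", "lncRNA")
  if (!all(mat$biotype %in% known))
    stopf("unknown biotype(s): %s",
          paste(unique(setdiff(mat$biotype, known)), collapse = ", "))
  m <- as.matrix(mat[, fpkm_columns(mat), drop = FALSE])
  if (any(m < 0)) stopf("FPKM values must be non-negative")
  mean_f <- rowMeans(m)
  max_f <- apply(m, 1, max)
  min_f <- apply(m, 1, min)
  denom <- ifelse(min_f == 0, params$fpkm_log_pseudocount, min_f)
  fold <- max_f / denom
  is_pc <- mat$biotype == "protein_coding"
  keep <- ifelse(is_pc,
    mean_f >= params$min_mean_fpkm[["pc"]] & fold >= params$min_fold[["pc"]],
    mean_f >= params$min_mean_fpkm[["lnc"]] & fold >= params$min_fold[["lnc"]] &
      max_f >= params$lnc_min_peak_fpkm)
  mat$gene_id[keep]
}

#' lncRNA TSS isolation filter
#'
#' A lncRNA is retained iff no other gene body overlaps the window
#' `[TSS - 5000, TSS + 5000]` on the same strand, nor `[TSS - 50, TSS + 50]`
#' on the opposite strand (window half-widths from `params$isolation`;
#' positions 0-based, windows inclusive of both ends).
#'
#' @param models Gene-model list (`genes` data.frame with `gene_id`,
#'   `biotype`, `chrom`, `strand`, `start`, `end`, `tss`).
#' @param params A [selection_params()].
#' @return Character vector of retained lncRNA gene ids.
#' @export
lnc_isolation_filter <- function(models, params = selection_params()) {
  genes <- if (is.data.frame(models)) models else models$genes
  if (any(!genes$strand %in% c("+", "-")))
    stopf("every gene model needs a '+' or '-' strand")
  lnc <- genes[genes$biotype == "lncRNA", , drop = FALSE]
  same_w <- params$isolation[["same_strand_bp"]]
  opp_w <- params$isolation[["opposite_strand_bp"]]
  overlaps <- function(gs, ge, ws, we) gs <= we & ge - 1L >= ws  # bodies half-open
  keep <- vapply(seq_len(nrow(lnc)), function(i) {
    g <- lnc[i, ]
    others <- genes[genes$gene_id != g$gene_id & genes$chrom == g$chrom, ,
                    drop = FALSE]
    if (!nrow(others)) return(TRUE)
    same <- others$strand == g$strand
    hit_same <- overlaps(others$start[same], others$end[same],
                         g$tss - same_w, g$tss + same_w)
    hit_opp <- overlaps(others$start[!same], others$end[!same],
                        g$tss - opp_w, g$tss + opp_w)
    !any(hit_same) && !any(hit_opp)
  }, logical(1))
  lnc$gene_id[keep]
}

#' Cluster temporal profiles with k-means
#'
#' Profiles are log10(FPKM + pseudocount)-transformed and z-scored per gene
#' across the timepoints, then clustered with k-means (multiple restarts,
#' fixed seed). Genes whose profile has zero variance are dropped with a
#' warning (their z-score is undefined).
#'
#' @param mat FPKM data.frame restricted to the genes to cluster.
#' @param k Number of clusters; must not exceed the number of genes kept.
#' @param params A [selection_params()] (pseudocount, restarts, seed).
#' @return List with `assignments` (named integer vector of cluster ids),
#'   `centroids` (k x timepoints matrix on the z scale) and `timepoints_h`.
#' @export
cluster_profiles <- function(mat, k, params = selection_params()) {
  cols <- fpkm_columns(mat)
  z <- log10(as.matrix(mat[, cols, drop = FALSE]) + params$fpkm_log_pseudocount)
  sds <- apply(z, 1, sd)
  if (any(sds == 0)) {
    warnf("dropping %d constant-profile gene(s) before clustering (z-score undefined)",
          sum(sds == 0))
    mat <- mat[sds > 0, , drop = FALSE]
    z <- z[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (k > nrow(z)) stopf("k = %d exceeds the %d genes available", k, nrow(z))
  z <- (z - rowMeans(z)) / sds
  rownames(z) <- mat$gene_id
  fit <- with_seed(params$seed, {
    kmeans(z, centers = k, nstart = params$kmeans_restarts, iter.max = 100L)
  })
  assignments <- fit$cluster
  names(assignments) <- mat$gene_id
  centroids <- fit$centers
  colnames(centroids) <- cols
  list(assignments = assignments, centroids = centroids,
       timepoints_h = as.numeric(sub("^h", "", cols)))
}

#' Label cluster centroids as peaking / upregulated / other
#'
#' Automates the visual triage of cluster shapes with explicit thresholds:
#' a centroid is `upregulated` if its last z value is its maximum (within
#' tolerance) and exceeds the first by at least `delta_up`; `peaking` if its
#' maximum sits at an internal timepoint with a rise of at least `delta_up`
#' before the peak and a fall of at least `delta_down` after it; otherwise
#' `other`.
#'
#' @param centroids k x timepoints matrix on the z scale.
#' @param params A [selection_params()] (`delta_up`, `delta_down`).
#' @param tol Numeric tolerance used when testing "last value is the
#'   maximum".
#' @return data.frame with `cluster_id` and `label`.
#' @export
classify_profiles <- function(centroids, params = selection_params(),
                              tol = 1e-8) {
  labels <- apply(centroids, 1, function(z) {
    n <- length(z)
    imax <- which.max(z)
    if (z[n] >= max(z) - tol && z[n] - z[1] >= params$delta_up)
      return("upregulated")
    if (imax > 1L && imax < n &&
        z[imax] - min(z[1:imax]) >= params$delta_up &&
        z[imax] - min(z[imax:n]) >= params$delta_down)
      return("peaking")
    "other"
  })
  data.frame(cluster_id = seq_len(nrow(centroids)), label = unname(labels),
             stringsAsFactors = FALSE)
}

# Per-gene labels from a clustering and its centroid labels.
label_genes <- function(clust, centroid_labels) {
  data.frame(gene_id = names(clust$assignments),
             label = centroid_labels$label[clust$assignments],
             stringsAsFactors = FALSE)
}

#' Intersect selected profiles across replicates
#'
#' The final candidate list contains genes labelled peaking or upregulated
#' in replicate 1 AND in replicate 2 (profiles pooled within each replicate,
#' then intersected between replicates).
#'
#' @param labels_rep1,labels_rep2 Per-gene label data.frames (`gene_id`,
#'   `label`), one per replicate, each computed on that replicate's own
#'   filtered gene set.
#' @param biotypes Optional data.frame (`gene_id`, `biotype`) to annotate
#'   the output.
#' @return data.frame with `gene_id`, `label_rep1`, `label_rep2` (and
#'   `biotype` when supplied). Empty with a warning if the intersection is
#'   empty.
#' @export
finalize_candidates <- function(labels_rep1, labels_rep2, biotypes = NULL) {
  wanted <- c("peaking", "upregulated")
  s1 <- labels_rep1[labels_rep1$label %in% wanted, , drop = FALSE]
  s2 <- labels_rep2[labels_rep2$label %in% wanted, , drop = FALSE]
  ids <- intersect(s1$gene_id, s2$gene_id)
  if (!length(ids)) warnf("no gene selected in both replicates")
  out <- data.frame(gene_id = ids,
                    label_rep1 = s1$label[match(ids, s1$gene_id)],
                    label_rep2 = s2$label[match(ids, s2$gene_id)],
                    stringsAsFactors = FALSE)
  if (!is.null(biotypes))
    out$biotype <- biotypes$biotype[match(out$gene_id, biotypes$gene_id)]
  out[order(out$gene_id), , drop = FALSE]
}

#' Full target nomination from two replicate time courses
#'
#' Runs, per replicate: the expression/fold filter, the lncRNA TSS isolation
#' filter (when gene models are supplied), per-biotype k-means clustering,
#' and centroid labelling; then intersects the peaking/upregulated genes
#' between replicates.
#'
#' @param rep1,rep2 FPKM data.frames.
#' @param models Optional gene-model list for the isolation filter.
#' @param params A [selection_params()]. `k_clusters` entries are used per
#'   biotype; a biotype with fewer retained genes than k is an error.
#' @return A data.frame as returned by [finalize_candidates()].
#' @export
select_targets <- function(rep1, rep2, models = NULL,
                           params = selection_params()) {
  iso <- if (!is.null(models)) lnc_isolation_filter(models, params) else NULL
  label_one <- function(mat) {
    keep <- select_expressed(mat, params)
    if (!is.null(iso)) {
      lnc_ids <- mat$gene_id[mat$biotype == "lncRNA"]
      keep <- setdiff(keep, setdiff(lnc_ids, iso))
    }
    sub <- mat[mat$gene_id %in% keep, , drop = FALSE]
    out <- lapply(c(pc = "protein_coding", lnc = "lncRNA"), function(bt) {
      ss <- sub[sub$biotype == bt, , drop = FALSE]
      if (!nrow(ss)) return(NULL)
      key <- if (bt == "protein_coding") "pc" else "lnc"
      cl <- cluster_profiles(ss, params$k_clusters[[key]], params)
      label_genes(cl, classify_profiles(cl$centroids, params))
    })
    do.call(rbind, out[!vapply(out, is.null, logical(1))])
  }
  biotypes <- unique(rbind(rep1[, c("gene_id", "biotype")],
                           rep2[, c("gene_id", "biotype")]))
  finalize_candidates(label_one(rep1), label_one(rep2), biotypes)
}
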