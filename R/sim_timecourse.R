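#' Expression template for a planted profile class
#'
#' Class templates on the FPKM scale: `upregulated` rises log-linearly from
#' 0.5 to 4 FPKM (8-fold, passing the 4x protein-coding and 2x lncRNA
#' fold-change filters); `peaking` rises from 0.5 to a 4-FPKM maximum at an
#' internal timepoint (36 h by default) and falls back; `flat` stays at
#' 2 FPKM; `down` falls log-linearly from 4 to 0.5 FPKM.
#'
#' @param class One of `"peaking"`, `"upregulated"`, `"flat"`, `"down"`.
#' @param timepoints_h Sampling times in hours.
#' @param lo,hi Low/high FPKM levels of the templates.
#' @param peak_h Peak time of the `peaking` template (hours; must be an
#'   internal timepoint).
#' @return Numeric vector of FPKM values, one per timepoint.
#' @export
profile_template <- function(class, timepoints_h, lo = 0.5, hi = 4, peak_h = 36) {
  n <- length(timepoints_h)
  idx <- seq_len(n)
  loglin <- function(from, to, m) 10^seq(log10(from), log10(to), length.out = m)
  switch(class,
    upregulated = loglin(lo, hi, n),
    down = loglin(hi, lo, n),
    flat = rep(2, n),
    peaking = {
      ip <- which(timepoints_h == peak_h)
      if (length(ip) != 1L || ip == 1L || ip == n)
        stopf("peak_h must match an internal timepoint")
      c(loglin(lo, hi, ip), loglin(hi, lo, n - ip + 1L)[-1])
    },
    stopf("unknown profile class '%s'", class)
  )
}

#' Simulate two-replicate FPKM time courses with planted profile classes
#'
#' Each gene gets a class template ([profile_template()]); the two
#' replicates are independent Gaussian noise draws around the same template
#' on the log10(FPKM + 0.01) scale. With `noise_sd = 0` both replicates
#' equal the template exactly.
#'
#' @param config A [sim_config()]; `n_genes_per_class` and `noise_sd` set
#'   the design, `seed` the draws.
#' @param genes Optional data.frame with columns `gene_id` and `biotype`:
#'   existing gene models to assign classes to (cycled over classes in
#'   proportion to `n_genes_per_class`). When `NULL`, synthetic gene ids
#'   are created, split evenly between biotypes within each class.
#' @return List with `rep1`/`rep2` (data.frames: `gene_id`, `biotype`, one
#'   `h<time>` column per timepoint) and `truth` (`gene_id`, `biotype`,
#'   `class`).
#' @export
make_timecourse <- function(config = sim_config(), genes = NULL) {
  if (config$noise_sd < 0) stopf("noise_sd must be non-negative")
  tp <- config$timepoints_h
  npc <- config$n_genes_per_class
  if (is.null(genes)) {
    truth <- do.call(rbind, lapply(names(npc), function(cl) {
      n <- npc[[cl]]
      if (n == 0L) return(NULL)
      data.frame(
        gene_id = sprintf("%s_%s_%03d",
                          rep_len(c("PC", "LNC"), n), toupper(cl), seq_len(n)),
        biotype = rep_len(c("protein_coding", "lncRNA"), n),
        class = cl, stringsAsFactors = FALSE)
    }))
  } else {
    classes <- rep(names(npc), times = npc)
    truth <- data.frame(gene_id = genes$gene_id, biotype = genes$biotype,
                        class = rep_len(classes, nrow(genes)),
                        stringsAsFactors = FALSE)
  }
  templates <- vapply(truth$class, profile_template, numeric(length(tp)),
                      timepoints_h = tp)
  templates <- t(templates)   # genes x timepoints
  with_seed(config$seed + 101L, {
    noisy <- function() {
      lg <- log10(templates + 0.01) +
        matrix(rnorm(length(templates), sd = config$noise_sd),
               nrow = nrow(templates))
      pmax(10^lg - 0.01, 0)
    }
    mk <- function(m) {
      df <- data.frame(gene_id = truth$gene_id, biotype = truth$biotype,
                       stringsAsFactors = FALSE)
      m <- as.data.frame(m)
      names(m) <- paste0("h", tp)
      cbind(df, m)
    }
    list(rep1 = mk(noisy()), rep2 = mk(noisy()), truth = truth)
  })
}

#' Read / write FPKM time-course tables
#'
#' TSV schema: `gene_id`, `biotype`, then one `h<time>` column per
#' timepoint.
#'
#' @param x FPKM data.frame (as produced by [make_timecourse()]).
#' @param path File path.
#' @return `read_fpkm` returns the data.frame; `write_fpkm` its path,
#'   invisibly.
#' @export
write_fpkm <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fpkm
#' @export
read_fpkm <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
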