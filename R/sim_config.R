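#' Simulation configuration for the synthetic screen
#'
#' Bundles every tunable of the synthetic-data generator: the toy genome and
#' annotation, the two-replicate FPKM time courses with planted profile
#' classes, and the sorted-population screen reads with planted
#' delayed-fraction enrichments. An identical configuration (including
#' `seed`) always yields byte-identical outputs.
#'
#' @param seed Integer seed driving every random draw of the generator.
#' @param n_genes_per_class Named integer vector: number of genes planted per
#'   expression profile class (`peaking`, `upregulated`, `flat`, `down`).
#' @param timepoints_h Strictly increasing sampling times in hours. The
#'   default is the 12-point transdifferentiation grid
#'   0, 3, 6, 9, 12, 18, 24, 36, 48, 72, 120, 168 h.
#' @param noise_sd Replicate noise, standard deviation of a Gaussian on
#'   log10(FPKM + 0.01). Must be non-negative.
#' @param genome_length Toy genome length in bp (single chromosome).
#' @param n_pc_genes,n_lnc_genes Number of protein-coding / lncRNA gene
#'   models placed on the toy genome.
#' @param read_len_1,read_len_2 Screen read lengths in bp. Defaults are the
#'   150-bp paired-end geometry of the screen; the plasmid-library QC runs
#'   at 125 bp, hence the lengths are exposed rather than fixed.
#' @param stagger_range Integer interval (inclusive) of stagger-prefix
#'   lengths in nt; staggered oligos diversify the first sequencing cycles.
#' @param error_rate Per-base substitution probability applied to both reads.
#' @param depth Mean read pairs per construct per sample.
#' @param spike_targets `NULL`, or a data.frame with columns `target_id` and
#'   `fold`: targets whose constructs have their delayed-fraction mean count
#'   multiplied by `fold`.
#' @param spike_cv Guide-efficiency spread of spiked constructs: log-sd of
#'   the lognormal per-construct factor applied to `fold` (shared across
#'   replicates; 0 disables the spread).
#' @param nb_dispersion Negative-binomial dispersion of per-construct counts
#'   (variance = mu + dispersion * mu^2). Must be positive.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes_per_class = c(peaking = 40L, upregulated = 40L,
                                             flat = 40L, down = 40L),
                       timepoints_h = c(0, 3, 6, 9, 12, 18, 24, 36, 48, 72, 120, 168),
                       noise_sd = 0.1,
                       genome_length = 120000L,
                       n_pc_genes = 4L,
                       n_lnc_genes = 4L,
                       read_len_1 = 150L,
                       read_len_2 = 150L,
                       stagger_range = c(0L, 7L),
                       error_rate = 0.001,
                       depth = 100,
                       spike_targets = NULL,
                       spike_cv = 0.8,
                       nb_dispersion = 0.2) {
  classes <- c("peaking", "upregulated", "flat", "down")
  if (is.null(names(n_genes_per_class))) names(n_genes_per_class) <- classes
  if (!all(classes %in% names(n_genes_per_class)))
    stopf("n_genes_per_class must name all classes: %s", paste(classes, collapse = ", "))
  if (any(diff(timepoints_h) <= 0))
    stopf("timepoints_h must be strictly increasing")
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  if (error_rate < 0 || error_rate > 1) stopf("error_rate must be in [0, 1]")
  if (nb_dispersion <= 0) stopf("nb_dispersion must be positive")
  if (spike_cv < 0) stopf("spike_cv must be non-negative")
  if (length(stagger_range) != 2L || stagger_range[1] > stagger_range[2] ||
      stagger_range[1] < 0)
    stopf("stagger_range must be a non-negative integer interval")
  if (!is.null(spike_targets) &&
      !all(c("target_id", "fold") %in% names(spike_targets)))
    stopf("spike_targets needs columns target_id and fold")
  structure(list(
    seed = as.integer(seed),
    n_genes_per_class = n_genes_per_class[classes],
    timepoints_h = timepoints_h,
    noise_sd = noise_sd,
    genome_length = as.integer(genome_length),
    n_pc_genes = as.integer(n_pc_genes),
    n_lnc_genes = as.integer(n_lnc_genes),
    read_len_1 = as.integer(read_len_1),
    read_len_2 = as.integer(read_len_2),
    stagger_range = as.integer(stagger_range),
    error_rate = error_rate,
    depth = depth,
    spike_targets = spike_targets,
    spike_cv = spike_cv,
    nb_dispersion = nb_dispersion
  ), class = "sim_config")
}
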