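# Shared fixtures, built in code. Kept small so the suite stays fast.

# Toy annotation + genome reused by design/selection tests.
fixture_annotation <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_toy_annotation(sim_config(seed = 7, genome_length = 120000,
                                               n_pc_genes = 4, n_lnc_genes = 4))
    cache
  }
})

# Small genome-designed library (2 pc + 1 lnc targets + controls).
fixture_library <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ann <- fixture_annotation()
      genes <- ann$models$genes
      targets <- rbind(
        genes[genes$biotype == "protein_coding", ][1:2, c("gene_id", "biotype")],
        genes[genes$biotype == "lncRNA", ][1, c("gene_id", "biotype")])
      cache <<- suppressWarnings(build_library(
        targets, ann$models, ann$genome,
        controls = control_spec(n_intergenic = 2, intergenic_designs = 2),
        n_designs = 3, seed = 7))
    }
    cache
  }
})

# A hand-written two-construct library with fully controlled guides.
tiny_library <- function() {
  data.frame(
    construct_id = c("tgtA_pg01", "tgtA_pg02", "tgtB_pg01"),
    target_id = c("tgtA", "tgtA", "tgtB"),
    class = "pc",
    guide1_seq = c(paste0("G", strrep("A", 20)),
                   paste0("G", strrep("C", 20)),
                   paste0("G", paste(rep(c("A", "C", "G", "T"), 5), collapse = ""))),
    guide2_seq = c(strrep("T", 20), strrep("G", 20),
                   paste(rep(c("T", "G"), 10), collapse = "")),
    stringsAsFactors = FALSE)
}

# Build a synthetic read pair for one construct with chosen geometry.
synth_read_pair <- function(guide1, guide2, stagger2 = 3L, stagger1 = 0L,
                            len1 = 150L, len2 = 150L) {
  fill <- strrep("CT", 120)
  r2 <- substr(paste0(substr(fill, 1, stagger2), pgdecko:::SIM_VEC2, "ACCG",
                      guide1, fill), 1, len2)
  r1 <- substr(paste0(substr(fill, 1, stagger1), pgdecko:::SIM_VEC1, "AAAC",
                      revcomp_chr(guide2), fill), 1, len1)
  list(read1 = r1, read2 = r2)
}

revcomp_chr <- function(x) oracle_revcomp(x)

random_dna_str <- function(n, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(rep_len(len, n), function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    character(1))
}
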