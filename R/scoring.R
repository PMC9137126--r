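#' Surrogate on-target activity scorer
#'
#' A deterministic, documented stand-in for gradient-boosted on-target
#' models: the score is a logistic squash of (i) a fixed position-nucleotide
#' weight sum over the 30-nt context (4 nt upstream + 20-nt protospacer +
#' NGG PAM + 3 nt downstream) and (ii) a GC-window penalty that charges
#' protospacers whose GC count falls outside 6..14. The weights encode the
#' canonical qualitative preferences of SpCas9 guides: G favoured and T
#' disfavoured at the PAM-proximal protospacer end, C disfavoured
#' immediately 5' of the PAM, a mild preference for A in the middle of the
#' spacer, and a variable PAM first base contribution.
#'
#' Any function `f(context) -> [0,1]` that is deterministic on the 30-nt
#' context can be plugged in wherever a `scorer` argument is accepted.
#'
#' @param context Character vector of 30-nt contexts (characters outside
#'   ACGT contribute zero weight).
#' @return Numeric scores in (0, 1).
#' @export
surrogate_scorer <- function(context) {
  W <- surrogate_weights()
  vapply(toupper(context), function(ctx) {
    ch <- strsplit(ctx, "")[[1]]
    if (length(ch) != 30L)
      stopf("scoring context must be 30 nt, got %d", length(ch))
    idx <- match(ch, rownames(W))            # N / ambiguity -> NA -> weight 0
    w <- W[cbind(idx, seq_len(30L))]
    raw <- sum(w, na.rm = TRUE)
    gc <- sum(ch[5:24] %in% c("G", "C"))
    penalty <- 0.08 * max(0, abs(gc - 10) - 4)
    1 / (1 + exp(-(raw - penalty)))
  }, numeric(1), USE.NAMES = FALSE)
}

# Fixed 4 x 30 position-nucleotide weight table of the surrogate scorer.
# Columns: context positions 1..30 (protospacer = 5..24, PAM = 25..27).
surrogate_weights <- function() {
  W <- matrix(0, nrow = 4, ncol = 30,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  W["A", 10:16] <- 0.05          # mid-spacer A preference
  W["G", 20:24] <- 0.15          # PAM-proximal G preference
  W["T", 20:24] <- -0.20         # PAM-proximal T aversion
  W["C", 24] <- -0.15            # C directly 5' of the PAM
  W["G", 24] <- 0.25
  W["C", 25] <- 0.10             # variable PAM base
  W["T", 25] <- -0.05
  W["G", 28] <- 0.05             # first downstream base
  W["A", 1:4] <- 0.02            # upstream A-richness, mild
  W
}

#' Score a protospacer with a pluggable scorer
#'
#' @param p Protospacer table (as from [enumerate_protospacers()], with a
#'   `context` column) or a character vector of 30-nt contexts.
#' @param scorer Function mapping a 30-nt context to a score in `[0, 1]`;
#'   defaults to [surrogate_scorer()]. Must be deterministic on the
#'   context.
#' @return `p` with a `score` column (or a numeric vector for character
#'   input). Contexts padded with `N` (insufficient flanking sequence) are
#'   scored on the available bases and flagged in a `context_complete`
#'   column.
#' @export
score_protospacer <- function(p, scorer = surrogate_scorer) {
  if (is.character(p)) return(scorer(p))
  p$score <- scorer(p$context)
  p$context_complete <- !grepl("N", p$context, fixed = TRUE)
  if (any(p$score < 0 | p$score > 1))
    stopf("scorer returned values outside [0, 1]")
  p
}
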