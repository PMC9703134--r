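# Shared fixture builders and independent oracles used across the suite.

# minimal sample sheet with one donor per sample unless stated
make_sheet <- function(passages, donors = NULL, segment = "TI") {
  n <- length(passages)
  tibble::tibble(
    sample_id = sprintf("s%03d", seq_len(n)),
    donor_id = donors %||% sprintf("d%03d", seq_len(n)),
    passage = as.integer(passages),
    segment = rep_len(segment, n),
    cohort = "fixture"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent Benjamini-Hochberg step-up, written from the definition:
# q_(i) = min_{j >= i} min(1, m * p_(j) / j)
bh_stepup_oracle <- function(p) {
  ok <- !is.na(p)
  q <- rep(NA_real_, length(p))
  pp <- p[ok]
  m <- length(pp)
  o <- order(pp)
  ranked <- pp[o] * m / seq_len(m)
  ranked <- rev(cummin(rev(ranked)))
  qq <- numeric(m)
  qq[o] <- pmin(ranked, 1)
  q[ok] <- qq
  q
}

# brute-force interval membership: label of the first interval (in track
# order) containing the 0-based position, else "none"
annotate_oracle <- function(ann, track) {
  vapply(seq_len(nrow(ann)), function(i) {
    for (j in seq_len(nrow(track))) {
      if (ann$chrom[i] == track$chrom[j] &&
          ann$pos[i] >= track$start[j] && ann$pos[i] < track$end[j]) {
        return(track$label[j])
      }
    }
    "none"
  }, character(1))
}

# exhaustive scan over all peak boundaries on the probe's chromosome
distance_oracle <- function(ann, peaks) {
  vapply(seq_len(nrow(ann)), function(i) {
    b <- c(peaks$start[peaks$chrom == ann$chrom[i]],
           peaks$end[peaks$chrom == ann$chrom[i]])
    if (length(b) == 0) return(NA_real_)
    min(abs(ann$pos[i] - b))
  }, numeric(1))
}

# all-pairs nearest transcript with the tie rules (distance, then start,
# then gene id); interval distance 0 when the point lies inside
nearest_gene_oracle <- function(ann, tx) {
  vapply(seq_len(nrow(ann)), function(i) {
    cand <- tx[tx$chrom == ann$chrom[i], ]
    if (nrow(cand) == 0) return(NA_character_)
    d <- pmax(cand$start - ann$pos[i], ann$pos[i] - (cand$end - 1), 0)
    cand <- cand[order(d, cand$start, cand$label), ]
    cand$label[1]
  }, character(1))
}
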