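## Probe-level quality filtering and the beta <-> M-value transforms.

#' Filter array probes by QC rules
#'
#' Removes probes that (i) sit on a sex chromosome, (ii) assay a polymorphic
#' CpG, (iii) can cross-hybridize to multiple genomic regions, or (iv) fail
#' detection in too large a fraction of samples. The retained set is
#' independent of rule order; the per-rule tallies in the report attribute
#' each removed probe to the first rule (in the order above) that catches it.
#'
#' @param beta Beta matrix (CpGs x samples).
#' @param ann Probe annotation tibble covering every probe in `beta`
#'   (columns `probe_id`, `sex_chr`, `polymorphic`, `cross_hyb`; see
#'   [read_probe_annotation()]).
#' @param detection_p Optional matrix of detection p-values with the same
#'   dimnames as `beta`. When absent the detection rule is skipped.
#' @param p_threshold Detection p-value above which a measurement counts as
#'   failed (default 0.05).
#' @param sample_fraction A probe is removed when the fraction of samples
#'   failing detection exceeds this value (default 0.01, i.e. "more than 1%
#'   of samples"). Set `strict = FALSE` to use "at least" instead.
#' @param strict Logical; `TRUE` (default) removes on strictly greater
#'   fraction, `FALSE` on greater-or-equal.
#' @return List with `beta` (filtered matrix) and `report`, a tibble of
#'   per-rule removal counts plus the retained count.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_cpgs = 50, n_samples = 8, n_donors = 4))
#' tr <- simulate_tracks(cohort$truth, frac_sex = 0.1, seed = 2)
#' filter_probes(cohort$beta, tr$annotation)$report
#' @export
filter_probes <- function(beta, ann, detection_p = NULL,
                          p_threshold = 0.05, sample_fraction = 0.01,
                          strict = TRUE) {
  missing_ann <- setdiff(rownames(beta), ann$probe_id)
  if (length(missing_ann) > 0) {
    stop_ctx("probe(s) missing annotation: %s",
             paste(head(missing_ann, 3), collapse = ", "))
  }
  ann <- ann[match(rownames(beta), ann$probe_id), ]
  rules <- list(
    sex_chromosome = isTRUE_vec(ann$sex_chr),
    polymorphic = isTRUE_vec(ann$polymorphic),
    cross_hybridizing = isTRUE_vec(ann$cross_hyb),
    detection_failure = detection_fail(beta, detection_p, p_threshold,
                                       sample_fraction, strict)
  )
  removed_any <- Reduce(`|`, rules)
  first_rule <- rep(NA_character_, nrow(beta))
  for (nm in rev(names(rules))) first_rule[rules[[nm]]] <- nm
  counts <- vapply(names(rules), function(nm) sum(first_rule == nm, na.rm = TRUE),
                   integer(1))
  report <- tibble(
    rule = c(names(rules), "retained"),
    n_probes = c(as.integer(counts), sum(!removed_any))
  )
  list(beta = beta[!removed_any, , drop = FALSE], report = report)
}

isTRUE_vec <- function(x) !is.na(x) & x

detection_fail <- function(beta, detection_p, p_threshold, sample_fraction,
                           strict) {
  if (is.null(detection_p)) return(rep(FALSE, nrow(beta)))
  if (!identical(dim(detection_p), dim(beta))) {
    stop_ctx("detection_p dimensions (%s) differ from beta (%s)",
             paste(dim(detection_p), collapse = "x"),
             paste(dim(beta), collapse = "x"))
  }
  frac_fail <- rowMeans(detection_p > p_threshold, na.rm = TRUE)
  if (strict) frac_fail > sample_fraction else frac_fail >= sample_fraction
}

#' Convert beta values to M-values and back
#'
#' `beta_to_m()` computes `log2(beta / (1 - beta))` after clipping beta into
#' `(eps, 1 - eps)`; `m_to_beta()` inverts it. M-values are the
#' variance-stabilised scale conventionally used for modelling array
#' methylation.
#'
#' @param beta Numeric vector or matrix of methylation fractions.
#' @param m Numeric vector or matrix of M-values.
#' @param eps Clipping bound keeping the logit finite (default 1e-6).
#' @return Numeric object of the same shape.
#' @examples
#' beta_to_m(c(0.5, 0.8)) # 0, 2
#' m_to_beta(beta_to_m(0.73))
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  b <- clip_unit(beta, eps)
  log2(b / (1 - b))
}

#' @rdname beta_to_m
#' @export
m_to_beta <- function(m) {
  2^m / (1 + 2^m)
}
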