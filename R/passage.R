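## Per-CpG passage statistics and the three-way drift classification:
## hypomethylating, hypermethylating (linear trend + delta-beta threshold)
## and heteroskedastic (Breusch-Pagan) CpGs.

#' Passage design: grouping, thresholds and options for classification
#'
#' @param low,high Integer vectors of passages counted as low- and
#'   high-passage (defaults 1-4 and 5-16, the conventional split for
#'   organoid expansion cohorts). Must be disjoint.
#' @param alpha FDR threshold applied to BH-adjusted p-values (default 0.05).
#' @param delta_threshold Minimum absolute delta beta for a directional call
#'   (default 0.15).
#' @param delta_method How delta beta is computed for classification:
#'   `"model"` (default) uses the fitted slope times the observed passage
#'   span, i.e. the modelled change across the full culture period;
#'   `"group"` uses mean beta of high-passage minus mean beta of low-passage
#'   samples. See the methods vignette for why the model-based change is the
#'   default.
#' @param donor_covariate Include donor indicator covariates in the per-CpG
#'   linear model (default `FALSE`).
#' @return List of class `passage_design`.
#' @export
passage_design <- function(low = 1:4, high = 5:16, alpha = 0.05,
                           delta_threshold = 0.15,
                           delta_method = c("model", "group"),
                           donor_covariate = FALSE) {
  if (length(intersect(low, high)) > 0) stop_ctx("low and high passage sets must be disjoint")
  if (length(low) == 0 || length(high) == 0) stop_ctx("low and high passage sets must be non-empty")
  structure(list(
    low = as.integer(low), high = as.integer(high),
    alpha = alpha, delta_threshold = delta_threshold,
    delta_method = match.arg(delta_method),
    donor_covariate = isTRUE(donor_covariate)
  ), class = "passage_design")
}

passage_model_matrix <- function(sheet, donor_covariate) {
  if (length(unique(sheet$passage)) < 2) {
    stop_ctx("passage is constant across samples; trend undefined")
  }
  if (donor_covariate) {
    donor <- factor(sheet$donor_id)
    X <- stats::model.matrix(~ passage + donor, data = cbind(sheet, donor = donor))
  } else {
    X <- stats::model.matrix(~ passage, data = sheet)
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[seq(qr_x$rank + 1, ncol(X))]]
    stop_ctx("rank-deficient design; confounded term(s): %s",
             paste(aliased, collapse = ", "))
  }
  list(X = X, qr = qr_x)
}

#' Per-CpG linear model of beta on passage
#'
#' Ordinary least squares of one CpG's beta values on passage (continuous),
#' optionally with donor indicator covariates. Returns the passage slope,
#' its t-test p-value and the residual vector. A CpG with (numerically)
#' constant beta is reported with slope 0 and p = 1 so that the FDR universe
#' stays fixed.
#'
#' @param betas Numeric vector of beta values, one per sample (in sample
#'   sheet order).
#' @param sheet Sample sheet with `passage` (and `donor_id` if
#'   `donor_covariate`).
#' @param donor_covariate Include donor indicators (default `FALSE`).
#' @return List: `slope`, `p_value`, `residuals`.
#' @examples
#' sheet <- tibble::tibble(sample_id = paste0("s", 1:10),
#'                         donor_id = "d1", passage = 1:10)
#' fit_passage_lm(0.3 + 0.02 * (1:10), sheet)$slope
#' @export
fit_passage_lm <- function(betas, sheet, donor_covariate = FALSE) {
  if (length(betas) != nrow(sheet)) stop_ctx("betas length differs from sample sheet")
  if (length(betas) < 3) stop_ctx("need >= 3 samples")
  scan <- passage_scan_matrix(matrix(betas, nrow = 1,
                                     dimnames = list("cpg", sheet$sample_id)),
                              sheet, donor_covariate)
  list(slope = scan$stats$slope[1], p_value = scan$stats$p_linear[1],
       residuals = as.numeric(scan$residuals[, 1]))
}

# vectorised OLS of every CpG on a shared design matrix; the workhorse
# behind fit_passage_lm() and passage_scan()
passage_scan_matrix <- function(beta, sheet, donor_covariate) {
  mm <- passage_model_matrix(sheet, donor_covariate)
  X <- mm$X
  n <- nrow(X)
  p <- ncol(X)
  Y <- t(beta)                       # samples x CpGs
  B <- qr.coef(mm$qr, Y)
  fitted <- X %*% B
  res <- Y - fitted
  rss <- colSums(res^2)
  sigma2 <- rss / (n - p)
  xtx_inv <- chol2inv(qr.R(mm$qr))
  j <- match("passage", colnames(X))
  se <- sqrt(sigma2 * xtx_inv[j, j])
  slope <- B[j, ]
  tol <- 1e-12
  tstat <- ifelse(se > tol, slope / se, ifelse(abs(slope) > tol, Inf, 0))
  p_linear <- 2 * pt(abs(tstat), df = n - p, lower.tail = FALSE)
  p_linear[se <= tol & abs(slope) <= tol] <- 1   # constant CpGs
  list(
    stats = tibble(probe_id = rownames(beta), slope = unname(slope),
                   p_linear = unname(p_linear)),
    residuals = res,
    df_residual = n - p
  )
}

#' Breusch-Pagan test for passage-dependent residual variance
#'
#' Koenker's Lagrange-multiplier form: squared residuals are regressed on
#' passage in an auxiliary OLS and `LM = n * R^2` of that regression is
#' referred to a chi-square distribution with 1 degree of freedom. Passage
#' is the sole auxiliary regressor regardless of covariates in the mean
#' model. Residuals with zero variance in their squares give `LM = 0`,
#' `p = 1`.
#'
#' @param residuals Residual vector from a fitted per-CpG model.
#' @param passage Passage number per sample.
#' @return List: `statistic`, `p_value`.
#' @export
breusch_pagan <- function(residuals, passage) {
  if (length(residuals) != length(passage)) stop_ctx("residuals and passage lengths differ")
  if (length(unique(passage)) < 2) stop_ctx("passage is constant; heteroskedasticity w.r.t. passage undefined")
  out <- breusch_pagan_matrix(matrix(residuals, ncol = 1), passage)
  list(statistic = out$statistic[1], p_value = out$p_value[1])
}

breusch_pagan_matrix <- function(res, passage) {
  # res: samples x CpGs
  n <- nrow(res)
  u <- res^2
  X <- cbind(1, passage)
  qr_x <- qr(X)
  aux_res <- qr.resid(qr_x, u)
  tss <- colSums(sweep(u, 2, colMeans(u))^2)
  rsq <- ifelse(tss > 1e-300, 1 - colSums(aux_res^2) / tss, 0)
  rsq <- pmin(pmax(rsq, 0), 1)
  stat <- n * rsq
  tibble(statistic = unname(stat),
         p_value = unname(pchisq(stat, df = 1, lower.tail = FALSE)))
}

#' Delta beta between high- and low-passage groups
#'
#' Mean beta over high-passage samples minus mean beta over low-passage
#' samples, for one CpG (vector) or all CpGs (matrix).
#'
#' @param betas Numeric vector (one CpG) or matrix (CpGs x samples).
#' @param sheet Sample sheet with `passage`.
#' @param design A [passage_design()] giving the low/high passage sets.
#' @return Numeric vector of delta beta values.
#' @export
delta_beta <- function(betas, sheet, design = passage_design()) {
  in_low <- sheet$passage %in% design$low
  in_high <- sheet$passage %in% design$high
  if (!any(in_low) || !any(in_high)) {
    stop_ctx("empty passage group (low: %d samples, high: %d samples)",
             sum(in_low), sum(in_high))
  }
  if (is.matrix(betas)) {
    rowMeans(betas[, in_high, drop = FALSE]) -
      rowMeans(betas[, in_low, drop = FALSE])
  } else {
    mean(betas[in_high]) - mean(betas[in_low])
  }
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (wraps [stats::p.adjust()]); `NA` p-values
#' propagate to `NA` q-values and are excluded from the adjustment universe.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_ctx("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Per-CpG passage statistics for a whole beta matrix
#'
#' Vectorised computation of, for every CpG: the OLS slope of beta on
#' passage and its p-value, the Breusch-Pagan statistic and p-value on the
#' model residuals, and both delta-beta variants (high-minus-low group
#' means, and slope times observed passage span).
#'
#' @inheritParams delta_beta
#' @param beta Beta matrix (CpGs x samples); columns must match
#'   `sheet$sample_id`.
#' @return Tibble: `probe_id`, `slope`, `p_linear`, `bp_stat`, `p_bp`,
#'   `delta_group`, `delta_model`.
#' @export
passage_scan <- function(beta, sheet, design = passage_design()) {
  if (!identical(colnames(beta), sheet$sample_id)) {
    idx <- match(sheet$sample_id, colnames(beta))
    if (anyNA(idx)) stop_ctx("beta matrix columns do not match sample sheet")
    beta <- beta[, idx, drop = FALSE]
  }
  scan <- passage_scan_matrix(beta, sheet, design$donor_covariate)
  bp <- breusch_pagan_matrix(scan$residuals, sheet$passage)
  span <- max(sheet$passage) - min(sheet$passage)
  scan$stats |>
    mutate(
      bp_stat = bp$statistic,
      p_bp = bp$p_value,
      delta_group = delta_beta(beta, sheet, design),
      delta_model = .data$slope * span
    )
}

#' Classify CpGs into drift classes
#'
#' Applies the drift rules to per-CpG statistics: a CpG is called
#' hypomethylating when its BH-adjusted linear-model q-value is below
#' `alpha` and its delta beta is below `-delta_threshold`;
#' hypermethylating mirrors that; heteroskedastic when the BH-adjusted
#' Breusch-Pagan q-value is below `alpha`. Flags are non-exclusive (a CpG
#' can be both directional and heteroskedastic); the primary label uses the
#' precedence hypo/hyper over heteroskedastic over stable.
#'
#' @param stats Tibble from [passage_scan()].
#' @param design A [passage_design()].
#' @return Tibble of class `drift_classification`: the input statistics
#'   plus `delta_beta` (the variant selected by the design), `q_linear`,
#'   `q_bp`, logical flags `hypo`, `hyper`, `hetero`, and `class`.
#' @export
classify_cpgs <- function(stats, design = passage_design()) {
  delta <- if (design$delta_method == "model") stats$delta_model else stats$delta_group
  out <- stats |>
    mutate(
      delta_beta = delta,
      q_linear = bh_fdr(.data$p_linear),
      q_bp = bh_fdr(.data$p_bp),
      hypo = .data$q_linear < design$alpha & delta < -design$delta_threshold,
      hyper = .data$q_linear < design$alpha & delta > design$delta_threshold,
      hetero = .data$q_bp < design$alpha,
      class = dplyr::case_when(
        .data$hypo ~ "hypo",
        .data$hyper ~ "hyper",
        .data$hetero ~ "hetero",
        TRUE ~ "stable"
      )
    )
  class(out) <- c("drift_classification", class(out))
  out
}

#' One call from beta matrix to drift classification
#'
#' Convenience wrapper running [passage_scan()] then [classify_cpgs()].
#'
#' @inheritParams passage_scan
#' @return See [classify_cpgs()].
#' @examples
#' cohort <- simulate_cohort(sim_config(n_cpgs = 500, n_samples = 24, n_donors = 6))
#' cls <- classify_passage(cohort$beta, cohort$samples)
#' dplyr::count(cls, class)
#' @export
classify_passage <- function(beta, sheet, design = passage_design()) {
  classify_cpgs(passage_scan(beta, sheet, design), design)
}

#' @describeIn classify_cpgs Class counts and proportions.
#' @param x A `drift_classification` tibble.
#' @param ... Unused.
#' @export
glance.drift_classification <- function(x, ...) {
  n <- nrow(x)
  tibble(
    n_cpgs = n,
    n_hetero = sum(x$hetero), pct_hetero = 100 * mean(x$hetero),
    n_hypo = sum(x$hypo), pct_hypo = 100 * mean(x$hypo),
    n_hyper = sum(x$hyper), pct_hyper = 100 * mean(x$hyper)
  )
}

#' Concordance of drift classifications between two cohorts
#'
#' Restricts both classifications to their shared probe universe, counts
#' per-class overlaps, and for CpGs directionally significant in either
#' cohort summarises agreement of the delta-beta direction and the Spearman
#' correlation of delta-beta values.
#'
#' @param a,b `drift_classification` tibbles from [classify_cpgs()].
#' @return List with `classes` (per-class counts: in `a`, in `b`, overlap)
#'   and `directional` (one row: `n_union`, `sign_agreement`,
#'   `spearman_rho`).
#' @export
cross_cohort_concordance <- function(a, b) {
  shared <- intersect(a$probe_id, b$probe_id)
  if (length(shared) == 0) stop_ctx("classifications share no probes")
  a <- a[match(shared, a$probe_id), ]
  b <- b[match(shared, b$probe_id), ]
  per_class <- purrr::map_dfr(c("hypo", "hyper", "hetero"), function(cl) {
    fa <- a[[cl]]
    fb <- b[[cl]]
    tibble(class = cl, n_a = sum(fa), n_b = sum(fb), n_overlap = sum(fa & fb))
  })
  dir_any <- (a$hypo | a$hyper) | (b$hypo | b$hyper)
  if (sum(dir_any) >= 2) {
    da <- a$delta_beta[dir_any]
    db <- b$delta_beta[dir_any]
    directional <- tibble(
      n_union = sum(dir_any),
      sign_agreement = mean(sign(da) == sign(db)),
      spearman_rho = suppressWarnings(stats::cor(da, db, method = "spearman"))
    )
  } else {
    directional <- tibble(n_union = sum(dir_any), sign_agreement = NA_real_,
                          spearman_rho = NA_real_)
  }
  list(classes = per_class, directional = directional)
}
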