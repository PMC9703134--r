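## Variance decomposition: PCA of the beta matrix with samples as
## observations, plus per-PC association with sample covariates.

#' Principal component analysis of a beta matrix
#'
#' Runs PCA with samples as observations and CpGs as variables, CpG-wise
#' mean-centred, on beta values directly (set `use_m_values = TRUE` to
#' transform first). Variance fractions are computed from the singular
#' values over all non-trivial components, so they sum to 1 regardless of
#' how many component scores are kept. Each component is oriented so that
#' its largest-magnitude loading is positive, making outputs reproducible
#' across BLAS implementations.
#'
#' @param beta Beta matrix (CpGs x samples), no missing values unless
#'   `impute_mean = TRUE`.
#' @param n_components Number of component scores to keep (default all).
#' @param use_m_values Analyse M-values instead of beta values.
#' @param impute_mean Replace missing betas by the CpG mean before PCA.
#' @return Object of class `meth_pca`: list with `scores` (tibble,
#'   `sample_id` + `PC1..PCk`), `var_frac` (named numeric over all
#'   components), `loadings` (CpGs x k matrix), `n_components`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_cpgs = 100, n_samples = 12, n_donors = 4))
#' pca <- meth_pca(cohort$beta, n_components = 3)
#' tidy(pca)
#' @export
meth_pca <- function(beta, n_components = NULL, use_m_values = FALSE,
                     impute_mean = FALSE) {
  if (ncol(beta) < 2) stop_ctx("PCA needs at least 2 samples")
  x <- if (use_m_values) beta_to_m(beta) else beta
  if (anyNA(x)) {
    if (!impute_mean) stop_ctx("beta matrix has missing values; set impute_mean = TRUE")
    rm <- rowMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- rm[idx[, 1]]
  }
  max_k <- min(ncol(x) - 1L, nrow(x))
  k <- if (is.null(n_components)) max_k else min(as.integer(n_components), max_k)
  if (!is.null(n_components) && n_components > max_k) {
    warn(sprintf("n_components truncated to %d (rank limit)", max_k))
  }
  pc <- prcomp(t(x), center = TRUE, scale. = FALSE)
  keep <- seq_len(k)
  rot <- pc$rotation[, keep, drop = FALSE]
  scr <- pc$x[, keep, drop = FALSE]
  # deterministic sign: largest-|loading| entry of each PC is positive
  flip <- vapply(keep, function(j) {
    v <- rot[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  rot <- sweep(rot, 2, flip, `*`)
  scr <- sweep(scr, 2, flip, `*`)
  ev <- pc$sdev^2
  ev <- ev[seq_len(max_k)]
  structure(list(
    scores = bind_cols(tibble(sample_id = colnames(beta)), as_tibble(scr)),
    var_frac = setNames(ev / sum(ev), paste0("PC", seq_along(ev))),
    loadings = rot,
    n_components = k
  ), class = "meth_pca")
}

#' @export
print.meth_pca <- function(x, ...) {
  cat(sprintf("<meth_pca> %d components kept; top variance fractions:\n",
              x$n_components))
  print(round(head(x$var_frac, 5), 3))
  invisible(x)
}

#' @describeIn meth_pca Tidy per-component summary (variance fractions).
#' @param x A `meth_pca` object.
#' @param ... Unused.
#' @export
tidy.meth_pca <- function(x, ...) {
  tibble(
    component = names(x$var_frac),
    var_frac = unname(x$var_frac),
    cum_var_frac = cumsum(unname(x$var_frac))
  )
}

#' @describeIn meth_pca One-row summary.
#' @export
glance.meth_pca <- function(x, ...) {
  tibble(
    n_samples = nrow(x$scores),
    n_components = x$n_components,
    var_frac_pc1 = unname(x$var_frac[1])
  )
}

#' Associate principal components with sample covariates
#'
#' For every kept component and every covariate, tests the association
#' between sample scores and the covariate: one-way ANOVA (F test) for
#' categorical covariates, Spearman rank correlation (average ranks on
#' ties) for continuous ones. Missing covariate values are dropped
#' pairwise. Categorical covariates observed at a single level yield `NA`.
#'
#' @param pca A `meth_pca` object.
#' @param sheet Sample sheet containing `sample_id` plus the covariates.
#' @param covariates Named character vector mapping covariate column ->
#'   type (`"categorical"` or `"continuous"`). Defaults to the study
#'   covariates present in `sheet`: passage and age continuous; donor,
#'   segment, sex, cohort categorical.
#' @return Tibble: `component`, `covariate`, `type`, `statistic` (F or
#'   Spearman rho), `p_value`.
#' @export
associate_pcs <- function(pca, sheet, covariates = NULL) {
  stopifnot(inherits(pca, "meth_pca"))
  if (is.null(covariates)) {
    defaults <- c(passage = "continuous", age = "continuous",
                  donor_id = "categorical", segment = "categorical",
                  sex = "categorical", cohort = "categorical")
    covariates <- defaults[intersect(names(defaults), names(sheet))]
  }
  df <- left_join(pca$scores, sheet, by = "sample_id")
  pcs <- paste0("PC", seq_len(pca$n_components))
  grid <- tidyr::expand_grid(component = pcs, covariate = names(covariates))
  purrr::pmap_dfr(grid, function(component, covariate) {
    type <- unname(covariates[[covariate]])
    s <- df[[component]]
    v <- df[[covariate]]
    ok <- !is.na(s) & !is.na(v)
    res <- assoc_one(s[ok], v[ok], type)
    tibble(component = component, covariate = covariate, type = type,
           statistic = res$statistic, p_value = res$p_value)
  })
}

assoc_one <- function(scores, covariate, type) {
  if (type == "categorical") {
    f <- factor(covariate)
    if (nlevels(f) < 2 || length(scores) < 3) {
      return(list(statistic = NA_real_, p_value = NA_real_))
    }
    tab <- anova(aov(scores ~ f))
    list(statistic = tab[["F value"]][1], p_value = tab[["Pr(>F)"]][1])
  } else {
    if (length(scores) < 3 || sd(covariate) == 0) {
      return(list(statistic = NA_real_, p_value = NA_real_))
    }
    ct <- suppressWarnings(
      cor.test(scores, as.numeric(covariate), method = "spearman", exact = FALSE)
    )
    list(statistic = unname(ct$estimate), p_value = ct$p.value)
  }
}
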