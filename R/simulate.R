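#' Simulation configuration for a synthetic organoid methylation cohort
#'
#' Builds and validates the parameter set used by [simulate_cohort()]. The
#' defaults describe a cohort resembling a paediatric intestinal-organoid
#' passaging study profiled on a methylation array: bimodal baseline beta
#' values, donor random intercepts, a gut-segment signature on a minority of
#' CpGs, and three planted drift archetypes — CpGs losing methylation with
#' passage (hypo), gaining it (hyper), and becoming more variable without a
#' mean trend (heteroskedastic).
#'
#' All effects and noise are applied on the logit scale and mapped back
#' through the inverse logit, so simulated beta values stay strictly inside
#' (0, 1) and inherit the mean-variance coupling of real array data.
#'
#' @param n_cpgs Number of CpG probes.
#' @param n_samples Number of samples (organoid harvests).
#' @param n_donors Number of donors; samples are spread across donors, and a
#'   donor may be observed at several passages (unbalanced designs allowed).
#' @param passage_range Integer vector giving the span of passages sampled
#'   (only its range is used); default passages 1 to 16.
#' @param fraction_hypo,fraction_hyper,fraction_hetero Proportions of CpGs
#'   planted as hypomethylating, hypermethylating and heteroskedastic. Must
#'   sum to at most 1; the remainder is stable.
#' @param delta_beta_effect Target absolute change in mean beta between the
#'   lowest and highest passage for directional CpGs (fraction units).
#' @param hetero_sd_slope Per-passage increase of the logit-scale noise SD at
#'   heteroskedastic CpGs.
#' @param donor_sd SD of per-CpG, per-donor logit-scale random intercepts.
#' @param base_noise_sd Logit-scale residual SD shared by all CpGs.
#' @param segment_fraction Proportion of CpGs carrying a gut-segment effect.
#' @param segment_effect Logit-scale magnitude of the gut-segment effect
#'   (sign randomised per CpG).
#' @param mix_weights Length-3 weights of the baseline beta mixture
#'   (low-methylated mode, high-methylated mode, mid-range component).
#' @param seed Integer seed; fixed seed gives byte-identical cohorts.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cpgs = 10000,
                       n_samples = 40,
                       n_donors = 12,
                       passage_range = 1:16,
                       fraction_hypo = 0.02,
                       fraction_hyper = 0.01,
                       fraction_hetero = 0.05,
                       delta_beta_effect = 0.25,
                       hetero_sd_slope = 0.1,
                       donor_sd = 0.3,
                       base_noise_sd = 0.3,
                       segment_fraction = 0.1,
                       segment_effect = 1,
                       mix_weights = c(low = 0.45, high = 0.45, mid = 0.10),
                       seed = 1L) {
  cfg <- list(
    n_cpgs = as.integer(n_cpgs), n_samples = as.integer(n_samples),
    n_donors = as.integer(n_donors),
    passage_min = min(passage_range), passage_max = max(passage_range),
    fraction_hypo = fraction_hypo, fraction_hyper = fraction_hyper,
    fraction_hetero = fraction_hetero,
    delta_beta_effect = delta_beta_effect,
    hetero_sd_slope = hetero_sd_slope,
    donor_sd = donor_sd, base_noise_sd = base_noise_sd,
    segment_fraction = segment_fraction, segment_effect = segment_effect,
    mix_weights = mix_weights / sum(mix_weights),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fr <- cfg$fraction_hypo + cfg$fraction_hyper + cfg$fraction_hetero
  if (any(c(cfg$fraction_hypo, cfg$fraction_hyper, cfg$fraction_hetero) < 0) ||
      fr > 1) {
    stop_ctx("drift class fractions must be non-negative and sum to <= 1 (got %.3f)", fr)
  }
  if (cfg$n_donors > cfg$n_samples) {
    stop_ctx("n_donors (%d) cannot exceed n_samples (%d)", cfg$n_donors, cfg$n_samples)
  }
  if (cfg$passage_min >= cfg$passage_max) stop_ctx("passage_range must span at least two passages")
  if (cfg$passage_min < 1) stop_ctx("passages must be >= 1")
  for (f in c("hetero_sd_slope", "donor_sd", "base_noise_sd", "delta_beta_effect")) {
    if (cfg[[f]] < 0) stop_ctx("%s must be >= 0", f)
  }
  if (cfg$n_samples < 4) stop_ctx("need at least 4 samples")
  invisible(cfg)
}

# draw baseline mean beta values from a bimodal mixture, optionally
# constrained to an interval (rejection sampling; used so directional CpGs
# have room to move by the planted effect)
draw_baseline <- function(n, mix_weights, lower = 0, upper = 1) {
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(2L * (n - length(out)), 64L)
    comp <- sample.int(3L, m, replace = TRUE, prob = mix_weights)
    x <- numeric(m)
    x[comp == 1L] <- rbeta(sum(comp == 1L), 5, 45)
    x[comp == 2L] <- rbeta(sum(comp == 2L), 45, 5)
    x[comp == 3L] <- rbeta(sum(comp == 3L), 2, 2)
    x <- clip_unit(x, 0.01)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Simulate a synthetic organoid methylation cohort
#'
#' Generates a beta-value matrix, a sample sheet and a ground-truth table
#' under the model described in [sim_config()]. Directional CpGs drift
#' linearly on the logit scale so that the expected beta change between the
#' lowest and the highest passage equals `delta_beta_effect` (negative for
#' hypo, positive for hyper). Heteroskedastic CpGs keep a flat mean while
#' their logit-scale noise SD grows linearly with passage. Donor random
#' intercepts are shared by all samples from the same donor.
#'
#' @param config A `sim_config` object.
#' @return A list of class `meth_cohort` with elements
#'   \describe{
#'     \item{beta}{numeric matrix, CpGs x samples, values strictly in (0,1)}
#'     \item{samples}{tibble: `sample_id`, `donor_id`, `passage`, `segment`,
#'       `age`, `sex`, `cohort`}
#'     \item{truth}{tibble: `probe_id`, `class`
#'       (stable/hypo/hyper/hetero), `true_effect` (signed planted
#'       beta change for directional CpGs, noise-SD slope for
#'       heteroskedastic, 0 for stable)}
#'   }
#' @examples
#' cohort <- simulate_cohort(sim_config(n_cpgs = 200, n_samples = 12, n_donors = 4))
#' range(cohort$beta)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  p_min <- cfg$passage_min
  p_max <- cfg$passage_max
  span <- p_max - p_min

  ## --- sample sheet -------------------------------------------------------
  # passages cycle through the full range so both extremes are observed;
  # donor assignment is shuffled, giving unbalanced passage subsets per donor
  passages <- rep_len(seq(p_min, p_max), cfg$n_samples)
  donors <- sample(rep_len(sprintf("D%02d", seq_len(cfg$n_donors)), cfg$n_samples))
  donor_meta <- tibble(
    donor_id = sprintf("D%02d", seq_len(cfg$n_donors)),
    segment = rep_len(c("TI", "SC"), cfg$n_donors),
    age = round(runif(cfg$n_donors, 2, 16), 1),
    sex = sample(c("F", "M"), cfg$n_donors, replace = TRUE)
  )
  samples <- tibble(
    sample_id = sprintf("S%03d", seq_len(cfg$n_samples)),
    donor_id = donors,
    passage = as.integer(passages)
  ) |>
    left_join(donor_meta, by = "donor_id") |>
    mutate(cohort = "sim")

  ## --- per-CpG plan -------------------------------------------------------
  n <- cfg$n_cpgs
  probe_ids <- sprintf("cg%08d", seq_len(n))
  n_hypo <- round(n * cfg$fraction_hypo)
  n_hyper <- round(n * cfg$fraction_hyper)
  n_het <- round(n * cfg$fraction_hetero)
  classes <- rep("stable", n)
  idx <- sample.int(n, n_hypo + n_hyper + n_het)
  classes[idx[seq_len(n_hypo)]] <- "hypo"
  classes[idx[n_hypo + seq_len(n_hyper)]] <- "hyper"
  classes[idx[n_hypo + n_hyper + seq_len(n_het)]] <- "hetero"

  delta <- cfg$delta_beta_effect
  margin <- min(0.05, (1 - delta) / 2)
  base_beta <- numeric(n)
  base_beta[classes == "stable"] <- draw_baseline(sum(classes == "stable"),
                                                  cfg$mix_weights)
  # heteroskedastic CpGs start at intermediate methylation: a CpG pinned near
  # 0 or 1 has no room for its beta spread to grow
  base_beta[classes == "hetero"] <-
    draw_baseline(n_het, cfg$mix_weights, lower = 0.2, upper = 0.8)
  base_beta[classes == "hypo"] <-
    draw_baseline(n_hypo, cfg$mix_weights, lower = delta + margin)
  base_beta[classes == "hyper"] <-
    draw_baseline(n_hyper, cfg$mix_weights, upper = 1 - delta - margin)

  target_beta <- base_beta
  target_beta[classes == "hypo"] <- clip_unit(base_beta[classes == "hypo"] - delta, 0.01)
  target_beta[classes == "hyper"] <- clip_unit(base_beta[classes == "hyper"] + delta, 0.01)
  m0 <- qlogis(base_beta)
  slope_logit <- (qlogis(target_beta) - m0) / span

  seg_fx <- numeric(n)
  n_seg <- round(n * cfg$segment_fraction)
  if (n_seg > 0) {
    seg_idx <- sample.int(n, n_seg)
    seg_fx[seg_idx] <- cfg$segment_effect * sample(c(-1, 1), n_seg, replace = TRUE)
  }

  het_slope <- ifelse(classes == "hetero", cfg$hetero_sd_slope, 0)

  ## --- assemble the matrix ------------------------------------------------
  donor_idx <- match(samples$donor_id, donor_meta$donor_id)
  donor_fx <- matrix(rnorm(n * cfg$n_donors, 0, cfg$donor_sd), nrow = n)
  p_centered <- samples$passage - p_min
  is_sc <- as.numeric(samples$segment == "SC")

  mean_logit <- m0 + outer(slope_logit, p_centered) + donor_fx[, donor_idx] +
    outer(seg_fx, is_sc)
  sd_mat <- cfg$base_noise_sd + outer(het_slope, p_centered)
  beta <- plogis(mean_logit + matrix(rnorm(length(mean_logit)), nrow = n) * sd_mat)
  beta <- clip_unit(beta)
  dimnames(beta) <- list(probe_ids, samples$sample_id)

  truth <- tibble(
    probe_id = probe_ids,
    class = classes,
    true_effect = dplyr::case_when(
      classes == "hypo" ~ -delta,
      classes == "hyper" ~ delta,
      classes == "hetero" ~ cfg$hetero_sd_slope,
      TRUE ~ 0
    )
  )

  structure(
    list(beta = beta, samples = samples, truth = truth, config = cfg),
    class = "meth_cohort"
  )
}

#' @export
print.meth_cohort <- function(x, ...) {
  cat(sprintf(
    "<meth_cohort> %d CpGs x %d samples (%d donors, passages %d-%d)\n",
    nrow(x$beta), ncol(x$beta), length(unique(x$samples$donor_id)),
    min(x$samples$passage), max(x$samples$passage)
  ))
  print(table(x$truth$class))
  invisible(x)
}

#' Simulate genomic feature tracks and a probe annotation
#'
#' Scatters the cohort's probes along a synthetic chromosome and builds
#' interval tracks whose overlap with each ground-truth drift class follows a
#' requested fold enrichment relative to the background rate. Used to
#' exercise the enrichment machinery end to end with a known answer.
#'
#' Each track is built independently: for every probe a feature label is
#' drawn with probability `fold * base_rate / n_labels` (capped at 0.95
#' total), an interval is placed around probes carrying the label, and
#' intervals of the same label are merged. Tracks generated this way are
#' BED-like, 0-based and half-open. An unlabeled origin-of-replication peak
#' track is placed uniformly at random.
#'
#' @param truth Ground-truth tibble from [simulate_cohort()] (columns
#'   `probe_id`, `class`).
#' @param genome_length Length in bp of the synthetic chromosome.
#' @param feature_labels Character vector of regulatory feature labels.
#' @param enrichment_plan Optional tibble with columns `class`, `label`,
#'   `fold` requesting overlap enrichment of a drift class in a regulatory
#'   label (fold 1 = background rate). Classes/labels not listed use fold 1.
#' @param cdmr_plan As `enrichment_plan`, for the colon-cancer DMR track
#'   whose labels are `loss` and `gain`.
#' @param base_rate Total background probability that a probe overlaps any
#'   label of a track (split evenly across the track's labels).
#' @param feature_width Width (bp) of the interval placed around a probe.
#' @param n_orc,orc_width Number and width of origin-of-replication peaks.
#' @param frac_sex,frac_polymorphic,frac_cross_hyb Fractions of probes
#'   flagged for the corresponding QC-removal rules (sex-flagged probes are
#'   placed on chrX).
#' @param seed Integer seed.
#'
#' @return List with `annotation` (probe annotation tibble: `probe_id`,
#'   `chrom`, `pos`, `sex_chr`, `polymorphic`, `cross_hyb`) and `tracks`, a
#'   named list of interval tibbles (`chrom`, `start`, `end`, `label`):
#'   `regulatory`, `cdmr`, and `orc`.
#' @export
simulate_tracks <- function(truth,
                            genome_length = 1e8,
                            feature_labels = c("promoter", "promoter_flank",
                                               "enhancer", "ctcf",
                                               "tf_binding", "open_chromatin"),
                            enrichment_plan = NULL,
                            cdmr_plan = NULL,
                            base_rate = 0.3,
                            feature_width = 400,
                            n_orc = 500,
                            orc_width = 1000,
                            frac_sex = 0,
                            frac_polymorphic = 0,
                            frac_cross_hyb = 0,
                            seed = 1L) {
  stopifnot(is.data.frame(truth), all(c("probe_id", "class") %in% names(truth)))
  n <- nrow(truth)
  if (genome_length < 2 * n * feature_width + n_orc * orc_width) {
    stop_ctx("genome_length %g too small for %d probes / %d peaks", genome_length, n, n_orc)
  }
  withr::with_seed(as.integer(seed), {
    chrom <- rep("chr1", n)
    n_sex <- round(n * frac_sex)
    if (n_sex > 0) chrom[sample.int(n, n_sex)] <- "chrX"
    pos <- sort(sample.int(genome_length - 1L, n))
    ann <- tibble(
      probe_id = truth$probe_id,
      chrom = chrom,
      pos = pos,
      sex_chr = chrom == "chrX",
      polymorphic = seq_len(n) %in% sample.int(n, round(n * frac_polymorphic)),
      cross_hyb = seq_len(n) %in% sample.int(n, round(n * frac_cross_hyb))
    )
    tracks <- list(
      regulatory = build_planted_track(ann, truth$class, feature_labels,
                                       enrichment_plan, base_rate, feature_width),
      cdmr = build_planted_track(ann, truth$class, c("loss", "gain"),
                                 cdmr_plan, base_rate, feature_width),
      orc = build_orc_track(genome_length, n_orc, orc_width)
    )
    list(annotation = ann, tracks = tracks)
  })
}

build_planted_track <- function(ann, classes, labels, plan, base_rate, width) {
  empty <- tibble(chrom = character(), start = double(), end = double(),
                  label = character())
  if (length(labels) == 0) return(empty)
  q <- base_rate / length(labels)
  prob_of <- function(class, label) {
    f <- 1
    if (!is.null(plan)) {
      hit <- plan$fold[plan$class == class & plan$label == label]
      if (length(hit) == 1) f <- hit
    }
    f * q
  }
  n <- nrow(ann)
  assigned <- rep(NA_character_, n)
  for (cl in unique(classes)) {
    sel <- which(classes == cl & ann$chrom == "chr1")
    p <- vapply(labels, prob_of, numeric(1), class = cl)
    if (sum(p) > 0.95) stop_ctx("enrichment plan infeasible for class '%s' (total prob %.2f)", cl, sum(p))
    draw <- sample(c(labels, NA), length(sel), replace = TRUE,
                   prob = c(p, 1 - sum(p)))
    assigned[sel] <- draw
  }
  hits <- which(!is.na(assigned))
  if (length(hits) == 0) return(empty)
  half <- floor(width / 2)
  iv <- tibble(
    chrom = "chr1",
    start = pmax(0, ann$pos[hits] - half),
    end = ann$pos[hits] + half + 1,
    label = assigned[hits]
  )
  # merge overlapping intervals within a label
  iv |>
    group_by(.data$label) |>
    group_modify_merge() |>
    ungroup() |>
    arrange(.data$start) |>
    select("chrom", "start", "end", "label")
}

group_modify_merge <- function(grouped) {
  dplyr::group_modify(grouped, function(df, key) {
    ir <- IRanges::reduce(IRanges::IRanges(start = df$start + 1, end = df$end))
    tibble(chrom = "chr1",
           start = IRanges::start(ir) - 1,
           end = IRanges::end(ir))
  })
}

build_orc_track <- function(genome_length, n_orc, orc_width) {
  if (n_orc == 0) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  label = character()))
  }
  block <- floor(genome_length / n_orc)
  if (block <= orc_width) stop_ctx("genome too small for %d ORC peaks", n_orc)
  offset <- floor(runif(n_orc, 0, block - orc_width))
  tibble(
    chrom = "chr1",
    start = (seq_len(n_orc) - 1) * block + offset,
    end = (seq_len(n_orc) - 1) * block + offset + orc_width,
    label = "orc_peak"
  )
}
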