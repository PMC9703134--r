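## Genomic-feature annotation and the resampling enrichment machinery:
## feasibility-corrected backgrounds, empirical enrichment p-values from
## random same-size probe lists, colon-cancer DMR concordance, distance to
## replication-origin peaks, and CpG -> gene assignment.

track_granges <- function(track) {
  GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(start = track$start + 1, end = track$end),
    label = if ("label" %in% names(track)) track$label else "feature"
  )
}

probe_granges <- function(ann) {
  GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(start = ann$pos + 1, width = 1)
  )
}

#' Annotate probes with the genomic feature containing them
#'
#' Each probe is labelled with the feature whose interval contains its
#' position (intervals are 0-based half-open, so a probe at position 100 is
#' inside `[100, 200)` and a probe at 200 is not), or `"none"`. When a probe
#' falls in overlapping intervals of different labels, the label earliest in
#' the track's label ordering wins (deterministic tie-break).
#'
#' @param ann Probe annotation tibble (`probe_id`, `chrom`, `pos`).
#' @param track Interval tibble (`chrom`, `start`, `end`, `label`).
#' @return Tibble: `probe_id`, `feature`.
#' @export
annotate_probes <- function(ann, track) {
  if (nrow(track) == 0) {
    return(tibble(probe_id = ann$probe_id, feature = "none"))
  }
  off_track <- setdiff(unique(ann$chrom), unique(track$chrom))
  if (length(off_track) > 0) {
    warn(sprintf("no track intervals on: %s; probes there annotated 'none'",
                 paste(off_track, collapse = ", ")))
  }
  gr_p <- probe_granges(ann)
  gr_t <- track_granges(track)
  hits <- GenomicRanges::findOverlaps(gr_p, gr_t)
  feature <- rep("none", nrow(ann))
  if (length(hits) > 0) {
    h <- tibble(
      probe = S4Vectors::queryHits(hits),
      label = gr_t$label[S4Vectors::subjectHits(hits)]
    ) |>
      mutate(rank = match(.data$label, unique(track$label))) |>
      arrange(.data$probe, .data$rank) |>
      distinct(.data$probe, .keep_all = TRUE)
    feature[h$probe] <- h$label
  }
  tibble(probe_id = ann$probe_id, feature = feature)
}

#' Feasibility-corrected enrichment background
#'
#' Restricts an enrichment background to CpGs whose baseline methylation
#' permits reaching the delta-beta threshold in the tested direction: a CpG
#' with baseline beta below the threshold can never lose that much
#' methylation, and one with baseline above `1 - threshold` can never gain
#' it. Such CpGs are excluded from the background for the loss and gain
#' analyses respectively.
#'
#' @param baseline_beta Tibble with `probe_id` and `beta0`, the per-probe
#'   beta at the reference (lowest) passage, covering `universe`.
#' @param direction `"loss"` or `"gain"`.
#' @param threshold Delta-beta threshold (default 0.15).
#' @param universe Character vector of probe ids to restrict (default: all
#'   probes in `baseline_beta`).
#' @return List: `background` (retained probe ids), `n_excluded`.
#' @export
feasibility_background <- function(baseline_beta, direction = c("loss", "gain"),
                                   threshold = 0.15, universe = NULL) {
  direction <- match.arg(direction)
  if (is.null(universe)) universe <- baseline_beta$probe_id
  miss <- setdiff(universe, baseline_beta$probe_id)
  if (length(miss) > 0) {
    stop_ctx("baseline beta missing for probe(s): %s",
             paste(head(miss, 3), collapse = ", "))
  }
  b0 <- baseline_beta$beta0[match(universe, baseline_beta$probe_id)]
  # achievable loss from baseline b0 is b0 itself; achievable gain is 1 - b0
  feasible <- if (direction == "loss") b0 >= threshold else (1 - b0) >= threshold
  kept <- universe[feasible]
  if (length(kept) == 0) stop_ctx("feasibility correction removed the whole background")
  list(background = kept, n_excluded = sum(!feasible))
}

#' Baseline beta at the reference passage
#'
#' Mean beta per probe over the sample(s) at the lowest observed passage,
#' used as the reference methylation level for feasibility correction.
#'
#' @param beta Beta matrix (CpGs x samples).
#' @param sheet Sample sheet with `passage`.
#' @return Tibble: `probe_id`, `beta0`.
#' @export
baseline_beta <- function(beta, sheet) {
  idx <- which(sheet$passage == min(sheet$passage))
  cols <- match(sheet$sample_id[idx], colnames(beta))
  tibble(probe_id = rownames(beta),
         beta0 = unname(rowMeans(beta[, cols, drop = FALSE])))
}

#' Resampling enrichment of a probe set in genomic features
#'
#' Compares the observed per-feature counts of a target probe set against
#' `n_samplings` random lists of the same size drawn uniformly without
#' replacement from the background, accounting for the distribution of
#' probes on the array. Reports, per feature: observed count, expected
#' (mean sampled) count, fold change observed/expected, the SD of the
#' per-sampling fold ratios as a standard error, empirical enrichment and
#' depletion p-values with plus-one correction
#' (`p = (1 + extreme) / (1 + n_samplings)`), and BH-adjusted q-values
#' across features.
#'
#' @param target Character vector of probe ids; must be a subset of
#'   `background`.
#' @param background Character vector of probe ids.
#' @param annotation Tibble `probe_id` -> `feature` from
#'   [annotate_probes()], covering the background.
#' @param n_samplings Number of random lists (default 1000).
#' @param seed Integer seed making the resampling reproducible.
#' @param continuity Add 0.5 to zero sampled counts when forming fold
#'   ratios (default `FALSE`: features never hit by sampling get `NA` fold).
#' @return Tibble of class `drift_enrichment`: `feature`, `n_target`,
#'   `observed`, `expected`, `fold`, `se_fold`, `p_enrich`, `p_deplete`,
#'   `q_enrich`, `q_deplete`.
#' @export
sampling_enrichment <- function(target, background, annotation,
                                n_samplings = 1000, seed = 1L,
                                continuity = FALSE) {
  n_t <- length(target)
  n_b <- length(background)
  if (n_t == 0) stop_ctx("empty target set")
  if (length(setdiff(target, background)) > 0) {
    stop_ctx("target contains %d probe(s) outside the background; align the feasibility background first",
             length(setdiff(target, background)))
  }
  if (n_b <= n_t) stop_ctx("background (%d) must be larger than target (%d)", n_b, n_t)
  feat <- annotation$feature[match(background, annotation$probe_id)]
  if (anyNA(feat)) stop_ctx("annotation missing for %d background probe(s)", sum(is.na(feat)))
  levels <- sort(unique(feat))
  fi <- match(feat, levels)
  k <- length(levels)
  obs <- tabulate(fi[match(target, background)], nbins = k)
  counts <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_samplings), function(s) {
      tabulate(fi[sample.int(n_b, n_t)], nbins = k)
    }, integer(k))
  })
  counts <- matrix(counts, nrow = k)   # features x samplings
  expected <- rowMeans(counts)
  denom <- if (continuity) pmax(counts, 0.5) else counts
  ratios <- sweep(1 / denom, 1, obs, `*`)   # obs / sampled count
  ratios[!is.finite(ratios)] <- NA
  out <- tibble(
    feature = levels,
    n_target = n_t,
    observed = obs,
    expected = expected,
    fold = ifelse(expected > 0, obs / expected, NA_real_),
    se_fold = apply(ratios, 1, function(r) {
      if (anyNA(r)) NA_real_ else sd(r)
    }),
    p_enrich = (1 + rowSums(counts >= obs)) / (1 + n_samplings),
    p_deplete = (1 + rowSums(counts <= obs)) / (1 + n_samplings)
  ) |>
    mutate(q_enrich = bh_fdr(.data$p_enrich),
           q_deplete = bh_fdr(.data$p_deplete))
  class(out) <- c("drift_enrichment", class(out))
  out
}

#' Drift-class enrichment in colon-cancer DMRs
#'
#' Runs [sampling_enrichment()] of each directional drift class (and,
#' optionally, the heteroskedastic class) against colon-cancer DMR
#' intervals labelled by their direction of change in cancer (`loss` /
#' `gain`), using the feasibility-corrected background appropriate to each
#' drift direction (the heteroskedastic class keeps the full tested
#' universe). Flags whether the same-direction cell of the fold-change
#' table exceeds the cross-direction cell.
#'
#' @param classification `drift_classification` tibble.
#' @param cdmr_track Interval tibble whose `label` column holds the cancer
#'   direction (`loss` / `gain`).
#' @param ann Probe annotation tibble.
#' @param baseline Tibble from [baseline_beta()].
#' @param design A [passage_design()] (supplies the delta threshold).
#' @param include_hetero Also test the heteroskedastic class (default TRUE).
#' @inheritParams sampling_enrichment
#' @return List with `enrichment` (long tibble: `class`, plus
#'   [sampling_enrichment()] columns per cDMR direction; classes with no
#'   CpGs yield an `NA` row) and `same_direction` (tibble: directional
#'   class, logical flag).
#' @export
cdmr_concordance <- function(classification, cdmr_track, ann, baseline,
                             design = passage_design(), n_samplings = 1000,
                             seed = 1L, include_hetero = TRUE) {
  if (nrow(cdmr_track) == 0) stop_ctx("empty cDMR track")
  annotation <- annotate_probes(ann, cdmr_track)
  universe <- classification$probe_id
  class_dirs <- c(hypo = "loss", hyper = "gain")
  classes <- names(class_dirs)
  if (include_hetero) classes <- c(classes, "hetero")
  res <- purrr::map_dfr(classes, function(cl) {
    tgt <- classification$probe_id[classification[[cl]]]
    bg <- if (cl %in% names(class_dirs)) {
      feasibility_background(baseline, class_dirs[[cl]],
                             threshold = design$delta_threshold,
                             universe = universe)$background
    } else {
      universe
    }
    tgt <- intersect(tgt, bg)
    if (length(tgt) == 0 || length(bg) <= length(tgt)) {
      return(tibble(class = cl, feature = NA_character_, n_target = 0L,
                    observed = NA_integer_, expected = NA_real_,
                    fold = NA_real_, se_fold = NA_real_,
                    p_enrich = NA_real_, p_deplete = NA_real_,
                    q_enrich = NA_real_, q_deplete = NA_real_))
    }
    er <- sampling_enrichment(tgt, bg, annotation, n_samplings = n_samplings,
                              seed = derive_seed(seed, match(cl, classes)))
    bind_cols(tibble(class = cl), as_tibble(er))
  })
  same_dir <- purrr::map_dfr(names(class_dirs), function(cl) {
    same <- res$fold[res$class == cl & res$feature == class_dirs[[cl]]]
    other <- setdiff(c("loss", "gain"), class_dirs[[cl]])
    cross <- res$fold[res$class == cl & res$feature == other]
    tibble(class = cl,
           same_direction_enriched = length(same) == 1 && length(cross) == 1 &&
             !is.na(same) && !is.na(cross) && same > cross)
  })
  list(enrichment = res, same_direction = same_dir)
}

#' Minimum distance from each probe to a peak boundary
#'
#' Absolute minimum distance (bp) between a probe's position and any start
#' or end coordinate of a peak on the same chromosome; a probe inside a
#' peak is measured to the nearest edge, not given zero (set
#' `zero_inside = TRUE` for the alternative). Probes on chromosomes without
#' peaks get `NA`.
#'
#' @param ann Probe annotation tibble (`probe_id`, `chrom`, `pos`).
#' @param peaks Interval tibble of peaks.
#' @param zero_inside Give probes lying inside a peak distance 0.
#' @return Tibble: `probe_id`, `distance`.
#' @export
min_distance_to_boundaries <- function(ann, peaks, zero_inside = FALSE) {
  out <- rep(NA_real_, nrow(ann))
  for (ch in unique(ann$chrom)) {
    pk <- peaks[peaks$chrom == ch, ]
    idx <- which(ann$chrom == ch)
    if (nrow(pk) == 0) next
    bounds <- sort(unique(c(pk$start, pk$end)))
    pos <- ann$pos[idx]
    right <- findInterval(pos, bounds) + 1L
    left <- right - 1L
    d_left <- ifelse(left >= 1, pos - bounds[pmax(left, 1L)], Inf)
    d_right <- ifelse(right <= length(bounds),
                      bounds[pmin(right, length(bounds))] - pos, Inf)
    d <- pmin(d_left, d_right)
    if (zero_inside) {
      gr_p <- probe_granges(ann[idx, ])
      inside <- IRanges::overlapsAny(gr_p, track_granges(pk))
      d[inside] <- 0
    }
    out[idx] <- d
  }
  tibble(probe_id = ann$probe_id, distance = out)
}

#' Permutation test of mean distance against random probe lists
#'
#' Compares the observed mean of a per-probe distance over a target set
#' with the means of `n_samplings` random same-size lists drawn from the
#' background. Two one-sided empirical p-values with plus-one correction
#' are reported, plus the direction of the deviation.
#'
#' @param target Character vector of probe ids (subset of background).
#' @param background Character vector of probe ids.
#' @param distances Tibble `probe_id`, `distance` covering the background
#'   (probes with `NA` distance are dropped from both sets).
#' @inheritParams sampling_enrichment
#' @return Tibble: `n_target`, `observed_mean`, `expected_mean`,
#'   `p_farther`, `p_nearer`, `direction`.
#' @export
distance_permutation_test <- function(target, background, distances,
                                      n_samplings = 1000, seed = 1L) {
  if (length(target) == 0) stop_ctx("empty target set")
  if (length(setdiff(target, background)) > 0) stop_ctx("target not contained in background")
  d <- distances$distance[match(background, distances$probe_id)]
  keep <- !is.na(d)
  background <- background[keep]
  d <- d[keep]
  target <- intersect(target, background)
  n_t <- length(target)
  if (n_t == 0) stop_ctx("no target probe has a defined distance")
  obs <- mean(d[match(target, background)])
  means <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_samplings), function(s) mean(d[sample.int(length(d), n_t)]),
           numeric(1))
  })
  tibble(
    n_target = n_t,
    observed_mean = obs,
    expected_mean = mean(means),
    p_farther = (1 + sum(means >= obs)) / (1 + n_samplings),
    p_nearer = (1 + sum(means <= obs)) / (1 + n_samplings),
    direction = ifelse(obs >= mean(means), "farther", "nearer")
  )
}

#' Assign each probe to the gene of its nearest transcript
#'
#' Distance 0 for probes inside a transcript; ties (equidistant
#' transcripts, or overlapping ones) are broken by the smaller transcript
#' start coordinate, then by lexically smaller gene id. Probes on
#' chromosomes without transcripts get `NA`.
#'
#' @param ann Probe annotation tibble.
#' @param transcripts Interval tibble whose `label` column carries gene ids.
#' @return Tibble: `probe_id`, `gene`, `distance`.
#' @export
cpg_to_gene <- function(ann, transcripts) {
  if (nrow(transcripts) == 0) stop_ctx("empty transcript track")
  gr_p <- probe_granges(ann)
  gr_t <- track_granges(transcripts)
  hits <- GenomicRanges::distanceToNearest(gr_p, gr_t, select = "all")
  h <- tibble(
    probe = S4Vectors::queryHits(hits),
    tx = S4Vectors::subjectHits(hits),
    distance = S4Vectors::mcols(hits)$distance
  ) |>
    mutate(start = transcripts$start[.data$tx],
           gene = transcripts$label[.data$tx]) |>
    arrange(.data$probe, .data$distance, .data$start, .data$gene) |>
    distinct(.data$probe, .keep_all = TRUE)
  gene <- rep(NA_character_, nrow(ann))
  dist <- rep(NA_real_, nrow(ann))
  gene[h$probe] <- h$gene
  dist[h$probe] <- h$distance
  tibble(probe_id = ann$probe_id, gene = gene, distance = dist)
}

#' Fraction of a gene list associated with passage-affected CpGs
#'
#' Share of genes in `gene_list` that have at least one CpG with
#' passage-associated methylation change assigned to them.
#'
#' @param gene_list Character vector of gene ids (non-empty).
#' @param passage_cpg_genes Character vector: genes assigned to
#'   passage-associated CpGs.
#' @return Single numeric fraction in \[0, 1\].
#' @export
gene_overlap_fraction <- function(gene_list, passage_cpg_genes) {
  if (length(gene_list) == 0) stop_ctx("empty gene list")
  length(intersect(unique(gene_list), unique(passage_cpg_genes))) /
    length(unique(gene_list))
}
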