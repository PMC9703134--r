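test_that("probe annotation respects half-open interval boundaries", {
  track <- tibble::tibble(chrom = "chr1", start = 100, end = 200, label = "enh")
  ann <- tibble::tibble(probe_id = c("a", "b", "c", "d"), chrom = "chr1",
                        pos = c(100, 150, 199, 200))
  feat <- annotate_probes(ann, track)
  expect_equal(feat$feature, c("enh", "enh", "enh", "none"))
})

test_that("annotation matches the brute-force all-pairs scan", {
  withr::local_seed(61)
  track <- tibble::tibble(
    chrom = "chr1",
    start = c(100, 500, 900),
    end = c(200, 650, 1200),
    label = c("promoter", "enhancer", "ctcf")
  )
  ann <- tibble::tibble(
    probe_id = sprintf("p%02d", 1:20),
    chrom = "chr1",
    pos = sort(sample.int(1400, 20))
  )
  feat <- annotate_probes(ann, track)
  expect_equal(feat$feature, annotate_oracle(ann, track))
})

test_that("probes on chromosomes without track intervals warn and get none", {
  track <- tibble::tibble(chrom = "chr1", start = 0, end = 100, label = "x")
  ann <- tibble::tibble(probe_id = c("a", "b"), chrom = c("chr1", "chr2"),
                        pos = c(10, 10))
  expect_warning(feat <- annotate_probes(ann, track), "chr2")
  expect_equal(feat$feature, c("x", "none"))
})

test_that("feasibility rules exclude exactly the unreachable baselines", {
  base <- tibble::tibble(probe_id = c("a", "b", "c"), beta0 = c(0.10, 0.50, 0.90))
  loss <- feasibility_background(base, "loss", threshold = 0.15)
  expect_setequal(loss$background, c("b", "c"))
  expect_equal(loss$n_excluded, 1L)
  gain <- feasibility_background(base, "gain", threshold = 0.15)
  expect_setequal(gain$background, c("a", "b"))
  # exactness: excluded <=> achievable change below threshold, over a grid
  grid <- tidyr::expand_grid(beta0 = seq(0, 1, by = 0.01),
                             thr = c(0.05, 0.15, 0.3))
  for (thr in unique(grid$thr)) {
    b <- grid$beta0[grid$thr == thr]
    bb <- tibble::tibble(probe_id = as.character(seq_along(b)), beta0 = b)
    kept_loss <- feasibility_background(bb, "loss", thr)$background
    achievable_loss <- b   # a CpG can lose at most its baseline
    expect_setequal(kept_loss, bb$probe_id[achievable_loss >= thr])
    kept_gain <- feasibility_background(bb, "gain", thr)$background
    achievable_gain <- 1 - b
    expect_setequal(kept_gain, bb$probe_id[achievable_gain >= thr])
  }
})

test_that("baseline beta is the mean over lowest-passage samples", {
  co <- simulate_cohort(sim_config(n_cpgs = 40, n_samples = 12, n_donors = 4, seed = 62))
  b0 <- baseline_beta(co$beta, co$samples)
  lo <- co$samples$sample_id[co$samples$passage == min(co$samples$passage)]
  expect_equal(b0$beta0, unname(rowMeans(co$beta[, lo, drop = FALSE])))
})

enrich_fixture <- function(n_bg = 1000, n_feat = 100, n_target = 50) {
  bg <- sprintf("cg%04d", seq_len(n_bg))
  annotation <- tibble::tibble(
    probe_id = bg,
    feature = c(rep("featA", n_feat), rep("none", n_bg - n_feat))
  )
  list(bg = bg, annotation = annotation, target = bg[seq_len(n_target)])
}

test_that("a feature covering the whole background gives fold 1 with zero SE", {
  fx <- enrich_fixture()
  ann_all <- dplyr::mutate(fx$annotation, feature = "everything")
  res <- sampling_enrichment(fx$target, fx$bg, ann_all, n_samplings = 50, seed = 63)
  expect_equal(res$observed, 50L)
  expect_equal(res$fold, 1)
  expect_equal(res$se_fold, 0)
  expect_equal(res$p_enrich + res$p_deplete, 2 * 51 / 51)
})

test_that("enrichment matches the hypergeometric oracle on the planted fixture", {
  fx <- enrich_fixture()
  res <- sampling_enrichment(fx$target, fx$bg, fx$annotation,
                             n_samplings = 2000, seed = 64)
  row <- res[res$feature == "featA", ]
  # hypergeometric expectation: 50 * 100 / 1000 = 5 -> fold 10
  expect_equal(row$expected, 5, tolerance = 0.1)
  expect_equal(row$fold, 10, tolerance = 0.1 * 10)
  expect_equal(row$p_enrich, 1 / 2001)
  expect_equal(row$p_deplete, 1)
})

test_that("a target outside the background is refused", {
  fx <- enrich_fixture()
  expect_error(
    sampling_enrichment(c(fx$target, "rogue"), fx$bg, fx$annotation,
                        n_samplings = 10, seed = 65),
    "outside the background"
  )
  expect_error(sampling_enrichment(character(0), fx$bg, fx$annotation),
               "empty target")
  expect_error(sampling_enrichment(fx$bg, fx$bg, fx$annotation),
               "larger than target")
})

test_that("same seed reproduces the enrichment result exactly", {
  fx <- enrich_fixture()
  r1 <- sampling_enrichment(fx$target, fx$bg, fx$annotation, n_samplings = 200, seed = 66)
  r2 <- sampling_enrichment(fx$target, fx$bg, fx$annotation, n_samplings = 200, seed = 66)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("empirical p-values are never zero and the two sides overlap", {
  fx <- enrich_fixture()
  res <- sampling_enrichment(fx$target, fx$bg, fx$annotation, n_samplings = 100, seed = 67)
  expect_true(all(res$p_enrich > 0 & res$p_deplete > 0))
  expect_true(all(res$p_enrich + res$p_deplete >= 1 + 1 / 101))
})

test_that("random targets give fold near 1 across features", {
  withr::local_seed(68)
  n_bg <- 2000
  bg <- sprintf("cg%04d", seq_len(n_bg))
  annotation <- tibble::tibble(
    probe_id = bg,
    feature = sample(c("a", "b", "c", "d", "none"), n_bg, replace = TRUE,
                     prob = c(0.1, 0.1, 0.15, 0.15, 0.5))
  )
  hits <- 0L
  total <- 0L
  for (r in 1:20) {
    tgt <- sample(bg, 100)
    res <- sampling_enrichment(tgt, bg, annotation, n_samplings = 200, seed = r)
    use <- !is.na(res$se_fold)
    hits <- hits + sum(abs(res$fold[use] - 1) <= 3 * res$se_fold[use])
    total <- total + sum(use)
  }
  expect_gte(hits / total, 0.9)
})

test_that("minimum boundary distance handles edge, interior and between-peak probes", {
  peaks <- tibble::tibble(chrom = "chr1", start = c(100, 400), end = c(200, 500),
                          label = "orc_peak")
  ann <- tibble::tibble(
    probe_id = c("edge", "interior", "between", "far"),
    chrom = "chr1",
    pos = c(100, 150, 300, 900)
  )
  d <- min_distance_to_boundaries(ann, peaks)
  expect_equal(d$distance, c(0, 50, 100, 400))
  # zero-inside variant zeroes only the interior probe
  d0 <- min_distance_to_boundaries(ann, peaks, zero_inside = TRUE)
  expect_equal(d0$distance, c(0, 0, 100, 400))
})

test_that("boundary distances match the exhaustive scan on random fixtures", {
  withr::local_seed(69)
  peaks <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), 15, replace = TRUE),
    start = sort(sample.int(9000, 15)) * 10
  )
  peaks$end <- peaks$start + sample(50:500, 15)
  peaks$label <- "orc_peak"
  ann <- tibble::tibble(
    probe_id = sprintf("p%02d", 1:40),
    chrom = sample(c("chr1", "chr2", "chr3"), 40, replace = TRUE),
    pos = sample.int(100000, 40)
  )
  d <- min_distance_to_boundaries(ann, peaks)
  expect_equal(d$distance, distance_oracle(ann, peaks))
})

test_that("the most distant subset yields the extremal farther p-value", {
  withr::local_seed(70)
  n <- 2000
  ids <- sprintf("cg%04d", seq_len(n))
  dist <- tibble::tibble(probe_id = ids, distance = runif(n, 0, 1e6))
  target <- ids[order(dist$distance, decreasing = TRUE)][1:50]
  res <- distance_permutation_test(target, ids, dist, n_samplings = 500, seed = 71)
  expect_equal(res$p_farther, 1 / 501)
  expect_equal(res$direction, "farther")
  expect_equal(res$p_nearer, 1)
})

test_that("target equal to background gives p = 1 in both directions", {
  ids <- sprintf("cg%02d", 1:30)
  dist <- tibble::tibble(probe_id = ids, distance = seq(10, 300, by = 10))
  res <- distance_permutation_test(ids, ids, dist, n_samplings = 50, seed = 72)
  expect_equal(res$p_farther, 1)
  expect_equal(res$p_nearer, 1)
})

test_that("random distance targets give unremarkable p-values", {
  withr::local_seed(73)
  n <- 1000
  ids <- sprintf("cg%04d", seq_len(n))
  dist <- tibble::tibble(probe_id = ids, distance = rexp(n, 1e-4))
  ps <- vapply(1:30, function(r) {
    tgt <- sample(ids, 80)
    distance_permutation_test(tgt, ids, dist, n_samplings = 200,
                              seed = r)$p_farther
  }, numeric(1))
  expect_gt(median(ps), 0.2)
  expect_lt(median(ps), 0.8)
})

test_that("CpG-to-gene assignment follows proximity with deterministic ties", {
  tx <- tibble::tibble(
    chrom = "chr1",
    start = c(1000, 3000, 3000, 6000),
    end = c(2000, 4000, 4000, 7000),
    label = c("GENE_B", "GENE_C", "GENE_A", "GENE_D")
  )
  ann <- tibble::tibble(
    probe_id = c("inside", "tie_overlap", "equidistant", "lonely"),
    chrom = "chr1",
    pos = c(1500, 3500, 5000, 9000)
  )
  res <- cpg_to_gene(ann, tx)
  expect_equal(res$gene[1], "GENE_B")
  expect_equal(res$distance[1], 0)
  # two transcripts with identical coordinates: lexically smaller gene wins
  expect_equal(res$gene[2], "GENE_A")
  # pos 5000 is 1001 bp from [3000,4000) end and 1000 from [6000,7000) start
  expect_equal(res$gene[3], "GENE_D")
  expect_equal(res$gene[4], "GENE_D")
  expect_error(cpg_to_gene(ann, tx[0, ]), "empty transcript")
})

test_that("gene assignment matches the all-pairs nearest scan", {
  withr::local_seed(74)
  tx <- tibble::tibble(
    chrom = "chr1",
    start = sort(sample.int(50000, 8)),
    label = sprintf("G%02d", 1:8)
  )
  tx$end <- tx$start + 500
  ann <- tibble::tibble(probe_id = sprintf("p%02d", 1:10), chrom = "chr1",
                        pos = sample.int(60000, 10))
  res <- cpg_to_gene(ann, tx)
  expect_equal(res$gene, nearest_gene_oracle(ann, tx))
})

test_that("gene overlap fraction is a simple set ratio", {
  expect_equal(gene_overlap_fraction(c("a", "b"), c("x", "y")), 0)
  expect_equal(gene_overlap_fraction(c("a", "b"), c("a", "b", "c")), 1)
  expect_equal(gene_overlap_fraction(sprintf("g%d", 1:10), sprintf("g%d", c(1, 5, 9, 30))), 0.3)
  expect_error(gene_overlap_fraction(character(0), "a"), "empty gene list")
})

test_that("planted cDMR concordance shows same-direction enrichment", {
  co <- simulate_cohort(sim_config(
    n_cpgs = 10000, n_samples = 40, n_donors = 10,
    fraction_hypo = 0.04, fraction_hyper = 0.03, seed = 75
  ))
  tr <- simulate_tracks(
    co$truth,
    cdmr_plan = tibble::tibble(class = c("hypo", "hyper"),
                               label = c("loss", "gain"), fold = c(3, 3)),
    seed = 76
  )
  cls <- classify_passage(co$beta, co$samples)
  base <- baseline_beta(co$beta, co$samples)
  cc <- cdmr_concordance(cls, tr$tracks$cdmr, tr$annotation, base,
                         n_samplings = 300, seed = 77, include_hetero = FALSE)
  expect_true(all(cc$same_direction$same_direction_enriched))
  hypo_loss <- cc$enrichment$fold[cc$enrichment$class == "hypo" &
                                    cc$enrichment$feature == "loss"]
  expect_gt(hypo_loss, 1.5)
})

test_that("empty drift classes produce NA rows, one-direction tracks work", {
  co <- simulate_cohort(sim_config(
    n_cpgs = 2000, n_samples = 24, n_donors = 6,
    fraction_hypo = 0.05, fraction_hyper = 0, fraction_hetero = 0, seed = 78
  ))
  tr <- simulate_tracks(co$truth, seed = 79)
  cls <- classify_passage(co$beta, co$samples)
  base <- baseline_beta(co$beta, co$samples)
  one_dir <- dplyr::filter(tr$tracks$cdmr, label == "loss")
  cc <- cdmr_concordance(cls, one_dir, tr$annotation, base,
                         n_samplings = 100, seed = 80, include_hetero = FALSE)
  hyper_rows <- cc$enrichment[cc$enrichment$class == "hyper", ]
  expect_true(all(is.na(hyper_rows$fold)))
  expect_gt(sum(!is.na(cc$enrichment$fold)), 0)
})
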