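## End-to-end orchestration: simulate (or read) -> filter -> variance
## decomposition -> drift classification -> genomic enrichment, with every
## intermediate table written to the output directory and a deterministic
## machine-readable report.

config_defaults <- function() {
  list(
    mode = "simulate",
    seed = 1L,
    output_dir = NULL,
    # simulate mode
    n_cpgs = 5000L, n_samples = 40L, n_donors = 12L,
    passage_min = 1L, passage_max = 16L,
    fraction_hypo = 0.02, fraction_hyper = 0.01, fraction_hetero = 0.05,
    delta_beta_effect = 0.25, hetero_sd_slope = 0.1,
    donor_sd = 0.3, base_noise_sd = 0.3, segment_fraction = 0.1,
    genome_length = 1e8, n_orc = 500,
    # real mode
    beta_path = NULL, samples_path = NULL, annotation_path = NULL,
    regulatory_bed = NULL, cdmr_bed = NULL, orc_bed = NULL,
    # design
    low_passage_max = 4L, alpha = 0.05, delta_threshold = 0.15,
    delta_method = "model", donor_covariate = FALSE,
    # decomposition / enrichment
    n_components = 10L, n_samplings = 1000L
  )
}

#' Validate a pipeline configuration
#'
#' Reads a flat `key: value` YAML file (or takes a named list), fills in
#' defaults, checks types and ranges, and cross-checks that real-mode input
#' paths exist. An empty file yields the all-defaults simulation config.
#'
#' @param path Path to a YAML config file, or `NULL`.
#' @param config Named list of settings overriding the file (and defaults).
#' @return List of class `drift_config`.
#' @examples
#' cfg <- validate_config(config = list(n_cpgs = 1000, seed = 7))
#' cfg$mode
#' @export
validate_config <- function(path = NULL, config = list()) {
  from_file <- if (!is.null(path)) {
    if (!file.exists(path)) stop_ctx("config file not found: %s", path)
    yaml::read_yaml(path) %||% list()
  } else {
    list()
  }
  user <- modifyList(from_file, config)
  defaults <- config_defaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop_ctx("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  cfg <- modifyList(defaults, user)
  if (!cfg$mode %in% c("simulate", "real")) stop_ctx("mode must be 'simulate' or 'real'")
  for (f in c("n_cpgs", "n_samples", "n_donors", "n_components", "n_samplings",
              "passage_min", "passage_max", "low_passage_max", "n_orc")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] < 1 ||
        cfg[[f]] != floor(cfg[[f]])) {
      stop_ctx("config key '%s' must be a positive integer (got %s)", f,
               paste(cfg[[f]], collapse = ","))
    }
    cfg[[f]] <- as.integer(cfg[[f]])
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop_ctx("alpha must be in (0, 1)")
  if (cfg$delta_threshold < 0 || cfg$delta_threshold >= 1) {
    stop_ctx("delta_threshold must be in [0, 1)")
  }
  if (!cfg$delta_method %in% c("model", "group")) {
    stop_ctx("delta_method must be 'model' or 'group'")
  }
  if (cfg$mode == "real") {
    for (f in c("beta_path", "samples_path", "annotation_path")) {
      if (is.null(cfg[[f]])) stop_ctx("real mode requires config key '%s'", f)
      if (!file.exists(cfg[[f]])) stop_ctx("config key '%s': file not found: %s", f, cfg[[f]])
    }
    for (f in c("regulatory_bed", "cdmr_bed", "orc_bed")) {
      if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
        stop_ctx("config key '%s': file not found: %s", f, cfg[[f]])
      }
    }
  }
  structure(cfg, class = "drift_config")
}

pipeline_design <- function(cfg) {
  passage_design(
    low = seq(cfg$passage_min, cfg$low_passage_max),
    high = seq(cfg$low_passage_max + 1L, cfg$passage_max),
    alpha = cfg$alpha, delta_threshold = cfg$delta_threshold,
    delta_method = cfg$delta_method, donor_covariate = cfg$donor_covariate
  )
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_ctx("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

# demo enrichment plans used in simulate mode: directional classes are
# planted in features concordant with their direction, mirroring the
# biology the enrichment stage is meant to detect
demo_enrichment_plan <- function() {
  tibble(class = c("hypo", "hyper", "hetero"),
         label = c("enhancer", "tf_binding", "open_chromatin"),
         fold = c(3, 3, 2))
}

demo_cdmr_plan <- function() {
  tibble(class = c("hypo", "hyper"), label = c("loss", "gain"), fold = c(3, 3))
}

#' Run the full methylation-drift pipeline
#'
#' Executes simulate/read -> probe filtering -> PCA + covariate association
#' -> per-CpG passage statistics and drift classification -> genomic
#' enrichment (regulatory features, cDMR concordance, replication-origin
#' distances), writing every intermediate table to `output_dir` together
#' with `report.json`, a deterministic machine-readable summary (class
#' counts and proportions, PC associations, enrichment folds, distance
#' p-values, seed and package version). Any stage error aborts the run
#' naming the failing stage.
#'
#' @param config A `drift_config` from [validate_config()] (or a named list,
#'   validated on the way in).
#' @param output_dir Output directory; overrides `config$output_dir`.
#' @return The report, invisibly (list of class `drift_report`).
#' @examples
#' \donttest{
#' rep <- run_pipeline(validate_config(config = list(n_cpgs = 800, n_samplings = 100)),
#'                     output_dir = tempfile())
#' rep$classes
#' }
#' @export
run_pipeline <- function(config = validate_config(), output_dir = NULL) {
  if (!inherits(config, "drift_config")) config <- validate_config(config = config)
  cfg <- config
  out <- output_dir %||% cfg$output_dir %||% stop_ctx("no output directory given")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  ## stage: inputs
  inputs <- run_stage("inputs", {
    if (cfg$mode == "simulate") {
      cohort <- simulate_cohort(sim_config(
        n_cpgs = cfg$n_cpgs, n_samples = cfg$n_samples, n_donors = cfg$n_donors,
        passage_range = cfg$passage_min:cfg$passage_max,
        fraction_hypo = cfg$fraction_hypo, fraction_hyper = cfg$fraction_hyper,
        fraction_hetero = cfg$fraction_hetero,
        delta_beta_effect = cfg$delta_beta_effect,
        hetero_sd_slope = cfg$hetero_sd_slope, donor_sd = cfg$donor_sd,
        base_noise_sd = cfg$base_noise_sd,
        segment_fraction = cfg$segment_fraction,
        seed = derive_seed(cfg$seed, 1)
      ))
      tr <- simulate_tracks(cohort$truth,
        genome_length = cfg$genome_length, n_orc = cfg$n_orc,
        enrichment_plan = demo_enrichment_plan(), cdmr_plan = demo_cdmr_plan(),
        seed = derive_seed(cfg$seed, 2)
      )
      list(beta = cohort$beta, samples = cohort$samples, truth = cohort$truth,
           annotation = tr$annotation, tracks = tr$tracks)
    } else {
      beta <- read_beta_matrix(cfg$beta_path)
      samples <- read_sample_sheet(cfg$samples_path, beta = beta)
      tracks <- list()
      for (tr in c("regulatory", "cdmr", "orc")) {
        p <- cfg[[paste0(if (tr == "regulatory") "regulatory" else tr, "_bed")]]
        if (!is.null(p)) tracks[[tr]] <- read_bed(p)
      }
      list(beta = beta, samples = samples, truth = NULL,
           annotation = read_probe_annotation(cfg$annotation_path),
           tracks = tracks)
    }
  })

  ## stage: filter
  filtered <- run_stage("filter", {
    filter_probes(inputs$beta, inputs$annotation)
  })
  readr::write_tsv(filtered$report, file.path(out, "filter_report.tsv"),
                   progress = FALSE)

  ## stage: variance decomposition
  pca_assoc <- run_stage("pca", {
    pca <- meth_pca(filtered$beta,
                    n_components = min(cfg$n_components, ncol(filtered$beta) - 1L))
    list(pca = pca, assoc = associate_pcs(pca, inputs$samples))
  })
  readr::write_tsv(tidy(pca_assoc$pca), file.path(out, "pca_scree.tsv"),
                   progress = FALSE)
  readr::write_tsv(pca_assoc$assoc, file.path(out, "pc_associations.tsv"),
                   progress = FALSE)

  ## stage: classify
  design <- pipeline_design(cfg)
  classification <- run_stage("classify", {
    classify_passage(filtered$beta, inputs$samples, design)
  })
  readr::write_tsv(classification, file.path(out, "classification.tsv"),
                   progress = FALSE)

  ## stage: enrich
  enrich <- run_stage("enrich", {
    base <- baseline_beta(filtered$beta, inputs$samples)
    universe <- classification$probe_id
    regulatory <- NULL
    if (!is.null(inputs$tracks$regulatory)) {
      feat_ann <- annotate_probes(inputs$annotation, inputs$tracks$regulatory)
      regulatory <- purrr::map_dfr(c("hypo", "hyper", "hetero"), function(cl) {
        tgt <- classification$probe_id[classification[[cl]]]
        bg <- switch(cl,
          hypo = feasibility_background(base, "loss", design$delta_threshold,
                                        universe)$background,
          hyper = feasibility_background(base, "gain", design$delta_threshold,
                                         universe)$background,
          hetero = universe
        )
        tgt <- intersect(tgt, bg)
        if (length(tgt) == 0 || length(bg) <= length(tgt)) {
          return(tibble(class = cl, feature = NA_character_))
        }
        bind_cols(tibble(class = cl),
                  as_tibble(sampling_enrichment(
                    tgt, bg, feat_ann, n_samplings = cfg$n_samplings,
                    seed = derive_seed(cfg$seed, 10 + match(cl, c("hypo", "hyper", "hetero")))
                  )))
      })
    }
    cdmr <- NULL
    if (!is.null(inputs$tracks$cdmr)) {
      cdmr <- cdmr_concordance(classification, inputs$tracks$cdmr,
                               inputs$annotation, base, design,
                               n_samplings = cfg$n_samplings,
                               seed = derive_seed(cfg$seed, 20))
    }
    orc <- NULL
    if (!is.null(inputs$tracks$orc) && nrow(inputs$tracks$orc) > 0) {
      dist <- min_distance_to_boundaries(inputs$annotation, inputs$tracks$orc)
      orc <- purrr::map_dfr(c("hypo", "hyper", "hetero"), function(cl) {
        tgt <- classification$probe_id[classification[[cl]]]
        if (length(tgt) == 0) return(tibble(class = cl, n_target = 0L))
        bind_cols(tibble(class = cl),
                  distance_permutation_test(
                    tgt, universe, dist, n_samplings = cfg$n_samplings,
                    seed = derive_seed(cfg$seed, 30 + match(cl, c("hypo", "hyper", "hetero")))
                  ))
      })
    }
    list(regulatory = regulatory, cdmr = cdmr, orc = orc)
  })
  if (!is.null(enrich$regulatory)) {
    readr::write_tsv(enrich$regulatory, file.path(out, "enrichment_regulatory.tsv"),
                     progress = FALSE)
  }
  if (!is.null(enrich$cdmr)) {
    readr::write_tsv(enrich$cdmr$enrichment, file.path(out, "enrichment_cdmr.tsv"),
                     progress = FALSE)
  }
  if (!is.null(enrich$orc)) {
    readr::write_tsv(enrich$orc, file.path(out, "orc_distance.tsv"),
                     progress = FALSE)
  }

  ## report
  report <- run_stage("report", {
    cls <- glance.drift_classification(classification)
    rep <- list(
      manifest = list(
        package = "methdrift",
        version = as.character(utils::packageVersion("methdrift")),
        mode = cfg$mode,
        seed = cfg$seed
      ),
      filter = as.list(setNames(filtered$report$n_probes, filtered$report$rule)),
      classes = as.list(cls),
      pc_passage = pca_assoc$assoc |>
        filter(.data$covariate == "passage") |>
        select("component", "statistic", "p_value") |>
        head(5) |>
        as.list(),
      enrichment_folds = if (!is.null(enrich$regulatory)) {
        enrich$regulatory |>
          filter(!is.na(.data$feature)) |>
          select("class", "feature", "fold", "q_enrich") |>
          as.list()
      },
      orc_distance = if (!is.null(enrich$orc)) as.list(enrich$orc)
    )
    structure(rep, class = "drift_report")
  })
  jsonlite::write_json(unclass(report), file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       null = "null")
  invisible(report)
}
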