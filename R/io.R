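## Readers and writers for the on-disk formats: tab-separated tables for the
## beta matrix, sample sheet and probe annotation, and BED (3-4 columns,
## 0-based half-open) for interval tracks. All genomic coordinates are kept
## 0-based half-open internally; probe positions are single-base points.

#' Read a beta-value matrix
#'
#' Expects a tab-separated file with a header row; the first column holds
#' probe ids, remaining columns one sample each. Values must be methylation
#' fractions in \[0, 1\] or the literal token `NA`.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix (CpGs x samples) with probe ids as rownames.
#' @export
read_beta_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 2) stop_ctx("beta matrix needs a probe-id column plus >= 1 sample")
  probes <- as.character(df[[1]])
  if (anyDuplicated(probes)) {
    stop_ctx("duplicate probe id(s): %s",
             paste(head(unique(probes[duplicated(probes)]), 3), collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop_ctx("non-numeric beta values in %s", path)
  rownames(m) <- probes
  if (anyDuplicated(colnames(m))) stop_ctx("duplicate sample id(s) in header")
  validate_beta_matrix(m)
  m
}

validate_beta_matrix <- function(m) {
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_ctx("beta value out of [0,1] at probe %s, sample %s (value %g)",
             rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]],
             m[bad[1, 1], bad[1, 2]])
  }
  invisible(m)
}

#' Write a beta-value matrix
#' @param beta Numeric matrix with probe rownames and sample colnames.
#' @param path Output path.
#' @param digits Decimal places kept on disk (default 6).
#' @export
write_beta_matrix <- function(beta, path, digits = 6) {
  df <- tibble(probe_id = rownames(beta)) |>
    bind_cols(as_tibble(round(beta, digits)))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' Tab-separated with header; required columns `sample_id`, `donor_id`,
#' `passage`; optional `segment`, `age`, `sex`, `cohort`.
#'
#' @param path Path to a TSV file.
#' @param beta Optional beta matrix to cross-check sample ids against.
#' @return Tibble, one row per sample.
#' @export
read_sample_sheet <- function(path, beta = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("sample_id", "donor_id", "passage")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) stop_ctx("sample sheet missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop_ctx("duplicate sample id(s) in sample sheet")
  if (any(is.na(df$passage)) || any(df$passage < 1) || any(df$passage != floor(df$passage))) {
    stop_ctx("passage must be a positive integer for every sample")
  }
  df$passage <- as.integer(df$passage)
  if (!is.null(beta)) check_samples_match(beta, df)
  as_tibble(df)
}

check_samples_match <- function(beta, sheet) {
  miss <- setdiff(colnames(beta), sheet$sample_id)
  if (length(miss) > 0) {
    stop_ctx("beta matrix sample(s) absent from sample sheet: %s",
             paste(head(miss, 3), collapse = ", "))
  }
  invisible(TRUE)
}

#' @rdname read_sample_sheet
#' @param sheet Sample-sheet tibble.
#' @export
write_sample_sheet <- function(sheet, path) {
  readr::write_tsv(sheet, path, progress = FALSE)
  invisible(path)
}

#' Read a probe annotation table
#'
#' Tab-separated with header; required columns `probe_id`, `chrom`, `pos`
#' (0-based bp); optional logical flags `sex_chr`, `polymorphic`,
#' `cross_hyb` (absent flags default to `FALSE`).
#'
#' @param path Path to a TSV file.
#' @return Tibble, one row per probe.
#' @export
read_probe_annotation <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("probe_id", "chrom", "pos")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) stop_ctx("probe annotation missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$probe_id)) stop_ctx("duplicate probe id(s) in annotation")
  if (any(df$pos < 0)) stop_ctx("negative probe position at row %d", which(df$pos < 0)[1])
  for (fl in c("sex_chr", "polymorphic", "cross_hyb")) {
    if (!fl %in% names(df)) df[[fl]] <- FALSE
    df[[fl]] <- as.logical(df[[fl]])
  }
  as_tibble(df)
}

#' @rdname read_probe_annotation
#' @param ann Probe-annotation tibble.
#' @export
write_probe_annotation <- function(ann, path) {
  readr::write_tsv(ann, path, progress = FALSE)
  invisible(path)
}

#' Read a BED interval track
#'
#' BED 3-4 columns, tab-separated, no header: chrom, start, end, optional
#' name used as the feature label. Coordinates are 0-based half-open; the
#' line `chr1 100 200` covers positions 100..199.
#'
#' @param path Path to a BED file.
#' @return Tibble with columns `chrom`, `start`, `end`, `label` (label is
#'   `"feature"` when the name column is absent).
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path,
    col_names = FALSE, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  if (ncol(df) < 3) stop_ctx("BED needs >= 3 columns: %s", path)
  start <- suppressWarnings(as.numeric(df[[2]]))
  end <- suppressWarnings(as.numeric(df[[3]]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) stop_ctx("malformed BED line %d in %s", bad[1], path)
  bad <- which(start >= end)
  if (length(bad) > 0) {
    stop_ctx("BED line %d has start >= end (%s:%g-%g)", bad[1],
             df[[1]][bad[1]], start[bad[1]], end[bad[1]])
  }
  tibble(
    chrom = df[[1]], start = start, end = end,
    label = if (ncol(df) >= 4) df[[4]] else "feature"
  )
}

#' @rdname read_bed
#' @param track Interval tibble (`chrom`, `start`, `end`, optional `label`).
#' @export
write_bed <- function(track, path) {
  df <- track[, intersect(c("chrom", "start", "end", "label"), names(track))]
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write every table of a simulated cohort to a directory
#'
#' Emits `beta.tsv`, `samples.tsv`, `truth.tsv`, and, when tracks are given,
#' `annotation.tsv` plus one BED file per track.
#'
#' @param cohort A `meth_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param tracks Optional result of [simulate_tracks()].
#' @param digits Decimal places for beta values.
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir, tracks = NULL, digits = 6) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_beta_matrix(cohort$beta, file.path(dir, "beta.tsv"), digits = digits)
  write_sample_sheet(cohort$samples, file.path(dir, "samples.tsv"))
  readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  if (!is.null(tracks)) {
    write_probe_annotation(tracks$annotation, file.path(dir, "annotation.tsv"))
    for (nm in names(tracks$tracks)) {
      write_bed(tracks$tracks[[nm]], file.path(dir, paste0(nm, ".bed")))
    }
  }
  invisible(dir)
}
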