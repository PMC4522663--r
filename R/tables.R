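#' Per-sample statistics of the 16-sample capture study
#'
#' Loads the per-sample sequencing statistics of the sixteen-dog capture
#' study shipped with the package (read accounting and on-target depth,
#' regions below the 5x threshold, base pairs covered at >= 5x for the full
#' design and its coding-only subset, and variant counts inside each design).
#' These are printed study values packaged as plain-text fixtures; every
#' study-level average in this package is recomputed from them, never
#' hard-coded.
#'
#' @return Tibble with one row per sample: `sample`, `pool`, `total_reads`,
#'   `mapped_reads`, `duplicate_reads`, `remaining_reads`, `remaining_pct`,
#'   `depth_x`, `n_regions_min_below`, `n_regions_never`, `bp_covered_plus`,
#'   `bp_covered_cds`, `variants_plus`, `variants_cds`.
#' @export
study_sample_stats <- function() {
  dir <- system.file("extdata", "study", package = "capdesign",
                     mustWork = TRUE)
  rd <- function(f) {
    readr::read_tsv(file.path(dir, f), col_types = readr::cols(),
                    progress = FALSE)
  }
  t1 <- rd("sample_sequencing.tsv")
  t2 <- rd("sample_regions_below.tsv")
  t3 <- rd("sample_bp_covered.tsv")
  t4 <- rd("sample_variants.tsv")
  out <- dplyr::left_join(t1, t2[, c("sample", "n_regions_min_below",
                                     "n_regions_never")], by = "sample")
  out <- dplyr::left_join(out, t3[, c("sample", "bp_covered_plus",
                                      "bp_covered_cds")], by = "sample")
  dplyr::left_join(out, t4[, c("sample", "variants_plus", "variants_cds")],
                   by = "sample")
}

#' Design-level constants of the capture study
#'
#' The study's two design sizes (full transcriptome-wide design and its
#' coding-only subset), the extra coding bases contributed by ORF prediction,
#' the cohort reproducibility counts, and the printed three-way design
#' partition sizes in Mb. These are inputs (printed constants), used for
#' percentage denominators and consistency checks.
#'
#' @return A list with elements `plus_bp`, `plus_regions`, `cds_bp`,
#'   `cds_regions`, `cds_extra_bp`, `repro` (named counts) and
#'   `venn_mb` (tibble: membership flags and size in Mb).
#' @export
study_design_constants <- function() {
  list(
    plus_bp = 151698592,
    plus_regions = 242914,
    cds_bp = 71254801,
    cds_regions = 244543,
    cds_extra_bp = 115044,
    repro = c(regions_all = 154318, regions_never = 4220,
              bp_all = 137071014, bp_never = 3642390),
    venn_mb = tibble::tibble(
      plus = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
      cds = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE),
      exome1 = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE),
      mb = c(34.77, 36.37, 17.57, 62.99, 0, 0.12, 0.09)
    )
  )
}

#' Check the arithmetic identities of per-sample statistics
#'
#' Verifies, per sample, that remaining reads equal mapped minus duplicate
#' reads and that the printed retained percentage equals
#' 100 x remaining / total rounded half away from zero to 1 decimal.
#'
#' @param stats Tibble as returned by [study_sample_stats()].
#' @return Tibble with `sample`, `reads_identity_ok`, `pct_ok`, `pass`.
#' @export
validate_sample_stats <- function(stats) {
  reads_ok <- stats$remaining_reads ==
    stats$mapped_reads - stats$duplicate_reads
  pct_ok <- round_half_away(100 * stats$remaining_reads / stats$total_reads,
                            1) == stats$remaining_pct
  tibble::tibble(sample = stats$sample, reads_identity_ok = reads_ok,
                 pct_ok = pct_ok, pass = reads_ok & pct_ok)
}

#' Study-level averages from per-sample statistics
#'
#' Recomputes every headline average from the per-sample rows: mean reads per
#' sample (nearest million), mean percentage of reads retained after
#' trimming/mapping/duplicate removal, mean on-target depth, mean number and
#' percentage of fully covered and of never covered regions at the 5x
#' threshold, mean covered base pairs (and percentage of the design) for the
#' full design and the coding subset, and mean variant counts. Percentages
#' are rounded half away from zero to 1 decimal; variant and region means to
#' the nearest integer.
#'
#' @param stats Tibble as returned by [study_sample_stats()].
#' @param design_sizes List with `plus_bp`, `plus_regions`, `cds_bp`,
#'   `cds_regions` (default [study_design_constants()]).
#' @return Tibble with `metric` and `value`, recomputable from `stats` alone.
#' @export
average_metrics <- function(stats, design_sizes = study_design_constants()) {
  stopifnot(nrow(stats) >= 1)
  n_reg <- design_sizes$plus_regions
  mean_fully <- n_reg - mean(stats$n_regions_min_below)
  tibble::tibble(
    metric = c(
      "mean_total_reads_millions", "mean_pct_reads_retained",
      "mean_on_target_depth_x",
      "mean_regions_fully_covered", "pct_regions_fully_covered",
      "mean_regions_never_covered", "pct_regions_never_covered",
      "mean_bp_covered_plus", "pct_bp_covered_plus",
      "mean_bp_covered_cds", "pct_bp_covered_cds",
      "mean_variants_plus", "mean_variants_cds"
    ),
    value = c(
      round_half_away(mean(stats$total_reads) / 1e6),
      round_half_away(mean(stats$remaining_pct), 1),
      round_half_away(mean(stats$depth_x), 1),
      round_half_away(mean_fully),
      round_half_away(100 * mean_fully / n_reg, 1),
      round_half_away(mean(stats$n_regions_never)),
      round_half_away(100 * mean(stats$n_regions_never) / n_reg, 1),
      round_half_away(mean(stats$bp_covered_plus)),
      round_half_away(100 * mean(stats$bp_covered_plus) /
                        design_sizes$plus_bp, 1),
      round_half_away(mean(stats$bp_covered_cds)),
      round_half_away(100 * mean(stats$bp_covered_cds) /
                        design_sizes$cds_bp, 1),
      round_half_away(mean(stats$variants_plus)),
      round_half_away(mean(stats$variants_cds))
    )
  )
}

#' Reproducibility counts as percentages of a design
#'
#' @param counts Named vector/list with `regions_all`, `regions_never`,
#'   `bp_all`, `bp_never` (cohort-wide reproducibility counts).
#' @param design_sizes List with `plus_regions` and `plus_bp` denominators.
#' @return Tibble with `metric` and `value` (percent, 1 decimal).
#' @export
reproducibility_percentages <- function(counts,
                                        design_sizes =
                                          study_design_constants()) {
  counts <- as.list(counts)
  if (counts$regions_all > design_sizes$plus_regions ||
      counts$regions_never > design_sizes$plus_regions ||
      counts$bp_all > design_sizes$plus_bp ||
      counts$bp_never > design_sizes$plus_bp) {
    stop("count exceeds its design size", call. = FALSE)
  }
  tibble::tibble(
    metric = c("pct_regions_covered_all", "pct_regions_never_all",
               "pct_bp_covered_all", "pct_bp_never_all"),
    value = c(
      round_half_away(100 * counts$regions_all / design_sizes$plus_regions, 1),
      round_half_away(100 * counts$regions_never / design_sizes$plus_regions, 1),
      round_half_away(100 * counts$bp_all / design_sizes$plus_bp, 1),
      round_half_away(100 * counts$bp_never / design_sizes$plus_bp, 1)
    )
  )
}
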