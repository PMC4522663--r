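#' Assign regions to the three performance groups
#'
#' Partitions the design regions by their coverage behaviour across the whole
#' cohort: group 1 holds regions fully covered at the depth threshold in
#' every sample; group 3 holds regions whose maximum depth stayed below the
#' threshold in every sample; group 2 is everything in between (regions that
#' at least partially missed the threshold in some sample). The three groups
#' are disjoint and exhaustive by construction.
#'
#' @param summaries List of `coverage_summary` objects (>= 1), all computed
#'   on the same design.
#' @return Tibble with `region_id` and `group` (integer 1/2/3).
#' @export
assign_groups <- function(summaries) {
  stopifnot(length(summaries) >= 1)
  ids <- summaries[[1]]$regions$region_id
  fully <- rep(TRUE, length(ids))
  never <- rep(TRUE, length(ids))
  for (s in summaries) {
    r <- s$regions
    if (!identical(r$region_id, ids)) {
      stop("samples do not share a region universe", call. = FALSE)
    }
    fully <- fully & r$fully_covered
    never <- never & r$never_covered
  }
  tibble::tibble(
    region_id = ids,
    group = dplyr::case_when(fully ~ 1L, never ~ 3L, TRUE ~ 2L)
  )
}

#' GC content of design regions
#'
#' Percentage of G+C over the unambiguous bases (A, C, G, T, case
#' insensitive) of each region. Ambiguous bases (N etc.) are excluded from
#' the denominator; a region with no unambiguous base gets `NA` and is
#' flagged.
#'
#' @param genome A [Biostrings::DNAStringSet] (or FASTA path).
#' @param regions Interval tibble or `capture_design`.
#' @return Tibble with `region_id` (when available), `chrom`, `start`, `end`,
#'   `gc` (percent, `NA` when undefined) and `all_ambiguous`.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "ATGCANGC"))
#' gc_content(g, tibble::tibble(chrom = "chr1", start = 0, end = 8))
#' @export
gc_content <- function(genome, regions) {
  if (is.character(genome)) genome <- read_genome(genome)
  if (inherits(regions, "capture_design")) regions <- regions$regions
  check_intervals(regions, "regions")
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  unknown <- setdiff(unique(as.character(regions$chrom)), names(lens))
  if (length(unknown) > 0) {
    stop("region on sequence absent from genome: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(regions$end > lens[as.character(regions$chrom)])) {
    stop("region extends beyond sequence end", call. = FALSE)
  }
  seqs <- Biostrings::subseq(genome[as.character(regions$chrom)],
                             start = regions$start + 1L, end = regions$end)
  counts <- Biostrings::letterFrequency(seqs, letters = c("A", "C", "G", "T"))
  denom <- rowSums(counts)
  gc <- ifelse(denom > 0, 100 * (counts[, "C"] + counts[, "G"]) / denom,
               NA_real_)
  out <- tibble::tibble(chrom = regions$chrom, start = regions$start,
                        end = regions$end, gc = gc,
                        all_ambiguous = denom == 0)
  if ("region_id" %in% names(regions)) {
    out <- dplyr::bind_cols(tibble::tibble(region_id = regions$region_id), out)
  }
  out
}

#' Sequenceable-GC cut-offs from a reference group
#'
#' Regions that were completely covered in every sample are taken as the
#' reliable reference for what GC content is sequenceable; the cut-offs are
#' the 2.5th and 97.5th percentiles of that group's per-region GC values
#' (linear interpolation between order statistics, [stats::quantile()]
#' type 7 by default).
#'
#' @param gc Numeric vector of per-region GC percentages (NAs dropped).
#' @param lo_pct,hi_pct Percentile bounds (defaults 2.5 and 97.5).
#' @param type Quantile algorithm passed to [stats::quantile()].
#' @return Named numeric vector `c(lo = , hi = )`.
#' @export
gc_cutoffs <- function(gc, lo_pct = 2.5, hi_pct = 97.5, type = 7) {
  gc <- gc[is.finite(gc)]
  if (length(gc) < 2) {
    stop("need at least two finite GC values", call. = FALSE)
  }
  q <- stats::quantile(gc, probs = c(lo_pct, hi_pct) / 100, type = type,
                       names = FALSE)
  c(lo = q[1], hi = q[2])
}

#' Flag regions overlapping bait-exclusion tracks
#'
#' A region is flagged for a track when it overlaps it by at least one base
#' ("at least partially excluded"). The tracks model the vendor's bait-design
#' exclusions: unknown sequence (Ns), repeats/low-complexity, and the
#' vendor's prediction of regions that will not be sequenced (a subset of
#' the former two).
#'
#' @param d A `capture_design`.
#' @param ns,repeats,predicted_unseq Interval tibbles (normalized or not).
#' @return Tibble with `region_id`, `has_ns`, `has_repeat`, `any_exclusion`
#'   (Ns or repeats) and `predicted_unseq`.
#' @export
annotate_exclusions <- function(d, ns, repeats, predicted_unseq) {
  stopifnot(inherits(d, "capture_design"))
  gr <- as_granges(d$regions)
  flag <- function(track) {
    check_intervals(track, "track")
    if (nrow(track) == 0) return(rep(FALSE, length(gr)))
    suppressWarnings(GenomicRanges::countOverlaps(gr, as_granges(track))) > 0
  }
  has_ns <- flag(ns)
  has_repeat <- flag(repeats)
  tibble::tibble(
    region_id = d$regions$region_id,
    has_ns = has_ns,
    has_repeat = has_repeat,
    any_exclusion = has_ns | has_repeat,
    predicted_unseq = flag(predicted_unseq)
  )
}

#' GC and bait-exclusion risk report per performance group
#'
#' For each group, summarises the per-region GC distribution and the overlap
#' with the exclusion tracks, and combines them into two "at risk of reduced
#' sequencing" criteria: variant A flags a region with extreme GC (strictly
#' outside the cut-offs) *or* any bait-design exclusion (Ns/repeats);
#' variant B flags extreme GC *or* predicted-unsequenced. The GC median and
#' extreme proportion are also recomputed after dropping the
#' predicted-unsequenced regions and after dropping all Ns/repeat-excluded
#' regions, to show whether the remaining regions shift.
#'
#' @param groups Tibble from [assign_groups()].
#' @param gc Tibble from [gc_content()] (or numeric vector aligned on
#'   region id).
#' @param cutoffs Numeric `c(lo, hi)` from [gc_cutoffs()].
#' @param flags Tibble from [annotate_exclusions()].
#' @return A `gc_risk_report` object: list with `by_group` (one row per
#'   group) and `regions` (the joined per-region table, used by
#'   [ggplot2::autoplot()]).
#' @export
risk_report <- function(groups, gc, cutoffs, flags) {
  if (is.numeric(gc)) {
    gc <- tibble::tibble(region_id = groups$region_id, gc = gc)
  }
  stopifnot(length(cutoffs) == 2, cutoffs[1] < cutoffs[2] ||
              cutoffs[1] == cutoffs[2])
  reg <- dplyr::inner_join(groups, gc[, c("region_id", "gc")], by = "region_id")
  reg <- dplyr::inner_join(reg, flags, by = "region_id")
  if (nrow(reg) != nrow(groups)) {
    stop("groups, gc and flags do not align on region_id", call. = FALSE)
  }
  lo <- cutoffs[[1]]; hi <- cutoffs[[2]]
  reg$extreme_gc <- !is.na(reg$gc) & (reg$gc < lo | reg$gc > hi)
  pct <- function(x) round_half_away(100 * mean(x), 1)
  by_group <- dplyr::summarise(
    dplyr::group_by(reg, .data$group),
    n = dplyr::n(),
    median_gc = round_half_away(stats::median(.data$gc, na.rm = TRUE), 1),
    pct_extreme_gc = pct(.data$extreme_gc),
    pct_ns = pct(.data$has_ns),
    pct_repeat = pct(.data$has_repeat),
    pct_any_exclusion = pct(.data$any_exclusion),
    pct_predicted_unseq = pct(.data$predicted_unseq),
    pct_at_risk_exclusion = pct(.data$extreme_gc | .data$any_exclusion),
    pct_at_risk_predicted = pct(.data$extreme_gc | .data$predicted_unseq),
    median_gc_drop_predicted = round_half_away(
      stats::median(.data$gc[!.data$predicted_unseq], na.rm = TRUE), 1),
    pct_extreme_gc_drop_predicted = pct_subset(
      .data$extreme_gc, !.data$predicted_unseq),
    median_gc_drop_exclusion = round_half_away(
      stats::median(.data$gc[!.data$any_exclusion], na.rm = TRUE), 1),
    pct_extreme_gc_drop_exclusion = pct_subset(
      .data$extreme_gc, !.data$any_exclusion),
    .groups = "drop"
  )
  structure(list(by_group = by_group, regions = reg,
                 cutoffs = c(lo = lo, hi = hi)),
            class = "gc_risk_report")
}

pct_subset <- function(x, keep) {
  if (!any(keep)) return(NA_real_)
  round_half_away(100 * mean(x[keep]), 1)
}

#' @export
print.gc_risk_report <- function(x, ...) {
  cat("<gc_risk_report> GC cut-offs: ", x$cutoffs[["lo"]], "% - ",
      x$cutoffs[["hi"]], "%\n", sep = "")
  print(x$by_group)
  invisible(x)
}

#' @method tidy gc_risk_report
#' @export
tidy.gc_risk_report <- function(x, ...) x$regions

#' @method glance gc_risk_report
#' @export
glance.gc_risk_report <- function(x, ...) x$by_group

#' Completeness stratified by region size
#'
#' Longer regions need every one of their bases to reach the threshold, so
#' the chance of complete coverage drops with region length. This compares,
#' per sample, the proportion of fully covered regions among regions shorter
#' than `size_cutoff` against regions at least that long, and reports the
#' averaged difference in percentage points.
#'
#' @param d A `capture_design`.
#' @param summaries List of `coverage_summary` objects on `d`.
#' @param size_cutoff Length cut in bp (default 260, a typical mean region
#'   size of older exon-centric designs).
#' @return List with `per_sample` (tibble: `sample_id`, `pct_full_short`,
#'   `pct_full_long`, `diff_points`) and `mean_diff_points`.
#' @export
size_stratified_completeness <- function(d, summaries, size_cutoff = 260) {
  stopifnot(inherits(d, "capture_design"), length(summaries) >= 1)
  per <- purrr::map_dfr(summaries, function(s) {
    r <- s$regions
    short <- r$length < size_cutoff
    tibble::tibble(
      sample_id = s$summary$sample_id,
      pct_full_short = 100 * mean(r$fully_covered[short]),
      pct_full_long = 100 * mean(r$fully_covered[!short])
    )
  })
  per$diff_points <- per$pct_full_short - per$pct_full_long
  list(per_sample = per,
       mean_diff_points = round_half_away(mean(per$diff_points), 1))
}
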