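#' Per-region and per-sample threshold coverage
#'
#' For every design region, computes the minimum and maximum per-base depth,
#' the number of bases at or above `threshold`, and whether the region is
#' fully covered (every base >= threshold) or never covered (maximum depth
#' below threshold). Positions absent from the sparse depth track count as
#' depth 0. The comparison is inclusive: "at least 5x" means depth >= 5, and
#' a region whose maximum depth is 4 reads is never covered at 5x.
#'
#' @param depth Depth tibble (`chrom`, `pos` 0-based, `depth`), as returned
#'   by [read_depth_track()] or [simulate_depth()].
#' @param design A `capture_design`.
#' @param threshold Depth cut-off in reads (default 5, the usual minimum for
#'   variant calling).
#' @param chrom_sizes Optional tibble (`chrom`, `size`) or named vector; when
#'   `NULL`, sizes are inferred from the design and the track.
#' @param sample_id Optional sample identifier carried into the summary.
#' @return A `coverage_summary` object: list with `summary` (one-row tibble:
#'   `sample_id`, `threshold`, `n_regions`, `n_fully_covered`, `n_min_below`,
#'   `n_never`, `covered_bp`, `total_bp`, `pct_bp_covered`,
#'   `mean_on_target_depth`) and `regions` (per-region tibble with
#'   `min_depth`, `max_depth`, `covered_bp`, `frac_covered`, `fully_covered`,
#'   `never_covered`). Use [generics::tidy()] / [generics::glance()] to
#'   extract the two tables.
#' @export
sample_coverage_summary <- function(depth, design, threshold = 5,
                                    chrom_sizes = NULL,
                                    sample_id = NA_character_) {
  stopifnot(inherits(design, "capture_design"), threshold >= 1)
  regions <- design$regions
  if (nrow(regions) == 0) stop("empty design", call. = FALSE)
  sizes <- coverage_chrom_sizes(chrom_sizes, regions, depth)
  cov <- depth_rle_list(depth, sizes)

  per_chrom <- lapply(split(regions, regions$chrom), function(r) {
    ch <- as.character(r$chrom[1])
    v <- IRanges::Views(cov[[ch]],
                        IRanges::IRanges(start = r$start + 1L, end = r$end))
    hit <- IRanges::Views(S4Vectors::Rle(as.integer(
      S4Vectors::runValue(cov[[ch]]) >= threshold),
      S4Vectors::runLength(cov[[ch]])),
      IRanges::IRanges(start = r$start + 1L, end = r$end))
    tibble::tibble(
      region_id = r$region_id, chrom = r$chrom, start = r$start, end = r$end,
      length = r$end - r$start,
      min_depth = IRanges::viewMins(v),
      max_depth = IRanges::viewMaxs(v),
      depth_sum = IRanges::viewSums(v),
      covered_bp = IRanges::viewSums(hit)
    )
  })
  reg <- dplyr::arrange(dplyr::bind_rows(per_chrom), .data$region_id)
  reg <- dplyr::mutate(
    reg,
    frac_covered = .data$covered_bp / .data$length,
    fully_covered = .data$covered_bp == .data$length,
    never_covered = .data$max_depth < threshold
  )
  total_bp <- sum(reg$length)
  summary <- tibble::tibble(
    sample_id = sample_id,
    threshold = threshold,
    n_regions = nrow(reg),
    n_fully_covered = sum(reg$fully_covered),
    n_min_below = sum(!reg$fully_covered),
    n_never = sum(reg$never_covered),
    covered_bp = sum(reg$covered_bp),
    total_bp = total_bp,
    pct_bp_covered = round_half_away(100 * sum(reg$covered_bp) / total_bp, 1),
    mean_on_target_depth = round_half_away(sum(reg$depth_sum) / total_bp, 1)
  )
  structure(list(summary = summary,
                 regions = dplyr::select(reg, -"depth_sum")),
            class = "coverage_summary")
}

coverage_chrom_sizes <- function(chrom_sizes, regions, depth) {
  if (!is.null(chrom_sizes)) {
    sizes <- as_chrom_sizes(chrom_sizes)
  } else {
    ends <- dplyr::bind_rows(
      tibble::tibble(chrom = as.character(regions$chrom), end = regions$end),
      if (nrow(depth) > 0) {
        tibble::tibble(chrom = as.character(depth$chrom),
                       end = depth$pos + 1L)
      }
    )
    sizes <- as_chrom_sizes(NULL, fallback = ends)
  }
  missing <- setdiff(unique(as.character(regions$chrom)), names(sizes))
  if (length(missing) > 0) {
    stop("no chromosome size for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sizes
}

#' @export
print.coverage_summary <- function(x, ...) {
  s <- x$summary
  cat("<coverage_summary> sample ", s$sample_id, " at >=", s$threshold,
      "x\n", sep = "")
  cat("  regions fully covered: ", s$n_fully_covered, "/", s$n_regions,
      "; never covered: ", s$n_never, "\n", sep = "")
  cat("  base pairs covered: ", s$covered_bp, "/", s$total_bp, " (",
      s$pct_bp_covered, "%), mean on-target depth ",
      s$mean_on_target_depth, "x\n", sep = "")
  invisible(x)
}

#' @method tidy coverage_summary
#' @export
tidy.coverage_summary <- function(x, ...) x$regions

#' @method glance coverage_summary
#' @export
glance.coverage_summary <- function(x, ...) x$summary

#' Breadth-of-coverage curve over regions
#'
#' For each grid value g, the percentage of regions covered at least g% at
#' the depth threshold (the per-region fraction covered comes from
#' [sample_coverage_summary()]). The curve is non-increasing in g.
#'
#' @param regions Per-region coverage tibble (with a `frac_covered` column)
#'   or a `coverage_summary` object.
#' @param grid Integer percentages (default `0:100`).
#' @return Tibble with `min_pct_covered` and `pct_regions`.
#' @export
coverage_fraction_curve <- function(regions, grid = 0:100) {
  if (inherits(regions, "coverage_summary")) regions <- regions$regions
  stopifnot(nrow(regions) > 0, all(grid >= 0 & grid <= 100))
  tibble::tibble(
    min_pct_covered = grid,
    pct_regions = vapply(grid, function(g) {
      100 * mean(regions$frac_covered >= g / 100)
    }, numeric(1))
  )
}

#' Percentage of reads on target
#'
#' A read is on target when it overlaps at least one design base (any
#' overlap, half-open coordinates: a read starting exactly at a region's end
#' does not overlap it). Reads on chromosomes absent from the design count as
#' off-target.
#'
#' @param reads Read tibble (`chrom`, `start`, `end`) from
#'   [read_alignments()] or [simulate_reads()].
#' @param design A `capture_design`.
#' @return Tibble with one row per chromosome plus a final `"all"` row:
#'   `chrom`, `reads_on_target`, `total_reads`, `pct_on_target` (1 decimal).
#' @export
pct_reads_on_target <- function(reads, design) {
  stopifnot(inherits(design, "capture_design"))
  check_intervals(reads, "reads")
  if (nrow(reads) == 0) {
    return(tibble::tibble(chrom = "all", reads_on_target = 0L,
                          total_reads = 0L, pct_on_target = NA_real_))
  }
  hits <- suppressWarnings(GenomicRanges::countOverlaps(
    as_granges(reads), as_granges(design$regions))) > 0
  per <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(chrom = as.character(reads$chrom),
                                   on = hits), .data$chrom),
    reads_on_target = sum(.data$on), total_reads = dplyr::n(),
    .groups = "drop"
  )
  per <- dplyr::arrange(per, .data$chrom)
  all_row <- tibble::tibble(chrom = "all",
                            reads_on_target = sum(per$reads_on_target),
                            total_reads = sum(per$total_reads))
  out <- dplyr::bind_rows(per, all_row)
  dplyr::mutate(out, pct_on_target = round_half_away(
    100 * .data$reads_on_target / .data$total_reads, 1))
}

#' Multi-sample reproducibility of coverage
#'
#' A region is reproducibly covered when it is fully covered at the threshold
#' in *every* sample, and reproducibly missed when its maximum depth is below
#' the threshold in every sample. A base is reproducibly covered when its
#' depth reaches the threshold in every sample, and reproducibly missed when
#' it never does.
#'
#' @param summaries List of `coverage_summary` objects, one per sample, all
#'   computed on `design`.
#' @param design The shared `capture_design`.
#' @param tracks List of depth tibbles, parallel to `summaries` (needed for
#'   the per-base counts).
#' @param threshold Depth cut-off (default 5).
#' @param chrom_sizes Optional chromosome sizes.
#' @return One-row tibble: `n_samples`, `regions_fully_covered_all`,
#'   `regions_never_all`, `bp_covered_all`, `bp_never_all` plus the
#'   corresponding percentages of the design (1 decimal).
#' @export
reproducibility <- function(summaries, design, tracks, threshold = 5,
                            chrom_sizes = NULL) {
  stopifnot(inherits(design, "capture_design"), length(summaries) >= 2,
            length(tracks) == length(summaries))
  ids <- design$regions$region_id
  fully <- rep(TRUE, length(ids))
  never <- rep(TRUE, length(ids))
  for (s in summaries) {
    r <- s$regions
    if (!identical(r$region_id, ids)) {
      stop("coverage summaries were not computed on the same design",
           call. = FALSE)
    }
    fully <- fully & r$fully_covered
    never <- never & r$never_covered
  }
  sizes <- coverage_chrom_sizes(chrom_sizes, design$regions,
                                dplyr::bind_rows(tracks))
  gr <- as_granges(design$regions)
  # per-base AND across samples of (depth >= threshold) / (depth < threshold)
  bp_all <- 0; bp_never <- 0
  for (ch in unique(as.character(design$regions$chrom))) {
    covered <- NULL; missed <- NULL
    for (tr in tracks) {
      rle <- depth_rle_list(tr[tr$chrom == ch, ],
                            sizes[ch])[[ch]]
      hit <- rle >= threshold
      covered <- if (is.null(covered)) hit else covered & hit
      missed <- if (is.null(missed)) !hit else missed & !hit
    }
    r <- design$regions[design$regions$chrom == ch, ]
    ir <- IRanges::IRanges(start = r$start + 1L, end = r$end)
    to_int <- function(x) S4Vectors::Rle(as.integer(S4Vectors::runValue(x)),
                                         S4Vectors::runLength(x))
    bp_all <- bp_all + sum(IRanges::viewSums(IRanges::Views(to_int(covered), ir)))
    bp_never <- bp_never + sum(IRanges::viewSums(IRanges::Views(to_int(missed), ir)))
  }
  total_bp <- sum(design$regions$end - design$regions$start)
  tibble::tibble(
    n_samples = length(summaries),
    threshold = threshold,
    regions_fully_covered_all = sum(fully),
    regions_never_all = sum(never),
    bp_covered_all = bp_all,
    bp_never_all = bp_never,
    pct_regions_fully_covered_all = round_half_away(
      100 * sum(fully) / length(ids), 1),
    pct_regions_never_all = round_half_away(100 * sum(never) / length(ids), 1),
    pct_bp_covered_all = round_half_away(100 * bp_all / total_bp, 1),
    pct_bp_never_all = round_half_away(100 * bp_never / total_bp, 1)
  )
}

#' Project a sample's coverage onto a subset design
#'
#' Re-evaluates a depth track, generated under a superset capture, over the
#' regions of a subset design. No depth rescaling is applied even though the
#' subset would have enjoyed a denser bait tiling, so the projection is, if
#' anything, conservative.
#'
#' @inheritParams sample_coverage_summary
#' @param subset The subset `capture_design`.
#' @return A `coverage_summary`, exactly as [sample_coverage_summary()] on
#'   the subset design.
#' @export
project_to_subset <- function(depth, subset, threshold = 5,
                              chrom_sizes = NULL, sample_id = NA_character_) {
  sample_coverage_summary(depth, subset, threshold = threshold,
                          chrom_sizes = chrom_sizes, sample_id = sample_id)
}
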