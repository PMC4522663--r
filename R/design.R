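#' Build a capture design from annotation sources
#'
#' Reproduces the construction used for transcriptome-wide capture designs:
#' the union of all source tracks is taken, regions on excluded chromosomes
#' (by default the mitochondrial genome, to avoid over-capturing it relative
#' to nuclear DNA) are dropped, overlapping and book-ended regions are merged,
#' regions under `min_len` bp are padded to `min_len` (the vendor padding
#' rule), and the result is re-merged and given dense region ids in
#' (chrom, start) order.
#'
#' @param sources A list of interval tibbles (or a single tibble), e.g.
#'   exons, newly discovered protein-coding exons, microRNAs, long non-coding
#'   and antisense transcripts.
#' @param name Design name.
#' @param chrom_sizes Tibble (`chrom`, `size`) or named vector.
#' @param exclude_chroms Chromosomes dropped from the design
#'   (default `"chrM"`).
#' @param min_len Minimum region length after padding (default 100 bp); use
#'   `min_len = 1` to disable padding.
#' @return A `capture_design` object: a list with `name`, `regions` (tibble
#'   `region_id`, `chrom`, `start`, `end`) and `provenance`.
#' @examples
#' sizes <- tibble::tibble(chrom = "chr1", size = 10000)
#' exons <- tibble::tibble(chrom = "chr1", start = c(0, 150), end = c(200, 400))
#' build_design(exons, "toy", sizes)
#' @export
build_design <- function(sources, name, chrom_sizes,
                         exclude_chroms = "chrM", min_len = 100) {
  if (is.data.frame(sources)) sources <- list(sources)
  stopifnot(length(sources) >= 1)
  provenance <- names(sources)
  if (is.null(provenance)) provenance <- paste0("source", seq_along(sources))
  for (s in sources) check_intervals(s, "sources")
  pooled <- dplyr::bind_rows(lapply(sources, function(s) {
    s[, c("chrom", "start", "end")]
  }))
  pooled <- pooled[!(as.character(pooled$chrom) %in% exclude_chroms), ]
  if (nrow(pooled) == 0) {
    stop("design is empty after excluding chromosomes: ",
         paste(exclude_chroms, collapse = ", "), call. = FALSE)
  }
  regions <- merge_intervals(pooled)
  regions <- pad_intervals(regions, min_len = min_len,
                           chrom_sizes = chrom_sizes)
  new_capture_design(regions, name, provenance)
}

new_capture_design <- function(regions, name, provenance) {
  regions <- dplyr::arrange(regions, .data$chrom, .data$start)
  regions <- tibble::tibble(region_id = seq_len(nrow(regions)),
                            chrom = regions$chrom, start = regions$start,
                            end = regions$end)
  structure(list(name = name, regions = regions, provenance = provenance),
            class = "capture_design")
}

#' @export
print.capture_design <- function(x, ...) {
  st <- design_stats(x)
  cat("<capture_design> ", x$name, "\n", sep = "")
  cat("  ", st$n_regions, " regions, ", format(st$total_bp, big.mark = ","),
      " bp (mean region ", st$mean_region_bp, " bp)\n", sep = "")
  cat("  sources: ", paste(x$provenance, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @method tidy capture_design
#' @export
tidy.capture_design <- function(x, ...) x$regions

#' @method glance capture_design
#' @export
glance.capture_design <- function(x, ...) design_stats(x)

#' Derive a subset design
#'
#' Intersects a parent design with a `keep` track (e.g. coding sequence only,
#' dropping 5'/3' UTRs) and re-applies merge and padding. Because one parent
#' region can be split by several kept fragments, the subset can contain
#' *more* regions than the parent despite covering fewer bases.
#'
#' @param parent A `capture_design`.
#' @param keep Interval tibble of bases to retain.
#' @param name Name of the subset design.
#' @param chrom_sizes Tibble (`chrom`, `size`) or named vector; defaults to
#'   sizes inferred from the parent regions.
#' @param min_len Padding rule re-applied to the fragments (default 100 bp,
#'   as the vendor pads whatever design it receives); `min_len = 1` disables
#'   re-padding.
#' @param extra Optional interval tibble of keep-only intervals absent from
#'   the parent (e.g. additional coding exons found by ORF prediction),
#'   unioned in before padding.
#' @return A `capture_design`.
#' @export
subset_design <- function(parent, keep, name, chrom_sizes = NULL,
                          min_len = 100, extra = NULL) {
  stopifnot(inherits(parent, "capture_design"))
  check_intervals(keep, "keep")
  regions <- intersect_intervals(parent$regions, keep)
  if (!is.null(extra)) {
    check_intervals(extra, "extra")
    regions <- merge_intervals(dplyr::bind_rows(regions, extra))
  }
  if (nrow(regions) == 0) {
    stop("subset design is empty: `keep` does not intersect the parent",
         call. = FALSE)
  }
  sizes <- as_chrom_sizes(chrom_sizes, fallback = parent$regions)
  regions <- pad_intervals(regions, min_len = min_len, chrom_sizes = sizes)
  new_capture_design(regions, name,
                     provenance = c(parent$name, "subset"))
}

#' Summary statistics of a design
#'
#' @param d A `capture_design`.
#' @return One-row tibble: `name`, `n_regions`, `total_bp`, `mean_region_bp`
#'   (1 decimal) and `mean_region_bp_reported` (integer-truncated, the
#'   convention used in printed design summaries, e.g. 151,698,592 bp over
#'   242,914 regions is reported as a 624 bp mean).
#' @export
design_stats <- function(d) {
  stopifnot(inherits(d, "capture_design"))
  if (nrow(d$regions) == 0) stop("empty design", call. = FALSE)
  n <- nrow(d$regions)
  bp <- sum(d$regions$end - d$regions$start)
  tibble::tibble(
    name = d$name,
    n_regions = n,
    total_bp = bp,
    mean_region_bp = round_half_away(bp / n, 1),
    mean_region_bp_reported = as.integer(bp / n)
  )
}
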