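#' Merge overlapping and nearby intervals
#'
#' Unions intervals that overlap or are separated by at most `gap` bases.
#' With `gap = 0` (the default, matching `bedtools merge`), book-ended
#' intervals — one ending exactly where the next starts — are merged too.
#' Labels are dropped: a merged region has no unique source label.
#'
#' @param x Interval tibble (`chrom`, `start`, `end`; 0-based half-open).
#' @param gap Maximum separation in bp that is still merged (default 0).
#' @return Normalized interval tibble: non-overlapping, sorted by
#'   (chrom, start).
#' @examples
#' x <- tibble::tibble(chrom = "chr1", start = c(0, 10), end = c(10, 20))
#' merge_intervals(x) # one interval [0, 20)
#' @export
merge_intervals <- function(x, gap = 0) {
  check_intervals(x)
  stopifnot(gap >= 0)
  if (nrow(x) == 0) return(as_interval_tbl(GenomicRanges::GRanges()))
  as_interval_tbl(GenomicRanges::reduce(as_granges(x), min.gapwidth = gap + 1))
}

#' Intersect two interval sets
#'
#' @param a,b Interval tibbles.
#' @return Normalized interval tibble containing exactly the bases present in
#'   both `a` and `b`.
#' @export
intersect_intervals <- function(a, b) {
  check_intervals(a, "a"); check_intervals(b, "b")
  as_interval_tbl(suppressWarnings(
    GenomicRanges::intersect(as_granges(a), as_granges(b))))
}

#' Subtract one interval set from another
#'
#' @param a,b Interval tibbles.
#' @return Normalized interval tibble with the bases of `a` not in `b`.
#' @export
subtract_intervals <- function(a, b) {
  check_intervals(a, "a"); check_intervals(b, "b")
  as_interval_tbl(suppressWarnings(
    GenomicRanges::setdiff(as_granges(a), as_granges(b))))
}

#' Pad short intervals to a minimum length
#'
#' Intervals shorter than `min_len` are extended symmetrically around their
#' midpoint; when the padding is odd, the extra base goes downstream (higher
#' coordinate). Intervals are kept inside `[0, chromosome length)`: padding
#' that would run off one end is pushed back from the other, so the padded
#' interval keeps length `min(min_len, chromosome length)`. The result is
#' re-normalized, since padding can make neighbours overlap.
#'
#' @param x Interval tibble.
#' @param min_len Minimum interval length in bp (default 100, the padding
#'   rule used by capture-bait vendors).
#' @param chrom_sizes Tibble (`chrom`, `size`) or named vector covering every
#'   chromosome in `x`.
#' @return Normalized interval tibble with every interval of length
#'   >= `min(min_len, chromosome length)`.
#' @examples
#' sizes <- tibble::tibble(chrom = "chr1", size = 1000)
#' x <- tibble::tibble(chrom = "chr1", start = 50, end = 60)
#' pad_intervals(x, 100, sizes) # [5, 105)
#' @export
pad_intervals <- function(x, min_len = 100, chrom_sizes) {
  check_intervals(x)
  if (nrow(x) == 0) return(merge_intervals(x))
  sizes <- as_chrom_sizes(chrom_sizes)
  unknown <- setdiff(unique(as.character(x$chrom)), names(sizes))
  if (length(unknown) > 0) {
    stop("interval on unknown chromosome: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  len <- x$end - x$start
  chrom_len <- sizes[as.character(x$chrom)]
  target <- pmin(min_len, chrom_len)
  pad <- pmax(target - len, 0)
  start <- x$start - floor(pad / 2)
  end <- x$end + ceiling(pad / 2)
  # clip-then-extend: keep the target length when chromosome space allows
  over_left <- pmax(0 - start, 0)
  start <- start + over_left
  end <- end + over_left
  over_right <- pmax(end - chrom_len, 0)
  end <- end - over_right
  start <- pmax(start - over_right, 0)
  merge_intervals(tibble::tibble(chrom = x$chrom, start = as.integer(start),
                                 end = as.integer(end)))
}

#' Total length of an interval set
#'
#' @param x Interval tibble. Normalized first, so overlapping input does not
#'   double-count bases.
#' @return Total covered length in bp.
#' @export
total_length <- function(x) {
  check_intervals(x)
  if (nrow(x) == 0) return(0L)
  m <- merge_intervals(x)
  sum(m$end - m$start)
}
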