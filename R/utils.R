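#' Round half away from zero
#'
#' Printed sequencing-statistics tables conventionally round 0.5 away from
#' zero, unlike [base::round()] (banker's rounding). All percentages and
#' means reported by this package go through this helper.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_away(0.5)   # 1, where round(0.5) is 0
#' round_half_away(68.325, 1)
#' @export
round_half_away <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Validate an interval tibble: chrom/start/end, 0-based half-open.
check_intervals <- function(x, arg = "x") {
  if (!is.data.frame(x)) {
    stop("`", arg, "` must be a data frame of intervals", call. = FALSE)
  }
  needed <- c("chrom", "start", "end")
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0) {
    stop("`", arg, "` is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(as.character(x$chrom)))) {
    stop("`", arg, "` has empty chromosome names", call. = FALSE)
  }
  if (any(x$start < 0)) {
    stop("`", arg, "` has negative start coordinates", call. = FALSE)
  }
  if (any(x$end <= x$start)) {
    bad <- which(x$end <= x$start)[1]
    stop("`", arg, "` has end <= start at row ", bad,
         " (coordinates are 0-based half-open)", call. = FALSE)
  }
  invisible(x)
}

# tibble (0-based half-open) -> GRanges (1-based closed)
as_granges <- function(x) {
  if (nrow(x) == 0) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

# GRanges -> tibble (0-based half-open), sorted by (chrom, start)
as_interval_tbl <- function(gr) {
  if (length(gr) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer()))
  }
  out <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  dplyr::arrange(out, .data$chrom, .data$start)
}

# Named integer vector of chromosome lengths from a tibble(chrom, size),
# a named vector, or NULL (inferred from a fallback interval tibble).
as_chrom_sizes <- function(chrom_sizes, fallback = NULL) {
  if (is.null(chrom_sizes)) {
    if (is.null(fallback) || nrow(fallback) == 0) {
      stop("chromosome sizes are required and could not be inferred",
           call. = FALSE)
    }
    sizes <- tapply(fallback$end, as.character(fallback$chrom), max)
    return(stats::setNames(as.integer(sizes), names(sizes)))
  }
  if (is.data.frame(chrom_sizes)) {
    return(stats::setNames(as.integer(chrom_sizes$size),
                           as.character(chrom_sizes$chrom)))
  }
  stats::setNames(as.integer(chrom_sizes), names(chrom_sizes))
}

# Per-chromosome integer Rle coverage from a sparse depth tibble
# (chrom, pos 0-based, depth). Absent positions are depth 0.
depth_rle_list <- function(depth, chrom_sizes) {
  sizes <- as_chrom_sizes(chrom_sizes,
                          fallback = if (nrow(depth) > 0) {
                            tibble::tibble(chrom = depth$chrom,
                                           end = depth$pos + 1L)
                          })
  out <- lapply(names(sizes), function(ch) {
    len <- sizes[[ch]]
    v <- integer(len)
    rows <- depth$chrom == ch
    if (any(rows)) {
      p <- depth$pos[rows]
      if (any(p >= len)) {
        stop("depth positions beyond chromosome length on ", ch,
             call. = FALSE)
      }
      v[p + 1L] <- depth$depth[rows]
    }
    S4Vectors::Rle(v)
  })
  names(out) <- names(sizes)
  IRanges::RleList(out, compress = FALSE)
}
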