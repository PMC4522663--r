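# Brute-force per-base boolean-mask oracles, kept independent of the
# interval engine: every operation is re-derived on a plain logical vector.

mask_from_intervals <- function(x, chroms, len) {
  masks <- lapply(stats::setNames(chroms, chroms), function(ch) {
    m <- logical(len)
    rows <- x[x$chrom == ch, , drop = FALSE]
    if (nrow(rows) > 0) {
      for (i in seq_len(nrow(rows))) {
        m[(rows$start[i] + 1):rows$end[i]] <- TRUE
      }
    }
    m
  })
  masks
}

intervals_from_mask <- function(masks) {
  out <- lapply(names(masks), function(ch) {
    r <- rle(masks[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    tibble::tibble(chrom = ch, start = as.integer(starts[keep]),
                   end = as.integer(ends[keep]))
  })
  x <- dplyr::bind_rows(out)
  dplyr::arrange(x, chrom, start)
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), len = 10000,
                             max_len = 400) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(len - max_len, n, replace = TRUE) - 1L
  width <- sample.int(max_len, n, replace = TRUE)
  tibble::tibble(chrom = chrom, start = start,
                 end = pmin(start + width, len))
}

# sparse random depth track over given chromosomes
random_depth <- function(chroms = c("chr1", "chr2"), len = 10000,
                         density = 0.4, max_depth = 10) {
  out <- lapply(chroms, function(ch) {
    pos <- which(stats::runif(len) < density) - 1L
    tibble::tibble(chrom = ch, pos = pos,
                   depth = sample.int(max_depth, length(pos), replace = TRUE))
  })
  dplyr::bind_rows(out)
}

# dense depth vectors (one per chromosome) from a sparse track
dense_depth <- function(depth, chroms, len) {
  lapply(stats::setNames(chroms, chroms), function(ch) {
    v <- integer(len)
    rows <- depth[depth$chrom == ch, , drop = FALSE]
    v[rows$pos + 1L] <- rows$depth
    v
  })
}

toy_sizes <- function(chroms = c("chr1", "chr2"), len = 10000) {
  tibble::tibble(chrom = chroms, size = len)
}

# design over explicit regions, bypassing merge/pad (regions must already be
# disjoint and sorted)
design_from_regions <- function(regions, name = "toy") {
  capdesign:::new_capture_design(regions, name, provenance = "test")
}
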