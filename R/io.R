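#' Read a BED file into an interval tibble
#'
#' Reads 3-6 column BED. Coordinates are kept in the BED convention used
#' throughout this package: 0-based, half-open `[start, end)`. Column 4, when
#' present, becomes the `label` column. Chromosome names are matched exactly
#' everywhere downstream; no "chr" aliasing is ever applied.
#'
#' @param path Path to a tab-separated BED file.
#' @return A tibble with columns `chrom`, `start`, `end` and, if the file has
#'   a name column, `label`, in file order.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t0\t100", "chr1\t99\t100\tx"), f)
#' read_bed(f)
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield < 3)) {
    bad <- which(nfield < 3)[1]
    stop("malformed BED record at line ", bad, ": fewer than 3 columns",
         call. = FALSE)
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3)))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1]
    stop("malformed BED record at line ", bad, ": non-numeric coordinates",
         call. = FALSE)
  }
  out <- tibble::tibble(
    chrom = vapply(fields, `[[`, "", 1),
    start = start,
    end = end
  )
  if (any(nfield >= 4)) {
    out$label <- vapply(fields, function(f) {
      if (length(f) >= 4) f[[4]] else NA_character_
    }, "")
  }
  if (any(out$end <= out$start)) {
    bad <- which(out$end <= out$start)[1]
    stop("invalid BED record at line ", bad, ": end <= start", call. = FALSE)
  }
  if (any(out$start < 0)) {
    bad <- which(out$start < 0)[1]
    stop("invalid BED record at line ", bad, ": negative start", call. = FALSE)
  }
  out
}

#' Write an interval tibble as BED
#'
#' Inverse of [read_bed()]: writes 3 columns, or 4 when a `label` column is
#' present. Round-trips canonical 3/4-column records bit-identically.
#'
#' @param x Interval tibble with `chrom`, `start`, `end` and optional `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  check_intervals(x)
  cols <- c("chrom", "start", "end")
  if ("label" %in% names(x)) cols <- c(cols, "label")
  lines <- do.call(paste, c(unname(as.list(x[cols])), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-base depth track
#'
#' Two dialects are supported and yield identical tracks for equivalent
#' content:
#' * `"bedgraph"`: `chrom  start  end  depth`, 0-based half-open, the depth
#'   applying to every base of the interval;
#' * `"depth_tsv"`: `chrom  pos  depth` with a **1-based** position, the
#'   format emitted by `samtools depth`.
#'
#' The returned track is sparse: positions with depth 0 are never stored, and
#' every consumer in this package treats absent positions as depth 0.
#'
#' @param path Path to the file.
#' @param dialect `"bedgraph"` or `"depth_tsv"`. No sniffing is done.
#' @return A tibble with columns `chrom`, `pos` (0-based), `depth` (> 0),
#'   sorted by chromosome then position.
#' @export
read_depth_track <- function(path, dialect = c("bedgraph", "depth_tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cols <- if (dialect == "bedgraph") {
    readr::cols(chrom = readr::col_character(), start = readr::col_double(),
                end = readr::col_double(), depth = readr::col_double())
  } else {
    readr::cols(chrom = readr::col_character(), pos = readr::col_double(),
                depth = readr::col_double())
  }
  x <- readr::read_tsv(path, col_names = names(cols$cols), col_types = cols,
                       progress = FALSE)
  if (nrow(x) > 0 && any(x$depth < 0)) {
    stop("negative depth values in ", path, call. = FALSE)
  }
  if (dialect == "bedgraph") {
    x <- x[x$depth > 0, , drop = FALSE]
    if (nrow(x) == 0) return(empty_depth_track())
    out <- tibble::tibble(
      chrom = rep(x$chrom, x$end - x$start),
      pos = as.integer(unlist(Map(seq.int, x$start, x$end - 1))),
      depth = as.integer(rep(x$depth, x$end - x$start))
    )
  } else {
    x <- x[x$depth > 0, , drop = FALSE]
    if (nrow(x) == 0) return(empty_depth_track())
    out <- tibble::tibble(chrom = x$chrom, pos = as.integer(x$pos) - 1L,
                          depth = as.integer(x$depth))
    if (any(out$pos < 0)) stop("depth_tsv positions are 1-based; found 0",
                               call. = FALSE)
  }
  dplyr::arrange(out, .data$chrom, .data$pos)
}

empty_depth_track <- function() {
  tibble::tibble(chrom = character(), pos = integer(), depth = integer())
}

#' Write a depth track as bedGraph
#'
#' Runs of equal consecutive depth are collapsed into single bedGraph
#' records; zero-depth positions are omitted.
#'
#' @param depth Depth tibble (`chrom`, `pos` 0-based, `depth`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(depth, path) {
  depth <- dplyr::arrange(depth[depth$depth > 0, ], .data$chrom, .data$pos)
  if (nrow(depth) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  new_run <- c(TRUE, depth$chrom[-1] != depth$chrom[-nrow(depth)] |
                 depth$pos[-1] != depth$pos[-nrow(depth)] + 1L |
                 depth$depth[-1] != depth$depth[-nrow(depth)])
  run <- cumsum(new_run)
  runs <- dplyr::summarise(
    dplyr::group_by(depth, run = run),
    chrom = .data$chrom[1], start = min(.data$pos), end = max(.data$pos) + 1L,
    depth = .data$depth[1], .groups = "drop"
  )
  writeLines(paste(runs$chrom, runs$start, runs$end, runs$depth, sep = "\t"),
             path)
  invisible(path)
}

#' Read aligned reads as an interval tibble
#'
#' @param path Path to a SAM/BAM file or a 3-column TSV (`chrom`, `start`,
#'   `end`, 0-based half-open).
#' @param format `"bam"` (also accepts SAM, converted on the fly) or
#'   `"interval_tsv"`.
#' @return A tibble with `chrom`, `start`, `end`, one row per mapped read.
#'   The number of skipped unmapped records is attached as attribute
#'   `n_unmapped`.
#' @export
read_alignments <- function(path, format = c("bam", "interval_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "interval_tsv") {
    if (file.size(path) == 0) {
      out <- tibble::tibble(chrom = character(), start = integer(),
                            end = integer())
      attr(out, "n_unmapped") <- 0L
      return(out)
    }
    x <- readr::read_tsv(
      path, col_names = c("chrom", "start", "end"),
      col_types = readr::cols(readr::col_character(), readr::col_double(),
                              readr::col_double()),
      progress = FALSE
    )
    out <- tibble::tibble(chrom = x$chrom, start = as.integer(x$start),
                          end = as.integer(x$end))
    check_intervals(out, "alignments")
    attr(out, "n_unmapped") <- 0L
    return(out)
  }
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  p <- Rsamtools::ScanBamParam(flag = flag, what = c("rname", "pos", "qwidth"))
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  n_total <- Rsamtools::countBam(bam)$records
  out <- tibble::tibble(
    chrom = as.character(rec$rname),
    start = rec$pos - 1L,
    end = rec$pos - 1L + rec$qwidth
  )
  attr(out, "n_unmapped") <- as.integer(n_total - nrow(out))
  out
}

#' Read chromosome sizes
#'
#' @param path Two-column TSV `chrom  size` (no header).
#' @return Tibble with columns `chrom`, `size`.
#' @export
read_chrom_sizes <- function(path) {
  x <- readr::read_tsv(
    path, col_names = c("chrom", "size"),
    col_types = readr::cols(readr::col_character(), readr::col_double()),
    progress = FALSE
  )
  tibble::tibble(chrom = x$chrom, size = as.integer(x$size))
}

#' Read a reference genome from FASTA
#'
#' @param path FASTA path.
#' @return A [Biostrings::DNAStringSet] named by sequence.
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Chromosome sizes of a genome
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @return Tibble with columns `chrom`, `size`.
#' @export
genome_sizes <- function(genome) {
  tibble::tibble(chrom = names(genome), size = Biostrings::width(genome))
}
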