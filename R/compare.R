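#' Partition several designs into exhaustive membership classes
#'
#' Splits the union of the designs' target spaces into disjoint pieces and
#' sizes every non-empty membership class (bases in design A only, in A and B
#' but not C, ...). Works for any number of designs; [venn3()] is the
#' conventional three-way view.
#'
#' @param designs Named list of `capture_design` objects or interval tibbles.
#' @return A `venn_partition` tibble: one row per membership class, with one
#'   logical column per design, `membership` (e.g. `"A+B"`), `bp`, and `mb`
#'   (bp / 1e6 rounded half away from zero to 2 decimals, the convention of
#'   printed design-size figures). Classes of size 0 are kept so the rows
#'   always partition the union.
#' @export
venn_partition <- function(designs) {
  stopifnot(is.list(designs), length(designs) >= 2)
  nm <- names(designs)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("`designs` must be a named list", call. = FALSE)
  }
  tbls <- lapply(designs, function(d) {
    if (inherits(d, "capture_design")) d$regions else {
      check_intervals(d); merge_intervals(d)
    }
  })
  grl <- lapply(tbls, as_granges)
  pieces <- GenomicRanges::disjoin(suppressWarnings(do.call(c, unname(grl))))
  member <- vapply(grl, function(g) {
    suppressWarnings(GenomicRanges::countOverlaps(pieces, g)) > 0
  }, logical(length(pieces)))
  if (length(pieces) == 1) member <- matrix(member, nrow = 1,
                                            dimnames = list(NULL, nm))
  w <- GenomicRanges::width(pieces)
  # every non-empty combination of designs
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(nm)))
  combos <- combos[rowSums(combos) > 0, , drop = FALSE]
  names(combos) <- nm
  key <- apply(member, 1, function(m) paste(as.integer(m), collapse = ""))
  combo_key <- apply(combos, 1, function(m) paste(as.integer(m), collapse = ""))
  bp <- vapply(combo_key, function(k) sum(w[key == k]), numeric(1))
  out <- tibble::as_tibble(combos)
  out$membership <- apply(combos, 1, function(m) paste(nm[as.logical(m)],
                                                       collapse = "+"))
  out$bp <- unname(bp)
  out$mb <- round_half_away(out$bp / 1e6, 2)
  out <- dplyr::arrange(out, rowSums(out[nm]), .data$membership)
  class(out) <- c("venn_partition", class(out))
  out
}

#' Three-way design comparison
#'
#' @param a,b,c `capture_design` objects or interval tibbles.
#' @param names Names used in the membership labels (defaults to the design
#'   names or `A`/`B`/`C`).
#' @return A `venn_partition` tibble with the 7 membership classes.
#' @export
venn3 <- function(a, b, c, names = NULL) {
  designs <- list(a, b, c)
  if (is.null(names)) {
    names <- vapply(seq_along(designs), function(i) {
      d <- designs[[i]]
      if (inherits(d, "capture_design") && !is.null(d$name)) d$name
      else LETTERS[i]
    }, "")
  }
  names(designs) <- names
  venn_partition(designs)
}

#' @method autoplot venn_partition
#' @export
autoplot.venn_partition <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(.data$membership, .data$bp),
                               y = .data$mb)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "membership class", y = "size (Mb)",
                  title = "Design partition sizes")
}
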