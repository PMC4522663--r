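test_that("region coverage classifies threshold cases inclusively", {
  d <- design_from_regions(tibble::tibble(chrom = "chr1", start = 0, end = 4))
  at <- tibble::tibble(chrom = "chr1", pos = 0:3, depth = 5L)
  cs <- sample_coverage_summary(at, d, 5, toy_sizes("chr1", 10))
  expect_true(tidy(cs)$fully_covered)
  expect_equal(tidy(cs)$frac_covered, 1)

  below <- tibble::tibble(chrom = "chr1", pos = 0:3, depth = 4L)
  cs2 <- sample_coverage_summary(below, d, 5, toy_sizes("chr1", 10))
  expect_true(tidy(cs2)$never_covered)
  expect_equal(tidy(cs2)$covered_bp, 0)
  expect_equal(glance(cs2)$n_never, 1)
})

test_that("per-region statistics match a per-base brute-force recount", {
  set.seed(303)
  chroms <- c("chr1", "chr2")
  for (rep in 1:20) {
    regions <- merge_intervals(random_intervals(50, chroms))
    d <- design_from_regions(regions)
    depth <- random_depth(chroms)
    cs <- sample_coverage_summary(depth, d, 5, toy_sizes(chroms))
    dense <- dense_depth(depth, chroms, 10000)
    reg <- tidy(cs)
    for (i in seq_len(nrow(reg))) {
      v <- dense[[reg$chrom[i]]][(reg$start[i] + 1):reg$end[i]]
      expect_equal(reg$min_depth[i], min(v))
      expect_equal(reg$max_depth[i], max(v))
      expect_equal(reg$covered_bp[i], sum(v >= 5))
    }
    expect_equal(glance(cs)$covered_bp,
                 sum(reg$covered_bp))
    expect_equal(glance(cs)$n_fully_covered + glance(cs)$n_min_below,
                 glance(cs)$n_regions)
  }
})

test_that("coverage metrics are monotone in the depth threshold", {
  set.seed(404)
  regions <- merge_intervals(random_intervals(40))
  d <- design_from_regions(regions)
  depth <- random_depth()
  prev <- NULL
  for (thr in 1:8) {
    g <- glance(sample_coverage_summary(depth, d, thr, toy_sizes()))
    if (!is.null(prev)) {
      expect_lte(g$covered_bp, prev$covered_bp)
      expect_lte(g$n_fully_covered, prev$n_fully_covered)
      expect_gte(g$n_never, prev$n_never)
    }
    prev <- g
  }
})

test_that("coverage fraction curve counts regions and never increases", {
  reg <- tibble::tibble(frac_covered = c(1.0, 0.5))
  curve <- coverage_fraction_curve(reg, grid = c(0, 50, 100))
  expect_equal(curve$pct_regions, c(100, 100, 50))

  full <- tibble::tibble(frac_covered = rep(1, 5))
  expect_true(all(coverage_fraction_curve(full)$pct_regions == 100))

  set.seed(5)
  fr <- tibble::tibble(frac_covered = runif(200))
  curve <- coverage_fraction_curve(fr)
  expect_true(all(diff(curve$pct_regions) <= 0))
  # direct counting oracle
  for (g in c(0, 10, 55, 90, 100)) {
    expect_equal(curve$pct_regions[curve$min_pct_covered == g],
                 100 * mean(fr$frac_covered >= g / 100))
  }
})

test_that("on-target percentage uses any-overlap, half-open bounds", {
  d <- design_from_regions(tibble::tibble(chrom = "chr1", start = 0, end = 100))
  reads <- tibble::tibble(
    chrom = "chr1",
    start = c(0, 50, 99, 100),  # the last read abuts the region end
    end = c(50, 120, 149, 150)
  )
  ot <- pct_reads_on_target(reads, d)
  all_row <- ot[ot$chrom == "all", ]
  expect_equal(all_row$reads_on_target, 3L)
  expect_equal(all_row$pct_on_target, 75.0)

  # reads on chromosomes unknown to the design are off-target
  reads2 <- tibble::tibble(chrom = c("chr1", "chrZ"), start = c(0, 0),
                           end = c(10, 10))
  expect_equal(pct_reads_on_target(reads2, d)$reads_on_target[
    pct_reads_on_target(reads2, d)$chrom == "all"], 1L)
})

test_that("on-target counts match a brute-force overlap check", {
  set.seed(505)
  chroms <- c("chr1", "chr2")
  regions <- merge_intervals(random_intervals(30, chroms))
  d <- design_from_regions(regions)
  masks <- mask_from_intervals(regions, chroms, 10000)
  reads <- random_intervals(1000, chroms, max_len = 75)
  expected <- vapply(seq_len(nrow(reads)), function(i) {
    any(masks[[reads$chrom[i]]][(reads$start[i] + 1):reads$end[i]])
  }, logical(1))
  ot <- pct_reads_on_target(reads, d)
  expect_equal(ot$reads_on_target[ot$chrom == "all"], sum(expected))
  for (ch in chroms) {
    expect_equal(ot$reads_on_target[ot$chrom == ch],
                 sum(expected[reads$chrom == ch]))
  }
})

test_that("reproducibility equals per-base AND/NOR masks across samples", {
  set.seed(606)
  chroms <- c("chr1", "chr2")
  regions <- merge_intervals(random_intervals(40, chroms))
  d <- design_from_regions(regions)
  tracks <- lapply(1:4, function(i) random_depth(chroms, density = 0.6))
  summaries <- lapply(tracks, function(tr) {
    sample_coverage_summary(tr, d, 5, toy_sizes(chroms))
  })
  rep_out <- reproducibility(summaries, d, tracks, 5, toy_sizes(chroms))

  dense <- lapply(tracks, dense_depth, chroms = chroms, len = 10000)
  dmask <- mask_from_intervals(regions, chroms, 10000)
  bp_all <- 0; bp_never <- 0
  for (ch in chroms) {
    cov_all <- Reduce(`&`, lapply(dense, function(v) v[[ch]] >= 5))
    cov_none <- Reduce(`&`, lapply(dense, function(v) v[[ch]] < 5))
    bp_all <- bp_all + sum(cov_all & dmask[[ch]])
    bp_never <- bp_never + sum(cov_none & dmask[[ch]])
  }
  expect_equal(rep_out$bp_covered_all, bp_all)
  expect_equal(rep_out$bp_never_all, bp_never)

  fully <- Reduce(`&`, lapply(summaries, function(s) s$regions$fully_covered))
  never <- Reduce(`&`, lapply(summaries, function(s) s$regions$never_covered))
  expect_equal(rep_out$regions_fully_covered_all, sum(fully))
  expect_equal(rep_out$regions_never_all, sum(never))
  # bounds: the cohort-wide counts never exceed any single sample's
  expect_lte(rep_out$regions_fully_covered_all,
             min(vapply(summaries, function(s) glance(s)$n_fully_covered, 1)))
  expect_lte(rep_out$regions_never_all,
             min(vapply(summaries, function(s) glance(s)$n_never, 1)))
})

test_that("identical samples reproduce the single-sample classification", {
  set.seed(707)
  regions <- merge_intervals(random_intervals(30))
  d <- design_from_regions(regions)
  tr <- random_depth(density = 0.7)
  cs <- sample_coverage_summary(tr, d, 5, toy_sizes())
  rep_out <- reproducibility(list(cs, cs), d, list(tr, tr), 5, toy_sizes())
  expect_equal(rep_out$regions_fully_covered_all, glance(cs)$n_fully_covered)
  expect_equal(rep_out$regions_never_all, glance(cs)$n_never)
  expect_equal(rep_out$bp_covered_all, glance(cs)$covered_bp)
})

test_that("projection onto a subset equals direct evaluation on it", {
  set.seed(808)
  sizes <- toy_sizes()
  parent <- build_design(random_intervals(40), "parent", sizes)
  keep <- random_intervals(30)
  sub <- subset_design(parent, keep, "sub", sizes)
  depth <- random_depth(density = 0.5)
  expect_identical(
    glance(project_to_subset(depth, sub, 5, sizes)),
    glance(sample_coverage_summary(depth, sub, 5, sizes))
  )
  # projecting onto the parent itself is the identity
  expect_identical(
    glance(project_to_subset(depth, parent, 5, sizes)),
    glance(sample_coverage_summary(depth, parent, 5, sizes))
  )
  # a subset region inside a fully covered parent region stays fully covered
  full_track <- tibble::tibble(chrom = "chr1", pos = 0:999, depth = 9L)
  p1 <- design_from_regions(tibble::tibble(chrom = "chr1", start = 0,
                                           end = 1000))
  s1 <- subset_design(p1, tibble::tibble(chrom = "chr1", start = 200,
                                         end = 400), "s", toy_sizes("chr1"))
  expect_true(all(tidy(project_to_subset(full_track, s1, 5,
                                         toy_sizes("chr1")))$fully_covered))
})
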