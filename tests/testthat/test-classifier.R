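make_summary <- function(d, fully, never) {
  # synthetic coverage_summary with prescribed per-region outcomes
  reg <- d$regions
  structure(list(
    summary = tibble::tibble(sample_id = NA_character_),
    regions = tibble::tibble(
      region_id = reg$region_id, length = reg$end - reg$start,
      fully_covered = fully, never_covered = never
    )
  ), class = "coverage_summary")
}

test_that("groups partition regions by cohort-wide coverage behaviour", {
  d <- design_from_regions(tibble::tibble(chrom = "chr1",
                                          start = c(0, 200, 400),
                                          end = c(100, 300, 500)))
  s1 <- make_summary(d, fully = c(TRUE, FALSE, FALSE),
                     never = c(FALSE, FALSE, TRUE))
  s2 <- make_summary(d, fully = c(TRUE, TRUE, FALSE),
                     never = c(FALSE, FALSE, TRUE))
  g <- assign_groups(list(s1, s2))
  expect_equal(g$group, c(1L, 2L, 3L))

  # partition: disjoint and exhaustive for random outcomes
  set.seed(11)
  for (rep in 1:10) {
    n <- 50
    regions <- tibble::tibble(chrom = "chr1",
                              start = seq(0, by = 200, length.out = n),
                              end = seq(100, by = 200, length.out = n))
    dd <- design_from_regions(regions)
    sums <- lapply(1:4, function(i) {
      never <- runif(n) < 0.2
      fully <- !never & runif(n) < 0.5
      make_summary(dd, fully, never)
    })
    g <- assign_groups(sums)
    expect_equal(nrow(g), n)
    expect_true(all(g$group %in% 1:3))
    fully_all <- Reduce(`&`, lapply(sums, function(s) s$regions$fully_covered))
    never_all <- Reduce(`&`, lapply(sums, function(s) s$regions$never_covered))
    expect_equal(g$group == 1, fully_all)
    expect_equal(g$group == 3, never_all & !fully_all)
  }

  bad <- make_summary(design_from_regions(
    tibble::tibble(chrom = "chr1", start = 0, end = 100)), TRUE, FALSE)
  expect_error(assign_groups(list(s1, bad)), "region universe")
})

test_that("gc_content counts unambiguous bases only", {
  g <- Biostrings::DNAStringSet(c(chr1 = "GCGCATGCANGCNNNN"))
  regs <- tibble::tibble(chrom = "chr1",
                         start = c(0, 4, 8, 12),
                         end = c(4, 8, 12, 16))
  gc <- gc_content(g, regs)
  expect_equal(gc$gc[1], 100)
  expect_equal(gc$gc[2], 50)
  expect_equal(round(gc$gc[3], 1), 66.7)  # "ANGC": 2 GC of 3 unambiguous
  expect_true(is.na(gc$gc[4]))
  expect_true(gc$all_ambiguous[4])
  expect_error(gc_content(g, tibble::tibble(chrom = "chr1", start = 10,
                                            end = 20)), "beyond")
  expect_error(gc_content(g, tibble::tibble(chrom = "chr9", start = 0,
                                            end = 4)), "absent")
})

test_that("gc_cutoffs are interpolated order statistics", {
  cut <- gc_cutoffs(1:100)
  expect_equal(unname(cut), c(3.475, 97.525))
  expect_equal(unname(gc_cutoffs(rep(42, 10))), c(42, 42))
  expect_error(gc_cutoffs(numeric(0)), "at least two")
  expect_error(gc_cutoffs(c(NA, NA, 5)), "at least two")
})

test_that("exclusion flags use any-overlap and agree with the mask oracle", {
  d <- design_from_regions(tibble::tibble(chrom = "chr1", start = 0, end = 100))
  ns <- tibble::tibble(chrom = "chr1", start = 50, end = 60)
  none <- tibble::tibble(chrom = "chr1", start = 500, end = 600)
  fl <- annotate_exclusions(d, ns, none, none)
  expect_true(fl$has_ns)
  expect_false(fl$has_repeat)
  expect_true(fl$any_exclusion)
  expect_false(fl$predicted_unseq)

  set.seed(22)
  chroms <- c("chr1", "chr2")
  for (rep in 1:10) {
    regions <- merge_intervals(random_intervals(40, chroms))
    dd <- design_from_regions(regions)
    tr_ns <- random_intervals(10, chroms)
    tr_rep <- random_intervals(10, chroms)
    tr_pred <- random_intervals(5, chroms)
    fl <- annotate_exclusions(dd, tr_ns, tr_rep, tr_pred)
    m_ns <- mask_from_intervals(tr_ns, chroms, 10000)
    m_rep <- mask_from_intervals(tr_rep, chroms, 10000)
    m_pred <- mask_from_intervals(tr_pred, chroms, 10000)
    overlap <- function(masks, i) {
      any(masks[[regions$chrom[i]]][(regions$start[i] + 1):regions$end[i]])
    }
    for (i in seq_len(nrow(regions))) {
      expect_equal(fl$has_ns[i], overlap(m_ns, i))
      expect_equal(fl$has_repeat[i], overlap(m_rep, i))
      expect_equal(fl$predicted_unseq[i], overlap(m_pred, i))
    }
  }
})

test_that("risk report combines extreme GC and exclusions by inclusion", {
  n <- 100
  groups <- tibble::tibble(region_id = 1:n, group = rep(1L, n))
  # planted: 30 extreme-GC regions and 10 flagged regions, disjoint
  gc <- tibble::tibble(region_id = 1:n,
                       gc = c(rep(80, 30), rep(50, 70)))
  flags <- tibble::tibble(
    region_id = 1:n,
    has_ns = c(rep(FALSE, 30), rep(TRUE, 10), rep(FALSE, 60)),
    has_repeat = FALSE,
    any_exclusion = c(rep(FALSE, 30), rep(TRUE, 10), rep(FALSE, 60)),
    predicted_unseq = FALSE
  )
  rep_out <- risk_report(groups, gc, c(32, 64.5), flags)
  row <- rep_out$by_group
  expect_equal(row$pct_extreme_gc, 30)
  expect_equal(row$pct_any_exclusion, 10)
  expect_equal(row$pct_at_risk_exclusion, 40)  # disjoint: percentages add
  expect_equal(row$pct_at_risk_predicted, 30)
  expect_equal(row$median_gc, 50)
  # dropping flagged regions cannot increase a group's size
  expect_lte(sum(!flags$any_exclusion), n)

  # boundary GC values are sequenceable (strict comparison)
  gc2 <- tibble::tibble(region_id = 1:n, gc = rep(c(32, 64.5), n / 2))
  expect_equal(risk_report(groups, gc2, c(32, 64.5),
                           flags)$by_group$pct_extreme_gc, 0)

  # no extremes, no flags -> nothing at risk
  gc3 <- tibble::tibble(region_id = 1:n, gc = rep(50, n))
  flags0 <- dplyr::mutate(flags, has_ns = FALSE, any_exclusion = FALSE)
  expect_equal(risk_report(groups, gc3, c(32, 64.5),
                           flags0)$by_group$pct_at_risk_exclusion, 0)
})

test_that("risk report percentages ignore region-id relabeling", {
  set.seed(33)
  n <- 60
  groups <- tibble::tibble(region_id = 1:n,
                           group = sample(1:3, n, replace = TRUE))
  gc <- tibble::tibble(region_id = 1:n, gc = runif(n, 20, 80))
  flags <- tibble::tibble(region_id = 1:n,
                          has_ns = runif(n) < 0.2,
                          has_repeat = runif(n) < 0.2,
                          predicted_unseq = runif(n) < 0.1)
  flags$any_exclusion <- flags$has_ns | flags$has_repeat
  r1 <- risk_report(groups, gc, c(32, 64.5), flags)$by_group
  perm <- sample(n)
  relabel <- function(x) {
    x$region_id <- perm[x$region_id]
    x
  }
  r2 <- risk_report(relabel(groups), relabel(gc), c(32, 64.5),
                    relabel(flags))$by_group
  expect_equal(r1, r2)
})

test_that("size-stratified completeness measures the short-region advantage", {
  regions <- tibble::tibble(chrom = "chr1",
                            start = seq(0, by = 1000, length.out = 10),
                            end = seq(0, by = 1000, length.out = 10) +
                              rep(c(100, 500), 5))
  d <- design_from_regions(regions)
  all_cov <- make_summary(d, fully = rep(TRUE, 10), never = rep(FALSE, 10))
  res <- size_stratified_completeness(d, list(all_cov), 260)
  expect_equal(res$mean_diff_points, 0)

  short_only <- make_summary(d, fully = rep(c(TRUE, FALSE), 5),
                             never = rep(FALSE, 10))
  res2 <- size_stratified_completeness(d, list(short_only), 260)
  expect_equal(res2$mean_diff_points, 100)

  # simulated size-dependent dropout vs direct counting
  set.seed(44)
  fully <- ifelse(regions$end - regions$start < 260,
                  runif(10) < 0.9, runif(10) < 0.5)
  s <- make_summary(d, fully, never = rep(FALSE, 10))
  res3 <- size_stratified_completeness(d, list(s), 260)
  short <- regions$end - regions$start < 260
  expect_equal(res3$per_sample$pct_full_short, 100 * mean(fully[short]))
  expect_equal(res3$per_sample$pct_full_long, 100 * mean(fully[!short]))
})
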