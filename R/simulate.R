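#' Configuration for the synthetic capture study
#'
#' Describes a toy genome and cohort with the statistical structure the
#' pipeline assumes: chromosomes are tiled with GC zones, most at a
#' sequenceable GC content and a minority at extreme (high or low) GC;
#' annotation sources (multi-exon genes with UTR/CDS structure plus
#' non-coding RNAs) define the capture design; per-base depth follows a
#' negative binomial whose mean is depressed outside a sequenceable GC band
#' and zeroed over predicted-unsequenceable bases, so that all three region
#' performance groups arise.
#'
#' Defaults give 3 chromosomes of 1 Mb, roughly 2,000 design regions, 4
#' samples at a baseline on-target depth of 80x, and a sequenceable GC band
#' of 32-64.5%.
#'
#' @param seed Integer master seed; every emitted artifact is byte-identical
#'   under the same seed.
#' @param n_chroms,chrom_length Genome shape.
#' @param zone_length GC-zone length in bp.
#' @param gc_ok Sequenceable GC band `c(lo, hi)` in percent: the depth
#'   multiplier is 1 inside it and decays linearly outside.
#' @param gc_mid_range,gc_high_range,gc_low_range Target GC ranges for
#'   ordinary, high-extreme and low-extreme zones.
#' @param p_zone_high,p_zone_low Probability that a zone is an extreme zone.
#' @param n_genes_per_chrom,exons_per_gene,exon_len_meanlog,exon_len_sdlog
#'   Gene structure parameters; exon lengths are log-normal.
#' @param intron_len,intergenic_len,utr_len Ranges (bp) sampled uniformly.
#' @param n_ncrna_per_chrom,ncrna_len Non-coding RNA count and length range
#'   (includes lengths below 100 bp so design padding is exercised).
#' @param n_runs_per_chrom,n_run_len Unknown-sequence (N) runs.
#' @param n_repeats_per_chrom,repeat_len Repeat-exclusion intervals.
#' @param p_predicted Probability that an exclusion interval contributes a
#'   predicted-unsequenceable subinterval (predicted is always a subset of
#'   Ns plus repeats).
#' @param n_samples Cohort size.
#' @param sample_scale_range Per-sample library-size multiplier range.
#' @param baseline_depth Mean on-target depth at sequenceable GC, scale 1.
#' @param nb_size Negative-binomial dispersion (size) of per-base depth.
#' @param gc_window Sliding-window width (bp) for the local GC driving the
#'   depth multiplier.
#' @param gc_decay_points GC percentage points beyond the band edge at which
#'   the depth multiplier reaches its floor.
#' @param floor_multiplier Depth multiplier floor at extreme GC.
#' @param on_target_rate Probability that a simulated read is on target.
#' @param read_len Simulated read length (bp).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_chroms = 3,
                       chrom_length = 1e6,
                       zone_length = 25000,
                       gc_ok = c(32, 64.5),
                       gc_mid_range = c(35, 62),
                       gc_high_range = c(72, 85),
                       gc_low_range = c(14, 26),
                       p_zone_high = 0.12,
                       p_zone_low = 0.08,
                       n_genes_per_chrom = 160,
                       exons_per_gene = c(2, 5),
                       exon_len_meanlog = log(250),
                       exon_len_sdlog = 0.5,
                       intron_len = c(150, 800),
                       intergenic_len = c(400, 1500),
                       utr_len = c(40, 150),
                       n_ncrna_per_chrom = 40,
                       ncrna_len = c(70, 300),
                       n_runs_per_chrom = 3,
                       n_run_len = c(500, 2000),
                       n_repeats_per_chrom = 25,
                       repeat_len = c(200, 1500),
                       p_predicted = 0.5,
                       n_samples = 4,
                       sample_scale_range = c(0.7, 1.2),
                       baseline_depth = 80,
                       nb_size = 6,
                       gc_window = 101,
                       gc_decay_points = 6,
                       floor_multiplier = 0.02,
                       on_target_rate = 0.75,
                       read_len = 75) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_chroms >= 1, cfg$chrom_length >= cfg$zone_length,
            cfg$gc_ok[1] < cfg$gc_ok[2],
            cfg$p_zone_high + cfg$p_zone_low <= 1,
            cfg$on_target_rate >= 0, cfg$on_target_rate <= 1,
            cfg$n_samples >= 1, cfg$baseline_depth > 0)
  structure(cfg, class = "sim_config")
}

# deterministic sub-seed, kept below 2^31
sub_seed <- function(seed, stream, index = 0L) {
  as.integer((abs(as.numeric(seed)) %% 1e6) * 2011 + stream * 131 + index)
}

runif_int <- function(n, range) {
  as.integer(round(stats::runif(n, range[1], range[2])))
}

#' Generate a toy genome with GC zones
#'
#' Each chromosome is tiled into zones; each zone gets a target GC content
#' (ordinary or extreme per the configured probabilities) and its sequence is
#' drawn base-by-base at that GC probability, so realized zone GC
#' concentrates tightly around the target. N runs are then planted.
#'
#' @param cfg A [sim_config()].
#' @return List with `genome` ([Biostrings::DNAStringSet]), `chrom_sizes`
#'   (tibble), and `zones` (tibble: `chrom`, `start`, `end`, `target_gc`,
#'   `class` in ok/high/low).
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(sub_seed(cfg$seed, 1))
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  zones <- list()
  seqs <- character(cfg$n_chroms)
  for (i in seq_len(cfg$n_chroms)) {
    L <- as.integer(cfg$chrom_length)
    starts <- seq(0L, L - 1L, by = as.integer(cfg$zone_length))
    ends <- pmin(starts + as.integer(cfg$zone_length), L)
    nz <- length(starts)
    cls <- sample(c("high", "low", "ok"), nz, replace = TRUE,
                  prob = c(cfg$p_zone_high, cfg$p_zone_low,
                           1 - cfg$p_zone_high - cfg$p_zone_low))
    target <- numeric(nz)
    target[cls == "ok"] <- stats::runif(sum(cls == "ok"),
                                        cfg$gc_mid_range[1],
                                        cfg$gc_mid_range[2])
    target[cls == "high"] <- stats::runif(sum(cls == "high"),
                                          cfg$gc_high_range[1],
                                          cfg$gc_high_range[2])
    target[cls == "low"] <- stats::runif(sum(cls == "low"),
                                         cfg$gc_low_range[1],
                                         cfg$gc_low_range[2])
    zones[[i]] <- tibble::tibble(chrom = chroms[i], start = starts,
                                 end = ends, target_gc = target, class = cls)
    p <- rep(target / 100, ends - starts)
    is_gc <- stats::runif(L) < p
    strong <- sample(c("G", "C"), L, replace = TRUE)
    weak <- sample(c("A", "T"), L, replace = TRUE)
    base <- ifelse(is_gc, strong, weak)
    # plant N runs
    if (cfg$n_runs_per_chrom > 0) {
      for (k in seq_len(cfg$n_runs_per_chrom)) {
        len <- runif_int(1, cfg$n_run_len)
        s <- sample.int(L - len, 1)
        base[s:(s + len - 1)] <- "N"
      }
    }
    seqs[i] <- paste(base, collapse = "")
  }
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chroms
  list(genome = genome,
       chrom_sizes = tibble::tibble(chrom = chroms,
                                    size = as.integer(cfg$chrom_length)),
       zones = dplyr::bind_rows(zones))
}

#' Generate annotation and exclusion tracks
#'
#' Places multi-exon genes (first/last exon partially UTR, so CDS is a strict
#' subset of exons and UTR = exons minus CDS), non-coding RNAs, repeat
#' exclusions, and a predicted-unsequenceable track that is by construction a
#' subset of the union of Ns and repeats. The Ns track is derived from the
#' actual N runs in the genome.
#'
#' @param cfg A [sim_config()].
#' @param sim_genome Output of [simulate_genome()].
#' @return List of interval tibbles: `exons`, `cds`, `utrs`, `ncrna`, `ns`,
#'   `repeats`, `predicted`.
#' @export
simulate_annotation <- function(cfg, sim_genome) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(sub_seed(cfg$seed, 2))
  genome <- sim_genome$genome
  chroms <- names(genome)
  L <- as.integer(cfg$chrom_length)
  margin <- 2L * cfg$read_len
  exons <- list(); cds <- list(); ncrna <- list(); repeats <- list()
  for (ch in chroms) {
    pos <- runif_int(1, c(1000, 3000))
    ex_s <- integer(0); ex_e <- integer(0)
    cds_s <- integer(0); cds_e <- integer(0)
    for (g in seq_len(cfg$n_genes_per_chrom)) {
      k <- sample(seq(cfg$exons_per_gene[1], cfg$exons_per_gene[2]), 1)
      lens <- pmax(30L, as.integer(round(stats::rlnorm(
        k, cfg$exon_len_meanlog, cfg$exon_len_sdlog))))
      gaps <- if (k > 1) runif_int(k - 1, cfg$intron_len) else integer(0)
      if (pos + sum(lens) + sum(gaps) >= L - margin) break
      s <- pos + c(0L, cumsum(lens[-k] + gaps))
      e <- s + lens
      ex_s <- c(ex_s, s); ex_e <- c(ex_e, e)
      # UTRs at the gene's outer ends; CDS is the remainder of each exon
      u5 <- min(runif_int(1, cfg$utr_len), lens[1] - 10L)
      u3 <- min(runif_int(1, cfg$utr_len), lens[k] - 10L)
      cs <- s; ce <- e
      cs[1] <- s[1] + max(u5, 0L)
      ce[k] <- e[k] - max(u3, 0L)
      keep <- ce > cs
      cds_s <- c(cds_s, cs[keep]); cds_e <- c(cds_e, ce[keep])
      pos <- e[k] + runif_int(1, cfg$intergenic_len)
    }
    exons[[ch]] <- tibble::tibble(chrom = ch, start = ex_s, end = ex_e)
    cds[[ch]] <- tibble::tibble(chrom = ch, start = cds_s, end = cds_e)
    nc_len <- runif_int(cfg$n_ncrna_per_chrom, cfg$ncrna_len)
    nc_s <- as.integer(sapply(nc_len, function(l) {
      sample.int(L - margin - l, 1)
    }))
    ncrna[[ch]] <- tibble::tibble(chrom = ch, start = nc_s,
                                  end = nc_s + nc_len)
    rep_len <- runif_int(cfg$n_repeats_per_chrom, cfg$repeat_len)
    rep_s <- as.integer(sapply(rep_len, function(l) {
      sample.int(L - margin - l, 1)
    }))
    repeats[[ch]] <- tibble::tibble(chrom = ch, start = rep_s,
                                    end = rep_s + rep_len)
  }
  exons <- dplyr::bind_rows(exons)
  cds <- dplyr::bind_rows(cds)
  ncrna <- dplyr::bind_rows(ncrna)
  repeats <- merge_intervals(dplyr::bind_rows(repeats))
  ns <- n_runs(genome)
  # predicted-unsequenceable: random subintervals of Ns/repeats
  pool <- merge_intervals(dplyr::bind_rows(ns, repeats))
  take <- stats::runif(nrow(pool)) < cfg$p_predicted
  pred <- pool[take, , drop = FALSE]
  if (nrow(pred) > 0) {
    len <- pred$end - pred$start
    cut_l <- as.integer(floor(stats::runif(nrow(pred), 0, len / 4)))
    cut_r <- as.integer(floor(stats::runif(nrow(pred), 0, len / 4)))
    pred$start <- pred$start + cut_l
    pred$end <- pred$end - cut_r
  }
  list(exons = exons, cds = cds,
       utrs = subtract_intervals(exons, cds),
       ncrna = ncrna, ns = ns, repeats = repeats,
       predicted = merge_intervals(pred))
}

# intervals of N bases in a genome
n_runs <- function(genome) {
  out <- lapply(names(genome), function(ch) {
    m <- Biostrings::maskMotif(genome[[ch]], "N")
    r <- as(Biostrings::masks(m)[[1]], "IRanges")
    tibble::tibble(chrom = ch, start = IRanges::start(r) - 1L,
                   end = IRanges::end(r))
  })
  dplyr::bind_rows(out)
}

# per-base depth multiplier from windowed GC, N status and exclusions
depth_multiplier <- function(cfg, chrom_seq, excl_pos0 = integer(0)) {
  v <- strsplit(as.character(chrom_seq), "", fixed = TRUE)[[1]]
  L <- length(v)
  is_gc <- as.integer(v %in% c("G", "C", "g", "c"))
  is_acgt <- as.integer(v %in% c("A", "C", "G", "T", "a", "c", "g", "t"))
  h <- (cfg$gc_window - 1) %/% 2
  cs_gc <- c(0, cumsum(is_gc))
  cs_ok <- c(0, cumsum(is_acgt))
  i <- seq_len(L)
  hi <- pmin(i + h, L)
  lo <- pmax(i - h - 1L, 0L)
  denom <- cs_ok[hi + 1L] - cs_ok[lo + 1L]
  gc_pct <- ifelse(denom > 0,
                   100 * (cs_gc[hi + 1L] - cs_gc[lo + 1L]) / denom, 0)
  dist <- pmax(cfg$gc_ok[1] - gc_pct, gc_pct - cfg$gc_ok[2], 0)
  mult <- pmax(cfg$floor_multiplier,
               1 - dist / cfg$gc_decay_points * (1 - cfg$floor_multiplier))
  mult[is_acgt == 0] <- 0 # unknown sequence cannot be captured
  if (length(excl_pos0) > 0) mult[excl_pos0 + 1L] <- 0
  mult
}

#' Simulate a per-sample depth track over a design
#'
#' Expected per-base depth is baseline x per-sample library scale x a GC
#' multiplier computed on a sliding window (1 inside the sequenceable band,
#' decaying linearly to a floor outside) x an exclusion multiplier (0 over N
#' bases and over predicted-unsequenceable intervals). Realized depth is
#' negative binomial around that expectation. Deterministic under
#' `(seed, sample_index)`.
#'
#' @param cfg A [sim_config()].
#' @param sim_genome Output of [simulate_genome()].
#' @param design A `capture_design` built on this genome.
#' @param sample_index Integer sample index (1-based).
#' @param exclusions Interval tibble of predicted-unsequenceable bases
#'   (depth 0), e.g. the `predicted` track of [simulate_annotation()].
#' @return Sparse depth tibble (`chrom`, `pos` 0-based, `depth` > 0) over the
#'   design bases.
#' @export
simulate_depth <- function(cfg, sim_genome, design, sample_index,
                           exclusions = NULL) {
  stopifnot(inherits(cfg, "sim_config"), inherits(design, "capture_design"))
  set.seed(sub_seed(cfg$seed, 3, sample_index))
  scale <- stats::runif(1, cfg$sample_scale_range[1],
                        cfg$sample_scale_range[2])
  out <- list()
  for (ch in unique(as.character(design$regions$chrom))) {
    r <- design$regions[design$regions$chrom == ch, ]
    excl <- if (!is.null(exclusions)) {
      e <- exclusions[exclusions$chrom == ch, , drop = FALSE]
      if (nrow(e) > 0) {
        as.integer(unlist(Map(seq.int, e$start, e$end - 1L)))
      } else integer(0)
    } else integer(0)
    mult <- depth_multiplier(cfg, sim_genome$genome[[ch]], excl)
    pos <- as.integer(unlist(Map(seq.int, r$start, r$end - 1L)))
    mu <- cfg$baseline_depth * scale * mult[pos + 1L]
    depth <- stats::rnbinom(length(pos), size = cfg$nb_size, mu = mu)
    keep <- depth > 0
    out[[ch]] <- tibble::tibble(chrom = ch, pos = pos[keep],
                                depth = as.integer(depth[keep]))
  }
  dplyr::bind_rows(out)
}

#' Simulate aligned reads with a known on-target rate
#'
#' Each read is on target with probability `on_target_rate`: on-target reads
#' start so that they overlap at least one design base (start positions
#' weighted by region length), off-target reads are placed uniformly over the
#' non-design space, rejecting accidental design overlap.
#'
#' @param cfg A [sim_config()].
#' @param design A `capture_design`.
#' @param n_reads Number of reads.
#' @param sample_index Sample index (seeds the stream).
#' @param chrom_sizes Tibble (`chrom`, `size`) or named vector.
#' @return Read tibble (`chrom`, `start`, `end`, `on_target_truth`).
#' @export
simulate_reads <- function(cfg, design, n_reads, sample_index = 1,
                           chrom_sizes = NULL) {
  stopifnot(inherits(cfg, "sim_config"), n_reads >= 0)
  set.seed(sub_seed(cfg$seed, 4, sample_index))
  sizes <- as_chrom_sizes(chrom_sizes, fallback = design$regions)
  rl <- as.integer(cfg$read_len)
  if (n_reads == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), on_target_truth = logical()))
  }
  on <- stats::runif(n_reads) < cfg$on_target_rate
  n_on <- sum(on); n_off <- n_reads - n_on
  reg <- design$regions
  gr_design <- as_granges(reg)
  res <- list()
  if (n_on > 0) {
    idx <- sample.int(nrow(reg), n_on, replace = TRUE,
                      prob = reg$end - reg$start + rl - 1)
    lo <- pmax(reg$start[idx] - rl + 1L, 0L)
    hi <- pmin(reg$end[idx] - 1L,
               sizes[as.character(reg$chrom[idx])] - rl)
    s <- lo + as.integer(floor(stats::runif(n_on) * (hi - lo + 1L)))
    res$on <- tibble::tibble(chrom = as.character(reg$chrom[idx]),
                             start = s, end = s + rl,
                             on_target_truth = TRUE)
  }
  if (n_off > 0) {
    placed <- list(); need <- n_off
    while (need > 0) {
      m <- max(need * 2L, 100L)
      ch <- sample(names(sizes), m, replace = TRUE,
                   prob = as.numeric(sizes))
      s <- as.integer(floor(stats::runif(m) * (sizes[ch] - rl)))
      cand <- tibble::tibble(chrom = ch, start = s, end = s + rl)
      ok <- suppressWarnings(
        GenomicRanges::countOverlaps(as_granges(cand), gr_design)) == 0
      cand <- cand[ok, , drop = FALSE]
      if (nrow(cand) > need) cand <- cand[seq_len(need), , drop = FALSE]
      placed[[length(placed) + 1]] <- cand
      need <- need - nrow(cand)
    }
    off <- dplyr::bind_rows(placed)
    off$on_target_truth <- FALSE
    res$off <- off
  }
  out <- dplyr::bind_rows(res)
  out[sample.int(nrow(out)), ]
}

#' Run the full synthetic study
#'
#' Convenience wrapper: generates the genome and annotation, builds the full
#' design (exons + non-coding RNAs) and its coding-only subset, simulates a
#' per-sample depth track for every sample, and records region-level ground
#' truth (realized GC, planted extreme-GC status against the configured
#' sequenceable band, exclusion flags).
#'
#' @param cfg A [sim_config()].
#' @return List with `config`, `genome`, `chrom_sizes`, `zones`, `tracks`
#'   (annotation/exclusion tibbles), `design`, `design_cds`, `depths` (list
#'   of per-sample tracks) and `truth` (per-region tibble).
#' @export
simulate_study <- function(cfg = sim_config()) {
  g <- simulate_genome(cfg)
  ann <- simulate_annotation(cfg, g)
  design <- build_design(list(exons = ann$exons, ncrna = ann$ncrna),
                         name = "sim-plus", chrom_sizes = g$chrom_sizes)
  design_cds <- subset_design(design, ann$cds, name = "sim-cds",
                              chrom_sizes = g$chrom_sizes)
  depths <- lapply(seq_len(cfg$n_samples), function(i) {
    simulate_depth(cfg, g, design, i, exclusions = ann$predicted)
  })
  gc <- gc_content(g$genome, design)
  flags <- annotate_exclusions(design, ns = ann$ns, repeats = ann$repeats,
                               predicted_unseq = ann$predicted)
  truth <- dplyr::mutate(
    dplyr::inner_join(gc[, c("region_id", "gc", "all_ambiguous")], flags,
                      by = "region_id"),
    planted_extreme_gc = !is.na(.data$gc) &
      (.data$gc < cfg$gc_ok[1] | .data$gc > cfg$gc_ok[2])
  )
  list(config = cfg, genome = g$genome, chrom_sizes = g$chrom_sizes,
       zones = g$zones, tracks = ann, design = design,
       design_cds = design_cds, depths = depths, truth = truth)
}
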