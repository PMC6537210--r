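test_that("flag_snps handles the limiting call patterns", {
  p <- best_setting()
  # 200 homozygous calls: everything flagged
  expect_true(all(flag_snps(rep(0L, 200), p)))
  # heterozygote at every SNP, window 50, allowance 1: no window qualifies
  expect_false(any(flag_snps(rep(1L, 200), p)))
  expect_false(any(flag_snps(rep(c(0L, 1L), 100), p)))
  # chromosome shorter than the window: no windows fit, nothing flagged
  expect_false(any(flag_snps(rep(0L, 30), p)))
  expect_length(flag_snps(integer(0), p), 0)
})

test_that("a planted toy matches window-by-window enumeration", {
  p <- best_setting()
  calls <- rep(0L, 300)
  calls[c(120, 180)] <- 1L
  pos <- seq_len(300) * 10000L
  oracle <- roh_oracle(calls, pos, p)
  expect_equal(flag_snps(calls, p), oracle$flags)
  expect_equal(call_segments(flag_snps(calls, p), pos, p), oracle$segments)
})

test_that("call_segments applies length, count, density and gap rules", {
  p <- best_setting()
  # one 2-Mb run of 200 flagged SNPs -> a single spanning segment
  pos <- seq(1e6, 3e6, length.out = 200)
  pos <- as.integer(round(pos))
  segs <- call_segments(rep(TRUE, 200), pos, p)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start_bp, pos[1])
  expect_equal(segs$end_bp, pos[200])
  expect_equal(segs$n_snps, 200L)

  # 400-kb run fails the 500-kb minimum
  pos2 <- as.integer(seq(1e6, 1.4e6, length.out = 150))
  expect_equal(nrow(call_segments(rep(TRUE, 150), pos2, p)), 0)

  # a 150-kb inter-SNP gap splits the run; pieces filtered independently
  pos3 <- c(
    as.integer(seq(1e6, 3e6, length.out = 150)), # 2 Mb, 150 SNPs: kept
    as.integer(seq(3.15e6, 3.5e6, length.out = 60)) # 350 kb: dropped
  )
  segs3 <- call_segments(rep(TRUE, 210), pos3, p)
  expect_equal(nrow(segs3), 1)
  expect_equal(segs3$end_bp, pos3[150])
  # oracle agreement on the same fixture
  expect_equal(segs3, roh_oracle(rep(0L, 210), pos3, p)$segments)

  # density rule: 100 SNPs over 8 Mb is 80 kb/SNP, too sparse
  pos4 <- as.integer(seq(1e6, 9e6, length.out = 100))
  p4 <- roh_params(max_gap_kb = 200)
  expect_equal(nrow(call_segments(rep(TRUE, 100), pos4, p4)), 0)
})

test_that("detect_roh composes per-individual calling deterministically", {
  p <- best_setting()
  # fully heterozygous matrix: no segments
  g_het <- make_geno(matrix(1L, nrow = 3, ncol = 200))
  expect_equal(nrow(detect_roh(g_het, p)), 0)

  # one fully homozygous individual on a 3-Mb chromosome with 300 SNPs
  g_hom <- make_geno(
    matrix(0L, nrow = 1, ncol = 300),
    positions = as.integer(seq(1e4, 3e6, length.out = 300))
  )
  segs <- detect_roh(g_hom, p)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$n_snps, 300L)
  expect_equal(segs$length_bp, segs$end_bp - segs$start_bp + 1)
})

test_that("random chromosomes match the brute-force caller segment for segment", {
  settings <- list(
    best_setting(),
    roh_params(het = 0, missing = 0),
    roh_params(min_snps = 15, het = 0, missing = 1)
  )
  for (seed in 1:20) {
    fix <- random_roh_chromosome(seed)
    for (p in settings) {
      oracle <- roh_oracle(fix$calls, fix$pos, p)
      flags <- flag_snps(fix$calls, p)
      expect_equal(flags, oracle$flags)
      expect_equal(call_segments(flags, fix$pos, p), oracle$segments)
    }
  }
})

test_that("every emitted segment satisfies all four filters", {
  p <- roh_params(min_kb = 300, min_snps = 20, density_kb = 60, max_gap_kb = 80)
  for (seed in 31:45) {
    fix <- random_roh_chromosome(seed)
    segs <- call_segments(flag_snps(fix$calls, p), fix$pos, p)
    if (nrow(segs) == 0) next
    expect_true(all(segs$length_bp >= p$min_kb * 1000))
    expect_true(all(segs$n_snps >= p$min_snps))
    expect_true(all(segs$length_bp / segs$n_snps <= p$density_kb * 1000))
    expect_equal(segs$length_bp, segs$end_bp - segs$start_bp + 1)
    # no internal gap above the limit
    for (r in seq_len(nrow(segs))) {
      inside <- fix$pos[fix$pos >= segs$start_bp[r] & fix$pos <= segs$end_bp[r]]
      expect_true(all(diff(inside) <= p$max_gap_kb * 1000))
    }
  }
})

test_that("raising het/missing allowances never unflags a SNP", {
  for (seed in 51:60) {
    fix <- random_roh_chromosome(seed)
    base <- flag_snps(fix$calls, roh_params(het = 0, missing = 0, min_snps = 15))
    for (h in 0:2) {
      for (mi in c(0, 2, 5)) {
        f2 <- flag_snps(fix$calls, roh_params(het = h, missing = mi, min_snps = 15))
        expect_true(all(f2[base]))
      }
    }
  }
})

test_that("F_ROH is summed segment length over the covered genome", {
  ext <- genome_extent(2e9)
  segs <- tibble::tibble(
    sample_id = "h1", chromosome = c(1L, 2L),
    start_bp = c(1, 1), end_bp = c(1.5e8, 0.5e8),
    n_snps = c(100L, 100L), length_bp = c(1.5e8, 0.5e8)
  )
  expect_equal(compute_f_roh(segs, ext)$f_roh, 0.1)
  # no segments -> 0 when the screened sample list is supplied
  none <- segs[0, ]
  expect_equal(compute_f_roh(none, ext, samples = "h1")$f_roh, 0)
  # segments covering the whole extent -> 1
  whole <- tibble::tibble(
    sample_id = "h1", chromosome = 1L, start_bp = 1,
    end_bp = 2e9, n_snps = 10L, length_bp = 2e9
  )
  expect_equal(compute_f_roh(whole, ext)$f_roh, 1)
  # overlapping segments are rejected
  bad <- segs
  bad$chromosome <- c(1L, 1L)
  bad$start_bp <- c(1, 1e8)
  bad$end_bp <- c(1.5e8, 2e8)
  expect_error(compute_f_roh(bad, ext), "overlap")
})

test_that("genome extent follows per-chromosome spans from the map", {
  map <- tibble::tibble(
    chromosome = c(1L, 1L, 2L, 2L),
    position_bp = c(1L, 1000000L, 100L, 20000099L)
  )
  ext <- genome_extent_from_map(map)
  expect_equal(ext$total_bp, 1e6 + 2e7)
  expect_equal(ext$per_chromosome$span_bp, c(1e6, 2e7))
  # chromosome with one SNP excluded with a warning
  map2 <- rbind(map, tibble::tibble(chromosome = 3L, position_bp = 5L))
  expect_warning(ext2 <- genome_extent_from_map(map2), "fewer than 2")
  expect_equal(ext2$total_bp, ext$total_bp)
  # 31-chromosome synthetic map equals direct max-min+1 summation
  set.seed(77)
  big <- tibble::tibble(
    chromosome = rep(1:31, each = 50),
    position_bp = as.integer(runif(31 * 50, 1, 5e7))
  )
  direct <- sum(tapply(big$position_bp, big$chromosome, function(x) {
    max(x) - min(x) + 1
  }))
  expect_equal(genome_extent_from_map(big)$total_bp, direct)
})

test_that("chromosome coverage averages over all screened individuals", {
  ext <- genome_extent(tibble::tibble(
    chromosome = c(1L, 2L), length_bp = c(1e6, 2e6)
  ))
  segs <- tibble::tibble(
    sample_id = c("a", "a", "b"), chromosome = c(1L, 2L, 1L),
    start_bp = c(1, 1, 1), end_bp = c(1e6, 1e6, 5e5),
    n_snps = 10L, length_bp = c(1e6, 1e6, 5e5)
  )
  cov <- chromosome_coverage(segs, ext, samples = c("a", "b"))
  expect_equal(cov$mean_pct[cov$chromosome == 1], 100 * (1 + 0.5) / 2)
  expect_equal(cov$mean_pct[cov$chromosome == 2], 100 * (0.5 + 0) / 2)
  # no segments anywhere -> zeros
  cov0 <- chromosome_coverage(segs[0, ], ext, samples = c("a", "b"))
  expect_equal(cov0$mean_pct, c(0, 0))
})

test_that("the .hom-style report round-trips through read.table", {
  segs <- tibble::tibble(
    sample_id = c("h1", "h2"), chromosome = c(1L, 2L),
    start_bp = c(1e6, 2e6), end_bp = c(2e6, 4e6),
    n_snps = c(120L, 150L), length_bp = c(1e6 + 1, 2e6 + 1)
  )
  tf <- tempfile(fileext = ".hom")
  write_hom_report(segs, tf)
  back <- utils::read.table(tf, header = TRUE)
  expect_equal(names(back), c(
    "IID", "CHR", "SNP1", "SNP2", "POS1", "POS2",
    "KB", "NSNP", "DENSITY"
  ))
  expect_equal(back$POS2, segs$end_bp)
  expect_equal(back$KB, round(segs$length_bp / 1000, 3))
})

test_that("grid files round-trip through read_roh_grid", {
  grid <- read_roh_grid(system.file("extdata", "roh_grid.yaml", package = "autozyg"))
  expect_length(grid, 8)
  expect_true("50snp_500kb_100snp_1_5" %in% names(grid))
  expect_true(grid[["pruned_50snp_500kb_50snp_0_1"]]$pruned)
  expect_equal(grid[["500snp_500kb_50snp_0_1"]]$window_snps, 500L)
  # defaults fill in unstated keys
  expect_equal(grid[[1]]$hit_threshold, 0.05)
  expect_equal(grid[[1]]$max_gap_kb, 100)
})
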