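# small configs keep the suite fast; the headline recovery run lives in
# test-acceptance.R
tiny_cfg <- function(seed, ...) {
  sim_config(
    n_founders = 20L, n_generations = 4L, offspring_per_generation = 30L,
    chromosomes = tibble::tibble(chromosome = 1:2, length_bp = 5e7),
    snps_per_chromosome = 500L, seed = seed, ...
  )
}

test_that("the generator is fully deterministic given the seed", {
  a <- simulate_population(tiny_cfg(99L))
  b <- simulate_population(tiny_cfg(99L))
  expect_identical(tibble::as_tibble(a$pedigree), tibble::as_tibble(b$pedigree))
  expect_identical(a$truth$true_f, b$truth$true_f)
  expect_identical(a$genotypes$calls, b$genotypes$calls)
  expect_identical(a$panel_b$samples, b$panel_b$samples)
  c <- simulate_population(tiny_cfg(100L))
  expect_false(identical(a$genotypes$calls, c$genotypes$calls))
})

test_that("pedigree simulation respects generations, pools and years", {
  cfg0 <- tiny_cfg(1L)
  cfg0$n_generations <- 0L
  ped0 <- simulate_pedigree(cfg0)
  expect_equal(nrow(ped0), 20)
  expect_true(all(is.na(ped0$sire_id)))

  ped <- simulate_pedigree(tiny_cfg(2L))
  expect_equal(ped$birth_year, 2000L + ped$generation)
  # every named sire is male and belongs to the top pool of its generation
  for (g in 1:4) {
    gen <- ped[ped$generation == g, ]
    prev <- ped[ped$generation == g - 1L, ]
    males <- prev$animal_id[prev$sex == "M"]
    pool <- males[seq_len(ceiling(0.15 * length(males)))]
    expect_true(all(gen$sire_id %in% pool))
    expect_true(all(gen$dam_id %in% prev$animal_id[prev$sex == "F"]))
  }

  # random mating among many founders: generation-1 F is essentially zero
  cfg_rm <- sim_config(
    n_founders = 60L, n_generations = 1L, offspring_per_generation = 50L,
    sire_pool_fraction = 1, seed = 3L
  )
  f1 <- compute_f_ped(simulate_pedigree(cfg_rm))
  expect_equal(max(f1$f_ped), 0)
})

test_that("intense sire selection drives median F_PED upward", {
  cfg <- sim_config(
    n_founders = 40L, n_generations = 10L, offspring_per_generation = 60L,
    sire_pool_fraction = 0.1, seed = 11L
  )
  ped <- simulate_pedigree(cfg)
  f <- compute_f_ped(ped)
  s <- summarize_f_by_year(f, ped, "median")
  med <- s$f[s$birth_year >= 2002] # generation 2 onwards
  expect_true(all(diff(med) > 0))
  expect_gt(trend_delta(s, 2002, 2010), 0)
})

test_that("gene dropping transmits unbroken haplotypes when recombination is off", {
  cfg <- tiny_cfg(7L, recomb_rate_cM_per_Mb = 0)
  ped <- simulate_pedigree(cfg)
  mos <- drop_genes(ped, cfg)
  for (id in sample(names(mos), 20)) {
    for (hap in mos[[id]][c("pat", "mat")]) {
      for (chr in hap) {
        expect_length(chr$labels, 1)
      }
    }
  }
  # founders carry two pure, distinct labels
  founder <- ped$animal_id[is.na(ped$sire_id)][1]
  expect_false(mos[[founder]]$pat[[1]]$labels == mos[[founder]]$mat[[1]]$labels)
})

test_that("crossover counts follow the Poisson genetic-map length", {
  # 2 founders, many offspring: every gamete junction is a crossover
  ped <- as_pedigree(tibble::tibble(
    animal_id = c("A", "B", sprintf("x%04d", 1:2000)),
    sire_id = c(NA, NA, rep("A", 2000)),
    dam_id = c(NA, NA, rep("B", 2000))
  ))
  cfg <- sim_config(
    n_founders = 2L,
    chromosomes = tibble::tibble(chromosome = 1L, length_bp = 1e8),
    recomb_rate_cM_per_Mb = 1, seed = 12L
  )
  mos <- drop_genes(ped, cfg)
  junctions <- unlist(lapply(sprintf("x%04d", 1:2000), function(id) {
    c(
      length(mos[[id]]$pat[[1]]$labels) - 1L,
      length(mos[[id]]$mat[[1]]$labels) - 1L
    )
  }))
  # expected 1.0 per 100-Mb gamete at 1 cM/Mb; 4000 replicates
  expect_equal(mean(junctions), 1.0, tolerance = 0.06)
})

test_that("true autozygosity matches the pedigree expectation", {
  # parent-offspring mating, no recombination: per-chromosome IBD is 0/1
  # with expectation 0.25
  n_rep <- 1500
  ped <- as_pedigree(tibble::tibble(
    animal_id = c("A", "B", "S", sprintf("x%04d", 1:n_rep)),
    sire_id = c(NA, NA, "A", rep("S", n_rep)),
    dam_id = c(NA, NA, "B", rep("B", n_rep))
  ))
  cfg <- sim_config(
    n_founders = 2L,
    chromosomes = tibble::tibble(chromosome = 1L, length_bp = 1e8),
    recomb_rate_cM_per_Mb = 0, seed = 13L
  )
  truth <- true_autozygosity(drop_genes(ped, cfg), cfg,
    ids = sprintf("x%04d", 1:n_rep)
  )
  expect_true(all(truth$true_f %in% c(0, 1)))
  # MC standard error ~ sqrt(0.1875/1500) = 0.011; allow 3 SE
  expect_equal(mean(truth$true_f), 0.25, tolerance = 0.034)
  # founders are never autozygous
  expect_equal(true_autozygosity(drop_genes(ped, cfg), cfg, ids = "A")$true_f, 0)

  # population mean truth tracks mean F_PED in full simulations; the gap is
  # dominated by drift shared across a cohort, so average over replicates
  gaps <- vapply(c(14L, 140L, 1400L), function(s) {
    sim <- simulate_population(tiny_cfg(s))
    fped <- compute_f_ped(sim$pedigree)
    mean(sim$truth$true_f) -
      mean(fped$f_ped[match(sim$cohort, fped$animal_id)])
  }, numeric(1))
  expect_lt(abs(mean(gaps)), 0.04)
})

test_that("genotypes agree with mosaics when error and missingness are off", {
  cfg <- tiny_cfg(15L, genotyping_error_rate = 0, missing_rate = 0)
  ped <- simulate_pedigree(cfg)
  mos <- drop_genes(ped, cfg)
  ids <- ped$animal_id[ped$generation == 4L][1:10]
  geno <- genotypes_from_mosaics(mos, cfg, ids = ids)
  g <- geno$genotypes
  expect_false(anyNA(g$calls))
  # autozygous positions must be homozygous
  truth <- true_autozygosity(mos, cfg, ids = ids)
  for (k in seq_along(ids)) {
    segs <- truth$ibd_segments[[k]]
    for (r in seq_len(nrow(segs))) {
      jj <- which(g$map$chromosome == segs$chromosome[r] &
        g$map$position_bp > segs$start_bp[r] &
        g$map$position_bp <= segs$end_bp[r])
      expect_true(all(g$calls[k, jj] %in% c(0L, 2L)))
    }
  }
})

test_that("error and missingness rates act as specified", {
  cfg <- tiny_cfg(16L, missing_rate = 1)
  ped <- simulate_pedigree(cfg)
  mos <- drop_genes(ped, cfg)
  g <- genotypes_from_mosaics(mos, cfg, ids = ped$animal_id[1:5])$genotypes
  expect_true(all(is.na(g$calls)))

  cfg2 <- tiny_cfg(17L, genotyping_error_rate = 0.3, missing_rate = 0)
  cfg3 <- tiny_cfg(17L, genotyping_error_rate = 0, missing_rate = 0)
  ids <- simulate_pedigree(cfg2)$animal_id[1:20]
  mos2 <- drop_genes(simulate_pedigree(cfg2), cfg2)
  g2 <- genotypes_from_mosaics(mos2, cfg2, ids = ids)$genotypes
  g3 <- genotypes_from_mosaics(mos2, cfg3, ids = ids)$genotypes
  frac_changed <- mean(g2$calls != g3$calls)
  # 20,000 Bernoulli(0.3) cells: MC standard error ~0.0032, allow ~4 SE
  expect_lt(abs(frac_changed - 0.3), 0.015)
})

test_that("the two-panel split shares the configured SNP fraction", {
  cfg <- tiny_cfg(18L, panel_overlap_fraction = 0.9)
  sim <- simulate_population(cfg)
  m_total <- nrow(sim$genotypes$map)
  shared <- intersect(sim$panel_a$map$name, sim$panel_b$map$name)
  expect_equal(length(shared), round(0.9 * m_total))
  # cohorts are disjoint and cover the genotyped set
  expect_length(intersect(sim$panel_a$samples, sim$panel_b$samples), 0)
  expect_setequal(
    c(sim$panel_a$samples, sim$panel_b$samples),
    sim$genotypes$samples
  )
  # merging the panels recovers exactly the shared SNPs
  merged <- merge_panels(sim$panel_a, sim$panel_b)
  expect_setequal(merged$map$name, shared)
})

test_that("allowance settings recover at least as much ROH under genotyping error", {
  cfg <- sim_config(
    n_founders = 30L, n_generations = 6L, offspring_per_generation = 60L,
    chromosomes = tibble::tibble(chromosome = 1:2, length_bp = 1e8),
    snps_per_chromosome = 2000L,
    genotyping_error_rate = 0.01, missing_rate = 0.01,
    seed = 19L
  )
  sim <- simulate_population(cfg)
  total_by <- function(p) {
    segs <- detect_roh(sim$genotypes, p)
    s <- compute_f_roh(segs, genome_extent_from_map(sim$genotypes$map),
      samples = sim$cohort
    )
    s$f_roh
  }
  with_allow <- total_by(best_setting())
  strict <- total_by(roh_params(het = 0, missing = 0))
  expect_gte(mean(with_allow), mean(strict))
})
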