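#' Configuration for the gene-dropping simulator
#'
#' Describes a closed population bred for a fixed number of discrete
#' generations under intense sire selection: every generation,
#' `offspring_per_generation` offspring draw their sire uniformly from the
#' top `sire_pool_fraction` of the previous generation's males and their dam
#' uniformly from the previous generation's females. Founder haplotypes carry
#' distinct labels; gametes recombine under a Haldane (no-interference) model
#' with a Poisson crossover count of mean
#' `length_bp * recomb_rate_cM_per_Mb / 1e8` per chromosome. Genotypes are
#' read off the haplotype mosaics at array-like, regularly spaced SNPs, then
#' perturbed by symmetric genotyping error and missingness, and split into
#' two partially overlapping SNP panels.
#'
#' @param n_founders Number of founders (sex alternates male/female).
#' @param n_generations Number of discrete offspring generations.
#' @param offspring_per_generation Offspring per generation (sex alternates).
#' @param sire_pool_fraction Fraction of the previous generation's males used
#'   as sires, in (0, 1\].
#' @param chromosomes Data frame with `chromosome` and `length_bp`; default 5
#'   autosomes of 100 Mb.
#' @param snps_per_chromosome SNPs per chromosome, equally spaced.
#' @param founder_allele_freq Length-2 vector: the alternate-allele frequency
#'   of each SNP is drawn uniformly from this range.
#' @param recomb_rate_cM_per_Mb Recombination rate (1 cM/Mb default).
#' @param genotyping_error_rate Probability a call is replaced by a uniformly
#'   chosen different call.
#' @param missing_rate Probability a call is set missing.
#' @param panel_overlap_fraction Fraction of SNPs shared by the two panels;
#'   the remainder is split evenly between them.
#' @param cohort_b_fraction Fraction of genotyped individuals assigned to the
#'   second (smaller) panel's cohort.
#' @param seed Mandatory integer seed; every stochastic operation derives its
#'   stream from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_founders = 40L,
                       n_generations = 10L,
                       offspring_per_generation = 200L,
                       sire_pool_fraction = 0.15,
                       chromosomes = tibble::tibble(
                         chromosome = 1:5,
                         length_bp = 1e8
                       ),
                       snps_per_chromosome = 2000L,
                       founder_allele_freq = c(0.05, 0.5),
                       recomb_rate_cM_per_Mb = 1.0,
                       genotyping_error_rate = 0.002,
                       missing_rate = 0.01,
                       panel_overlap_fraction = 0.9,
                       cohort_b_fraction = 0.16,
                       seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(
    n_founders >= 2, n_generations >= 0, offspring_per_generation >= 1,
    sire_pool_fraction > 0, sire_pool_fraction <= 1,
    all(chromosomes$length_bp > 0),
    snps_per_chromosome >= 2,
    genotyping_error_rate >= 0, genotyping_error_rate <= 1,
    missing_rate >= 0, missing_rate <= 1,
    panel_overlap_fraction >= 0, panel_overlap_fraction <= 1,
    cohort_b_fraction >= 0, cohort_b_fraction < 1
  )
  structure(
    list(
      n_founders = as.integer(n_founders),
      n_generations = as.integer(n_generations),
      offspring_per_generation = as.integer(offspring_per_generation),
      sire_pool_fraction = sire_pool_fraction,
      chromosomes = tibble::as_tibble(chromosomes),
      snps_per_chromosome = as.integer(snps_per_chromosome),
      founder_allele_freq = founder_allele_freq,
      recomb_rate_cM_per_Mb = recomb_rate_cM_per_Mb,
      genotyping_error_rate = genotyping_error_rate,
      missing_rate = missing_rate,
      panel_overlap_fraction = panel_overlap_fraction,
      cohort_b_fraction = cohort_b_fraction,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate a multi-generation pedigree under sire selection
#'
#' Discrete generations with `birth_year = 2000 + generation`; founders are
#' generation 0. Sex alternates deterministically within each generation so
#' both parent pools are always non-empty.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed (default `cfg$seed`).
#' @return A `pedigree` tibble with extra columns `sex` ("M"/"F") and
#'   `generation`.
#' @export
simulate_pedigree <- function(cfg, seed = cfg$seed) {
  set.seed(seed)
  founders <- tibble::tibble(
    animal_id = sprintf("G00_%04d", seq_len(cfg$n_founders)),
    sire_id = NA_character_, dam_id = NA_character_,
    birth_year = 2000L, country = NA_character_,
    sex = rep_len(c("M", "F"), cfg$n_founders),
    generation = 0L
  )
  gens <- list(founders)
  prev <- founders
  for (g in seq_len(cfg$n_generations)) {
    males <- prev$animal_id[prev$sex == "M"]
    females <- prev$animal_id[prev$sex == "F"]
    if (length(males) == 0 || length(females) == 0) {
      stop("empty sire or dam pool in generation ", g, call. = FALSE)
    }
    pool <- males[seq_len(max(1L, ceiling(cfg$sire_pool_fraction * length(males))))]
    n <- cfg$offspring_per_generation
    gen <- tibble::tibble(
      animal_id = sprintf("G%02d_%04d", g, seq_len(n)),
      sire_id = sample(pool, n, replace = TRUE),
      dam_id = sample(females, n, replace = TRUE),
      birth_year = 2000L + g, country = NA_character_,
      sex = rep_len(c("M", "F"), n),
      generation = g
    )
    gens[[g + 1L]] <- gen
    prev <- gen
  }
  all <- dplyr::bind_rows(gens)
  ped <- as_pedigree(all)
  ped$sex <- all$sex
  ped$generation <- all$generation
  ped
}

## extract the part of a haplotype inside (a, b]; ends/labels representation
slice_hap <- function(ends, labels, a, b) {
  keep <- which(ends > a)
  keep <- keep[c(TRUE, ends[keep][-length(keep)] < b)] # segments starting before b
  e <- pmin(ends[keep], b)
  list(ends = e, labels = labels[keep])
}

## one meiosis: recombine two parental haplotypes of one chromosome
meiose <- function(hap1, hap2, length_bp, rate_cm_per_mb) {
  n_xo <- rpois(1, length_bp * rate_cm_per_mb / 1e8)
  cur <- sample(1:2, 1)
  if (n_xo == 0) {
    return(if (cur == 1) hap1 else hap2)
  }
  xo <- sort(runif(n_xo, min = 0, max = length_bp))
  bounds <- c(xo, length_bp)
  ends <- numeric(0)
  labels <- integer(0)
  a <- 0
  for (b in bounds) {
    if (b > a) {
      h <- if (cur == 1) hap1 else hap2
      piece <- slice_hap(h$ends, h$labels, a, b)
      ends <- c(ends, piece$ends)
      labels <- c(labels, piece$labels)
      a <- b
    }
    cur <- 3L - cur
  }
  ## merge runs of equal labels
  same <- c(labels[-1] == labels[-length(labels)], FALSE)
  list(ends = ends[!same], labels = labels[!same])
}

#' Drop founder-labelled genes through a pedigree
#'
#' Assigns the `2 * n_founders` founder haplotypes distinct integer labels and
#' transmits them through the pedigree: each gamete draws a Poisson number of
#' crossovers per chromosome, places them uniformly, and alternates between
#' the parent's two haplotypes. Every individual's genome is then a mosaic of
#' founder-labelled segments.
#'
#' @param ped A `pedigree` (typically from [simulate_pedigree()]).
#' @param cfg A [sim_config()].
#' @param seed Integer seed (default `cfg$seed + 1`).
#' @return A `mosaics` object: named list (by animal id) of
#'   `list(pat = , mat = )`, each a per-chromosome list of
#'   `list(ends, labels)` with continuous bp coordinates; the chromosome table
#'   is attached as attribute `chromosomes`.
#' @export
drop_genes <- function(ped, cfg, seed = cfg$seed + 1L) {
  set.seed(seed)
  ord <- topological_order(ped)
  sire <- setNames(ped$sire_id, ped$animal_id)
  dam <- setNames(ped$dam_id, ped$animal_id)
  chrs <- cfg$chromosomes
  mos <- vector("list", nrow(ped))
  names(mos) <- ord
  next_label <- 1L
  for (id in ord) {
    s <- sire[[id]]
    d <- dam[[id]]
    if (is.na(s) || is.na(d)) {
      ## founder (or unknown-parent individual): two fresh unbroken haplotypes
      hap <- function(lab) {
        lapply(chrs$length_bp, function(L) list(ends = L, labels = lab))
      }
      mos[[id]] <- list(pat = hap(next_label), mat = hap(next_label + 1L))
      next_label <- next_label + 2L
    } else {
      gamete_from <- function(parent) {
        lapply(seq_len(nrow(chrs)), function(c) {
          meiose(
            parent$pat[[c]], parent$mat[[c]],
            chrs$length_bp[c], cfg$recomb_rate_cM_per_Mb
          )
        })
      }
      mos[[id]] <- list(
        pat = gamete_from(mos[[s]]),
        mat = gamete_from(mos[[d]])
      )
    }
  }
  structure(mos, class = "mosaics", chromosomes = chrs)
}

#' True autozygosity from founder-label mosaics
#'
#' Intersects each individual's paternal and maternal label mosaics:
#' identity by descent holds wherever the two labels agree. The autozygous
#' fraction is the summed IBD length over the total autosome length.
#'
#' @param mosaics A `mosaics` object from [drop_genes()].
#' @param cfg The generating [sim_config()].
#' @param ids Animal ids to evaluate (default: all).
#' @return Tibble with `sample_id`, `true_f`, and a list-column
#'   `ibd_segments` of per-individual segment tibbles
#'   (`chromosome`, `start_bp`, `end_bp`).
#' @export
true_autozygosity <- function(mosaics, cfg, ids = NULL) {
  if (is.null(ids)) ids <- names(mosaics)
  chrs <- attr(mosaics, "chromosomes")
  total <- sum(chrs$length_bp)
  rows <- purrr::map(ids, function(id) {
    m <- mosaics[[id]]
    segs <- list()
    ibd_bp <- 0
    for (c in seq_len(nrow(chrs))) {
      p <- m$pat[[c]]
      q <- m$mat[[c]]
      ends <- sort(unique(c(p$ends, q$ends)))
      starts <- c(0, ends[-length(ends)])
      mid <- (starts + ends) / 2
      lp <- p$labels[findInterval(mid, p$ends) + 1L]
      lq <- q$labels[findInterval(mid, q$ends) + 1L]
      ibd <- lp == lq
      if (any(ibd)) {
        ## merge adjacent IBD pieces
        r <- rle(ibd)
        e <- cumsum(r$lengths)
        s <- e - r$lengths + 1L
        for (k in which(r$values)) {
          segs[[length(segs) + 1L]] <- tibble::tibble(
            chromosome = chrs$chromosome[c],
            start_bp = starts[s[k]], end_bp = ends[e[k]]
          )
          ibd_bp <- ibd_bp + ends[e[k]] - starts[s[k]]
        }
      }
    }
    tibble::tibble(
      sample_id = id,
      true_f = ibd_bp / total,
      ibd_segments = list(
        if (length(segs) > 0) {
          dplyr::bind_rows(segs)
        } else {
          tibble::tibble(
            chromosome = integer(0),
            start_bp = numeric(0), end_bp = numeric(0)
          )
        }
      )
    )
  })
  dplyr::bind_rows(rows)
}

#' Genotypes (and a two-panel split) from founder-label mosaics
#'
#' Places `snps_per_chromosome` equally spaced SNPs per chromosome, draws each
#' SNP's alternate-allele frequency uniformly from `founder_allele_freq`,
#' assigns every founder haplotype an allele per SNP at that frequency, and
#' reads diploid calls off the two mosaics of each requested individual.
#' Symmetric genotyping error then replaces each call, independently with
#' probability `genotyping_error_rate`, by a uniformly chosen different call,
#' and calls are set missing with probability `missing_rate`. Finally
#' individuals are partitioned into two cohorts whose SNP panels share
#' `panel_overlap_fraction` of the SNPs.
#'
#' @param mosaics A `mosaics` object from [drop_genes()].
#' @param cfg The generating [sim_config()].
#' @param ids Individuals to genotype (default: all in `mosaics`).
#' @param seed Integer seed (default `cfg$seed + 2`).
#' @return List: `genotypes` (the full [genotype_matrix()], all ids x all
#'   SNPs), `panel_a`, `panel_b` (cohort-and-panel submatrices) and
#'   `cohorts` (tibble of `sample_id`, `cohort`).
#' @export
genotypes_from_mosaics <- function(mosaics, cfg, ids = NULL, seed = cfg$seed + 2L) {
  set.seed(seed)
  if (is.null(ids)) ids <- names(mosaics)
  chrs <- attr(mosaics, "chromosomes")
  m_per <- cfg$snps_per_chromosome
  maps <- purrr::map(seq_len(nrow(chrs)), function(c) {
    spacing <- floor(chrs$length_bp[c] / m_per)
    tibble::tibble(
      chromosome = chrs$chromosome[c],
      name = sprintf("snp_%d_%04d", chrs$chromosome[c], seq_len(m_per)),
      cm = 0,
      position_bp = spacing * seq_len(m_per),
      a1 = "A", a2 = "B"
    )
  })
  map <- dplyr::bind_rows(maps)
  m <- nrow(map)
  p_alt <- runif(m, cfg$founder_allele_freq[1], cfg$founder_allele_freq[2])
  n_hap <- 2L * cfg$n_founders
  ## rows indexed by founder haplotype label
  hap_alleles <- matrix(
    rbinom(n_hap * m, 1L, rep(p_alt, each = n_hap)),
    nrow = n_hap, ncol = m
  )
  ## labels beyond the founder range (unknown-parent augmentation) draw fresh
  max_lab <- max(unlist(lapply(
    mosaics[ids],
    function(x) vapply(c(x$pat, x$mat), function(h) max(as.numeric(h$labels)), numeric(1))
  )))
  if (max_lab > n_hap) {
    extra <- matrix(
      rbinom((max_lab - n_hap) * m, 1L, rep(p_alt, each = max_lab - n_hap)),
      nrow = max_lab - n_hap, ncol = m
    )
    hap_alleles <- rbind(hap_alleles, extra)
  }

  calls <- matrix(NA_integer_, nrow = length(ids), ncol = m)
  chr_cols <- split(seq_len(m), map$chromosome)[as.character(chrs$chromosome)]
  for (i in seq_along(ids)) {
    mo <- mosaics[[ids[i]]]
    for (c in seq_len(nrow(chrs))) {
      jj <- chr_cols[[c]]
      pos <- map$position_bp[jj]
      hp <- mo$pat[[c]]
      hm <- mo$mat[[c]]
      ## segment k covers (ends[k-1], ends[k]]; left-open matching is exact
      lp <- hp$labels[findInterval(pos, hp$ends, left.open = TRUE) + 1L]
      lm <- hm$labels[findInterval(pos, hm$ends, left.open = TRUE) + 1L]
      calls[i, jj] <- hap_alleles[cbind(lp, jj)] + hap_alleles[cbind(lm, jj)]
    }
  }
  ## symmetric genotyping error, then missingness
  if (cfg$genotyping_error_rate > 0) {
    hit <- which(runif(length(calls)) < cfg$genotyping_error_rate)
    if (length(hit) > 0) {
      shift <- sample(1:2, length(hit), replace = TRUE)
      calls[hit] <- (calls[hit] + shift) %% 3L
    }
  }
  if (cfg$missing_rate > 0) {
    calls[runif(length(calls)) < cfg$missing_rate] <- NA_integer_
  }
  g <- genotype_matrix(ids, map, calls)

  ## two-cohort, two-panel split
  n_b <- round(cfg$cohort_b_fraction * length(ids))
  b_ids <- if (n_b > 0) sample(ids, n_b) else character(0)
  a_ids <- setdiff(ids, b_ids)
  n_shared <- round(cfg$panel_overlap_fraction * m)
  shared <- sort(sample.int(m, n_shared))
  rest <- setdiff(seq_len(m), shared)
  only_a <- rest[seq_along(rest) %% 2L == 1L]
  only_b <- setdiff(rest, only_a)
  panel_a <- subset_genotypes(g,
    samples = a_ids,
    snps = map$name[sort(c(shared, only_a))]
  )
  panel_b <- subset_genotypes(g,
    samples = b_ids,
    snps = map$name[sort(c(shared, only_b))]
  )
  list(
    genotypes = g, panel_a = panel_a, panel_b = panel_b,
    cohorts = tibble::tibble(
      sample_id = c(a_ids, b_ids),
      cohort = rep(c("A", "B"), c(length(a_ids), length(b_ids)))
    )
  )
}

#' Run the full simulation pipeline
#'
#' Convenience wrapper: pedigree, gene dropping, ground-truth autozygosity and
#' genotypes for the final generation (the genotyped cohort).
#'
#' @param cfg A [sim_config()].
#' @return List with `config`, `pedigree`, `mosaics`, `cohort` (ids of the
#'   final generation), `truth`, and the [genotypes_from_mosaics()] output
#'   (`genotypes`, `panel_a`, `panel_b`, `cohorts`).
#' @export
simulate_population <- function(cfg) {
  ped <- simulate_pedigree(cfg)
  mos <- drop_genes(ped, cfg)
  cohort <- ped$animal_id[ped$generation == cfg$n_generations]
  truth <- true_autozygosity(mos, cfg, ids = cohort)
  geno <- genotypes_from_mosaics(mos, cfg, ids = cohort)
  c(
    list(
      config = cfg, pedigree = ped, mosaics = mos,
      cohort = cohort, truth = truth
    ),
    geno
  )
}
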