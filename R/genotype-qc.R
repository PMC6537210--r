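AUTOSOMES <- 1:31 # equine autosome labels; X/Y are never admitted

#' Merge two genotyping panels on identical SNP coordinates
#'
#' Keeps exactly the SNPs whose (name, chromosome, position) triplet is
#' identical in both panels, drops non-autosomal SNPs, and concatenates the
#' (disjoint) individual sets. A SNP name present in both panels with a
#' conflicting chromosome or position is excluded and reported in the
#' `conflicts` attribute rather than failing the merge. Allele orientation is
#' harmonised to panel `a`; a shared SNP with an incompatible allele pair is
#' also treated as a conflict.
#'
#' @param a,b [genotype_matrix()] objects with disjoint sample ids.
#' @return A [genotype_matrix()] with attribute `conflicts` (tibble of
#'   excluded SNP names and reasons).
#' @export
merge_panels <- function(a, b) {
  if (length(intersect(a$samples, b$samples)) > 0) {
    stop("panels share sample ids; cohorts must be disjoint", call. = FALSE)
  }
  shared <- intersect(a$map$name, b$map$name)
  ia <- match(shared, a$map$name)
  ib <- match(shared, b$map$name)
  same_locus <- a$map$chromosome[ia] == b$map$chromosome[ib] &
    a$map$position_bp[ia] == b$map$position_bp[ib]
  same_alleles <- mapply(function(x1, x2, y1, y2) {
    setequal(setdiff(c(x1, x2), NA), setdiff(c(y1, y2), NA)) ||
      all(is.na(c(x1, x2))) || all(is.na(c(y1, y2)))
  }, a$map$a1[ia], a$map$a2[ia], b$map$a1[ib], b$map$a2[ib])
  autosomal <- a$map$chromosome[ia] %in% AUTOSOMES
  ok <- same_locus & same_alleles & autosomal
  conflicts <- tibble::tibble(
    name = shared[!ok],
    reason = dplyr::case_when(
      !same_locus[!ok] ~ "coordinate mismatch",
      !same_alleles[!ok] ~ "allele mismatch",
      TRUE ~ "non-autosomal"
    )
  )
  ia <- ia[ok]
  ib <- ib[ok]
  ## flip panel-b calls where its a1/a2 orientation is swapped
  calls_b <- b$calls[, ib, drop = FALSE]
  flipped <- !is.na(b$map$a1[ib]) & !is.na(a$map$a2[ia]) &
    b$map$a1[ib] == a$map$a2[ia] & b$map$a2[ib] != b$map$a1[ib]
  if (any(flipped)) {
    calls_b[, flipped] <- 2L - calls_b[, flipped, drop = FALSE]
  }
  map <- a$map[ia, , drop = FALSE]
  ord <- order(map$chromosome, map$position_bp)
  out <- genotype_matrix(
    c(a$samples, b$samples),
    map[ord, , drop = FALSE],
    rbind(a$calls[, ia, drop = FALSE], calls_b)[, ord, drop = FALSE]
  )
  attr(out, "conflicts") <- conflicts
  out
}

#' Per-SNP allele frequency and call rate
#'
#' @param g A [genotype_matrix()].
#' @return Tibble with one row per SNP: `name`, `maf` = min(p, 1 - p) where p
#'   is the alternate-allele frequency among non-missing calls (`NA` when all
#'   calls are missing), and `call_rate` = non-missing / total.
#' @export
allele_frequency <- function(g) {
  nonmiss <- unname(colSums(!is.na(g$calls)))
  alt <- unname(colSums(g$calls, na.rm = TRUE))
  p <- ifelse(nonmiss > 0, alt / (2 * nonmiss), NA_real_)
  tibble::tibble(
    name = g$map$name,
    maf = pmin(p, 1 - p),
    call_rate = nonmiss / length(g$samples)
  )
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditional on the allele counts: the p-value is the
#' sum of probabilities, over all heterozygote counts of the same parity
#' within the feasible range, whose conditional probability does not exceed
#' that of the observed count. Probabilities are built by the standard stable
#' recurrence from the distribution mode. Vectorised over genotype counts.
#'
#' @param n_hom1,n_het,n_hom2 Non-negative genotype counts (recycled).
#' @return p-values in (0, 1\]; a monomorphic SNP gives exactly 1.
#' @export
#' @examples
#' hwe_exact_pvalue(10, 5, 5)
hwe_exact_pvalue <- function(n_hom1, n_het, n_hom2) {
  args <- vctrs_recycle(n_hom1, n_het, n_hom2)
  mapply(hwe_exact_one, args[[1]], args[[2]], args[[3]])
}

vctrs_recycle <- function(...) {
  xs <- list(...)
  n <- max(lengths(xs))
  lapply(xs, rep_len, length.out = n)
}

hwe_exact_one <- function(n_hom1, n_het, n_hom2) {
  stopifnot(n_hom1 >= 0, n_het >= 0, n_hom2 >= 0)
  n <- n_hom1 + n_het + n_hom2
  if (n < 1) stop("at least one genotyped individual required", call. = FALSE)
  n_rare <- 2L * min(n_hom1, n_hom2) + n_het
  dist <- hwe_het_distribution(n, n_rare)
  p_obs <- dist[as.character(n_het)]
  ## relative tolerance guards against ties lost to floating-point noise
  min(1, sum(dist[dist <= p_obs * (1 + 1e-12)]))
}

## conditional distribution of the heterozygote count given n individuals and
## n_rare copies of the rarer allele; names are attainable het counts
hwe_het_distribution <- function(n, n_rare) {
  if (n_rare == 0) {
    return(stats::setNames(1, "0"))
  }
  hets <- seq(n_rare %% 2L, min(n_rare, 2L * n - n_rare), by = 2L)
  probs <- numeric(length(hets))
  mid_i <- which.min(abs(hets - n_rare * (2 * n - n_rare) / (2 * n)))
  probs[mid_i] <- 1
  ## downward recurrence: P(h-2)/P(h) = h(h-1) / (4 (nAA+1)(nBB+1))
  if (mid_i > 1) {
    for (k in seq(mid_i, 2L)) {
      h <- hets[k]
      naa <- (n_rare - h) / 2
      nbb <- n - naa - h
      probs[k - 1] <- probs[k] * h * (h - 1) / (4 * (naa + 1) * (nbb + 1))
    }
  }
  ## upward recurrence: P(h+2)/P(h) = 4 nAA nBB / ((h+2)(h+1))
  if (mid_i < length(hets)) {
    for (k in seq(mid_i, length(hets) - 1L)) {
      h <- hets[k]
      naa <- (n_rare - h) / 2
      nbb <- n - naa - h
      probs[k + 1] <- probs[k] * 4 * naa * nbb / ((h + 2) * (h + 1))
    }
  }
  stats::setNames(probs / sum(probs), hets)
}

#' Quality-control thresholds
#'
#' Defaults follow common SNP-array practice for this kind of study: SNPs are
#' retained only when MAF > 0.01, HWE exact p > 1e-4 and call rate > 0.95
#' (strict inequalities); individuals with more than 15% missing calls are
#' removed first.
#'
#' @param maf_min,hwe_p_min,snp_call_rate_min,indiv_missing_max Reals in
#'   \[0, 1\].
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(maf_min = 0.01, hwe_p_min = 1e-4,
                          snp_call_rate_min = 0.95, indiv_missing_max = 0.15) {
  vals <- c(maf_min, hwe_p_min, snp_call_rate_min, indiv_missing_max)
  stopifnot(all(vals >= 0 & vals <= 1))
  structure(
    list(
      maf_min = maf_min, hwe_p_min = hwe_p_min,
      snp_call_rate_min = snp_call_rate_min,
      indiv_missing_max = indiv_missing_max
    ),
    class = "qc_thresholds"
  )
}

#' Quality-filter a genotype matrix
#'
#' Removes, in one pass each: (1) individuals whose missing-call fraction
#' exceeds `indiv_missing_max`; then (2) SNPs failing any of MAF >
#' `maf_min`, HWE exact p > `hwe_p_min`, call rate > `snp_call_rate_min`
#' (all strict). Each removed SNP is counted once, under the first criterion
#' it fails (MAF, then HWE, then call rate).
#'
#' @param g A [genotype_matrix()].
#' @param thresholds A [qc_thresholds()].
#' @return List with `genotypes` (filtered matrix) and `report`, a tibble of
#'   per-criterion removal counts.
#' @export
qc_filter <- function(g, thresholds = qc_thresholds()) {
  t <- thresholds
  miss_frac <- rowMeans(is.na(g$calls))
  drop_ind <- miss_frac > t$indiv_missing_max
  g2 <- genotype_matrix(
    g$samples[!drop_ind], g$map,
    g$calls[!drop_ind, , drop = FALSE]
  )
  af <- allele_frequency(g2)
  counts <- genotype_counts(g2)
  hwe_p <- hwe_exact_pvalue(counts$n_hom1, counts$n_het, counts$n_hom2)
  hwe_p[counts$n_hom1 + counts$n_het + counts$n_hom2 == 0] <- NA_real_
  fail_maf <- is.na(af$maf) | af$maf <= t$maf_min
  fail_hwe <- !fail_maf & (is.na(hwe_p) | hwe_p <= t$hwe_p_min)
  fail_rate <- !fail_maf & !fail_hwe & af$call_rate <= t$snp_call_rate_min
  keep <- !(fail_maf | fail_hwe | fail_rate)
  out <- genotype_matrix(
    g2$samples, g2$map[keep, , drop = FALSE],
    g2$calls[, keep, drop = FALSE]
  )
  if (length(out$samples) == 0 || nrow(out$map) == 0) {
    warning("quality filtering removed all individuals or all SNPs", call. = FALSE)
  }
  report <- tibble::tibble(
    criterion = c(
      "individual_missingness", "maf", "hwe", "call_rate",
      "snps_retained", "individuals_retained"
    ),
    removed = c(
      sum(drop_ind), sum(fail_maf), sum(fail_hwe), sum(fail_rate),
      sum(keep), length(out$samples)
    )
  )
  list(genotypes = out, report = report)
}

genotype_counts <- function(g) {
  tibble::tibble(
    name = g$map$name,
    n_hom1 = colSums(g$calls == 0L, na.rm = TRUE),
    n_het = colSums(g$calls == 1L, na.rm = TRUE),
    n_hom2 = colSums(g$calls == 2L, na.rm = TRUE)
  )
}

#' Greedy sliding-window LD pruning
#'
#' Within each window of `window_snps` consecutive SNPs, repeatedly removes
#' the later SNP of any pair whose squared pairwise-complete genotype
#' correlation exceeds `r2_max`, then advances by `step_snps`. Zero-variance
#' SNPs are treated as uncorrelated. Deterministic.
#'
#' @param g A [genotype_matrix()].
#' @param window_snps,step_snps Window size and step, in SNPs.
#' @param r2_max Squared-correlation threshold.
#' @return Character vector of retained SNP names, in map order.
#' @export
ld_prune <- function(g, window_snps = 50L, step_snps = 5L, r2_max = 0.5) {
  m <- nrow(g$map)
  keep <- rep(TRUE, m)
  for (chr in unique(g$map$chromosome)) {
    jj <- which(g$map$chromosome == chr)
    start <- 1L
    while (start <= length(jj)) {
      win <- jj[start:min(start + window_snps - 1L, length(jj))]
      win_live <- win[keep[win]]
      if (length(win_live) > 1) {
        x <- g$calls[, win_live, drop = FALSE]
        suppressWarnings(r <- stats::cor(x, use = "pairwise.complete.obs"))
        r[is.na(r)] <- 0 # zero-variance or no shared calls
        r2 <- r^2
        for (a in seq_len(length(win_live) - 1L)) {
          if (!keep[win_live[a]]) next
          for (b in seq(a + 1L, length(win_live))) {
            if (keep[win_live[b]] && r2[a, b] > r2_max) {
              keep[win_live[b]] <- FALSE
            }
          }
        }
      }
      if (start + window_snps - 1L >= length(jj)) break
      start <- start + step_snps
    }
  }
  g$map$name[keep]
}
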