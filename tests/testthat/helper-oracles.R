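# Independent brute-force oracles and fixture builders. These deliberately
# share no code with the package implementations they cross-check.

# Random acyclic pedigree with frequent loops; parents are any two distinct
# earlier individuals (the F recursion is sex-agnostic).
random_pedigree <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("I%03d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i >= 3 && runif(1) < 0.85) {
      pars <- sample(i - 1L, 2L)
      sire[i] <- ids[pars[1]]
      dam[i] <- ids[pars[2]]
    }
  }
  as_pedigree(tibble::tibble(
    animal_id = ids, sire_id = sire, dam_id = dam,
    birth_year = 2000L + (seq_len(n) - 1L) %/% 5L
  ))
}

# Recursive kinship coefficient with memoisation; phi(parents) is the
# offspring's F.
kinship_oracle <- function(ped) {
  idx <- seq_len(nrow(ped))
  names(idx) <- ped$animal_id
  sire <- unname(idx[ped$sire_id])
  dam <- unname(idx[ped$dam_id])
  rank <- match(ped$animal_id, topological_order(ped))
  memo <- new.env(parent = emptyenv())
  phi <- function(a, b) {
    if (is.na(a) || is.na(b)) return(0)
    key <- paste(min(a, b), max(a, b))
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (a == b) {
      0.5 * (1 + phi(sire[a], dam[a]))
    } else {
      x <- if (rank[a] > rank[b]) a else b
      y <- if (rank[a] > rank[b]) b else a
      0.5 * (phi(sire[x], y) + phi(dam[x], y))
    }
    memo[[key]] <- val
    val
  }
  function(a, b) phi(unname(idx[a]), unname(idx[b]))
}

# Literal sliding-window ROH caller: enumerate every window, then scan
# maximal flagged runs, split at gaps, apply the four filters.
roh_oracle <- function(calls, pos, p) {
  n <- length(calls)
  flags <- rep(FALSE, n)
  w <- p$window_snps
  if (n >= w) {
    nw <- n - w + 1L
    winhom <- logical(nw)
    for (j in seq_len(nw)) {
      win <- calls[j:(j + w - 1L)]
      winhom[j] <- sum(win == 1L, na.rm = TRUE) <= p$het &&
        sum(is.na(win)) <= p$missing
    }
    for (i in seq_len(n)) {
      js <- max(1L, i - w + 1L):min(i, nw)
      flags[i] <- mean(winhom[js]) >= p$hit_threshold
    }
  }
  segs <- list()
  i <- 1L
  while (i <= n) {
    if (!flags[i]) {
      i <- i + 1L
      next
    }
    j <- i
    while (j < n && flags[j + 1L]) j <- j + 1L
    ks <- i
    if (j > i) {
      for (k in i:(j - 1L)) {
        if (pos[k + 1L] - pos[k] > p$max_gap_kb * 1000) {
          segs <- c(segs, list(c(ks, k)))
          ks <- k + 1L
        }
      }
    }
    segs <- c(segs, list(c(ks, j)))
    i <- j + 1L
  }
  out <- list()
  for (s in segs) {
    len <- pos[s[2]] - pos[s[1]] + 1
    nsnp <- s[2] - s[1] + 1L
    if (len >= p$min_kb * 1000 && nsnp >= p$min_snps &&
      len / nsnp <= p$density_kb * 1000) {
      out[[length(out) + 1L]] <- tibble::tibble(
        start_bp = pos[s[1]], end_bp = pos[s[2]],
        n_snps = nsnp, length_bp = len
      )
    }
  }
  list(
    flags = flags,
    segments = if (length(out) > 0) {
      dplyr::bind_rows(out)
    } else {
      tibble::tibble(
        start_bp = integer(0), end_bp = integer(0),
        n_snps = integer(0), length_bp = numeric(0)
      )
    }
  )
}

# Random single-chromosome genotype vector with hets and missing sprinkled in.
random_roh_chromosome <- function(seed) {
  set.seed(seed)
  n <- sample(100:500, 1)
  span <- sample(c(8e6, 15e6, 25e6), 1)
  pos <- sort(sample.int(span, n))
  calls <- sample(c(0L, 2L), n, replace = TRUE)
  het_rate <- runif(1, 0, 0.08)
  mis_rate <- runif(1, 0, 0.05)
  calls[runif(n) < het_rate] <- 1L
  calls[runif(n) < mis_rate] <- NA_integer_
  list(calls = calls, pos = pos)
}

# Per-base carrier counting oracle for consensus regions (toy chromosomes).
consensus_oracle <- function(segments, n_individuals, fraction, max_bp) {
  kmin <- ceiling(fraction * n_individuals)
  out <- list()
  for (chr in sort(unique(segments$chromosome))) {
    seg <- segments[segments$chromosome == chr, , drop = FALSE]
    cov <- integer(max_bp)
    for (r in seq_len(nrow(seg))) {
      rng <- seg$start_bp[r]:seg$end_bp[r]
      cov[rng] <- cov[rng] + 1L
    }
    ok <- cov >= kmin
    rl <- rle(ok)
    e <- cumsum(rl$lengths)
    s <- e - rl$lengths + 1L
    for (k in which(rl$values)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        chromosome = chr, start_bp = s[k], end_bp = e[k],
        n_carriers = min(cov[s[k]:e[k]])
      )
    }
  }
  if (length(out) > 0) dplyr::bind_rows(out) else {
    tibble::tibble(
      chromosome = integer(0), start_bp = integer(0),
      end_bp = integer(0), n_carriers = integer(0)
    )
  }
}

# Staggered, per-individual-disjoint toy segments on one 1-Mb chromosome.
staggered_segments <- function(n_ind, seed, max_segs = 4) {
  set.seed(seed)
  dplyr::bind_rows(lapply(sprintf("h%02d", seq_len(n_ind)), function(id) {
    k <- sample(seq_len(max_segs), 1)
    starts <- sort(sample.int(9e5, k))
    ends <- pmin(starts + sample.int(3e5, k), 1e6)
    keep_s <- keep_e <- numeric(0)
    last_end <- 0
    for (q in seq_len(k)) { # greedy disjoint subset
      if (starts[q] > last_end) {
        keep_s <- c(keep_s, starts[q])
        keep_e <- c(keep_e, ends[q])
        last_end <- ends[q]
      }
    }
    tibble::tibble(
      sample_id = id, chromosome = 1L,
      start_bp = keep_s, end_bp = keep_e,
      n_snps = 10L, length_bp = keep_e - keep_s + 1
    )
  }))
}

# Direct log-multinomial enumeration of the conditional heterozygote-count
# distribution; returns the two-sided exact p (and the raw distribution).
hwe_oracle <- function(n_hom1, n_het, n_hom2, return_dist = FALSE) {
  n <- n_hom1 + n_het + n_hom2
  n_rare <- 2 * min(n_hom1, n_hom2) + n_het
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  logp <- vapply(hets, function(h) {
    naa <- (n_rare - h) / 2
    nbb <- n - naa - h
    lfactorial(n) - lfactorial(naa) - lfactorial(h) - lfactorial(nbb) +
      h * log(2) +
      lfactorial(n_rare) + lfactorial(2 * n - n_rare) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp)
  if (return_dist) {
    return(stats::setNames(p, hets))
  }
  obs <- p[match(n_het, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

# Build a genotype_matrix from a plain call matrix.
make_geno <- function(calls, chromosome = 1L, positions = NULL,
                      samples = NULL) {
  m <- ncol(calls)
  if (is.null(positions)) positions <- seq_len(m) * 10000L
  if (is.null(samples)) samples <- sprintf("id%02d", seq_len(nrow(calls)))
  genotype_matrix(
    samples,
    tibble::tibble(
      chromosome = rep_len(chromosome, m),
      name = sprintf("s%04d", seq_len(m)),
      cm = 0, position_bp = positions,
      a1 = "A", a2 = "B"
    ),
    calls
  )
}

# The grid point reported to agree best with pedigree inbreeding.
best_setting <- function() roh_params(
  window_snps = 50, het = 1, missing = 5,
  min_kb = 500, min_snps = 100, density_kb = 50, max_gap_kb = 100
)
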