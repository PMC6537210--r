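#' ROH threshold setting
#'
#' One point of the threshold grid used to call runs of homozygosity with the
#' sliding-window approach. The window rule declares a window of `window_snps`
#' consecutive SNPs homozygous when it contains at most `het` heterozygous and
#' at most `missing` missing calls; a SNP is flagged homozygous when at least
#' a fraction `hit_threshold` of the windows covering it are homozygous.
#' Flagged runs are then split at inter-SNP gaps above `max_gap_kb` and kept
#' as ROH only when they span at least `min_kb`, contain at least `min_snps`
#' SNPs and average at most `density_kb` kb per SNP.
#'
#' @param window_snps Sliding-window size in SNPs.
#' @param het Heterozygous calls allowed per window.
#' @param missing Missing calls allowed per window.
#' @param min_kb Minimum run length in kb.
#' @param min_snps Minimum number of SNPs in a run.
#' @param density_kb Maximum mean spacing, kb per SNP (50 = "1 SNP per 50 kb").
#' @param max_gap_kb Maximum gap between consecutive SNPs of a run, kb.
#' @param hit_threshold Fraction of covering windows that must be homozygous
#'   for a SNP to be flagged.
#' @param pruned Whether the setting is meant to run on LD-pruned input
#'   (label bookkeeping only; pruning itself is [ld_prune()]).
#' @param label Free-text label; default follows the
#'   `"<window>snp_<min_kb>kb_<min_snps>snp_<het>_<missing>"` naming scheme.
#' @return A `roh_params` list.
#' @export
#' @examples
#' roh_params() # the grid point with the best F_PED agreement: 50/500kb/100/1/5
roh_params <- function(window_snps = 50L, het = 1L, missing = 5L,
                       min_kb = 500, min_snps = 100L, density_kb = 50,
                       max_gap_kb = 100, hit_threshold = 0.05,
                       pruned = FALSE, label = NULL) {
  stopifnot(
    window_snps >= 1, het >= 0, missing >= 0, min_snps >= 0,
    min_kb > 0, max_gap_kb > 0, density_kb > 0,
    hit_threshold > 0, hit_threshold <= 1
  )
  if (is.null(label)) {
    label <- paste0(
      if (pruned) "pruned_" else "",
      window_snps, "snp_", format(min_kb, scientific = FALSE), "kb_",
      min_snps, "snp_", het, "_", missing
    )
  }
  structure(
    list(
      window_snps = as.integer(window_snps), het = as.integer(het),
      missing = as.integer(missing), min_kb = min_kb,
      min_snps = as.integer(min_snps), density_kb = density_kb,
      max_gap_kb = max_gap_kb, hit_threshold = hit_threshold,
      pruned = isTRUE(pruned), label = label
    ),
    class = "roh_params"
  )
}

#' Read a grid of ROH threshold settings from YAML
#'
#' The file holds a top-level `settings:` list; each entry maps the
#' [roh_params()] argument names (`window_snps, het, missing, min_kb,
#' min_snps, density_kb, max_gap_kb, hit_threshold, pruned, label`), with
#' omitted keys falling back to the defaults.
#'
#' @param path YAML file path.
#' @return Named list of `roh_params`, named by label.
#' @export
read_roh_grid <- function(path) {
  cfg <- yaml::read_yaml(path)
  entries <- cfg$settings
  if (is.null(entries)) stop("grid file has no `settings` list", call. = FALSE)
  grid <- lapply(entries, function(e) do.call(roh_params, e))
  stats::setNames(grid, vapply(grid, `[[`, character(1), "label"))
}

#' Flag SNPs by the sliding-window homozygosity rule
#'
#' @param calls Integer vector of one individual's calls on one chromosome
#'   (0/1/2, `NA` = missing), aligned to position-sorted SNPs.
#' @param p A [roh_params()].
#' @return Logical vector: `TRUE` where the proportion of covering windows
#'   that are homozygous reaches `hit_threshold`. Only windows that physically
#'   fit on the chromosome are counted; a chromosome shorter than the window
#'   has no windows and no flagged SNPs.
#' @export
flag_snps <- function(calls, p) {
  n <- length(calls)
  w <- p$window_snps
  if (n == 0L) {
    return(logical(0))
  }
  if (n < w) {
    return(rep(FALSE, n))
  }
  het <- !is.na(calls) & calls == 1L
  mis <- is.na(calls)
  ch <- cumsum(het)
  cm <- cumsum(mis)
  nw <- n - w + 1L
  j <- seq_len(nw)
  win_het <- ch[j + w - 1L] - c(0L, ch)[j]
  win_mis <- cm[j + w - 1L] - c(0L, cm)[j]
  win_hom <- win_het <= p$het & win_mis <= p$missing
  cw <- c(0L, cumsum(win_hom))
  i <- seq_len(n)
  lo <- pmax(1L, i - w + 1L)
  hi <- pmin(i, nw)
  n_tot <- hi - lo + 1L
  n_hom <- cw[hi + 1L] - cw[lo]
  n_hom / n_tot >= p$hit_threshold
}

#' Call ROH segments from flagged SNPs on one chromosome
#'
#' Candidate segments are maximal runs of flagged SNPs, split wherever two
#' adjacent flagged SNPs lie more than `max_gap_kb` apart; a candidate is kept
#' iff it satisfies the length, SNP-count and density filters. Segment
#' endpoints are the positions of the first and last flagged SNP, 1-based
#' inclusive, so `length_bp = end_bp - start_bp + 1`.
#'
#' @param flags Logical vector from [flag_snps()].
#' @param positions Integer vector of SNP positions (bp, sorted ascending).
#' @param p A [roh_params()].
#' @return Tibble with `start_bp`, `end_bp`, `n_snps`, `length_bp`.
#' @export
call_segments <- function(flags, positions, p) {
  stopifnot(length(flags) == length(positions))
  empty <- tibble::tibble(
    start_bp = integer(0), end_bp = integer(0),
    n_snps = integer(0), length_bp = numeric(0)
  )
  if (!any(flags)) {
    return(empty)
  }
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in which(r$values)) {
    i0 <- starts[k]
    i1 <- ends[k]
    pos <- positions[i0:i1]
    ## split the run at oversized gaps
    brk <- which(diff(pos) > p$max_gap_kb * 1000)
    piece_start <- c(1L, brk + 1L)
    piece_end <- c(brk, length(pos))
    for (q in seq_along(piece_start)) {
      a <- piece_start[q]
      b <- piece_end[q]
      len <- pos[b] - pos[a] + 1
      nsnp <- b - a + 1L
      if (len >= p$min_kb * 1000 &&
        nsnp >= p$min_snps &&
        len / nsnp <= p$density_kb * 1000) {
        out[[length(out) + 1L]] <- tibble::tibble(
          start_bp = pos[a], end_bp = pos[b],
          n_snps = nsnp, length_bp = len
        )
      }
    }
  }
  if (length(out) == 0) empty else dplyr::bind_rows(out)
}

#' Detect runs of homozygosity for all individuals
#'
#' Applies [flag_snps()] and [call_segments()] per individual and chromosome
#' and concatenates the results, ordered by (sample, chromosome, start).
#'
#' @param g A [genotype_matrix()] (position-sorted within chromosomes).
#' @param p A [roh_params()].
#' @return Tibble with `sample_id`, `chromosome`, `start_bp`, `end_bp`,
#'   `n_snps`, `length_bp`.
#' @export
detect_roh <- function(g, p = roh_params()) {
  chrs <- unique(g$map$chromosome)
  res <- list()
  for (chr in chrs) {
    jj <- which(g$map$chromosome == chr)
    jj <- jj[order(g$map$position_bp[jj])]
    pos <- g$map$position_bp[jj]
    for (i in seq_along(g$samples)) {
      calls <- g$calls[i, jj]
      segs <- call_segments(flag_snps(calls, p), pos, p)
      if (nrow(segs) > 0) {
        segs$sample_id <- g$samples[i]
        segs$chromosome <- chr
        res[[length(res) + 1L]] <- segs
      }
    }
  }
  if (length(res) == 0) {
    return(tibble::tibble(
      sample_id = character(0), chromosome = integer(0),
      start_bp = integer(0), end_bp = integer(0),
      n_snps = integer(0), length_bp = numeric(0)
    ))
  }
  dplyr::bind_rows(res) |>
    dplyr::select(
      "sample_id", "chromosome", "start_bp", "end_bp",
      "n_snps", "length_bp"
    ) |>
    dplyr::arrange(.data$sample_id, .data$chromosome, .data$start_bp)
}

#' SNP-covered genome extent
#'
#' Operationalises "genome length covered with SNPs" as the sum over
#' chromosomes of (last SNP position - first SNP position + 1). Chromosomes
#' with fewer than two SNPs are excluded with a warning.
#'
#' @param map SNP map tibble with `chromosome` and `position_bp`.
#' @return A `genome_extent` list: `total_bp` and `per_chromosome` tibble
#'   (`chromosome`, `span_bp`).
#' @export
genome_extent_from_map <- function(map) {
  per <- tibble::as_tibble(map) |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::summarise(
      span_bp = max(.data$position_bp) - min(.data$position_bp) + 1,
      n_snps = dplyr::n(), .groups = "drop"
    )
  thin <- per$chromosome[per$n_snps < 2]
  if (length(thin) > 0) {
    warning(
      "chromosome(s) with fewer than 2 SNPs excluded from extent: ",
      paste(thin, collapse = ", "),
      call. = FALSE
    )
    per <- per[per$n_snps >= 2, , drop = FALSE]
  }
  structure(
    list(
      total_bp = sum(per$span_bp),
      per_chromosome = dplyr::select(per, "chromosome", "span_bp")
    ),
    class = "genome_extent"
  )
}

#' Genome extent from known chromosome lengths
#'
#' @param chromosomes Tibble/data frame with `chromosome` and `length_bp`, or
#'   a single total in bp.
#' @return A `genome_extent` (see [genome_extent_from_map()]).
#' @export
genome_extent <- function(chromosomes) {
  if (is.numeric(chromosomes) && length(chromosomes) == 1) {
    return(structure(
      list(total_bp = chromosomes, per_chromosome = NULL),
      class = "genome_extent"
    ))
  }
  per <- tibble::tibble(
    chromosome = chromosomes$chromosome,
    span_bp = chromosomes$length_bp
  )
  structure(
    list(total_bp = sum(per$span_bp), per_chromosome = per),
    class = "genome_extent"
  )
}

#' Genomic inbreeding coefficient F_ROH
#'
#' F_ROH of an individual is the summed length of its ROH divided by the
#' SNP-covered genome length.
#'
#' @param segments Segment tibble from [detect_roh()] (any subset of
#'   individuals). Segments of one individual must not overlap within a
#'   chromosome.
#' @param extent A `genome_extent`.
#' @param samples Optional character vector of sample ids that were screened;
#'   individuals without segments then appear with F_ROH = 0.
#' @return Tibble with `sample_id` and `f_roh` in \[0, 1\].
#' @export
compute_f_roh <- function(segments, extent, samples = NULL) {
  check_no_overlap(segments)
  out <- segments |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(f_roh = sum(.data$length_bp) / extent$total_bp, .groups = "drop")
  if (!is.null(samples)) {
    out <- tibble::tibble(sample_id = as.character(samples)) |>
      dplyr::left_join(out, by = "sample_id") |>
      dplyr::mutate(f_roh = dplyr::coalesce(.data$f_roh, 0))
  }
  if (any(out$f_roh > 1 + 1e-9)) {
    stop("summed ROH length exceeds genome extent; segments inconsistent", call. = FALSE)
  }
  out
}

check_no_overlap <- function(segments) {
  if (nrow(segments) < 2) {
    return(invisible(TRUE))
  }
  bad <- segments |>
    dplyr::group_by(.data$sample_id, .data$chromosome) |>
    dplyr::arrange(.data$start_bp, .by_group = TRUE) |>
    dplyr::summarise(
      ovl = dplyr::n() > 1 &&
        any(.data$start_bp[-1] <= .data$end_bp[-dplyr::n()]),
      .groups = "drop"
    )
  if (any(bad$ovl)) {
    stop("overlapping ROH segments within an individual", call. = FALSE)
  }
  invisible(TRUE)
}

#' Mean per-chromosome ROH coverage
#'
#' For each chromosome, the mean over individuals of the percentage of the
#' chromosome's SNP-covered span that lies in ROH.
#'
#' @param segments Segment tibble from [detect_roh()].
#' @param extent A `genome_extent` with per-chromosome spans.
#' @param samples Character vector of all screened sample ids (individuals
#'   without ROH on a chromosome contribute 0 to its mean).
#' @return Tibble with `chromosome` and `mean_pct`.
#' @export
chromosome_coverage <- function(segments, extent, samples) {
  if (is.null(extent$per_chromosome)) {
    stop("extent lacks per-chromosome spans", call. = FALSE)
  }
  n <- length(samples)
  per <- segments |>
    dplyr::filter(.data$sample_id %in% samples) |>
    dplyr::group_by(.data$chromosome, .data$sample_id) |>
    dplyr::summarise(bp = sum(.data$length_bp), .groups = "drop") |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::summarise(total_bp = sum(.data$bp), .groups = "drop")
  extent$per_chromosome |>
    dplyr::left_join(per, by = "chromosome") |>
    dplyr::mutate(
      mean_pct = 100 * dplyr::coalesce(.data$total_bp, 0) / (.data$span_bp * n)
    ) |>
    dplyr::select("chromosome", "mean_pct")
}

#' Write a .hom-style segment report
#'
#' Tab-separated with header `IID CHR SNP1 SNP2 POS1 POS2 KB NSNP DENSITY`;
#' KB and DENSITY (kb per SNP) carry three decimals. SNP names are looked up
#' from `map` when given, otherwise left blank.
#'
#' @param segments Segment tibble from [detect_roh()].
#' @param path Output file.
#' @param map Optional SNP map for SNP1/SNP2 name lookup.
#' @return Invisibly, `path`.
#' @export
write_hom_report <- function(segments, path, map = NULL) {
  name_at <- function(chr, pos) {
    if (is.null(map)) {
      return(rep(".", length(pos)))
    }
    key <- paste(map$chromosome, map$position_bp)
    map$name[match(paste(chr, pos), key)]
  }
  out <- data.frame(
    IID = segments$sample_id,
    CHR = segments$chromosome,
    SNP1 = name_at(segments$chromosome, segments$start_bp),
    SNP2 = name_at(segments$chromosome, segments$end_bp),
    POS1 = segments$start_bp,
    POS2 = segments$end_bp,
    KB = sprintf("%.3f", segments$length_bp / 1000),
    NSNP = segments$n_snps,
    DENSITY = sprintf("%.3f", segments$length_bp / 1000 / segments$n_snps)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' F_ROH across a grid of threshold settings
#'
#' Runs [detect_roh()] under each setting and assembles the individuals x
#' settings F_ROH table used for estimator comparison.
#'
#' @param g A [genotype_matrix()].
#' @param grid Named list of [roh_params()] (see [read_roh_grid()]).
#' @param extent A `genome_extent`; default derives it from `g`'s map.
#' @return Tibble: `sample_id` plus one F_ROH column per setting label.
#' @export
compute_froh_grid <- function(g, grid, extent = NULL) {
  if (is.null(extent)) extent <- genome_extent_from_map(g$map)
  cols <- lapply(grid, function(p) {
    gg <- g
    if (isTRUE(p$pruned)) {
      gg <- subset_genotypes(g, snps = ld_prune(g))
    }
    compute_f_roh(detect_roh(gg, p), extent, samples = g$samples)$f_roh
  })
  tibble::as_tibble(c(list(sample_id = g$samples), cols))
}
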