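#' Minimum carrier count for a sharing fraction
#'
#' "Shared by at least a fraction f of N individuals" means a carrier count of
#' at least `ceiling(f * N)`; for the 566-horse cohort at 95% that is 538.
#'
#' @param n_individuals Cohort size (>= 1).
#' @param fraction Sharing fraction in (0, 1\].
#' @return Integer carrier threshold.
#' @export
min_carrier_count <- function(n_individuals, fraction) {
  stopifnot(n_individuals >= 1)
  if (fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]", call. = FALSE)
  }
  as.integer(ceiling(fraction * n_individuals))
}

#' Population-consensus ROH regions
#'
#' Sweep-line over per-chromosome segment endpoints: carrier count changes
#' only at segment starts (+1) and one base past segment ends (-1), so between
#' consecutive breakpoints the count is constant. Maximal runs of bases with
#' carrier count >= `ceiling(fraction * n_individuals)` are reported; adjacent
#' qualifying base intervals are merged, and each region is annotated with the
#' minimum carrier count it attains. Single-base regions are legitimate
#' output; no minimum-length filter is applied.
#'
#' @param segments ROH tibble from [detect_roh()] (all individuals, one
#'   threshold setting); per-individual segments must not overlap.
#' @param n_individuals Number of screened individuals (the sharing
#'   denominator; may exceed the number of individuals with segments).
#' @param fraction Sharing fraction in (0, 1\], default 0.95.
#' @return Tibble with `chromosome`, `start_bp`, `end_bp` (1-based inclusive),
#'   `length_bp`, `n_carriers` (minimum over the region) and `frac_carriers`,
#'   sorted by (chromosome, start).
#' @export
consensus_regions <- function(segments, n_individuals, fraction = 0.95) {
  kmin <- min_carrier_count(n_individuals, fraction)
  check_no_overlap(segments)
  empty <- tibble::tibble(
    chromosome = integer(0), start_bp = numeric(0), end_bp = numeric(0),
    length_bp = numeric(0), n_carriers = integer(0), frac_carriers = numeric(0)
  )
  if (nrow(segments) == 0) {
    return(empty)
  }
  out <- list()
  for (chr in sort(unique(segments$chromosome))) {
    seg <- segments[segments$chromosome == chr, , drop = FALSE]
    bp <- c(seg$start_bp, seg$end_bp + 1)
    delta <- c(rep(1L, nrow(seg)), rep(-1L, nrow(seg)))
    o <- order(bp)
    bp <- bp[o]
    delta <- delta[o]
    ## collapse ties, then cumulative coverage on [bp[k], bp[k+1] - 1]
    ub <- unique(bp)
    dsum <- vapply(split(delta, match(bp, ub)), sum, integer(1))
    cov <- cumsum(dsum)
    piece_start <- ub[-length(ub)]
    piece_end <- ub[-1] - 1
    piece_cov <- cov[-length(cov)]
    ok <- piece_cov >= kmin
    if (!any(ok)) next
    ## merge adjacent qualifying pieces (they are contiguous by construction)
    r <- rle(ok)
    e <- cumsum(r$lengths)
    s <- e - r$lengths + 1L
    for (k in which(r$values)) {
      idx <- s[k]:e[k]
      out[[length(out) + 1L]] <- tibble::tibble(
        chromosome = chr,
        start_bp = piece_start[idx[1]],
        end_bp = piece_end[idx[length(idx)]],
        n_carriers = as.integer(min(piece_cov[idx]))
      )
    }
  }
  if (length(out) == 0) {
    return(empty)
  }
  dplyr::bind_rows(out) |>
    dplyr::mutate(
      length_bp = .data$end_bp - .data$start_bp + 1,
      frac_carriers = .data$n_carriers / n_individuals
    ) |>
    dplyr::select(
      "chromosome", "start_bp", "end_bp", "length_bp",
      "n_carriers", "frac_carriers"
    ) |>
    dplyr::arrange(.data$chromosome, .data$start_bp)
}

#' Write consensus regions as BED (plus a 1-based CSV twin)
#'
#' Internally coordinates are 1-based inclusive; BED output converts to
#' 0-based half-open (`start - 1`, `end`). Score is the carrier count.
#'
#' @param regions Tibble from [consensus_regions()].
#' @param path Output BED path; a `.csv` twin with 1-based coordinates is
#'   written next to it.
#' @return Invisibly, the BED path.
#' @export
write_consensus_bed <- function(regions, path) {
  bed <- data.frame(
    chrom = regions$chromosome,
    start = format(regions$start_bp - 1, scientific = FALSE, trim = TRUE),
    end = format(regions$end_bp, scientific = FALSE, trim = TRUE),
    name = paste0("region_", seq_len(nrow(regions))),
    score = regions$n_carriers
  )
  utils::write.table(bed, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  readr::write_csv(regions, sub("\\.bed$", ".csv", path))
  invisible(path)
}

#' Read a QTL interval table
#'
#' Tab-separated with header
#' `qtl_id symbol trait_name chr start_bp end_bp trait_class`. The package
#' ships a transcription of the 35 previously reported health/reproduction QTL
#' intervals for the horse as `qtl_table4.tsv` (the default).
#'
#' @param path TSV path; default the packaged table.
#' @return Tibble of validated QTL records.
#' @export
read_qtl_table <- function(path = system.file("extdata", "qtl_table4.tsv",
                             package = "autozyg"
                           )) {
  qtl <- readr::read_tsv(path,
    col_types = readr::cols(
      qtl_id = "i", symbol = "c", trait_name = "c",
      chr = "i", start_bp = "d", end_bp = "d", trait_class = "c"
    ), progress = FALSE
  )
  bad <- which(is.na(qtl$start_bp) | is.na(qtl$end_bp) | qtl$start_bp > qtl$end_bp)
  if (length(bad) > 0) {
    stop("malformed coordinates for QTL ", qtl$qtl_id[bad[1]], call. = FALSE)
  }
  if (!all(qtl$chr %in% AUTOSOMES)) {
    stop("QTL table contains non-autosomal chromosomes", call. = FALSE)
  }
  qtl
}

#' Overlap consensus regions with QTL intervals
#'
#' Any-overlap semantics on 1-based inclusive coordinates: a pair is emitted
#' iff both intervals share a chromosome and at least one base,
#' i.e. `max(starts) <= min(ends)`. Adjacency (region ending at x, QTL
#' starting at x + 1) is not overlap.
#'
#' @param regions Tibble from [consensus_regions()].
#' @param qtls Tibble from [read_qtl_table()].
#' @return Tibble with one row per overlapping (region, QTL) pair:
#'   `region_id`, `chromosome`, `region_start`, `region_end`, `qtl_id`,
#'   `symbol`, `trait_name`, `trait_class`, `overlap_bp`.
#' @export
overlap_regions_qtl <- function(regions, qtls) {
  regions <- dplyr::mutate(regions, region_id = paste0("region_", dplyr::row_number()))
  out <- dplyr::inner_join(
    dplyr::select(regions, "region_id",
      chromosome = "chromosome",
      region_start = "start_bp", region_end = "end_bp"
    ),
    dplyr::rename(qtls, chromosome = "chr"),
    by = "chromosome",
    relationship = "many-to-many"
  ) |>
    dplyr::filter(
      pmax(.data$region_start, .data$start_bp) <=
        pmin(.data$region_end, .data$end_bp)
    ) |>
    dplyr::mutate(
      overlap_bp = pmin(.data$region_end, .data$end_bp) -
        pmax(.data$region_start, .data$start_bp) + 1
    ) |>
    dplyr::select(
      "region_id", "chromosome", "region_start", "region_end",
      "qtl_id", "symbol", "trait_name", "trait_class", "overlap_bp"
    )
  out
}

#' Summarise QTL overlaps by trait
#'
#' @param pairs Tibble from [overlap_regions_qtl()].
#' @return An `overlap_summary` list: `n_qtl_overlapped` (distinct QTL),
#'   `by_symbol` and `by_class` tibbles with counts and percentages of the
#'   distinct overlapped QTL (one decimal).
#' @export
summarize_overlaps <- function(pairs) {
  distinct_qtl <- dplyr::distinct(
    pairs, .data$qtl_id, .data$symbol,
    .data$trait_name, .data$trait_class
  )
  n <- nrow(distinct_qtl)
  by_symbol <- distinct_qtl |>
    dplyr::count(.data$symbol, name = "n_qtl") |>
    dplyr::mutate(pct = if (n > 0) round(100 * .data$n_qtl / n, 1) else NA_real_) |>
    dplyr::arrange(dplyr::desc(.data$n_qtl))
  by_class <- distinct_qtl |>
    dplyr::count(.data$trait_class, name = "n_qtl") |>
    dplyr::mutate(pct = if (n > 0) round(100 * .data$n_qtl / n, 1) else NA_real_) |>
    dplyr::arrange(dplyr::desc(.data$n_qtl))
  structure(
    list(n_qtl_overlapped = n, by_symbol = by_symbol, by_class = by_class),
    class = "overlap_summary"
  )
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat("<overlap_summary> ", x$n_qtl_overlapped, " distinct QTL overlapped\n", sep = "")
  if (x$n_qtl_overlapped > 0) {
    print(x$by_symbol)
    print(x$by_class)
  }
  invisible(x)
}

#' Percentage of overlapped QTL associated with a set of symbols
#'
#' Convenience for trait groups spanning several symbols (e.g. the
#' osteochondrosis symbols `OSTEO` and `OSTD`).
#'
#' @param summary An `overlap_summary` from [summarize_overlaps()].
#' @param symbols Character vector of trait symbols to pool.
#' @return Percentage of distinct overlapped QTL (one decimal).
#' @export
symbol_group_pct <- function(summary, symbols) {
  n <- sum(summary$by_symbol$n_qtl[summary$by_symbol$symbol %in% symbols])
  round(100 * n / summary$n_qtl_overlapped, 1)
}
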