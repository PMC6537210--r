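#' Genotype matrix container
#'
#' Bundles sample ids, a SNP map and an integer call matrix. Calls are coded
#' as copies of the alternate allele: 0 = homozygous reference, 1 =
#' heterozygous, 2 = homozygous alternate, `NA` = missing. The reference
#' allele of a SNP is the alphabetically first allele observed for it, a
#' cosmetic convention: minor-allele frequency and the Hardy-Weinberg test are
#' orientation-invariant.
#'
#' @param samples Character vector of sample ids (unique).
#' @param map Tibble with columns `chromosome` (integer), `name`, `position_bp`
#'   (1-based), `a1`, `a2` (allele codes; `a1` = reference).
#' @param calls Integer matrix, `length(samples)` rows x `nrow(map)` columns.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(samples, map, calls) {
  samples <- as.character(samples)
  map <- tibble::as_tibble(map)
  stopifnot(
    all(c("chromosome", "name", "position_bp", "a1", "a2") %in% names(map)),
    is.matrix(calls),
    nrow(calls) == length(samples),
    ncol(calls) == nrow(map),
    !anyDuplicated(samples)
  )
  storage.mode(calls) <- "integer"
  rownames(calls) <- samples
  colnames(calls) <- map$name
  structure(
    list(samples = samples, map = map, calls = calls),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(
    "<genotype_matrix> ", length(x$samples), " individuals x ",
    nrow(x$map), " SNPs on ", length(unique(x$map$chromosome)),
    " chromosome(s)\n",
    sep = ""
  )
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Read genotypes from PED/MAP text files
#'
#' Parses the classic whitespace-delimited PED/MAP layout: MAP rows are
#' `chromosome snp_name cm position`; PED rows are the six leading columns
#' `fid iid pat mat sex pheno` followed by two allele columns per SNP, with
#' `0 0` coding a missing call. Each SNP's allele pair is discovered from the
#' data; a SNP showing more than two alleles is an error.
#'
#' @param ped_path,map_path Paths to the PED and MAP files.
#' @return A [genotype_matrix()].
#' @export
read_ped_map <- function(ped_path, map_path) {
  map_raw <- utils::read.table(map_path,
    header = FALSE, colClasses = c("integer", "character", "numeric", "integer")
  )
  names(map_raw) <- c("chromosome", "name", "cm", "position_bp")
  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  fields <- strsplit(trimws(ped_lines), "[ \t]+")
  m <- nrow(map_raw)
  want <- 6L + 2L * m
  lens <- lengths(fields)
  if (any(lens != want)) {
    stop(
      "PED/MAP column mismatch: expected ", want, " fields per PED row for ",
      m, " SNPs, found ", lens[which(lens != want)[1]],
      call. = FALSE
    )
  }
  n <- length(fields)
  flat <- unlist(fields, use.names = FALSE)
  block <- matrix(flat, nrow = n, byrow = TRUE)
  iid <- block[, 2]
  a_odd <- block[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  a_even <- block[, 6L + 2L * seq_len(m), drop = FALSE]

  calls <- matrix(NA_integer_, nrow = n, ncol = m)
  a1 <- character(m)
  a2 <- character(m)
  for (j in seq_len(m)) {
    x <- a_odd[, j]
    y <- a_even[, j]
    miss <- x == "0" | y == "0"
    alleles <- sort(unique(c(x[!miss], y[!miss])))
    if (length(alleles) > 2) {
      stop("more than two alleles observed at SNP ", map_raw$name[j], call. = FALSE)
    }
    a1[j] <- if (length(alleles) >= 1) alleles[1] else NA_character_
    a2[j] <- if (length(alleles) == 2) alleles[2] else a1[j]
    g <- if (length(alleles) == 2) {
      (x == a2[j]) + (y == a2[j])
    } else {
      rep(0L, n) # monomorphic: every non-missing call is hom-ref
    }
    g[miss] <- NA_integer_
    calls[, j] <- as.integer(g)
  }
  map <- tibble::as_tibble(map_raw)
  map$a1 <- a1
  map$a2 <- a2
  genotype_matrix(iid, map, calls)
}

#' Write genotypes to PED/MAP text files
#'
#' @param g A [genotype_matrix()].
#' @param prefix Output path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return Invisibly, the two file paths.
#' @export
write_ped_map <- function(g, prefix) {
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  utils::write.table(
    data.frame(
      g$map$chromosome, g$map$name,
      0, g$map$position_bp
    ),
    map_path,
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t"
  )
  m <- nrow(g$map)
  n <- length(g$samples)
  out <- matrix("0", nrow = n, ncol = 6L + 2L * m)
  out[, 1] <- g$samples
  out[, 2] <- g$samples
  out[, 5] <- "1"
  out[, 6] <- "-9"
  for (j in seq_len(m)) {
    gj <- g$calls[, j]
    x <- rep("0", n)
    y <- rep("0", n)
    x[!is.na(gj) & gj == 0L] <- g$map$a1[j]
    y[!is.na(gj) & gj == 0L] <- g$map$a1[j]
    x[!is.na(gj) & gj == 1L] <- g$map$a1[j]
    y[!is.na(gj) & gj == 1L] <- g$map$a2[j]
    x[!is.na(gj) & gj == 2L] <- g$map$a2[j]
    y[!is.na(gj) & gj == 2L] <- g$map$a2[j]
    out[, 6L + 2L * j - 1L] <- x
    out[, 6L + 2L * j] <- y
  }
  writeLines(apply(out, 1, paste, collapse = " "), ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Subset a genotype matrix
#'
#' @param g A [genotype_matrix()].
#' @param samples,snps Character vectors of sample ids / SNP names to keep
#'   (default: all). Order of the original object is preserved.
#' @return A [genotype_matrix()].
#' @export
subset_genotypes <- function(g, samples = NULL, snps = NULL) {
  keep_i <- if (is.null(samples)) seq_along(g$samples) else which(g$samples %in% samples)
  keep_j <- if (is.null(snps)) seq_len(nrow(g$map)) else which(g$map$name %in% snps)
  genotype_matrix(
    g$samples[keep_i],
    g$map[keep_j, , drop = FALSE],
    g$calls[keep_i, keep_j, drop = FALSE]
  )
}
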