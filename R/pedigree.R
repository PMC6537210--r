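#' Read a pedigree file
#'
#' Reads a delimited pedigree table with one row per animal and columns naming
#' the animal, its sire and its dam, plus optional `birth_year` and `country`
#' columns. Unknown parents are coded by an empty field, `NA`, or the sentinel
#' `"0"`. Parents that are named on some row but never defined as a row of
#' their own are appended as founder records with unknown parents.
#'
#' @param path Path to a delimited text file (comma, tab or whitespace
#'   separated) with a header row. Column names are matched case-insensitively
#'   against `animal_id`/`animal`/`id`, `sire_id`/`sire`, `dam_id`/`dam`, and
#'   optionally `birth_year`/`year` and `country`.
#' @return A `pedigree` tibble with columns `animal_id`, `sire_id`, `dam_id`
#'   (character, `NA` = unknown), `birth_year` (integer, `NA` allowed) and
#'   `country` (character, `NA` allowed).
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("animal_id,sire_id,dam_id,birth_year,country",
#'              "A,0,0,2000,NO", "B,0,0,2000,SE", "C,A,B,2005,NO"), tf)
#' read_pedigree(tf)
read_pedigree <- function(path) {
  raw <- readr::read_delim(path,
    delim = guess_delim(path), col_types = readr::cols(.default = "c"),
    trim_ws = TRUE, progress = FALSE, show_col_types = FALSE
  )
  nm <- tolower(names(raw))
  pick <- function(cands) {
    hit <- which(nm %in% cands)
    if (length(hit) == 0) NULL else raw[[hit[1]]]
  }
  animal <- pick(c("animal_id", "animal", "id", "iid"))
  sire <- pick(c("sire_id", "sire", "father"))
  dam <- pick(c("dam_id", "dam", "mother"))
  if (is.null(animal) || is.null(sire) || is.null(dam)) {
    stop("pedigree file must name animal, sire and dam columns", call. = FALSE)
  }
  year <- pick(c("birth_year", "year", "yob"))
  country <- pick(c("country", "origin"))
  ped <- tibble::tibble(
    animal_id = as.character(animal),
    sire_id = as.character(sire),
    dam_id = as.character(dam),
    birth_year = if (is.null(year)) NA_integer_ else suppressWarnings(as.integer(year)),
    country = if (is.null(country)) NA_character_ else as.character(country)
  )
  as_pedigree(ped)
}

guess_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl(",", first, fixed = TRUE)) "," else if (grepl("\t", first, fixed = TRUE)) "\t" else " "
}

#' Validate a data frame as a pedigree
#'
#' Normalises unknown-parent codes to `NA`, appends founder records for
#' parents that are named but never defined, and checks that animal ids are
#' unique and that the parent graph is acyclic.
#'
#' @param df Data frame with at least `animal_id`, `sire_id`, `dam_id`;
#'   optional `birth_year`, `country`.
#' @return A validated `pedigree` tibble (see [read_pedigree()]).
#' @export
as_pedigree <- function(df) {
  stopifnot(all(c("animal_id", "sire_id", "dam_id") %in% names(df)))
  ped <- tibble::tibble(
    animal_id = as.character(df$animal_id),
    sire_id = blank_to_na(df$sire_id),
    dam_id = blank_to_na(df$dam_id),
    birth_year = if ("birth_year" %in% names(df)) as.integer(df$birth_year) else NA_integer_,
    country = if ("country" %in% names(df)) as.character(df$country) else NA_character_
  )
  if (anyNA(ped$animal_id) || any(ped$animal_id == "")) {
    stop("missing animal_id in pedigree", call. = FALSE)
  }
  dup <- ped$animal_id[duplicated(ped$animal_id)]
  if (length(dup) > 0) {
    stop("duplicate animal_id in pedigree: ", dup[1], call. = FALSE)
  }
  named_parents <- unique(stats::na.omit(c(ped$sire_id, ped$dam_id)))
  missing_parents <- setdiff(named_parents, ped$animal_id)
  if (length(missing_parents) > 0) {
    ped <- dplyr::bind_rows(ped, tibble::tibble(
      animal_id = missing_parents,
      sire_id = NA_character_, dam_id = NA_character_,
      birth_year = NA_integer_, country = NA_character_
    ))
  }
  ## topological sort doubles as the cycle check
  invisible(topo_index(ped))
  class(ped) <- c("pedigree", class(tibble::tibble()))
  ped
}

blank_to_na <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == "" | x == "0"] <- NA_character_
  x
}

## Kahn-style topological sort on row indices; errors on a cycle, naming one
## individual that sits on it.
topo_index <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$animal_id
  s <- unname(idx[ped$sire_id])
  d <- unname(idx[ped$dam_id])
  indeg <- integer(n) # number of unprocessed parents
  indeg <- indeg + (!is.na(s)) + (!is.na(d))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.na(s[i])) children[[s[i]]] <- c(children[[s[i]]], i)
    if (!is.na(d[i])) children[[d[i]]] <- c(children[[d[i]]], i)
  }
  order <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue) > 0) {
    i <- queue[1]
    queue <- queue[-1]
    order <- c(order, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n) {
    bad <- ped$animal_id[which(indeg > 0L)[1]]
    stop("pedigree contains a cycle involving individual ", bad, call. = FALSE)
  }
  order
}

#' Topological order of a pedigree
#'
#' Returns the animal ids ordered so that every parent precedes all of its
#' offspring; this is the evaluation order for the inbreeding recursion.
#'
#' @param ped A `pedigree` (see [read_pedigree()]).
#' @return Character vector: a permutation of `ped$animal_id`.
#' @export
topological_order <- function(ped) {
  ped$animal_id[topo_index(ped)]
}

#' Pedigree inbreeding coefficients (F_PED)
#'
#' Computes Wright's inbreeding coefficient for every animal by an exact
#' tabular recursion over a topological order: for each non-founder, the
#' additive-relationship diagonal of a virtual progeny of its parents is
#' accumulated from within-family gene contributions and Cholesky diagonal
#' terms, giving F as the parents' kinship. Animals with at least one unknown
#' parent receive F = 0 (founder convention; unknown ancestry is not imputed).
#'
#' @param ped A `pedigree`.
#' @return Tibble with `animal_id`, `f_ped` in \[0, 1\] and
#'   `both_parents_known` (logical).
#' @export
#' @examples
#' ped <- as_pedigree(data.frame(
#'   animal_id = c("A", "B", "S", "D", "X"),
#'   sire_id   = c(NA, NA, "A", "A", "S"),
#'   dam_id    = c(NA, NA, "B", "B", "D")
#' ))
#' compute_f_ped(ped) # full-sib mating: F(X) = 0.25
compute_f_ped <- function(ped) {
  ord <- topo_index(ped)
  n <- nrow(ped)
  pos <- integer(n) # rank of each original row in topological order
  pos[ord] <- seq_len(n)
  idx <- seq_len(n)
  names(idx) <- ped$animal_id
  sire <- unname(idx[ped$sire_id])[ord] # parents as topological ranks
  dam <- unname(idx[ped$dam_id])[ord]
  sire <- ifelse(is.na(sire), 0L, pos[sire])
  dam <- ifelse(is.na(dam), 0L, pos[dam])

  f <- numeric(n)
  ## Cholesky diagonal D_j: founders 1; one known parent 0.75 - F_p/4;
  ## both parents 0.5 - (F_s + F_d)/4. Filled as F becomes available.
  dvec <- numeric(n)
  for (i in seq_len(n)) {
    s <- sire[i]
    d <- dam[i]
    if (s == 0L && d == 0L) {
      dvec[i] <- 1
      next
    }
    if (s == 0L || d == 0L) {
      p <- max(s, d)
      f[i] <- 0
      dvec[i] <- 0.75 - 0.25 * f[p]
      next
    }
    ## gene contribution of each ancestor to a virtual progeny of (s, d)
    L <- numeric(i - 1L)
    L[s] <- L[s] + 0.5
    L[d] <- L[d] + 0.5
    acc <- 0
    for (j in seq(i - 1L, 1L)) {
      lj <- L[j]
      if (lj == 0) next
      acc <- acc + lj * lj * dvec[j]
      sj <- sire[j]
      dj <- dam[j]
      if (sj > 0L) L[sj] <- L[sj] + 0.5 * lj
      if (dj > 0L) L[dj] <- L[dj] + 0.5 * lj
    }
    d_self <- 0.5 - 0.25 * (f[s] + f[d])
    f[i] <- acc + d_self - 1 # a_ii = 1 + F
    dvec[i] <- 0.5 - 0.25 * (f[s] + f[d])
  }
  out <- numeric(n)
  out[ord] <- f
  bpk <- !is.na(ped$sire_id) & !is.na(ped$dam_id)
  tibble::tibble(
    animal_id = ped$animal_id,
    f_ped = out,
    both_parents_known = bpk
  )
}

#' Wright's path-counting inbreeding coefficient (enumeration oracle)
#'
#' Computes F for one individual by literally enumerating ancestor paths:
#' F = sum over pairs of paths, one from the sire and one from the dam to a
#' common ancestor A sharing no other individual, of
#' (1/2)^(n_sire + n_dam + 1) * (1 + F_A). Exponential in pedigree depth;
#' intended as an independent cross-check on small pedigrees.
#'
#' @param ped A `pedigree` of at most `max_size` individuals.
#' @param id Animal id to evaluate.
#' @param max_size Enumeration guard (default 40 individuals).
#' @return F as a single double.
#' @export
wright_path_oracle <- function(ped, id, max_size = 40L) {
  if (nrow(ped) > max_size) {
    stop("pedigree too large for path enumeration (", nrow(ped), " > ", max_size, ")",
      call. = FALSE
    )
  }
  idx <- seq_len(nrow(ped))
  names(idx) <- ped$animal_id
  if (!id %in% ped$animal_id) stop("unknown animal id: ", id, call. = FALSE)
  sire <- unname(idx[ped$sire_id])
  dam <- unname(idx[ped$dam_id])
  memo <- new.env(parent = emptyenv())

  ## all simple upward paths from i, each a vector of row indices starting at i
  paths_up <- function(i) {
    out <- list(i)
    for (p in c(sire[i], dam[i])) {
      if (!is.na(p)) {
        out <- c(out, lapply(paths_up(p), function(pp) c(i, pp)))
      }
    }
    out
  }

  f_of <- function(i) {
    key <- as.character(i)
    if (!is.null(memo[[key]])) {
      return(memo[[key]])
    }
    s <- sire[i]
    d <- dam[i]
    val <- 0
    if (!is.na(s) && !is.na(d)) {
      ps <- paths_up(s)
      pd <- paths_up(d)
      for (p1 in ps) {
        for (p2 in pd) {
          a <- p1[length(p1)]
          if (p2[length(p2)] != a) next
          ## paths may share only the common ancestor itself
          if (length(intersect(p1[-length(p1)], p2)) > 0) next
          if (length(intersect(p2[-length(p2)], p1)) > 0) next
          n1 <- length(p1) - 1L
          n2 <- length(p2) - 1L
          val <- val + 0.5^(n1 + n2 + 1) * (1 + f_of(a))
        }
      }
    }
    memo[[key]] <- val
    val
  }
  f_of(unname(idx[id]))
}

#' Per-birth-year inbreeding summary
#'
#' @param tab Inbreeding table from [compute_f_ped()] (or any tibble with
#'   `animal_id` and a single F column named `f_ped` or `f_roh`).
#' @param ped A `pedigree` supplying `birth_year`.
#' @param statistic `"median"` (default) or `"mean"`.
#' @return Tibble with one row per year carrying `birth_year`, `f` (the chosen
#'   statistic, proportion scale) and `n`; animals with unknown birth year and
#'   years with zero animals are omitted.
#' @export
summarize_f_by_year <- function(tab, ped, statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  fcol <- intersect(c("f_ped", "f_roh", "f"), names(tab))[1]
  if (is.na(fcol)) stop("no inbreeding column (f_ped/f_roh/f) in `tab`", call. = FALSE)
  stat_fun <- if (statistic == "median") stats::median else mean
  tab |>
    dplyr::inner_join(
      dplyr::select(tibble::as_tibble(ped), "animal_id", "birth_year"),
      by = "animal_id"
    ) |>
    dplyr::filter(!is.na(.data$birth_year)) |>
    dplyr::group_by(.data$birth_year) |>
    dplyr::summarise(
      f = stat_fun(.data[[fcol]]),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$birth_year)
}

#' Change in inbreeding between two birth years
#'
#' Difference of the per-year summary statistic between two years, reported in
#' percentage points (the summary stores proportions; presentation multiplies
#' by 100).
#'
#' @param summary Per-year table from [summarize_f_by_year()].
#' @param year_from,year_to Years present in `summary`.
#' @return `100 * (f[year_to] - f[year_from])`, a single double.
#' @export
trend_delta <- function(summary, year_from, year_to) {
  lookup <- function(y) {
    hit <- summary$f[summary$birth_year == y]
    if (length(hit) != 1) stop("year ", y, " not present in summary", call. = FALSE)
    hit
  }
  100 * (lookup(year_to) - lookup(year_from))
}

#' Truncate a pedigree at a fixed ancestral depth
#'
#' Reassigns every ancestor more than `n_generations` above the given focal
#' animals as a founder (unknown parents), emulating a shallow recorded
#' pedigree. Used to study how pedigree depth biases F_PED downwards relative
#' to realized autozygosity.
#'
#' @param ped A `pedigree`.
#' @param focal_ids Animals whose ancestry depth is measured from (default:
#'   all animals that are nobody's parent).
#' @param n_generations Number of ancestral generations to retain.
#' @return A `pedigree` with the same rows, parents blanked beyond the depth.
#' @export
truncate_pedigree <- function(ped, n_generations, focal_ids = NULL) {
  stopifnot(n_generations >= 0)
  idx <- seq_len(nrow(ped))
  names(idx) <- ped$animal_id
  sire <- unname(idx[ped$sire_id])
  dam <- unname(idx[ped$dam_id])
  if (is.null(focal_ids)) {
    parents <- unique(stats::na.omit(c(ped$sire_id, ped$dam_id)))
    focal_ids <- setdiff(ped$animal_id, parents)
  }
  depth <- rep(Inf, nrow(ped))
  frontier <- unname(idx[focal_ids])
  depth[frontier] <- 0
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (i in frontier) {
      for (p in c(sire[i], dam[i])) {
        if (!is.na(p) && depth[p] > depth[i] + 1) {
          depth[p] <- depth[i] + 1
          nxt <- c(nxt, p)
        }
      }
    }
    frontier <- unique(nxt)
  }
  cut <- depth >= n_generations
  out <- tibble::as_tibble(ped)
  out$sire_id[cut] <- NA_character_
  out$dam_id[cut] <- NA_character_
  as_pedigree(out)
}
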