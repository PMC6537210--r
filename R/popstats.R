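#' Pearson correlation with significance
#'
#' @param x,y Numeric vectors of equal length (n >= 3), neither constant.
#' @return Tibble with `r` and the two-sided `p` from the t statistic
#'   `r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value)
}

#' Paired t-test
#'
#' Two-sided paired t on the differences `x - y`, n - 1 degrees of freedom.
#' Identical vectors (all differences zero) return t = 0, p = 1 by convention;
#' a constant non-zero difference has zero variance and returns a signed
#' infinite t with p = 0.
#'
#' @param x,y Numeric vectors of equal length (n >= 2).
#' @return Tibble with `t` and `p`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  stderr <- stats::sd(d) / sqrt(length(d))
  if (stderr == 0 || stderr < 10 * .Machine$double.eps * abs(mean(d))) {
    if (abs(mean(d)) <= stderr) {
      return(tibble::tibble(t = 0, p = 1))
    }
    return(tibble::tibble(t = sign(mean(d)) * Inf, p = 0))
  }
  tt <- stats::t.test(x, y, paired = TRUE, alternative = "two.sided")
  tibble::tibble(t = unname(tt$statistic), p = tt$p.value)
}

#' Compare F_ROH threshold settings against F_PED
#'
#' Computes the Pearson correlation of every setting's F_ROH with F_PED,
#' all pairwise paired t-tests among settings, and the count/fraction of
#' setting pairs showing no significant difference at `alpha` (two-sided, no
#' multiplicity correction; raw counts only).
#'
#' @param froh Tibble with `sample_id` and one numeric F_ROH column per
#'   setting (see [compute_froh_grid()]).
#' @param f_ped Tibble with `animal_id`/`sample_id` and `f_ped`, or a numeric
#'   vector aligned to `froh` rows.
#' @param alpha Significance threshold for the non-significant pair count.
#' @return A `grid_comparison` object; see [tidy.grid_comparison()] and
#'   [glance.grid_comparison()].
#' @export
grid_compare <- function(froh, f_ped, alpha = 0.05) {
  settings <- setdiff(names(froh), "sample_id")
  if (length(settings) < 1) stop("no setting columns in `froh`", call. = FALSE)
  if (is.data.frame(f_ped)) {
    idcol <- intersect(c("sample_id", "animal_id"), names(f_ped))[1]
    fp <- f_ped$f_ped[match(froh$sample_id, f_ped[[idcol]])]
  } else {
    fp <- as.numeric(f_ped)
  }
  if (anyNA(fp)) stop("f_ped missing for some individuals in the grid", call. = FALSE)
  vals <- as.matrix(froh[settings])

  cor_tab <- purrr::map_dfr(settings, function(s) {
    ct <- pearson_r(fp, vals[, s])
    tibble::tibble(setting = s, r = ct$r, p = ct$p)
  })
  k <- length(settings)
  t_p <- matrix(NA_real_, k, k, dimnames = list(settings, settings))
  diag(t_p) <- 1
  if (k > 1) {
    for (a in seq_len(k - 1)) {
      for (b in seq(a + 1, k)) {
        p <- paired_t(vals[, a], vals[, b])$p
        t_p[a, b] <- p
        t_p[b, a] <- p
      }
    }
  }
  n_pairs <- k * (k - 1) / 2
  nonsig <- if (n_pairs > 0) sum(t_p[upper.tri(t_p)] > alpha) else 0L
  best <- cor_tab$setting[which.max(cor_tab$r)]
  structure(
    list(
      correlations = cor_tab,
      paired_p = t_p,
      alpha = alpha,
      n_individuals = nrow(froh),
      best_setting = best,
      r_best = max(cor_tab$r),
      n_nonsignificant = nonsig,
      frac_nonsignificant = if (n_pairs > 0) nonsig / n_pairs else NA_real_
    ),
    class = "grid_comparison"
  )
}

#' @export
print.grid_comparison <- function(x, ...) {
  cat("<grid_comparison> ", nrow(x$correlations), " threshold settings, ",
    x$n_individuals, " individuals\n",
    sep = ""
  )
  cat(sprintf(
    "  best setting: %s (r = %.4f with F_PED)\n",
    x$best_setting, x$r_best
  ))
  cat(sprintf(
    "  paired-t pairs with no significant difference at alpha = %g: %d (%.2f%%)\n",
    x$alpha, x$n_nonsignificant, 100 * x$frac_nonsignificant
  ))
  invisible(x)
}

#' Tidy a grid comparison
#'
#' @param x A `grid_comparison` from [grid_compare()].
#' @param ... Unused.
#' @return One row per setting: `setting`, `r`, `p` (correlation with F_PED).
#' @export
tidy.grid_comparison <- function(x, ...) {
  x$correlations
}

#' One-row summary of a grid comparison
#'
#' @param x A `grid_comparison` from [grid_compare()].
#' @param ... Unused.
#' @return Tibble with `best_setting`, `r_best`, `n_nonsignificant`,
#'   `frac_nonsignificant`, `n_individuals`, `alpha`.
#' @export
glance.grid_comparison <- function(x, ...) {
  tibble::tibble(
    best_setting = x$best_setting,
    r_best = x$r_best,
    n_nonsignificant = x$n_nonsignificant,
    frac_nonsignificant = x$frac_nonsignificant,
    n_individuals = x$n_individuals,
    alpha = x$alpha
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
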