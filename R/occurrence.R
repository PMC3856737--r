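#' Plot- and patch-level occurrence statistics
#'
#' Nonparametric comparisons of patch size, connectivity and stone-field
#' distance between plots with and without voles (Mann–Whitney U, Fisher
#' exact), Pearson correlations of transformed densities against habitat
#' predictors, the home-range-to-dispersal scaling used to bracket plausible
#' dispersal thresholds, and the trapping density index.
#'
#' @name occurrence_stats
NULL

#' Mann–Whitney U test (two-sided)
#'
#' Exact permutation null when the combined sample size is at most 20 and no
#' ties are present; tie-corrected normal approximation (no continuity
#' correction, matching the conventional reporting of the U statistic's
#' normal deviate) otherwise. When every value in both samples is identical
#' the test is degenerate and `p = 1` is returned with a warning.
#'
#' @param x,y numeric samples (non-empty).
#' @return List with `U` (for the first sample) and `p`.
#' @export
mann_whitney <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  if (length(unique(c(x, y))) == 1) {
    warning("all values identical in both samples; p = 1")
    return(list(U = length(x) * length(y) / 2, p = 1))
  }
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y) <= 20) && !ties
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = FALSE))
  list(U = unname(ht$statistic), p = ht$p.value)
}

#' Fisher exact test on a 2x2 table (two-sided)
#'
#' Two-sided p-value under the standard rule: the sum of hypergeometric
#' probabilities, over all tables with the observed margins, of tables no
#' more probable than the observed one (with a small relative slack for
#' floating-point ties). Degenerate margins give `p = 1`.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  stats::fisher.test(tab)$p.value
}

#' Pearson correlation on transformed variables
#'
#' Supports the transforms used by the analysis: `"log"` is `log(x + eps)`
#' with `eps` = half the smallest positive value when zeros occur (0
#' otherwise), and `"arcsin_sqrt"` is `asin(sqrt(p))` for proportions (the
#' variance-stabilizing angular transform). Pairs with missing values are
#' dropped; the two-sided p-value comes from the t distribution with `n - 2`
#' degrees of freedom.
#'
#' @param x,y numeric vectors.
#' @param transform_x,transform_y one of `"identity"`, `"log"`,
#'   `"arcsin_sqrt"`.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_corr <- function(x, y, transform_x = "identity", transform_y = "identity") {
  tf <- function(v, how) {
    switch(how,
      identity = v,
      log = {
        eps <- if (any(v == 0, na.rm = TRUE)) {
          pos <- v[!is.na(v) & v > 0]
          if (length(pos)) min(pos) / 2 else 1
        } else 0
        log(v + eps)
      },
      arcsin_sqrt = {
        if (any(v < 0 | v > 1, na.rm = TRUE)) stop("arcsin_sqrt needs values in [0, 1]")
        asin(sqrt(v))
      },
      stop("unknown transform: ", how))
  }
  keep <- stats::complete.cases(x, y)
  x <- tf(x[keep], transform_x); y <- tf(y[keep], transform_y)
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance after transform")
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value, n = length(x))
}

#' Dispersal distances predicted from home-range size
#'
#' Allometric home-range-to-dispersal scaling for mammals: with home-range
#' area A in square metres and linear dimension `L = sqrt(A)` metres, the
#' median dispersal distance is `7 L` and the maximum dispersal distance
#' `40 L`. For the grey-sided vole's reproducing-female home range of
#' 0.135 ha this gives 0.26 km (median) and 1.47 km (maximum), bracketing —
#' together with published natal and long-range estimates — the dispersal
#' thresholds used for the connectivity analysis.
#'
#' @param area_ha home-range area in hectares, > 0.
#' @return List with `median_km` and `max_km` (unrounded; round to taste).
#' @export
dispersal_from_home_range <- function(area_ha) {
  if (!is.numeric(area_ha) || area_ha <= 0) stop("home-range area must be > 0")
  L <- sqrt(area_ha * 1e4)           # linear dimension, metres
  list(median_km = 7 * L / 1000, max_km = 40 * L / 1000)
}

#' Trapping density index
#'
#' Voles per 100 trap nights. The standard effort per plot is 150 trap
#' nights: 10 stations x 5 snap traps x 3 nights.
#'
#' @param count number of voles caught (>= 0).
#' @param trap_nights trapping effort (> 0).
#' @return Density index (animals per 100 trap nights).
#' @export
density_index <- function(count, trap_nights) {
  if (any(count < 0)) stop("count must be >= 0")
  if (any(trap_nights <= 0)) stop("trap_nights must be > 0")
  100 * count / trap_nights
}
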