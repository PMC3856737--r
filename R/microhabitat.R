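#' Station-level microhabitat occurrence modelling
#'
#' Vole occurrence at trap stations (0/1) is modelled against ordinal and
#' continuous ground-structure covariates with a binomial-logit mixed model:
#' stations are nested in 1-ha sampling plots, which enter as a Gaussian
#' random intercept. Candidate covariates are prefiltered for collinearity
#' (Spearman |rho| > 0.5, greedy keep-first in the documented inventory
#' order) and for low variance (< 1 on the 1–5 cover scale, scale-adjusted
#' for other codings). All covariate subsets are then fitted and ranked by
#' AICc; Akaike weights feed full model averaging and per-variable relative
#' importance (the sum of weights of the models containing the variable).
#'
#' @name microhabitat_stats
NULL

#' Metadata for the station inventory covariates
#'
#' The 26 structural covariates recorded at each trap station, in the fixed
#' inventory order used by the greedy collinearity filter, with their coding:
#' five-class cover scores (1 = 0%, 2 = >0–12%, 3 = >12–25%, 4 = >25–50%,
#' 5 = >50%), hole-count classes (0 = 0–4, 5 = 5–9, 10 = 10–19, 20 = 20–39,
#' 40 = >= 40; large stone holes split the first class into 0 = none and
#' 1 = 1–4), tree-species proportions in \[0, 1\], coarse woody debris length
#' in metres, and raw counts for snags and large stones.
#'
#' @return `data.frame` with `variable`, `scale` (`cover5`, `holes`,
#'   `holes_ls`, `prop`, `length_m`, `count`), `min`, `max` (legal range used
#'   by the scale-adjusted variance threshold).
#' @export
station_variable_info <- function() {
  v <- rbind(
    c("bilb", "cover5"), c("cowb", "cover5"), c("t_lichens", "cover5"),
    c("cwd", "length_m"), c("fwd", "cover5"), c("snags", "count"),
    c("lichens", "cover5"), c("mosses", "cover5"), c("grasses", "cover5"),
    c("u_veg", "cover5"), c("fl_veg", "cover5"), c("lstones", "cover5"),
    c("lstones_no", "count"), c("stones", "cover5"), c("s_holes", "holes"),
    c("l_holes", "holes"), c("ls_holes", "holes_ls"), c("pine", "prop"),
    c("spruce", "prop"), c("birch", "prop"), c("aspen", "prop"),
    c("g_willow", "prop"), c("other_trees", "prop"), c("bushes", "cover5"),
    c("tl1", "cover5"), c("tl2", "cover5"))
  rng <- list(cover5 = c(1, 5), holes = c(0, 40), holes_ls = c(0, 40),
              prop = c(0, 1), length_m = c(0, 20), count = c(0, 40))
  data.frame(variable = v[, 1], scale = v[, 2],
             min = vapply(v[, 2], function(s) rng[[s]][1], 0),
             max = vapply(v[, 2], function(s) rng[[s]][2], 0))
}

#' Legal code sets for the ordinal station covariates
#'
#' @return Named list of legal values: `cover5` 1–5, `holes` {0,5,10,20,40},
#'   `holes_ls` {0,1,5,10,20,40}.
#' @export
station_code_sets <- function() {
  list(cover5 = 1:5, holes = c(0, 5, 10, 20, 40), holes_ls = c(0, 1, 5, 10, 20, 40))
}

#' Greedy collinearity prefilter on Spearman correlation
#'
#' Scans the variables in the given (documented, fixed) order; a variable is
#' dropped when its |Spearman rho| with any already-retained variable exceeds
#' the threshold. Constant variables have undefined rho: they are flagged and
#' passed through for the variance filter to remove.
#'
#' @param data data frame of station records.
#' @param variables covariate names in scan order (default: inventory order).
#' @param threshold |rho| above which the later variable is dropped (0.5).
#' @return Character vector of retained variable names; dropped and flagged
#'   names in attributes `dropped` and `flagged`.
#' @export
collinearity_filter <- function(data, variables = intersect(station_variable_info()$variable, names(data)),
                                threshold = 0.5) {
  if (nrow(data) < 3) stop("need at least 3 stations")
  kept <- character(0); dropped <- character(0); flagged <- character(0)
  for (v in variables) {
    if (stats::sd(data[[v]]) == 0) { flagged <- c(flagged, v); kept <- c(kept, v); next }
    ok <- TRUE
    for (u in setdiff(kept, flagged)) {
      rho <- suppressWarnings(stats::cor(data[[v]], data[[u]], method = "spearman"))
      if (!is.na(rho) && abs(rho) > threshold) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, v) else dropped <- c(dropped, v)
  }
  structure(kept, dropped = dropped, flagged = flagged)
}

#' Low-variance prefilter
#'
#' Retains variables whose sample variance is at least `min_var` on the 1–5
#' cover scale. Other codings use a scale-equivalent threshold: ordinal
#' class codes (cover classes, hole-count classes) are mapped to their class
#' index 1..K and thresholded at `min_var * ((K - 1)/4)^2` (a variance of 1
#' on the 4-unit-wide 5-class scale); continuous variables are thresholded
#' at `min_var * (range/4)^2` with `range` the legal range for proportions
#' and the observed range otherwise.
#'
#' @param data data frame of station records.
#' @param variables covariate names to screen.
#' @param min_var variance threshold on the 1–5 scale (default 1).
#' @param info metadata with scales and legal ranges (default
#'   [station_variable_info()]); variables absent from it are treated as
#'   continuous with observed range.
#' @return Character vector of retained names; dropped names in attribute
#'   `dropped`.
#' @export
variance_filter <- function(data, variables = intersect(station_variable_info()$variable, names(data)),
                            min_var = 1, info = station_variable_info()) {
  codes <- station_code_sets()
  kept <- character(0); dropped <- character(0)
  for (v in variables) {
    i <- match(v, info$variable)
    scale <- if (!is.na(i)) info$scale[i] else "continuous"
    if (scale %in% names(codes)) {
      idx <- match(data[[v]], codes[[scale]])
      thr <- min_var * ((length(codes[[scale]]) - 1) / 4)^2
      vv <- stats::var(idx)
    } else {
      rng <- if (scale == "prop") 1 else diff(range(data[[v]]))
      thr <- min_var * (rng / 4)^2
      vv <- stats::var(data[[v]])
    }
    if (vv >= thr) kept <- c(kept, v) else dropped <- c(dropped, v)
  }
  structure(kept, dropped = dropped)
}

#' Fit the binomial-logit mixed model for one covariate subset
#'
#' Logistic regression of station occurrence on the listed covariates with a
#' Gaussian random intercept per sampling plot, fitted by maximum likelihood
#' (`lme4::glmer`, Laplace approximation by default; `nAGQ = 0` gives a
#' faster penalized-least-squares approximation useful in simulation
#' studies). The parameter count `k` is the number of fixed effects
#' (including the intercept) plus one for the random-intercept variance.
#'
#' @param data data frame with `occurrence` (0/1), `plot_id`, and covariates.
#' @param variables character vector of covariate names (may be empty: null
#'   model).
#' @param nAGQ integrand approximation passed to `lme4::glmer` (1 = Laplace).
#' @return List with `loglik`, `k`, `n`, `coefficients` (fixed effects),
#'   `flagged` (non-convergence or separation), `fit` (the `glmerMod`).
#' @export
fit_station_model <- function(data, variables = character(0), nAGQ = 1) {
  if (length(unique(data$plot_id)) < 2) stop("need at least 2 plots")
  rhs <- paste(c("1", variables), collapse = " + ")
  f <- stats::as.formula(paste("occurrence ~", rhs, "+ (1 | plot_id)"))
  flagged <- FALSE; msg <- NULL
  fit <- withCallingHandlers(
    suppressMessages(lme4::glmer(f, data = data, family = stats::binomial, nAGQ = nAGQ)),
    warning = function(w) {
      if (!grepl("singular", conditionMessage(w))) {
        flagged <<- TRUE; msg <<- conditionMessage(w)
      }
      invokeRestart("muffleWarning")
    })
  beta <- lme4::fixef(fit)
  if (any(abs(beta) > 15)) { flagged <- TRUE; msg <- "possible separation (|coef| > 15)" }
  list(loglik = as.numeric(stats::logLik(fit)), k = length(beta) + 1L,
       n = nrow(data), coefficients = beta, flagged = flagged, message = msg,
       fit = fit)
}

#' Small-sample Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1)`.
#'
#' @param loglik maximized log-likelihood.
#' @param k parameter count.
#' @param n sample size (number of stations).
#' @return AICc, or `NA` when `n <= k + 1`.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) return(NA_real_)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' All-subsets AICc model selection over the candidate covariates
#'
#' Fits every subset of the candidate covariates (including the null model),
#' ranks by AICc (sample size = number of stations), and attaches the AICc
#' difference to the best model (`delta`) and Akaike weights
#' `w_i = exp(-delta_i/2) / sum(exp(-delta/2))`. Models flagged for
#' non-convergence or separation, and models with `n <= k + 1`, are excluded
#' with a warning. Models with `delta < 4` carry `supported = TRUE`
#' (models beyond that have considerably less empirical support).
#'
#' @param data station data frame (see [fit_station_model()]).
#' @param variables candidate covariates (at most 12).
#' @param nAGQ passed to [fit_station_model()].
#' @return A `candidate_model_table`: data frame with `formula`, `k`,
#'   `loglik`, `AICc`, `delta`, `weight`, `supported`, one row per fitted
#'   model, best first; per-model coefficients in attribute `coefficients`
#'   and the variable membership matrix in attribute `membership`.
#' @export
dredge_stations <- function(data, variables, nAGQ = 1) {
  p <- length(variables)
  if (p > 12) stop("at most 12 candidate variables (2^12 models)")
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), p))
  if (p == 0) subsets <- data.frame(row.names = 1)
  rows <- list(); coefs <- list(); memb <- list()
  for (s in seq_len(nrow(subsets))) {
    vars <- variables[unlist(subsets[s, ])]
    m <- fit_station_model(data, vars, nAGQ = nAGQ)
    a <- aicc(m$loglik, m$k, m$n)
    if (m$flagged || is.na(a)) {
      warning(sprintf("model '%s' excluded: %s",
                      paste(c("1", vars), collapse = " + "),
                      if (m$flagged) m$message else "n <= k + 1"))
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      formula = paste(c("(Intercept)", vars), collapse = " + "),
      k = m$k, loglik = m$loglik, AICc = a)
    coefs[[length(coefs) + 1]] <- m$coefficients
    memb[[length(memb) + 1]] <- variables %in% vars
  }
  if (!length(rows)) stop("no model could be fitted")
  tab <- do.call(rbind, rows)
  tab$delta <- tab$AICc - min(tab$AICc)
  tab$weight <- exp(-tab$delta / 2) / sum(exp(-tab$delta / 2))
  tab$supported <- tab$delta < 4
  o <- order(tab$AICc)
  tab <- tab[o, ]
  rownames(tab) <- NULL
  memb <- do.call(rbind, memb)[o, , drop = FALSE]
  colnames(memb) <- variables
  structure(tab, coefficients = coefs[o], membership = memb,
            class = c("candidate_model_table", "data.frame"))
}

#' Full model averaging and relative variable importance
#'
#' Full (not conditional) averaging: a variable's averaged coefficient is
#' `sum_i w_i beta_i` with `beta_i = 0` in models that omit it; its relative
#' importance is the summed Akaike weight of the models that contain it
#' (0–1). Output is sorted by decreasing importance.
#'
#' @param table a `candidate_model_table` from [dredge_stations()].
#' @return `data.frame` with `variable`, `coefficient`, `importance`,
#'   `direction` (sign of the averaged coefficient). The averaged intercept
#'   is included with importance 1.
#' @export
model_average <- function(table) {
  stopifnot(inherits(table, "candidate_model_table"))
  memb <- attr(table, "membership")
  coefs <- attr(table, "coefficients")
  w <- table$weight
  vars <- colnames(memb)
  avg <- vapply(vars, function(v) {
    sum(vapply(seq_along(coefs), function(i) {
      b <- coefs[[i]]
      w[i] * if (v %in% names(b)) b[[v]] else 0
    }, 0))
  }, 0)
  imp <- colSums(memb * w)
  int <- sum(vapply(seq_along(coefs), function(i) w[i] * coefs[[i]][["(Intercept)"]], 0))
  out <- data.frame(variable = c("(Intercept)", vars),
                    coefficient = c(int, avg),
                    importance = c(1, imp))
  out$direction <- sign(out$coefficient)
  out <- out[c(1, 1 + order(-imp)), ]
  rownames(out) <- NULL
  out
}
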