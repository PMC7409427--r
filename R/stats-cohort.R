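#' Pearson correlation with two-sided t-based p-value
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return List with `r`, `p`, `n` and `undefined` (TRUE, with a warning,
#'   when either input has zero variance).
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` lengths differ", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined", call. = FALSE)
    return(list(r = NA_real_, p = NA_real_, n = length(x), undefined = TRUE))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       undefined = FALSE)
}

#' Multivariable linear regression of CVD on age, axial length and SCT
#'
#' Ordinary least squares `cvd ~ age + axial_length + sct`. The SCT
#' coefficient (and its confidence interval) is rescaled to CVD percentage
#' points per 100 um of SCT for reporting.
#'
#' @param data Data.frame with numeric columns `cvd` (percent), `age`
#'   (years), `axial_length` (mm) and `sct` (um); n >= 10.
#' @param conf_level Confidence level for the intervals.
#' @return Object of class `cvd_regression`: `coefficients` (data.frame with
#'   estimate, CI bounds and p per predictor; row `sct_per_100um` is on the
#'   per-100-um scale), `n`, and the underlying `fit`.
#' @export
fit_cvd_regression <- function(data, conf_level = 0.95) {
  needed <- c("cvd", "age", "axial_length", "sct")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    stop("data is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(data) < 10) stop("need at least 10 eyes", call. = FALSE)
  fit <- stats::lm(cvd ~ age + axial_length + sct, data = data)
  X <- stats::model.matrix(fit)
  if (anyNA(stats::coef(fit)) || kappa(X) > 1e8) {
    warning("predictors are (near-)collinear; coefficients are unstable",
            call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit, level = conf_level)
  tab <- data.frame(
    estimate = sm[-1, 1],
    ci_lower = ci[-1, 1], ci_upper = ci[-1, 2],
    p = sm[-1, 4]
  )
  rownames(tab) <- c("age", "axial_length", "sct")
  tab["sct", c("estimate", "ci_lower", "ci_upper")] <-
    tab["sct", c("estimate", "ci_lower", "ci_upper")] * 100
  rownames(tab)[rownames(tab) == "sct"] <- "sct_per_100um"
  structure(list(coefficients = tab, n = nrow(data), conf_level = conf_level,
                 fit = fit),
            class = "cvd_regression")
}

#' @export
print.cvd_regression <- function(x, digits = 3, ...) {
  cat(sprintf("CVD regression (n = %d): cvd ~ age + axial_length + sct\n",
              x$n))
  tab <- x$coefficients
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-14s %+.*f  (%d%% CI %.*f to %.*f)  p = %.3g\n",
                rownames(tab)[i], digits, tab$estimate[i],
                round(100 * x$conf_level), digits, tab$ci_lower[i],
                digits, tab$ci_upper[i], tab$p[i]))
  }
  invisible(x)
}

#' One-way ANOVA reconstructed from group summary statistics
#'
#' Rebuilds the between- and within-group sums of squares from per-group
#' means, SDs and sizes. Exact: it equals the raw-data one-way ANOVA on any
#' dataset having those summaries.
#'
#' @param means,sds,ns Numeric vectors, one entry per group (>= 2 groups;
#'   each n >= 2; SDs are sample SDs > 0 or 0).
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
anova_from_summary <- function(means, sds, ns) {
  k <- length(means)
  if (k < 2 || length(sds) != k || length(ns) != k) {
    stop("`means`, `sds`, `ns` must have one entry per group (>= 2 groups)",
         call. = FALSE)
  }
  if (any(ns < 2)) stop("each group needs n >= 2", call. = FALSE)
  if (any(sds < 0) || any(!is.finite(sds))) {
    stop("`sds` must be finite and non-negative", call. = FALSE)
  }
  N <- sum(ns)
  gm <- sum(ns * means) / N
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((ns - 1) * sds^2)
  df1 <- k - 1
  df2 <- N - k
  if (ssw == 0) {
    Fv <- if (ssb == 0) 0 else Inf
  } else {
    Fv <- (ssb / df1) / (ssw / df2)
  }
  p <- if (is.infinite(Fv)) 0 else
    stats::pf(Fv, df1, df2, lower.tail = FALSE)
  if (Fv == 0) p <- 1
  list(F = Fv, df1 = df1, df2 = df2, p = p)
}

#' SCT-adjusted group comparison of CVD (ANCOVA)
#'
#' Fits the common-slope linear model `cvd ~ group + sct` and tests the
#' group effect with the extra-sum-of-squares F test against `cvd ~ sct`.
#' Adjusted group means are evaluated at the grand-mean SCT. If the
#' covariate is constant the comparison reduces to a one-way ANOVA (with a
#' message). A significant group x SCT interaction only triggers a warning
#' (the common-slope model is still reported, as in standard ANCOVA).
#'
#' @param data Data.frame with `cvd`, `group` (factor or character, >= 2
#'   levels with >= 3 eyes each) and `sct`.
#' @return List with `p`, `F`, `df1`, `df2`, `adjusted_means` (named, at the
#'   grand-mean SCT), `covariate_used` (FALSE when SCT was constant) and
#'   `group_means` (raw).
#' @export
ancova_group_effect <- function(data) {
  needed <- c("cvd", "group", "sct")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    stop("data is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data$group <- factor(data$group)
  tabn <- table(data$group)
  if (length(tabn) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(tabn < 3)) stop("each group needs n >= 3", call. = FALSE)
  raw_means <- tapply(data$cvd, data$group, mean)

  if (stats::sd(data$sct) == 0) {
    message("SCT is constant; ANCOVA reduces to one-way ANOVA")
    fit <- stats::lm(cvd ~ group, data = data)
    an <- stats::anova(fit)
    return(list(p = an[["Pr(>F)"]][1], F = an[["F value"]][1],
                df1 = an[["Df"]][1], df2 = an[["Df"]][2],
                adjusted_means = raw_means, covariate_used = FALSE,
                group_means = raw_means))
  }

  full <- stats::lm(cvd ~ group + sct, data = data)
  reduced <- stats::lm(cvd ~ sct, data = data)
  cmpr <- stats::anova(reduced, full)
  inter <- stats::lm(cvd ~ group * sct, data = data)
  itest <- stats::anova(full, inter)
  if (!is.na(itest[["Pr(>F)"]][2]) && itest[["Pr(>F)"]][2] < 0.05) {
    warning("group x SCT interaction is significant; common-slope ANCOVA assumption is questionable",
            call. = FALSE)
  }
  nd <- data.frame(group = factor(levels(data$group),
                                  levels = levels(data$group)),
                   sct = mean(data$sct))
  adj <- stats::predict(full, newdata = nd)
  names(adj) <- levels(data$group)
  list(p = cmpr[["Pr(>F)"]][2], F = cmpr[["F"]][2],
       df1 = cmpr[["Df"]][2], df2 = full$df.residual,
       adjusted_means = adj, covariate_used = TRUE,
       group_means = raw_means)
}

#' Lilliefors-corrected Kolmogorov-Smirnov normality test
#'
#' One-sample K-S test against a Normal with the sample mean and SD,
#' Lilliefors-corrected for the estimated parameters. Advisory only; no
#' downstream computation gates on it.
#'
#' @param x Numeric vector, n >= 5.
#' @return List with `statistic`, `p` and `degenerate` (TRUE, with a
#'   warning, for constant input).
#' @export
ks_normality <- function(x) {
  if (length(x) < 5) stop("need at least 5 observations", call. = FALSE)
  if (stats::sd(x) == 0) {
    warning("constant input: normality test undefined", call. = FALSE)
    return(list(statistic = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  lt <- nortest::lillie.test(x)
  list(statistic = unname(lt$statistic), p = lt$p.value, degenerate = FALSE)
}

#' Select matched controls for a case series
#'
#' Greedy nearest-neighbour matching without replacement: controls must have
#' the same sex as the case, and among unused same-sex candidates the one
#' minimizing `|d age| / age_scale + |d AL| / al_scale` is taken. The scales
#' default to typical cohort SDs of age (12.3 y) and axial length (1.18 mm).
#'
#' @param cases Data.frame of case eyes with `age`, `sex`, `axial_length`.
#' @param pool Data.frame of candidate control eyes (same columns).
#' @param age_scale,al_scale Matching scales.
#' @return The matched rows of `pool`, one per case, in case order.
#' @export
match_controls <- function(cases, pool, age_scale = 12.3, al_scale = 1.18) {
  used <- rep(FALSE, nrow(pool))
  picks <- integer(nrow(cases))
  for (i in seq_len(nrow(cases))) {
    cand <- which(!used & pool$sex == cases$sex[i])
    if (!length(cand)) {
      stop(sprintf("no unused %s control available for case %d",
                   cases$sex[i], i), call. = FALSE)
    }
    d <- abs(pool$age[cand] - cases$age[i]) / age_scale +
      abs(pool$axial_length[cand] - cases$axial_length[i]) / al_scale
    picks[i] <- cand[which.min(d)]
    used[picks[i]] <- TRUE
  }
  pool[picks, , drop = FALSE]
}
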