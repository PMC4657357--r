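# Individuality statistics: coefficients of variation between and within
# individuals, the PIC ratio, univariate group tests, multicollinearity
# screening, robust outlier flagging, class balancing, quadratic
# discriminant analysis with jack-knife leave-one-out cross-validation,
# and forward stepwise feature ranking.

#' Between-individual coefficient of variation (CVb)
#'
#' `CVb = 100 * SD / mean` over the pooled sample of all calls (sample
#' SD, n-1 denominator).
#'
#' @param values numeric vector, all calls' values of one parameter.
#' @return CVb in percent.
#' @export
cv_between <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop_arg("at least 2 values are required")
  m <- mean(values)
  if (m == 0) stop_arg("CV is undefined for zero mean")
  100 * stats::sd(values) / m
}

#' Within-individual coefficient of variation (CVw)
#'
#' Small-sample-corrected CV of one individual's values:
#' `CVw = 100 * (SD / mean) * (1 + 1/(4n))`.
#'
#' @param values numeric vector, one individual's values of one parameter.
#' @return CVw in percent.
#' @export
cv_within <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop_arg("at least 2 values are required")
  m <- mean(values)
  if (m == 0) stop_arg("CV is undefined for zero mean")
  100 * (stats::sd(values) / m) * (1 + 1 / (4 * n))
}

#' Potential for individual coding (PIC)
#'
#' `PIC = CVb / mean(CVw)`, the ratio of between-individual variation to
#' the average within-individual variation. PIC > 1 suggests a parameter
#' can encode individual identity.
#'
#' @param cvb between-individual CV, percent.
#' @param cvw_per_individual numeric vector of per-individual CVw values
#'   (a single pre-averaged mean CVw is also accepted).
#' @return PIC ratio.
#' @export
pic <- function(cvb, cvw_per_individual) {
  m <- mean(cvw_per_individual)
  if (!is.finite(m) || m <= 0) stop_arg("mean CVw must be positive")
  cvb / m
}

#' PIC table over a feature set
#'
#' Computes CVb, per-individual CVw, mean CVw and PIC for each parameter.
#'
#' @param features data.frame of per-call parameter values.
#' @param labels factor or character vector of individual labels (one per
#'   row of `features`).
#' @param params parameter columns to use (default [feature_names()]
#'   intersected with the available columns).
#' @return data.frame of class `pic_table`: one row per parameter with
#'   `cvb`, `cvw_<label>` columns, `mean_cvw`, `pic`.
#' @export
pic_table <- function(features, labels, params = NULL) {
  labels <- factor(labels)
  params <- params %||% intersect(feature_names(), names(features))
  rows <- lapply(params, function(p) {
    v <- features[[p]]
    cvb <- cv_between(v)
    cvw <- vapply(levels(labels), function(l) {
      vi <- v[labels == l & !is.na(v)]
      if (length(vi) < 2) return(NA_real_)
      cv_within(vi)
    }, numeric(1))
    mcw <- mean(cvw, na.rm = TRUE)
    data.frame(parameter = p, cvb = cvb,
               t(stats::setNames(cvw, paste0("cvw_", levels(labels)))),
               mean_cvw = mcw, pic = pic(cvb, mcw),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pic_table", class(out))
  out
}

#' Kruskal-Wallis test across individuals
#'
#' Tie-corrected rank-based H statistic (chi-square approximation) via
#' `stats::kruskal.test`. All-identical values give a zero statistic with
#' a warning instead of an error.
#'
#' @param groups list of numeric vectors, one per individual.
#' @return list: `statistic` (chi-squared), `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop_arg("at least 2 groups are required")
  if (any(vapply(groups, length, integer(1)) < 1))
    stop_arg("every group needs at least 1 value")
  all_v <- unlist(groups)
  if (length(unique(all_v)) == 1) {
    warning("all values identical; statistic is 0")
    return(list(statistic = 0, df = length(groups) - 1, p_value = 1))
  }
  kt <- stats::kruskal.test(groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' One-way ANOVA across individuals
#'
#' Standard fixed-effects decomposition with df1 = k-1, df2 = N-k.
#' Zero within-group variance is flagged degenerate (F undefined or
#' infinite).
#'
#' @param groups list of numeric vectors, one per individual.
#' @return list: `F`, `df1`, `df2`, `p_value`, `degenerate`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop_arg("at least 2 groups are required")
  v <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  k <- length(groups)
  N <- length(v)
  within_var <- sum(vapply(groups, function(x)
    sum((x - mean(x))^2), numeric(1)))
  if (within_var == 0) {
    return(list(F = NA_real_, df1 = k - 1, df2 = N - k, p_value = NA_real_,
                degenerate = TRUE))
  }
  fit <- stats::oneway.test(v ~ g, var.equal = TRUE)
  list(F = unname(fit$statistic), df1 = unname(fit$parameter[1]),
       df2 = unname(fit$parameter[2]), p_value = fit$p.value,
       degenerate = FALSE)
}

#' Variance-inflation-factor screening
#'
#' VIF_j = 1 / (1 - R^2_j) from regressing feature j on the remaining
#' features. Features are removed iteratively (largest VIF first, perfect
#' collinearity counts as infinite) until all remaining VIFs fall below
#' the threshold.
#'
#' @param features data.frame or matrix of candidate features (rows =
#'   calls).
#' @param threshold removal threshold (default 20, the conventional "high
#'   multicollinearity" cut used for this analysis).
#' @return list of class `vif_screen`: `vif_initial`, `removed` (in
#'   removal order), `vif_final`, `retained`.
#' @export
vif_screen <- function(features, threshold = 20.0) {
  x <- as.data.frame(features)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (ncol(x) < 2) stop_arg("at least 2 features are required")
  if (nrow(x) <= ncol(x)) stop_arg("more rows than features are required")
  vifs <- function(d) {
    vapply(names(d), function(j) {
      # perfect fits (exactly collinear features) warn in summary.lm;
      # they are expected here and map to infinite VIF
      r2 <- suppressWarnings(
        summary(stats::lm(d[[j]] ~ ., data = d[setdiff(names(d), j)]))$r.squared)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  initial <- vifs(x)
  removed <- character(0)
  cur <- x
  repeat {
    v <- vifs(cur)
    if (max(v) < threshold || ncol(cur) <= 2) break
    worst <- names(v)[which.max(v)]
    removed <- c(removed, worst)
    cur <- cur[setdiff(names(cur), worst)]
  }
  structure(list(vif_initial = initial, removed = removed,
                 vif_final = vifs(cur), retained = names(cur),
                 threshold = threshold),
            class = "vif_screen")
}

#' Robust multivariate outlier flagging
#'
#' Robust Mahalanobis distances from an MCD (minimum covariance
#' determinant) location/scatter fit; rows whose squared distance exceeds
#' the chi-square quantile at p degrees of freedom are flagged. Flags do
#' not remove rows: dropping outliers is an explicit, separate decision.
#'
#' @param features numeric matrix / data.frame (rows = calls).
#' @param quantile chi-square quantile for flagging (default 0.975).
#' @param seed optional seed for the MCD subsampling.
#' @return list: `distance2` (squared robust distances), `flag`
#'   (logical), `cutoff`.
#' @export
robust_outliers <- function(features, quantile = 0.975, seed = NULL) {
  x <- as.matrix(features)
  p <- ncol(x)
  if (nrow(x) <= 2 * p) stop_arg("need more than 2 x p rows")
  fit <- with_seed(seed, tryCatch(
    MASS::cov.rob(x, method = "mcd"),
    error = function(e) stop_arg(
      "robust scatter estimation failed (singular data?); ",
      "screen features first: ", conditionMessage(e))))
  d2 <- stats::mahalanobis(x, fit$center, fit$cov)
  cutoff <- stats::qchisq(quantile, df = p)
  list(distance2 = d2, flag = d2 > cutoff, cutoff = cutoff)
}

#' Balance class sizes by random subsampling
#'
#' Classes larger than `target_n` are subsampled without replacement
#' (deterministically for a given seed); smaller classes are untouched.
#'
#' @param labels class labels (one per row).
#' @param target_n per-class cap (>= 1).
#' @param seed integer seed.
#' @return sorted integer vector of retained row indices.
#' @export
balance_classes <- function(labels, target_n, seed = 1) {
  if (target_n < 1) stop_arg("target_n must be >= 1")
  labels <- as.character(labels)
  with_seed(seed, {
    keep <- unlist(lapply(unique(labels), function(l) {
      idx <- which(labels == l)
      if (length(idx) > target_n) sort(sample(idx, target_n)) else idx
    }))
    sort(keep)
  })
}

#' Quadratic discriminant analysis with leave-one-out cross-validation
#'
#' Fits per-class Gaussian densities (class mean and covariance) and
#' classifies each call by maximum prior-weighted log-density, with
#' jack-knife leave-one-out cross-validation (each call classified by a
#' model fitted without it). Priors default to class sample proportions.
#'
#' @param features numeric matrix / data.frame of predictor columns.
#' @param labels class labels.
#' @param prior "proportional" (class sample sizes), "uniform", or a
#'   named numeric vector of prior weights.
#' @return object of class `dfa_result`: `confusion` (individuals x
#'   predicted), `overall_pct`, `per_class_pct`, `prior`, `features`,
#'   `n`, `predicted`.
#' @export
qda_loocv <- function(features, labels, prior = "proportional") {
  x <- as.matrix(as.data.frame(features))
  g <- factor(labels)
  if (any(!stats::complete.cases(x))) {
    keep <- stats::complete.cases(x)
    x <- x[keep, , drop = FALSE]
    g <- droplevels(g[keep])
  }
  cnt <- table(g)
  if (any(cnt <= ncol(x) + 1)) {
    bad <- names(cnt)[cnt <= ncol(x) + 1]
    stop_arg("class(es) too small for a per-class covariance: ",
             paste(bad, collapse = ", "))
  }
  pr <- if (identical(prior, "proportional")) as.numeric(cnt) / length(g)
        else if (identical(prior, "uniform")) rep(1 / nlevels(g), nlevels(g))
        else as.numeric(prior[levels(g)])
  fit <- tryCatch(
    MASS::qda(x, g, prior = pr, CV = TRUE),
    error = function(e) stop_arg("QDA failed (singular class covariance?): ",
                                 conditionMessage(e)))
  pred <- fit$class
  cm <- table(individual = g, predicted = pred)
  overall <- 100 * sum(diag(cm)) / length(g)
  per_class <- 100 * diag(cm) / rowSums(cm)
  structure(list(confusion = cm, overall_pct = overall,
                 per_class_pct = per_class,
                 prior = stats::setNames(pr, levels(g)),
                 features = colnames(x), n = length(g), predicted = pred),
            class = "dfa_result")
}

#' @export
print.dfa_result <- function(x, ...) {
  cat(sprintf("<dfa_result: %d calls, %d features, LOOCV %.1f%% correct>\n",
              x$n, length(x$features), x$overall_pct))
  print(x$confusion)
  invisible(x)
}

#' Forward stepwise feature ranking by LOOCV correctness
#'
#' At each step the feature whose addition maximizes the leave-one-out
#' QDA correct-classification fraction is added. The best single feature
#' is always selected; subsequent features must improve the criterion by
#' at least `improvement_min` (fraction of calls) or selection stops.
#'
#' @param features data.frame of candidate features.
#' @param labels class labels.
#' @param improvement_min minimum improvement of the LOOCV correctness
#'   fraction to continue (default 0.05).
#' @param prior passed to [qda_loocv()].
#' @return list of class `stepwise_result`: `selected` (in order),
#'   `criterion` (LOOCV fraction after each selection), `trace`
#'   (per-step candidate rates).
#' @export
stepwise_select <- function(features, labels, improvement_min = 0.05,
                            prior = "proportional") {
  x <- as.data.frame(features)
  if (ncol(x) < 2) stop_arg("at least 2 candidate features are required")
  selected <- character(0)
  crit <- numeric(0)
  trace <- list()
  current <- 0
  repeat {
    remaining <- setdiff(names(x), selected)
    if (length(remaining) == 0) break
    rates <- vapply(remaining, function(f) {
      tryCatch(qda_loocv(x[c(selected, f)], labels, prior)$overall_pct / 100,
               error = function(e) NA_real_)
    }, numeric(1))
    trace[[length(trace) + 1]] <- rates
    if (all(is.na(rates))) {
      if (length(selected) == 0)
        stop_arg("no candidate feature admits a QDA fit")
      break
    }
    best <- names(rates)[which.max(rates)]
    best_rate <- max(rates, na.rm = TRUE)
    if (length(selected) > 0 && best_rate < current + improvement_min) break
    selected <- c(selected, best)
    crit <- c(crit, best_rate)
    current <- best_rate
  }
  structure(list(selected = selected, criterion = crit, trace = trace,
                 improvement_min = improvement_min),
            class = "stepwise_result")
}

#' Covariance and normality diagnostics
#'
#' Box's M test for homogeneity of the class covariance matrices
#' (chi-square approximation) and Mardia's multivariate skewness and
#' kurtosis tests on the within-class-centred residuals (the documented
#' substitute for an unnamed multivariate Shapiro-Wilk variant).
#'
#' @param features numeric matrix / data.frame.
#' @param labels class labels (>= 2 classes).
#' @return list of class `cov_diagnostics`: `box_m` (`statistic`,
#'   `chi2`, `df`, `p_value`) and `mardia` (`skew_stat`, `skew_df`,
#'   `skew_p`, `kurt_z`, `kurt_p`).
#' @export
covariance_diagnostics <- function(features, labels) {
  x <- as.matrix(as.data.frame(features))
  g <- factor(labels)
  if (nlevels(g) < 2) stop_arg("at least 2 classes are required")
  p <- ncol(x)
  k <- nlevels(g)
  ns <- as.numeric(table(g))
  if (any(ns <= p)) stop_arg("every class needs more rows than features")
  covs <- lapply(levels(g), function(l) stats::cov(x[g == l, , drop = FALSE]))
  N <- nrow(x)
  Sp <- Reduce(`+`, Map(function(S, n) (n - 1) * S, covs, ns)) / (N - k)
  lds <- vapply(covs, function(S) {
    d <- determinant(S, logarithm = TRUE)
    if (d$sign <= 0) stop_arg("singular class covariance")
    as.numeric(d$modulus)
  }, numeric(1))
  dp <- determinant(Sp, logarithm = TRUE)
  if (dp$sign <= 0) stop_arg("singular pooled covariance")
  M <- (N - k) * as.numeric(dp$modulus) - sum((ns - 1) * lds)
  c1 <- (sum(1 / (ns - 1)) - 1 / (N - k)) *
    (2 * p^2 + 3 * p - 1) / (6 * (p + 1) * (k - 1))
  chi2 <- M * (1 - c1)
  df_m <- p * (p + 1) * (k - 1) / 2
  p_m <- stats::pchisq(chi2, df_m, lower.tail = FALSE)
  # Mardia on pooled within-class residuals
  resid <- x - apply(x, 2, function(col) stats::ave(col, g))
  S <- stats::cov(resid) * (N - 1) / N
  Sinv <- solve(S)
  G <- resid %*% Sinv %*% t(resid)
  b1 <- mean(G^3)
  b2 <- mean(diag(G)^2)
  skew_stat <- N * b1 / 6
  skew_df <- p * (p + 1) * (p + 2) / 6
  skew_p <- stats::pchisq(skew_stat, skew_df, lower.tail = FALSE)
  kurt_z <- (b2 - p * (p + 2)) / sqrt(8 * p * (p + 2) / N)
  kurt_p <- 2 * stats::pnorm(abs(kurt_z), lower.tail = FALSE)
  structure(list(
    box_m = list(statistic = M, chi2 = chi2, df = df_m, p_value = p_m),
    mardia = list(skew_stat = skew_stat, skew_df = skew_df, skew_p = skew_p,
                  kurt_z = kurt_z, kurt_p = kurt_p)
  ), class = "cov_diagnostics")
}
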