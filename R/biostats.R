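#' Wilcoxon-Mann-Whitney test with exact small-sample p-value
#'
#' For combined sample sizes up to `exact_max` (default 20) the two-sided
#' p-value is computed by full enumeration of the C(n_x + n_y, n_x) group
#' labelings of the (mid-)ranks -- the appropriate treatment for the n = 5-8
#' groups typical of murine studies, where the normal approximation is
#' unreliable. Two-sided p = 2 * min(tail probabilities), capped at 1; ties
#' receive mid-ranks. Larger samples fall back to the normal approximation
#' with tie-corrected variance and continuity correction; both values are
#' available.
#'
#' @param x,y numeric samples (each n >= 2)
#' @param exact_max largest combined n for exact enumeration
#' @return list(U, p, p_exact, p_asymptotic, method)
#' @export
wmw_test <- function(x, y, exact_max = 20) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop_bonemech("each group needs >= 2 observations")
  r <- rank(c(x, y))            # mid-ranks for ties
  rx <- sum(r[seq_len(nx)])
  U <- rx - nx * (nx + 1) / 2
  p_exact <- NA_real_
  if (nx + ny <= exact_max) {
    combos <- combn(nx + ny, nx)
    sums <- colSums(matrix(r[combos], nrow = nx))
    lo <- mean(sums <= rx + 1e-9)
    hi <- mean(sums >= rx - 1e-9)
    p_exact <- min(1, 2 * min(lo, hi))
  }
  # tie-corrected normal approximation
  mu <- nx * ny / 2
  ties <- table(r)
  sig2 <- nx * ny / 12 *
    ((nx + ny + 1) - sum(ties^3 - ties) / ((nx + ny) * (nx + ny - 1)))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
  p_asym <- min(1, 2 * pnorm(-abs(z)))
  use_exact <- !is.na(p_exact)
  list(U = U, p = if (use_exact) p_exact else p_asym,
       p_exact = p_exact, p_asymptotic = p_asym,
       method = if (use_exact) "exact" else "normal approximation")
}

#' Percent difference versus a control mean
#'
#' 100 * (treated - control) / control. `percent_difference_rounded` applies
#' the report convention (integer percent, half away from zero).
#'
#' @param mean_treated,mean_control group means
#' @return percent difference (numeric)
#' @export
percent_difference <- function(mean_treated, mean_control) {
  100 * (mean_treated - mean_control) / mean_control
}

#' @rdname percent_difference
#' @export
percent_difference_rounded <- function(mean_treated, mean_control) {
  round_half_away(percent_difference(mean_treated, mean_control))
}

#' Group comparison table (means, SD, percent difference, exact WMW p)
#'
#' One row per outcome, mirroring the familiar phenotyping-table layout:
#' control mean +/- SD, treated mean +/- SD, integer percent difference and
#' the exact rank-test p-value.
#'
#' @param data data.frame with one row per specimen
#' @param outcomes character vector of outcome column names
#' @param group name of the two-level grouping column
#' @param control level regarded as control
#' @return data.frame
#' @export
group_comparison <- function(data, outcomes, group, control) {
  g <- as.character(data[[group]])
  lv <- unique(g)
  if (length(lv) != 2L) stop_bonemech("group must have exactly two levels")
  treated <- setdiff(lv, control)
  out <- lapply(outcomes, function(o) {
    xc <- data[[o]][g == control]; xt <- data[[o]][g == treated]
    xc <- xc[!is.na(xc)]; xt <- xt[!is.na(xt)]
    w <- wmw_test(xt, xc)
    data.frame(outcome = o,
               control_mean = mean(xc), control_sd = sd(xc),
               treated_mean = mean(xt), treated_sd = sd(xt),
               n_control = length(xc), n_treated = length(xt),
               percent_difference = percent_difference_rounded(mean(xt),
                                                               mean(xc)),
               percent_difference_raw = percent_difference(mean(xt),
                                                           mean(xc)),
               U = w$U, p = w$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Nested linear mixed model for repeated tissue-level measures
#'
#' REML fit (via lme4) of an outcome on fixed factors with nested random
#' intercepts reflecting the physical sampling hierarchy
#' mouse / quadrant / cortex-region (multiple indents or spectra per
#' region). Residual normality is summarized by the Q-Q quantile
#' correlation and homoscedasticity by a Levene test of the residuals
#' across the first fixed factor.
#'
#' @param data long-format data.frame
#' @param outcome outcome column name
#' @param fixed character vector of fixed-effect column names
#' @param random character vector of nesting levels, outermost first
#'   (default c("mouse", "quadrant", "region"))
#' @return object of class `lmm_fit`: list(model, fixed (estimate, SE),
#'   varcomp, logLik, qq_correlation, levene_p, data, outcome, formula)
#' @export
fit_lmm <- function(data, outcome, fixed,
                    random = c("mouse", "quadrant", "region")) {
  for (f in fixed)
    if (length(unique(data[[f]])) < 2L)
      stop_bonemech("fixed factor ", f, " needs >= 2 levels")
  terms <- character(0)
  for (k in seq_along(random)) {
    grp <- paste(random[seq_len(k)], collapse = ":")
    terms <- c(terms, sprintf("(1 | %s)", grp))
  }
  fml <- as.formula(paste(outcome, "~", paste(fixed, collapse = " + "), "+",
                          paste(terms, collapse = " + ")))
  fit <- suppressMessages(lme4::lmer(fml, data = data, REML = TRUE))
  sm <- summary(fit)
  fe <- data.frame(term = rownames(sm$coefficients),
                   estimate = sm$coefficients[, "Estimate"],
                   se = sm$coefficients[, "Std. Error"],
                   t = sm$coefficients[, "t value"],
                   row.names = NULL, stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  res <- residuals(fit)
  qq <- cor(sort(res), qnorm(ppoints(length(res))))
  lev <- tryCatch(
    levene_test(res, data[[fixed[1]]])$p, error = function(e) NA_real_)
  structure(list(model = fit, fixed = fe, varcomp = vc,
                 logLik = as.numeric(logLik(fit)),
                 singular = lme4::isSingular(fit),
                 qq_correlation = qq, levene_p = lev,
                 data = data, outcome = outcome, formula = fml,
                 fixed_factors = fixed, random_levels = random),
            class = "lmm_fit")
}

#' Confidence interval for a fixed effect with containment df
#'
#' Wald-type t interval; degrees of freedom are containment-style: for a
#' factor varying at the mouse level (e.g. genotype) df = n_mice - p_between
#' where p_between counts mouse-level fixed parameters.
#'
#' @param fit an `lmm_fit`
#' @param term coefficient name (e.g. "genotypeTallyHO")
#' @param level confidence level (default 0.95)
#' @param df optional override for the degrees of freedom
#' @return c(lower, upper, estimate, se, df)
#' @export
lmm_confint <- function(fit, term, level = 0.95, df = NULL) {
  fe <- fit$fixed
  i <- match(term, fe$term)
  if (is.na(i)) stop_bonemech("no fixed-effect term ", term)
  if (is.null(df)) {
    n_mice <- length(unique(fit$data[[fit$random_levels[1]]]))
    df <- max(2, n_mice - 2)
  }
  a <- 1 - level
  hw <- qt(1 - a / 2, df) * fe$se[i]
  c(lower = fe$estimate[i] - hw, upper = fe$estimate[i] + hw,
    estimate = fe$estimate[i], se = fe$se[i], df = df)
}

#' Tukey HSD comparisons for a fixed factor of a mixed model
#'
#' All pairwise level contrasts with studentized-range adjusted p-values:
#' q = sqrt(2) |diff| / SE_diff referred to the studentized range
#' distribution with the number of factor levels and residual df. For a
#' two-level factor this reduces exactly to the unadjusted t-test.
#'
#' @param fit an `lmm_fit`
#' @param factor name of the fixed factor
#' @return data.frame(contrast, estimate, se, q, df, p_adj)
#' @export
tukey_hsd <- function(fit, factor) {
  if (!factor %in% fit$fixed_factors)
    stop_bonemech(factor, " is not a fixed factor of the fit")
  mod <- fit$model
  dat <- fit$data
  levs <- levels(as.factor(dat[[factor]]))
  k <- length(levs)
  if (k < 2L) stop_bonemech("factor has < 2 levels")
  beta <- lme4::fixef(mod)
  V <- as.matrix(vcov(mod))
  # contrast vectors in coefficient space: treatment coding, no interactions
  cvec <- function(lv) {
    v <- setNames(numeric(length(beta)), names(beta))
    nm <- paste0(factor, lv)
    if (nm %in% names(v)) v[nm] <- 1
    v
  }
  n <- nrow(dat)
  df <- n - length(beta)
  out <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ci <- cvec(levs[j]) - cvec(levs[i])
    est <- sum(ci * beta)
    se <- sqrt(drop(t(ci) %*% V %*% ci))
    q <- sqrt(2) * abs(est) / se
    p <- ptukey(q, k, df, lower.tail = FALSE)
    out[[length(out) + 1]] <- data.frame(
      contrast = paste(levs[j], "-", levs[i]), estimate = est, se = se,
      q = q, df = df, p_adj = p, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Levene test of homoscedasticity (mean-centered)
#'
#' W statistic on absolute deviations from the group means, referred to an
#' F distribution with (k - 1, N - k) df.
#'
#' @param values numeric vector
#' @param groups group labels
#' @return list(W, df1, df2, p)
#' @export
levene_test <- function(values, groups) {
  groups <- as.factor(groups)
  k <- nlevels(droplevels(groups))
  if (k < 2L) stop_bonemech("Levene test needs >= 2 groups")
  z <- abs(values - ave(values, groups, FUN = mean))
  zbar <- mean(z)
  zg <- tapply(z, groups, mean)
  ng <- tapply(z, groups, length)
  num <- sum(ng * (zg - zbar)^2) / (k - 1)
  den <- sum((z - ave(z, groups, FUN = mean))^2) / (length(z) - k)
  W <- if (den == 0) 0 else num / den
  p <- if (den == 0) 1 else pf(W, k - 1, length(z) - k, lower.tail = FALSE)
  list(W = W, df1 = k - 1, df2 = length(z) - k, p = p)
}

#' Simple linear regression with slope test
#'
#' @param x,y numeric vectors
#' @return list(slope, intercept, r, R2, p, n); degenerate n = 2 fits warn
#' @export
linreg <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L) stop_bonemech("need >= 2 points")
  if (n == 2L) warning("n = 2: R^2 = 1 is degenerate")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  p <- if (n > 2) sm$coefficients[2, 4] else NA_real_
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r = sign(coef(fit)[2]) * sqrt(sm$r.squared), R2 = sm$r.squared,
       p = p, n = n)
}

#' ANCOVA test of slope equality between two groups
#'
#' p-value of the group x covariate interaction in y ~ x * group.
#'
#' @param x covariate
#' @param y response
#' @param group two-level grouping
#' @return list(interaction_estimate, se, p, slopes)
#' @export
ancova_slopes <- function(x, y, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L)
    stop_bonemech("group must have exactly two levels")
  if (any(table(group) < 3L))
    stop_bonemech("each group needs >= 3 points")
  fit <- lm(y ~ x * group)
  sm <- summary(fit)$coefficients
  row <- grep(":", rownames(sm))
  slopes <- vapply(levels(group), function(g)
    unname(coef(lm(y[group == g] ~ x[group == g]))[2]), 0)
  list(interaction_estimate = sm[row, 1], se = sm[row, 2], p = sm[row, 4],
       slopes = slopes)
}

#' Small-sample corrected AIC
#'
#' AICc = AIC + 2k(k+1)/(n-k-1) with k the number of estimated parameters
#' including the intercept and the error variance.
#'
#' @param fit an `lm` fit
#' @return AICc value
#' @export
aicc <- function(fit) {
  n <- length(residuals(fit))
  k <- attr(logLik(fit), "df")          # coefficients + sigma
  if (n - k - 1 <= 0) return(Inf)
  AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
}

#' Backward stepwise selection by AICc
#'
#' Starts from the full candidate set and removes, at each step, the
#' predictor whose removal lowers AICc the most; stops when no removal
#' lowers AICc. Exact ties are broken in favour of the smaller model.
#'
#' @param data data.frame
#' @param response response column name
#' @param candidates character vector of candidate predictor columns
#' @return list(selected, coefficients, R2, aicc, trace, model)
#' @export
stepwise_aicc <- function(data, response, candidates) {
  current <- candidates
  make_fit <- function(preds) {
    rhs <- if (length(preds)) paste(preds, collapse = " + ") else "1"
    lm(as.formula(paste(response, "~", rhs)), data = data)
  }
  fit <- make_fit(current)
  best <- aicc(fit)
  trace <- data.frame(step = 0L, action = "start",
                      model = paste(current, collapse = "+"),
                      aicc = best, stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    if (length(current) == 0L) break
    cand_aicc <- vapply(current, function(p)
      aicc(make_fit(setdiff(current, p))), 0)
    if (min(cand_aicc) <= best + 1e-10) {   # ties -> smaller model
      drop <- names(cand_aicc)[which.min(cand_aicc)]
      current <- setdiff(current, drop)
      fit <- make_fit(current)
      best <- aicc(fit)
      step <- step + 1L
      trace <- rbind(trace, data.frame(
        step = step, action = paste("drop", drop),
        model = paste(if (length(current)) current else "1", collapse = "+"),
        aicc = best, stringsAsFactors = FALSE))
    } else break
  }
  list(selected = current, coefficients = coef(fit),
       R2 = summary(fit)$r.squared, aicc = best, trace = trace, model = fit)
}

#' Lifetime-average blood glucose
#'
#' Arithmetic mean of the available weekly values over the study period;
#' missing weeks are skipped and counted.
#'
#' @param weekly numeric vector of weekly glucose values, mg/dL
#' @return list(mean, n_used, n_missing)
#' @export
lifetime_average_glucose <- function(weekly) {
  ok <- !is.na(weekly)
  if (!any(ok)) stop_bonemech("all weekly glucose values are missing")
  list(mean = mean(weekly[ok]), n_used = sum(ok), n_missing = sum(!ok))
}

#' Filter diabetic-group mice by minimum weekly glucose
#'
#' Diabetic-strain mice that did not maintain a minimum non-fasting glucose
#' above the threshold (default 250 mg/dL) over the study are excluded;
#' control mice are never filtered.
#'
#' @param mice data.frame with columns mouse, genotype
#' @param glucose data.frame with columns mouse, week, glucose
#' @param threshold mg/dL (default 250)
#' @param diabetic_strain genotype label the rule applies to
#' @return filtered `mice` data.frame (attribute "excluded" lists removals)
#' @export
diabetic_inclusion_filter <- function(mice, glucose, threshold = 250,
                                      diabetic_strain = "TallyHO") {
  mins <- tapply(glucose$glucose, glucose$mouse, min, na.rm = TRUE)
  bad <- names(mins)[mins <= threshold]
  drop <- mice$genotype == diabetic_strain & mice$mouse %in% bad
  out <- mice[!drop, , drop = FALSE]
  attr(out, "excluded") <- mice$mouse[drop]
  out
}
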