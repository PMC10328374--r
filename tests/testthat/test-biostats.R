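# statistical layer

test_that("wmw_test: exact enumeration, symmetry, separated groups", {
  # fully separated 5 vs 8: two-sided exact p = 2/C(13,5)
  w <- wmw_test(11:18, 1:5)
  expect_equal(w$p, 2 / choose(13, 5), tolerance = 1e-12)
  expect_identical(w$method, "exact")
  expect_equal(wmw_test(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # matches the independent enumeration oracle exactly (with and without ties)
  set.seed(11)
  for (k in 1:40) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- sample(1:8, nx, replace = TRUE)   # ties likely
    y <- sample(1:8, ny, replace = TRUE)
    expect_equal(wmw_test(x, y)$p, wmw_enumeration_oracle(x, y),
                 tolerance = 1e-12)
  }
  expect_error(wmw_test(1, 1:4), ">= 2")
})

test_that("percent_difference: worked table values and rounding convention", {
  expect_equal(percent_difference_rounded(354.50, 236.50), 50)
  expect_equal(percent_difference_rounded(9.90, 5.00), 98)
  expect_equal(percent_difference(5, 5), 0)
  # half away from zero, both signs
  expect_equal(round_half_away(c(0.5, -0.5, 2.5, -2.5)), c(1, -1, 3, -3))
})

test_that("group_comparison mirrors the phenotyping table layout", {
  co <- gen_cohort(cohort_spec(seed = 21))
  tab <- group_comparison(co$mice, c("Tt.Ar", "BV_TV", "HbA1c"),
                          "genotype", "C57Bl/6J")
  expect_equal(nrow(tab), 3)
  expect_true(all(c("percent_difference", "U", "p") %in% names(tab)))
  expect_true(all(tab$p > 0 & tab$p <= 1))
  # sign of the percent difference matches the mean ordering
  expect_equal(sign(tab$percent_difference_raw),
               sign(tab$treated_mean - tab$control_mean))
})

test_that("fit_lmm: collapse to OLS, balanced-design identity, diagnostics", {
  co <- gen_cohort(cohort_spec(
    hierarchy_cv = c(mouse = 0, quadrant = 0, region = 0, residual = 0.05),
    seed = 8))
  fit <- suppressWarnings(suppressMessages(
    fit_lmm(co$tissue, "mineral_matrix", fixed = c("genotype", "quadrant"))))
  ols <- lm(mineral_matrix ~ genotype + quadrant, data = co$tissue)
  i <- match("genotypeTallyHO", fit$fixed$term)
  expect_equal(fit$fixed$estimate[i], unname(coef(ols)["genotypeTallyHO"]),
               tolerance = 1e-3)
  expect_true(is.finite(fit$qq_correlation))
  expect_gt(fit$qq_correlation, 0.95)
  # balanced two-group design, genotype only, zero variance components:
  # estimate equals the difference of group means
  d <- data.frame(mouse = rep(sprintf("m%d", 1:6), each = 4),
                  genotype = rep(c("a", "b"), each = 12),
                  quadrant = "AL", region = "endosteal",
                  y = rep(c(1, 3), each = 12))
  d$y <- d$y + rep(rnorm(6, 0, 1e-8), each = 4)
  fit2 <- suppressWarnings(suppressMessages(
    fit_lmm(d, "y", fixed = "genotype", random = "mouse")))
  expect_equal(fit2$fixed$estimate[2],
               mean(d$y[d$genotype == "b"]) - mean(d$y[d$genotype == "a"]),
               tolerance = 1e-6)
  expect_error(fit_lmm(d[d$genotype == "a", ], "y", fixed = "genotype"),
               ">= 2 levels")
})

test_that("tukey_hsd: two-level identity with t test, null behaviour", {
  co <- gen_cohort(cohort_spec(seed = 13))
  fit <- fit_lmm(co$tissue, "E_s_GPa",
                 fixed = c("genotype", "quadrant", "region"))
  tk <- tukey_hsd(fit, "genotype")
  # q = t sqrt(2) identity: ptukey(.,2,df) == 2 pt(.)
  i <- match("genotypeTallyHO", fit$fixed$term)
  tstat <- abs(fit$fixed$estimate[i] / fit$fixed$se[i])
  expect_equal(tk$p_adj,
               2 * pt(tstat, tk$df, lower.tail = FALSE), tolerance = 1e-6)
  tr <- tukey_hsd(fit, "region")
  expect_equal(nrow(tr), 3)
  # identical groups (same values in every level): adjusted p = 1
  set.seed(5)
  base_y <- rnorm(24)
  d <- data.frame(mouse = rep(sprintf("m%d", 1:12), each = 6),
                  genotype = "a",
                  grp = rep(c("x", "y", "z"), 24),
                  quadrant = rep(c("AL", "PM"), each = 3),
                  y = rep(base_y, each = 3))   # identical across grp levels
  fit0 <- suppressWarnings(suppressMessages(
    fit_lmm(d, "y", fixed = c("grp"), random = "mouse")))
  t0 <- tukey_hsd(fit0, "grp")
  expect_true(all(t0$p_adj > 0.99))
})

test_that("levene_test: degenerate and powered cases", {
  expect_equal(levene_test(rep(c(1, 2, 3), 2), rep(1:2, each = 3))$W, 0)
  hits <- vapply(1:100, function(k) {
    set.seed(6000 + k)
    levene_test(c(rnorm(50, 0, 1), rnorm(50, 0, 3)),
                rep(1:2, each = 50))$p < 0.01
  }, NA)
  expect_gte(sum(hits), 95)
  expect_error(levene_test(rnorm(5), rep(1, 5)), ">= 2 groups")
})

test_that("linreg: exact line, null slope coverage, degenerate n", {
  r <- suppressWarnings(linreg(1:10, 2 * (1:10) + 1))  # perfect-fit warning
  expect_equal(r$R2, 1, tolerance = 1e-12)
  expect_lt(r$p, 1e-10)
  # calibration of the 2-SE band under the null: the empirical frequency
  # must sit within 3 binomial SEs of the exact t-probability
  nrep <- 200
  within2se <- vapply(seq_len(nrep), function(k) {
    set.seed(1000 + k)
    x <- rnorm(100); y <- rnorm(100)
    fit <- lm(y ~ x)
    abs(coef(fit)[2]) < 2 * summary(fit)$coefficients[2, 2]
  }, NA)
  p0 <- 2 * pt(2, df = 98) - 1
  expect_lt(abs(mean(within2se) - p0), 3 * sqrt(p0 * (1 - p0) / nrep))
  expect_warning(r2 <- linreg(c(1, 2), c(3, 5)), "degenerate")
  expect_equal(r2$R2, 1)
})

test_that("ancova_slopes: null and strong interaction, input guard", {
  set.seed(2)
  est_over_se <- vapply(1:50, function(k) {
    x <- rnorm(60); g <- rep(c("a", "b"), 30)
    y <- 2 * x + rnorm(60, 0, 0.5)
    a <- ancova_slopes(x, y, g)
    abs(a$interaction_estimate / a$se)
  }, 0)
  expect_gt(mean(est_over_se < 2), 0.9)
  x <- rnorm(60); g <- rep(c("a", "b"), 30)
  y <- ifelse(g == "a", x, 3 * x) + rnorm(60, 0, 0.3)
  expect_lt(ancova_slopes(x, y, g)$p, 0.01)
  expect_error(ancova_slopes(c(1, 2, 3, 4), c(1, 2, 3, 4),
                             c("a", "a", "a", "b")), ">= 3")
})

test_that("aicc formula and large-n limit", {
  set.seed(3)
  d <- data.frame(x = rnorm(30))
  d$y <- 1 + d$x + rnorm(30)
  fit <- lm(y ~ x, data = d)
  k <- attr(logLik(fit), "df")
  expect_equal(aicc(fit), AIC(fit) + 2 * k * (k + 1) / (30 - k - 1),
               tolerance = 1e-12)
  dn <- data.frame(x = rnorm(1e5))
  dn$y <- dn$x + rnorm(1e5)
  fitn <- lm(y ~ x, data = dn)
  expect_lt(aicc(fitn) - AIC(fitn), 0.01)
})

test_that("stepwise_aicc: true-pair recovery, noise behaviour, trace invariant", {
  sel <- vapply(1:100, function(k) {
    set.seed(9000 + k)
    n <- 13
    d <- data.frame(crystallinity = rnorm(n, 0.058, 0.0011),
                    collagen_maturity = rnorm(n, 1.65, 0.105),
                    carbonate_phosphate = rnorm(n, 0.175, 0.01),
                    mineral_matrix = rnorm(n, 0.70, 0.04),
                    pen_ratio = rnorm(n, 0.30, 0.03))
    sig <- sqrt((124.73^2 * 0.0011^2 + 1.3^2 * 0.105^2) * 0.17 / 0.83)
    d$pyd <- 0.97 - 124.73 * d$crystallinity - 1.3 * d$collagen_maturity +
      rnorm(n, 0, sig)
    r <- stepwise_aicc(d, "pyd", names(d)[1:5])
    setequal(r$selected, c("crystallinity", "collagen_maturity"))
  }, NA)
  expect_gte(sum(sel), 80)
  # pure noise at the small-n study scale: intercept-only in the majority
  none <- vapply(1:100, function(k) {
    set.seed(500 + k)
    d <- as.data.frame(matrix(rnorm(10 * 5), 10, 5))
    names(d) <- paste0("x", 1:5)
    d$y <- rnorm(10)
    length(stepwise_aicc(d, "y", paste0("x", 1:5))$selected) == 0
  }, NA)
  expect_gt(sum(none), 50)
  # AICc of the selected model is minimal over the visited trace
  set.seed(77)
  d <- as.data.frame(matrix(rnorm(15 * 4), 15, 4))
  names(d) <- paste0("x", 1:4)
  d$y <- d$x1 + rnorm(15, 0, 0.5)
  r <- stepwise_aicc(d, "y", paste0("x", 1:4))
  expect_equal(r$aicc, min(r$trace$aicc))
})

test_that("selection frequency of the true pair is non-decreasing from n = 10 to 13", {
  freq <- vapply(c(10, 13), function(n) {
    sum(vapply(1:60, function(k) {
      set.seed(8000 + k)
      d <- data.frame(crystallinity = rnorm(n, 0.058, 0.0011),
                      collagen_maturity = rnorm(n, 1.65, 0.105),
                      carbonate_phosphate = rnorm(n, 0.175, 0.01),
                      mineral_matrix = rnorm(n, 0.70, 0.04),
                      pen_ratio = rnorm(n, 0.30, 0.03))
      sig <- sqrt((124.73^2 * 0.0011^2 + 1.3^2 * 0.105^2) * 0.17 / 0.83)
      d$pyd <- 0.97 - 124.73 * d$crystallinity -
        1.3 * d$collagen_maturity + rnorm(n, 0, sig)
      setequal(stepwise_aicc(d, "pyd", names(d)[1:5])$selected,
               c("crystallinity", "collagen_maturity"))
    }, NA))
  }, 0)
  expect_gte(freq[2], freq[1])
})

test_that("lifetime glucose and the diabetic inclusion filter", {
  expect_equal(lifetime_average_glucose(rep(200, 16))$mean, 200)
  expect_equal(lifetime_average_glucose(seq(100, 250, by = 10))$mean, 175)
  g <- c(NA, 150, NA, 250)
  r <- lifetime_average_glucose(g)
  expect_equal(r$mean, 200)
  expect_equal(r$n_missing, 2)
  expect_error(lifetime_average_glucose(c(NA, NA)), "missing")

  mice <- data.frame(mouse = sprintf("m%d", 1:12),
                     genotype = rep(c("TallyHO", "C57Bl/6J"), c(10, 2)),
                     stringsAsFactors = FALSE)
  gl <- expand.grid(mouse = mice$mouse, week = 1:16,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gl$glucose <- 400
  gl$glucose[gl$mouse %in% c("m3", "m7") & gl$week == 5] <- 240
  gl$glucose[gl$mouse == "m11"] <- 100          # control below threshold
  kept <- diabetic_inclusion_filter(mice, gl)
  expect_equal(sum(kept$genotype == "TallyHO"), 8)
  expect_true(all(c("m11", "m12") %in% kept$mouse))  # controls untouched
  expect_setequal(attr(kept, "excluded"), c("m3", "m7"))
  kept0 <- diabetic_inclusion_filter(mice, gl, threshold = 0)
  expect_equal(nrow(kept0), 12)
})

test_that("mass adjustment preserves percent differences when mass is uninformative", {
  set.seed(9)
  n <- 40
  strain <- rep(c("c", "t"), each = n)
  mass <- c(rnorm(n, 34, 3), rnorm(n, 39, 5))
  y <- ifelse(strain == "c", 10, 13) + rnorm(2 * n, 0, 0.5)  # no mass link
  adj <- mass_adjust(y, mass, strain)
  pd_raw <- percent_difference(mean(y[strain == "t"]),
                               mean(y[strain == "c"]))
  pd_adj <- percent_difference(mean(adj[strain == "t"]),
                               mean(adj[strain == "c"]))
  expect_equal(pd_adj, pd_raw, tolerance = 0.05)
})
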