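test_that("CI screen uses the published critical values and strict flags", {
  # z constants
  expect_equal(unname(mutscreen:::CI_Z), c(1.96, 2.575, 3.3))
  res <- ci_screen(c(a = 10, b = 9.8, c = -10), sigma_P = 10, n_reps = 4,
                   levels = 0.95)
  expect_equal(res$half_width_95, rep(9.8, 3))
  expect_equal(res$flag_95, c(TRUE, FALSE, TRUE))   # tie is not significant
  expect_equal(res$direction_95, c("increased", "ns", "decreased"))
  expect_error(ci_screen(1, sigma_P = 0, n_reps = 2), "> 0")
})

test_that("CI flags are nested across confidence levels", {
  set.seed(14)
  dev <- rnorm(500, 0, 8)
  res <- ci_screen(dev, sigma_P = 6, n_reps = 4)
  expect_true(all(res$flag_999 <= res$flag_99))
  expect_true(all(res$flag_99 <= res$flag_95))
})

test_that("Dunnett with one comparison reduces to the two-sample t-test", {
  set.seed(8)
  vm <- data.frame(line = rep(c("CTRL", "L1"), each = 6), sex = "male",
                   vial = 1:6, mean_lifespan = rnorm(12, 50, 5))
  res <- dunnett_test(vm, "CTRL", sex = "male")
  tt <- t.test(mean_lifespan ~ line, data = vm, var.equal = TRUE)
  expect_equal(res$p_adjusted, tt$p.value, tolerance = 1e-10)
  expect_equal(res$p_adjusted, res$p_unadjusted)
})

test_that("Dunnett adjusted P matches the multcomp implementation", {
  skip_if_not_installed("multcomp")
  set.seed(3)
  vm <- data.frame(line = rep(c("CTRL", "A", "B", "D"), each = 5),
                   sex = "male", vial = 1:5,
                   mean_lifespan = rnorm(20, 50, 4))
  vm$mean_lifespan[vm$line == "B"] <- vm$mean_lifespan[vm$line == "B"] + 6
  res <- dunnett_test(vm, "CTRL", sex = "male", seed = 5)
  fit <- stats::aov(mean_lifespan ~ line,
                    data = transform(vm, line = relevel(factor(line),
                                                        "CTRL")))
  g <- summary(multcomp::glht(fit, linfct = multcomp::mcp(line = "Dunnett")))
  expect_equal(sort(res$p_adjusted), sort(as.numeric(g$test$pvalues)),
               tolerance = 5e-3)
})

test_that("Dunnett adjusted P matches a max-|t| Monte-Carlo oracle", {
  set.seed(6)
  vm <- data.frame(line = rep(c("CTRL", "A", "B", "D"), each = 4),
                   sex = "male", vial = 1:4,
                   mean_lifespan = rnorm(16, 50, 3))
  res <- dunnett_test(vm, "CTRL", sex = "male", seed = 2)
  # oracle: simulate the joint null law of the three t statistics
  ns <- c(4, 4, 4); n0 <- 4
  df <- 16 - 4
  lambda <- sqrt(ns / (ns + n0))
  corr <- outer(lambda, lambda); diag(corr) <- 1
  set.seed(1000)
  B <- 2e5
  Z <- MASS::mvrnorm(B, mu = rep(0, 3), Sigma = corr)
  S <- sqrt(rchisq(B, df) / df)
  maxt <- apply(abs(Z / S), 1, max)
  for (k in seq_len(nrow(res))) {
    p_mc <- mean(maxt >= abs(res$t[k]))
    expect_equal(res$p_adjusted[k], p_mc, tolerance = 0.01)
  }
})

test_that("Dunnett familywise P is never below the unadjusted P", {
  set.seed(44)
  vm <- data.frame(line = rep(c("CTRL", paste0("L", 1:6)), each = 4),
                   sex = "male", vial = 1:4,
                   mean_lifespan = rnorm(28, 50, 4))
  res <- dunnett_test(vm, "CTRL", sex = "male")
  expect_true(all(res$p_adjusted >= res$p_unadjusted))
  expect_error(dunnett_test(vm, "NOPE", sex = "male"), "absent")
})

test_that("standardized mutational effects follow the a/sigma_P convention", {
  e <- mutational_effect(60, 50, 10)
  expect_equal(c(e$percent, e$a, e$a_over_sigmaP), c(20, 5, 0.5))
  e0 <- mutational_effect(50, 50, 10)
  expect_equal(c(e0$percent, e0$a, e0$a_over_sigmaP), c(0, 0, 0))
  en <- mutational_effect(45, 50, 10)
  expect_equal(c(en$percent, en$a, en$a_over_sigmaP), c(-10, -2.5, -0.25))
  expect_error(mutational_effect(50, 0, 10), "> 0")
  expect_error(mutational_effect(50, 50, 0), "> 0")
})

test_that("sex-effect classifier reproduces the published 58-line categories", {
  fx <- read.csv(system.file("extdata", "longlived_line_classifications.csv",
                             package = "mutscreen"),
                 stringsAsFactors = FALSE)
  expect_equal(nrow(fx), 58)
  got <- vapply(seq_len(nrow(fx)), function(i) {
    classify_sex_effect(
      significance_code_p(fx$p_line[i]),
      significance_code_p(fx$p_line_sex[i]),
      significance_code_p(fx$p_line_male[i]),
      significance_code_p(fx$p_line_female[i]),
      effect_male = fx$pct_male[i], effect_female = fx$pct_female[i])
  }, character(1))
  expect_equal(got, fx$category)
  # published marginal counts
  expect_equal(sum(got == "both sexes"), 17)
  expect_equal(sum(got == "male-specific"), 22)
  expect_equal(sum(got == "female-specific"), 9)
  expect_equal(sum(got == "sex-antagonistic"), 6)
  expect_equal(sum(got == "male-biased"), 2)
  expect_equal(sum(got == "female-biased"), 2)
})

test_that("classifier is symmetric under swapping the sexes", {
  set.seed(23)
  swap_lab <- function(x) {
    x <- sub("^male", "TMP", x); x <- sub("^female", "male", x)
    sub("^TMP", "female", x)
  }
  for (i in 1:200) {
    p <- runif(4)
    em <- rnorm(1); ef <- rnorm(1)
    a <- classify_sex_effect(p[1], p[2], p[3], p[4],
                             effect_male = em, effect_female = ef)
    b <- classify_sex_effect(p[1], p[2], p[4], p[3],
                             effect_male = ef, effect_female = em)
    expect_equal(b, swap_lab(a))
  }
  expect_error(classify_sex_effect(1.2, 0.5, 0.5, 0.5), "\\[0, 1\\]")
})

test_that("tukey letters: trivial cases behave as expected", {
  same <- tukey_letters(c(a = 50, b = 50, c = 50), 5, 10, 20)
  expect_true(all(same$letters == same$letters[1]))
  se_gap <- tukey_letters(c(lo = 50, hi = 50 + 10 * sqrt(10 / 5)), 5, 10, 20)
  expect_true(se_gap$letters[1] != se_gap$letters[2])
  expect_error(tukey_letters(c(a = 1, b = 2), 3, 0, 10), "degenerate")
})

test_that("tukey letter partition matches the multcomp compact display", {
  skip_if_not_installed("multcomp")
  set.seed(31)
  g <- factor(rep(c("ctrl", "mut", "rev1", "rev3"), each = 8))
  y <- c(rnorm(8, 50, 3), rnorm(8, 60, 3), rnorm(8, 51, 3), rnorm(8, 55, 3))
  fit <- stats::aov(y ~ g)
  ms_err <- summary(fit)[[1]]["Residuals", "Mean Sq"]
  mine <- tukey_letters(tapply(y, g, mean), 8, ms_err,
                        df_error = fit$df.residual)
  cld <- multcomp::cld(multcomp::glht(fit, linfct = multcomp::mcp(g = "Tukey")))
  share <- function(letts) outer(letts, letts, Vectorize(function(x, y)
    length(intersect(strsplit(x, "")[[1]], strsplit(y, "")[[1]])) > 0))
  expect_equal(unname(share(mine$letters)),
               unname(share(cld$mcletters$Letters[mine$group])))
})

test_that("tukey letters match an exhaustive pairwise-test oracle", {
  set.seed(77)
  for (rep in 1:20) {
    k <- 4
    means <- rnorm(k, 50, 6)
    names(means) <- paste0("g", 1:k)
    n <- 6; ms <- 9; dfe <- k * (n - 1)
    res <- tukey_letters(means, n, ms, dfe)
    # oracle: recompute every pairwise studentized-range P directly
    pm <- attr(res, "p_matrix")
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      q <- abs(means[[i]] - means[[j]]) / sqrt(ms / n)
      expect_equal(unname(pm[i, j]),
                   ptukey(q, k, dfe, lower.tail = FALSE),
                   tolerance = 1e-12)
    }
    # groups share a letter iff they are not significantly different
    sig <- pm < 0.05
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      shared <- length(intersect(strsplit(res$letters[i], "")[[1]],
                                 strsplit(res$letters[j], "")[[1]])) > 0
      expect_equal(shared, !sig[i, j])
    }
  }
})

test_that("verdict combiner honours union and intersection rules", {
  ci <- c(TRUE, TRUE, FALSE, FALSE)
  dp <- c(0.01, 0.5, 0.01, NA)
  dev <- c(3, -3, 3, -3)
  expect_equal(combine_screen_verdicts(ci, dp, dev),
               c("increased", "decreased", "increased", "ns"))
  expect_equal(combine_screen_verdicts(ci, dp, dev,
                                       method = "intersection"),
               c("increased", "ns", "ns", "ns"))
})

test_that("confirmation rate reproduces screen bookkeeping percentages", {
  expect_equal(confirmation_rate(58, 1332), 4.4)
  expect_equal(confirmation_rate(58, 83, digits = 0), 70)
})

test_that("full screen pipeline flags a planted long-lived line", {
  p <- screen_sim_params(n_lines = 20, sigma2_line = 0, sigma2_line_sex = 0,
                         sigma2_vial = 4, sigma2_error = 25,
                         vials_per_sex = 6, seed = 55)
  sim <- simulate_screen(p)
  rec <- as.data.frame(sim$records)
  rec$line[rec$line == "L0001"] <- "CTRL"
  rec$death_age[rec$line == "L0002"] <- rec$death_age[rec$line == "L0002"] + 12
  res <- screen_lines(rec, "CTRL")
  expect_s3_class(res, "screen_result")
  hit <- res[res$line == "L0002", ]
  expect_true(hit$flag_95_pooled)
  expect_equal(hit$direction_95_pooled, "increased")
  expect_lt(hit$p_dunnett_male, 0.05)
  expect_gt(hit$percent, 5)
  # most null lines are unflagged
  expect_lt(mean(res$flag_95_pooled[res$line != "L0002"]), 0.4)
})
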