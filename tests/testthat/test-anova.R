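test_that("anova_table applies the error-MS denominator convention", {
  tab <- anova_table(c("Sex", "Line", "Line:Sex", "Error"),
                     df = c(1, 1331, 1312, 3301),
                     ms = c(274.89, 241.89, 101.56, 45.02))
  f <- setNames(tab$f, tab$source)
  expect_equal(round(f[["Line"]], 2), 5.37)
  expect_equal(round(f[["Line:Sex"]], 2), 2.26)
  expect_equal(round(f[["Sex"]], 2), 6.11)
  expect_true(all(tab$p[tab$source %in% c("Line", "Line:Sex")] < 1e-4))
  # one-way layouts
  tabm <- anova_table(c("Line", "Error"), c(1321, 1643), c(164.50, 34.60))
  tabf <- anova_table(c("Line", "Error"), c(1322, 1658), c(180.11, 55.36))
  expect_equal(round(tabm$f[1], 2), 4.75)
  expect_equal(round(tabf$f[1], 2), 3.25)
})

test_that("balanced two-factor components equal the closed-form EMS solution", {
  vm <- balanced_vm(a = 15, r = 3, seed = 8)
  fit <- suppressWarnings(two_factor_mixed_anova(vm))
  tab <- fit$anova
  ms <- setNames(tab$ms, tab$source)
  r <- 3; b <- 2
  s_e <- ms[["Error"]]
  s_ls <- (ms[["Line:Sex"]] - ms[["Error"]]) / r
  s_l <- (ms[["Line"]] - ms[["Line:Sex"]]) / (r * b)
  expect_equal(fit$components$sigma2_error, unname(s_e), tolerance = 1e-10)
  expect_equal(fit$components$sigma2_line_sex, unname(max(s_ls, 0)),
               tolerance = 1e-10)
  expect_equal(fit$components$sigma2_line, unname(max(s_l, 0)),
               tolerance = 1e-10)
  # EMS coefficients are the textbook ones for the balanced layout
  expect_equal(unname(fit$ems["Line", ]), c(r * b, r, 1), tolerance = 1e-9)
  expect_equal(unname(fit$ems["Line:Sex", c(2, 3)]), c(r, 1),
               tolerance = 1e-9)
})

test_that("synthesis EMS coefficients match a dense projection-matrix oracle", {
  set.seed(21)
  vm <- balanced_vm(a = 8, r = 3, seed = 21)
  vm <- vm[-sample(nrow(vm), 9), ]          # make it unbalanced
  fit <- suppressWarnings(two_factor_mixed_anova(vm))
  # oracle: explicit projection matrices and traces
  line <- factor(vm$line); sex <- factor(vm$sex, c("male", "female"))
  Xl <- list(matrix(1, nrow(vm), 1), model.matrix(~sex),
             model.matrix(~sex + line), model.matrix(~sex * line))
  P <- lapply(Xl, function(X) X %*% MASS::ginv(crossprod(X)) %*% t(X))
  Zl <- model.matrix(~0 + line)
  Zls <- model.matrix(~0 + line:sex)
  n <- nrow(vm)
  Q <- list(P[[3]] - P[[2]], P[[4]] - P[[3]], diag(n) - P[[4]])
  dfq <- sapply(list(c("Line"), c("Line:Sex"), c("Error")), function(s)
    fit$anova$df[fit$anova$source == s])
  for (k in 1:3) {
    cl <- sum(diag(Q[[k]] %*% tcrossprod(Zl))) / dfq[k]
    cls <- sum(diag(Q[[k]] %*% tcrossprod(Zls))) / dfq[k]
    row <- c("Line", "Line:Sex", "Error")[k]
    expect_equal(unname(fit$ems[row, "sigma2_line"]), cl, tolerance = 1e-8)
    expect_equal(unname(fit$ems[row, "sigma2_line_sex"]), cls,
                 tolerance = 1e-8)
  }
})

test_that("per-sex one-way ANOVA matches aov and the closed-form component", {
  vm <- balanced_vm(a = 10, r = 4, seed = 3)
  fit <- per_sex_anova(vm, "male")
  sub <- vm[vm$sex == "male", ]
  ref <- anova(lm(mean_lifespan ~ line, data = sub))
  expect_equal(fit$anova$ms, ref[["Mean Sq"]], tolerance = 1e-10)
  expect_equal(fit$components$sigma2_line,
               max((ref[["Mean Sq"]][1] - ref[["Mean Sq"]][2]) / 4, 0),
               tolerance = 1e-10)
})

test_that("nested individual ANOVA matches direct cell-means sums of squares", {
  set.seed(12)
  rec <- expand.grid(line = c("MUT", "CTRL"), sex = c("male", "female"),
                     vial = sprintf("V%02d", 1:12), fly = 1:5,
                     stringsAsFactors = FALSE)
  rec$block <- "B1"
  rec$death_age <- 50 + 3 * (rec$line == "MUT") +
    rnorm(nrow(rec) / 5, 0, 2)[as.integer(interaction(rec$line, rec$sex,
                                                      rec$vial))] +
    rnorm(nrow(rec), 0, 4)
  fit <- nested_individual_anova(rec)
  o <- nested_ss_oracle(rec)
  tab <- fit$anova
  ss <- setNames(tab$ms * tab$df, tab$source)
  expect_equal(ss[["Sex"]], o$ss_sex, tolerance = 1e-8)
  expect_equal(ss[["Line"]], o$ss_line, tolerance = 1e-8)
  expect_equal(ss[["Line"]] + ss[["Sex"]] + ss[["Line:Sex"]], o$ss_cells,
               tolerance = 1e-8)
  expect_equal(ss[["Replicate"]], o$ss_rep, tolerance = 1e-8)
  expect_equal(ss[["Error"]], o$ss_within, tolerance = 1e-8)
  # L, S, LxS are tested over the replicate stratum
  ms <- setNames(tab$ms, tab$source)
  expect_equal(tab$f[tab$source == "Line"],
               unname(ms[["Line"]] / ms[["Replicate"]]))
})

test_that("duplicating flies within vials zeroes the within-vial MS only", {
  set.seed(5)
  rec <- expand.grid(line = c("A", "B"), sex = c("male", "female"),
                     vial = c("V1", "V2", "V3"), stringsAsFactors = FALSE)
  rec$block <- "B1"
  rec$death_age <- 50 + rnorm(nrow(rec), 0, 3)
  dup <- rbind(rec, rec)
  fit <- nested_individual_anova(dup)
  ms <- setNames(fit$anova$ms, fit$anova$source)
  expect_lt(abs(ms[["Error"]]), 1e-8)
  # between-vial F ratios are unchanged relative to vial-mean analysis
  f_line <- fit$anova$f[fit$anova$source == "Line"]
  vmfit <- suppressWarnings(two_factor_mixed_anova(
    data.frame(line = rec$line, sex = rec$sex, vial = rec$vial,
               mean_lifespan = rec$death_age)))
  expect_equal(f_line,
               vmfit$anova$ms[vmfit$anova$source == "Line"] /
                 vmfit$anova$ms[vmfit$anova$source == "Error"],
               tolerance = 1e-8)
  # one fly per vial: within-vial error inestimable
  expect_error(nested_individual_anova(rec), "inestimable")
})

test_that("heritability follows its defining ratio and edge cases", {
  expect_equal(round(heritability(31.39, 25.24, 45.02), 3), 0.557)
  expect_equal(heritability(0, 0, 45.02), 0)
  expect_equal(heritability(10, 0, 0), 1)
  expect_error(heritability(0, 0, 0), "undefined")
  expect_error(heritability(-1, 0, 1), "non-negative")
})

test_that("cross-sex genetic correlation: conventions, symmetry, clamping", {
  expect_equal(round(as.numeric(
    cross_sex_genetic_correlation(31.39, 57.93, 55.37)), 3), 0.554)
  s2 <- c(40, 90)
  expect_equal(as.numeric(
    cross_sex_genetic_correlation(sqrt(prod(s2)), s2[1], s2[2])), 1)
  expect_equal(as.numeric(cross_sex_genetic_correlation(0, 30, 50)), 0)
  expect_error(cross_sex_genetic_correlation(10, 0, 50), "> 0")
  r <- cross_sex_genetic_correlation(100, 30, 50)
  expect_equal(as.numeric(r), 1)
  expect_true(attr(r, "clamped"))
})

test_that("heritability is invariant to rescaling all lifespans", {
  vm <- balanced_vm(a = 20, r = 3, seed = 17)
  f1 <- suppressWarnings(two_factor_mixed_anova(vm))
  vm2 <- vm
  vm2$mean_lifespan <- vm2$mean_lifespan * 3
  f2 <- suppressWarnings(two_factor_mixed_anova(vm2))
  expect_equal(f2$components$sigma2_line, 9 * f1$components$sigma2_line,
               tolerance = 1e-8)
  expect_equal(heritability(f1$components), heritability(f2$components),
               tolerance = 1e-10)
})

test_that("null simulated screens give calibrated F statistics", {
  set.seed(99)
  nsim <- 300
  fs <- replicate(nsim, {
    vm <- balanced_vm(a = 10, r = 2, s_line = 0, s_ls = 0, s_err = 5,
                      seed = sample.int(1e6, 1))
    tab <- suppressWarnings(two_factor_mixed_anova(vm))$anova
    c(tab$f[tab$source == "Line"], tab$f[tab$source == "Line:Sex"])
  })
  # F stats should live inside the central 99% band of their null law
  df1 <- 9; df2 <- 20
  for (k in 1:2) {
    inside <- mean(fs[k, ] > qf(0.005, df1, df2) &
                     fs[k, ] < qf(0.995, df1, df2))
    expect_gt(inside, 0.95)
  }
})

test_that("single-line or single-sex inputs are rejected with guidance", {
  vm <- balanced_vm(a = 5, r = 2)
  expect_error(two_factor_mixed_anova(vm[vm$line == "L01", ]), "2 lines")
  expect_error(two_factor_mixed_anova(vm[vm$sex == "male", ]),
               "per_sex_anova")
})
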