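# Mixed-model ANOVA on replicate-vial means, method-of-moments variance
# components, mutational heritability and cross-sex genetic correlation.
#
# Sums of squares are sequential (fitting order Sex, Line, Line x Sex),
# computed by projection onto nested model spaces.  Expected-mean-square
# coefficients for the random terms are obtained by Hartley's method of
# synthesis -- running each random-effect indicator column through the same
# quadratic forms -- which reduces to the textbook coefficients for
# balanced data and generalises Henderson's method to arbitrary
# unbalanced designs.

# -- sequential projections --------------------------------------------------

# returns a function(Y) -> vector of residual sums of squares per column
.rss_fun <- function(X) {
  q <- qr(X)
  r <- q$rank
  function(Y) {
    Y <- as.matrix(Y)
    qty <- qr.qty(q, Y)
    colSums(Y^2) - colSums(qty[seq_len(r), , drop = FALSE]^2)
  }
}

#' Assemble an ANOVA table from per-term mean squares
#'
#' Computes F ratios and P values for a set of sources given their degrees
#' of freedom and mean squares, with a configurable denominator map.  This
#' is the table-building convention used by every ANOVA in the package: by
#' default every term is tested over the error mean square.
#'
#' @param source character vector of term names (must include the
#'   denominator term(s)).
#' @param df integer degrees of freedom per term.
#' @param ms mean square per term.
#' @param denominator either a single term name used as denominator for
#'   all other terms (default `"Error"`), or a named character vector
#'   mapping term -> denominator term.
#' @return data frame with columns `source`, `df`, `ms`, `f`, `p` (F and P
#'   are `NA` for denominator-only terms).
#' @export
anova_table <- function(source, df, ms, denominator = "Error") {
  stopifnot(length(source) == length(df), length(df) == length(ms))
  denom_of <- function(term) {
    if (length(denominator) == 1L && is.null(names(denominator)))
      denominator else unname(denominator[term])
  }
  f <- p <- rep(NA_real_, length(source))
  for (i in seq_along(source)) {
    d <- denom_of(source[i])
    if (is.na(d) || identical(source[i], d)) next
    j <- match(d, source)
    if (is.na(j)) stop_("denominator term '%s' not in table", d)
    f[i] <- ms[i] / ms[j]
    p[i] <- pf(f[i], df[i], df[j], lower.tail = FALSE)
  }
  data.frame(source = source, df = df, ms = ms, f = f, p = p,
             stringsAsFactors = FALSE)
}

#' Variance-component container
#'
#' @param sigma2_line,sigma2_line_sex,sigma2_error pooled-model components,
#'   days^2.
#' @param sigma2_line_male,sigma2_line_female per-sex line components.
#' @param cov_fm cross-sex covariance of line means.
#' @param truncated character vector of components truncated to zero.
#' @return a `variance_components` list.
#' @export
variance_components <- function(sigma2_line, sigma2_line_sex, sigma2_error,
                                sigma2_line_male = NA_real_,
                                sigma2_line_female = NA_real_,
                                cov_fm = NA_real_,
                                truncated = character(0)) {
  structure(list(sigma2_line = sigma2_line,
                 sigma2_line_sex = sigma2_line_sex,
                 sigma2_error = sigma2_error,
                 sigma2_line_male = sigma2_line_male,
                 sigma2_line_female = sigma2_line_female,
                 cov_fm = cov_fm, truncated = truncated),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Variance components (days^2):\n")
  cat(sprintf("  line        %8.3f\n  line x sex  %8.3f\n  error       %8.3f\n",
              x$sigma2_line, x$sigma2_line_sex, x$sigma2_error))
  if (!is.na(x$sigma2_line_male))
    cat(sprintf("  line (male) %8.3f   line (female) %8.3f\n",
                x$sigma2_line_male, x$sigma2_line_female))
  if (!is.na(x$cov_fm)) cat(sprintf("  cov(F,M)    %8.3f\n", x$cov_fm))
  if (length(x$truncated))
    cat("  (truncated to zero:", paste(x$truncated, collapse = ", "), ")\n")
  invisible(x)
}

.truncate_vc <- function(est) {
  trunc <- names(est)[est < 0]
  est[est < 0] <- 0
  if (length(trunc))
    warning("negative variance component(s) truncated to zero: ",
            paste(trunc, collapse = ", "), call. = FALSE)
  list(est = est, truncated = trunc)
}

#' Two-factor mixed-model ANOVA on vial means
#'
#' Fits the sexes-pooled model `Y = mu + L + S + L x S + e` on replicate
#' vial means (line random, sex fixed, unrestricted convention) with
#' sequential sums of squares, and estimates the variance components
#' `sigma2_line`, `sigma2_line_sex`, `sigma2_error` by method of moments
#' with expected-mean-square coefficients derived from the actual
#' (possibly unbalanced) design.  By default every F ratio uses the error
#' mean square as denominator; a conservative mixed-model test of Line
#' over the interaction is available via `denominator`.
#'
#' Per-sex line components and the cross-sex covariance of line means are
#' computed alongside (the latter from lines observed in both sexes).
#'
#' @param vm `vial_means` data frame (columns `line`, `sex`,
#'   `mean_lifespan`; `block` optional and ignored by the model).
#' @param denominator `"error"` (default; reproduces the printed-F
#'   convention of screen reports) or `"interaction"` to test Line over
#'   the Line x Sex mean square.
#' @return list of class `mixed_anova` with elements `anova` (the table),
#'   `components` (a [variance_components()] object), `ems` (the EMS
#'   coefficient matrix used), and `model = "pooled-vial-means"`.
#' @export
two_factor_mixed_anova <- function(vm, denominator = c("error",
                                                       "interaction")) {
  denominator <- match.arg(denominator)
  assert_columns(vm, c("line", "sex", "mean_lifespan"), "vial means")
  line <- factor(vm$line)
  sex <- factor(as.character(vm$sex), levels = SEX_LEVELS)
  if (nlevels(line) < 2) stop_("need >= 2 lines for the two-factor model")
  if (length(unique(sex[!is.na(sex)])) < 2)
    stop_("only one sex present; use per_sex_anova()")
  y <- vm$mean_lifespan
  n <- length(y)
  X0 <- matrix(1, n, 1)
  Xs <- model.matrix(~sex)
  Xsl <- model.matrix(~sex + line)
  Xfull <- model.matrix(~sex * line)
  Z_line <- model.matrix(~0 + line)
  Z_ls <- model.matrix(~0 + line:sex)
  Xlist <- list(X0, Xs, Xsl, Xfull)
  rssf <- lapply(Xlist, .rss_fun)
  ranks <- vapply(Xlist, function(X) qr(X)$rank, integer(1))
  ry <- vapply(rssf, function(f) f(y), numeric(1))
  # synthesis: quadratic-form traces for each random indicator block
  rzL <- vapply(rssf, function(f) sum(f(Z_line)), numeric(1))
  rzLS <- vapply(rssf, function(f) sum(f(Z_ls)), numeric(1))
  ss <- c(-diff(ry), ry[4])
  df <- c(diff(ranks), n - ranks[4])
  src <- c("Sex", "Line", "Line:Sex", "Error")
  if (df[4] < 1) stop_("no residual degrees of freedom (need replicate vials)")
  ms <- ss / df
  denom_map <- if (denominator == "error")
    "Error" else c(Line = "Line:Sex", Sex = "Error", `Line:Sex` = "Error")
  tab <- anova_table(src, df, ms, denominator = denom_map)
  # EMS: E[MS_t] = cL_t * s2_L + cLS_t * s2_LS + s2_e  (rows Line, LxS, Err)
  cL <- c(-diff(rzL), rzL[4]) / df
  cLS <- c(-diff(rzLS), rzLS[4]) / df
  ems <- cbind(sigma2_line = cL, sigma2_line_sex = cLS, sigma2_error = 1)
  rownames(ems) <- src
  keep <- c("Line", "Line:Sex", "Error")
  est <- solve(ems[keep, ], ms[match(keep, src)])
  names(est) <- colnames(ems)
  tr <- .truncate_vc(est)
  # per-sex components and cross-sex covariance of line means
  psm <- per_sex_anova(vm, "male")
  psf <- per_sex_anova(vm, "female")
  lm_m <- tapply(y[sex == "male"], droplevels(line[sex == "male"]), mean)
  lm_f <- tapply(y[sex == "female"], droplevels(line[sex == "female"]), mean)
  common <- intersect(names(lm_m), names(lm_f))
  cov_fm <- if (length(common) >= 3)
    cov(lm_m[common], lm_f[common]) else NA_real_
  vc <- variance_components(unname(tr$est["sigma2_line"]),
                            unname(tr$est["sigma2_line_sex"]),
                            unname(tr$est["sigma2_error"]),
                            sigma2_line_male = psm$components$sigma2_line,
                            sigma2_line_female = psf$components$sigma2_line,
                            cov_fm = cov_fm, truncated = tr$truncated)
  structure(list(anova = tab, components = vc, ems = ems,
                 model = "pooled-vial-means"),
            class = "mixed_anova")
}

#' One-way per-sex ANOVA on vial means
#'
#' Fits the reduced model `Y = mu + L + e` to one sex's vial means and
#' estimates `sigma2_line` by method of moments,
#' `(MS_L - MS_E) / c` with the unbalanced expected-mean-square
#' coefficient `c = (N - sum(n_i^2)/N) / (a - 1)` (equal to the common
#' replicate count for balanced data).
#'
#' @param vm `vial_means` data frame.
#' @param sex `"male"` or `"female"`.
#' @return list of class `mixed_anova` with `anova`, `components`
#'   (`sigma2_line_sex` is `NA` for the one-way layout) and
#'   `model = "per-sex"`.
#' @export
per_sex_anova <- function(vm, sex) {
  sex <- match.arg(sex, SEX_LEVELS)
  assert_columns(vm, c("line", "sex", "mean_lifespan"), "vial means")
  sub <- vm[as.character(vm$sex) == sex, ]
  if (nrow(sub) == 0L) stop_("no records for sex '%s'", sex)
  line <- droplevels(factor(sub$line))
  if (nlevels(line) < 2) stop_("need >= 2 lines")
  y <- sub$mean_lifespan
  N <- length(y)
  a <- nlevels(line)
  ni <- tabulate(line)
  grand <- mean(y)
  ss_line <- sum(tapply(y, line, sum)^2 / ni) - N * grand^2
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_line
  df <- c(a - 1, N - a)
  if (df[2] < 1) stop_("no residual degrees of freedom (need replicate vials)")
  ms <- c(ss_line, ss_err) / df
  tab <- anova_table(c("Line", "Error"), df, ms)
  cc <- (N - sum(ni^2) / N) / (a - 1)
  est <- c(sigma2_line = (ms[1] - ms[2]) / cc, sigma2_error = ms[2])
  tr <- .truncate_vc(est)
  vc <- variance_components(unname(tr$est["sigma2_line"]), NA_real_,
                            unname(tr$est["sigma2_error"]),
                            truncated = tr$truncated)
  structure(list(anova = tab, components = vc, ems_coef = cc,
                 model = "per-sex", sex = sex),
            class = "mixed_anova")
}

#' Nested ANOVA on individual death ages
#'
#' Fits `Y = mu + L + S + L x S + R(L x S) + e` (or the per-sex reduction
#' `Y = mu + L + R(L) + e`) to individual records, separating the
#' replicate-vial stratum from the within-vial error.  Line, Sex and
#' Line x Sex are tested over the replicate-vial mean square; the
#' replicate term over the within-vial error.  This is the model of the
#' secondary (confirmation) screen, where Line is a fixed
#' mutant-vs-control contrast.
#'
#' @param records survival record data frame.
#' @param sexes `"pooled"` (default), `"male"` or `"female"`.
#' @return list of class `mixed_anova` with `anova` and
#'   `model = "individual-nested"`.
#' @export
nested_individual_anova <- function(records, sexes = c("pooled", SEX_LEVELS)) {
  sexes <- match.arg(sexes)
  assert_columns(records, c("line", "sex", "vial", "death_age"),
                 "survival table")
  rec <- as.data.frame(records)
  rec$sex <- as.character(rec$sex)
  if (sexes != "pooled") rec <- rec[rec$sex == sexes, ]
  if (nrow(rec) == 0L) stop_("no records to analyse")
  line <- droplevels(factor(rec$line))
  if (nlevels(line) < 2) stop_("need >= 2 lines")
  blk <- if ("block" %in% names(rec)) rec$block else ""
  vialf <- droplevels(interaction(blk, rec$line, rec$sex, rec$vial,
                                  drop = TRUE))
  y <- rec$death_age
  n <- length(y)
  Zv <- model.matrix(~0 + vialf)
  if (sexes == "pooled") {
    sex <- factor(rec$sex, levels = SEX_LEVELS)
    if (length(unique(sex)) < 2)
      stop_("only one sex present; use sexes = 'male' or 'female'")
    Xlist <- list(matrix(1, n, 1), model.matrix(~sex),
                  model.matrix(~sex + line), model.matrix(~sex * line),
                  cbind(model.matrix(~sex * line), Zv))
    src <- c("Sex", "Line", "Line:Sex", "Replicate", "Error")
  } else {
    Xlist <- list(matrix(1, n, 1), model.matrix(~line),
                  cbind(model.matrix(~line), Zv))
    src <- c("Line", "Replicate", "Error")
  }
  rssf <- lapply(Xlist, .rss_fun)
  ranks <- vapply(Xlist, function(X) qr(X)$rank, integer(1))
  ry <- vapply(rssf, function(f) f(y), numeric(1))
  ss <- c(-diff(ry), ry[length(ry)])
  df <- c(diff(ranks), n - ranks[length(ranks)])
  if (df[length(df)] < 1)
    stop_("within-vial error inestimable: need > 1 fly in some vial")
  if (df[length(df) - 1L] < 1)
    stop_("replicate-vial stratum inestimable: need replicate vials")
  ms <- ss / df
  denom <- setNames(rep("Replicate", length(src)), src)
  denom["Replicate"] <- "Error"
  denom <- denom[src != "Error"]
  tab <- anova_table(src, df, ms, denominator = denom)
  structure(list(anova = tab, model = "individual-nested", sexes = sexes),
            class = "mixed_anova")
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat(sprintf("ANOVA (%s)\n", x$model))
  tab <- x$anova
  tab$ms <- round(tab$ms, 4)
  tab$f <- round(tab$f, 3)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  if (!is.null(x$components)) print(x$components)
  invisible(x)
}

#' Broad-sense mutational heritability
#'
#' `H^2 = (sigma2_line + sigma2_line_sex) / (sigma2_line +
#' sigma2_line_sex + sigma2_error)`: the fraction of phenotypic variance
#' among replicate-vial means attributable to line and line-by-sex
#' effects.
#'
#' @param vc a [variance_components()] object, or `sigma2_line` as a
#'   number with `sigma2_line_sex` and `sigma2_error` supplied.
#' @param sigma2_line_sex,sigma2_error components when `vc` is numeric.
#' @return heritability in `[0, 1]`.
#' @examples
#' heritability(31.39, 25.24, 45.02)  # 0.557
#' @export
heritability <- function(vc, sigma2_line_sex = NULL, sigma2_error = NULL) {
  if (inherits(vc, "variance_components")) {
    s <- c(vc$sigma2_line, vc$sigma2_line_sex, vc$sigma2_error)
  } else {
    s <- c(vc, sigma2_line_sex, sigma2_error)
  }
  if (length(s) != 3 || any(is.na(s)))
    stop_("need the three pooled components (line, line x sex, error)")
  if (any(s < 0)) stop_("variance components must be non-negative")
  tot <- sum(s)
  if (tot == 0) stop_("all variance components are zero: H^2 undefined")
  (s[1] + s[2]) / tot
}

#' Cross-sex mutational genetic correlation
#'
#' `r_MF = cov_FM / (sigma_LF * sigma_LM)`: the correlation of line
#' effects between males and females.  The numerator is the cross-sex
#' covariance of line means when available (`numerator = "cov"`); the
#' alternative convention uses the pooled-model line component
#' (`numerator = "pooled"`), appropriate when the covariance was not
#' estimated directly.  The denominator is always the product of the
#' per-sex line standard deviations.  The result is clamped to
#' `[-1, 1]`, with attribute `clamped` set if clamping occurred.
#'
#' @param vc a [variance_components()] object, or the numerator as a
#'   number (with `sigma2_line_male`, `sigma2_line_female` supplied).
#' @param sigma2_line_male,sigma2_line_female per-sex line components when
#'   `vc` is numeric.
#' @param numerator `"cov"` or `"pooled"` (only used for
#'   `variance_components` input; numeric input is taken as the numerator
#'   directly).
#' @return correlation in `[-1, 1]`.
#' @examples
#' cross_sex_genetic_correlation(31.39, 57.93, 55.37)  # 0.554
#' @export
cross_sex_genetic_correlation <- function(vc, sigma2_line_male = NULL,
                                          sigma2_line_female = NULL,
                                          numerator = c("cov", "pooled")) {
  numerator <- match.arg(numerator)
  if (inherits(vc, "variance_components")) {
    num <- if (numerator == "cov" && !is.na(vc$cov_fm)) vc$cov_fm
           else vc$sigma2_line
    s2m <- vc$sigma2_line_male
    s2f <- vc$sigma2_line_female
  } else {
    num <- vc
    s2m <- sigma2_line_male
    s2f <- sigma2_line_female
  }
  if (is.null(s2m) || is.null(s2f) || is.na(s2m) || is.na(s2f))
    stop_("per-sex line components required")
  if (s2m <= 0 || s2f <= 0)
    stop_("per-sex line components must be > 0")
  r <- num / sqrt(s2m * s2f)
  clamped <- FALSE
  if (abs(r) > 1) { r <- sign(r); clamped <- TRUE }
  attr(r, "clamped") <- clamped
  r
}
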