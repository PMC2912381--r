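# Line-level screening against the co-isogenic control: normal confidence
# intervals on deviations, Dunnett many-to-one tests within blocks,
# standardized mutational effects, sex-effect classification, and compact
# letter displays for revertant comparisons.

# critical values used by the screen's CI method
CI_Z <- c(`0.95` = 1.96, `0.99` = 2.575, `0.999` = 3.3)

#' Confidence-interval screen of line deviations
#'
#' Flags a line at level alpha iff `|deviation| > z * sigma / sqrt(n)`
#' (strict inequality; ties are not significant), with z = 1.96, 2.575 and
#' 3.3 at the 95, 99 and 99.9% levels.  `sigma` is the phenotypic standard
#' deviation of a vial mean, `sqrt(sigma2_line + sigma2_line_sex +
#' sigma2_error)` for the pooled model or `sqrt(sigma2_line +
#' sigma2_error)` per sex, and `n` the number of replicate vials behind the
#' deviation (4 pooled / 2 per sex in the initial screen design).
#'
#' @param deviations numeric vector of line-mean deviations from the
#'   control (days), or a `deviation_table` from
#'   [deviations_from_control()] (one sex at a time).
#' @param sigma_P phenotypic standard deviation, days (> 0).
#' @param n_reps replicate vials per line (scalar or per-line).
#' @param levels confidence levels; each must have a known z (95/99/99.9
#'   by default) unless `z` is supplied.
#' @param z optional named vector of critical values overriding the
#'   built-in constants.
#' @return data frame with the deviation, half-widths, and logical flag
#'   plus direction (`increased`/`decreased`/`ns`) per level; flags are
#'   nested (99.9% implies 99% implies 95%).
#' @export
ci_screen <- function(deviations, sigma_P, n_reps,
                      levels = c(0.95, 0.99, 0.999), z = NULL) {
  if (inherits(deviations, "deviation_table")) {
    dev <- deviations$deviation
    labs <- deviations$line
  } else {
    dev <- as.numeric(deviations)
    labs <- names(deviations) %||% as.character(seq_along(dev))
  }
  if (!is.numeric(sigma_P) || sigma_P <= 0) stop_("sigma_P must be > 0")
  if (any(n_reps < 1)) stop_("n_reps must be >= 1")
  zmap <- z %||% CI_Z
  out <- data.frame(line = labs, deviation = dev,
                    stringsAsFactors = FALSE)
  for (lv in levels) {
    key <- as.character(lv)
    if (!key %in% names(zmap))
      stop_("no critical value for level %s; supply z", key)
    half <- zmap[[key]] * sigma_P / sqrt(n_reps)
    flag <- abs(dev) > half
    dir <- ifelse(!flag, "ns", ifelse(dev > 0, "increased", "decreased"))
    suf <- gsub("^0\\.", "", key)
    out[[paste0("half_width_", suf)]] <- half
    out[[paste0("flag_", suf)]] <- flag
    out[[paste0("direction_", suf)]] <- dir
  }
  out
}

# Dunnett adjusted p for many-to-one comparisons.
# t statistics share the control mean, giving product correlation
# rho_jk = lambda_j lambda_k with lambda_j = sqrt(n_j / (n_j + n0)).
.dunnett_adj_p <- function(tstat, lambda, df, seed = 1L) {
  k <- length(tstat)
  corr <- outer(lambda, lambda)
  diag(corr) <- 1
  vapply(abs(tstat), function(tt) {
    if (!is.finite(tt)) return(0)
    pr <- mvtnorm::pmvt(lower = rep(-tt, k), upper = rep(tt, k),
                        df = as.integer(df), corr = corr, sigma = NULL,
                        algorithm = mvtnorm::GenzBretz(abseps = 1e-4),
                        seed = seed)
    max(0, min(1, 1 - as.numeric(pr)))
  }, numeric(1))
}

#' Dunnett's many-to-one test against a common control
#'
#' Two-sided comparisons of every non-control line with the control within
#' one experimental block, on replicate-vial means, with familywise error
#' controlled by the joint multivariate-t distribution of the test
#' statistics (product-correlation structure, which accommodates unequal
#' replicate counts; the integral is evaluated by the Genz-Bretz
#' Monte-Carlo algorithm with a fixed seed).
#'
#' @param vm `vial_means` data frame for one block (or a plain data frame
#'   with `line`, `sex`, `mean_lifespan`).
#' @param control_line label of the control.
#' @param sex `"male"`, `"female"`, or `"pooled"` (pooled uses all vials,
#'   ignoring sex).
#' @param seed seed for the multivariate-t integrator.
#' @return data frame with one row per non-control line: `line`, `sex`,
#'   `estimate` (line minus control mean), `t`, `df`, `p_unadjusted`,
#'   `p_adjusted`.
#' @export
dunnett_test <- function(vm, control_line, sex = c("pooled", SEX_LEVELS),
                         seed = 1L) {
  sex <- match.arg(sex)
  assert_columns(vm, c("line", "sex", "mean_lifespan"), "vial means")
  dat <- as.data.frame(vm)
  dat$sex <- as.character(dat$sex)
  if (sex != "pooled") dat <- dat[dat$sex == sex, ]
  if (!control_line %in% dat$line)
    stop_("control line '%s' absent", control_line)
  line <- droplevels(factor(dat$line))
  if (nlevels(line) < 2) stop_("need at least one non-control line")
  y <- dat$mean_lifespan
  means <- tapply(y, line, mean)
  ns <- tabulate(line)
  names(ns) <- levels(line)
  df <- length(y) - nlevels(line)
  if (df < 1) stop_("no residual degrees of freedom for the pooled error")
  mse <- sum((y - means[line])^2) / df
  test <- setdiff(levels(line), control_line)
  n0 <- ns[control_line]
  est <- means[test] - means[control_line]
  se <- sqrt(mse * (1 / ns[test] + 1 / n0))
  tstat <- est / se
  lambda <- sqrt(ns[test] / (ns[test] + n0))
  p_unadj <- 2 * pt(-abs(tstat), df)
  p_adj <- if (length(test) == 1L) p_unadj
           else .dunnett_adj_p(tstat, lambda, df, seed = seed)
  data.frame(line = test, sex = sex, estimate = as.numeric(est),
             t = as.numeric(tstat), df = df,
             p_unadjusted = as.numeric(p_unadj),
             p_adjusted = pmax(as.numeric(p_adj), as.numeric(p_unadj)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Standardized mutational effect
#'
#' Percent deviation `100 (mutant - control) / control`, the allelic
#' effect `a = (mutant - control) / 2` (half the homozygous difference),
#' and the standardized effect `a / sigma_P`, where `sigma_P` is the
#' phenotypic standard deviation of the control line.
#'
#' @param mutant_mean,control_mean line mean life spans, days.
#' @param control_sigmaP control phenotypic standard deviation, days (> 0).
#' @return list with `percent`, `a`, `a_over_sigmaP`.
#' @examples
#' mutational_effect(60, 50, 10)  # 20%, a = 5, a/sigma_P = 0.5
#' @export
mutational_effect <- function(mutant_mean, control_mean, control_sigmaP) {
  if (any(control_mean <= 0)) stop_("control mean must be > 0")
  if (any(control_sigmaP <= 0)) stop_("control sigma_P must be > 0")
  d <- mutant_mean - control_mean
  list(percent = 100 * d / control_mean, a = d / 2,
       a_over_sigmaP = (d / 2) / control_sigmaP)
}

#' Classify the sex pattern of a mutational effect
#'
#' Deterministic classification from the significance pattern of the
#' pooled Line term, the Line x Sex interaction, and the separate-sex Line
#' terms, with optional per-sex effect signs to separate antagonistic from
#' biased patterns:
#'
#' * interaction not significant: Line significant -> `"both sexes"`;
#'   otherwise exactly one sex significant -> sex-specific; else
#'   `"not significant"`.
#' * interaction significant and only one sex significant -> sex-specific
#'   (the significant sex names the category).
#' * interaction significant and both sexes responsive (both below
#'   `alpha_marginal`, at least one below `alpha`): opposite-sign effects
#'   (when supplied) or a non-significant pooled Line term ->
#'   `"sex-antagonistic"`; otherwise (pooled Line significant, same-sign
#'   effects) -> sex-biased, named for the sex with the smaller P (ties
#'   broken by the larger absolute effect).
#'
#' @param p_L,p_LxS pooled-model P values for Line and Line x Sex.
#' @param p_L_male,p_L_female separate-sex Line P values.
#' @param alpha significance threshold (default 0.05).
#' @param alpha_marginal marginal threshold used only to judge whether the
#'   second sex responds when the interaction is significant (default
#'   0.10).
#' @param effect_male,effect_female optional per-sex effect sizes (any
#'   common scale, e.g. percent deviation); only their signs and relative
#'   magnitudes are used.
#' @return one of `"both sexes"`, `"male-specific"`, `"female-specific"`,
#'   `"male-biased"`, `"female-biased"`, `"sex-antagonistic"`,
#'   `"not significant"`.
#' @export
classify_sex_effect <- function(p_L, p_LxS, p_L_male, p_L_female,
                                alpha = 0.05, alpha_marginal = 0.10,
                                effect_male = NULL, effect_female = NULL) {
  ps <- c(p_L, p_LxS, p_L_male, p_L_female)
  if (any(!is.finite(ps)) || any(ps < 0 | ps > 1))
    stop_("P values must lie in [0, 1]")
  sig_m <- p_L_male < alpha
  sig_f <- p_L_female < alpha
  resp_m <- p_L_male < alpha_marginal
  resp_f <- p_L_female < alpha_marginal
  if (p_LxS >= alpha) {
    if (p_L < alpha) return("both sexes")
    if (xor(sig_m, sig_f))
      return(if (sig_m) "male-specific" else "female-specific")
    return("not significant")
  }
  # interaction significant
  if (resp_m && resp_f && (sig_m || sig_f)) {
    opposite <- !is.null(effect_male) && !is.null(effect_female) &&
      sign(effect_male) * sign(effect_female) < 0
    if (opposite || p_L >= alpha) return("sex-antagonistic")
    if (p_L_male < p_L_female) return("male-biased")
    if (p_L_female < p_L_male) return("female-biased")
    if (!is.null(effect_male) && !is.null(effect_female) &&
        abs(effect_male) != abs(effect_female))
      return(if (abs(effect_male) > abs(effect_female))
        "male-biased" else "female-biased")
    return("male-biased")
  }
  if (xor(sig_m, sig_f))
    return(if (sig_m) "male-specific" else "female-specific")
  "not significant"
}

#' Representative P values for significance star codes
#'
#' Maps the star codes of published screen tables to representative P
#' values inside the coded bound: `ns` (P > 0.1) -> 0.3, `mar`
#' (0.05 < P < 0.1) -> 0.075, `*` (P < 0.05) -> 0.03, `**` -> 0.005,
#' `***` -> 5e-4, `****` -> 5e-5.  Used to drive [classify_sex_effect()]
#' from a significance pattern.
#'
#' @param code character vector of codes.
#' @return numeric P values.
#' @export
significance_code_p <- function(code) {
  map <- c(ns = 0.3, mar = 0.075, `*` = 0.03, `**` = 0.005,
           `***` = 5e-4, `****` = 5e-5)
  bad <- !code %in% names(map)
  if (any(bad)) stop_("unknown significance code '%s'", code[bad][1])
  unname(map[code])
}

#' Compact letter display from all-pairs Tukey tests
#'
#' Tukey-Kramer studentized-range tests on a set of group means with a
#' pooled error mean square; groups sharing a letter are not significantly
#' different at `alpha`.  Letters are assigned by the insert-and-absorb
#' algorithm: start with one letter covering all groups, split on each
#' significant pair, absorb redundant letters.
#'
#' @param group_means named numeric vector of group means.
#' @param n_per_group replicate count per group (scalar or named vector).
#' @param error_ms pooled error mean square.
#' @param df_error its degrees of freedom.
#' @param alpha familywise level (default 0.05).
#' @return data frame `group`, `mean`, `letters`, plus attribute
#'   `p_matrix` of pairwise adjusted P values.
#' @export
tukey_letters <- function(group_means, n_per_group, error_ms, df_error,
                          alpha = 0.05) {
  k <- length(group_means)
  if (k < 2) stop_("need >= 2 groups")
  grp <- names(group_means) %||% paste0("g", seq_len(k))
  names(group_means) <- grp
  if (length(n_per_group) == 1L)
    n_per_group <- setNames(rep(n_per_group, k), grp)
  if (error_ms < 0) stop_("error MS must be >= 0")
  if (error_ms == 0 && length(unique(group_means)) > 1L)
    stop_("zero error MS with unequal means: tests degenerate")
  pmat <- matrix(1, k, k, dimnames = list(grp, grp))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(error_ms / 2 * (1 / n_per_group[i] + 1 / n_per_group[j]))
    if (se == 0) { pmat[i, j] <- pmat[j, i] <- 1; next }
    q <- abs(group_means[i] - group_means[j]) / se
    p <- ptukey(q, nmeans = k, df = df_error, lower.tail = FALSE)
    pmat[i, j] <- pmat[j, i] <- p
  }
  sig <- pmat < alpha
  # insert-and-absorb: letters are sets of mutually non-different groups
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (!sig[i, j]) next
    for (s in seq_along(sets)) {
      if (all(c(i, j) %in% sets[[s]])) {
        a <- setdiff(sets[[s]], i)
        b <- setdiff(sets[[s]], j)
        sets[[s]] <- a
        sets[[length(sets) + 1L]] <- b
      }
    }
    # absorb sets contained in another
    keep <- rep(TRUE, length(sets))
    for (s in seq_along(sets)) for (t in seq_along(sets)) {
      if (s != t && keep[t] && all(sets[[s]] %in% sets[[t]]) &&
          length(sets[[s]]) < length(sets[[t]])) keep[s] <- FALSE
    }
    sets <- unique(sets[keep])
  }
  # order letter sets by the mean of their best group for stable output
  ord <- order(vapply(sets, function(s) -max(group_means[s]), numeric(1)))
  sets <- sets[ord]
  letts <- vapply(seq_len(k), function(g) {
    paste0(letters[which(vapply(sets, function(s) g %in% s, logical(1)))],
           collapse = "")
  }, character(1))
  out <- data.frame(group = grp, mean = as.numeric(group_means),
                    letters = letts, stringsAsFactors = FALSE)
  attr(out, "p_matrix") <- pmat
  out
}

#' Combine CI-screen and Dunnett verdicts for a line
#'
#' The two screening methods can disagree; the combined call is either
#' their union (significant by at least one method, the default) or their
#' intersection (significant by both).  Direction comes from the sign of
#' the deviation.
#'
#' @param ci_flag logical, CI-screen significance.
#' @param dunnett_p Dunnett adjusted P (`NA` treated as not significant).
#' @param deviation line-mean deviation from the control, days.
#' @param alpha level for the Dunnett verdict.
#' @param method `"union"` or `"intersection"`.
#' @return `"increased"`, `"decreased"` or `"ns"` (vectorised).
#' @export
combine_screen_verdicts <- function(ci_flag, dunnett_p, deviation,
                                    alpha = 0.05,
                                    method = c("union", "intersection")) {
  method <- match.arg(method)
  dun <- !is.na(dunnett_p) & dunnett_p < alpha
  sig <- if (method == "union") (ci_flag | dun) else (ci_flag & dun)
  ifelse(!sig, "ns", ifelse(deviation > 0, "increased", "decreased"))
}

#' Confirmation rate of a screen
#'
#' Percentage of all screened lines whose effects were confirmed, e.g.
#' confirmed long-lived lines over lines screened.
#'
#' @param n_confirmed,n_screened counts.
#' @param digits rounding for the printed percentage (default 1).
#' @return percentage.
#' @export
confirmation_rate <- function(n_confirmed, n_screened, digits = 1) {
  if (n_screened < 1) stop_("n_screened must be >= 1")
  round(100 * n_confirmed / n_screened, digits)
}
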