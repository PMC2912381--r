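# Mutational correlations among traits: Pearson correlations of line-mean
# deviations per sex x age cell, with t tests against zero and a
# Fisher-z test against unity.

#' Test a Pearson correlation against zero
#'
#' `se = sqrt((1 - r^2) / df)`, `t = r / se`, two-sided P from the t
#' distribution on `df = n - 2` degrees of freedom.
#'
#' @param r sample correlation, |r| < 1.
#' @param df degrees of freedom (number of line pairs minus 2).
#' @return list `se`, `t`, `p`.
#' @examples
#' corr_test_vs_zero(0.328, 48)  # se 0.136, t 2.41
#' @export
corr_test_vs_zero <- function(r, df) {
  if (abs(r) >= 1) stop_("|r| must be < 1 (degenerate at the boundary)")
  if (df < 1) stop_("df must be >= 1")
  se <- sqrt((1 - r^2) / df)
  t <- r / se
  list(se = se, t = t, p = 2 * pt(-abs(t), df))
}

#' Test a correlation against unity
#'
#' One-sided test of H0: rho = rho_bound (a fixed boundary just below 1,
#' default 0.999) against rho < rho_bound, via the Fisher z transform:
#' `z = (atanh(r) - atanh(rho_bound)) * sqrt(df - 1)`, `p = pnorm(z)`.  An
#' exact test at rho = 1 is impossible (the z transform diverges), so the
#' boundary comparison is used; P is non-decreasing in r, approaching 0.5
#' as r approaches the boundary.
#'
#' @param r sample correlation, r < 1.
#' @param df degrees of freedom (n - 2); the z test uses n - 3 = df - 1.
#' @param rho_bound boundary correlation (default 0.999).
#' @return one-sided P value for rho < rho_bound.
#' @export
corr_test_vs_one <- function(r, df, rho_bound = 0.999) {
  if (r >= 1) stop_("r >= 1 is degenerate for a test against unity")
  if (df < 2) stop_("df must be >= 2 for the Fisher z test")
  z <- (atanh(r) - atanh(rho_bound)) * sqrt(df - 1)
  pnorm(z)
}

#' Pairwise mutational correlations from a trait deviation table
#'
#' Pearson product-moment correlations among line-mean deviations for
#' every trait pair within each sex x age cell, using pairwise-complete
#' lines (traits may be measured on different line subsets), with
#' `df = n_pairs - 2`, the t test against zero and the Fisher-z test
#' against unity.  Cells with fewer than 3 complete pairs are marked
#' inestimable.
#'
#' @param traits long data frame `line`, `sex`, `age_weeks`, `trait`,
#'   `value` (deviations from control), e.g. from [read_trait_table()] or
#'   [simulate_pleiotropy()].
#' @return data frame of class `correlation_results`: `sex`, `age_weeks`,
#'   `trait_a`, `trait_b`, `n`, `df`, `r`, `se`, `t`, `p_vs_zero`,
#'   `p_vs_one`, `estimable`.
#' @export
mutational_correlations <- function(traits) {
  assert_columns(traits, c("line", "sex", "age_weeks", "trait", "value"),
                 "trait table")
  res <- list()
  for (s in unique(traits$sex)) for (a in unique(traits$age_weeks)) {
    sub <- traits[traits$sex == s & traits$age_weeks == a, ]
    if (nrow(sub) == 0L) next
    tr <- sort(unique(sub$trait))
    if (length(tr) < 2) next
    wide <- lapply(tr, function(tt) {
      d <- sub[sub$trait == tt, ]
      setNames(d$value, d$line)
    })
    names(wide) <- tr
    for (i in seq_len(length(tr) - 1)) for (j in (i + 1):length(tr)) {
      xi <- wide[[i]]
      xj <- wide[[j]]
      common <- intersect(names(xi), names(xj))
      ok <- common[is.finite(xi[common]) & is.finite(xj[common])]
      npairs <- length(ok)
      if (npairs < 3) {
        res[[length(res) + 1L]] <- data.frame(
          sex = s, age_weeks = a, trait_a = tr[i], trait_b = tr[j],
          n = npairs, df = NA_integer_, r = NA_real_, se = NA_real_,
          t = NA_real_, p_vs_zero = NA_real_, p_vs_one = NA_real_,
          estimable = FALSE, stringsAsFactors = FALSE)
        next
      }
      r <- cor(xi[ok], xj[ok])
      df <- npairs - 2L
      if (abs(r) < 1) {
        tz <- corr_test_vs_zero(r, df)
        p1 <- if (df >= 2) corr_test_vs_one(r, df) else NA_real_
      } else {
        tz <- list(se = 0, t = sign(r) * Inf, p = 0)
        p1 <- if (r > 0) 1 else 0
      }
      res[[length(res) + 1L]] <- data.frame(
        sex = s, age_weeks = a, trait_a = tr[i], trait_b = tr[j],
        n = npairs, df = df, r = r, se = tz$se, t = tz$t,
        p_vs_zero = tz$p, p_vs_one = p1, estimable = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- unique(c("correlation_results", class(out)))
  out
}

#' Correlation matrix for one sex x age cell
#'
#' Symmetric unit-diagonal matrix of the pairwise mutational correlations
#' of one cell of a [mutational_correlations()] result.
#'
#' @param cr `correlation_results` data frame.
#' @param sex,age_weeks cell selectors.
#' @return correlation matrix.
#' @export
correlation_matrix <- function(cr, sex, age_weeks) {
  sub <- cr[cr$sex == sex & cr$age_weeks == age_weeks, ]
  if (nrow(sub) == 0L) stop_("no correlations for that cell")
  tr <- sort(unique(c(sub$trait_a, sub$trait_b)))
  m <- diag(length(tr))
  dimnames(m) <- list(tr, tr)
  for (k in seq_len(nrow(sub))) {
    m[sub$trait_a[k], sub$trait_b[k]] <- sub$r[k]
    m[sub$trait_b[k], sub$trait_a[k]] <- sub$r[k]
  }
  m
}
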