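# End-to-end screen orchestration: from raw survival records to a
# one-row-per-line result table with deviations, CI flags, Dunnett P,
# standardized effects and sex-effect categories.

#' Run the full line screen against a control
#'
#' Aggregates records to vial means, fits the pooled and per-sex
#' variance-component models to obtain the phenotypic standard deviations
#' used by the CI method, computes per-line deviations from the
#' contemporaneous control, CI flags at 95/99/99.9%, Dunnett adjusted P
#' per sex within each block, standardized mutational effects against the
#' control, per-line mutant-vs-control nested ANOVAs, and the sex-effect
#' category.
#'
#' @param records survival record data frame (validated).
#' @param control_line label of the co-isogenic control.
#' @param alpha significance level for classification (default 0.05).
#' @param ci_levels confidence levels for the CI screen.
#' @param dunnett_seed seed for the multivariate-t integrator.
#' @return data frame of class `screen_result`, one row per non-control
#'   line; the fitted pooled model is attached as attribute `anova`.
#' @export
screen_lines <- function(records, control_line, alpha = 0.05,
                         ci_levels = c(0.95, 0.99, 0.999),
                         dunnett_seed = 1L) {
  vm <- vial_means(records)
  if (!control_line %in% vm$line)
    stop_("control line '%s' not in data", control_line)
  fit <- two_factor_mixed_anova(vm)
  vc <- fit$components
  sigma_pooled <- sqrt(vc$sigma2_line + vc$sigma2_line_sex + vc$sigma2_error)
  fit_m <- per_sex_anova(vm, "male")
  fit_f <- per_sex_anova(vm, "female")
  sigma_sex <- c(
    male = sqrt(fit_m$components$sigma2_line + fit_m$components$sigma2_error),
    female = sqrt(fit_f$components$sigma2_line +
                    fit_f$components$sigma2_error))
  devs <- deviations_from_control(vm, control_line)
  lines <- setdiff(unique(vm$line), control_line)
  # Dunnett within block per sex
  dun <- list()
  for (b in unique(vm$block)) for (s in SEX_LEVELS) {
    sub <- vm[vm$block == b & as.character(vm$sex) == s, ]
    if (!control_line %in% sub$line || length(unique(sub$line)) < 2) next
    d <- dunnett_test(sub, control_line, sex = s, seed = dunnett_seed)
    d$block <- b
    dun[[length(dun) + 1L]] <- d
  }
  dun <- if (length(dun)) do.call(rbind, dun) else NULL
  rows <- list()
  for (ln in lines) {
    dl <- devs[devs$line == ln, ]
    dev_p <- dl$deviation[dl$sex == "pooled"]
    dev_m <- dl$deviation[dl$sex == "male"]
    dev_f <- dl$deviation[dl$sex == "female"]
    n_p <- dl$n_replicates[dl$sex == "pooled"]
    blk <- dl$block[1]
    # control stats within the line's block
    ctl <- records[records$line == control_line & records$block == blk, ]
    ln_rec <- records[records$line == ln, ]
    two <- rbind(ln_rec, ctl)
    cls <- tryCatch({
      ap <- nested_individual_anova(two, "pooled")$anova
      am <- nested_individual_anova(two, "male")$anova
      af <- nested_individual_anova(two, "female")$anova
      p_L <- ap$p[ap$source == "Line"]
      p_LxS <- ap$p[ap$source == "Line:Sex"]
      p_m <- am$p[am$source == "Line"]
      p_f <- af$p[af$source == "Line"]
      list(p_L = p_L, p_LxS = p_LxS, p_m = p_m, p_f = p_f,
           category = classify_sex_effect(
             p_L, p_LxS, p_m, p_f, alpha = alpha,
             effect_male = if (length(dev_m)) dev_m else NULL,
             effect_female = if (length(dev_f)) dev_f else NULL))
    }, error = function(e) list(p_L = NA, p_LxS = NA, p_m = NA, p_f = NA,
                                category = NA_character_))
    ctl_mean <- mean(ctl$death_age)
    ctl_sd <- sd(ctl$death_age)
    eff <- mutational_effect(mean(ln_rec$death_age), ctl_mean, ctl_sd)
    ci_p <- ci_screen(setNames(dev_p, ln), sigma_pooled, n_p,
                      levels = ci_levels)
    row <- data.frame(line = ln, block = blk,
                      deviation_pooled = dev_p,
                      deviation_male = if (length(dev_m)) dev_m else NA,
                      deviation_female = if (length(dev_f)) dev_f else NA,
                      percent = eff$percent, a = eff$a,
                      a_over_sigmaP = eff$a_over_sigmaP,
                      p_line = cls$p_L, p_line_sex = cls$p_LxS,
                      p_line_male = cls$p_m, p_line_female = cls$p_f,
                      category = cls$category, stringsAsFactors = FALSE)
    for (nm in grep("^(flag|direction)_", names(ci_p), value = TRUE))
      row[[paste0(nm, "_pooled")]] <- ci_p[[nm]]
    for (s in SEX_LEVELS) {
      dev_s <- dl$deviation[dl$sex == s]
      n_s <- dl$n_replicates[dl$sex == s]
      if (length(dev_s)) {
        ci_s <- ci_screen(setNames(dev_s, ln), sigma_sex[[s]], n_s,
                          levels = ci_levels)
        for (nm in grep("^flag_", names(ci_s), value = TRUE))
          row[[paste0(nm, "_", s)]] <- ci_s[[nm]]
      }
      if (!is.null(dun)) {
        dd <- dun[dun$line == ln & dun$sex == s, ]
        row[[paste0("p_dunnett_", s)]] <-
          if (nrow(dd)) dd$p_adjusted[1] else NA_real_
      }
    }
    for (s in SEX_LEVELS) {
      fl <- row[[paste0("flag_95_", s)]]
      dp <- row[[paste0("p_dunnett_", s)]]
      dv <- row[[paste0("deviation_", s)]]
      row[[paste0("verdict_", s)]] <-
        if (is.null(fl) || is.na(dv)) NA_character_
        else combine_screen_verdicts(fl, dp %||% NA_real_, dv)
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "anova") <- fit
  class(out) <- unique(c("screen_result", class(out)))
  out
}
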