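# Seed-reproducible generators for the three experimental designs: the
# line screen (random line effects), the half-diallel (fixed GCA/SCA), and
# multi-trait line-mean deviations (multivariate normal).  Each generator
# returns the data alongside a sidecar ground-truth object so downstream
# estimators admit parameter-recovery tests.
#
# All randomness flows from the single `seed` through one stream with a
# fixed drawing order (line effects, then line x sex, then vials, then
# individuals), so identical seeds give byte-identical tables and subsets
# can be reproduced by regenerating and slicing.

#' Parameters for the screen generator
#'
#' Defaults emulate the magnitudes of a large insertion-line life-span
#' screen: grand mean 55 d, line variance 30, line-by-sex variance 25, and
#' a residual that decomposes into a vial effect (25) plus within-vial
#' individual variance (100), so that on the replicate-vial-mean scale the
#' error component is 25 + 100/5 = 45 days^2 under the default 5 flies per
#' vial.  Deaths are recorded on a 2-day census grid.
#'
#' @param mu grand mean life span, days.
#' @param sigma2_line,sigma2_line_sex,sigma2_vial,sigma2_error variance
#'   components, days^2 (line, line x sex, replicate vial, within-vial
#'   individual).
#' @param n_lines,vials_per_sex,flies_per_vial design counts.
#' @param sex_effect fixed female-minus-male difference, days.
#' @param census_interval census spacing, days.
#' @param block block label for the generated records.
#' @param seed integer seed.
#' @return a `screen_sim_params` list.
#' @export
screen_sim_params <- function(mu = 55, sigma2_line = 30,
                              sigma2_line_sex = 25, sigma2_vial = 25,
                              sigma2_error = 100, n_lines = 100,
                              vials_per_sex = 2, flies_per_vial = 5,
                              sex_effect = 2, census_interval = 2,
                              block = "B1", seed = 1L) {
  p <- list(mu = mu, sigma2_line = sigma2_line,
            sigma2_line_sex = sigma2_line_sex, sigma2_vial = sigma2_vial,
            sigma2_error = sigma2_error, n_lines = n_lines,
            vials_per_sex = vials_per_sex, flies_per_vial = flies_per_vial,
            sex_effect = sex_effect, census_interval = census_interval,
            block = block, seed = as.integer(seed))
  vars <- c("sigma2_line", "sigma2_line_sex", "sigma2_vial", "sigma2_error")
  for (v in vars) if (p[[v]] < 0) stop_("%s must be >= 0", v)
  for (v in c("n_lines", "vials_per_sex", "flies_per_vial"))
    if (p[[v]] < 1) stop_("%s must be >= 1", v)
  class(p) <- "screen_sim_params"
  p
}

# deaths are recorded at the census on/after true death
snap_to_grid <- function(x, interval, start = interval) {
  pmax(start, start + interval * ceiling((x - start) / interval - 1e-9))
}

#' Simulate a line screen with known ground truth
#'
#' Generates individual death ages as
#' mu + sex effect + line draw + line-by-sex draw + vial draw + individual
#' draw, snapped *up* to the census grid (the recorded census day is the
#' lifespan) and truncated below at one census interval.  Line and
#' interaction effects are drawn normal.
#'
#' @param params a [screen_sim_params()] object.
#' @return list with `records` (a `survival_records` data frame) and
#'   `truth` (per-line effects: `line`, `line_effect`, `ls_male`,
#'   `ls_female`, the realised line and line x sex draws).
#' @export
simulate_screen <- function(params) {
  p <- if (inherits(params, "screen_sim_params")) params
       else do.call(screen_sim_params, params)
  set.seed(p$seed)
  lines <- sprintf("L%04d", seq_len(p$n_lines))
  line_eff <- rnorm(p$n_lines, 0, sqrt(p$sigma2_line))
  # one line x sex draw per line per sex, in line-major order
  ls_eff <- matrix(rnorm(2 * p$n_lines, 0, sqrt(p$sigma2_line_sex)),
                   nrow = p$n_lines, ncol = 2,
                   dimnames = list(lines, SEX_LEVELS))
  rows <- vector("list", p$n_lines * 2L * p$vials_per_sex)
  k <- 0L
  for (i in seq_len(p$n_lines)) {
    for (s in SEX_LEVELS) {
      sex_shift <- if (s == "female") p$sex_effect / 2 else -p$sex_effect / 2
      for (v in seq_len(p$vials_per_sex)) {
        vial_eff <- rnorm(1, 0, sqrt(p$sigma2_vial))
        ind <- rnorm(p$flies_per_vial, 0, sqrt(p$sigma2_error))
        age <- p$mu + sex_shift + line_eff[i] + ls_eff[i, s] + vial_eff + ind
        age <- snap_to_grid(age, p$census_interval)
        k <- k + 1L
        rows[[k]] <- data.frame(
          block = p$block, line = lines[i], sex = s,
          vial = sprintf("V%02d", v), death_age = age,
          stringsAsFactors = FALSE)
      }
    }
  }
  rec <- do.call(rbind, rows)
  rec <- validate_survival(rec, p$census_interval)
  truth <- data.frame(line = lines, line_effect = line_eff,
                      ls_male = ls_eff[, "male"],
                      ls_female = ls_eff[, "female"],
                      stringsAsFactors = FALSE)
  list(records = rec, truth = truth, params = p)
}

#' Parameters for the half-diallel generator
#'
#' @param n_parents number of parental mutant lines (>= 3).
#' @param mu grand mean life span of the double heterozygotes, days.
#' @param gca length-`n_parents` vector of general combining abilities
#'   (must sum to 0); default all zero.
#' @param sca symmetric `n x n` matrix of specific combining abilities,
#'   zero diagonal, each row summing to 0 over the off-diagonal cells;
#'   default all zero.
#' @param sex_gca,sex_sca sex-interaction analogues (female gets `+`, male
#'   `-` the stated effect); same constraints; default zero.
#' @param sex_effect fixed female-minus-male difference, days.
#' @param sigma2_vial,sigma2_error variance of the vial effect and of the
#'   residual of a vial mean, days^2.
#' @param reps_per_cross_per_sex replicate vials per cross per sex.
#' @param seed integer seed.
#' @return a `diallel_sim_params` list.
#' @export
diallel_sim_params <- function(n_parents = 10, mu = 60, gca = NULL,
                               sca = NULL, sex_gca = NULL, sex_sca = NULL,
                               sex_effect = 0, sigma2_vial = 4,
                               sigma2_error = 9,
                               reps_per_cross_per_sex = 8, seed = 1L) {
  n <- n_parents
  if (n < 3) stop_("n_parents must be >= 3")
  gca <- gca %||% numeric(n)
  sca <- sca %||% matrix(0, n, n)
  sex_gca <- sex_gca %||% numeric(n)
  sex_sca <- sex_sca %||% matrix(0, n, n)
  check_sca <- function(m, what) {
    if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
      stop_("%s matrix must be symmetric", what)
    if (any(abs(diag(m)) > 1e-8)) stop_("%s matrix must have zero diagonal", what)
    rs <- rowSums(m)
    if (any(abs(rs) > 1e-6))
      stop_("%s rows must sum to 0 over the half-diallel (row %d sums to %g)",
            what, which.max(abs(rs)), rs[which.max(abs(rs))])
  }
  if (abs(sum(gca)) > 1e-6) stop_("gca must sum to 0")
  if (abs(sum(sex_gca)) > 1e-6) stop_("sex_gca must sum to 0")
  check_sca(sca, "sca"); check_sca(sex_sca, "sex_sca")
  if (sigma2_vial < 0 || sigma2_error < 0) stop_("variances must be >= 0")
  if (reps_per_cross_per_sex < 1) stop_("reps_per_cross_per_sex must be >= 1")
  structure(list(n_parents = n, mu = mu, gca = gca, sca = sca,
                 sex_gca = sex_gca, sex_sca = sex_sca,
                 sex_effect = sex_effect, sigma2_vial = sigma2_vial,
                 sigma2_error = sigma2_error,
                 reps_per_cross_per_sex = reps_per_cross_per_sex,
                 seed = as.integer(seed)),
            class = "diallel_sim_params")
}

#' Simulate a half-diallel cross
#'
#' Generates replicate vial means for all i < j crosses (no selfs, no
#' reciprocals) with expectation
#' `mu +/- sex_effect/2 + g_i + g_j + s_ij +/- (sg_i + sg_j + ss_ij)`
#' (female `+`, male `-` for the sex-interaction terms) and independent
#' normal noise `sigma2_vial + sigma2_error` per vial mean.
#'
#' @param params a [diallel_sim_params()] object.
#' @return list with `data` (data frame `parent_i`, `parent_j`, `sex`,
#'   `vial`, `value`, one row per replicate vial) and `truth` (the
#'   parameter object).
#' @export
simulate_diallel <- function(params) {
  p <- if (inherits(params, "diallel_sim_params")) params
       else do.call(diallel_sim_params, params)
  set.seed(p$seed)
  n <- p$n_parents
  parents <- sprintf("P%02d", seq_len(n))
  pairs <- t(combn(n, 2))
  sd_vm <- sqrt(p$sigma2_vial + p$sigma2_error)
  rows <- list()
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    base <- p$mu + p$gca[i] + p$gca[j] + p$sca[i, j]
    sexint <- p$sex_gca[i] + p$sex_gca[j] + p$sex_sca[i, j]
    for (s in SEX_LEVELS) {
      sgn <- if (s == "female") 1 else -1
      mu_cell <- base + sgn * (p$sex_effect / 2 + sexint)
      val <- mu_cell + rnorm(p$reps_per_cross_per_sex, 0, sd_vm)
      rows[[length(rows) + 1L]] <- data.frame(
        parent_i = parents[i], parent_j = parents[j], sex = s,
        vial = sprintf("V%02d", seq_len(p$reps_per_cross_per_sex)),
        value = val, stringsAsFactors = FALSE)
    }
  }
  list(data = do.call(rbind, rows), truth = p)
}

#' Parameters for the pleiotropy generator
#'
#' @param n_lines number of mutant lines.
#' @param cells data frame describing the trait x sex x age cells, columns
#'   `trait`, `sex`, `age_weeks`; one multivariate-normal dimension each.
#' @param covariance symmetric positive-semidefinite matrix over the cells
#'   (days^2 or trait units^2); dimension must match `nrow(cells)`.
#' @param mean optional vector of cell means (default 0: deviations from
#'   control).
#' @param seed integer seed.
#' @return a `pleiotropy_sim_params` list.
#' @export
pleiotropy_sim_params <- function(n_lines, cells, covariance, mean = NULL,
                                  seed = 1L) {
  assert_columns(cells, c("trait", "sex", "age_weeks"), "cells")
  d <- nrow(cells)
  if (!is.matrix(covariance) || nrow(covariance) != d || ncol(covariance) != d)
    stop_("covariance must be a %d x %d matrix matching the cells", d, d)
  if (!isTRUE(all.equal(covariance, t(covariance), tolerance = 1e-8)))
    stop_("covariance must be symmetric")
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop_("covariance is not positive semidefinite (eigenvalue %g < 0)",
          min(ev))
  structure(list(n_lines = n_lines, cells = cells, covariance = covariance,
                 mean = mean %||% numeric(d), seed = as.integer(seed)),
            class = "pleiotropy_sim_params")
}

#' Simulate multi-trait line-mean deviations
#'
#' Draws `n_lines` multivariate-normal vectors over the trait x sex x age
#' cells with the requested covariance (rank-deficient PSD accepted) and
#' returns them as a long trait table.
#'
#' @param params a [pleiotropy_sim_params()] object.
#' @return list with `data` (long data frame `line`, `sex`, `age_weeks`,
#'   `trait`, `value`) and `truth` (the parameter object).
#' @export
simulate_pleiotropy <- function(params) {
  p <- if (inherits(params, "pleiotropy_sim_params")) params
       else do.call(pleiotropy_sim_params, params)
  set.seed(p$seed)
  d <- nrow(p$cells)
  x <- MASS::mvrnorm(p$n_lines, mu = p$mean, Sigma = p$covariance,
                     tol = 1e-6)
  x <- matrix(x, nrow = p$n_lines)
  lines <- sprintf("L%04d", seq_len(p$n_lines))
  long <- do.call(rbind, lapply(seq_len(d), function(k) data.frame(
    line = lines, sex = p$cells$sex[k], age_weeks = p$cells$age_weeks[k],
    trait = p$cells$trait[k], value = x[, k], stringsAsFactors = FALSE)))
  rownames(long) <- NULL
  list(data = long, truth = p)
}
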