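# Half-diallel combining-ability analysis, Griffing Method 4 (no selfs,
# no reciprocals), Model 1 (parents fixed): GCA/SCA estimation with the
# classical standard errors, ANOVA partition of the genotype term into
# GCA and SCA (and their sex interactions), and epistasis calls from
# significant SCA effects.

#' Assemble and validate half-diallel data
#'
#' Accepts replicate-level vial means (`parent_i`, `parent_j`, `sex`,
#' `vial`, `value`) for all i < j crosses of `n` parents.  Pairs are
#' normalised to a canonical orientation; selfs are rejected, and every
#' cross must be present (the combining-ability formulas assume a complete
#' half-diallel).
#'
#' @param df replicate-level data frame; `sex` optional (a single pooled
#'   set of replicates is then assumed).
#' @return list of class `diallel_data`: `data` (normalised replicates),
#'   `parents`, `n_parents`.
#' @export
diallel_data <- function(df) {
  assert_columns(df, c("parent_i", "parent_j", "vial", "value"),
                 "diallel table")
  if (!"sex" %in% names(df)) df$sex <- "pooled"
  df$parent_i <- as.character(df$parent_i)
  df$parent_j <- as.character(df$parent_j)
  if (any(df$parent_i == df$parent_j))
    stop_("self cross present (%s x %s): Method 4 excludes selfs",
          df$parent_i[df$parent_i == df$parent_j][1],
          df$parent_j[df$parent_i == df$parent_j][1])
  swap <- df$parent_i > df$parent_j
  tmp <- df$parent_i[swap]
  df$parent_i[swap] <- df$parent_j[swap]
  df$parent_j[swap] <- tmp
  parents <- sort(unique(c(df$parent_i, df$parent_j)))
  n <- length(parents)
  if (n < 3) stop_("need >= 3 parents")
  expected <- t(combn(parents, 2))
  have <- unique(paste(df$parent_i, df$parent_j))
  missing <- setdiff(paste(expected[, 1], expected[, 2]), have)
  if (length(missing))
    stop_("incomplete half-diallel: missing cross(es) %s",
          paste(missing, collapse = ", "))
  structure(list(data = df, parents = parents, n_parents = n),
            class = "diallel_data")
}

# cross-mean matrix for one sex selection ("pooled" = all replicates)
.cross_means <- function(dd, sex) {
  df <- dd$data
  if (sex != "pooled") df <- df[df$sex == sex, ]
  if (nrow(df) == 0L) stop_("no data for sex '%s'", sex)
  n <- dd$n_parents
  X <- matrix(NA_real_, n, n, dimnames = list(dd$parents, dd$parents))
  agg <- aggregate(df$value,
                   by = list(i = df$parent_i, j = df$parent_j), FUN = mean)
  for (k in seq_len(nrow(agg))) {
    X[agg$i[k], agg$j[k]] <- agg$x[k]
    X[agg$j[k], agg$i[k]] <- agg$x[k]
  }
  if (any(is.na(X[upper.tri(X)])))
    stop_("incomplete half-diallel for sex '%s'", sex)
  X
}

# pooled within-cross error on the vial-mean scale: MS and df of replicate
# vials within cross x sex, plus the (harmonic-mean) replicate count
.replicate_error <- function(dd, sex) {
  df <- dd$data
  if (sex != "pooled") df <- df[df$sex == sex, ]
  cell <- interaction(df$parent_i, df$parent_j, df$sex, drop = TRUE)
  ni <- tabulate(cell)
  dfe <- sum(ni - 1L)
  if (dfe < 1) return(list(ms = NA_real_, df = 0L, r = mean(ni)))
  cm <- tapply(df$value, cell, mean)
  ss <- sum((df$value - cm[cell])^2)
  # replicates behind one entry of the cross-mean matrix
  r_eff <- length(df$value) / nlevels(cell) *
    (if (sex == "pooled") nlevels(cell) / choose(dd$n_parents, 2) else 1)
  list(ms = ss / dfe, df = dfe, r = r_eff)
}

#' Griffing Method 4 combining abilities
#'
#' For a complete half-diallel of `n` parents with cross means `X_ij`:
#' `GCA_i = T_i/(n-2) - SumT/(n(n-2))` and
#' `SCA_ij = X_ij - (T_i + T_j)/(n-2) + SumT/((n-1)(n-2))`, where `T_i` is
#' the sum of mean life spans of all crosses involving parent i and
#' `SumT = sum_i T_i` (twice the sum over all cross means).  The grand
#' mean is `SumT / (n(n-1))` and the reconstruction
#' `X_ij = grand mean + GCA_i + GCA_j + SCA_ij` is exact.
#'
#' Standard errors use the Model 1 (fixed-effects) results
#' `Var(GCA_i) = (n-1)/(n(n-2)) sigma2_m` and
#' `Var(SCA_ij) = (n-3)/(n-1) sigma2_m`, with `sigma2_m` the error
#' variance of a cross mean estimated from the replicate-vial stratum
#' (`MS_rep / r`).
#'
#' @param dd a [diallel_data()] object (or a data frame accepted by it).
#' @param sex `"pooled"` (default; all replicates), `"male"` or
#'   `"female"`.
#' @return list of class `combining_abilities`: `grand_mean`, `gca`
#'   (named vector), `sca` (symmetric zero-diagonal matrix), `se_gca`,
#'   `se_sca`, `T` (row totals), `sum_T`, `df_error`, `sigma2_mean`,
#'   `t_gca`/`p_gca`, `t_sca`/`p_sca`.
#' @export
combining_abilities <- function(dd, sex = c("pooled", SEX_LEVELS)) {
  sex <- match.arg(sex)
  if (!inherits(dd, "diallel_data")) dd <- diallel_data(dd)
  n <- dd$n_parents
  X <- .cross_means(dd, sex)
  Ti <- rowSums(X, na.rm = TRUE)
  sumT <- sum(Ti)
  gca <- Ti / (n - 2) - sumT / (n * (n - 2))
  sca <- matrix(0, n, n, dimnames = dimnames(X))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sca[i, j] <- X[i, j] - (Ti[i] + Ti[j]) / (n - 2) +
      sumT / ((n - 1) * (n - 2))
    sca[j, i] <- sca[i, j]
  }
  gm <- sumT / (n * (n - 1))
  err <- .replicate_error(dd, sex)
  s2m <- if (is.na(err$ms)) NA_real_ else err$ms / err$r
  se_gca <- sqrt((n - 1) / (n * (n - 2)) * s2m)
  se_sca <- sqrt((n - 3) / (n - 1) * s2m)
  t_gca <- gca / se_gca
  t_sca <- sca / se_sca
  diag(t_sca) <- NA_real_
  p_gca <- 2 * pt(-abs(t_gca), err$df)
  p_sca <- 2 * pt(-abs(t_sca), err$df)
  structure(list(grand_mean = gm, gca = gca, sca = sca,
                 se_gca = se_gca, se_sca = se_sca,
                 T = Ti, sum_T = sumT, sex = sex,
                 sigma2_mean = s2m, df_error = err$df,
                 t_gca = t_gca, p_gca = p_gca,
                 t_sca = t_sca, p_sca = p_sca),
            class = "combining_abilities")
}

#' @export
print.combining_abilities <- function(x, ...) {
  cat(sprintf("Half-diallel combining abilities (%s), n = %d parents\n",
              x$sex, length(x$gca)))
  cat(sprintf("grand mean %.3f; SE(GCA) %.3g, SE(SCA) %.3g (df %d)\n",
              x$grand_mean, x$se_gca, x$se_sca, x$df_error))
  print(round(x$gca, 3))
  invisible(x)
}

#' Half-diallel ANOVA with GCA/SCA partition
#'
#' ANOVA of replicate vial means among the double-heterozygote genotypes.
#' `partition = "genotype"` fits `Y = G + S + G x S + e(rep)` (per-sex:
#' `Y = G + e(rep)`); `partition = "combining"` splits the genotype term
#' into its additive (GCA, df n-1) and interaction (SCA, df n(n-3)/2)
#' components, plus `GCA x S` and `SCA x S` when pooled.  Sums of squares
#' are sequential, so `SS(G) = SS(GCA) + SS(SCA)` exactly; every term is
#' tested over the replicate-vial stratum.
#'
#' @param dd a [diallel_data()] object.
#' @param sex `"pooled"`, `"male"` or `"female"`.
#' @param partition `"combining"` (default) or `"genotype"`.
#' @return an `anova_table` data frame.
#' @export
diallel_anova <- function(dd, sex = c("pooled", SEX_LEVELS),
                          partition = c("combining", "genotype")) {
  sex <- match.arg(sex)
  partition <- match.arg(partition)
  if (!inherits(dd, "diallel_data")) dd <- diallel_data(dd)
  df <- dd$data
  if (sex != "pooled") df <- df[df$sex == sex, ]
  n <- dd$n_parents
  cross <- factor(paste(df$parent_i, df$parent_j, sep = ":"))
  cell <- interaction(cross, df$sex, drop = TRUE)
  if (sum(tabulate(cell) - 1L) < 1)
    stop_("no replication: effects estimable but tests are not")
  y <- df$value
  N <- length(y)
  # additive (GCA) design: one column per parent, 1 if parent in the cross
  A <- matrix(0, N, n, dimnames = list(NULL, dd$parents))
  A[cbind(seq_len(N), match(df$parent_i, dd$parents))] <- 1
  A[cbind(seq_len(N), match(df$parent_j, dd$parents))] <- 1
  one <- matrix(1, N, 1)
  pooled <- sex == "pooled" && length(unique(df$sex)) > 1
  if (pooled) {
    S <- model.matrix(~factor(df$sex))
    Xg <- model.matrix(~0 + cross)
    AS <- A * as.numeric(S[, 2])          # additive x sex
    XgS <- Xg * as.numeric(S[, 2])        # genotype x sex
    Xlist <- list(one, S, cbind(S, A), cbind(S, Xg), cbind(S, Xg, AS),
                  cbind(S, Xg, XgS))
    terms <- c("Sex", "GCA", "SCA", "GCA:Sex", "SCA:Sex")
  } else {
    Xg <- model.matrix(~0 + cross)
    Xlist <- list(one, A, Xg)
    terms <- c("GCA", "SCA")
  }
  rssf <- lapply(Xlist, .rss_fun)
  ranks <- vapply(Xlist, function(X) qr(X)$rank, integer(1))
  ry <- vapply(rssf, function(f) f(y), numeric(1))
  ss <- -diff(ry)
  dfs <- diff(ranks)
  rss_final <- ry[length(ry)]
  df_final <- N - ranks[length(ranks)]
  src <- c(terms, "Error")
  ss <- c(ss, rss_final)
  dfs <- c(dfs, df_final)
  if (partition == "genotype") {
    if (pooled) {
      src2 <- c("Sex", "Genotype", "Genotype:Sex", "Error")
      ss2 <- c(ss[1], ss[2] + ss[3], ss[4] + ss[5], rss_final)
      df2 <- c(dfs[1], dfs[2] + dfs[3], dfs[4] + dfs[5], df_final)
    } else {
      src2 <- c("Genotype", "Error")
      ss2 <- c(ss[1] + ss[2], rss_final)
      df2 <- c(dfs[1] + dfs[2], df_final)
    }
    return(anova_table(src2, df2, ss2 / df2))
  }
  anova_table(src, dfs, ss / dfs)
}

#' Epistasis network edges from significant SCA effects
#'
#' Each significant specific combining ability becomes an edge between its
#' two parents: negative SCA (double heterozygote shorter-lived than
#' expected, closer to wild type) is a *suppressing* interaction, positive
#' SCA (longer-lived than expected) *enhancing*.
#'
#' @param ca a [combining_abilities()] object with standard errors.
#' @param alpha per-edge significance level (default 0.05).
#' @return data frame `parent_i`, `parent_j`, `sex`, `sca`, `se`, `t`,
#'   `p`, `sign` (`"enhancing"`/`"suppressing"`), one row per significant
#'   pair.
#' @export
sca_epistasis_calls <- function(ca, alpha = 0.05) {
  stopifnot(inherits(ca, "combining_abilities"))
  if (is.na(ca$se_sca)) stop_("no SCA standard errors (no replication)")
  n <- length(ca$gca)
  rows <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- ca$p_sca[i, j]
    if (is.na(p) || p >= alpha) next
    rows[[length(rows) + 1L]] <- data.frame(
      parent_i = names(ca$gca)[i], parent_j = names(ca$gca)[j],
      sex = ca$sex, sca = ca$sca[i, j], se = ca$se_sca,
      t = ca$t_sca[i, j], p = p,
      sign = if (ca$sca[i, j] > 0) "enhancing" else "suppressing",
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(parent_i = character(0), parent_j = character(0),
                      sex = character(0), sca = numeric(0), se = numeric(0),
                      t = numeric(0), p = numeric(0), sign = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Project a symmetric matrix onto the valid SCA space
#'
#' Utility for constructing simulation ground truth: returns the closest
#' (least-squares) symmetric zero-diagonal matrix whose off-diagonal row
#' sums vanish, the constraint satisfied by any half-diallel SCA matrix.
#'
#' @param m symmetric matrix (diagonal ignored).
#' @return projected matrix.
#' @export
project_sca <- function(m) {
  n <- nrow(m)
  if (n < 4) stop_("need n >= 4 for a nonzero SCA space")
  m <- (m + t(m)) / 2
  diag(m) <- 0
  # closed form: same double-centring that carries cross means to SCA
  rs <- rowSums(m)
  tot <- sum(rs)
  out <- m - (outer(rs, rep(1, n)) + outer(rep(1, n), rs)) / (n - 2) +
    tot / ((n - 1) * (n - 2))
  diag(out) <- 0
  out
}
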