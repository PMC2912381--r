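# Shared fixture builders and independent oracles.

# random but grid-valid survival records
random_records <- function(n = 200, n_lines = 10, seed = 1,
                           census_interval = 2) {
  set.seed(seed)
  data.frame(
    block = sample(c("B1", "B2"), n, replace = TRUE),
    line = sprintf("L%02d", sample(n_lines, n, replace = TRUE)),
    sex = sample(c("male", "female"), n, replace = TRUE),
    vial = sprintf("V%d", sample(3, n, replace = TRUE)),
    death_age = census_interval * sample(10:40, n, replace = TRUE),
    stringsAsFactors = FALSE)
}

# balanced vial-mean layout: a lines x 2 sexes x r vials
balanced_vm <- function(a = 12, r = 3, mu = 50, s_line = 4, s_ls = 3,
                        s_err = 5, seed = 1) {
  set.seed(seed)
  lines <- sprintf("L%02d", seq_len(a))
  le <- rnorm(a, 0, s_line)
  ls <- matrix(rnorm(2 * a, 0, s_ls), a, 2)
  out <- expand.grid(line = lines, sex = c("male", "female"),
                     vial = sprintf("V%d", seq_len(r)),
                     stringsAsFactors = FALSE)
  i <- match(out$line, lines)
  j <- ifelse(out$sex == "male", 1L, 2L)
  out$mean_lifespan <- mu + le[i] + ls[cbind(i, j)] +
    rnorm(nrow(out), 0, s_err)
  out$block <- "B1"
  out
}

# independent grouping oracle for vial means: explicit double loop
vial_means_oracle <- function(records) {
  keys <- unique(records[, c("block", "line", "sex", "vial")])
  keys <- keys[order(keys$block, keys$line, keys$sex, keys$vial), ]
  res <- keys
  res$mean_lifespan <- NA_real_
  res$n_flies <- NA_integer_
  for (k in seq_len(nrow(keys))) {
    sel <- records$block == keys$block[k] & records$line == keys$line[k] &
      records$sex == keys$sex[k] & records$vial == keys$vial[k]
    res$mean_lifespan[k] <- mean(records$death_age[sel])
    res$n_flies[k] <- sum(sel)
  }
  rownames(res) <- NULL
  res
}

# replicate-level half-diallel table from a cross-mean matrix
make_dd <- function(X, reps = 2, noise = 0, seed = 1) {
  set.seed(seed)
  n <- nrow(X)
  parents <- sprintf("P%02d", seq_len(n))
  rows <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    rows[[length(rows) + 1L]] <- data.frame(
      parent_i = parents[i], parent_j = parents[j], sex = "female",
      vial = seq_len(reps), value = X[i, j] + rnorm(reps, 0, noise),
      stringsAsFactors = FALSE)
  }
  diallel_data(do.call(rbind, rows))
}

# brute-force least-squares oracle for half-diallel combining abilities:
# fit mean + additive parent effects (sum-to-zero) by normal equations,
# then take the per-cross residual as the interaction effect
diallel_ls_oracle <- function(X) {
  n <- nrow(X)
  pairs <- t(combn(n, 2))
  y <- X[pairs]
  # design: intercept + n parent columns; impose sum(g) = 0 by augmentation
  D <- matrix(0, nrow(pairs), n + 1)
  D[, 1] <- 1
  for (k in seq_len(nrow(pairs))) D[k, 1 + pairs[k, ]] <- 1
  Daug <- rbind(D, c(0, rep(1, n)))          # constraint row, weight large
  yaug <- c(y, 0)
  w <- c(rep(1, length(y)), 1e6)
  beta <- solve(t(Daug) %*% (w * Daug), t(Daug) %*% (w * yaug))
  mu <- beta[1]
  g <- beta[-1]
  s <- matrix(0, n, n)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    s[i, j] <- s[j, i] <- y[k] - mu - g[i] - g[j]
  }
  list(mu = mu, g = as.numeric(g), s = s)
}

# direct cell-means sums of squares for the nested individual model
nested_ss_oracle <- function(rec) {
  y <- rec$death_age
  N <- length(y)
  gm <- mean(y)
  cell <- interaction(rec$line, rec$sex)
  vial <- interaction(rec$line, rec$sex, rec$vial)
  ss_total <- sum((y - gm)^2)
  cellm <- tapply(y, cell, mean)[cell]
  vialm <- tapply(y, vial, mean)[vial]
  sexm <- tapply(y, rec$sex, mean)[rec$sex]
  linem <- tapply(y, rec$line, mean)[rec$line]
  list(
    ss_sex = sum((sexm - gm)^2),
    ss_line = sum((linem - gm)^2),
    ss_cells = sum((cellm - gm)^2),
    ss_rep = sum((vialm - cellm)^2),
    ss_within = sum((y - vialm)^2))
}
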