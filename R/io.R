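# Data model and file I/O shared by all analysis stages.
#
# A survival table is a plain data frame with columns
#   block, line, sex, vial, death_age
# one row per fly.  Death ages sit on a census grid: deaths are recorded at
# the census on/after true death, so the recorded census day IS the
# lifespan value (no midpoint correction).  Sex has exactly two levels,
# "male" and "female".  Vial labels are unique within line x sex x block.

SEX_LEVELS <- c("male", "female")

#' Validate a survival record table
#'
#' Checks the invariants of the screen's atomic data: positive death ages
#' aligned to the census grid and strict sex levels. Called by
#' [read_survival_table()] and by the generators, and usable directly on a
#' data frame assembled in R.
#'
#' @param records data frame with columns `block`, `line`, `sex`, `vial`,
#'   `death_age`.
#' @param census_interval census spacing in days (default 2).
#' @param census_start day of the first census (default `census_interval`);
#'   valid death ages are `census_start + k * census_interval`, k >= 0.
#' @return the validated data frame, invisibly classed `survival_records`.
#' @export
validate_survival <- function(records, census_interval = 2,
                              census_start = census_interval) {
  assert_columns(records, c("block", "line", "sex", "vial", "death_age"),
                 "survival table")
  bad_sex <- !(as.character(records$sex) %in% SEX_LEVELS)
  if (any(bad_sex))
    stop_("survival table: unknown sex level '%s' at row %d (allowed: %s)",
          as.character(records$sex)[which(bad_sex)[1]], which(bad_sex)[1],
          paste(SEX_LEVELS, collapse = ", "))
  age <- records$death_age
  if (!is.numeric(age) || any(!is.finite(age)) || any(age <= 0))
    stop_("survival table: death_age must be finite and positive (row %d)",
          which(!is.finite(age) | age <= 0)[1])
  k <- (age - census_start) / census_interval
  off <- abs(k - round(k)) > 1e-8 | k < -1e-8
  if (any(off))
    stop_(paste0("survival table: death_age %g at row %d is not on the ",
                 "census grid (start %g, interval %g)"),
          age[which(off)[1]], which(off)[1], census_start, census_interval)
  out <- records
  out$sex <- factor(as.character(out$sex), levels = SEX_LEVELS)
  class(out) <- unique(c("survival_records", class(out)))
  attr(out, "census_interval") <- census_interval
  attr(out, "census_start") <- census_start
  invisible(out)
}

.sep_for <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a survival table from CSV/TSV
#'
#' The separator is auto-detected from the file extension (`.tsv`/`.txt`
#' tab, otherwise comma); files are UTF-8 with a one-line header and the
#' exact column names `block`, `line`, `sex`, `vial`, `death_age`. Row
#' order is preserved and every record is validated against the census
#' grid and sex-level invariants.
#'
#' @inheritParams validate_survival
#' @param path file to read.
#' @return a `survival_records` data frame.
#' @seealso [write_survival_table()], [vial_means()]
#' @export
read_survival_table <- function(path, census_interval = 2,
                                census_start = census_interval) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  df <- read.csv(path, sep = .sep_for(path), stringsAsFactors = FALSE,
                 fileEncoding = "UTF-8")
  rec <- validate_survival(df, census_interval, census_start)
  # validate_survival returns invisibly; re-expose visibly
  rec
}

#' Write a survival table to CSV/TSV
#'
#' Counterpart of [read_survival_table()]; round-trips are lossless for
#' valid tables.
#'
#' @param records survival record data frame.
#' @param path output path; extension selects the separator.
#' @export
write_survival_table <- function(records, path) {
  assert_columns(records, c("block", "line", "sex", "vial", "death_age"),
                 "survival table")
  out <- as.data.frame(records)[, c("block", "line", "sex", "vial",
                                    "death_age")]
  out$sex <- as.character(out$sex)
  utils::write.table(out, path, sep = .sep_for(path), row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a trait table from CSV/TSV
#'
#' Long-format trait values (raw line means or deviations from control)
#' with columns `line`, `sex`, `age_weeks`, `trait`, `value`.
#'
#' @param path file to read.
#' @return data frame.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  df <- read.csv(path, sep = .sep_for(path), stringsAsFactors = FALSE,
                 fileEncoding = "UTF-8")
  assert_columns(df, c("line", "sex", "age_weeks", "trait", "value"),
                 "trait table")
  bad <- !(as.character(df$sex) %in% SEX_LEVELS)
  if (any(bad))
    stop_("trait table: unknown sex level '%s' at row %d",
          as.character(df$sex)[which(bad)[1]], which(bad)[1])
  df
}

#' Aggregate survival records to replicate-vial means
#'
#' The vial mean is the unit of analysis for all line-level models: one row
#' per (block, line, sex, vial) group with the arithmetic mean death age
#' and the number of contributing flies.
#'
#' @param records survival record data frame (validated or raw; raw input
#'   is validated with default census settings skipped).
#' @return data frame of class `vial_means` with columns `block`, `line`,
#'   `sex`, `vial`, `mean_lifespan`, `n_flies`.
#' @export
vial_means <- function(records) {
  assert_columns(records, c("block", "line", "sex", "vial", "death_age"),
                 "survival table")
  if (nrow(records) == 0L) stop_("vial_means: empty input")
  key <- list(block = records$block, line = records$line,
              sex = as.character(records$sex), vial = records$vial)
  agg <- aggregate(records$death_age, by = key, FUN = mean)
  n <- aggregate(records$death_age, by = key, FUN = length)
  out <- agg
  names(out)[names(out) == "x"] <- "mean_lifespan"
  out$n_flies <- n$x
  out <- out[order(out$block, out$line, out$sex, out$vial), ]
  rownames(out) <- NULL
  out$sex <- factor(out$sex, levels = SEX_LEVELS)
  class(out) <- unique(c("vial_means", class(out)))
  out
}

#' Line-mean deviations from the contemporaneous control
#'
#' Computes, per line and sex, the mean of the line's vial means minus the
#' mean of the control line's vial means for the same sex *within the same
#' experimental block* ("contemporaneous"), plus the pooled deviation (mean
#' of the two sex deviations).  The control line must be present in every
#' block, for every sex in which test lines were assayed.
#'
#' @param vm `vial_means` data frame (or any data frame with columns
#'   `block`, `line`, `sex`, `vial`, `mean_lifespan`).
#' @param control_line label of the co-isogenic control.
#' @return data frame of class `deviation_table` with one row per line x
#'   sex plus one `pooled` row per line: columns `block`, `line`, `sex`
#'   (`male`/`female`/`pooled`), `deviation`, `line_mean`, `control_mean`,
#'   `n_replicates`.
#' @export
deviations_from_control <- function(vm, control_line) {
  assert_columns(vm, c("block", "line", "sex", "vial", "mean_lifespan"),
                 "vial means")
  vm$sex <- as.character(vm$sex)
  if (!control_line %in% vm$line)
    stop_("control line '%s' not present in data", control_line)
  blocks <- unique(vm$block)
  res <- list()
  for (b in blocks) {
    sub <- vm[vm$block == b, ]
    for (s in intersect(SEX_LEVELS, unique(sub$sex))) {
      ss <- sub[sub$sex == s, ]
      ctrl <- ss[ss$line == control_line, ]
      if (nrow(ctrl) == 0L)
        stop_("control line '%s' absent for sex '%s' in block '%s'",
              control_line, s, b)
      cm <- mean(ctrl$mean_lifespan)
      for (ln in unique(ss$line)) {
        lv <- ss$mean_lifespan[ss$line == ln]
        res[[length(res) + 1L]] <- data.frame(
          block = b, line = ln, sex = s,
          deviation = mean(lv) - cm, line_mean = mean(lv),
          control_mean = cm, n_replicates = length(lv),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, res)
  # pooled row: mean of the per-sex deviations present for the line
  pooled <- lapply(split(out, list(out$block, out$line), drop = TRUE),
                   function(d) data.frame(
                     block = d$block[1], line = d$line[1], sex = "pooled",
                     deviation = mean(d$deviation),
                     line_mean = mean(d$line_mean),
                     control_mean = mean(d$control_mean),
                     n_replicates = sum(d$n_replicates),
                     stringsAsFactors = FALSE))
  out <- rbind(out, do.call(rbind, pooled))
  out <- out[order(out$block, out$line, match(out$sex,
                                              c(SEX_LEVELS, "pooled"))), ]
  rownames(out) <- NULL
  class(out) <- unique(c("deviation_table", class(out)))
  out
}
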