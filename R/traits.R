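## Reproductive trait derivation and cohort summaries.

BIRTH_TRAITS <- c("litter_size", "n_live", "n_stillborn", "survival_rate")
WEANING_TRAITS <- c("n_weaned", "n_preweaning_dead", "weaning_rate")
COUNT_TRAITS <- c("litter_size", "n_live", "n_stillborn", "n_weaned",
                  "n_preweaning_dead")
RATE_TRAITS <- c("survival_rate", "weaning_rate")

#' Validate a mating-record table
#'
#' Checks the structural invariants of mating records: nonnegative counts,
#' `n_live + n_stillborn = litter_size`, and — for records with weaning
#' data — `n_weaned + n_preweaning_dead = n_live`.  Weaning fields must be
#' missing (NA) together; missing values encode unavailable weaning
#' follow-up, not zeros.
#'
#' @param matings data.frame with columns `mating_id`, `sow_id`, `boar_id`,
#'   `litter_size`, `n_live`, `n_stillborn`, `n_weaned`,
#'   `n_preweaning_dead`.
#' @param file optional source filename used in error messages; row `i` of
#'   the data is reported as line `i + 1` (header line 1).
#' @return The validated data.frame, invisibly.
#' @export
validateMatings <- function(matings, file = NULL) {
  need <- c("mating_id", "sow_id", "boar_id", "litter_size", "n_live",
            "n_stillborn", "n_weaned", "n_preweaning_dead")
  miss <- setdiff(need, names(matings))
  if (length(miss))
    stop("matings table missing column(s): ", paste(miss, collapse = ", "))
  where <- function(i) {
    if (is.null(file)) paste0("row ", i)
    else paste0(file, " line ", i + 1L)
  }
  fail <- function(i, what)
    stop("invalid mating record (", where(i), ", mating_id=",
         matings$mating_id[i], "): ", what)
  num <- c("litter_size", "n_live", "n_stillborn")
  for (cl in num) {
    bad <- which(is.na(matings[[cl]]) | matings[[cl]] < 0)
    if (length(bad)) fail(bad[1], paste(cl, "must be a nonnegative count"))
  }
  bad <- which(matings$n_live + matings$n_stillborn != matings$litter_size)
  if (length(bad)) fail(bad[1], "n_live + n_stillborn != litter_size")
  w <- matings$n_weaned
  d <- matings$n_preweaning_dead
  bad <- which(is.na(w) != is.na(d))
  if (length(bad))
    fail(bad[1], "n_weaned and n_preweaning_dead must be missing together")
  has <- !is.na(w)
  bad <- which(has & (w < 0 | d < 0))
  if (length(bad)) fail(bad[1], "weaning counts must be nonnegative")
  bad <- which(has & (w + d != matings$n_live))
  if (length(bad)) fail(bad[1], "n_weaned + n_preweaning_dead != n_live")
  invisible(matings)
}

#' Derive the seven reproductive traits per mating
#'
#' Adds `survival_rate = n_live / litter_size` and
#' `weaning_rate = n_weaned / n_live` to a validated mating table.  A rate
#' is missing when its denominator is zero or its inputs are missing.
#'
#' @inheritParams validateMatings
#' @return The input data.frame with `survival_rate` and `weaning_rate`
#'   columns appended (values in `[0, 1]` or NA).
#' @export
deriveTraits <- function(matings) {
  validateMatings(matings)
  matings$survival_rate <- ifelse(matings$litter_size > 0,
                                  matings$n_live / matings$litter_size,
                                  NA_real_)
  matings$weaning_rate <- ifelse(!is.na(matings$n_weaned) & matings$n_live > 0,
                                 matings$n_weaned / matings$n_live, NA_real_)
  matings
}

#' Cohort-level trait summary
#'
#' Per-trait mean and standard error over a mating cohort, in the layout of
#' a reproductive-performance summary table.  Birth traits are summarised
#' over all records, weaning traits only over records with weaning data.
#' Cohort survival and weaning rates are reported as percentages; the
#' default is the pooled ratio (total live / total born; total weaned /
#' total live among weaning-complete records), with the mean of per-mating
#' ratios available as an alternative.
#'
#' @inheritParams validateMatings
#' @param rateMode `"pooled"` or `"per-mating"`.
#' @return data.frame: `stage`, `trait`, `n`, `mean`, `se` (SE is NA for
#'   the pooled rates, which are ratios, not means).
#' @export
cohortSummary <- function(matings, rateMode = c("pooled", "per-mating")) {
  rateMode <- match.arg(rateMode)
  stopifnot(nrow(matings) >= 1)
  tv <- deriveTraits(matings)
  wean <- tv[!is.na(tv$n_weaned), , drop = FALSE]
  one <- function(stage, trait, x) {
    x <- x[!is.na(x)]
    data.frame(stage = stage, trait = trait, n = length(x), mean = mean(x),
               se = stats::sd(x) / sqrt(length(x)), stringsAsFactors = FALSE)
  }
  rate <- function(stage, trait, num, den, per) {
    v <- if (rateMode == "pooled") {
      if (sum(den) > 0) 100 * sum(num) / sum(den) else NA_real_
    } else 100 * mean(per, na.rm = TRUE)
    data.frame(stage = stage, trait = trait, n = length(den), mean = v,
               se = NA_real_, stringsAsFactors = FALSE)
  }
  out <- rbind(
    one("birth", "litter_size", tv$litter_size),
    one("birth", "n_live", tv$n_live),
    one("birth", "n_stillborn", tv$n_stillborn),
    rate("birth", "survival_rate", tv$n_live, tv$litter_size,
         tv$survival_rate),
    if (nrow(wean)) rbind(
      one("weaning", "n_weaned", wean$n_weaned),
      one("weaning", "n_preweaning_dead", wean$n_preweaning_dead),
      rate("weaning", "weaning_rate", wean$n_weaned, wean$n_live,
           wean$weaning_rate))
  )
  rownames(out) <- NULL
  out
}
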