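## Per-mating dissimilarity scores, range-group binning, sparse-group
## merging, and Spearman correlation of group summaries.

LOCUS_KEYS <- c("SLA-1(*12:01)", "SLA-1(*13:01)", "SLA-3", "SLA-2",
                "DRB1", "DQB1")

.keyLocus <- function(key) sub("\\(.*\\)$", "", key)

.distLookup <- function(m) {
  if (is(m, "AlleleDistanceMatrix")) m@values else as.matrix(m)
}

#' Four-term dissimilarity sum of a mating pair at one locus
#'
#' With sire alleles `{A, a}` and dam alleles `{B, b}`, the per-mating
#' dissimilarity at a locus is the sum of the four cross distances
#' `D = D_AB + D_Ab + D_aB + D_ab`.  Homozygotes repeat their allele, and
#' the sum is zero exactly when all four cross pairs are identical-allele
#' pairs.
#'
#' @param sireAlleles,damAlleles character vectors of length 2 (length-1
#'   input is treated as homozygous and repeated).
#' @param m an [AlleleDistanceMatrix-class] or plain symmetric matrix with
#'   allele-id dimnames.
#' @return The nonnegative score `D`, in substitutions per site.
#' @examples
#' m <- matrix(c(0, .2, .2, 0), 2, dimnames = list(c("x","y"), c("x","y")))
#' pairScore(c("x","x"), c("y","y"), m)  # 0.8
#' @export
pairScore <- function(sireAlleles, damAlleles, m) {
  v <- .distLookup(m)
  if (length(sireAlleles) == 1L) sireAlleles <- rep(sireAlleles, 2L)
  if (length(damAlleles) == 1L) damAlleles <- rep(damAlleles, 2L)
  stopifnot(length(sireAlleles) == 2L, length(damAlleles) == 2L)
  all4 <- c(sireAlleles, damAlleles)
  missing <- setdiff(all4, rownames(v))
  if (length(missing))
    stop("allele(s) absent from distance matrix: ",
         paste(missing, collapse = ", "))
  sum(v[sireAlleles, damAlleles])
}

## Representative SLA-1 alleles of a diplotype under one duplicated-gene
## variant: carriers of both duplicated alleles are represented by
## `variant`; other haplotypes keep their single allele.
.diplotypeAlleles <- function(registry, haps, lc, variant = NULL) {
  vapply(haps, function(hp) {
    haplotypeAlleles(registry, hp, lc, sla1Variant = variant)[1]
  }, character(1), USE.NAMES = FALSE)
}

#' SLA-1 score under each duplicated-gene variant
#'
#' Haplotypes of the Hp-35 family carry two SLA-1 alleles (`*12:01` and
#' `*13:01`), so the SLA-1 score of a mating is computed twice: once
#' substituting `*12:01` for every duplicated carrier and once `*13:01`.
#' Matings with no duplicated-carrier haplotype give two equal values.
#'
#' @param sireHps,damHps the two haplotype ids of sire and dam.
#' @param registry a [HaplotypeRegistry-class].
#' @param m SLA-1 distance matrix.
#' @return Named numeric vector `SLA-1(*12:01)`, `SLA-1(*13:01)`.
#' @export
sla1VariantScores <- function(sireHps, damHps, registry, m) {
  out <- vapply(SLA1_DUPLICATED, function(v) {
    pairScore(.diplotypeAlleles(registry, sireHps, "SLA-1", v),
              .diplotypeAlleles(registry, damHps, "SLA-1", v), m)
  }, numeric(1))
  names(out) <- sprintf("SLA-1(%s)", sub("^SLA-1", "", SLA1_DUPLICATED))
  out
}

#' Per-mating dissimilarity scores at every locus key
#'
#' Computes the four-term score of each mating for the six locus keys: the
#' two SLA-1 duplicated-gene variants, SLA-3, SLA-2, DRB1 and DQB1.
#' Distinct (sire diplotype, dam diplotype) combinations are computed once
#' and reused.
#'
#' @param matings data.frame with `sow_id`, `boar_id`.
#' @param animals data.frame with `animal_id`, `sex`, `hap1`, `hap2`.
#' @param registry a [HaplotypeRegistry-class].
#' @param matrices named list of distance matrices for loci `SLA-1`,
#'   `SLA-3`, `SLA-2`, `DRB1`, `DQB1` ([AlleleDistanceMatrix-class] or
#'   plain matrices).
#' @return Numeric matrix, one row per mating, one column per locus key.
#' @export
matingScores <- function(matings, animals, registry, matrices) {
  .checkAnimals(animals, registry)
  miss <- setdiff(SLA_LOCI, names(matrices))
  if (length(miss))
    stop("missing distance matrix for locus: ", paste(miss, collapse = ", "))
  i <- match(matings$sow_id, animals$animal_id)
  j <- match(matings$boar_id, animals$animal_id)
  if (anyNA(i) || anyNA(j))
    stop("mating references unknown animal id(s): ",
         paste(unique(c(matings$sow_id[is.na(i)],
                        matings$boar_id[is.na(j)])), collapse = ", "))
  damHp <- cbind(animals$hap1[i], animals$hap2[i])
  sireHp <- cbind(animals$hap1[j], animals$hap2[j])
  hpIds <- registry@haplotypes$haplotype_id
  ## per-haplotype representative allele at each locus key, as lookup vectors
  lookups <- lapply(LOCUS_KEYS, function(key) {
    lc <- .keyLocus(key)
    variant <- if (lc == "SLA-1")
      SLA1_DUPLICATED[grepl(sub(".*\\(\\*", "", sub("\\)$", "", key)),
                            SLA1_DUPLICATED, fixed = TRUE)] else NULL
    stats::setNames(vapply(hpIds, function(hp)
      haplotypeAlleles(registry, hp, lc, sla1Variant = variant)[1],
      character(1)), hpIds)
  })
  names(lookups) <- LOCUS_KEYS
  out <- vapply(LOCUS_KEYS, function(key) {
    al <- lookups[[key]]
    v <- .distLookup(matrices[[.keyLocus(key)]])
    A <- al[sireHp[, 1]]; a <- al[sireHp[, 2]]
    B <- al[damHp[, 1]]; b <- al[damHp[, 2]]
    missing <- setdiff(unique(c(A, a, B, b)), rownames(v))
    if (length(missing))
      stop("allele(s) absent from ", .keyLocus(key), " matrix: ",
           paste(missing, collapse = ", "))
    v[cbind(A, B)] + v[cbind(A, b)] + v[cbind(a, B)] + v[cbind(a, b)]
  }, numeric(nrow(matings)))
  if (!is.matrix(out)) out <- matrix(out, nrow = nrow(matings))
  dimnames(out) <- list(NULL, LOCUS_KEYS)
  out
}

#' Bin scores into incremental range groups
#'
#' Scores are assigned to a singleton zero group (`|D| <= 1e-9`) and to
#' half-open positive groups `[k w, (k+1) w)` — the first positive group is
#' `(0, w)` — tiling `[0, max score]`.  Group centers are the interval
#' midpoints (`0.05, 0.15, ...` for `w = 0.1`; `0.025, 0.075, ...` for
#' `w = 0.05`) and 0 for the zero group.  Intermediate empty groups are kept
#' (they are dropped later, at the merge step).
#'
#' @param scores nonnegative numeric vector.
#' @param width increment `w` (0.1 for most loci, 0.05 for DQB1).
#' @return list with `groups` (data.frame `lower`, `upper`, `center`, `n`)
#'   and `assignment` (group row index per score).
#' @export
binScores <- function(scores, width = 0.1) {
  if (any(scores < 0)) stop("scores must be nonnegative")
  stopifnot(width > 0)
  zero <- abs(scores) <= 1e-9
  ## guard the half-open boundaries against floating-point ratio error
  k <- ifelse(zero, -1L, floor(round(scores / width, 9)))
  kmax <- max(0L, k)
  groups <- data.frame(
    lower = c(0, (0:kmax) * width),
    upper = c(0, (1:(kmax + 1)) * width),
    center = c(0, round(((0:kmax) + 0.5) * width, 6))
  )
  assignment <- ifelse(zero, 1L, k + 2L)
  groups$n <- as.integer(table(factor(assignment, levels = seq_len(nrow(groups)))))
  list(groups = groups, assignment = assignment)
}

#' Merge sparsely populated range groups
#'
#' Empty groups are dropped, then any group with fewer than `minN` matings
#' is merged into its nearest non-empty neighbour (by center distance,
#' upward on ties) until none remain (or a single group is left).  A merged
#' group spans the union of its parts and its center is the midpoint of the
#' merged span rounded to 2 decimals.
#'
#' @param bins result of [binScores()].
#' @param minN minimum matings per group (default 2: the published rule
#'   merges groups holding a single mating).
#' @return list with `groups` and `assignment` as in [binScores()].
#' @export
mergeSparseGroups <- function(bins, minN = 2) {
  g <- bins$groups
  a <- bins$assignment
  keep <- which(g$n > 0L)
  remap <- match(seq_len(nrow(g)), keep)
  a <- remap[a]
  g <- g[keep, , drop = FALSE]
  rownames(g) <- NULL
  while (nrow(g) > 1L && any(g$n < minN)) {
    i <- which(g$n < minN)[1]
    others <- setdiff(seq_len(nrow(g)), i)
    dist <- abs(g$center[others] - g$center[i])
    nearest <- others[dist == min(dist)]
    j <- max(nearest)  # upward on ties
    lo <- min(g$lower[c(i, j)]); hi <- max(g$upper[c(i, j)])
    tgt <- min(i, j); src <- max(i, j)
    g$lower[tgt] <- lo
    g$upper[tgt] <- hi
    g$center[tgt] <- roundHalfUp((lo + hi) / 2, 2)
    g$n[tgt] <- g$n[i] + g$n[j]
    a[a == src] <- tgt
    a[a > src] <- a[a > src] - 1L
    g <- g[-src, , drop = FALSE]
    rownames(g) <- NULL
  }
  list(groups = g, assignment = a)
}

#' Summarise traits within one range group
#'
#' Count traits are averaged over the group members that carry them; rate
#' traits are the pooled ratio over members (default) or the mean of
#' per-mating ratios, reported as percentages.
#'
#' @param members data.frame of the group's matings, with derived traits
#'   (see [deriveTraits()]).
#' @param traits trait names to summarise.
#' @param rateMode `"pooled"` or `"per-mating"`.
#' @return Named numeric vector of summaries (NA when no member carries the
#'   trait).
#' @export
groupTraitSummary <- function(members,
                              traits = c(BIRTH_TRAITS, WEANING_TRAITS),
                              rateMode = c("pooled", "per-mating")) {
  rateMode <- match.arg(rateMode)
  pooled <- function(num, den) {
    if (sum(den, na.rm = TRUE) > 0)
      100 * sum(num, na.rm = TRUE) / sum(den, na.rm = TRUE)
    else NA_real_
  }
  vapply(traits, function(tr) {
    if (tr %in% COUNT_TRAITS) {
      x <- members[[tr]]
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    } else if (tr == "survival_rate") {
      if (rateMode == "pooled") pooled(members$n_live, members$litter_size)
      else if (all(is.na(members$survival_rate))) NA_real_
      else 100 * mean(members$survival_rate, na.rm = TRUE)
    } else if (tr == "weaning_rate") {
      ok <- !is.na(members$n_weaned)
      if (rateMode == "pooled") pooled(members$n_weaned[ok], members$n_live[ok])
      else if (all(is.na(members$weaning_rate))) NA_real_
      else 100 * mean(members$weaning_rate, na.rm = TRUE)
    } else stop("unknown trait: ", tr)
  }, numeric(1))
}

#' Spearman rank correlation with tie handling
#'
#' Rank correlation on average ranks.  The default two-sided p-value uses
#' the t transform `t = rs sqrt((n-2)/(1-rs^2))` on `n - 2` degrees of
#' freedom; `|rs| = 1` reports the smallest positive double rather than
#' dividing by zero.  For `n <= 9`, an exact p-value from the full
#' permutation distribution is available.
#'
#' @param x,y paired numeric vectors; pairs with a missing value are
#'   dropped.
#' @param pMethod `"t"` or `"permutation"`.
#' @return list with `rs`, `p`, `n`, `method`.
#' @examples
#' spearmanCorrelation(1:5, c(1, 3, 2, 5, 4))$rs  # 0.8
#' @export
spearmanCorrelation <- function(x, y, pMethod = c("t", "permutation")) {
  pMethod <- match.arg(pMethod)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3)
    stop(errorCondition(
      paste0("need at least 3 paired values for a rank correlation (got ",
             n, ")"),
      class = c("sla_insufficient_data", "error", "condition")))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop(errorCondition(
      "rank correlation undefined: zero variance in x or y",
      class = c("sla_undefined_result", "error", "condition")))
  rx <- rank(x); ry <- rank(y)
  rs <- stats::cor(rx, ry)
  if (pMethod == "t") {
    if (1 - rs^2 < 1e-14) {
      p <- .Machine$double.xmin
    } else {
      tstat <- rs * sqrt((n - 2) / (1 - rs^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  } else {
    if (n > 9) stop("exact permutation p-value supported only for n <= 9")
    perms <- .permutations(seq_len(n))
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    rsAll <- as.numeric(matrix(rxc[perms], nrow(perms)) %*% ryc) / denom
    p <- mean(abs(rsAll) >= abs(rs) - 1e-12)
  }
  list(rs = rs, p = p, n = n, method = pMethod)
}

.permCache <- new.env(parent = emptyenv())

.permutations <- function(v) {
  n <- length(v)
  key <- paste0("n", n)
  if (identical(v, seq_len(n)) && !is.null(.permCache[[key]]))
    return(.permCache[[key]])
  res <- if (n == 1L) matrix(v, 1L, 1L) else {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      sub <- .permutations(v[-i])
      out[[i]] <- cbind(v[i], sub, deparse.level = 0)
    }
    do.call(rbind, out)
  }
  if (identical(v, seq_len(n))) .permCache[[key]] <- res
  res
}

#' Run the binned dissimilarity-trait analysis
#'
#' The full pipeline: per-mating four-term scores at the six locus keys,
#' range-group binning (0.1 increments; 0.05 for DQB1), sparse-group
#' merging, per-group trait summaries, and Spearman correlation of group
#' centers against group summaries.  Birth-stage traits use all matings;
#' weaning-stage traits use only weaning-complete matings, re-binned on
#' that subset.  Cells whose correlation cannot be computed (fewer than 3
#' groups, or zero variance) are reported with `NA` and a note; the run
#' completes.
#'
#' @inheritParams matingScores
#' @param increments named increment per locus key; defaults to 0.1
#'   everywhere except 0.05 for DQB1.
#' @param minGroupN sparse-merge threshold (see [mergeSparseGroups()]).
#' @param rateMode `"pooled"` or `"per-mating"` group rates.
#' @param pMethod p-value method (see [spearmanCorrelation()]).
#' @return A [SlaAnalysis-class].
#' @export
runAnalysis <- function(matings, animals, registry, matrices,
                        increments = NULL, minGroupN = 2,
                        rateMode = c("pooled", "per-mating"),
                        pMethod = c("t", "permutation")) {
  rateMode <- match.arg(rateMode)
  pMethod <- match.arg(pMethod)
  tv <- deriveTraits(matings)
  inc <- stats::setNames(rep(0.1, length(LOCUS_KEYS)), LOCUS_KEYS)
  inc["DQB1"] <- 0.05
  if (!is.null(increments)) inc[names(increments)] <- increments
  scores <- matingScores(tv, animals, registry, matrices)
  stages <- list(
    birth = list(rows = seq_len(nrow(tv)), traits = BIRTH_TRAITS),
    weaning = list(rows = which(!is.na(tv$n_weaned)),
                   traits = WEANING_TRAITS)
  )
  groupRows <- list()
  corRows <- list()
  series <- list()
  for (stage in names(stages)) {
    rows <- stages[[stage]]$rows
    traits <- stages[[stage]]$traits
    sub <- tv[rows, , drop = FALSE]
    for (key in LOCUS_KEYS) {
      merged <- mergeSparseGroups(binScores(scores[rows, key], inc[[key]]),
                                  minN = minGroupN)
      g <- merged$groups
      summ <- t(vapply(seq_len(nrow(g)), function(gi) {
        groupTraitSummary(sub[merged$assignment == gi, , drop = FALSE],
                          traits, rateMode)
      }, numeric(length(traits))))
      colnames(summ) <- traits
      allTraits <- c(BIRTH_TRAITS, WEANING_TRAITS)
      padded <- matrix(NA_real_, nrow(summ), length(allTraits),
                       dimnames = list(NULL, allTraits))
      padded[, traits] <- summ
      groupRows[[length(groupRows) + 1L]] <- cbind(
        data.frame(stage = stage, locus_key = key, stringsAsFactors = FALSE),
        g, as.data.frame(padded))
      for (tr in traits) {
        ## exact enumeration is limited to 9 groups; larger layouts use the
        ## t transform even under pMethod = "permutation"
        pm <- if (pMethod == "permutation" &&
                  sum(!is.na(summ[, tr])) > 9) "t" else pMethod
        res <- tryCatch(
          spearmanCorrelation(g$center, summ[, tr], pMethod = pm),
          sla_insufficient_data = function(e)
            list(rs = NA_real_, p = NA_real_,
                 n = sum(!is.na(summ[, tr])), method = conditionMessage(e)),
          sla_undefined_result = function(e)
            list(rs = NA_real_, p = NA_real_,
                 n = sum(!is.na(summ[, tr])), method = conditionMessage(e)))
        note <- if (is.na(res$rs)) res$method else ""
        corRows[[length(corRows) + 1L]] <- data.frame(
          stage = stage, locus_key = key, trait = tr, n = res$n,
          rs = res$rs, p = res$p, note = note, stringsAsFactors = FALSE)
        series[[stage]][[key]][[tr]] <-
          list(center = g$center, summary = unname(summ[, tr]))
      }
    }
  }
  new("SlaAnalysis",
      groups = do.call(rbind, groupRows),
      correlations = do.call(rbind, corRows),
      series = series,
      params = list(increments = as.list(inc), min_group_n = minGroupN,
                    rate_mode = rateMode, p_method = pMethod,
                    n_matings_birth = length(stages$birth$rows),
                    n_matings_weaning = length(stages$weaning$rows)))
}

#' @rdname SlaAnalysis-class
#' @export
setMethod("groupTable", "SlaAnalysis", function(x) x@groups)

#' @rdname SlaAnalysis-class
#' @export
setMethod("correlationTable", "SlaAnalysis", function(x) x@correlations)

#' @rdname SlaAnalysis-class
#' @export
setMethod("analysisSeries", "SlaAnalysis", function(x) x@series)

#' @rdname SlaAnalysis-class
#' @export
setMethod("analysisParams", "SlaAnalysis", function(x) x@params)

#' @describeIn SlaAnalysis-class compact display of the correlation grid.
#' @export
setMethod("show", "SlaAnalysis", function(object) {
  co <- object@correlations
  cat(sprintf("SlaAnalysis: %d matings at birth, %d at weaning\n",
              object@params$n_matings_birth,
              object@params$n_matings_weaning))
  for (stage in unique(co$stage)) {
    cat(" stage:", stage, "\n")
    sub <- co[co$stage == stage, ]
    for (tr in unique(sub$trait)) {
      s <- sub[sub$trait == tr, ]
      cat(sprintf("  %-18s %s\n", tr,
                  paste(sprintf("%s: rs=%s p=%s", s$locus_key,
                                ifelse(is.na(s$rs), "NA", sprintf("%.3f", s$rs)),
                                ifelse(is.na(s$p), "NA", sprintf("%.3g", s$p))),
                        collapse = "  ")))
    }
  }
})
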