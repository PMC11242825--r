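## SLA haplotype registry, frequency accounting and homozygosity.

## Round half away from zero, matching how printed percentage tables round.
roundHalfUp <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' The packaged SLA haplotype registry
#'
#' Loads the eleven SLA class I / class II haplotypes of the study herd
#' (eight parental and three recombinant), including the Hp-35 family that
#' carries the duplicated SLA-1 genes (`SLA-1*12:01` and `SLA-1*13:01`), and
#' the dam/sire haplotype counts accumulated over the 650-mating series.
#'
#' @return A [HaplotypeRegistry-class].
#' @examples
#' reg <- slaRegistry()
#' haplotypeIds(reg)
#' @export
slaRegistry <- function() {
  readRegistry(system.file("extdata", "sla_haplotypes.csv",
                           package = "SLAdissim", mustWork = TRUE))
}

#' Read a haplotype registry from CSV
#'
#' @param path CSV with columns `haplotype_id`, `class1_id`, `class2_id`,
#'   `sla1_alleles` (";"-joined, 1 or 2 names), `sla3_allele`,
#'   `sla2_allele`, `drb1_allele`, `dqb1_allele`, `recombinant`, and
#'   optionally `dam_count`, `sire_count`.
#' @return A [HaplotypeRegistry-class].
#' @export
readRegistry <- function(path) {
  h <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(haplotype_id = "character",
                                      class1_id = "character",
                                      class2_id = "character"))
  h$recombinant <- as.logical(h$recombinant)
  reg <- new("HaplotypeRegistry", haplotypes = h)
  validObject(reg)
  reg
}

#' @rdname HaplotypeRegistry-class
#' @export
setMethod("haplotypeIds", "HaplotypeRegistry",
          function(x) x@haplotypes$haplotype_id)

#' @rdname HaplotypeRegistry-class
#' @export
setMethod("haplotypeTable", "HaplotypeRegistry", function(x) x@haplotypes)

#' @describeIn HaplotypeRegistry-class number of haplotypes.
#' @export
setMethod("length", "HaplotypeRegistry", function(x) nrow(x@haplotypes))

#' @describeIn HaplotypeRegistry-class compact display.
#' @export
setMethod("show", "HaplotypeRegistry", function(object) {
  h <- object@haplotypes
  cat(sprintf("HaplotypeRegistry: %d haplotypes (%d recombinant)\n",
              nrow(h), sum(h$recombinant)))
  cat("  ids:", paste(h$haplotype_id, collapse = ", "), "\n")
})

.regRow <- function(registry, hpId) {
  h <- registry@haplotypes
  i <- match(hpId, h$haplotype_id)
  if (is.na(i)) stop("unknown haplotype id: ", hpId)
  h[i, , drop = FALSE]
}

#' Alleles carried by a haplotype at one locus
#'
#' For SLA-1 a haplotype of the duplicated-gene family carries two alleles;
#' `sla1Variant` selects which one represents the haplotype (the analysis is
#' run once per variant).  Other haplotypes ignore `sla1Variant`.
#'
#' @param registry a [HaplotypeRegistry-class].
#' @param hpId haplotype id.
#' @param locus one of `"SLA-1"`, `"SLA-3"`, `"SLA-2"`, `"DRB1"`, `"DQB1"`.
#' @param sla1Variant for SLA-1, the allele to substitute for duplicated
#'   carriers (e.g. `"SLA-1*12:01"`); `NULL` returns all carried alleles.
#' @return Character vector of allele names (length 1, or 2 for duplicated
#'   SLA-1 with `sla1Variant = NULL`).
#' @export
haplotypeAlleles <- function(registry, hpId, locus, sla1Variant = NULL) {
  row <- .regRow(registry, hpId)
  if (locus == "SLA-1") {
    al <- strsplit(row$sla1_alleles, ";", fixed = TRUE)[[1]]
    if (!is.null(sla1Variant) && length(al) > 1L) {
      if (!sla1Variant %in% al)
        stop("variant ", sla1Variant, " not carried by haplotype ", hpId)
      al <- sla1Variant
    }
    return(al)
  }
  col <- switch(locus, "SLA-3" = "sla3_allele", "SLA-2" = "sla2_allele",
                "DRB1" = "drb1_allele", "DQB1" = "dqb1_allele",
                stop("unknown locus: ", locus))
  row[[col]]
}

#' Resolve a two-digit allele call to four digits
#'
#' Low-resolution typing yields two-digit allele groups (e.g. `DQB1*04:XX`)
#' that are disambiguated by the class II haplotype context: the registry
#' supplies the unique four-digit allele that the given class II component
#' carries within the two-digit group.
#'
#' @param allele allele label, either already four-digit (returned
#'   unchanged) or two-digit as `"<locus>*<field1>"` or
#'   `"<locus>*<field1>:XX"`.
#' @param class2Id class II component id (e.g. `"0.11"`), or a full
#'   haplotype id (e.g. `"10.11"`) whose class II part is used.
#' @param registry a [HaplotypeRegistry-class].
#' @return The four-digit allele name.  Unresolvable or ambiguous contexts
#'   raise an error listing the candidates.
#' @examples
#' resolveTwoDigit("DQB1*04:XX", "0.11", slaRegistry())  # DQB1*04:02
#' @export
resolveTwoDigit <- function(allele, class2Id, registry = slaRegistry()) {
  if (!grepl(":XX$", allele) && grepl(":", allele, fixed = TRUE))
    return(allele)  # already high resolution
  stem <- sub(":XX$", "", allele)
  parts <- strsplit(stem, "*", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    stop("allele label must look like '<locus>*<field1>[:XX]': ", allele)
  glocus <- parts[1]
  h <- registry@haplotypes
  ctx <- h[h$class2_id == class2Id | h$haplotype_id == class2Id, , drop = FALSE]
  if (nrow(ctx) == 0L) stop("unknown class II context: ", class2Id)
  col <- switch(glocus, "DRB1" = "drb1_allele", "DQB1" = "dqb1_allele",
                "SLA-1" = "sla1_alleles", "SLA-3" = "sla3_allele",
                "SLA-2" = "sla2_allele", stop("unknown locus: ", glocus))
  cand <- unique(unlist(strsplit(ctx[[col]], ";", fixed = TRUE)))
  hit <- cand[startsWith(cand, paste0(stem, ":"))]
  if (length(hit) == 0L)
    stop("no four-digit allele in group ", allele, " for context ", class2Id,
         " (carried: ", paste(cand, collapse = ", "), ")")
  if (length(hit) > 1L)
    stop("ambiguous two-digit group ", allele, " in context ", class2Id,
         ": candidates ", paste(hit, collapse = ", "))
  hit
}

.checkAnimals <- function(animals, registry) {
  need <- c("animal_id", "sex", "hap1", "hap2")
  miss <- setdiff(need, names(animals))
  if (length(miss))
    stop("animals table missing column(s): ", paste(miss, collapse = ", "))
  if (!all(animals$sex %in% c("sow", "boar")))
    stop("animal sex must be 'sow' or 'boar'")
  known <- registry@haplotypes$haplotype_id
  bad <- setdiff(unique(c(animals$hap1, animals$hap2)), known)
  if (length(bad))
    stop("unregistered haplotype id(s): ", paste(bad, collapse = ", "))
  invisible(animals)
}

#' Haplotype counts over a mating series
#'
#' Each mating contributes the dam's two haplotypes and the sire's two
#' haplotypes, so the denominator is four observations per mating (an
#' animal used in k matings contributes k times).  A per-animal weighting
#' (each animal counted once regardless of use) is available for
#' sensitivity checks.
#'
#' @param matings data.frame with columns `sow_id`, `boar_id` (one row per
#'   mating event).
#' @param animals data.frame with columns `animal_id`, `sex` (`"sow"` /
#'   `"boar"`), `hap1`, `hap2`.
#' @param registry a [HaplotypeRegistry-class].
#' @param weighting `"per-mating"` (default) or `"per-animal"`.
#' @return data.frame with one row per registered haplotype: `haplotype_id`,
#'   `dam_count`, `sire_count`, `count`, `percent` (half-up, 2 decimals);
#'   attribute `denominator` holds the total observation count.
#' @export
matingHaplotypeCounts <- function(matings, animals, registry = slaRegistry(),
                                  weighting = c("per-mating", "per-animal")) {
  weighting <- match.arg(weighting)
  .checkAnimals(animals, registry)
  ids <- registry@haplotypes$haplotype_id
  if (weighting == "per-mating") {
    i <- match(matings$sow_id, animals$animal_id)
    j <- match(matings$boar_id, animals$animal_id)
    if (anyNA(i) || anyNA(j)) {
      bad <- unique(c(matings$sow_id[is.na(i)], matings$boar_id[is.na(j)]))
      stop("mating references unknown animal id(s): ",
           paste(bad, collapse = ", "))
    }
    damHaps <- c(animals$hap1[i], animals$hap2[i])
    sireHaps <- c(animals$hap1[j], animals$hap2[j])
  } else {
    sows <- animals[animals$sex == "sow", ]
    boars <- animals[animals$sex == "boar", ]
    damHaps <- c(sows$hap1, sows$hap2)
    sireHaps <- c(boars$hap1, boars$hap2)
  }
  dam <- as.integer(table(factor(damHaps, levels = ids)))
  sire <- as.integer(table(factor(sireHaps, levels = ids)))
  denom <- length(damHaps) + length(sireHaps)
  out <- data.frame(haplotype_id = ids, dam_count = dam, sire_count = sire,
                    count = dam + sire, stringsAsFactors = FALSE)
  out$percent <- if (denom > 0) roundHalfUp(100 * out$count / denom, 2) else NA_real_
  attr(out, "denominator") <- denom
  out
}

#' Allele frequencies from haplotype counts
#'
#' Pools haplotype counts onto the alleles they carry, per locus.  Alleles
#' shared across haplotypes accumulate (e.g. a DQB1 allele present on three
#' class II components); the two duplicated SLA-1 alleles are carried
#' jointly by every Hp-35-family haplotype and are reported as one pooled
#' row.  Per-locus counts therefore sum to the haplotype denominator.
#'
#' @param counts data.frame with columns `haplotype_id` and `count` (as
#'   returned by [matingHaplotypeCounts()], or the registry's own packaged
#'   counts via `counts = NULL`).
#' @param registry a [HaplotypeRegistry-class].
#' @return data.frame: `locus`, `allele` (", "-joined for the pooled
#'   duplicated pair), `count`, `percent` (half-up, 2 decimals); attribute
#'   `denominator`.
#' @examples
#' af <- alleleFrequencies()   # packaged herd counts
#' subset(af, allele == "DQB1*06:01")$percent  # 41.08
#' @export
alleleFrequencies <- function(counts = NULL, registry = slaRegistry()) {
  h <- registry@haplotypes
  if (is.null(counts)) {
    if (!all(c("dam_count", "sire_count") %in% names(h)))
      stop("registry has no packaged counts; supply `counts`")
    counts <- data.frame(haplotype_id = h$haplotype_id,
                         count = h$dam_count + h$sire_count)
  }
  if (!all(counts$haplotype_id %in% h$haplotype_id))
    stop("counts reference unregistered haplotypes")
  cnt <- counts$count[match(h$haplotype_id, counts$haplotype_id)]
  cnt[is.na(cnt)] <- 0
  denom <- sum(cnt)
  out <- do.call(rbind, lapply(SLA_LOCI, function(lc) {
    key <- vapply(seq_len(nrow(h)), function(i) {
      al <- haplotypeAlleles(registry, h$haplotype_id[i], lc)
      paste(sort(al), collapse = ", ")
    }, character(1))
    agg <- rowsum(cnt, key)
    data.frame(locus = lc, allele = rownames(agg), count = as.numeric(agg),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  out$percent <- if (denom > 0) roundHalfUp(100 * out$count / denom, 2) else NA_real_
  out <- out[out$count > 0 | denom == 0, ]
  rownames(out) <- NULL
  attr(out, "denominator") <- denom
  out
}

#' Homozygosity rate per sex
#'
#' An animal is homozygous when its two haplotype ids are identical (the
#' haplotype spans both the class I and class II components, so this is
#' joint class I + II homozygosity).
#'
#' @param animals data.frame with columns `animal_id`, `sex`, `hap1`, `hap2`.
#' @return data.frame: `sex`, `n`, `n_homozygous`, `percent` (half-up, one
#'   decimal).
#' @export
homozygosityRate <- function(animals) {
  stopifnot(all(c("sex", "hap1", "hap2") %in% names(animals)))
  hom <- animals$hap1 == animals$hap2
  out <- do.call(rbind, lapply(c("sow", "boar"), function(s) {
    sel <- animals$sex == s
    data.frame(sex = s, n = sum(sel), n_homozygous = sum(hom[sel]),
               percent = if (any(sel)) roundHalfUp(100 * mean(hom[sel]), 1)
                         else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
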