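#' @import methods
NULL

## Canonical amino-acid ordering used throughout (PAML order).
AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

## Symbols tolerated in input sequences beyond the 20 amino acids.
AA_MISSING <- c("-", "X")

SLA_LOCI <- c("SLA-1", "SLA-3", "SLA-2", "DRB1", "DQB1")

## The duplicated SLA-1 alleles carried jointly by the Hp-35 family.
SLA1_DUPLICATED <- c("SLA-1*12:01", "SLA-1*13:01")

#' Empirical amino-acid substitution model
#'
#' A time-reversible 20-state substitution model defined by a symmetric
#' exchangeability matrix S and equilibrium frequencies pi, from which the
#' rate matrix Q (Q_ij = S_ij * pi_j, rows summing to zero) is derived and
#' normalised to one expected substitution per site per unit time.  Site-rate
#' heterogeneity is modelled, when \code{gammaShape} is finite, by a
#' continuous Gamma(alpha, alpha) distribution of relative rates.
#'
#' The spectral decomposition of Q is precomputed and cached in the object so
#' transition-probability evaluation is a single reconstruction.
#'
#' @slot name model identifier, e.g. \code{"JTT"}.
#' @slot exchangeabilities symmetric nonnegative 20x20 matrix with zero
#'   diagonal, rows/columns in the order \code{A R N D C Q E G H I L K M F P
#'   S T W Y V}.
#' @slot frequencies equilibrium amino-acid frequencies (length 20, positive,
#'   summing to 1).
#' @slot gammaShape positive shape alpha of the continuous-gamma rate
#'   distribution, or \code{NA_real_} for rate homogeneity.
#' @slot eigenValues eigenvalues of the normalised rate matrix (all <= 0).
#' @slot eigenVectors orthogonal eigenvectors of the symmetrised rate matrix.
#'
#' @seealso [jttModel()], [transitionProbabilities()]
#' @export
setClass("SubstitutionModel",
  representation(
    name = "character",
    exchangeabilities = "matrix",
    frequencies = "numeric",
    gammaShape = "numeric",
    eigenValues = "numeric",
    eigenVectors = "matrix"
  )
)

setValidity("SubstitutionModel", function(object) {
  msg <- character(0)
  S <- object@exchangeabilities
  p <- object@frequencies
  if (!all(dim(S) == c(20L, 20L)))
    msg <- c(msg, "exchangeability matrix must be 20x20")
  else {
    if (max(abs(S - t(S))) > 1e-12) msg <- c(msg, "exchangeabilities must be symmetric")
    if (any(diag(S) != 0)) msg <- c(msg, "exchangeability diagonal must be zero")
    if (any(S < 0)) msg <- c(msg, "exchangeabilities must be nonnegative")
  }
  if (length(p) != 20L || any(p <= 0) || abs(sum(p) - 1) > 1e-8)
    msg <- c(msg, "frequencies must be 20 positive values summing to 1")
  a <- object@gammaShape
  if (length(a) != 1L || (!is.na(a) && (!is.finite(a) || a <= 0)))
    msg <- c(msg, "gammaShape must be a single positive finite value or NA")
  if (length(msg)) msg else TRUE
})

#' Per-locus allele distance matrix
#'
#' Symmetric matrix of pairwise amino-acid distances (expected substitutions
#' per site) between the alleles of one SLA locus.
#'
#' @slot locus locus name (one of SLA-1, SLA-2, SLA-3, DRB1, DQB1, or any
#'   label for synthetic loci).
#' @slot values symmetric numeric matrix with zero diagonal; dimnames are the
#'   allele identifiers.
#' @slot gammaShape gamma shape used when estimating, \code{NA} for none
#'   (provenance; not used in computation).
#' @slot gapMode gap-handling mode used when estimating (provenance).
#' @slot saturated logical matrix flagging pairs whose likelihood was still
#'   increasing at the upper distance bound, or a 0x0 matrix when unknown.
#'
#' @seealso [buildDistanceMatrix()], [summarizeMatrix()], [pairScore()]
#' @export
setClass("AlleleDistanceMatrix",
  representation(
    locus = "character",
    values = "matrix",
    gammaShape = "numeric",
    gapMode = "character",
    saturated = "matrix"
  ),
  prototype(gammaShape = NA_real_, gapMode = NA_character_,
            saturated = matrix(logical(0), 0, 0))
)

setValidity("AlleleDistanceMatrix", function(object) {
  v <- object@values
  msg <- character(0)
  if (length(object@locus) != 1L) msg <- c(msg, "locus must be a single string")
  if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
  ids <- rownames(v)
  if (is.null(ids) || is.null(colnames(v)) || !identical(ids, colnames(v)))
    msg <- c(msg, "values must carry identical row and column allele ids")
  else if (anyDuplicated(ids)) msg <- c(msg, "allele ids must be unique")
  if (nrow(v) > 0) {
    if (any(diag(v) != 0)) msg <- c(msg, "diagonal must be exactly zero")
    if (max(abs(v - t(v))) > 0) msg <- c(msg, "values must be exactly symmetric")
    if (any(v < 0)) msg <- c(msg, "distances must be nonnegative")
  }
  if (length(msg)) msg else TRUE
})

#' Registry of SLA class I / class II haplotypes
#'
#' Holds named haplotypes, each pairing a class I component (alleles at
#' SLA-1, SLA-3, SLA-2) with a class II component (DRB1, DQB1).  The SLA-1
#' slot may carry two alleles (the duplicated-gene Hp-35 family).  Optional
#' dam/sire haplotype counts over the mating series may be attached (as in
#' the published herd table).
#'
#' @slot haplotypes data.frame with columns \code{haplotype_id},
#'   \code{class1_id}, \code{class2_id}, \code{sla1_alleles} (";"-joined,
#'   one or two names), \code{sla3_allele}, \code{sla2_allele},
#'   \code{drb1_allele}, \code{dqb1_allele}, \code{recombinant} (logical),
#'   and optionally \code{dam_count}, \code{sire_count}.
#'
#' @seealso [slaRegistry()], [readRegistry()], [haplotypeAlleles()]
#' @export
setClass("HaplotypeRegistry", representation(haplotypes = "data.frame"))

setValidity("HaplotypeRegistry", function(object) {
  h <- object@haplotypes
  need <- c("haplotype_id", "class1_id", "class2_id", "sla1_alleles",
            "sla3_allele", "sla2_allele", "drb1_allele", "dqb1_allele",
            "recombinant")
  miss <- setdiff(need, names(h))
  if (length(miss))
    return(paste("missing registry columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(h$haplotype_id)) return("haplotype ids must be unique")
  n1 <- lengths(strsplit(h$sla1_alleles, ";", fixed = TRUE))
  if (any(n1 < 1L | n1 > 2L)) return("sla1_alleles must hold 1 or 2 alleles")
  TRUE
})

#' Result of the binned dissimilarity-trait analysis
#'
#' Container for the output of [runAnalysis()]: the range-group layout with
#' per-group trait summaries, the per locus/trait Spearman grid, the
#' group-center series underlying trend figures, and a configuration echo.
#'
#' @slot groups data.frame, one row per (stage, locus key, range group):
#'   bounds, center, mating count, per-trait summaries.
#' @slot correlations data.frame, one row per (stage, locus key, trait):
#'   number of groups used, rs, p, and a note for cells that could not be
#'   computed.
#' @slot series named list of (center, summary) series per stage/locus/trait.
#' @slot params configuration echo (increments, merge threshold, rate mode,
#'   p-value method, gamma shape).
#'
#' @seealso [runAnalysis()], [writeAnalysis()]
#' @export
setClass("SlaAnalysis",
  representation(
    groups = "data.frame",
    correlations = "data.frame",
    series = "list",
    params = "list"
  )
)
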