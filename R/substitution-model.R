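## JTT substitution model and its transition-probability kernel.

#' Construct a substitution model
#'
#' @description
#' `substitutionModel()` builds a [SubstitutionModel-class] from an
#' exchangeability matrix and equilibrium frequencies; `jttModel()` builds
#' the JTT (Jones-Taylor-Thornton) empirical model, whose published
#' exchangeability and frequency tables are taken from the phylogenetics
#' package \pkg{phangorn}.
#'
#' The rate matrix is normalised so that one unit of distance equals one
#' expected amino-acid substitution per site at equilibrium, so distances
#' estimated under the model are in substitutions per site.
#'
#' @param exchangeabilities symmetric nonnegative 20x20 matrix (zero
#'   diagonal) in amino-acid order `A R N D C Q E G H I L K M F P S T W Y V`.
#' @param frequencies equilibrium frequencies, length 20, summing to 1.
#' @param gammaShape positive shape `alpha` of the continuous
#'   Gamma(alpha, alpha) distribution of site rates, or `NA` for rate
#'   homogeneity.  Not stated by typical study reports; the default used
#'   throughout this package is 1.
#' @param name model identifier.
#' @return A [SubstitutionModel-class] object.
#' @examples
#' mod <- jttModel(gammaShape = 1)
#' equilibriumFrequencies(mod)[1:5]
#' @export
substitutionModel <- function(exchangeabilities, frequencies,
                              gammaShape = NA_real_, name = "custom") {
  if (length(gammaShape) != 1L || (!is.na(gammaShape) && !is.finite(gammaShape)))
    stop("gammaShape must be a single finite positive value or NA")
  S <- unname(as.matrix(exchangeabilities))
  p <- unname(as.numeric(frequencies))
  dimnames(S) <- list(AA_ORDER, AA_ORDER)
  names(p) <- AA_ORDER
  ## rate matrix Q_ij = S_ij * pi_j, rows sum to zero, mean rate 1
  Q <- sweep(S, 2, p, "*")
  diag(Q) <- -rowSums(Q)
  Q <- Q / (-sum(p * diag(Q)))
  ## reversibility: B = D^{1/2} Q D^{-1/2} is symmetric, eigen-decomposable
  sp <- sqrt(p)
  B <- Q * (sp %o% (1 / sp))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  new("SubstitutionModel", name = name, exchangeabilities = S,
      frequencies = p, gammaShape = as.numeric(gammaShape),
      eigenValues = pmin(e$values, 0), eigenVectors = e$vectors)
}

.modelCache <- new.env(parent = emptyenv())

#' @rdname substitutionModel
#' @export
jttModel <- function(gammaShape = 1) {
  key <- paste0("JTT_", gammaShape)
  if (!is.null(.modelCache[[key]])) return(.modelCache[[key]])
  jtt <- utils::getFromNamespace(".JTT", "phangorn")
  stopifnot(length(jtt$Q) == 190L, length(jtt$bf) == 20L)
  S <- matrix(0, 20, 20)
  S[lower.tri(S)] <- jtt$Q
  S <- S + t(S)
  mod <- substitutionModel(S, unname(jtt$bf), gammaShape = gammaShape,
                           name = "JTT")
  .modelCache[[key]] <- mod
  mod
}

#' @rdname SubstitutionModel-class
#' @export
setMethod("gammaShape", "SubstitutionModel", function(x) x@gammaShape)

#' @rdname SubstitutionModel-class
#' @export
setMethod("equilibriumFrequencies", "SubstitutionModel",
          function(x) x@frequencies)

#' @describeIn SubstitutionModel-class compact display.
#' @export
setMethod("show", "SubstitutionModel", function(object) {
  gs <- object@gammaShape
  cat(sprintf("%s amino-acid substitution model (%s)\n", object@name,
              if (is.na(gs)) "rate-homogeneous"
              else sprintf("continuous-gamma rates, shape = %g", gs)))
  cat("  20 states, rate matrix normalised to 1 substitution/site/unit\n")
})

#' Transition probabilities at a given distance
#'
#' Computes the 20x20 stochastic matrix `P(d)` of amino-acid transition
#' probabilities at distance `d` substitutions per site.  Without gamma
#' rates this is `exp(Qd)` via the cached spectral decomposition; with a
#' continuous Gamma(alpha, alpha) distribution of site rates the matrix
#' exponential is replaced by its expectation over rates, obtained by
#' applying `g(lambda d) = (1 - lambda d / alpha)^(-alpha)` to the
#' eigenvalues `lambda <= 0` of Q.
#'
#' @param model a [SubstitutionModel-class].
#' @param d nonnegative distance in substitutions per site.
#' @return 20x20 numeric matrix; each row sums to 1, entries are clipped at
#'   zero against round-off, and detailed balance
#'   `pi_i P_ij(d) = pi_j P_ji(d)` holds to numerical precision.
#' @examples
#' P <- transitionProbabilities(jttModel(NA), 0.1)
#' range(rowSums(P))
#' @export
transitionProbabilities <- function(model, d) {
  stopifnot(is(model, "SubstitutionModel"))
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 0)
    stop("distance d must be a single nonnegative number")
  lam <- model@eigenValues
  U <- model@eigenVectors
  a <- model@gammaShape
  g <- if (is.na(a)) exp(lam * d) else (1 - lam * d / a)^(-a)
  sp <- sqrt(model@frequencies)
  P <- (U %*% (g * t(U))) * ((1 / sp) %o% sp)
  P[P < 0] <- 0
  dimnames(P) <- list(AA_ORDER, AA_ORDER)
  P
}

## Transition-probability row for a single ancestor state: avoids forming
## the full matrix inside per-site simulation loops.
.transitionRow <- function(model, d, state) {
  lam <- model@eigenValues
  U <- model@eigenVectors
  a <- model@gammaShape
  g <- if (is.na(a)) exp(lam * d) else (1 - lam * d / a)^(-a)
  sp <- sqrt(model@frequencies)
  p <- as.numeric((U[state, ] * g) %*% t(U)) * sp / sp[state]
  p[p < 0] <- 0
  p
}
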