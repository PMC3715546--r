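# Goldman-Yang codon substitution model: instantaneous rate matrix and
# equilibrium codon frequency schemes.

#' Build a GY94 instantaneous rate matrix
#'
#' Constructs the 61x61 codon rate matrix with entries
#' \eqn{q_{ij} = \pi_j \kappa^{[transition]} \omega^{[nonsynonymous]}}
#' for codon pairs differing at exactly one position, 0 for pairs differing
#' at more than one position, diagonal set to minus the row sum, and the
#' whole matrix scaled so that the expected number of substitutions per
#' unit branch length is 1 at stationarity.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio (>= 0).
#' @param pi Numeric(61) equilibrium codon frequencies summing to 1, in
#'   \code{\link{codonStates}} order. Zero frequencies are tolerated (the
#'   corresponding states are unreachable) with a warning.
#' @return A 61x61 matrix with dimnames \code{codonStates()}.
#' @export
#' @examples
#' Q <- buildRateMatrix(2, 0.5, rep(1/61, 61))
#' max(abs(rowSums(Q)))  # rows sum to zero
buildRateMatrix <- function(kappa, omega, pi) {
  stopifnot(length(pi) == 61L, kappa > 0, omega >= 0)
  if (abs(sum(pi) - 1) > 1e-8) stop("pi must sum to 1")
  if (any(pi < 0)) stop("pi must be non-negative")
  if (any(pi == 0))
    warning("zero codon frequencies: those states are unreachable")
  tab <- .codonTables()
  Q <- matrix(0, 61L, 61L, dimnames = list(tab$states, tab$states))
  Q[tab$single] <- rep(pi, each = 61L)[tab$single]
  Q[tab$single & tab$transition] <-
    Q[tab$single & tab$transition] * kappa
  Q[tab$single & tab$nonsyn] <- Q[tab$single & tab$nonsyn] * omega
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  if (scale > 0) Q <- Q / scale
  Q
}

#' Equilibrium codon frequencies from an alignment
#'
#' \code{"equal"} gives 1/61 for every sense codon; \code{"F1x4"} builds
#' codon frequencies from the overall nucleotide composition; \code{"F3x4"}
#' (the default used in model fits) from the nucleotide composition at each
#' of the three codon positions. Stop codons are excluded and the result
#' renormalized over the 61 sense states. Gaps and Ns are ignored when
#' counting.
#'
#' @param alignment A \linkS4class{CodonAlignment} whose aligned length is
#'   a multiple of 3 (a cleaned alignment), or NULL for \code{"equal"}.
#' @param scheme One of \code{"equal"}, \code{"F1x4"}, \code{"F3x4"}.
#' @return Numeric(61) frequencies in \code{\link{codonStates}} order.
#' @export
codonFrequencies <- function(alignment = NULL,
                             scheme = c("F3x4", "F1x4", "equal")) {
  scheme <- match.arg(scheme)
  states <- codonStates()
  if (scheme == "equal") return(setNames(rep(1 / 61, 61L), states))
  stopifnot(is(alignment, "CodonAlignment"))
  txt <- as.character(alignment@seqs)
  len <- nchar(txt[1])
  if (len %% 3L != 0L)
    stop("alignment length must be a multiple of 3 for F1x4/F3x4")
  mat <- do.call(rbind, strsplit(txt, ""))
  posIdx <- rep(1:3, length.out = len)
  countNuc <- function(cols) {
    v <- mat[, cols, drop = FALSE]
    tab <- table(factor(v[v %in% .NUC], levels = .NUC))
    p <- as.numeric(tab)
    if (sum(p) == 0) rep(0.25, 4) else p / sum(p)
  }
  smat <- do.call(rbind, strsplit(states, ""))
  if (scheme == "F1x4") {
    f <- countNuc(seq_len(len))
    pi <- f[match(smat[, 1], .NUC)] * f[match(smat[, 2], .NUC)] *
      f[match(smat[, 3], .NUC)]
  } else {
    f1 <- countNuc(which(posIdx == 1L))
    f2 <- countNuc(which(posIdx == 2L))
    f3 <- countNuc(which(posIdx == 3L))
    pi <- f1[match(smat[, 1], .NUC)] * f2[match(smat[, 2], .NUC)] *
      f3[match(smat[, 3], .NUC)]
  }
  setNames(pi / sum(pi), states)
}

#' Codon transition probability matrices
#'
#' \eqn{P(t) = \exp(Qt)} for each requested branch length, computed by
#' symmetric eigendecomposition of the reversible GY94 generator.
#'
#' @inheritParams buildRateMatrix
#' @param t Numeric vector of branch lengths (expected substitutions per
#'   codon).
#' @return A list of 61x61 probability matrices, one per element of
#'   \code{t}.
#' @export
transitionMatrices <- function(kappa, omega, pi, t) {
  tab <- .codonTables()
  out <- cl_transition_matrices(kappa, omega, as.numeric(pi),
                                as.numeric(t),
                                tab$single * 1L, tab$transition * 1L,
                                tab$nonsyn * 1L)
  lapply(out, function(P) {
    dimnames(P) <- list(tab$states, tab$states)
    P
  })
}
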