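# Codon state space and substitution bookkeeping for the GY94 machinery.
# Universal nuclear genetic code; stop set {TAA, TAG, TGA} is fixed.

.NUC <- c("A", "C", "G", "T")
.STOPS <- c("TAA", "TAG", "TGA")

.allCodons <- function() {
  g <- expand.grid(p3 = .NUC, p2 = .NUC, p1 = .NUC,
                   stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

#' Sense codon states
#'
#' The 61 sense codons of the universal genetic code, in the fixed order
#' used for all rate matrices and likelihood computations in this package.
#'
#' @return Character vector of 61 codon strings.
#' @export
#' @examples
#' length(codonStates())
codonStates <- function() {
  cods <- .allCodons()
  cods[!cods %in% .STOPS]
}

# Cache of structural tables shared by the rate matrix, the likelihood
# kernel and the simulator: amino acid per codon, and for every ordered
# codon pair whether it is a single-nucleotide change, a transition, and
# a nonsynonymous change.
.codonCache <- new.env(parent = emptyenv())

.codonTables <- function() {
  if (!is.null(.codonCache$tab)) return(.codonCache$tab)
  states <- codonStates()
  n <- length(states)
  mat <- do.call(rbind, strsplit(states, ""))
  aa <- as.character(Biostrings::GENETIC_CODE[states])
  nd <- matrix(0L, n, n)
  for (k in 1:3) nd <- nd + outer(mat[, k], mat[, k], "!=")
  single <- nd == 1L
  # transition iff the single differing pair is A<->G or C<->T
  ts <- matrix(FALSE, n, n)
  for (k in 1:3) {
    purine <- mat[, k] %in% c("A", "G")
    samek <- outer(mat[, k], mat[, k], "==")
    othersame <- nd - outer(mat[, k], mat[, k], "!=") == 0L
    ts <- ts | (single & !samek & othersame & outer(purine, purine, "=="))
  }
  ns <- single & outer(aa, aa, "!=")
  tab <- list(states = states, aa = aa, single = single,
              transition = ts, nonsyn = ns)
  .codonCache$tab <- tab
  tab
}

.isStopCodon <- function(codon) codon %in% .STOPS

# Map one codon string (possibly containing N or -) to a 61-length 0/1
# compatibility vector; N and - are full per-base ambiguity.
.codonPartial <- function(codon) {
  tab <- .codonTables()
  bases <- strsplit(codon, "")[[1]]
  keep <- rep(TRUE, length(tab$states))
  smat <- do.call(rbind, strsplit(tab$states, ""))
  for (k in 1:3) {
    b <- bases[k]
    if (b %in% .NUC) keep <- keep & smat[, k] == b
  }
  as.numeric(keep)
}
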