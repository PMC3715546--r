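# Phylogenetic likelihood of a cleaned codon alignment under branch-class
# GY94 models (Felsenstein pruning, gaps and N as per-sequence ambiguity).

# Split every sequence into codon strings; error on internal stop codons
# (the alignment must be cleaned first).
.codonMatrix <- function(alignment, tips) {
  txt <- as.character(alignment@seqs[tips])
  len <- nchar(txt[1])
  if (len %% 3L != 0L)
    stop("alignment length (", len, ") is not a multiple of 3; ",
         "run stripDisruptions() first")
  nsite <- len %/% 3L
  starts <- 3L * (seq_len(nsite) - 1L) + 1L
  cods <- vapply(txt, function(s) substring(s, starts, starts + 2L),
                 character(nsite))
  if (nsite == 1L) cods <- matrix(cods, nrow = 1L)
  bad <- which(matrix(cods %in% .STOPS, nrow = nsite), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("internal stop codon in '%s' at codon site %d; clean the alignment first",
                 tips[bad[1, 2]], bad[1, 1]))
  cods  # nsite x ntips
}

# Compress codon site columns into unique patterns with weights and build
# the 61 x npat x ntip partial-likelihood cube.
.tipPartials <- function(alignment, tips) {
  cods <- .codonMatrix(alignment, tips)
  key <- apply(cods, 1L, paste, collapse = "|")
  upat <- !duplicated(key)
  weights <- as.numeric(table(factor(key, levels = key[upat])))
  pat <- cods[upat, , drop = FALSE]
  states <- codonStates()
  npat <- nrow(pat)
  cube <- array(0, dim = c(61L, npat, length(tips)))
  ambCache <- new.env(parent = emptyenv())
  for (k in seq_along(tips)) {
    idx <- match(pat[, k], states)
    for (p in seq_len(npat)) {
      if (!is.na(idx[p])) {
        cube[idx[p], p, k] <- 1
      } else {
        cod <- pat[p, k]
        part <- ambCache[[cod]]
        if (is.null(part)) {
          part <- .codonPartial(cod)
          ambCache[[cod]] <- part
        }
        cube[, p, k] <- part
      }
    }
  }
  list(cube = cube, weights = weights)
}

# Postorder edge data for the pruning kernel.
.edgeData <- function(tree) {
  tr <- if (is(tree, "SpeciesTree")) tree@tree else tree
  fg <- if (is(tree, "SpeciesTree")) tree@foreground
        else rep(FALSE, nrow(tr$edge))
  po <- ape::reorder.phylo(tr, "postorder")
  ord <- match(paste(po$edge[, 1], po$edge[, 2]),
               paste(tr$edge[, 1], tr$edge[, 2]))
  list(tree = tr, edge = po$edge, order = ord, foreground = fg[ord])
}

#' Log-likelihood of a codon alignment under a branch-class GY94 model
#'
#' Computes the phylogenetic log-likelihood by Felsenstein pruning over
#' codon sites, with separate omega (dN/dS) classes on background and
#' foreground branches. Gap and N characters are treated as per-sequence
#' ambiguity. The alignment must be cleaned (length divisible by 3, no
#' internal stop codons); sequences not matching a tree tip (such as the
#' functional reference) are ignored.
#'
#' @param alignment A cleaned \linkS4class{CodonAlignment}.
#' @param tree A \linkS4class{SpeciesTree} (or rooted \code{phylo}, all
#'   background); every tip must have a sequence.
#' @param kappa Transition/transversion rate ratio.
#' @param omega Single value, or named vector with elements
#'   \code{background} and \code{foreground}.
#' @param pi Numeric(61) codon frequencies (\code{\link{codonFrequencies}}).
#' @param branchLengths Expected substitutions per codon per edge, in the
#'   tree's edge order; defaults to the tree's own edge lengths.
#' @return The log-likelihood (a finite scalar, or -Inf for impossible
#'   data).
#' @export
codonLogLik <- function(alignment, tree, kappa, omega, pi,
                        branchLengths = NULL) {
  ed <- .edgeData(tree)
  tr <- ed$tree
  miss <- setdiff(tr$tip.label, speciesIds(alignment))
  if (length(miss))
    stop("tree tips missing from alignment: ", paste(miss, collapse = ", "))
  if (is.null(branchLengths)) branchLengths <- tr$edge.length
  if (is.null(branchLengths))
    stop("branch lengths absent from tree and not supplied")
  bl <- branchLengths[ed$order]
  if (length(omega) == 1L && is.null(names(omega)))
    omega <- c(background = unname(omega))
  omegas <- unname(omega["background"])
  classIdx <- rep(1L, nrow(ed$edge))
  if (any(ed$foreground)) {
    if (is.na(omega["foreground"]))
      stop("foreground branches present but no foreground omega supplied")
    omegas <- c(omegas, unname(omega["foreground"]))
    classIdx[ed$foreground] <- 2L
  }
  tp <- .tipPartials(alignment, tr$tip.label)
  tab <- .codonTables()
  ll <- cl_loglik(tp$cube, tp$weights, ed$edge, as.numeric(bl),
                  as.integer(classIdx), kappa, as.numeric(omegas),
                  as.numeric(pi), tab$single * 1L, tab$transition * 1L,
                  tab$nonsyn * 1L, tr$Nnode)
  if (is.nan(ll)) stop("non-finite likelihood")
  ll
}
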