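# Accessors and show methods.

#' @describeIn CodonAlignment-class Aligned sequences as a DNAStringSet.
#' @param x,object A \code{CodonAlignment} (or the class under description).
#' @export
alignedSeqs <- function(x) {
  stopifnot(is(x, "CodonAlignment"))
  x@seqs
}

#' @describeIn CodonAlignment-class Identifier of the functional reference.
#' @export
referenceId <- function(x) {
  stopifnot(is(x, "CodonAlignment"))
  x@referenceId
}

#' @describeIn CodonAlignment-class 0-based frame offset in the reference.
#' @export
frameOffset <- function(x) {
  stopifnot(is(x, "CodonAlignment"))
  x@frameOffset
}

#' @describeIn CodonAlignment-class Sequence identifiers.
#' @export
speciesIds <- function(x) {
  stopifnot(is(x, "CodonAlignment"))
  names(x@seqs)
}

setMethod("show", "CodonAlignment", function(object) {
  cat(sprintf(
    "CodonAlignment: %d sequences, %d columns (reference '%s', frame offset %d)\n",
    length(object@seqs), Biostrings::width(object@seqs)[1],
    object@referenceId, object@frameOffset))
})

#' @describeIn FrameMap-class Reference coordinate per alignment column.
#' @param x,object A \code{FrameMap}.
#' @export
refPositions <- function(x) {
  stopifnot(is(x, "FrameMap"))
  x@refPos
}

#' @describeIn FrameMap-class Codon phase per alignment column.
#' @export
codonPhase <- function(x) {
  stopifnot(is(x, "FrameMap"))
  x@phase
}

setMethod("show", "FrameMap", function(object) {
  cat(sprintf(
    "FrameMap: %d alignment columns, reference CDS length %d (offset %d)\n",
    length(object@refPos), object@refLength, object@frameOffset))
})

#' @describeIn SpeciesTree-class Underlying ape phylo tree.
#' @param x,object A \code{SpeciesTree}.
#' @export
apeTree <- function(x) {
  stopifnot(is(x, "SpeciesTree"))
  x@tree
}

#' @describeIn SpeciesTree-class Logical foreground flag per edge.
#' @export
foregroundEdges <- function(x) {
  stopifnot(is(x, "SpeciesTree"))
  x@foreground
}

#' @describeIn SpeciesTree-class Tips descending from any foreground edge.
#' @export
foregroundTips <- function(x) {
  stopifnot(is(x, "SpeciesTree"))
  tr <- x@tree
  if (!any(x@foreground)) return(character())
  kids <- tr$edge[x@foreground, 2L]
  tips <- unique(unlist(lapply(kids, .tipsBelow, tree = tr)))
  sort(tr$tip.label[tips])
}

setMethod("show", "SpeciesTree", function(object) {
  cat(sprintf("SpeciesTree: %d tips, %d edges (%d foreground)\n",
              length(object@tree$tip.label), nrow(object@tree$edge),
              sum(object@foreground)))
  fg <- foregroundTips(object)
  if (length(fg))
    cat("  foreground tips:", paste(fg, collapse = ", "), "\n")
})

setMethod("show", "CodonFit", function(object) {
  om <- paste(sprintf("%s=%.4f", names(object@omega), object@omega),
              collapse = ", ")
  cat(sprintf("CodonFit [%s]  np = %d  lnL = %.2f\n",
              object@model, object@np, object@logLik))
  cat(sprintf("  kappa = %.3f  omega: %s  (freq %s, converged: %s)\n",
              object@kappa, om, object@freqScheme, object@converged))
})

#' @describeIn CodonFit-class Maximized log-likelihood of a fit.
#' @param x,object A \code{CodonFit}.
#' @export
fitLogLik <- function(x) {
  stopifnot(is(x, "CodonFit"))
  x@logLik
}

#' @describeIn CodonFit-class Free-parameter count of a fit.
#' @export
fitNp <- function(x) {
  stopifnot(is(x, "CodonFit"))
  x@np
}

#' @describeIn CodonFit-class Named omega estimates per branch class.
#' @export
fitOmega <- function(x) {
  stopifnot(is(x, "CodonFit"))
  x@omega
}

#' @describeIn CodonFit-class Estimated kappa.
#' @export
fitKappa <- function(x) {
  stopifnot(is(x, "CodonFit"))
  x@kappa
}

# All tip indices below a node (the node itself when it is a tip).
.tipsBelow <- function(node, tree) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  out <- integer()
  stack <- node
  while (length(stack)) {
    nd <- stack[[1L]]; stack <- stack[-1L]
    kids <- tree$edge[tree$edge[, 1L] == nd, 2L]
    out <- c(out, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  sort(out)
}
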