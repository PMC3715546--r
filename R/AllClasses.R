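setOldClass("phylo")

#' CodonAlignment: aligned coding sequences with a functional reference
#'
#' Holds an aligned set of coding nucleotide sequences (alphabet
#' \code{A,C,G,T,N,-}) together with the identifier of a designated
#' functional reference sequence whose ungapped residues define the codon
#' reading frame, and a 0-based \code{frameOffset} locating codon phase 0
#' within the reference.
#'
#' @slot seqs A \link[Biostrings]{DNAStringSet} of equal-width aligned
#'   sequences.
#' @slot referenceId Character scalar; name of the reference sequence.
#' @slot frameOffset Integer scalar (0-based) where codon phase 0 starts
#'   in the reference's ungapped coordinates.
#'
#' @export
setClass("CodonAlignment",
  slots = c(seqs = "DNAStringSet", referenceId = "character",
            frameOffset = "integer"))

setValidity("CodonAlignment", function(object) {
  msg <- character()
  if (length(object@seqs) < 1L) msg <- c(msg, "alignment has no sequences")
  w <- Biostrings::width(object@seqs)
  if (length(unique(w)) > 1L)
    msg <- c(msg, "aligned sequences must all have equal length")
  if (any(w == 0L)) msg <- c(msg, "sequences must be non-empty")
  nm <- names(object@seqs)
  if (is.null(nm) || anyDuplicated(nm))
    msg <- c(msg, "sequence ids must be present and unique")
  if (length(object@referenceId) != 1L ||
      !object@referenceId %in% nm)
    msg <- c(msg, sprintf("reference id '%s' not found in alignment",
                          paste(object@referenceId, collapse = ",")))
  if (length(object@frameOffset) != 1L || is.na(object@frameOffset) ||
      object@frameOffset < 0L)
    msg <- c(msg, "frameOffset must be a single non-negative integer")
  chars <- unique(unlist(strsplit(as.character(object@seqs), "")))
  bad <- setdiff(chars, c("A", "C", "G", "T", "N", "-"))
  if (length(bad))
    msg <- c(msg, sprintf("illegal characters in alignment: %s",
                          paste(bad, collapse = " ")))
  if (length(msg) == 0L && object@referenceId %in% nm) {
    ref <- gsub("-", "", as.character(object@seqs[[object@referenceId]]))
    if (nchar(ref) <= object@frameOffset) {
      msg <- c(msg, "frameOffset beyond reference length")
    } else {
      cds <- substr(ref, object@frameOffset + 1L, nchar(ref))
      ncod <- nchar(cds) %/% 3L
      if (ncod > 0L) {
        cods <- substring(cds, 3L * (seq_len(ncod) - 1L) + 1L,
                          3L * seq_len(ncod))
        internal <- cods[-length(cods)]
        if (any(.isStopCodon(internal)))
          msg <- c(msg,
            "reference contains an internal stop codon before its terminal stop")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' FrameMap: alignment-column to reference-CDS coordinate map
#'
#' For each alignment column, the 1-based coordinate of the reference base
#' occupying it (NA where the reference is gapped) and the codon phase
#' (0, 1, 2) of that base relative to the frame offset.
#'
#' @slot refPos Integer vector, one per alignment column; NA at reference
#'   gap columns.
#' @slot phase Integer vector parallel to \code{refPos}.
#' @slot refLength Integer; total ungapped reference length.
#' @slot frameOffset Integer; copied from the alignment.
#'
#' @export
setClass("FrameMap",
  slots = c(refPos = "integer", phase = "integer",
            refLength = "integer", frameOffset = "integer"))

setValidity("FrameMap", function(object) {
  msg <- character()
  ok <- !is.na(object@refPos)
  pos <- object@refPos[ok]
  if (length(pos) && any(diff(pos) <= 0L))
    msg <- c(msg, "mapped reference coordinates must be strictly increasing")
  if (length(pos) != object@refLength ||
      (length(pos) && !identical(pos, seq_len(object@refLength))))
    msg <- c(msg, "mapped coordinates must cover 1..refLength exactly once")
  if (any(is.na(object@phase[ok])))
    msg <- c(msg, "phase must be defined wherever refPos is")
  if (length(msg)) msg else TRUE
})

#' SpeciesTree: rooted topology with background/foreground branch classes
#'
#' Wraps an \pkg{ape} \code{phylo} tree (rooted, unique tip labels) and a
#' logical vector marking each edge as foreground (its own dN/dS class in
#' two-ratio models) or background.
#'
#' @slot tree A rooted \code{phylo} object.
#' @slot foreground Logical vector, one element per edge row of
#'   \code{tree$edge}.
#'
#' @export
setClass("SpeciesTree",
  slots = c(tree = "phylo", foreground = "logical"))

setValidity("SpeciesTree", function(object) {
  msg <- character()
  tr <- object@tree
  if (!ape::is.rooted(tr)) msg <- c(msg, "tree must be rooted")
  if (anyDuplicated(tr$tip.label))
    msg <- c(msg, "tip labels must be unique")
  if (length(object@foreground) != nrow(tr$edge))
    msg <- c(msg, "foreground flag must have one element per edge")
  if (anyNA(object@foreground))
    msg <- c(msg, "foreground flags must not be NA")
  if (length(msg)) msg else TRUE
})

#' CodonFit: one branch-model maximum-likelihood fit
#'
#' @slot model One of \code{"one_ratio"}, \code{"two_ratio_free"},
#'   \code{"two_ratio_fixed1"}.
#' @slot np Integer; count of free parameters (branch lengths + kappa +
#'   free omega ratios).
#' @slot logLik Numeric; maximized log-likelihood.
#' @slot kappa Numeric; transition/transversion rate ratio estimate.
#' @slot omega Named numeric; omega per branch class (background and,
#'   for two-ratio models, foreground).
#' @slot branchLengths Numeric; expected substitutions per codon per edge,
#'   ordered as the tree's edge matrix.
#' @slot frequencies Numeric(61); equilibrium codon frequencies used.
#' @slot freqScheme Character; "equal", "F1x4" or "F3x4".
#' @slot converged Logical.
#' @slot nRestarts Integer; optimizer starts used.
#'
#' @export
setClass("CodonFit",
  slots = c(model = "character", np = "integer", logLik = "numeric",
            kappa = "numeric", omega = "numeric",
            branchLengths = "numeric", frequencies = "numeric",
            freqScheme = "character", converged = "logical",
            nRestarts = "integer"))

setValidity("CodonFit", function(object) {
  msg <- character()
  if (!object@model %in% c("one_ratio", "two_ratio_free", "two_ratio_fixed1"))
    msg <- c(msg, "unknown model")
  if (abs(sum(object@frequencies) - 1) > 1e-9)
    msg <- c(msg, "frequencies must sum to 1")
  if (any(object@omega < 0)) msg <- c(msg, "omega must be non-negative")
  if (object@kappa <= 0) msg <- c(msg, "kappa must be positive")
  if (length(msg)) msg else TRUE
})
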