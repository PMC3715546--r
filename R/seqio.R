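# Sequence and tree input/output, and the alignment-column -> reference-CDS
# coordinate map used by every downstream module.

#' Read coding sequences from a FASTA file
#'
#' Identifiers are taken from the header line up to the first whitespace;
#' residues are upper-cased and RNA \code{U} is converted to \code{T}.
#' Records with duplicate ids or characters outside \code{A,C,G,T,N,-} are
#' rejected with the offending record named.
#'
#' @param path Path to a FASTA file.
#' @return A named \link[Biostrings]{DNAStringSet}.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1 functional", "atgAAATGA", ">s2", "ATGAAGTGA"), fa)
#' readCodonFasta(fa)
readCodonFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(raw))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sequence ids: ", paste(unique(dup), collapse = ", "))
  txt <- toupper(as.character(raw))
  txt <- gsub("U", "T", txt, fixed = TRUE)
  for (i in seq_along(txt)) {
    bad <- setdiff(unique(strsplit(txt[i], "")[[1]]),
                   c("A", "C", "G", "T", "N", "-"))
    if (length(bad))
      stop(sprintf("illegal characters in record '%s': %s",
                   ids[i], paste(bad, collapse = " ")))
    if (nchar(txt[i]) == 0L)
      stop(sprintf("empty sequence in record '%s'", ids[i]))
  }
  out <- Biostrings::DNAStringSet(txt)
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param x A named \code{DNAStringSet} or \code{CodonAlignment}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeCodonFasta <- function(x, path) {
  if (is(x, "CodonAlignment")) x <- alignedSeqs(x)
  Biostrings::writeXStringSet(x, filepath = path, width = 70L)
  invisible(path)
}

#' Construct a CodonAlignment
#'
#' @param seqs Named \code{DNAStringSet} (or character vector) of aligned,
#'   equal-width sequences.
#' @param referenceId Name of the functional reference sequence whose
#'   ungapped residues define the reading frame.
#' @param frameOffset 0-based position in the reference where codon phase 0
#'   starts (0 for a sequence that begins in frame).
#' @return A \linkS4class{CodonAlignment}.
#' @export
#' @examples
#' aln <- codonAlignment(c(ref = "ATGAAATGA", sp1 = "ATGAA-TGA"), "ref")
codonAlignment <- function(seqs, referenceId, frameOffset = 0L) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  new("CodonAlignment", seqs = seqs, referenceId = referenceId,
      frameOffset = as.integer(frameOffset))
}

#' Read a rooted species tree from Newick, honouring "#1" foreground tags
#'
#' Branches whose tip or internal node label carries a trailing \code{#1}
#' tag (codeml convention) are marked foreground; all other branches are
#' background. Polytomies are preserved.
#'
#' @param path Path to a Newick file, or a Newick string when \code{text}.
#' @param text Logical; treat \code{path} as Newick text.
#' @return A \linkS4class{SpeciesTree}.
#' @export
#' @examples
#' readSpeciesTree("((A,B)#1,C);", text = TRUE)
readSpeciesTree <- function(path, text = FALSE) {
  nwk <- if (text) path else {
    if (!file.exists(path)) stop("file not found: ", path)
    paste(readLines(path, warn = FALSE), collapse = "")
  }
  if (!nzchar(gsub("\\s", "", nwk))) stop("unreadable or empty Newick input")
  tr <- tryCatch(ape::read.tree(text = nwk),
                 error = function(e) stop("unreadable Newick tree: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("unreadable Newick tree")
  tagged <- function(lab) !is.na(lab) & grepl("#1$", lab)
  ntip <- length(tr$tip.label)
  tipTag <- tagged(tr$tip.label)
  nodeTag <- if (is.null(tr$node.label)) rep(FALSE, tr$Nnode)
             else tagged(tr$node.label)
  tr$tip.label <- sub("\\s*#1$", "", tr$tip.label)
  if (!is.null(tr$node.label))
    tr$node.label <- sub("\\s*#1$", "", tr$node.label)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
               collapse = ", "))
  childTagged <- c(tipTag, nodeTag)
  fg <- childTagged[tr$edge[, 2L]]
  new("SpeciesTree", tree = tr, foreground = fg)
}

#' Construct a SpeciesTree with a foreground designation
#'
#' The foreground may be given as a character vector of tip labels, in
#' which case every branch of the subtree they span (including the stem of
#' their most recent common ancestor, when more than one tip is named) is
#' marked foreground -- the "branches leading to" a lineage convention of
#' branch-model tests. Alternatively a logical vector per edge may be
#' supplied directly.
#'
#' @param tree A rooted \code{phylo} object.
#' @param foreground Character vector of tip labels, logical per-edge
#'   vector, or NULL (all background).
#' @return A \linkS4class{SpeciesTree}.
#' @export
speciesTree <- function(tree, foreground = NULL) {
  stopifnot(inherits(tree, "phylo"))
  ne <- nrow(tree$edge)
  if (is.null(foreground)) {
    fg <- rep(FALSE, ne)
  } else if (is.logical(foreground)) {
    fg <- foreground
  } else {
    miss <- setdiff(foreground, tree$tip.label)
    if (length(miss))
      stop("foreground tips not in tree: ", paste(miss, collapse = ", "))
    tipIdx <- match(foreground, tree$tip.label)
    ntip <- length(tree$tip.label)
    fg <- vapply(seq_len(ne), function(e) {
      below <- .tipsBelow(tree$edge[e, 2L], tree)
      length(below) > 0L && all(below %in% tipIdx)
    }, logical(1))
    # single tip: only its terminal edge; clade: spanned edges + stem
  }
  new("SpeciesTree", tree = tree, foreground = fg)
}

#' Build the alignment-column to reference-CDS coordinate map
#'
#' Walks the reference row of the alignment: every ungapped reference base
#' is assigned its 1-based CDS coordinate (strictly increasing across
#' columns); columns where the reference is gapped (insertions in other
#' sequences) carry no coordinate. Codon phase is computed from the
#' alignment's frame offset.
#'
#' @param alignment A \linkS4class{CodonAlignment}.
#' @return A \linkS4class{FrameMap}.
#' @export
#' @examples
#' aln <- codonAlignment(c(ref = "ATG---AAA", sp = "ATGCCCAAA"), "ref")
#' refPositions(buildFrameMap(aln))
buildFrameMap <- function(alignment) {
  stopifnot(is(alignment, "CodonAlignment"))
  refChars <- strsplit(
    as.character(alignment@seqs[[alignment@referenceId]]), "")[[1]]
  isBase <- refChars != "-"
  refPos <- rep(NA_integer_, length(refChars))
  refPos[isBase] <- seq_len(sum(isBase))
  phase <- rep(NA_integer_, length(refChars))
  phase[isBase] <- (refPos[isBase] - 1L - alignment@frameOffset) %% 3L
  new("FrameMap", refPos = refPos, phase = phase,
      refLength = sum(isBase), frameOffset = alignment@frameOffset)
}
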