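# ORF-disruption scanning: insertions, deletions and premature stop codons
# relative to the functional reference frame, plus the alignment-cleaning
# steps (masking, stripping) that precede selection analysis.

.emptyRecords <- function() {
  data.frame(species = character(), kind = character(),
             ref_position = integer(), length = integer(),
             frameshift = logical(), stringsAsFactors = FALSE)
}

.alignChars <- function(alignment, id) {
  strsplit(as.character(alignment@seqs[[id]]), "")[[1]]
}

# Maximal runs of TRUE in a logical vector -> start/end indices.
.trueRuns <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Scan one sequence for insertions and deletions against the reference
#'
#' Within the region where both the query and the reference are aligned
#' (terminal overhangs and truncations at the alignment ends are excluded
#' as amplification artifacts, not loss evidence), each maximal run of
#' query gaps opposite reference bases yields one deletion record, and
#' each maximal run of reference gaps opposite query bases one insertion
#' record. Deletions are reported at the first deleted reference base;
#' insertions at the last mapped reference coordinate preceding the
#' inserted block. An indel is flagged frameshifting when its length is
#' not a multiple of 3.
#'
#' @param alignment A \linkS4class{CodonAlignment}.
#' @param frameMap The \linkS4class{FrameMap} of \code{alignment}.
#' @param species Sequence id to scan (not the reference).
#' @return A data.frame with columns species, kind, ref_position, length,
#'   frameshift.
#' @export
scanIndels <- function(alignment, frameMap, species) {
  stopifnot(is(alignment, "CodonAlignment"), is(frameMap, "FrameMap"))
  if (!species %in% speciesIds(alignment))
    stop("species not found in alignment: ", species)
  if (identical(species, alignment@referenceId))
    stop("cannot scan the reference against itself")
  q <- .alignChars(alignment, species)
  refPos <- frameMap@refPos
  qBase <- q != "-"
  rBase <- !is.na(refPos)
  if (!any(qBase)) return(.emptyRecords())
  span <- max(which(qBase)[1], which(rBase)[1]) :
          min(tail(which(qBase), 1), tail(which(rBase), 1))
  out <- .emptyRecords()
  # deletions: walk the reference-base columns only, so insertion columns
  # belonging to other sequences cannot split one contiguous deletion
  refCols <- span[rBase[span]]
  if (length(refCols)) {
    runs <- .trueRuns(!qBase[refCols])
    for (i in seq_len(nrow(runs))) {
      cols <- refCols[runs$start[i]:runs$end[i]]
      len <- length(cols)
      out <- rbind(out, data.frame(
        species = species, kind = "deletion",
        ref_position = refPos[cols[1]], length = len,
        frameshift = len %% 3L != 0L, stringsAsFactors = FALSE))
    }
  }
  # insertions: maximal runs of reference-gap columns holding query bases
  insFlag <- logical(length(q))
  insFlag[span] <- !rBase[span] & qBase[span]
  runs <- .trueRuns(insFlag)
  for (i in seq_len(nrow(runs))) {
    len <- runs$end[i] - runs$start[i] + 1L
    before <- refPos[seq_len(runs$start[i] - 1L)]
    before <- before[!is.na(before)]
    out <- rbind(out, data.frame(
      species = species, kind = "insertion",
      ref_position = if (length(before)) tail(before, 1) else 0L,
      length = len, frameshift = len %% 3L != 0L,
      stringsAsFactors = FALSE))
  }
  out[order(out$ref_position), , drop = FALSE]
}

# First-base reference coordinate of the reference's terminal stop codon,
# or NA when the (possibly partial) reference carries none.
.terminalStopPos <- function(alignment) {
  ref <- gsub("-", "",
              as.character(alignment@seqs[[alignment@referenceId]]))
  off <- alignment@frameOffset
  cds <- substr(ref, off + 1L, nchar(ref))
  ncod <- nchar(cds) %/% 3L
  if (ncod == 0L) return(NA_integer_)
  last <- substr(cds, 3L * (ncod - 1L) + 1L, 3L * ncod)
  if (.isStopCodon(last)) off + 3L * (ncod - 1L) + 1L else NA_integer_
}

#' Scan one sequence for premature stop codons
#'
#' In the default \code{frame = "query"} mode the query's ungapped residues
#' are translated in their own running reading frame -- started in phase
#' with the reference at the first aligned position, and therefore shifted
#' downstream of any frameshifting indel exactly as a ribosome would read
#' the pseudogene. In \code{frame = "reference"} mode only query codons
#' aligned to complete reference codons are read; this mode recovers
#' planted stops exactly and is insensitive to frameshifts.
#'
#' Every TAA/TAG/TGA codon found before the reference's terminal stop is
#' reported at the reference coordinate of its first base (or the nearest
#' preceding mapped coordinate when that base sits in an inserted column).
#' Codons containing N (or, in reference mode, a gap) are skipped: a
#' disruption is never called from ambiguity.
#'
#' @inheritParams scanIndels
#' @param frame \code{"query"} (running frame) or \code{"reference"}.
#' @return A data.frame as in \code{\link{scanIndels}}, kind
#'   \code{"premature_stop"}, length 3.
#' @export
scanPrematureStops <- function(alignment, frameMap, species,
                               frame = c("query", "reference")) {
  frame <- match.arg(frame)
  stopifnot(is(alignment, "CodonAlignment"), is(frameMap, "FrameMap"))
  if (!species %in% speciesIds(alignment))
    stop("species not found in alignment: ", species)
  if (identical(species, alignment@referenceId))
    stop("cannot scan the reference against itself")
  q <- .alignChars(alignment, species)
  refPos <- frameMap@refPos
  phase <- frameMap@phase
  termStop <- .terminalStopPos(alignment)
  out <- .emptyRecords()
  addStop <- function(pos) {
    if (!is.na(termStop) && pos >= termStop) return(invisible())
    out <<- rbind(out, data.frame(
      species = species, kind = "premature_stop",
      ref_position = pos, length = 3L, frameshift = FALSE,
      stringsAsFactors = FALSE))
  }
  if (frame == "reference") {
    codonIdx <- which(!is.na(phase) & phase == 0L &
                      refPos > alignment@frameOffset)
    for (c1 in codonIdx) {
      p1 <- refPos[c1]
      c2 <- which(refPos == p1 + 1L)
      c3 <- which(refPos == p1 + 2L)
      if (!length(c2) || !length(c3)) next
      cod <- paste0(q[c1], q[c2], q[c3])
      if (grepl("[-N]", cod)) next
      if (.isStopCodon(cod)) addStop(p1)
    }
    return(out[order(out$ref_position), , drop = FALSE])
  }
  # query (running) frame
  qCols <- which(q != "-")
  if (!length(qCols)) return(out)
  mappedQ <- qCols[!is.na(refPos[qCols])]
  if (!length(mappedQ)) return(out)
  anchor <- mappedQ[1]
  k <- sum(qCols <= anchor)               # query bases up to the anchor
  phase0 <- (phase[anchor] - (k - 1L)) %% 3L
  i0 <- ((3L - phase0) %% 3L) + 1L        # first base with running phase 0
  idx <- i0
  while (idx + 2L <= length(qCols)) {
    cols <- qCols[idx:(idx + 2L)]
    cod <- paste0(q[cols[1]], q[cols[2]], q[cols[3]])
    if (!grepl("N", cod) && .isStopCodon(cod)) {
      p <- refPos[cols[1]]
      if (is.na(p)) {
        prior <- refPos[seq_len(cols[1])]
        prior <- prior[!is.na(prior)]
        p <- if (length(prior)) tail(prior, 1) else 0L
      }
      addStop(p)
    }
    idx <- idx + 3L
  }
  out[order(out$ref_position), , drop = FALSE]
}

#' Scan every sequence for ORF disruptions
#'
#' Convenience wrapper running \code{\link{scanIndels}} and
#' \code{\link{scanPrematureStops}} for each non-reference sequence.
#'
#' @inheritParams scanPrematureStops
#' @param species Sequence ids to scan; defaults to all but the reference.
#' @return A combined disruption data.frame.
#' @export
scanDisruptions <- function(alignment, frameMap = buildFrameMap(alignment),
                            species = NULL,
                            frame = c("query", "reference")) {
  frame <- match.arg(frame)
  if (is.null(species))
    species <- setdiff(speciesIds(alignment), alignment@referenceId)
  recs <- lapply(species, function(sp) {
    rbind(scanIndels(alignment, frameMap, sp),
          scanPrematureStops(alignment, frameMap, sp, frame = frame))
  })
  out <- do.call(rbind, c(list(.emptyRecords()), recs))
  rownames(out) <- NULL
  out
}

#' Classify sequences as functional or nonfunctional
#'
#' A sequence is nonfunctional if and only if it carries at least one
#' ORF-disrupting record (insertion, deletion or premature stop codon).
#'
#' @param records Disruption data.frame from \code{\link{scanDisruptions}}.
#' @param species Character vector of all scanned sequence ids (so that
#'   sequences with zero records are classified functional).
#' @return A data.frame with columns species, status
#'   (functional/nonfunctional) and n_disruptions.
#' @export
classifyFunctional <- function(records, species) {
  n <- vapply(species, function(sp) sum(records$species == sp), integer(1))
  data.frame(species = species,
             status = ifelse(n > 0L, "nonfunctional", "functional"),
             n_disruptions = n, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Remove a reference-coordinate interval from an alignment
#'
#' Drops every alignment column whose reference coordinate falls inside the
#' closed interval \code{[start, end]} (used, e.g., to excise a
#' hypervariable region that would distort selection estimates). Columns
#' where the reference is gapped are retained unless flanked inside the
#' interval; the frame map must be rebuilt afterwards.
#'
#' @param alignment A \linkS4class{CodonAlignment}.
#' @param start,end 1-based reference CDS coordinates, \code{start <= end}.
#' @return A new \linkS4class{CodonAlignment}.
#' @export
maskRegion <- function(alignment, start, end) {
  stopifnot(is(alignment, "CodonAlignment"))
  if (length(start) != 1L || length(end) != 1L || is.na(start) ||
      is.na(end) || start < 1L || end < start)
    stop("invalid mask interval [", start, ", ", end, "]")
  fm <- buildFrameMap(alignment)
  drop <- !is.na(fm@refPos) & fm@refPos >= start & fm@refPos <= end
  if (!any(drop)) return(alignment)
  keep <- which(!drop)
  txt <- vapply(as.character(alignment@seqs), function(s)
    paste(strsplit(s, "")[[1]][keep], collapse = ""), character(1))
  codonAlignment(Biostrings::DNAStringSet(txt), alignment@referenceId,
                 alignment@frameOffset)
}

#' Strip disruptions from an alignment before selection analysis
#'
#' Produces the cleaned codon alignment used for model fitting: columns
#' where the reference is gapped (insertions) are removed, the remaining
#' columns are grouped into complete reference codons, every codon column
#' containing a gap in any sequence is dropped, and any remaining internal
#' stop codon (e.g. a planted premature stop in a nonfunctional sequence)
#' is replaced by missing data (NNN). The result has aligned length
#' divisible by 3 and no sequence contains an internal stop.
#'
#' @param alignment A \linkS4class{CodonAlignment}.
#' @param calls Optional functional-call data.frame from
#'   \code{\link{classifyFunctional}}; when supplied, a warning is issued
#'   if a stop codon had to be removed from a sequence classified
#'   functional (an inconsistency between scan and strip inputs).
#' @return A cleaned \linkS4class{CodonAlignment}.
#' @export
stripDisruptions <- function(alignment, calls = NULL) {
  stopifnot(is(alignment, "CodonAlignment"))
  fm <- buildFrameMap(alignment)
  keep <- which(!is.na(fm@refPos))
  mat <- do.call(rbind, strsplit(as.character(alignment@seqs), ""))
  rownames(mat) <- speciesIds(alignment)
  mat <- mat[, keep, drop = FALSE]
  pos <- fm@refPos[keep]
  off <- alignment@frameOffset
  codon <- (pos - 1L - off) %/% 3L    # codon index; negative = pre-frame
  inFrame <- pos > off
  groups <- split(seq_along(pos)[inFrame], codon[inFrame])
  groups <- Filter(function(g) length(g) == 3L, groups)
  hasGap <- vapply(groups, function(g)
    any(mat[, g, drop = FALSE] == "-"), logical(1))
  groups <- groups[!hasGap]
  ord <- order(vapply(groups, `[`, integer(1), 1L))
  cols <- unlist(groups[ord], use.names = FALSE)
  if (length(cols) == 0L)
    stop("no complete gap-free codon columns remain after stripping")
  mat <- mat[, cols, drop = FALSE]
  # drop the reference's terminal stop codon (codon models have no stop
  # states), then neutralize any remaining stop codon as missing data
  nc <- ncol(mat) %/% 3L
  j <- 3L * (nc - 1L) + 1L
  refLast <- paste0(mat[alignment@referenceId, j],
                    mat[alignment@referenceId, j + 1L],
                    mat[alignment@referenceId, j + 2L])
  if (.isStopCodon(refLast)) {
    mat <- mat[, -(j:(j + 2L)), drop = FALSE]
    nc <- nc - 1L
  }
  if (nc == 0L) stop("no codons remain after stripping")
  stopFixed <- character()
  for (i in seq_len(nrow(mat))) {
    for (cdx in seq_len(nc)) {
      j <- 3L * (cdx - 1L) + 1L
      cod <- paste0(mat[i, j], mat[i, j + 1L], mat[i, j + 2L])
      if (.isStopCodon(cod)) {
        mat[i, j:(j + 2L)] <- "N"
        stopFixed <- c(stopFixed, rownames(mat)[i])
      }
    }
  }
  if (!is.null(calls)) {
    fn <- calls$species[calls$status == "functional"]
    odd <- intersect(unique(stopFixed), fn)
    if (length(odd))
      warning("stop codons removed from sequences classified functional: ",
              paste(odd, collapse = ", "))
  }
  if (nc < 30L)
    warning("fewer than 30 codons remain after stripping; ",
            "selection analysis on this alignment is unreliable")
  txt <- apply(mat, 1L, paste, collapse = "")
  codonAlignment(Biostrings::DNAStringSet(txt), alignment@referenceId, 0L)
}

#' Write a disruption report as TSV
#'
#' @param records Disruption data.frame.
#' @param calls Functional-call data.frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeDisruptionReport <- function(records, calls, path) {
  rep <- merge(records, calls[, c("species", "status")], by = "species",
               all.x = TRUE, sort = FALSE)
  rep <- rep[order(rep$species, rep$ref_position), ]
  write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
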