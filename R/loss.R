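# Shared-disruption grouping and Dollo-style inference of independent vs.
# ancestral gene-loss events on a rooted species tree.

#' Group disruption records into shared-disruption keys
#'
#' Records are grouped by exact key equality on (kind, ref_position,
#' length): identically placed, identically sized disruptions in different
#' species are treated as homologous (inherited from a common ancestor),
#' anything else as independent. An optional position tolerance (in bp)
#' relaxes the position component; it defaults to 0 because fuzzy matching
#' can manufacture false ancestry.
#'
#' @param records Disruption data.frame (from \code{\link{scanDisruptions}}).
#' @param tol Non-negative integer; records of the same kind and length
#'   whose positions differ by at most \code{tol} are merged (single-linkage).
#' @return A data.frame with one row per shared key: kind, ref_position,
#'   length, n_carriers and a comma-separated \code{carriers} column.
#' @export
collectShared <- function(records, tol = 0L) {
  if (nrow(records) == 0L)
    return(data.frame(kind = character(), ref_position = integer(),
                      length = integer(), n_carriers = integer(),
                      carriers = character(), stringsAsFactors = FALSE))
  recs <- records
  recs$group <- NA_integer_
  gid <- 0L
  bykl <- split(seq_len(nrow(recs)),
                paste(recs$kind, recs$length, sep = "|"))
  for (idx in bykl) {
    o <- idx[order(recs$ref_position[idx])]
    for (i in seq_along(o)) {
      if (i == 1L ||
          recs$ref_position[o[i]] - recs$ref_position[o[i - 1L]] > tol) {
        gid <- gid + 1L
      }
      recs$group[o[i]] <- gid
    }
  }
  grp <- split(recs, recs$group)
  out <- do.call(rbind, lapply(grp, function(g) {
    data.frame(kind = g$kind[1], ref_position = min(g$ref_position),
               length = g$length[1],
               n_carriers = length(unique(g$species)),
               carriers = paste(sort(unique(g$species)), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$kind, out$ref_position, out$length), ]
  rownames(out) <- NULL
  out
}

.carrierList <- function(shared) strsplit(shared$carriers, ",", fixed = TRUE)

#' Infer minimum independent gene-loss events under a Dollo model
#'
#' A gene, once pseudogenized, is never regained; a disruption shared by a
#' set of species is evidence that the loss happened on the stem branch of
#' their most recent common ancestor. A candidate ancestral event at a
#' clade is accepted only when every tip of that clade is nonfunctional
#' and all of them carry at least one common disruption key. Each
#' nonfunctional tip is then assigned to the deepest (most ancestral)
#' accepted clade containing it; nonfunctional tips covered by no accepted
#' clade become terminal-branch events. Shared keys whose carrier MRCA
#' clade contains functional tips are reported as conflicts, not events.
#'
#' @param shared Shared-disruption data.frame from \code{\link{collectShared}}.
#' @param calls Functional-call data.frame from
#'   \code{\link{classifyFunctional}}.
#' @param tree A \linkS4class{SpeciesTree} or rooted \code{phylo}; every
#'   carrier must be a tip.
#' @return A list with \code{events} (data.frame: event id, branch as a
#'   comma-separated tip set, covered species, supporting keys),
#'   \code{n_independent}, and \code{conflicts} (keys whose carrier clade
#'   includes functional tips).
#' @export
inferLossEvents <- function(shared, calls, tree) {
  tr <- if (is(tree, "SpeciesTree")) tree@tree else tree
  stopifnot(inherits(tr, "phylo"))
  nf <- calls$species[calls$status == "nonfunctional"]
  missTips <- setdiff(calls$species, tr$tip.label)
  if (length(missTips))
    stop("species not in tree: ", paste(missTips, collapse = ", "))
  carr <- if (nrow(shared)) .carrierList(shared) else list()
  bad <- setdiff(unique(unlist(carr)), tr$tip.label)
  if (length(bad))
    stop("carrier not in tree: ", paste(bad, collapse = ", "))
  ntip <- length(tr$tip.label)

  cladeOf <- function(tips) {
    idx <- match(tips, tr$tip.label)
    node <- if (length(idx) == 1L) idx else ape::getMRCA(tr, idx)
    sort(tr$tip.label[.tipsBelow(node, tr)])
  }
  keyLab <- function(i) sprintf("%s@%d/%d", shared$kind[i],
                                shared$ref_position[i], shared$length[i])

  accepted <- list()       # clade tip-sets keyed by collapsed label
  support <- list()
  conflicts <- character()
  for (i in seq_len(nrow(shared))) {
    clade <- cladeOf(carr[[i]])
    if (!all(clade %in% nf)) {
      if (length(carr[[i]]) > 1L) conflicts <- c(conflicts, keyLab(i))
      next
    }
    if (!setequal(clade, carr[[i]]))
      next  # all-nonfunctional clade but the key is not carried by all tips
    labc <- paste(clade, collapse = ",")
    accepted[[labc]] <- clade
    support[[labc]] <- c(support[[labc]], keyLab(i))
  }
  # each nonfunctional tip -> largest accepted clade containing it
  assign <- setNames(rep(NA_character_, length(nf)), nf)
  sizes <- vapply(accepted, length, integer(1))
  for (labc in names(accepted)[order(-sizes)]) {
    hit <- nf %in% accepted[[labc]] & is.na(assign)
    assign[hit] <- labc
  }
  terminal <- names(assign)[is.na(assign)]
  for (tip in terminal) {
    assign[tip] <- tip
    keys <- if (nrow(shared))
      which(vapply(carr, function(x) tip %in% x, logical(1)) &
            shared$n_carriers == 1L) else integer()
    support[[tip]] <- vapply(keys, keyLab, character(1))
  }
  branches <- unique(assign)
  events <- do.call(rbind, lapply(seq_along(branches), function(k) {
    labc <- branches[k]
    data.frame(event = k, branch = labc,
               covered = paste(sort(names(assign)[assign == labc]),
                               collapse = ","),
               support = paste(support[[labc]], collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(events))
    events <- data.frame(event = integer(), branch = character(),
                         covered = character(), support = character(),
                         stringsAsFactors = FALSE)
  list(events = events, n_independent = nrow(events),
       conflicts = unique(conflicts))
}

#' Write a loss-event report as TSV
#'
#' @param lossEvents Result of \code{\link{inferLossEvents}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeLossReport <- function(lossEvents, path) {
  ev <- lossEvents$events
  ev$conflict_keys <- paste(lossEvents$conflicts, collapse = ";")
  write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
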