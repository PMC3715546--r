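# The per-foreground testing protocol: dataset pruning, the three-model
# battery and chi-square likelihood-ratio tests.

#' Likelihood-ratio test between nested branch models
#'
#' @param logLikNull,logLikAlt Maximized log-likelihoods of the nested and
#'   the more general model.
#' @param df Degrees of freedom (difference in free parameter counts).
#' @param label Optional comparison label (e.g. \code{"B vs. A"}).
#' @return A data.frame with columns comparison, statistic, df, p. A
#'   negative statistic within numerical tolerance (1e-6) is clipped to 0;
#'   larger negative values indicate a failed alternative fit and raise a
#'   warning.
#' @export
#' @examples
#' lrTest(-2432.15, -2430.85, 1)  # p = 0.107
lrTest <- function(logLikNull, logLikAlt, df, label = NA_character_) {
  stopifnot(df >= 1L)
  stat <- 2 * (logLikAlt - logLikNull)
  if (stat < 0) {
    if (stat < -1e-6)
      warning(sprintf(
        "alternative log-likelihood below null by %.3g: alternative fit may not have converged",
        -stat / 2))
    stat <- 0
  }
  data.frame(comparison = label, statistic = stat, df = as.integer(df),
             p = pchisq(stat, df, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Format a p-value as reported (3 decimals, floored display below 0.001)
#'
#' @param p Numeric p-values.
#' @return Character vector such as \code{"0.107"} or \code{"<0.001"}.
#' @export
formatP <- function(p) {
  ifelse(p < 0.001, "<0.001", sprintf("%.3f", round(p, 3)))
}

#' Prune a dataset to one foreground lineage
#'
#' Removes every nonfunctional species outside the foreground lineage (so
#' that other pseudogenes cannot depress or inflate the background omega),
#' prunes the tree to the retained species and re-strips the alignment
#' columns. The functional reference row is kept in the alignment for
#' frame bookkeeping but is not a tree tip.
#'
#' @param alignment A \linkS4class{CodonAlignment} (raw, with indels).
#' @param calls Functional-call data.frame from
#'   \code{\link{classifyFunctional}}.
#' @param tree A \linkS4class{SpeciesTree} or rooted \code{phylo} over the
#'   species in \code{calls}.
#' @param foreground Character vector of foreground species (the lineage
#'   being tested); all must be tree tips.
#' @return A list with elements \code{alignment} (cleaned), \code{tree}
#'   (a \linkS4class{SpeciesTree} with the foreground edges marked) and
#'   \code{removed} (dropped species).
#' @export
pruneDataset <- function(alignment, calls, tree, foreground) {
  tr <- if (is(tree, "SpeciesTree")) tree@tree else tree
  miss <- setdiff(foreground, tr$tip.label)
  if (length(miss))
    stop("foreground species not in tree: ", paste(miss, collapse = ", "))
  nf <- calls$species[calls$status == "nonfunctional"]
  drop <- setdiff(nf, foreground)
  keep <- setdiff(tr$tip.label, drop)
  if (length(keep) < 4L)
    stop("pruning would leave fewer than 4 species (", length(keep), ")")
  prTr <- ape::keep.tip(tr, keep)
  st <- speciesTree(prTr, foreground = intersect(foreground,
                                                 prTr$tip.label))
  ids <- intersect(speciesIds(alignment),
                   c(keep, alignment@referenceId))
  sub <- codonAlignment(alignment@seqs[ids], alignment@referenceId,
                        alignment@frameOffset)
  cleaned <- stripDisruptions(sub)
  list(alignment = cleaned, tree = st, removed = drop)
}

#' Run the three-model battery and LRTs for one foreground lineage
#'
#' Prunes the dataset to the foreground lineage, then fits model A
#' (one-ratio null), model B (two-ratio, free foreground omega) and model
#' C (two-ratio, foreground omega fixed at 1), and reports the B-vs-A and
#' C-vs-B likelihood-ratio tests (each df 1). The interpretation is
#' \code{"relaxed selection"} when B-vs-A is significant but C-vs-B is not
#' (the foreground omega is elevated and indistinguishable from 1),
#' \code{"purifying"} when C-vs-B is significant with the foreground omega
#' estimate below 1, and \code{"no shift"} when B-vs-A is not significant.
#'
#' @inheritParams pruneDataset
#' @param freq Codon frequency scheme for the fits.
#' @param alpha Significance level used for the interpretation field.
#' @param ... Further arguments passed to \code{\link{fitBranchModel}}.
#' @return A list with \code{fits} (named list of \linkS4class{CodonFit}),
#'   \code{lrt} (two-row data.frame), \code{table} (a results-table style
#'   data.frame: model, np, lnL, omega0, omegaX, comparison, p),
#'   \code{interpretation}, \code{nSequences}.
#' @export
runBattery <- function(alignment, calls, tree, foreground,
                       freq = c("F3x4", "F1x4", "equal"), alpha = 0.05,
                       ...) {
  freq <- match.arg(freq)
  pruned <- pruneDataset(alignment, calls, tree, foreground)
  aln <- pruned$alignment
  st <- pruned$tree
  fitA <- fitBranchModel(aln, st, "one_ratio", freq = freq, ...)
  fitB <- fitBranchModel(aln, st, "two_ratio_free", freq = freq, ...)
  fitC <- fitBranchModel(aln, st, "two_ratio_fixed1", freq = freq, ...)
  for (f in list(fitA, fitB, fitC))
    if (!f@converged)
      warning("model ", f@model, " did not converge")
  lrtBA <- lrTest(fitA@logLik, fitB@logLik, fitB@np - fitA@np, "B vs. A")
  lrtCB <- lrTest(fitC@logLik, fitB@logLik, fitB@np - fitC@np, "C vs. B")
  lrt <- rbind(lrtBA, lrtCB)
  omegaFg <- fitB@omega["foreground"]
  interp <- if (lrtBA$p >= alpha) "no shift"
            else if (lrtCB$p >= alpha) "relaxed selection"
            else if (omegaFg < 1) "purifying"
            else "divergent (omega above 1)"
  tab <- data.frame(
    model = c("A. one ratio", "B. two ratios", "C. two ratios, fg = 1"),
    np = c(fitA@np, fitB@np, fitC@np),
    lnL = c(fitA@logLik, fitB@logLik, fitC@logLik),
    omega0 = c(fitA@omega["background"], fitB@omega["background"],
               fitC@omega["background"]),
    omegaX = c(NA, fitB@omega["foreground"], 1),
    comparison = c(NA, "B vs. A", "C vs. B"),
    p = c(NA, lrtBA$p, lrtCB$p),
    stringsAsFactors = FALSE, row.names = NULL)
  list(fits = list(A = fitA, B = fitB, C = fitC), lrt = lrt, table = tab,
       interpretation = interp,
       nSequences = length(st@tree$tip.label),
       removed = pruned$removed)
}

#' Write a battery report as TSV
#'
#' @param battery Result of \code{\link{runBattery}}.
#' @param foreground Label for the tested lineage.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeBatteryReport <- function(battery, foreground, path) {
  tab <- battery$table
  tab$foreground <- foreground
  tab$n_sequences <- battery$nSequences
  tab$p_display <- ifelse(is.na(tab$p), "", formatP(tab$p))
  tab <- tab[, c("foreground", "n_sequences", "model", "np", "lnL",
                 "omega0", "omegaX", "comparison", "p", "p_display")]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
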