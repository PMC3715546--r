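# Synthetic codon evolution with branch-specific selection pressure, and
# planted pseudogenization (shared indels and premature stops) with known
# truth, so the scanner, the loss-event logic and the model fits can all
# be validated without external data.

#' Simulation configuration
#'
#' Bundles and validates the settings of the codon evolution simulator.
#' Defaults emulate a mammalian nuclear gene under purifying selection
#' (background omega 0.2) with a foreground lineage drifting toward
#' neutrality (omega 1), kappa 2, and a pseudogene decay process whose
#' geometric indel lengths (mean ~6.7 bp, about a quarter of events 10 bp
#' or longer) cover the long-deletion scale seen in real pseudogenes.
#'
#' @param tree A \linkS4class{SpeciesTree} with branch lengths (expected
#'   substitutions per codon).
#' @param nCodons Number of codon sites (>= 30).
#' @param kappa Transition/transversion rate ratio.
#' @param pi Numeric(61) codon frequencies or \code{"equal"}.
#' @param omega Named vector: \code{background} and (when the tree has
#'   foreground branches) \code{foreground}.
#' @param refDivergence Branch length from the root to the simulated
#'   functional reference (a sister outgroup standing in for a non-focal
#'   mammal).
#' @param refId Identifier of the reference row.
#' @param lossClades List of character vectors; each is the full tip set
#'   of a clade whose stem branch suffers pseudogenization (a single tip
#'   means a terminal-branch loss).
#' @param indelRate Expected planted indels per loss branch (Poisson).
#' @param indelGeomP Geometric length parameter for indels
#'   (\code{length = rgeom + 1}).
#' @param frameshiftFrac Fraction of indels with length not divisible by 3.
#' @param deletionProb Probability an indel is a deletion.
#' @param stopProb Per-codon probability of conversion to a premature stop
#'   on a loss branch.
#' @param seed Mandatory integer seed; the same config gives byte-identical
#'   output.
#' @return A validated list of class \code{simConfig}.
#' @export
simConfig <- function(tree, nCodons = 300L, kappa = 2, pi = "equal",
                      omega = c(background = 0.2, foreground = 1),
                      refDivergence = 0.1, refId = "Reference",
                      lossClades = list(), indelRate = 2,
                      indelGeomP = 0.15, frameshiftFrac = 2 / 3,
                      deletionProb = 0.7, stopProb = 0.02, seed) {
  if (!is(tree, "SpeciesTree")) tree <- speciesTree(tree)
  stopifnot(nCodons >= 30L, kappa > 0, all(omega >= 0),
            indelGeomP > 0, indelGeomP < 1,
            frameshiftFrac >= 0, frameshiftFrac <= 1,
            deletionProb >= 0, deletionProb <= 1,
            stopProb >= 0, stopProb <= 1)
  if (missing(seed) || !is.finite(seed)) stop("a seed is required")
  if (is.null(tree@tree$edge.length))
    stop("simulation tree must have branch lengths")
  if (identical(pi, "equal")) pi <- setNames(rep(1 / 61, 61), codonStates())
  stopifnot(length(pi) == 61L, abs(sum(pi) - 1) < 1e-8)
  if (any(tree@foreground) && is.na(omega["foreground"]))
    stop("tree has foreground branches but no foreground omega given")
  for (clade in lossClades) {
    bad <- setdiff(clade, tree@tree$tip.label)
    if (length(bad))
      stop("loss clade tips not in tree: ", paste(bad, collapse = ", "))
    below <- tree@tree$tip.label[
      .tipsBelow(if (length(clade) == 1L)
                   match(clade, tree@tree$tip.label)
                 else ape::getMRCA(tree@tree,
                                   match(clade, tree@tree$tip.label)),
                 tree@tree)]
    if (!setequal(below, clade))
      stop("loss clade is not monophyletic: ", paste(clade, collapse = ","))
  }
  structure(list(tree = tree, nCodons = as.integer(nCodons), kappa = kappa,
                 pi = as.numeric(pi), omega = omega,
                 refDivergence = refDivergence, refId = refId,
                 lossClades = lossClades, indelRate = indelRate,
                 indelGeomP = indelGeomP, frameshiftFrac = frameshiftFrac,
                 deletionProb = deletionProb, stopProb = stopProb,
                 seed = as.integer(seed)),
            class = "simConfig")
}

# Sample child codon states given parent states and a transition matrix.
.sampleStates <- function(parent, P) {
  child <- integer(length(parent))
  for (s in unique(parent)) {
    idx <- which(parent == s)
    child[idx] <- sample.int(61L, length(idx), replace = TRUE,
                             prob = P[s, ])
  }
  child
}

# Gillespie realization of one branch for one vector of parent states;
# exact but slow, used to validate the matrix-exponential sampler.
.gillespieStates <- function(parent, Q, t) {
  child <- parent
  for (i in seq_along(parent)) {
    s <- parent[i]
    time <- 0
    repeat {
      rate <- -Q[s, s]
      if (rate <= 0) break
      time <- time + stats::rexp(1, rate)
      if (time > t) break
      probs <- Q[s, ]
      probs[s] <- 0
      s <- sample.int(61L, 1L, prob = probs)
    }
    child[i] <- s
  }
  child
}

#' Simulate a codon alignment on a tree with branch-specific omega
#'
#' Root codons are drawn from the equilibrium frequencies and evolved
#' branch by branch by sampling each site from the GY94 transition matrix
#' \eqn{\exp(Q_{class} t)} (or, with \code{method = "gillespie"}, by exact
#' stochastic simulation of the substitution process; the two agree in
#' distribution and the slower Gillespie mode exists to validate the
#' matrix-exponential sampler). No stop codon is ever produced: the state
#' space is the 61 sense codons. A functional reference row, evolved from
#' the root along a short branch under the background omega, is appended
#' for the scanner's reading frame.
#'
#' @param config A \code{\link{simConfig}}.
#' @param method \code{"matrix"} (default) or \code{"gillespie"}.
#' @return A list: \code{alignment} (a gap-free
#'   \linkS4class{CodonAlignment}), \code{truth} (list with per-class
#'   omega, the per-edge class, an empty planted-record table and the loss
#'   clades to be planted).
#' @export
simulateAlignment <- function(config, method = c("matrix", "gillespie")) {
  method <- match.arg(method)
  stopifnot(inherits(config, "simConfig"))
  set.seed(config$seed)
  st <- config$tree
  tr <- ape::reorder.phylo(st@tree, "cladewise")
  ordEdge <- match(paste(tr$edge[, 1], tr$edge[, 2]),
                   paste(st@tree$edge[, 1], st@tree$edge[, 2]))
  fg <- st@foreground[ordEdge]
  ntip <- length(tr$tip.label)
  nNodes <- ntip + tr$Nnode
  root <- ntip + 1L
  omegaBg <- unname(config$omega["background"])
  omegaFg <- if (!is.na(config$omega["foreground"]))
    unname(config$omega["foreground"]) else omegaBg

  states <- vector("list", nNodes)
  states[[root]] <- sample.int(61L, config$nCodons, replace = TRUE,
                               prob = config$pi)
  Qbg <- buildRateMatrix(config$kappa, omegaBg, config$pi)
  Qfg <- if (any(fg)) buildRateMatrix(config$kappa, omegaFg, config$pi)
         else NULL
  refStates <- if (method == "matrix") {
    Pref <- transitionMatrices(config$kappa, omegaBg, config$pi,
                               config$refDivergence)[[1]]
    .sampleStates(states[[root]], Pref)
  } else {
    .gillespieStates(states[[root]], Qbg, config$refDivergence)
  }
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1L]
    child <- tr$edge[e, 2L]
    om <- if (fg[e]) omegaFg else omegaBg
    states[[child]] <- if (method == "matrix") {
      P <- transitionMatrices(config$kappa, om, config$pi,
                              tr$edge.length[e])[[1]]
      .sampleStates(states[[parent]], P)
    } else {
      .gillespieStates(states[[parent]], if (fg[e]) Qfg else Qbg,
                       tr$edge.length[e])
    }
  }
  cods <- codonStates()
  seqTxt <- vapply(seq_len(ntip), function(i)
    paste(cods[states[[i]]], collapse = ""), character(1))
  names(seqTxt) <- tr$tip.label
  seqTxt[config$refId] <- paste(cods[refStates], collapse = "")
  aln <- codonAlignment(Biostrings::DNAStringSet(seqTxt), config$refId, 0L)
  truth <- list(omega = c(background = omegaBg,
                          foreground = if (any(fg)) omegaFg else NA_real_),
                foregroundEdges = st@foreground,
                records = cbind(.emptyRecords()[, -1, drop = FALSE],
                                data.frame(branch = character(),
                                           carriers = character())),
                lossClades = config$lossClades)
  list(alignment = aln, truth = truth)
}

#' Plant pseudogenization events on designated loss branches
#'
#' For each loss branch the decay events -- indels with geometric lengths
#' and a controlled frameshift fraction, and per-codon premature-stop
#' conversions -- are drawn once and applied identically to every
#' descendant tip, so each planted disruption is shared by descent by
#' exactly the tips below its branch. Every loss branch receives at least
#' one disruption. Events are kept non-overlapping and separated by at
#' least two reference bases (overlapping draws are rejected, up to 100
#' attempts) and away from the alignment ends, so the scanner can recover
#' each planted record exactly.
#'
#' @param alignment Gap-free \linkS4class{CodonAlignment} from
#'   \code{\link{simulateAlignment}}.
#' @param truth Truth list from \code{\link{simulateAlignment}}.
#' @param config The same \code{\link{simConfig}}.
#' @param seed Optional seed for the planting draws; by default the RNG
#'   state left by the simulation is used (the config seed therefore makes
#'   the whole simulate-then-plant pipeline deterministic).
#' @return A list: \code{alignment} (with planted indels and stops) and
#'   \code{truth} with planted records (kind, ref_position, length,
#'   frameshift, branch, carriers).
#' @export
plantPseudogenization <- function(alignment, truth, config, seed = NULL) {
  stopifnot(inherits(config, "simConfig"))
  if (!is.null(seed)) set.seed(seed)
  lossClades <- config$lossClades
  if (!length(lossClades)) return(list(alignment = alignment, truth = truth))
  mat <- do.call(rbind, strsplit(as.character(alignment@seqs), ""))
  rownames(mat) <- speciesIds(alignment)
  refLen <- sum(mat[alignment@referenceId, ] != "-")
  if (any(mat == "-"))
    stop("planting requires a gap-free simulated alignment")
  margin <- 9L
  occupied <- matrix(numeric(0), ncol = 2)   # closed ref intervals + pad
  clash <- function(a, b) {
    nrow(occupied) > 0 &&
      any(a <= occupied[, 2] + 2 & b >= occupied[, 1] - 2)
  }
  reserve <- function(a, b) occupied <<- rbind(occupied, c(a, b))
  drawLen <- function() {
    wantShift <- runif(1) < config$frameshiftFrac
    for (i in 1:200) {
      L <- rgeom(1, config$indelGeomP) + 1L
      if ((L %% 3L != 0L) == wantShift) return(L)
    }
    if (wantShift) 1L else 3L
  }
  records <- data.frame()
  insertions <- list()   # applied last, right to left

  for (ci in seq_along(lossClades)) {
    clade <- lossClades[[ci]]
    branch <- paste(sort(clade), collapse = ",")
    nIndel <- rpois(1, config$indelRate)
    branchRecs <- data.frame()
    for (k in seq_len(nIndel)) {
      placed <- FALSE
      for (attempt in 1:100) {
        L <- drawLen()
        isDel <- runif(1) < config$deletionProb
        if (isDel) {
          if (refLen - L - 2L * margin < 1L) next
          sChoices <- seq.int(margin + 1L, refLen - L - margin + 1L)
          s <- sChoices[sample.int(length(sChoices), 1L)]
          if (clash(s, s + L - 1L)) next
          reserve(s, s + L - 1L)
          mat[clade, s:(s + L - 1L)] <- "-"
          branchRecs <- rbind(branchRecs, data.frame(
            kind = "deletion", ref_position = s, length = L,
            frameshift = L %% 3L != 0L, branch = branch,
            carriers = branch, stringsAsFactors = FALSE))
        } else {
          pChoices <- seq.int(margin + 1L, refLen - margin - 1L)
          p <- pChoices[sample.int(length(pChoices), 1L)]
          if (clash(p, p + 1L)) next
          reserve(p, p + 1L)
          bases <- sample(.NUC, L, replace = TRUE)
          insertions[[length(insertions) + 1L]] <-
            list(after = p, bases = bases, clade = clade)
          branchRecs <- rbind(branchRecs, data.frame(
            kind = "insertion", ref_position = p, length = L,
            frameshift = L %% 3L != 0L, branch = branch,
            carriers = branch, stringsAsFactors = FALSE))
        }
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place a planted indel after 100 attempts")
    }
    # premature stop conversions, reference-frame codons
    nCodon <- refLen %/% 3L
    candidates <- seq.int(ceiling((margin + 1L) / 3) + 1L,
                          nCodon - ceiling(margin / 3) - 1L)
    free <- candidates[!vapply(candidates, function(cd)
      clash(3L * (cd - 1L) + 1L, 3L * cd), logical(1))]
    hit <- free[runif(length(free)) < config$stopProb]
    if (nrow(branchRecs) == 0L && length(hit) == 0L && length(free))
      hit <- free[sample.int(length(free), 1L)]  # a loss branch must disable the gene
    for (cd in hit) {
      a <- 3L * (cd - 1L) + 1L
      reserve(a, a + 2L)
      stopCod <- strsplit(sample(.STOPS, 1L), "")[[1]]
      mat[clade, a:(a + 2L)] <- matrix(stopCod, nrow = length(clade),
                                       ncol = 3L, byrow = TRUE)
      branchRecs <- rbind(branchRecs, data.frame(
        kind = "premature_stop", ref_position = a, length = 3L,
        frameshift = FALSE, branch = branch, carriers = branch,
        stringsAsFactors = FALSE))
    }
    records <- rbind(records, branchRecs)
  }

  # apply insertions right-to-left so earlier coordinates stay valid
  if (length(insertions)) {
    ord <- order(-vapply(insertions, `[[`, numeric(1), "after"))
    for (ins in insertions[ord]) {
      col <- ins$after        # gap-free alignment: ref pos == column
      L <- length(ins$bases)
      block <- matrix("-", nrow = nrow(mat), ncol = L)
      rownames(block) <- rownames(mat)
      block[ins$clade, ] <- matrix(ins$bases, nrow = length(ins$clade),
                                   ncol = L, byrow = TRUE)
      mat <- cbind(mat[, seq_len(col), drop = FALSE], block,
                   mat[, seq.int(col + 1L, ncol(mat)), drop = FALSE])
    }
  }
  txt <- apply(mat, 1L, paste, collapse = "")
  alnOut <- codonAlignment(Biostrings::DNAStringSet(txt),
                           alignment@referenceId, alignment@frameOffset)
  truth$records <- records[order(records$branch, records$ref_position), ]
  rownames(truth$records) <- NULL
  truth$lossClades <- lossClades
  list(alignment = alnOut, truth = truth)
}

#' Write a simulated fixture bundle (FASTA + Newick + truth TSV)
#'
#' @param sim Result of \code{\link{plantPseudogenization}} (or
#'   \code{\link{simulateAlignment}}).
#' @param config The \code{\link{simConfig}} used.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeSimBundle <- function(sim, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "alignment.fasta")
  nwk <- file.path(dir, "tree.nwk")
  tsv <- file.path(dir, "truth.tsv")
  writeCodonFasta(sim$alignment, fa)
  ape::write.tree(config$tree@tree, file = nwk)
  write.table(sim$truth$records, tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(fa, nwk, tsv))
}
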