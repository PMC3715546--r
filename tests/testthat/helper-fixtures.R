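# Shared fixtures and independent oracles.

# An 8-tip balanced tree used by the simulation-based tests; the (A,B)
# clade is the foreground lineage.
eightTipTree <- function(fg = c("A", "B")) {
  nwk <- paste0("(((A:0.1,B:0.1):0.05,(C:0.1,D:0.1):0.05):0.05,",
                "((E:0.1,F:0.1):0.05,(G:0.1,H:0.1):0.05):0.05);")
  speciesTree(ape::read.tree(text = nwk), foreground = fg)
}

# A 6-tip tree for the null-calibration replicates.
sixTipTree <- function(fg = c("A", "B")) {
  nwk <- paste0("(((A:0.15,B:0.15):0.08,C:0.2):0.05,",
                "((D:0.15,E:0.15):0.08,F:0.2):0.05);")
  speciesTree(ape::read.tree(text = nwk), foreground = fg)
}

# Random rooted tree with unit-scale branch lengths, reproducible.
randomTree <- function(ntips, seed) {
  set.seed(seed)
  tr <- ape::rtree(ntips, rooted = TRUE)
  tr$edge.length <- runif(nrow(tr$edge), 0.02, 0.25)
  tr
}

# Brute-force phylogenetic likelihood by exhaustive enumeration over all
# internal-node codon assignments. Transition matrices come from
# Matrix::expm applied to the exported rate matrix, an independent path
# from the pruning kernel's eigendecomposition.
bruteLogLik <- function(alignment, tree, kappa, omega, pi,
                        foreground = NULL) {
  tr <- if (is(tree, "SpeciesTree")) apeTree(tree) else tree
  fg <- if (is(tree, "SpeciesTree")) foregroundEdges(tree)
        else rep(FALSE, nrow(tr$edge))
  ntip <- length(tr$tip.label)
  states <- codonStates()
  txt <- as.character(alignedSeqs(alignment)[tr$tip.label])
  nsite <- nchar(txt[1]) %/% 3L
  starts <- 3L * (seq_len(nsite) - 1L) + 1L
  tipState <- vapply(txt, function(s)
    match(substring(s, starts, starts + 2L), states), integer(nsite))
  if (nsite == 1L) tipState <- matrix(tipState, nrow = 1L)
  stopifnot(!anyNA(tipState))  # oracle fixtures are unambiguous

  omegaOf <- function(e) {
    if (fg[e]) omega[["foreground"]] else
      if (length(omega) > 1L) omega[["background"]] else unname(omega[1])
  }
  P <- lapply(seq_len(nrow(tr$edge)), function(e) {
    Q <- buildRateMatrix(kappa, omegaOf(e), pi)
    as.matrix(Matrix::expm(Q * tr$edge.length[e]))
  })

  nInternal <- tr$Nnode
  grid <- as.matrix(expand.grid(rep(list(seq_len(61L)), nInternal)))
  root <- ntip + 1L
  nodeCol <- function(node) node - ntip   # internal node -> grid column
  ll <- 0
  for (s in seq_len(nsite)) {
    prob <- pi[grid[, nodeCol(root)]]
    for (e in seq_len(nrow(tr$edge))) {
      pa <- tr$edge[e, 1L]
      ch <- tr$edge[e, 2L]
      ps <- grid[, nodeCol(pa)]
      cs <- if (ch <= ntip) rep(tipState[s, ch], nrow(grid))
            else grid[, nodeCol(ch)]
      prob <- prob * P[[e]][cbind(ps, cs)]
    }
    ll <- ll + log(sum(prob))
  }
  ll
}

# Simulate, plant losses and scan in reference frame: the standard round
# trip used by several tests.
roundTrip <- function(tree, lossClades, seed, nCodons = 120L,
                      stopProb = 0.03) {
  cfg <- simConfig(tree, nCodons = nCodons, lossClades = lossClades,
                   stopProb = stopProb, seed = seed)
  sim <- simulateAlignment(cfg)
  sim <- plantPseudogenization(sim$alignment, sim$truth, cfg)
  fm <- buildFrameMap(sim$alignment)
  species <- setdiff(speciesIds(sim$alignment),
                     referenceId(sim$alignment))
  records <- scanDisruptions(sim$alignment, fm, species = species,
                             frame = "reference")
  calls <- classifyFunctional(records, species)
  list(sim = sim, records = records, calls = calls, config = cfg)
}

# Expand planted truth records (one row per carrier set) to one row per
# carrier species, for set comparison with scanner output.
expandTruth <- function(truth) {
  if (nrow(truth$records) == 0L)
    return(data.frame(species = character(), kind = character(),
                      ref_position = integer(), length = integer()))
  do.call(rbind, lapply(seq_len(nrow(truth$records)), function(i) {
    sp <- strsplit(truth$records$carriers[i], ",")[[1]]
    data.frame(species = sp, kind = truth$records$kind[i],
               ref_position = truth$records$ref_position[i],
               length = truth$records$length[i],
               stringsAsFactors = FALSE)
  }))
}

recordKey <- function(df) {
  sort(paste(df$species, df$kind, df$ref_position, df$length, sep = "|"))
}

# Exhaustive minimal loss-event count: the smallest number of valid clades
# (monophyletic, all tips nonfunctional, every tip sharing one disruption
# key; singleton tips always valid) that partitions the nonfunctional
# tips. Recursive exact search, independent of inferLossEvents.
bruteMinEvents <- function(shared, calls, tree) {
  tr <- if (is(tree, "SpeciesTree")) apeTree(tree) else tree
  nf <- sort(calls$species[calls$status == "nonfunctional"])
  if (!length(nf)) return(0L)
  ntip <- length(tr$tip.label)
  cladeTipSets <- lapply(seq_len(ntip + tr$Nnode), function(node) {
    tips <- tr$tip.label[codonLoss:::.tipsBelow(node, tr)]
    sort(tips)
  })
  carrierSets <- lapply(strsplit(shared$carriers, ","), sort)
  valid <- Filter(function(tips) {
    length(tips) == 1L ||
      (all(tips %in% nf) &&
       any(vapply(carrierSets, function(cs) setequal(cs, tips),
                  logical(1))))
  }, cladeTipSets)
  valid <- valid[vapply(valid, function(tips) all(tips %in% nf),
                        logical(1))]
  best <- Inf
  recurse <- function(remaining, used) {
    if (used >= best) return(invisible())
    if (!length(remaining)) {
      best <<- min(best, used)
      return(invisible())
    }
    tip <- remaining[1]
    for (v in valid) {
      if (tip %in% v && all(v %in% remaining))
        recurse(setdiff(remaining, v), used + 1L)
    }
  }
  recurse(nf, 0L)
  as.integer(best)
}
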