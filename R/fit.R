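# Maximum-likelihood fitting of the three branch models: one-ratio,
# two-ratio with free foreground omega, and two-ratio with foreground
# omega fixed at 1 (pure relaxation).

#' Free-parameter count of a branch model
#'
#' Every model estimates one branch length per edge of the rooted topology
#' (2n - 2 for a binary tree with n tips) plus kappa; the one-ratio and
#' fixed-foreground models add one free omega, the free two-ratio model
#' two. Empirical codon frequencies are not counted, following standard
#' codeml-style accounting.
#'
#' @param nTips Number of tips.
#' @param model One of \code{"one_ratio"}, \code{"two_ratio_free"},
#'   \code{"two_ratio_fixed1"}.
#' @param nEdges Edge count; defaults to the binary rooted value
#'   \code{2 * nTips - 2}.
#' @return Integer parameter count.
#' @export
#' @examples
#' npBranchModel(30, "one_ratio")       # 60
#' npBranchModel(30, "two_ratio_free")  # 61
npBranchModel <- function(nTips,
                          model = c("one_ratio", "two_ratio_free",
                                    "two_ratio_fixed1"),
                          nEdges = 2L * nTips - 2L) {
  model <- match.arg(model)
  nFreeOmega <- if (model == "two_ratio_free") 2L else 1L
  as.integer(nEdges + 1L + nFreeOmega)
}

#' Fit a branch model by maximum likelihood
#'
#' Maximizes the GY94 codon model likelihood over kappa, the free omega
#' ratios and all branch lengths, using bounded quasi-Newton (L-BFGS-B) on
#' log-transformed parameters with multiple starting values for omega (the
#' omega likelihood surface can be multimodal near 0 and 1).
#'
#' @param alignment A cleaned \linkS4class{CodonAlignment}.
#' @param tree A \linkS4class{SpeciesTree}; foreground branches must be
#'   labeled for the two-ratio models.
#' @param model \code{"one_ratio"} (single omega, the null),
#'   \code{"two_ratio_free"} (separate foreground omega) or
#'   \code{"two_ratio_fixed1"} (foreground omega fixed at 1, testing pure
#'   relaxation).
#' @param freq Codon frequency scheme (\code{\link{codonFrequencies}});
#'   ignored when \code{pi} is given.
#' @param pi Optional numeric(61) codon frequencies.
#' @param omegaStarts Starting values for each free omega.
#' @param kappaStart Starting kappa.
#' @param control Optimizer control: \code{maxit} and \code{factr} are
#'   passed to \code{\link[stats]{optim}}.
#' @return A \linkS4class{CodonFit}.
#' @export
fitBranchModel <- function(alignment, tree,
                           model = c("one_ratio", "two_ratio_free",
                                     "two_ratio_fixed1"),
                           freq = c("F3x4", "F1x4", "equal"), pi = NULL,
                           omegaStarts = c(0.05, 0.5, 1.5),
                           kappaStart = 2,
                           control = list(maxit = 500L, factr = 1e7)) {
  model <- match.arg(model)
  if (!is(tree, "SpeciesTree")) tree <- speciesTree(tree)
  if (model != "one_ratio" && !any(tree@foreground))
    stop("two-ratio models require a non-empty foreground branch set")
  if (is.null(pi)) {
    freq <- match.arg(freq)
    pi <- codonFrequencies(alignment, freq)
  } else {
    freq <- "custom"
  }
  if (any(pi <= 0)) {  # keep states reachable for the reversible solver
    pi <- pmax(pi, 1e-8)
    pi <- pi / sum(pi)
  }

  ed <- .edgeData(tree)
  tr <- ed$tree
  miss <- setdiff(tr$tip.label, speciesIds(alignment))
  if (length(miss))
    stop("tree tips missing from alignment: ", paste(miss, collapse = ", "))
  tp <- .tipPartials(alignment, tr$tip.label)
  tab <- .codonTables()
  nEdge <- nrow(ed$edge)
  twoClass <- model != "one_ratio"
  classIdx <- rep(1L, nEdge)
  if (twoClass) classIdx[ed$foreground] <- 2L
  freeFg <- model == "two_ratio_free"

  bl0 <- if (!is.null(tr$edge.length)) pmax(tr$edge.length[ed$order], 1e-4)
         else rep(0.1, nEdge)
  nFree <- nEdge + 1L + 1L + as.integer(freeFg)
  lower <- c(rep(log(1e-7), nEdge), log(0.05),
             rep(log(1e-6), 1L + as.integer(freeFg)))
  upper <- c(rep(log(30), nEdge), log(100),
             rep(log(99), 1L + as.integer(freeFg)))

  negll <- function(theta) {
    bl <- exp(theta[seq_len(nEdge)])
    kap <- exp(theta[nEdge + 1L])
    om <- exp(theta[-seq_len(nEdge + 1L)])
    omegas <- if (model == "one_ratio") om[1L]
              else if (freeFg) c(om[1L], om[2L])
              else c(om[1L], 1.0)
    ll <- cl_loglik(tp$cube, tp$weights, ed$edge, bl,
                    if (twoClass) classIdx else rep(1L, nEdge),
                    kap, omegas, as.numeric(pi), tab$single * 1L,
                    tab$transition * 1L, tab$nonsyn * 1L, tr$Nnode)
    if (!is.finite(ll)) return(1e12)
    -ll
  }

  best <- NULL
  nRestarts <- 0L
  for (om0 in omegaStarts) {
    theta0 <- c(log(bl0), log(kappaStart),
                log(rep(max(om0, 1e-4), 1L + as.integer(freeFg))))
    fit <- tryCatch(
      optim(theta0, negll, method = "L-BFGS-B", lower = lower,
            upper = upper,
            control = list(maxit = control$maxit %||% 500L,
                           factr = control$factr %||% 1e7)),
      error = function(e) NULL)
    nRestarts <- nRestarts + 1L
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("optimization failed for model ", model, " on every start")

  theta <- best$par
  bl <- exp(theta[seq_len(nEdge)])
  kap <- exp(theta[nEdge + 1L])
  om <- exp(theta[-seq_len(nEdge + 1L)])
  omega <- if (model == "one_ratio") c(background = unname(om[1L]))
           else if (freeFg) c(background = unname(om[1L]),
                              foreground = unname(om[2L]))
           else c(background = unname(om[1L]), foreground = 1)
  # back to the input tree's edge order
  blInput <- numeric(nEdge)
  blInput[ed$order] <- bl
  new("CodonFit", model = model,
      np = npBranchModel(length(tr$tip.label), model, nEdges = nEdge),
      logLik = -best$value, kappa = kap, omega = omega,
      branchLengths = blInput, frequencies = as.numeric(pi),
      freqScheme = freq, converged = best$convergence == 0L,
      nRestarts = nRestarts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
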