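test_that("GY94 rate matrix has the defining structure", {
  states <- codonStates()
  piEq <- setNames(rep(1 / 61, 61), states)

  # kappa = omega = 1, equal pi: every allowed off-diagonal rate equal
  Q <- buildRateMatrix(1, 1, piEq)
  off <- Q[row(Q) != col(Q)]
  allowed <- off[off > 0]
  expect_gt(length(allowed), 0)
  expect_lt(diff(range(allowed)), 1e-14)

  # omega = 0: every nonsynonymous rate is zero, checked over all pairs
  Q0 <- buildRateMatrix(2, 0, piEq)
  aa <- as.character(Biostrings::GENETIC_CODE[states])
  for (i in seq_len(61)) {
    ns <- aa != aa[i]
    expect_true(all(Q0[i, ns] == 0))
  }

  # multi-hit pairs always have rate zero
  set.seed(5)
  piR <- rexp(61); piR <- piR / sum(piR)
  QR <- buildRateMatrix(3.1, 0.4, piR)
  nd <- sapply(states, function(a) sapply(states, function(b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])))
  expect_true(all(QR[t(nd) > 1] == 0))

  # rows sum to zero and expected rate is scaled to one
  expect_lt(max(abs(rowSums(QR))), 1e-12)
  expect_equal(-sum(piR * diag(QR)), 1, tolerance = 1e-12)
})

test_that("detailed balance holds for random parameter draws", {
  set.seed(42)
  worst <- 0
  for (i in 1:1000) {
    kappa <- exp(runif(1, log(0.2), log(10)))
    omega <- exp(runif(1, log(0.01), log(5)))
    pi <- rexp(61); pi <- pi / sum(pi)
    Q <- buildRateMatrix(kappa, omega, pi)
    M <- pi * Q
    worst <- max(worst, max(abs(M - t(M))))
  }
  expect_lt(worst, 1e-13)
})

test_that("transition matrices agree with an independent matrix exponential", {
  set.seed(9)
  pi <- rexp(61); pi <- pi / sum(pi)
  Q <- buildRateMatrix(2.4, 0.3, pi)
  for (t in c(0, 0.05, 0.7, 3)) {
    P <- transitionMatrices(2.4, 0.3, pi, t)[[1]]
    Pref <- as.matrix(Matrix::expm(Q * t))
    expect_lt(max(abs(P - Pref)), 1e-10)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
  }
})

test_that("single-tip likelihood is the log equilibrium probability", {
  tr <- ape::read.tree(text = "(A:0.1);")
  aln <- codonAlignment(c(A = "ATGAAACAT", R = "ATGAAACAT"), "R")
  set.seed(2)
  pi <- rexp(61); pi <- pi / sum(pi)
  names(pi) <- codonStates()
  ll <- codonLogLik(aln, tr, kappa = 2, omega = 0.5, pi = pi)
  expect_equal(ll, log(pi[["ATG"]]) + log(pi[["AAA"]]) + log(pi[["CAT"]]),
               tolerance = 1e-10)
})

test_that("pruning equals the exhaustive enumeration oracle", {
  set.seed(30)
  pi <- rexp(61); pi <- pi / sum(pi)
  for (ntips in 2:4) {
    tr <- randomTree(ntips, seed = 100 + ntips)
    st <- speciesTree(tr, foreground = tr$tip.label[1])
    cfg <- simConfig(st, nCodons = 30,
                     omega = c(background = 0.3, foreground = 1.2),
                     seed = 300 + ntips)
    sim <- simulateAlignment(cfg)
    aln <- sim$alignment
    # truncate to 8 sites to keep the enumeration honest but quick
    short <- codonAlignment(Biostrings::DNAStringSet(
      substr(as.character(alignedSeqs(aln)), 1, 24)),
      referenceId(aln))
    omega <- c(background = 0.25, foreground = 1.4)
    ll <- codonLogLik(short, st, kappa = 1.8, omega = omega, pi = pi)
    llBrute <- bruteLogLik(short, st, kappa = 1.8, omega = omega, pi = pi)
    expect_equal(ll, llBrute, tolerance = 1e-8)
  }
})

test_that("likelihood is invariant under rerooting (pulley principle)", {
  # three rootings of one unrooted 4-tip metric
  nwk <- c("((A:0.10,B:0.20):0.06,(C:0.30,D:0.40):0.06);",
           "((A:0.10,B:0.20):0.12,(C:0.30,D:0.40):0.00);",
           "(A:0.04,(B:0.20,(C:0.30,D:0.40):0.12):0.06);")
  set.seed(8)
  pi <- rexp(61); pi <- pi / sum(pi)
  tr1 <- ape::read.tree(text = nwk[1])
  cfg <- simConfig(speciesTree(tr1), nCodons = 40,
                   omega = c(background = 0.5), seed = 77)
  aln <- simulateAlignment(cfg)$alignment
  lls <- vapply(nwk, function(x)
    codonLogLik(aln, ape::read.tree(text = x), kappa = 2.2, omega = 0.4,
                pi = pi), numeric(1))
  expect_lt(max(lls) - min(lls), 1e-8)
})

test_that("the generator is scaled to one substitution per unit time", {
  # independent event-counting simulation of the CTMC defined by Q
  set.seed(14)
  states <- codonStates()
  pi <- setNames(rep(1 / 61, 61), states)
  Q <- buildRateMatrix(1, 1, pi)
  nsites <- 20000L
  t <- 1
  nSub <- 0L
  s <- sample.int(61L, nsites, replace = TRUE, prob = pi)
  for (i in seq_len(nsites)) {
    time <- 0
    cur <- s[i]
    repeat {
      time <- time + rexp(1, -Q[cur, cur])
      if (time > t) break
      pr <- Q[cur, ]; pr[cur] <- 0
      cur <- sample.int(61L, 1L, prob = pr)
      nSub <- nSub + 1L
    }
  }
  expect_equal(nSub / nsites, 1, tolerance = 0.02)
})

test_that("model fits respect nesting and sit at a local optimum", {
  st <- eightTipTree()
  cfg <- simConfig(st, nCodons = 150,
                   omega = c(background = 0.2, foreground = 0.8),
                   seed = 99)
  aln <- stripDisruptions(simulateAlignment(cfg)$alignment)
  fits <- list(
    A = fitBranchModel(aln, st, "one_ratio", omegaStarts = c(0.2, 1)),
    B = fitBranchModel(aln, st, "two_ratio_free", omegaStarts = c(0.2, 1)),
    C = fitBranchModel(aln, st, "two_ratio_fixed1", omegaStarts = c(0.2, 1)))
  expect_gte(fitLogLik(fits$B), fitLogLik(fits$A) - 1e-6)
  expect_gte(fitLogLik(fits$B), fitLogLik(fits$C) - 1e-6)
  expect_identical(fitNp(fits$A), 16L)  # 14 branches + kappa + 1 omega
  expect_identical(fitNp(fits$B), 17L)
  expect_identical(fitNp(fits$C), 16L)
  expect_true(all(vapply(fits, function(f) f@converged, logical(1))))

  # perturbing the fitted omega away from the MLE lowers the likelihood
  f <- fits$B
  pi <- f@frequencies
  atMLE <- codonLogLik(aln, st, fitKappa(f), fitOmega(f), pi,
                       branchLengths = f@branchLengths)
  expect_equal(atMLE, fitLogLik(f), tolerance = 1e-6)
  for (fac in c(0.7, 1.4)) {
    om <- fitOmega(f)
    om["foreground"] <- om["foreground"] * fac
    expect_lt(codonLogLik(aln, st, fitKappa(f), om, pi,
                          branchLengths = f@branchLengths), atMLE)
  }
})

test_that("gaps and N act as ambiguity, never as signal", {
  tr <- randomTree(3, seed = 4)
  st <- speciesTree(tr)
  cfg <- simConfig(st, nCodons = 30, omega = c(background = 0.4),
                   seed = 123)
  aln <- simulateAlignment(cfg)$alignment
  set.seed(6)
  pi <- rexp(61); pi <- pi / sum(pi)
  llFull <- codonLogLik(aln, tr, 2, 0.4, pi)
  # replacing one codon with NNN can only raise the site's probability sum
  txt <- as.character(alignedSeqs(aln))
  txt[[tr$tip.label[1]]] <- paste0("NNN", substr(txt[[tr$tip.label[1]]],
                                                 4, nchar(txt[[1]])))
  alnN <- codonAlignment(Biostrings::DNAStringSet(txt), referenceId(aln))
  expect_gt(codonLogLik(alnN, tr, 2, 0.4, pi), llFull)
})
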