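mkRec <- function(species, kind, pos, len) {
  data.frame(species = species, kind = kind, ref_position = as.integer(pos),
             length = as.integer(len), frameshift = len %% 3 != 0,
             stringsAsFactors = FALSE)
}

test_that("shared-disruption grouping uses exact (kind, position, length) keys", {
  recs <- rbind(mkRec("h_armiger", "deletion", 979, 17),
                mkRec("h_pratti", "deletion", 979, 17),
                mkRec("solo", "deletion", 500, 2))
  shared <- collectShared(recs)
  k979 <- shared[shared$ref_position == 979, ]
  expect_identical(k979$n_carriers, 2L)
  expect_identical(k979$carriers, "h_armiger,h_pratti")
  expect_identical(shared[shared$ref_position == 500, ]$n_carriers, 1L)

  # same position, different length: distinct keys
  recs2 <- rbind(mkRec("x", "deletion", 100, 2), mkRec("y", "deletion", 100, 3))
  expect_identical(nrow(collectShared(recs2)), 2L)
  # positional tolerance merges near-identical keys when asked
  recs3 <- rbind(mkRec("x", "deletion", 100, 2), mkRec("y", "deletion", 101, 2))
  expect_identical(nrow(collectShared(recs3)), 2L)
  expect_identical(nrow(collectShared(recs3, tol = 1L)), 1L)

  # six keys shared by the same species pair stay six keys
  pos <- c(312, 544, 852, 980, 1905)
  recs4 <- rbind(
    do.call(rbind, lapply(pos, function(p)
      rbind(mkRec("p_davyi", "deletion", p, 4),
            mkRec("p_parnellii", "deletion", p, 4)))),
    mkRec("p_davyi", "insertion", 1298, 1),
    mkRec("p_parnellii", "insertion", 1298, 1))
  shared4 <- collectShared(recs4)
  expect_identical(nrow(shared4), 6L)
  expect_true(all(shared4$n_carriers == 2L))
})

test_that("loss events: ancestral when a whole nonfunctional clade shares a key", {
  tr <- ape::read.tree(text = "(((v1,v2),v3),(f1,(f2,n1)));")
  calls <- data.frame(species = tr$tip.label,
                      status = ifelse(tr$tip.label %in%
                                        c("v1", "v2", "v3", "n1"),
                                      "nonfunctional", "functional"))
  recs <- do.call(rbind, lapply(c("v1", "v2", "v3"), function(sp)
    rbind(mkRec(sp, "deletion", 201, 1), mkRec(sp, "deletion", 275, 4),
          mkRec(sp, "deletion", 1185, 2))))
  recs <- rbind(recs, mkRec("n1", "premature_stop", 88, 3))
  ev <- inferLossEvents(collectShared(recs), calls, tr)
  expect_identical(ev$n_independent, 2L)
  expect_setequal(ev$events$branch, c("v1,v2,v3", "n1"))
  vesp <- ev$events[ev$events$branch == "v1,v2,v3", ]
  expect_identical(vesp$covered, "v1,v2,v3")
  expect_match(vesp$support, "deletion@201/1")
  expect_length(ev$conflicts, 0L)
})

test_that("loss events: no key shared by all implies several independent losses", {
  tr <- ape::read.tree(text = "(((r1,r2),(r3,r4)),out);")
  calls <- data.frame(species = tr$tip.label,
                      status = c(rep("nonfunctional", 4), "functional"))
  # r1+r2 share one key; r3 and r4 carry only private disruptions
  recs <- rbind(mkRec("r1", "deletion", 50, 2), mkRec("r2", "deletion", 50, 2),
                mkRec("r3", "premature_stop", 120, 3),
                mkRec("r4", "deletion", 300, 5))
  ev <- inferLossEvents(collectShared(recs), calls, tr)
  expect_identical(ev$n_independent, 3L)
  expect_setequal(ev$events$branch, c("r1,r2", "r3", "r4"))
})

test_that("a shared key spanning functional tips is a conflict, not an event", {
  tr <- ape::read.tree(text = "((a,(b,c)),d);")
  calls <- data.frame(species = tr$tip.label,
                      status = c("nonfunctional", "functional",
                                 "nonfunctional", "functional"))
  recs <- rbind(mkRec("a", "deletion", 10, 2), mkRec("c", "deletion", 10, 2))
  ev <- inferLossEvents(collectShared(recs), calls, tr)
  expect_identical(ev$n_independent, 2L)  # two terminal events
  expect_identical(ev$conflicts, "deletion@10/2")
})

test_that("planted stem and terminal losses are recovered exactly", {
  tr <- ape::read.tree(text = paste0(
    "(((s1:.1,s2:.1):.05,(s3:.1,(s4:.1,s5:.1):.05):.05):.05,",
    "((t1:.1,t2:.1):.05,t3:.1):.05);"))
  st <- speciesTree(tr)
  loss <- list(c("s4", "s5"), c("t1", "t2"), "s1")
  rt <- roundTrip(st, loss, seed = 202)
  ev <- inferLossEvents(collectShared(rt$records), rt$calls, tr)
  expect_identical(ev$n_independent, 3L)
  expect_setequal(ev$events$branch, c("s4,s5", "t1,t2", "s1"))
})

test_that("inferred event count matches the exhaustive minimal cover", {
  for (seed in 1:30) {
    set.seed(seed)
    ntips <- sample(6:12, 1)
    tr <- randomTree(ntips, seed)
    tips <- tr$tip.label
    # random loss clades: pick 1-3 disjoint clades/tips
    nodes <- c(seq_along(tips), length(tips) + seq_len(tr$Nnode))
    cladeSets <- lapply(nodes, function(nd)
      tips[codonLoss:::.tipsBelow(nd, tr)])
    cladeSets <- Filter(function(x) length(x) < ntips, cladeSets)
    chosen <- list()
    for (k in seq_len(sample(1:3, 1))) {
      cand <- cladeSets[sample(length(cladeSets))]
      for (cs in cand) {
        if (!any(vapply(chosen, function(x)
          length(intersect(x, cs)) > 0, logical(1)))) {
          chosen <- c(chosen, list(cs))
          break
        }
      }
    }
    rt <- roundTrip(speciesTree(tr), chosen, seed = seed * 7 + 1)
    shared <- collectShared(rt$records)
    ev <- inferLossEvents(shared, rt$calls, tr)
    expect_identical(ev$n_independent,
                     bruteMinEvents(shared, rt$calls, tr),
                     info = paste("seed", seed))
  }
})

test_that("a functional tip inside a clade blocks the ancestral event", {
  trNest <- ape::read.tree(text = "((a,(c,b)),out);")
  callsAllNf <- data.frame(species = trNest$tip.label,
                           status = c("nonfunctional", "nonfunctional",
                                      "nonfunctional", "functional"))
  recs <- do.call(rbind, lapply(c("a", "b", "c"), function(sp)
    mkRec(sp, "deletion", 77, 2)))
  evBefore <- inferLossEvents(collectShared(recs), callsAllNf, trNest)
  expect_identical(evBefore$n_independent, 1L)
  # same evidence, but c is functional: the clade event is blocked and
  # the loss count can only go up
  callsMix <- callsAllNf
  callsMix$status[callsMix$species == "c"] <- "functional"
  recsMix <- recs[recs$species != "c", ]
  evAfter <- inferLossEvents(collectShared(recsMix), callsMix, trNest)
  expect_gte(evAfter$n_independent, evBefore$n_independent)
  expect_identical(evAfter$n_independent, 2L)
})
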