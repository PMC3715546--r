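# Hand-walked toy alignments are the oracles here: expected records were
# derived by reading the alignments by eye, as in the comments.

test_that("indel scanning finds deletions and insertions with positions", {
  # ref codons: ATG CTG CTG CTG AAA CCC
  ref <- "ATGCTGCTGCTGAAACCC"
  fm <- function(aln) buildFrameMap(aln)

  alnId <- codonAlignment(c(ref = ref, sp = ref), "ref")
  expect_identical(nrow(scanIndels(alnId, fm(alnId), "sp")), 0L)

  # 2-bp gap at reference positions 4-5: frameshifting deletion
  q2 <- paste0(substr(ref, 1, 3), "--", substr(ref, 6, 18))
  aln2 <- codonAlignment(c(ref = ref, sp = q2), "ref")
  rec <- scanIndels(aln2, fm(aln2), "sp")
  expect_identical(rec$kind, "deletion")
  expect_identical(rec$ref_position, 4L)
  expect_identical(rec$length, 2L)
  expect_true(rec$frameshift)

  # 3-bp gap: in-frame deletion
  q3 <- paste0(substr(ref, 1, 3), "---", substr(ref, 7, 18))
  aln3 <- codonAlignment(c(ref = ref, sp = q3), "ref")
  rec <- scanIndels(aln3, fm(aln3), "sp")
  expect_identical(rec$length, 3L)
  expect_false(rec$frameshift)

  # insertion: reference gapped, query holds 2 extra bases after ref pos 6
  refIns <- paste0(substr(ref, 1, 6), "--", substr(ref, 7, 18))
  qIns <- paste0(substr(ref, 1, 6), "GG", substr(ref, 7, 18))
  alnIns <- codonAlignment(c(ref = refIns, sp = qIns), "ref")
  rec <- scanIndels(alnIns, fm(alnIns), "sp")
  expect_identical(rec$kind, "insertion")
  expect_identical(rec$ref_position, 6L)
  expect_identical(rec$length, 2L)
  expect_true(rec$frameshift)

  # terminal truncations are not disruptions
  qTrunc <- paste0("------", substr(ref, 7, 15), "---")
  alnT <- codonAlignment(c(ref = ref, sp = qTrunc), "ref")
  expect_identical(nrow(scanIndels(alnT, fm(alnT), "sp")), 0L)

  expect_error(scanIndels(alnId, fm(alnId), "missing"), "not found")
  expect_error(scanIndels(alnId, fm(alnId), "ref"), "reference")
})

test_that("premature stops are read in the query's running frame", {
  # ref codons: ATG CTG CTG CTG AAA TGA (terminal stop at coords 16-18)
  ref <- "ATGCTGCTGCTGAAATGA"
  alnId <- codonAlignment(c(ref = ref, sp = ref), "ref")
  fmId <- buildFrameMap(alnId)
  # the query's own terminal stop is not premature
  expect_identical(nrow(scanPrematureStops(alnId, fmId, "sp")), 0L)

  # codon 5 mutated to TGA: premature stop at reference coordinate 13
  qStop <- paste0(substr(ref, 1, 12), "TGA", substr(ref, 16, 18))
  alnS <- codonAlignment(c(ref = ref, sp = qStop), "ref")
  rec <- scanPrematureStops(alnS, buildFrameMap(alnS), "sp")
  expect_identical(rec$kind, "premature_stop")
  expect_identical(rec$ref_position, 13L)
  expect_identical(rec$length, 3L)

  # a codon containing N is never called
  qN <- paste0(substr(ref, 1, 12), "TGN", substr(ref, 16, 18))
  alnN <- codonAlignment(c(ref = ref, sp = qN), "ref")
  expect_identical(nrow(scanPrematureStops(alnN, buildFrameMap(alnN),
                                           "sp")), 0L)

  # 1-bp deletion shifts the frame and exposes a downstream stop:
  # ref  ATG ATG ACC AAA CCC TTT ; query deletes ref position 4, so its
  # running frame reads ATG TGA ... -> stop with first base at ref pos 5
  ref2 <- "ATGATGACCAAACCCTTT"
  q2 <- paste0("ATG-", substr(ref2, 5, 18))
  aln2 <- codonAlignment(c(ref = ref2, sp = q2), "ref")
  fm2 <- buildFrameMap(aln2)
  rec <- scanPrematureStops(aln2, fm2, "sp")
  expect_identical(rec$ref_position, 5L)
  # in reference-frame mode the gapped codon is skipped and the shifted
  # stop is invisible
  expect_identical(
    nrow(scanPrematureStops(aln2, fm2, "sp", frame = "reference")), 0L)
})

test_that("classification is nonfunctional iff any disruption exists", {
  species <- c("a", "b", "c")
  recs <- data.frame(species = c("b", "b"),
                     kind = c("deletion", "premature_stop"),
                     ref_position = c(10L, 40L), length = c(2L, 3L),
                     frameshift = c(TRUE, FALSE))
  calls <- classifyFunctional(recs, species)
  expect_identical(calls$status[calls$species == "a"], "functional")
  expect_identical(calls$status[calls$species == "b"], "nonfunctional")
  # one premature stop alone is enough
  one <- classifyFunctional(recs[2, ], species)
  expect_identical(one$status[one$species == "b"], "nonfunctional")
  # monotone: adding records never flips a call back to functional
  for (k in seq_len(nrow(recs))) {
    part <- classifyFunctional(recs[seq_len(k), ], species)
    expect_identical(part$status[part$species == "b"], "nonfunctional")
  }
})

test_that("masking removes exactly the mapped interval", {
  ref <- paste(rep("ATGCTGCTGCA", 3), collapse = "")  # 33 nt, stop-free
  ref <- substr(ref, 1, 30)
  aln <- codonAlignment(c(ref = ref, sp = ref), "ref")
  expect_identical(maskRegion(aln, 40, 50), aln)  # nothing mapped there
  masked <- maskRegion(aln, 10, 18)
  expect_identical(unname(Biostrings::width(alignedSeqs(masked))[1]), 21L)
  expect_error(maskRegion(aln, 18, 10), "invalid")
})

test_that("stripping yields a gap-free, stop-free, in-frame alignment", {
  # ref: 12 stop-free codons
  ref <- "ATGCTGAAACCCGGGTTTCATCAGGACGAGCTGCTG"
  clean <- codonAlignment(c(ref = ref, sp = ref), "ref")
  out <- suppressWarnings(stripDisruptions(clean))
  expect_identical(as.character(alignedSeqs(out)),
                   as.character(alignedSeqs(clean)))

  # sp1: frameshift gap at ref position 4 plus a planted TAA at codon 6
  sp1 <- paste0(substr(ref, 1, 3), "-", substr(ref, 5, 15), "TAA",
                substr(ref, 19, 36))
  aln <- codonAlignment(c(ref = ref, sp1 = sp1, sp2 = ref), "ref")
  out <- suppressWarnings(stripDisruptions(aln))
  w <- unname(Biostrings::width(alignedSeqs(out))[1])
  expect_identical(w %% 3L, 0L)
  expect_identical(w, 33L)  # one gapped codon column dropped
  txt <- as.character(alignedSeqs(out))
  expect_false(any(grepl("-", txt)))
  expect_true(grepl("NNN", txt[["sp1"]]))
  # every retained sequence now scans as functional
  fm <- buildFrameMap(out)
  calls <- classifyFunctional(
    scanDisruptions(out, fm, frame = "query"),
    setdiff(speciesIds(out), referenceId(out)))
  expect_true(all(calls$status == "functional"))
})
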