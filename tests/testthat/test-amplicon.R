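# a fixed amplicon with a planted SpCas9 protospacer+PAM used throughout
make_amp <- function(len = 240L, seed = 31L) {
  set.seed(seed)
  s <- rand_seq(len)
  guide <- "GACGTTACGGATCCAGTCAA"
  substr(s, 101, 120) <- guide
  substr(s, 121, 123) <- "TGG"
  ampliconRef(s, spCas9(), guide = guide)
}

test_that("amplicon geometry: PAM adjacency, cut and window placement", {
  amp <- make_amp()
  expect_equal(IRanges::start(amp@pam), 121L)
  expect_equal(amp@cutAfter, 117L)  # 3 bp 5' of the PAM
  expect_equal(IRanges::start(amp@quantWindow), 108L)
  expect_equal(IRanges::end(amp@quantWindow), 127L)
  expect_error(ampliconRef(strrep("A", 50), spCas9(), guide = "GGG"),
               "spacer length")
  expect_error(ampliconRef(strrep("A", 50), spCas9(),
                           guide = strrep("A", 20)), "0 times")
})

test_that("global alignment is exact and prefers mismatch over gaps", {
  a <- alignGlobal("ACGT", "ACGT")
  expect_equal(a$score, 20)
  expect_equal(a$alnRead, a$alnRef)

  a <- alignGlobal("ACT", "ACGT")
  expect_equal(sum(strsplit(a$alnRead, "")[[1]] == "-"), 1L)
  expect_equal(sum(strsplit(a$alnRef, "")[[1]] == "-"), 0L)

  # one substitution scores better than two 1-bp gaps under the defaults
  a <- alignGlobal("ACGTACGT", "ACGAACGT")
  expect_equal(a$score, 7 * 5 - 4)
  expect_error(alignGlobal("", "ACGT"), "empty")
})

test_that("alignment score equals exhaustive enumeration on short pairs", {
  set.seed(51)
  for (i in 1:60) {
    a <- rand_seq(sample(2:6, 1))
    b <- rand_seq(sample(2:6, 1))
    got <- alignGlobal(a, b)$score
    want <- oracle_align_score(a, b)
    expect_equal(got, want, info = paste(a, b))
  }
})

test_that("event calling maps gaps and mismatch runs into the window", {
  amp <- make_amp()
  s <- amp@sequence
  # 1-bp insertion at the cut site
  rd <- paste0(substr(s, 1, 117), "A", substring(s, 118))
  aln <- alignGlobal(rd, s)
  ev <- callEvents(aln$alnRead, aln$alnRef, amp)
  expect_equal(ev$kind, "I")
  expect_equal(ev$length, 1L)

  # 3-bp deletion spanning the cut
  rd <- paste0(substr(s, 1, 116), substring(s, 120))
  aln <- alignGlobal(rd, s)
  ev <- callEvents(aln$alnRead, aln$alnRef, amp)
  expect_equal(ev$kind, "D")
  expect_equal(ev$length, 3L)

  # substitution two bases 5' of the PAM's N: pam_rel = -2
  rd <- s
  old <- substr(rd, 119, 119)
  substr(rd, 119, 119) <- setdiff(c("A", "C", "G", "T"), old)[1]
  aln <- alignGlobal(rd, s)
  ev <- callEvents(aln$alnRead, aln$alnRef, amp)
  expect_equal(ev$kind, "S")
  expect_equal(ev$pam_rel, -2L)

  # an event far outside the quantification window is discarded
  rd <- paste0("A", substring(s, 1))  # insertion at position 0
  aln <- alignGlobal(rd, s)
  expect_equal(nrow(callEvents(aln$alnRead, aln$alnRef, amp)), 0L)
})

test_that("low-quality substitution runs are suppressed when qualities exist", {
  amp <- make_amp()
  s <- amp@sequence
  rd <- s
  old <- substr(rd, 118, 118)
  substr(rd, 118, 118) <- setdiff(c("A", "C", "G", "T"), old)[1]
  aln <- alignGlobal(rd, s)
  qualHigh <- strrep("I", nchar(rd))             # Q40 everywhere
  qualLow <- qualHigh
  substr(qualLow, 118, 118) <- "#"               # Q2 at the mismatch
  expect_equal(nrow(callEvents(aln$alnRead, aln$alnRef, amp,
                               qual = qualHigh)), 1L)
  expect_equal(nrow(callEvents(aln$alnRead, aln$alnRef, amp,
                               qual = qualLow)), 0L)
})

test_that("read classification follows the single-kind/combination rule", {
  none <- data.frame(kind = character(0), length = integer(0),
                     ref_start = integer(0), pam_rel = integer(0))
  expect_equal(classifyRead(none)$category, "unmodified")
  i1 <- data.frame(kind = "I", length = 1L, ref_start = 117L,
                   pam_rel = -4L)
  expect_equal(classifyRead(i1)$label, "I1")
  both <- rbind(i1, data.frame(kind = "D", length = 2L, ref_start = 118L,
                               pam_rel = -3L))
  cl <- classifyRead(both)
  expect_equal(cl$category, "C")
  expect_equal(cl$total_bp, 3L)
})

test_that("spectra and efficiency behave on degenerate inputs", {
  amp <- make_amp()
  sim <- simAmpliconReads(amp, c(I1 = 1.0), n = 10L, baseError = 0,
                          seed = 61)
  prof <- profileAmplicon(sim$reads, amp, qualities = sim$qualities)
  expect_equal(editingEfficiency(prof), 1.0)
  sp <- buildSpectra(prof)
  expect_equal(unname(sp$labelFreq["I1"]), 1.0)
  expect_equal(sum(sp$labelFreq), 1.0)

  sim0 <- simAmpliconReads(amp, c(I1 = 0), n = 10L, baseError = 0,
                           seed = 62)
  prof0 <- profileAmplicon(sim0$reads, amp, qualities = sim0$qualities)
  expect_equal(editingEfficiency(prof0), 0.0)
  expect_warning(buildSpectra(prof0), "unmodified")
})

test_that("simulated spectra are recovered within binomial error", {
  amp <- make_amp()
  spectrum <- c(I1 = 0.6, D2 = 0.2)
  n <- 800L
  sim <- simAmpliconReads(amp, spectrum, n = n, baseError = 0.001,
                          seed = 71)
  prof <- profileAmplicon(sim$reads, amp, qualities = sim$qualities)
  expect_equal(prof$n_dropped, 0L)

  eff <- editingEfficiency(prof)
  sigma <- sqrt(0.8 * 0.2 / n)
  expect_lt(abs(eff - 0.8), 3 * sigma)

  sp <- buildSpectra(prof)
  nm <- sp$n_modified
  for (lab in names(spectrum)) {
    p <- spectrum[[lab]] / sum(spectrum)   # over modified reads
    expect_lt(abs(sp$labelFreq[[lab]] - p), 3 * sqrt(p * (1 - p) / nm))
  }
  # frequencies over modified reads always sum to 1
  expect_equal(sum(sp$labelFreq), 1, tolerance = 1e-9)

  # classification is invariant to read order
  perm <- sample(seq_along(sim$reads))
  prof2 <- profileAmplicon(sim$reads[perm], amp,
                           qualities = sim$qualities[perm])
  expect_equal(sort(prof2$outcomes$label), sort(prof$outcomes$label))
  expect_equal(editingEfficiency(prof2), eff)
})

test_that("FASTQ round trip preserves reads and qualities", {
  amp <- make_amp()
  sim <- simAmpliconReads(amp, c(D2 = 0.5), n = 20L, seed = 81)
  f <- tempfile(fileext = ".fq")
  writeFastq(sim$reads, f, sim$qualities)
  back <- readAmpliconReads(f)
  expect_equal(as.character(back$reads), unname(sim$reads),
               ignore_attr = TRUE)
  expect_equal(unname(back$qualities), unname(sim$qualities))
})
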