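test_that("an exact planted on-target is found once at zero mismatches", {
  set.seed(91)
  s <- rand_seq(3000)
  guide <- "GACGTTACGGATCCAGTCAA"
  substr(s, 1001, 1020) <- guide
  substr(s, 1021, 1023) <- "AGG"
  g <- Biostrings::DNAStringSet(s)
  names(g) <- "chr1"
  ot <- enumerateOffTargets(g, guide, spCas9(), maxMismatch = 0L)
  hit <- ot[GenomicRanges::start(ot) == 1001]
  expect_equal(length(hit), 1L)
  expect_equal(S4Vectors::mcols(hit)$mismatch_count, 0L)
  expect_equal(S4Vectors::mcols(hit)$site_seq, guide)
  expect_error(enumerateOffTargets(g, "ACGT", spCas9()), "spacer length")
})

test_that("off-target enumeration matches the brute-force oracle", {
  set.seed(92)
  for (i in 1:10) {
    s <- rand_seq(500, withN = i %% 4 == 0)
    g <- Biostrings::DNAStringSet(s)
    names(g) <- "chrZ"
    for (nuc in nucleaseRegistry()) {
      spacer <- rand_seq(spacerLength(nuc))
      for (mm in c(0L, 1L, 2L)) {
        got <- enumerateOffTargets(g, spacer, nuc, maxMismatch = mm)
        want <- oracle_offtargets(s, spacer, nuc, mm)
        expect_equal(
          sort(paste(GenomicRanges::start(got),
                     as.character(GenomicRanges::strand(got)),
                     S4Vectors::mcols(got)$mismatch_count)),
          sort(paste(want$proto_start, want$strand, want$mm)),
          info = paste("genome", i, nucleaseName(nuc), "mm", mm))
      }
    }
  }
})

test_that("site counts are monotone in the mismatch budget and PAM relaxation", {
  set.seed(93)
  s <- rand_seq(4000)
  g <- Biostrings::DNAStringSet(s)
  names(g) <- "chr1"
  spacer <- rand_seq(20)
  counts <- vapply(0:4, function(k)
    length(enumerateOffTargets(g, spacer, spCas9(), maxMismatch = k)),
    integer(1))
  expect_true(all(diff(counts) >= 0))
  strictN <- length(enumerateOffTargets(g, spacer, spCas9(), 3L))
  relaxedN <- length(enumerateOffTargets(g, spacer, spCas9(), 3L,
                                         relaxPam = TRUE))
  expect_gte(relaxedN, strictN)
})

test_that("background subtraction obeys its algebraic identities", {
  vt <- simVariantTables(nShared = 5L, nUnique = 3L, seed = 94)
  A <- vt$treated; B <- vt$control
  expect_equal(nrow(subtractBackground(A, A)), 0L)
  expect_equal(subtractBackground(A, A[0, ]), A, ignore_attr = TRUE)
  u <- subtractBackground(A, B)
  expect_equal(nrow(u), 3L)
  expect_setequal(paste(u$chrom, u$pos, u$ref, u$alt, sep = ":"),
                  vt$truthKeys)
  # idempotence
  expect_equal(subtractBackground(u, B), u)
  # stable input order
  expect_false(is.unsorted(match(paste(u$chrom, u$pos, u$ref, u$alt),
                                 paste(A$chrom, A$pos, A$ref, A$alt))))
})

test_that("variant-site intersection respects the slop window", {
  sites <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1000L, 5000L), width = 23L))
  inside <- data.frame(chrom = "chr1", pos = 1010L, ref = "A", alt = "AT")
  away <- data.frame(chrom = "chr1", pos = 1123L, ref = "A", alt = "AT")
  expect_equal(nrow(intersectOffTargets(inside, sites, slop = 0L)), 1L)
  expect_equal(nrow(intersectOffTargets(away, sites, slop = 25L)), 0L)
  # slop pulls nearby variants in
  near <- data.frame(chrom = "chr1", pos = 1040L, ref = "A", alt = "AT")
  expect_equal(nrow(intersectOffTargets(near, sites, slop = 0L)), 0L)
  expect_equal(nrow(intersectOffTargets(near, sites, slop = 25L)), 1L)
  expect_error(intersectOffTargets(near, sites, slop = -1L))
})

test_that("indel classification reproduces published ref/alt patterns", {
  got <- classifyIndel("TGTG", "TGTGGTG")
  expect_equal(got$kind, "insertion")
  expect_equal(got$net_length, 3L)
  got <- classifyIndel("AACAACAACAA", "AACAACAA")
  expect_equal(got$kind, "deletion")
  expect_equal(got$net_length, -3L)
  got <- classifyIndel("TGGGGG", "TGGGGGG")
  expect_equal(got$kind, "insertion")
  expect_equal(got$net_length, 1L)
  got <- classifyIndel("CAT", "C")
  expect_equal(got$kind, "deletion")
  expect_equal(got$net_length, -2L)
  expect_equal(classifyIndel("ACGT", "TTTT")$kind, "complex")
  expect_error(classifyIndel("A", "A"), "differ")
})

test_that("reframe annotation: exon frameshift yes, in-frame/intron no", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c(
    "chr1\t99\t200\tGENEA\t0\t+",     # exon GENEA 100-200 (1-based)
    "chr1\t299\t400\tGENEA\t0\t+",    # second exon; 201-299 is intron
    "chr1\t999\t1100\tGENEB\t0\t-"), bed)
  m <- readGeneModels(bed)
  v <- data.frame(
    chrom = "chr1",
    pos = c(150L, 250L, 150L, 5000L),
    ref = c("T", "GA", "A", "C"),
    alt = c("TG", "GATA", "AGGG", "CAT"))
  got <- annotateReframe(v, m)
  expect_equal(got$region, c("exon", "intron", "exon", "intergenic"))
  expect_equal(got$reframed, c("yes", "no", "no", NA))  # +1, +2, +3, n/a
  expect_equal(got$model_gene[1:3], c("GENEA", "GENEA", "GENEA"))
})
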