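test_that("mutation records classify by ref/alt shape", {
  expect_equal(classifyMutationRecord("G", "A"), "SNV")
  expect_equal(classifyMutationRecord("CAT", "C"), "deletion")
  expect_equal(classifyMutationRecord("TGTG", "TGTGGTG"), "insertion")
  expect_equal(classifyMutationRecord("AC", "GT"), "indel")
  # COSMIC-style empty alleles
  expect_equal(classifyMutationRecord("-", "ACG"), "insertion")
  expect_equal(classifyMutationRecord("ACG", "-"), "deletion")
  expect_equal(classifyMutationRecord(c("G", "GA"), c("A", "G")),
               c("SNV", "deletion"))
  expect_error(classifyMutationRecord("-", "-"), "empty")
  expect_error(classifyMutationRecord(c("A", "C"), "G"), "equal length")
})

test_that("catalog TSV loading: parsing, skipping, dedup, round-trip", {
  toy <- data.frame(
    gene = c("KRAS", "KRAS", "TP53", "EGFR"),
    chrom = "chr1", pos = c(34L, 35L, 100L, 200L),
    ref = c("G", "G", "CAT", "T"), alt = c("A", "T", "C", "TGG"))
  f <- tempfile(fileext = ".tsv")
  writeCatalog(toy, f)
  got <- loadCatalog(f)
  expect_equal(nrow(got), 4L)
  expect_equal(got$mutation_class,
               c("SNV", "SNV", "deletion", "insertion"))
  expect_equal(got[, names(toy)], toy)

  # malformed rows are skipped with a message when rare (< 10%) and fatal
  # when frequent
  big <- toy[rep(1:4, 3), ]
  big$pos <- 1:12
  writeCatalog(big, f)
  lines <- readLines(f)
  writeLines(c(lines, "BAD\tchr1\tnotanumber\tA\tC"), f)
  expect_message(got2 <- loadCatalog(f), "skipping 1 malformed")
  expect_equal(nrow(got2), 12L)
  writeLines(c(lines[1:3], "B\tchr1\tx\tA\tC"), f)
  expect_error(suppressMessages(loadCatalog(f)), "malformed")

  # duplicates removed with a count
  writeLines(c(lines, lines[2]), f)
  expect_message(got3 <- loadCatalog(f), "1 duplicate")
  expect_equal(nrow(got3), 12L)
})

test_that("VCF catalogs split multiallelic rows", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t34\t.\tG\tA,T\t.\tPASS\tGENE=KRAS",
    "chr1\t90\t.\tC\tCA\t.\tPASS\t."), f)
  got <- loadCatalog(f, format = "vcf")
  expect_equal(nrow(got), 3L)
  expect_equal(got$alt[1:2], c("A", "T"))
  expect_equal(got$gene[1:2], c("KRAS", "KRAS"))
  expect_equal(got$mutation_class, c("SNV", "SNV", "insertion"))
})

test_that("context extraction checks the reference and pads boundaries", {
  g <- genGenome(500, 0.5, seed = 9, name = "chrT")
  s <- as.character(g[[1]])
  pos <- 250L
  ref <- substr(s, pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  ctx <- extractContext(g, "chrT", pos, ref, alt, radius = 25L)
  expect_equal(substr(flankRef(ctx), 26, 26), ref)
  expect_equal(substr(flankAlt(ctx), 26, 26), alt)
  expect_equal(flankRef(ctx), substr(s, pos - 25L, pos + 25L))
  expect_false(ctx@truncated)

  # left boundary: window padded with N, offset invariant
  ref1 <- substr(s, 1, 1)
  alt1 <- setdiff(c("A", "C", "G", "T"), ref1)[1]
  ctx1 <- extractContext(g, "chrT", 1L, ref1, alt1, radius = 25L)
  expect_equal(nchar(flankRef(ctx1)), 51L)
  expect_equal(substr(flankRef(ctx1), 1, 25), strrep("N", 25))
  expect_true(ctx1@truncated)

  # reference mismatch names the offending locus
  other <- setdiff(c("A", "C", "G", "T"), ref)
  expect_error(extractContext(g, "chrT", pos, other[1], other[2],
                              radius = 25L), "chrT:250")
  expect_silent(extractContext(g, "chrT", pos, other[1], other[2],
                               radius = 25L, checkRef = FALSE))
  expect_error(extractContext(g, "nope", 10, "A", "C"), "not found")
  expect_error(extractContext(g, "chrT", 501L, "A", "C"), "outside")
})

test_that("summarizeCatalog recovers planted editable fractions exactly", {
  g <- genGenome(8000, 0.5, seed = 21)
  pl <- plantSnvCatalog(g, n = 80, fraction = 0.5, nuclease = spCas9(),
                        seed = 22)
  sm <- summarizeCatalog(pl$catalog, g, nucleases = list(SpCas9 = spCas9()))
  expect_equal(unname(sm$overall["SpCas9"]), 50)
  expect_equal(sm$n_snv_total, 80L)
  expect_equal(unname(sm$classPct["SNV"]), 100)

  # permutation invariance of the summary
  perm <- pl$catalog[sample.int(nrow(pl$catalog)), ]
  sm2 <- summarizeCatalog(perm, g, nucleases = list(SpCas9 = spCas9()))
  expect_equal(sm$overall, sm2$overall)
  expect_equal(sm$perGene[order(sm$perGene$gene), ],
               sm2$perGene[order(sm2$perGene$gene), ])

  # strand-category partition sums to the editable count, per gene
  pg <- sm$perGene
  expect_equal(pg$n_S_SpCas9 + pg$n_AS_SpCas9 + pg$n_SAS_SpCas9,
               pg$n_editable_SpCas9)
  expect_true(all(pg$pct_any >= 0 & pg$pct_any <= 100))
})

test_that("a PAM-free sequence yields zero percent editability", {
  # an AC dinucleotide repeat with a central A>G: the lone G can complete
  # no NGG, NNGRRT or TTTV window on either strand
  s <- strrep("AC", 300)
  g <- Biostrings::DNAStringSet(s)
  names(g) <- "flat"
  cat_ <- data.frame(gene = "X", chrom = "flat", pos = 301L,
                     ref = "A", alt = "G")
  sm <- summarizeCatalog(cat_, g)
  expect_true(all(sm$overall == 0))
})

test_that("percentages use half-up rounding to one decimal", {
  expect_equal(crisprAllele:::roundHalfUp(0.25, 1), 0.3)
  expect_equal(crisprAllele:::roundHalfUp(70.65, 1), 70.7)
  expect_equal(crisprAllele:::roundHalfUp(20.74, 1), 20.7)
})
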