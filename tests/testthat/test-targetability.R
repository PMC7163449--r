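# helper: a random SNV context wide enough for the given nuclease
rand_context <- function(nuc, pad = 0L) {
  r <- contextRadius(nuc) + pad
  win <- rand_seq(2L * r + 1L)
  ref <- substr(win, r + 1L, r + 1L)
  alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
  SnvContext(win, offset = r + 1L, altBase = alt)
}

test_that("the KRAS G12S context is SpCas9-editable via a seed guide", {
  ctx <- krasG12SContext()
  call <- editability(ctx, spCas9())
  expect_true(isEditable(call))
  expect_equal(strandCategory(call), "S")
  g <- rankGuides(call)
  expect_true(all(g$snv_in == "seed"))
  # the PAM-proximal guide ends two bases from the variant (the TGG PAM
  # immediately 3' of codon 12)
  expect_equal(g$snv_to_pam_distance[1], 2L)
  expect_equal(g$pam[1], "TGG")
  # every qualifying guide carries a discriminating wild-type mismatch
  expect_true(all(g$wt_mismatch_count >= 1L))
})

test_that("a window without PAM-compatible bases yields no candidates", {
  # 47 nt of alternating AT: no G or C anywhere, and a T>A change at the
  # centre cannot create one on either strand
  win <- paste0(strrep("AT", 23), "A")
  ctx <- SnvContext(win, offset = 24L, altBase = "A")
  expect_equal(nrow(enumerateProtospacers(ctx, spCas9())), 0L)
  expect_false(isEditable(editability(ctx, spCas9())))
})

test_that("candidate enumeration matches the brute-force oracle", {
  set.seed(101)
  for (nuc in nucleaseRegistry()) {
    for (i in 1:70) {
      ctx <- rand_context(nuc)
      got <- enumerateProtospacers(ctx, nuc)
      want <- oracle_candidates(flankAlt(ctx), snvOffset(ctx), nuc)
      expect_equal(cand_key(got$strand, got$pam_start, got$snv_in,
                            got$snv_to_pam_distance),
                   cand_key(want$strand, want$pam_start, want$snv_in,
                            want$dist),
                   info = paste(nucleaseName(nuc), "context", i))
      expect_equal(isEditable(editability(ctx, nuc)),
                   oracle_editable(flankAlt(ctx), snvOffset(ctx), nuc))
    }
  }
})

test_that("editability is monotone in seed length", {
  set.seed(202)
  nuc <- spCas9()
  for (i in 1:100) {
    ctx <- rand_context(nuc)
    for (s in c(4L, 8L, 12L)) {
      lo <- nuc; seedLength(lo) <- s
      hi <- nuc; seedLength(hi) <- s + 1L
      if (isEditable(editability(ctx, lo)))
        expect_true(isEditable(editability(ctx, hi)),
                    info = paste("context", i, "seed", s))
    }
  }
})

test_that("strict discrimination only removes degenerate-position hits", {
  set.seed(303)
  nuc <- spCas9()
  sawDifference <- FALSE
  for (i in 1:150) {
    ctx <- rand_context(nuc)
    lax <- editability(ctx, nuc, strict = FALSE)
    strict <- editability(ctx, nuc, strict = TRUE)
    # strict qualifying set is a subset of the lax one
    expect_true(all(which(guides(strict)$qualifying) %in%
                    which(guides(lax)$qualifying)))
    if (isEditable(lax) && !isEditable(strict)) sawDifference <- TRUE
    # anything dropped by strict mode must have zero wild-type mismatches
    dropped <- guides(lax)$qualifying & !guides(strict)$qualifying
    expect_true(all(guides(lax)$wt_mismatch_count[dropped] == 0L))
  }
  # the N of NGG: an SNV there matches both alleles, so lax mode counts it
  # (it is in the PAM) but strict mode must refuse it
  win <- paste0(strrep("AT", 11), "A", "GG", strrep("TA", 12))
  ctx <- SnvContext(win, offset = 23L, altBase = "T")  # N-position SNV
  lax <- editability(ctx, spCas9())
  strict <- editability(ctx, spCas9(), strict = TRUE)
  expect_true(isEditable(lax))
  expect_equal(guides(lax)$snv_in[guides(lax)$qualifying], "pam")
  expect_false(isEditable(strict))
})

test_that("rankGuides is a deterministic total order", {
  ctx <- krasG12SContext()
  call <- editability(ctx, spCas9())
  r <- rankGuides(call)
  expect_true(all(diff(r$snv_to_pam_distance) >= 0))
  # single qualifying guide ranks as itself
  one <- call
  g <- guides(call)
  keep <- which(g$qualifying)[1]
  g$qualifying[-keep] <- FALSE
  one@guides <- g
  expect_equal(rankGuides(one)$protospacer, g$protospacer[keep])
  # no qualifying guides -> empty ranking
  none <- editability(SnvContext(paste0(strrep("A", 22), "G",
                                        strrep("A", 23)), 23L, "T"),
                      spCas9())
  expect_equal(nrow(rankGuides(none)), 0L)
  # random contexts: the ordering keys never collide
  set.seed(404)
  for (i in 1:50) {
    r <- rankGuides(editability(rand_context(spCas9()), spCas9()))
    if (nrow(r) > 1L) {
      keys <- paste(r$snv_to_pam_distance, r$strand, r$protospacer)
      expect_false(anyDuplicated(keys) > 0)
    }
  }
})

test_that("a too-short window is refused", {
  ctx <- SnvContext("AAAGAAA", offset = 4L, altBase = "T")
  expect_error(enumerateProtospacers(ctx, spCas9()), "too short")
})
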