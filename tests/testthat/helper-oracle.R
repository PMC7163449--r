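# Independent first-principles oracles used to cross-check the production
# scanners. Everything here is written from the definitions with plain
# loops and its own degeneracy table; nothing is shared with the package
# internals beyond exported constructors.

ORACLE_IUPAC <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
                  S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT",
                  D = "AGT", H = "ACT", V = "ACG", N = "ACGTN")

oracle_base_ok <- function(patternChar, base) {
  base %in% strsplit(ORACLE_IUPAC[[patternChar]], "")[[1]]
}

oracle_window_ok <- function(chars, i, patChars) {
  for (k in seq_along(patChars)) {
    if (!oracle_base_ok(patChars[k], chars[i + k - 1L])) return(FALSE)
  }
  TRUE
}

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

rand_seq <- function(n, withN = FALSE) {
  alpha <- c("A", "C", "G", "T")
  s <- sample(alpha, n, replace = TRUE)
  if (withN) {
    k <- rbinom(1, n, 0.02)
    if (k > 0) s[sample.int(n, k)] <- "N"
  }
  paste(s, collapse = "")
}

# all PAM sites of `seq` for a nuclease, by looping every window on each
# strand. Reverse-strand windows are tested by reading the forward window
# backwards through the complement, and geometry is derived directly from
# the strand orientation (for a 3' PAM on the reverse strand the
# protospacer lies at HIGHER forward coordinates than the PAM).
oracle_pam_sites <- function(seq, nuc) {
  pat <- pamConsensus(nuc)
  patChars <- strsplit(pat, "")[[1]]
  plen <- length(patChars)
  sp <- spacerLength(nuc)
  sd <- seedLength(nuc)
  side <- pamSide(nuc)
  chars <- strsplit(seq, "")[[1]]
  comp <- strsplit(chartr("ACGTN", "TGCAN", seq), "")[[1]]
  L <- length(chars)
  rows <- list()
  for (i in seq_len(max(0L, L - plen + 1L))) {
    if (oracle_window_ok(chars, i, patChars)) {
      if (side == "3prime") {
        ps <- i - sp; pe <- i - 1L; ss <- i - sd; se <- i - 1L
      } else {
        ps <- i + plen; pe <- i + plen + sp - 1L
        ss <- i + plen; se <- i + plen + sd - 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        start = i, end = i + plen - 1L, strand = "+",
        proto_start = ps, proto_end = pe, seed_start = ss, seed_end = se,
        truncated = ps < 1L || pe > L)
    }
    # reverse strand: guide reads complement right-to-left, so pattern
    # position k sits at forward position i + plen - k
    ok <- TRUE
    for (k in seq_len(plen)) {
      if (!oracle_base_ok(patChars[k], comp[i + plen - k])) {
        ok <- FALSE; break
      }
    }
    if (ok) {
      if (side == "3prime") {
        ps <- i + plen; pe <- i + plen + sp - 1L
        ss <- i + plen; se <- i + plen + sd - 1L
      } else {
        ps <- i - sp; pe <- i - 1L; ss <- i - sd; se <- i - 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        start = i, end = i + plen - 1L, strand = "-",
        proto_start = ps, proto_end = pe, seed_start = ss, seed_end = se,
        truncated = ps < 1L || pe > L)
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), proto_start = integer(0),
                      proto_end = integer(0), seed_start = integer(0),
                      seed_end = integer(0), truncated = logical(0)))
  do.call(rbind, rows)
}

site_key <- function(d) {
  sort(paste(d$start, d$end, d$strand, d$proto_start, d$proto_end,
             d$seed_start, d$seed_end, d$truncated, sep = "/"))
}

# guide candidates covering the SNV of a mutant-allele window: every
# non-truncated PAM site whose protospacer-or-PAM span contains the SNV,
# annotated with seed/pam/distal membership and PAM distance
oracle_candidates <- function(flankAlt, snvPos, nuc) {
  sites <- oracle_pam_sites(flankAlt, nuc)
  sites <- sites[!sites$truncated, , drop = FALSE]
  out <- list()
  for (r in seq_len(nrow(sites))) {
    s <- sites[r, ]
    lo <- min(s$proto_start, s$start); hi <- max(s$proto_end, s$end)
    if (snvPos < lo || snvPos > hi) next
    inPam <- snvPos >= s$start && snvPos <= s$end
    inSeed <- snvPos >= s$seed_start && snvPos <= s$seed_end
    proximal <- if (s$start < s$proto_start) s$proto_start else s$proto_end
    dist <- if (inPam) 0L else abs(snvPos - proximal) + 1L
    out[[length(out) + 1L]] <- data.frame(
      strand = s$strand, pam_start = s$start,
      snv_in = if (inSeed) "seed" else if (inPam) "pam" else "distal",
      dist = dist)
  }
  if (!length(out))
    return(data.frame(strand = character(0), pam_start = integer(0),
                      snv_in = character(0), dist = integer(0)))
  do.call(rbind, out)
}

cand_key <- function(strand, pam_start, snv_in, dist) {
  sort(paste(strand, pam_start, snv_in, dist, sep = "/"))
}

oracle_editable <- function(flankAlt, snvPos, nuc) {
  any(oracle_candidates(flankAlt, snvPos, nuc)$snv_in %in% c("seed", "pam"))
}

# every off-target site: windows on both strands with a matching PAM and
# <= maxMM spacer mismatches (spacer compared in guide orientation)
oracle_offtargets <- function(seq, spacer, nuc, maxMM) {
  sites <- oracle_pam_sites(seq, nuc)
  sites <- sites[!sites$truncated, , drop = FALSE]
  spChars <- strsplit(spacer, "")[[1]]
  out <- list()
  for (r in seq_len(nrow(sites))) {
    s <- sites[r, ]
    obs <- substr(seq, s$proto_start, s$proto_end)
    if (s$strand == "-") obs <- oracle_revcomp(obs)
    obsChars <- strsplit(obs, "")[[1]]
    mm <- sum(obsChars != spChars)
    if (mm <= maxMM)
      out[[length(out) + 1L]] <- data.frame(
        proto_start = s$proto_start, strand = s$strand, mm = mm)
  }
  if (!length(out))
    return(data.frame(proto_start = integer(0), strand = character(0),
                      mm = integer(0)))
  do.call(rbind, out)
}

# exhaustive global-alignment score by recursive enumeration of all move
# sequences under affine gap costs (a gap of length g costs open + g*ext);
# feasible for strings up to ~6 bases
oracle_align_score <- function(a, b, match = 5, mismatch = -4,
                               open = 10, ext = 1) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  n <- length(ac); m <- length(bc)
  rec <- function(i, j, last) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      sc <- if (ac[i] == bc[j]) match else mismatch
      best <- max(best, sc + rec(i + 1L, j + 1L, "M"))
    }
    if (i <= n) {
      cost <- ext + if (last == "U") 0 else open
      best <- max(best, rec(i + 1L, j, "U") - cost)
    }
    if (j <= m) {
      cost <- ext + if (last == "L") 0 else open
      best <- max(best, rec(i, j + 1L, "L") - cost)
    }
    best
  }
  rec(1L, 1L, "none")
}
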