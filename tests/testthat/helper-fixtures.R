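# Shared fixtures and independent brute-force oracles. The oracles re-derive
# every annotation from the documented site conventions using plain regex /
# substring scans, deliberately avoiding the package's internal helpers.

# O(1) byte length (chromosome strings are ASCII)
ncb <- function(s) nchar(s, type = "bytes")

randSeq <- function(n, seed = 1, gc = 0.4) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

smallCloneSet <- function() {
  cloneSet(c("a1", "a2", "a3", "b1", "b2"),
           c("A", "A", "A", "B", "B"),
           c("wt", "wt", "wt", "ko", "ko"))
}

vkey <- function(d) paste(d$chrom, d$pos, d$ref, d$alt)

# --- oracle: CG dinucleotide starts via fixed-string regex ------------------
oracleCgStarts <- function(s) {
  out <- integer(0); from <- 1L
  repeat {
    m <- regexpr("CG", substr(s, from, ncb(s)), fixed = TRUE)
    if (m == -1L) break
    out <- c(out, from + as.integer(m) - 1L)
    from <- from + as.integer(m)      # step one base: catches every start
  }
  out
}

# --- oracle: CpG within w of an indel site ----------------------------------
# INS anchor a: CG start q in [a+1-w, a+w]. DEL span [a+1, a+L]: CG footprint
# [q, q+1] intersects [a+1-w, a+L+w], i.e. q in [a-w, a+L+w]. The scan is
# restricted to a window just covering the admissible q range.
oracleCpgWithin <- function(s, a, vclass, L, w) {
  if (vclass == "INS") { lo <- a + 1L - w; hi <- a + w }
  else { lo <- a - w; hi <- a + L + w }
  win0 <- max(1L, lo)
  win <- substr(s, win0, min(ncb(s), hi + 1L))
  q <- oracleCgStarts(win) + win0 - 1L
  any(q >= lo & q <= hi)
}

# --- oracle: junction microhomology by trying all alignments ----------------
oracleMH <- function(s, s0, e0) {
  L <- e0 - s0 + 1L
  del <- substr(s, s0, e0)
  best <- 0L
  for (k in seq_len(L)) {            # 3' junction: prefix vs downstream
    if (e0 + k > ncb(s)) break
    if (substr(del, 1L, k) == substr(s, e0 + 1L, e0 + k)) best <- max(best, k)
  }
  for (k in seq_len(L)) {            # 5' junction: suffix vs upstream
    if (s0 - k < 1L) break
    if (substr(del, L - k + 1L, L) == substr(s, s0 - k, s0 - 1L))
      best <- max(best, k)
  }
  min(best, L)
}

# --- oracle: templated duplication ------------------------------------------
oracleDup <- function(s, a, S) {
  L <- nchar(S)
  a + L <= ncb(s) && toupper(S) == toupper(substr(s, a + 1L, a + L))
}

# --- oracle: repeat-context class -------------------------------------------
# Regex scan for maximal runs; a run qualifies when a phase-aligned copy
# boundary coincides with the anchor gap (copies ending at a plus copies
# starting at a+1 total >= 5), or a run of >= 5 copies starts at a+2 or ends
# at a-1 (the 1 bp abut tolerance).
oracleRunCount <- function(s, a, unit) {
  k <- nchar(unit)
  left <- 0L; p <- a
  while (p - k + 1L >= 1L && substr(s, p - k + 1L, p) == unit) {
    left <- left + 1L; p <- p - k
  }
  right <- 0L; p <- a + 1L
  while (p + k - 1L <= ncb(s) && substr(s, p, p + k - 1L) == unit) {
    right <- right + 1L; p <- p + k
  }
  c(main = left + right,
    tolr = oracleRightRun(s, a + 2L, unit),
    toll = oracleLeftRun(s, a - 1L, unit))
}
oracleRightRun <- function(s, from, unit) {
  k <- nchar(unit); n <- 0L; p <- from
  while (p + k - 1L <= ncb(s) && substr(s, p, p + k - 1L) == unit) {
    n <- n + 1L; p <- p + k
  }
  n
}
oracleLeftRun <- function(s, to, unit) {
  k <- nchar(unit); n <- 0L; p <- to
  while (p - k + 1L >= 1L && substr(s, p - k + 1L, p) == unit) {
    n <- n + 1L; p <- p - k
  }
  n
}
oracleRepeatClass <- function(s, a, S, min_copies = 5L, max_motif = 6L) {
  L <- nchar(S)
  chars <- unique(strsplit(S, "", fixed = TRUE)[[1]])
  if (length(chars) == 1L &&
      max(oracleRunCount(s, a, chars)) >= min_copies)
    return("homopolymer")
  for (k in 2:min(max_motif, L)) {
    if (L %% k != 0L) next
    m <- substr(S, 1L, k)
    if (strrep(m, L %/% k) != S) next
    if (length(unique(strsplit(m, "", fixed = TRUE)[[1]])) == 1L) next
    if (max(oracleRunCount(s, a, m)) >= min_copies) return("tandem_repeat")
  }
  "nonrepeat"
}

# --- oracle: SBS96 category via lookup table --------------------------------
oracleSbs96 <- function(s, pos, refb, altb) {
  if (pos < 2L || pos > ncb(s) - 1L) return(NA_character_)
  tri <- substr(s, pos - 1L, pos + 1L)
  if (grepl("[^ACGT]", tri)) return(NA_character_)
  rc <- function(x) paste(rev(strsplit(chartr("ACGT", "TGCA", x), "",
                                       fixed = TRUE)[[1]]), collapse = "")
  if (refb %in% c("A", "G")) {
    tri <- rc(tri); refb <- rc(refb); altb <- rc(altb)
  }
  paste0(substr(tri, 1, 1), "[", refb, ">", altb, "]", substr(tri, 3, 3))
}

# Random anchored indels on a sequence, for property tests.
randomIndels <- function(s, n, seed, chrom = "chr1", max_len = 8L) {
  set.seed(seed)
  pos <- sample(150:(ncb(s) - 150L), n)
  len <- sample(seq_len(max_len), n, replace = TRUE)
  ins <- runif(n) < 0.5
  ref <- character(n); alt <- character(n)
  for (i in seq_len(n)) {
    anchor <- substr(s, pos[i], pos[i])
    if (ins[i]) {
      S <- paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE),
                 collapse = "")
      ref[i] <- anchor; alt[i] <- paste0(anchor, S)
    } else {
      ref[i] <- substr(s, pos[i], pos[i] + len[i])
      alt[i] <- anchor
    }
  }
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             vclass = ifelse(ins, "INS", "DEL"), stringsAsFactors = FALSE)
}
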