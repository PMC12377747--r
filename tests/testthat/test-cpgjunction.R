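# CpG proximity/profile, CpG gain/loss bookkeeping, templated duplications,
# and deletion-junction microhomology.

test_that("cpgWithin follows the site conventions", {
  # insertion point directly 3' of ...AACG| : CG start two bases upstream
  ref <- c(chr1 = "TTAACGTTTTTTTTTTTTTTTTTT")
  r <- cpgWithin("chr1", 6, "G", "GAT", ref, w = 2)
  expect_true(r$within)
  expect_identical(r$count, 1L)
  # no C or G within 10 bp
  r2 <- cpgWithin("chr1", 15, "T", "TA", ref, w = 2)
  r10 <- cpgWithin("chr1", 15, "T", "TA", ref, w = 10)
  expect_false(r2$within)
  expect_false(r10$within)
  # a CpG wholly inside a deleted span counts as at-the-site
  ref2 <- c(chr1 = "TTTTTACGATTTTT")
  rdel <- cpgWithin("chr1", 5, "TACGA", "T", ref2, w = 2)
  expect_true(rdel$within)
})

test_that("cpgWithin(2) implies cpgWithin(10) and matches the brute scan", {
  s <- randSeq(10000, seed = 101)
  ref <- c(chr1 = s)
  vars <- randomIndels(s, 500, seed = 102)
  for (i in seq_len(nrow(vars))) {
    L <- abs(nchar(vars$ref[i]) - nchar(vars$alt[i]))
    for (w in c(2L, 10L)) {
      got <- cpgWithin("chr1", vars$pos[i], vars$ref[i], vars$alt[i],
                       ref, w = w)$within
      want <- oracleCpgWithin(s, vars$pos[i], vars$vclass[i], L, w)
      expect_identical(got, want)
    }
    w2 <- cpgWithin("chr1", vars$pos[i], vars$ref[i], vars$alt[i], ref, 2)
    w10 <- cpgWithin("chr1", vars$pos[i], vars$ref[i], vars$alt[i], ref, 10)
    if (w2$within) expect_true(w10$within)
  }
})

test_that("cpgProfile localizes planted CpGs and conserves counts", {
  # all insertions exactly 5 bp 5' of a planted CG -> single spike
  base <- strsplit(strrep("T", 400), "")[[1]]
  base[201] <- "C"; base[202] <- "G"
  ref <- c(chr1 = paste(base, collapse = ""))
  vars <- data.frame(chrom = "chr1", pos = 195, ref = "T", alt = "TA",
                     stringsAsFactors = FALSE)
  prof <- cpgProfile(vars, ref, w = 100)
  expect_equal(sum(prof$frequency), 1)
  expect_equal(prof$frequency[prof$offset == 6], 1)  # CG at q = pos + 6

  # CpG-free sequence -> all-zero profile
  ref0 <- c(chr1 = strrep("AT", 300))
  vars0 <- data.frame(chrom = "chr1", pos = c(150, 200), ref = "A",
                      alt = "AG", stringsAsFactors = FALSE)
  expect_true(all(cpgProfile(vars0, ref0, w = 50)$frequency == 0))

  # profile totals equal brute-force window CG counts
  s <- randSeq(20000, seed = 7)
  ref1 <- c(chr1 = s)
  vars1 <- randomIndels(s, 100, seed = 8)
  prof1 <- cpgProfile(vars1, ref1, w = 100)
  brute <- 0
  q <- oracleCgStarts(s)
  for (i in seq_len(nrow(vars1))) {
    a <- vars1$pos[i]
    L <- abs(nchar(vars1$ref[i]) - nchar(vars1$alt[i]))
    if (vars1$vclass[i] == "INS")
      brute <- brute + sum(q >= a + 1 - 100 & q <= a + 100)
    else
      brute <- brute + sum(q + 1 >= a + 1 - 100 & q <= a + L + 100)
  }
  expect_equal(sum(prof1$frequency) * nrow(vars1), brute)
})

test_that("cpgGainLoss tracks created and destroyed CpG sites", {
  # inserting CG gains one site
  ref <- c(chr1 = "TTTAAAGTTTTTTTTT")
  g1 <- cpgGainLoss("chr1", 6, "A", "ACG", ref)
  expect_identical(g1, list(gain = 1L, loss = 0L))
  # deleting a CG loses one
  ref2 <- c(chr1 = "TTTTACGATTTTTTTT")
  g2 <- cpgGainLoss("chr1", 5, "ACG", "A", ref2)
  expect_identical(g2, list(gain = 0L, loss = 1L))
  # junction deletion creates a new CG
  ref3 <- c(chr1 = "TTTTTCAGTTTTTTTT")
  g3 <- cpgGainLoss("chr1", 6, "CA", "C", ref3)
  expect_identical(g3, list(gain = 1L, loss = 0L))
})

test_that("gain - loss equals the net window CpG change on random indels", {
  s <- randSeq(10000, seed = 55, gc = 0.55)
  ref <- c(chr1 = s)
  vars <- randomIndels(s, 300, seed = 56)
  w <- 10L
  for (i in seq_len(nrow(vars))) {
    a <- vars$pos[i]
    gl <- cpgGainLoss("chr1", a, vars$ref[i], vars$alt[i], ref, w = w)
    # recount window strings directly
    if (vars$vclass[i] == "INS") {
      S <- substr(vars$alt[i], 2, nchar(vars$alt[i]))
      before <- substr(s, a + 1 - w, a + w)
      after <- paste0(substr(s, a + 1 - w, a), S, substr(s, a + 1, a + w))
    } else {
      L <- nchar(vars$ref[i]) - 1
      before <- substr(s, a + 1 - w, a + L + w)
      after <- paste0(substr(s, a + 1 - w, a), substr(s, a + L + 1, a + L + w))
    }
    net <- length(oracleCgStarts(after)) - length(oracleCgStarts(before))
    expect_identical(gl$gain - gl$loss, as.integer(net))
    expect_gte(gl$gain, 0L); expect_gte(gl$loss, 0L)
  }
})

test_that("isDuplication detects templated downstream insertions", {
  ref <- c(chr1 = "TTACCGGTAAATTTTT")
  d1 <- isDuplication("chr1", 3, "A", "ACCGG", ref)
  expect_true(d1$is_dup)
  expect_identical(d1$duplicated_span, 4L)
  d2 <- isDuplication("chr1", 3, "A", "ATTTT", ref)
  expect_false(d2$is_dup)
  # case-insensitive
  d3 <- isDuplication("chr1", 3, "A", "accgg", ref)
  expect_true(d3$is_dup)
  # contig end: undecidable -> FALSE with edge flag
  d4 <- isDuplication("chr1", 14, "T", "TAAAA", ref)
  expect_false(d4$is_dup)
  expect_true(d4$edge)
})

test_that("microhomology matches the junction-scan oracle", {
  # deleted GCTA, downstream GCCC, upstream AATT -> prefix match GC = 2
  ref <- c(chr1 = "TAATTGCTAGCCCTT")
  m1 <- microhomology("chr1", 5, "TGCTA", "T", ref)
  expect_identical(m1$mh_len, 2L)
  expect_false(m1$full_homology)
  # no terminal bases shared
  ref2 <- c(chr1 = "TTTTTGCATTTTTTT")
  m2 <- microhomology("chr1", 5, "TGCA", "T", ref2)
  expect_identical(m2$mh_len, 0L)
  # AA deleted inside AAAAA: full homology, capped at deletion length
  ref3 <- c(chr1 = "TGCAAAAAGCTTTTT")
  m3 <- microhomology("chr1", 3, "CAA", "C", ref3)
  expect_identical(m3$mh_len, 2L)
  expect_true(m3$full_homology)

  # random spans against the exhaustive oracle
  s <- randSeq(8000, seed = 77)
  refs <- c(chr1 = s)
  set.seed(78)
  for (i in 1:300) {
    a <- sample(100:7800, 1)
    L <- sample(1:12, 1)
    got <- microhomology("chr1", a, substr(s, a, a + L), substr(s, a, a),
                         refs)$mh_len
    expect_identical(got, oracleMH(s, a + 1L, a + L))
  }
})

test_that("annotations are strand-invariant (CG is its own complement)", {
  s <- "TTACGTTTTTCCGGAATTTTTTTT"
  L <- nchar(s)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  fwd <- c(chr1 = s); rev <- c(chr1 = rc)
  # insertion after a=6 on fwd == insertion after a' = L - 6 on rc
  a <- 6L
  f <- cpgWithin("chr1", a, substr(s, a, a),
                 paste0(substr(s, a, a), "AT"), fwd, w = 3)
  ap <- L - a
  r <- cpgWithin("chr1", ap, substr(rc, ap, ap),
                 paste0(substr(rc, ap, ap), "AT"), rev, w = 3)
  expect_identical(f$within, r$within)
  expect_identical(f$count, r$count)
  # deletion span [s0, e0] on fwd maps to [L-e0+1, L-s0+1] on rc
  s0 <- 11L; e0 <- 14L
  fd <- cpgWithin("chr1", s0 - 1L, substr(s, s0 - 1L, e0),
                  substr(s, s0 - 1L, s0 - 1L), fwd, w = 2)
  s0r <- L - e0 + 1L
  rd <- cpgWithin("chr1", s0r - 1L, substr(rc, s0r - 1L, L - s0 + 1L),
                  substr(rc, s0r - 1L, s0r - 1L), rev, w = 2)
  expect_identical(fd$within, rd$within)
  expect_identical(fd$count, rd$count)
})
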