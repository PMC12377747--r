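# SBS96 / ID83 category assignment, count conservation, NNLS refitting, and
# the CpG>GpG transversion tally.

test_that("category alphabets have the fixed sizes and orders", {
  expect_identical(length(sbs96Categories()), 96L)
  expect_identical(anyDuplicated(sbs96Categories()), 0L)
  expect_identical(sbs96Categories()[1], "A[C>A]A")
  expect_identical(length(id83Categories()), 83L)
  expect_identical(anyDuplicated(id83Categories()), 0L)
  expect_identical(id83Categories()[1], "1:Del:C:0")
  expect_identical(id83Categories()[83], "5:Del:M:5")
})

test_that("sbs96Matrix collapses purine references to the pyrimidine strand", {
  # G>A in 5'-TGA-3' context == C>T at 5'-TCA-3'
  ref <- c(chr1 = "AAATGAAAAA")
  snvs <- data.frame(chrom = "chr1", pos = 5, ref = "G", alt = "A",
                     clone_id = "s1", stringsAsFactors = FALSE)
  m <- sigCounts(sbs96Matrix(snvs, ref))
  expect_identical(sum(m), 1L)
  expect_identical(m["T[C>T]A", "s1"], 1L)

  # one C>T at ACA: that cell 1, column sum 1
  ref2 <- c(chr1 = "TTACATTT")
  snvs2 <- data.frame(chrom = "chr1", pos = 4, ref = "C", alt = "T",
                      clone_id = "s1", stringsAsFactors = FALSE)
  m2 <- sigCounts(sbs96Matrix(snvs2, ref2))
  expect_identical(m2["A[C>T]A", "s1"], 1L)
  expect_identical(as.integer(colSums(m2)[["s1"]]), 1L)
})

test_that("sbs96Matrix equals the independent per-variant classifier", {
  s <- randSeq(20000, seed = 31)
  ref <- c(chr1 = s)
  set.seed(32)
  n <- 500
  pos <- sample(100:19900, n)
  refb <- vapply(pos, function(p) substr(s, p, p), character(1))
  altb <- vapply(refb, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  snvs <- data.frame(chrom = "chr1", pos = pos, ref = refb, alt = altb,
                     clone_id = sample(c("x", "y"), n, replace = TRUE),
                     stringsAsFactors = FALSE)
  m <- sigCounts(sbs96Matrix(snvs, ref, samples = c("x", "y")))
  want <- matrix(0L, 96, 2, dimnames = list(sbs96Categories(), c("x", "y")))
  for (i in seq_len(n)) {
    cat <- oracleSbs96(s, pos[i], refb[i], altb[i])
    want[cat, snvs$clone_id[i]] <- want[cat, snvs$clone_id[i]] + 1L
  }
  expect_identical(m, want)
  expect_equal(colSums(m), c(x = sum(snvs$clone_id == "x"),
                                 y = sum(snvs$clone_id == "y")))
})

test_that("sbs96 classification is reverse-complement invariant", {
  s <- randSeq(5000, seed = 41)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  L <- nchar(s)
  set.seed(42)
  pos <- sample(50:4950, 200)
  refb <- vapply(pos, function(p) substr(s, p, p), character(1))
  altb <- vapply(refb, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  fwd <- data.frame(chrom = "chr1", pos = pos, ref = refb, alt = altb,
                    clone_id = "s", stringsAsFactors = FALSE)
  comp <- function(x) chartr("ACGT", "TGCA", x)
  rev <- data.frame(chrom = "chr1", pos = L - pos + 1L, ref = comp(refb),
                    alt = comp(altb), clone_id = "s", stringsAsFactors = FALSE)
  expect_identical(sigCounts(sbs96Matrix(fwd, c(chr1 = s))),
                   sigCounts(sbs96Matrix(rev, c(chr1 = rc))))
})

test_that("contexts containing N are excluded and logged", {
  ref <- c(chr1 = "ANCAT")
  snvs <- data.frame(chrom = "chr1", pos = c(3, 1), ref = c("C", "A"),
                     alt = c("T", "G"), clone_id = "s1",
                     stringsAsFactors = FALSE)
  m <- sbs96Matrix(snvs, ref)
  expect_identical(sum(sigCounts(m)), 0L)   # N context + contig edge
  expect_identical(as.integer(attr(m, "excluded")[["s1"]]), 2L)
})

test_that("id83 classification follows the COSMIC binning rules", {
  cls <- function(s, pos, ref, alt) {
    m <- id83Matrix(data.frame(chrom = "chr1", pos = pos, ref = ref,
                               alt = alt, clone_id = "s1",
                               stringsAsFactors = FALSE), c(chr1 = s))
    rownames(sigCounts(m))[sigCounts(m)[, 1] > 0]
  }
  # 1 bp T deletion inside a run of 6 T's -> longest homopolymer bin
  expect_identical(cls("AGCTTTTTTAGC", 4, "TT", "T"), "1:Del:T:5")
  # 1 bp G deletion with no neighbours, purine collapsed to C, bin 0
  expect_identical(cls("ATAGATAAAT", 3, "AG", "A"), "1:Del:C:0")
  # 1 bp C insertion with no pre-existing copy -> 0 copies
  expect_identical(cls("ATATATTTAT", 4, "T", "TC"), "1:Ins:C:0")
  # 1 bp A insertion next to 2 existing A's
  expect_identical(cls("TTGAATTTTT", 3, "G", "GA"), "1:Ins:T:2")
  # 3 bp deletion of one unit from a 5-copy tract: 5 units incl. deleted
  expect_identical(cls("TTCAGCAGCAGCAGCAGTT", 2, "TCAG", "T"), "3:Del:R:4")
  # 2 bp insertion duplicating one existing copy
  expect_identical(cls("TTGCATTTTT", 2, "T", "TGC"), "2:Ins:R:1")
  # 5 bp deletion, no tandem context, microhomology 2
  s <- "TAATTGCTAGGCCCCTTAAT"     # deleted GCTAG, downstream GCCCC: mh 2
  expect_identical(cls(s, 5, "TGCTAG", "T"), "5:Del:M:2")
  # 4 bp deletion, no repeat, no microhomology
  expect_identical(cls("TTTTTGCAATTTTTTT", 5, "TGCAA", "T"), "4:Del:R:0")
})

test_that("id83 column sums conserve input indel counts", {
  spec <- genomeSpec(n_chromosomes = 1, chrom_length = 150000, dmr_count = 5,
                     repeat_tract_count = 80, seed = 17)
  ref <- generateReference(spec)
  cs <- smallCloneSet()
  des <- cloneDesign(clones = cs, shared_per_animal = 0, unique_snv_rate = 0,
                     unique_indel_rate = 15, repeat_indel_fraction = 0.5)
  truth <- plantMutations(ref, des, seed = 21)
  m <- id83Matrix(truth, ref$genome, samples = cloneIds(cs))
  expect_identical(sum(sigCounts(m)) + sum(attr(m, "excluded")),
                   nrow(truth))
  expect_identical(sum(attr(m, "excluded")), 0L)
  percl <- table(factor(truth$clone_id, levels = cloneIds(cs)))
  expect_equal(unname(colSums(sigCounts(m))), as.numeric(percl))
})

test_that("refitSignatures recovers exact and noisy mixtures", {
  refs <- syntheticSignatureCatalog("SBS96", n = 3, seed = 5)
  # pure signature
  m1 <- matrix(round(1000 * refs[, 2]), 96, 1,
               dimnames = list(sbs96Categories(), "s"))
  r1 <- refitSignatures(signatureMatrix(m1, "SBS96"), refs)
  expect_gt(r1$contributions["synthSig2", "s"], 0.99)
  expect_lt(r1$residual_norm[["s"]], 0.01)
  # exact 0.5/0.5 mixture
  m2 <- matrix(round(2000 * (0.5 * refs[, 1] + 0.5 * refs[, 3])), 96, 1,
               dimnames = list(sbs96Categories(), "s"))
  r2 <- refitSignatures(signatureMatrix(m2, "SBS96"), refs)
  expect_lt(abs(r2$contributions["synthSig1", "s"] - 0.5), 0.02)
  expect_lt(abs(r2$contributions["synthSig3", "s"] - 0.5), 0.02)
  # weights are proportions
  expect_equal(sum(r2$contributions[, "s"]), 1)
  # alphabet mismatch errors
  bad <- refs[1:95, ]
  expect_error(refitSignatures(signatureMatrix(m2, "SBS96"), bad),
               "alphabet mismatch")
})

test_that("adding a signature never increases the refit residual", {
  refs <- syntheticSignatureCatalog("SBS96", n = 4, seed = 9)
  set.seed(10)
  cvec <- as.integer(table(factor(
    sample(1:96, 400, replace = TRUE,
           prob = 0.6 * refs[, 1] + 0.4 * refs[, 4]), levels = 1:96)))
  m <- matrix(cvec, 96, 1, dimnames = list(sbs96Categories(), "s"))
  sm <- signatureMatrix(m, "SBS96")
  r2 <- refitSignatures(sm, refs[, c(1, 2)], prune_threshold = 0)
  r3 <- refitSignatures(sm, refs[, c(1, 2, 3)], prune_threshold = 0)
  r4 <- refitSignatures(sm, refs, prune_threshold = 0)
  expect_lte(r3$residual_norm[["s"]], r2$residual_norm[["s"]] + 1e-12)
  expect_lte(r4$residual_norm[["s"]], r3$residual_norm[["s"]] + 1e-12)
})

test_that("cpgTransversionTally counts C>G at CpG on either strand", {
  #          123456789012345
  ref <- c(chr1 = "TTACGATTCCGATTT")
  snvs <- data.frame(
    chrom = "chr1",
    pos = c(4, 10, 11, 4, 7),
    ref = c("C", "C", "G", "C", "T"),
    alt = c("G", "G", "C", "T", "A"),   # CpG C>G; CpG C>G; GpC G>C (= CpG C>G
    clone_id = "s1",                    # on the minus strand); C>T; T>A
    stringsAsFactors = FALSE)
  got <- cpgTransversionTally(snvs, ref)
  expect_identical(got[["s1"]], 3L)
  # C>G with a non-G 3' neighbour is not counted
  snvs2 <- data.frame(chrom = "chr1", pos = 9, ref = "C", alt = "G",
                      clone_id = "s1", stringsAsFactors = FALSE)
  expect_identical(cpgTransversionTally(snvs2, ref)[["s1"]], 0L)
})
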