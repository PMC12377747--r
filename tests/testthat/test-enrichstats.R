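# Interval overlap, genomic-region annotation with precedence, Welch's t
# test, and the per-clone group summary.

test_that("overlapIntervals uses the site conventions at boundaries", {
  # interval covering 0-based [100, 200) == 1-based 101..200
  iv <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
  mk <- function(pos, ref, alt) data.frame(chrom = "chr1", pos = pos,
                                           ref = ref, alt = alt,
                                           stringsAsFactors = FALSE)
  # deletion span intersecting the interval is a member
  d <- overlapIntervals(mk(100, strrep("A", 11), "A"), list(x = iv))
  expect_true(d$membership[1, "x"])
  # insertion point at 0-based 99 (after 1-based base 99): non-member
  expect_false(overlapIntervals(mk(99, "A", "AT"),
                                list(x = iv))$membership[1, "x"])
  # insertion point at 0-based 100 (just inside the left edge): member
  expect_true(overlapIntervals(mk(100, "A", "AT"),
                               list(x = iv))$membership[1, "x"])
  # deletion wholly before the interval: non-member
  expect_false(overlapIntervals(mk(90, strrep("A", 10), "A"),
                                list(x = iv))$membership[1, "x"])
})

test_that("overlap counts match brute force and ignore representation", {
  L <- 20000L
  s <- randSeq(L, seed = 61)
  vars <- randomIndels(s, 300, seed = 62)
  set.seed(63)
  st <- sort(sample(seq_len(L - 500L), 40))
  iv <- GenomicRanges::reduce(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(st, st + sample(20:400, 40, replace = TRUE))))
  got <- overlapIntervals(vars, list(x = iv))$membership[, "x"]
  inside <- rep(FALSE, L + 500L)
  for (i in seq_along(iv))
    inside[GenomicRanges::start(iv)[i]:GenomicRanges::end(iv)[i]] <- TRUE
  want <- vapply(seq_len(nrow(vars)), function(i) {
    a <- vars$pos[i]
    if (vars$vclass[i] == "INS") any(inside[c(a, a + 1L)])
    else any(inside[(a + 1L):(a + nchar(vars$ref[i]) - 1L)])
  }, logical(1))
  expect_identical(unname(got), want)

  # splitting intervals at arbitrary points leaves membership unchanged
  splitat <- GenomicRanges::start(iv) + floor(GenomicRanges::width(iv) / 2)
  pieces <- c(GenomicRanges::GRanges("chr1", IRanges::IRanges(
                GenomicRanges::start(iv), pmax(GenomicRanges::start(iv),
                                               splitat - 1L))),
              GenomicRanges::GRanges("chr1", IRanges::IRanges(
                pmin(splitat, GenomicRanges::end(iv)),
                GenomicRanges::end(iv))))
  got2 <- overlapIntervals(vars, list(x = pieces))$membership[, "x"]
  expect_identical(unname(got2), want)
})

test_that("genomic-region annotation applies the fixed precedence", {
  # gene A on chr1: 1001-3000; exon1 1001-1400 (5'UTR 1001-1200,
  # CDS 1201-1400), intron 1401-2600, exon2 2601-3000 (CDS 2601-2800,
  # 3'UTR 2801-3000). Gene B (transcript conflict): 1101-1500 all intron.
  gm <- c(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 3000),
                           strand = "+", type = "gene"),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1400),
                           strand = "+", type = "exon"),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(2601, 3000),
                           strand = "+", type = "exon"),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1200),
                           strand = "+", type = "five_prime_UTR"),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(1201, 1400),
                           strand = "+", type = "CDS"),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(2601, 2800),
                           strand = "+", type = "CDS"),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(2801, 3000),
                           strand = "+", type = "three_prime_UTR"))
  probes <- data.frame(
    chrom = "chr1",
    pos = c(1100, 1300, 2000, 2700, 2900, 500, 5000),
    ref = "A", alt = "AT", stringsAsFactors = FALSE)
  got <- annotateGenomicRegion(probes, gm)
  expect_identical(as.character(got$category),
                   c("five_utr", "exon_coding", "intron", "exon_coding",
                     "three_utr", "promoter", "intergenic"))
  # a 5'UTR position that is intron in a second transcript stays 5'UTR
  gm2 <- c(gm, GenomicRanges::GRanges("chr1", IRanges::IRanges(900, 1500),
                                      strand = "+", type = "gene"))
  got2 <- annotateGenomicRegion(
    data.frame(chrom = "chr1", pos = 1100, ref = "A", alt = "AT",
               stringsAsFactors = FALSE), gm2)
  expect_identical(as.character(got2$category), "five_utr")
  # off-model contig: intergenic with a flag
  off <- suppressWarnings(annotateGenomicRegion(
    data.frame(chrom = "chrZ", pos = 100, ref = "A", alt = "AT",
               stringsAsFactors = FALSE), gm))
  expect_identical(as.character(off$category), "intergenic")
  expect_true(off$off_model)
  # categories partition: exactly one per variant
  expect_false(anyNA(got$category))
})

test_that("welchT matches the closed form and the reference implementation", {
  r0 <- welchT(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)

  x <- c(10, 12, 14); y <- c(10, 12, 14, 16)
  r <- welchT(x, y)
  tt <- t.test(x, y)
  expect_equal(r$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(r$df, unname(tt$parameter), tolerance = 1e-12)
  expect_equal(r$p, tt$p.value, tolerance = 1e-12)

  # scale invariance
  r2 <- welchT(3.7 * x, 3.7 * y)
  expect_equal(r2$t, r$t, tolerance = 1e-12)
  expect_equal(r2$p, r$p, tolerance = 1e-12)

  expect_error(welchT(c(1, 1), c(2, 2)), "degenerate")
  expect_error(welchT(1, c(1, 2)), "at least 2")

  # high-precision agreement on 1,000 random small samples
  set.seed(71)
  for (i in 1:1000) {
    x <- rnorm(sample(2:8, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(2:8, 1), mean = runif(1, -1, 1))
    if (var(x) == 0 && var(y) == 0) next
    r <- welchT(x, y); tt <- t.test(x, y)
    expect_lt(abs(r$t - tt$statistic), 1e-10)
    expect_lt(abs(r$p - tt$p.value), 1e-10)
  }
})

test_that("groupSummary reports folds and suppresses degenerate p-values", {
  met <- data.frame(clone_id = paste0("c", 1:8),
                    genotype = rep(c("wt", "ko"), each = 4),
                    m1 = c(1, 1, 1, 1, 4, 4, 4, 4),
                    m2 = c(1, 2, 3, 4, 2, 4, 6, 8),
                    stringsAsFactors = FALSE)
  out <- groupSummary(met)
  r1 <- out[out$metric == "m1", ]
  expect_equal(r1$fold_change, 4)
  expect_equal(r1$sd_wt, 0)
  expect_true(is.na(r1$p_value))
  expect_identical(r1$p_reason, "zero_variance")
  r2 <- out[out$metric == "m2", ]
  expect_equal(r2$fold_change, 2)
  expect_false(is.na(r2$p_value))
  # single-clone group: statistics without p-value
  met2 <- met[c(1, 5:8), ]
  out2 <- groupSummary(met2)
  expect_identical(out2$p_reason[1], "group_too_small")
  expect_true(is.na(out2$p_value[1]))
})
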