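# Synthetic-data generator: determinism, controlled CpG density, planted
# property closure, and read-support statistics.

test_that("reference generation is deterministic and respects the spec", {
  spec <- genomeSpec(n_chromosomes = 2, chrom_length = 60000, dmr_count = 3,
                     repeat_tract_count = 20, seed = 42)
  r1 <- generateReference(spec)
  r2 <- generateReference(spec)
  expect_identical(as.character(r1$genome), as.character(r2$genome))
  expect_identical(as.data.frame(r1$dmr), as.data.frame(r2$dmr))

  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(r1$genome, f1, width = 60)
  Biostrings::writeXStringSet(r2$genome, f2, width = 60)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("degenerate and invalid genome specs are handled", {
  r <- generateReference(genomeSpec(n_chromosomes = 1, chrom_length = 20000,
                                    dmr_count = 0, repeat_tract_count = 10,
                                    seed = 1))
  expect_identical(length(r$dmr), 0L)
  expect_error(genomeSpec(chrom_length = 5000, dmr_count = 10,
                          dmr_length = 1000),
               "exceeds chrom_length")
})

test_that("DMRs carry the planted CpG density", {
  spec <- genomeSpec(n_chromosomes = 1, chrom_length = 100000, dmr_count = 4,
                     dmr_length = 1000, dmr_cpg_density = 50,
                     repeat_tract_count = 10, seed = 7)
  r <- generateReference(spec)
  s <- as.character(r$genome[[1]])
  ncg <- function(x) length(oracleCgStarts(x))
  dens_dmr <- vapply(seq_along(r$dmr), function(i) {
    w <- substr(s, GenomicRanges::start(r$dmr)[i], GenomicRanges::end(r$dmr)[i])
    ncg(w)
  }, numeric(1))
  # 500 planted per 1 kb DMR, plus a handful of background CGs
  expect_true(all(dens_dmr >= 500 & dens_dmr <= 560))
  bg_dens <- ncg(substr(s, 50000, 99000)) / 49000
  expect_gt(min(dens_dmr) / 1000, bg_dens * 5)
})

test_that("planted mutations carry their designed properties", {
  spec <- genomeSpec(n_chromosomes = 1, chrom_length = 150000, dmr_count = 6,
                     repeat_tract_count = 60, seed = 3)
  ref <- generateReference(spec)
  cs <- smallCloneSet()

  # indel rate zero -> only SNVs and shared events
  d0 <- cloneDesign(clones = cs, shared_per_animal = 3, unique_snv_rate = 5,
                    unique_indel_rate = 0)
  t0 <- plantMutations(ref, d0, seed = 1)
  expect_true(all(t0$vclass == "SNV"))
  expect_true(all(t0$origin %in% c("unique", "shared")))

  # forced duplications pass the duplication test; point-mass microhomology
  d1 <- cloneDesign(clones = cs, shared_per_animal = 0, unique_snv_rate = 0,
                    unique_indel_rate = 12, repeat_indel_fraction = 0,
                    nonrepeat_ins_fraction = 0.5,
                    p_duplication_insertion = 1, p_cpg_targeted = 0,
                    mh_probs = rbind(wt = c(0, 0, 0, 1, 0),
                                     ko = c(0, 0, 0, 1, 0)))
  t1 <- plantMutations(ref, d1, seed = 2)
  s <- as.character(ref$genome[[1]])
  ins <- t1[t1$vclass == "INS", ]
  expect_gt(nrow(ins), 5)
  for (i in seq_len(nrow(ins))) {
    d <- isDuplication(ins$chrom[i], ins$pos[i], ins$ref[i], ins$alt[i],
                       ref$genome)
    expect_true(d$is_dup)
  }
  del <- t1[t1$vclass == "DEL", ]
  expect_gt(nrow(del), 5)
  mh <- vapply(seq_len(nrow(del)), function(i)
    microhomology(del$chrom[i], del$pos[i], del$ref[i], del$alt[i],
                  ref$genome)$mh_len, numeric(1))
  expect_true(all(mh == 3))
})

test_that("read support follows the binomial model", {
  cs <- smallCloneSet()
  n <- 1200
  truth <- data.frame(chrom = "chr1", pos = seq_len(n) * 200, ref = "A",
                      alt = "T", vclass = "SNV", origin = "unique",
                      clone_id = "a1", animal_id = "A", genotype = "wt",
                      carriers = "a1", stringsAsFactors = FALSE)
  sup <- simulateReadSupport(truth, cs, depth_mean = 40, contamination = 0,
                             seed = 5)
  # no contamination: non-carriers have zero alt reads
  expect_true(all(sup$AD_alt[, c("a2", "a3", "b1", "b2")] == 0))
  # carrier VAF centers on 0.5 across >= 1000 sites
  v <- sup$AD_alt[, "a1"] / sup$DP[, "a1"]
  expect_lt(abs(mean(v) - 0.5), 0.02)
  expect_true(all(sup$DP > 0))

  sup2 <- simulateReadSupport(truth, cs, depth_mean = 40, p_uncovered = 0.1,
                              seed = 6)
  expect_gt(sum(sup2$DP == 0), 0)
  expect_true(all(sup2$AD_alt[sup2$DP == 0] == 0))
  expect_error(simulateReadSupport(truth, cs, contamination = 0.2),
               "contamination")
})

test_that("candidate VCF round-trips through the reader", {
  cs <- smallCloneSet()
  truth <- data.frame(chrom = "chr1", pos = c(500, 900, 1500),
                      ref = c("A", "TGC", "C"), alt = c("G", "T", "CATT"),
                      vclass = c("SNV", "DEL", "INS"),
                      origin = "unique", clone_id = "a1", animal_id = "A",
                      genotype = "wt", carriers = "a1",
                      stringsAsFactors = FALSE)
  sup <- simulateReadSupport(truth, cs, depth_mean = 30, seed = 2)
  path <- tempfile(fileext = ".vcf")
  writeCandidateVcf(sup, path, c(chr1 = 5000))
  back <- readVcfCandidates(path)
  expect_equal(back$variants$pos, sup$variants$pos)
  expect_identical(back$variants$ref, sup$variants$ref)
  expect_identical(back$variants$alt, sup$variants$alt)
  expect_identical(unname(back$DP), unname(sup$DP))
  expect_identical(unname(back$AD_alt), unname(sup$AD_alt))
  # same support, same file bytes
  path2 <- tempfile(fileext = ".vcf")
  writeCandidateVcf(sup, path2, c(chr1 = 5000))
  expect_identical(readLines(path), readLines(path2))
})

test_that("overlapping depth-track artifacts are rejected", {
  g <- Biostrings::DNAStringSet(c(chr1 = randSeq(2000, 1)))
  bad <- data.frame(chrom = "chr1", start = c(100, 150), end = c(200, 250),
                    type = c("dropout", "spike"))
  expect_error(simulateDepthTracks(g, "c1", artifacts = bad), "overlapping")
})
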