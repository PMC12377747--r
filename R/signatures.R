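# Mutation-signature matrices over the COSMIC v3 category systems: SBS96
# (pyrimidine-centered trinucleotide substitution contexts) and ID83 (indel
# length / repeat / microhomology classes), plus refitting of sample count
# vectors against a reference catalog by non-negative least squares.

#' @importFrom pracma lsqnonneg
NULL

.PYR_SUBS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The fixed SBS96 category alphabet
#'
#' 96 categories in the conventional order: the six pyrimidine-centered
#' substitution classes C>A, C>G, C>T, T>A, T>C, T>G, each crossed with the
#' sixteen 5'/3' flank combinations (5' flank outer, 3' flank inner, both
#' A,C,G,T), written `"A[C>A]A"` etc.
#'
#' @return Character vector of length 96.
#' @export
sbs96Categories <- function() {
  out <- character(0)
  for (sub in .PYR_SUBS)
    for (f5 in c("A", "C", "G", "T"))
      for (f3 in c("A", "C", "G", "T"))
        out <- c(out, paste0(f5, "[", sub, "]", f3))
  out
}

#' The fixed ID83 category alphabet
#'
#' 83 indel categories following the COSMIC v3 scheme: 1 bp deletions and
#' insertions by base (C/T, purines collapsed) x six homopolymer-length
#' bins; >= 2 bp deletions and insertions in repeat context by length bin
#' (2,3,4,5+) x six repeat-unit bins; deletions with junction microhomology
#' by length bin x microhomology-length bin. Labels are
#' `"<len>:<Del|Ins>:<C|T|R|M>:<bin>"`; for deletions the final number
#' encodes homopolymer/repeat length 1..6+ as 0..5, for insertions the
#' number of pre-existing copies 0..5+, and for `M` categories the
#' microhomology length.
#'
#' @return Character vector of length 83.
#' @export
id83Categories <- function() {
  out <- character(0)
  for (ty in c("Del", "Ins"))
    for (b in c("C", "T"))
      out <- c(out, paste0("1:", ty, ":", b, ":", 0:5))
  # reorder: all Del first then Ins (1:Del:C, 1:Del:T, 1:Ins:C, 1:Ins:T)
  out <- c(out[1:6], out[7:12], out[13:18], out[19:24])
  for (L in 2:5) out <- c(out, paste0(L, ":Del:R:", 0:5))
  for (L in 2:5) out <- c(out, paste0(L, ":Ins:R:", 0:5))
  out <- c(out, "2:Del:M:1",
           paste0("3:Del:M:", 1:2),
           paste0("4:Del:M:", 1:3),
           paste0("5:Del:M:", 1:5))
  out
}

# SBS96 category of one SNV; NA when the trinucleotide context is
# unavailable (contig edge) or contains a non-ACGT base.
.sbs96Class <- function(s, pos, refb, altb) {
  if (pos < 2L || pos > .nc(s) - 1L) return(NA_character_)
  ctx <- substr(s, pos - 1L, pos + 1L)
  if (grepl("[^ACGT]", ctx) || !altb %in% c("A", "C", "G", "T"))
    return(NA_character_)
  if (refb %in% c("A", "G")) {       # collapse to the pyrimidine strand
    ctx <- .rc1(ctx)
    refb <- chartr("AG", "TC", refb)
    altb <- chartr("ACGT", "TGCA", altb)
  }
  paste0(substr(ctx, 1L, 1L), "[", refb, ">", altb, "]",
         substr(ctx, 3L, 3L))
}

#' Build the SBS96 matrix from SNVs
#'
#' Maps each SNV to its pyrimidine-centered trinucleotide category (purine
#' reference SNVs are reverse-complemented) and tabulates counts per sample.
#' SNVs with an unavailable or ambiguous context are excluded; the number of
#' exclusions per sample is attached as attribute `"excluded"`.
#'
#' @param snvs data.frame with `chrom`, `pos`, `ref`, `alt` and the sample
#'   column.
#' @param reference Reference sequences.
#' @param sample_col Column naming the sample (default `"clone_id"`).
#' @param samples Optional sample order (default: order of appearance).
#' @return A [SignatureMatrix-class] of kind `"SBS96"`.
#' @export
sbs96Matrix <- function(snvs, reference, sample_col = "clone_id",
                        samples = NULL) {
  .checkVariantTable(snvs, c("chrom", "pos", "ref", "alt", sample_col))
  seqs <- .refChar(reference)
  if (is.null(samples)) samples <- unique(snvs[[sample_col]])
  cats <- vapply(seq_len(nrow(snvs)), function(i)
    .sbs96Class(seqs[[snvs$chrom[i]]], as.integer(snvs$pos[i]),
                snvs$ref[i], snvs$alt[i]), character(1))
  keep <- !is.na(cats)
  tab <- table(factor(cats[keep], levels = sbs96Categories()),
               factor(snvs[[sample_col]][keep], levels = samples))
  m <- matrix(as.integer(tab), nrow = 96L,
              dimnames = list(sbs96Categories(), samples))
  out <- signatureMatrix(m, "SBS96")
  attr(out, "excluded") <- table(factor(snvs[[sample_col]][!keep],
                                        levels = samples))
  out
}

# ID83 category of one normalized indel; NA when unclassifiable.
.id83Class <- function(s, a, ref, alt) {
  S <- .indelSeq(ref, alt)
  L <- nchar(S)
  if (L == 0L || grepl("[^ACGT]", S)) return(NA_character_)
  is_del <- nchar(ref) > nchar(alt)
  ty <- if (is_del) "Del" else "Ins"
  if (L == 1L) {
    b <- S
    run <- .countLeft(s, a, b) + .countRight(s, a + 1L, b)
    blab <- if (b %in% c("C", "G")) "C" else "T"
    # deletions: run includes the deleted base, bins 1..6+ encoded 0..5;
    # insertions: run counts pre-existing copies, bins 0..5+
    bin <- if (is_del) min(run, 6L) - 1L else min(run, 5L)
    return(paste0("1:", ty, ":", blab, ":", bin))
  }
  Lb <- min(L, 5L)
  cop <- .countLeft(s, a, S) + .countRight(s, a + 1L, S)
  if (is_del) {
    if (cop >= 2L) return(paste0(Lb, ":Del:R:", min(cop, 6L) - 1L))
    mh3 <- .lcp(substr(s, a + 1L, a + L),
                substr(s, a + L + 1L, min(.nc(s), a + 2L * L)))
    revstr <- function(x)
      paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
    mh5 <- .lcp(revstr(substr(s, a + 1L, a + L)),
                revstr(substr(s, max(1L, a + 1L - L), a)))
    mh <- min(max(mh3, mh5), L - 1L)
    if (mh >= 1L) {
      bin <- if (Lb == 5L) min(mh, 5L) else min(mh, Lb - 1L)
      return(paste0(Lb, ":Del:M:", bin))
    }
    return(paste0(Lb, ":Del:R:0"))
  }
  paste0(Lb, ":Ins:R:", min(cop, 5L))
}

#' Build the ID83 matrix from indels
#'
#' Assigns each normalized indel to one of the 83 COSMIC-style categories
#' (1 bp events by base and homopolymer length, longer events by length and
#' repeat-unit count, non-repeat deletions by junction microhomology) and
#' tabulates counts per sample. For 1 bp insertions the run count is the
#' number of pre-existing copies of the base; for deletions it includes the
#' deleted copy. Unclassifiable indels (non-ACGT content) are excluded and
#' counted in attribute `"excluded"`.
#'
#' @param indels data.frame with `chrom`, `pos`, `ref`, `alt` and the
#'   sample column; rows must be normalized indels.
#' @param reference Reference sequences.
#' @param sample_col Column naming the sample (default `"clone_id"`).
#' @param samples Optional sample order.
#' @return A [SignatureMatrix-class] of kind `"ID83"`.
#' @export
id83Matrix <- function(indels, reference, sample_col = "clone_id",
                       samples = NULL) {
  .checkVariantTable(indels, c("chrom", "pos", "ref", "alt", sample_col))
  seqs <- .refChar(reference)
  if (is.null(samples)) samples <- unique(indels[[sample_col]])
  cats <- vapply(seq_len(nrow(indels)), function(i)
    .id83Class(seqs[[indels$chrom[i]]], as.integer(indels$pos[i]),
               indels$ref[i], indels$alt[i]), character(1))
  keep <- !is.na(cats)
  tab <- table(factor(cats[keep], levels = id83Categories()),
               factor(indels[[sample_col]][keep], levels = samples))
  m <- matrix(as.integer(tab), nrow = 83L,
              dimnames = list(id83Categories(), samples))
  out <- signatureMatrix(m, "ID83")
  attr(out, "excluded") <- table(factor(indels[[sample_col]][!keep],
                                        levels = samples))
  out
}

#' Refit sample spectra against a reference signature catalog
#'
#' Per sample, solves `min || R w - c ||_2` subject to `w >= 0` where `R` is
#' the reference catalog and `c` the sample's count vector, then normalizes
#' `w` to proportions. Signatures contributing less than `prune_threshold`
#' are zeroed and the system re-solved once on the remaining signatures.
#'
#' @param mat A [SignatureMatrix-class] (or plain categories x samples
#'   matrix whose rownames match the catalog).
#' @param refs Reference catalog: categories x signatures matrix with the
#'   identical category alphabet and order.
#' @param prune_threshold Minimum retained contribution (default 0.05).
#' @return List with `contributions` (signatures x samples, columns sum to 1
#'   for non-empty samples) and `residual_norm` (per sample,
#'   `||Rw - c|| / ||c||`).
#' @export
refitSignatures <- function(mat, refs, prune_threshold = 0.05) {
  m <- if (methods::is(mat, "SignatureMatrix")) sigCounts(mat) else mat
  if (!identical(rownames(m), rownames(refs))) {
    miss <- setdiff(rownames(m), rownames(refs))
    extra <- setdiff(rownames(refs), rownames(m))
    stop("category alphabet mismatch between matrix and catalog",
         if (length(miss)) paste0("; missing from catalog: ",
                                  paste(utils::head(miss, 5), collapse = ", ")),
         if (length(extra)) paste0("; extra in catalog: ",
                                   paste(utils::head(extra, 5), collapse = ", ")))
  }
  R <- as.matrix(refs)
  contrib <- matrix(0, ncol(R), ncol(m),
                    dimnames = list(colnames(R), colnames(m)))
  resid <- setNames(numeric(ncol(m)), colnames(m))
  for (j in seq_len(ncol(m))) {
    cvec <- as.numeric(m[, j])
    if (sum(cvec) == 0) { resid[j] <- 0; next }
    w <- pracma::lsqnonneg(R, cvec)$x
    p <- if (sum(w) > 0) w / sum(w) else w
    keep <- p >= prune_threshold
    if (any(keep) && !all(keep)) {
      w2 <- numeric(length(w))
      w2[keep] <- pracma::lsqnonneg(R[, keep, drop = FALSE], cvec)$x
      w <- w2
    }
    contrib[, j] <- if (sum(w) > 0) w / sum(w) else w
    resid[j] <- sqrt(sum((R %*% w - cvec)^2)) / sqrt(sum(cvec^2))
  }
  list(contributions = contrib, residual_norm = resid)
}

#' Tally CpG>GpG transversions per sample
#'
#' Counts SNVs whose pyrimidine-strand change is C>G with a 3' neighbor G —
#' i.e. a C>G transversion at a CpG site (or the equivalent G>C with a 5'
#' C on the other strand).
#'
#' @param snvs data.frame with `chrom`, `pos`, `ref`, `alt` and the sample
#'   column.
#' @param reference Reference sequences.
#' @param sample_col Column naming the sample (default `"clone_id"`).
#' @param samples Optional sample order.
#' @return Named integer vector of counts per sample.
#' @export
cpgTransversionTally <- function(snvs, reference, sample_col = "clone_id",
                                 samples = NULL) {
  .checkVariantTable(snvs, c("chrom", "pos", "ref", "alt", sample_col))
  seqs <- .refChar(reference)
  if (is.null(samples)) samples <- unique(snvs[[sample_col]])
  hit <- vapply(seq_len(nrow(snvs)), function(i) {
    s <- seqs[[snvs$chrom[i]]]; p <- as.integer(snvs$pos[i])
    (snvs$ref[i] == "C" && snvs$alt[i] == "G" &&
       substr(s, p + 1L, p + 1L) == "G") ||
    (snvs$ref[i] == "G" && snvs$alt[i] == "C" &&
       substr(s, p - 1L, p - 1L) == "C")
  }, logical(1))
  tab <- table(factor(snvs[[sample_col]][hit], levels = samples))
  setNames(as.integer(tab), samples)
}

#' Read a reference signature catalog from TSV
#'
#' Tab-separated file with the category label in the first column and one
#' column per signature; categories must cover the full alphabet.
#'
#' @param path TSV path.
#' @return Numeric matrix, categories x signatures.
#' @export
readSignatureCatalog <- function(path) {
  dt <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- dt[[1]]
  storage.mode(m) <- "double"
  m
}

#' Construct a synthetic reference signature catalog
#'
#' Builds a synthetic catalog of probability vectors over the SBS96 or ID83
#' alphabet with largely disjoint, peaked supports — a stand-in for a real
#' signature catalog, suitable for refitting demonstrations and mixture
#' recovery experiments. Columns sum to 1. Deterministic given `seed`.
#'
#' @param kind `"SBS96"` or `"ID83"`.
#' @param n Number of signatures (default 3).
#' @param seed Integer seed.
#' @return Numeric matrix, categories x signatures, columns named
#'   `synthSig1..n`.
#' @export
syntheticSignatureCatalog <- function(kind = c("SBS96", "ID83"), n = 3L,
                                      seed = 1L) {
  kind <- match.arg(kind)
  alph <- if (kind == "SBS96") sbs96Categories() else id83Categories()
  set.seed(seed)
  K <- length(alph)
  blocks <- split(seq_len(K), rep(seq_len(n), length.out = K))
  m <- matrix(0, K, n, dimnames = list(alph, paste0("synthSig", seq_len(n))))
  for (j in seq_len(n)) {
    w <- rep(0.02 / K, K)                       # faint flat background
    w[blocks[[j]]] <- stats::rexp(length(blocks[[j]]))  # peaked main support
    m[, j] <- w / sum(w)
  }
  m
}
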