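# CpG-context and junction annotation of normalized indels: CpG proximity
# (+/-2, +/-10 bp), the +/-100 bp CpG positional profile, CpG gain/loss
# under the allele edit, templated-duplication status of insertions, and
# deletion-junction microhomology.
#
# Site conventions (CG = its own reverse complement, so everything here is
# strand-invariant):
#  * insertion site = the inter-base gap after the normalized anchor `pos`;
#    a CG starting at reference position q is within w bp iff
#    q in [pos+1-w, pos+w]; its signed offset is q-pos-1 (q <= pos) or
#    q-pos (q > pos), so offsets run -w..-1, 1..w.
#  * deletion site = the closed deleted span [s, e]; a CG is within w bp iff
#    its 2-bp footprint intersects [s-w, e+w]; CGs whose footprint touches
#    the span itself (including CpGs inside the deleted bases) get offset 0,
#    others the signed distance to the nearest span edge.

# Signed CpG offsets around an indel site, restricted to |offset| <= w.
.cpgOffsets <- function(seqs, chrom, pos, ref, alt, w,
                        del_mode = c("span", "breakpoints")) {
  del_mode <- match.arg(del_mode)
  s <- seqs[[chrom]]
  vclass <- .vclass(ref, alt)
  a <- as.integer(pos)
  if (vclass == "INS") {
    lo <- a + 1L - w; hi <- a + w
    win0 <- max(1L, lo)
    q <- .cgStarts(substr(s, win0, min(.nc(s), hi + 1L))) + win0 - 1L
    q <- q[q >= lo & q <= hi]
    return(ifelse(q <= a, q - a - 1L, q - a))
  }
  L <- nchar(ref) - nchar(alt)
  s0 <- a + 1L; e0 <- a + L
  win0 <- max(1L, s0 - w - 1L)
  q <- .cgStarts(substr(s, win0, min(.nc(s), e0 + w + 1L))) + win0 - 1L
  q <- q[q >= s0 - w - 1L & q <= e0 + w]
  off <- ifelse(q >= s0 - 1L & q <= e0, 0L,
                ifelse(q < s0, q - s0 + 1L, q - e0))
  if (del_mode == "breakpoints")
    off <- off[off == 0L |
               (q + 1L >= s0 - w & q <= s0 + w) |
               (q + 1L >= e0 - w & q <= e0 + w)]
  off
}

#' CpG proximity of an indel site
#'
#' Tests whether a CpG dinucleotide lies within `w` bp of the indel site
#' (insertion point or deleted span; see the conventions in the package
#' vignette). CpGs wholly inside a deleted span count: they are at the site.
#'
#' @param chrom,pos,ref,alt Normalized indel.
#' @param reference Reference sequences.
#' @param w Window half-width in bp (2 and 10 are the analysis windows).
#' @param del_mode `"span"` (default) measures deletion windows from the
#'   deleted span; `"breakpoints"` from each breakpoint separately.
#' @return List with `within` (logical) and `count` (number of CpG starts in
#'   the window). Windows clipped at contig edges are evaluated on the
#'   available bases.
#' @examples
#' ref <- c(chr1 = "TTAACGTTTT")
#' cpgWithin("chr1", 6, "G", "GAT", ref, w = 2)  # CG at offset -2
#' @export
cpgWithin <- function(chrom, pos, ref, alt, reference, w,
                      del_mode = c("span", "breakpoints")) {
  seqs <- .refChar(reference)
  off <- .cpgOffsets(seqs, chrom, pos, ref, alt, as.integer(w), del_mode)
  list(within = length(off) > 0L, count = length(off))
}

#' CpG positional profile around indel sites
#'
#' Mean CpG occurrence per signed offset within +/- `w` bp across a set of
#' indels; the vector that shows whether CpGs pile up at the sites.
#'
#' @param variants data.frame of normalized indels (`chrom`, `pos`, `ref`,
#'   `alt`).
#' @param reference Reference sequences.
#' @param w Window half-width (default 100).
#' @return data.frame with `offset` (-w..w) and `frequency` (mean CpG starts
#'   per variant at that offset).
#' @export
cpgProfile <- function(variants, reference, w = 100L) {
  .checkVariantTable(variants)
  stopifnot(nrow(variants) >= 1L)
  seqs <- .refChar(reference)
  w <- as.integer(w)
  acc <- integer(2L * w + 1L)
  for (i in seq_len(nrow(variants))) {
    off <- .cpgOffsets(seqs, variants$chrom[i], variants$pos[i],
                       variants$ref[i], variants$alt[i], w)
    if (length(off)) {
      tab <- table(off + w + 1L)
      acc[as.integer(names(tab))] <- acc[as.integer(names(tab))] +
        as.integer(tab)
    }
  }
  data.frame(offset = seq.int(-w, w), frequency = acc / nrow(variants))
}

#' CpG sites gained and lost by an indel
#'
#' Counts CG dinucleotides in the +/- `w` bp reference window around the
#' indel before and after applying the allele edit to the window string.
#' Site identities are tracked by aligning CG start coordinates outside the
#' edit, so a CpG destroyed on one side and a different CpG created at the
#' junction count as one loss and one gain; `gain - loss` always equals the
#' net change in window CpG count.
#'
#' @param chrom,pos,ref,alt Normalized indel.
#' @param reference Reference sequences.
#' @param w Window half-width (default 10).
#' @return List with `gain` and `loss` (non-negative counts).
#' @examples
#' ref <- c(chr1 = "TTTCAGTTTT")
#' cpgGainLoss("chr1", 4, "CA", "C", ref)  # junction creates CG: gain 1
#' @export
cpgGainLoss <- function(chrom, pos, ref, alt, reference, w = 10L) {
  seqs <- .refChar(reference)
  s <- seqs[[chrom]]
  w <- as.integer(w)
  a <- as.integer(pos)
  vclass <- .vclass(ref, alt)
  if (vclass == "SNV") stop("not an indel: ", ref, ">", alt)

  if (vclass == "INS") {
    S <- .indelSeq(ref, alt)
    L0 <- max(1L, a + 1L - w); R0 <- min(.nc(s), a + w)
    before <- substr(s, L0, R0)
    g <- a - L0 + 1L                     # window coord of the anchor base
    after <- paste0(substr(before, 1L, g), S,
                    substr(before, g + 1L, nchar(before)))
    B <- .cgStarts(before); A <- .cgStarts(after)
    mapped <- B[B <= g - 1L]
    mapped <- c(mapped, B[B >= g + 1L] + nchar(S))
  } else {
    Ld <- nchar(ref) - nchar(alt)
    s0 <- a + 1L; e0 <- a + Ld
    L0 <- max(1L, s0 - w); R0 <- min(.nc(s), e0 + w)
    before <- substr(s, L0, R0)
    ws <- s0 - L0 + 1L; we <- e0 - L0 + 1L
    after <- paste0(substr(before, 1L, ws - 1L),
                    substr(before, we + 1L, nchar(before)))
    B <- .cgStarts(before); A <- .cgStarts(after)
    mapped <- B[B <= ws - 2L]            # CG fully left of the span
    mapped <- c(mapped, B[B >= we + 1L] - Ld)
  }
  survived <- sum(mapped %in% A)
  list(gain = length(A) - survived, loss = length(B) - survived)
}

#' Is an insertion a templated downstream duplication?
#'
#' TRUE when the inserted sequence equals (case-insensitively) the reference
#' substring of the same length starting immediately 3' of the insertion
#' point — the signature of a templated insertion.
#'
#' @param chrom,pos,ref,alt Normalized insertion.
#' @param reference Reference sequences.
#' @return List with `is_dup`, `duplicated_span` (insertion length when
#'   TRUE, else 0) and `edge` (TRUE when too few downstream bases remain to
#'   decide; `is_dup` is then FALSE).
#' @examples
#' ref <- c(chr1 = "TTACCGGTTT")
#' isDuplication("chr1", 3, "A", "ACCGG", ref)  # downstream CCGG: TRUE
#' @export
isDuplication <- function(chrom, pos, ref, alt, reference) {
  seqs <- .refChar(reference)
  s <- seqs[[chrom]]
  if (nchar(alt) <= nchar(ref)) stop("not an insertion: ", ref, ">", alt)
  S <- .indelSeq(ref, alt)
  L <- nchar(S)
  a <- as.integer(pos)
  down <- substr(s, a + 1L, a + L)
  if (nchar(down) < L)
    return(list(is_dup = FALSE, duplicated_span = 0L, edge = TRUE))
  hit <- toupper(S) == toupper(down)
  list(is_dup = hit, duplicated_span = if (hit) L else 0L, edge = FALSE)
}

#' Junction microhomology of a deletion
#'
#' The longer of (a) the longest prefix of the deleted sequence matching the
#' reference immediately 3' of the deleted span and (b) the longest suffix
#' of the deleted sequence matching the reference immediately 5' of the
#' span, capped at the deletion length. Deletions whose full length matches
#' flanking sequence are representation-degenerate with repeat contractions
#' and carry a `full_homology` flag.
#'
#' @param chrom,pos,ref,alt Normalized deletion.
#' @param reference Reference sequences.
#' @return List with `mh_len` and `full_homology`.
#' @examples
#' ref <- c(chr1 = "AATTGCTAGCCCAA")
#' microhomology("chr1", 4, "TGCTA", "T", ref)  # deleted GCTA vs GCCC: 2
#' @export
microhomology <- function(chrom, pos, ref, alt, reference) {
  seqs <- .refChar(reference)
  s <- seqs[[chrom]]
  if (nchar(ref) <= nchar(alt)) stop("not a deletion: ", ref, ">", alt)
  a <- as.integer(pos)
  L <- nchar(ref) - nchar(alt)
  s0 <- a + 1L; e0 <- a + L
  del <- substr(s, s0, e0)
  down <- substr(s, e0 + 1L, min(.nc(s), e0 + L))
  mh3 <- .lcp(del, down)
  up <- substr(s, max(1L, s0 - L), s0 - 1L)
  revstr <- function(x)
    paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
  mh5 <- .lcp(revstr(del), revstr(up))
  mh <- min(max(mh3, mh5), L)
  list(mh_len = mh, full_homology = mh == L)
}

#' Full CpG/junction annotation of an indel table
#'
#' Adds, per indel: `cpg_within_2`, `cpg_within_10`, `cpg_count_10`,
#' `cpg_gain`, `cpg_loss`, `is_dup` and `dup_span` (insertions; NA for
#' deletions), `mh_len` and `full_homology` (deletions; NA for insertions).
#' SNV rows pass through with NAs.
#'
#' @param variants data.frame of normalized variants (`chrom`, `pos`,
#'   `ref`, `alt`).
#' @param reference Reference sequences.
#' @param gain_w Window for [cpgGainLoss()] (default 10).
#' @return The annotated data.frame.
#' @export
annotateIndels <- function(variants, reference, gain_w = 10L) {
  .checkVariantTable(variants)
  if (is.null(variants$vclass))
    variants$vclass <- .vclass(variants$ref, variants$alt)
  seqs <- .refChar(reference)
  n <- nrow(variants)
  cpg_within_2 <- cpg_within_10 <- is_dup <- full_homology <- rep(NA, n)
  cpg_count_10 <- cpg_gain <- cpg_loss <- rep(NA_integer_, n)
  dup_span <- mh_len <- rep(NA_integer_, n)
  for (i in which(variants$vclass != "SNV")) {
    ch <- variants$chrom[i]; p <- variants$pos[i]
    r <- variants$ref[i]; al <- variants$alt[i]
    o2 <- .cpgOffsets(seqs, ch, p, r, al, 2L)
    o10 <- .cpgOffsets(seqs, ch, p, r, al, 10L)
    cpg_within_2[i] <- length(o2) > 0L
    cpg_within_10[i] <- length(o10) > 0L
    cpg_count_10[i] <- length(o10)
    gl <- cpgGainLoss(ch, p, r, al, seqs, w = gain_w)
    cpg_gain[i] <- gl$gain
    cpg_loss[i] <- gl$loss
    if (variants$vclass[i] == "INS") {
      d <- isDuplication(ch, p, r, al, seqs)
      is_dup[i] <- d$is_dup
      dup_span[i] <- d$duplicated_span
    } else {
      m <- microhomology(ch, p, r, al, seqs)
      mh_len[i] <- m$mh_len
      full_homology[i] <- m$full_homology
    }
  }
  variants$cpg_within_2 <- cpg_within_2
  variants$cpg_within_10 <- cpg_within_10
  variants$cpg_count_10 <- cpg_count_10
  variants$cpg_gain <- cpg_gain
  variants$cpg_loss <- cpg_loss
  variants$is_dup <- is_dup
  variants$dup_span <- dup_span
  variants$mh_len <- mh_len
  variants$full_homology <- full_homology
  variants
}
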