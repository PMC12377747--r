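# Indel normalization (parsimony + left alignment) and repeat-context
# classification: nonrepeat, tandem_repeat, or homopolymer. The repeat rule
# is the ">= 5 copies of the same motif" convention, with motif length
# bounded to 2-6 bp (microsatellite convention) and the single-base case
# treated as the homopolymer class.

#' Normalize an indel to its minimal, left-aligned representation
#'
#' Trims the allele pair to a minimal anchored representation (common suffix
#' then common prefix, keeping one anchor base) and shifts it left while the
#' base entering the varying window from the left equals the base leaving it
#' on the right, the standard left-alignment used before context annotation.
#'
#' @param chrom,pos,ref,alt The VCF-style variant (1-based `pos`).
#' @param reference Reference (DNAStringSet or named character).
#' @return List with normalized `chrom`, `pos`, `ref`, `alt`, `vclass`.
#' @examples
#' ref <- c(chr1 = "CAAAT")
#' normalizeIndel("chr1", 3, "AA", "A", ref)  # -> pos 1, CA > C
#' @export
normalizeIndel <- function(chrom, pos, ref, alt, reference) {
  seqs <- .refChar(reference)
  s <- seqs[[chrom]]
  pos <- as.integer(pos); ref <- toupper(ref); alt <- toupper(alt)
  obs <- substr(s, pos, pos + nchar(ref) - 1L)
  if (obs != ref)
    stop("data error: REF allele '", ref, "' does not match reference '",
         obs, "' at ", chrom, ":", pos)

  # parsimony: trim the shared suffix, re-anchoring on the preceding
  # reference base whenever an allele empties (this walks a deletion or
  # insertion leftward through a repeat tract), then trim the shared prefix
  # keeping one anchor base
  while (nchar(ref) + nchar(alt) > 2L &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
    if (nchar(ref) == 0L || nchar(alt) == 0L) {
      if (pos == 1L)
        stop("cannot re-anchor an unanchored indel at the contig start")
      pos <- pos - 1L
      b <- substr(s, pos, pos)
      ref <- paste0(b, ref)
      alt <- paste0(b, alt)
    }
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref)); alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }

  if (nchar(ref) > 1L && nchar(alt) > 1L)
    stop("complex substitution cannot be normalized to a simple indel: ",
         ref, ">", alt)

  if (nchar(ref) == 1L && nchar(alt) == 1L)
    return(list(chrom = chrom, pos = pos, ref = ref, alt = alt,
                vclass = "SNV"))

  if (nchar(alt) > nchar(ref)) {            # insertion: S after anchor
    S <- substr(alt, 2L, nchar(alt))
    L <- nchar(S)
    while (pos > 1L && substr(s, pos, pos) == substr(S, L, L)) {
      S <- paste0(substr(s, pos, pos), substr(S, 1L, L - 1L))
      pos <- pos - 1L
    }
    return(list(chrom = chrom, pos = pos, ref = substr(s, pos, pos),
                alt = paste0(substr(s, pos, pos), S), vclass = "INS"))
  }
  # deletion: span [pos+1, pos+L]; shift while ref[pos] == ref[pos+L]
  L <- nchar(ref) - 1L
  while (pos > 1L && substr(s, pos, pos) == substr(s, pos + L, pos + L))
    pos <- pos - 1L
  list(chrom = chrom, pos = pos, ref = substr(s, pos, pos + L),
       alt = substr(s, pos, pos), vclass = "DEL")
}

#' Classify the repeat context of a normalized indel
#'
#' An indel is `homopolymer` when it lies in or extends a single-base
#' reference run of at least `min_copies` bases; else `tandem_repeat` when a
#' 2-6 bp motif tandemly repeated at least `min_copies` times in the
#' reference contains or directly abuts (within 1 bp) the indel site and the
#' inserted/deleted sequence is a whole number of motif copies; else
#' `nonrepeat`. Classes are mutually exclusive with precedence
#' homopolymer > tandem_repeat > nonrepeat.
#'
#' @param chrom,pos,ref,alt The normalized variant (see [normalizeIndel()]).
#' @param reference Reference (DNAStringSet or named character).
#' @param max_motif Maximum motif length considered (default 6).
#' @param min_copies Copy-number threshold defining a repeat (default 5).
#' @return List: `repeat_class`, `motif` (empty for nonrepeat),
#'   `motif_copies`, `indel_length`, and `edge` (TRUE when the +/-60 bp
#'   context window was truncated by a contig end).
#' @examples
#' ref <- c(chr1 = "TTGCAGCAGCAGCAGCAGTT")
#' classifyRepeatContext("chr1", 2, "T", "TCAG", ref)
#' @export
classifyRepeatContext <- function(chrom, pos, ref, alt, reference,
                                  max_motif = 6L, min_copies = 5L) {
  seqs <- .refChar(reference)
  s <- seqs[[chrom]]
  S <- .indelSeq(ref, alt)
  if (nchar(S) == 0L) stop("not an indel: ", ref, ">", alt)
  res <- .repeatClassAt(s, as.integer(pos), S,
                        max_motif = max_motif, min_copies = min_copies)
  edge <- pos - 60L < 1L || pos + nchar(ref) - 1L + 60L > .nc(s)
  list(repeat_class = res$class, motif = res$motif,
       motif_copies = as.integer(res$copies),
       indel_length = nchar(S), edge = edge)
}

#' Annotate a table of indels with repeat context
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt` (normalized).
#' @param reference Reference sequences.
#' @param ... Passed to [classifyRepeatContext()].
#' @return `variants` with `repeat_class`, `motif`, `motif_copies`,
#'   `indel_length` columns added (SNV rows get NA).
#' @export
annotateRepeatContext <- function(variants, reference, ...) {
  .checkVariantTable(variants)
  if (is.null(variants$vclass))
    variants$vclass <- .vclass(variants$ref, variants$alt)
  seqs <- .refChar(reference)
  n <- nrow(variants)
  repeat_class <- rep(NA_character_, n)
  motif <- rep(NA_character_, n)
  motif_copies <- rep(NA_integer_, n)
  for (i in which(variants$vclass != "SNV")) {
    a <- classifyRepeatContext(variants$chrom[i], variants$pos[i],
                               variants$ref[i], variants$alt[i],
                               seqs, ...)
    repeat_class[i] <- a$repeat_class
    motif[i] <- a$motif
    motif_copies[i] <- a$motif_copies
  }
  variants$repeat_class <- repeat_class
  variants$motif <- motif
  variants$motif_copies <- motif_copies
  variants$indel_length <- abs(nchar(variants$alt) - nchar(variants$ref))
  variants
}

#' Summarize indel counts and sizes per clone and group
#'
#' Tabulates insertion/deletion counts per clone split by repeat class, and
#' summarizes indel sizes (mean, sample SD with the n-1 denominator) per
#' genotype group, insertions and deletions separately.
#'
#' @param annotations data.frame with columns `clone_id`, `genotype`,
#'   `vclass` (INS/DEL), `repeat_class`, `indel_length`.
#' @param repeat_class Restrict size summaries to one class (default
#'   `"nonrepeat"`, the comparison of interest); NULL for all.
#' @return List with `counts` (clone x (vclass x repeat_class) table as a
#'   data.frame), `sizes` (per genotype x vclass: n, mean, sd — sd is 0 with
#'   an `n1` flag when n = 1, NA when n = 0), and `histogram` (genotype x
#'   vclass x length counts).
#' @export
indelLengthSummary <- function(annotations, repeat_class = "nonrepeat") {
  need <- c("clone_id", "genotype", "vclass", "repeat_class", "indel_length")
  miss <- setdiff(need, colnames(annotations))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  a <- annotations[annotations$vclass %in% c("INS", "DEL"), , drop = FALSE]

  counts <- as.data.frame.matrix(table(
    a$clone_id, paste(a$vclass, a$repeat_class, sep = ".")))
  counts <- cbind(clone_id = rownames(counts), counts)
  rownames(counts) <- NULL

  b <- if (is.null(repeat_class)) a
       else a[a$repeat_class == repeat_class, , drop = FALSE]
  groups <- expand.grid(genotype = unique(a$genotype),
                        vclass = c("INS", "DEL"),
                        stringsAsFactors = FALSE)
  sizes <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    x <- b$indel_length[b$genotype == groups$genotype[i] &
                        b$vclass == groups$vclass[i]]
    data.frame(genotype = groups$genotype[i], vclass = groups$vclass[i],
               n = length(x),
               mean = if (length(x)) mean(x) else NA_real_,
               sd = if (length(x) >= 2L) stats::sd(x)
                    else if (length(x) == 1L) 0 else NA_real_,
               n1 = length(x) == 1L,
               stringsAsFactors = FALSE)
  }))
  hist <- as.data.frame(table(genotype = b$genotype, vclass = b$vclass,
                              length = b$indel_length),
                        stringsAsFactors = FALSE)
  hist$length <- as.integer(hist$length)
  list(counts = counts, sizes = sizes, histogram = hist)
}
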