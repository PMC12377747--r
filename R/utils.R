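# Internal sequence and small-I/O helpers shared across modules.

#' @importFrom Biostrings DNAStringSet reverseComplement
#' @importFrom methods is new validObject slot
NULL

# Coerce a reference (DNAStringSet or named character) to a named uppercase
# character vector, one element per chromosome. Conversion of a multi-Mb
# genome is not free, so the result is stamped and returned as-is when fed
# back in — per-variant loops pass the converted object around.
.refChar <- function(reference) {
  if (isTRUE(attr(reference, "somaticlone_ref"))) return(reference)
  if (methods::is(reference, "DNAStringSet")) {
    out <- as.character(reference)
  } else if (is.character(reference)) {
    out <- toupper(reference)
  } else {
    stop("reference must be a DNAStringSet or a named character vector")
  }
  if (is.null(names(out)) || anyNA(names(out)) || any(names(out) == ""))
    stop("reference sequences must be named by chromosome")
  attr(out, "somaticlone_ref") <- TRUE
  out
}

# Byte length: O(1), unlike character counting, and identical for the
# ASCII sequence alphabet. Use for chromosome-scale strings.
.nc <- function(s) nchar(s, type = "bytes")

# Clipped 1-based substring of one chromosome; returns "" when the window
# falls entirely off the contig.
.refWindow <- function(seqs, chrom, start, end) {
  s <- seqs[[chrom]]
  L <- .nc(s)
  a <- max(1L, as.integer(start))
  b <- min(L, as.integer(end))
  if (a > b) return("")
  substr(s, a, b)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Fast scalar reverse complement for ACGTN strings.
.rc1 <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# 1-based start positions of "CG" dinucleotides in a string.
.cgStarts <- function(x) {
  if (nchar(x) < 2L) return(integer(0))
  m <- gregexpr("(?=CG)", x, perl = TRUE)[[1]]
  if (length(m) == 1L && m[1] == -1L) integer(0) else as.integer(m)
}

# Longest common prefix length of two strings.
.lcp <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- strsplit(a, "", fixed = TRUE)[[1]][seq_len(n)]
  bv <- strsplit(b, "", fixed = TRUE)[[1]][seq_len(n)]
  d <- which(av != bv)
  if (length(d) == 0L) n else d[1L] - 1L
}

# Variant class from REF/ALT allele strings (anchored VCF representation).
.vclass <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  out <- rep("SNV", length(ref))
  out[la > lr] <- "INS"
  out[la < lr] <- "DEL"
  out
}

# Inserted / deleted sequence of an anchored, minimal indel.
.indelSeq <- function(ref, alt) {
  if (nchar(alt) > nchar(ref)) substr(alt, nchar(ref) + 1L, nchar(alt))
  else substr(ref, nchar(alt) + 1L, nchar(ref))
}

# Validate that a variant table has the columns the annotators expect.
.checkVariantTable <- function(x, need = c("chrom", "pos", "ref", "alt")) {
  miss <- setdiff(need, colnames(x))
  if (length(miss))
    stop("variant table is missing column(s): ", paste(miss, collapse = ", "))
  invisible(x)
}

.writeLinesAtomic <- function(lines, path) {
  con <- file(path, open = "wb")  # "wb": identical bytes on every platform
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
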