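# Clone-unique variant filtering: classify multi-clone candidates into
# unique / shared / ambiguous / absent from per-clone allele depths, using
# the VAF thresholds (>30% in one clone, <1% in its sister clones),
# restricted to the shared callable (EWC) regions.

#' @importFrom VariantAnnotation readVcf geno ref alt
#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom IRanges IRanges
NULL

#' Variant allele frequency
#'
#' @param ad_alt Alt-supporting read count(s).
#' @param dp Total depth(s).
#' @return `ad_alt / dp`; `NA` where `dp == 0` (site uncallable for that
#'   clone). Errors if any `ad_alt > dp`.
#' @examples
#' vaf(15, 30)
#' vaf(c(0, 10), c(28, 0))
#' @export
vaf <- function(ad_alt, dp) {
  if (any(ad_alt > dp & dp > 0, na.rm = TRUE) ||
      any(ad_alt > 0 & dp == 0, na.rm = TRUE))
    stop("data error: ad_alt exceeds dp")
  ifelse(dp > 0, ad_alt / dp, NA_real_)
}

# Classify one site from its per-clone VAF vector. Carriers are clones with
# VAF > vaf_unique_min (strict). Rules, in order:
#   shared    iff >= shared_min_clones carriers;
#   unique    iff exactly one carrier and every sister clone (same animal)
#             has a defined VAF < vaf_sister_max (strict);
#   ambiguous iff a carrier's sister is undefined or in the gray zone
#             [vaf_sister_max, vaf_unique_min], or (no carrier) any clone is
#             undefined or in the gray zone;
#   absent    otherwise.
# Clones from other animals are ignored for the uniqueness check.
.classifyOne <- function(v, animal, config) {
  lo <- config@vaf_sister_max; hi <- config@vaf_unique_min
  carrier <- !is.na(v) & v > hi
  n_carr <- sum(carrier)
  if (n_carr >= config@shared_min_clones)
    return(list(label = "shared",
                clones = names(v)[carrier]))
  if (n_carr == 1L) {
    ci <- which(carrier)
    sis <- animal == animal[ci] & seq_along(v) != ci
    if (any(is.na(v[sis])) || any(v[sis] >= lo))
      return(list(label = "ambiguous", clones = character(0)))
    return(list(label = "unique", clones = names(v)[ci]))
  }
  if (any(is.na(v)) || any(v >= lo & v <= hi))
    return(list(label = "ambiguous", clones = character(0)))
  list(label = "absent", clones = character(0))
}

#' Classify a variant across clones by VAF
#'
#' @param ad_alt,dp Named per-clone alt depths and total depths (names are
#'   clone ids), or `vafs` may be given directly.
#' @param clones A [CloneSet-class]; every clone with support must be listed.
#' @param config A [FilterConfig-class].
#' @param vafs Optional named per-clone VAF vector (overrides `ad_alt`/`dp`).
#' @return List with `label` (one of `"unique"`, `"shared"`, `"ambiguous"`,
#'   `"absent"`) and `clones` (carrier clone ids, empty unless
#'   unique/shared).
#' @examples
#' cs <- cloneSet(c("a", "b", "c"), c("X", "X", "X"), c("wt", "wt", "wt"))
#' classifyVariant(clones = cs, vafs = c(a = 0.5, b = 0, c = 0))
#' @export
classifyVariant <- function(ad_alt = NULL, dp = NULL, clones,
                            config = filterConfig(), vafs = NULL) {
  validObject(config)
  if (is.null(vafs)) vafs <- vaf(ad_alt, dp)
  ids <- cloneIds(clones)
  unknown <- setdiff(names(vafs), ids)
  if (length(unknown))
    stop("configuration error: clone(s) in data but not in CloneSet: ",
         paste(unknown, collapse = ", "))
  v <- vafs[ids]
  names(v) <- ids
  .classifyOne(v, animalIds(clones), config)
}

#' Read variant candidates from a multi-sample VCF
#'
#' Reads a VCF v4.2 with per-sample `AD` (ref,alt) and `DP` FORMAT fields,
#' as produced by a haplotype caller or by [writeCandidateVcf()], into the
#' candidate-set structure the filter consumes. Only biallelic records are
#' supported.
#'
#' @param path VCF file path.
#' @return List with `variants` (data.frame `chrom`, `pos`, `ref`, `alt`,
#'   `vclass`) and matrices `AD_alt`, `AD_ref`, `DP` (sites x samples).
#' @export
readVcfCandidates <- function(path) {
  v <- VariantAnnotation::readVcf(path)
  altl <- VariantAnnotation::alt(v)
  if (any(lengths(altl) != 1L))
    stop("multiallelic records are not supported; normalize the VCF first")
  rr <- SummarizedExperiment::rowRanges(v)
  variants <- data.frame(
    chrom = as.character(seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(v)),
    alt = as.character(unlist(altl)),
    stringsAsFactors = FALSE)
  variants$vclass <- .vclass(variants$ref, variants$alt)

  ad <- VariantAnnotation::geno(v)$AD
  dp <- VariantAnnotation::geno(v)$DP
  n <- nrow(variants); ids <- colnames(dp)
  AD_ref <- matrix(0L, n, length(ids), dimnames = list(NULL, ids))
  AD_alt <- AD_ref
  for (j in seq_along(ids)) {
    # Number=R fields parse as a 3-d array or as a matrix of lists,
    # depending on record uniformity
    cell <- if (length(dim(ad)) == 3L) {
      lapply(seq_len(n), function(i) ad[i, j, ])
    } else ad[, j]
    AD_ref[, j] <- vapply(cell, function(x)
      if (is.null(x) || anyNA(x)) 0L else as.integer(x[1L]), integer(1))
    AD_alt[, j] <- vapply(cell, function(x)
      if (is.null(x) || anyNA(x)) 0L else as.integer(x[2L]), integer(1))
  }
  DP <- matrix(as.integer(dp), n, length(ids), dimnames = list(NULL, ids))
  DP[is.na(DP)] <- 0L
  list(variants = variants, AD_alt = AD_alt, AD_ref = AD_ref, DP = DP)
}

#' Call clone-unique mutations from a candidate set
#'
#' Normalizes indels against the reference (when given), restricts
#' candidates to the shared callable regions — a deletion requires its whole
#' deleted span inside, an insertion its anchor base and the following base
#' — classifies every remaining candidate by VAF, and returns the per-clone
#' unique-mutation table. Dropped and non-unique candidates are logged with
#' reasons.
#'
#' @param candidates Candidate set from [readVcfCandidates()] or
#'   [simulateReadSupport()].
#' @param clones A [CloneSet-class].
#' @param ewc GRanges of shared callable regions, or NULL to skip the
#'   restriction.
#' @param config A [FilterConfig-class].
#' @param reference Optional reference (DNAStringSet or named character) for
#'   indel normalization.
#' @return List with `unique` (data.frame: chrom, pos, ref, alt, vclass,
#'   clone_id, vaf, label), `shared` (ditto with comma-joined clone ids),
#'   `counts` (unique mutations per clone), and `log` (data.frame of
#'   non-unique candidates with a `reason`).
#' @export
callUnique <- function(candidates, clones, ewc = NULL,
                       config = filterConfig(), reference = NULL) {
  v <- candidates$variants
  .checkVariantTable(v, c("chrom", "pos", "ref", "alt"))
  if (is.null(v$vclass)) v$vclass <- .vclass(v$ref, v$alt)
  unknown <- setdiff(colnames(candidates$DP), cloneIds(clones))
  if (length(unknown))
    stop("configuration error: clone(s) in data but not in CloneSet: ",
         paste(unknown, collapse = ", "))

  if (!is.null(reference)) {
    seqs <- .refChar(reference)
    for (i in which(v$vclass != "SNV")) {
      nv <- normalizeIndel(v$chrom[i], v$pos[i], v$ref[i], v$alt[i], seqs)
      v$pos[i] <- nv$pos; v$ref[i] <- nv$ref; v$alt[i] <- nv$alt
    }
  }

  n <- nrow(v)
  label <- character(n); carrier <- character(n); reason <- character(n)

  inside <- rep(TRUE, n)
  if (!is.null(ewc) && n > 0L) {
    span_end <- ifelse(v$vclass == "DEL", v$pos + nchar(v$ref) - 1L,
                       ifelse(v$vclass == "INS", v$pos + 1L, v$pos))
    site <- GRanges(v$chrom, IRanges(v$pos, span_end))
    hits <- findOverlaps(site, ewc, type = "within")
    inside <- seq_len(n) %in% S4Vectors::queryHits(hits)
  }

  ids <- cloneIds(clones)
  an <- animalIds(clones)
  for (i in seq_len(n)) {
    if (!inside[i]) { label[i] <- "dropped"; reason[i] <- "outside_EWC"; next }
    vv <- vaf(candidates$AD_alt[i, ids], candidates$DP[i, ids])
    names(vv) <- ids
    res <- .classifyOne(vv, an, config)
    label[i] <- res$label
    carrier[i] <- paste(res$clones, collapse = ",")
    reason[i] <- switch(res$label, unique = "", shared = "shared_in_sisters",
                        ambiguous = "gray_zone_or_uncallable",
                        absent = "no_carrier", dropped = "")
  }

  uq <- which(label == "unique")
  uvaf <- vapply(uq, function(i)
    vaf(candidates$AD_alt[i, carrier[i]], candidates$DP[i, carrier[i]]),
    numeric(1))
  unique_tab <- cbind(v[uq, , drop = FALSE],
                      data.frame(clone_id = carrier[uq], vaf = uvaf,
                                 label = rep("unique", length(uq)),
                                 stringsAsFactors = FALSE))
  rownames(unique_tab) <- NULL
  sh <- which(label == "shared")
  shared_tab <- cbind(v[sh, , drop = FALSE],
                      data.frame(clone_id = carrier[sh],
                                 label = rep("shared", length(sh)),
                                 stringsAsFactors = FALSE))
  rownames(shared_tab) <- NULL
  counts <- table(factor(unique_tab$clone_id, levels = ids))
  logdf <- cbind(v[label != "unique", , drop = FALSE],
                 data.frame(label = label[label != "unique"],
                            reason = reason[label != "unique"],
                            stringsAsFactors = FALSE))
  rownames(logdf) <- NULL
  list(unique = unique_tab, shared = shared_tab,
       counts = as.integer(counts) |> setNames(ids), log = logdf)
}
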