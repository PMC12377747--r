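# Effective whole-genome coverage (EWC): per-sample callable regions from
# depth tracks, and their intersection across samples. A position is callable
# when its MQ60 depth lies within [low_frac, high_frac] of the per-chromosome
# peak (modal) depth (both bounds inclusive), the MQ60/all-mapped depth ratio
# is at least min_mq_ratio, and the base-quality mask passes.

#' @importFrom GenomicRanges GRanges start end width
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlevels seqlengths seqlengths<- seqnames
NULL

#' Per-sample depth profile
#'
#' Holds, per chromosome, the MQ60 (highly reliable read) depth, the
#' all-mapped-reads depth, and a precomputed base-quality pass mask. Depths
#' are dense: element `i` of each vector is position `i` (1-based).
#'
#' @slot mq60 Named list of integer vectors, one per chromosome.
#' @slot all Named list of integer vectors (same names/lengths as `mq60`).
#' @slot bq_pass Named list of logical vectors (same shape).
#' @seealso [depthProfile()], [ewcRegions()], [peakDepth()]
#' @export
setClass("DepthProfile", representation(
  mq60 = "list", all = "list", bq_pass = "list"))

setValidity("DepthProfile", function(object) {
  msg <- character(0)
  nm <- names(object@mq60)
  if (is.null(nm) || !identical(nm, names(object@all)) ||
      !identical(nm, names(object@bq_pass)))
    return("mq60, all and bq_pass must be named lists over the same chromosomes")
  for (ch in nm) {
    if (length(object@mq60[[ch]]) != length(object@all[[ch]]) ||
        length(object@mq60[[ch]]) != length(object@bq_pass[[ch]]))
      msg <- c(msg, paste0("length mismatch on ", ch))
    else if (any(object@mq60[[ch]] > object@all[[ch]]))
      msg <- c(msg, paste0("mq60 depth exceeds all-reads depth on ", ch))
  }
  if (length(msg)) msg else TRUE
})

#' @rdname DepthProfile-class
#' @param mq60,all Named lists of integer depth vectors per chromosome.
#' @param bq_pass Named list of logical vectors, or NULL for all-pass.
#' @return A [DepthProfile-class].
#' @export
depthProfile <- function(mq60, all = mq60, bq_pass = NULL) {
  mq60 <- lapply(mq60, as.integer)
  all <- lapply(all, as.integer)
  if (is.null(bq_pass))
    bq_pass <- lapply(mq60, function(v) rep(TRUE, length(v)))
  new("DepthProfile", mq60 = mq60, all = all, bq_pass = bq_pass)
}

setMethod("show", "DepthProfile", function(object) {
  cat("DepthProfile:", length(object@mq60), "chromosome(s),",
      sum(lengths(object@mq60)), "positions\n")
})

#' Read a depth track TSV
#'
#' Reads a 3-column TSV (chrom, 1-based position, depth) in the dialect of
#' `samtools depth -a` and returns a named list of dense integer vectors.
#' Positions must be contiguous from 1 within each chromosome.
#'
#' @param path TSV file path (no header).
#' @return Named list of integer depth vectors.
#' @export
readDepthTrack <- function(path) {
  dt <- data.table::fread(path, header = FALSE,
                          col.names = c("chrom", "pos", "depth"))
  out <- lapply(split(dt, by = "chrom", keep.by = TRUE), function(d) {
    if (!identical(d$pos, seq_len(nrow(d))))
      stop("depth track positions are not contiguous from 1 in ", path)
    as.integer(d$depth)
  })
  out[unique(dt$chrom)]
}

#' Read a BED mask into per-chromosome logical fail vectors
#'
#' @param path BED3 path (0-based half-open intervals of *failing* bases).
#' @param seqlens Named chromosome lengths.
#' @return Named list of logical vectors, TRUE where the mask passes.
#' @export
readBqMask <- function(path, seqlens) {
  pass <- lapply(seqlens, function(L) rep(TRUE, L))
  if (file.exists(path) && file.size(path) > 0) {
    bed <- data.table::fread(path, header = FALSE)
    for (i in seq_len(nrow(bed))) {
      ch <- as.character(bed[[1]][i])
      pass[[ch]][(bed[[2]][i] + 1L):bed[[3]][i]] <- FALSE
    }
  }
  pass
}

#' Peak (modal) depth
#'
#' The peak coverage of a chromosome is the mode of the integer MQ60 depth
#' histogram over positions with nonzero depth; ties are broken toward the
#' lower depth, which widens the exclusion of suspicious high-depth regions.
#'
#' @param x An integer depth vector, or a [DepthProfile-class] (the MQ60
#'   track is used, and a named per-chromosome vector is returned).
#' @return Integer modal depth (scalar, or named vector for a profile).
#' @examples
#' peakDepth(c(30L, 30L, 30L, 15L))
#' @export
peakDepth <- function(x) {
  if (methods::is(x, "DepthProfile"))
    return(vapply(x@mq60, peakDepth, numeric(1)))
  x <- x[x > 0L]
  if (!length(x)) stop("no coverage: all depths are zero")
  tab <- table(x)
  vals <- as.integer(names(tab))
  min(vals[tab == max(tab)])
}

#' Compute callable (EWC) regions for one sample
#'
#' Evaluates the three callable-region criteria positionwise and emits
#' maximal runs of passing positions as a GRanges (1-based closed; export
#' with rtracklayer for BED 0-based half-open). Sites with zero all-reads
#' depth fail the ratio criterion.
#'
#' @param profile A [DepthProfile-class].
#' @param config An [EWCConfig-class].
#' @return GRanges of callable regions with seqlengths set.
#' @examples
#' p <- depthProfile(mq60 = list(chr1 = rep(30L, 100)))
#' ewcRegions(p)
#' @export
ewcRegions <- function(profile, config = ewcConfig()) {
  validObject(profile); validObject(config)
  gr <- lapply(names(profile@mq60), function(ch) {
    mq <- profile@mq60[[ch]]
    al <- profile@all[[ch]]
    bq <- profile@bq_pass[[ch]]
    peak <- peakDepth(mq)
    depth_ok <- mq >= config@low_frac * peak & mq <= config@high_frac * peak
    ratio_ok <- al > 0L & mq >= config@min_mq_ratio * al
    pass <- depth_ok & ratio_ok & bq
    if (!any(pass)) return(GRanges())
    ir <- IRanges::reduce(IRanges(which(pass), width = 1L))
    GRanges(ch, ir)
  })
  out <- suppressWarnings(do.call(c, gr))
  sl <- vapply(profile@mq60, length, integer(1))
  GenomeInfoDb::seqlevels(out) <- names(sl)
  seqlengths(out) <- sl
  out
}

#' Intersect callable regions across samples
#'
#' Positionwise intersection of per-sample callable-region sets; the regions
#' shared among all samples are the ones used for mutation analyses. Also
#' reports the fraction of each chromosome (and of the genome) covered.
#'
#' @param sets List of GRanges (per-sample callable regions).
#' @param seqlens Optional named chromosome lengths; taken from the first
#'   set's seqlengths when absent.
#' @return List with `regions` (GRanges) and `fraction` (named numeric per
#'   chromosome plus `genome`).
#' @export
intersectEwc <- function(sets, seqlens = NULL) {
  stopifnot(length(sets) >= 1L)
  lev <- lapply(sets, function(g) sort(seqlevels(g)))
  for (i in seq_along(sets)[-1L]) {
    if (!identical(lev[[i]], lev[[1L]]))
      stop("chromosome sets differ between samples: {",
           paste(lev[[1L]], collapse = ","), "} vs {",
           paste(lev[[i]], collapse = ","), "}")
  }
  regions <- Reduce(function(a, b)
    GenomicRanges::intersect(a, b, ignore.strand = TRUE), sets)
  if (is.null(seqlens)) {
    seqlens <- seqlengths(sets[[1L]])
    if (anyNA(seqlens))
      stop("seqlens must be supplied when the input sets lack seqlengths")
  }
  covered <- vapply(names(seqlens), function(ch)
    sum(width(regions[seqnames(regions) == ch])), numeric(1))
  fraction <- c(covered / seqlens, genome = sum(covered) / sum(seqlens))
  list(regions = regions, fraction = fraction)
}
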