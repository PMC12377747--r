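# Interval overlap of indel sites with DMR/feDMR sets, genomic-region
# annotation against a gene model, and the group statistics used for the
# headline comparisons: means +/- sample SD, fold changes on per-clone
# means, and Welch's t test.

#' @importFrom GenomicRanges GRanges promoters setdiff findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom stats pt sd var setNames
NULL

# Variant site GRanges: deletions occupy their deleted span; insertions the
# anchor base and the following base (the two flanks of the inter-base
# insertion point), so an insertion point belongs to an interval iff one of
# its flanking bases does.
.siteRanges <- function(variants) {
  .checkVariantTable(variants)
  vclass <- if (is.null(variants$vclass))
    .vclass(variants$ref, variants$alt) else variants$vclass
  end <- ifelse(vclass == "DEL",
                variants$pos + nchar(variants$ref) - 1L,
                ifelse(vclass == "INS", variants$pos + 1L, variants$pos))
  start <- ifelse(vclass == "DEL", variants$pos + 1L, variants$pos)
  GRanges(variants$chrom, IRanges(start, end))
}

#' Overlap variant sites with named interval sets
#'
#' A variant belongs to a set iff its site (insertion point / deleted span)
#' intersects any interval of the set. Sets that nest (e.g. feDMRs inside
#' CG-DMRs) are reported independently. Counting is invariant under
#' splitting or merging of intervals covering the same positions.
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param interval_sets Named list of GRanges (BED intervals are imported
#'   0-based half-open by rtracklayer and arrive here 1-based closed).
#' @return List with `membership` (logical matrix, variants x sets) and
#'   `counts` (named totals per set).
#' @export
overlapIntervals <- function(variants, interval_sets) {
  stopifnot(is.list(interval_sets), !is.null(names(interval_sets)))
  site <- .siteRanges(variants)
  membership <- vapply(interval_sets, function(g)
    IRanges::overlapsAny(site, GenomicRanges::reduce(g)),
    logical(nrow(variants)))
  if (nrow(variants) == 1L)
    membership <- matrix(membership, nrow = 1L,
                         dimnames = list(NULL, names(interval_sets)))
  list(membership = membership, counts = colSums(membership))
}

#' Derive annotation feature sets from a gene model
#'
#' Accepts a GFF3-style GRanges (e.g. from `rtracklayer::import`) with a
#' `type` column covering `gene`, `exon`, `CDS` and (optionally)
#' `five_prime_UTR` / `three_prime_UTR`, and returns the feature sets used
#' by [annotateGenomicRegion()]: introns are gene bodies minus exons,
#' promoters the `promoter_width` bp upstream of each gene's TSS.
#'
#' @param gene_model GRanges with a `type` metadata column.
#' @param promoter_width Promoter extent upstream of the TSS (default 2000).
#' @return Named list of GRanges: `five_utr`, `three_utr`, `exon_coding`,
#'   `intron`, `promoter`.
#' @export
buildGeneFeatures <- function(gene_model, promoter_width = 2000L) {
  ty <- S4Vectors::mcols(gene_model)$type
  if (is.null(ty)) stop("gene model needs a 'type' metadata column")
  ty <- as.character(ty)
  genes <- gene_model[ty == "gene"]
  exons <- gene_model[ty == "exon"]
  list(
    five_utr = GenomicRanges::reduce(gene_model[ty %in%
      c("five_prime_UTR", "5UTR", "five_utr")]),
    three_utr = GenomicRanges::reduce(gene_model[ty %in%
      c("three_prime_UTR", "3UTR", "three_utr")]),
    exon_coding = GenomicRanges::reduce(gene_model[ty == "CDS"]),
    intron = GenomicRanges::setdiff(GenomicRanges::reduce(genes),
                                    GenomicRanges::reduce(exons)),
    promoter = GenomicRanges::reduce(
      GenomicRanges::promoters(genes, upstream = promoter_width,
                               downstream = 0L)))
}

#' Assign each variant to one genomic region category
#'
#' One category per variant with fixed precedence
#' 5'UTR > 3'UTR > coding exon > intron > promoter > intergenic;
#' multi-transcript conflicts resolve by the same precedence. Variants on
#' contigs absent from the model are intergenic and flagged.
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param features Named list from [buildGeneFeatures()], or a GFF3-style
#'   GRanges (converted internally).
#' @param promoter_width Used when `features` is a raw gene model.
#' @return data.frame with `category` (factor over the six categories) and
#'   `off_model` (TRUE when the contig is absent from the model).
#' @export
annotateGenomicRegion <- function(variants, features,
                                  promoter_width = 2000L) {
  if (!is.list(features) || is.null(features$intron))
    features <- buildGeneFeatures(features, promoter_width)
  site <- .siteRanges(variants)
  prec <- c("five_utr", "three_utr", "exon_coding", "intron", "promoter")
  cat <- rep("intergenic", nrow(variants))
  for (f in rev(prec)) {          # apply upward so high precedence wins last
    hit <- IRanges::overlapsAny(site, features[[f]])
    cat[hit] <- f
  }
  model_chroms <- unique(unlist(lapply(features, function(g)
    as.character(GenomeInfoDb::seqnames(g)))))
  off <- !(variants$chrom %in% model_chroms)
  data.frame(category = factor(cat, levels = c(prec, "intergenic")),
             off_model = off)
}

#' Welch's two-sample t test
#'
#' `t = (mean(x) - mean(y)) / sqrt(s2x/nx + s2y/ny)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value from the
#' t distribution; the unequal-variance test used for all group
#' comparisons.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return List with `t`, `df`, `p`.
#' @examples
#' welchT(c(10, 12, 14), c(10, 12, 14, 16))
#' @export
welchT <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 observations")
  vx <- var(x); vy <- var(y)
  if (vx == 0 && vy == 0) stop("degenerate samples: both variances are zero")
  nx <- length(x); ny <- length(y)
  se2 <- vx / nx + vy / ny
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df))
}

#' Group summary of per-clone metrics
#'
#' For every metric column: per-genotype mean and sample SD (n-1
#' denominator), the ko/wt fold change computed on per-clone means, and
#' Welch's t test (suppressed, with a reason, when a group has fewer than 2
#' clones or both variances are zero).
#'
#' @param metrics data.frame with one row per clone: `clone_id`,
#'   `genotype` (`wt`/`ko`), plus numeric metric columns.
#' @return data.frame with one row per metric: `metric`, `mean_wt`, `sd_wt`,
#'   `n_wt`, `mean_ko`, `sd_ko`, `n_ko`, `fold_change` (NA when
#'   `mean_wt == 0`), `welch_t`, `df`, `p_value`, `p_reason`.
#' @export
groupSummary <- function(metrics) {
  need <- c("clone_id", "genotype")
  miss <- setdiff(need, colnames(metrics))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  cols <- setdiff(colnames(metrics), need)
  cols <- cols[vapply(metrics[cols], is.numeric, logical(1))]
  if (!length(cols)) {
    warning("no numeric metric columns; nothing to summarize")
    return(data.frame())
  }
  do.call(rbind, lapply(cols, function(cl) {
    x <- metrics[[cl]][metrics$genotype == "wt"]
    y <- metrics[[cl]][metrics$genotype == "ko"]
    fold <- if (length(x) && mean(x) > 0) mean(y) / mean(x) else NA_real_
    tt <- NULL; reason <- ""
    if (length(x) >= 2L && length(y) >= 2L) {
      if (var(x) == 0 && var(y) == 0) reason <- "zero_variance"
      else tt <- welchT(y, x)
    } else reason <- "group_too_small"
    data.frame(metric = cl,
               mean_wt = if (length(x)) mean(x) else NA_real_,
               sd_wt = if (length(x) >= 2L) sd(x) else NA_real_,
               n_wt = length(x),
               mean_ko = if (length(y)) mean(y) else NA_real_,
               sd_ko = if (length(y) >= 2L) sd(y) else NA_real_,
               n_ko = length(y),
               fold_change = fold,
               welch_t = if (is.null(tt)) NA_real_ else tt$t,
               df = if (is.null(tt)) NA_real_ else tt$df,
               p_value = if (is.null(tt)) NA_real_ else tt$p,
               p_reason = reason,
               stringsAsFactors = FALSE)
  }))
}
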