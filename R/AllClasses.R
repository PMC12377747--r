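#' @import methods
NULL

## ---------------------------------------------------------------------------
## GenomeSpec
## ---------------------------------------------------------------------------

#' Specification of a synthetic reference genome
#'
#' Describes the synthetic reference the simulator emits: i.i.d. background
#' sequence at a given GC content, CpG-dense intervals emulating
#' differentially methylated CpG regions (CG-DMRs), and planted repeat tracts
#' (homopolymers and short tandem repeats) into which repeat-context indels
#' can later be placed.
#'
#' @slot n_chromosomes Number of chromosomes.
#' @slot chrom_length Length of every chromosome in bases.
#' @slot gc_background Background GC fraction in (0, 1).
#' @slot dmr_count Number of CpG-dense (DMR) intervals per chromosome.
#' @slot dmr_length Length of each DMR in bases.
#' @slot dmr_cpg_density Target CpG dinucleotides per 100 bp inside DMRs.
#' @slot repeat_tract_count Number of repeat tracts planted per chromosome
#'   (split evenly between homopolymers and 2-6 bp tandem repeats).
#' @slot repeat_tract_copies Motif copy number of each planted tract.
#' @slot seed Integer seed making the genome reproducible.
#'
#' @seealso [genomeSpec()], [generateReference()]
#' @export
setClass("GenomeSpec", representation(
  n_chromosomes = "integer",
  chrom_length = "integer",
  gc_background = "numeric",
  dmr_count = "integer",
  dmr_length = "integer",
  dmr_cpg_density = "numeric",
  repeat_tract_count = "integer",
  repeat_tract_copies = "integer",
  seed = "integer"
))

setValidity("GenomeSpec", function(object) {
  msg <- character(0)
  if (object@n_chromosomes < 1L) msg <- c(msg, "n_chromosomes must be >= 1")
  if (object@chrom_length < 1000L) msg <- c(msg, "chrom_length must be >= 1000")
  if (object@gc_background <= 0 || object@gc_background >= 1)
    msg <- c(msg, "gc_background must be in (0, 1)")
  if (object@dmr_count < 0L) msg <- c(msg, "dmr_count must be >= 0")
  if (object@dmr_count > 0L &&
      as.numeric(object@dmr_count) * object@dmr_length > object@chrom_length)
    msg <- c(msg, "dmr_count * dmr_length exceeds chrom_length")
  if (object@dmr_cpg_density < 0 || object@dmr_cpg_density > 50)
    msg <- c(msg, "dmr_cpg_density must be in [0, 50] CpG per 100 bp")
  if (object@repeat_tract_copies < 5L)
    msg <- c(msg, "repeat_tract_copies must be >= 5 (repeat definition)")
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeSpec
#'
#' @param n_chromosomes,chrom_length,gc_background,dmr_count,dmr_length
#'   See the class slots.
#' @param dmr_cpg_density CpG dinucleotides per 100 bp inside DMRs.
#' @param repeat_tract_count,repeat_tract_copies Planted repeat tracts per
#'   chromosome and their copy number.
#' @param seed Integer seed.
#' @return A [GenomeSpec-class] object.
#' @examples
#' genomeSpec(n_chromosomes = 1, chrom_length = 50000, seed = 1)
#' @export
genomeSpec <- function(n_chromosomes = 2L, chrom_length = 1500000L,
                       gc_background = 0.42, dmr_count = 30L,
                       dmr_length = 1000L, dmr_cpg_density = 8,
                       repeat_tract_count = 900L, repeat_tract_copies = 8L,
                       seed = 1L) {
  new("GenomeSpec",
      n_chromosomes = as.integer(n_chromosomes),
      chrom_length = as.integer(chrom_length),
      gc_background = as.numeric(gc_background),
      dmr_count = as.integer(dmr_count),
      dmr_length = as.integer(dmr_length),
      dmr_cpg_density = as.numeric(dmr_cpg_density),
      repeat_tract_count = as.integer(repeat_tract_count),
      repeat_tract_copies = as.integer(repeat_tract_copies),
      seed = as.integer(seed))
}

setMethod("show", "GenomeSpec", function(object) {
  cat("GenomeSpec:", object@n_chromosomes, "chromosome(s) x",
      object@chrom_length, "bp; GC", object@gc_background, "\n")
  cat("  DMRs/chrom:", object@dmr_count, "x", object@dmr_length,
      "bp @", object@dmr_cpg_density, "CpG/100bp;",
      "repeat tracts/chrom:", object@repeat_tract_count, "\n")
  cat("  seed:", object@seed, "\n")
})

## ---------------------------------------------------------------------------
## CloneSet
## ---------------------------------------------------------------------------

#' Named clones grouped by animal and genotype
#'
#' Sister relationships (clones derived from the same animal) drive the
#' clone-unique variant filter: a mutation is attributed to one clone only if
#' its sister clones show essentially no supporting reads.
#'
#' @slot clones data.frame with columns `clone_id`, `animal_id`, `genotype`
#'   (values `"wt"` or `"ko"`).
#' @seealso [cloneSet()]
#' @export
setClass("CloneSet", representation(clones = "data.frame"))

setValidity("CloneSet", function(object) {
  df <- object@clones
  msg <- character(0)
  need <- c("clone_id", "animal_id", "genotype")
  if (!all(need %in% colnames(df)))
    return(paste("clones needs columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(df$clone_id)) msg <- c(msg, "clone_id values must be unique")
  if (!all(df$genotype %in% c("wt", "ko")))
    msg <- c(msg, "genotype must be 'wt' or 'ko'")
  if (length(msg)) msg else TRUE
})

#' Construct a CloneSet
#'
#' @param clone_id,animal_id,genotype Parallel vectors describing each clone.
#' @return A [CloneSet-class] object.
#' @examples
#' cloneSet(c("A1", "A2", "C1", "C2"), c("A", "A", "C", "C"),
#'          c("wt", "wt", "ko", "ko"))
#' @export
cloneSet <- function(clone_id, animal_id, genotype) {
  new("CloneSet", clones = data.frame(
    clone_id = as.character(clone_id),
    animal_id = as.character(animal_id),
    genotype = as.character(genotype),
    stringsAsFactors = FALSE))
}

#' The clonal design of the original study
#'
#' Seven wild-type clones from two animals (A1-3, B1-4) and eight
#' knockout clones from two animals (C1-4, D1-4).
#' @return A [CloneSet-class] with 15 clones.
#' @export
defaultCloneSet <- function() {
  cloneSet(
    clone_id = c("A1", "A2", "A3", "B1", "B2", "B3", "B4",
                 "C1", "C2", "C3", "C4", "D1", "D2", "D3", "D4"),
    animal_id = c(rep("A", 3), rep("B", 4), rep("C", 4), rep("D", 4)),
    genotype = c(rep("wt", 7), rep("ko", 8)))
}

#' @describeIn cloneSet Clone identifiers.
#' @param x A CloneSet.
#' @export
cloneIds <- function(x) x@clones$clone_id

#' @describeIn cloneSet Animal identifier per clone.
#' @export
animalIds <- function(x) x@clones$animal_id

#' @describeIn cloneSet Genotype per clone.
#' @export
genotypes <- function(x) x@clones$genotype

#' @describeIn cloneSet Sister clones (same animal, excluding the clone itself).
#' @param clone A clone_id present in `x`.
#' @export
sistersOf <- function(x, clone) {
  df <- x@clones
  i <- match(clone, df$clone_id)
  if (is.na(i)) stop("unknown clone: ", clone)
  setdiff(df$clone_id[df$animal_id == df$animal_id[i]], clone)
}

setMethod("show", "CloneSet", function(object) {
  df <- object@clones
  cat("CloneSet:", nrow(df), "clones,",
      length(unique(df$animal_id)), "animals (",
      sum(df$genotype == "wt"), "wt /", sum(df$genotype == "ko"), "ko )\n")
})

setMethod("length", "CloneSet", function(x) nrow(x@clones))

## ---------------------------------------------------------------------------
## CloneDesign
## ---------------------------------------------------------------------------

#' Mutation-planting design for the simulator
#'
#' Expected per-clone mutation loads and indel properties used by
#' [plantMutations()]. All rate/probability slots are named numeric vectors
#' with elements `wt` and `ko` so that the two genotypes can differ, as they
#' do in the study design the defaults encode; a scalar is recycled to both.
#'
#' @slot clones A [CloneSet-class].
#' @slot shared_per_animal Early-lineage SNVs shared by all clones of an
#'   animal (count per animal).
#' @slot unique_snv_rate,unique_indel_rate Expected clone-unique events per
#'   clone (Poisson means), per genotype.
#' @slot repeat_indel_fraction Fraction of indels placed in planted repeat
#'   tracts (the rest are nonrepeat-context).
#' @slot nonrepeat_ins_fraction,repeat_ins_fraction Fraction of
#'   nonrepeat/repeat indels that are insertions.
#' @slot p_duplication_insertion Probability a nonrepeat insertion is a
#'   templated duplication of the downstream reference.
#' @slot p_cpg_targeted Probability a nonrepeat indel is placed within
#'   `cpg_window` bp of a CpG site (drawn from DMR CpGs).
#' @slot cpg_window Targeting window in bp (default 2).
#' @slot mh_probs 2 x 5 matrix (rows wt, ko) of deletion junction
#'   microhomology length probabilities for lengths 0-4 (4 = "4+", planted
#'   as exactly 4).
#' @slot ins_size_mean,ins_size_sd,del_size_mean,del_size_sd Per-genotype
#'   nonrepeat indel size moments (bp); sizes are drawn from a discretized
#'   gamma with these moments, floored at 1.
#' @seealso [cloneDesign()]
#' @export
setClass("CloneDesign", representation(
  clones = "CloneSet",
  shared_per_animal = "integer",
  unique_snv_rate = "numeric",
  unique_indel_rate = "numeric",
  repeat_indel_fraction = "numeric",
  nonrepeat_ins_fraction = "numeric",
  repeat_ins_fraction = "numeric",
  p_duplication_insertion = "numeric",
  p_cpg_targeted = "numeric",
  cpg_window = "integer",
  mh_probs = "matrix",
  ins_size_mean = "numeric",
  ins_size_sd = "numeric",
  del_size_mean = "numeric",
  del_size_sd = "numeric"
))

.gt2 <- function(x, what) {
  if (length(x) == 1L) return(c(wt = as.numeric(x), ko = as.numeric(x)))
  if (is.null(names(x)) || !setequal(names(x), c("wt", "ko")))
    stop(what, " must be a scalar or a named c(wt=, ko=) vector")
  c(wt = as.numeric(x[["wt"]]), ko = as.numeric(x[["ko"]]))
}

setValidity("CloneDesign", function(object) {
  msg <- character(0)
  probs <- c(object@repeat_indel_fraction, object@nonrepeat_ins_fraction,
             object@repeat_ins_fraction, object@p_duplication_insertion,
             object@p_cpg_targeted)
  if (any(probs < 0 | probs > 1)) msg <- c(msg, "probabilities must be in [0, 1]")
  if (any(c(object@unique_snv_rate, object@unique_indel_rate) < 0))
    msg <- c(msg, "rates must be >= 0")
  if (!identical(dim(object@mh_probs), c(2L, 5L)))
    msg <- c(msg, "mh_probs must be a 2 x 5 matrix (rows wt, ko; lengths 0-4)")
  else if (any(object@mh_probs < 0) ||
           any(abs(rowSums(object@mh_probs) - 1) > 1e-8))
    msg <- c(msg, "mh_probs rows must be probability vectors summing to 1")
  if (length(msg)) msg else TRUE
})

#' Construct a CloneDesign
#'
#' Defaults encode the study conditions: 7 wt + 8 ko clones; per-clone SNV
#' loads 76 (wt) and 62 (ko); per-clone indel loads 123 (wt) and 111 (ko);
#' nonrepeat indels 4.4/clone wt (1.7 insertions + 2.7 deletions) versus
#' 14.1/clone ko (7.3 + 6.8); duplication fraction of nonrepeat insertions
#' 9/12 wt, 60/60 ko; CpG targeting (within +/-2 bp) 1/12 wt, 40/60 ko for
#' insertions; deletion microhomology present in 12/19 wt, 36/52 ko;
#' nonrepeat insertion sizes 4.2 +/- 3.5 bp wt, 7.3 +/- 3.7 bp ko and
#' deletion sizes 4.9 +/- 5.4 / 5.1 +/- 5.1 bp.
#'
#' @param clones A [CloneSet-class].
#' @param shared_per_animal Shared (early-lineage) SNVs per animal.
#' @param unique_snv_rate,unique_indel_rate,repeat_indel_fraction,nonrepeat_ins_fraction,repeat_ins_fraction,p_duplication_insertion,p_cpg_targeted
#'   Scalars or `c(wt=, ko=)` vectors; see the class slots.
#' @param cpg_window CpG-targeting window (bp).
#' @param mh_probs 2 x 5 microhomology length probability matrix.
#' @param ins_size_mean,ins_size_sd,del_size_mean,del_size_sd Size moments.
#' @return A [CloneDesign-class].
#' @export
cloneDesign <- function(clones = defaultCloneSet(),
                        shared_per_animal = 10L,
                        unique_snv_rate = c(wt = 76, ko = 62),
                        unique_indel_rate = c(wt = 123, ko = 111),
                        repeat_indel_fraction = c(wt = 0.964, ko = 0.873),
                        nonrepeat_ins_fraction = c(wt = 0.386, ko = 0.518),
                        repeat_ins_fraction = c(wt = 0.60, ko = 0.55),
                        p_duplication_insertion = c(wt = 0.75, ko = 1.0),
                        p_cpg_targeted = c(wt = 0.08, ko = 0.60),
                        cpg_window = 2L,
                        mh_probs = rbind(
                          wt = c(0.37, 0.25, 0.18, 0.12, 0.08),
                          ko = c(0.31, 0.26, 0.20, 0.13, 0.10)),
                        ins_size_mean = c(wt = 4.2, ko = 7.3),
                        ins_size_sd = c(wt = 3.5, ko = 3.7),
                        del_size_mean = c(wt = 4.9, ko = 5.1),
                        del_size_sd = c(wt = 5.4, ko = 5.1)) {
  colnames(mh_probs) <- as.character(0:4)
  new("CloneDesign",
      clones = clones,
      shared_per_animal = as.integer(shared_per_animal),
      unique_snv_rate = .gt2(unique_snv_rate, "unique_snv_rate"),
      unique_indel_rate = .gt2(unique_indel_rate, "unique_indel_rate"),
      repeat_indel_fraction = .gt2(repeat_indel_fraction, "repeat_indel_fraction"),
      nonrepeat_ins_fraction = .gt2(nonrepeat_ins_fraction, "nonrepeat_ins_fraction"),
      repeat_ins_fraction = .gt2(repeat_ins_fraction, "repeat_ins_fraction"),
      p_duplication_insertion = .gt2(p_duplication_insertion, "p_duplication_insertion"),
      p_cpg_targeted = .gt2(p_cpg_targeted, "p_cpg_targeted"),
      cpg_window = as.integer(cpg_window),
      mh_probs = mh_probs,
      ins_size_mean = .gt2(ins_size_mean, "ins_size_mean"),
      ins_size_sd = .gt2(ins_size_sd, "ins_size_sd"),
      del_size_mean = .gt2(del_size_mean, "del_size_mean"),
      del_size_sd = .gt2(del_size_sd, "del_size_sd"))
}

setMethod("show", "CloneDesign", function(object) {
  cat("CloneDesign with", length(object@clones), "clones\n")
  cat("  SNVs/clone (wt, ko):", object@unique_snv_rate, "\n")
  cat("  indels/clone (wt, ko):", object@unique_indel_rate,
      "| repeat fraction:", object@repeat_indel_fraction, "\n")
})

## ---------------------------------------------------------------------------
## Configs
## ---------------------------------------------------------------------------

#' Effective whole-genome coverage (EWC) configuration
#'
#' A position is callable when (1) its MQ60 depth lies within
#' `low_frac`-`high_frac` of the per-chromosome peak (modal) depth, both
#' bounds inclusive, (2) the MQ60/all-reads depth ratio is at least
#' `min_mq_ratio`, and (3) the base-quality mask passes (minimum base
#' quality `min_bq`, consumed as a precomputed track).
#'
#' @slot low_frac,high_frac Depth window as fractions of the peak (0.5, 3.0).
#' @slot min_mq_ratio Minimum MQ60/all depth ratio (0.8).
#' @slot min_bq Nominal minimum base quality the mask encodes (20).
#' @export
setClass("EWCConfig", representation(
  low_frac = "numeric", high_frac = "numeric",
  min_mq_ratio = "numeric", min_bq = "numeric"))

setValidity("EWCConfig", function(object) {
  msg <- character(0)
  if (!(object@low_frac > 0 && object@low_frac < object@high_frac))
    msg <- c(msg, "need 0 < low_frac < high_frac")
  if (!(object@min_mq_ratio > 0 && object@min_mq_ratio <= 1))
    msg <- c(msg, "need 0 < min_mq_ratio <= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname EWCConfig-class
#' @param low_frac,high_frac,min_mq_ratio,min_bq See the class slots.
#' @return An [EWCConfig-class].
#' @export
ewcConfig <- function(low_frac = 0.50, high_frac = 3.00,
                      min_mq_ratio = 0.80, min_bq = 20) {
  new("EWCConfig", low_frac = low_frac, high_frac = high_frac,
      min_mq_ratio = min_mq_ratio, min_bq = min_bq)
}

setMethod("show", "EWCConfig", function(object) {
  cat(sprintf("EWCConfig: depth in [%g, %g] x peak; MQ60/all >= %g; BQ >= %g\n",
              object@low_frac, object@high_frac, object@min_mq_ratio,
              object@min_bq))
})

#' Clone-unique variant filter configuration
#'
#' A variant is clone-unique when its VAF exceeds `vaf_unique_min` in exactly
#' one clone (strict) and stays below `vaf_sister_max` (strict) in every
#' sister clone; it is shared when at least `shared_min_clones` clones exceed
#' `vaf_unique_min`.
#'
#' @slot vaf_unique_min Carrier threshold (0.30).
#' @slot vaf_sister_max Sister threshold (0.01).
#' @slot shared_min_clones Minimum carriers for a shared call (2).
#' @export
setClass("FilterConfig", representation(
  vaf_unique_min = "numeric", vaf_sister_max = "numeric",
  shared_min_clones = "integer"))

setValidity("FilterConfig", function(object) {
  if (!(object@vaf_sister_max >= 0 &&
        object@vaf_sister_max < object@vaf_unique_min &&
        object@vaf_unique_min <= 1))
    return("need 0 <= vaf_sister_max < vaf_unique_min <= 1")
  TRUE
})

#' @rdname FilterConfig-class
#' @param vaf_unique_min,vaf_sister_max,shared_min_clones See the class slots.
#' @return A [FilterConfig-class].
#' @export
filterConfig <- function(vaf_unique_min = 0.30, vaf_sister_max = 0.01,
                         shared_min_clones = 2L) {
  new("FilterConfig", vaf_unique_min = vaf_unique_min,
      vaf_sister_max = vaf_sister_max,
      shared_min_clones = as.integer(shared_min_clones))
}

setMethod("show", "FilterConfig", function(object) {
  cat(sprintf("FilterConfig: unique VAF > %g, sister VAF < %g, shared >= %d clones\n",
              object@vaf_unique_min, object@vaf_sister_max,
              object@shared_min_clones))
})

## ---------------------------------------------------------------------------
## SignatureMatrix
## ---------------------------------------------------------------------------

#' Mutation count matrix over a fixed category alphabet
#'
#' Rows are the fixed, ordered category alphabet (96 trinucleotide
#' substitution contexts or 83 indel categories following the COSMIC v3
#' conventions); columns are samples; cells are non-negative counts.
#'
#' @slot counts Integer matrix, categories x samples.
#' @slot kind `"SBS96"` or `"ID83"`.
#' @seealso [sbs96Matrix()], [id83Matrix()], [refitSignatures()]
#' @export
setClass("SignatureMatrix", representation(counts = "matrix", kind = "character"))

setValidity("SignatureMatrix", function(object) {
  alph <- switch(object@kind, SBS96 = sbs96Categories(),
                 ID83 = id83Categories(),
                 return("kind must be 'SBS96' or 'ID83'"))
  if (!identical(rownames(object@counts), alph))
    return("rownames(counts) must equal the fixed category alphabet in order")
  if (any(object@counts < 0)) return("counts must be non-negative")
  TRUE
})

#' @rdname SignatureMatrix-class
#' @param counts Categories x samples count matrix (rownames = alphabet).
#' @param kind `"SBS96"` or `"ID83"`.
#' @return A [SignatureMatrix-class].
#' @export
signatureMatrix <- function(counts, kind) {
  new("SignatureMatrix", counts = counts, kind = kind)
}

#' @describeIn SignatureMatrix-class The count matrix.
#' @param x A SignatureMatrix.
#' @export
sigCounts <- function(x) x@counts

#' @describeIn SignatureMatrix-class The alphabet kind.
#' @export
sigKind <- function(x) x@kind

setMethod("show", "SignatureMatrix", function(object) {
  cat(sprintf("%s SignatureMatrix: %d categories x %d samples; total %d mutations\n",
              object@kind, nrow(object@counts), ncol(object@counts),
              sum(object@counts)))
})
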