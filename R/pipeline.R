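# End-to-end orchestration: candidate VCF + reference + clone table (+
# optional depth tracks, DMR/feDMR BEDs, gene model, signature catalogs)
# through callable-region construction, clone-unique filtering, indel
# annotation, signature matrices and the group report, with a manifest
# recording seed, configuration and output checksums. Stages communicate
# through plain files (TSV/VCF/BED/JSON) so each is independently testable.

#' Validate and assemble a pipeline run configuration
#'
#' @param vcf Multi-sample candidate VCF path.
#' @param reference_fasta Reference FASTA path.
#' @param clones_tsv TSV with columns clone_id, animal_id, genotype.
#' @param out_dir Output directory (created).
#' @param tracks_dir Optional directory of `<clone>.mq60.tsv` /
#'   `<clone>.all.tsv` / `<clone>.bqfail.bed` depth tracks; when absent the
#'   EWC restriction is skipped.
#' @param dmr_bed,fedmr_bed Optional BED paths of CG-DMR / feDMR intervals.
#' @param gene_model Optional GFF3 path for genomic-region annotation.
#' @param sbs_catalog,id_catalog Optional signature catalog TSVs; synthetic
#'   catalogs are used when absent.
#' @param filter,ewc [FilterConfig-class] / [EWCConfig-class].
#' @param seed Integer seed recorded in the manifest.
#' @return A validated configuration (class `somaticloneRunConfig`).
#' @export
runConfig <- function(vcf, reference_fasta, clones_tsv, out_dir,
                      tracks_dir = NULL, dmr_bed = NULL, fedmr_bed = NULL,
                      gene_model = NULL, sbs_catalog = NULL,
                      id_catalog = NULL, filter = filterConfig(),
                      ewc = ewcConfig(), seed = 1L) {
  cfg <- list(vcf = vcf, reference_fasta = reference_fasta,
              clones_tsv = clones_tsv, out_dir = out_dir,
              tracks_dir = tracks_dir, dmr_bed = dmr_bed,
              fedmr_bed = fedmr_bed, gene_model = gene_model,
              sbs_catalog = sbs_catalog, id_catalog = id_catalog,
              filter = filter, ewc = ewc, seed = as.integer(seed))
  for (f in c("vcf", "reference_fasta", "clones_tsv", "tracks_dir",
              "dmr_bed", "fedmr_bed", "gene_model", "sbs_catalog",
              "id_catalog")) {
    p <- cfg[[f]]
    if (!is.null(p) && !file.exists(p))
      stop("validation error: input '", f, "' does not exist: ", p)
  }
  validObject(filter); validObject(ewc)
  class(cfg) <- "somaticloneRunConfig"
  cfg
}

.stage <- function(name, expr) {
  message("[somaticlone] stage: ", name)
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes coverage -> unique-call -> annotation -> signatures -> report on
#' the configured inputs and writes every stage output plus a manifest
#' (tool version, seed, configuration, md5 checksums) to `out_dir`. Rerun
#' with an identical configuration reproduces identical outputs.
#'
#' @param config From [runConfig()].
#' @return Invisibly, a list with the principal in-memory results:
#'   `ewc` (or NULL), `calls`, `annotated`, `summary`, `sbs96`, `id83`,
#'   `refit_sbs`, `refit_id`, `report`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "somaticloneRunConfig"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)

  reference <- .stage("load_reference",
                      Biostrings::readDNAStringSet(config$reference_fasta))
  names(reference) <- sub("\\s.*$", "", names(reference))
  seqlens <- stats::setNames(Biostrings::width(reference), names(reference))
  cl <- utils::read.delim(config$clones_tsv, stringsAsFactors = FALSE)
  clones <- cloneSet(cl$clone_id, cl$animal_id, cl$genotype)
  candidates <- .stage("read_vcf", readVcfCandidates(config$vcf))

  ewc <- NULL
  fraction <- NULL
  if (!is.null(config$tracks_dir)) {
    ewc_sets <- .stage("ewc", lapply(cloneIds(clones), function(cid) {
      mq <- readDepthTrack(file.path(config$tracks_dir,
                                     paste0(cid, ".mq60.tsv")))
      al <- readDepthTrack(file.path(config$tracks_dir,
                                     paste0(cid, ".all.tsv")))
      bqp <- file.path(config$tracks_dir, paste0(cid, ".bqfail.bed"))
      bq <- if (file.exists(bqp)) readBqMask(bqp, lengths(mq)) else NULL
      ewcRegions(depthProfile(mq, al, bq), config$ewc)
    }))
    inter <- intersectEwc(ewc_sets, seqlens)
    ewc <- inter$regions
    fraction <- inter$fraction
    rtracklayer::export(ewc, file.path(out, "ewc_shared.bed"), format = "BED")
  }

  calls <- .stage("call_unique",
                  callUnique(candidates, clones, ewc = ewc,
                             config = config$filter, reference = reference))
  gtmap <- stats::setNames(genotypes(clones), cloneIds(clones))
  uniq <- calls$unique
  uniq$genotype <- gtmap[uniq$clone_id]
  data.table::fwrite(data.table::as.data.table(uniq),
                     file.path(out, "unique_mutations.tsv"), sep = "\t")
  data.table::fwrite(data.table::as.data.table(calls$log),
                     file.path(out, "filter_log.tsv"), sep = "\t")

  annotated <- .stage("annotate", {
    a <- annotateRepeatContext(uniq, reference)
    annotateIndels(a, reference)
  })
  data.table::fwrite(data.table::as.data.table(annotated),
                     file.path(out, "annotated_mutations.tsv"), sep = "\t")

  indels <- annotated[annotated$vclass != "SNV", , drop = FALSE]
  snvs <- annotated[annotated$vclass == "SNV", , drop = FALSE]
  sizes <- indelLengthSummary(indels)
  data.table::fwrite(data.table::as.data.table(sizes$sizes),
                     file.path(out, "indel_sizes.tsv"), sep = "\t")

  nonrep_ins <- indels[indels$repeat_class == "nonrepeat" &
                       indels$vclass == "INS", , drop = FALSE]
  if (nrow(nonrep_ins)) {
    prof <- cpgProfile(nonrep_ins, reference, w = 100L)
    data.table::fwrite(data.table::as.data.table(prof),
                       file.path(out, "cpg_profile_insertions.tsv"),
                       sep = "\t")
  }

  ids <- cloneIds(clones)
  sbs <- .stage("sbs96", sbs96Matrix(snvs, reference, samples = ids))
  id <- .stage("id83", id83Matrix(indels, reference, samples = ids))
  .writeSigTsv <- function(m, path) {
    dt <- data.table::data.table(category = rownames(sigCounts(m)))
    for (cn in colnames(sigCounts(m))) dt[[cn]] <- sigCounts(m)[, cn]
    data.table::fwrite(dt, path, sep = "\t")
  }
  .writeSigTsv(sbs, file.path(out, "sbs96_matrix.tsv"))
  .writeSigTsv(id, file.path(out, "id83_matrix.tsv"))

  sbs_cat <- if (is.null(config$sbs_catalog))
    syntheticSignatureCatalog("SBS96", seed = config$seed)
  else readSignatureCatalog(config$sbs_catalog)
  id_cat <- if (is.null(config$id_catalog))
    syntheticSignatureCatalog("ID83", seed = config$seed)
  else readSignatureCatalog(config$id_catalog)
  refit_sbs <- .stage("refit_sbs", refitSignatures(sbs, sbs_cat))
  refit_id <- .stage("refit_id", refitSignatures(id, id_cat))

  # per-clone metrics feeding the headline report
  met <- data.frame(clone_id = ids, genotype = gtmap[ids],
                    stringsAsFactors = FALSE)
  cnt <- function(sel) vapply(ids, function(cid)
    sum(sel & indels$clone_id == cid), numeric(1))
  nr <- indels$repeat_class == "nonrepeat"
  met$snv <- vapply(ids, function(cid) sum(snvs$clone_id == cid), numeric(1))
  met$indel <- vapply(ids, function(cid)
    sum(indels$clone_id == cid), numeric(1))
  met$nonrepeat_ins <- cnt(nr & indels$vclass == "INS")
  met$nonrepeat_del <- cnt(nr & indels$vclass == "DEL")
  met$ins_cpg10 <- cnt(nr & indels$vclass == "INS" & indels$cpg_within_10)
  met$del_cpg10 <- cnt(nr & indels$vclass == "DEL" & indels$cpg_within_10)
  met$cpg_transversions <- as.numeric(
    cpgTransversionTally(snvs, reference, samples = ids))
  summary_tab <- groupSummary(met)
  data.table::fwrite(data.table::as.data.table(summary_tab),
                     file.path(out, "group_summary.tsv"), sep = "\t")
  data.table::fwrite(data.table::as.data.table(met),
                     file.path(out, "clone_metrics.tsv"), sep = "\t")

  dmr_counts <- NULL
  if (!is.null(config$dmr_bed) && nrow(indels)) {
    sets <- list(cg_dmr = rtracklayer::import(config$dmr_bed))
    if (!is.null(config$fedmr_bed))
      sets$fedmr <- rtracklayer::import(config$fedmr_bed)
    ov <- overlapIntervals(indels, sets)
    dmr_counts <- as.list(ov$counts)
  }
  region_tab <- NULL
  if (!is.null(config$gene_model) && nrow(indels)) {
    gm <- rtracklayer::import(config$gene_model)
    region_tab <- table(annotateGenomicRegion(indels, gm)$category)
  }

  report <- list(
    n_candidates = nrow(candidates$variants),
    n_unique = nrow(uniq), n_shared = nrow(calls$shared),
    unique_per_clone = as.list(calls$counts),
    ewc_fraction = as.list(fraction),
    refit_sbs = as.list(rowMeans(refit_sbs$contributions)),
    refit_id = as.list(rowMeans(refit_id$contributions)),
    dmr_counts = dmr_counts,
    genomic_regions = if (is.null(region_tab)) NULL else as.list(region_tab))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  files <- list.files(out, full.names = TRUE)
  manifest <- list(
    tool = "somaticlone",
    version = as.character(utils::packageVersion("somaticlone")),
    seed = config$seed,
    config = lapply(config[c("vcf", "reference_fasta", "clones_tsv",
                             "tracks_dir", "dmr_bed", "fedmr_bed",
                             "gene_model")],
                    function(x) if (is.null(x)) NA else x),
    checksums = as.list(tools::md5sum(setdiff(files,
      file.path(out, "manifest.json")))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(ewc = ewc, ewc_fraction = fraction, calls = calls,
                 annotated = annotated, summary = summary_tab,
                 metrics = met, sbs96 = sbs, id83 = id,
                 refit_sbs = refit_sbs, refit_id = refit_id,
                 report = report))
}
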