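# Synthetic-data generator: reference genome with CpG-dense DMR intervals and
# planted repeat tracts, clone lineage mutations with controlled indel
# properties, binomial read support, and depth tracks with planted artifacts.
# Every output carries a machine-readable truth table so downstream modules
# can be tested by parameter recovery.

#' @importFrom GenomicRanges GRanges reduce findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqnames
#' @importFrom stats rpois rbinom rgamma runif qpois ppois
#' @importFrom Biostrings writeXStringSet
NULL

.BASES <- c("A", "C", "G", "T")

# ---------------------------------------------------------------------------
# Reference generation
# ---------------------------------------------------------------------------

# Non-overlapping interval placement: one interval per equal-width block with
# a random offset, so placement is collision-free by construction.
.placeBlocks <- function(n, len, lo, hi) {
  if (n == 0L) return(integer(0))
  span <- hi - lo + 1L
  block <- span %/% n
  if (block <= len) stop("intervals of length ", len, " do not fit: ",
                         n, " requested in ", span, " bp")
  offs <- floor(runif(n, 0, block - len))
  as.integer(lo + (seq_len(n) - 1L) * block + offs)
}

#' Generate a synthetic reference genome
#'
#' Builds i.i.d. background sequence at the requested GC content, then
#' overwrites (i) CpG-dense DMR intervals in which CG dinucleotides are
#' planted at the target density and (ii) repeat tracts (homopolymers and
#' 2-4 bp tandem repeats, half/half) whose boundaries are sealed so the
#' planted copy numbers are exact. Deterministic given `spec@seed`.
#'
#' @param spec A [GenomeSpec-class].
#' @return A list with elements `genome` (named [Biostrings::DNAStringSet]),
#'   `dmr` (GRanges of DMR intervals) and `repeats` (GRanges of planted
#'   repeat tracts with metadata columns `class`, `motif`, `copies`).
#' @examples
#' ref <- generateReference(genomeSpec(n_chromosomes = 1,
#'                                     chrom_length = 50000, seed = 7))
#' ref$genome
#' @export
generateReference <- function(spec) {
  validObject(spec)
  set.seed(spec@seed)
  L <- spec@chrom_length
  gc <- spec@gc_background
  pb <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  chroms <- paste0("chr", seq_len(spec@n_chromosomes))

  genome <- character(length(chroms))
  dmr_all <- vector("list", length(chroms))
  rep_all <- vector("list", length(chroms))

  for (ci in seq_along(chroms)) {
    s <- sample(.BASES, L, replace = TRUE, prob = pb)

    # DMRs in the left-of-center region, repeat tracts to their right; both
    # placed block-wise so that no two planted features overlap.
    margin <- 500L
    dmr_starts <- integer(0)
    if (spec@dmr_count > 0L) {
      dmr_zone_hi <- margin + max(spec@dmr_count * spec@dmr_length * 4L,
                                  L %/% 3L)
      dmr_zone_hi <- min(dmr_zone_hi, L %/% 2L)
      dmr_starts <- .placeBlocks(spec@dmr_count, spec@dmr_length,
                                 margin, dmr_zone_hi)
      n_cpg <- as.integer(round(spec@dmr_length * spec@dmr_cpg_density / 100))
      for (d in dmr_starts) {
        cand <- seq.int(d, d + spec@dmr_length - 2L, by = 2L)
        starts <- sort(sample(cand, min(n_cpg, length(cand))))
        s[starts] <- "C"
        s[starts + 1L] <- "G"
      }
    }

    tracts <- NULL
    if (spec@repeat_tract_count > 0L) {
      zone_lo <- if (length(dmr_starts))
        max(dmr_starts) + spec@dmr_length + 100L else margin
      n_t <- spec@repeat_tract_count
      maxlen <- 4L * spec@repeat_tract_copies + 2L
      starts <- .placeBlocks(n_t, maxlen, zone_lo, L - margin)
      cls <- rep(c("homopolymer", "tandem_repeat"), length.out = n_t)
      motif <- character(n_t); tlen <- integer(n_t)
      for (i in seq_len(n_t)) {
        if (cls[i] == "homopolymer") {
          motif[i] <- sample(.BASES, 1L)
        } else {
          k <- sample(2:4, 1L)
          repeat {
            m <- paste(sample(.BASES, k, replace = TRUE), collapse = "")
            ch <- strsplit(m, "", fixed = TRUE)[[1]]
            if (length(unique(ch)) > 1L &&
                !(k == 4L && ch[1] == ch[3] && ch[2] == ch[4])) break
          }
          motif[i] <- m
        }
        k <- nchar(motif[i])
        tlen[i] <- k * spec@repeat_tract_copies
        tract <- strsplit(strrep(motif[i], spec@repeat_tract_copies),
                          "", fixed = TRUE)[[1]]
        a <- starts[i]
        s[a:(a + tlen[i] - 1L)] <- tract
        # seal the boundaries so the copy number is exactly as planted and
        # a motif-copy indel at the left edge is already left-aligned
        last <- substr(motif[i], k, k)
        first <- substr(motif[i], 1L, 1L)
        s[a - 1L] <- sample(setdiff(.BASES, c(last, first)), 1L)
        s[a + tlen[i]] <- sample(setdiff(.BASES, c(first, last)), 1L)
      }
      tracts <- GRanges(chroms[ci], IRanges(starts, width = tlen),
                        class = cls, motif = motif,
                        copies = spec@repeat_tract_copies)
    }

    genome[ci] <- paste(s, collapse = "")
    dmr_all[[ci]] <- if (length(dmr_starts))
      GRanges(chroms[ci], IRanges(dmr_starts, width = spec@dmr_length))
    else GRanges()
    rep_all[[ci]] <- if (is.null(tracts)) GRanges() else tracts
  }

  names(genome) <- chroms
  gset <- Biostrings::DNAStringSet(genome)
  sl <- setNames(rep(L, length(chroms)), chroms)
  dmr <- suppressWarnings(do.call(c, dmr_all))
  reps <- suppressWarnings(do.call(c, rep_all))
  seqlengths(dmr) <- sl[GenomeInfoDb::seqlevels(dmr)]
  seqlengths(reps) <- sl[GenomeInfoDb::seqlevels(reps)]
  list(genome = gset, dmr = dmr, repeats = reps)
}

# ---------------------------------------------------------------------------
# Plant-time scanners (shared definitions; see classifyRepeatContext)
# ---------------------------------------------------------------------------

# consecutive copies of `unit` in `s` starting at `from` going right
.countRight <- function(s, from, unit) {
  k <- nchar(unit); n <- 0L; p <- as.integer(from); L <- .nc(s)
  while (p + k - 1L <= L && substr(s, p, p + k - 1L) == unit) {
    n <- n + 1L; p <- p + k
  }
  n
}

# consecutive copies of `unit` ending at position `to` going left
.countLeft <- function(s, to, unit) {
  k <- nchar(unit); n <- 0L; p <- as.integer(to)
  while (p - k + 1L >= 1L && substr(s, p - k + 1L, p) == unit) {
    n <- n + 1L; p <- p - k
  }
  n
}

# Repeat-context class of an anchored indel (anchor a, indel sequence S).
# Precedence homopolymer > tandem_repeat > nonrepeat; a run/tract counts when
# it is contiguous with the site or starts/ends within 1 bp of it.
.repeatClassAt <- function(s, a, S, max_motif = 6L, min_copies = 5L) {
  L <- nchar(S)
  ch <- strsplit(S, "", fixed = TRUE)[[1]]
  if (length(unique(ch)) == 1L) {
    b <- ch[1]
    run <- .countLeft(s, a, b) + .countRight(s, a + 1L, b)
    if (run < min_copies)
      run <- max(run, .countRight(s, a + 2L, b), .countLeft(s, a - 1L, b))
    if (run >= min_copies)
      return(list(class = "homopolymer", motif = b, copies = run))
  }
  for (k in 2:min(max_motif, L)) {
    if (L %% k != 0L) next
    m <- substr(S, 1L, k)
    if (strrep(m, L %/% k) != S) next
    if (length(unique(strsplit(m, "", fixed = TRUE)[[1]])) == 1L) next
    cop <- .countLeft(s, a, m) + .countRight(s, a + 1L, m)
    if (cop < min_copies)
      cop <- max(cop, .countRight(s, a + 2L, m), .countLeft(s, a - 1L, m))
    if (cop >= min_copies)
      return(list(class = "tandem_repeat", motif = m, copies = cop))
  }
  list(class = "nonrepeat", motif = "", copies = 0L)
}

# Junction microhomology of a deletion span [s0, e0] by direct scan of both
# junction orientations, capped at the deletion length.
.bruteMH <- function(s, s0, e0) {
  L <- e0 - s0 + 1L
  del <- substr(s, s0, e0)
  down <- substr(s, e0 + 1L, min(.nc(s), e0 + L))
  a <- .lcp(del, down)
  up <- substr(s, max(1L, s0 - L), s0 - 1L)
  rdel <- .rc1(del); rup <- .rc1(up)
  # suffix match of del against upstream == prefix match of reverse complements
  # of the *reversed* strings; plain character reversal is what we need:
  revstr <- function(x) paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
  b <- .lcp(revstr(del), revstr(up))
  min(max(a, b), L)
}

# CpG-window flag used to stamp planted truth: INS anchor a -> CG start in
# [a+1-w, a+w]; DEL span [s0,e0] -> CG footprint intersects [s0-w, e0+w].
.scanCpGWithin <- function(s, a, vclass, indel_len, w) {
  if (vclass == "INS") {
    lo <- a + 1L - w; hi <- a + w
  } else {
    lo <- a + 1L - w - 1L; hi <- a + indel_len + w
  }
  win <- substr(s, max(1L, lo), min(.nc(s), hi + 1L))
  length(.cgStarts(win)) > 0L
}

# ---------------------------------------------------------------------------
# Mutation planting
# ---------------------------------------------------------------------------

.sizeDraw <- function(n, mean, sd) {
  if (n == 0L) return(integer(0))
  shape <- (mean / sd)^2; rate <- mean / sd^2
  pmax(1L, as.integer(round(rgamma(n, shape = shape, rate = rate))))
}

#' Plant clone lineage mutations into a synthetic reference
#'
#' Draws per-clone Poisson numbers of clone-unique SNVs and indels plus a
#' fixed number of early-lineage SNVs shared by all clones of an animal, and
#' places them on the reference with controlled properties: repeat-context
#' indels are whole-motif-copy edits at planted tract edges; nonrepeat
#' insertions are templated downstream duplications with the design
#' probability; nonrepeat deletions carry an exactly-planted junction
#' microhomology length; CpG-targeted indels are placed within the design
#' window of a DMR CpG. All planted representations are left-aligned and
#' separated by at least `min_spacing` bp.
#'
#' @param reference Output of [generateReference()] (list with `genome`,
#'   `dmr`, `repeats`), or a DNAStringSet if `dmr`/`repeats` are given.
#' @param design A [CloneDesign-class].
#' @param dmr,repeats Optional GRanges overriding `reference$dmr` /
#'   `reference$repeats`.
#' @param seed Integer seed.
#' @param min_spacing Minimum distance between planted anchors (bp).
#' @param margin Chromosome-end exclusion (bp) so +/-100 bp windows exist.
#' @param max_tries Placement attempts per event before giving up.
#' @return A truth table `data.frame` with one row per planted variant:
#'   coordinates and alleles (`chrom`, `pos`, `ref`, `alt`, `vclass`), origin
#'   (`origin`, `clone_id`, `animal_id`, `genotype`, `carriers`), and planted
#'   properties (`repeat_class`, `motif`, `motif_copies`, `indel_length`,
#'   `is_dup`, `mh_len`, `cpg_within_2`, `cpg_within_10`, `in_dmr`).
#' @export
plantMutations <- function(reference, design, dmr = NULL, repeats = NULL,
                           seed = 1L, min_spacing = 150L, margin = 200L,
                           max_tries = 10000L) {
  validObject(design)
  if (is.list(reference) && !is.null(reference$genome)) {
    if (is.null(dmr)) dmr <- reference$dmr
    if (is.null(repeats)) repeats <- reference$repeats
    reference <- reference$genome
  }
  seqs <- .refChar(reference)
  chroms <- names(seqs)
  clen <- nchar(seqs)
  set.seed(seed)

  cl <- design@clones@clones
  used <- lapply(chroms, function(x) integer(0)); names(used) <- chroms

  okSpacing <- function(chrom, a) {
    u <- used[[chrom]]
    !length(u) || all(abs(u - a) >= min_spacing)
  }
  register <- function(chrom, a) used[[chrom]][length(used[[chrom]]) + 1L] <<- a

  # CpG positions inside DMRs, per chromosome (targets for CpG-proximal indels)
  dmr_cg <- lapply(chroms, function(ch) {
    g <- dmr[as.character(seqnames(dmr)) == ch]
    if (!length(g)) return(integer(0))
    unlist(lapply(seq_along(g), function(i) {
      st <- GenomicRanges::start(g)[i]
      .cgStarts(substr(seqs[[ch]], st, GenomicRanges::end(g)[i])) + st - 1L
    }))
  })
  names(dmr_cg) <- chroms

  # available repeat tracts (one indel per tract)
  if (is.null(repeats)) repeats <- GRanges()
  tract_free <- rep(TRUE, length(repeats))
  tract_chr <- as.character(seqnames(repeats))
  tract_start <- GenomicRanges::start(repeats)
  tract_motif <- if (length(repeats)) mcols(repeats)$motif else character(0)
  tract_class <- if (length(repeats)) mcols(repeats)$class else character(0)
  tract_copies <- if (length(repeats)) mcols(repeats)$copies else integer(0)

  rows <- list()
  addRow <- function(...) rows[[length(rows) + 1L]] <<- list(...)

  pickChrom <- function() sample(chroms, 1L, prob = clen / sum(clen))

  plantSNV <- function(clone_id, animal_id, genotype, carriers, origin) {
    for (t in seq_len(max_tries)) {
      ch <- pickChrom()
      a <- sample.int(clen[[ch]] - 2L * margin, 1L) + margin
      if (!okSpacing(ch, a)) next
      rb <- substr(seqs[[ch]], a, a)
      if (!rb %in% .BASES) next
      alt <- sample(setdiff(.BASES, rb), 1L)
      register(ch, a)
      addRow(chrom = ch, pos = a, ref = rb, alt = alt, vclass = "SNV",
             origin = origin, clone_id = clone_id, animal_id = animal_id,
             genotype = genotype, carriers = carriers,
             repeat_class = NA_character_, motif = NA_character_,
             motif_copies = NA_integer_, indel_length = 0L,
             is_dup = NA, mh_len = NA_integer_,
             cpg_within_2 = NA, cpg_within_10 = NA)
      return(invisible(TRUE))
    }
    stop("could not place SNV after ", max_tries, " tries; ",
         "genome too small for the requested rates")
  }

  plantRepeatIndel <- function(clone_id, animal_id, genotype, is_ins) {
    idx <- which(tract_free)
    if (!length(idx)) stop("no free repeat tracts left; increase ",
                           "repeat_tract_count in the GenomeSpec")
    for (t in seq_len(max_tries)) {
      if (!length(idx)) break
      i <- if (length(idx) == 1L) idx else sample(idx, 1L)
      ch <- tract_chr[i]; a <- tract_start[i] - 1L
      if (!okSpacing(ch, a)) { idx <- setdiff(idx, i); next }
      m <- tract_motif[i]; k <- nchar(m)
      anchor <- substr(seqs[[ch]], a, a)
      if (is_ins) {
        ref <- anchor; alt <- paste0(anchor, m)
      } else {
        ref <- substr(seqs[[ch]], a, a + k); alt <- anchor
      }
      tract_free[i] <<- FALSE
      register(ch, a)
      addRow(chrom = ch, pos = a, ref = ref, alt = alt,
             vclass = if (is_ins) "INS" else "DEL",
             origin = "unique", clone_id = clone_id, animal_id = animal_id,
             genotype = genotype, carriers = clone_id,
             repeat_class = tract_class[i], motif = m,
             motif_copies = tract_copies[i], indel_length = k,
             is_dup = NA, mh_len = NA_integer_,
             cpg_within_2 = NA, cpg_within_10 = NA)
      return(invisible(TRUE))
    }
    stop("could not place repeat indel (tract collisions); ",
         "increase repeat_tract_count or genome size")
  }

  drawAnchor <- function(targeted, w, span) {
    # returns c(chrom index?, pos); targeted anchors sit near a DMR CpG
    ch <- pickChrom()
    if (targeted && length(dmr_cg[[ch]])) {
      q <- sample(dmr_cg[[ch]], 1L)
      a <- q + sample.int(2L * w + span, 1L) - w - span - 1L
    } else {
      a <- sample.int(clen[[ch]] - 2L * margin, 1L) + margin
    }
    list(chrom = ch, a = a)
  }

  plantNonrepIns <- function(clone_id, animal_id, genotype, size, dup,
                             targeted, w) {
    s_try <- size
    for (t in seq_len(max_tries)) {
      d <- drawAnchor(targeted, w, 0L); ch <- d$chrom; a <- d$a
      if (a <= margin || a >= clen[[ch]] - margin) next
      if (!okSpacing(ch, a)) next
      sq <- seqs[[ch]]
      anchor <- substr(sq, a, a)
      if (dup) {
        S <- substr(sq, a + 1L, a + s_try)
        if (nchar(S) < s_try) next
      } else {
        S <- paste(sample(.BASES, s_try, replace = TRUE), collapse = "")
        if (substr(S, 1L, 1L) == substr(sq, a + 1L, a + 1L)) next  # not a dup
      }
      if (substr(S, s_try, s_try) == anchor) next        # keep left-aligned
      if (.repeatClassAt(sq, a, S)$class != "nonrepeat") next
      if (targeted && !.scanCpGWithin(sq, a, "INS", s_try, w)) next
      register(ch, a)
      addRow(chrom = ch, pos = a, ref = anchor, alt = paste0(anchor, S),
             vclass = "INS", origin = "unique", clone_id = clone_id,
             animal_id = animal_id, genotype = genotype, carriers = clone_id,
             repeat_class = "nonrepeat", motif = "", motif_copies = 0L,
             indel_length = s_try, is_dup = dup, mh_len = NA_integer_,
             cpg_within_2 = NA, cpg_within_10 = NA)
      return(invisible(TRUE))
    }
    stop("could not place nonrepeat insertion after ", max_tries, " tries")
  }

  plantNonrepDel <- function(clone_id, animal_id, genotype, size, mh_target,
                             targeted, w) {
    Ld <- max(size, mh_target + 1L)
    B <- 256L
    for (batch in seq_len(max(1L, max_tries %/% B))) {
      # batched candidate anchors on one chromosome, screened vectorized:
      # margin, left-alignment, then exact junction microhomology computed
      # as leading-run matches on both junction orientations
      ch <- pickChrom()
      sq <- seqs[[ch]]
      if (targeted && length(dmr_cg[[ch]])) {
        q <- sample(dmr_cg[[ch]], B, replace = TRUE)
        a <- q + sample.int(2L * w + Ld, B, replace = TRUE) - w - Ld - 1L
      } else {
        a <- sample.int(clen[[ch]] - 2L * margin, B, replace = TRUE) + margin
      }
      a <- a[a > margin & a + Ld < clen[[ch]] - margin]
      if (!length(a)) next
      a <- a[substring(sq, a, a) != substring(sq, a + Ld, a + Ld)]
      if (!length(a)) next
      run3 <- run5 <- integer(length(a))
      alive3 <- alive5 <- rep(TRUE, length(a))
      for (k in seq_len(Ld)) {
        alive3 <- alive3 & substring(sq, a + k, a + k) ==
          substring(sq, a + Ld + k, a + Ld + k)
        run3 <- run3 + alive3
        alive5 <- alive5 & substring(sq, a + Ld - k + 1L, a + Ld - k + 1L) ==
          substring(sq, a - k + 1L, a - k + 1L)
        run5 <- run5 + alive5
      }
      a <- a[pmin(pmax(run3, run5), Ld) == mh_target]
      for (cand in a) {
        if (!okSpacing(ch, cand)) next
        S <- substr(sq, cand + 1L, cand + Ld)
        if (.repeatClassAt(sq, cand, S)$class != "nonrepeat") next
        if (targeted && !.scanCpGWithin(sq, cand, "DEL", Ld, w)) next
        register(ch, cand)
        addRow(chrom = ch, pos = cand, ref = substr(sq, cand, cand + Ld),
               alt = substr(sq, cand, cand), vclass = "DEL",
               origin = "unique", clone_id = clone_id,
               animal_id = animal_id, genotype = genotype,
               carriers = clone_id, repeat_class = "nonrepeat", motif = "",
               motif_copies = 0L, indel_length = Ld, is_dup = NA,
               mh_len = mh_target, cpg_within_2 = NA, cpg_within_10 = NA)
        return(invisible(TRUE))
      }
    }
    stop("could not place nonrepeat deletion (mh=", mh_target,
         ") after ", max_tries, " tries")
  }

  # shared early-lineage SNVs, one batch per animal
  for (an in unique(cl$animal_id)) {
    members <- cl$clone_id[cl$animal_id == an]
    gt <- cl$genotype[cl$animal_id == an][1]
    if (length(members) >= 2L && design@shared_per_animal > 0L) {
      for (i in seq_len(design@shared_per_animal))
        plantSNV(NA_character_, an, gt, paste(members, collapse = ","),
                 "shared")
    }
  }

  # clone-unique events: draw all per-clone counts, then plant repeat
  # indels first (they are tied to fixed tract positions, which free-floating
  # variants would otherwise block through the spacing rule)
  n_snv <- n_rep <- rep_ins <- n_non <- integer(nrow(cl))
  for (i in seq_len(nrow(cl))) {
    gt <- cl$genotype[i]
    n_snv[i] <- rpois(1L, design@unique_snv_rate[[gt]])
    n_ind <- rpois(1L, design@unique_indel_rate[[gt]])
    n_rep[i] <- rbinom(1L, n_ind, design@repeat_indel_fraction[[gt]])
    rep_ins[i] <- rbinom(1L, n_rep[i], design@repeat_ins_fraction[[gt]])
    n_non[i] <- n_ind - n_rep[i]
  }
  for (i in seq_len(nrow(cl))) {
    id <- cl$clone_id[i]; an <- cl$animal_id[i]; gt <- cl$genotype[i]
    for (j in seq_len(rep_ins[i])) plantRepeatIndel(id, an, gt, TRUE)
    for (j in seq_len(n_rep[i] - rep_ins[i])) plantRepeatIndel(id, an, gt, FALSE)
  }
  for (i in seq_len(nrow(cl))) {
    id <- cl$clone_id[i]; an <- cl$animal_id[i]; gt <- cl$genotype[i]
    for (j in seq_len(n_snv[i])) plantSNV(id, an, gt, id, "unique")

    n_ins <- rbinom(1L, n_non[i], design@nonrepeat_ins_fraction[[gt]])
    n_del <- n_non[i] - n_ins
    w <- design@cpg_window
    if (n_ins > 0L) {
      sizes <- .sizeDraw(n_ins, design@ins_size_mean[[gt]],
                         design@ins_size_sd[[gt]])
      dups <- runif(n_ins) < design@p_duplication_insertion[[gt]]
      targ <- runif(n_ins) < design@p_cpg_targeted[[gt]]
      for (j in seq_len(n_ins))
        plantNonrepIns(id, an, gt, sizes[j], dups[j], targ[j], w)
    }
    if (n_del > 0L) {
      sizes <- .sizeDraw(n_del, design@del_size_mean[[gt]],
                         design@del_size_sd[[gt]])
      mhs <- sample(0:4, n_del, replace = TRUE,
                    prob = design@mh_probs[gt, ])
      targ <- runif(n_del) < design@p_cpg_targeted[[gt]]
      for (j in seq_len(n_del))
        plantNonrepDel(id, an, gt, sizes[j], mhs[j], targ[j], w)
    }
  }

  truth <- as.data.frame(data.table::rbindlist(rows))
  truth <- truth[order(truth$chrom, truth$pos), , drop = FALSE]
  rownames(truth) <- NULL

  # stamp CpG-window flags and DMR membership on every indel by direct scan
  is_indel <- truth$vclass != "SNV"
  truth$cpg_within_2[is_indel] <- vapply(which(is_indel), function(i)
    .scanCpGWithin(seqs[[truth$chrom[i]]], truth$pos[i], truth$vclass[i],
                   truth$indel_length[i], 2L), logical(1))
  truth$cpg_within_10[is_indel] <- vapply(which(is_indel), function(i)
    .scanCpGWithin(seqs[[truth$chrom[i]]], truth$pos[i], truth$vclass[i],
                   truth$indel_length[i], 10L), logical(1))
  site <- GRanges(truth$chrom,
                  IRanges(truth$pos,
                          truth$pos + pmax(1L, nchar(truth$ref) - 1L)))
  truth$in_dmr <- IRanges::overlapsAny(site, dmr)
  truth
}

# ---------------------------------------------------------------------------
# Read support
# ---------------------------------------------------------------------------

# zero-truncated Poisson
.rztpois <- function(n, lambda) {
  p0 <- ppois(0, lambda)
  qpois(runif(n, p0, 1), lambda)
}

#' Simulate per-clone read support for planted variants
#'
#' For every site and clone, draws total depth from a zero-truncated
#' Poisson(`depth_mean`) and alt-supporting reads from a binomial with the
#' contamination-adjusted allele frequency: carrier clones have expected VAF
#' `(1 - contamination) * 0.5`, non-carriers `contamination * 0.5`
#' (cross-clone leakage at the VAF level). A fraction `p_uncovered` of
#' clone-site cells is emitted with zero depth (uncallable).
#'
#' @param truth Truth table from [plantMutations()].
#' @param clones A [CloneSet-class].
#' @param depth_mean Mean sequencing depth per clone.
#' @param contamination Cross-clone contamination fraction in [0, 0.05].
#' @param p_uncovered Probability a clone-site cell has no coverage.
#' @param seed Integer seed.
#' @return A candidate set: list with `variants` (data.frame chrom, pos, ref,
#'   alt, vclass) and matrices `AD_alt`, `AD_ref`, `DP` (sites x clones).
#' @export
simulateReadSupport <- function(truth, clones, depth_mean = 40,
                                contamination = 0, p_uncovered = 0,
                                seed = 1L) {
  stopifnot(depth_mean > 0)
  if (contamination < 0 || contamination > 0.05)
    stop("contamination must be in [0, 0.05]")
  set.seed(seed)
  ids <- cloneIds(clones)
  n <- nrow(truth); m <- length(ids)

  carrier <- matrix(FALSE, n, m, dimnames = list(NULL, ids))
  carr <- strsplit(truth$carriers, ",", fixed = TRUE)
  for (i in seq_len(n)) carrier[i, carr[[i]]] <- TRUE

  vaf_true <- ifelse(carrier, (1 - contamination) * 0.5,
                     contamination * 0.5)
  DP <- matrix(as.integer(.rztpois(n * m, depth_mean)), n, m,
               dimnames = list(NULL, ids))
  if (p_uncovered > 0)
    DP[runif(n * m) < p_uncovered] <- 0L
  AD_alt <- matrix(as.integer(rbinom(n * m, as.vector(DP),
                                     as.vector(vaf_true))),
                   n, m, dimnames = list(NULL, ids))
  AD_ref <- DP - AD_alt

  list(variants = truth[, c("chrom", "pos", "ref", "alt", "vclass")],
       AD_alt = AD_alt, AD_ref = AD_ref, DP = DP)
}

#' Write a candidate set as a multi-sample VCF v4.2
#'
#' Emits one biallelic record per variant with per-sample `AD` (ref,alt) and
#' `DP` FORMAT fields. Zero-depth cells are written as missing genotypes with
#' `AD=.,.` and `DP=0`. Output is byte-deterministic.
#'
#' @param support Candidate set from [simulateReadSupport()].
#' @param path Output file path.
#' @param seqlens Named vector of chromosome lengths for contig headers.
#' @return `path`, invisibly.
#' @export
writeCandidateVcf <- function(support, path, seqlens) {
  v <- support$variants
  ids <- colnames(support$DP)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=somaticlone",
           paste0("##contig=<ID=", names(seqlens), ",length=", seqlens, ">"),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", ids), collapse = "\t"))
  n <- nrow(v)
  cells <- matrix("", n, length(ids))
  for (j in seq_along(ids)) {
    dp <- support$DP[, j]; aa <- support$AD_alt[, j]; ar <- support$AD_ref[, j]
    gt <- ifelse(dp == 0L, "./.", ifelse(aa > 0L, "0/1", "0/0"))
    ad <- ifelse(dp == 0L, ".,.", paste0(ar, ",", aa))
    cells[, j] <- paste0(gt, ":", ad, ":", dp)
  }
  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", ".", ".", "GT:AD:DP",
                apply(cells, 1L, paste, collapse = "\t"), sep = "\t")
  .writeLinesAtomic(c(hdr, body), path)
}

# ---------------------------------------------------------------------------
# Depth tracks
# ---------------------------------------------------------------------------

#' Simulate per-clone depth tracks with planted coverage artifacts
#'
#' Baseline tracks are constant at `depth` for both the MQ60 and all-reads
#' profile, so the per-chromosome peak equals `depth` and, absent artifacts,
#' the callable region is the whole chromosome. Each planted artifact
#' violates exactly one callable-region criterion: `dropout` scales both
#' depths to 20% of baseline (fails the depth window), `spike` scales both
#' to 10x (fails the depth window), `lowmq` halves the MQ60 depth only
#' (fails the MQ60/all ratio), `bqfail` marks the interval in the
#' base-quality fail mask.
#'
#' @param reference DNAStringSet or output list of [generateReference()].
#' @param clones A [CloneSet-class] or character vector of clone ids.
#' @param depth Baseline depth.
#' @param artifacts Optional data.frame with columns `chrom`, `start`, `end`
#'   (1-based closed), `type` in dropout/spike/lowmq/bqfail, and optionally
#'   `clone_id` (NA or absent = all clones). Overlapping artifacts are
#'   rejected.
#' @param dir Optional directory; when given, writes per-clone
#'   `<clone>.mq60.tsv` / `<clone>.all.tsv` (chrom, 1-based pos, depth) and
#'   `<clone>.bqfail.bed`.
#' @return Named list of [DepthProfile-class] objects, one per clone.
#' @export
simulateDepthTracks <- function(reference, clones, depth = 40,
                                artifacts = NULL, dir = NULL) {
  if (is.list(reference) && !is.null(reference$genome))
    reference <- reference$genome
  seqs <- .refChar(reference)
  clen <- nchar(seqs)
  ids <- if (methods::is(clones, "CloneSet")) cloneIds(clones)
         else as.character(clones)

  if (!is.null(artifacts)) {
    if (!"clone_id" %in% colnames(artifacts)) artifacts$clone_id <- NA
    for (cid in c(NA, ids)) {
      af <- artifacts[is.na(artifacts$clone_id) |
                      artifacts$clone_id %in% cid, , drop = FALSE]
      for (ch in unique(af$chrom)) {
        a <- af[af$chrom == ch, , drop = FALSE]
        if (nrow(a) > 1L) {
          o <- order(a$start)
          if (any(a$start[o][-1L] <= a$end[o][-nrow(a)]))
            stop("overlapping artifact intervals on ", ch)
        }
      }
    }
  }

  profiles <- lapply(ids, function(cid) {
    mq <- lapply(clen, function(L) rep(as.integer(depth), L))
    al <- lapply(clen, function(L) rep(as.integer(depth), L))
    bq <- lapply(clen, function(L) rep(TRUE, L))
    names(mq) <- names(al) <- names(bq) <- names(seqs)
    if (!is.null(artifacts)) {
      af <- artifacts[is.na(artifacts$clone_id) |
                      artifacts$clone_id == cid, , drop = FALSE]
      for (i in seq_len(nrow(af))) {
        ch <- af$chrom[i]; idx <- af$start[i]:af$end[i]
        switch(af$type[i],
          dropout = { mq[[ch]][idx] <- as.integer(round(0.2 * depth))
                      al[[ch]][idx] <- as.integer(round(0.2 * depth)) },
          spike = { mq[[ch]][idx] <- as.integer(10 * depth)
                    al[[ch]][idx] <- as.integer(10 * depth) },
          lowmq = { mq[[ch]][idx] <- as.integer(round(0.5 * depth)) },
          bqfail = { bq[[ch]][idx] <- FALSE },
          stop("unknown artifact type: ", af$type[i]))
      }
    }
    depthProfile(mq60 = mq, all = al, bq_pass = bq)
  })
  names(profiles) <- ids

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (cid in ids) {
      p <- profiles[[cid]]
      for (kind in c("mq60", "all")) {
        dt <- data.table::rbindlist(lapply(names(seqs), function(ch) {
          data.table::data.table(chrom = ch, pos = seq_len(clen[[ch]]),
                                 depth = slot(p, kind)[[ch]])
        }))
        data.table::fwrite(dt, file.path(dir, paste0(cid, ".", kind, ".tsv")),
                           sep = "\t", col.names = FALSE)
      }
      fail <- lapply(names(seqs), function(ch) {
        r <- !p@bq_pass[[ch]]
        if (!any(r)) return(NULL)
        ir <- IRanges(which(r))
        ir <- IRanges::reduce(ir)
        data.table::data.table(chrom = ch, start = IRanges::start(ir) - 1L,
                               end = IRanges::end(ir))
      })
      fail <- data.table::rbindlist(fail[!vapply(fail, is.null, logical(1))])
      bedpath <- file.path(dir, paste0(cid, ".bqfail.bed"))
      if (nrow(fail)) data.table::fwrite(fail, bedpath, sep = "\t",
                                         col.names = FALSE)
      else file.create(bedpath)
    }
  }
  profiles
}

#' Run the full simulator and write all artifacts to a directory
#'
#' Convenience wrapper: generates the reference, plants mutations, simulates
#' read support, writes FASTA, DMR/repeat BEDs, the multi-sample candidate
#' VCF, the truth table TSV, and a JSON manifest recording the seed and
#' specification.
#'
#' @param spec A [GenomeSpec-class].
#' @param design A [CloneDesign-class].
#' @param depth_mean,contamination Passed to [simulateReadSupport()].
#' @param outdir Output directory (created if missing).
#' @param write_tracks Also write per-clone depth tracks (large; off by
#'   default — [simulateDepthTracks()] returns in-memory profiles).
#' @return Invisibly, a list with `reference`, `truth`, `support` and the
#'   file paths written.
#' @export
simulateRun <- function(spec, design, depth_mean = 40, contamination = 0,
                        outdir, write_tracks = FALSE) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  ref <- generateReference(spec)
  truth <- plantMutations(ref, design, seed = spec@seed + 1L)
  support <- simulateReadSupport(truth, design@clones,
                                 depth_mean = depth_mean,
                                 contamination = contamination,
                                 seed = spec@seed + 2L)
  sl <- setNames(Biostrings::width(ref$genome), names(ref$genome))

  fa <- file.path(outdir, "reference.fa")
  Biostrings::writeXStringSet(ref$genome, fa, width = 60)
  dmr_bed <- file.path(outdir, "dmr.bed")
  rtracklayer::export(ref$dmr, dmr_bed, format = "BED")
  vcf <- file.path(outdir, "candidates.vcf")
  writeCandidateVcf(support, vcf, sl)
  truth_tsv <- file.path(outdir, "truth.tsv")
  data.table::fwrite(data.table::as.data.table(truth), truth_tsv, sep = "\t")
  clones_tsv <- file.path(outdir, "clones.tsv")
  data.table::fwrite(data.table::as.data.table(design@clones@clones),
                     clones_tsv, sep = "\t")

  tracks <- NULL
  if (write_tracks)
    tracks <- simulateDepthTracks(ref, design@clones, depth = depth_mean,
                                  dir = file.path(outdir, "tracks"))

  manifest <- list(
    tool = "somaticlone",
    version = as.character(utils::packageVersion("somaticlone")),
    seed = spec@seed,
    depth_mean = depth_mean,
    contamination = contamination,
    n_variants = nrow(truth),
    spec = list(n_chromosomes = spec@n_chromosomes,
                chrom_length = spec@chrom_length,
                gc_background = spec@gc_background,
                dmr_count = spec@dmr_count,
                dmr_length = spec@dmr_length,
                dmr_cpg_density = spec@dmr_cpg_density))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(reference = ref, truth = truth, support = support,
                 files = c(fasta = fa, dmr = dmr_bed, vcf = vcf,
                           truth = truth_tsv, clones = clones_tsv)))
}
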