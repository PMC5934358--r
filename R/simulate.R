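# Synthetic study generator with planted ground truth.
#
# Emulates the study design: a toy genome carrying box C/D and H/ACA snoRNA
# transcription units, a subset transcribed with 5' extensions that contain
# one planted AGNN stem-loop each; NET-seq 3'-end tracks with pileups at
# the planted cleavage points; WT versus rnt1-delta-like RNA-seq coverage
# where only Rnt1-dependent box C/D units gain short 3' extensions;
# circularized clone reads; and low/high-dNTP qPCR Ct tables with planted
# RT blockages. Every output is a pure function of the configuration seed,
# and generators write the same on-disk formats the real-data path reads.

#' Simulation configuration
#'
#' Category counts echo the genomic census of independently transcribed
#' yeast snoRNA (most box C/D are Rnt1-processed 5'-extended precursors,
#' most box H/ACA are capped). Coverage depth reflects that snoRNA are
#' among the most abundant Pol II transcripts; the mutant library scale
#' defaults to 1/1.73 so the realized WT-referenced normalization factor
#' is about 1.73.
#'
#' @param seed Integer master seed; fully determines every output.
#' @param n_cd_ext Box C/D genes with 5' extensions (Rnt1-dependent).
#' @param n_cd_noext Box C/D genes transcribed without 5' extension.
#' @param n_haca_capped Capped box H/ACA genes (no extension).
#' @param n_haca_ext Box H/ACA genes with Rnt1-cleaved 5' extensions.
#' @param n_polycistron Two-unit box C/D polycistronic TUs.
#' @param ext5_range 5'-extension length range (nt).
#' @param spacer_range Polycistron inter-unit spacer length range (nt).
#' @param mature_range Mature snoRNA length range (nt).
#' @param three_range Mature 3' end to terminator distance range (nt).
#' @param stem_range Planted hairpin stem length range (bp).
#' @param cleavage_distance Planted cleavage point, nt upstream of the 5'
#'   AGNN loop boundary.
#' @param gap Intergenic spacing (nt).
#' @param netseq_peak Planted NET-seq pileup height (reads).
#' @param netseq_bg Poisson background rate along transcribed regions.
#' @param depth_wt Mean WT per-base coverage over mature snoRNA.
#' @param mut_library_scale Global multiplier on mutant coverage depth.
#' @param overdispersion Gamma-Poisson overdispersion (0 = pure Poisson).
#' @param ext3_mut_range Planted mutant 3'-extension lengths (nt).
#' @param ext3_precursor_range 3'-extension range for WT precursor-focused
#'   clones (nt; capped by the terminator).
#' @param tailA_range Non-templated oligo(A) tail length range (nt).
#' @param clone_error_rate Per-base substitution rate in clone reads.
#' @param n_clones_ext,n_clones_mature Mutant-cohort clone counts
#'   (5'-extended with tails; 5'-mature with mature 3' ends).
#' @param n_clones_wt WT-cohort clone counts.
#' @param n_high_signal Capped H/ACA genes given outlier expression (the
#'   metagene exclusion use case).
#' @param high_signal_mult Expression multiplier for those genes.
#' @param ct_sigma Gaussian Ct noise (cycles).
#' @param qpcr_reps qPCR replicates per measurement.
#' @param qpcr_blockage Named list per condition of planted extra
#'   low-dNTP cycles for regions R1..R4 (reference R1 is 0).
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       n_cd_ext = 12L, n_cd_noext = 4L,
                       n_haca_capped = 15L, n_haca_ext = 6L,
                       n_polycistron = 2L,
                       ext5_range = c(30L, 120L),
                       spacer_range = c(45L, 80L),
                       mature_range = c(80L, 150L),
                       three_range = c(30L, 60L),
                       stem_range = c(12L, 16L),
                       cleavage_distance = 14L,
                       gap = 150L,
                       netseq_peak = 50, netseq_bg = 1,
                       depth_wt = 800, mut_library_scale = 1 / 1.73,
                       overdispersion = 0,
                       ext3_mut_range = c(2L, 10L),
                       ext3_precursor_range = c(2L, 100L),
                       tailA_range = c(1L, 10L),
                       clone_error_rate = 0,
                       n_clones_ext = 20L, n_clones_mature = 5L,
                       n_clones_wt = 10L,
                       n_high_signal = 2L, high_signal_mult = 8,
                       ct_sigma = 0.15, qpcr_reps = 3L,
                       qpcr_blockage = list(
                         WT = c(R1 = 0, R2 = 2.0, R3 = 2.0, R4 = 6.8),
                         rnt1d = c(R1 = 0, R2 = 0.36, R3 = 0.36,
                                   R4 = 1.7))) {
  cfg <- as.list(environment())
  stopifnot(ext5_range[1L] <= ext5_range[2L],
            stem_range[1L] <= stem_range[2L],
            ext5_range[1L] >= 2L * stem_range[1L] + 6L,
            mature_range[1L] >= 30L,
            cleavage_distance >= 1L)
  class(cfg) <- "sim_config"
  cfg
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Plant one AGNN hairpin inside a random extension of length e; returns the
# extension string plus the hairpin's coordinates (0-based, relative to the
# extension start). Rejection-sampled so the scan region (extension plus
# `overhang` nt of downstream sequence) contains exactly the planted
# hairpin, recovered with its exact coordinates and stem length.
.plant_extension <- function(e, downstream, cfg,
                             params = hairpin_params(), overhang = 5L) {
  smax <- min(cfg$stem_range[2L], (e - 4L - 2L) %/% 2L)
  smin <- cfg$stem_range[1L]
  if (smax < smin) stop("extension too short for the stem range")
  for (try in 1:400) {
    s <- sample(smin:smax, 1L)
    a_lo <- max(2L, cfg$cleavage_distance - s)
    a_hi <- e - 2L * s - 4L
    if (a_hi < a_lo) next
    a <- if (a_hi == a_lo) a_lo else sample(a_lo:a_hi, 1L)
    arm5 <- .rand_dna(s)
    loop <- paste0("AG", .rand_dna(2L))
    arm3 <- revcomp(arm5)
    # turn up to two Watson-Crick pairs into G.T wobbles
    gpos <- which(strsplit(arm5, "")[[1L]] == "G")
    nw <- min(sample(0:2, 1L), length(gpos))
    if (nw > 0L) {
      a3 <- strsplit(arm3, "")[[1L]]
      for (g in sample(gpos, nw)) a3[s - g + 1L] <- "T"
      arm3 <- paste(a3, collapse = "")
    }
    hp <- paste0(arm5, loop, arm3)
    left <- if (a > 0L) .rand_dna(a) else ""
    right_len <- e - a - nchar(hp)
    right <- if (right_len > 0L) .rand_dna(right_len) else ""
    ext <- paste0(left, hp, right)
    scan <- paste0(ext, substr(downstream, 1L, overhang))
    found <- find_hairpins(scan, params)
    loop_start <- a + s
    if (nrow(found) == 1L && found$loop_start == loop_start &&
        found$stem_len == s) {
      return(list(seq = ext, loop_start = loop_start,
                  loop_end = loop_start + 4L, stem_len = s,
                  n_wobble = found$n_wobble))
    }
  }
  stop("failed to plant a clean hairpin after 400 tries")
}

# extension/spacer without any hairpin in the scan region
.clean_region <- function(n, downstream, params = hairpin_params(),
                          overhang = 5L) {
  for (try in 1:400) {
    s <- .rand_dna(n)
    if (nrow(find_hairpins(paste0(s, substr(downstream, 1L, overhang)),
                           params)) == 0L) {
      return(s)
    }
  }
  stop("failed to draw a hairpin-free region")
}

#' Generate the toy genome and gene table with planted ground truth
#'
#' Transcription units are laid down on one chromosome, alternating
#' strands, separated by \code{cfg$gap} nt of random sequence.
#' Extension-bearing units carry exactly one planted AGNN hairpin per
#' extension (polycistrons one per unit: in the leading extension and in
#' the inter-unit spacer); extensions are rejection-sampled so they
#' contain no other hairpin at default scanner parameters. Accidental
#' hairpins elsewhere in the genome are left in place as specificity
#' decoys.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return list with \code{genome} (named character), \code{genes}
#'   (\code{sno_genes}), and \code{truth} (per-gene data.frame of planted
#'   hairpin/cleavage coordinates, extension status, mutant 3'-extension
#'   lengths, expression multipliers).
#' @export
gen_genome_and_genes <- function(cfg) {
  set.seed(cfg$seed)
  params <- hairpin_params()
  ri <- function(rg) if (rg[1L] == rg[2L]) rg[1L] else sample(rg[1L]:rg[2L], 1L)

  units <- list()   # per annotation row
  tus <- list()     # per transcription unit: tu string + row indices
  add_tu <- function(tu_seq, rows) {
    tus[[length(tus) + 1L]] <<- list(seq = tu_seq, rows = rows)
  }
  categories <- c(rep("cd_ext", cfg$n_cd_ext),
                  rep("cd_noext", cfg$n_cd_noext),
                  rep("haca_capped", cfg$n_haca_capped),
                  rep("haca_ext", cfg$n_haca_ext),
                  rep("polycistron", cfg$n_polycistron))
  counters <- c(cd_ext = 0L, cd_noext = 0L, haca_capped = 0L,
                haca_ext = 0L, polycistron = 0L)
  high_left <- cfg$n_high_signal

  for (cat in categories) {
    counters[[cat]] <- counters[[cat]] + 1L
    idx <- counters[[cat]]
    if (cat == "polycistron") {
      pc_id <- sprintf("pc%02d", idx)
      m1 <- ri(cfg$mature_range); m2 <- ri(cfg$mature_range)
      th <- ri(cfg$three_range)
      e1 <- ri(cfg$ext5_range); sp <- ri(cfg$spacer_range)
      mat1 <- .rand_dna(m1); mat2 <- .rand_dna(m2)
      three <- .rand_dna(th)
      p1 <- .plant_extension(e1, mat1, cfg, params)
      p2 <- .plant_extension(sp, mat2, cfg, params)
      tu_seq <- paste0(p1$seq, mat1, p2$seq, mat2, three)
      ext3 <- ri(cfg$ext3_mut_range)
      rowA <- list(gene_id = paste0(pc_id, ".1"), class = "CD",
                   category = cat, u0 = 0L, ext = e1, mat = m1,
                   hairpin = p1, polycistron_id = pc_id, rank = 1L,
                   rd_3prime = TRUE, ext3_mut = NA_integer_,
                   expr_mult = 1, high_signal = FALSE)
      rowB <- list(gene_id = paste0(pc_id, ".2"), class = "CD",
                   category = cat, u0 = e1 + m1, ext = sp, mat = m2,
                   hairpin = p2, polycistron_id = pc_id, rank = 2L,
                   rd_3prime = TRUE, ext3_mut = ext3,
                   expr_mult = 1, high_signal = FALSE)
      add_tu(tu_seq, list(rowA, rowB))
    } else {
      cls <- if (startsWith(cat, "cd")) "CD" else "HACA"
      m <- ri(cfg$mature_range); th <- ri(cfg$three_range)
      mat <- .rand_dna(m); three <- .rand_dna(th)
      has_ext <- cat %in% c("cd_ext", "haca_ext")
      e <- if (has_ext) ri(cfg$ext5_range) else 0L
      hp <- NULL
      ext_seq <- ""
      if (has_ext) {
        hp <- .plant_extension(e, mat, cfg, params)
        ext_seq <- hp$seq
      }
      expr <- 1; high <- FALSE
      if (cat == "haca_capped" && high_left > 0L) {
        expr <- cfg$high_signal_mult; high <- TRUE
        high_left <- high_left - 1L
      }
      rd <- cat == "cd_ext"
      row <- list(gene_id = sprintf("%s%02d", cat, idx), class = cls,
                  category = cat, u0 = 0L, ext = e, mat = m,
                  hairpin = hp, polycistron_id = NA_character_,
                  rank = NA_integer_, rd_3prime = rd,
                  ext3_mut = if (rd) ri(cfg$ext3_mut_range) else
                    NA_integer_,
                  expr_mult = expr, high_signal = high)
      add_tu(paste0(ext_seq, mat, three), list(row))
    }
  }

  # lay transcription units on one chromosome, alternating strands
  chrom <- "chrS"
  pieces <- list(.rand_dna(cfg$gap))
  offset <- cfg$gap
  gene_rows <- list()
  truth_rows <- list()
  strand_i <- 0L
  for (tu in tus) {
    strand <- if (strand_i %% 2L == 0L) "+" else "-"
    strand_i <- strand_i + 1L
    len <- nchar(tu$seq)
    pieces[[length(pieces) + 1L]] <-
      if (strand == "+") tu$seq else revcomp(tu$seq)
    tu_off <- offset
    offset <- offset + len
    pieces[[length(pieces) + 1L]] <- .rand_dna(cfg$gap)
    offset <- offset + cfg$gap
    for (u in tu$rows) {
      if (strand == "+") {
        tss <- tu_off + u$u0
        mstart <- tss + u$ext
        mend <- mstart + u$mat
        term <- tu_off + len
      } else {
        tss <- tu_off + len - u$u0
        mend <- tss - u$ext
        mstart <- mend - u$mat
        term <- tu_off
      }
      grow <- data.frame(gene_id = u$gene_id, chrom = chrom,
                         strand = strand, class = u$class,
                         tss = tss, mature_start = mstart,
                         mature_end = mend, terminator_end = term,
                         polycistron_id = u$polycistron_id,
                         polycistron_rank = u$rank,
                         stringsAsFactors = FALSE)
      gene_rows[[length(gene_rows) + 1L]] <- grow
      hp <- u$hairpin
      if (!is.null(hp)) {
        g1 <- if (strand == "+") tss + hp$loop_start else
          tss - 1L - (hp$loop_end - 1L)
        cup_t <- hp$loop_start - cfg$cleavage_distance
        cdn_t <- hp$loop_end - 1L + cfg$cleavage_distance
        cup_g <- if (strand == "+") tss + cup_t else tss - 1L - cup_t
        cdn_g <- if (strand == "+") tss + cdn_t else tss - 1L - cdn_t
      }
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        gene_id = u$gene_id, category = u$category, class = u$class,
        has_rcs = !is.null(hp),
        loop_start_t = if (is.null(hp)) NA_integer_ else hp$loop_start,
        loop_end_t = if (is.null(hp)) NA_integer_ else hp$loop_end,
        stem_len = if (is.null(hp)) NA_integer_ else hp$stem_len,
        loop_gstart = if (is.null(hp)) NA_integer_ else g1,
        loop_gend = if (is.null(hp)) NA_integer_ else g1 + 4L,
        cleave_up_t = if (is.null(hp)) NA_integer_ else cup_t,
        cleave_up_g = if (is.null(hp)) NA_integer_ else cup_g,
        cleave_down_g = if (is.null(hp)) NA_integer_ else cdn_g,
        ext5_len = u$ext,
        rd_3prime = u$rd_3prime, ext3_mut = u$ext3_mut,
        expr_mult = u$expr_mult, high_signal = u$high_signal,
        stringsAsFactors = FALSE)
    }
  }
  genome <- stats::setNames(paste(unlist(pieces), collapse = ""), chrom)
  genes <- if (length(gene_rows)) as_sno_genes(do.call(rbind, gene_rows))
  else as_sno_genes(data.frame(gene_id = character(),
                               chrom = character(), strand = character(),
                               class = character(), tss = integer(),
                               mature_start = integer(),
                               mature_end = integer(),
                               terminator_end = integer()))
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else NULL
  list(genome = genome, genes = genes, truth = truth)
}

# truth rows grouped into transcription units (shared coverage spans)
.tu_groups <- function(genes) {
  key <- ifelse(is.na(genes$polycistron_id), genes$gene_id,
                genes$polycistron_id)
  split(seq_len(nrow(genes)), factor(key, levels = unique(key)))
}

.add_noise <- function(lambda, n, overdispersion) {
  if (lambda <= 0) return(numeric(n))
  if (overdispersion > 0) {
    shape <- 1 / overdispersion
    lam <- stats::rgamma(n, shape = shape, rate = shape / lambda)
    stats::rpois(n, lam)
  } else {
    stats::rpois(n, lambda)
  }
}

#' Generate a NET-seq 3'-end track
#'
#' Poisson background along every transcribed region plus a pileup of
#' \code{cfg$netseq_peak} reads at each planted upstream cleavage point of
#' extension-bearing genes. Genes without 5' extensions receive no pileup.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param sim Output of \code{\link{gen_genome_and_genes}}.
#' @return A \code{basetrack} of kind \code{netseq_3prime_ends}.
#' @export
gen_netseq <- function(cfg, sim) {
  set.seed(cfg$seed + 1L)
  genes <- sim$genes; truth <- sim$truth
  track <- new_track(stats::setNames(nchar(sim$genome), names(sim$genome)),
                     "netseq_3prime_ends")
  for (rows in .tu_groups(genes)) {
    g <- genes[rows[1L], ]
    last <- genes[rows[length(rows)], ]
    span <- if (g$strand == "+") c(g$tss, last$terminator_end)
    else c(last$terminator_end, g$tss)
    key <- .track_key(g$chrom, g$strand)
    idx <- (span[1L] + 1L):span[2L]
    track$counts[[key]][idx] <- track$counts[[key]][idx] +
      .add_noise(cfg$netseq_bg, length(idx), cfg$overdispersion)
  }
  if (is.null(truth)) return(track)
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    if (!tr$has_rcs) next
    g <- genes[genes$gene_id == tr$gene_id, ]
    key <- .track_key(g$chrom, g$strand)
    track$counts[[key]][tr$cleave_up_g + 1L] <-
      track$counts[[key]][tr$cleave_up_g + 1L] + cfg$netseq_peak
  }
  track
}

#' Generate an RNA-seq coverage track for one condition
#'
#' WT: per-base Poisson coverage over mature snoRNA spans only. Mutant
#' (rnt1-delta-like): full unprocessed precursors over Rnt1-dependent
#' box C/D units (5' extension through the planted 3' extension of
#' +2..+10 nt past the mature end), 5'-extended but 3'-mature precursors
#' over extension-bearing H/ACA units, mature-only coverage elsewhere;
#' the whole library is scaled by \code{cfg$mut_library_scale}.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param sim Output of \code{\link{gen_genome_and_genes}}.
#' @param condition \code{"WT"} or \code{"mutant"}.
#' @return A \code{basetrack} of kind \code{coverage}.
#' @export
gen_rnaseq <- function(cfg, sim, condition = c("WT", "mutant")) {
  condition <- match.arg(condition)
  set.seed(cfg$seed + if (condition == "WT") 2L else 3L)
  genes <- sim$genes; truth <- sim$truth
  depth <- if (condition == "WT") cfg$depth_wt
  else cfg$depth_wt * cfg$mut_library_scale
  track <- new_track(stats::setNames(nchar(sim$genome), names(sim$genome)),
                     "coverage")
  cover <- function(gene, t0, t1, lambda) {
    if (t1 <= t0) return()
    w <- tx_window_g(gene, t0, t1)
    key <- .track_key(gene$chrom, gene$strand)
    idx <- (w[1L] + 1L):w[2L]
    track$counts[[key]][idx] <<- track$counts[[key]][idx] +
      .add_noise(lambda, length(idx), cfg$overdispersion)
  }
  for (rows in .tu_groups(genes)) {
    first <- genes[rows[1L], ]
    tr_first <- truth[truth$gene_id == first$gene_id, ]
    lam <- depth * tr_first$expr_mult
    if (condition == "WT" || !tr_first$rd_3prime &&
        tr_first$ext5_len == 0L) {
      for (i in rows) {
        g <- genes[i, ]
        cover(g, ext5_len(g), mature_end_t(g), lam)
      }
    } else if (tr_first$rd_3prime) {
      # uncleaved precursor: TSS of the first unit through the planted 3'
      # extension past the last unit's mature end
      last <- genes[rows[length(rows)], ]
      tr_last <- truth[truth$gene_id == last$gene_id, ]
      ext3 <- tr_last$ext3_mut
      # coordinates in the first unit's transcript frame
      end_t <- if (first$strand == "+") {
        (last$mature_end - first$tss) + ext3
      } else {
        (first$tss - last$mature_start) + ext3
      }
      cover(first, 0L, end_t, lam)
    } else {
      # extension-bearing H/ACA: 5'-extended precursor, mature 3' end
      for (i in rows) {
        g <- genes[i, ]
        cover(g, 0L, mature_end_t(g), lam)
      }
    }
  }
  track
}

.random_cut <- function(lo, hi) if (hi <= lo) lo else sample(lo:(hi - 1L), 1L)

.mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

#' Generate circularized clone reads for one gene
#'
#' Each clone is a molecule \code{T[s,e) + A^tail} circularly permuted at
#' a random point inside its mature portion, optionally with substitution
#' errors. Ground-truth calls are stored in canonical junction form (see
#' \code{\link{canonicalize_junction}}).
#'
#' Cohorts: \code{"wt"} (5'- and 3'-mature molecules), \code{"mutant"}
#' (\code{n_clones_ext} 5'-extended molecules with short templated 3'
#' extensions and oligo(A) tails plus \code{n_clones_mature} fully mature
#' molecules), \code{"wt_precursor"} (5'-extended molecules with 3'
#' extensions from 2 nt up to the terminator, no tails — the
#' precursor-focused primer design).
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param sim Output of \code{\link{gen_genome_and_genes}}.
#' @param condition Cohort; see Details.
#' @param gene_id Target gene; default: the first Rnt1-dependent box C/D
#'   gene.
#' @return list with \code{clones} (named character vector) and
#'   \code{truth} (data.frame: canonical \code{five_offset, ext3_len,
#'   tailA_len} per clone).
#' @export
gen_clones <- function(cfg, sim, condition = c("wt", "mutant",
                                               "wt_precursor"),
                       gene_id = NULL) {
  condition <- match.arg(condition)
  set.seed(cfg$seed + switch(condition, wt = 4L, mutant = 5L,
                             wt_precursor = 6L))
  genes <- sim$genes
  if (is.null(gene_id)) {
    gene_id <- sim$truth$gene_id[sim$truth$category == "cd_ext"][1L]
  }
  gene <- genes[genes$gene_id == gene_id, ]
  txs <- transcript_seq(sim$genome, gene)
  n <- nchar(txs)
  mstart <- ext5_len(gene); mend <- mature_end_t(gene)
  ri <- function(rg) if (rg[1L] >= rg[2L]) rg[1L] else
    sample(rg[1L]:rg[2L], 1L)

  spec <- switch(condition,
    wt = data.frame(kind = rep("mature", cfg$n_clones_wt)),
    mutant = data.frame(kind = c(rep("extended", cfg$n_clones_ext),
                                 rep("mature", cfg$n_clones_mature))),
    wt_precursor = data.frame(kind = rep("precursor", cfg$n_clones_wt)))
  clones <- character(nrow(spec))
  names(clones) <- sprintf("%s_%s_clone%02d", gene_id, condition,
                           seq_len(nrow(spec)))
  truth_rows <- vector("list", nrow(spec))
  for (i in seq_len(nrow(spec))) {
    kind <- spec$kind[i]
    if (kind == "mature") {
      s <- mstart; e <- mend; tail <- 0L
    } else if (kind == "extended") {
      s <- .random_cut(0L, max(1L, mstart - 20L) + 1L)
      e <- mend + min(ri(cfg$ext3_mut_range), n - mend)
      tail <- ri(cfg$tailA_range)
    } else {                               # precursor
      s <- .random_cut(0L, max(1L, mstart - 20L) + 1L)
      e <- mend + min(ri(cfg$ext3_precursor_range), n - mend)
      tail <- 0L
    }
    molecule <- paste0(substr(txs, s + 1L, e), strrep("A", tail))
    L <- nchar(molecule)
    cut_lo <- (mstart - s) + 15L
    cut_hi <- mend - s
    cut <- .random_cut(cut_lo, cut_hi)
    read <- paste0(substr(molecule, cut + 1L, L),
                   substr(molecule, 1L, cut))
    read <- .mutate_seq(read, cfg$clone_error_rate)
    clones[[i]] <- read
    canon <- canonicalize_junction(txs, s, e, tail, prefer = mstart)
    truth_rows[[i]] <- data.frame(
      clone_id = names(clones)[i], kind = kind,
      five_offset = canon$s - mstart,
      ext3_len = canon$e - mend, tailA_len = canon$tail,
      stringsAsFactors = FALSE)
  }
  list(clones = clones, truth = do.call(rbind, truth_rows))
}

#' Generate a low/high-dNTP qPCR Ct table with planted blockages
#'
#' High-dNTP Ct is a per-(region, condition) baseline plus Gaussian noise;
#' low-dNTP Ct adds the planted blockage (extra cycles). The reference
#' region R1 has blockage 0 in every condition.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return list with \code{table} (data.frame: region, condition,
#'   dntp_level, replicate, ct) and \code{truth} (planted blockage per
#'   region and condition).
#' @export
gen_qpcr <- function(cfg) {
  set.seed(cfg$seed + 7L)
  rows <- list()
  truth <- list()
  for (cond in names(cfg$qpcr_blockage)) {
    b <- cfg$qpcr_blockage[[cond]]
    for (rg in names(b)) {
      base <- stats::runif(1L, 15, 20)
      for (rep_i in seq_len(cfg$qpcr_reps)) {
        rows[[length(rows) + 1L]] <- data.frame(
          region = rg, condition = cond, dntp_level = "high",
          replicate = rep_i,
          ct = base + stats::rnorm(1L, 0, cfg$ct_sigma),
          stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          region = rg, condition = cond, dntp_level = "low",
          replicate = rep_i,
          ct = base + b[[rg]] + stats::rnorm(1L, 0, cfg$ct_sigma),
          stringsAsFactors = FALSE)
      }
      truth[[length(truth) + 1L]] <- data.frame(
        region = rg, condition = cond, blockage = b[[rg]],
        stringsAsFactors = FALSE)
    }
  }
  list(table = do.call(rbind, rows), truth = do.call(rbind, truth))
}

#' Write a complete synthetic dataset to disk
#'
#' Emits the on-disk formats the analysis functions read: genome FASTA,
#' gene TSV, strand-split bedGraph pairs for NET-seq and both RNA-seq
#' conditions, clone FASTA cohorts, the qPCR CSV and a JSON ground-truth
#' sidecar. Byte-identical across runs with the same configuration.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with every in-memory object (\code{sim},
#'   tracks, clone cohorts, qPCR table) and the file paths.
#' @export
simulate_dataset <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, paste0(...))
  sim <- gen_genome_and_genes(cfg)
  write_genome(sim$genome, p("genome.fa"))
  write_genes(sim$genes, p("genes.tsv"))
  netseq <- gen_netseq(cfg, sim)
  write_bedgraph(netseq, "+", p("netseq.plus.bedgraph"))
  write_bedgraph(netseq, "-", p("netseq.minus.bedgraph"))
  wt <- gen_rnaseq(cfg, sim, "WT")
  mut <- gen_rnaseq(cfg, sim, "mutant")
  write_bedgraph(wt, "+", p("rnaseq.wt.plus.bedgraph"))
  write_bedgraph(wt, "-", p("rnaseq.wt.minus.bedgraph"))
  write_bedgraph(mut, "+", p("rnaseq.mut.plus.bedgraph"))
  write_bedgraph(mut, "-", p("rnaseq.mut.minus.bedgraph"))
  clones_wt <- gen_clones(cfg, sim, "wt")
  clones_mut <- gen_clones(cfg, sim, "mutant")
  clones_pre <- gen_clones(cfg, sim, "wt_precursor")
  wfa <- function(x, path) {
    Biostrings::writeXStringSet(Biostrings::BStringSet(x), path)
  }
  wfa(clones_wt$clones, p("clones.wt.fa"))
  wfa(clones_mut$clones, p("clones.mut.fa"))
  wfa(clones_pre$clones, p("clones.wt_precursor.fa"))
  qpcr <- gen_qpcr(cfg)
  utils::write.csv(qpcr$table, p("qpcr.csv"), row.names = FALSE,
                   quote = FALSE)
  truth <- list(genes = sim$truth, clones_wt = clones_wt$truth,
                clones_mut = clones_mut$truth,
                clones_wt_precursor = clones_pre$truth,
                qpcr = qpcr$truth)
  jsonlite::write_json(truth, p("truth.json"), dataframe = "rows",
                       digits = NA, pretty = TRUE)
  invisible(list(sim = sim, netseq = netseq, wt = wt, mut = mut,
                 clones = list(wt = clones_wt, mutant = clones_mut,
                               wt_precursor = clones_pre),
                 qpcr = qpcr, dir = dir))
}
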