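# NET-seq / RNA-seq signal analysis: 5' extension detection, NET-seq peak
# co-localization with predicted Rnt1 cleavage structures, loop-anchored
# and mature-3'-end-anchored metagene profiles, and per-gene 3'-extension
# classification with the WT-referenced normalization factor.

#' Detect a 5'-extended precursor from coverage
#'
#' Compares mutant versus WT coverage over the annotated 5' extension
#' after library-size scaling. The gene is called extended in the mutant
#' when the per-base mutant/WT ratio is at least \code{min_ratio} over at
#' least \code{min_len} contiguous nucleotides.
#'
#' @param gene One-row \code{sno_genes} data.frame.
#' @param wt_cov,mut_cov Coverage \code{basetrack}s.
#' @param min_ratio Minimum per-base mutant/WT coverage ratio.
#' @param min_len Minimum contiguous run (nt) above the ratio.
#' @param pseudocount Added to the WT denominator.
#' @return list with \code{extended_in_mut}, \code{est_extension_len} and,
#'   when no extension is annotated, a \code{reason}.
#' @export
detect_five_prime_extension <- function(gene, wt_cov, mut_cov,
                                        min_ratio = 3, min_len = 10L,
                                        pseudocount = 0.5) {
  if (wt_cov$kind != "coverage" || mut_cov$kind != "coverage") {
    stop("detect_five_prime_extension needs coverage tracks")
  }
  e5 <- ext5_len(gene)
  if (e5 <= 0L) {
    return(list(extended_in_mut = FALSE, est_extension_len = 0L,
                reason = "no 5' extension annotated"))
  }
  wt <- tx_values(wt_cov, gene, 0L, e5)
  mut <- tx_values(mut_cov, gene, 0L, e5)
  scale <- track_total(wt_cov) / max(track_total(mut_cov), 1e-12)
  ratio <- (mut * scale) / (wt + pseudocount)
  r <- rle(ratio >= min_ratio)
  runs <- r$lengths[r$values]
  longest <- if (length(runs)) max(runs) else 0L
  list(extended_in_mut = longest >= min_len,
       est_extension_len = as.integer(longest))
}

#' Co-localize a predicted cleavage structure with NET-seq 3' ends
#'
#' Searches the sense-strand NET-seq 3'-end counts in a window of
#' \code{w} nt around the AGNN loop (which covers both hairpin arms) for
#' its maximum, and compares that peak with the gene-body background
#' (median count over the transcribed region excluding the window).
#'
#' @param rcs One-row prediction from \code{\link{predict_rcs}}.
#' @param gene The corresponding one-row \code{sno_genes} data.frame.
#' @param netseq A \code{basetrack} of kind \code{netseq_3prime_ends}.
#' @param w Half-window in nt around the loop.
#' @param min_peak Minimum window maximum (reads) to call support.
#' @param min_enrichment Minimum peak/background ratio.
#' @param pseudocount Floor of the background denominator.
#' @return One-row data.frame: \code{rcs_id, peak_t, peak_offset} (peak
#'   position minus the 5' loop boundary; cleavage upstream of the loop
#'   gives negative offsets), \code{peak_count, background, enrichment,
#'   is_colocalized}.
#' @export
colocalize_rcs <- function(rcs, gene, netseq, w = 25L, min_peak = 10,
                           min_enrichment = 5, pseudocount = 0.5) {
  if (netseq$kind != "netseq_3prime_ends") {
    stop("colocalize_rcs needs a netseq_3prime_ends track")
  }
  txl <- tx_len(gene)
  w0 <- max(0L, rcs$loop_start_t - w)
  w1 <- min(txl, rcs$loop_end_t + w)
  vals <- tx_values(netseq, gene, w0, w1)
  peak_i <- which.max(vals)                 # deterministic: first maximum
  peak_t <- w0 + peak_i - 1L
  peak_count <- vals[peak_i]
  body <- tx_values(netseq, gene, 0L, txl)
  keep <- rep(TRUE, txl)
  keep[(w0 + 1L):w1] <- FALSE
  background <- if (any(keep)) stats::median(body[keep]) else 0
  enrichment <- peak_count / max(background, pseudocount)
  data.frame(rcs_id = rcs$rcs_id, gene_id = rcs$gene_id,
             peak_t = peak_t,
             peak_offset = peak_t - rcs$loop_start_t,
             peak_count = peak_count, background = background,
             enrichment = enrichment,
             is_colocalized = peak_count >= min_peak &
               enrichment >= min_enrichment,
             stringsAsFactors = FALSE)
}

#' Co-localize every predicted cleavage structure
#'
#' @param rcs data.frame from \code{\link{predict_rcs_all}}.
#' @param genes A \code{sno_genes} data.frame containing every
#'   \code{gene_id} in \code{rcs}.
#' @inheritParams colocalize_rcs
#' @return data.frame, one row per RCS.
#' @export
colocalize_rcs_all <- function(rcs, genes, netseq, ...) {
  rows <- lapply(seq_len(nrow(rcs)), function(i) {
    gene <- genes[genes$gene_id == rcs$gene_id[i], ]
    colocalize_rcs(rcs[i, ], gene, netseq, ...)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(rcs_id = character(), gene_id = character(),
                      peak_t = integer(), peak_offset = integer(),
                      peak_count = numeric(), background = numeric(),
                      enrichment = numeric(), is_colocalized = logical(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Loop-anchored NET-seq metagene
#'
#' Averages library-normalized (counts per million) NET-seq 3'-end signal
#' across cleavage structures, anchored at the 5' boundary of the AGNN
#' loop (offset 0). Sense and antisense signal are kept separate and never
#' mixed.
#'
#' @param rcs data.frame from \code{\link{predict_rcs_all}}.
#' @param genes A \code{sno_genes} data.frame.
#' @param netseq A \code{basetrack} of kind \code{netseq_3prime_ends}.
#' @param w Half-window in nt.
#' @return Object of class \code{metagene_profile}: \code{offsets},
#'   \code{mean} (list with \code{sense}, \code{antisense}),
#'   \code{n_genes}, \code{anchor}.
#' @export
metagene_5prime <- function(rcs, genes, netseq, w = 25L) {
  if (nrow(rcs) == 0L) stop("metagene_5prime needs at least one RCS")
  offsets <- seq.int(-w, w)
  cpm <- 1e6 / max(track_total(netseq), 1e-12)
  row_for <- function(i, sense) {
    gene <- genes[genes$gene_id == rcs$gene_id[i], ]
    anchor <- rcs$loop_start_t[i]
    t0 <- anchor - w; t1 <- anchor + w + 1L
    txl <- tx_len(gene)
    v <- numeric(length(offsets))
    lo <- max(t0, 0L); hi <- min(t1, txl)
    if (hi > lo) {
      v[(lo - t0 + 1L):(hi - t0)] <- tx_values(netseq, gene, lo, hi, sense)
    }
    v * cpm
  }
  sense_mat <- t(vapply(seq_len(nrow(rcs)), row_for, numeric(length(offsets)),
                        sense = TRUE))
  anti_mat <- t(vapply(seq_len(nrow(rcs)), row_for, numeric(length(offsets)),
                       sense = FALSE))
  structure(list(anchor = "agnn_loop", offsets = offsets,
                 mean = list(sense = colMeans(sense_mat),
                             antisense = colMeans(anti_mat)),
                 matrix = list(sense = sense_mat, antisense = anti_mat),
                 n_genes = nrow(rcs), norm_factor = 1,
                 excluded_genes = character()),
            class = "metagene_profile")
}

# transcript-coordinate positions of the 3'-anchored window; offset 0 is
# the last mature (coding) base, positive offsets are the 3' extension.
.anchor3_row <- function(track, gene, offsets) {
  a <- mature_end_t(gene) - 1L
  t0 <- a + offsets[1L]; t1 <- a + offsets[length(offsets)] + 1L
  txl <- tx_len(gene)
  v <- numeric(length(offsets))
  lo <- max(t0, 0L); hi <- min(t1, txl)
  if (hi > lo) v[(lo - t0 + 1L):(hi - t0)] <- tx_values(track, gene, lo, hi)
  v
}

#' Mature-3'-end-anchored coverage metagene with WT normalization
#'
#' Builds per-gene coverage rows around the annotated mature 3' end
#' (offset 0 = last coding base) for both conditions, removes excluded
#' genes before averaging, and rescales the mutant rows by the
#' normalization factor: mean WT coverage over the last \code{ref_width}
#' coding nucleotides divided by the mean mutant coverage over the same
#' window. The factor is always computed from the data, never assumed.
#'
#' @param genes A \code{sno_genes} data.frame (one cohort/class).
#' @param wt_cov,mut_cov Coverage \code{basetrack}s.
#' @param window Integer length-2: offset range around the anchor.
#' @param exclude Character vector of gene_ids to drop before averaging
#'   (for genes with outlier signal).
#' @param ref_width Width (nt) of the reference window at the 3' end of
#'   the coding sequence.
#' @return \code{metagene_profile} with \code{mean$wt},
#'   \code{mean$mut} (normalized), \code{norm_factor}, \code{n_genes},
#'   \code{excluded_genes}.
#' @export
metagene_3prime <- function(genes, wt_cov, mut_cov, window = c(-30L, 30L),
                            exclude = character(), ref_width = 6L) {
  keep <- !genes$gene_id %in% exclude
  genes <- genes[keep, , drop = FALSE]
  if (nrow(genes) == 0L) stop("no genes left after exclusions")
  offsets <- seq.int(window[1L], window[2L])
  wt_mat <- t(vapply(seq_len(nrow(genes)), function(i)
    .anchor3_row(wt_cov, genes[i, ], offsets), numeric(length(offsets))))
  mut_mat <- t(vapply(seq_len(nrow(genes)), function(i)
    .anchor3_row(mut_cov, genes[i, ], offsets), numeric(length(offsets))))
  ref_cols <- which(offsets >= -(ref_width - 1L) & offsets <= 0L)
  wt_ref <- mean(wt_mat[, ref_cols])
  mut_ref <- mean(mut_mat[, ref_cols])
  if (mut_ref <= 0) stop("normalization undefined: no mutant signal over ",
                         "the reference window")
  norm_factor <- wt_ref / mut_ref
  structure(list(anchor = "mature_3prime_end", offsets = offsets,
                 mean = list(wt = colMeans(wt_mat),
                             mut = colMeans(mut_mat) * norm_factor),
                 matrix = list(wt = wt_mat, mut = mut_mat),
                 n_genes = nrow(genes), norm_factor = norm_factor,
                 excluded_genes = exclude),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat("metagene_profile anchored at", x$anchor, "\n")
  cat("  offsets:", x$offsets[1L], "..", x$offsets[length(x$offsets)],
      " n_genes:", x$n_genes, "\n")
  if (!is.null(x$norm_factor)) {
    cat("  norm_factor:", format(x$norm_factor, digits = 4), "\n")
  }
  invisible(x)
}

#' Classify a gene as 3'-extended in the mutant
#'
#' The extension signal is the mean mutant coverage (rescaled by
#' \code{norm_factor}) over the \code{L} nucleotides downstream of the
#' mature 3' end. The gene is called extended when that signal is at
#' least \code{floor} times the WT coding-body signal (last
#' \code{ref_width} coding nt) and at least \code{ratio_min} times the WT
#' signal over the same extension window (pseudocount in the
#' denominator).
#'
#' @param gene One-row \code{sno_genes} data.frame.
#' @param wt_cov,mut_cov Coverage \code{basetrack}s.
#' @param norm_factor Mutant rescaling factor, normally taken from
#'   \code{\link{metagene_3prime}}.
#' @param L Extension window length (nt).
#' @param ratio_min Minimum mutant/WT ratio over the extension window.
#' @param floor Minimum extension signal as a fraction of body signal.
#' @param pseudocount Added to the WT denominator.
#' @param ref_width Body reference window width (nt).
#' @return One-row data.frame: \code{gene_id, ext_signal, body_signal,
#'   wt_ext_signal, extended}.
#' @export
classify_three_prime_extension <- function(gene, wt_cov, mut_cov,
                                           norm_factor = 1, L = 15L,
                                           ratio_min = 3, floor = 0.1,
                                           pseudocount = 0.5,
                                           ref_width = 6L) {
  a <- mature_end_t(gene)
  txl <- tx_len(gene)
  hi <- min(a + L, txl)
  ext_win <- if (hi > a) c(a, hi) else NULL
  mean_or0 <- function(track, w) if (is.null(w)) 0 else
    mean(tx_values(track, gene, w[1L], w[2L]))
  ext_signal <- mean_or0(mut_cov, ext_win) * norm_factor
  wt_ext_signal <- mean_or0(wt_cov, ext_win)
  body_signal <- mean(tx_values(wt_cov, gene, a - ref_width, a))
  extended <- ext_signal >= floor * body_signal &&
    ext_signal / (wt_ext_signal + pseudocount) >= ratio_min
  data.frame(gene_id = gene$gene_id, ext_signal = ext_signal,
             body_signal = body_signal, wt_ext_signal = wt_ext_signal,
             extended = extended, stringsAsFactors = FALSE)
}

#' Classify every gene in a table
#'
#' @param genes A \code{sno_genes} data.frame.
#' @inheritParams classify_three_prime_extension
#' @return data.frame, one row per gene.
#' @export
classify_three_prime_all <- function(genes, wt_cov, mut_cov,
                                     norm_factor = 1, ...) {
  out <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    classify_three_prime_extension(genes[i, ], wt_cov, mut_cov,
                                   norm_factor, ...)
  }))
  rownames(out) <- NULL
  out
}
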