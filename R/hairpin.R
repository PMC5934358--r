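# AGNN tetraloop stem-loop detection and Rnt1 cleavage-site prediction.
#
# An Rnt1 cleavage structure is a double-stranded stem capped by a 4-nt loop
# matching the AGNN consensus. The scanner enumerates candidate loops and
# extends the stem base-pair by base-pair outward from the loop; the closing
# pair (adjacent to the loop) and the outermost pair must pair, interior
# unpaired positions are tolerated up to max_mismatch, and G.T wobbles count
# as paired when allow_wobble is on. For each loop the maximal valid stem is
# reported; hairpins shorter than min_stem are dropped.

#' Hairpin scanner parameters
#'
#' @param loop_consensus 4-letter loop pattern over A,C,G,T,N (N = any);
#'   default \code{"AGNN"}, the Rnt1 recognition consensus.
#' @param min_stem Minimum stem length in base pairs to report.
#' @param max_stem Maximum stem length considered.
#' @param allow_wobble Count G.T (rG.U) as paired.
#' @param max_mismatch Maximum interior unpaired positions in the stem.
#' @param max_scan_span Maximum total hairpin span (2*stem + 4) in nt.
#' @return Object of class \code{hairpin_params}.
#' @export
hairpin_params <- function(loop_consensus = "AGNN", min_stem = 10L,
                           max_stem = 25L, allow_wobble = TRUE,
                           max_mismatch = 0L, max_scan_span = 70L) {
  loop_consensus <- toupper(loop_consensus)
  if (nchar(loop_consensus) != 4L ||
      grepl("[^ACGTN]", loop_consensus)) {
    stop("loop_consensus must be a 4-letter pattern over A,C,G,T,N")
  }
  if (min_stem < 1L) stop("min_stem must be >= 1")
  if (max_mismatch < 0L) stop("max_mismatch must be >= 0")
  if (max_stem < min_stem) stop("max_stem must be >= min_stem")
  structure(list(loop_consensus = loop_consensus,
                 min_stem = as.integer(min_stem),
                 max_stem = as.integer(max_stem),
                 allow_wobble = isTRUE(allow_wobble),
                 max_mismatch = as.integer(max_mismatch),
                 max_scan_span = as.integer(max_scan_span)),
            class = "hairpin_params")
}

# pair classification: 2 = Watson-Crick, 1 = wobble, 0 = unpaired.
.pair_class <- function(a, b) {
  wc <- (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
  wob <- (a == "G" & b == "T") | (a == "T" & b == "G")
  ifelse(wc, 2L, ifelse(wob, 1L, 0L))
}

.empty_hairpins <- function() {
  data.frame(loop_start = integer(), loop_end = integer(),
             stem_len = integer(), arm5_start = integer(),
             arm3_end = integer(), n_wobble = integer(),
             n_mismatch = integer(), loop_seq = character(),
             stringsAsFactors = FALSE)
}

#' Find AGNN-tetraloop hairpins in a sequence
#'
#' Scans one sequence (given 5' to 3') for stem-loops whose 4-nt loop
#' matches \code{params$loop_consensus}. All coordinates in the result are
#' 0-based half-open positions in \code{seq}. The reported stem is maximal
#' for its loop; no N is allowed anywhere inside the reported span.
#'
#' @param seq Character scalar over A,C,G,T,N.
#' @param params A \code{\link{hairpin_params}} object.
#' @return data.frame with one row per hairpin: \code{loop_start, loop_end,
#'   stem_len, arm5_start, arm3_end, n_wobble, n_mismatch, loop_seq},
#'   sorted by \code{loop_start}.
#' @export
find_hairpins <- function(seq, params = hairpin_params()) {
  s <- toupper(seq)
  n <- nchar(s)
  if (n < 2L * params$min_stem + 4L) return(.empty_hairpins())
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  if (any(!ch %in% c("A", "C", "G", "T", "N"))) {
    stop("sequence contains a character outside A,C,G,T,N")
  }
  cons <- strsplit(params$loop_consensus, "", fixed = TRUE)[[1L]]
  # candidate loop starts (0-based): consensus match, no literal N in loop
  idx <- seq_len(n - 3L)                      # 1-based loop starts
  ok <- rep(TRUE, length(idx))
  for (k in 0:3) {
    b <- ch[idx + k]
    ok <- ok & b != "N" & (cons[k + 1L] == "N" | b == cons[k + 1L])
  }
  loops0 <- idx[ok] - 1L
  rows <- vector("list", length(loops0))
  nr <- 0L
  for (i0 in loops0) {
    best_len <- 0L; best_wob <- 0L; best_mis <- 0L
    k <- 0L; mis <- 0L; wob <- 0L
    repeat {
      a <- i0 - 1L - k; b <- i0 + 4L + k     # 0-based pair positions
      if (a < 0L || b >= n) break
      if (k + 1L > params$max_stem) break
      if (2L * (k + 1L) + 4L > params$max_scan_span) break
      A <- ch[a + 1L]; B <- ch[b + 1L]
      if (A == "N" || B == "N") break
      pc <- .pair_class(A, B)
      if (pc == 1L && !params$allow_wobble) pc <- 0L
      if (pc == 0L) {
        if (k == 0L) break                    # closing pair must pair
        mis <- mis + 1L
        if (mis > params$max_mismatch) break
      } else {
        if (pc == 1L) wob <- wob + 1L
        best_len <- k + 1L; best_wob <- wob; best_mis <- mis
      }
      k <- k + 1L
    }
    if (best_len >= params$min_stem) {
      nr <- nr + 1L
      rows[[nr]] <- data.frame(
        loop_start = i0, loop_end = i0 + 4L, stem_len = best_len,
        arm5_start = i0 - best_len, arm3_end = i0 + 4L + best_len,
        n_wobble = best_wob, n_mismatch = best_mis,
        loop_seq = substr(s, i0 + 1L, i0 + 4L),
        stringsAsFactors = FALSE)
    }
  }
  if (nr == 0L) return(.empty_hairpins())
  out <- do.call(rbind, rows[seq_len(nr)])
  out[order(out$loop_start), , drop = FALSE]
}

#' Rank hairpins for best-per-gene selection
#'
#' Orders by stem length (longest first), then fewest wobbles, then
#' leftmost loop.
#'
#' @param hairpins data.frame from \code{\link{find_hairpins}}.
#' @return The same data.frame, reordered.
#' @export
rank_hairpins <- function(hairpins) {
  hairpins[order(-hairpins$stem_len, hairpins$n_wobble,
                 hairpins$loop_start), , drop = FALSE]
}

.empty_rcs <- function(reason = NA_character_) {
  out <- data.frame(gene_id = character(), rcs_id = character(),
                    chrom = character(), strand = character(),
                    loop_start_t = integer(), loop_end_t = integer(),
                    stem_len = integer(), n_wobble = integer(),
                    n_mismatch = integer(), loop_seq = character(),
                    loop_gstart = integer(), loop_gend = integer(),
                    cleave_up_t = integer(), cleave_down_t = integer(),
                    cleave_up_g = integer(), cleave_down_g = integer(),
                    within_extension = logical(),
                    stringsAsFactors = FALSE)
  attr(out, "reason") <- reason
  out
}

#' Predict Rnt1 cleavage sites in a gene's 5' extension
#'
#' Scans the 5' extension (plus a short overhang into the mature sequence)
#' in transcript orientation for AGNN hairpins and, for each, reports two
#' candidate cleavage positions at \code{d_point} nt from the loop: one
#' upstream of the 5' loop boundary and one downstream of the 3' loop
#' boundary. The configurable band \code{[d_min, d_max]} describes where
#' cleavage-derived nascent 3' ends are expected relative to the loop.
#'
#' @param gene One-row \code{sno_genes} data.frame.
#' @param genome Named character vector from \code{\link{read_genome}}.
#' @param params A \code{\link{hairpin_params}} object.
#' @param d_min,d_max Distance band (nt from the loop boundary).
#' @param d_point Point estimate of the cleavage distance.
#' @param overhang Nucleotides of mature sequence appended to the scanned
#'   region, so hairpins straddling the mature boundary are still seen.
#' @return data.frame with one row per hairpin (columns include transcript
#'   and genome coordinates of the loop and both cleavage candidates, and
#'   \code{within_extension}). Empty with attribute \code{reason} when the
#'   gene has no 5' extension. Candidate positions outside the primary
#'   transcript are NA.
#' @export
predict_rcs <- function(gene, genome, params = hairpin_params(),
                        d_min = 12L, d_max = 18L, d_point = 14L,
                        overhang = 5L) {
  if (!gene$chrom %in% names(genome)) {
    stop("gene ", gene$gene_id, " is on unknown chromosome ", gene$chrom)
  }
  e5 <- ext5_len(gene)
  if (e5 <= 0L) return(.empty_rcs("no 5' extension"))
  scan_end <- min(e5 + overhang, tx_len(gene))
  region <- transcript_seq(genome, gene, 0L, scan_end)
  hp <- find_hairpins(region, params)
  if (nrow(hp) == 0L) return(.empty_rcs("no hairpin found"))
  txl <- tx_len(gene)
  inside <- function(t) ifelse(t >= 0L & t < txl, t, NA_integer_)
  up_t <- inside(hp$loop_start - d_point)
  down_t <- inside(hp$loop_end - 1L + d_point)
  gpos <- function(t) ifelse(is.na(t), NA_integer_, t2g(gene, t))
  g1 <- t2g(gene, hp$loop_start)
  g2 <- t2g(gene, hp$loop_end - 1L)
  out <- data.frame(
    gene_id = gene$gene_id,
    rcs_id = paste0(gene$gene_id, ".L", hp$loop_start),
    chrom = gene$chrom, strand = gene$strand,
    loop_start_t = hp$loop_start, loop_end_t = hp$loop_end,
    stem_len = hp$stem_len, n_wobble = hp$n_wobble,
    n_mismatch = hp$n_mismatch, loop_seq = hp$loop_seq,
    loop_gstart = pmin(g1, g2), loop_gend = pmax(g1, g2) + 1L,
    cleave_up_t = up_t, cleave_down_t = down_t,
    cleave_up_g = gpos(up_t), cleave_down_g = gpos(down_t),
    within_extension = hp$arm3_end <= e5,
    stringsAsFactors = FALSE)
  attr(out, "d_band") <- c(d_min, d_max)
  out
}

#' Predict Rnt1 cleavage sites for every gene in a table
#'
#' @param genes A \code{sno_genes} data.frame.
#' @inheritParams predict_rcs
#' @return data.frame; rows concatenated over genes (genes without a 5'
#'   extension contribute none).
#' @export
predict_rcs_all <- function(genes, genome, params = hairpin_params(), ...) {
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    predict_rcs(genes[i, ], genome, params, ...)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- .empty_rcs()
  rownames(out) <- NULL
  out
}

#' Export RCS predictions as BED6
#'
#' Writes hairpin loops and both candidate cleavage points; names encode
#' gene, arm and distance.
#'
#' @param rcs data.frame from \code{\link{predict_rcs_all}}.
#' @param path Output path.
#' @param d_point Distance encoded in the feature names.
#' @return Invisibly, \code{path}.
#' @export
write_rcs_bed <- function(rcs, path, d_point = 14L) {
  feats <- list()
  if (nrow(rcs) > 0L) {
    feats[[1L]] <- data.frame(
      chrom = rcs$chrom, start = rcs$loop_gstart, end = rcs$loop_gend,
      name = paste0(rcs$rcs_id, ".loop"), score = rcs$stem_len,
      strand = rcs$strand, stringsAsFactors = FALSE)
    for (arm in c("up", "down")) {
      g <- rcs[[paste0("cleave_", arm, "_g")]]
      keep <- !is.na(g)
      if (any(keep)) {
        feats[[length(feats) + 1L]] <- data.frame(
          chrom = rcs$chrom[keep], start = g[keep], end = g[keep] + 1L,
          name = paste0(rcs$rcs_id[keep], ".", arm, d_point), score = 0,
          strand = rcs$strand[keep], stringsAsFactors = FALSE)
      }
    }
  }
  write_bed(if (length(feats)) do.call(rbind, feats) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               name = character(), strand = character()), path)
}
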