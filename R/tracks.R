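# Strand-specific per-base count tracks.
#
# A track holds one numeric vector per (chromosome, strand); values are
# per-base counts, either NET-seq nascent 3' ends or RNA-seq coverage.
# Tracks stay genome-oriented; transcript-orientation views are produced at
# extraction time by tx_values().

.track_key <- function(chrom, strand) paste0(chrom, ":", strand)

#' Create an empty track
#'
#' @param seqlens Named integer vector of chromosome lengths (for example
#'   \code{nchar(genome)}).
#' @param kind \code{"coverage"} (RNA-seq per-base coverage) or
#'   \code{"netseq_3prime_ends"} (per-base nascent 3' end counts).
#' @return Object of class \code{basetrack}.
#' @export
new_track <- function(seqlens, kind = c("coverage", "netseq_3prime_ends")) {
  kind <- match.arg(kind)
  counts <- list()
  for (chrom in names(seqlens)) {
    for (st in c("+", "-")) {
      counts[[.track_key(chrom, st)]] <- numeric(seqlens[[chrom]])
    }
  }
  structure(list(counts = counts,
                 seqlens = vapply(seqlens, as.integer, 0L),
                 kind = kind),
            class = "basetrack")
}

#' Total counts in a track (library size)
#' @param track A \code{basetrack}.
#' @return Numeric scalar.
#' @export
track_total <- function(track) sum(vapply(track$counts, sum, 0))

#' Multiply a track by a constant
#' @param track A \code{basetrack}.
#' @param factor Positive scalar.
#' @return The scaled track.
#' @export
track_scale <- function(track, factor) {
  track$counts <- lapply(track$counts, `*`, factor)
  track
}

#' Load one strand of a bedGraph file into a track
#'
#' Reads a 4-column bedGraph (0-based half-open intervals) and expands the
#' interval values to per-base counts on the given strand.
#'
#' @param path Path to the bedGraph file.
#' @param strand \code{"+"} or \code{"-"}.
#' @param kind Track kind; see \code{\link{new_track}}.
#' @param seqlens Chromosome lengths. Required unless \code{into} is given;
#'   if missing entirely, lengths are inferred from the data.
#' @param into Optional existing \code{basetrack} to add the strand to
#'   (used to combine a plus/minus file pair into one track).
#' @return A \code{basetrack}.
#' @export
load_bedgraph <- function(path, strand, kind = c("coverage",
                                                 "netseq_3prime_ends"),
                          seqlens = NULL, into = NULL) {
  kind <- match.arg(kind)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (!file.exists(path)) stop("bedGraph not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "bedGraph"),
                 error = function(e) NULL)
  if (is.null(gr)) {                     # empty file
    gr <- GenomicRanges::GRanges()
  }
  if (is.null(into)) {
    if (is.null(seqlens)) {
      seqlens <- integer()
      if (length(gr)) {
        ends <- tapply(BiocGenerics::end(gr),
                       as.character(GenomicRanges::seqnames(gr)), max)
        seqlens <- stats::setNames(as.integer(ends), names(ends))
      }
    }
    track <- new_track(seqlens, kind)
  } else {
    track <- into
    if (track$kind != kind) stop("track kind mismatch: ", track$kind,
                                 " vs ", kind)
  }
  if (length(gr) == 0L) return(track)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  s0 <- BiocGenerics::start(gr) - 1L        # back to 0-based half-open
  e <- BiocGenerics::end(gr)
  val <- GenomicRanges::mcols(gr)$score
  if (any(val < 0)) stop("negative value in bedGraph ", path)
  # overlapping intervals with conflicting values are an input error
  o <- order(chrom, s0)
  oc <- chrom[o]; os <- s0[o]; oe <- e[o]; ov <- val[o]
  if (length(o) > 1L) {
    same <- oc[-1L] == oc[-length(oc)]
    lap <- same & os[-1L] < oe[-length(oe)]
    conflict <- lap & ov[-1L] != ov[-length(ov)]
    if (any(conflict)) {
      i <- which(conflict)[1L] + 1L
      stop("overlapping bedGraph intervals with conflicting values at ",
           oc[i], ":", os[i])
    }
  }
  for (i in seq_along(s0)) {
    key <- .track_key(chrom[i], strand)
    if (!key %in% names(track$counts)) {
      stop("bedGraph chromosome ", chrom[i], " not in track")
    }
    if (e[i] > track$seqlens[[chrom[i]]]) {
      stop("bedGraph interval beyond chromosome bounds on ", chrom[i])
    }
    track$counts[[key]][(s0[i] + 1L):e[i]] <- val[i]
  }
  track
}

#' Load a plus/minus bedGraph pair as one strand-specific track
#'
#' @param plus_path,minus_path Paths to the strand-split bedGraph files.
#' @inheritParams load_bedgraph
#' @return A \code{basetrack} with both strands populated.
#' @export
load_bedgraph_pair <- function(plus_path, minus_path,
                               kind = c("coverage", "netseq_3prime_ends"),
                               seqlens) {
  kind <- match.arg(kind)
  track <- new_track(seqlens, kind)
  track <- load_bedgraph(plus_path, "+", kind, into = track)
  load_bedgraph(minus_path, "-", kind, into = track)
}

#' Write one strand of a track as bedGraph
#'
#' Emits runs of equal non-zero value as half-open intervals, in
#' chromosome order; deterministic output for identical tracks.
#'
#' @param track A \code{basetrack}.
#' @param strand \code{"+"} or \code{"-"}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_bedgraph <- function(track, strand, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (chrom in names(track$seqlens)) {
    v <- track$counts[[.track_key(chrom, strand)]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep)) {
      writeLines(paste(chrom, starts[keep], ends[keep],
                       format(r$values[keep], trim = TRUE,
                              scientific = FALSE),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Per-base values over a genome window
#'
#' Positions outside the chromosome are returned as zero (with a warning
#' when the window had to be truncated).
#'
#' @param track A \code{basetrack}.
#' @param chrom,strand Location.
#' @param gstart,gend Genome half-open window.
#' @return Numeric vector of length \code{gend - gstart}.
#' @export
track_values <- function(track, chrom, strand, gstart, gend) {
  key <- .track_key(chrom, strand)
  if (!key %in% names(track$counts)) {
    stop("unknown chromosome/strand: ", key)
  }
  n <- track$seqlens[[chrom]]
  out <- numeric(gend - gstart)
  lo <- max(gstart, 0L)
  hi <- min(gend, n)
  if (lo > gstart || hi < gend) {
    warning("window [", gstart, ",", gend, ") truncated to chromosome ",
            chrom, " bounds")
  }
  if (hi > lo) {
    out[(lo - gstart + 1L):(hi - gstart)] <-
      track$counts[[key]][(lo + 1L):hi]
  }
  out
}

#' Per-base values over a transcript-coordinate window
#'
#' Returns counts in transcript orientation (index 1 = \code{t0}).
#'
#' @param track A \code{basetrack}.
#' @param gene One-row \code{sno_genes} data.frame.
#' @param t0,t1 Transcript interval \code{[t0, t1)}.
#' @param sense If TRUE (default) read the gene's strand, else the
#'   opposite (antisense) strand.
#' @return Numeric vector of length \code{t1 - t0}.
#' @export
tx_values <- function(track, gene, t0, t1, sense = TRUE) {
  w <- tx_window_g(gene, t0, t1)
  st <- gene$strand
  if (!sense) st <- if (st == "+") "-" else "+"
  v <- track_values(track, gene$chrom, st, w[1L], w[2L])
  if (gene$strand == "-") rev(v) else v
}

#' Reads Per Kilobase per Million mapped reads
#'
#' @param gene_count Reads assigned to the gene.
#' @param gene_length Gene length in nt (> 0).
#' @param total_mapped Total mapped reads in the library (> 0).
#' @return \code{gene_count / ((gene_length/1000) * (total_mapped/1e6))}.
#' @export
rpkm <- function(gene_count, gene_length, total_mapped) {
  if (any(gene_length <= 0)) stop("gene_length must be > 0")
  if (any(total_mapped <= 0)) stop("total_mapped must be > 0")
  gene_count / ((gene_length / 1000) * (total_mapped / 1e6))
}
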