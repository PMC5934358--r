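# ---------------------------------------------------------------------------
# Coordinate contract
# ---------------------------------------------------------------------------
# Every interval in this package is 0-based half-open in genome coordinates,
# the convention of BED and bedGraph. Gene tables store, per transcription
# unit:
#   + strand:  tss <= mature_start < mature_end <= terminator_end
#              (transcript covers [tss, terminator_end))
#   - strand:  terminator_end <= mature_start < mature_end <= tss
#              (transcript covers [terminator_end, tss); the TSS base itself
#              is position tss - 1)
# Per-gene computations run in *transcript* orientation: transcript position
# t (0 = TSS base) maps to genome position tss + t on the plus strand and
# tss - 1 - t on the minus strand.  Conversions happen only through the
# helpers below.

#' Read a genome from a FASTA file
#'
#' Loads every record, case-folds to upper case and validates the alphabet.
#' Record names are the first whitespace-delimited token of the header.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of chromosome sequences over
#'   \code{A,C,G,T,N}.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chrI", "acgtACGT"), fa)
#' read_genome(fa)
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  x <- Biostrings::readBStringSet(path)
  nm <- vapply(strsplit(names(x), "[ \t]"), `[`, "", 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate record name in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  s <- toupper(as.character(x))
  for (i in seq_along(s)) {
    if (nchar(s[[i]]) == 0L) stop("empty sequence for record ", nm[[i]])
    bad <- regexpr("[^ACGTN]", s[[i]])
    if (bad > 0L) {
      stop("non-ACGTN character '", substr(s[[i]], bad, bad),
           "' in record ", nm[[i]], " at position ", bad)
    }
  }
  names(s) <- nm
  s
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector as returned by
#'   \code{\link{read_genome}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_genome <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Reverse-complement a DNA string
#'
#' Plain-string reverse complement over the ACGTN alphabet (N maps to N).
#'
#' @param s Character scalar.
#' @return Character scalar.
#' @export
revcomp <- function(s) {
  comp <- chartr("ACGTN", "TGCAN", s)
  vapply(comp, function(x) {
    paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

.gene_columns <- c("gene_id", "chrom", "strand", "class", "tss",
                   "mature_start", "mature_end", "terminator_end",
                   "polycistron_id", "polycistron_rank")

#' Validate a snoRNA gene table
#'
#' Enforces the coordinate contract (see package source header) and the
#' class vocabulary (\code{CD}, \code{HACA}).
#'
#' @param genes data.frame with columns \code{gene_id, chrom, strand, class,
#'   tss, mature_start, mature_end, terminator_end} and optionally
#'   \code{polycistron_id, polycistron_rank}.
#' @return The validated data.frame with class \code{sno_genes}.
#' @export
as_sno_genes <- function(genes) {
  need <- setdiff(.gene_columns[1:8], names(genes))
  if (length(need)) stop("gene table missing columns: ",
                         paste(need, collapse = ", "))
  if (!"polycistron_id" %in% names(genes)) {
    genes$polycistron_id <- rep(NA_character_, nrow(genes))
  }
  if (!"polycistron_rank" %in% names(genes)) {
    genes$polycistron_rank <- rep(NA_integer_, nrow(genes))
  }
  genes <- genes[, .gene_columns]
  for (col in c("tss", "mature_start", "mature_end", "terminator_end")) {
    genes[[col]] <- as.integer(genes[[col]])
    if (anyNA(genes[[col]]) || any(genes[[col]] < 0L)) {
      stop("column ", col, " must hold non-negative integers")
    }
  }
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id in gene table")
  bad <- !genes$strand %in% c("+", "-")
  if (any(bad)) stop("unknown strand for gene ", genes$gene_id[bad][1L])
  bad <- !genes$class %in% c("CD", "HACA")
  if (any(bad)) stop("unknown class tag '", genes$class[bad][1L],
                     "' for gene ", genes$gene_id[bad][1L])
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ok <- if (g$strand == "+") {
      g$tss <= g$mature_start && g$mature_start < g$mature_end &&
        g$mature_end <= g$terminator_end
    } else {
      g$terminator_end <= g$mature_start && g$mature_start < g$mature_end &&
        g$mature_end <= g$tss
    }
    if (!ok) {
      stop("gene ", g$gene_id, ": coordinates violate the strand-adjusted ",
           "tss <= mature interval <= terminator contract")
    }
  }
  class(genes) <- c("sno_genes", "data.frame")
  genes
}

#' Read a snoRNA gene table
#'
#' Tab-delimited table with a header row; column order as in
#' \code{as_sno_genes}. Empty strings in \code{polycistron_id} become NA.
#'
#' @param path Path to the TSV file.
#' @return A \code{sno_genes} data.frame.
#' @export
read_genes <- function(path) {
  if (!file.exists(path)) stop("gene table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  if ("polycistron_id" %in% names(df)) {
    df$polycistron_id[df$polycistron_id %in% c("", "NA", ".")] <- NA
  }
  if ("polycistron_rank" %in% names(df)) {
    df$polycistron_rank <- suppressWarnings(as.integer(df$polycistron_rank))
  }
  as_sno_genes(df)
}

#' Write a snoRNA gene table
#'
#' @param genes A \code{sno_genes} data.frame.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_genes <- function(genes, path) {
  genes <- as_sno_genes(genes)
  out <- as.data.frame(genes)
  out$polycistron_id[is.na(out$polycistron_id)] <- ""
  out$polycistron_rank[is.na(out$polycistron_rank)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write features as BED6
#'
#' @param features data.frame with columns \code{chrom, start, end, name,
#'   strand} and optionally \code{score} (defaults to 0).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_bed <- function(features, path) {
  if (nrow(features) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  need <- setdiff(c("chrom", "start", "end", "name", "strand"),
                  names(features))
  if (length(need)) stop("BED features missing columns: ",
                         paste(need, collapse = ", "))
  if (any(features$start < 0 | features$end < 0)) {
    stop("negative coordinate in BED features")
  }
  score <- if ("score" %in% names(features)) features$score else 0
  bed <- data.frame(features$chrom, features$start, features$end,
                    features$name, score, features$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# --- transcript-orientation helpers ----------------------------------------

#' Transcript length of a gene
#' @param gene One-row \code{sno_genes} data.frame (or equivalent list).
#' @return Integer number of transcribed nucleotides.
#' @export
tx_len <- function(gene) {
  if (gene$strand == "+") gene$terminator_end - gene$tss
  else gene$tss - gene$terminator_end
}

#' 5' extension length (TSS to mature start, strand-adjusted)
#' @inheritParams tx_len
#' @return Integer, >= 0.
#' @export
ext5_len <- function(gene) {
  if (gene$strand == "+") gene$mature_start - gene$tss
  else gene$tss - gene$mature_end
}

#' Mature length of a gene
#' @inheritParams tx_len
#' @return Integer.
#' @export
mature_len <- function(gene) gene$mature_end - gene$mature_start

#' Transcript coordinate of the mature 3' end (half-open)
#'
#' The transcript position just past the last mature base; the last coding
#' base is at \code{mature_end_t(gene) - 1}.
#' @inheritParams tx_len
#' @return Integer.
#' @export
mature_end_t <- function(gene) ext5_len(gene) + mature_len(gene)

#' Map a transcript position to a genome position
#' @inheritParams tx_len
#' @param t Integer vector of transcript positions (0 = TSS base).
#' @return Integer vector of 0-based genome positions.
#' @export
t2g <- function(gene, t) {
  if (gene$strand == "+") gene$tss + t else gene$tss - 1L - t
}

#' Genome window of a transcript-coordinate interval
#' @inheritParams tx_len
#' @param t0,t1 Transcript interval \code{[t0, t1)}.
#' @return Integer length-2 vector: genome half-open \code{c(start, end)}.
#' @export
tx_window_g <- function(gene, t0, t1) {
  if (gene$strand == "+") c(gene$tss + t0, gene$tss + t1)
  else c(gene$tss - t1, gene$tss - t0)
}

#' Extract transcript-orientation sequence
#'
#' @param genome Named character vector from \code{\link{read_genome}}.
#' @inheritParams tx_len
#' @param t0,t1 Transcript interval \code{[t0, t1)}; defaults to the whole
#'   primary transcript.
#' @return Character scalar in transcript orientation (5' to 3').
#' @export
transcript_seq <- function(genome, gene, t0 = 0L, t1 = tx_len(gene)) {
  if (!gene$chrom %in% names(genome)) {
    stop("gene ", gene$gene_id, " is on unknown chromosome ", gene$chrom)
  }
  w <- tx_window_g(gene, t0, t1)
  s <- substr(genome[[gene$chrom]], w[1L] + 1L, w[2L])
  if (gene$strand == "-") revcomp(s) else s
}
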