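# Independent brute-force hairpin enumerator, written against the stated
# definition only (no code shared with the scanner): a hairpin is a 4-nt
# loop matching the consensus with a stem of L pairs where position
# loop_start-1-k pairs with loop_end+k, the closing (k = 0) and outermost
# (k = L-1) pairs must pair, at most max_mismatch interior positions are
# unpaired, no N anywhere in the span, span <= max_scan_span, and L is the
# maximum valid stem for that loop.
oracle_hairpins <- function(seq, params = hairpin_params()) {
  ch <- strsplit(toupper(seq), "")[[1L]]
  n <- length(ch)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  is_pair <- function(x, y) {
    if (x == "N" || y == "N") return(FALSE)
    if (comp[[x]] == y) return(TRUE)
    params$allow_wobble && ((x == "G" && y == "T") ||
                              (x == "T" && y == "G"))
  }
  cons <- strsplit(params$loop_consensus, "")[[1L]]
  hits <- list()
  for (i0 in 0:(n - 4L)) {
    loop <- ch[(i0 + 1L):(i0 + 4L)]
    if (any(loop == "N")) next
    if (!all(cons == "N" | loop == cons)) next
    best <- NULL
    for (L in params$min_stem:params$max_stem) {
      if (i0 - L < 0L || i0 + 4L + L > n) break
      if (2L * L + 4L > params$max_scan_span) break
      span <- ch[(i0 - L + 1L):(i0 + 4L + L)]
      if (any(span == "N")) break
      paired <- vapply(0:(L - 1L), function(k) {
        is_pair(ch[i0 - k], ch[i0 + 5L + k])
      }, TRUE)
      closing_ok <- TRUE
      for (k in 0:(L - 1L)) {
        # every prefix must stay within the mismatch budget for the stem
        # to have been extendable this far
        if (sum(!paired[1:(k + 1L)]) > params$max_mismatch) {
          closing_ok <- FALSE
          break
        }
      }
      if (!paired[1L] || !closing_ok) break
      if (paired[L] && sum(!paired) <= params$max_mismatch) {
        nw <- sum(vapply(0:(L - 1L), function(k) {
          x <- ch[i0 - k]; y <- ch[i0 + 5L + k]
          (x == "G" && y == "T") || (x == "T" && y == "G")
        }, TRUE) & paired)
        best <- data.frame(loop_start = i0, loop_end = i0 + 4L,
                           stem_len = L, arm5_start = i0 - L,
                           arm3_end = i0 + 4L + L,
                           n_wobble = nw, n_mismatch = sum(!paired),
                           loop_seq = paste(loop, collapse = ""),
                           stringsAsFactors = FALSE)
      }
    }
    if (!is.null(best)) hits[[length(hits) + 1L]] <- best
  }
  if (!length(hits)) {
    return(data.frame(loop_start = integer(), loop_end = integer(),
                      stem_len = integer(), arm5_start = integer(),
                      arm3_end = integer(), n_wobble = integer(),
                      n_mismatch = integer(), loop_seq = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out[order(out$loop_start), , drop = FALSE]
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# dinucleotide-preserving shuffle: random Eulerian walk over the
# first-order transition multigraph, retried until all edges are used.
dinuc_shuffle <- function(seq, max_try = 200L) {
  ch <- strsplit(seq, "")[[1L]]
  n <- length(ch)
  if (n < 3L) return(seq)
  for (try in seq_len(max_try)) {
    edges <- split(ch[-1L], factor(ch[-n], levels = unique(ch)))
    edges <- lapply(edges, sample)
    used <- lapply(edges, function(e) 0L)
    walk <- character(n)
    walk[1L] <- ch[1L]
    ok <- TRUE
    for (i in 2:n) {
      v <- walk[i - 1L]
      k <- used[[v]] + 1L
      if (is.null(edges[[v]]) || k > length(edges[[v]])) {
        ok <- FALSE
        break
      }
      walk[i] <- edges[[v]][k]
      used[[v]] <- k
    }
    if (ok) return(paste(walk, collapse = ""))
  }
  stop("dinucleotide shuffle failed")
}

# one-row gene table for hand-built fixtures
make_gene <- function(gene_id = "g1", chrom = "chrT", strand = "+",
                      tss = 0L, mature_start = 0L, mature_end = 10L,
                      terminator_end = 10L, class = "CD") {
  as_sno_genes(data.frame(gene_id = gene_id, chrom = chrom,
                          strand = strand, class = class, tss = tss,
                          mature_start = mature_start,
                          mature_end = mature_end,
                          terminator_end = terminator_end,
                          stringsAsFactors = FALSE))
}

# mirror a genome and its annotations (reverse-complement every
# chromosome, flip coordinates and strands)
mirror_dataset <- function(genome, genes) {
  lens <- nchar(genome)
  mg <- vapply(genome, revcomp, "")
  names(mg) <- names(genome)
  flip <- function(chrom, pos) lens[[chrom]] - pos
  out <- genes
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    out$strand[i] <- if (g$strand == "+") "-" else "+"
    out$tss[i] <- flip(g$chrom, g$tss)
    out$mature_start[i] <- flip(g$chrom, g$mature_end)
    out$mature_end[i] <- flip(g$chrom, g$mature_start)
    out$terminator_end[i] <- flip(g$chrom, g$terminator_end)
  }
  list(genome = mg, genes = as_sno_genes(as.data.frame(out)))
}
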