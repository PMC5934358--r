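# Circular RT-PCR clone analysis.
#
# A clone read is a circular permutation of one RNA molecule: the molecule's
# 3' portion followed by its 5' portion, because the RNA was circularized
# before reverse transcription and the primers sit inside the mature
# sequence. The molecule itself is genome-templated transcript sequence
# T[s, e) plus a non-templated oligo(A) tail of length t:
#
#     molecule = T[s:e) + "A" x t        (transcript orientation)
#
# Because only the circle is observed, several (s, e, t) decompositions can
# describe the same read (a tail A abutting a genomic A, or a tail-free
# molecule whose first and last flanking bases coincide). A canonical form
# resolves this deterministically: maximal genome-templated length, ties
# broken toward the 3'-most rotation. An A at the extension/tail boundary
# that matches the genome is therefore always counted as templated.

#' Canonical form of a circular junction call
#'
#' Normalizes a valid decomposition \code{molecule = T[s:e) + A^t} of a
#' circularized clone to a unique representative: maximal templated length
#' (tail A's matching genomic A's are absorbed, 3' side first), and among
#' the remaining fully-templated rotation ties the 5' terminus closest to
#' \code{prefer} (normally the annotated mature start), or the 3'-most
#' rotation when no preference is given.
#'
#' @param tx_seq Primary-transcript sequence (character scalar, transcript
#'   orientation).
#' @param s,e Templated interval \code{[s, e)} in transcript coordinates
#'   (0-based half-open).
#' @param tail Non-templated 3'-terminal A count.
#' @param prefer Optional transcript position used to break rotation ties.
#' @return list \code{(s, e, tail)} in canonical form.
#' @export
canonicalize_junction <- function(tx_seq, s, e, tail, prefer = NULL) {
  n <- nchar(tx_seq)
  base_at <- function(i) substr(tx_seq, i + 1L, i + 1L)   # 0-based
  while (tail > 0L && e < n && base_at(e) == "A") {       # absorb at 3' end
    e <- e + 1L; tail <- tail - 1L
  }
  while (tail > 0L && s > 0L && base_at(s - 1L) == "A") { # absorb at 5' end
    s <- s - 1L; tail <- tail - 1L
  }
  if (tail == 0L) {
    # fully templated: every rotation with matching flanks describes the
    # same circle; find the contiguous tie range and pick one end point
    s_lo <- s; e_lo <- e
    while (s_lo > 0L && base_at(s_lo - 1L) == base_at(e_lo - 1L)) {
      s_lo <- s_lo - 1L; e_lo <- e_lo - 1L
    }
    s_hi <- s; e_hi <- e
    while (e_hi < n && base_at(s_hi) == base_at(e_hi)) {
      s_hi <- s_hi + 1L; e_hi <- e_hi + 1L
    }
    s <- if (is.null(prefer)) s_hi else min(max(prefer, s_lo), s_hi)
    e <- s + (e_lo - s_lo)
  }
  list(s = as.integer(s), e = as.integer(e), tail = as.integer(tail))
}

#' Read circularized clone sequences from FASTA
#'
#' @param path Path to a FASTA file of clone reads (sense of the snoRNA).
#' @return Named character vector.
#' @export
read_clones <- function(path) {
  if (!file.exists(path)) stop("clone FASTA not found: ", path)
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) {
    return(stats::setNames(character(), character()))
  }
  x <- Biostrings::readBStringSet(path)
  s <- toupper(as.character(x))
  names(s) <- vapply(strsplit(names(x), "[ \t]"), `[`, "", 1L)
  s
}

# tolerant left-to-right match of character vector `qch` against `sch`
# starting at 0-based subject position `at`. In tolerant mode every
# mismatch may be read as a substitution; the returned prefix is the one
# maximizing (matched length - penalty * substitutions), ending on an
# exact match, so a substitution is only ever accepted when it buys more
# than `penalty` further matched bases. Strict mode stops at the first
# mismatch.
.tolerant_match <- function(qch, sch, at, tolerant, penalty = 4L) {
  n_ov <- min(length(qch), length(sch) - at)
  if (n_ov <= 0L) return(list(len = 0L, subs = 0L))
  eq <- qch[seq_len(n_ov)] == sch[at + seq_len(n_ov)]
  if (!tolerant) {
    m <- which(!eq)[1L]
    m <- if (is.na(m)) n_ov else m - 1L
    return(list(len = m, subs = 0L))
  }
  if (!any(eq)) return(list(len = 0L, subs = 0L))
  subs_cum <- cumsum(!eq)
  score <- seq_len(n_ov) - penalty * subs_cum
  best <- which.max(ifelse(eq, score, -Inf))
  list(len = best, subs = as.integer(subs_cum[best]))
}

.cr_call_row <- function(clone_id, status, five_offset = NA_integer_,
                         ext3_len = NA_integer_, tailA_len = NA_integer_,
                         n_sub = NA_integer_) {
  data.frame(clone_id = clone_id, status = status,
             five_offset = five_offset, ext3_len = ext3_len,
             tailA_len = tailA_len,
             mature_3prime = !is.na(ext3_len) & ext3_len == 0L &
               !is.na(tailA_len) & tailA_len == 0L,
             n_sub = n_sub, stringsAsFactors = FALSE)
}

#' Parse a circularized clone against its gene
#'
#' Locates the ligation junction by anchoring the first \code{min_anchor}
#' mature nucleotides inside the doubled read, extends the templated match
#' maximally in both directions (an A at the extension/tail boundary that
#' matches the genome is templated, not tail), requires the remaining
#' read suffix to be the oligo(A) tail, and reports the canonical call.
#'
#' @param read_seq Clone read (character scalar, snoRNA sense).
#' @param clone_id Identifier carried into the result.
#' @param gene One-row \code{sno_genes} data.frame.
#' @param genome Named character vector from \code{\link{read_genome}}.
#' @param min_anchor Minimum exact-match anchor (nt) on each side of the
#'   junction; below this the clone is rejected, not force-called.
#' @param tolerant Allow isolated substitution errors (about one per
#'   hundred nt) in anchors and extensions. An exact parse is always
#'   attempted first; the tolerant pass only rescues reads the exact
#'   pass cannot place.
#' @return One-row data.frame: \code{clone_id, status} (\code{"ok"},
#'   \code{"unmappable"} or \code{"ambiguous"}), \code{five_offset}
#'   (clone 5' terminus relative to mature start; negative = 5'-extended),
#'   \code{ext3_len} (templated extension beyond the mature 3' end),
#'   \code{tailA_len}, \code{mature_3prime}, \code{n_sub} (substitutions
#'   absorbed).
#' @export
parse_clone <- function(read_seq, clone_id, gene, genome,
                        min_anchor = 12L, tolerant = TRUE) {
  strict <- .parse_clone_once(read_seq, clone_id, gene, genome,
                              min_anchor, tolerant = FALSE)
  if (strict$status == "ok" || !tolerant) return(strict)
  loose <- .parse_clone_once(read_seq, clone_id, gene, genome,
                             min_anchor, tolerant = TRUE)
  if (loose$status == "ok") loose else
    if (strict$status == "ambiguous") strict else loose
}

.parse_clone_once <- function(read_seq, clone_id, gene, genome,
                              min_anchor, tolerant) {
  read_seq <- toupper(read_seq)
  L <- nchar(read_seq)
  txs <- transcript_seq(genome, gene)
  n <- nchar(txs)
  mstart <- ext5_len(gene)
  mend <- mature_end_t(gene)
  if (L < 2L * min_anchor) return(.cr_call_row(clone_id, "unmappable"))
  rr <- paste0(read_seq, read_seq)
  # anchor seeds at several offsets into the mature sequence, so a
  # sequencing error inside one seed does not lose the clone; every hit
  # is mapped back to the rotation that pins mature start to read space
  offsets <- seq(0L, mend - mstart - min_anchor, by = min_anchor)
  offsets <- offsets[seq_len(min(3L, length(offsets)))]
  hits <- integer()
  for (off in offsets) {
    seed <- substr(txs, mstart + off + 1L, mstart + off + min_anchor)
    h <- BiocGenerics::start(Biostrings::matchPattern(seed, rr))
    hits <- c(hits, (h - 1L - off) %% L)
  }
  hits <- unique(hits)
  if (length(hits) == 0L && tolerant) {
    anchor <- substr(txs, mstart + 1L, mstart + min_anchor)
    h <- BiocGenerics::start(Biostrings::matchPattern(anchor, rr,
                                                      max.mismatch = 1L))
    hits <- unique((h - 1L) %% L)
  }
  if (length(hits) == 0L) return(.cr_call_row(clone_id, "unmappable"))

  max_bad <- if (tolerant) max(3L, ceiling(0.02 * L)) else 0L
  rch <- strsplit(rr, "", fixed = TRUE)[[1L]]
  tch <- strsplit(txs, "", fixed = TRUE)[[1L]]
  # A candidate 5' terminus s fixes the rotation (the anchor pins read
  # position q0 to transcript position mstart). Every s upstream of the
  # mature start is evaluated by one tolerant forward pass over the whole
  # molecule; the winner maximizes exactly-matched bases, with each
  # substitution hypothesis costing sub_penalty matched bases so that a
  # junction is never crossed on substitution evidence alone.
  sub_penalty <- 4L
  parse_at <- function(q0) {
    best <- NULL
    for (s in mstart:0) {
      p <- (q0 - (mstart - s)) %% L
      molecule <- rch[(p + 1L):(p + L)]
      fwd <- .tolerant_match(molecule, tch, s, tolerant)
      m <- fwd$len
      if (m < min_anchor) next
      non_a <- if (m < L) sum(molecule[(m + 1L):L] != "A") else 0L
      if (non_a > max_bad) next
      score <- m - sub_penalty * (fwd$subs + non_a)
      if (is.null(best) || score > best$score ||
          (score == best$score && fwd$subs + non_a < best$all_subs)) {
        best <- list(s = s, m = m, tail = L - m, score = score,
                     all_subs = fwd$subs + non_a)
      }
    }
    if (is.null(best)) return(NULL)
    canon <- canonicalize_junction(txs, best$s, best$s + best$m,
                                   best$tail, prefer = mstart)
    list(s = canon$s, e = canon$e, tail = canon$tail, m = best$m,
         subs = best$all_subs)
  }

  cands <- Filter(Negate(is.null), lapply(hits, parse_at))
  if (length(cands) == 0L) return(.cr_call_row(clone_id, "unmappable"))
  if (length(cands) > 1L) {
    ms <- vapply(cands, `[[`, 0L, "m")
    best <- which(ms == max(ms))
    if (length(best) > 1L) {
      keys <- vapply(cands[best], function(x)
        paste(x$s, x$e, x$tail), "")
      if (length(unique(keys)) > 1L) {
        return(.cr_call_row(clone_id, "ambiguous"))
      }
    }
    cands <- cands[best[1L]]
  }
  cc <- cands[[1L]]
  .cr_call_row(clone_id, "ok",
               five_offset = cc$s - mstart,
               ext3_len = cc$e - mend,
               tailA_len = cc$tail,
               n_sub = cc$subs)
}

#' Parse a cohort of clones
#'
#' @param clones Named character vector from \code{\link{read_clones}}.
#' @inheritParams parse_clone
#' @return data.frame, one row per clone.
#' @export
parse_clones <- function(clones, gene, genome, min_anchor = 12L,
                         tolerant = TRUE) {
  out <- do.call(rbind, lapply(seq_along(clones), function(i) {
    parse_clone(clones[[i]], names(clones)[i], gene, genome,
                min_anchor, tolerant)
  }))
  if (is.null(out)) out <- .cr_call_row(character(), character())[0, ]
  rownames(out) <- NULL
  out
}

#' Summarize circular RT-PCR calls
#'
#' @param calls data.frame from \code{\link{parse_clones}} (rows with
#'   status other than \code{"ok"} are tallied but not summarized).
#' @return list: \code{n, n_ok, mature_fraction} (fraction of mappable
#'   clones with fully mature 3' ends), \code{ext3} and \code{tailA}
#'   summaries, and \code{crosstab} of 5' status (mature vs extended) by
#'   3' status.
#' @export
summarize_clones <- function(calls) {
  if (nrow(calls) == 0L) stop("summarize_clones needs at least one call")
  ok <- calls[calls$status == "ok", , drop = FALSE]
  five <- factor(ifelse(ok$five_offset < 0L, "five_extended",
                        "five_mature"),
                 levels = c("five_mature", "five_extended"))
  three <- factor(ifelse(ok$mature_3prime, "three_mature",
                         "three_extended"),
                  levels = c("three_mature", "three_extended"))
  list(n = nrow(calls), n_ok = nrow(ok),
       n_unmappable = sum(calls$status == "unmappable"),
       n_ambiguous = sum(calls$status == "ambiguous"),
       mature_fraction = if (nrow(ok)) mean(ok$mature_3prime) else NA_real_,
       ext3 = summary(ok$ext3_len),
       ext3_table = table(ok$ext3_len),
       tailA_table = table(ok$tailA_len),
       crosstab = table(five, three))
}
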