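# rRNA 2'-O-methylation scoring from low-dNTP reverse-transcription qPCR.
#
# Reverse transcription at low dNTP concentration stalls at 2'-O-methylated
# positions, so methylated regions yield less cDNA and a delayed threshold
# cycle. Per region and condition, delta_ct = Ct(low dNTP) - Ct(high dNTP);
# the delta of an unmethylated reference region removes the reaction's
# overall RT efficiency, giving ddct, and 2^ddct is the fold RT blockage
# under the standard per-cycle doubling assumption.

#' Read a qPCR Ct table
#'
#' CSV with columns \code{region, condition, dntp_level, replicate, ct}.
#'
#' @param path Path to the CSV file.
#' @return data.frame.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop("Ct table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- setdiff(c("region", "condition", "dntp_level", "replicate", "ct"),
                  names(df))
  if (length(need)) stop("Ct table missing columns: ",
                         paste(need, collapse = ", "))
  if (!all(df$dntp_level %in% c("high", "low"))) {
    stop("dntp_level must be 'high' or 'low'")
  }
  if (any(df$ct <= 0)) stop("Ct values must be positive")
  key <- paste(df$region, df$condition, df$dntp_level, df$replicate)
  if (anyDuplicated(key)) stop("duplicate (region, condition, level, ",
                               "replicate) measurement")
  df
}

#' Score RT blockage per region relative to an unmethylated reference
#'
#' For every (region, condition): aggregates replicate Ct at each dNTP
#' level, forms \code{delta_ct = agg(low) - agg(high)}, subtracts the same
#' condition's reference-region delta to give \code{ddct}, and reports
#' \code{fold_block = 2^ddct}. Replicate variability is summarized as the
#' standard deviation of the per-replicate paired deltas (replicates are
#' paired by their replicate id across dNTP levels when complete, and
#' propagated from the two groups otherwise), together with the standard
#' error of \code{delta_ct}.
#'
#' @param measurements data.frame as from \code{\link{read_ct_table}}.
#' @param reference_region Region id of the unmethylated reference.
#' @param agg \code{"mean"} (default) or \code{"median"} replicate
#'   aggregation.
#' @return data.frame with one row per (region, condition):
#'   \code{region, condition, n_rep, delta_ct, sd_delta, se_delta, ddct,
#'   fold_block}. The reference region has \code{ddct = 0},
#'   \code{fold_block = 1} by construction.
#' @export
rtln_score <- function(measurements, reference_region = "R1",
                       agg = c("mean", "median")) {
  agg <- match.arg(agg)
  aggf <- if (agg == "mean") mean else stats::median
  df <- measurements
  if (!reference_region %in% df$region) {
    stop("reference region ", reference_region, " missing from table")
  }
  combos <- unique(df[, c("region", "condition")])
  combos <- combos[order(combos$condition, combos$region), ]
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    rg <- combos$region[i]; cd <- combos$condition[i]
    sub <- df[df$region == rg & df$condition == cd, ]
    lo <- sub[sub$dntp_level == "low", ]
    hi <- sub[sub$dntp_level == "high", ]
    if (nrow(lo) == 0L || nrow(hi) == 0L) {
      stop("missing ", if (nrow(lo) == 0L) "low" else "high",
           "-dNTP measurements for region ", rg, ", condition ", cd)
    }
    delta <- aggf(lo$ct) - aggf(hi$ct)
    paired <- nrow(lo) == nrow(hi) &&
      setequal(lo$replicate, hi$replicate)
    if (paired && nrow(lo) > 1L) {
      d <- lo$ct[order(lo$replicate)] - hi$ct[order(hi$replicate)]
      sd_delta <- stats::sd(d)
      se_delta <- sd_delta / sqrt(length(d))
    } else if (nrow(lo) > 1L && nrow(hi) > 1L) {
      sd_delta <- sqrt(stats::var(lo$ct) + stats::var(hi$ct))
      se_delta <- sqrt(stats::var(lo$ct) / nrow(lo) +
                         stats::var(hi$ct) / nrow(hi))
    } else {
      sd_delta <- NA_real_; se_delta <- NA_real_
    }
    data.frame(region = rg, condition = cd, n_rep = nrow(lo),
               delta_ct = delta, sd_delta = sd_delta,
               se_delta = se_delta, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ref <- out[out$region == reference_region, ]
  ref_delta <- stats::setNames(ref$delta_ct, ref$condition)
  missing_ref <- setdiff(out$condition, names(ref_delta))
  if (length(missing_ref)) {
    stop("reference region missing for condition ",
         paste(missing_ref, collapse = ", "))
  }
  out$ddct <- out$delta_ct - ref_delta[out$condition]
  out$fold_block <- 2^out$ddct
  rownames(out) <- NULL
  out
}

#' Compare RT blockage between two conditions
#'
#' @param scores data.frame from \code{\link{rtln_score}}.
#' @param cond_a,cond_b Condition labels; the comparison is A minus B.
#' @return data.frame per region: \code{ddct_diff = ddct_A - ddct_B} and
#'   \code{rel_fold = 2^ddct_diff}, the relative RT blockage of A over B
#'   (equivalently, the fold difference in low-dNTP cDNA yield of B over
#'   A).
#' @export
rtln_compare <- function(scores, cond_a, cond_b) {
  a <- scores[scores$condition == cond_a, ]
  b <- scores[scores$condition == cond_b, ]
  regions <- intersect(a$region, b$region)
  if (length(regions) == 0L) stop("no shared regions between conditions")
  da <- stats::setNames(a$ddct, a$region)[regions]
  db <- stats::setNames(b$ddct, b$region)[regions]
  data.frame(region = regions, ddct_diff = da - db,
             rel_fold = 2^(da - db), row.names = NULL,
             stringsAsFactors = FALSE)
}
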