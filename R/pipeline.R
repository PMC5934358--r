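# Workflow orchestration: the NET-seq/RCS discovery workflow and the
# WT-versus-mutant 3'-end workflow, with TSV + JSON reports.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Discovery workflow: RCS prediction, NET-seq support, 5' metagene
#'
#' Chains \code{\link{predict_rcs_all}}, \code{\link{colocalize_rcs_all}}
#' and \code{\link{metagene_5prime}}. The headline summary is the
#' fraction of predicted cleavage structures supported by a NET-seq peak
#' and the distribution of supported-peak distances from the AGNN loop.
#'
#' @param genome Named character vector from \code{\link{read_genome}}.
#' @param genes A \code{sno_genes} data.frame.
#' @param netseq A \code{basetrack} of NET-seq 3' ends.
#' @param params A \code{\link{hairpin_params}}.
#' @param w,min_peak,min_enrichment Co-localization settings; see
#'   \code{\link{colocalize_rcs}}.
#' @param d_band Expected cleavage-distance band (nt from the loop).
#' @param outdir Optional directory for TSV/JSON reports.
#' @return list: \code{rcs}, \code{coloc}, \code{metagene},
#'   \code{summary} (n_rcs, n_supported, support_fraction,
#'   supported_offsets, in_band_fraction).
#' @export
run_discovery <- function(genome, genes, netseq,
                          params = hairpin_params(), w = 25L,
                          min_peak = 10, min_enrichment = 5,
                          d_band = c(12L, 18L), outdir = NULL) {
  rcs <- predict_rcs_all(genes, genome, params,
                         d_min = d_band[1L], d_max = d_band[2L])
  if (nrow(rcs) == 0L) {
    summary <- list(n_rcs = 0L, n_supported = 0L,
                    support_fraction = NA_real_,
                    supported_offsets = integer(),
                    in_band_fraction = NA_real_)
    out <- list(rcs = rcs, coloc = NULL, metagene = NULL,
                summary = summary)
  } else {
    coloc <- colocalize_rcs_all(rcs, genes, netseq, w = w,
                                min_peak = min_peak,
                                min_enrichment = min_enrichment)
    mg <- metagene_5prime(rcs, genes, netseq, w = w)
    offs <- coloc$peak_offset[coloc$is_colocalized]
    summary <- list(
      n_rcs = nrow(rcs),
      n_supported = sum(coloc$is_colocalized),
      support_fraction = mean(coloc$is_colocalized),
      supported_offsets = offs,
      in_band_fraction = if (length(offs)) {
        mean(abs(offs) >= d_band[1L] & abs(offs) <= d_band[2L])
      } else NA_real_)
    out <- list(rcs = rcs, coloc = coloc, metagene = mg,
                summary = summary)
  }
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    .write_tsv(out$rcs, file.path(outdir, "rcs.tsv"))
    if (!is.null(out$coloc)) {
      .write_tsv(out$coloc, file.path(outdir, "coloc.tsv"))
      mg <- out$metagene
      .write_tsv(data.frame(offset = mg$offsets,
                            sense = mg$mean$sense,
                            antisense = mg$mean$antisense),
                 file.path(outdir, "metagene5.tsv"))
    }
    jsonlite::write_json(out$summary,
                         file.path(outdir, "discovery_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

# class grouping used throughout the 3'-end workflow
.gene_group <- function(genes) {
  e5 <- vapply(seq_len(nrow(genes)), function(i) ext5_len(genes[i, ]), 0L)
  ifelse(genes$class == "HACA", "haca",
         ifelse(e5 > 0L | !is.na(genes$polycistron_id), "rd_cd", "ri_cd"))
}

#' 3'-end workflow: metagenes, normalization, per-gene extension calls
#'
#' Groups genes into Rnt1-dependent box C/D (5'-extended or polycistronic
#' C/D), Rnt1-independent box C/D (no extension), and box H/ACA; builds a
#' mature-3'-end metagene per group; takes the mutant normalization
#' factor from the Rnt1-dependent C/D group; classifies every gene; and
#' summarizes CR-RT-PCR clones when supplied.
#'
#' @param genome,genes,outdir As in \code{\link{run_discovery}}.
#' @param wt_cov,mut_cov Coverage \code{basetrack}s.
#' @param exclude Gene ids dropped from metagene averaging (outlier
#'   signal).
#' @param window Metagene offset window.
#' @param L,ratio_min,floor Classification settings; see
#'   \code{\link{classify_three_prime_extension}}.
#' @param clones Optional named character vector of clone reads.
#' @param clone_gene_id Gene the clones belong to (required with
#'   \code{clones}).
#' @return list: \code{metagenes} (per group), \code{norm_factor},
#'   \code{calls}, \code{class_summary} (per-group extended fraction),
#'   \code{crrtpcr} (or NULL).
#' @export
run_ends <- function(genome, genes, wt_cov, mut_cov,
                     exclude = character(), window = c(-30L, 30L),
                     L = 15L, ratio_min = 3, floor = 0.1,
                     clones = NULL, clone_gene_id = NULL,
                     outdir = NULL) {
  group <- .gene_group(genes)
  metagenes <- list()
  for (grp in unique(group)) {
    sub <- genes[group == grp, , drop = FALSE]
    sub <- sub[!sub$gene_id %in% exclude, , drop = FALSE]
    if (nrow(sub) == 0L) next
    metagenes[[grp]] <- metagene_3prime(sub, wt_cov, mut_cov,
                                        window = window,
                                        exclude = exclude)
  }
  if (is.null(metagenes$rd_cd)) {
    stop("run_ends needs at least one Rnt1-dependent box C/D gene")
  }
  nf <- metagenes$rd_cd$norm_factor
  calls <- classify_three_prime_all(genes, wt_cov, mut_cov,
                                    norm_factor = nf, L = L,
                                    ratio_min = ratio_min, floor = floor)
  calls$group <- group
  class_summary <- do.call(rbind, lapply(unique(group), function(grp) {
    sub <- calls[calls$group == grp, ]
    data.frame(group = grp, n = nrow(sub),
               n_extended = sum(sub$extended),
               extended_fraction = mean(sub$extended),
               stringsAsFactors = FALSE)
  }))
  cr <- NULL
  if (!is.null(clones)) {
    if (is.null(clone_gene_id)) stop("clone_gene_id required with clones")
    gene <- genes[genes$gene_id == clone_gene_id, ]
    cr_calls <- parse_clones(clones, gene, genome)
    cr <- list(calls = cr_calls, summary = summarize_clones(cr_calls))
  }
  out <- list(metagenes = metagenes, norm_factor = nf, calls = calls,
              class_summary = class_summary, crrtpcr = cr)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    .write_tsv(calls, file.path(outdir, "three_prime_calls.tsv"))
    .write_tsv(class_summary, file.path(outdir, "class_summary.tsv"))
    for (grp in names(metagenes)) {
      mg <- metagenes[[grp]]
      .write_tsv(data.frame(offset = mg$offsets, wt = mg$mean$wt,
                            mut_normalized = mg$mean$mut),
                 file.path(outdir, paste0("metagene3_", grp, ".tsv")))
    }
    if (!is.null(cr)) {
      .write_tsv(cr$calls, file.path(outdir, "crrtpcr_calls.tsv"))
    }
    jsonlite::write_json(
      list(norm_factor = nf,
           class_summary = class_summary),
      file.path(outdir, "ends_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")
  }
  out
}
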