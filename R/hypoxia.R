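#' Hypoxia score by median dichotomization
#'
#' For every signature gene present in the expression matrix, the median
#' expression across samples is computed (even n: mean of the two middle
#' values). A sample scores +1 for that gene if its expression is
#' strictly greater than the median, otherwise -1 (ties at the median
#' score -1 by default; set \code{tie_score = 0} to score ties 0). The
#' per-signature score is the sum over the signature's present genes;
#' \code{combined} is the sum over signatures. Genes absent from the
#' matrix are skipped with a log message. Because only the rank of each
#' sample relative to the per-gene median matters, the score is
#' invariant to strictly increasing per-gene transforms of expression.
#'
#' @param expression genes x samples numeric matrix.
#' @param signatures named list of gene-symbol vectors (see
#'   \code{\link{read_gene_signatures}}).
#' @param tie_score score assigned when expression equals the median
#'   exactly: -1 (default) or 0.
#' @return data.frame: sample_id, one column per signature, combined.
#' @export
hypoxia_score <- function(expression, signatures, tie_score = -1) {
  if (ncol(expression) < 2) {
    stop("hypoxia scoring needs at least 2 samples")
  }
  stopifnot(tie_score %in% c(-1, 0))
  out <- data.frame(sample_id = colnames(expression),
                    stringsAsFactors = FALSE)
  for (sig_name in names(signatures)) {
    genes <- signatures[[sig_name]]
    present <- intersect(genes, rownames(expression))
    if (!length(present)) {
      stop("signature '", sig_name,
           "' has no genes present in the expression matrix")
    }
    skipped <- setdiff(genes, present)
    if (length(skipped)) {
      pgin_log("signature '", sig_name, "': ", length(skipped),
               " gene(s) absent from expression matrix, skipped")
    }
    sub <- expression[present, , drop = FALSE]
    med <- apply(sub, 1, stats::median)
    up <- sub > med
    at <- sub == med
    per_gene <- ifelse(up, 1, ifelse(at, tie_score, -1))
    out[[sig_name]] <- colSums(per_gene)
  }
  out$combined <- rowSums(out[, names(signatures), drop = FALSE])
  out
}

#' Synthetic hypoxia signature gene lists
#'
#' Three small synthetic placeholder signatures over the simulator's
#' gene namespace, for testing and demonstration only; real analyses
#' must supply published hypoxia gene lists.
#'
#' @param genes_per_signature genes in each list.
#' @return Named list of three gene-symbol vectors.
#' @export
synthetic_hypoxia_signatures <- function(genes_per_signature = 15) {
  g <- genes_per_signature
  list(
    hypoxia_buffa_syn = paste0("HYPX_A_", seq_len(g)),
    hypoxia_winter_syn = paste0("HYPX_B_", seq_len(g)),
    hypoxia_ragnum_syn = paste0("HYPX_C_", seq_len(g))
  )
}

#' Write hypoxia scores to TSV
#' @param scores data.frame from \code{\link{hypoxia_score}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_hypoxia_scores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
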