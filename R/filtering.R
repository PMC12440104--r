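#' Post-calling quality filter
#'
#' A variant survives iff every present quality metric satisfies its
#' strict inequality: DP > 10, GQ > 20, QD > 5, MQ > 40,
#' ReadPosRankSum > -3, MQRankSum > -10, FS < 200 and QUAL > 50.
#' Missing metrics satisfy their predicate vacuously (RNA-seq callers
#' omit rank-sum statistics at homozygous sites) unless
#' \code{config$strict_missing_quality} is TRUE.
#'
#' @param variants canonical variant data.frame.
#' @param config a \code{\link{pgin_config}}.
#' @return List with \code{variants} (survivors) and \code{tally}
#'   (named integer vector of per-metric failure counts).
#' @export
quality_filter <- function(variants, config = pgin_config()) {
  specs <- list(
    dp = list(op = ">", cut = 10), gq = list(op = ">", cut = 20),
    qd = list(op = ">", cut = 5), mq = list(op = ">", cut = 40),
    read_pos_rank_sum = list(op = ">", cut = -3),
    mq_rank_sum = list(op = ">", cut = -10),
    fs = list(op = "<", cut = 200), qual = list(op = ">", cut = 50))
  n <- nrow(variants)
  keep <- rep(TRUE, n)
  tally <- integer(length(specs))
  names(tally) <- names(specs)
  for (m in names(specs)) {
    x <- variants[[m]]
    ok <- if (specs[[m]]$op == ">") x > specs[[m]]$cut else x < specs[[m]]$cut
    ok[is.na(x)] <- !config$strict_missing_quality
    tally[m] <- sum(!ok)
    keep <- keep & ok
  }
  list(variants = variants[keep, , drop = FALSE], tally = tally)
}

#' Somatic artefact exclusions
#'
#' Removes known RNA-editing sites, low-complexity-region calls, and
#' common variants, as flagged in the input table.
#'
#' @inheritParams quality_filter
#' @return Surviving variants.
#' @export
somatic_exclusions <- function(variants) {
  flagged <- variants$rna_editing_site | variants$low_complexity |
    variants$common_variant
  flagged[is.na(flagged)] <- FALSE
  variants[!flagged, , drop = FALSE]
}

#' Rare-variant filter
#'
#' Retains variants with coverage depth strictly above the preset
#' threshold and population MAX_AF strictly below the rarity threshold
#' (missing MAX_AF counts as rare when \code{missing_af_is_rare}).
#' Cohort-recurrence filters then drop any variant (chrom, pos, ref,
#' alt identity) observed in more than \code{variant_recurrence_max} of
#' samples, and all variants of any gene mutated in more than
#' \code{gene_recurrence_max} of samples. Recurrence denominators are
#' the number of samples in the analysis set.
#'
#' @inheritParams quality_filter
#' @param n_samples number of samples in the analysis set; defaults to
#'   the number of distinct sample_ids in \code{variants}.
#' @return Rare variants (data.frame).
#' @export
rare_filter <- function(variants, config = pgin_config(), n_samples = NULL) {
  if (is.null(n_samples)) {
    n_samples <- length(unique(variants$sample_id))
  }
  if (nrow(variants) && n_samples < 1) {
    stop("rare_filter requires a positive number of samples")
  }
  dp_ok <- variants$dp > config$burden_depth_threshold
  dp_ok[is.na(variants$dp)] <- FALSE
  af_ok <- variants$max_af < config$rare_af_threshold
  af_ok[is.na(variants$max_af)] <- config$missing_af_is_rare
  rare <- variants[dp_ok & af_ok, , drop = FALSE]
  if (!nrow(rare)) return(rare)

  key <- paste(rare$chrom, rare$pos, rare$ref, rare$alt, sep = ":")
  var_frac <- vapply(split(rare$sample_id, key),
                     function(s) length(unique(s)), integer(1)) / n_samples
  rare <- rare[var_frac[key] <= config$variant_recurrence_max, , drop = FALSE]
  if (!nrow(rare)) return(rare)

  gene_frac <- vapply(split(rare$sample_id, rare$gene),
                      function(s) length(unique(s)), integer(1)) / n_samples
  keep_gene <- is.na(rare$gene) |
    gene_frac[rare$gene] <= config$gene_recurrence_max
  rare[keep_gene, , drop = FALSE]
}

#' Damaging-variant filter
#'
#' Under the default \code{union} rule a rare variant is damaging iff
#' (PolyPhen "damaging" OR SIFT "deleterious" OR it is a
#' nonsense/nonstop mutation) AND ClinVar does not assert "benign".
#' Under \code{intersection}, PolyPhen and SIFT must agree (nonsense and
#' nonstop still qualify on their own); the benign veto applies in both.
#'
#' @param rare_variants rare variants from \code{\link{rare_filter}}.
#' @inheritParams quality_filter
#' @return Rare damaging variants (data.frame).
#' @export
damaging_filter <- function(rare_variants, config = pgin_config()) {
  v <- rare_variants
  truncating <- !is.na(v$classification) &
    v$classification %in% c("nonsense", "nonstop")
  pp <- !is.na(v$polyphen) & v$polyphen == "damaging"
  sf <- !is.na(v$sift) & v$sift == "deleterious"
  impact <- if (config$damaging_rule == "union") pp | sf | truncating
            else (pp & sf) | truncating
  benign <- !is.na(v$clinvar_sig) & v$clinvar_sig == "benign"
  v[impact & !benign, , drop = FALSE]
}

#' Run the full filter cascade
#'
#' Stages in order: quality, somatic exclusions, rarity (depth, MAX_AF
#' and cohort recurrence), then damaging classification. Summary counts
#' of rare and rare-damaging variants and their unique genes are
#' reported alongside the surviving sets.
#'
#' @inheritParams rare_filter
#' @return A list of class \code{"filter_cascade"} with elements
#'   \code{quality_pass}, \code{somatic}, \code{rare}, \code{rare_damaging}
#'   (data.frames), \code{quality_tally} and \code{summary}
#'   (n_input, n_quality_pass, n_somatic, n_rare, n_rare_damaging,
#'   n_rare_genes, n_rare_damaging_genes).
#' @export
run_cascade <- function(variants, config = pgin_config(), n_samples = NULL) {
  if (is.null(n_samples)) n_samples <- length(unique(variants$sample_id))
  q <- quality_filter(variants, config)
  s <- somatic_exclusions(q$variants)
  r <- rare_filter(s, config, n_samples = n_samples)
  d <- damaging_filter(r, config)
  summary <- c(
    n_input = nrow(variants),
    n_quality_pass = nrow(q$variants),
    n_somatic = nrow(s),
    n_rare = nrow(r),
    n_rare_damaging = nrow(d),
    n_rare_genes = length(unique(stats::na.omit(r$gene))),
    n_rare_damaging_genes = length(unique(stats::na.omit(d$gene))))
  structure(list(quality_pass = q$variants, somatic = s, rare = r,
                 rare_damaging = d, quality_tally = q$tally,
                 summary = summary, n_samples = n_samples,
                 config = config),
            class = "filter_cascade")
}

#' @export
print.filter_cascade <- function(x, ...) {
  cat("Filter cascade over", x$n_samples, "sample(s)\n")
  s <- x$summary
  cat(sprintf("  input: %d  quality-pass: %d  post-exclusion: %d\n",
              s[["n_input"]], s[["n_quality_pass"]], s[["n_somatic"]]))
  cat(sprintf("  rare: %d in %d genes; rare damaging: %d in %d genes\n",
              s[["n_rare"]], s[["n_rare_genes"]],
              s[["n_rare_damaging"]], s[["n_rare_damaging_genes"]]))
  invisible(x)
}
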