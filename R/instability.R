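#' Size of the capture region at a depth threshold
#'
#' The capture region of a sample is the set of genome positions whose
#' sequencing depth reaches the threshold; its size is the sum of the
#' depth-histogram counts over all depths >= \code{depth_threshold}.
#'
#' @param profile a \code{coverage_profile}.
#' @param depth_threshold minimum depth (reads).
#' @return Number of positions covered at or above the threshold.
#' @export
covered_region_size <- function(profile, depth_threshold) {
  depths <- as.numeric(names(profile$depth_hist))
  sum(profile$depth_hist[depths >= depth_threshold])
}

#' Genomic instability: expressed mutational burden per covered megabase
#'
#' The per-sample genomic-instability score is the number of expressed
#' rare somatic variants divided by the megabases of the sample's own
#' capture region at the configured depth threshold (50x for placental
#' RNA, 10x for circulating RNA). Indels count by default; set
#' \code{config$snv_only} to restrict to SNVs.
#'
#' @param rare_variants the sample's rare variants (data.frame).
#' @param profile the sample's \code{coverage_profile}.
#' @param config a \code{\link{pgin_config}}.
#' @return A one-row data.frame: sample_id, n_rare_variants,
#'   covered_bases, depth_threshold, burden (variants per Mb).
#' @export
instability <- function(rare_variants, profile, config = pgin_config()) {
  v <- rare_variants
  if (config$snv_only) v <- v[v$variant_type == "SNV", , drop = FALSE]
  covered <- covered_region_size(profile, config$burden_depth_threshold)
  if (covered <= 0) {
    stop("sample ", profile$sample_id,
         " has no positions covered at >= ", config$burden_depth_threshold,
         "x; instability is undefined (coverage QC failure)")
  }
  data.frame(sample_id = profile$sample_id,
             n_rare_variants = nrow(v),
             covered_bases = covered,
             depth_threshold = config$burden_depth_threshold,
             burden = nrow(v) / (covered / 1e6),
             stringsAsFactors = FALSE)
}

#' Genomic instability for a cohort
#'
#' @param rare_variants rare variants for all samples (data.frame with
#'   sample_id).
#' @param profiles named list of \code{coverage_profile}s (one per
#'   sample; names are sample ids).
#' @param config a \code{\link{pgin_config}}.
#' @return data.frame with one row per profile, as in
#'   \code{\link{instability}}. Samples without variants get burden 0.
#' @export
instability_scores <- function(rare_variants, profiles,
                               config = pgin_config()) {
  rows <- lapply(profiles, function(p) {
    v <- rare_variants[rare_variants$sample_id == p$sample_id, ,
                       drop = FALSE]
    instability(v, p, config)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
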