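.PRESETS <- list(
  placental_rna = list(burden_depth_threshold = 50),
  circulating_rna = list(burden_depth_threshold = 10),
  wgs_cell_line = list(burden_depth_threshold = 30,
                       variant_recurrence_max = 0.33)
)

#' Run configuration
#'
#' Builds a validated configuration object. Presets encode the depth
#' threshold appropriate to each assay: placental RNA uses depth > 50,
#' circulating RNA depth > 10, and WGS cell lines depth > 30 with a 33%
#' cohort-recurrence cap.
#'
#' @param preset one of \code{"placental_rna"}, \code{"circulating_rna"},
#'   \code{"wgs_cell_line"}.
#' @param burden_depth_threshold integer depth threshold for the variant
#'   depth filter and the covered-region denominator.
#' @param rare_af_threshold variants with population MAX_AF strictly below
#'   this are rare (default 0.01).
#' @param variant_recurrence_max drop a variant seen in more than this
#'   fraction of samples (default 0.70).
#' @param gene_recurrence_max drop all variants of a gene mutated in more
#'   than this fraction of samples (default 0.50).
#' @param damaging_rule \code{"union"} (PolyPhen damaging OR SIFT
#'   deleterious) or \code{"intersection"} (both required).
#' @param missing_af_is_rare treat variants absent from population
#'   catalogs (missing MAX_AF) as rare (default TRUE).
#' @param strict_missing_quality if TRUE, a missing quality metric fails
#'   its predicate instead of being vacuously satisfied.
#' @param snv_only if TRUE, the burden counts SNVs only (default counts
#'   SNVs and indels).
#' @param seed integer seed used by stochastic stages.
#' @param hypoxia_signature_path optional path to a signature gene-list TSV.
#' @param reference_signature_path optional path to a reference SBS TSV.
#' @return A list of class \code{"pgin_config"}.
#' @export
pgin_config <- function(preset = "placental_rna",
                        burden_depth_threshold = NULL,
                        rare_af_threshold = 0.01,
                        variant_recurrence_max = NULL,
                        gene_recurrence_max = 0.5,
                        damaging_rule = c("union", "intersection"),
                        missing_af_is_rare = TRUE,
                        strict_missing_quality = FALSE,
                        snv_only = FALSE,
                        seed = 1L,
                        hypoxia_signature_path = NULL,
                        reference_signature_path = NULL) {
  if (!preset %in% names(.PRESETS)) {
    stop("unknown preset '", preset, "'; expected one of: ",
         paste(names(.PRESETS), collapse = ", "))
  }
  damaging_rule <- match.arg(damaging_rule)
  p <- .PRESETS[[preset]]
  if (is.null(burden_depth_threshold)) {
    burden_depth_threshold <- p$burden_depth_threshold
  }
  if (is.null(variant_recurrence_max)) {
    variant_recurrence_max <- if (is.null(p$variant_recurrence_max)) 0.7
                              else p$variant_recurrence_max
  }
  stopifnot(burden_depth_threshold > 0,
            rare_af_threshold > 0, rare_af_threshold <= 1,
            variant_recurrence_max > 0, variant_recurrence_max <= 1,
            gene_recurrence_max > 0, gene_recurrence_max <= 1)
  structure(list(
    preset = preset,
    burden_depth_threshold = as.integer(burden_depth_threshold),
    rare_af_threshold = rare_af_threshold,
    variant_recurrence_max = variant_recurrence_max,
    gene_recurrence_max = gene_recurrence_max,
    damaging_rule = damaging_rule,
    missing_af_is_rare = isTRUE(missing_af_is_rare),
    strict_missing_quality = isTRUE(strict_missing_quality),
    snv_only = isTRUE(snv_only),
    seed = as.integer(seed),
    hypoxia_signature_path = hypoxia_signature_path,
    reference_signature_path = reference_signature_path
  ), class = "pgin_config")
}

#' Load a run configuration from a YAML file
#'
#' Unspecified fields take the preset's defaults.
#'
#' @param path YAML file with at least a \code{preset} key.
#' @return A \code{pgin_config} object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$preset)) raw$preset <- "placental_rna"
  known <- names(formals(pgin_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pgin_config, raw)
}
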