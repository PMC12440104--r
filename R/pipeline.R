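#' Run pipeline stages over a cohort directory
#'
#' Reads the cohort inputs (variants.tsv, coverage_<sample>.tsv,
#' expression.tsv, metadata.csv) from \code{in_dir}, runs the requested
#' stages and writes tidy TSV outputs to \code{out_dir}. Stage
#' \code{"simulate"} instead generates the inputs into \code{in_dir}
#' from \code{spec}. Stage \code{"all"} runs simulate (if no inputs
#' exist yet) followed by every analysis stage. All stochastic stages
#' are seeded from \code{config$seed}, so repeated runs produce
#' byte-identical outputs.
#'
#' @param stages character vector from \{simulate, filter, burden,
#'   signatures, hypoxia, associate, predict, all\}.
#' @param config a \code{\link{pgin_config}}.
#' @param in_dir directory of cohort inputs.
#' @param out_dir directory for outputs (created).
#' @param spec \code{\link{simulation_spec}} used by the simulate stage.
#' @param signature_rank K for signature extraction (default 3).
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(stages = "all", config = pgin_config(),
                         in_dir, out_dir, spec = NULL,
                         signature_rank = 3) {
  all_stages <- c("filter", "burden", "signatures", "hypoxia",
                  "associate", "predict")
  if ("all" %in% stages) {
    stages <- c(if (!file.exists(file.path(in_dir, "variants.tsv")))
      "simulate", all_stages)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()

  if ("simulate" %in% stages) {
    if (is.null(spec)) spec <- simulation_spec(seed = config$seed)
    bundle <- simulate_cohort(spec, config)
    write_cohort(bundle, in_dir)
    pgin_log("simulate: wrote ", nrow(bundle$variants), " variants for ",
             nrow(bundle$metadata), " samples")
    res$simulate <- bundle
  }

  needs_inputs <- length(intersect(stages, all_stages)) > 0
  if (!needs_inputs) return(invisible(res))

  variants <- read_variant_table(file.path(in_dir, "variants.tsv"))
  metadata <- derive_groups(read_metadata(file.path(in_dir, "metadata.csv")))
  samples <- metadata$sample_id
  cov_files <- file.path(in_dir, paste0("coverage_", samples, ".tsv"))
  profiles <- lapply(seq_along(samples), function(i) {
    read_coverage(cov_files[i], sample_id = samples[i])
  })
  names(profiles) <- samples

  cascade <- run_cascade(variants, config, n_samples = length(samples))
  if ("filter" %in% stages) {
    write_variant_table(cascade$rare, file.path(out_dir, "rare_variants.tsv"))
    write_variant_table(cascade$rare_damaging,
                        file.path(out_dir, "rare_damaging_variants.tsv"))
    utils::write.table(
      data.frame(stage = names(cascade$summary),
                 count = as.integer(cascade$summary)),
      file.path(out_dir, "filter_summary.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    pgin_log("filter: ", cascade$summary[["n_rare"]], " rare / ",
             cascade$summary[["n_rare_damaging"]], " rare-damaging variants")
  }
  res$filter <- cascade

  scores <- instability_scores(cascade$rare, profiles, config)
  if ("burden" %in% stages) {
    utils::write.table(format(scores, digits = 10, trim = TRUE,
                              scientific = FALSE),
                       file.path(out_dir, "instability.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pgin_log("burden: median ", round(stats::median(scores$burden), 3),
             " variants/Mb over ", nrow(scores), " samples")
  }
  res$burden <- scores

  if ("signatures" %in% stages) {
    catalog <- build_catalog(cascade$rare, samples = samples)
    nonzero <- colSums(catalog) > 0
    sigset <- extract_signatures(catalog[, nonzero, drop = FALSE],
                                 rank = signature_rank,
                                 seed = config$seed)
    reference <- if (!is.null(config$reference_signature_path)) {
      read_reference_signatures(config$reference_signature_path)
    } else synthetic_reference_signatures()
    matches <- match_to_reference(sigset, reference)
    contrib <- group_contributions(sigset, metadata, "group")
    write_catalog(catalog, file.path(out_dir, "catalog.tsv"))
    write_catalog(sigset$signatures, file.path(out_dir, "signatures.tsv"))
    utils::write.table(data.frame(sample_id = rownames(sigset$exposures),
                                  sigset$exposures, check.names = FALSE),
                       file.path(out_dir, "exposures.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(matches, file.path(out_dir, "reference_matches.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(group = rownames(contrib), contrib,
                                  check.names = FALSE),
                       file.path(out_dir, "group_contributions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pgin_log("signatures: K=", signature_rank, ", best matches ",
             paste(matches$reference, collapse = ", "))
    res$signatures <- list(catalog = catalog, signature_set = sigset,
                           matches = matches, contributions = contrib)
  }

  expression <- read_expression(file.path(in_dir, "expression.tsv"))
  sig_lists <- if (!is.null(config$hypoxia_signature_path)) {
    read_gene_signatures(config$hypoxia_signature_path)
  } else synthetic_hypoxia_signatures()
  hyp <- hypoxia_score(expression, sig_lists)
  if ("hypoxia" %in% stages) {
    write_hypoxia_scores(hyp, file.path(out_dir, "hypoxia_scores.tsv"))
    pgin_log("hypoxia: scored ", nrow(hyp), " samples over ",
             length(sig_lists), " signatures")
  }
  res$hypoxia <- hyp

  tab <- metadata
  tab$burden <- scores$burden[match(tab$sample_id, scores$sample_id)]
  tab$hypoxia <- hyp$combined[match(tab$sample_id, hyp$sample_id)]
  res$table <- tab

  if ("associate" %in% stages) {
    cmp <- compare_groups(tab$burden, tab$group)
    cmp$feature <- "burden"
    cmp2 <- compare_groups(tab$hypoxia, tab$group)
    cmp2$feature <- "hypoxia"
    utils::write.table(rbind(cmp, cmp2),
                       file.path(out_dir, "group_comparisons.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cox <- fit_cox(tab, features = c("burden", "hypoxia"),
                   event = "pe", seed = config$seed)
    coef_tab <- data.frame(feature = cox$features,
                           coef = cox$coefficients,
                           hazard_ratio = cox$hazard_ratios,
                           ci_low = cox$ci_low, ci_high = cox$ci_high,
                           p_value = cox$p_values,
                           penalizer = cox$penalizer, row.names = NULL)
    utils::write.table(coef_tab, file.path(out_dir, "cox_pe.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    curves <- partial_effect_curves(cox, cox$features[1])
    utils::write.table(curves, file.path(out_dir, "cox_pe_curves.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pgin_log("associate: Cox HR(burden) = ",
             round(cox$hazard_ratios[1], 3))
    res$associate <- list(comparisons = rbind(cmp, cmp2), cox = cox)
  }

  if ("predict" %in% stages) {
    feats <- list(c("burden", "hypoxia"),
                  c("burden", "hypoxia", "fetal_sex"),
                  c("burden", "hypoxia", "fetal_sex", "maternal_age"))
    cv <- cross_validate(tab, "pe", feats, seed = config$seed)
    metrics <- data.frame(
      feature_set = names(cv),
      auc = vapply(cv, `[[`, numeric(1), "auc"),
      accuracy = vapply(cv, `[[`, numeric(1), "accuracy"),
      row.names = NULL)
    utils::write.table(metrics, file.path(out_dir, "knn_metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    best <- cv[[attr(cv, "ranking")[1]]]
    utils::write.table(best$roc_points, file.path(out_dir, "knn_roc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pgin_log("predict: best feature set ",
             paste(best$features, collapse = "+"),
             " AUC ", round(best$auc, 3))
    res$predict <- cv
  }

  invisible(res)
}
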