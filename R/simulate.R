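#' Specification for a synthetic cohort
#'
#' Defaults mirror the discovery-cohort structure the pipeline targets:
#' 112 placentas in four clinical groups (23 EP-N, 30 NTT-N, 20 EP-PE,
#' 39 NTT-PE), a doubled rare-variant rate in EP-PE, group-specific SBS
#' signature mixtures (EP-PE dominated by the oxidative-damage-like
#' profile, EP-N by the flat endogenous profile), an up-shift of the
#' hypoxia signature genes in all groups except NTT-N, and a
#' proportional-hazards structure on gestational age at delivery with a
#' planted log hazard ratio of ln(1.7) per unit burden.
#'
#' Two generation modes exist. When \code{group_scheme} is a named
#' vector of group sizes (the default), groups are assigned exactly and
#' gestational ages are drawn within each group's window. When
#' \code{group_scheme = NULL}, gestational age and the preeclampsia
#' event are drawn from an exponential-baseline proportional-hazards
#' model using the planted log hazard ratios, and groups are derived —
#' this is the mode used for Cox parameter-recovery checks.
#'
#' @param n_samples cohort size (used when \code{group_scheme} is NULL).
#' @param seed integer master seed; per-component substreams are derived
#'   from it so stages can be regenerated independently.
#' @param group_scheme named integer vector of group sizes over
#'   EP-N/NTT-N/EP-PE/NTT-PE, or NULL for hazard-driven generation.
#' @param mean_variants_per_sample Poisson mean of called variants.
#' @param frac_rare fraction of variants drawn with MAX_AF < 0.01.
#' @param frac_damaging_of_rare fraction of rare variants annotated as
#'   protein-damaging.
#' @param frac_fail_quality fraction of variants planted to fail exactly
#'   one of the eight quality predicates.
#' @param frac_artifact fraction flagged as RNA-editing / low-complexity
#'   / common-variant artefacts.
#' @param frac_shallow fraction of otherwise clean variants with depth
#'   between 11 and the burden threshold (pass quality, fail rarity
#'   depth).
#' @param covered_mb_range megabases of the capture region, drawn
#'   uniformly per sample.
#' @param signature_mixture named list (one entry per group, or a
#'   single "all" entry) of exposure vectors over the reference
#'   signatures; each sums to 1.
#' @param rare_rate_multiplier named vector of per-group multipliers on
#'   the rare-variant rate.
#' @param mutations_per_catalog mutations per sample used by
#'   \code{\link{simulate_catalog}} driven tests.
#' @param hypoxia_gene_sets named list of gene vectors planted as
#'   up-shifted in affected samples.
#' @param hypoxia_shift log2-fold up-shift of hypoxia genes in affected
#'   samples.
#' @param n_background_genes background genes in the expression matrix.
#' @param true_log_hr_instability,true_log_hr_hypoxia planted log hazard
#'   ratios per unit of burden and of hypoxia score.
#' @param baseline_hazard exponential baseline hazard (per week past
#'   \code{censor_week_min}).
#' @param censor_week_min,censor_week_max gestational-age window; non-
#'   events are censored at the maximum.
#' @param vaf_shape1,vaf_shape2 Beta parameters for variant allele
#'   fraction.
#' @return List of class \code{"simulation_spec"}.
#' @export
simulation_spec <- function(
    n_samples = 112,
    seed = 1,
    group_scheme = c("EP-N" = 23, "NTT-N" = 30, "EP-PE" = 20,
                     "NTT-PE" = 39),
    mean_variants_per_sample = 150,
    frac_rare = 0.35,
    frac_damaging_of_rare = 0.25,
    frac_fail_quality = 0.15,
    frac_artifact = 0.10,
    frac_shallow = 0.15,
    covered_mb_range = c(30, 60),
    signature_mixture = list(
      "EP-N"   = c(0.15, 0.60, 0.20, 0.05),
      "NTT-N"  = c(0.35, 0.20, 0.40, 0.05),
      "EP-PE"  = c(0.10, 0.15, 0.60, 0.15),
      "NTT-PE" = c(0.30, 0.20, 0.45, 0.05)),
    rare_rate_multiplier = c("EP-N" = 1, "NTT-N" = 1, "EP-PE" = 2,
                             "NTT-PE" = 1),
    mutations_per_catalog = 2000,
    hypoxia_gene_sets = synthetic_hypoxia_signatures(),
    hypoxia_shift = 1.5,
    n_background_genes = 400,
    true_log_hr_instability = log(1.7),
    true_log_hr_hypoxia = 0.024,
    baseline_hazard = 0.08,
    censor_week_min = 20,
    censor_week_max = 42,
    vaf_shape1 = 2, vaf_shape2 = 2) {
  spec <- as.list(environment())
  fr <- c(spec$frac_rare, spec$frac_damaging_of_rare,
          spec$frac_fail_quality, spec$frac_artifact, spec$frac_shallow)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (!is.null(group_scheme)) {
    if (is.null(names(group_scheme)) ||
        !all(names(group_scheme) %in%
               c("EP-N", "NTT-N", "EP-PE", "NTT-PE"))) {
      stop("group_scheme must be named over EP-N/NTT-N/EP-PE/NTT-PE")
    }
    spec$n_samples <- sum(group_scheme)
  }
  if (spec$n_samples < 2) stop("n_samples must be at least 2")
  for (mx in signature_mixture) {
    if (abs(sum(mx) - 1) > 1e-8) stop("signature mixtures must sum to 1")
  }
  structure(spec, class = "simulation_spec")
}

# substream seeds derived from the master seed (kept below 2^31)
.substream <- function(seed, offset) {
  as.integer((as.numeric(seed) * 97 + offset * 1009) %% 2147483647)
}

#' Simulate one 96-channel catalog column from a signature mixture
#'
#' Draws \code{n_mutations} channel assignments from the multinomial
#' distribution given by \code{reference \%*\% mixture}.
#'
#' @param mixture exposure vector summing to 1 (one weight per
#'   reference signature).
#' @param n_mutations total mutations to draw.
#' @param reference 96 x K probability matrix.
#' @param seed integer seed.
#' @return Integer vector of 96 channel counts (sums to
#'   \code{n_mutations}).
#' @export
simulate_catalog <- function(mixture, n_mutations,
                             reference = synthetic_reference_signatures(),
                             seed = 1) {
  if (length(mixture) != ncol(reference)) {
    stop("mixture length must equal the number of reference signatures")
  }
  if (abs(sum(mixture) - 1) > 1e-8) stop("mixture must sum to 1")
  p <- as.vector(reference %*% mixture)
  old <- .rng_state_save(); on.exit(.rng_state_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  counts <- as.vector(stats::rmultinom(1, n_mutations, p))
  names(counts) <- rownames(reference)
  counts
}

# decompose a channel label into (ref, alt, flank5, flank3)
.channel_parts <- function(channel) {
  data.frame(context5 = substr(channel, 1, 1),
             ref = substr(channel, 3, 3),
             alt = substr(channel, 5, 5),
             context3 = substr(channel, 7, 7),
             stringsAsFactors = FALSE)
}

# vectorized variant generation for the whole cohort; channel_probs is
# a list: probs (96 x n_mixtures channel distributions) and
# mix_of_sample (mixture index per sample)
.simulate_variants_all <- function(ids, n_var, spec, channel_probs,
                                   config) {
  thr <- config$burden_depth_threshold
  N <- sum(n_var)
  sidx <- rep(seq_along(ids), n_var)
  if (N == 0) {
    empty <- as_variant_table(
      data.frame(sample_id = character(), chrom = character(),
                 pos = integer(), ref = character(), alt = character(),
                 gene = character()))
    return(list(variants = empty,
                n_rare = integer(length(ids)),
                n_rare_damaging = integer(length(ids))))
  }
  fail_q <- stats::runif(N) < spec$frac_fail_quality
  artifact <- stats::runif(N) < spec$frac_artifact
  shallow <- stats::runif(N) < spec$frac_shallow
  is_rare_af <- stats::runif(N) < spec$frac_rare
  dmg <- is_rare_af & (stats::runif(N) < spec$frac_damaging_of_rare)

  # quality metrics on the passing side
  dp <- thr + stats::rpois(N, 40) + 1
  dp[shallow] <- 11 + floor(stats::runif(sum(shallow)) * (thr - 11))
  gq <- stats::runif(N, 30, 99)
  qd <- stats::runif(N, 6, 30)
  mq <- stats::runif(N, 41, 60)
  rprs <- stats::runif(N, -2, 2)
  mqrs <- stats::runif(N, -5, 5)
  fs <- stats::runif(N, 0, 50)
  qual <- stats::runif(N, 60, 1000)
  # rank-sum statistics are missing at a realistic rate
  rprs[stats::runif(N) < 0.1] <- NA
  mqrs[stats::runif(N) < 0.1] <- NA

  # planted quality failures: one metric pushed over its threshold
  which_m <- sample(8, N, replace = TRUE)
  fm <- function(m) which(fail_q & which_m == m)
  i <- fm(1); dp[i] <- sample(1:10, length(i), replace = TRUE)
  i <- fm(2); gq[i] <- stats::runif(length(i), 0, 20)
  i <- fm(3); qd[i] <- stats::runif(length(i), 0, 5)
  i <- fm(4); mq[i] <- stats::runif(length(i), 0, 40)
  i <- fm(5); rprs[i] <- stats::runif(length(i), -10, -3.001)
  i <- fm(6); mqrs[i] <- stats::runif(length(i), -20, -10.001)
  i <- fm(7); fs[i] <- stats::runif(length(i), 200.001, 400)
  i <- fm(8); qual[i] <- stats::runif(length(i), 0, 50)

  max_af <- stats::runif(N, 0.02, 0.5)
  max_af[is_rare_af] <- stats::runif(sum(is_rare_af), 0, 0.0099)
  max_af[is_rare_af & stats::runif(N) < 0.3] <- NA

  flag_kind <- sample(3, N, replace = TRUE)
  rna_edit <- artifact & flag_kind == 1
  lowc <- artifact & flag_kind == 2
  common <- artifact & flag_kind == 3

  is_snv <- stats::runif(N) < 0.9
  # per-variant channel draw from the owning sample's distribution;
  # samples share one of a few group mixtures, so draw group-wise
  chan <- integer(N)
  vmix <- channel_probs$mix_of_sample[sidx]
  for (m in unique(vmix)) {
    idx <- which(vmix == m)
    chan[idx] <- sample(96, length(idx), replace = TRUE,
                        prob = channel_probs$probs[, m])
  }
  parts <- .channel_parts(sbs_channels()[chan])
  ref <- parts$ref; alt <- parts$alt
  c5 <- parts$context5; c3 <- parts$context3
  # report half the SNVs on the purine strand to exercise the
  # reverse-complement mapping
  flip <- is_snv & stats::runif(N) < 0.5
  if (any(flip)) {
    nr <- complement_base(ref[flip]); na_ <- complement_base(alt[flip])
    n5 <- complement_base(c3[flip]); n3 <- complement_base(c5[flip])
    ref[flip] <- nr; alt[flip] <- na_; c5[flip] <- n5; c3[flip] <- n3
  }
  ins <- !is_snv & stats::runif(N) < 0.5
  ref[!is_snv] <- "A"
  alt[!is_snv & ins] <- "AT"
  ref[!is_snv & !ins] <- "AT"
  alt[!is_snv & !ins] <- "A"
  c5[!is_snv] <- NA; c3[!is_snv] <- NA

  classification <- ifelse(is_snv, "missense", "frameshift")
  polyphen <- sample(c("benign", "possibly_damaging", NA), N,
                     replace = TRUE, prob = c(0.4, 0.2, 0.4))
  sift <- sample(c("tolerated", NA), N, replace = TRUE)
  clinvar <- rep(NA_character_, N)
  di <- which(dmg)
  trunc_d <- stats::runif(length(di)) < 0.25
  classification[di[trunc_d]] <- sample(c("nonsense", "nonstop"),
                                        sum(trunc_d), replace = TRUE)
  polyphen[di[!trunc_d]] <- "damaging"
  sift[di[!trunc_d]] <- ifelse(stats::runif(sum(!trunc_d)) < 0.7,
                               "deleterious", NA)
  # a few non-damaging variants carry damaging in-silico labels vetoed
  # by a benign ClinVar assertion
  veto <- which(!dmg & is_rare_af & stats::runif(N) < 0.05)
  polyphen[veto] <- "damaging"
  clinvar[veto] <- "benign"

  vaf <- stats::rbeta(N, spec$vaf_shape1, spec$vaf_shape2)
  alt_count <- pmin(round(vaf * dp), dp)
  ref_count <- dp - alt_count

  v <- data.frame(
    sample_id = ids[sidx],
    chrom = paste0("chr", sample(1:22, N, replace = TRUE)),
    pos = sample.int(1e8, N, replace = TRUE),
    ref = ref, alt = alt,
    gene = sprintf("GENE%04d", sample.int(2000, N, replace = TRUE)),
    classification = classification, variant_type = NA,
    dp = dp, gq = gq, qd = qd, mq = mq,
    read_pos_rank_sum = rprs, mq_rank_sum = mqrs, fs = fs, qual = qual,
    max_af = max_af, polyphen = polyphen, sift = sift,
    clinvar_sig = clinvar, alt_count = alt_count, ref_count = ref_count,
    context5 = c5, context3 = c3,
    rna_editing_site = rna_edit, low_complexity = lowc,
    common_variant = common,
    stringsAsFactors = FALSE)
  clean <- !fail_q & !artifact & !shallow
  tally <- function(keep) {
    as.integer(tabulate(sidx[keep], nbins = length(ids)))
  }
  list(variants = as_variant_table(v),
       n_rare = tally(clean & is_rare_af),
       n_rare_damaging = tally(clean & dmg))
}

#' Simulate a complete synthetic cohort
#'
#' Generates variants, per-sample coverage histograms, an expression
#' matrix, cohort metadata and a truth object holding every planted
#' parameter. Fully reproducible from the spec's seed.
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @param config a \code{\link{pgin_config}} fixing the depth preset the
#'   coverage and depth draws respect.
#' @param reference reference signature matrix for context generation.
#' @return List of class \code{"cohort_bundle"}: \code{variants}
#'   (canonical data.frame), \code{profiles} (named list of
#'   coverage_profile), \code{expression} (genes x samples matrix),
#'   \code{metadata} (data.frame with groups derived), \code{truth}.
#' @export
simulate_cohort <- function(spec = simulation_spec(),
                            config = pgin_config(),
                            reference = synthetic_reference_signatures()) {
  stopifnot(inherits(spec, "simulation_spec"))
  old <- .rng_state_save(); on.exit(.rng_state_restore(old), add = TRUE)
  n <- spec$n_samples
  ids <- sprintf("S%03d", seq_len(n))
  hazard_mode <- is.null(spec$group_scheme)

  # --- metadata substream -------------------------------------------------
  set.seed(.substream(spec$seed, 1))
  if (!hazard_mode) {
    group <- rep(names(spec$group_scheme), spec$group_scheme)
    ga <- ifelse(grepl("^EP", group),
                 stats::runif(n, spec$censor_week_min + 3, 33.9),
                 stats::runif(n, 34.1, spec$censor_week_max - 0.5))
    pe <- grepl("PE$", group)
  } else {
    group <- NULL  # derived after survival draw
    pe <- NULL
    ga <- NULL
  }
  fetal_sex <- sample(c("male", "female"), n, replace = TRUE)
  maternal_age <- pmin(pmax(round(stats::rnorm(n, 30, 5)), 18), 45)

  # --- coverage substream -------------------------------------------------
  set.seed(.substream(spec$seed, 2))
  thr <- config$burden_depth_threshold
  covered <- round(stats::runif(n, spec$covered_mb_range[1],
                                spec$covered_mb_range[2]) * 1e6)
  profiles <- lapply(seq_len(n), function(i) {
    at_thr <- round(covered[i] * 0.6)
    hist <- c(covered[i] * 2, at_thr, covered[i] - at_thr)
    names(hist) <- c(max(1, thr %/% 5), thr, thr + 25)
    coverage_profile(ids[i], hist)
  })
  names(profiles) <- ids

  # --- variant substream --------------------------------------------------
  set.seed(.substream(spec$seed, 3))
  mult <- if (hazard_mode) {
    stats::rlnorm(n, 0, 0.5)
  } else {
    unname(spec$rare_rate_multiplier[group])
  }
  n_var <- stats::rpois(n, spec$mean_variants_per_sample * mult)
  if (hazard_mode || is.null(names(spec$signature_mixture))) {
    mix_of_sample <- rep(1L, n)
    mix_mat <- matrix(spec$signature_mixture[[1]], ncol = 1)
  } else {
    mix_names <- names(spec$signature_mixture)
    mix_of_sample <- match(group, mix_names)
    mix_mat <- do.call(cbind, spec$signature_mixture)
  }
  channel_probs <- list(probs = reference %*% mix_mat,
                        mix_of_sample = mix_of_sample)
  sim <- .simulate_variants_all(ids, n_var, spec, channel_probs, config)
  variants <- sim$variants
  planted_rare <- sim$n_rare
  planted_dmg <- sim$n_rare_damaging
  planted_burden <- planted_rare / (covered / 1e6)

  # --- expression substream ----------------------------------------------
  set.seed(.substream(spec$seed, 4))
  hyp_genes <- unique(unlist(spec$hypoxia_gene_sets))
  genes <- c(hyp_genes, sprintf("BG_%04d", seq_len(spec$n_background_genes)))
  gene_mean <- stats::rnorm(length(genes), 8, 2)
  expr <- matrix(stats::rnorm(length(genes) * n, 0, 1),
                 nrow = length(genes),
                 dimnames = list(genes, ids)) + gene_mean
  if (hazard_mode) {
    hypoxia_affected <- stats::runif(n) < 0.5
  } else {
    hypoxia_affected <- group != "NTT-N"
  }
  expr[hyp_genes, hypoxia_affected] <-
    expr[hyp_genes, hypoxia_affected] + spec$hypoxia_shift
  planted_hyp <- hypoxia_score(expr, spec$hypoxia_gene_sets)$combined

  # --- survival substream -------------------------------------------------
  set.seed(.substream(spec$seed, 5))
  if (hazard_mode) {
    lp <- spec$true_log_hr_instability * planted_burden +
      spec$true_log_hr_hypoxia * planted_hyp
    lp <- lp - mean(lp)
    t_raw <- stats::rexp(n, rate = spec$baseline_hazard * exp(lp))
    ga <- spec$censor_week_min + t_raw
    event <- ga <= spec$censor_week_max
    ga[!event] <- spec$censor_week_max
    pe <- event
  } else {
    lp <- rep(NA_real_, n)
    event <- pe
  }
  p_mvm <- ifelse(pe, 0.47, 0.19)
  mvm <- stats::runif(n) < p_mvm
  p_sga <- ifelse(pe, 0.76, 0.05)
  sga <- stats::runif(n) < p_sga

  metadata <- derive_groups(data.frame(
    sample_id = ids, ga_weeks = ga, pe = pe, mvm = mvm, sga = sga,
    fetal_sex = fetal_sex, maternal_age = maternal_age,
    stringsAsFactors = FALSE))
  if (!hazard_mode) metadata$group <- group

  truth <- list(
    spec = spec, mode = if (hazard_mode) "hazard" else "fixed_groups",
    per_sample = data.frame(
      sample_id = ids, group = metadata$group,
      n_variants = n_var, planted_rare = planted_rare,
      planted_rare_damaging = planted_dmg,
      covered_bases = covered, planted_burden = planted_burden,
      hypoxia_affected = hypoxia_affected,
      planted_hypoxia = planted_hyp,
      linear_predictor = lp, event = event,
      stringsAsFactors = FALSE),
    true_log_hr_instability = spec$true_log_hr_instability,
    true_log_hr_hypoxia = spec$true_log_hr_hypoxia,
    signature_mixture = spec$signature_mixture)

  structure(list(variants = variants, profiles = profiles,
                 expression = expr, metadata = metadata, truth = truth),
            class = "cohort_bundle")
}

#' Write a simulated cohort bundle to a directory
#'
#' Emits variants.tsv, coverage_<sample>.tsv (2-column depth histogram
#' dialect), expression.tsv, metadata.csv and truth_per_sample.tsv.
#'
#' @param bundle a \code{cohort_bundle}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_variant_table(bundle$variants, file.path(dir, "variants.tsv"))
  for (p in bundle$profiles) {
    utils::write.table(
      data.frame(depth = as.numeric(names(p$depth_hist)),
                 count = as.numeric(p$depth_hist)),
      file.path(dir, paste0("coverage_", p$sample_id, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  write_expression(bundle$expression, file.path(dir, "expression.tsv"))
  utils::write.csv(bundle$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  utils::write.table(bundle$truth$per_sample,
                     file.path(dir, "truth_per_sample.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
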