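#' Derive clinical groups from metadata
#'
#' Early preterm (EP) is a gestational age at delivery strictly below 34
#' weeks; combined with the preeclampsia flag this yields the four
#' groups EP-N, NTT-N, EP-PE and NTT-PE.
#'
#' @param metadata data.frame with at least sample_id, ga_weeks, pe.
#' @return The metadata with added logical \code{ep} and character
#'   \code{group} columns.
#' @export
derive_groups <- function(metadata) {
  if (any(is.na(metadata$ga_weeks))) {
    stop("missing gestational age at row ",
         which(is.na(metadata$ga_weeks))[1])
  }
  ep <- metadata$ga_weeks < 34
  pe <- metadata$pe
  metadata$ep <- ep
  metadata$group <- paste0(ifelse(ep, "EP", "NTT"),
                           ifelse(pe, "-PE", "-N"))
  metadata
}

#' Pairwise Mann-Whitney group comparisons with BH correction
#'
#' Runs a Mann-Whitney U test for every requested pair of groups and
#' adjusts the resulting p-values by Benjamini-Hochberg across the
#' family of pairs tested in this one call.
#'
#' @param values numeric vector of per-sample values.
#' @param labels group label per sample.
#' @param pairs optional list of length-2 character vectors; defaults to
#'   all unordered pairs of observed groups.
#' @param sided \code{"two"} (default) or \code{"one"}; one-sided tests
#'   take \code{alternative} for the direction of the first group.
#' @param alternative direction for one-sided tests ("greater" means
#'   the first group of the pair is hypothesized to be larger).
#' @return data.frame: group1, group2, n1, n2, statistic (U of group1
#'   vs group2), p_value, p_adjusted.
#' @export
compare_groups <- function(values, labels, pairs = NULL,
                           sided = c("two", "one"),
                           alternative = "greater") {
  sided <- match.arg(sided)
  labels <- as.character(labels)
  groups <- unique(labels[!is.na(labels)])
  if (length(groups) < 2) stop("need at least 2 groups")
  sizes <- table(labels)
  if (any(sizes < 1)) stop("every group needs at least one observation")
  if (is.null(pairs)) {
    pairs <- utils::combn(groups, 2, simplify = FALSE)
  }
  alt <- if (sided == "two") "two.sided" else alternative
  rows <- lapply(pairs, function(pr) {
    x <- values[labels == pr[1]]
    y <- values[labels == pr[2]]
    wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alt))
    data.frame(group1 = pr[1], group2 = pr[2],
               n1 = length(x), n2 = length(y),
               statistic = unname(wt$statistic), p_value = wt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Fisher exact enrichment test on a 2x2 table
#'
#' Builds the carriers x outcome contingency table and reports the
#' exact conditional (hypergeometric) two-sided p-value, the
#' conditional-MLE odds ratio with its exact confidence interval, and
#' the sample (cross-product) odds ratio. An empty margin makes the
#' odds ratio undefined; it is flagged while the p-value is still
#' returned.
#'
#' @param carrier_flags logical vector (e.g. gene/pathway carriers), or
#'   a 2x2 numeric matrix (rows = carrier yes/no, cols = outcome
#'   yes/no), in which case \code{outcome_flags} is ignored.
#' @param outcome_flags logical vector of the same length.
#' @param set_name optional label for the tested set.
#' @return data.frame: set, a, b, c, d (table cells), odds_ratio
#'   (conditional MLE), ci_low, ci_high, sample_or, or_defined, p_value.
#' @export
enrichment_test <- function(carrier_flags, outcome_flags = NULL,
                            set_name = NA_character_) {
  if (is.matrix(carrier_flags)) {
    tab <- carrier_flags
    stopifnot(all(dim(tab) == c(2, 2)))
  } else {
    tab <- table(factor(carrier_flags, levels = c(TRUE, FALSE)),
                 factor(outcome_flags, levels = c(TRUE, FALSE)))
    tab <- as.matrix(unclass(tab))
  }
  if (sum(tab) <= 0) stop("contingency table has zero grand total")
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  ft <- stats::fisher.test(tab)
  sample_or <- (a * d) / (b * c_)
  or_defined <- all(rowSums(tab) > 0) && all(colSums(tab) > 0) &&
    is.finite(sample_or)
  data.frame(set = set_name, a = a, b = b, c = c_, d = d,
             odds_ratio = unname(ft$estimate),
             ci_low = ft$conf.int[1], ci_high = ft$conf.int[2],
             sample_or = sample_or, or_defined = or_defined,
             p_value = ft$p.value, stringsAsFactors = FALSE)
}

# Breslow partial log-likelihood at a fixed coefficient vector
.cox_pll <- function(time, event, X, beta) {
  lp <- as.vector(X %*% beta)
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; lp <- lp[ord]
  elp <- exp(lp)
  # risk-set sums: cumulative from the back, ties at the same time share
  # the full risk set (Breslow)
  rev_cum <- rev(cumsum(rev(elp)))
  first_at_time <- match(time, time)
  risk_sum <- rev_cum[first_at_time]
  sum(lp[event == 1] - log(risk_sum[event == 1]))
}

#' Gestational-age-to-event Cox model with penalizer selection
#'
#' Fits a Cox proportional-hazards model on gestational age at delivery
#' as the time axis. A ridge penalizer is chosen from a grid by k-fold
#' cross-validated partial log-likelihood (Verweij-van Houwelingen:
#' the full-data partial likelihood at the fold-trained coefficients
#' minus the training-fold partial likelihood). Proportional-hazards
#' assumptions are then checked per feature by the scaled-Schoenfeld
#' score test at p = 0.05; failing features are replaced by their
#' squares and the model refit once. Ties are handled by the Breslow
#' method.
#'
#' @param table data.frame with the duration, event and feature columns.
#' @param features character vector of feature column names (logical or
#'   two-level character features are converted to 0/1).
#' @param duration name of the time column (default "ga_weeks").
#' @param event name of the logical/0-1 event column.
#' @param penalizer_grid ridge penalties to try (default 0, 0.01, 0.1, 1).
#' @param k_folds folds for penalizer selection (default 5).
#' @param seed seed controlling fold assignment.
#' @param ph_check run the proportional-hazards check and the
#'   square-and-refit pass (default TRUE); set FALSE to keep the plain
#'   proportional fit, e.g. in simulation studies of the estimator
#'   itself.
#' @return A list of class \code{"cox_fit"}: coefficients,
#'   hazard_ratios, ci_low, ci_high, p_values (per feature),
#'   penalizer, ph_test (data.frame feature/chisq/p/pass),
#'   transformed_features, model (the survival::coxph fit), data used.
#' @export
fit_cox <- function(table, features, duration = "ga_weeks", event,
                    penalizer_grid = c(0, 0.01, 0.1, 1), k_folds = 5,
                    seed = 1, ph_check = TRUE) {
  if (nrow(table) < 20) stop("Cox fit requires at least 20 samples")
  X <- .feature_matrix(table, features)
  if (anyNA(X)) stop("missing feature values are not allowed in fit_cox")
  time <- table[[duration]]
  ev <- as.integer(table[[event]])
  if (length(unique(time[ev == 1])) <= 1 && sum(ev) > 1) {
    stop("all event durations are tied; model is degenerate")
  }

  penalizer <- penalizer_grid[1]
  if (length(penalizer_grid) > 1) {
    old <- .rng_state_save(); on.exit(.rng_state_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    fold <- sample(rep_len(seq_len(k_folds), nrow(table)))
    cvpl <- vapply(penalizer_grid, function(th) {
      s <- 0
      for (f in seq_len(k_folds)) {
        tr <- fold != f
        fit_tr <- .cox_ridge_fit(time[tr], ev[tr], X[tr, , drop = FALSE], th)
        if (is.null(fit_tr)) return(-Inf)
        beta <- fit_tr$beta
        s <- s + (.cox_pll(time, ev, X, beta) -
                    .cox_pll(time[tr], ev[tr], X[tr, , drop = FALSE], beta))
      }
      s / k_folds
    }, numeric(1))
    penalizer <- penalizer_grid[which.max(cvpl)]
  }

  fit <- .cox_ridge_fit(time, ev, X, penalizer)
  if (is.null(fit)) stop("Cox model failed to converge")

  # proportional-hazards check on the unpenalized companion fit
  ph <- if (!ph_check) NULL else tryCatch({
    df0 <- data.frame(time = time, ev = ev, X, check.names = FALSE)
    f0 <- survival::coxph(
      Surv(time, ev) ~ ., data = df0, ties = "breslow")
    z <- survival::cox.zph(f0)
    zt <- z$table[rownames(z$table) != "GLOBAL", , drop = FALSE]
    data.frame(feature = rownames(zt), chisq = zt[, "chisq"],
               p = zt[, "p"], pass = zt[, "p"] >= 0.05,
               stringsAsFactors = FALSE, row.names = NULL)
  }, error = function(e) NULL)

  transformed <- character(0)
  if (!is.null(ph) && any(!ph$pass)) {
    transformed <- ph$feature[!ph$pass]
    for (fcol in transformed) {
      X[, fcol] <- X[, fcol]^2
    }
    colnames(X)[colnames(X) %in% transformed] <-
      paste0(transformed, "_sq")
    fit <- .cox_ridge_fit(time, ev, X, penalizer)
    if (is.null(fit)) stop("Cox refit after squaring failed to converge")
  }

  beta <- fit$beta; se <- fit$se
  zq <- stats::qnorm(0.975)
  structure(list(
    coefficients = beta,
    hazard_ratios = exp(beta),
    ci_low = exp(beta - zq * se),
    ci_high = exp(beta + zq * se),
    se = se,
    p_values = 2 * stats::pnorm(-abs(beta / se)),
    penalizer = penalizer,
    ph_test = ph,
    transformed_features = transformed,
    features = colnames(X),
    model = fit$model,
    time = time, event = ev, X = X
  ), class = "cox_fit")
}

.feature_matrix <- function(table, features) {
  cols <- lapply(features, function(f) {
    x <- table[[f]]
    if (is.null(x)) stop("feature column not found: ", f)
    if (is.logical(x)) return(as.numeric(x))
    if (is.character(x) || is.factor(x)) {
      lev <- sort(unique(as.character(x)))
      if (length(lev) > 2) stop("categorical feature '", f,
                                "' has more than 2 levels")
      return(as.numeric(as.character(x) == lev[length(lev)]))
    }
    as.numeric(x)
  })
  X <- do.call(cbind, cols)
  colnames(X) <- features
  X
}

.cox_ridge_fit <- function(time, ev, X, theta) {
  df <- data.frame(time = time, ev = ev, X, check.names = FALSE)
  fml <- if (theta > 0) {
    stats::as.formula(paste0(
      "Surv(time, ev) ~ ridge(",
      paste(sprintf("`%s`", colnames(X)), collapse = ", "),
      ", theta = ", theta, ", scale = FALSE)"))
  } else {
    stats::as.formula(paste0(
      "Surv(time, ev) ~ ",
      paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  }
  fit <- tryCatch(
    survival::coxph(fml, data = df, ties = "breslow"),
    error = function(e) NULL, warning = function(w) {
      suppressWarnings(survival::coxph(fml, data = df, ties = "breslow"))
    })
  if (is.null(fit)) return(NULL)
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  names(beta) <- names(se) <- colnames(X)
  list(beta = beta, se = se, model = fit)
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (penalizer =", x$penalizer, ")\n")
  tab <- data.frame(coef = x$coefficients, HR = x$hazard_ratios,
                    ci_low = x$ci_low, ci_high = x$ci_high,
                    p = x$p_values)
  print(round(tab, 4))
  if (length(x$transformed_features)) {
    cat("squared (failed PH check):",
        paste(x$transformed_features, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Partial-effect cumulative-incidence curves
#'
#' Predicted probability of the event by each gestational week for
#' covariate vectors holding the feature of interest at its 10th and
#' 90th percentiles (other features at their means), from the Breslow
#' baseline cumulative hazard of the fitted model.
#'
#' @param fit a \code{cox_fit}.
#' @param feature feature name (after any squaring transform).
#' @param percentiles two percentiles in (0, 100), default c(10, 90).
#' @return data.frame: week, cuminc_low, cuminc_high (cumulative
#'   incidence for the low/high percentile covariate vectors).
#' @export
partial_effect_curves <- function(fit, feature, percentiles = c(10, 90)) {
  if (any(percentiles <= 0 | percentiles >= 100)) {
    stop("percentiles must lie strictly inside (0, 100)")
  }
  if (!feature %in% colnames(fit$X)) {
    stop("feature not in fitted model: ", feature)
  }
  X <- fit$X; beta <- fit$coefficients
  qs <- stats::quantile(X[, feature], probs = percentiles / 100,
                        names = FALSE)
  base <- colMeans(X)
  x_lo <- base; x_lo[feature] <- qs[1]
  x_hi <- base; x_hi[feature] <- qs[2]

  # Breslow baseline cumulative hazard at the mean covariate vector
  lp <- as.vector(X %*% beta) - sum(base * beta)
  ord <- order(fit$time)
  t_s <- fit$time[ord]; e_s <- fit$event[ord]; elp <- exp(lp)[ord]
  rev_cum <- rev(cumsum(rev(elp)))
  risk_at <- rev_cum[match(t_s, t_s)]
  etimes <- unique(t_s[e_s == 1])
  h0 <- vapply(etimes, function(tt) {
    sum(e_s == 1 & t_s == tt) / risk_at[match(tt, t_s)]
  }, numeric(1))
  H0 <- cumsum(h0)
  weeks <- etimes
  rel_lo <- exp(sum((x_lo - base) * beta))
  rel_hi <- exp(sum((x_hi - base) * beta))
  data.frame(week = weeks,
             cuminc_low = 1 - exp(-H0 * rel_lo),
             cuminc_high = 1 - exp(-H0 * rel_hi))
}
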