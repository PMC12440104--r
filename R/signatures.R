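#' Build a 96-context mutation catalog from SNVs
#'
#' Each context-complete SNV is mapped to its pyrimidine-centric channel
#' (purine-reference calls are reverse-complemented, see
#' \code{\link{snv_channel}}); SNVs lacking flank context are dropped
#' with a logged count.
#'
#' @param variants canonical variant data.frame (only rows with
#'   variant_type "SNV" are used).
#' @param samples optional character vector fixing the column set and
#'   order; defaults to the distinct sample_ids present.
#' @return A 96 x n_samples integer matrix with channel rownames, in
#'   canonical channel order.
#' @export
build_catalog <- function(variants, samples = NULL) {
  snv <- variants[!is.na(variants$variant_type) &
                    variants$variant_type == "SNV", , drop = FALSE]
  if (is.null(samples)) samples <- unique(snv$sample_id)
  ch <- sbs_channels()
  m <- matrix(0L, nrow = 96, ncol = length(samples),
              dimnames = list(ch, samples))
  if (!nrow(snv)) return(m)
  lab <- snv_channel(snv$ref, snv$alt, snv$context5, snv$context3)
  dropped <- sum(is.na(lab))
  if (dropped > 0) {
    pgin_log(dropped, " SNV(s) lacking usable context dropped from catalog")
  }
  keep <- !is.na(lab) & snv$sample_id %in% samples
  if (any(keep)) {
    tab <- table(factor(lab[keep], levels = ch),
                 factor(snv$sample_id[keep], levels = samples))
    m <- m + as.matrix(unclass(tab))
    dimnames(m) <- list(ch, samples)
  }
  storage.mode(m) <- "integer"
  m
}

# one multiplicative-update NMF run (Frobenius loss)
.nmf_run <- function(V, k, tol, max_iter) {
  n <- nrow(V); m <- ncol(V)
  W <- matrix(stats::runif(n * k, 0.1, 1), n, k)
  H <- matrix(stats::runif(k * m, 0.1, 1), k, m)
  eps <- .Machine$double.eps
  err_prev <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V) / (crossprod(W) %*% H + eps))
    W <- W * (V %*% t(H) / (W %*% tcrossprod(H) + eps))
    if (it %% 10 == 0 || it == max_iter) {
      err <- sqrt(sum((V - W %*% H)^2))
      if (is.finite(err_prev) &&
          abs(err_prev - err) <= tol * max(err_prev, eps)) break
      err_prev <- err
    }
  }
  list(W = W, H = H, error = sqrt(sum((V - W %*% H)^2)))
}

#' Extract de-novo mutational signatures by NMF
#'
#' Factorizes the catalog V (96 x samples) as W H with non-negative
#' factors, minimizing Frobenius reconstruction error by multiplicative
#' updates (relative-change tolerance 1e-6, at most 5000 iterations),
#' keeping the best of \code{n_restarts} random initializations.
#' Signatures (columns of W) are normalized to probability vectors and
#' exposures rescaled accordingly. Deterministic given \code{seed}.
#'
#' @param catalog 96 x n_samples non-negative matrix.
#' @param rank number of signatures K (2 <= K <= min(96, n_samples);
#'   K = 1 is allowed for degenerate single-process catalogs).
#' @param n_restarts random restarts (default 10).
#' @param seed integer seed.
#' @param tol relative-change stopping tolerance.
#' @param max_iter iteration cap per restart.
#' @return A list of class \code{"signature_set"}: \code{signatures}
#'   (96 x K probability matrix, columns SBSA, SBSB, ...),
#'   \code{exposures} (n_samples x K), \code{error} (Frobenius),
#'   \code{rank}.
#' @export
extract_signatures <- function(catalog, rank, n_restarts = 10, seed = 1,
                               tol = 1e-6, max_iter = 5000) {
  if (sum(catalog) <= 0) stop("catalog has zero total count; cannot factorize")
  if (rank < 1 || rank > min(96, ncol(catalog))) {
    stop("rank must be between 1 and min(96, n_samples)")
  }
  V <- catalog
  storage.mode(V) <- "double"
  best <- NULL
  old <- .rng_state_save()
  on.exit(.rng_state_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  for (r in seq_len(n_restarts)) {
    fit <- .nmf_run(V, rank, tol, max_iter)
    if (is.null(best) || fit$error < best$error) best <- fit
  }
  scale <- colSums(best$W)
  scale[scale == 0] <- 1
  sig <- sweep(best$W, 2, scale, "/")
  exp <- t(best$H * scale)
  labels <- paste0("SBS", LETTERS[seq_len(rank)])
  dimnames(sig) <- list(rownames(catalog), labels)
  dimnames(exp) <- list(colnames(catalog), labels)
  structure(list(signatures = sig, exposures = exp,
                 error = best$error, rank = rank),
            class = "signature_set")
}

.rng_state_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.rng_state_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Cosine similarity between vectors
#' @param a,b numeric vectors of equal length.
#' @return Cosine similarity in [-1, 1]; 0 if either vector is null.
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Match extracted signatures to a reference catalog
#'
#' For each extracted signature, reports the reference signature with
#' the largest cosine similarity (ties broken by reference column
#' order).
#'
#' @param signature_set a \code{signature_set} or a 96 x K signature
#'   matrix.
#' @param reference 96 x R reference probability matrix with channel
#'   rownames in canonical order.
#' @return data.frame: signature, reference, cosine.
#' @export
match_to_reference <- function(signature_set, reference) {
  sig <- if (inherits(signature_set, "signature_set"))
    signature_set$signatures else signature_set
  if (!identical(rownames(sig), rownames(reference))) {
    if (is.null(rownames(reference)) ||
        !setequal(rownames(sig), rownames(reference))) {
      stop("reference channel labels do not align with extracted signatures")
    }
    reference <- reference[rownames(sig), , drop = FALSE]
  }
  rows <- lapply(seq_len(ncol(sig)), function(j) {
    cs <- apply(reference, 2, cosine_similarity, b = sig[, j])
    best <- which.max(cs)  # first max wins ties
    data.frame(signature = colnames(sig)[j],
               reference = colnames(reference)[best],
               cosine = unname(cs[best]), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Mean relative signature contributions by group
#'
#' Per-sample exposures are normalized to sum 1 (samples with zero total
#' exposure are excluded with a log message), then averaged within each
#' level of the grouping variable.
#'
#' @param signature_set a \code{signature_set}.
#' @param metadata data.frame with sample_id and the grouping column.
#' @param grouping name of the metadata column to group by.
#' @return Matrix of mean relative contributions, groups x signatures.
#' @export
group_contributions <- function(signature_set, metadata, grouping) {
  exp <- signature_set$exposures
  tot <- rowSums(exp)
  zero <- tot == 0
  if (any(zero)) {
    pgin_log(sum(zero), " sample(s) with zero total exposure excluded ",
             "from group contributions")
  }
  rel <- exp[!zero, , drop = FALSE] / tot[!zero]
  g <- metadata[[grouping]][match(rownames(rel), metadata$sample_id)]
  groups <- unique(stats::na.omit(metadata[[grouping]]))
  out <- matrix(NA_real_, length(groups), ncol(exp),
                dimnames = list(as.character(groups), colnames(exp)))
  for (gr in as.character(groups)) {
    idx <- which(!is.na(g) & as.character(g) == gr)
    if (!length(idx)) {
      warning("group '", gr, "' has no samples with exposures; skipped")
      next
    }
    out[gr, ] <- colMeans(rel[idx, , drop = FALSE])
  }
  out
}

#' Rank correlation between a signature's contribution and burden
#'
#' Spearman's rho with a two-sided p-value on paired (relative
#' contribution, genomic instability) values.
#'
#' @param signature_set a \code{signature_set}.
#' @param scores data.frame from \code{\link{instability_scores}}.
#' @param signature label of the signature of interest (default first).
#' @return List: rho, p_value, n.
#' @export
correlate_contribution_burden <- function(signature_set, scores,
                                          signature = NULL) {
  exp <- signature_set$exposures
  if (is.null(signature)) signature <- colnames(exp)[1]
  tot <- rowSums(exp)
  rel <- ifelse(tot > 0, exp[, signature] / tot, NA)
  idx <- match(rownames(exp), scores$sample_id)
  b <- scores$burden[idx]
  ok <- !is.na(rel) & !is.na(b)
  if (sum(ok) < 3) stop("need at least 3 samples with both quantities")
  if (stats::sd(rel[ok]) == 0 || stats::sd(b[ok]) == 0) {
    stop("constant input; rank correlation undefined")
  }
  ct <- suppressWarnings(
    stats::cor.test(rel[ok], b[ok], method = "spearman", exact = TRUE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}

#' Write a mutation catalog to TSV (channels x samples)
#' @param catalog 96 x samples matrix.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  df <- data.frame(channel = rownames(catalog), catalog, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
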