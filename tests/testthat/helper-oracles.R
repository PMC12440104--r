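# Independent oracles and fixture builders shared across tests.
# Every oracle re-derives its answer from first principles (enumeration,
# direct predicate evaluation, pair counting) without calling the code
# path it checks.

# --- variant fixtures ----------------------------------------------------

# a random variant table exercising every threshold boundary, with
# shared positions/genes so the cohort-recurrence filters fire
random_variant_fixture <- function(n, n_samples = 8, seed = 1) {
  set.seed(seed)
  pick <- function(vals) sample(vals, n, replace = TRUE)
  df <- data.frame(
    sample_id = paste0("S", sample.int(n_samples, n, replace = TRUE)),
    chrom = pick(c("chr1", "chr2")),
    pos = sample(1:40, n, replace = TRUE),
    ref = pick(c("C", "T", "A", "G")),
    alt = NA_character_,
    gene = pick(paste0("G", 1:12)),
    classification = pick(c("missense", "nonsense", "nonstop", "silent",
                            "frameshift", NA)),
    dp = pick(c(NA, 5, 10, 11, 49, 50, 51, 120)),
    gq = pick(c(NA, 10, 20, 21, 80)),
    qd = pick(c(NA, 4, 5, 5.5, 20)),
    mq = pick(c(NA, 30, 40, 41, 60)),
    read_pos_rank_sum = pick(c(NA, -5, -3, -2.9, 0)),
    mq_rank_sum = pick(c(NA, -12, -10, -9.9, 0)),
    fs = pick(c(NA, 0, 199, 200, 250)),
    qual = pick(c(NA, 30, 50, 51, 400)),
    max_af = pick(c(NA, 0, 0.005, 0.0099, 0.01, 0.02, 0.3)),
    polyphen = pick(c("damaging", "possibly_damaging", "benign", NA)),
    sift = pick(c("deleterious", "tolerated", NA)),
    clinvar_sig = pick(c("benign", "pathogenic", NA)),
    rna_editing_site = pick(c(TRUE, FALSE, FALSE, FALSE)),
    low_complexity = pick(c(TRUE, FALSE, FALSE, FALSE)),
    common_variant = pick(c(TRUE, FALSE, FALSE, FALSE)),
    stringsAsFactors = FALSE)
  comp <- c(C = "c", T = "t", A = "a", G = "g")
  df$alt <- ifelse(df$ref == "C", "A", ifelse(df$ref == "T", "G",
                   ifelse(df$ref == "A", "T", "C")))
  as_variant_table(df)
}

# naive per-variant predicate evaluation of the whole cascade; returns
# integer row indices of the rare and rare-damaging sets
oracle_cascade <- function(v, config, n_samples) {
  n <- nrow(v)
  gt <- function(x, cut) ifelse(is.na(x), !config$strict_missing_quality,
                                x > cut)
  lt <- function(x, cut) ifelse(is.na(x), !config$strict_missing_quality,
                                x < cut)
  qpass <- gt(v$dp, 10) & gt(v$gq, 20) & gt(v$qd, 5) & gt(v$mq, 40) &
    gt(v$read_pos_rank_sum, -3) & gt(v$mq_rank_sum, -10) &
    lt(v$fs, 200) & gt(v$qual, 50)
  clean <- qpass & !(v$rna_editing_site | v$low_complexity |
                       v$common_variant)
  deep <- !is.na(v$dp) & v$dp > config$burden_depth_threshold
  rare_af <- ifelse(is.na(v$max_af), config$missing_af_is_rare,
                    v$max_af < config$rare_af_threshold)
  cand <- which(clean & deep & rare_af)
  # variant recurrence
  key <- paste(v$chrom, v$pos, v$ref, v$alt)[cand]
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    carriers <- unique(v$sample_id[cand][key == key[i]])
    keep[i] <- length(carriers) / n_samples <= config$variant_recurrence_max
  }
  cand <- cand[keep]
  # gene recurrence
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    g <- v$gene[cand][i]
    if (is.na(g)) { keep[i] <- TRUE; next }
    carriers <- unique(v$sample_id[cand][!is.na(v$gene[cand]) &
                                           v$gene[cand] == g])
    keep[i] <- length(carriers) / n_samples <= config$gene_recurrence_max
  }
  rare <- cand[keep]
  trunc <- !is.na(v$classification) &
    v$classification %in% c("nonsense", "nonstop")
  pp <- !is.na(v$polyphen) & v$polyphen == "damaging"
  sf <- !is.na(v$sift) & v$sift == "deleterious"
  impact <- if (config$damaging_rule == "union") pp | sf | trunc
            else (pp & sf) | trunc
  benign <- !is.na(v$clinvar_sig) & v$clinvar_sig == "benign"
  dmg <- rare[impact[rare] & !benign[rare]]
  list(rare = sort(rare), damaging = sort(dmg))
}

cascade_rows <- function(df) sort(as.integer(rownames(df)))

# --- exact-test oracles --------------------------------------------------

# two-sided Fisher p by direct hypergeometric enumeration: sum the
# probabilities of all tables with the observed margins whose
# probability does not exceed the observed table's
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(m, k)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# two-sided Mann-Whitney p by exhaustive enumeration of group
# assignments (tie-free data only)
oracle_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(y) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Benjamini-Hochberg step-up from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# AUC by direct pair counting with half credit for ties
oracle_auc <- function(prob, truth) {
  pos <- prob[truth]; neg <- prob[!truth]
  grid <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(grid)
}

# optimal one-to-one signature assignment over all K! permutations;
# returns the per-reference cosine under the best assignment
oracle_match_cosines <- function(extracted, reference) {
  K <- ncol(reference)
  cs <- sapply(seq_len(ncol(extracted)), function(j) {
    sapply(seq_len(K), function(r) {
      cosine_similarity(extracted[, j], reference[, r])
    })
  })
  perms <- .permutations(K)
  scores <- apply(perms, 1, function(p) sum(cs[cbind(p, seq_len(K))]))
  best <- perms[which.max(scores), ]
  list(cosines = cs[cbind(best, seq_len(K))], assignment = best)
}

.permutations <- function(k) {
  if (k == 1) return(matrix(1))
  sub <- .permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# tiny MAF-like fixture on disk
write_maf_fixture <- function(path, rows) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  path
}
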