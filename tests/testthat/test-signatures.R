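snv_row <- function(sample_id, ref, alt, c5, c3) {
  data.frame(sample_id = sample_id, chrom = "chr1", pos = 1, ref = ref,
             alt = alt, gene = "G", context5 = c5, context3 = c3,
             stringsAsFactors = FALSE)
}

test_that("catalog maps channels and reverse-complements purine refs", {
  v <- as_variant_table(snv_row("s1", "C", "A", "A", "A"))
  cat1 <- build_catalog(v)
  expect_equal(cat1["A[C>A]A", "s1"], 1L)
  expect_equal(sum(cat1), 1)

  # G>T with flanks (T, G) is C>A with flanks (C, A) on the other strand
  v2 <- as_variant_table(snv_row("s1", "G", "T", "T", "G"))
  cat2 <- build_catalog(v2)
  expect_equal(cat2["C[C>A]A", "s1"], 1L)

  # column sums are conserved over context-complete SNVs
  set.seed(2)
  ref <- synthetic_reference_signatures()
  chan <- sample(sbs_channels(), 100, replace = TRUE)
  v3 <- as_variant_table(do.call(rbind, lapply(chan, function(ch) {
    snv_row("s1", substr(ch, 3, 3), substr(ch, 5, 5),
            substr(ch, 1, 1), substr(ch, 7, 7))
  })))
  expect_equal(sum(build_catalog(v3)[, "s1"]), 100)
})

test_that("strand involution leaves the catalog unchanged", {
  b <- simulate_cohort(simulation_spec(
    group_scheme = c("EP-PE" = 6), seed = 12,
    mean_variants_per_sample = 80))
  v <- b$variants[b$variants$variant_type == "SNV", ]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flipped <- v
  flipped$ref <- unname(comp[v$ref])
  flipped$alt <- unname(comp[v$alt])
  flipped$context5 <- unname(comp[v$context3])
  flipped$context3 <- unname(comp[v$context5])
  expect_equal(build_catalog(v), build_catalog(flipped))
})

test_that("SNVs without context are dropped with a log message", {
  v <- as_variant_table(rbind(snv_row("s1", "C", "A", "A", "A"),
                              snv_row("s1", "C", "T", NA, "G")))
  expect_message(cat1 <- build_catalog(v), "dropped")
  expect_equal(sum(cat1), 1)
})

test_that("NMF recovers a single planted signature and is deterministic", {
  ref <- synthetic_reference_signatures()
  counts <- simulate_catalog(c(0, 0, 1, 0), 8000, ref, seed = 4)
  catalog <- matrix(counts, ncol = 1,
                    dimnames = list(names(counts), "s1"))
  ss <- extract_signatures(catalog, rank = 1, seed = 10)
  expect_gte(cosine_similarity(ss$signatures[, 1], ref[, 3]), 0.99)
  expect_equal(sum(ss$signatures[, 1]), 1, tolerance = 1e-9)

  ss2 <- extract_signatures(catalog, rank = 1, seed = 10)
  expect_identical(ss$signatures, ss2$signatures)
  expect_identical(ss$exposures, ss2$exposures)

  expect_error(extract_signatures(catalog * 0, rank = 1), "zero")
})

test_that("reconstruction error is non-increasing in the rank", {
  ref <- synthetic_reference_signatures()
  set.seed(6)
  mixes <- t(apply(matrix(stats::rgamma(20 * 3, 1), 20), 1,
                   function(m) m / sum(m)))
  catalog <- sapply(seq_len(20), function(i) {
    simulate_catalog(c(mixes[i, ], 0), 500,
                     ref, seed = 600 + i)
  })
  rownames(catalog) <- sbs_channels()
  colnames(catalog) <- paste0("s", 1:20)
  errs <- vapply(1:4, function(k) {
    extract_signatures(catalog, rank = k, n_restarts = 4,
                       seed = 3)$error
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-6))
})

test_that("reference matching reports argmax cosine with stable ties", {
  ref <- synthetic_reference_signatures()
  m <- match_to_reference(ref[, 2, drop = FALSE], ref)
  expect_equal(m$reference, "SBS5_like")
  expect_equal(m$cosine, 1.0, tolerance = 1e-12)

  # orthogonal probe still yields a match row with cosine 0
  probe <- matrix(0, 96, 1, dimnames = list(sbs_channels(), "x"))
  zref <- matrix(c(rep(0, 95), 1), 96, 1,
                 dimnames = list(sbs_channels(), "z"))
  probe[1, 1] <- 1
  expect_equal(match_to_reference(probe, zref)$cosine, 0)

  # duplicated reference: first in file order wins
  dup <- cbind(first = ref[, 1], second = ref[, 1])
  expect_equal(match_to_reference(ref[, 1, drop = FALSE], dup)$reference,
               "first")

  bad <- ref
  rownames(bad) <- rev(rownames(bad))
  expect_error(match_to_reference(ref[, 1, drop = FALSE],
                                  unname(bad)), "align")
})

test_that("group contributions normalize per sample then average", {
  ss <- structure(list(
    signatures = NULL,
    exposures = matrix(c(2, 6, 1, 0, 0, 1, 0, 0), 4, 2, byrow = TRUE,
                       dimnames = list(paste0("s", 1:4), c("A", "B")))),
    class = "signature_set")
  md <- data.frame(sample_id = paste0("s", 1:4),
                   grp = c("g1", "g2", "g2", "g3"),
                   stringsAsFactors = FALSE)
  # the zero-exposure sample is excluded (message) leaving g3 empty
  # (warning) with an all-NA row
  expect_warning(
    expect_message(out <- group_contributions(ss, md, "grp"), "zero"),
    "g3")
  expect_equal(unname(out["g1", ]), c(0.25, 0.75))
  expect_equal(unname(out["g2", ]), c(0.5, 0.5))
  expect_true(all(is.na(out["g3", ])))
})

test_that("contribution-burden correlation matches exact enumeration", {
  ss <- structure(list(exposures = matrix(
    c(1, 9, 3, 7, 5, 5, 6, 4, 9, 1), 5, 2, byrow = TRUE,
    dimnames = list(paste0("s", 1:5), c("A", "B")))),
    class = "signature_set")
  rel <- ss$exposures[, 1] / rowSums(ss$exposures)
  burden <- c(0.3, 0.9, 0.5, 1.2, 2.0)
  scores <- data.frame(sample_id = paste0("s", 1:5), burden = burden)
  out <- correlate_contribution_burden(ss, scores, "A")

  rho_obs <- stats::cor(rank(rel), rank(burden))
  perms <- .permutations(5)
  rhos <- apply(perms, 1, function(p) {
    stats::cor(rank(rel), rank(burden[p]))
  })
  p_exact <- mean(abs(rhos) >= abs(rho_obs) - 1e-9)
  expect_equal(out$rho, rho_obs, tolerance = 1e-12)
  expect_equal(out$p_value, p_exact, tolerance = 1e-9)

  mono <- data.frame(sample_id = paste0("s", 1:5),
                     burden = sort(rel) * 2 + 1)
  ss_sorted <- ss
  ord <- order(rel)
  ss_sorted$exposures <- ss$exposures[ord, ]
  rownames(ss_sorted$exposures) <- paste0("s", 1:5)
  expect_equal(correlate_contribution_burden(ss_sorted, mono, "A")$rho, 1)

  const <- data.frame(sample_id = paste0("s", 1:5), burden = rep(1, 5))
  expect_error(correlate_contribution_burden(ss, const, "A"), "constant")
})
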