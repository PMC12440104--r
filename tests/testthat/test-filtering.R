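vt <- function(...) {
  as_variant_table(data.frame(sample_id = "A", chrom = "chr1", pos = 1,
                              ref = "C", alt = "T", gene = "G1", ...,
                              stringsAsFactors = FALSE))
}

test_that("quality thresholds are strict inequalities as printed", {
  passing <- vt(dp = 11, gq = 21, qd = 5.1, mq = 41,
                read_pos_rank_sum = 0, mq_rank_sum = 0, fs = 0, qual = 51)
  expect_equal(nrow(quality_filter(passing)$variants), 1)

  at_dp <- passing; at_dp$dp <- 10
  expect_equal(nrow(quality_filter(at_dp)$variants), 0)

  at_fs <- passing; at_fs$fs <- 200
  out <- quality_filter(at_fs)
  expect_equal(nrow(out$variants), 0)
  expect_equal(unname(out$tally["fs"]), 1L)
})

test_that("missing quality metrics pass vacuously unless strict", {
  v <- vt(dp = 30, qual = 80)  # all other metrics missing
  expect_equal(nrow(quality_filter(v)$variants), 1)
  strict <- pgin_config(strict_missing_quality = TRUE)
  expect_equal(nrow(quality_filter(v, strict)$variants), 0)
})

test_that("somatic exclusions drop any flagged variant", {
  v <- random_variant_fixture(10, seed = 9)
  v$rna_editing_site <- c(TRUE, rep(FALSE, 9))
  v$low_complexity <- c(FALSE, TRUE, TRUE, rep(FALSE, 7))
  v$common_variant <- FALSE
  expect_equal(nrow(somatic_exclusions(v)), 7)
  v$rna_editing_site <- FALSE
  v$low_complexity <- FALSE
  expect_equal(nrow(somatic_exclusions(v)), 10)
})

test_that("rarity threshold is strict and recurrence uses cohort fractions", {
  cfg <- pgin_config()
  at_af <- vt(dp = 120, max_af = 0.01)
  expect_equal(nrow(rare_filter(at_af, cfg, n_samples = 10)), 0)
  below <- vt(dp = 120, max_af = 0.0099)
  expect_equal(nrow(rare_filter(below, cfg, n_samples = 10)), 1)

  # same variant in 8 of 10 samples: 80% > 70% -> removed
  rec <- as_variant_table(data.frame(
    sample_id = paste0("S", 1:8), chrom = "chr1", pos = 500, ref = "C",
    alt = "T", gene = paste0("G", 1:8), dp = 120, max_af = 0.001,
    stringsAsFactors = FALSE))
  expect_equal(nrow(rare_filter(rec, cfg, n_samples = 10)), 0)
  # 7 of 10 (70%, not > 70%) -> kept
  expect_equal(nrow(rare_filter(rec[1:7, ], cfg, n_samples = 10)), 7)

  # one gene mutated in 6 of 10 samples at distinct sites -> all removed
  generec <- as_variant_table(data.frame(
    sample_id = paste0("S", 1:6), chrom = "chr1", pos = 1:6, ref = "C",
    alt = "T", gene = "HOT", dp = 120, max_af = 0.001,
    stringsAsFactors = FALSE))
  expect_equal(nrow(rare_filter(generec, cfg, n_samples = 10)), 0)
  expect_equal(nrow(rare_filter(generec[1:5, ], cfg, n_samples = 10)), 5)
})

test_that("damaging rules honor truncating rescue and benign veto", {
  cfg_u <- pgin_config(damaging_rule = "union")
  cfg_i <- pgin_config(damaging_rule = "intersection")

  nonsense <- vt(dp = 120, max_af = 0.001, classification = "nonsense")
  expect_equal(nrow(damaging_filter(nonsense, cfg_u)), 1)
  expect_equal(nrow(damaging_filter(nonsense, cfg_i)), 1)

  vetoed <- vt(dp = 120, max_af = 0.001, polyphen = "damaging",
               clinvar_sig = "benign")
  expect_equal(nrow(damaging_filter(vetoed, cfg_u)), 0)

  silent <- vt(dp = 120, max_af = 0.001, classification = "silent",
               sift = "tolerated")
  expect_equal(nrow(damaging_filter(silent, cfg_u)), 0)
  expect_equal(nrow(damaging_filter(silent, cfg_i)), 0)

  # union accepts single-tool evidence, intersection demands both
  pp_only <- vt(dp = 120, max_af = 0.001, classification = "missense",
                polyphen = "damaging", sift = "tolerated")
  expect_equal(nrow(damaging_filter(pp_only, cfg_u)), 1)
  expect_equal(nrow(damaging_filter(pp_only, cfg_i)), 0)
  both <- pp_only; both$sift <- "deleterious"
  expect_equal(nrow(damaging_filter(both, cfg_i)), 1)
})

test_that("cascade equals brute-force predicate evaluation", {
  v <- random_variant_fixture(300, seed = 11)
  for (preset in c("placental_rna", "circulating_rna", "wgs_cell_line")) {
    for (rule in c("union", "intersection")) {
      cfg <- pgin_config(preset = preset, damaging_rule = rule)
      casc <- run_cascade(v, cfg, n_samples = 8)
      oracle <- oracle_cascade(v, cfg, n_samples = 8)
      expect_equal(cascade_rows(casc$rare), oracle$rare)
      expect_equal(cascade_rows(casc$rare_damaging), oracle$damaging)
    }
  }
})

test_that("cascade stages are monotone and counts are consistent", {
  v <- random_variant_fixture(400, seed = 21)
  casc <- run_cascade(v, pgin_config(), n_samples = 8)
  s <- casc$summary
  expect_true(all(diff(s[c("n_input", "n_quality_pass", "n_somatic",
                           "n_rare", "n_rare_damaging")]) <= 0))
  expect_true(all(rownames(casc$rare_damaging) %in% rownames(casc$rare)))
  expect_true(all(rownames(casc$rare) %in% rownames(casc$somatic)))
  expect_equal(s[["n_rare_genes"]], length(unique(casc$rare$gene)))
})

test_that("degenerate cascades behave: all fail quality, shared-gene counts", {
  v <- random_variant_fixture(20, seed = 5)
  v$qual <- 10  # everything fails QUAL > 50
  casc <- run_cascade(v, pgin_config(), n_samples = 8)
  expect_equal(casc$summary[["n_rare"]], 0L)
  expect_equal(casc$summary[["n_rare_genes"]], 0L)

  two <- as_variant_table(data.frame(
    sample_id = "A", chrom = "chr1", pos = c(1, 2), ref = "C", alt = "T",
    gene = "SAME", classification = "nonsense", dp = 120, max_af = 0.001,
    stringsAsFactors = FALSE))
  casc2 <- run_cascade(two, pgin_config(), n_samples = 4)
  expect_equal(casc2$summary[["n_rare_damaging"]], 2L)
  expect_equal(casc2$summary[["n_rare_damaging_genes"]], 1L)
})
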