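test_that("dosage_matrix validates its contents", {
  expect_error(dosage_matrix(matrix(0:3, 2, 2), c("a", "b"), c("v1", "v2")),
               "0, 1, 2 or NA")
  expect_error(dosage_matrix(matrix(0L, 2, 2), c("a"), c("v1", "v2")),
               "dimensions")
  dm <- dosage_matrix(matrix(c(0L, 1L, 2L, NA), 2, 2), c("a", "b"),
                      c("v1", "v2"))
  expect_equal(sum(is.na(dm$dosage)), 1L)
})

test_that("compute_prs implements the weighted mean-normalized score", {
  panel <- toy_panel()           # weights 0.5, 1.0, 1.5; mean 1.0
  dm <- dosage_matrix(matrix(c(2L, 1L, 0L), 1, 3), "p1", panel$rsid)
  expect_equal(compute_prs(dm, panel)$prs, 2.0)   # (2*0.5 + 1*1.0)/1.0

  zeros <- dosage_matrix(matrix(0L, 2, 3), c("a", "b"), panel$rsid)
  expect_equal(compute_prs(zeros, panel)$prs, c(0, 0))

  # equal weights cancel: the PRS is the raw risk-allele count
  eq <- toy_panel(or = rep(exp(0.7), 3))
  d <- matrix(c(0L, 1L, 2L, 2L, 1L, 0L), 2, 3, byrow = TRUE)
  dm_eq <- dosage_matrix(d, c("a", "b"), eq$rsid)
  expect_equal(compute_prs(dm_eq, eq)$prs, rowSums(d))

  # misalignment and degenerate mean weight are hard errors
  dm_other <- dosage_matrix(d, c("a", "b"), c("rsX1", "rsX2", "rsX3"))
  expect_error(compute_prs(dm_other, panel), "aligned")
  flat <- toy_panel(or = c(1, 1, 1))
  expect_error(compute_prs(dosage_matrix(d, c("a", "b"), flat$rsid), flat),
               "positive")
})

test_that("missing-dosage policies impute or zero-fill with a warning", {
  panel <- toy_panel(freq = c(0.25, 0.25, 0.25))
  d <- matrix(c(NA, 1L, 2L), 1, 3)
  dm <- dosage_matrix(d, "p1", panel$rsid)
  got <- compute_prs(dm, panel, missing_policy = "impute_freq")
  expect_equal(got$prs, (2 * 0.25 * 0.5 + 1 * 1.0 + 2 * 1.5) / 1.0)
  expect_equal(got$n_missing, 1L)
  expect_warning(z <- compute_prs(dm, panel, missing_policy = "zero"),
                 "biased")
  expect_equal(z$prs, (1 * 1.0 + 2 * 1.5) / 1.0)

  nofreq <- toy_panel()
  nofreq$freq <- NA_real_
  expect_error(compute_prs(dm, nofreq, missing_policy = "impute_freq"),
               "frequencies")
})

test_that("vectorized PRS matches the brute-force oracle", {
  panel <- synthetic_panel_47()
  withr::with_seed(99, {
    for (rep in 1:5) {
      d <- matrix(sample(0:2, 40 * 47, replace = TRUE), 40, 47)
      d[sample(length(d), 30)] <- NA
      dm <- dosage_matrix(d, sprintf("i%02d", 1:40), panel$rsid)
      expect_equal(compute_prs(dm, panel)$prs,
                   prs_oracle(d, panel$effect_weight, panel$freq,
                              "impute_freq"),
                   tolerance = 1e-12)
    }
  })
})

test_that("PRS is monotone in every dosage entry", {
  panel <- synthetic_panel_47()
  withr::with_seed(17, {
    d <- matrix(sample(0:1, 10 * 47, replace = TRUE), 10, 47)
    base <- compute_prs(dosage_matrix(d, letters[1:10], panel$rsid), panel)$prs
    for (rep in 1:20) {
      i <- sample(10, 1); j <- sample(47, 1)
      d2 <- d; d2[i, j] <- d2[i, j] + 1L
      bumped <- compute_prs(dosage_matrix(d2, letters[1:10], panel$rsid),
                            panel)$prs
      expect_gte(bumped[i], base[i])
      expect_equal(bumped[-i], base[-i])
    }
  })
})

test_that("quintile thresholds derive from reference percentiles", {
  ref <- as.numeric(1:100)
  t <- derive_quintile_thresholds(ref)
  expect_equal(as.numeric(t),
               unname(quantile(ref, c(0.2, 0.4, 0.6, 0.8), type = 7)))
  expect_error(derive_quintile_thresholds(c(1, 2, 3)), "at least 5")
  expect_error(derive_quintile_thresholds(rep(5, 50)), "ascending")
  expect_equal(as.numeric(amd_quintile_thresholds()),
               c(25.3, 29.9, 34.5, 39.1))
})

test_that("risk group assignment honors the published boundaries", {
  t <- amd_quintile_thresholds()
  expect_equal(assign_risk_group(25.3, t), 1L)
  expect_equal(assign_risk_group(25.31, t), 2L)
  expect_equal(assign_risk_group(29.9, t), 2L)
  expect_equal(assign_risk_group(29.91, t), 3L)
  expect_equal(assign_risk_group(34.5, t), 3L)
  expect_equal(assign_risk_group(34.51, t), 4L)
  expect_equal(assign_risk_group(39.1, t), 4L)
  expect_equal(assign_risk_group(40, t), 5L)

  # the groups partition the line: every value gets exactly one group,
  # assignment is monotone
  withr::with_seed(23, {
    x <- sort(runif(500, 10, 55))
    g <- assign_risk_group(x, t)
    expect_true(all(g %in% 1:5))
    expect_true(all(diff(g) >= 0))
  })
  expect_error(quintile_thresholds(c(1, 2, 2, 3)), "ascending")
})

test_that("strong-effect QC flags only strong variants with missingness", {
  panel <- toy_panel(or = c(1.47, 1.05, 2.0))
  full <- dosage_matrix(matrix(1L, 10, 3), sprintf("i%d", 1:10), panel$rsid)
  expect_true(qc_strong_effect(full, panel)$pass)

  d <- matrix(1L, 10, 3)
  d[1:5, 1] <- NA   # 50% missing on the OR = 1.47 variant
  d[1:5, 2] <- NA   # 50% missing on the weak OR = 1.05 variant
  qc <- qc_strong_effect(dosage_matrix(d, sprintf("i%d", 1:10), panel$rsid),
                         panel)
  expect_false(qc$pass)
  expect_equal(qc$strong_effect_flags, "rsT1")
  expect_equal(qc$per_variant$missing_fraction, c(0.5, 0.5, 0))
  expect_false(qc$per_variant$flagged[2])
})

test_that("score_cohort attaches risk groups and writes TSV", {
  panel <- synthetic_panel_47()
  dm <- simulate_genotypes(panel, 200, seed = 61)
  tab <- score_cohort(dm, panel)
  expect_true(all(tab$risk_group %in% 1:5))
  expect_equal(tab$risk_group,
               assign_risk_group(tab$prs, amd_quintile_thresholds()))
  derived <- score_cohort(dm, panel, thresholds = NULL)
  expect_equal(unname(table(derived$risk_group)), rep(40L, 5L),
               ignore_attr = TRUE)
  path <- tempfile(fileext = ".tsv")
  write_prs_table(tab, path)
  back <- read.delim(path)
  expect_equal(back$prs, tab$prs)
})

test_that("most preset cases land in the upper risk groups", {
  pre <- make_iamdgc_preset(seed = 8)
  tab <- score_cohort(pre$valid$dosages, pre$panel)
  case_groups <- tab$risk_group[pre$valid$phenotypes$status == "case"]
  expect_gt(mean(case_groups >= 3), 0.6)
  ctrl_groups <- tab$risk_group[pre$valid$phenotypes$status == "control"]
  expect_gt(quintile_fraction(case_groups), quintile_fraction(ctrl_groups))
})
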