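test_that("the packaged panel loads with the expected structure", {
  rec <- load_chemistry()
  expect_true(all(c("cohort", "animal", "round", "pH", "iCa", "status",
                    "suspect") %in% names(rec)))
  c12 <- dplyr::filter(rec, cohort %in% 1:2)
  expect_equal(sum(c12$round == "baseline"), 24)
  expect_equal(sum(c12$round == "1"), 20)
  expect_equal(sum(!c12$round %in% c("baseline", "1")), 43)
  expect_true(all(rec$iCa > 0, na.rm = TRUE))
})

test_that("chemistry records round-trip through CSV", {
  rec <- load_chemistry()
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(rec, path)
  back <- load_chemistry(path)
  expect_equal(as.data.frame(back), as.data.frame(rec))
})

test_that("missing-status records are excluded from aggregation", {
  rec <- tibble::tibble(
    cohort = 3L, animal = 1L, round = c("baseline", "1", "1"),
    pH = c(7.4, 7.2, 7.9), iCa = c(1.3, 1.2, 9),
    bolus_ca = NA_integer_, epi = NA_integer_,
    status = c("ok", "ok", "missing"), suspect = FALSE
  )
  agg <- aggregate_chemistry(rec)
  r1 <- agg[agg$group == "round1" & agg$analyte == "iCa", ]
  expect_equal(r1$n, 1)
  expect_equal(r1$mean, 1.2)
  expect_true(is.na(r1$sd)) # single record: sample SD undefined
})

test_that("invalid round/cohort combinations are rejected with the row", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cohort,animal,round,pH,iCa,bolus_ca,epi,status,suspect",
               "2,1,5,7.4,1.2,,,ok,FALSE"), path)
  expect_error(load_chemistry(path), "row")
})

test_that("group summaries reproduce the verified cells and flag the rest", {
  report <- chemistry_report()
  base_ica <- report[report$group == "baseline" & report$analyte == "iCa", ]
  expect_true(base_ica$mean_matches && base_ica$sd_matches)
  other_ica <- report[report$group == "other" & report$analyte == "iCa", ]
  expect_false(other_ica$mean_matches) # recomputes to 1.21, not the printed 1.19
  expect_equal(round(other_ica$mean_computed, 2), 1.21)
  expect_true(all(report$n_matches))
})

test_that("one-way ANOVA behaves on canonical inputs", {
  same <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  res <- one_way_anova(same)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)

  # two groups: F equals the square of the pooled two-sample t statistic
  g1 <- c(4.1, 5.2, 6.3, 5.5)
  g2 <- c(6.8, 7.7, 7.1)
  res2 <- one_way_anova(list(g1, g2))
  tt <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(res2$F, unname(tt$statistic)^2, tolerance = 1e-12)

  expect_error(one_way_anova(list(c(1, 2))), "2 groups")
  expect_error(one_way_anova(list(c(1, 2), 3)), "n >= 2")
})

test_that("ANOVA matches a brute-force sum-of-squares oracle", {
  set.seed(5)
  for (i in 1:20) {
    groups <- lapply(sample(2:5, sample(2:4, 1), replace = TRUE) + 1,
                     function(n) rnorm(n, sample(0:3, 1)))
    got <- one_way_anova(groups)
    want <- brute_force_anova(groups)
    expect_equal(got$F, want$F, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
    expect_equal(got$df_between, want$df_between)
    expect_equal(got$df_within, want$df_within)
  }
})

test_that("per-animal and pooled groupings are both available", {
  c12 <- dplyr::filter(load_chemistry(), cohort %in% 1:2)
  per <- chemistry_anova(c12, rounds2plus = "per_animal")
  pooled <- chemistry_anova(c12, rounds2plus = "pooled")
  expect_equal(per$df_between, 2)
  # per-animal: 24 + 20 + 15 animals - 3 groups
  expect_equal(per$df_within, 24 + 20 + 15 - 3)
  expect_equal(pooled$df_within, 24 + 20 + 43 - 3)
  expect_false(isTRUE(all.equal(per$p, pooled$p)))
})
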