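test_that("the QC depth gate is inclusive at the boundary", {
  tab <- toy_table(matrix(c(4999L, 5000L, 12000L), 1, 3))
  md <- toy_metadata(sample_ids(tab), rep("floor", 3))
  out <- qc_filter(tab, md, min_depth = 5000)
  expect_equal(sort(sample_ids(out$table)), c("s2", "s3"))
  expect_equal(sum(out$report$pass), 2L)

  all_pass <- qc_filter(tab, md, min_depth = 1)
  expect_equal(ncol(all_pass$table$counts), 3L)
})

test_that("QC pass counts match a brute-force column-sum count", {
  b <- simulate_cleanroom_study(study_config(seed = 17, n_features = 60))
  out <- qc_filter(b$table, b$metadata, 5000)
  expect_equal(sum(out$report$pass), sum(colSums(b$table$counts) >= 5000))
  expect_identical(unname(out$report$totals), unname(colSums(b$table$counts)))
})

test_that("the two-clause contaminant rule works on the worked toy", {
  # f1: controls (10, 12), floors (1, 0, 2); f2: controls (0, 5), floors 9s
  cnt <- rbind(f1 = c(10, 12, 1, 0, 2), f2 = c(0, 5, 9, 9, 9))
  tab <- toy_table(cnt, fids = c("f1", "f2"),
                   sids = c("c1", "c2", "s1", "s2", "s3"))
  md <- toy_metadata(sample_ids(tab),
                     c("negative_control", "extraction_control",
                       "floor", "floor", "floor"))
  out <- flag_contaminants(tab, md)
  expect_identical(out$report$flagged, "f1")
  expect_false("f1" %in% feature_ids(out$table))
  expect_true("f2" %in% feature_ids(out$table))
})

test_that("both clauses are required: prevalence and control abundance", {
  # f1 misses one control; f2 in all controls but floors dominate
  cnt <- rbind(f1 = c(5, 0, 5, 0, 0), f2 = c(3, 3, 3, 50, 50))
  tab <- toy_table(cnt, sids = c("c1", "c2", "c3", "s1", "s2"))
  md <- toy_metadata(sample_ids(tab),
                     c(rep("negative_control", 3), "floor", "floor"))
  out <- flag_contaminants(tab, md)
  expect_length(out$report$flagged, 0L)
})

test_that("running decontamination without controls is an explicit error", {
  tab <- toy_table(matrix(1L, 2, 2))
  md <- toy_metadata(sample_ids(tab), c("floor", "floor"))
  expect_error(flag_contaminants(tab, md), "skip decontamination")
})

test_that("contaminant flags equal the double-loop oracle on random tables", {
  set.seed(2024)
  for (i in 1:200) {
    d <- random_design_table(n_feat = sample(2:10, 1),
                             n_floor = sample(2:8, 1),
                             n_ctrl = sample(1:4, 1))
    got <- flag_contaminants(d$table, d$metadata)$report$flagged
    want <- oracle_flag_contaminants(d$table, d$metadata)
    expect_identical(got, want)
  }
})

test_that("flagging never removes a feature absent from every control", {
  set.seed(31)
  for (i in 1:30) {
    d <- random_design_table(6, 5, 3)
    ctrl <- d$metadata$sample_id[d$metadata$sample_type != "floor"]
    flagged <- flag_contaminants(d$table, d$metadata)$report$flagged
    if (length(flagged))
      expect_true(all(rowSums(d$table$counts[flagged, ctrl,
                                             drop = FALSE] > 0) > 0))
  }
})

test_that("control-prevalence stats match exhaustive enumeration", {
  cnt <- rbind(f1 = c(1, 0, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
               f2 = c(2, 3, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0),
               f3 = c(0, 0, 5, 5, 5, 5, 5, 5, 5, 5, 5, 5),
               f4 = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
               f5 = c(4, 4, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0))
  tab <- toy_table(cnt, sids = c(paste0("c", 1:2), paste0("s", 1:10)))
  md <- toy_metadata(sample_ids(tab),
                     c(rep("negative_control", 2), rep("floor", 10)))
  got <- control_prevalence_stats(tab, md, prevalence_cut = 0.2)
  # by hand: f1, f2, f5 occur in a control; study prevalence 1.0, 0.1, 0.1
  expect_equal(got$n_control_features, 3L)
  expect_equal(got$n_rare_in_study, 2L)

  none <- control_prevalence_stats(
    ft_subset(tab, features = "f4"), md, 0.2)
  expect_equal(none$n_control_features, 0L)
  expect_equal(none$n_rare_in_study, 0L)

  full <- control_prevalence_stats(tab, md, prevalence_cut = 1.0)
  present_everywhere <- sum(rowSums(cnt[, 3:12] > 0) == 10 &
                              rowSums(cnt[, 1:2] > 0) > 0)
  expect_equal(full$n_rare_in_study,
               full$n_control_features - present_everywhere)
})

test_that("rarefaction hits the target depth exactly and never inflates", {
  tab <- toy_table(matrix(c(7000L, 0L, 3000L, 4000L, 100L, 200L), 2, 3))
  r <- rarefy(tab, depth = 5000, seed = 1)
  expect_equal(ncol(r$counts), 2L)  # the 300-read sample is dropped
  expect_true(all(colSums(r$counts) == 5000L))
  expect_equal(r$counts[1L, "s1"], 5000L)  # single-support sample
  expect_true(all(r$counts <= tab$counts[, sample_ids(r)]))

  expect_identical(rarefy(tab, 5000, seed = 9)$counts,
                   rarefy(tab, 5000, seed = 9)$counts)
})

test_that("rarefied counts follow the hypergeometric expectation", {
  tab <- toy_table(matrix(c(6000L, 4000L), 2, 1))
  draws <- vapply(1:2000, function(s)
    rarefy(tab, 5000, seed = s)$counts[1L, 1L], numeric(1))
  expectation <- 5000 * 6000 / 10000
  v <- 5000 * 0.6 * 0.4 * (10000 - 5000) / (10000 - 1)
  se <- sqrt(v / length(draws))
  expect_lt(abs(mean(draws) - expectation), 3 * se)
})
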