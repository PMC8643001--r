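test_that("features bin into NSA / non-NSA spore / non-spore categories", {
  tax <- c(f1 = "k__Bacteria;g__Bacillus",
           f2 = "k__Bacteria;g__Clostridium",
           f3 = "k__Bacteria;g__Sphingobium",
           f4 = "k__Bacteria;g__Geobacillus")
  cnt <- matrix(c(500L, 500L, 500L, 100L), 4, 1,
                dimnames = list(names(tax), "s1"))
  tab <- feature_table(cnt, tax)
  labels <- c(f1 = "spore_former", f2 = "spore_former",
              f3 = "non_spore_former", f4 = "spore_former")
  cm <- classify_taxa(tab, labels, read_threshold = 100)
  expect_equal(cm$category[cm$feature_id == "f1"], "nsa_spore")
  expect_equal(cm$category[cm$feature_id == "f2"], "non_nsa_spore")
  expect_equal(cm$category[cm$feature_id == "f3"], "non_spore")
  # exactly at the threshold -> excluded (strict > rule)
  expect_equal(cm$category[cm$feature_id == "f4"], "excluded")
})

test_that("spore labels work as logicals and without taxonomy", {
  cnt <- matrix(c(500L, 500L), 2, 1, dimnames = list(c("f1", "f2"), "s1"))
  tab <- feature_table(cnt)
  expect_message(cm <- classify_taxa(tab, c(f1 = TRUE, f2 = FALSE)),
                 "without a resolvable genus")
  expect_equal(cm$category, c("non_nsa_spore", "non_spore"))
})

test_that("category read fractions are normalized per group", {
  tax <- c(f1 = "g__Bacillus", f2 = "g__Clostridium", f3 = "g__Sphingobium")
  cnt <- matrix(c(1000L, 2000L, 7000L,
                  300L, 300L, 2400L), 3, 2,
                dimnames = list(names(tax), c("s1", "s2")))
  tab <- feature_table(cnt, tax)
  labels <- c(f1 = "spore_former", f2 = "spore_former",
              f3 = "non_spore_former")
  cm <- classify_taxa(tab, labels, read_threshold = 100)
  fr <- category_fractions(tab, cm)
  expect_equal(fr$fraction[fr$category == "nsa_spore"], 0.10)
  expect_equal(fr$fraction[fr$category == "non_nsa_spore"], 0.1769231,
               tolerance = 1e-6)
  expect_equal(sum(fr$fraction), 1, tolerance = 1e-12)

  md <- toy_metadata(c("s1", "s2"), c("floor", "floor"),
                     session_index = c(1L, 2L))
  by_sess <- category_fractions(tab, cm, md, group_by = "session")
  for (g in unique(by_sess$group))
    expect_equal(sum(by_sess$fraction[by_sess$group == g]), 1,
                 tolerance = 1e-12)
  expect_equal(by_sess$fraction[by_sess$group == "1" &
                                  by_sess$category == "non_spore"], 0.7)
})

test_that("a single represented category takes the whole fraction", {
  cnt <- matrix(c(500L, 300L), 2, 1, dimnames = list(c("f1", "f2"), "s1"))
  tab <- feature_table(cnt)
  cm <- suppressMessages(classify_taxa(tab, c(f1 = FALSE, f2 = FALSE)))
  fr <- category_fractions(tab, cm)
  expect_equal(fr$fraction[fr$category == "non_spore"], 1.0)
})

test_that("group log-ratios are scale invariant and antisymmetric", {
  cnt <- matrix(c(50L, 50L, 60L, 40L, 100L, 10L, 0L, 7L), 2, 4,
                dimnames = list(c("f1", "f2"), paste0("s", 1:4)))
  tab <- feature_table(cnt)
  lr <- group_log_ratio(tab, "f1", "f2")
  expect_equal(unname(lr$values["s1"]), 0)
  expect_equal(unname(lr$values["s3"]), log(10))
  expect_equal(lr$dropped, "s4")  # zero numerator sum

  scaled <- feature_table(cnt * 7L)
  lr7 <- group_log_ratio(scaled, "f1", "f2")
  expect_equal(lr7$values, lr$values)

  rev <- group_log_ratio(tab, "f2", "f1")
  expect_equal(rev$values, -lr$values)
  expect_error(group_log_ratio(tab, c("f1", "f2"), "f2"), "overlap")
})

test_that("log-ratio comparisons are Welch t with Bonferroni", {
  same <- c(a1 = 1, a2 = 2, a3 = 3, b1 = 1, b2 = 2, b3 = 3)
  grp <- c(rep("A", 3), rep("B", 3))
  res <- compare_log_ratio(same, grp)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)

  set.seed(5)
  sep <- c(rnorm(4, 0, 1e-6), rnorm(4, 1, 1e-6))
  names(sep) <- paste0("x", 1:8)
  res2 <- compare_log_ratio(sep, rep(c("A", "B"), each = 4))
  expect_lt(res2$p, 1e-6)

  set.seed(6)
  v <- rnorm(10); names(v) <- paste0("v", 1:10)
  g <- rep(c("A", "B"), 5)
  raw <- stats::t.test(v ~ factor(g))$p.value
  res3 <- compare_log_ratio(v, g, n_comparisons = 3)
  expect_equal(res3$p_adjusted, min(1, raw * 3))
})

test_that("the gradient correlation matches hand geometry", {
  md <- toy_metadata(paste0("s", 1:3), rep("floor", 3),
                     pma_treated = TRUE, location_id = 1:3,
                     radius = c(0, 1, 2))
  # symmetric tent: correlation exactly 0
  tent <- setNames(c(0, 1, 0), paste0("s", 1:3))
  g0 <- gradient_correlation(tent, md)
  expect_equal(g0$r, 0)

  lin <- setNames(c(0, 0.5, 1), paste0("s", 1:3))
  g1 <- gradient_correlation(lin, md)
  expect_equal(g1$r, 1.0)
})

test_that("gradient r equals a from-scratch covariance implementation", {
  set.seed(91)
  for (i in 1:20) {
    k <- sample(4:10, 1)
    md <- toy_metadata(paste0("s", 1:k), rep("floor", k),
                       pma_treated = TRUE, location_id = 1:k,
                       radius = sort(runif(k, 10, 1000)))
    v <- setNames(rnorm(k), paste0("s", 1:k))
    g <- gradient_correlation(v, md)
    x <- md$radius; y <- unname(v)
    r_hand <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(g$r, r_hand, tolerance = 1e-12)
    tstat <- r_hand * sqrt((k - 2) / (1 - r_hand^2))
    expect_equal(g$p, 2 * pt(-abs(tstat), k - 2), tolerance = 1e-12)
  }
})

test_that("gradient filtering honors the PMA subset choice", {
  md <- toy_metadata(paste0("s", 1:6), rep("floor", 6),
                     pma_treated = rep(c(TRUE, FALSE), 3),
                     location_id = rep(1:3, each = 2),
                     radius = rep(c(10, 20, 30), each = 2))
  v <- setNames(c(1, 100, 2, 100, 3, 100), paste0("s", 1:6))
  g <- gradient_correlation(v, md, samples = "pma_treated")
  expect_equal(g$per_location$mean_log_ratio, c(1, 2, 3))
  expect_equal(g$r, 1.0)
})

test_that("richness tests flag the planted PMA viability deficit", {
  b <- simulate_cleanroom_study(study_config(seed = 23))
  qc <- qc_filter(b$table, b$metadata, 5000)
  r <- rarefy(qc$table, 5000, seed = 2)
  res <- richness_tests(r, b$metadata)
  expect_lt(res$kruskal$p, 0.01)
  rich <- res$richness
  md <- b$metadata[match(rich$sample_id, b$metadata$sample_id), ]
  naive <- rich$richness[md$sample_type == "floor" & !md$pma_treated]
  treated <- rich$richness[md$sample_type == "floor" & md$pma_treated]
  expect_gt(mean(naive), mean(treated))
})

test_that("identical richness across groups gives a zero KW statistic", {
  cnt <- matrix(rep(c(10L, 10L, 0L), 4), 3, 4,
                dimnames = list(paste0("f", 1:3), paste0("s", 1:4)))
  tab <- feature_table(cnt)
  md <- toy_metadata(paste0("s", 1:4), rep("floor", 4),
                     pma_treated = c(TRUE, TRUE, FALSE, FALSE))
  res <- richness_tests(tab, md)
  expect_equal(res$kruskal$statistic, 0)
})

test_that("pairwise post hoc p-values carry Benjamini-Hochberg adjustment", {
  set.seed(14)
  rich <- c(rnorm(8, 10), rnorm(8, 14), rnorm(8, 30))
  grp <- rep(c("a", "b", "c"), each = 8)
  raw <- c(
    wilcox.test(rich[grp == "a"], rich[grp == "b"])$p.value,
    wilcox.test(rich[grp == "a"], rich[grp == "c"])$p.value,
    wilcox.test(rich[grp == "b"], rich[grp == "c"])$p.value)
  adj <- p.adjust(raw, "BH")
  pw <- suppressWarnings(
    stats::pairwise.wilcox.test(rich, grp, p.adjust.method = "BH"))$p.value
  expect_equal(unname(c(pw["b", "a"], pw["c", "a"], pw["c", "b"])), adj)
})

test_that("rank:name selectors aggregate features by lineage", {
  tax <- c(f1 = "k__Bacteria;o__Pseudomonadales;g__Pseudomonas",
           f2 = "k__Bacteria;o__Bacillales;g__Bacillus",
           f3 = "k__Bacteria;o__Pseudomonadales;g__Azotobacter")
  expect_setequal(features_matching(tax, "o:Pseudomonadales"),
                  c("f1", "f3"))
  expect_equal(features_matching(tax, "g:Bacillus"), "f2")
  expect_equal(genus_of(tax[["f2"]]), "Bacillus")
  expect_equal(genus_of("Bacteria;Firmicutes;Bacilli"), "Bacilli")
  expect_true(is.na(genus_of("k__Bacteria;g__")))
})

test_that("isolate tallies report the spore-former percentage", {
  s <- isolate_spore_summary(c("Bacillus", "Bacillus", "Micrococcus"))
  expect_equal(s$n_spore_formers, 2L)
  expect_equal(s$percent_spore_formers, 200 / 3, tolerance = 1e-12)
})
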