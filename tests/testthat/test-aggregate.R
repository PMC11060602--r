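make_leaves <- function(values_by_rep, group = "g", measure = "length") {
  dplyr::bind_rows(purrr::imap(values_by_rep, function(v, r) {
    tibble::tibble(group = group, replicate = r, image = 1,
                   scan = seq_along(v), measure = measure, value_nm = v)
  }))
}

test_that("two-stage averaging uses unweighted replicate means", {
  leaves <- make_leaves(list(c(2, 2), c(4, 4)))
  nm <- aggregate_measures(leaves)
  expect_equal(nm$by_group$mean_nm, 3)
  # closed form on replicate means [2, 4]: sample SD and CV%
  expect_equal(nm$by_group$sd_nm, sqrt(2), tolerance = 1e-6)
  expect_equal(nm$by_group$cv_pct, 100 * sqrt(2) / 3, tolerance = 1e-6)

  # unbalanced design: grand mean is the unweighted mean of replicate means,
  # not the leaf mean
  unb <- make_leaves(list(rep(2, 8), c(4, 4)))
  nm2 <- aggregate_measures(unb)
  expect_equal(nm2$by_group$mean_nm, 3)
  expect_false(isTRUE(all.equal(nm2$by_group$mean_nm, mean(unb$value_nm))))
})

test_that("sample statistics use the n-1 denominator everywhere", {
  leaves <- make_leaves(list(c(2, 4)))
  nm <- aggregate_measures(leaves)
  rep_row <- nm$by_replicate
  expect_equal(rep_row$sd_nm, sd(c(2, 4)))        # 1.4142
  expect_equal(rep_row$cv_pct, 100 * sd(c(2, 4)) / 3, tolerance = 1e-4) # 47.14
})

test_that("summaries are exactly recomputable from the stored leaves", {
  leaves <- withr::with_seed(8, tibble::tibble(
    group = rep(c("a", "b"), each = 30),
    replicate = rep(rep(1:3, each = 10), 2),
    image = rep(rep(1:2, each = 5), 6),
    scan = rep(1:5, 12),
    measure = "width",
    value_nm = rnorm(60, 100, 10)))
  nm <- aggregate_measures(leaves)
  again <- aggregate_measures(nm$leaves)
  expect_identical(nm$by_image, again$by_image)
  expect_identical(nm$by_replicate, again$by_replicate)
  expect_identical(nm$by_group, again$by_group)
  # grand mean identity per group
  for (g in c("a", "b")) {
    reps <- nm$by_replicate$mean_nm[nm$by_replicate$group == g]
    expect_equal(nm$by_group$mean_nm[nm$by_group$group == g], mean(reps))
  }
  # tidy/glance accessors
  expect_identical(tidy(nm), nm$by_group)
  expect_equal(glance(nm)$n_replicates, 6)
})

test_that("identical groups give a null t-test and insufficient replication errors", {
  x <- c(2000, 2400, 2800)
  leaves <- dplyr::bind_rows(
    make_leaves(list(x, x, x), group = "a"),
    make_leaves(list(x, x, x), group = "b"))
  cmp <- compare_groups(leaves)
  tt <- cmp$tests[cmp$tests$test == "welch_t_replicate_means", ]
  expect_gt(tt$p_value, 0.99)

  one_rep <- dplyr::bind_rows(make_leaves(list(x), group = "a"),
                              make_leaves(list(x, x), group = "b"))
  expect_error(compare_groups(one_rep), "insufficient replication")
})

test_that("the leaf-level F-test detects a 9-fold variance ratio at alpha 0.01", {
  leaves <- withr::with_seed(21, dplyr::bind_rows(
    make_leaves(split(rnorm(50, 2400, 30), rep(1:5, each = 10)), group = "a"),
    make_leaves(split(rnorm(50, 2400, 90), rep(1:5, each = 10)), group = "b")))
  cmp <- compare_groups(leaves, design = "two_sample")
  ft <- cmp$tests[cmp$tests$test == "f_variance_leaves", ]
  expect_lt(ft$p_value, 0.01)
})

test_that("the multi-group ANOVA is calibrated under the null", {
  # three identical-distribution groups, many seeds: F should average ~1
  fs <- vapply(1:200, function(s) {
    leaves <- withr::with_seed(s, dplyr::bind_rows(purrr::map(
      c("a", "b", "c"),
      function(g) make_leaves(split(rnorm(30, 2400, 60), rep(1:3, each = 10)),
                              group = g))))
    cmp <- compare_groups(leaves, design = "multi")
    cmp$tests$statistic[cmp$tests$test == "anova_replicate_means"]
  }, numeric(1))
  # under H0 the statistic is F(2, 6): E[F] = 6/4 = 1.5, SD ~2.6
  expect_lt(abs(mean(fs) - 1.5), 3 * 2.6 / sqrt(200))
  expect_lt(abs(median(fs) - qf(0.5, 2, 6)), 0.3)
})

test_that("multi-group comparisons report Holm-adjusted pairwise tests", {
  leaves <- withr::with_seed(3, dplyr::bind_rows(
    make_leaves(split(rnorm(30, 2000, 20), rep(1:3, each = 10)), group = "a"),
    make_leaves(split(rnorm(30, 2400, 20), rep(1:3, each = 10)), group = "b"),
    make_leaves(split(rnorm(30, 2800, 20), rep(1:3, each = 10)), group = "c")))
  cmp <- compare_groups(leaves, design = "multi")
  an <- cmp$tests[cmp$tests$test == "anova_replicate_means", ]
  expect_lt(an$p_value, 0.001)
  pw <- cmp$tests[cmp$tests$test == "pairwise_welch_holm", ]
  expect_equal(nrow(pw), 3)
  expect_true(all(pw$p_adjust <= 1))
})
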