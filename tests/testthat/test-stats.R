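# Nonparametric statistics: exact Wilcoxon routines against enumeration and
# stats::wilcox.test, the adjusted correlation matrix, kappa, and the
# cluster permutation test.

test_that("signed-rank exact p-values match hand enumeration", {
  t1 <- wilcoxon_signed_rank(c(1, 2, 3), alternative = "greater")
  expect_equal(t1$statistic, 6)
  expect_equal(t1$p_value, 0.125) # all-positive pattern: 1 of 8

  t2 <- wilcoxon_signed_rank(c(4, -4))
  expect_equal(t2$p_value, 1) # symmetric pair

  expect_error(wilcoxon_signed_rank(c(0, 0)), "zero")
})

test_that("signed-rank matches wilcox.test exactly when no ties", {
  set.seed(5)
  for (i in 1:15) {
    n <- sample(4:20, 1)
    d <- rnorm(n)
    got <- wilcoxon_signed_rank(d)
    want <- stats::wilcox.test(d, exact = TRUE)
    expect_equal(got$p_value, want$p.value, tolerance = 1e-12)
    expect_equal(got$statistic, unname(want$statistic))
  }
})

test_that("signed-rank exact and normal approximation agree at n = 30", {
  set.seed(8)
  for (i in 1:5) {
    d <- rnorm(30, 0.2)
    exact <- wilcoxon_signed_rank(d, exact_max = 30)
    approx <- wilcoxon_signed_rank(d, exact_max = 0)
    expect_lt(abs(exact$p_value - approx$p_value), 0.02)
  }
})

test_that("rank-sum exact p-values match enumeration and wilcox.test", {
  t1 <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(t1$statistic, 0)
  expect_equal(t1$p_value, 1 / 3)

  x <- c(2, 2, 2); expect_equal(wilcoxon_rank_sum(x, x)$p_value, 1)

  set.seed(13)
  for (i in 1:15) {
    n1 <- sample(3:8, 1); n2 <- sample(3:10, 1)
    x <- rnorm(n1); y <- rnorm(n2, 0.5)
    got <- wilcoxon_rank_sum(x, y)
    want <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(got$p_value, want$p.value, tolerance = 1e-12)
  }
})

test_that("rank-sum detects a large shift", {
  set.seed(2)
  x <- rnorm(15); y <- rnorm(15, 4)
  expect_lt(wilcoxon_rank_sum(x, y)$p_value, 0.001)
})

test_that("correlation matrix is symmetric with Holm-monotone adjusted p", {
  set.seed(31)
  tab <- tibble::tibble(a = rnorm(30), b = rnorm(30))
  tab$c <- tab$a * 0.8 + rnorm(30, 0, 0.3)
  tab$d <- rnorm(30)
  res <- correlation_matrix(tab, method = "spearman", adjust = "holm")
  expect_equal(res$r, t(res$r))
  expect_equal(diag(res$r), setNames(rep(1, 4), names(tab)))
  up <- upper.tri(res$p_raw)
  expect_true(all(res$p_adj[up] >= res$p_raw[up] - 1e-12))
  expect_equal(res$p_adj[up], p.adjust(res$p_raw[up], "holm"))

  # Spearman r equals Pearson r on mid-ranks
  pe <- correlation_matrix(dplyr::mutate(tab, dplyr::across(dplyr::everything(), rank)),
                           method = "pearson")
  expect_equal(res$r, pe$r, tolerance = 1e-12)
})

test_that("Holm step-down matches the hand computation", {
  expect_equal(p.adjust(c(0.01, 0.04, 0.03), "holm"), c(0.03, 0.06, 0.06))
})

test_that("constant columns are flagged, not fatal", {
  tab <- tibble::tibble(a = rnorm(10), b = rep(2, 10), c = rnorm(10))
  res <- correlation_matrix(tab)
  expect_true(is.na(res$r["a", "b"]))
  expect_equal(res$flag["a", "b"], "constant")
  expect_false(is.na(res$r["a", "c"]))
})

test_that("Cohen's kappa matches the closed form", {
  expect_equal(cohen_kappa(c("x", "y", "x"), c("x", "y", "x")), 1)

  # 2x2 table a=20, b=5, c=10, d=15: p_o = 0.7, p_e = 0.5, kappa = 0.4
  a_lab <- c(rep("P", 25), rep("N", 25))
  b_lab <- c(rep("P", 20), rep("N", 5), rep("P", 10), rep("N", 15))
  expect_equal(cohen_kappa(a_lab, b_lab), 0.4)

  set.seed(17)
  ka <- cohen_kappa(sample(c("u", "v"), 4000, TRUE), sample(c("u", "v"), 4000, TRUE))
  expect_lt(abs(ka), 0.06) # chance level

  expect_warning(k1 <- cohen_kappa(rep("x", 5), rep("x", 5)), "undefined")
  expect_true(is.na(k1))
  expect_error(cohen_kappa("x", c("x", "y")), "equal length")
})

test_that("cluster permutation test is calibrated and deterministic", {
  set.seed(23)
  cl <- rep(sprintf("d%02d", 1:10), each = 3)
  grp <- rep(rep(c("A", "B"), each = 5), each = 3)
  y_null <- rnorm(30)
  t1 <- permutation_group_compare(y_null, grp, cl, n_perm = 499, seed = 7)
  t2 <- permutation_group_compare(y_null, grp, cl, n_perm = 499, seed = 7)
  expect_identical(t1$p_value, t2$p_value)
  expect_gt(t1$p_value, 0.05)

  # identical groups: p near 1
  y_same <- rep(rnorm(10)[as.integer(factor(cl))], 1)
  t3 <- permutation_group_compare(rep(0, 30) + rnorm(30, 0, 1e-8), grp, cl,
                                  n_perm = 199, seed = 1)
  expect_gt(t3$p_value, 0.5)

  expect_warning(
    permutation_group_compare(rnorm(8), rep(c("A", "B"), each = 4),
                              rep(1:4, each = 2), n_perm = 99, seed = 1),
    "coarse")
})

test_that("cluster permutation test has power against a 2x mean shift", {
  hits <- vapply(1:20, function(k) {
    set.seed(400 + k)
    cl <- rep(sprintf("d%02d", 1:30), each = 3)
    grp <- rep(rep(c("A", "B"), each = 15), each = 3)
    mu <- ifelse(grp == "A", 2, 1)
    y <- rnorm(90, mu, 0.8)
    permutation_group_compare(y, grp, cl, n_perm = 199, seed = k)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("model-matrix export carries outcome, fixed and grouping columns", {
  meta <- read_session_meta(toy_path("toy_meta.csv"))
  summaries <- tibble::tibble(session_id = meta$session_id,
                              avoidance_count = seq_len(nrow(meta)))
  mm <- attachment_model_matrix(summaries, meta, "avoidance_count")
  expect_setequal(names(mm), c("session_id", "outcome", "pnd", "rearing",
                               "caregiver_role", "caregiver_id", "infant_id",
                               "family_id"))
  expect_equal(mm$outcome, seq_len(nrow(meta)))
})
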