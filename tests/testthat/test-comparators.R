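test_that("COPA contrasts the case percentile against the overall median", {
  withr::with_seed(21, {
    ctrl <- rnorm(20)
    # no group difference, symmetric data: statistic stays moderate
    expect_lt(abs(copa_stat(ctrl, ctrl, r = 0.9)), 2)
    # planted extreme outlier drives it up
    cases <- c(rnorm(9), 10)
    expect_gt(copa_stat(rep(0, 10) + rnorm(10, sd = 0.1), cases, r = 0.95),
              5)
    # location/scale equivariance of the ratio
    g <- random_gene()
    expect_equal(copa_stat(2 * g$controls, 2 * g$cases),
                 copa_stat(g$controls, g$cases))
    expect_equal(copa_stat(g$controls + 3, g$cases + 3),
                 copa_stat(g$controls, g$cases))
  })
  expect_true(is.na(copa_stat(rep(1, 5), rep(1, 5))))
  expect_error(copa_stat(1:5, 1:5, r = 0.4), "r")
})

test_that("OS sums standardised case values beyond the outer fence", {
  withr::with_seed(22, {
    ctrl <- rnorm(10)
    inside <- stats::quantile(c(ctrl, ctrl), 0.75) - 0.01
    expect_identical(os_stat(ctrl, rep(inside, 4)), 0)
    # one case at +10 overall-MAD units: sum is about its standardised value
    cases <- c(rnorm(9), 10)
    s <- os_stat(ctrl, cases)
    all <- c(ctrl, cases)
    expect_equal(s, (10 - median(all)) / mad(all), tolerance = 1e-12)
    g <- random_gene()
    expect_equal(os_stat(g$controls + 5, g$cases + 5),
                 os_stat(g$controls, g$cases))
    expect_equal(os_stat(2 * g$controls, 2 * g$cases),
                 os_stat(g$controls, g$cases))
  })
  expect_true(is.na(os_stat(rep(2, 4), rep(2, 4))))
})

test_that("ORT matches a direct hand computation on a toy gene", {
  ctrl <- c(1, 2, 3, 4, 100)
  cases <- c(2.5, 9, 12)
  # by hand: q75(ctrl)=4, IQR=2, fence=6 -> outliers 9 and 12
  # median(ctrl)=3, deviations |ctrl-3| = 2 1 0 1 97; |case-9| = 6.5 0 3
  # pooled median of {2,1,0,1,97,6.5,0,3} = 1.5; scale = 1.4826*1.5
  expected <- ((9 - 3) + (12 - 3)) / (1.4826 * 1.5)
  expect_equal(ort_stat(ctrl, cases), expected, tolerance = 1e-12)
  expect_identical(ort_stat(c(0, 1, 2, 3), c(1, 2)), 0)
  withr::with_seed(23, {
    g <- random_gene()
    expect_equal(ort_stat(g$controls + 2, g$cases + 2),
                 ort_stat(g$controls, g$cases))
    expect_equal(ort_stat(2 * g$controls, 2 * g$cases),
                 ort_stat(g$controls, g$cases))
  })
  expect_true(is.na(ort_stat(rep(1, 6), rep(1, 3))))
  expect_error(ort_stat(1:3, 1:3), "n1")
})

test_that("MOST picks the ordered subset and reports its size", {
  withr::with_seed(24, {
    ctrl <- rnorm(10)
    cases <- c(rnorm(7), 8)
    s <- most_stat(ctrl, cases, n_rep = 2e4)
    expect_equal(attr(s, "k"), 1L)  # the single spiked case wins
    # permutation invariance of case order
    s2 <- most_stat(ctrl, sample(cases), n_rep = 2e4)
    expect_equal(as.numeric(s), as.numeric(s2))
    # null sanity: the fixed-k standardised sums are centred (up to the
    # robust-scale estimation bias), and the max statistic stays O(1) --
    # a maximum over k of mean-zero variates necessarily has a small
    # positive mean, far below any planted signal
    cons <- dids:::most_constants(25, n_rep = 2e4)
    z3 <- replicate(300, {
      ctrl <- rnorm(25); cases <- rnorm(25)
      medc <- median(ctrl)
      scale <- 1.4826 * median(c(abs(ctrl - medc),
                                 abs(cases - median(cases))))
      b <- sort(cases, decreasing = TRUE)
      (((cumsum(b) - seq_len(25) * medc) / scale) - cons$mu)[3] /
        cons$sigma[3]
    })
    expect_lt(abs(mean(z3)), 0.5)
    nulls <- replicate(300, {
      as.numeric(most_stat(rnorm(25), rnorm(25), n_rep = 2e4))
    })
    expect_gt(mean(nulls), 0)
    expect_lt(mean(nulls), 2)
    spiked <- replicate(50, {
      as.numeric(most_stat(rnorm(25), c(rnorm(20), rnorm(5) + 6),
                           n_rep = 2e4))
    })
    expect_gt(mean(spiked), mean(nulls) + 5)
  })
  expect_true(is.na(most_stat(rep(1, 5), rep(1, 4))))
})

test_that("classical statistics agree with base R to 1e-8 on 100 fixtures", {
  withr::with_seed(25, {
    for (i in 1:100) {
      n1 <- sample(4:30, 1)
      n2 <- sample(4:30, 1)
      ctrl <- rnorm(n1, sd = runif(1, 0.5, 2))
      cases <- rnorm(n2, mean = runif(1, -1, 1))

      ev <- classical_stat(ctrl, cases, "ttest_ev")
      ref <- stats::t.test(cases, ctrl, var.equal = TRUE)
      expect_equal(ev$statistic, unname(ref$statistic), tolerance = 1e-8)
      expect_equal(ev$p_value, ref$p.value, tolerance = 1e-8)

      uv <- classical_stat(ctrl, cases, "ttest_uv")
      ref <- stats::t.test(cases, ctrl, var.equal = FALSE)
      expect_equal(uv$statistic, unname(ref$statistic), tolerance = 1e-8)
      expect_equal(uv$p_value, ref$p.value, tolerance = 1e-8)

      mw <- classical_stat(ctrl, cases, "mw")
      ref <- suppressWarnings(stats::wilcox.test(cases, ctrl,
                                                 exact = FALSE,
                                                 correct = TRUE))
      expect_equal(mw$statistic, unname(ref$statistic), tolerance = 1e-8)
      expect_equal(mw$p_value, ref$p.value, tolerance = 1e-8)

      ks <- classical_stat(ctrl, cases, "ks")
      ref <- suppressWarnings(stats::ks.test(cases, ctrl, exact = FALSE))
      expect_equal(ks$statistic, unname(ref$statistic), tolerance = 1e-8)
      expect_equal(ks$p_value, ref$p.value, tolerance = 1e-8)
    }
  })
})

test_that("classical statistics honour their symmetries", {
  g <- list(controls = c(1, 2, 3), cases = c(4, 5, 6))
  expect_equal(classical_stat(g$controls, g$cases, "mw")$statistic, 9)
  expect_equal(classical_stat(g$controls, g$cases, "ks")$statistic, 1)
  same <- classical_stat(1:6, 1:6, "ttest_ev")
  expect_equal(same$statistic, 0)
  expect_equal(classical_stat(1:6, 1:6, "ks")$statistic, 0)
  expect_equal(classical_stat(1:6, 1:6, "mw")$statistic, 36 / 2)
  withr::with_seed(26, {
    g <- random_gene(7, 9)
    t1 <- classical_stat(g$controls, g$cases, "ttest_uv")$statistic
    t2 <- classical_stat(g$cases, g$controls, "ttest_uv")$statistic
    expect_equal(t1, -t2)
    u1 <- classical_stat(g$controls, g$cases, "mw")$statistic
    u2 <- classical_stat(g$cases, g$controls, "mw")$statistic
    expect_equal(u1 - 7 * 9 / 2, -(u2 - 7 * 9 / 2))
  })
  expect_true(is.na(classical_stat(rep(1, 4), rep(1, 4),
                                   "ttest_ev")$statistic))
})

test_that("vectorised matrix engines agree with the per-gene statistics", {
  withr::with_seed(27, {
    n1 <- 12; n2 <- 15; n_genes <- 40
    ctrl <- matrix(rnorm(n_genes * n1), n_genes)
    case <- matrix(rnorm(n_genes * n2, mean = 0.3), n_genes)
    per_gene <- function(fun) {
      vapply(seq_len(n_genes),
             function(i) as.numeric(fun(ctrl[i, ], case[i, ])),
             numeric(1))
    }
    expect_equal(dids:::copa_scores(ctrl, case),
                 per_gene(function(a, b) copa_stat(a, b)))
    expect_equal(dids:::os_scores(ctrl, case), per_gene(os_stat))
    expect_equal(dids:::ort_scores(ctrl, case), per_gene(ort_stat))
    expect_equal(dids:::most_scores(ctrl, case, n_rep = 2e4),
                 per_gene(function(a, b) most_stat(a, b, n_rep = 2e4)))
    expect_equal(abs(dids:::t_scores(ctrl, case, TRUE)$statistic),
                 per_gene(function(a, b)
                   abs(classical_stat(a, b, "ttest_ev")$statistic)))
    expect_equal(dids:::mw_scores(ctrl, case)$statistic,
                 per_gene(function(a, b)
                   classical_stat(a, b, "mw")$statistic))
    expect_equal(dids:::ks_scores(ctrl, case)$statistic,
                 per_gene(function(a, b)
                   classical_stat(a, b, "ks")$statistic))
  })
})

test_that("outlier methods rise far above their null level on reporters", {
  withr::with_seed(28, {
    n1 <- 25; n2 <- 25
    null_ctrl <- matrix(rnorm(1000 * n1), 1000)
    null_case <- matrix(rnorm(1000 * n2), 1000)
    rep_ctrl <- matrix(rnorm(1000 * n1), 1000)
    rep_case <- matrix(rnorm(1000 * n2), 1000)
    rep_case[, 1:5] <- rep_case[, 1:5] + 6   # small subgroup, large shift
    for (m in c("dids_tanh", "copa", "os", "ort", "most")) {
      null_mean <- mean(dids:::method_score_matrix(m, null_ctrl, null_case),
                        na.rm = TRUE)
      rep_mean <- mean(dids:::method_score_matrix(m, rep_ctrl, rep_case),
                       na.rm = TRUE)
      expect_gt(rep_mean, null_mean + 3 * 0.5, label = m)
    }
  })
})

test_that("comparator_scores returns a ranked tidy table", {
  td <- toy_dataset()
  res <- comparator_scores(td$expr, td$labels, method = "copa")
  expect_equal(res$rank, seq_len(nrow(res)))
  expect_true(all(diff(res$score) <= 0))
  expect_true(all(is.na(res$p_value)))
  expect_equal(res$gene_id[1], "gene01")  # the spiked gene wins

  most <- comparator_scores(td$expr, td$labels, method = "most")
  expect_true("k_hat" %in% names(most))

  tt <- comparator_scores(td$expr, td$labels, method = "ttest-uv")
  expect_false(any(is.na(tt$p_value)))
  expect_error(comparator_scores(td$expr, td$labels, method = "sam"),
               "unknown method")
})
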