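## Geometric-mean label score identities are checked on a hand-built model
## whose PS bins are known exactly: parameter values 0.5, 1.5, 2.5, 3.5
## index bins 1-4 of each unit-width numeric parameter.

ls_fixture <- function(ps1, ps2, ps3, ps4) {
  model <- manual_ps_model(list(
    "11" = ps1, "9" = ps2, "10" = ps3, "12" = ps4))
  tab <- synthetic_table(1, seed = 1)
  tab[[param_column(11)]] <- 0.5
  tab[[param_column(9)]] <- 0.5
  tab[[param_column(10)]] <- 0.5
  tab[[param_column(12)]] <- 0.5
  list(model = model, tab = tab)
}

test_that("label score equals the geometric mean of the selected PS", {
  f <- ls_fixture(c(1, 1), c(1, 1), c(1, 1), c(1, 1))
  r <- compute_label_score(f$tab, f$model, selection = c(11, 9, 10, 12),
                           allow_same_category = TRUE)
  expect_equal(r$ls, 1)

  f2 <- ls_fixture(c(2, 1), c(2, 1), c(0.5, 1), c(0.5, 1))
  r2 <- compute_label_score(f2$tab, f2$model, selection = c(11, 9, 10, 12),
                            allow_same_category = TRUE)
  expect_equal(r2$ls, 1)

  f3 <- ls_fixture(c(16, 1), c(1, 1), c(1, 1), c(1, 1))
  r3 <- compute_label_score(f3$tab, f3$model, selection = c(11, 9, 10, 12),
                            allow_same_category = TRUE)
  expect_equal(r3$ls, 2)

  ## permutation invariance and single-parameter identity
  r4 <- compute_label_score(f3$tab, f3$model, selection = c(12, 10, 9, 11),
                            allow_same_category = TRUE)
  expect_equal(r4$ls, r3$ls)
  r5 <- compute_label_score(f3$tab, f3$model, selection = 11)
  expect_equal(r5$ls, 16)
})

test_that("LS is monotone in each PS and zero iff any PS is zero", {
  for (v in c(0.5, 1, 2, 4)) {
    f <- ls_fixture(c(v, 1), c(1, 1), c(1, 1), c(1, 1))
    r <- compute_label_score(f$tab, f$model, selection = c(11, 9, 10, 12),
                             allow_same_category = TRUE)
    expect_equal(r$ls, v^(1 / 4))
  }
  f0 <- ls_fixture(c(0, 1), c(2, 1), c(2, 1), c(2, 1))
  r0 <- compute_label_score(f0$tab, f0$model, selection = c(11, 9, 10, 12),
                            allow_same_category = TRUE)
  expect_equal(r0$ls, 0)
})

test_that("missing-value policies: strict flags failures, reduce shrinks n", {
  model <- manual_ps_model(list("11" = c(4, 1), "13" = c(4, 1)))
  tab <- synthetic_table(2, seed = 2)
  tab[[param_column(11)]] <- c(0.5, 0.5)
  tab[[param_column(13)]] <- c(0.5, NA)
  strict <- compute_label_score(tab, model, selection = c(11, 13),
                                policy = "strict")
  expect_equal(strict$ls, c(4, 0))
  expect_equal(strict$failed, c(FALSE, TRUE))
  red <- compute_label_score(tab, model, selection = c(11, 13),
                             policy = "reduce")
  expect_equal(red$ls, c(4, 4))
  expect_equal(red$n_used, c(2L, 1L))
})

test_that("selection rules: one per category unless overridden; clamping", {
  model <- manual_ps_model(list("11" = c(1, 2), "9" = c(1, 2)))
  tab <- synthetic_table(1, seed = 3)
  tab[[param_column(11)]] <- 0.5
  tab[[param_column(9)]] <- 0.5
  expect_error(compute_label_score(tab, model, selection = c(11, 9)),
               "more than one parameter")
  expect_error(compute_label_score(tab, model, selection = c(11, 13)),
               "untrained")
  ## out-of-range numeric clamps to the edge bin with a warning
  tab2 <- tab
  tab2[[param_column(11)]] <- 99
  expect_warning(
    r <- compute_label_score(tab2, model, selection = 11),
    "clamped")
  expect_equal(r$ls, 2)   # edge bin PS
})

test_that("ranking is by descending LS with residue-number tie-break", {
  res <- data.frame(key = c("A:1:", "A:2:", "A:3:"), chain = "A",
                    resno = 1:3, aa = "ALA",
                    ls = c(2, 0.5, 1), n_used = 4L, failed = FALSE,
                    stringsAsFactors = FALSE)
  top <- rank_residues(res, 1 / 3)
  expect_equal(top$key, "A:1:")
  bot <- rank_residues(res, 1 / 3, which = "bottom")
  expect_equal(bot$key, "A:2:")

  ties <- res; ties$ls <- 1
  expect_equal(rank_residues(ties)$resno, 1:3)

  fifty <- data.frame(key = res_key("A", 1:50), chain = "A", resno = 1:50,
                      aa = "ALA", ls = stats::runif(50), n_used = 4L,
                      failed = FALSE, stringsAsFactors = FALSE)
  expect_equal(nrow(rank_residues(fifty, 0.1, "bottom")), 5L)
})

test_that("enrichment ratios recover planted structure", {
  set.seed(20)
  ls_all <- stats::rlnorm(20000, 0, 0.4)
  er0 <- enrichment_ratio(ls_all, ls_all)
  expect_true(all(abs(er0$ratio[er0$p_all > 0] - 1) < 1e-9))

  ## labeled = strictly the top half: ratio 2 above the median, 0 below
  med <- stats::median(ls_all)
  er <- enrichment_ratio(ls_all, ls_all[ls_all > med])
  hi <- er$p_all > 0.01 & er$lo >= med
  lo <- er$p_all > 0.01 & er$hi <= med
  expect_equal(er$ratio[hi], rep(2, sum(hi)), tolerance = 0.05)
  expect_equal(er$ratio[lo], rep(0, sum(lo)))

  ## planted x3 enrichment above a threshold, bootstrap CI covers it
  thr <- 1.5
  w <- ifelse(ls_all > thr, 3, 1)
  lab <- sample(ls_all, 4000, prob = w, replace = TRUE)
  er3 <- enrichment_ratio(ls_all, lab, n_boot = 200, seed = 3)
  expected_hi <- 3 / sum(w / length(w))   # normalization of the weights
  hi3 <- er3$p_all > 0.02 & er3$lo >= thr
  expect_true(all(er3$lower[hi3] <= expected_hi * 1.05 &
                    expected_hi * 0.95 <= er3$upper[hi3]))
})
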