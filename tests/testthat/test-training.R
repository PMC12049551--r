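test_that("label databases load with validation, duplicates collapse", {
  p <- tempfile(fileext = ".csv")
  db <- data.frame(pdb_id = c("1ABC", "1ABC", "2XYZ"),
                   chain = c("A", "A", "B"), resno = c(10L, 20L, 5L),
                   mutation = c("cysteine", "UAA", "cysteine"),
                   assay = c("smFRET", "imaging", "other"),
                   fluorophore = "Cy5")
  utils::write.csv(db, p, row.names = FALSE)
  got <- load_label_database(p)
  expect_s3_class(got, "label_db")
  expect_equal(nrow(got), 3L)

  dup <- rbind(db, db[1, ])
  utils::write.csv(dup, p, row.names = FALSE)
  expect_warning(got2 <- load_label_database(p), "duplicated")
  expect_equal(nrow(got2), 3L)

  utils::write.csv(db[, -3], p, row.names = FALSE)
  expect_error(load_label_database(p), "resno")
})

test_that("parameter-score estimation: null, closed form and planted cases", {
  set.seed(10)
  ## null: labeled drawn identically to the background
  v <- stats::runif(20000)
  lab <- seq_along(v) %in% sample.int(20000, 2000)
  e <- estimate_parameter_score(v, lab, seq(0, 1, 0.1), "numeric")
  expect_equal(sum(e$p_all), 1, tolerance = 1e-9)
  expect_equal(sum(e$p_labeled), 1, tolerance = 1e-9)
  expect_true(all(abs(e$ps - 1) <= 2 * e$sigma))

  ## closed form: uniform 2-bin background, labeled all in bin 1
  v2 <- c(rep(0.25, 500), rep(0.75, 500))
  lab2 <- c(rep(TRUE, 100), rep(FALSE, 900))
  e2 <- estimate_parameter_score(v2, lab2, c(0, 0.5, 1), "numeric")
  expect_equal(e2$ps, c(2, 0))

  ## planted enrichment: labeled subset carries 30% of its mass in the
  ## first decile (background 10%), so PS(first bin) = 3 at n > 1e4
  set.seed(11)
  n <- 12000L
  v3 <- stats::runif(n)
  in1 <- which(v3 < 0.1)
  out1 <- setdiff(seq_len(n), in1)
  lab3 <- seq_len(n) %in% c(in1[1:600], out1[1:1400])
  e3 <- estimate_parameter_score(v3, lab3, seq(0, 1, 0.1), "numeric")
  expect_lt(abs(e3$ps[1] - 3), 2 * e3$sigma[1])
})

test_that("PS is scale-free: k-fold counts leave PS fixed, shrink sigma", {
  set.seed(12)
  v <- stats::runif(2000)
  lab <- seq_along(v) %in% sample.int(2000, 200)
  e1 <- estimate_parameter_score(v, lab, seq(0, 1, 0.2), "numeric")
  e4 <- estimate_parameter_score(rep(v, 4), rep(lab, 4), seq(0, 1, 0.2),
                                 "numeric")
  expect_equal(e4$ps, e1$ps)
  expect_equal(e4$sigma, e1$sigma / 2, tolerance = 1e-9)
})

test_that("information measures hit their closed forms and the Gini oracle", {
  im <- information_measures(c(1, 1, 1, 1))
  expect_equal(unname(im), c(0, 0, 1))
  expect_equal(information_measures(c(2, 0))[["H"]], 0)

  ## brute-force mean-absolute-difference Gini as independent oracle
  set.seed(13)
  for (rep in 1:5) {
    ps <- stats::runif(sample(3:12, 1), 0, 3)
    g <- information_measures(ps)[["gini"]]
    n <- length(ps)
    oracle <- sum(abs(outer(ps, ps, "-"))) / (2 * n^2 * mean(ps))
    expect_equal(g, oracle, tolerance = 1e-9)
    expect_gte(g, 0); expect_lt(g, 1)
    expect_true(information_measures(ps)[["H"]] <= 1 + 1e-9)
  }
  expect_error(information_measures(c(NA, 2)), "at least 2")
})

test_that("correlation estimators select by datatype and match oracles", {
  x <- c(1, 2, 3, 4, 5)
  pc <- parameter_correlation(x, 2 * x + 1)
  expect_equal(pc$estimator, "pearson")
  expect_equal(pc$r, 1)

  cc <- parameter_correlation(c("a", "a", "b", "b"), c("p", "p", "q", "q"))
  expect_equal(cc$estimator, "cramers_v")
  expect_equal(cc$r, 1)

  ## independent 3x4 table with exactly expected counts
  xi <- rep(c("a", "b", "c"), each = 4)
  yi <- rep(c("w", "x", "y", "z"), 3)
  expect_equal(cramers_v(xi, yi), 0)
  ## agreement with the chi-square machinery
  suppressWarnings({
    chi <- stats::chisq.test(table(c("a","a","b","b","a","b"),
                                   c("p","q","p","q","q","p")),
                             correct = FALSE)$statistic
  })
  v <- cramers_v(c("a","a","b","b","a","b"), c("p","q","p","q","q","p"))
  expect_equal(v, sqrt(unname(chi) / 6), tolerance = 1e-9)

  ## interclass correlation against a hand-computed two-class fixture:
  ## groups (1,2,3) and (7,8,9): MST 54, MSE 1, n0 3 -> r = 53/56
  ic <- parameter_correlation(c("a","a","a","b","b","b"),
                              c(1, 2, 3, 7, 8, 9))
  expect_equal(ic$estimator, "interclass")
  expect_equal(ic$r, 53 / 56, tolerance = 1e-12)

  expect_error(cramers_v(c("a", "a", "a"), c("p", "q", "p")),
               "single category")
  expect_error(parameter_correlation(1:2, 2:3), "at least 3")
})

test_that("set correlation combines pairwise values as a 2-norm", {
  expect_equal(set_correlation(rep(0, 6)), 0)
  expect_equal(set_correlation(rep(0.5, 6)), sqrt(6 * 0.25))
  m <- matrix(0.5, 4, 4); diag(m) <- 1
  expect_equal(set_correlation(m), sqrt(6 * 0.25))
  ## permutation invariance over parameter order
  p <- sample(4)
  expect_equal(set_correlation(m[p, p]), set_correlation(m))
  ## literal printed variant
  expect_equal(set_correlation(rep(0.5, 6), literal = TRUE), sqrt(3))
  expect_error(set_correlation(c(0.1, NA)), "missing")
})

test_that("selection metrics: t, dynamic range and the planted slope", {
  set.seed(14)
  ls <- stats::rlnorm(5000, 0, 0.5)
  m0 <- selection_metrics(ls, ls)
  expect_equal(m0$t, 0)
  expect_equal(m0$dynamic_range, stats::sd(log(ls)))

  eq <- selection_metrics(rep(1.3, 50), rep(1.3, 20), fit_slope = FALSE)
  expect_equal(eq$dynamic_range, 0)

  ## labeled re-weighted proportional to LS^2 -> slope m = 2
  set.seed(15)
  ls_all <- stats::rlnorm(40000, 0, 0.45)
  lab <- sample(ls_all, 8000, prob = ls_all^2, replace = TRUE)
  ms <- selection_metrics(ls_all, lab)
  expect_equal(ms$slope, 2, tolerance = 0.2)
  expect_error(selection_metrics(rep(1, 10), rep(1, 10)), "populated")
})

test_that("bootstrap envelopes are deterministic and cover the point", {
  tab <- synthetic_table(800, seed = 16)
  set.seed(17)
  lab <- tab$key %in% sample(tab$key, 150)
  b1 <- bootstrap_scores(tab, lab, params = c(11, 18, 25), n_boot = 60,
                         seed = 5)
  b2 <- bootstrap_scores(tab, lab, params = c(11, 18, 25), n_boot = 60,
                         seed = 5)
  expect_identical(b1, b2)
  pop <- b1$point > 0
  covered <- b1$lower[pop] <= b1$point[pop] + 1e-12 &
    b1$point[pop] <= b1$upper[pop] + 1e-12
  expect_gte(mean(covered), 0.95)
  b3 <- bootstrap_scores(tab, lab, params = c(11, 18, 25), n_boot = 2,
                         seed = 6)
  expect_true(all(b3$lower <= b3$upper))
})

test_that("ROC behaves at the separable, null and sign-flipped limits", {
  sep <- roc_curve(c(rep(0, 50), rep(1, 50)),
                   c(rep(FALSE, 50), rep(TRUE, 50)))
  expect_equal(sep$auc, 1)

  set.seed(18)
  sc <- stats::runif(10000)
  lab <- rep(c(TRUE, FALSE), 5000)
  null <- roc_curve(sc, lab)
  expect_lt(abs(null$auc - 0.5), 0.02)

  r1 <- roc_curve(sc, lab)
  r2 <- roc_curve(-sc, lab)
  expect_equal(r2$auc, 1 - r1$auc, tolerance = 1e-9)
  expect_error(roc_curve(sc, rep(TRUE, length(sc))), "positive and")
})
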