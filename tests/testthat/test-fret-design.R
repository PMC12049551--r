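test_that("FRET score closed forms and symmetry", {
  expect_equal(fret_score(1, 1, 0.5), 1)
  expect_equal(fret_score(1, 1, 1.0), 0)
  expect_equal(fret_score(1, 1, 0.0), 0)
  expect_equal(fret_score(2, 0.5, 0.25), 0.5)
  expect_equal(fret_score(2, 0.5, 0.25), fret_score(0.5, 2, 0.25))
  expect_error(fret_score(1, 1, 1.2), "outside")
})

test_that("the FS sensitivity factor peaks exactly at E = 0.5", {
  e_grid <- seq(0, 1, by = 0.001)
  fs <- fret_score(1, 1, e_grid)
  expect_equal(e_grid[which.max(fs)], 0.5)
  expect_equal(max(fs), 1)
})

test_that("FRET difference score closed forms", {
  expect_equal(fret_delta_score(1, 1, 1, 1, 0.2, 0.8), 0.6)
  expect_equal(fret_delta_score(1, 1, 1, 1, 0.4, 0.4), 0)
  expect_equal(fret_delta_score(4, 1, 1, 1, 0.2, 0.7), 2 * 1 * 0.5)
  ## i <-> j exchange symmetry
  expect_equal(fret_delta_score(4, 2, 1, 3, 0.1, 0.6),
               fret_delta_score(1, 3, 4, 2, 0.1, 0.6))
})

make_screen_inputs <- function(n = 10, seed = 30) {
  g <- generate_toy_structure("globule", n, seed = seed)
  ls <- data.frame(key = g$residues$key, chain = g$residues$chain,
                   resno = g$residues$resno, aa = g$residues$aa,
                   ls = 1.2, n_used = 4L, failed = FALSE,
                   stringsAsFactors = FALSE)
  list(model = g, ls = ls)
}

test_that("screening enumerates pairs and refinement preserves structure", {
  si <- make_screen_inputs(10)
  scr <- screen_pairs(si$model, si$ls, ls_min = 0, refine_top = 0L)
  expect_equal(nrow(scr$pairs), choose(10, 2))
  ## refine_top = 0: final ranking equals the screening ranking
  expect_identical(scr$pairs$score, scr$pairs$score_screen)

  scr2 <- screen_pairs(si$model, si$ls, ls_min = 0, refine_top = 5L,
                       spacing = 1.4)
  expect_equal(sum(!is.na(scr2$pairs$score_refined)), 5L)
  expect_warning(screen_pairs(si$model, si$ls, ls_min = 99), "no residue pair")
})

test_that("two-state screening: identical structures give FS_delta 0", {
  si <- make_screen_inputs(8)
  scr <- screen_pairs(list(si$model, si$model), list(si$ls, si$ls),
                      ls_min = 0, refine_top = 0L)
  expect_true(all(abs(scr$pairs$score) < 1e-12))
  ## every both-states-sensitive pair is a negative-control candidate
  expect_true(all(scr$negative_controls$score < 0.05))
})

test_that("pair matrices are symmetric with an empty diagonal", {
  si <- make_screen_inputs(8)
  scr <- screen_pairs(si$model, si$ls, ls_min = 0, refine_top = 0L)
  p <- tempfile(fileext = ".csv")
  m <- pair_matrix_export(scr, "fs", p)
  expect_true(file.exists(p))
  expect_true(all(is.na(diag(m))))
  expect_equal(m, t(m))

  scr2 <- screen_pairs(list(si$model, si$model), list(si$ls, si$ls),
                       ls_min = 0, refine_top = 0L)
  mcb <- pair_matrix_export(scr2, "cbeta_delta", tempfile(fileext = ".csv"),
                            models = list(si$model, si$model))
  expect_true(all(mcb[!is.na(mcb)] == 0))
})

test_that("single-structure screen ranks the pair nearest E = 0.5 first", {
  si <- make_screen_inputs(8, seed = 31)
  pair <- dye_pair("generic")
  scr <- screen_pairs(si$model, si$ls, pair = pair, ls_min = 0,
                      refine_top = 0L)
  ## with equal label scores the FS ordering is the sensitivity ordering
  expect_equal(order(-scr$pairs$score),
               order(abs(0.5 - scr$pairs$e_screen)))
})
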