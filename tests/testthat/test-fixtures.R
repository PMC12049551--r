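test_that("fixture generators are deterministic and emit valid structures", {
  g1 <- generate_toy_structure("globule", 50, seed = 9)
  g2 <- generate_toy_structure("globule", 50, seed = 9)
  p1 <- tempfile(); p2 <- tempfile()
  write_structure_pdb(g1, p1); write_structure_pdb(g2, p2)
  expect_identical(readLines(p1), readLines(p2))
  ## parseable by the reader
  back <- read_structure(p1, format = "pdb")
  expect_equal(nrow(back$residues), 50L)
  expect_error(generate_toy_structure("banana", 5), "unknown fixture")
})

test_that("construction targets: helix helical, shell center occluded", {
  h <- generate_toy_structure("helix", 12, seed = 1)
  ss <- assign_secondary_structure(h)
  expect_true(all(ss$ss8[4:9] == "H"))
  shell <- generate_toy_structure("shell", 1, seed = 1)
  s <- compute_sasa(shell)
  expect_equal(s$asa[shell$residues$aa == "ALA"], 0)
})

test_that("null label database gives a uniform subsample with PS near 1", {
  tab <- synthetic_table(4000, seed = 40)
  db <- generate_label_database(tab, list(), n_labeled = 800, seed = 41)
  expect_equal(nrow(db), 800L)
  fit <- ps_fit(tab, db, params = c(11, 18, 25))
  for (e in fit$entries) {
    pop <- !is.na(e$ps) & e$p_all > 0.02
    expect_true(all(abs(e$ps[pop] - 1) <= 3 * e$sigma[pop]))
  }
})

test_that("planted enrichment in the database is recovered within 2 sigma", {
  tab <- synthetic_table(12000, seed = 42)
  frac <- mean(tab[[param_column(1)]] > 0.8)     # planted stratum mass
  mult <- 3
  db <- generate_label_database(
    tab, list(list(id = 1, test = function(v) v > 0.8, mult = mult)),
    n_labeled = 2500, seed = 43)
  fit <- ps_fit(tab, db, params = 1)
  e <- fit$entries[["1"]]
  expected <- mult / (1 - frac + mult * frac)    # renormalized odds ratio
  hi <- which(e$edges[-length(e$edges)] >= 0.8)
  for (b in hi[e$p_all[hi] > 0.02])
    expect_lt(abs(e$ps[b] - expected), 2 * e$sigma[b] + 0.05)
})

test_that("database metadata mimics the curated schema", {
  tab <- synthetic_table(5000, seed = 44)
  db <- generate_label_database(tab, list(), n_labeled = 2000, seed = 45)
  expect_true(all(db$mutation %in% c("cysteine", "UAA")))
  expect_equal(mean(db$mutation == "cysteine"), 0.9, tolerance = 0.03)
  expect_true(all(db$assay %in% c("smFRET", "imaging", "bulk-FRET", "other")))
  ## round-trips through the CSV loader
  p <- tempfile(fileext = ".csv")
  write_label_database(db, p)
  back <- load_label_database(p)
  expect_equal(nrow(back), nrow(db))
})

test_that("the AV benchmark manifest enumerates the tuple grid", {
  bm <- generate_av_test_set(seed = 3)
  expect_equal(nrow(bm$tuples), 10 * 10 * 5)
  bm_full <- generate_av_test_set(10, 100,
                                  dye_param_grid = data.frame(
                                    linker_length = seq(10, 20,
                                                        length.out = 35),
                                    linker_width = 4.5,
                                    dye_radius = 3.5),
                                  seed = 3)
  expect_equal(nrow(bm_full$tuples), 35000L)
  bm2 <- generate_av_test_set(seed = 3)
  expect_identical(bm$tuples, bm2$tuples)
})

test_that("null end-to-end pipeline concentrates LS at 1", {
  tabs <- lapply(1:2, function(s) {
    g <- generate_toy_structure("globule", 60, seed = 800 + s)
    build_parameter_table(g, sasa_points = 120)
  })
  tab <- do.call(rbind, tabs)
  attr(tab, "registry") <- parameter_registry()
  class(tab) <- c("parameter_table", "data.frame")
  db <- generate_label_database(tab, list(), n_labeled = 40, seed = 9)
  fit <- ps_fit(tab, db, params = c(11, 18, 25))
  ls <- compute_label_score(tab, fit, selection = c(11, 18, 25),
                            policy = "reduce")
  expect_gte(stats::median(ls$ls), 0.8)
  expect_lte(stats::median(ls$ls), 1.25)
})
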