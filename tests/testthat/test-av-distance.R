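test_that("C-beta distances: identity, scale and symmetry", {
  g <- generate_toy_structure("globule", 20, seed = 1)
  k <- g$residues$key
  expect_equal(cbeta_distance(g, k[1], k[1]), 0)
  expect_equal(cbeta_distance(g, k[1], k[5]), cbeta_distance(g, k[5], k[1]))

  ## two residues with CB placed at (0,0,0)/(3,4,0)
  at <- g$atoms[g$atoms$key %in% k[1:2], ]
  cb <- at$name == "CB"
  at[cb & at$key == k[1], c("x", "y", "z")] <- c(0, 0, 0)
  at[cb & at$key == k[2], c("x", "y", "z")] <- c(3, 4, 0)
  m <- dyesite:::new_structure_model(at, "T")
  expect_equal(cbeta_distance(m, k[1], k[2]), 5)
})

test_that("grid AV: free-site symmetry, wall displacement, convergence", {
  dye <- fluorophore_params(linker_length = 12)
  iso <- generate_toy_structure("helix", 1, seed = 1)
  avf <- grid_accessible_volume(iso, iso$residues$key[1], dye, 1.0)
  expect_false(avf$empty)
  expect_lt(sqrt(sum((avf$mean_position - avf$attachment)^2)), 1.0)

  w <- generate_toy_structure("wall", 1, seed = 1)
  k <- w$residues$key[1]
  avw <- grid_accessible_volume(w, k, dye, 1.0)
  wall_z <- min(w$atoms$z)
  disp <- avw$mean_position - avw$attachment
  expect_gt(disp[3], 1)                      # pushed away from the wall
  ## halving the spacing moves the mean position by less than one coarse
  ## grid cell (measured 0.3-0.75 A on wall and globule fixtures: the
  ## boundary-quantization floor of the discretization)
  avw2 <- grid_accessible_volume(w, k, dye, 0.5)
  expect_lt(sqrt(sum((avw$mean_position - avw2$mean_position)^2)), 1.0)
})

test_that("grid AV is rotation-equivariant", {
  g <- generate_toy_structure("globule", 40, seed = 2)
  dye <- fluorophore_params(linker_length = 12)
  sas <- compute_sasa(g, n_points = 120)
  k <- g$residues$key[which.max(sas$rel_asa)]
  av1 <- grid_accessible_volume(g, k, dye, 1.0)
  rot <- rotation_z(37)
  g2 <- transform_model(g, rot, shift = c(3, -7, 11))
  av2 <- grid_accessible_volume(g2, k, dye, 1.0)
  expected <- as.numeric(rot %*% av1$mean_position + c(3, -7, 11))
  expect_lt(sqrt(sum((av2$mean_position - expected)^2)), 1.0)
})

test_that("SSM closed-form displacement relation", {
  rt <- 20.5
  dp <- c(rt, 0, 0)
  expect_equal(ssm_offset(dp, rt), c(rt / 4, 0, 0))
  expect_equal(ssm_offset(c(0.75 * rt, 0, 0), rt), c(0, 0, 0))
  expect_equal(ssm_offset(c(0, 0, 0), rt), c(0, 0, 0))
  ## half-space regime: anti-parallel displacement
  d <- ssm_offset(c(0.375 * rt, 0, 0), rt)
  expect_lt(d[1], 0)
})

test_that("SSM mean position tracks the grid oracle on a wall fixture", {
  w <- generate_toy_structure("wall", 1, seed = 1)
  k <- w$residues$key[1]
  dye <- fluorophore_params(linker_length = 15)
  av <- grid_accessible_volume(w, k, dye, 1.0)
  sm <- ssm_mean_position(w, k, dye)
  oav <- av$mean_position - av$attachment
  osm <- sm$offset
  expect_gt(osm[3], 0)                       # same side as the oracle
  cosang <- sum(oav * osm) / sqrt(sum(oav^2) * sum(osm^2))
  expect_gt(cosang, 0.95)
  expect_lt(abs(sqrt(sum(osm^2)) - sqrt(sum(oav^2))), 3)
})

test_that("Forster relation closed forms", {
  expect_equal(fret_efficiency(50, 50), 0.5)
  expect_equal(fret_efficiency(0, 50), 1)
  expect_equal(fret_efficiency(100, 50), 1 / 65)
})

test_that("mean-position to FRET-averaged conversion is calibrated sanely", {
  pair <- dye_pair("generic")
  expect_lt(mp_to_fret_averaged(200, pair) - 200, 0.1)
  grid <- seq(0, 120, 0.5)
  re <- mp_to_fret_averaged(grid, pair)
  expect_true(all(diff(re) > 0))             # monotone
  expect_true(all(re >= grid))               # positive correction
  expect_error(mp_to_fret_averaged(50, c(a = NA, b = NA)), "calibrat")
})

test_that("correction calibration recovers planted constants within 5%", {
  a_true <- 9; b_true <- 18
  set.seed(21)
  rmp <- stats::runif(60, 10, 80)
  delta <- a_true * exp(-rmp / b_true) + stats::rnorm(60, 0, 0.05)
  cf <- fit_correction(rmp, delta)
  expect_lt(abs(cf$a - a_true) / a_true, 0.05)
  expect_lt(abs(cf$b - b_true) / b_true, 0.05)
})

test_that("calibration against the grid oracle is deterministic and tight", {
  models <- lapply(1:2, function(s)
    generate_toy_structure("globule", 100, seed = 700 + s))
  pair <- dye_pair("generic")
  c1 <- calibrate_correction(models, pair, seed = 3, n_pairs = 22,
                             spacing = 1.4)
  c2 <- calibrate_correction(models, pair, seed = 3, n_pairs = 22,
                             spacing = 1.4)
  expect_equal(c1$a, c2$a)
  expect_equal(c1$b, c2$b)
  expect_lt(c1$rms_residual, 2)
  ## correction is positive at 40 A for ~50 A Forster-radius dyes
  expect_gt(mp_to_fret_averaged(40, pair) - 40, 0)
})

test_that("pair_distance ties the three estimators together", {
  g <- generate_toy_structure("globule", 60, seed = 8)
  sas <- compute_sasa(g, n_points = 120)
  keys <- g$residues$key[order(-sas$rel_asa)][1:2]
  pair <- dye_pair("generic")
  d_cb <- pair_distance(g, keys[1], keys[2], pair, estimator = "cbeta")
  d_ssm <- pair_distance(g, keys[1], keys[2], pair, estimator = "ssm")
  d_av <- pair_distance(g, keys[1], keys[2], pair, estimator = "grid_av")
  expect_equal(d_cb$r_mp, d_cb$r_cbeta)
  expect_true(all(c(d_ssm$efficiency, d_av$efficiency) >= 0 &
                    c(d_ssm$efficiency, d_av$efficiency) <= 1))
  expect_equal(d_av$efficiency,
               fret_efficiency(d_av$r_e, pair$r0))
})
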