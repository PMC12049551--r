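test_that("hand-written PDB parses to the expected residues", {
  p <- write_mini_pdb(tempfile(fileext = ".pdb"))
  m <- read_structure(p)
  expect_s3_class(m, "structure_model")
  expect_equal(nrow(m$residues), 4L)
  expect_equal(unique(m$residues$chain), "A")
  expect_equal(m$residues$aa, c("ALA", "GLY", "SER", "LEU"))
  expect_false(m$residues$has_cbeta[2])   # glycine
  expect_true(all(m$residues$has_cbeta[-2]))
})

test_that("mmCIF parse matches the PDB parse of the same content", {
  p <- write_mini_pdb(tempfile(fileext = ".pdb"))
  cf <- write_mini_cif(tempfile(fileext = ".cif"))
  mp <- read_structure(p)
  mc <- read_structure(cf)
  expect_equal(mc$residues$aa, mp$residues$aa)
  expect_equal(mc$residues$key, mp$residues$key)
  expect_lt(max(abs(as.matrix(mc$atoms[, c("x", "y", "z")]) -
                      as.matrix(mp$atoms[, c("x", "y", "z")]))), 1e-3)
})

test_that("alternate locations resolve to the highest-occupancy conformer", {
  p <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.458   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA BALA A   1       1.500   0.100   0.000  0.40  0.00           C",
    "ATOM      4  C   ALA A   1       2.009   0.774   1.192  1.00  0.00           C",
    "ATOM      5  O   ALA A   1       1.383   1.726   1.649  1.00  0.00           O",
    "END"), p)
  m <- read_structure(p)
  ca <- m$atoms[m$atoms$name == "CA", ]
  expect_equal(nrow(ca), 1L)
  expect_equal(ca$x, 1.458)   # conformer A kept
})

test_that("unreadable and empty inputs produce informative errors", {
  expect_error(read_structure(tempfile()), "not found")
  p <- tempfile(fileext = ".pdb")
  writeLines("HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
             p)
  expect_error(read_structure(p), "empty structure|no protein")
})

test_that("preprocess filters chains, removes waters and records gaps", {
  h <- generate_toy_structure("helix", 6, seed = 1)
  h2 <- generate_toy_structure("helix", 6, seed = 1)
  h2$atoms$chain <- "B"
  h2$atoms$serial <- h2$atoms$serial + 100L
  dimer <- dyesite:::new_structure_model(rbind(h$atoms, h2$atoms),
                                         pdb_id = "DIM")
  one <- preprocess_structure(dimer, keep_chains = "A")
  expect_equal(unique(one$atoms$chain), "A")
  expect_error(preprocess_structure(dimer, keep_chains = "Z"), "unknown chain")

  wat <- h$atoms[1, ]
  wat$resid <- "HOH"; wat$name <- "O"; wat$element <- "O"
  wat$hetero <- TRUE; wat$resno <- 99L; wat$serial <- 999L
  withwat <- dyesite:::new_structure_model(rbind(h$atoms, wat), pdb_id = "W")
  clean <- preprocess_structure(withwat)
  expect_false(any(clean$atoms$resid == "HOH"))

  gap <- h$atoms[h$atoms$resno != 3L, ]
  gm <- preprocess_structure(dyesite:::new_structure_model(gap, pdb_id = "G"))
  expect_true(any(grepl("A:3", gm$provenance$missing_residues)))
})

test_that("preprocess never alters coordinates of retained atoms", {
  h <- generate_toy_structure("helix", 8, seed = 2)
  out <- preprocess_structure(h)
  expect_identical(out$atoms[, c("x", "y", "z")],
                   h$atoms[, c("x", "y", "z")])
})

test_that("score PDB writing encodes scores in the B-factor and round-trips", {
  h <- generate_toy_structure("helix", 4, seed = 1)
  keys <- h$residues$key
  sc <- stats::setNames(c(1.0, 1.0, 1.0, 1.0), keys)
  p <- tempfile(fileext = ".pdb")
  write_score_pdb(h, sc, p)
  lines <- readLines(p)
  b_fields <- substr(lines[grepl("^ATOM", lines)], 61, 66)
  expect_true(all(b_fields == "  1.00"))

  sc2 <- stats::setNames(c(1.23, 0.5, 2.0, 0.77), keys)
  write_score_pdb(h, sc2, p)
  back <- read_structure(p)
  got <- vapply(keys, function(k)
    unique(back$atoms$b[back$atoms$key == k]), numeric(1))
  expect_equal(unname(got), unname(sc2), tolerance = 0.011)

  expect_warning(write_score_pdb(h, sc2[-1], p), "no score")
  back2 <- suppressWarnings({write_score_pdb(h, sc2[-1], p); read_structure(p)})
  expect_equal(unique(back2$atoms$b[back2$atoms$key == keys[1]]), 0)
  expect_error(write_score_pdb(h, stats::setNames(rep(1e4, 4), keys), p),
               "999.99")
})

test_that("parse-write-parse is idempotent on coordinates", {
  g <- generate_toy_structure("globule", 30, seed = 5)
  p1 <- tempfile(fileext = ".pdb"); p2 <- tempfile(fileext = ".pdb")
  write_structure_pdb(g, p1)
  m1 <- read_structure(p1)
  write_structure_pdb(m1, p2)
  m2 <- read_structure(p2)
  expect_lt(max(abs(as.matrix(m1$atoms[, c("x", "y", "z")]) -
                      as.matrix(m2$atoms[, c("x", "y", "z")]))), 1e-3)
})

test_that("virtual C-beta is placed for glycine from backbone geometry", {
  p <- write_mini_pdb(tempfile(fileext = ".pdb"))
  m <- read_structure(p)
  gly <- m$residues$key[m$residues$aa == "GLY"]
  cb <- cbeta_position(m, gly)
  ca <- atom_xyz(m, gly, "CA")
  expect_equal(sqrt(sum((cb - ca)^2)), 1.53, tolerance = 0.05)
})
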