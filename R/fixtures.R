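## Synthetic structure and database generators.
##
## Everything the test-suite and the benchmarks need is generated in code:
## ideal-geometry peptide chains (helix / sheet / coil), jittered-lattice
## globules, and blocking-atom wall / shell arrangements for
## accessible-volume tests.  All generators are deterministic under `seed`.

## ideal backbone geometry (Angstrom / degrees, Engh-Huber style)
.BB <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
            ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
            ang_ca_c_o = 120.8)

## place atom D given A,B,C at bond length r (C-D), angle theta (B-C-D),
## dihedral phi (A-B-C-D); natural-extension reference frame construction
place_atom <- function(a, b, c, r, theta, phi) {
  theta <- theta * pi / 180
  phi <- phi * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-r * cos(theta), r * sin(theta) * cos(phi), -r * sin(theta) * sin(phi))
  c + d[1] * bc + d[2] * m + d[3] * n
}

## Build an ideal peptide chain from per-residue (phi, psi); returns the
## atom data.frame of a structure_model.  Glycines get no CB atom.
build_chain_atoms <- function(phi, psi, aa, chain = "A", resno_start = 1L) {
  n_res <- length(phi)
  stopifnot(length(psi) == n_res, length(aa) == n_res)
  coords <- list()
  ## seed first residue
  n1 <- c(0, 0, 0)
  ca1 <- c(.BB$n_ca, 0, 0)
  c1 <- place_atom(c(-1, 1, 0), n1, ca1, .BB$ca_c, .BB$ang_n_ca_c, phi[1])
  prev <- list(n = n1, ca = ca1, c = c1)
  for (i in seq_len(n_res)) {
    res <- list(N = prev$n, CA = prev$ca, C = prev$c)
    res$O <- place_atom(res$N, res$CA, res$C, .BB$c_o, .BB$ang_ca_c_o,
                        psi[i] + 180)
    if (aa[i] != "GLY") res$CB <- virtual_cbeta(res$N, res$CA, res$C)
    coords[[i]] <- res
    if (i < n_res) {
      nn <- place_atom(res$N, res$CA, res$C, .BB$c_n, .BB$ang_ca_c_n, psi[i])
      nca <- place_atom(res$CA, res$C, nn, .BB$n_ca, .BB$ang_c_n_ca, 180)
      nc <- place_atom(res$C, nn, nca, .BB$ca_c, .BB$ang_n_ca_c, phi[i + 1])
      prev <- list(n = nn, ca = nca, c = nc)
    }
  }
  rows <- list()
  serial <- 0L
  for (i in seq_len(n_res)) {
    for (nm in names(coords[[i]])) {
      serial <- serial + 1L
      xyz <- coords[[i]][[nm]]
      rows[[serial]] <- data.frame(
        serial = serial, name = nm,
        element = if (nm == "O") "O" else if (nm == "N") "N" else "C",
        chain = chain, resno = resno_start + i - 1L, icode = "",
        resid = aa[i], x = xyz[1], y = xyz[2], z = xyz[3],
        occupancy = 1, b = 0, hetero = FALSE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

## one rigid residue template (backbone + CB + side-chain pseudo-atoms),
## local frame.  Side-chain atom counts track real residue sizes so that
## globule fixtures reach protein-like heavy-atom packing density.
.N_SIDE <- c(GLY = 0L, ALA = 0L, SER = 1L, CYS = 1L, THR = 2L, VAL = 2L,
             PRO = 2L, LEU = 3L, ILE = 3L, ASN = 3L, ASP = 3L, MET = 3L,
             GLN = 4L, GLU = 4L, LYS = 4L, HIS = 5L, ARG = 6L, PHE = 6L,
             TYR = 7L, TRP = 9L)
.residue_template <- function(aa = "ALA") {
  n <- c(-1.458, 0, 0)
  ca <- c(0, 0, 0)
  cc <- place_atom(c(-2, 1, 0), n, ca, .BB$ca_c, .BB$ang_n_ca_c, -60)
  o <- place_atom(n, ca, cc, .BB$c_o, .BB$ang_ca_c_o, 120)
  out <- rbind(N = n, CA = ca, C = cc, O = o)
  if (aa != "GLY") {
    cb <- virtual_cbeta(n, ca, cc)
    out <- rbind(out, CB = cb)
    nside <- .N_SIDE[[aa]]
    if (is.null(nside)) nside <- 2L
    if (nside > 0L) {
      dir <- cb - ca
      dir <- dir / sqrt(sum(dir^2))
      perp <- c(dir[2], -dir[1], 0)
      if (sum(perp^2) < 1e-6) perp <- c(1, 0, 0)
      perp <- perp / sqrt(sum(perp^2))
      names_sc <- c("CG", "CD", "CE", "CZ", "CH", "CI", "CK", "CL", "CM")
      for (s in seq_len(nside)) {
        pos <- cb + s * 1.25 * dir + 0.65 * perp * (-1)^s
        out <- rbind(out, pos)
        rownames(out)[nrow(out)] <- names_sc[s]
      }
    }
  }
  out
}

random_rotation <- function() {
  ## uniform random rotation from a normalized quaternion
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

block_atoms_df <- function(xyz, chain, resno, serial0) {
  data.frame(serial = serial0 + seq_len(nrow(xyz)), name = "C",
             element = "C", chain = chain, resno = resno, icode = "",
             resid = "UNK", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             occupancy = 1, b = 0, hetero = FALSE, stringsAsFactors = FALSE)
}

#' Generate a deterministic toy protein structure
#'
#' Kinds: `helix` (phi = -57, psi = -47), `sheet` (two H-bonded antiparallel
#' strands), `coil` (extended, jittered, no H-bonds), `globule` (residues on
#' a jittered lattice inside a sphere, packing density giving both buried
#' and exposed residues), `wall` (one alanine next to a plane of blocking
#' atoms) and `shell` (one alanine enclosed by a dense atom shell).
#'
#' @param kind one of "helix", "sheet", "coil", "globule", "wall", "shell".
#' @param n_residues number of amino-acid residues.
#' @param seed integer RNG seed; same arguments + seed give identical output.
#' @param aa optional vector of 3-letter residue codes (recycled).
#' @return a `structure_model`.
#' @export
generate_toy_structure <- function(kind, n_residues = 12L, seed = 1L,
                                   aa = NULL) {
  set.seed(seed)
  n <- as.integer(n_residues)
  stopifnot(n >= 1L)
  if (is.null(aa)) {
    aa <- rep(c("ALA", "LEU", "SER", "LYS", "GLU", "VAL", "THR", "GLY",
                "ASP", "PHE"), length.out = n)
  } else aa <- rep(aa, length.out = n)
  atoms <- switch(
    kind,
    helix = build_chain_atoms(rep(-57, n), rep(-47, n), aa),
    coil = build_chain_atoms(-75 + stats::rnorm(n, 0, 8),
                             145 + stats::rnorm(n, 0, 8), aa),
    sheet = {
      m <- max(2L, n %/% 2L)
      s1 <- build_chain_atoms(rep(-139, m), rep(135, m), aa[1:m],
                              resno_start = 1L)
      s2 <- build_chain_atoms(rep(-139, m), rep(135, m),
                              aa[(m + 1):(2 * m)], resno_start = m + 1L)
      ## place strand 2 antiparallel beside strand 1 (proper 2-fold rotation
      ## about y, then offsets tuned once for N-H...O=C registry)
      xyz <- as.matrix(s2[, c("x", "y", "z")])
      xyz[, 1] <- -xyz[, 1]
      xyz[, 3] <- -xyz[, 3]
      xyz[, 1] <- xyz[, 1] + max(s1$x) + min(s1$x) - 1.5
      xyz[, 2] <- xyz[, 2] - 3
      xyz[, 3] <- xyz[, 3] + 7
      s2[, c("x", "y", "z")] <- xyz
      s2$serial <- s2$serial + max(s1$serial)
      rbind(s1, s2)
    },
    globule = {
      ## packing tuned so ~30% of residues end up buried (rel ASA < 0.1)
      spacing <- 4.9
      tmpl_cache <- list()
      rad <- (3 * n * spacing^3 / (4 * pi))^(1 / 3)
      g <- expand.grid(x = seq(-rad, rad, spacing),
                       y = seq(-rad, rad, spacing),
                       z = seq(-rad, rad, spacing))
      d2 <- g$x^2 + g$y^2 + g$z^2
      g <- g[order(d2), , drop = FALSE][seq_len(min(n, nrow(g))), ]
      if (nrow(g) < n) stop("lattice too small for n_residues")
      rows <- list()
      serial <- 0L
      for (i in seq_len(n)) {
        tmpl <- tmpl_cache[[aa[i]]]
        if (is.null(tmpl)) tmpl <- tmpl_cache[[aa[i]]] <- .residue_template(aa[i])
        rot <- random_rotation()
        cen <- as.numeric(g[i, ]) + stats::runif(3, -0.8, 0.8)
        xyz <- tmpl %*% t(rot)
        xyz <- sweep(xyz, 2, cen, "+")
        for (j in seq_len(nrow(tmpl))) {
          serial <- serial + 1L
          nm <- rownames(tmpl)[j]
          rows[[serial]] <- data.frame(
            serial = serial, name = nm,
            element = if (nm == "O") "O" else if (nm == "N") "N" else "C",
            chain = "A", resno = i, icode = "", resid = aa[i],
            x = xyz[j, 1], y = xyz[j, 2], z = xyz[j, 3],
            occupancy = 1, b = 0, hetero = FALSE, stringsAsFactors = FALSE)
        }
      }
      do.call(rbind, rows)
    },
    wall = {
      res <- build_chain_atoms(-57, -47, "ALA")
      ## dense plane of blocking atoms 3 A below the residue, 50x50 A
      g <- expand.grid(x = seq(-25, 25, 1.5), y = seq(-25, 25, 1.5))
      xyz <- cbind(g$x, g$y, rep(min(res$z) - 3, nrow(g)))
      rbind(res, block_atoms_df(xyz, "A", 2L, max(res$serial)))
    },
    shell = {
      res <- build_chain_atoms(-57, -47, "ALA")
      cen <- colMeans(res[, c("x", "y", "z")])
      pts <- golden_spiral_points(600)
      xyz <- sweep(pts * 5.0, 2, as.numeric(cen), "+")
      rbind(res, block_atoms_df(xyz, "A", 2L, max(res$serial)))
    },
    stop("unknown fixture kind: ", kind))
  prov <- list(source = sprintf("synthetic:%s(n=%d,seed=%d)", kind, n, seed),
               format = "synthetic", log = character())
  new_structure_model(atoms, pdb_id = sprintf("%s%03d", toupper(substr(kind, 1, 3)), seed),
                      provenance = prov)
}

#' Generate a synthetic label database with planted enrichments
#'
#' Emulates a curated database of successfully labeled residues: residues
#' of `background_table` are sampled with probability proportional to the
#' product of planted per-parameter weights, and each record carries
#' plausible metadata (cysteine mutations ~90%, UAA ~10%).
#'
#' @param background_table a parameter table (see [build_parameter_table()]).
#' @param enrichments list of plants, each `list(id =, test =, mult =)`: a
#'   registry parameter id, a predicate on its values, and a sampling weight
#'   multiplier (>= 0) applied where the predicate holds.  Empty list gives
#'   a uniform (null) subsample.
#' @param n_labeled number of labeled records to draw.
#' @param seed integer RNG seed.
#' @return a data.frame with the label-database schema (class `label_db`).
#' @export
generate_label_database <- function(background_table, enrichments = list(),
                                    n_labeled, seed = 1L) {
  set.seed(seed)
  tab <- background_table
  n <- nrow(tab)
  stopifnot(n_labeled <= n)
  w <- rep(1, n)
  for (e in enrichments) {
    col <- param_column(e$id)
    if (!col %in% names(tab)) stop("parameter not in table: ", e$id)
    hit <- e$test(tab[[col]])
    hit[is.na(hit)] <- FALSE
    w[hit] <- w[hit] * e$mult
  }
  if (all(w == 0)) stop("all sampling weights are zero")
  idx <- sample.int(n, n_labeled, replace = FALSE, prob = w)
  db <- data.frame(
    pdb_id = tab$pdb_id[idx],
    soluble = TRUE,
    stoichiometry = "monomer",
    homology_model = FALSE,
    chain = tab$chain[idx],
    resno = tab$resno[idx],
    mutation = sample(c("cysteine", "UAA"), n_labeled, replace = TRUE,
                      prob = c(0.9, 0.1)),
    assay = sample(c("smFRET", "imaging", "bulk-FRET", "other"), n_labeled,
                   replace = TRUE, prob = c(0.6, 0.2, 0.1, 0.1)),
    fluorophore = sample(c("Alexa555", "Alexa647", "Cy3", "Cy5", "ATTO647N"),
                         n_labeled, replace = TRUE),
    reference = sprintf("synthetic-%04d", seq_len(n_labeled)),
    stringsAsFactors = FALSE)
  class(db) <- c("label_db", "data.frame")
  db
}

#' Generate a manifest for the accessible-volume benchmark
#'
#' Produces (structure, residue pair, dye parameters) tuples for the
#' SSM-vs-grid-AV comparison.  Defaults are the desk-scale benchmark of
#' 10 structures x 10 pairs x 5 dye variants (500 tuples).
#'
#' @param n_structures number of globule structures.
#' @param n_pairs residue pairs per structure.
#' @param dye_param_grid data.frame of dye variants with columns
#'   `linker_length`, `linker_width`, `dye_radius` (defaults: 5 variants
#'   spanning 10-20 A linkers).
#' @param seed integer RNG seed.
#' @param n_residues residues per globule structure.
#' @return list with `structures` (specs) and `tuples` (data.frame).
#' @export
generate_av_test_set <- function(n_structures = 10L, n_pairs = 10L,
                                 dye_param_grid = NULL, seed = 1L,
                                 n_residues = 120L) {
  if (is.null(dye_param_grid)) {
    dye_param_grid <- data.frame(
      linker_length = c(10, 12.5, 15, 17.5, 20),
      linker_width = c(4.5, 4.5, 4.5, 4.5, 4.5),
      dye_radius = c(3.5, 4.0, 4.5, 5.0, 5.5))
  }
  set.seed(seed)
  tuples <- list()
  structures <- list()
  k <- 0L
  for (s in seq_len(n_structures)) {
    sseed <- seed * 1000L + s
    structures[[s]] <- list(kind = "globule", n_residues = n_residues,
                            seed = sseed)
    pairs <- t(replicate(n_pairs, sample.int(n_residues, 2L)))
    for (p in seq_len(n_pairs)) {
      for (d in seq_len(nrow(dye_param_grid))) {
        k <- k + 1L
        tuples[[k]] <- data.frame(structure = s, res_i = pairs[p, 1],
                                  res_j = pairs[p, 2], variant = d)
      }
    }
  }
  tuples <- do.call(rbind, tuples)
  tuples <- cbind(tuples, dye_param_grid[tuples$variant, , drop = FALSE])
  rownames(tuples) <- NULL
  list(structures = structures, dye_param_grid = dye_param_grid,
       tuples = tuples, seed = seed)
}
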