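# Shared fixture builders: everything is generated in code at test time.

# hand-written 4-residue PDB text (not via the package writer)
write_mini_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   0.774   1.192  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.383   1.726   1.649  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1       1.989  -1.425   0.107  1.00  0.00           C",
    "ATOM      6  N   GLY A   2       3.227   0.446   1.603  1.00  0.00           N",
    "ATOM      7  CA  GLY A   2       3.872   1.124   2.716  1.00  0.00           C",
    "ATOM      8  C   GLY A   2       3.092   0.939   4.012  1.00  0.00           C",
    "ATOM      9  O   GLY A   2       2.460  -0.096   4.218  1.00  0.00           O",
    "ATOM     10  N   SER A   3       3.134   1.938   4.884  1.00  0.00           N",
    "ATOM     11  CA  SER A   3       2.430   1.887   6.158  1.00  0.00           C",
    "ATOM     12  C   SER A   3       3.078   0.880   7.098  1.00  0.00           C",
    "ATOM     13  O   SER A   3       4.301   0.787   7.167  1.00  0.00           O",
    "ATOM     14  CB  SER A   3       2.410   3.272   6.800  1.00  0.00           C",
    "ATOM     15  N   LEU A   4       2.256   0.122   7.817  1.00  0.00           N",
    "ATOM     16  CA  LEU A   4       2.742  -0.888   8.749  1.00  0.00           C",
    "ATOM     17  C   LEU A   4       3.498  -0.246   9.905  1.00  0.00           C",
    "ATOM     18  O   LEU A   4       3.113   0.819  10.389  1.00  0.00           O",
    "ATOM     19  CB  LEU A   4       1.571  -1.738   9.240  1.00  0.00           C",
    "END"), path)
  path
}

# same residues as minimal mmCIF
write_mini_cif <- function(path) {
  pdb_tmp <- tempfile(fileext = ".pdb")
  write_mini_pdb(pdb_tmp)
  m <- read_structure(pdb_tmp)
  at <- m$atoms
  writeLines(c(
    "data_mini",
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    sprintf("ATOM %d %s %s . %s A 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s A %s 1",
            at$serial, at$element, at$name, at$resid, at$resno,
            at$x, at$y, at$z, at$resno, at$resid, at$name)), path)
  path
}

write_consurf_fixture <- function(path) {
  writeLines(c(
    " POS  SEQ  SCORE  COLOR",
    "   1    M  -1.234  9",
    "   2    A  -0.500  7",
    "   3    S   0.120  5",
    "   4    K   0.870  2",
    "   5    E   1.400  1"), path)
  path
}

write_msa_fixture <- function(path, n_seq = 8L, n_col = 12L, seed = 42L) {
  set.seed(seed)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ref <- sample(aas, n_col, replace = TRUE)
  rows <- list(ref)
  for (s in 2:n_seq) {
    r <- ref
    mutate <- seq(2, n_col, by = 2)           # odd columns stay invariant
    r[mutate] <- sample(aas, length(mutate), replace = TRUE)
    rows[[s]] <- r
  }
  lines <- unlist(lapply(seq_len(n_seq), function(s)
    c(sprintf(">seq%d", s), paste(rows[[s]], collapse = ""))))
  writeLines(lines, path)
  path
}

# rigid-body transform of a structure model
transform_model <- function(model, rot = diag(3), shift = c(0, 0, 0)) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(rot)
  xyz <- sweep(xyz, 2, shift, "+")
  model$atoms[, c("x", "y", "z")] <- xyz
  model
}

rotation_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

# synthetic parameter table with uniform numeric values (no structures)
synthetic_table <- function(n, seed = 1L) {
  set.seed(seed)
  tab <- data.frame(pdb_id = "SYN", key = res_key("A", seq_len(n)),
                    chain = "A", resno = seq_len(n), icode = "",
                    aa = sample(names(dyesite:::WILKE_MAX_ASA), n, TRUE),
                    stringsAsFactors = FALSE)
  tab[[param_column(1)]] <- stats::runif(n, 0, 1)
  tab[[param_column(11)]] <- stats::runif(n, 0, 12)
  tab[[param_column(13)]] <- stats::rnorm(n)
  tab[[param_column(18)]] <- sample(c("H", "E", "T", "-"), n, TRUE)
  tab[[param_column(25)]] <- tab$aa
  attr(tab, "registry") <- parameter_registry()
  class(tab) <- c("parameter_table", "data.frame")
  tab
}

# a ps_model with hand-chosen PS values for label-score identity tests
manual_ps_model <- function(ps_by_param) {
  entries <- list()
  reg <- parameter_registry()
  for (id in names(ps_by_param)) {
    row <- reg[reg$id == as.integer(id), ]
    ps <- ps_by_param[[id]]
    if (row$datatype == "numeric") {
      edges <- seq(0, length(ps), 1)
      e <- list(datatype = "numeric", edges = edges,
                labels = sprintf("[%d,%d)", edges[-length(edges)], edges[-1]),
                ps = ps, sigma = rep(0.1, length(ps)),
                p_all = rep(1 / length(ps), length(ps)),
                p_labeled = rep(1 / length(ps), length(ps)),
                counts_all = rep(10L, length(ps)),
                counts_labeled = rep(10L, length(ps)),
                n_all = 10L * length(ps), n_labeled = 10L * length(ps))
    } else {
      lev <- names(ps)
      e <- list(datatype = "categorical", edges = NULL, labels = lev,
                ps = unname(ps), sigma = rep(0.1, length(ps)),
                p_all = rep(1 / length(ps), length(ps)),
                p_labeled = rep(1 / length(ps), length(ps)),
                counts_all = rep(10L, length(ps)),
                counts_labeled = rep(10L, length(ps)),
                n_all = 10L * length(ps), n_labeled = 10L * length(ps))
    }
    e$id <- as.integer(id)
    e$name <- row$name
    e$category <- row$category
    entries[[id]] <- e
  }
  structure(list(entries = entries, params = as.integer(names(entries)),
                 n_residues = 100L, n_labeled = 10L,
                 registry = reg, call = NULL), class = "ps_model")
}
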