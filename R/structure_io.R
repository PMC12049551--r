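## Structure reading, pre-processing and score-annotated PDB output.
##
## Internal representation: a `structure_model` S3 object holding a flat atom
## table (one row per atom) plus a derived residue table.  Author residue
## numbering with insertion codes is the public key everywhere; residues are
## addressed as "chain:resno:icode" strings and never renumbered.

#' Build a residue key string
#'
#' @param chain chain identifier(s).
#' @param resno author residue number(s).
#' @param icode insertion code(s), "" when absent.
#' @return character vector "chain:resno:icode".
#' @export
res_key <- function(chain, resno, icode = "") {
  icode[is.na(icode)] <- ""
  sprintf("%s:%d:%s", as.character(chain), as.integer(resno),
          as.character(icode))
}

new_structure_model <- function(atoms, pdb_id = "", provenance = list()) {
  stopifnot(is.data.frame(atoms))
  atoms$key <- res_key(atoms$chain, atoms$resno, atoms$icode)
  ord <- order(match(atoms$key, unique(atoms$key)))  # keep file order
  atoms <- atoms[ord, , drop = FALSE]
  rownames(atoms) <- NULL
  model <- list(pdb_id = pdb_id, atoms = atoms, provenance = provenance)
  class(model) <- "structure_model"
  model$residues <- build_residue_table(model)
  model
}

build_residue_table <- function(model) {
  at <- model$atoms[!model$atoms$hetero | model$atoms$resid %in%
                      names(NONSTANDARD_AA_MAP), , drop = FALSE]
  if (nrow(at) == 0L) {
    return(data.frame(key = character(), chain = character(),
                      resno = integer(), icode = character(),
                      aa = character(), standard = logical(),
                      has_cbeta = logical(), stringsAsFactors = FALSE))
  }
  first <- !duplicated(at$key)
  res <- data.frame(key = at$key[first], chain = at$chain[first],
                    resno = at$resno[first], icode = at$icode[first],
                    aa = at$resid[first], stringsAsFactors = FALSE)
  mapped <- NONSTANDARD_AA_MAP[res$aa]
  res$aa_parent <- ifelse(res$aa %in% STANDARD_AA, res$aa,
                          ifelse(!is.na(mapped), unname(mapped), NA_character_))
  res$standard <- !is.na(res$aa_parent)
  res$has_cbeta <- res$key %in% at$key[at$name == "CB"]
  rownames(res) <- NULL
  res
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %s: %d atoms, %d residues, chains %s\n",
              if (nzchar(x$pdb_id)) x$pdb_id else "(unnamed)",
              nrow(x$atoms), nrow(x$residues),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Chains present in a structure
#' @param model a `structure_model`.
#' @return character vector of chain ids.
#' @export
model_chains <- function(model) unique(model$atoms$chain)

#' Read a protein structure from PDB or mmCIF
#'
#' Parses the first model of the file, keeps all ATOM records, flags HETATM
#' records and resolves alternate locations to the highest-occupancy
#' conformer.  Author numbering and insertion codes are preserved.
#'
#' @param path path to the structure file.
#' @param format "auto" (by extension), "pdb" or "cif".
#' @param pdb_id optional identifier stored on the model; defaults to the
#'   file base name.
#' @return a `structure_model`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           pdb_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
    else suppressWarnings(bio3d::read.cif(path, verbose = FALSE)),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  if (nrow(a) == 0L) stop("empty structure: no atoms in ", path)
  icode <- a$insert
  icode[is.na(icode)] <- ""
  element <- a$elesy
  if (is.null(element) || all(is.na(element)) || all(element == ""))
    element <- guess_element(a$elety)
  element[is.na(element) | element == ""] <-
    guess_element(a$elety[is.na(element) | element == ""])
  occ <- a$o
  occ[is.na(occ)] <- 1
  atoms <- data.frame(serial = a$eleno, name = trimws(a$elety),
                      element = toupper(element), chain = a$chain,
                      resno = a$resno, icode = icode, resid = a$resid,
                      x = a$x, y = a$y, z = a$z, occupancy = occ,
                      b = ifelse(is.na(a$b), 0, a$b),
                      hetero = a$type == "HETATM",
                      stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- "A"
  ## resolve altlocs: keep highest-occupancy conformer per atom slot
  alt <- a$alt
  alt[is.na(alt)] <- ""
  if (any(alt != "")) {
    slot <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$name)
    ord <- order(slot, -atoms$occupancy, alt)
    keep <- !duplicated(slot[ord])
    atoms <- atoms[ord, ][keep, ]
    atoms <- atoms[order(atoms$serial), ]
  }
  if (!any(!atoms$hetero)) stop("empty structure: no protein residues in ", path)
  prov <- list(source = path, format = format,
               read_time = as.character(Sys.time()),
               log = character())
  new_structure_model(atoms, pdb_id = if (is.null(pdb_id))
    sub("\\.[^.]*$", "", basename(path)) else pdb_id, provenance = prov)
}

#' Pre-process a structure for scoring
#'
#' Retains only the requested chains, always removes waters, optionally
#' drops all remaining HETATM records, and records numbering gaps in the
#' provenance log without interpolating missing residues.  Coordinates of
#' retained atoms are never altered.
#'
#' @param model a `structure_model`.
#' @param keep_chains optional character vector of chain ids to retain.
#' @param drop_hetero drop HETATM records (ligands etc.); waters go always.
#' @return the filtered `structure_model`.
#' @export
preprocess_structure <- function(model, keep_chains = NULL,
                                 drop_hetero = TRUE) {
  at <- model$atoms
  log <- model$provenance$log
  if (!is.null(keep_chains)) {
    unknown <- setdiff(keep_chains, unique(at$chain))
    if (length(unknown))
      stop("keep_chains selects unknown chain(s): ",
           paste(unknown, collapse = ","))
    at <- at[at$chain %in% keep_chains, , drop = FALSE]
    log <- c(log, paste0("kept chains: ", paste(keep_chains, collapse = ",")))
  }
  nwat <- sum(at$resid %in% c("HOH", "WAT", "DOD", "H2O"))
  at <- at[!at$resid %in% c("HOH", "WAT", "DOD", "H2O"), , drop = FALSE]
  if (nwat) log <- c(log, sprintf("removed %d water atoms", nwat))
  if (drop_hetero) {
    drop <- at$hetero & !at$resid %in% names(NONSTANDARD_AA_MAP)
    if (any(drop)) log <- c(log, sprintf("removed %d hetero atoms", sum(drop)))
    at <- at[!drop, , drop = FALSE]
  }
  if (nrow(at) == 0L) stop("pre-processing removed every atom")
  ## record numbering gaps per chain (missing residues, never interpolated)
  missing <- character()
  for (ch in unique(at$chain)) {
    rn <- sort(unique(at$resno[at$chain == ch & !at$hetero]))
    if (length(rn) > 1L) {
      gaps <- setdiff(seq(min(rn), max(rn)), rn)
      if (length(gaps))
        missing <- c(missing, sprintf("%s:%d", ch, gaps))
    }
  }
  if (length(missing))
    log <- c(log, paste0("missing residues: ", paste(missing, collapse = " ")))
  prov <- model$provenance
  prov$log <- log
  prov$missing_residues <- missing
  new_structure_model(at, pdb_id = model$pdb_id, provenance = prov)
}

#' Coordinates of all atoms of one residue
#' @param model a `structure_model`.
#' @param key residue key (see [res_key()]).
#' @return numeric matrix (n x 3).
#' @export
residue_coords <- function(model, key) {
  at <- model$atoms[model$atoms$key == key, , drop = FALSE]
  as.matrix(at[, c("x", "y", "z")])
}

#' Coordinate of a named atom of one residue (or NULL)
#' @inheritParams residue_coords
#' @param name atom name, e.g. "CA".
#' @export
atom_xyz <- function(model, key, name) {
  i <- which(model$atoms$key == key & model$atoms$name == name)
  if (!length(i)) return(NULL)
  as.numeric(model$atoms[i[1L], c("x", "y", "z")])
}

#' Actual or ideal-geometry virtual C-beta position
#'
#' For glycine (or any residue lacking a C-beta) a virtual C-beta is
#' constructed from the backbone N/CA/C atoms with ideal tetrahedral
#' geometry, so that attachment-direction math is defined for every residue.
#'
#' @inheritParams residue_coords
#' @return numeric length-3 vector, or NULL if the backbone is incomplete.
#' @export
cbeta_position <- function(model, key) {
  cb <- atom_xyz(model, key, "CB")
  if (!is.null(cb)) return(cb)
  n <- atom_xyz(model, key, "N")
  ca <- atom_xyz(model, key, "CA")
  cc <- atom_xyz(model, key, "C")
  if (is.null(n) || is.null(ca) || is.null(cc)) return(NULL)
  virtual_cbeta(n, ca, cc)
}

## ideal C-beta from backbone (standard reconstruction constants)
virtual_cbeta <- function(n, ca, c) {
  b <- ca - n
  cc <- c - ca
  a <- c(b[2] * cc[3] - b[3] * cc[2],
         b[3] * cc[1] - b[1] * cc[3],
         b[1] * cc[2] - b[2] * cc[1])
  -0.58273431 * a + 0.56802827 * b - 0.54067466 * cc + ca
}

#' Write a structure with per-residue scores in the B-factor column
#'
#' Each atom's B-factor is set to its residue's score (2 decimals).
#' Residues missing from the score map are written as 0.00 with a warning.
#'
#' @param model a `structure_model`.
#' @param scores named numeric vector, names are residue keys.
#' @param path output PDB path.
#' @return invisibly, the path.
#' @export
write_score_pdb <- function(model, scores, path) {
  at <- model$atoms
  sc <- scores[at$key]
  missing_keys <- unique(at$key[is.na(sc)])
  if (length(missing_keys))
    warning("no score for ", length(missing_keys),
            " residue(s); writing 0.00")
  sc[is.na(sc)] <- 0
  if (any(abs(sc) > 999.99))
    stop("score magnitude exceeds the PDB B-factor field (999.99)")
  lines <- sprintf(
    "%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(at$hetero, "HETATM", "ATOM"),
    at$serial %% 100000L,
    ifelse(nchar(at$name) < 4L, paste0(" ", at$name), at$name),
    "", substr(at$resid, 1, 3), at$chain, at$resno %% 10000L, at$icode,
    at$x, at$y, at$z, pmin(at$occupancy, 9.99), sc,
    substr(at$element, 1, 2))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a structure model as a plain PDB file
#' @inheritParams write_score_pdb
#' @export
write_structure_pdb <- function(model, path) {
  b <- model$atoms$b
  names(b) <- NULL
  at <- model$atoms
  lines <- sprintf(
    "%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(at$hetero, "HETATM", "ATOM"),
    at$serial %% 100000L,
    ifelse(nchar(at$name) < 4L, paste0(" ", at$name), at$name),
    "", substr(at$resid, 1, 3), at$chain, at$resno %% 10000L, at$icode,
    at$x, at$y, at$z, pmin(at$occupancy, 9.99), b,
    substr(at$element, 1, 2))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write provenance information as JSON
#' @param model a `structure_model`.
#' @param path output path.
#' @export
write_provenance <- function(model, path) {
  jsonlite::write_json(model$provenance, path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
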