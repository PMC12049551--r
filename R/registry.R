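## The per-residue parameter registry: 28 parameters in four categories
## (SE solvent exposure, CS conservation, SS secondary structure, CR
## cysteine resemblance).  The named anchors (#1 relative surface area
## (Wilke), #4 first half-sphere exposure (10 A), #11 mean surface
## distance, #13 conservation score, #16 variant length in homologs,
## #17 cysteine in homologs, #18 secondary structure (DSSP), #25 amino
## acid identity, #27 amino acid charge) follow their published
## definitions; the remaining registry slots are implemented per their
## category and name, with the interpretation recorded in the `definition`
## column and flagged "interpretation".

#' Column name of a registry parameter in a parameter table
#' @param id integer parameter id (1-28).
#' @return character like "p11".
#' @export
param_column <- function(id) sprintf("p%02d", as.integer(id))

#' The 28-parameter registry
#'
#' @return data.frame with `id`, `name`, `category` (CS/SE/SS/CR),
#'   `datatype` (numeric/categorical), `definition`, `interpretation`
#'   (TRUE where the definition is this package's reading of the name).
#' @export
parameter_registry <- function() {
  r <- function(id, name, cat, type, def, interp = TRUE)
    data.frame(id = id, name = name, category = cat, datatype = type,
               definition = def, interpretation = interp,
               stringsAsFactors = FALSE)
  rbind(
    r(1, "rel_asa", "SE", "numeric",
      "relative surface area (Wilke): Shrake-Rupley ASA / theoretical max",
      FALSE),
    r(2, "abs_asa", "SE", "numeric", "absolute residue ASA (A^2)"),
    r(3, "rel_asa_probe3", "SE", "numeric",
      "relative surface area with a 3.0 A probe (pocket-insensitive)"),
    r(4, "hse_up_10", "SE", "numeric",
      "first half-sphere exposure, 10 A (CA neighbours on the CB side)",
      FALSE),
    r(5, "hse_down_10", "SE", "numeric",
      "second half-sphere exposure, 10 A"),
    r(6, "hse_up_13", "SE", "numeric", "first half-sphere exposure, 13 A"),
    r(7, "hse_down_13", "SE", "numeric", "second half-sphere exposure, 13 A"),
    r(8, "contact_number_10", "SE", "numeric",
      "CA contact number within 10 A"),
    r(9, "ca_depth", "SE", "numeric", "CA distance to molecular surface (A)"),
    r(10, "cb_depth", "SE", "numeric",
      "CB (virtual for Gly) distance to molecular surface (A)"),
    r(11, "mean_surface_distance", "SE", "numeric",
      "mean distance of all residue atoms to the molecular surface (A)",
      FALSE),
    r(12, "exposure_ratio", "SE", "numeric",
      "hse_up / (hse_up + hse_down) at 10 A"),
    r(13, "consurf_score", "CS", "numeric",
      "ConSurf normalized conservation score (negative = conserved)", FALSE),
    r(14, "consurf_grade", "CS", "categorical",
      "ConSurf grade 1-9 (9 = most conserved)", FALSE),
    r(15, "msa_conservation", "CS", "numeric",
      "MSA Shannon-entropy conservation, mean 0 / SD 1, negative = conserved"),
    r(16, "variant_length", "CS", "numeric",
      "variant length in homologs: distinct amino acids in the MSA column",
      FALSE),
    r(17, "cys_in_homologs", "CS", "categorical",
      "cysteine present at this position in any homolog (yes/no)", FALSE),
    r(18, "ss8", "SS", "categorical",
      "secondary structure of the labeled residue (DSSP 8-state)", FALSE),
    r(19, "ss3", "SS", "categorical", "secondary structure, 3-state H/E/C"),
    r(20, "phi", "SS", "numeric", "backbone phi dihedral (deg)"),
    r(21, "psi", "SS", "numeric", "backbone psi dihedral (deg)"),
    r(22, "ss_segment_length", "SS", "numeric",
      "length of the contiguous 3-state segment containing the residue"),
    r(23, "ss3_prev", "SS", "categorical",
      "3-state class of the preceding residue"),
    r(24, "ss3_next", "SS", "categorical",
      "3-state class of the following residue"),
    r(25, "aa_identity", "CR", "categorical",
      "amino acid identity of the exchanged residue", FALSE),
    r(26, "mass_delta", "CR", "numeric", "residue mass minus cysteine (Da)"),
    r(27, "aa_charge", "CR", "categorical",
      "side-chain charge class (positive/negative/neutral)", FALSE),
    r(28, "volume_delta", "CR", "numeric",
      "residue volume minus cysteine (A^3)"))
}

## default histogram edges / category levels per parameter id
default_binning <- function(id) {
  switch(as.character(id),
    "1" = seq(0, 1.2, 0.1),
    "2" = seq(0, 260, 20),
    "3" = seq(0, 1.2, 0.1),
    "4" = seq(0, 40, 4), "5" = seq(0, 40, 4),
    "6" = seq(0, 60, 5), "7" = seq(0, 60, 5),
    "8" = seq(0, 60, 5),
    "9" = seq(0, 12, 1), "10" = seq(0, 12, 1), "11" = seq(0, 12, 1),
    "12" = seq(0, 1, 0.1),
    "13" = seq(-2.5, 2.5, 0.5),
    "14" = as.character(1:9),
    "15" = seq(-2.5, 2.5, 0.5),
    "16" = seq(0.5, 20.5, 2),
    "17" = c("no", "yes"),
    "18" = c("H", "G", "I", "E", "B", "T", "S", "-"),
    "19" = c("H", "E", "C"),
    "20" = seq(-180, 180, 30), "21" = seq(-180, 180, 30),
    "22" = seq(0.5, 30.5, 3),
    "23" = c("H", "E", "C"), "24" = c("H", "E", "C"),
    "25" = STANDARD_AA,
    "26" = seq(-60, 120, 20),
    "27" = c("positive", "negative", "neutral"),
    "28" = seq(-60, 140, 20),
    stop("no default binning for parameter ", id))
}

#' The default four-parameter selection
#'
#' One parameter per category: mean surface distance (SE, #11),
#' conservation score (CS, #13), secondary structure (SS, #18) and amino
#' acid identity (CR, #25).
#' @return integer vector of parameter ids.
#' @export
default_selection <- function() c(11L, 13L, 18L, 25L)

#' Compute the per-residue parameter table
#'
#' Evaluates every registry parameter for every standard residue of the
#' model.  Conservation parameters come from a ConSurf grades file and/or
#' an MSA; without those inputs the CS columns are missing (missing values
#' are data, not errors).  Per-parameter completeness fractions are stored
#' in the `"completeness"` attribute.
#'
#' @param model a `structure_model`.
#' @param consurf optional: path to a ConSurf grades file or a data.frame
#'   from [parse_consurf_grades()].
#' @param dssp optional: path to a DSSP file or a data.frame from
#'   [parse_dssp_file()]; default is the internal assignment.
#' @param msa optional: path to an aligned FASTA for the conservation
#'   fallback and homolog parameters.
#' @param registry parameter registry (default [parameter_registry()]).
#' @param sasa_points dots per atom for surface calculations.
#' @return data.frame (class `parameter_table`) with residue keys and one
#'   `pNN` column per registry parameter.
#' @export
build_parameter_table <- function(model, consurf = NULL, dssp = NULL,
                                  msa = NULL, registry = parameter_registry(),
                                  sasa_points = 480L) {
  stopifnot(nrow(registry) > 0)
  res <- model$residues[model$residues$standard, , drop = FALSE]
  tab <- data.frame(pdb_id = model$pdb_id, key = res$key, chain = res$chain,
                    resno = res$resno, icode = res$icode, aa = res$aa_parent,
                    stringsAsFactors = FALSE)
  n <- nrow(tab)
  ids <- registry$id
  want <- function(id) id %in% ids
  pick <- function(df, col) df[[col]][match(tab$key, df$key)]

  ## --- solvent exposure ---
  if (any(ids <= 12)) {
    sasa <- compute_sasa(model, n_points = sasa_points)
    if (want(1)) tab[[param_column(1)]] <- pick(sasa, "rel_asa")
    if (want(2)) tab[[param_column(2)]] <- pick(sasa, "asa")
    if (want(3)) {
      s3 <- compute_sasa(model, probe_radius = 3.0, n_points = sasa_points)
      tab[[param_column(3)]] <- pick(s3, "rel_asa")
    }
    if (any(ids %in% 4:5) || want(12)) {
      h10 <- compute_half_sphere_exposure(model, 10)
      if (want(4)) tab[[param_column(4)]] <- pick(h10, "hse_up")
      if (want(5)) tab[[param_column(5)]] <- pick(h10, "hse_down")
      if (want(12)) {
        tot <- pick(h10, "hse_up") + pick(h10, "hse_down")
        tab[[param_column(12)]] <- ifelse(tot > 0,
                                          pick(h10, "hse_up") / tot, NA)
      }
    }
    if (any(ids %in% 6:7)) {
      h13 <- compute_half_sphere_exposure(model, 13)
      if (want(6)) tab[[param_column(6)]] <- pick(h13, "hse_up")
      if (want(7)) tab[[param_column(7)]] <- pick(h13, "hse_down")
    }
    if (want(8)) {
      h <- compute_half_sphere_exposure(model, 10)
      tab[[param_column(8)]] <- pick(h, "hse_up") + pick(h, "hse_down")
    }
    if (any(ids %in% 9:11)) {
      msd <- compute_mean_surface_distance(model,
                                           n_points = min(sasa_points, 240L))
      if (want(11)) tab[[param_column(11)]] <- pick(msd, "msd")
      if (any(ids %in% 9:10)) {
        sd_cache <- surface_dots(model, n_points = min(sasa_points, 240L))
        near <- function(p) sqrt(min((sd_cache[, 1] - p[1])^2 +
                                       (sd_cache[, 2] - p[2])^2 +
                                       (sd_cache[, 3] - p[3])^2))
        if (want(9))
          tab[[param_column(9)]] <- vapply(tab$key, function(k) {
            p <- atom_xyz(model, k, "CA")
            if (is.null(p)) NA_real_ else near(p)
          }, numeric(1))
        if (want(10))
          tab[[param_column(10)]] <- vapply(tab$key, function(k) {
            p <- cbeta_position(model, k)
            if (is.null(p)) NA_real_ else near(p)
          }, numeric(1))
      }
    }
  }

  ## --- conservation ---
  if (!is.null(consurf)) {
    cs <- if (is.character(consurf)) parse_consurf_grades(consurf) else consurf
    ## partial coverage is fine (sentinels); but if most of the grades file
    ## fails to match the structure, the numbering is off
    matched <- mean(cs$key %in% tab$key)
    if (matched < 0.8)
      stop(sprintf("only %.0f%% of ConSurf grade rows match the structure",
                   100 * matched))
    if (want(13)) tab[[param_column(13)]] <- pick(cs, "consurf_score")
    if (want(14)) tab[[param_column(14)]] <-
        as.character(pick(cs, "consurf_grade"))
  }
  if (!is.null(msa)) {
    mc <- compute_msa_conservation(msa, model, chain = tab$chain[1])
    if (want(15)) tab[[param_column(15)]] <- pick(mc, "msa_conservation")
    if (want(16)) tab[[param_column(16)]] <- pick(mc, "variant_length")
    if (want(17)) tab[[param_column(17)]] <-
        ifelse(pick(mc, "cys_in_homologs"), "yes", "no")
    if (is.null(consurf) && want(13))
      tab[[param_column(13)]] <- pick(mc, "msa_conservation")
  }
  for (id in intersect(13:17, ids))
    if (!param_column(id) %in% names(tab))
      tab[[param_column(id)]] <- if (id %in% c(14, 17)) NA_character_
        else NA_real_

  ## --- secondary structure ---
  if (any(ids %in% 18:24)) {
    ss <- if (is.null(dssp)) assign_secondary_structure(model)
      else if (is.character(dssp)) parse_dssp_file(dssp) else dssp
    if (want(18)) tab[[param_column(18)]] <- pick(ss, "ss8")
    ss3 <- pick(ss, "ss3")
    if (want(19)) tab[[param_column(19)]] <- ss3
    if (any(ids %in% 20:21)) {
      pp <- compute_phi_psi(model)
      if (want(20)) tab[[param_column(20)]] <- pick(pp, "phi")
      if (want(21)) tab[[param_column(21)]] <- pick(pp, "psi")
    }
    if (want(22)) {
      seg <- rep(NA_integer_, n)
      if (n > 0) {
        runs <- rle(paste(tab$chain, ss3))
        seg <- rep(runs$lengths, runs$lengths)
      }
      tab[[param_column(22)]] <- seg
    }
    if (want(23)) tab[[param_column(23)]] <-
        c(NA_character_, ss3[-n])[seq_len(n)]
    if (want(24)) tab[[param_column(24)]] <-
        c(ss3[-1], NA_character_)[seq_len(n)]
  }

  ## --- cysteine resemblance ---
  if (any(ids %in% 25:28)) {
    cr <- compute_cysteine_resemblance(tab$aa)
    if (want(25)) tab[[param_column(25)]] <- cr$aa
    if (want(26)) tab[[param_column(26)]] <- cr$mass_delta
    if (want(27)) tab[[param_column(27)]] <- cr$charge
    if (want(28)) tab[[param_column(28)]] <- cr$volume_delta
  }

  cols <- param_column(ids)
  comp <- vapply(cols, function(cc)
    if (cc %in% names(tab)) mean(!is.na(tab[[cc]])) else 0, numeric(1))
  attr(tab, "completeness") <- comp
  attr(tab, "registry") <- registry
  class(tab) <- c("parameter_table", "data.frame")
  tab
}

## solvent-exposed dot cloud of a model (helper shared by depth parameters)
surface_dots <- function(model, probe_radius = 1.4, n_points = 240L) {
  at <- model$atoms[model$atoms$element != "H", , drop = FALSE]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  core <- sasa_core(xyz, vdw_radius(at$element), probe_radius, n_points,
                    keep_dots = TRUE)
  dots <- do.call(rbind, core$dots[!vapply(core$dots, is.null, logical(1))])
  if (is.null(dots)) stop("no solvent-exposed surface dots")
  dots
}

#' Write a parameter table as CSV with a JSON definition sidecar
#' @param table a `parameter_table`.
#' @param path CSV path; the sidecar is written next to it (".json").
#' @export
write_parameter_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  side <- list(registry = attr(table, "registry"),
               completeness = as.list(attr(table, "completeness")))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}
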