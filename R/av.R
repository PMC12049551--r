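## Interdye distance estimators: C-beta distances, the spherical-sector
## model (SSM) closed-form mean-position approximation, and the grid-based
## accessible-volume (AV) simulation, plus conversion of mean-position
## distances to FRET-averaged distances.

#' Fluorophore linker/dye parameters
#'
#' @param name label for the parameter set.
#' @param linker_length linker length R in Angstrom (typical 10-20).
#' @param linker_width linker width in Angstrom.
#' @param dye_radii one to three dye radii in Angstrom; the conservative
#'   single-volume clash test uses the largest.
#' @param epsilon small linker-length correction (~0.5 A) compensating the
#'   fluorophore core size in the SSM.
#' @return list of class `fluorophore_params`.
#' @export
fluorophore_params <- function(name = "generic", linker_length = 20,
                               linker_width = 4.5, dye_radii = c(3.5),
                               epsilon = 0.5) {
  stopifnot(linker_length > 0, epsilon >= 0, all(dye_radii > 0))
  structure(list(name = name, linker_length = linker_length,
                 linker_width = linker_width, dye_radii = dye_radii,
                 epsilon = epsilon), class = "fluorophore_params")
}

#' Dye-pair registry
#'
#' Shipped parameter sets for the three common donor-acceptor pairs
#' (Forster radii 51, 58 and 65 A) plus a generic default.  The
#' `correction` entries are the (a, b) constants of the mean-position to
#' FRET-averaged distance conversion, calibrated against the grid-AV
#' oracle on synthetic benchmark structures (see
#' [calibrate_correction()]); override them for custom dyes.
#'
#' @param name one of "AF555-AF647", "ATTO532-ATTO643", "AF546-AF647",
#'   "generic".
#' @return list of class `dye_pair` with `r0` (A), `donor`, `acceptor`
#'   (`fluorophore_params`) and `correction` (a, b).
#' @export
dye_pair <- function(name = c("generic", "AF555-AF647", "ATTO532-ATTO643",
                              "AF546-AF647")) {
  name <- match.arg(name)
  r0 <- switch(name, "AF555-AF647" = 51, "ATTO532-ATTO643" = 58,
               "AF546-AF647" = 65, generic = 50)
  dye <- fluorophore_params(name = name)
  corr <- switch(name,
                 "AF555-AF647" = c(a = 22.52, b = 25.4),
                 "ATTO532-ATTO643" = c(a = 22.01, b = 27.7),
                 "AF546-AF647" = c(a = 21.69, b = 29.2),
                 generic = c(a = 22.62, b = 25.0))
  structure(list(name = name, r0 = r0, donor = dye, acceptor = dye,
                 correction = corr), class = "dye_pair")
}

## heavy-atom coordinates + clash radii of a model
clash_atoms <- function(model) {
  at <- model$atoms[model$atoms$element != "H", , drop = FALSE]
  list(xyz = as.matrix(at[, c("x", "y", "z")]),
       r = vdw_radius(at$element))
}

#' C-beta to C-beta distance of a residue pair
#'
#' Glycine (or any residue lacking a C-beta) uses the ideal-geometry
#' virtual C-beta.
#'
#' @param model a `structure_model`.
#' @param key_i,key_j residue keys.
#' @return distance in Angstrom.
#' @export
cbeta_distance <- function(model, key_i, key_j) {
  ci <- cbeta_position(model, key_i)
  cj <- cbeta_position(model, key_j)
  if (is.null(ci) || is.null(cj))
    stop("missing backbone: cannot place C-beta for ",
         if (is.null(ci)) key_i else key_j)
  sqrt(sum((ci - cj)^2))
}

#' Grid-based accessible volume of a dye at a residue
#'
#' Enumerates grid positions within the linker length of the attachment
#' C-beta; a position is allowed iff the dye sphere (largest dye radius,
#' conservative single-volume variant) clears every protein atom and the
#' position is linker-reachable through cells with linker-width clearance.
#' An empty AV is returned flagged, not as an error.
#'
#' @param model a `structure_model`.
#' @param key residue key of the attachment site.
#' @param dye a `fluorophore_params`.
#' @param spacing grid spacing in Angstrom (default 1.0).
#' @param return_points also return the allowed point cloud.
#' @return list of class `accessible_volume` with `attachment`,
#'   `mean_position`, `n_points`, `spacing`, optionally `points`.
#' @export
grid_accessible_volume <- function(model, key, dye, spacing = 1.0,
                                   return_points = FALSE) {
  att <- cbeta_position(model, key)
  if (is.null(att)) stop("residue ", key, " has no attachment C-beta")
  ca <- clash_atoms(model)
  res <- av_grid_cpp(att, ca$xyz, ca$r, dye$linker_length, dye$linker_width,
                     max(dye$dye_radii), spacing, return_points)
  structure(list(key = key, attachment = att,
                 mean_position = as.numeric(res$mean_position),
                 n_points = as.integer(res$n_points), spacing = spacing,
                 empty = res$n_points == 0,
                 points = if (return_points) res$points else NULL),
            class = "accessible_volume")
}

#' Export an accessible-volume point cloud as XYZ
#' @param av an `accessible_volume` computed with `return_points = TRUE`.
#' @param path output path.
#' @export
av_export_xyz <- function(av, path) {
  if (is.null(av$points)) stop("AV was computed without return_points")
  n <- nrow(av$points)
  writeLines(c(as.character(n), sprintf("accessible volume %s", av$key),
               sprintf("D %10.4f %10.4f %10.4f", av$points[, 1],
                       av$points[, 2], av$points[, 3])), path)
  invisible(path)
}

#' Spherical-sector displacement relation
#'
#' The closed-form heart of the spherical-sector model: given the center
#' of mass d' of the inaccessible volume inside the sphere of effective
#' linker radius R~, the accessible-volume center is
#' d = (1 - (3/4) R~ / |d'|) d'.  In the typical regime |d'| < (3/4) R~
#' the factor is negative, so d points away from the blocking mass;
#' |d'| = (3/4) R~ is the symmetric root with d = 0, and |d'| = R~ gives
#' |d| = R~ / 4.
#'
#' @param d_prime 3-vector, inaccessible-volume COM relative to the
#'   attachment.
#' @param r_tilde effective linker length R + epsilon (A).
#' @return the displacement 3-vector d.
#' @export
ssm_offset <- function(d_prime, r_tilde) {
  nd <- sqrt(sum(d_prime^2))
  if (nd < 1e-9) return(c(0, 0, 0))
  (1 - 0.75 * r_tilde / nd) * d_prime
}

#' Spherical-sector-model mean dye position
#'
#' Fast closed-form approximation of the AV mean position: with effective
#' linker length R~ = R + epsilon, the protein atoms within reach of the
#' attachment define the dye-inaccessible volume (each atom dilated by its
#' vdW radius plus the dye radius); its center of mass d', estimated on a
#' deterministic coarse sample of the R~-ball without any path search,
#' enters the spherical-sector relation [ssm_offset()].  A free site (no
#' blocking atoms) gives d = 0 by symmetry.
#'
#' @param model a `structure_model`.
#' @param key residue key.
#' @param dye a `fluorophore_params`.
#' @param sample_spacing coarse-sampling grid step in Angstrom.
#' @return list with `offset` (d), `mean_position` (attachment + d),
#'   `d_prime`, `frac_inaccessible`, `attachment`.
#' @export
ssm_mean_position <- function(model, key, dye, sample_spacing = 1.7) {
  att <- cbeta_position(model, key)
  if (is.null(att)) stop("residue ", key, " has no attachment C-beta")
  rt <- dye$linker_length + dye$epsilon
  ca <- clash_atoms(model)
  core <- ssm_core_cpp(att, ca$xyz, ca$r, rt, max(dye$dye_radii),
                       sample_spacing)
  dprime <- as.numeric(core$d_prime)
  if (core$frac_inaccessible == 0) {
    return(list(offset = c(0, 0, 0), mean_position = att,
                d_prime = c(0, 0, 0), frac_inaccessible = 0,
                attachment = att))
  }
  d <- ssm_offset(dprime, rt)
  list(offset = d, mean_position = att + d, d_prime = dprime,
       frac_inaccessible = core$frac_inaccessible, attachment = att)
}

#' Forster relation: FRET efficiency from distance
#' @param r interdye distance (A), `r >= 0`.
#' @param r0 Forster radius (A), `> 0`.
#' @return E in (0, 1].
#' @export
fret_efficiency <- function(r, r0) {
  stopifnot(all(r >= 0), r0 > 0)
  1 / (1 + (r / r0)^6)
}

#' Convert a mean-position distance to a FRET-averaged distance
#'
#' R<E> = R_MP + a exp(-R_MP / b): the correction accounts for the
#' efficiency-weighted averaging over the dye clouds, vanishes at large
#' separation and is monotone in R_MP for the calibrated constants.
#'
#' @param r_mp mean-position distance(s), A.
#' @param pair a `dye_pair` (uses its calibrated `correction`), or a
#'   numeric c(a, b).
#' @return FRET-averaged distance(s), A.
#' @export
mp_to_fret_averaged <- function(r_mp, pair = dye_pair("generic")) {
  stopifnot(all(r_mp >= 0))
  corr <- if (inherits(pair, "dye_pair")) pair$correction else pair
  if (is.null(corr) || length(corr) != 2L || anyNA(corr))
    stop("no calibrated correction for this dye pair")
  r_mp + corr[[1]] * exp(-r_mp / corr[[2]])
}

#' Oracle FRET-averaged distance from two AV point clouds
#'
#' Averages the Forster efficiency over pairs of allowed dye positions
#' (isotropic orientation assumption) and converts the mean efficiency
#' back to a distance.  Clouds are deterministically thinned to at most
#' `max_points` positions each.
#'
#' @param av1,av2 `accessible_volume` objects with point clouds.
#' @param r0 Forster radius (A).
#' @param max_points per-cloud cap.
#' @return list with `r_mp`, `r_e` and `e_mean`.
#' @export
av_fret_averaged <- function(av1, av2, r0, max_points = 800L) {
  if (av1$empty || av2$empty) stop("empty accessible volume")
  thin <- function(p) {
    if (nrow(p) <= max_points) return(p)
    p[seq(1, nrow(p), length.out = max_points), , drop = FALSE]
  }
  p1 <- thin(av1$points); p2 <- thin(av2$points)
  r_mp <- sqrt(sum((av1$mean_position - av2$mean_position)^2))
  ## pairwise distances in one outer-product pass per coordinate
  d2 <- outer(p1[, 1], p2[, 1], "-")^2 + outer(p1[, 2], p2[, 2], "-")^2 +
    outer(p1[, 3], p2[, 3], "-")^2
  e <- mean(1 / (1 + (d2 / r0^2)^3))
  list(r_mp = r_mp, r_e = r0 * (1 / e - 1)^(1 / 6), e_mean = e)
}

#' Calibrate the mean-position to FRET-averaged correction
#'
#' Samples residue pairs on benchmark structures, computes R_MP and the
#' grid-AV oracle R<E> for the dye pair, and fits
#' R<E> - R_MP = a exp(-R_MP / b) by nonlinear least squares.
#'
#' @param models list of `structure_model`s (e.g. globule fixtures).
#' @param pair a `dye_pair`.
#' @param seed RNG seed for pair sampling.
#' @param n_pairs pairs per structure.
#' @param spacing AV grid spacing.
#' @return list with `a`, `b`, `rms_residual`, `n_pairs_used` and the
#'   fitted points.
#' @export
calibrate_correction <- function(models, pair, seed = 1L, n_pairs = 25L,
                                 spacing = 1.2) {
  set.seed(seed)
  dye <- pair$donor
  rmp <- numeric(0); delta <- numeric(0)
  for (model in models) {
    keys <- model$residues$key[model$residues$standard]
    keys <- keys[!vapply(keys, function(k) is.null(cbeta_position(model, k)),
                         logical(1))]
    if (length(keys) < 2L) next
    avs <- list()
    for (p in seq_len(n_pairs)) {
      ij <- sample(keys, 2L)
      for (k in ij) if (is.null(avs[[k]]))
        avs[[k]] <- grid_accessible_volume(model, k, dye, spacing,
                                           return_points = TRUE)
      a1 <- avs[[ij[1]]]; a2 <- avs[[ij[2]]]
      if (a1$empty || a2$empty) next
      o <- av_fret_averaged(a1, a2, pair$r0)
      rmp <- c(rmp, o$r_mp)
      delta <- c(delta, o$r_e - o$r_mp)
    }
  }
  if (length(rmp) < 20L)
    stop("calibration needs at least 20 usable pairs, got ", length(rmp))
  out <- fit_correction(rmp, delta)
  out$n_pairs_used <- length(rmp)
  out$r_mp <- rmp
  out$delta <- delta
  out
}

#' Fit the exponential distance-correction model
#'
#' Least-squares fit of delta = a exp(-r_mp / b); the workhorse behind
#' [calibrate_correction()], exposed so corrections can be fitted against
#' any oracle data.
#'
#' @param r_mp mean-position distances (A).
#' @param delta oracle FRET-averaged minus mean-position distances (A).
#' @return list with `a`, `b`, `rms_residual`.
#' @export
fit_correction <- function(r_mp, delta) {
  fit <- tryCatch(
    minpack.lm::nlsLM(delta ~ a * exp(-r_mp / b),
                      start = list(a = max(stats::median(delta), 0.5) * 3,
                                   b = 15),
                      lower = c(0, 1), upper = c(100, 200)),
    error = function(e) stop("correction fit did not converge: ",
                             conditionMessage(e),
                             " (rms delta = ",
                             signif(sqrt(mean(delta^2)), 3), ")"))
  cf <- stats::coef(fit)
  list(a = unname(cf["a"]), b = unname(cf["b"]),
       rms_residual = sqrt(mean(stats::resid(fit)^2)))
}

#' Run the SSM vs grid-AV benchmark over a generated manifest
#'
#' Builds the manifest's structures, computes for every (structure,
#' residue pair, dye variant) tuple the C-beta distance and the
#' mean-position distances under both the spherical-sector model and the
#' grid accessible-volume simulation (AVs cached per site).  Pairs whose
#' grid AV is empty (fully buried sites) carry NA grid distances.
#'
#' @param manifest output of [generate_av_test_set()].
#' @param spacing grid spacing for the AV oracle (A).
#' @return data.frame with one row per tuple: `r_cbeta`, `r_ssm`, `r_av`.
#' @export
av_benchmark <- function(manifest, spacing = 1.0) {
  models <- lapply(manifest$structures, function(s)
    generate_toy_structure(s$kind, s$n_residues, s$seed))
  av_cache <- new.env(parent = emptyenv())
  tu <- manifest$tuples
  out <- tu
  out$r_cbeta <- NA_real_; out$r_ssm <- NA_real_; out$r_av <- NA_real_
  for (r in seq_len(nrow(tu))) {
    m <- models[[tu$structure[r]]]
    keys <- m$residues$key[c(tu$res_i[r], tu$res_j[r])]
    dye <- fluorophore_params(linker_length = tu$linker_length[r],
                              linker_width = tu$linker_width[r],
                              dye_radii = tu$dye_radius[r])
    get_av <- function(k) {
      id <- sprintf("%d|%d|%s", tu$structure[r], tu$variant[r], k)
      if (is.null(av_cache[[id]]))
        av_cache[[id]] <- grid_accessible_volume(m, k, dye, spacing)
      av_cache[[id]]
    }
    a1 <- get_av(keys[1]); a2 <- get_av(keys[2])
    s1 <- ssm_mean_position(m, keys[1], dye)$mean_position
    s2 <- ssm_mean_position(m, keys[2], dye)$mean_position
    out$r_cbeta[r] <- cbeta_distance(m, keys[1], keys[2])
    out$r_ssm[r] <- sqrt(sum((s1 - s2)^2))
    if (!a1$empty && !a2$empty)
      out$r_av[r] <- sqrt(sum((a1$mean_position - a2$mean_position)^2))
  }
  out
}

#' Interdye distance and efficiency for a residue pair
#'
#' Computes the C-beta distance plus the mean-position distance under the
#' chosen estimator ("ssm" or "grid_av"), converts it to a FRET-averaged
#' distance with the pair's calibrated correction, and evaluates the
#' Forster efficiency.
#'
#' @param model a `structure_model`.
#' @param key_i,key_j residue keys.
#' @param pair a `dye_pair`.
#' @param estimator "ssm", "grid_av" or "cbeta".
#' @param spacing AV grid spacing (grid_av only).
#' @return one-row data.frame: `r_cbeta`, `r_mp`, `r_e`, `efficiency`,
#'   `estimator`.
#' @export
pair_distance <- function(model, key_i, key_j, pair = dye_pair("generic"),
                          estimator = c("ssm", "grid_av", "cbeta"),
                          spacing = 1.0) {
  estimator <- match.arg(estimator)
  rcb <- cbeta_distance(model, key_i, key_j)
  if (estimator == "cbeta") {
    r_mp <- rcb
  } else if (estimator == "ssm") {
    mi <- ssm_mean_position(model, key_i, pair$donor)$mean_position
    mj <- ssm_mean_position(model, key_j, pair$acceptor)$mean_position
    r_mp <- sqrt(sum((mi - mj)^2))
  } else {
    ai <- grid_accessible_volume(model, key_i, pair$donor, spacing)
    aj <- grid_accessible_volume(model, key_j, pair$acceptor, spacing)
    if (ai$empty || aj$empty)
      return(data.frame(key_i = key_i, key_j = key_j, r_cbeta = rcb,
                        r_mp = NA_real_, r_e = NA_real_,
                        efficiency = NA_real_, estimator = estimator,
                        stringsAsFactors = FALSE))
    r_mp <- sqrt(sum((ai$mean_position - aj$mean_position)^2))
  }
  r_e <- if (estimator == "cbeta") rcb else mp_to_fret_averaged(r_mp, pair)
  data.frame(key_i = key_i, key_j = key_j, r_cbeta = rcb, r_mp = r_mp,
             r_e = r_e, efficiency = fret_efficiency(r_e, pair$r0),
             estimator = estimator, stringsAsFactors = FALSE)
}
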