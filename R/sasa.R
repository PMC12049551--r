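## Solvent accessibility: Shrake-Rupley dot-sphere SASA with deterministic
## golden-spiral dot placement, plus the derived mean-surface-distance
## burial measure.

#' Deterministic golden-spiral points on the unit sphere
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

## per-atom SASA plus the exposed surface dots; shared core for
## compute_sasa() and compute_mean_surface_distance()
sasa_core <- function(xyz, radii, probe_radius = 1.4, n_points = 960L,
                      keep_dots = FALSE) {
  n <- nrow(xyz)
  sph <- golden_spiral_points(n_points)
  r_ext <- radii + probe_radius
  area <- numeric(n)
  dots <- if (keep_dots) vector("list", n) else NULL
  maxr <- max(r_ext)
  for (i in seq_len(n)) {
    ci <- xyz[i, ]
    d2 <- (xyz[, 1] - ci[1])^2 + (xyz[, 2] - ci[2])^2 + (xyz[, 3] - ci[3])^2
    nb <- which(d2 < (r_ext[i] + maxr)^2 & d2 > 1e-8)
    nb <- nb[sqrt(d2[nb]) < r_ext[i] + r_ext[nb]]
    pts <- sweep(sph * r_ext[i], 2, ci, "+")
    if (length(nb)) {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        cj <- xyz[j, ]
        dd2 <- (pts[, 1] - cj[1])^2 + (pts[, 2] - cj[2])^2 +
          (pts[, 3] - cj[3])^2
        free <- free & dd2 >= r_ext[j]^2
        if (!any(free)) break
      }
    } else free <- rep(TRUE, n_points)
    frac <- sum(free) / n_points
    area[i] <- 4 * pi * r_ext[i]^2 * frac
    ## exposed dots are emitted on the vdW contact surface, so that the
    ## distance of a fully exposed atom to "the surface" is ~ its radius
    if (keep_dots && any(free))
      dots[[i]] <- sweep(sph[free, , drop = FALSE] * radii[i], 2, ci, "+")
  }
  list(area = area, dots = dots)
}

#' Per-residue solvent-accessible surface area
#'
#' Shrake-Rupley dot-sphere SASA with deterministic golden-spiral dots,
#' summed per residue.  Relative ASA divides by the Wilke theoretical
#' maximum for the residue's amino acid (clipped to 1.2); residues without
#' a Wilke constant (non-standard) get `NA` relative values.
#'
#' @param model a `structure_model`.
#' @param probe_radius solvent probe radius in Angstrom (default 1.4).
#' @param n_points dots per atom sphere (default 960).
#' @return data.frame with `key`, `asa` (absolute, A^2) and `rel_asa`.
#' @export
compute_sasa <- function(model, probe_radius = 1.4, n_points = 960L) {
  at <- model$atoms
  if (nrow(at) == 0L) stop("structure has no atoms")
  heavy <- at$element != "H"
  at <- at[heavy, , drop = FALSE]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  core <- sasa_core(xyz, vdw_radius(at$element), probe_radius, n_points)
  asa <- tapply(core$area, at$key, sum)
  res <- model$residues
  out <- data.frame(key = res$key,
                    asa = as.numeric(asa[res$key]),
                    stringsAsFactors = FALSE)
  out$asa[is.na(out$asa)] <- 0
  mx <- WILKE_MAX_ASA[res$aa_parent]
  out$rel_asa <- pmin(out$asa / as.numeric(mx), 1.2)
  out
}

#' Per-residue mean distance to the molecular surface
#'
#' Builds the solvent-exposed Shrake-Rupley dot cloud of the whole
#' structure, then reports for every residue the mean distance of its atoms
#' to the nearest surface dot.  Surface residues score near zero, buried
#' residues score high.
#'
#' @inheritParams compute_sasa
#' @return data.frame with `key` and `msd` (Angstrom).
#' @export
compute_mean_surface_distance <- function(model, probe_radius = 1.4,
                                          n_points = 240L) {
  at <- model$atoms[model$atoms$element != "H", , drop = FALSE]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  core <- sasa_core(xyz, vdw_radius(at$element), probe_radius, n_points,
                    keep_dots = TRUE)
  dots <- do.call(rbind, core$dots[!vapply(core$dots, is.null, logical(1))])
  if (is.null(dots) || nrow(dots) == 0L)
    stop("no solvent-exposed surface dots; degenerate input")
  res <- model$residues
  msd <- vapply(res$key, function(k) {
    ax <- xyz[at$key == k, , drop = FALSE]
    if (nrow(ax) == 0L) return(NA_real_)
    mean(vapply(seq_len(nrow(ax)), function(i) {
      sqrt(min((dots[, 1] - ax[i, 1])^2 + (dots[, 2] - ax[i, 2])^2 +
                 (dots[, 3] - ax[i, 3])^2))
    }, numeric(1)))
  }, numeric(1))
  data.frame(key = res$key, msd = as.numeric(msd), stringsAsFactors = FALSE)
}

#' Half-sphere exposure
#'
#' Counts neighbouring C-alpha atoms within `radius` of each residue's
#' C-alpha, split into the half-sphere containing the C-alpha -> C-beta
#' direction ("up") and the opposite one ("down").  Glycine uses a virtual
#' C-beta from ideal backbone geometry.
#'
#' @param model a `structure_model`.
#' @param radius neighbour cutoff in Angstrom (default 10).
#' @return data.frame with `key`, `hse_up`, `hse_down`.
#' @export
compute_half_sphere_exposure <- function(model, radius = 10) {
  stopifnot(radius > 0)
  res <- model$residues
  ca <- t(vapply(res$key, function(k) {
    v <- atom_xyz(model, k, "CA")
    if (is.null(v)) rep(NA_real_, 3) else v
  }, numeric(3)))
  cb <- t(vapply(res$key, function(k) {
    v <- cbeta_position(model, k)
    if (is.null(v)) rep(NA_real_, 3) else v
  }, numeric(3)))
  n <- nrow(res)
  up <- integer(n); down <- integer(n)
  if (n < 2L) {
    warning("fewer than 2 residues: half-sphere exposure is zero")
    return(data.frame(key = res$key, hse_up = up, hse_down = down,
                      stringsAsFactors = FALSE))
  }
  for (i in seq_len(n)) {
    if (anyNA(ca[i, ]) || anyNA(cb[i, ])) { up[i] <- NA; down[i] <- NA; next }
    dir <- cb[i, ] - ca[i, ]
    dir <- dir / sqrt(sum(dir^2))
    rel <- sweep(ca, 2, ca[i, ])
    d2 <- rowSums(rel^2)
    nb <- which(d2 < radius^2 & d2 > 1e-8 & !is.na(d2))
    if (!length(nb)) next
    side <- rel[nb, , drop = FALSE] %*% dir
    up[i] <- sum(side > 0)
    down[i] <- sum(side <= 0)
  }
  data.frame(key = res$key, hse_up = up, hse_down = down,
             stringsAsFactors = FALSE)
}
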