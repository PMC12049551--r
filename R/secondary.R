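## Secondary-structure assignment from backbone geometry.
##
## Hydrogen bonds are detected with the Kabsch-Sander electrostatic energy
## (amide H placed from ideal geometry, cutoff -0.5 kcal/mol); n-turns and
## bridges then drive an 8-state assignment (H, G, I, E, B, T, S, "-")
## reducible to 3 states (H/E/C).

## backbone coordinate matrices per chain, in residue-table order
backbone_coords <- function(model) {
  res <- model$residues
  get <- function(name) t(vapply(res$key, function(k) {
    v <- atom_xyz(model, k, name)
    if (is.null(v)) rep(NA_real_, 3) else v
  }, numeric(3)))
  list(N = get("N"), CA = get("CA"), C = get("C"), O = get("O"),
       res = res)
}

## Kabsch-Sander H-bond energy matrix (kcal/mol); e[i, j] is the energy of
## the bond N-H(i) ... O=C(j)
ks_hbond_energy <- function(bb) {
  n <- nrow(bb$res)
  ## amide H: 1.0 A from N, opposite the C(i-1)->N / CA->N bisector
  H <- matrix(NA_real_, n, 3)
  chain <- bb$res$chain
  connected <- c(FALSE, vapply(seq_len(n - 1L), function(i) {
    if (chain[i] != chain[i + 1L]) return(FALSE)
    if (anyNA(bb$C[i, ]) || anyNA(bb$N[i + 1L, ])) return(FALSE)
    sqrt(sum((bb$C[i, ] - bb$N[i + 1L, ])^2)) < 2.5
  }, logical(1)))
  for (i in seq_len(n)) {
    if (!connected[i]) next               # chain start / break: no H
    if (anyNA(bb$N[i, ]) || anyNA(bb$CA[i, ])) next
    u1 <- bb$N[i, ] - bb$C[i - 1L, ]
    u2 <- bb$N[i, ] - bb$CA[i, ]
    u1 <- u1 / sqrt(sum(u1^2)); u2 <- u2 / sqrt(sum(u2^2))
    d <- u1 + u2
    H[i, ] <- bb$N[i, ] + d / sqrt(sum(d^2))
  }
  e <- matrix(Inf, n, n)
  q <- 0.084 * 332  # partial charges times conversion factor
  for (i in seq_len(n)) {
    if (anyNA(H[i, ]) || bb$res$aa[i] == "PRO") next
    for (j in seq_len(n)) {
      if (abs(i - j) < 2L && chain[i] == chain[j]) next
      if (anyNA(bb$O[j, ]) || anyNA(bb$C[j, ])) next
      rON <- sqrt(sum((bb$O[j, ] - bb$N[i, ])^2))
      if (rON > 5.2) next                 # distance pre-screen
      rCH <- sqrt(sum((bb$C[j, ] - H[i, ])^2))
      rOH <- sqrt(sum((bb$O[j, ] - H[i, ])^2))
      rCN <- sqrt(sum((bb$C[j, ] - bb$N[i, ])^2))
      e[i, j] <- q * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
    }
  }
  e
}

#' Assign secondary structure from backbone geometry
#'
#' @param model a `structure_model`.
#' @param reduce return the 3-state reduction (H/E/C) instead of 8-state.
#' @return data.frame with `key`, `ss8`, `ss3`; residues with missing
#'   backbone atoms get class `"-"` / `"C"` ("unassigned").
#' @export
assign_secondary_structure <- function(model, reduce = FALSE) {
  bb <- backbone_coords(model)
  n <- nrow(bb$res)
  out <- data.frame(key = bb$res$key, ss8 = rep("-", n),
                    ss3 = rep("C", n), stringsAsFactors = FALSE)
  if (n < 3L) return(out)
  e <- ks_hbond_energy(bb)
  hb <- e < -0.5                           # hb[i, j]: N-H(i)...O=C(j)
  chain <- bb$res$chain
  samechain <- outer(chain, chain, "==")
  ## peptide-bond continuity i -> i+1
  conn <- vapply(seq_len(n - 1L), function(i)
    chain[i] == chain[i + 1L] && !anyNA(bb$C[i, ]) && !anyNA(bb$N[i + 1L, ]) &&
      sqrt(sum((bb$C[i, ] - bb$N[i + 1L, ])^2)) < 2.5, logical(1))
  contiguous <- function(i, k) i + k <= n && all(conn[i:(i + k - 1L)])
  ## n-turns: O=C(i) ... H-N(i+k), requiring chain continuity
  turn <- function(k) vapply(seq_len(n), function(i)
    contiguous(i, k) && hb[i + k, i], logical(1))
  t3 <- turn(3L); t4 <- turn(4L); t5 <- turn(5L)
  ss <- rep("-", n)
  ## helices: two consecutive turn starts
  mark_helix <- function(t, k, code) {
    for (i in seq_len(n - k)) {
      if (i > 1L && t[i] && t[i - 1L]) {
        idx <- i:(i + k - 1L)
        ss[idx][ss[idx] == "-" | (code == "H")] <<- code
      }
    }
  }
  ## bridges (parallel / antiparallel ladders)
  bridge <- matrix(FALSE, n, n)
  for (i in 2:(n - 1L)) {
    for (j in 2:(n - 1L)) {
      if (abs(i - j) < 3L && samechain[i, j]) next
      para <- (hb[i, j - 1L] && hb[j + 1L, i]) ||
        (hb[j, i - 1L] && hb[i + 1L, j])
      anti <- (hb[i, j] && hb[j, i]) ||
        (hb[i - 1L, j + 1L] && hb[j - 1L, i + 1L])
      if (para || anti) bridge[i, j] <- TRUE
    }
  }
  has_bridge <- apply(bridge, 1, any)
  ## extended strands: bridges in consecutive residues form ladders
  for (i in seq_len(n)) {
    if (!has_bridge[i]) next
    neighbor_ladder <- (i > 1L && has_bridge[i - 1L]) ||
      (i < n && has_bridge[i + 1L])
    ss[i] <- if (neighbor_ladder) "E" else "B"
  }
  mark_helix(t4, 4L, "H")
  mark_helix(t3, 3L, "G")
  mark_helix(t5, 5L, "I")
  ## turns: residues covered by an isolated n-turn
  for (i in seq_len(n)) {
    if (ss[i] != "-") next
    covered <- FALSE
    for (k in 3:5) {
      t <- switch(as.character(k), "3" = t3, "4" = t4, "5" = t5)
      lo <- max(1L, i - k + 1L)
      if (any(t[lo:min(i, n - k)])) covered <- TRUE
    }
    if (covered) ss[i] <- "T"
  }
  ## bend: CA curvature > 70 degrees over i-2, i, i+2
  for (i in 3:(n - 2L)) {
    if (ss[i] != "-") next
    if (anyNA(bb$CA[i - 2L, ]) || anyNA(bb$CA[i, ]) || anyNA(bb$CA[i + 2L, ]))
      next
    if (!samechain[i - 2L, i + 2L]) next
    u <- bb$CA[i, ] - bb$CA[i - 2L, ]
    v <- bb$CA[i + 2L, ] - bb$CA[i, ]
    ang <- acos(pmin(1, pmax(-1, sum(u * v) /
                               sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
    if (is.finite(ang) && ang > 70) ss[i] <- "S"
  }
  ## missing backbone -> unassigned
  bad <- apply(is.na(bb$N) | is.na(bb$CA) | is.na(bb$C) | is.na(bb$O), 1, any)
  ss[bad] <- "-"
  out$ss8 <- ss
  out$ss3 <- ifelse(ss %in% c("H", "G", "I"), "H",
                    ifelse(ss %in% c("E", "B"), "E", "C"))
  if (reduce) out$ss <- out$ss3
  out
}

#' Backbone dihedral angles
#' @param model a `structure_model`.
#' @return data.frame with `key`, `phi`, `psi` in degrees (NA at termini).
#' @export
compute_phi_psi <- function(model) {
  bb <- backbone_coords(model)
  n <- nrow(bb$res)
  dihedral <- function(p1, p2, p3, p4) {
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
            b1[1] * b2[2] - b1[2] * b2[1])
    n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
            b2[1] * b3[2] - b2[2] * b3[1])
    m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
            n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
    atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  }
  phi <- rep(NA_real_, n); psi <- rep(NA_real_, n)
  chain <- bb$res$chain
  for (i in seq_len(n)) {
    if (i > 1L && chain[i] == chain[i - 1L] &&
        !anyNA(c(bb$C[i - 1L, ], bb$N[i, ], bb$CA[i, ], bb$C[i, ])) &&
        sqrt(sum((bb$C[i - 1L, ] - bb$N[i, ])^2)) < 2.5)
      phi[i] <- dihedral(bb$C[i - 1L, ], bb$N[i, ], bb$CA[i, ], bb$C[i, ])
    if (i < n && chain[i] == chain[i + 1L] &&
        !anyNA(c(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$N[i + 1L, ])) &&
        sqrt(sum((bb$C[i, ] - bb$N[i + 1L, ])^2)) < 2.5)
      psi[i] <- dihedral(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$N[i + 1L, ])
  }
  data.frame(key = bb$res$key, phi = phi, psi = psi,
             stringsAsFactors = FALSE)
}

#' Parse a classic-format DSSP output file
#'
#' Reads the per-residue block of a DSSP text file and returns the 8-state
#' class per residue.  Chain-break rows ("!") are skipped; unparsed lines
#' are counted in the result's `"skipped"` attribute.
#'
#' @param path path to a DSSP file.
#' @return data.frame with `key`, `ss8`, `ss3`.
#' @export
parse_dssp_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (!length(hdr)) stop("malformed DSSP file: residue header not found")
  body <- lines[(hdr[1] + 1L):length(lines)]
  skipped <- 0L
  rows <- list()
  for (ln in body) {
    if (nchar(ln) < 17) { skipped <- skipped + 1L; next }
    aa1 <- substr(ln, 14, 14)
    if (aa1 == "!") next                   # chain break
    resno <- suppressWarnings(as.integer(trimws(substr(ln, 6, 10))))
    if (is.na(resno)) { skipped <- skipped + 1L; next }
    icode <- trimws(substr(ln, 11, 11))
    chain <- trimws(substr(ln, 12, 12))
    ss <- substr(ln, 17, 17)
    if (ss == " ") ss <- "-"
    rows[[length(rows) + 1L]] <- data.frame(
      key = res_key(chain, resno, icode), ss8 = ss,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("malformed DSSP file: no residue rows parsed")
  out$ss3 <- ifelse(out$ss8 %in% c("H", "G", "I"), "H",
                    ifelse(out$ss8 %in% c("E", "B"), "E", "C"))
  attr(out, "skipped") <- skipped
  out
}
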