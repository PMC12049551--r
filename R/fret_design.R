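## FRET assay design: pair scores for a single structure (FS) and for two
## interconverting structures (FS-delta), plus the screen-then-refine
## workflow (SSM screening, grid-AV refinement of the best pairs).

#' FRET score of a residue pair (single structure)
#'
#' FS = sqrt(LS_i LS_j) (1 - 2 |1/2 - E|): the geometric-mean label score
#' weighted by a sensitivity factor that is maximal at predicted
#' efficiency 0.5 (interdye distance near the Forster radius) and zero at
#' E = 0 or 1.
#'
#' @param ls_i,ls_j label scores (>= 0).
#' @param e predicted FRET efficiency in [0, 1].
#' @return FS (vectorized).
#' @export
fret_score <- function(ls_i, ls_j, e) {
  stopifnot(all(ls_i >= 0, na.rm = TRUE), all(ls_j >= 0, na.rm = TRUE))
  if (any(e < 0 | e > 1, na.rm = TRUE))
    stop("FRET efficiency outside [0, 1]")
  sqrt(ls_i * ls_j) * (1 - 2 * abs(0.5 - e))
}

#' FRET difference score of a residue pair (two structures)
#'
#' FS_delta = sqrt(LS_i^A LS_i^B) sqrt(LS_j^A LS_j^B) |E^A - E^B|:
#' rewards pairs that are labelable in both conformations and shift
#' efficiency between them.
#'
#' @param ls_i_a,ls_i_b,ls_j_a,ls_j_b label scores in structures A and B.
#' @param e_a,e_b predicted efficiencies in A and B.
#' @return FS_delta (vectorized).
#' @export
fret_delta_score <- function(ls_i_a, ls_i_b, ls_j_a, ls_j_b, e_a, e_b) {
  stopifnot(all(c(ls_i_a, ls_i_b, ls_j_a, ls_j_b) >= 0, na.rm = TRUE))
  if (any(c(e_a, e_b) < 0 | c(e_a, e_b) > 1, na.rm = TRUE))
    stop("FRET efficiency outside [0, 1]")
  sqrt(ls_i_a * ls_i_b) * sqrt(ls_j_a * ls_j_b) * abs(e_a - e_b)
}

## per-residue SSM or grid-AV mean positions, memoized over keys
mean_positions <- function(model, keys, dye, estimator, spacing = 1.0) {
  mp <- matrix(NA_real_, length(keys), 3, dimnames = list(keys, NULL))
  for (k in keys) {
    p <- tryCatch(
      if (estimator == "ssm") ssm_mean_position(model, k, dye)$mean_position
      else {
        av <- grid_accessible_volume(model, k, dye, spacing)
        if (av$empty) NULL else av$mean_position
      }, error = function(e) NULL)
    if (!is.null(p)) mp[k, ] <- p
  }
  mp
}

#' Screen residue pairs for a FRET assay, then refine the best ones
#'
#' Stage 1 scores every unordered residue pair whose geometric-mean label
#' score passes `ls_min` using SSM-derived efficiencies; stage 2 re-scores
#' the `refine_top` best pairs with the grid accessible-volume simulation.
#' With one structure the score is FS; with two structures (A, B, matched
#' by residue key) it is FS_delta, and pairs with high FS in both states
#' but FS_delta below `negctrl_threshold` are reported as negative-control
#' candidates.
#'
#' @param models a `structure_model` or list of two (states A and B).
#' @param ls label-score data.frame(s) from [compute_label_score()]
#'   (one per structure).
#' @param pair a `dye_pair`.
#' @param ls_min minimum geometric-mean LS for a pair (default 1).
#' @param refine_top number of pairs refined with the grid AV (default 300;
#'   0 skips refinement).
#' @param spacing grid spacing for the refinement stage.
#' @param intra_chain restrict pairs to residues on the same chain.
#' @param negctrl_threshold FS_delta below which a both-states-bright pair
#'   is listed as a negative control.
#' @return list of class `fret_screen`: `pairs` (ranked data.frame),
#'   `negative_controls`, `settings`.
#' @export
screen_pairs <- function(models, ls, pair = dye_pair("generic"), ls_min = 1,
                         refine_top = 300L, spacing = 1.0,
                         intra_chain = TRUE, negctrl_threshold = 0.05) {
  two_state <- is.list(models) && !inherits(models, "structure_model")
  if (two_state) {
    stopifnot(length(models) == 2L)
    ls_a <- ls[[1]]; ls_b <- ls[[2]]
    keys <- intersect(ls_a$key, ls_b$key)
    if (!length(keys)) stop("no overlapping residue keys between structures")
    model_a <- models[[1]]; model_b <- models[[2]]
  } else {
    model_a <- models
    ls_a <- ls
    keys <- ls_a$key
  }
  lsv_a <- stats::setNames(ls_a$ls, ls_a$key)[keys]
  if (two_state) lsv_b <- stats::setNames(ls_b$ls, ls_b$key)[keys]
  ## scorable residues need an LS and an attachment point
  has_cb <- vapply(keys, function(k)
    !is.null(cbeta_position(model_a, k)) &&
      (!two_state || !is.null(cbeta_position(model_b, k))), logical(1))
  keep_keys <- has_cb & !is.na(lsv_a)
  if (two_state) keep_keys <- keep_keys & !is.na(lsv_b)
  keys <- keys[keep_keys]
  if (length(keys) < 2L) stop("fewer than 2 scorable residues")
  if (intra_chain) {
    ch <- sub(":.*", "", keys)
  }
  cmb <- utils::combn(keys, 2L)
  pl_a <- sqrt(lsv_a[cmb[1, ]] * lsv_a[cmb[2, ]])
  pair_ls <- if (two_state)
    sqrt(sqrt(lsv_a[cmb[1, ]] * lsv_b[cmb[1, ]]) *
           sqrt(lsv_a[cmb[2, ]] * lsv_b[cmb[2, ]]))
    else pl_a
  keep <- pair_ls >= ls_min
  if (intra_chain) keep <- keep & ch[match(cmb[1, ], keys)] ==
      ch[match(cmb[2, ], keys)]
  if (!any(keep)) {
    warning("no residue pair passes ls_min = ", ls_min)
    return(structure(list(pairs = data.frame(), negative_controls = data.frame(),
                          settings = list(ls_min = ls_min)),
                     class = "fret_screen"))
  }
  cmb <- cmb[, keep, drop = FALSE]

  score_stage <- function(estimator, subset = NULL) {
    idx <- if (is.null(subset)) seq_len(ncol(cmb)) else subset
    used <- unique(c(cmb[1, idx], cmb[2, idx]))
    mp_a <- mean_positions(model_a, used, pair$donor, estimator, spacing)
    if (two_state) mp_b <- mean_positions(model_b, used, pair$donor,
                                          estimator, spacing)
    e_of <- function(mp, i, j) {
      d <- sqrt(rowSums((mp[i, , drop = FALSE] - mp[j, , drop = FALSE])^2))
      fret_efficiency(mp_to_fret_averaged(d, pair), pair$r0)
    }
    e_a <- e_of(mp_a, cmb[1, idx], cmb[2, idx])
    if (two_state) {
      e_b <- e_of(mp_b, cmb[1, idx], cmb[2, idx])
      fs_a <- fret_score(lsv_a[cmb[1, idx]], lsv_a[cmb[2, idx]], e_a)
      fs_b <- fret_score(lsv_b[cmb[1, idx]], lsv_b[cmb[2, idx]], e_b)
      fsd <- fret_delta_score(lsv_a[cmb[1, idx]], lsv_b[cmb[1, idx]],
                              lsv_a[cmb[2, idx]], lsv_b[cmb[2, idx]],
                              e_a, e_b)
      data.frame(idx = idx, e_a = e_a, e_b = e_b, fs_a = fs_a, fs_b = fs_b,
                 score = fsd)
    } else {
      data.frame(idx = idx, e_a = e_a,
                 score = fret_score(lsv_a[cmb[1, idx]], lsv_a[cmb[2, idx]],
                                    e_a))
    }
  }
  s1 <- score_stage("ssm")
  out <- data.frame(key_i = cmb[1, ], key_j = cmb[2, ],
                    pair_ls = as.numeric(pair_ls[keep]),
                    e_screen = s1$e_a, score_screen = s1$score,
                    stringsAsFactors = FALSE)
  if (two_state) {
    out$e_a_screen <- s1$e_a; out$e_b_screen <- s1$e_b
    out$fs_a <- s1$fs_a; out$fs_b <- s1$fs_b
  }
  out$score_refined <- NA_real_
  if (refine_top > 0L && nrow(out) > 0L) {
    ord <- order(-out$score_screen)
    top <- ord[seq_len(min(refine_top, length(ord)))]
    s2 <- score_stage("grid_av", subset = top)
    out$score_refined[s2$idx] <- s2$score
    if (two_state) {
      out$e_a_refined <- NA_real_; out$e_b_refined <- NA_real_
      out$e_a_refined[s2$idx] <- s2$e_a
      out$e_b_refined[s2$idx] <- s2$e_b
    } else {
      out$e_refined <- NA_real_
      out$e_refined[s2$idx] <- s2$e_a
    }
  }
  out$score <- ifelse(is.na(out$score_refined), out$score_screen,
                      out$score_refined)
  out <- out[order(-out$score, out$key_i, out$key_j), , drop = FALSE]
  rownames(out) <- NULL
  negctrl <- if (two_state)
    out[out$fs_a > 0.2 & out$fs_b > 0.2 & out$score < negctrl_threshold, ]
    else out[0, ]
  structure(list(pairs = out, negative_controls = negctrl,
                 settings = list(ls_min = ls_min, refine_top = refine_top,
                                 dye_pair = pair$name, spacing = spacing,
                                 two_state = two_state)),
            class = "fret_screen")
}

#' @export
print.fret_screen <- function(x, n = 5L, ...) {
  cat(sprintf("<fret_screen> %d pair(s), dye pair %s%s\n", nrow(x$pairs),
              x$settings$dye_pair,
              if (isTRUE(x$settings$two_state)) ", two-state" else ""))
  if (nrow(x$pairs)) print(utils::head(x$pairs, n))
  invisible(x)
}

#' Export a residue-by-residue pair matrix as CSV
#'
#' Builds the symmetric matrix of a pair quantity (C-beta distance change,
#' SSM distance change, FS, or FS_delta) over all residues that appear in
#' the screen; the diagonal is empty.
#'
#' @param screen a `fret_screen`.
#' @param mode one of "fs", "fs_delta", "cbeta_delta", "ssm_delta"
#'   (the *_delta modes need a two-state screen with distance columns).
#' @param path CSV output path.
#' @param models optional structure(s) for the distance-change modes.
#' @return the matrix, invisibly (also written to `path`).
#' @export
pair_matrix_export <- function(screen, mode = c("fs", "fs_delta",
                                                "cbeta_delta", "ssm_delta"),
                               path, models = NULL) {
  mode <- match.arg(mode)
  p <- screen$pairs
  if (!nrow(p)) stop("empty screen")
  keys <- sort(unique(c(p$key_i, p$key_j)))
  m <- matrix(NA_real_, length(keys), length(keys),
              dimnames = list(keys, keys))
  val <- switch(mode,
    fs = if (isTRUE(screen$settings$two_state)) p$fs_a else p$score,
    fs_delta = {
      if (!isTRUE(screen$settings$two_state))
        stop("fs_delta needs a two-state screen")
      p$score
    },
    cbeta_delta = {
      if (is.null(models) || length(models) != 2L)
        stop("cbeta_delta needs the two structures")
      vapply(seq_len(nrow(p)), function(i)
        cbeta_distance(models[[2]], p$key_i[i], p$key_j[i]) -
          cbeta_distance(models[[1]], p$key_i[i], p$key_j[i]), numeric(1))
    },
    ssm_delta = {
      if (is.null(models) || length(models) != 2L)
        stop("ssm_delta needs the two structures")
      dmod <- dye_pair("generic")
      vapply(seq_len(nrow(p)), function(i) {
        d <- function(mod) {
          mi <- ssm_mean_position(mod, p$key_i[i], dmod$donor)$mean_position
          mj <- ssm_mean_position(mod, p$key_j[i], dmod$donor)$mean_position
          sqrt(sum((mi - mj)^2))
        }
        d(models[[2]]) - d(models[[1]])
      }, numeric(1))
    })
  for (i in seq_len(nrow(p))) {
    m[p$key_i[i], p$key_j[i]] <- val[i]
    m[p$key_j[i], p$key_i[i]] <- val[i]
  }
  utils::write.csv(m, path, row.names = TRUE, na = "")
  invisible(m)
}
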