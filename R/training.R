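## Parameter-score training: the naive-Bayes odds ratio PS(s) = P(s|l)/P(s)
## per parameter bin, with Poisson counting-statistics uncertainties, plus
## the diagnostics used to choose parameter sets (information measures,
## cross-correlations, set correlation, t value, dynamic range, log-bin
## enrichment slope).

#' Load a label database CSV
#'
#' Mandatory columns (case-insensitive): pdb_id, chain, resno, mutation,
#' assay.  Duplicate (pdb_id, chain, resno) records are collapsed with a
#' warning.
#'
#' @param path CSV path.
#' @return data.frame of class `label_db`.
#' @export
load_label_database <- function(path) {
  db <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(db) <- tolower(names(db))
  need <- c("pdb_id", "chain", "resno", "mutation", "assay")
  miss <- setdiff(need, names(db))
  if (length(miss))
    stop("label database is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  db$mutation <- tolower(db$mutation)
  db$mutation[db$mutation == "uaa"] <- "UAA"
  bad <- !db$mutation %in% c("cysteine", "UAA")
  if (any(bad)) stop("unknown mutation type(s): ",
                     paste(unique(db$mutation[bad]), collapse = ", "))
  keyid <- paste(db$pdb_id, db$chain, db$resno)
  if (anyDuplicated(keyid)) {
    warning("collapsed ", sum(duplicated(keyid)),
            " duplicated labeled-residue record(s)")
    db <- db[!duplicated(keyid), , drop = FALSE]
  }
  rownames(db) <- NULL
  class(db) <- c("label_db", "data.frame")
  db
}

#' Write a label database CSV
#' @param db a `label_db`.
#' @param path CSV path.
#' @export
write_label_database <- function(db, path) {
  utils::write.csv(as.data.frame(db), path, row.names = FALSE)
  invisible(path)
}

## match database records onto parameter-table rows -> logical mask
labeled_mask_from_db <- function(table, db) {
  tk <- paste(table$pdb_id, table$chain, table$resno)
  dk <- paste(db$pdb_id, db$chain, db$resno)
  tk %in% dk
}

#' Estimate the parameter score for one parameter
#'
#' Numeric parameters are histogrammed on shared bin edges for the
#' background and the labeled subset; categorical parameters are counted
#' per category.  PS = P(s|l)/P(s) per bin; bins never seen in the
#' background (P(s) = 0) are excluded (NA), bins with no labeled
#' observation give PS = 0 with a one-count upper-bound uncertainty.
#' Uncertainties follow Poisson counting statistics propagated through the
#' ratio.
#'
#' @param values vector of parameter values over all residues.
#' @param labeled logical mask of labeled residues.
#' @param binning numeric bin edges, or character category levels.
#' @param datatype "numeric" or "categorical".
#' @return list with bin definition, probabilities, `ps`, `sigma`, counts.
#' @export
estimate_parameter_score <- function(values, labeled, binning,
                                     datatype = c("numeric", "categorical")) {
  datatype <- match.arg(datatype)
  stopifnot(length(labeled) == length(values))
  ok <- !is.na(values)
  v_all <- values[ok]
  v_lab <- values[ok & labeled]
  if (!length(v_lab)) stop("no labeled residues with non-missing values")
  if (datatype == "numeric") {
    edges <- binning
    clamp <- function(v) pmin(pmax(v, edges[1]),
                              edges[length(edges)] - 1e-9)
    bin_of <- function(v) findInterval(clamp(v), edges,
                                       rightmost.closed = TRUE)
    k <- length(edges) - 1L
    c_all <- tabulate(bin_of(v_all), k)
    c_lab <- tabulate(bin_of(v_lab), k)
    labels <- sprintf("[%g,%g)", edges[-length(edges)], edges[-1])
  } else {
    levels <- binning
    c_all <- as.integer(table(factor(v_all, levels = levels)))
    c_lab <- as.integer(table(factor(v_lab, levels = levels)))
    labels <- levels
    edges <- NULL
  }
  n_all <- sum(c_all)
  n_lab <- sum(c_lab)
  p_all <- c_all / n_all
  p_lab <- c_lab / n_lab
  ps <- ifelse(p_all > 0, p_lab / p_all, NA_real_)
  sig_sl <- sqrt(p_lab / n_lab)
  sig_s <- sqrt(p_all / n_all)
  sigma <- ifelse(p_all > 0 & p_lab > 0,
                  ps * sqrt((sig_sl / p_lab)^2 + (sig_s / p_all)^2),
                  NA_real_)
  ## one-count upper bound where no labeled observation fell in the bin
  zero <- p_all > 0 & p_lab == 0
  sigma[zero] <- (1 / n_lab) / p_all[zero]
  list(datatype = datatype, edges = edges, labels = labels,
       counts_all = c_all, counts_labeled = c_lab,
       p_all = p_all, p_labeled = p_lab, ps = ps, sigma = sigma,
       n_all = n_all, n_labeled = n_lab)
}

#' Fit a parameter-score model
#'
#' The central fitting function: estimates, for every selected registry
#' parameter, the binned odds ratio PS(s) = P(s|l)/P(s) between labeled
#' residues and the full background, with counting-statistics errors.
#' The prior P(l) is deliberately not estimated (the literature is biased
#' towards successes); PS values are comparative figures, not
#' probabilities.
#'
#' @param table a `parameter_table` covering all residues (background).
#' @param labeled logical mask over table rows, a `label_db`, or a
#'   character vector of residue keys.
#' @param params integer ids of the parameters to train (default: all
#'   parameters present in the table).
#' @param bins optional named list (by id) of bin edges / category levels
#'   overriding the registry defaults.
#' @return an object of class `ps_model`.
#' @export
ps_fit <- function(table, labeled, params = NULL, bins = list()) {
  reg <- attr(table, "registry")
  if (is.null(reg)) reg <- parameter_registry()
  if (is.null(params)) {
    params <- reg$id[param_column(reg$id) %in% names(table)]
  }
  if (inherits(labeled, "label_db")) labeled <- labeled_mask_from_db(table, labeled)
  if (is.character(labeled)) labeled <- table$key %in% labeled
  stopifnot(is.logical(labeled), length(labeled) == nrow(table))
  if (!any(labeled)) stop("empty labeled set")
  entries <- list()
  for (id in params) {
    col <- param_column(id)
    if (!col %in% names(table)) stop("parameter not in table: #", id)
    row <- reg[reg$id == id, ]
    binning <- bins[[as.character(id)]]
    if (is.null(binning)) binning <- default_binning(id)
    vals <- table[[col]]
    if (all(is.na(vals[labeled]))) next   # untrainable: no labeled data
    e <- estimate_parameter_score(vals, labeled, binning, row$datatype)
    e$id <- id
    e$name <- row$name
    e$category <- row$category
    entries[[as.character(id)]] <- e
  }
  if (!length(entries)) stop("no trainable parameters")
  structure(list(entries = entries, params = as.integer(names(entries)),
                 n_residues = nrow(table), n_labeled = sum(labeled),
                 registry = reg, call = match.call()),
            class = "ps_model")
}

#' @export
print.ps_model <- function(x, ...) {
  cat(sprintf("<ps_model> %d parameter score(s), %d residues (%d labeled)\n",
              length(x$entries), x$n_residues, x$n_labeled))
  for (e in x$entries)
    cat(sprintf("  #%d %s [%s, %s]: %d bins, PS range %.2f-%.2f\n",
                e$id, e$name, e$category, e$datatype, length(e$ps),
                min(e$ps, na.rm = TRUE), max(e$ps, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.ps_model <- function(object, ...) {
  rows <- lapply(object$entries, function(e) {
    im <- information_measures(e$ps)
    data.frame(id = e$id, name = e$name, category = e$category,
               datatype = e$datatype, n_bins = length(e$ps),
               msd = im[["msd"]], gini = im[["gini"]], entropy = im[["H"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("summary.ps_model", "data.frame")
  out
}

#' @export
coef.ps_model <- function(object, ...) {
  rows <- lapply(object$entries, function(e)
    data.frame(id = e$id, name = e$name, bin = e$labels, ps = e$ps,
               sigma = e$sigma, p_all = e$p_all, p_labeled = e$p_labeled,
               stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
plot.ps_model <- function(x, ids = x$params, ...) {
  old <- graphics::par(mfrow = c(1, length(ids)))
  on.exit(graphics::par(old))
  for (id in ids) {
    e <- x$entries[[as.character(id)]]
    bp <- graphics::barplot(e$ps, names.arg = e$labels, las = 2,
                            main = sprintf("#%d %s", e$id, e$name),
                            ylab = "PS", ...)
    graphics::arrows(bp, e$ps - e$sigma, bp, e$ps + e$sigma,
                     angle = 90, code = 3, length = 0.03)
    graphics::abline(h = 1, lty = 2)
  }
  invisible(x)
}

#' Serialize / restore a trained model as JSON
#' @param model a `ps_model`.
#' @param path JSON path.
#' @export
write_ps_model <- function(model, path) {
  payload <- list(n_residues = model$n_residues, n_labeled = model$n_labeled,
                  entries = unname(model$entries))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_ps_model
#' @export
read_ps_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  entries <- lapply(seq_len(nrow(p$entries)), function(i) {
    e <- lapply(p$entries, function(col)
      if (is.data.frame(col)) col[i, ] else
        if (is.list(col)) col[[i]] else col[i])
    e$edges <- unlist(e$edges)
    e$labels <- unlist(e$labels)
    e$ps <- unlist(e$ps)
    e$sigma <- unlist(e$sigma)
    e$p_all <- unlist(e$p_all)
    e$p_labeled <- unlist(e$p_labeled)
    e$counts_all <- unlist(e$counts_all)
    e$counts_labeled <- unlist(e$counts_labeled)
    e
  })
  names(entries) <- vapply(entries, function(e) as.character(e$id),
                           character(1))
  structure(list(entries = entries,
                 params = as.integer(names(entries)),
                 n_residues = p$n_residues, n_labeled = p$n_labeled,
                 registry = parameter_registry(), call = NULL),
            class = "ps_model")
}

#' Information content of a parameter-score distribution
#'
#' Three measures of deviation from an equal distribution (PS = 1 in every
#' bin, the zero-information case): the mean-square deviation from 1, the
#' Gini coefficient of the PS values, and a Shannon entropy of the
#' normalized PS adapted for the bin count (1 = no information).
#'
#' @param ps numeric vector of parameter scores per bin (NAs dropped).
#' @return named vector with `msd`, `gini`, `H`.
#' @export
information_measures <- function(ps) {
  ps <- ps[!is.na(ps)]
  n <- length(ps)
  if (n < 2L) stop("need at least 2 non-missing bins")
  msd <- sum((ps - 1)^2) / n
  x <- sort(ps)
  s <- sum(x)
  cum <- cumsum(x)
  gini <- (((n - 1) / 2) * s - sum(cum[-n])) / ((n / 2) * s)
  pt <- ps / s
  nz <- pt > 0
  H <- -sum(pt[nz] * log(pt[nz])) / log(n)
  c(msd = msd, gini = gini, H = H)
}

#' Correlation between two parameters
#'
#' Selects the estimator by datatype: Pearson for numeric-numeric,
#' interclass correlation (one-way ANOVA ICC) for categorical-numeric, and
#' Cramer's V for categorical-categorical.
#'
#' @param x,y parameter value vectors (numeric or character/factor).
#' @return list with `r` and `estimator`.
#' @export
parameter_correlation <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 paired non-missing observations")
  num_x <- is.numeric(x); num_y <- is.numeric(y)
  if (num_x && num_y) {
    list(r = stats::cor(x, y), estimator = "pearson")
  } else if (!num_x && !num_y) {
    list(r = cramers_v(x, y), estimator = "cramers_v")
  } else {
    if (num_x) { tmp <- x; x <- y; y <- tmp }
    list(r = interclass_correlation(x, y), estimator = "interclass")
  }
}

#' Interclass correlation (one-way ANOVA ICC)
#'
#' @param groups categorical vector (k classes).
#' @param values numeric vector.
#' @return correlation estimate in [-1, 1].
#' @export
interclass_correlation <- function(groups, values) {
  groups <- as.character(groups)
  k <- length(unique(groups))
  if (k < 2L) stop("categorical parameter has a single category; undefined")
  n <- length(values)
  xb <- mean(values)
  ni <- tapply(values, groups, length)
  xbi <- tapply(values, groups, mean)
  mst <- sum(ni * (xbi - xb)^2) / (k - 1)
  mse <- sum((values - xbi[groups])^2) / (n - k)
  n0 <- (n - sum(ni^2) / n) / (k - 1)
  (mst - mse) / (mst + (n0 - 1) * mse)
}

#' Cramer's V association between two categorical parameters
#' @param x,y categorical vectors.
#' @return V in [0, 1].
#' @export
cramers_v <- function(x, y) {
  x <- as.character(x); y <- as.character(y)
  k <- length(unique(x)); l <- length(unique(y))
  if (k < 2L || l < 2L)
    stop("categorical parameter has a single category; undefined")
  nij <- table(x, y)
  n <- sum(nij)
  expected <- outer(rowSums(nij), colSums(nij)) / n
  chi2 <- sum((nij - expected)^2 / expected)
  sqrt(chi2 / (n * (min(k, l) - 1)))
}

#' Joined correlation of a parameter set
#'
#' Combines all unordered pairwise correlations of a parameter set into one
#' number.  Default is the 2-norm sqrt(sum r_ij^2); `literal = TRUE` uses
#' sqrt(sum r_ij) instead.
#'
#' @param r matrix of pairwise correlations (symmetric) or vector of the
#'   unordered pair values.
#' @param literal use the un-squared radicand variant.
#' @return the set correlation (scalar).
#' @export
set_correlation <- function(r, literal = FALSE) {
  if (is.matrix(r)) {
    if (nrow(r) != ncol(r)) stop("correlation matrix must be square")
    vals <- r[upper.tri(r)]
  } else vals <- r
  if (anyNA(vals)) stop("missing pairwise correlation")
  if (literal) sqrt(sum(vals)) else sqrt(sum(vals^2))
}

#' Parameter-set selection metrics
#'
#' The separation t value between labeled and background label scores, the
#' dynamic range (SD of log LS over all residues), and the
#' enhancement/suppression slope m of log(P(LS|l)/P(LS)) against log(LS)
#' fitted on logarithmic bins with edges 1.5^i, i = -12..12.
#'
#' @param ls_all label scores of all residues.
#' @param ls_labeled label scores of the labeled residues.
#' @param fit_slope also fit the log-bin enhancement slope (errors when
#'   fewer than 2 log bins are populated in both samples).
#' @return list with `t`, `dynamic_range`, `slope`, `intercept`,
#'   `n_bins_used`, `n_zero_excluded`.
#' @export
selection_metrics <- function(ls_all, ls_labeled, fit_slope = TRUE) {
  stopifnot(length(ls_all) > 1L, length(ls_labeled) > 1L)
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  tval <- (mean(ls_labeled) - mean(ls_all)) /
    sqrt(sem(ls_labeled)^2 + sem(ls_all)^2)
  pos_all <- ls_all[ls_all > 0]
  n_zero <- sum(ls_all == 0) + sum(ls_labeled == 0)
  dyn <- if (length(pos_all) > 1L) stats::sd(log(pos_all)) else 0
  if (!fit_slope)
    return(list(t = unname(tval), dynamic_range = dyn, slope = NA_real_,
                intercept = NA_real_, n_bins_used = 0L,
                n_zero_excluded = n_zero))
  edges <- 1.5^seq(-12, 12)
  h_all <- graphics::hist(pos_all[pos_all >= edges[1] &
                                    pos_all < edges[length(edges)]],
                          breaks = edges, plot = FALSE)$counts
  pos_lab <- ls_labeled[ls_labeled > 0]
  h_lab <- graphics::hist(pos_lab[pos_lab >= edges[1] &
                                    pos_lab < edges[length(edges)]],
                          breaks = edges, plot = FALSE)$counts
  p_all <- h_all / sum(h_all)
  p_lab <- h_lab / sum(h_lab)
  use <- h_all > 0 & h_lab > 0
  if (sum(use) < 2L) stop("fewer than 2 populated log bins for the fit")
  centers <- sqrt(edges[-length(edges)] * edges[-1])
  fit <- stats::lm(log(p_lab[use] / p_all[use]) ~ log(centers[use]))
  list(t = unname(tval), dynamic_range = dyn,
       slope = unname(stats::coef(fit)[2]),
       intercept = exp(unname(stats::coef(fit)[1])),
       n_bins_used = sum(use), n_zero_excluded = n_zero)
}

#' Bootstrap confidence envelopes for the labeled label-score histogram
#'
#' Fits the model on the full data, computes the label scores of the
#' labeled residues, then resamples those residues with replacement and
#' rebuilds the LS histogram per replicate; returns the 2.5/97.5 percentile
#' envelope per log bin (order statistics, so two replicates give min/max).
#'
#' @param table a `parameter_table`.
#' @param labeled logical mask (or `label_db` / keys, as in [ps_fit()]).
#' @param params parameter ids (default [default_selection()]).
#' @param n_boot number of bootstrap replicates (>= 2).
#' @param seed RNG seed.
#' @param edges histogram bin edges for LS (default 1.5-base log bins).
#' @return list with `edges`, `point` (histogram of the full labeled set),
#'   `lower`, `upper` envelopes.
#' @export
bootstrap_scores <- function(table, labeled, params = default_selection(),
                             n_boot = 400L, seed = 1L,
                             edges = 1.5^seq(-12, 12)) {
  stopifnot(n_boot >= 2L)
  if (inherits(labeled, "label_db")) labeled <- labeled_mask_from_db(table, labeled)
  if (is.character(labeled)) labeled <- table$key %in% labeled
  set.seed(seed)
  fit <- ps_fit(table, labeled, params = params)
  ls_lab <- compute_label_score(table, fit, selection = params,
                                policy = "reduce")$ls[labeled]
  ls_lab <- ls_lab[!is.na(ls_lab)]
  hist_of <- function(v) {
    v <- v[v > 0 & v >= edges[1] & v < edges[length(edges)]]
    h <- graphics::hist(v, breaks = edges, plot = FALSE)$counts
    h / max(1L, sum(h))
  }
  point <- hist_of(ls_lab)
  reps <- t(vapply(seq_len(n_boot), function(b)
    hist_of(sample(ls_lab, length(ls_lab), replace = TRUE)),
    numeric(length(point))))
  list(edges = edges, point = point,
       lower = apply(reps, 2, stats::quantile, 0.025, type = 1),
       upper = apply(reps, 2, stats::quantile, 0.975, type = 1))
}

#' ROC curve of label scores against the labeled mask
#'
#' @param scores numeric scores for all residues.
#' @param labeled logical mask (positives).
#' @return list with `fpr`, `tpr`, `auc`.
#' @export
roc_curve <- function(scores, labeled) {
  ok <- !is.na(scores)
  scores <- scores[ok]; labeled <- labeled[ok]
  if (!any(labeled) || all(labeled))
    stop("ROC needs at least one positive and one negative")
  r <- pROC::roc(response = labeled, predictor = scores,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  list(fpr = rev(1 - r$specificities), tpr = rev(r$sensitivities),
       auc = as.numeric(r$auc))
}
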