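## The combined label score: geometric mean of the selected parameter
## scores, one parameter per category, evaluated for every residue of a
## query structure.

ps_lookup <- function(entry, values) {
  if (entry$datatype == "numeric") {
    edges <- entry$edges
    out_of_range <- !is.na(values) &
      (values < edges[1] | values >= edges[length(edges)])
    if (any(out_of_range))
      warning(sum(out_of_range),
              " value(s) outside the trained range; clamped to edge bins")
    v <- pmin(pmax(values, edges[1]), edges[length(edges)] - 1e-9)
    bin <- findInterval(v, edges, rightmost.closed = TRUE)
    ps <- entry$ps[bin]
    ps[is.na(values)] <- NA
    ps
  } else {
    entry$ps[match(as.character(values), entry$labels)]
  }
}

#' Label scores for a parameter table under a trained model
#'
#' Maps each residue's parameter values to their trained PS bins and
#' combines the selected parameters (at most one per category unless
#' `allow_same_category`) by geometric mean: LS = (PS1 ... PSn)^(1/n).
#' Out-of-range numeric values clamp to the edge bins with a warning.
#'
#' Missing-value policy: `"strict"` flags the residue as failed (LS = 0)
#' when any selected parameter value or PS is missing; `"reduce"` takes
#' the geometric mean over the available parameters, recording `n_used`.
#'
#' @param table a `parameter_table`.
#' @param model a `ps_model`.
#' @param selection integer parameter ids (default [default_selection()]).
#' @param policy "strict" or "reduce".
#' @param allow_same_category allow more than one parameter per category.
#' @return data.frame with residue keys, per-parameter PS columns
#'   (`ps_NN`), `ls`, `n_used`, `failed`.
#' @export
compute_label_score <- function(table, model,
                                selection = default_selection(),
                                policy = c("strict", "reduce"),
                                allow_same_category = FALSE) {
  policy <- match.arg(policy)
  missing_train <- setdiff(as.character(selection), names(model$entries))
  if (length(missing_train))
    stop("selection references untrained parameter(s): #",
         paste(missing_train, collapse = ", #"))
  cats <- vapply(as.character(selection),
                 function(id) model$entries[[id]]$category, character(1))
  if (!allow_same_category && anyDuplicated(cats))
    stop("selection uses more than one parameter from category ",
         paste(unique(cats[duplicated(cats)]), collapse = ","),
         " (set allow_same_category = TRUE to override)")
  psm <- sapply(as.character(selection), function(id) {
    col <- param_column(as.integer(id))
    if (!col %in% names(table)) stop("parameter not in table: #", id)
    ps_lookup(model$entries[[id]], table[[col]])
  })
  psm <- matrix(psm, nrow = nrow(table),
                dimnames = list(NULL, sprintf("ps_%02d", selection)))
  n_avail <- rowSums(!is.na(psm))
  if (policy == "strict") {
    failed <- n_avail < length(selection)
    ls <- ifelse(failed, 0,
                 apply(psm, 1, function(p) exp(mean(log(pmax(p, 0)))) ))
    ls[!failed & apply(psm == 0, 1, any)] <- 0
    n_used <- ifelse(failed, 0L, length(selection))
  } else {
    failed <- n_avail == 0L
    ls <- apply(psm, 1, function(p) {
      p <- p[!is.na(p)]
      if (!length(p)) return(0)
      if (any(p == 0)) return(0)
      exp(mean(log(p)))
    })
    n_used <- n_avail
  }
  out <- data.frame(key = table$key, chain = table$chain,
                    resno = table$resno, aa = table$aa,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(psm))
  out$ls <- as.numeric(ls)
  out$n_used <- as.integer(n_used)
  out$failed <- failed
  out
}

#' Predict label scores for new residues
#'
#' @param object a `ps_model`.
#' @param newdata a `parameter_table`.
#' @param selection,policy,... passed to [compute_label_score()].
#' @return the label-score data.frame.
#' @export
predict.ps_model <- function(object, newdata,
                             selection = default_selection(),
                             policy = "strict", ...) {
  sel <- intersect(selection, object$params)
  if (!length(sel)) sel <- object$params
  compute_label_score(newdata, object, selection = sel, policy = policy, ...)
}

#' Rank residues by label score
#'
#' Descending LS, ties broken by (chain, residue number) ascending — so
#' the "best 10%" / "worst 10%" control protocols are reproducible.
#'
#' @param results label-score data.frame from [compute_label_score()].
#' @param top_fraction fraction of residues to return (1 = all).
#' @param which "top" (highest LS) or "bottom".
#' @return the ordered subset of `results`.
#' @export
rank_residues <- function(results, top_fraction = 1, which = c("top", "bottom")) {
  which <- match.arg(which)
  stopifnot(nrow(results) > 0)
  ord <- order(-results$ls, results$chain, results$resno)
  if (which == "bottom") ord <- rev(ord)
  k <- if (top_fraction >= 1) nrow(results)
    else max(0L, floor(nrow(results) * top_fraction + 1e-9))
  results[ord[seq_len(k)], , drop = FALSE]
}

#' Per-bin enrichment of labeled over background label scores
#'
#' Ratio of the normalized labeled and background LS histograms on shared
#' logarithmic bins, optionally with a bootstrap confidence band.
#'
#' @param ls_all background label scores.
#' @param ls_labeled labeled-residue label scores.
#' @param log_bins bin edges (default 1.5-base bins).
#' @param n_boot bootstrap replicates for the CI (0 = none).
#' @param seed RNG seed for the bootstrap.
#' @return data.frame with bin edges, centers, `ratio` and optionally
#'   `lower`/`upper`.
#' @export
enrichment_ratio <- function(ls_all, ls_labeled,
                             log_bins = 1.5^seq(-12, 12),
                             n_boot = 0L, seed = 1L) {
  stopifnot(length(ls_all) > 0, length(ls_labeled) > 0)
  hist_of <- function(v) {
    v <- v[!is.na(v) & v >= log_bins[1] & v < log_bins[length(log_bins)]]
    h <- graphics::hist(v, breaks = log_bins, plot = FALSE)$counts
    h / max(1L, sum(h))
  }
  p_all <- hist_of(ls_all)
  p_lab <- hist_of(ls_labeled)
  ratio <- ifelse(p_all > 0, p_lab / p_all, NA_real_)
  out <- data.frame(lo = log_bins[-length(log_bins)], hi = log_bins[-1],
                    center = sqrt(log_bins[-length(log_bins)] * log_bins[-1]),
                    p_all = p_all, p_labeled = p_lab, ratio = ratio)
  if (n_boot > 0L) {
    set.seed(seed)
    reps <- t(vapply(seq_len(n_boot), function(b) {
      r <- hist_of(sample(ls_labeled, length(ls_labeled), replace = TRUE))
      ifelse(p_all > 0, r / p_all, NA_real_)
    }, numeric(length(ratio))))
    out$lower <- apply(reps, 2, stats::quantile, 0.025, na.rm = TRUE, type = 1)
    out$upper <- apply(reps, 2, stats::quantile, 0.975, na.rm = TRUE, type = 1)
  }
  out
}
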