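# Screening-protocol validation
# -----------------------------
# ROC curves with tie grouping, trapezoidal AUC (equal to the tie-corrected
# rank-sum statistic), enrichment factors, and side-by-side protocol
# comparison.

#' ROC curve and AUC of an active/decoy ranking
#'
#' Sweeps thresholds over the unique scores (ties grouped into single curve
#' steps, producing diagonal segments). The trapezoidal area equals the
#' Mann-Whitney U statistic normalized by `n_actives * n_decoys` with ties
#' counted 1/2.
#'
#' @param scores numeric score per compound (higher = more active-like).
#' @param labels binary labels (1/TRUE = active).
#' @return object of class `roc_result`: list with `fpr`, `tpr` (non-
#'   decreasing, starting at (0,0), ending at (1,1)), `auc`, `n_actives`,
#'   `n_decoys`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  n_act <- sum(labels == 1); n_dec <- sum(labels == 0)
  if (n_act == 0 || n_dec == 0) stop("degenerate labels: both classes required")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l); fp <- cumsum(1 - l)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / n_act)
  fpr <- c(0, fp[last] / n_dec)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(fpr = fpr, tpr = tpr, auc = auc,
                 n_actives = n_act, n_decoys = n_dec),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d actives vs %d decoys)\n",
              x$auc, x$n_actives, x$n_decoys))
  invisible(x)
}

#' Rank-sum (Mann-Whitney) AUC with tie correction
#'
#' Independent of the threshold-sweep path; used to cross-check [roc_auc()].
#'
#' @inheritParams roc_auc
#' @return AUC as a scalar.
#' @export
ranksum_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n_act <- sum(labels == 1); n_dec <- sum(labels == 0)
  if (n_act == 0 || n_dec == 0) stop("degenerate labels: both classes required")
  r <- rank(scores)                 # midranks handle ties as 1/2
  (sum(r[labels == 1]) - n_act * (n_act + 1) / 2) / (n_act * n_dec)
}

#' Enrichment factor at a top fraction of the ranked library
#'
#' `(actives in top / compounds in top) / (total actives / total compounds)`.
#' Compounds tied with the score at the top-set boundary are all included.
#'
#' @inheritParams roc_auc
#' @param top_fraction fraction of the library examined, in (0, 1].
#' @return enrichment factor (1 = no enrichment).
#' @export
enrichment_factor <- function(scores, labels, top_fraction) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2) stop("degenerate labels: both classes required")
  n <- length(scores)
  n_top <- max(1L, floor(top_fraction * n))
  cutoff <- sort(scores, decreasing = TRUE)[n_top]
  top <- scores >= cutoff
  (sum(labels[top]) / sum(top)) / (sum(labels) / n)
}

#' Compare screening protocols on the same library
#'
#' @param runs named list; each element a list with `scores` and `labels`
#'   vectors named by compound (or plain vectors of identical length/order).
#' @param ef_fractions enrichment-factor fractions to report.
#' @return list with `metrics` (data.frame: run, auc, one EF column per
#'   fraction) and `auc_differences` (pairwise matrix).
#' @export
compare_protocols <- function(runs, ef_fractions = c(0.05, 0.1)) {
  stopifnot(length(runs) >= 1)
  nm <- names(runs)
  if (is.null(nm)) nm <- paste0("run", seq_along(runs))
  ids <- lapply(runs, function(r) names(r$scores))
  if (all(!vapply(ids, is.null, TRUE))) {
    ref <- sort(ids[[1]])
    for (i in seq_along(ids)) {
      if (!identical(sort(ids[[i]]), ref)) {
        diffs <- c(setdiff(ids[[i]], ref), setdiff(ref, ids[[i]]))
        stop("mismatched compound sets across runs: ",
             paste(unique(diffs), collapse = ", "))
      }
    }
  }
  metrics <- do.call(rbind, lapply(seq_along(runs), function(i) {
    r <- runs[[i]]
    row <- data.frame(run = nm[i], auc = roc_auc(r$scores, r$labels)$auc,
                      stringsAsFactors = FALSE)
    for (f in ef_fractions) {
      row[[sprintf("ef_%g", f)]] <- enrichment_factor(r$scores, r$labels, f)
    }
    row
  }))
  dmat <- outer(metrics$auc, metrics$auc, "-")
  dimnames(dmat) <- list(nm, nm)
  list(metrics = metrics, auc_differences = dmat)
}
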