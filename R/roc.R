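# AUROC estimation and comparison. The point estimate is the Mann-Whitney
# concordance (ties counted one half); the standard error is the DeLong
# variance estimator; curve comparisons use the DeLong test for paired or
# unpaired ROC curves (via pROC).

#' Area under the ROC curve with DeLong standard error
#'
#' The AUROC equals the probability that a randomly chosen case outranks a
#' randomly chosen control, ties counted one half.
#'
#' @param probabilities Numeric score vector (any monotone transform of a
#'   probability gives the same AUROC).
#' @param outcomes Binary 0/1 outcome vector, same length.
#' @param ids Optional subject identifiers, kept for paired comparisons.
#' @return An object of class `ll_roc` with `auroc`, `se`, `n_pos`, `n_neg`
#'   (and the scores/outcomes for later paired tests).
#' @export
compute_auroc <- function(probabilities, outcomes, ids = NULL) {
  stopifnot(length(probabilities) == length(outcomes),
            all(outcomes %in% c(0, 1)))
  n_pos <- sum(outcomes == 1)
  n_neg <- sum(outcomes == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("compute_auroc: need at least one case and one control;",
         " discrimination is undefined for a single-class outcome")
  if (length(unique(probabilities)) < 2) {
    # all scores tied: every case/control pair counts one half
    return(structure(list(auroc = 0.5, se = 0, n_pos = n_pos, n_neg = n_neg,
                          scores = probabilities, outcomes = outcomes,
                          ids = ids),
                     class = "ll_roc"))
  }
  r <- pROC::roc(response = outcomes, predictor = probabilities,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  v <- withCallingHandlers(
    pROC::var(r, method = "delong"),
    warning = function(w) {
      # a perfectly ranked sample legitimately has zero DeLong variance
      if (grepl("AUC == 1", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  structure(list(auroc = as.numeric(pROC::auc(r)), se = sqrt(v),
                 n_pos = n_pos, n_neg = n_neg,
                 scores = probabilities, outcomes = outcomes, ids = ids),
            class = "ll_roc")
}

#' @export
print.ll_roc <- function(x, ...) {
  cat(sprintf("<ll_roc> AUROC %.4f +/- %.4f (DeLong), %d cases / %d controls\n",
              x$auroc, x$se, x$n_pos, x$n_neg))
  invisible(x)
}

#' Compare two AUROCs (DeLong test)
#'
#' Two-sided DeLong test for the difference between two ROC curves, paired
#' (same patients scored by two models, the usual situation here) or
#' unpaired. Comparing a curve with itself yields statistic 0 and p = 1.
#'
#' @param roc_a,roc_b `ll_roc` objects from [compute_auroc()].
#' @param paired Were both scores computed on the same patients?
#' @return List of class `ll_roc_test` with `p_value`, `statistic`,
#'   `auroc_a`, `auroc_b`, `paired`.
#' @export
compare_auroc <- function(roc_a, roc_b, paired = TRUE) {
  stopifnot(inherits(roc_a, "ll_roc"), inherits(roc_b, "ll_roc"))
  if (paired) {
    if (length(roc_a$scores) != length(roc_b$scores) ||
        !identical(as.numeric(roc_a$outcomes), as.numeric(roc_b$outcomes)))
      stop("compare_auroc: paired comparison requires the same patients",
           " and outcomes")
    if (!is.null(roc_a$ids) && !is.null(roc_b$ids) &&
        !identical(roc_a$ids, roc_b$ids))
      stop("compare_auroc: paired comparison requires identical patient sets")
    if (identical(roc_a$scores, roc_b$scores))
      return(structure(list(p_value = 1, statistic = 0,
                            auroc_a = roc_a$auroc, auroc_b = roc_b$auroc,
                            paired = TRUE), class = "ll_roc_test"))
  }
  ra <- pROC::roc(roc_a$outcomes, roc_a$scores, levels = c(0, 1),
                  direction = "<", quiet = TRUE)
  rb <- pROC::roc(roc_b$outcomes, roc_b$scores, levels = c(0, 1),
                  direction = "<", quiet = TRUE)
  tt <- withCallingHandlers(
    pROC::roc.test(ra, rb, method = "delong", paired = paired),
    warning = function(w) {
      # the caller chose the pairing explicitly
      if (grepl("seem to be paired", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  structure(list(p_value = as.numeric(tt$p.value),
                 statistic = as.numeric(tt$statistic),
                 auroc_a = roc_a$auroc, auroc_b = roc_b$auroc,
                 paired = paired),
            class = "ll_roc_test")
}

#' @export
print.ll_roc_test <- function(x, ...) {
  cat(sprintf(
    "<ll_roc_test> DeLong %s: AUROC %.4f vs %.4f, statistic %.3f, p = %.4g\n",
    if (x$paired) "paired" else "unpaired", x$auroc_a, x$auroc_b,
    x$statistic, x$p_value))
  invisible(x)
}
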