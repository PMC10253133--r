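# Diagnostic agreement between pipeline core calls and reference review:
# sensitivity/specificity with exact (Clopper-Pearson) binomial confidence
# intervals and Cohen's kappa with an asymptotic Wald interval.

#' 2x2 confusion table of core calls against a reference
#'
#' Flagged and invalid pipeline calls are excluded before tabulation (they go
#' to manual review, not to the automated diagnosis); remaining cores are
#' cross-tabulated against the reference for the positive class.
#'
#' @param calls data.frame with `core_label`, `call` (pipeline output).
#' @param reference data.frame with `core_label`, `call` (reference labels;
#'   must contain every non-flagged pipeline core, no flags).
#' @param positive_class the call treated as positive (default
#'   `"MLH1DeficientTumour"`).
#' @return Object of class `confusion_table`: list `tp`, `fp`, `fn`, `tn`,
#'   `n`, `positive_class`, `n_excluded`.
#' @export
confusion <- function(calls, reference, positive_class = "MLH1DeficientTumour") {
  keep <- !calls$call %in% c("Flagged", "Invalid")
  n_excluded <- sum(!keep)
  calls <- calls[keep, , drop = FALSE]
  m <- match(calls$core_label, reference$core_label)
  if (anyNA(m))
    stop("core label(s) missing from the reference: ",
         paste(head(calls$core_label[is.na(m)], 5L), collapse = ", "),
         call. = FALSE)
  pred <- calls$call == positive_class
  truth <- reference$call[m] == positive_class
  confusion_table(tp = sum(pred & truth), fp = sum(pred & !truth),
                  fn = sum(!pred & truth), tn = sum(!pred & !truth),
                  positive_class = positive_class, n_excluded = n_excluded)
}

#' @rdname confusion
#' @param tp,fp,fn,tn non-negative integer counts.
#' @param n_excluded number of flagged/invalid cores excluded upstream.
#' @export
confusion_table <- function(tp, fp, fn, tn,
                            positive_class = "MLH1DeficientTumour",
                            n_excluded = 0L) {
  counts <- c(tp, fp, fn, tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers", call. = FALSE)
  if (sum(counts) == 0L) stop("confusion table is empty", call. = FALSE)
  structure(list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
                 tn = as.integer(tn), n = as.integer(sum(counts)),
                 positive_class = positive_class,
                 n_excluded = as.integer(n_excluded)),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("Confusion table (positive = %s), n = %d\n",
              x$positive_class, x$n))
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2L, 2L,
              dimnames = list(reference = c("positive", "negative"),
                              call = c("positive", "negative")))
  print(m)
  if (x$n_excluded > 0)
    cat(sprintf("(%d flagged/invalid core(s) excluded)\n", x$n_excluded))
  invisible(x)
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' Beta-quantile form of the exact interval: for `k` successes in `n` trials,
#' lower = `qbeta(alpha/2, k, n - k + 1)` (0 when k = 0) and upper =
#' `qbeta(1 - alpha/2, k + 1, n - k)` (1 when k = n). At k = n the lower
#' bound reduces to `(alpha/2)^(1/n)`.
#'
#' @param successes,trials counts, `0 <= successes <= trials`, `trials >= 1`.
#' @param level confidence level in percent.
#' @return Named numeric `c(lo, hi)` in percent.
#' @export
clopper_pearson <- function(successes, trials, level = 95) {
  if (trials < 1) stop("trials must be >= 1", call. = FALSE)
  if (successes < 0 || successes > trials)
    stop("successes must lie in [0, trials]", call. = FALSE)
  alpha <- 1 - level / 100
  lo <- if (successes == 0) 0 else qbeta(alpha / 2, successes, trials - successes + 1)
  hi <- if (successes == trials) 1 else qbeta(1 - alpha / 2, successes + 1,
                                              trials - successes)
  c(lo = 100 * lo, hi = 100 * hi)
}

#' Sensitivity and specificity with exact confidence intervals
#'
#' `sensitivity = tp / (tp + fn)`, `specificity = tn / (tn + fp)`, each with
#' its Clopper-Pearson interval, in percent. An empty margin leaves that
#' statistic `NA`.
#'
#' @param table a [confusion_table()].
#' @param level confidence level in percent.
#' @return List with `sensitivity` and `specificity`, each
#'   `c(estimate, lo, hi)` in percent (or `NA`s).
#' @export
sensitivity_specificity <- function(table, level = 95) {
  stopifnot(inherits(table, "confusion_table"))
  one <- function(k, n) {
    if (n == 0) return(c(estimate = NA_real_, lo = NA_real_, hi = NA_real_))
    ci <- clopper_pearson(k, n, level)
    c(estimate = 100 * k / n, lo = unname(ci["lo"]), hi = unname(ci["hi"]))
  }
  list(sensitivity = one(table$tp, table$tp + table$fn),
       specificity = one(table$tn, table$tn + table$fp))
}

#' Cohen's kappa with a Wald confidence interval
#'
#' Chance-corrected agreement of the 2x2 table:
#' `po = (tp + tn) / n`,
#' `pe = ((tp+fp)(tp+fn) + (fn+tn)(fp+tn)) / n^2`,
#' `kappa = (po - pe) / (1 - pe)`, with the asymptotic standard error
#' `SE = sqrt(po (1 - po) / (n (1 - pe)^2))` and Wald interval
#' `kappa +/- z SE`. The upper bound is deliberately not truncated at 1 (the
#' Wald interval is symmetric and may exceed it near-perfect agreement). The
#' p-value tests kappa = 0 via the Wald z statistic.
#'
#' @param table a [confusion_table()].
#' @param level confidence level in percent.
#' @return List: `kappa`, `lo`, `hi`, `se`, `z`, `p_value`.
#' @export
cohens_kappa <- function(table, level = 95) {
  stopifnot(inherits(table, "confusion_table"))
  n <- table$n
  if (n < 2) stop("need at least 2 cores for kappa", call. = FALSE)
  po <- (table$tp + table$tn) / n
  pe <- ((table$tp + table$fp) * (table$tp + table$fn) +
           (table$fn + table$tn) * (table$fp + table$tn)) / n^2
  if (abs(1 - pe) < 1e-12)
    stop("expected agreement is 1; kappa undefined", call. = FALSE)
  kappa <- (po - pe) / (1 - pe)
  se <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
  z <- stats::qnorm(1 - (1 - level / 100) / 2)
  zstat <- if (se > 0) kappa / se else Inf
  list(kappa = kappa, lo = kappa - z * se, hi = kappa + z * se, se = se,
       z = zstat, p_value = 2 * stats::pnorm(-abs(zstat)))
}

#' Full agreement report
#'
#' @param calls,reference call tables as in [confusion()]; alternatively pass
#'   a ready [confusion_table()] as `calls` (then `reference` is ignored).
#' @param positive_class positive call.
#' @param level confidence level in percent.
#' @return Object of class `agreement_report`: the confusion table plus
#'   sensitivity, specificity and kappa with intervals.
#' @export
agreement_report <- function(calls, reference = NULL,
                             positive_class = "MLH1DeficientTumour",
                             level = 95) {
  tab <- if (inherits(calls, "confusion_table")) calls
         else confusion(calls, reference, positive_class)
  ss <- sensitivity_specificity(tab, level)
  kp <- cohens_kappa(tab, level)
  structure(list(table = tab, sensitivity = ss$sensitivity,
                 specificity = ss$specificity, kappa = kp,
                 n_classified = tab$n, level = level),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  fmt <- function(v) sprintf("%.2f%% (%d%% CI %.2f, %.2f)", v[["estimate"]],
                             x$level, v[["lo"]], v[["hi"]])
  cat(sprintf("Agreement on %d classified cores (positive = %s)\n",
              x$n_classified, x$table$positive_class))
  cat("  sensitivity:", fmt(x$sensitivity), "\n")
  cat("  specificity:", fmt(x$specificity), "\n")
  cat(sprintf("  Cohen's kappa: %.3f (%d%% CI %.3f, %.3f), p %s\n",
              x$kappa$kappa, x$level, x$kappa$lo, x$kappa$hi,
              if (x$kappa$p_value < 0.001) "< 0.001"
              else sprintf("= %.3f", x$kappa$p_value)))
  invisible(x)
}

#' Reference confusion table of the MLH1 TMA validation
#'
#' The bundled 74-core validation example used throughout the documentation
#' and tests: of 99 assessable cores, 25 were flagged for review, leaving 74
#' classified; there was exactly one error, a marker-proficient tumour called
#' deficient (one false positive), and no false negatives. The reported
#' sensitivity (100%) and specificity (98.25% = 56/57) pin down the unique
#' integer table tp = 17, fp = 1, fn = 0, tn = 56.
#'
#' @return A [confusion_table()] with tp 17, fp 1, fn 0, tn 56.
#' @export
reference_confusion <- function() {
  confusion_table(tp = 17L, fp = 1L, fn = 0L, tn = 56L, n_excluded = 25L)
}
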