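#' Classify tumors as MSI-H under a panel's >= m-unstable rule
#'
#' A tumor is MSI-H when at least `panel$min_unstable` of the panel's loci
#' are called unstable; no-calls count as stable (conservative toward
#' specificity). Every (sample, panel locus) pair must be present in
#' `calls` — provide explicit no-call rows rather than dropping loci.
#'
#' @param calls Call tibble covering the panel's loci for the samples to
#'   classify.
#' @param panel An `msi_panel` (or a list with `locus_ids` and
#'   `min_unstable`).
#' @return Prediction tibble: `sample_id`, `msi_status` (`"MSI-H"` or
#'   `"MSS/MSI-L"`), `n_unstable`, `n_no_call`.
#' @export
classify_samples <- function(calls, panel) {
  loci <- panel$locus_ids
  m <- panel$min_unstable
  sub <- dplyr::filter(calls, .data$locus_id %in% loci)
  chk <- dplyr::count(sub, .data$sample_id)
  if (any(chk$n != length(loci))) {
    bad <- chk$sample_id[chk$n != length(loci)]
    abort(paste0("missing panel-locus calls for sample(s): ",
                 paste(head(bad, 5), collapse = ", "),
                 "; provide explicit no-call rows"))
  }
  sub |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_unstable = sum(.data$unstable & !.data$no_call),
      n_no_call = sum(.data$no_call),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      msi_status = ifelse(.data$n_unstable >= m, "MSI-H", "MSS/MSI-L")
    ) |>
    dplyr::select("sample_id", "msi_status", "n_unstable", "n_no_call")
}

#' Confusion-matrix diagnostics against dMMR labels
#'
#' The positive class is dMMR (label) / MSI-H (prediction). Sensitivity =
#' TP/(TP+FN), specificity = TN/(TN+FP), PPV = TP/(TP+FP), NPV =
#' TN/(TN+FN), each as a percentage. A zero denominator yields `NA` and is
#' flagged, never silently coerced to 0.
#'
#' @param predictions Prediction tibble from [classify_samples()]
#'   (`sample_id`, `msi_status`).
#' @param labels Tibble with `sample_id` and `mmr_status`
#'   (`"dMMR"`/`"pMMR"`) for every predicted sample.
#' @return An `msi_confusion` object; see [confusion_from_counts()].
#' @export
confusion_metrics <- function(predictions, labels) {
  labels <- dplyr::filter(labels, .data$mmr_status %in% c("dMMR", "pMMR"))
  j <- dplyr::inner_join(
    dplyr::select(predictions, "sample_id", "msi_status"),
    dplyr::select(labels, "sample_id", "mmr_status"),
    by = "sample_id"
  )
  if (nrow(j) != nrow(predictions)) {
    abort("every prediction must have a dMMR/pMMR label with matching sample_id")
  }
  pos_pred <- j$msi_status == "MSI-H"
  pos_lab <- j$mmr_status == "dMMR"
  confusion_from_counts(
    tp = sum(pos_pred & pos_lab), fn = sum(!pos_pred & pos_lab),
    fp = sum(pos_pred & !pos_lab), tn = sum(!pos_pred & !pos_lab)
  )
}

#' Confusion diagnostics from raw counts
#'
#' @param tp,fn,fp,tn Confusion-matrix counts (positive class =
#'   dMMR / MSI-H).
#' @return An `msi_confusion` object with the counts and `sensitivity`,
#'   `specificity`, `ppv`, `npv` as percentages (`NA` where the denominator
#'   is zero; names of the undefined metrics in `$undefined`).
#' @examples
#' confusion_from_counts(tp = 16, fn = 0, fp = 1, tn = 15)
#' @export
confusion_from_counts <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers")
  }
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  out <- list(
    tp = as.integer(tp), fn = as.integer(fn),
    fp = as.integer(fp), tn = as.integer(tn),
    sensitivity = pct(tp, tp + fn),
    specificity = pct(tn, tn + fp),
    ppv = pct(tp, tp + fp),
    npv = pct(tn, tn + fn)
  )
  out$undefined <- names(which(vapply(
    out[c("sensitivity", "specificity", "ppv", "npv")], is.na, logical(1)
  )))
  structure(out, class = "msi_confusion")
}

fmt_pct <- function(x) ifelse(is.na(x), "undefined", sprintf("%.2f%%", x))

#' @export
print.msi_confusion <- function(x, ...) {
  cat("<msi_confusion> (positive = dMMR / MSI-H)\n")
  cat(sprintf("            MSI-H  MSS/MSI-L\n"))
  cat(sprintf("  dMMR  %7d  %9d\n", x$tp, x$fn))
  cat(sprintf("  pMMR  %7d  %9d\n", x$fp, x$tn))
  cat("  sensitivity ", fmt_pct(x$sensitivity),
      "  specificity ", fmt_pct(x$specificity), "\n", sep = "")
  cat("  PPV         ", fmt_pct(x$ppv),
      "  NPV         ", fmt_pct(x$npv), "\n", sep = "")
  invisible(x)
}

#' @rdname confusion_from_counts
#' @param x An `msi_confusion`.
#' @param ... Unused.
#' @method tidy msi_confusion
#' @export
tidy.msi_confusion <- function(x, ...) {
  tibble::tibble(
    metric = c("sensitivity", "specificity", "ppv", "npv"),
    estimate = c(x$sensitivity, x$specificity, x$ppv, x$npv),
    formatted = fmt_pct(c(x$sensitivity, x$specificity, x$ppv, x$npv))
  )
}

#' @rdname confusion_from_counts
#' @method glance msi_confusion
#' @export
glance.msi_confusion <- function(x, ...) {
  tibble::tibble(
    tp = x$tp, fn = x$fn, fp = x$fp, tn = x$tn,
    sensitivity = x$sensitivity, specificity = x$specificity,
    ppv = x$ppv, npv = x$npv
  )
}
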