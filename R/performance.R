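#' Confusion matrix of binary screening calls
#'
#' @param calls logical vector of screen calls (`TRUE` = BTT-like).
#' @param truth logical vector of ground truth, same length.
#' @return A `btt_confusion` object with integer counts `tp`, `fn`,
#'   `tn`, `fp`.
#' @export
confusion_matrix <- function(calls, truth) {
  if (length(calls) != length(truth))
    stop("calls and truth differ in length (", length(calls), " vs ",
         length(truth), ")", call. = FALSE)
  if (length(calls) == 0L) stop("empty input", call. = FALSE)
  calls <- as.logical(calls); truth <- as.logical(truth)
  if (anyNA(calls) || anyNA(truth)) stop("NA in calls or truth", call. = FALSE)
  structure(list(
    tp = sum(calls & truth),
    fn = sum(!calls & truth),
    tn = sum(!calls & !truth),
    fp = sum(calls & !truth)
  ), class = "btt_confusion")
}

#' @export
print.btt_confusion <- function(x, ...) {
  cat(sprintf("<btt_confusion> TP=%d FN=%d TN=%d FP=%d\n",
              x$tp, x$fn, x$tn, x$fp))
  invisible(x)
}

.safe_ratio <- function(num, den) if (den > 0) num / den else NA_real_

#' The eight performance measures of a confusion matrix
#'
#' Sensitivity SE = TP/(TP+FN), specificity SP = TN/(TN+FP), Youden index
#' YI = SE+SP-1, single-operating-point AUC = (SE+SP)/2, accuracy,
#' positive and negative predictive values, and the false omission rate
#' FOR = FN/(TN+FN). FOR is the one cost-direction measure (lower is
#' better); the rest are benefit-direction.
#'
#' Measures whose denominator is zero are reported as `NA` and named in
#' the `undefined` attribute — never imputed as 0, which would silently
#' distort entropy weighting downstream.
#'
#' @param cm a `btt_confusion`.
#' @return A `performance_profile`: named numeric vector with elements
#'   `acc`, `se`, `sp`, `yi`, `auc`, `ppv`, `npv`, `for`, plus attribute
#'   `undefined` (character vector of NA measures) and `counts`.
#' @export
performance_profile <- function(cm) {
  stopifnot(inherits(cm, "btt_confusion"))
  se  <- .safe_ratio(cm$tp, cm$tp + cm$fn)
  sp  <- .safe_ratio(cm$tn, cm$tn + cm$fp)
  ppv <- .safe_ratio(cm$tp, cm$tp + cm$fp)
  npv <- .safe_ratio(cm$tn, cm$tn + cm$fn)
  for_ <- .safe_ratio(cm$fn, cm$tn + cm$fn)
  acc <- .safe_ratio(cm$tp + cm$tn, cm$tp + cm$tn + cm$fp + cm$fn)
  yi  <- se + sp - 1
  auc <- (se + sp) / 2
  m <- c(acc = acc, se = se, sp = sp, yi = yi, auc = auc,
         ppv = ppv, npv = npv, "for" = for_)
  structure(m, undefined = names(m)[is.na(m)], counts = cm,
            class = c("performance_profile", "numeric"))
}

#' @export
print.performance_profile <- function(x, digits = 3, ...) {
  v <- unclass(x); attributes(v) <- list(names = names(v))
  print(round(v, digits))
  und <- attr(x, "undefined")
  if (length(und) > 0L) cat("undefined:", paste(und, collapse = ", "), "\n")
  invisible(x)
}

#' Clinical utility products of a performance profile
#'
#' The positive utility SE x PPV summarises how trustworthy a positive
#' screen call is; the negative utility SP x NPV does the same for a
#' negative call.
#'
#' @param profile a `performance_profile`.
#' @return named numeric vector `c(positive = se*ppv, negative = sp*npv)`;
#'   `NA` where an input measure is undefined.
#' @export
clinical_utility <- function(profile) {
  stopifnot(inherits(profile, "performance_profile"))
  c(positive = unname(profile["se"] * profile["ppv"]),
    negative = unname(profile["sp"] * profile["npv"]))
}

#' Write a performance table as CSV
#'
#' Produces the conventional layout: one row per formula, columns ACC,
#' SE, SP, YI, AUC-ROC, PPV, NPV, FOR.
#'
#' @param table data frame as returned by [build_performance_table()].
#' @param path output file path.
#' @param digits display rounding (default 3); the returned/in-memory
#'   values are never rounded.
#' @return `path`, invisibly.
#' @export
write_performance_table <- function(table, path, digits = 3) {
  out <- table
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], round, digits = digits)
  names(out) <- sub("^acc$", "ACC", names(out))
  names(out) <- sub("^se$", "SE", names(out))
  names(out) <- sub("^sp$", "SP", names(out))
  names(out) <- sub("^yi$", "YI", names(out))
  names(out) <- sub("^auc$", "AUC-ROC", names(out))
  names(out) <- sub("^ppv$", "PPV", names(out))
  names(out) <- sub("^npv$", "NPV", names(out))
  names(out) <- sub("^for$", "FOR", names(out))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
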