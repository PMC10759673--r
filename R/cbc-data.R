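#' Construct a CBC cohort from a data frame
#'
#' Validates one hemogram record per row and returns a `cbc_cohort`: a
#' data frame carrying the seven red-cell parameters on conventional
#' clinical scales (Hb g/dL, HCT %, MCV fl, MCH pg, MCHC g/dL, RBC
#' 10^12/L, RDW %), an opaque `subject_id`, and optionally a diagnostic
#' `group` label. Rows failing validation are not dropped silently: they
#' are collected into a rejection report retrievable with [rejections()].
#'
#' A file whose HCT column is fraction-scaled (median below 1) is refused
#' outright rather than rescaled, because several indices (e.g. the
#' MCV/HCT ratio with its cut-off of 2) are only meaningful with
#' percent-scale hematocrit.
#'
#' @param x data frame with columns `hb`, `hct`, `mcv`, `mch`, `mchc`,
#'   `rbc`, `rdw`; optionally `subject_id` and `group`.
#' @return A `cbc_cohort` data frame; rejected rows are stored in
#'   `attr(, "rejections")` as a data frame with columns `row`, `reason`.
#' @seealso [read_cohort()], [write_cohort()]
#' @export
cbc_cohort <- function(x) {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(CBC_PARAMS, names(x))
  if (length(missing_cols) > 0L)
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(x) == 0L)
    stop("cohort has no data rows", call. = FALSE)

  if (!"subject_id" %in% names(x))
    x$subject_id <- sprintf("S%05d", seq_len(nrow(x)))
  x$subject_id <- as.character(x$subject_id)

  labeled <- "group" %in% names(x)
  if (labeled) {
    x$group <- as.character(x$group)
    bad_grp <- !x$group %in% CBC_GROUPS
  } else {
    bad_grp <- rep(FALSE, nrow(x))
  }

  # coerce parameter columns, tracking non-numeric cells per row
  reasons <- character(0)
  rows <- integer(0)
  vals <- matrix(NA_real_, nrow(x), length(CBC_PARAMS),
                 dimnames = list(NULL, CBC_PARAMS))
  for (p in CBC_PARAMS) {
    v <- suppressWarnings(as.numeric(x[[p]]))
    nn <- which(is.na(v) & !is.na(x[[p]]) | is.na(x[[p]]))
    vals[, p] <- v
    for (i in nn) {
      rows <- c(rows, i)
      reasons <- c(reasons, paste0("non-numeric ", p))
    }
  }

  # scale check before per-row validation: fraction-scaled HCT is a file-level
  # error, not a row-level one
  hct_ok <- vals[, "hct"][is.finite(vals[, "hct"])]
  if (length(hct_ok) > 0L && stats::median(hct_ok) < 1)
    stop("hct appears fraction-scaled (median < 1); expected percent scale ",
         "(values ~20-60). Refusing to convert automatically.", call. = FALSE)

  nonpos <- which(apply(vals, 1L, function(r) any(!is.finite(r) | r <= 0)))
  already <- unique(rows)
  for (i in setdiff(nonpos, already)) {
    bad <- CBC_PARAMS[!is.finite(vals[i, ]) | vals[i, ] <= 0]
    rows <- c(rows, i)
    reasons <- c(reasons, paste0("non-positive ", paste(bad, collapse = "/")))
  }
  for (i in which(bad_grp)) {
    rows <- c(rows, i)
    reasons <- c(reasons, paste0("unknown group '", x$group[i], "'"))
  }

  rej <- data.frame(row = rows, reason = reasons,
                    stringsAsFactors = FALSE)
  rej <- rej[!duplicated(rej$row), , drop = FALSE]
  rej <- rej[order(rej$row), , drop = FALSE]

  keep <- setdiff(seq_len(nrow(x)), rej$row)
  out <- data.frame(subject_id = x$subject_id[keep],
                    vals[keep, , drop = FALSE],
                    stringsAsFactors = FALSE)
  if (labeled) out$group <- x$group[keep]
  rownames(out) <- NULL
  structure(out, rejections = rej,
            class = c("cbc_cohort", "data.frame"))
}

#' Read a labeled or unlabeled CBC cohort from delimited text
#'
#' @param path path to a delimited text file with a header row.
#' @param dialect optional named character vector mapping the canonical
#'   column names (`hb`, `hct`, ... , `subject_id`, `group`) to the names
#'   used in the file, e.g. `c(hb = "HGB", rbc = "RBC_count")`.
#' @param delim field delimiter, default `","`.
#' @return A `cbc_cohort`; see [cbc_cohort()] for validation semantics.
#' @export
read_cohort <- function(path, dialect = NULL, delim = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, colClasses = "character",
                           check.names = FALSE)
  if (nrow(raw) == 0L) stop("empty cohort file: ", path, call. = FALSE)
  names(raw) <- tolower(names(raw))
  if (!is.null(dialect)) {
    dialect <- stats::setNames(tolower(dialect), tolower(names(dialect)))
    for (canon in names(dialect)) {
      idx <- match(dialect[[canon]], names(raw))
      if (!is.na(idx)) names(raw)[idx] <- canon
    }
  }
  if ("id" %in% names(raw) && !"subject_id" %in% names(raw))
    names(raw)[names(raw) == "id"] <- "subject_id"
  cbc_cohort(raw)
}

#' Write a cohort back to delimited text
#'
#' Inverse of [read_cohort()] for valid cohorts: writing then reading
#' reproduces the records exactly (up to numeric formatting precision).
#'
#' @param cohort a `cbc_cohort`.
#' @param path output file path.
#' @param delim field delimiter, default `","`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, delim = ",") {
  stopifnot(inherits(cohort, "cbc_cohort"))
  df <- as.data.frame(cohort)
  utils::write.table(df, path, sep = delim, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Rejection report of a cohort
#'
#' @param cohort a `cbc_cohort`.
#' @return data frame with columns `row` (1-based data-row index in the
#'   source) and `reason`.
#' @export
rejections <- function(cohort) {
  attr(cohort, "rejections") %||% data.frame(row = integer(0),
                                             reason = character(0))
}

#' Write a cohort's rejection report as CSV
#'
#' @param cohort a `cbc_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rejections <- function(cohort, path) {
  utils::write.csv(rejections(cohort), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Ground-truth screen positivity of diagnostic groups
#'
#' Maps diagnostic group labels to the binary truth used when scoring a
#' screening formula. The carrier state proper and its double-heterozygous
#' or concomitant variants (HbE-beta, BTT with iron deficiency, HbD-beta,
#' HbS-beta) count as positive; the mapping is configurable.
#'
#' @param group character vector of group labels.
#' @param positive_groups groups treated as screen-positive.
#' @return logical vector.
#' @export
is_btt_positive <- function(group, positive_groups = BTT_POSITIVE_GROUPS) {
  unknown <- setdiff(unique(group), CBC_GROUPS)
  if (length(unknown) > 0L)
    stop("unknown group label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  group %in% positive_groups
}

#' Binary truth vector of a labeled cohort
#'
#' @param cohort a labeled `cbc_cohort`.
#' @inheritParams is_btt_positive
#' @return logical vector, one element per record.
#' @export
cohort_truth <- function(cohort, positive_groups = BTT_POSITIVE_GROUPS) {
  if (!"group" %in% names(cohort))
    stop("cohort is unlabeled: performance operations need a 'group' column",
         call. = FALSE)
  is_btt_positive(cohort$group, positive_groups)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
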