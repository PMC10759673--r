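#' Bundled published performance table (35 + 7 formulae x 8 measures)
#'
#' The package ships, as plain CSV, the published performance table of
#' the 42 discriminant formulae evaluated on a 6,388-sample hospital
#' cohort (722 carrier-positive), which serves as the canonical
#' regression input for the ranking machinery: it decouples ranking
#' tests and re-analysis from any (non-public) patient-level data.
#'
#' @return data frame with columns `formula_id`, `display_name`, `acc`,
#'   `se`, `sp`, `yi`, `auc`, `ppv`, `npv`, `for`.
#' @export
reference_performance_table <- function() {
  path <- system.file("extdata", "reference_performance.csv",
                      package = "thalscreen", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Bundled published rankings of the 35 retained formulae
#'
#' The published TOPSIS / COPRAS / SECA scores and ranks corresponding to
#' [reference_performance_table()] after negative-Youden exclusion; used
#' for regression comparison.
#'
#' @return data frame keyed by `formula_id`.
#' @export
reference_ranking_table <- function() {
  path <- system.file("extdata", "reference_rankings.csv",
                      package = "thalscreen", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Per-formula performance table on a labeled cohort
#'
#' Scores every registry formula against the cohort's ground truth.
#' Composite formulae without a configured member list are skipped with a
#' warning (they cannot be evaluated on records).
#'
#' @param cohort a labeled `cbc_cohort`.
#' @param registry formula registry, default [btt_formulae()].
#' @param positive_groups groups counted as screen-positive truth.
#' @return data frame: one row per evaluated formula with the eight
#'   measures and the four confusion counts.
#' @export
build_performance_table <- function(cohort, registry = btt_formulae(),
                                    positive_groups = BTT_POSITIVE_GROUPS) {
  truth <- cohort_truth(cohort, positive_groups)
  if (!any(truth) || all(truth))
    stop("cohort must contain both positive and negative records; ",
         "got ", sum(truth), " positives of ", length(truth), call. = FALSE)
  rows <- list()
  for (spec in registry) {
    if (spec$kind == "composite" && is.null(spec$members)) {
      warning("skipping composite formula '", spec$formula_id,
              "': member list not configured", call. = FALSE)
      next
    }
    calls <- classify_record(spec, cohort, registry)
    cm <- confusion_matrix(calls, truth)
    p <- performance_profile(cm)
    rows[[spec$formula_id]] <- data.frame(
      formula_id = spec$formula_id, display_name = spec$display_name,
      t(unclass(p)[]), tp = cm$tp, fn = cm$fn, tn = cm$tn, fp = cm$fp,
      check.names = FALSE, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exclude formulae with negative Youden index
#'
#' A negative Youden index marks a worse-than-chance operating point
#' (extensively high misclassification cost); such formulae are removed
#' before ranking. The boundary YI = 0 is retained: only strictly
#' negative values are excluded.
#'
#' @param table performance table with columns `formula_id` and `yi`.
#' @return list with elements `retained` (sub-table) and `excluded`
#'   (data frame `formula_id`, `reason`).
#' @export
exclude_negative_yi <- function(table) {
  if (anyNA(table$yi)) stop("YI undefined for some formulae", call. = FALSE)
  bad <- table$yi < 0
  list(retained = table[!bad, , drop = FALSE],
       excluded = data.frame(formula_id = table$formula_id[bad],
                             reason = rep("negative Youden index", sum(bad)),
                             stringsAsFactors = FALSE))
}

#' Decision matrix from a performance table
#'
#' Columns ACC, SE, SP, YI, AUC, PPV, NPV enter as benefit criteria and
#' FOR as the single cost criterion. Formulae with an undefined (NA) or
#' non-positive measure cannot be ranked — entropy weighting and the
#' COPRAS cost ratio require strictly positive cells — and are dropped
#' with a reason recorded in the `dropped` attribute rather than imputed.
#'
#' @param table performance table (after [exclude_negative_yi()]).
#' @return A `decision_matrix`; `attr(, "dropped")` lists any formulae
#'   removed, with reasons.
#' @export
performance_decision_matrix <- function(table) {
  meas <- c("acc", "se", "sp", "yi", "auc", "ppv", "npv", "for")
  vals <- as.matrix(table[, meas])
  rownames(vals) <- table$formula_id
  bad_na <- apply(vals, 1L, anyNA)
  bad_np <- !bad_na & apply(vals, 1L, function(r) any(r <= 0))
  reason <- ifelse(bad_na, "undefined measure",
                   "non-positive measure (ranking needs strictly positive cells)")
  dropped <- data.frame(
    formula_id = rownames(vals)[bad_na | bad_np],
    reason = reason[bad_na | bad_np],
    stringsAsFactors = FALSE)
  vals <- vals[!(bad_na | bad_np), , drop = FALSE]
  dm <- decision_matrix(vals, impacts = c(rep("benefit", 7), "cost"))
  attr(dm, "dropped") <- dropped
  dm
}

#' Rank formulae with the three MCDM methods
#'
#' Runs entropy-weighted TOPSIS and COPRAS plus self-weighted SECA on a
#' performance decision matrix, and reports pairwise Spearman rank
#' correlations among the three rank vectors.
#'
#' The default conventions are those that reproduce the published
#' ranking of the 35 retained formulae (see the methods vignette):
#' TOPSIS takes entropy weights computed with cost criteria inverted,
#' COPRAS takes raw-value entropy weights and aggregates unnormalised
#' values, and SECA runs at `beta`.
#'
#' @param dm a `decision_matrix` (or performance table, which is
#'   converted).
#' @param beta SECA trade-off coefficient.
#' @param topsis_entropy_on,copras_entropy_on entropy variant per method.
#' @param copras_normalization passed to [copras()].
#' @param seed passed to [seca()].
#' @return list with `topsis`, `copras`, `seca` (`ranking_result`s),
#'   `weights` (list of the two entropy vectors), and `spearman` (named
#'   vector of the three pairwise correlations).
#' @export
rank_formulae <- function(dm, beta = 3,
                          topsis_entropy_on = "cost_inverted",
                          copras_entropy_on = "raw",
                          copras_normalization = "none",
                          seed = 1) {
  if (is.data.frame(dm)) dm <- performance_decision_matrix(dm)
  w_t <- entropy_weights(dm, on = topsis_entropy_on)
  w_c <- entropy_weights(dm, on = copras_entropy_on)
  rt <- topsis(dm, w_t)
  rc <- copras(dm, w_c, normalization = copras_normalization)
  rs <- seca(dm, beta = beta, seed = seed)
  sp <- c(topsis_copras = spearman_rho(rt$ranks, rc$ranks),
          topsis_seca = spearman_rho(rt$ranks, rs$ranks),
          copras_seca = spearman_rho(rc$ranks, rs$ranks))
  list(topsis = rt, copras = rc, seca = rs,
       weights = list(topsis = w_t, copras = w_c),
       spearman = sp)
}

#' Full evaluation report for a labeled cohort
#'
#' Orchestrates the pipeline: per-formula performance, negative-Youden
#' exclusion, decision matrix, the three rankings and their rank
#' agreement.
#'
#' @inheritParams build_performance_table
#' @inheritParams rank_formulae
#' @return list with `performance` (full table), `excluded`, `retained`,
#'   `decision_matrix`, `rankings` (as from [rank_formulae()]), and
#'   `best` / `worst` formula per measure.
#' @export
evaluate_formulae <- function(cohort, registry = btt_formulae(),
                              positive_groups = BTT_POSITIVE_GROUPS,
                              beta = 3, seed = 1) {
  perf <- build_performance_table(cohort, registry, positive_groups)
  split <- exclude_negative_yi(perf)
  dm <- performance_decision_matrix(split$retained)
  rankings <- rank_formulae(dm, beta = beta, seed = seed)
  meas <- c("acc", "se", "sp", "yi", "auc", "ppv", "npv", "for")
  best <- vapply(meas, function(m) {
    i <- if (m == "for") which.min(perf[[m]]) else which.max(perf[[m]])
    perf$formula_id[i]
  }, "")
  worst <- vapply(meas, function(m) {
    i <- if (m == "for") which.max(perf[[m]]) else which.min(perf[[m]])
    perf$formula_id[i]
  }, "")
  list(performance = perf, excluded = split$excluded,
       retained = split$retained, decision_matrix = dm,
       rankings = rankings, best = best, worst = worst)
}

#' False-negative parameter range profile
#'
#' For a formula on a labeled cohort, the range (min, max) of each of the
#' seven CBC parameters over the records the formula misses (truth
#' positive, call negative), plus the diagnostic-group breakdown of those
#' misses. Inspecting where the misses live motivates gating rules such
#' as the MCV <= 80 fl condition.
#'
#' @param cohort a labeled `cbc_cohort`.
#' @param spec formula (or id).
#' @param registry formula registry.
#' @param positive_groups groups counted as positive truth.
#' @return An `fn_range_profile`: list with `formula_id`, `fn_count`,
#'   `ranges` (7 x 2 matrix, NA when no false negatives), `groups`
#'   (table).
#' @export
fn_range_profile <- function(cohort, spec, registry = btt_formulae(),
                             positive_groups = BTT_POSITIVE_GROUPS) {
  if (is.character(spec)) spec <- get_formula(spec, registry)
  truth <- cohort_truth(cohort, positive_groups)
  calls <- classify_record(spec, cohort, registry)
  fn <- truth & !calls
  ranges <- matrix(NA_real_, length(CBC_PARAMS), 2,
                   dimnames = list(CBC_PARAMS, c("min", "max")))
  if (any(fn))
    for (p in CBC_PARAMS) ranges[p, ] <- range(cohort[[p]][fn])
  structure(list(formula_id = spec$formula_id,
                 fn_count = sum(fn),
                 ranges = ranges,
                 groups = table(cohort$group[fn])),
            class = "fn_range_profile")
}

#' @export
print.fn_range_profile <- function(x, ...) {
  cat(sprintf("<fn_range_profile> %s: %d false negative(s)\n",
              x$formula_id, x$fn_count))
  if (x$fn_count > 0) print(round(x$ranges, 2))
  invisible(x)
}

#' Two-step mass screen: MCV gate then SCS_BTT score
#'
#' The recommended screening rule: a record is referred for confirmatory
#' testing when its MCV is at most 80 fl (inclusive) *and* its SCS_BTT
#' linear score falls below the 24.99 cut-off. Records failing the gate
#' are screen-negative by default; under the `borderline_hba2` policy a
#' gated-out record with a supplied HbA2 at or below `hba2_cutoff` is
#' flagged for further examination instead, since carriers with normal
#' red-cell volume or borderline HbA2 do occur.
#'
#' @param records a `cbc_cohort` or data frame with the seven parameters
#'   (label not required); may carry an optional `hba2` column.
#' @param policy `"default"` or `"borderline_hba2"`.
#' @param mcv_gate gate threshold in fl, inclusive; default 80.
#' @param hba2_cutoff HbA2 (%) at or below which a gated-out record is
#'   sent to further examination under `borderline_hba2`.
#' @return data frame: `subject_id`, `mcv_gate` (logical), `scs_value`,
#'   `call` in `refer_confirmatory` / `screen_negative` /
#'   `further_examination`.
#' @export
two_step_screen <- function(records, policy = c("default", "borderline_hba2"),
                            mcv_gate = 80, hba2_cutoff = 4) {
  policy <- match.arg(policy)
  scs <- get_formula("scs_btt")
  vals <- evaluate_formula(scs, records)
  gate <- records$mcv <= mcv_gate
  positive <- gate & .apply_cutoff(vals, scs$comparator, scs$cutoff)
  call <- ifelse(positive, "refer_confirmatory", "screen_negative")
  if (policy == "borderline_hba2") {
    if (!"hba2" %in% names(records))
      stop("policy 'borderline_hba2' needs an 'hba2' column", call. = FALSE)
    borderline <- !gate & !is.na(records$hba2) & records$hba2 <= hba2_cutoff
    call[borderline] <- "further_examination"
  }
  data.frame(subject_id = records$subject_id %||%
               sprintf("S%05d", seq_len(nrow(records))),
             mcv_gate = gate, scs_value = vals, call = call,
             stringsAsFactors = FALSE)
}
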