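## Declarative registry of published red-cell discriminant indices.
## Expressions are stored as character arithmetic over the seven CBC
## parameter names so the registry can be exported, audited and extended
## without code changes; evaluation happens in a sealed environment that
## exposes only those seven columns (plus abs).

# one row per formula: id, display name, expression, comparator, cutoff.
# comparator is the printed cut-off symbol; the side satisfying it is
# called BTT-like. Composite entries aggregate member votes instead of an
# arithmetic expression.
.registry_table <- function() {
  tab <- rbind(
    c("sb",              "S & B",            "mch / rbc",                                   "<",  "3.8"),
    c("ef",              "E & F",            "mcv - rbc - 5 * hb",                          "<",  "0"),
    c("mentzer",         "Mentzer",          "mcv / rbc",                                   "<",  "13"),
    c("rbc",             "RBC",              "rbc",                                         ">",  "5"),
    c("shine_lal",       "S & L",            "mcv^2 * mch / 100",                           "<",  "1530"),
    c("rdw",             "RDW",              "rdw",                                         "<",  "14"),
    c("ricerca",         "Ricerca",          "rdw / rbc",                                   "<",  "4.4"),
    c("green_king",      "G & K",            "mcv^2 * rdw / (100 * hb)",                    "<",  "65"),
    c("das_gupta",       "Das Gupta",        "1.89 * rbc - 0.33 * rdw - 3.28",              ">",  "0"),
    c("telmissani_mchd", "Telmissani-MCHD",  "mch / mcv",                                   "<",  "0.34"),
    c("telmissani_mdhl", "Telmissani-MDHL",  "mch * rbc / mcv",                             ">",  "1.75"),
    c("jayabose_rdwi",   "Jayabose-RDWI",    "mcv * rdw / rbc",                             "<",  "220"),
    c("huber_herklotz",  "Huber-Herklotz",   "mch * rdw / (10 * rbc) + rdw",                "<",  "20"),
    c("sirdah",          "Sirdah",           "mcv - rbc - 3 * hb",                          "<",  "27"),
    c("kerman_1",        "Kerman-I",         "mcv * mch / rbc",                             "<",  "300"),
    c("kerman_2",        "Kerman-II",        "mcv * mch * 10 / (rbc * mchc)",               "<",  "85"),
    c("ehsani",          "Ehsani",           "mcv - 10 * rbc",                              "<",  "15"),
    c("keikhaei",        "Keikhaei",         "hb * rdw * 100 / (rbc^2 * mchc)",             ">",  "1.27"),
    c("wongprachum",     "Wongprachum",      "mcv * rdw / rbc - 10 * hb",                   "<",  "104"),
    c("nishad",          "Nishad",           "0.615 * mcv + 0.518 * mch + 0.446 * rdw",     "<",  "59"),
    c("sehgal",          "Sehgal",           "mcv^2 / rbc",                                 "<",  "972"),
    c("sargolzaie",      "Sargolzie",
      "125.6 + 44.3 * rbc - 20.9 * hb - 2.5 * mcv + 20.3 * mch - 12.18 * mchc", "<", "0.5"),
    c("pornprasert",     "Pornprasert",      "mchc",                                        "<",  "31"),
    c("sirachainan",     "Sirachainan",      "1.5 * hb - 0.05 * mcv",                       ">",  "14"),
    c("bordbar",         "Bordbar",          "abs(80 - mcv) * abs(27 - mch)",               ">",  "44.76"),
    c("hameed",          "Hameed",           "mch * hct * rdw / (rbc * hb)^2",              "<",  "220"),
    c("hisham",          "Hisham",           "mch * rdw / rbc",                             "<",  "67"),
    c("matos",           "Matos",            "1.91 * rbc + 0.44 * mchc",                    ">",  "23.85"),
    c("ravanbakhsh_f1",  "Ravanbakhsh-F1",   "mcv / hct",                                   "<",  "2"),
    c("ravanbakhsh_f2",  "Ravanbakhsh-F2",   "rdw - 3 * rbc",                               "<",  "1.5"),
    c("ravanbakhsh_f3",  "Ravanbakhsh-F3",   "mcv * rdw - 100 * rbc",                       "<",  "600"),
    c("ravanbakhsh_f4",  "Ravanbakhsh-F4",   "mcv * hb / (rdw * rbc)",                      "<",  "10"),
    c("zaghloul_1",      "Zaghloul-1",       "hb * hct + rbc",                              ">",  "52.5"),
    c("zaghloul_2",      "Zaghloul-2",       "hb * hct + rbc - rdw",                        ">",  "37.1"),
    c("kandhro_1",       "Kandhro-1",        "rbc / hct + 0.5 * rdw",                       "<",  "8.2"),
    c("kandhro_2",       "Kandhro-2",        "5 * rdw / rbc",                               "<",  "16.8"),
    c("merdin_1",        "Merdin-1",         "rdw * rbc / mcv",                             ">",  "1.27"),
    c("merdin_2",        "Merdin-2",         "rdw * rbc * hb / mcv",                        ">",  "14.7"),
    c("cruise",          "Cruise",
      "0.66 * (mch - 27.0) / 3.9 + 0.98 * mchc + 0.603 * rbc + 0.523 * rdw",   ">=", "42.63"),
    c("index26",         "Index26",          NA,                                            ">=", "16"),
    c("janel_11t",       "Janel (11T)",      NA,                                            ">=", "8"),
    c("scs_btt",         "SCS_BTT",
      "0.2815 * mcv + 0.2015 * mch - 0.2641 * rbc - 0.1693 * rdw + 0.0835 * hb", "<", "24.99")
  )
  colnames(tab) <- c("formula_id", "display_name", "expression",
                     "comparator", "cutoff")
  as.data.frame(tab, stringsAsFactors = FALSE)
}

.formula_note <- c(
  cruise = paste("Multi-line source typesetting read as a single linear",
                 "combination: 0.66(MCH-27)/3.9 + 0.98 MCHC + 0.603 RBC +",
                 "0.523 RDW, BTT-like at or above 42.63."),
  index26 = "Composite vote over 26 member indices; members must be configured.",
  janel_11t = "Composite vote over 11 member indices; members must be configured."
)

.make_formula <- function(formula_id, display_name, expression, comparator,
                          cutoff, members = NULL) {
  kind <- if (is.na(expression) || is.null(expression)) "composite" else "simple"
  structure(list(
    formula_id = formula_id,
    display_name = display_name,
    expression = if (kind == "simple") expression else NA_character_,
    comparator = comparator,
    cutoff = as.numeric(cutoff),
    kind = kind,
    members = members,
    note = unname(.formula_note[formula_id])
  ), class = "btt_formula")
}

#' The registry of 42 published discriminant formulae
#'
#' Returns the full registry of red-cell discriminant indices with their
#' published cut-offs. Each entry records the arithmetic expression over
#' the seven CBC parameters (lower-case `hb`, `hct`, `mcv`, `mch`,
#' `mchc`, `rbc`, `rdw`), the cut-off value, and the printed comparison
#' symbol; the side of the cut-off satisfying the comparison is the
#' BTT-like call. Two entries (`index26`, `janel_11t`) are composite
#' votes over member indices; their member lists are not part of the
#' registry and must be supplied via [set_composite_members()] before
#' they can be evaluated on records.
#'
#' @return A named list of `btt_formula` objects, length 42, in stable
#'   registry order.
#' @seealso [get_formula()], [evaluate_formula()], [classify_record()]
#' @export
btt_formulae <- function() {
  tab <- .registry_table()
  out <- lapply(seq_len(nrow(tab)), function(i)
    .make_formula(tab$formula_id[i], tab$display_name[i], tab$expression[i],
                  tab$comparator[i], tab$cutoff[i]))
  names(out) <- tab$formula_id
  out
}

#' Look up one formula by id
#'
#' @param formula_id registry key, e.g. `"mentzer"`, `"scs_btt"`.
#' @param registry a registry list, by default the built-in one.
#' @return A `btt_formula`.
#' @export
get_formula <- function(formula_id, registry = btt_formulae()) {
  if (!formula_id %in% names(registry))
    stop("unknown formula id: ", formula_id, call. = FALSE)
  registry[[formula_id]]
}

#' @export
print.btt_formula <- function(x, ...) {
  cat(sprintf("<btt_formula> %s (%s)\n", x$formula_id, x$display_name))
  if (x$kind == "simple") {
    cat("  expression:", x$expression, "\n")
  } else {
    nm <- if (is.null(x$members)) "<unconfigured>"
          else paste(x$members, collapse = ", ")
    cat("  composite vote over:", nm, "\n")
  }
  cat(sprintf("  BTT-like when value %s %s\n", x$comparator, x$cutoff))
  invisible(x)
}

#' Configure the member list of a composite formula
#'
#' The two composite entries aggregate votes of member indices, but their
#' member lists come from the original publications and are deliberately
#' not hard-coded; supply them explicitly.
#'
#' @param registry a registry list from [btt_formulae()].
#' @param formula_id id of a composite entry (`"index26"` or `"janel_11t"`).
#' @param members character vector of simple formula ids.
#' @return The modified registry.
#' @export
set_composite_members <- function(registry, formula_id, members) {
  spec <- get_formula(formula_id, registry)
  if (spec$kind != "composite")
    stop(formula_id, " is not a composite formula", call. = FALSE)
  missing_ids <- setdiff(members, names(registry))
  if (length(missing_ids) > 0L)
    stop("unknown member id(s): ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  if (any(vapply(registry[members], function(f) f$kind, "") != "simple"))
    stop("composite members must be simple formulae", call. = FALSE)
  spec$members <- members
  registry[[formula_id]] <- spec
  registry
}

# evaluation environment exposing only the seven parameters and abs()
.formula_env <- function(records) {
  env <- new.env(parent = baseenv())
  for (p in CBC_PARAMS) assign(p, records[[p]], envir = env)
  env
}

#' Evaluate a simple formula on records
#'
#' Computes the raw index value, with no clamping or rounding. A
#' non-finite result (division by zero slipping past validation) is an
#' error naming the offending formula.
#'
#' @param spec a `btt_formula` of kind `"simple"` (or its id).
#' @param records a `cbc_cohort` or data frame with the seven parameters.
#' @param registry registry used to resolve `spec` when given as id.
#' @return numeric vector of index values, one per record.
#' @export
evaluate_formula <- function(spec, records, registry = btt_formulae()) {
  if (is.character(spec)) spec <- get_formula(spec, registry)
  if (spec$kind != "simple")
    stop("evaluate_formula() handles simple formulae; use evaluate_composite() for ",
         spec$formula_id, call. = FALSE)
  vals <- eval(parse(text = spec$expression)[[1]], envir = .formula_env(records))
  vals <- rep_len(vals, nrow(records))  # single-parameter constants recycle
  if (any(!is.finite(vals)))
    stop("non-finite value evaluating formula '", spec$formula_id,
         "' (check for zero denominators)", call. = FALSE)
  vals
}

.apply_cutoff <- function(values, comparator, cutoff) {
  switch(comparator,
         "<"  = values <  cutoff,
         "<=" = values <= cutoff,
         ">"  = values >  cutoff,
         ">=" = values >= cutoff,
         stop("bad comparator: ", comparator, call. = FALSE))
}

#' Composite vote count
#'
#' Number of member formulae calling a record BTT-like.
#'
#' @inheritParams evaluate_formula
#' @return integer vector of vote counts, one per record.
#' @export
evaluate_composite <- function(spec, records, registry = btt_formulae()) {
  if (is.character(spec)) spec <- get_formula(spec, registry)
  if (spec$kind != "composite")
    stop(spec$formula_id, " is not a composite formula", call. = FALSE)
  if (is.null(spec$members))
    stop("composite formula '", spec$formula_id, "' has no member list ",
         "configured; supply one with set_composite_members()", call. = FALSE)
  votes <- vapply(spec$members, function(id)
    classify_record(registry[[id]], records, registry), logical(nrow(records)))
  if (nrow(records) == 1L) votes <- matrix(votes, nrow = 1L)
  as.integer(rowSums(votes))
}

#' Binary BTT call of a formula on records
#'
#' Applies the published cut-off with the printed comparison strictness:
#' a bare `<` classifies the boundary value negative.
#'
#' @inheritParams evaluate_formula
#' @return logical vector: `TRUE` = BTT-like.
#' @export
classify_record <- function(spec, records, registry = btt_formulae()) {
  if (is.character(spec)) spec <- get_formula(spec, registry)
  vals <- if (spec$kind == "simple") evaluate_formula(spec, records, registry)
          else evaluate_composite(spec, records, registry)
  .apply_cutoff(vals, spec$comparator, spec$cutoff)
}

#' Export a registry as delimited text
#'
#' One row per formula: id, display name, expression, comparator,
#' cut-off, kind. Composite member lists are serialized
#' semicolon-separated. The inverse of [read_formula_registry()].
#'
#' @param registry a registry list.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_formula_registry <- function(registry, path) {
  df <- data.frame(
    formula_id = vapply(registry, `[[`, "", "formula_id"),
    display_name = vapply(registry, `[[`, "", "display_name"),
    expression = vapply(registry, `[[`, "", "expression"),
    comparator = vapply(registry, `[[`, "", "comparator"),
    cutoff = vapply(registry, `[[`, 0, "cutoff"),
    kind = vapply(registry, `[[`, "", "kind"),
    members = vapply(registry, function(f)
      if (is.null(f$members)) "" else paste(f$members, collapse = ";"), ""),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Import a registry from delimited text
#'
#' @param path file written by [write_formula_registry()] (or hand-edited
#'   in the same layout, allowing user-defined indices without code
#'   changes).
#' @return A registry list of `btt_formula` objects.
#' @export
read_formula_registry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "NA")
  out <- lapply(seq_len(nrow(df)), function(i) {
    members <- if (!is.na(df$members[i]) && nzchar(df$members[i]))
      strsplit(df$members[i], ";", fixed = TRUE)[[1]] else NULL
    expr <- df$expression[i]
    if (is.na(expr) || !nzchar(expr)) expr <- NA_character_
    .make_formula(df$formula_id[i], df$display_name[i], expr,
                  df$comparator[i], df$cutoff[i], members = members)
  })
  names(out) <- df$formula_id
  out
}
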