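## Seeded synthetic hemogram cohorts.
##
## Group parameters (means, SDs, correlation, physiologic truncation) are
## literature-typical hematology values chosen so the generated cohort
## satisfies the qualitative orderings the analysis assumes (carriers:
## lowest Hb/MCV/MCH, highest RBC/RDW of all groups; iron deficiency the
## microcytic mimic; normals normocytic). They are NOT estimates fitted to
## any real cohort; source: non-paper defaults (see the methods vignette).

# shared 7x7 parameter correlation (hb, hct, mcv, mch, mchc, rbc, rdw);
# strong MCV-MCH coupling, negative MCV-RBC and MCV-RDW in this mix.
.default_correlation <- function() {
  p <- CBC_PARAMS
  R <- diag(7)
  dimnames(R) <- list(p, p)
  set_r <- function(a, b, v) {
    R[a, b] <<- v
    R[b, a] <<- v
  }
  set_r("hb", "hct", 0.90); set_r("hb", "mcv", 0.45); set_r("hb", "mch", 0.50)
  set_r("hb", "mchc", 0.40); set_r("hb", "rbc", 0.35); set_r("hb", "rdw", -0.35)
  set_r("hct", "mcv", 0.55); set_r("hct", "mch", 0.45); set_r("hct", "mchc", 0.15)
  set_r("hct", "rbc", 0.55); set_r("hct", "rdw", -0.30)
  set_r("mcv", "mch", 0.85); set_r("mcv", "mchc", 0.40); set_r("mcv", "rbc", -0.35)
  set_r("mcv", "rdw", -0.45)
  set_r("mch", "mchc", 0.60); set_r("mch", "rbc", -0.30); set_r("mch", "rdw", -0.45)
  set_r("mchc", "rbc", -0.10); set_r("mchc", "rdw", -0.35)
  set_r("rbc", "rdw", 0.10)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {  # clip tiny negative eigenvalues, rescale to unit diag
    es <- eigen(R, symmetric = TRUE)
    R <- es$vectors %*% diag(pmax(es$values, 1e-6)) %*% t(es$vectors)
    D <- diag(1 / sqrt(diag(R)))
    R <- D %*% R %*% D
    dimnames(R) <- list(p, p)
  }
  R
}

.default_truncation <- function() {
  cbind(lower = c(hb = 3, hct = 10, mcv = 40, mch = 10, mchc = 22,
                  rbc = 1.5, rdw = 9),
        upper = c(hb = 20, hct = 65, mcv = 130, mch = 45, mchc = 40,
                  rbc = 8.5, rdw = 30))
}

#' Construct generation parameters for one diagnostic group
#'
#' @param group group label (one of the recognised diagnostic groups).
#' @param n number of records to generate.
#' @param location named 7-vector of parameter means (`hb`, `hct`,
#'   `mcv`, `mch`, `mchc`, `rbc`, `rdw`).
#' @param scale named 7-vector of standard deviations, all positive.
#' @param correlation 7x7 positive-semidefinite correlation matrix.
#' @param truncation 7x2 matrix of physiologic bounds (`lower`, `upper`).
#' @return A `group_params` object.
#' @export
group_params <- function(group, n, location, scale,
                         correlation = .default_correlation(),
                         truncation = .default_truncation()) {
  stopifnot(group %in% CBC_GROUPS, n >= 0)
  location <- location[CBC_PARAMS]; scale <- scale[CBC_PARAMS]
  if (anyNA(location) || anyNA(scale))
    stop("location and scale must name all seven parameters", call. = FALSE)
  if (any(scale <= 0)) stop("scales must be positive", call. = FALSE)
  if (!isTRUE(all.equal(unname(diag(correlation)), rep(1, 7))))
    stop("correlation must have unit diagonal", call. = FALSE)
  if (min(eigen(correlation, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("correlation must be positive semidefinite", call. = FALSE)
  if (any(truncation[, "lower"] >= truncation[, "upper"]))
    stop("truncation bounds must be ordered", call. = FALSE)
  structure(list(group = group, n = as.integer(n), location = location,
                 scale = scale, correlation = correlation,
                 truncation = truncation),
            class = "group_params")
}

#' Default multi-group cohort parameters
#'
#' Nine diagnostic groups with counts echoing a large heterogeneous
#' hospital screening cohort (5,035 normals, 722 carrier-positives of
#' which 40 HbE-beta, 17 with concomitant iron deficiency and 4
#' HbD-beta, 194 iron deficiencies, 65 HbE, 203 sickle-cell and 169 HbD
#' traits). Locations and scales are literature-typical values (not
#' fitted to any real data) chosen to satisfy the qualitative group
#' orderings: carriers lowest in Hb, MCV, MCH and highest in RBC, RDW.
#'
#' @param scale_n multiply all group sizes by this factor (rounded),
#'   e.g. `scale_n = 0.1` for a fast small cohort.
#' @return named list of `group_params`.
#' @export
default_group_params <- function(scale_n = 1) {
  loc <- function(hb, mcv, mch, rbc, rdw) {
    hct <- mcv * rbc / 10
    c(hb = hb, hct = hct, mcv = mcv, mch = mch,
      mchc = mch / mcv * 100, rbc = rbc, rdw = rdw)
  }
  sc <- function(hb, hct, mcv, mch, mchc, rbc, rdw)
    c(hb = hb, hct = hct, mcv = mcv, mch = mch, mchc = mchc,
      rbc = rbc, rdw = rdw)
  spec <- list(
    NS      = list(n = 5035, loc = loc(13.5, 88, 29.5, 4.60, 13.0),
                   sc = sc(1.2, 3.6, 4.5, 1.8, 1.0, 0.40, 0.9)),
    BTT     = list(n =  661, loc = loc(10.2, 63, 19.5, 5.80, 17.5),
                   sc = sc(1.3, 4.0, 4.0, 1.6, 1.1, 0.55, 1.6)),
    IDA     = list(n =  194, loc = loc(10.8, 74, 23.5, 4.30, 16.5),
                   sc = sc(1.4, 4.2, 5.0, 2.0, 1.2, 0.45, 1.5)),
    HbE     = list(n =   65, loc = loc(12.0, 78, 25.0, 4.90, 14.5),
                   sc = sc(1.2, 3.8, 4.5, 1.8, 1.0, 0.45, 1.1)),
    SCT     = list(n =  203, loc = loc(12.8, 84, 27.5, 4.70, 13.8),
                   sc = sc(1.2, 3.8, 4.5, 1.8, 1.0, 0.42, 1.0)),
    HbD     = list(n =  169, loc = loc(13.0, 85, 28.0, 4.60, 13.5),
                   sc = sc(1.2, 3.8, 4.5, 1.8, 1.0, 0.42, 1.0)),
    EBeta   = list(n =   40, loc = loc(10.5, 66, 20.5, 5.50, 17.0),
                   sc = sc(1.3, 4.0, 4.2, 1.7, 1.1, 0.50, 1.5)),
    BTT_IDA = list(n =   17, loc = loc(9.8, 64, 19.8, 5.20, 18.0),
                   sc = sc(1.3, 4.0, 4.2, 1.7, 1.1, 0.50, 1.6)),
    DBeta   = list(n =    4, loc = loc(10.8, 67, 21.0, 5.40, 16.5),
                   sc = sc(1.3, 4.0, 4.2, 1.7, 1.1, 0.50, 1.5))
  )
  out <- lapply(names(spec), function(g)
    group_params(g, n = max(0L, as.integer(round(spec[[g]]$n * scale_n))),
                 location = spec[[g]]$loc, scale = spec[[g]]$sc))
  names(out) <- names(spec)
  out
}

# truncated multivariate normal: redraw out-of-bounds records
.draw_group <- function(gp, coherent) {
  n <- gp$n
  if (n == 0L)
    return(NULL)
  Sigma <- diag(gp$scale) %*% gp$correlation %*% diag(gp$scale)
  lower <- gp$truncation[, "lower"]; upper <- gp$truncation[, "upper"]
  out <- matrix(NA_real_, 0, 7)
  attempts <- 0L
  while (nrow(out) < n) {
    attempts <- attempts + 1L
    if (attempts > 1000L)
      stop("truncation bounds for group ", gp$group,
           " exclude nearly all probability mass", call. = FALSE)
    need <- n - nrow(out)
    draw <- MASS::mvrnorm(max(need, 2L), mu = gp$location, Sigma = Sigma)
    ok <- apply(draw, 1L, function(r) all(r >= lower & r <= upper))
    out <- rbind(out, draw[ok, , drop = FALSE])
  }
  out <- out[seq_len(n), , drop = FALSE]
  colnames(out) <- CBC_PARAMS
  df <- as.data.frame(out)
  if (coherent) {
    df$hct <- df$mcv * df$rbc / 10
    df$mchc <- df$mch / df$mcv * 100
  }
  df$group <- gp$group
  df
}

#' Generate a labeled synthetic cohort
#'
#' Draws each group from a truncated multivariate normal over the seven
#' CBC parameters (out-of-bounds records are redrawn). With
#' `coherent = TRUE` (default) the derived quantities are recomputed
#' from their definitions after drawing — HCT = MCV x RBC / 10,
#' MCHC = MCH / MCV x 100 — so records satisfy the analyzer identities
#' exactly.
#'
#' Per-group random streams are derived deterministically from the one
#' global seed, so the same call always yields the same cohort and
#' adding a group does not disturb the others.
#'
#' @param params list of `group_params`, e.g. [default_group_params()].
#' @param seed integer seed.
#' @param coherent recompute HCT and MCHC from their definitions.
#' @return A labeled `cbc_cohort`.
#' @export
generate_cohort <- function(params = default_group_params(), seed = 1,
                            coherent = TRUE) {
  if (!any(vapply(params, function(p) p$n, 0L) > 0L))
    stop("at least one group must have n > 0", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  group_seeds <- sample.int(.Machine$integer.max - 1L, length(params))
  pieces <- vector("list", length(params))
  for (i in seq_along(params)) {
    set.seed(group_seeds[i])
    pieces[[i]] <- .draw_group(params[[i]], coherent)
  }
  df <- do.call(rbind, pieces)
  df$subject_id <- sprintf("SYN%05d", seq_len(nrow(df)))
  cbc_cohort(df)
}

#' A deliberately separable two-class cohort
#'
#' Test helper cohort in which every positive record is guaranteed to
#' pass the two-step screen: carrier-like records with MCV in 55-75 fl
#' and an SCS_BTT value below the 24.99 cut-off (enforced by rejection
#' sampling on the linear form), and normal-like records with MCV in
#' 85-100 fl. On such a cohort the two-step screen attains sensitivity
#' 1 by construction.
#'
#' @param n_pos,n_neg class sizes, at least 1 each.
#' @param seed integer seed.
#' @return A labeled `cbc_cohort` with groups `BTT` and `NS`.
#' @export
separable_cohort <- function(n_pos, n_neg, seed = 1) {
  stopifnot(n_pos >= 1, n_neg >= 1)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  draw_pos <- function(n) {
    data.frame(hb = stats::runif(n, 8, 12), mcv = stats::runif(n, 55, 75),
               mch = stats::runif(n, 17, 24), rbc = stats::runif(n, 4.5, 6.5),
               rdw = stats::runif(n, 14, 20))
  }
  pos <- draw_pos(n_pos)
  repeat {  # guarantee the score cut-off, not just make it likely
    scs <- 0.2815 * pos$mcv + 0.2015 * pos$mch - 0.2641 * pos$rbc -
      0.1693 * pos$rdw + 0.0835 * pos$hb
    bad <- scs >= 24.99
    if (!any(bad)) break
    pos[bad, ] <- draw_pos(sum(bad))
  }
  neg <- data.frame(hb = stats::runif(n_neg, 13, 16),
                    mcv = stats::runif(n_neg, 85, 100),
                    mch = stats::runif(n_neg, 27, 33),
                    rbc = stats::runif(n_neg, 4.0, 5.2),
                    rdw = stats::runif(n_neg, 11.5, 14.5))
  df <- rbind(cbind(pos, group = "BTT"), cbind(neg, group = "NS"))
  df$hct <- df$mcv * df$rbc / 10
  df$mchc <- df$mch / df$mcv * 100
  df$subject_id <- sprintf("SEP%05d", seq_len(nrow(df)))
  cbc_cohort(df)
}
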