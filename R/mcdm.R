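#' Construct a decision matrix
#'
#' An alternatives-by-criteria grid of finite positive values with a
#' benefit/cost impact flag per criterion. For formula ranking the
#' alternatives are discriminant formulae and the criteria are the eight
#' performance measures (all benefit except the false omission rate).
#'
#' @param values numeric matrix, rownames = alternative ids, colnames =
#'   criterion ids. All cells finite and strictly positive; at least two
#'   alternatives.
#' @param impacts character vector, one of `"benefit"`/`"cost"` per
#'   criterion.
#' @return A `decision_matrix`.
#' @export
decision_matrix <- function(values, impacts) {
  values <- as.matrix(values)
  if (nrow(values) < 2L) stop("need at least 2 alternatives", call. = FALSE)
  if (ncol(values) < 1L) stop("need at least 1 criterion", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0))
    stop("decision matrix cells must be finite and strictly positive; ",
         "drop or repair undefined measures before ranking", call. = FALSE)
  if (length(impacts) != ncol(values))
    stop("one impact per criterion required", call. = FALSE)
  if (!all(impacts %in% c("benefit", "cost")))
    stop("impacts must be 'benefit' or 'cost'", call. = FALSE)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("A", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("C", seq_len(ncol(values)))
  structure(list(values = values, impacts = impacts),
            class = "decision_matrix")
}

#' @export
print.decision_matrix <- function(x, ...) {
  cat(sprintf("<decision_matrix> %d alternatives x %d criteria\n",
              nrow(x$values), ncol(x$values)))
  cat("impacts:", paste(colnames(x$values), x$impacts, sep = "=",
                        collapse = ", "), "\n")
  invisible(x)
}

# ranks with deterministic tie-break by row order
.rank_desc <- function(scores) {
  rk <- rank(-scores, ties.method = "first")
  as.integer(rk)
}

.ranking_result <- function(method, scores, intermediates, alternatives) {
  structure(list(method = method,
                 alternatives = alternatives,
                 scores = stats::setNames(scores, alternatives),
                 intermediates = intermediates,
                 ranks = stats::setNames(.rank_desc(scores), alternatives)),
            class = "ranking_result")
}

#' @export
print.ranking_result <- function(x, n = 5, ...) {
  cat(sprintf("<ranking_result> %s, %d alternatives; top %d:\n",
              x$method, length(x$scores), n))
  o <- order(x$ranks)[seq_len(min(n, length(x$ranks)))]
  print(data.frame(rank = x$ranks[o], score = round(x$scores[o], 4)))
  invisible(x)
}

#' Shannon-entropy criterion weights
#'
#' Weights each criterion by its information divergence across
#' alternatives: \eqn{p_{ij} = x_{ij}/\sum_i x_{ij}}, \eqn{e_j = -\sum_i
#' p_{ij} \ln p_{ij} / \ln m}, \eqn{d_j = 1 - e_j}, \eqn{w_j = d_j /
#' \sum_j d_j}. A near-constant criterion carries almost no weight.
#'
#' Entropy is invariant to rescaling a column but not to nonlinear
#' transforms, so the treatment of cost criteria matters. With
#' `on = "raw"` all columns enter as-is (dispersion is direction-free);
#' with `on = "cost_inverted"` cost columns enter as their reciprocals,
#' matching pipelines that normalise cost criteria as min(x)/x before
#' weighting.
#'
#' @param dm a `decision_matrix`.
#' @param on `"raw"` or `"cost_inverted"`.
#' @return numeric weight vector summing to 1.
#' @export
entropy_weights <- function(dm, on = c("raw", "cost_inverted")) {
  on <- match.arg(on)
  X <- dm$values
  if (on == "cost_inverted")
    X[, dm$impacts == "cost"] <- 1 / X[, dm$impacts == "cost", drop = FALSE]
  P <- sweep(X, 2, colSums(X), "/")
  H <- -colSums(P * log(P))
  e <- H / log(nrow(X))
  d <- 1 - e
  if (all(abs(d) < 1e-14))
    stop("no discriminating criteria: every column is constant", call. = FALSE)
  d[abs(d) < 1e-14] <- 0
  stats::setNames(d / sum(d), colnames(X))
}

.check_weights <- function(dm, w) {
  if (length(w) != ncol(dm$values))
    stop("weight length does not match criterion count", call. = FALSE)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  unname(w)
}

#' TOPSIS ranking
#'
#' Technique for Order of Preference by Similarity to Ideal Solution, in
#' the canonical vector-normalised form: \eqn{r_{ij} = x_{ij} /
#' \sqrt{\sum_i x_{ij}^2}}, \eqn{v_{ij} = w_j r_{ij}}; the ideal solution
#' takes the column maximum of \eqn{v} for benefit criteria and the
#' minimum for cost criteria (anti-ideal reversed); Euclidean distances
#' \eqn{D^+_i}, \eqn{D^-_i} to the two; closeness \eqn{C_i = D^-_i /
#' (D^+_i + D^-_i)}, ranked descending.
#'
#' @param dm a `decision_matrix`.
#' @param w criterion weights (e.g. [entropy_weights()]).
#' @return A `ranking_result` with scores = closeness coefficients and
#'   intermediates `d_pos`, `d_neg`.
#' @export
topsis <- function(dm, w) {
  w <- .check_weights(dm, w)
  X <- dm$values
  R <- sweep(X, 2, sqrt(colSums(X^2)), "/")
  V <- sweep(R, 2, w, "*")
  benefit <- dm$impacts == "benefit"
  ideal <- ifelse(benefit, apply(V, 2, max), apply(V, 2, min))
  anti  <- ifelse(benefit, apply(V, 2, min), apply(V, 2, max))
  d_pos <- sqrt(rowSums(sweep(V, 2, ideal)^2))
  d_neg <- sqrt(rowSums(sweep(V, 2, anti)^2))
  tot <- d_pos + d_neg
  degenerate <- tot == 0
  C <- ifelse(degenerate, 0.5, d_neg / ifelse(tot == 0, 1, tot))
  res <- .ranking_result("TOPSIS", C,
                         list(d_pos = d_pos, d_neg = d_neg, weights = w),
                         rownames(X))
  if (any(degenerate)) attr(res, "degenerate") <- TRUE
  res
}

#' COPRAS ranking
#'
#' Complex Proportional Assessment: weighted criterion values are split
#' into a benefit sum \eqn{S^+_i} and a cost sum \eqn{S^-_i} per
#' alternative, combined as
#' \deqn{Q_i = S^+_i + \frac{\min_k S^-_k \sum_k S^-_k}{S^-_i \sum_k
#' (\min_k S^-_k / S^-_k)}}
#' and reported as utility degrees \eqn{U_i = 100 Q_i / \max_k Q_k}
#' (exactly one alternative attains 100).
#'
#' `normalization` controls the values entering the weighted sums:
#' `"none"` uses the raw criterion values (the convention that reproduces
#' the published ranking this package re-implements), `"sum"` divides
#' each column by its total first (the textbook form). Rankings agree on
#' dominance but the Q scale differs.
#'
#' @param dm a `decision_matrix`.
#' @param w criterion weights.
#' @param normalization `"none"` or `"sum"`.
#' @return A `ranking_result` with scores = utility degrees `U` and
#'   intermediates `s_pos`, `s_neg`, `s_min_ratio`, `q`.
#' @export
copras <- function(dm, w, normalization = c("none", "sum")) {
  normalization <- match.arg(normalization)
  w <- .check_weights(dm, w)
  X <- dm$values
  if (normalization == "sum") X <- sweep(X, 2, colSums(X), "/")
  V <- sweep(X, 2, w, "*")
  benefit <- dm$impacts == "benefit"
  s_pos <- rowSums(V[, benefit, drop = FALSE])
  if (any(!benefit)) {
    s_neg <- rowSums(V[, !benefit, drop = FALSE])
    if (any(s_neg == 0))
      stop("an alternative has zero cost-criterion sum; COPRAS's cost ratio ",
           "is undefined. Shift or repair the cost column explicitly.",
           call. = FALSE)
    q <- s_pos + (min(s_neg) * sum(s_neg)) / (s_neg * sum(min(s_neg) / s_neg))
    s_min_ratio <- min(s_neg) / s_neg
  } else {
    s_neg <- rep(0, nrow(X))
    s_min_ratio <- rep(NA_real_, nrow(X))
    q <- s_pos
  }
  U <- 100 * (q / max(q))   # argmax attains exactly 100
  .ranking_result("COPRAS", U,
                  list(s_pos = s_pos, s_neg = s_neg,
                       s_min_ratio = s_min_ratio, q = q, weights = w),
                  rownames(dm$values))
}

# --- SECA -------------------------------------------------------------------

# benefit x/max, cost min/x normalisation used by the SECA model
.seca_normalize <- function(dm) {
  X <- dm$values
  R <- X
  for (j in seq_len(ncol(X)))
    R[, j] <- if (dm$impacts[j] == "benefit") X[, j] / max(X[, j])
              else min(X[, j]) / X[, j]
  R
}

# Euclidean projection of v onto {w : sum(w) = 1, w >= eps}
.project_simplex <- function(v, eps) {
  n <- length(v)
  mass <- 1 - n * eps
  if (mass < 0) stop("eps too large for criterion count", call. = FALSE)
  u <- v - eps
  us <- sort(u, decreasing = TRUE)
  css <- cumsum(us)
  rho <- max(which(us - (css - mass) / seq_len(n) > 0))
  theta <- (css[rho] - mass) / rho
  pmax(u - theta, 0) + eps
}

#' SECA ranking: simultaneous evaluation of criteria and alternatives
#'
#' SECA derives criterion weights and alternative scores together by
#' maximising, over the weight simplex, the worst alternative's overall
#' score minus a penalty pulling the weights towards two data-driven
#' reference points:
#' \deqn{\max\; \lambda_a - \beta(\lambda_b + \lambda_c)}
#' where \eqn{\lambda_a = \min_i \sum_j w_j x^N_{ij}} with the
#' benefit-\eqn{x/\max}, cost-\eqn{\min/x} normalisation \eqn{x^N},
#' \eqn{\lambda_b = \sum_j (w_j - \sigma^N_j)^2} (normalised column
#' standard deviations) and \eqn{\lambda_c = \sum_j (w_j - \pi^N_j)^2}
#' (normalised \eqn{\pi_j = \sum_l (1 - r_{jl})} from the column
#' correlation matrix), subject to \eqn{\sum w_j = 1}, \eqn{w_j \ge
#' \epsilon}. Larger `beta` anchors the weights to the reference points;
#' smaller `beta` lets the max-min term dominate.
#'
#' The objective is concave (a minimum of linear functions minus convex
#' quadratics), so the optimum is found reliably by projected gradient
#' ascent on a log-sum-exp smoothing of the minimum with a decreasing
#' temperature schedule; `restarts` additional random starting points
#' guard against flat regions. Fixed `seed` + fixed `restarts` give
#' bit-identical results.
#'
#' @param dm a `decision_matrix`.
#' @param beta trade-off coefficient, non-negative; default 3.
#' @param eps lower bound on each weight.
#' @param restarts random restarts beyond the uniform start.
#' @param seed integer seed for the restart draws.
#' @return A `ranking_result` with scores = overall alternative scores
#'   and intermediates `weights`, `objective`, `lambda_a`, `sigma_ref`,
#'   `pi_ref`, `beta`.
#' @export
seca <- function(dm, beta = 3, eps = 1e-3, restarts = 4, seed = 1) {
  if (beta < 0) stop("beta must be non-negative", call. = FALSE)
  R <- .seca_normalize(dm)
  n <- ncol(R)
  sigma <- apply(R, 2, stats::sd)
  if (all(sigma == 0)) {
    # identical criteria columns: symmetric optimum, equal weights
    w <- rep(1 / n, n)
    S <- as.vector(R %*% w)
    return(.ranking_result("SECA", S,
             list(weights = stats::setNames(w, colnames(R)),
                  objective = min(S), lambda_a = min(S),
                  sigma_ref = rep(1 / n, n), pi_ref = rep(1 / n, n),
                  beta = beta),
             rownames(dm$values)))
  }
  sigmaN <- sigma / sum(sigma)
  cr <- suppressWarnings(stats::cor(R))
  cr[is.na(cr)] <- 1  # constant column correlates with nothing; treat as aligned
  piv <- colSums(1 - cr)
  piN <- if (sum(piv) > 0) piv / sum(piv) else rep(1 / n, n)

  objective <- function(w)
    min(R %*% w) - beta * (sum((w - sigmaN)^2) + sum((w - piN)^2))

  ascend <- function(w0) {
    w <- .project_simplex(w0, eps)
    for (temp in c(1e-2, 1e-3, 1e-4, 1e-5)) {
      step <- 0.5 / (max(abs(R)) / temp + 4 * beta + 1)
      for (it in 1:4000) {
        S <- as.vector(R %*% w)
        qs <- exp(-(S - min(S)) / temp)
        qs <- qs / sum(qs)
        g <- as.vector(crossprod(R, qs)) - 2 * beta * (2 * w - sigmaN - piN)
        w_new <- .project_simplex(w + step * g, eps)
        if (max(abs(w_new - w)) < 1e-12) { w <- w_new; break }
        w <- w_new
      }
    }
    w
  }

  starts <- list(rep(1 / n, n), sigmaN, piN)
  if (restarts > 0) {
    rs <- local({
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
      replicate(restarts, {
        v <- stats::runif(n)
        v / sum(v)
      }, simplify = FALSE)
    })
    starts <- c(starts, rs)
  }
  cand <- lapply(starts, ascend)
  objs <- vapply(cand, objective, 0)
  if (all(!is.finite(objs)))
    stop("SECA solver failed to converge from any start", call. = FALSE)
  w <- cand[[which.max(objs)]]
  S <- as.vector(R %*% w)
  .ranking_result("SECA", S,
                  list(weights = stats::setNames(w, colnames(R)),
                       objective = max(objs), lambda_a = min(S),
                       sigma_ref = sigmaN, pi_ref = piN, beta = beta),
                  rownames(dm$values))
}

#' Sweep SECA's trade-off coefficient over a grid
#'
#' Runs [seca()] at each `beta` and returns all results, for studying the
#' sensitivity of the ranking to the trade-off coefficient.
#'
#' @param dm a `decision_matrix`.
#' @param betas numeric grid, default `c(0.5, 1, 2, 3, 4, 5)`.
#' @param ... passed to [seca()].
#' @return named list of `ranking_result`s, one per beta.
#' @export
seca_beta_sweep <- function(dm, betas = c(0.5, 1, 2, 3, 4, 5), ...) {
  out <- lapply(betas, function(b) seca(dm, beta = b, ...))
  names(out) <- format(betas)
  out
}

#' Spearman rank correlation of two rankings
#'
#' @param ranks_a,ranks_b numeric rank vectors of equal length (average
#'   ranks for ties are accepted).
#' @return correlation in \[-1, 1\].
#' @export
spearman_rho <- function(ranks_a, ranks_b) {
  if (length(ranks_a) != length(ranks_b))
    stop("rank vectors differ in length", call. = FALSE)
  unname(stats::cor(ranks_a, ranks_b, method = "spearman"))
}

#' Read a decision matrix from CSV
#'
#' Layout: first column = alternative id; a row with id `impact` giving
#' `benefit`/`cost` per criterion; remaining rows = values.
#'
#' @param path input CSV path.
#' @return A `decision_matrix`.
#' @export
read_decision_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- df[[1]]
  irow <- which(ids == "impact")
  if (length(irow) != 1L)
    stop("decision matrix CSV needs exactly one 'impact' row", call. = FALSE)
  impacts <- as.character(unlist(df[irow, -1]))
  vals <- as.matrix(df[-irow, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids[-irow]
  decision_matrix(vals, impacts)
}

#' Write a decision matrix to CSV
#'
#' @param dm a `decision_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_decision_matrix <- function(dm, path) {
  df <- rbind(data.frame(alternative = "impact",
                         as.list(stats::setNames(dm$impacts,
                                                 colnames(dm$values))),
                         check.names = FALSE),
              data.frame(alternative = rownames(dm$values), dm$values,
                         check.names = FALSE, row.names = NULL))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
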