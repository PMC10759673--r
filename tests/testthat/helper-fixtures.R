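# small valid cohort built in code
make_cohort_df <- function(n = 6, labeled = TRUE, seed = 7) {
  set.seed(seed)
  df <- data.frame(
    subject_id = sprintf("T%03d", seq_len(n)),
    hb = runif(n, 9, 15), hct = runif(n, 28, 45),
    mcv = runif(n, 60, 95), mch = runif(n, 18, 32),
    mchc = runif(n, 29, 35), rbc = runif(n, 3.8, 6.2),
    rdw = runif(n, 12, 19), stringsAsFactors = FALSE)
  if (labeled) df$group <- rep(c("BTT", "NS"), length.out = n)
  df
}

write_cohort_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# independent naive implementations of every simple formula, coded from
# the published expressions separately from the registry
naive_formula_values <- function(id, r) {
  with(r, switch(id,
    sb = mch / rbc,
    ef = mcv - rbc - 5 * hb,
    mentzer = mcv / rbc,
    rbc = rbc,
    shine_lal = mcv * mcv * mch / 100,
    rdw = rdw,
    ricerca = rdw / rbc,
    green_king = mcv * mcv * rdw / (100 * hb),
    das_gupta = 1.89 * rbc - 0.33 * rdw - 3.28,
    telmissani_mchd = mch / mcv,
    telmissani_mdhl = mch * rbc / mcv,
    jayabose_rdwi = mcv * rdw / rbc,
    huber_herklotz = mch * rdw / (10 * rbc) + rdw,
    sirdah = mcv - rbc - 3 * hb,
    kerman_1 = mcv * mch / rbc,
    kerman_2 = mcv * mch * 10 / (rbc * mchc),
    ehsani = mcv - 10 * rbc,
    keikhaei = hb * rdw * 100 / (rbc^2 * mchc),
    wongprachum = mcv * rdw / rbc - 10 * hb,
    nishad = 0.615 * mcv + 0.518 * mch + 0.446 * rdw,
    sehgal = mcv^2 / rbc,
    sargolzaie = 125.6 + 44.3 * rbc - 20.9 * hb - 2.5 * mcv +
      20.3 * mch - 12.18 * mchc,
    pornprasert = mchc,
    sirachainan = 1.5 * hb - 0.05 * mcv,
    bordbar = abs(80 - mcv) * abs(27 - mch),
    hameed = mch * hct * rdw / (rbc * hb)^2,
    hisham = mch * rdw / rbc,
    matos = 1.91 * rbc + 0.44 * mchc,
    ravanbakhsh_f1 = mcv / hct,
    ravanbakhsh_f2 = rdw - 3 * rbc,
    ravanbakhsh_f3 = mcv * rdw - 100 * rbc,
    ravanbakhsh_f4 = mcv * hb / (rdw * rbc),
    zaghloul_1 = hb * hct + rbc,
    zaghloul_2 = hb * hct + rbc - rdw,
    kandhro_1 = rbc / hct + 0.5 * rdw,
    kandhro_2 = 5 * rdw / rbc,
    merdin_1 = rdw * rbc / mcv,
    merdin_2 = rdw * rbc * hb / mcv,
    cruise = 0.66 * (mch - 27.0) / 3.9 + 0.98 * mchc + 0.603 * rbc +
      0.523 * rdw,
    scs_btt = 0.2815 * mcv + 0.2015 * mch - 0.2641 * rbc -
      0.1693 * rdw + 0.0835 * hb,
    stop("no naive oracle for ", id)))
}

# independent step-by-step TOPSIS (loops, no shared code path)
oracle_topsis <- function(X, impacts, w) {
  m <- nrow(X); n <- ncol(X)
  R <- matrix(0, m, n)
  for (j in 1:n) {
    nrm <- sqrt(sum(X[, j]^2))
    for (i in 1:m) R[i, j] <- X[i, j] / nrm
  }
  V <- R
  for (j in 1:n) V[, j] <- V[, j] * w[j]
  ideal <- numeric(n); anti <- numeric(n)
  for (j in 1:n) {
    if (impacts[j] == "benefit") {
      ideal[j] <- max(V[, j]); anti[j] <- min(V[, j])
    } else {
      ideal[j] <- min(V[, j]); anti[j] <- max(V[, j])
    }
  }
  dp <- dn <- numeric(m)
  for (i in 1:m) {
    dp[i] <- sqrt(sum((V[i, ] - ideal)^2))
    dn[i] <- sqrt(sum((V[i, ] - anti)^2))
  }
  ifelse(dp + dn == 0, 0.5, dn / (dp + dn))
}

# independent step-by-step COPRAS
oracle_copras <- function(X, impacts, w, normalization = "sum") {
  m <- nrow(X); n <- ncol(X)
  D <- X
  if (normalization == "sum")
    for (j in 1:n) D[, j] <- X[, j] / sum(X[, j])
  for (j in 1:n) D[, j] <- D[, j] * w[j]
  sp <- sm <- numeric(m)
  for (i in 1:m) {
    for (j in 1:n) {
      if (impacts[j] == "benefit") sp[i] <- sp[i] + D[i, j]
      else sm[i] <- sm[i] + D[i, j]
    }
  }
  if (any(impacts == "cost")) {
    q <- numeric(m)
    for (i in 1:m)
      q[i] <- sp[i] + (min(sm) * sum(sm)) / (sm[i] * sum(min(sm) / sm))
  } else q <- sp
  100 * q / max(q)
}

# SECA objective pieces, independently coded
oracle_seca_objective <- function(X, impacts, beta) {
  m <- nrow(X); n <- ncol(X)
  R <- X
  for (j in 1:n)
    R[, j] <- if (impacts[j] == "benefit") X[, j] / max(X[, j])
              else min(X[, j]) / X[, j]
  sig <- apply(R, 2, sd); sigN <- sig / sum(sig)
  cm <- suppressWarnings(cor(R)); cm[is.na(cm)] <- 1
  piv <- colSums(1 - cm); piN <- piv / sum(piv)
  function(w) min(R %*% w) - beta * (sum((w - sigN)^2) + sum((w - piN)^2))
}

# nested-grid maximization over the weight simplex (2 or 3 criteria)
oracle_seca_grid <- function(X, impacts, beta, eps = 1e-3) {
  f <- oracle_seca_objective(X, impacts, beta)
  n <- ncol(X)
  if (n == 2) {
    g <- seq(eps, 1 - eps, by = 1e-4)
    vals <- vapply(g, function(w1) f(c(w1, 1 - w1)), 0)
    best <- which.max(vals)
    list(obj = vals[best], w = c(g[best], 1 - g[best]))
  } else if (n == 3) {
    best <- NULL
    centre <- rep(1 / 3, 2); half <- 0.5
    for (step in c(0.01, 0.001, 1e-4)) {
      w1s <- seq(max(eps, centre[1] - half), min(1 - 2 * eps, centre[1] + half),
                 by = step)
      for (w1 in w1s) {
        w2s <- seq(max(eps, centre[2] - half),
                   min(1 - w1 - eps, centre[2] + half), by = step)
        w2s <- w2s[w2s >= eps & 1 - w1 - w2s >= eps]
        if (!length(w2s)) next
        vals <- vapply(w2s, function(w2) f(c(w1, w2, 1 - w1 - w2)), 0)
        k <- which.max(vals)
        if (is.null(best) || vals[k] > best$obj)
          best <- list(obj = vals[k], w = c(w1, w2s[k], 1 - w1 - w2s[k]))
      }
      centre <- best$w[1:2]; half <- step * 2
    }
    best
  } else stop("grid oracle supports 2 or 3 criteria")
}

random_decision_values <- function(m, n, seed) {
  set.seed(seed)
  matrix(runif(m * n, 0.05, 1), m, n,
         dimnames = list(paste0("a", 1:m), paste0("c", 1:n)))
}
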