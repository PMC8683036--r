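# Correlation-matrix PCA, Jolliffe method-B2 backward variable
# elimination, and the component-retention stopping-rule battery.

#' Correlation-matrix principal components analysis
#'
#' Eigen-decomposition of the sample correlation matrix of a standardized
#' feature matrix. Loadings are variable-component correlations
#' (eigenvector entries scaled by `sqrt(lambda)`); component signs are
#' canonicalized so that the largest-|loading| variable of each component
#' loads positively. Rank-deficient input yields trailing zero
#' eigenvalues, not an error.
#'
#' @param x numeric matrix (`n` vocalizations x `p` features), columns
#'   standardized.
#' @return an `ardi_pca` list: `eigenvalues`, `variance_fractions`
#'   (`lambda/p`), `loadings`, `rotation` (eigenvectors), `scores`, `n`,
#'   `p`.
#' @export
run_pca <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(p))
  if (p < 2) stop("need at least two variables")
  if (n <= p) stop("need more observations than variables")
  R <- stats::cor(x)
  eig <- eigen(R, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  vectors <- eig$vectors
  loadings <- sweep(vectors, 2, sqrt(lambda), `*`)
  # sign canonicalization: top-|loading| variable positive per component
  for (j in seq_len(p)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      vectors[, j] <- -vectors[, j]
    }
  }
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(p)))
  dimnames(vectors) <- dimnames(loadings)
  scores <- x %*% vectors
  structure(
    list(
      eigenvalues = lambda,
      variance_fractions = lambda / p,
      loadings = loadings,
      rotation = vectors,
      scores = scores,
      n = n, p = p
    ),
    class = "ardi_pca"
  )
}

#' @export
print.ardi_pca <- function(x, ...) {
  cat("<ardi_pca> n =", x$n, "| p =", x$p, "\n")
  cat(
    "eigenvalues:",
    paste(sprintf("%.3f", x$eigenvalues), collapse = ", "), "\n"
  )
  invisible(x)
}

#' Jolliffe method-B2 backward variable elimination
#'
#' Walks the principal components from the smallest eigenvalue upward;
#' for every component with `lambda < cutoff` the not-yet-eliminated
#' variable with the largest absolute loading on that component is
#' discarded, and the walk stops at the first component at or above the
#' cutoff. `mode = "single"` (default) uses one decomposition for the
#' whole walk; `mode = "iterative"` recomputes the PCA on the surviving
#' variables after each elimination.
#'
#' @param x standardized feature matrix.
#' @param cutoff eigenvalue cutoff in `(0, 1.5)`.
#' @param mode `"single"` or `"iterative"`.
#' @return a list: `trace` (data frame `step`, `component`, `eigenvalue`,
#'   `eliminated`, `abs_loading`), `retained` variable names, `mode`.
#' @export
jolliffe_b2_eliminate <- function(x, cutoff = 0.7, mode = c("single", "iterative")) {
  mode <- match.arg(mode)
  stopifnot(cutoff > 0, cutoff < 1.5)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  vars <- colnames(x)
  trace <- data.frame(
    step = integer(0), component = integer(0), eigenvalue = numeric(0),
    eliminated = character(0), abs_loading = numeric(0),
    stringsAsFactors = FALSE
  )
  if (mode == "single") {
    fit <- run_pca(x)
    eliminated <- character(0)
    step <- 0L
    for (j in rev(seq_len(fit$p))) { # smallest lambda first
      if (fit$eigenvalues[j] >= cutoff) break
      alive <- setdiff(vars, eliminated)
      if (length(alive) <= 1) stop("cutoff would eliminate all variables")
      ld <- abs(fit$loadings[alive, j])
      victim <- alive[which.max(ld)]
      step <- step + 1L
      trace <- rbind(trace, data.frame(
        step = step, component = j, eigenvalue = fit$eigenvalues[j],
        eliminated = victim, abs_loading = max(ld),
        stringsAsFactors = FALSE
      ))
      eliminated <- c(eliminated, victim)
    }
  } else {
    eliminated <- character(0)
    step <- 0L
    repeat {
      alive <- setdiff(vars, eliminated)
      if (length(alive) < 2) break
      fit <- run_pca(x[, alive, drop = FALSE])
      j <- fit$p # smallest component of the current decomposition
      if (fit$eigenvalues[j] >= cutoff) break
      ld <- abs(fit$loadings[, j])
      victim <- alive[which.max(ld)]
      step <- step + 1L
      trace <- rbind(trace, data.frame(
        step = step, component = j, eigenvalue = fit$eigenvalues[j],
        eliminated = victim, abs_loading = max(ld),
        stringsAsFactors = FALSE
      ))
      eliminated <- c(eliminated, victim)
      if (length(setdiff(vars, eliminated)) <= 1) {
        stop("cutoff would eliminate all variables")
      }
    }
  }
  list(trace = trace, retained = setdiff(vars, eliminated), mode = mode)
}

#' Threshold-based component retention rules
#'
#' Kaiser-Guttman (`lambda >= kaiser_threshold`), Jolliffe's relaxed
#' Kaiser rule (`lambda >= jolliffe_cutoff`), and cumulative variance
#' (smallest `k` whose cumulative variance fraction reaches the
#' threshold).
#'
#' @param result an `ardi_pca`.
#' @param kaiser_threshold,jolliffe_cutoff eigenvalue thresholds.
#' @param cumvar_threshold cumulative variance fraction.
#' @return data frame: `rule`, `threshold`, `retained`.
#' @export
threshold_rules <- function(result, kaiser_threshold = 1.0,
                            jolliffe_cutoff = 0.7, cumvar_threshold = 0.90) {
  lambda <- result$eigenvalues
  cumfrac <- cumsum(lambda) / sum(lambda)
  data.frame(
    rule = c("kaiser_guttman", "jolliffe_kg", "cumulative_variance"),
    threshold = c(kaiser_threshold, jolliffe_cutoff, cumvar_threshold),
    retained = c(
      sum(lambda >= kaiser_threshold),
      sum(lambda >= jolliffe_cutoff),
      which(cumfrac >= cumvar_threshold)[1]
    ),
    stringsAsFactors = FALSE
  )
}

#' Horn's parallel analysis
#'
#' Simulates `replicates` matrices of iid standard normal values with the
#' observed dimensions, takes the correlation-matrix eigenvalues of each,
#' and aggregates them per rank (mean, or 95th percentile). Retained is
#' the number of leading observed eigenvalues exceeding their rank's
#' simulated threshold (stopping at the first failure).
#'
#' @param result an `ardi_pca`, or a list with `eigenvalues`, `n`, `p`.
#' @param replicates number of simulated matrices (>= 100).
#' @param criterion `"mean"` or `"percentile95"`.
#' @param seed optional integer seed for the simulation.
#' @return list: `retained`, `thresholds` (per rank), `criterion`.
#' @export
parallel_analysis <- function(result, replicates = 1000,
                              criterion = c("mean", "percentile95"),
                              seed = NULL) {
  criterion <- match.arg(criterion)
  stopifnot(replicates >= 100)
  if (!is.null(seed)) set.seed(seed)
  n <- result$n
  p <- result$p
  lambda <- result$eigenvalues
  if (p == 1) {
    return(list(retained = 1L, thresholds = 1, criterion = criterion))
  }
  sims <- matrix(NA_real_, replicates, p)
  for (r in seq_len(replicates)) {
    z <- matrix(stats::rnorm(n * p), n, p)
    sims[r, ] <- eigen(stats::cor(z), symmetric = TRUE, only.values = TRUE)$values
  }
  thresholds <- switch(criterion,
    mean = colMeans(sims),
    percentile95 = apply(sims, 2, stats::quantile, probs = 0.95, names = FALSE)
  )
  above <- lambda > thresholds
  retained <- if (above[1]) {
    fail <- which(!above)
    if (length(fail) == 0) p else fail[1] - 1L
  } else {
    0L
  }
  list(retained = as.integer(retained), thresholds = thresholds, criterion = criterion)
}

#' Broken-stick retention rule
#'
#' Expected variance fractions under a random partition of total
#' variance: `b_k = (1/p) * sum(1/i, i = k..p)`. Retained is the number
#' of leading components whose variance fraction exceeds `b_k`, stopping
#' at the first failure.
#'
#' @param result an `ardi_pca`.
#' @return list: `retained`, `expected_fractions`.
#' @export
broken_stick <- function(result) {
  p <- result$p
  stopifnot(p >= 2)
  b <- vapply(seq_len(p), function(k) sum(1 / (k:p)) / p, numeric(1))
  frac <- result$variance_fractions
  above <- frac > b
  retained <- if (above[1]) {
    fail <- which(!above)
    if (length(fail) == 0) p else fail[1] - 1L
  } else {
    0L
  }
  list(retained = as.integer(retained), expected_fractions = b)
}

#' Velicer's minimum average partial (MAP) rule
#'
#' For `m = 0, 1, ...` the first `m` principal components are partialled
#' out of the correlation matrix and the average squared off-diagonal
#' partial correlation is recorded; retained is the `m` minimizing that
#' average. The loop stops early if the partial covariance matrix
#' develops a (near-)zero diagonal.
#'
#' @param R correlation matrix.
#' @param max_components largest `m` to evaluate (default `p - 1`).
#' @return list: `retained`, `avg_sq_partial` (named by `m`).
#' @export
velicer_map <- function(R, max_components = ncol(R) - 1) {
  R <- as.matrix(R)
  p <- ncol(R)
  eig <- eigen(R, symmetric = TRUE)
  off <- upper.tri(R)
  avg <- c("0" = mean(R[off]^2))
  for (m in seq_len(max_components)) {
    L <- eig$vectors[, seq_len(m), drop = FALSE] %*%
      diag(sqrt(pmax(eig$values[seq_len(m)], 0)), m, m)
    C <- R - tcrossprod(L)
    d <- diag(C)
    if (any(d < 1e-10)) break
    Pm <- C / sqrt(tcrossprod(d))
    avg[as.character(m)] <- mean(Pm[off]^2)
  }
  list(
    retained = as.integer(names(avg)[which.min(avg)]),
    avg_sq_partial = avg
  )
}

#' Bartlett's eigenvalue-homogeneity retention rule
#'
#' Iteratively tests whether the last `p - k` eigenvalues are equal using
#' the likelihood-ratio chi-square for eigenvalue homogeneity; retained
#' is the smallest `k` whose remainder test is non-significant.
#'
#' @param result an `ardi_pca` (needs `n`).
#' @param alpha_level significance level.
#' @return list: `retained`, `p_values` (per tested `k`).
#' @export
bartlett_retention <- function(result, alpha_level = 0.05) {
  lambda <- pmax(result$eigenvalues, .Machine$double.eps)
  n <- result$n
  p <- result$p
  pvals <- numeric(0)
  for (k in 0:(p - 2)) {
    rem <- lambda[(k + 1):p]
    q <- length(rem)
    stat <- (n - 1 - (2 * p + 5) / 6) * (q * log(mean(rem)) - sum(log(rem)))
    df <- (q + 2) * (q - 1) / 2
    pvals[as.character(k)] <- stats::pchisq(stat, df, lower.tail = FALSE)
    if (pvals[as.character(k)] >= alpha_level) {
      return(list(retained = as.integer(k), p_values = pvals))
    }
  }
  list(retained = as.integer(p - 1), p_values = pvals)
}

#' Scree and LEV elbow detection
#'
#' Locates the elbow as the index maximizing the second difference of the
#' eigenvalues (scree) or of their logarithms (LEV, log-eigenvalue
#' diagram); ties break to the smallest index. A mechanical approximation
#' of the visual judgement.
#'
#' @param result an `ardi_pca` with `p >= 3`.
#' @return list: `scree_retained`, `lev_retained`.
#' @export
scree_elbows <- function(result) {
  lambda <- result$eigenvalues
  p <- result$p
  stopifnot(p >= 3)
  elbow <- function(v) {
    d2 <- v[1:(p - 2)] - 2 * v[2:(p - 1)] + v[3:p] # at indices 2..p-1
    as.integer(which.max(d2) + 1L)
  }
  list(
    scree_retained = elbow(lambda),
    lev_retained = elbow(log(pmax(lambda, .Machine$double.eps)))
  )
}

#' Full stopping-rule battery
#'
#' Runs every retention rule on one PCA result and assembles them into a
#' single report table.
#'
#' @param result an `ardi_pca`.
#' @param config an [ardi_config()].
#' @param seed seed for the parallel-analysis simulation (defaults to the
#'   config's `rng_seed`).
#' @return data frame: `rule`, `threshold`, `retained`.
#' @export
stopping_rule_report <- function(result, config = ardi_config(), seed = config$rng_seed) {
  thr <- threshold_rules(
    result, config$kaiser_threshold,
    config$jolliffe_cutoff, config$cumvar_threshold
  )
  pa <- parallel_analysis(result, config$pa_replicates, config$pa_criterion, seed)
  bs <- broken_stick(result)
  # reconstruct the correlation matrix from the full loading matrix
  R <- tcrossprod(result$loadings)
  vm <- velicer_map(R)
  bt <- bartlett_retention(result)
  el <- scree_elbows(result)
  rbind(
    thr,
    data.frame(
      rule = c(
        "parallel_analysis", "broken_stick", "velicer_map",
        "bartlett", "scree_elbow", "lev_elbow"
      ),
      threshold = NA_real_,
      retained = c(
        pa$retained, bs$retained, vm$retained, bt$retained,
        el$scree_retained, el$lev_retained
      ),
      stringsAsFactors = FALSE
    )
  )
}

#' Attach first-component scores to an index table
#'
#' Copies the (sign-canonicalized) PC1 score of each vocalization into
#' the index table and reports the sign of the ARDI-PC1 correlation
#' rather than imposing an orientation.
#'
#' @param result an `ardi_pca` whose score rows align with the index
#'   table rows.
#' @param index_table an `index_table`.
#' @return the index table with `pc1_score` filled; the ARDI-PC1
#'   correlation is attached as attribute `ardi_pc1_correlation`.
#' @export
attach_pc1_scores <- function(result, index_table) {
  if (nrow(result$scores) != nrow(index_table)) {
    stop("PCA scores and index table have different numbers of rows")
  }
  sc <- result$scores[, 1]
  if (!is.null(rownames(result$scores))) {
    j <- match(index_table$vocalization_id, rownames(result$scores))
    if (anyNA(j)) stop("PCA score rows do not match the index table")
    sc <- sc[j]
  }
  index_table$pc1_score <- unname(sc)
  attr(index_table, "ardi_pc1_correlation") <-
    stats::cor(index_table$ardi, index_table$pc1_score)
  index_table
}
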