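# Rater aggregation, probability rescaling, standardization, and the
# inter-rater reliability statistics (mean pairwise Spearman, Cronbach's
# alpha, rater-subset agreement differences).

# panel -> vocalization x rater score matrix for one feature (NA = unscored)
panel_matrix <- function(panel, feature) {
  sub <- panel[panel$feature == feature, , drop = FALSE]
  if (nrow(sub) == 0) stop("no scores for feature: ", feature)
  vocs <- sort(unique(sub$vocalization_id))
  raters <- sort(unique(sub$rater_id))
  m <- matrix(NA_real_, length(vocs), length(raters),
    dimnames = list(vocs, raters)
  )
  m[cbind(
    match(sub$vocalization_id, vocs),
    match(sub$rater_id, raters)
  )] <- sub$score
  m
}

#' Average rater scores per vocalization
#'
#' Each vocalization x feature cell becomes the arithmetic mean of the
#' available rater scores, with the sample standard deviation across
#' raters stored alongside (0 when a single rater scored the cell).
#' Scores stay on their original scale (1--10 ordinal, raw count for
#' syllables); see [rescale_probabilities()] for the probability rescale.
#'
#' @param panel a `score_panel`.
#' @return a `feature_table` data frame: `vocalization_id`, one column per
#'   feature, and one `<feature>_sd` column per feature.
#' @export
average_raters <- function(panel) {
  if (nrow(panel) == 0) stop("empty score panel")
  feats <- intersect(ardi_features(), unique(panel$feature))
  vocs <- sort(unique(panel$vocalization_id))
  out <- data.frame(vocalization_id = vocs, stringsAsFactors = FALSE)
  for (f in feats) {
    m <- panel_matrix(panel, f)
    mu <- rowMeans(m, na.rm = TRUE)
    sdev <- apply(m, 1, function(r) {
      r <- r[!is.na(r)]
      if (length(r) < 2) 0 else stats::sd(r)
    })
    out[[f]] <- unname(mu[vocs])
    out[[paste0(f, "_sd")]] <- unname(sdev[vocs])
  }
  if (anyNA(out[feats])) {
    stop("some vocalizations have no score for a present feature")
  }
  class(out) <- c("feature_table", "data.frame")
  attr(out, "rescaled") <- FALSE
  out
}

#' Rescale ordinal features to probabilities
#'
#' Divides the five 1--10 ordinal features by 10 so they read as
#' probabilities in `[0.1, 1]`; the syllable count is left on its native
#' count scale (the index multiplies a count by a probability, so the
#' count must not be shrunk).
#'
#' @param table a `feature_table` from [average_raters()].
#' @return the table with probability-scale ordinal features.
#' @export
rescale_probabilities <- function(table) {
  if (isTRUE(attr(table, "rescaled"))) {
    stop("feature table is already on the probability scale")
  }
  for (f in intersect(bounded_features(), names(table))) {
    table[[f]] <- table[[f]] / 10
    sd_col <- paste0(f, "_sd")
    if (sd_col %in% names(table)) table[[sd_col]] <- table[[sd_col]] / 10
  }
  attr(table, "rescaled") <- TRUE
  table
}

#' Standardize a feature matrix to zero mean and unit variance
#'
#' Column-wise centering and scaling by the sample standard deviation, so
#' every feature enters the PCA with equal weight. Idempotent within
#' numerical tolerance.
#'
#' @param x a numeric matrix or a `feature_table` (its feature columns are
#'   extracted).
#' @return numeric matrix with column means 0 and sample variances 1.
#' @export
standardize_features <- function(x) {
  if (is.data.frame(x)) {
    feats <- intersect(ardi_features(), names(x))
    rn <- if ("vocalization_id" %in% names(x)) x$vocalization_id else NULL
    x <- as.matrix(x[, feats, drop = FALSE])
    rownames(x) <- rn
  }
  if (nrow(x) < 2) stop("need at least two rows to standardize")
  sds <- apply(x, 2, stats::sd)
  zero <- sds == 0 | !is.finite(sds)
  if (any(zero)) {
    stop(
      "zero-variance feature(s): ",
      paste(colnames(x)[zero], collapse = ", ")
    )
  }
  scale(x, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Mean pairwise inter-rater rank correlation
#'
#' For one feature, computes the Spearman correlation (midranks for ties)
#' between every pair of raters over their pairwise-complete
#' vocalizations and returns the mean across pairs. Pairs sharing fewer
#' than `min_shared` vocalizations are skipped with a warning.
#'
#' @param panel a `score_panel`.
#' @param feature a canonical feature name.
#' @param min_shared minimum shared vocalizations per rater pair.
#' @return list with `mean_rho`, `pair_rho` (named vector), `n_pairs`.
#' @export
pairwise_intercoder_correlation <- function(panel, feature, min_shared = 3) {
  m <- panel_matrix(panel, feature)
  raters <- colnames(m)
  if (length(raters) < 2) stop("need at least two raters")
  pairs <- utils::combn(raters, 2, simplify = FALSE)
  rho <- numeric(0)
  skipped <- 0L
  for (pr in pairs) {
    a <- m[, pr[1]]
    b <- m[, pr[2]]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < min_shared) {
      skipped <- skipped + 1L
      next
    }
    r <- stats::cor(a[ok], b[ok], method = "spearman")
    rho[paste(pr, collapse = "~")] <- r
  }
  if (skipped > 0) {
    warning(skipped, " rater pair(s) skipped: fewer than ", min_shared,
      " shared vocalizations",
      call. = FALSE
    )
  }
  if (length(rho) == 0) stop("all rater pairs skipped")
  list(mean_rho = mean(rho), pair_rho = rho, n_pairs = length(rho))
}

#' Cronbach's alpha across raters
#'
#' Raters are treated as items and vocalizations as observations
#' (complete cases only): `alpha = k/(k-1) * (1 - sum(var_i)/var_total)`
#' with sample variances, `var_i` the variance of rater i's scores and
#' `var_total` the variance of the per-vocalization rater sum.
#'
#' @param panel a `score_panel`.
#' @param feature a canonical feature name.
#' @return list with `alpha` (NA when undefined), `status` (`"ok"` or
#'   `"undefined"`), `k` raters, `n` complete vocalizations.
#' @export
cronbach_alpha <- function(panel, feature) {
  m <- panel_matrix(panel, feature)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  k <- ncol(m)
  n <- nrow(m)
  if (k < 2) stop("need at least two raters")
  if (n < 3) stop("need at least three complete vocalizations")
  item_var <- apply(m, 2, stats::var)
  total_var <- stats::var(rowSums(m))
  if (total_var <= 0) {
    return(list(alpha = NA_real_, status = "undefined", k = k, n = n))
  }
  alpha <- k / (k - 1) * (1 - sum(item_var) / total_var)
  list(alpha = alpha, status = "ok", k = k, n = n)
}

#' Mean differences between disjoint rater-subset averages
#'
#' For every vocalization and every disjoint pair of rater subsets of
#' sizes `size_a` and `size_b`, computes `|mean(subset A) - mean(subset
#' B)|`. Comparing the (1,1) and (2,3) splits shows how aggregation
#' shrinks scoring disagreement.
#'
#' @param panel a `score_panel`.
#' @param feature a canonical feature name.
#' @param size_a,size_b subset sizes; their sum must not exceed the
#'   number of raters.
#' @return list with `differences` (data frame `vocalization_id`,
#'   `subset_a`, `subset_b`, `abs_diff`) and `mean_abs_diff`.
#' @export
subset_mean_differences <- function(panel, feature, size_a, size_b) {
  m <- panel_matrix(panel, feature)
  raters <- colnames(m)
  if (size_a + size_b > length(raters)) {
    stop("subset sizes exceed the number of raters")
  }
  splits <- list()
  subs_a <- utils::combn(raters, size_a, simplify = FALSE)
  for (a in subs_a) {
    rest <- setdiff(raters, a)
    subs_b <- utils::combn(rest, size_b, simplify = FALSE)
    for (b in subs_b) {
      if (size_a == size_b && paste(a, collapse = ",") > paste(b, collapse = ",")) {
        next # unordered pair: keep one orientation
      }
      splits[[length(splits) + 1L]] <- list(a = a, b = b)
    }
  }
  rows <- lapply(splits, function(s) {
    ma <- rowMeans(m[, s$a, drop = FALSE], na.rm = TRUE)
    mb <- rowMeans(m[, s$b, drop = FALSE], na.rm = TRUE)
    data.frame(
      vocalization_id = rownames(m),
      subset_a = paste(s$a, collapse = "+"),
      subset_b = paste(s$b, collapse = "+"),
      abs_diff = abs(ma - mb),
      stringsAsFactors = FALSE
    )
  })
  differences <- do.call(rbind, rows)
  differences <- differences[is.finite(differences$abs_diff), , drop = FALSE]
  rownames(differences) <- NULL
  list(
    differences = differences,
    mean_abs_diff = mean(differences$abs_diff)
  )
}

#' Per-feature reliability report
#'
#' Mean pairwise Spearman correlation and Cronbach's alpha for every
#' feature present in the panel.
#'
#' @param panel a `score_panel`.
#' @param min_shared passed to [pairwise_intercoder_correlation()].
#' @return data frame: `feature`, `mean_rho`, `alpha`, `n_pairs`.
#' @export
reliability_report <- function(panel, min_shared = 3) {
  feats <- intersect(ardi_features(), unique(panel$feature))
  rows <- lapply(feats, function(f) {
    rho <- pairwise_intercoder_correlation(panel, f, min_shared)
    ca <- cronbach_alpha(panel, f)
    data.frame(
      feature = f, mean_rho = rho$mean_rho, alpha = ca$alpha,
      n_pairs = rho$n_pairs, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
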