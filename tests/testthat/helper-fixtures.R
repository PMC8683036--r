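# In-code fixtures: small score panels and independent oracles used
# across the test files.

# long-format panel from a vocalization x rater score matrix (one feature)
panel_from_matrix <- function(m, feature = "tone",
                              voc_ids = sprintf("v%02d", seq_len(nrow(m))),
                              raters = sprintf("r%d", seq_len(ncol(m)))) {
  df <- expand.grid(
    row = seq_len(nrow(m)), col = seq_len(ncol(m)),
    stringsAsFactors = FALSE
  )
  as_score_panel(data.frame(
    vocalization_id = voc_ids[df$row],
    feature = feature,
    rater_id = raters[df$col],
    score = m[cbind(df$row, df$col)],
    stringsAsFactors = FALSE
  ))
}

# complete panel: every vocalization x all six features x each rater
full_panel <- function(n_voc = 2, n_raters = 5, seed = 1) {
  set.seed(seed)
  rows <- expand.grid(
    vocalization_id = sprintf("v%02d", seq_len(n_voc)),
    feature = ardi_features(),
    rater_id = sprintf("r%d", seq_len(n_raters)),
    stringsAsFactors = FALSE
  )
  rows$score <- ifelse(
    rows$feature == "syllables",
    sample(0:8, nrow(rows), replace = TRUE),
    sample(1:10, nrow(rows), replace = TRUE)
  )
  as_score_panel(rows)
}

# independent Cronbach oracle: covariance-matrix identity
# alpha = k/(k-1) * (1 - tr(C)/sum(C)), C = rater covariance matrix
oracle_alpha <- function(m) {
  C <- stats::cov(m)
  k <- ncol(m)
  k / (k - 1) * (1 - sum(diag(C)) / sum(C))
}

# independent eigenvalue oracle for 3x3 symmetric matrices: roots of the
# characteristic polynomial det(R - lambda I) found with polyroot()
oracle_eigen3 <- function(R) {
  stopifnot(nrow(R) == 3, ncol(R) == 3)
  a <- R[1, 1]; b <- R[1, 2]; c <- R[1, 3]
  d <- R[2, 2]; e <- R[2, 3]; f <- R[3, 3]
  # det(R - xI) = -x^3 + tr x^2 - m2 x + det
  tr <- a + d + f
  m2 <- (a * d - b^2) + (a * f - c^2) + (d * f - e^2)
  dt <- a * (d * f - e^2) - b * (b * f - c * e) + c * (b * e - c * d)
  roots <- polyroot(c(dt, -m2, tr, -1))
  sort(Re(roots), decreasing = TRUE)
}

# exhaustive rank-sum enumeration: all C(n, n1) assignments of the
# pooled midranks to group a
oracle_ranksum <- function(a, b, alternative = "two.sided") {
  n1 <- length(a)
  rk <- rank(c(a, b))
  obs <- sum(rk[seq_len(n1)])
  sums <- apply(utils::combn(length(rk), n1), 2, function(idx) sum(rk[idx]))
  p_le <- mean(sums <= obs + 1e-9)
  p_ge <- mean(sums >= obs - 1e-9)
  switch(alternative,
    less = p_le,
    greater = p_ge,
    two.sided = min(1, 2 * min(p_le, p_ge))
  )
}
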