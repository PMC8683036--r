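test_that("PCA eigen-structure identities hold on random matrices", {
  set.seed(21)
  for (i in 1:10) {
    x <- standardize_features(matrix(rnorm(40 * 5), 40, 5))
    fit <- run_pca(x)
    expect_lt(abs(sum(fit$eigenvalues) - 5), 1e-9)
    # per-variable communalities sum to 1, per-component to lambda
    expect_lt(max(abs(rowSums(fit$loadings^2) - 1)), 1e-9)
    expect_lt(max(abs(colSums(fit$loadings^2) - fit$eigenvalues)), 1e-9)
    expect_true(all(diff(fit$eigenvalues) <= 1e-12))
    # sign convention: strongest loading positive in every component
    for (j in 1:5) {
      expect_gte(fit$loadings[which.max(abs(fit$loadings[, j])), j], 0)
    }
  }
})

test_that("PCA recovers degenerate correlation structures", {
  set.seed(22)
  n <- 5000
  x <- matrix(rnorm(n * 6), n, 6)
  fit <- run_pca(standardize_features(x))
  expect_true(all(abs(fit$eigenvalues - 1) < 0.2)) # near-identity correlation
  y <- rnorm(n)
  two <- standardize_features(cbind(y, y + 1e-8 * rnorm(n)))
  fit2 <- run_pca(two)
  expect_equal(fit2$eigenvalues[1], 2, tolerance = 1e-3)
  expect_lt(fit2$eigenvalues[2], 1e-3)
})

test_that("PCA eigenvalues match the characteristic-polynomial oracle", {
  set.seed(23)
  grid <- expand.grid(r12 = c(-0.6, 0, 0.4), r13 = c(-0.3, 0.2), r23 = c(0, 0.5))
  for (i in seq_len(nrow(grid))) {
    R <- diag(3)
    R[1, 2] <- R[2, 1] <- grid$r12[i]
    R[1, 3] <- R[3, 1] <- grid$r13[i]
    R[2, 3] <- R[3, 2] <- grid$r23[i]
    if (min(eigen(R, only.values = TRUE)$values) <= 0.01) next
    # draw data near this correlation structure via its square root
    ev <- eigen(R)
    x <- matrix(rnorm(600 * 3), 600, 3)
    x <- x %*% (ev$vectors %*% diag(sqrt(ev$values)) %*% t(ev$vectors))
    fit <- run_pca(standardize_features(x))
    Rhat <- cor(standardize_features(x))
    expect_equal(fit$eigenvalues, oracle_eigen3(Rhat), tolerance = 1e-8)
  }
})

test_that("B2 elimination removes one variable per redundant pair", {
  set.seed(24)
  n <- 800
  a <- rnorm(n); b <- rnorm(n)
  x <- cbind(
    p1 = a, p2 = a + 0.3 * rnorm(n), # tight pair 1
    q1 = b, q2 = b + 0.3 * rnorm(n) # tight pair 2
  )
  res <- jolliffe_b2_eliminate(standardize_features(x), cutoff = 0.7)
  expect_equal(length(res$trace$eliminated), 2)
  expect_equal(sum(res$trace$eliminated %in% c("p1", "p2")), 1)
  expect_equal(sum(res$trace$eliminated %in% c("q1", "q2")), 1)
  # orthogonal variables: nothing to eliminate
  z <- standardize_features(matrix(rnorm(4000 * 4), 4000, 4))
  expect_equal(nrow(jolliffe_b2_eliminate(z, 0.7)$trace), 0)
  expect_equal(length(jolliffe_b2_eliminate(z, 0.7)$retained), 4)
  # iterative mode agrees on this clean structure
  it <- jolliffe_b2_eliminate(standardize_features(x), 0.7, mode = "iterative")
  expect_equal(sum(it$trace$eliminated %in% c("p1", "p2")), 1)
  expect_equal(sum(it$trace$eliminated %in% c("q1", "q2")), 1)
})

test_that("threshold rules count retained components correctly", {
  lam <- c(2.56, 1.30, 6 * 0.138, 6 * 0.117, 0.49, 0.13)
  fake <- list(eigenvalues = lam, variance_fractions = lam / 6, n = 832, p = 6)
  rules <- threshold_rules(fake, 1.0, 0.7, 0.90)
  expect_equal(rules$retained[rules$rule == "kaiser_guttman"], 2)
  expect_equal(rules$retained[rules$rule == "jolliffe_kg"], 4)
  lam2 <- c(4, 0, 0, 0)
  fake2 <- list(eigenvalues = lam2, variance_fractions = lam2 / 4, n = 100, p = 4)
  expect_equal(threshold_rules(fake2)$retained[1], 1)
})

test_that("parallel analysis thresholds are monotone and near 1 for large n", {
  lam <- c(3, 1.5, 0.8, 0.4, 0.2, 0.1)
  fake <- list(eigenvalues = lam, n = 10000, p = 6)
  pa <- parallel_analysis(fake, replicates = 100, seed = 99)
  expect_true(all(diff(pa$thresholds) <= 0))
  expect_true(all(pa$thresholds > 0.9 & pa$thresholds < 1.1))
  one <- parallel_analysis(list(eigenvalues = 2, n = 50, p = 1), replicates = 100)
  expect_equal(one$retained, 1L)
})

test_that("broken stick matches the harmonic closed form", {
  lam2 <- c(1.4, 0.6)
  bs <- broken_stick(list(eigenvalues = lam2, variance_fractions = lam2 / 2, p = 2))
  expect_equal(bs$expected_fractions, c(0.75, 0.25))
  lam6 <- c(3, 1, 0.8, 0.6, 0.4, 0.2)
  bs6 <- broken_stick(list(eigenvalues = lam6, variance_fractions = lam6 / 6, p = 6))
  expect_equal(bs6$expected_fractions[1], sum(1 / (1:6)) / 6)
  lamd <- c(4, 0, 0, 0)
  expect_equal(
    broken_stick(list(eigenvalues = lamd, variance_fractions = lamd / 4, p = 4))$retained,
    1L
  )
})

test_that("broken stick agrees with the vegan reference", {
  skip_if_not_installed("vegan")
  p <- 6
  ref <- vegan::bstick(p, tot.var = p) / p
  lam <- c(2.5, 1.4, 0.9, 0.6, 0.4, 0.2)
  bs <- broken_stick(list(eigenvalues = lam, variance_fractions = lam / p, p = p))
  expect_equal(bs$expected_fractions, unname(ref), tolerance = 1e-12)
})

test_that("Velicer MAP finds the known minima of structured matrices", {
  expect_equal(velicer_map(diag(4))$retained, 0L)
  # one-factor matrix: uniform off-diagonal 0.9
  R1 <- matrix(0.9, 4, 4); diag(R1) <- 1
  expect_equal(velicer_map(R1)$retained, 1L)
  # two tight three-variable blocks: minimum at m = 2
  R2 <- diag(6)
  R2[1:3, 1:3] <- 0.9
  R2[4:6, 4:6] <- 0.9
  diag(R2) <- 1
  v <- velicer_map(R2)
  expect_equal(v$retained, 2L)
  # brute-force shape of the profile: decreasing to m = 2, rising after
  expect_true(which.min(v$avg_sq_partial) == 3) # index of m = 2
})

test_that("Bartlett retention tracks eigenvalue homogeneity", {
  eq <- list(eigenvalues = rep(1, 6), n = 500, p = 6)
  expect_equal(bartlett_retention(eq)$retained, 0L)
  one <- list(eigenvalues = c(4, rep(0.4, 5)), n = 5000, p = 6)
  expect_equal(bartlett_retention(one)$retained, 1L)
  geo <- list(eigenvalues = 2^(3:-2), n = 5000, p = 6)
  expect_equal(bartlett_retention(geo)$retained, 5L)
})

test_that("scree and LEV elbows sit at the maximal second difference", {
  f <- function(lam) list(eigenvalues = lam, p = length(lam))
  expect_equal(scree_elbows(f(c(10, 2, 1.9, 1.8)))$scree_retained, 2L)
  expect_equal(scree_elbows(f(c(3, 2.9, 0.5, 0.4)))$scree_retained, 3L)
  # linear decline: degenerate, smallest index wins
  expect_equal(scree_elbows(f(c(4, 3, 2, 1)))$scree_retained, 2L)
})

test_that("PC1 scores attach by row identity and are permutation-equivariant", {
  set.seed(25)
  ft <- rescale_probabilities(average_raters(full_panel(n_voc = 30, seed = 25)))
  std <- standardize_features(ft)
  fit <- run_pca(std)
  it <- build_index_table(ft)
  got <- attach_pc1_scores(fit, it)
  # scores equal the loadings-weighted (eigenvector) combination
  expect_equal(got$pc1_score, as.numeric(std %*% fit$rotation[, 1]))
  perm <- sample(nrow(it))
  got_perm <- attach_pc1_scores(fit, it[perm, ])
  expect_equal(got_perm$pc1_score, got$pc1_score[perm])
  expect_error(attach_pc1_scores(fit, it[1:3, ]), "different numbers")
})

test_that("the stopping-rule report assembles every rule", {
  std <- standardize_features(matrix(rnorm(300 * 5), 300, 5))
  rep <- stopping_rule_report(run_pca(std), ardi_config(pa_replicates = 100))
  expect_setequal(
    rep$rule,
    c(
      "kaiser_guttman", "jolliffe_kg", "cumulative_variance",
      "parallel_analysis", "broken_stick", "velicer_map", "bartlett",
      "scree_elbow", "lev_elbow"
    )
  )
  expect_true(all(rep$retained >= 0 & rep$retained <= 5))
})
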