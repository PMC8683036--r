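# Corroboration of the indices against researcher call-name labels and
# the species-level socioecological hypothesis battery.

default_context_map <- function() {
  # keyword -> higher-order call context grouping; editable by the caller
  list(
    alarm = c("alarm", "alert", "warning", "predator"),
    territorial = c("territor", "loud call", "long call", "roar"),
    display = c("song", "duet", "trio", "chorus", "great", "display"),
    social = c("contact", "greeting", "social", "group", "cohesion"),
    aggression = c("aggress", "threat", "fight", "bark"),
    mating = c("mating", "copulat", "courtship", "sexual", "estrus"),
    infant_care = c("infant", "mother", "isolation", "distress"),
    foraging = c("forag", "food", "feeding", "exploration", "location"),
    travel = c("travel", "movement", "departure")
  )
}

#' Classify call names by musical keywords
#'
#' Case-insensitive substring match of each call name against a keyword
#' list (default: song, duet, trio, chorus, great, music, scale, coda,
#' intro, interlude); the first matching keyword in list order is
#' recorded. Contexts, when present, are bucketed into higher-order
#' groupings by a configurable keyword map (empty context becomes
#' `"unlabeled"`).
#'
#' @param metadata vocalization metadata with `call_name` (and optionally
#'   `context`).
#' @param keywords character vector of musical keywords.
#' @param context_map named list mapping category -> context keywords.
#' @return data frame: `vocalization_id`, `musical_flag`,
#'   `matched_keyword`, `context_category`.
#' @export
classify_call_names <- function(metadata,
                                keywords = ardi_config()$musical_keywords,
                                context_map = default_context_map()) {
  nm <- tolower(trimws(metadata$call_name))
  matched <- rep(NA_character_, length(nm))
  for (kw in keywords) {
    hit <- is.na(matched) & grepl(kw, nm, fixed = TRUE)
    matched[hit] <- kw
  }
  ctx <- if ("context" %in% names(metadata)) {
    tolower(trimws(ifelse(is.na(metadata$context), "", metadata$context)))
  } else {
    rep("", length(nm))
  }
  category <- rep("unlabeled", length(ctx))
  for (cat in names(context_map)) {
    for (kw in context_map[[cat]]) {
      hit <- category == "unlabeled" & ctx != "" & grepl(kw, ctx, fixed = TRUE)
      category[hit] <- cat
    }
  }
  category[category == "unlabeled" & ctx != ""] <- "other"
  data.frame(
    vocalization_id = metadata$vocalization_id,
    musical_flag = !is.na(matched),
    matched_keyword = matched,
    context_category = category,
    stringsAsFactors = FALSE
  )
}

#' Correlation between an index and the musical-label indicator
#'
#' Correlates a per-call index with the binary musical indicator from
#' [classify_call_names()]. Because "rank correlation with a binary
#' label" is convention-dependent, three methods are available: Pearson
#' on midranks (the default, identical to Spearman with ties), plain
#' Pearson, and Spearman.
#'
#' @param index_table an `index_table`.
#' @param classification output of [classify_call_names()].
#' @param method `"pearson_on_ranks"`, `"pearson"`, or `"spearman"`.
#' @param index which index column to correlate (default `"ardi"`).
#' @return an `ardi_test` list: `test`, `statistic` (r), `n`, `p_value`.
#' @export
index_label_correlation <- function(index_table, classification,
                                    method = c("pearson_on_ranks", "pearson", "spearman"),
                                    index = "ardi") {
  method <- match.arg(method)
  j <- match(index_table$vocalization_id, classification$vocalization_id)
  if (anyNA(j)) stop("classification does not cover all vocalizations")
  x <- index_table[[index]]
  y <- as.numeric(classification$musical_flag[j])
  if (length(x) < 3) stop("need at least three calls")
  if (length(unique(y)) < 2) stop("both musical and non-musical calls required")
  ct <- switch(method,
    pearson_on_ranks = stats::cor.test(rank(x), rank(y), method = "pearson"),
    pearson = stats::cor.test(x, y, method = "pearson"),
    spearman = suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  )
  structure(
    list(
      test = paste0("index_label_correlation[", method, "]"),
      statistic = unname(ct$estimate), n = length(x),
      p_value = ct$p.value
    ),
    class = "ardi_test"
  )
}

# exact rank-sum distribution by dynamic programming over (doubled)
# midranks: counts subsets of size n1 by rank sum; handles ties exactly
ranksum_exact_p <- function(ranks2, n1, w2_obs) {
  n <- length(ranks2)
  maxsum <- sum(sort(ranks2, decreasing = TRUE)[seq_len(n1)])
  # f[j+1, s+1] = number of size-j subsets with doubled-rank sum s
  f <- matrix(0, n1 + 1, maxsum + 1)
  f[1, 1] <- 1
  for (r in ranks2) {
    for (j in min(n1, n):1) { # reverse to avoid reuse
      src <- f[j, ]
      if (any(src > 0)) {
        shifted <- c(rep(0, r), src[seq_len(maxsum + 1 - r)])
        f[j + 1, ] <- f[j + 1, ] + shifted
      }
    }
  }
  counts <- f[n1 + 1, ]
  total <- sum(counts)
  sums <- 0:maxsum
  p_le <- sum(counts[sums <= w2_obs]) / total
  p_ge <- sum(counts[sums >= w2_obs]) / total
  list(less = p_le, greater = p_ge, two.sided = min(1, 2 * min(p_le, p_ge)))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Midranks for ties. Reports `U` for the first group, its complement
#' `U2 = n1*n2 - U`, and `W`, the Mann-Whitney statistic of the first
#' group (the convention R's `wilcox.test` prints, noted in the output).
#' The p value comes from exact enumeration of the rank-sum distribution
#' (a tie-aware subset-count recursion equivalent to full enumeration)
#' whenever `n1 * n2 <= exact_limit`, otherwise from the normal
#' approximation with tie correction and continuity correction.
#'
#' @param values_a,values_b numeric vectors, both nonempty.
#' @param alternative `"two.sided"`, `"less"`, or `"greater"`.
#' @param exact_limit use exact enumeration when `n1 * n2` is at most
#'   this.
#' @return an `ardi_test` list: `test`, `statistic` (U of group a), `U2`,
#'   `W`, `w_convention`, `p_value`, `method` (exact or normal), `n1`,
#'   `n2`, `effect` (rank-biserial `2U/(n1 n2) - 1`).
#' @export
ranksum_test <- function(values_a, values_b,
                         alternative = c("two.sided", "less", "greater"),
                         exact_limit = 400) {
  alternative <- match.arg(alternative)
  n1 <- length(values_a)
  n2 <- length(values_b)
  if (n1 == 0 || n2 == 0) stop("both groups must be nonempty")
  all_v <- c(values_a, values_b)
  rk <- rank(all_v) # midranks
  r1 <- sum(rk[seq_len(n1)])
  U <- r1 - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U
  if (n1 * n2 <= exact_limit) {
    # doubled midranks are integers; observed doubled rank sum of group a
    p <- ranksum_exact_p(as.integer(round(2 * rk)), n1, as.integer(round(2 * r1)))
    p_value <- p[[alternative]]
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(rk)
    sigma2 <- n1 * n2 / 12 *
      ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
    sigma <- sqrt(sigma2)
    z_l <- (U + 0.5 - mu) / sigma
    z_g <- (U - 0.5 - mu) / sigma
    p_value <- switch(alternative,
      less = stats::pnorm(z_l),
      greater = stats::pnorm(z_g, lower.tail = FALSE),
      two.sided = min(1, 2 * min(
        stats::pnorm(z_l),
        stats::pnorm(z_g, lower.tail = FALSE)
      ))
    )
    method <- "normal_tie_corrected"
  }
  structure(
    list(
      test = "ranksum", statistic = U, U2 = U2, W = U,
      w_convention = "Mann-Whitney U of the first group (R wilcox.test W)",
      p_value = p_value, method = method, n1 = n1, n2 = n2,
      effect = 2 * U / (n1 * n2) - 1,
      alternative = alternative
    ),
    class = "ardi_test"
  )
}

#' Welch's two-sample t test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and two-sided p value; the effect estimate is
#' `mean(a) - mean(b)`. Degenerate inputs: two zero-variance groups with
#' equal means give `t = 0, p = 1`; zero variance with unequal means is
#' an error status (the statistic is undefined).
#'
#' @param values_a,values_b numeric vectors with at least two values
#'   each.
#' @return an `ardi_test` list: `test`, `statistic` (t), `df`, `p_value`,
#'   `effect`, `n1`, `n2`, `status`.
#' @export
welch_t_test <- function(values_a, values_b) {
  n1 <- length(values_a)
  n2 <- length(values_b)
  if (n1 < 2 || n2 < 2) stop("each group needs at least two values")
  v1 <- stats::var(values_a)
  v2 <- stats::var(values_b)
  eff <- mean(values_a) - mean(values_b)
  if (v1 == 0 && v2 == 0) {
    if (eff == 0) {
      return(structure(
        list(
          test = "welch_t", statistic = 0, df = n1 + n2 - 2, p_value = 1,
          effect = 0, n1 = n1, n2 = n2, status = "ok"
        ),
        class = "ardi_test"
      ))
    }
    return(structure(
      list(
        test = "welch_t", statistic = NA_real_, df = NA_real_,
        p_value = NA_real_, effect = eff, n1 = n1, n2 = n2,
        status = "undefined: zero variance with unequal means"
      ),
      class = "ardi_test"
    ))
  }
  tt <- stats::t.test(values_a, values_b, var.equal = FALSE)
  structure(
    list(
      test = "welch_t", statistic = unname(tt$statistic),
      df = unname(tt$parameter), p_value = tt$p.value,
      effect = eff, n1 = n1, n2 = n2, status = "ok"
    ),
    class = "ardi_test"
  )
}

#' @export
print.ardi_test <- function(x, ...) {
  cat("<ardi_test>", x$test, "| statistic =", signif(x$statistic, 4))
  if (!is.null(x$df)) cat(" | df =", signif(x$df, 4))
  if (!is.null(x$p_value)) cat(" | p =", signif(x$p_value, 3))
  cat("\n")
  invisible(x)
}

#' Categorize species group size
#'
#' Solitary species are their own class; group sizes of 2--6 are
#' `"small"`, larger than 6 `"large"`, and a missing size without the
#' solitary flag is `"unknown"`.
#'
#' @param group_size numeric vector of mean group sizes.
#' @param solitary_flag logical vector.
#' @return character vector of categories.
#' @export
categorize_group_size <- function(group_size, solitary_flag) {
  out <- rep("unknown", length(group_size))
  out[!is.na(group_size) & group_size >= 2 & group_size <= 6] <- "small"
  out[!is.na(group_size) & group_size > 6] <- "large"
  out[!is.na(solitary_flag) & solitary_flag] <- "solitary"
  out
}

#' Socioecological hypothesis battery
#'
#' Welch t tests of the species-level maximum ARDI against each binary
#' covariate (monogamous, wooded, arboreal, territorial) and against
#' group-size class (small vs large-or-solitary). No multiple-testing
#' correction is applied, matching the exploratory design; a Holm column
#' is provided alongside and every row carries an `adjusted = FALSE`
#' flag. A covariate with only one class is skipped with a notice.
#'
#' @param species_summary output of [species_max_index()] with
#'   covariates.
#' @param index column to test (default `"max_ardi"`).
#' @return data frame: one row per test with `test`, `statistic`, `df`,
#'   `p_value`, `p_holm`, `effect` (mean TRUE-group minus FALSE-group),
#'   `n_true`, `n_false`, `adjusted`, `note`.
#' @export
run_hypothesis_battery <- function(species_summary, index = "max_ardi") {
  y <- species_summary[[index]]
  rows <- list()
  binary <- intersect(
    c("monogamous", "wooded", "arboreal", "territorial"),
    names(species_summary)
  )
  for (cov in binary) {
    g <- species_summary[[cov]]
    ok <- !is.na(g) & !is.na(y)
    a <- y[ok & g]
    b <- y[ok & !g]
    if (length(a) < 2 || length(b) < 2) {
      rows[[cov]] <- data.frame(
        test = cov, statistic = NA_real_, df = NA_real_, p_value = NA_real_,
        effect = NA_real_, n_true = length(a), n_false = length(b),
        note = "skipped: fewer than two species in a class",
        stringsAsFactors = FALSE
      )
      next
    }
    wt <- welch_t_test(a, b)
    rows[[cov]] <- data.frame(
      test = cov, statistic = wt$statistic, df = wt$df,
      p_value = wt$p_value, effect = wt$effect,
      n_true = length(a), n_false = length(b), note = "",
      stringsAsFactors = FALSE
    )
  }
  if (all(c("group_size", "solitary") %in% names(species_summary))) {
    cls <- categorize_group_size(species_summary$group_size, species_summary$solitary)
    a <- y[cls == "small" & !is.na(y)]
    b <- y[cls %in% c("large", "solitary") & !is.na(y)]
    if (length(a) >= 2 && length(b) >= 2) {
      wt <- welch_t_test(a, b)
      rows[["group_size"]] <- data.frame(
        test = "small_vs_large_or_solitary", statistic = wt$statistic,
        df = wt$df, p_value = wt$p_value, effect = wt$effect,
        n_true = length(a), n_false = length(b), note = "",
        stringsAsFactors = FALSE
      )
    } else {
      rows[["group_size"]] <- data.frame(
        test = "small_vs_large_or_solitary", statistic = NA_real_,
        df = NA_real_, p_value = NA_real_, effect = NA_real_,
        n_true = length(a), n_false = length(b),
        note = "skipped: fewer than two species in a class",
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_holm <- NA_real_
  tested <- !is.na(out$p_value)
  out$p_holm[tested] <- stats::p.adjust(out$p_value[tested], method = "holm")
  out$adjusted <- FALSE
  out[, c(
    "test", "statistic", "df", "p_value", "p_holm", "effect",
    "n_true", "n_false", "adjusted", "note"
  )]
}

#' Rank calls by each complexity metric
#'
#' Descending rank (ties get the minimum rank, the next rank is skipped)
#' of each call on ARDI, syllable count and log(SCI); PC1 is ranked
#' ascending because in the study orientation more negative first-
#' component scores mark richer signals -- the orientation used is noted
#' in the output attribute `pc1_orientation`. An optional name filter
#' subsets calls first (case-insensitive substring on the call name).
#'
#' @param index_table an `index_table`.
#' @param metadata vocalization metadata supplying call names.
#' @param subset optional character: keep calls whose name contains any
#'   of these substrings.
#' @return data frame with call names, metric values, and
#'   `<metric>_rank` columns.
#' @export
ranking_table <- function(index_table, metadata, subset = NULL) {
  j <- match(index_table$vocalization_id, metadata$vocalization_id)
  out <- data.frame(
    vocalization_id = index_table$vocalization_id,
    species = metadata$species[j],
    call_name = metadata$call_name[j],
    ardi = index_table$ardi,
    syllables = index_table$syllables,
    pc1_score = index_table$pc1_score,
    log_sci = index_table$log_sci,
    stringsAsFactors = FALSE
  )
  if (!is.null(subset)) {
    keep <- Reduce(`|`, lapply(
      tolower(subset),
      function(s) grepl(s, tolower(out$call_name), fixed = TRUE)
    ))
    out <- out[keep, , drop = FALSE]
    if (nrow(out) == 0) {
      return(out)
    }
  }
  min_rank_desc <- function(v) rank(-v, ties.method = "min", na.last = "keep")
  out$ardi_rank <- min_rank_desc(out$ardi)
  out$syllables_rank <- min_rank_desc(out$syllables)
  out$pc1_rank <- rank(out$pc1_score, ties.method = "min", na.last = "keep")
  out$log_sci_rank <- min_rank_desc(out$log_sci)
  out <- out[order(out$ardi_rank), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pc1_orientation") <- "ascending (more negative = richer signal)"
  out
}

#' Per-context distribution summaries
#'
#' For each context category and each index (ARDI, syllables, SCI),
#' reports n, mean, median and quartiles -- the numbers behind a violin
#' plot. Categories with fewer than three calls are flagged.
#'
#' @param index_table an `index_table`.
#' @param classification output of [classify_call_names()].
#' @return data frame: `context_category`, `index`, `n`, `mean`,
#'   `median`, `q1`, `q3`, `small_sample`.
#' @export
context_summaries <- function(index_table, classification) {
  j <- match(index_table$vocalization_id, classification$vocalization_id)
  cat_of <- classification$context_category[j]
  cat_of[is.na(cat_of) | cat_of == ""] <- "unlabeled"
  rows <- list()
  for (cc in sort(unique(cat_of))) {
    for (idx in c("ardi", "syllables", "sci")) {
      v <- index_table[[idx]][cat_of == cc]
      v <- v[!is.na(v)]
      if (length(v) == 0) next
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      rows[[paste(cc, idx)]] <- data.frame(
        context_category = cc, index = idx, n = length(v),
        mean = mean(v), median = q[2], q1 = q[1], q3 = q[3],
        small_sample = length(v) < 3,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
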