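# The musicality indices: reappearance probability, ARDI, the song
# complexity index (exact and call-level approximation), species maxima,
# and the tone/reappearance summary for putative musical calls.

#' Reappearance probability of a vocal unit
#'
#' Repetition (same frequency, later in time) and transposition
#' (different frequency) are treated as mutually exclusive ways a unit
#' can reappear, so their probabilities add with a zero joint term:
#' `P = p_rep + p_trans`. Because rater scores are only approximately
#' probabilities the sum can exceed 1; `clamp = TRUE` re-bounds it at 1.
#'
#' @param p_rep,p_trans probability-scale scores in `[0, 1]` (vectorized).
#' @param clamp cap the sum at 1?
#' @return numeric vector of reappearance probabilities.
#' @export
reappearance_probability <- function(p_rep, p_trans, clamp = FALSE) {
  if (any(p_rep < 0 | p_rep > 1, na.rm = TRUE) ||
    any(p_trans < 0 | p_trans > 1, na.rm = TRUE)) {
    stop("repetition and transposition scores must lie in [0, 1]")
  }
  p <- p_rep + p_trans
  if (clamp) p <- pmin(p, 1)
  p
}

#' Acoustic reappearance diversity index (ARDI)
#'
#' The expected number of distinct syllables that reappear within a call:
#' `ardi = syllables * (p_rep + p_trans)`. The product is exact; any
#' display rounding (two significant figures in reports) is left to the
#' caller. A zero syllable count or zero reappearance probability
#' guarantees a zero index.
#'
#' @param syllables mean syllable count, `>= 0` (vectorized).
#' @param p_rep,p_trans probability-scale scores in `[0, 1]`.
#' @param clamp cap the reappearance probability at 1?
#' @return numeric vector of ARDI values.
#' @export
compute_ardi <- function(syllables, p_rep, p_trans, clamp = FALSE) {
  if (any(syllables < 0, na.rm = TRUE)) stop("syllable count must be >= 0")
  syllables * reappearance_probability(p_rep, p_trans, clamp)
}

#' Approximate song complexity index
#'
#' Call-level approximation of the syllable-level song complexity index,
#' using the expected per-syllable repetition `E(m) = l/n` (`l` units,
#' `n` syllables): `sci = sqrt(n * l^2 - n * (l/n - 1)^2)`. Returns 0
#' when `n = 0`; a negative radicand yields `NA` with a warning.
#'
#' @param n syllable count (vectorized).
#' @param l unit count.
#' @return numeric vector of SCI values.
#' @export
approximate_sci <- function(n, l) {
  if (length(l) == 1) l <- rep(l, length(n))
  if (length(n) == 1) n <- rep(n, length(l))
  out <- numeric(length(n))
  zero <- !is.na(n) & n == 0
  out[zero] <- 0
  pos <- !is.na(n) & n >= 1
  if (any(pos & !is.na(l) & l < 1)) stop("unit count l must be >= 1")
  rad <- n[pos] * l[pos]^2 - n[pos] * (l[pos] / n[pos] - 1)^2
  bad <- rad < 0
  if (any(bad, na.rm = TRUE)) {
    warning(
      "negative radicand for (n, l) = ",
      paste(sprintf("(%g, %g)", n[pos][bad], l[pos][bad]), collapse = ", "),
      "; returning NA", call. = FALSE
    )
    rad[bad] <- NA_real_
  }
  out[pos] <- sqrt(rad)
  out[is.na(n) | is.na(l)] <- NA_real_
  out
}

#' Exact song complexity index
#'
#' `sci = sqrt(n * l^2 - sum((m_i - 1)^2))` with the per-syllable
#' repetition counts `m_i` given explicitly. Coincides with
#' [approximate_sci()] whenever all `m_i` equal `l/n`.
#'
#' @param n syllable count (scalar).
#' @param l unit count (scalar).
#' @param m numeric vector of `n` per-syllable repetition counts, each
#'   `>= 1`.
#' @return SCI value (scalar).
#' @export
exact_sci <- function(n, l, m) {
  if (length(m) != n) stop("m must have exactly n entries")
  if (any(m < 1)) stop("per-syllable repetition counts must be >= 1")
  rad <- n * l^2 - sum((m - 1)^2)
  if (rad < 0) {
    warning("negative radicand for (n = ", n, ", l = ", l, "); returning NA",
      call. = FALSE
    )
    return(NA_real_)
  }
  sqrt(rad)
}

#' Build the per-vocalization index table
#'
#' Combines a probability-rescaled feature table with metadata into one
#' row per vocalization carrying syllable count, repetition and
#' transposition probabilities, reappearance probability, ARDI, SCI and
#' log(SCI) (natural log; needs `unit_count` in the metadata), and a
#' placeholder `pc1_score` column filled by [attach_pc1_scores()].
#'
#' @param feature_table probability-rescaled `feature_table`.
#' @param metadata vocalization metadata (optional; needed for SCI).
#' @param clamp cap the reappearance probability at 1?
#' @return an `index_table` data frame.
#' @export
build_index_table <- function(feature_table, metadata = NULL, clamp = FALSE) {
  if (!isTRUE(attr(feature_table, "rescaled"))) {
    stop("feature table must be probability-rescaled first")
  }
  reapp <- reappearance_probability(
    feature_table$repetition, feature_table$transposition, clamp
  )
  out <- data.frame(
    vocalization_id = feature_table$vocalization_id,
    syllables = feature_table$syllables,
    p_repetition = feature_table$repetition,
    p_transposition = feature_table$transposition,
    reappearance = reapp,
    ardi = feature_table$syllables * reapp,
    sci = NA_real_,
    log_sci = NA_real_,
    pc1_score = NA_real_,
    stringsAsFactors = FALSE
  )
  if (!is.null(metadata) && "unit_count" %in% names(metadata)) {
    l <- metadata$unit_count[match(out$vocalization_id, metadata$vocalization_id)]
    ok <- !is.na(l)
    # SCI needs at least one syllable and at least as many units
    n_sci <- pmax(round(out$syllables), 1)
    l_sci <- pmax(l, n_sci)
    out$sci[ok] <- approximate_sci(n_sci[ok], l_sci[ok])
    pos <- ok & !is.na(out$sci) & out$sci > 0
    out$log_sci[pos] <- log(out$sci[pos])
  }
  class(out) <- c("index_table", "data.frame")
  out
}

#' Species-level index maxima
#'
#' One row per species with the maximum ARDI, SCI and syllable count over
#' that species' scored call types (the species' most elaborate display
#' is what the socioecological tests use), repertoire size, the sex of
#' the maximum-ARDI call, and the joined covariates. Species absent from
#' the covariate table are kept with missing covariates and flagged.
#'
#' @param index_table an `index_table`.
#' @param metadata vocalization metadata mapping calls to species.
#' @param covariates species covariate table (optional).
#' @return data frame of one row per species.
#' @export
species_max_index <- function(index_table, metadata, covariates = NULL) {
  sp <- metadata$species[match(index_table$vocalization_id, metadata$vocalization_id)]
  if (anyNA(sp)) stop("some vocalizations are missing from the metadata")
  key <- normalize_species(sp)
  rows <- lapply(split(seq_len(nrow(index_table)), key), function(idx) {
    sub <- index_table[idx, , drop = FALSE]
    top <- idx[which.max(sub$ardi)]
    sex <- if ("sex" %in% names(metadata)) {
      metadata$sex[match(index_table$vocalization_id[top], metadata$vocalization_id)]
    } else {
      NA_character_
    }
    data.frame(
      species = sp[match(key[idx][1], key)][1],
      max_ardi = max(sub$ardi, na.rm = TRUE),
      max_sci = if (all(is.na(sub$sci))) NA_real_ else max(sub$sci, na.rm = TRUE),
      max_syllables = max(sub$syllables, na.rm = TRUE),
      repertoire_size = nrow(sub),
      top_call_sex = sex,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(covariates)) {
    j <- match(normalize_species(out$species), normalize_species(covariates$species))
    for (col in setdiff(names(covariates), "species")) {
      out[[col]] <- covariates[[col]][j]
    }
    out$covariates_missing <- is.na(j)
  }
  out
}

#' Tone and reappearance of putative musical calls
#'
#' Average tone probability and reappearance probability within the set
#' of calls whose ARDI exceeds `threshold`, next to the overall means.
#' An empty threshold set yields missing subset means, not an error.
#'
#' @param feature_table probability-rescaled `feature_table` (supplies tone).
#' @param index_table an `index_table` aligned with it.
#' @param threshold ARDI cutoff defining the putative musical set.
#' @return one-row data frame: `n_musical`, `mean_tone_musical`,
#'   `mean_reappearance_musical`, `mean_tone_overall`,
#'   `mean_reappearance_overall`.
#' @export
summarize_putative_musical <- function(feature_table, index_table, threshold = 2) {
  j <- match(index_table$vocalization_id, feature_table$vocalization_id)
  if (anyNA(j)) stop("index and feature tables are misaligned")
  tone <- feature_table$tone[j]
  reapp <- index_table$reappearance
  musical <- index_table$ardi > threshold
  data.frame(
    n_musical = sum(musical),
    mean_tone_musical = if (any(musical)) mean(tone[musical]) else NA_real_,
    mean_reappearance_musical = if (any(musical)) mean(reapp[musical]) else NA_real_,
    mean_tone_overall = mean(tone),
    mean_reappearance_overall = mean(reapp)
  )
}
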