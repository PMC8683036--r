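# Input/output and validation for the tabular formats the pipeline consumes:
# long-format rater scores, vocalization metadata, and species covariates.

#' Canonical acoustic feature names
#'
#' The six structural features scored from spectrograms. Five are ordinal
#' 1--10 scores; `syllables` is a count of distinct unit shapes and has no
#' upper bound. `"variation"` is accepted on input as a synonym for
#' `syllables`.
#'
#' @return Character vector of the six canonical feature names.
#' @export
ardi_features <- function() {
  c("tone", "interval", "rhythm", "repetition", "transposition", "syllables")
}

# features bounded on the 1-10 ordinal scale (all but the syllable count)
bounded_features <- function() setdiff(ardi_features(), "syllables")

normalize_feature <- function(x) {
  x <- tolower(trimws(x))
  x[x == "variation"] <- "syllables"
  x
}

#' Normalize species names for matching
#'
#' Species binomials are matched case-insensitively after trimming and
#' collapsing internal whitespace; identifiers are otherwise opaque.
#'
#' @param x character vector of species names.
#' @return normalized character vector.
#' @export
normalize_species <- function(x) {
  tolower(gsub("[[:space:]]+", " ", trimws(as.character(x))))
}

#' Read a long-format rater score panel
#'
#' Reads a CSV with columns `vocalization_id`, `feature`, `rater_id`,
#' `score` (one row per rater judgement). Feature names are normalized to
#' the canonical lowercase set (see [ardi_features()]).
#'
#' @param path path to a CSV file.
#' @return A `score_panel` data frame with columns `vocalization_id`,
#'   `feature`, `rater_id`, `score`.
#' @export
read_score_panel <- function(path) {
  if (!file.exists(path)) stop("score file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("vocalization_id", "feature", "rater_id", "score")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    stop("score file is missing column(s): ", paste(missing, collapse = ", "))
  }
  raw <- raw[, needed]
  as_score_panel(raw)
}

#' Construct a score panel from a data frame
#'
#' @param df data frame with columns `vocalization_id`, `feature`,
#'   `rater_id`, `score`.
#' @return A `score_panel` data frame.
#' @export
as_score_panel <- function(df) {
  df$vocalization_id <- as.character(df$vocalization_id)
  df$rater_id <- as.character(df$rater_id)
  df$feature <- normalize_feature(df$feature)
  bad <- !(df$feature %in% ardi_features())
  if (any(bad)) {
    stop(
      "unknown feature name(s) at row(s) ",
      paste(utils::head(which(bad), 5), collapse = ", "),
      ": ", paste(unique(df$feature[bad]), collapse = ", ")
    )
  }
  score <- suppressWarnings(as.numeric(df$score))
  nonnum <- is.na(score) & !is.na(df$score)
  if (any(nonnum)) {
    stop(
      "non-numeric score at row(s) ",
      paste(utils::head(which(nonnum), 5), collapse = ", ")
    )
  }
  df$score <- score
  class(df) <- c("score_panel", "data.frame")
  df
}

#' @export
print.score_panel <- function(x, ...) {
  cat(
    "<score_panel> ", nrow(x), " scores | ",
    length(unique(x$vocalization_id)), " vocalizations | ",
    length(unique(x$rater_id)), " raters | ",
    length(unique(x$feature)), " features\n",
    sep = ""
  )
  invisible(x)
}

#' Validate a rater score panel
#'
#' Checks the panel invariants: ordinal features within `[1, 10]`,
#' syllable counts nonnegative, and every vocalization scored by at least
#' one rater for each canonical feature. Violations are returned as data,
#' not raised as errors.
#'
#' @param panel a `score_panel`.
#' @return Data frame with columns `vocalization_id`, `feature`,
#'   `rater_id`, `rule`; zero rows when the panel is clean.
#' @export
validate_panel <- function(panel) {
  out <- data.frame(
    vocalization_id = character(0), feature = character(0),
    rater_id = character(0), rule = character(0),
    stringsAsFactors = FALSE
  )
  bounded <- panel$feature %in% bounded_features()
  oor <- bounded & (panel$score < 1 | panel$score > 10)
  if (any(oor)) {
    out <- rbind(out, data.frame(
      vocalization_id = panel$vocalization_id[oor],
      feature = panel$feature[oor],
      rater_id = panel$rater_id[oor],
      rule = "score outside [1, 10]",
      stringsAsFactors = FALSE
    ))
  }
  neg <- !bounded & panel$score < 0
  if (any(neg)) {
    out <- rbind(out, data.frame(
      vocalization_id = panel$vocalization_id[neg],
      feature = panel$feature[neg],
      rater_id = panel$rater_id[neg],
      rule = "negative syllable count",
      stringsAsFactors = FALSE
    ))
  }
  # completeness: >= 1 rater for every vocalization x canonical feature
  vocs <- unique(panel$vocalization_id)
  have <- unique(panel[, c("vocalization_id", "feature")])
  full <- expand.grid(
    vocalization_id = vocs, feature = ardi_features(),
    stringsAsFactors = FALSE
  )
  key_have <- paste(have$vocalization_id, have$feature, sep = "\r")
  key_full <- paste(full$vocalization_id, full$feature, sep = "\r")
  miss <- full[!(key_full %in% key_have), , drop = FALSE]
  if (nrow(miss) > 0) {
    out <- rbind(out, data.frame(
      vocalization_id = miss$vocalization_id,
      feature = miss$feature,
      rater_id = NA_character_,
      rule = "no rater scored this feature",
      stringsAsFactors = FALSE
    ))
  }
  rownames(out) <- NULL
  out
}

#' Read vocalization metadata
#'
#' Columns: `vocalization_id`, `species`, `genus`, `call_name`, and
#' optionally `context`, `sex`, `unit_count`.
#'
#' @param path path to a CSV file.
#' @return data frame of vocalization records.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("vocalization_id", "species", "genus", "call_name")
  missing <- setdiff(needed, names(md))
  if (length(missing) > 0) {
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "))
  }
  md$vocalization_id <- as.character(md$vocalization_id)
  if (anyDuplicated(md$vocalization_id)) {
    stop("duplicate vocalization_id in metadata")
  }
  if (!is.null(md$unit_count)) {
    md$unit_count <- as.numeric(md$unit_count)
    if (any(!is.na(md$unit_count) & md$unit_count < 1)) {
      stop("unit_count must be >= 1 when present")
    }
  }
  md
}

#' Read species covariates
#'
#' Columns: `species`, `monogamous`, `group_size`, `arboreal`, `wooded`,
#' `territorial`, `solitary`. Logical columns accept TRUE/FALSE or 0/1.
#'
#' @param path path to a CSV file.
#' @return data frame of one row per species.
#' @export
read_species_covariates <- function(path) {
  if (!file.exists(path)) stop("species file not found: ", path)
  sp <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c(
    "species", "monogamous", "group_size", "arboreal",
    "wooded", "territorial", "solitary"
  )
  missing <- setdiff(needed, names(sp))
  if (length(missing) > 0) {
    stop("species table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(normalize_species(sp$species))) {
    stop("duplicate species in covariate table")
  }
  for (col in c("monogamous", "arboreal", "wooded", "territorial", "solitary")) {
    sp[[col]] <- as.logical(sp[[col]])
  }
  sp$group_size <- as.numeric(sp$group_size)
  sp
}

#' Write a pipeline table to CSV
#'
#' Round-trip stable: reading the written file back reproduces the table
#' field-for-field (text fields containing commas are quoted).
#'
#' @param table nonempty data frame.
#' @param path destination path.
#' @return invisibly, the path written.
#' @export
write_table <- function(table, path) {
  if (is.null(table) || nrow(as.data.frame(table)) == 0) {
    stop("refusing to write an empty table")
  }
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Analysis configuration
#'
#' Bundles the tunable parameters of the pipeline with their defaults:
#' the Jolliffe elimination cutoff (0.7), Kaiser-Guttman threshold (1.0),
#' cumulative-variance threshold (0.90), parallel-analysis settings, the
#' musical keyword list used for call-name corroboration, and the final
#' consolidated feature set.
#'
#' @param clamp_reappearance cap the reappearance probability at 1?
#' @param jolliffe_cutoff eigenvalue cutoff for backward elimination.
#' @param kaiser_threshold eigenvalue threshold for the Kaiser-Guttman rule.
#' @param cumvar_threshold cumulative variance fraction to reach.
#' @param pa_replicates number of parallel-analysis replicates (>= 100).
#' @param pa_criterion `"mean"` or `"percentile95"` aggregation of the
#'   simulated eigenvalues.
#' @param rng_seed integer seed used by stochastic steps.
#' @param musical_keywords keywords marking a call name as musical.
#' @param final_feature_set features kept after the declared post-B2
#'   consolidation step.
#' @return a list of class `ardi_config`.
#' @export
ardi_config <- function(clamp_reappearance = FALSE,
                        jolliffe_cutoff = 0.7,
                        kaiser_threshold = 1.0,
                        cumvar_threshold = 0.90,
                        pa_replicates = 1000,
                        pa_criterion = c("mean", "percentile95"),
                        rng_seed = 1L,
                        musical_keywords = c(
                          "song", "duet", "trio", "chorus", "great",
                          "music", "scale", "coda", "intro", "interlude"
                        ),
                        final_feature_set = c("syllables", "repetition", "transposition")) {
  pa_criterion <- match.arg(pa_criterion)
  stopifnot(
    jolliffe_cutoff > 0, jolliffe_cutoff < kaiser_threshold,
    kaiser_threshold <= 2, pa_replicates >= 100,
    cumvar_threshold > 0, cumvar_threshold <= 1
  )
  structure(
    list(
      clamp_reappearance = clamp_reappearance,
      jolliffe_cutoff = jolliffe_cutoff,
      kaiser_threshold = kaiser_threshold,
      cumvar_threshold = cumvar_threshold,
      pa_replicates = as.integer(pa_replicates),
      pa_criterion = pa_criterion,
      rng_seed = as.integer(rng_seed),
      musical_keywords = musical_keywords,
      final_feature_set = final_feature_set
    ),
    class = "ardi_config"
  )
}
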