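# Seeded synthetic generator for multi-rater spectrogram score panels.
# Emulates the study conditions: ~55 species, ~830 vocalizations, 5
# raters, six features, rater dispersion under 2 points on the 10-point
# scale, strong rhythm~repetition coupling and moderate interval~tone
# coupling, and four call archetypes (musical, temporal-repetitive,
# spectral-tonal, noisy single-unit).

#' Default call archetypes
#'
#' True feature means on the probability scale plus syllable-count
#' ranges, for the four archetypes the generator mixes: `musical` (high
#' everything, 3--6 syllables), `temporal` (rhythmic-repetitive, 2--4),
#' `spectral` (tonal, 1--3), `noisy` (low structure, single unit).
#' Mixture weights sum to 1.
#'
#' @return data frame of archetype parameters.
#' @export
default_archetypes <- function() {
  data.frame(
    name = c("musical", "temporal", "spectral", "noisy"),
    weight = c(0.12, 0.22, 0.31, 0.35),
    tone = c(0.72, 0.40, 0.65, 0.28),
    interval = c(0.60, 0.36, 0.56, 0.32),
    rhythm = c(0.60, 0.70, 0.36, 0.30),
    repetition = c(0.64, 0.70, 0.36, 0.26),
    transposition = c(0.48, 0.28, 0.46, 0.16),
    syll_min = c(2, 1, 1, 1),
    syll_max = c(6, 5, 5, 3),
    stringsAsFactors = FALSE
  )
}

#' Generator configuration
#'
#' Defaults reproduce the study scale: 55 species with 10--20 call types
#' each (about 830 vocalizations), five raters with noise standard
#' deviation 1.5 on the 10-point scale and small per-rater biases, a
#' rhythm~repetition correlation target of 0.8 and an interval~tone
#' target of 0.5 (measured on rater-averaged scores), and covariate
#' effects that tilt monogamous and wooded species toward the musical
#' archetype.
#'
#' @param n_species number of species.
#' @param calls_per_species length-2 integer range.
#' @param n_raters number of raters.
#' @param rater_noise_sd rater noise sd on the 10-point scale.
#' @param rater_bias_sd sd of per-rater additive bias (10-point scale).
#' @param rho_rhythm_repetition,rho_interval_tone target correlations of
#'   the rater-averaged scores, in (-1, 1).
#' @param within_sd within-archetype sd of the true feature values on
#'   the probability scale; either a scalar or a named vector over the
#'   five ordinal features (transposition carries the most independent
#'   variance by default so that it, like the syllable count, retains a
#'   component of its own).
#' @param monogamy_uplift,wooded_uplift added to the musical-archetype
#'   mixture weight for species with the covariate (renormalized).
#' @param mean_repetitions mean per-syllable repetition count used to
#'   draw unit counts (geometric tail).
#' @param archetypes archetype parameter table.
#' @param rng_seed integer seed.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_species = 55,
                             calls_per_species = c(10, 20),
                             n_raters = 5,
                             rater_noise_sd = 1.5,
                             rater_bias_sd = 0.5,
                             rho_rhythm_repetition = 0.8,
                             rho_interval_tone = 0.5,
                             within_sd = c(
                               tone = 0.15, interval = 0.18,
                               rhythm = 0.15, repetition = 0.15,
                               transposition = 0.26
                             ),
                             monogamy_uplift = 0.70,
                             wooded_uplift = 0.08,
                             mean_repetitions = 2,
                             archetypes = default_archetypes(),
                             rng_seed = 1L) {
  stopifnot(
    rater_noise_sd > 0,
    abs(rho_rhythm_repetition) < 1, abs(rho_interval_tone) < 1,
    n_raters >= 1, n_species >= 1,
    all(calls_per_species >= 1), length(calls_per_species) == 2,
    all(within_sd > 0)
  )
  if (length(within_sd) == 1) {
    within_sd <- stats::setNames(rep(within_sd, 5), bounded_features())
  }
  stopifnot(all(bounded_features() %in% names(within_sd)))
  structure(
    list(
      n_species = as.integer(n_species),
      calls_per_species = as.integer(calls_per_species),
      n_raters = as.integer(n_raters),
      rater_noise_sd = rater_noise_sd,
      rater_bias_sd = rater_bias_sd,
      rho_rhythm_repetition = rho_rhythm_repetition,
      rho_interval_tone = rho_interval_tone,
      within_sd = within_sd,
      monogamy_uplift = monogamy_uplift,
      wooded_uplift = wooded_uplift,
      mean_repetitions = mean_repetitions,
      archetypes = archetypes,
      rng_seed = as.integer(rng_seed)
    ),
    class = "generator_config"
  )
}

# Mixing weight for the coupled draw of y given x within archetype a:
#   x = mu_x[a] + sx*z1,  y = mu_y[a] + sy*(w*z1 + sqrt(1-w^2)*z2)
# The overall (mixture) correlation combines the within part (w) with the
# between-archetype covariance of the means; solving for w that attains a
# target latent correlation, after first deflating the target by the
# attenuation from averaged rater noise, gives an analytic calibration.
solve_within_rho <- function(target, mu_x, mu_y, weights, sx, sy, noise_var) {
  ex <- sum(weights * mu_x)
  ey <- sum(weights * mu_y)
  vbx <- sum(weights * mu_x^2) - ex^2
  vby <- sum(weights * mu_y^2) - ey^2
  cb <- sum(weights * mu_x * mu_y) - ex * ey
  vx <- vbx + sx^2
  vy <- vby + sy^2
  atten <- sqrt((vx / (vx + noise_var)) * (vy / (vy + noise_var)))
  latent <- target / atten
  w <- (latent * sqrt(vx * vy) - cb) / (sx * sy)
  if (!is.finite(w) || abs(w) >= 1) {
    stop(
      "correlation target ", target,
      " is infeasible for the given archetype structure"
    )
  }
  w
}

latin_species_names <- function(n) {
  gen_a <- c(
    "Sim", "Vok", "Cant", "Arb", "Noct", "Mel", "Phon", "Dry",
    "Call", "Tars", "Lem", "Gal", "Hyl", "Ceb", "Mac", "Pith"
  )
  gen_b <- c("ius", "emur", "ara", "ops", "ix", "odes", "ella")
  sp_a <- c(
    "alb", "nigr", "ruf", "grise", "aure", "virid", "mont",
    "silv", "camp", "rivul", "insul", "borea"
  )
  sp_b <- c("us", "a", "um", "icola", "ensis", "atus")
  combos <- expand.grid(
    g1 = gen_a, g2 = gen_b, s1 = sp_a, s2 = sp_b,
    stringsAsFactors = FALSE
  )
  combos <- combos[sample.int(nrow(combos), n), ]
  data.frame(
    genus = paste0(combos$g1, combos$g2),
    species = paste0(combos$g1, combos$g2, " ", combos$s1, combos$s2),
    stringsAsFactors = FALSE
  )
}

archetype_call_name <- function(arch) {
  pools <- list(
    musical = c(
      "song", "duet song", "great call duet", "trio song",
      "musical sequence", "quaver interlude", "coda phrase"
    ),
    temporal = c(
      "trill", "twitter", "pant series", "staccato call",
      "chatter", "pulsed call"
    ),
    spectral = c("whistle", "tonal note", "tsic", "peep", "moan"),
    noisy = c("alarm bark", "grunt", "scream", "growl", "roar")
  )
  # most musical-archetype calls get a musical name; a few do not, and a
  # few non-musical calls carry musical-sounding names (label noise)
  vapply(arch, function(a) {
    pool <- if (a == "musical") {
      if (stats::runif(1) < 0.85) pools$musical else pools$temporal
    } else if (stats::runif(1) < 0.03) {
      pools$musical
    } else {
      pools[[a]]
    }
    sample(pool, 1)
  }, character(1))
}

archetype_context <- function(arch) {
  pools <- list(
    musical = c("territorial display", "pair duet", "morning display"),
    temporal = c("travel", "group cohesion", "foraging contact"),
    spectral = c("location", "contact", "foraging"),
    noisy = c("alarm", "predator alert", "aggression threat")
  )
  vapply(arch, function(a) sample(pools[[a]], 1), character(1))
}

#' Generate a synthetic rater-score dataset
#'
#' Draws species with covariates, per-species archetype mixtures shifted
#' by the monogamy and wooded uplifts, per-call true feature values with
#' the configured cross-feature coupling, per-syllable repetition counts
#' (hence unit counts), and per-rater ordinal scores
#' `round(10 * true + bias_r + noise)` truncated to 1--10 (syllable
#' counts: `round(true + noise)` floored at 1). Deterministic for a
#' fixed seed.
#'
#' @param config a [generator_config()].
#' @return list: `panel` (a `score_panel`), `metadata`, `covariates`,
#'   `truth` (per-call archetype, true feature values, true syllable
#'   count, per-syllable repetition counts as a comma-joined string).
#' @export
generate_dataset <- function(config = generator_config()) {
  set.seed(config$rng_seed)
  arch <- config$archetypes
  s <- config$within_sd
  noise_var_avg <- (config$rater_noise_sd / 10)^2 / config$n_raters
  w_rr <- solve_within_rho(
    config$rho_rhythm_repetition, arch$repetition, arch$rhythm,
    arch$weight, s[["repetition"]], s[["rhythm"]], noise_var_avg
  )
  w_it <- solve_within_rho(
    config$rho_interval_tone, arch$tone, arch$interval,
    arch$weight, s[["tone"]], s[["interval"]], noise_var_avg
  )

  sp <- latin_species_names(config$n_species)
  covariates <- data.frame(
    species = sp$species,
    monogamous = stats::runif(config$n_species) < 0.30,
    group_size = NA_real_,
    arboreal = stats::runif(config$n_species) < 0.60,
    wooded = stats::runif(config$n_species) < 0.55,
    territorial = stats::runif(config$n_species) < 0.45,
    solitary = stats::runif(config$n_species) < 0.12,
    stringsAsFactors = FALSE
  )
  covariates$group_size <- ifelse(
    covariates$solitary, 1,
    pmax(2, round(exp(stats::rnorm(config$n_species, log(8), 0.8))))
  )
  # monogamous species skew small-group
  small <- covariates$monogamous & !covariates$solitary
  covariates$group_size[small] <- pmin(covariates$group_size[small], sample(2:6, sum(small), TRUE))

  n_calls_sp <- sample(
    config$calls_per_species[1]:config$calls_per_species[2],
    config$n_species,
    replace = TRUE
  )
  total <- sum(n_calls_sp)
  sp_idx <- rep(seq_len(config$n_species), n_calls_sp)

  # per-species archetype mixture, tilted by covariates
  mix <- matrix(rep(arch$weight, config$n_species), ncol = 4, byrow = TRUE)
  uplift <- config$monogamy_uplift * covariates$monogamous +
    config$wooded_uplift * covariates$wooded
  mix[, 1] <- mix[, 1] + uplift
  mix <- mix / rowSums(mix)

  call_arch_idx <- vapply(
    sp_idx,
    function(i) sample.int(4, 1, prob = mix[i, ]),
    integer(1)
  )
  a <- call_arch_idx # row index into archetype table

  z1t <- stats::rnorm(total) # time-domain latent (repetition)
  z2t <- stats::rnorm(total)
  z1s <- stats::rnorm(total) # spectral latent (tone)
  z2s <- stats::rnorm(total)
  clamp01 <- function(x) pmin(1, pmax(0, x))
  true <- data.frame(
    repetition = clamp01(arch$repetition[a] + s[["repetition"]] * z1t),
    rhythm = clamp01(
      arch$rhythm[a] + s[["rhythm"]] * (w_rr * z1t + sqrt(1 - w_rr^2) * z2t)
    ),
    tone = clamp01(arch$tone[a] + s[["tone"]] * z1s),
    interval = clamp01(
      arch$interval[a] + s[["interval"]] * (w_it * z1s + sqrt(1 - w_it^2) * z2s)
    ),
    transposition = clamp01(
      arch$transposition[a] + s[["transposition"]] * stats::rnorm(total)
    )
  )
  true$syllables <- mapply(
    function(lo, hi) if (lo == hi) lo else sample(lo:hi, 1),
    arch$syll_min[a], arch$syll_max[a]
  )

  # unit counts: per-syllable repetition counts m_i = 1 + geometric tail
  p_geom <- 1 / config$mean_repetitions
  m_list <- lapply(true$syllables, function(k) 1L + stats::rgeom(k, p_geom))
  unit_count <- vapply(m_list, sum, numeric(1))

  voc_id <- sprintf("v%04d", seq_len(total))
  metadata <- data.frame(
    vocalization_id = voc_id,
    species = sp$species[sp_idx],
    genus = sp$genus[sp_idx],
    call_name = archetype_call_name(arch$name[a]),
    context = archetype_context(arch$name[a]),
    sex = sample(c("female", "male", "both", "unknown"), total,
      replace = TRUE, prob = c(0.3, 0.35, 0.15, 0.2)
    ),
    unit_count = unit_count,
    stringsAsFactors = FALSE
  )

  # rater scores: ordinal censoring after noise
  raters <- sprintf("r%02d", seq_len(config$n_raters))
  bias <- stats::rnorm(config$n_raters, 0, config$rater_bias_sd)
  feats <- ardi_features()
  panels <- vector("list", length(feats) * config$n_raters)
  k <- 0L
  for (f in feats) {
    for (r in seq_len(config$n_raters)) {
      if (f == "syllables") {
        raw <- true$syllables + stats::rnorm(total, 0, config$rater_noise_sd / 2)
        score <- pmax(1, round(raw))
      } else {
        raw <- 10 * true[[f]] + bias[r] + stats::rnorm(total, 0, config$rater_noise_sd)
        score <- pmin(10, pmax(1, round(raw)))
      }
      k <- k + 1L
      panels[[k]] <- data.frame(
        vocalization_id = voc_id, feature = f, rater_id = raters[r],
        score = score, stringsAsFactors = FALSE
      )
    }
  }
  panel <- as_score_panel(do.call(rbind, panels))

  truth <- data.frame(
    vocalization_id = voc_id,
    archetype = arch$name[a],
    true_tone = true$tone,
    true_interval = true$interval,
    true_rhythm = true$rhythm,
    true_repetition = true$repetition,
    true_transposition = true$transposition,
    true_syllables = true$syllables,
    syllable_repetitions = vapply(
      m_list, function(m) paste(m, collapse = ";"), character(1)
    ),
    stringsAsFactors = FALSE
  )
  list(panel = panel, metadata = metadata, covariates = covariates, truth = truth)
}

#' Realized effect sizes of a generated dataset
#'
#' Computes, from the ground truth (not the noisy scores), the realized
#' mean difference in species-maximum true ARDI for each binary
#' covariate, and the realized archetype mixture -- so recovery tests
#' can compare estimates against what the draw actually produced rather
#' than the nominal configuration.
#'
#' @param dataset output of [generate_dataset()].
#' @return list: `covariate_effects` (data frame `covariate`, `effect`,
#'   `n_true`, `n_false`), `archetype_mixture` (named proportions).
#' @export
truth_effect_summary <- function(dataset) {
  tr <- dataset$truth
  md <- dataset$metadata
  cv <- dataset$covariates
  true_ardi <- tr$true_syllables * (tr$true_repetition + tr$true_transposition)
  sp <- md$species[match(tr$vocalization_id, md$vocalization_id)]
  max_by_sp <- tapply(true_ardi, normalize_species(sp), max)
  j <- match(normalize_species(cv$species), names(max_by_sp))
  y <- as.numeric(max_by_sp[j])
  rows <- lapply(
    c("monogamous", "wooded", "arboreal", "territorial"),
    function(cov) {
      g <- cv[[cov]]
      n1 <- sum(g & !is.na(y))
      n0 <- sum(!g & !is.na(y))
      eff <- if (n1 >= 1 && n0 >= 1) {
        mean(y[g], na.rm = TRUE) - mean(y[!g], na.rm = TRUE)
      } else {
        NA_real_ # single-class covariate: effect undefined
      }
      data.frame(
        covariate = cov, effect = eff, n_true = n1, n_false = n0,
        stringsAsFactors = FALSE
      )
    }
  )
  list(
    covariate_effects = do.call(rbind, rows),
    archetype_mixture = prop.table(table(tr$archetype))
  )
}
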