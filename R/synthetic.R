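#' Configuration for a synthetic concussion cohort
#'
#' Describes a cohort that emulates the structure of the restricted
#' validation data: four date-stamped blood samples per concussion
#' (under 6 h, 24-48 h, when asymptomatic, 7 days after return to play),
#' per-subject heterogeneity in the amount released (`D0`) and in blood
#' volume (`Vd`), multiplicative assay noise, and optionally missing
#' date stamps. Ground truth is retained so estimators can be validated.
#'
#' `D0` is drawn from a mean-preserving lognormal around `d0_nominal`
#' (or from a two-component lognormal mixture via `d0_mixture`, which
#' emulates the bimodal spread of kinetic profiles seen in real
#' cohorts). `Vd` is a sex-specific truncated normal (nominal total
#' blood volumes 4,750/5,320 ml for women/men). Each scheduled draw
#' happens at the scheduled hour plus a uniform jitter, shared across
#' biomarkers of the same subject and visit (one venipuncture). Levels
#' are the model concentration at the true time multiplied by
#' mean-preserving lognormal noise, plus an optional baseline drawn
#' uniformly from the biomarker's healthy range.
#'
#' @param n_subjects Number of concussed subjects (>= 1).
#' @param biomarkers Character vector of preset names (default the four
#'   assayed in the validation cohort).
#' @param d0_nominal Nominal release, pg (default 400,000).
#' @param d0_sigma Lognormal sigma of the release (default 0.3).
#' @param d0_mixture Optional list with `nominals`, `sigmas`, `weights`
#'   describing a lognormal mixture for `D0`; overrides
#'   `d0_nominal`/`d0_sigma`.
#' @param sex_prob Probability a subject is female (default 0.5).
#' @param vd_means Named vector of sex-specific mean blood volumes, ml.
#' @param vd_sigma_frac Sd of `Vd` as a fraction of the sex mean
#'   (default 0.1).
#' @param schedule Data.frame with columns `label`, `hours`, `jitter`
#'   (uniform half-width, h). Default: lt6h at 6 +/- 3, 24-48h at
#'   36 +/- 12, asymptomatic at 168 +/- 48, rtp7d at 336 +/- 48.
#' @param jitter Scalar override applied to every schedule jitter
#'   half-width (e.g. `0` for perfectly timed draws).
#' @param noise_sigma Multiplicative lognormal assay noise sigma
#'   (default 0.2).
#' @param baseline Add a healthy-range baseline level (default `FALSE`:
#'   the kinetic model describes the injury-attributable rise only).
#' @param missing_rate Probability a row loses its date stamp
#'   (label and nominal time become `NA`); default 0.
#' @param seed Integer seed.
#' @return An object of class `cohort_config`.
#' @examples
#' cohort_config(n_subjects = 10, biomarkers = "GFAP", seed = 1)
#' @export
cohort_config <- function(n_subjects,
                          biomarkers = c("GFAP", "UCH-L1", "tau", "NF-L"),
                          d0_nominal = 400000, d0_sigma = 0.3,
                          d0_mixture = NULL,
                          sex_prob = 0.5,
                          vd_means = c(female = 4750, male = 5320),
                          vd_sigma_frac = 0.1,
                          schedule = default_schedule(),
                          jitter = NULL,
                          noise_sigma = 0.2,
                          baseline = FALSE,
                          missing_rate = 0,
                          seed = 1) {
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stop("config field `n_subjects`: must be >= 1")
  bad <- setdiff(biomarkers, list_presets())
  if (length(bad))
    stop("config field `biomarkers`: unknown preset(s) ",
         paste(bad, collapse = ", "))
  if (d0_sigma < 0) stop("config field `d0_sigma`: must be >= 0")
  if (!is.null(d0_mixture)) {
    need <- c("nominals", "sigmas", "weights")
    if (!is.list(d0_mixture) || !all(need %in% names(d0_mixture)) ||
        length(unique(lengths(d0_mixture[need]))) != 1)
      stop("config field `d0_mixture`: needs equal-length ",
           "`nominals`, `sigmas`, `weights`")
  }
  if (sex_prob < 0 || sex_prob > 1)
    stop("config field `sex_prob`: must be in [0, 1]")
  if (vd_sigma_frac < 0) stop("config field `vd_sigma_frac`: must be >= 0")
  if (!is.data.frame(schedule) ||
      !all(c("label", "hours", "jitter") %in% names(schedule)))
    stop("config field `schedule`: needs columns label, hours, jitter")
  if (!is.null(jitter)) schedule$jitter <- jitter
  if (any(schedule$hours - schedule$jitter < 0))
    stop("config field `schedule`: jitter window extends below t = 0")
  if (noise_sigma < 0) stop("config field `noise_sigma`: must be >= 0")
  if (missing_rate < 0 || missing_rate > 1)
    stop("config field `missing_rate`: must be in [0, 1]")
  structure(list(n_subjects = as.integer(n_subjects), biomarkers = biomarkers,
                 d0_nominal = d0_nominal, d0_sigma = d0_sigma,
                 d0_mixture = d0_mixture, sex_prob = sex_prob,
                 vd_means = vd_means, vd_sigma_frac = vd_sigma_frac,
                 schedule = schedule, noise_sigma = noise_sigma,
                 baseline = baseline, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_schedule <- function() {
  data.frame(label = c("lt6h", "24-48h", "asymptomatic", "rtp7d"),
             hours = c(6, 36, 168, 336),
             jitter = c(3, 12, 48, 48),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort table
#'
#' Draws the cohort described by a [cohort_config()]: one row per
#' subject x biomarker x scheduled timepoint, with the measurement
#' columns an analyst would see (`subject_id`, `biomarker`,
#' `timepoint_label`, `time_hr` — `NA`, since real draws are date
#' stamped but not time stamped — and `level_pg_ml`) plus hidden ground
#' truth (`true_D0`, `true_Vd`, `true_time_hr`, `sex`). Reproducible
#' from the config seed.
#'
#' @param config A [cohort_config()].
#' @return A data.frame of class `cohort_table`.
#' @examples
#' tab <- generate_cohort(cohort_config(n_subjects = 3, biomarkers = "GFAP",
#'                                      seed = 7))
#' head(tab)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    stop("`config` must be a cohort_config object")
  set.seed(substream_seed(config$seed, "cohort"))
  ns <- config$n_subjects
  sched <- config$schedule

  sex <- ifelse(stats::runif(ns) < config$sex_prob, "female", "male")
  mu <- config$vd_means[sex]
  sd <- config$vd_sigma_frac * mu
  vd <- stats::rnorm(ns, mu, sd)
  while (any(bad <- vd <= 0)) vd[bad] <- stats::rnorm(sum(bad), mu[bad], sd[bad])

  if (is.null(config$d0_mixture)) {
    d0 <- if (config$d0_sigma == 0) rep(config$d0_nominal, ns) else
      stats::rlnorm(ns, log(config$d0_nominal) - config$d0_sigma^2 / 2,
                    config$d0_sigma)
  } else {
    mix <- config$d0_mixture
    comp <- sample.int(length(mix$weights), ns, replace = TRUE,
                       prob = mix$weights)
    d0 <- stats::rlnorm(ns, log(mix$nominals[comp]) - mix$sigmas[comp]^2 / 2,
                        mix$sigmas[comp])
  }

  # one venipuncture per subject x visit: jittered time shared by biomarkers
  tt <- matrix(NA_real_, ns, nrow(sched))
  for (j in seq_len(nrow(sched)))
    tt[, j] <- sched$hours[j] +
      stats::runif(ns, -sched$jitter[j], sched$jitter[j])

  rows <- vector("list", ns * length(config$biomarkers) * nrow(sched))
  k <- 0
  for (i in seq_len(ns)) {
    for (bm in config$biomarkers) {
      pr <- get_preset(bm)
      for (j in seq_len(nrow(sched))) {
        lvl <- plasma_concentration(pr$params,
                                    injury_scenario(D0 = d0[i], Vd = vd[i]),
                                    tt[i, j])
        if (config$noise_sigma > 0)
          lvl <- lvl * stats::rlnorm(1, -config$noise_sigma^2 / 2,
                                     config$noise_sigma)
        if (isTRUE(config$baseline))
          lvl <- lvl + stats::runif(1, pr$normal_range["low"],
                                    pr$normal_range["high"])
        k <- k + 1
        rows[[k]] <- data.frame(
          subject_id = sprintf("S%03d", i), biomarker = bm,
          timepoint_label = sched$label[j], time_hr = NA_real_,
          level_pg_ml = max(lvl, 0),
          true_D0 = d0[i], true_Vd = vd[i], true_time_hr = tt[i, j],
          sex = sex[i], stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (config$missing_rate > 0) {
    drop <- stats::runif(nrow(out)) < config$missing_rate
    out$timepoint_label[drop] <- NA_character_
  }
  structure(out, class = c("cohort_table", "data.frame"),
            config = config)
}

#' Ground-truth summary of a generated cohort
#'
#' One row per subject with the hidden generator values (`true_D0`,
#' `true_Vd`, `sex` and the true draw times), for validating the inverse
#' estimator against known truth.
#'
#' @param table A `cohort_table` from [generate_cohort()].
#' @return Data.frame: `subject_id`, `sex`, `true_D0`, `true_Vd`, one
#'   `true_t_<label>` column per scheduled timepoint.
#' @export
truth_report <- function(table) {
  if (!all(c("true_D0", "true_Vd", "true_time_hr") %in% names(table)))
    stop("`table` lacks ground-truth columns; was it made by generate_cohort()?")
  subj <- !duplicated(table$subject_id)
  out <- data.frame(subject_id = table$subject_id[subj],
                    sex = table$sex[subj],
                    true_D0 = table$true_D0[subj],
                    true_Vd = table$true_Vd[subj],
                    stringsAsFactors = FALSE)
  one_bm <- table[table$biomarker == table$biomarker[1], ]
  labs <- unique(one_bm$timepoint_label)
  labs <- labs[!is.na(labs)]
  for (lb in labs) {
    sub <- one_bm[!is.na(one_bm$timepoint_label) &
                    one_bm$timepoint_label == lb, ]
    out[[paste0("true_t_", lb)]] <-
      sub$true_time_hr[match(out$subject_id, sub$subject_id)]
  }
  out
}
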