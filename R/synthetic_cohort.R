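# Simulated screening cohorts with the age-sex vBMD structure of a chest-CT
# screening population and built-in DXA/QCT discordance.

#' Default per-bin true vBMD means
#'
#' Mean true trabecular density (mg/cc) per decade bin and sex. The 30-39 and
#' 80+ anchors are 155.19 / 66.59 mg/cc for women and 161.7 / 72.2 mg/cc for
#' men, with linear interpolation across the intermediate bins; the under-30
#' bin sits slightly above the 30-39 value (women 160, men 165). These
#' reproduce the progressive age-related decline of thoracic trabecular
#' density, steeper in women after the menopausal decades.
#'
#' @return a 7 x 2 matrix (rows = age bins, cols = F, M).
#' @export
default_bin_means <- function() {
  interp <- function(lo, hi) lo + (hi - lo) * (0:5) / 5
  m <- cbind(
    F = c(160, interp(155.19, 66.59)),
    M = c(165, interp(161.7, 72.2))
  )
  rownames(m) <- AGE_BIN_LABELS
  m
}

#' Cohort simulation model
#'
#' Describes the population a simulated screening cohort is drawn from: the
#' sex ratio and per-sex age distributions, per-age-bin true vBMD means and
#' SD, QCT measurement noise, the affine DXA T-score linkage, the
#' age-increasing probability of osteophyte/calcification T-score inflation
#' (the mechanism behind DXA false negatives), and exclusion-flag
#' probabilities.
#'
#' The default T-score linkage maps true vBMD affinely so the diagnostic
#' boundaries coincide: 80 mg/cc maps to T = -2.5 and 120 mg/cc to
#' T = -1.0 (`t_per_mgcc = 0.0375`, `t_zero_at_mgcc = 146.667`). This is a
#' modelling convenience that makes the two modalities nominally consistent
#' before noise and inflation are added.
#'
#' @param n cohort size.
#' @param prop_female proportion of women (default 383/649).
#' @param age_mean,age_sd named (`F`, `M`) age distribution parameters.
#' @param age_range ages are truncated to this interval.
#' @param bin_means 7 x 2 matrix of per-bin true vBMD means (see
#'   [default_bin_means()]).
#' @param bin_sd within-bin SD of true vBMD, mg/cc.
#' @param qct_noise_sd SD of QCT measurement error around truth, mg/cc.
#' @param t_per_mgcc,t_zero_at_mgcc the affine T-score linkage
#'   `T = (vBMD - t_zero_at_mgcc) * t_per_mgcc`.
#' @param t_noise_sd per-site T-score noise SD.
#' @param inflation_base,inflation_per_year,inflation_max probability of
#'   spine T-score inflation: `min(base + per_year * max(age - 50, 0), max)`.
#' @param inflation_shape,inflation_scale gamma parameters of the inflation
#'   magnitude (T-score units; defaults mean 1.0).
#' @param p_no_ldct,p_no_t12,p_dxa_incomplete exclusion-flag probabilities
#'   (defaults 58/741, 4/741, 30/741).
#' @param seed RNG seed.
#' @return an object of class `cohort_model`.
#' @export
cohort_model <- function(n = 649, prop_female = 383 / 649,
                         age_mean = c(F = 60.02, M = 55.06),
                         age_sd = c(F = 10.47, M = 12.37),
                         age_range = c(20, 95),
                         bin_means = default_bin_means(),
                         bin_sd = 25,
                         qct_noise_sd = 5,
                         t_per_mgcc = 0.0375,
                         t_zero_at_mgcc = 146.667,
                         t_noise_sd = 0.5,
                         inflation_base = 0.04,
                         inflation_per_year = 0.01,
                         inflation_max = 0.45,
                         inflation_shape = 2,
                         inflation_scale = 0.5,
                         p_no_ldct = 58 / 741,
                         p_no_t12 = 4 / 741,
                         p_dxa_incomplete = 30 / 741,
                         seed = 1L) {
  probs <- c(prop_female, p_no_ldct, p_no_t12, p_dxa_incomplete,
             inflation_base, inflation_max)
  if (any(probs < 0 | probs > 1)) abort("probabilities must be in [0, 1]")
  if (bin_sd <= 0) abort("bin_sd must be > 0")
  if (!all(dim(bin_means) == c(7, 2))) abort("bin_means must be 7 x 2 (bins x F/M)")
  structure(
    as.list(environment()),
    class = "cohort_model"
  )
}

#' Generate a simulated screening cohort
#'
#' Draws a cohort from a [cohort_model()]: ages and sexes per the model,
#' true vBMD from the per-bin normal, observed QCT vBMD = truth +
#' measurement noise, DXA T-scores from the affine linkage with independent
#' per-site noise and (spine only) osteophyte/calcification inflation, and
#' exclusion flags. Fully reproducible from the model seed. Ground-truth
#' columns are prefixed with a dot (`.true_vbmd`, `.dxa_inflated`,
#' `.t_true`) and are dropped by [write_cohort()].
#'
#' @param model a [cohort_model()].
#' @param exclusion_counts optional named vector
#'   `c(no_ldct = , no_t12 = , dxa_incomplete = )`: assign exactly these
#'   disjoint flag counts (randomly placed) instead of drawing flags by
#'   probability.
#' @return a tibble with the cohort schema of [load_cohort()] plus the
#'   dotted ground-truth columns.
#' @export
generate_cohort <- function(model, exclusion_counts = NULL) {
  stopifnot(inherits(model, "cohort_model"))
  m <- model
  if (m$n == 0) {
    return(validate_cohort(tibble(patient_id = character(),
                                  age = numeric(), sex = character()))[0, ])
  }
  withr::with_seed(m$seed, {
    sex <- ifelse(runif(m$n) < m$prop_female, "F", "M")
    age <- pmin(pmax(rnorm(m$n, m$age_mean[sex], m$age_sd[sex]),
                     m$age_range[1]), m$age_range[2])
    bins <- age_bin(age)
    truth <- pmax(rnorm(m$n,
                        mean = m$bin_means[cbind(as.integer(bins),
                                                 ifelse(sex == "F", 1L, 2L))],
                        sd = m$bin_sd), 5)
    qct <- truth + rnorm(m$n, sd = m$qct_noise_sd)
    t_true <- (truth - m$t_zero_at_mgcc) * m$t_per_mgcc
    inflate_p <- pmin(m$inflation_base +
                        m$inflation_per_year * pmax(age - 50, 0),
                      m$inflation_max)
    inflated <- runif(m$n) < inflate_p
    inflation <- ifelse(inflated,
                        rgamma(m$n, shape = m$inflation_shape,
                               scale = m$inflation_scale), 0)
    spine_t <- t_true + rnorm(m$n, sd = m$t_noise_sd) + inflation
    fn_t <- t_true + rnorm(m$n, sd = m$t_noise_sd)
    th_t <- t_true + rnorm(m$n, sd = m$t_noise_sd)

    height <- ifelse(sex == "M", rnorm(m$n, 171.80, 5.71), rnorm(m$n, 159.76, 5.21))
    weight <- ifelse(sex == "M", rnorm(m$n, 76.68, 12.29), rnorm(m$n, 63.74, 10.08))

    if (is.null(exclusion_counts)) {
      no_ldct <- runif(m$n) < m$p_no_ldct
      no_t12 <- runif(m$n) < m$p_no_t12
      dxa_inc <- runif(m$n) < m$p_dxa_incomplete
    } else {
      ec <- exclusion_counts[EXCLUSION_REASONS]
      ec[is.na(ec)] <- 0
      if (sum(ec) > m$n) abort("exclusion_counts exceed cohort size")
      picked <- sample.int(m$n, sum(ec))
      no_ldct <- no_t12 <- dxa_inc <- rep(FALSE, m$n)
      no_ldct[picked[seq_len(ec[1])]] <- TRUE
      no_t12[picked[ec[1] + seq_len(ec[2])]] <- TRUE
      dxa_inc[picked[ec[1] + ec[2] + seq_len(ec[3])]] <- TRUE
    }

    devices <- device_presets()$name
    device <- sample(devices, m$n, replace = TRUE)

    qct[no_ldct | no_t12] <- NA_real_
    spine_t[dxa_inc] <- NA_real_
    fn_t[dxa_inc] <- NA_real_
    th_t[dxa_inc] <- NA_real_

    tbl <- tibble(
      patient_id = sprintf("S%04d", seq_len(m$n)),
      age = age, sex = sex,
      height_cm = height, weight_kg = weight,
      bmi = weight / (height / 100)^2,
      spine_dxa_t = spine_t, fn_dxa_t = fn_t, th_dxa_t = th_t,
      spine_dxa_bmd = 1.047 + 0.110 * spine_t,
      hip_dxa_bmd = 0.942 + 0.122 * pmin(fn_t, th_t),
      qct_vbmd = qct,
      device = device,
      has_ldct = !no_ldct, has_t12 = !no_t12,
      dxa_complete = !dxa_inc
    )
    tbl <- validate_cohort(tbl)
    tbl$.true_vbmd <- truth
    tbl$.t_true <- t_true
    tbl$.dxa_inflated <- inflated
    tbl
  })
}
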