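#' Instrument noise configuration
#'
#' The simulator's replicate noise budget has three parts, applied in order
#' to the noise-free voltage change: a multiplicative positioning deviation
#' drawn per replicate with a per-frequency coefficient of variation (the
#' observed off-centre standing effect, +/-2.5 % at the low and +/-1.5 % at
#' the high frequency), an additive Gaussian electronic replicate noise, and
#' ADC quantization with a +/-2 LSB uniform accuracy offset. With the default
#' drive calibration the three together reproduce total replicate standard
#' deviations near the 1.71 mV (low) and 1.89 mV (high) observed in the
#' feasibility study, the quantization term being the dominant one.
#'
#' @param replicate_sd_low,replicate_sd_high Additive electronic replicate
#'   noise SD, mV.
#' @param positioning_cv_low,positioning_cv_high Positioning coefficient of
#'   variation, percent of the voltage change.
#' @param adc An [adc_spec()], or `NULL` to bypass quantization entirely
#'   (useful for noise-free checks against ground truth).
#' @return Object of class `noise_config`.
#' @export
noise_config <- function(replicate_sd_low = 0.55, replicate_sd_high = 0.30,
                         positioning_cv_low = 2.5, positioning_cv_high = 1.5,
                         adc = adc_spec()) {
  stopifnot(replicate_sd_low >= 0, replicate_sd_high >= 0,
            positioning_cv_low >= 0, positioning_cv_high >= 0,
            is.null(adc) || inherits(adc, "adc_spec"))
  structure(list(replicate_sd_low = replicate_sd_low,
                 replicate_sd_high = replicate_sd_high,
                 positioning_cv_low = positioning_cv_low,
                 positioning_cv_high = positioning_cv_high,
                 adc = adc),
            class = "noise_config")
}

#' Cohort sampling configuration
#'
#' Anthropometric and compositional distributions for the synthetic cohort.
#' Fat areas are lognormal (visceral-fat median 90 cm^2 spanning roughly
#' 30-300, subcutaneous median 150 cm^2), muscle thickness is truncated
#' normal, and per-level areas share a subject-level latent factor giving an
#' inter-level correlation of 0.9. Subcutaneous fat is sampled independently
#' of visceral fat. Waist circumference follows from the shell geometry at
#' navel level and draws outside the window are rejected; BMI is derived from
#' a height draw and a cylindrical mass proxy and is a covariate only — the
#' physics never uses it.
#'
#' @param vf_median,vf_sdlog Lognormal parameters of visceral-fat area, cm^2.
#' @param sf_median,sf_sdlog Lognormal parameters of subcutaneous-fat area.
#' @param lean_mean,lean_sd Normal parameters of the lean interior area, cm^2
#'   (truncated below at `lean_floor`).
#' @param lean_floor Lower truncation of the lean interior area, cm^2.
#' @param muscle_mean,muscle_sd,muscle_floor Truncated-normal parameters of
#'   the muscle sheath thickness, cm.
#' @param interlevel_rho Correlation of log areas between adjacent levels.
#' @param level_factors Deterministic per-level multipliers on the fat areas,
#'   named by [bela_levels()]; the small gradient yields the few-percent
#'   level-to-level rate differences seen in practice.
#' @param wc_window Acceptance window for waist circumference, cm.
#' @param height_range_f,height_range_m Uniform height ranges by sex, m.
#' @param mass_density_factor Effective density (fraction of 1000 kg/m^3)
#'   of the whole-body cylinder mass proxy.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(vf_median = 90, vf_sdlog = 0.6,
                          sf_median = 150, sf_sdlog = 0.4,
                          lean_mean = 250, lean_sd = 30, lean_floor = 100,
                          muscle_mean = 2.2, muscle_sd = 0.4,
                          muscle_floor = 0.2,
                          interlevel_rho = 0.9,
                          level_factors = c("navel-5" = 0.97, "navel" = 1,
                                            "navel+5" = 1.03),
                          wc_window = c(70, 112),
                          height_range_f = c(1.55, 1.80),
                          height_range_m = c(1.65, 1.95),
                          mass_density_factor = 0.58) {
  stopifnot(vf_median > 0, vf_sdlog >= 0, sf_median > 0, sf_sdlog >= 0,
            lean_mean > 0, lean_sd >= 0, muscle_sd >= 0,
            muscle_floor >= 0, muscle_mean > muscle_floor,
            interlevel_rho >= 0, interlevel_rho <= 1,
            length(wc_window) == 2L, wc_window[1] < wc_window[2],
            all(names(level_factors) == bela_levels()),
            mass_density_factor > 0)
  structure(as.list(environment()), class = "cohort_config")
}

# latent per-level z scores sharing a subject factor: corr(z_a, z_b) = rho
level_z <- function(rho) {
  z_subj <- stats::rnorm(1)
  sqrt(rho) * z_subj + sqrt(1 - rho) * stats::rnorm(3)
}

rtruncnorm1 <- function(mean, sd, lower) {
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lower) return(x)
  }
}

#' Sample one synthetic subject
#'
#' Draws anthropometrics and per-level trunk compositions from
#' [cohort_config()]. Waist circumference is the implied circumference of the
#' navel-level shell model; draws outside the configured window are rejected
#' and redrawn.
#'
#' @param id Subject identifier.
#' @param config A [cohort_config()].
#' @param tissues Tissue parameter set for the geometry-derived WC.
#' @return List with `record` (one-row data frame: `subject_id`, `sex`,
#'   `age_y`, `bmi`, `wc_cm`, `weight_kg`, `height_m`, `thin_muscle`) and
#'   `sections` (named list of three [composition_section()]s).
#' @export
sample_subject <- function(id, config = cohort_config(),
                           tissues = default_tissues()) {
  stopifnot(inherits(config, "cohort_config"))
  for (attempt in seq_len(1000L)) {
    sex <- sample(c("F", "M"), 1L)
    hr <- if (sex == "F") config$height_range_f else config$height_range_m
    height <- stats::runif(1, hr[1], hr[2])
    age <- round(stats::runif(1, 22, 60))

    zv <- level_z(config$interlevel_rho)
    zs <- level_z(config$interlevel_rho)
    zl <- level_z(config$interlevel_rho)
    lf <- config$level_factors
    vf <- config$vf_median * exp(config$vf_sdlog * zv) * lf
    sf <- config$sf_median * exp(config$sf_sdlog * zs) * lf
    lean <- pmax(config$lean_mean + config$lean_sd * zl, config$lean_floor)
    tm <- rtruncnorm1(config$muscle_mean, config$muscle_sd,
                      config$muscle_floor)

    sections <- lapply(seq_along(bela_levels()), function(i) {
      composition_section(lean_interior_area = lean[i], vf_area = vf[i],
                          sf_area = sf[i], muscle_thickness = tm,
                          level = bela_levels()[i])
    })
    names(sections) <- bela_levels()

    wc <- shells_from_composition(sections[["navel"]], tissues)$wc_cm
    if (wc < config$wc_window[1] || wc > config$wc_window[2]) next

    r_out_m <- wc / (2 * pi) / 100
    weight <- config$mass_density_factor * 1000 * pi * r_out_m^2 * height
    record <- data.frame(
      subject_id = as.character(id), sex = sex, age_y = age,
      bmi = weight / height^2, wc_cm = wc, weight_kg = weight,
      height_m = height, thin_muscle = tm <= 0.5,
      stringsAsFactors = FALSE)
    return(list(record = record, sections = sections))
  }
  stop("could not draw a subject inside the waist-circumference window; ",
       "infeasible cohort configuration", call. = FALSE)
}

#' Impose a thin-outside-fat-inside (TOFI) anatomy on a subject
#'
#' Overrides every level's composition to a large visceral-fat depot behind a
#' very thin abdominal-muscle sheath and sets the `thin_muscle` flag. This is
#' the documented failure anatomy of the method: with almost no conductive
#' sheath separating the fat pools, the instrument cannot tell visceral from
#' total fat and underestimates the visceral depot.
#'
#' @param subject A [sample_subject()] result.
#' @param vf_area Visceral-fat area to impose, cm^2.
#' @param muscle_thickness Muscle thickness to impose, cm.
#' @param tissues Tissue set for the recomputed waist circumference.
#' @return The modified subject (record anthropometrics re-derived).
#' @export
set_tofi <- function(subject, vf_area = 250, muscle_thickness = 0.3,
                     tissues = default_tissues()) {
  stopifnot(is.list(subject), !is.null(subject$sections))
  lf <- c("navel-5" = 0.97, "navel" = 1, "navel+5" = 1.03)
  subject$sections <- lapply(subject$sections, function(s) {
    composition_section(lean_interior_area = s$lean_interior_area,
                        vf_area = vf_area * lf[[s$level]],
                        sf_area = s$sf_area,
                        muscle_thickness = muscle_thickness,
                        level = s$level)
  })
  wc <- shells_from_composition(subject$sections[["navel"]], tissues)$wc_cm
  subject$record$wc_cm <- wc
  r_out_m <- wc / (2 * pi) / 100
  weight <- 0.58 * 1000 * pi * r_out_m^2 * subject$record$height_m
  subject$record$weight_kg <- weight
  subject$record$bmi <- weight / subject$record$height_m^2
  subject$record$thin_muscle <- muscle_thickness <= 0.5
  subject
}

#' Simulate one measurement session for a subject
#'
#' Produces replicated in-phase voltage changes at every level and both
#' frequencies. Per replicate, the noise-free voltage change is multiplied by
#' a positioning deviation (Gaussian with the per-frequency CV), perturbed by
#' additive electronic noise, and quantized through the ADC model. Replicates
#' are marginal per frequency (no paired sweep is assumed).
#'
#' @param subject A [sample_subject()] result.
#' @param freqs A [frequency_pair()].
#' @param drive A calibrated [drive_config()].
#' @param noise A [noise_config()].
#' @param n_replicates Replicates per level and frequency (protocol: 5).
#' @param tissues Tissue parameter set.
#' @return Data frame of raw measurements: `subject_id`, `level`,
#'   `frequency_khz`, `delta_v_i_mv`, `replicate`.
#' @export
simulate_session <- function(subject, freqs = frequency_pair(), drive,
                             noise = noise_config(), n_replicates = 5L,
                             tissues = default_tissues()) {
  stopifnot(inherits(noise, "noise_config"), n_replicates >= 2L)
  out <- list()
  for (s in subject$sections) {
    dv <- forward_voltage_change(s, freqs, drive, tissues)
    for (role in c("low", "high")) {
      f <- if (role == "low") freqs$f_low else freqs$f_high
      cv <- if (role == "low") noise$positioning_cv_low else noise$positioning_cv_high
      sdr <- if (role == "low") noise$replicate_sd_low else noise$replicate_sd_high
      base <- dv[[paste0("dv_", role)]]
      v <- base * (1 + stats::rnorm(n_replicates, 0, cv / 100)) +
        stats::rnorm(n_replicates, 0, sdr)
      v <- pmax(v, 0)
      if (!is.null(noise$adc)) v <- adc_quantize(v, noise$adc)
      out[[length(out) + 1L]] <- data.frame(
        subject_id = subject$record$subject_id, level = s$level,
        frequency_khz = f, delta_v_i_mv = v,
        replicate = seq_len(n_replicates), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Generate a full synthetic cohort with ground truth
#'
#' End-to-end generation: subjects are sampled, optionally the first
#' `n_tofi` are overridden to the TOFI failure anatomy, the drive gain is
#' calibrated on the reference composition, and a full measurement session is
#' simulated per subject. The returned ground truth stores every composition
#' together with its noise-free voltage changes and loss changing rate, so
#' recovery tests can compare estimates against generative truth.
#'
#' @param n Number of subjects (>= 3).
#' @param seed Integer seed; every stochastic step flows from it.
#' @param config A [cohort_config()].
#' @param noise A [noise_config()].
#' @param freqs A [frequency_pair()].
#' @param target_m_loss Gain-calibration target for the reference anatomy,
#'   mV/kHz.
#' @param n_tofi Number of subjects forced to the TOFI anatomy.
#' @param tofi_vf,tofi_muscle TOFI override parameters, cm^2 and cm.
#' @param n_replicates Replicates per level and frequency.
#' @param tissues Tissue parameter set.
#' @return List with data frames `subjects`, `areas`, `measurements`,
#'   `ground_truth`, plus the `drive` used and a `manifest` (seed and full
#'   configuration echo).
#' @export
simulate_cohort <- function(n, seed = 1L, config = cohort_config(),
                            noise = noise_config(),
                            freqs = frequency_pair(), target_m_loss = 0.6,
                            n_tofi = 0L, tofi_vf = 250, tofi_muscle = 0.3,
                            n_replicates = 5L,
                            tissues = default_tissues()) {
  if (n < 3L) stop("cohort needs at least 3 subjects", call. = FALSE)
  stopifnot(n_tofi >= 0L, n_tofi <= n)
  set.seed(as.integer(seed))
  drive <- calibrate_gain(reference_composition(), freqs, target_m_loss,
                          tissues)
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    subj <- sample_subject(sprintf("S%03d", i), config, tissues)
    if (i <= n_tofi) subj <- set_tofi(subj, tofi_vf, tofi_muscle, tissues)
    subjects[[i]] <- subj
  }
  meas <- do.call(rbind, lapply(subjects, simulate_session, freqs = freqs,
                                drive = drive, noise = noise,
                                n_replicates = n_replicates,
                                tissues = tissues))
  areas <- do.call(rbind, lapply(subjects, function(su) {
    do.call(rbind, lapply(su$sections, function(s) data.frame(
      subject_id = su$record$subject_id, level = s$level,
      vf_area_cm2 = s$vf_area, sf_area_cm2 = s$sf_area,
      stringsAsFactors = FALSE)))
  }))
  rownames(areas) <- NULL
  truth <- do.call(rbind, lapply(subjects, function(su) {
    do.call(rbind, lapply(su$sections, function(s) {
      dv <- forward_voltage_change(s, freqs, drive, tissues)
      data.frame(subject_id = su$record$subject_id, level = s$level,
                 lean_interior_area = s$lean_interior_area,
                 vf_area = s$vf_area, sf_area = s$sf_area,
                 muscle_thickness = s$muscle_thickness,
                 dv_low = dv[["dv_low"]], dv_high = dv[["dv_high"]],
                 m_loss = compute_m_loss(dv[["dv_high"]], dv[["dv_low"]],
                                         freqs),
                 thin_muscle = su$record$thin_muscle,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(truth) <- NULL
  recs <- do.call(rbind, lapply(subjects, `[[`, "record"))
  manifest <- list(
    seed = as.integer(seed), n = n, n_tofi = n_tofi,
    tofi_vf = tofi_vf, tofi_muscle = tofi_muscle,
    n_replicates = n_replicates, target_m_loss = target_m_loss,
    gain = drive$gain,
    freqs = unclass(freqs),
    noise = list(replicate_sd_low = noise$replicate_sd_low,
                 replicate_sd_high = noise$replicate_sd_high,
                 positioning_cv_low = noise$positioning_cv_low,
                 positioning_cv_high = noise$positioning_cv_high,
                 adc = if (is.null(noise$adc)) NULL else unclass(noise$adc)),
    cohort_config = lapply(unclass(config), unname),
    package_version = as.character(utils::packageVersion("bela")))
  list(subjects = recs, areas = areas, measurements = meas,
       ground_truth = truth, drive = drive, manifest = manifest)
}
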