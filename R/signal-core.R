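#' Two-frequency excitation pair
#'
#' The loss-changing-rate statistic compares in-phase coil voltage changes at
#' a low and a high excitation frequency. The study protocol used 103 and
#' 185 kHz, chosen so that the wavelength is far above the subject diameter
#' while still drawing signal from the interior of the trunk; those are the
#' defaults here. Wavelength sanity is a protocol note, not an enforced
#' invariant.
#'
#' @param f_low Low excitation frequency in kHz.
#' @param f_high High excitation frequency in kHz. Must exceed `f_low`.
#' @return An object of class `frequency_pair` with fields `f_low`, `f_high`.
#' @export
#' @examples
#' frequency_pair()          # study default, 103/185 kHz
#' frequency_pair(100, 200)
frequency_pair <- function(f_low = 103, f_high = 185) {
  stopifnot(is.numeric(f_low), is.numeric(f_high),
            length(f_low) == 1L, length(f_high) == 1L,
            is.finite(f_low), is.finite(f_high))
  if (!(f_high > f_low && f_low > 0)) {
    stop("frequency pair requires f_high > f_low > 0 (got ",
         f_low, ", ", f_high, " kHz)", call. = FALSE)
  }
  structure(list(f_low = f_low, f_high = f_high), class = "frequency_pair")
}

#' @export
print.frequency_pair <- function(x, ...) {
  cat(sprintf("frequency pair: %g / %g kHz (span %g kHz)\n",
              x$f_low, x$f_high, x$f_high - x$f_low))
  invisible(x)
}

#' Canonical abdominal measurement levels
#'
#' Measurements are taken at three axial levels: 5 cm below the navel, at the
#' navel, and 5 cm above. Levels are never pooled in the analysis.
#'
#' @return Character vector of the three level labels, in caudal-to-cranial
#'   order.
#' @export
bela_levels <- function() c("navel-5", "navel", "navel+5")

check_level <- function(level) {
  bad <- setdiff(unique(level), bela_levels())
  if (length(bad)) {
    stop("unknown level(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(bela_levels(), collapse = ", "),
         call. = FALSE)
  }
  invisible(level)
}

#' In-phase voltage change between empty and loaded coil
#'
#' A body inside the coil dissipates eddy-current losses, lowering the
#' resonance quality factor; the instrument observes this as a change of the
#' in-phase coil voltage between the empty and the loaded state. Losses are
#' reported as positive magnitudes regardless of the raw sign convention of
#' the electronics.
#'
#' @param empty_v Coil voltage with the coil empty, mV.
#' @param loaded_v Coil voltage with the subject in place, mV.
#' @return `abs(loaded_v - empty_v)` in mV. Vectorized.
#' @export
voltage_change <- function(empty_v, loaded_v) {
  if (!is.numeric(empty_v) || !is.numeric(loaded_v) ||
      any(!is.finite(empty_v)) || any(!is.finite(loaded_v))) {
    stop("voltage_change() requires finite numeric inputs", call. = FALSE)
  }
  abs(loaded_v - empty_v)
}

#' Loss changing rate between two excitation frequencies
#'
#' The core statistic of the method: the difference between the in-phase
#' voltage changes at the high and low frequency, divided by the frequency
#' difference,
#' \deqn{m_{loss} = \frac{\Delta V_{i,H} - \Delta V_{i,L}}{f_H - f_L},}
#' in mV/kHz. Because lean tissue conducts more than ten times better than
#' fat and its conductivity rises faster with frequency, a larger visceral
#' (interior) fat depot shifts the loss budget and changes this rate.
#'
#' A negative rate is physically suspect (losses should grow with frequency)
#' but is returned as-is with a warning rather than clamped.
#'
#' @param dv_high,dv_low In-phase voltage changes at `f_high` and `f_low`, mV.
#'   Vectorized.
#' @param freqs A [frequency_pair()].
#' @return Loss changing rate(s) in mV/kHz.
#' @export
#' @examples
#' compute_m_loss(59.2, 10, frequency_pair())  # 49.2/82 = 0.6 mV/kHz
compute_m_loss <- function(dv_high, dv_low, freqs = frequency_pair()) {
  stopifnot(inherits(freqs, "frequency_pair"), is.numeric(dv_high),
            is.numeric(dv_low))
  span <- freqs$f_high - freqs$f_low
  if (span == 0) stop("degenerate frequency pair: f_high == f_low", call. = FALSE)
  m <- (dv_high - dv_low) / span
  if (any(m < 0, na.rm = TRUE)) {
    warning("negative loss changing rate(s): physically suspect, not clamped",
            call. = FALSE)
  }
  m
}

#' Repeatability of the loss changing rate
#'
#' Propagates the replicate standard deviations of the two voltage changes to
#' a half-range repeatability of the rate,
#' \deqn{\Delta m_{loss} = \frac{\sigma_H + \sigma_L}{f_H - f_L}.}
#' The contribution of frequency-measurement uncertainty is negligible at the
#' instrument's frequency stability and is deliberately omitted.
#'
#' @param sigma_high,sigma_low Replicate standard deviations of the voltage
#'   changes at the high and low frequency, mV. Alternatively `sigma_high`
#'   may be a level-measurement data frame (as returned by
#'   [aggregate_replicates()]) carrying `sigma_H` and `sigma_L` columns.
#' @param freqs A [frequency_pair()].
#' @return Half-range repeatability in mV/kHz, same length as the inputs.
#' @export
#' @examples
#' compute_repeatability(1.89, 1.71, frequency_pair())  # 3.60/82 mV/kHz
compute_repeatability <- function(sigma_high, sigma_low = NULL,
                                  freqs = frequency_pair()) {
  if (is.data.frame(sigma_high)) {
    lm_ <- sigma_high
    stopifnot(all(c("sigma_H", "sigma_L") %in% names(lm_)))
    sigma_low <- lm_$sigma_L
    sigma_high <- lm_$sigma_H
  }
  stopifnot(inherits(freqs, "frequency_pair"),
            is.numeric(sigma_high), is.numeric(sigma_low))
  if (any(sigma_high < 0 | sigma_low < 0, na.rm = TRUE)) {
    stop("replicate standard deviations must be non-negative", call. = FALSE)
  }
  span <- freqs$f_high - freqs$f_low
  if (span == 0) stop("degenerate frequency pair: f_high == f_low", call. = FALSE)
  (sigma_high + sigma_low) / span
}

#' Aggregate replicate measurements for one subject and level
#'
#' Collapses the replicated voltage changes of a single subject at a single
#' abdominal level to per-frequency means and sample standard deviations
#' (n-1 denominator). Replicates are treated marginally per frequency; no
#' pairing across the two frequencies is assumed.
#'
#' @param measurements Data frame with columns `subject_id`, `level`,
#'   `frequency_khz`, `delta_v_i_mv`, `replicate`, all rows belonging to one
#'   subject and level.
#' @param freqs A [frequency_pair()] used to classify rows as low/high.
#' @return One-row data frame with `subject_id`, `level`, `mean_dv_L`,
#'   `mean_dv_H`, `sigma_L`, `sigma_H`, `n_replicates` (the smaller of the
#'   per-frequency counts).
#' @export
aggregate_replicates <- function(measurements, freqs = frequency_pair()) {
  stopifnot(is.data.frame(measurements), inherits(freqs, "frequency_pair"))
  need <- c("subject_id", "level", "frequency_khz", "delta_v_i_mv", "replicate")
  miss <- setdiff(need, names(measurements))
  if (length(miss)) {
    stop("measurement table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(measurements$subject_id)) != 1L ||
      length(unique(measurements$level)) != 1L) {
    stop("aggregate_replicates() expects a single subject and level; got ",
         length(unique(measurements$subject_id)), " subject(s), ",
         length(unique(measurements$level)), " level(s)", call. = FALSE)
  }
  check_level(measurements$level)
  if (any(measurements$delta_v_i_mv < 0)) {
    stop("voltage changes must be stored as positive loss magnitudes",
         call. = FALSE)
  }
  role <- classify_frequency(measurements$frequency_khz, freqs)
  lo <- measurements$delta_v_i_mv[role == "low"]
  hi <- measurements$delta_v_i_mv[role == "high"]
  if (length(lo) < 2L || length(hi) < 2L) {
    stop("insufficient replicates: need >= 2 per frequency, got ",
         length(lo), " low / ", length(hi), " high", call. = FALSE)
  }
  data.frame(
    subject_id = measurements$subject_id[1L],
    level = measurements$level[1L],
    mean_dv_L = mean(lo), mean_dv_H = mean(hi),
    sigma_L = stats::sd(lo), sigma_H = stats::sd(hi),
    n_replicates = min(length(lo), length(hi)),
    stringsAsFactors = FALSE
  )
}

# Map measured frequencies onto the low/high roles of a frequency pair.
# A small relative tolerance absorbs frequency read-back jitter.
classify_frequency <- function(f_khz, freqs, tol = 1e-6) {
  role <- rep(NA_character_, length(f_khz))
  role[abs(f_khz - freqs$f_low) <= tol * freqs$f_low] <- "low"
  role[abs(f_khz - freqs$f_high) <= tol * freqs$f_high] <- "high"
  if (anyNA(role)) {
    stop("frequency value(s) ", paste(unique(f_khz[is.na(role)]), collapse = ", "),
         " kHz match neither ", freqs$f_low, " nor ", freqs$f_high, " kHz",
         call. = FALSE)
  }
  role
}

#' Analog-to-digital converter specification
#'
#' The feasibility instrument digitized the in-phase voltage with a 10-bit
#' converter referenced to 1.1 V and an absolute accuracy of +/-2 least
#' significant bits; those are the defaults.
#'
#' @param bits Resolution in bits.
#' @param v_ref Voltage reference in volts.
#' @param lsb_error Absolute accuracy as a +/- LSB count.
#' @return An object of class `adc_spec`.
#' @export
adc_spec <- function(bits = 10L, v_ref = 1.1, lsb_error = 2L) {
  stopifnot(bits >= 1, v_ref > 0, lsb_error >= 0)
  structure(list(bits = as.integer(bits), v_ref = v_ref,
                 lsb_error = as.integer(lsb_error)),
            class = "adc_spec")
}

#' Size of one least significant bit, in mV
#' @param spec An [adc_spec()].
#' @return LSB size in mV.
#' @export
adc_lsb_mv <- function(spec = adc_spec()) {
  stopifnot(inherits(spec, "adc_spec"))
  spec$v_ref / 2^spec$bits * 1000
}

#' Absolute ADC accuracy in mV
#'
#' The +/- LSB accuracy count expressed on the voltage scale:
#' `lsb_error * v_ref / 2^bits`, in mV. With the default 10-bit, 1.1 V,
#' +/-2 LSB specification this is 2.148 mV, the accuracy floor that limited
#' the feasibility instrument.
#'
#' @param spec An [adc_spec()].
#' @return Accuracy half-width in mV (full precision; round only for display).
#' @export
#' @examples
#' adc_accuracy(adc_spec(10, 1.1, 2))  # ~2.15 mV
adc_accuracy <- function(spec = adc_spec()) {
  stopifnot(inherits(spec, "adc_spec"))
  spec$lsb_error * adc_lsb_mv(spec)
}

#' Quantize a voltage through the ADC error model
#'
#' Snaps a voltage to the converter's LSB grid and adds an integer offset
#' drawn uniformly from `-lsb_error..+lsb_error` LSB, emulating the absolute
#' accuracy of the converter. The total error is bounded by
#' `(lsb_error + 0.5) * LSB`. Uses R's RNG; seed upstream for reproducibility.
#'
#' @param v_mv Voltage(s) in mV; must lie within the converter range
#'   `[0, v_ref * 1000]` (violations signal a simulator gain misconfiguration).
#' @param spec An [adc_spec()].
#' @return Quantized voltage(s) in mV.
#' @export
adc_quantize <- function(v_mv, spec = adc_spec()) {
  stopifnot(inherits(spec, "adc_spec"), is.numeric(v_mv))
  vmax <- spec$v_ref * 1000
  if (any(v_mv < 0 | v_mv > vmax)) {
    stop("voltage outside ADC range [0, ", vmax,
         "] mV: rebalance simulator gain or noise", call. = FALSE)
  }
  lsb <- adc_lsb_mv(spec)
  offs <- if (spec$lsb_error > 0) {
    sample(seq.int(-spec$lsb_error, spec$lsb_error), length(v_mv),
           replace = TRUE)
  } else {
    rep(0L, length(v_mv))
  }
  (round(v_mv / lsb) + offs) * lsb
}
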