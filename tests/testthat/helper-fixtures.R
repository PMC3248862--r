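# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

study_freqs <- function() frequency_pair(103, 185)

# a minimal replicate table for one subject/level
make_replicates <- function(lo, hi, subject = "S1", level = "navel",
                            freqs = study_freqs()) {
  data.frame(
    subject_id = subject,
    level = level,
    frequency_khz = c(rep(freqs$f_low, length(lo)),
                      rep(freqs$f_high, length(hi))),
    delta_v_i_mv = c(lo, hi),
    replicate = c(seq_along(lo), seq_along(hi)),
    stringsAsFactors = FALSE)
}

# independent two-pass sample SD (oracle for aggregate_replicates)
two_pass_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# hat-matrix leave-one-out shortcut (oracle for loocv_rmse)
loocv_hat_oracle <- function(x, y) {
  fit <- lm(y ~ x)
  h <- hatvalues(fit)
  sqrt(mean((residuals(fit) / (1 - h))^2))
}

# brute-force leave-one-out by explicit enumeration
loocv_brute <- function(x, y) {
  n <- length(x)
  e <- numeric(n)
  for (i in seq_len(n)) {
    cf <- coef(lm(y[-i] ~ x[-i]))
    e[i] <- cf[1] + cf[2] * x[i] - y[i]
  }
  sqrt(mean(e^2))
}

# numerical radial quadrature of the eddy-current loss integrand
# (2 pi f^2 * integral of sigma(r) r^3 dr); the closed shell form carries
# the same integral without the 2 pi / 4 constant, so quadrature * 2 / pi
# must equal section_loss.
quadrature_loss <- function(shells, f) {
  sig <- function(r) {
    out <- numeric(length(r))
    out[r <= shells$r_interior] <-
      tissue_conductivity(shells$interior_sigma_params, f)
    idx <- r > shells$r_interior & r <= shells$r_muscle_out
    out[idx] <- tissue_conductivity(shells$muscle_sigma_params, f)
    idx <- r > shells$r_muscle_out
    out[idx] <- tissue_conductivity(shells$fat_sigma_params, f)
    out
  }
  # integrate piecewise to keep quadrature exact on each smooth piece
  cuts <- c(0, shells$r_interior, shells$r_muscle_out, shells$r_outer)
  total <- 0
  for (i in 1:3) {
    total <- total + integrate(function(r) sig(r) * r^3, cuts[i], cuts[i + 1],
                               rel.tol = 1e-12)$value
  }
  2 * pi * f^2 * total
}
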