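# Shared fixtures: noise-free generator variants and tiny inputs built in
# code at test time.

noiselessHapticConfig <- function() {
  cfg <- phantomDefaults()
  cfg$haptic$vibAmp <- c(0, 0)
  cfg$haptic$whiteSd <- 0
  cfg
}

# A clean approach/ramp/plateau trace with a known plateau level.
cleanTrace <- function(plateau, label = "mature") {
  synthesizeHapticTrace(label, config = noiselessHapticConfig(), seed = 1,
                        plateau = plateau)
}

# Steady sinusoid as a HapticTrace (for filter-response checks).
sineTrace <- function(freq, rate = 100, duration = 15) {
  tt <- (seq_len(rate * duration) - 1) / rate
  HapticTrace(sin(2 * pi * freq * tt), rate)
}

# Fitted amplitude of a sinusoid over the central (steady-state) section.
fittedAmplitude <- function(x, freq, rate = 100, trim = 0.25) {
  n <- length(x)
  keep <- seq.int(floor(n * trim), ceiling(n * (1 - trim)))
  tt <- (keep - 1) / rate
  fit <- stats::lm(x[keep] ~ sin(2 * pi * freq * tt) +
                     cos(2 * pi * freq * tt))
  sqrt(sum(stats::coef(fit)[2:3]^2))
}

# Mean corrected spectrum over n seeded phantom draws.
meanCorrectedSpectrum <- function(label, n, seedBase = 1000,
                                  config = phantomDefaults()) {
  acc <- NULL
  for (i in seq_len(n)) {
    cs <- correctedSignal(correctSpectrum(
      synthesizeSpectrum(label, config, seed = seedBase + i)))
    acc <- if (is.null(acc)) cs else acc + cs
  }
  acc / n
}
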