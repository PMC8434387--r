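# Synthetic multi-subject IMU data with quasi-periodic gait signatures.
# Each activity is a harmonic-plus-noise process on a latent gait phase; the
# gyroscope channel is a phase-shifted, differently weighted transform of the
# same latent process mixed with a class-specific complementary component.

#' Define an activity signal template
#'
#' @param name Class label, one of [activity_classes()].
#' @param base_freq_hz Dominant gait frequency in Hz, must lie in (0, 50)
#'   (below the Nyquist frequency at the 100 Hz sampling rate).
#' @param accel_amp,gyro_amp Numeric length-3 per-axis amplitudes.
#' @param harmonic_weights Weights of the harmonics of the gait frequency.
#' @param duty_pattern Optional list `list(period_s=, on_frac=, off_level=)`
#'   giving an on/off envelope for intermittent activities such as eating.
#' @param noise_sd Standard deviation of additive white Gaussian sensor noise.
#' @return Object of class `activity_template`.
#' @export
activity_template <- function(name, base_freq_hz, accel_amp, gyro_amp,
                              harmonic_weights = 1, duty_pattern = NULL,
                              noise_sd = 0.3) {
  stopifnot(name %in% activity_classes(),
            is.numeric(base_freq_hz), length(base_freq_hz) == 1L,
            base_freq_hz > 0, base_freq_hz < 50,
            length(accel_amp) == 3L, length(gyro_amp) == 3L,
            all(harmonic_weights >= 0), length(harmonic_weights) >= 1L,
            is.numeric(noise_sd), noise_sd >= 0)
  if (!is.null(duty_pattern))
    stopifnot(is.list(duty_pattern), duty_pattern$period_s > 0,
              duty_pattern$on_frac > 0, duty_pattern$on_frac <= 1)
  structure(list(name = name, base_freq_hz = base_freq_hz,
                 accel_amp = as.numeric(accel_amp),
                 gyro_amp = as.numeric(gyro_amp),
                 harmonic_weights = as.numeric(harmonic_weights),
                 duty_pattern = duty_pattern, noise_sd = noise_sd),
            class = "activity_template")
}

#' Default activity templates
#'
#' Six templates reproducing the qualitative structure the classification
#' problem rests on: every class has a distinct quasi-periodic signature
#' except the two walking classes, which share frequency and harmonic shape
#' and differ only by a small relative amplitude offset `walk_delta`
#' (walking under a rider is slightly more damped/loaded), so class confusion
#' concentrates on that pair; eating is low-frequency and intermittent
#' (chewing bursts); trotting and galloping are high-frequency,
#' high-amplitude and adjacent in frequency; standing is near-quiescent.
#'
#' @param walk_delta Relative amplitude offset separating `walking_rider`
#'   from `walking_natural` (default 0.25).  The offset is applied coherently
#'   to both modalities, so it stays detectable under independent per-subject
#'   per-modality amplitude jitter smaller than itself, while keeping the
#'   pair far closer to each other than to any other class.
#' @param noise_sd Sensor noise standard deviation shared by all templates.
#' @return List of six [activity_template()] objects, one per registered
#'   class, in registry order.
#' @export
default_templates <- function(walk_delta = 0.25, noise_sd = 0.3) {
  walk_acc <- c(1.00, 0.75, 0.55)
  walk_gyr <- c(0.85, 0.65, 0.45)
  walk_h <- c(1, 0.45, 0.15)
  out <- list(
    activity_template("eating", 1.1,
                      accel_amp = c(0.55, 0.40, 0.30),
                      gyro_amp = c(0.50, 0.35, 0.25),
                      harmonic_weights = c(1, 0.4),
                      duty_pattern = list(period_s = 1.6, on_frac = 0.55,
                                          off_level = 0.15),
                      noise_sd = noise_sd),
    activity_template("galloping", 3.4,
                      accel_amp = c(2.6, 2.0, 1.6),
                      gyro_amp = c(2.2, 1.7, 1.2),
                      harmonic_weights = c(1, 0.6, 0.3),
                      noise_sd = noise_sd),
    activity_template("standing", 0.5,
                      accel_amp = c(0.12, 0.10, 0.08),
                      gyro_amp = c(0.10, 0.08, 0.06),
                      harmonic_weights = 1,
                      noise_sd = noise_sd),
    activity_template("trotting", 2.5,
                      accel_amp = c(1.9, 1.5, 1.1),
                      gyro_amp = c(1.6, 1.2, 0.9),
                      harmonic_weights = c(1, 0.5, 0.2),
                      noise_sd = noise_sd),
    activity_template("walking_natural", 1.4,
                      accel_amp = walk_acc,
                      gyro_amp = walk_gyr,
                      harmonic_weights = walk_h,
                      noise_sd = noise_sd),
    activity_template("walking_rider", 1.4,
                      accel_amp = walk_acc * (1 + walk_delta),
                      gyro_amp = walk_gyr * (1 + walk_delta),
                      harmonic_weights = walk_h,
                      noise_sd = noise_sd)
  )
  names(out) <- vapply(out, function(t) t$name, "")
  out
}

#' Class proportions of the study dataset
#'
#' The printed shares of the six activities in the reference horse dataset
#' (eating 18.32, galloping 4.50, standing 5.84, trotting 28.62,
#' walking_natural 3.80, walking_rider 38.94, in percent), renormalized to
#' sum to one; their max/min ratio is the dataset's imbalance ratio of 10.25.
#'
#' @return Named numeric of length 6 summing to 1, in registry order.
#' @export
reference_class_proportions <- function() {
  p <- c(eating = 18.32, galloping = 4.50, standing = 5.84,
         trotting = 28.62, walking_natural = 3.80, walking_rider = 38.94)
  p / sum(p)
}

#' Generator configuration
#'
#' @param n_subjects Number of subjects (animals), at least 2; default 6 as
#'   in the study protocol.
#' @param segments_per_subject Segments generated per subject.
#' @param class_proportions Length-6 non-negative numeric summing to 1 (in
#'   registry order).  Defaults to the study dataset's shares, i.e. imbalance
#'   ratio 10.25; use `rep(1/6, 6)` for a balanced set.
#' @param subject_effect_sd Log-normal sd of the per-subject multiplicative
#'   amplitude jitter; when positive, each subject also gets a fixed
#'   frequency multiplier drawn uniformly in `+/- freq_jitter`.
#' @param freq_jitter Half-width of the per-subject relative gait-frequency
#'   jitter (default 0.05, i.e. +/-5 percent); only drawn when
#'   `subject_effect_sd > 0`.
#' @param coupling In `[0, 1]`: 1 makes the gyroscope a purely redundant
#'   (phase-shifted) transform of the accelerometer's latent gait process,
#'   smaller values mix in a class-specific complementary component.
#' @param eating_walk_mix Amplitude fraction of a walking-like component mixed
#'   into eating draws (grazing animals walk slowly while eating).
#' @param phase_jitter_sd Standard deviation (radians) of a per-segment random
#'   phase offset; 0 by default so that a noise-free, jitter-free
#'   configuration generates identical segments.
#' @param seed Integer seed; the dataset is a pure function of
#'   `(config, templates)`.
#' @return Object of class `imu_generator_config`.
#' @export
generator_config <- function(n_subjects = 6,
                             segments_per_subject = 100,
                             class_proportions = reference_class_proportions(),
                             subject_effect_sd = 0.1,
                             freq_jitter = 0.05,
                             coupling = 0.6,
                             eating_walk_mix = 0.15,
                             phase_jitter_sd = 0,
                             seed = 1) {
  class_proportions <- as.numeric(class_proportions)
  stopifnot(n_subjects >= 2, segments_per_subject >= 1,
            length(class_proportions) == 6L, all(class_proportions >= 0),
            subject_effect_sd >= 0, freq_jitter >= 0, freq_jitter < 1,
            coupling >= 0, coupling <= 1,
            eating_walk_mix >= 0, phase_jitter_sd >= 0)
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class_proportions must sum to 1 (got ", sum(class_proportions), ")")
  structure(list(n_subjects = as.integer(n_subjects),
                 segments_per_subject = as.integer(segments_per_subject),
                 class_proportions = class_proportions,
                 subject_effect_sd = subject_effect_sd,
                 freq_jitter = freq_jitter,
                 coupling = coupling,
                 eating_walk_mix = eating_walk_mix,
                 phase_jitter_sd = phase_jitter_sd,
                 seed = as.integer(seed)),
            class = "imu_generator_config")
}

# Apportion n segments to classes by largest-remainder rounding (ties to the
# lower class index), so realized counts match requested proportions exactly.
largest_remainder_counts <- function(n, proportions) {
  quota <- n * proportions
  counts <- floor(quota)
  short <- n - sum(counts)
  if (short > 0) {
    frac <- quota - counts
    give <- order(-frac, seq_along(frac))[seq_len(short)]
    counts[give] <- counts[give] + 1
  }
  as.integer(counts)
}

# Evaluate one template draw; returns list(accel, gyro) of 3 x 200 matrices
# without sensor noise.  amp_mult: length-2 (accel, gyro) subject amplitude
# multipliers; freq_mult scalar.
template_signal <- function(tpl, amp_mult, freq_mult, coupling, phase0,
                            walk_mix = NULL) {
  t <- (0:199) / 100
  f <- tpl$base_freq_hz * freq_mult
  hw <- tpl$harmonic_weights
  axis_phase <- c(0, 2 * pi / 3, 4 * pi / 3)
  harmonics <- function(freq, extra_phase) {
    vapply(seq_along(hw), function(k) {
      sapply(axis_phase, function(ph)
        hw[k] * sin(2 * pi * k * freq * t + ph + extra_phase + phase0))
    }, matrix(0, 200, 3)) |> apply(c(1, 2), sum) |> t() # 3 x 200
  }
  env <- rep(1, 200)
  if (!is.null(tpl$duty_pattern)) {
    dp <- tpl$duty_pattern
    on <- ((t / dp$period_s) %% 1) < dp$on_frac
    env <- ifelse(on, 1, dp$off_level)
  }
  shared <- harmonics(f, 0)
  shared_q <- harmonics(f, pi / 2)                 # phase-shifted for gyro
  comp_f <- tpl$base_freq_hz * 1.35 + 0.2          # class-specific complement
  comp <- harmonics(comp_f * freq_mult, pi / 5)
  accel <- tpl$accel_amp * amp_mult[1] * shared
  gyro <- tpl$gyro_amp * amp_mult[2] *
    (coupling * shared_q + (1 - coupling) * comp)
  accel <- sweep(accel, 2, env, `*`)
  gyro <- sweep(gyro, 2, env, `*`)
  if (!is.null(walk_mix)) {
    accel <- accel + walk_mix$accel
    gyro <- gyro + walk_mix$gyro
  }
  list(accel = accel, gyro = gyro)
}

#' Generate a synthetic labeled IMU dataset
#'
#' Deterministic given the config seed: per-subject effects (a log-normal
#' amplitude multiplier per modality and a fixed +/-5 percent frequency
#' multiplier) are drawn first, then segments, so enlarging
#' `segments_per_subject` never perturbs subject identities.  Per-subject
#' class counts follow `class_proportions` under largest-remainder rounding.
#'
#' @param config An [generator_config()] object.
#' @param templates List of six [activity_template()] covering the registry
#'   (default [default_templates()]).
#' @return List of [sensor_segment()] objects.
#' @export
generate_dataset <- function(config, templates = default_templates()) {
  stopifnot(inherits(config, "imu_generator_config"))
  if (length(templates) != 6L)
    stop("need exactly 6 templates, got ", length(templates))
  tpl_names <- vapply(templates, function(t) t$name, "")
  if (!setequal(tpl_names, activity_classes()))
    stop("templates must cover the 6 registered classes exactly")
  templates <- templates[match(activity_classes(), tpl_names)]

  with_local_seed(config$seed, {
    ns <- config$n_subjects
    subject_ids <- sprintf("subject%02d", seq_len(ns))
    amp_mult <- matrix(exp(stats::rnorm(2 * ns, 0, config$subject_effect_sd)),
                       nrow = ns)                  # cols: accel, gyro
    freq_mult <- if (config$subject_effect_sd > 0)
      1 + stats::runif(ns, -config$freq_jitter, config$freq_jitter)
    else rep(1, ns)

    counts <- largest_remainder_counts(config$segments_per_subject,
                                       config$class_proportions)
    walk_tpl <- templates[[which(activity_classes() == "walking_natural")]]
    segments <- vector("list", ns * sum(counts))
    k <- 0L
    for (s in seq_len(ns)) {
      for (ci in seq_along(activity_classes())) {
        tpl <- templates[[ci]]
        for (r in seq_len(counts[ci])) {
          phase0 <- if (config$phase_jitter_sd > 0)
            stats::rnorm(1, 0, config$phase_jitter_sd) else 0
          walk_mix <- NULL
          if (tpl$name == "eating" && config$eating_walk_mix > 0) {
            wm <- template_signal(walk_tpl, amp_mult[s, ], freq_mult[s],
                                  config$coupling, phase0)
            walk_mix <- list(accel = config$eating_walk_mix * wm$accel,
                             gyro = config$eating_walk_mix * wm$gyro)
          }
          sig <- template_signal(tpl, amp_mult[s, ], freq_mult[s],
                                 config$coupling, phase0, walk_mix)
          if (tpl$noise_sd > 0) {
            sig$accel <- sig$accel + matrix(stats::rnorm(600, 0, tpl$noise_sd), 3)
            sig$gyro <- sig$gyro + matrix(stats::rnorm(600, 0, tpl$noise_sd), 3)
          }
          k <- k + 1L
          segments[[k]] <- sensor_segment(sig$accel, sig$gyro, tpl$name,
                                          subject_ids[s])
        }
      }
    }
    segments[seq_len(k)]
  })
}

# Run code with a fixed RNG seed, restoring the caller's RNG state afterwards.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
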