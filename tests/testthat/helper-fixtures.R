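# Shared fixtures, all generated in code.

# A deterministic segment with recognizable per-axis values.
manual_segment <- function(label = "eating", subject = "s1", offset = 0) {
  base <- outer(1:3, seq(0, 1.99, by = 0.01)) + offset
  sensor_segment(accel = base, gyro = -base / 2, label = label,
                 subject_id = subject)
}

# Small synthetic dataset shared by several tests.
small_dataset <- function(n_subjects = 3, per_subject = 12,
                          proportions = rep(1 / 6, 6), seed = 42,
                          noise_sd = 0.3) {
  generate_dataset(
    generator_config(n_subjects = n_subjects,
                     segments_per_subject = per_subject,
                     class_proportions = proportions, seed = seed),
    default_templates(noise_sd = noise_sd)
  )
}

tiny_model_config <- function(...) {
  model_config(widths = c(2L, 3L, 3L, 4L), cmim_hidden = 3L, fc_width = 5L,
               seed = 11L, ...)
}

subjects_of <- function(segments) {
  vapply(segments, function(s) s$subject_id, "")
}

labels_of <- function(segments) {
  vapply(segments, function(s) s$label, "")
}

# minimal functional setter used by finite-difference probes
set_in_tree <- function(tree, path, value) {
  k <- path[[1L]]
  if (length(path) == 1L) {
    tree[[k]] <- value
  } else {
    tree[[k]] <- set_in_tree(tree[[k]], path[-1L], value)
  }
  tree
}

random_batch <- function(B, seed = 1) {
  withr::with_seed(seed, list(
    accel = array(stats::rnorm(B * 3 * 200), c(B, 3, 200)),
    gyro = array(stats::rnorm(B * 3 * 200), c(B, 3, 200))
  ))
}
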