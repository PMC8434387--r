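#' Registered activity classes
#'
#' The six activities the classifier distinguishes, in the fixed alphabetical
#' order that defines the logit-index-to-class mapping everywhere in the
#' package: eating, galloping, standing, trotting, walking without a rider
#' (`walking_natural`), and walking under a rider (`walking_rider`).
#'
#' @return Character vector of length 6.
#' @export
#' @examples
#' activity_classes()
activity_classes <- function() {
  c("eating", "galloping", "standing", "trotting",
    "walking_natural", "walking_rider")
}

#' Encode activity labels as class indices
#'
#' @param labels Character vector (or factor) of activity names.
#' @return Integer vector in `1..6`, ordered by [activity_classes()].
#' @export
encode_labels <- function(labels) {
  idx <- match(as.character(labels), activity_classes())
  if (anyNA(idx)) {
    bad <- unique(as.character(labels)[is.na(idx)])
    stop("unknown activity label(s): ", paste(bad, collapse = ", "))
  }
  idx
}

#' Construct a labeled two-second sensor segment
#'
#' A segment is one 2 s window sampled at 100 Hz from a neck-attached inertial
#' measurement unit: a 3 x 200 accelerometer array and a 3 x 200 gyroscope
#' array (axes X/Y/Z by timestep), an activity label, and a subject identifier.
#'
#' @param accel Numeric 3 x 200 matrix, accelerometer axes by timestep.
#' @param gyro Numeric 3 x 200 matrix, gyroscope axes by timestep.
#' @param label One of [activity_classes()].
#' @param subject_id Non-empty scalar identifying the animal.
#' @return An object of class `sensor_segment`.
#' @export
sensor_segment <- function(accel, gyro, label, subject_id) {
  accel <- as.matrix(accel)
  gyro <- as.matrix(gyro)
  dimnames(accel) <- dimnames(gyro) <- NULL
  for (nm in c("accel", "gyro")) {
    x <- if (nm == "accel") accel else gyro
    if (!is.numeric(x) || !identical(dim(x), c(3L, 200L)))
      stop(nm, " must be a numeric 3 x 200 matrix")
    if (!all(is.finite(x)))
      stop(nm, " contains non-finite values")
  }
  label <- as.character(label)
  if (length(label) != 1L || !label %in% activity_classes())
    stop("label must be one of: ", paste(activity_classes(), collapse = ", "))
  subject_id <- as.character(subject_id)
  if (length(subject_id) != 1L || is.na(subject_id) || !nzchar(subject_id))
    stop("subject_id must be a non-empty scalar")
  structure(list(accel = accel, gyro = gyro, label = label,
                 subject_id = subject_id),
            class = "sensor_segment")
}

#' @export
print.sensor_segment <- function(x, ...) {
  cat("<sensor_segment> subject", x$subject_id, "label", x$label,
      sprintf("(accel rms %.3f, gyro rms %.3f)\n",
              sqrt(mean(x$accel^2)), sqrt(mean(x$gyro^2))))
  invisible(x)
}

segment_table_columns <- function() {
  c("subject_id", "segment_id", "label", "sample_index",
    "ax", "ay", "az", "gx", "gy", "gz")
}

#' Read a segment table from disk
#'
#' The on-disk form is a delimited text table with header
#' `subject_id,segment_id,label,sample_index,ax,ay,az,gx,gy,gz` and exactly
#' 200 rows (sample_index 0..199) per `(subject_id, segment_id)` pair.
#'
#' @param path Path to the segment table.
#' @param delim Field delimiter, comma by default.
#' @return List of [sensor_segment()] objects, one per distinct
#'   `(subject_id, segment_id)`.
#' @export
load_segments <- function(path, delim = ",") {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, sep = delim, header = TRUE)
  missing_cols <- setdiff(segment_table_columns(), names(dt))
  if (length(missing_cols))
    stop("segment table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(dt) == 0L) return(list())
  for (cc in c("subject_id", "segment_id", "label"))
    data.table::set(dt, j = cc, value = as.character(dt[[cc]]))
  bad_label <- setdiff(unique(dt$label), activity_classes())
  if (length(bad_label))
    stop("unknown label(s) in segment table: ", paste(bad_label, collapse = ", "))
  num_cols <- c("ax", "ay", "az", "gx", "gy", "gz")
  for (cc in num_cols) {
    v <- dt[[cc]]
    if (!is.numeric(v) || !all(is.finite(v))) {
      row <- which(!is.finite(suppressWarnings(as.numeric(v))))[1L]
      stop("non-finite or non-numeric value in column '", cc, "' at data row ", row)
    }
  }
  data.table::setorder(dt, subject_id, segment_id, sample_index)
  keys <- paste(dt$subject_id, dt$segment_id, sep = "\r")
  groups <- split(seq_len(nrow(dt)), factor(keys, levels = unique(keys)))
  lapply(groups, function(ix) {
    sub <- dt[ix]
    seg_name <- paste0("(", sub$subject_id[1L], ", ", sub$segment_id[1L], ")")
    if (nrow(sub) != 200L)
      stop("segment ", seg_name, " has ", nrow(sub), " rows; expected 200")
    if (!identical(as.integer(sub$sample_index), 0:199))
      stop("segment ", seg_name, " has sample_index not covering 0..199 in order")
    if (length(unique(sub$label)) != 1L)
      stop("segment ", seg_name, " has inconsistent labels")
    sensor_segment(
      accel = t(as.matrix(sub[, c("ax", "ay", "az")])),
      gyro = t(as.matrix(sub[, c("gx", "gy", "gz")])),
      label = sub$label[1L],
      subject_id = sub$subject_id[1L]
    )
  }) |> unname()
}

#' Write segments to a segment table
#'
#' Inverse of [load_segments()]: emits the delimited segment-table format with
#' full-precision floats, so a write/load round trip reproduces segment values
#' exactly (to at least 9 significant digits, in practice bit-exactly).
#'
#' @param segments List of [sensor_segment()] objects.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path, delim = ",") {
  stopifnot(is.list(segments))
  if (length(segments) == 0L) {
    writeLines(paste(segment_table_columns(), collapse = delim), path)
    return(invisible(path))
  }
  ids <- make.unique(vapply(segments, function(s) s$subject_id, ""), sep = "\r")
  tabs <- lapply(seq_along(segments), function(i) {
    s <- segments[[i]]
    if (!inherits(s, "sensor_segment")) stop("element ", i, " is not a sensor_segment")
    data.table::data.table(
      subject_id = s$subject_id,
      segment_id = sprintf("seg%05d", i),
      label = s$label,
      sample_index = 0:199,
      ax = s$accel[1L, ], ay = s$accel[2L, ], az = s$accel[3L, ],
      gx = s$gyro[1L, ], gy = s$gyro[2L, ], gz = s$gyro[3L, ]
    )
  })
  data.table::fwrite(data.table::rbindlist(tabs), path, sep = delim)
  invisible(path)
}

axis_names <- function() c("ax", "ay", "az", "gx", "gy", "gz")

#' Fit per-axis standardization statistics
#'
#' Computes the mean and population standard deviation of every axis of each
#' modality (accelerometer X/Y/Z, gyroscope X/Y/Z) pooled over all timesteps
#' of all supplied segments.  Applying the resulting statistics removes the
#' mean and scales to unit variance per axis.  To avoid evaluation leakage the
#' training protocol fits these on training-subject segments only (see
#' [train_fold()]).
#'
#' @param segments Non-empty list of [sensor_segment()] objects.
#' @return Object of class `imu_norm_stats`: list with `means` and `stds`,
#'   each a named numeric of length 6 in order `ax,ay,az,gx,gy,gz`.
#' @export
fit_normalization <- function(segments) {
  if (!is.list(segments) || length(segments) == 0L)
    stop("fit_normalization needs a non-empty list of segments")
  acc <- vapply(segments, function(s) s$accel, matrix(0, 3, 200))
  gyr <- vapply(segments, function(s) s$gyro, matrix(0, 3, 200))
  pool <- rbind(matrix(acc, nrow = 3L), matrix(gyr, nrow = 3L)) # 6 x (200*B)
  means <- rowMeans(pool)
  stds <- sqrt(rowMeans(pool^2) - means^2) # population sd
  degenerate <- stds <= 0 | !is.finite(stds)
  if (any(degenerate)) {
    warning("zero-variance axis(es) ", paste(axis_names()[degenerate], collapse = ", "),
            "; substituting sd = 1")
    stds[degenerate] <- 1
  }
  structure(list(means = stats::setNames(means, axis_names()),
                 stds = stats::setNames(stds, axis_names())),
            class = "imu_norm_stats")
}

#' @export
print.imu_norm_stats <- function(x, ...) {
  cat("<imu_norm_stats>\n")
  print(round(rbind(mean = x$means, sd = x$stds), 4))
  invisible(x)
}

#' Standardize a segment (or list of segments)
#'
#' Applies the per-axis affine transform `(x - mean) / sd` from fitted
#' statistics.  The input is not mutated; labels and subject ids pass through.
#'
#' @param segments A [sensor_segment()] or list thereof.
#' @param stats An `imu_norm_stats` object from [fit_normalization()].
#' @param invert If `TRUE`, applies the inverse transform `x * sd + mean`.
#' @return Object(s) of the same shape as the input.
#' @export
apply_normalization <- function(segments, stats, invert = FALSE) {
  stopifnot(inherits(stats, "imu_norm_stats"))
  one <- function(s) {
    stopifnot(inherits(s, "sensor_segment"))
    m <- stats$means; sd <- stats$stds
    if (invert) {
      s$accel <- s$accel * sd[1:3] + m[1:3]
      s$gyro <- s$gyro * sd[4:6] + m[4:6]
    } else {
      s$accel <- (s$accel - m[1:3]) / sd[1:3]
      s$gyro <- (s$gyro - m[4:6]) / sd[4:6]
    }
    s
  }
  if (inherits(segments, "sensor_segment")) one(segments) else lapply(segments, one)
}

#' Save / load standardization statistics
#'
#' @param stats An `imu_norm_stats` object.
#' @param path YAML file path.
#' @return `save_normalization` returns `path` invisibly; `load_normalization`
#'   returns the `imu_norm_stats` object.
#' @export
save_normalization <- function(stats, path) {
  stopifnot(inherits(stats, "imu_norm_stats"))
  yaml::write_yaml(list(means = as.list(stats$means),
                        stds = as.list(stats$stds)),
                   path, precision = 15L)
  invisible(path)
}

#' @rdname save_normalization
#' @export
load_normalization <- function(path) {
  y <- yaml::read_yaml(path)
  means <- unlist(y$means)[axis_names()]
  stds <- unlist(y$stds)[axis_names()]
  if (anyNA(means) || anyNA(stds) || any(stds <= 0))
    stop("malformed normalization stats file: ", path)
  structure(list(means = means, stds = stds), class = "imu_norm_stats")
}

#' Class distribution and imbalance ratio
#'
#' Counts segments per registered class and reports the imbalance ratio, the
#' largest class count divided by the smallest *non-zero* class count (the
#' study dataset's ratio is 10.25).  Classes with zero segments are excluded
#' from the ratio and listed separately.
#'
#' @param segments List of [sensor_segment()] objects (or a character vector
#'   of labels).
#' @return List with `counts` (named integer over all registered classes),
#'   `total`, `imbalance_ratio` (full precision), and `zero_classes`.
#' @export
class_distribution <- function(segments) {
  labels <- if (is.character(segments)) segments
  else vapply(segments, function(s) s$label, "")
  if (length(labels) == 0L) stop("class_distribution needs a non-empty input")
  encode_labels(labels) # validates
  counts <- table(factor(labels, levels = activity_classes()))
  counts <- stats::setNames(as.integer(counts), activity_classes())
  nonzero <- counts[counts > 0L]
  list(counts = counts,
       total = sum(counts),
       imbalance_ratio = max(nonzero) / min(nonzero),
       zero_classes = names(counts)[counts == 0L])
}
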