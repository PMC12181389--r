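# Seeded generator of synthetic multi-finger tremor recordings and their
# 640x10 grayscale image encodings. The generator emulates the sensor output
# format (10 fingers sampled at 128 Hz for 5 s, one image row per finger) and
# the four-class severity scheme; it is a format stand-in, not a claim about
# tremor physiology.

#' Signal-model parameters for the synthetic generator
#'
#' Each subject has one dominant tremor frequency drawn uniformly from the
#' 4-12 Hz band. Severity classes differ by oscillation amplitude; Healthy has
#' zero tremor amplitude (noise and baseline drift only). Units are normalized
#' signal units (the image encoder maps `[-clip_range, clip_range]` onto the
#' 8-bit gray scale).
#'
#' @param fs sampling rate in Hz (default 128).
#' @param duration recording length in seconds (default 5).
#' @param fingers number of sensor channels / image rows (default 10).
#' @param f0_range tremor-frequency band in Hz (default `c(4, 12)`).
#' @param class_amps per-class oscillation amplitudes, Healthy..Severe
#'   (default `c(0, 0.15, 0.40, 0.80)`, strictly increasing).
#' @param harmonic2 relative weight of the second harmonic (default 0.3).
#' @param phase_jitter sd (radians) of per-finger phase offsets around the
#'   subject's base phase (default 0.5).
#' @param drift_amp amplitude of the slow baseline drift (default 0.02).
#' @param noise_sd white-noise standard deviation (default 0.05).
#' @param clip_range symmetric amplitude bound of the image encoder (default 1).
#' @return list of class `signal_params`.
#' @export
signal_params <- function(fs = 128, duration = 5, fingers = 10,
                          f0_range = c(4, 12),
                          class_amps = c(0, 0.15, 0.40, 0.80),
                          harmonic2 = 0.3, phase_jitter = 0.5,
                          drift_amp = 0.02, noise_sd = 0.05,
                          clip_range = 1) {
  if (length(class_amps) != 4L || any(diff(class_amps) <= 0)) {
    qt_stop("class_amps must be 4 strictly increasing amplitudes",
            class = "qtremor_domain_error")
  }
  if (f0_range[1] < 0 || f0_range[2] <= f0_range[1]) {
    qt_stop("invalid f0_range", class = "qtremor_domain_error")
  }
  structure(list(fs = fs, duration = duration, fingers = as.integer(fingers),
                 f0_range = f0_range, class_amps = class_amps,
                 harmonic2 = harmonic2, phase_jitter = phase_jitter,
                 drift_amp = drift_amp, noise_sd = noise_sd,
                 clip_range = clip_range),
            class = "signal_params")
}

#' Simulate one multi-finger tremor recording
#'
#' Per finger f: `s_f(t) = A_cls * [sin(2 pi f0 t + phi_f) + h2 * sin(4 pi f0 t
#' + phi'_f)] + drift_f(t) + sigma * eps_f(t)`, with the subject's `f0` drawn
#' from the 4-12 Hz band and the Healthy class having `A = 0`.
#'
#' @param cls class label 0..3 (Healthy, Mild, Moderate, Severe).
#' @param params a [signal_params()].
#' @param seed integer seed (fully determines the recording).
#' @return `tremor_recording`: a `fingers x (fs*duration)` numeric matrix with
#'   attributes `label`, `seed`, `f0` and `params`.
#' @export
simulate_recording <- function(cls, params = signal_params(), seed = NULL) {
  if (!is.numeric(cls) || length(cls) != 1L || !cls %in% 0:3) {
    qt_stop("cls must be a class label in 0..3", class = "qtremor_domain_error")
  }
  n <- round(params$fs * params$duration)
  t <- (seq_len(n) - 1L) / params$fs
  A <- params$class_amps[cls + 1L]
  rec <- with_seed(seed, {
    f0 <- runif(1, params$f0_range[1], params$f0_range[2])
    base_phase <- runif(1, 0, 2 * pi)
    out <- matrix(0, params$fingers, n)
    for (f in seq_len(params$fingers)) {
      ph1 <- base_phase + rnorm(1, 0, params$phase_jitter)
      ph2 <- runif(1, 0, 2 * pi)
      drift_f <- runif(1, 0.1, 0.5)          # slow baseline wander, Hz
      drift_ph <- runif(1, 0, 2 * pi)
      out[f, ] <- A * (sin(2 * pi * f0 * t + ph1) +
                       params$harmonic2 * sin(4 * pi * f0 * t + ph2)) +
        params$drift_amp * sin(2 * pi * drift_f * t + drift_ph) +
        params$noise_sd * rnorm(n)
    }
    attr(out, "f0") <- f0
    out
  })
  structure(rec, class = "tremor_recording", label = as.integer(cls),
            seed = seed, params = params)
}

#' Encode a recording as an 8-bit grayscale tremor image
#'
#' Affine clip-and-quantize: `pixel = round(255 * clip(0.5 + s / (2 *
#' clip_range), 0, 1))`, so zero signal maps to mid-gray 128 and the full
#' `[-clip_range, clip_range]` swing spans the 8-bit range.
#'
#' @param rec a [simulate_recording()] result (or plain numeric matrix).
#' @param clip_range symmetric amplitude bound (> 0).
#' @return `tremor_image`: integer matrix (same shape) with values in 0..255
#'   and the label carried over.
#' @export
encode_image <- function(rec, clip_range = 1) {
  if (!is.numeric(clip_range) || clip_range <= 0) {
    qt_stop("clip_range must be > 0", class = "qtremor_domain_error")
  }
  if (any(!is.finite(rec))) qt_stop("signal must be finite", class = "qtremor_domain_error")
  px <- round(255 * pmin(pmax(0.5 + unclass(rec) / (2 * clip_range), 0), 1))
  structure(matrix(as.integer(px), nrow(rec), ncol(rec)),
            class = "tremor_image",
            label = attr(rec, "label"), seed = attr(rec, "seed"))
}

#' Normalized `[0, 1]` view of a tremor image
#'
#' @param img a `tremor_image`.
#' @return numeric matrix, `pixel / 255`.
#' @export
normalized_pixels <- function(img) {
  unclass(img) / 255
}

#' @export
print.tremor_image <- function(x, ...) {
  cat(sprintf("<tremor_image %dx%d, label %s>\n", nrow(x), ncol(x),
              attr(x, "label") %||% "NA"))
  invisible(x)
}

#' Generate a labeled synthetic dataset
#'
#' Draws near-balanced class labels (largest-remainder allocation of
#' `class_proportions`), simulates one recording per image, encodes the 8-bit
#' images, and assigns stratified train/validation/test splits. For `n = 193`
#' the split sizes are the sensor study's reported 153/17/23; otherwise
#' validation and test each get `floor(n/10)` images and the remainder trains.
#'
#' @param n number of images (default 193).
#' @param class_proportions length-4 proportions summing to 1 (default equal).
#' @param params a [signal_params()].
#' @param seed integer base seed; the dataset is a pure function of
#'   `(params, seed)`.
#' @return `labeled_dataset`: list with `images` (list of `tremor_image`),
#'   `labels` (integer 0..3), `split` (factor train/val/test), `manifest`
#'   (per-image seed and dominant frequency) and the generation parameters.
#' @export
generate_dataset <- function(n = 193L, class_proportions = rep(0.25, 4),
                             params = signal_params(), seed = 1L) {
  if (n < 8) qt_stop("n must be >= 8", class = "qtremor_domain_error")
  if (length(class_proportions) != 4L || any(class_proportions < 0) ||
      abs(sum(class_proportions) - 1) > 1e-8) {
    qt_stop("class_proportions must be 4 non-negative values summing to 1",
            class = "qtremor_domain_error")
  }
  # largest-remainder class counts
  raw <- n * class_proportions
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    give <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[give] <- cnt[give] + 1
  }
  labels <- rep(0:3, times = cnt)

  images <- vector("list", n)
  f0s <- numeric(n)
  seeds <- vapply(seq_len(n), function(i) derive_seed(seed, 101L, i), integer(1))
  for (i in seq_len(n)) {
    rec <- simulate_recording(labels[i], params, seeds[i])
    f0s[i] <- attr(rec, "f0")
    images[[i]] <- encode_image(rec, params$clip_range)
  }

  if (n == 193L) {
    n_val <- 17L; n_test <- 23L
  } else {
    n_val <- n %/% 10L; n_test <- n %/% 10L
  }
  # stratified assignment: shuffle within class, interleave classes, then slice
  ord <- with_seed(derive_seed(seed, 202L), {
    by_class <- lapply(0:3, function(c) sample(which(labels == c)))
    len <- max(lengths(by_class))
    idx <- unlist(lapply(seq_len(len), function(r) {
      vapply(by_class, function(v) if (r <= length(v)) v[r] else NA_integer_, integer(1))
    }))
    idx[!is.na(idx)]
  })
  split <- rep("train", n)
  split[ord[seq_len(n_test)]] <- "test"
  split[ord[n_test + seq_len(n_val)]] <- "val"
  structure(list(images = images, labels = as.integer(labels),
                 split = factor(split, levels = c("train", "val", "test")),
                 manifest = data.frame(index = seq_len(n), label = labels,
                                       split = split, seed = seeds, f0 = f0s),
                 params = params, seed = as.integer(seed)),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset: %d images (%s), classes %s>\n",
              length(x$images),
              paste(table(x$split), collapse = "/"),
              paste(table(x$labels), collapse = "/")))
  invisible(x)
}

#' Write / read a dataset directory
#'
#' One 8-bit grayscale PNG per image plus a CSV manifest (filename, label,
#' split, seed) and a JSON snapshot of the generation parameters. Reading back
#' is pixel- and label-exact.
#'
#' @param ds a `labeled_dataset`.
#' @param dir target directory (created if missing).
#' @return invisibly, the manifest path.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(ds$images)
  files <- sprintf("img_%04d.png", seq_len(n))
  for (i in seq_len(n)) {
    png::writePNG(normalized_pixels(ds$images[[i]]), file.path(dir, files[i]))
  }
  man <- cbind(data.frame(file = files), ds$manifest)
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(c(unclass(ds$params), list(seed = ds$seed)),
                       file.path(dir, "params.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(file.path(dir, "manifest.csv"))
}

#' @rdname write_dataset
#' @param dir dataset directory containing `manifest.csv` and the PNGs.
#' @export
read_dataset <- function(dir) {
  man_path <- file.path(dir, "manifest.csv")
  if (!file.exists(man_path)) {
    qt_stop("missing manifest: ", man_path, class = "qtremor_io_error")
  }
  man <- read.csv(man_path)
  params_path <- file.path(dir, "params.json")
  params <- if (file.exists(params_path)) {
    pj <- jsonlite::read_json(params_path, simplifyVector = TRUE)
    do.call(signal_params, pj[setdiff(names(pj), "seed")])
  } else signal_params()
  images <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    f <- file.path(dir, man$file[i])
    if (!file.exists(f)) qt_stop("missing image file: ", f, class = "qtremor_io_error")
    px <- round(png::readPNG(f) * 255)
    images[[i]] <- structure(matrix(as.integer(px), nrow(px), ncol(px)),
                             class = "tremor_image",
                             label = man$label[i], seed = man$seed[i])
  }
  structure(list(images = images, labels = as.integer(man$label),
                 split = factor(man$split, levels = c("train", "val", "test")),
                 manifest = man[, setdiff(names(man), "file")],
                 params = params, seed = NA_integer_),
            class = "labeled_dataset")
}

#' Bilinear image resize
#'
#' @param mat numeric matrix (values in `[0, 1]`).
#' @param h,w output height and width.
#' @return resized matrix, values clipped back to `[0, 1]`.
#' @export
resize_image <- function(mat, h, w) {
  out <- EBImage::resize(mat, w = h, h = w, filter = "bilinear")
  pmin(pmax(out, 0), 1)
}

#' Dominant frequency of a signal by periodogram argmax
#'
#' @param x numeric signal vector.
#' @param fs sampling rate in Hz.
#' @param min_freq frequencies below this are ignored (default 1 Hz, excluding
#'   DC and baseline drift).
#' @return frequency in Hz of the largest periodogram ordinate.
#' @export
dominant_frequency <- function(x, fs, min_freq = 1) {
  n <- length(x)
  spec <- Mod(stats::fft(x - mean(x)))^2
  freq <- (seq_len(n) - 1L) * fs / n
  keep <- freq >= min_freq & freq <= fs / 2
  freq[keep][which.max(spec[keep])]
}
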