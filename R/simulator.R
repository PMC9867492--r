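AMBIENT_LEVELS <- c(18, 21, 24, 27, 30)

#' Scenario configuration
#'
#' One synthetic bathroom scene, defined by the factor grid of the test
#' design: five ambient temperatures crossed with six binary factors and
#' the fall / non-fall label.  Non-fall scenes map onto four activity
#' types covering the behaviours the detector must not alarm on:
#' \describe{
#'   \item{shower + sitting}{a normal shower (person standing with
#'     micro-movements next to the warm-water patch)}
#'   \item{shower + lying}{shower only, no person (residual warm water)}
#'   \item{no shower + sitting}{squat-and-rise}
#'   \item{no shower + lying}{walk-through}
#' }
#'
#' @param ambient_c Ambient temperature: 18, 21, 24, 27 or 30 (degrees C).
#' @param objective `"female_160"` or `"male_180"` (controls blob size).
#' @param illumination `"led"` (flat background) or `"sunlight"` (adds a
#'   lateral background gradient).
#' @param speed `"fast"` (0.5 s fall) or `"slow"` (2.5 s two-stage fall
#'   with a mid pause).
#' @param state Post-fall posture, `"sitting"` (area ratio ~0.85) or
#'   `"lying"` (~0.6).
#' @param area Pre-fall position, `"boundary"` or `"center"`.
#' @param scene `"shower"` (adds a static warm patch) or `"no_shower"`.
#' @param label `"fall"` or `"non_fall"`.
#' @param noise_sigma Gaussian pixel noise sd in degrees C (default 0.3,
#'   a typical thermopile NETD scale).
#' @param seed RNG seed; streams are bit-identical given the seed.
#' @param duration_s Stream length in seconds (default 120).
#' @param fs Sampling rate in Hz (default 5).
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(ambient_c = 24,
                            objective = c("female_160", "male_180"),
                            illumination = c("led", "sunlight"),
                            speed = c("fast", "slow"),
                            state = c("sitting", "lying"),
                            area = c("boundary", "center"),
                            scene = c("shower", "no_shower"),
                            label = c("fall", "non_fall"),
                            noise_sigma = 0.3, seed = 1,
                            duration_s = 120, fs = 5) {
  if (!ambient_c %in% AMBIENT_LEVELS)
    stop("`ambient_c` must be one of ", paste(AMBIENT_LEVELS, collapse = ", "),
         call. = FALSE)
  if (duration_s <= 0 || fs <= 0)
    stop("`duration_s` and `fs` must be positive", call. = FALSE)
  structure(
    list(ambient_c = ambient_c, objective = match.arg(objective),
         illumination = match.arg(illumination), speed = match.arg(speed),
         state = match.arg(state), area = match.arg(area),
         scene = match.arg(scene), label = match.arg(label),
         noise_sigma = noise_sigma, seed = as.integer(seed),
         duration_s = duration_s, fs = fs),
    class = "scenario_config"
  )
}

ellipse_mask <- function(r0, c0, ar, ac) {
  rr <- matrix(seq_len(GRID_DIM), GRID_DIM, GRID_DIM)
  cc <- t(rr)
  ((rr - r0) / ar)^2 + ((cc - c0) / ac)^2 <= 1
}

# Per-frame body placement for each activity; returns a data.frame of
# r0, c0, ar, ac, present for the n frames.  Times in seconds.
body_path <- function(config, times) {
  n <- length(times)
  D <- config$duration_s
  semi <- switch(config$objective,
                 female_160 = c(ar = 4.5, ac = 3.0),
                 male_180   = c(ar = 5.5, ac = 3.5))
  c_pre <- if (config$area == "center") 16 else 6.5
  r_pre <- 10
  path <- data.frame(r0 = rep(r_pre, n), c0 = rep(c_pre, n),
                     ar = rep(semi["ar"], n), ac = rep(semi["ac"], n),
                     present = rep(TRUE, n))
  jitter_c <- rep_len(c(0.3, -0.3), n)        # alternating micro-motion

  activity <- if (config$label == "fall") "fall" else
    switch(paste(config$scene, config$state, sep = "."),
           shower.sitting    = "normal_shower",
           shower.lying      = "shower_only",
           no_shower.sitting = "squat_rise",
           no_shower.lying   = "walk_through")

  if (activity == "fall") {
    t0 <- 0.35 * D
    fall_dur <- if (config$speed == "fast") 0.5 else 2.5
    settle <- 2.5
    r_post <- 21
    c_post <- c_pre + 0.6
    shape <- if (config$state == "lying") c(0.55, 1.10) else c(0.80, 1.06)
    for (k in seq_len(n)) {
      t <- times[k]
      if (t < t0) next
      if (t < t0 + fall_dur) {
        frac <- if (config$speed == "fast") (t - t0) / fall_dur else {
          # two-stage descent with a mid pause (0.95 s / 0.6 s / 0.95 s)
          tt <- t - t0
          if (tt < 0.95) 0.6 * tt / 0.95
          else if (tt < 1.55) 0.6
          else 0.6 + 0.4 * (tt - 1.55) / 0.95
        }
        path$r0[k] <- r_pre + frac * (r_post - r_pre)
        path$c0[k] <- c_pre + frac * (c_post - c_pre)
        path$ar[k] <- semi["ar"] * (1 + frac * (shape[1] - 1))
        path$ac[k] <- semi["ac"] * (1 + frac * (shape[2] - 1))
      } else {
        path$r0[k] <- r_post
        path$ar[k] <- semi["ar"] * shape[1]
        path$ac[k] <- semi["ac"] * shape[2]
        path$c0[k] <- c_post +
          if (t < t0 + fall_dur + settle) jitter_c[k] else 0
      }
    }
    # the fall action completes when the body comes to rest (descent plus
    # post-impact settling)
    attr(path, "fall_time_s") <- t0 + fall_dur + settle
    attr(path, "pre") <- c(r0 = r_pre, c0 = c_pre, semi)
    attr(path, "post") <- c(r0 = r_post, c0 = c_post,
                            ar = unname(semi["ar"]) * shape[1],
                            ac = unname(semi["ac"]) * shape[2])
  } else if (activity == "squat_rise") {
    t0 <- 0.3 * D
    mv <- if (config$speed == "fast") 1 else 2   # descent / rise duration
    hold <- 4
    drop <- 3                                    # << LY/2: not a fall drop
    for (k in seq_len(n)) {
      t <- times[k]
      frac <-
        if (t < t0) 0
        else if (t < t0 + mv) (t - t0) / mv
        else if (t < t0 + mv + hold) 1
        else if (t < t0 + 2 * mv + hold) 1 - (t - t0 - mv - hold) / mv
        else 0
      path$r0[k] <- r_pre + frac * drop
      path$ar[k] <- semi["ar"] * (1 - 0.1 * frac)
      path$ac[k] <- semi["ac"] * (1 - 0.1 * frac)
    }
  } else if (activity == "walk_through") {
    t0 <- 0.3 * D
    cross <- if (config$speed == "fast") 8 else 16
    for (k in seq_len(n)) {
      t <- times[k]
      if (t < t0 || t > t0 + cross) {
        path$present[k] <- FALSE
      } else {
        path$r0[k] <- 12
        path$c0[k] <- -4 + 40 * (t - t0) / cross
      }
    }
  } else if (activity == "shower_only") {
    path$present <- FALSE
  } else if (activity == "normal_shower") {
    path$r0 <- 11
    path$c0 <- if (config$area == "center") 16 else 9
    # brief micro-movement bursts every 2 s while washing
    frame_in_cycle <- (seq_len(n) - 1L) %% as.integer(2 * config$fs)
    burst <- frame_in_cycle < 3L
    path$c0 <- path$c0 + ifelse(burst, jitter_c, 0)
  }
  attr(path, "activity") <- activity
  path
}

#' Generate one synthetic scenario stream
#'
#' Renders a stream of 32x32 temperature frames: ambient background plus
#' an illumination gradient and Gaussian pixel noise, a uniform-temperature
#' elliptical body blob (34.5-36 degrees C, never above the 40 degree
#' abnormal-pixel bound), and, in shower scenes, a static warm patch that
#' is confusable (38 degrees C) on even seeds and filterable (42 degrees
#' C, i.e. deleted by the abnormal-pixel rule) on odd seeds.  Fall
#' scenarios translate the blob down by more than half its row span and
#' shrink its area to a ratio inside (0.5, 1) over the speed-dependent
#' duration, followed by 2.5 s of settling micro-motion; the raw PIR
#' channel is 1 on frames where the body centre moved at least 0.5 px.
#' Streams are bit-identical given the seed.
#'
#' @param config A [scenario_config()].
#' @return `list(stream = <frame_stream>, truth = <scenario_truth>)`; the
#'   truth carries `fall_time_s` (onset completion; `NA` for non-falls),
#'   the rendered `rnc` (post/pre pixel-count ratio) and `dsy_ratio`
#'   (|centre drop| / pre-fall row span), and the `activity` rendered.
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  n <- as.integer(round(config$duration_s * config$fs))
  times <- (seq_len(n) - 1) / config$fs

  with_seed(config$seed, {
    body_temp <- stats::runif(1, 34.5, 36)
    grad <- if (config$illumination == "sunlight")
      matrix(seq(-0.75, 0.75, length.out = GRID_DIM),
             GRID_DIM, GRID_DIM, byrow = TRUE)
    else matrix(0, GRID_DIM, GRID_DIM)
    patch <- NULL
    if (config$scene == "shower") {
      patch <- list(mask = ellipse_mask(28.5, 5, 2.2, 2.2),
                    temp = if (config$seed %% 2 == 0) 38 else 42)
    }
    path <- body_path(config, times)

    frames <- vector("list", n)
    prev_center <- NULL
    for (k in seq_len(n)) {
      g <- matrix(config$ambient_c, GRID_DIM, GRID_DIM) + grad
      if (!is.null(patch)) g[patch$mask] <- patch$temp
      pir <- 0L
      if (path$present[k]) {
        g[ellipse_mask(path$r0[k], path$c0[k], path$ar[k], path$ac[k])] <-
          body_temp
        ctr <- c(path$r0[k], path$c0[k])
        if (!is.null(prev_center) &&
            sqrt(sum((ctr - prev_center)^2)) >= 0.5) pir <- 1L
        prev_center <- ctr
      } else {
        prev_center <- NULL
      }
      if (config$noise_sigma > 0)
        g <- g + matrix(stats::rnorm(N_PIXELS, 0, config$noise_sigma),
                        GRID_DIM, GRID_DIM)
      frames[[k]] <- thermal_frame(g, ambient = config$ambient_c,
                                   timestamp = times[k], pir = pir)
    }

    truth <- list(activity = attr(path, "activity"),
                  fall_time_s = NA_real_, rnc = NA_real_,
                  dsy_ratio = NA_real_)
    if (config$label == "fall") {
      pre <- attr(path, "pre"); post <- attr(path, "post")
      pre_mask <- ellipse_mask(pre["r0"], pre["c0"], pre["ar"], pre["ac"])
      post_mask <- ellipse_mask(post["r0"], post["c0"], post["ar"], post["ac"])
      pre_rows <- range(which(apply(pre_mask, 1, any)))
      ly <- diff(pre_rows) + 1
      pre_center_r <- mean(which(pre_mask, arr.ind = TRUE)[, 1])
      post_center_r <- mean(which(post_mask, arr.ind = TRUE)[, 1])
      truth$fall_time_s <- attr(path, "fall_time_s")
      truth$rnc <- sum(post_mask) / sum(pre_mask)
      truth$dsy_ratio <- abs(post_center_r - pre_center_r) / ly
      truth$ly <- ly
      truth$n_pre <- sum(pre_mask)
      truth$n_post <- sum(post_mask)
    }

    meta <- config[c("ambient_c", "objective", "illumination", "speed",
                     "state", "area", "scene")]
    list(stream = frame_stream(frames, fs = config$fs, label = config$label,
                               scenario_meta = meta),
         truth = structure(truth, class = "scenario_truth"))
  })
}

#' The full factorial scenario plan
#'
#' Crosses the five ambient levels with the six binary factors and the
#' fall / non-fall label: 5 x 2^6 x 2 = 640 scenarios, 128 per ambient
#' level, 64 falls and 64 non-falls per level.  Per-scenario seeds are
#' derived deterministically from `base_seed`, so two plans with different
#' base seeds differ only in their seed column.
#'
#' @param base_seed Integer master seed.
#' @param duration_s,noise_sigma,fs Passed to every scenario.
#' @return A `data.frame` (the dataset manifest) with columns `file`,
#'   `label`, `ambient_level`, `objective`, `illumination`, `speed`,
#'   `state`, `area`, `scene`, `seed`.
#' @export
scenario_grid <- function(base_seed = 1, duration_s = 120,
                          noise_sigma = 0.3, fs = 5) {
  grid <- expand.grid(
    label = c("fall", "non_fall"),
    objective = c("female_160", "male_180"),
    illumination = c("led", "sunlight"),
    speed = c("fast", "slow"),
    state = c("sitting", "lying"),
    area = c("boundary", "center"),
    scene = c("shower", "no_shower"),
    ambient_level = AMBIENT_LEVELS,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid$seed <- with_seed(base_seed,
                         sample.int(.Machine$integer.max, nrow(grid)))
  grid$file <- sprintf("scenario_%03d.csv", seq_len(nrow(grid)))
  grid$duration_s <- duration_s
  grid$noise_sigma <- noise_sigma
  grid$fs <- fs
  grid[c("file", "label", "ambient_level", "objective", "illumination",
         "speed", "state", "area", "scene", "seed", "duration_s",
         "noise_sigma", "fs")]
}

manifest_config <- function(row) {
  scenario_config(ambient_c = row$ambient_level, objective = row$objective,
                  illumination = row$illumination, speed = row$speed,
                  state = row$state, area = row$area, scene = row$scene,
                  label = row$label, noise_sigma = row$noise_sigma,
                  seed = row$seed, duration_s = row$duration_s, fs = row$fs)
}

#' Generate (and optionally write) the full 640-scenario dataset
#'
#' Materializes every scenario of [scenario_grid()] as a frame-csv file in
#' `dir` plus a `manifest.csv`, the layout consumed by [run_cv()].
#'
#' @param dir Output directory (created if needed).
#' @param base_seed Master seed.
#' @param duration_s Stream length in seconds (default 120; evaluation
#'   harnesses typically use shorter streams).
#' @param noise_sigma Pixel noise sd (degrees C).
#' @param fs Sampling rate (Hz).
#' @param materialize If `FALSE`, no streams are rendered and only the
#'   manifest data.frame is returned (design inspection).
#' @return The manifest `data.frame`, invisibly when materialized.
#' @export
generate_dataset <- function(dir = NULL, base_seed = 1, duration_s = 120,
                             noise_sigma = 0.3, fs = 5, materialize = TRUE) {
  manifest <- scenario_grid(base_seed, duration_s, noise_sigma, fs)
  if (!materialize) return(manifest)
  if (is.null(dir)) stop("`dir` is required to materialize a dataset",
                         call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(manifest))) {
    sc <- generate_scenario(manifest_config(manifest[i, ]))
    write_stream(sc$stream, file.path(dir, manifest$file[i]))
  }
  data.table::fwrite(manifest, file.path(dir, "manifest.csv"), eol = "\n")
  invisible(manifest)
}
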