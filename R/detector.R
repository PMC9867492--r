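#' Detector configuration
#'
#' Tunable conventions of the streaming fall detector.  The numeric gates
#' of the fall-action set/reset rules are fixed properties of the method
#' and are not configurable.
#'
#' @param std_estimator `"population"` (default; divide by n) or `"sample"`
#'   (divide by n-1) for all rolling standard deviations.
#' @param strict_signs If `TRUE`, the set/reset difference conditions use
#'   the one-sided (signed) comparisons exactly as printed in the rule
#'   listings; the default applies absolute values to the centre and
#'   temperature differences as the accompanying prose describes.
#'   `Tc - Tc0` and `Nc - Nc0` in the reset rule are one-sided growth
#'   checks in both modes.
#' @param stable_push_dist Minimum centre displacement (px) between the
#'   anchored stable snapshot and a new stable frame for the frame to
#'   count as a *new* stable moment (snapshot push); below it the frame is
#'   treated as the same posture, so a continuously stable body does not
#'   self-compare every frame.
#' @param stable_confirm_s Minimum duration (s) a stable episode must
#'   survive before it is committed as a new stable moment; shorter
#'   stability blips (e.g. the mid pause of a slow, staged fall) are
#'   discarded rather than anchored.
#' @param pir_hold_s PIR hold time in seconds (activity latches SPIR = 1
#'   for this long after the last raw pulse).
#' @param tbm_window_s Sliding window (s) over which body-movement time
#'   `tbm` is accumulated.
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(std_estimator = c("population", "sample"),
                            strict_signs = FALSE,
                            stable_push_dist = 1,
                            stable_confirm_s = 1,
                            pir_hold_s = 2,
                            tbm_window_s = 60) {
  structure(
    list(std_estimator = match.arg(std_estimator),
         strict_signs = strict_signs,
         stable_push_dist = stable_push_dist,
         stable_confirm_s = stable_confirm_s,
         pir_hold_s = pir_hold_s,
         tbm_window_s = tbm_window_s),
    class = "detector_config"
  )
}

roll_std <- function(x, estimator) {
  n <- length(x)
  if (n < 2) return(0)
  if (estimator == "population") sqrt(mean((x - mean(x))^2))
  else stats::sd(x)
}

#' Fresh detector state
#'
#' Holds every persistent quantity of the streaming state machine: the
#' rolling centre buffer, per-frame area/temperature buffers, the two
#' stable snapshots, the fall-action flag with its latched reference values
#' and duration timer, and the PIR hold/sliding-window bookkeeping.
#'
#' @param fs Sampling rate in Hz.
#' @param config A [detector_config()].
#' @return A list of class `detector_state`.
#' @export
new_detector_state <- function(fs = 5, config = detector_config()) {
  structure(
    list(fs = fs, config = config,
         track = list(xc = NA_real_, yc = NA_real_,
                      dxc = NA_real_, dyc = NA_real_,
                      buffer = matrix(numeric(0), 0, 2),
                      std_xc = 0, std_yc = 0,
                      m_xc = NA_real_, m_yc = NA_real_),
         nc_buf = numeric(0), tc_buf = numeric(0),
         prev_stable = NULL, curr_stable = NULL, stable_view = NULL,
         pending_stable = NULL, stable_run_len = 0L,
         was_stable = FALSE,
         flag_sta = 0L, flag_act = 0L,
         td = 0, tc0 = NA_real_, nc0 = NA_real_,
         pir_hold = 0L, spir = 0L,
         spir_window = integer(0)),
    class = "detector_state"
  )
}

#' Update the centre track with a new locked region
#'
#' The region centre is the mean column (`xc`) and mean row (`yc`) of its
#' pixels; the track keeps the frame-to-frame differences and the rolling
#' buffer of the latest 5 centres (1 s at 5 Hz) with their standard
#' deviations and means.
#'
#' @param region A non-empty `locked_region`.
#' @param track The current track (from a `detector_state`).
#' @param config A [detector_config()].
#' @return The updated track list.
#' @export
update_center <- function(region, track, config = detector_config()) {
  xc <- mean(region$pixels[, "c"])
  yc <- mean(region$pixels[, "r"])
  track$dxc <- xc - track$xc
  track$dyc <- yc - track$yc
  track$xc <- xc; track$yc <- yc
  buf <- rbind(track$buffer, c(xc, yc))
  if (nrow(buf) > 5) buf <- buf[(nrow(buf) - 4):nrow(buf), , drop = FALSE]
  track$buffer <- buf
  track$std_xc <- roll_std(buf[, 1], config$std_estimator)
  track$std_yc <- roll_std(buf[, 2], config$std_estimator)
  track$m_xc <- mean(buf[, 1])
  track$m_yc <- mean(buf[, 2])
  track
}

#' Stability test on the centre track
#'
#' The locked area is stable (`flag_sta = 1`) when the centre buffer holds
#' a full second of samples, both rolling standard deviations are below 1
#' pixel and the absolute frame-to-frame centre displacements are below 2
#' pixels (all strict inequalities).  Before the buffer fills, the area is
#' unstable by definition.
#'
#' @param track A centre track.
#' @return `1L` or `0L`.
#' @export
check_stability <- function(track) {
  if (nrow(track$buffer) < 5) return(0L)
  if (is.na(track$dxc) || is.na(track$dyc)) return(0L)
  as.integer(track$std_xc < 1 && track$std_yc < 1 &&
             abs(track$dxc) < 2 && abs(track$dyc) < 2)
}

#' Euclidean temperature distance between stable snapshots
#'
#' Root of the summed squared per-pixel temperature differences between the
#' current and previous stable grids, evaluated over the locked region's
#' pixels.  Distinguishes a genuinely new posture (the body now occupies
#' previously-background pixels, large `ED`) from residual heat already
#' present at the last stable moment (small `ED`).
#'
#' @param old_snap,new_snap Stable snapshots (lists with a `grid` field).
#' @param pixels n x 2 matrix of `(r, c)` region pixels; defaults to the
#'   new snapshot's own region pixels.
#' @return `ED` in degrees C.
#' @export
euclidean_distance <- function(old_snap, new_snap,
                               pixels = new_snap$pixels) {
  sqrt(sum((new_snap$grid[pixels] - old_snap$grid[pixels])^2))
}

#' Advance the PIR hold and body-movement bookkeeping by one frame
#'
#' A raw pulse sets the hold to `pir_hold_s * fs` frames; the held output
#' `SPIR` is 1 on pulse frames and while the hold is positive, and the
#' hold decrements once per frame.  Seconds with `SPIR == 1` inside the
#' sliding `tbm_window_s` window accumulate into the body-movement time
#' `tbm`.
#'
#' @param raw_pir Raw PIR level of the frame, 0 or 1.
#' @param state A `detector_state`.
#' @return The updated state, with fields `spir` and the window buffer
#'   advanced; `tbm` is available via [detector_tbm()].
#' @export
update_pir <- function(raw_pir, state) {
  if (raw_pir == 1) {
    state$pir_hold <- as.integer(state$config$pir_hold_s * state$fs)
    state$spir <- 1L
  } else {
    state$spir <- as.integer(state$pir_hold > 0L)
    state$pir_hold <- max(0L, state$pir_hold - 1L)
  }
  win <- c(state$spir_window, state$spir)
  max_len <- as.integer(state$config$tbm_window_s * state$fs)
  if (length(win) > max_len) win <- win[(length(win) - max_len + 1L):length(win)]
  state$spir_window <- win
  state
}

#' Body-movement time within the sliding window
#'
#' @param state A `detector_state`.
#' @return `tbm` in seconds (bounded by the window length).
#' @export
detector_tbm <- function(state) sum(state$spir_window) / state$fs

#' Fall-action set rule
#'
#' Evaluates the conjunction that recognizes a fall between two adjacent
#' stable snapshots: temperature change `|dTc| < 2` degrees C, area ratio
#' `RNc = Nc_new/Nc_old` in the open interval (0.5, 1), current area
#' `20 < Nc < 200` px, lateral stable-centre shift `|dSXc| < LY/3`,
#' vertical drop `|dSYc| > LY/2` (LY = previous stable row-span), held PIR
#' `SPIR == 1`, stable centre away from the columns boundary
#' `1 < SXc < 30`, temperature distance `ED > 10` degrees C, and current
#' stability `flag_sta == 1`.
#'
#' @param prev_snap,curr_snap The previous and current stable snapshots
#'   (fields `sx`, `sy`, `t_mean`, `n_pix`, `row_span`, `grid`, `pixels`).
#' @param spir Held PIR output, 0/1.
#' @param flag_sta Current stability flag, 0/1.
#' @param ed Euclidean temperature distance; computed from the snapshots
#'   when omitted.
#' @param config A [detector_config()].
#' @return `1L` when all conditions hold, else `0L`.
#' @export
detect_fall_action <- function(prev_snap, curr_snap, spir, flag_sta,
                               ed = NULL, config = detector_config()) {
  if (is.null(prev_snap) || is.null(curr_snap)) return(0L)
  if (is.null(ed)) ed <- euclidean_distance(prev_snap, curr_snap)
  dtc <- curr_snap$t_mean - prev_snap$t_mean
  dsx <- curr_snap$sx - prev_snap$sx
  dsy <- curr_snap$sy - prev_snap$sy
  if (!config$strict_signs) {
    dtc <- abs(dtc); dsx <- abs(dsx); dsy <- abs(dsy)
  }
  rnc <- curr_snap$n_pix / prev_snap$n_pix
  nc <- curr_snap$n_pix
  ly <- prev_snap$row_span
  as.integer(dtc < 2 &&
             rnc > 0.5 && rnc < 1 &&
             nc > 20 && nc < 200 &&
             dsx < ly / 3 &&
             dsy > ly / 2 &&
             spir == 1 &&
             curr_snap$sx > 1 && curr_snap$sx < 30 &&
             ed > 10 &&
             flag_sta == 1)
}

#' Fall-action reset rule
#'
#' Clears a latched fall action when any of the following hold: the centre
#' moves (`|dXc| > 2` or `|dYc| > 2` px frame-to-frame), the duration timer
#' exceeds 120 s, the locked-area temperature grows by more than 2 degrees
#' C over its value at the latch (`Tc - Tc0 > 2`), or the locked area
#' grows by more than a third (`Nc - Nc0 > Nc0/3`).  The temperature and
#' area terms are one-sided growth checks.
#'
#' @param dxc,dyc Frame-to-frame centre differences (px).
#' @param td Fall-action duration (s).
#' @param tc,tc0 Current and latched locked-area mean temperature.
#' @param nc,nc0 Current and latched locked-area pixel count.
#' @param config A [detector_config()].
#' @return `TRUE` when the action must be cleared.
#' @export
reset_fall_action <- function(dxc, dyc, td, tc, tc0, nc, nc0,
                              config = detector_config()) {
  if (!config$strict_signs) {
    dxc <- abs(dxc); dyc <- abs(dyc)
  }
  isTRUE(dxc > 2 || dyc > 2 || td > 120 ||
         (tc - tc0) > 2 || (nc - nc0) > nc0 / 3)
}

make_snapshot <- function(track, region, grid) {
  list(sx = track$m_xc, sy = track$m_yc,
       grid = grid,
       t_mean = mean(grid[region$pixels]),
       n_pix = region$count,
       row_span = region$row_span,
       pixels = region$pixels)
}

#' Advance the detector by one (filtered) frame
#'
#' Runs segmentation, centre tracking, the stability test, stable-snapshot
#' bookkeeping, the fall-action set/reset rules and the PIR hold, then
#' emits the 8-element feature vector
#' `(stdXc, stdYc, td, tbm, stdNc, stdTc, flag_sta, flag_act)`.
#' When segmentation finds no region the centre and area/temperature
#' buffers are cleared and both flags decay to 0.
#'
#' Stable-moment semantics: a maximal run of consecutive stable frames is
#' one stable *episode*, and one episode is one stable moment, represented
#' by the snapshot anchored at its onset (the filtered image of a posture
#' that is about to be left decays, so late frames of an episode are not
#' representative of it).  When stability breaks and re-establishes with
#' the buffered mean centre at least `stable_push_dist` away from the
#' anchor, a new stable moment opens -- once the episode has survived
#' `stable_confirm_s` -- and the old anchor becomes the previous snapshot;
#' re-stabilizing near the anchor is treated as the same posture resuming,
#' and episodes that die before confirming are discarded.  The set rule is
#' evaluated at every stable frame
#' once two distinct stable moments exist, comparing the previous anchor
#' against the *current* stable view, so a condition that only becomes
#' true as the filtered image converges (e.g. `|dTc| < 2`) is still
#' caught while the PIR hold is alive.
#'
#' @param state A `detector_state`.
#' @param frame A filtered `thermal_frame` (carrying the raw PIR level).
#' @return `list(state = <updated state>, features = <named numeric(8)>)`.
#' @export
detector_step <- function(state, frame) {
  cfg <- state$config
  state <- update_pir(frame$pir, state)
  region <- segment(frame)

  if (is.null(region)) {
    state$track$buffer <- matrix(numeric(0), 0, 2)
    state$track$xc <- state$track$yc <- NA_real_
    state$track$dxc <- state$track$dyc <- NA_real_
    state$track$std_xc <- state$track$std_yc <- 0
    state$nc_buf <- numeric(0); state$tc_buf <- numeric(0)
    state$flag_sta <- 0L; state$flag_act <- 0L; state$td <- 0
    state$was_stable <- FALSE
    return(list(state = state, features = feature_vector(state)))
  }

  state$track <- update_center(region, state$track, cfg)
  state$flag_sta <- check_stability(state$track)

  nc <- region$count
  tc <- mean(frame$grid[region$pixels])
  state$nc_buf <- utils::tail(c(state$nc_buf, nc), 5)
  state$tc_buf <- utils::tail(c(state$tc_buf, tc), 5)

  if (state$flag_sta == 1L) {
    cand <- make_snapshot(state$track, region, frame$grid)
    state$stable_view <- cand              # latest stable view of the scene
    state$stable_run_len <-
      if (state$was_stable) state$stable_run_len + 1L else 1L
    if (!state$was_stable) {               # onset of a new stable episode
      if (is.null(state$curr_stable)) {
        state$pending_stable <- cand
      } else {
        d <- sqrt((cand$sx - state$curr_stable$sx)^2 +
                  (cand$sy - state$curr_stable$sy)^2)
        # distinct centre: provisionally a new stable moment; otherwise
        # the same posture resumed after a blip (keep the old anchor)
        state$pending_stable <-
          if (d >= cfg$stable_push_dist) cand else NULL
      }
    }
    if (!is.null(state$pending_stable) &&
        state$stable_run_len >= cfg$stable_confirm_s * state$fs) {
      if (!is.null(state$curr_stable))
        state$prev_stable <- state$curr_stable
      state$curr_stable <- state$pending_stable
      state$pending_stable <- NULL
    }
    if (state$flag_act == 0L && !is.null(state$prev_stable)) {
      hit <- detect_fall_action(state$prev_stable, cand,
                                spir = state$spir,
                                flag_sta = state$flag_sta, config = cfg)
      if (hit == 1L) {
        state$flag_act <- 1L
        state$td <- 0
        state$tc0 <- cand$t_mean
        state$nc0 <- cand$n_pix
      }
    }
  }

  if (state$flag_act == 1L) {
    state$td <- state$td + 1 / state$fs
    sv <- state$stable_view
    if (reset_fall_action(state$track$dxc, state$track$dyc, state$td,
                          tc = sv$t_mean, tc0 = state$tc0,
                          nc = sv$n_pix, nc0 = state$nc0,
                          config = cfg)) {
      state$flag_act <- 0L
      state$td <- 0
    }
  }

  if (state$flag_sta == 0L) {
    state$pending_stable <- NULL           # episode died before confirming
    state$stable_run_len <- 0L
  }
  state$was_stable <- state$flag_sta == 1L
  list(state = state, features = feature_vector(state))
}

feature_vector <- function(state) {
  cfg <- state$config
  c(std_xc = state$track$std_xc,
    std_yc = state$track$std_yc,
    td = state$td,
    tbm = detector_tbm(state),
    std_nc = roll_std(state$nc_buf, cfg$std_estimator),
    std_tc = roll_std(state$tc_buf, cfg$std_estimator),
    flag_sta = as.numeric(state$flag_sta),
    flag_act = as.numeric(state$flag_act))
}

#' Extract the per-frame feature table of a stream
#'
#' Low-pass filters the stream and runs the streaming detector over it,
#' emitting one 8-element feature vector per frame.
#'
#' @param stream A raw `frame_stream`.
#' @param coeffs Filter design (default `design_lpf(1, stream$fs)`).
#' @param config A [detector_config()].
#' @param filtered Set `TRUE` if `stream` is already filtered.
#' @return A `data.frame` with `timestamp` plus the 8 feature columns
#'   `std_xc, std_yc, td, tbm, std_nc, std_tc, flag_sta, flag_act`.
#' @export
extract_features <- function(stream, coeffs = design_lpf(1, stream$fs),
                             config = detector_config(), filtered = FALSE) {
  fstream <- if (filtered) stream else filter_stream(stream, coeffs)
  state <- new_detector_state(fs = stream$fs, config = config)
  n <- length(fstream$frames)
  out <- matrix(NA_real_, n, 8)
  ts <- numeric(n)
  for (k in seq_len(n)) {
    res <- detector_step(state, fstream$frames[[k]])
    state <- res$state
    out[k, ] <- res$features
    ts[k] <- fstream$frames[[k]]$timestamp
  }
  df <- as.data.frame(out)
  names(df) <- names(feature_vector(state))
  cbind(timestamp = ts, df)
}

#' Indices of matured frames
#'
#' Classification is evaluated per frame, but an alarm decision is only
#' meaningful once the feature window has matured: key features aggregate
#' the trailing minute, so the response time of the detector is about one
#' minute.  For streams shorter than the window the final frame is the
#' matured decision point.
#'
#' @param features Feature table from [extract_features()].
#' @param window_s Maturity window in seconds (default 60).
#' @return Integer vector of row indices with
#'   `timestamp >= min(window_s, last timestamp)`.
#' @export
matured_frames <- function(features, window_s = 60) {
  tmax <- max(features$timestamp)
  which(features$timestamp >= min(window_s, tmax))
}
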