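#' @keywords internal
"_PACKAGE"

GRID_DIM <- 32L
N_PIXELS <- GRID_DIM * GRID_DIM

pixel_col_names <- function() {
  paste0("p_r", rep(seq_len(GRID_DIM), each = GRID_DIM),
         "c", rep(seq_len(GRID_DIM), times = GRID_DIM))
}

#' Construct a single thermal frame
#'
#' A thermal frame is the unit of all image processing: one 32x32 grid of
#' absolute temperatures in degrees Celsius, the sensor's ambient-temperature
#' reading, a timestamp in seconds since stream start, and the raw (un-held)
#' binary PIR motion level.
#'
#' Grids are addressed as `grid[r, c]` with one-based row `r` increasing
#' downward and column `c` increasing rightward; all modules share this
#' convention.
#'
#' @param grid 32x32 numeric matrix of temperatures (degrees C).
#' @param ambient Ambient temperature (degrees C).
#' @param timestamp Seconds since stream start.
#' @param pir Raw PIR level, 0 or 1.
#' @return An object of class `thermal_frame`.
#' @export
thermal_frame <- function(grid, ambient, timestamp, pir = 0L) {
  if (!is.matrix(grid) || !identical(dim(grid), c(GRID_DIM, GRID_DIM)))
    stop("`grid` must be a 32x32 numeric matrix", call. = FALSE)
  if (!is.numeric(grid)) stop("`grid` must be numeric", call. = FALSE)
  if (!pir %in% c(0, 1)) stop("`pir` must be 0 or 1", call. = FALSE)
  structure(
    list(grid = grid, ambient = as.numeric(ambient),
         timestamp = as.numeric(timestamp), pir = as.integer(pir)),
    class = "thermal_frame"
  )
}

#' Construct a frame stream
#'
#' An ordered sequence of [thermal_frame()]s sampled at a nominal rate `fs`
#' (default 5 Hz, i.e. 0.2 s spacing), optionally carrying a ground-truth
#' label and the scenario factor levels it was generated under.
#'
#' @param frames List of `thermal_frame` objects with strictly increasing
#'   timestamps.
#' @param fs Sampling rate in Hz.
#' @param label Optional ground truth, `"fall"` or `"non_fall"`.
#' @param scenario_meta Optional named list of scenario factor levels.
#' @return An object of class `frame_stream`.
#' @export
frame_stream <- function(frames, fs = 5, label = NULL, scenario_meta = NULL) {
  if (!length(frames)) stop("a frame stream must contain frames", call. = FALSE)
  if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
  ts <- vapply(frames, function(f) f$timestamp, numeric(1))
  if (length(ts) > 1 && any(diff(ts) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  if (!is.null(label) && !label %in% c("fall", "non_fall"))
    stop("`label` must be \"fall\" or \"non_fall\"", call. = FALSE)
  structure(
    list(frames = frames, fs = as.numeric(fs), label = label,
         scenario_meta = scenario_meta),
    class = "frame_stream"
  )
}

#' @export
length.frame_stream <- function(x) length(x$frames)

#' @export
print.frame_stream <- function(x, ...) {
  cat(sprintf("<frame_stream> %d frames @ %g Hz (%.1f s)%s\n",
              length(x$frames), x$fs,
              x$frames[[length(x$frames)]]$timestamp,
              if (is.null(x$label)) "" else paste0(", label: ", x$label)))
  invisible(x)
}

#' Extract the pixel matrix of a stream
#'
#' Stacks every frame's grid into an `n_frames x 1024` matrix in row-major
#' pixel order (r1c1, r1c2, ..., r32c32), the layout used by the frame-csv
#' serialization.
#'
#' @param stream A `frame_stream`.
#' @return Numeric matrix, one row per frame.
#' @export
stream_matrix <- function(stream) {
  t(vapply(stream$frames, function(f) as.vector(t(f$grid)),
           numeric(N_PIXELS)))
}

#' Read a frame stream from a frame-csv file
#'
#' The frame-csv dialect stores one frame per row under the header
#' `timestamp,ambient,pir,p_r1c1,...,p_r32c32` (pixels row-major, names
#' one-based).
#'
#' @param path Path to a frame-csv file.
#' @return A [frame_stream()].
#' @export
read_stream <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, fill = TRUE, showProgress = FALSE)
  expected <- c("timestamp", "ambient", "pir", pixel_col_names())
  if (ncol(dt) != length(expected))
    stop(sprintf("frame-csv must have %d columns, found %d",
                 length(expected), ncol(dt)), call. = FALSE)
  if (!identical(names(dt), expected))
    stop("frame-csv header does not match the canonical column names",
         call. = FALSE)
  m <- as.matrix(dt[, -(1:3)])
  bad <- which(!stats::complete.cases(m))
  if (length(bad))
    stop(sprintf("malformed pixel data in row %d (expected %d pixel values)",
                 bad[1], N_PIXELS), call. = FALSE)
  ts <- dt$timestamp
  if (length(ts) > 1 && any(diff(ts) <= 0))
    stop("timestamps are not strictly increasing (row ",
         which(diff(ts) <= 0)[1] + 1L, ")", call. = FALSE)
  frames <- lapply(seq_len(nrow(dt)), function(i) {
    thermal_frame(matrix(m[i, ], GRID_DIM, GRID_DIM, byrow = TRUE),
                  ambient = dt$ambient[i], timestamp = ts[i],
                  pir = dt$pir[i])
  })
  fs <- if (length(ts) > 1) 1 / stats::median(diff(ts)) else 5
  frame_stream(frames, fs = round(fs, 6))
}

#' Write a frame stream to a frame-csv file
#'
#' Inverse of [read_stream()]: `read_stream(write_stream(s, p))` reproduces
#' the data model, and re-writing a canonical file is byte-identical.
#'
#' @param stream A non-empty `frame_stream`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path) {
  if (!inherits(stream, "frame_stream") || !length(stream$frames))
    stop("`stream` must be a non-empty frame_stream", call. = FALSE)
  dt <- data.table::as.data.table(stream_matrix(stream))
  data.table::setnames(dt, pixel_col_names())
  meta <- data.table::data.table(
    timestamp = vapply(stream$frames, `[[`, numeric(1), "timestamp"),
    ambient   = vapply(stream$frames, `[[`, numeric(1), "ambient"),
    pir       = vapply(stream$frames, function(f) as.integer(f$pir), integer(1))
  )
  data.table::fwrite(cbind(meta, dt), path, eol = "\n")
  invisible(path)
}

#' Read a dataset manifest
#'
#' @param dir Dataset directory containing `manifest.csv` as written by
#'   [generate_dataset()].
#' @return A `data.frame` with one row per stream.
#' @export
read_manifest <- function(dir) {
  path <- file.path(dir, "manifest.csv")
  if (!file.exists(path)) stop("no manifest.csv in ", dir, call. = FALSE)
  as.data.frame(data.table::fread(path, showProgress = FALSE))
}

# Seed-scoped RNG: runs `code` under `seed` and restores the caller's RNG
# state, so generators are deterministic without clobbering the session.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
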