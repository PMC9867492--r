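# Independent flood-fill oracle for 8-connected component labeling, and
# small fixture builders used across the test files.

# Breadth-first flood fill over a logical mask; returns an integer matrix
# of component ids (0 = background), ids assigned in raster discovery
# order.  Deliberately naive and independent of the two-pass scan.
flood_fill_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  comp <- matrix(0L, nr, nc)
  next_id <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c] || comp[r, c] != 0L) next
    next_id <- next_id + 1L
    queue <- list(c(r, c))
    comp[r, c] <- next_id
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1] + dr; cc <- p[2] + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            mask[rr, cc] && comp[rr, cc] == 0L) {
          comp[rr, cc] <- next_id
          queue <- c(queue, list(c(rr, cc)))
        }
      }
    }
  }
  comp
}

# Embed a small logical mask into an empty 32x32 grid at an offset.
embed_mask <- function(small, row_off = 0L, col_off = 0L) {
  m <- matrix(FALSE, 32, 32)
  m[row_off + seq_len(nrow(small)), col_off + seq_len(ncol(small))] <- small
  m
}

# A frame whose thresholded candidate mask equals `mask` exactly:
# background at 20 C, mask pixels at 34 C (threshold lands at 27 C).
frame_from_mask <- function(mask, hot = 34, bg = 20, timestamp = 0) {
  g <- matrix(bg, 32, 32)
  g[mask] <- hot
  thermal_frame(g, ambient = bg, timestamp = timestamp)
}

# Run the package's full labeling path on a logical mask.
segment_mask <- function(mask, method = "union_find") {
  select_largest(merge_blocks(first_scan(fallsense:::mask_object(mask)),
                              method = method))
}

# Check that a locked region is a maximal 8-connected component of `mask`
# with the greatest pixel count (the oracle property).
expect_region_is_largest_component <- function(region, mask) {
  comp <- flood_fill_components(mask)
  if (max(comp) == 0L) {
    expect_null(region)
    return(invisible())
  }
  sizes <- tabulate(comp[comp > 0L])
  expect_equal(region$count, max(sizes))
  ids <- unique(comp[region_mask(region)])
  expect_length(ids, 1L)                       # one oracle component...
  expect_equal(sum(comp == ids), region$count) # ...covered entirely
}

# A constant-temperature stream.
constant_stream <- function(n, value = 25, fs = 5) {
  frame_stream(lapply(seq_len(n) - 1L, function(k)
    thermal_frame(matrix(value, 32, 32), ambient = value,
                  timestamp = k / fs)), fs = fs)
}

# A minimal stable snapshot for the set/reset rule tests.
snapshot_fixture <- function(sx, sy, t_mean, n_pix, row_span,
                             grid = matrix(20, 32, 32), pixels = NULL) {
  if (is.null(pixels)) {
    raster <- cbind(r = rep(1:20, each = 20), c = rep(1:20, 20))
    pixels <- raster[seq_len(n_pix), , drop = FALSE]
  }
  list(sx = sx, sy = sy, grid = grid, t_mean = t_mean, n_pix = n_pix,
       row_span = row_span, pixels = pixels)
}

# Random logical mask with density p under a seed.
random_mask <- function(seed, nr = 32, nc = 32, p = 0.3) {
  set.seed(seed)
  matrix(stats::runif(nr * nc) < p, nr, nc)
}
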