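#' Threshold a frame into candidate body pixels
#'
#' Abnormal pixels hotter than 40 degrees C or colder than 0 degrees C are
#' deleted outright (they neither enter the mask nor the extremes).  Over
#' the remaining valid pixels the minimum `t_min` and maximum `t_max` are
#' found and their average becomes the threshold `t_th`; candidate pixels
#' are the valid pixels with temperature in the inclusive interval
#' `[t_th, t_max]`.  (The inclusive interval follows the labeling
#' pseudo-code; a strict upper bound would exclude the hottest pixel.)
#' When every pixel of the grid is equal, `t_th == t_max` and all pixels
#' are selected.
#'
#' @param frame A (filtered) `thermal_frame`.
#' @return An object of class `candidate_mask` with fields `selected`
#'   (32x32 logical), `t_min`, `t_max`, `t_th`; or `NULL` when no valid
#'   pixel exists.
#' @export
threshold_frame <- function(frame) {
  g <- frame$grid
  valid <- g >= 0 & g <= 40
  if (!any(valid)) return(NULL)
  t_min <- min(g[valid]); t_max <- max(g[valid])
  t_th <- (t_min + t_max) / 2
  structure(
    list(selected = valid & g >= t_th & g <= t_max,
         t_min = t_min, t_max = t_max, t_th = t_th),
    class = "candidate_mask"
  )
}

# Wrap a bare logical matrix as a candidate_mask (used by tests and by the
# idempotence property); temperatures are notional.
mask_object <- function(selected) {
  structure(list(selected = selected, t_min = NA_real_, t_max = NA_real_,
                 t_th = NA_real_), class = "candidate_mask")
}

#' First boundary scan: provisional labeling
#'
#' Progressive raster scan (rows, then columns, one-based) over the
#' candidate mask, writing into a 34x34 label grid whose one-pixel zero
#' border removes all edge special-casing.  For each candidate pixel the
#' set `P1` of its 8 neighbours' labels is read; removing zeros and
#' duplicates yields `P2`.  An empty `P2` opens a fresh block number, else
#' the pixel takes `min(P2)`; whenever `|P2| > 1` the set is appended to
#' the relationship table `Q` for the merge pass.
#'
#' @param mask A `candidate_mask` (or `NULL`, which propagates).
#' @return An object of class `label_grid`: `labels` (34x34 integer, border
#'   zero), `relations` (list of integer vectors), `n_labels`.
#' @export
first_scan <- function(mask) {
  if (is.null(mask)) return(NULL)
  sel <- mask$selected
  L <- integer(34 * 34)                 # bordered label grid, column-major
  relations <- vector("list", 64)
  n_rel <- 0L
  bn <- 1L
  off <- c(-35L, -34L, -33L, -1L, 1L, 33L, 34L, 35L)  # 8 neighbours
  idx <- which(sel, arr.ind = TRUE)
  if (nrow(idx)) {
    ord <- order(idx[, 1L], idx[, 2L])  # raster order: r then c
    rs <- idx[ord, 1L]; cs <- idx[ord, 2L]
    for (i in seq_along(rs)) {
      p <- (rs[i] + 1L) + cs[i] * 34L   # bordered position (r+1, c+1)
      nb <- L[p + off]
      nz <- nb[nb > 0L]
      if (!length(nz)) {
        L[p] <- bn
        bn <- bn + 1L
      } else {
        L[p] <- min(nz)
        p2 <- unique(nz)
        if (length(p2) > 1L) {
          n_rel <- n_rel + 1L
          if (n_rel > length(relations))
            relations <- c(relations, vector("list", length(relations)))
          relations[[n_rel]] <- sort(p2)
        }
      }
    }
  }
  structure(
    list(labels = matrix(L, 34L, 34L),
         relations = if (n_rel) relations[seq_len(n_rel)] else list(),
         n_labels = bn - 1L),
    class = "label_grid"
  )
}

# Transitive closure of the relationship table by union-find (union by
# minimum, so each class's representative is its smallest block number).
closure_union_find <- function(relations, n_labels) {
  parent <- seq_len(n_labels)
  find <- function(a) {
    while (parent[a] != a) a <- parent[a]
    a
  }
  for (s in relations) {
    r0 <- find(s[1L])
    for (b in s[-1L]) {
      rb <- find(b)
      if (rb != r0) {
        lo <- min(r0, rb); hi <- max(r0, rb)
        parent[hi] <- lo
        r0 <- lo
      }
    }
  }
  vapply(seq_len(n_labels), find, integer(1))
}

# Literal pairwise union sweep of the relationship table, as in the
# two-pass pseudo-code; optionally iterated to a fixpoint (a single pass
# can miss chains like {1,2},{3,4},{2,3}).
closure_pairwise <- function(relations, n_labels, fixpoint = TRUE) {
  Q <- relations
  repeat {
    changed <- FALSE
    nq <- length(Q)
    if (nq >= 2L) {
      for (i in seq_len(nq - 1L)) {
        if (!length(Q[[i]])) next
        for (j in seq.int(i + 1L, nq)) {
          if (length(Q[[j]]) && length(intersect(Q[[i]], Q[[j]]))) {
            Q[[i]] <- sort(union(Q[[i]], Q[[j]]))
            Q[[j]] <- integer(0)
            changed <- TRUE
          }
        }
      }
    }
    if (!fixpoint || !changed) break
  }
  lut <- seq_len(n_labels)
  for (s in Q) if (length(s) > 1L) lut[s] <- min(s)
  lut
}

#' Second boundary scan: merge adjacent blocks
#'
#' Relation sets with non-empty intersection are unioned to transitive
#' closure and every labeled pixel whose block number lies in a closed set
#' is relabeled to that set's minimum, so that after merging any two
#' 8-adjacent nonzero pixels share one label.  `counts` tallies pixels per
#' surviving label.
#'
#' @param grid A `label_grid` from [first_scan()].
#' @param method `"union_find"` (default; computes the same closure in
#'   near-linear time), `"pairwise"` (the literal pairwise-union sweep
#'   iterated to fixpoint) or `"single_pass"` (one sweep only, the strict
#'   reading of the pseudo-code).
#' @return The `label_grid` with merged `labels` and a named `counts`
#'   vector.
#' @export
merge_blocks <- function(grid,
                         method = c("union_find", "pairwise", "single_pass")) {
  if (is.null(grid)) return(NULL)
  method <- match.arg(method)
  lut <- switch(method,
    union_find  = closure_union_find(grid$relations, grid$n_labels),
    pairwise    = closure_pairwise(grid$relations, grid$n_labels, TRUE),
    single_pass = closure_pairwise(grid$relations, grid$n_labels, FALSE))
  L <- grid$labels
  pos <- L > 0L
  if (grid$n_labels > 0L) L[pos] <- lut[L[pos]]
  cnt <- table(L[pos])
  grid$labels <- L
  grid$counts <- stats::setNames(as.integer(cnt), names(cnt))
  grid
}

#' Retain the largest block as the locked body region
#'
#' The block with the greatest pixel count is kept and all others are
#' removed; ties break toward the smallest block number (deterministic; the
#' scan order of `find(max(cnt))` is otherwise unspecified).
#'
#' @param grid A merged `label_grid`.
#' @return An object of class `locked_region` with fields `pixels` (n x 2
#'   matrix of one-based `(r, c)`), `label`, `count`, `row_span`,
#'   `col_span`; or `NULL` when no pixel is labeled.
#' @export
select_largest <- function(grid) {
  if (is.null(grid) || is.null(grid$counts) || !length(grid$counts))
    return(NULL)
  labs <- as.integer(names(grid$counts))
  best <- labs[grid$counts == max(grid$counts)]
  id <- min(best)
  interior <- grid$labels[2:33, 2:33]
  px <- which(interior == id, arr.ind = TRUE)
  colnames(px) <- c("r", "c")
  structure(
    list(pixels = px, label = id, count = nrow(px),
         row_span = max(px[, 1]) - min(px[, 1]) + 1L,
         col_span = max(px[, 2]) - min(px[, 2]) + 1L),
    class = "locked_region"
  )
}

#' Segment a frame into its locked body region
#'
#' Composition of [threshold_frame()], [first_scan()], [merge_blocks()] and
#' [select_largest()]; `NULL` (no valid or no candidate pixel) propagates.
#'
#' @param frame A (filtered) `thermal_frame`.
#' @inheritParams merge_blocks
#' @return A `locked_region` or `NULL`.
#' @export
segment <- function(frame, method = "union_find") {
  select_largest(merge_blocks(first_scan(threshold_frame(frame)),
                              method = method))
}

#' Render a locked region back into a 32x32 logical mask
#'
#' @param region A `locked_region`.
#' @return 32x32 logical matrix.
#' @export
region_mask <- function(region) {
  m <- matrix(FALSE, GRID_DIM, GRID_DIM)
  if (!is.null(region)) m[region$pixels] <- TRUE
  m
}

#' Export a label grid as a CSV heatmap (debug aid)
#'
#' @param grid A `label_grid`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_label_grid <- function(grid, path) {
  utils::write.table(grid$labels[2:33, 2:33], path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
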