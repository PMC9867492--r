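#' Confusion matrix
#'
#' `tp` counts fall events detected correctly, `fn` fall events missed,
#' `tn` non-fall events detected correctly, `fp` non-fall events flagged
#' as falls.
#'
#' @param tp,fn,tn,fp Non-negative counts.
#' @return A list of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fn, tn, fp) {
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (sum(counts) == 0) stop("at least one count must be positive", call. = FALSE)
  structure(as.list(counts), class = "confusion_matrix")
}

#' Performance metrics of a confusion matrix
#'
#' Recall `RE = TP/(TP+FN)`, precision `PR = TP/(TP+FP)`, accuracy
#' `ACC = (TP+TN)/(TP+TN+FP+FN)` and
#' `F1 = 2 RE PR / (RE + PR)` (equivalently `2TP/(2TP+FN+FP)`).  Metrics
#' whose denominator is zero are returned as `NaN` with a warning.
#'
#' @param cm A [confusion_matrix()].
#' @return A list of class `metric_set` with fields `re`, `pr`, `acc`,
#'   `f1`, all proportions in \[0, 1\].
#' @export
cm_metrics <- function(cm) {
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)", call. = FALSE)
      return(NaN)
    }
    num / den
  }
  re <- safe_div(cm$tp, cm$tp + cm$fn, "recall")
  pr <- safe_div(cm$tp, cm$tp + cm$fp, "precision")
  acc <- (cm$tp + cm$tn) / (cm$tp + cm$fn + cm$tn + cm$fp)
  f1 <- if (is.nan(re) || is.nan(pr) || (re + pr) == 0) {
    warning("F1 undefined", call. = FALSE); NaN
  } else 2 * re * pr / (re + pr)
  structure(list(re = re, pr = pr, acc = acc, f1 = f1),
            class = "metric_set")
}

#' Round a proportion to a printed percentage
#'
#' Two decimals, half-up (so 0.909375 prints as 90.94).
#'
#' @param x Proportion(s) in \[0, 1\].
#' @return Percentage value(s).
#' @export
as_percent <- function(x) floor(x * 10000 + 0.5) / 100

#' The published per-fold confusion counts
#'
#' The five confusion matrices of the bathroom fall experiments (one per
#' ambient-temperature fold), packaged as fixture data for
#' [reproduce_table2()].
#'
#' @return A `data.frame` with columns `fold`, `tp`, `fn`, `tn`, `fp`.
#' @export
table2_counts <- function() {
  data.frame(fold = 1:5,
             tp = c(59, 60, 60, 58, 54),
             fn = c(5, 4, 4, 6, 10),
             tn = c(61, 62, 62, 60, 58),
             fp = c(3, 2, 2, 4, 6))
}

fold_report <- function(cms) {
  metrics <- lapply(cms, cm_metrics)
  avg_counts <- c(tp = mean(vapply(cms, `[[`, numeric(1), "tp")),
                  fn = mean(vapply(cms, `[[`, numeric(1), "fn")),
                  tn = mean(vapply(cms, `[[`, numeric(1), "tn")),
                  fp = mean(vapply(cms, `[[`, numeric(1), "fp")))
  avg_metrics <- c(re = mean(vapply(metrics, `[[`, numeric(1), "re")),
                   pr = mean(vapply(metrics, `[[`, numeric(1), "pr")),
                   acc = mean(vapply(metrics, `[[`, numeric(1), "acc")),
                   f1 = mean(vapply(metrics, `[[`, numeric(1), "f1")))
  pooled <- confusion_matrix(sum(vapply(cms, `[[`, numeric(1), "tp")),
                             sum(vapply(cms, `[[`, numeric(1), "fn")),
                             sum(vapply(cms, `[[`, numeric(1), "tn")),
                             sum(vapply(cms, `[[`, numeric(1), "fp")))
  structure(
    list(per_fold = Map(function(cm, m) list(cm = cm, metrics = m),
                        cms, metrics),
         avg_counts = avg_counts,
         avg_metrics = avg_metrics,      # mean of per-fold metrics
         pooled_metrics = cm_metrics(pooled)),
    class = "fold_report"
  )
}

#' @export
print.fold_report <- function(x, ...) {
  cat("5-fold evaluation\n")
  cat(sprintf("  %-5s %4s %4s %4s %4s  %7s %7s %7s %7s\n",
              "fold", "TP", "FN", "TN", "FP", "PR%", "RE%", "ACC%", "F1%"))
  for (i in seq_along(x$per_fold)) {
    f <- x$per_fold[[i]]
    cat(sprintf("  %-5d %4g %4g %4g %4g  %7.2f %7.2f %7.2f %7.2f\n",
                i, f$cm$tp, f$cm$fn, f$cm$tn, f$cm$fp,
                as_percent(f$metrics$pr), as_percent(f$metrics$re),
                as_percent(f$metrics$acc), as_percent(f$metrics$f1)))
  }
  cat(sprintf("  %-5s %4.1f %4.1f %4.1f %4.1f  %7.2f %7.2f %7.2f %7.2f\n",
              "avg", x$avg_counts["tp"], x$avg_counts["fn"],
              x$avg_counts["tn"], x$avg_counts["fp"],
              as_percent(x$avg_metrics["pr"]), as_percent(x$avg_metrics["re"]),
              as_percent(x$avg_metrics["acc"]), as_percent(x$avg_metrics["f1"])))
  invisible(x)
}

#' Reproduce the published cross-validation arithmetic
#'
#' Feeds per-fold confusion counts (by default the packaged published
#' counts) through the metric formulas and the averaging convention used
#' in the publication: the reported averages are the *means of the
#' per-fold metrics*, not the metrics of the pooled counts (pooled
#' precision would be 58.2/61.6 = 94.48 %, whereas the printed average is
#' 94.45 %).  Pooled-count metrics are also attached, clearly labeled.
#'
#' @param counts A data.frame with columns `tp`, `fn`, `tn`, `fp`, one row
#'   per fold.
#' @return A `fold_report`.
#' @export
reproduce_table2 <- function(counts = table2_counts()) {
  cms <- lapply(seq_len(nrow(counts)), function(i)
    confusion_matrix(counts$tp[i], counts$fn[i], counts$tn[i], counts$fp[i]))
  fold_report(cms)
}

#' Split a dataset by ambient temperature into 5 folds
#'
#' Fold i validates on the i-th ambient-temperature set (S1 = 18 C ... S5
#' = 30 C) and trains on the other four, so each temperature serves once
#' as the validation condition.
#'
#' @param manifest Dataset manifest with an `ambient_level` column covering
#'   all five levels.
#' @return List of 5 folds, each `list(fold, ambient, train_idx, val_idx)`.
#' @export
kfold_by_temperature <- function(manifest) {
  levels_present <- sort(unique(manifest$ambient_level))
  if (!identical(as.numeric(levels_present), as.numeric(AMBIENT_LEVELS)))
    stop("manifest must cover the five ambient levels ",
         paste(AMBIENT_LEVELS, collapse = ", "), call. = FALSE)
  lapply(seq_along(AMBIENT_LEVELS), function(i) {
    val <- which(manifest$ambient_level == AMBIENT_LEVELS[i])
    list(fold = i, ambient = AMBIENT_LEVELS[i],
         train_idx = setdiff(seq_len(nrow(manifest)), val),
         val_idx = val)
  })
}

#' Extract per-stream classification features from a dataset
#'
#' Runs the filtering + segmentation + feature pipeline over every stream
#' of a materialized dataset and keeps, per stream, the representative
#' training vector (the final matured frame -- each test contributes one
#' 8-input example) and the feature vectors of all matured frames (used
#' for the stream-level decision rule).
#'
#' @param dir Dataset directory (frame-csv files + manifest.csv).
#' @param manifest Optional manifest override (defaults to the one in
#'   `dir`); labels are taken from it.
#' @param config A [detector_config()].
#' @param window_s Maturity window in seconds.
#' @return A list of class `dataset_features`: per-stream entries with
#'   `rep` (named numeric 8), `matured` (matrix), `label`, `ambient`, plus
#'   the manifest as an attribute.
#' @export
extract_dataset_features <- function(dir, manifest = NULL,
                                     config = detector_config(),
                                     window_s = 60) {
  if (is.null(manifest)) manifest <- read_manifest(dir)
  feature_cols <- c("std_xc", "std_yc", "td", "tbm", "std_nc", "std_tc",
                    "flag_sta", "flag_act")
  entries <- lapply(seq_len(nrow(manifest)), function(i) {
    stream <- read_stream(file.path(dir, manifest$file[i]))
    feats <- extract_features(stream, config = config)
    rows <- matured_frames(feats, window_s)
    m <- as.matrix(feats[rows, feature_cols, drop = FALSE])
    list(rep = m[nrow(m), ], matured = m,
         label = manifest$label[i], ambient = manifest$ambient_level[i])
  })
  structure(entries, class = "dataset_features", manifest = manifest)
}

#' Five-fold cross-validation of the full pipeline
#'
#' For each ambient-temperature fold the classifier is trained on the
#' representative feature vectors of the training streams and every
#' validation stream is classified as a fall iff any of its matured frames
#' classifies as a fall; confusion counts and metrics are tallied per fold
#' and averaged as in [reproduce_table2()].
#'
#' @param features A `dataset_features` object from
#'   [extract_dataset_features()] (or `dir` to extract on the fly).
#' @param tconfig A [train_config()]; the per-fold seed is derived from
#'   `tconfig$seed` plus the fold number.
#' @param manifest Optional manifest override (e.g. permuted labels for a
#'   null check); defaults to the features' own manifest.
#' @return A `fold_report` with a `fold_ambient` attribute.
#' @export
run_cv <- function(features, tconfig = train_config(), manifest = NULL) {
  if (is.character(features)) features <- extract_dataset_features(features)
  if (is.null(manifest)) manifest <- attr(features, "manifest")
  folds <- kfold_by_temperature(manifest)
  cms <- lapply(folds, function(fold) {
    x_train <- t(vapply(features[fold$train_idx], `[[`, numeric(8), "rep"))
    y_train <- as.numeric(manifest$label[fold$train_idx] == "fall")
    fold_cfg <- tconfig
    fold_cfg$seed <- tconfig$seed + fold$fold
    clf <- bp_train(x_train, y_train, fold_cfg)
    pred_fall <- vapply(features[fold$val_idx], function(e)
      any(bp_classify(clf, e$matured) == "fall"), logical(1))
    truth_fall <- manifest$label[fold$val_idx] == "fall"
    confusion_matrix(tp = sum(pred_fall & truth_fall),
                     fn = sum(!pred_fall & truth_fall),
                     tn = sum(!pred_fall & !truth_fall),
                     fp = sum(pred_fall & !truth_fall))
  })
  rep <- fold_report(cms)
  attr(rep, "fold_ambient") <- vapply(folds, `[[`, numeric(1), "ambient")
  rep
}
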