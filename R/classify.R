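#' SVM classification configuration
#'
#' Defaults follow libSVM practice: log-spaced grids for the
#' misclassification penalty C and the RBF kernel width delta (the `gamma`
#' of [e1071::svm()]), 5-fold outer and inner stratified cross-validation,
#' and 10 repeats with different random partitions whose accuracies are
#' averaged.
#'
#' @param C_grid penalty grid
#' @param delta_grid RBF kernel width grid
#' @param outer_folds,inner_folds stratified fold counts (>= 2)
#' @param n_repeats cross-validation repeats
#' @param max_features cap on features added by forward selection
#'   (`Inf` = no cap)
#' @param seed base seed; repeat r uses `seed + r`
#' @return list of class `svm_config`
#' @export
svm_config <- function(C_grid = 2^seq(-5, 15, by = 2),
                       delta_grid = 2^seq(-15, 3, by = 2),
                       outer_folds = 5, inner_folds = 5,
                       n_repeats = 10, max_features = Inf, seed = 1) {
  stopifnot(length(C_grid) > 0, length(delta_grid) > 0,
            all(C_grid > 0), all(delta_grid > 0),
            outer_folds >= 2, inner_folds >= 2, n_repeats >= 1)
  structure(list(C_grid = C_grid, delta_grid = delta_grid,
                 outer_folds = outer_folds, inner_folds = inner_folds,
                 n_repeats = n_repeats, max_features = max_features,
                 seed = seed),
            class = "svm_config")
}

#' Build a trial-by-feature matrix for state classification
#'
#' Each force-trial cell is the mean z-score of one channel x band feature
#' over -400 to +400 ms around force onset; each trial also contributes a
#' rest row averaged over the matching window centred 1 s into the
#' following rest period (600-1400 ms after force offset), late enough for
#' the channels to have returned to resting levels. Two-state labels pool
#' all force levels against rest; three-state labels use the lowest level
#' (LIGHT) and highest level (HARD) against rest, dropping intermediate
#' levels. Trials without a detected onset are excluded and counted in the
#' `n_excluded` attribute.
#'
#' @param bp a `band_power` object
#' @param trials trial table with onset and offset times (imagined trials
#'   must have surrogate onsets from [assign_imagined_onsets()])
#' @param states `"two"` (rest vs force) or `"three"` (rest/light/hard)
#' @param force_window seconds around force onset
#' @param rest_center seconds after force offset at which the rest window
#'   is centred
#' @param executed use executed (`TRUE`) or imagined (`FALSE`) trials
#' @return object of class `feature_matrix`: `x` (trials x features), `y`
#'   (factor), `meta`, `feature_info`
#' @export
build_feature_matrix <- function(bp, trials, states = c("two", "three"),
                                 force_window = c(-0.4, 0.4),
                                 rest_center = 1.0, executed = TRUE) {
  states <- match.arg(states)
  tr <- trials[trials$executed == executed & !is.na(trials$onset_time_s), ]
  n_excluded <- sum(trials$executed == executed) - nrow(tr)
  if (nrow(tr) == 0) stop("no trials with onset times to classify")
  rest_events <- tr$offset_time_s + rest_center
  half <- (force_window[2] - force_window[1]) / 2

  window_means <- function(events, window) {
    ep <- epoch_bandpower(bp, events, window)
    m <- apply(ep, c(1, 2, 3), mean)        # trials x channels x features
    list(x = matrix(aperm(m, c(1, 3, 2)), nrow = dim(m)[1]),
         kept = attr(ep, "kept"))
  }
  fw <- window_means(tr$onset_time_s, force_window)
  rw <- window_means(rest_events, c(-half, half))
  # columns are channel-major: ch1_feat1, ch1_feat2, ..., ch2_feat1, ...
  n_ch <- dim(bp$values)[1]
  n_ft <- dim(bp$values)[2]
  ch_names <- bp$channel_names %||% as.character(seq_len(n_ch))
  cn <- as.vector(t(outer(ch_names, bp$features, paste, sep = "_")))
  fx <- fw$x
  rx <- rw$x
  colnames(fx) <- colnames(rx) <- cn

  tr_f <- tr[fw$kept, ]
  tr_r <- tr[rw$kept, ]
  lab_force <- if (states == "two") rep("FORCE", nrow(tr_f)) else {
    lv <- tr_f$level_pct_mvc
    ifelse(lv == min(trials$level_pct_mvc), "LIGHT",
           ifelse(lv == max(trials$level_pct_mvc), "HARD", NA))
  }
  keep_f <- !is.na(lab_force)
  x <- rbind(fx[keep_f, , drop = FALSE], rx)
  y <- factor(c(lab_force[keep_f], rep("REST", nrow(rx))),
              levels = if (states == "two") c("REST", "FORCE")
                       else c("REST", "LIGHT", "HARD"))
  meta <- data.frame(
    trial_id = c(tr_f$trial_id[keep_f], tr_r$trial_id),
    grasp = c(tr_f$grasp[keep_f], tr_r$grasp),
    executed = executed,
    role = rep(c("force", "rest"), c(sum(keep_f), nrow(tr_r))),
    stringsAsFactors = FALSE)
  fi <- data.frame(column = cn,
                   channel = rep(ch_names, each = n_ft),
                   band = rep(bp$features, n_ch),
                   stringsAsFactors = FALSE)
  if (!is.null(bp$channels)) {
    fi$region <- bp$channels$region[match(fi$channel, bp$channels$channel)]
    fi$shaft_id <- bp$channels$shaft_id[match(fi$channel,
                                              bp$channels$channel)]
  }
  structure(list(x = x, y = y, meta = meta, feature_info = fi),
            class = "feature_matrix",
            n_excluded = n_excluded)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d trials x %d features\n",
              nrow(x$x), ncol(x$x)))
  print(table(x$y))
  invisible(x)
}

#' Subsample rest trials to match force class counts
#'
#' Keeps a uniform random subsample of rest rows equal to the (smallest)
#' force-class count so class priors do not bias the classifier.
#'
#' @param fm a `feature_matrix`
#' @param seed seed for the subsample
#' @return a balanced `feature_matrix`
#' @export
balance_rest <- function(fm, seed = 1) {
  counts <- table(fm$y)
  force_classes <- setdiff(names(counts), "REST")
  target <- min(counts[force_classes])
  n_rest <- counts[["REST"]]
  if (n_rest < target)
    stop("fewer rest trials (", n_rest, ") than force trials per class (",
         target, ")")
  if (n_rest == target) return(fm)
  set.seed(seed)
  rest_idx <- which(fm$y == "REST")
  keep <- sort(c(which(fm$y != "REST"), sample(rest_idx, target)))
  fm$x <- fm$x[keep, , drop = FALSE]
  fm$y <- droplevels(fm$y[keep])
  fm$meta <- fm$meta[keep, , drop = FALSE]
  fm
}

#' Stratified fold assignment
#'
#' Deals units out to folds round-robin within each class after shuffling.
#' `groups` forces rows of the same group (e.g. duplicated trials) into the
#' same fold. Errors if a class is too small for every training partition
#' to contain it.
#'
#' @param y class labels
#' @param k number of folds
#' @param groups optional grouping vector
#' @return integer fold id per row
#' @export
make_stratified_folds <- function(y, k, groups = NULL) {
  groups <- groups %||% seq_along(y)
  units <- unique(groups)
  unit_y <- y[match(units, groups)]
  if (any(table(unit_y) < 2))
    stop("cannot stratify: a class has fewer than 2 unit(s)")
  fold_of_unit <- integer(length(units))
  offset <- 0L
  for (cl in levels(factor(unit_y))) {
    idx <- which(unit_y == cl)
    idx <- idx[sample.int(length(idx))]
    # rotate the starting fold between classes to even out fold sizes
    fold_of_unit[idx] <- ((seq_along(idx) - 1 + offset) %% k) + 1
    offset <- offset + length(idx) %% k
  }
  fold_of_unit[match(groups, units)]
}

scale_apply <- function(x, center, scale) {
  scale[scale == 0] <- 1
  sweep(sweep(x, 2, center), 2, scale, "/")
}

fit_predict_svm <- function(xtr, ytr, xte, C, delta) {
  fit <- e1071::svm(x = xtr, y = ytr, scale = FALSE, kernel = "radial",
                    cost = C, gamma = delta)
  stats::predict(fit, xte)
}

# pooled inner-CV accuracy per fold for a fixed (C, delta) and feature set;
# standardization is refit on each inner-training split
inner_fold_accs <- function(x, y, folds, C, delta, cols) {
  vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    mu <- colMeans(x[tr, cols, drop = FALSE])
    sg <- apply(x[tr, cols, drop = FALSE], 2, stats::sd)
    xtr <- scale_apply(x[tr, cols, drop = FALSE], mu, sg)
    xte <- scale_apply(x[!tr, cols, drop = FALSE], mu, sg)
    mean(fit_predict_svm(xtr, y[tr], xte, C, delta) == y[!tr])
  }, numeric(1))
}

tune_svm <- function(x, y, folds, config, cols) {
  best <- NULL
  best_acc <- -Inf
  for (C in config$C_grid) {
    for (delta in config$delta_grid) {
      acc <- mean(inner_fold_accs(x, y, folds, C, delta, cols))
      if (acc > best_acc) {
        best_acc <- acc
        best <- c(C = C, delta = delta)
      }
    }
  }
  list(C = best[["C"]], delta = best[["delta"]], acc = best_acc)
}

# greedy forward selection with fixed (C, delta) on fixed inner folds;
# halts when the best candidate's paired improvement over the current set
# is not larger than one standard error of the per-fold differences
sfs_select <- function(x, y, folds, C, delta, max_features = Inf) {
  p <- ncol(x)
  selected <- integer(0)
  cur_accs <- NULL
  while (length(selected) < min(p, max_features)) {
    cand <- setdiff(seq_len(p), selected)
    best_j <- NA_integer_
    best_accs <- NULL
    best_mean <- -Inf
    for (j in cand) {
      accs <- inner_fold_accs(x, y, folds, C, delta, c(selected, j))
      if (mean(accs) > best_mean) {   # strict: ties keep the lowest index
        best_mean <- mean(accs)
        best_j <- j
        best_accs <- accs
      }
    }
    if (length(selected) == 0) {
      selected <- best_j
      cur_accs <- best_accs
      next
    }
    d <- best_accs - cur_accs
    se <- stats::sd(d) / sqrt(length(d))
    accept <- if (is.na(se) || se == 0) mean(d) > 0 else mean(d) > se
    if (!accept) break
    selected <- c(selected, best_j)
    cur_accs <- best_accs
  }
  selected
}

#' Nested cross-validated RBF-SVM classification
#'
#' Two-stage cross-validation: hyperparameters (and, with `sfs = TRUE`, the
#' feature subset) are chosen by stratified inner cross-validation on each
#' outer-training partition; generalization accuracy is measured only on
#' the untouched outer-test folds, pooled over folds, and averaged over
#' `n_repeats` random partitions. Feature standardization is refit inside
#' every training split, so no statistic of the test data ever reaches the
#' model. Duplicated rows are forced into the same fold. With `sfs`, the
#' (C, delta) pair is tuned once per outer fold on all candidate features
#' and then held fixed during greedy selection; selection halts when the
#' best candidate's mean inner-CV improvement does not exceed one standard
#' error of its per-fold differences.
#'
#' @param fm a `feature_matrix` (or a list with `x` and `y`)
#' @param config an [svm_config()]
#' @param features optional column indices or names restricting the
#'   feature set
#' @param sfs run sequential forward selection inside each outer fold
#' @param folds optional fixed outer fold assignment (vector of fold ids,
#'   one per row) used for every repeat; default: fresh stratified folds
#'   per repeat
#' @param keep_fold_details retain per-repeat fold assignments and
#'   outer-test predictions
#' @return object of class `svm_cv_result`
#' @export
nested_cv_svm <- function(fm, config = svm_config(), features = NULL,
                          sfs = FALSE, folds = NULL,
                          keep_fold_details = FALSE) {
  x <- fm$x
  y <- fm$y
  if (!is.null(features)) x <- x[, features, drop = FALSE]
  stopifnot(nlevels(droplevels(factor(y))) >= 2)
  y <- droplevels(factor(y))
  # co-assign byte-identical rows to one fold
  row_key <- apply(x, 1, function(r)
    paste(format(r, digits = 17), collapse = ","))
  groups <- match(row_key, unique(row_key))

  n_rep <- config$n_repeats
  accuracies <- numeric(n_rep)
  confusions <- vector("list", n_rep)
  params <- NULL
  selected <- vector("list", n_rep)
  details <- if (keep_fold_details) vector("list", n_rep) else NULL

  for (r in seq_len(n_rep)) {
    set.seed(config$seed + r)
    fr <- folds %||% make_stratified_folds(y, config$outer_folds, groups)
    pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
    sel_r <- vector("list", length(unique(fr)))
    for (k in sort(unique(fr))) {
      set.seed((config$seed + r) * 1000 + k)   # fold-local RNG
      tr <- fr != k
      xtr_raw <- x[tr, , drop = FALSE]
      ytr <- y[tr]
      inner <- make_stratified_folds(ytr, config$inner_folds,
                                     groups[tr])
      tuned <- tune_svm(xtr_raw, ytr, inner, config, seq_len(ncol(x)))
      cols <- seq_len(ncol(x))
      if (sfs) {
        cols <- sfs_select(xtr_raw, ytr, inner, tuned$C, tuned$delta,
                           config$max_features)
        if (length(cols) == 0) cols <- 1L
      }
      mu <- colMeans(xtr_raw[, cols, drop = FALSE])
      sg <- apply(xtr_raw[, cols, drop = FALSE], 2, stats::sd)
      xtr <- scale_apply(xtr_raw[, cols, drop = FALSE], mu, sg)
      xte <- scale_apply(x[!tr, cols, drop = FALSE], mu, sg)
      pred[!tr] <- fit_predict_svm(xtr, ytr, xte, tuned$C, tuned$delta)
      params <- rbind(params, data.frame(repeat_ = r, fold = k,
                                         C = tuned$C, delta = tuned$delta))
      sel_r[[k]] <- colnames(x)[cols]
    }
    accuracies[r] <- mean(pred == y)
    cm <- table(truth = y, pred = pred)
    confusions[[r]] <- cm / rowSums(cm)
    if (sfs) selected[[r]] <- sel_r
    if (keep_fold_details)
      details[[r]] <- list(folds = fr, pred = pred, truth = y)
  }
  conf <- Reduce(`+`, confusions) / n_rep
  structure(list(mean_accuracy = mean(accuracies),
                 accuracies = accuracies,
                 confusion = conf,
                 best_params = params,
                 selected_features = if (sfs) selected else NULL,
                 n_trials = length(y),
                 levels = levels(y),
                 config = config,
                 fold_details = details),
            class = "svm_cv_result")
}

#' @export
print.svm_cv_result <- function(x, ...) {
  cat(sprintf(
    "<svm_cv_result> %d-state, %d trials: mean accuracy %.3f (range %.3f-%.3f over %d repeats)\n",
    length(x$levels), x$n_trials, x$mean_accuracy, min(x$accuracies),
    max(x$accuracies), length(x$accuracies)))
  cat("  mean row-normalized confusion matrix:\n")
  print(round(x$confusion, 3))
  if (!is.null(x$selected_features)) {
    feats <- table(unlist(x$selected_features))
    feats <- sort(feats, decreasing = TRUE)
    cat("  most-selected features:",
        paste(utils::head(names(feats), 5), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Single-feature classification screen
#'
#' Runs the nested-CV SVM once per feature (tuning C and delta per
#' feature), the screen used to ask which individual channel x band
#' features discriminate force from rest.
#'
#' @param fm a `feature_matrix`
#' @param config an [svm_config()]
#' @return data.frame with one row per feature: `mean_accuracy`, accuracy
#'   range over repeats, and the feature's channel/region/band
#' @export
single_feature_screen <- function(fm, config = svm_config()) {
  out <- fm$feature_info
  out$mean_accuracy <- NA_real_
  out$min_accuracy <- NA_real_
  out$max_accuracy <- NA_real_
  for (j in seq_len(ncol(fm$x))) {
    res <- nested_cv_svm(fm, config, features = j)
    out$mean_accuracy[j] <- res$mean_accuracy
    out$min_accuracy[j] <- min(res$accuracies)
    out$max_accuracy[j] <- max(res$accuracies)
  }
  out
}
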