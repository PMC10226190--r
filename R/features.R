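#' Per-epoch feature table
#'
#' One row per (subject, epoch) for one frequency band; columns are the
#' row-major vectorized 30 x 30 band connectome (900 values, diagonal zeros
#' retained), optionally concatenated with the 121 graph-metric values.
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param y Factor of group labels, one per row.
#' @param subject Character vector of subject ids, one per row.
#' @param epoch Integer epoch index, one per row.
#' @param band Band label for the table.
#' @return Object of class `feature_table`.
#' @export
feature_table <- function(x, y, subject, epoch, band) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), nrow(x) == length(subject),
            nrow(x) == length(epoch))
  if (anyNA(x)) stop("feature matrix contains missing values")
  structure(list(x = x, y = factor(y), subject = as.character(subject),
                 epoch = as.integer(epoch), band = band),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> band %s: %d rows x %d features, %d classes, %d subjects\n",
              x$band, nrow(x$x), ncol(x$x), nlevels(x$y),
              length(unique(x$subject))))
  invisible(x)
}

#' Assemble per-band feature tables from subject-level results
#'
#' For each band, vectorizes every subject's per-epoch connectome row-major
#' (900 values at 30 channels) and, in `"pdc+graph"` mode, appends the
#' 121-value graph-metric vector of that epoch, yielding per-band row
#' widths of 900 or 1021.
#'
#' @param subjects Named list; each element a list with `per_epoch` (named
#'   list band -> `n x n x E` connectome array), `group` (label) and, for
#'   `"pdc+graph"`, `metrics` (named list band -> `(4n+1) x E` matrix).
#' @param mode `"pdc"` or `"pdc+graph"`.
#' @return Named list band -> [feature_table()].
#' @export
build_features <- function(subjects, mode = c("pdc", "pdc+graph")) {
  mode <- match.arg(mode)
  bands <- names(subjects[[1]]$per_epoch)
  out <- lapply(bands, function(b) {
    rows <- list(); y <- c(); subj <- c(); ep <- c()
    for (s in names(subjects)) {
      a <- subjects[[s]]$per_epoch[[b]]
      ne <- dim(a)[3]
      if (mode == "pdc+graph") {
        gm <- subjects[[s]]$metrics[[b]]
        if (is.null(gm) || ncol(gm) != ne)
          stop("subject ", s, ": graph metrics misaligned with epochs")
      }
      for (e in seq_len(ne)) {
        v <- as.vector(t(a[, , e]))            # row-major vectorization
        if (mode == "pdc+graph") v <- c(v, gm[, e])
        rows[[length(rows) + 1L]] <- v
      }
      y <- c(y, rep(subjects[[s]]$group, ne))
      subj <- c(subj, rep(s, ne))
      ep <- c(ep, seq_len(ne))
    }
    feature_table(do.call(rbind, rows), y, subj, ep, b)
  })
  names(out) <- bands
  out
}

#' Per-epoch connectomes and graph metrics for one subject
#'
#' Convenience wrapper running [subject_connectome()] and (optionally)
#' per-epoch [compute_graph_metrics()] so the result plugs directly into
#' [build_features()].
#'
#' @param es An [epoch_set()].
#' @param group The subject's group label.
#' @param p MVAR order (default 5).
#' @param bands Band table.
#' @param with_metrics Also compute per-epoch graph metrics (default TRUE).
#' @param seed Louvain seed.
#' @return List with `per_epoch`, `mean`, `group` and (optionally) `metrics`.
#' @export
subject_features <- function(es, group, p = 5, bands = connectivity_bands(),
                             with_metrics = TRUE, seed = 42L) {
  sc <- subject_connectome(es, p, bands)
  out <- list(per_epoch = sc$per_epoch, mean = sc$mean, group = group)
  if (with_metrics) {
    out$metrics <- lapply(names(bands), function(b) {
      vapply(seq_len(dim(sc$per_epoch[[b]])[3]), function(e) {
        m <- sc$per_epoch[[b]][, , e]
        attr(m, "band") <- b
        metrics_vector(compute_graph_metrics(m, seed))
      }, numeric(4 * dim(sc$per_epoch[[b]])[1] + 1))
    })
    names(out$metrics) <- names(bands)
  }
  out
}

# fit one of the five supported classifiers on (xtr, ytr) and predict xte.
# xtr/xte are numeric matrices already standardized by the caller.
train_predict <- function(xtr, ytr, xte, classifier, params = list()) {
  cls <- toupper(classifier)
  maj <- names(sort(table(ytr), decreasing = TRUE))[1]   # degenerate fallback
  pred <- switch(
    cls,
    KNN = class::knn(xtr, xte, ytr, k = params$k %||% 5),
    LDA = tryCatch(
      predict(MASS::lda(xtr, grouping = ytr), xte)$class,
      error = function(e) factor(rep(maj, nrow(xte)), levels = levels(ytr))),
    NB = predict(e1071::naiveBayes(xtr, ytr), xte),
    DT = {
      df_tr <- data.frame(.y = ytr, xtr)
      df_te <- data.frame(xte); names(df_te) <- names(df_tr)[-1]
      fit <- rpart::rpart(.y ~ ., df_tr, method = "class",
                          control = rpart::rpart.control(
                            maxdepth = params$maxdepth %||% 5))
      predict(fit, df_te, type = "class")
    },
    SVM = predict(e1071::svm(xtr, ytr, kernel = "radial",
                             cost = params$cost %||% 1,
                             gamma = params$gamma %||% (1 / ncol(xtr))),
                  xte),
    stop("unknown classifier '", classifier,
         "'; supported: KNN, LDA, NB, DT, SVM"))
  factor(as.character(pred), levels = levels(ytr))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stratified fold assignment: within each class, shuffled round-robin
stratified_folds <- function(y, folds) {
  fold_id <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_id
}

#' Sequential forward feature selection
#'
#' Greedy wrapper selection: starting empty, repeatedly adds the column
#' that maximizes inner cross-validated accuracy of the estimator, stopping
#' at `k_max` columns or when the best improvement falls below `tol`.
#' Deterministic under `seed`.
#'
#' @param x Numeric feature matrix.
#' @param y Factor of labels.
#' @param estimator Classifier name used for the wrapper (default `"LDA"`,
#'   cheap and stable for repeated refits).
#' @param k_max Maximum number of columns to select (>= 1).
#' @param inner_folds Inner CV folds (default 5).
#' @param seed Integer seed.
#' @param tol Minimum accuracy improvement to continue (default 1e-4).
#' @return Integer vector of selected column indices (in selection order).
#' @export
sfs_select <- function(x, y, estimator = "LDA", k_max, inner_folds = 5,
                       seed = 1L, tol = 1e-4) {
  if (k_max < 1) stop("k_max must be >= 1")
  k_max <- min(k_max, ncol(x))
  y <- factor(y)
  with_seed(seed, {
    fold_id <- stratified_folds(y, inner_folds)
    cv_acc <- function(cols) {
      acc <- 0
      for (f in seq_len(inner_folds)) {
        te <- fold_id == f
        pred <- train_predict(x[!te, cols, drop = FALSE], y[!te],
                              x[te, cols, drop = FALSE], estimator)
        acc <- acc + sum(pred == y[te])
      }
      acc / length(y)
    }
    selected <- integer(0)
    best_acc <- -Inf
    repeat {
      cand <- setdiff(seq_len(ncol(x)), selected)
      accs <- vapply(cand, function(j) cv_acc(c(selected, j)), 0)
      if (max(accs) < best_acc + tol && length(selected) > 0) break
      best_acc <- max(accs)
      selected <- c(selected, cand[which.max(accs)])
      if (length(selected) >= k_max) break
    }
    selected
  })
}

#' Stratified k-fold cross-validated classification
#'
#' Stratified fold assignment over rows (epochs as samples, the
#' subject-dependent protocol; set `by_subject = TRUE` for the
#' subject-grouped variant that keeps all epochs of a subject in one fold).
#' Within every training fold, and only there: z-score standardization is
#' fit, optional sequential forward selection is run, and the classifier is
#' trained; the held-out fold is then transformed and predicted. Predicted
#' labels are aggregated over all folds.
#'
#' @param table A [feature_table()].
#' @param classifier One of `"KNN"`, `"LDA"`, `"NB"`, `"DT"`, `"SVM"`.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed.
#' @param sfs_k If non-NULL, run [sfs_select()] with this `k_max` inside
#'   each training fold.
#' @param by_subject Grouped folds by subject instead of by row.
#' @param params Optional classifier hyperparameters (see
#'   `train_predict` defaults).
#' @return Object of class `cv_result`: aggregate and per-fold confusion
#'   matrices, metrics in percent (see [score_confusion()]), fold-wise
#'   accuracy mean and sd.
#' @export
crossvalidate <- function(table, classifier, folds = 10, seed = 1L,
                          sfs_k = NULL, by_subject = FALSE, params = list()) {
  stopifnot(inherits(table, "feature_table"))
  x <- table$x; y <- table$y
  if (min(table(y)) < folds && !by_subject)
    stop("need at least ", folds, " rows per class for ", folds, "-fold CV")
  with_seed(seed, {
    if (by_subject) {
      subj <- unique(table$subject)
      sgrp <- factor(table$y[match(subj, table$subject)])
      sfold <- stratified_folds(sgrp, folds)
      fold_id <- sfold[match(table$subject, subj)]
    } else {
      fold_id <- stratified_folds(y, folds)
    }
    pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
    fold_acc <- numeric(folds)
    for (f in seq_len(folds)) {
      te <- fold_id == f
      mu <- colMeans(x[!te, , drop = FALSE])
      sg <- apply(x[!te, , drop = FALSE], 2, sd)
      sg[sg == 0] <- 1
      xtr <- sweep(sweep(x[!te, , drop = FALSE], 2, mu), 2, sg, "/")
      xte <- sweep(sweep(x[te, , drop = FALSE], 2, mu), 2, sg, "/")
      cols <- seq_len(ncol(x))
      if (!is.null(sfs_k))
        cols <- sfs_select(xtr, y[!te], estimator = classifier,
                           k_max = sfs_k, seed = sample.int(1e6, 1))
      p <- train_predict(xtr[, cols, drop = FALSE], y[!te],
                         xte[, cols, drop = FALSE], classifier, params)
      pred[te] <- p
      fold_acc[f] <- 100 * mean(p == y[te])
    }
  })
  cm <- table(truth = y, predicted = pred)
  sc <- score_confusion(cm)
  structure(c(sc, list(confusion = cm, classifier = toupper(classifier),
                       folds = folds, band = table$band,
                       acc_mean = mean(fold_acc), acc_sd = sd(fold_acc),
                       fold_accuracy = fold_acc)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, %s band, %d-fold: accuracy %.2f%% (+/- %.2f), sensitivity %.2f%%, specificity %.2f%%\n",
              x$classifier, x$band %||% "?", x$folds, x$accuracy, x$acc_sd,
              x$sensitivity, x$specificity))
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, sensitivity and specificity in percent. For two classes these
#' are the direct true/false positive formulas; for more classes,
#' one-vs-rest sensitivity/specificity are macro-averaged. When a
#' `control` class is present, the SAD-vs-control collapsed binary metrics
#' are also returned (`binary_sensitivity` = detection of any
#' above-control severity, `binary_specificity` = control detection).
#'
#' @param cm Confusion matrix, rows = truth, columns = predicted.
#' @param control_class Label of the healthy class (default `"control"`).
#' @return List with `accuracy`, `sensitivity`, `specificity`, `per_class`,
#'   and optionally `binary_sensitivity` / `binary_specificity`, all in
#'   percent.
#' @export
score_confusion <- function(cm, control_class = "control") {
  cm <- as.matrix(cm)
  if (sum(cm) == 0) stop("empty confusion matrix")
  total <- sum(cm)
  acc <- 100 * sum(diag(cm)) / total
  per <- t(vapply(seq_len(nrow(cm)), function(i) {
    tp <- cm[i, i]; fn <- sum(cm[i, -i]); fp <- sum(cm[-i, i])
    tn <- total - tp - fn - fp
    c(sensitivity = 100 * tp / (tp + fn),
      specificity = 100 * tn / (tn + fp))
  }, c(sensitivity = 0, specificity = 0)))
  rownames(per) <- rownames(cm)
  out <- list(accuracy = acc,
              sensitivity = mean(per[, "sensitivity"], na.rm = TRUE),
              specificity = mean(per[, "specificity"], na.rm = TRUE),
              per_class = per)
  if (control_class %in% rownames(cm) && nrow(cm) > 2) {
    sad <- setdiff(rownames(cm), control_class)
    tp <- sum(cm[sad, sad]); fn <- sum(cm[sad, control_class])
    fp <- sum(cm[control_class, sad]); tn <- cm[control_class, control_class]
    out$binary_sensitivity <- 100 * tp / (tp + fn)
    out$binary_specificity <- 100 * tn / (tn + fp)
  }
  out
}

#' Full classification factorial
#'
#' Runs [crossvalidate()] for every combination of feature mode, band and
#' classifier, returning one tidy row per combination and metric
#' (mean +/- sd across folds for accuracy; aggregate sensitivity and
#' specificity).
#'
#' @param tables Named list mode -> (named list band -> [feature_table()]),
#'   e.g. as produced by [build_features()] per mode.
#' @param classifiers Classifier names (default all five).
#' @param folds,seed,sfs_k,params Passed to [crossvalidate()].
#' @return data.frame with columns `feature_set`, `classifier`, `band`,
#'   `metric`, `mean`, `sd`.
#' @export
run_matrix <- function(tables, classifiers = c("KNN", "LDA", "NB", "DT", "SVM"),
                       folds = 10, seed = 1L, sfs_k = NULL, params = list()) {
  rows <- list()
  for (mode in names(tables)) for (b in names(tables[[mode]]))
    for (cl in classifiers) {
      cv <- crossvalidate(tables[[mode]][[b]], cl, folds = folds,
                          seed = derive_seed(seed, length(rows) + 1L),
                          sfs_k = sfs_k, params = params)
      rows[[length(rows) + 1L]] <-
        data.frame(feature_set = mode, classifier = cl, band = b,
                   metric = c("accuracy", "sensitivity", "specificity"),
                   mean = c(cv$acc_mean, cv$sensitivity, cv$specificity),
                   sd = c(cv$acc_sd, NA, NA))
    }
  do.call(rbind, rows)
}
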