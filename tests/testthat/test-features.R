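fake_subjects <- function(n_sub = 2, n = 30, ne = 5, seed = 1) {
  withr::with_seed(seed, {
    subs <- lapply(seq_len(n_sub), function(s) {
      pe <- lapply(connectivity_bands(), function(b) {
        a <- array(runif(n * n * ne), c(n, n, ne))
        for (e in seq_len(ne)) diag(a[, , e]) <- 0
        a
      })
      mets <- lapply(connectivity_bands(), function(b)
        matrix(runif((4 * n + 1) * ne), 4 * n + 1, ne))
      list(per_epoch = pe, metrics = mets,
           group = c("severe", "control")[1 + s %% 2])
    })
    names(subs) <- sprintf("sub-%02d", seq_len(n_sub))
    subs
  })
}

test_that("feature tables have the canonical widths and row counts", {
  subs <- fake_subjects(n_sub = 1, ne = 40)
  pdc_only <- build_features(subs, mode = "pdc")
  both <- build_features(subs, mode = "pdc+graph")
  expect_named(pdc_only, c("delta", "theta", "alpha", "beta"))
  expect_equal(ncol(pdc_only$theta$x), 900)
  expect_equal(ncol(both$theta$x), 1021)
  # one subject, 40 epochs, 4 bands: 160 rows in total
  expect_equal(sum(vapply(pdc_only, function(tb) nrow(tb$x), 0)), 160)
  # row-major vectorization: entry (i, j) lands at (i-1)*n + j
  a <- subs[[1]]$per_epoch$theta[, , 1]
  expect_equal(pdc_only$theta$x[1, (2 - 1) * 30 + 5], a[2, 5])
  # diagonal zeros retained
  expect_true(all(pdc_only$theta$x[, (0:29) * 30 + 1:30] == 0))
  bad <- subs
  bad[[1]]$metrics$theta <- bad[[1]]$metrics$theta[, 1:3]
  expect_error(build_features(bad, mode = "pdc+graph"), "misaligned")
})

test_that("sequential forward selection finds planted features", {
  hits <- vapply(1:20, function(s) {
    tab <- make_clusters(n_per = 25, informative = 2, noise = 98,
                         sep = 3, seed = 1000 + s)
    sel <- sfs_select(tab$x, tab$y, estimator = "LDA", k_max = 4,
                      seed = 2000 + s)
    all(1:2 %in% sel)
  }, TRUE)
  expect_gte(mean(hits), 0.9)
  tab <- make_clusters(seed = 3)
  one <- sfs_select(tab$x, tab$y, k_max = 1, seed = 5)
  expect_length(one, 1)
  expect_true(one %in% 1:2)      # an informative column is the single best
  sel <- sfs_select(tab$x, tab$y, k_max = 5, seed = 6)
  expect_true(all(sel %in% seq_len(ncol(tab$x))))
  expect_false(anyDuplicated(sel) > 0)
  expect_error(sfs_select(tab$x, tab$y, k_max = 0, seed = 1), "k_max")
  # deterministic under seed
  expect_identical(sfs_select(tab$x, tab$y, k_max = 3, seed = 9),
                   sfs_select(tab$x, tab$y, k_max = 3, seed = 9))
})

test_that("cross-validation is exact on separable data and fair on noise", {
  # four well-separated clusters at the corners of a square
  corners <- matrix(c(-10, -10, -10, 10, 10, -10, 10, 10), 4, 2,
                    byrow = TRUE)
  y <- rep(c("severe", "moderate", "mild", "control"), each = 30)
  x <- withr::with_seed(11, corners[rep(1:4, each = 30), ] +
                          matrix(rnorm(240), 120))
  tab <- feature_table(x, y, subject = sprintf("s%03d", 1:120),
                       epoch = rep(1L, 120), band = "alpha")
  for (cl in c("KNN", "LDA", "SVM")) {
    cv <- crossvalidate(tab, cl, folds = 10, seed = 1)
    expect_equal(cv$accuracy, 100)
  }
  # chance level under label permutation, averaged over seeds
  accs <- vapply(1:20, function(s) {
    tabp <- tab
    tabp$y <- withr::with_seed(s, sample(tab$y))
    crossvalidate(tabp, "LDA", folds = 5, seed = s)$accuracy
  }, 0)
  expect_equal(mean(accs), 25, tolerance = 6 / 25)
  expect_error(crossvalidate(tab, "MLP", seed = 1), "KNN, LDA, NB, DT, SVM")
})

test_that("fold test sets partition the rows exactly", {
  tab <- make_clusters(n_per = 20, seed = 21)
  fold_id <- pdcnet:::with_seed(7, pdcnet:::stratified_folds(tab$y, 10))
  expect_equal(sort(unique(fold_id)), 1:10)
  expect_equal(length(fold_id), nrow(tab$x))
  expect_true(all(table(fold_id) == nrow(tab$x) / 10))
  # subject-grouped mode keeps each subject's rows in one fold
  tab2 <- make_clusters(n_per = 20, seed = 22)
  tab2$subject <- rep(sprintf("s%02d", 1:20), each = 4)
  cv <- crossvalidate(tab2, "LDA", folds = 5, seed = 2, by_subject = TRUE)
  expect_equal(sum(cv$confusion), nrow(tab2$x))
})

test_that("no information leaks from test folds into selection", {
  # canary column: equals the class label on one known fold's rows only,
  # noise elsewhere. Honest per-fold SFS never sees a usable canary at
  # train time, so accuracy stays at chance.
  n_per <- 25; folds <- 5; seed <- 31
  y <- factor(rep(c("severe", "moderate", "mild", "control"), each = n_per))
  x <- matrix(withr::with_seed(41, rnorm(length(y) * 10)), length(y))
  fold_id <- pdcnet:::with_seed(seed, pdcnet:::stratified_folds(y, folds))
  canary <- withr::with_seed(42, rnorm(length(y)))
  canary[fold_id == 1] <- as.numeric(y)[fold_id == 1]
  tab <- feature_table(cbind(canary, x), y,
                       subject = sprintf("s%03d", seq_along(y)),
                       epoch = rep(1L, length(y)), band = "alpha")
  cv <- crossvalidate(tab, "LDA", folds = folds, seed = seed, sfs_k = 2)
  expect_lt(cv$accuracy, 45)                      # chance is 25%
  expect_lt(cv$fold_accuracy[1], 60)
})

test_that("confusion-matrix scoring reproduces the textbook formulas", {
  cm <- matrix(c(9, 1, 2, 8), 2, 2, byrow = TRUE,
               dimnames = list(c("pos", "neg"), c("pos", "neg")))
  sc <- score_confusion(cm)
  expect_equal(sc$accuracy, 85)
  expect_equal(sc$per_class["pos", "sensitivity"], 90)
  expect_equal(sc$per_class["pos", "specificity"], 80)
  perfect <- diag(c(10, 10, 10, 10))
  dimnames(perfect) <- list(levels <- c("severe", "moderate", "mild",
                                        "control"), levels)
  sp <- score_confusion(perfect)
  expect_equal(sp$accuracy, 100)
  expect_equal(sp$sensitivity, 100)
  expect_equal(sp$specificity, 100)
  expect_equal(sp$binary_sensitivity, 100)
  expect_equal(sp$binary_specificity, 100)
  expect_error(score_confusion(matrix(0, 2, 2)), "empty")
  # macro average reduces to the binary formulas for two classes
  sc2 <- score_confusion(cm)
  expect_equal(sc2$sensitivity, mean(c(90, 80)))
})

test_that("the classification factorial covers modes x classifiers x bands", {
  tabs <- list(
    pdc = list(alpha = make_clusters(n_per = 20, sep = 2, seed = 51)),
    `pdc+graph` = list(alpha = make_clusters(n_per = 20, sep = 5, seed = 51)))
  rep1 <- run_matrix(tabs, classifiers = c("KNN", "LDA"), folds = 5, seed = 3)
  expect_equal(nrow(rep1), 2 * 2 * 3)    # modes x classifiers x 3 metrics
  rep2 <- run_matrix(tabs, classifiers = c("KNN", "LDA"), folds = 5, seed = 3)
  expect_identical(rep1, rep2)           # bit-exact under a fixed seed
  # a more separable feature block should not hurt mean accuracy
  acc <- with(rep1, tapply(mean[metric == "accuracy"],
                           feature_set[metric == "accuracy"], mean))
  expect_gte(acc[["pdc+graph"]], acc[["pdc"]])
})
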