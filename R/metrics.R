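# Classification metrics (ACC, MCC, AUC) and the stratified k-fold
# cross-validation harness.

check_labels_scores <- function(labels, scores) {
  if (length(labels) == 0L) stop("empty input", call. = FALSE)
  if (length(labels) != length(scores)) {
    stop("`labels` and `scores` lengths differ", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1))) {
    stop("`labels` must be binary 0/1", call. = FALSE)
  }
}

#' Classification accuracy at a threshold
#'
#' @param labels 0/1 vector.
#' @param scores Predicted probabilities.
#' @param threshold Decision threshold (default 0.5; scores at or above it
#'   are called positive).
#' @return Fraction of correct calls.
#' @export
accuracy <- function(labels, scores, threshold = 0.5) {
  check_labels_scores(labels, scores)
  mean((scores >= threshold) == (labels == 1))
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; returns 0 when
#' any factor of the denominator is zero (degenerate confusion matrix).
#'
#' @inheritParams accuracy
#' @return Value in `[-1, 1]`.
#' @export
mcc <- function(labels, scores, threshold = 0.5) {
  check_labels_scores(labels, scores)
  pred <- as.numeric(scores >= threshold)
  # doubles: the denominator product overflows 32-bit integers at n ~ 200
  tp <- as.numeric(sum(pred == 1 & labels == 1))
  tn <- as.numeric(sum(pred == 0 & labels == 0))
  fp <- as.numeric(sum(pred == 1 & labels == 0))
  fn <- as.numeric(sum(pred == 0 & labels == 1))
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive outscores
#' a random negative, ties counted one half. Computed from mean ranks.
#'
#' @inheritParams accuracy
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(labels, scores) {
  check_labels_scores(labels, scores)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC requires both classes to be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' All three metrics as a one-row report
#'
#' @inheritParams accuracy
#' @return One-row tibble: `acc`, `mcc`, `auc`, `n_pos`, `n_neg`.
#' @export
metrics_report <- function(labels, scores, threshold = 0.5) {
  tibble::tibble(acc = accuracy(labels, scores, threshold),
                 mcc = mcc(labels, scores, threshold),
                 auc = auc(labels, scores),
                 n_pos = sum(labels == 1),
                 n_neg = sum(labels == 0))
}

#' Stratified k-fold assignment
#'
#' Shuffled, seeded, class-stratified partition: within each class the fold
#' sizes differ by at most one.
#'
#' @param labels 0/1 (or categorical) label vector.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in 1..k, one per sample.
#' @export
kfold_split <- function(labels, k = 10L, seed = 1L) {
  stopifnot(k >= 2L)
  folds <- integer(length(labels))
  withr::with_seed(as.integer(seed), {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < k) {
        stop("class ", cl, " has fewer than k = ", k, " members",
             call. = FALSE)
      }
      folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Cross-validated evaluation of the ORI classifier
#'
#' Stratified k-fold cross-validation: for every fold the model is trained
#' on the remaining k-1 parts (with an inner stratified 90/10
#' train/validation split for early stopping) and ACC/MCC/AUC are measured
#' on the held-out part.
#'
#' @param data Labelled sequence tibble (`id`, `seq`, `label`).
#' @param zconfig A [zspace()] configuration.
#' @param cconfig,tconfig Model/training configuration.
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @param threshold Decision threshold for ACC/MCC.
#' @param train_fn Optional custom trainer `function(x_train, y_train)`
#'   returning a scorer `function(x_test) -> scores` (used to evaluate the
#'   harness with cheap or degenerate models).
#' @return Object of class `ori_cv`: per-fold metrics, fold assignment and
#'   aggregates; see [tidy.ori_cv()] and [glance.ori_cv()].
#' @export
cross_validate <- function(data, zconfig = zspace(),
                           cconfig = classifier_config(zspace_dim(zconfig)),
                           tconfig = train_config(), k = 10L, seed = 1L,
                           threshold = 0.5, train_fn = NULL) {
  data <- tibble::as_tibble(data)
  stopifnot("label" %in% names(data))
  enc <- encode_sequences(data, zconfig)
  x <- z_matrix(enc)
  y <- as.numeric(data$label)
  folds <- kfold_split(y, k = k, seed = seed)
  per_fold <- lapply(seq_len(k), function(f) {
    tr <- folds != f
    scorer <- if (is.null(train_fn)) {
      xt <- x[tr, , drop = FALSE]; yt <- y[tr]
      iv <- stratified_holdout(yt, 0.1,
                               derive_seed(seed, paste0("fold", f)))
      tcf <- tconfig
      tcf$seed <- derive_seed(tconfig$seed, paste0("fold", f))
      model <- train_classifier(xt[-iv, , drop = FALSE], yt[-iv],
                                xt[iv, , drop = FALSE], yt[iv],
                                cconfig, tcf)
      function(xx) predict(model, xx)
    } else {
      train_fn(x[tr, , drop = FALSE], y[tr])
    }
    scores <- scorer(x[!tr, , drop = FALSE])
    dplyr::mutate(metrics_report(y[!tr], scores, threshold),
                  fold = f, .before = 1L)
  })
  structure(list(folds = dplyr::bind_rows(per_fold),
                 assignment = folds, k = k, seed = seed),
            class = "ori_cv")
}

#' @export
print.ori_cv <- function(x, ...) {
  cat("<ori_cv> ", x$k, "-fold cross-validation\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' Per-fold cross-validation metrics
#' @param x An `ori_cv`.
#' @param ... Unused.
#' @return Tibble with one row per fold (acc, mcc, auc, class sizes).
#' @export
tidy.ori_cv <- function(x, ...) x$folds

#' Aggregate cross-validation metrics
#' @param x An `ori_cv`.
#' @param ... Unused.
#' @return One-row tibble with mean and SD of each metric.
#' @export
glance.ori_cv <- function(x, ...) {
  f <- x$folds
  tibble::tibble(k = x$k,
                 acc = mean(f$acc), acc_sd = stats::sd(f$acc),
                 mcc = mean(f$mcc), mcc_sd = stats::sd(f$mcc),
                 auc = mean(f$auc), auc_sd = stats::sd(f$auc))
}

#' Plot per-fold cross-validation metrics
#' @param object An `ori_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ori_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(object$folds[c("fold", "acc", "mcc", "auc")],
                              -"fold", names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(.data$metric, .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "per-fold value") +
    ggplot2::theme_minimal()
}

#' Per-line and pooled cross-validation across cell-line datasets
#'
#' Runs [cross_validate()] on each labelled dataset alone and on their
#' pooled union, for comparing per-line models with a cross-line model.
#'
#' @param datasets Named list (>= 2) of labelled sequence tibbles, each with
#'   both classes present.
#' @param ... Passed on to [cross_validate()].
#' @return Named list of `ori_cv` objects (one per dataset plus `"pooled"`).
#' @export
cross_cell_line_experiment <- function(datasets, ...) {
  stopifnot(is.list(datasets), length(datasets) >= 2L)
  if (is.null(names(datasets))) {
    names(datasets) <- paste0("set", seq_along(datasets))
  }
  for (nm in names(datasets)) {
    if (length(unique(datasets[[nm]]$label)) < 2L) {
      stop("dataset ", nm, " does not contain both classes", call. = FALSE)
    }
  }
  out <- lapply(datasets, cross_validate, ...)
  pooled <- dplyr::bind_rows(datasets, .id = "line")
  pooled$id <- paste(pooled$line, pooled$id, sep = ".")
  out$pooled <- cross_validate(pooled, ...)
  out
}

#' Can sequences be told apart by pseudo-cell-line?
#'
#' Takes the positive (ORI-like) sequences of two datasets drawn from the
#' same distribution, labels them by line, and trains the classifier to
#' separate them; with identically distributed lines the metrics should sit
#' near chance (ACC about 0.5, AUC about 0.5), the negative control for
#' cross-line modelling.
#'
#' @param line_a,line_b Labelled tibbles (their `label == 1` rows are used).
#' @param zconfig,cconfig,tconfig Encoder/model/training configuration.
#' @param holdout_fraction Fraction held out for the reported metrics.
#' @param seed Integer seed.
#' @return One-row metrics tibble (acc, mcc, auc, class sizes).
#' @export
cell_line_discrimination <- function(line_a, line_b, zconfig = zspace(),
                                     cconfig = classifier_config(zspace_dim(zconfig)),
                                     tconfig = train_config(),
                                     holdout_fraction = 0.2, seed = 1L) {
  pos_a <- dplyr::filter(line_a, .data$label == 1L)
  pos_b <- dplyr::filter(line_b, .data$label == 1L)
  data <- dplyr::bind_rows(dplyr::mutate(pos_a, label = 1L),
                           dplyr::mutate(pos_b, label = 0L))
  data$id <- paste0("s", seq_len(nrow(data)))
  enc <- encode_sequences(data, zconfig)
  x <- z_matrix(enc)
  y <- as.numeric(data$label)
  test <- stratified_holdout(y, holdout_fraction, derive_seed(seed, "test"))
  val <- stratified_holdout(y[-test], 0.1, derive_seed(seed, "val"))
  xt <- x[-test, , drop = FALSE]; yt <- y[-test]
  model <- train_classifier(xt[-val, , drop = FALSE], yt[-val],
                            xt[val, , drop = FALSE], yt[val],
                            cconfig, tconfig)
  metrics_report(y[test], predict(model, x[test, , drop = FALSE]))
}
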