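#' Project descriptor triplets onto the first two principal components
#'
#' Centers and scales the feature columns to unit variance, performs the
#' eigen-decomposition of the correlation structure, and returns the first
#' two component scores together with the fraction of variance they explain.
#' Component signs are fixed by making the largest-magnitude loading of each
#' component positive.
#'
#' @param data A data frame containing the feature columns (metadata columns
#'   are carried through to the scores).
#' @param features Feature columns to project (default `c("SM", "B", "LS")`).
#' @return An object of class `mf_pca`: list with `scores` (input metadata
#'   plus `PC1`, `PC2`), `variance_explained` (first two components),
#'   `loadings`, and `sdev`.
#' @examples
#' d <- simulate_descriptors("day", seed = 1)
#' pca <- pca_project(d)
#' pca$variance_explained
#' @export
pca_project <- function(data, features = c("SM", "B", "LS")) {
  if (!is.data.frame(data) || nrow(data) < 3L) {
    mf_abort("`data` must be a data frame with at least 3 rows.", "input")
  }
  missing_cols <- setdiff(features, names(data))
  if (length(missing_cols) > 0) {
    mf_abort(paste0("Missing feature columns: ",
                    paste(missing_cols, collapse = ", "), "."), "input")
  }
  X <- as.matrix(data[, features])
  if (anyNA(X)) mf_abort("Feature columns contain missing values.", "input")
  sds <- apply(X, 2, sd)
  if (any(sds < 1e-12)) {
    mf_abort(paste0("Zero-variance feature column(s): ",
                    paste(features[sds < 1e-12], collapse = ", "), "."), "input")
  }
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  rot <- pc$rotation
  for (k in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, k]))
    if (rot[i, k] < 0) {
      rot[, k] <- -rot[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  ve <- sum(pc$sdev[1:2]^2) / sum(pc$sdev^2)
  scores <- dplyr::bind_cols(
    dplyr::select(data, -dplyr::all_of(features)),
    tibble(PC1 = pc$x[, 1], PC2 = pc$x[, 2]))
  structure(list(scores = scores, variance_explained = ve,
                 loadings = rot, sdev = pc$sdev, features = features),
            class = "mf_pca")
}

#' @export
print.mf_pca <- function(x, ...) {
  cat("<mf_pca> ", nrow(x$scores), " samples on (",
      paste(x$features, collapse = ", "), "); first two components explain ",
      sprintf("%.1f%%", 100 * x$variance_explained), " of the variance\n",
      sep = "")
  invisible(x)
}

#' @describeIn pca_project Scores tibble with metadata, `PC1` and `PC2`.
#' @param x,... An `mf_pca`; further arguments ignored.
#' @method tidy mf_pca
#' @export
tidy.mf_pca <- function(x, ...) x$scores

#' @describeIn pca_project One-row summary with the variance fractions.
#' @method glance mf_pca
#' @export
glance.mf_pca <- function(x, ...) {
  v <- x$sdev^2 / sum(x$sdev^2)
  tibble(variance_explained_2pc = x$variance_explained,
         variance_pc1 = v[1], variance_pc2 = v[2])
}

#' Rank-based AUC (area under the ROC curve)
#'
#' Probability that a randomly chosen positive is scored above a randomly
#' chosen negative; ties count one half. Computed from the Wilcoxon rank
#' sum, so it is invariant under strictly monotone transforms of the scores.
#'
#' @param score Numeric classifier scores (higher means more positive-like).
#' @param truth Labels, coercible to factor.
#' @param positive Label treated as positive (default: last factor level).
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_rank(c(0.9, 0.6, 0.8, 0.5), c("a", "a", "b", "b"), positive = "a")
#' @export
auc_rank <- function(score, truth, positive = NULL) {
  truth <- factor(truth)
  if (nlevels(truth) != 2L) mf_abort("`truth` must have exactly 2 classes.", "input")
  if (is.null(positive)) positive <- levels(truth)[2]
  pos <- truth == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) mf_abort("Both classes must be present.", "input")
  r <- rank(score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## ---- classifier registry -------------------------------------------------
## Each entry fits on (X, y) and returns a scoring closure giving
## P(positive)-like scores plus hard class predictions on new data.

median_heuristic_gamma <- function(X) {
  n <- nrow(X)
  idx <- if (n > 200) sample.int(n, 200) else seq_len(n)
  d <- stats::dist(X[idx, , drop = FALSE])
  med <- median(as.vector(d))
  if (!is.finite(med) || med <= 0) med <- 1
  1 / (2 * med^2)
}

make_classifiers <- function(knn_k = 5) {
  list(
    svm_linear = function(X, y, positive) {
      fit <- e1071::svm(X, y, kernel = "linear", probability = FALSE)
      sgn <- if (levels(y)[1] == positive) 1 else -1
      function(Xn) {
        pr <- predict(fit, Xn, decision.values = TRUE)
        list(score = sgn * drop(attr(pr, "decision.values")), class = pr)
      }
    },
    svm_radial = function(X, y, positive) {
      fit <- e1071::svm(X, y, kernel = "radial",
                        gamma = median_heuristic_gamma(X))
      sgn <- if (levels(y)[1] == positive) 1 else -1
      function(Xn) {
        pr <- predict(fit, Xn, decision.values = TRUE)
        list(score = sgn * drop(attr(pr, "decision.values")), class = pr)
      }
    },
    naive_bayes = function(X, y, positive) {
      fit <- e1071::naiveBayes(as.data.frame(X), y)
      function(Xn) {
        post <- predict(fit, as.data.frame(Xn), type = "raw")
        cls <- factor(colnames(post)[max.col(post, ties.method = "first")],
                      levels = levels(y))
        list(score = post[, positive], class = cls)
      }
    },
    lda = function(X, y, positive) {
      fit <- MASS::lda(X, y)
      function(Xn) {
        pr <- predict(fit, Xn)
        list(score = pr$posterior[, positive], class = pr$class)
      }
    },
    qda = function(X, y, positive) {
      fit <- MASS::qda(X, y)
      function(Xn) {
        pr <- predict(fit, Xn)
        list(score = pr$posterior[, positive], class = pr$class)
      }
    },
    knn = function(X, y, positive) {
      force(X); force(y)
      function(Xn) {
        pr <- class::knn(X, Xn, y, k = knn_k, prob = TRUE)
        win <- attr(pr, "prob")
        score <- ifelse(pr == positive, win, 1 - win)
        list(score = score, class = pr)
      }
    },
    decision_tree = function(X, y, positive) {
      d <- data.frame(y = y, X)
      fit <- rpart::rpart(y ~ ., data = d, method = "class",
                          control = rpart::rpart.control(
                            minsplit = 2, minbucket = 1, cp = 0))
      function(Xn) {
        post <- predict(fit, data.frame(Xn), type = "prob")
        cls <- predict(fit, data.frame(Xn), type = "class")
        list(score = post[, positive], class = cls)
      }
    })
}

stratified_folds <- function(y, folds) {
  out <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    idx <- idx[sample.int(length(idx))]
    out[idx] <- rep_len(seq_len(folds), length(idx))
  }
  out
}

#' Evaluate the seven classifiers with repeated stratified cross-validation
#'
#' For each classifier: a fit on all data gives the resubstitution
#' (all-data) AUC and classification error; then `replications` rounds of
#' stratified k-fold cross-validation, each with a fresh seeded shuffle,
#' give the CV AUC (rank-based, on the held-out scores pooled within a
#' replicate) and CV error, averaged over replicates.
#'
#' @param scores A data frame with the predictor columns and a label column.
#' @param label Name of the label column (two classes; default `"group"`).
#' @param predictors Predictor columns (default `c("PC1", "PC2")`).
#' @param folds Number of CV folds (default 10); must not exceed the
#'   minority class size.
#' @param replications Number of CV replications (default 100; the study
#'   protocol used 1000).
#' @param seed Integer seed driving all shuffles.
#' @param positive Positive class label (default: last factor level).
#' @param knn_k Neighbors for the k-NN classifier (default 5).
#' @return An object of class `mf_discrimination` whose `table` has one row
#'   per classifier: `auc_all_data`, `error_all_data`, `auc_cv_mean`,
#'   `auc_cv_sd`, `error_cv_mean`, `error_cv_sd`.
#' @examples
#' d <- simulate_descriptors("day", seed = 1)
#' pca <- pca_project(d)
#' ev <- evaluate_classifiers(tidy(pca), replications = 3, seed = 1)
#' tidy(ev)
#' @export
evaluate_classifiers <- function(scores, label = "group",
                                 predictors = c("PC1", "PC2"),
                                 folds = 10, replications = 100, seed,
                                 positive = NULL, knn_k = 5) {
  if (!is.data.frame(scores)) mf_abort("`scores` must be a data frame.", "input")
  missing_cols <- setdiff(c(predictors, label), names(scores))
  if (length(missing_cols) > 0) {
    mf_abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", "), "."),
             "input")
  }
  y <- droplevels(factor(scores[[label]]))
  if (nlevels(y) != 2L) mf_abort("The label must have exactly 2 classes.", "input")
  if (is.null(positive)) positive <- levels(y)[2]
  X <- as.matrix(scores[, predictors])
  n_min <- min(table(y))
  if (folds < 2 || folds > n_min) {
    mf_abort(paste0("`folds` must be between 2 and the minority class size (",
                    n_min, ")."), "input")
  }
  clfs <- make_classifiers(knn_k = knn_k)

  res <- with_seed(seed, {
    purrr::imap_dfr(clfs, function(make, name) {
      scorer <- make(X, y, positive)
      all_pred <- scorer(X)
      auc_all <- auc_rank(all_pred$score, y, positive)
      err_all <- mean(all_pred$class != y)
      rep_auc <- numeric(replications)
      rep_err <- numeric(replications)
      for (r in seq_len(replications)) {
        fold <- stratified_folds(y, folds)
        sc <- numeric(length(y))
        cl <- factor(rep(levels(y)[1], length(y)), levels = levels(y))
        for (f in seq_len(folds)) {
          te <- fold == f
          sub <- make(X[!te, , drop = FALSE], droplevels(y[!te]), positive)
          pr <- sub(X[te, , drop = FALSE])
          sc[te] <- pr$score
          cl[te] <- pr$class
        }
        rep_auc[r] <- auc_rank(sc, y, positive)
        rep_err[r] <- mean(cl != y)
      }
      tibble(classifier = name,
             auc_all_data = auc_all, error_all_data = err_all,
             auc_cv_mean = mean(rep_auc), auc_cv_sd = sd(rep_auc),
             error_cv_mean = mean(rep_err), error_cv_sd = sd(rep_err))
    })
  })
  structure(list(table = res, folds = folds, replications = replications,
                 seed = seed, positive = positive, n = length(y)),
            class = "mf_discrimination")
}

#' @export
print.mf_discrimination <- function(x, ...) {
  cat("<mf_discrimination> ", x$n, " samples, ", x$folds, "-fold CV x ",
      x$replications, " replications (positive class: ", x$positive, ")\n",
      sep = "")
  print(as.data.frame(x$table), row.names = FALSE, digits = 3)
  invisible(x)
}

#' @describeIn evaluate_classifiers Per-classifier performance tibble.
#' @param x,... An `mf_discrimination`; further arguments ignored.
#' @method tidy mf_discrimination
#' @export
tidy.mf_discrimination <- function(x, ...) x$table

#' @describeIn evaluate_classifiers One-row summary of the protocol.
#' @method glance mf_discrimination
#' @export
glance.mf_discrimination <- function(x, ...) {
  tibble(n = x$n, folds = x$folds, replications = x$replications,
         best_cv_auc = max(x$table$auc_cv_mean),
         best_classifier = x$table$classifier[which.max(x$table$auc_cv_mean)])
}
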