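#' Leave-one-participant-out folds over a document-term matrix
#'
#' One fold per participant: the test set is that participant's two chain
#' rows (pre and post); the training set is every other row. Folds partition
#' the rows exactly, so both of a participant's chains are always held out
#' together and never inform the rule that classifies them.
#'
#' @param dtm A scaled `linger_dtm` (2 rows per participant).
#' @return List of folds, each a list with `participant_id`, `test` (row
#'   indices), `train` (row indices).
#' @export
lopo_folds <- function(dtm) {
  stopifnot(inherits(dtm, "linger_dtm"))
  participants <- unique(dtm$participant_id)
  if (length(participants) < 2) {
    stop("need at least 2 participants for leave-one-participant-out folds",
         call. = FALSE)
  }
  all_rows <- seq_len(nrow(dtm$values))
  lapply(participants, function(p) {
    test <- which(dtm$participant_id == p)
    list(participant_id = p, test = test, train = setdiff(all_rows, test))
  })
}

#' Train a linear maximal-margin classifier
#'
#' Fits a soft-margin linear support-vector machine (hinge loss, L2 penalty,
#' regularization constant `cost`) and returns an explicit affine decision
#' rule: weight vector `w` and bias `b`, with prediction
#' `post` if `x . w + b > 0` and `pre` otherwise (a score of exactly 0 ties
#' to `pre`).
#'
#' @param train_matrix Numeric matrix, one row per training chain.
#' @param labels Character/factor vector of `"pre"`/`"post"` per row; both
#'   classes must be present.
#' @param cost Regularization constant C (default 1).
#' @return A `linger_svm` list with `w`, `b`, and `predict(newx)` giving
#'   labels for the rows of `newx`.
#' @export
train_linear_margin <- function(train_matrix, labels, cost = 1) {
  labels <- factor(as.character(labels), levels = c("pre", "post"))
  if (nlevels(droplevels(labels)) < 2) {
    stop("training set must contain both classes", call. = FALSE)
  }
  fit <- e1071::svm(train_matrix, labels, kernel = "linear", cost = cost,
                    scale = FALSE)
  # explicit affine rule: e1071's decision value d(x) = x.w0 - rho is
  # positive for the class it encountered first (fit$labels[1]); orient so a
  # positive score always means "post"
  w0 <- drop(t(fit$coefs) %*% fit$SV)
  positive_class <- fit$levels[fit$labels[1]]
  flip <- if (positive_class == "post") 1 else -1
  w <- flip * w0
  b <- flip * (-fit$rho)
  rule <- list(w = w, b = b, cost = cost)
  rule$predict <- function(newx) {
    score <- drop(newx %*% w) + b
    ifelse(score > 0, "post", "pre")
  }
  class(rule) <- "linger_svm"
  rule
}

#' Run leave-one-participant-out classification with bootstrap repeats
#'
#' For each repeat, every fold's training participants are resampled with
#' replacement (keeping each resampled participant's pre/post pair intact),
#' a linear maximal-margin rule is trained on the resampled rows, and the
#' held-out participant's two chains are predicted. Repeat accuracy is the
#' proportion of correct predictions over all held-out rows; the reported
#' `mean_accuracy` is the mean over repeats. With `resample = FALSE` the
#' procedure is a single deterministic pass (each fold trained on the full
#' remaining sample), and `n_repeats` is forced to 1.
#'
#' Only the document-term matrix is used: the order in which words appeared
#' within a chain never enters the procedure.
#'
#' @param dtm A scaled `linger_dtm`.
#' @param n_repeats Number of bootstrap repeats (default 500).
#' @param seed Integer seed.
#' @param cost SVM regularization constant (default 1).
#' @param resample Resample training participants per repeat (default TRUE).
#' @return A `linger_classification` list: `mean_accuracy`,
#'   `repeat_accuracies`, `n_repeats`, `seed`, `cost`.
#' @export
run_classification <- function(dtm, n_repeats = 500, seed = 1L, cost = 1,
                               resample = TRUE) {
  stopifnot(inherits(dtm, "linger_dtm"))
  if (!isTRUE(dtm$scaled)) {
    stop("classification expects a scaled document-term matrix", call. = FALSE)
  }
  if (n_repeats < 1) stop("n_repeats must be >= 1", call. = FALSE)
  if (!resample) n_repeats <- 1L
  folds <- lopo_folds(dtm)
  X <- dtm$values
  phase <- dtm$phase
  pid <- dtm$participant_id
  n_rows <- nrow(X)
  acc <- withr::with_seed(seed, {
    vapply(seq_len(n_repeats), function(r) {
      correct <- 0L
      for (f in folds) {
        if (resample) {
          train_p <- unique(pid[f$train])
          boot_p <- sample(train_p, length(train_p), replace = TRUE)
          tr <- unlist(lapply(boot_p, function(p) which(pid == p)),
                       use.names = FALSE)
        } else {
          tr <- f$train
        }
        rule <- train_linear_margin(X[tr, , drop = FALSE], phase[tr],
                                    cost = cost)
        pred <- rule$predict(X[f$test, , drop = FALSE])
        correct <- correct + sum(pred == phase[f$test])
      }
      correct / n_rows
    }, numeric(1))
  })
  structure(list(mean_accuracy = mean(acc), repeat_accuracies = acc,
                 n_repeats = n_repeats, seed = seed, cost = cost,
                 resample = resample),
            class = "linger_classification")
}

#' @export
print.linger_classification <- function(x, ...) {
  cat("<linger_classification> mean accuracy ",
      sprintf("%.1f%%", 100 * x$mean_accuracy), " over ", x$n_repeats,
      " repeat(s)\n", sep = "")
  invisible(x)
}

#' Permutation null distribution of classification accuracy
#'
#' For each permutation the leave-one-participant-out procedure is scored
#' after independently swapping each held-out participant's pre/post labels
#' with probability 1/2. Because held-out labels never enter training, each
#' fold's predictions are fixed across permutations and are computed once;
#' swapping a fold's labels turns its correct count `c` (of 2) into `2 - c`.
#' The resulting accuracies estimate the distribution expected when chains
#' carry no pre/post information.
#'
#' @param dtm A scaled `linger_dtm`.
#' @param n_perm Number of permutations (default 500).
#' @param seed Integer seed.
#' @param cost SVM regularization constant (default 1).
#' @return Numeric vector of `n_perm` null accuracies.
#' @export
permutation_null <- function(dtm, n_perm = 500, seed = 1L, cost = 1) {
  stopifnot(inherits(dtm, "linger_dtm"))
  if (!isTRUE(dtm$scaled)) {
    stop("permutation null expects a scaled document-term matrix",
         call. = FALSE)
  }
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  folds <- lopo_folds(dtm)
  X <- dtm$values
  phase <- dtm$phase
  fold_correct <- vapply(folds, function(f) {
    rule <- train_linear_margin(X[f$train, , drop = FALSE], phase[f$train],
                                cost = cost)
    sum(rule$predict(X[f$test, , drop = FALSE]) == phase[f$test])
  }, numeric(1))
  n_rows <- nrow(X)
  withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      swap <- stats::runif(length(fold_correct)) < 0.5
      sum(ifelse(swap, 2 - fold_correct, fold_correct)) / n_rows
    }, numeric(1))
  })
}

#' One-sided permutation p-value
#'
#' The p-value is the proportion of null accuracies strictly greater than
#' the observed accuracy. When no null value exceeds the observed accuracy
#' the p-value is below the test's resolution and is flagged as
#' `"< 1/n_perm"` (with 500 permutations, `"< 0.002"`).
#'
#' @param observed Observed mean accuracy.
#' @param nulls Numeric vector of null accuracies.
#' @return List with `p` (numeric; `1/n_perm` when below resolution),
#'   `below_resolution` (logical), and `label` (printable, e.g. `"< 0.002"`
#'   or `"0.340"`).
#' @export
permutation_pvalue <- function(observed, nulls) {
  stopifnot(length(nulls) >= 1)
  n_perm <- length(nulls)
  count <- sum(nulls > observed)
  if (count == 0) {
    list(p = 1 / n_perm, below_resolution = TRUE,
         label = paste0("< ", format(1 / n_perm, scientific = FALSE)))
  } else {
    p <- count / n_perm
    list(p = p, below_resolution = FALSE,
         label = format(round(p, 3), nsmall = 3, scientific = FALSE))
  }
}
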