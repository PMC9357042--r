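#' Encode regression predictors and responses from a cohort
#'
#' Builds the design matrix for predicting lingering: transportation
#' proportion and comprehension proportion (both z-scored to mean 0, SD 1),
#' plus dummy-coded condition with the least-coherent level (lowest
#' configured injection rate; last listed level for external data) as
#' reference. Responses are the z-scored 1-7 lingering rating and, when an
#' embedding table and theme set are supplied, the per-participant
#' theme-similarity delta (post minus pre chain means). Constant predictor
#' columns are dropped with a warning; rows with missing fields are excluded
#' with a message.
#'
#' @param cohort A `linger_cohort` (or a participants tibble plus `chains`).
#' @param embeddings Optional embedding matrix (for the delta response).
#' @param themes Optional `linger_themes` set (for the delta response).
#' @return List with `X` (design matrix, named columns), `y_lingering`
#'   (z-scored), `y_delta` (or NULL), `participant_id`, `reference_level`.
#' @export
encode_predictors <- function(cohort, embeddings = NULL, themes = NULL) {
  stopifnot(inherits(cohort, "linger_cohort"))
  parts <- cohort$participants
  transport <- vapply(parts$transportation, score_questionnaire, numeric(1),
                      scale_max = 7)
  comp <- vapply(parts$comprehension, score_questionnaire, numeric(1),
                 scale_max = 1)
  cond <- as.character(parts$condition)
  # reference = least-coherent condition (smallest configured delta)
  deltas <- vapply(cohort$config$conditions, `[[`, numeric(1), "delta")
  ref <- names(deltas)[which.min(deltas)]
  lev <- c(ref, setdiff(unique(cond), ref))
  condf <- factor(cond, levels = lev)
  keep <- !is.na(transport) & !is.na(comp) & !is.na(parts$lingering_rating)
  if (any(!keep)) {
    message(sum(!keep), " participant(s) excluded for missing fields: ",
            paste(parts$participant_id[!keep], collapse = ", "))
  }
  zscore <- function(v) (v - mean(v)) / stats::sd(v)
  X <- cbind(transportation = transport[keep],
             comprehension = comp[keep])
  const <- apply(X, 2, function(v) stats::sd(v) == 0)
  if (any(const)) {
    warning("dropping constant predictor(s): ",
            paste(colnames(X)[const], collapse = ", "), call. = FALSE)
    X <- X[, !const, drop = FALSE]
  }
  X <- apply(X, 2, zscore)
  if (nlevels(droplevels(condf[keep])) > 1) {
    mm <- stats::model.matrix(~condf, data = data.frame(condf = condf[keep]))
    dummies <- mm[, -1, drop = FALSE]
    colnames(dummies) <- paste0("condition_", lev[-1])
    X <- cbind(X, dummies)
  }
  y_delta <- NULL
  if (!is.null(embeddings) && !is.null(themes)) {
    dts <- cohort_theme_deltas(cohort$chains, embeddings, themes)
    y_delta <- dts$delta[match(parts$participant_id[keep],
                               dts$participant_id)]
  }
  list(X = X,
       y_lingering = zscore(as.numeric(parts$lingering_rating[keep])),
       y_delta = y_delta,
       participant_id = parts$participant_id[keep],
       reference_level = ref)
}

rss_of <- function(X, y, cols) {
  Xi <- cbind(Intercept = 1, X[, cols, drop = FALSE])
  fit <- stats::lm.fit(Xi, y)
  sum(fit$residuals^2)
}

#' Backward stepwise feature selection with k-fold cross-validation
#'
#' Starting from the full predictor set, iteratively removes the predictor
#' whose removal least increases the residual sum of squares, recording one
#' candidate set per model size. Each candidate set's out-of-sample RMSE is
#' estimated by k-fold cross-validation (folds assigned by a seeded shuffle
#' of the rows; with one row per participant this is participant-level
#' assignment). The selected size is, under the default `"one_se"` rule, the
#' smallest whose mean CV RMSE is within one standard error of the minimum
#' (the usual parsimony rule, which keeps pure-noise predictors out); under
#' `"min"` it is the size with the smallest mean CV RMSE. The selected set
#' is refit on all data by least squares, reporting coefficients, t
#' statistics, and R-squared.
#'
#' @param X Numeric design matrix with named columns.
#' @param y Numeric response.
#' @param k_folds Number of CV folds (default 10; must be < `nrow(X)`).
#' @param seed Integer seed for fold assignment.
#' @param selection Size-selection rule: `"one_se"` (default) or `"min"`.
#' @return A `linger_stepwise` list: `path` (per-size candidate sets with
#'   mean and SE of CV RMSE), `selected` (feature names), `fit`
#'   (coefficients, t, df, r_squared), `seed`.
#' @export
backward_stepwise_cv <- function(X, y, k_folds = 10, seed = 1L,
                                 selection = c("one_se", "min")) {
  selection <- match.arg(selection)
  stopifnot(is.matrix(X), ncol(X) >= 1, nrow(X) == length(y))
  if (nrow(X) <= k_folds) stop("need more rows than folds", call. = FALSE)
  features <- colnames(X)
  stopifnot(!is.null(features), !anyDuplicated(features))
  # backward elimination path by exhaustive one-out RSS comparison
  path_sets <- list()
  current <- features
  path_sets[[length(current)]] <- current
  while (length(current) > 1) {
    rss <- vapply(current, function(f)
      rss_of(X, y, setdiff(current, f)), numeric(1))
    current <- setdiff(current, current[which.min(rss)])
    path_sets[[length(current)]] <- current
  }
  # seeded fold assignment
  n <- nrow(X)
  fold_id <- withr::with_seed(seed,
    sample(rep(seq_len(k_folds), length.out = n)))
  cv_stats <- lapply(seq_along(path_sets), function(size) {
    cols <- path_sets[[size]]
    rmse <- vapply(seq_len(k_folds), function(f) {
      tr <- fold_id != f
      Xi <- cbind(Intercept = 1, X[tr, cols, drop = FALSE])
      fit <- tryCatch(stats::lm.fit(Xi, y[tr]), error = function(e) NULL)
      if (is.null(fit) || any(is.na(fit$coefficients))) return(NA_real_)
      Xt <- cbind(Intercept = 1, X[!tr, cols, drop = FALSE])
      sqrt(mean((y[!tr] - drop(Xt %*% fit$coefficients))^2))
    }, numeric(1))
    ok <- !is.na(rmse)
    if (!any(ok)) stop("all folds singular for size ", size, call. = FALSE)
    if (any(!ok)) warning(sum(!ok), " singular fold(s) skipped at size ",
                          size, call. = FALSE)
    c(mean = mean(rmse[ok]), se = stats::sd(rmse[ok]) / sqrt(sum(ok)))
  })
  cv_mean <- vapply(cv_stats, `[[`, numeric(1), "mean")
  cv_se <- vapply(cv_stats, `[[`, numeric(1), "se")
  i_min <- which.min(cv_mean)
  best_size <- if (selection == "min") i_min else
    min(which(cv_mean <= cv_mean[i_min] + cv_se[i_min]))
  selected <- path_sets[[best_size]]
  fit <- fit_ols(X[, selected, drop = FALSE], y)
  structure(list(
    path = tibble::tibble(
      size = seq_along(path_sets),
      features = vapply(path_sets, paste, "", collapse = "+"),
      cv_rmse = cv_mean,
      cv_rmse_se = cv_se),
    selected = selected, fit = fit, k_folds = k_folds, seed = seed,
    selection = selection),
    class = "linger_stepwise")
}

#' @export
print.linger_stepwise <- function(x, ...) {
  cat("<linger_stepwise> selected {", paste(x$selected, collapse = ", "),
      "}; R^2 = ", round(x$fit$r_squared, 3), "\n", sep = "")
  invisible(x)
}

#' Ordinary least squares with t statistics and R-squared
#'
#' Least-squares fit with intercept via [stats::lm()]. Rank-deficient
#' designs (e.g. perfectly collinear predictors) are rejected.
#'
#' @param X Numeric design matrix (may have zero columns for an
#'   intercept-only model).
#' @param y Numeric response.
#' @return List with `coefficients` (named, incl. intercept), `t`, `df`,
#'   `r_squared`, `residual_se`, `n`.
#' @export
fit_ols <- function(X, y) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  df_fit <- data.frame(y = y, X, check.names = FALSE)
  fm <- if (ncol(X)) stats::as.formula(
    paste("y ~", paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  else y ~ 1
  fit <- stats::lm(fm, data = df_fit)
  if (any(is.na(stats::coef(fit)))) {
    stop("rank-deficient design (collinear predictors)", call. = FALSE)
  }
  sm <- summary(fit)
  co <- sm$coefficients
  list(coefficients = stats::setNames(co[, 1], rownames(co)),
       t = stats::setNames(co[, 3], rownames(co)),
       df = fit$df.residual,
       r_squared = if (ncol(X)) sm$r.squared else 0,
       residual_se = sm$sigma, n = length(y))
}
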