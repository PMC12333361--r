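#' Classify SNE values into low / medium / high enhancement
#'
#' Three-class coarse labelling of the signal-to-noise enhancement used by
#' the semiquantitative classifier: low (SNE < 40), medium (40 < SNE < 90)
#' and high (SNE > 90) with the default thresholds. Exact boundary values
#' are assigned to the medium class (the symmetric closed-interval
#' convention).
#'
#' @param sne Numeric vector of absolute SNE values (>= 0).
#' @param thresholds Length-2 numeric: (low upper bound, high lower
#'   bound).
#' @return Factor with levels low < medium < high.
#' @examples
#' classify_sne(c(10, 40, 65, 90, 120))
#' @export
classify_sne <- function(sne, thresholds = c(40, 90)) {
  if (any(sne < 0)) stop("domain error: sne must be >= 0")
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
  lab <- ifelse(sne < thresholds[1], "low",
                ifelse(sne > thresholds[2], "high", "medium"))
  factor(lab, levels = c("low", "medium", "high"), ordered = TRUE)
}

.ml_matrix <- function(table) {
  df <- as.data.frame(table)
  as.matrix(df[, feature_names()])
}

.standardize_train_test <- function(train, ...) {
  mu <- colMeans(train)
  sdv <- apply(train, 2, stats::sd)
  sdv[sdv == 0] <- 1
  scale_one <- function(m) sweep(sweep(m, 2, mu), 2, sdv, "/")
  c(list(scale_one(train)), lapply(list(...), scale_one))
}

.stratified_split <- function(classes, train_fraction) {
  idx_train <- integer(0)
  for (cl in levels(classes)) {
    i <- which(classes == cl)
    n_tr <- round(length(i) * train_fraction)
    n_tr <- max(1L, min(length(i) - 1L, n_tr))
    idx_train <- c(idx_train, sample(i, n_tr))
  }
  sort(idx_train)
}

#' Repeated random-split classification of enhancement classes
#'
#' Trains a multinomial logistic model on many independent stratified
#' random splits of the site table and accumulates test-set predictions
#' into a cumulative confusion matrix, row-normalized by true class, so
#' each diagonal entry is the fraction of correctly classified test
#' protons of that class over all runs. Feature importances are the mean
#' absolute standardized coefficients per feature, normalized to sum 1.
#' Features are standardized with train-fold statistics only. The run is
#' deterministic given the seed.
#'
#' @param table A [feature_table()].
#' @param n_runs Number of random splits.
#' @param train_fraction Stratified train fraction (default 0.7).
#' @param seed Integer seed.
#' @param thresholds SNE class thresholds, see [classify_sne()].
#' @return A `cumulative_confusion`: list with `matrix` (3x3
#'   row-normalized, rows = true class), `counts`, `n_runs`,
#'   `per_class_support` (class sizes in the full table), `importances`,
#'   and `n_resampled` (splits redrawn because a class was missing from a
#'   fold).
#' @export
repeated_split_classification <- function(table, n_runs = 1000,
                                          train_fraction = 0.7,
                                          seed = 1L,
                                          thresholds = c(40, 90)) {
  X <- .ml_matrix(table)
  y <- classify_sne(as.data.frame(table)$sne, thresholds)
  support <- table(y)
  if (any(support < 2)) {
    stop("each class needs >= 2 members; got: ",
         paste(sprintf("%s=%d", names(support), support), collapse = ", "))
  }
  counts <- matrix(0, 3, 3, dimnames = list(true = levels(y),
                                            pred = levels(y)))
  imp_sum <- stats::setNames(numeric(ncol(X)), colnames(X))
  n_resampled <- 0L
  set.seed(derive_seed(seed, "classify"))
  for (r in seq_len(n_runs)) {
    repeat {
      tr <- .stratified_split(y, train_fraction)
      te <- setdiff(seq_along(y), tr)
      if (nlevels(droplevels(y[tr])) == nlevels(y) && length(te) > 0) break
      n_resampled <- n_resampled + 1L
    }
    sc <- .standardize_train_test(X[tr, , drop = FALSE],
                                  X[te, , drop = FALSE])
    dtr <- data.frame(class = y[tr], sc[[1]])
    # small weight decay keeps the fit finite under complete separation
    fit <- nnet::multinom(class ~ ., data = dtr, trace = FALSE,
                          maxit = 200, decay = 1e-4)
    pred <- stats::predict(fit, newdata = data.frame(sc[[2]]))
    tt <- table(factor(y[te], levels = levels(y)),
                factor(pred, levels = levels(y)))
    counts <- counts + tt
    co <- stats::coef(fit)
    if (is.null(dim(co))) co <- matrix(co, nrow = 1,
                                       dimnames = list(NULL, names(co)))
    imp_sum <- imp_sum + colMeans(abs(co[, colnames(X), drop = FALSE]))
  }
  rs <- rowSums(counts)
  mat <- counts / ifelse(rs == 0, 1, rs)
  importances <- imp_sum / sum(imp_sum)
  structure(list(matrix = mat, counts = counts, n_runs = n_runs,
                 per_class_support = support, importances = importances,
                 n_resampled = n_resampled, model = "multinomial logistic"),
            class = "cumulative_confusion")
}

#' @export
print.cumulative_confusion <- function(x, ...) {
  cat(sprintf("<cumulative_confusion> %d runs (%s)\n", x$n_runs, x$model))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Regression and classification performance metrics
#'
#' R-squared (coefficient of determination, the primary score), root mean
#' squared error and mean absolute error of predictions against observed
#' values. The composite model score used by the regression suite is the
#' mean test-fold R-squared; RMSE and MAE are reported alongside.
#'
#' @param y_true,y_pred Numeric vectors of equal length >= 2.
#' @return List with `r_squared` (coefficient of determination),
#'   `pearson_r2` (squared Pearson correlation; NA for constant
#'   predictions), `rmse`, `mae`.
#' @export
performance_score <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) < 2) stop("need at least 2 observations")
  res <- y_true - y_pred
  ss_tot <- sum((y_true - mean(y_true))^2)
  pr2 <- if (stats::var(y_pred) == 0) NA_real_ else
    stats::cor(y_true, y_pred)^2
  list(r_squared = 1 - sum(res^2) / ss_tot,
       pearson_r2 = pr2,
       rmse = sqrt(mean(res^2)),
       mae = mean(abs(res)))
}

# Model registry: each entry fits on standardized train data with a small
# hyperparameter grid tuned on the validation fold, and supplies a
# predict function plus a native importance where the model has one
# (tree models: gain/impurity); others fall back to permutation
# importance on the test fold.
.regression_models <- function() {
  list(
    knn = list(
      label = "k-nearest neighbors (caret::knnreg)",
      grid = list(k = c(3, 5, 7)),
      fit = function(X, y, par) caret::knnreg(X, y, k = par$k),
      predict = function(m, X) stats::predict(m, X),
      importance = NULL),
    gbt = list(
      label = "gradient-boosted trees (xgboost)",
      grid = list(max_depth = c(2, 3), nrounds = c(50, 100)),
      fit = function(X, y, par) {
        xgboost::xgboost(X, y, nrounds = par$nrounds,
                         max_depth = par$max_depth, learning_rate = 0.1,
                         nthreads = 1, verbosity = 0,
                         objective = "reg:squarederror")
      },
      predict = function(m, X) stats::predict(m, X),
      importance = function(m, X) {
        im <- xgboost::xgb.importance(model = m)
        out <- stats::setNames(numeric(ncol(X)), colnames(X))
        out[im$Feature] <- im$Gain
        out
      }),
    rf = list(
      label = "random forest (ranger)",
      grid = list(mtry = c(2, 4)),
      fit = function(X, y, par) {
        ranger::ranger(x = as.data.frame(X), y = y, num.trees = 300,
                       mtry = par$mtry, importance = "impurity",
                       num.threads = 1,
                       seed = sample.int(.Machine$integer.max, 1))
      },
      predict = function(m, X) {
        stats::predict(m, data = as.data.frame(X))$predictions
      },
      importance = function(m, X) {
        im <- m$variable.importance
        pmax(im, 0) / sum(pmax(im, 0))
      }),
    ridge = list(
      label = "ridge linear model (glmnet)",
      grid = list(lambda = c(1e-3, 1e-2, 1e-1, 1)),
      fit = function(X, y, par) {
        glmnet::glmnet(X, y, alpha = 0, lambda = par$lambda)
      },
      predict = function(m, X) as.numeric(stats::predict(m, X)),
      importance = NULL),
    svr = list(
      label = "support vector regression (e1071, RBF)",
      grid = list(cost = c(1, 10)),
      fit = function(X, y, par) e1071::svm(X, y, cost = par$cost),
      predict = function(m, X) as.numeric(stats::predict(m, X)),
      importance = NULL)
  )
}

.expand_grid_list <- function(grid) {
  g <- do.call(expand.grid, c(grid, list(KEEP.OUT.ATTRS = FALSE)))
  lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
}

.permutation_importance <- function(predict_fn, model, X, y) {
  base_mse <- mean((y - predict_fn(model, X))^2)
  delta <- vapply(seq_len(ncol(X)), function(j) {
    Xp <- X
    Xp[, j] <- sample(Xp[, j])
    mean((y - predict_fn(model, Xp))^2) - base_mse
  }, numeric(1))
  delta <- pmax(delta, 0)
  if (sum(delta) == 0) delta <- rep(1 / length(delta), length(delta))
  else delta <- delta / sum(delta)
  stats::setNames(delta, colnames(X))
}

#' Repeated random-split regression suite for quantitative SNE prediction
#'
#' Evaluates a suite of regression models (k-nearest neighbors,
#' gradient-boosted decision trees, random forest, ridge linear model,
#' support vector regression) over repeated independent random splits into
#' training, validation and test sets. Per run: features are standardized
#' on the train fold, each model's small hyperparameter grid is tuned on
#' the validation fold by RMSE, and performance is scored on the test fold
#' only. Feature importances are the model's native gain/impurity for
#' tree models and test-fold permutation importance otherwise, averaged
#' over runs and normalized to sum 1. Reports are sorted by composite
#' score (mean test R-squared).
#'
#' @param table A [feature_table()].
#' @param models Character subset of `c("knn","gbt","rf","ridge","svr")`.
#' @param n_runs Number of independent runs (default 100).
#' @param fractions Train/validation/test fractions (default 0.6/0.2/0.2).
#' @param seed Integer seed; fixed seed gives identical reports.
#' @return List of `evaluation_report`s (one per model), sorted by
#'   composite score: each has `model`, `model_label`, `per_run_scores`,
#'   `mean_scores`, `sd_scores`, `composite_score`, `importances`.
#' @export
repeated_split_regression <- function(table,
                                      models = c("knn", "gbt", "rf",
                                                 "ridge", "svr"),
                                      n_runs = 100,
                                      fractions = c(0.6, 0.2, 0.2),
                                      seed = 1L) {
  registry <- .regression_models()
  unknown <- setdiff(models, names(registry))
  if (length(unknown)) {
    stop("unknown model(s): ", paste(unknown, collapse = ", "),
         "; supported: ", paste(names(registry), collapse = ", "))
  }
  stopifnot(abs(sum(fractions) - 1) < 1e-8, length(fractions) == 3)
  X <- .ml_matrix(table)
  y <- as.data.frame(table)$sne
  n <- nrow(X)
  n_tr <- floor(n * fractions[1])
  n_va <- floor(n * fractions[2])
  if (min(n_tr, n_va, n - n_tr - n_va) < 2) {
    stop("table too small for the requested split fractions")
  }
  runs <- lapply(models, function(m) {
    list(scores = matrix(NA_real_, n_runs, 3,
                         dimnames = list(NULL, c("r_squared", "rmse", "mae"))),
         imp = matrix(0, n_runs, ncol(X),
                      dimnames = list(NULL, colnames(X))))
  })
  names(runs) <- models
  for (r in seq_len(n_runs)) {
    set.seed(derive_seed(seed, sprintf("regress-%d", r)))
    perm <- sample.int(n)
    tr <- perm[seq_len(n_tr)]
    va <- perm[n_tr + seq_len(n_va)]
    te <- perm[(n_tr + n_va + 1):n]
    sc <- .standardize_train_test(X[tr, , drop = FALSE],
                                  X[va, , drop = FALSE],
                                  X[te, , drop = FALSE])
    for (m in models) {
      spec <- registry[[m]]
      best <- NULL; best_rmse <- Inf
      for (par in .expand_grid_list(spec$grid)) {
        fit <- spec$fit(sc[[1]], y[tr], par)
        rmse <- sqrt(mean((y[va] - spec$predict(fit, sc[[2]]))^2))
        if (rmse < best_rmse) { best_rmse <- rmse; best <- fit }
      }
      pred <- spec$predict(best, sc[[3]])
      ps <- performance_score(y[te], pred)
      runs[[m]]$scores[r, ] <- c(ps$r_squared, ps$rmse, ps$mae)
      runs[[m]]$imp[r, ] <- if (is.null(spec$importance)) {
        .permutation_importance(spec$predict, best, sc[[3]], y[te])
      } else {
        spec$importance(best, sc[[3]])
      }
    }
  }
  reports <- lapply(models, function(m) {
    s <- runs[[m]]$scores
    imp <- colMeans(runs[[m]]$imp)
    imp <- imp / sum(imp)
    structure(list(model = m, model_label = registry[[m]]$label,
                   per_run_scores = as.data.frame(s),
                   mean_scores = colMeans(s),
                   sd_scores = apply(s, 2, stats::sd),
                   composite_score = mean(s[, "r_squared"]),
                   importances = imp, n_runs = n_runs),
              class = "evaluation_report")
  })
  reports[order(vapply(reports, function(r) r$composite_score,
                       numeric(1)), decreasing = TRUE)]
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s: composite R2 = %.3f (RMSE %.2f, MAE %.2f) over %d runs\n",
              x$model_label, x$composite_score,
              x$mean_scores["rmse"], x$mean_scores["mae"], x$n_runs))
  top <- sort(x$importances, decreasing = TRUE)[1:3]
  cat("  top importances:",
      paste(sprintf("%s=%.2f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}
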