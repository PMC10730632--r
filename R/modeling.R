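## Response modeling: log transform, fold-wise normalization, logistic
## regression, repeated stratified cross-validation with corrected resampled
## t-test confidence intervals, Youden thresholding and external validation.

#' Signed log transform
#'
#' `sign(x) * log(1 + |x|)`: monotone, odd, and defined on all of R. Used
#' for the TTE difference, which spans negative values where a plain log is
#' undefined; for the positive ratio features the plain natural log is used.
#'
#' @param x numeric vector.
#' @return transformed values; [signed_exp()] is the inverse.
#' @export
signed_log <- function(x) sign(x) * log1p(abs(x))

#' @rdname signed_log
#' @export
signed_exp <- function(x) sign(x) * expm1(abs(x))

#' Log-transform a relative-feature table
#'
#' Ratio features (`r_wir*`, `r_mre*`, `r_auc*`, `r_volume`) are natural-log
#' transformed to reduce right skew; `delta_tte*` columns use the signed log.
#' A single [relative_features()] object is transformed field-wise to a
#' named numeric vector.
#'
#' @param records data.frame with relative-feature columns, or one
#'   `relative_features` object.
#' @return the data.frame with transformed feature columns, or a named
#'   numeric vector.
#' @export
log_transform_features <- function(records) {
  if (inherits(records, "relative_features")) {
    for (f in c("r_wir", "r_mre", "r_auc")) {
      if (records[[f]] <= 0) stop("non-positive ratio feature in `", f, "`")
    }
    return(c(r_wir = log(records$r_wir), r_mre = log(records$r_mre),
             r_auc = log(records$r_auc),
             delta_tte = signed_log(records$delta_tte),
             r_volume = log(records$r_volume)))
  }
  for (col in intersect(cohort_feature_columns(), names(records))) {
    x <- records[[col]]
    if (startsWith(col, "delta_tte")) {
      records[[col]] <- signed_log(x)
    } else {
      if (any(x <= 0)) stop("non-positive ratio feature in `", col, "`")
      records[[col]] <- log(x)
    }
  }
  records
}

#' Model specification
#'
#' One candidate model: a segmentation method and one or two relative
#' features (the cohort size caps models at two features).
#'
#' @param method `"whole_slab"` or `"focal_area"`.
#' @param features character subset of `r_wir`, `r_mre`, `r_auc`,
#'   `delta_tte`, `r_volume`; length 1 or 2.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(method = c("whole_slab", "focal_area"), features) {
  method <- match.arg(method)
  valid <- c("r_wir", "r_mre", "r_auc", "delta_tte", "r_volume")
  if (length(features) < 1 || length(features) > 2) {
    stop("a model uses one or two features")
  }
  if (!all(features %in% valid)) stop("unknown feature name")
  if (anyDuplicated(features)) stop("duplicated feature")
  structure(list(method = method, features = features),
            class = "model_spec")
}

#' @export
format.model_spec <- function(x, ...) {
  sprintf("%s: %s", x$method, paste(x$features, collapse = " + "))
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", format(x), "\n")
  invisible(x)
}

# map a spec's features to cohort-table column names
spec_columns <- function(spec) {
  suffix <- if (spec$method == "whole_slab") "_ws" else "_fa"
  ifelse(spec$features == "r_volume", "r_volume",
         paste0(spec$features, suffix))
}

#' Candidate model grid
#'
#' All models evaluated during selection: every relative feature alone
#' (both segmentation methods, plus rVolume alone), every pair of perfusion
#' features within a method, and every perfusion feature paired with
#' rVolume per method — 29 candidates in total.
#'
#' @return list of [model_spec()] objects.
#' @export
candidate_model_grid <- function() {
  perf <- c("r_wir", "r_mre", "r_auc", "delta_tte")
  grid <- list()
  for (m in c("whole_slab", "focal_area")) {
    for (f in perf) grid[[length(grid) + 1]] <- model_spec(m, f)
    pairs <- utils::combn(perf, 2, simplify = FALSE)
    for (p in pairs) grid[[length(grid) + 1]] <- model_spec(m, p)
    for (f in perf) {
      grid[[length(grid) + 1]] <- model_spec(m, c(f, "r_volume"))
    }
  }
  grid[[length(grid) + 1]] <- model_spec("whole_slab", "r_volume")
  grid
}

#' Fold-wise feature normalizer
#'
#' Z-score parameters estimated on training-fold rows only; validation rows
#' must be transformed with the same parameters (no information may leak
#' from the validation fold).
#'
#' @param x numeric matrix (training rows x features).
#' @return list with `mean` and `sd` per column.
#' @export
fit_normalizer <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 training rows")
  m <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  if (any(s < 1e-12)) stop("degenerate feature: zero variance in training fold")
  list(mean = m, sd = s)
}

#' @rdname fit_normalizer
#' @param params normalizer from [fit_normalizer()].
#' @export
apply_normalizer <- function(params, x) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, params$mean, "-"), 2, params$sd, "/")
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit with an optional small ridge penalty on
#' the slopes (not the intercept) for numerical stability under
#' near-separation; `ridge_lambda = 0` reproduces the plain ML fit. Poor
#' response is coded 1.
#'
#' @param x standardized feature matrix.
#' @param y 0/1 outcome (1 = poor response).
#' @param ridge_lambda ridge penalty on slope coefficients.
#' @param max_iter,tol convergence control.
#' @return list with `intercept`, `slopes`, `converged`.
#' @export
fit_logistic <- function(x, y, ridge_lambda = 1e-4, max_iter = 100,
                         tol = 1e-10) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("both outcome classes must be present")
  X <- cbind(1, x)
  p <- ncol(X)
  pen <- diag(c(0, rep(ridge_lambda, p - 1)), p)
  beta <- rep(0, p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- crossprod(X, y - mu) - pen %*% beta
    H <- crossprod(X, X * w) + pen
    step <- solve(H, grad)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }
  list(intercept = beta[1], slopes = beta[-1], converged = converged)
}

predict_logistic <- function(fit, x) {
  stats::plogis(fit$intercept + drop(as.matrix(x) %*% fit$slopes))
}

# rank (Mann-Whitney) ROC AUC; probability that a poor case scores above a
# good case, ties counted half
auc_score <- function(probs, y) {
  r <- rank(probs)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

classification_metrics <- function(pred, y) {
  tp <- sum(pred == 1 & y == 1)
  tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  list(
    accuracy = (tp + tn) / length(y),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
  )
}

stratified_fold_ids <- function(y, k) {
  ids <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < k) stop("class too small for ", k, "-fold stratification")
    ids[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  ids
}

#' Corrected resampled t-test confidence interval
#'
#' Confidence interval for the mean of repeated cross-validation scores.
#' The fold scores are positively correlated because training sets overlap;
#' the naive variance `var/J` is therefore corrected to
#' `var * (1/J + n_test/n_train)`.
#'
#' @param fold_scores numeric vector of per-fold scores (J >= 2).
#' @param n_train,n_test training and validation fold sizes.
#' @param alpha two-sided error rate.
#' @return c(lo, hi).
#' @export
corrected_resampled_ci <- function(fold_scores, n_train, n_test,
                                   alpha = 0.05) {
  J <- length(fold_scores)
  if (J < 2) stop("need at least 2 fold scores")
  m <- mean(fold_scores)
  v <- stats::var(fold_scores)
  half <- stats::qt(1 - alpha / 2, df = J - 1) *
    sqrt(v * (1 / J + n_test / n_train))
  c(m - half, m + half)
}

#' Repeated stratified cross-validation of one candidate model
#'
#' 5-fold stratified cross-validation repeated with fresh shuffles
#' (default 50 repeats). Within every train/validation split the features
#' are log-transformed, z-scored on the training fold only, and a logistic
#' model is fitted on the training fold and scored on the validation fold:
#' ROC AUC plus accuracy/sensitivity/specificity at probability 0.5.
#'
#' @param records cohort feature table (natural scale) with a `response`
#'   column ("good"/"poor").
#' @param spec a [model_spec()].
#' @param folds,repeats cross-validation design.
#' @param seed master seed for the fold shuffles.
#' @param ridge_lambda passed to [fit_logistic()].
#' @return object of class `cv_result`: per-fold `scores` data.frame,
#'   `means`, corrected resampled t `cis`, and the design sizes.
#' @export
cross_validate <- function(records, spec, folds = 5, repeats = 50, seed = 1,
                           ridge_lambda = 1e-4) {
  stopifnot(inherits(spec, "model_spec"))
  y <- as.integer(records$response == "poor")
  cols <- spec_columns(spec)
  X <- as.matrix(log_transform_features(records)[, cols, drop = FALSE])
  n <- length(y)
  out <- vector("list", folds * repeats)
  withr::with_seed(seed, {
    for (r in seq_len(repeats)) {
      ids <- stratified_fold_ids(y, folds)
      for (f in seq_len(folds)) {
        tr <- ids != f
        va <- !tr
        norm <- fit_normalizer(X[tr, , drop = FALSE])
        Xtr <- apply_normalizer(norm, X[tr, , drop = FALSE])
        Xva <- apply_normalizer(norm, X[va, , drop = FALSE])
        fit <- fit_logistic(Xtr, y[tr], ridge_lambda)
        probs <- predict_logistic(fit, Xva)
        cm <- classification_metrics(as.integer(probs >= 0.5), y[va])
        out[[(r - 1) * folds + f]] <- data.frame(
          rep = r, fold = f,
          auc = auc_score(probs, y[va]),
          accuracy = cm$accuracy,
          sensitivity = cm$sensitivity,
          specificity = cm$specificity,
          n_train = sum(tr), n_test = sum(va)
        )
      }
    }
  })
  scores <- do.call(rbind, out)
  metrics <- c("auc", "accuracy", "sensitivity", "specificity")
  means <- vapply(scores[metrics], mean, numeric(1), na.rm = TRUE)
  ratio_train <- mean(scores$n_train)
  ratio_test <- mean(scores$n_test)
  cis <- lapply(scores[metrics], function(s) {
    corrected_resampled_ci(s[!is.na(s)], ratio_train, ratio_test)
  })
  structure(
    list(spec = spec, scores = scores, means = means, cis = cis,
         n_folds = folds, n_repeats = repeats),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result>", format(x$spec), "\n")
  for (m in names(x$means)) {
    cat(sprintf("  %-11s %.3f (95%% CI %.3f-%.3f)\n", m, x$means[[m]],
                x$cis[[m]][1], x$cis[[m]][2]))
  }
  invisible(x)
}

#' Select the best candidate model by mean cross-validated AUC
#'
#' Ties are broken in favor of fewer features, then alphabetically by the
#' feature names, so selection does not depend on candidate order.
#'
#' @param cv_results list of [cross_validate()] results.
#' @return the winning [model_spec()], with the corresponding `cv_result`
#'   attached as attribute `cv`.
#' @export
select_model <- function(cv_results) {
  if (length(cv_results) == 0) stop("no candidate results")
  key <- vapply(cv_results, function(r) {
    sprintf("%012.9f|%d|%s", 1 - r$means[["auc"]],
            length(r$spec$features),
            paste(sort(r$spec$features), collapse = ","))
  }, character(1))
  best <- cv_results[[order(key)[1]]]
  structure(best$spec, cv = best)
}

#' Youden-optimal probability threshold
#'
#' Scans the midpoints between adjacent distinct predicted probabilities and
#' returns the threshold maximizing Youden's J = sensitivity + specificity
#' - 1 (cases with probability >= threshold are called poor responders).
#' Ties resolve to the lowest threshold, i.e. the more sensitive cut.
#'
#' @param probs predicted probabilities of poor response.
#' @param labels outcome, "poor"/"good" or 1/0.
#' @return the probability threshold, with Youden's J as attribute `J`.
#' @export
youden_threshold <- function(probs, labels) {
  y <- if (is.numeric(labels)) as.integer(labels) else
    as.integer(labels == "poor")
  if (length(unique(y)) < 2) stop("both outcome classes must be present")
  u <- sort(unique(probs))
  mids <- if (length(u) > 1) (utils::head(u, -1) + utils::tail(u, -1)) / 2
          else numeric(0)
  # boundary cuts call everyone poor / everyone good (J = 0), so the
  # maximized J is never negative
  cands <- c(min(u) - 1, mids, max(u) + 1)
  js <- vapply(cands, function(th) {
    pred <- as.integer(probs >= th)
    sum(pred == 1 & y == 1) / sum(y == 1) +
      sum(pred == 0 & y == 0) / sum(y == 0) - 1
  }, numeric(1))
  best <- which(js >= max(js) - 1e-12)[1]   # lowest threshold among ties
  structure(cands[best], J = js[best])
}

#' Freeze the final model on the full training cohort
#'
#' Log-transforms, z-scores on the whole training cohort, fits the logistic
#' model, and fixes the Youden-optimal probability threshold on the
#' full-training-set predictions. For a single-feature model the
#' natural-scale feature threshold is derived as well.
#'
#' @param records training cohort feature table.
#' @param spec the selected [model_spec()].
#' @param ridge_lambda passed to [fit_logistic()].
#' @return object of class `fitted_response_model`.
#' @export
finalize_model <- function(records, spec, ridge_lambda = 1e-4) {
  y <- as.integer(records$response == "poor")
  cols <- spec_columns(spec)
  X <- as.matrix(log_transform_features(records)[, cols, drop = FALSE])
  norm <- fit_normalizer(X)
  fit <- fit_logistic(apply_normalizer(norm, X), y, ridge_lambda)
  probs <- predict_logistic(fit, apply_normalizer(norm, X))
  thr <- youden_threshold(probs, y)
  model <- structure(
    list(spec = spec, columns = cols, normalizer = norm,
         intercept = fit$intercept, slopes = fit$slopes,
         prob_threshold = as.numeric(thr), youden_j = attr(thr, "J"),
         training_probs = probs),
    class = "fitted_response_model"
  )
  if (length(spec$features) == 1) {
    model$natural_threshold <- natural_scale_threshold(model)
  }
  model
}

#' Natural-scale threshold of a single-feature model
#'
#' Inverts the probability threshold through the logistic link and the
#' training normalization, then maps back from the log scale, yielding a
#' cutoff directly on the feature's natural (ratio) scale. The direction
#' states on which side of the cutoff poor response is predicted.
#'
#' @param model a single-feature [finalize_model()] fit.
#' @return list with `feature`, `threshold` (natural scale) and `direction`
#'   (`"poor_below"` or `"poor_above"`).
#' @export
natural_scale_threshold <- function(model) {
  stopifnot(inherits(model, "fitted_response_model"))
  if (length(model$spec$features) != 1) {
    stop("natural-scale threshold requires a single-feature model")
  }
  b1 <- model$slopes[1]
  z <- (stats::qlogis(model$prob_threshold) - model$intercept) / b1
  x_log <- z * model$normalizer$sd[1] + model$normalizer$mean[1]
  feature <- model$spec$features[1]
  natural <- if (feature == "delta_tte") signed_exp(x_log) else exp(x_log)
  list(feature = feature, threshold = as.numeric(natural),
       direction = if (b1 < 0) "poor_below" else "poor_above")
}

#' Percent decrease corresponding to a pre/post ratio
#'
#' A pre/post ratio r means the feature fell to 1/r of its pre-treatment
#' value, i.e. a decrease of `100 (1 - 1/r)` percent. A ratio of 2.3 is a
#' 57\% decrease (after integer rounding).
#'
#' @param r positive pre/post ratio.
#' @return percent decrease (negative for an increase).
#' @export
ratio_to_percent_decrease <- function(r) {
  if (any(r <= 0)) stop("`r` must be > 0")
  100 * (1 - 1 / r)
}

#' External validation of a frozen model on a test cohort
#'
#' Applies the frozen normalization, coefficients and probability threshold
#' to an unseen cohort, optionally after harmonizing the test features into
#' the training cohort's frame with reference-batch ComBat. Nothing is
#' refitted on test data.
#'
#' @param model a [finalize_model()] fit.
#' @param test_records test cohort feature table (natural scale).
#' @param train_records training cohort table; required when
#'   `use_combat = TRUE` (the harmonization reference frame).
#' @param use_combat harmonize before scoring.
#' @param combat_covariates preserve the response label as a covariate in
#'   the ComBat design.
#' @return list with `accuracy`, `sensitivity`, `specificity`, `auc`,
#'   `probs` and `predicted`.
#' @export
external_validate <- function(model, test_records, train_records = NULL,
                              use_combat = TRUE, combat_covariates = TRUE) {
  stopifnot(inherits(model, "fitted_response_model"))
  y <- as.integer(test_records$response == "poor")
  feat_cols <- intersect(cohort_feature_columns(), names(test_records))
  test_log <- log_transform_features(test_records)
  if (use_combat) {
    if (is.null(train_records)) {
      stop("`train_records` needed to define the harmonization reference")
    }
    train_log <- log_transform_features(train_records)
    all_x <- rbind(as.matrix(train_log[, feat_cols]),
                   as.matrix(test_log[, feat_cols]))
    batch <- c(train_records$center_id, test_records$center_id)
    covs <- if (combat_covariates) {
      data.frame(response = c(train_records$response, test_records$response))
    } else NULL
    cb <- fit_combat(all_x, batch, reference = train_records$center_id[1],
                     covariates = covs)
    harm <- apply_combat(cb, all_x, batch, covariates = covs)
    test_log[, feat_cols] <- harm[batch != train_records$center_id[1], ,
                                  drop = FALSE]
  }
  X <- apply_normalizer(model$normalizer,
                        as.matrix(test_log[, model$columns, drop = FALSE]))
  probs <- stats::plogis(model$intercept + drop(X %*% model$slopes))
  pred <- as.integer(probs >= model$prob_threshold)
  cm <- classification_metrics(pred, y)
  list(accuracy = cm$accuracy, sensitivity = cm$sensitivity,
       specificity = cm$specificity, auc = auc_score(probs, y),
       probs = probs, predicted = pred)
}
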