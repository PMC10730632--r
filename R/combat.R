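## Reference-batch ComBat harmonization.
##
## Parametric empirical-Bayes location/scale batch adjustment in which one
## batch (the training center) is the reference frame: its rows pass through
## bit-unchanged and every other batch is adjusted into its frame. The
## fit/apply split yields a serializable model that can later be applied to
## unseen rows of a known batch. Features are expected on the modeling (log)
## scale, rows are samples, columns are features.

# moment-matched inverse-gamma hyperparameters for the scale prior
ig_moments <- function(delta_hat) {
  m <- mean(delta_hat)
  s2 <- stats::var(delta_hat)
  list(a = (2 * s2 + m^2) / s2, b = (m * s2 + m^3) / s2)
}

# iterative conditional update of the EB-shrunk batch effects
eb_solve <- function(z_batch, gamma_hat, delta_hat, gamma_bar, tau2,
                     a_prior, b_prior, tol = 1e-6, max_iter = 200) {
  n_b <- nrow(z_batch)
  g_new <- gamma_hat
  d_new <- delta_hat
  for (it in seq_len(max_iter)) {
    g_old <- g_new
    d_old <- d_new
    g_new <- (n_b * tau2 * gamma_hat + d_new * gamma_bar) /
      (n_b * tau2 + d_new)
    ss <- colSums(sweep(z_batch, 2, g_new, "-")^2)
    d_new <- (b_prior + 0.5 * ss) / (n_b / 2 + a_prior - 1)
    if (max(abs(g_new - g_old), abs(d_new - d_old)) < tol) break
  }
  list(gamma_star = g_new, delta_star = d_new)
}

combat_design <- function(covariates, n) {
  if (is.null(covariates)) {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    if (!is.data.frame(covariates)) {
      covariates <- data.frame(covariate = covariates)
    }
    stats::model.matrix(~ ., data = covariates)
  }
}

#' Fit a reference-batch ComBat model
#'
#' Standardizes features using location/scale (and optional covariate
#' effects) estimated on the reference batch, estimates per-batch
#' location/scale deviations for the remaining batches, and shrinks them
#' with parametric empirical Bayes (normal prior on locations,
#' inverse-gamma on scales, moment-matched hyperparameters, iterative
#' conditional update). The reference batch's stored effects are the
#' identity by construction.
#'
#' @param x numeric matrix or data.frame, samples in rows, features in
#'   columns, on the modeling (log) scale.
#' @param batch batch label per row.
#' @param reference label of the reference batch (the frame everything is
#'   harmonized into).
#' @param covariates optional vector or data.frame of biological covariates
#'   to preserve (e.g. the response label); their effects are estimated on
#'   the reference batch and removed before batch effects are measured.
#' @param eb set `FALSE` to skip empirical-Bayes shrinkage (location/scale
#'   used as estimated).
#' @param tol,max_iter convergence control of the EB update.
#' @return object of class `combat_model`.
#' @export
fit_combat <- function(x, batch, reference, covariates = NULL, eb = TRUE,
                       tol = 1e-6, max_iter = 200) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  batch <- as.character(batch)
  if (length(batch) != nrow(x)) stop("`batch` must label every row")
  if (!reference %in% batch) stop("reference batch absent from data")
  batches <- unique(batch)
  tab <- table(batch)
  if (any(tab < 3)) stop("every batch needs at least 3 samples")
  single <- length(batches) == 1
  if (single) warning("single batch: fitting an identity model")

  design <- combat_design(covariates, nrow(x))
  ref_rows <- batch == reference
  Xr <- design[ref_rows, , drop = FALSE]
  Yr <- x[ref_rows, , drop = FALSE]
  B <- solve(crossprod(Xr), crossprod(Xr, Yr))
  resid_r <- Yr - Xr %*% B
  var_pooled <- colMeans(resid_r^2)
  if (any(var_pooled < 1e-12)) {
    stop("degenerate feature: zero variance within the reference batch")
  }

  fitted_all <- design %*% B
  z <- sweep(x - fitted_all, 2, sqrt(var_pooled), "/")

  nf <- ncol(x)
  gamma_star <- matrix(0, length(batches), nf,
                       dimnames = list(batches, colnames(x)))
  delta_star <- matrix(1, length(batches), nf,
                       dimnames = list(batches, colnames(x)))
  for (b in setdiff(batches, reference)) {
    zb <- z[batch == b, , drop = FALSE]
    gamma_hat <- colMeans(zb)
    delta_hat <- apply(zb, 2, stats::var)
    if (eb && nf >= 2) {
      pri <- ig_moments(delta_hat)
      sol <- eb_solve(zb, gamma_hat, delta_hat,
                      gamma_bar = mean(gamma_hat),
                      tau2 = stats::var(gamma_hat),
                      a_prior = pri$a, b_prior = pri$b,
                      tol = tol, max_iter = max_iter)
      gamma_star[b, ] <- sol$gamma_star
      delta_star[b, ] <- sol$delta_star
    } else {
      gamma_star[b, ] <- gamma_hat
      delta_star[b, ] <- delta_hat
    }
  }
  structure(
    list(features = colnames(x), B = B,
         design_columns = colnames(design),
         has_covariates = !is.null(covariates),
         var_pooled = var_pooled, batches = batches,
         reference = reference, gamma_star = gamma_star,
         delta_star = delta_star, eb = eb),
    class = "combat_model"
  )
}

#' Apply a fitted ComBat model
#'
#' Reference-batch rows are returned bit-identical; rows of any other known
#' batch are location/scale-adjusted into the reference frame.
#'
#' @param model a [fit_combat()] model.
#' @param x samples x features matrix on the scale the model was fitted on.
#' @param batch batch label per row; must be known to the model.
#' @param covariates covariates per row, as in the fit (required when the
#'   model was fitted with covariates).
#' @return harmonized matrix, same shape and dimnames as `x`.
#' @export
apply_combat <- function(model, x, batch, covariates = NULL) {
  stopifnot(inherits(model, "combat_model"))
  x <- as.matrix(x)
  batch <- as.character(batch)
  unknown <- setdiff(unique(batch), model$batches)
  if (length(unknown) > 0) {
    stop("unknown batch label(s): ", paste(unknown, collapse = ", "))
  }
  if (model$has_covariates && is.null(covariates)) {
    stop("model was fitted with covariates; supply them for `apply_combat`")
  }
  design <- combat_design(covariates, nrow(x))
  if (!identical(colnames(design), model$design_columns)) {
    stop("covariate design does not match the fitted model")
  }
  fitted <- design %*% model$B[, model$features, drop = FALSE]
  out <- x
  for (b in setdiff(unique(batch), model$reference)) {
    rows <- batch == b
    z <- sweep(x[rows, , drop = FALSE] - fitted[rows, , drop = FALSE],
               2, sqrt(model$var_pooled), "/")
    z_adj <- sweep(sweep(z, 2, model$gamma_star[b, ], "-"),
                   2, sqrt(model$delta_star[b, ]), "/")
    out[rows, ] <- sweep(z_adj, 2, sqrt(model$var_pooled), "*") +
      fitted[rows, , drop = FALSE]
  }
  out
}
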