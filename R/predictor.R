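# L1-penalised logistic biomarker models: design-matrix construction,
# LASSO path (glmnet backend), nested cross-validation with AUC
# reporting, variance-based effect decomposition and linear Shapley
# attribution.

#' Build the predictor matrix for biomarker modelling
#'
#' Features are the antigens passing the modelling gates (differential
#' q below `q_threshold` and case prevalence above
#' `prevalence_threshold`); values are the normalised (log2 CPM + 1)
#' counts of the selected samples.  Standardisation is deliberately NOT
#' applied here: fold-wise standardisation with training statistics only
#' is done inside [nested_cv()] to avoid leakage.
#'
#' @param norm antigen x sample normalised matrix.
#' @param diff_result data frame from [differential_selection()].
#' @param labels named binary response (0/1) over the modelling samples.
#' @param q_threshold,prevalence_threshold modelling gates (defaults
#'   0.05 and 0.30).
#' @return list with `X` (samples x features), `y`, `features`.
#' @export
build_design_matrix <- function(norm, diff_result, labels,
                                q_threshold = 0.05,
                                prevalence_threshold = 0.30) {
  stopifnot(all(labels %in% 0:1))
  keep <- !is.na(diff_result$q) & diff_result$q < q_threshold &
    diff_result$prev_case > prevalence_threshold
  features <- diff_result$antigen[keep]
  if (length(features) == 0L) stop("no antigen passes the modelling gates")
  X <- t(norm[features, names(labels), drop = FALSE])
  v <- apply(X, 2L, var)
  if (any(v == 0)) {
    warning("dropping zero-variance antigen(s): ",
            paste(colnames(X)[v == 0], collapse = ", "))
    X <- X[, v > 0, drop = FALSE]
    features <- colnames(X)
  }
  list(X = X, y = unname(labels), features = features)
}

standardize_fit <- function(X) {
  mu <- colMeans(X)
  sdev <- apply(X, 2L, sd)
  sdev[sdev == 0] <- 1
  list(mu = mu, sd = sdev)
}

standardize_apply <- function(X, stats) {
  sweep(sweep(X, 2L, stats$mu), 2L, stats$sd, "/")
}

lambda_grid <- function(X, y, nlambda = 100L, lambda_min_ratio = 1e-3) {
  lmax <- max(abs(crossprod(X, y - mean(y)))) / length(y)
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
}

#' Fit an L1-penalised logistic solution path
#'
#' Minimises `-(1/n) loglik + lambda * sum(|beta|)` (intercept
#' unpenalised) over a decreasing lambda grid, via glmnet.  At
#' `lambda >= lambda_max` all coefficients are zero; the grid defaults to
#' 100 log-spaced points from `lambda_max` down to `lambda_max / 1000`.
#'
#' @param X standardized predictor matrix (samples x features).
#' @param y binary response.
#' @param lambda optional explicit grid (strictly decreasing).
#' @param nlambda,lambda_min_ratio grid shape when `lambda` is `NULL`.
#' @return a `lasso_path`: list with `lambda`, `beta` (features x
#'   lambda), `intercept`, `l1_norm`, `df`.
#' @export
fit_lasso_path <- function(X, y, lambda = NULL, nlambda = 100L,
                           lambda_min_ratio = 1e-3) {
  stopifnot(all(y %in% 0:1))
  if (is.null(lambda)) {
    lambda <- lambda_grid(X, y, nlambda, lambda_min_ratio)
  }
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 1,
                        lambda = lambda, standardize = FALSE,
                        thresh = 1e-10, maxit = 1e6)
  if (fit$jerr != 0) {
    stop("glmnet did not converge (jerr = ", fit$jerr, ")")
  }
  beta <- as.matrix(fit$beta)
  structure(list(lambda = fit$lambda, beta = beta,
                 intercept = as.numeric(fit$a0),
                 l1_norm = colSums(abs(beta)),
                 df = colSums(beta != 0)),
            class = "lasso_path")
}

path_predict <- function(path, X) {
  sweep(X %*% path$beta, 2L, path$intercept, "+")
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' `AUC = P(score_case > score_control) + 0.5 P(tie)`, computed from
#' midranks; invariant to strictly monotone transforms of the scores.
#'
#' @param scores numeric scores.
#' @param labels binary labels (1 = case).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == 1
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Nested cross-validation for the LASSO-logistic biomarker model
#'
#' Outer K-fold (stratified) performance estimation around inner L-fold
#' lambda selection.  For each outer fold, inner CV on the outer-training
#' portion picks the lambda maximising mean inner-validation AUC (ties to
#' the larger lambda); the model is refit on the outer-training data at
#' lambda*, giving a re-substitution (training) AUC and a held-out (test)
#' AUC.  The reported validation AUC is the mean inner-fold AUC at
#' lambda*.  The final model is refit on all data at the median lambda*.
#' Fold-wise standardisation uses training statistics only.
#'
#' @param X raw predictor matrix (samples x features).
#' @param y binary response.
#' @param K,L outer/inner fold counts (defaults 4 and 5).
#' @param nlambda,lambda_min_ratio lambda grid shape.
#' @param seed fold-assignment seed.
#' @return a `ModelReport`: list with `auc` (train/validation/test
#'   means), `folds` (per-outer-fold table), `final` (coefficients,
#'   lambda, retained/excluded features), `path` (full-data
#'   `lasso_path`), `effects`, `shap`.
#' @export
nested_cv <- function(X, y, K = 4L, L = 5L, nlambda = 100L,
                      lambda_min_ratio = 1e-3, seed = 1L) {
  stopifnot(K >= 2L, L >= 2L, all(y %in% 0:1))
  with_seed(seed, {
    outer <- stratified_folds(y, K)
    fold_rows <- list()
    for (k in seq_len(K)) {
      tr <- outer != k
      te <- !tr
      if (length(unique(y[tr])) < 2L || length(unique(y[te])) < 2L) {
        stop("stratification error: a fold is missing a class")
      }
      st <- standardize_fit(X[tr, , drop = FALSE])
      Xtr <- standardize_apply(X[tr, , drop = FALSE], st)
      Xte <- standardize_apply(X[te, , drop = FALSE], st)
      grid <- lambda_grid(Xtr, y[tr], nlambda, lambda_min_ratio)
      inner <- stratified_folds(y[tr], L)
      auc_mat <- matrix(NA_real_, L, length(grid))
      for (l in seq_len(L)) {
        itr <- inner != l
        iva <- !itr
        ist <- standardize_fit(X[tr, , drop = FALSE][itr, , drop = FALSE])
        Xitr <- standardize_apply(X[tr, , drop = FALSE][itr, , drop = FALSE], ist)
        Xiva <- standardize_apply(X[tr, , drop = FALSE][iva, , drop = FALSE], ist)
        pth <- fit_lasso_path(Xitr, y[tr][itr], lambda = grid)
        eta <- path_predict(pth, Xiva)
        yi <- y[tr][iva]
        if (length(unique(yi)) == 2L) {
          auc_mat[l, seq_len(ncol(eta))] <-
            apply(eta, 2L, roc_auc, labels = yi)
        }
      }
      mean_auc <- colMeans(auc_mat, na.rm = TRUE)
      best <- which(mean_auc == max(mean_auc, na.rm = TRUE))[1L]
      lambda_star <- grid[best]
      pth <- fit_lasso_path(Xtr, y[tr], lambda = grid)
      eta_tr <- path_predict(pth, Xtr)[, best]
      eta_te <- path_predict(pth, Xte)[, best]
      fold_rows[[k]] <- data.frame(
        fold = k, lambda_star = lambda_star,
        train_auc = roc_auc(eta_tr, y[tr]),
        validation_auc = mean_auc[best],
        test_auc = roc_auc(eta_te, y[te]),
        n_retained = sum(pth$beta[, best] != 0))
    }
    folds <- do.call(rbind, fold_rows)
    st <- standardize_fit(X)
    Xs <- standardize_apply(X, st)
    grid <- lambda_grid(Xs, y, nlambda, lambda_min_ratio)
    lambda_final <- median(folds$lambda_star)
    grid_final <- sort(unique(c(grid, lambda_final)), decreasing = TRUE)
    path <- fit_lasso_path(Xs, y, lambda = grid_final)
    j <- which.min(abs(path$lambda - lambda_final))
    beta <- path$beta[, j]
    final <- list(lambda = lambda_final,
                  intercept = path$intercept[j],
                  coefficients = beta,
                  retained = names(beta)[beta != 0],
                  excluded = names(beta)[beta == 0],
                  standardization = st)
    effects <- if (any(beta != 0)) {
      effect_decomposition(beta, Xs)
    } else NULL
    structure(list(
      auc = c(train = mean(folds$train_auc),
              validation = mean(folds$validation_auc),
              test = mean(folds$test_auc)),
      folds = folds,
      final = final,
      path = path,
      effects = effects,
      shap = shap_linear(beta, Xs, path$intercept[j]),
      seed = seed
    ), class = "ModelReport")
  })
}

#' @export
print.ModelReport <- function(x, ...) {
  cat(sprintf("ModelReport: train AUC %.4f, validation AUC %.4f, test AUC %.4f\n",
              x$auc["train"], x$auc["validation"], x$auc["test"]))
  cat("  retained", length(x$final$retained), "of",
      length(x$final$coefficients), "predictors at lambda",
      signif(x$final$lambda, 3), "\n")
  invisible(x)
}

#' Variance-based effect decomposition of a linear predictor
#'
#' Share of predictor j is `Var(beta_j x_j) / sum_k Var(beta_k x_k)`.
#' For a main-effects-only linear model the main and total effects
#' coincide (no interaction terms exist), so one table is returned with
#' both columns equal; shares are non-negative and sum to 1 over the
#' retained (non-zero) predictors.
#'
#' @param beta named coefficient vector.
#' @param X predictor matrix on the scale the model was fit on.
#' @return data frame `predictor`, `main_effect`, `total_effect`.
#' @export
effect_decomposition <- function(beta, X) {
  nz <- beta != 0
  if (!any(nz)) stop("all coefficients are zero")
  contrib <- vapply(which(nz), function(j) beta[j]^2 * var(X[, j]),
                    numeric(1))
  share <- contrib / sum(contrib)
  data.frame(predictor = names(beta)[nz],
             main_effect = unname(share), total_effect = unname(share),
             stringsAsFactors = FALSE)
}

#' Shapley attribution for a linear-logistic model
#'
#' On the linear-predictor scale with independent features the Shapley
#' value has the closed form `phi_ij = beta_j (x_ij - mean_j)`; row sums
#' reproduce each sample's deviation of the linear predictor from the
#' cohort mean (local accuracy).
#'
#' @param beta named coefficient vector.
#' @param X predictor matrix on the model scale.
#' @param intercept model intercept (unused by the attribution; kept for
#'   the local-accuracy identity).
#' @return samples x predictors Shapley matrix.
#' @export
shap_linear <- function(beta, X, intercept = 0) {
  phi <- sweep(X, 2L, colMeans(X))
  phi <- sweep(phi, 2L, beta, "*")
  phi
}
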