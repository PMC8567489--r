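#' Partial least squares regression (NIPALS, single response)
#'
#' Classical NIPALS PLS1 on autoscaled columns. For discrimination the
#' class labels are coded +1/-1 and the fit is an ordinary PLS regression
#' on the coded response (PLS-DA). Deterministic given the input order.
#'
#' @param X Numeric matrix or data frame of predictors (no missing values
#'   after listwise deletion by the caller).
#' @param y Numeric response (or factor with two levels, coded +1/-1).
#' @param ncomp Number of latent components (default 3; capped at
#'   `min(n - 1, p)`).
#' @param scale Autoscale columns (default TRUE).
#' @return Object of class `cortbs_pls`: weights `W`, loadings `P`,
#'   scores `T`, response loadings `q`, regression coefficients on the
#'   original scale (`coefficients`, `intercept`), column centers/scales,
#'   and fitted values.
#' @export
pls_fit <- function(X, y, ncomp = 3, scale = TRUE) {
  X <- as.matrix(X)
  if (is.factor(y)) {
    if (nlevels(y) != 2) fail("factor response must have two levels")
    y <- ifelse(y == levels(y)[1], -1, 1)
  }
  y <- as.numeric(y)
  if (anyNA(X) || anyNA(y)) fail("missing values in X or y")
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  sds <- apply(X, 2, stats::sd)
  zero <- which(sds == 0)
  if (length(zero))
    fail("zero-variance column(s): %s",
         paste(colnames(X)[zero] %||% zero, collapse = ", "))
  ncomp <- min(ncomp, n - 1, p)
  mx <- colMeans(X); my <- mean(y)
  sx <- if (scale) sds else rep(1, p)
  Xs <- sweep(sweep(X, 2, mx), 2, sx, "/")
  ys <- y - my
  W <- P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  Xd <- Xs
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xd, ys)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- a - 1L; break }
    w <- w / nw
    t_ <- Xd %*% w
    tt <- sum(t_^2)
    p_ <- crossprod(Xd, t_) / tt
    q[a] <- sum(ys * t_) / tt
    Xd <- Xd - t_ %*% t(p_)
    W[, a] <- w; P[, a] <- p_; Tm[, a] <- t_
  }
  if (ncomp < 1) fail("no usable PLS component")
  W <- W[, seq_len(ncomp), drop = FALSE]
  P <- P[, seq_len(ncomp), drop = FALSE]
  Tm <- Tm[, seq_len(ncomp), drop = FALSE]
  q <- q[seq_len(ncomp)]
  B_s <- W %*% solve(crossprod(P, W), q)      # scaled-space coefficients
  coef <- as.numeric(B_s) / sx
  intercept <- my - sum(coef * mx)
  fitted <- as.numeric(X %*% coef + intercept)
  structure(list(ncomp = ncomp, W = W, P = P, T = Tm, q = q,
                 coefficients = coef, intercept = intercept,
                 centers = mx, scales = sx, y_mean = my,
                 fitted = fitted,
                 r_squared = 1 - sum((y - fitted)^2) /
                   max(sum((y - mean(y))^2), 1e-300),
                 var_names = colnames(X)),
            class = "cortbs_pls")
}

#' @export
predict.cortbs_pls <- function(object, newdata, ...) {
  as.numeric(as.matrix(newdata) %*% object$coefficients + object$intercept)
}

#' Cross-validated PLS predictions
#'
#' Leave-one-out or stratified k-fold cross-validation of a PLS (or
#' PLS-DA) model: every subject is predicted only by models that were not
#' trained on it. For discrimination, folds are stratified by class; a
#' fold whose training set contains one class only is an error.
#'
#' @param X Predictor matrix.
#' @param y Response (numeric, or factor/± labels for discrimination).
#' @param ncomp Components (default 3).
#' @param scheme "loocv" or "kfold".
#' @param k Number of folds for k-fold (default 3).
#' @param stratify Stratify folds by the sign of `y` (default TRUE for
#'   two-class y).
#' @param center_scores Subtract each fold's training-set mean response
#'   from its predictions. With leave-one-out discrimination this removes
#'   the training-composition shift (leaving out a positive lowers the
#'   training mean and with it the held-out score), which otherwise biases
#'   the cross-validated AUC below 0.5 under the null. Default TRUE for
#'   two-class responses, FALSE for regression.
#' @param seed Seed for the fold assignment.
#' @return List: `predictions` (one per subject), `rho` (Spearman),
#'   `rmse`, `scheme`, `folds`.
#' @export
cross_validated_pls <- function(X, y, ncomp = 3, scheme = c("loocv", "kfold"),
                                k = 3, stratify = NULL,
                                center_scores = NULL, seed = NULL) {
  scheme <- match.arg(scheme)
  X <- as.matrix(X)
  if (is.factor(y)) y <- ifelse(y == levels(y)[1], -1, 1)
  y <- as.numeric(y)
  n <- nrow(X)
  two_class <- length(unique(y)) == 2
  if (is.null(stratify)) stratify <- two_class
  if (is.null(center_scores)) center_scores <- two_class
  folds <- if (scheme == "loocv") seq_len(n) else
    with_seed(seed, {
      f <- integer(n)
      if (stratify && two_class) {
        for (cl in unique(y)) {
          i <- which(y == cl)
          f[i] <- sample(rep_len(seq_len(k), length(i)))
        }
      } else f <- sample(rep_len(seq_len(k), n))
      f
    })
  preds <- rep(NA_real_, n)
  for (fold in unique(folds)) {
    test <- which(folds == fold)
    train <- setdiff(seq_len(n), test)
    if (two_class && length(unique(y[train])) < 2)
      fail("degenerate fold: training set contains one class only")
    fit <- pls_fit(X[train, , drop = FALSE], y[train], ncomp = ncomp)
    preds[test] <- predict(fit, X[test, , drop = FALSE])
    if (center_scores) preds[test] <- preds[test] - mean(y[train])
  }
  list(predictions = preds,
       rho = suppressWarnings(stats::cor(preds, y, method = "spearman")),
       rmse = sqrt(mean((preds - y)^2)),
       scheme = scheme, folds = folds)
}

#' Leave-pair-out cross-validated AUC
#'
#' For every (positive, negative) subject pair, a PLS-DA model trained
#' without both subjects scores them; the AUC is the fraction of
#' concordant pairs. Unlike the AUC of pooled leave-one-out scores, this
#' estimator is unbiased under the null (pooled LOOCV scores carry a
#' small pessimistic bias because each held-out label is anti-correlated
#' with its training set).
#'
#' @param X Predictor matrix.
#' @param y Two-class response (factor or +1/-1).
#' @param ncomp PLS components.
#' @return AUC in `[0, 1]`.
#' @export
lpocv_auc <- function(X, y, ncomp = 3) {
  X <- as.matrix(X)
  if (is.factor(y)) y <- ifelse(y == levels(y)[1], -1, 1)
  y <- sign(as.numeric(y))
  ip <- which(y > 0); im <- which(y <= 0)
  if (!length(ip) || !length(im)) fail("both classes must be present")
  conc <- 0
  for (i in ip) for (j in im) {
    tr <- setdiff(seq_along(y), c(i, j))
    fit <- pls_fit(X[tr, , drop = FALSE], y[tr], ncomp = ncomp)
    p <- predict(fit, X[c(i, j), , drop = FALSE])
    conc <- conc + (p[1] > p[2]) + 0.5 * (p[1] == p[2])
  }
  conc / (length(ip) * length(im))
}
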