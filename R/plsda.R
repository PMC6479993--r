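# Multi-class PLS-DA: NIPALS PLS2 on autoscaled predictors and a centered
# one-hot response, 7-fold cross-validated selection of the number of
# latent variables, cumulative R2Y/Q2, VIP scores, prediction by argmax,
# and a label-permutation validation test.

#' Autoscale a matrix
#'
#' Centers every column by its mean and divides by its standard deviation,
#' both computed on `fit_rows` only, so the same transformation can be
#' applied to validation rows. Columns with zero variance on the fit rows
#' get scale 1 (with a warning) and are flagged.
#'
#' @param X Numeric matrix.
#' @param fit_rows Row indices used to estimate center and scale (default:
#'   all rows).
#' @return List with `X` (the fully transformed matrix), `center`,
#'   `scale`, and `zero_var` (logical per column).
#' @export
autoscale <- function(X, fit_rows = NULL) {
  X <- as.matrix(X)
  fit_rows <- fit_rows %||% seq_len(nrow(X))
  if (length(fit_rows) == 0) stop("`fit_rows` must be non-empty")
  Xf <- X[fit_rows, , drop = FALSE]
  ctr <- colMeans(Xf)
  scl <- apply(Xf, 2, sd)
  zv <- !is.finite(scl) | scl < .Machine$double.eps^0.5
  if (any(zv)) {
    warning(sum(zv), " zero-variance column(s); scale set to 1")
    scl[zv] <- 1
  }
  list(X = sweep(sweep(X, 2, ctr), 2, scl, "/"),
       center = ctr, scale = scl, zero_var = zv)
}

apply_scaling <- function(X, center, scale) {
  sweep(sweep(as.matrix(X), 2, center), 2, scale, "/")
}

# One NIPALS PLS2 component on (already deflated) X and Y. Returns NULL
# when the residual is degenerate.
nipals_component <- function(X, Y, tol = 1e-12, max_iter = 500) {
  n <- nrow(X)
  u <- Y[, which.max(apply(Y, 2, var))]
  if (sum(u^2) < 1e-14) return(NULL)
  t_old <- rep(0, n)
  w <- t <- cvec <- NULL
  for (it in seq_len(max_iter)) {
    w <- crossprod(X, u)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) return(NULL)
    w <- w / nw
    t <- X %*% w
    tt <- sum(t^2)
    if (tt < 1e-14) return(NULL)
    cvec <- crossprod(Y, t) / tt
    u <- Y %*% cvec / sum(cvec^2)
    if (sqrt(sum((t - t_old)^2)) < tol * sqrt(tt)) break
    t_old <- t
  }
  tt <- sum(t^2)
  list(w = w, t = t, c = cvec, p = crossprod(X, t) / tt)
}

# NIPALS PLS2 with sequential deflation. Returns unit-norm weights W,
# X-loadings P, Y-loadings C, X-scores T and the residual sums of squares
# of Y and X after each component (index a+1 = after a components).
nipals_pls2 <- function(X, Y, A, tol = 1e-12, max_iter = 500) {
  p <- ncol(X)
  m <- ncol(Y)
  n <- nrow(X)
  W <- P <- matrix(0, p, 0)
  C <- matrix(0, m, 0)
  Tm <- matrix(0, n, 0)
  rss_y <- sum(Y^2)
  rss_x <- sum(X^2)
  for (a in seq_len(A)) {
    cp <- nipals_component(X, Y, tol, max_iter)
    if (is.null(cp)) break
    X <- X - cp$t %*% t(cp$p)
    Y <- Y - cp$t %*% t(cp$c)
    W <- cbind(W, cp$w)
    P <- cbind(P, cp$p)
    C <- cbind(C, cp$c)
    Tm <- cbind(Tm, cp$t)
    rss_y <- c(rss_y, sum(Y^2))
    rss_x <- c(rss_x, sum(X^2))
  }
  list(W = W, P = P, C = C, T = Tm, rss_y = rss_y, rss_x = rss_x,
       A = ncol(W))
}

# Project new (already scaled) data through a fitted component sequence,
# returning the cumulative Y prediction after each component.
pls2_predict_path <- function(fit, Xs) {
  A <- fit$A
  n <- nrow(Xs)
  m <- nrow(fit$C)
  preds <- vector("list", A)
  Yhat <- matrix(0, n, m)
  Xr <- Xs
  for (a in seq_len(A)) {
    t <- Xr %*% fit$W[, a]
    Xr <- Xr - t %*% t(fit$P[, a])
    Yhat <- Yhat + t %*% t(fit$C[, a])
    preds[[a]] <- Yhat
  }
  preds
}

venetian_folds <- function(n, folds, rotation = 0) {
  ((seq_len(n) - 1 + rotation) %% folds) + 1
}

#' Fit a multi-class PLS-DA model
#'
#' Regresses a centered one-hot class-membership matrix on the autoscaled
#' predictors by NIPALS PLS2. The number of latent variables `A` is chosen
#' by k-fold cross-validation with venetian-blind fold assignment: each
#' component is refitted on the training part of the current residual
#' matrices in every fold, and its held-out incremental prediction error
#' gives `Q2_a = 1 - PRESS_a / SS_(a-1)`, with `SS_(a-1)` the residual
#' response variance before the component. `A` is the largest count for
#' which every component so far has `Q2_a >= q2_threshold`. If no
#' component passes, the model has `status = "failed"` -- a value, not an
#' error, mirroring how a dataset can simply fail to support a
#' discriminant model.
#'
#' Reported quality measures: `R2Ycum = 1 - RSS_A / SSY` (fit to the
#' response), `R2Xcum` (explained predictor variance), and the cumulative
#' `Q2cum`, by default the multiplicative convention
#' `1 - prod_a(PRESS_a / SS_(a-1))`; `q2_convention = "plain"` instead
#' cross-validates the complete A-component prediction and reports
#' `1 - PRESS_A / SSY`.
#'
#' @param X Numeric matrix of predictors (samples x variables).
#' @param y Class labels (factor, character or integer), at least two
#'   classes.
#' @param folds Number of cross-validation folds.
#' @param A_max Maximum number of latent variables considered.
#' @param q2_threshold Per-component significance limit for `Q2_a`.
#' @param q2_convention `"cumulative"` (multiplicative, default) or
#'   `"plain"`.
#' @param cv_rotation Integer offset rotating the venetian-blind fold
#'   assignment (reproducibility knob).
#' @return Object of class `"plsda_model"`; see Details. Key fields:
#'   `A`, `status`, `R2cum`, `Q2cum`, `R2Xcum`, per-component `q2` and
#'   `r2y`, `weights`, `x_loadings`, `y_loadings`, `scores`, `center`,
#'   `scale`, `classes`.
#' @export
fit_plsda <- function(X, y, folds = 7, A_max = 10, q2_threshold = 0.05,
                      q2_convention = c("cumulative", "plain"),
                      cv_rotation = 0) {
  q2_convention <- match.arg(q2_convention)
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) stop("`y` must have one label per row of `X`")
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("need at least two classes")
  if (n < folds) stop("fewer samples than folds")
  Y1 <- onehot(y, classes)
  sc <- suppressWarnings(autoscale(X))
  y_center <- colMeans(Y1)
  Y0 <- sweep(Y1, 2, y_center)
  A_cap <- max(1, min(A_max, n - 1, ncol(X)))
  ssy <- sum(Y0^2)

  # Sequential extraction with per-component cross-validation: component a
  # is refitted on the training part of the current residual matrices in
  # every fold, its held-out incremental prediction error PRESS_a compared
  # against the residual response variance SS_(a-1). Scaling is fitted once
  # on the whole workset (SIMCA convention), not per fold.
  fold_id <- venetian_folds(n, folds, cv_rotation)
  EX <- sc$X
  FY <- Y0
  W <- P <- matrix(0, ncol(X), 0)
  C <- matrix(0, ncol(Y0), 0)
  Tm <- matrix(0, n, 0)
  press <- ss_prev <- q2 <- numeric(0)
  rss_y <- ssy
  rss_x <- sum(EX^2)
  for (a in seq_len(A_cap)) {
    ss_a <- sum(FY^2)
    pr <- 0
    for (f in sort(unique(fold_id))) {
      tr <- fold_id != f
      te <- !tr
      cpf <- nipals_component(EX[tr, , drop = FALSE],
                              FY[tr, , drop = FALSE])
      if (is.null(cpf)) {
        pr <- pr + sum(FY[te, , drop = FALSE]^2)
      } else {
        t_te <- EX[te, , drop = FALSE] %*% cpf$w
        pr <- pr + sum((FY[te, , drop = FALSE] - t_te %*% t(cpf$c))^2)
      }
    }
    cp <- nipals_component(EX, FY)
    if (is.null(cp)) break
    EX <- EX - cp$t %*% t(cp$p)
    FY <- FY - cp$t %*% t(cp$c)
    W <- cbind(W, cp$w)
    P <- cbind(P, cp$p)
    C <- cbind(C, cp$c)
    Tm <- cbind(Tm, cp$t)
    press <- c(press, pr)
    ss_prev <- c(ss_prev, ss_a)
    q2 <- c(q2, 1 - pr / ss_a)
    rss_y <- c(rss_y, sum(FY^2))
    rss_x <- c(rss_x, sum(EX^2))
  }
  A_avail <- ncol(W)
  if (A_avail == 0) {
    return(structure(list(status = "failed", A = 0L, classes = classes,
                          reason = "no latent variable could be extracted"),
                     class = "plsda_model"))
  }
  fit <- list(W = W, P = P, C = C, T = Tm, rss_y = rss_y, rss_x = rss_x)
  fail_at <- which(q2 < q2_threshold)[1]
  A <- if (is.na(fail_at)) A_avail else fail_at - 1L
  r2y_cum <- 1 - fit$rss_y[-1] / ssy
  r2x_cum <- 1 - fit$rss_x[-1] / fit$rss_x[1]
  status <- if (A >= 1) "fitted" else "failed"
  Q2cum <- if (A >= 1) {
    if (q2_convention == "cumulative") {
      1 - prod((press / ss_prev)[seq_len(A)])
    } else {
      # plain convention: CV prediction error of the complete A-component
      # model against the total response variance
      pr_full <- 0
      for (f in sort(unique(fold_id))) {
        tr <- fold_id != f
        te <- !tr
        ftr <- nipals_pls2(sc$X[tr, , drop = FALSE],
                           Y0[tr, , drop = FALSE], A)
        yhat <- if (ftr$A == 0) {
          matrix(0, sum(te), ncol(Y0))
        } else {
          path <- pls2_predict_path(ftr, sc$X[te, , drop = FALSE])
          path[[min(A, ftr$A)]]
        }
        pr_full <- pr_full + sum((Y0[te, , drop = FALSE] - yhat)^2)
      }
      1 - pr_full / ssy
    }
  } else {
    NA_real_
  }
  structure(list(status = status, A = as.integer(A),
                 A_available = as.integer(A_avail),
                 classes = classes,
                 weights = fit$W, x_loadings = fit$P,
                 y_loadings = fit$C, scores = fit$T,
                 center = sc$center, scale = sc$scale,
                 y_center = y_center, y = y,
                 q2 = q2, press = press,
                 r2y_cum = r2y_cum, r2x_cum = r2x_cum,
                 R2cum = if (A >= 1) r2y_cum[A] else NA_real_,
                 Q2cum = Q2cum,
                 R2Xcum = if (A >= 1) r2x_cum[A] else NA_real_,
                 ssy = ssy,
                 folds = folds, q2_threshold = q2_threshold,
                 q2_convention = q2_convention),
            class = "plsda_model")
}

#' @export
print.plsda_model <- function(x, ...) {
  if (x$status == "failed") {
    cat("<plsda_model> status: failed (no latent variable passed",
        "cross-validation)\n")
  } else {
    cat(sprintf(
      "<plsda_model> %d classes, A = %d, R2Y(cum) = %.4f, Q2(cum) = %.4f\n",
      length(x$classes), x$A, x$R2cum, x$Q2cum))
  }
  invisible(x)
}

#' Predict classes from a fitted PLS-DA model
#'
#' Applies the stored scaling, accumulates the `A` selected components,
#' and assigns each sample to the class with the largest predicted
#' membership value (ties break to the lowest class index).
#'
#' @param object A fitted `"plsda_model"`.
#' @param newdata Matrix with the same columns as the training data.
#' @param type `"class"` (default) for labels, `"response"` for the
#'   predicted membership matrix.
#' @param ... Unused.
#' @return Label vector or numeric matrix, per `type`.
#' @export
predict.plsda_model <- function(object, newdata,
                                type = c("class", "response"), ...) {
  type <- match.arg(type)
  if (object$status == "failed") stop("cannot predict from a failed model")
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$center)) {
    stop("`newdata` has the wrong number of columns")
  }
  Xs <- apply_scaling(newdata, object$center, object$scale)
  Yhat <- matrix(0, nrow(Xs), length(object$classes))
  Xr <- Xs
  for (a in seq_len(object$A)) {
    t <- Xr %*% object$weights[, a]
    Xr <- Xr - t %*% t(object$x_loadings[, a])
    Yhat <- Yhat + t %*% t(object$y_loadings[, a])
  }
  Yhat <- sweep(Yhat, 2, object$y_center, "+")
  colnames(Yhat) <- as.character(object$classes)
  if (type == "response") return(Yhat)
  object$classes[max.col(Yhat, ties.method = "first")]
}

#' Variable importance in projection (VIP)
#'
#' `VIP_j = sqrt(p * sum_a SSY_a * (w_aj / ||w_a||)^2 / sum_a SSY_a)`,
#' where `SSY_a` is the response variance explained by component `a` and
#' the sum runs over the selected components. The mean squared VIP is 1
#' (`sum VIP^2 = p`), so variables with VIP > 1 are more important than
#' average.
#'
#' @param model A fitted `"plsda_model"`.
#' @return Numeric vector of length `ncol(X)`.
#' @export
vip <- function(model) {
  if (model$status == "failed") stop("cannot compute VIP of a failed model")
  A <- model$A
  rss <- c(model$ssy, model$ssy * (1 - model$r2y_cum))
  ssy_a <- rss[seq_len(A)] - rss[seq_len(A) + 1]
  W <- model$weights[, seq_len(A), drop = FALSE]
  W2 <- sweep(W^2, 2, colSums(W^2), "/")
  p <- nrow(W)
  as.numeric(sqrt(p * (W2 %*% ssy_a) / sum(ssy_a)))
}

#' Permutation test of a PLS-DA model
#'
#' Refits the model `n_iter` times with uniformly permuted class labels,
#' using the same cross-validated component selection, and records each
#' permuted model's `R2Ycum` and `Q2cum` along with the correlation
#' between the permuted and original one-hot label matrices. A failed
#' permuted fit is recorded as `R2 = Q2 = 0`. The test passes when every
#' permuted value lies below the corresponding original value.
#'
#' @param X,y Data and labels, as in [fit_plsda()].
#' @param n_iter Number of permutations (default 30).
#' @param seed Integer seed for the permutation draws.
#' @param permutations Optional list of explicit permutation index vectors
#'   (overrides random draws; useful for checks).
#' @param ... Passed to [fit_plsda()].
#' @return Object of class `"permutation_result"` with `n_iter`,
#'   `permuted_R2`, `permuted_Q2`, `label_correlations`, `original_R2`,
#'   `original_Q2`, `passed`.
#' @export
permutation_test <- function(X, y, n_iter = 30, seed = 1,
                             permutations = NULL, ...) {
  orig <- fit_plsda(X, y, ...)
  if (orig$status == "failed") {
    stop("original model failed; nothing to permute against")
  }
  if (!is.null(permutations)) n_iter <- length(permutations)
  Y1 <- onehot(y, orig$classes)
  pr2 <- numeric(n_iter)
  pq2 <- numeric(n_iter)
  lcor <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    perm <- if (is.null(permutations)) {
      with_seed(child_seed(seed, i), sample(length(y)))
    } else {
      permutations[[i]]
    }
    yp <- y[perm]
    lcor[i] <- cor(as.vector(onehot(yp, orig$classes)), as.vector(Y1))
    m <- tryCatch(fit_plsda(X, yp, ...), error = function(e) NULL)
    if (is.null(m) || m$status == "failed") {
      pr2[i] <- 0
      pq2[i] <- 0
    } else {
      pr2[i] <- m$R2cum
      pq2[i] <- m$Q2cum
    }
  }
  structure(list(n_iter = n_iter, permuted_R2 = pr2, permuted_Q2 = pq2,
                 label_correlations = lcor,
                 original_R2 = orig$R2cum, original_Q2 = orig$Q2cum,
                 passed = all(pr2 < orig$R2cum) && all(pq2 < orig$Q2cum)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> %d iterations, original R2 = %.4f, Q2 = %.4f: %s\n",
    x$n_iter, x$original_R2, x$original_Q2,
    if (x$passed) "PASSED" else "NOT passed"))
  invisible(x)
}
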