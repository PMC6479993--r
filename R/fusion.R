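# Data fusion: low-level (variable concatenation) and mid-level (per-block
# PCA score concatenation), with strict sample correspondence. Rows are
# matched on sample_id for multi-technique fusion within one part, or on
# sclerotium_id when the two parts of one sclerotium are fused.

pairing_key <- function(b, pairing) {
  if (pairing == "by_sample") {
    b$row_meta$sample_id
  } else {
    if (!"sclerotium_id" %in% names(b$row_meta)) {
      stop("correspondence violation: `sclerotium_id` missing from row ",
           "metadata of block ", b$block_id)
    }
    b$row_meta$sclerotium_id
  }
}

# Reorder all blocks to the first block's key order; error on unmatched or
# duplicated keys.
match_blocks <- function(blocks, pairing) {
  keys <- lapply(blocks, pairing_key, pairing = pairing)
  ref <- keys[[1]]
  if (anyDuplicated(ref)) {
    stop("correspondence violation: duplicated pairing keys in block ",
         blocks[[1]]$block_id)
  }
  out <- vector("list", length(blocks))
  out[[1]] <- blocks[[1]]
  for (j in seq_along(blocks)[-1]) {
    k <- keys[[j]]
    if (anyDuplicated(k) || length(k) != length(ref) || !all(ref %in% k)) {
      stop("correspondence violation: blocks ", blocks[[1]]$block_id,
           " and ", blocks[[j]]$block_id, " do not list the same samples")
    }
    idx <- match(ref, k)
    b <- blocks[[j]]
    b$matrix <- b$matrix[idx, , drop = FALSE]
    b$row_meta <- b$row_meta[idx, , drop = FALSE]
    rownames(b$row_meta) <- NULL
    out[[j]] <- b
  }
  out
}

fused_row_meta <- function(b, pairing) {
  if (pairing == "by_sample") {
    m <- b$row_meta
  } else {
    m <- b$row_meta[, intersect(c("sclerotium_id", "class_label",
                                  "origin_abbrev"), names(b$row_meta)),
                    drop = FALSE]
  }
  rownames(m) <- NULL
  m
}

#' Low-level data fusion
#'
#' Concatenates the variables of several preprocessed blocks into one
#' matrix, after matching rows on the pairing key. The fused width is the
#' sum of the block widths and every column's origin is recorded.
#'
#' @param blocks List of [block()]s, concatenated in the given order.
#' @param pairing `"by_sample"` (multi-technique fusion of one part;
#'   matches `sample_id`) or `"by_sclerotium"` (two-part fusion; requires
#'   exactly one row per sclerotium per block).
#' @return Object of class `"fused_dataset"`: `matrix`, `row_meta`,
#'   `column_provenance` (data frame of `block_id`, `label`), `level`
#'   (`"low"`), `pairing`.
#' @export
low_level_fuse <- function(blocks, pairing = c("by_sample",
                                               "by_sclerotium")) {
  pairing <- match.arg(pairing)
  if (inherits(blocks, "block")) blocks <- list(blocks)
  if (length(blocks) < 1) stop("at least one block is required")
  blocks <- match_blocks(blocks, pairing)
  mats <- lapply(blocks, function(b) b$matrix)
  prov <- do.call(rbind, lapply(blocks, function(b) {
    data.frame(block_id = b$block_id,
               label = as.character(b$col_labels),
               stringsAsFactors = FALSE)
  }))
  structure(list(matrix = do.call(cbind, mats),
                 row_meta = fused_row_meta(blocks[[1]], pairing),
                 column_provenance = prov,
                 level = "low", pairing = pairing),
            class = "fused_dataset")
}

#' @export
print.fused_dataset <- function(x, ...) {
  cat(sprintf("<fused_dataset> %s-level, %s: %d samples x %d variables (%s)\n",
              x$level, x$pairing, nrow(x$matrix), ncol(x$matrix),
              paste(unique(x$column_provenance$block_id), collapse = " + ")))
  invisible(x)
}

# Economy SVD of a wide matrix (n << p) via the n x n cross-product.
svd_wide <- function(X, k) {
  G <- tcrossprod(X)
  e <- eigen(G, symmetric = TRUE)
  d2 <- pmax(e$values, 0)
  pos <- d2 > max(d2) * 1e-12
  k <- min(k, sum(pos))
  d <- sqrt(d2[seq_len(k)])
  U <- e$vectors[, seq_len(k), drop = FALSE]
  V <- crossprod(X, U) / rep(d, each = ncol(X))
  list(u = U, d = d, v = V)
}

# Element-wise speckled-holdout PRESS for PCA rank selection (Wold-style):
# elements are assigned to folds along diagonals; held-out elements are
# EM-imputed from the rank-k reconstruction and their squared prediction
# error accumulated per k.
pca_press <- function(X, folds = 7, k_max = 20, max_iter = 8, tol = 1e-3) {
  n <- nrow(X)
  p <- ncol(X)
  fold_id <- (outer(seq_len(n), seq_len(p), `+`) %% folds) + 1
  press <- numeric(k_max)
  xsd <- sd(X) + 1e-12
  for (f in seq_len(folds)) {
    M <- which(fold_id == f)
    mi <- ((M - 1) %% n) + 1
    mj <- ((M - 1) %/% n) + 1
    Xw <- X
    Xw[M] <- 0  # start from the column-mean (0) imputation
    for (k in seq_len(k_max)) {
      for (it in seq_len(max_iter)) {
        sv <- svd_wide(Xw, k)
        kk <- length(sv$d)
        Tk <- sv$u * rep(sv$d, each = n)
        newv <- rowSums(Tk[mi, , drop = FALSE] *
                          sv$v[mj, , drop = FALSE])
        delta <- max(abs(newv - Xw[M]))
        Xw[M] <- newv
        if (delta < tol * xsd) break
      }
      press[k] <- press[k] + sum((X[M] - Xw[M])^2)
    }
  }
  press
}

#' Extract PCA features from a block
#'
#' Centers and unit-variance scales the block (zero-variance columns are
#' dropped with a warning), then selects the number of components `k` by
#' 7-fold element-wise speckled-holdout cross-validation: held-out
#' elements are EM-imputed from the rank-k model and `k` minimises the
#' prediction error sum of squares (PRESS), capped at `k_max`.
#' Alternatively (`method = "cumvar"`) the smallest `k` whose cumulative
#' explained variance reaches `cumvar_threshold` is used. When `fit_rows`
#' is given, scaling and loadings are estimated from those rows only
#' (e.g. the calibration set) and applied to all rows, so no validation
#' information leaks into the features.
#'
#' @param b A [block()].
#' @param folds Number of cross-validation folds.
#' @param k_max Maximum number of components considered.
#' @param method `"press"` (default) or `"cumvar"`.
#' @param cumvar_threshold Explained-variance target for
#'   `method = "cumvar"`.
#' @param fit_rows Optional integer row indices used to fit the model.
#' @return Object of class `"pca_features"`: `scores` (all rows x k),
#'   `loadings` (variables x k, orthonormal columns), `k`,
#'   `explained_variance_fraction` (at `k`, on the fit rows), `center`,
#'   `scale`, `kept_cols`, `press` (PRESS per candidate k, when computed).
#' @export
extract_features_pca <- function(b, folds = 7, k_max = 20,
                                 method = c("press", "cumvar"),
                                 cumvar_threshold = 0.90,
                                 fit_rows = NULL) {
  method <- match.arg(method)
  X <- if (inherits(b, "block")) b$matrix else as.matrix(b)
  labels <- if (inherits(b, "block")) b$col_labels else seq_len(ncol(X))
  fit_rows <- fit_rows %||% seq_len(nrow(X))
  if (length(fit_rows) < folds) stop("fewer fit rows than folds")
  sc <- autoscale(X, fit_rows)
  keep <- !sc$zero_var
  if (any(!keep)) {
    warning(sum(!keep), " zero-variance column(s) dropped before PCA")
  }
  Xs <- sc$X[, keep, drop = FALSE]
  Xf <- Xs[fit_rows, , drop = FALSE]
  k_cap <- min(k_max, length(fit_rows) - 1, ncol(Xf))
  sv <- svd_wide(Xf, k_cap)
  k_cap <- min(k_cap, length(sv$d))  # numerical rank can be lower
  evf <- cumsum(sv$d^2) / sum(Xf^2)
  press <- NULL
  if (method == "press") {
    press <- pca_press(Xf, folds = folds, k_max = k_cap)
    k <- which.min(press)
  } else {
    k <- which(evf >= cumvar_threshold)[1]
    if (is.na(k)) k <- k_cap
  }
  V <- sv$v[, seq_len(k), drop = FALSE]
  scores <- Xs %*% V
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, loadings = V, k = k,
                 explained_variance_fraction = evf[k],
                 evf_per_k = evf,
                 center = sc$center[keep], scale = sc$scale[keep],
                 kept_cols = which(keep), col_labels = labels[keep],
                 press = press, method = method),
            class = "pca_features")
}

#' @export
print.pca_features <- function(x, ...) {
  cat(sprintf("<pca_features> k = %d (%s), %.2f%% variance explained\n",
              x$k, x$method, 100 * x$explained_variance_fraction))
  invisible(x)
}

#' Mid-level data fusion
#'
#' Extracts PCA scores per block with [extract_features_pca()] and
#' concatenates them, so the fused width is the sum of the chosen
#' per-block component counts -- far fewer variables than the low-level
#' concatenation of the same blocks.
#'
#' @inheritParams low_level_fuse
#' @inheritParams extract_features_pca
#' @return A `"fused_dataset"` with `level = "mid"`; column provenance
#'   labels are the per-block PC indices, and the per-block
#'   [extract_features_pca()] results are attached as attribute
#'   `"features"`.
#' @export
mid_level_fuse <- function(blocks, pairing = c("by_sample",
                                               "by_sclerotium"),
                           folds = 7, k_max = 20,
                           method = c("press", "cumvar"),
                           cumvar_threshold = 0.90,
                           fit_rows = NULL) {
  pairing <- match.arg(pairing)
  method <- match.arg(method)
  if (inherits(blocks, "block")) blocks <- list(blocks)
  blocks <- match_blocks(blocks, pairing)
  feats <- lapply(blocks, extract_features_pca, folds = folds,
                  k_max = k_max, method = method,
                  cumvar_threshold = cumvar_threshold,
                  fit_rows = fit_rows)
  mats <- lapply(feats, function(f) f$scores)
  prov <- do.call(rbind, lapply(seq_along(blocks), function(j) {
    data.frame(block_id = blocks[[j]]$block_id,
               label = colnames(feats[[j]]$scores),
               stringsAsFactors = FALSE)
  }))
  out <- structure(list(matrix = do.call(cbind, mats),
                        row_meta = fused_row_meta(blocks[[1]], pairing),
                        column_provenance = prov,
                        level = "mid", pairing = pairing),
                   class = "fused_dataset")
  attr(out, "features") <- feats
  out
}
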