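#' Principal component analysis of a spectra matrix
#'
#' Mean-centred singular value decomposition. Loadings carry the sign
#' convention that each vector's largest-magnitude element is positive.
#'
#' @param x A `spectra_matrix` or a samples x variables numeric matrix.
#' @param rank Number of components to keep (`NULL` = full rank).
#' @return A `pca_model`: `mean`, `loadings` (variables x rank), `scores`
#'   (samples x rank), `explained` (variance fractions, non-increasing),
#'   `rank`, `sample_id`.
#' @export
pca_fit <- function(x, rank = NULL) {
  m <- as_feature_matrix(x)
  n <- nrow(m)
  full <- min(n - 1L, ncol(m))
  if (is.null(rank)) rank <- full
  if (rank < 1) abort("`rank` must be >= 1.")
  if (rank > full) {
    warn(sprintf("`rank` reduced from %d to %d (sample/variable limit).", rank, full))
    rank <- full
  }
  mu <- colMeans(m)
  mc <- sweep(m, 2, mu)
  sv <- svd(mc, nu = rank, nv = rank)
  expl <- sv$d^2 / sum(sv$d^2)
  loadings <- sv$v
  scores <- sv$u %*% diag(sv$d[seq_len(rank)], rank)
  for (k in seq_len(rank)) { # sign convention
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  structure(
    list(
      mean = mu, loadings = loadings, scores = scores,
      explained = expl[seq_len(rank)], rank = rank,
      sample_id = rownames(m) %||% as.character(seq_len(n))
    ),
    class = "pca_model"
  )
}

as_feature_matrix <- function(x) {
  if (inherits(x, "spectra_matrix")) {
    return(x$intensities)
  }
  as.matrix(x)
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf(
    "<pca_model> rank %d; explained variance: %s\n",
    x$rank, paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", ")
  ))
  invisible(x)
}

#' @export
tidy.pca_model <- function(x, ...) {
  as_tibble(as.data.frame(x$scores)) %>%
    setNames(paste0("PC", seq_len(x$rank))) %>%
    mutate(sample_id = x$sample_id, .before = 1)
}

#' @export
glance.pca_model <- function(x, ...) {
  tibble(rank = x$rank, explained_total = sum(x$explained))
}

#' @param object A `pca_model`.
#' @param data Optional metadata tibble with `sample_id` to join for
#'   aesthetics.
#' @param colour_by,shape_by Metadata columns for aesthetics.
#' @param ... Unused.
#' @rdname pca_fit
#' @export
autoplot.pca_model <- function(object, data = NULL, colour_by = "genotype",
                               shape_by = NULL, ...) {
  df <- tidy(object)
  if (!is.null(data)) df <- left_join(df, data, by = "sample_id")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  aes_extra <- list()
  if (!is.null(data) && colour_by %in% names(df)) {
    p <- p + ggplot2::aes(colour = factor(.data[[colour_by]]))
  }
  if (!is.null(data) && !is.null(shape_by) && shape_by %in% names(df)) {
    p <- p + ggplot2::aes(shape = factor(.data[[shape_by]]))
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained[2]),
      colour = colour_by, shape = shape_by
    )
}

#' Bi-cross-validated rank selection
#'
#' Owen-Perry hold-out scheme for choosing how many principal components
#' capture systematic rather than noise variation: the rows and columns are
#' partitioned into folds; for every held-out row-block x column-block `A`,
#' the complementary blocks `B` (same rows), `C` (same columns) and `D`
#' (neither) predict it as `B D_k^+ C` with `D_k` the rank-k truncated SVD
#' of `D`. The rank minimising the mean squared prediction error is
#' returned; rank 0 (mean-only prediction) is allowed and is selected for
#' structureless data.
#'
#' @param x A `spectra_matrix` or numeric matrix.
#' @param row_folds,col_folds Number of folds (>= 2 each).
#' @param max_rank Largest candidate rank.
#' @param seed Seed for the random fold assignment.
#' @return Selected rank (integer, possibly 0) with attribute `errors`, the
#'   per-rank mean squared prediction errors.
#' @export
bcv_rank <- function(x, row_folds = 2, col_folds = 2, max_rank = 10,
                     seed = 1) {
  m <- as_feature_matrix(x)
  n <- nrow(m)
  p <- ncol(m)
  if (row_folds < 2 || col_folds < 2) abort("Folds must be >= 2.")
  if (max_rank < 1) abort("`max_rank` must be >= 1.")
  lim <- min(n - ceiling(n / row_folds) - 1L, p - ceiling(p / col_folds))
  if (max_rank > lim) {
    warn(sprintf("`max_rank` reduced from %d to %d (block size).", max_rank, lim))
    max_rank <- lim
  }
  set.seed(seed)
  rf <- sample(rep_len(seq_len(row_folds), n))
  cf <- sample(rep_len(seq_len(col_folds), p))
  errs <- numeric(max_rank + 1L) # index k+1 = rank k
  cnt <- 0
  for (ri in seq_len(row_folds)) {
    for (ci in seq_len(col_folds)) {
      hr <- rf == ri
      hc <- cf == ci
      # centre columns using only the training rows
      mu <- colMeans(m[!hr, , drop = FALSE])
      mc <- sweep(m, 2, mu)
      A <- mc[hr, hc, drop = FALSE]
      B <- mc[hr, !hc, drop = FALSE]
      Cm <- mc[!hr, hc, drop = FALSE]
      D <- mc[!hr, !hc, drop = FALSE]
      sv <- svd(D)
      errs[1] <- errs[1] + sum(A^2)
      for (k in seq_len(max_rank)) {
        dkp <- sv$v[, seq_len(k), drop = FALSE] %*%
          ((1 / sv$d[seq_len(k)]) * t(sv$u[, seq_len(k), drop = FALSE]))
        pred <- B %*% dkp %*% Cm
        errs[k + 1L] <- errs[k + 1L] + sum((A - pred)^2)
      }
      cnt <- cnt + length(A)
    }
  }
  errs <- errs / cnt
  k_sel <- which.min(errs) - 1L
  structure(as.integer(k_sel), errors = setNames(errs, 0:max_rank))
}

#' Maximum margin criterion discriminant analysis
#'
#' Supervised projection maximising between-class scatter while minimising
#' within-class scatter: the discriminant loadings are the top eigenvectors
#' of `S_b - S_w`, where `S_b = sum_c n_c (mu_c - mu)(mu_c - mu)' / n` and
#' `S_w = sum_c sum_{i in c} (x_i - mu_c)(x_i - mu_c)' / n`. Unlike Fisher
#' LDA no matrix inversion is needed, so it is stable when within-class
#' scatter is poorly conditioned.
#'
#' @param features Samples x variables matrix (typically PCA scores) or a
#'   `spectra_matrix`.
#' @param labels Class label per sample (>= 2 classes, each with >= 2
#'   samples).
#' @param n_components Number of discriminant axes (default
#'   `n_classes - 1`).
#' @return An `mmc_model`: `loadings`, `scores`, `eigenvalues`, `S_b`,
#'   `S_w`, `mean`, `labels`, `classes`.
#' @export
mmc <- function(features, labels, n_components = NULL) {
  m <- as_feature_matrix(features)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(m))
  classes <- sort(unique(labels))
  if (length(classes) < 2) abort("MMC needs at least 2 classes.")
  cls_n <- table(labels)
  if (any(cls_n < 2)) {
    abort(paste0(
      "Classes with a single sample: ",
      toString(names(cls_n)[cls_n < 2]), " (within-class scatter undefined)."
    ))
  }
  n <- nrow(m)
  p <- ncol(m)
  mu <- colMeans(m)
  S_b <- matrix(0, p, p)
  S_w <- matrix(0, p, p)
  for (cl in classes) {
    mi <- m[labels == cl, , drop = FALSE]
    mu_c <- colMeans(mi)
    d <- mu_c - mu
    S_b <- S_b + nrow(mi) * tcrossprod(d)
    mc <- sweep(mi, 2, mu_c)
    S_w <- S_w + crossprod(mc)
  }
  S_b <- S_b / n
  S_w <- S_w / n
  if (is.null(n_components)) n_components <- length(classes) - 1L
  n_components <- min(n_components, p)
  eg <- eigen(S_b - S_w, symmetric = TRUE)
  W <- eg$vectors[, seq_len(n_components), drop = FALSE]
  for (k in seq_len(ncol(W))) {
    j <- which.max(abs(W[, k]))
    if (W[j, k] < 0) W[, k] <- -W[, k]
  }
  scores <- sweep(m, 2, mu) %*% W
  structure(
    list(
      loadings = W, scores = scores,
      eigenvalues = eg$values[seq_len(n_components)],
      S_b = S_b, S_w = S_w, mean = mu,
      labels = labels, classes = classes,
      sample_id = rownames(m) %||% as.character(seq_len(n))
    ),
    class = "mmc_model"
  )
}

#' @export
print.mmc_model <- function(x, ...) {
  cat(sprintf(
    "<mmc_model> %d classes (%s), %d discriminant axes\n",
    length(x$classes), toString(x$classes), ncol(x$loadings)
  ))
  invisible(x)
}

#' @export
tidy.mmc_model <- function(x, ...) {
  as_tibble(as.data.frame(x$scores)) %>%
    setNames(paste0("MMC", seq_len(ncol(x$scores)))) %>%
    mutate(sample_id = x$sample_id, label = x$labels, .before = 1)
}

# quadratic discriminant with diagonal shrinkage, fit in discriminant space
qda_fit <- function(z, labels, shrinkage = 0.1, ridge = 1e-8) {
  classes <- sort(unique(labels))
  fits <- lapply(classes, function(cl) {
    zi <- z[labels == cl, , drop = FALSE]
    mu <- colMeans(zi)
    S <- stats::cov(zi)
    S <- (1 - shrinkage) * S + shrinkage * diag(diag(S), ncol(z))
    S <- S + ridge * mean(diag(S)) * diag(ncol(z))
    list(mu = mu, S = S, Sinv = solve(S), logdet = determinant(S)$modulus[1])
  })
  names(fits) <- classes
  fits
}

qda_predict <- function(fits, z) {
  d <- sapply(fits, function(f) {
    dev <- sweep(z, 2, f$mu)
    rowSums((dev %*% f$Sinv) * dev) + f$logdet
  })
  if (is.null(dim(d))) d <- matrix(d, nrow = 1, dimnames = list(NULL, names(fits)))
  colnames(d)[max.col(-d, ties.method = "first")]
}

#' Leave-mouse-out cross-validated discrimination
#'
#' Withholds all spectra of one animal at a time; on the training animals it
#' (optionally) selects features by one-way ANOVA at p < 0.05, reduces by
#' PCA, fits an MMC model, and fits a quadratic classifier (per-class
#' covariance with diagonal shrinkage) in the discriminant space. Held-out
#' spectra are projected and assigned to the class with the smallest
#' quadratic distance `(z - mu_c)' Sigma_c^-1 (z - mu_c) + ln det Sigma_c`.
#' Because selection, reduction and the model are refit inside every fold,
#' no information from the withheld animal leaks into its own prediction.
#'
#' @param features Samples x variables matrix or `spectra_matrix`.
#' @param labels Class label per sample.
#' @param mouse_ids Animal id per sample (the CV unit).
#' @param pca_rank PCA rank used before MMC (capped at
#'   `n_train - n_classes`); `NULL` skips the PCA step.
#' @param select_features If `TRUE`, keep only variables with training-fold
#'   ANOVA p < 0.05 (all variables kept when none pass).
#' @param shrinkage QDA covariance shrinkage toward its diagonal, in
#'   \[0, 1\].
#' @param n_components Number of MMC axes (default `n_classes - 1`).
#' @return A `cv_report`: `confusion` (true x predicted), `accuracy`,
#'   `predicted_variance`, `assignments` (tibble), `skipped_folds`.
#' @export
leave_mouse_out_cv <- function(features, labels, mouse_ids, pca_rank = NULL,
                               select_features = FALSE, shrinkage = 0.1,
                               n_components = NULL) {
  m <- as_feature_matrix(features)
  labels <- as.character(labels)
  mouse_ids <- as.character(mouse_ids)
  stopifnot(length(labels) == nrow(m), length(mouse_ids) == nrow(m))
  classes <- sort(unique(labels))
  per_class_mice <- tapply(mouse_ids, labels, function(x) length(unique(x)))
  if (any(per_class_mice < 2)) {
    abort("Every class needs spectra from at least 2 mice.")
  }
  # deterministic regardless of input order
  ord <- order(mouse_ids, rownames(m) %||% seq_len(nrow(m)))
  m <- m[ord, , drop = FALSE]
  labels <- labels[ord]
  mouse_ids <- mouse_ids[ord]
  folds <- unique(mouse_ids)
  assignments <- list()
  skipped <- character()
  rss <- 0
  tss <- 0
  for (mo in folds) {
    te <- mouse_ids == mo
    tr_lab <- labels[!te]
    if (length(unique(tr_lab)) < length(classes) || any(table(tr_lab) < 2)) {
      warn(sprintf("Fold %s skipped: a class is missing/degenerate in training.", mo))
      skipped <- c(skipped, mo)
      next
    }
    Xtr <- m[!te, , drop = FALSE]
    Xte <- m[te, , drop = FALSE]
    if (select_features) {
      av <- anova_f(Xtr, tr_lab)
      keep <- which(av$p < 0.05)
      if (length(keep) >= 2) {
        Xtr <- Xtr[, keep, drop = FALSE]
        Xte <- Xte[, keep, drop = FALSE]
      }
    }
    if (!is.null(pca_rank)) {
      r <- min(pca_rank, nrow(Xtr) - length(classes), ncol(Xtr))
      pc <- pca_fit(Xtr, rank = max(1L, r))
      Ztr <- pc$scores
      Zte <- sweep(Xte, 2, pc$mean) %*% pc$loadings
      back <- pc$loadings # orthonormal map into the reduced space
      mu_tr <- pc$mean
    } else {
      mu_tr <- colMeans(Xtr)
      Ztr <- sweep(Xtr, 2, mu_tr)
      Zte <- sweep(Xte, 2, mu_tr)
      back <- diag(ncol(Xtr))
    }
    mm <- mmc(Ztr, tr_lab, n_components = n_components)
    Dtr <- mm$scores
    Dte <- sweep(Zte, 2, mm$mean) %*% mm$loadings
    fits <- qda_fit(Dtr, tr_lab, shrinkage = shrinkage)
    pred <- qda_predict(fits, Dte)
    # predicted variance: held-out SS captured by the training discriminant
    # space (full-space direction = PCA loadings %*% MMC loadings, orthonormal)
    Wfull <- back %*% mm$loadings
    Xte_c <- sweep(Xte, 2, mu_tr)
    proj <- (Xte_c %*% Wfull) %*% t(Wfull)
    rss <- rss + sum((Xte_c - proj)^2)
    tss <- tss + sum(Xte_c^2)
    assignments[[mo]] <- tibble(
      mouse_id = mo,
      sample_id = rownames(Xte) %||% paste0(mo, "_", seq_len(nrow(Xte))),
      true = labels[te], predicted = pred
    )
  }
  if (!length(assignments)) abort("All folds were skipped.")
  asg <- bind_rows(assignments)
  confusion <- table(
    factor(asg$true, levels = classes),
    factor(asg$predicted, levels = classes),
    dnn = c("true", "predicted")
  )
  structure(
    list(
      confusion = confusion,
      accuracy = sum(diag(confusion)) / sum(confusion),
      predicted_variance = 1 - rss / tss,
      assignments = asg,
      skipped_folds = skipped
    ),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "<cv_report> leave-mouse-out accuracy %.3f, predicted variance %.3f\n",
    x$accuracy, x$predicted_variance
  ))
  print(x$confusion)
  invisible(x)
}

#' @export
tidy.cv_report <- function(x, ...) x$assignments

#' @export
glance.cv_report <- function(x, ...) {
  tibble(
    accuracy = x$accuracy,
    predicted_variance = x$predicted_variance,
    n_folds = length(unique(x$assignments$mouse_id)),
    n_skipped = length(x$skipped_folds)
  )
}

#' @param object A `cv_report`.
#' @param ... Unused.
#' @rdname leave_mouse_out_cv
#' @export
autoplot.cv_report <- function(object, ...) {
  df <- as.data.frame(object$confusion)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$predicted, y = .data$true, fill = .data$Freq
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = sprintf("accuracy = %.2f", object$accuracy))
}
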