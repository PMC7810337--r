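#' Fit a DAPC model (PCA followed by linear discriminant analysis)
#'
#' Two-step discriminant analysis of principal components: genotypes are
#' imputed and centered with the training means, projected onto the top
#' `n_pc` principal components, and a linear discriminant classifier with a
#' pooled within-class covariance is fit in that reduced space. The pooled
#' covariance is regularized by `ridge` times the mean of its diagonal
#' (adegenet's tool handles near-singularity silently; here it is explicit).
#' Class priors are proportional to training class sizes.
#'
#' @param ds a [geno_dataset] used for training.
#' @param labels class (breed) labels, one per sample; defaults to
#'   `ds$fam$breed`.
#' @param n_pc number of principal components retained for the LDA step;
#'   must be at most `n_train - 1` and at most the number of loci.
#' @param ridge regularization of the pooled within-class covariance as a
#'   fraction of its mean diagonal; 0 disables regularization.
#' @return object of class `dapc_model`.
#' @export
fit_dapc <- function(ds, labels = ds$fam$breed, n_pc, ridge = 1e-6) {
  x_raw <- ds$calls
  storage.mode(x_raw) <- "double"
  labels <- as.character(labels)
  n <- nrow(x_raw)
  if (length(labels) != n) stop("labels length must match samples")
  tab <- table(labels)
  if (any(tab < 2L)) {
    stop("every class needs >= 2 training samples; offending: ",
         names(tab)[tab < 2L][1L])
  }
  if (n_pc > min(n - 1L, ncol(x_raw))) {
    stop("n_pc must be <= min(n_train - 1, n_loci) = ",
         min(n - 1L, ncol(x_raw)))
  }
  mu <- colMeans(x_raw, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(x_raw))
  if (length(idx)) x_raw[idx] <- mu[(idx - 1L) %/% n + 1L]
  x <- sweep(x_raw, 2L, mu, "-")
  pc <- thin_pca(x, n_pc)
  n_pc_eff <- ncol(pc$scores)
  lda <- fit_lda_gaussian(pc$scores, labels, ridge)
  model <- structure(
    list(snp_id = ds$map$snp_id,
         pca_center = mu,
         pca_loadings = pc$loadings,
         n_pc = n_pc_eff,
         explained_variance_share = sum(pc$d^2) / pc$total_var,
         lda = lda,
         class_labels = lda$classes,
         class_priors = lda$priors),
    class = "dapc_model")
  model$training_assignment <- predict_scores(model, pc$scores)
  model$training_labels <- labels
  model
}

# Gaussian LDA with shared (pooled, ridge-regularized) covariance on an
# already reduced score matrix. Classes are kept in alphabetical order so
# posterior ties resolve deterministically to the first label.
fit_lda_gaussian <- function(scores, labels, ridge) {
  classes <- sort(unique(labels))
  p <- ncol(scores)
  n <- nrow(scores)
  means <- matrix(0, length(classes), p)
  for (ci in seq_along(classes)) {
    means[ci, ] <- colMeans(scores[labels == classes[ci], , drop = FALSE])
  }
  w <- matrix(0, p, p)
  for (ci in seq_along(classes)) {
    xc <- sweep(scores[labels == classes[ci], , drop = FALSE],
                2L, means[ci, ], "-")
    w <- w + crossprod(xc)
  }
  w <- w / (n - length(classes))
  if (ridge > 0) w <- w + diag(ridge * mean(diag(w)), p)
  w_inv <- tryCatch(chol2inv(chol(w)), error = function(e) {
    stop("singular within-class covariance; increase `ridge` ",
         "(got ridge = ", ridge, ")")
  })
  priors <- as.numeric(table(factor(labels, levels = classes))) / n
  # between-class covariance for the discriminant axes
  gm <- colMeans(scores)
  b <- matrix(0, p, p)
  for (ci in seq_along(classes)) {
    d <- means[ci, ] - gm
    b <- b + priors[ci] * tcrossprod(d)
  }
  ev <- eigen(w_inv %*% b)
  n_axes <- min(length(classes) - 1L, p)
  axes <- Re(ev$vectors[, seq_len(n_axes), drop = FALSE])
  list(classes = classes, means = means, w = w, w_inv = w_inv,
       priors = priors, axes = axes,
       axis_eigenvalues = Re(ev$values[seq_len(n_axes)]))
}

# posterior over classes for rows of a score matrix (linear discriminant
# shortcut: the shared quadratic term cancels in the softmax)
lda_posterior <- function(lda, scores) {
  k <- length(lda$classes)
  delta <- matrix(0, nrow(scores), k)
  for (ci in seq_len(k)) {
    mci <- lda$means[ci, ]
    wm <- lda$w_inv %*% mci
    delta[, ci] <- scores %*% wm - 0.5 * drop(crossprod(mci, wm)) +
      log(lda$priors[ci])
  }
  delta <- delta - apply(delta, 1L, max)
  post <- exp(delta)
  post <- post / rowSums(post)
  colnames(post) <- lda$classes
  post
}

predict_scores <- function(model, scores) {
  post <- lda_posterior(model$lda, scores)
  pred <- model$class_labels[apply(post, 1L, which.max)]
  list(predicted = pred, posterior = post,
       discriminant_scores = scores %*% model$lda$axes)
}

#' Classify samples with a trained DAPC model
#'
#' New samples are matched to the model's locus set by SNP id (loci absent
#' from `ds` are imputed at the training means), centered with the TRAINING
#' means, projected with the TRAINING loadings and classified with the
#' stored discriminants. Samples without a single non-missing overlapping
#' call carry no information and receive the class priors as posterior.
#'
#' @param model a `dapc_model` from [fit_dapc()].
#' @param ds a [geno_dataset] of samples to classify.
#' @return data.frame with `sample_id`, `true_breed`, `predicted_breed` and
#'   one posterior column per class (`post_<class>`), rows summing to 1.
#' @export
predict_membership <- function(model, ds) {
  hit <- match(model$snp_id, ds$map$snp_id)
  if (all(is.na(hit))) stop("zero overlapping loci between model and data")
  n <- n_samples(ds)
  m <- length(model$snp_id)
  x <- matrix(NA_real_, n, m)
  x[, !is.na(hit)] <- ds$calls[, hit[!is.na(hit)], drop = FALSE]
  no_info <- rowSums(!is.na(x)) == 0L
  idx <- which(is.na(x))
  if (length(idx)) x[idx] <- model$pca_center[(idx - 1L) %/% n + 1L]
  x <- sweep(x, 2L, model$pca_center, "-")
  scores <- x %*% model$pca_loadings
  pr <- predict_scores(model, scores)
  post <- pr$posterior
  if (any(no_info)) {
    post[no_info, ] <- matrix(model$class_priors, sum(no_info),
                              length(model$class_labels), byrow = TRUE)
    pr$predicted[no_info] <-
      model$class_labels[apply(post[no_info, , drop = FALSE], 1L, which.max)]
  }
  out <- data.frame(sample_id = ds$fam$sample_id,
                    true_breed = ds$fam$breed,
                    predicted_breed = pr$predicted,
                    stringsAsFactors = FALSE)
  colnames(post) <- paste0("post_", model$class_labels)
  cbind(out, as.data.frame(post))
}

#' @export
print.dapc_model <- function(x, ...) {
  cat("DAPC model:", length(x$class_labels), "classes,", x$n_pc,
      "PCs retained (", sprintf("%.1f%%", 100 * x$explained_variance_share),
      "of variance )\n")
  invisible(x)
}

#' Select the number of retained PCs by repeated stratified cross-validation
#'
#' For each repetition the samples are split into `folds` stratified by
#' class; within each training fold a single PCA at the largest candidate is
#' computed and every candidate `n_pc` is evaluated by truncation, scoring
#' the proportion of held-out samples assigned to their true class. The
#' candidate with the highest mean success is selected (smallest on ties).
#' Classes smaller than the fold count degrade gracefully: their few samples
#' simply appear in fewer folds (a warning is issued).
#'
#' @param ds a [geno_dataset].
#' @param labels class labels (default `ds$fam$breed`).
#' @param folds number of cross-validation folds.
#' @param repetitions number of random repetitions of the fold split.
#' @param max_pc cap on the candidate grid.
#' @param grid_step spacing of the default candidate grid
#'   `seq(grid_step, max_pc, grid_step)`.
#' @param grid explicit candidate vector overriding `max_pc`/`grid_step`.
#' @param ridge passed to the LDA step.
#' @param seed integer seed.
#' @return object of class `pc_selection_report`: data.frame `cv`
#'   (`n_pc`, `mean_success`, `sd_success`), `selected_n_pc`.
#' @export
select_n_pc_cv <- function(ds, labels = ds$fam$breed, folds = 10L,
                           repetitions = 30L, max_pc = 259L, grid_step = 10L,
                           grid = NULL, ridge = 1e-6, seed = 1L) {
  labels <- as.character(labels)
  n <- n_samples(ds)
  limit <- min(max_pc, n - ceiling(n / folds) - 1L, n_loci(ds))
  if (is.null(grid)) grid <- seq(grid_step, max_pc, by = grid_step)
  grid <- sort(unique(pmin(grid, limit)))
  stopifnot(length(grid) >= 1L, all(grid >= 1L))
  tab <- table(labels)
  if (any(tab < folds)) {
    warning("class(es) smaller than the fold count (",
            paste(names(tab)[tab < folds], collapse = ", "),
            "); their samples appear in fewer folds")
  }
  x_all <- ds$calls
  storage.mode(x_all) <- "double"
  set.seed(as.integer(seed))
  succ <- array(NA_real_, c(repetitions, folds, length(grid)))
  for (rep_i in seq_len(repetitions)) {
    fold_of <- stratified_folds(labels, folds)
    for (fd in seq_len(folds)) {
      test <- which(fold_of == fd)
      if (!length(test)) next
      train <- which(fold_of != fd)
      res <- eval_pc_grid(x_all, labels, train, test, grid, ridge)
      succ[rep_i, fd, ] <- res
    }
  }
  mean_succ <- apply(succ, 3L, mean, na.rm = TRUE)
  sd_succ <- apply(succ, 3L, stats::sd, na.rm = TRUE)
  cv <- data.frame(n_pc = grid, mean_success = mean_succ,
                   sd_success = sd_succ)
  structure(list(cv = cv,
                 selected_n_pc = grid[which.max(mean_succ)]),
            class = "pc_selection_report")
}

#' @export
print.pc_selection_report <- function(x, ...) {
  cat("PC selection by stratified CV; selected n_pc =", x$selected_n_pc, "\n")
  print(x$cv, row.names = FALSE)
  invisible(x)
}

stratified_folds <- function(labels, folds) {
  fold_of <- integer(length(labels))
  for (cl in unique(labels)) {
    i <- which(labels == cl)
    fold_of[i] <- sample(rep(seq_len(folds), length.out = length(i)))
  }
  fold_of
}

# Train-once evaluate-all-candidates helper: one PCA at max(grid) PCs on the
# training rows, candidate n_pc evaluated by truncating scores/loadings.
# Returns held-out assignment success per candidate.
eval_pc_grid <- function(x_all, labels, train, test, grid, ridge) {
  xtr <- x_all[train, , drop = FALSE]
  mu <- colMeans(xtr, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(xtr))
  if (length(idx)) xtr[idx] <- mu[(idx - 1L) %/% nrow(xtr) + 1L]
  xtr <- sweep(xtr, 2L, mu, "-")
  p_max <- min(max(grid), length(train) - 1L)
  pc <- thin_pca(xtr, p_max)
  xte <- x_all[test, , drop = FALSE]
  idx <- which(is.na(xte))
  if (length(idx)) xte[idx] <- mu[(idx - 1L) %/% nrow(xte) + 1L]
  xte <- sweep(xte, 2L, mu, "-")
  te_scores <- xte %*% pc$loadings
  ltr <- labels[train]
  lte <- labels[test]
  vapply(grid, function(np) {
    np <- min(np, ncol(pc$scores))
    lda <- fit_lda_gaussian(pc$scores[, seq_len(np), drop = FALSE], ltr,
                            ridge)
    post <- lda_posterior(lda, te_scores[, seq_len(np), drop = FALSE])
    pred <- lda$classes[apply(post, 1L, which.max)]
    mean(pred == lte)
  }, numeric(1))
}
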