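#' Log-likelihood of the admixture model
#'
#' Under the admixture model each individual i draws its two gene copies at
#' SNP j independently with allele-1 probability
#' \eqn{p_{ij} = \sum_k q_{ik} f_{kj}}, so the log-likelihood is
#' \deqn{\ell(Q,F) = \sum_{ij} g_{ij} \log p_{ij} + (2 - g_{ij}) \log(1 - p_{ij})}
#' with missing genotypes skipped. Probabilities are clamped to
#' \[eps, 1 - eps\] before taking logs.
#'
#' @param g integer dosage matrix (n x m), values 0, 1, 2 or `NA`.
#' @param q ancestry proportion matrix (n x K), rows summing to 1.
#' @param f ancestral allele-frequency matrix (K x m).
#' @param eps clamping constant.
#' @return scalar log-likelihood.
#' @export
admixture_loglik <- function(g, q, f, eps = 1e-6) {
  if (nrow(g) != nrow(q) || ncol(g) != ncol(f) || ncol(q) != nrow(f)) {
    stop("dimension mismatch between g (", nrow(g), "x", ncol(g),
         "), q (", nrow(q), "x", ncol(q), ") and f (",
         nrow(f), "x", ncol(f), ")")
  }
  p <- pmin(pmax(q %*% f, eps), 1 - eps)
  w <- !is.na(g)
  gm <- ifelse(w, g, 0)
  sum(gm * log(p)) - sum(gm * log(1 - p)) + sum(2 * w * log(1 - p))
}

#' Fit the admixture model by EM
#'
#' Alternating expectation-maximization updates of the ancestry proportions Q
#' and ancestral allele frequencies F; each sweep has the EM ascent property,
#' so the log-likelihood never decreases. Several random restarts guard
#' against local optima; the fit with the best final log-likelihood is kept.
#' Q is initialized from symmetric Dirichlet draws and F from the observed
#' allele frequencies perturbed by noise.
#'
#' @param g integer dosage matrix (n x m) with `NA` for missing calls.
#' @param k number of ancestral populations (K >= 1).
#' @param seed integer seed driving initialization.
#' @param tol relative log-likelihood gain below which iteration stops.
#' @param max_iter maximum EM sweeps per restart.
#' @param n_restarts number of random restarts.
#' @param eps allele-frequency clamp.
#' @return object of class `admixture_fit`: `K`, `Q` (n x K), `F` (K x m),
#'   `loglik`, `loglik_trace`, `n_iter`, `converged`.
#' @export
admixture_fit <- function(g, k, seed = 1L, tol = 1e-6, max_iter = 2000L,
                          n_restarts = 1L, eps = 1e-6) {
  stopifnot(k >= 1L, n_restarts >= 1L)
  g <- as.matrix(g)
  n <- nrow(g)
  m <- ncol(g)
  w <- !is.na(g)
  gm <- ifelse(w, as.numeric(g), 0)
  g2 <- 2 * w - gm                       # (2 - g), zero where missing
  m_i <- 2 * rowSums(w)                  # gene copies observed per sample
  if (any(m_i == 0)) stop("sample with zero non-missing genotypes")
  phat <- colSums(gm) / pmax(colSums(2 * w), 1)

  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(as.integer(seed) + (r - 1L) * 1009L)
    q <- matrix(stats::rgamma(n * k, shape = 1), n, k)
    q <- q / rowSums(q)
    f <- matrix(rep(phat, each = k), k, m) +
      matrix(stats::runif(k * m, -0.1, 0.1), k, m)
    f <- pmin(pmax(f, eps), 1 - eps)
    if (k == 1L) q[] <- 1

    ll_trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    it <- 0L
    while (it < max_iter) {
      it <- it + 1L
      p <- pmin(pmax(q %*% f, eps), 1 - eps)
      u <- gm / p                        # g / p   (0 where missing)
      v <- g2 / (1 - p)                  # (2-g) / (1-p)
      # F update: expected allele-1 counts over expected total counts per k
      num_f <- f * crossprod(q, u)       # K x m
      den_f <- (1 - f) * crossprod(q, v)
      tot <- num_f + den_f
      f_new <- ifelse(tot > 0, num_f / tot, f)
      f_new <- pmin(pmax(f_new, eps), 1 - eps)
      # Q update: expected ancestry-k gene copies / observed copies
      q_new <- q * (u %*% t(f) + v %*% t(1 - f)) / m_i
      q_new <- q_new / rowSums(q_new)
      q <- q_new
      f <- f_new
      ll <- admixture_loglik_known(gm, g2, q, f, eps)
      ll_trace <- c(ll_trace, ll)
      if (is.finite(ll_old) && (ll - ll_old) < tol * (abs(ll_old) + 1)) {
        converged <- TRUE
        break
      }
      ll_old <- ll
    }
    fit <- list(K = as.integer(k), Q = q, F = f,
                loglik = ll_trace[length(ll_trace)],
                loglik_trace = ll_trace, n_iter = it, converged = converged)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  structure(best, class = "admixture_fit")
}

# loglik with precomputed gm = g (0 for NA) and g2 = 2 - g (0 for NA)
admixture_loglik_known <- function(gm, g2, q, f, eps) {
  p <- pmin(pmax(q %*% f, eps), 1 - eps)
  sum(gm * log(p)) + sum(g2 * log(1 - p))
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat("admixture fit: K =", x$K, "| loglik =", format(x$loglik),
      "|", x$n_iter, "iterations",
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' Choose the number of ancestries by entry-masking cross-validation
#'
#' Non-missing genotype entries are partitioned into `folds` folds; for each
#' fold and each K the masked entries are treated as missing, the model is
#' refit, and the prediction error is the mean squared difference between the
#' held-out genotype and its expected dosage \eqn{2 \sum_k q_{ik} f_{kj}}.
#' Fold errors are averaged per K; the K with the smallest mean error wins,
#' with ties going to the smallest K.
#'
#' @param g integer dosage matrix with `NA` for missing calls.
#' @param k_range candidate K values (default 2:10).
#' @param folds number of cross-validation folds.
#' @param seed integer seed (fold assignment and fit initialization).
#' @param tol,max_iter,n_restarts fitting controls passed to
#'   [admixture_fit()]; the defaults here are looser than the fitting
#'   defaults because each fold only needs the error surface, not a polished
#'   fit.
#' @return object of class `k_selection_report`: data.frame `cv` with one row
#'   per K (`K`, `cv_error`) and `selected_K`.
#' @export
select_k_cv <- function(g, k_range = 2:10, folds = 10L, seed = 1L,
                        tol = 1e-5, max_iter = 200L, n_restarts = 1L) {
  stopifnot(length(k_range) >= 1L, folds >= 2L)
  k_range <- sort(unique(as.integer(k_range)))
  g <- as.matrix(g)
  idx <- which(!is.na(g))
  set.seed(as.integer(seed))
  fold_of <- sample(rep(seq_len(folds), length.out = length(idx)))
  err <- matrix(NA_real_, folds, length(k_range))
  for (fd in seq_len(folds)) {
    mask <- idx[fold_of == fd]
    if (!length(mask)) stop("fold ", fd, " has zero masked entries")
    gtr <- g
    gtr[mask] <- NA_integer_
    for (ki in seq_along(k_range)) {
      fit <- admixture_fit(gtr, k_range[ki],
                           seed = as.integer(seed) + 131L * fd + ki,
                           tol = tol, max_iter = max_iter,
                           n_restarts = n_restarts)
      pred <- 2 * (fit$Q %*% fit$F)
      err[fd, ki] <- mean((g[mask] - pred[mask])^2)
    }
  }
  cv <- data.frame(K = k_range, cv_error = colMeans(err))
  structure(list(cv = cv,
                 selected_K = k_range[which.min(cv$cv_error)]),
            class = "k_selection_report")
}

#' @export
print.k_selection_report <- function(x, ...) {
  cat("K selection by entry-masking CV; selected K =", x$selected_K, "\n")
  print(x$cv, row.names = FALSE)
  invisible(x)
}

#' Align ancestry labels of one Q matrix to a reference
#'
#' The admixture likelihood is invariant to permutations of the K labels, so
#' estimated Q matrices are only comparable to a reference after relabeling.
#' For K <= 8 all permutations are searched; the one minimizing the mean
#' absolute difference is applied.
#'
#' @param q estimated ancestry matrix (n x K).
#' @param q_ref reference ancestry matrix (n x K).
#' @return list with `Q` (the relabeled matrix), `perm` (applied column
#'   permutation) and `mae` (mean absolute error after alignment).
#' @export
match_ancestry_labels <- function(q, q_ref) {
  k <- ncol(q)
  if (k != ncol(q_ref)) stop("K differs between q and q_ref")
  if (k > 8L) stop("label alignment implemented for K <= 8")
  perms <- all_permutations(k)
  best_mae <- Inf
  best_perm <- seq_len(k)
  for (i in seq_len(nrow(perms))) {
    mae <- mean(abs(q[, perms[i, ], drop = FALSE] - q_ref))
    if (mae < best_mae) {
      best_mae <- mae
      best_perm <- perms[i, ]
    }
  }
  list(Q = q[, best_perm, drop = FALSE], perm = best_perm, mae = best_mae)
}

all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(k - 1L)
  out <- matrix(0L, 0L, k)
  for (pos in seq_len(k)) {
    out <- rbind(out, cbind(sub[, seq_len(pos - 1L), drop = FALSE], k,
                            sub[, seq(pos, k - 1L)[seq_len(k - pos)],
                                drop = FALSE]))
  }
  out
}

#' Write admixture matrices in the conventional .Q/.P layout
#'
#' @param fit an `admixture_fit`.
#' @param path_prefix files `<prefix>.Q` (samples x K) and `<prefix>.P`
#'   (SNPs x K) are written, whitespace-delimited without headers.
#' @return invisibly, the files written.
#' @export
write_admixture <- function(fit, path_prefix) {
  qf <- paste0(path_prefix, ".Q")
  pf <- paste0(path_prefix, ".P")
  utils::write.table(format(fit$Q, digits = 6), qf, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(format(t(fit$F), digits = 6), pf, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(qf, pf))
}

#' Mean ancestry proportions per breed
#'
#' @param fit an `admixture_fit`.
#' @param breeds character vector of breed labels, one per sample (row of Q).
#' @return data.frame with one row per breed and one column per ancestry.
#' @export
breed_mean_q <- function(fit, breeds) {
  agg <- stats::aggregate(fit$Q, by = list(breed = breeds), FUN = mean)
  names(agg)[-1L] <- paste0("K", seq_len(fit$K))
  agg
}
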