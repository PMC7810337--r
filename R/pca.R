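#' Standardize a genotype matrix for PCA
#'
#' Missing calls are imputed with the per-SNP mean dosage, columns are then
#' mean-centered. Unit-variance scaling is off by default (PCA on the raw
#' centered dosage scale). Columns that are monomorphic after imputation
#' carry no information and are dropped.
#'
#' @param ds a [geno_dataset] (normally after [apply_qc()]).
#' @param scale if `TRUE`, also divide each column by its standard deviation.
#' @return list with `matrix` (centered numeric matrix), `means` (per-kept-SNP
#'   mean dosages), `kept` (SNP ids of retained columns) and `dropped`
#'   (SNP ids of monomorphic columns).
#' @export
standardize_genotypes <- function(ds, scale = FALSE) {
  g <- ds$calls
  storage.mode(g) <- "double"
  n_obs <- colSums(!is.na(g))
  if (any(n_obs == 0L)) {
    stop("SNP entirely missing: ", ds$map$snp_id[which(n_obs == 0L)[1L]])
  }
  mu <- colMeans(g, na.rm = TRUE)
  idx <- which(is.na(g))
  if (length(idx)) g[idx] <- mu[(idx - 1L) %/% nrow(g) + 1L]
  v <- apply(g, 2L, stats::var)
  mono <- v == 0
  x <- sweep(g[, !mono, drop = FALSE], 2L, mu[!mono], "-")
  if (scale) x <- sweep(x, 2L, sqrt(v[!mono]), "/")
  list(matrix = x, means = mu[!mono],
       kept = ds$map$snp_id[!mono], dropped = ds$map$snp_id[mono])
}

#' PCA of a centered genotype matrix
#'
#' Thin singular value decomposition of the centered matrix; scores are the
#' left singular vectors scaled by the singular values, explained-variance
#' fractions come from the squared singular values.
#'
#' @param x centered numeric matrix (samples x SNPs), e.g. the `matrix`
#'   element of [standardize_genotypes()].
#' @param n_comp number of components to return (default: all).
#' @return object of class `pca_result`: `scores`, `loadings`, `sdev`,
#'   `explained_variance`.
#' @export
genotype_pca <- function(x, n_comp = NULL) {
  if (nrow(x) < 2L) stop("need at least two samples")
  k_max <- min(dim(x))
  k <- if (is.null(n_comp)) k_max else min(n_comp, k_max)
  s <- svd(x, nu = k, nv = k)
  d <- s$d[seq_len(k)]
  scores <- sweep(s$u, 2L, d, "*")
  colnames(scores) <- colnames(s$v) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(x)
  rownames(s$v) <- colnames(x)
  structure(list(scores = scores, loadings = s$v, sdev = s$d / sqrt(max(1, nrow(x) - 1L)),
                 explained_variance = s$d^2 / sum(s$d^2)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(5L, ncol(x$scores))
  cat("PCA:", nrow(x$scores), "samples,", ncol(x$scores), "components\n")
  cat("  explained variance (first", k, "):",
      sprintf("%.3f", x$explained_variance[seq_len(k)]), "\n")
  invisible(x)
}

# Fast thin PCA used inside cross-validation loops: eigen-decomposition on
# the smaller Gram matrix side. Returns at most n_comp components with
# positive singular value.
thin_pca <- function(x, n_comp) {
  n <- nrow(x)
  m <- ncol(x)
  n_comp <- min(n_comp, n, m)
  if (n <= m) {
    e <- eigen(tcrossprod(x), symmetric = TRUE)
    d2 <- pmax(e$values, 0)
    keep <- which(d2 > max(d2[1L], .Machine$double.eps) * 1e-12)
    keep <- keep[seq_len(min(n_comp, length(keep)))]
    d <- sqrt(d2[keep])
    u <- e$vectors[, keep, drop = FALSE]
    v <- crossprod(x, sweep(u, 2L, d, "/"))
  } else {
    e <- eigen(crossprod(x), symmetric = TRUE)
    d2 <- pmax(e$values, 0)
    keep <- which(d2 > max(d2[1L], .Machine$double.eps) * 1e-12)
    keep <- keep[seq_len(min(n_comp, length(keep)))]
    d <- sqrt(d2[keep])
    v <- e$vectors[, keep, drop = FALSE]
    u <- sweep(x %*% v, 2L, d, "/")
  }
  list(scores = sweep(u, 2L, d, "*"), loadings = v, d = d,
       total_var = sum(d2))
}
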