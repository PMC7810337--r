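# Independent oracles and fixture builders shared across the test files.
# Each oracle is a deliberately naive reformulation of the operation it
# checks, so agreement is informative.

# Brute-force consecutive-ROH oracle: for every candidate start, the maximal
# window satisfying the het/missing/gap allowances is found by direct
# forward extension with fresh counters; the scan then walks start points
# using the same restart rule as the package (after an emitted run: the
# violating SNP; after a discarded run: just past its first het/missing SNP,
# or past the violating SNP when the run was clean; after a gap: the SNP
# beyond the gap).
oracle_roh <- function(geno, pos, params) {
  n <- length(geno)
  het <- !is.na(geno) & geno == 1L
  mis <- is.na(geno)
  gap_max <- if (is.null(params$max_gap_bp)) Inf else params$max_gap_bp
  max_end <- function(s) {
    nh <- 0L
    nm <- 0L
    e <- s - 1L
    for (j in s:n) {
      if (j > s && pos[j] - pos[j - 1L] > gap_max) {
        return(list(e = e, cause = "gap", j = j))
      }
      if (nh + het[j] > params$max_het) return(list(e = e, cause = "het", j = j))
      if (nm + mis[j] > params$max_miss) return(list(e = e, cause = "miss", j = j))
      nh <- nh + het[j]
      nm <- nm + mis[j]
      e <- j
    }
    list(e = n, cause = "end", j = n + 1L)
  }
  out <- NULL
  s <- 1L
  while (s <= n) {
    r <- max_end(s)
    e <- r$e
    emitted <- e >= s && (e - s + 1L) >= params$min_snp &&
      (pos[e] - pos[s]) >= params$min_length_bp
    if (emitted) out <- rbind(out, c(s, e))
    if (r$j > n) break
    if (r$cause == "gap") {
      s <- r$j
    } else if (emitted) {
      s <- r$j + 1L
    } else {
      v <- which(het[s:e] | mis[s:e])
      s <- if (length(v)) s + v[1L] else r$j + 1L
    }
  }
  if (is.null(out)) {
    return(data.frame(start_idx = integer(0), end_idx = integer(0)))
  }
  data.frame(start_idx = out[, 1L], end_idx = out[, 2L])
}

# random dosage vector with tunable heterozygosity/missingness and a few
# planted homozygous stretches so qualifying runs actually occur
random_roh_vector <- function(n = 300L, p_het = 0.3, p_miss = 0.02,
                              n_stretch = 2L) {
  g <- sample(c(0L, 1L, 2L, NA_integer_), n, replace = TRUE,
              prob = c((1 - p_het - p_miss) / 2, p_het,
                       (1 - p_het - p_miss) / 2, p_miss))
  for (s in seq_len(n_stretch)) {
    len <- sample(10:60, 1L)
    at <- sample.int(n - len, 1L)
    g[at:(at + len)] <- sample(c(0L, 2L), len + 1L, replace = TRUE)
  }
  pos <- sort(sample.int(n * 80000L, n))
  list(geno = g, pos = pos)
}

# Full-density Gaussian LDA posterior: class means and pooled covariance are
# recomputed from the training scores, and posteriors come from the complete
# multivariate normal density (including the quadratic term the package's
# linear-discriminant shortcut cancels).
oracle_lda_posterior <- function(train_scores, labels, test_scores, ridge) {
  classes <- sort(unique(labels))
  p <- ncol(train_scores)
  n <- nrow(train_scores)
  means <- lapply(classes, function(cl) {
    colMeans(train_scores[labels == cl, , drop = FALSE])
  })
  w <- matrix(0, p, p)
  for (ci in seq_along(classes)) {
    xc <- sweep(train_scores[labels == classes[ci], , drop = FALSE],
                2, means[[ci]], "-")
    w <- w + t(xc) %*% xc
  }
  w <- w / (n - length(classes))
  if (ridge > 0) w <- w + diag(ridge * mean(diag(w)), p)
  w_inv <- solve(w)
  priors <- as.numeric(table(factor(labels, levels = classes))) / n
  logdens <- sapply(seq_along(classes), function(ci) {
    d <- sweep(test_scores, 2, means[[ci]], "-")
    -0.5 * rowSums((d %*% w_inv) * d) + log(priors[ci])
  })
  logdens <- logdens - apply(logdens, 1, max)
  post <- exp(logdens)
  post / rowSums(post)
}

# Hudson-type FST estimator between two breeds of a dataset
hudson_fst <- function(ds, breed_a, breed_b) {
  ga <- ds$calls[ds$fam$breed == breed_a, , drop = FALSE]
  gb <- ds$calls[ds$fam$breed == breed_b, , drop = FALSE]
  na <- colSums(!is.na(ga))
  nb <- colSums(!is.na(gb))
  pa <- colMeans(ga, na.rm = TRUE) / 2
  pb <- colMeans(gb, na.rm = TRUE) / 2
  keep <- na > 1 & nb > 1
  pa <- pa[keep]; pb <- pb[keep]
  na <- 2 * na[keep]; nb <- 2 * nb[keep]
  num <- (pa - pb)^2 - pa * (1 - pa) / (na - 1) - pb * (1 - pb) / (nb - 1)
  den <- pa * (1 - pb) + pb * (1 - pa)
  mean(num) / mean(den)
}

# hand-built polymorphic dataset (every SNP carries both alleles and at
# least one het) for round-trip properties
random_polymorphic_dataset <- function(n = 8L, m = 30L, n_chrom = 2L,
                                       missing_rate = 0.05) {
  repeat {
    calls <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
    if (missing_rate > 0) {
      calls[runif(n * m) < missing_rate] <- NA_integer_
    }
    ok <- apply(calls, 2, function(g) {
      g <- g[!is.na(g)]
      length(g) > 0 && any(g == 1L) && any(g != 1L)
    })
    if (all(ok)) break
  }
  chrom <- rep(as.character(seq_len(n_chrom)), length.out = m)
  pos <- stats::ave(seq_len(m), chrom, FUN = function(i) {
    sort(sample.int(1e6, length(i)))
  })
  geno_dataset(calls,
               map = data.frame(snp_id = sprintf("rs%03d", seq_len(m)),
                                chrom = chrom, pos_bp = pos,
                                allele1 = "A", allele2 = "C"),
               fam = data.frame(sample_id = sprintf("S%02d", seq_len(n)),
                                breed = rep(c("X", "Y"),
                                            length.out = n)))
}

# two perfectly separated breeds: fixed for opposite alleles at every SNP
separable_two_breed_dataset <- function(n_per = 6L, m = 40L) {
  calls <- rbind(matrix(2L, n_per, m), matrix(0L, n_per, m))
  geno_dataset(calls,
               map = data.frame(snp_id = sprintf("rs%03d", seq_len(m)),
                                chrom = "1", pos_bp = seq_len(m) * 1000L,
                                allele1 = "A", allele2 = "C"),
               fam = data.frame(sample_id = sprintf("S%02d", seq_len(2L * n_per)),
                                breed = rep(c("AA", "BB"), each = n_per)))
}
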