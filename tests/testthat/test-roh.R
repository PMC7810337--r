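test_that("clean homozygous stretches obey the SNP-count and length filters", {
  p <- roh_params()
  pos20 <- as.integer(seq(1e6, 2.2e6, length.out = 20))
  seg <- detect_roh_sample(rep(0L, 20), pos20, p)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$n_snp, 20L)
  expect_equal(seg$start_bp, pos20[1])
  expect_equal(seg$end_bp, pos20[20])

  # same SNPs squeezed into 0.9 Mbp: span filter rejects
  pos_short <- as.integer(seq(1e6, 1.9e6, length.out = 20))
  expect_equal(nrow(detect_roh_sample(rep(0L, 20), pos_short, p)), 0L)

  # all-heterozygous vector of any length gives nothing
  expect_equal(nrow(detect_roh_sample(rep(1L, 50), pos20[1] + 0:49 * 1000L, p)),
               0L)

  # unsorted positions are a contract violation
  expect_error(detect_roh_sample(rep(0L, 3), c(3L, 2L, 1L), p), "increasing")
})

test_that("one tolerated heterozygote extends a run; a second closes it", {
  p <- roh_params(min_snp = 5L, min_length_bp = 4000L, max_het = 1L,
                  max_miss = 0L, max_gap_bp = NULL)
  pos <- seq_len(20L) * 1000L
  g <- rep(0L, 20)
  g[10] <- 1L
  seg <- detect_roh_sample(g, pos, p)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$n_snp, 20L)

  # two heterozygotes split the vector into two reportable runs: the first
  # stops just before the second het, the second resumes past it
  g[15] <- 1L
  seg2 <- detect_roh_sample(g, pos, p)
  expect_equal(seg2$start_idx, c(1L, 16L))
  expect_equal(seg2$end_idx, c(14L, 20L))

  # a candidate discarded for shortness restarts after its FIRST het, so a
  # qualifying run sharing the tail is recovered: het at 3 and 11, with the
  # stretch 4..10 too short alone but 4..20 long enough once the scan
  # retries from index 4
  g2 <- rep(0L, 20)
  g2[c(3L, 11L)] <- 1L
  p2 <- roh_params(min_snp = 12L, min_length_bp = 4000L, max_het = 1L,
                   max_miss = 0L, max_gap_bp = NULL)
  seg3 <- detect_roh_sample(g2, pos, p2)
  expect_equal(seg3$start_idx, 4L)
  expect_equal(seg3$end_idx, 20L)
})

test_that("detection agrees with the exhaustive maximal-window oracle", {
  set.seed(101)
  params_list <- list(
    roh_params(min_snp = 10, min_length_bp = 5e5, max_het = 1, max_miss = 1),
    roh_params(min_snp = 15, min_length_bp = 1e6, max_het = 0, max_miss = 0,
               max_gap_bp = NULL),
    roh_params(min_snp = 5, min_length_bp = 2e5, max_het = 2, max_miss = 2,
               max_gap_bp = 3e5)
  )
  for (p in params_list) {
    for (i in 1:40) {
      v <- random_roh_vector(n = 250L, p_het = runif(1, 0.1, 0.5),
                             p_miss = runif(1, 0, 0.1))
      got <- detect_roh_sample(v$geno, v$pos, p)
      want <- oracle_roh(v$geno, v$pos, p)
      expect_identical(got[, c("start_idx", "end_idx")],
                       want, label = paste("setting", p$min_snp, "case", i))
    }
  }
})

test_that("stricter thresholds are monotone in the expected direction", {
  set.seed(202)
  for (i in 1:20) {
    v <- random_roh_vector(n = 300L, p_het = 0.25, p_miss = 0.05,
                           n_stretch = 3L)
    base <- roh_params(min_snp = 8, min_length_bp = 4e5, max_het = 1,
                       max_miss = 1)
    n_base <- nrow(detect_roh_sample(v$geno, v$pos, base))
    stricter_snp <- roh_params(min_snp = 16, min_length_bp = 4e5,
                               max_het = 1, max_miss = 1)
    stricter_len <- roh_params(min_snp = 8, min_length_bp = 9e5,
                               max_het = 1, max_miss = 1)
    looser_het <- roh_params(min_snp = 8, min_length_bp = 4e5, max_het = 3,
                             max_miss = 1)
    expect_lte(nrow(detect_roh_sample(v$geno, v$pos, stricter_snp)), n_base)
    expect_lte(nrow(detect_roh_sample(v$geno, v$pos, stricter_len)), n_base)
    # loosening the het allowance either extends the covered length or
    # merges neighbouring runs (which lowers the count); it can never do
    # neither
    s_base <- detect_roh_sample(v$geno, v$pos, base)
    s_loose <- detect_roh_sample(v$geno, v$pos, looser_het)
    expect_true(sum(s_loose$length_bp) >= sum(s_base$length_bp) ||
                  nrow(s_loose) < nrow(s_base))
  }
})

test_that("length classes partition (0, Inf) Mbp with right-closed bounds", {
  segs <- data.frame(length_bp = c(1.5e6, 2e6, 3.9e6, 4e6, 16e6, 17e6))
  cls <- classify_roh_lengths(segs)
  expect_equal(as.character(cls),
               c("0-2", "0-2", "2-4", "2-4", "8-16", ">16"))
  expect_false(anyNA(cls))
})

test_that("per-breed and per-chromosome summaries count correctly", {
  ds <- separable_two_breed_dataset(3L, 10L)
  segs <- data.frame(
    sample_id = c("S01", "S01", "S01", "S02", "S02"),
    breed = "AA",
    chrom = c("1", "1", "2", "1", "2"),
    start_bp = 1e6, end_bp = 2.5e6, n_snp = 20L, length_bp = 1.5e6)
  # give the dataset a second chromosome so the factor levels exist
  ds$map$chrom[6:10] <- "2"
  s <- summarize_roh(segs, ds)
  expect_equal(s$per_breed$n_roh[s$per_breed$breed == "AA"], 5L)
  expect_equal(s$per_breed$n_roh[s$per_breed$breed == "BB"], 0L)
  pc <- s$per_chromosome
  expect_equal(pc$n_roh[pc$breed == "AA" & pc$chrom == "1"], 3L)
  expect_equal(pc$sum_length_bp[pc$breed == "AA" & pc$chrom == "2"], 3e6)
  # each normalization sums to one over its own margin
  expect_equal(sum(s$class_freq_within_breed["AA", ]), 1)
  expect_equal(sum(s$class_freq_within_class[, "0-2"]), 1)
})

test_that("per-SNP ROH frequency matches a hand count", {
  n <- 5L
  m <- 10L
  calls <- matrix(0L, n, m)
  ds <- geno_dataset(calls,
                     map = data.frame(snp_id = sprintf("r%02d", 1:m),
                                      chrom = "1", pos_bp = (1:m) * 100000L,
                                      allele1 = "A", allele2 = "C"),
                     fam = data.frame(sample_id = sprintf("S%d", 1:n),
                                      breed = "GRF"))
  segs <- data.frame(sample_id = c("S1", "S2", "S3"), breed = "GRF",
                     chrom = "1", start_bp = 500000, end_bp = 800000,
                     n_snp = 4L, length_bp = 300000)
  f <- snp_roh_frequency(segs, ds, "GRF")
  expect_equal(f$freq, c(0, 0, 0, 0, 0.6, 0.6, 0.6, 0.6, 0, 0))
  expect_error(snp_roh_frequency(segs, ds, "NOPE"), "no samples")

  # below-threshold frequencies yield no islands
  expect_equal(nrow(detect_roh_islands(f, threshold = 0.7, breed = "GRF")),
               0L)
  # at 0.45 the covered SNPs form one island with the Table-style fields
  isl <- detect_roh_islands(f, threshold = 0.45, breed = "GRF")
  expect_equal(nrow(isl), 1L)
  expect_equal(isl$n_snp, 4L)
  expect_equal(isl$start_snp, "r05")
  expect_equal(isl$end_snp, "r08")
  expect_equal(isl$start_bp, 500000L)
  expect_equal(isl$end_bp, 800000L)
  expect_equal(isl$peak_frequency, 0.6)
})

test_that("F_ROH is segment length over map length, per genome and chromosome", {
  m <- 101L
  ds <- geno_dataset(matrix(0L, 2, m),
                     map = data.frame(snp_id = sprintf("r%03d", 1:m),
                                      chrom = "1", pos_bp = (0:100) * 1e6,
                                      allele1 = "A", allele2 = "C"),
                     fam = data.frame(sample_id = c("S1", "S2"), breed = "B"))
  # no segments -> 0 for everyone
  empty <- data.frame(sample_id = character(0), breed = character(0),
                      chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), n_snp = integer(0),
                      length_bp = numeric(0))
  expect_equal(compute_froh(empty, ds)$genome$froh, c(0, 0))
  segs <- data.frame(sample_id = "S1", breed = "B", chrom = "1",
                     start_bp = c(10e6, 50e6), end_bp = c(12e6, 53e6),
                     n_snp = 20L, length_bp = c(2e6, 3e6))
  f <- compute_froh(segs, ds)
  expect_equal(f$genome$froh, c(0.05, 0))
  expect_equal(f$by_chromosome$froh[f$by_chromosome$sample_id == "S1"], 0.05)

  # one segment spanning the whole single-chromosome map -> F_ROH = 1
  seg_all <- data.frame(sample_id = "S1", breed = "B", chrom = "1",
                        start_bp = 0, end_bp = 100e6, n_snp = m,
                        length_bp = 100e6)
  expect_equal(compute_froh(seg_all, ds)$genome$froh, c(1, 0))
})

test_that("genome F_ROH equals the map-length-weighted mean of chromosome F_ROH", {
  set.seed(33)
  cfg <- sim_config(n_breeds = 2, samples_per_breed = 5, n_chromosomes = 3,
                    snps_per_chromosome = 800, chromosome_length_bp = 8e7,
                    ancestral_freq_range = c(0.2, 0.8), drift = 0.05,
                    autozygosity = list(fraction = 0.15,
                                        length_range_bp = c(2e6, 6e6)),
                    missing_rate = 0, seed = 33)
  sim <- simulate_breed_panel(cfg)
  segs <- detect_roh(sim$dataset)
  f <- compute_froh(segs, sim$dataset)
  lens <- vapply(unique(sim$dataset$map$chrom), function(ch) {
    p <- sim$dataset$map$pos_bp[sim$dataset$map$chrom == ch]
    as.numeric(max(p) - min(p))
  }, numeric(1))
  for (s in f$genome$sample_id) {
    per_chr <- f$by_chromosome[f$by_chromosome$sample_id == s, ]
    weighted <- sum(per_chr$froh * lens[per_chr$chrom]) / sum(lens)
    expect_equal(f$genome$froh[f$genome$sample_id == s], weighted,
                 tolerance = 1e-12)
  }
})

test_that("an identical planted segment in half the breed becomes an island", {
  set.seed(44)
  n <- 10L
  m <- 400L
  pos <- sort(sample.int(2e7, m))
  calls <- matrix(sample(0:2, n * m, replace = TRUE,
                         prob = c(0.3, 0.4, 0.3)), n, m)
  # plant the same fully homozygous interval in 5 of 10 samples
  in_seg <- pos >= 5e6 & pos <= 8e6
  for (i in 1:5) calls[i, in_seg] <- sample(c(0L, 2L), sum(in_seg), TRUE)
  ds <- geno_dataset(calls,
                     map = data.frame(snp_id = sprintf("r%03d", 1:m),
                                      chrom = "1", pos_bp = pos,
                                      allele1 = "A", allele2 = "C"),
                     fam = data.frame(sample_id = sprintf("S%02d", 1:n),
                                      breed = "GRF"))
  segs <- detect_roh(ds, roh_params(max_gap_bp = NULL))
  f <- snp_roh_frequency(segs, ds, "GRF")
  isl <- detect_roh_islands(f, threshold = 0.45, breed = "GRF")
  expect_gte(nrow(isl), 1L)
  main <- isl[which.max(isl$n_snp), ]
  expect_lte(abs(main$start_bp - 5e6), 1e6)
  expect_gte(main$end_bp, 7.5e6)
  expect_gte(main$peak_frequency, 0.5)
})

test_that("ROH-profile PCA matches an eigen-decomposition oracle", {
  set.seed(55)
  profile <- matrix(rexp(5 * 29), 5, 29,
                    dimnames = list(paste0("B", 1:5), paste0("chr", 1:29)))
  p <- roh_profile_pca(profile)
  expect_equal(sum(p$explained_variance), 1)
  # oracle: eigen of the covariance of the centered profile
  xc <- scale(profile, center = TRUE, scale = FALSE)
  ev <- eigen(tcrossprod(xc), symmetric = TRUE)
  k <- 4L  # rank is n - 1
  scores_oracle <- ev$vectors[, 1:k] %*% diag(sqrt(pmax(ev$values[1:k], 0)))
  for (j in 1:k) {
    expect_lt(min(sum(abs(p$scores[, j] - scores_oracle[, j])),
                  sum(abs(p$scores[, j] + scores_oracle[, j]))), 1e-8)
  }
  # two identical breed profiles get identical scores
  prof2 <- rbind(profile, profile[1, , drop = FALSE])
  p2 <- roh_profile_pca(prof2)
  expect_equal(unname(p2$scores[1, ]), unname(p2$scores[6, ]),
               tolerance = 1e-10)
  expect_error(roh_profile_pca(profile[1, , drop = FALSE]), "two breeds")
})
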