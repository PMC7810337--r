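test_that("a separable two-breed problem is solved with one PC", {
  ds <- separable_two_breed_dataset(6L, 40L)
  model <- fit_dapc(ds, n_pc = 1L)
  expect_true(all(model$training_assignment$predicted == ds$fam$breed))
  expect_error(fit_dapc(ds, n_pc = 50L), "n_pc")
  single <- subset_genotypes(ds, samples = c(1, 7))
  expect_error(fit_dapc(single, n_pc = 1L), ">= 2 training samples")
})

test_that("posteriors match a full-density Gaussian LDA oracle", {
  set.seed(21)
  cfg <- sim_config(n_breeds = 3, samples_per_breed = 12, n_chromosomes = 2,
                    snps_per_chromosome = 60, drift = 0.15,
                    missing_rate = 0.02, seed = 21)
  sim <- simulate_breed_panel(cfg)
  ds <- sim$dataset
  model <- fit_dapc(ds, n_pc = 5L, ridge = 1e-6)
  pred <- predict_membership(model, ds)
  post <- as.matrix(pred[, grep("^post_", names(pred))])
  expect_equal(unname(rowSums(post)), rep(1, n_samples(ds)), tolerance = 1e-8)

  # oracle: recompute scores by centering/projection, then full densities
  x <- ds$calls
  storage.mode(x) <- "double"
  idx <- which(is.na(x))
  x[idx] <- model$pca_center[(idx - 1) %/% nrow(x) + 1]
  x <- sweep(x, 2, model$pca_center, "-")
  scores <- x %*% model$pca_loadings
  oracle <- oracle_lda_posterior(scores, ds$fam$breed, scores, ridge = 1e-6)
  expect_lt(max(abs(post - oracle)), 1e-8)
})

test_that("prediction re-uses training means and loadings, never test statistics", {
  # training: two breeds fixed for opposite alleles; the test batch is all
  # hom-allele1, i.e. identical to breed AA. Centering the test batch with
  # its own means would zero it out and make the assignment arbitrary.
  ds <- separable_two_breed_dataset(6L, 30L)
  model <- fit_dapc(ds, n_pc = 1L)
  test_ds <- geno_dataset(matrix(2L, 4, 30,
                                 dimnames = list(NULL, ds$map$snp_id)),
                          map = ds$map,
                          fam = data.frame(sample_id = paste0("T", 1:4),
                                           breed = "unknown"))
  pred <- predict_membership(model, test_ds)
  expect_true(all(pred$predicted_breed == "AA"))
  expect_true(all(pred$post_AA > 0.999))
})

test_that("prediction on the training set reproduces fit-time assignments", {
  set.seed(22)
  cfg <- sim_config(n_breeds = 4, samples_per_breed = 8, n_chromosomes = 2,
                    snps_per_chromosome = 80, drift = 0.1,
                    missing_rate = 0.01, seed = 22)
  ds <- simulate_breed_panel(cfg)$dataset
  model <- fit_dapc(ds, n_pc = 6L)
  pred <- predict_membership(model, ds)
  expect_identical(pred$predicted_breed,
                   model$training_assignment$predicted)
})

test_that("an all-missing sample falls back to the class priors", {
  ds <- separable_two_breed_dataset(6L, 20L)
  model <- fit_dapc(ds, n_pc = 1L)
  blank <- geno_dataset(matrix(NA_integer_, 1, 20,
                               dimnames = list(NULL, ds$map$snp_id)),
                        map = ds$map,
                        fam = data.frame(sample_id = "Z", breed = "?"))
  pred <- predict_membership(model, blank)
  expect_equal(unname(c(pred$post_AA, pred$post_BB)),
               unname(model$class_priors), tolerance = 1e-12)
  # no shared loci at all is a contract violation
  other <- geno_dataset(matrix(0L, 1, 2),
                        map = data.frame(snp_id = c("z1", "z2"), chrom = "1",
                                         pos_bp = c(1L, 2L), allele1 = "A",
                                         allele2 = "C"),
                        fam = data.frame(sample_id = "Z", breed = "?"))
  expect_error(predict_membership(model, other), "zero overlapping")
})

test_that("PC selection ties break to the smallest candidate and report shape", {
  ds <- separable_two_breed_dataset(10L, 40L)
  rep <- select_n_pc_cv(ds, folds = 5, repetitions = 2, grid = c(2, 5, 8),
                        seed = 3)
  expect_equal(names(rep$cv), c("n_pc", "mean_success", "sd_success"))
  expect_equal(nrow(rep$cv), 3L)
  expect_equal(rep$cv$mean_success, rep(1, 3))  # separable at any n_pc
  expect_equal(rep$selected_n_pc, 2L)           # tie -> smallest
})

test_that("held-out samples from a separable toy classify perfectly", {
  ds <- separable_two_breed_dataset(8L, 40L)
  train <- subset_genotypes(ds, samples = c(1:6, 9:14))
  test <- subset_genotypes(ds, samples = c(7, 8, 15, 16))
  model <- fit_dapc(train, n_pc = 1L)
  pred <- predict_membership(model, test)
  expect_true(all(pred$predicted_breed == pred$true_breed))
})

test_that("scenario 2 is deterministic under a fixed seed", {
  set.seed(23)
  cfg <- sim_config(n_breeds = 3, samples_per_breed = 10, n_chromosomes = 2,
                    snps_per_chromosome = 100, drift = 0.15,
                    missing_rate = 0, seed = 23)
  ds <- simulate_breed_panel(cfg)$dataset
  run <- function() {
    scenario_semisupervised(ds, "B01", holdout_n = 3, repetitions = 3,
                            seed = 99, select_folds = 4,
                            select_repetitions = 1, grid = c(4, 8))
  }
  a <- run()
  b <- run()
  expect_identical(a$assignment_table, b$assignment_table)
  expect_identical(a$details, b$details)
  expect_equal(a$mean_correct, 1)   # separable drifted breeds
  expect_equal(sum(a$assignment_table$mean_percent), 100)
})

test_that("scenario 3 with a single non-target breed is a forced choice", {
  set.seed(24)
  cfg <- sim_config(n_breeds = 2, samples_per_breed = 12, n_chromosomes = 2,
                    snps_per_chromosome = 100, drift = 0.1,
                    missing_rate = 0, seed = 24)
  ds <- simulate_breed_panel(cfg)$dataset
  expect_error(scenario_unsupervised(ds, "B01", train_fractions = 0.1,
                                     repetitions = 1, seed = 1,
                                     select_folds = 2,
                                     select_repetitions = 1, grid = 2),
               "training sample")
  s3 <- scenario_unsupervised(ds, "B01", train_fractions = c(0.5, 0.9),
                              repetitions = 2, seed = 1, select_folds = 3,
                              select_repetitions = 1, grid = c(2, 4))
  expect_true(all(s3$assignment_table["B02", ] == 100))
  expect_equal(unname(colSums(s3$assignment_table)), c(100, 100))
})

test_that("scenario 1 reports per-breed success and explained variance", {
  set.seed(25)
  cfg <- sim_config(n_breeds = 4, samples_per_breed = 10, n_chromosomes = 3,
                    snps_per_chromosome = 100, drift = 0.12,
                    missing_rate = 0.005, seed = 25)
  ds <- simulate_breed_panel(cfg)$dataset
  s1 <- scenario_supervised(ds, seed = 7, folds = 5, repetitions = 2,
                            grid = c(5, 10, 20))
  expect_setequal(s1$per_breed_success$breed, sprintf("B%02d", 1:4))
  expect_true(all(s1$per_breed_success$success == 1))
  expect_gt(s1$explained_variance_share, 0)
  expect_lt(s1$explained_variance_share, 1)
  expect_equal(ncol(s1$discriminant_scores), 3L)  # n_classes - 1
})

test_that("posteriors agree with MASS::lda on the retained PC scores", {
  set.seed(26)
  cfg <- sim_config(n_breeds = 3, samples_per_breed = 15, n_chromosomes = 2,
                    snps_per_chromosome = 80, drift = 0.12,
                    missing_rate = 0, seed = 26)
  ds <- simulate_breed_panel(cfg)$dataset
  model <- fit_dapc(ds, n_pc = 6L, ridge = 0)
  x <- ds$calls
  storage.mode(x) <- "double"
  scores <- sweep(x, 2, model$pca_center, "-") %*% model$pca_loadings
  ref <- MASS::lda(scores, grouping = ds$fam$breed)
  ref_post <- predict(ref, scores)$posterior
  pred <- predict_membership(model, ds)
  post <- as.matrix(pred[, grep("^post_", names(pred))])
  expect_lt(max(abs(post - ref_post[, sub("^post_", "", colnames(post))])),
            1e-6)
})
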