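#' Scenario 1: supervised breed assignment on the full dataset
#'
#' Selects the number of retained PCs by repeated stratified cross-validation
#' on the full data, fits the final DAPC model on all samples, and reports
#' the per-breed training assignment success together with the discriminant
#' scores (for external plotting) and the variance share explained by the
#' retained PCs.
#'
#' @param ds a [geno_dataset].
#' @param labels breed labels (default `ds$fam$breed`).
#' @param seed integer seed for the CV fold splits.
#' @param ... further arguments to [select_n_pc_cv()] (`folds`,
#'   `repetitions`, `grid`, ...).
#' @return list of class `dapc_scenario1`: `selection` (the
#'   `pc_selection_report`), `model`, `per_breed_success`,
#'   `overall_success`, `explained_variance_share`, `assignments`,
#'   `discriminant_scores`.
#' @export
scenario_supervised <- function(ds, labels = ds$fam$breed, seed = 1L, ...) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) stop("need at least two breeds")
  sel <- select_n_pc_cv(ds, labels, seed = seed, ...)
  model <- fit_dapc(ds, labels, n_pc = sel$selected_n_pc)
  pred <- model$training_assignment$predicted
  ok <- pred == labels
  per_breed <- tapply(ok, labels, mean)
  structure(list(
    selection = sel,
    model = model,
    per_breed_success = data.frame(breed = names(per_breed),
                                   success = as.numeric(per_breed),
                                   stringsAsFactors = FALSE),
    overall_success = mean(ok),
    cv_success = max(sel$cv$mean_success),
    explained_variance_share = model$explained_variance_share,
    assignments = data.frame(sample_id = ds$fam$sample_id,
                             true_breed = labels, predicted_breed = pred,
                             stringsAsFactors = FALSE),
    discriminant_scores = model$training_assignment$discriminant_scores),
    class = "dapc_scenario1")
}

#' Scenario 2: semi-supervised assignment of held-out target animals
#'
#' Per repetition, `holdout_n` random animals of the target breed form the
#' test set; the training set is everything else (including the remaining
#' target animals). PC selection and model fitting are redone on each
#' training set, the held-out animals are classified among all breeds, and
#' assignment percentages are averaged over repetitions.
#'
#' @param ds a [geno_dataset].
#' @param target_breed breed whose animals are held out.
#' @param holdout_n animals held out per repetition (must be smaller than the
#'   target breed).
#' @param repetitions number of repetitions.
#' @param seed integer seed.
#' @param select_folds,select_repetitions,grid,ridge PC-selection controls
#'   passed to [select_n_pc_cv()].
#' @return list of class `dapc_scenario2`: `assignment_table` (mean % of
#'   held-out animals assigned to each breed), `mean_correct` (fraction
#'   assigned back to the target breed), `per_repetition` (data.frame with
#'   `repetition`, `n_pc`, `correct`), `details` (per-animal assignments).
#' @export
scenario_semisupervised <- function(ds, target_breed, holdout_n = 5L,
                                    repetitions = 10L, seed = 1L,
                                    select_folds = 10L,
                                    select_repetitions = 30L,
                                    grid = NULL, ridge = 1e-6) {
  target_idx <- which(ds$fam$breed == target_breed)
  if (length(target_idx) <= holdout_n) {
    stop("holdout_n (", holdout_n, ") must be smaller than the target breed (",
         length(target_idx), " samples)")
  }
  breeds <- sort(unique(ds$fam$breed))
  set.seed(as.integer(seed))
  counts <- matrix(0, repetitions, length(breeds),
                   dimnames = list(NULL, breeds))
  per_rep <- data.frame(repetition = seq_len(repetitions),
                        n_pc = NA_integer_, correct = NA_real_)
  details <- vector("list", repetitions)
  for (r in seq_len(repetitions)) {
    test <- sample(target_idx, holdout_n)
    train_ds <- subset_genotypes(ds, samples = setdiff(seq_len(n_samples(ds)),
                                                       test))
    sel <- select_n_pc_cv(train_ds, folds = select_folds,
                          repetitions = select_repetitions, grid = grid,
                          ridge = ridge,
                          seed = as.integer(seed) + 977L * r)
    model <- fit_dapc(train_ds, n_pc = sel$selected_n_pc, ridge = ridge)
    res <- predict_membership(model, subset_genotypes(ds, samples = test))
    tab <- table(factor(res$predicted_breed, levels = breeds))
    counts[r, ] <- 100 * as.numeric(tab) / holdout_n
    per_rep$n_pc[r] <- sel$selected_n_pc
    per_rep$correct[r] <- mean(res$predicted_breed == target_breed)
    res$repetition <- r
    details[[r]] <- res
  }
  structure(list(
    target_breed = target_breed,
    assignment_table = data.frame(breed = breeds,
                                  mean_percent = colMeans(counts),
                                  stringsAsFactors = FALSE),
    mean_correct = mean(per_rep$correct),
    per_repetition = per_rep,
    details = do.call(rbind, details)),
    class = "dapc_scenario2")
}

#' Scenario 3: unsupervised (leave-breed-out) source attribution
#'
#' The target breed never enters training. Per training fraction and
#' repetition, that fraction of each non-target breed is sampled as the
#' training set and `test_fraction` of the target breed as the test set; PC
#' selection and fitting are redone, and the target animals are classified
#' among the non-target breeds. Assignment percentages are averaged over
#' repetitions, giving one distribution over breeds per training fraction.
#'
#' @param ds a [geno_dataset].
#' @param target_breed breed to attribute; excluded from training.
#' @param test_fraction fraction of the target breed sampled per repetition.
#' @param train_fractions fractions of each non-target breed used for
#'   training.
#' @param repetitions repetitions per training fraction.
#' @param seed integer seed.
#' @param select_folds,select_repetitions,grid,ridge PC-selection controls
#'   passed to [select_n_pc_cv()].
#' @return list of class `dapc_scenario3`: `assignment_table` (breeds x
#'   train_fractions matrix of mean %, columns summing to 100) and
#'   `per_repetition` records.
#' @export
scenario_unsupervised <- function(ds, target_breed, test_fraction = 0.80,
                                  train_fractions = seq(0.2, 0.9, by = 0.1),
                                  repetitions = 10L, seed = 1L,
                                  select_folds = 10L,
                                  select_repetitions = 30L,
                                  grid = NULL, ridge = 1e-6) {
  target_idx <- which(ds$fam$breed == target_breed)
  if (!length(target_idx)) stop("unknown target breed: ", target_breed)
  others <- sort(setdiff(unique(ds$fam$breed), target_breed))
  if (length(others) < 1L) stop("no non-target breeds available")
  set.seed(as.integer(seed))
  tab <- matrix(0, length(others), length(train_fractions),
                dimnames = list(others, paste0("frac_", train_fractions)))
  per_rep <- list()
  n_test <- max(1L, round(test_fraction * length(target_idx)))
  for (fi in seq_along(train_fractions)) {
    frac <- train_fractions[fi]
    acc <- matrix(0, repetitions, length(others),
                  dimnames = list(NULL, others))
    for (r in seq_len(repetitions)) {
      train <- integer(0)
      for (br in others) {
        bi <- which(ds$fam$breed == br)
        n_tr <- round(frac * length(bi))
        if (n_tr < 2L) {
          stop("train_fraction ", frac, " leaves breed ", br,
               " with ", n_tr, " training sample(s); need >= 2")
        }
        train <- c(train, sample(bi, n_tr))
      }
      test <- sample(target_idx, n_test)
      train_ds <- subset_genotypes(ds, samples = train)
      sel <- select_n_pc_cv(train_ds, folds = select_folds,
                            repetitions = select_repetitions, grid = grid,
                            ridge = ridge,
                            seed = as.integer(seed) + 7919L * fi + r)
      model <- fit_dapc(train_ds, n_pc = sel$selected_n_pc, ridge = ridge)
      res <- predict_membership(model, subset_genotypes(ds, samples = test))
      cnt <- table(factor(res$predicted_breed, levels = others))
      acc[r, ] <- 100 * as.numeric(cnt) / n_test
      per_rep[[length(per_rep) + 1L]] <-
        data.frame(train_fraction = frac, repetition = r,
                   n_pc = sel$selected_n_pc,
                   breed = others, percent = acc[r, ],
                   stringsAsFactors = FALSE)
    }
    tab[, fi] <- colMeans(acc)
  }
  structure(list(target_breed = target_breed,
                 train_fractions = train_fractions,
                 assignment_table = tab,
                 per_repetition = do.call(rbind, per_rep)),
            class = "dapc_scenario3")
}

#' @export
print.dapc_scenario1 <- function(x, ...) {
  cat("DAPC scenario 1 (supervised):", x$model$n_pc, "PCs,",
      sprintf("overall training success %.1f%%, CV success %.1f%%\n",
              100 * x$overall_success, 100 * x$cv_success))
  invisible(x)
}

#' @export
print.dapc_scenario2 <- function(x, ...) {
  cat("DAPC scenario 2 (semi-supervised), target", x$target_breed, ":",
      sprintf("mean back-assignment %.1f%%\n", 100 * x$mean_correct))
  invisible(x)
}

#' @export
print.dapc_scenario3 <- function(x, ...) {
  cat("DAPC scenario 3 (leave-breed-out), target", x$target_breed, "\n")
  print(round(x$assignment_table, 1))
  invisible(x)
}
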