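#' Configuration of the full diversity/traceability pipeline
#'
#' One object drives QC, ROH analysis, population structure and the DAPC
#' scenarios. Every field has a desk-scale default; the configuration is
#' validated here, before any stage runs, and echoed verbatim into the
#' output directory.
#'
#' @param input_prefix PLINK path prefix of the input genotypes.
#' @param dialect `"binary"` or `"text"`.
#' @param out_dir output directory (created if needed).
#' @param autosomes autosome labels for QC.
#' @param snp_call_rate_min,sample_missing_max QC thresholds
#'   (see [apply_qc()]).
#' @param roh a [roh_params] object.
#' @param island_threshold within-breed ROH frequency defining islands.
#' @param k_range candidate numbers of ancestries; `NULL` skips admixture.
#' @param k_cv_folds folds for the K selection CV; 0 fits every K in
#'   `k_range` without CV and reports the best log-likelihood fit of the
#'   largest K.
#' @param dapc list of DAPC settings: `target_breed` (`NULL` skips scenarios
#'   2 and 3), `scenarios` (subset of 1:3), `holdout_n`, `test_fraction`,
#'   `train_fractions`, `repetitions`, `select_folds`, `select_repetitions`,
#'   `grid`.
#' @param seed master integer seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_prefix, dialect = "binary",
                            out_dir = "breedtrace_out",
                            autosomes = as.character(1:29),
                            snp_call_rate_min = 0.95,
                            sample_missing_max = 0.10,
                            roh = roh_params(),
                            island_threshold = 0.45,
                            k_range = 2:10, k_cv_folds = 10L,
                            dapc = list(target_breed = NULL,
                                        scenarios = 1L,
                                        holdout_n = 5L,
                                        test_fraction = 0.8,
                                        train_fractions = seq(0.2, 0.9, 0.1),
                                        repetitions = 10L,
                                        select_folds = 10L,
                                        select_repetitions = 30L,
                                        grid = NULL),
                            seed = 1L) {
  stopifnot(is.character(input_prefix), length(input_prefix) == 1L,
            dialect %in% c("binary", "text"),
            inherits(roh, "roh_params"),
            island_threshold > 0, island_threshold <= 1)
  defaults <- list(target_breed = NULL, scenarios = 1L, holdout_n = 5L,
                   test_fraction = 0.8, train_fractions = seq(0.2, 0.9, 0.1),
                   repetitions = 10L, select_folds = 10L,
                   select_repetitions = 30L, grid = NULL)
  dapc <- utils::modifyList(defaults, dapc)
  if (!all(dapc$scenarios %in% 1:3)) stop("dapc$scenarios must be in 1:3")
  structure(list(input_prefix = input_prefix, dialect = dialect,
                 out_dir = out_dir, autosomes = autosomes,
                 snp_call_rate_min = snp_call_rate_min,
                 sample_missing_max = sample_missing_max,
                 roh = roh, island_threshold = island_threshold,
                 k_range = k_range, k_cv_folds = as.integer(k_cv_folds),
                 dapc = dapc, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Stages run in a fixed order -- load, qc, roh, structure, dapc -- with
#' results collected into an in-memory bundle and exported as TSV/JSON under
#' `out_dir/{qc,roh,structure,dapc}`. A manifest records every emitted file
#' with its MD5 checksum, plus per-stage wall time and the seed, so reruns
#' with the same config and seed can be verified byte-for-byte. Any stage
#' failure is re-raised annotated with the stage name.
#'
#' @param cfg a [pipeline_config].
#' @return the report bundle (list, class `pipeline_bundle`) with elements
#'   `qc`, `roh`, `structure`, `dapc`, `manifest`, `timings`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  jsonlite::write_json(config_as_list(cfg),
                       file.path(cfg$out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  bundle <- list()
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    res
  }

  ds_raw <- stage("load", read_genotypes(cfg$input_prefix, cfg$dialect))
  qc <- stage("qc", apply_qc(ds_raw, cfg$snp_call_rate_min,
                             cfg$sample_missing_max, cfg$autosomes))
  ds <- qc$dataset
  bundle$qc <- qc$report

  bundle$roh <- stage("roh", {
    segments <- detect_roh(ds, cfg$roh)
    summaries <- summarize_roh(segments, ds)
    froh <- compute_froh(segments, ds)
    breeds <- sort(unique(ds$fam$breed))
    islands <- do.call(rbind, lapply(breeds, function(br) {
      detect_roh_islands(snp_roh_frequency(segments, ds, br),
                         threshold = cfg$island_threshold, breed = br)
    }))
    profile <- roh_chromosome_profile(segments, ds)
    pca <- if (nrow(profile) >= 2L) roh_profile_pca(profile) else NULL
    list(segments = segments, summaries = summaries, froh = froh,
         islands = islands, chromosome_profile = profile, profile_pca = pca)
  })

  bundle$structure <- stage("structure", {
    std <- standardize_genotypes(ds)
    pca <- genotype_pca(std$matrix, n_comp = min(10L, nrow(std$matrix) - 1L))
    res <- list(pca = pca)
    if (!is.null(cfg$k_range)) {
      if (cfg$k_cv_folds > 0L) {
        ks <- select_k_cv(ds$calls, k_range = cfg$k_range,
                          folds = cfg$k_cv_folds, seed = cfg$seed)
        res$k_selection <- ks
        k_best <- ks$selected_K
      } else {
        k_best <- max(cfg$k_range)
      }
      fit <- admixture_fit(ds$calls, k_best, seed = cfg$seed,
                           n_restarts = 2L)
      res$admixture <- fit
      res$breed_mean_q <- breed_mean_q(fit, ds$fam$breed)
    }
    res
  })

  bundle$dapc <- stage("dapc", {
    d <- cfg$dapc
    out <- list()
    if (1L %in% d$scenarios) {
      out$scenario1 <- scenario_supervised(
        ds, seed = cfg$seed, folds = d$select_folds,
        repetitions = d$select_repetitions, grid = d$grid)
    }
    if (!is.null(d$target_breed)) {
      if (2L %in% d$scenarios) {
        out$scenario2 <- scenario_semisupervised(
          ds, d$target_breed, holdout_n = d$holdout_n,
          repetitions = d$repetitions, seed = cfg$seed + 1L,
          select_folds = d$select_folds,
          select_repetitions = d$select_repetitions, grid = d$grid)
      }
      if (3L %in% d$scenarios) {
        out$scenario3 <- scenario_unsupervised(
          ds, d$target_breed, test_fraction = d$test_fraction,
          train_fractions = d$train_fractions,
          repetitions = d$repetitions, seed = cfg$seed + 2L,
          select_folds = d$select_folds,
          select_repetitions = d$select_repetitions, grid = d$grid)
      }
    }
    out
  })

  bundle$timings <- timings
  bundle$seed <- cfg$seed
  files <- export_reports(bundle, cfg$out_dir)
  manifest <- data.frame(
    file = sub(paste0("^", cfg$out_dir, "/?"), "", files),
    md5 = as.character(tools::md5sum(files)),
    stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(cfg$out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(seed = cfg$seed, timings = timings,
                            files = manifest),
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  bundle$manifest <- manifest
  class(bundle) <- "pipeline_bundle"
  bundle
}

config_as_list <- function(cfg) {
  out <- unclass(cfg)
  out$roh <- unclass(out$roh)
  out
}

#' Export a pipeline bundle as TSV tables
#'
#' Writes the stage tables with fixed column orders under
#' `dir/{qc,roh,structure,dapc}` and returns the file paths. Formats other
#' than TSV/JSON are rejected.
#'
#' @param bundle a `pipeline_bundle` from [run_pipeline()].
#' @param dir output directory.
#' @param formats subset of `c("tsv", "json")`.
#' @return character vector of files written.
#' @export
export_reports <- function(bundle, dir, formats = c("tsv", "json")) {
  bad <- setdiff(formats, c("tsv", "json"))
  if (length(bad)) stop("unknown format: ", bad[1L])
  for (sub in c("qc", "roh", "structure", "dapc")) {
    if (!dir.exists(file.path(dir, sub))) {
      dir.create(file.path(dir, sub), recursive = TRUE)
    }
  }
  files <- character(0)
  tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <<- c(files, path)
  }
  if ("json" %in% formats && !is.null(bundle$qc)) {
    p <- file.path(dir, "qc", "qc_report.json")
    write_qc_report(bundle$qc, p, "json")
    files <- c(files, p)
  }
  if ("tsv" %in% formats) {
    if (!is.null(bundle$qc)) {
      write_qc_report(bundle$qc, file.path(dir, "qc", "qc_report.tsv"), "tsv")
      files <- c(files, file.path(dir, "qc", "qc_report.tsv"))
    }
    r <- bundle$roh
    if (!is.null(r)) {
      write_roh_segments(r$segments, file.path(dir, "roh", "segments.tsv"))
      files <- c(files, file.path(dir, "roh", "segments.tsv"))
      tsv(r$summaries$per_breed, file.path(dir, "roh", "per_breed.tsv"))
      tsv(r$summaries$per_chromosome,
          file.path(dir, "roh", "per_chromosome.tsv"))
      tsv(cbind(breed = rownames(r$summaries$class_counts),
                r$summaries$class_counts),
          file.path(dir, "roh", "length_classes.tsv"))
      tsv(r$islands, file.path(dir, "roh", "islands.tsv"))
      tsv(r$froh$genome, file.path(dir, "roh", "froh.tsv"))
      tsv(r$froh$by_chromosome,
          file.path(dir, "roh", "froh_by_chromosome.tsv"))
    }
    s <- bundle$structure
    if (!is.null(s)) {
      tsv(data.frame(sample_id = rownames(s$pca$scores),
                     s$pca$scores, check.names = FALSE),
          file.path(dir, "structure", "pca_scores.tsv"))
      if (!is.null(s$k_selection)) {
        tsv(s$k_selection$cv, file.path(dir, "structure", "k_selection.tsv"))
      }
      if (!is.null(s$admixture)) {
        qf <- write_admixture(s$admixture,
                              file.path(dir, "structure", "admixture"))
        files <- c(files, qf)
        tsv(s$breed_mean_q, file.path(dir, "structure", "breed_mean_Q.tsv"))
      }
    }
    d <- bundle$dapc
    if (!is.null(d$scenario1)) {
      tsv(d$scenario1$per_breed_success,
          file.path(dir, "dapc", "scenario1_success.tsv"))
      tsv(d$scenario1$selection$cv,
          file.path(dir, "dapc", "scenario1_pc_selection.tsv"))
      tsv(data.frame(sample_id = d$scenario1$assignments$sample_id,
                     d$scenario1$discriminant_scores),
          file.path(dir, "dapc", "scenario1_discriminant_scores.tsv"))
    }
    if (!is.null(d$scenario2)) {
      tsv(d$scenario2$assignment_table,
          file.path(dir, "dapc", "scenario2_assignment.tsv"))
    }
    if (!is.null(d$scenario3)) {
      tsv(cbind(breed = rownames(d$scenario3$assignment_table),
                as.data.frame(d$scenario3$assignment_table)),
          file.path(dir, "dapc", "scenario3_assignment.tsv"))
    }
  }
  files
}
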