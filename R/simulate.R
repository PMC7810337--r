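#' Configuration of the multi-breed genotype simulator
#'
#' The defaults describe a desk-scale stand-in for a 50k-chip multi-breed
#' goat panel: 10 breeds of 25 diploid animals on 29 autosomes of 100 Mbp,
#' 172 SNPs per chromosome (about 5,000 SNPs in total), breed
#' differentiation by Balding-Nichols drift from a shared ancestral pool,
#' and a small per-call missing rate.
#'
#' @param n_breeds number of breeds.
#' @param samples_per_breed animals per breed.
#' @param n_chromosomes number of autosomes.
#' @param snps_per_chromosome SNPs simulated per chromosome.
#' @param chromosome_length_bp length of every chromosome, bp.
#' @param ancestral_freq_range range of the uniform ancestral allele
#'   frequency; narrow it towards (0.2, 0.8) to emulate the common-variant
#'   ascertainment of commercial chips.
#' @param drift Balding-Nichols drift parameter per breed (recycled);
#'   approximately the expected differentiation (FST) of each breed from the
#'   ancestral pool.
#' @param admixture_design optional true ancestry matrix (one row per
#'   sample, one column per breed); default is pure breeds (one-hot rows).
#'   When supplied, `design_breeds` may give the breed label per sample
#'   (default: the majority ancestry).
#' @param design_breeds optional breed labels accompanying
#'   `admixture_design`.
#' @param autozygosity list with `fraction` (target autozygous fraction of
#'   the map per animal) and `length_range_bp` (segment lengths, drawn
#'   uniformly); `fraction = 0` plants nothing.
#' @param missing_rate independent per-call missing probability.
#' @param seed integer seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_breeds = 10L, samples_per_breed = 25L,
                       n_chromosomes = 29L, snps_per_chromosome = 172L,
                       chromosome_length_bp = 1e8,
                       ancestral_freq_range = c(0.05, 0.95),
                       drift = 0.1,
                       admixture_design = NULL, design_breeds = NULL,
                       autozygosity = list(fraction = 0,
                                           length_range_bp = c(2e6, 8e6)),
                       missing_rate = 0.002, seed = 1L) {
  stopifnot(n_breeds >= 1L, samples_per_breed >= 1L, n_chromosomes >= 1L,
            snps_per_chromosome >= 1L, chromosome_length_bp > 0,
            length(ancestral_freq_range) == 2L,
            all(ancestral_freq_range > 0), all(ancestral_freq_range < 1),
            all(drift > 0), all(drift < 1),
            missing_rate >= 0, missing_rate < 1,
            autozygosity$fraction >= 0, autozygosity$fraction <= 1)
  if (snps_per_chromosome > chromosome_length_bp) {
    stop("more SNPs than base-pair positions per chromosome")
  }
  structure(list(n_breeds = as.integer(n_breeds),
                 samples_per_breed = as.integer(samples_per_breed),
                 n_chromosomes = as.integer(n_chromosomes),
                 snps_per_chromosome = as.integer(snps_per_chromosome),
                 chromosome_length_bp = as.numeric(chromosome_length_bp),
                 ancestral_freq_range = as.numeric(ancestral_freq_range),
                 drift = rep_len(as.numeric(drift), n_breeds),
                 admixture_design = admixture_design,
                 design_breeds = design_breeds,
                 autozygosity = autozygosity,
                 missing_rate = as.numeric(missing_rate),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a multi-breed SNP genotype panel
#'
#' Balding-Nichols model: the ancestral allele frequency p_j is uniform on
#' the configured range; breed k's frequency f_kj is Beta-distributed with
#' mean p_j and variance `drift_k * p_j * (1 - p_j)`; each animal's genotype
#' at SNP j is Binomial(2, sum_k q_ik f_kj) with q its (possibly admixed)
#' true ancestry. Positions are uniform random, sorted and unique per
#' chromosome. Planted autozygosity and missingness from the config are
#' applied afterwards via [plant_autozygosity()] and [apply_missingness()].
#'
#' @param cfg a [sim_config].
#' @return list with `dataset` (a [geno_dataset]) and `truth` (class
#'   `sim_truth`: `Q` true ancestry per sample, `F` true breed frequencies,
#'   `ancestral_freq`, `drift`, `planted_segments`,
#'   `realized_autozygosity`).
#' @export
simulate_breed_panel <- function(cfg) {
  set.seed(cfg$seed)
  n_b <- cfg$n_breeds
  m_c <- cfg$snps_per_chromosome
  m <- m_c * cfg$n_chromosomes

  chrom <- rep(as.character(seq_len(cfg$n_chromosomes)), each = m_c)
  pos <- unlist(lapply(seq_len(cfg$n_chromosomes), function(ch) {
    sort(sample.int(cfg$chromosome_length_bp, m_c))
  }))
  snp_id <- sprintf("snp_c%02d_%05d", rep(seq_len(cfg$n_chromosomes),
                                          each = m_c),
                    rep(seq_len(m_c), cfg$n_chromosomes))

  p <- stats::runif(m, cfg$ancestral_freq_range[1L],
                    cfg$ancestral_freq_range[2L])
  f <- matrix(0, n_b, m)
  for (k in seq_len(n_b)) {
    c_k <- cfg$drift[k]
    if (c_k < 1e-9) {
      f[k, ] <- p
    } else {
      shape <- (1 - c_k) / c_k
      f[k, ] <- stats::rbeta(m, p * shape, (1 - p) * shape)
    }
    f[k, ] <- pmin(pmax(f[k, ], 1e-6), 1 - 1e-6)
  }

  breed_names <- sprintf("B%02d", seq_len(n_b))
  if (is.null(cfg$admixture_design)) {
    n <- n_b * cfg$samples_per_breed
    q <- matrix(0, n, n_b)
    breed_of <- rep(breed_names, each = cfg$samples_per_breed)
    q[cbind(seq_len(n), rep(seq_len(n_b), each = cfg$samples_per_breed))] <- 1
  } else {
    q <- as.matrix(cfg$admixture_design)
    if (ncol(q) != n_b) stop("admixture_design needs one column per breed")
    if (any(abs(rowSums(q) - 1) > 1e-8)) {
      stop("admixture_design rows must sum to 1")
    }
    n <- nrow(q)
    breed_of <- if (!is.null(cfg$design_breeds)) {
      as.character(cfg$design_breeds)
    } else {
      breed_names[apply(q, 1L, which.max)]
    }
  }
  pi_mat <- q %*% f
  calls <- matrix(stats::rbinom(n * m, 2L, pi_mat), n, m)
  fam <- data.frame(sample_id = sprintf("%s_%03d", breed_of,
                                        stats::ave(seq_len(n), breed_of,
                                                   FUN = seq_along)),
                    breed = breed_of, stringsAsFactors = FALSE)
  map <- data.frame(snp_id = snp_id, chrom = chrom, pos_bp = pos,
                    allele1 = "A", allele2 = "B", stringsAsFactors = FALSE)
  ds <- geno_dataset(calls, map, fam)

  truth <- structure(list(Q = q, F = f, ancestral_freq = p,
                          drift = cfg$drift, breed_names = breed_names,
                          planted_segments = empty_segments(),
                          realized_autozygosity =
                            stats::setNames(numeric(n), fam$sample_id)),
                     class = "sim_truth")
  rownames(truth$Q) <- fam$sample_id

  if (cfg$autozygosity$fraction > 0) {
    pl <- plant_autozygosity(ds, truth,
                             per_sample_fraction = cfg$autozygosity$fraction,
                             length_range_bp = cfg$autozygosity$length_range_bp,
                             seed = cfg$seed + 1L)
    ds <- pl$dataset
    truth <- pl$truth
  }
  if (cfg$missing_rate > 0) {
    ds <- apply_missingness(ds, cfg$missing_rate, seed = cfg$seed + 2L)
  }
  list(dataset = ds, truth = truth)
}

empty_segments <- function() {
  data.frame(sample_id = character(0), chrom = character(0),
             start_bp = numeric(0), end_bp = numeric(0))
}

#' Plant autozygous segments into a simulated panel
#'
#' Per animal, non-overlapping intervals with lengths drawn uniformly from
#' `length_range_bp` are placed on random chromosomes (probability
#' proportional to chromosome length) until the target fraction of the map
#' is covered. Within an interval every genotype is forced homozygous by
#' drawing ONE allele from the animal's own expected allele frequency and
#' doubling it, which mimics inheriting the same haplotype from both
#' parents without tracking phase.
#'
#' @param ds a [geno_dataset] from [simulate_breed_panel()].
#' @param truth the matching `sim_truth` (supplies expected frequencies).
#' @param per_sample_fraction target autozygous fraction of the total map.
#' @param length_range_bp two-element range of segment lengths, bp.
#' @param seed integer seed.
#' @param max_tries placement attempts per segment before giving up.
#' @return list with the modified `dataset` and updated `truth`
#'   (`planted_segments`, `realized_autozygosity`).
#' @export
plant_autozygosity <- function(ds, truth, per_sample_fraction,
                               length_range_bp = c(2e6, 8e6), seed = 1L,
                               max_tries = 200L) {
  stopifnot(per_sample_fraction >= 0, per_sample_fraction <= 1)
  if (per_sample_fraction == 0) {
    return(list(dataset = ds, truth = truth))
  }
  set.seed(as.integer(seed))
  chroms <- unique(ds$map$chrom)
  ch_len <- vapply(chroms, function(ch) {
    as.numeric(max(ds$map$pos_bp[ds$map$chrom == ch]))
  }, numeric(1))
  total_len <- sum(ch_len)
  pi_mat <- truth$Q %*% truth$F     # expected allele-1 frequency per call
  segs <- list()
  realized <- truth$realized_autozygosity
  if (per_sample_fraction >= 0.999) {
    # full autozygosity: one segment tiling each chromosome
    for (i in seq_len(n_samples(ds))) {
      one <- stats::rbinom(n_loci(ds), 1L, pi_mat[i, ])
      ds$calls[i, ] <- 2L * one
      segs[[i]] <- data.frame(sample_id = ds$fam$sample_id[i],
                              chrom = chroms, start_bp = 1,
                              end_bp = as.numeric(ch_len))
      realized[i] <- 1
    }
    truth$planted_segments <- do.call(rbind, segs)
    rownames(truth$planted_segments) <- NULL
    truth$realized_autozygosity <- realized
    return(list(dataset = ds, truth = truth))
  }
  for (i in seq_len(n_samples(ds))) {
    covered <- 0
    placed <- empty_segments()
    tries <- 0L
    while (covered < per_sample_fraction * total_len) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop("cannot place non-overlapping segments for sample ",
             ds$fam$sample_id[i], " at fraction ", per_sample_fraction)
      }
      len <- stats::runif(1, length_range_bp[1L], length_range_bp[2L])
      remaining <- per_sample_fraction * total_len - covered
      if (len > remaining) {
        # clip the final segment so the realized fraction tracks the target;
        # a clipped remnant too short to ever satisfy a 1 Mbp run filter is
        # not worth placing
        if (remaining < max(1.2e6, length_range_bp[1L] / 2)) break
        len <- remaining
      }
      ch <- sample(chroms, 1L, prob = ch_len)
      if (len >= ch_len[ch]) next
      start <- stats::runif(1, 1, ch_len[ch] - len)
      end <- start + len
      same <- placed[placed$chrom == ch, , drop = FALSE]
      if (nrow(same) && any(start <= same$end_bp & end >= same$start_bp)) {
        next
      }
      placed <- rbind(placed,
                      data.frame(sample_id = ds$fam$sample_id[i], chrom = ch,
                                 start_bp = start, end_bp = end))
      covered <- covered + len
      tries <- 0L
      li <- which(ds$map$chrom == ch & ds$map$pos_bp >= start &
                    ds$map$pos_bp <= end)
      if (length(li)) {
        one <- stats::rbinom(length(li), 1L, pi_mat[i, li])
        ds$calls[i, li] <- 2L * one
      }
    }
    segs[[i]] <- placed
    realized[i] <- covered / total_len
  }
  truth$planted_segments <- do.call(rbind, segs)
  rownames(truth$planted_segments) <- NULL
  truth$realized_autozygosity <- realized
  list(dataset = ds, truth = truth)
}

#' Set calls missing at random
#'
#' @param ds a [geno_dataset].
#' @param rate independent per-call missing probability, in \[0, 1).
#' @param seed integer seed.
#' @return the modified [geno_dataset].
#' @export
apply_missingness <- function(ds, rate, seed = 1L) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(ds)
  set.seed(as.integer(seed))
  hit <- stats::runif(length(ds$calls)) < rate
  ds$calls[hit] <- NA_integer_
  ds
}

#' Write a simulated panel and its ground truth to disk
#'
#' Emits the PLINK binary trio plus plain-text truth tables: `truth_Q.tsv`
#' (true ancestry per sample), `truth_segments.tsv` (planted autozygous
#' intervals) and `config.json` (the generating configuration).
#'
#' @param ds a [geno_dataset].
#' @param truth the matching `sim_truth`.
#' @param dir output directory (created if absent).
#' @param cfg optional [sim_config] echoed into `config.json`.
#' @return invisibly, the files written.
#' @export
write_fixture <- function(ds, truth, dir, cfg = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- write_genotypes(ds, file.path(dir, "panel"), "binary")
  qdf <- data.frame(sample_id = ds$fam$sample_id, breed = ds$fam$breed,
                    truth$Q, check.names = FALSE)
  names(qdf)[-(1:2)] <- truth$breed_names
  qp <- file.path(dir, "truth_Q.tsv")
  utils::write.table(qdf, qp, sep = "\t", quote = FALSE, row.names = FALSE)
  sp <- file.path(dir, "truth_segments.tsv")
  utils::write.table(truth$planted_segments, sp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  out <- c(files, qp, sp)
  if (!is.null(cfg)) {
    cp <- file.path(dir, "config.json")
    jsonlite::write_json(unclass(cfg)[setdiff(names(cfg),
                                              c("admixture_design"))],
                         cp, auto_unbox = TRUE, pretty = TRUE)
    out <- c(out, cp)
  }
  invisible(out)
}
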