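#' Parameters of the consecutive ROH scan
#'
#' Defaults follow common practice for 50k livestock chips: at least 15 SNPs
#' per run, at least 1 Mbp spanned, one heterozygous call tolerated per run
#' (to absorb genotyping errors), one missing call tolerated, and a maximum
#' gap of 1 Mbp between adjacent SNPs inside a run.
#'
#' @param min_snp minimum number of SNPs in a reported run.
#' @param min_length_bp minimum span (last SNP position minus first) in bp.
#' @param max_het maximum heterozygous calls tolerated inside a run.
#' @param max_miss maximum missing calls tolerated inside a run.
#' @param max_gap_bp maximum gap between adjacent SNPs inside a run;
#'   `NULL` disables the gap constraint.
#' @return an object of class `roh_params`.
#' @export
roh_params <- function(min_snp = 15L, min_length_bp = 1e6, max_het = 1L,
                       max_miss = 1L, max_gap_bp = 1e6) {
  stopifnot(min_snp >= 2L, min_length_bp > 0, max_het >= 0L, max_miss >= 0L)
  structure(list(min_snp = as.integer(min_snp),
                 min_length_bp = as.numeric(min_length_bp),
                 max_het = as.integer(max_het),
                 max_miss = as.integer(max_miss),
                 max_gap_bp = if (is.null(max_gap_bp)) NULL
                              else as.numeric(max_gap_bp)),
            class = "roh_params")
}

#' Detect runs of homozygosity on one chromosome of one individual
#'
#' Left-to-right consecutive scan: the current run is extended while the
#' cumulative heterozygous calls stay within `max_het`, cumulative missing
#' calls within `max_miss`, and (if set) every inter-SNP gap within
#' `max_gap_bp`. When the next SNP would violate a constraint the run is
#' closed and reported if it has at least `min_snp` SNPs and spans at least
#' `min_length_bp` (span = last SNP position - first SNP position). If the
#' closed candidate was too short to report, the scan restarts just after the
#' first heterozygous/missing SNP it contained, so a qualifying run sharing
#' its tail is not lost; after a reported run the scan resumes past the
#' violating SNP, which keeps reported segments of one individual
#' non-overlapping and never starts a run on the SNP that closed the
#' previous one.
#'
#' @param geno integer dosage vector (0, 1, 2 or `NA`) of one chromosome.
#' @param pos strictly increasing base-pair positions, same length as `geno`.
#' @param params a [roh_params] object.
#' @return data.frame with one row per run: `start_idx`, `end_idx`,
#'   `start_bp`, `end_bp`, `n_snp`, `length_bp` (= `end_bp - start_bp`).
#' @export
detect_roh_sample <- function(geno, pos, params = roh_params()) {
  n <- length(geno)
  if (length(pos) != n) stop("geno and pos lengths differ")
  if (n > 1L && any(diff(pos) <= 0)) stop("positions must be strictly increasing")
  het <- !is.na(geno) & geno == 1L
  mis <- is.na(geno)
  gap_max <- if (is.null(params$max_gap_bp)) Inf else params$max_gap_bp

  out_s <- integer(0)
  out_e <- integer(0)
  s <- 1L
  while (s <= n) {
    n_het <- 0L
    n_mis <- 0L
    first_viol <- 0L   # first tolerated het/missing SNP inside the run
    e <- s - 1L
    j <- s
    cause <- "end"
    while (j <= n) {
      if (j > s && pos[j] - pos[j - 1L] > gap_max) {
        cause <- "gap"
        break
      }
      if (het[j] && n_het + 1L > params$max_het) {
        cause <- "het"
        break
      }
      if (mis[j] && n_mis + 1L > params$max_miss) {
        cause <- "miss"
        break
      }
      if ((het[j] || mis[j]) && first_viol == 0L) first_viol <- j
      n_het <- n_het + (het[j])
      n_mis <- n_mis + (mis[j])
      e <- j
      j <- j + 1L
    }
    emitted <- FALSE
    if (e >= s && (e - s + 1L) >= params$min_snp &&
        (pos[e] - pos[s]) >= params$min_length_bp) {
      out_s <- c(out_s, s)
      out_e <- c(out_e, e)
      emitted <- TRUE
    }
    if (j > n) break
    if (cause == "gap") {
      s <- j                       # nothing inside the run can bridge a gap
    } else if (emitted) {
      s <- j + 1L                  # resume past the violating SNP
    } else if (first_viol > 0L) {
      s <- first_viol + 1L         # retry the tail after the first het/miss
    } else {
      s <- j + 1L                  # the violating SNP itself was the first
    }
  }
  data.frame(start_idx = out_s, end_idx = out_e,
             start_bp = pos[out_s], end_bp = pos[out_e],
             n_snp = out_e - out_s + 1L,
             length_bp = as.numeric(pos[out_e] - pos[out_s]))
}

#' Detect runs of homozygosity for every individual in a dataset
#'
#' Runs [detect_roh_sample()] per sample and chromosome.
#'
#' @param ds a [geno_dataset] (normally after [apply_qc()]).
#' @param params a [roh_params] object.
#' @return data.frame of segments: `sample_id`, `breed`, `chrom`, `start_bp`,
#'   `end_bp`, `n_snp`, `length_bp`.
#' @export
detect_roh <- function(ds, params = roh_params()) {
  chroms <- unique(ds$map$chrom)
  res <- vector("list", length(chroms) * n_samples(ds))
  k <- 0L
  for (ch in chroms) {
    li <- which(ds$map$chrom == ch)
    pos <- ds$map$pos_bp[li]
    for (i in seq_len(n_samples(ds))) {
      seg <- detect_roh_sample(ds$calls[i, li], pos, params)
      if (nrow(seg)) {
        k <- k + 1L
        res[[k]] <- data.frame(sample_id = ds$fam$sample_id[i],
                               breed = ds$fam$breed[i],
                               chrom = ch,
                               start_bp = seg$start_bp,
                               end_bp = seg$end_bp,
                               n_snp = seg$n_snp,
                               length_bp = seg$length_bp,
                               stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0L) {
    return(data.frame(sample_id = character(0), breed = character(0),
                      chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), n_snp = integer(0),
                      length_bp = numeric(0)))
  }
  out <- do.call(rbind, res[seq_len(k)])
  rownames(out) <- NULL
  out
}

#' Assign ROH segments to length classes
#'
#' The five standard classes partition (0, Inf) Mbp into left-open,
#' right-closed intervals: (0-2], (2-4], (4-8], (8-16] and >16 Mbp, so a
#' segment of exactly 16 Mbp falls in the 8-16 class.
#'
#' @param segments data.frame from [detect_roh()] (needs `length_bp`).
#' @return factor of class labels, one per segment, with levels
#'   `"0-2" "2-4" "4-8" "8-16" ">16"`.
#' @export
classify_roh_lengths <- function(segments) {
  cut(segments$length_bp / 1e6,
      breaks = c(0, 2, 4, 8, 16, Inf),
      labels = c("0-2", "2-4", "4-8", "8-16", ">16"),
      right = TRUE)
}

#' Summarize ROH per breed, chromosome and length class
#'
#' @param segments data.frame from [detect_roh()].
#' @param ds the [geno_dataset] the segments came from (supplies the full
#'   breed list so breeds with zero detected runs still appear).
#' @return list with `per_breed` (count, mean count per animal, mean length),
#'   `per_chromosome` (breed x chromosome counts and summed length),
#'   `class_counts` (breed x class), and the two Fig-style normalizations
#'   `class_freq_within_class` (each class column sums to 1 across breeds)
#'   and `class_freq_within_breed` (each breed row sums to 1 across classes).
#' @export
summarize_roh <- function(segments, ds) {
  breeds <- sort(unique(ds$fam$breed))
  n_per_breed <- table(factor(ds$fam$breed, levels = breeds))
  if (any(n_per_breed == 0L)) stop("breed with zero samples")
  segs <- segments
  segs$breed <- factor(segs$breed, levels = breeds)
  segs$class <- classify_roh_lengths(segs)

  per_breed <- data.frame(
    breed = breeds,
    n_samples = as.integer(n_per_breed),
    n_roh = as.integer(table(segs$breed)),
    stringsAsFactors = FALSE)
  per_breed$mean_roh_per_animal <- per_breed$n_roh / per_breed$n_samples
  per_breed$mean_length_bp <- as.numeric(
    tapply(segs$length_bp, segs$breed, mean, default = NA_real_))

  chroms <- unique(ds$map$chrom)
  segs$chrom <- factor(segs$chrom, levels = chroms)
  per_chromosome <- as.data.frame(table(breed = segs$breed,
                                        chrom = segs$chrom))
  names(per_chromosome)[3L] <- "n_roh"
  sum_len <- tapply(segs$length_bp, list(segs$breed, segs$chrom), sum)
  sum_len[is.na(sum_len)] <- 0
  per_chromosome$sum_length_bp <- as.vector(sum_len)

  class_counts <- table(breed = segs$breed, class = segs$class)
  totals_class <- colSums(class_counts)
  totals_breed <- rowSums(class_counts)
  within_class <- sweep(class_counts, 2L, pmax(totals_class, 1L), "/")
  within_breed <- sweep(class_counts, 1L, pmax(totals_breed, 1L), "/")

  list(per_breed = per_breed,
       per_chromosome = per_chromosome,
       class_counts = as.data.frame.matrix(class_counts),
       class_freq_within_class = as.data.frame.matrix(within_class),
       class_freq_within_breed = as.data.frame.matrix(within_breed))
}

#' Per-SNP ROH frequency inside one breed
#'
#' For every SNP of the map, the fraction of the breed's samples whose
#' detected runs cover the SNP position (segments of one sample never
#' overlap, so each sample contributes at most once per SNP).
#'
#' @param segments data.frame from [detect_roh()].
#' @param ds the [geno_dataset].
#' @param breed breed label; must have at least one sample.
#' @return data.frame `snp_id`, `chrom`, `pos_bp`, `freq` (in \[0, 1\]).
#' @export
snp_roh_frequency <- function(segments, ds, breed) {
  ids <- ds$fam$sample_id[ds$fam$breed == breed]
  if (!length(ids)) stop("breed '", breed, "' has no samples")
  segs <- segments[segments$sample_id %in% ids, , drop = FALSE]
  count <- numeric(n_loci(ds))
  for (ch in unique(segs$chrom)) {
    li <- which(ds$map$chrom == ch)
    pos <- ds$map$pos_bp[li]
    sch <- segs[segs$chrom == ch, , drop = FALSE]
    for (r in seq_len(nrow(sch))) {
      lo <- findInterval(sch$start_bp[r] - 0.5, pos) + 1L
      hi <- findInterval(sch$end_bp[r] + 0.5, pos)
      if (hi >= lo) count[li[lo:hi]] <- count[li[lo:hi]] + 1
    }
  }
  data.frame(snp_id = ds$map$snp_id, chrom = ds$map$chrom,
             pos_bp = ds$map$pos_bp, freq = count / length(ids),
             stringsAsFactors = FALSE)
}

#' Detect ROH islands shared within a breed
#'
#' Maximal stretches of consecutive SNPs (within a chromosome) whose
#' within-breed ROH frequency reaches `threshold` become islands; the island
#' bounds are the positions of its first and last SNP.
#'
#' @param freq data.frame from [snp_roh_frequency()].
#' @param threshold minimum within-breed ROH frequency, in (0, 1].
#' @param breed breed label stored in the output rows.
#' @return data.frame `breed`, `chrom`, `start_snp`, `end_snp`, `n_snp`,
#'   `start_bp`, `end_bp`, `peak_frequency`.
#' @export
detect_roh_islands <- function(freq, threshold = 0.45, breed = NA_character_) {
  stopifnot(threshold > 0, threshold <= 1)
  rows <- list()
  for (ch in unique(freq$chrom)) {
    f <- freq[freq$chrom == ch, , drop = FALSE]
    hot <- f$freq >= threshold
    if (!any(hot)) next
    r <- rle(hot)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      a <- starts[k]
      b <- ends[k]
      rows[[length(rows) + 1L]] <- data.frame(
        breed = breed, chrom = ch,
        start_snp = f$snp_id[a], end_snp = f$snp_id[b],
        n_snp = b - a + 1L,
        start_bp = f$pos_bp[a], end_bp = f$pos_bp[b],
        peak_frequency = max(f$freq[a:b]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(breed = character(0), chrom = character(0),
                      start_snp = character(0), end_snp = character(0),
                      n_snp = integer(0), start_bp = numeric(0),
                      end_bp = numeric(0), peak_frequency = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genomic inbreeding coefficient F_ROH
#'
#' F_ROH of an individual is the summed length of its runs of homozygosity
#' divided by the total autosomal length. The default denominator is the
#' SNP-covered map length (per chromosome: last SNP position minus first),
#' taken from the post-QC map; assembly chromosome lengths can be supplied
#' instead via `chrom_lengths`.
#'
#' @param segments data.frame from [detect_roh()].
#' @param ds the [geno_dataset].
#' @param chrom_lengths optional named numeric vector of chromosome lengths
#'   (bp) overriding the map-derived denominators.
#' @return list with `genome` (data.frame `sample_id`, `breed`, `froh`) and
#'   `by_chromosome` (data.frame `sample_id`, `chrom`, `froh`); all values in
#'   \[0, 1\].
#' @export
compute_froh <- function(segments, ds, chrom_lengths = NULL) {
  if (n_loci(ds) == 0L) stop("empty SNP map")
  chroms <- unique(ds$map$chrom)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chroms, function(ch) {
      p <- ds$map$pos_bp[ds$map$chrom == ch]
      as.numeric(max(p) - min(p))
    }, numeric(1))
    names(chrom_lengths) <- chroms
  } else {
    missing_ch <- setdiff(chroms, names(chrom_lengths))
    if (length(missing_ch)) stop("chrom_lengths lacks: ",
                                 paste(missing_ch, collapse = ", "))
    chrom_lengths <- chrom_lengths[chroms]
  }
  total <- sum(chrom_lengths)
  ids <- ds$fam$sample_id
  seg_len <- tapply(segments$length_bp,
                    factor(segments$sample_id, levels = ids), sum)
  seg_len[is.na(seg_len)] <- 0
  genome <- data.frame(sample_id = ids, breed = ds$fam$breed,
                       froh = as.numeric(seg_len) / total,
                       stringsAsFactors = FALSE)
  by_chrom <- expand.grid(sample_id = ids, chrom = chroms,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(segments$sample_id, segments$chrom)
  len_sc <- tapply(segments$length_bp, key, sum)
  hit <- len_sc[paste(by_chrom$sample_id, by_chrom$chrom)]
  hit[is.na(hit)] <- 0
  by_chrom$froh <- as.numeric(hit) / chrom_lengths[by_chrom$chrom]
  list(genome = genome, by_chromosome = by_chrom)
}

#' PCA of per-chromosome ROH profiles
#'
#' Column-centered singular value decomposition (via [stats::prcomp]) of a
#' breeds-by-chromosomes matrix of mean ROH counts, used to place breeds by
#' the genomic distribution of their runs.
#'
#' @param profile numeric matrix, breeds in rows, chromosomes in columns.
#' @return list with `scores`, `loadings` and `explained_variance` (fractions
#'   summing to 1).
#' @export
roh_profile_pca <- function(profile) {
  profile <- as.matrix(profile)
  if (nrow(profile) < 2L) stop("need at least two breeds")
  p <- stats::prcomp(profile, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  list(scores = p$x, loadings = p$rotation,
       explained_variance = ev / sum(ev))
}

#' Build the breed-by-chromosome mean ROH count matrix
#'
#' @param segments data.frame from [detect_roh()].
#' @param ds the [geno_dataset].
#' @return numeric matrix (breeds x chromosomes) of mean ROH counts per
#'   animal.
#' @export
roh_chromosome_profile <- function(segments, ds) {
  breeds <- sort(unique(ds$fam$breed))
  chroms <- unique(ds$map$chrom)
  counts <- table(factor(segments$breed, levels = breeds),
                  factor(segments$chrom, levels = chroms))
  n_per_breed <- as.integer(table(factor(ds$fam$breed, levels = breeds)))
  mat <- sweep(unclass(counts), 1L, pmax(n_per_breed, 1L), "/")
  dimnames(mat) <- list(breeds, chroms)
  mat
}

#' Export ROH tables as TSV
#'
#' @param segments data.frame from [detect_roh()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_roh_segments <- function(segments, path) {
  cols <- c("sample_id", "breed", "chrom", "start_bp", "end_bp",
            "n_snp", "length_bp")
  utils::write.table(segments[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
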