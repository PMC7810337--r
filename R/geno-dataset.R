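#' Genotype dataset container
#'
#' Bundles the three pieces every analysis stage consumes: a sample table
#' (`fam`), a SNP map (`map`) and an integer dosage matrix (`calls`).
#' Dosages count copies of `map$allele1` at each locus, so every stored value
#' is 0, 1, 2 or `NA` (the single missing-call sentinel). Loci are kept sorted
#' by chromosome and base-pair position; autosome labels are plain numbers
#' ("1".."29" for goat).
#'
#' @param calls integer matrix, samples in rows and SNPs in columns; values
#'   0, 1, 2 or `NA`.
#' @param map data.frame with columns `snp_id`, `chrom`, `pos_bp`, `allele1`,
#'   `allele2`; one row per column of `calls`.
#' @param fam data.frame with columns `sample_id` and `breed` (the breed label
#'   lives in the PLINK family-ID field); one row per row of `calls`.
#' @return An object of class `geno_dataset`.
#' @export
geno_dataset <- function(calls, map, fam) {
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  fam <- as.data.frame(fam, stringsAsFactors = FALSE)
  need_map <- c("snp_id", "chrom", "pos_bp", "allele1", "allele2")
  if (!all(need_map %in% names(map))) {
    stop("map must have columns: ", paste(need_map, collapse = ", "))
  }
  if (!all(c("sample_id", "breed") %in% names(fam))) {
    stop("fam must have columns: sample_id, breed")
  }
  map$snp_id <- as.character(map$snp_id)
  map$chrom <- as.character(map$chrom)
  map$pos_bp <- as.integer(map$pos_bp)
  fam$sample_id <- as.character(fam$sample_id)
  fam$breed <- as.character(fam$breed)

  if (nrow(fam) != nrow(calls) || nrow(map) != ncol(calls)) {
    stop("calls must be (n_samples x n_loci) = (", nrow(fam), " x ",
         nrow(map), "), got (", nrow(calls), " x ", ncol(calls), ")")
  }
  if (anyDuplicated(fam$sample_id)) stop("duplicate sample ids")
  if (anyDuplicated(map$snp_id)) stop("duplicate SNP ids")
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("calls must be 0, 1, 2 or NA")
  }
  if (any(map$pos_bp < 0L, na.rm = TRUE)) stop("negative base-pair position")

  ord <- order(chrom_rank(map$chrom), map$pos_bp)
  map <- map[ord, , drop = FALSE]
  calls <- calls[, ord, drop = FALSE]
  rownames(map) <- NULL
  rownames(fam) <- NULL
  dup <- stats::ave(map$pos_bp, map$chrom, FUN = function(p) {
    c(0L, as.integer(diff(p) <= 0L))
  })
  if (any(dup == 1L)) {
    stop("positions must be strictly increasing within a chromosome; ",
         "duplicated/unsorted position near SNP ",
         map$snp_id[which(dup == 1L)[1L]])
  }
  dimnames(calls) <- list(fam$sample_id, map$snp_id)
  structure(list(calls = calls, map = map, fam = fam),
            class = "geno_dataset")
}

#' @export
print.geno_dataset <- function(x, ...) {
  cat("geno_dataset:", nrow(x$fam), "samples x", nrow(x$map), "SNPs\n")
  cat("  chromosomes:", length(unique(x$map$chrom)), "| breeds:",
      length(unique(x$fam$breed)), "\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.3f%%\n", 100 * miss))
  invisible(x)
}

#' Number of samples / loci in a dataset
#' @param ds a `geno_dataset`.
#' @return integer count.
#' @export
n_samples <- function(ds) nrow(ds$fam)

#' @rdname n_samples
#' @export
n_loci <- function(ds) nrow(ds$map)

#' Subset a genotype dataset
#'
#' @param ds a `geno_dataset`.
#' @param samples sample indices, logical mask or sample ids; `NULL` keeps all.
#' @param loci locus indices, logical mask or SNP ids; `NULL` keeps all.
#' @return the subsetted `geno_dataset`.
#' @export
subset_genotypes <- function(ds, samples = NULL, loci = NULL) {
  si <- resolve_index(samples, ds$fam$sample_id, "sample")
  li <- resolve_index(loci, ds$map$snp_id, "SNP")
  geno_dataset(ds$calls[si, li, drop = FALSE],
               ds$map[li, , drop = FALSE],
               ds$fam[si, , drop = FALSE])
}

resolve_index <- function(idx, ids, what) {
  if (is.null(idx)) return(seq_along(ids))
  if (is.logical(idx)) {
    if (length(idx) != length(ids)) stop("bad logical ", what, " mask length")
    return(which(idx))
  }
  if (is.character(idx)) {
    pos <- match(idx, ids)
    if (anyNA(pos)) stop("unknown ", what, " id: ", idx[is.na(pos)][1L])
    return(pos)
  }
  as.integer(idx)
}

# numeric-aware chromosome ordering: 1..29 numerically, then other labels
chrom_rank <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  lab <- match(chrom, sort(unique(chrom[is.na(num)])))
  ifelse(is.na(num), 1e9 + lab, num)
}
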