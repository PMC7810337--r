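#' Read SNP-array genotypes in PLINK dialects
#'
#' Reads either the text dialect (`.ped`/`.map`) or the binary dialect
#' (`.bed` v1.00 SNP-major with `.bim`/`.fam` companions) into a
#' [geno_dataset]. Dosages count copies of allele 1: for the binary dialect
#' allele 1 is the `.bim` A1 column (bed codes 00 -> 2, 10 -> 1, 11 -> 0,
#' 01 -> missing); for the text dialect, which stores no allele order, the
#' counted allele is fixed as the alphabetically first allele observed at the
#' locus (so "A A" at an A/G SNP reads as dosage 2). The breed label is taken
#' from the family-ID column.
#'
#' @param path_prefix path without extension; companion files are derived.
#' @param dialect `"binary"` (.bed/.bim/.fam) or `"text"` (.ped/.map).
#' @return a [geno_dataset].
#' @export
read_genotypes <- function(path_prefix, dialect = c("binary", "text")) {
  dialect <- match.arg(dialect)
  if (dialect == "binary") read_plink_bed(path_prefix) else
    read_plink_ped(path_prefix)
}

#' Write genotypes in PLINK dialects
#'
#' The binary dialect is bit-exact re-readable (pad bits of the last byte per
#' SNP are zero, as PLINK writes them). Text output encodes dosage d at each
#' locus as d copies of `allele1` and 2-d copies of `allele2`; missing calls
#' become "0 0". Re-reading text output reproduces the dataset whenever
#' `allele1` sorts alphabetically before `allele2` (the text dialect itself
#' carries no allele order).
#'
#' @param ds a [geno_dataset]; must contain at least one sample and one SNP.
#' @param path_prefix output path without extension.
#' @param dialect `"binary"` or `"text"`.
#' @return invisibly, the character vector of files written.
#' @export
write_genotypes <- function(ds, path_prefix, dialect = c("binary", "text")) {
  dialect <- match.arg(dialect)
  if (n_samples(ds) == 0L || n_loci(ds) == 0L) {
    stop("refusing to write an empty dataset")
  }
  if (dialect == "binary") write_plink_bed(ds, path_prefix) else
    write_plink_ped(ds, path_prefix)
}

## ---- binary dialect ------------------------------------------------------

BED_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))

# 2-bit genotype codes of the v1.00 SNP-major format, sample index filling
# the low bits of each byte first: 00 hom A1, 01 missing, 10 het, 11 hom A2.
bed_decode_lut <- function() {
  lut <- matrix(NA_integer_, nrow = 256L, ncol = 4L)
  code2dose <- c(`0` = 2L, `1` = NA_integer_, `2` = 1L, `3` = 0L)
  for (b in 0:255) {
    for (s in 0:3) {
      code <- bitwAnd(bitwShiftR(b, 2L * s), 3L)
      lut[b + 1L, s + 1L] <- code2dose[[as.character(code)]]
    }
  }
  lut
}
.io_cache <- new.env(parent = emptyenv())

read_plink_bed <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  miss <- paths[!file.exists(paths)]
  if (length(miss)) stop("missing companion file(s): ",
                         paste(miss, collapse = ", "))
  bim <- utils::read.table(paths[2L], header = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  names(bim) <- c("chrom", "snp_id", "cm", "pos_bp", "allele1", "allele2")
  fam <- utils::read.table(paths[3L], header = FALSE,
                           colClasses = "character")
  names(fam)[1:2] <- c("breed", "sample_id")

  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(paths[1L], what = "raw", n = file.size(paths[1L]))
  if (length(raw) < 3L || !identical(raw[1:3], BED_MAGIC)) {
    stop("not a v1.00 SNP-major bed: bad magic bytes in ", paths[1L])
  }
  bps <- as.integer(ceiling(n / 4))
  payload <- raw[-(1:3)]
  if (length(payload) != bps * m) {
    stop(".bed payload has ", length(payload), " bytes, expected ", bps * m)
  }
  if (is.null(.io_cache$lut)) .io_cache$lut <- bed_decode_lut()
  # decode all bytes at once, then drop the pad slots of each SNP block
  dose <- .io_cache$lut[as.integer(payload) + 1L, , drop = FALSE] # (bps*m) x 4
  dose <- matrix(t(dose), nrow = 4L * bps)                        # slots x m
  calls <- dose[seq_len(n), , drop = FALSE]                       # n x m
  geno_dataset(calls,
               map = bim[, c("snp_id", "chrom", "pos_bp",
                             "allele1", "allele2")],
               fam = data.frame(sample_id = fam$sample_id, breed = fam$breed,
                                stringsAsFactors = FALSE))
}

write_plink_bed <- function(ds, prefix) {
  n <- n_samples(ds)
  m <- n_loci(ds)
  bps <- as.integer(ceiling(n / 4))
  # dosage -> 2-bit code; NA -> 01
  code <- matrix(1L, nrow = 4L * bps, ncol = m)  # default: pad bits 00 later
  g <- ds$calls
  cmap <- function(d) ifelse(is.na(d), 1L, c(3L, 2L, 0L)[d + 1L])
  code[seq_len(n), ] <- cmap(g)
  if (4L * bps > n) code[(n + 1L):(4L * bps), ] <- 0L  # pad samples = 00
  # pack 4 codes per byte, low bits first
  i4 <- seq_len(bps)
  b <- code[4L * (i4 - 1L) + 1L, , drop = FALSE] +
    4L * code[4L * (i4 - 1L) + 2L, , drop = FALSE] +
    16L * code[4L * (i4 - 1L) + 3L, , drop = FALSE] +
    64L * code[4L * (i4 - 1L) + 4L, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(BED_MAGIC, con)
  writeBin(as.raw(b), con)
  bim <- data.frame(ds$map$chrom, ds$map$snp_id, 0, ds$map$pos_bp,
                    ds$map$allele1, ds$map$allele2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  fam <- data.frame(ds$fam$breed, ds$fam$sample_id, 0, 0, 0, -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
}

## ---- text dialect --------------------------------------------------------

read_plink_ped <- function(prefix) {
  paths <- paste0(prefix, c(".ped", ".map"))
  miss <- paths[!file.exists(paths)]
  if (length(miss)) stop("missing companion file(s): ",
                         paste(miss, collapse = ", "))
  map <- utils::read.table(paths[2L], header = FALSE,
                           colClasses = c("character", "character",
                                          "numeric", "integer"))
  names(map) <- c("chrom", "snp_id", "cm", "pos_bp")
  m <- nrow(map)

  lines <- readLines(paths[1L])
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * m
  lens <- lengths(toks)
  if (any(lens != want)) {
    stop("ragged .ped row(s): row ", which(lens != want)[1L], " has ",
         lens[lens != want][1L], " fields, expected ", want)
  }
  ped <- do.call(rbind, toks)
  fam <- data.frame(sample_id = ped[, 2L], breed = ped[, 1L],
                    stringsAsFactors = FALSE)
  a_mat <- ped[, -(1:6), drop = FALSE]
  n <- nrow(a_mat)
  calls <- matrix(NA_integer_, n, m)
  allele1 <- allele2 <- character(m)
  for (j in seq_len(m)) {
    a <- a_mat[, 2L * j - 1L]
    b <- a_mat[, 2L * j]
    ok <- a != "0" & b != "0"
    obs <- sort(unique(c(a[ok], b[ok])))
    if (length(obs) > 2L) {
      stop("more than two alleles at SNP ", map$snp_id[j])
    }
    if (length(obs) == 2L) {
      a1 <- obs[1L]
      a2 <- obs[2L]
      calls[ok, j] <- (a[ok] == a1) + (b[ok] == a1)
    } else {
      # monomorphic (or all-missing) locus: the counted allele is unknown,
      # mirroring PLINK's missing A1 code; every non-missing call is hom a2
      a1 <- "0"
      a2 <- if (length(obs)) obs[1L] else "0"
      calls[ok, j] <- 0L
    }
    allele1[j] <- a1
    allele2[j] <- a2
  }
  geno_dataset(calls,
               map = data.frame(snp_id = map$snp_id, chrom = map$chrom,
                                pos_bp = map$pos_bp, allele1 = allele1,
                                allele2 = allele2, stringsAsFactors = FALSE),
               fam = fam)
}

write_plink_ped <- function(ds, prefix) {
  n <- n_samples(ds)
  m <- n_loci(ds)
  a1 <- ds$map$allele1
  a2 <- ds$map$allele2
  cols <- vector("list", m)
  for (j in seq_len(m)) {
    d <- ds$calls[, j]
    s <- character(n)
    s[!is.na(d) & d == 2L] <- paste(a1[j], a1[j])
    s[!is.na(d) & d == 1L] <- paste(a1[j], a2[j])
    s[!is.na(d) & d == 0L] <- paste(a2[j], a2[j])
    s[is.na(d)] <- "0 0"
    if (any(!is.na(d) & d > 0L & a1[j] == "0")) {
      stop("cannot write dosage > 0 at SNP ", ds$map$snp_id[j],
           " whose allele1 is the placeholder '0'")
    }
    cols[[j]] <- s
  }
  body <- do.call(paste, cols)
  lead <- paste(ds$fam$breed, ds$fam$sample_id, 0, 0, 0, -9)
  writeLines(paste(lead, body), paste0(prefix, ".ped"))
  map <- data.frame(ds$map$chrom, ds$map$snp_id, 0, ds$map$pos_bp)
  utils::write.table(map, paste0(prefix, ".map"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(paste0(prefix, c(".ped", ".map")))
}

## ---- merging -------------------------------------------------------------

#' Merge two genotype datasets
#'
#' Returns the union of samples over the intersection of SNPs (matched by
#' `snp_id`). Chromosome and position must agree for shared SNPs. When the two
#' datasets count opposite alleles at a SNP, dosages of the second dataset are
#' flipped to `2 - d`; palindromic (A/T or C/G) SNPs needing a flip are
#' rejected because a strand flip cannot be told from an allele swap.
#'
#' @param a,b two [geno_dataset] objects with disjoint sample ids.
#' @return the merged [geno_dataset].
#' @export
merge_datasets <- function(a, b) {
  clash <- intersect(a$fam$sample_id, b$fam$sample_id)
  if (length(clash)) stop("sample id collision: ", clash[1L])
  shared <- intersect(a$map$snp_id, b$map$snp_id)
  if (!length(shared)) stop("no shared SNPs to merge on")
  ia <- match(shared, a$map$snp_id)
  ib <- match(shared, b$map$snp_id)
  ma <- a$map[ia, ]
  mb <- b$map[ib, ]
  bad <- ma$chrom != mb$chrom | ma$pos_bp != mb$pos_bp
  if (any(bad)) {
    stop("inconsistent map for SNP ", shared[which(bad)[1L]],
         " (chromosome/position differ between inputs)")
  }
  gb <- b$calls[, ib, drop = FALSE]
  allele1 <- ma$allele1
  allele2 <- ma$allele2
  for (k in seq_along(shared)) {
    pa <- c(ma$allele1[k], ma$allele2[k])
    pb <- c(mb$allele1[k], mb$allele2[k])
    if (alleles_equal(pa, pb)) next
    if (alleles_equal(pa, rev(pb))) {
      if (is_palindromic(pa)) {
        stop("strand-ambiguous allele swap at SNP ", shared[k],
             " (", pa[1L], "/", pa[2L], "): cannot reconcile")
      }
      gb[, k] <- 2L - gb[, k]
    } else {
      stop("allele mismatch at SNP ", shared[k], ": ",
           paste(pa, collapse = "/"), " vs ", paste(pb, collapse = "/"))
    }
  }
  geno_dataset(rbind(a$calls[, ia, drop = FALSE], gb),
               map = data.frame(snp_id = shared, chrom = ma$chrom,
                                pos_bp = ma$pos_bp, allele1 = allele1,
                                allele2 = allele2, stringsAsFactors = FALSE),
               fam = rbind(a$fam, b$fam))
}

# "0" is the unknown-allele placeholder and matches anything
alleles_equal <- function(x, y) {
  all(x == y | x == "0" | y == "0")
}

is_palindromic <- function(pair) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  p <- toupper(pair)
  all(p %in% names(comp)) && identical(unname(comp[p[1L]]), p[2L])
}
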