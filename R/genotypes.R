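#' Mouse-proportioned default chromosome lengths
#'
#' Lengths in base pairs for 19 autosomes plus X, proportional to the house
#' mouse genome. A `scale` below 1 shrinks every chromosome for quick
#' simulations while preserving relative sizes.
#'
#' @param scale Multiplier applied to all lengths (default 1 = full size).
#' @return Named numeric vector of lengths (bp); names `"1"`..`"19"`, `"X"`.
#' @export
#' @examples
#' default_chrom_lengths(scale = 0.1)[c("1", "X")]
default_chrom_lengths <- function(scale = 1) {
  mb <- c(195.5, 182.1, 160.0, 156.5, 151.8, 149.7, 145.4, 129.4, 124.6,
          130.7, 122.1, 120.1, 120.4, 124.9, 104.0, 98.2, 94.9, 90.7, 61.4,
          171.0)
  out <- round(mb * 1e6 * scale)
  names(out) <- c(as.character(1:19), "X")
  out
}

#' Construct an admixed genotype set
#'
#' The central genotype container: an individuals x SNPs matrix of counts of
#' the *musculus* allele (0/1/2, `NA` = missing) together with a SNP map and
#' per-individual sex. Males are hemizygous on the X; their X genotypes are
#' coded 0/2 (diploid-homozygote convention) so one code path handles all
#' chromosomes.
#'
#' @param matrix Integer matrix, individuals x SNPs; rownames = individual
#'   ids, values in `{0, 1, 2, NA}`.
#' @param map Data frame with columns `snp_id`, `chrom` (`"1"`..`"19"`,
#'   `"X"`), `pos` (1-based bp); one row per matrix column, positions
#'   strictly increasing within chromosome.
#' @param sex Character vector per individual, `"M"` or `"F"`.
#' @param x_coding `"02"` (default, hemizygotes as 0/2) or `"01"`.
#' @return An object of class `admixed_genotypes`.
#' @export
admixed_genotypes <- function(matrix, map, sex = NULL, x_coding = c("02", "01")) {
  x_coding <- match.arg(x_coding)
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "integer"
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(map)))
  map$snp_id <- as.character(map$snp_id)
  map$chrom <- as.character(map$chrom)
  map$pos <- as.numeric(map$pos)
  if (nrow(map) != ncol(matrix))
    stop("map must have one row per genotype column", call. = FALSE)
  if (anyDuplicated(map$snp_id))
    stop("snp_ids must be unique", call. = FALSE)
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch,
           call. = FALSE)
  }
  bad <- !(matrix %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA", call. = FALSE)
  if (is.null(sex)) sex <- rep("M", nrow(matrix))
  sex <- toupper(as.character(sex))
  stopifnot(length(sex) == nrow(matrix), all(sex %in% c("M", "F")))
  if (is.null(rownames(matrix)))
    rownames(matrix) <- sprintf("ind%03d", seq_len(nrow(matrix)))
  colnames(matrix) <- map$snp_id
  if (x_coding == "02") {
    xc <- map$chrom == "X"
    if (any(xc) && any(sex == "M")) {
      het <- matrix[sex == "M", xc, drop = FALSE] == 1L
      if (any(het, na.rm = TRUE))
        stop("male X genotypes must be hemizygous (0/2 coding)", call. = FALSE)
    }
  }
  structure(list(matrix = matrix, map = map, sex = sex, x_coding = x_coding),
            class = "admixed_genotypes")
}

#' @export
print.admixed_genotypes <- function(x, ...) {
  cat(sprintf("Admixed genotypes: %d individuals x %d SNPs\n",
              nrow(x$matrix), ncol(x$matrix)))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$map$chrom), collapse = " ")))
  cat(sprintf("  males: %d, females: %d; missing genotypes: %.2f%%\n",
              sum(x$sex == "M"), sum(x$sex == "F"),
              100 * mean(is.na(x$matrix))))
  invisible(x)
}

#' @export
dim.admixed_genotypes <- function(x) dim(x$matrix)

#' Subset an admixed genotype set
#'
#' @param x An `admixed_genotypes` object.
#' @param i Individual index (rows). @param j SNP index (columns).
#' @param ... Unused.
#' @return An `admixed_genotypes` with the selected individuals/SNPs.
#' @export
`[.admixed_genotypes` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$matrix))
  if (missing(j)) j <- seq_len(ncol(x$matrix))
  admixed_genotypes(x$matrix[i, j, drop = FALSE], x$map[j, , drop = FALSE],
                    x$sex[i], x$x_coding)
}

n_ind <- function(g) nrow(g$matrix)
n_snp <- function(g) ncol(g$matrix)
autosomal <- function(g) g$map$chrom != "X"

snp_index <- function(g, snp_id) {
  idx <- match(snp_id, g$map$snp_id)
  if (anyNA(idx))
    stop("SNP(s) not found in map: ",
         paste(snp_id[is.na(idx)], collapse = ", "), call. = FALSE)
  idx
}

# Per-SNP allele frequency of the musculus allele (counts/2n), NA-aware.
allele_freq <- function(mat) colMeans(mat, na.rm = TRUE) / 2

# Minor allele frequency per SNP.
maf <- function(mat) {
  f <- allele_freq(mat)
  pmin(f, 1 - f)
}

# --- TSV genotype dialect -------------------------------------------------
# header: snp_id, chrom, pos, then one column per individual. Missing = NA.

#' Write/read genotypes in the package's TSV dialect
#'
#' Plain-text matrix transposed to SNPs x individuals with leading `snp_id`,
#' `chrom`, `pos` columns. Sex is stored in a companion `<path>.sex` file.
#'
#' @param g An `admixed_genotypes` object.
#' @param path Output/input file path.
#' @return `write_genotypes_tsv` returns `path` invisibly;
#'   `read_genotypes_tsv` returns an `admixed_genotypes`.
#' @export
write_genotypes_tsv <- function(g, path) {
  df <- cbind(g$map[, c("snp_id", "chrom", "pos")],
              as.data.frame(t(g$matrix)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(id = rownames(g$matrix), sex = g$sex),
                     paste0(path, ".sex"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  map <- data.frame(snp_id = df$snp_id, chrom = df$chrom,
                    pos = as.numeric(df$pos), stringsAsFactors = FALSE)
  gm <- as.matrix(df[, -(1:3), drop = FALSE])
  storage.mode(gm) <- "integer"
  mat <- t(gm)  # individuals x SNPs
  rownames(mat) <- colnames(df)[-(1:3)]
  sexf <- paste0(path, ".sex")
  sex <- if (file.exists(sexf)) {
    s <- utils::read.table(sexf, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
    s$sex[match(rownames(mat), s$id)]
  } else NULL
  admixed_genotypes(mat, map, sex)
}

# --- phenotype and pedigree TSVs -----------------------------------------

#' Write/read a phenotype table
#'
#' One row per individual; first column `individual_id`, remaining columns
#' numeric phenotypes. Duplicate ids are rejected on read.
#'
#' @param pheno Data frame with `individual_id` plus numeric columns.
#' @param path File path.
#' @export
write_phenotypes_tsv <- function(pheno, path) {
  stopifnot("individual_id" %in% names(pheno))
  utils::write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes_tsv
#' @export
read_phenotypes_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!"individual_id" %in% names(df))
    stop("phenotype TSV must have an `individual_id` column", call. = FALSE)
  dup <- df$individual_id[duplicated(df$individual_id)]
  if (length(dup))
    stop("duplicate individual_id in phenotype TSV: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  df
}

#' Write/read a pedigree table (id, dam, sire, sex)
#' @param ped Data frame with columns `id`, `dam`, `sire`, `sex`.
#' @param path File path.
#' @export
write_pedigree_tsv <- function(ped, path) {
  utils::write.table(ped[, c("id", "dam", "sire", "sex")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pedigree_tsv
#' @export
read_pedigree_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write/read a kinship matrix as square TSV with id header
#' @param K Symmetric numeric matrix with dimnames.
#' @param path File path.
#' @export
write_kinship_tsv <- function(K, path) {
  utils::write.table(K, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_kinship_tsv
#' @export
read_kinship_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}

# --- PLINK .bed/.bim/.fam -------------------------------------------------

#' Write/read PLINK binary genotype files
#'
#' Minimal SNP-major .bed/.bim/.fam support. The musculus allele is written
#' as allele "A1" (the counted allele), the alternate as "A2"; counts of A1
#' map to the PLINK 2-bit codes.
#'
#' @param g An `admixed_genotypes` object.
#' @param prefix Path prefix (files `<prefix>.bed/.bim/.fam` are written).
#' @return `write_plink` returns `prefix` invisibly; `read_plink` an
#'   `admixed_genotypes`.
#' @export
write_plink <- function(g, prefix) {
  mat <- g$matrix
  n <- nrow(mat); p <- ncol(mat)
  bim <- data.frame(chrom = ifelse(g$map$chrom == "X", "23", g$map$chrom),
                    snp_id = g$map$snp_id, cm = 0, pos = g$map$pos,
                    a1 = "A", a2 = "G")
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = rownames(mat), iid = rownames(mat), pat = 0,
                    mat = 0, sex = ifelse(g$sex == "M", 1L, 2L), pheno = -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  # bed codes per 2 bits: 00=hom A1 (2 copies), 10=het, 11=hom A2, 01=missing
  code <- matrix(3L, n, p)
  code[!is.na(mat) & mat == 2L] <- 0L
  code[!is.na(mat) & mat == 1L] <- 2L
  code[is.na(mat)] <- 1L
  bytes_per_snp <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- 4L * bytes_per_snp - n
  for (j in seq_len(p)) {
    cj <- c(code[, j], rep(3L, pad))
    quads <- matrix(cj, nrow = 4L)
    byte <- quads[1, ] + quads[2, ] * 4L + quads[3, ] * 16L + quads[4, ] * 64L
    writeBin(as.raw(byte), con)
  }
  invisible(prefix)
}

#' @rdname write_plink
#' @export
read_plink <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"), sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "pos",
                                         "a1", "a2"))
  fam <- utils::read.table(paste0(prefix, ".fam"), sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("fid", "iid", "pat", "mat", "sex",
                                         "pheno"))
  n <- nrow(fam); p <- nrow(bim)
  bytes_per_snp <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a SNP-major PLINK .bed file", call. = FALSE)
  raw <- readBin(con, "raw", bytes_per_snp * p)
  b <- as.integer(raw)
  quads <- rbind(b %% 4L, (b %/% 4L) %% 4L, (b %/% 16L) %% 4L,
                 (b %/% 64L) %% 4L)
  codes <- matrix(as.vector(quads), nrow = 4L * bytes_per_snp)[seq_len(n), ,
                                                               drop = FALSE]
  mat <- matrix(NA_integer_, n, p)
  mat[codes == 0L] <- 2L
  mat[codes == 2L] <- 1L
  mat[codes == 3L] <- 0L
  rownames(mat) <- fam$iid
  map <- data.frame(snp_id = bim$snp_id,
                    chrom = ifelse(bim$chrom == "23", "X",
                                   as.character(bim$chrom)),
                    pos = bim$pos, stringsAsFactors = FALSE)
  admixed_genotypes(mat, map, sex = ifelse(fam$sex == 1L, "M", "F"))
}

# --- BED interval export/import (0-based half-open) ----------------------

#' Export/import region sets as BED
#'
#' Regions are held 1-based inclusive internally and converted to the
#' 0-based half-open BED convention on write (and back on read).
#'
#' @param regions Data frame with `chrom`, `start`, `end` (1-based
#'   inclusive) and optionally `region_id`.
#' @param path File path.
#' @export
write_regions_bed <- function(regions, path) {
  df <- data.frame(chrom = regions$chrom,
                   start = as.integer(regions$start) - 1L,
                   end = as.integer(regions$end),
                   name = regions$region_id %||%
                     sprintf("region%03d", seq_len(nrow(regions))))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_regions_bed
#' @export
read_regions_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  out <- data.frame(region_id = if (ncol(df) >= 4) df[[4]] else
                      sprintf("region%03d", seq_len(nrow(df))),
                    chrom = as.character(df$chrom),
                    start = df$start + 1L, end = df$end,
                    stringsAsFactors = FALSE)
  out
}
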