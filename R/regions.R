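# Significant-SNP regions: LD-defined intervals, <10 Mb merging, interval
# overlap counting and the region-shuffle permutation test.

#' Genotypic (composite) LD between two SNPs
#'
#' Squared Pearson correlation of genotype codes, computed on pairwise
#' complete individuals — no phasing required.
#'
#' @param genotypes An `admixed_genotypes` object.
#' @param snp_a,snp_b SNP ids.
#' @return r^2 in \[0, 1\], or NA when either SNP is monomorphic or fewer
#'   than 2 complete pairs exist.
#' @export
genotypic_ld_r2 <- function(genotypes, snp_a, snp_b) {
  i <- snp_index(genotypes, snp_a)
  j <- snp_index(genotypes, snp_b)
  x <- genotypes$matrix[, i]
  y <- genotypes$matrix[, j]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])^2
}

# r^2 of one SNP against a set of columns (pairwise complete), vectorized
r2_vs_set <- function(mat, i, js) {
  x <- mat[, i]
  vapply(js, function(j) {
    y <- mat[, j]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(NA_real_)
    stats::cor(x[ok], y[ok])^2
  }, numeric(1))
}

#' Define significant genomic regions from significant SNPs
#'
#' Each significant SNP is expanded to the interval spanning all SNPs in
#' the full (unpruned) dataset on the same chromosome with r^2 above
#' `r2_flank` to it; intervals from significant SNPs less than
#' `merge_distance_bp` apart are unioned into one region. A significant
#' SNP with no linked neighbors yields a single-position (1 bp) region.
#'
#' @param sig_snps Character vector of significant SNP ids (must exist in
#'   the full map).
#' @param all_genotypes The full `admixed_genotypes` object used for LD.
#' @param r2_flank LD threshold for flanking SNPs (default 0.9).
#' @param merge_distance_bp Merge distance (default 10 Mb).
#' @param sig_perm_snps Optional ids significant at the stringent
#'   permutation threshold, counted per region.
#' @return Data frame of class `hz_regions`: `region_id`, `chrom`,
#'   `start`, `end` (1-based inclusive), `n_sig_snps`, `n_sig_perm`,
#'   `snp_ids` (comma-separated members).
#' @export
define_regions <- function(sig_snps, all_genotypes, r2_flank = 0.9,
                           merge_distance_bp = 10e6,
                           sig_perm_snps = character()) {
  if (length(sig_snps) == 0L)
    return(structure(data.frame(region_id = character(), chrom = character(),
                                start = numeric(), end = numeric(),
                                n_sig_snps = integer(), n_sig_perm = integer(),
                                snp_ids = character(),
                                stringsAsFactors = FALSE),
                     class = c("hz_regions", "data.frame")))
  map <- all_genotypes$map
  idx <- snp_index(all_genotypes, sig_snps)
  iv <- lapply(seq_along(idx), function(k) {
    i <- idx[k]
    same <- which(map$chrom == map$chrom[i])
    r2 <- r2_vs_set(all_genotypes$matrix, i, same)
    linked <- same[!is.na(r2) & r2 > r2_flank]
    rng <- range(map$pos[c(i, linked)])
    data.frame(chrom = map$chrom[i], start = rng[1], end = rng[2],
               snp_id = sig_snps[k], stringsAsFactors = FALSE)
  })
  iv <- do.call(rbind, iv)
  out <- list()
  for (ch in unique(iv$chrom)) {
    v <- iv[iv$chrom == ch, , drop = FALSE]
    v <- v[order(v$start, v$end), , drop = FALSE]
    cur <- v[1, ]; members <- v$snp_id[1]
    flush <- function(cur, members) {
      data.frame(chrom = ch, start = cur$start, end = cur$end,
                 n_sig_snps = length(members),
                 n_sig_perm = sum(members %in% sig_perm_snps),
                 snp_ids = paste(sort(members), collapse = ","),
                 stringsAsFactors = FALSE)
    }
    if (nrow(v) > 1) for (r in 2:nrow(v)) {
      if (v$start[r] - cur$end < merge_distance_bp) {
        cur$end <- max(cur$end, v$end[r])
        cur$start <- min(cur$start, v$start[r])
        members <- c(members, v$snp_id[r])
      } else {
        out[[length(out) + 1L]] <- flush(cur, members)
        cur <- v[r, ]; members <- v$snp_id[r]
      }
    }
    out[[length(out) + 1L]] <- flush(cur, members)
  }
  res <- do.call(rbind, out)
  chr_order <- order(match(res$chrom, c(as.character(1:19), "X")), res$start)
  res <- res[chr_order, , drop = FALSE]
  res <- cbind(region_id = sprintf("R%02d", seq_len(nrow(res))), res,
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("hz_regions", "data.frame")
  res
}

#' @export
print.hz_regions <- function(x, ...) {
  cat(sprintf("Significant regions: %d\n", nrow(x)))
  if (nrow(x)) {
    df <- data.frame(region = x$region_id, chrom = x$chrom,
                     Mb = sprintf("%.2f-%.2f", x$start / 1e6, x$end / 1e6),
                     length_kb = round((x$end - x$start + 1) / 1e3, 1),
                     sig_snps = x$n_sig_snps, sig_perm = x$n_sig_perm)
    print.data.frame(df, row.names = FALSE)
  }
  invisible(x)
}

#' Count regions in one set overlapping another
#'
#' Number of regions in `regions_a` that intersect at least one region in
#' `regions_b` (same chromosome, 1-based inclusive interval intersection).
#'
#' @param regions_a,regions_b Region data frames (`chrom`, `start`, `end`).
#' @return Integer count.
#' @export
count_overlaps <- function(regions_a, regions_b) {
  if (nrow(regions_a) == 0L || nrow(regions_b) == 0L) return(0L)
  hits <- vapply(seq_len(nrow(regions_a)), function(i) {
    b <- regions_b[regions_b$chrom == regions_a$chrom[i], , drop = FALSE]
    any(b$start <= regions_a$end[i] & b$end >= regions_a$start[i])
  }, logical(1))
  sum(hits)
}

# place region lengths uniformly at random in the genome; chromosome chosen
# with probability proportional to length among chromosomes that fit, no
# overlap among placed regions
shuffle_regions <- function(lengths, chrom_lengths, allow_reassign = TRUE,
                            orig_chrom = NULL, max_tries = 1000L) {
  placed <- data.frame(chrom = character(), start = numeric(),
                       end = numeric(), stringsAsFactors = FALSE)
  for (k in seq_along(lengths)) {
    len <- lengths[k]
    ok_ch <- names(chrom_lengths)[chrom_lengths >= len]
    if (length(ok_ch) == 0L)
      stop("region longer than every chromosome", call. = FALSE)
    if (!allow_reassign) ok_ch <- orig_chrom[k]
    for (t in seq_len(max_tries)) {
      ch <- if (length(ok_ch) == 1L) ok_ch else
        sample(ok_ch, 1L, prob = chrom_lengths[ok_ch])
      start <- floor(stats::runif(1, 1, chrom_lengths[[ch]] - len + 2))
      end <- start + len - 1
      clash <- any(placed$chrom == ch & placed$start <= end &
                     placed$end >= start)
      if (!clash) break
    }
    placed <- rbind(placed, data.frame(chrom = ch, start = start, end = end,
                                       stringsAsFactors = FALSE))
  }
  placed
}

#' Region-shuffle permutation test of co-localization
#'
#' Shuffles the positions of `regions_a` uniformly in the genome
#' (chromosome re-assignment with probability proportional to chromosome
#' length, lengths preserved, shuffled regions non-overlapping) and counts
#' overlaps with the fixed `regions_b` each time. The empirical p value is
#' `(1 + #permutations with count >= observed) / (n_perm + 1)`.
#'
#' @param regions_a Region set to shuffle.
#' @param regions_b Fixed region set.
#' @param chrom_lengths Named chromosome lengths (bp).
#' @param n_perm Number of shuffles (default 1000).
#' @param allow_chrom_reassign Allow regions to move between chromosomes
#'   (default TRUE).
#' @param seed Optional integer seed.
#' @return List: `p_value`, `observed`, `null_counts`.
#' @export
overlap_permutation_test <- function(regions_a, regions_b, chrom_lengths,
                                     n_perm = 1000,
                                     allow_chrom_reassign = TRUE,
                                     seed = NULL) {
  check_count(n_perm, "n_perm")
  lengths <- regions_a$end - regions_a$start + 1
  if (any(lengths > max(chrom_lengths)))
    stop("region longer than every chromosome", call. = FALSE)
  observed <- count_overlaps(regions_a, regions_b)
  with_seed(seed, {
    null_counts <- vapply(seq_len(n_perm), function(i) {
      shuf <- shuffle_regions(lengths, chrom_lengths,
                              allow_reassign = allow_chrom_reassign,
                              orig_chrom = regions_a$chrom)
      count_overlaps(shuf, regions_b)
    }, numeric(1))
    list(p_value = (1 + sum(null_counts >= observed)) / (n_perm + 1),
         observed = observed, null_counts = null_counts)
  })
}
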