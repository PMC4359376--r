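# Permutation-based chromosome-class significance thresholds, BH-FDR
# thresholds, and the trans-association enrichment rule.

#' Permutation-based significance thresholds
#'
#' Randomizes the phenotype among individuals `n_perm` times, rescans, and
#' records the lowest Wald p value over autosomal SNPs and over X SNPs
#' separately for each permutation. Thresholds are the `percentile`
#' quantile (default 5th) of the two min-p distributions; autosomes and X
#' are thresholded separately because male X hemizygosity changes the
#' test's null. Phenotypes are permuted against genotypes and kinship
#' jointly (simple randomization); `mode = "preserve_kinship"` instead
#' carries kinship rows along with the phenotype, breaking only the
#' phenotype-genotype link (slower: one eigendecomposition per
#' permutation).
#'
#' @param genotypes An `admixed_genotypes` object.
#' @param y Phenotype vector.
#' @param kinship Kinship matrix (default [centered_kinship()]).
#' @param n_perm Number of permutations (the reference analysis used
#'   10,000; smaller values are fine for exploratory runs).
#' @param percentile Quantile of the min-p distributions (default 0.05).
#' @param mode `"simple"` (default) or `"preserve_kinship"`.
#' @param seed Optional integer seed.
#' @param reml Use REML variance components.
#' @return List of class `hz_thresholds`: `autosome_p_threshold`,
#'   `x_p_threshold` (NA when no X SNPs), `percentile`, `n_permutations`,
#'   and the per-permutation minima `min_p_autosome`, `min_p_x`.
#' @export
permutation_thresholds <- function(genotypes, y, kinship = NULL,
                                   n_perm = 1000, percentile = 0.05,
                                   mode = c("simple", "preserve_kinship"),
                                   seed = NULL, reml = TRUE) {
  mode <- match.arg(mode)
  check_count(n_perm, "n_perm")
  check_fraction(percentile, "percentile")
  y <- as.numeric(y)
  keep <- which(!is.na(y))
  genotypes <- genotypes[keep, ]
  y <- y[keep]
  if (is.null(kinship)) kinship <- centered_kinship(genotypes)
  else kinship <- as.matrix(kinship)[keep, keep]
  auto <- autosomal(genotypes)
  has_x <- any(!auto)
  with_seed(seed, {
    if (mode == "simple") {
      cache <- build_scan_cache(genotypes, kinship)
      mins <- vapply(seq_len(n_perm), function(i) {
        p <- scan_with_cache(cache, sample(y), reml = reml)$p
        c(min(p[auto], na.rm = TRUE),
          if (has_x) min(p[!auto], na.rm = TRUE) else NA_real_)
      }, numeric(2))
    } else {
      mins <- vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(length(y))
        cache <- build_scan_cache(genotypes, kinship[idx, idx])
        p <- scan_with_cache(cache, y[idx], reml = reml)$p
        c(min(p[auto], na.rm = TRUE),
          if (has_x) min(p[!auto], na.rm = TRUE) else NA_real_)
      }, numeric(2))
    }
    structure(list(
      autosome_p_threshold = unname(stats::quantile(mins[1, ], percentile)),
      x_p_threshold = if (has_x)
        unname(stats::quantile(mins[2, ], percentile)) else NA_real_,
      percentile = percentile, n_permutations = n_perm,
      min_p_autosome = mins[1, ],
      min_p_x = if (has_x) mins[2, ] else NULL),
      class = "hz_thresholds")
  })
}

#' @export
print.hz_thresholds <- function(x, ...) {
  cat(sprintf(
    "Permutation thresholds (%d permutations, %g%% percentile):\n",
    x$n_permutations, 100 * x$percentile))
  cat(sprintf("  autosomes: p < %.3g\n", x$autosome_p_threshold))
  cat(sprintf("  X:         p < %.3g\n", x$x_p_threshold))
  invisible(x)
}

#' Benjamini-Hochberg FDR threshold
#'
#' Step-up procedure at level `q`: with sorted p values p(1) <= ... <=
#' p(m), the equivalent p cutoff is the largest p(i) <= (i/m) q, and all p
#' values at or below it are flagged significant. NAs are excluded from m
#' and flagged FALSE.
#'
#' @param p_values Numeric p values in (0, 1].
#' @param q FDR level (default 0.1).
#' @return List: `equivalent_p_cutoff` (0 when nothing passes),
#'   `significant` logical vector aligned with input, `q`, `m`.
#' @export
bh_fdr_threshold <- function(p_values, q = 0.1) {
  check_fraction(q, "q")
  if (length(p_values) == 0L) stop("empty p value vector", call. = FALSE)
  ok <- !is.na(p_values)
  m <- sum(ok)
  if (m == 0L) stop("all p values missing", call. = FALSE)
  ps <- sort(p_values[ok])
  pass <- which(ps <= seq_len(m) / m * q)
  cutoff <- if (length(pass)) ps[max(pass)] else 0
  sig <- !is.na(p_values) & p_values <= cutoff
  list(equivalent_p_cutoff = cutoff, significant = sig, q = q, m = m)
}

#' Trans-association enrichment threshold
#'
#' Flags SNPs whose count of significantly associated different-chromosome
#' transcripts is at least the `percentile` quantile of counts across all
#' SNPs, with a floor of `min_count` transcripts.
#'
#' @param counts Integer vector: per-SNP significant trans-transcript
#'   counts.
#' @param percentile Quantile across SNPs (default 0.95).
#' @param min_count Floor on the count threshold (default 30).
#' @return List: `count_threshold`, `enriched` logical vector.
#' @export
trans_enrichment_threshold <- function(counts, percentile = 0.95,
                                       min_count = 30) {
  check_fraction(percentile, "percentile")
  thr <- max(stats::quantile(counts, percentile, na.rm = TRUE), min_count)
  list(count_threshold = unname(thr),
       enriched = !is.na(counts) & counts >= thr)
}

#' Assemble a full threshold set for one phenotype scan
#'
#' Combines permutation-based chromosome-class thresholds with the BH-FDR
#' equivalent p cutoff computed from the observed scan.
#'
#' @param perm An `hz_thresholds` object from [permutation_thresholds()].
#' @param scan_p Observed scan p values.
#' @param fdr_q FDR level (default 0.1).
#' @return List of class `hz_threshold_set` with both permutation
#'   thresholds, `fdr_q`, `fdr_equivalent_p` and `n_permutations`.
#' @export
threshold_set <- function(perm, scan_p, fdr_q = 0.1) {
  bh <- bh_fdr_threshold(scan_p, q = fdr_q)
  structure(list(autosome_p_threshold = perm$autosome_p_threshold,
                 x_p_threshold = perm$x_p_threshold, fdr_q = fdr_q,
                 fdr_equivalent_p = bh$equivalent_p_cutoff,
                 n_permutations = perm$n_permutations),
            class = "hz_threshold_set")
}

#' @export
print.hz_threshold_set <- function(x, ...) {
  cat("Significance thresholds:\n")
  cat(sprintf("  permutation (%d perms): autosomes p < %.3g, X p < %.3g\n",
              x$n_permutations, x$autosome_p_threshold, x$x_p_threshold))
  cat(sprintf("  FDR < %g equivalent: p <= %.3g\n", x$fdr_q,
              x$fdr_equivalent_p))
  invisible(x)
}

#' Flag significant SNPs under a threshold set
#'
#' Applies either the stringent permutation rule (chromosome-class
#' specific: autosomal SNPs against the autosomal threshold, X SNPs
#' against the X threshold) or the permissive FDR cutoff.
#'
#' @param scan An `hz_assoc` scan result (needs `chrom` and `p_wald`).
#' @param thresholds An `hz_threshold_set` from [threshold_set()].
#' @param rule `"fdr"` (default) or `"permutation"`.
#' @return Logical vector over scan rows.
#' @export
significant_snps <- function(scan, thresholds,
                             rule = c("fdr", "permutation")) {
  rule <- match.arg(rule)
  if (rule == "permutation") {
    thr <- ifelse(scan$chrom == "X", thresholds$x_p_threshold,
                  thresholds$autosome_p_threshold)
    !is.na(scan$p_wald) & scan$p_wald < thr
  } else {
    !is.na(scan$p_wald) & scan$p_wald <= thresholds$fdr_equivalent_p &
      thresholds$fdr_equivalent_p > 0
  }
}
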