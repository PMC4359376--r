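# SNP filtering and LD pruning that define the mapping SNP set.

#' Filter SNPs on frequency, missingness and map position
#'
#' Retains SNPs with minor allele frequency strictly above `maf_min` in
#' the mapping population, missingness at most `missing_max` in the
#' mapping population and in each reference panel, and a defined genome
#' position. Every exclusion is logged with its reason.
#'
#' @param genotypes Mapping-population `admixed_genotypes`.
#' @param reference_panels Optional `subspecies_panels`; when supplied,
#'   panel missingness is checked too.
#' @param maf_min Minor-allele-frequency threshold, strict (default 0.05).
#' @param missing_max Maximum missing fraction (default 0.15).
#' @return List: `genotypes` (filtered), `log` (data frame `snp_id`,
#'   `reason` for every excluded SNP).
#' @export
filter_snps <- function(genotypes, reference_panels = NULL, maf_min = 0.05,
                        missing_max = 0.15) {
  check_fraction(maf_min, "maf_min")
  check_fraction(missing_max, "missing_max")
  mat <- genotypes$matrix
  map <- genotypes$map
  reason <- rep(NA_character_, ncol(mat))
  no_pos <- is.na(map$pos) | is.na(map$chrom)
  reason[no_pos] <- "no genome position"
  miss <- colMeans(is.na(mat))
  bad_miss <- is.na(reason) & miss > missing_max
  reason[bad_miss] <- sprintf("missingness %.3f > %.2f in mapping population",
                              miss[bad_miss], missing_max)
  if (!is.null(reference_panels)) {
    for (pn in c("domesticus", "musculus")) {
      pg <- reference_panels[[pn]]$genotypes
      idx <- match(map$snp_id, colnames(pg))
      pm <- rep(0, ncol(mat))
      pm[!is.na(idx)] <- colMeans(is.na(pg))[idx[!is.na(idx)]]
      bad <- is.na(reason) & pm > missing_max
      reason[bad] <- sprintf("missingness %.3f > %.2f in %s panel",
                             pm[bad], missing_max, pn)
    }
  }
  f <- maf(mat)
  bad_maf <- is.na(reason) & (is.na(f) | f <= maf_min)
  reason[bad_maf] <- sprintf("MAF %.3f <= %.2f", f[bad_maf], maf_min)
  keep <- is.na(reason)
  if (!any(keep))
    stop("no SNPs survive filtering", call. = FALSE)
  list(genotypes = genotypes[, which(keep)],
       log = data.frame(snp_id = map$snp_id[!keep],
                        reason = reason[!keep],
                        stringsAsFactors = FALSE))
}

# multiple R^2 of column j regressed on the other columns of (centered,
# imputed) matrix W; rank-deficient designs handled by lm.fit
multiple_r2 <- function(W, j) {
  yv <- W[, j]
  tss <- sum(yv^2)
  if (tss == 0) return(NA_real_)
  X <- W[, -j, drop = FALSE]
  fit <- stats::lm.fit(X, yv)
  max(0, min(1, 1 - sum(fit$residuals^2) / tss))
}

#' LD-prune SNPs with a sliding window
#'
#' Within each `window_snps`-SNP window (advanced by `step_snps`,
#' per chromosome), SNPs whose multiple correlation with the remaining
#' window SNPs exceeds `r2_max` are removed one at a time — the candidate
#' with the lowest minor allele frequency first, ties broken by removing
#' the later SNP in map order — until no SNP in the window exceeds the
#' threshold. With the default `r2_max = 0.999` this removes SNPs in
#' (essentially) perfect LD. Deterministic given the input order.
#'
#' @param genotypes An `admixed_genotypes` object.
#' @param window_snps Window size in SNPs (default 30).
#' @param step_snps Step size in SNPs (default 5).
#' @param r2_max Multiple-R^2 removal threshold (default 0.999).
#' @return The pruned `admixed_genotypes`.
#' @export
ld_prune <- function(genotypes, window_snps = 30, step_snps = 5,
                     r2_max = 0.999) {
  check_count(window_snps, "window_snps")
  check_count(step_snps, "step_snps")
  check_fraction(r2_max, "r2_max")
  if (window_snps < step_snps)
    stop("window_snps must be >= step_snps", call. = FALSE)
  W <- scale(mean_impute(genotypes$matrix), center = TRUE, scale = FALSE)
  f <- maf(genotypes$matrix)
  removed <- rep(FALSE, ncol(W))
  for (ch in unique(genotypes$map$chrom)) {
    chr_idx <- which(genotypes$map$chrom == ch)
    m <- length(chr_idx)
    starts <- if (m <= window_snps) 1L
              else unique(c(seq(1L, m - window_snps + 1L, by = step_snps),
                            m - window_snps + 1L))
    for (s in starts) {
      win <- chr_idx[s:min(s + window_snps - 1L, m)]
      repeat {
        active <- win[!removed[win]]
        if (length(active) < 2L) break
        r2 <- vapply(seq_along(active), function(k)
          multiple_r2(W[, active, drop = FALSE], k), numeric(1))
        cand <- which(!is.na(r2) & r2 > r2_max)
        if (length(cand) == 0L) break
        # drop the lowest-MAF offender; ties -> later map position
        ord <- order(f[active[cand]], -active[cand])
        removed[active[cand[ord[1L]]]] <- TRUE
      }
    }
  }
  genotypes[, which(!removed)]
}
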