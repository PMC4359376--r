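# Restricted pairwise Dobzhansky-Muller interaction testing among
# significant SNPs, two-locus effect sizes, and sterile-allele inference.

#' Pairwise interaction scan among significant SNPs
#'
#' Tests all pairs of significant SNPs located on different chromosomes.
#' For each pair the kinship mixed model
#' `y ~ g_a + g_b + g_a:g_b + u(K)` is fitted (variance ratio re-estimated
#' per pair by REML) and the Wald p value of the interaction term
#' recorded; with `parameterization = "factor"` genotype classes enter as
#' factors and the interaction p is a joint Wald test of all interaction
#' columns. Interactions are declared significant when `p < p_cutoff` AND
#' they pass the BH-FDR flag at level `fdr_q` computed over all tested
#' pairs. Pairs whose interaction column is collinear with the main
#' effects (sparse two-locus cells) are marked untestable.
#'
#' @param sig_snps Character vector of significant SNP ids.
#' @param genotypes An `admixed_genotypes` object.
#' @param y Phenotype vector.
#' @param kinship Kinship matrix (default [centered_kinship()]).
#' @param p_cutoff Nominal interaction p cutoff (default 0.05).
#' @param fdr_q FDR level over tested pairs (default 0.1).
#' @param parameterization `"additive"` (default; 0/1/2 dosage product) or
#'   `"factor"` (genotype classes).
#' @param reml Use REML (default).
#' @return Data frame of class `hz_interactions`: `snp_a`, `snp_b`,
#'   `chrom_a`, `chrom_b`, `p_int`, `fdr_sig`, `significant`,
#'   `min_cell_mean`, `min_cell`, `n_min_cell`, `untestable`, `reason`.
#' @export
interaction_scan <- function(sig_snps, genotypes, y, kinship = NULL,
                             p_cutoff = 0.05, fdr_q = 0.1,
                             parameterization = c("additive", "factor"),
                             reml = TRUE) {
  parameterization <- match.arg(parameterization)
  y <- as.numeric(y)
  keep <- which(!is.na(y))
  genotypes <- genotypes[keep, ]
  y <- y[keep]
  if (is.null(kinship)) kinship <- centered_kinship(genotypes)
  else kinship <- as.matrix(kinship)[keep, keep]
  idx <- snp_index(genotypes, sig_snps)
  chrom <- genotypes$map$chrom[idx]
  pairs <- which(outer(chrom, chrom, `!=`) & upper.tri(diag(length(idx))),
                 arr.ind = TRUE)
  if (nrow(pairs) == 0L)
    stop("no cross-chromosome pairs among the supplied SNPs", call. = FALSE)
  eig <- eigen(kinship, symmetric = TRUE)
  eig$values <- pmax(eig$values, 0)
  yr <- drop(crossprod(eig$vectors, y))
  G <- mean_impute(genotypes$matrix[, idx, drop = FALSE])
  rows <- lapply(seq_len(nrow(pairs)), function(r) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    ga <- G[, a]; gb <- G[, b]
    mt <- two_locus_genotype_means(genotypes, sig_snps[a], sig_snps[b], y)
    mn <- which.min(mt$mean)
    base <- data.frame(snp_a = sig_snps[a], snp_b = sig_snps[b],
                       chrom_a = chrom[a], chrom_b = chrom[b],
                       p_int = NA_real_,
                       min_cell_mean = mt$mean[mn],
                       min_cell = names(mt$mean)[mn] %||%
                         paste(rownames(mt$mean)[row(mt$mean)[mn]],
                               colnames(mt$mean)[col(mt$mean)[mn]],
                               sep = ""),
                       n_min_cell = mt$n[mn],
                       untestable = FALSE, reason = "",
                       stringsAsFactors = FALSE)
    X <- if (parameterization == "additive") {
      cbind(ga = ga, gb = gb, int = ga * gb)
    } else {
      fa <- factor(ga); fb <- factor(gb)
      mm <- stats::model.matrix(~ fa * fb)
      mm[, -1, drop = FALSE]
    }
    Xfull <- cbind(1, X)
    qrX <- qr(Xfull)
    int_cols <- grep("int|:", colnames(X)) + 1L
    if (qrX$rank < ncol(Xfull)) {
      base$untestable <- TRUE
      base$reason <- "interaction collinear (sparse two-locus cells)"
      return(base)
    }
    Xr <- crossprod(eig$vectors, Xfull)
    opt <- stats::optimize(lmm_loglik, interval = log(c(1e-5, 1e5)),
                           d = eig$values, yr = yr, Xr = Xr, reml = reml,
                           maximum = TRUE, tol = 1e-6)
    fit <- lmm_gls(exp(opt$maximum), eig$values, yr, Xr, reml = reml)
    if (length(int_cols) == 1L) {
      w <- fit$beta[int_cols]^2 / fit$cov[int_cols, int_cols]
      base$p_int <- stats::pchisq(w, 1, lower.tail = FALSE)
    } else {
      bi <- fit$beta[int_cols]
      Vi <- fit$cov[int_cols, int_cols, drop = FALSE]
      w <- drop(crossprod(bi, solve(Vi, bi)))
      base$p_int <- stats::pchisq(w, length(int_cols), lower.tail = FALSE)
    }
    base
  })
  res <- do.call(rbind, rows)
  bh <- bh_fdr_threshold(res$p_int, q = fdr_q)
  res$fdr_sig <- bh$significant
  res$significant <- !is.na(res$p_int) & res$p_int < p_cutoff & res$fdr_sig
  class(res) <- c("hz_interactions", "data.frame")
  attr(res, "fdr_equivalent_p") <- bh$equivalent_p_cutoff
  res
}

#' @export
print.hz_interactions <- function(x, ...) {
  cat(sprintf("Interaction scan: %d cross-chromosome pairs, %d significant (p < 0.05 & FDR), %d untestable\n",
              nrow(x), sum(x$significant, na.rm = TRUE), sum(x$untestable)))
  invisible(x)
}

#' Phenotype means by two-locus genotype
#'
#' Mean phenotype and count per observed two-locus genotype class.
#' Genotype classes are labeled D (homozygous domesticus), H
#' (heterozygous), M (homozygous musculus); hemizygous male X genotypes
#' occupy the D/M classes only. Cells with no carriers are reported as
#' absent (NA mean, n = 0), never as zero.
#'
#' @param genotypes An `admixed_genotypes` object.
#' @param snp_a,snp_b SNP ids (rows = `snp_a` classes).
#' @param y Phenotype vector.
#' @return List with `mean` and `n` matrices (classes of `snp_a` x classes
#'   of `snp_b`).
#' @export
two_locus_genotype_means <- function(genotypes, snp_a, snp_b, y) {
  i <- snp_index(genotypes, snp_a); j <- snp_index(genotypes, snp_b)
  lab <- c(`0` = "D", `1` = "H", `2` = "M")
  ga <- factor(lab[as.character(genotypes$matrix[, i])], levels = lab)
  gb <- factor(lab[as.character(genotypes$matrix[, j])], levels = lab)
  ok <- !is.na(ga) & !is.na(gb) & !is.na(y)
  mean_tab <- tapply(y[ok], list(ga[ok], gb[ok]), mean)
  n_tab <- table(ga[ok], gb[ok])
  present_a <- rowSums(n_tab) > 0
  present_b <- colSums(n_tab) > 0
  list(mean = mean_tab[present_a, present_b, drop = FALSE],
       n = unclass(n_tab[present_a, present_b, drop = FALSE]))
}

#' Genotype-class means for single SNPs
#'
#' Per-SNP phenotype mean by genotype class, used for single-locus effect
#' sizes and sterile-allele inference.
#'
#' @param genotypes An `admixed_genotypes` object.
#' @param snp_ids SNP ids.
#' @param y Phenotype vector.
#' @return Named list per SNP with `mean` and `n` per class (D/H/M).
#' @export
single_locus_genotype_means <- function(genotypes, snp_ids, y) {
  idx <- snp_index(genotypes, snp_ids)
  lab <- c(`0` = "D", `1` = "H", `2` = "M")
  out <- lapply(idx, function(i) {
    g <- factor(lab[as.character(genotypes$matrix[, i])], levels = lab)
    ok <- !is.na(g) & !is.na(y)
    m <- tapply(y[ok], g[ok], mean)
    n <- table(g[ok])
    keep <- n > 0
    list(mean = m[keep], n = unclass(n[keep]))
  })
  names(out) <- snp_ids
  out
}

#' Effect sizes as deviations from the population mean
#'
#' Single-SNP effect = most negative (genotype-class mean - population
#' mean); pair effect = most negative two-locus cell mean - population
#' mean. A locus or pair is flagged `below_pure_range` when its minimum
#' genotypic mean falls strictly below the minimum observed in pure
#' subspecies.
#'
#' @param results Either an `hz_interactions` data frame (pair effects,
#'   using `min_cell_mean`) or the list from
#'   [single_locus_genotype_means()] (single-SNP effects).
#' @param population_mean Population phenotype mean.
#' @param pure_range_min Minimum phenotype in pure subspecies.
#' @return Data frame: `id`, `min_genotype_mean`, `effect` (deviation, in
#'   phenotype units), `below_pure_range`.
#' @export
effect_deviations <- function(results, population_mean, pure_range_min) {
  if (inherits(results, "hz_interactions")) {
    mins <- results$min_cell_mean
    ids <- paste(results$snp_a, results$snp_b, sep = ":")
  } else {
    mins <- vapply(results, function(r) min(r$mean), numeric(1))
    ids <- names(results)
  }
  data.frame(id = ids, min_genotype_mean = mins,
             effect = mins - population_mean,
             below_pure_range = mins < pure_range_min,
             stringsAsFactors = FALSE)
}

#' Collapse SNP-pair interactions to region pairs
#'
#' Maps every tested SNP to its region (SNPs must belong to at most one
#' region), counts significant SNP pairs per region pair, and reports the
#' minimum interaction counts: a region pair counts once regardless of
#' SNP-pair multiplicity, split into autosomal-autosomal and X-autosomal
#' classes.
#'
#' @param interactions An `hz_interactions` data frame.
#' @param regions An `hz_regions` data frame.
#' @return List: `pairs` (region_a, region_b, n_sig_pairs, class),
#'   `n_auto_auto`, `n_x_auto`, `n_sig_snp_pairs`.
#' @export
summarize_region_pairs <- function(interactions, regions) {
  member <- strsplit(regions$snp_ids, ",")
  snp2region <- stats::setNames(
    rep(regions$region_id, lengths(member)), unlist(member))
  if (anyDuplicated(names(snp2region)))
    stop("SNP assigned to more than one region; regions must be disjoint",
         call. = FALSE)
  sig <- interactions[which(interactions$significant), , drop = FALSE]
  if (nrow(sig) == 0L)
    return(list(pairs = data.frame(region_a = character(),
                                   region_b = character(),
                                   n_sig_pairs = integer(),
                                   class = character(),
                                   stringsAsFactors = FALSE),
                n_auto_auto = 0L, n_x_auto = 0L, n_sig_snp_pairs = 0L))
  ra <- snp2region[sig$snp_a]; rb <- snp2region[sig$snp_b]
  if (anyNA(ra) || anyNA(rb))
    stop("tested SNP not found in any region", call. = FALSE)
  swap <- ra > rb
  tmp <- ra[swap]; ra[swap] <- rb[swap]; rb[swap] <- tmp
  key <- paste(ra, rb)
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  parts <- do.call(rbind, strsplit(agg$key, " "))
  x_region <- stats::setNames(regions$chrom == "X", regions$region_id)
  cls <- ifelse(x_region[parts[, 1]] | x_region[parts[, 2]],
                "X-auto", "auto-auto")
  pairs <- data.frame(region_a = parts[, 1], region_b = parts[, 2],
                      n_sig_pairs = agg$Freq, class = cls,
                      stringsAsFactors = FALSE)
  list(pairs = pairs,
       n_auto_auto = sum(pairs$class == "auto-auto"),
       n_x_auto = sum(pairs$class == "X-auto"),
       n_sig_snp_pairs = sum(pairs$n_sig_pairs))
}

#' Infer the sterile allele for each significant region
#'
#' For each member SNP, the allele whose carriers show the lower phenotype
#' (sign of the dosage-phenotype slope) is taken as the sterile allele and
#' assigned to the subspecies in which it is the major allele in the
#' reference panels. The region call is the majority vote across member
#' SNPs: `D`/`M` for domesticus/musculus, lower-case when the SNP set's
#' majority has F_ST below `f_st_threshold`, `U` when the allele is
#' nondiagnostic (major in both or neither panel) or there is no majority.
#'
#' @param regions An `hz_regions` data frame.
#' @param genotypes An `admixed_genotypes` object.
#' @param y Phenotype vector.
#' @param panels A `subspecies_panels` object (or diagnostic data frame
#'   from [assign_diagnostic_status()]).
#' @param f_st_threshold Lower-case cutoff (default 0.7).
#' @return Data frame: `region_id`, `sterile_allele` in
#'   `{D, M, d, m, U}`, `n_snps`, `n_d`, `n_m`, `n_u`.
#' @export
infer_sterile_allele <- function(regions, genotypes, y, panels,
                                 f_st_threshold = 0.7) {
  diag_df <- if (is.data.frame(panels)) panels
             else assign_diagnostic_status(panels, f_st_threshold)
  rows <- lapply(seq_len(nrow(regions)), function(r) {
    snps <- strsplit(regions$snp_ids[r], ",")[[1]]
    calls <- vapply(snps, function(s) {
      i <- snp_index(genotypes, s)
      g <- genotypes$matrix[, i]
      ok <- !is.na(g) & !is.na(y)
      if (sum(ok) < 3 || stats::sd(g[ok]) == 0) return("U")
      slope <- stats::cov(g[ok], y[ok]) / stats::var(g[ok])
      # slope < 0: musculus allele lowers phenotype -> sterile allele is
      # the musculus allele; otherwise the domesticus allele
      d <- diag_df[match(s, diag_df$snp_id), ]
      if (is.na(d$fst)) return("U")
      if (slope < 0) {
        sterile_freq_mus <- d$freq_musculus
        sterile_freq_dom <- d$freq_domesticus
        letter <- "M"
      } else {
        sterile_freq_mus <- 1 - d$freq_musculus
        sterile_freq_dom <- 1 - d$freq_domesticus
        letter <- "D"
      }
      major_own <- if (letter == "M") sterile_freq_mus > 0.5
                   else sterile_freq_dom > 0.5
      major_other <- if (letter == "M") sterile_freq_dom > 0.5
                     else sterile_freq_mus > 0.5
      if (!major_own || major_other) return("U")
      if (d$fst < f_st_threshold) tolower(letter) else letter
    }, character(1))
    up <- toupper(calls)
    n_d <- sum(up == "D"); n_m <- sum(up == "M"); n_u <- sum(up == "U")
    call <- if (n_d > n_m + n_u) "D"
            else if (n_m > n_d + n_u) "M"
            else if (n_d > n_m && n_d > n_u) "D"
            else if (n_m > n_d && n_m > n_u) "M"
            else "U"
    if (call != "U") {
      member_fst <- diag_df$fst[match(snps[up == call], diag_df$snp_id)]
      if (all(is.na(member_fst)) ||
          stats::median(member_fst, na.rm = TRUE) < f_st_threshold)
        call <- tolower(call)
    }
    data.frame(region_id = regions$region_id[r], sterile_allele = call,
               n_snps = length(snps), n_d = n_d, n_m = n_m, n_u = n_u,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
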