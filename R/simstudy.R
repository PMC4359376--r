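# Two-locus incompatibility simulation framework: causal-pair selection,
# nine genetic architectures with Z-score genotype means, phenotype
# generation, and power / false-discovery evaluation of the mapping
# pipeline.

#' Architecture class labels
#'
#' The nine simulated two-locus architectures: all dominance combinations
#' of two autosomal loci (locus 1 musculus-sterile, locus 2
#' domesticus-sterile) plus three X-autosomal classes where locus 1 is the
#' hemizygous X-linked locus and the label gives the autosomal partner's
#' dominance.
#'
#' @return Character vector of the nine class labels.
#' @export
architecture_classes <- function() {
  c("rec-rec", "rec-add", "rec-dom", "add-add", "add-dom", "dom-dom",
    "X-rec", "X-add", "X-dom")
}

# penetrance factor per genotype class (carrier dose 0/1/2 of the sterile
# allele) under a dominance model; hemizygous X in males: dose 0 or 2 -> 0/1
penetrance_factor <- function(dose, model) {
  switch(model,
         rec = c(0, 0, 1)[dose + 1L],
         add = c(0, 0.5, 1)[dose + 1L],
         dom = c(0, 1, 1)[dose + 1L],
         hemi = c(0, NA, 1)[dose + 1L],
         stop("unknown dominance model: ", model, call. = FALSE))
}

#' Build the two-locus genotype-mean table for an architecture
#'
#' Mean phenotypes are on the Z-score scale. Per-locus penetrance factors
#' f are 0 for non-carriers, and for carriers depend on dominance:
#' recessive 0 (het) / 1 (hom), additive 0.5 / 1, dominant 1 / 1; the
#' X-linked locus in males is hemizygous with f in {0, 1}. Cells where
#' both loci express the sterile allele (f1 * f2 > 0) have mean
#' `severe_mean_sd * f1 * f2` (default -2.3, so additive heterozygote
#' combinations give -1.15); all other cells draw one mean from
#' `U(nonsterile_range)` (default U(-0.5, 0.5)).
#'
#' @param architecture_class One of [architecture_classes()].
#' @param severe_mean_sd Most severe mean (default -2.3 SD).
#' @param nonsterile_range Range of non-sterile cell means.
#' @param residual_sd Residual SD of simulated phenotypes (default 0.75).
#' @param seed Optional seed for the non-sterile draws.
#' @return Object of class `hz_architecture`: the dominance pair, the
#'   mean table (rows = locus 1 dose 0/1/2, cols = locus 2 dose), the
#'   deterministic sterile-cell mask, and the parameters.
#' @export
build_genotype_mean_table <- function(architecture_class,
                                      severe_mean_sd = -2.3,
                                      nonsterile_range = c(-0.5, 0.5),
                                      residual_sd = 0.75, seed = NULL) {
  stopifnot(architecture_class %in% architecture_classes())
  stopifnot(residual_sd > 0, severe_mean_sd < min(nonsterile_range))
  parts <- strsplit(architecture_class, "-")[[1]]
  m1 <- if (parts[1] == "X") "hemi" else parts[1]
  m2 <- parts[2]
  with_seed(seed, {
    f1 <- vapply(0:2, penetrance_factor, 0, model = m1)
    f2 <- vapply(0:2, penetrance_factor, 0, model = m2)
    ff <- outer(f1, f2)
    mean_tab <- severe_mean_sd * ff
    sterile <- !is.na(ff) & ff > 0
    ns <- !sterile & !is.na(ff)
    mean_tab[ns] <- stats::runif(sum(ns), nonsterile_range[1],
                                 nonsterile_range[2])
    mean_tab[is.na(ff)] <- NA_real_  # het X in males: class absent
    dimnames(mean_tab) <- list(locus1 = 0:2, locus2 = 0:2)
    structure(list(class = architecture_class, model1 = m1, model2 = m2,
                   mean_table = mean_tab, sterile_cell = sterile,
                   severe_mean_sd = severe_mean_sd,
                   nonsterile_range = nonsterile_range,
                   residual_sd = residual_sd),
              class = "hz_architecture")
  })
}

#' @export
print.hz_architecture <- function(x, ...) {
  cat(sprintf("Two-locus architecture %s (severe mean %.2f SD, residual SD %.2f)\n",
              x$class, x$severe_mean_sd, x$residual_sd))
  print(round(x$mean_table, 2))
  invisible(x)
}

#' Select eligible causal SNP pairs
#'
#' Causal ("sterile") SNPs must have minor allele frequency > 0.05 in the
#' mapping population and the alternate non-sterile allele fixed in the
#' other subspecies panel (so the sterile allele may be polymorphic or
#' fixed in its own subspecies, frequency 0.05-1). Pairs are drawn at
#' random without replacement from the eligible pool, always on different
#' chromosomes. For `pair_class = "auto-auto"`, locus 1 carries a
#' musculus sterile allele and locus 2 a domesticus sterile allele; for
#' `"X-auto"`, locus 1 is X-linked (half musculus-sterile, half
#' domesticus-sterile by default) and locus 2 is autosomal with the
#' opposite subspecies' sterile allele.
#'
#' @param genotypes Mapping-population `admixed_genotypes`.
#' @param panels A `subspecies_panels` object.
#' @param n_pairs Number of pairs to draw.
#' @param pair_class `"auto-auto"` or `"X-auto"`.
#' @param seed Optional integer seed.
#' @return Data frame of class `hz_causal_pairs`: `snp_1`, `snp_2`,
#'   `chrom_1`, `chrom_2`, `sterile_1`, `sterile_2` (subspecies whose
#'   allele is sterile at each locus), `pair_class`.
#' @export
select_causal_pairs <- function(genotypes, panels, n_pairs,
                                pair_class = c("auto-auto", "X-auto"),
                                seed = NULL) {
  pair_class <- match.arg(pair_class)
  check_count(n_pairs, "n_pairs")
  map <- genotypes$map
  common <- intersect(map$snp_id, panels$map$snp_id)
  gi <- match(common, map$snp_id)
  pi <- match(common, panels$map$snp_id)
  f_map <- maf(genotypes$matrix[, gi, drop = FALSE])
  p_dom <- allele_freq(panels$domesticus$genotypes[, pi, drop = FALSE])
  p_mus <- allele_freq(panels$musculus$genotypes[, pi, drop = FALSE])
  # musculus-sterile: sterile allele = musculus allele; the alternate
  # (domesticus) allele must be fixed in domesticus (musculus-allele freq
  # 0 there); sterile-allele frequency in musculus 0.05-1
  ok_common <- !is.na(f_map) & f_map > 0.05
  mus_pool <- common[ok_common & p_dom == 0 & p_mus >= 0.05]
  dom_pool <- common[ok_common & p_mus == 1 & (1 - p_dom) >= 0.05]
  on_x <- function(ids) map$chrom[match(ids, map$snp_id)] == "X"
  pool_info <- function(p1, p2) sprintf("pool sizes: %d / %d",
                                        length(p1), length(p2))
  with_seed(seed, {
    if (pair_class == "auto-auto") {
      p1 <- mus_pool[!on_x(mus_pool)]
      p2 <- dom_pool[!on_x(dom_pool)]
      if (length(p1) < n_pairs || length(p2) < n_pairs)
        stop("eligible SNP pool smaller than n_pairs; ",
             pool_info(p1, p2), call. = FALSE)
      s1 <- sample(p1, n_pairs)
      s2 <- character(n_pairs)
      st1 <- rep("musculus", n_pairs); st2 <- rep("domesticus", n_pairs)
    } else {
      x_mus <- mus_pool[on_x(mus_pool)]
      x_dom <- dom_pool[on_x(dom_pool)]
      n_mus <- ceiling(n_pairs / 2); n_dom <- n_pairs - n_mus
      if (length(x_mus) < n_mus || length(x_dom) < n_dom)
        stop("eligible X-linked SNP pool smaller than n_pairs; ",
             pool_info(x_mus, x_dom), call. = FALSE)
      s1 <- c(sample(x_mus, n_mus), sample(x_dom, n_dom))
      st1 <- rep(c("musculus", "domesticus"), c(n_mus, n_dom))
      st2 <- ifelse(st1 == "musculus", "domesticus", "musculus")
      s2 <- character(n_pairs)
    }
    for (k in seq_len(n_pairs)) {
      pool2 <- if (st2[k] == "domesticus") dom_pool else mus_pool
      pool2 <- pool2[!on_x(pool2)]
      pool2 <- setdiff(pool2, s2[seq_len(k - 1)])
      pool2 <- pool2[map$chrom[match(pool2, map$snp_id)] !=
                       map$chrom[match(s1[k], map$snp_id)]]
      if (length(pool2) == 0L)
        stop("eligible partner pool exhausted at pair ", k, call. = FALSE)
      s2[k] <- if (length(pool2) == 1L) pool2 else sample(pool2, 1L)
    }
    res <- data.frame(snp_1 = s1, snp_2 = s2,
                      chrom_1 = map$chrom[match(s1, map$snp_id)],
                      chrom_2 = map$chrom[match(s2, map$snp_id)],
                      sterile_1 = st1, sterile_2 = st2,
                      pair_class = pair_class, stringsAsFactors = FALSE)
    class(res) <- c("hz_causal_pairs", "data.frame")
    res
  })
}

# sterile-allele dose (0/1/2) at a causal SNP: the genotype codes count
# musculus alleles, so domesticus-sterile loci flip the code
sterile_dose <- function(genotypes, snp_id, sterile) {
  g <- genotypes$matrix[, snp_index(genotypes, snp_id)]
  if (sterile == "domesticus") g <- 2L - g
  g
}

#' Simulate phenotype datasets for one causal pair and architecture
#'
#' Each dataset draws one set of non-sterile cell means from the uniform
#' range, assigns every individual the mean of its two-locus genotype
#' class, and adds Gaussian noise with `residual_sd`. Individuals with a
#' missing causal genotype are assigned the mean-genotype (rounded dose)
#' class. The affected fraction is the share of individuals whose class
#' mean is at or below the additive-heterozygote severity (half the severe
#' mean).
#'
#' @param pair One row of an `hz_causal_pairs` data frame.
#' @param model An `hz_architecture` from [build_genotype_mean_table()].
#' @param genotypes Mapping-population `admixed_genotypes`.
#' @param n_datasets Number of datasets (default 100).
#' @param seed Optional integer seed.
#' @return List: `phenotypes` (individuals x datasets matrix),
#'   `affected_fraction` (per dataset), `dose_1`, `dose_2`.
#' @export
simulate_phenotype_datasets <- function(pair, model, genotypes,
                                        n_datasets = 100, seed = NULL) {
  check_count(n_datasets, "n_datasets")
  d1 <- sterile_dose(genotypes, pair$snp_1, pair$sterile_1)
  d2 <- sterile_dose(genotypes, pair$snp_2, pair$sterile_2)
  # missing causal genotypes take the modal dose class (always a class
  # that exists for that locus, incl. hemizygous X where dose 1 is absent)
  impute_dose <- function(d) {
    if (anyNA(d)) {
      tab <- table(d)
      d[is.na(d)] <- as.integer(names(tab)[which.max(tab)])
    }
    d
  }
  d1 <- impute_dose(d1); d2 <- impute_dose(d2)
  n <- length(d1)
  sev <- model$severe_mean_sd
  with_seed(seed, {
    pheno <- matrix(NA_real_, n, n_datasets)
    affected <- numeric(n_datasets)
    for (k in seq_len(n_datasets)) {
      tab <- model$mean_table
      ns <- !model$sterile_cell & !is.na(tab)
      tab[ns] <- stats::runif(sum(ns), model$nonsterile_range[1],
                              model$nonsterile_range[2])
      mu <- tab[cbind(d1 + 1L, d2 + 1L)]
      pheno[, k] <- stats::rnorm(n, mu, model$residual_sd)
      affected[k] <- mean(mu <= sev / 2)
    }
    rownames(pheno) <- rownames(genotypes$matrix)
    list(phenotypes = pheno, affected_fraction = affected,
         dose_1 = d1, dose_2 = d2)
  })
}

#' Detection flags for one scan against one causal pair
#'
#' A locus counts as detected at a distance criterion when at least one
#' significant SNP lies within that distance on the same chromosome.
#'
#' @param scan An `hz_assoc` scan result.
#' @param significant Logical vector: which scan SNPs are significant.
#' @param pair One row of an `hz_causal_pairs` data frame.
#' @param genotypes The scanned `admixed_genotypes` (for causal positions).
#' @param distance_criteria_bp Distances (default 0.2, 1 and 10 Mb).
#' @return List: `detected` (matrix loci x criteria), `both` (per
#'   criterion), `distances_1`, `distances_2` (distances of significant
#'   same-chromosome SNPs to each causal SNP, bp).
#' @export
evaluate_detection <- function(scan, significant, pair, genotypes,
                               distance_criteria_bp = c(0.2e6, 1e6, 10e6)) {
  map <- genotypes$map
  loc <- function(snp) {
    i <- match(snp, map$snp_id)
    list(chrom = map$chrom[i], pos = map$pos[i])
  }
  l1 <- loc(pair$snp_1); l2 <- loc(pair$snp_2)
  sig <- which(significant & !is.na(scan$p_wald))
  dist_to <- function(l) {
    same <- sig[scan$chrom[sig] == l$chrom]
    abs(scan$pos[same] - l$pos)
  }
  d1 <- dist_to(l1); d2 <- dist_to(l2)
  det <- rbind(locus1 = vapply(distance_criteria_bp,
                               function(d) any(d1 <= d), logical(1)),
               locus2 = vapply(distance_criteria_bp,
                               function(d) any(d2 <= d), logical(1)))
  colnames(det) <- paste0(distance_criteria_bp / 1e6, "Mb")
  list(detected = det, both = det[1, ] & det[2, ],
       distances_1 = d1, distances_2 = d2)
}

#' Per-dataset false positive rate of the mapping procedure
#'
#' Significant SNPs on chromosomes carrying neither causal SNP are false
#' positives; same-chromosome significant SNPs within `tp_distance_bp`
#' (default 50 Mb) of the causal SNP are true positives; same-chromosome
#' SNPs beyond that distance are excluded. FDR = FP / (FP + TP). The
#' reporting rule requires at least `min_tp` significant SNPs within the
#' distance of either causal locus; otherwise NA is returned.
#'
#' @param scan An `hz_assoc` scan result.
#' @param significant Logical significance flags.
#' @param pair One row of `hz_causal_pairs`.
#' @param genotypes The scanned `admixed_genotypes`.
#' @param tp_distance_bp True-positive distance (default 50 Mb).
#' @param min_tp Reporting floor on within-distance SNPs (default 10).
#' @return List: `fdr` (NA when unreportable or undefined), `tp`, `fp`,
#'   `excluded`, `reportable`.
#' @export
false_positive_rate <- function(scan, significant, pair, genotypes,
                                tp_distance_bp = 50e6, min_tp = 10) {
  map <- genotypes$map
  i1 <- match(pair$snp_1, map$snp_id); i2 <- match(pair$snp_2, map$snp_id)
  ch <- c(map$chrom[i1], map$chrom[i2])
  pos <- c(map$pos[i1], map$pos[i2])
  sig <- which(significant & !is.na(scan$p_wald))
  if (length(sig) == 0L)
    return(list(fdr = NA_real_, tp = 0L, fp = 0L, excluded = 0L,
                reportable = FALSE))
  on1 <- scan$chrom[sig] == ch[1]
  on2 <- scan$chrom[sig] == ch[2]
  d <- rep(Inf, length(sig))
  d[on1] <- abs(scan$pos[sig[on1]] - pos[1])
  d[on2] <- pmin(d[on2], abs(scan$pos[sig[on2]] - pos[2]))
  same <- on1 | on2
  tp <- sum(same & d <= tp_distance_bp)
  excluded <- sum(same & d > tp_distance_bp)
  fp <- sum(!same)
  reportable <- tp >= min_tp
  fdr <- if (reportable && (fp + tp) > 0) fp / (fp + tp) else NA_real_
  list(fdr = fdr, tp = tp, fp = fp, excluded = excluded,
       reportable = reportable)
}

#' Run the full two-locus mapping simulation study
#'
#' Orchestrates causal-pair selection, architecture construction,
#' phenotype simulation, the kinship LMM scan, permutation-based and
#' FDR thresholds, detection and false-positive evaluation, for every
#' architecture class. The reference design is 9 architectures x 100 SNP
#' pairs x 100 datasets (90,000 simulations); the scaled default is
#' 9 x 10 x 10. Permutation thresholds are recomputed once per causal
#' pair from the first dataset's phenotype (`thresholds_per = "pair"`),
#' or per dataset (`"dataset"`, much slower).
#'
#' @param genotypes Mapping-population `admixed_genotypes`.
#' @param panels A `subspecies_panels` object.
#' @param kinship Kinship matrix (default [centered_kinship()]).
#' @param architectures Architecture classes (default all nine).
#' @param n_pairs_per_class SNP pairs per class (default 10).
#' @param n_datasets Datasets per pair (default 10).
#' @param n_perm Permutations for thresholds (default 200).
#' @param fdr_q FDR level (default 0.1).
#' @param distance_criteria_bp Detection distances (default 0.2/1/10 Mb).
#' @param thresholds_per `"pair"` (default) or `"dataset"`.
#' @param count_only If TRUE, only enumerate the design and return the
#'   dataset count without executing any simulation.
#' @param seed Optional integer seed.
#' @return Object of class `hz_power_study`: `report` (per-architecture
#'   detection percentages and significant-SNP summaries in a Table-3
#'   style layout, for both threshold rules), `datasets` (per-dataset
#'   log), `n_datasets_total`, `config`.
#' @export
run_full_study <- function(genotypes, panels, kinship = NULL,
                           architectures = architecture_classes(),
                           n_pairs_per_class = 10, n_datasets = 10,
                           n_perm = 200, fdr_q = 0.1,
                           distance_criteria_bp = c(0.2e6, 1e6, 10e6),
                           thresholds_per = c("pair", "dataset"),
                           count_only = FALSE, seed = NULL) {
  thresholds_per <- match.arg(thresholds_per)
  stopifnot(all(architectures %in% architecture_classes()))
  n_total <- as.integer(length(architectures) * n_pairs_per_class *
                          n_datasets)
  config <- list(architectures = architectures,
                 n_pairs_per_class = n_pairs_per_class,
                 n_datasets = n_datasets, n_perm = n_perm, fdr_q = fdr_q,
                 distance_criteria_bp = distance_criteria_bp,
                 thresholds_per = thresholds_per, seed = seed)
  if (count_only)
    return(structure(list(report = NULL, datasets = NULL,
                          n_datasets_total = n_total, config = config),
                     class = "hz_power_study"))
  if (is.null(kinship)) kinship <- centered_kinship(genotypes)
  cache <- build_scan_cache(genotypes, kinship)
  auto <- autosomal(genotypes)
  has_x <- any(!auto)
  scan_template <- genotypes$map[, c("snp_id", "chrom", "pos")]
  perm_thresholds <- function(y, seed_k) {
    with_seed(seed_k, {
      mins <- vapply(seq_len(n_perm), function(i) {
        p <- scan_with_cache(cache, sample(y))$p
        c(min(p[auto], na.rm = TRUE),
          if (has_x) min(p[!auto], na.rm = TRUE) else NA_real_)
      }, numeric(2))
      c(stats::quantile(mins[1, ], 0.05, names = FALSE),
        if (has_x) stats::quantile(mins[2, ], 0.05, names = FALSE)
        else NA_real_)
    })
  }
  logs <- list()
  for (a in seq_along(architectures)) {
    arch <- architectures[a]
    pair_class <- if (startsWith(arch, "X")) "X-auto" else "auto-auto"
    pairs <- select_causal_pairs(genotypes, panels, n_pairs_per_class,
                                 pair_class,
                                 seed = derive_seed(seed, paste0("pairs_",
                                                                 arch)))
    model <- build_genotype_mean_table(arch)
    for (k in seq_len(n_pairs_per_class)) {
      pair <- pairs[k, ]
      sim <- simulate_phenotype_datasets(
        pair, model, genotypes, n_datasets,
        seed = derive_seed(seed, paste0("pheno_", arch, "_", k)))
      thr <- NULL
      for (ds in seq_len(n_datasets)) {
        y <- sim$phenotypes[, ds]
        sc <- scan_with_cache(cache, y, exact = TRUE)
        scan <- cbind(scan_template,
                      data.frame(beta = sc$beta, se = sc$se,
                                 p_wald = sc$p))
        if (is.null(thr) || thresholds_per == "dataset") {
          thr <- perm_thresholds(
            y, derive_seed(seed, paste0("thr_", arch, "_", k, "_",
                                        if (thresholds_per == "dataset")
                                          ds else 0)))
        }
        sig_perm <- !is.na(sc$p) &
          sc$p < ifelse(scan$chrom == "X", thr[2], thr[1])
        bh <- bh_fdr_threshold(sc$p, q = fdr_q)
        sig_fdr <- bh$significant
        det_p <- evaluate_detection(scan, sig_perm, pair, genotypes,
                                    distance_criteria_bp)
        det_f <- evaluate_detection(scan, sig_fdr, pair, genotypes,
                                    distance_criteria_bp)
        fdr_p <- false_positive_rate(scan, sig_perm, pair, genotypes)
        fdr_f <- false_positive_rate(scan, sig_fdr, pair, genotypes)
        n_within <- function(sigv, d) {
          sig <- which(sigv)
          on1 <- scan$chrom[sig] == pair$chrom_1 &
            abs(scan$pos[sig] - genotypes$map$pos[
              match(pair$snp_1, genotypes$map$snp_id)]) <= d
          on2 <- scan$chrom[sig] == pair$chrom_2 &
            abs(scan$pos[sig] - genotypes$map$pos[
              match(pair$snp_2, genotypes$map$snp_id)]) <= d
          sum(on1 | on2)
        }
        logs[[length(logs) + 1L]] <- data.frame(
          architecture = arch, pair = k, dataset = ds,
          affected_fraction = sim$affected_fraction[ds],
          l1_perm_0.2 = det_p$detected["locus1", 1],
          l1_perm_1 = det_p$detected["locus1", 2],
          l1_perm_10 = det_p$detected["locus1", 3],
          l2_perm_0.2 = det_p$detected["locus2", 1],
          l2_perm_1 = det_p$detected["locus2", 2],
          l2_perm_10 = det_p$detected["locus2", 3],
          both_perm_0.2 = det_p$both[1], both_perm_1 = det_p$both[2],
          both_perm_10 = det_p$both[3],
          l1_fdr_0.2 = det_f$detected["locus1", 1],
          l1_fdr_1 = det_f$detected["locus1", 2],
          l1_fdr_10 = det_f$detected["locus1", 3],
          l2_fdr_0.2 = det_f$detected["locus2", 1],
          l2_fdr_1 = det_f$detected["locus2", 2],
          l2_fdr_10 = det_f$detected["locus2", 3],
          both_fdr_0.2 = det_f$both[1], both_fdr_1 = det_f$both[2],
          both_fdr_10 = det_f$both[3],
          n_sig_perm = sum(sig_perm), n_sig_fdr = sum(sig_fdr),
          n_perm_10Mb = n_within(sig_perm, 10e6),
          n_perm_50Mb = n_within(sig_perm, 50e6),
          n_fdr_10Mb = n_within(sig_fdr, 10e6),
          n_fdr_50Mb = n_within(sig_fdr, 50e6),
          n_same_chr_perm = length(det_p$distances_1) +
            length(det_p$distances_2),
          n_same_chr_10Mb_perm = sum(det_p$distances_1 <= 10e6) +
            sum(det_p$distances_2 <= 10e6),
          n_same_chr_fdr = length(det_f$distances_1) +
            length(det_f$distances_2),
          n_same_chr_10Mb_fdr = sum(det_f$distances_1 <= 10e6) +
            sum(det_f$distances_2 <= 10e6),
          n_perm_diff_chr = fdr_p$fp, n_fdr_diff_chr = fdr_f$fp,
          fdr_rate_perm = fdr_p$fdr, fdr_rate_fdr = fdr_f$fdr,
          median_dist_same_chr_perm = stats::median(
            c(det_p$distances_1, det_p$distances_2)) / 1e6,
          stringsAsFactors = FALSE)
      }
    }
  }
  datasets <- do.call(rbind, logs)
  pct <- function(x) 100 * mean(x, na.rm = TRUE)
  report <- do.call(rbind, lapply(architectures, function(arch) {
    d <- datasets[datasets$architecture == arch, ]
    data.frame(
      architecture = arch,
      l1_perm_0.2 = pct(d$l1_perm_0.2), l1_perm_1 = pct(d$l1_perm_1),
      l1_perm_10 = pct(d$l1_perm_10),
      l2_perm_0.2 = pct(d$l2_perm_0.2), l2_perm_1 = pct(d$l2_perm_1),
      l2_perm_10 = pct(d$l2_perm_10),
      both_perm_0.2 = pct(d$both_perm_0.2),
      both_perm_1 = pct(d$both_perm_1),
      both_perm_10 = pct(d$both_perm_10),
      l1_fdr_10 = pct(d$l1_fdr_10), l2_fdr_10 = pct(d$l2_fdr_10),
      both_fdr_10 = pct(d$both_fdr_10),
      mean_sig_10Mb_perm = mean(d$n_perm_10Mb),
      mean_sig_50Mb_perm = mean(d$n_perm_50Mb),
      mean_sig_diff_chr_perm = mean(d$n_perm_diff_chr),
      median_fdr_perm = stats::median(d$fdr_rate_perm, na.rm = TRUE),
      median_fdr_fdr = stats::median(d$fdr_rate_fdr, na.rm = TRUE),
      mean_affected = 100 * mean(d$affected_fraction),
      stringsAsFactors = FALSE)
  }))
  structure(list(report = report, datasets = datasets,
                 n_datasets_total = n_total, config = config),
            class = "hz_power_study")
}

#' @export
print.hz_power_study <- function(x, ...) {
  cat(sprintf("Two-locus mapping power study: %d datasets (%d architectures)\n",
              x$n_datasets_total, length(x$config$architectures)))
  if (!is.null(x$report)) {
    cols <- c("architecture", "both_perm_0.2", "both_perm_1",
              "both_perm_10", "median_fdr_perm", "median_fdr_fdr")
    df <- x$report[, cols]
    df[, -1] <- round(df[, -1], 3)
    print.data.frame(df, row.names = FALSE)
  } else cat("  (design enumeration only; not executed)\n")
  invisible(x)
}
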