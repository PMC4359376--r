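# Synthetic hybrid-zone data generator: two diverged subspecies panels, a
# pedigreed admixed mapping population with block ancestry LD, and the basic
# phenotype utilities (relative testis weight, subfertility flag, hybrid
# index).

#' Simulate two diverged subspecies reference panels
#'
#' Generates a SNP map over 19 autosomes plus X and genotypes for two
#' reference panels ("domesticus" and "musculus"). A fraction
#' `prop_fixed_diff` of SNPs are fixed differences (musculus-allele
#' frequency 0 vs 1); the remainder diverge by drift from a shared ancestral
#' frequency under a Balding-Nichols model with differentiation `fst`.
#'
#' @param n_domesticus,n_musculus Panel sizes (default 21 and 22).
#' @param n_snps Total number of SNPs.
#' @param prop_fixed_diff Fraction of SNPs that are fixed differences.
#' @param fst Balding-Nichols differentiation for non-fixed SNPs.
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param seed Optional integer seed.
#' @return A list of class `subspecies_panels` with elements `domesticus`
#'   and `musculus` (each `genotypes` matrix + true `freq`), `map`, and the
#'   bookkeeping flag `is_fixed_diff`.
#' @export
simulate_ancestral_panels <- function(n_domesticus = 21, n_musculus = 22,
                                      n_snps = 5000, prop_fixed_diff = 0.4,
                                      fst = 0.3,
                                      chrom_lengths = default_chrom_lengths(),
                                      seed = NULL) {
  check_count(n_domesticus, "n_domesticus", min = 2)
  check_count(n_musculus, "n_musculus", min = 2)
  check_count(n_snps, "n_snps", min = length(chrom_lengths))
  check_fraction(prop_fixed_diff, "prop_fixed_diff")
  check_fraction(fst, "fst", lo = 1e-6, hi = 1 - 1e-6)
  with_seed(seed, {
    # SNP counts per chromosome proportional to length, at least 2 each
    n_chr <- length(chrom_lengths)
    alloc <- pmax(2L, round(n_snps * chrom_lengths / sum(chrom_lengths)))
    while (sum(alloc) != n_snps) {
      i <- which.max(alloc)
      alloc[i] <- alloc[i] + sign(n_snps - sum(alloc))
    }
    map <- do.call(rbind, lapply(seq_len(n_chr), function(i) {
      pos <- sort(sample.int(chrom_lengths[i], alloc[i]))
      data.frame(chrom = names(chrom_lengths)[i], pos = pos,
                 stringsAsFactors = FALSE)
    }))
    map <- data.frame(snp_id = sprintf("snp%05d", seq_len(n_snps)),
                      map, stringsAsFactors = FALSE)
    is_fixed <- rep(FALSE, n_snps)
    is_fixed[sample.int(n_snps, round(prop_fixed_diff * n_snps))] <- TRUE
    p_dom <- p_mus <- numeric(n_snps)
    p_dom[is_fixed] <- 0; p_mus[is_fixed] <- 1
    k <- sum(!is_fixed)
    if (k > 0) {
      anc <- stats::runif(k, 0.05, 0.95)
      shape <- (1 - fst) / fst
      p_dom[!is_fixed] <- stats::rbeta(k, anc * shape, (1 - anc) * shape)
      p_mus[!is_fixed] <- stats::rbeta(k, anc * shape, (1 - anc) * shape)
    }
    draw <- function(n, p) {
      m <- matrix(stats::rbinom(n * length(p), 2L, rep(p, each = n)), n)
      rownames(m) <- sprintf("ref%02d", seq_len(n))
      colnames(m) <- map$snp_id
      m
    }
    structure(list(
      domesticus = list(panel_id = "domesticus",
                        genotypes = draw(n_domesticus, p_dom), freq = p_dom),
      musculus = list(panel_id = "musculus",
                      genotypes = draw(n_musculus, p_mus), freq = p_mus),
      map = map, is_fixed_diff = is_fixed), class = "subspecies_panels")
  })
}

#' @export
print.subspecies_panels <- function(x, ...) {
  cat(sprintf(
    "Subspecies panels: %d domesticus + %d musculus individuals, %d SNPs (%d simulated fixed differences)\n",
    nrow(x$domesticus$genotypes), nrow(x$musculus$genotypes),
    nrow(x$map), sum(x$is_fixed_diff)))
  invisible(x)
}

#' Classify SNPs as ancestry-diagnostic and compute F_ST between panels
#'
#' A SNP is diagnostic when alternate alleles are fixed in the two panel
#' samples. Differentiation is measured with Hudson's estimator
#' F_ST = 1 - Hw/Hb, where Hw = p1(1-p1) + p2(1-p2) and
#' Hb = p1(1-p2) + p2(1-p1); SNPs with F_ST at or above `f_st_threshold`
#' are flagged as highly differentiated. SNPs monomorphic for the same
#' allele in both panels have undefined F_ST (Hb = 0) and are flagged.
#'
#' @param panels A `subspecies_panels` object (or any list with
#'   `domesticus$genotypes` and `musculus$genotypes`).
#' @param f_st_threshold High-differentiation cutoff (default 0.7).
#' @return Data frame: `snp_id`, panel sample frequencies, `fst`,
#'   `diagnostic`, `high_fst`, `fst_undefined`.
#' @export
assign_diagnostic_status <- function(panels, f_st_threshold = 0.7) {
  check_fraction(f_st_threshold, "f_st_threshold")
  p1 <- allele_freq(panels$domesticus$genotypes)
  p2 <- allele_freq(panels$musculus$genotypes)
  hw <- p1 * (1 - p1) + p2 * (1 - p2)
  hb <- p1 * (1 - p2) + p2 * (1 - p1)
  fst <- ifelse(hb > 0, 1 - hw / hb, NA_real_)
  data.frame(snp_id = colnames(panels$domesticus$genotypes),
             freq_domesticus = p1, freq_musculus = p2, fst = fst,
             diagnostic = (p1 == 0 & p2 == 1) | (p1 == 1 & p2 == 0),
             high_fst = !is.na(fst) & fst >= f_st_threshold,
             fst_undefined = is.na(fst),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate a hybrid-zone mating design
#'
#' Builds a one-generation breeding design from wild-caught admixed
#' founders: `n_pairs` dam x sire matings drawn from `n_dams` dams and
#' `n_sires` sires with reuse, so the offspring cohort contains full
#' siblings, half siblings and unrelated individuals. Each founder's hybrid
#' index is drawn from a Beta distribution (default uniform). Defaults
#' mirror a mapping population of 185 males from 63 pairs of 37 dams and
#' 35 sires.
#'
#' @param n_dams,n_sires,n_pairs,n_offspring Design counts.
#' @param founder_beta Length-2 shape parameters of the founder
#'   hybrid-index Beta distribution.
#' @param founder_hybrid_index Optional explicit per-founder hybrid indices
#'   (named vector over founder ids), overriding the Beta draw.
#' @param seed Optional integer seed.
#' @return List of class `hz_pedigree`: `pedigree` (id, dam, sire, sex) and
#'   `founders` (id, sex, hybrid_index).
#' @export
simulate_hybrid_zone_pedigree <- function(n_dams = 37, n_sires = 35,
                                          n_pairs = 63, n_offspring = 185,
                                          founder_beta = c(1, 1),
                                          founder_hybrid_index = NULL,
                                          seed = NULL) {
  check_count(n_dams, "n_dams"); check_count(n_sires, "n_sires")
  check_count(n_pairs, "n_pairs")
  check_count(n_offspring, "n_offspring")
  if (n_offspring < n_pairs)
    stop("n_offspring must be >= n_pairs (each pair produces offspring)",
         call. = FALSE)
  with_seed(seed, {
    dam_ids <- sprintf("dam%02d", seq_len(n_dams))
    sire_ids <- sprintf("sire%02d", seq_len(n_sires))
    # every founder used at least once, then reuse at random; unique pairs
    pair_dams <- c(dam_ids[seq_len(min(n_dams, n_pairs))],
                   sample(dam_ids, max(0L, n_pairs - n_dams), replace = TRUE))
    pair_sires <- c(sire_ids[seq_len(min(n_sires, n_pairs))],
                    sample(sire_ids, max(0L, n_pairs - n_sires),
                           replace = TRUE))
    pair_sires <- sample(pair_sires)
    key <- paste(pair_dams, pair_sires)
    tries <- 0L
    while (anyDuplicated(key) && tries < 1000L) {
      i <- which(duplicated(key))[1]
      pair_sires[i] <- sample(sire_ids, 1L)
      key <- paste(pair_dams, pair_sires)
      tries <- tries + 1L
    }
    counts <- rep(1L, n_pairs)
    extra <- n_offspring - n_pairs
    if (extra > 0) {
      add <- table(sample.int(n_pairs, extra, replace = TRUE))
      counts[as.integer(names(add))] <- counts[as.integer(names(add))] +
        as.integer(add)
    }
    pedigree <- data.frame(
      id = sprintf("ind%03d", seq_len(n_offspring)),
      dam = rep(pair_dams, counts), sire = rep(pair_sires, counts),
      sex = "M", stringsAsFactors = FALSE)
    h <- if (!is.null(founder_hybrid_index)) {
      founder_hybrid_index[c(dam_ids, sire_ids)]
    } else {
      stats::rbeta(n_dams + n_sires, founder_beta[1], founder_beta[2])
    }
    founders <- data.frame(id = c(dam_ids, sire_ids),
                           sex = rep(c("F", "M"), c(n_dams, n_sires)),
                           hybrid_index = as.numeric(h),
                           stringsAsFactors = FALSE)
    structure(list(pedigree = pedigree, founders = founders),
              class = "hz_pedigree")
  })
}

#' @export
print.hz_pedigree <- function(x, ...) {
  cat(sprintf("Hybrid-zone pedigree: %d offspring from %d pairs (%d dams, %d sires)\n",
              nrow(x$pedigree), length(unique(paste(x$pedigree$dam,
                                                    x$pedigree$sire))),
              length(unique(x$pedigree$dam)),
              length(unique(x$pedigree$sire))))
  invisible(x)
}

# Simulate one founder haplotype for a chromosome: ancestry tracts with
# Poisson boundaries at `gen * rate` per Mb, tract ancestry ~ Bern(h)
# (1 = musculus), alleles drawn from the ancestral panel frequency.
founder_haplotype <- function(pos, chrom_len, gen, rate, h, p_dom, p_mus) {
  n_b <- if (gen > 0) stats::rpois(1L, gen * rate * chrom_len / 1e6) else 0L
  if (n_b > 0) {
    breaks <- sort(stats::runif(n_b, 1, chrom_len))
    anc_tract <- stats::rbinom(n_b + 1L, 1L, h)
    anc <- anc_tract[1L + findInterval(pos, breaks)]
  } else {
    anc <- rep(stats::rbinom(1L, 1L, h), length(pos))
  }
  p <- ifelse(anc == 1L, p_mus, p_dom)
  list(allele = stats::rbinom(length(pos), 1L, p), anc = anc)
}

#' Drop genotypes through the pedigree to build the admixed mapping panel
#'
#' Founder genomes are mosaics of subspecies ancestry tracts whose expected
#' tract length shrinks with `admix_generations`; within a tract, alleles
#' are drawn from the corresponding panel's allele frequency. Offspring
#' receive one Poisson-crossover recombinant haplotype per parent per
#' chromosome; males inherit their single X from the dam and are coded
#' hemizygous (0/2).
#'
#' @param panels A `subspecies_panels` object.
#' @param pedigree An `hz_pedigree` object.
#' @param recomb_rate_per_Mb Expected crossovers per Mb per meiosis
#'   (default 0.005, i.e. 0.5 cM/Mb).
#' @param admix_generations Generations of admixture encoded in founder
#'   tract structure (default 8).
#' @param chrom_lengths Chromosome lengths (bp) matching the panel map.
#' @param missing_rate Missing-at-random genotype rate (default 0.01).
#' @param seed Optional integer seed.
#' @return An `admixed_genotypes` object with an extra `truth` element:
#'   per-individual realized autosomal musculus ancestry fraction.
#' @export
drop_genotypes_through_pedigree <- function(panels, pedigree,
                                            recomb_rate_per_Mb = 0.005,
                                            admix_generations = 8,
                                            chrom_lengths =
                                              default_chrom_lengths(),
                                            missing_rate = 0.01,
                                            seed = NULL) {
  check_fraction(missing_rate, "missing_rate", hi = 0.5)
  if (recomb_rate_per_Mb < 0) stop("recomb_rate_per_Mb must be >= 0",
                                   call. = FALSE)
  if (admix_generations < 0) stop("admix_generations must be >= 0",
                                  call. = FALSE)
  map <- panels$map
  ped <- pedigree$pedigree
  founders <- pedigree$founders
  with_seed(seed, {
    chroms <- unique(map$chrom)
    by_chr <- lapply(chroms, function(ch) which(map$chrom == ch))
    names(by_chr) <- chroms
    p_dom <- panels$domesticus$freq
    p_mus <- panels$musculus$freq
    # founder genomes: per chromosome a 2 x m (or 1 x m for sire X)
    fg <- lapply(seq_len(nrow(founders)), function(i) {
      h <- founders$hybrid_index[i]
      male <- founders$sex[i] == "M"
      g <- lapply(chroms, function(ch) {
        j <- by_chr[[ch]]
        nh <- if (ch == "X" && male) 1L else 2L
        haps <- lapply(seq_len(nh), function(k)
          founder_haplotype(map$pos[j], chrom_lengths[[ch]],
                            admix_generations, recomb_rate_per_Mb, h,
                            p_dom[j], p_mus[j]))
        list(allele = do.call(rbind, lapply(haps, `[[`, "allele")),
             anc = do.call(rbind, lapply(haps, `[[`, "anc")))
      })
      names(g) <- chroms
      g
    })
    names(fg) <- founders$id
    n <- nrow(ped); m <- nrow(map)
    geno <- matrix(0L, n, m, dimnames = list(ped$id, map$snp_id))
    anc_frac <- numeric(n)
    auto_snps <- sum(map$chrom != "X")
    for (i in seq_len(n)) {
      dam <- fg[[ped$dam[i]]]; sire <- fg[[ped$sire[i]]]
      male <- ped$sex[i] == "M"
      anc_sum <- 0
      for (ch in chroms) {
        j <- by_chr[[ch]]
        pos <- map$pos[j]; L <- chrom_lengths[[ch]]
        if (ch == "X") {
          hd_i <- recombine_with_anc(dam[[ch]], pos, L, recomb_rate_per_Mb)
          if (male) {
            geno[i, j] <- 2L * hd_i$allele
          } else {
            hs <- list(allele = sire[[ch]]$allele[1, ],
                       anc = sire[[ch]]$anc[1, ])
            geno[i, j] <- hd_i$allele + hs$allele
          }
        } else {
          hd_i <- recombine_with_anc(dam[[ch]], pos, L, recomb_rate_per_Mb)
          hs_i <- recombine_with_anc(sire[[ch]], pos, L, recomb_rate_per_Mb)
          geno[i, j] <- hd_i$allele + hs_i$allele
          anc_sum <- anc_sum + sum(hd_i$anc) + sum(hs_i$anc)
        }
      }
      anc_frac[i] <- anc_sum / (2 * auto_snps)
    }
    if (missing_rate > 0) {
      miss <- matrix(stats::runif(n * m) < missing_rate, n, m)
      geno[miss] <- NA_integer_
    }
    out <- admixed_genotypes(geno, map, sex = ped$sex)
    out$truth <- list(musculus_ancestry = stats::setNames(anc_frac, ped$id))
    out
  })
}

# recombine both allele and ancestry rows coherently (same crossovers)
recombine_with_anc <- function(chr, pos, chrom_len, rate) {
  if (nrow(chr$allele) == 1L)
    return(list(allele = chr$allele[1, ], anc = chr$anc[1, ]))
  n_x <- stats::rpois(1L, rate * chrom_len / 1e6)
  use <- sample.int(2L, 1L)
  if (n_x == 0L) return(list(allele = chr$allele[use, ],
                             anc = chr$anc[use, ]))
  breaks <- sort(stats::runif(n_x, 1, chrom_len))
  seg <- findInterval(pos, breaks)
  idx <- 1L + (use - 1L + seg) %% 2L
  sel <- cbind(idx, seq_along(pos))
  list(allele = chr$allele[sel], anc = chr$anc[sel])
}

#' Simulate a complete synthetic mapping population
#'
#' Convenience wrapper composing [simulate_ancestral_panels()],
#' [simulate_hybrid_zone_pedigree()] and
#' [drop_genotypes_through_pedigree()] under one seed.
#'
#' @param n_snps,prop_fixed_diff,chrom_scale Panel settings.
#' @param n_offspring Mapping-population size (default 185 males).
#' @param admix_generations,recomb_rate_per_Mb,missing_rate Admixture
#'   settings.
#' @param seed Optional integer seed.
#' @return List: `panels`, `pedigree`, `genotypes`, `diagnostic`
#'   (from [assign_diagnostic_status()]), `chrom_lengths`.
#' @export
simulate_mapping_population <- function(n_snps = 5000, prop_fixed_diff = 0.4,
                                        chrom_scale = 1, n_offspring = 185,
                                        admix_generations = 8,
                                        recomb_rate_per_Mb = 0.005,
                                        missing_rate = 0.01, seed = NULL) {
  cl <- default_chrom_lengths(chrom_scale)
  panels <- simulate_ancestral_panels(n_snps = n_snps,
                                      prop_fixed_diff = prop_fixed_diff,
                                      chrom_lengths = cl,
                                      seed = derive_seed(seed, "panels"))
  # scale the 37/35/63 breeding design proportionally for smaller cohorts
  sc <- min(1, n_offspring / 185)
  ped <- simulate_hybrid_zone_pedigree(
    n_dams = max(2, round(37 * sc)), n_sires = max(2, round(35 * sc)),
    n_pairs = max(1, min(round(63 * sc), n_offspring)),
    n_offspring = n_offspring, seed = derive_seed(seed, "pedigree"))
  geno <- drop_genotypes_through_pedigree(
    panels, ped, recomb_rate_per_Mb = recomb_rate_per_Mb,
    admix_generations = admix_generations, chrom_lengths = cl,
    missing_rate = missing_rate, seed = derive_seed(seed, "drop"))
  list(panels = panels, pedigree = ped, genotypes = geno,
       diagnostic = assign_diagnostic_status(panels), chrom_lengths = cl)
}

#' Relative testis weight
#'
#' Combined testis weight divided by body weight, in mg/g — the
#' fertility-proxy phenotype for male hybrids.
#'
#' @param testis_mg Combined testis weight(s), mg.
#' @param body_g Body weight(s), g.
#' @return Numeric vector, mg/g.
#' @export
#' @examples compute_relative_testis_weight(200, 20)  # 10 mg/g
compute_relative_testis_weight <- function(testis_mg, body_g) {
  if (any(!is.finite(testis_mg)) || any(!is.finite(body_g)) ||
      any(testis_mg <= 0) || any(body_g <= 0))
    stop("weights must be positive and finite", call. = FALSE)
  testis_mg / body_g
}

#' Flag subfertile individuals
#'
#' An individual is flagged when its phenotype falls strictly below the
#' minimum observed in pure subspecies males.
#'
#' @param phenotype_values Numeric phenotype vector.
#' @param pure_range_min Minimum of the pure-subspecies range.
#' @return Logical vector.
#' @export
classify_subfertile <- function(phenotype_values, pure_range_min) {
  stopifnot(is.numeric(pure_range_min), length(pure_range_min) == 1L)
  phenotype_values < pure_range_min
}

#' Per-individual hybrid index
#'
#' Fraction of musculus alleles among non-missing diagnostic autosomal
#' genotypes; 0 = pure domesticus, 1 = pure musculus.
#'
#' @param genotypes An `admixed_genotypes` object.
#' @param diagnostic Logical per-SNP diagnostic flags, or the data frame
#'   from [assign_diagnostic_status()].
#' @return Named numeric vector in \[0, 1\].
#' @export
hybrid_index <- function(genotypes, diagnostic) {
  if (is.data.frame(diagnostic)) {
    diagnostic <- diagnostic$diagnostic[match(genotypes$map$snp_id,
                                              diagnostic$snp_id)]
  }
  use <- which(diagnostic & autosomal(genotypes))
  if (length(use) == 0L)
    stop("no usable diagnostic autosomal SNPs", call. = FALSE)
  h <- rowMeans(genotypes$matrix[, use, drop = FALSE] / 2, na.rm = TRUE)
  if (anyNA(h))
    stop("individual(s) with no non-missing diagnostic genotypes",
         call. = FALSE)
  h
}
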