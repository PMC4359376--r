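test_that("architecture mean tables follow the penetrance-product rule", {
  m <- build_genotype_mean_table("add-add", seed = 80)
  # heterozygote x sterile homozygote under additive models: -1.15
  expect_equal(m$mean_table["1", "2"], -1.15)
  expect_equal(m$mean_table["2", "1"], -1.15)
  expect_equal(m$mean_table["2", "2"], -2.3)
  expect_equal(m$mean_table["1", "1"], -2.3 * 0.25)
  # non-carrier x sterile homozygote: drawn from U(-0.5, 0.5)
  expect_true(m$mean_table["0", "2"] >= -0.5 && m$mean_table["0", "2"] <= 0.5)

  mdd <- build_genotype_mean_table("dom-dom", seed = 81)
  expect_equal(mdd$mean_table["1", "1"], -2.3)  # het x het fully severe
  mrr <- build_genotype_mean_table("rec-rec", seed = 82)
  expect_true(all(mrr$mean_table[c("0", "1"), ] >= -0.5))
  expect_equal(mrr$mean_table["2", "2"], -2.3)

  mx <- build_genotype_mean_table("X-dom", seed = 83)
  expect_true(all(is.na(mx$mean_table["1", ])))  # no het class on male X
  expect_equal(mx$mean_table["2", "1"], -2.3)

  expect_error(build_genotype_mean_table("foo"), "architecture_class")
  expect_equal(length(architecture_classes()), 9L)
})

test_that("causal-pair selection enforces the frequency and fixation criteria", {
  pop <- tiny_pop()
  # no SNP fixed anywhere -> empty pool error
  set.seed(84)
  loose <- matrix(rbinom(30 * 50, 2, runif(50, 0.3, 0.7)), 30, 50,
                  byrow = TRUE)
  panels_loose <- list(
    domesticus = list(genotypes = {
      m <- loose[1:15, ]; colnames(m) <- pop$genotypes$map$snp_id[1:50]; m
    }),
    musculus = list(genotypes = {
      m <- loose[16:30, ]; colnames(m) <- pop$genotypes$map$snp_id[1:50]; m
    }),
    map = pop$panels$map[1:50, ])
  expect_error(select_causal_pairs(pop$genotypes, panels_loose, 3,
                                   "auto-auto", seed = 85),
               "pool")

  # drawn pairs always satisfy the criteria (property over seeds)
  f_map <- colMeans(pop$genotypes$matrix, na.rm = TRUE) / 2
  maf_map <- pmin(f_map, 1 - f_map)
  p_dom <- colMeans(pop$panels$domesticus$genotypes) / 2
  p_mus <- colMeans(pop$panels$musculus$genotypes) / 2
  for (s in 1:25) {
    pr <- select_causal_pairs(pop$genotypes, pop$panels, 4, "auto-auto",
                              seed = s)
    expect_true(all(pr$chrom_1 != pr$chrom_2))
    i1 <- match(pr$snp_1, pop$genotypes$map$snp_id)
    i2 <- match(pr$snp_2, pop$genotypes$map$snp_id)
    expect_true(all(maf_map[c(i1, i2)] > 0.05))
    # locus 1 musculus-sterile: alternate allele fixed in domesticus
    expect_true(all(p_dom[i1] == 0))
    expect_true(all(p_mus[i1] >= 0.05))
    # locus 2 domesticus-sterile: alternate (musculus) fixed in musculus
    expect_true(all(p_mus[i2] == 1))
    expect_true(all(1 - p_dom[i2] >= 0.05))
  }
  prx <- select_causal_pairs(pop$genotypes, pop$panels, 6, "X-auto",
                             seed = 86)
  expect_true(all(prx$chrom_1 == "X"))
  expect_true(all(prx$chrom_2 != "X"))
  expect_equal(sum(prx$sterile_1 == "musculus"), 3)
})

test_that("phenotype simulation draws around the genotype-class means", {
  pop <- tiny_pop()
  pr <- select_causal_pairs(pop$genotypes, pop$panels, 1, "auto-auto",
                            seed = 87)
  m <- build_genotype_mean_table("rec-rec", seed = 88)
  # near-degenerate noise: phenotypes equal class means
  m0 <- m; m0$residual_sd <- 1e-9
  sim0 <- simulate_phenotype_datasets(pr[1, ], m0, pop$genotypes, 1,
                                      seed = 89)
  dbl <- sim0$dose_1 == 2 & sim0$dose_2 == 2
  if (any(dbl)) expect_equal(unname(sim0$phenotypes[dbl, 1]),
                             rep(-2.3, sum(dbl)), tolerance = 1e-6)
  # CLT check on the severe class with real noise
  sim <- simulate_phenotype_datasets(pr[1, ], m, pop$genotypes, 50,
                                     seed = 90)
  if (any(dbl)) {
    sev <- colMeans(sim$phenotypes[dbl, , drop = FALSE])
    n_sev <- sum(dbl) * 50
    expect_lt(abs(mean(sev) + 2.3), 4 * 0.75 / sqrt(n_sev))
  }
  # affected fraction = share of individuals in classes at or below -1.15
  tab <- m$mean_table
  cls_mean <- tab[cbind(sim$dose_1 + 1L, sim$dose_2 + 1L)]
  expect_equal(sim$affected_fraction[1], mean(cls_mean <= -1.15))
})

test_that("detection and false-positive bookkeeping match hand enumeration", {
  map <- data.frame(snp_id = sprintf("m%02d", 1:8),
                    chrom = c("1", "1", "1", "2", "2", "3", "3", "3"),
                    pos = c(1e6, 5e6, 80e6, 10e6, 30e6, 1e6, 2e6, 90e6))
  scan <- cbind(map, data.frame(p_wald = 1e-8))
  geno <- admixed_genotypes(matrix(rep(c(0L, 1L, 2L), length.out = 3 * 8),
                                   3, 8), map)
  pair <- data.frame(snp_1 = "m01", snp_2 = "m04", chrom_1 = "1",
                     chrom_2 = "2", stringsAsFactors = FALSE)
  # significant: m02 (4 Mb from m01), m03 (79 Mb, same chrom),
  # m05 (20 Mb from m04), m06 (other chrom)
  sig <- c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE)
  det <- evaluate_detection(scan, sig, pair, geno)
  expect_equal(unname(det$detected["locus1", ]), c(FALSE, FALSE, TRUE))
  expect_equal(unname(det$detected["locus2", ]), c(FALSE, FALSE, FALSE))
  expect_equal(unname(det$both), c(FALSE, FALSE, FALSE))

  # significant SNP exactly at the causal position: detected everywhere
  sig_at <- c(TRUE, rep(FALSE, 7))
  det_at <- evaluate_detection(scan, sig_at, pair, geno)
  expect_true(all(det_at$detected["locus1", ]))

  # only SNP 15 Mb away -> not detected at any criterion
  map2 <- map; map2$pos[2] <- 16e6
  scan2 <- cbind(map2, data.frame(p_wald = 1e-8))
  geno2 <- admixed_genotypes(geno$matrix, map2)
  det2 <- evaluate_detection(scan2, c(FALSE, TRUE, rep(FALSE, 6)), pair,
                             geno2)
  expect_false(any(det2$detected["locus1", ]))

  # FDR arithmetic: TP = m02, m05 (<50 Mb), excluded = m03 (79 Mb),
  # FP = m06 -> 1 / (1 + 2) with reporting floor lowered
  fp <- false_positive_rate(scan, sig, pair, geno, min_tp = 1)
  expect_equal(fp$tp, 2L); expect_equal(fp$fp, 1L)
  expect_equal(fp$excluded, 1L)
  expect_equal(fp$fdr, 1 / 3)
  # constructed mixture 3 TP / 1 FP / 2 excluded -> 0.25:
  # TP m01, m02, m04; excluded m03 (59 Mb), m05 (55 Mb); FP m06
  sig3 <- c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  map3 <- map; map3$pos[3] <- 60e6; map3$pos[5] <- 65e6
  scan3 <- cbind(map3, data.frame(p_wald = 1e-8))
  geno3 <- admixed_genotypes(geno$matrix, map3)
  fp3 <- false_positive_rate(scan3, sig3, pair, geno3, min_tp = 1)
  expect_equal(c(fp3$tp, fp3$fp, fp3$excluded), c(3L, 1L, 2L))
  expect_equal(fp3$fdr, 0.25)
  # all significant on non-causal chromosomes -> FDR 1 (unreportable by
  # default floor, so relax it)
  sig_fp <- c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  fp_all <- false_positive_rate(scan, sig_fp, pair, geno, min_tp = 0)
  expect_equal(fp_all$fdr, 1)
  # all within 1 Mb -> FDR 0
  fp0 <- false_positive_rate(scan, sig_at, pair, geno, min_tp = 1)
  expect_equal(fp0$fdr, 0)
  # reporting rule: fewer than 10 within-50 Mb SNPs -> NA
  fp_na <- false_positive_rate(scan, sig, pair, geno)
  expect_true(is.na(fp_na$fdr))
})

test_that("the study design enumerates the full factorial without execution", {
  pop <- tiny_pop()
  st <- run_full_study(pop$genotypes, pop$panels,
                       n_pairs_per_class = 100, n_datasets = 100,
                       count_only = TRUE)
  expect_equal(st$n_datasets_total, 9L * 100L * 100L)
  expect_equal(st$n_datasets_total, 90000L)
  st2 <- run_full_study(pop$genotypes, pop$panels,
                        architectures = "dom-dom", n_pairs_per_class = 2,
                        n_datasets = 3, count_only = TRUE)
  expect_equal(st2$n_datasets_total, 6L)
})

test_that("a mini study runs, logs every dataset and orders dominance sensibly", {
  pop <- tiny_pop()
  K <- centered_kinship(pop$genotypes)
  st <- run_full_study(pop$genotypes, pop$panels, K,
                       architectures = c("rec-rec", "dom-dom"),
                       n_pairs_per_class = 2, n_datasets = 3,
                       n_perm = 40, seed = 91)
  expect_equal(nrow(st$datasets), 12L)
  expect_equal(nrow(st$report), 2L)
  # detection non-decreasing in distance criterion
  for (r in seq_len(nrow(st$report))) {
    expect_lte(st$report$both_perm_0.2[r], st$report$both_perm_1[r])
    expect_lte(st$report$both_perm_1[r], st$report$both_perm_10[r])
  }
  # both-loci <= each single locus
  expect_true(all(st$report$both_perm_10 <=
                    pmin(st$report$l1_perm_10, st$report$l2_perm_10)))
  # determinism under seed
  st_rep <- run_full_study(pop$genotypes, pop$panels, K,
                           architectures = c("rec-rec", "dom-dom"),
                           n_pairs_per_class = 2, n_datasets = 3,
                           n_perm = 40, seed = 91)
  expect_identical(st$datasets, st_rep$datasets)
})
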