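make_two_chrom_genotypes <- function(n, m_per_chrom = 3, seed = 1) {
  set.seed(seed)
  mat <- matrix(sample(0:2, n * 2 * m_per_chrom, replace = TRUE), n)
  storage.mode(mat) <- "integer"
  map <- data.frame(snp_id = sprintf("s%02d", seq_len(2 * m_per_chrom)),
                    chrom = rep(c("1", "2"), each = m_per_chrom),
                    pos = rep(seq_len(m_per_chrom) * 1e6, 2))
  admixed_genotypes(mat, map)
}

test_that("interaction scan with K = I equals the ordinary-regression oracle", {
  n <- 100
  g <- make_two_chrom_genotypes(n, seed = 70)
  set.seed(71)
  ga <- g$matrix[, 1]; gb <- g$matrix[, 4]
  y <- 0.3 * ga - 0.2 * gb + 0.5 * ga * gb + rnorm(n)
  res <- interaction_scan(c("s01", "s04"), g, y, kinship = diag(n))
  expect_equal(nrow(res), 1L)
  # OLS oracle with the same Wald construction (chi-square from t stat)
  f <- summary(lm(y ~ ga * gb))$coefficients
  p_oracle <- pchisq((f["ga:gb", 1] / f["ga:gb", 2])^2, 1,
                     lower.tail = FALSE)
  expect_equal(res$p_int, p_oracle, tolerance = 1e-8)
})

test_that("same-chromosome pairs are excluded from interaction testing", {
  n <- 50
  g <- make_two_chrom_genotypes(n, seed = 72)
  y <- rnorm(n)
  expect_error(interaction_scan(c("s01", "s02"), g, y, kinship = diag(n)),
               "cross-chromosome")
  res <- interaction_scan(c("s01", "s02", "s04"), g, y,
                          kinship = diag(n))
  expect_equal(nrow(res), 2L)  # s01-s04 and s02-s04 only
  expect_true(all(res$chrom_a != res$chrom_b))
})

test_that("interaction type-I error is controlled under additive truth", {
  n <- 120
  g <- make_two_chrom_genotypes(n, seed = 73)
  set.seed(74)
  ga <- g$matrix[, 2]; gb <- g$matrix[, 5]
  hits <- 0; reps <- 400
  for (r in seq_len(reps)) {
    y <- 0.4 * ga + 0.4 * gb + rnorm(n)
    res <- interaction_scan(c("s02", "s05"), g, y, kinship = diag(n))
    if (!is.na(res$p_int) && res$p_int < 0.05) hits <- hits + 1
  }
  rate <- hits / reps
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(rate - 0.05), 4 * se + 0.01)
})

test_that("a strong double-carrier incompatibility is detected", {
  pop <- tiny_pop()
  g <- pop$genotypes
  K <- centered_kinship(g)
  # pick two common cross-chromosome SNPs and plant a -2.3 SD effect in
  # double homozygotes
  f <- colMeans(g$matrix, na.rm = TRUE) / 2
  cand <- which(f > 0.35 & f < 0.65 & g$map$chrom %in% c("1", "2"))
  a <- cand[g$map$chrom[cand] == "1"][1]
  b <- cand[g$map$chrom[cand] == "2"][1]
  set.seed(75)
  ga <- g$matrix[, a]; gb <- g$matrix[, b]
  ga[is.na(ga)] <- 1L; gb[is.na(gb)] <- 1L
  y <- rnorm(nrow(K), 0, 0.75)
  y[ga == 2 & gb == 2] <- y[ga == 2 & gb == 2] - 2.3
  res <- interaction_scan(g$map$snp_id[c(a, b)], g, y, kinship = K)
  expect_lt(res$p_int, 1e-4)
  expect_true(res$significant)
})

test_that("two-locus genotype means are exact and absent cells stay absent", {
  mat <- cbind(c(0L, 0L, 1L, 1L, 2L, 2L), c(0L, 2L, 0L, 2L, 0L, 2L))
  map <- data.frame(snp_id = c("a", "b"), chrom = c("1", "2"),
                    pos = c(1e6, 1e6))
  g <- admixed_genotypes(mat, map)
  y <- c(10, 20, 30, 40, 50, 60)
  mt <- two_locus_genotype_means(g, "a", "b", y)
  expect_equal(mt$mean["D", "D"], 10)
  expect_equal(mt$mean["M", "M"], 60)
  expect_equal(unname(mt$n["H", ]), c(1L, 1L))
  # no H class at locus b: column absent entirely
  expect_false("H" %in% colnames(mt$mean))
  # constant phenotype: all present cells equal
  mt2 <- two_locus_genotype_means(g, "a", "b", rep(7, 6))
  expect_true(all(mt2$mean == 7, na.rm = TRUE))
})

test_that("effect deviations recover constructed single and pair effects", {
  # cohort built so the worst single-locus genotype mean deviates -1.81
  # and the worst two-locus cell deviates -4.07 from the population mean
  pop_mean <- 10
  n_cell <- 20
  ga <- rep(0:2, each = 3 * n_cell)
  gb <- rep(rep(0:2, each = n_cell), 3)
  # worst two-locus cell (M,M) mean = pop_mean - 4.07; the other two
  # cells of the ga = 2 row chosen so the row mean is pop_mean - 1.81
  y <- rep(pop_mean, length(ga))
  y[ga == 2 & gb == 2] <- pop_mean - 4.07
  y[ga == 2 & gb != 2] <- pop_mean - (3 * 1.81 - 4.07) / 2
  mat <- cbind(as.integer(ga), as.integer(gb))
  map <- data.frame(snp_id = c("a", "b"), chrom = c("1", "2"),
                    pos = c(1e6, 1e6))
  g <- admixed_genotypes(mat, map)
  sm <- single_locus_genotype_means(g, "a", y)
  dev_single <- effect_deviations(sm, pop_mean, pure_range_min = 7)
  expect_equal(mean(y[ga == 2]), pop_mean - 1.81)
  expect_equal(dev_single$effect, -1.81, tolerance = 1e-12)
  mt <- two_locus_genotype_means(g, "a", "b", y)
  expect_equal(min(mt$mean), pop_mean - 4.07)
  fake_int <- structure(data.frame(snp_a = "a", snp_b = "b",
                                   min_cell_mean = min(mt$mean)),
                        class = c("hz_interactions", "data.frame"))
  dev_pair <- effect_deviations(fake_int, pop_mean, pure_range_min = 7)
  expect_equal(dev_pair$effect, -4.07)
  expect_true(dev_pair$below_pure_range)   # 5.93 < 7
  expect_false(dev_single$below_pure_range) # 8.19 >= 7

  # degenerate cohort: identical values -> zero deviation, no flag
  y0 <- rep(5, 6)
  g0 <- admixed_genotypes(cbind(c(0L,1L,2L,0L,1L,2L), rep(c(0L,2L),3)),
                          map)
  sm0 <- single_locus_genotype_means(g0, "a", y0)
  d0 <- effect_deviations(sm0, 5, pure_range_min = 5)
  expect_equal(d0$effect, 0)
  expect_false(d0$below_pure_range)
})

test_that("region-pair summaries aggregate SNP pairs and respect disjointness", {
  regions <- structure(
    data.frame(region_id = c("R01", "R02", "R03"),
               chrom = c("1", "2", "X"),
               start = c(1, 1, 1), end = c(2e6, 2e6, 2e6),
               snp_ids = c("a1,a2", "b1", "x1"),
               stringsAsFactors = FALSE),
    class = c("hz_regions", "data.frame"))
  ints <- structure(
    data.frame(snp_a = c("a1", "a2", "a1", "x1"),
               snp_b = c("b1", "b1", "x1", "b1"),
               significant = c(TRUE, TRUE, TRUE, FALSE),
               stringsAsFactors = FALSE),
    class = c("hz_interactions", "data.frame"))
  s <- summarize_region_pairs(ints, regions)
  expect_equal(nrow(s$pairs), 2L)
  expect_equal(s$n_sig_snp_pairs, 3L)  # counts sum to total sig pairs
  expect_equal(s$pairs$n_sig_pairs[s$pairs$region_a == "R01" &
                                     s$pairs$region_b == "R02"], 2L)
  expect_equal(s$n_auto_auto, 1L)
  expect_equal(s$n_x_auto, 1L)
  # a SNP in two regions is an error
  regions2 <- regions
  regions2$snp_ids[2] <- "a1,b1"
  expect_error(summarize_region_pairs(ints, regions2), "disjoint")
  # no significant pairs -> empty table
  ints0 <- ints; ints0$significant <- FALSE
  s0 <- summarize_region_pairs(ints0, regions)
  expect_equal(nrow(s0$pairs), 0L)
})

test_that("sterile-allele inference follows frequency and effect direction", {
  # 5-SNP region; genotypes code musculus-allele counts
  n <- 60
  set.seed(76)
  mat <- matrix(rbinom(n * 5, 2, 0.5), n)
  storage.mode(mat) <- "integer"
  g <- toy_genotypes(mat)
  regions <- structure(
    data.frame(region_id = "R01", chrom = "1", start = 1e6, end = 5e6,
               snp_ids = paste(g$map$snp_id, collapse = ","),
               stringsAsFactors = FALSE),
    class = c("hz_regions", "data.frame"))
  diag_df <- data.frame(snp_id = g$map$snp_id,
                        freq_domesticus = c(0, 0, 0.05, 0.3, 0.4),
                        freq_musculus = c(1, 1, 0.95, 0.6, 0.5),
                        fst = c(1, 1, 0.81, 0.09, 0.01),
                        diagnostic = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  # phenotype decreases with musculus dosage at SNPs 1-3 -> M calls
  y <- -rowSums(mat[, 1:3]) + rnorm(n, 0, 0.1)
  res <- infer_sterile_allele(regions, g, y, diag_df)
  expect_equal(res$sterile_allele, "M")
  expect_gte(res$n_m, 3)

  # domesticus-sterile: phenotype decreases with domesticus dosage at a
  # SNP fixed for domesticus (musculus freq 0 in domesticus panel)
  g1 <- toy_genotypes(mat[, 1, drop = FALSE])
  regions1 <- structure(
    data.frame(region_id = "R01", chrom = "1", start = 1e6, end = 1e6,
               snp_ids = "t001", stringsAsFactors = FALSE),
    class = c("hz_regions", "data.frame"))
  diag1 <- data.frame(snp_id = "t001", freq_domesticus = 0,
                      freq_musculus = 1, fst = 1, diagnostic = TRUE)
  y1 <- rowSums(mat[, 1, drop = FALSE]) + rnorm(n, 0, 0.1)  # musc raises
  res1 <- infer_sterile_allele(regions1, g1, y1, diag1)
  expect_equal(res1$sterile_allele, "D")

  # balanced opposing calls -> U
  diag2 <- data.frame(snp_id = g$map$snp_id[1:2],
                      freq_domesticus = c(0, 0),
                      freq_musculus = c(1, 1),
                      fst = c(1, 1), diagnostic = TRUE)
  g2 <- toy_genotypes(mat[, 1:2])
  regions2 <- structure(
    data.frame(region_id = "R01", chrom = "1", start = 1e6, end = 2e6,
               snp_ids = "t001,t002", stringsAsFactors = FALSE),
    class = c("hz_regions", "data.frame"))
  y2 <- -mat[, 1] - (2 - mat[, 2]) + rnorm(n, 0, 0.1)
  res2 <- infer_sterile_allele(regions2, g2, y2, diag2)
  expect_equal(res2$sterile_allele, "U")
})
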