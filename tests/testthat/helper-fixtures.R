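# Shared fixtures, generated once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small admixed population for unit tests: 80 males x 800 SNPs
tiny_pop <- function() {
  fixture("tiny_pop",
          simulate_mapping_population(n_snps = 800, n_offspring = 80,
                                      missing_rate = 0.01, seed = 42))
}

# genotype container built by hand from a plain matrix (one chromosome)
toy_genotypes <- function(mat, pos = NULL, chrom = "1", sex = NULL) {
  m <- ncol(mat)
  if (is.null(pos)) pos <- seq_len(m) * 1e6
  map <- data.frame(snp_id = sprintf("t%03d", seq_len(m)),
                    chrom = rep(chrom, length.out = m), pos = pos)
  admixed_genotypes(mat, map, sex = sex)
}

# pedigree-based kinship coefficients by the standard tabular recursion;
# founders assumed unrelated and non-inbred
pedigree_kinship <- function(pedigree, founders) {
  ids <- c(founders$id, pedigree$id)
  par <- rbind(data.frame(id = founders$id, dam = NA, sire = NA),
               pedigree[, c("id", "dam", "sire")])
  n <- length(ids)
  K <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    di <- par$dam[i]; si <- par$sire[i]
    K[i, i] <- if (is.na(di)) 0.5 else 0.5 + 0.5 * K[di, si]
    if (i > 1) for (j in seq_len(i - 1)) {
      K[i, j] <- K[j, i] <- if (is.na(di)) 0 else
        0.5 * (K[j, di] + K[j, si])
    }
  }
  K
}
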