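# Kinship-corrected univariate mixed model: the computational core behind
# the association scan, the permutation thresholds, the epistasis tests and
# the power simulations.
#
# Model: y = X beta + u + e,  u ~ N(0, sigma_g^2 K),  e ~ N(0, sigma_e^2 I).
# With lambda = sigma_g^2 / sigma_e^2 and K = U D U', rotating by U'
# diagonalizes the covariance; lambda is found by 1-D bounded search of the
# (restricted) likelihood and per-SNP tests reduce to weighted least squares
# in the rotated space.

#' Centered genotype relatedness matrix
#'
#' K = (1/p) * sum_s (x_s - xbar_s)(x_s - xbar_s)' over all p SNPs, the
#' centered kinship used as the random-effect covariance in every
#' association and interaction model. Missing genotypes are mean-imputed
#' per SNP for this computation only.
#'
#' @param genotypes An `admixed_genotypes` object or a numeric matrix
#'   (individuals x SNPs).
#' @return Symmetric n x n matrix with individual ids as dimnames.
#' @export
centered_kinship <- function(genotypes) {
  mat <- if (inherits(genotypes, "admixed_genotypes")) genotypes$matrix
         else as.matrix(genotypes)
  if (nrow(mat) < 2) stop("need at least 2 individuals", call. = FALSE)
  if (any(colSums(!is.na(mat)) == 0L))
    stop("SNP(s) with all genotypes missing", call. = FALSE)
  W <- mean_impute(mat)
  W <- scale(W, center = TRUE, scale = FALSE)
  K <- tcrossprod(W) / ncol(W)
  dimnames(K) <- list(rownames(mat), rownames(mat))
  K
}

# per-SNP mean imputation
mean_impute <- function(mat) {
  storage.mode(mat) <- "double"
  if (anyNA(mat)) {
    mu <- colMeans(mat, na.rm = TRUE)
    idx <- which(is.na(mat), arr.ind = TRUE)
    mat[idx] <- mu[idx[, 2]]
  }
  mat
}

# restricted / full log-likelihood of the rotated model at a given lambda
# d: eigenvalues, yr: U'y, Xr: U'X
lmm_loglik <- function(log_lambda, d, yr, Xr, reml = TRUE) {
  lambda <- exp(log_lambda)
  w <- 1 / (lambda * d + 1)
  sw <- sqrt(w)
  Xw <- Xr * sw
  yw <- yr * sw
  XtX <- crossprod(Xw)
  ch <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  beta <- backsolve(ch, forwardsolve(t(ch), crossprod(Xw, yw)))
  rss <- sum((yw - Xw %*% beta)^2)
  n <- length(yr); q <- ncol(Xr)
  if (rss <= 0) return(-Inf)
  if (reml) {
    0.5 * ((n - q) * log((n - q) / (2 * pi)) - (n - q) -
             (n - q) * log(rss) + sum(log(w)) -
             2 * sum(log(diag(ch))))
  } else {
    0.5 * (n * log(n / (2 * pi)) - n - n * log(rss) + sum(log(w)))
  }
}

# GLS fit at fixed lambda in the rotated space; returns coefficients,
# covariance, residual variance estimate and log-likelihood pieces.
lmm_gls <- function(lambda, d, yr, Xr, reml = TRUE) {
  w <- 1 / (lambda * d + 1)
  sw <- sqrt(w)
  Xw <- Xr * sw
  yw <- yr * sw
  XtX <- crossprod(Xw)
  XtXi <- solve(XtX)
  beta <- drop(XtXi %*% crossprod(Xw, yw))
  resid <- yw - Xw %*% beta
  rss <- sum(resid^2)
  n <- length(yr); q <- ncol(Xr)
  sigma2 <- rss / (if (reml) n - q else n)
  list(beta = beta, cov = XtXi * sigma2, sigma2 = sigma2, rss = rss,
       w = w, fitted_rot = drop(Xw %*% beta) / sw)
}

#' Fit the null (no-SNP) linear mixed model
#'
#' Eigendecomposes the kinship matrix once, finds the variance ratio
#' `lambda` = sigma_g^2 / sigma_e^2 by bounded 1-D search of the REML (or
#' ML) criterion on the log scale, and caches the spectral rotation for
#' fast downstream per-SNP tests.
#'
#' @param y Numeric phenotype vector (one value per individual; no NAs —
#'   apply listwise deletion first).
#' @param kinship Symmetric positive semidefinite kinship matrix.
#' @param X Optional fixed-effect design matrix; an intercept column is
#'   always included.
#' @param reml Use REML (default) or ML.
#' @param lambda_bounds Search interval for lambda (default `c(1e-5, 1e5)`).
#' @param tol Convergence tolerance of the 1-D search (default 1e-6).
#' @return An object of class `hz_lmm` with components `lambda`, `tau`
#'   (residual variance), `loglik`, `coefficients`, `eig` (cached
#'   eigendecomposition), `boundary` flag, and the rotated data.
#' @export
hz_lmm <- function(y, kinship, X = NULL, reml = TRUE,
                   lambda_bounds = c(1e-5, 1e5), tol = 1e-6) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 3) stop("need at least 3 individuals", call. = FALSE)
  if (anyNA(y)) stop("y must be complete (listwise-delete first)",
                     call. = FALSE)
  kinship <- as.matrix(kinship)
  stopifnot(nrow(kinship) == n, ncol(kinship) == n)
  if (max(abs(kinship - t(kinship))) > 1e-8)
    stop("kinship matrix must be symmetric", call. = FALSE)
  eig <- eigen(kinship, symmetric = TRUE)
  if (min(eig$values) < -1e-6 * max(abs(eig$values), 1))
    stop("kinship matrix is not positive semidefinite", call. = FALSE)
  eig$values <- pmax(eig$values, 0)
  X0 <- cbind(`(Intercept)` = rep(1, n), X)
  yr <- drop(crossprod(eig$vectors, y))
  Xr <- crossprod(eig$vectors, X0)
  opt <- stats::optimize(lmm_loglik, interval = log(lambda_bounds),
                         d = eig$values, yr = yr, Xr = Xr, reml = reml,
                         maximum = TRUE, tol = tol)
  # the interior optimum can be worse than an endpoint; check both
  cand <- c(opt$maximum, log(lambda_bounds))
  ll <- c(opt$objective,
          vapply(log(lambda_bounds), lmm_loglik, 0, d = eig$values,
                 yr = yr, Xr = Xr, reml = reml))
  best <- which.max(ll)
  lambda <- exp(cand[best])
  boundary <- best > 1L ||
    min(abs(log(lambda) - log(lambda_bounds))) < 1e-3
  if (boundary && lambda > 1)
    warning("lambda estimate at search boundary", call. = FALSE)
  fit <- lmm_gls(lambda, eig$values, yr, Xr, reml = reml)
  structure(list(lambda = lambda, tau = fit$sigma2, loglik = ll[best],
                 coefficients = stats::setNames(fit$beta, colnames(X0)),
                 cov = fit$cov, reml = reml, boundary = boundary,
                 eig = eig, y = y, yr = yr, Xr = Xr, X0 = X0, n = n,
                 kinship = kinship),
            class = "hz_lmm")
}

#' @export
print.hz_lmm <- function(x, ...) {
  cat(sprintf("Kinship linear mixed model (%s)\n",
              if (x$reml) "REML" else "ML"))
  cat(sprintf("  n = %d, lambda = %.4g, residual variance = %.4g\n",
              x$n, x$lambda, x$tau))
  cat("  fixed effects:\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
summary.hz_lmm <- function(object, ...) {
  se <- sqrt(diag(object$cov))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z,
               `Pr(>|z|)` = stats::pchisq(z^2, 1, lower.tail = FALSE))
  out <- list(call_class = class(object), coefficients = tab,
              lambda = object$lambda, tau = object$tau,
              h2 = object$lambda / (1 + object$lambda),
              loglik = object$loglik, n = object$n, reml = object$reml,
              boundary = object$boundary)
  class(out) <- "summary.hz_lmm"
  out
}

#' @export
print.summary.hz_lmm <- function(x, ...) {
  cat(sprintf("Kinship linear mixed model (%s), n = %d\n",
              if (x$reml) "REML" else "ML", x$n))
  cat(sprintf("  lambda = %.4g  (variance-ratio h2 = %.3f)\n", x$lambda,
              x$h2))
  cat(sprintf("  residual variance = %.4g, log-likelihood = %.3f\n",
              x$tau, x$loglik))
  if (x$boundary) cat("  note: lambda at search boundary\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
coef.hz_lmm <- function(object, ...) object$coefficients

#' @export
logLik.hz_lmm <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) + 2L,
            nobs = object$n, class = "logLik")
}

#' @export
fitted.hz_lmm <- function(object, ...) {
  drop(object$X0 %*% object$coefficients)
}

#' @export
residuals.hz_lmm <- function(object, ...) {
  object$y - fitted(object)
}

#' Simulate phenotypes from a fitted kinship mixed model
#'
#' Draws `nsim` response vectors from N(X beta, tau * (lambda K + I)).
#'
#' @param object A fitted `hz_lmm`.
#' @param nsim Number of replicates.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Data frame with `nsim` columns.
#' @export
simulate.hz_lmm <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    n <- object$n
    sdev <- sqrt(object$tau * (object$lambda * object$eig$values + 1))
    mu <- fitted(object)
    out <- vapply(seq_len(nsim), function(i) {
      mu + drop(object$eig$vectors %*% (stats::rnorm(n) * sdev))
    }, numeric(n))
    as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
  })
}

# --- scan machinery -------------------------------------------------------

# Precompute everything reusable across scans of the same genotypes/kinship:
# eigendecomposition, rotated (mean-imputed) genotypes and their squares.
build_scan_cache <- function(genotypes, kinship) {
  mat <- genotypes$matrix
  eig <- eigen(as.matrix(kinship), symmetric = TRUE)
  eig$values <- pmax(eig$values, 0)
  G <- mean_impute(mat)
  n_used <- colSums(!is.na(mat))
  mono <- apply(G, 2, stats::sd) == 0
  Gr <- crossprod(eig$vectors, G)
  list(eig = eig, Gr = Gr, Gr2 = Gr * Gr,
       ones_r = drop(crossprod(eig$vectors, rep(1, nrow(mat)))),
       map = genotypes$map, n = nrow(mat), n_used = n_used, mono = mono)
}

# Vectorized single-SNP Wald scan for one phenotype using a cache.
# exact = TRUE refits lambda per SNP (the behaviour of exact mixed-model
# association software) by a vectorized profile-likelihood grid search;
# exact = FALSE reuses the null-model lambda for every SNP (the standard
# fast approximation, adequate under the null and used for permutations).
scan_with_cache <- function(cache, y, reml = TRUE, exact = FALSE,
                            lambda_bounds = c(1e-5, 1e5),
                            grid_points = 61L) {
  d <- cache$eig$values
  yr <- drop(crossprod(cache$eig$vectors, y))
  Xr <- matrix(cache$ones_r, ncol = 1)
  opt <- stats::optimize(lmm_loglik, interval = log(lambda_bounds), d = d,
                         yr = yr, Xr = Xr, reml = reml, maximum = TRUE,
                         tol = 1e-6)
  ll_ends <- vapply(log(lambda_bounds), lmm_loglik, 0, d = d, yr = yr,
                    Xr = Xr, reml = reml)
  lambda <- exp(c(opt$maximum, log(lambda_bounds))[
    which.max(c(opt$objective, ll_ends))])
  n <- cache$n
  # per-SNP sufficient statistics at one lambda; returns also the pieces
  # of the profiled (restricted) log-likelihood
  stat_one <- function(lam, j = NULL) {
    w <- 1 / (lam * d + 1)
    Gr <- if (is.null(j)) cache$Gr else cache$Gr[, j, drop = FALSE]
    Gr2 <- if (is.null(j)) cache$Gr2 else cache$Gr2[, j, drop = FALSE]
    s1 <- drop(crossprod(w * cache$ones_r, Gr))        # sum w * 1r * xr
    sxx <- drop(crossprod(w, Gr2))
    sy <- sum(w * cache$ones_r * yr)
    syy <- sum(w * yr * yr)
    sxy <- drop(crossprod(w * yr, Gr))
    s_w1 <- sum(w * cache$ones_r^2)                    # sum w * 1r^2
    det <- s_w1 * sxx - s1^2
    det[det <= 0] <- NA_real_  # constant (monomorphic) columns
    beta <- (s_w1 * sxy - s1 * sy) / det
    beta0 <- (sxx * sy - s1 * sxy) / det
    rss <- syy - beta0 * sy - beta * sxy
    rss[!is.na(rss) & rss <= 0] <- NA_real_  # numerically exact fits
    sigma2 <- rss / (n - 2)
    se2 <- sigma2 * s_w1 / det
    se2[!is.na(se2) & se2 <= 0] <- NA_real_
    ll <- if (reml) {
      0.5 * ((n - 2) * (log((n - 2) / (2 * pi)) - 1) -
               (n - 2) * log(rss) + sum(log(w)) - log(det))
    } else {
      0.5 * (n * (log(n / (2 * pi)) - 1) - n * log(rss) + sum(log(w)))
    }
    list(beta = beta, se = sqrt(se2), ll = ll)
  }
  if (!exact) {
    st <- stat_one(lambda)
    beta <- st$beta; se <- st$se
  } else {
    grid <- exp(seq(log(lambda_bounds[1]), log(lambda_bounds[2]),
                    length.out = grid_points))
    gp <- length(grid)
    p_snp <- ncol(cache$Gr)
    # profile REML over the whole grid in two matrix products:
    # rows of the G x p matrices index grid lambdas, columns SNPs
    Wmat <- 1 / (outer(d, grid) + 1)                 # n x G
    B <- crossprod(cbind(Wmat * cache$ones_r, Wmat * yr), cache$Gr)
    s1m <- B[seq_len(gp), , drop = FALSE]            # sum w 1r xr
    sxym <- B[gp + seq_len(gp), , drop = FALSE]      # sum w yr xr
    Sxx <- crossprod(Wmat, cache$Gr2)                # sum w xr^2
    sy_g <- colSums(Wmat * (cache$ones_r * yr))
    syy_g <- colSums(Wmat * yr * yr)
    s_w1_g <- colSums(Wmat * cache$ones_r^2)
    slw_g <- colSums(log(Wmat))
    det <- s_w1_g * Sxx - s1m^2                      # G-vectors recycle
    det[det <= 0] <- NA_real_
    bet <- (s_w1_g * sxym - s1m * sy_g) / det
    bet0 <- (Sxx * sy_g - s1m * sxym) / det
    rss <- syy_g - bet0 * sy_g - bet * sxym
    rss[!is.na(rss) & rss <= 0] <- NA_real_
    ll <- 0.5 * ((n - 2) * (log((n - 2) / (2 * pi)) - 1) -
                   (n - 2) * log(rss) + slw_g - log(det))
    ll[is.na(ll)] <- -Inf
    best_idx <- max.col(t(ll), ties.method = "first")
    beta <- se <- rep(NA_real_, p_snp)
    for (gi in unique(best_idx)) {
      j <- which(best_idx == gi)
      stj <- stat_one(grid[gi], j)
      beta[j] <- stj$beta
      se[j] <- stj$se
    }
  }
  p <- stats::pchisq((beta / se)^2, 1, lower.tail = FALSE)
  beta[cache$mono] <- NA_real_
  se[cache$mono] <- NA_real_
  p[cache$mono] <- NA_real_
  list(beta = beta, se = se, p = p, lambda = lambda)
}

#' Kinship-corrected single-SNP association scan with Wald tests
#'
#' For each SNP, fits the mixed model `y ~ intercept + snp + u(K)` and
#' records the allele-count effect, its standard error and the Wald
#' chi-square (1 df) p value. By default the variance ratio lambda is
#' re-estimated per SNP by a vectorized profile-likelihood grid search
#' (`exact = TRUE`, the behaviour of exact mixed-model association
#' software, which matters for power at SNPs correlated with genome-wide
#' ancestry); `exact = FALSE` estimates lambda once on the null model and
#' reuses it across SNPs (the fast approximation, indistinguishable under
#' the null and used inside permutation thresholds).
#' Missing genotypes are mean-imputed per SNP by default (with the
#' non-missing count recorded in `n_used`); `missing = "drop"` performs
#' exact per-SNP listwise deletion (slow).
#'
#' @param genotypes An `admixed_genotypes` object.
#' @param y Phenotype vector aligned with individuals; individuals with
#'   missing phenotype are dropped for the whole scan.
#' @param kinship Kinship matrix (defaults to [centered_kinship()] of
#'   `genotypes`).
#' @param covariates Optional numeric matrix of extra fixed effects.
#' @param missing `"impute"` (default) or `"drop"`.
#' @param exact Refit lambda per SNP (default TRUE).
#' @param reml Use REML variance components (default) or ML.
#' @return Data frame of class `hz_assoc`: `snp_id`, `chrom`, `pos`,
#'   `beta`, `se`, `p_wald`, `n_used`, `note`; attributes `lambda` (the
#'   null-model estimate), `reml`.
#' @export
wald_scan <- function(genotypes, y, kinship = NULL, covariates = NULL,
                      missing = c("impute", "drop"), exact = TRUE,
                      reml = TRUE) {
  missing <- match.arg(missing)
  y <- as.numeric(y)
  stopifnot(length(y) == n_ind(genotypes))
  keep <- which(!is.na(y))
  if (length(keep) < length(y)) {
    genotypes <- genotypes[keep, ]
    if (!is.null(kinship)) kinship <- kinship[keep, keep]
    if (!is.null(covariates))
      covariates <- as.matrix(covariates)[keep, , drop = FALSE]
    y <- y[keep]
  }
  if (is.null(kinship)) kinship <- centered_kinship(genotypes)
  if (!is.null(covariates) || missing == "drop") {
    res <- scan_slow(genotypes, y, kinship, covariates, missing, exact, reml)
  } else {
    cache <- build_scan_cache(genotypes, kinship)
    sc <- scan_with_cache(cache, y, reml = reml, exact = exact)
    res <- data.frame(snp_id = genotypes$map$snp_id,
                      chrom = genotypes$map$chrom,
                      pos = genotypes$map$pos,
                      beta = sc$beta, se = sc$se, p_wald = sc$p,
                      n_used = cache$n_used,
                      note = ifelse(cache$mono, "monomorphic", ""),
                      stringsAsFactors = FALSE)
    attr(res, "lambda") <- sc$lambda
  }
  attr(res, "reml") <- reml
  class(res) <- c("hz_assoc", "data.frame")
  res
}

# Slow per-SNP path: covariates and/or true listwise deletion.
scan_slow <- function(genotypes, y, kinship, covariates, missing, exact,
                      reml) {
  mat <- genotypes$matrix
  n <- nrow(mat)
  full_fit <- hz_lmm(y, kinship, X = covariates, reml = reml)
  out <- lapply(seq_len(ncol(mat)), function(j) {
    x <- mat[, j]
    ok <- if (missing == "drop") !is.na(x) else rep(TRUE, n)
    xj <- x[ok]
    xj[is.na(xj)] <- mean(xj, na.rm = TRUE)
    if (stats::sd(xj) == 0 || sum(ok) < 3)
      return(data.frame(beta = NA_real_, se = NA_real_, p_wald = NA_real_,
                        n_used = sum(!is.na(x)), note = "monomorphic"))
    if (all(ok)) {
      eig <- full_fit$eig
      yr <- full_fit$yr
      X0 <- full_fit$X0
    } else {
      eig <- eigen(kinship[ok, ok], symmetric = TRUE)
      eig$values <- pmax(eig$values, 0)
      yr <- drop(crossprod(eig$vectors, y[ok]))
      X0 <- cbind(rep(1, sum(ok)), if (!is.null(covariates))
        as.matrix(covariates)[ok, , drop = FALSE])
    }
    Xr <- crossprod(eig$vectors, cbind(X0, snp = xj))
    if (exact || !all(ok)) {
      oj <- stats::optimize(lmm_loglik, interval = log(c(1e-5, 1e5)),
                            d = eig$values, yr = yr, Xr = Xr, reml = reml,
                            maximum = TRUE, tol = 1e-6)
      lam <- exp(oj$maximum)
    } else lam <- full_fit$lambda
    fit <- lmm_gls(lam, eig$values, yr, Xr, reml = reml)
    k <- ncol(Xr)
    beta <- fit$beta[k]; se <- sqrt(fit$cov[k, k])
    data.frame(beta = beta, se = se,
               p_wald = stats::pchisq((beta / se)^2, 1, lower.tail = FALSE),
               n_used = sum(!is.na(x)), note = "")
  })
  res <- cbind(genotypes$map[, c("snp_id", "chrom", "pos")],
               do.call(rbind, out))
  attr(res, "lambda") <- full_fit$lambda
  res
}

#' @export
print.hz_assoc <- function(x, n = 6L, ...) {
  cat(sprintf("Association scan: %d SNPs (lambda = %.4g)\n", nrow(x),
              attr(x, "lambda") %||% NA))
  ord <- order(x$p_wald)
  cat("  top SNPs:\n")
  print.data.frame(utils::head(x[ord, c("snp_id", "chrom", "pos", "beta",
                                        "se", "p_wald")], n),
                   row.names = FALSE)
  invisible(x)
}

#' Normal quantile-rank transform
#'
#' Replaces values by normal scores `qnorm((rank - 0.5) / m)` with ties
#' averaged, the standard transform applied to expression phenotypes before
#' scanning. NAs are preserved.
#'
#' @param values Numeric vector (at least 3 distinct non-missing values).
#' @return Numeric vector of normal scores.
#' @export
quantile_rank_transform <- function(values) {
  ok <- !is.na(values)
  v <- values[ok]
  if (length(v) < 3) stop("need at least 3 non-missing values", call. = FALSE)
  if (length(unique(v)) == 1L) stop("all values are equal", call. = FALSE)
  r <- rank(v, ties.method = "average")
  out <- rep(NA_real_, length(values))
  out[ok] <- stats::qnorm((r - 0.5) / length(v))
  out
}
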