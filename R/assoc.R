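#' GCTA-style genetic relationship matrix
#'
#' Off-diagonal entries average `(x_ij - 2p_i)(x_ik - 2p_i) / (2 p_i (1 - p_i))`
#' over SNPs; diagonal entries use the homozygosity-based estimator
#' `1 + mean_i [x^2 - (1 + 2p) x + 2 p^2] / (2 p (1 - p))`. Allele
#' frequencies are computed from the cohort. Monomorphic SNPs are skipped;
#' missing dosages are mean-imputed per SNP (with a message).
#'
#' @param gm a `"genotypes"` object.
#' @return List of class `"grm"`: `A` (n x n symmetric matrix with sample-id
#'   dimnames), `ids`, `M` (number of SNPs used).
#' @export
compute_grm <- function(gm) {
  g <- gm$geno
  p <- colMeans(g, na.rm = TRUE) / 2
  poly <- which(!is.na(p) & p > 0 & p < 1)
  if (!length(poly)) stop("no polymorphic SNPs left for the GRM")
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  if (anyNA(g)) {
    message("mean-imputing missing dosages for the GRM")
    for (j in which(colSums(is.na(g)) > 0L)) {
      g[is.na(g[, j]), j] <- 2 * p[j]
    }
  }
  M <- length(p)
  denom <- 2 * p * (1 - p)
  Z <- sweep(sweep(g, 2L, 2 * p, "-"), 2L, sqrt(denom), "/")
  A <- tcrossprod(Z) / M
  dg <- 1 + rowMeans((g^2 - sweep(g, 2L, 1 + 2 * p, "*") +
                        rep(2 * p^2, each = nrow(g))) /
                       rep(denom, each = nrow(g)))
  diag(A) <- dg
  dimnames(A) <- list(rownames(gm$geno), rownames(gm$geno))
  structure(list(A = A, ids = rownames(gm$geno), M = M), class = "grm")
}

#' Mixed-linear-model association scan
#'
#' Estimates the polygenic and residual variance components once under the
#' null model (no SNP) by AI-REML, then tests every SNP by generalized least
#' squares with the covariance `V = Vg * A + Ve * I` held fixed: the
#' standard non-LOCO MLMA design (the candidate SNP stays in the GRM). The
#' Wald statistic `(b / SE)^2` is referred to chi-square(1). Works for both
#' the carrier-augmented quantitative code (2/1/0) and a 0/1 binary code,
#' both analyzed with the same linear mixed model.
#'
#' @param gm a `"genotypes"` object.
#' @param grm a [compute_grm()] result over the same samples.
#' @param phenotype numeric vector aligned with the samples (names used to
#'   align when present).
#' @param covariates optional numeric matrix of fixed covariates.
#' @param varcomp optional fixed variance components `c(Vg, Ve)` to use
#'   instead of REML estimation (with `Vg = 0` the scan is exactly ordinary
#'   least squares).
#' @return Data frame of class `"mlma_result"`: chr, snp, bp, a1, freq, b,
#'   se, p, q_genomewide, q_chr. SNPs with zero dosage variance get b = 0,
#'   se = NA, p = 1.
#' @export
mlma_scan <- function(gm, grm, phenotype, covariates = NULL, varcomp = NULL) {
  ids <- rownames(gm$geno)
  if (!identical(grm$ids, ids))
    stop("GRM and genotypes cover different samples")
  y <- if (!is.null(names(phenotype))) phenotype[ids] else phenotype
  if (length(y) != length(ids) || anyNA(y))
    stop("phenotype must cover every sample")
  X <- cbind(`(Intercept)` = rep(1, length(y)), covariates)
  if (is.null(varcomp)) {
    fit <- ai_reml(grm, y, covariates = covariates)
    varcomp <- c(fit$Vg, fit$Ve)
  } else {
    fit <- NULL
  }
  V <- varcomp[1] * grm$A + diag(varcomp[2], length(y))
  Vi <- chol2inv(chol(V))
  g <- gm$geno
  p_hat <- colMeans(g, na.rm = TRUE) / 2
  if (anyNA(g)) {
    for (j in which(colSums(is.na(g)) > 0L))
      g[is.na(g[, j]), j] <- 2 * p_hat[j]
  }
  one <- rep(1, length(y))
  Vi1 <- Vi %*% one
  Viy <- Vi %*% y
  a11 <- drop(crossprod(one, Vi1))
  a1y <- drop(crossprod(one, Viy))
  ViX <- Vi %*% g                       # n x m
  a1x <- drop(crossprod(one, ViX))      # 1'Vi x per SNP
  axx <- colSums(g * ViX)
  axy <- drop(crossprod(g, Viy))
  det_ <- a11 * axx - a1x^2
  b <- (a11 * axy - a1x * a1y) / det_
  varb <- a11 / det_
  se <- sqrt(varb)
  zerovar <- apply(g, 2L, stats::var) < .Machine$double.eps
  b[zerovar] <- 0; se[zerovar] <- NA_real_
  chisq <- (b / se)^2
  pval <- stats::pchisq(chisq, df = 1L, lower.tail = FALSE)
  pval[zerovar] <- 1
  pval[pval == 0] <- .Machine$double.xmin
  out <- data.frame(
    chr = gm$map$chr, snp = gm$map$id, bp = gm$map$bp, a1 = gm$map$a1,
    freq = allele_frequency(gm), b = b, se = se, p = pval,
    stringsAsFactors = FALSE, row.names = NULL)
  out$q_genomewide <- qvalues(out$p)
  out$q_chr <- qvalues(out$p, strata = out$chr)
  attr(out, "varcomp") <- fit
  class(out) <- c("mlma_result", "data.frame")
  out
}

# Storey pi0 estimate from a lambda grid with cubic spline smoothing,
# evaluated at the largest lambda
.pi0_storey <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  m <- length(p)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- stats::predict(fit, x = max(lambda))$y
  min(max(pi0, .Machine$double.eps), 1)
}

#' Storey q-values, genome-wide or per stratum
#'
#' Estimates the null proportion pi0 from a lambda grid (0.05 to 0.95) with
#' spline smoothing, then computes step-up q-values
#' `q_(i) = min_{j >= i} pi0 * m * p_(j) / j`. With `pi0 = 1` this is
#' exactly the Benjamini-Hochberg adjustment. Strata (e.g. chromosomes) are
#' processed independently; a stratum with fewer than 100 p-values uses
#' `pi0 = 1`.
#'
#' @param p p-values in `(0, 1]`.
#' @param strata optional factor (e.g. chromosome labels) splitting the
#'   p-values into independently adjusted strata.
#' @param pi0 optional fixed pi0 overriding estimation.
#' @return Numeric vector of q-values aligned with `p`.
#' @export
qvalues <- function(p, strata = NULL, pi0 = NULL) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  if (!is.null(strata)) {
    out <- numeric(length(p))
    for (s in unique(strata)) {
      i <- which(strata == s)
      out[i] <- qvalues(p[i], pi0 = pi0)
    }
    return(out)
  }
  m <- length(p)
  if (is.null(pi0)) pi0 <- if (m < 100L) 1 else .pi0_storey(p)
  ord <- order(p, decreasing = TRUE)
  q <- numeric(m)
  running <- pi0 * p[ord[1]]
  q[ord[1]] <- running
  ranks <- rank(p, ties.method = "max")
  for (k in seq_along(ord)[-1]) {
    i <- ord[k]
    running <- min(running, pi0 * m * p[i] / ranks[i])
    q[i] <- running
  }
  pmin(q, 1)
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Two-locus haplotype frequencies are estimated by EM from unphased
#' genotypes ([em_hap_freqs()] on the SNP pair); `r^2 = D^2 / (pA qA pB qB)`
#' and `D' = D / Dmax` are derived from them.
#'
#' @param gm a `"genotypes"` object.
#' @param snp_i,snp_j variant ids or indices.
#' @return List with `r2`, `dprime`, `d` (raw coefficient). Errors if either
#'   SNP is monomorphic.
#' @export
ld_r2 <- function(gm, snp_i, snp_j) {
  idx <- c(snp_i, snp_j)
  if (is.character(idx)) idx <- match(idx, gm$map$id)
  counts <- .pair_counts(gm, idx[1], idx[2])
  margin_a <- rowSums(counts); margin_b <- colSums(counts)
  pA_chk <- sum(margin_a * 0:2) / (2 * sum(margin_a))
  pB_chk <- sum(margin_b * 0:2) / (2 * sum(margin_b))
  if (pA_chk %in% c(0, 1) || pB_chk %in% c(0, 1))
    stop("monomorphic SNP: LD undefined")
  h <- .em2(counts)
  h11 <- h[4]
  pA <- h[3] + h[4]
  pB <- h[2] + h[4]
  D <- h11 - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  list(r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)),
       dprime = if (dmax > 0) abs(D) / dmax else NA_real_,
       d = D)
}

#' Backward stepwise selection over candidate SNPs
#'
#' Fits an ordinary linear model of the (1/2-coded, carriers removed)
#' phenotype on additive dosages of the candidate SNPs and prunes it with
#' `stats::step(direction = "backward")` under AIC: at each step the
#' predictor whose removal lowers AIC most is dropped, stopping when no
#' removal lowers AIC. Perfectly collinear (aliased) predictors are dropped
#' up front with a warning.
#'
#' @param gm a `"genotypes"` object.
#' @param phenotype numeric outcome aligned with samples (names honoured).
#' @param candidate_snps variant ids to start from (e.g. the top 100 by
#'   association p-value).
#' @param k AIC penalty per parameter (2 = classic AIC).
#' @return List of class `"stepwise_result"`: `retained` (variant ids),
#'   `rse`, `df_residual`, `adj_r2`, `model_p` (overall F-test), `fit`.
#' @export
backward_stepwise <- function(gm, phenotype, candidate_snps, k = 2) {
  vi <- match(candidate_snps, gm$map$id)
  if (anyNA(vi)) stop("unknown candidate variant ids")
  ids <- rownames(gm$geno)
  y <- if (!is.null(names(phenotype))) phenotype[ids] else phenotype
  keep <- !is.na(y)
  y <- y[keep]
  n <- length(y)
  if (n <= length(vi) + 1L)
    stop("need more observations than candidate SNPs plus intercept")
  Xg <- gm$geno[keep, vi, drop = FALSE]
  for (j in seq_len(ncol(Xg))) {
    if (anyNA(Xg[, j])) Xg[is.na(Xg[, j]), j] <- mean(Xg[, j], na.rm = TRUE)
  }
  dat <- as.data.frame(Xg)
  safe <- make.names(colnames(dat))
  name_map <- stats::setNames(colnames(dat), safe)
  colnames(dat) <- safe
  dat$.y <- y
  full <- stats::lm(.y ~ ., data = dat)
  aliased <- names(stats::coef(full))[is.na(stats::coef(full))]
  if (length(aliased)) {
    warning("dropping ", length(aliased), " aliased predictor(s)")
    dat <- dat[, !(colnames(dat) %in% aliased), drop = FALSE]
    full <- stats::lm(.y ~ ., data = dat)
  }
  red <- stats::step(full, direction = "backward", trace = 0, k = k)
  sm <- summary(red)
  fstat <- sm$fstatistic
  model_p <- if (is.null(fstat)) NA_real_ else
    stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  retained_safe <- setdiff(names(stats::coef(red)), "(Intercept)")
  structure(list(retained = unname(name_map[retained_safe]),
                 rse = sm$sigma,
                 df_residual = red$df.residual,
                 adj_r2 = sm$adj.r.squared,
                 model_p = unname(model_p),
                 fit = red),
            class = "stepwise_result")
}
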