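#' GRM from a genomic region
#'
#' Builds the genetic relationship matrix from the SNPs of one region only:
#' the whole map (`"all"`), one chromosome (`"18"` or `"chr18"`), or a
#' range (`"18:37000000-56000000"`). Used for partitioned heritability
#' (all autosomes, each chromosome separately, significant regions).
#'
#' @param gm a `"genotypes"` object.
#' @param region region string as above.
#' @return A `"grm"` with `M` = the number of region SNPs used.
#' @export
grm_subset <- function(gm, region = "all") {
  map <- gm$map
  region <- as.character(region)
  if (region == "all") {
    idx <- seq_len(nrow(map))
  } else if (grepl(":", region, fixed = TRUE)) {
    parts <- strsplit(region, "[:-]")[[1]]
    if (length(parts) != 3L)
      stop("range region must look like 'chr:start-end'")
    chr <- sub("^chr", "", parts[1])
    lo <- as.numeric(parts[2]); hi <- as.numeric(parts[3])
    idx <- which(sub("^chr", "", map$chr) == chr & map$bp >= lo & map$bp <= hi)
  } else {
    chr <- sub("^chr", "", region)
    idx <- which(sub("^chr", "", map$chr) == chr)
  }
  if (!length(idx)) stop("region contains no SNPs: ", region)
  compute_grm(subset_genotypes(gm, variants = idx))
}

# Restricted log-likelihood and projection quantities at (Vg, Ve), in the
# GRM eigenbasis: with A = U D U', V is diagonal there (v_i = Vg d_i + Ve)
# and every trace/quadratic form reduces to vector arithmetic. Returns NULL
# when (Vg, Ve) leaves V positive definite territory (the homozygosity-based
# GRM diagonal admits negative eigenvalues, so feasibility is not automatic).
.reml_eval_rot <- function(d, Xr, yr, Vg, Ve) {
  v <- Vg * d + Ve
  if (any(v < 1e-10)) return(NULL)
  Xv <- Xr / v
  XtViX <- crossprod(Xr, Xv)
  ch2 <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(ch2)) return(NULL)
  logdetX <- 2 * sum(log(diag(ch2)))
  XtViXi <- chol2inv(ch2)
  beta <- XtViXi %*% crossprod(Xr, yr / v)
  Py <- (yr - Xr %*% beta) / v
  # P z in the rotated basis
  Pfun <- function(z) z / v - Xv %*% (XtViXi %*% crossprod(Xr, z / v))
  diagP <- 1 / v - rowSums((Xv %*% XtViXi) * Xv)
  list(ll = -0.5 * (sum(log(v)) + logdetX + drop(crossprod(yr, Py))),
       Py = Py, Pfun = Pfun, diagP = diagP)
}

#' Average-information REML variance components
#'
#' Estimates the polygenic and residual variance components of
#' `y = Xb + g + e`, `g ~ N(0, A Vg)`, `e ~ N(0, I Ve)` by
#' average-information REML. Starting values split the phenotypic variance
#' equally; the first update is an EM-REML step, later updates use the AI
#' matrix with an EM fallback when the AI matrix is singular; components are
#' floored at `1e-6 * Vp` (negative GRM eigenvalues are absorbed by an
#' internal eigenvalue shift so the floor keeps V positive definite).
#' Convergence is declared
#' when the restricted log-likelihood moves by less than `tol`. The null
#' (residual-only) restricted likelihood, the likelihood-ratio statistic and
#' its boundary-mixture p-value, and a delta-method standard error for
#' `Vg / Vp` from the inverse AI matrix are included.
#'
#' @param grm a `"grm"` object (or a plain relationship matrix).
#' @param phenotype numeric vector (names honoured for alignment).
#' @param covariates optional fixed-effect matrix (intercept always added).
#' @param max_iter,tol iteration controls.
#' @param mixture use the half-chi-square boundary mixture for the LRT
#'   p-value (default TRUE).
#' @return List of class `"reml_fit"`: `Vg`, `Ve`, `Vp`, `h2_obs`, `se_h2`,
#'   `logL`, `logL0`, `lrt`, `p`, `n`, `M`, `iterations`, `converged`.
#' @export
ai_reml <- function(grm, phenotype, covariates = NULL, max_iter = 300L,
                    tol = 1e-4, mixture = TRUE) {
  A <- if (inherits(grm, "grm")) grm$A else as.matrix(grm)
  ids <- rownames(A)
  y <- if (!is.null(names(phenotype)) && !is.null(ids)) phenotype[ids]
       else phenotype
  if (length(y) != nrow(A) || anyNA(y))
    stop("phenotype must cover every sample in the GRM")
  n <- length(y)
  if (n < 30L) stop("need at least 30 samples for REML")
  if (max(abs(A - diag(n))) < 1e-8)
    stop("GRM is (numerically) the identity: variance components are unidentifiable")
  X <- cbind(rep(1, n), covariates)
  eg <- eigen(A, symmetric = TRUE)
  d <- eg$values
  # The homozygosity-based GRM diagonal admits (small) negative eigenvalues,
  # which would make positive definiteness of V = Vg A + Ve I a joint
  # constraint on (Vg, Ve). Shifting the eigenvalues up by |d_min| and
  # working with the residual component on the shifted scale turns that
  # constraint into the ordinary Ve > 0 box: the covariance, and hence the
  # restricted likelihood, are unchanged, and the reported Ve is recovered
  # as Ve_shifted + |d_min| Vg at the end.
  shift <- max(0, -min(d))
  dt <- d + shift
  yr <- drop(crossprod(eg$vectors, y))
  Xr <- crossprod(eg$vectors, X)
  Vp0 <- stats::var(y)
  if (!is.finite(Vp0) || Vp0 <= 0)
    stop("phenotype has no variance: nothing to partition")
  floor_v <- 1e-6 * Vp0
  Vg <- Vp0 / 2; Ve <- Vp0 / 2
  ev <- .reml_eval_rot(dt, Xr, yr, Vg, Ve)
  if (is.null(ev)) stop("restricted likelihood undefined at the starting values")
  ll <- ev$ll
  AI <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Py <- ev$Py
    APy <- dt * Py
    trPA <- sum(ev$diagP * dt)
    trP <- sum(ev$diagP)
    yPAPy <- drop(crossprod(Py, APy))
    yPPy <- drop(crossprod(Py, Py))
    grad <- -0.5 * c(trPA - yPAPy, trP - yPPy)
    PAPy <- ev$Pfun(APy)
    PPy <- ev$Pfun(Py)
    AI <- 0.5 * matrix(c(drop(crossprod(APy, PAPy)), drop(crossprod(APy, PPy)),
                         drop(crossprod(APy, PPy)), drop(crossprod(Py, PPy))),
                       2L, 2L)
    em_step <- c(Vg + Vg^2 * (yPAPy - trPA) / n,
                 Ve + Ve^2 * (yPPy - trP) / n)
    prop <- if (it == 1L) em_step else {
      delta <- tryCatch(solve(AI, grad), error = function(e) NULL)
      if (is.null(delta)) em_step else c(Vg, Ve) + delta
    }
    if (any(!is.finite(prop))) prop <- em_step
    # a component driven past zero is clamped at the floor (boundary
    # estimate) rather than retreating to a slow EM crawl
    prop <- pmax(pmin(prop, 1e6 * Vp0), floor_v)
    ev_new <- .reml_eval_rot(dt, Xr, yr, prop[1], prop[2])
    if (is.null(ev_new)) stop("AI-REML step left the parameter space")
    Vg <- prop[1]; Ve <- prop[2]
    dll <- ev_new$ll - ll
    ll <- ev_new$ll
    ev <- ev_new
    if (abs(dll) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf(
      "AI-REML did not converge in %d iterations (last Vg=%.4g Ve=%.4g logL=%.4f)",
      max_iter, Vg, Ve, ll))
  Ve <- Ve + shift * Vg                 # back to the unshifted scale
  Vp <- Vg + Ve
  h2 <- Vg / Vp
  S <- tryCatch(solve(AI), error = function(e) matrix(NA_real_, 2, 2))
  # delta method on the internal (Vg, Ve_shifted) parameterization
  gh <- c(Ve - shift * Vg, -Vg) / Vp^2
  se_h2 <- sqrt(max(0, drop(t(gh) %*% S %*% gh)))
  # null model: Vg = 0, residual REML variance in closed form
  qrX <- qr(X)
  rss <- sum(stats::resid(stats::lm.fit(X, y))^2)
  Ve0 <- rss / (n - qrX$rank)
  ll0 <- .reml_eval_rot(rep(0, n), Xr, yr, 0, Ve0)$ll
  # the constrained (floored) optimum can sit a hair below the boundary
  # maximum when Vg is truly zero; the LRT is zero there, not negative
  lrt <- max(0, 2 * (ll - ll0))
  structure(list(Vg = Vg, Ve = Ve, Vp = Vp, h2_obs = h2, se_h2 = se_h2,
                 logL = ll, logL0 = ll0, lrt = lrt,
                 p = lrt_pvalue(ll0 + lrt / 2, ll0, mixture = mixture),
                 n = n, M = if (inherits(grm, "grm")) grm$M else NA_integer_,
                 iterations = it, converged = converged),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf(
    "REML: V(G)=%.4g V(e)=%.4g  V(G)/Vp=%.4f (SE %.4f)  logL=%.3f logL0=%.3f LRT=%.3f p=%.3g (n=%d)\n",
    x$Vg, x$Ve, x$h2_obs, x$se_h2, x$logL, x$logL0, x$lrt, x$p, x$n))
  invisible(x)
}

#' Likelihood-ratio p-value for a variance component
#'
#' `LRT = 2 (logL - logL0)`. Because the null value Vg = 0 lies on the
#' boundary of the parameter space, the default reference distribution is
#' the equal mixture of a point mass at zero and chi-square(1):
#' `p = 0.5 * P(chi2_1 > LRT)` (so LRT = 0 gives p = 0.5). Set
#' `mixture = FALSE` for the plain chi-square(1) test.
#'
#' @param logL,logL0 full and null restricted log-likelihoods.
#' @param mixture use the boundary mixture (default TRUE).
#' @param tolerance allowed negative slack in the LRT before erroring.
#' @return p-value.
#' @export
lrt_pvalue <- function(logL, logL0, mixture = TRUE, tolerance = 1e-6) {
  lrt <- 2 * (logL - logL0)
  if (lrt < -tolerance)
    stop("negative likelihood-ratio statistic: null fits better than the full model")
  lrt <- max(0, lrt)
  p1 <- stats::pchisq(lrt, df = 1L, lower.tail = FALSE)
  if (mixture) 0.5 * p1 else p1
}

#' Observed-scale to liability-scale heritability
#'
#' Threshold-model conversion for ascertained case-control samples:
#' with population prevalence K, sample case proportion P, liability
#' threshold `t = qnorm(1 - K)` and normal density `z = dnorm(t)`, the
#' conversion factor is
#' `c = [K (1 - K) / z^2] * [K (1 - K) / (P (1 - P))]`,
#' and `h2_L = c * h2_obs`, `SE_L = c * SE_obs`. Under ascertainment
#' (P much larger than K) a large observed-scale estimate can shrink
#' markedly on the liability scale.
#'
#' @param h2_obs,se_obs observed-scale heritability and its SE (any scale:
#'   proportions and percentages both work, the factor is multiplicative).
#' @param K assumed population prevalence, strictly inside (0, 1).
#' @param n_cases,n_total sample composition giving `P = n_cases / n_total`.
#' @return List of class `"liability_estimate"`: `K`, `P`, `t`, `z`,
#'   `factor`, `h2_liability`, `se_liability`, plus the inputs.
#' @export
liability_transform <- function(h2_obs, se_obs = NA_real_, K, n_cases, n_total) {
  if (K <= 0 || K >= 1) stop("prevalence K must be strictly inside (0, 1)")
  if (n_cases <= 0 || n_cases >= n_total)
    stop("need 0 < n_cases < n_total")
  P <- n_cases / n_total
  t <- stats::qnorm(1 - K)
  z <- stats::dnorm(t)
  cf <- (K * (1 - K) / z^2) * (K * (1 - K) / (P * (1 - P)))
  structure(list(h2_obs = h2_obs, se_obs = se_obs, K = K, P = P, t = t,
                 z = z, factor = cf, h2_liability = cf * h2_obs,
                 se_liability = cf * se_obs),
            class = "liability_estimate")
}

#' @export
print.liability_estimate <- function(x, ...) {
  cat(sprintf(
    "liability transform: K=%.3g P=%.3g c=%.4f  h2 %.4g -> %.4g (SE %.4g -> %.4g)\n",
    x$K, x$P, x$factor, x$h2_obs, x$h2_liability, x$se_obs, x$se_liability))
  invisible(x)
}

#' hsq-style variance-component report
#'
#' Formats a REML fit as the familiar Source/Variance/SE table, appending
#' one liability-scale row per requested prevalence.
#'
#' @param fit a [ai_reml()] result.
#' @param prevalences numeric vector of assumed prevalences (may be empty).
#' @param n_cases,n_total case-control composition for the liability rows.
#' @return Data frame with columns `source`, `value`, `se`.
#' @export
reml_report <- function(fit, prevalences = numeric(0), n_cases = NA_integer_,
                        n_total = NA_integer_) {
  rows <- data.frame(
    source = c("V(G)", "V(e)", "Vp", "V(G)/Vp"),
    value = c(fit$Vg, fit$Ve, fit$Vp, fit$h2_obs),
    se = c(NA_real_, NA_real_, NA_real_, fit$se_h2),
    stringsAsFactors = FALSE)
  for (K in prevalences) {
    lt <- liability_transform(fit$h2_obs, fit$se_h2, K, n_cases, n_total)
    rows <- rbind(rows, data.frame(
      source = sprintf("V(G)/Vp_L (K=%g)", K),
      value = lt$h2_liability, se = lt$se_liability, stringsAsFactors = FALSE))
  }
  rbind(rows, data.frame(
    source = c("logL", "logL0", "LRT", "Pval", "n"),
    value = c(fit$logL, fit$logL0, fit$lrt, fit$p, fit$n),
    se = NA_real_, stringsAsFactors = FALSE))
}
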