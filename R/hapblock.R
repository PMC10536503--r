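# per-sample enumeration of ordered diplotypes compatible with an unphased
# multilocus genotype; dosage-1 sites phase both ways, missing sites take any
# allele pair. Haplotypes are returned as integer bit codes (site s = bit
# 2^(s-1)), which keeps the enumeration numeric.
.enumerate_diplotypes <- function(dose, max_states = 65536L) {
  opts <- lapply(dose, function(d) {
    if (is.na(d)) list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
    else if (d == 0L) list(c(0L, 0L))
    else if (d == 2L) list(c(1L, 1L))
    else list(c(0L, 1L), c(1L, 0L))
  })
  n_states <- prod(lengths(opts))
  if (n_states > max_states)
    stop("too many compatible phase configurations; split the block")
  grid <- expand.grid(lapply(opts, seq_along))
  L <- length(dose)
  pow <- 2^(seq_len(L) - 1)
  c1 <- numeric(nrow(grid)); c2 <- numeric(nrow(grid))
  for (s in seq_len(L)) {
    pick <- do.call(rbind, opts[[s]])[grid[[s]], , drop = FALSE]
    c1 <- c1 + pick[, 1] * pow[s]
    c2 <- c2 + pick[, 2] * pow[s]
  }
  cbind(c1, c2)
}

#' EM haplotype-frequency estimation within a block
#'
#' Maximum-likelihood haplotype frequencies for a short block of SNPs from
#' unphased genotypes, by expectation-maximization over the diplotypes
#' compatible with each sample's multilocus genotype. Initialization is the
#' linkage-equilibrium product of single-SNP allele frequencies; iteration
#' stops when no frequency moves by more than `tol` (default 1e-6) or after
#' `max_iter` iterations. Haplotypes ending below frequency 1e-4 are pruned.
#' The log-likelihood is non-decreasing across iterations and is returned as
#' a trace.
#'
#' @param gm a `"genotypes"` object.
#' @param block_snps variant ids (or indices) of the block, at most 20 SNPs.
#' @param tol,max_iter convergence controls.
#' @return List of class `"haplotype_table"`: `haplotypes` (binary strings,
#'   1 = the variant's a1 allele), `alleles` (letter strings), `freq`,
#'   `snps`, `samples`, `posterior` (per sample, data frame h1/h2/post over
#'   ordered diplotypes), `best` (n x 2 matrix of haplotype indices, sorted),
#'   `best_post`, `best_tied` (TRUE when the top unordered diplotypes tie),
#'   `loglik` (trace).
#' @export
em_hap_freqs <- function(gm, block_snps, tol = 1e-6, max_iter = 1000L) {
  vi <- block_snps
  if (is.character(vi)) vi <- match(vi, gm$map$id)
  if (anyNA(vi)) stop("unknown block variant ids")
  if (length(vi) > 20L)
    stop("block larger than 20 SNPs: enumeration infeasible, split the block")
  g <- gm$geno[, vi, drop = FALSE]
  n <- nrow(g)
  L <- length(vi)
  codes <- lapply(seq_len(n), function(k) .enumerate_diplotypes(g[k, ]))
  registry <- sort(unique(unlist(codes, use.names = FALSE)))
  pairs <- lapply(codes, function(cp)
    cbind(match(cp[, 1], registry), match(cp[, 2], registry)))
  hap_strings <- vapply(registry, function(code)
    paste(as.integer((code %/% 2^(seq_len(L) - 1)) %% 2), collapse = ""), "")
  H <- length(hap_strings)
  # linkage-equilibrium initialization from single-SNP frequencies
  p_site <- colMeans(g, na.rm = TRUE) / 2
  p_site[is.na(p_site)] <- 0.5
  p_site <- pmin(pmax(p_site, 1e-6), 1 - 1e-6)
  bits <- do.call(rbind, lapply(strsplit(hap_strings, ""), as.integer))
  f <- exp(bits %*% log(p_site) + (1 - bits) %*% log(1 - p_site))[, 1]
  f <- f / sum(f)
  # flatten the per-sample enumerations so each EM step is vectorized
  S <- rep.int(seq_len(n), vapply(pairs, nrow, integer(1)))
  H1 <- unlist(lapply(pairs, function(pr) pr[, 1]), use.names = FALSE)
  H2 <- unlist(lapply(pairs, function(pr) pr[, 2]), use.names = FALSE)
  ll_trace <- numeric(0)
  wn <- NULL
  for (it in seq_len(max_iter)) {
    w <- f[H1] * f[H2]
    sw <- drop(rowsum(w, S))           # per-sample likelihoods (S is 1..n)
    ll_trace <- c(ll_trace, sum(log(sw + 1e-300)))
    wn <- w / pmax(sw[S], 1e-300)
    rs <- rowsum(c(wn, wn), c(H1, H2))
    counts <- numeric(H)
    counts[as.integer(rownames(rs))] <- drop(rs)
    f_new <- counts / (2 * n)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) break
  }
  post <- split(wn, S)
  keep <- f >= 1e-4
  ids <- rownames(gm$geno)
  best <- matrix(NA_integer_, n, 2L)
  best_post <- numeric(n)
  best_tied <- logical(n)
  posterior <- vector("list", n)
  for (k in seq_len(n)) {
    pr <- pairs[[k]]
    # collapse ordered diplotypes to unordered
    key_a <- pmin(pr[, 1], pr[, 2]); key_b <- pmax(pr[, 1], pr[, 2])
    key <- paste(key_a, key_b)
    agg <- rowsum(post[[k]], key)
    kk <- strsplit(rownames(agg), " ")
    tab <- data.frame(h1 = as.integer(vapply(kk, `[`, "", 1L)),
                      h2 = as.integer(vapply(kk, `[`, "", 2L)),
                      post = agg[, 1], row.names = NULL)
    tab <- tab[order(-tab$post), , drop = FALSE]
    posterior[[k]] <- tab
    best[k, ] <- c(tab$h1[1], tab$h2[1])
    best_post[k] <- tab$post[1]
    best_tied[k] <- nrow(tab) > 1L && (tab$post[1] - tab$post[2]) <= 1e-9
  }
  names(posterior) <- ids
  letters_of <- function(s) {
    b <- as.integer(strsplit(s, "")[[1]])
    paste(ifelse(b == 1L, gm$map$a1[vi], gm$map$a2[vi]), collapse = "")
  }
  structure(list(
    haplotypes = hap_strings, alleles = vapply(hap_strings, letters_of, "",
                                               USE.NAMES = FALSE),
    freq = f, kept = keep, snps = gm$map$id[vi], samples = ids,
    posterior = posterior, best = best, best_post = best_post,
    best_tied = best_tied, loglik = ll_trace), class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  keep <- x$kept
  cat(sprintf("haplotype table: %d SNPs, %d haplotype(s) above 1e-4\n",
              length(x$snps), sum(keep)))
  df <- data.frame(haplotype = x$alleles[keep],
                   freq = round(x$freq[keep], 4))
  print(df[order(-df$freq), ], row.names = FALSE)
  invisible(x)
}

# 3x3 genotype-pair count table (dosage 0/1/2 at each SNP, complete pairs)
.pair_counts <- function(gm, i, j) {
  g1 <- gm$geno[, i]; g2 <- gm$geno[, j]
  ok <- !is.na(g1) & !is.na(g2)
  matrix(tabulate(1L + 3L * g1[ok] + g2[ok], 9L), 3, 3, byrow = TRUE)
}

# fast two-locus EM on the count table: only the double-heterozygote cell is
# phase-ambiguous, so the M-step is a closed-form allele-count update
.em2 <- function(counts, tol = 1e-10, max_iter = 1000L) {
  n2 <- 2 * sum(counts)
  if (n2 == 0) stop("no complete genotype pairs")
  pc <- 0.5
  h <- rep(0.25, 4)  # h00 h01 h10 h11
  for (it in seq_len(max_iter)) {
    c00 <- 2 * counts[1, 1] + counts[1, 2] + counts[2, 1] + pc * counts[2, 2]
    c01 <- 2 * counts[1, 3] + counts[1, 2] + counts[2, 3] + (1 - pc) * counts[2, 2]
    c10 <- 2 * counts[3, 1] + counts[2, 1] + counts[3, 2] + (1 - pc) * counts[2, 2]
    c11 <- 2 * counts[3, 3] + counts[3, 2] + counts[2, 3] + pc * counts[2, 2]
    h_new <- c(c00, c01, c10, c11) / n2
    cis <- h_new[1] * h_new[4]; trans <- h_new[2] * h_new[3]
    pc <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    if (max(abs(h_new - h)) < tol) { h <- h_new; break }
    h <- h_new
  }
  h
}

# log-likelihood of the count table over a whole grid of |D'| values at once
.ll_grid <- function(counts, pA, pB, sgn, grid) {
  dmax <- if (sgn >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  D <- sgn * grid * dmax
  h11 <- pmax(pA * pB + D, 0)
  h10 <- pmax(pA * (1 - pB) - D, 0)
  h01 <- pmax((1 - pA) * pB - D, 0)
  h00 <- pmax((1 - pA) * (1 - pB) + D, 0)
  lg <- function(x) log(x + 1e-300)
  # rows of `counts`: dosage at SNP A; cols: dosage at SNP B
  counts[1, 1] * lg(h00^2) + counts[1, 2] * lg(2 * h00 * h01) +
    counts[1, 3] * lg(h01^2) + counts[2, 1] * lg(2 * h00 * h10) +
    counts[2, 2] * lg(2 * (h00 * h11 + h01 * h10)) +
    counts[2, 3] * lg(2 * h01 * h11) + counts[3, 1] * lg(h10^2) +
    counts[3, 2] * lg(2 * h10 * h11) + counts[3, 3] * lg(h11^2)
}

#' Likelihood-based confidence interval for |D'|
#'
#' Profiles the likelihood of a SNP pair's unphased genotype data over a
#' grid of |D'| values in `[0, 1]`, with the two-locus haplotype margins
#' fixed at the sample allele frequencies and the sign of D taken from the
#' EM point estimate. The central 90% (by default) of the normalized grid
#' likelihood gives the interval endpoints used by Gabriel-style block
#' finding.
#'
#' @param gm a `"genotypes"` object.
#' @param snp_i,snp_j variant ids or indices.
#' @param conf interval mass (default 0.90).
#' @param grid_n number of grid points (default 101).
#' @return List: `dprime` (EM point estimate), `ci_low`, `ci_high`,
#'   `informative` (FALSE when fewer than 10 informative chromosomes),
#'   `n_chrom`.
#' @export
dprime_ci <- function(gm, snp_i, snp_j, conf = 0.90, grid_n = 101L) {
  idx <- c(snp_i, snp_j)
  if (is.character(idx)) idx <- match(idx, gm$map$id)
  counts <- .pair_counts(gm, idx[1], idx[2])
  n_chrom <- 2L * sum(counts)
  h <- .em2(counts)
  pA <- h[3] + h[4]; pB <- h[2] + h[4]
  D <- h[4] - pA * pB
  dmax_pt <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
             else min(pA * pB, (1 - pA) * (1 - pB))
  point_dprime <- if (dmax_pt > 0) abs(D) / dmax_pt else NA_real_
  sgn <- if (D >= 0) 1 else -1
  grid <- seq(0, 1, length.out = grid_n)
  ll <- .ll_grid(counts, pA, pB, sgn, grid)
  w <- exp(ll - max(ll))
  cum <- cumsum(w) / sum(w)
  alpha <- (1 - conf) / 2
  ci_low <- grid[which(cum >= alpha)[1]]
  ci_high <- grid[which(cum >= 1 - alpha)[1]]
  list(dprime = point_dprime, ci_low = ci_low, ci_high = ci_high,
       informative = n_chrom >= 10L, n_chrom = n_chrom)
}

#' Gabriel-style haplotype-block detection
#'
#' Classifies SNP pairs on a chromosome by their |D'| confidence intervals:
#' "strong LD" when `ci_low >= ci_strong_low` and `ci_high >= ci_strong_high`,
#' "recombination" when `ci_high < ci_recomb_high` (other pairs are
#' uninformative). A candidate span is a block when at least
#' `informative_frac` of its informative pairs are in strong LD; candidates
#' are accepted greedily, longest physical span first, without overlap.
#'
#' @param gm a `"genotypes"` object.
#' @param chromosome chromosome label.
#' @param ci_strong_low,ci_strong_high,ci_recomb_high CI thresholds
#'   (Haploview defaults).
#' @param informative_frac minimum strong-LD fraction (default 0.95).
#' @param max_span_kb maximum block span in kb (default 200).
#' @param maf_floor SNPs below this MAF are ignored (default 0.05).
#' @return Data frame of class `"hap_blocks"`: chr, start_bp, end_bp,
#'   n_snps, snps (comma-separated variant ids). Possibly empty.
#' @export
find_blocks <- function(gm, chromosome, ci_strong_low = 0.70,
                        ci_strong_high = 0.98, ci_recomb_high = 0.90,
                        informative_frac = 0.95, max_span_kb = 200,
                        maf_floor = 0.05) {
  empty <- structure(data.frame(chr = character(0), start_bp = integer(0),
                                end_bp = integer(0), n_snps = integer(0),
                                snps = character(0), stringsAsFactors = FALSE),
                     class = c("hap_blocks", "data.frame"))
  on_chr <- which(gm$map$chr == as.character(chromosome))
  if (!length(on_chr)) stop("chromosome not present: ", chromosome)
  f <- allele_frequency(gm)[on_chr]
  on_chr <- on_chr[!is.na(f) & f >= maf_floor & f <= 1 - maf_floor]
  w <- length(on_chr)
  if (w < 2L) return(empty)
  bp <- gm$map$bp[on_chr]
  span_bp <- max_span_kb * 1000
  strong <- matrix(NA, w, w)  # NA = uninformative or out of span
  for (i in seq_len(w - 1L)) {
    for (j in (i + 1L):w) {
      if (bp[j] - bp[i] > span_bp) break
      ci <- dprime_ci(gm, on_chr[i], on_chr[j])
      if (!ci$informative) next
      if (ci$ci_low >= ci_strong_low && ci$ci_high >= ci_strong_high)
        strong[i, j] <- TRUE
      else if (ci$ci_high < ci_recomb_high)
        strong[i, j] <- FALSE
    }
  }
  cand <- list()
  for (i in seq_len(w - 1L)) {
    for (j in (i + 1L):w) {
      if (bp[j] - bp[i] > span_bp) break
      sub <- strong[i:j, i:j]
      vals <- sub[upper.tri(sub)]
      n_inf <- sum(!is.na(vals))
      if (n_inf == 0L) next
      if (sum(vals, na.rm = TRUE) / n_inf >= informative_frac)
        cand[[length(cand) + 1L]] <- c(i, j)
    }
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  spans <- bp[cand[, 2]] - bp[cand[, 1]]
  ord <- order(-spans, bp[cand[, 1]])
  taken <- rep(FALSE, w)
  rows <- list()
  for (r in ord) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (any(taken[i:j])) next
    taken[i:j] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      chr = as.character(chromosome), start_bp = bp[i], end_bp = bp[j],
      n_snps = j - i + 1L,
      snps = paste(gm$map$id[on_chr[i:j]], collapse = ","),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hap_blocks", "data.frame")
  out
}

#' Expected per-sample haplotype dosages
#'
#' For each haplotype in the table, each sample's expected copy number under
#' the posterior over compatible diplotypes.
#'
#' @param table a [em_hap_freqs()] result.
#' @return Matrix samples x haplotypes.
#' @export
hap_dosage <- function(table) {
  H <- length(table$haplotypes)
  n <- length(table$samples)
  out <- matrix(0, n, H, dimnames = list(table$samples, table$haplotypes))
  for (k in seq_len(n)) {
    tab <- table$posterior[[k]]
    for (r in seq_len(nrow(tab))) {
      out[k, tab$h1[r]] <- out[k, tab$h1[r]] + tab$post[r]
      out[k, tab$h2[r]] <- out[k, tab$h2[r]] + tab$post[r]
    }
  }
  out
}

#' Per-haplotype association within a block
#'
#' Regresses the phenotype on each haplotype's expected dosage (haplotype
#' versus all others): a linear model for the 2/1/0 quantitative code, or a
#' logistic model (reporting an odds ratio per dosage unit) for the binary
#' case/control code. Haplotypes below the rarity floor are not tested.
#' Logistic fits with complete separation are flagged and their p-value
#' omitted.
#'
#' @param gm a `"genotypes"` object (used for sample alignment only).
#' @param table a [em_hap_freqs()] result.
#' @param phenotype numeric vector (names honoured); samples with NA
#'   phenotype are dropped.
#' @param model `"linear"` or `"logistic"`.
#' @param rare_floor minimum haplotype frequency to test (default 0.01).
#' @return Data frame of class `"hap_assoc"`: haplotype (letters), freq,
#'   effect (linear beta or log-OR), odds_ratio (logistic only), se, p,
#'   separated.
#' @export
hap_association <- function(gm, table, phenotype, model = c("linear", "logistic"),
                            rare_floor = 0.01) {
  model <- match.arg(model)
  dos <- hap_dosage(table)
  ids <- table$samples
  y <- if (!is.null(names(phenotype))) phenotype[ids] else phenotype
  keep <- !is.na(y)
  y <- y[keep]; dos <- dos[keep, , drop = FALSE]
  test_idx <- which(table$freq >= rare_floor)
  rows <- list()
  for (h in test_idx) {
    d <- dos[, h]
    sep <- FALSE
    if (model == "linear") {
      fit <- stats::lm(y ~ d)
      cf <- summary(fit)$coefficients
      if (nrow(cf) < 2L) next
      eff <- cf["d", "Estimate"]; se <- cf["d", "Std. Error"]
      pv <- cf["d", "Pr(>|t|)"]
      or <- NA_real_
    } else {
      fit <- suppressWarnings(stats::glm(y ~ d, family = stats::binomial()))
      cf <- summary(fit)$coefficients
      if (!"d" %in% rownames(cf)) next
      eff <- cf["d", "Estimate"]; se <- cf["d", "Std. Error"]
      pv <- cf["d", "Pr(>|z|)"]
      sep <- !fit$converged || abs(eff) > 15 || se > 100
      if (sep) pv <- NA_real_
      or <- exp(eff)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      haplotype = table$alleles[h], freq = table$freq[h], effect = eff,
      odds_ratio = or, se = se, p = pv, separated = sep,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(haplotype = character(0), freq = numeric(0),
               effect = numeric(0), odds_ratio = numeric(0), se = numeric(0),
               p = numeric(0), separated = logical(0))
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hap_assoc", "data.frame")
  out
}

#' Per-group haplotype homozygosity table
#'
#' A sample counts as homozygous for a haplotype exactly when its
#' maximum-posterior diplotype is that haplotype paired with itself, with a
#' strict argmax: a posterior tie is counted as not homozygous. Frequencies
#' are reported per status group with counts, formatted as "0.29 (9)".
#'
#' @param table a [em_hap_freqs()] result.
#' @param statuses a [classify_cohort()] result (columns `id`, `status`).
#' @param groups status groups to tabulate.
#' @param rare_floor minimum haplotype frequency to report.
#' @return Long-format data frame: haplotype, group, n_group, f_hom, n_hom,
#'   formatted.
#' @export
hap_homozygosity_by_group <- function(table, statuses,
                                      groups = c("case", "carrier", "control"),
                                      rare_floor = 0.01) {
  ids <- table$samples
  hom_hap <- rep(NA_integer_, length(ids))
  is_hom <- !table$best_tied & table$best[, 1] == table$best[, 2]
  hom_hap[is_hom] <- table$best[is_hom, 1]
  rows <- list()
  for (h in which(table$freq >= rare_floor)) {
    for (grp in groups) {
      members <- statuses$id[statuses$status == grp]
      in_grp <- ids %in% members
      ng <- sum(in_grp)
      n_hom <- sum(in_grp & !is.na(hom_hap) & hom_hap == h)
      f_hom <- if (ng) n_hom / ng else 0
      rows[[length(rows) + 1L]] <- data.frame(
        haplotype = table$alleles[h], group = grp, n_group = ng,
        f_hom = round(f_hom, 2L), n_hom = n_hom,
        formatted = sprintf("%.2f (%d)", f_hom, n_hom),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
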