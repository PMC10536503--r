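test_that("D-prime confidence intervals behave at the LD extremes", {
  set.seed(41)
  # duplicated SNP in 60 samples: point estimate 1, confident lower bound
  x <- rbinom(60, 2, 0.4)
  gm <- make_gm(cbind(a = x, b = x))
  ci <- dprime_ci(gm, 1, 2)
  expect_equal(ci$dprime, 1, tolerance = 1e-6)
  expect_gte(ci$ci_low, 0.7)
  expect_true(ci$informative)
  # independent SNPs at n = 200: interval reaches down to low values
  g2 <- cbind(u = rbinom(200, 2, 0.4), v = rbinom(200, 2, 0.4))
  ci2 <- dprime_ci(make_gm(g2), 1, 2)
  expect_lt(ci2$ci_low, 0.5)
  expect_lt(ci2$ci_high, 0.98)
  # tiny sample flagged uninformative
  g3 <- cbind(p = c(0L, 1L, 2L), q = c(0L, 1L, 2L))
  expect_false(dprime_ci(make_gm(g3), 1, 2)$informative)
})

test_that("D-prime interval is invariant to allele relabelling", {
  set.seed(42)
  x <- rbinom(150, 2, 0.35)
  y <- ifelse(runif(150) < 0.8, x, rbinom(150, 2, 0.35))
  gm <- make_gm(cbind(a = x, b = y))
  gm_flip <- make_gm(cbind(a = x, b = 2L - y))   # swap labels at SNP b
  ci <- dprime_ci(gm, 1, 2)
  ci_flip <- dprime_ci(gm_flip, 1, 2)
  expect_equal(ci$dprime, ci_flip$dprime, tolerance = 1e-9)
  expect_equal(ci$ci_low, ci_flip$ci_low, tolerance = 1e-9)
  expect_equal(ci$ci_high, ci_flip$ci_high, tolerance = 1e-9)
})

test_that("block finding skips equilibrium chromosomes and enforces the span rule", {
  set.seed(43)
  g <- matrix(rbinom(200 * 12, 2, 0.4), 200, 12)
  gm <- make_gm(g, bp = seq_len(12) * 10000L)
  expect_equal(nrow(find_blocks(gm, "1")), 0L)
  # two perfect-LD SNPs 300 kb apart must not form a block at max span 200
  x <- rbinom(200, 2, 0.4)
  gm2 <- make_gm(cbind(x, x), bp = c(1000L, 301000L))
  expect_equal(nrow(find_blocks(gm2, "1", max_span_kb = 200)), 0L)
  expect_equal(nrow(find_blocks(gm2, "1", max_span_kb = 400)), 1L)
  expect_error(find_blocks(gm, "7"), "chromosome not present")
})

test_that("EM haplotype frequencies equal direct counts when phase is known", {
  # doubly homozygous samples only
  g <- rbind(s1 = c(0L, 0L, 0L), s2 = c(2L, 2L, 2L), s3 = c(0L, 0L, 0L),
             s4 = c(2L, 2L, 2L), s5 = c(0L, 0L, 0L))
  tab <- em_hap_freqs(make_gm(g), 1:3)
  expect_setequal(tab$haplotypes[tab$kept], c("000", "111"))
  expect_equal(sort(tab$freq[tab$kept]), c(0.4, 0.6))
  expect_equal(sum(tab$freq), 1, tolerance = 1e-8)
  # every sample doubly heterozygous: symmetric stationary point at 0.25
  g2 <- matrix(1L, 6, 2)
  rownames(g2) <- sprintf("t%d", 1:6)
  tab2 <- em_hap_freqs(make_gm(g2), 1:2)
  expect_equal(unname(tab2$freq), rep(0.25, 4), tolerance = 1e-6)
  expect_error(em_hap_freqs(make_gm(matrix(1L, 2, 21,
    dimnames = list(c("a", "b"), NULL))), 1:21), "20 SNPs")
})

test_that("EM attains the brute-force likelihood maximum on 3-SNP blocks", {
  # oracle: direct maximization over the 8-haplotype simplex
  block_loglik <- function(f, pairs_list) {
    sum(vapply(pairs_list, function(pr)
      log(sum(f[pr[, 1]] * f[pr[, 2]]) + 1e-300), numeric(1)))
  }
  for (s in 1:3) {
    set.seed(400 + s)
    hap_pool <- rbind(c(0, 0, 0), c(1, 1, 0), c(0, 1, 1), c(1, 0, 1))
    draw <- sample(1:4, 200, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
    hmat <- hap_pool[draw, ]
    g <- hmat[seq(1, 199, 2), ] + hmat[seq(2, 200, 2), ]
    storage.mode(g) <- "integer"
    rownames(g) <- sprintf("s%03d", 1:100)
    gm <- make_gm(g)
    tab <- em_hap_freqs(gm, 1:3)
    expect_true(all(diff(tab$loglik) >= -1e-8))   # EM monotonicity
    # independent oracle: optimize the same likelihood from random starts
    codes <- lapply(seq_len(nrow(g)), function(k)
      carriergwas:::.enumerate_diplotypes(g[k, ]))
    registry <- sort(unique(unlist(codes)))
    pairs_list <- lapply(codes, function(cp)
      cbind(match(cp[, 1], registry), match(cp[, 2], registry)))
    H <- length(registry)
    best <- -Inf
    for (r in 1:40) {
      w <- rexp(H)
      opt <- optim(log(w), function(lw) {
        f <- exp(lw) / sum(exp(lw))
        -block_loglik(f, pairs_list)
      }, method = "BFGS", control = list(maxit = 200))
      best <- max(best, -opt$value)
    }
    expect_gte(utils::tail(tab$loglik, 1), best - 1e-3)
  }
})

test_that("haplotype tables are invariant to sample order", {
  set.seed(44)
  g <- matrix(rbinom(40 * 4, 2, 0.4), 40, 4)
  rownames(g) <- sprintf("s%02d", 1:40)
  gm <- make_gm(g)
  t1 <- em_hap_freqs(gm, 1:4)
  perm <- sample(40)
  t2 <- em_hap_freqs(genotypes(g[perm, ], gm$map), 1:4)
  m <- match(t1$haplotypes, t2$haplotypes)
  expect_equal(t1$freq, t2$freq[m], tolerance = 1e-8)
})

test_that("haplotype regression matches hard-count regression when phase is unambiguous", {
  set.seed(45)
  # doubly homozygous block -> expected dosages are exact counts
  hap <- rbinom(120, 1, 0.35)
  g <- cbind(2L * hap, 2L * hap, 2L * hap)
  rownames(g) <- sprintf("s%03d", 1:120)
  gm <- make_gm(g)
  tab <- em_hap_freqs(gm, 1:3)
  y <- 0.8 * (2 * hap) + rnorm(120, sd = 0.4)
  names(y) <- rownames(g)
  res <- hap_association(gm, tab, y, model = "linear")
  h1 <- which(res$haplotype == paste(rep("A", 3), collapse = ""))
  hard <- summary(lm(y ~ I(2 * hap)))$coefficients[2, ]
  row <- res[res$haplotype == "AAA", ]
  expect_equal(row$effect, unname(hard["Estimate"]), tolerance = 1e-8)
  expect_equal(row$p, unname(hard["Pr(>|t|)"]), tolerance = 1e-8)
  # perfect signal: the causal haplotype has the smallest p in its block
  expect_equal(res$haplotype[which.min(res$p)], "AAA")
})

test_that("logistic haplotype regression reports odds ratios and flags separation", {
  set.seed(46)
  hap <- rbinom(150, 1, 0.4)
  g <- cbind(2L * hap, 2L * hap)
  rownames(g) <- sprintf("s%03d", 1:150)
  gm <- make_gm(g)
  tab <- em_hap_freqs(gm, 1:2)
  y_sep <- as.numeric(hap == 1)            # perfect separation
  names(y_sep) <- rownames(g)
  res_sep <- hap_association(gm, tab, y_sep, model = "logistic")
  expect_true(any(res_sep$separated))
  expect_true(all(is.na(res_sep$p[res_sep$separated])))
  y_soft <- rbinom(150, 1, plogis(-1 + 1.2 * hap))
  names(y_soft) <- rownames(g)
  res <- hap_association(gm, tab, y_soft, model = "logistic")
  expect_true(all(res$odds_ratio > 0))
})

test_that("haplotype regression p-values are uniform under permutation", {
  set.seed(47)
  cfg <- sim_config(n_generations = 1, n_founders = 100, n_chromosomes = 1,
                    snps_per_chromosome = 4, block_length_mean = 4,
                    haplotypes_per_block = c(3L, 3L), maf_floor = 0.1,
                    risk_locus = list(chr = 1, index = 1, freq = 0.4), seed = 47)
  co <- simulate_cohort(cfg)
  gm <- co$genotypes
  tab <- em_hap_freqs(gm, seq_len(4))
  pvals <- unlist(lapply(1:60, function(i) {
    y <- sample(c(rep(2, 30), rep(0, 70)))
    names(y) <- rownames(gm$geno)
    hap_association(gm, tab, y, model = "linear")$p
  }))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("homozygosity tables use a strict best-diplotype argmax", {
  g <- rbind(hom = c(2L, 2L), het = c(1L, 1L), other = c(0L, 0L))
  gm <- make_gm(g)
  tab <- em_hap_freqs(gm, 1:2)
  statuses <- data.frame(id = c("hom", "het", "other"),
                         status = c("case", "case", "control"))
  res <- hap_homozygosity_by_group(tab, statuses, groups = c("case", "control"))
  row11 <- res[res$haplotype == "AA" & res$group == "case", ]
  expect_equal(row11$n_hom, 1L)             # only the unambiguous homozygote
  expect_equal(row11$formatted, "0.50 (1)")
  # the double het ties between (00,11) and (01,10): never counted homozygous
  expect_true(all(res$n_hom[res$haplotype != "AA" | res$group != "case"] <= 1))
  # unambiguous phased truth recovers exact group counts
  set.seed(48)
  hap <- rbinom(80, 1, 0.5)
  g2 <- cbind(2L * hap, 2L * hap)
  rownames(g2) <- sprintf("s%02d", 1:80)
  tab2 <- em_hap_freqs(make_gm(g2), 1:2)
  st2 <- data.frame(id = rownames(g2),
                    status = rep(c("case", "control"), 40))
  res2 <- hap_homozygosity_by_group(tab2, st2, groups = c("case", "control"))
  r <- res2[res2$haplotype == "AA" & res2$group == "case", ]
  expect_equal(r$n_hom, sum(hap[seq(1, 80, 2)] == 1))
})
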