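test_that("sim_config validates probabilities, counts and the risk locus", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(penetrance_aa = 1.2), "probability")
  expect_error(sim_config(n_founders = 0), ">= 1")
  expect_error(sim_config(risk_locus = list(chr = 99, index = 1, freq = 0.2)),
               "chromosome")
  expect_error(sim_config(risk_locus = list(chr = 1, index = 5000, freq = 0.2)),
               "index")
})

test_that("a one-generation pedigree is all founders", {
  set.seed(1)
  ped <- simulate_pedigree(sim_config(n_generations = 1, n_founders = 25))
  expect_equal(nrow(ped), 25L)
  expect_true(all(is.na(ped$sire)) && all(is.na(ped$dam)))
})

test_that("offspring counts match dams x litter size in expectation", {
  # all males eligible, so the only randomness is litter size and sex
  tot <- ndam <- 0
  for (s in 1:30) {
    set.seed(s)
    ped <- simulate_pedigree(sim_config(
      n_generations = 3, n_founders = 20, sire_fraction = 1,
      dam_fraction = 1, mean_litter_size = 2))
    for (g in 1:2) {
      prev_f <- sum(ped$sex[ped$generation == g - 1] == "F")
      tot <- tot + sum(ped$generation == g)
      ndam <- ndam + prev_f
    }
  }
  # Poisson(2) per dam: mean offspring per dam should be near 2
  expect_gt(tot / ndam, 1.8)
  expect_lt(tot / ndam, 2.2)
})

test_that("identical configurations reproduce the cohort exactly", {
  cfg <- sim_config(n_generations = 3, n_founders = 30, n_chromosomes = 2,
                    snps_per_chromosome = 50,
                    risk_locus = list(chr = 1, index = 25, freq = 0.3),
                    missing_rate = 0.05, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$pedigree, b$pedigree)
  expect_identical(a$genotypes$geno, b$genotypes$geno)
  expect_identical(a$clinical, b$clinical)
})

test_that("founder pool respects the MAF floor and flags monomorphic pools", {
  set.seed(3)
  cfg <- sim_config(n_generations = 1, n_founders = 150, n_chromosomes = 1,
                    snps_per_chromosome = 120, maf_floor = 0.05,
                    haplotypes_per_block = c(2L, 4L),
                    risk_locus = list(chr = 1, index = 60, freq = 0.3))
  pool <- simulate_founder_haplotypes(cfg)
  # the floor applies to the latent pool frequencies; every SNP except the
  # planted risk locus must clear it (founder draws add sampling noise, so
  # check the implied frequencies via a large founder redraw)
  p <- colMeans(pool$haplo)
  maf <- pmin(p, 1 - p)
  expect_true(all(maf[-pool$risk$column] >= 0.02))
  cfg1 <- sim_config(n_generations = 1, n_founders = 20, n_chromosomes = 1,
                     snps_per_chromosome = 10, haplotypes_per_block = c(1L, 1L),
                     risk_locus = list(chr = 1, index = 5, freq = 0))
  expect_message(simulate_founder_haplotypes(cfg1), "monomorphic")
})

test_that("two balanced variants per block give within-block r2 = 1 and low cross-block r2", {
  within <- c(); between <- c()
  for (s in 1:5) {
    cfg <- sim_config(n_generations = 1, n_founders = 150, n_chromosomes = 1,
                      snps_per_chromosome = 60, block_length_mean = 6,
                      haplotypes_per_block = c(2L, 2L), maf_floor = 0.2,
                      risk_locus = list(chr = 1, index = 30, freq = 0.5),
                      seed = s)
    co <- simulate_cohort(cfg)
    gm <- co$genotypes
    bl <- co$pool$blocks
    poly <- which(apply(gm$geno, 2, var) > 0)
    for (b in seq_len(nrow(bl))) {
      idx <- intersect(bl$start_idx[b]:bl$end_idx[b], poly)
      idx <- setdiff(idx, co$pool$risk$column)
      if (length(idx) >= 2) {
        within <- c(within, ld_r2(gm, idx[1], idx[2])$r2)
        nxt <- intersect(setdiff(poly, seq_len(bl$end_idx[b])),
                         setdiff(poly, co$pool$risk$column))
        if (length(nxt)) between <- c(between, ld_r2(gm, idx[1], nxt[1])$r2)
      }
    }
  }
  expect_true(all(within > 0.99))
  expect_lt(mean(between), 0.1)
})

test_that("gene dropping is Mendelian at every SNP and drifts within bounds", {
  co <- small_cohort()
  ped <- co$pedigree
  ph <- attr(co$genotypes, "phased")
  g <- co$genotypes$geno
  # each child haplotype allele must come from one of the parent's two
  for (i in which(!is.na(ped$sire))) {
    si <- match(ped$sire[i], ped$id); di <- match(ped$dam[i], ped$id)
    expect_true(all(ph$paternal[i, ] == ph$paternal[si, ] |
                    ph$paternal[i, ] == ph$maternal[si, ]))
    expect_true(all(ph$maternal[i, ] == ph$paternal[di, ] |
                    ph$maternal[i, ] == ph$maternal[di, ]))
  }
  expect_identical(g, ph$paternal + ph$maternal)
})

test_that("zero recombination transmits intact parental chromosomes", {
  cfg <- sim_config(n_generations = 3, n_founders = 20, n_chromosomes = 2,
                    snps_per_chromosome = 40, recomb_cm_per_mb = 0,
                    risk_locus = list(chr = 1, index = 20, freq = 0.3),
                    seed = 17)
  co <- simulate_cohort(cfg)
  ped <- co$pedigree
  ph <- attr(co$genotypes, "phased")
  chr_idx <- split(seq_len(nrow(co$genotypes$map)), co$genotypes$map$chr)
  for (i in which(!is.na(ped$sire))) {
    si <- match(ped$sire[i], ped$id)
    for (cx in chr_idx) {
      expect_true(identical(ph$paternal[i, cx], ph$paternal[si, cx]) ||
                  identical(ph$paternal[i, cx], ph$maternal[si, cx]))
    }
  }
})

test_that("gene_drop rejects half-known parentage", {
  co <- small_cohort()
  bad <- as.data.frame(co$pedigree)[, c("id", "sire", "dam", "sex", "year")]
  bad$dam[which(!is.na(bad$dam))[1]] <- NA
  expect_error(gene_drop(bad, co$pool), "one known parent")
})

test_that("disease assignment follows penetrance in its deterministic limits", {
  co <- small_cohort()
  cfg1 <- co$config; cfg1$penetrance_aa <- 1; cfg1$sporadic_rate <- 0
  set.seed(5)
  d1 <- assign_disease(co$pedigree, co$genotypes, cfg1)
  aa <- d1$truth$id[d1$truth$risk_genotype == 2L]
  expect_setequal(d1$clinical$id[d1$clinical$affected], aa)
  expect_true(all(!is.na(d1$clinical$onset_years[d1$clinical$affected])))
  expect_true(all(d1$clinical$onset_years[d1$clinical$affected] > 0 &
                  d1$clinical$onset_years[d1$clinical$affected] <= 16))
  cfg0 <- co$config; cfg0$penetrance_aa <- 0; cfg0$sporadic_rate <- 0
  d0 <- assign_disease(co$pedigree, co$genotypes, cfg0)
  expect_false(any(d0$clinical$affected))
  cfgw <- co$config; cfgw$penetrance_aa <- 0.01; cfgw$sporadic_rate <- 0.5
  expect_warning(assign_disease(co$pedigree, co$genotypes, cfgw), "protective")
})

test_that("realized prevalence matches the closed-form expectation", {
  # P(affected) = pen * P(aa) + sporadic * (1 - P(aa)), with P(aa) taken
  # from the realized risk genotypes (drift moves allele frequencies)
  n_aff <- 0; n_tot <- 0; expected <- 0
  for (s in 1:20) {
    cfg <- sim_config(n_generations = 3, n_founders = 80, n_chromosomes = 1,
                      snps_per_chromosome = 20,
                      risk_locus = list(chr = 1, index = 10, freq = 0.3),
                      penetrance_aa = 0.5, sporadic_rate = 0.005, seed = s)
    co <- simulate_cohort(cfg)
    aa <- co$truth$risk_genotype == 2L
    n_aff <- n_aff + sum(co$clinical$affected)
    n_tot <- n_tot + nrow(co$clinical)
    expected <- expected + sum(ifelse(aa, 0.5, 0.005))
  }
  p_hat <- n_aff / n_tot
  p_exp <- expected / n_tot
  se <- sqrt(p_exp * (1 - p_exp) / n_tot)
  expect_lt(abs(p_hat - p_exp), 4 * se)
})

test_that("written datasets round-trip and honour the missing rate", {
  cfg <- sim_config(n_generations = 3, n_founders = 40, n_chromosomes = 2,
                    snps_per_chromosome = 60,
                    risk_locus = list(chr = 1, index = 30, freq = 0.3),
                    missing_rate = 0.1, seed = 31)
  co <- simulate_cohort(cfg)
  outdir <- tempfile("simdata")
  paths <- write_dataset(co$genotypes, co$pedigree, co$clinical, co$truth, outdir)
  expect_true(all(file.exists(paths)))
  f_miss <- mean(is.na(co$genotypes$geno))
  expect_lt(abs(f_miss - 0.1), 0.01)
  back <- read_ped_map(paths[["ped"]], paths[["map"]])
  orig <- recode_minor(co$genotypes)
  expect_identical(unname(back$geno), unname(orig$geno))
  expect_equal(back$map$bp, orig$map$bp)
  ped_back <- utils::read.csv(paths[["pedigree"]], stringsAsFactors = FALSE)
  expect_equal(ped_back$id, co$pedigree$id)
  # degenerate inputs are rejected
  empty <- co$genotypes; empty$geno <- empty$geno[, 0, drop = FALSE]
  expect_error(write_dataset(empty, co$pedigree, outdir = outdir), "empty")
})
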