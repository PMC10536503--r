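#' Simulation configuration for a closed breeding population
#'
#' Builds and validates the parameter set for the synthetic cohort generator:
#' a discrete-generation pedigree with popular-sire skew, founder haplotypes
#' with blockwise linkage disequilibrium, Mendelian gene dropping with Haldane
#' recombination, and a planted recessive risk locus with incomplete
#' penetrance and a sporadic (phenocopy) rate.
#'
#' Defaults describe a breed-like closed population: a few hundred dogs over
#' several non-overlapping generations, a minority of males used at stud,
#' disease prevalence in the few-percent range, predominantly B-cell
#' immunophenotype, and age at onset centred on 8.7 years (SD 3.3) truncated
#' to (0, 16].
#'
#' @param n_generations number of discrete generations (founders = generation 0).
#' @param n_founders number of founder dogs.
#' @param sire_fraction fraction of available males used as sires each
#'   generation; matings are additionally skewed so a minority of those sires
#'   account for most offspring.
#' @param popular_sire_skew exponent applied to the exponential stud-use
#'   weights; larger values concentrate matings on fewer sires (0 = uniform
#'   use of the selected sires).
#' @param dam_fraction fraction of available females bred each generation.
#' @param mean_litter_size Poisson mean litter size per dam.
#' @param n_chromosomes,snps_per_chromosome genome dimensions.
#' @param snp_spacing_bp physical spacing between adjacent SNPs (bp).
#' @param block_length_mean mean latent LD-block length in SNPs (geometric).
#' @param haplotypes_per_block integer range (length 2) of distinct haplotype
#'   variants per latent block.
#' @param maf_floor minimum per-SNP minor allele frequency among founder
#'   haplotypes.
#' @param risk_locus list with elements `chr`, `index` (SNP index within that
#'   chromosome) and `freq` (founder risk-allele frequency).
#' @param penetrance_aa probability of disease given two risk alleles.
#' @param sporadic_rate probability of disease given any other genotype.
#' @param bcell_fraction probability an affected dog is B-cell type.
#' @param untyped_fraction fraction of affected dogs whose immunophenotype is
#'   relabelled "untyped".
#' @param onset_mean_years,onset_sd_years,onset_max_years age-at-onset normal
#'   parameters; onset is truncated to `(0, onset_max_years]`.
#' @param missing_rate completely-at-random genotype missingness applied to
#'   the exported calls.
#' @param genotype_last_generations if set, only dogs from this many most
#'   recent generations are genotyped (the pedigree and clinical records
#'   still cover everyone, as in a registry-based study); `NULL` genotypes
#'   the whole pedigree.
#' @param n_genotyped_controls if set, genotyping is case-ascertained: every
#'   affected dog is genotyped (any generation) plus this many unaffected
#'   dogs sampled from the genotyping window, mirroring a case series with
#'   biobank controls; `NULL` genotypes the whole window.
#' @param recomb_cm_per_mb genetic map density (Haldane model, no
#'   interference).
#' @param base_year birth year assigned to founders; each generation adds two
#'   years.
#' @param seed integer seed consumed once by [simulate_cohort()].
#' @return A validated list of class `"sim_config"`.
#' @seealso [simulate_cohort()] for the one-call generator.
#' @export
sim_config <- function(n_generations = 5L,
                       n_founders = 300L,
                       sire_fraction = 0.5,
                       popular_sire_skew = 1,
                       dam_fraction = 0.8,
                       mean_litter_size = 2.5,
                       n_chromosomes = 10L,
                       snps_per_chromosome = 1000L,
                       snp_spacing_bp = 50000L,
                       block_length_mean = 8,
                       haplotypes_per_block = c(2L, 6L),
                       maf_floor = 0.02,
                       risk_locus = list(chr = 1L, index = 500L, freq = 0.25),
                       penetrance_aa = 0.8,
                       sporadic_rate = 0.01,
                       bcell_fraction = 0.85,
                       untyped_fraction = 0.3,
                       onset_mean_years = 8.7,
                       onset_sd_years = 3.3,
                       onset_max_years = 16,
                       missing_rate = 0,
                       genotype_last_generations = NULL,
                       n_genotyped_controls = NULL,
                       recomb_cm_per_mb = 1,
                       base_year = 2000L,
                       seed = 1L) {
  cfg <- list(
    n_generations = as.integer(n_generations), n_founders = as.integer(n_founders),
    sire_fraction = sire_fraction, popular_sire_skew = popular_sire_skew,
    dam_fraction = dam_fraction,
    mean_litter_size = mean_litter_size,
    n_chromosomes = as.integer(n_chromosomes),
    snps_per_chromosome = as.integer(snps_per_chromosome),
    snp_spacing_bp = as.integer(snp_spacing_bp),
    block_length_mean = block_length_mean,
    haplotypes_per_block = as.integer(haplotypes_per_block),
    maf_floor = maf_floor, risk_locus = risk_locus,
    penetrance_aa = penetrance_aa, sporadic_rate = sporadic_rate,
    bcell_fraction = bcell_fraction, untyped_fraction = untyped_fraction,
    onset_mean_years = onset_mean_years, onset_sd_years = onset_sd_years,
    onset_max_years = onset_max_years, missing_rate = missing_rate,
    genotype_last_generations =
      if (is.null(genotype_last_generations)) NULL
      else as.integer(genotype_last_generations),
    n_genotyped_controls =
      if (is.null(n_genotyped_controls)) NULL
      else as.integer(n_genotyped_controls),
    recomb_cm_per_mb = recomb_cm_per_mb, base_year = as.integer(base_year),
    seed = as.integer(seed)
  )
  probs <- c("sire_fraction", "dam_fraction", "maf_floor", "penetrance_aa",
             "sporadic_rate", "bcell_fraction", "untyped_fraction",
             "missing_rate")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("'%s' must be a probability in [0, 1]", p))
  }
  counts <- c("n_generations", "n_founders", "n_chromosomes",
              "snps_per_chromosome", "snp_spacing_bp")
  for (p in counts) {
    if (cfg[[p]] < 1L) stop(sprintf("'%s' must be >= 1", p))
  }
  if (cfg$mean_litter_size <= 0) stop("'mean_litter_size' must be positive")
  if (cfg$popular_sire_skew < 0) stop("'popular_sire_skew' must be >= 0")
  if (cfg$block_length_mean < 1) stop("'block_length_mean' must be >= 1")
  if (length(cfg$haplotypes_per_block) != 2L ||
      any(cfg$haplotypes_per_block < 1L) ||
      cfg$haplotypes_per_block[1] > cfg$haplotypes_per_block[2])
    stop("'haplotypes_per_block' must be an increasing range of counts >= 1")
  rl <- cfg$risk_locus
  if (!is.list(rl) || !all(c("chr", "index", "freq") %in% names(rl)))
    stop("'risk_locus' must be a list with elements chr, index, freq")
  if (rl$chr < 1L || rl$chr > cfg$n_chromosomes)
    stop("risk locus chromosome outside the simulated genome")
  if (rl$index < 1L || rl$index > cfg$snps_per_chromosome)
    stop("risk locus SNP index outside its chromosome")
  if (rl$freq < 0 || rl$freq > 1) stop("risk-allele frequency must be in [0, 1]")
  if (cfg$onset_sd_years <= 0 || cfg$onset_max_years <= 0)
    stop("onset distribution parameters must be positive")
  structure(cfg, class = "sim_config")
}

#' Simulate a multi-generation breed pedigree
#'
#' Discrete non-overlapping generations. Founders (generation 0) have unknown
#' parents. Each later generation is produced by mating a sampled subset of
#' the previous generation's females to a sampled subset of its males; sires
#' are drawn with heavily skewed weights so that a minority of sires account
#' for the majority of offspring (the popular-sire effect typical of pedigree
#' dog breeding).
#'
#' @param config a [sim_config()] object.
#' @return A pedigree data frame (see [build_pedigree()]) with columns `id`,
#'   `sire`, `dam`, `sex`, `year` plus a `generation` column.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n0 <- config$n_founders
  sex0 <- ifelse(stats::runif(n0) < 0.5, "M", "F")
  # guarantee both sexes among founders when any later generation is required
  if (config$n_generations > 1L) {
    if (!any(sex0 == "M")) sex0[1] <- "M"
    if (!any(sex0 == "F")) sex0[n0] <- "F"
  }
  recs <- data.frame(
    id = sprintf("G0_%03d", seq_len(n0)),
    sire = NA_character_, dam = NA_character_,
    sex = sex0, year = config$base_year, generation = 0L,
    stringsAsFactors = FALSE
  )
  prev <- recs
  for (g in seq_len(config$n_generations - 1L)) {
    males <- prev$id[prev$sex == "M"]
    females <- prev$id[prev$sex == "F"]
    if (length(males) == 0L)
      stop(sprintf("no males available to sire generation %d", g))
    if (length(females) == 0L)
      stop(sprintf("no females available to breed generation %d", g))
    n_sires <- max(1L, ceiling(config$sire_fraction * length(males)))
    n_dams <- max(1L, round(config$dam_fraction * length(females)))
    sires <- sample(males, n_sires)
    dams <- sample(females, n_dams)
    # long-tailed stud-use weights: a minority of sires draws most matings
    w <- stats::rexp(n_sires)^config$popular_sire_skew
    kids <- vector("list", n_dams)
    for (d in seq_len(n_dams)) {
      litter <- stats::rpois(1L, config$mean_litter_size)
      if (litter == 0L) next
      sire_d <- sires[sample.int(n_sires, 1L, prob = w)]
      kids[[d]] <- data.frame(
        sire = rep(sire_d, litter), dam = rep(dams[d], litter),
        stringsAsFactors = FALSE
      )
    }
    kids <- do.call(rbind, kids)
    if (is.null(kids) || nrow(kids) == 0L)
      stop(sprintf("no offspring produced in generation %d", g))
    gen <- data.frame(
      id = sprintf("G%d_%03d", g, seq_len(nrow(kids))),
      sire = kids$sire, dam = kids$dam,
      sex = ifelse(stats::runif(nrow(kids)) < 0.5, "M", "F"),
      year = config$base_year + 2L * g, generation = g,
      stringsAsFactors = FALSE
    )
    recs <- rbind(recs, gen)
    prev <- gen
  }
  build_pedigree(recs)
}

# force a SNP's implied founder allele frequency above the MAF floor by
# reassigning its allele across block variants: variants whose cumulative
# frequency is nearest 0.5 carry the "1" allele
.fix_maf <- function(alleles_col, freqs, floor) {
  ord <- order(freqs, decreasing = TRUE)
  cum <- cumsum(freqs[ord])
  k <- which.min(abs(cum - 0.5))
  out <- integer(length(freqs))
  out[ord[seq_len(k)]] <- 1L
  out
}

#' Simulate founder haplotypes with blockwise linkage disequilibrium
#'
#' Each chromosome is partitioned into latent blocks of geometric length.
#' Within a block a small number of distinct haplotype variants segregate at
#' Dirichlet(1) frequencies; founder haplotypes are drawn independently
#' blockwise. This exchangeable-block model is deliberately simple: it gives
#' strong within-block and absent between-block LD, providing planted truth
#' for block-detection tests. The risk locus column is overwritten with
#' independent Bernoulli draws at the configured founder frequency.
#'
#' @param config a [sim_config()] object.
#' @param n_founders number of founders to draw haplotypes for (defaults to
#'   `config$n_founders`).
#' @return A list of class `"haplotype_pool"` with elements `haplo`
#'   (2*n_founders x m binary matrix; rows `2i-1`, `2i` belong to founder i),
#'   `map` (variant map data frame with allele letters), `blocks` (latent
#'   block truth: chr, start/end SNP index, bp bounds, n_variants) and `risk`
#'   (the planted locus: chr, index, column, freq).
#' @export
simulate_founder_haplotypes <- function(config, n_founders = config$n_founders) {
  stopifnot(inherits(config, "sim_config"))
  m_chr <- config$snps_per_chromosome
  n_hap <- 2L * n_founders
  maps <- vector("list", config$n_chromosomes)
  blocks <- vector("list", config$n_chromosomes)
  cols <- vector("list", config$n_chromosomes)
  kmin <- config$haplotypes_per_block[1]
  kmax <- config$haplotypes_per_block[2]
  for (chr in seq_len(config$n_chromosomes)) {
    bp <- seq_len(m_chr) * config$snp_spacing_bp
    # partition into geometric-length blocks
    starts <- integer(0); lens <- integer(0); pos <- 1L
    while (pos <= m_chr) {
      len <- 1L + stats::rgeom(1L, prob = 1 / config$block_length_mean)
      if (pos + len - 1L > m_chr) len <- m_chr - pos + 1L  # clip at chromosome end
      starts <- c(starts, pos); lens <- c(lens, len)
      pos <- pos + len
    }
    hap_chr <- matrix(0L, n_hap, m_chr)
    nvar <- integer(length(starts))
    for (b in seq_along(starts)) {
      idx <- starts[b]:(starts[b] + lens[b] - 1L)
      k <- if (kmin == kmax) kmin else sample(kmin:kmax, 1L)
      nvar[b] <- k
      variants <- matrix(stats::rbinom(k * lens[b], 1L, 0.5), k, lens[b])
      # every variant frequency must clear the MAF floor, otherwise no
      # allele assignment can keep the block's SNPs above it
      freqs <- rep(1 / k, k)
      for (tries in 1:200) {
        cand <- stats::rgamma(k, 1); cand <- cand / sum(cand)
        if (k == 1L || min(cand) >= config$maf_floor) { freqs <- cand; break }
      }
      if (k > 1L) {
        # distinct variants and a MAF floor at every SNP
        for (tries in 1:50) {
          p_snp <- as.vector(freqs %*% variants)
          maf <- pmin(p_snp, 1 - p_snp)
          dup <- duplicated(apply(variants, 1L, paste, collapse = ""))
          if (all(maf >= config$maf_floor) && !any(dup)) break
          bad <- which(maf < config$maf_floor)
          for (j in bad) variants[, j] <- .fix_maf(variants[, j], freqs, config$maf_floor)
          if (any(dup)) {
            for (r in which(dup)) variants[r, ] <- stats::rbinom(lens[b], 1L, 0.5)
          }
        }
      } else {
        message(sprintf(
          "chromosome %d block %d has a single haplotype variant; its SNPs are monomorphic",
          chr, b))
      }
      draws <- sample.int(k, n_hap, replace = TRUE, prob = freqs)
      hap_chr[, idx] <- variants[draws, , drop = FALSE]
    }
    maps[[chr]] <- data.frame(
      chr = as.character(chr), id = sprintf("%d:%d", chr, bp),
      cm = bp / 1e6 * config$recomb_cm_per_mb, bp = bp,
      stringsAsFactors = FALSE
    )
    blocks[[chr]] <- data.frame(
      chr = as.character(chr), start_idx = starts,
      end_idx = starts + lens - 1L,
      start_bp = bp[starts], end_bp = bp[starts + lens - 1L],
      n_variants = nvar, stringsAsFactors = FALSE
    )
    cols[[chr]] <- hap_chr
  }
  haplo <- do.call(cbind, cols)
  map <- do.call(rbind, maps)
  # plant the recessive risk locus as an independent biallelic site
  risk_col <- (config$risk_locus$chr - 1L) * m_chr + config$risk_locus$index
  haplo[, risk_col] <- stats::rbinom(n_hap, 1L, config$risk_locus$freq)
  # allele letters for PED export: a1 carries the internal "1" allele
  letters_pool <- c("A", "C", "G", "T")
  a1 <- sample(letters_pool, nrow(map), replace = TRUE)
  shift <- sample.int(3L, nrow(map), replace = TRUE)
  a2 <- letters_pool[((match(a1, letters_pool) - 1L + shift) %% 4L) + 1L]
  map$a1 <- a1; map$a2 <- a2
  colnames(haplo) <- map$id
  structure(
    list(haplo = haplo, map = map, blocks = do.call(rbind, blocks),
         risk = list(chr = config$risk_locus$chr,
                     index = config$risk_locus$index,
                     column = risk_col, freq = config$risk_locus$freq)),
    class = "haplotype_pool"
  )
}

# one recombinant gamete from a parent's two chromosome-wise haplotypes,
# Haldane model: Poisson crossover count, uniform positions, random start phase
.gamete <- function(h1, h2, cm) {
  len_morgan <- (cm[length(cm)] - cm[1]) / 100
  n_x <- stats::rpois(1L, len_morgan)
  phase0 <- sample.int(2L, 1L)
  if (n_x == 0L) {
    return(if (phase0 == 1L) h1 else h2)
  }
  xpos <- sort(stats::runif(n_x, min = cm[1], max = cm[length(cm)]))
  seg <- findInterval(cm, xpos)  # 0..n_x, increments at each crossover
  phase <- ((phase0 - 1L + seg) %% 2L) + 1L
  ifelse(phase == 1L, h1, h2)
}

#' Drop genes down a pedigree
#'
#' Transmits the founder haplotypes through the pedigree: every offspring
#' receives one recombinant gamete from each parent, with crossovers placed
#' by the Haldane (no-interference) model on the genetic map. Phased
#' haplotypes are retained as an attribute; the returned object exposes
#' unphased 0/1/2 dosages of each variant's internal "1" allele.
#'
#' @param pedigree a pedigree data frame ([build_pedigree()]); individuals
#'   must have either two known parents or none.
#' @param pool a [simulate_founder_haplotypes()] result whose founder count
#'   matches the pedigree's founders.
#' @return A `"genotypes"` object (see [genotypes()]) with attribute
#'   `"phased"` = list of two haplotype matrices and attribute `"risk"`
#'   copied from the pool.
#' @export
gene_drop <- function(pedigree, pool) {
  stopifnot(inherits(pool, "haplotype_pool"))
  ped <- as.data.frame(pedigree)
  one_parent <- xor(is.na(ped$sire), is.na(ped$dam))
  if (any(one_parent))
    stop("individuals with exactly one known parent: ",
         paste(utils::head(ped$id[one_parent], 5L), collapse = ", "),
         " (complete the pedigree with founders first)")
  founders <- ped$id[is.na(ped$sire)]
  if (2L * length(founders) > nrow(pool$haplo))
    stop("haplotype pool has fewer founders than the pedigree")
  map <- pool$map
  m <- nrow(map)
  chr_idx <- split(seq_len(m), map$chr)
  ord <- .topo_order(ped)
  h1 <- matrix(0L, nrow(ped), m, dimnames = list(ped$id, map$id))
  h2 <- h1
  founder_row <- stats::setNames(seq_along(founders), founders)
  for (i in ord) {
    id <- ped$id[i]
    if (is.na(ped$sire[i])) {
      fr <- founder_row[[id]]
      h1[i, ] <- pool$haplo[2L * fr - 1L, ]
      h2[i, ] <- pool$haplo[2L * fr, ]
    } else {
      si <- match(ped$sire[i], ped$id)
      di <- match(ped$dam[i], ped$id)
      for (cx in chr_idx) {
        cmx <- map$cm[cx]
        h1[i, cx] <- .gamete(h1[si, cx], h2[si, cx], cmx)
        h2[i, cx] <- .gamete(h1[di, cx], h2[di, cx], cmx)
      }
    }
  }
  gm <- genotypes(h1 + h2, map)
  attr(gm, "phased") <- list(paternal = h1, maternal = h2)
  attr(gm, "risk") <- pool$risk
  gm
}

#' Assign disease phenotypes under a recessive model
#'
#' Dogs homozygous for the planted risk allele are affected with probability
#' `penetrance_aa`; all other dogs with probability `sporadic_rate`
#' (phenocopies). Affected dogs receive an age at onset from a normal
#' distribution truncated to `(0, onset_max_years]` and an immunophenotype
#' (B with probability `bcell_fraction`, otherwise T), after which a fraction
#' are relabelled "untyped".
#'
#' @param pedigree pedigree data frame covering the genotyped dogs.
#' @param genotypes a `"genotypes"` object carrying a `"risk"` attribute
#'   (from [gene_drop()]).
#' @param config a [sim_config()] object.
#' @return List with `clinical` (id, affected, immunophenotype, onset_years)
#'   and `truth` (id, risk_genotype, carrier_truth, affected, phenocopy).
#' @export
assign_disease <- function(pedigree, genotypes, config) {
  stopifnot(inherits(config, "sim_config"))
  risk <- attr(genotypes, "risk")
  if (is.null(risk)) stop("genotypes carry no risk-locus annotation")
  if (config$penetrance_aa < config$sporadic_rate)
    warning("penetrance below sporadic rate: the risk genotype is protective as configured")
  dose <- genotypes$geno[, risk$column]
  n <- length(dose)
  p_aff <- ifelse(dose == 2L, config$penetrance_aa, config$sporadic_rate)
  affected <- stats::runif(n) < p_aff
  onset <- rep(NA_real_, n)
  pheno_type <- rep(NA_character_, n)
  if (any(affected)) {
    k <- sum(affected)
    lo <- stats::pnorm(0, config$onset_mean_years, config$onset_sd_years)
    hi <- stats::pnorm(config$onset_max_years, config$onset_mean_years,
                       config$onset_sd_years)
    onset[affected] <- round(stats::qnorm(stats::runif(k, lo, hi),
                                          config$onset_mean_years,
                                          config$onset_sd_years), 2L)
    pheno_type[affected] <- ifelse(stats::runif(k) < config$bcell_fraction, "B", "T")
    untype <- affected & (stats::runif(n) < config$untyped_fraction)
    pheno_type[untype] <- "untyped"
  }
  ids <- rownames(genotypes$geno)
  list(
    clinical = data.frame(id = ids, affected = affected,
                          immunophenotype = pheno_type,
                          onset_years = onset, stringsAsFactors = FALSE),
    truth = data.frame(id = ids, risk_genotype = as.integer(dose),
                       carrier_truth = dose == 1L, affected = affected,
                       phenocopy = affected & dose != 2L,
                       stringsAsFactors = FALSE)
  )
}

#' Simulate a complete cohort
#'
#' One-call generator: seeds the RNG from `config$seed`, simulates the
#' pedigree, founder haplotypes, gene drop, disease assignment and (if
#' `missing_rate > 0`) completely-at-random missing genotype calls.
#' Identical configurations produce identical cohorts.
#'
#' @param config a [sim_config()] object.
#' @return List of class `"sim_cohort"`: `pedigree`, `pool`, `genotypes`,
#'   `clinical`, `truth`, `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ped <- simulate_pedigree(config)
  pool <- simulate_founder_haplotypes(config, n_founders = sum(is.na(ped$sire)))
  gm <- gene_drop(ped, pool)
  dis <- assign_disease(ped, gm, config)
  window <- ped$id
  if (!is.null(config$genotype_last_generations)) {
    cutoff <- max(ped$generation) - config$genotype_last_generations + 1L
    window <- ped$id[ped$generation >= cutoff]
  }
  genotyped <- window
  if (!is.null(config$n_genotyped_controls)) {
    cases <- dis$clinical$id[dis$clinical$affected]
    ctrl_pool <- setdiff(window, cases)
    controls <- if (length(ctrl_pool) > config$n_genotyped_controls)
      sample(ctrl_pool, config$n_genotyped_controls) else ctrl_pool
    genotyped <- c(cases, controls)
  }
  genotyped <- ped$id[ped$id %in% genotyped]  # pedigree order
  if (length(genotyped) < nrow(ped))
    gm <- subset_genotypes(gm, samples = genotyped)
  if (config$missing_rate > 0) {
    drop <- matrix(stats::runif(length(gm$geno)) < config$missing_rate,
                   nrow(gm$geno))
    gm$geno[drop] <- NA_integer_
  }
  structure(list(pedigree = ped, pool = pool, genotypes = gm,
                 clinical = dis$clinical, truth = dis$truth, config = config),
            class = "sim_cohort")
}

#' Write a simulated cohort to plain-text files
#'
#' Emits PLINK-style PED/MAP genotypes plus pedigree, clinical and truth CSV
#' tables. Reading the files back with [read_ped_map()] reproduces the
#' genotype calls (after minor-allele recoding).
#'
#' @param genotypes a `"genotypes"` object.
#' @param pedigree pedigree data frame.
#' @param clinical,truth tables from [assign_disease()] (may be `NULL`).
#' @param outdir output directory, created if needed.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_dataset <- function(genotypes, pedigree, clinical = NULL, truth = NULL,
                          outdir) {
  if (is.null(genotypes$geno) || nrow(genotypes$geno) == 0L ||
      ncol(genotypes$geno) == 0L)
    stop("empty genotype matrix; nothing to write")
  ids <- rownames(genotypes$geno)
  if (anyDuplicated(ids))
    stop("duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ped <- as.data.frame(pedigree)
  map <- genotypes$map
  pheno <- rep(-9L, length(ids))
  if (!is.null(clinical)) {
    mi <- match(ids, clinical$id)
    pheno <- ifelse(is.na(mi), -9L, ifelse(clinical$affected[mi], 2L, 1L))
  }
  pi <- match(ids, ped$id)
  sex_code <- ifelse(is.na(ped$sex[pi]), 0L, ifelse(ped$sex[pi] == "M", 1L, 2L))
  # allele pairs: dosage d of a1 -> d copies of a1, 2-d of a2; NA -> "0 0"
  g <- genotypes$geno
  n <- nrow(g); m <- ncol(g)
  al1 <- matrix(rep(map$a1, each = n), n, m)
  al2 <- matrix(rep(map$a2, each = n), n, m)
  first <- ifelse(is.na(g), "0", ifelse(g >= 1L, al1, al2))
  second <- ifelse(is.na(g), "0", ifelse(g == 2L, al1, al2))
  allele_cols <- matrix("", n, 2L * m)
  allele_cols[, seq(1L, 2L * m, 2L)] <- first
  allele_cols[, seq(2L, 2L * m, 2L)] <- second
  ped_out <- cbind(
    data.frame(fid = "POP", iid = ids,
               pat = ifelse(is.na(ped$sire[pi]), "0", ped$sire[pi]),
               mat = ifelse(is.na(ped$dam[pi]), "0", ped$dam[pi]),
               sex = sex_code, pheno = pheno, stringsAsFactors = FALSE),
    as.data.frame(allele_cols, stringsAsFactors = FALSE)
  )
  paths <- c(ped = file.path(outdir, "cohort.ped"),
             map = file.path(outdir, "cohort.map"),
             pedigree = file.path(outdir, "pedigree.csv"),
             clinical = file.path(outdir, "clinical.csv"),
             truth = file.path(outdir, "truth.csv"))
  data.table::fwrite(ped_out, paths[["ped"]], sep = " ", col.names = FALSE,
                     quote = FALSE)
  data.table::fwrite(map[, c("chr", "id", "cm", "bp")], paths[["map"]],
                     sep = "\t", col.names = FALSE, quote = FALSE)
  ped_csv <- ped[, c("id", "sire", "dam", "sex", "year")]
  data.table::fwrite(ped_csv, paths[["pedigree"]], na = "", quote = FALSE)
  if (!is.null(clinical)) data.table::fwrite(clinical, paths[["clinical"]],
                                             na = "", quote = FALSE)
  else paths <- paths[names(paths) != "clinical"]
  if (!is.null(truth)) data.table::fwrite(truth, paths[["truth"]],
                                          na = "", quote = FALSE)
  else paths <- paths[names(paths) != "truth"]
  invisible(paths)
}
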