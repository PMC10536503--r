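#' Genotype container
#'
#' Samples-by-variants dosage matrix with a variant map. Dosages count
#' copies of the variant's `a1` allele (0, 1, 2 or NA). After
#' [recode_minor()] or [read_ped_map()], `a1` is the minor allele per
#' variant, so dosages are minor-allele counts.
#'
#' @param geno integer matrix, samples x variants, with sample ids as
#'   rownames; values in 0/1/2/NA.
#' @param map data frame with columns `chr`, `id`, `bp` and allele columns
#'   `a1`, `a2` (a `cm` column is kept if present). Sorted by (chr, bp).
#' @return List of class `"genotypes"` with elements `geno` and `map`.
#' @export
genotypes <- function(geno, map) {
  if (is.null(rownames(geno))) stop("genotype matrix needs sample id rownames")
  need <- c("chr", "id", "bp", "a1", "a2")
  if (!all(need %in% names(map)))
    stop("map needs columns ", paste(need, collapse = ", "))
  if (ncol(geno) != nrow(map))
    stop("genotype matrix and map disagree on variant count")
  if (any(map$bp <= 0)) stop("base-pair positions must be positive")
  if (any(map$a1 == map$a2)) stop("a1 and a2 must differ for every variant")
  chr_num <- suppressWarnings(as.numeric(map$chr))  # natural chromosome order
  ord <- order(is.na(chr_num), chr_num, map$chr, map$bp, method = "radix")
  map <- map[ord, , drop = FALSE]
  geno <- geno[, ord, drop = FALSE]
  rownames(map) <- NULL
  colnames(geno) <- map$id
  structure(list(geno = geno, map = map), class = "genotypes")
}

#' @export
print.genotypes <- function(x, ...) {
  cat(sprintf("genotypes: %d samples x %d variants on %d chromosome(s)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$chr))))
  invisible(x)
}

#' @export
dim.genotypes <- function(x) dim(x$geno)

#' Subset a genotypes object
#'
#' @param gm a `"genotypes"` object.
#' @param samples sample ids or indices (default all).
#' @param variants variant ids or indices (default all).
#' @return A `"genotypes"` object.
#' @export
subset_genotypes <- function(gm, samples = NULL, variants = NULL) {
  g <- gm$geno; map <- gm$map
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, rownames(g))
    if (anyNA(samples)) stop("unknown sample ids")
    g <- g[samples, , drop = FALSE]
  }
  if (!is.null(variants)) {
    if (is.character(variants)) variants <- match(variants, map$id)
    if (anyNA(variants)) stop("unknown variant ids")
    g <- g[, variants, drop = FALSE]
    map <- map[variants, , drop = FALSE]
  }
  out <- genotypes(g, map)
  attr(out, "risk") <- attr(gm, "risk")
  ph <- attr(gm, "phased")
  if (!is.null(ph)) {
    sub <- function(h) {
      h <- h[rownames(out$geno), , drop = FALSE]
      if (!is.null(variants)) h[, variants, drop = FALSE] else h
    }
    attr(out, "phased") <- lapply(ph, sub)
  }
  out
}

#' Recode dosages to count the minor allele
#'
#' For each variant, the less frequent allele becomes `a1` and dosages count
#' its copies; ties are broken alphabetically (the alphabetically first
#' allele is taken as minor). Idempotent.
#'
#' @param gm a `"genotypes"` object.
#' @return A `"genotypes"` object with minor-allele dosages.
#' @export
recode_minor <- function(gm) {
  g <- gm$geno; map <- gm$map
  n_obs <- colSums(!is.na(g))
  a1_count <- colSums(g, na.rm = TRUE)           # copies of current a1
  a2_count <- 2 * n_obs - a1_count
  flip <- a1_count > a2_count |
    (a1_count == a2_count & map$a1 > map$a2)
  if (any(flip)) {
    g[, flip] <- 2L - g[, flip, drop = FALSE]
    tmp <- map$a1[flip]; map$a1[flip] <- map$a2[flip]; map$a2[flip] <- tmp
  }
  out <- genotypes(g, map)
  attr(out, "risk") <- attr(gm, "risk")
  out
}

#' Read PLINK-style PED/MAP text genotypes
#'
#' Whitespace-delimited PED (FID IID PAT MAT SEX PHENO + two allele columns
#' per variant, missing allele "0") and MAP (chromosome, id, cM, bp).
#' Alleles are recoded so dosages count the minor allele (ties broken
#' alphabetically); a variant observed with a single allele is kept,
#' monomorphic, with an arbitrary second allele and MAF 0.
#'
#' @param ped_path,map_path file paths.
#' @return A `"genotypes"` object; the PED's pedigree columns are attached
#'   as attribute `"fam"`.
#' @export
read_ped_map <- function(ped_path, map_path) {
  map_raw <- data.table::fread(map_path, header = FALSE,
                               colClasses = list(character = 1:2))
  if (ncol(map_raw) == 3L) {
    map <- data.frame(chr = map_raw[[1]], id = map_raw[[2]],
                      bp = as.integer(map_raw[[3]]), stringsAsFactors = FALSE)
  } else {
    map <- data.frame(chr = map_raw[[1]], id = map_raw[[2]],
                      cm = as.numeric(map_raw[[3]]),
                      bp = as.integer(map_raw[[4]]), stringsAsFactors = FALSE)
  }
  m <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * m
  len <- lengths(toks)
  if (any(len != want))
    stop(sprintf("ragged PED line %d: %d fields, expected %d",
                 which(len != want)[1], len[len != want][1], want))
  n <- length(toks)
  tokm <- matrix(unlist(toks), nrow = n, byrow = TRUE)
  fam <- data.frame(fid = tokm[, 1], id = tokm[, 2], pat = tokm[, 3],
                    mat = tokm[, 4], sex = as.integer(tokm[, 5]),
                    pheno = as.numeric(tokm[, 6]), stringsAsFactors = FALSE)
  al1 <- tokm[, 6L + seq(1L, 2L * m, 2L), drop = FALSE]
  al2 <- tokm[, 6L + seq(2L, 2L * m, 2L), drop = FALSE]
  al1[al1 == "0"] <- NA_character_
  al2[al2 == "0"] <- NA_character_
  half <- xor(is.na(al1), is.na(al2))
  if (any(half)) {
    al1[half] <- NA_character_; al2[half] <- NA_character_
  }
  geno <- matrix(NA_integer_, n, m)
  a1c <- character(m); a2c <- character(m)
  for (j in seq_len(m)) {
    obs <- c(al1[, j], al2[, j])
    tab <- sort(table(obs), decreasing = FALSE)
    if (length(tab) > 2L)
      stop(sprintf("variant %s has more than two alleles", map$id[j]))
    if (length(tab) == 0L) {
      a1c[j] <- "A"; a2c[j] <- "N"
      next
    }
    if (length(tab) == 1L) {
      # monomorphic: the observed allele is the major one, MAF 0
      major <- names(tab)[1]
      minor <- setdiff(c("A", "C", "G", "T", "N"), major)[1]
    } else if (tab[1] == tab[2]) {
      minor <- min(names(tab)); major <- max(names(tab))
    } else {
      minor <- names(tab)[1]; major <- names(tab)[2]
    }
    a1c[j] <- minor; a2c[j] <- major
    geno[, j] <- (al1[, j] == minor) + (al2[, j] == minor)
  }
  map$a1 <- a1c; map$a2 <- a2c
  rownames(geno) <- fam$id
  out <- genotypes(geno, map)
  attr(out, "fam") <- fam
  out
}

.missing_by_sample <- function(gm) rowMeans(is.na(gm$geno))
.missing_by_variant <- function(gm) colMeans(is.na(gm$geno))

#' Quality-control filtering of a genotype matrix
#'
#' PLINK-like filter sequence: (1) remove samples with missingness above
#' `mind`; (2) remove variants with missingness above `geno`; (3) recompute
#' allele frequencies on the retained samples and remove variants with minor
#' allele frequency strictly below `maf` (frequency exactly at the threshold
#' is retained). Variants are re-recoded to minor-allele dosage after sample
#' removal.
#'
#' @param gm a `"genotypes"` object.
#' @param mind,geno,maf thresholds in `[0, 1]`.
#' @return List with `genotypes` (filtered) and `report` (class
#'   `"qc_report"`): removed sample ids with missingness, removed variant ids
#'   with reason ("geno" or "maf"), thresholds.
#' @export
qc_filter <- function(gm, mind = 0.2, geno = 0.25, maf = 0.02) {
  for (thr in c(mind, geno, maf))
    if (thr < 0 || thr > 1) stop("thresholds must be in [0, 1]")
  fmiss_s <- .missing_by_sample(gm)
  drop_s <- fmiss_s > mind
  removed_samples <- data.frame(id = rownames(gm$geno)[drop_s],
                                fmiss = fmiss_s[drop_s],
                                stringsAsFactors = FALSE)
  if (all(drop_s)) stop("all samples removed by the mind filter")
  gm2 <- subset_genotypes(gm, samples = which(!drop_s))
  fmiss_v <- .missing_by_variant(gm2)
  drop_geno <- fmiss_v > geno
  gm3 <- subset_genotypes(gm2, variants = which(!drop_geno))
  gm3 <- recode_minor(gm3)
  freq <- allele_frequency(gm3)
  drop_maf <- freq < maf
  removed_variants <- rbind(
    data.frame(id = gm2$map$id[drop_geno],
               reason = rep("geno", sum(drop_geno)), stringsAsFactors = FALSE),
    data.frame(id = gm3$map$id[drop_maf],
               reason = rep("maf", sum(drop_maf)), stringsAsFactors = FALSE)
  )
  gm4 <- subset_genotypes(gm3, variants = which(!drop_maf))
  report <- structure(
    list(removed_samples = removed_samples,
         removed_variants = removed_variants,
         thresholds = c(mind = mind, geno = geno, maf = maf),
         n_samples = nrow(gm4$geno), n_variants = ncol(gm4$geno)),
    class = "qc_report")
  list(genotypes = gm4, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "qc: removed %d sample(s) (mind > %g), %d variant(s) (%d geno > %g, %d maf < %g); retained %d x %d\n",
    nrow(x$removed_samples), x$thresholds["mind"], nrow(x$removed_variants),
    sum(x$removed_variants$reason == "geno"), x$thresholds["geno"],
    sum(x$removed_variants$reason == "maf"), x$thresholds["maf"],
    x$n_samples, x$n_variants))
  invisible(x)
}

#' Per-variant A1 (minor) allele frequency
#'
#' `freq = (2 * n_hom_minor + n_het) / (2 * n_nonmissing)` over the chosen
#' samples.
#'
#' @param gm a `"genotypes"` object with minor-allele dosages.
#' @param samples optional sample ids or indices.
#' @return Named numeric vector, one frequency per variant.
#' @export
allele_frequency <- function(gm, samples = NULL) {
  g <- gm$geno
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, rownames(g))
    if (anyNA(samples) || length(samples) == 0L)
      stop("sample subset empty or unknown")
    g <- g[samples, , drop = FALSE]
  }
  n_obs <- colSums(!is.na(g))
  f <- colSums(g, na.rm = TRUE) / (2 * n_obs)
  f[n_obs == 0L] <- NA_real_
  stats::setNames(f, gm$map$id)
}

#' Per-group genotype frequency table
#'
#' For each requested variant and status group, the frequency and count of
#' minor-allele homozygotes (A1A1) and heterozygotes (A1A2), formatted as in
#' published per-group tables, e.g. `"0.26 (8)"`.
#'
#' @param gm a `"genotypes"` object (minor-allele coded).
#' @param statuses a [classify_cohort()] result (or any data frame with `id`
#'   and `status`); groups tabulated are case, carrier, control.
#' @param variant_ids variants to tabulate.
#' @param groups status groups, default `c("case", "carrier", "control")`.
#' @return Long-format data frame: variant, a1, a2, group, n_group, f_hom,
#'   n_hom, f_het, n_het, hom (formatted), het (formatted).
#' @export
genotype_group_table <- function(gm, statuses, variant_ids,
                                 groups = c("case", "carrier", "control")) {
  vi <- match(variant_ids, gm$map$id)
  if (anyNA(vi))
    stop("unknown variant ids: ",
         paste(variant_ids[is.na(vi)], collapse = ", "))
  fmt <- function(f, n) sprintf("%.2f (%d)", f, n)
  rows <- list()
  for (k in seq_along(vi)) {
    j <- vi[k]
    for (grp in groups) {
      ids <- statuses$id[statuses$status == grp]
      gsub_ <- gm$geno[intersect(ids, rownames(gm$geno)), j]
      ng <- length(gsub_)
      n_hom <- sum(gsub_ == 2L, na.rm = TRUE)
      n_het <- sum(gsub_ == 1L, na.rm = TRUE)
      f_hom <- if (ng) n_hom / ng else 0
      f_het <- if (ng) n_het / ng else 0
      rows[[length(rows) + 1L]] <- data.frame(
        variant = variant_ids[k], a1 = gm$map$a1[j], a2 = gm$map$a2[j],
        group = grp, n_group = ng,
        f_hom = round(f_hom, 2L), n_hom = n_hom,
        f_het = round(f_het, 2L), n_het = n_het,
        hom = fmt(f_hom, n_hom), het = fmt(f_het, n_het),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Merge two genotype panels on shared variants
#'
#' Keeps variants present in both panels with identical chromosome, position
#' and allele pair (in either orientation); conflicting allele pairs are an
#' error rather than being guessed at. Samples are stacked.
#'
#' @param gm1,gm2 `"genotypes"` objects with disjoint sample ids.
#' @return A `"genotypes"` object over the shared variants.
#' @export
merge_genotypes <- function(gm1, gm2) {
  if (length(intersect(rownames(gm1$geno), rownames(gm2$geno))))
    stop("sample ids overlap between panels")
  shared <- intersect(gm1$map$id, gm2$map$id)
  if (!length(shared)) stop("no shared variants")
  i1 <- match(shared, gm1$map$id); i2 <- match(shared, gm2$map$id)
  m1 <- gm1$map[i1, ]; m2 <- gm2$map[i2, ]
  same <- (m1$a1 == m2$a1 & m1$a2 == m2$a2)
  flipped <- (m1$a1 == m2$a2 & m1$a2 == m2$a1)
  bad <- !(same | flipped)
  if (any(bad))
    stop("allele conflict at shared variant(s): ",
         paste(utils::head(shared[bad], 5L), collapse = ", "))
  g2 <- gm2$geno[, i2, drop = FALSE]
  g2[, flipped] <- 2L - g2[, flipped, drop = FALSE]
  genotypes(rbind(gm1$geno[, i1, drop = FALSE], g2), m1)
}
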