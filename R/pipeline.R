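#' Pipeline configuration
#'
#' Assembles and validates the settings for [run_pipeline()]: either a
#' simulation block or input file paths, the QC/classification/significance
#' thresholds (all defaulting to the values appropriate for a
#' carrier-augmented recessive-model GWAS), the designs to run, and the
#' prevalences for the liability-scale heritability report.
#'
#' @param simulation a [sim_config()] object, or `NULL` when loading files.
#' @param ped_path,map_path,pedigree_path,clinical_path input files (used
#'   when `simulation` is NULL): PED/MAP genotypes, pedigree CSV
#'   (id,sire,dam,sex,year) and clinical CSV (id,affected,immunophenotype,
#'   onset_years).
#' @param mind,geno,maf QC thresholds.
#' @param pihat_cutoff relatedness exclusion threshold (default 0.25).
#' @param q_cutoff chromosome-wise q-value significance threshold (default
#'   0.1).
#' @param hap_p_cutoff haplotype-report significance threshold (default
#'   1e-4).
#' @param k mutual kNN neighbourhood size (default 10).
#' @param top_n_stepwise candidate count for backward stepwise (default
#'   100).
#' @param prevalences assumed disease prevalences for the liability report.
#' @param designs subset of `c("quantitative", "binary")`.
#' @param seed RNG seed for the run.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(simulation = NULL,
                            ped_path = NULL, map_path = NULL,
                            pedigree_path = NULL, clinical_path = NULL,
                            mind = 0.2, geno = 0.25, maf = 0.02,
                            pihat_cutoff = 0.25, q_cutoff = 0.1,
                            hap_p_cutoff = 1e-4, k = 10L,
                            top_n_stepwise = 100L,
                            prevalences = c(0.1, 0.05, 0.025),
                            designs = c("quantitative", "binary"),
                            seed = 1L) {
  designs <- as.character(designs)
  if (!length(designs) || !all(designs %in% c("quantitative", "binary")))
    stop("designs must be a non-empty subset of quantitative/binary")
  for (thr in list(mind = mind, geno = geno, maf = maf,
                   pihat_cutoff = pihat_cutoff, q_cutoff = q_cutoff,
                   hap_p_cutoff = hap_p_cutoff)) {
    if (thr < 0 || thr > 1) stop("thresholds must be in [0, 1]")
  }
  if (is.null(simulation) && (is.null(ped_path) || is.null(map_path) ||
                              is.null(pedigree_path) || is.null(clinical_path)))
    stop("either a simulation block or all four input paths are required")
  structure(list(simulation = simulation, ped_path = ped_path,
                 map_path = map_path, pedigree_path = pedigree_path,
                 clinical_path = clinical_path, mind = mind, geno = geno,
                 maf = maf, pihat_cutoff = pihat_cutoff,
                 q_cutoff = q_cutoff, hap_p_cutoff = hap_p_cutoff,
                 k = as.integer(k), top_n_stepwise = as.integer(top_n_stepwise),
                 prevalences = prevalences, designs = designs,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file may contain any [pipeline_config()] argument; a
#' `simulation:` mapping is passed to [sim_config()].
#'
#' @param path YAML file.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulation)) {
    if (!is.null(raw$simulation$risk_locus))
      raw$simulation$risk_locus <- as.list(raw$simulation$risk_locus)
    if (!is.null(raw$simulation$haplotypes_per_block))
      raw$simulation$haplotypes_per_block <-
        as.integer(unlist(raw$simulation$haplotypes_per_block))
    raw$simulation <- do.call(sim_config, raw$simulation)
  }
  do.call(pipeline_config, raw)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage:%s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full carrier-augmented GWAS pipeline
#'
#' Orchestrates the analysis end to end: simulate (or load) the cohort, QC
#' the genotypes, estimate pairwise IBD, classify the cohort into cases /
#' carriers / controls / exclusions, run the mixed-linear-model scan for
#' each requested design with genome-wide and chromosome-wise q-values,
#' tabulate significant SNPs by group, prune the top SNPs by backward
#' stepwise regression, detect haplotype blocks in the significant regions
#' and test them, build the mutual-kNN relationship network, and estimate
#' (liability-scale) heritability for all SNPs and each significant
#' chromosome. All tables are written as TSV files under `outdir` along
#' with a run log; reruns of the same configuration are byte-identical.
#'
#' @param config a [pipeline_config()] object.
#' @param outdir output directory.
#' @return Invisibly, a list with every intermediate result.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  log_lines <- c(
    sprintf("carriergwas %s | %s", as.character(utils::packageVersion("carriergwas")),
            R.version.string),
    sprintf("seed=%d designs=%s", config$seed,
            paste(config$designs, collapse = ",")),
    sprintf("thresholds: mind=%g geno=%g maf=%g pihat=%g q=%g hap_p=%g k=%d top_n=%d",
            config$mind, config$geno, config$maf, config$pihat_cutoff,
            config$q_cutoff, config$hap_p_cutoff, config$k,
            config$top_n_stepwise))
  if (!is.null(config$simulation)) {
    cohort <- .stage("simulate", simulate_cohort(config$simulation))
    ped <- cohort$pedigree
    gm_raw <- cohort$genotypes
    clinical <- cohort$clinical
  } else {
    gm_raw <- .stage("load", read_ped_map(config$ped_path, config$map_path))
    ped <- .stage("load", build_pedigree(
      utils::read.csv(config$pedigree_path, stringsAsFactors = FALSE)))
    clinical <- .stage("load", utils::read.csv(config$clinical_path,
                                               stringsAsFactors = FALSE))
  }
  gm_raw <- recode_minor(gm_raw)
  qc <- .stage("qc", qc_filter(gm_raw, mind = config$mind,
                               geno = config$geno, maf = config$maf))
  gm <- qc$genotypes
  log_lines <- c(log_lines, utils::capture.output(print(qc$report)))
  ibd <- .stage("relatedness", pihat(gm))
  case_ids <- clinical$id[isTRUE_vec(clinical$affected)]
  diagnoses <- data.frame(id = clinical$id, ambiguous = FALSE,
                          immunophenotype =
                            if ("immunophenotype" %in% names(clinical))
                              clinical$immunophenotype else NA_character_,
                          stringsAsFactors = FALSE)
  statuses <- .stage("classify", classify_cohort(
    ped, case_ids, rownames(gm$geno), diagnoses = diagnoses,
    pihat = data.frame(id1 = ibd$id1, id2 = ibd$id2, pihat = ibd$pihat),
    pihat_threshold = config$pihat_cutoff, drop_tcell = FALSE))
  log_lines <- c(log_lines, sprintf("status counts: %s",
    paste(sprintf("%s=%d", names(table(statuses$status)),
                  table(statuses$status)), collapse = " ")))
  results <- list(config = config, pedigree = ped, genotypes = gm,
                  qc_report = qc$report, ibd = ibd, statuses = statuses)
  designs <- list()
  for (design in config$designs) {
    if (design == "quantitative") {
      keep <- statuses$id[statuses$status %in% c("case", "carrier", "control")]
      y <- stats::setNames(statuses$y[match(keep, statuses$id)], keep)
    } else {
      keep <- statuses$id[statuses$status %in% c("case", "control")]
      y <- stats::setNames(
        ifelse(statuses$status[match(keep, statuses$id)] == "case", 1, 0), keep)
    }
    gmd <- subset_genotypes(gm, samples = keep)
    grm <- .stage(paste0("grm_", design), compute_grm(gmd))
    scan <- .stage(paste0("mlma_", design), mlma_scan(gmd, grm, y))
    sig <- scan[scan$q_chr < config$q_cutoff, , drop = FALSE]
    sig_chr <- unique(sig$chr)
    # stepwise on cases vs controls (1/2 coding, carriers removed)
    cc <- statuses$id[statuses$status %in% c("case", "control")]
    cc <- intersect(cc, keep)
    y_cc <- stats::setNames(
      ifelse(statuses$status[match(cc, statuses$id)] == "case", 2, 1), cc)
    top <- scan$snp[order(scan$p)][seq_len(min(config$top_n_stepwise,
                                               length(cc) - 2L,
                                               nrow(scan)))]
    sw <- .stage(paste0("stepwise_", design), backward_stepwise(
      subset_genotypes(gm, samples = cc), y_cc, top))
    group_tab <- if (nrow(sig))
      genotype_group_table(gm, statuses, sig$snp) else NULL
    # haplotype blocks in the significant regions (chromosome-wise)
    hap <- list()
    for (chr in sig_chr) {
      bps <- sig$bp[sig$chr == chr]
      lo <- max(min(bps) - 250000, 1); hi <- max(bps) + 250000
      idx <- which(gmd$map$chr == chr & gmd$map$bp >= lo & gmd$map$bp <= hi)
      if (length(idx) < 2L) next
      region <- subset_genotypes(gmd, variants = idx)
      blocks <- .stage(paste0("blocks_", design), find_blocks(region, chr))
      chr_haps <- list()
      for (b in seq_len(nrow(blocks))) {
        snps <- strsplit(blocks$snps[b], ",")[[1]]
        tab <- tryCatch(em_hap_freqs(region, snps), error = function(e) NULL)
        if (is.null(tab)) next   # block too ambiguous to phase; skip
        assoc <- hap_association(region, tab, y,
                                 model = if (design == "quantitative")
                                   "linear" else "logistic")
        best_p <- suppressWarnings(min(assoc$p, na.rm = TRUE))
        hom <- if (is.finite(best_p) && best_p < config$hap_p_cutoff)
          hap_homozygosity_by_group(tab, statuses) else NULL
        chr_haps[[b]] <- list(block = blocks[b, ], table = tab,
                              assoc = assoc, homozygosity = hom)
      }
      hap[[as.character(chr)]] <- list(blocks = blocks, tests = chr_haps)
    }
    # heritability: all SNPs plus each significant chromosome
    n_cases <- sum(statuses$status == "case")
    n_cc <- length(cc)
    herit <- list()
    y_bin <- stats::setNames(
      ifelse(statuses$status[match(cc, statuses$id)] == "case", 1, 0), cc)
    gm_cc <- subset_genotypes(gm, samples = cc)
    for (region in c("all", sig_chr)) {
      fit <- tryCatch(
        ai_reml(grm_subset(gm_cc, region), y_bin),
        error = function(e) e)
      herit[[region]] <- if (inherits(fit, "error")) fit else
        list(fit = fit, report = reml_report(fit, config$prevalences,
                                             n_cases, n_cc))
    }
    designs[[design]] <- list(phenotype = y, grm = grm, scan = scan,
                              significant = sig, group_table = group_tab,
                              stepwise = sw, haplotypes = hap,
                              heritability = herit)
    log_lines <- c(log_lines, sprintf(
      "%s design: n=%d, %d chromosome-wise significant SNP(s) on {%s}",
      design, length(keep), nrow(sig), paste(sig_chr, collapse = ",")))
  }
  results$designs <- designs
  if (all(c("quantitative", "binary") %in% names(designs))) {
    overlap <- intersect(designs$quantitative$significant$snp,
                         designs$binary$significant$snp)
    results$design_overlap <- overlap
    log_lines <- c(log_lines, sprintf(
      "design overlap: %d SNP(s) significant in both designs", length(overlap)))
  }
  # relationship network on the analyzed cohort
  net_ids <- statuses$id[statuses$status %in% c("case", "carrier", "control")]
  net <- .stage("network", mknn_graph(
    ibs_distance_matrix(subset_genotypes(gm, samples = net_ids)),
    k = config$k))
  results$network <- net
  .write_pipeline_outputs(results, outdir, log_lines)
  invisible(results)
}

.write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA")
}

.write_pipeline_outputs <- function(results, outdir, log_lines) {
  .write_tsv(results$statuses, file.path(outdir, "statuses.tsv"))
  .write_tsv(results$ibd, file.path(outdir, "ibd.tsv"))
  .write_tsv(results$network$edges, file.path(outdir, "network_edges.tsv"))
  for (design in names(results$designs)) {
    d <- results$designs[[design]]
    scan <- d$scan
    out <- data.frame(Chr = scan$chr, SNP = scan$snp, bp = scan$bp,
                      A1 = scan$a1, Freq = scan$freq, b = scan$b,
                      SE = scan$se, p = scan$p,
                      q_genomewide = scan$q_genomewide, q_chr = scan$q_chr)
    .write_tsv(out, file.path(outdir, sprintf("mlma_%s.tsv", design)))
    if (nrow(d$significant))
      .write_tsv(d$significant, file.path(outdir,
                                          sprintf("significant_%s.tsv", design)))
    if (!is.null(d$group_table))
      .write_tsv(d$group_table, file.path(outdir,
                                          sprintf("group_table_%s.tsv", design)))
    sw <- data.frame(retained = d$stepwise$retained)
    .write_tsv(sw, file.path(outdir, sprintf("stepwise_%s.tsv", design)))
    for (chr in names(d$haplotypes)) {
      h <- d$haplotypes[[chr]]
      .write_tsv(h$blocks, file.path(outdir,
                                     sprintf("blocks_%s_chr%s.tsv", design, chr)))
      assoc_all <- do.call(rbind, lapply(seq_along(h$tests), function(b) {
        a <- h$tests[[b]]$assoc
        if (is.null(a) || !nrow(a)) return(NULL)
        cbind(block_start = h$tests[[b]]$block$start_bp, a)
      }))
      if (!is.null(assoc_all))
        .write_tsv(assoc_all, file.path(outdir,
                                        sprintf("hap_assoc_%s_chr%s.tsv", design, chr)))
      hom_all <- do.call(rbind, lapply(seq_along(h$tests), function(b) {
        hh <- if (is.null(h$tests[[b]])) NULL else h$tests[[b]]$homozygosity
        if (is.null(hh)) return(NULL)
        cbind(block_start = h$tests[[b]]$block$start_bp, hh)
      }))
      if (!is.null(hom_all))
        .write_tsv(hom_all, file.path(outdir,
                                      sprintf("hap_homozygosity_%s_chr%s.tsv", design, chr)))
    }
    for (region in names(d$heritability)) {
      hr <- d$heritability[[region]]
      if (!inherits(hr, "error"))
        .write_tsv(hr$report, file.path(outdir,
          sprintf("hsq_%s_%s.tsv", design, gsub("[:-]", "_", region))))
    }
  }
  writeLines(log_lines, file.path(outdir, "run_log.txt"))
}
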