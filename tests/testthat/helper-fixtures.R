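# quick genotypes constructor for hand-built dosage matrices
make_gm <- function(g, chr = "1", bp = NULL, a1 = "A", a2 = "G") {
  m <- ncol(g)
  if (is.null(bp)) bp <- seq_len(m) * 1000L
  if (length(chr) == 1L) chr <- rep(chr, m)
  if (is.null(rownames(g))) rownames(g) <- sprintf("S%03d", seq_len(nrow(g)))
  map <- data.frame(chr = chr, id = sprintf("%s:%d", chr, bp), bp = bp,
                    a1 = rep(a1, length.out = m), a2 = rep(a2, length.out = m),
                    stringsAsFactors = FALSE)
  genotypes(g, map)
}

# three-generation toy pedigree used by the classification tests:
#   founders gp1 x gp2 -> sire S; gp3 x gp4 -> dam D and her full sib AUNT
#   S x D -> case X and full sib SIB; X x MATE -> child KID; KID2 = child of
#   SIB; U1/U2 unrelated founders
toy_ped <- function() {
  build_pedigree(data.frame(
    id   = c("gp1", "gp2", "gp3", "gp4", "S", "D", "AUNT", "MATE", "X",
             "SIB", "KID", "U1", "U2", "HS"),
    sire = c(NA, NA, NA, NA, "gp1", "gp3", "gp3", NA, "S",
             "S", "X", NA, NA, "S"),
    dam  = c(NA, NA, NA, NA, "gp2", "gp4", "gp4", NA, "D",
             "D", "MATE", NA, NA, "U2"),
    sex  = c("M", "F", "M", "F", "M", "F", "F", "F", "M",
             "M", "F", "M", "F", "M"),
    year = c(1990, 1990, 1990, 1990, 1995, 1995, 1995, 1996, 2000,
             2000, 2004, 1990, 1990, 2001),
    stringsAsFactors = FALSE))
}

# small simulated cohort reused across tests (built once per test run)
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_generations = 4, n_founders = 60, n_chromosomes = 2,
                        snps_per_chromosome = 200, snp_spacing_bp = 10000,
                        risk_locus = list(chr = 1, index = 100, freq = 0.3),
                        penetrance_aa = 0.9, sporadic_rate = 0.01, seed = 421)
      cache <<- simulate_cohort(cfg)
    }
    cache
  }
})
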