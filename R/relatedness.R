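#' Identity-by-state distance matrix
#'
#' `distance(i, j) = 1 - mean(IBS(i, j)) / 2` over the SNPs non-missing in
#' both samples, with `IBS` counting shared alleles (0, 1 or 2) at each SNP.
#' This is the allele-sharing distance used to build genotype-based
#' relationship networks.
#'
#' @param gm a `"genotypes"` object (at least two samples).
#' @return Symmetric matrix in `[0, 1]` with zero diagonal; a pair with no
#'   shared non-missing SNPs gets `NA` with a warning.
#' @export
ibs_distance_matrix <- function(gm) {
  g <- gm$geno
  n <- nrow(g)
  if (n < 2L) stop("need at least two samples")
  M <- !is.na(g)
  gz <- g; gz[!M] <- 0L
  I0 <- (gz == 0L) & M; I1 <- (gz == 1L) & M; I2 <- (gz == 2L) & M
  mode(I0) <- "numeric"; mode(I1) <- "numeric"; mode(I2) <- "numeric"
  Mm <- M; mode(Mm) <- "numeric"
  shared <- tcrossprod(Mm)
  # IBS0: opposite homozygotes; IBS1: one het, one hom; rest of shared = IBS2
  n_ibs0 <- tcrossprod(I0, I2) + tcrossprod(I2, I0)
  n_ibs1 <- tcrossprod(I1, I0 + I2) + tcrossprod(I0 + I2, I1)
  n_ibs2 <- shared - n_ibs0 - n_ibs1
  d <- 1 - (2 * n_ibs2 + n_ibs1) / (2 * shared)
  if (any(shared == 0 & row(d) != col(d))) {
    warning("pair(s) with no shared non-missing SNPs: distance set to NA")
  }
  d[shared == 0] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- list(rownames(g), rownames(g))
  d
}

#' Method-of-moments IBD estimation (PIHAT) for all sample pairs
#'
#' PLINK-style `--genome` estimator: for each pair, the observed counts of
#' IBS states 0/1/2 over shared non-missing SNPs are inverted against their
#' expectations given IBD state, with expectations computed from cohort
#' allele frequencies. The resulting Z0/Z1/Z2 are truncated to `[0, 1]`,
#' renormalized to sum to one, and summarized as `PIHAT = Z2 + Z1/2`.
#' Monomorphic SNPs are uninformative and skipped.
#'
#' @param gm a `"genotypes"` object (minor-allele coded).
#' @return Data frame of class `"ibd_estimates"` with columns `id1`, `id2`,
#'   `z0`, `z1`, `z2`, `pihat`, one row per unordered pair.
#' @export
pihat <- function(gm) {
  p <- allele_frequency(gm)
  poly <- which(!is.na(p) & p > 0 & p < 1)
  if (!length(poly))
    stop("no polymorphic SNPs: IBS expectations are undefined")
  g <- gm$geno[, poly, drop = FALSE]
  p <- p[poly]; q <- 1 - p
  n <- nrow(g)
  if (n < 2L) stop("need at least two samples")
  M <- !is.na(g)
  gz <- g; gz[!M] <- 0L
  I0 <- (gz == 0L) & M; I1 <- (gz == 1L) & M; I2 <- (gz == 2L) & M
  mode(I0) <- "numeric"; mode(I1) <- "numeric"; mode(I2) <- "numeric"
  Mm <- M; mode(Mm) <- "numeric"
  n_shared <- tcrossprod(Mm)
  n_ibs0 <- tcrossprod(I0, I2) + tcrossprod(I2, I0)
  n_ibs1 <- tcrossprod(I1, I0 + I2) + tcrossprod(I0 + I2, I1)
  n_ibs2 <- n_shared - n_ibs0 - n_ibs1
  # per-SNP IBS-state probabilities conditional on IBD state, using
  # unbiased product-moment estimators of p^a q^b from the allele counts
  # (the finite-sample correction that keeps unrelated pairs near zero)
  n_obs <- colSums(M)
  Nc <- 2 * n_obs                       # observed chromosomes per SNP
  X <- colSums(gz)                      # minor-allele count
  Y <- Nc - X
  d4 <- Nc * (Nc - 1) * (Nc - 2) * (Nc - 3)
  d3 <- Nc * (Nc - 1) * (Nc - 2)
  ok4 <- Nc >= 4
  p0_ibd0 <- ifelse(ok4, 2 * X * (X - 1) * Y * (Y - 1) / d4, 2 * p^2 * q^2)
  p1_ibd0 <- ifelse(ok4,
                    4 * (X * (X - 1) * (X - 2) * Y +
                         X * Y * (Y - 1) * (Y - 2)) / d4,
                    4 * p^3 * q + 4 * p * q^3)
  p1_ibd1 <- ifelse(Nc >= 3,
                    2 * (X * (X - 1) * Y + X * Y * (Y - 1)) / d3,
                    2 * p^2 * q + 2 * p * q^2)
  # pair-wise expected counts: sums of per-SNP probs over shared SNPs
  wsum <- function(w) (Mm * rep(w, each = n)) %*% t(Mm)
  E0 <- wsum(p0_ibd0)
  E1_0 <- wsum(p1_ibd0)
  E1_1 <- wsum(p1_ibd1)
  E2_0 <- n_shared - E0 - E1_0
  E2_1 <- n_shared - E1_1
  z0 <- n_ibs0 / E0
  z1 <- (n_ibs1 - z0 * E1_0) / E1_1
  z2 <- (n_ibs2 - z0 * E2_0 - z1 * E2_1) / n_shared
  ut <- upper.tri(z0)
  ids <- rownames(g)
  pair <- which(ut, arr.ind = TRUE)
  Z <- cbind(z0[ut], z1[ut], z2[ut])
  Z[Z < 0] <- 0; Z[Z > 1] <- 1
  Z <- Z / rowSums(Z)
  out <- data.frame(id1 = ids[pair[, 1]], id2 = ids[pair[, 2]],
                    z0 = Z[, 1], z1 = Z[, 2], z2 = Z[, 3],
                    pihat = Z[, 3] + Z[, 2] / 2, stringsAsFactors = FALSE)
  class(out) <- c("ibd_estimates", "data.frame")
  out
}

#' Mutual k-nearest-neighbour graph
#'
#' Builds the undirected graph with an edge (i, j) exactly when j is among
#' i's k nearest neighbours and i is among j's: the construction underlying
#' genotype relationship networks. Distance ties are broken by sample-id
#' order; isolated nodes are retained.
#'
#' @param dist symmetric distance matrix with sample-id dimnames.
#' @param k neighbourhood size (default 10). `k >= n` yields the complete
#'   mutual graph with a warning.
#' @return List of class `"mknn_graph"`: `edges` (data frame id1, id2,
#'   distance), `membership` (named component id per sample), `graph`
#'   (an igraph object).
#' @export
mknn_graph <- function(dist, k = 10L) {
  if (k < 1L) stop("k must be >= 1")
  n <- nrow(dist)
  ids <- rownames(dist)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (n == 1L) {
    g <- igraph::make_empty_graph(1L, directed = FALSE)
    igraph::V(g)$name <- ids
    return(structure(list(edges = data.frame(id1 = character(0),
                                             id2 = character(0),
                                             distance = numeric(0)),
                          membership = stats::setNames(1L, ids), graph = g),
                     class = "mknn_graph"))
  }
  if (k >= n) {
    warning("k >= number of samples: mutual kNN graph is complete")
    k <- n - 1L
  }
  nn <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    ord <- order(dist[i, -i], ids[-i])[seq_len(k)]
    nn[i, setdiff(seq_len(n), i)[ord]] <- TRUE
  }
  mutual <- nn & t(nn)
  pair <- which(mutual & upper.tri(mutual), arr.ind = TRUE)
  edges <- data.frame(id1 = ids[pair[, 1]], id2 = ids[pair[, 2]],
                      distance = dist[pair], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)
  structure(list(edges = edges,
                 membership = comp$membership[ids],
                 graph = g),
            class = "mknn_graph")
}

#' @export
print.mknn_graph <- function(x, ...) {
  cat(sprintf("mutual kNN graph: %d nodes, %d edges, %d component(s)\n",
              length(x$membership), nrow(x$edges),
              length(unique(x$membership))))
  invisible(x)
}
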