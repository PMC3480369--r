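#' Nei's unbiased haplotype diversity
#'
#' `Hd = n/(n-1) * (1 - sum((c_i/n)^2))` for haplotype counts `c_i`,
#' `n = sum(c_i)`: the probability that two sequences drawn without
#' replacement carry different haplotypes.
#'
#' @param counts Non-negative integer vector of haplotype counts for one
#'   population.
#' @return Haplotype diversity in `[0, 1]`.
#' @export
haplotype_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("haplotype diversity needs a sample of at least 2 (n = ",
                  n, ")")
  n / (n - 1) * (1 - sum((counts / n)^2))
}

#' Nucleotide diversity of one population from haplotype counts
#'
#' Average number of pairwise substitution differences per site:
#' `pi = sum_{i<j} c_i c_j d_ij / choose(n, 2) / k`. The distance matrix
#' must count substitution sites only (use
#' `haplotype_distances(ht, "site_deletion")`), so haplotypes distinguished
#' only by indels contribute zero -- populations can show `Hd > 0` with
#' `pi = 0`.
#'
#' @param counts Haplotype counts for one population, aligned with `dist`
#'   (named vectors are matched by name).
#' @param dist Substitutions-only haplotype distance matrix.
#' @param k Alignment length in bp.
#' @return Nucleotide diversity per site.
#' @export
nucleotide_diversity <- function(counts, dist, k) {
  if (!is.null(names(counts))) {
    dist <- dist[names(counts), names(counts), drop = FALSE]
  }
  n <- sum(counts)
  if (n < 2) stop("nucleotide diversity needs a sample of at least 2")
  stopifnot(length(counts) == nrow(dist), k >= 1)
  (drop(counts %*% dist %*% counts) / 2) / choose(n, 2) / k
}

# Pons & Petit within/total diversity for an arbitrary "difference" matrix D.
# With D = 1 - I these are hS/hT (frequency-based); with D a mutational
# distance matrix they are vS/vT (distance-weighted). Returns S, T and the
# differentiation coefficient (T - S)/T.
.pp_stats <- function(counts, D, corrected = TRUE) {
  n <- rowSums(counts)
  K <- nrow(counts)
  p <- counts / n
  vk <- rowSums((p %*% D) * p)
  if (corrected) vk <- n / (n - 1) * vk
  vS <- mean(vk)
  if (K < 2) return(c(S = vS, T = NA_real_, ST = NA_real_))
  ntil <- K / sum(1 / n)
  xbar <- colMeans(p)
  vT_plug <- drop(xbar %*% D %*% xbar) +
    if (corrected) vS / (ntil * K) else 0
  vT <- vS + K / (K - 1) * (vT_plug - vS)
  c(S = vS, T = vT,
    ST = if (is.finite(vT) && vT > 0) (vT - vS) / vT else NA_real_)
}

#' Pons & Petit diversity and differentiation (HS, HT, GST, NST)
#'
#' Within-population diversity `HS` (unweighted mean of per-population
#' unbiased diversities), total diversity `HT` (from unweighted mean
#' haplotype frequencies with both the small-sample correction
#' `hS/(n~ K)` -- `n~` the harmonic mean sample size -- and the `K/(K-1)`
#' correction on the between-population component), and
#' `GST = (HT - HS)/HT`. When a haplotype distance matrix is supplied the
#' same estimators are computed with diversities weighted by `d_ij`,
#' giving `vS`, `vT` and `NST`. Standard errors are delete-one jackknife
#' over populations.
#'
#' Populations with fewer than 2 individuals cannot contribute an unbiased
#' within-population diversity and are dropped with a warning. With all
#' populations fixed for one haplotype `HT = 0` and `GST` is not computable
#' (`NA`, flagged `"NC"`).
#'
#' @param ht A `haplotype_table`.
#' @param dist Optional haplotype distance matrix (for `NST`).
#' @param populations Optional character vector restricting the analysis.
#' @param corrected Use the unbiased (sample-size corrected) estimators
#'   (default); `FALSE` gives the plug-in versions, which are exactly
#'   invariant to scaling all counts by a common integer.
#' @return A `permut_diversity` list: `HS`, `HT`, `GST`, `NST`, `vS`, `vT`,
#'   their jackknife standard errors, `n_pops`, and per-population `hd`.
#' @export
permut_diversity <- function(ht, dist = NULL, populations = NULL,
                             corrected = TRUE) {
  stopifnot(inherits(ht, "haplotype_table"))
  counts <- ht$counts
  if (!is.null(populations)) {
    bad <- setdiff(populations, rownames(counts))
    if (length(bad) > 0L) stop("unknown population: ", bad[1L])
    counts <- counts[populations, , drop = FALSE]
  }
  small <- rowSums(counts) < 2L
  if (any(small)) {
    warning("dropping population(s) with n < 2: ",
            paste(rownames(counts)[small], collapse = ", "))
    counts <- counts[!small, , drop = FALSE]
  }
  if (nrow(counts) < 2L) stop("need at least 2 usable populations")
  counts <- counts[, colSums(counts) > 0L, drop = FALSE]
  m <- ncol(counts)
  D01 <- 1 - diag(m)
  if (!is.null(dist)) {
    dist <- dist[colnames(counts), colnames(counts), drop = FALSE]
  }

  est <- function(cnt) {
    h <- .pp_stats(cnt, D01, corrected)
    v <- if (!is.null(dist)) .pp_stats(cnt, dist, corrected) else
      c(S = NA, T = NA, ST = NA)
    c(HS = unname(h["S"]), HT = unname(h["T"]), GST = unname(h["ST"]),
      vS = unname(v["S"]), vT = unname(v["T"]), NST = unname(v["ST"]))
  }
  theta <- est(counts)
  K <- nrow(counts)
  jack <- vapply(seq_len(K), function(k) est(counts[-k, , drop = FALSE]),
                 numeric(6L))
  se <- apply(jack, 1L, function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2L) return(NA_real_)
    sqrt((length(x) - 1) / length(x) * sum((x - mean(x))^2))
  })
  hd <- apply(counts, 1L, haplotype_diversity)
  structure(list(HS = theta[["HS"]], HT = theta[["HT"]],
                 GST = theta[["GST"]], NST = theta[["NST"]],
                 vS = theta[["vS"]], vT = theta[["vT"]],
                 se = se, n_pops = K, populations = rownames(counts),
                 hd = hd),
            class = "permut_diversity")
}

#' @export
print.permut_diversity <- function(x, ...) {
  fmt <- function(v, s) if (is.na(v)) "NC" else
    sprintf("%.3f (%.4f)", v, s)
  cat("Pons & Petit diversity over", x$n_pops, "populations\n")
  cat("  HS  =", fmt(x$HS, x$se["HS"]), "\n")
  cat("  HT  =", fmt(x$HT, x$se["HT"]), "\n")
  cat("  GST =", fmt(x$GST, x$se["GST"]), "\n")
  if (!is.na(x$NST)) cat("  NST =", fmt(x$NST, x$se["NST"]), "\n")
  invisible(x)
}

#' Permutation test for phylogeographic structure (NST > GST)
#'
#' Haplotype identities are shuffled on the distance matrix (frequencies
#' untouched) `n_perm` times; the one-sided P-value is the fraction of
#' permutations with `NST - GST` at least the observed difference, with the
#' `+1/(n_perm + 1)` correction. `NST > GST` indicates that closely related
#' haplotypes co-occur geographically.
#'
#' @param ht A `haplotype_table`.
#' @param dist Haplotype distance matrix.
#' @param populations Optional subset of populations.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Random seed (required for reproducibility).
#' @return List with `NST`, `GST`, `diff`, `P`, `n_perm`.
#' @export
nst_gst_test <- function(ht, dist, populations = NULL, n_perm = 1000,
                         seed) {
  if (missing(seed)) stop("a seed is required")
  if (n_perm < 100) stop("n_perm must be >= 100")
  counts <- ht$counts
  if (!is.null(populations)) counts <- counts[populations, , drop = FALSE]
  counts <- counts[rowSums(counts) >= 2L, , drop = FALSE]
  counts <- counts[, colSums(counts) > 0L, drop = FALSE]
  D <- dist[colnames(counts), colnames(counts), drop = FALSE]
  m <- ncol(D)
  off <- D[upper.tri(D)]
  h <- .pp_stats(counts, 1 - diag(m))
  GST <- h[["ST"]]

  # NST is linear in D through two inner products; precompute the weights
  n <- rowSums(counts)
  K <- nrow(counts)
  p <- counts / n
  ntil <- K / sum(1 / n)
  WS <- crossprod(sqrt(n / (n - 1) / K) * p)      # vS = <WS, D>
  xbar <- colMeans(p)
  WX <- tcrossprod(xbar)                          # plug-in total = <WX, D>
  nst_of <- function(Dm) {
    vS <- sum(WS * Dm)
    vT_plug <- sum(WX * Dm) + vS / (ntil * K)
    vT <- vS + K / (K - 1) * (vT_plug - vS)
    if (vT > 0) (vT - vS) / vT else NA_real_
  }
  NST <- nst_of(D)
  obs <- NST - GST
  if (length(unique(off)) == 1L) {
    warning("all off-diagonal distances equal: NST == GST by construction")
    return(list(NST = NST, GST = GST, diff = 0, P = 1, n_perm = n_perm))
  }
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    s <- sample.int(m)
    if ((nst_of(D[s, s]) - GST) >= obs) exceed <- exceed + 1L
  }
  P <- (exceed + 1) / (n_perm + 1)
  list(NST = NST, GST = GST, diff = obs, P = P, n_perm = n_perm)
}

#' Migrants per generation from GST
#'
#' Equilibrium island-model conversion for a haploid, maternally inherited
#' marker: `Nm = (1 - GST) / (2 * GST)`.
#'
#' @param gst Differentiation coefficient in `(0, 1]`.
#' @return Effective number of migrants per generation.
#' @export
nm_from_gst <- function(gst) {
  if (any(gst <= 0 | gst > 1)) stop("GST must lie in (0, 1]")
  (1 - gst) / (2 * gst)
}
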