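# Sum of squared deviations of one unit from haplotype counts c and the
# matrix of (squared) inter-haplotype distances D:
#   SS = sum_{pairs a,b in unit} d_ab / n = (c' D c) / (2 n)
.ss_unit <- function(c, D) drop(c %*% D %*% c) / (2 * sum(c))

# Three-level AMOVA components from a population x haplotype count matrix,
# a population -> group factor, and the distance matrix (used as squared
# Euclidean distances, the ARLEQUIN convention for counts of differences).
.amova_components <- function(counts, pop_group, D) {
  K <- nrow(counts)
  n_k <- rowSums(counts)
  N <- sum(n_k)
  G <- length(unique(pop_group))
  ss_wp <- sum(vapply(seq_len(K), function(k) .ss_unit(counts[k, ], D), 0))
  grp_counts <- rowsum(counts, pop_group)
  ss_wg <- sum(vapply(seq_len(nrow(grp_counts)),
                      function(g) .ss_unit(grp_counts[g, ], D), 0))
  ss_tot <- .ss_unit(colSums(counts), D)
  SSD <- c(AG = ss_tot - ss_wg, AP = ss_wg - ss_wp, WP = ss_wp)
  df <- c(AG = G - 1, AP = K - G, WP = N - K)
  MS <- SSD / df
  N_g <- tapply(n_k, pop_group, sum)
  sum_nk2_over_Ng <- sum(tapply(n_k^2, pop_group, sum) / N_g)
  n1 <- (N - sum_nk2_over_Ng) / (K - G)
  n2 <- (sum_nk2_over_Ng - sum(n_k^2) / N) / (G - 1)
  n3 <- (N - sum(N_g^2) / N) / (G - 1)
  sig_c <- MS[["WP"]]
  sig_b <- (MS[["AP"]] - sig_c) / n1
  sig_a <- (MS[["AG"]] - sig_c - n2 * sig_b) / n3
  tot <- sig_a + sig_b + sig_c
  list(SSD = SSD, df = df, sigma = c(a = sig_a, b = sig_b, c = sig_c),
       FCT = sig_a / tot, FSC = sig_b / (sig_b + sig_c),
       FST = (sig_a + sig_b) / tot)
}

# Two-level AMOVA (among / within populations) -> F_ST
.amova2 <- function(counts, D) {
  K <- nrow(counts)
  n_k <- rowSums(counts)
  N <- sum(n_k)
  ss_wp <- sum(vapply(seq_len(K), function(k) .ss_unit(counts[k, ], D), 0))
  ss_tot <- .ss_unit(colSums(counts), D)
  MS_a <- (ss_tot - ss_wp) / (K - 1)
  MS_w <- ss_wp / (N - K)
  nprime <- (N - sum(n_k^2) / N) / (K - 1)
  sig_a <- (MS_a - MS_w) / nprime
  sig_a / (sig_a + MS_w)
}

# expand a count matrix into per-individual haplotype / population indices
.expand_individuals <- function(counts) {
  m <- ncol(counts)
  hap <- unlist(lapply(seq_len(nrow(counts)), function(k)
    rep(seq_len(m), counts[k, ])), use.names = FALSE)
  pop <- rep(seq_len(nrow(counts)), rowSums(counts))
  list(hap = hap, pop = pop, m = m, K = nrow(counts))
}

.counts_from_ind <- function(hap, pop, K, m) {
  matrix(tabulate((hap - 1L) * K + pop, nbins = K * m), nrow = K, ncol = m)
}

#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Partitions the sum of squared inter-haplotype distances into
#' among-group, among-population-within-group, and within-population
#' components (Excoffier-style), yielding the fixation indices `F_CT`,
#' `F_SC` and `F_ST`. Distances are counts of mutational differences used
#' directly as squared distances; set `frequency_only = TRUE` for
#' `d_ij = 1 (i != j)`. Negative variance components are reported as
#' computed. Significance by permutation: individuals among populations
#' within groups (`F_SC`), whole populations among groups (`F_CT`),
#' individuals among all populations (`F_ST`), each with the `+1`
#' correction.
#'
#' @param ht A `haplotype_table`.
#' @param dist Haplotype distance matrix (ignored if `frequency_only`).
#' @param grouping Named character vector mapping population to group; by
#'   default the `region` column of `ht$pops`.
#' @param n_perm Permutations per index (default 1000).
#' @param seed Random seed (required when `n_perm > 0`).
#' @param frequency_only Use presence/absence distances.
#' @return An `amova_result`: data.frame `table` (d.f., SS, variance
#'   components, percentage) plus `FCT`, `FSC`, `FST` and their P-values.
#' @export
amova <- function(ht, dist, grouping = NULL, n_perm = 1000, seed = NULL,
                  frequency_only = FALSE) {
  stopifnot(inherits(ht, "haplotype_table"))
  counts <- ht$counts[, colSums(ht$counts) > 0L, drop = FALSE]
  if (is.null(grouping)) {
    if (is.null(ht$pops) || !"region" %in% names(ht$pops)) {
      stop("no grouping supplied and haplotype table has no region column")
    }
    grouping <- stats::setNames(as.character(ht$pops$region),
                                ht$pops$population)
  }
  grouping <- grouping[rownames(counts)]
  if (anyNA(grouping)) stop("grouping misses population(s): ",
                            rownames(counts)[is.na(grouping)][1L])
  if (length(unique(grouping)) < 2L) stop("need at least 2 groups")
  sizes <- table(grouping)
  if (any(sizes < 2L)) {
    stop("group with a single population (F_SC undefined): ",
         names(sizes)[sizes < 2L][1L])
  }
  D <- if (frequency_only) 1 - diag(ncol(counts)) else
    dist[colnames(counts), colnames(counts), drop = FALSE]
  if (.ss_unit(colSums(counts), D) == 0) {
    stop("all individuals identical: total molecular variance is zero")
  }
  pop_group <- factor(grouping)
  obs <- .amova_components(counts, pop_group, D)

  p <- c(FCT = NA_real_, FSC = NA_real_, FST = NA_real_)
  if (n_perm > 0) {
    if (is.null(seed)) stop("a seed is required when permuting")
    set.seed(seed)
    ind <- .expand_individuals(counts)
    exceed <- c(FCT = 0L, FSC = 0L, FST = 0L)
    grp_of_pop <- as.integer(pop_group)
    for (b in seq_len(n_perm)) {
      # F_ST: individuals among all populations
      cs <- .counts_from_ind(ind$hap, sample(ind$pop), ind$K, ind$m)
      if (.amova_components(cs, pop_group, D)$FST >= obs$FST) {
        exceed[["FST"]] <- exceed[["FST"]] + 1L
      }
      # F_SC: individuals among populations within their group
      pop_perm <- ind$pop
      for (g in seq_along(levels(pop_group))) {
        sel <- grp_of_pop[ind$pop] == g
        pop_perm[sel] <- sample(ind$pop[sel])
      }
      cs <- .counts_from_ind(ind$hap, pop_perm, ind$K, ind$m)
      if (.amova_components(cs, pop_group, D)$FSC >= obs$FSC) {
        exceed[["FSC"]] <- exceed[["FSC"]] + 1L
      }
      # F_CT: whole populations among groups
      if (.amova_components(counts, sample(pop_group), D)$FCT >= obs$FCT) {
        exceed[["FCT"]] <- exceed[["FCT"]] + 1L
      }
    }
    p <- (exceed + 1) / (n_perm + 1)
  }
  tot <- sum(obs$sigma)
  tab <- data.frame(
    source = c("Among groups", "Among populations within groups",
               "Within populations", "Total"),
    df = c(obs$df, sum(obs$df)),
    SS = c(obs$SSD, sum(obs$SSD)),
    variance = c(obs$sigma, tot),
    percent = c(100 * obs$sigma / tot, NA))
  structure(list(table = tab, FCT = obs$FCT, FSC = obs$FSC, FST = obs$FST,
                 p = p, n_perm = n_perm),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (", x$n_perm, "permutations )\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("F_CT = %.4f (P = %.4g)  F_SC = %.4f (P = %.4g)  F_ST = %.4f (P = %.4g)\n",
              x$FCT, x$p[["FCT"]], x$FSC, x$p[["FSC"]], x$FST,
              x$p[["FST"]]))
  invisible(x)
}

#' Pairwise divergence between groups of populations (F_CT)
#'
#' Two-group hierarchical AMOVA for every pair of groups. The returned
#' matrix is symmetric; the diagonal is set to 1 purely as a reporting
#' convention (it is not a self-divergence).
#'
#' @inheritParams amova
#' @return Matrix of pairwise `F_CT` with unit diagonal.
#' @export
pairwise_fct <- function(ht, dist, grouping = NULL) {
  counts <- ht$counts[, colSums(ht$counts) > 0L, drop = FALSE]
  if (is.null(grouping)) {
    grouping <- stats::setNames(as.character(ht$pops$region),
                                ht$pops$population)
  }
  grouping <- grouping[rownames(counts)]
  groups <- unique(grouping)
  D <- dist[colnames(counts), colnames(counts), drop = FALSE]
  out <- matrix(1, length(groups), length(groups),
                dimnames = list(groups, groups))
  for (i in seq_along(groups)) for (j in seq_len(i - 1L)) {
    sel <- grouping %in% groups[c(i, j)]
    cc <- counts[sel, , drop = FALSE]
    res <- .amova_components(cc, factor(grouping[sel]), D)
    out[i, j] <- out[j, i] <- res$FCT
  }
  out
}

#' Pairwise F_ST between populations
#'
#' Two-population AMOVA for every pair. Raw estimates are returned
#' (negative values are not truncated); clamp at the reporting layer if
#' needed.
#'
#' @inheritParams amova
#' @return Symmetric matrix with zero diagonal.
#' @export
fst_matrix <- function(ht, dist) {
  counts <- ht$counts[, colSums(ht$counts) > 0L, drop = FALSE]
  D <- dist[colnames(counts), colnames(counts), drop = FALSE]
  K <- nrow(counts)
  out <- matrix(0, K, K, dimnames = list(rownames(counts),
                                         rownames(counts)))
  for (i in seq_len(K)) for (j in seq_len(i - 1L)) {
    cc <- counts[c(i, j), , drop = FALSE]
    f <- if (.ss_unit(colSums(cc), D) == 0) 0 else .amova2(cc, D)
    out[i, j] <- out[j, i] <- f
  }
  out
}

#' Great-circle distance (haversine)
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (vectorised).
#' @return Distance in km (mean Earth radius 6371.0 km).
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad / 2
  dlon <- (lon2 - lon1) * rad / 2
  a <- sin(dlat)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon)^2
  2 * 6371.0 * asin(pmin(1, sqrt(a)))
}

#' Mantel test of isolation by distance
#'
#' Correlates linearised genetic distance `F_ST / (1 - F_ST)` with
#' great-circle geographic distance (km). `r` is the Pearson correlation of
#' the off-diagonal upper triangles; significance by joint row/column
#' permutation of the genetic matrix (one-sided, `+1` correction).
#'
#' @param fst Population-by-population `F_ST` matrix (all entries `< 1`).
#' @param coords `data.frame` with `population`, `lat`, `lon` covering the
#'   populations of `fst`.
#' @param n_perm Number of permutations.
#' @param seed Random seed (required).
#' @param linearize Apply `F_ST/(1 - F_ST)` (default) or use `fst` as-is.
#' @return A `mantel_result` list: `r`, `P`, `n_perm`, `n`.
#' @export
mantel_ibd <- function(fst, coords, n_perm = 1000, seed,
                       linearize = TRUE) {
  if (missing(seed)) stop("a seed is required")
  pops <- rownames(fst)
  if (linearize) {
    if (any(fst[upper.tri(fst)] >= 1)) {
      idx <- which(fst >= 1 & upper.tri(fst), arr.ind = TRUE)[1L, ]
      stop("F_ST = 1 between ", pops[idx[1L]], " and ", pops[idx[2L]],
           ": linearisation F_ST/(1-F_ST) is infinite")
    }
    gen <- fst / (1 - fst)
  } else gen <- fst
  i <- match(pops, coords$population)
  if (anyNA(i)) stop("coordinates missing for population: ",
                     pops[is.na(i)][1L])
  lat <- coords$lat[i]; lon <- coords$lon[i]
  geo <- outer(seq_along(pops), seq_along(pops), function(a, b)
    haversine_km(lat[a], lon[a], lat[b], lon[b]))
  ut <- upper.tri(gen)
  x <- gen[ut]; y <- geo[ut]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance in a distance matrix: Mantel r undefined")
    return(structure(list(r = NA_real_, P = NA_real_, n_perm = n_perm,
                          n = length(pops)), class = "mantel_result"))
  }
  r_obs <- stats::cor(x, y)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    s <- sample.int(length(pops))
    if (stats::cor(gen[s, s][ut], y) >= r_obs) exceed <- exceed + 1L
  }
  structure(list(r = r_obs, P = (exceed + 1) / (n_perm + 1),
                 n_perm = n_perm, n = length(pops)),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel IBD: r = %.3f, P = %.3g (%d populations, %d permutations)\n",
              x$r, x$P, x$n, x$n_perm))
  invisible(x)
}
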