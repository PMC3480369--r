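# Independent brute-force oracles. These re-derive every statistic from its
# definition by explicit enumeration or quadrature, sharing no code with the
# package internals.

# quick haplotype_table from a count matrix
make_ht <- function(counts, seqs = NULL, region = NULL) {
  pops <- data.frame(population = rownames(counts),
                     stringsAsFactors = FALSE)
  if (!is.null(region)) pops$region <- region
  haplotype_table(counts, seqs = seqs, pops = pops)
}

# alignment + popmap from a vector of sequences and population labels
make_sample <- function(seqs, pop, region = NULL, lat = NULL, lon = NULL) {
  ids <- sprintf("s%03d", seq_along(seqs))
  aln <- cp_alignment(stats::setNames(seqs, ids))
  upop <- unique(pop)
  if (is.null(region)) region <- rep(1L, length(upop))
  if (is.null(lat)) lat <- seq(20, 40, length.out = length(upop))
  if (is.null(lon)) lon <- seq(100, 130, length.out = length(upop))
  popmap <- data.frame(individual = ids, population = pop,
                       region = region[match(pop, upop)],
                       lat = lat[match(pop, upop)],
                       lon = lon[match(pop, upop)],
                       stringsAsFactors = FALSE)
  list(aln = aln, popmap = popmap)
}

# per-column substitution differences between two sequences
oracle_sub_diff <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- 0L
  for (i in seq_along(av)) {
    if (av[i] %in% c("A", "C", "G", "T") &&
        bv[i] %in% c("A", "C", "G", "T") && av[i] != bv[i]) n <- n + 1L
  }
  n
}

# naive O(n^2) nucleotide diversity over expanded individual sequences
oracle_pi <- function(seqs, k) {
  n <- length(seqs)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    tot <- tot + oracle_sub_diff(seqs[i], seqs[j])
  }
  tot / choose(n, 2) / k
}

# three-level AMOVA from first principles: explicit double loops over
# individual pairs for every sum of squares, textbook expected mean squares
oracle_amova3 <- function(hap, pop, grp, D) {
  N <- length(hap)
  ss_within <- function(idx) {
    if (length(idx) < 2L) return(0)
    tot <- 0
    for (a in idx) for (b in idx) tot <- tot + D[hap[a], hap[b]]
    tot / (2 * length(idx))
  }
  ss_tot <- ss_within(seq_len(N))
  ss_wp <- sum(vapply(unique(pop), function(p) ss_within(which(pop == p)),
                      0))
  ss_wg <- sum(vapply(unique(grp), function(g) ss_within(which(grp == g)),
                      0))
  K <- length(unique(pop)); G <- length(unique(grp))
  SSD <- c(AG = ss_tot - ss_wg, AP = ss_wg - ss_wp, WP = ss_wp)
  df <- c(G - 1, K - G, N - K)
  MS <- SSD / df
  n_k <- as.numeric(table(pop)[unique(pop)])
  grp_of_pop <- vapply(unique(pop), function(p)
    grp[which(pop == p)[1L]], grp[1L])
  N_g <- vapply(unique(grp), function(g) sum(n_k[grp_of_pop == g]), 0)
  names(N_g) <- unique(grp)
  s1 <- sum(vapply(unique(grp), function(g)
    sum(n_k[grp_of_pop == g]^2) / N_g[[g]], 0))
  n1 <- (N - s1) / (K - G)
  n2 <- (s1 - sum(n_k^2) / N) / (G - 1)
  n3 <- (N - sum(N_g^2) / N) / (G - 1)
  sc <- MS[[3L]]
  sb <- (MS[[2L]] - sc) / n1
  sa <- (MS[[1L]] - sc - n2 * sb) / n3
  list(sigma = c(sa, sb, sc), SSD = SSD,
       FCT = sa / (sa + sb + sc), FSC = sb / (sb + sc),
       FST = (sa + sb) / (sa + sb + sc))
}

oracle_amova2_fst <- function(hap, pop, D) {
  N <- length(hap)
  ss_within <- function(idx) {
    tot <- 0
    for (a in idx) for (b in idx) tot <- tot + D[hap[a], hap[b]]
    tot / (2 * length(idx))
  }
  K <- length(unique(pop))
  ss_tot <- ss_within(seq_len(N))
  ss_wp <- sum(vapply(unique(pop), function(p) ss_within(which(pop == p)),
                      0))
  MS_a <- (ss_tot - ss_wp) / (K - 1)
  MS_w <- ss_wp / (N - K)
  n_k <- as.numeric(table(pop)[unique(pop)])
  np <- (N - sum(n_k^2) / N) / (K - 1)
  sa <- (MS_a - MS_w) / np
  sa / (sa + MS_w)
}

# all spanning trees of a small complete graph via Pruefer sequences;
# returns the union of edges over all minimum-weight trees
oracle_mst_union_prufer <- function(D) {
  n <- nrow(D)
  decode <- function(pr) {
    deg <- rep(1L, n)
    for (v in pr) deg[v] <- deg[v] + 1L
    edges <- matrix(0L, n - 1L, 2L)
    for (e in seq_along(pr)) {
      leaf <- which(deg == 1L)[1L]
      edges[e, ] <- c(leaf, pr[e])
      deg[leaf] <- deg[leaf] - 1L
      deg[pr[e]] <- deg[pr[e]] - 1L
    }
    last <- which(deg == 1L)
    edges[n - 1L, ] <- last
    edges
  }
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  best <- Inf
  union_edges <- character(0)
  for (r in seq_len(nrow(grid))) {
    ed <- decode(grid[r, ])
    w <- sum(D[ed])
    key <- apply(cbind(pmin(ed[, 1L], ed[, 2L]),
                       pmax(ed[, 1L], ed[, 2L])), 1L, paste,
                 collapse = "-")
    if (w < best - 1e-9) {
      best <- w
      union_edges <- key
    } else if (abs(w - best) < 1e-9) {
      union_edges <- union(union_edges, key)
    }
  }
  sort(union_edges)
}

# cycle-property oracle: edge (i,j) belongs to some MST iff i and j are not
# connected using only edges strictly lighter than d_ij
oracle_mst_union_cycle <- function(D) {
  n <- nrow(D)
  out <- character(0)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    w <- D[i, j]
    adj <- D < w & upper.tri(D) | D < w & lower.tri(D)
    reach <- rep(FALSE, n); reach[i] <- TRUE
    repeat {
      new <- reach | apply(adj[, reach, drop = FALSE], 1L, any)
      if (identical(new, reach)) break
      reach <- new
    }
    if (!reach[j]) out <- c(out, paste(i, j, sep = "-"))
  }
  sort(out)
}

# Tajima's D re-derived from a character matrix of individual sequences
oracle_tajima <- function(seqm) {
  n <- nrow(seqm)
  S <- 0L
  for (c in seq_len(ncol(seqm))) {
    col <- seqm[, c]
    col <- col[col %in% c("A", "C", "G", "T")]
    if (length(unique(col)) > 1L) S <- S + 1L
  }
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    tot <- tot + oracle_sub_diff(paste(seqm[i, ], collapse = ""),
                                 paste(seqm[j, ], collapse = ""))
  }
  kbar <- tot / choose(n, 2)
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (kbar - S / a1) / sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

# exact Ewens-formula Fu's FS for n = 5 using integer Stirling numbers
oracle_fs_n5 <- function(k_obs, theta) {
  stirl <- c(24, 50, 35, 10, 1) # |s(5, 1..5)|
  denom <- theta * (theta + 1) * (theta + 2) * (theta + 3) * (theta + 4)
  pk <- stirl * theta^(1:5) / denom
  Sp <- sum(pk[k_obs:5])
  log(Sp / (1 - Sp))
}

# expected mismatch class probability by numerical quadrature of the
# coalescence-time mixture density
oracle_mismatch_demographic <- function(i, tau, theta0, theta1) {
  recent <- stats::integrate(function(t)
    exp(-t) * t^i / factorial(i) * (1 / theta1) * exp(-t / theta1),
    0, tau, rel.tol = 1e-12)$value
  old <- stats::integrate(function(t)
    exp(-t) * t^i / factorial(i) *
      exp(-tau / theta1) * (1 / theta0) * exp(-(t - tau) / theta0),
    tau, Inf, rel.tol = 1e-12)$value
  recent + old
}

oracle_mismatch_spatial <- function(i, tau, theta, M) {
  a <- (1 + 2 * M) / theta
  recent <- stats::integrate(function(t)
    exp(-t) * t^i / factorial(i) * (1 / theta) * exp(-a * t),
    0, tau, rel.tol = 1e-12)$value
  p_reach <- exp(-a * tau) + 2 * M / (1 + 2 * M) * (1 - exp(-a * tau))
  old <- stats::integrate(function(t)
    exp(-t) * t^i / factorial(i) *
      p_reach * (1 / theta) * exp(-(t - tau) / theta),
    tau, Inf, rel.tol = 1e-12)$value
  recent + old
}

# direct Pearson correlation of the upper triangles
oracle_mantel_r <- function(A, B) {
  ut <- upper.tri(A)
  x <- A[ut]; y <- B[ut]
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
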