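d01 <- function(haps) {
  D <- 1 - diag(length(haps))
  dimnames(D) <- list(haps, haps)
  D
}

test_that("AMOVA recovers complete fixation and no structure", {
  # two populations fixed for different haplotypes one step apart
  cnt <- matrix(c(8L, 0L, 0L, 8L), 2, 2,
                dimnames = list(c("A", "B"), c("H1", "H2")))
  ht <- make_ht(cnt)
  f <- fst_matrix(ht, d01(c("H1", "H2")))
  expect_equal(f["A", "B"], 1)
  expect_equal(diag(f), c(A = 0, B = 0))

  # identical composition -> F_CT ~ 0
  cnt <- matrix(c(5L, 5L, 5L, 5L), 2, 2,
                dimnames = list(c("A", "B"), c("H1", "H2")))
  cnt <- rbind(cnt, cnt); rownames(cnt) <- c("A", "B", "C", "D")
  ht <- make_ht(cnt)
  res <- amova(ht, d01(c("H1", "H2")),
               grouping = c(A = "g1", B = "g1", C = "g2", D = "g2"),
               n_perm = 0)
  expect_lt(abs(res$FCT), 1e-10)
  expect_equal(sum(res$table$percent, na.rm = TRUE), 100, tolerance = 1e-8)
})

test_that("AMOVA equals the brute-force double-loop oracle", {
  set.seed(42)
  haps <- paste0("H", 1:4)
  D <- matrix(sample(0:2, 16, replace = TRUE), 4)
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  diag(D) <- 0
  dimnames(D) <- list(haps, haps)
  cnt <- matrix(rpois(16, 2) + 1L, 4, 4,
                dimnames = list(paste0("P", 1:4), haps))
  ht <- make_ht(cnt)
  grouping <- c(P1 = "g1", P2 = "g1", P3 = "g2", P4 = "g2")
  res <- amova(ht, D, grouping, n_perm = 0)

  hap <- unlist(lapply(1:4, function(k) rep(haps, cnt[k, ])))
  pop <- rep(rownames(cnt), rowSums(cnt))
  grp <- grouping[pop]
  orc <- oracle_amova3(hap, pop, grp, D)
  expect_equal(unname(res$table$variance[1:3]), unname(orc$sigma),
               tolerance = 1e-10)
  expect_equal(res$FCT, orc$FCT, tolerance = 1e-10)
  expect_equal(res$FSC, orc$FSC, tolerance = 1e-10)
  expect_equal(res$FST, orc$FST, tolerance = 1e-10)
  expect_equal(sum(res$table$percent, na.rm = TRUE), 100, tolerance = 1e-8)

  # pairwise F_ST against the two-level oracle
  fm <- fst_matrix(ht, D)
  for (i in 1:4) for (j in seq_len(i - 1)) {
    sel <- pop %in% rownames(cnt)[c(i, j)]
    expect_equal(fm[i, j], oracle_amova2_fst(hap[sel], pop[sel], D),
                 tolerance = 1e-10)
  }
  expect_true(isSymmetric(fm))
  expect_true(all(diag(fm) == 0))
})

test_that("AMOVA rejects degenerate designs", {
  cnt <- matrix(c(5L, 5L, 5L, 1L, 1L, 1L), 3, 2,
                dimnames = list(c("A", "B", "C"), c("H1", "H2")))
  ht <- make_ht(cnt)
  expect_error(amova(ht, d01(c("H1", "H2")),
                     grouping = c(A = "g1", B = "g2", C = "g2"),
                     n_perm = 0), "single population")
  cnt2 <- matrix(c(5L, 5L, 5L, 5L), 4, 1,
                 dimnames = list(c("A", "B", "C", "D"), "H1"))
  expect_error(amova(make_ht(cnt2), matrix(0, 1, 1,
                                           dimnames = list("H1", "H1")),
                     grouping = c(A = "g1", B = "g1", C = "g2", D = "g2"),
                     n_perm = 0), "zero")
})

test_that("pairwise F_CT reproduces the founder mainland/island pattern", {
  # mainland populations: diverse, related haplotypes; two island groups
  # fixed for the same founder haplotype far from the mainland pool
  haps <- paste0("H", 1:5)
  D <- matrix(c(0, 1, 2, 8, 8,
                1, 0, 1, 8, 8,
                2, 1, 0, 9, 9,
                8, 8, 9, 0, 1,
                8, 8, 9, 1, 0), 5, 5, dimnames = list(haps, haps))
  cnt <- rbind(M1 = c(6L, 3L, 1L, 0L, 0L),
               M2 = c(2L, 5L, 3L, 0L, 0L),
               M3 = c(4L, 4L, 2L, 0L, 0L),
               I1 = c(0L, 0L, 0L, 9L, 1L),
               I2 = c(0L, 0L, 0L, 8L, 2L),
               J1 = c(0L, 0L, 0L, 9L, 2L),
               J2 = c(0L, 0L, 0L, 7L, 3L))
  colnames(cnt) <- haps
  ht <- make_ht(cnt)
  grouping <- c(M1 = "mainland", M2 = "mainland", M3 = "mainland",
                I1 = "island1", I2 = "island1",
                J1 = "island2", J2 = "island2")
  fct <- pairwise_fct(ht, d01(haps) * 0 + D, grouping)
  expect_equal(diag(fct), c(mainland = 1, island1 = 1, island2 = 1))
  expect_lt(fct["island1", "island2"], fct["mainland", "island1"])
  expect_lt(fct["island1", "island2"], fct["mainland", "island2"])

  # a group compared with a copy of itself diverges by ~0
  cnt2 <- rbind(cnt[1:3, ], cnt[1:3, ])
  rownames(cnt2) <- c("M1", "M2", "M3", "C1", "C2", "C3")
  cnt2 <- cnt2[, colSums(cnt2) > 0]
  fct2 <- pairwise_fct(make_ht(cnt2), D,
                       c(M1 = "a", M2 = "a", M3 = "a",
                         C1 = "b", C2 = "b", C3 = "b"))
  expect_lt(abs(fct2["a", "b"]), 0.05)

  # two-group F_CT agrees with the brute-force oracle
  sel <- rownames(cnt)[1:5]
  hap <- unlist(lapply(sel, function(p) rep(haps, cnt[p, ])))
  pop <- rep(sel, rowSums(cnt[sel, ]))
  orc <- oracle_amova3(hap, pop, grouping[pop], D)
  expect_equal(fct["mainland", "island1"], orc$FCT, tolerance = 1e-10)
})

test_that("haversine distance is a metric with zero self-distance", {
  expect_equal(haversine_km(31, 121, 31, 121), 0)
  expect_equal(haversine_km(10, 20, 30, 40), haversine_km(30, 40, 10, 20))
  set.seed(8)
  for (r in 1:30) {
    lat <- runif(3, -80, 80); lon <- runif(3, -170, 170)
    d12 <- haversine_km(lat[1], lon[1], lat[2], lon[2])
    d13 <- haversine_km(lat[1], lon[1], lat[3], lon[3])
    d23 <- haversine_km(lat[2], lon[2], lat[3], lon[3])
    expect_lte(d12, d13 + d23 + 1e-9)
  }
})

test_that("Mantel r matches the direct correlation and vegan", {
  set.seed(13)
  pops <- paste0("P", 1:6)
  coords <- data.frame(population = pops, lat = runif(6, 25, 40),
                       lon = runif(6, 100, 135))
  geo <- outer(1:6, 1:6, function(a, b)
    haversine_km(coords$lat[a], coords$lon[a], coords$lat[b],
                 coords$lon[b]))
  # genetic matrix whose linearisation equals geography -> r = 1
  fst <- geo / (1 + geo)
  dimnames(fst) <- list(pops, pops)
  res <- mantel_ibd(fst, coords, n_perm = 199, seed = 4)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_lt(res$P, 0.05)

  # random genetic matrix: r equals the hand-computed Pearson value
  g <- matrix(runif(36, 0, 0.5), 6); g <- (g + t(g)) / 2; diag(g) <- 0
  dimnames(g) <- list(pops, pops)
  res2 <- mantel_ibd(g, coords, n_perm = 199, seed = 4)
  expect_equal(res2$r, oracle_mantel_r(g / (1 - g), geo),
               tolerance = 1e-12)
  if (requireNamespace("vegan", quietly = TRUE)) {
    vg <- vegan::mantel(as.dist(g / (1 - g)), as.dist(geo),
                        permutations = 99)
    expect_equal(res2$r, unname(vg$statistic), tolerance = 1e-10)
  }

  # degenerate inputs
  const <- matrix(0.3, 6, 6); diag(const) <- 0
  dimnames(const) <- list(pops, pops)
  expect_warning(res3 <- mantel_ibd(const, coords, n_perm = 199, seed = 1),
                 "zero variance")
  expect_true(is.na(res3$r))
  bad <- g; bad["P1", "P2"] <- bad["P2", "P1"] <- 1
  expect_error(mantel_ibd(bad, coords, n_perm = 199, seed = 1),
               "P1.*P2|F_ST = 1")
})

test_that("fixation-index P-values are calibrated under no structure", {
  set.seed(99)
  haps <- paste0("H", 1:3)
  D <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3,
              dimnames = list(haps, haps))
  ps <- matrix(NA_real_, 200, 3, dimnames = list(NULL,
                                                 c("FCT", "FSC", "FST")))
  for (r in 1:200) {
    cnt <- matrix(rmultinom(6, 8, c(0.5, 0.3, 0.2)), 6, 3, byrow = TRUE,
                  dimnames = list(paste0("P", 1:6), haps))
    ht <- make_ht(cnt)
    res <- tryCatch(
      amova(ht, D, grouping = setNames(rep(c("g1", "g2"), each = 3),
                                       paste0("P", 1:6)),
            n_perm = 99, seed = r),
      error = function(e) NULL)
    if (!is.null(res)) ps[r, ] <- res$p
  }
  ps <- ps[stats::complete.cases(ps), , drop = FALSE]
  for (idx in colnames(ps)) {
    expect_gt(mean(ps[, idx]), 0.35)
    expect_lt(mean(ps[, idx]), 0.65)
    expect_lt(mean(ps[, idx] <= 0.05), 0.12)
  }
})
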