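named_D <- function(D) {
  dimnames(D) <- list(paste0("H", seq_len(nrow(D))),
                      paste0("H", seq_len(nrow(D))))
  D
}

edge_keys <- function(net, ids = NULL) {
  if (nrow(net$edges) == 0) return(character(0))
  a <- net$edges$from; b <- net$edges$to
  if (!is.null(ids)) { a <- match(a, ids); b <- match(b, ids) }
  sort(paste(pmin(a, b), pmax(a, b), sep = "-"))
}

test_that("minimum spanning networks retain ties and respect epsilon", {
  D <- named_D(matrix(c(0, 3, 3, 0), 2))
  net <- build_msn(D)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$steps, 3)

  # equilateral triangle: all links tie, all retained
  D <- named_D(matrix(1, 3, 3) - diag(3))
  net <- build_msn(D)
  expect_equal(nrow(net$edges), 3L)

  # single haplotype
  net1 <- build_msn(named_D(matrix(0, 1, 1)))
  expect_equal(nrow(net1$edges), 0L)
  expect_equal(nrow(net1$nodes), 1L)
})

test_that("epsilon = 0 network equals the brute-force MST union", {
  set.seed(17)
  for (r in 1:5) {
    n <- 7
    D <- matrix(sample(1:6, n * n, replace = TRUE), n)
    D[lower.tri(D)] <- t(D)[lower.tri(D)]
    diag(D) <- 0
    D <- named_D(D)
    net <- build_msn(D)
    ids <- net$nodes$id
    expect_equal(edge_keys(net, ids), oracle_mst_union_prufer(D),
                 label = paste("replicate", r))
  }
  # larger instance against the cycle-property characterisation
  for (r in 1:5) {
    n <- 8
    D <- matrix(sample(1:7, n * n, replace = TRUE), n)
    D[lower.tri(D)] <- t(D)[lower.tri(D)]
    diag(D) <- 0
    D <- named_D(D)
    net <- build_msn(D)
    expect_equal(edge_keys(net, net$nodes$id), oracle_mst_union_cycle(D))
  }
})

test_that("the epsilon = 0 network contains a full spanning tree", {
  set.seed(23)
  n <- 9
  D <- matrix(sample(1:9, n * n, replace = TRUE), n)
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  diag(D) <- 0
  net <- build_msn(named_D(D))
  g <- igraph::graph_from_data_frame(net$edges[, 1:2], directed = FALSE,
                                     vertices = net$nodes$id)
  expect_true(igraph::is_connected(g))
})

test_that("median joining inserts the star median and leaves paths alone", {
  # three haplotypes pairwise two steps apart: consensus 'AAA' joins them
  s <- make_sample(c("TAA", "ATA", "AAT"), rep("P1", 3))
  ht <- call_haplotypes(s$aln, s$popmap)
  net <- median_joining(ht)
  expect_equal(sum(net$nodes$type == "median_vector"), 1L)
  expect_equal(nrow(net$edges), 3L)
  expect_true(all(net$edges$steps == 1))
  mv <- net$nodes$id[net$nodes$type == "median_vector"]
  expect_true(all(c(net$edges$from, net$edges$to) %in%
                    c(mv, paste0("H", 1:3))))
  expect_equal(sort(table(c(net$edges$from, net$edges$to)))[[4]], 3L)

  # exhaustive Steiner check: 000 is the unique optimal insertion
  X <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  best <- NULL; best_cost <- Inf
  for (v in 0:7) {
    m <- as.integer(intToBits(v)[1:3])
    cost <- sum(abs(sweep(X, 2, m))) # Steiner star cost of candidate m
    if (cost < best_cost) { best_cost <- cost; best <- m }
  }
  expect_equal(best, c(0L, 0L, 0L))

  # already-minimal path gains no medians
  s <- make_sample(c("AAA", "TAA", "TTA", "TTT"), rep("P1", 4))
  ht <- call_haplotypes(s$aln, s$popmap)
  net <- median_joining(ht)
  expect_equal(sum(net$nodes$type == "median_vector"), 0L)
  expect_equal(nrow(net$edges), 3L)
})

test_that("median vectors have degree >= 3 and never raise network cost", {
  sim <- simulate_planted_haplotypes(seed = 31)
  ht <- call_haplotypes(sim$alignment, sim$popmap)
  net <- median_joining(ht)
  X <- attr(net, "vectors")
  # connected, all sampled haplotypes present
  g <- igraph::graph_from_data_frame(net$edges[, 1:2], directed = FALSE,
                                     vertices = net$nodes$id)
  expect_true(igraph::is_connected(g))
  expect_true(all(paste0("H", 1:26) %in% net$nodes$id))
  # every edge's steps equal the recomputed distance between its endpoints
  for (e in seq_len(nrow(net$edges))) {
    a <- X[net$edges$from[e], ]; b <- X[net$edges$to[e], ]
    expect_equal(net$edges$steps[e], sum(a != b))
  }
  deg <- table(factor(c(net$edges$from, net$edges$to),
                      levels = net$nodes$id))
  mv <- net$nodes$id[net$nodes$type == "median_vector"]
  if (length(mv) > 0) expect_true(all(deg[mv] >= 3))
  # cost of the final node set does not exceed the sampled-only MST cost
  Xs <- X[paste0("H", 1:26), ]
  hm <- function(M) {
    G <- tcrossprod(M); s <- diag(G); outer(s, s, "+") - 2 * G
  }
  expect_lte(cpphylo:::.mst_weight(hm(X)), cpphylo:::.mst_weight(hm(Xs)))
  # sampled node frequencies carried for plotting
  expect_equal(sum(net$nodes$freq), 528)
})

test_that("a divergent haplotype keeps its long branch", {
  sim <- simulate_planted_haplotypes(
    n_hap = 8, n_sub = 10, k = 400,
    counts = matrix(rep(2L, 8), 1, dimnames = list("P1", paste0("H", 1:8))),
    popmap_meta = data.frame(population = "P1", region = 1, lat = 30,
                             lon = 120),
    seed = 77)
  seqs <- sim$truth$representative_seqs
  far <- strsplit(seqs[["H8"]], "")[[1]]
  flip <- setdiff(300:330, which(far == "-"))[1:25]
  far[flip] <- vapply(far[flip], function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], "")
  seqs[["H8"]] <- paste(far, collapse = "")
  s <- make_sample(rep(unname(seqs), each = 2), rep("P1", 16))
  ht <- call_haplotypes(s$aln, s$popmap)
  net <- median_joining(ht)
  inc <- net$edges[net$edges$from == "H8" | net$edges$to == "H8", ]
  expect_gte(min(inc$steps), 20)
})

test_that("network export round-trips across formats", {
  D <- named_D(matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3))
  freq <- c(H1 = 5, H2 = 2, H3 = 1)
  type <- c(H1 = "sampled", H2 = "sampled", H3 = "sampled")
  net <- build_msn(D, freq = freq, type = type)
  for (fmt in c("graphml", "tsv_edgelist")) {
    p <- withr::local_tempfile(fileext = paste0(".", fmt))
    export_network(net, p, fmt)
    back <- read_network(p, fmt)
    expect_equal(edge_keys(back), edge_keys(net))
    expect_equal(back$nodes[order(back$nodes$id), c("id", "type", "freq")],
                 net$nodes[order(net$nodes$id), c("id", "type", "freq")],
                 ignore_attr = TRUE)
  }
  # DOT export is write-only but must produce a document
  p <- withr::local_tempfile(fileext = ".dot")
  export_network(net, p, "dot")
  expect_gt(file.size(p), 0)
  # single-node network exports a valid (edgeless) document
  net1 <- build_msn(named_D(matrix(0, 1, 1)))
  p <- withr::local_tempfile(fileext = ".tsv")
  export_network(net1, p, "tsv_edgelist")
  back <- read_network(p, "tsv_edgelist")
  expect_equal(nrow(back$edges), 0L)
  expect_equal(nrow(back$nodes), 1L)
})
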