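test_that("FASTA alignments parse, normalise case and reject bad input", {
  p <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "acgtacgt-n", ">b", "ACGTACGTAC", ">c", "ACGTTCGTAC"),
             p)
  aln <- read_fasta_alignment(p)
  expect_equal(aln$k, 10L)
  expect_equal(aln$ids, c("a", "b", "c"))
  expect_equal(unname(aln$seqs[["a"]]), "ACGTACGT-N")

  writeLines(c(">a", "ACGTACGTA", ">b", "ACGTACGTAC"), p)
  expect_error(read_fasta_alignment(p), "ragged.*'a'")

  writeLines(character(0), p)
  expect_error(read_fasta_alignment(p), "empty")

  writeLines(c(">a", "ACGTXCGTAC"), p)
  expect_error(read_fasta_alignment(p), "non-IUPAC.*position 5")
})

test_that("alignment FASTA round-trips", {
  sim <- simulate_planted_haplotypes(n_hap = 5, n_sub = 6, k = 60,
                                     counts = matrix(
                                       c(3L, 1L, 2L, 1L, 1L), 1,
                                       dimnames = list("P1",
                                                       paste0("H", 1:5))),
                                     popmap_meta = data.frame(
                                       population = "P1", region = 1,
                                       lat = 30, lon = 120),
                                     seed = 5)
  p <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_alignment(sim$alignment, p)
  back <- read_fasta_alignment(p)
  expect_identical(back$seqs, sim$alignment$seqs)
})

test_that("population maps are validated", {
  p <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(individual = paste0("i", 1:5),
                   population = c("A", "A", "B", "B", "B"),
                   region = c(1, 1, 2, 2, 2),
                   lat = c(30, 30, 35, 35, 35),
                   lon = c(110, 110, 120, 120, 120))
  write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(nrow(read_population_map(p)), 5L)

  bad <- df; bad$lat[3] <- 123
  write.table(bad, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_population_map(p), "latitude")

  bad <- df; bad$individual[2] <- "i1"
  write.table(bad, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_population_map(p), "twice")

  bad <- df; bad$region[4] <- 3 # population B in two regions
  write.table(bad, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_population_map(p), "more than one region")
})

test_that("haplotype calling collapses identical sequences", {
  s <- make_sample(rep("ACGTACGT", 4), rep("P1", 4))
  ht <- call_haplotypes(s$aln, s$popmap)
  expect_equal(ncol(ht$counts), 1L)
  expect_equal(unname(ht$counts[1, 1]), 4L)

  s <- make_sample(c("AAAA", "AAAT", "AAAT"), rep("P1", 3))
  ht <- call_haplotypes(s$aln, s$popmap)
  expect_equal(unname(ht$counts[1, ]), c(1L, 2L))
  expect_equal(colnames(ht$counts), c("H1", "H2"))

  s <- make_sample(c("AAAA", "AAAT"), c("P1", "P2"))
  s$popmap <- s$popmap[1, ]
  expect_error(call_haplotypes(s$aln, s$popmap), "not in population map")
})

test_that("N is missing data: it matches any base and never founds a haplotype", {
  s <- make_sample(c("AAAA", "AANA", "AATA"), rep("P1", 3))
  ht <- call_haplotypes(s$aln, s$popmap)
  # AANA joins the first-seen compatible haplotype (AAAA)
  expect_equal(ncol(ht$counts), 2L)
  expect_equal(unname(ht$counts[1, ]), c(2L, 1L))
})

test_that("gap modes behave as specified", {
  seqs <- c("AA-A", "AATA", "AA-A", "CATA")
  s <- make_sample(seqs, rep("P1", 4))
  ht_si <- call_haplotypes(s$aln, s$popmap, "simple_indel")
  expect_equal(ncol(ht_si$counts), 3L)
  ht_sd <- call_haplotypes(s$aln, s$popmap, "site_deletion")
  expect_equal(ncol(ht_sd$counts), 2L) # indel-only distinction merged

  # without gaps, site_deletion and simple_indel agree
  s2 <- make_sample(c("AAAA", "AATA", "CATA"), rep("P1", 3))
  expect_equal(ncol(call_haplotypes(s2$aln, s2$popmap,
                                    "site_deletion")$counts),
               ncol(call_haplotypes(s2$aln, s2$popmap,
                                    "simple_indel")$counts))

  # a shared-boundary gap run is one mutational event
  d <- haplotype_distances(ht_si, "simple_indel")
  expect_equal(d["H1", "H2"], 1L) # AA-A vs AATA
  expect_equal(d["H2", "H3"], 1L) # AATA vs CATA
  expect_equal(d["H1", "H3"], 2L) # indel + substitution
  expect_true(all(diag(d) == 0))
})

test_that("haplotype calling is idempotent", {
  sim <- simulate_planted_haplotypes(seed = 11)
  ht <- call_haplotypes(sim$alignment, sim$popmap)
  reps <- ht$seqs
  s2 <- make_sample(unname(reps), rep("P1", length(reps)))
  ht2 <- call_haplotypes(s2$aln, s2$popmap)
  expect_equal(ncol(ht2$counts), ncol(ht$counts))
})

test_that("distances match the per-column brute-force oracle", {
  set.seed(3)
  sim <- simulate_planted_haplotypes(
    n_hap = 10, n_sub = 14, n_indel = 1, k = 80,
    counts = matrix(rep(1L, 10), 1, dimnames = list("P1",
                                                    paste0("H", 1:10))),
    popmap_meta = data.frame(population = "P1", region = 1, lat = 30,
                             lon = 120),
    seed = 3)
  ht <- call_haplotypes(sim$alignment, sim$popmap)
  d <- haplotype_distances(ht, "site_deletion")
  m <- ht$seqs
  keep <- Reduce(intersect, lapply(m, function(s)
    which(strsplit(s, "")[[1]] != "-")))
  for (i in seq_along(m)) for (j in seq_len(i - 1)) {
    a <- paste(strsplit(m[i], "")[[1]][keep], collapse = "")
    b <- paste(strsplit(m[j], "")[[1]][keep], collapse = "")
    expect_equal(unname(d[i, j]), oracle_sub_diff(a, b))
  }
  # metric invariants
  expect_true(all(d == t(d)))
  for (i in 1:10) for (j in 1:10) for (l in 1:10) {
    expect_lte(d[i, j], d[i, l] + d[l, j])
  }
})

test_that("the planted 26-haplotype world is recovered exactly", {
  sim <- simulate_planted_haplotypes(seed = 99)
  expect_equal(length(sim$alignment$ids), 528L)
  expect_equal(sim$alignment$k, 1670L)
  ht <- call_haplotypes(sim$alignment, sim$popmap)
  expect_equal(ncol(ht$counts), sim$truth$n_haplotypes)
  expect_equal(ncol(ht$counts), 26L)
  # recovered partition matches the planted one (up to haplotype labels)
  planted <- unclass(table(sim$popmap$population, sim$truth$hap_of))
  for (p in rownames(ht$counts)) {
    expect_equal(sort(ht$counts[p, ht$counts[p, ] > 0]),
                 sort(planted[p, planted[p, ] > 0]),
                 ignore_attr = TRUE)
  }
})

test_that("count tables round-trip bit-exactly", {
  ht <- load_table1_fixture()
  p <- withr::local_tempfile(fileext = ".tsv")
  write_haplotype_counts(ht, p)
  back <- read_haplotype_counts(p)
  expect_identical(back$counts, ht$counts)
})

test_that("the packaged survey fixture matches its published summaries", {
  ht <- load_table1_fixture()
  expect_equal(nrow(ht$counts), 50L)
  expect_equal(ncol(ht$counts), 26L)
  expect_equal(sum(ht$counts), 528L)
  xy <- ht$counts["XY", ht$counts["XY", ] > 0]
  expect_equal(xy, c(H3 = 2L, H15 = 2L, H25 = 1L, H26 = 3L))
  expect_equal(sum(ht$counts["XY", ]), 8L)
  expect_equal(length(unique(ht$pops$region)), 7L)
})
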