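#' Pipeline configuration
#'
#' Two entry modes: *alignment mode* (FASTA + population map: the full
#' analysis including distances, NST, AMOVA, network and demography) and
#' *counts mode* (a haplotype count table in the Table-1 layout: frequency
#' statistics only; sequence-dependent outputs are reported `NC`).
#' Dating constants default to the oak study's values: substitution rate
#' `mu = 7.905e-10` s/s/y, sequence length `k = 1670` bp, generation time
#' `g = 50` yr.
#'
#' @param alignment Path to an aligned FASTA (alignment mode).
#' @param popmap Path to a population-map TSV (alignment mode).
#' @param counts Path to a wide haplotype count TSV, or a
#'   `haplotype_table` (counts mode). `"table1"` loads the packaged oak
#'   fixture.
#' @param out_dir Output directory.
#' @param gap_mode Haplotype-calling gap mode (see [call_haplotypes()]).
#' @param n_perm Permutations for all permutation tests.
#' @param n_boot Parametric bootstrap replicates for mismatch fits.
#' @param mu,k,g Dating constants (see [expansion_time()]).
#' @param seed Mandatory seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(alignment = NULL, popmap = NULL, counts = NULL,
                            out_dir, gap_mode = "simple_indel",
                            n_perm = 1000L, n_boot = 100L,
                            mu = 7.905e-10, k = 1670L, g = 50, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (is.null(counts) && (is.null(alignment) || is.null(popmap))) {
    stop("supply either counts or both alignment and popmap")
  }
  for (p in c(alignment, popmap,
              if (is.character(counts) && !identical(counts, "table1"))
                counts)) {
    if (!file.exists(p)) stop("input file does not exist: ", p)
  }
  structure(list(alignment = alignment, popmap = popmap, counts = counts,
                 out_dir = out_dir, gap_mode = gap_mode,
                 n_perm = as.integer(n_perm), n_boot = as.integer(n_boot),
                 mu = mu, k = k, g = g, seed = seed),
            class = "pipeline_config")
}

.fmt_se <- function(v, s) {
  if (is.null(v) || is.na(v)) "NC" else sprintf("%.3f (%.4f)", v, s)
}

# Table-3-style differentiation report rows for one population subset
.permut_row <- function(region, ht, dist, pops, n_perm, seed) {
  usable <- pops[rowSums(ht$counts[pops, , drop = FALSE]) >= 2L]
  if (length(usable) < 2L) {
    return(data.frame(region = region, n_pops = length(pops), HT = "NC",
                      HS = "NC", GST = "NC", NST = "NC", P = "NC",
                      Nm = "NC", stringsAsFactors = FALSE))
  }
  pd <- suppressWarnings(permut_diversity(ht, dist, populations = pops))
  nst <- p <- "NC"
  if (!is.null(dist) && !is.na(pd$GST)) {
    tst <- tryCatch(suppressWarnings(
      nst_gst_test(ht, dist, populations = pops, n_perm = n_perm,
                   seed = seed)), error = function(e) NULL)
    if (!is.null(tst)) {
      nst <- .fmt_se(tst$NST, pd$se[["NST"]])
      p <- sprintf("%.3f%s", tst$P, if (tst$P < 0.05) "*" else "^ns^")
    }
  }
  data.frame(region = region, n_pops = pd$n_pops,
             HT = .fmt_se(pd$HT, pd$se[["HT"]]),
             HS = .fmt_se(pd$HS, pd$se[["HS"]]),
             GST = .fmt_se(pd$GST, pd$se[["GST"]]),
             NST = nst, P = p,
             Nm = if (is.na(pd$GST) || pd$GST <= 0) "NC" else
               sprintf("%.3f", nm_from_gst(pd$GST)),
             stringsAsFactors = FALSE)
}

#' Run the full phylogeography pipeline
#'
#' Orchestrates haplotype calling, diversity and differentiation reports,
#' AMOVA, pairwise divergence, isolation by distance, the median-joining
#' network, and mismatch/neutrality demography, writing TSV reports
#' (`table1_diversity.tsv` ... `table5_demography.tsv`,
#' `network.graphml`) plus a run log into `cfg$out_dir`. In counts mode
#' the sequence-dependent outputs carry explicit `NC` markers.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the computed objects and file paths.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat(sprintf("cpphylo %s | seed %d | n_perm %d | n_boot %d\n",
              as.character(utils::packageVersion("cpphylo")),
              cfg$seed, cfg$n_perm, cfg$n_boot),
      file = log_path)

  counts_mode <- !is.null(cfg$counts)
  if (counts_mode) {
    ht <- if (inherits(cfg$counts, "haplotype_table")) cfg$counts
      else if (identical(cfg$counts, "table1")) load_table1_fixture()
      else read_haplotype_counts(cfg$counts)
    dist <- NULL
    logf("stage input: counts mode, %d populations", nrow(ht$counts))
  } else {
    aln <- read_fasta_alignment(cfg$alignment)
    pm <- read_population_map(cfg$popmap)
    ht <- call_haplotypes(aln, pm, gap_mode = cfg$gap_mode)
    dist <- haplotype_distances(ht, gap_mode = cfg$gap_mode)
    logf("stage input: alignment mode, %d sequences, %d haplotypes",
         length(aln$ids), ncol(ht$counts))
  }
  sub_dist <- if (!counts_mode) haplotype_distances(ht, "site_deletion")
  paths <- character(0)

  # table 1: per-population diversity
  n_k <- rowSums(ht$counts)
  hd <- vapply(seq_len(nrow(ht$counts)), function(i)
    if (n_k[i] < 2) NA_real_ else haplotype_diversity(ht$counts[i, ]), 0)
  pi_col <- if (counts_mode) rep("NC", nrow(ht$counts)) else
    vapply(seq_len(nrow(ht$counts)), function(i)
      if (n_k[i] < 2) "NC" else
        sprintf("%.6f", nucleotide_diversity(ht$counts[i, ], sub_dist,
                                             k = nchar(ht$seqs[1L]))), "")
  t1 <- data.frame(population = rownames(ht$counts), n = n_k,
                   hd = ifelse(is.na(hd), "NC", sprintf("%.3f", hd)),
                   pi = pi_col)
  paths["table1"] <- file.path(cfg$out_dir, "table1_diversity.tsv")
  utils::write.table(t1, paths["table1"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  logf("stage table1: written")

  # table 3: differentiation per region and overall
  region_of <- stats::setNames(as.character(ht$pops$region),
                               ht$pops$population)
  rows <- list()
  for (r in unique(region_of)) {
    rows[[r]] <- .permut_row(r, ht, dist,
                             names(region_of)[region_of == r],
                             cfg$n_perm, cfg$seed)
  }
  rows[["all"]] <- .permut_row("All data", ht, dist, rownames(ht$counts),
                               cfg$n_perm, cfg$seed)
  t3 <- do.call(rbind, rows)
  paths["table3"] <- file.path(cfg$out_dir, "table3_permut.tsv")
  utils::write.table(t3, paths["table3"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  logf("stage table3: written")

  amv <- fct <- net <- demog <- NULL
  if (counts_mode) {
    for (f in c("table2_pairwise_fct.tsv", "table4_amova.tsv",
                "table5_demography.tsv")) {
      p <- file.path(cfg$out_dir, f)
      writeLines("NC\trequires sequence data (counts-only input)", p)
      paths[f] <- p
    }
    logf("stage tables 2/4/5, network: NC (counts mode)")
  } else {
    fct <- pairwise_fct(ht, dist, region_of)
    paths["table2"] <- file.path(cfg$out_dir, "table2_pairwise_fct.tsv")
    utils::write.table(
      data.frame(group = rownames(fct), round(fct, 4), check.names = FALSE),
      paths["table2"], sep = "\t", quote = FALSE, row.names = FALSE)
    logf("stage table2: written")

    amv <- amova(ht, dist, region_of, n_perm = cfg$n_perm, seed = cfg$seed)
    t4 <- amv$table
    t4$fixation <- c(sprintf("FCT=%.4f (P=%.4g)", amv$FCT, amv$p[["FCT"]]),
                     sprintf("FSC=%.4f (P=%.4g)", amv$FSC, amv$p[["FSC"]]),
                     sprintf("FST=%.4f (P=%.4g)", amv$FST, amv$p[["FST"]]),
                     "")
    paths["table4"] <- file.path(cfg$out_dir, "table4_amova.tsv")
    utils::write.table(t4, paths["table4"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    logf("stage table4: written")

    net <- median_joining(ht)
    paths["network"] <- file.path(cfg$out_dir, "network.graphml")
    export_network(net, paths["network"], "graphml")
    logf("stage network: %d nodes, %d edges", nrow(net$nodes),
         nrow(net$edges))

    n_all <- sum(ht$counts)
    td <- tryCatch(tajimas_d(ht, dist = sub_dist), error = function(e) NULL)
    obs <- mismatch_observed(ht, dist = sub_dist)
    kbar <- sum(obs * (seq_along(obs) - 1)) / sum(obs)
    fs <- tryCatch(fus_fs(n_all, ncol(ht$counts), kbar),
                   error = function(e) NA_real_)
    demog <- list()
    t5 <- list()
    for (mod in c("demographic", "spatial")) {
      fit <- fit_expansion(obs, model = mod, n_boot = cfg$n_boot,
                           seed = cfg$seed, n_seq = n_all)
      tt <- expansion_time(c(fit$tau, fit$tau_ci), cfg$mu, cfg$k, cfg$g)
      t5[[mod]] <- data.frame(
        model = paste(mod, "expansion"),
        tau = sprintf("%.3f (%.3f-%.3f)", fit$tau, fit$tau_ci[1L],
                      fit$tau_ci[2L]),
        t_kyr = sprintf("%.1f (%.1f-%.1f)", tt[1L], tt[2L], tt[3L]),
        SSD = sprintf("%.4f%s", fit$ssd,
                      if (fit$P_ssd < 0.05) "*" else "^NS^"),
        H_Rag = sprintf("%.4f%s", fit$raggedness,
                        if (fit$P_rag < 0.05) "*" else "^NS^"),
        Fu_FS = if (is.na(fs)) "NC" else sprintf("%.3f", fs),
        Tajima_D = if (is.null(td)) "NC" else sprintf("%.3f", td$D),
        unimodal = length(unique(diff(sign(diff(fit$expected))))) <= 2)
      demog[[mod]] <- fit
    }
    paths["table5"] <- file.path(cfg$out_dir, "table5_demography.tsv")
    utils::write.table(do.call(rbind, t5), paths["table5"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    logf("stage table5: written")
  }
  logf("pipeline complete")
  invisible(list(ht = ht, dist = dist, table3 = t3, amova = amv,
                 pairwise_fct = fct, network = net, demography = demog,
                 paths = paths))
}
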