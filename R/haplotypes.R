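#' @title Haplotype tables
#' @description
#' A `haplotype_table` is the central container: a population x haplotype
#' count matrix, optional representative aligned sequences (one per
#' haplotype), and per-population metadata (region, coordinates). Row sums
#' equal per-population sample sizes.
#' @param counts Integer matrix, populations in rows, haplotypes in columns.
#' @param seqs Optional named character vector of representative aligned
#'   sequences, names matching `colnames(counts)`.
#' @param pops Optional `data.frame` of per-population metadata with a
#'   `population` column matching `rownames(counts)` (extra columns such as
#'   `region`, `lat`, `lon` are carried along).
#' @return A `haplotype_table`.
#' @export
haplotype_table <- function(counts, seqs = NULL, pops = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have population rownames and haplotype colnames")
  }
  if (any(counts < 0L)) stop("negative haplotype count")
  if (any(colSums(counts) == 0L)) {
    stop("haplotype with zero total count: ",
         colnames(counts)[colSums(counts) == 0L][1L])
  }
  if (!is.null(seqs)) {
    if (!setequal(names(seqs), colnames(counts))) {
      stop("sequence names do not match haplotype names")
    }
    seqs <- seqs[colnames(counts)]
  }
  if (!is.null(pops)) {
    stopifnot(is.data.frame(pops), "population" %in% names(pops))
    pops <- pops[match(rownames(counts), pops$population), , drop = FALSE]
    rownames(pops) <- NULL
  }
  structure(list(counts = counts, seqs = seqs, pops = pops),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("haplotype table:", nrow(x$counts), "populations,",
      ncol(x$counts), "haplotypes,", sum(x$counts), "individuals",
      if (is.null(x$seqs)) "(counts only)" else
        paste0("(", nchar(x$seqs[1L]), " bp representatives)"), "\n")
  invisible(x)
}

# collapse non-ACGT ambiguity codes to N (missing)
.normalise_missing <- function(m) {
  m[!(m %in% c("A", "C", "G", "T", "-"))] <- "N"
  m
}

.seq_matrix <- function(seqs) {
  m <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}

# maximal gap runs of one row, encoded "start:length"
.gap_runs <- function(chars) {
  r <- rle(chars == "-")
  if (!any(r$values)) return(character(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  paste0(starts[r$values], ":", r$lengths[r$values])
}

# TRUE if two rows are the same haplotype under the gap mode; N matches any base
.same_hap <- function(a, b, gap_mode) {
  if (gap_mode == "site_deletion") {
    keep <- a != "-" & b != "-"
    a <- a[keep]; b <- b[keep]
  } else {
    # fifth_state and simple_indel: gap pattern must agree exactly
    if (!identical(a == "-", b == "-")) return(FALSE)
  }
  all(a == b | a == "N" | b == "N")
}

#' Collapse aligned sequences into haplotypes
#'
#' Sequences identical under the chosen gap mode are merged into one
#' haplotype; haplotypes are numbered `H1`, `H2`, ... in order of first
#' appearance in the alignment. Missing data (`N` and non-ACGT ambiguity
#' codes) match any base and never found a haplotype of their own;
#' representative sequences are completed where later members resolve an
#' `N`.
#'
#' Gap modes: `simple_indel` (default) treats a contiguous gap run as a
#' single mutational event, so indels distinguish haplotypes;
#' `fifth_state` treats the gap as a fifth character per column;
#' `site_deletion` ignores gapped positions, so haplotypes differing only
#' by indels are merged.
#'
#' @param aln A `cp_alignment`.
#' @param popmap Population map `data.frame` (see [read_population_map()]).
#' @param gap_mode One of `"simple_indel"`, `"fifth_state"`,
#'   `"site_deletion"`.
#' @return A `haplotype_table` with representative sequences.
#' @export
call_haplotypes <- function(aln, popmap,
                            gap_mode = c("simple_indel", "fifth_state",
                                         "site_deletion")) {
  gap_mode <- match.arg(gap_mode)
  stopifnot(inherits(aln, "cp_alignment"))
  popmap <- validate_population_map(popmap)
  missing_ids <- setdiff(aln$ids, popmap$individual)
  if (length(missing_ids) > 0L) {
    stop("alignment id not in population map: ", missing_ids[1L])
  }
  m <- .normalise_missing(.seq_matrix(aln$seqs))
  n <- nrow(m)
  hap_of <- integer(n)
  reps <- list()          # representative rows
  for (i in seq_len(n)) {
    row <- m[i, ]
    hit <- 0L
    for (h in seq_along(reps)) {
      if (.same_hap(reps[[h]], row, gap_mode)) { hit <- h; break }
    }
    if (hit == 0L) {
      reps[[length(reps) + 1L]] <- row
      hit <- length(reps)
    } else {
      unk <- reps[[hit]] == "N" & row != "N"
      if (any(unk)) reps[[hit]][unk] <- row[unk]
    }
    hap_of[i] <- hit
  }
  hap_names <- paste0("H", seq_along(reps))
  pops_order <- unique(popmap$population)
  pop_of <- popmap$population[match(aln$ids, popmap$individual)]
  counts <- table(factor(pop_of, levels = pops_order),
                  factor(hap_names[hap_of], levels = hap_names))
  counts <- matrix(as.integer(counts), nrow = length(pops_order),
                   dimnames = list(pops_order, hap_names))
  counts <- counts[rowSums(counts) > 0L, , drop = FALSE]
  seqs <- vapply(reps, paste, "", collapse = "")
  names(seqs) <- hap_names
  meta_cols <- intersect(c("population", "region", "lat", "lon", "alt"),
                         names(popmap))
  pops <- unique(popmap[popmap$population %in% rownames(counts), meta_cols])
  haplotype_table(counts, seqs = seqs, pops = pops)
}

#' Pairwise mutational distances between haplotypes
#'
#' Counts the number of substitution differences between representative
#' sequences (positions where both carry a determined base that differs;
#' `N` is ignored), plus, under `simple_indel`, one step per maximal gap
#' run present in only one of the two sequences (or with differing
#' boundaries). Under `site_deletion` every column gapped in any haplotype
#' is dropped first, so only substitutions count; under `fifth_state` each
#' gapped column counts as a difference.
#'
#' @param ht A `haplotype_table` with representative sequences.
#' @param gap_mode As in [call_haplotypes()].
#' @return Symmetric integer matrix of class `dist`-like (plain matrix),
#'   zero diagonal.
#' @export
haplotype_distances <- function(ht, gap_mode = c("simple_indel",
                                                 "fifth_state",
                                                 "site_deletion")) {
  gap_mode <- match.arg(gap_mode)
  stopifnot(inherits(ht, "haplotype_table"))
  if (is.null(ht$seqs)) {
    stop("haplotype table has no representative sequences; ",
         "distances are unavailable for counts-only input")
  }
  m <- .normalise_missing(.seq_matrix(ht$seqs))
  if (gap_mode == "site_deletion") {
    m <- m[, colSums(m == "-") == 0L, drop = FALSE]
  }
  nh <- nrow(m)
  d <- matrix(0L, nh, nh, dimnames = list(rownames(m), rownames(m)))
  runs <- if (gap_mode == "simple_indel") {
    apply(m, 1L, .gap_runs, simplify = FALSE)
  }
  for (i in seq_len(nh)) {
    for (j in seq_len(i - 1L)) {
      a <- m[i, ]; b <- m[j, ]
      det <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
      steps <- sum(a[det] != b[det])
      if (gap_mode == "simple_indel") {
        steps <- steps + length(union(runs[[i]], runs[[j]])) -
          length(intersect(runs[[i]], runs[[j]]))
      } else if (gap_mode == "fifth_state") {
        gp <- (a == "-") != (b == "-")
        steps <- steps + sum(gp)
      }
      d[i, j] <- d[j, i] <- as.integer(steps)
    }
  }
  d
}

#' Packaged transcription of the 50-population oak survey (Table 1 fixture)
#'
#' Returns the published population x haplotype count matrix for the
#' range-wide *Quercus variabilis* cpDNA survey: 50 populations across
#' seven regions of East Asia, 26 haplotypes, 528 individuals, together
#' with collection coordinates and the printed per-population haplotype
#' (Hd) and nucleotide (pi x 10^3) diversities for cross-checking.
#'
#' @return A counts-only `haplotype_table`; `$pops` carries `region`,
#'   `region_name`, `lat`, `lon`, `alt_m`, and the printed `hd` and `pi_e3`.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_populations.tsv",
                      package = "cpphylo", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  parsed <- lapply(strsplit(tab$haplotypes, ";", fixed = TRUE), function(p) {
    kv <- strsplit(p, ":", fixed = TRUE)
    stats::setNames(as.integer(vapply(kv, `[`, "", 2L)),
                    vapply(kv, `[`, "", 1L))
  })
  haps <- paste0("H", seq_len(26L))
  counts <- matrix(0L, nrow(tab), length(haps),
                   dimnames = list(tab$population, haps))
  for (i in seq_along(parsed)) counts[i, names(parsed[[i]])] <- parsed[[i]]
  stopifnot(all(rowSums(counts) == tab$n))
  pops <- tab[, c("population", "region", "region_name", "lat", "lon",
                  "alt_m", "n", "hd", "pi_e3")]
  haplotype_table(counts, pops = pops)
}

#' Write / read a haplotype count table (wide TSV, Table 1 layout)
#'
#' Populations in rows, haplotypes in columns, first column `population`.
#'
#' @param ht A `haplotype_table`.
#' @param path Output (input) path.
#' @return `path` invisibly; for the reader, a counts-only
#'   `haplotype_table`.
#' @export
write_haplotype_counts <- function(ht, path) {
  df <- data.frame(population = rownames(ht$counts), ht$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_haplotype_counts
#' @export
read_haplotype_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  counts <- as.matrix(df[, -1L, drop = FALSE])
  rownames(counts) <- df$population
  haplotype_table(counts)
}

#' Write a haplotype distance matrix as TSV
#' @param d Symmetric distance matrix from [haplotype_distances()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  df <- data.frame(haplotype = rownames(d), d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
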