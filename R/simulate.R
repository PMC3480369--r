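#' Simulation configuration
#'
#' The defaults state the world the package's analyses assume: a
#' 528-individual, 50-population survey grouped into 7 regions, a 1670-bp
#' non-recombining chloroplast alignment, and a sudden expansion from
#' `theta0 = 0.1` to `theta1 = 1000` at mutational time `tau = 2.2` before
#' present (the scale of the fitted oak expansion). Structured simulations
#' use an island or stepping-stone model with per-deme `deme_theta` and
#' scaled migrant number `migration_rate` (2Nm); `structured_mutations`
#' confines migration almost entirely within regions so that related
#' haplotypes co-occur geographically (the signal NST > GST detects).
#'
#' @param n_pops Number of populations (demes).
#' @param samples_per_pop Integer vector (recycled) of per-population
#'   sample sizes; the default gives 528 individuals over 50 populations.
#' @param k Alignment length in bp.
#' @param tau,theta0,theta1 Sudden-expansion history (mutational units).
#' @param n_regions Number of regions (contiguous blocks of populations).
#' @param migration_model `"island"` or `"stepping_stone"`.
#' @param migration_rate Scaled migrant number M = 2Nm (> 0).
#' @param deme_theta Within-deme scaled mutation parameter.
#' @param structured_mutations Plant regional phylogeographic structure.
#' @param seed Mandatory random seed.
#' @return A `cp_sim_config` list.
#' @export
cp_sim_config <- function(n_pops = 50L, samples_per_pop = NULL, k = 1670L,
                          tau = 2.2, theta0 = 0.1, theta1 = 1000,
                          n_regions = 7L,
                          migration_model = c("island", "stepping_stone"),
                          migration_rate = 1, deme_theta = 1,
                          structured_mutations = FALSE, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  migration_model <- match.arg(migration_model)
  if (is.null(samples_per_pop)) {
    samples_per_pop <- if (n_pops == 50L) rep(c(11L, 10L), c(28L, 22L))
      else rep(10L, n_pops)
  }
  samples_per_pop <- rep_len(as.integer(samples_per_pop), n_pops)
  stopifnot(n_pops >= 1, all(samples_per_pop >= 1), k >= 1, tau >= 0,
            theta0 >= 0, theta1 >= 0, migration_rate >= 0,
            deme_theta > 0, n_regions >= 1, n_regions <= n_pops)
  region_of <- sort(rep_len(seq_len(n_regions), n_pops))
  structure(list(n_pops = n_pops, samples_per_pop = samples_per_pop,
                 k = k, tau = tau, theta0 = theta0, theta1 = theta1,
                 n_regions = n_regions, region_of = region_of,
                 migration_model = migration_model,
                 migration_rate = migration_rate, deme_theta = deme_theta,
                 structured_mutations = structured_mutations, seed = seed),
            class = "cp_sim_config")
}

# waiting time to the next coalescence among k lineages under the sudden
# expansion history (theta1 until tau, theta0 earlier), from time t
.next_coal_time <- function(t, k, tau, theta0, theta1) {
  pairs <- choose(k, 2)
  th <- if (t < tau) theta1 else theta0
  if (th == 0) return(if (t < tau) t else t) # instant coalescence
  dt <- stats::rexp(1L, pairs / th)
  if (t < tau && t + dt > tau) {
    if (theta0 == 0) return(tau)
    return(tau + stats::rexp(1L, pairs / theta0))
  }
  t + dt
}

# Run a panmictic Kingman coalescent with the expansion history. Maintains
# per-clade leaf vectors and leaf-to-clade-root mutation counts; optionally
# records mutation events (members + count) for sequence construction.
# Returns the pairwise-difference histogram, mutation records, tree length.
.coalesce_expansion <- function(n, tau, theta0, theta1,
                                record_mutations = FALSE) {
  members <- lapply(seq_len(n), identity)
  muts <- lapply(seq_len(n), function(i) 0L)
  created <- numeric(n)
  hist_max <- 0L
  hist <- numeric(256L)
  events <- list()
  tree_len <- 0
  t <- 0
  while (length(members) > 1L) {
    k <- length(members)
    t <- .next_coal_time(t, k, tau, theta0, theta1)
    pick <- sample.int(k, 2L)
    i <- pick[1L]; j <- pick[2L]
    for (idx in c(i, j)) {
      len <- t - created[idx]
      tree_len <- tree_len + len
      m <- if (len > 0) stats::rpois(1L, len / 2) else 0L
      if (m > 0L) {
        muts[[idx]] <- muts[[idx]] + m
        if (record_mutations) {
          events[[length(events) + 1L]] <- list(members = members[[idx]],
                                                n_mut = m)
        }
      }
    }
    cross <- outer(muts[[i]], muts[[j]], "+")
    mx <- max(cross)
    if (mx + 1L > length(hist)) hist <- c(hist, numeric(mx + 1L))
    tb <- tabulate(cross + 1L, nbins = length(hist))
    hist <- hist + tb
    hist_max <- max(hist_max, mx)
    members[[i]] <- c(members[[i]], members[[j]])
    muts[[i]] <- c(muts[[i]], muts[[j]])
    created[i] <- t
    members[[j]] <- NULL
    muts <- muts[-j]
    created <- created[-j]
  }
  list(hist = hist[1:(hist_max + 1L)], events = events,
       tree_length = tree_len,
       leaf_order = members[[1L]], leaf_muts = muts[[1L]])
}

#' Pairwise mismatch histogram simulated under sudden expansion
#'
#' Low-level engine (used by the parametric bootstrap of
#' [fit_expansion()]): simulates one coalescent genealogy of `n` sequences
#' under the sudden-expansion history and returns the histogram of all
#' pairwise differences. Uses the current RNG state.
#'
#' @param n Number of sequences.
#' @param tau,theta0,theta1 Expansion history.
#' @return Integer vector of pair counts, names `0..max`.
#' @export
sim_mismatch_expansion <- function(n, tau, theta0, theta1) {
  r <- .coalesce_expansion(n, tau, theta0, theta1)
  stats::setNames(as.integer(r$hist), seq_along(r$hist) - 1L)
}

#' Pairwise mismatch histogram under the spatial (infinite-island) model
#'
#' All `n` sequences are sampled in one deme of size `theta`; looking back,
#' same-deme pairs coalesce at rate `1/theta` per mutational time unit and
#' each lineage emigrates to a fresh deme at rate `M/theta`; at time `tau`
#' all surviving lineages enter the ancestral deme (size `theta`).
#'
#' @inheritParams sim_mismatch_expansion
#' @param theta Deme scaled mutation parameter.
#' @param M Scaled migrant number 2Nm.
#' @export
sim_mismatch_spatial <- function(n, tau, theta, M) {
  deme <- rep(1L, n)
  members <- lapply(seq_len(n), identity)
  muts <- lapply(seq_len(n), function(i) 0L)
  created <- numeric(n)
  hist <- numeric(256L); hist_max <- 0L
  next_deme <- 2L
  t <- 0
  merge_pair <- function(i, j, t) {
    for (idx in c(i, j)) {
      len <- t - created[idx]
      m <- if (len > 0) stats::rpois(1L, len / 2) else 0L
      muts[[idx]] <<- muts[[idx]] + m
    }
    cross <- outer(muts[[i]], muts[[j]], "+")
    mx <- max(cross)
    if (mx + 1L > length(hist)) hist <<- c(hist, numeric(mx + 1L))
    hist <<- hist + tabulate(cross + 1L, nbins = length(hist))
    hist_max <<- max(hist_max, mx)
    members[[i]] <<- c(members[[i]], members[[j]])
    muts[[i]] <<- c(muts[[i]], muts[[j]])
    created[i] <<- t
    members[[j]] <<- NULL
    muts <<- muts[-j]
    created <<- created[-j]
    deme <<- deme[-j]
  }
  # Infinite islands: a migrant always enters a fresh deme, so a lineage
  # alone in its deme is inert until the expansion time tau. Only demes
  # holding >= 2 lineages generate events.
  while (length(members) > 1L && t < tau) {
    tab <- table(deme)
    multi <- as.integer(names(tab)[tab >= 2L])
    if (length(multi) == 0L) { t <- tau; break }
    active <- deme %in% multi
    pairs_per_deme <- choose(as.numeric(tab[as.character(multi)]), 2)
    coal_rate <- sum(pairs_per_deme) / theta
    mig_rate <- sum(active) * M / theta
    total <- coal_rate + mig_rate
    dt <- stats::rexp(1L, total)
    if (t + dt > tau) { t <- tau; break }
    t <- t + dt
    if (stats::runif(1L) < coal_rate / total) {
      d <- if (length(multi) == 1L) multi else
        sample(multi, 1L, prob = pairs_per_deme)
      idx <- which(deme == d)
      pick <- sample(idx, 2L)
      merge_pair(pick[1L], pick[2L], t)
    } else {
      cand <- which(active)
      l <- if (length(cand) == 1L) cand else sample(cand, 1L)
      deme[l] <- next_deme
      next_deme <- next_deme + 1L
    }
  }
  # ancestral deme: plain Kingman at theta
  while (length(members) > 1L) {
    k <- length(members)
    t <- t + stats::rexp(1L, choose(k, 2) / theta)
    pick <- sample.int(k, 2L)
    merge_pair(pick[1L], pick[2L], t)
  }
  stats::setNames(as.integer(hist[1:(hist_max + 1L)]), 0:hist_max)
}

# build an aligned character matrix from mutation events under infinite
# sites; returns uppercase sequence strings
.sequences_from_events <- function(n, k, events, gap_events = NULL) {
  total_mut <- sum(vapply(events, function(e) e$n_mut, 0L))
  if (total_mut > k) {
    stop("infinite-sites violation: ", total_mut, " mutations exceed ", k,
         " columns; increase k or reduce theta/tau")
  }
  bases <- c("A", "C", "G", "T")
  root <- sample(bases, k, replace = TRUE)
  m <- matrix(rep(root, each = n), nrow = n)
  cols <- sample.int(k, total_mut)
  ptr <- 0L
  for (e in events) {
    for (r in seq_len(e$n_mut)) {
      ptr <- ptr + 1L
      col <- cols[ptr]
      m[e$members, col] <- sample(setdiff(bases, root[col]), 1L)
    }
  }
  if (!is.null(gap_events)) {
    for (g in gap_events) m[g$members, g$cols] <- "-"
  }
  apply(m, 1L, paste, collapse = "")
}

.synthetic_popmap <- function(n_pops, samples_per_pop, region_of) {
  pop_names <- sprintf("P%02d", seq_len(n_pops))
  data.frame(
    individual = sprintf("ind%04d", seq_len(sum(samples_per_pop))),
    population = rep(pop_names, samples_per_pop),
    region = rep(region_of, samples_per_pop),
    lat = rep(22 + 2.5 * region_of + 0.4 * seq_len(n_pops) %% 5,
              samples_per_pop),
    lon = rep(100 + 4 * region_of + 0.7 * seq_len(n_pops) %% 7,
              samples_per_pop),
    stringsAsFactors = FALSE)
}

#' Simulate an expansion-history alignment
#'
#' Panmictic coalescent under the sudden-expansion history of `cfg`, with
#' infinite-sites mutations mapped onto a `k`-bp alignment. Population
#' labels partition the (panmictic) sample so that every downstream reader
#' works unchanged. The truth record carries the genealogy summaries the
#' tests score against: tree length, number of mutations, the exact
#' pairwise mismatch histogram, and the planted haplotype label of every
#' individual.
#'
#' @param cfg A [cp_sim_config()].
#' @param sequences Build the alignment (set `FALSE` for mismatch-only
#'   studies; much faster).
#' @return List `alignment` (`cp_alignment` or `NULL`), `popmap`
#'   (`data.frame`), `truth` (list).
#' @export
simulate_expansion_coalescent <- function(cfg, sequences = TRUE) {
  stopifnot(inherits(cfg, "cp_sim_config"))
  set.seed(cfg$seed)
  n <- sum(cfg$samples_per_pop)
  r <- .coalesce_expansion(n, cfg$tau, cfg$theta0, cfg$theta1,
                           record_mutations = sequences)
  hist <- stats::setNames(as.integer(r$hist), seq_along(r$hist) - 1L)
  truth <- list(tau = cfg$tau, theta0 = cfg$theta0, theta1 = cfg$theta1,
                tree_length = r$tree_length,
                n_mutations = sum(vapply(r$events, function(e) e$n_mut,
                                         0L)),
                mismatch = hist,
                mean_pairwise = sum(hist * (seq_along(hist) - 1)) /
                  sum(hist))
  popmap <- .synthetic_popmap(cfg$n_pops, cfg$samples_per_pop,
                              cfg$region_of)
  aln <- NULL
  if (sequences) {
    seqs <- .sequences_from_events(n, cfg$k, r$events)
    names(seqs) <- popmap$individual
    aln <- cp_alignment(seqs)
    key <- factor(seqs, levels = unique(seqs))
    truth$hap_labels <- stats::setNames(as.integer(key), popmap$individual)
    truth$n_haplotypes <- nlevels(key)
  }
  list(alignment = aln, popmap = popmap, truth = truth)
}

#' Simulate a structured (island / stepping-stone) alignment
#'
#' Equilibrium structured coalescent over `n_pops` demes of size
#' `deme_theta` exchanging `migration_rate` migrants (island: uniform
#' target; stepping stone: ring neighbours). With `structured_mutations`
#' 99% of migration stays within the deme's region, planting the
#' phylogeographic signal (related haplotypes co-occurring) that NST > GST
#' detects.
#'
#' @inheritParams simulate_expansion_coalescent
#' @return As [simulate_expansion_coalescent()].
#' @export
simulate_structured <- function(cfg, sequences = TRUE) {
  stopifnot(inherits(cfg, "cp_sim_config"))
  if (cfg$migration_rate <= 0 && cfg$n_pops > 1L) {
    stop("migration_rate must be > 0: isolated demes never coalesce")
  }
  set.seed(cfg$seed)
  n <- sum(cfg$samples_per_pop)
  deme <- rep(seq_len(cfg$n_pops), cfg$samples_per_pop)
  members <- lapply(seq_len(n), identity)
  muts <- lapply(seq_len(n), function(i) 0L)
  created <- numeric(n)
  events <- list()
  tree_len <- 0
  theta <- cfg$deme_theta
  M <- cfg$migration_rate
  t <- 0
  while (length(members) > 1L) {
    k <- length(members)
    tab <- tabulate(deme, nbins = cfg$n_pops)
    pairs_per_deme <- choose(tab, 2)
    coal_rate <- sum(pairs_per_deme) / theta
    mig_rate <- k * M / theta
    t <- t + stats::rexp(1L, coal_rate + mig_rate)
    if (stats::runif(1L) < coal_rate / (coal_rate + mig_rate)) {
      d <- sample.int(cfg$n_pops, 1L, prob = pairs_per_deme)
      idx <- which(deme == d)
      pick <- sample(idx, 2L)
      i <- pick[1L]; j <- pick[2L]
      for (idx2 in c(i, j)) {
        len <- t - created[idx2]
        tree_len <- tree_len + len
        m <- if (len > 0) stats::rpois(1L, len / 2) else 0L
        if (m > 0L) {
          muts[[idx2]] <- muts[[idx2]] + m
          if (sequences) {
            events[[length(events) + 1L]] <-
              list(members = members[[idx2]], n_mut = m)
          }
        }
      }
      members[[i]] <- c(members[[i]], members[[j]])
      muts[[i]] <- c(muts[[i]], muts[[j]])
      created[i] <- t
      members[[j]] <- NULL
      muts <- muts[-j]
      created <- created[-j]
      deme <- deme[-j]
    } else {
      l <- sample.int(k, 1L)
      deme[l] <- .migration_target(deme[l], cfg)
    }
  }
  popmap <- .synthetic_popmap(cfg$n_pops, cfg$samples_per_pop,
                              cfg$region_of)
  truth <- list(model = cfg$migration_model, migration_rate = M,
                deme_theta = theta, tree_length = tree_len,
                structured_mutations = cfg$structured_mutations)
  aln <- NULL
  if (sequences) {
    seqs <- .sequences_from_events(n, cfg$k, events)
    names(seqs) <- popmap$individual
    aln <- cp_alignment(seqs)
    key <- factor(seqs, levels = unique(seqs))
    truth$hap_labels <- stats::setNames(as.integer(key), popmap$individual)
    truth$n_haplotypes <- nlevels(key)
  }
  list(alignment = aln, popmap = popmap, truth = truth)
}

.migration_target <- function(from, cfg) {
  if (cfg$n_pops == 1L) return(from)
  if (cfg$migration_model == "stepping_stone") {
    step <- if (stats::runif(1L) < 0.5) -1L else 1L
    return(((from - 1L + step) %% cfg$n_pops) + 1L)
  }
  if (cfg$structured_mutations) {
    same_region <- setdiff(which(cfg$region_of == cfg$region_of[from]),
                           from)
    if (length(same_region) > 0L && stats::runif(1L) < 0.99) {
      return(if (length(same_region) == 1L) same_region else
        sample(same_region, 1L))
    }
  }
  tgt <- sample.int(cfg$n_pops - 1L, 1L)
  if (tgt >= from) tgt + 1L else tgt
}

#' Plant an exact set of haplotypes on a coalescent topology
#'
#' Builds `n_hap` pairwise-distinct haplotype sequences -- `n_sub`
#' substitution mutations plus gap-run (indel) events on a random
#' coalescent topology, with additional indels inserted until all tips are
#' distinct under `simple_indel` collapsing (so some haplotypes differ by
#' indels only, reproducing the Hd > 0, pi = 0 pattern) -- and expands
#' them into individuals. By default the planted counts are the packaged
#' 50-population survey matrix (26 haplotypes, 528 individuals, 23
#' variable substitution sites in 1670 bp).
#'
#' @param n_hap Number of haplotypes to plant.
#' @param n_sub Number of substitution (variable) sites.
#' @param n_indel Number of baseline indel events.
#' @param k Alignment length.
#' @param counts Population x haplotype count matrix with `n_hap` columns;
#'   default [load_table1_fixture()] counts.
#' @param popmap_meta Optional per-population `data.frame` with
#'   `population`, `region`, `lat`, `lon`.
#' @param seed Mandatory seed.
#' @return List `alignment`, `popmap`, `truth` (with `hap_of` giving each
#'   individual's planted haplotype).
#' @export
simulate_planted_haplotypes <- function(n_hap = 26L, n_sub = 23L,
                                        n_indel = 2L, k = 1670L,
                                        counts = NULL, popmap_meta = NULL,
                                        seed) {
  if (missing(seed)) stop("a seed is mandatory")
  set.seed(seed)
  if (is.null(counts)) {
    fx <- load_table1_fixture()
    counts <- fx$counts
    if (is.null(popmap_meta)) {
      popmap_meta <- fx$pops[, c("population", "region", "lat", "lon")]
    }
  }
  stopifnot(ncol(counts) == n_hap)
  # random coalescent topology: edges as descendant tip sets
  clades <- lapply(seq_len(n_hap), identity)
  edges <- list()
  while (length(clades) > 1L) {
    pick <- sample.int(length(clades), 2L)
    edges <- c(edges, clades[pick])
    clades[[pick[1L]]] <- c(clades[[pick[1L]]], clades[[pick[2L]]])
    clades[[pick[2L]]] <- NULL
  }
  informative <- which(vapply(edges, length, 0L) < n_hap)
  bases <- c("A", "C", "G", "T")
  root <- sample(bases, k, replace = TRUE)
  m <- matrix(rep(root, each = n_hap), nrow = n_hap)
  reserve <- min(200L, max(5L * (n_indel + n_hap), k %/% 4L))
  sub_cols <- sample.int(k - reserve, n_sub) # tail reserved for indels
  for (s in seq_len(n_sub)) {
    e <- edges[[informative[1L + (s - 1L) %% length(informative)]]]
    m[e, sub_cols[s]] <- sample(setdiff(bases, root[sub_cols[s]]), 1L)
  }
  indel_start <- k - reserve + 1L
  place_indel <- function(tips) {
    len <- sample(1:3, 1L)
    if (indel_start + len > k) stop("ran out of columns for indel events")
    m[tips, indel_start:(indel_start + len - 1L)] <<- "-"
    indel_start <<- indel_start + len + 1L # spacer keeps runs distinct
  }
  for (g in seq_len(n_indel)) {
    place_indel(edges[[sample(informative, 1L)]])
  }
  repeat { # split residual duplicates with private indels
    key <- apply(m, 1L, paste, collapse = "")
    dup <- which(duplicated(key))
    if (length(dup) == 0L) break
    place_indel(dup[1L])
  }
  seqs <- apply(m, 1L, paste, collapse = "")
  names(seqs) <- paste0("H", seq_len(n_hap))
  # expand to individuals following the count matrix
  hap_of <- unlist(lapply(seq_len(nrow(counts)), function(p)
    rep(seq_len(n_hap), counts[p, ])), use.names = FALSE)
  pop_of <- rep(rownames(counts), rowSums(counts))
  ids <- sprintf("ind%04d", seq_along(hap_of))
  aln <- cp_alignment(stats::setNames(seqs[hap_of], ids))
  meta <- popmap_meta[match(pop_of, popmap_meta$population), ]
  popmap <- data.frame(individual = ids, population = pop_of,
                       region = meta$region, lat = meta$lat,
                       lon = meta$lon, stringsAsFactors = FALSE)
  truth <- list(n_haplotypes = n_hap, n_sub_sites = n_sub,
                hap_of = stats::setNames(paste0("H", hap_of), ids),
                representative_seqs = seqs)
  list(alignment = aln, popmap = popmap, truth = truth)
}

#' Write a simulation to disk in the package's exchange formats
#'
#' FASTA alignment, TSV population map, JSON truth record.
#'
#' @param sim Result of a `simulate_*` function.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
save_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(sim$alignment)) {
    write_fasta_alignment(sim$alignment, file.path(dir, "alignment.fasta"))
  }
  utils::write.table(sim$popmap, file.path(dir, "popmap.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
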