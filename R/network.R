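#' @title Haplotype networks
#' @description
#' A `haplotype_network` holds `nodes` (`id`, `type` in
#' `{"sampled", "median_vector"}`, `freq`), `edges` (`from`, `to`, `steps`)
#' and the relaxation parameter `epsilon`.
#' @keywords internal
#' @name haplotype_network
NULL

new_haplotype_network <- function(nodes, edges, epsilon) {
  structure(list(nodes = nodes, edges = edges, epsilon = epsilon),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("haplotype network:", nrow(x$nodes), "nodes (",
      sum(x$nodes$type == "median_vector"), "median vectors ),",
      nrow(x$edges), "edges, epsilon =", x$epsilon, "\n")
  invisible(x)
}

# minimax (single-linkage) connection threshold between all pairs:
# t[i,j] = min over paths of the maximum edge weight
.minimax <- function(D) {
  t <- D
  for (k in seq_len(nrow(D))) {
    via <- outer(t[, k], t[k, ], pmax)
    t <- pmin(t, via)
  }
  t
}

# total weight of a minimum spanning tree (Prim)
.mst_weight <- function(D) {
  m <- nrow(D)
  if (m < 2L) return(0)
  inset <- c(TRUE, rep(FALSE, m - 1L))
  best <- D[1L, ]
  w <- 0
  for (step in seq_len(m - 1L)) {
    cand <- which(!inset)
    v <- cand[which.min(best[cand])]
    w <- w + best[v]
    inset[v] <- TRUE
    best <- pmin(best, D[v, ])
  }
  w
}

#' Minimum spanning network of haplotypes
#'
#' Contains every edge that belongs to some minimum spanning tree of the
#' distance matrix, plus (for `epsilon > 0`) all feasible links within
#' `epsilon` of the connection threshold: edge `(i, j)` is retained iff
#' `d_ij <= t_ij + epsilon` where `t_ij` is the minimax path weight. Ties
#' are retained, which is what distinguishes the network from a single
#' tree.
#'
#' @param dist Symmetric haplotype distance matrix.
#' @param epsilon Non-negative relaxation (default 0).
#' @param freq Optional named node frequencies (plotting only).
#' @param type Optional named node types (defaults to `"sampled"`).
#' @return A `haplotype_network`.
#' @export
build_msn <- function(dist, epsilon = 0, freq = NULL, type = NULL) {
  stopifnot(epsilon >= 0)
  ids <- rownames(dist)
  if (is.null(ids)) ids <- paste0("H", seq_len(nrow(dist)))
  nodes <- data.frame(id = ids,
                      type = if (is.null(type)) "sampled" else
                        unname(type[ids]),
                      freq = if (is.null(freq)) NA_real_ else
                        unname(freq[ids]),
                      stringsAsFactors = FALSE)
  m <- nrow(dist)
  if (m == 1L) {
    return(new_haplotype_network(nodes, data.frame(
      from = character(0), to = character(0), steps = numeric(0)), epsilon))
  }
  t <- .minimax(dist)
  keep <- which(upper.tri(dist) & dist <= t + epsilon, arr.ind = TRUE)
  edges <- data.frame(from = ids[keep[, 1L]], to = ids[keep[, 2L]],
                      steps = dist[keep], stringsAsFactors = FALSE)
  edges <- edges[order(edges$steps, edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  new_haplotype_network(nodes, edges, epsilon)
}

# recode representative sequences into 0/1 indicator characters over the
# variable columns; gaps are a state, N is imputed to the column majority
.recode_binary <- function(seqs) {
  m <- .normalise_missing(.seq_matrix(seqs))
  for (j in seq_len(ncol(m))) {
    miss <- m[, j] == "N"
    if (any(miss)) {
      tab <- table(m[!miss, j])
      m[miss, j] <- if (length(tab)) names(tab)[which.max(tab)] else "A"
    }
  }
  cols <- list()
  for (j in seq_len(ncol(m))) {
    st <- sort(unique(m[, j]))
    if (length(st) < 2L) next
    if (length(st) == 2L) {
      cols[[length(cols) + 1L]] <- as.integer(m[, j] == st[2L])
    } else {
      for (s in st) cols[[length(cols) + 1L]] <- as.integer(m[, j] == s)
    }
  }
  X <- if (length(cols)) do.call(cbind, cols) else
    matrix(0L, nrow(m), 0L)
  rownames(X) <- rownames(m)
  X
}

.hamming <- function(X) {
  G <- tcrossprod(X)
  s <- diag(G)
  outer(s, s, "+") - 2 * G
}

#' Median-joining haplotype network
#'
#' Starting from the minimum spanning network of the sampled haplotypes
#' (recoded to binary characters over the variable alignment columns),
#' consensus (majority) vectors of node triplets are inserted as median
#' vectors whenever they reduce the total network cost (minimum
#' spanning-tree weight); obsolete median vectors are pruned until every
#' retained one has degree >= 3. Multistate columns are reduced to binary
#' indicators per state -- a simplification of the quasi-median rule,
#' adequate for data where each column carries at most one mutation.
#'
#' @param ht A `haplotype_table` with representative sequences.
#' @param epsilon Relaxation parameter passed to [build_msn()].
#' @param max_iter Cap on median-insertion rounds.
#' @return A `haplotype_network`; the recoded node vectors are attached as
#'   attribute `"vectors"`. If `max_iter` is hit a warning is raised and
#'   attribute `"converged"` is `FALSE`.
#' @export
median_joining <- function(ht, epsilon = 0, max_iter = 50L) {
  stopifnot(inherits(ht, "haplotype_table"))
  if (is.null(ht$seqs)) stop("median joining needs representative sequences")
  X <- .recode_binary(ht$seqs)
  n_sampled <- nrow(X)
  freq <- colSums(ht$counts)[rownames(X)]
  converged <- TRUE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) {
      warning("median joining did not converge in ", max_iter,
              " iterations; returning partial network")
      converged <- FALSE
      break
    }
    D <- .hamming(X)
    w0 <- .mst_weight(D)
    m <- nrow(X)
    if (m < 3L) break
    # majority medians of all triples, deduplicated
    trip <- utils::combn(m, 3L)
    med <- t(apply(trip, 2L, function(tr)
      as.integer(colSums(X[tr, , drop = FALSE]) >= 2L)))
    med <- unique(med)
    keys_x <- apply(X, 1L, paste, collapse = "")
    med <- med[!(apply(med, 1L, paste, collapse = "") %in% keys_x), ,
               drop = FALSE]
    if (nrow(med) == 0L) break
    delta <- vapply(seq_len(nrow(med)), function(i) {
      dv <- colSums(abs(t(X) - med[i, ]))
      .mst_weight(rbind(cbind(D, dv), c(dv, 0))) - w0
    }, 0)
    best <- which.min(delta)
    if (delta[best] >= 0) break
    X <- rbind(X, med[best, , drop = FALSE])
    rownames(X)[nrow(X)] <- paste0(".mv", nrow(X))
  }
  # prune obsolete median vectors
  repeat {
    D <- .hamming(X)
    w0 <- .mst_weight(D)
    med_idx <- which(seq_len(nrow(X)) > n_sampled)
    if (length(med_idx) == 0L) break
    net <- build_msn(D * 1.0, epsilon)
    deg <- table(factor(c(net$edges$from, net$edges$to),
                        levels = rownames(X)))
    drop_one <- NA_integer_
    for (v in med_idx) {
      if (deg[[rownames(X)[v]]] < 3L ||
          .mst_weight(D[-v, -v, drop = FALSE]) <= w0) {
        drop_one <- v
        break
      }
    }
    if (is.na(drop_one)) break
    X <- X[-drop_one, , drop = FALSE]
  }
  med_n <- nrow(X) - n_sampled
  ids <- rownames(X)
  if (med_n > 0L) {
    ids[(n_sampled + 1L):nrow(X)] <- paste0("mv", seq_len(med_n))
    rownames(X) <- ids
  }
  type <- stats::setNames(rep(c("sampled", "median_vector"),
                              c(n_sampled, med_n)), ids)
  fr <- stats::setNames(c(freq, rep(0, med_n)), ids)
  D <- .hamming(X)
  storage.mode(D) <- "double"
  net <- build_msn(D, epsilon, freq = fr, type = type)
  attr(net, "vectors") <- X
  attr(net, "converged") <- converged
  net
}

#' Export / import a haplotype network
#'
#' `graphml` and `dot` are written through igraph; `tsv_edgelist` is a
#' plain-text format with a commented node block followed by the edge
#' list, losslessly re-read by [read_network()] (as is `graphml`).
#'
#' @param net A `haplotype_network`.
#' @param path Output file.
#' @param format One of `"graphml"`, `"dot"`, `"tsv_edgelist"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path,
                           format = c("graphml", "dot", "tsv_edgelist")) {
  format <- match.arg(format)
  if (format == "tsv_edgelist") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# epsilon\t%g", net$epsilon), con)
    writeLines(sprintf("#node\t%s\t%s\t%g", net$nodes$id, net$nodes$type,
                       net$nodes$freq), con)
    writeLines("from\tto\tsteps", con)
    if (nrow(net$edges) > 0L) {
      writeLines(sprintf("%s\t%s\t%g", net$edges$from, net$edges$to,
                         net$edges$steps), con)
    }
    return(invisible(path))
  }
  g <- igraph::graph_from_data_frame(
    cbind(net$edges[, c("from", "to")], weight = net$edges$steps),
    directed = FALSE, vertices = net$nodes)
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

#' @rdname export_network
#' @param epsilon Relaxation recorded in the returned object (graphml does
#'   not carry it).
#' @export
read_network <- function(path, format = c("graphml", "tsv_edgelist"),
                         epsilon = 0) {
  format <- match.arg(format)
  if (format == "tsv_edgelist") {
    lines <- readLines(path)
    eps <- as.numeric(strsplit(lines[1L], "\t")[[1L]][2L])
    nl <- grep("^#node\t", lines, value = TRUE)
    parts <- do.call(rbind, strsplit(sub("^#node\t", "", nl), "\t"))
    freq <- suppressWarnings(as.numeric(parts[, 3L])) # "NA" for unset
    nodes <- data.frame(id = parts[, 1L], type = parts[, 2L],
                        freq = freq, stringsAsFactors = FALSE)
    body <- lines[(grep("^from\tto\tsteps$", lines)[1L]):length(lines)]
    edges <- utils::read.delim(text = paste(body, collapse = "\n"),
                               stringsAsFactors = FALSE)
    if (nrow(edges) == 0L) {
      edges <- data.frame(from = character(0), to = character(0),
                          steps = numeric(0))
    }
    return(new_haplotype_network(nodes, edges, eps))
  }
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(id = igraph::V(g)$name, type = igraph::V(g)$type,
                      freq = igraph::V(g)$freq, stringsAsFactors = FALSE)
  el <- igraph::as_data_frame(g, what = "edges")
  edges <- data.frame(from = el$from, to = el$to, steps = el$weight,
                      stringsAsFactors = FALSE)
  new_haplotype_network(nodes, edges, epsilon)
}
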