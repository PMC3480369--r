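#' Tajima's D
#'
#' Compares the mean number of pairwise substitution differences with the
#' number of segregating substitution sites scaled by `a1 = sum(1/i)`:
#' `D = (kbar - S/a1) / sqrt(e1*S + e2*S*(S-1))` with Tajima's (1989)
#' constants. Indel-only variation is excluded throughout.
#'
#' @param ht A `haplotype_table` with representative sequences.
#' @param populations Optional subset of populations (pooled).
#' @param dist Optional substitutions-only distance matrix (computed with
#'   `gap_mode = "site_deletion"` when missing).
#' @return List with `D`, `S`, `n`, `kbar`.
#' @export
tajimas_d <- function(ht, populations = NULL, dist = NULL) {
  stopifnot(inherits(ht, "haplotype_table"))
  if (is.null(ht$seqs)) stop("Tajima's D needs representative sequences")
  counts <- ht$counts
  if (!is.null(populations)) counts <- counts[populations, , drop = FALSE]
  cnt <- colSums(counts)
  cnt <- cnt[cnt > 0]
  n <- sum(cnt)
  if (n < 4) stop("Tajima's D needs n >= 4 sequences")
  if (is.null(dist)) dist <- haplotype_distances(ht, "site_deletion")
  D <- dist[names(cnt), names(cnt), drop = FALSE]
  m <- .normalise_missing(.seq_matrix(ht$seqs[names(cnt)]))
  S <- sum(apply(m, 2L, function(col) {
    length(unique(col[col %in% c("A", "C", "G", "T")])) > 1L
  }))
  if (S < 1) stop("no segregating substitution sites: D is undefined")
  kbar <- (drop(cnt %*% D %*% cnt) / 2) / choose(n, 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(D = (kbar - S / a1) / sqrt(e1 * S + e2 * S * (S - 1)),
       S = S, n = n, kbar = kbar)
}

.logaddexp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(a) & is.infinite(b) & a < 0 & b < 0] <- -Inf
  out
}

# log unsigned Stirling numbers of the first kind |s(n, 1..n)|, cached by n
.stirling_env <- new.env(parent = emptyenv())
.log_stirling_row <- function(n) {
  key <- as.character(n)
  if (!is.null(.stirling_env[[key]])) return(.stirling_env[[key]])
  ls <- 0 # row n = 1: |s(1,1)| = 1
  for (m in seq_len(n - 1L)) { # build row m+1 from row m
    ls <- .logaddexp(c(-Inf, ls), log(m) + c(ls, -Inf))
  }
  .stirling_env[[key]] <- ls
  ls
}

#' Fu's FS neutrality statistic
#'
#' `S' = Pr(K >= k_obs | theta)` under the Ewens sampling formula with
#' `theta` set to the observed mean number of pairwise differences, using
#' log-space unsigned Stirling numbers of the first kind (stable up to
#' n in the hundreds); `FS = ln(S'/(1 - S'))`. Large negative values signal
#' an excess of recent, low-frequency haplotypes, the signature of
#' demographic expansion.
#'
#' @param n Number of sequences.
#' @param k_obs Number of distinct haplotypes observed.
#' @param theta_pi Mean pairwise differences (> 0).
#' @return The FS statistic (scalar).
#' @export
fus_fs <- function(n, k_obs, theta_pi) {
  if (theta_pi <= 0) stop("theta_pi must be positive")
  stopifnot(n >= 2, k_obs >= 1, k_obs <= n)
  ls <- .log_stirling_row(n)
  k <- seq_len(n)
  logterm <- ls + k * log(theta_pi)
  # normalise in log space; the terms sum to the rising factorial exactly
  mx <- max(logterm)
  logZ <- mx + log(sum(exp(logterm - mx)))
  logp <- logterm - logZ
  sel <- logp[k >= k_obs]
  ms <- max(sel)
  logSp <- ms + log(sum(exp(sel - ms)))
  Sp <- exp(logSp)
  if (k_obs == 1L || Sp >= 1 - 1e-12) {
    stop("S' is numerically degenerate at 1 (k_obs = ", k_obs,
         "); FS is unbounded -- expansion cannot be assessed from this ",
         "configuration")
  }
  if (!is.finite(logSp)) {
    stop("S' underflowed to 0 (k_obs = ", k_obs, ", n = ", n,
         "); FS is unbounded below")
  }
  # FS = log(S'/(1-S')), stable for very small S' (strong expansion)
  logSp - log1p(-Sp)
}

#' Observed mismatch distribution
#'
#' Histogram of all pairwise substitution differences among the pooled
#' individuals of the selected populations.
#'
#' @inheritParams tajimas_d
#' @return Integer vector of pair counts, names `0..max`.
#' @export
mismatch_observed <- function(ht, populations = NULL, dist = NULL) {
  counts <- ht$counts
  if (!is.null(populations)) counts <- counts[populations, , drop = FALSE]
  cnt <- colSums(counts)
  cnt <- cnt[cnt > 0]
  if (sum(cnt) < 2) stop("mismatch distribution needs n >= 2")
  if (is.null(dist)) dist <- haplotype_distances(ht, "site_deletion")
  D <- dist[names(cnt), names(cnt), drop = FALSE]
  dmax <- max(D)
  h <- numeric(dmax + 1L)
  h[1L] <- sum(choose(cnt, 2)) # within-haplotype pairs at distance 0
  for (i in seq_along(cnt)) for (j in seq_len(i - 1L)) {
    h[D[i, j] + 1L] <- h[D[i, j] + 1L] + cnt[i] * cnt[j]
  }
  stats::setNames(as.integer(h), 0:dmax)
}

#' Harpending's raggedness index
#'
#' `sum over i of (x_i - x_{i-1})^2` of the relative mismatch frequencies,
#' zero class included; small under the smooth unimodal curves produced by
#' expansion.
#'
#' @param observed Mismatch count (or frequency) vector over classes
#'   `0..d`.
#' @return Raggedness index.
#' @export
raggedness <- function(observed) {
  x <- observed / sum(observed)
  sum(diff(x)^2)
}

.geom_F <- function(i, theta) {
  # equilibrium mismatch theta^i / (theta+1)^(i+1), safe at theta = 0
  if (theta == 0) return(as.numeric(i == 0))
  exp(i * log(theta) - (i + 1) * log(theta + 1))
}

.tau_pois <- function(i, tau) {
  # tau^i / i! without the exponential, safe at tau = 0
  if (tau == 0) return(as.numeric(i == 0))
  exp(i * log(tau) - lgamma(i + 1))
}

#' Expected mismatch under sudden demographic expansion
#'
#' Closed-form expectation of the pairwise-difference distribution when a
#' population of scaled size `theta0` grew instantaneously to `theta1` at
#' mutational time `tau` before present: pairs coalescing since the
#' expansion contribute a truncated equilibrium term at `theta1`, earlier
#' pairs a Poisson(`tau`)-shifted equilibrium at `theta0`. Reduces to the
#' geometric `theta^i/(theta+1)^(i+1)` at `tau = 0` with
#' `theta0 = theta1`.
#'
#' @param tau Expansion time in mutational units (>= 0).
#' @param theta0,theta1 Pre-/post-expansion scaled mutation parameters.
#' @param n_classes Number of difference classes (0 to `n_classes - 1`).
#' @return Probability vector of length `n_classes` (sums to 1 as
#'   `n_classes` grows).
#' @export
expected_mismatch_demographic <- function(tau, theta0, theta1,
                                          n_classes = 30L) {
  stopifnot(tau >= 0, theta0 >= 0, theta1 >= 0)
  i <- 0:(n_classes - 1L)
  if (theta1 == 0) {
    recent <- as.numeric(i == 0) # instant coalescence now
    return(recent)
  }
  lam <- tau * (theta1 + 1) / theta1
  recent <- .geom_F(i, theta1) * stats::pgamma(lam, i + 1)
  w <- .tau_pois(i, tau)
  f0 <- .geom_F(i, theta0)
  old <- exp(-lam) * vapply(i, function(ii)
    sum(w[1:(ii + 1)] * f0[(ii + 1):1]), 0)
  recent + old
}

#' Expected mismatch under sudden spatial expansion
#'
#' Infinite-island range-expansion model: at mutational time `tau` a single
#' deme of size `theta` colonised infinitely many demes exchanging `M`
#' migrants (2Nm) per generation. A sampled pair either coalesces within
#' its deme before one lineage emigrates, or survives to the expansion and
#' coalesces in the ancestral deme. Exact mixture form; labelled
#' experimental.
#'
#' @param tau Expansion time in mutational units.
#' @param theta Deme (and ancestral) scaled mutation parameter (> 0).
#' @param M Scaled migrant number 2Nm (> 0).
#' @inheritParams expected_mismatch_demographic
#' @return Probability vector of length `n_classes`.
#' @export
expected_mismatch_spatial <- function(tau, theta, M, n_classes = 30L) {
  stopifnot(tau >= 0, theta > 0, M > 0)
  i <- 0:(n_classes - 1L)
  a <- (1 + 2 * M) / theta          # rate of leaving the together state
  b <- 1 + a
  recent <- (1 / theta) * exp(-(i + 1) * log(b)) *
    stats::pgamma(b * tau, i + 1)
  p_reach <- exp(-a * tau) + (2 * M / (1 + 2 * M)) * (1 - exp(-a * tau))
  w <- .tau_pois(i, tau)
  f0 <- .geom_F(i, theta)
  old <- p_reach * exp(-tau) * vapply(i, function(ii)
    sum(w[1:(ii + 1)] * f0[(ii + 1):1]), 0)
  recent + old
}

.mismatch_ssd <- function(obs_rel, expected) sum((expected - obs_rel)^2)

#' Fit an expansion model to an observed mismatch distribution
#'
#' Least-squares fit of (`tau`, `theta0`, `theta1`) (demographic) or
#' (`tau`, `theta`, `M`) (spatial) by coarse grid search followed by
#' Nelder-Mead refinement on square-root-transformed parameters (the SSD
#' surface is multimodal). Goodness of fit (`P_SSD`, `P_Rag`) and the
#' `tau` confidence interval come from a parametric bootstrap: `n_boot`
#' datasets of `n_seq` sequences are simulated by coalescent under the
#' fitted model, refitted, and compared.
#'
#' @param observed Integer vector of pair counts over classes `0..d` (as
#'   from [mismatch_observed()]).
#' @param model `"demographic"` or `"spatial"`.
#' @param n_boot Parametric bootstrap replicates (0 disables; < 100 warns).
#' @param seed Random seed (required when `n_boot > 0`).
#' @param n_seq Number of sequences behind `observed` (needed for the
#'   bootstrap).
#' @return A `mismatch_fit` list: `tau`, `theta0`, `theta1` (or `theta`,
#'   `M`), `ssd`, `raggedness`, `expected`, and with bootstrap `P_ssd`,
#'   `P_rag`, `tau_ci`.
#' @export
fit_expansion <- function(observed, model = c("demographic", "spatial"),
                          n_boot = 0L, seed = NULL, n_seq = NULL) {
  model <- match.arg(model)
  if (sum(observed > 0) < 2L) {
    stop("need at least 2 mismatch classes with observed mass")
  }
  obs_rel <- observed / sum(observed)
  C <- length(observed)
  expfun <- if (model == "demographic") {
    # theta1 is capped: beyond ~1e5 the expectation is flat in theta1
    function(p) expected_mismatch_demographic(p[1L], p[2L],
                                              min(p[3L], 1e5), C)
  } else {
    function(p) expected_mismatch_spatial(p[1L], max(p[2L], 1e-6),
                                          max(p[3L], 1e-6), C)
  }
  ssd_of <- function(p) .mismatch_ssd(obs_rel, expfun(p))
  grid <- if (model == "demographic") {
    expand.grid(tau = seq(0, 20, by = 0.5),
                a = c(0, 0.1, 0.5, 1, 2, 5, 10),
                b = c(1, 5, 10, 50, 100, 1000, 10000))
  } else {
    expand.grid(tau = seq(0, 20, by = 0.5),
                a = c(0.1, 0.5, 1, 2, 5, 10, 50),
                b = c(0.1, 0.5, 1, 5, 20, 100))
  }
  ssd_grid <- apply(as.matrix(grid), 1L, ssd_of)
  p0 <- as.numeric(grid[which.min(ssd_grid), ])
  opt <- stats::optim(sqrt(p0), function(q) ssd_of(q^2),
                      method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  fit <- opt$par^2
  out <- list(model = model, tau = fit[1L], ssd = opt$value,
              raggedness = raggedness(observed),
              observed = observed, expected = expfun(fit),
              n_boot = n_boot, converged = opt$convergence == 0L)
  if (model == "demographic") {
    out$theta0 <- fit[2L]; out$theta1 <- min(fit[3L], 1e5)
  } else {
    out$theta <- fit[2L]; out$M <- fit[3L]
  }
  if (n_boot > 0L) {
    if (is.null(seed)) stop("a seed is required for the bootstrap")
    if (is.null(n_seq)) stop("n_seq is required for the bootstrap")
    if (n_boot < 100L) warning("n_boot < 100: bootstrap P-values are crude")
    set.seed(seed)
    ssd_b <- rag_b <- tau_b <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      h <- if (model == "demographic") {
        sim_mismatch_expansion(n_seq, out$tau, out$theta0, out$theta1)
      } else {
        sim_mismatch_spatial(n_seq, out$tau, out$theta, out$M)
      }
      refit <- fit_expansion(h, model = model, n_boot = 0L)
      # compare on the same class span as the data
      hh <- h[seq_len(min(length(h), C))]
      ssd_b[b] <- .mismatch_ssd(hh / sum(hh),
                                expfun(fit)[seq_along(hh)])
      rag_b[b] <- raggedness(h)
      tau_b[b] <- refit$tau
    }
    out$P_ssd <- mean(ssd_b >= out$ssd)
    out$P_rag <- mean(rag_b >= out$raggedness)
    out$tau_ci <- stats::quantile(tau_b, c(0.025, 0.975), names = FALSE)
  }
  class(out) <- "mismatch_fit"
  out
}

#' @export
print.mismatch_fit <- function(x, ...) {
  cat("mismatch fit (", x$model, "expansion )\n")
  if (x$model == "demographic") {
    cat(sprintf("  tau = %.3f  theta0 = %.3f  theta1 = %.3f\n",
                x$tau, x$theta0, x$theta1))
  } else {
    cat(sprintf("  tau = %.3f  theta = %.3f  M = %.3f\n",
                x$tau, x$theta, x$M))
  }
  cat(sprintf("  SSD = %.4g  raggedness = %.4g\n", x$ssd, x$raggedness))
  if (!is.null(x$P_ssd)) {
    cat(sprintf("  P_SSD = %.3f  P_Rag = %.3f  tau 95%% CI [%.2f, %.2f]\n",
                x$P_ssd, x$P_rag, x$tau_ci[1L], x$tau_ci[2L]))
  }
  invisible(x)
}

#' Absolute expansion time from tau
#'
#' `T = tau / (2u)` with `u = mu * k * g`, the per-sequence
#' per-generation mutation rate. The result is reported in kyr following
#' the field convention that treats `tau/(2u)` as years (strictly it is
#' generations; the caveat travels as an attribute).
#'
#' @param tau Expansion parameter (mutational units); vectorised, so a CI
#'   can be passed.
#' @param mu Substitution rate per site per year.
#' @param k Sequence length in bp.
#' @param g Generation time in years.
#' @return Expansion time in kyr, attribute `units`.
#' @export
expansion_time <- function(tau, mu, k, g) {
  if (any(tau < 0) || mu <= 0 || k <= 0 || g <= 0) {
    stop("tau must be >= 0 and mu, k, g positive")
  }
  u <- mu * k * g
  structure(tau / (2 * u) / 1000,
            units = paste("kyr; tau/(2u) is in generations but is",
                          "conventionally reported as years"))
}
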