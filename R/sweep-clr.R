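#' Post-sweep site frequency spectrum at a given distance
#'
#' Expected sample spectrum immediately after a sweep for a site at distance
#' `d` bp from the selected position, given the neutral background spectrum.
#' Each of the `n` lineages escapes the sweep independently with probability
#' `p_e = 1 - exp(-alpha * d)`. Conditional on `E` escapees, the `n - E` swept
#' lineages descend from a single founder, so the site's ancestry reduces to
#' `m = E + 1` founders, a hypergeometric down-projection of the background
#' spectrum from `n` to `m` lineages; if `j` of the `m` founders carry the
#' derived allele, the swept founder is derived with probability `j/m`, giving
#' a post-sweep derived count of `(n - E) + (j - 1)`, and `j` otherwise. With
#' `E = n` (all escape) the background is returned unchanged.
#'
#' @param background normalized `sv_sfs` over classes `0..n`.
#' @param alpha compound sweep-strength parameter (per-bp escape rate).
#' @param d distance from the sweep position in bp.
#' @param n haploid sample size (defaults to the background's).
#' @return normalized `sv_sfs` over classes `0..n`.
#' @export
post_sweep_sfs <- function(background, alpha, d, n = background$n) {
  if (!background$normalized) {
    abort("background SFS must be normalized", class = "sv_precondition_error")
  }
  if (alpha < 0 || d < 0) abort("alpha and d must be non-negative")
  p <- background$counts
  s <- alpha * d
  if (s > 700) return(background)
  p_e <- -expm1(-s)
  out <- numeric(n + 1)
  wE <- stats::dbinom(0:n, n, p_e)
  # E = n: all lineages escape, background unchanged
  out <- out + wE[n + 1] * p
  for (E in 0:(n - 1)) {
    if (wE[E + 1] == 0) next
    m <- E + 1
    # down-projection: q_m(j) = sum_i p_i P(Hypergeom(i, n - i, m) = j)
    qm <- numeric(m + 1)
    for (i in 0:n) {
      if (p[i + 1] == 0) next
      j <- max(0, m - (n - i)):min(m, i)
      qm[j + 1] <- qm[j + 1] + p[i + 1] * stats::dhyper(j, i, n - i, m)
    }
    for (j in 0:m) {
      if (qm[j + 1] == 0) next
      if (j > 0) {
        k_swept <- (n - E) + (j - 1)
        out[k_swept + 1] <- out[k_swept + 1] + wE[E + 1] * qm[j + 1] * (j / m)
      }
      out[j + 1] <- out[j + 1] + wE[E + 1] * qm[j + 1] * (1 - j / m)
    }
  }
  sfs(out / sum(out), n, normalized = TRUE)
}

#' Pooled background spectrum from neutral simulations
#'
#' Pools the derived-class counts of a population across simulated replicates
#' into one spectrum over classes `0..n`, with invariant-site bookkeeping:
#' every simulated position not segregating in the population contributes to
#' class 0, and positions fixed derived in the population (but still variable
#' in the combined sample) to class `n`.
#'
#' @param sims list of `sv_sim_replicate` objects.
#' @param population population tag (default `"EU"`).
#' @return an `sv_sfs` of pooled counts.
#' @export
background_from_simulations <- function(sims, population = "EU") {
  if (!length(sims)) abort("need at least one simulated replicate")
  n <- sims[[1]]$samples[[population]]
  counts <- numeric(n + 1)
  for (rep_i in sims) {
    hap <- sim_haplotypes(rep_i, population)
    k <- if (ncol(hap)) colSums(hap) else integer(0)
    tb <- tabulate(k[k >= 1] + 1L, nbins = n + 1)
    counts <- counts + tb
    counts[1] <- counts[1] + rep_i$L - sum(k >= 1)
  }
  if (sum(counts) <= 0) abort("no sites in the pooled simulations")
  sfs(counts, n)
}

#' Estimate the neutral background spectrum under a demographic model
#'
#' Convenience wrapper: simulates `reps` neutral replicates under the model
#' and pools them with [background_from_simulations()].
#'
#' @param model a [demographic_model()].
#' @param samples named haploid sample sizes (the combined sample whose
#'   joint polarization defines class `n`).
#' @param L region length per replicate (bp).
#' @param reps number of replicates.
#' @param seed optional seed.
#' @param population focal population.
#' @return an `sv_sfs` of pooled counts.
#' @export
neutral_background <- function(model, samples = c(AF = 12, EU = 12), L = 20011,
                               reps = 200, seed = NULL, population = "EU") {
  if (!is.null(seed)) set.seed(seed)
  sims <- lapply(seq_len(reps), function(i) simulate_region(model, samples, L))
  background_from_simulations(sims, population)
}

# normalize a background for likelihood use: zero-mass classes get a 0.5-site
# pseudocount before normalization so no observed class has probability zero
clr_background_probs <- function(background) {
  counts <- background$counts
  if (background$normalized) {
    z <- counts == 0
    if (any(z)) {
      counts[z] <- 0.5 / max(sum(counts), 1)
      counts <- counts / sum(counts)
    }
    return(counts)
  }
  counts[counts == 0] <- 0.5
  counts / sum(counts)
}

# tabulate sweep-model log-probabilities over a log-spaced grid of
# s = alpha * distance; beyond s_max the model is the background itself
clr_precompute <- function(background, n, L, n_s = 256, s_min = 1e-6,
                           s_max = 50) {
  p <- clr_background_probs(background)
  bg <- sfs(p, n, normalized = TRUE)
  sgrid <- exp(seq(log(s_min), log(s_max), length.out = n_s))
  logq <- vapply(sgrid, function(s) log(post_sweep_sfs(bg, s, 1)$counts),
                 numeric(n + 1))
  list(logq = logq, s_min = s_min, s_max = s_max, logp = log(p), n = n, L = L)
}

default_alpha_grid <- function(L, n_alpha = 64) {
  lo <- -log1p(-1e-4) / L
  hi <- -log1p(-0.9999) / L
  exp(seq(log(lo), log(hi), length.out = n_alpha))
}

# core CLR scan on point sites (classes >= 1) plus the invariant class-0 bulk.
# The bulk is position-binned (default ~40 bp bins) since the sweep model
# varies smoothly with distance; point sites are used exactly.
clr_scan_core <- function(point_pos, point_class, L, prep, grid_size = 1000,
                          n_alpha = 64, invariant_pos = NULL, refine = TRUE,
                          bin_width = 40, alphas = NULL) {
  nbin <- max(8L, ceiling(L / bin_width))
  breaks <- seq(0, L, length.out = nbin + 1)
  bin_pos <- (breaks[-1] + breaks[-length(breaks)]) / 2
  if (is.null(invariant_pos)) {
    tot <- diff(breaks)
    pts <- if (length(point_pos)) {
      tabulate(pmin(nbin, pmax(1L, findInterval(point_pos, breaks,
                                                rightmost.closed = TRUE))),
               nbins = nbin)
    } else {
      numeric(nbin)
    }
    bin_count <- pmax(0, tot - pts)
  } else {
    bin_count <- tabulate(pmin(nbin, pmax(1L, findInterval(invariant_pos, breaks,
                                                           rightmost.closed = TRUE))),
                          nbins = nbin)
  }
  keep <- bin_count > 0
  grid <- seq(1, L, length.out = grid_size)
  if (is.null(alphas)) alphas <- default_alpha_grid(L, n_alpha)
  res <- sv_clr_scan_cpp(as.numeric(point_pos), as.integer(point_class),
                         bin_pos[keep], bin_count[keep], grid, alphas,
                         prep$logq, prep$s_min, prep$s_max, prep$logp)
  tbl <- tibble(position = grid, value = res$value, alpha = res$alpha)
  out <- new_scan_result(tbl, "clr")
  if (refine && length(alphas) > 1 && attr(out, "max_value") > 0) {
    gi <- which.max(res$value)
    ai <- match(res$alpha[gi], alphas)
    lo <- alphas[max(1L, ai - 1L)]
    hi <- alphas[min(length(alphas), ai + 1L)]
    opt <- stats::optimize(function(a)
      sv_clr_loglik_cpp(grid[gi], a, as.numeric(point_pos),
                        as.integer(point_class), bin_pos[keep],
                        bin_count[keep], prep$logq, prep$s_min, prep$s_max,
                        prep$logp),
      lower = lo, upper = hi, maximum = TRUE, tol = 1e-6 * hi)
    stat <- 2 * (opt$objective - res$ll_neutral)
    if (stat > attr(out, "max_value")) {
      out$value[gi] <- stat
      out$alpha[gi] <- opt$maximum
      out <- new_scan_result(tidy(out), "clr")
    }
  }
  out
}

#' Composite-likelihood-ratio sweep scan
#'
#' Scans a grid of candidate sweep positions. At each position `x` the
#' composite likelihood of all site classes (including the invariant class-0
#' bulk; monomorphic sites are informative about a sweep) is maximized over
#' the sweep-strength parameter `alpha` on a log-spaced grid, with a local
#' refinement of `alpha` at the argmax position, and compared with the
#' neutral background likelihood: the reported statistic is
#' `2 * (log CL_sweep - log CL_neutral)`, floored at zero (the sweep model
#' nests neutrality as escape becomes certain).
#'
#' @param x an `sv_site_table` (with `population`) or an `sv_sim_replicate`.
#' @param background normalized or count `sv_sfs` over classes `0..n`;
#'   zero-mass classes receive a 0.5-site pseudocount.
#' @param population focal population tag.
#' @param grid_size number of equally spaced candidate positions.
#' @param n_alpha number of log-spaced alpha grid points, spanning an escape
#'   probability at distance `L` from about `1e-4` to `0.9999`.
#' @param alphas explicit alpha grid overriding `n_alpha`.
#' @param ... passed between methods.
#' @return an `sv_scan_result` with columns `position`, `value` (the CLR) and
#'   `alpha` (the optimizing sweep strength).
#' @export
clr_scan <- function(x, background, ..., grid_size = 1000, n_alpha = 64,
                     alphas = NULL) {
  UseMethod("clr_scan")
}

#' @rdname clr_scan
#' @export
clr_scan.sv_site_table <- function(x, background, population, ...,
                                   grid_size = 1000, n_alpha = 64,
                                   alphas = NULL) {
  n <- sv_nsizes(x)[[population]]
  if (background$n != n) abort("background SFS sample size does not match")
  use <- usable_sites(x)
  k <- x[[paste0("derived_", population)]]
  bad <- use & !is.na(k) & (k < 0 | k > n)
  if (any(bad)) abort("derived count outside 0..n", class = "sv_data_error")
  # joint polarization: fixed-derived (class n) points require the combined
  # ingroup dataset to be variable; combined-invariant columns that merely
  # differ from the outgroup are part of the class-0 bulk
  combined_var <- x$kind %in% c("segregating", "fixed_difference")
  is_point <- use & !is.na(k) &
    (k %in% seq_len(n - 1) | (k == n & combined_var))
  prep <- clr_precompute(background, n, attr(x, "L"))
  clr_scan_core(x$column[is_point], k[is_point], attr(x, "L"), prep,
                grid_size = grid_size, n_alpha = n_alpha, alphas = alphas,
                invariant_pos = x$column[use & !is_point], ...)
}

#' @rdname clr_scan
#' @export
clr_scan.sv_sim_replicate <- function(x, background, population = "EU", ...,
                                      grid_size = 1000, n_alpha = 64,
                                      alphas = NULL) {
  cls <- eu_site_classes(x)
  prep <- clr_precompute(background, x$samples[[population]], x$L)
  clr_scan_core(cls$pos, cls$class, x$L, prep, grid_size = grid_size,
                n_alpha = n_alpha, alphas = alphas, ...)
}
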