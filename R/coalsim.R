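#' Three-population out-of-Africa demographic model
#'
#' Piecewise-constant three-population model of the demographic history of
#' African, European and Asian populations of *D. melanogaster*: an ancestral
#' African population expands instantaneously to its current size; Europe is
#' founded from Africa through a bottleneck; Asia is founded from Europe
#' through its own bottleneck. There is no migration. Defaults are the
#' X-chromosome posterior modes of the fitted model, with times in years
#' converted internally to generations at `gen_per_year` generations per year.
#' Founding populations stay at their bottleneck size from the founding time
#' until a recovery event; by default the bottleneck lasts half the founding
#' time, so recovery happens midway to the present.
#'
#' @param N_afr_cur,N_eur_cur,N_asia_cur current effective sizes (diploid).
#' @param N_eur_bot,N_asia_bot bottleneck sizes of the founded populations.
#' @param N_afr_anc ancestral African size before the African expansion.
#' @param T_exit time of the exit out of Africa (years before present).
#' @param T_asia colonization time of Asia (years).
#' @param T_afr_exp time of the African expansion (years).
#' @param gen_per_year generations per year (default 10).
#' @param mu per-bp per-generation mutation rate (divergence-based default).
#' @param r per-bp per-generation recombination rate.
#' @param bottleneck_duration_eur,bottleneck_duration_asia bottleneck
#'   durations in generations; `NULL` means half the founding time.
#' @return an object of class `demographic_model`.
#' @export
demographic_model <- function(N_afr_cur = 4635114, N_eur_cur = 1586481,
                              N_asia_cur = 338810, N_eur_bot = 22975,
                              N_asia_bot = 10741, N_afr_anc = 1890641,
                              T_exit = 15628, T_asia = 3264,
                              T_afr_exp = 27643, gen_per_year = 10,
                              mu = 1.5e-9, r = 3.64e-8,
                              bottleneck_duration_eur = NULL,
                              bottleneck_duration_asia = NULL) {
  sizes <- c(N_afr_cur, N_eur_cur, N_asia_cur, N_eur_bot, N_asia_bot, N_afr_anc)
  if (any(sizes <= 0)) abort("all effective sizes must be positive",
                             class = "sv_model_error")
  if (T_exit <= T_asia || T_asia <= 0 || T_afr_exp <= 0) {
    abort("need T_exit > T_asia > 0 and T_afr_exp > 0", class = "sv_model_error")
  }
  if (mu <= 0 || r < 0) abort("need mu > 0 and r >= 0", class = "sv_model_error")
  g_exit <- T_exit * gen_per_year
  g_asia <- T_asia * gen_per_year
  if (is.null(bottleneck_duration_eur)) bottleneck_duration_eur <- g_exit / 2
  if (is.null(bottleneck_duration_asia)) bottleneck_duration_asia <- g_asia / 2
  if (bottleneck_duration_eur > g_exit || bottleneck_duration_asia > g_asia) {
    abort("bottleneck durations cannot exceed the founding times",
          class = "sv_model_error")
  }
  structure(list(N_afr_cur = N_afr_cur, N_eur_cur = N_eur_cur,
                 N_asia_cur = N_asia_cur, N_eur_bot = N_eur_bot,
                 N_asia_bot = N_asia_bot, N_afr_anc = N_afr_anc,
                 T_exit = T_exit, T_asia = T_asia, T_afr_exp = T_afr_exp,
                 gen_per_year = gen_per_year, mu = mu, r = r,
                 bottleneck_duration_eur = bottleneck_duration_eur,
                 bottleneck_duration_asia = bottleneck_duration_asia),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("<demographic_model> three-population bottleneck/expansion model\n")
  cat(sprintf("  N (AF, EU, AS current): %s / %s / %s\n",
              format(x$N_afr_cur, big.mark = ","),
              format(x$N_eur_cur, big.mark = ","),
              format(x$N_asia_cur, big.mark = ",")))
  cat(sprintf("  bottlenecks (EU, AS): %s / %s; ancestral AF: %s\n",
              format(x$N_eur_bot, big.mark = ","),
              format(x$N_asia_bot, big.mark = ","),
              format(x$N_afr_anc, big.mark = ",")))
  cat(sprintf("  times (years): exit %s, Asia %s, AF expansion %s (%d gen/yr)\n",
              format(x$T_exit, big.mark = ","), format(x$T_asia, big.mark = ","),
              format(x$T_afr_exp, big.mark = ","), x$gen_per_year))
  cat(sprintf("  mu = %g, r = %g per bp per generation\n", x$mu, x$r))
  invisible(x)
}

# backward-time event table (generations): sizes switch to bottleneck values
# at the recovery time, founded populations merge into their source at the
# founding time, Africa reverts to its ancestral size at the expansion time.
model_events <- function(model) {
  g <- model$gen_per_year
  g_exit <- model$T_exit * g
  g_asia <- model$T_asia * g
  g_afr <- model$T_afr_exp * g
  ev <- list(
    c(g_asia - model$bottleneck_duration_asia, 0, 2, model$N_asia_bot),
    c(g_exit - model$bottleneck_duration_eur, 0, 1, model$N_eur_bot),
    c(g_asia, 1, 2, 1),  # Asia merges into Europe
    c(g_afr, 0, 0, model$N_afr_anc),
    c(g_exit, 1, 1, 0)   # Europe merges into Africa
  )
  m <- do.call(rbind, ev)
  m[order(m[, 1]), , drop = FALSE]
}

POP_ORDER <- c("AF", "EU", "AS")

normalize_samples <- function(samples) {
  if (is.null(names(samples))) {
    names(samples) <- POP_ORDER[seq_along(samples)]
  }
  out <- setNames(integer(3), POP_ORDER)
  out[names(samples)] <- as.integer(samples)
  out
}

#' Simulate one replicate under the demographic model
#'
#' Hudson-style coalescent simulation with recombination of `L` bp for the
#' requested haploid sample sizes (named `AF`, `EU`, `AS`). The population
#' mutation rate is fixed by the model's effective sizes and mutation rate,
#' never by an observed number of segregating sites. Mutations follow the
#' infinite-sites model at continuous positions; see
#' [sim_positions_bp()] for the integer-bp view.
#'
#' @param model a [demographic_model()].
#' @param samples named haploid sample sizes, e.g. `c(EU = 12)` or
#'   `c(AF = 12, EU = 12, AS = 12)`; total at most 64.
#' @param L region length in bp.
#' @param seed optional integer seed (sets R's RNG).
#' @return an `sv_sim_replicate`: list with `positions` (continuous, in
#'   `(0, L)`), `genotypes` (0/1 matrix, rows = haplotypes in AF, EU, AS
#'   order), `samples`, `L`, `seed`, and event diagnostics.
#' @export
simulate_region <- function(model, samples, L, seed = NULL) {
  stopifnot(inherits(model, "demographic_model"))
  if (!is.null(seed)) set.seed(seed)
  ss <- normalize_samples(samples)
  if (sum(ss) < 2) abort("total sample size must be >= 2")
  ev <- model_events(model)
  res <- sv_simulate_cpp(L, unname(ss),
                         c(model$N_afr_cur, model$N_eur_cur, model$N_asia_cur),
                         model$r, model$mu, ev[, 1], as.integer(ev[, 2]),
                         as.integer(ev[, 3]), ev[, 4])
  rows <- rep(POP_ORDER, times = ss)
  structure(list(positions = res$positions, genotypes = res$genotypes,
                 pop = rows, samples = ss, L = as.integer(L), seed = seed,
                 n_coalescence = res$n_coalescence,
                 n_recombination = res$n_recombination),
            class = "sv_sim_replicate")
}

#' @export
print.sv_sim_replicate <- function(x, ...) {
  cat("<sv_sim_replicate> ", sum(x$samples), " haplotypes, L = ", x$L,
      ", S = ", length(x$positions), "\n", sep = "")
  invisible(x)
}

#' Integer-bp mutation positions of a replicate
#'
#' Maps the continuous infinite-sites positions of a replicate to 1-based
#' integer bp; collisions are resolved by moving a site to the nearest free
#' integer position.
#'
#' @param rep an `sv_sim_replicate`.
#' @return integer positions, strictly increasing, in `[1, L]`.
#' @export
sim_positions_bp <- function(rep) {
  p <- floor(rep$positions) + 1L
  p[p > rep$L] <- rep$L
  if (!length(p)) return(integer(0))
  occ <- logical(rep$L)
  out <- integer(length(p))
  for (i in seq_along(p)) {
    x <- p[i]
    if (!occ[x]) {
      occ[x] <- TRUE
      out[i] <- x
      next
    }
    for (d in seq_len(rep$L)) {
      if (x + d <= rep$L && !occ[x + d]) { out[i] <- x + d; occ[x + d] <- TRUE; break }
      if (x - d >= 1L && !occ[x - d]) { out[i] <- x - d; occ[x - d] <- TRUE; break }
    }
  }
  sort(out)
}

#' Haplotypes of one population from a replicate
#'
#' @param rep an `sv_sim_replicate`.
#' @param population population tag (`AF`, `EU` or `AS`).
#' @return 0/1 matrix of the population's haplotypes (all simulated columns).
#' @export
sim_haplotypes <- function(rep, population) {
  rep$genotypes[rep$pop == population, , drop = FALSE]
}

#' Calibrate neutral significance thresholds for scan maxima
#'
#' Simulates neutral replicates under the demographic model, computes the
#' maximum of each requested scan statistic on the European subset of every
#' replicate, and returns empirical upper quantiles as significance
#' thresholds. Replicates on which a statistic is undefined (e.g. fewer than
#' four usable sites for omega) contribute the statistic's defined minimum of
#' zero. Infinite omega sentinels are capped at the 99.9th percentile of the
#' finite null values before taking quantiles.
#'
#' @param model a [demographic_model()].
#' @param samples named haploid sample sizes simulated per replicate; must
#'   include `EU`.
#' @param L region length in bp.
#' @param background normalized background `sv_sfs` (classes 0..n of the EU
#'   sample) for the CLR statistic; see [background_from_simulations()].
#' @param reps number of neutral replicates.
#' @param q quantile(s) of the null maxima to report.
#' @param seed optional integer seed.
#' @param statistics subset of `c("clr", "omega")`.
#' @param clr_grid,clr_alphas CLR scan settings (see [clr_scan()]).
#' @param omega_grid,omega_min_window,omega_max_window omega scan settings.
#' @return list with `thresholds` (tibble: statistic, q, threshold) and
#'   `null_max` (tibble of per-replicate maxima for diagnostics).
#' @export
calibrate_thresholds <- function(model, samples, L, background = NULL,
                                 reps = 10000, q = 0.95, seed = NULL,
                                 statistics = c("clr", "omega"),
                                 clr_grid = 200, clr_alphas = 32,
                                 omega_grid = 200, omega_min_window = 2000,
                                 omega_max_window = 10000) {
  statistics <- match.arg(statistics, several.ok = TRUE)
  if (reps < 100) abort("need at least 100 replicates")
  if (!is.null(seed)) set.seed(seed)
  ss <- normalize_samples(samples)
  if (ss[["EU"]] < 2) abort("samples must include an EU sample of >= 2")
  n_eu <- ss[["EU"]]
  prep <- NULL
  if ("clr" %in% statistics) {
    if (is.null(background)) abort("a background SFS is required for the CLR")
    prep <- clr_precompute(background, n_eu, L)
  }
  clr_max <- omega_max <- rep(NA_real_, reps)
  for (i in seq_len(reps)) {
    rep_i <- simulate_region(model, ss, L)
    eu <- sim_haplotypes(rep_i, "EU")
    k_eu <- if (ncol(eu)) colSums(eu) else integer(0)
    if ("clr" %in% statistics) {
      cls <- eu_site_classes(rep_i, k_eu)
      sc <- clr_scan_core(cls$pos, cls$class, L, prep, grid_size = clr_grid,
                          n_alpha = clr_alphas)
      clr_max[i] <- attr(sc, "max_value")
    }
    if ("omega" %in% statistics) {
      keep <- k_eu >= 2 & k_eu <= n_eu - 2
      omega_max[i] <- if (sum(keep) >= 4) {
        om <- omega_scan_core(rep_i$positions[keep],
                              eu[, keep, drop = FALSE], L,
                              grid_size = omega_grid,
                              min_window = omega_min_window,
                              max_window = omega_max_window)
        mv <- attr(om, "max_value")
        if (is.finite(mv)) mv else Inf
      } else {
        0
      }
    }
  }
  null_max <- tibble(replicate = seq_len(reps))
  out <- list()
  if ("clr" %in% statistics) null_max$clr_max <- clr_max
  if ("omega" %in% statistics) {
    fin <- omega_max[is.finite(omega_max)]
    cap <- if (length(fin)) quantile(fin, 0.999, names = FALSE) else 0
    omega_max[!is.finite(omega_max)] <- cap
    null_max$omega_max <- omega_max
  }
  thr <- purrr::map_dfr(intersect(c("clr", "omega"), statistics), function(st) {
    v <- null_max[[paste0(st, "_max")]]
    tibble(statistic = st, q = q,
           threshold = quantile(v, q, names = FALSE, type = 7))
  })
  list(thresholds = thr, null_max = null_max)
}

# EU-subset site classes for the CLR on a simulated replicate: classes 1..n-1
# from the EU derived counts; sites fixed derived in EU but still variable in
# the combined sample map to class n (the combined dataset polarizes them);
# everything else is part of the invariant class-0 bulk.
eu_site_classes <- function(rep, k_eu = NULL) {
  eu <- sim_haplotypes(rep, "EU")
  n <- nrow(eu)
  if (is.null(k_eu)) k_eu <- if (ncol(eu)) colSums(eu) else integer(0)
  keep <- k_eu >= 1 & k_eu <= n
  list(pos = rep$positions[keep], class = as.integer(k_eu[keep]))
}
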