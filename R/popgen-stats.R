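#' Sample-size constants for diversity statistics
#'
#' The harmonic-number constants entering Watterson's estimator and the
#' variance normalization of Tajima's D.
#'
#' @param n haploid sample size (>= 2).
#' @return named list with `n`, `a1`, `a2`, `b1`, `b2`, `c1`, `c2`, `e1`, `e2`.
#' @export
stat_constants <- function(n) {
  if (n < 2) abort("sample size must be >= 2")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(n = n, a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Watterson's estimator of the population mutation rate
#'
#' @param S number of segregating sites.
#' @param n haploid sample size.
#' @param L number of sites surveyed.
#' @return per-site theta_W = S / (a1 * L).
#' @export
watterson_theta <- function(S, n, L) {
  if (n < 2 || L < 1) abort("need n >= 2 and L >= 1")
  if (any(S < 0)) abort("S must be non-negative")
  S / (stat_constants(n)$a1 * L)
}

#' Tajima's D
#'
#' Normalized difference between the pairwise-diversity and segregating-sites
#' estimators of theta. Returns `NA` (undefined) when `S = 0`.
#'
#' @param S number of segregating sites.
#' @param pi_total sum over sites of per-site pairwise diversity (i.e. the mean
#'   number of pairwise differences, not divided by L).
#' @param n haploid sample size (>= 4 for a positive variance).
#' @return Tajima's D, or `NA_real_` when undefined.
#' @export
tajimas_d <- function(S, pi_total, n) {
  if (S == 0) return(NA_real_)
  k <- stat_constants(n)
  (pi_total - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

usable_sites <- function(table) table$kind != "indel" & table$kind != "masked"

#' Per-site nucleotide diversity of a population
#'
#' Unbiased mean pairwise diversity: at each usable (non-gap, called) column,
#' `n_s/(n_s - 1) * (1 - sum of squared allele frequencies)` with `n_s` the
#' called sample size at the column, averaged over `L` sites.
#'
#' @param table an `sv_site_table`.
#' @param population population tag.
#' @param L number of sites to divide by; defaults to the number of usable
#'   columns (gap and masked columns are excluded, shrinking the denominator).
#' @return per-site pi.
#' @export
nucleotide_diversity <- function(table, population, L = NULL) {
  het <- table[[paste0("het_", population)]]
  if (is.null(het)) abort(paste0("population not in table: ", population))
  use <- usable_sites(table)
  if (is.null(L)) L <- sum(use)
  if (L < 1) abort("L must be >= 1")
  sum(het[use]) / L
}

#' Per-site divergence to the outgroup
#'
#' Mean over usable columns (with an outgroup call) of the fraction of
#' ingroup alleles differing from the outgroup allele; equivalently the mean
#' per-sequence divergence.
#'
#' @inheritParams nucleotide_diversity
#' @return per-site divergence.
#' @export
divergence <- function(table, population, L = NULL) {
  mm <- table[[paste0("mismatch_", population)]]
  if (is.null(mm)) abort(paste0("population not in table: ", population))
  use <- usable_sites(table) & !is.na(mm)
  if (!any(use)) abort("no outgroup calls available", class = "sv_precondition_error")
  if (is.null(L)) L <- sum(use)
  sum(mm[use]) / L
}

#' Sliding-window summary statistics
#'
#' Splits the alignment into overlapping windows (default 1 kb sliding by
#' 500 bp) and computes, per window and population: segregating sites `S`,
#' per-site `pi`, Watterson's `theta_w`, Tajima's D (`NA` when `S = 0`) and
#' per-site divergence to the outgroup. Gap and masked columns are excluded
#' and the effective window length reduced accordingly. Windows start at
#' columns 1, 1+step, ... while a full window fits; remaining tail columns
#' form their own window when at least half a window long and are otherwise
#' merged into the last window.
#'
#' @param table an `sv_site_table`.
#' @param population population tag.
#' @param window window size in columns.
#' @param step step between window starts.
#' @return tibble with `start`, `end`, `L_eff`, `S`, `pi`, `theta_w`,
#'   `tajima_d`, `divergence`.
#' @export
sliding_windows <- function(table, population, window = 1000L, step = 500L) {
  if (step < 1 || window < step) abort("need window >= step >= 1")
  L <- attr(table, "L")
  n <- sv_nsizes(table)[[population]]
  if (window > L) {
    starts <- 1L; ends <- L
  } else {
    starts <- seq.int(1L, L - window + 1L, by = step)
    ends <- starts + window - 1L
    tail_len <- L - ends[length(ends)]
    if (tail_len >= window / 2) {
      starts <- c(starts, ends[length(ends)] + 1L)
      ends <- c(ends, L)
    } else if (tail_len > 0) {
      ends[length(ends)] <- L
    }
  }
  seg <- table[[paste0("seg_", population)]]
  het <- table[[paste0("het_", population)]]
  mm <- table[[paste0("mismatch_", population)]]
  use <- usable_sites(table)
  purrr::map2_dfr(starts, ends, function(s, e) {
    in_w <- table$column >= s & table$column <= e & use
    L_eff <- sum(in_w)
    S <- sum(seg & in_w)
    pi_total <- sum(het[in_w])
    div_use <- in_w & !is.na(mm)
    tibble(start = s, end = e, L_eff = L_eff, S = S,
           pi = if (L_eff > 0) pi_total / L_eff else NA_real_,
           theta_w = if (L_eff > 0) watterson_theta(S, n, L_eff) else NA_real_,
           tajima_d = tajimas_d(S, pi_total, n),
           divergence = if (any(div_use)) sum(mm[div_use]) / sum(div_use) else NA_real_)
  })
}

#' Region-level summary of a population sample
#'
#' Both the unweighted mean of per-window statistics (the sliding-window
#' region mean) and the whole-region estimates computed on all usable columns.
#'
#' @inheritParams sliding_windows
#' @return one-row tibble with window means (`theta_w_mean`, `pi_mean`,
#'   `tajima_d_mean`, `divergence_mean`) and whole-region values
#'   (`theta_w_region`, `pi_region`, `S_region`, `L_eff`).
#' @export
region_summary <- function(table, population, window = 1000L, step = 500L) {
  w <- sliding_windows(table, population, window, step)
  n <- sv_nsizes(table)[[population]]
  use <- usable_sites(table)
  S <- sum(table[[paste0("seg_", population)]] & use)
  L_eff <- sum(use)
  tibble(population = population,
         theta_w_mean = mean(w$theta_w, na.rm = TRUE),
         pi_mean = mean(w$pi, na.rm = TRUE),
         tajima_d_mean = mean(w$tajima_d, na.rm = TRUE),
         divergence_mean = mean(w$divergence, na.rm = TRUE),
         theta_w_region = watterson_theta(S, n, L_eff),
         pi_region = nucleotide_diversity(table, population),
         S_region = S, L_eff = L_eff)
}

#' Site-frequency-spectrum container
#'
#' @param counts numeric vector of length `n + 1`, classes 0..n (class 0 =
#'   monomorphic ancestral, class n = fixed derived).
#' @param n haploid sample size.
#' @param normalized whether `counts` sums to one.
#' @return an `sv_sfs` object.
#' @export
sfs <- function(counts, n = length(counts) - 1L, normalized = FALSE) {
  if (length(counts) != n + 1) abort("counts must have length n + 1")
  if (any(counts < 0)) abort("counts must be non-negative")
  if (normalized && abs(sum(counts) - 1) > 1e-12) abort("normalized SFS must sum to 1")
  structure(list(n = as.integer(n), counts = as.numeric(counts),
                 normalized = isTRUE(normalized)), class = "sv_sfs")
}

#' @export
print.sv_sfs <- function(x, ...) {
  cat("<sv_sfs> n =", x$n, if (x$normalized) "(normalized)" else "(counts)", "\n")
  print(setNames(x$counts, 0:x$n))
  invisible(x)
}

#' Normalize an SFS to proportions
#' @param x an `sv_sfs`.
#' @return normalized `sv_sfs`.
#' @export
normalize_sfs <- function(x) {
  tot <- sum(x$counts)
  if (tot <= 0) abort("cannot normalize an empty SFS")
  sfs(x$counts / tot, x$n, normalized = TRUE)
}

#' Fold an SFS onto minor-allele classes
#'
#' Folding maps class k onto min(k, n - k); applying it twice is the same as
#' applying it once.
#'
#' @param x an `sv_sfs`.
#' @return folded `sv_sfs` (upper classes zeroed).
#' @export
fold_sfs <- function(x) {
  n <- x$n
  out <- numeric(n + 1)
  for (k in 0:n) {
    j <- min(k, n - k)
    out[j + 1] <- out[j + 1] + x$counts[k + 1]
  }
  sfs(out, n, normalized = x$normalized)
}

#' Site frequency spectrum of a population from a site table
#'
#' Counts sites by derived-allele class in the focal population. With
#' `polarize_via_joint`, sites that are monomorphic in the focal population
#' are assigned using the combined ingroup dataset: sites invariant across all
#' ingroup samples count as class 0; sites variable in the combined dataset
#' (or divergent between populations) are placed in class 0 or class n
#' according to the outgroup polarization of the focal allele. Unpolarizable
#' focal-monomorphic sites fall back to class 0. Gap and masked columns are
#' skipped.
#'
#' @param table polarized `sv_site_table`.
#' @param population population tag.
#' @param include_invariant keep classes 0 and n (default); otherwise they are
#'   dropped and the spectrum covers classes 1..n-1.
#' @param polarize_via_joint use the combined dataset for focal-monomorphic
#'   sites as described above.
#' @return an `sv_sfs` of counts.
#' @export
sfs_from_table <- function(table, population, include_invariant = TRUE,
                           polarize_via_joint = TRUE) {
  n <- sv_nsizes(table)[[population]]
  use <- usable_sites(table)
  seg <- table[[paste0("seg_", population)]] & use
  k <- table[[paste0("derived_", population)]]
  counts <- numeric(n + 1)
  seg_pol <- seg & !is.na(k)
  if (any(seg & is.na(k)) && include_invariant && !polarize_via_joint) {
    abort("table contains unpolarized segregating sites",
          class = "sv_precondition_error")
  }
  tb <- tabulate(k[seg_pol] + 1L, nbins = n + 1)
  counts <- counts + tb
  mono <- use & !seg
  if (polarize_via_joint) {
    k_m <- k[mono]
    # focal-monomorphic sites count as fixed derived only when the combined
    # ingroup dataset is variable there; sites invariant across all ingroup
    # samples are class 0 even where the outgroup differs
    combined_var <- table$kind[mono] %in% c("segregating", "fixed_difference")
    fixed_derived <- !is.na(k_m) & k_m == n & combined_var
    counts[n + 1] <- counts[n + 1] + sum(fixed_derived)
    counts[1] <- counts[1] + sum(!fixed_derived)
  } else {
    counts[1] <- counts[1] + sum(mono & !is.na(k) & k == 0)
    counts[n + 1] <- counts[n + 1] + sum(mono & !is.na(k) & k == n)
  }
  if (!include_invariant) {
    counts[c(1, n + 1)] <- 0
  }
  sfs(counts, n)
}

#' Wilcoxon rank-sum comparison of window statistics
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test comparing a region's
#' non-overlapping window values against a chromosome-wide baseline, exact for
#' small tie-free samples and normal-approximated with tie correction
#' otherwise.
#'
#' @param region_values numeric window statistics of the focal region.
#' @param baseline_values numeric window statistics of the baseline.
#' @return one-row tibble with `statistic` (W) and `p_value`.
#' @export
wilcoxon_window_test <- function(region_values, baseline_values) {
  if (!length(region_values) || !length(baseline_values)) {
    abort("both inputs must be non-empty")
  }
  wt <- suppressWarnings(wilcox.test(region_values, baseline_values,
                                     alternative = "two.sided"))
  p <- wt$p.value
  if (is.nan(p)) p <- 1  # fully tied data carry no evidence either way
  tibble(statistic = unname(wt$statistic), p_value = min(p, 1))
}

#' Binomial clustering test for derived alleles
#'
#' Upper-tail probability that at least `observed_in_segment` of `m` derived
#' alleles fall inside a segment covering a fraction `f` of the region,
#' under uniform placement: `P(X >= observed)` for `X ~ Binomial(m, f)`.
#'
#' @param m total number of derived alleles in the region.
#' @param observed_in_segment number observed inside the segment.
#' @param f fraction of the region covered by the segment, in (0, 1].
#' @return upper-tail probability.
#' @export
binomial_cluster_test <- function(m, observed_in_segment, f) {
  if (f <= 0 || f > 1) abort("f must be in (0, 1]")
  if (observed_in_segment < 0 || observed_in_segment > m) {
    abort("observed_in_segment must be in [0, m]")
  }
  pbinom(observed_in_segment - 1, m, f, lower.tail = FALSE)
}
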