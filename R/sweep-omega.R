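#' Squared allelic correlation between two biallelic sites
#'
#' `r^2 = D^2 / (p_A (1 - p_A) p_B (1 - p_B))` computed on pairwise-complete
#' haplotypes (rows missing at either site are dropped).
#'
#' @param col_i,col_j 0/1/NA vectors over the same haplotypes.
#' @return r-squared in `[0, 1]`, or `NA` when either site is monomorphic on
#'   the shared non-missing rows.
#' @export
r2_pair <- function(col_i, col_j) {
  ok <- !is.na(col_i) & !is.na(col_j)
  if (sum(ok) < 2) return(NA_real_)
  a <- col_i[ok]; b <- col_j[ok]
  pa <- mean(a); pb <- mean(b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) return(NA_real_)
  pab <- mean(a * b)
  (pab - pa * pb)^2 / (pa * (1 - pa) * pb * (1 - pb))
}

#' Pairwise r-squared matrix of a haplotype matrix
#'
#' @param hap 0/1/NA matrix, haplotypes in rows, sites in columns.
#' @return symmetric matrix of [r2_pair()] values with unit diagonal;
#'   undefined pairs are `NA`.
#' @export
r2_matrix <- function(hap) {
  S <- ncol(hap)
  m <- matrix(NA_real_, S, S)
  if (!anyNA(hap)) {
    # complete data: correlation squared equals the count-based definition
    v <- apply(hap, 2L, stats::var)
    poly <- v > 0
    if (any(poly)) {
      cc <- suppressWarnings(stats::cor(hap[, poly, drop = FALSE]))
      m[poly, poly] <- cc^2
    }
  } else {
    for (i in seq_len(S)) {
      for (j in seq_len(S)) {
        if (j > i) m[i, j] <- r2_pair(hap[, i], hap[, j])
      }
    }
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
  }
  diag(m) <- 1
  m
}

#' Omega statistic for a fixed block split
#'
#' Ratio of the average r-squared within the two site blocks (sites `1..l`
#' and `l+1..S`) to the average r-squared between them, with combinatorial
#' pair counts as denominators. Undefined (`NA`) pairs contribute zero to the
#' sums. Returns `Inf` when the between-block sum is zero while the
#' within-block sum is positive.
#'
#' @param r2 symmetric r-squared matrix over `S` sites.
#' @param l split point: the left block is sites `1..l`; `2 <= l <= S - 2`.
#' @return omega.
#' @export
omega_at_split <- function(r2, l) {
  S <- nrow(r2)
  if (l < 2 || l > S - 2) abort("need 2 <= l <= S - 2")
  left <- seq_len(l); right <- (l + 1):S
  ut <- function(m) m[upper.tri(m)]
  w_sum <- sum(ut(r2[left, left, drop = FALSE]), na.rm = TRUE) +
    sum(ut(r2[right, right, drop = FALSE]), na.rm = TRUE)
  b_sum <- sum(r2[left, right, drop = FALSE], na.rm = TRUE)
  n_w <- choose(l, 2) + choose(S - l, 2)
  n_b <- l * (S - l)
  num <- w_sum / n_w
  den <- b_sum / n_b
  if (den > 0) num / den else if (num > 0) Inf else NaN
}

omega_window_sizes <- function(min_window, max_window) {
  sizes <- min_window * sqrt(2)^(0:floor(2 * log2(max_window / min_window)))
  sizes <- sizes[sizes < max_window]
  c(sizes, max_window)
}

# admissible (left, right) flank half-widths: each flank border moves over a
# geometric ladder, the total window size stays within [min, max]; ordered
# smallest-total first so argmax ties prefer the smaller window
omega_half_widths <- function(min_window, max_window) {
  h <- omega_window_sizes(min_window, max_window) / 2
  grid <- expand.grid(left = h, right = h)
  tot <- grid$left + grid$right
  keep <- tot >= min_window & tot <= max_window
  grid <- grid[keep, ]
  grid <- grid[order(tot[keep], grid$left), ]
  as.matrix(grid)
}

omega_scan_core <- function(positions, hap, L, grid_size = 1000,
                            min_window = 2000, max_window = 10000) {
  r2 <- r2_matrix(hap)
  r2[is.na(r2)] <- 0
  diag(r2) <- 0
  centers <- seq(1, L, length.out = grid_size)
  halves <- omega_half_widths(min_window, max_window)
  res <- sv_omega_scan_cpp(as.numeric(positions), r2, centers, halves)
  tbl <- tibble(position = centers, value = res$value, window = res$window,
                split_after = res$split_after, n_sites = res$n_sites)
  new_scan_result(tbl, "omega")
}

#' Extract a population's biallelic haplotype matrix
#'
#' Builds the 0/1 haplotype matrix of a population's segregating sites from a
#' region alignment: biallelic (within the population) non-gap columns with
#' minor-allele count at least `mac_min`; the first allele observed is coded
#' 0 (omega is invariant to the coding). Missing calls are `NA`.
#'
#' @param aln a [region_alignment()].
#' @param population population tag.
#' @param mac_min minimum minor-allele count (default 2: singletons carry no
#'   linkage signal).
#' @return 0/1 matrix with site positions (alignment columns) as `positions`
#'   attribute.
#' @export
haplotype_matrix <- function(aln, population, mac_min = 2) {
  rows <- which(aln$population == population)
  sub <- aln$mat[rows, , drop = FALSE]
  bases <- c("A", "C", "G", "T")
  keep <- integer(0)
  cols <- list()
  for (j in seq_len(ncol(sub))) {
    v <- sub[, j]
    if (any(v == "-")) next
    obs <- v[v %in% bases]
    al <- unique(obs)
    if (length(al) != 2) next
    cnt <- c(sum(obs == al[1]), sum(obs == al[2]))
    if (min(cnt) < mac_min) next
    x <- rep(NA_integer_, length(v))
    x[v == al[1]] <- 0L
    x[v == al[2]] <- 1L
    keep <- c(keep, j)
    cols[[length(cols) + 1L]] <- x
  }
  m <- if (length(cols)) do.call(cbind, cols) else
    matrix(integer(0), nrow = length(rows), ncol = 0)
  attr(m, "positions") <- keep
  m
}

#' Omega linkage-disequilibrium sweep scan
#'
#' For every grid center, the candidate sweep position splits the usable sites
#' into a left and a right flanking block and omega is maximized jointly over
#' the outer borders of the two flanks, which vary independently over a
#' geometric ladder of half-widths keeping the total window size between
#' `min_window` and `max_window`; each flank must hold at least two sites.
#' Ties prefer the smaller window, then the leftmost center. Sites with
#' minor-allele count below `mac_min` are excluded.
#'
#' @param x a [region_alignment()], an `sv_sim_replicate`, or a 0/1 haplotype
#'   matrix with a `positions` attribute (or passed via `positions`).
#' @param population focal population tag (alignment/replicate methods).
#' @param min_window,max_window window-size search range in bp.
#' @param grid_size number of grid centers.
#' @param mac_min minimum minor-allele count.
#' @param ... passed between methods.
#' @return an `sv_scan_result` with per-center `value` (max omega), the
#'   optimizing `window` size, `split_after` position and `n_sites`.
#' @export
omega_scan <- function(x, ..., min_window = 2000, max_window = 10000,
                       grid_size = 1000, mac_min = 2) {
  UseMethod("omega_scan")
}

#' @rdname omega_scan
#' @export
omega_scan.region_alignment <- function(x, population, ...,
                                        min_window = 2000, max_window = 10000,
                                        grid_size = 1000, mac_min = 2) {
  hap <- haplotype_matrix(x, population, mac_min)
  if (ncol(hap) < 4) {
    abort("fewer than 4 usable segregating sites", class = "sv_empty_result")
  }
  omega_scan_core(attr(hap, "positions"), hap, x$L, grid_size, min_window,
                  max_window)
}

#' @rdname omega_scan
#' @export
omega_scan.sv_sim_replicate <- function(x, population = "EU", ...,
                                        min_window = 2000, max_window = 10000,
                                        grid_size = 1000, mac_min = 2) {
  hap <- sim_haplotypes(x, population)
  n <- nrow(hap)
  k <- if (ncol(hap)) colSums(hap) else integer(0)
  keep <- k >= mac_min & k <= n - mac_min
  if (sum(keep) < 4) {
    abort("fewer than 4 usable segregating sites", class = "sv_empty_result")
  }
  omega_scan_core(x$positions[keep], hap[, keep, drop = FALSE], x$L,
                  grid_size, min_window, max_window)
}

#' @rdname omega_scan
#' @param positions site positions in bp (matrix method; defaults to the
#'   matrix's `positions` attribute).
#' @param L region length in bp (matrix method; defaults to the last position).
#' @export
omega_scan.matrix <- function(x, positions = attr(x, "positions"), L = NULL,
                              ..., min_window = 2000, max_window = 10000,
                              grid_size = 1000, mac_min = 2) {
  if (is.null(positions)) abort("site positions are required")
  if (is.null(L)) L <- max(positions)
  if (ncol(x) < 4) {
    abort("fewer than 4 usable segregating sites", class = "sv_empty_result")
  }
  omega_scan_core(positions, x, L, grid_size, min_window, max_window)
}
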