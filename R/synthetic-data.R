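#' Sweep specification for the region generator
#'
#' @param position sweep position in bp within the region.
#' @param alpha per-bp escape-rate parameter (> 0); the mean escape distance
#'   is `1/alpha` bp. The default corresponds to a strong sweep with a mean
#'   escape distance of 5 kb.
#' @param population tag of the swept population.
#' @return a `sweep_spec` list.
#' @export
sweep_spec <- function(position = 10006, alpha = 2e-4, population = "EU") {
  if (alpha <= 0) abort("alpha must be positive")
  structure(list(position = position, alpha = alpha, population = population),
            class = "sweep_spec")
}

frag_summaries <- function(k, n, L) {
  # per-fragment summaries from derived counts of one population
  seg <- k >= 1 & k <= n - 1
  S <- sum(seg)
  ks <- k[seg]
  pi_total <- sum(2 * ks * (n - ks) / (n * (n - 1)))
  list(S = S, pi = pi_total / L, tajima_d = tajimas_d(S, pi_total, n))
}

#' Generate a multi-fragment genome-scan dataset
#'
#' Simulates `n_fragments` independent short loci under the demographic model
#' and summarizes each fragment per population (`S`, per-site `pi`, Tajima's
#' D, undefined when `S = 0`). Defaults emulate an X-chromosome scan of 250
#' fragments of 500 bp in three population samples of 12 lines.
#'
#' @param model a [demographic_model()].
#' @param n_fragments number of fragments.
#' @param frag_len fragment length in bp.
#' @param samples named haploid sample sizes.
#' @param seed optional integer seed.
#' @param keep_haplotypes keep the simulated replicates (memory-heavy for
#'   large scans) in the result's `replicates` attribute.
#' @return an `sv_fragment_dataset`: tibble with one row per fragment and
#'   population (`fragment`, `population`, `n`, `L`, `S`, `pi`, `tajima_d`).
#' @export
generate_genome_scan <- function(model, n_fragments = 250, frag_len = 500,
                                 samples = c(AF = 12, EU = 12, AS = 12),
                                 seed = NULL, keep_haplotypes = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  ss <- normalize_samples(samples)
  pops <- names(ss)[ss > 0]
  reps <- vector("list", if (keep_haplotypes) n_fragments else 0L)
  rows <- vector("list", n_fragments)
  for (f in seq_len(n_fragments)) {
    rep_f <- simulate_region(model, ss, frag_len)
    if (keep_haplotypes) reps[[f]] <- rep_f
    rows[[f]] <- purrr::map_dfr(pops, function(p) {
      hap <- sim_haplotypes(rep_f, p)
      k <- if (ncol(hap)) colSums(hap) else integer(0)
      sm <- frag_summaries(k, ss[[p]], frag_len)
      tibble(fragment = f, population = p, n = ss[[p]], L = frag_len,
             S = sm$S, pi = sm$pi, tajima_d = sm$tajima_d)
    })
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "samples") <- ss
  if (keep_haplotypes) attr(out, "replicates") <- reps
  class(out) <- c("sv_fragment_dataset", class(out))
  out
}

random_other_base <- function(base, n = length(base)) {
  bases <- c("A", "C", "G", "T")
  vapply(seq_len(n), function(i) sample(setdiff(bases, base[[i]]), 1),
         character(1))
}

#' Generate a contiguous region alignment with outgroup
#'
#' Simulates neutral haplotypes for the sampled populations under the
#' demographic model, synthesizes nucleotide states (ancestral allele uniform
#' on A/C/G/T per column, derived allele uniform on the remaining three), adds
#' an outgroup sequence carrying independent substitutions at the given
#' divergence, and optionally injects a selective sweep into one population:
#' per haplotype, left and right escape breakpoints are drawn at
#' Exponential(`alpha`) distances from the sweep position and the enclosed
#' interval is replaced by a single shared swept founder haplotype.
#' Non-swept populations are never altered.
#'
#' @param model a [demographic_model()].
#' @param L region length in bp.
#' @param samples named haploid sample sizes.
#' @param outgroup_divergence per-site substitution probability of the
#'   outgroup relative to the ancestral sequence, in (0, 0.25).
#' @param sweep a [sweep_spec()], or `NULL` for a neutral region.
#' @param seed optional integer seed.
#' @param region_offset absolute coordinate of column 1.
#' @return a [region_alignment()] with labels `E01..`/`A01..`/`S01..` and an
#'   outgroup; the generating truth (sweep spec, site positions) is attached
#'   as attribute `truth`.
#' @export
generate_sweep_region <- function(model, L = 20011,
                                  samples = c(AF = 12, EU = 12),
                                  outgroup_divergence = 0.06, sweep = NULL,
                                  seed = NULL, region_offset = 14810552) {
  if (outgroup_divergence <= 0 || outgroup_divergence >= 0.25) {
    abort("outgroup_divergence must be in (0, 0.25)")
  }
  if (!is.null(seed)) set.seed(seed)
  ss <- normalize_samples(samples)
  rep_r <- simulate_region(model, ss, L)
  G <- rep_r$genotypes
  pos <- sim_positions_bp(rep_r)
  # nucleotide states are drawn before the sweep transform so that, under a
  # fixed seed, injection changes only the swept population's genotypes
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, L, replace = TRUE)
  derived <- random_other_base(anc[pos])
  outg <- anc
  sub <- runif(L) < outgroup_divergence
  outg[sub] <- random_other_base(anc[sub], sum(sub))
  if (!is.null(sweep)) {
    stopifnot(inherits(sweep, "sweep_spec"))
    if (!sweep$population %in% rep_r$pop) {
      abort("sweep population is not sampled", class = "sv_spec_error")
    }
    rows <- which(rep_r$pop == sweep$population)
    founder <- G[rows[1], ]
    for (rix in rows) {
      lo <- sweep$position - rexp(1, sweep$alpha)
      hi <- sweep$position + rexp(1, sweep$alpha)
      inside <- pos > lo & pos < hi
      G[rix, inside] <- founder[inside]
    }
  }
  n_in <- sum(ss)
  mat <- matrix(rep(anc, each = n_in), nrow = n_in)
  for (j in seq_along(pos)) {
    carriers <- G[, j] == 1L
    mat[carriers, pos[j]] <- derived[j]
  }
  labels <- c(sprintf("A%02d", seq_len(ss[["AF"]])),
              sprintf("E%02d", seq_len(ss[["EU"]])),
              sprintf("S%02d", seq_len(ss[["AS"]])), "outgroup")
  seqs <- c(apply(mat, 1L, paste0, collapse = ""), paste0(outg, collapse = ""))
  aln <- region_alignment(seqs, labels,
                          c(rep_r$pop, "outgroup"), region_offset)
  attr(aln, "truth") <- list(sweep = sweep, positions = pos,
                             derived = derived, seed = seed)
  aln
}

# Table-2-style fixed-difference configurations: outgroup / Africa / Europe
# alleles for 11 substitutions plus one fixed insertion private to Europe.
TABLE2_CONFIG <- data.frame(
  outgroup = c("G", "T", "C", "G", "A", "A", "G", "G", "C", "C", "C", "-"),
  africa   = c("G", "C", "T", "G", "A", "A", "G", "G", "T", "C", "C", "-"),
  europe   = c("A", "T", "C", "A", "G", "C", "T", "A", "C", "T", "A", "T"),
  stringsAsFactors = FALSE
)

#' Deterministic fixed-difference fixture alignment
#'
#' A 24-ingroup (12 European, 12 African) plus one outgroup alignment in which
#' exactly twelve fixed-difference configurations occur at known columns:
#' eleven nucleotide substitutions (eight derived-private European, three
#' derived-private African) and one fixed insertion present only in the
#' European sample; all other columns are monomorphic across all sequences.
#'
#' @param spacing distance between consecutive event columns.
#' @return a [region_alignment()] with the event columns recorded in the
#'   `truth` attribute.
#' @export
table2_fixture <- function(spacing = 15L) {
  n_ev <- nrow(TABLE2_CONFIG)
  L <- spacing * (n_ev + 1)
  cols <- spacing * seq_len(n_ev)
  bases <- c("A", "C", "G", "T")
  bg <- bases[(seq_len(L) - 1L) %% 4L + 1L]
  eu <- af <- og <- bg
  og[cols] <- TABLE2_CONFIG$outgroup
  af[cols] <- TABLE2_CONFIG$africa
  eu[cols] <- TABLE2_CONFIG$europe
  seqs <- c(rep(paste0(eu, collapse = ""), 12),
            rep(paste0(af, collapse = ""), 12),
            paste0(og, collapse = ""))
  labels <- c(sprintf("E%02d", 1:12), sprintf("A%02d", 1:12), "outgroup")
  aln <- region_alignment(seqs, labels,
                          c(rep("EU", 12), rep("AF", 12), "outgroup"),
                          region_offset = 14810552)
  attr(aln, "truth") <- list(columns = cols, config = TABLE2_CONFIG)
  aln
}
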