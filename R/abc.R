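ABC_PARAMS <- c("N_afr_cur", "N_eur_cur", "N_asia_cur", "N_eur_bot",
                "N_asia_bot", "T_exit", "T_asia", "T_afr_exp", "N_afr_anc")

#' Default priors for the demographic parameters
#'
#' Independent log-uniform priors per parameter (sizes in diploid
#' individuals, times in years). The default ranges span the fitted model's
#' 95% credibility intervals widened by a factor 3 on each side; draws are
#' additionally constrained to `T_exit > T_asia`.
#'
#' @param widen multiplicative widening of the interval bounds.
#' @return tibble with `parameter`, `dist`, `low`, `high`.
#' @export
default_priors <- function(widen = 3) {
  ci <- list(N_afr_cur = c(2392436, 28700928), N_eur_cur = c(760318, 4866692),
             N_asia_cur = c(91417, 4540468), N_eur_bot = c(10898, 87811),
             N_asia_bot = c(3554, 90142), T_exit = c(7700, 36616),
             T_asia = c(1194, 7518), T_afr_exp = c(2383, 369569),
             N_afr_anc = c(580795, 2457912))
  purrr::map_dfr(ABC_PARAMS, function(p) {
    tibble(parameter = p, dist = "loguniform",
           low = ci[[p]][1] / widen, high = ci[[p]][2] * widen)
  })
}

draw_from_priors <- function(priors, n) {
  draws <- purrr::map(seq_len(nrow(priors)), function(i) {
    lo <- priors$low[i]; hi <- priors$high[i]
    if (priors$dist[i] == "loguniform") {
      exp(runif(n, log(lo), log(hi)))
    } else {
      runif(n, lo, hi)
    }
  })
  m <- do.call(cbind, draws)
  colnames(m) <- priors$parameter
  # enforce the ordering constraint of the model by joint redraw
  bad <- which(m[, "T_exit"] <= m[, "T_asia"])
  while (length(bad)) {
    sub <- draw_from_priors(priors, length(bad))
    m[bad, ] <- as.matrix(sub)
    bad <- bad[m[bad, "T_exit"] <= m[bad, "T_asia"]]
  }
  as_tibble(m)
}

params_to_model <- function(par, template = demographic_model()) {
  demographic_model(N_afr_cur = par[["N_afr_cur"]],
                    N_eur_cur = par[["N_eur_cur"]],
                    N_asia_cur = par[["N_asia_cur"]],
                    N_eur_bot = par[["N_eur_bot"]],
                    N_asia_bot = par[["N_asia_bot"]],
                    N_afr_anc = par[["N_afr_anc"]],
                    T_exit = par[["T_exit"]], T_asia = par[["T_asia"]],
                    T_afr_exp = par[["T_afr_exp"]],
                    gen_per_year = template$gen_per_year, mu = template$mu,
                    r = template$r)
}

#' Summary vector of a fragment dataset
#'
#' Per population, in a fixed order: mean and variance across fragments of
#' per-site pi, mean and variance of Tajima's D over fragments where it is
#' defined (`S >= 1`), mean `S`, and the number of monomorphic fragments
#' (`S = 0`). Monomorphic-fragment counts carry drift information that the
#' moment summaries discard, which is why they are part of the vector.
#'
#' @param data an `sv_fragment_dataset` (or any tibble with columns
#'   `fragment`, `population`, `S`, `pi`, `tajima_d`).
#' @return named numeric vector
#'   (`<pop>_pi_mean`, `<pop>_pi_var`, `<pop>_D_mean`, `<pop>_D_var`,
#'   `<pop>_S_mean`, `<pop>_n_monomorphic`, populations in dataset order).
#' @export
summarize_fragments <- function(data) {
  if (!nrow(data)) abort("empty fragment dataset")
  pops <- unique(data$population)
  out <- purrr::map(pops, function(p) {
    d <- data[data$population == p, ]
    dd <- d$tajima_d[d$S >= 1]
    v <- c(mean(d$pi), stats::var(d$pi),
           if (length(dd)) mean(dd) else 0,
           if (length(dd) > 1) stats::var(dd) else 0,
           mean(d$S), sum(d$S == 0))
    setNames(v, paste0(p, c("_pi_mean", "_pi_var", "_D_mean", "_D_var",
                            "_S_mean", "_n_monomorphic")))
  })
  unlist(out)
}

#' Build an ABC reference table of prior draws and simulated summaries
#'
#' Draws parameter vectors from the priors, simulates a fragment dataset per
#' draw under the demographic model (mutation and recombination rates and the
#' generation time come from `template`), and records the summary vector.
#'
#' @param priors prior table as in [default_priors()].
#' @param n_sims number of prior draws.
#' @param n_fragments,frag_len,samples fragment-panel design.
#' @param template [demographic_model()] supplying fixed rates.
#' @param seed optional integer seed.
#' @return list with `params` (tibble of draws) and `summaries` (matrix).
#' @export
abc_reference_table <- function(priors, n_sims, n_fragments = 250,
                                frag_len = 500,
                                samples = c(AF = 12, EU = 12, AS = 12),
                                template = demographic_model(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  params <- draw_from_priors(priors, n_sims)
  summaries <- NULL
  for (i in seq_len(n_sims)) {
    model <- params_to_model(as.list(params[i, ]), template)
    sm <- fast_scan_summaries(model, n_fragments, frag_len, samples)
    if (is.null(summaries)) {
      summaries <- matrix(NA_real_, n_sims, length(sm),
                          dimnames = list(NULL, names(sm)))
    }
    summaries[i, ] <- sm
  }
  list(params = params, summaries = summaries)
}

# summary vector of a simulated fragment panel without materializing the tidy
# per-fragment dataset; numerically identical to
# summarize_fragments(generate_genome_scan(...)) under the same RNG state
fast_scan_summaries <- function(model, n_fragments, frag_len, samples) {
  ss <- normalize_samples(samples)
  pops <- names(ss)[ss > 0]
  kc <- lapply(pops, function(p) stat_constants(ss[[p]]))
  names(kc) <- pops
  pi_m <- S_m <- D_m <- matrix(NA_real_, n_fragments, length(pops),
                               dimnames = list(NULL, pops))
  for (f in seq_len(n_fragments)) {
    rep_f <- simulate_region(model, ss, frag_len)
    for (p in pops) {
      n <- ss[[p]]
      hap <- rep_f$genotypes[rep_f$pop == p, , drop = FALSE]
      k <- if (ncol(hap)) colSums(hap) else integer(0)
      k <- k[k >= 1 & k <= n - 1]
      S <- length(k)
      pi_total <- sum(2 * k * (n - k) / (n * (n - 1)))
      S_m[f, p] <- S
      pi_m[f, p] <- pi_total / frag_len
      D_m[f, p] <- if (S == 0) NA_real_ else {
        co <- kc[[p]]
        (pi_total - S / co$a1) / sqrt(co$e1 * S + co$e2 * S * (S - 1))
      }
    }
  }
  out <- lapply(pops, function(p) {
    dd <- D_m[!is.na(D_m[, p]), p]
    v <- c(mean(pi_m[, p]), stats::var(pi_m[, p]),
           if (length(dd)) mean(dd) else 0,
           if (length(dd) > 1) stats::var(dd) else 0,
           mean(S_m[, p]), sum(S_m[, p] == 0))
    setNames(v, paste0(p, c("_pi_mean", "_pi_var", "_D_mean", "_D_var",
                            "_S_mean", "_n_monomorphic")))
  })
  unlist(out)
}

#' Rejection ABC for the demographic parameters
#'
#' Plain rejection: parameters are drawn from the priors, a fragment panel is
#' simulated per draw, summaries are standardized by the simulated pool's
#' median absolute deviation, and the draws with the smallest Euclidean
#' distance to the observed summary vector are accepted. Summary coordinates
#' with zero spread across the pool are dropped with a warning.
#'
#' @param observed observed summary vector ([summarize_fragments()]).
#' @param priors prior table as in [default_priors()].
#' @param n_sims number of prior simulations (ignored when `ref` is given).
#' @param accept_fraction fraction of draws accepted.
#' @param seed optional integer seed.
#' @param ref optional precomputed [abc_reference_table()]; when supplied the
#'   expensive simulation step is skipped.
#' @param ... passed to [abc_reference_table()].
#' @return an `sv_abc_posterior`: list with `accepted` (tibble of parameter
#'   draws with distances, sorted), `tolerance` (largest accepted distance),
#'   `n_sims` and `accept_fraction`.
#' @export
abc_reject <- function(observed, priors = default_priors(), n_sims = 20000,
                       accept_fraction = 0.005, seed = NULL, ref = NULL, ...) {
  if (is.null(ref)) {
    if (n_sims < 1 / accept_fraction) {
      abort("n_sims too small for the acceptance fraction")
    }
    ref <- abc_reference_table(priors, n_sims, seed = seed, ...)
  }
  sm <- ref$summaries
  common <- intersect(names(observed), colnames(sm))
  sm <- sm[, common, drop = FALSE]
  obs <- observed[common]
  mads <- apply(sm, 2L, stats::mad)
  if (any(mads == 0)) {
    drop <- colnames(sm)[mads == 0]
    warn(paste0("dropping zero-spread summaries: ", paste(drop, collapse = ", ")))
    sm <- sm[, mads > 0, drop = FALSE]
    obs <- obs[mads > 0]
    mads <- mads[mads > 0]
  }
  z <- sweep(sm, 2L, mads, `/`)
  zo <- obs / mads
  dist <- sqrt(rowSums(sweep(z, 2L, zo, `-`)^2))
  n_acc <- max(1L, ceiling(accept_fraction * nrow(sm)))
  ord <- order(dist)[seq_len(n_acc)]
  acc <- ref$params[ord, ]
  acc$distance <- dist[ord]
  structure(list(accepted = acc, tolerance = max(acc$distance),
                 n_sims = nrow(sm), accept_fraction = accept_fraction),
            class = "sv_abc_posterior")
}

#' @export
print.sv_abc_posterior <- function(x, ...) {
  cat("<sv_abc_posterior>", nrow(x$accepted), "accepted of", x$n_sims,
      "simulations (tolerance", format(x$tolerance, digits = 3), ")\n")
  print(posterior_report(x))
  invisible(x)
}

#' Posterior report: modes and credibility intervals
#'
#' Marginal posterior mode (argmax of a Gaussian kernel density with
#' Silverman bandwidth on the accepted draws) and 2.5%/97.5% quantiles per
#' parameter. Sizes are effective diploid individuals; times are years.
#'
#' @param post an `sv_abc_posterior` with at least 50 accepted draws.
#' @return tibble with `parameter`, `mode`, `q2.5`, `q97.5`.
#' @export
posterior_report <- function(post) {
  acc <- post$accepted
  if (nrow(acc) < 50) {
    abort("too few accepted draws for a reliable report",
          class = "sv_reliability_error")
  }
  purrr::map_dfr(intersect(ABC_PARAMS, names(acc)), function(p) {
    v <- acc[[p]]
    mode <- if (length(unique(v)) == 1) {
      v[1]
    } else {
      dd <- density(v)
      dd$x[which.max(dd$y)]
    }
    qs <- quantile(v, c(0.025, 0.975), names = FALSE)
    tibble(parameter = p, mode = mode, q2.5 = qs[1], q97.5 = qs[2])
  })
}

#' @exportS3Method generics::tidy
tidy.sv_abc_posterior <- function(x, ...) {
  tidyr::pivot_longer(x$accepted, cols = dplyr::all_of(intersect(ABC_PARAMS, names(x$accepted))),
                      names_to = "parameter", values_to = "value")
}

#' @exportS3Method generics::glance
glance.sv_abc_posterior <- function(x, ...) {
  tibble(n_sims = x$n_sims, n_accepted = nrow(x$accepted),
         accept_fraction = x$accept_fraction, tolerance = x$tolerance)
}

#' @exportS3Method ggplot2::autoplot
autoplot.sv_abc_posterior <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 20) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "parameter value (log scale)", y = "accepted draws") +
    ggplot2::theme_minimal()
}
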