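#' Population-labeled region alignments
#'
#' A `region_alignment` holds equal-length haplotype sequences sampled from one
#' or more populations, optionally together with a single outgroup sequence used
#' to polarize variants, plus the absolute genomic coordinate of the first
#' alignment column. Symbols are restricted to `A,C,G,T,-,N`; `N` marks missing
#' data, `-` an alignment gap.
#'
#' @param sequences character vector of equal-length nucleotide strings.
#' @param labels per-sequence sample identifiers (unique).
#' @param population per-sequence population tag; the tag `"outgroup"` is
#'   reserved for the (at most one) outgroup sequence.
#' @param region_offset absolute genomic coordinate of alignment column 1.
#' @return An object of class `region_alignment`: a list with a character
#'   matrix `mat` (sequences in rows), `labels`, `population`, `region_offset`
#'   and alignment length `L`.
#' @examples
#' aln <- region_alignment(c("ACGT", "ACGA", "ACGA"), c("E1", "A1", "out"),
#'                         c("EU", "AF", "outgroup"))
#' aln$L
#' @export
region_alignment <- function(sequences, labels, population, region_offset = 1L) {
  stopifnot(length(sequences) >= 1, length(labels) == length(sequences),
            length(population) == length(sequences))
  if (anyDuplicated(labels)) abort("sequence labels must be unique")
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    abort("all sequences must have equal length", class = "sv_alignment_shape_error")
  }
  L <- lens[[1]]
  if (L < 1) abort("alignment length must be >= 1", class = "sv_alignment_shape_error")
  if (sum(population == "outgroup") > 1) {
    abort("at most one outgroup sequence is allowed", class = "sv_configuration_error")
  }
  if (!any(population != "outgroup")) abort("at least one ingroup sequence is required")
  if (region_offset < 0) abort("region_offset must be non-negative")
  mat <- matrix(unlist(strsplit(sequences, "", fixed = TRUE), use.names = FALSE),
                nrow = length(sequences), ncol = L, byrow = TRUE)
  # ambiguity codes and anything unexpected count as missing
  mat[!(mat %in% c("A", "C", "G", "T", "-"))] <- "N"
  rownames(mat) <- labels
  structure(list(mat = mat, labels = labels,
                 population = setNames(as.character(population), labels),
                 region_offset = as.integer(region_offset), L = as.integer(L)),
            class = "region_alignment")
}

#' @export
print.region_alignment <- function(x, ...) {
  pops <- table(x$population)
  cat("<region_alignment> ", nrow(x$mat), " sequences x ", x$L, " columns\n", sep = "")
  cat("  populations:", paste0(names(pops), "=", pops, collapse = ", "), "\n")
  cat("  region offset:", x$region_offset, "\n")
  invisible(x)
}

#' Ingroup population tags of an alignment
#' @param aln a [region_alignment()].
#' @return character vector of ingroup population tags, in order of appearance.
#' @export
ingroup_populations <- function(aln) {
  unique(unname(aln$population[aln$population != "outgroup"]))
}

#' Read a population-labeled FASTA alignment
#'
#' Reads a multi-FASTA alignment and attaches population tags via a label-to-tag
#' map. Sequences are uppercased; `N` and ambiguity codes become missing.
#'
#' @param path path to a FASTA file.
#' @param population_map either a named character vector (`label -> tag`) or a
#'   two-column data frame with columns `label` and `tag`. The tag `"outgroup"`
#'   marks the outgroup sequence.
#' @param region_offset absolute coordinate of alignment column 1.
#' @return a [region_alignment()].
#' @export
read_alignment <- function(path, population_map, region_offset = 1L) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (is.data.frame(population_map)) {
    population_map <- setNames(as.character(population_map$tag),
                               population_map$label)
  }
  seqs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) abort(paste0("not a readable FASTA file: ", path),
                                             class = "sv_format_error"))
  if (length(seqs) == 0) abort("empty FASTA file", class = "sv_format_error")
  labels <- sub("\\s.*$", "", names(seqs))
  missing_lab <- setdiff(labels, names(population_map))
  if (length(missing_lab)) {
    abort(paste0("labels absent from population map: ",
                 paste(missing_lab, collapse = ", ")),
          class = "sv_configuration_error")
  }
  if (length(unique(Biostrings::width(seqs))) != 1L) {
    abort("FASTA records have unequal lengths", class = "sv_alignment_shape_error")
  }
  region_alignment(as.character(seqs), labels,
                   unname(population_map[labels]), region_offset)
}

#' Write an alignment to FASTA
#'
#' Inverse of [read_alignment()]: `read_alignment(write_alignment(aln, f), ...)`
#' reproduces `aln` exactly.
#'
#' @param aln a [region_alignment()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(aln$mat, 1L, paste0, collapse = "")
  x <- Biostrings::BStringSet(seqs)
  names(x) <- aln$labels
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Classify every alignment column
#'
#' Produces one record per alignment column: its kind (`monomorphic`,
#' `segregating`, `fixed_difference`, `indel`, `masked`), per-population allele
#' summaries, and the outgroup polarization. The polarization rule is
#' parsimony with a single outgroup: the ancestral allele is the one shared
#' with the outgroup, the derived allele the one absent from it; columns where
#' the outgroup is missing, gapped, or carries a third allele are left
#' unpolarized. A column is a `fixed_difference` when there are exactly two
#' ingroup populations, each internally fixed (at full call rate) for
#' different nucleotides. Any column containing a gap in an ingroup or the
#' outgroup sequence is kind `indel`; columns with no ingroup calls are
#' `masked`.
#'
#' @param aln a [region_alignment()].
#' @return a tibble of class `sv_site_table`, one row per column, with columns
#'   `column`, `abs_position`, `kind`, `outgroup_allele`, `derived_allele`, and
#'   per population `<tag>`: `n_<tag>` (called sample size), `allele_<tag>`
#'   (the fixed symbol if internally monomorphic else `NA`), `seg_<tag>`
#'   (polymorphic within the population), `het_<tag>` (unbiased per-site
#'   pairwise diversity), `derived_<tag>` (derived-allele count, `NA` when
#'   unpolarized), `mismatch_<tag>` (fraction of called alleles differing from
#'   the outgroup). Population tags and sample sizes are kept as attributes.
#' @export
classify_sites <- function(aln) {
  stopifnot(inherits(aln, "region_alignment"))
  pops <- ingroup_populations(aln)
  if (length(pops) < 1) abort("need at least one ingroup population")
  mat <- aln$mat
  L <- aln$L
  bases <- c("A", "C", "G", "T")
  out_row <- which(aln$population == "outgroup")
  outg <- if (length(out_row)) mat[out_row, ] else rep(NA_character_, L)
  outg[!is.na(outg) & !(outg %in% c(bases, "-"))] <- NA_character_

  # per-population base counts: list of 5 x L integer matrices (A,C,G,T,-)
  count_syms <- c(bases, "-")
  pop_counts <- lapply(pops, function(p) {
    rows <- which(aln$population == p)
    sub <- mat[rows, , drop = FALSE]
    do.call(rbind, lapply(count_syms, function(b) colSums(sub == b)))
  })
  names(pop_counts) <- pops
  nsizes <- vapply(pops, function(p) sum(aln$population == p), integer(1))

  all_counts <- Reduce(`+`, pop_counts)
  rownames(all_counts) <- count_syms
  base_counts_all <- all_counts[bases, , drop = FALSE]
  n_alleles_all <- colSums(base_counts_all > 0)
  any_gap <- all_counts["-", ] > 0 | (!is.na(outg) & outg == "-")
  any_call <- colSums(base_counts_all) > 0

  # combined-ingroup allele pair for polarization (<= 2 distinct bases)
  tc <- t(base_counts_all)
  top1 <- max.col(tc, ties.method = "first")
  tc2 <- tc
  tc2[cbind(seq_len(L), top1)] <- -1L
  top2 <- max.col(tc2, ties.method = "first")
  a1 <- bases[top1]; a2 <- bases[top2]
  a1[!any_call] <- NA_character_
  minor_present <- tc[cbind(seq_len(L), top2)] > 0
  a2[!minor_present] <- NA_character_

  outg_base <- ifelse(!is.na(outg) & outg %in% bases, outg, NA_character_)
  derived <- rep(NA_character_, L)
  ok2 <- n_alleles_all <= 2 & any_call & !is.na(outg_base)
  match1 <- ok2 & outg_base == a1
  match2 <- ok2 & !is.na(a2) & outg_base == a2
  # outgroup matches the (or a) segregating allele -> the other one is derived
  derived[match1 & !is.na(a2)] <- a2[match1 & !is.na(a2)]
  derived[match2] <- a1[match2]
  # monomorphic ingroup differing from the outgroup: ingroup allele is derived
  mono_div <- ok2 & is.na(a2) & outg_base != a1
  derived[mono_div] <- a1[mono_div]
  # monomorphic ingroup matching the outgroup: no derived allele, count 0
  mono_eq <- ok2 & is.na(a2) & outg_base == a1
  # biallelic ingroup with a third outgroup allele stays unpolarized

  res <- tibble(column = seq_len(L),
                abs_position = aln$region_offset + seq_len(L) - 1L,
                outgroup_allele = outg,
                derived_allele = derived)

  pop_fixed <- matrix(NA_character_, nrow = length(pops), ncol = L)
  pop_seg <- matrix(FALSE, nrow = length(pops), ncol = L)
  for (i in seq_along(pops)) {
    p <- pops[[i]]
    cnt <- pop_counts[[p]]
    bc <- cnt[seq_len(4), , drop = FALSE]
    ns <- colSums(bc)
    nal <- colSums(bc > 0)
    gaps <- cnt[5L, ]
    # fixed symbol on non-missing calls ('-' is a state for indel columns)
    fx <- rep(NA_character_, L)
    one_base <- nal == 1 & gaps == 0 & ns > 0
    fx[one_base] <- bases[max.col(t(bc[, one_base, drop = FALSE]),
                                  ties.method = "first")]
    all_gap <- nal == 0 & gaps > 0
    fx[all_gap] <- "-"
    pop_fixed[i, ] <- fx
    pop_seg[i, ] <- nal >= 2
    het <- rep(0, L)
    use <- ns >= 2
    sumsq <- colSums(bc^2)
    het[use] <- (ns[use] / (ns[use] - 1)) * (1 - sumsq[use] / ns[use]^2)
    dv <- rep(NA_real_, L)
    has_d <- !is.na(derived)
    dv[has_d] <- bc[cbind(match(derived[has_d], bases), which(has_d))]
    dv[mono_eq] <- 0
    mm <- rep(NA_real_, L)
    has_o <- !is.na(outg_base) & ns > 0
    out_cnt <- rep(0, L)
    out_cnt[has_o] <- bc[cbind(match(outg_base[has_o], bases), which(has_o))]
    mm[has_o] <- (ns[has_o] - out_cnt[has_o]) / ns[has_o]
    res[[paste0("n_", p)]] <- as.integer(ns)
    res[[paste0("allele_", p)]] <- fx
    res[[paste0("seg_", p)]] <- pop_seg[i, ]
    res[[paste0("het_", p)]] <- het
    res[[paste0("derived_", p)]] <- as.integer(round(dv))
    res[[paste0("mismatch_", p)]] <- mm
  }

  kind <- rep("monomorphic", L)
  kind[colSums(pop_seg) > 0 | n_alleles_all >= 2] <- "segregating"
  if (length(pops) == 2) {
    full <- res[[paste0("n_", pops[1])]] == nsizes[1] &
      res[[paste0("n_", pops[2])]] == nsizes[2]
    f1 <- pop_fixed[1L, ]; f2 <- pop_fixed[2L, ]
    fd <- !is.na(f1) & !is.na(f2) & f1 != f2 & f1 != "-" & f2 != "-" & full
    kind[fd] <- "fixed_difference"
  }
  kind[any_gap] <- "indel"
  kind[!any_call] <- "masked"
  res$kind <- kind
  res <- res[, c("column", "abs_position", "kind",
                 setdiff(names(res), c("column", "abs_position", "kind")))]
  attr(res, "populations") <- pops
  attr(res, "sample_sizes") <- nsizes
  attr(res, "region_offset") <- aln$region_offset
  attr(res, "L") <- L
  class(res) <- c("sv_site_table", class(res))
  res
}

sv_pops <- function(table) attr(table, "populations")
sv_nsizes <- function(table) attr(table, "sample_sizes")

#' Fixed differences between two population samples
#'
#' Extracts the columns at which the two ingroup populations are each
#' internally fixed for different states. Nucleotide substitutions and fixed
#' indels are reported separately; runs of consecutive fixed-indel columns are
#' merged into a single indel event. Each difference is polarized against the
#' outgroup: when one population shares the outgroup state, the other carries
#' the derived, private allele.
#'
#' @param table an `sv_site_table` from [classify_sites()] with exactly two
#'   ingroup populations.
#' @param min_call_rate minimum fraction of called (non-missing) alleles per
#'   population for a column to be eligible; the default 1 requires the state
#'   to be fixed in all sampled lines.
#' @return a tibble with columns `column`, `abs_position`, one allele column
#'   per population, `outgroup_allele`,
#'   `status` (`derived_private_<tag>` or `unpolarized`) and `is_indel`.
#' @export
fixed_differences <- function(table, min_call_rate = 1) {
  pops <- sv_pops(table)
  if (length(pops) != 2) {
    abort("fixed_differences requires exactly 2 ingroup populations",
          class = "sv_unsupported_design_error")
  }
  ns <- sv_nsizes(table)
  f1 <- table[[paste0("allele_", pops[1])]]
  f2 <- table[[paste0("allele_", pops[2])]]
  ok1 <- table[[paste0("n_", pops[1])]] >= min_call_rate * ns[1] |
    (!is.na(f1) & f1 == "-")
  ok2 <- table[[paste0("n_", pops[2])]] >= min_call_rate * ns[2] |
    (!is.na(f2) & f2 == "-")
  cand <- !is.na(f1) & !is.na(f2) & f1 != f2 & ok1 & ok2
  idx <- which(cand)
  if (!length(idx)) {
    return(tibble(column = integer(), abs_position = integer(),
                  !!paste0("allele_", pops[1]) := character(),
                  !!paste0("allele_", pops[2]) := character(),
                  outgroup_allele = character(), status = character(),
                  is_indel = logical()))
  }
  og <- table$outgroup_allele[idx]
  s1 <- f1[idx]; s2 <- f2[idx]
  status <- rep("unpolarized", length(idx))
  usable <- !is.na(og)
  status[usable & og == s1] <- paste0("derived_private_", pops[2])
  status[usable & og == s2] <- paste0("derived_private_", pops[1])
  is_indel <- s1 == "-" | s2 == "-"
  out <- tibble(column = table$column[idx],
                abs_position = table$abs_position[idx],
                !!paste0("allele_", pops[1]) := s1,
                !!paste0("allele_", pops[2]) := s2,
                outgroup_allele = og, status = status, is_indel = is_indel)
  # merge runs of adjacent indel columns into one event
  keep <- rep(TRUE, nrow(out))
  if (any(is_indel)) {
    prev_same <- c(FALSE, diff(out$column) == 1L & is_indel[-length(is_indel)] &
                     is_indel[-1] & out$status[-nrow(out)] == out$status[-1])
    keep[prev_same] <- FALSE
  }
  out[keep, ]
}

#' Count derived private substitutions
#'
#' Number of fixed nucleotide substitutions at which the given population
#' carries the derived (outgroup-absent) allele. Indel events are not counted.
#'
#' @param diffs result of [fixed_differences()].
#' @param population population tag.
#' @return integer count.
#' @export
count_derived_private <- function(diffs, population) {
  sum(!diffs$is_indel & diffs$status == paste0("derived_private_", population))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Open-reading-frame integrity check
#'
#' Checks, per sequence, whether the gap-stripped sequence from a declared
#' frame start forms an intact ORF: it must begin with `ATG`, have length
#' divisible by 3, and contain no in-frame stop codon before the final codon.
#' Defects are classified with the priority `no_start` > `frameshift`
#' (gap-stripped length not a multiple of 3) > `premature_stop`.
#'
#' @param coding_aln a [region_alignment()] covering the transcript.
#' @param frame_start alignment column at which the reading frame begins.
#' @return tibble with `label`, `population`, `status` (one of `intact`,
#'   `no_start`, `frameshift`, `premature_stop`) and `first_defect_codon`
#'   (codon index of the first premature stop, `NA` otherwise).
#' @export
orf_check <- function(coding_aln, frame_start = 1L) {
  stopifnot(inherits(coding_aln, "region_alignment"))
  if (frame_start < 1 || frame_start > coding_aln$L) {
    abort("frame_start outside the alignment")
  }
  mat <- coding_aln$mat[, frame_start:coding_aln$L, drop = FALSE]
  if (any(!(mat %in% c("A", "C", "G", "T", "-")))) {
    abort("non-nucleotide symbols in coding alignment", class = "sv_format_error")
  }
  one <- function(chars) {
    s <- chars[chars != "-"]
    len <- length(s)
    if (len < 3 || paste0(s[1:3], collapse = "") != "ATG") {
      return(list(status = "no_start", codon = NA_integer_))
    }
    if (len %% 3L != 0L) return(list(status = "frameshift", codon = NA_integer_))
    ncod <- len %/% 3L
    codons <- vapply(seq_len(ncod), function(i)
      paste0(s[(3 * i - 2):(3 * i)], collapse = ""), character(1))
    stops <- which(codons %in% STOP_CODONS)
    early <- stops[stops < ncod]
    if (length(early)) {
      return(list(status = "premature_stop", codon = early[[1]]))
    }
    list(status = "intact", codon = NA_integer_)
  }
  checks <- apply(mat, 1L, one)
  tibble(label = coding_aln$labels,
         population = unname(coding_aln$population),
         status = unname(vapply(checks, `[[`, character(1), "status")),
         first_defect_codon = unname(vapply(checks, `[[`, integer(1), "codon")))
}
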