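#' Feature family names
#'
#' The seven IDR descriptor families, in canonical order, with their fixed
#' dimensions 5, 20, 125, 125, 400, 400 and 400.
#'
#' @format Character vector of length 7.
#' @export
FEATURE_FAMILIES <- c("chemical_composition", "aa_composition",
                      "composition_dubchak", "occurrence_dubchak",
                      "sequence_bigrams", "alternate_bigrams",
                      "profile_bigrams")

check_nonempty <- function(res, what) {
  if (length(res) < 1L)
    stop(what, ": empty sequence (no standard residues)", call. = FALSE)
}

#' Chemical composition of an IDR
#'
#' Fractions of positively charged (R, K, H), negatively charged (D, E),
#' polar (S, T, N, Q, Y, C), hydrophobic (A, V, L, I, M, F, W) and special
#' (P, G) residues, in that fixed order. Histidine is counted with the
#' positively charged class so the five classes partition the alphabet and
#' the fractions sum to 1.
#'
#' @param seq An [idr_sequence()], a character scalar, or a vector of residue
#'   letters.
#' @return Named numeric vector of length 5.
#' @export
#' @examples
#' chemical_composition("RKDESTAVPG")
chemical_composition <- function(seq) {
  res <- as_residues(seq)
  check_nonempty(res, "chemical_composition")
  v <- vapply(CHEM_CLASSES, function(cl) sum(res %in% cl), numeric(1))
  v / length(res)
}

#' Amino-acid composition of an IDR
#'
#' The fraction of each of the 20 amino acids, in alphabet order; sums to 1.
#'
#' @inheritParams chemical_composition
#' @return Named numeric vector of length 20.
#' @export
aa_composition <- function(seq) {
  res <- as_residues(seq)
  check_nonempty(res, "aa_composition")
  aa_counts(res) / length(res)
}

#' Amino-acid occurrence of an IDR
#'
#' The un-normalized count of each of the 20 amino acids; sums to the IDR
#' length.
#'
#' @inheritParams chemical_composition
#' @return Named numeric vector of length 20 of non-negative integers.
#' @export
aa_occurrence <- function(seq) {
  res <- as_residues(seq)
  check_nonempty(res, "aa_occurrence")
  aa_counts(res)
}

aa_counts <- function(res) {
  v <- as.numeric(tabulate(match(res, AA_ALPHABET), nbins = 20L))
  names(v) <- AA_ALPHABET
  v
}

#' Composition-transition-distribution block for one property
#'
#' Encodes a sequence against a three-group physicochemical partition as 21
#' values: 3 group compositions (fractions, sum 1), 3 transition frequencies
#' (adjacent residue pairs crossing between two groups, counted in both
#' directions and divided by L-1; 0 when L = 1), and 15 distribution values
#' (for each group, the 1-based positions of its first, 25%, 50%, 75% and last
#' occurrence divided by L; all 0 for an absent group). Quantile anchors are
#' the ceiling(q * n_g)-th occurrences.
#'
#' @inheritParams chemical_composition
#' @param partition List of 3 disjoint residue groups covering the alphabet.
#' @param name Label used as prefix in the component names.
#' @return Named numeric vector of length 21.
#' @export
#' @examples
#' p <- default_property_partitions()
#' ctd_block("ADAD", p$hydrophobicity)
ctd_block <- function(seq, partition, name = "prop") {
  validate_partition(partition, name)
  res <- as_residues(seq)
  check_nonempty(res, "ctd_block")
  L <- length(res)
  grp <- integer(L)
  for (g in 1:3) grp[res %in% partition[[g]]] <- g

  comp <- tabulate(grp, nbins = 3L) / L

  trans <- numeric(3)  # T12, T13, T23
  if (L > 1L) {
    a <- grp[-L]; b <- grp[-1L]
    pair <- pmin(a, b) * 10L + pmax(a, b)
    trans <- c(sum(pair == 12L), sum(pair == 13L), sum(pair == 23L)) / (L - 1)
  }

  anchors <- c("first", "p25", "p50", "p75", "last")
  dist <- numeric(15)
  for (g in 1:3) {
    idx <- which(grp == g)
    n_g <- length(idx)
    if (n_g > 0L) {
      k <- c(1L, ceiling(c(0.25, 0.50, 0.75) * n_g), n_g)
      dist[(g - 1L) * 5L + 1:5] <- idx[k] / L
    }
  }

  out <- c(comp, trans, dist)
  names(out) <- paste(name, c("C1", "C2", "C3", "T12", "T13", "T23",
                              paste0("D", rep(1:3, each = 5), ".",
                                     rep(anchors, 3))), sep = ".")
  out
}

#' Dubchak descriptor vector (composition or occurrence variant)
#'
#' Concatenates the 20 amino-acid compositions (mode `"composition"`) or
#' occurrences (mode `"occurrence"`) with the 21-value CTD block for each of
#' five physicochemical properties (hydrophobicity, normalized van der Waals
#' volume, polarity, polarizability, secondary-structure former classes):
#' 20 + 5 x 21 = 125 values.
#'
#' @inheritParams chemical_composition
#' @param mode `"composition"` or `"occurrence"` for the leading 20 values.
#' @param partitions Named list of five 3-group partitions; defaults to
#'   [default_property_partitions()].
#' @return Named numeric vector of length 125.
#' @export
dubchak_features <- function(seq, mode = c("composition", "occurrence"),
                             partitions = default_property_partitions()) {
  mode <- match.arg(mode)
  if (!is.list(partitions) || length(partitions) != 5L ||
      is.null(names(partitions)))
    stop("partitions must be a named list of 5 property partitions")
  res <- as_residues(seq)
  check_nonempty(res, "dubchak_features")
  head20 <- if (mode == "composition") aa_composition(res) else aa_occurrence(res)
  blocks <- lapply(names(partitions), function(nm)
    ctd_block(res, partitions[[nm]], name = nm))
  c(head20, unlist(blocks))
}

bigram_names <- local({
  nm <- as.vector(t(outer(AA_ALPHABET, AA_ALPHABET, paste0)))
  function() nm
})

# Shared counting core: ordered pairs (position i, position i + gap + 1),
# flattened row-major (first residue varies slowest), divided by the window
# count. Returns all zeros plus a warning when too short.
bigram_vector <- function(res, gap, family, min_len) {
  L <- length(res)
  v <- numeric(400)
  names(v) <- bigram_names()
  if (L < min_len) {
    warning(sprintf("%s: sequence of length %d is too short (needs >= %d); returning all zeros",
                    family, L, min_len), call. = FALSE)
    return(v)
  }
  step <- gap + 1L
  a <- match(res[seq_len(L - step)], AA_ALPHABET)
  b <- match(res[seq_len(L - step) + step], AA_ALPHABET)
  counts <- tabulate((a - 1L) * 20L + b, nbins = 400L)
  v[] <- counts / (L - step)
  v
}

#' Adjacent residue bigram probabilities
#'
#' The 400 ordered amino-acid dimer frequencies: count of each adjacent pair
#' (a, b) divided by the number of windows L-1, flattened row-major with the
#' first residue varying slowest. Sums to 1 for L >= 2; a length-1 sequence
#' yields all zeros with a warning so protein-level collation stays total.
#'
#' @inheritParams chemical_composition
#' @return Named numeric vector of length 400.
#' @export
#' @examples
#' v <- sequence_bigrams("ACA")
#' v[v > 0]
sequence_bigrams <- function(seq) {
  res <- as_residues(seq)
  check_nonempty(res, "sequence_bigrams")
  bigram_vector(res, gap = 0L, family = "sequence_bigrams", min_len = 2L)
}

#' One-gap (alternate) residue bigram probabilities
#'
#' Ordered pairs of residues separated by exactly one position, counted over
#' the L-2 windows and normalized by that window count. Sums to 1 for L >= 3;
#' shorter sequences yield all zeros with a warning.
#'
#' @inheritParams chemical_composition
#' @return Named numeric vector of length 400.
#' @export
alternate_bigrams <- function(seq) {
  res <- as_residues(seq)
  check_nonempty(res, "alternate_bigrams")
  bigram_vector(res, gap = 1L, family = "alternate_bigrams", min_len = 3L)
}

#' Profile (PSSM) bigram features
#'
#' Bigram transition frequencies computed from a row-normalized L x 20
#' position-specific scoring matrix E: for each ordered residue pair (m, n),
#' `T[m, n] = sum_{i=1}^{L-1} E[i, m] * E[i+1, n]`, flattened in the same
#' row-major order as [sequence_bigrams()]. For row-normalized profiles the
#' 400 values sum to L-1. A one-row profile yields all zeros with a warning;
#' rows that do not sum to 1 (tolerance 1e-6) are rejected.
#'
#' @param pssm A [pssm_matrix()] object or a plain L x 20 numeric matrix with
#'   columns in canonical alphabet order.
#' @return Named numeric vector of length 400.
#' @seealso [read_pssm_ascii()], [generate_pssm()]
#' @export
profile_bigrams <- function(pssm) {
  E <- as_pssm_probs(pssm)
  L <- nrow(E)
  if (L < 1L) stop("profile_bigrams: empty PSSM")
  if (any(abs(rowSums(E) - 1) > 1e-6))
    stop("profile_bigrams: PSSM rows must be normalized (sum to 1 within 1e-6)")
  v <- numeric(400)
  names(v) <- bigram_names()
  if (L < 2L) {
    warning("profile_bigrams: PSSM with a single row; returning all zeros",
            call. = FALSE)
    return(v)
  }
  Tmat <- crossprod(E[-L, , drop = FALSE], E[-1L, , drop = FALSE])
  v[] <- as.vector(t(Tmat))
  v
}

#' Extract one feature family for a set of IDRs
#'
#' Applies a single descriptor family to every IDR and stacks the vectors into
#' a matrix (rows = IDRs, columns = named components). For
#' `"profile_bigrams"` a named list of PSSMs must be supplied; IDRs without a
#' PSSM are omitted from the matrix and their count reported via a message,
#' mirroring profile coverage gaps in homology searches.
#'
#' @param seqs List of [idr_sequence()] objects.
#' @param family One of [FEATURE_FAMILIES].
#' @param pssms Named list of PSSM objects (names = idr ids); required for
#'   `"profile_bigrams"`.
#' @param partitions Property partitions for the Dubchak families.
#' @return Numeric matrix with one row per IDR (rownames = idr ids).
#' @export
feature_matrix <- function(seqs, family, pssms = NULL,
                           partitions = default_property_partitions()) {
  family <- match.arg(family, FEATURE_FAMILIES)
  ids <- vapply(seqs, function(s) s$idr_id, character(1))
  if (family == "profile_bigrams") {
    if (is.null(pssms))
      stop("feature_matrix: profile_bigrams requires a named list of PSSMs")
    have <- ids %in% names(pssms)
    if (any(!have))
      message(sprintf("feature_matrix: %d IDR(s) without a PSSM omitted from profile_bigrams",
                      sum(!have)))
    rows <- lapply(ids[have], function(id) profile_bigrams(pssms[[id]]))
    ids <- ids[have]
  } else {
    f <- switch(family,
      chemical_composition = chemical_composition,
      aa_composition       = aa_composition,
      composition_dubchak  = function(s) dubchak_features(s, "composition", partitions),
      occurrence_dubchak   = function(s) dubchak_features(s, "occurrence", partitions),
      sequence_bigrams     = sequence_bigrams,
      alternate_bigrams    = alternate_bigrams)
    rows <- lapply(seqs, f)
  }
  m <- do.call(rbind, rows)
  rownames(m) <- ids
  m
}
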