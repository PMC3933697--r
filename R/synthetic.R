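# Disorder-like background residue frequencies: elevated P, S, E, K; depleted
# W, C, F, I; D+E at 12% of residues. Sums to 1 exactly.
DISORDER_BACKGROUND <- c(
  A = 0.080, C = 0.010, D = 0.040, E = 0.080, F = 0.020, G = 0.080,
  H = 0.020, I = 0.025, K = 0.080, L = 0.055, M = 0.015, N = 0.040,
  P = 0.095, Q = 0.060, R = 0.050, S = 0.105, T = 0.070, V = 0.050,
  W = 0.005, Y = 0.020
)

#' Configuration of the synthetic IDR dataset generator
#'
#' Describes a seeded synthetic study: proteins carrying one or more IDRs, a
#' two-level GO Slim hierarchy (leaf terms with immediate parents), per-term
#' residue-composition signals, and the concentration of the noisy profile
#' generator. Defaults emulate the shape of a genome-scale IDR study at desk
#' scale: 1-3 IDRs per protein (matching a roughly 1.7 IDR/protein ratio),
#' IDR lengths uniform on 30-300 residues, 12 leaf terms under 4 parents,
#' 1-6 leaf terms per protein, and one "acidic" leaf term whose IDRs have
#' their D+E mass enriched from the 12% background to 30%.
#'
#' @param n_proteins Number of proteins (default 250, approx. 500 IDRs).
#' @param idrs_per_protein Integer range `c(min, max)` sampled uniformly.
#' @param idr_length Integer range `c(min, max)` sampled uniformly.
#' @param n_terms Number of leaf GO Slim terms.
#' @param n_parents Number of parent terms; leaves are assigned round-robin.
#' @param terms_per_protein Integer range of leaf terms drawn per protein.
#' @param signal_map Named list: leaf term id -> `list(residues, fraction)`;
#'   IDRs of proteins annotated with that term have the residue set's total
#'   composition set to `fraction`. Signal residue sets must be disjoint and
#'   fractions must sum below 1.
#' @param background Named 20-vector of background residue frequencies.
#' @param pssm_concentration Dirichlet concentration of [generate_pssm()]
#'   rows around the true residue (default 20).
#' @param seed Integer seed; a fixed seed makes the dataset byte-identical.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 250L,
                       idrs_per_protein = c(1L, 3L),
                       idr_length = c(30L, 300L),
                       n_terms = 12L,
                       n_parents = 4L,
                       terms_per_protein = c(1L, 6L),
                       signal_map = list(
                         "GO:SYN0001" = list(residues = c("D", "E"),
                                             fraction = 0.30)),
                       background = DISORDER_BACKGROUND,
                       pssm_concentration = 20,
                       seed = 1L) {
  stopifnot(n_proteins >= 1L, n_terms >= 1L, n_parents >= 1L,
            length(idrs_per_protein) == 2L, idrs_per_protein[1] >= 1L,
            length(idr_length) == 2L, idr_length[1] >= 1L,
            length(terms_per_protein) == 2L, terms_per_protein[1] >= 1L,
            terms_per_protein[2] <= n_terms,
            pssm_concentration > 0,
            length(background) == 20L, all(background > 0))
  names(background) <- AA_ALPHABET[match(names(background), AA_ALPHABET)]
  if (anyNA(names(background)))
    stop("sim_config: background must be named by the 20 standard residues")
  background <- background[AA_ALPHABET] / sum(background)
  if (length(signal_map) > 0) {
    fr <- vapply(signal_map, function(s) s$fraction, numeric(1))
    if (any(fr <= 0 | fr >= 1))
      stop("sim_config: enriched fractions must lie in (0, 1)")
    if (sum(fr) >= 1)
      stop("sim_config: signal fractions sum to >= 1; composition would be inconsistent")
    all_res <- unlist(lapply(signal_map, `[[`, "residues"))
    if (anyDuplicated(all_res))
      stop("sim_config: signal residue sets must be disjoint")
    if (!all(all_res %in% AA_ALPHABET))
      stop("sim_config: signal residues must be standard amino acids")
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 idrs_per_protein = as.integer(idrs_per_protein),
                 idr_length = as.integer(idr_length),
                 n_terms = as.integer(n_terms),
                 n_parents = as.integer(n_parents),
                 terms_per_protein = as.integer(terms_per_protein),
                 signal_map = signal_map,
                 background = background,
                 pssm_concentration = pssm_concentration,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Uniform integer from an inclusive range; safe when min == max (plain
# sample() would treat a scalar as 1:n).
runif_int <- function(rng) {
  if (rng[1] == rng[2]) return(rng[1])
  sample(rng[1]:rng[2], 1L)
}

synthetic_term_ids <- function(n_terms, n_parents) {
  leaves <- sprintf("GO:SYN%04d", seq_len(n_terms))
  parents <- sprintf("GO:SYNP%02d", seq_len(n_parents))
  parent_map <- parents[((seq_len(n_terms) - 1L) %% n_parents) + 1L]
  names(parent_map) <- leaves
  list(leaves = leaves, parents = parents, parent_map = parent_map)
}

# Residue sampling distribution for an IDR given its protein's leaf terms:
# each active signal set gets its enriched total fraction (split within the
# set proportional to background); the remaining mass goes to the other
# residues proportional to background.
signal_composition <- function(terms, signal_map, background) {
  active <- signal_map[intersect(names(signal_map), terms)]
  if (length(active) == 0L) return(background)
  p <- background
  signal_res <- character(0)
  total_signal <- 0
  for (s in active) {
    idx <- s$residues
    p[idx] <- s$fraction * background[idx] / sum(background[idx])
    signal_res <- c(signal_res, idx)
    total_signal <- total_signal + s$fraction
  }
  rest <- setdiff(AA_ALPHABET, signal_res)
  p[rest] <- (1 - total_signal) * background[rest] / sum(background[rest])
  p
}

#' Generate a synthetic IDR dataset
#'
#' Draws a complete seeded dataset with the statistical structure the
#' pipeline assumes: each protein receives a uniform number of leaf GO Slim
#' terms and of IDRs; every IDR of a protein carries the protein's full term
#' set (IDRs inherit the parent protein's annotation); IDR residues are
#' drawn i.i.d. from the disorder-like background shifted by the
#' composition signals of the protein's terms; and each IDR gets a noisy
#' profile from [generate_pssm()]. Annotations are stored unexpanded (leaf
#' terms only); ancestor expansion is applied downstream.
#'
#' @param config A [sim_config()].
#' @return Object of class `synthetic_dataset`: list with `sequences` (list
#'   of [idr_sequence()]), `pssms` (named list of [pssm_matrix()]),
#'   `annotations` (named list idr id -> leaf term set), `proteins` (named
#'   character idr id -> protein id), `parent_map`, `terms` (leaf ids),
#'   `truth` (the signal map), `config`.
#' @export
generate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  hier <- synthetic_term_ids(config$n_terms, config$n_parents)
  with_seed(config$seed, {
    sequences <- list(); pssms <- list()
    annotations <- list(); proteins <- character(0)
    for (pi in seq_len(config$n_proteins)) {
      protein_id <- sprintf("P%04d", pi)
      n_terms_p <- runif_int(config$terms_per_protein)
      terms_p <- sort(hier$leaves[sample.int(config$n_terms, n_terms_p)])
      comp <- signal_composition(terms_p, config$signal_map, config$background)
      n_idrs <- runif_int(config$idrs_per_protein)
      for (ri in seq_len(n_idrs)) {
        idr_id <- sprintf("%s_IDR%d", protein_id, ri)
        L <- runif_int(config$idr_length)
        res <- sample(AA_ALPHABET, L, replace = TRUE, prob = comp)
        sequences[[length(sequences) + 1L]] <-
          idr_sequence(idr_id, res, protein_id)
        pssms[[idr_id]] <- generate_pssm(res, config$pssm_concentration,
                                         idr_id = idr_id)
        annotations[[idr_id]] <- terms_p
        proteins[idr_id] <- protein_id
      }
    }
    structure(list(sequences = sequences, pssms = pssms,
                   annotations = annotations, proteins = proteins,
                   parent_map = hier$parent_map, terms = hier$leaves,
                   truth = config$signal_map, config = config),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d IDRs / %d proteins / %d leaf terms (+%d parents)\n",
              length(x$sequences), length(unique(x$proteins)),
              length(x$terms), length(unique(x$parent_map))))
  invisible(x)
}

#' Generate a noisy PSSM for a sequence
#'
#' Emulates the per-position substitution profile a homology search would
#' return: row i is a Dirichlet draw with concentration vector
#' `concentration * onehot(residue_i) + 2 * background`, i.e. centred on the
#' true residue and smoothed by a substitution-like background. As
#' `concentration` grows the rows approach the exact one-hot encoding of the
#' sequence. Rows always sum to 1.
#'
#' @param seq An [idr_sequence()], character scalar or residue vector.
#' @param concentration Positive scalar (default 20).
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (as inside [generate_dataset()]).
#' @param idr_id Id recorded in the returned [pssm_matrix()].
#' @return A [pssm_matrix()].
#' @export
generate_pssm <- function(seq, concentration = 20, seed = NULL,
                          idr_id = seq_id(seq)) {
  stopifnot(concentration > 0)
  res <- as_residues(seq)
  if (length(res) == 0L) stop("generate_pssm: empty sequence")
  draw <- function() {
    idx <- match(res, AA_ALPHABET)
    alpha <- matrix(rep(2 * DISORDER_BACKGROUND, each = length(res)),
                    nrow = length(res))
    alpha[cbind(seq_along(idx), idx)] <-
      alpha[cbind(seq_along(idx), idx)] + concentration
    g <- matrix(stats::rgamma(length(alpha), shape = alpha),
                nrow = length(res))
    g / rowSums(g)
  }
  probs <- if (is.null(seed)) draw() else with_seed(seed, draw())
  pssm_matrix(if (is.na(idr_id)) "synthetic" else idr_id, probs)
}

#' Write a synthetic dataset to its file bundle
#'
#' Emits the four-file bundle the readers consume: `idrs.fasta` (one record
#' per IDR), one `<idr_id>.pssm` PSI-BLAST ASCII file per IDR under
#' `pssms/`, `annotations.tsv` (idr_id, protein_id, comma-separated terms)
#' and `parent_map.tsv` (child_id, parent_id). The bundle round-trips
#' losslessly through [read_fasta()], [read_pssm_dir()],
#' [read_annotations()] and [read_parent_map()] (PSSM probabilities to
#' within the 1e-4 precision of the percentage columns).
#'
#' @param ds A `synthetic_dataset`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_dataset <- function(ds, out_dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pssm_dir <- file.path(out_dir, "pssms")
  dir.create(pssm_dir, showWarnings = FALSE)

  seqs <- Biostrings::AAStringSet(vapply(ds$sequences, function(s)
    paste(s$residues, collapse = ""), character(1)))
  names(seqs) <- vapply(ds$sequences, function(s) s$idr_id, character(1))
  Biostrings::writeXStringSet(seqs, file.path(out_dir, "idrs.fasta"))

  for (s in ds$sequences)
    write_pssm_ascii(ds$pssms[[s$idr_id]],
                     file.path(pssm_dir, paste0(s$idr_id, ".pssm")),
                     residues = s$residues)

  ann <- data.frame(idr_id = names(ds$annotations),
                    protein_id = unname(ds$proteins[names(ds$annotations)]),
                    terms = vapply(ds$annotations, paste, character(1),
                                   collapse = ","),
                    stringsAsFactors = FALSE)
  utils::write.table(ann, file.path(out_dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  pm <- data.frame(child_id = names(ds$parent_map),
                   parent_id = unname(ds$parent_map),
                   stringsAsFactors = FALSE)
  utils::write.table(pm, file.path(out_dir, "parent_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
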