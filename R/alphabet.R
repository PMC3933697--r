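#' Canonical amino-acid alphabet
#'
#' The fixed 20-letter ordering `"ACDEFGHIKLMNPQRSTVWY"` used for every
#' composition vector, bigram flattening and internal PSSM column order.
#' A single canonical order prevents silent column permutation between
#' sequence-derived and profile-derived bigram vectors.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Chemical classes of the five-component composition descriptor. Histidine
# goes with the positively charged residues so the five classes partition
# the alphabet and the fractions sum to 1.
CHEM_CLASSES <- list(
  positive    = c("R", "K", "H"),
  negative    = c("D", "E"),
  polar       = c("S", "T", "N", "Q", "Y", "C"),
  hydrophobic = c("A", "V", "L", "I", "M", "F", "W"),
  special     = c("P", "G")
)

#' Three-group physicochemical property partitions
#'
#' Builds the standard three-group splits of the 20 amino acids used by the
#' composition-transition-distribution (CTD) descriptors: hydrophobicity,
#' normalized van der Waals volume, polarity, polarizability, and
#' secondary-structure former classes (helix/strand/coil propensity). The
#' groupings follow the protein fold-recognition CTD scheme; they are returned
#' as an ordinary named list so callers can substitute their own partitions
#' (e.g. an externally predicted secondary-structure assignment converted to a
#' partition).
#'
#' @return Named list of five partitions; each partition is a list of three
#'   disjoint character vectors jointly covering the alphabet.
#' @seealso [ctd_block()], [dubchak_features()]
#' @export
#' @examples
#' p <- default_property_partitions()
#' names(p)
default_property_partitions <- function() {
  p <- list(
    hydrophobicity = list(
      c("R", "K", "E", "D", "Q", "N"),            # polar
      c("G", "A", "S", "T", "P", "H", "Y"),       # neutral
      c("C", "L", "V", "I", "M", "F", "W")        # hydrophobic
    ),
    vdw_volume = list(
      c("G", "A", "S", "C", "T", "P", "D"),       # 0-2.78
      c("N", "V", "E", "Q", "I", "L"),            # 2.95-4.0
      c("M", "H", "K", "F", "R", "Y", "W")        # 4.03-8.08
    ),
    polarity = list(
      c("L", "I", "F", "W", "C", "M", "V", "Y"),  # 4.9-6.2
      c("P", "A", "T", "G", "S"),                 # 8.0-9.2
      c("H", "Q", "R", "K", "N", "E", "D")        # 10.4-13.0
    ),
    polarizability = list(
      c("G", "A", "S", "D", "T"),                 # 0-0.108
      c("C", "P", "N", "V", "E", "Q", "I", "L"),  # 0.128-0.186
      c("K", "M", "H", "F", "R", "Y", "W")        # 0.219-0.409
    ),
    secondary_structure = list(
      c("E", "A", "L", "M", "Q", "K", "R", "H"),  # helix formers
      c("V", "I", "Y", "C", "W", "F", "T"),       # strand formers
      c("G", "N", "P", "S", "D")                  # coil formers
    )
  )
  for (nm in names(p)) validate_partition(p[[nm]], nm)
  p
}

validate_partition <- function(groups, name = "partition") {
  if (!is.list(groups) || length(groups) != 3L)
    stop(name, ": a property partition must have exactly 3 groups")
  all_res <- unlist(groups)
  if (anyDuplicated(all_res) || !setequal(all_res, AA_ALPHABET))
    stop(name, ": the 3 groups must partition the 20-letter alphabet exactly")
  invisible(groups)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}
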