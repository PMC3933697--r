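#' Construct an IDR sequence record
#'
#' An IDR (intrinsically disordered region) sequence carries its own id, the
#' id of the protein it was excised from, and its residues over the 20-letter
#' amino-acid alphabet. Residues outside the standard alphabet (B, Z, X, U, O,
#' gap or stop symbols) are dropped with a warning and the number removed is
#' recorded in the `n_dropped` field, since every descriptor here is defined
#' only over the 20 standard residues.
#'
#' @param idr_id Character scalar, unique id of the IDR.
#' @param residues Character scalar (the sequence) or character vector of
#'   single letters.
#' @param protein_id Character scalar id of the parent protein (`NA` when
#'   unknown, e.g. straight from FASTA before joining annotations).
#' @return An object of class `idr_sequence`: a list with fields `idr_id`,
#'   `protein_id`, `residues` (character vector of single letters), `length`,
#'   `n_dropped`.
#' @export
#' @examples
#' s <- idr_sequence("idr1", "MKKXEEP")
#' s$length     # 6: the X was dropped
idr_sequence <- function(idr_id, residues, protein_id = NA_character_) {
  stopifnot(is.character(idr_id), length(idr_id) == 1L, nzchar(idr_id))
  res <- sanitize_residues(residues, idr_id)
  structure(
    list(idr_id = idr_id, protein_id = protein_id,
         residues = res$residues, length = length(res$residues),
         n_dropped = res$n_dropped),
    class = "idr_sequence"
  )
}

# Uppercase, split to single letters, drop non-standard symbols with a warning.
sanitize_residues <- function(residues, idr_id = "?") {
  if (length(residues) == 1L && nchar(residues) != 1L)
    residues <- strsplit(residues, "")[[1]]
  residues <- toupper(as.character(residues))
  keep <- residues %in% AA_ALPHABET
  n_dropped <- sum(!keep)
  if (n_dropped > 0L)
    warning(sprintf("%s: dropped %d non-standard residue(s) (%s)",
                    idr_id, n_dropped,
                    paste(unique(residues[!keep]), collapse = ",")),
            call. = FALSE)
  list(residues = residues[keep], n_dropped = n_dropped)
}

#' @export
print.idr_sequence <- function(x, ...) {
  cat(sprintf("<idr_sequence> %s (protein %s), L=%d\n  %s%s\n",
              x$idr_id, x$protein_id, x$length,
              paste(utils::head(x$residues, 60), collapse = ""),
              if (x$length > 60) "..." else ""))
  invisible(x)
}

# Accept an idr_sequence, a character scalar, or a letter vector; return the
# residue letter vector. Feature extractors funnel through this.
as_residues <- function(seq) {
  if (inherits(seq, "idr_sequence")) return(seq$residues)
  sanitize_residues(seq)$residues
}

seq_id <- function(seq) {
  if (inherits(seq, "idr_sequence")) seq$idr_id else NA_character_
}
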