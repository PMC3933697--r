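# PSI-BLAST writes its ASCII matrix with this residue column order; internal
# storage always uses the alphabetical canonical order.
PSIBLAST_COL_ORDER <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

#' Construct a PSSM probability matrix
#'
#' An L x 20 matrix of per-position amino-acid relative probabilities for one
#' IDR, columns in canonical alphabet order, every row summing to 1.
#'
#' @param idr_id Id of the IDR the profile belongs to.
#' @param probs Numeric L x 20 matrix; rows are renormalized to sum to 1.
#' @return Object of class `pssm_matrix`.
#' @export
pssm_matrix <- function(idr_id, probs) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 20L)
    stop("pssm_matrix: probs must have 20 columns")
  if (any(!is.finite(probs)) || any(probs < 0))
    stop("pssm_matrix: probabilities must be finite and non-negative")
  rs <- rowSums(probs)
  if (any(rs <= 0))
    stop("pssm_matrix: every row must have positive mass")
  probs <- probs / rs
  colnames(probs) <- AA_ALPHABET
  structure(list(idr_id = idr_id, probs = probs, length = nrow(probs)),
            class = "pssm_matrix")
}

#' @export
print.pssm_matrix <- function(x, ...) {
  cat(sprintf("<pssm_matrix> %s: %d positions x 20 residues\n",
              x$idr_id, x$length))
  invisible(x)
}

as_pssm_probs <- function(pssm) {
  if (inherits(pssm, "pssm_matrix")) return(pssm$probs)
  m <- as.matrix(pssm)
  if (ncol(m) != 20L) stop("expected a pssm_matrix or an L x 20 matrix")
  colnames(m) <- AA_ALPHABET
  m
}

#' Read a PSI-BLAST ASCII PSSM file
#'
#' Parses the `-out_ascii_pssm` dialect: header lines, then one row per
#' position carrying the residue, 20 log-odds columns and 20 weighted
#' observed percentage columns. The residue order of the columns is taken
#' from the header line (PSI-BLAST uses A R N D C Q E G H I L K M F P S T W
#' Y V) and mapped to the canonical alphabetical order.
#'
#' Two conversions to per-row probabilities are offered, since profile
#' "relative probabilities" can be read off either block:
#' `mode = "percentages"` divides the percentage columns by 100 and
#' renormalizes each row (an all-zero percentage row, which PSI-BLAST can
#' emit, is replaced by a uniform row with a warning);
#' `mode = "logodds_sigmoid"` maps each log-odds entry through the logistic
#' function `1/(1+exp(-x))` and renormalizes.
#'
#' @param path Path to the ASCII PSSM file.
#' @param mode `"percentages"` (default) or `"logodds_sigmoid"`.
#' @param idr_id Id to attach; defaults to the file name without `.pssm`.
#' @return A [pssm_matrix()].
#' @export
read_pssm_ascii <- function(path, mode = c("percentages", "logodds_sigmoid"),
                            idr_id = sub("\\.pssm$", "", basename(path))) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("read_pssm_ascii: no such file: ", path)
  lines <- readLines(path, warn = FALSE)

  # Header = first line whose tokens are 40 single residue letters.
  header_at <- NA_integer_
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) == 40L && all(tok %in% AA_ALPHABET)) { header_at <- i; break }
  }
  if (is.na(header_at))
    stop("read_pssm_ascii: ", path, ": no 40-column residue header found")
  tok <- strsplit(trimws(lines[header_at]), "\\s+")[[1]]
  lo_order <- tok[1:20]; pc_order <- tok[21:40]

  logodds <- list(); perc <- list()
  for (i in seq((header_at + 1L), length(lines))) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) break                       # blank line ends the matrix
    if (!grepl("^[0-9]", ln)) break              # footer (K, Lambda, ...)
    f <- strsplit(ln, "\\s+")[[1]]
    # pos, residue, 20 log-odds, 20 percentages [, information, weight]
    if (length(f) < 42L)
      stop(sprintf("read_pssm_ascii: %s: malformed row at line %d (%d fields, expected >= 42)",
                   path, i, length(f)))
    vals <- suppressWarnings(as.numeric(f[3:42]))
    if (anyNA(vals))
      stop(sprintf("read_pssm_ascii: %s: non-numeric matrix entry at line %d",
                   path, i))
    logodds[[length(logodds) + 1L]] <- vals[1:20]
    perc[[length(perc) + 1L]] <- vals[21:40]
  }
  if (length(perc) == 0L)
    stop("read_pssm_ascii: ", path, ": no matrix rows found")

  if (mode == "percentages") {
    m <- do.call(rbind, perc)[, match(AA_ALPHABET, pc_order), drop = FALSE] / 100
    zero <- rowSums(m) == 0
    if (any(zero)) {
      warning(sprintf("read_pssm_ascii: %s: %d all-zero percentage row(s) replaced by uniform",
                      path, sum(zero)), call. = FALSE)
      m[zero, ] <- 1 / 20
    }
  } else {
    lo <- do.call(rbind, logodds)[, match(AA_ALPHABET, lo_order), drop = FALSE]
    m <- 1 / (1 + exp(-lo))
  }
  pssm_matrix(idr_id, m)
}

#' Read a directory of per-IDR PSSM files
#'
#' Looks for `<idr_id>.pssm` for each requested id. Missing profiles are
#' tolerated and counted (profile construction upstream does not cover every
#' IDR); the result only contains the ids that were found.
#'
#' @param dir Directory containing `<idr_id>.pssm` files.
#' @param ids Character vector of IDR ids to load.
#' @inheritParams read_pssm_ascii
#' @return Named list of [pssm_matrix()] objects.
#' @export
read_pssm_dir <- function(dir, ids, mode = c("percentages", "logodds_sigmoid")) {
  mode <- match.arg(mode)
  paths <- file.path(dir, paste0(ids, ".pssm"))
  have <- file.exists(paths)
  if (any(!have))
    message(sprintf("read_pssm_dir: %d of %d PSSM file(s) missing in %s",
                    sum(!have), length(ids), dir))
  out <- lapply(which(have), function(i) read_pssm_ascii(paths[i], mode, ids[i]))
  names(out) <- ids[have]
  out
}

#' Write a PSSM in the PSI-BLAST ASCII layout
#'
#' Emits the header and per-position rows of the `-out_ascii_pssm` dialect
#' with the PSI-BLAST residue column order. Percentage columns are written
#' with four decimals (instead of PSI-BLAST's rounded integers) so stored
#' probabilities round-trip through [read_pssm_ascii()] to within 1e-4;
#' log-odds columns hold the logit of each probability so the
#' `logodds_sigmoid` reading recovers the same row up to normalization.
#'
#' @param pssm A [pssm_matrix()].
#' @param path Output file path.
#' @param residues Optional residue letters for the second column (defaults
#'   to the most probable residue per row).
#' @export
write_pssm_ascii <- function(pssm, path, residues = NULL) {
  E <- as_pssm_probs(pssm)
  L <- nrow(E)
  if (is.null(residues)) residues <- AA_ALPHABET[max.col(E, ties.method = "first")]
  stopifnot(length(residues) == L)
  ord <- match(PSIBLAST_COL_ORDER, AA_ALPHABET)
  p <- pmin(pmax(E[, ord, drop = FALSE], 1e-9), 1 - 1e-9)
  lo <- log(p / (1 - p))

  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("           ",
           paste(sprintf("%7s", c(PSIBLAST_COL_ORDER, PSIBLAST_COL_ORDER)),
                 collapse = ""))), con)
  for (i in seq_len(L)) {
    writeLines(paste0(sprintf("%5d %s ", i, residues[i]),
                      paste(sprintf("%7.2f", lo[i, ]), collapse = ""),
                      " ",
                      paste(sprintf("%9.4f", 100 * E[i, ord]), collapse = ""),
                      sprintf("  %4.2f %8.2f", 0, 0)), con)
  }
  writeLines("", con)
  invisible(path)
}
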