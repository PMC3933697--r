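#' Read IDR sequences from a FASTA file
#'
#' One record per IDR; the record id (first word of the header) becomes the
#' idr id. Ids must be unique and the file non-empty. Residues outside the
#' 20-letter alphabet are dropped per record with a warning carrying the
#' count, mirroring the sanitization rule of the feature extractors.
#'
#' @param path FASTA file.
#' @return List of [idr_sequence()] objects (protein ids filled in later by
#'   [read_annotations()]).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("read_fasta: no such file: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("read_fasta: ", path, " contains no records")
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L)
    stop("read_fasta: duplicate record id(s): ", paste(dup, collapse = ", "))
  mapply(function(id, s) idr_sequence(id, s),
         ids, as.character(set), SIMPLIFY = FALSE, USE.NAMES = TRUE)
}

#' Read the IDR annotation table
#'
#' TSV with header columns `idr_id`, `protein_id`, `terms` (comma-separated
#' GO Slim ids). When a parent map is supplied, term ids outside its
#' vocabulary (children and parents) are reported with a warning but
#' retained.
#'
#' @param path Annotation TSV.
#' @param parent_map Optional named child -> parent vector used to validate
#'   the term vocabulary.
#' @return List with `annotations` (named list idr id -> term set) and
#'   `proteins` (named character idr id -> protein id).
#' @export
read_annotations <- function(path, parent_map = NULL) {
  if (!file.exists(path)) stop("read_annotations: no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("idr_id", "protein_id", "terms")
  if (!all(need %in% names(df)))
    stop("read_annotations: missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (anyDuplicated(df$idr_id))
    stop("read_annotations: duplicate idr_id rows")
  ann <- lapply(strsplit(df$terms, ","), function(tt) sort(unique(trimws(tt))))
  names(ann) <- df$idr_id
  if (!is.null(parent_map)) {
    vocab <- unique(c(names(parent_map), unname(parent_map)))
    unknown <- setdiff(unique(unlist(ann)), vocab)
    if (length(unknown) > 0L)
      warning(sprintf("read_annotations: %d term id(s) not in the parent-map vocabulary (retained): %s",
                      length(unknown),
                      paste(utils::head(unknown, 5), collapse = ", ")),
              call. = FALSE)
  }
  proteins <- df$protein_id
  names(proteins) <- df$idr_id
  list(annotations = ann, proteins = proteins)
}

#' Read the GO Slim parent map
#'
#' TSV with header columns `child_id`, `parent_id`, one row per child term's
#' immediate ancestor.
#'
#' @param path Parent-map TSV.
#' @return Named character vector, child id -> parent id.
#' @export
read_parent_map <- function(path) {
  if (!file.exists(path)) stop("read_parent_map: no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("child_id", "parent_id") %in% names(df)))
    stop("read_parent_map: needs columns child_id, parent_id")
  pm <- df$parent_id
  names(pm) <- df$child_id
  pm
}

#' Write a feature matrix to TSV
#'
#' One row per IDR: first column `idr_id`, then one named column per
#' component.
#'
#' @param m Matrix from [feature_matrix()].
#' @param path Output TSV path.
#' @export
write_feature_tsv <- function(m, path) {
  df <- data.frame(idr_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full feature/classification/evaluation pipeline
#'
#' Executes, for each requested feature family, the two-stage scheme:
#' feature extraction over all IDRs, then per-term one-vs-rest Gaussian
#' naive Bayes with seeded stratified 10-fold cross-validation, the derived
#' per-term metric and per-family average tables, and the held-out per-IDR
#' precision-recall analysis. Annotations are ancestor-expanded once, up
#' front, and the expanded vocabulary (leaves and parents) defines the set
#' of term classifiers.
#'
#' Inputs may be given as file paths (`fasta`, `annotations`, `parent_map`,
#' `pssm_dir`) or as a `synthetic_dataset` via `dataset`, in which case the
#' in-memory objects are used directly. When `out_dir` is supplied, the
#' confusion, metric, average, prediction and PR-curve tables are written
#' there as TSVs.
#'
#' @param fasta,annotations,parent_map,pssm_dir Input file paths (ignored
#'   when `dataset` is given; `pssm_dir` may be `NULL`, which disables
#'   `profile_bigrams`).
#' @param dataset Optional `synthetic_dataset`.
#' @param out_dir Optional output directory for the TSV bundle.
#' @param families Feature families to run (default all seven; families
#'   needing PSSMs are dropped with a message when none are available).
#' @param k,cv_seed Cross-validation folds and seed.
#' @param min_positives,var_floor_frac Classifier options (see
#'   [cross_validate_term()]).
#' @param test_n,pr_seed,prob_grid Held-out PR protocol: test-set size
#'   (default 105), sampling seed, probability grid.
#' @param pssm_mode Conversion used by [read_pssm_ascii()].
#' @return List with `metrics` (per-term data.frame across families),
#'   `averages` (per-family data.frame), `pr_curves` (named list of
#'   `pr_curve`), `predictions`, `n_idrs`, `terms`.
#' @export
run_pipeline <- function(fasta = NULL, annotations = NULL, parent_map = NULL,
                         pssm_dir = NULL, dataset = NULL, out_dir = NULL,
                         families = FEATURE_FAMILIES,
                         k = 10L, cv_seed = 1L, min_positives = 10L,
                         var_floor_frac = 1e-9,
                         test_n = 105L, pr_seed = 1L,
                         prob_grid = seq(0, 1, by = 0.05),
                         pssm_mode = c("percentages", "logodds_sigmoid")) {
  pssm_mode <- match.arg(pssm_mode)
  families <- match.arg(families, FEATURE_FAMILIES, several.ok = TRUE)
  if (k < 2L) stop("run_pipeline: k must be >= 2")

  if (!is.null(dataset)) {
    stopifnot(inherits(dataset, "synthetic_dataset"))
    seqs <- dataset$sequences
    ann_raw <- dataset$annotations
    pmap <- dataset$parent_map
    pssms <- dataset$pssms
  } else {
    if (is.null(fasta) || is.null(annotations) || is.null(parent_map))
      stop("run_pipeline: provide either `dataset` or fasta/annotations/parent_map paths")
    seqs <- read_fasta(fasta)
    pmap <- read_parent_map(parent_map)
    loaded <- read_annotations(annotations, pmap)
    ann_raw <- loaded$annotations
    ids <- vapply(seqs, function(s) s$idr_id, character(1))
    missing_ann <- setdiff(ids, names(ann_raw))
    if (length(missing_ann) > 0L)
      stop("run_pipeline: ", length(missing_ann), " IDR(s) lack annotations")
    for (i in seq_along(seqs))
      seqs[[i]]$protein_id <- unname(loaded$proteins[seqs[[i]]$idr_id])
    pssms <- if (!is.null(pssm_dir)) read_pssm_dir(pssm_dir, ids, pssm_mode)
             else NULL
  }
  ids <- vapply(seqs, function(s) s$idr_id, character(1))
  ann <- expand_annotation_list(ann_raw[ids], pmap)
  terms <- sort(unique(unlist(ann)))
  if (is.null(pssms) && "profile_bigrams" %in% families) {
    message("run_pipeline: no PSSMs available; dropping profile_bigrams")
    families <- setdiff(families, "profile_bigrams")
  }

  split_ids <- sample_test_set(ids, n = min(test_n, length(ids) - 1L),
                               seed = pr_seed)

  metrics_all <- list(); averages <- list()
  pr_curves <- list(); predictions <- list()
  for (fam in families) {
    x <- feature_matrix(seqs, fam, pssms = pssms)
    cv <- cv_all_terms(x, ann, terms, family = fam, k = k, seed = cv_seed,
                       min_positives = min_positives,
                       var_floor_frac = var_floor_frac)
    met <- term_metrics(cv)
    metrics_all[[fam]] <- met
    av <- average_over_terms(met)
    averages[[fam]] <- data.frame(family = fam, n_terms = av$n_terms,
                                  n_skipped = av$n_skipped,
                                  sensitivity = av$sensitivity,
                                  specificity = av$specificity,
                                  precision = av$precision,
                                  mcc = av$mcc, stringsAsFactors = FALSE)

    te <- intersect(split_ids$test, rownames(x))
    tr <- intersect(split_ids$train, rownames(x))
    pred <- predict_test_set(x[tr, , drop = FALSE], x[te, , drop = FALSE],
                             ann, terms, min_positives = min_positives,
                             var_floor_frac = var_floor_frac)
    predictions[[fam]] <- if (nrow(pred) > 0L)
      cbind(family = fam, pred, stringsAsFactors = FALSE) else NULL
    if (nrow(pred) > 0L)
      pr_curves[[fam]] <- pr_analysis(pred, ann, test_ids = te,
                                      prob_grid = prob_grid)
  }

  metrics <- do.call(rbind, c(metrics_all, list(make.row.names = FALSE)))
  avg_df <- do.call(rbind, c(averages, list(make.row.names = FALSE)))
  pred_df <- do.call(rbind, c(predictions[!vapply(predictions, is.null, logical(1))],
                              list(make.row.names = FALSE)))
  result <- list(metrics = metrics, averages = avg_df, pr_curves = pr_curves,
                 predictions = pred_df, n_idrs = length(ids), terms = terms,
                 test_ids = split_ids$test)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(metrics, file.path(out_dir, "metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(avg_df, file.path(out_dir, "averages.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(pred_df))
      utils::write.table(pred_df, file.path(out_dir, "predictions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    pr_df <- do.call(rbind, lapply(names(pr_curves), function(fam)
      cbind(family = fam, pr_curves[[fam]]$points, stringsAsFactors = FALSE)))
    if (!is.null(pr_df))
      utils::write.table(pr_df, file.path(out_dir, "pr_curve.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  result
}
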