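#' Expand a term set with immediate GO Slim ancestors
#'
#' Adds, for every term with a known parent in the map, that single immediate
#' ancestor (one step only, not the transitive closure), so that parent-child
#' relations between GO Slim terms are reflected in the per-IDR label sets.
#' Terms absent from the map pass through unchanged.
#'
#' @param terms Character vector of term ids.
#' @param parent_map Named character vector, child id -> immediate parent id
#'   (as returned by [read_parent_map()]).
#' @return Character vector: the union of `terms` and their known parents.
#' @export
#' @examples
#' expand_annotations(c("a", "b"), c(a = "q", b = "q"))
expand_annotations <- function(terms, parent_map) {
  parents <- unname(parent_map[terms])
  sort(unique(c(terms, parents[!is.na(parents)])))
}

# Apply expansion to a named list of per-IDR term sets.
expand_annotation_list <- function(annotations, parent_map) {
  out <- lapply(annotations, expand_annotations, parent_map = parent_map)
  names(out) <- names(annotations)
  out
}

#' Binary label of one term across a set of IDRs
#'
#' The one-vs-rest decomposition: an IDR is labelled 1 for a term exactly when
#' the term is in its (ancestor-expanded) annotation set, else 0.
#'
#' @param annotations Named list, idr id -> character vector of expanded terms.
#' @param term_id The term to binarize against.
#' @return Named integer vector of 0/1 labels, one per IDR.
#' @export
binarize <- function(annotations, term_id) {
  y <- vapply(annotations, function(tt) as.integer(term_id %in% tt), integer(1))
  names(y) <- names(annotations)
  y
}

#' Train a Gaussian naive Bayes term classifier
#'
#' Fits per-component class-conditional normal densities for the positive and
#' negative class with empirical class priors. Each component variance is
#' floored at `var_floor_frac` times that component's global (all-instance)
#' variance, with a small absolute floor for globally constant components;
#' sparse bigram vectors routinely produce zero within-class variances and the
#' floor keeps every density proper.
#'
#' @param x Numeric matrix, one row per training IDR.
#' @param y Integer/numeric 0/1 labels, one per row of `x`.
#' @param var_floor_frac Fraction of the global component variance used as the
#'   variance floor (default 1e-9).
#' @return Object of class `nb_model`.
#' @export
nb_train <- function(x, y, var_floor_frac = 1e-9) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(y) != nrow(x)) stop("nb_train: length(y) must equal nrow(x)")
  if (!all(y %in% c(0L, 1L))) stop("nb_train: labels must be 0/1")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("nb_train: both classes must be present in the training set")

  global_var <- col_var(x)
  floor_ <- pmax(var_floor_frac * global_var, 1e-12)

  stats_for <- function(cls) {
    xi <- x[y == cls, , drop = FALSE]
    mu <- colMeans(xi)
    v <- if (nrow(xi) > 1L) col_var(xi) else rep(0, ncol(xi))
    v[!is.finite(v)] <- 0
    list(mu = mu, var = pmax(v, floor_))
  }
  s0 <- stats_for(0L); s1 <- stats_for(1L)

  structure(list(
    mu0 = s0$mu, var0 = s0$var, mu1 = s1$mu, var1 = s1$var,
    log_prior0 = log(n0 / length(y)), log_prior1 = log(n1 / length(y)),
    n_pos = n1, n_neg = n0, n_features = ncol(x),
    component_names = colnames(x)
  ), class = "nb_model")
}

col_var <- function(x) {
  n <- nrow(x)
  if (n < 2L) return(rep(0, ncol(x)))
  mu <- colMeans(x)
  colSums((x - rep(mu, each = n))^2) / (n - 1L)
}

#' Posterior probability of the positive class
#'
#' Evaluates the Gaussian naive Bayes posterior for each query in log space
#' (sums of log densities plus log priors, combined through a logistic
#' difference) so long feature vectors cannot underflow to 0/0.
#'
#' @param model An [nb_train()] model.
#' @param x Numeric matrix (or single vector) of queries with the same
#'   components, in the same order, as the training matrix.
#' @return Numeric vector of positive-class posteriors in `[0, 1]`.
#' @export
nb_predict_proba <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L, dimnames = list(NULL, names(x)))
  x <- as.matrix(x)
  if (ncol(x) != model$n_features)
    stop("nb_predict_proba: query has ", ncol(x), " components but the model was trained on ",
         model$n_features)
  if (!is.null(model$component_names) && !is.null(colnames(x)) &&
      !identical(colnames(x), model$component_names))
    stop("nb_predict_proba: feature family/component mismatch between model and query")

  loglik <- function(mu, v) {
    # sum_j log N(x_j; mu_j, v_j), vectorized over rows
    const <- -0.5 * sum(log(2 * pi * v))
    const - 0.5 * colSums((t(x) - mu)^2 / v)
  }
  l1 <- loglik(model$mu1, model$var1) + model$log_prior1
  l0 <- loglik(model$mu0, model$var0) + model$log_prior0
  1 / (1 + exp(l0 - l1))
}

#' Seeded stratified fold assignment
#'
#' Assigns each instance to one of `k` cross-validation folds, stratified by
#' the binary label: shuffled positives are dealt round-robin into the folds,
#' then shuffled negatives continue the deal from the next fold, so per-class
#' and total fold sizes each differ by at most one.
#'
#' @param y 0/1 labels (named by idr id if available).
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return Integer vector of fold indices in `1..k`, same names as `y`.
#' @export
make_folds <- function(y, k = 10L, seed = 1L) {
  if (k < 2L) stop("make_folds: k must be >= 2")
  y <- as.integer(y)
  n <- length(y)
  fold <- integer(n)
  pos <- which(y == 1L); neg <- which(y == 0L)
  with_seed(seed, {
    order_pos <- pos[sample.int(length(pos))]   # sample.int: safe for length 1
    order_neg <- neg[sample.int(length(neg))]
  })
  dealt <- c(order_pos, order_neg)
  fold[dealt] <- ((seq_len(n) - 1L) %% k) + 1L
  names(fold) <- names(y)
  fold
}

#' Cross-validated confusion counts for one term
#'
#' Runs seeded stratified k-fold cross-validation of the one-vs-rest Gaussian
#' naive Bayes classifier for a single GO Slim term: each IDR is scored
#' exactly once, in the fold where it is held out, and called positive when
#' its posterior is at or above the 0.5 operating point (the tie at exactly
#' 0.5 counts as a positive call). Terms with fewer than `min_positives`
#' positive or negative IDRs, or with a training fold containing a single
#' class, are skipped with the reason recorded.
#'
#' @param x Feature matrix (rows = IDRs, rownames = idr ids).
#' @param y 0/1 labels aligned with the rows of `x`.
#' @param k Folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param min_positives Minimum members required in each class (default 10).
#' @param var_floor_frac Passed to [nb_train()].
#' @param threshold Posterior call threshold (default 0.5, inclusive).
#' @return A list with `status` (`"ok"` or `"skipped"`), `reason`, `counts`
#'   (named tp/fp/tn/fn when ok), `n_pos`, and the fold assignment.
#' @export
cross_validate_term <- function(x, y, k = 10L, seed = 1L, min_positives = 10L,
                                var_floor_frac = 1e-9, threshold = 0.5) {
  x <- as.matrix(x)
  y <- as.integer(y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 < min_positives || n0 < min_positives) {
    return(list(status = "skipped",
                reason = sprintf("class sizes %d/%d below min_positives=%d",
                                 n1, n0, min_positives),
                counts = NULL, n_pos = n1, folds = NULL))
  }
  fold <- make_folds(y, k = k, seed = seed)
  tp <- fp <- tn <- fn <- 0L
  for (f in seq_len(k)) {
    test <- fold == f
    ytr <- y[!test]
    if (length(unique(ytr)) < 2L)
      return(list(status = "skipped",
                  reason = sprintf("fold %d leaves a single-class training set", f),
                  counts = NULL, n_pos = n1, folds = fold))
    model <- nb_train(x[!test, , drop = FALSE], ytr,
                      var_floor_frac = var_floor_frac)
    p <- nb_predict_proba(model, x[test, , drop = FALSE])
    call_pos <- p >= threshold
    yt <- y[test] == 1L
    tp <- tp + sum(call_pos & yt);  fp <- fp + sum(call_pos & !yt)
    fn <- fn + sum(!call_pos & yt); tn <- tn + sum(!call_pos & !yt)
  }
  list(status = "ok", reason = NA_character_,
       counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
       n_pos = n1, folds = fold)
}

#' Cross-validate every term for one feature family
#'
#' Applies [cross_validate_term()] to each term of the vocabulary against one
#' feature matrix and collects the confusion counts into a data frame (one
#' row per term, skipped terms flagged with their reason).
#'
#' @param x Feature matrix (rownames = idr ids).
#' @param annotations Named list idr id -> expanded term set; must cover the
#'   rownames of `x`.
#' @param terms Character vector of term ids to evaluate.
#' @param family Family label recorded in the output.
#' @inheritParams cross_validate_term
#' @return data.frame with columns term_id, family, status, reason,
#'   n_train_pos, tp, fp, tn, fn.
#' @export
cv_all_terms <- function(x, annotations, terms, family = "feature",
                         k = 10L, seed = 1L, min_positives = 10L,
                         var_floor_frac = 1e-9) {
  ids <- rownames(x)
  if (is.null(ids) || !all(ids %in% names(annotations)))
    stop("cv_all_terms: feature matrix rownames must all have annotations")
  ann <- annotations[ids]
  rows <- lapply(terms, function(tm) {
    y <- binarize(ann, tm)
    r <- cross_validate_term(x, y, k = k, seed = seed,
                             min_positives = min_positives,
                             var_floor_frac = var_floor_frac)
    cts <- if (r$status == "ok") r$counts else c(tp = NA_integer_, fp = NA_integer_,
                                                 tn = NA_integer_, fn = NA_integer_)
    data.frame(term_id = tm, family = family, status = r$status,
               reason = r$reason, n_train_pos = r$n_pos,
               tp = cts[["tp"]], fp = cts[["fp"]], tn = cts[["tn"]],
               fn = cts[["fn"]], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Train per-term classifiers on a training split and score a test split
#'
#' Supports the held-out precision-recall protocol: for every term with at
#' least `min_positives` members in each class on the training rows, a
#' Gaussian naive Bayes model is fitted and the positive posterior of every
#' test IDR is recorded.
#'
#' @param x_train,x_test Feature matrices (rownames = idr ids).
#' @param annotations Named list idr id -> expanded term set.
#' @param terms Term vocabulary.
#' @inheritParams cross_validate_term
#' @return data.frame with columns idr_id, term_id, probability.
#' @export
predict_test_set <- function(x_train, x_test, annotations, terms,
                             min_positives = 10L, var_floor_frac = 1e-9) {
  ann_tr <- annotations[rownames(x_train)]
  out <- list()
  for (tm in terms) {
    y <- binarize(ann_tr, tm)
    if (sum(y == 1L) < min_positives || sum(y == 0L) < min_positives) next
    model <- nb_train(x_train, y, var_floor_frac = var_floor_frac)
    p <- nb_predict_proba(model, x_test)
    out[[tm]] <- data.frame(idr_id = rownames(x_test), term_id = tm,
                            probability = unname(p), stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(idr_id = character(), term_id = character(),
                      probability = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
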