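# Independent brute-force oracles, deliberately written in a different style
# (explicit loops over every possibility) from the implementation they check.

AA <- idrfunc::AA_ALPHABET

random_residues <- function(L) sample(AA, L, replace = TRUE)

# Count-every-ordered-pair bigram oracle; gap = 0 adjacent, 1 alternate.
oracle_bigrams <- function(res, gap = 0L) {
  L <- length(res)
  step <- gap + 1L
  out <- numeric(400)
  names(out) <- as.vector(t(outer(AA, AA, paste0)))
  if (L <= step) return(out)
  for (a in AA) for (b in AA) {
    cnt <- 0L
    for (i in seq_len(L - step))
      if (res[i] == a && res[i + step] == b) cnt <- cnt + 1L
    out[paste0(a, b)] <- cnt / (L - step)
  }
  out
}

# Position-and-pair enumeration oracle for one CTD property block.
oracle_ctd <- function(res, partition) {
  L <- length(res)
  grp <- vapply(res, function(r) {
    for (g in 1:3) if (r %in% partition[[g]]) return(g)
    stop("residue not covered")
  }, integer(1))
  comp <- c(mean(grp == 1), mean(grp == 2), mean(grp == 3))
  trans <- c(0, 0, 0)
  if (L > 1) {
    for (i in 1:(L - 1)) {
      pr <- sort(c(grp[i], grp[i + 1]))
      if (pr[1] == 1 && pr[2] == 2) trans[1] <- trans[1] + 1
      if (pr[1] == 1 && pr[2] == 3) trans[2] <- trans[2] + 1
      if (pr[1] == 2 && pr[2] == 3) trans[3] <- trans[3] + 1
    }
    trans <- trans / (L - 1)
  }
  dist <- numeric(15)
  for (g in 1:3) {
    pos <- which(grp == g)
    n <- length(pos)
    if (n > 0) {
      ks <- c(1, ceiling(0.25 * n), ceiling(0.5 * n), ceiling(0.75 * n), n)
      dist[(g - 1) * 5 + 1:5] <- pos[ks] / L
    }
  }
  unname(c(comp, trans, dist))
}

# Brute-force set-comparison oracle for the per-IDR PR procedure.
oracle_pr <- function(predictions, known_terms, test_ids, prob_grid) {
  res <- data.frame()
  for (p in prob_grid) {
    n_correct <- 0
    recalls <- c(); precisions <- c()
    for (id in test_ids) {
      rows <- predictions[predictions$idr_id == id, ]
      predicted <- rows$term_id[rows$probability >= p]
      known <- known_terms[[id]]
      tp <- sum(known %in% predicted)
      fp <- sum(!(predicted %in% known))
      fn <- sum(!(known %in% predicted))
      recalls <- c(recalls, if (tp + fn > 0) tp / (tp + fn) else 0)
      precisions <- c(precisions, if (tp + fp > 0) tp / (tp + fp) else 0)
      if (tp >= 1) n_correct <- n_correct + 1
    }
    res <- rbind(res, data.frame(
      p = p, overall_precision = n_correct / length(test_ids),
      average_recall = mean(recalls), mean_idr_precision = mean(precisions),
      n_correct = n_correct))
  }
  res
}

# One-hot PSSM encoding of a sequence.
one_hot_pssm <- function(res, idr_id = "onehot") {
  m <- matrix(0, nrow = length(res), ncol = 20)
  m[cbind(seq_along(res), match(res, AA))] <- 1
  idrfunc::pssm_matrix(idr_id, m)
}

# Small labelled feature set used in classifier tests: 1-D Gaussian classes.
toy_1d <- function(n_pos = 20, n_neg = 20, mu_pos = 10, mu_neg = 0, sd = 1,
                   seed = 42) {
  set.seed(seed)
  x <- matrix(c(rnorm(n_pos, mu_pos, sd), rnorm(n_neg, mu_neg, sd)), ncol = 1)
  colnames(x) <- "f1"
  list(x = x, y = c(rep(1L, n_pos), rep(0L, n_neg)))
}
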