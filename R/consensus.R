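#' Pairwise Spearman concordance between experts
#'
#' Spearman rank correlation over pairwise-complete items, with average
#' ranks for ties. Pairs with fewer than two overlapping items, and experts
#' whose usable ratings have zero variance, yield `NA` entries.
#'
#' @param ratings Experts x items numeric matrix in 1..5, `NA` = missing.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(ratings) {
  ratings <- as.matrix(ratings)
  stopifnot(nrow(ratings) >= 2)
  n <- nrow(ratings)
  cc <- suppressWarnings(
    stats::cor(t(ratings), method = "spearman",
               use = "pairwise.complete.obs"))
  # overlap < 2 items -> undefined
  obs <- !is.na(ratings)
  overlap <- obs %*% t(obs)
  cc[overlap < 2] <- NA
  diag(cc) <- 1
  cc
}

#' Competence weights from a concordance matrix
#'
#' Fits a single-factor maximum-likelihood factor analysis to the expert
#' correlation matrix; the first-factor loadings are the competence weights
#' and the first factor's variance share is the consensus rate. Missing
#' entries are imputed from the two experts' mean observed correlations.
#' Negative loadings are floored at 0 (consensus theory assumes non-negative
#' competence). On non-convergence the first principal eigenvector (scaled
#' into `[0, 1]`) is used; with fewer than 3 experts the fallback weight is
#' each expert's mean correlation with the others, floored at 0.
#'
#' @param corr Expert correlation matrix from [spearman_matrix()].
#' @return List with `weights` (per expert, in `[0, 1]`) and
#'   `consensus_rate` (first-factor variance share, `NA` for fallbacks
#'   without one).
#' @export
competence_weights <- function(corr) {
  corr <- as.matrix(corr)
  n <- nrow(corr)
  ids <- rownames(corr)
  if (n < 3) {
    off <- corr
    diag(off) <- NA
    w <- pmax(rowMeans(off, na.rm = TRUE), 0)
    w[is.nan(w)] <- 0
    return(list(weights = stats::setNames(pmin(w, 1), ids),
                consensus_rate = NA_real_))
  }
  # impute undefined pairs from the two experts' mean observed correlation
  off <- corr
  diag(off) <- NA
  row_mean <- rowMeans(off, na.rm = TRUE)
  row_mean[is.nan(row_mean)] <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && is.na(corr[i, j]))
      corr[i, j] <- (row_mean[i] + row_mean[j]) / 2
  }
  fa <- tryCatch(
    stats::factanal(covmat = corr, factors = 1, n.obs = n),
    error = function(e) NULL)
  if (!is.null(fa)) {
    load <- as.numeric(fa$loadings[, 1])
    if (sum(load) < 0) load <- -load   # factor sign is arbitrary
    consensus <- sum(load^2) / n
  } else {
    eig <- eigen(corr, symmetric = TRUE)
    load <- eig$vectors[, 1]
    if (sum(load) < 0) load <- -load
    load <- load / max(abs(load))
    consensus <- eig$values[1] / n
  }
  w <- pmin(pmax(load, 0), 1)
  list(weights = stats::setNames(w, ids), consensus_rate = consensus)
}

#' Competence-weighted item scores
#'
#' `S_j = sum_i w_i r_ij / sum_i w_i` over the experts who rated item j.
#' Items rated only by zero-weight experts get `NA` and a warning.
#'
#' @param ratings Experts x items matrix, `NA` = missing.
#' @param weights Per-expert non-negative weights.
#' @return Named numeric vector of per-item scores in `[1, 5]`.
#' @export
weighted_scores <- function(ratings, weights) {
  ratings <- as.matrix(ratings)
  stopifnot(length(weights) == nrow(ratings), all(weights >= 0))
  scores <- apply(ratings, 2, function(col) {
    ok <- !is.na(col)
    wsum <- sum(weights[ok])
    if (wsum <= 0) return(NA_real_)
    sum(weights[ok] * col[ok]) / wsum
  })
  if (anyNA(scores))
    warning("item(s) rated only by zero-weight experts: score undefined")
  scores
}

#' Pick the winning item from weighted scores
#'
#' Argmax over defined scores; ties are broken by the lowest item index with
#' a warning.
#'
#' @param scores Named numeric vector (possibly with `NA`s).
#' @return The winning item's name (or index when unnamed).
#' @export
select_best <- function(scores) {
  ok <- which(!is.na(scores))
  if (length(ok) == 0) stop("no defined scores")
  best <- ok[which.max(scores[ok])]
  if (sum(scores[ok] == scores[best], na.rm = TRUE) > 1)
    warning("tied top scores; keeping the lowest item index")
  if (!is.null(names(scores))) names(scores)[best] else best
}

#' Cultural-consensus analysis of an expert rating block
#'
#' Runs the full consensus chain on one experts x items block: experts with
#' fewer than two usable ratings are dropped, pairwise Spearman concordance
#' is computed, a single-factor ML factor analysis yields per-expert
#' competence weights, and competence-weighted item scores are produced.
#' `average_concordance` is the mean weight over the valid experts, matching
#' the per-species "average concordance value" reported alongside weighted
#' scores.
#'
#' @param ratings Experts x items matrix in 1..5, `NA` = missing.
#' @return An object of class `consensus`: `weights`, `scores`,
#'   `average_concordance`, `consensus_rate`, `n_valid_experts`, `best`.
#' @export
consensus <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (is.null(rownames(ratings)))
    rownames(ratings) <- paste0("expert_", seq_len(nrow(ratings)))
  if (is.null(colnames(ratings)))
    colnames(ratings) <- paste0("item_", seq_len(ncol(ratings)))
  usable <- rowSums(!is.na(ratings)) >= 2
  kept <- ratings[usable, , drop = FALSE]
  if (nrow(kept) < 2) stop("fewer than 2 experts with >= 2 usable ratings")
  cc <- spearman_matrix(kept)
  cw <- competence_weights(cc)
  scores <- weighted_scores(kept, cw$weights)
  structure(list(weights = cw$weights,
                 scores = scores,
                 average_concordance = mean(cw$weights),
                 consensus_rate = cw$consensus_rate,
                 n_valid_experts = nrow(kept),
                 best = select_best(scores),
                 dropped_experts = rownames(ratings)[!usable]),
            class = "consensus")
}

#' @export
print.consensus <- function(x, ...) {
  cat(sprintf("consensus: %d valid experts, average concordance %.2f\n",
              x$n_valid_experts, x$average_concordance))
  cat("weighted scores:\n")
  print(round(x$scores, 2))
  cat(sprintf("best item: %s\n", x$best))
  invisible(x)
}

#' @export
summary.consensus <- function(object, ...) {
  cat(sprintf("Valid experts: %d (dropped: %s)\n", object$n_valid_experts,
              if (length(object$dropped_experts))
                paste(object$dropped_experts, collapse = ", ") else "none"))
  cat(sprintf("First-factor consensus rate: %.3f\n", object$consensus_rate))
  cat("Expert weights:\n"); print(round(object$weights, 3))
  cat("Weighted item scores:\n"); print(round(object$scores, 3))
  invisible(object)
}

#' @export
coef.consensus <- function(object, ...) object$weights

#' Normalize a 1-5 sensitivity score to [0, 1]
#'
#' Default maps the printed 1-5 scale linearly onto `[0, 1]` as
#' `(S - 1) / 4`; `"over5"` uses `S / 5`; `"minmax"` rescales a vector of
#' scores by its own range.
#'
#' @param scores Numeric scores in `[1, 5]`.
#' @param mode Normalization mode.
#' @return Normalized scores in `[0, 1]`.
#' @export
normalize_sensitivity <- function(scores,
                                  mode = c("minus1_over4", "over5",
                                           "minmax")) {
  mode <- match.arg(mode)
  stopifnot(all(scores >= 1 & scores <= 5, na.rm = TRUE))
  switch(mode,
         minus1_over4 = (scores - 1) / 4,
         over5 = scores / 5,
         minmax = {
           rng <- range(scores, na.rm = TRUE)
           if (diff(rng) == 0) rep(0, length(scores))
           else (scores - rng[1]) / diff(rng)
         })
}
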