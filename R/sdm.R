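#' Stepwise variable elimination by variance inflation factor
#'
#' Repeatedly removes the variable with the largest VIF while that VIF
#' exceeds the threshold. `VIF_k = 1 / (1 - R^2_k)` where `R^2_k` comes from
#' regressing variable k on the remaining variables over masked-in cells;
#' a perfectly collinear variable has infinite VIF and is removed first.
#'
#' @param env An `env_stack` with at least two variables.
#' @param threshold Maximum VIF allowed in the retained set (default 20).
#' @return Character vector of retained variable names, in original order.
#' @export
vif_stepwise <- function(env, threshold = 20) {
  stopifnot(inherits(env, "env_stack"), length(env) >= 2)
  mask <- Reduce(`&`, lapply(env, `[[`, "mask"))
  X <- vapply(env, function(l) l$values[mask], numeric(sum(mask)))
  if (nrow(X) < ncol(X) + 2) stop("too few masked cells for VIF regression")
  keep <- colnames(X)
  vif_of <- function(k, vars) {
    y <- X[, k]
    others <- X[, setdiff(vars, k), drop = FALSE]
    r2 <- summary(stats::lm(y ~ others))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  repeat {
    if (length(keep) < 2) break
    vifs <- vapply(keep, vif_of, 0, vars = keep)
    if (max(vifs) <= threshold) break
    keep <- setdiff(keep, keep[which.max(vifs)])
  }
  names(env)[names(env) %in% keep]
}

#' Area under the ROC curve, Mann-Whitney form
#'
#' `P(pos > neg) + 0.5 * P(pos = neg)` computed from joint ranks, so tied
#' scores contribute half a win.
#'
#' @param pos,neg Numeric score vectors for positives (presences) and
#'   negatives (background); both non-empty.
#' @return AUC in `[0, 1]`.
#' @export
auc_mw <- function(pos, neg) {
  if (length(pos) == 0 || length(neg) == 0)
    stop("auc_mw: empty score vector")
  r <- rank(c(pos, neg))
  np <- length(pos)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * length(neg))
}

#' Ensemble calibration configuration
#'
#' Defaults are the assessment's standard protocol: 2000 background
#' locations, 4-fold splits, 5 calibration repeats, the 10 best of 12
#' candidate submodels kept, a VIF ceiling of 20 and a minimum of 30 unique
#' presence cells per species.
#'
#' @param n_background Background cells sampled per repeat (without
#'   replacement, excluding presence cells).
#' @param n_folds Number of random subsets for train/test splitting.
#' @param n_repeats Number of calibration repeats averaged.
#' @param n_keep Number of top-AUC candidates receiving ensemble weight.
#' @param min_unique_obs Minimum unique presence cells; fewer raises a
#'   `species_rejected` error.
#' @param vif_threshold VIF ceiling for [vif_stepwise()].
#' @param candidates Candidate registry (see [default_candidates()]).
#' @return A list of class `sdm_config`.
#' @export
sdm_config <- function(n_background = 2000, n_folds = 4, n_repeats = 5,
                       n_keep = 10, min_unique_obs = 30, vif_threshold = 20,
                       candidates = default_candidates()) {
  stopifnot(n_background >= 1, n_folds >= 2, n_repeats >= 1, n_keep >= 1,
            min_unique_obs >= 1, vif_threshold > 0, length(candidates) >= 1)
  structure(list(n_background = n_background, n_folds = n_folds,
                 n_repeats = n_repeats, n_keep = n_keep,
                 min_unique_obs = min_unique_obs,
                 vif_threshold = vif_threshold, candidates = candidates),
            class = "sdm_config")
}

# rows of environmental values at linear cell indices
env_rows <- function(env, cells) {
  as.data.frame(lapply(env, function(l) l$values[cells]))
}

# map occurrence records to unique masked-in linear cell indices
presence_cells <- function(occurrences, env) {
  spec <- env[[1]]$spec
  mask <- Reduce(`&`, lapply(env, `[[`, "mask"))
  idx <- point_cell_index(occurrences$lon, occurrences$lat, spec)
  keep <- idx$inside
  cells <- (idx$col[keep] - 1L) * spec$n_rows + idx$row[keep]
  cells <- unique(cells[mask[cells]])
  cells
}

#' Calibrate an AUC-weighted ensemble species distribution model
#'
#' For each calibration repeat: sample background cells (excluding presence
#' cells), split presences and backgrounds into `n_folds` random subsets,
#' fit every candidate on the training folds and score the held-out fold by
#' AUC. Candidate AUCs are averaged over folds and repeats; the `n_keep`
#' candidates with the highest mean AUC receive weights proportional to
#' those AUCs (summing to 1). The final suitability layer is the mean over
#' repeats of the weighted ensemble prediction from candidates refitted on
#' each repeat's full data. Presence thresholds (`minimum` and `tpr90`) are
#' computed on the final averaged suitability at the presence cells.
#'
#' A candidate that errors anywhere receives AUC 0 for that fold and cannot
#' enter the kept set; if fewer than `n_keep` candidates survive, all
#' survivors are used and their weights renormalized (with a message). Ties
#' at the `n_keep`-th rank are broken by registry order.
#'
#' @param occurrences Data frame with `lon`, `lat` columns (one species).
#' @param env An `env_stack` of calibration-scenario variables.
#' @param config An [sdm_config()].
#' @param seed Integer seed controlling background sampling and fold splits.
#' @return An object of class `ensemble_sdm`.
#' @export
calibrate_ensemble <- function(occurrences, env, config = sdm_config(),
                               seed = 1) {
  stopifnot(inherits(env, "env_stack"), inherits(config, "sdm_config"))
  spec <- env[[1]]$spec
  mask <- Reduce(`&`, lapply(env, `[[`, "mask"))
  pres <- presence_cells(occurrences, env)
  if (length(pres) < config$min_unique_obs)
    stop(structure(class = c("species_rejected", "error", "condition"),
                   list(message = sprintf(
                     paste0("species rejected: %d unique presence cells, ",
                            "minimum of %d unique observations required"),
                     length(pres), config$min_unique_obs),
                     call = sys.call())))
  pool <- setdiff(which(mask), pres)
  n_bg <- min(config$n_background, length(pool))
  if (n_bg < config$n_background)
    message(sprintf("only %d background cells available (requested %d)",
                    n_bg, config$n_background))

  cands <- config$candidates
  n_cand <- length(cands)
  set.seed(seed)
  auc_mat <- matrix(0, n_cand, config$n_repeats,
                    dimnames = list(names(cands), NULL))
  repeat_models <- vector("list", config$n_repeats)
  repeat_bg <- vector("list", config$n_repeats)
  # held-out predictions kept so the ensemble's own test AUC can be scored
  # once the weights are known
  test_preds <- vector("list", config$n_repeats)

  X_pres <- env_rows(env, pres)
  for (r in seq_len(config$n_repeats)) {
    bg <- sample(pool, n_bg)
    repeat_bg[[r]] <- bg
    X_bg <- env_rows(env, bg)
    fold_p <- sample(rep_len(seq_len(config$n_folds), length(pres)))
    fold_b <- sample(rep_len(seq_len(config$n_folds), n_bg))
    fold_auc <- matrix(0, n_cand, config$n_folds)
    tp <- vector("list", config$n_folds)
    for (f in seq_len(config$n_folds)) {
      tr_x <- rbind(X_pres[fold_p != f, , drop = FALSE],
                    X_bg[fold_b != f, , drop = FALSE])
      tr_y <- c(rep(1, sum(fold_p != f)), rep(0, sum(fold_b != f)))
      te_x <- rbind(X_pres[fold_p == f, , drop = FALSE],
                    X_bg[fold_b == f, , drop = FALSE])
      te_y <- c(rep(1, sum(fold_p == f)), rep(0, sum(fold_b == f)))
      preds <- matrix(NA_real_, nrow(te_x), n_cand,
                      dimnames = list(NULL, names(cands)))
      for (k in seq_len(n_cand)) {
        sc <- tryCatch({
          m <- cands[[k]]$fit(tr_x, tr_y)
          cands[[k]]$predict(m, te_x)
        }, error = function(e) NULL)
        if (!is.null(sc) && all(is.finite(sc))) {
          preds[, k] <- sc
          fold_auc[k, f] <- auc_mw(sc[te_y == 1], sc[te_y == 0])
        }
      }
      tp[[f]] <- list(preds = preds, y = te_y)
    }
    test_preds[[r]] <- tp
    auc_mat[, r] <- rowMeans(fold_auc)
  }

  mean_auc <- rowMeans(auc_mat)
  ok <- which(mean_auc > 0)
  ord <- ok[order(-mean_auc[ok], ok)]
  kept <- sort(ord[seq_len(min(config$n_keep, length(ord)))])
  if (length(kept) < config$n_keep)
    message(sprintf("only %d of %d candidates fit successfully; %s",
                    length(ord), n_cand,
                    "using all survivors with renormalized weights"))
  weights <- stats::setNames(rep(0, n_cand), names(cands))
  weights[kept] <- mean_auc[kept] / sum(mean_auc[kept])

  # refit kept candidates on each repeat's full data; predict masked cells
  all_cells <- which(mask)
  X_all <- env_rows(env, all_cells)
  suit_sum <- rep(0, length(all_cells))
  ens_test_auc <- numeric(0)
  for (r in seq_len(config$n_repeats)) {
    X_bg <- env_rows(env, repeat_bg[[r]])
    x <- rbind(X_pres, X_bg)
    y <- c(rep(1, nrow(X_pres)), rep(0, nrow(X_bg)))
    models <- vector("list", length(kept))
    names(models) <- names(cands)[kept]
    ens_r <- rep(0, length(all_cells))
    for (m in seq_along(kept)) {
      k <- kept[m]
      fitted <- tryCatch(cands[[k]]$fit(x, y), error = function(e) NULL)
      models[[m]] <- fitted
      if (!is.null(fitted))
        ens_r <- ens_r + weights[k] *
          tryCatch(cands[[k]]$predict(fitted, X_all),
                   error = function(e) rep(0, length(all_cells)))
    }
    repeat_models[[r]] <- models
    suit_sum <- suit_sum + ens_r
    # ensemble held-out AUC for this repeat, from stored fold predictions
    for (f in seq_len(config$n_folds)) {
      tp <- test_preds[[r]][[f]]
      w_ok <- kept[!is.na(colSums(tp$preds[, kept, drop = FALSE]))]
      if (length(w_ok)) {
        es <- as.numeric(tp$preds[, w_ok, drop = FALSE] %*%
                           (weights[w_ok] / sum(weights[w_ok])))
        ens_test_auc <- c(ens_test_auc,
                          auc_mw(es[tp$y == 1], es[tp$y == 0]))
      }
    }
  }
  suit_vals <- matrix(0, spec$n_rows, spec$n_cols)
  suit_vals[all_cells] <- clamp01(suit_sum / config$n_repeats)
  suitability <- grid_layer(spec, suit_vals, mask)

  pres_scores <- suit_vals[pres]
  obj <- structure(list(
    variables = names(env),
    candidates = data.frame(candidate = names(cands),
                            mean_auc = unname(mean_auc),
                            weight = unname(weights)),
    weights = weights,
    kept = names(cands)[kept],
    suitability = suitability,
    presence_cells = pres,
    threshold_min = threshold_min(pres_scores),
    threshold_tpr90 = threshold_tpr90(pres_scores),
    ensemble_test_auc = mean(ens_test_auc),
    repeat_models = repeat_models,
    config = config,
    seed = seed),
    class = "ensemble_sdm")
  obj
}

#' Minimum-presence suitability threshold
#'
#' The smallest predicted suitability over presence cells; the presence map
#' `suitability >= threshold` then covers every presence cell.
#'
#' @param pres_scores Suitability values at presence cells (non-empty).
#' @return The threshold.
#' @export
threshold_min <- function(pres_scores) {
  stopifnot(length(pres_scores) >= 1)
  min(pres_scores)
}

#' 90%-true-positive-rate suitability threshold
#'
#' The largest threshold `t` such that at least 90% of presence scores are
#' `>= t`: the `floor(0.1 n) + 1`-th smallest presence score.
#'
#' @param pres_scores Suitability values at presence cells (non-empty).
#' @return The threshold.
#' @export
threshold_tpr90 <- function(pres_scores) {
  n <- length(pres_scores)
  stopifnot(n >= 1)
  sort(pres_scores)[floor(0.1 * n) + 1]
}

#' @export
print.ensemble_sdm <- function(x, ...) {
  cat(sprintf("ensemble_sdm: %d candidates, %d kept, %d presence cells\n",
              nrow(x$candidates), length(x$kept), length(x$presence_cells)))
  cat(sprintf("variables: %s\n", paste(x$variables, collapse = ", ")))
  cat(sprintf("thresholds: minimum %.4f, tpr90 %.4f; mean test AUC %.3f\n",
              x$threshold_min, x$threshold_tpr90, x$ensemble_test_auc))
  invisible(x)
}

#' @export
summary.ensemble_sdm <- function(object, ...) {
  tab <- object$candidates[order(-object$candidates$mean_auc), ]
  rownames(tab) <- NULL
  structure(list(candidates = tab,
                 threshold_min = object$threshold_min,
                 threshold_tpr90 = object$threshold_tpr90,
                 ensemble_test_auc = object$ensemble_test_auc,
                 n_presences = length(object$presence_cells)),
            class = "summary.ensemble_sdm")
}

#' @export
print.summary.ensemble_sdm <- function(x, ...) {
  cat("Candidate submodels (mean held-out AUC and ensemble weight):\n")
  print(x$candidates, digits = 3)
  cat(sprintf("\nPresence cells: %d\nEnsemble mean test AUC: %.3f\n",
              x$n_presences, x$ensemble_test_auc))
  cat(sprintf("Thresholds: minimum %.4f, tpr90 %.4f\n",
              x$threshold_min, x$threshold_tpr90))
  invisible(x)
}

#' @export
coef.ensemble_sdm <- function(object, ...) object$weights

#' Predict ensemble suitability or presence on an environment stack
#'
#' Suitability on a new stack (e.g. a future scenario) is the mean over
#' calibration repeats of the AUC-weighted candidate predictions from the
#' models refitted on each repeat's full data. With `type = "presence"` the
#' suitability is cut at the requested calibration threshold.
#'
#' @param object An `ensemble_sdm`.
#' @param env An `env_stack` containing the model's variables; defaults to
#'   returning the stored calibration-scenario suitability.
#' @param type `"suitability"` or `"presence"`.
#' @param threshold `"tpr90"` or `"minimum"` (used for presence maps).
#' @param ... Unused.
#' @return A `grid_layer`; for presence maps values are 0/1.
#' @export
predict.ensemble_sdm <- function(object, env = NULL,
                                 type = c("suitability", "presence"),
                                 threshold = c("tpr90", "minimum"), ...) {
  type <- match.arg(type)
  threshold <- match.arg(threshold)
  if (is.null(env)) {
    suit <- object$suitability
  } else {
    stopifnot(inherits(env, "env_stack"))
    missing <- setdiff(object$variables, names(env))
    if (length(missing))
      stop("env stack lacks model variable(s): ",
           paste(missing, collapse = ", "))
    env <- env_stack(env[object$variables])
    spec <- env[[1]]$spec
    mask <- Reduce(`&`, lapply(env, `[[`, "mask"))
    cells <- which(mask)
    X <- env_rows(env, cells)
    cands <- object$config$candidates
    w <- object$weights
    total <- rep(0, length(cells))
    n_rep <- length(object$repeat_models)
    for (r in seq_len(n_rep)) {
      models <- object$repeat_models[[r]]
      for (nm in names(models)) {
        if (is.null(models[[nm]])) next
        total <- total + w[nm] *
          tryCatch(cands[[nm]]$predict(models[[nm]], X),
                   error = function(e) rep(0, length(cells)))
      }
    }
    vals <- matrix(0, spec$n_rows, spec$n_cols)
    vals[cells] <- clamp01(total / n_rep)
    suit <- grid_layer(spec, vals, mask)
  }
  if (type == "suitability") return(suit)
  t_val <- if (threshold == "tpr90") object$threshold_tpr90 else
    object$threshold_min
  grid_layer(suit$spec, (suit$values >= t_val) * 1, suit$mask)
}

#' Presence/absence map from a calibrated ensemble
#'
#' Thin wrapper over [predict.ensemble_sdm()] with `type = "presence"`.
#'
#' @inheritParams predict.ensemble_sdm
#' @return A 0/1 `grid_layer`.
#' @export
predict_presence <- function(object, env = NULL,
                             threshold = c("tpr90", "minimum")) {
  predict(object, env = env, type = "presence",
          threshold = match.arg(threshold))
}

#' Detect novel climate cells
#'
#' A cell is novel under a future stack when at least one variable falls
#' outside the closed min-max envelope of current conditions over the
#' reference mask (a value exactly equal to the current extreme is not
#' novel).
#'
#' @param current,future `env_stack`s on one grid.
#' @param variables Variables to check; default all shared variables.
#' @param reference_mask Logical matrix delimiting the reference region;
#'   default the current stack's validity mask.
#' @return A 0/1 `grid_layer` (1 = novel).
#' @export
detect_novel <- function(current, future, variables = NULL,
                         reference_mask = NULL) {
  stopifnot(inherits(current, "env_stack"), inherits(future, "env_stack"))
  if (is.null(variables))
    variables <- intersect(names(current), names(future))
  spec <- current[[1]]$spec
  if (!same_spec(spec, future[[1]]$spec))
    stop("current and future stacks on different grids")
  if (is.null(reference_mask))
    reference_mask <- Reduce(`&`, lapply(current[variables], `[[`, "mask"))
  novel <- matrix(FALSE, spec$n_rows, spec$n_cols)
  out_mask <- Reduce(`&`, lapply(future[variables], `[[`, "mask"))
  for (v in variables) {
    cur_v <- current[[v]]$values[reference_mask]
    lo <- min(cur_v); hi <- max(cur_v)
    fv <- future[[v]]$values
    novel <- novel | (out_mask & (fv < lo | fv > hi))
  }
  grid_layer(spec, novel * 1, out_mask)
}
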