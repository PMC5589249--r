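# Candidate submodel registry for the suitability ensemble.
#
# Contract: each candidate is a list(id, fit, predict) where
#   fit(x, y)         x: data.frame of environmental values, y: 0/1 vector
#   predict(model, x) returns suitability scores in [0, 1]
# Candidates that error during calibration are assigned AUC 0 by the
# ensemble and cannot enter the kept set.

clamp01 <- function(p) pmin(pmax(p, 0), 1)

quad_expand <- function(x) {
  sq <- as.data.frame(lapply(x, function(v) v^2))
  names(sq) <- paste0(names(x), "_sq")
  cbind(x, sq)
}

cand_glm_linear <- function() {
  list(id = "glm_linear",
       fit = function(x, y)
         stats::glm(y ~ ., data = cbind(x, y = y), family = stats::binomial()),
       predict = function(m, x)
         clamp01(stats::predict(m, newdata = x, type = "response")))
}

cand_glm_quadratic <- function() {
  list(id = "glm_quadratic",
       fit = function(x, y) {
         d <- quad_expand(x)
         stats::glm(y ~ ., data = cbind(d, y = y), family = stats::binomial())
       },
       predict = function(m, x)
         clamp01(stats::predict(m, newdata = quad_expand(x),
                                type = "response")))
}

cand_gam_spline <- function() {
  list(id = "gam_spline",
       fit = function(x, y) {
         k <- vapply(x, function(v) min(4, length(unique(v))), 0)
         terms <- ifelse(k >= 3, sprintf("s(%s, k = %d)", names(x), k),
                         names(x))
         f <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
         mgcv::gam(f, data = cbind(x, y = y), family = stats::binomial())
       },
       predict = function(m, x)
         clamp01(as.numeric(mgcv::predict.gam(m, newdata = x,
                                              type = "response"))))
}

cand_cart <- function() {
  list(id = "cart",
       fit = function(x, y)
         rpart::rpart(y ~ ., data = cbind(x, y = factor(y, levels = 0:1)),
                      method = "class",
                      control = rpart::rpart.control(cp = 0.005)),
       predict = function(m, x)
         clamp01(stats::predict(m, newdata = x, type = "prob")[, "1"]))
}

cand_random_forest <- function() {
  list(id = "random_forest",
       fit = function(x, y)
         ranger::ranger(y = factor(y, levels = 0:1), x = x,
                        probability = TRUE, num.trees = 200,
                        num.threads = 1),
       predict = function(m, x)
         clamp01(stats::predict(m, data = x,
                                num.threads = 1)$predictions[, "1"]))
}

cand_gradient_boost <- function() {
  list(id = "gradient_boost",
       fit = function(x, y)
         xgboost::xgboost(data = as.matrix(x), label = y, nrounds = 30,
                          max_depth = 3, eta = 0.3, nthread = 1,
                          objective = "binary:logistic", verbose = 0),
       predict = function(m, x)
         clamp01(stats::predict(m, as.matrix(x))))
}

cand_knn <- function() {
  list(id = "knn",
       fit = function(x, y) {
         mu <- vapply(x, mean, 0); sd <- vapply(x, stats::sd, 0)
         sd[sd == 0] <- 1
         list(train = scale(as.matrix(x), mu, sd), y = y, mu = mu, sd = sd,
              k = max(1, min(7, length(y) - 1)))
       },
       predict = function(m, x) {
         te <- scale(as.matrix(x), m$mu, m$sd)
         cl <- class::knn(m$train, te, factor(m$y, levels = 0:1), k = m$k,
                          prob = TRUE)
         p_win <- attr(cl, "prob")
         clamp01(ifelse(cl == "1", p_win, 1 - p_win))
       })
}

cand_naive_bayes <- function() {
  list(id = "naive_bayes",
       fit = function(x, y) e1071::naiveBayes(x, factor(y, levels = 0:1)),
       predict = function(m, x)
         clamp01(stats::predict(m, x, type = "raw")[, "1"]))
}

# Rectilinear (BIOCLIM-style) climate envelope: presence-only; per-variable
# score from the presence empirical CDF, 2*min(F, 1-F); overall = minimum
# over variables.
cand_envelope <- function() {
  list(id = "climate_envelope",
       fit = function(x, y) lapply(x[y == 1, , drop = FALSE], sort),
       predict = function(m, x) {
         s <- rep(1, nrow(x))
         for (v in names(m)) {
           f <- (findInterval(x[[v]], m[[v]])) / length(m[[v]])
           s <- pmin(s, 2 * pmin(f, 1 - f))
         }
         clamp01(s)
       })
}

# Mahalanobis-distance envelope: presence-only; suitability is the upper
# chi-square tail of the squared distance to the presence centroid.
cand_mahalanobis <- function() {
  list(id = "mahalanobis",
       fit = function(x, y) {
         xp <- as.matrix(x[y == 1, , drop = FALSE])
         S <- stats::cov(xp)
         S <- S + diag(1e-8 * (diag(S) + 1e-12), nrow(S))  # ridge guard
         list(center = colMeans(xp), cov = S, p = ncol(xp))
       },
       predict = function(m, x) {
         d2 <- stats::mahalanobis(as.matrix(x), m$center, m$cov)
         clamp01(stats::pchisq(d2, df = m$p, lower.tail = FALSE))
       })
}

cand_discriminant <- function() {
  list(id = "discriminant",
       fit = function(x, y) MASS::lda(x, grouping = factor(y, levels = 0:1)),
       predict = function(m, x)
         clamp01(stats::predict(m, x)$posterior[, "1"]))
}

# Max-entropy-flavoured exponential model: lasso-regularized logistic
# regression on linear + quadratic features, evaluated at the least
# penalized lambda of the path.
cand_maxent_like <- function() {
  list(id = "maxent_like",
       fit = function(x, y) {
         xm <- as.matrix(quad_expand(x))
         f <- glmnet::glmnet(xm, y, family = "binomial", alpha = 1,
                             nlambda = 30)
         list(fit = f, s = min(f$lambda))
       },
       predict = function(m, x) {
         xm <- as.matrix(quad_expand(x))
         clamp01(as.numeric(stats::predict(m$fit, xm, s = m$s,
                                           type = "response")))
       })
}

#' Default registry of 12 candidate suitability submodels
#'
#' Logistic regression (linear and quadratic), spline additive model,
#' classification tree, random forest, gradient-boosted trees, k-nearest
#' neighbours, naive Bayes, rectilinear climate envelope, Mahalanobis
#' envelope, linear discriminant, and a lasso-regularized exponential
#' (max-entropy-flavoured) model. Each exposes `fit(x, y)` and
#' `predict(model, x)` returning suitabilities in `[0, 1]`; the registry is
#' pluggable via the `candidates` entry of [sdm_config()].
#'
#' @return Named list of candidate definitions.
#' @export
default_candidates <- function() {
  cands <- list(cand_glm_linear(), cand_glm_quadratic(), cand_gam_spline(),
                cand_cart(), cand_random_forest(), cand_gradient_boost(),
                cand_knn(), cand_naive_bayes(), cand_envelope(),
                cand_mahalanobis(), cand_discriminant(), cand_maxent_like())
  stats::setNames(cands, vapply(cands, `[[`, "", "id"))
}
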