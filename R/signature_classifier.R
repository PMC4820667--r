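#' Select a sparse predictive model
#'
#' L1-penalized logistic regression over a decreasing penalty path with
#' the penalty chosen by cross-validated deviance and the 1-SE rule
#' (glmnet). Features are standardized internally and the scaling stored
#' so the model can be reapplied exactly. The support size can be capped
#' by walking down the path to the largest penalty admitting at most
#' `max_features` nonzero coefficients.
#'
#' @param x samples x features matrix (gene expression and/or clinical
#'   covariates, numeric).
#' @param y binary response (0/1, logical, or two-level factor).
#' @param max_features optional cap on support size.
#' @param nfolds folds for internal penalty selection.
#' @param seed seed for the internal CV fold split.
#' @return an `srs_model` list: `features` (selected ids), `intercept`,
#'   `coefficients` (on the standardized scale), `center`, `scale`,
#'   `lambda`, `separation_warning`.
#' @export
select_predictive_model <- function(x, y, max_features = NULL,
                                    nfolds = 10L, seed = 1L) {
  y <- as.integer(as.factor(y)) - 1L
  if (length(unique(y)) != 2) stop("response must be binary")
  if (min(table(y)) < 2) stop("need at least 2 samples per class")
  x <- as.matrix(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- scale(x, center = ctr, scale = scl)

  set.seed(stream_seed(seed, "classifier"))
  cv <- glmnet::cv.glmnet(xs, y, family = "binomial", alpha = 1,
                          standardize = FALSE, nfolds = nfolds,
                          type.measure = "deviance")
  lambda <- cv$lambda.1se
  if (!is.null(max_features)) {
    ok <- which(cv$nzero <= max_features)
    if (!length(ok)) stop("no penalty on the path satisfies the support cap")
    # best CV deviance among penalties within the support cap
    lambda <- cv$lambda[ok[which.min(cv$cvm[ok])]]
  }
  beta <- as.numeric(stats::coef(cv$glmnet.fit, s = lambda))
  names(beta) <- c("(Intercept)", colnames(xs))
  nz <- beta[-1][beta[-1] != 0]

  # crude separation check: fitted probabilities pinned at 0/1
  eta <- beta[1] + xs %*% beta[-1]
  pr <- 1 / (1 + exp(-eta))
  sep <- all(abs(pr - y) < 1e-8) && length(nz) > 0
  if (sep) warning("complete separation at the chosen penalty")

  structure(list(
    features = names(nz),
    intercept = unname(beta[1]),
    coefficients = nz,
    center = ctr[names(nz)],
    scale = scl[names(nz)],
    lambda = lambda,
    separation_warning = sep
  ), class = "srs_model")
}

#' Apply a sparse SRS model to new samples
#'
#' Applies the stored standardization and coefficients; a sample is
#' labelled SRS1 when its predicted probability is at least 0.5. Missing
#' features are an error (no silent imputation).
#'
#' @param x samples x features matrix for the new cohort.
#' @param model an `srs_model`.
#' @return data.frame with sample_id, probability (of class 1 = SRS1),
#'   label.
#' @export
assign_srs <- function(x, model) {
  x <- as.matrix(x)
  miss <- setdiff(model$features, colnames(x))
  if (length(miss)) {
    stop("missing model feature(s): ", paste(miss, collapse = ", "))
  }
  eta <- rep(model$intercept, nrow(x))
  if (length(model$features)) {
    xs <- sweep(sweep(x[, model$features, drop = FALSE], 2, model$center),
                2, model$scale, "/")
    eta <- eta + as.numeric(xs %*% model$coefficients)
  }
  pr <- 1 / (1 + exp(-eta))
  data.frame(
    sample_id = if (is.null(rownames(x))) seq_len(nrow(x)) else rownames(x),
    probability = pr,
    label = ifelse(pr >= 0.5, "SRS1", "SRS2"),
    stringsAsFactors = FALSE
  )
}

#' Leave-one-out cross-validated misclassification
#'
#' The entire selection-plus-fit procedure is repeated inside every
#' leave-one-out fold (no information leakage); the held-out sample is
#' predicted by the 0.5 probability cut. A fold whose training set loses
#' an entire class falls back to the majority-class prediction and is
#' flagged.
#'
#' @param x samples x features matrix.
#' @param y binary response.
#' @param max_features optional support cap passed to selection.
#' @param nfolds folds of the inner penalty-selection CV.
#' @param seed seed for the inner CV splits.
#' @return a `cv_result` list: `misclassification_rate`, `predictions`
#'   (per-fold label and probability), `n_folds`, `degenerate_folds`.
#' @export
loocv_misclassification <- function(x, y, max_features = NULL,
                                    nfolds = 10L, seed = 1L) {
  x <- as.matrix(x)
  y01 <- as.integer(as.factor(y)) - 1L
  n <- nrow(x)
  if (n < 10) stop("need at least 10 samples for LOOCV")
  pred <- numeric(n)
  degenerate <- logical(n)
  for (i in seq_len(n)) {
    ytr <- y01[-i]
    if (length(unique(ytr)) < 2) {
      pred[i] <- as.numeric(mean(ytr) >= 0.5)
      degenerate[i] <- TRUE
      next
    }
    m <- suppressWarnings(
      select_predictive_model(x[-i, , drop = FALSE], ytr,
                              max_features = max_features,
                              nfolds = nfolds, seed = seed + i)
    )
    pred[i] <- assign_srs(x[i, , drop = FALSE], m)$probability
  }
  wrong <- (pred >= 0.5) != (y01 == 1L)
  structure(list(
    misclassification_rate = mean(wrong),
    predictions = data.frame(index = seq_len(n), probability = pred,
                             predicted = as.integer(pred >= 0.5),
                             observed = y01),
    n_folds = n,
    degenerate_folds = sum(degenerate)
  ), class = "cv_result")
}

#' Compare predictor families
#'
#' Runs sparse selection + LOOCV per feature family (e.g.
#' expression-only, clinical-only, severity-scores-only) and tabulates
#' misclassification rates, mirroring the comparison of gene-expression
#' and clinical-covariate models for group membership.
#'
#' @param families named list of samples x features matrices.
#' @param y binary response.
#' @param ... passed to [loocv_misclassification()].
#' @return data.frame with family, n_features, misclassification_rate.
#' @export
compare_predictor_families <- function(families, y, ...) {
  rows <- lapply(names(families), function(nm) {
    xf <- families[[nm]]
    if (is.null(xf) || ncol(as.matrix(xf)) == 0) {
      warning("family '", nm, "' is empty; skipped")
      return(NULL)
    }
    cv <- loocv_misclassification(as.matrix(xf), y, ...)
    data.frame(family = nm, n_features = ncol(as.matrix(xf)),
               misclassification_rate = cv$misclassification_rate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}
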