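#' Construct a risk model
#'
#' A risk model is the frozen object applied to new specimens: a gene
#' panel, one coefficient per gene (score units per delta-Cp cycle), an
#' intercept, and the score cutoff at or above which a specimen is
#' classified as ovarian cancer.
#'
#' @param genes Character vector of panel gene ids.
#' @param beta Numeric coefficients, one per gene.
#' @param epsilon Intercept.
#' @param cutoff Classification cutoff on the score scale.
#' @param provenance List describing how the model was obtained.
#' @return An object of class `risk_model`.
#' @export
risk_model <- function(genes, beta, epsilon, cutoff, provenance = list()) {
  stopifnot(length(genes) == length(beta))
  structure(
    list(
      genes = as.character(genes),
      beta = stats::setNames(as.numeric(beta), genes),
      epsilon = as.numeric(epsilon),
      cutoff = as.numeric(cutoff),
      provenance = provenance
    ),
    class = "risk_model"
  )
}

#' @export
print.risk_model <- function(x, ...) {
  cat("Ovarian-cancer risk model\n")
  cat("  score = ", format(x$epsilon), " + ",
      paste(sprintf("(%s) x dCp[%s]", format(x$beta), x$genes), collapse = " + "),
      "\n", sep = "")
  cat("  cutoff:", format(x$cutoff), "(score >= cutoff classifies as OC)\n")
  src <- if (is.character(x$provenance)) x$provenance else x$provenance$source
  if (!is.null(src)) cat("  provenance:", src, "\n")
  invisible(x)
}

#' The published three-gene risk model
#'
#' The frozen ovarian-cancer risk equation for cervical-scraping qMSP:
#' score = (-0.47) x dCp(AMPD3) + (-0.41) x dCp(NRN1) +
#' (-0.57) x dCp(TBX15) + 6.38, with classification cutoff 0.73.
#' Negative coefficients mean that lower delta-Cp (more methylation)
#' raises the risk score.
#'
#' @return A `risk_model` with provenance `"published"`.
#' @examples
#' m <- published_model()
#' risk_score(m, c(AMPD3 = 2.0, NRN1 = 0.4, TBX15 = 4.9)) # 2.483
#' @export
published_model <- function() {
  risk_model(
    genes = c("AMPD3", "NRN1", "TBX15"),
    beta = c(-0.47, -0.41, -0.57),
    epsilon = 6.38,
    cutoff = 0.73,
    provenance = list(source = "published")
  )
}

#' Score specimens with a risk model
#'
#' @param model A `risk_model`.
#' @param delta_cp Named numeric vector (one specimen) or a samples x
#'   genes matrix/data frame with named columns; every model gene must
#'   be present and non-missing.
#' @return Numeric score(s): `epsilon + sum(beta_i * delta_cp_i)`.
#' @export
risk_score <- function(model, delta_cp) {
  stopifnot(inherits(model, "risk_model"))
  if (is.null(dim(delta_cp))) {
    delta_cp <- matrix(delta_cp, nrow = 1L,
                       dimnames = list(NULL, names(delta_cp)))
  }
  delta_cp <- as.matrix(delta_cp)
  missing_genes <- setdiff(model$genes, colnames(delta_cp))
  if (length(missing_genes) > 0L) {
    stop("missing delta-Cp for model gene(s): ",
         paste(missing_genes, collapse = ", "))
  }
  x <- delta_cp[, model$genes, drop = FALSE]
  if (anyNA(x)) stop("delta-Cp values for model genes must be non-missing")
  drop(model$epsilon + x %*% model$beta)
}

#' Classify specimens by risk score
#'
#' Scores at or above the model cutoff are classified `"OC"`, others
#' `"normal"` (the boundary counts as positive).
#'
#' @param model A `risk_model`.
#' @param score Numeric scores; when missing, computed from `delta_cp`.
#' @param delta_cp Passed to [risk_score()] when `score` is missing.
#' @return Character vector of `"OC"` / `"normal"`.
#' @export
classify_risk <- function(model, score = NULL, delta_cp = NULL) {
  stopifnot(inherits(model, "risk_model"))
  if (is.null(score)) score <- risk_score(model, delta_cp)
  ifelse(score >= model$cutoff, "OC", "normal")
}

#' Fit a risk model by repeated cross-validated logistic regression
#'
#' Runs `replications` rounds of stratified `folds`-fold splitting; each
#' training fold (the complement of one held-out fold) contributes one
#' logistic fit of case status on the per-gene delta-Cp, so
#' `folds * replications` coefficient vectors are collected. The final
#' coefficients are their mean (default) or median; both aggregates are
#' stored. The classification cutoff is then chosen by
#' closest-to-top-left on the aggregated model's in-sample scores.
#' Logistic fits fall back to a tiny ridge penalty under separation; the
#' number of ridged fits is recorded in the provenance.
#'
#' @param delta_cp Samples x genes matrix (named columns, no missing
#'   values).
#' @param labels Case/control labels per row.
#' @param folds Number of CV folds (default 10); each class must have at
#'   least `folds` samples.
#' @param replications Number of repeated splits (default 200).
#' @param seed Integer seed for the fold shuffling.
#' @param aggregation `"mean"` (default) or `"median"`.
#' @param positive Case level when `labels` is not logical.
#' @return A `risk_model` whose provenance records folds, replications,
#'   seed, aggregation, both aggregates and the coefficient spread.
#' @export
fit_cv_model <- function(delta_cp, labels, folds = 10L, replications = 200L,
                         seed = NULL, aggregation = c("mean", "median"),
                         positive = NULL) {
  aggregation <- match.arg(aggregation)
  delta_cp <- as.matrix(delta_cp)
  if (is.null(colnames(delta_cp))) stop("delta_cp needs gene column names")
  if (anyNA(delta_cp)) stop("delta_cp must be complete-case")
  pos <- .as_case_logical(labels, positive)
  if (sum(pos) < folds || sum(!pos) < folds) {
    stop("each class needs at least `folds` samples for stratified folds")
  }
  if (!is.null(seed)) set.seed(seed)
  y <- as.numeric(pos)
  p <- ncol(delta_cp)
  coefs <- matrix(NA_real_, nrow = folds * replications, ncol = p + 1L)
  ridged <- 0L
  row <- 0L
  for (r in seq_len(replications)) {
    fold_id <- .stratified_folds(pos, folds)
    for (k in seq_len(folds)) {
      train <- fold_id != k
      # stratification guarantees both classes in every training fold
      fit <- .logistic_fit(delta_cp[train, , drop = FALSE], y[train])
      row <- row + 1L
      coefs[row, ] <- fit$coefficients
      if (fit$ridged) ridged <- ridged + 1L
    }
  }
  colnames(coefs) <- c("(Intercept)", colnames(delta_cp))
  agg_mean <- colMeans(coefs)
  agg_median <- apply(coefs, 2L, stats::median)
  agg <- if (aggregation == "mean") agg_mean else agg_median
  model <- risk_model(
    genes = colnames(delta_cp),
    beta = agg[-1L],
    epsilon = agg[1L],
    cutoff = NA_real_,
    provenance = list(
      source = "cross_validation",
      folds = folds, replications = replications, seed = seed,
      aggregation = aggregation,
      coef_mean = agg_mean, coef_median = agg_median,
      coef_sd = apply(coefs, 2L, stats::sd),
      n_fits = nrow(coefs), n_ridged_fits = ridged
    )
  )
  scores <- risk_score(model, delta_cp)
  ct <- closest_topleft_cutoff(scores, pos, direction = "higher_is_positive")
  model$cutoff <- ct$cutoff
  model$provenance$train_sensitivity <- ct$sensitivity
  model$provenance$train_specificity <- ct$specificity
  model
}

# Stratified fold assignment: shuffles each class and deals folds round
# robin, so every fold contains both classes whenever n >= folds per class.
.stratified_folds <- function(pos, folds) {
  fold_id <- integer(length(pos))
  for (cls in c(TRUE, FALSE)) {
    idx <- sample(which(pos == cls))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_id
}

#' Evaluate a risk model on a labeled cohort
#'
#' Applies the frozen model (score, classify at its cutoff) and reports
#' sensitivity, specificity, and the score AUC with stratified-bootstrap
#' confidence intervals. A cohort with only one class yields the defined
#' metric and `NA` (flagged) for the other.
#'
#' @param model A `risk_model` with a finite cutoff.
#' @param delta_cp Samples x genes matrix.
#' @param labels Case/control labels.
#' @param B Bootstrap iterations for the CIs (default 200); `0` skips
#'   CIs.
#' @param seed Seed for the bootstrap.
#' @param positive Case level when `labels` is not logical.
#' @return List with `sensitivity`, `specificity`, `auc`, their CIs,
#'   `n_case`, `n_control`, and the per-sample `scores` and `calls`.
#' @export
evaluate_risk_model <- function(model, delta_cp, labels, B = 200L,
                                seed = NULL, positive = NULL) {
  stopifnot(inherits(model, "risk_model"), is.finite(model$cutoff))
  delta_cp <- as.matrix(delta_cp)
  if (nrow(delta_cp) == 0L) stop("empty input")
  pos <- .as_case_logical(labels, positive)
  scores <- risk_score(model, delta_cp)
  calls <- classify_risk(model, score = scores)
  sens <- if (any(pos)) mean(calls[pos] == "OC") else NA_real_
  spec <- if (any(!pos)) mean(calls[!pos] == "normal") else NA_real_
  out <- list(
    sensitivity = sens, specificity = spec,
    auc = if (any(pos) && any(!pos)) {
      roc_auc(scores, pos, direction = "higher_is_positive")
    } else NA_real_,
    n_case = sum(pos), n_control = sum(!pos),
    scores = scores, calls = calls,
    one_class_only = !(any(pos) && any(!pos))
  )
  if (B > 0L && !out$one_class_only) {
    out$auc_ci <- bootstrap_ci(
      scores, pos,
      function(v, l) roc_auc(v, l, direction = "higher_is_positive"),
      B = B, seed = seed
    )
    out$sensitivity_ci <- bootstrap_ci(
      scores, pos,
      function(v, l) mean(v[l] >= model$cutoff),
      B = B, seed = if (is.null(seed)) NULL else seed + 1L
    )
    out$specificity_ci <- bootstrap_ci(
      scores, pos,
      function(v, l) mean(v[!l] < model$cutoff),
      B = B, seed = if (is.null(seed)) NULL else seed + 2L
    )
  }
  out
}

#' Per-group sample size for detecting an AUC above a null value
#'
#' Smallest per-group n such that a two-sided level-`alpha` test of
#' AUC = `theta_null` attains the requested power at AUC = `theta_alt`,
#' using the Hanley-McNeil variance
#' V(theta, n) = \[theta(1-theta) + (n-1)(Q1-theta^2) +
#' (n*ratio-1)(Q2-theta^2)\] / (n^2 * ratio), with
#' Q1 = theta/(2-theta) and Q2 = 2 theta^2/(1+theta).
#'
#' @param theta_alt Alternative AUC (e.g. 0.75).
#' @param theta_null Null AUC (default 0.5).
#' @param alpha Two-sided type I error (default 0.05).
#' @param power Target power (default 0.8).
#' @param ratio Control-to-case ratio (default 1).
#' @param n_max Search cap (default 1e6).
#' @return Integer n per (case) group.
#' @examples
#' auc_sample_size(0.75) # 20
#' @export
auc_sample_size <- function(theta_alt, theta_null = 0.5, alpha = 0.05,
                            power = 0.8, ratio = 1, n_max = 1e6L) {
  stopifnot(theta_null >= 0.5, theta_null < theta_alt, theta_alt < 1,
            alpha > 0, alpha < 1, power > 0, power < 1, ratio > 0)
  v <- function(theta, n) {
    q1 <- theta / (2 - theta)
    q2 <- 2 * theta^2 / (1 + theta)
    (theta * (1 - theta) + (n - 1) * (q1 - theta^2) +
       (n * ratio - 1) * (q2 - theta^2)) / (n^2 * ratio)
  }
  z_a <- stats::qnorm(1 - alpha / 2)
  z_b <- stats::qnorm(power)
  delta <- theta_alt - theta_null
  for (n in seq_len(n_max)) {
    if (z_a * sqrt(v(theta_null, n)) + z_b * sqrt(v(theta_alt, n)) <= delta) {
      return(n)
    }
  }
  stop("no solution below n_max")
}

#' Derive enrolled training/testing set sizes from a base per-group n
#'
#' The enrollment plan takes `n + pad` per group in the testing set and
#' `round_half_up(ratio * n) + pad` per group in the training set (the
#' pad guards against failed detections; half counts round up, so a base
#' n of 19 with ratio 1.5 gives 31 + 31 training and 21 + 21 testing
#' specimens, 62 and 42 in total).
#'
#' @param n_test_per_group Base per-group n (e.g. from
#'   [auc_sample_size()]).
#' @param train_to_test_ratio Training-to-testing ratio (default 1.5).
#' @param pad_per_group Extra specimens per group (default 2).
#' @return List with per-group and total sizes of both sets.
#' @export
plan_study <- function(n_test_per_group, train_to_test_ratio = 1.5,
                       pad_per_group = 2L) {
  stopifnot(n_test_per_group >= 1, train_to_test_ratio > 0, pad_per_group >= 0)
  round_half_up <- function(x) floor(x + 0.5)
  test_pg <- n_test_per_group + pad_per_group
  train_pg <- round_half_up(train_to_test_ratio * n_test_per_group) + pad_per_group
  list(
    n_base_per_group = n_test_per_group,
    test_per_group = test_pg, test_total = 2L * test_pg,
    train_per_group = train_pg, train_total = 2L * train_pg
  )
}
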