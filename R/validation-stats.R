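#' Two-tailed Mann-Whitney U test
#'
#' Rank-sum comparison of two independent groups, the workhorse test for
#' differential methylation calls and for the per-gene validation tables.
#' The exact null distribution is used when both groups have at most
#' `exact_limit` observations and there are no ties; otherwise the normal
#' approximation with continuity and tie correction is used.
#'
#' @param x,y Numeric vectors, the two groups (both nonempty).
#' @param exact_limit Largest per-group size for which the exact
#'   distribution is attempted (default 8).
#' @return A list with elements `U` (the Mann-Whitney statistic for `x`,
#'   i.e. the number of (x, y) pairs with x > y, ties counted 1/2),
#'   `p_value` (two-sided), and `exact` (logical, which path was taken).
#' @examples
#' mann_whitney_two_tailed(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1
#' @export
mann_whitney_two_tailed <- function(x, y, exact_limit = 8L) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) {
    stop("both groups must be nonempty")
  }
  has_ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- !has_ties && length(x) <= exact_limit && length(y) <= exact_limit
  wt <- suppressWarnings(
    stats::wilcox.test(x, y,
      alternative = "two.sided",
      exact = use_exact, correct = TRUE
    )
  )
  list(
    U = unname(wt$statistic),
    p_value = min(1, unname(wt$p.value)),
    exact = use_exact
  )
}

#' Area under the ROC curve by pair counting
#'
#' AUC as the probability that a randomly chosen case outranks a randomly
#' chosen control, with ties counted one half. The direction argument
#' states which side of the measurement scale is disease-positive; qMSP
#' delta-Cp uses `"lower_is_positive"` because hypermethylated cases have
#' lower delta-Cp, whereas risk scores use `"higher_is_positive"`.
#'
#' @param values Numeric measurements.
#' @param labels Logical or two-level vector; `TRUE` (or the level given
#'   by `positive`) marks cases.
#' @param direction `"lower_is_positive"` or `"higher_is_positive"`.
#' @param positive When `labels` is not logical, the level that counts as
#'   a case.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(values, labels,
                    direction = c("higher_is_positive", "lower_is_positive"),
                    positive = NULL) {
  direction <- match.arg(direction)
  pos <- .as_case_logical(labels, positive)
  if (!any(pos) || all(pos)) stop("both classes must be present")
  v <- if (direction == "lower_is_positive") -values else values
  keep <- !is.na(v)
  v <- v[keep]
  pos <- pos[keep]
  n1 <- sum(pos)
  n0 <- sum(!pos)
  r <- rank(v)
  u <- sum(r[pos]) - n1 * (n1 + 1) / 2
  u / (n1 * n0)
}

#' Cutoff by the closest-to-top-left criterion
#'
#' Scans all candidate thresholds (midpoints between adjacent sorted
#' unique values, plus the two infinities) and returns the one minimizing
#' (1 - sensitivity)^2 + (1 - specificity)^2. Ties are broken in favor of
#' smaller (1 - sensitivity), then the lower cutoff. Classification at
#' the cutoff is inclusive on the disease side: for
#' `"lower_is_positive"`, values <= cutoff are called positive; for
#' `"higher_is_positive"`, values >= cutoff.
#'
#' @inheritParams roc_auc
#' @return A list with `cutoff`, `sensitivity`, `specificity`.
#' @export
closest_topleft_cutoff <- function(values, labels,
                                   direction = c("higher_is_positive", "lower_is_positive"),
                                   positive = NULL) {
  direction <- match.arg(direction)
  pos <- .as_case_logical(labels, positive)
  if (!any(pos) || all(pos)) stop("both classes must be present")
  keep <- !is.na(values)
  values <- values[keep]
  pos <- pos[keep]
  u <- sort(unique(values))
  mids <- if (length(u) > 1L) (u[-1] + u[-length(u)]) / 2 else numeric(0)
  cand <- c(-Inf, mids, Inf)
  best <- NULL
  for (cut in cand) {
    called <- if (direction == "lower_is_positive") values <= cut else values >= cut
    se <- sum(called & pos) / sum(pos)
    sp <- sum(!called & !pos) / sum(!pos)
    d2 <- (1 - se)^2 + (1 - sp)^2
    if (is.null(best) ||
        d2 < best$d2 - 1e-12 ||
        (abs(d2 - best$d2) <= 1e-12 && (1 - se) < (1 - best$sensitivity) - 1e-12) ||
        (abs(d2 - best$d2) <= 1e-12 && abs(se - best$sensitivity) <= 1e-12 &&
         cut < best$cutoff)) {
      best <- list(cutoff = cut, sensitivity = se, specificity = sp, d2 = d2)
    }
  }
  best$d2 <- NULL
  best
}

#' Stratified bootstrap percentile confidence interval
#'
#' Resamples with replacement within each class (so both classes are
#' always present) and returns the percentile interval of a metric.
#'
#' @param values Numeric measurements.
#' @param labels Case/control labels (see [roc_auc()]).
#' @param metric_fn Function of `(values, labels)` returning one number.
#' @param B Number of bootstrap iterations (default 200).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed for reproducible intervals.
#' @param positive Case level when `labels` is not logical.
#' @return Numeric vector `c(lo, hi)`.
#' @export
bootstrap_ci <- function(values, labels, metric_fn, B = 200L, level = 0.95,
                         seed = NULL, positive = NULL) {
  stopifnot(B >= 2L)
  if (!is.null(seed)) set.seed(seed)
  pos <- .as_case_logical(labels, positive)
  idx_pos <- which(pos)
  idx_neg <- which(!pos)
  stats_boot <- numeric(B)
  for (b in seq_len(B)) {
    ii <- c(
      sample(idx_pos, length(idx_pos), replace = TRUE),
      sample(idx_neg, length(idx_neg), replace = TRUE)
    )
    stats_boot[b] <- metric_fn(values[ii], labels[ii])
  }
  unname(stats::quantile(stats_boot,
    probs = c((1 - level) / 2, 1 - (1 - level) / 2),
    na.rm = TRUE
  ))
}

#' Logistic combination of a gene panel
#'
#' Fits a maximum-likelihood logistic regression of case status on the
#' per-gene delta-Cp values and returns the fitted probabilities as a
#' composite score (to be fed to the ROC machinery with
#' `"higher_is_positive"`). Under complete separation the fit falls back
#' to a tiny ridge penalty and the result is flagged.
#'
#' @param delta_cp Numeric matrix, samples x genes (complete cases only).
#' @param labels Case/control labels.
#' @param positive Case level when `labels` is not logical.
#' @return A list with `coefficients` (intercept first), `scores`
#'   (fitted probabilities), `linear` (linear predictor), and `ridged`
#'   (logical separation flag).
#' @export
combine_genes_logistic <- function(delta_cp, labels, positive = NULL) {
  delta_cp <- as.matrix(delta_cp)
  if (anyNA(delta_cp)) stop("delta_cp must be complete-case (no missing values)")
  pos <- .as_case_logical(labels, positive)
  fit <- .logistic_fit(delta_cp, as.numeric(pos))
  eta <- drop(cbind(1, delta_cp) %*% fit$coefficients)
  list(
    coefficients = fit$coefficients,
    scores = stats::plogis(eta),
    linear = eta,
    ridged = fit$ridged
  )
}

#' Kruskal-Wallis comparison across groups with Dunn post hoc
#'
#' Rank-based comparison of a score across >= 2 categories (e.g. risk
#' score by histology or FIGO stage). When the omnibus p-value falls
#' below `posthoc_alpha`, pairwise Dunn z-tests with Holm adjustment are
#' reported and pairs below `posthoc_alpha` are flagged.
#'
#' @param scores Numeric vector.
#' @param groups Factor-like vector of the same length, >= 2 levels each
#'   nonempty.
#' @param posthoc_alpha Significance gate for running/flagging the post
#'   hoc tests (default 0.05).
#' @return A list with `H`, `p_value`, `df`, and `posthoc` (data frame of
#'   pairs with z, raw and Holm-adjusted p, `flag`; empty when the
#'   omnibus test is not significant).
#' @export
group_comparison <- function(scores, groups, posthoc_alpha = 0.05) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (any(table(groups) == 0L)) stop("every group must be nonempty")
  kw <- stats::kruskal.test(scores, groups)
  res <- list(
    H = unname(kw$statistic),
    df = unname(kw$parameter),
    p_value = unname(kw$p.value)
  )
  posthoc <- data.frame(
    group1 = character(0), group2 = character(0),
    z = numeric(0), p_value = numeric(0), p_adjusted = numeric(0),
    flag = logical(0), stringsAsFactors = FALSE
  )
  if (res$p_value < posthoc_alpha) {
    posthoc <- .dunn_posthoc(scores, groups)
    posthoc$flag <- posthoc$p_adjusted < posthoc_alpha
  }
  res$posthoc <- posthoc
  res
}

# Dunn's pairwise z-tests on the joint ranking, Holm-adjusted.
.dunn_posthoc <- function(scores, groups) {
  r <- rank(scores)
  n <- length(scores)
  ties <- table(scores)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  lev <- levels(groups)
  mean_rank <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  pairs <- utils::combn(lev, 2L)
  z <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1L, j]
    b <- pairs[2L, j]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / n_g[[a]] + 1 / n_g[[b]]))
    z[j] <- (mean_rank[[a]] - mean_rank[[b]]) / se
    p[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  data.frame(
    group1 = pairs[1L, ], group2 = pairs[2L, ],
    z = z, p_value = p, p_adjusted = stats::p.adjust(p, "holm"),
    stringsAsFactors = FALSE
  )
}

#' @keywords internal
#' @noRd
.as_case_logical <- function(labels, positive = NULL) {
  if (is.logical(labels)) return(labels)
  if (is.null(positive)) {
    lv <- if (is.factor(labels)) levels(labels) else sort(unique(as.character(labels)))
    if (length(lv) > 2L) {
      stop("labels must be logical or at most two-level; otherwise supply `positive`")
    }
    # conventional case labels recognized without an explicit `positive`
    known <- c("OC", "case", "cancer", "tumor", "1", "TRUE")
    hit <- lv[lv %in% known]
    positive <- if (length(hit) == 1L) {
      hit
    } else if (length(lv) == 2L) {
      lv[2L]
    } else {
      # single level not recognized as a case label: treat as all-control
      paste0(lv[1L], "_case")
    }
  }
  as.character(labels) == as.character(positive)
}

# Logistic ML fit with ridge-IRLS fallback under separation.
# X: n x p matrix without intercept column; y in {0,1}.
.logistic_fit <- function(X, y, ridge = 1e-6) {
  X1 <- cbind(`(Intercept)` = 1, X)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(X1, y, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("did not converge", conditionMessage(w))) {
        separated <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  if (!separated && fit$converged) {
    return(list(coefficients = stats::coef(fit), ridged = FALSE))
  }
  list(coefficients = .irls_ridge(X1, y, lambda = ridge), ridged = TRUE)
}

# Penalized IRLS; the intercept is unpenalized. Survives separation by
# keeping the normal equations nonsingular.
.irls_ridge <- function(X1, y, lambda = 1e-6, max_iter = 100L, tol = 1e-10) {
  p <- ncol(X1)
  pen <- diag(c(0, rep(lambda, p - 1L)), p, p)
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X1 %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    new_beta <- tryCatch(
      solve(crossprod(X1, w * X1) + pen, crossprod(X1, w * z)),
      error = function(e) NULL
    )
    if (is.null(new_beta)) break
    new_beta <- drop(new_beta)
    if (max(abs(new_beta - beta)) < tol) {
      beta <- new_beta
      break
    }
    beta <- new_beta
  }
  names(beta) <- colnames(X1)
  beta
}
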