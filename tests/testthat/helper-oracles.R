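# Independent brute-force oracles used to check the analytic machinery.

# AUC by explicit pair counting over all (case, control) pairs.
oracle_auc <- function(case, control) {
  cmp <- outer(case, control, ">") + 0.5 * outer(case, control, "==")
  mean(cmp)
}

# Exhaustive closest-to-top-left scan over midpoint thresholds,
# replicating the documented tie-breaks (smaller 1 - sensitivity, then
# lower cutoff) with an independent loop.
oracle_topleft <- function(values, pos, lower_is_positive = FALSE) {
  u <- sort(unique(values))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  best <- NULL
  for (cut in cand) {
    called <- if (lower_is_positive) values <= cut else values >= cut
    se <- sum(called & pos) / sum(pos)
    sp <- sum(!called & !pos) / sum(!pos)
    d2 <- (1 - se)^2 + (1 - sp)^2
    better <- is.null(best) || d2 < best$d2 - 1e-12 ||
      (abs(d2 - best$d2) <= 1e-12 && (1 - se) < (1 - best$se) - 1e-12) ||
      (abs(d2 - best$d2) <= 1e-12 && abs(se - best$se) <= 1e-12 && cut < best$cut)
    if (better) best <- list(cut = cut, se = se, sp = sp, d2 = d2)
  }
  best
}

# Exact two-sided Mann-Whitney p by full enumeration of all group
# assignments (no ties assumed). Two-sided mass of |U - n1*n2/2| at
# least as extreme as observed; equals the doubled one-sided tail under
# the symmetric null.
oracle_mw_p <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(abs(u_all - n1 * n2 / 2) >= abs(u_obs - n1 * n2 / 2) - 1e-9)
}

# Small labeled dataset builders shared across tests.
two_group_values <- function(case, control) {
  list(
    values = c(case, control),
    labels = c(rep(TRUE, length(case)), rep(FALSE, length(control)))
  )
}
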