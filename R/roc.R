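# Empirical ROC analysis with DeLong confidence intervals and the
# Youden-optimal "associated criterion".
#
# Implemented in-package because the reported criterion semantics are fixed:
# low score = positive, thresholds are attained scores reported as "<= c",
# AUC uses the Mann-Whitney 1/2 tie convention, and ties in Youden's J are
# broken toward higher specificity.

#' Empirical ROC analysis
#'
#' Builds the empirical ROC of a continuous score against a binary reference
#' where a LOWER score argues for the positive class (low vBMD = diseased),
#' computes AUC by the Mann-Whitney statistic (equivalently the trapezoidal
#' rule, with ties counted 1/2), a 95% CI (DeLong by default, seeded
#' stratified bootstrap as an alternative), and the Youden-optimal
#' "associated criterion", reported as "<= c" with c an attained score.
#' Ties in J are broken toward higher specificity, then toward the smaller
#' criterion.
#'
#' @param scores numeric scores (e.g. vBMD in mg/cc).
#' @param labels binary reference: logical, 0/1, or a factor whose second
#'   level is positive.
#' @param direction `"lower"` (default: low score = positive) or
#'   `"higher"`.
#' @param ci_method `"delong"` (default) or `"bootstrap"`.
#' @param conf_level CI level (default 0.95).
#' @param n_boot bootstrap replicates (when `ci_method = "bootstrap"`).
#' @param seed seed for the bootstrap.
#' @return an object of class `plqct_roc`: `auc`, `ci95_low`, `ci95_high`,
#'   `sensitivity_pct`, `specificity_pct`, `youden_j`,
#'   `associated_criterion`, `criterion_direction`, `n`, `n_pos`, `n_neg`,
#'   and `curve` (a tibble of threshold, sensitivity, specificity).
#' @export
roc_analysis <- function(scores, labels, direction = c("lower", "higher"),
                         ci_method = c("delong", "bootstrap"),
                         conf_level = 0.95, n_boot = 2000, seed = 1L) {
  direction <- match.arg(direction)
  ci_method <- match.arg(ci_method)
  pos <- as_binary_labels(labels)
  ok <- is.finite(scores) & !is.na(pos)
  scores <- scores[ok]; pos <- pos[ok]
  if (length(scores) < 2 || !any(pos) || all(pos)) {
    abort("degenerate reference: both classes must be present")
  }
  flip <- direction == "higher"
  s <- if (flip) -scores else scores

  sp <- s[pos]; sn <- s[!pos]
  m <- length(sp); n <- length(sn)

  # AUC = P(score_pos < score_neg) + 0.5 P(equal), via midranks
  r <- rank(c(sp, sn), ties.method = "average")
  auc <- 1 - (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)

  # exhaustive threshold search over attained scores (plus the empty rule)
  cs <- sort(unique(s))
  sens <- vapply(cs, function(c) mean(sp <= c), numeric(1))
  spec <- vapply(cs, function(c) mean(sn > c), numeric(1))
  curve <- tibble(
    threshold = c(-Inf, cs),
    sensitivity = c(0, sens),
    specificity = c(1, spec)
  )
  j <- sens + spec - 1
  jmax <- max(j)
  cand <- which(j >= jmax - 1e-12)
  cand <- cand[order(-spec[cand], cs[cand])][1]
  criterion <- cs[cand]

  if (ci_method == "delong") {
    if (m >= 2 && n >= 2) {
      v10 <- vapply(sp, function(x) mean((x < sn) + 0.5 * (x == sn)), numeric(1))
      v01 <- vapply(sn, function(y) mean((sp < y) + 0.5 * (sp == y)), numeric(1))
      se <- sqrt(var(v10) / m + var(v01) / n)
    } else {
      warn("fewer than 2 observations in a class: DeLong CI unavailable")
      se <- NA_real_
    }
    z <- qnorm(1 - (1 - conf_level) / 2)
    ci <- c(max(0, auc - z * se), min(1, auc + z * se))
  } else {
    ci <- withr::with_seed(seed, {
      ip <- which(pos); ineg <- which(!pos)
      reps <- vapply(seq_len(n_boot), function(i) {
        bp <- s[sample(ip, m, replace = TRUE)]
        bn <- s[sample(ineg, n, replace = TRUE)]
        rb <- rank(c(bp, bn), ties.method = "average")
        1 - (sum(rb[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
      }, numeric(1))
      unname(quantile(reps, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)))
    })
  }

  structure(
    list(
      auc = auc,
      ci95_low = ci[1], ci95_high = ci[2], ci_method = ci_method,
      sensitivity_pct = 100 * sens[cand],
      specificity_pct = 100 * spec[cand],
      youden_j = j[cand],
      associated_criterion = if (flip) -criterion else criterion,
      criterion_direction = if (flip) ">=" else "<=",
      n = m + n, n_pos = m, n_neg = n,
      curve = curve
    ),
    class = "plqct_roc"
  )
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1, NA))) abort("numeric labels must be 0/1")
    return(labels == 1)
  }
  if (is.factor(labels) || is.character(labels)) {
    f <- as.factor(labels)
    if (nlevels(f) != 2) abort("labels must have exactly two levels")
    return(f == levels(f)[2])
  }
  abort("labels must be logical, 0/1, or two-level factor")
}

#' @export
print.plqct_roc <- function(x, ...) {
  cat(sprintf(
    "<plqct_roc> AUC %.3f (95%% CI %.3f-%.3f, %s), n = %d (%d+/%d-)\n",
    x$auc, x$ci95_low, x$ci95_high, x$ci_method, x$n, x$n_pos, x$n_neg))
  cat(sprintf(
    "  criterion %s %.1f: sensitivity %.1f%%, specificity %.1f%%, J = %.2f\n",
    x$criterion_direction, x$associated_criterion,
    x$sensitivity_pct, x$specificity_pct, x$youden_j))
  invisible(x)
}
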