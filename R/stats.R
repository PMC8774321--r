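# Cohort-level statistics: Mann-Whitney U, empirical ROC with Youden
# cut-off and DeLong variance, paired DeLong comparison of correlated
# AUCs, Spearman rank correlation, and the threshold-multiple sweep.

#' Mann-Whitney U test
#'
#' `U` counts pairs `(a, b)` with `a > b` (plus 1/2 per tie), so
#' `U / (n_x * n_y)` is the AUC of `x` against `y`. The two-sided p-value
#' uses the exact null distribution when `n_x * n_y <= 400` and the data
#' are tie-free, and otherwise the normal approximation with tie-corrected
#' variance and continuity correction.
#'
#' @param x,y numeric score vectors for the two groups, each non-empty.
#' @return A list with `U`, `p_value`, `n_x`, `n_y`, and `method`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- table(c(x, y))
  has_ties <- any(ties > 1)

  if (!has_ties && nx * ny <= 400) {
    # exact two-sided p from the null distribution of U
    p_lo <- pwilcox(U, nx, ny)
    p_hi <- pwilcox(U - 1, nx, ny, lower.tail = FALSE)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- nx * ny / 2
    tie_term <- sum(ties^3 - ties) / ((nx + ny) * (nx + ny - 1))
    sigma <- sqrt(nx * ny / 12 * (nx + ny + 1 - tie_term))
    if (sigma == 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sigma  # continuity correction
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal approximation (tie-corrected, continuity-corrected)"
  }
  list(U = U, p_value = p, n_x = nx, n_y = ny, method = method)
}

# placement values of the positive/negative scores: V10[i] = fraction of
# negatives beaten by positive i (ties half), V01[j] symmetric
placements <- function(scores, positive) {
  sp <- scores[positive]; sn <- scores[!positive]
  psi <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' Empirical ROC analysis with Youden-index cut-off
#'
#' Higher score predicts the positive class; the polarity is never
#' auto-flipped, and an AUC below 0.5 is reported as-is with a warning
#' (it indicates a score whose direction contradicts the convention).
#' The AUC is the trapezoidal area of the empirical curve, which equals
#' the Mann-Whitney `U / (n1 * n0)`. The optimal cut-off is the observed
#' score value maximizing Youden's J (sensitivity + specificity - 1),
#' ties broken toward higher specificity, and classifies `score >= cutoff`
#' as positive. The standard error and 95% CI come from the DeLong
#' placement-value variance.
#'
#' @param scores numeric scores.
#' @param labels logical vector (TRUE = positive class) or a factor /
#'   character vector with levels `"positive"`/`"negative"`.
#' @return An object of class `roc_result`: `auc`, `se_auc`, `ci95`,
#'   `points` (threshold/sensitivity/specificity table), `optimal_cutoff`,
#'   `sensitivity`, `specificity`, `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(scores, labels) {
  pos <- as_positive_logical(labels)
  scores <- as.numeric(scores)
  if (length(scores) != length(pos)) stop("scores and labels differ in length")
  if (anyNA(scores)) stop("missing scores not allowed")
  if (!any(pos) || all(pos)) stop("both classes must be present")
  n1 <- sum(pos); n0 <- sum(!pos)

  thr <- sort(unique(scores))
  sens <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!pos] < t), numeric(1))
  points <- data.frame(
    threshold = c(-Inf, thr, Inf),
    sensitivity = c(1, sens, 0),
    specificity = c(0, spec, 1)
  )

  fpr <- 1 - points$specificity
  tpr <- points$sensitivity
  ord <- order(fpr, tpr)
  auc <- sum(diff(fpr[ord]) * (tpr[ord][-1] + tpr[ord][-length(tpr)]) / 2)
  auc <- abs(auc)
  if (auc < 0.5)
    warning("AUC below 0.5: score polarity contradicts the higher-",
            "score-positive convention; reported as-is")

  j <- sens + spec - 1
  best <- which(j == max(j))
  if (length(best) > 1) best <- best[which.max(spec[best])]
  pl <- placements(scores, pos)
  se <- sqrt(var(pl$v10) / n1 + var(pl$v01) / n0)
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * 1.959964 * se))

  structure(
    list(auc = auc, se_auc = se, ci95 = ci, points = points,
         optimal_cutoff = thr[best], sensitivity = sens[best],
         specificity = spec[best], n_pos = n1, n_neg = n0),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (95%% CI %.3f-%.3f), n = %d pos / %d neg\n",
              x$auc, x$ci95[1], x$ci95[2], x$n_pos, x$n_neg))
  cat(sprintf("  optimal cut-off >= %.4g: sensitivity %.3f, specificity %.3f\n",
              x$optimal_cutoff, x$sensitivity, x$specificity))
  invisible(x)
}

as_positive_logical <- function(labels) {
  if (is.logical(labels)) return(labels)
  l <- as.character(labels)
  if (!all(l %in% c("positive", "negative")))
    stop("labels must be logical or \"positive\"/\"negative\"")
  l == "positive"
}

#' DeLong comparison of two paired ROC curves
#'
#' Both score vectors are measured on the same cases, so the AUC
#' estimates are correlated; the DeLong placement-value covariance
#' accounts for that and the difference is tested with a z statistic.
#'
#' @param scores_1,scores_2 numeric score vectors over the same cases.
#' @param labels as in [roc_analysis()].
#' @return A list: `auc_1`, `auc_2`, `difference`, `se`, `z`, `p_value`.
#' @export
compare_roc_paired <- function(scores_1, scores_2, labels) {
  pos <- as_positive_logical(labels)
  if (length(scores_1) != length(scores_2) ||
      length(scores_1) != length(pos))
    stop("scores_1, scores_2 and labels must have equal length")
  if (!any(pos) || all(pos)) stop("both classes must be present")
  n1 <- sum(pos); n0 <- sum(!pos)
  p1 <- placements(scores_1, pos)
  p2 <- placements(scores_2, pos)
  d10 <- p1$v10 - p2$v10
  d01 <- p1$v01 - p2$v01
  se <- sqrt(var(d10) / n1 + var(d01) / n0)
  diff <- p1$auc - p2$auc
  if (diff == 0) {
    z <- 0; p <- 1
  } else if (se == 0) {
    z <- sign(diff) * Inf; p <- 0
  } else {
    z <- diff / se
    p <- 2 * pnorm(-abs(z))
  }
  list(auc_1 = p1$auc, auc_2 = p2$auc, difference = diff, se = se,
       z = z, p_value = p)
}

#' Paired bootstrap p-value for an AUC difference
#'
#' Stratified (per-class) paired bootstrap of the difference between two
#' correlated AUCs; used as a validation oracle for
#' [compare_roc_paired()]. The p-value is the two-sided bootstrap
#' tail probability of the difference crossing zero.
#'
#' @inheritParams compare_roc_paired
#' @param n_boot number of bootstrap resamples, default 2000.
#' @return A list: `difference`, `p_value`.
#' @export
bootstrap_roc_comparison <- function(scores_1, scores_2, labels,
                                     n_boot = 2000) {
  pos <- as_positive_logical(labels)
  diffs <- .boot_auc_diff_cpp(as.numeric(scores_1), as.numeric(scores_2),
                              pos, as.integer(n_boot))
  obs <- placements(scores_1, pos)$auc - placements(scores_2, pos)$auc
  p <- 2 * min(mean(diffs <= 0), mean(diffs >= 0))
  list(difference = obs, p_value = min(1, p))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks. The p-value uses the t approximation
#' for n > 8 and the exact permutation distribution for n <= 8. A constant
#' input leaves rho undefined; the result is flagged rather than an error
#' so cohort reports can annotate the column.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return A list: `rho`, `p_value`, `n`, `method`, `undefined` (logical).
#' @export
spearman_corr <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must be paired")
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                method = "undefined (constant input)", undefined = TRUE))
  rx <- rank(x); ry <- rank(y)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  if (n <= 8) {
    perms <- all_permutations(n)
    ryc <- ry - mean(ry)
    rxc <- rx - mean(rx)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    rho_perm <- as.numeric(matrix(ryc[perms], nrow(perms)) %*% rxc) / denom
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p_value = p, n = n, method = method, undefined = FALSE)
}

# all permutations of 1..n as an (n!) x n matrix
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (pos in seq_len(n)) {
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], n,
                   sub[, seq(pos, n - 1)[seq_len(n - pos)], drop = FALSE])
    out[row:(row + nrow(sub) - 1), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Sweep the SUV-mean threshold multiple
#'
#' Re-quantifies every case at each threshold multiple `k` and computes
#' the shape-feature AUC per `k`. A `k` whose threshold empties the VOI in
#' more than half the cases is flagged and excluded from the argmax (not
#' silently dropped). Because the threshold is defined relative to the
#' SUV mean, the sweep is invariant under global rescaling of the PET
#' intensities.
#'
#' @param cases list of per-case lists with elements `pet`
#'   ([voxel_grid()]), `brain_mask` ([binary_mask()]) and `group`
#'   (`"positive"`/`"negative"`), e.g. the `"cases"` attribute of
#'   [simulate_cohort()] run with `keep_cases = TRUE`.
#' @param k_values numeric vector of threshold multiples, non-empty.
#' @param score which score to evaluate, default `"shape_feature"`.
#' @param ... further arguments passed to [quantify_case()].
#' @return A `data.frame` with columns `k`, `auc`, `n_failed`, `excluded`;
#'   attribute `"argmax"` holds the set of included `k` attaining the
#'   maximal AUC.
#' @export
threshold_sweep <- function(cases, k_values, score = "shape_feature", ...) {
  if (length(k_values) == 0) stop("k_values must be non-empty")
  groups <- vapply(cases, function(cs) cs$group, character(1))
  dots <- list(...)
  sm <- dots$surface_method %||% "mesh"
  ss <- dots$smoothing_sigma %||% 1.25
  # the brain surface does not depend on k; mesh it once per case
  brain_geoms <- lapply(cases, function(cs) {
    list(volume = mask_volume(cs$brain_mask),
         area = mask_surface_area(cs$brain_mask, method = sm,
                                  smoothing_sigma = ss))
  })
  rows <- lapply(k_values, function(kk) {
    vals <- vapply(seq_along(cases), function(ci) {
      cs <- cases[[ci]]
      tryCatch(quantify_case(cs$pet, cs$brain_mask, k = kk,
                             .brain_geom = brain_geoms[[ci]], ...)[[score]],
               error = function(e) NA_real_)
    }, numeric(1))
    failed <- sum(is.na(vals))
    ok <- !is.na(vals)
    excluded <- failed > length(vals) / 2 ||
      length(unique(groups[ok])) < 2
    auc <- if (excluded) NA_real_ else roc_analysis(vals[ok], groups[ok])$auc
    if (excluded)
      warning("k = ", kk, " empties the VOI in ", failed, "/", length(vals),
              " cases (or leaves one class only); excluded from the sweep ",
              "argmax")
    data.frame(k = kk, auc = auc, n_failed = failed, excluded = excluded)
  })
  out <- do.call(rbind, rows)
  inc <- out[!out$excluded, , drop = FALSE]
  attr(out, "argmax") <-
    if (nrow(inc)) inc$k[inc$auc == max(inc$auc)] else numeric(0)
  out
}
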