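test_that("Mann-Whitney U counts exceeding pairs; exact p matches base R", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_identical(mw$U, 0)
  expect_identical(mann_whitney(c(4, 5, 6), c(1, 2, 3))$U, 9)
  wt <- wilcox.test(c(1, 2, 3), c(4, 5, 6), exact = TRUE)
  expect_equal(mw$p_value, wt$p.value, tolerance = 1e-12)

  same <- c(2, 4, 4, 7)
  tied <- mann_whitney(same, same)
  expect_equal(tied$U, length(same)^2 / 2)
  expect_gt(tied$p_value, 0.9)
})

test_that("exact branch agrees with full permutation enumeration", {
  set.seed(91)
  x <- rnorm(5); y <- rnorm(6)
  mw <- mann_whitney(x, y)
  expect_match(mw$method, "exact")
  pool <- c(x, y)
  combs <- combn(11, 5)
  u_all <- apply(combs, 2, function(idx) {
    xs <- pool[idx]; ys <- pool[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  })
  p_perm <- min(1, 2 * min(mean(u_all <= mw$U), mean(u_all >= mw$U)))
  expect_equal(mw$p_value, p_perm, tolerance = 1e-12)
})

test_that("tie-corrected normal approximation matches wilcox.test", {
  set.seed(14)
  for (i in 1:10) {
    x <- sample(1:8, 25, replace = TRUE)
    y <- sample(2:9, 30, replace = TRUE)
    mw <- mann_whitney(x, y)
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(mw$U, unname(wt$statistic))
    expect_equal(mw$p_value, wt$p.value, tolerance = 1e-12)
  }
})

test_that("ROC: separation, hand-counted AUC, and the U identity", {
  r <- roc_analysis(c(3, 4, 5, 0.5, 1, 2),
                    c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_identical(r$auc, 1)
  expect_identical(r$sensitivity, 1)
  expect_identical(r$specificity, 1)
  expect_identical(r$optimal_cutoff, 3)   # an observed score

  r2 <- roc_analysis(c(0.9, 0.8, 0.85, 0.7), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r2$auc, 0.75)

  set.seed(8)
  for (i in 1:30) {
    n1 <- sample(3:20, 1); n0 <- sample(3:20, 1)
    sc <- c(round(rnorm(n1, 1), 1), round(rnorm(n0), 1))  # ties likely
    lab <- rep(c(TRUE, FALSE), c(n1, n0))
    r <- roc_analysis(sc, lab)
    mw <- mann_whitney(sc[lab], sc[!lab])
    expect_equal(r$auc * n1 * n0, mw$U, tolerance = 1e-12)
  }
})

test_that("ROC operating points are monotone and AUC matches its curve", {
  set.seed(15)
  sc <- rnorm(40); lab <- rep(c(TRUE, FALSE), 20)
  r <- roc_analysis(sc, lab)
  expect_true(all(diff(r$points$sensitivity) <= 0))   # threshold rises
  expect_true(all(diff(r$points$specificity) >= 0))
  fpr <- 1 - r$points$specificity; tpr <- r$points$sensitivity
  ord <- order(fpr, tpr)
  expect_equal(sum(diff(fpr[ord]) *
                     (tpr[ord][-1] + tpr[ord][-length(tpr)]) / 2),
               r$auc, tolerance = 1e-12)
})

test_that("optimal cut-off maximizes Youden J (exhaustive re-scan)", {
  set.seed(21)
  for (i in 1:25) {
    sc <- round(rnorm(30), 1)
    lab <- sample(c(TRUE, FALSE), 30, replace = TRUE)
    if (length(unique(lab)) < 2) next
    r <- suppressWarnings(roc_analysis(sc, lab))
    js <- vapply(sort(unique(sc)), function(t) {
      mean(sc[lab] >= t) + mean(sc[!lab] < t) - 1
    }, numeric(1))
    expect_equal(r$sensitivity + r$specificity - 1, max(js),
                 tolerance = 1e-12)
    # tie-break toward higher specificity
    tied <- sort(unique(sc))[js == max(js)]
    specs <- vapply(tied, function(t) mean(sc[!lab] < t), numeric(1))
    expect_equal(mean(sc[!lab] < r$optimal_cutoff), max(specs))
  }
})

test_that("AUC and DeLong CI agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(33)
  for (i in 1:10) {
    sc <- rnorm(45) + rep(c(0.8, 0), c(20, 25))
    lab <- rep(c(TRUE, FALSE), c(20, 25))
    r <- roc_analysis(sc, lab)
    pr <- pROC::roc(lab, sc, direction = "<", quiet = TRUE)
    expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
    ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
    expect_equal(r$ci95, ci[c(1, 3)], tolerance = 1e-8)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(12)
  sc <- rexp(30); lab <- rep(c(TRUE, FALSE), 15)
  a0 <- suppressWarnings(roc_analysis(sc, lab))$auc
  expect_equal(suppressWarnings(roc_analysis(log(sc), lab))$auc, a0)
  expect_equal(suppressWarnings(roc_analysis(sc^3 + 2, lab))$auc, a0)
  expect_error(roc_analysis(sc, rep(TRUE, 30)), "both classes")
})

test_that("low-AUC polarity is reported as-is with a warning", {
  expect_warning(
    r <- roc_analysis(c(1, 2, 8, 9), c(TRUE, TRUE, FALSE, FALSE)),
    "polarity")
  expect_identical(r$auc, 0)
})

test_that("paired DeLong: self-comparison and rank invariance are null", {
  set.seed(44)
  sc <- rnorm(30); lab <- rep(c(TRUE, FALSE), 15)
  self <- compare_roc_paired(sc, sc, lab)
  expect_identical(self$difference, 0)
  expect_identical(self$p_value, 1)
  mono <- compare_roc_paired(sc, exp(sc) + 5, lab)
  expect_identical(mono$difference, 0)
  expect_identical(mono$p_value, 1)
  expect_error(compare_roc_paired(sc, sc[-1], lab), "equal length")
})

test_that("paired DeLong matches pROC::roc.test", {
  skip_if_not_installed("pROC")
  set.seed(59)
  for (i in 1:8) {
    lab <- rep(c(TRUE, FALSE), c(23, 27))
    latent <- rnorm(50) + ifelse(lab, 1, 0)
    s1 <- latent + rnorm(50, sd = 0.6)
    s2 <- latent + rnorm(50, sd = 0.9)
    mine <- compare_roc_paired(s1, s2, lab)
    r1 <- pROC::roc(lab, s1, direction = "<", quiet = TRUE)
    r2 <- pROC::roc(lab, s2, direction = "<", quiet = TRUE)
    pt <- pROC::roc.test(r1, r2, method = "delong", paired = TRUE)
    expect_equal(mine$p_value, pt$p.value, tolerance = 1e-8)
    expect_equal(mine$z, unname(pt$statistic), tolerance = 1e-8)
  }
})

test_that("Spearman: hand values, exact small-n permutation, t approximation", {
  expect_equal(spearman_corr(1:7, (1:7)^3)$rho, 1)
  s <- spearman_corr(c(1, 2, 3), c(3, 1, 2))
  expect_equal(s$rho, -0.5, tolerance = 1e-12)

  set.seed(66)
  x <- rnorm(6); y <- rnorm(6)
  ex <- spearman_corr(x, y)
  expect_match(ex$method, "permutation")
  ct <- cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(ex$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_lt(abs(ex$p_value - ct$p.value), 0.05)  # approximation vs exact

  x20 <- rnorm(20); y20 <- x20 + rnorm(20)
  mine <- spearman_corr(x20, y20)
  ref <- cor.test(x20, y20, method = "spearman", exact = FALSE)
  expect_equal(mine$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)

  flagged <- spearman_corr(rep(1, 5), rnorm(5))
  expect_true(flagged$undefined)
  expect_true(is.na(flagged$rho))
})

test_that("bootstrap ROC comparison is seed-reproducible and sane", {
  set.seed(71)
  lab <- rep(c(TRUE, FALSE), c(12, 14))
  latent <- rnorm(26) + ifelse(lab, 1.2, 0)
  s1 <- latent + rnorm(26, sd = 0.4)
  s2 <- latent + rnorm(26, sd = 0.4)
  set.seed(1); b1 <- bootstrap_roc_comparison(s1, s2, lab, n_boot = 500)
  set.seed(1); b2 <- bootstrap_roc_comparison(s1, s2, lab, n_boot = 500)
  expect_identical(b1, b2)
  expect_gte(b1$p_value, 0)
  expect_lte(b1$p_value, 1)
})

test_that("threshold sweep: singleton, brute-force argmax, scale invariance", {
  cases <- lapply(1:8, function(i) {
    cs <- small_case(seed = 300 + i,
                     pattern = if (i %% 2) "filled_smooth" else "cortical_ribbon",
                     depth = if (i %% 2) 4 else 1)
    list(pet = cs$pet, brain_mask = cs$brain_mask,
         group = if (i %% 2) "positive" else "negative")
  })

  single <- threshold_sweep(cases, 1.5)
  expect_identical(nrow(single), 1L)
  expect_identical(attr(single, "argmax"), 1.5)

  kv <- c(1.2, 1.35, 1.5)
  sw <- threshold_sweep(cases, kv)
  # independent brute force: plain quantify_case loop + pair-count AUC
  brute <- vapply(kv, function(kk) {
    vals <- vapply(cases, function(cs)
      tryCatch(quantify_case(cs$pet, cs$brain_mask, k = kk)$shape_feature,
               error = function(e) NA_real_), numeric(1))
    grp <- vapply(cases, `[[`, character(1), "group")
    pos <- vals[grp == "positive" & !is.na(vals)]
    neg <- vals[grp == "negative" & !is.na(vals)]
    (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
      (length(pos) * length(neg))
  }, numeric(1))
  expect_equal(sw$auc, brute, tolerance = 1e-12)
  expect_identical(attr(sw, "argmax"), kv[brute == max(brute)])

  doubled <- lapply(cases, function(cs) {
    cs$pet$values <- cs$pet$values * 2
    cs
  })
  sw2 <- threshold_sweep(doubled, kv)
  expect_identical(sw$auc, sw2$auc)
})

test_that("a k emptying most VOIs is flagged and excluded", {
  cases <- lapply(1:4, function(i) {
    cs <- small_case(seed = 400 + i)
    list(pet = cs$pet, brain_mask = cs$brain_mask,
         group = if (i <= 2) "positive" else "negative")
  })
  expect_warning(sw <- threshold_sweep(cases, c(1.3, 40)), "excluded")
  expect_true(sw$excluded[sw$k == 40])
  expect_identical(attr(sw, "argmax"), 1.3)
})
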