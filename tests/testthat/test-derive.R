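test_that("median and tertile dichotomization follow their definitions", {
  expect_equal(as.character(dichotomize_rppa(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  expect_equal(as.character(dichotomize_rppa(1:6, "tertile_extremes")),
               c("low", "low", "excluded", "excluded", "high", "high"))
  expect_error(dichotomize_rppa(c(5, 5, 5, 5)), "identical")
  expect_error(dichotomize_rppa(c(1, 2, NA, NA, NA)), "at least 4")
  # missing values stay unlabelled
  lab <- dichotomize_rppa(c(1, 2, 3, 4, NA))
  expect_true(is.na(lab[5]))
})

test_that("Welch differential expression matches t.test per gene", {
  set.seed(21)
  expr <- expression_matrix(matrix(rnorm(4 * 12), 4, 12),
                            paste0("g", 1:4), paste0("s", 1:12))
  lab <- factor(rep(c("high", "low"), each = 6),
                levels = c("low", "excluded", "high"))
  de <- differential_expression(expr, lab)
  for (i in 1:4) {
    tt <- t.test(expr[i, 1:6], expr[i, 7:12])
    expect_equal(de$t_statistic[i], unname(tt$statistic), tolerance = 1e-6)
    expect_equal(de$p_value[i], tt$p.value, tolerance = 1e-6)
    expect_equal(de$log2_fc[i], unname(diff(rev(tt$estimate))),
                 tolerance = 1e-9)
  }
})

test_that("degenerate genes and small classes are handled", {
  expr <- expression_matrix(rbind(g1 = rep(1, 8),
                                  g2 = c(2, 2, 2, 2, 0, 0, 0, 0)),
                            sample_ids = paste0("s", 1:8))
  lab <- rep(c("high", "low"), each = 4)
  de <- differential_expression(expr, lab)
  expect_equal(de$log2_fc[1], 0)
  expect_equal(de$p_value[1], 1)
  expect_equal(de$log2_fc[2], 2)
  expect_equal(de$p_value[2], 0)
  expect_error(differential_expression(expr, c("high", rep("low", 7))),
               "at least 2 samples")
})

test_that("missing expression is complete-case per gene", {
  x <- rbind(g1 = c(4, 4, NA, 1, 1, 1), g2 = c(3, 3, 3, 0, 0, NA))
  expr <- expression_matrix(x, sample_ids = paste0("s", 1:6))
  lab <- rep(c("high", "low"), each = 3)
  de <- differential_expression(expr, lab)
  expect_equal(de$log2_fc, c(3, 3))
})

test_that("BH adjustment reproduces the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(1), 1)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(2)
  for (i in 1:20) {
    p <- runif(sample(2:30, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-14)
  }
})

test_that("AUC equals pairwise concordance and handles ties", {
  expect_equal(auc_mann_whitney(c(1, 2, 3, 4),
                                c("low", "low", "high", "high"))$auc, 1)
  expect_equal(auc_mann_whitney(c(2, 1, 3, 2),
                                c("low", "low", "high", "high"))$auc,
               0.875)
  set.seed(3)
  for (i in 1:50) {
    n <- sample(4:16, 1)
    sc <- sample(1:6, n, replace = TRUE)
    lab <- c("high", "low", sample(c("high", "low"), n - 2, TRUE))
    expect_equal(auc_mann_whitney(sc, lab)$auc, brute_auc(sc, lab))
  }
  expect_error(auc_mann_whitney(1:3, rep("high", 3)), "non-empty")
  # permuted labels at n = 200 stay near chance
  set.seed(4)
  a <- auc_mann_whitney(rnorm(200), sample(rep(c("high", "low"), 100)))
  expect_lt(abs(a$auc - 0.5), 0.08)
})

test_that("signature selection applies the FDR and fold-change rule", {
  de <- structure(data.frame(gene = c("A", "B", "C"),
                             mean_high = c(1, -1, 0.2),
                             mean_low = c(0, 0, 0),
                             log2_fc = c(1.2, -1, 0.2),
                             t_statistic = c(5, -5, 1), df = rep(10, 3),
                             p_value = c(0.001, 0.001, 0.4),
                             q_value = c(0.01, 0.01, 0.4)),
                  class = c("de_result", "data.frame"))
  sig <- select_signature(de, 0.05, 1.0)
  expect_equal(sig$up, "A")
  expect_equal(sig$down, "B")
  expect_length(select_signature(de, 0, 0.5), 0L)
})

test_that("relaxing selection thresholds never removes a gene", {
  set.seed(5)
  expr <- expression_matrix(matrix(rnorm(200 * 30, sd = 2), 200, 30),
                            sprintf("g%03d", 1:200), paste0("s", 1:30))
  lab <- rep(c("high", "low"), 15)
  de <- differential_expression(expr, lab)
  for (i in 1:10) {
    f1 <- runif(1, 0.01, 0.5); f2 <- runif(1, f1, 0.8)
    c1 <- runif(1, 0.5, 2); c2 <- runif(1, 0, c1)
    tight <- select_signature(de, f1, c1)
    loose <- select_signature(de, f2, c2)
    expect_true(all(tight$up %in% loose$up))
    expect_true(all(tight$down %in% loose$down))
  }
})

test_that("nested CV recovers a planted signature on a small cohort", {
  co <- small_cohort(seed = 5, effect = 2)
  cv <- nested_cv_derive(co$expr, co$rppa[, "pAKT"], k = 5, seed = 5,
                         marker = "pAKT")
  expect_gt(cv$outer_auc, 0.8)
  sig <- cv$signature
  planted <- co$truth$planted$pAKT
  rec <- length(intersect(sig$up, planted$up)) +
    length(intersect(sig$down, planted$down))
  expect_gt(rec / 30, 0.7)
  # derived up and down sets are disjoint by construction
  expect_length(intersect(sig$up, sig$down), 0L)
  expect_equal(sig$cv_auc, cv$outer_auc)
})

test_that("a single-point grid is chosen and still inner-validated", {
  co <- small_cohort(seed = 6, effect = 2)
  g1 <- data.frame(fdr_max = 0.05, fc_min = 0.5)
  cv <- nested_cv_derive(co$expr, co$rppa[, "pAKT"], grid = g1, k = 5,
                         seed = 6)
  expect_equal(cv$chosen$fdr_max, 0.05)
  expect_true(all(is.finite(cv$inner_auc)))
  expect_error(nested_cv_derive(co$expr, co$rppa[, "pAKT"],
                                grid = g1[0, ]), "empty threshold grid")
})

test_that("inner-CV choices ignore the outer test fold (no leakage)", {
  co <- small_cohort(seed = 7, effect = 1.5)
  cv1 <- nested_cv_derive(co$expr, co$rppa[, "pAKT"], k = 5, seed = 7)
  # permute each gene's values within the samples of outer fold 1
  expr2 <- co$expr
  fold1 <- names(cv1$outer_fold)[cv1$outer_fold == 1]
  set.seed(99)
  for (g in seq_len(nrow(expr2)))
    expr2[g, fold1] <- expr2[g, sample(fold1)]
  cv2 <- nested_cv_derive(expr2, co$rppa[, "pAKT"], k = 5, seed = 7)
  expect_identical(cv1$outer_fold, cv2$outer_fold)
  expect_equal(cv1$inner_auc[, 1], cv2$inner_auc[, 1])
  expect_identical(cv1$chosen_per_fold[1], cv2$chosen_per_fold[1])
})

test_that("an all-empty derivation is flagged with AUC 0.5", {
  co <- small_cohort(seed = 8, effect = 0, n = 80, g = 60)
  g1 <- data.frame(fdr_max = 1e-12, fc_min = 4)
  expect_warning(cv <- nested_cv_derive(co$expr, co$rppa[, "pAKT"],
                                        grid = g1, k = 5, seed = 8),
                 "empty signature")
  expect_true(cv$empty_flag)
  expect_equal(cv$outer_auc, 0.5)
  expect_length(cv$signature, 0L)
})

test_that("the rppa_signature fit object exposes the model interface", {
  co <- small_cohort(seed = 5, effect = 2)
  fit <- rppa_signature(co$expr, co$rppa, marker = "pAKT", k = 5,
                        seed = 5)
  expect_s3_class(fit, "rppa_signature")
  w <- coef(fit)
  expect_true(all(w %in% c(-1, 1)))
  sc <- predict(fit, co$expr)
  expect_length(sc, ncol(co$expr))
  s <- summary(fit)
  expect_equal(sum(s$grid$times_chosen), fit$cv$k)
  expect_output(print(fit), "RPPA-guided")
  # scores separate the activation classes it was trained on
  a <- auc_mann_whitney(unclass(sc)[names(fit$cv$labels)],
                        as.character(fit$cv$labels))
  expect_gt(a$auc, 0.8)
})
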