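test_that("Kruskal-Wallis matches the hand-computed H and degenerates", {
  kw <- kruskal_wallis(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_equal(kw$statistic, 2.4)
  expect_equal(kw$p_value, pchisq(2.4, 1, lower.tail = FALSE))
  dg <- kruskal_wallis(rep(1, 6), rep(c("a", "b"), 3))
  expect_equal(dg$p_value, 1)
  expect_equal(dg$flag, "degenerate")
  expect_error(kruskal_wallis(1:4, rep("a", 4)), "at least 2 groups")
  # forced signal
  set.seed(41)
  sc <- c(rnorm(50), rnorm(50, 5))
  expect_lt(kruskal_wallis(sc, rep(c("a", "b"), each = 50))$p_value, 1e-6)
})

test_that("two-group Kruskal-Wallis agrees with the U-test normal form", {
  set.seed(42)
  for (i in 1:5) {
    sc <- rnorm(60)  # continuous: no ties
    g <- rep(c("high", "low"), each = 30)
    kw <- kruskal_wallis(sc, g)
    mw <- auc_mann_whitney(sc, g)
    expect_equal(kw$p_value, mw$p_value, tolerance = 1e-9)
  }
})

test_that("Mann-Whitney is exact for small untied samples", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$p_value, 0.1)  # 2/20 rank splits are as extreme
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("mutation associations detect the planted logistic model", {
  co <- simulate_cohort(sim_config(n_samples = 500, n_genes = 400,
                                   planted_up = 30, planted_down = 30,
                                   seed = 43))
  tr <- co$truth$planted$pAKT
  sig <- gene_signature("pAKT", up = tr$up, down = tr$down)
  sc <- signature_score(rescale_dataset(co$expr), sig)
  res <- mutation_association(sc, co$clinical, "PIK3CA", by_exon = TRUE)
  expect_lt(res$mut$p_value, 0.01)
  mut_mean <- mean(as.vector(sc)[co$clinical$pik3ca_status != "wt"])
  wt_mean <- mean(as.vector(sc)[co$clinical$pik3ca_status == "wt"])
  expect_gt(mut_mean, wt_mean)
  expect_named(res, c("mut", "exon9", "exon20", "other_exon"))
  # a score unrelated to the mutation shows no association
  set.seed(44)
  null_sc <- structure(rnorm(500), names = names(sc))
  expect_gt(mutation_association(null_sc, co$clinical,
                                 "PIK3CA")$mut$p_value, 0.001)
})

test_that("undersized mutation classes are flagged, not tested", {
  clin <- clinical_table(data.frame(
    sample_id = paste0("s", 1:30),
    pik3ca_status = c(rep("wt", 25), rep("exon9", 5))))
  sc <- structure(rnorm(30), names = paste0("s", 1:30))
  res <- mutation_association(sc, clin, "PIK3CA", by_exon = TRUE)
  expect_match(res$mut$flag, "skipped")
  expect_match(res$exon20$flag, "skipped")
  expect_true(is.na(res$exon20$p_value))
  expect_error(mutation_association(sc, clin, "P53"), "lacks column")
})

test_that("Kaplan-Meier estimates match the hand product-limit", {
  g <- rep(c("A", "B"), each = 3)
  res <- km_logrank(g, c(1, 2, 3, 4, 5, 6), rep(1, 6))
  sm <- summary(res$curves)
  surv_A <- sm$surv[sm$strata == "g=A"]
  expect_equal(surv_A, c(2 / 3, 1 / 3, 0))
  expect_gt(res$test$statistic, 0)  # group B fares better
  # identical groups: no log-rank signal
  same <- km_logrank(rep(c("A", "B"), each = 10), rep(1:10, 2),
                     rep(1, 20))
  expect_equal(same$test$statistic, 0, tolerance = 1e-9)
  expect_equal(same$test$p_value, 1, tolerance = 1e-9)
  none <- km_logrank(g, 1:6, rep(0, 6))
  expect_equal(none$test$flag, "no events")
  expect_true(is.na(none$test$p_value))
})

test_that("Cox HR per SD is invariant to affine score rescaling", {
  set.seed(45)
  sc <- rnorm(400)
  sv <- simulate_survival(sc, log(1.6), 0.01, 0.3, seed = 46)
  clin <- clinical_table(data.frame(sample_id = paste0("s", 1:400),
                                    rfs_time = sv$rfs_time,
                                    rfs_event = sv$rfs_event))
  h1 <- cox_fit(sc, clin)
  h2 <- cox_fit(10 * sc - 3, clin)
  expect_equal(h1$hr, h2$hr, tolerance = 1e-9)
  expect_lte(h1$ci_low, h1$hr)
  expect_gte(h1$ci_high, h1$hr)
  expect_lte(h1$n_events, h1$n)
})

test_that("degenerate Cox designs are caught", {
  set.seed(47)
  sc <- rnorm(200)
  sv <- simulate_survival(sc, log(2), 0.01, 0.2, seed = 48)
  clin <- clinical_table(data.frame(sample_id = paste0("s", 1:200),
                                    age = 50, grade = 2,
                                    rfs_time = sv$rfs_time,
                                    rfs_event = sv$rfs_event))
  expect_warning(h <- cox_fit(sc, clin, multivariable = TRUE),
                 "constant covariate")
  expect_gt(h$hr, 1)
  expect_error(cox_fit(rep(1, 200), clin), "constant")
  expect_error(cox_fit(sc[1:8], clin[1:8, ], min_events = 10),
               "fewer than")
})

test_that("pooling two cohorts tightens the interval around both HRs", {
  mk <- function(seed) simulate_cohort(sim_config(
    n_samples = 400, n_genes = 600, planted_up = 20, planted_down = 20,
    effect_size = 1.5, seed = seed,
    survival_model = list(baseline = 0.005,
                          log_hr = c(pAKT = log(0.6), pmTOR = log(1.8)),
                          censor_rate = 0.6)))
  d1 <- mk(21)
  d2 <- mk(22)
  tr <- d1$truth$planted$pAKT
  sig <- gene_signature("pAKT", up = tr$up, down = tr$down)
  per_ds <- lapply(list(d1, d2), function(d)
    cox_fit(signature_score(rescale_dataset(d$expr), sig), d$clinical))
  pooled <- pooled_analysis(list(d1, d2), list(sig), strata = "luminal",
                            models = "univariable")
  hrs <- vapply(per_ds, `[[`, numeric(1), "hr")
  expect_gte(pooled$hr, min(hrs))
  expect_lte(pooled$hr, max(hrs))
  widths <- vapply(per_ds, function(h) h$ci_high - h$ci_low, numeric(1))
  expect_lt(pooled$ci_high - pooled$ci_low, min(widths))
  expect_equal(pooled$n, 800L)
})

test_that("stratum filters select exactly the flagged samples", {
  co <- simulate_cohort(sim_config(n_samples = 200, n_genes = 300,
                                   planted_up = 10, planted_down = 10,
                                   seed = 23))
  tr <- co$truth$planted$pAKT
  sig <- gene_signature("pAKT", up = tr$up, down = tr$down)
  ft <- pooled_analysis(list(co), list(sig),
                        strata = c("luminal", "endocrine"),
                        models = "univariable", min_events = 5)
  n_endo <- sum(co$clinical$endocrine_only == 1)
  expect_equal(ft$n[ft$stratum == "endocrine"], n_endo)
  expect_equal(ft$n[ft$stratum == "luminal"], 200L)
  # a dataset without luminal-A samples contributes nothing to lumA
  co2 <- co
  co2$clinical$subtype <- "LumB"
  ft2 <- pooled_analysis(list(co, co2), list(sig), strata = "lumA",
                         models = "univariable", min_events = 5)
  expect_equal(ft2$n, sum(co$clinical$subtype == "LumA"))
})

test_that("tertile log-rank detects a planted survival gradient", {
  set.seed(49)
  sc <- rnorm(600)
  sv <- simulate_survival(sc, log(2.5), 0.01, 0.3, seed = 50)
  g <- tertile_groups(sc)
  res <- km_logrank(g, sv$rfs_time, sv$rfs_event)
  expect_lt(res$test$p_value, 1e-6)
  expect_equal(res$test$group_sizes, rep(200L, 3))
})
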