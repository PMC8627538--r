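test_that("z-score embedding has unit-variance centred columns and drops constants", {
  set.seed(1)
  X <- cbind(a = rnorm(10), b = runif(10), const = rep(3, 10))
  ft <- toy_features(X, rep(c("P1", "P2"), each = 5))
  emb <- embed_features(ft)
  expect_equal(unname(colMeans(emb$coordinates)), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(emb$coordinates, 2, sd)), c(1, 1),
               tolerance = 1e-9)
  expect_equal(emb$dropped, "const")
  # z-scores match the direct formula
  expect_equal(unname(emb$coordinates[, "a"]),
               (X[, "a"] - mean(X[, "a"])) / sd(X[, "a"]), tolerance = 1e-12)
})

test_that("duplicated lesion rows embed to identical coordinates", {
  X <- cbind(x = c(1, 2, 3, 1), y = c(0, 1, 2, 0))
  emb <- embed_features(toy_features(X, c("P1", "P1", "P2", "P2")))
  expect_equal(emb$coordinates[1, ], emb$coordinates[4, ],
               ignore_attr = TRUE)
})

test_that("an all-constant feature table cannot be embedded", {
  X <- cbind(a = rep(1, 4), b = rep(2, 4))
  expect_error(embed_features(toy_features(X, c("P1", "P1", "P2", "P2"))),
               class = "radiohet_embedding_degenerate")
})

test_that("silhouettes are 1 for coincident-pair patients far apart and 0 on ties", {
  X <- rbind(c(0, 0), c(0, 0), c(10, 10), c(10, 10))
  s <- lesion_silhouettes(X, c("A", "A", "B", "B"))
  expect_equal(s$s, rep(1, 4))
  # a == b tie: symmetric triangle construction
  Xt <- rbind(c(0, 0), c(2, 0), c(1, 0))
  st <- lesion_silhouettes(Xt, c("A", "A", "B"))
  # for lesion 3 (singleton patient B): excluded zero
  expect_true(st$excluded[3])
  # lesion 1: a = 2 (to lesion 2), b = 1 (to B) -> s = -0.5
  expect_equal(st$s[1], -0.5)
})

test_that("silhouettes equal the brute-force oracle on random instances", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(4:30, 1)
    X <- matrix(rnorm(n * 3), n)
    labels <- sample(sprintf("P%d", 1:sample(2:5, 1)), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    s <- lesion_silhouettes(X, labels)
    expect_equal(s$s, oracle_silhouette(X, labels), tolerance = 1e-12)
  }
})

test_that("silhouettes agree with cluster::silhouette on multi-lesion groups", {
  skip_if_not_installed("cluster")
  set.seed(11)
  X <- matrix(rnorm(40), 20)
  labels <- rep(1:4, each = 5)
  s <- lesion_silhouettes(X, labels)
  cs <- cluster::silhouette(labels, dist(X))
  expect_equal(s$s, as.numeric(cs[, "sil_width"]), tolerance = 1e-12)
})

test_that("silhouette values are scale invariant and bounded", {
  set.seed(3)
  X <- matrix(rnorm(24), 12)
  labels <- rep(c("A", "B", "C"), each = 4)
  s1 <- lesion_silhouettes(X, labels)
  s2 <- lesion_silhouettes(X * 37.5, labels)
  expect_equal(s1$s, s2$s, tolerance = 1e-12)
  expect_true(all(s1$s >= -1 & s1$s <= 1))
})

test_that("a single distinct patient is rejected", {
  X <- matrix(rnorm(6), 3)
  expect_error(lesion_silhouettes(X, rep("P1", 3)),
               class = "radiohet_silhouette_undefined")
})

test_that("patient means, exclusion of single-lesion patients, and cohort mean", {
  pl <- data.frame(lesion_id = as.character(1:5),
                   label = c("P1", "P1", "P2", "P2", "P3"),
                   s = c(0.2, -0.4, 1, 1, 0),
                   excluded = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  pr <- patient_silhouette(pl)
  expect_equal(pr$per_patient$mean_s[pr$per_patient$patient_id == "P1"],
               -0.1)
  p3 <- pr$per_patient[pr$per_patient$patient_id == "P3", ]
  expect_equal(p3$mean_s, 0)
  expect_true(p3$excluded)
  # cohort mean over non-excluded patients only
  expect_equal(pr$mean_index, mean(c(-0.1, 1)))
})

test_that("single-site cohorts make anatomy-based equal patient-based", {
  set.seed(5)
  X <- matrix(rnorm(24), 12)
  ft <- toy_features(X, rep(sprintf("P%d", 1:4), each = 3),
                     site = rep("BONE", 12),
                     suv = runif(12, 2, 8))
  all_res <- patient_silhouette(
    lesion_silhouettes(embed_features(ft)$coordinates, ft$patient_id))
  an <- anatomy_silhouette(ft, "BONE")
  expect_equal(an$mean_index, all_res$mean_index, tolerance = 1e-12)
  expect_error(anatomy_silhouette(ft, "REGIONAL_LN"),
               class = "radiohet_silhouette_undefined")
})

test_that("tertile assignment follows the inclusive lower-tertile tie rule", {
  expect_equal(suv_tertiles(rep(4, 10)), rep(1L, 10))
  expect_equal(suv_tertiles(1:9), rep(1:3, each = 3))
})

test_that("site-restricted analysis reduces apparent heterogeneity under site effects", {
  cfg <- cohort_config(n_patients = 24, lesion_count_law = c(`4` = 1),
                       n_archetypes = 24, sigma_between = 1,
                       sigma_within = 1.2, site_effect_scale = 2.5,
                       seed = 31)
  co <- simulate_cohort(cfg)
  fit <- lesion_similarity(co$feature_table)
  site_means <- vapply(fit$anatomy, `[[`, numeric(1), "mean_index")
  expect_gt(mean(site_means), fit$patient$mean_index)
})

test_that("SUV-phenotype coupling makes tertile-restricted indices higher", {
  # patients carry a latent metabolic trait; strong coupling plus tight
  # per-lesion SUV noise makes tertiles group metabolically alike patients
  law <- lapply(default_suv_law(), function(x) c(x[1], 0.2))
  for (seed in c(13, 5)) {
    cfg <- cohort_config(n_patients = 24, lesion_count_law = c(`6` = 1),
                         n_archetypes = 6, sigma_between = 1.5,
                         sigma_within = 1, site_effect_scale = 0,
                         suv_coupling = 2.5, suv_law = law,
                         feature_names = paste0("f", 1:5), seed = seed)
    fit <- lesion_similarity(simulate_cohort(cfg)$feature_table)
    tert_means <- vapply(fit$metabolism, `[[`, numeric(1), "mean_index")
    expect_gt(mean(tert_means), fit$patient$mean_index)
  }
})

test_that("paired slicing test conventions and formula", {
  mk <- function(vals, ids = sprintf("P%d", seq_along(vals))) {
    structure(list(per_patient = data.frame(patient_id = ids, mean_s = vals,
                                            n_lesions = 2,
                                            excluded = FALSE)),
              class = "silhouette_result")
  }
  # identical values -> t = 0, p = 1
  r <- paired_slicing_test(mk(c(0.1, 0.2, 0.3)), mk(c(0.1, 0.2, 0.3)))
  expect_equal(r$t, 0); expect_equal(r$p, 1)
  # constant non-zero differences -> degenerate NaN
  r2 <- paired_slicing_test(mk(c(0, 0, 0)), mk(c(1, 1, 1)))
  expect_true(r2$degenerate); expect_true(is.nan(r2$p))
  # 10 pairs match the textbook formula (t.test as the oracle)
  set.seed(9)
  a <- rnorm(10); b <- a + rnorm(10, 0.3, 0.2)
  r3 <- paired_slicing_test(mk(a), mk(b))
  tt <- t.test(b, a, paired = TRUE)
  expect_equal(r3$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(r3$p, tt$p.value, tolerance = 1e-12)
})

test_that("cohort mean silhouette decreases with the within/between ratio", {
  ratios <- c(0.2, 1, 4)
  means <- vapply(ratios, function(r) {
    cfg <- cohort_config(n_patients = 25, lesion_count_law = c(`4` = 1),
                         n_archetypes = 25, sigma_between = 1,
                         sigma_within = r, site_effect_scale = 0, seed = 17)
    fit <- lesion_similarity(simulate_cohort(cfg)$feature_table,
                             slicings = "patient")
    fit$patient$mean_index
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("random label shuffles drive the mean index to zero or below", {
  cfg <- cohort_config(n_patients = 20, lesion_count_law = c(`3` = 1),
                       n_archetypes = 20, sigma_within = 0.3, seed = 23)
  co <- simulate_cohort(cfg)
  emb <- embed_features(co$feature_table)
  set.seed(1)
  shuffled <- replicate(20, {
    lab <- sample(co$feature_table$patient_id)
    patient_silhouette(lesion_silhouettes(emb$coordinates, lab))$mean_index
  })
  expect_lte(mean(shuffled), 0.05)
})

test_that("the lesion_similarity fit carries slicings, methods print, and plots", {
  co <- simulate_cohort(cohort_config(n_patients = 12, seed = 41))
  fit <- lesion_similarity(co$feature_table)
  expect_s3_class(fit, "lesion_similarity")
  expect_true(is.finite(fit$patient$mean_index))
  expect_output(print(fit), "mean similarity index")
  sm <- summary(fit)
  expect_true("ALL" %in% names(sm$slicing_means))
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})
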