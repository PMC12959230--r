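test_that("CV2 uses the sample sd convention and is scale invariant", {
  expect_equal(cv2_stats(c(5, 5, 5))$cv2, 0)
  st <- cv2_stats(c(1, 2, 3))
  expect_equal(st$mean, 2)
  expect_equal(st$sd, 1)       # n - 1 denominator
  expect_equal(st$cv2, 0.25)
  expect_equal(cv2_stats(c(2, 4, 6))$cv2, 0.25)
  set.seed(1)
  v <- rgamma_meancv2(40, 3, 0.02)
  expect_equal(cv2_stats(v * 17.3)$cv2, cv2_stats(v)$cv2, tolerance = 1e-12)
  expect_error(cv2_stats(5), "at least 2")
  expect_error(cv2_stats(c(1, -1, 2)), "positive")
})

test_that("relative effects are signed with absolute magnitude", {
  e <- relative_effect(12, 10)
  expect_equal(e$rel_effect, 0.2)
  expect_equal(e$abs_rel_effect, 0.2)
  expect_equal(relative_effect(10, 10)$rel_effect, 0)
  e <- relative_effect(8, 10)
  expect_equal(e$rel_effect, -0.2)
  expect_equal(e$abs_rel_effect, 0.2)
  # unit invariance: rescaling both means leaves the effect unchanged
  expect_equal(relative_effect(12 * 3.7, 10 * 3.7)$rel_effect, 0.2)
  expect_error(relative_effect(5, 0), "positive")
})

test_that("expression summaries match hand-computed moments", {
  toy <- rbind(g1 = c(1, 2, 3), g2 = c(10, 20, 30))
  es <- expression_summary(toy)
  expect_equal(es$cv2_expr, c(0.25, 0.25))
  expect_equal(es$log10_mean_expr, c(log10(2), log10(20)))
  expect_equal(expression_summary(rbind(g = c(4, 4, 4)))$cv2_expr, 0)
  expect_error(expression_summary(cbind(c(1, 2))), "at least 2 samples")
  # zero-mean genes are flagged, not dropped
  es0 <- expression_summary(rbind(a = c(0, 0, 0), b = c(1, 2, 3)))
  expect_true(es0$zero_mean[1])
  expect_true(is.na(es0$log10_mean_expr[1]))
})

test_that("Pearson test reproduces the t-transform oracle", {
  expect_equal(pearson_test(1:5, 2 * (1:5) + 1)$r, 1)
  expect_equal(pearson_test(c(1, 2, 3), c(6, 4, 2))$r, -1)
  res <- pearson_test(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(res$r, 0.8)
  # independent oracle: p from t = r sqrt((n-2)/(1-r^2)) on n-2 df
  t_or <- 0.8 * sqrt(2 / (1 - 0.64))
  expect_equal(res$p, 2 * pt(-t_or, df = 2), tolerance = 1e-12)
  expect_identical(res$n, 4L)
  expect_error(pearson_test(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_test(1:3, 1:4), "equal length")
  expect_error(pearson_test(1:2, 2:3), "at least 3")
})

test_that("the screen table joins phenotype and expression per mutant", {
  study <- quick_study(seed = 21L)
  st <- build_screen_table(study$measurements, study$expr, study$gene_map)
  expect_identical(nrow(st), 16L * 4L)
  expect_identical(sort(unique(st$parameter)),
                   sort(c("area", "length", "width", "aspect_ratio")))
  expect_true(all(table(st$parameter) == 16))
  # cv2 and effect recomputed from raw rows agree
  one <- st[st$genotype == "pmr6" & st$parameter == "area", ]
  raw <- study$measurements$area[study$measurements$genotype == "pmr6"]
  expect_equal(one$cv2, (sd(raw) / mean(raw))^2)
  ctrl <- study$measurements[study$measurements$genotype == "col0" &
                               study$measurements$batch == one$batch, ]
  expect_equal(one$rel_effect, (mean(raw) - mean(ctrl$area)) / mean(ctrl$area))

  # a mutant without a mapped gene is rejected with a warning
  gm <- study$gene_map[study$gene_map$genotype != "pmr6", ]
  expect_warning(st15 <- build_screen_table(study$measurements, study$expr, gm),
                 "pmr6")
  expect_identical(nrow(st15), 15L * 4L)
  expect_identical(attr(st15, "rejects")$genotype, "pmr6")
})

test_that("screen grid covers every response x parameter x covariate", {
  study <- quick_study(seed = 22L)
  st <- build_screen_table(study$measurements, study$expr, study$gene_map)
  sc <- run_screens(st)
  expect_identical(nrow(sc), 16L)  # 2 responses x 4 parameters x 2 covariates
  expect_true(all(sc$n == 16))
  expect_true(all(abs(sc$r) <= 1))
  expect_true(all(sc$p > 0 & sc$p <= 1))
  # correction hook: off by default, monotone when on
  sc_bh <- run_screens(st, p_adjust = "BH")
  expect_identical(sc$p, sc_bh$p)
  expect_true(all(sc_bh$p_adj >= sc_bh$p))
})

test_that("log base of the expression covariate cannot change r or p", {
  study <- quick_study(seed = 23L)
  st <- build_screen_table(study$measurements, study$expr, study$gene_map)
  st_ln <- st
  st_ln$log10_mean_expr <- log(st$mean_expr)  # natural log instead
  a <- run_screens(st)
  b <- run_screens(st_ln)
  expect_equal(a$r, b$r, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("reference band averages per-batch control CV2", {
  study <- quick_study(seed = 24L)
  band <- reference_band(study$measurements)
  expect_identical(nrow(band), 4L)
  ctrl <- study$measurements[study$measurements$genotype == "col0", ]
  cv2s <- sapply(split(ctrl$area, ctrl$batch),
                 function(v) (sd(v) / mean(v))^2)
  expect_equal(band$mean_cv2[band$parameter == "area"], mean(cv2s))
  expect_equal(band$sd_cv2[band$parameter == "area"], sd(cv2s))
  # two batches with CV2 0.01 and 0.03 give mean 0.02, sd sqrt(2e-4)
  expect_equal(sd(c(0.01, 0.03)), 0.01414214, tolerance = 1e-6)
  one_batch <- ctrl[ctrl$batch == ctrl$batch[1], ]
  expect_error(reference_band(one_batch), "at least 2 control batches")
})

test_that("sample-size confound test is affine invariant in n", {
  study <- quick_study(seed = 25L)
  st <- build_screen_table(study$measurements, study$expr, study$gene_map)
  conf <- sample_size_confound(st)
  expect_identical(nrow(conf), 4L)
  st2 <- st
  st2$n <- 2L * st$n
  conf2 <- sample_size_confound(st2)
  expect_equal(conf$r, conf2$r, tolerance = 1e-12)
  expect_equal(conf$p, conf2$p, tolerance = 1e-12)
  st_eq <- st
  st_eq$n <- 50L
  expect_error(sample_size_confound(st_eq), "zero variance")
})

test_that("estimated CV2 tracks generator truth within sampling error", {
  hits <- 0L; total <- 0L
  for (s in 1:4) {
    study <- simulate_study(quick_cfg(seed = 100L + s,
                                      sepals_per_genotype_range = c(90L, 90L)))
    st <- build_screen_table(study$measurements, study$expr, study$gene_map)
    sub <- st[st$parameter == "area", ]
    truth <- study$truth$genotypes
    tru <- truth$cv2_area[match(sub$genotype, truth$genotype)]
    se <- tru * sqrt(2 / (sub$n - 1) + 4 * tru / sub$n)
    hits <- hits + sum(abs(sub$cv2 - tru) < 3 * se)
    total <- total + nrow(sub)
  }
  expect_gte(hits / total, 0.95)
})

test_that("fitted screen object summarizes and plots", {
  fit <- sepal_screen(quick_study(seed = 26L))
  expect_s3_class(fit, "sepal_screen")
  expect_output(print(fit), "16 mutants")
  expect_output(print(summary(fit)), "reference band")
  tmp <- withr::local_tempfile(fileext = ".png")
  grDevices::png(tmp)
  expect_invisible(plot(fit))
  grDevices::dev.off()
  expect_true(file.exists(tmp))
})
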