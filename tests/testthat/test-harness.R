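test_that("subject-wise splitting is disjoint, rounded and deterministic", {
  ds <- make_dataset(10, 2, rng_seed = 1, L = 300)
  sp <- split_by_subject(ds, rng_seed = 3)
  expect_length(sp$subjects$train, 7)
  expect_length(sp$subjects$val, 1)
  expect_length(sp$subjects$test, 2)
  for (seed in 1:10) {
    s <- split_by_subject(ds, rng_seed = seed)$subjects
    expect_length(intersect(s$train, s$val), 0)
    expect_length(intersect(s$train, s$test), 0)
    expect_length(intersect(s$val, s$test), 0)
    expect_setequal(c(s$train, s$val, s$test), unique(ds$subject))
  }
  expect_identical(split_by_subject(ds, rng_seed = 5)$subjects,
                   split_by_subject(ds, rng_seed = 5)$subjects)
  few <- dataset_subset(ds, ds$subject <= 2)
  expect_error(split_by_subject(few), "at least 3 subjects")
})

test_that("training records best-validation bookkeeping and early-stops", {
  ds <- make_mapping_dataset(4, 8, rng_seed = 2, L = 128)
  sp <- split_by_subject(ds, ratios = c(0.5, 0.25, 0.25), rng_seed = 2)
  model <- maru_model(model_config("tiny", input_len = 128L), rng_seed = 2)
  fit <- train_model(model, sp,
                     train_config(lr = 3e-3, max_epochs = 5L, patience = 4L,
                                  batch_size = 8L, rng_seed = 2))
  h <- fit$history
  expect_true(all(diff(h$best_val) <= 1e-12))            # monotone best-val trace
  # patience 2 with a stalled validation loss stops within 2 epochs of the stall
  model2 <- maru_model(model_config("tiny", input_len = 128L), rng_seed = 2)
  fit2 <- train_model(model2, sp,
                      train_config(lr = 1e-12, max_epochs = 10L, patience = 2L,
                                   batch_size = 8L, rng_seed = 2))
  expect_lte(nrow(fit2$history), fit2$best_epoch + 2L)   # stops within patience
  # checkpoint round-trip reproduces the validation loss exactly
  tmp <- tempfile(fileext = ".rds")
  save_model(fit$model, tmp)
  reloaded <- load_model(tmp)
  unlink(tmp)
  pr1 <- maru_predict(fit$model, resample_windows(sp$val$rpw, 128L))
  pr2 <- maru_predict(reloaded, resample_windows(sp$val$rpw, 128L))
  expect_identical(pr1$sbp, pr2$sbp)
  expect_identical(pr1$abp, pr2$abp)
  expect_error(train_model(model, list(train = NULL)), "empty training split")
})

test_that("error metrics follow their definitions", {
  m <- bp_metrics(c(1, -1) + c(10, 20), c(10, 20))
  expect_equal(m$me, 0)
  expect_equal(m$mae, 1)
  expect_equal(m$sd, sqrt(2))
  expect_equal(m$rmse, 1)
  ident <- bp_metrics(c(100, 110, 120), c(100, 110, 120))
  expect_equal(ident$mae, 0)
  expect_equal(ident$pct5, 100)
  expect_equal(ident$pct15, 100)
  expect_warning(mm <- bp_metrics(c(5, 5, 5), c(1, 2, 3)), "undefined")
  expect_true(is.nan(mm$r))
  expect_error(bp_metrics(1, 1), "at least 2")
  # RMSE identity: rmse^2 = me^2 + sd^2 (n-1)/n
  set.seed(3)
  p <- rnorm(50, 120, 8); r <- rnorm(50, 120, 8)
  mm2 <- bp_metrics(p, r)
  expect_equal(mm2$rmse^2, mm2$me^2 + mm2$sd^2 * 49 / 50, tolerance = 1e-9)
})

test_that("AAMI and BHS grading agree with brute-force threshold tables", {
  expect_true(aami_check(0.07, 5.90))
  expect_true(aami_check(5.0, 8.0))                      # boundary inclusive
  expect_false(aami_check(6.0, 7.0))
  expect_false(aami_check(0, 8.5))
  expect_identical(bhs_grade(75.7, 92.1, 97.0), "A")
  expect_identical(bhs_grade(60, 85, 95), "A")
  expect_identical(bhs_grade(50, 75, 90), "B")
  expect_identical(bhs_grade(40, 65, 85), "C")
  expect_identical(bhs_grade(39, 65, 85), "D")
  # exhaustive agreement with the threshold tables on an integer grid
  brute <- function(p5, p10, p15) {
    tab <- rbind(A = c(60, 85, 95), B = c(50, 75, 90), C = c(40, 65, 85))
    for (g in rownames(tab)) if (all(c(p5, p10, p15) >= tab[g, ])) return(g)
    "D"
  }
  for (p5 in seq(0, 100, by = 10)) for (p10 in seq(p5, 100, by = 10)) {
    for (p15 in seq(p10, 100, by = 10)) {
      expect_identical(bhs_grade(p5, p10, p15), brute(p5, p10, p15))
    }
  }
  expect_error(bhs_grade(80, 70, 90))
})

test_that("Bland-Altman limits bracket the bias", {
  set.seed(4)
  p <- rnorm(100, 120, 5); r <- rnorm(100, 119, 5)
  ba <- bland_altman(p, r)
  expect_equal(ba$bias, mean(p - r))
  expect_equal(unname(diff(ba$loa)), 2 * 1.96 * sd(p - r))
})

test_that("ablation variants share the data split and report one row each", {
  ds <- make_mapping_dataset(5, 6, rng_seed = 5, L = 128)
  sp <- split_by_subject(ds, ratios = c(0.6, 0.2, 0.2), rng_seed = 5)
  tab <- run_ablation("temporal_module", sp,
                      model_cfg = model_config("tiny", input_len = 128L),
                      train_cfg = train_config(max_epochs = 2L, patience = 1L,
                                               batch_size = 8L, rng_seed = 5))
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$variant, c("temporal=none", "temporal=bimamba"))
  expect_identical(attr(tab, "subjects"), sp$subjects)
  expect_true(all(is.finite(tab$sbp_mae)))
})
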