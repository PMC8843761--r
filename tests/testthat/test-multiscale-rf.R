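# small synthetic classification data with a known informative predictor
toy_dataset <- function(n = 120, seed = 1, extra_constant = FALSE) {
  set.seed(seed)
  y <- factor(rep(c("presence", "absence"), each = n / 2),
              levels = c("absence", "presence"))
  signal <- ifelse(y == "presence", 1, 0) + rnorm(n, 0, 0.4)
  d <- data.frame(signal = signal, noise1 = rnorm(n), noise2 = rnorm(n),
                  y = y)
  if (extra_constant) d$flatvar <- 1
  d
}

test_that("model datasets honor the equal-sampling contract", {
  ls1 <- synthetic_landscape(landscape_config(seed = 12, nrow = 80,
                                              ncol = 80))
  th <- thin_occurrences(ls1$occurrences, 1200)
  td <- terrain_derivatives(ls1$terrain)
  ab <- generate_pseudo_absences(th, absence_constraints(n_sets = 2),
                                 ls1$terrain, td$slope, seed = 3)
  stack <- build_multiscale_stack(
    list(elevation = ls1$terrain, villages = ls1$features$villages),
    scales = c(1000, 4000), vars = c("ELE", "Densvil"))
  ds <- make_model_datasets(th, ab, stack)
  for (d in ds) {
    expect_equal(sum(d$y == "presence"), sum(d$y == "absence"))
    expect_false(anyNA(d))
  }
  # labels line up with the point order: presences first
  expect_true(all(ds[[1]]$y[seq_len(nrow(th))] == "presence"))
  expect_equal(ds[[1]]$ELE_1000[1],
               focal_mean(ls1$terrain, 1000)$values[
                 grid_rowcol(ls1$terrain, th$x[1], th$y[1])$row,
                 grid_rowcol(ls1$terrain, th$x[1], th$y[1])$col])
})

test_that("univariate scale selection breaks ties toward the finest
           scale and flags missing scales", {
  set.seed(7)
  d <- toy_dataset()
  # a variable identical at all scales: OOB errors tie, finest wins
  d$V_1000 <- d$signal; d$V_2000 <- d$signal
  prof <- univariate_scale_selection(list(d, d), "V", c(1000, 2000),
                                     num_trees = 100, seed = 2)
  expect_equal(unname(prof$chosen["V"]), 1000)
  expect_error(
    univariate_scale_selection(list(d), "V", c(1000, 3000), seed = 1),
    "missing at scale")
})

test_that("collinearity screening removes one member of each highly
           correlated pair", {
  set.seed(8)
  a <- rnorm(500)
  df <- data.frame(a = a, b = a + rnorm(500, 0, 0.01), c = rnorm(500))
  scr <- collinearity_screen(df, threshold = 0.85)
  expect_length(scr$retained, 2)
  expect_true("c" %in% scr$retained)
  expect_equal(nrow(scr$removed), 1)

  # independent layers all survive
  ind <- data.frame(x = rnorm(300), y = rnorm(300), z = rnorm(300))
  expect_length(collinearity_screen(ind, threshold = 0.85)$retained, 3)

  # priority decides which member is dropped (higher OOB error goes)
  scr2 <- collinearity_screen(df, threshold = 0.85,
                              priority = c(a = 0.4, b = 0.2, c = 0.3))
  expect_false("a" %in% scr2$retained)
  expect_true("b" %in% scr2$retained)

  # constant layers are retained with a warning
  cst <- data.frame(u = rnorm(100), v = rep(1, 100))
  expect_warning(out <- collinearity_screen(cst, threshold = 0.85),
                 "constant")
  expect_true("v" %in% out$retained)
})

test_that("MIR normalization and threshold subsets follow the 0.1-step
           rule", {
  imp <- c(v1 = 0.50, v2 = 0.25, v3 = 0.05)
  ms <- mir_subsets(imp)
  expect_equal(unname(ms$mir), c(1, 0.5, 0.1))
  expect_equal(ms$subsets[["0.3"]], c("v1", "v2"))
  expect_equal(ms$subsets[["0.0"]], c("v1", "v2", "v3"))  # all variables
  expect_length(ms$subsets, 10)
  expect_error(mir_subsets(c(a = 0, b = -1)), "MIR undefined")
})

test_that("MIR model selection keeps the informative variable and
           achieves the best candidate OOB", {
  d <- toy_dataset(n = 160, seed = 3)
  m <- mir_model_selection(d, c("signal", "noise1", "noise2"),
                           num_trees = 200, seed = 4)
  expect_true("signal" %in% m$variables)
  expect_equal(m$oob, min(m$oob_by_threshold$oob))
  expect_equal(m$mir$mir[m$mir$variable == "signal"], 1)
  # threshold 0 candidate is the full model
  expect_equal(m$oob_by_threshold$n_vars[1], 3)
})

test_that("degenerate all-constant predictors are rejected", {
  d <- toy_dataset(seed = 5)
  d$c1 <- 1; d$c2 <- 2
  expect_error(mir_model_selection(d, c("c1", "c2"), num_trees = 50,
                                   seed = 1))
})

test_that("rank-based AUC equals exhaustive pair counting", {
  expect_equal(auc_score(rep(0.3, 20), rep(c(TRUE, FALSE), 10)), 0.5)
  expect_equal(auc_score(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  set.seed(9)
  scores <- sample(seq(0, 1, 0.05), 50, replace = TRUE)  # with ties
  pos <- rep(c(TRUE, FALSE), 25)
  expect_equal(auc_score(scores, pos), bf_auc(scores, pos))
  expect_error(auc_score(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("an ensemble of one model reproduces that model's vote
           fraction and propagates nodata", {
  d <- toy_dataset(n = 160, seed = 6)
  m <- mir_model_selection(d, c("signal", "noise1"), num_trees = 200,
                           seed = 7)
  nr <- 12
  vals <- matrix(seq(-1, 2, length.out = nr * nr), nr, nr)
  stack <- list(layers = list(
    signal = raster_grid(vals, cell_size = 250),
    noise1 = raster_grid(matrix(0, nr, nr), cell_size = 250)))
  stack$layers$signal$values[3, 3] <- NA
  hs <- ensemble_predict(m, stack)
  expect_true(all(hs$values >= 0 & hs$values <= 1, na.rm = TRUE))
  expect_true(is.na(hs$values[3, 3]))
  # direct prediction agrees
  nd <- data.frame(signal = vals[5, 5], noise1 = 0)
  direct <- predict(m$model, data = nd[, m$variables, drop = FALSE],
                    num.threads = 1)$predictions[, "presence"]
  expect_equal(hs$values[5, 5], unname(direct))
  # strong signal separates the extremes
  expect_gt(hs$values[12, 12], hs$values[1, 1])
  # a missing covariate layer is an error
  stack$layers$signal <- NULL
  if ("signal" %in% m$variables)
    expect_error(ensemble_predict(m, stack), "missing")
})

test_that("split-sample AUC is near-perfect on separable data and
           near 0.5 on permuted labels", {
  d <- toy_dataset(n = 200, seed = 10)
  d$signal <- ifelse(d$y == "presence", 1, 0) + rnorm(200, 0, 0.05)
  ens <- structure(list(models = list(
    structure(list(model = NULL, variables = "signal", training = d),
              class = "mir_model"))), class = "rf_ensemble")
  auc <- evaluate_auc(ens, split = 0.7, reps = 3, seed = 11,
                      num_trees = 100)
  expect_gt(auc$mean, 0.95)
  expect_equal(dim(auc$per_model), c(3, 1))
  set.seed(12)
  d2 <- d; d2$y <- sample(d2$y)
  ens2 <- structure(list(models = list(
    structure(list(model = NULL, variables = c("signal", "noise1"),
                   training = d2), class = "mir_model"))),
    class = "rf_ensemble")
  auc2 <- evaluate_auc(ens2, split = 0.7, reps = 5, seed = 13,
                       num_trees = 100)
  expect_gt(auc2$mean, 0.35)
  expect_lt(auc2$mean, 0.65)
})

test_that("partial dependence is flat for an unused variable and errors
           for a variable outside every subset", {
  d <- toy_dataset(n = 160, seed = 14, extra_constant = TRUE)
  m <- mir_model_selection(d, c("signal", "flatvar"), num_trees = 200,
                           seed = 15)
  expect_error(partial_dependence(m, "absent_var"), "subset")
  if ("flatvar" %in% m$variables) {
    pd <- partial_dependence(m, "flatvar", grid_points = 10)
    expect_lt(diff(range(pd$mean)), 1e-9)
  }
  pd2 <- partial_dependence(m, "signal", grid_points = 15)
  expect_equal(nrow(pd2), 15)
  expect_true(all(pd2$lower <= pd2$mean & pd2$mean <= pd2$upper))
  # monotone generating effect: fitted curve increases overall
  expect_gt(pd2$mean[15], pd2$mean[1])
})
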