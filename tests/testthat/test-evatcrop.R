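fast_cfg <- function(combinations, seed = 1) {
  experiment_config(combinations = combinations, hidden_grid = 4,
                    activations = "tanh", seed = seed, max_iterations = 150)
}

fit_small <- function(n = 240, combinations = c("C1", "C2"), seed = 1) {
  s <- generate_synthetic_weather(n, terai_site(), seed = seed)
  sp <- chronological_split(s, 0.7)
  y <- reference_et0(sp$train)
  list(series = s, split = sp, targets = y,
       model = fit_evatcrop(sp$train, y, fast_cfg(combinations, seed)))
}

test_that("fitted model structure matches the rule-group dimension law", {
  f <- fit_small(200, "C1")
  expect_s3_class(f$model, "evatcrop_model")
  expect_named(f$model$heads, "C1")
  expect_equal(f$model$heads$C1$spec$input_dim, 9L)

  f8 <- fit_small(200, names(standard_combinations()))
  dims <- vapply(f8$model$heads, function(h) h$spec$input_dim, integer(1))
  expect_identical(unname(dims), c(9L, 27L, 27L, 27L, 81L, 81L, 81L, 243L))
  for (id in names(f8$model$heads)) {
    expect_equal(dims[[id]], enumerate_rule_group(id)$size)
  }
})

test_that("combinations lacking variables are skipped with a diagnostic", {
  s <- generate_synthetic_weather(120, terai_site(), seed = 2)
  s_nows <- weather_series(as.data.frame(s)[, c("date", "tmin", "tmax", "rh",
                                                "sr")], terai_site())
  y <- 0.1 * s_nows$tmax  # any aligned target works structurally
  expect_message(m <- fit_evatcrop(s_nows, y, fast_cfg(c("C1", "C2", "C3"))),
                 "skipping C2")
  expect_named(m$heads, c("C1", "C3"))
})

test_that("prediction composes transform and head, out-of-range stays finite", {
  f <- fit_small(240, "C1")
  test_set <- f$split$test

  # record at all partition midpoints equals the head's response to the
  # one-hot all-medium interim vector
  parts <- f$model$partitions
  mid <- data.frame(tmin = parts$tmin$m, tmax = parts$tmax$m)
  onehot <- interim_vectors(mid, "C1", parts)
  expect_equal(sum(onehot == 1), 1)
  expect_equal(predict(f$model, mid, "C1"),
               predict_head(f$model$heads$C1, onehot))

  # far beyond the training maximum: clamped memberships, finite output
  hot <- data.frame(tmin = parts$tmin$h + 15, tmax = parts$tmax$h + 20)
  expect_true(is.finite(predict(f$model, hot, "C1")))

  # batch prediction equals per-record prediction concatenated
  batch <- predict(f$model, test_set, "C1")
  loop <- vapply(seq_len(nrow(test_set)), function(i) {
    predict(f$model, as.data.frame(test_set)[i, , drop = FALSE], "C1")
  }, numeric(1))
  expect_equal(batch, loop)

  expect_error(predict(f$model, test_set, "C5"), "no head")
})

test_that("run_experiment returns one row per model, combination and phase", {
  s <- generate_synthetic_weather(260, terai_site(), seed = 3)
  cfg <- experiment_config(combinations = "C1", hidden_grid = 4,
                           activations = "tanh", seed = 3,
                           max_iterations = 150, baselines = TRUE,
                           tree_depth_grid = c(3, 6), tree_cp_grid = c(0, 0.01))
  res <- run_experiment(s, cfg)
  tab <- res$table
  expect_setequal(unique(tab$model), c("EvatCrop", "DT", "ANN"))
  expect_equal(nrow(tab), 3 * 2)  # 3 models x 1 combination x 2 phases
  expect_true(all(c("r2", "d", "rmse", "rmsre", "ag", "ae") %in% names(tab)))
  expect_true(all(tab$d >= 0 & tab$d <= 1))
  expect_equal(tab$ag, (tab$r2 + tab$d) / 2)

  # internal consistency: re-predicting the training part reproduces the
  # training-phase row
  sp <- chronological_split(s, 0.7)
  y_tr <- reference_et0(sp$train)
  m <- metric_report(y_tr, predict(res$model, sp$train, "C1"))
  row <- tab[tab$model == "EvatCrop" & tab$phase == "train", ]
  expect_equal(row$r2, m$r2)
  expect_equal(row$rmse, m$rmse)
})

test_that("experiments are deterministic and blind to the test block", {
  s <- generate_synthetic_weather(260, terai_site(), seed = 4)
  cfg <- fast_cfg("C2", seed = 4)
  r1 <- run_experiment(s, cfg)
  r2 <- run_experiment(s, cfg)
  expect_identical(r1$table, r2$table)
  expect_identical(r1$model$heads, r2$model$heads)

  # mutate only the test block: the fitted model must not change
  sp <- chronological_split(s, 0.7)
  y_tr <- reference_et0(sp$train)
  m_ref <- fit_evatcrop(sp$train, y_tr, cfg)
  mutated <- as.data.frame(s)
  idx <- (nrow(sp$train) + 1):nrow(s)
  mutated$tmax[idx] <- mutated$tmax[idx] + 5
  mutated$tmin[idx] <- mutated$tmin[idx] + 5
  sp2 <- chronological_split(weather_series(mutated, terai_site()), 0.7)
  m_mut <- fit_evatcrop(sp2$train, reference_et0(sp2$train), cfg)
  expect_identical(m_ref$partitions, m_mut$partitions)
  expect_identical(m_ref$heads, m_mut$heads)
})

test_that("decision-tree baseline recovers a single-split step function", {
  s <- generate_synthetic_weather(120, terai_site(), seed = 6)
  y_step <- ifelse(s$tmax > median(s$tmax), 5, 2)
  cfg <- experiment_config(combinations = "C1", hidden_grid = 2,
                           activations = "identity", seed = 6,
                           max_iterations = 50,
                           tree_depth_grid = 2, tree_cp_grid = 0.01)
  b <- fit_baselines(s, y_step, cfg)
  expect_named(b, c("dt", "ann"))
  pred <- evatcrop:::predict_baseline_dt(b$dt$C1, s)
  expect_equal(pred, y_step, tolerance = 1e-9)
  expect_equal(b$dt$C1$depth, 2L)  # depth grid of one value is selected
})

test_that("save/load round trip preserves predictions bitwise and checks tampering", {
  f <- fit_small(200, c("C1", "C2"), seed = 7)
  path <- tempfile(fileext = ".json")
  save_model(f$model, path)
  back <- load_model(path)
  expect_identical(names(back$heads), names(f$model$heads))
  probe <- generate_synthetic_weather(100, terai_site(), seed = 8)
  for (id in names(f$model$heads)) {
    expect_identical(predict(f$model, probe, id), predict(back, probe, id))
  }
  # tamper with the stored architecture (still valid JSON)
  txt <- readLines(path)
  expect_true(any(grepl('"hidden_units": 4', txt)))
  txt <- sub('"hidden_units": 4', '"hidden_units": 5', txt)
  tampered <- tempfile(fileext = ".json")
  writeLines(txt, tampered)
  expect_error(load_model(tampered), "checksum")
  expect_error(load_model(tempfile()), "not found")

  # saving twice under the same seed yields byte-identical bundles
  path2 <- tempfile(fileext = ".json")
  refit <- fit_small(200, c("C1", "C2"), seed = 7)
  save_model(refit$model, path2)
  expect_identical(readLines(path), readLines(path2))
})
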