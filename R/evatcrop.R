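# The composed estimator: shared per-site fuzzy partitions + one neural head
# per input combination, plus the experiment runner and baseline models.

MODEL_FORMAT_VERSION <- "1"

#' Experiment configuration
#'
#' Bundles every tunable of the eight-combination experiment. Defaults
#' mirror the evaluation protocol: 70/30 chronological split, hidden sizes
#' 2..16 under five-fold cross-validated grid search, L-BFGS training.
#' Scaled-down grids (a subset of hidden sizes / activations) give the same
#' pipeline at a fraction of the cost and are the intended way to run quick
#' experiments.
#'
#' @param train_fraction Chronological training share in (0, 1); default 0.7.
#' @param combinations Character vector of combination ids to fit
#'   (default all of C1..C8).
#' @param hidden_grid Hidden sizes for the head grid search (default 2:16).
#' @param activations Activations for the grid search.
#' @param cv_folds Cross-validation folds for the grids (default 5).
#' @param seed Master seed; per-combination head seeds are derived from it.
#' @param max_iterations,tolerance Passed to [training_config()].
#' @param baselines If `TRUE`, [run_experiment()] also fits and scores the
#'   decision-tree and raw-input neural-network baselines.
#' @param tree_depth_grid Max-depth grid of the tree baseline (default 2:16).
#' @param tree_cp_grid Cost-complexity pruning grid in [0, 1].
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(train_fraction = 0.7,
                              combinations = names(standard_combinations()),
                              hidden_grid = 2:16,
                              activations = c("tanh", "relu", "logistic",
                                              "identity"),
                              cv_folds = 5L, seed = 1L,
                              max_iterations = 400L, tolerance = 1e-8,
                              baselines = FALSE,
                              tree_depth_grid = 2:16,
                              tree_cp_grid = c(0, 1e-4, 1e-3, 1e-2, 1e-1, 1)) {
  stopifnot(train_fraction > 0, train_fraction < 1,
            all(combinations %in% names(standard_combinations())),
            all(tree_cp_grid >= 0 & tree_cp_grid <= 1))
  structure(list(train_fraction = train_fraction,
                 combinations = combinations,
                 hidden_grid = as.integer(hidden_grid),
                 activations = activations,
                 cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed),
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance,
                 baselines = isTRUE(baselines),
                 tree_depth_grid = as.integer(tree_depth_grid),
                 tree_cp_grid = tree_cp_grid),
            class = "experiment_config")
}

# distinct deterministic sub-seed per combination, kept under 2^31
derive_seed <- function(seed, idx) {
  (as.integer(seed) %% 1000003L) * 1000L + 7L * idx
}

#' Fit the quasi-fuzzy neural estimator
#'
#' Fits one shared triangular partition per variable on the training series
#' (a single fuzzification of each variable, shared by all combinations),
#' then, per requested combination, transforms the records to interim
#' vectors, grid-searches the head architecture by cross-validation and
#' trains the winning head on the full training set. Combinations whose
#' variables are absent from the series are skipped with a message.
#'
#' @param train Training [weather_series()].
#' @param targets Reference ET0 (mm per day), aligned to `train` records;
#'   usually [reference_et0()] output.
#' @param cfg An [experiment_config()].
#' @return An object of class `evatcrop_model`: `partitions`, `heads`
#'   (named by combination id), `site` and `provenance`.
#' @export
fit_evatcrop <- function(train, targets, cfg = experiment_config()) {
  stopifnot(inherits(train, "weather_series"),
            inherits(cfg, "experiment_config"))
  if (length(targets) != nrow(train)) {
    stop("targets not aligned to training records", call. = FALSE)
  }
  combos <- standard_combinations()[cfg$combinations]
  usable <- vapply(combos, function(v) all(v %in% names(train)), logical(1))
  for (id in names(combos)[!usable]) {
    message("skipping ", id, ": variable(s) ",
            paste(setdiff(combos[[id]], names(train)), collapse = ", "),
            " absent from training data")
  }
  combos <- combos[usable]
  if (!length(combos)) stop("no fittable combination", call. = FALSE)

  vars <- unique(unlist(combos))
  partitions <- fit_partitions(train, vars)

  heads <- vector("list", length(combos))
  names(heads) <- names(combos)
  for (i in seq_along(combos)) {
    id <- names(combos)[i]
    X <- interim_vectors(train, id, partitions)
    tc <- training_config(max_iterations = cfg$max_iterations,
                          tolerance = cfg$tolerance,
                          seed = derive_seed(cfg$seed, i))
    spec <- if (length(cfg$hidden_grid) == 1L &&
                length(cfg$activations) == 1L) {
      head_spec(ncol(X), cfg$hidden_grid, cfg$activations)
    } else {
      grid_search_head(X, targets, cfg$hidden_grid, cfg$activations,
                       cfg = tc, folds = cfg$cv_folds)
    }
    heads[[id]] <- fit_head(X, targets, spec, tc)
  }

  structure(list(
    partitions = partitions,
    heads = heads,
    site = attr(train, "site"),
    provenance = list(seed = cfg$seed,
                      n_train = nrow(train),
                      train_window = range(train$date),
                      rule_counts = rule_group_sizes()[names(heads)],
                      version = MODEL_FORMAT_VERSION)
  ), class = "evatcrop_model")
}

#' @export
print.evatcrop_model <- function(x, ...) {
  cat(sprintf("<evatcrop_model> site %s, %d head(s): %s\n",
              x$site$name, length(x$heads),
              paste(names(x$heads), collapse = ", ")))
  cat(sprintf("trained on %d records (%s to %s), seed %d\n",
              x$provenance$n_train,
              format(x$provenance$train_window[1]),
              format(x$provenance$train_window[2]),
              x$provenance$seed))
  invisible(x)
}

#' Predict daily ET0 with a fitted estimator
#'
#' Selects the head of the requested combination, quasi-fuzzy transforms the
#' records with the model's training-time partitions and runs the forward
#' pass. Values outside the training data space are handled by the clamped
#' memberships, never rejected.
#'
#' @param object An `evatcrop_model`.
#' @param newdata A [weather_series()] (or data frame) carrying the
#'   combination's variables.
#' @param combination Combination id, e.g. `"C2"`.
#' @param ... Unused.
#' @return Numeric vector of ET0 estimates, mm per day.
#' @export
predict.evatcrop_model <- function(object, newdata, combination, ...) {
  if (!combination %in% names(object$heads)) {
    stop("model has no head for combination ", combination, call. = FALSE)
  }
  X <- interim_vectors(newdata, combination, object$partitions)
  predict_head(object$heads[[combination]], X)
}

standardizer <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}

apply_standardizer <- function(X, st) {
  sweep(sweep(X, 2, st$mu, "-"), 2, st$sd, "/")
}

#' Fit the baseline models
#'
#' Per combination: (i) a CART regression tree (via \pkg{rpart}) on the raw
#' variables, grid-searched over maximum depth and minimal cost-complexity
#' pruning strength by k-fold cross-validation; (ii) a one-hidden-layer
#' network on the standardised raw variables, grid-searched over hidden
#' sizes. Both consume raw inputs, not interim vectors — they are the
#' conventional competitors of the quasi-fuzzy pipeline.
#'
#' @inheritParams fit_evatcrop
#' @return List with elements `dt` and `ann`, each a named-by-combination
#'   list of fitted baseline objects.
#' @export
fit_baselines <- function(train, targets, cfg = experiment_config()) {
  stopifnot(inherits(cfg, "experiment_config"))
  combos <- standard_combinations()[cfg$combinations]
  combos <- combos[vapply(combos, function(v) all(v %in% names(train)),
                          logical(1))]
  dt <- ann <- vector("list", length(combos))
  names(dt) <- names(ann) <- names(combos)
  n <- nrow(train)
  fold <- cv_fold_ids(n, cfg$cv_folds)

  for (i in seq_along(combos)) {
    id <- names(combos)[i]
    Xraw <- as.matrix(as.data.frame(train)[, combos[[id]], drop = FALSE])
    df <- data.frame(Xraw, y = targets)

    # --- decision tree: depth x cp grid, k-fold CV --------------------------
    grid <- expand.grid(depth = cfg$tree_depth_grid, cp = cfg$tree_cp_grid)
    grid$cv_mse <- vapply(seq_len(nrow(grid)), function(g) {
      mean(vapply(seq_len(cfg$cv_folds), function(f) {
        tr <- fold != f
        fit <- rpart::rpart(y ~ ., data = df[tr, , drop = FALSE],
                            method = "anova",
                            control = rpart::rpart.control(
                              maxdepth = grid$depth[g], cp = grid$cp[g],
                              xval = 0))
        mean((stats::predict(fit, df[!tr, , drop = FALSE]) - targets[!tr])^2)
      }, numeric(1)))
    }, numeric(1))
    best <- order(grid$cv_mse, grid$depth, grid$cp)[1L]
    dt[[id]] <- list(
      fit = rpart::rpart(y ~ ., data = df, method = "anova",
                         control = rpart::rpart.control(
                           maxdepth = grid$depth[best], cp = grid$cp[best],
                           xval = 0)),
      depth = grid$depth[best], cp = grid$cp[best],
      variables = combos[[id]])

    # --- raw-input neural network ------------------------------------------
    st <- standardizer(Xraw)
    Xs <- apply_standardizer(Xraw, st)
    tc <- training_config(max_iterations = cfg$max_iterations,
                          tolerance = cfg$tolerance,
                          seed = derive_seed(cfg$seed, 100L + i))
    spec <- if (length(cfg$hidden_grid) == 1L &&
                length(cfg$activations) == 1L) {
      head_spec(ncol(Xs), cfg$hidden_grid, cfg$activations)
    } else {
      grid_search_head(Xs, targets, cfg$hidden_grid, cfg$activations,
                       cfg = tc, folds = cfg$cv_folds)
    }
    ann[[id]] <- list(head = fit_head(Xs, targets, spec, tc),
                      standardizer = st, variables = combos[[id]])
  }
  list(dt = dt, ann = ann)
}

predict_baseline_dt <- function(b, records) {
  df <- as.data.frame(records)[, b$variables, drop = FALSE]
  unname(stats::predict(b$fit, df))
}

predict_baseline_ann <- function(b, records) {
  X <- as.matrix(as.data.frame(records)[, b$variables, drop = FALSE])
  predict_head(b$head, apply_standardizer(X, b$standardizer))
}

#' Run the eight-combination experiment
#'
#' Computes FAO-56 reference targets for the whole series, splits it
#' chronologically, fits the quasi-fuzzy neural estimator (and, if enabled,
#' the baselines) on the training part, and scores every model /
#' combination / phase with the full metric set. Fully deterministic under
#' a fixed configuration.
#'
#' @param series A [weather_series()] with all five variables.
#' @param cfg An [experiment_config()].
#' @return List with elements `table` (data frame: `model`, `combination`,
#'   `phase`, `r2`, `d`, `rmse`, `rmsre`, `ag`, `ae`), `model` (the fitted
#'   `evatcrop_model`) and `baselines` (or `NULL`).
#' @export
run_experiment <- function(series, cfg = experiment_config()) {
  stopifnot(inherits(series, "weather_series"))
  targets_all <- reference_et0(series)
  parts <- chronological_split(series, cfg$train_fraction)
  n_train <- nrow(parts$train)
  y <- list(train = targets_all[seq_len(n_train)],
            test = targets_all[-seq_len(n_train)])

  model <- fit_evatcrop(parts$train, y$train, cfg)
  baselines <- if (cfg$baselines) fit_baselines(parts$train, y$train, cfg)

  rows <- list()
  add_row <- function(model_name, id, phase, pred) {
    m <- metric_report(y[[phase]], pred)
    rows[[length(rows) + 1L]] <<- data.frame(
      model = model_name, combination = id, phase = phase,
      r2 = m$r2, d = m$d, rmse = m$rmse, rmsre = m$rmsre,
      ag = m$ag, ae = m$ae, stringsAsFactors = FALSE)
  }
  for (id in names(model$heads)) {
    for (phase in c("train", "test")) {
      add_row("EvatCrop", id, phase,
              predict(model, parts[[phase]], id))
    }
  }
  if (!is.null(baselines)) {
    for (id in names(baselines$dt)) {
      for (phase in c("train", "test")) {
        add_row("DT", id, phase,
                predict_baseline_dt(baselines$dt[[id]], parts[[phase]]))
        add_row("ANN", id, phase,
                predict_baseline_ann(baselines$ann[[id]], parts[[phase]]))
      }
    }
  }
  list(table = do.call(rbind, rows), model = model, baselines = baselines)
}

# ---- model persistence -----------------------------------------------------

model_payload <- function(model) {
  list(
    format = "evatcrop-model",
    version = MODEL_FORMAT_VERSION,
    site = unclass(model$site),
    partitions = lapply(model$partitions, unclass),
    heads = lapply(model$heads, function(h) list(
      input_dim = h$spec$input_dim,
      hidden_units = h$spec$hidden_units,
      activation = h$spec$activation,
      W1 = as.numeric(h$weights$W1),
      b1 = h$weights$b1, W2 = h$weights$W2, b2 = h$weights$b2,
      meta = h$meta
    )),
    provenance = list(
      seed = model$provenance$seed,
      n_train = model$provenance$n_train,
      train_window = format(model$provenance$train_window, "%Y-%m-%d"),
      rule_counts = as.list(model$provenance$rule_counts),
      version = model$provenance$version
    )
  )
}

payload_json <- function(payload) {
  # 17 significant digits: doubles survive the write/read round trip exactly
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
}

md5_of_string <- function(s) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(s, tmp)
  unname(tools::md5sum(tmp))
}

#' Save a fitted model bundle
#'
#' Writes a versioned plain-text JSON document holding the partitions, the
#' head weights at full double precision and the provenance, plus an md5
#' checksum of the payload. A save/load round trip reproduces predictions
#' bitwise.
#'
#' @param model An `evatcrop_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "evatcrop_model"))
  # canonical form: encode, parse, re-encode — identical to what load_model
  # recomputes from the document, so the checksum verifies byte-for-byte
  parsed <- jsonlite::parse_json(payload_json(model_payload(model)))
  doc <- jsonlite::toJSON(list(checksum = md5_of_string(payload_json(parsed)),
                               payload = parsed),
                          auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  writeLines(doc, path)
  invisible(path)
}

#' Load a model bundle
#'
#' @param path Path written by [save_model()].
#' @return An `evatcrop_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$payload) || is.null(doc$checksum)) {
    stop("not a model bundle", call. = FALSE)
  }
  payload <- doc$payload
  if (!identical(payload$format, "evatcrop-model")) {
    stop("not a model bundle", call. = FALSE)
  }
  if (!identical(payload$version, MODEL_FORMAT_VERSION)) {
    stop("unsupported model format version: ", payload$version,
         call. = FALSE)
  }
  recoded <- payload_json(payload)
  if (!identical(md5_of_string(recoded), doc$checksum)) {
    stop("checksum mismatch: model bundle corrupted or tampered",
         call. = FALSE)
  }
  site <- site_meta(payload$site$name, payload$site$latitude,
                    payload$site$elevation)
  partitions <- lapply(payload$partitions, function(p) {
    fuzzy_partition(p$variable, p$l, p$m, p$h)
  })
  heads <- lapply(payload$heads, function(h) {
    d <- h$input_dim; hu <- h$hidden_units
    structure(list(
      spec = head_spec(d, hu, h$activation),
      weights = list(
        W1 = matrix(unlist(h$W1), d, hu),
        b1 = unlist(h$b1), W2 = unlist(h$W2), b2 = unlist(h$b2)),
      meta = h$meta
    ), class = "trained_head")
  })
  structure(list(
    partitions = partitions,
    heads = heads,
    site = site,
    provenance = list(
      seed = payload$provenance$seed,
      n_train = payload$provenance$n_train,
      train_window = as.Date(unlist(payload$provenance$train_window)),
      rule_counts = unlist(payload$provenance$rule_counts),
      version = payload$provenance$version)
  ), class = "evatcrop_model")
}
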