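RESP_LEVELS <- c("absence", "presence")

# single entry point for every forest fit: 500 trees by default, one
# thread, explicit seed, so ensembles are reproducible run-to-run
fit_forest <- function(data, variables, num_trees = 500, seed = 1,
                       probability = FALSE, importance = "none") {
  ranger::ranger(
    x = data[, variables, drop = FALSE], y = data$y,
    num.trees = num_trees, probability = probability,
    importance = importance, seed = seed, num.threads = 1
  )
}

#' Assemble balanced presence / pseudo-absence model datasets
#'
#' One data.frame per pseudo-absence set: all presences plus that set's
#' equally many pseudo-absences (the equal-sampling contract), with the
#' covariates extracted at the point locations and a response factor `y`
#' (`"absence"` / `"presence"`).
#'
#' @param presences data.frame `x`, `y` of (thinned) presences.
#' @param absence_sets list of pseudo-absence data.frames from
#'   [generate_pseudo_absences()].
#' @param stack a `covariate_stack`.
#' @param layers covariate layer names to extract (default all).
#' @return list of data.frames.
#' @export
make_model_datasets <- function(presences, absence_sets, stack,
                                layers = names(stack$layers)) {
  lapply(absence_sets, function(ab) {
    stopifnot(nrow(ab) == nrow(presences))
    pts <- rbind(presences[, c("x", "y")], ab[, c("x", "y")])
    d <- extract_covariates(stack, pts, layers)
    d$y <- factor(rep(c("presence", "absence"),
                      c(nrow(presences), nrow(ab))),
                  levels = RESP_LEVELS)
    if (anyNA(d)) stop("covariates contain nodata at some points")
    d
  })
}

#' Univariate random-forest scale optimization
#'
#' For every variable and candidate scale, fits a univariate forest on each
#' presence / pseudo-absence dataset and records its out-of-bag (OOB)
#' misclassification error. The best scale per dataset is the one with the
#' lowest OOB error (ties go to the finest scale); the final chosen scale
#' per variable is the modal best scale across datasets (ties again to the
#' finest scale).
#'
#' @param datasets list of model data.frames from [make_model_datasets()].
#' @param variables base variable names (e.g. `"ELE"`).
#' @param scales candidate scales in meters.
#' @param num_trees trees per forest (default 500).
#' @param seed integer seed.
#' @return a `scale_profile`: list with `oob` (variable x scale x dataset
#'   array), `best` (variable x dataset matrix of best scales), `chosen`
#'   (named vector), `frequency` (datasets agreeing with the chosen
#'   scale).
#' @export
univariate_scale_selection <- function(datasets, variables, scales,
                                       num_trees = 500, seed = 1) {
  scales <- sort(scales)
  nd <- length(datasets)
  oob <- array(NA_real_,
               dim = c(length(variables), length(scales), nd),
               dimnames = list(variables, scales, NULL))
  for (k in seq_len(nd)) {
    d <- datasets[[k]]
    for (i in seq_along(variables)) {
      for (j in seq_along(scales)) {
        col <- paste0(variables[i], "_", scales[j])
        if (!col %in% names(d))
          stop(sprintf("variable %s missing at scale %d", variables[i],
                       scales[j]))
        fit <- fit_forest(d, col, num_trees,
                          seed = seed + 7919L * i + 101L * j + k)
        oob[i, j, k] <- fit$prediction.error
      }
    }
  }
  best <- apply(oob, c(1, 3), function(e) scales[which.min(e)])
  chosen <- apply(best, 1, function(b) {
    tab <- table(b)
    cand <- as.numeric(names(tab)[tab == max(tab)])
    min(cand)  # modal scale, ties to the finest
  })
  freq <- vapply(seq_along(variables),
                 function(i) sum(best[i, ] == chosen[i]), 0L)
  names(freq) <- variables
  structure(list(oob = oob, best = best, chosen = chosen,
                 frequency = freq, scales = scales, variables = variables),
            class = "scale_profile")
}

#' @export
print.scale_profile <- function(x, ...) {
  cat("Univariate scale optimization\n")
  df <- data.frame(variable = x$variables,
                   chosen_scale_m = x$chosen,
                   datasets_agreeing = x$frequency,
                   row.names = NULL)
  print(df)
  invisible(x)
}

#' Pairwise-correlation collinearity screen
#'
#' Iteratively removes one member of every layer pair whose absolute
#' Pearson correlation (over valid cells) exceeds `threshold`. When a
#' priority vector is given (typically mean univariate OOB error), the
#' less predictive member (higher value) is dropped; otherwise the member
#' with the higher mean absolute correlation with all remaining layers.
#' Constant layers have no defined correlation and are retained with a
#' warning.
#'
#' @param stack a `covariate_stack` (or a data.frame of layer columns).
#' @param layers layer names to screen.
#' @param threshold absolute correlation above which a pair is collinear
#'   (default 0.85).
#' @param priority optional named numeric; higher = dropped first.
#' @return list with `retained` (layer names) and `removed` (data.frame
#'   `removed`, `kept`, `r`).
#' @export
collinearity_screen <- function(stack, layers = NULL, threshold = 0.85,
                                priority = NULL) {
  m <- if (is.data.frame(stack)) {
    as.matrix(stack[, layers %||% names(stack), drop = FALSE])
  } else {
    layers <- layers %||% names(stack$layers)
    vapply(stack$layers[layers], function(g) as.vector(g$values),
           numeric(length(stack$layers[[layers[1]]]$values)))
  }
  if (ncol(m) < 2) stop("need at least two layers to screen")
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  if (any(sds == 0, na.rm = TRUE))
    warning(sprintf("constant layer(s) retained (correlation undefined): %s",
                    paste(colnames(m)[sds == 0], collapse = ", ")))
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  r[is.na(r)] <- 0
  diag(r) <- 0
  keep <- colnames(m)
  removed <- data.frame(removed = character(0), kept = character(0),
                        r = numeric(0))
  repeat {
    sub <- abs(r[keep, keep, drop = FALSE])
    mx <- max(sub)
    if (mx <= threshold) break
    ij <- which(sub == mx, arr.ind = TRUE)[1, ]
    a <- keep[ij[1]]; b <- keep[ij[2]]
    drop_a <- if (!is.null(priority) && all(c(a, b) %in% names(priority))) {
      priority[a] >= priority[b]
    } else {
      mean(sub[a, ]) >= mean(sub[b, ])
    }
    gone <- if (drop_a) a else b
    kept <- if (drop_a) b else a
    removed <- rbind(removed,
                     data.frame(removed = gone, kept = kept,
                                r = r[gone, kept]))
    keep <- setdiff(keep, gone)
    if (length(keep) < 2) break
  }
  list(retained = keep, removed = removed)
}

#' Model Improvement Ratio thresholds and variable subsets
#'
#' MIR standardizes permutation importances to \[0, 1\] by dividing by the
#' maximum importance. Candidate subsets retain every variable with MIR at
#' or above thresholds 0, 0.1, ..., 0.9, always computed from the original
#' model's importances.
#'
#' @param importance named numeric vector of permutation importances.
#' @param step threshold increment (default 0.1).
#' @return list with `mir` (named vector) and `subsets` (list keyed by
#'   threshold).
#' @export
mir_subsets <- function(importance, step = 0.1) {
  if (max(importance) <= 0) stop("all importances are <= 0; MIR undefined")
  # negative permutation importances carry no evidence: clamp to 0 so the
  # zero threshold always reproduces the full model
  mir <- pmax(importance, 0) / max(importance)
  thresholds <- seq(0, 1 - step, by = step)
  subsets <- lapply(thresholds, function(t) names(mir)[mir >= t])
  names(subsets) <- format(thresholds)
  list(mir = mir, subsets = subsets)
}

#' MIR-guided model selection for one dataset
#'
#' Fits the full forest with permutation importance, forms MIR-threshold
#' subsets ([mir_subsets()]), refits a forest on each non-empty subset, and
#' keeps the subset with the lowest OOB error (ties go to the smallest
#' subset). The returned model is a probability forest refit on the
#' selected variables; per-cell predictions are the fraction of trees
#' voting presence.
#'
#' @param data one model data.frame (response `y` plus covariates).
#' @param variables candidate variable (column) names.
#' @param num_trees trees per forest (default 500).
#' @param seed integer seed.
#' @param step MIR threshold increment.
#' @return a `mir_model`: list with `model` (ranger probability forest),
#'   `variables` (selected subset), `mir` (data.frame), `oob_by_threshold`,
#'   `oob`, `training` (the data).
#' @export
mir_model_selection <- function(data, variables, num_trees = 500, seed = 1,
                                step = 0.1) {
  full <- fit_forest(data, variables, num_trees, seed = seed,
                     importance = "permutation")
  imp <- full$variable.importance
  ms <- mir_subsets(imp, step)
  cand <- ms$subsets[!duplicated(ms$subsets)]
  cand <- cand[vapply(cand, length, 0L) > 0]
  oobs <- vapply(seq_along(cand), function(i) {
    fit_forest(data, cand[[i]], num_trees, seed = seed + i)$prediction.error
  }, 0)
  sizes <- vapply(cand, length, 0L)
  best <- order(oobs, sizes)[1]  # lowest OOB, ties to the smaller subset
  sel <- cand[[best]]
  model <- fit_forest(data, sel, num_trees, seed = seed,
                      probability = TRUE)
  structure(list(
    model = model, variables = sel,
    mir = data.frame(variable = names(imp), importance = unname(imp),
                     mir = unname(ms$mir)),
    oob_by_threshold = data.frame(threshold = names(cand),
                                  n_vars = sizes, oob = oobs),
    oob = oobs[best], training = data
  ), class = "mir_model")
}

#' Fit the equal-sampling random-forest ensemble
#'
#' Runs [mir_model_selection()] on each of the balanced presence /
#' pseudo-absence datasets (conventionally ten) and collects the fitted
#' probability forests.
#'
#' @param datasets list of model data.frames.
#' @param variables candidate variable names (post-screening).
#' @param num_trees trees per forest.
#' @param seed integer seed.
#' @param step MIR threshold increment.
#' @return an `rf_ensemble`: list of `mir_model`s plus metadata.
#' @export
fit_rf_ensemble <- function(datasets, variables, num_trees = 500, seed = 1,
                            step = 0.1) {
  models <- lapply(seq_along(datasets), function(i) {
    mir_model_selection(datasets[[i]], variables, num_trees,
                        seed = seed + 1000L * i, step = step)
  })
  structure(list(models = models, variables = variables,
                 num_trees = num_trees),
            class = "rf_ensemble")
}

#' @export
print.rf_ensemble <- function(x, ...) {
  cat(sprintf("rf_ensemble: %d models, %d trees each\n",
              length(x$models), x$num_trees))
  for (i in seq_along(x$models))
    cat(sprintf("  model %d: OOB %.4f, %d variables (%s)\n", i,
                x$models[[i]]$oob, length(x$models[[i]]$variables),
                paste(x$models[[i]]$variables, collapse = ", ")))
  invisible(x)
}

#' Predict the habitat suitability surface
#'
#' Per-cell habitat suitability HS = the mean over ensemble members of the
#' fraction of trees voting presence, in \[0, 1\]. Nodata in any required
#' covariate propagates to the output.
#'
#' @param ensemble an `rf_ensemble` (or a single `mir_model`).
#' @param stack a `covariate_stack` holding every selected variable.
#' @return suitability [raster_grid()].
#' @export
ensemble_predict <- function(ensemble, stack) {
  models <- if (inherits(ensemble, "mir_model")) list(ensemble)
    else ensemble$models
  need <- unique(unlist(lapply(models, `[[`, "variables")))
  missing <- setdiff(need, names(stack$layers))
  if (length(missing) > 0)
    stop(sprintf("covariate layer(s) missing from stack: %s",
                 paste(missing, collapse = ", ")))
  tmpl <- stack$layers[[need[1]]]
  newdata <- as.data.frame(lapply(stack$layers[need],
                                  function(g) as.vector(g$values)),
                           check.names = FALSE)
  valid <- stats::complete.cases(newdata)
  hs <- rep(NA_real_, nrow(newdata))
  if (any(valid)) {
    preds <- vapply(models, function(m) {
      p <- stats::predict(m$model,
                          data = newdata[valid, m$variables, drop = FALSE],
                          num.threads = 1)$predictions
      p[, "presence"]
    }, numeric(sum(valid)))
    hs[valid] <- rowMeans(preds)
  }
  raster_grid(matrix(hs, grid_nrow(tmpl), grid_ncol(tmpl)),
              xmin = tmpl$xmin, ymin = tmpl$ymin,
              cell_size = tmpl$cell_size, crs = tmpl$crs)
}

#' Rank-based AUC
#'
#' The probability that a randomly chosen presence receives a higher score
#' than a randomly chosen absence (ties count one half), computed from
#' midranks.
#'
#' @param scores numeric scores.
#' @param positive logical, `TRUE` for presences.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, positive) {
  np <- sum(positive); nn <- sum(!positive)
  if (np == 0 || nn == 0) stop("AUC needs both classes")
  r <- rank(scores)
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

stratified_split <- function(y, split) {
  train <- logical(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    n_tr <- round(split * length(idx))
    train[sample(idx, n_tr)] <- TRUE
  }
  train
}

#' Split-sample AUC evaluation of the ensemble
#'
#' For each repetition, every ensemble member's training data are split
#' into a training (70% by default) and validation (30%) part, stratified
#' by class; the member is refit on the training part (using its selected
#' variables) and scored on the validation part with the rank-based AUC. A
#' repetition's AUC is the mean over members; the mean and standard
#' deviation over repetitions are returned. Degenerate single-class
#' validation folds are redrawn and logged.
#'
#' @param ensemble an `rf_ensemble`.
#' @param split training fraction in (0, 1).
#' @param reps number of repetitions (default 10).
#' @param seed integer seed.
#' @param num_trees trees per refit forest.
#' @return list with `mean`, `sd`, `per_rep`, `per_model` (reps x models
#'   matrix), `redraws`.
#' @export
evaluate_auc <- function(ensemble, split = 0.7, reps = 10, seed = 1,
                         num_trees = 500) {
  stopifnot(split > 0, split < 1, reps >= 1)
  models <- ensemble$models
  per_model <- matrix(NA_real_, reps, length(models))
  redraws <- 0L
  with_seed(seed, {
    for (r in seq_len(reps)) {
      for (i in seq_along(models)) {
        m <- models[[i]]
        d <- m$training
        repeat {
          tr <- stratified_split(d$y, split)
          if (length(unique(d$y[!tr])) == 2) break
          redraws <- redraws + 1L
        }
        fit <- fit_forest(d[tr, , drop = FALSE], m$variables, num_trees,
                          seed = seed + 31L * r + i, probability = TRUE)
        p <- stats::predict(fit, data = d[!tr, m$variables, drop = FALSE],
                            num.threads = 1)$predictions[, "presence"]
        per_model[r, i] <- auc_score(p, d$y[!tr] == "presence")
      }
    }
  })
  per_rep <- rowMeans(per_model)
  list(mean = mean(per_rep), sd = stats::sd(per_rep), per_rep = per_rep,
       per_model = per_model, redraws = redraws)
}

#' Partial dependence of predicted suitability on one variable
#'
#' For each ensemble member whose selected subset contains the variable,
#' predictions are made over a grid of its values with every other
#' variable held at that member's training mean. Returns per-grid-point
#' ensemble mean and a 95% band across members.
#'
#' @param ensemble an `rf_ensemble` or single `mir_model`.
#' @param variable variable (column) name.
#' @param grid_points number of evaluation points.
#' @return data.frame `value`, `mean`, `lower`, `upper`, with the
#'   per-member curve matrix in attribute `curves`.
#' @export
partial_dependence <- function(ensemble, variable, grid_points = 25) {
  models <- if (inherits(ensemble, "mir_model")) list(ensemble)
    else ensemble$models
  models <- Filter(function(m) variable %in% m$variables, models)
  if (length(models) == 0)
    stop(sprintf("'%s' is not in any model's selected subset", variable))
  rng <- range(unlist(lapply(models, function(m) m$training[[variable]])))
  grid <- seq(rng[1], rng[2], length.out = grid_points)
  curves <- vapply(models, function(m) {
    mu <- vapply(m$training[, m$variables, drop = FALSE], mean, 0)
    nd <- as.data.frame(as.list(mu))[rep(1, grid_points), , drop = FALSE]
    names(nd) <- m$variables
    nd[[variable]] <- grid
    stats::predict(m$model, data = nd,
                   num.threads = 1)$predictions[, "presence"]
  }, numeric(grid_points))
  out <- data.frame(
    value = grid,
    mean = rowMeans(curves),
    lower = apply(curves, 1, stats::quantile, 0.025),
    upper = apply(curves, 1, stats::quantile, 0.975)
  )
  attr(out, "curves") <- curves
  out
}
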