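#' Default base-learner specifications
#'
#' The stacked ensemble draws on five families: two distinct
#' gradient-boosted tree configurations, a random forest, extremely
#' randomized trees, and a single-hidden-layer feed-forward network (which
#' standardizes its inputs internally; the tree learners consume raw
#' features).
#'
#' @param families subset of
#'   \code{c("gbdt_a", "gbdt_b", "random_forest",
#'   "extremely_randomized_trees", "feedforward_net")}.
#' @param fast if \code{TRUE}, lighter settings (fewer trees/rounds) for
#'   small data or quick runs.
#' @return list of \code{learner_spec} objects (family, params, seed
#'   offset).
#' @export
default_learners <- function(families = c("gbdt_a", "gbdt_b",
                                          "random_forest",
                                          "extremely_randomized_trees",
                                          "feedforward_net"),
                             fast = FALSE) {
  all <- list(
    gbdt_a = list(family = "gbdt_a",
                  params = list(nrounds = if (fast) 60L else 150L,
                                eta = 0.1, max_depth = 6L,
                                subsample = 0.8, colsample_bytree = 0.8)),
    gbdt_b = list(family = "gbdt_b",
                  params = list(nrounds = if (fast) 120L else 300L,
                                eta = 0.05, max_depth = 4L,
                                subsample = 0.9, colsample_bytree = 0.6)),
    random_forest = list(family = "random_forest",
                         params = list(num.trees = if (fast) 100L else 300L,
                                       splitrule = "variance")),
    extremely_randomized_trees =
      list(family = "extremely_randomized_trees",
           params = list(num.trees = if (fast) 100L else 300L,
                         splitrule = "extratrees",
                         num.random.splits = 1L)),
    feedforward_net = list(family = "feedforward_net",
                           params = list(size = if (fast) 4L else 8L,
                                         decay = 1e-3,
                                         maxit = if (fast) 60L else 150L))
  )
  specs <- all[match.arg(families, names(all), several.ok = TRUE)]
  for (i in seq_along(specs)) {
    specs[[i]]$seed_offset <- i
    class(specs[[i]]) <- "learner_spec"
  }
  unname(specs)
}

.fit_base <- function(spec, x, y, seed) {
  fam <- spec$family
  p <- spec$params
  s <- as.integer((seed + spec$seed_offset * 131L) %% 2147483647L)
  if (fam %in% c("gbdt_a", "gbdt_b")) {
    fit <- xgboost::xgboost(
      x = x, y = y, objective = "reg:squarederror",
      nrounds = p$nrounds, learning_rate = p$eta,
      max_depth = p$max_depth, subsample = p$subsample,
      colsample_bytree = p$colsample_bytree,
      nthreads = 1L, seed = s, verbosity = 0L)
    return(structure(list(family = fam, fit = fit), class = "base_fit"))
  }
  if (fam %in% c("random_forest", "extremely_randomized_trees")) {
    fit <- ranger::ranger(
      x = as.data.frame(x), y = y, num.trees = p$num.trees,
      splitrule = p$splitrule,
      num.random.splits = p$num.random.splits %||% 1L,
      seed = s, num.threads = 1L)
    return(structure(list(family = fam, fit = fit), class = "base_fit"))
  }
  if (fam == "feedforward_net") {
    ctr <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    xs <- scale(x, center = ctr, scale = scl)
    yc <- mean(y); ys <- stats::sd(y); if (ys == 0 || !is.finite(ys)) ys <- 1
    set.seed(s)
    fit <- nnet::nnet(xs, (y - yc) / ys, size = p$size, decay = p$decay,
                      maxit = p$maxit, linout = TRUE, trace = FALSE,
                      MaxNWts = (ncol(x) + 2L) * p$size + p$size + 1L + 1000L)
    return(structure(list(family = fam, fit = fit, center = ctr,
                          scale = scl, y_center = yc, y_scale = ys),
                     class = "base_fit"))
  }
  stop("unknown learner family: ", fam)
}

.predict_base <- function(bf, x) {
  switch(bf$family,
    gbdt_a = ,
    gbdt_b = predict(bf$fit, x),
    random_forest = ,
    extremely_randomized_trees =
      predict(bf$fit, data = as.data.frame(x),
              num.threads = 1L)$predictions,
    feedforward_net = {
      xs <- scale(x, center = bf$center, scale = bf$scale)
      as.numeric(predict(bf$fit, xs)) * bf$y_scale + bf$y_center
    },
    stop("unknown learner family: ", bf$family))
}

## greedy forward selection with replacement over base-model OOF columns,
## minimizing OOF MSE of the bag average (Caruana-style ensemble selection)
.greedy_weights <- function(oof, y, max_rounds = 25L) {
  nb <- ncol(oof)
  counts <- integer(nb)
  bag <- numeric(nrow(oof))
  best_mse <- Inf
  for (r in seq_len(max_rounds)) {
    cand_mse <- vapply(seq_len(nb), function(j) {
      mean((y - (bag * (r - 1L) + oof[, j]) / r)^2)
    }, numeric(1))
    j <- which.min(cand_mse)
    if (cand_mse[j] >= best_mse && r > 1L) break
    best_mse <- cand_mse[j]
    bag <- (bag * (r - 1L) + oof[, j]) / r
    counts[j] <- counts[j] + 1L
  }
  w <- counts / sum(counts)
  list(weights = w, oof_mse = best_mse)
}

#' Fit a stacked ensemble regressor
#'
#' The central fitting function. Each base learner is cross-fitted to
#' produce out-of-fold (OOF) predictions; a combiner then assigns
#' non-negative weights (summing to one) to the base models by greedy
#' forward selection with replacement, minimizing OOF mean squared error.
#' Finally every base model with non-zero weight is refit on all training
#' rows. The greedy pool contains each single base model, so the combined
#' OOF MSE never exceeds the best single base model's.
#'
#' @param x numeric feature matrix (rows = records), or a
#'   \code{feature_matrix}.
#' @param y numeric label vector (log10 EC50); defaults to the feature
#'   matrix labels.
#' @param specs list of base-learner specifications from
#'   [default_learners()] (at least two).
#' @param folds number of cross-fitting folds (default 5).
#' @param seed integer seed controlling fold assignment and every base
#'   learner's randomness; identical seed and specs give identical weights
#'   and predictions.
#' @param time_budget soft wall-clock budget in seconds (default 600):
#'   when exceeded, remaining base learners are skipped with a warning
#'   (at least one is always fitted).
#' @return an object of class \code{stack_ensemble} with the fitted base
#'   models, OOF prediction matrix, combiner weights, OOF MSE, and
#'   metadata (feature names, folds, seed). Methods: \code{predict},
#'   \code{print}, \code{summary}, \code{coef} (combiner weights),
#'   \code{residuals}.
#' @export
stack_ensemble <- function(x, y = NULL, specs = default_learners(),
                           folds = 5L, seed = 1L, time_budget = 600) {
  if (inherits(x, "feature_matrix")) {
    y <- y %||% x$labels
    x <- x$x
  }
  stopifnot(is.matrix(x), is.numeric(y), nrow(x) == length(y),
            length(specs) >= 2L, folds >= 2L)
  n <- nrow(x)
  if (n <= folds)
    stop("need more training rows (", n, ") than folds (", folds, ")")
  seed <- as.integer(seed) %% 2147483647L
  set.seed(child_seed(seed, "folds"))
  fold_id <- sample(rep(seq_len(folds), length.out = n))

  t0 <- Sys.time()
  oof_cols <- list()
  kept_specs <- list()
  for (spec in specs) {
    if (length(oof_cols) >= 1L &&
        as.numeric(difftime(Sys.time(), t0, units = "secs")) > time_budget) {
      warning("time budget exceeded; skipping remaining base learners")
      break
    }
    oof <- rep(NA_real_, n)
    ok <- TRUE
    for (f in seq_len(folds)) {
      hold <- fold_id == f
      fit <- tryCatch(.fit_base(spec, x[!hold, , drop = FALSE], y[!hold],
                                seed = child_seed(seed, paste0("cv", f))),
                      error = function(e) NULL)
      if (is.null(fit)) { ok <- FALSE; break }
      oof[hold] <- .predict_base(fit, x[hold, , drop = FALSE])
    }
    if (!ok || anyNA(oof)) {
      warning("base learner '", spec$family, "' failed to fit; excluded")
      next
    }
    oof_cols[[spec$family]] <- oof
    kept_specs[[spec$family]] <- spec
  }
  if (length(oof_cols) == 0L)
    stop("all base learners failed to fit")
  oof <- do.call(cbind, oof_cols)

  gw <- .greedy_weights(oof, y)
  refits <- lapply(seq_along(kept_specs), function(i) {
    if (gw$weights[i] == 0) return(NULL)
    .fit_base(kept_specs[[i]], x, y, seed = child_seed(seed, "refit"))
  })
  names(refits) <- names(kept_specs)

  structure(list(base_models = refits, specs = kept_specs,
                 weights = stats::setNames(gw$weights, names(kept_specs)),
                 oof_predictions = oof, oof_mse = gw$oof_mse,
                 y_train = y, folds = folds, seed = seed,
                 feature_names = colnames(x), n_train = n),
            class = "stack_ensemble")
}

#' @export
predict.stack_ensemble <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_matrix")) newdata <- newdata$x
  stopifnot(is.matrix(newdata))
  if (!is.null(object$feature_names) && !is.null(colnames(newdata)) &&
      !identical(colnames(newdata), object$feature_names))
    stop("newdata columns do not match the training feature columns")
  pred <- numeric(nrow(newdata))
  for (nm in names(object$base_models)) {
    w <- object$weights[[nm]]
    if (w == 0 || is.null(object$base_models[[nm]])) next
    pred <- pred + w * .predict_base(object$base_models[[nm]], newdata)
  }
  pred
}

#' @export
print.stack_ensemble <- function(x, ...) {
  cat("Stacked ensemble regressor (", x$n_train, " training records, ",
      length(x$feature_names), " features, ", x$folds, "-fold OOF)\n",
      sep = "")
  cat("  combiner weights:\n")
  for (nm in names(x$weights))
    cat(sprintf("    %-28s %.3f\n", nm, x$weights[[nm]]))
  cat(sprintf("  out-of-fold MSE: %.4f\n", x$oof_mse))
  invisible(x)
}

#' @method summary stack_ensemble
#' @export
summary.stack_ensemble <- function(object, ...) {
  base_mse <- apply(object$oof_predictions, 2,
                    function(p) mean((object$y_train - p)^2))
  out <- list(weights = object$weights, base_oof_mse = base_mse,
              ensemble_oof_mse = object$oof_mse,
              n_train = object$n_train,
              n_features = length(object$feature_names))
  class(out) <- "summary.stack_ensemble"
  out
}

#' @export
print.summary.stack_ensemble <- function(x, ...) {
  cat("Stacked ensemble:", x$n_train, "records,", x$n_features,
      "features\n")
  df <- data.frame(weight = round(x$weights, 3),
                   oof_mse = round(x$base_oof_mse, 4))
  print(df)
  cat(sprintf("ensemble OOF MSE: %.4f\n", x$ensemble_oof_mse))
  invisible(x)
}

#' @method coef stack_ensemble
#' @export
coef.stack_ensemble <- function(object, ...) object$weights

#' @method residuals stack_ensemble
#' @export
residuals.stack_ensemble <- function(object, ...) {
  object$y_train - as.numeric(object$oof_predictions %*% object$weights)
}

.filter_mode <- function(records, mode_filter) {
  if (mode_filter == "merged") return(rep(TRUE, nrow(records)))
  records$mode == mode_filter
}

#' Train a multitask model
#'
#' Fits one stacked ensemble on the pooled training records of all
#' modelled receptors (receptor identity is carried by the aligned
#' protein-code features, so the model can predict for receptors unseen
#' in training, e.g. orphans). The mode filter selects agonist-only,
#' antagonist-only, or the merged task.
#'
#' @param fm assembled \code{feature_matrix} covering at least the
#'   training records.
#' @param split a \code{dataset_split}.
#' @param mode_filter \code{"merged"} (default), \code{"agonist"} or
#'   \code{"antagonist"}.
#' @param specs,folds,seed,time_budget passed to [stack_ensemble()].
#' @return an object of class \code{mtl_model} wrapping the ensemble with
#'   the task definition; supports \code{predict} on any
#'   \code{feature_matrix}.
#' @export
train_multitask <- function(fm, split, mode_filter = c("merged", "agonist",
                                                       "antagonist"),
                            specs = default_learners(), folds = 5L,
                            seed = 1L, time_budget = 600) {
  mode_filter <- match.arg(mode_filter)
  keep <- split$train$record_id[.filter_mode(split$train, mode_filter)]
  if (length(keep) == 0L)
    stop("mode filter '", mode_filter, "' leaves no training records")
  tr <- subset_records(fm, keep)
  ens <- stack_ensemble(tr$x, tr$labels, specs = specs, folds = folds,
                        seed = seed, time_budget = time_budget)
  structure(list(ensemble = ens, task = "multitask",
                 mode_filter = mode_filter, blocks = fm$blocks,
                 provenance = fm$provenance, seed = as.integer(seed)),
            class = "mtl_model")
}

#' @export
predict.mtl_model <- function(object, newdata, ...) {
  predict(object$ensemble, newdata)
}

#' @export
print.mtl_model <- function(x, ...) {
  cat("Multitask EC50 model (mode filter:", x$mode_filter, ")\n")
  print(x$ensemble)
  invisible(x)
}

#' Train single-task models per receptor
#'
#' Fits an independent stacked ensemble for each (receptor, mode) group —
#' or per receptor with both modes pooled when
#' \code{mode_filter = "merged"} — using only that group's training
#' records. Groups with fewer than \code{min_group} training records are
#' skipped and logged.
#'
#' @inheritParams train_multitask
#' @param min_group minimum training records per group (default 4).
#' @return an object of class \code{stl_models}: a named list of
#'   \code{stack_ensemble} fits (one per group) plus a \code{skipped}
#'   data frame.
#' @export
train_single_task <- function(fm, split, mode_filter = c("agonist",
                                                         "antagonist",
                                                         "merged"),
                              min_group = 4L, specs = default_learners(),
                              folds = 5L, seed = 1L, time_budget = 600) {
  mode_filter <- match.arg(mode_filter)
  tr <- split$train[.filter_mode(split$train, mode_filter), , drop = FALSE]
  grp <- if (mode_filter == "merged") tr$receptor_id
         else paste(tr$receptor_id, tr$mode, sep = ":")
  groups <- split(tr$record_id, grp)
  fits <- list()
  skipped <- data.frame(group = character(0), n = integer(0))
  for (g in names(groups)) {
    ids <- groups[[g]]
    if (length(ids) < min_group) {
      skipped <- rbind(skipped, data.frame(group = g, n = length(ids)))
      next
    }
    sub <- subset_records(fm, ids)
    f <- min(folds, length(ids))
    if (length(ids) <= f) f <- max(2L, length(ids) - 1L)
    fits[[g]] <- stack_ensemble(sub$x, sub$labels, specs = specs,
                                folds = f, seed = seed,
                                time_budget = time_budget)
  }
  structure(list(fits = fits, skipped = skipped,
                 mode_filter = mode_filter, min_group = min_group),
            class = "stl_models")
}

#' @export
print.stl_models <- function(x, ...) {
  cat("Single-task models:", length(x$fits), "groups fitted,",
      nrow(x$skipped), "skipped (<", x$min_group, "training records)\n")
  invisible(x)
}

#' Mean squared error
#' @param y_true,y_pred numeric vectors of equal length.
#' @return mean of squared differences.
#' @export
mse_metric <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  mean((y_true - y_pred)^2)
}

#' Pearson correlation coefficient
#'
#' Returns \code{NA} (not 0) when either vector is constant, in which
#' case the correlation is undefined.
#' @param y_true,y_pred numeric vectors of equal length.
#' @return correlation in [-1, 1], or \code{NA} if undefined.
#' @export
cc_metric <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  if (length(y_true) < 2L) return(NA_real_)
  if (stats::sd(y_true) == 0 || stats::sd(y_pred) == 0) return(NA_real_)
  num <- sum((y_true - mean(y_true)) * (y_pred - mean(y_pred)))
  den <- sqrt(sum((y_true - mean(y_true))^2) *
                sum((y_pred - mean(y_pred))^2))
  num / den
}

#' Per-group and overall model evaluation
#'
#' Computes MSE and Pearson correlation per grouping level (typically
#' receptor or receptor x mode) and overall. Groups where either the
#' labels or the predictions are constant get \code{cc = NA} with
#' \code{cc_defined = FALSE}.
#'
#' @param y_true,y_pred numeric vectors.
#' @param group grouping labels, one per record.
#' @return an object of class \code{evaluation_report}: list with
#'   \code{per_group} (data frame: group, n, mse, cc, cc_defined) and
#'   \code{overall} (n, mse, cc).
#' @export
evaluate_predictions <- function(y_true, y_pred, group) {
  stopifnot(length(y_true) == length(y_pred),
            length(group) == length(y_true))
  idx <- split(seq_along(y_true), group)
  per_group <- do.call(rbind, lapply(names(idx), function(g) {
    i <- idx[[g]]
    cc <- cc_metric(y_true[i], y_pred[i])
    data.frame(group = g, n = length(i),
               mse = mse_metric(y_true[i], y_pred[i]),
               cc = cc, cc_defined = !is.na(cc),
               stringsAsFactors = FALSE)
  }))
  structure(list(per_group = per_group,
                 overall = list(n = length(y_true),
                                mse = mse_metric(y_true, y_pred),
                                cc = cc_metric(y_true, y_pred))),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation over %d records: MSE %.4f, CC %s\n",
              x$overall$n, x$overall$mse,
              ifelse(is.na(x$overall$cc), "undefined",
                     sprintf("%.4f", x$overall$cc))))
  cat(nrow(x$per_group), "groups; per-group summary of MSE:\n")
  print(summary(x$per_group$mse))
  invisible(x)
}

#' Evaluate a multitask model on a split partition
#'
#' @param model an \code{mtl_model}.
#' @param fm \code{feature_matrix} covering the partition records.
#' @param split a \code{dataset_split}.
#' @param partition \code{"validation"} (default), \code{"train"} or
#'   \code{"orphan_test"}.
#' @param by grouping for the report: \code{"receptor"} (default) or
#'   \code{"receptor_mode"}.
#' @return an \code{evaluation_report}; predictions are attached as
#'   attribute \code{predictions} (data frame record_id, y_true, y_pred).
#' @export
evaluate_model <- function(model, fm, split,
                           partition = c("validation", "train",
                                         "orphan_test"),
                           by = c("receptor", "receptor_mode")) {
  partition <- match.arg(partition)
  by <- match.arg(by)
  recs <- split[[partition]]
  recs <- recs[.filter_mode(recs, model$mode_filter), , drop = FALSE]
  if (nrow(recs) == 0L) stop("no records in partition '", partition, "'")
  sub <- subset_records(fm, recs$record_id)
  pred <- predict(model, sub)
  grp <- if (by == "receptor") recs$receptor_id
         else paste(recs$receptor_id, recs$mode, sep = ":")
  rep <- evaluate_predictions(sub$labels, pred, grp)
  attr(rep, "predictions") <- data.frame(record_id = recs$record_id,
                                         y_true = sub$labels,
                                         y_pred = pred,
                                         stringsAsFactors = FALSE)
  rep
}

#' Mann-Whitney U comparison of two metric samples
#'
#' Compares per-receptor performance metrics of two model families with
#' the two-sided Mann-Whitney U test. For small samples
#' (n_A + n_B <= \code{exact_max}) the null distribution of U is obtained
#' by exhaustive enumeration of all group assignments of the pooled
#' values (exact even under ties); larger samples use the normal
#' approximation with tie correction and continuity correction.
#'
#' @param a,b numeric vectors of per-group metrics (both non-empty).
#' @param exact_max largest n_A + n_B for which the exact enumeration is
#'   used (default 12).
#' @return list with \code{U} (statistic of the first sample), \code{p}
#'   (two-sided), and \code{method}.
#' @export
compare_model_groups <- function(a, b, exact_max = 12L) {
  stopifnot(length(a) >= 1L, length(b) >= 1L,
            all(is.finite(a)), all(is.finite(b)))
  n1 <- length(a); n2 <- length(b)
  u_stat <- function(av, bv)
    sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  u_obs <- u_stat(a, b)
  pooled <- c(a, b)
  if (n1 + n2 <= exact_max) {
    sets <- utils::combn(n1 + n2, n1)
    us <- apply(sets, 2, function(ia)
      u_stat(pooled[ia], pooled[-ia]))
    p <- min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
    return(list(U = u_obs, p = p, method = "exact enumeration"))
  }
  r <- rank(pooled)
  mu <- n1 * n2 / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 *
    ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
  if (sigma2 <= 0) return(list(U = u_obs, p = 1,
                               method = "normal approximation"))
  z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
  list(U = u_obs, p = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal approximation")
}
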