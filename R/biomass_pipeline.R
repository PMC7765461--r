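# Random-forest biomass workflow: predictor filtering, grid-search tuning
# with the 10%-loss parsimony rule, and the two validation strategies
# (plain stratified holdout; leave-one-location-out spatial CV with
# biomass-distribution-preserving downsampling).

predictor_columns <- function(tbl) {
  cand <- setdiff(names(tbl), c("id", "location", "biomass"))
  cand[vapply(tbl[cand], is.numeric, logical(1L))]
}

check_predictor_table <- function(tbl) {
  if (is.null(tbl$biomass) || any(is.na(tbl$biomass))) {
    abort_ps("predictor table needs a complete 'biomass' target column",
             "pasturespec_format_error")
  }
  if (length(predictor_columns(tbl)) == 0L) {
    abort_ps("predictor table has no numeric predictor columns",
             "pasturespec_format_error")
  }
  invisible(tbl)
}

#' Filter predictors by Pearson correlation with biomass
#'
#' Retains predictors whose absolute Pearson correlation with the biomass
#' target meets the threshold (default |0.2|). Constant predictors are
#' dropped with reason `"constant"`. To avoid leakage the filter should be
#' computed on the training portion only; [run_biomass_pipeline()] does
#' this automatically.
#'
#' @param tbl Predictor table: numeric predictor columns plus `biomass`
#'   (kg DM/ha) and optionally `id`, `location`.
#' @param threshold Minimum absolute correlation, in (0, 1).
#' @return List with `table` (the filtered predictor table) and `report`
#'   (per predictor: `r`, `kept`, `reason`).
#' @export
correlation_filter <- function(tbl, threshold = 0.2) {
  check_predictor_table(tbl)
  if (nrow(tbl) < 3L) {
    abort_ps("correlation filter needs at least 3 rows",
             "pasturespec_format_error")
  }
  if (threshold <= 0 || threshold >= 1) {
    abort_ps("threshold must lie in (0, 1)", "pasturespec_format_error")
  }
  preds <- predictor_columns(tbl)
  r <- vapply(preds, function(p) {
    x <- tbl[[p]]
    if (all(is.na(x)) || stats::sd(x, na.rm = TRUE) == 0) return(NA_real_)
    stats::cor(x, tbl$biomass, use = "complete.obs")
  }, numeric(1L))
  kept <- !is.na(r) & abs(r) >= threshold
  reason <- ifelse(kept, "",
                   ifelse(is.na(r), "constant", "below threshold"))
  keep_cols <- c(intersect(c("id", "location"), names(tbl)),
                 preds[kept], "biomass")
  list(table = tbl[, keep_cols, drop = FALSE],
       report = data.frame(predictor = preds, r = r, kept = kept,
                           reason = reason, row.names = NULL,
                           stringsAsFactors = FALSE))
}

#' Default random-forest tuning grid
#'
#' Number of trees and number of predictors drawn at each split; `mtry`
#' entries exceeding the predictor count are skipped at tune time.
#' @return Data frame of `(num_trees, mtry)` pairs.
#' @export
default_rf_grid <- function() {
  expand.grid(num_trees = c(500L, 1000L, 1500L, 2000L),
              mtry = c(2L, 3L, 4L, 6L, 8L))
}

# Center/scale predictors by training statistics only (leakage guard).
scale_by_train <- function(train, test, preds) {
  mu <- vapply(train[preds], mean, numeric(1L))
  sg <- vapply(train[preds], stats::sd, numeric(1L))
  sg[!is.finite(sg) | sg == 0] <- 1
  apply_scale <- function(df) {
    df[preds] <- Map(function(x, m, s) (x - m) / s, df[preds], mu, sg)
    df
  }
  list(train = apply_scale(train), test = apply_scale(test))
}

fit_rf <- function(train, preds, num_trees, mtry, seed) {
  ranger::ranger(
    x = train[, preds, drop = FALSE], y = train$biomass,
    num.trees = num_trees, mtry = mtry, seed = seed, num.threads = 1L)
}

predict_rf <- function(model, newdata, preds) {
  stats::predict(model, data = newdata[, preds, drop = FALSE],
                 num.threads = 1L)$predictions
}

#' Parsimony rule: least complex model within 10% of the best RMSE
#'
#' Among grid entries whose cross-validated RMSE is within `pct_loss` of
#' the grid minimum, selects the least complex pair: fewest trees first,
#' then smallest `mtry`.
#'
#' @param grid_results Data frame with `num_trees`, `mtry`, `rmse_cv`.
#' @param pct_loss Allowed relative RMSE loss, default 0.10.
#' @return The selected row of `grid_results`.
#' @export
select_parsimonious <- function(grid_results, pct_loss = 0.10) {
  ok <- is.finite(grid_results$rmse_cv)
  if (!any(ok)) abort_ps("no finite grid results", "pasturespec_fit_error")
  cutoff <- (1 + pct_loss) * min(grid_results$rmse_cv[ok])
  qual <- grid_results[ok & grid_results$rmse_cv <= cutoff, , drop = FALSE]
  qual[order(qual$num_trees, qual$mtry), , drop = FALSE][1L, , drop = FALSE]
}

#' Tune a random forest by k-fold grid search
#'
#' Evaluates every `(num_trees, mtry)` pair by k-fold cross-validated RMSE
#' on centered/scaled predictors (scaling fit on each training fold only)
#' and applies the parsimony rule of [select_parsimonious()]: the chosen
#' pair is within ten percent of the minimal RMSE and minimal in the
#' complexity order (trees, then `mtry`).
#'
#' @param tbl Predictor table (see [correlation_filter()]).
#' @param grid Tuning grid, default [default_rf_grid()].
#' @param k Number of folds, `>= 2`.
#' @param seed Integer seed; identical seeds give identical results.
#' @return An object of class `"tune_result"`: `grid` (with `rmse_cv`,
#'   `rmse_sd`), `selected`, `rule`, `k`, `seed`.
#' @export
tune_random_forest <- function(tbl, grid = default_rf_grid(), k = 10L,
                               seed = 1L) {
  check_predictor_table(tbl)
  if (k < 2L) abort_ps("k must be >= 2", "pasturespec_format_error")
  if (nrow(grid) == 0L) abort_ps("empty tuning grid",
                                 "pasturespec_format_error")
  preds <- predictor_columns(tbl)
  n <- nrow(tbl)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  grid <- as.data.frame(grid)
  grid$rmse_cv <- NA_real_
  grid$rmse_sd <- NA_real_
  for (g in seq_len(nrow(grid))) {
    if (grid$mtry[g] > length(preds)) {
      warning(sprintf("skipping grid entry mtry=%d > %d predictors",
                      grid$mtry[g], length(preds)))
      next
    }
    fold_rmse <- vapply(seq_len(k), function(f) {
      tr <- tbl[fold != f, , drop = FALSE]
      va <- tbl[fold == f, , drop = FALSE]
      sc <- scale_by_train(tr, va, preds)
      m <- fit_rf(sc$train, preds, grid$num_trees[g], grid$mtry[g],
                  seed = seed + f)
      rmse(va$biomass, predict_rf(m, sc$test, preds))
    }, numeric(1L))
    grid$rmse_cv[g] <- mean(fold_rmse)
    grid$rmse_sd[g] <- stats::sd(fold_rmse)
  }
  selected <- select_parsimonious(grid)
  stopifnot(selected$rmse_cv <= 1.10 * min(grid$rmse_cv, na.rm = TRUE))
  structure(list(
    grid = grid,
    selected = list(num_trees = selected$num_trees, mtry = selected$mtry,
                    rmse_cv = selected$rmse_cv),
    rule = "within 10% of minimal CV RMSE; fewest trees, then smallest mtry",
    k = k, seed = seed),
    class = "tune_result")
}

#' @export
print.tune_result <- function(x, ...) {
  cat(sprintf(
    "<tune_result> %d grid points, k=%d; selected %d trees, mtry=%d (CV RMSE %.1f)\n",
    nrow(x$grid), x$k, x$selected$num_trees, x$selected$mtry,
    x$selected$rmse_cv))
  invisible(x)
}

# Per-location stratified train/holdout indices.
stratified_split_idx <- function(location, fraction, seed) {
  if (!is.finite(fraction) || fraction <= 0 || fraction >= 1) {
    abort_ps("split fraction must lie strictly between 0 and 1",
             "pasturespec_format_error")
  }
  location <- as.character(location)
  location[is.na(location)] <- "(none)"
  set.seed(seed)
  train <- logical(length(location))
  for (loc in unique(location)) {
    idx <- which(location == loc)
    if (length(idx) < 4L) {
      warning(sprintf(
        "location '%s' has %d samples; proportional fallback", loc,
        length(idx)))
    }
    n_tr <- max(1L, min(length(idx) - 1L, round(length(idx) * fraction)))
    train[sample(idx, n_tr)] <- TRUE
  }
  list(train = which(train), test = which(!train))
}

new_biomass_eval <- function(strategy, metrics, predictions, tuned) {
  pooled_rmse <- rmse(predictions$observed, predictions$predicted)
  pooled_r2 <- rsq(predictions$observed, predictions$predicted)
  structure(list(strategy = strategy, metrics = metrics,
                 rmse = pooled_rmse, r2 = pooled_r2,
                 predictions = predictions,
                 num_trees = tuned$selected$num_trees,
                 mtry = tuned$selected$mtry),
            class = "biomass_eval")
}

#' @export
print.biomass_eval <- function(x, ...) {
  cat(sprintf("<biomass_eval> %s: RMSE %.1f kg DM/ha, R2 %.3f (%d predictions)\n",
              x$strategy, x$rmse, x$r2, nrow(x$predictions)))
  invisible(x)
}

#' Holdout validation with a location-stratified split
#'
#' Trains a random forest with the tuned hyperparameters on a 75%
#' location-stratified split (scaling statistics from the training side
#' only) and reports RMSE (kg DM/ha) and R^2 (squared Pearson
#' correlation) on the held-out 25%.
#'
#' @param tbl Predictor table.
#' @param tuned A [tune_random_forest()] result (or a list with
#'   `selected$num_trees`, `selected$mtry`).
#' @param split Training fraction, strictly between 0 and 1.
#' @param seed Integer seed controlling the split and forest.
#' @return An object of class `"biomass_eval"` with pooled `rmse`, `r2`,
#'   a per-fold `metrics` table and the `(id, location, observed,
#'   predicted, fold)` predictions.
#' @export
evaluate_cv <- function(tbl, tuned, split = 0.75, seed = 1L) {
  check_predictor_table(tbl)
  preds <- predictor_columns(tbl)
  loc <- if (is.null(tbl$location)) rep("(none)", nrow(tbl)) else tbl$location
  sp <- stratified_split_idx(loc, split, seed)
  tr <- tbl[sp$train, , drop = FALSE]
  te <- tbl[sp$test, , drop = FALSE]
  sc <- scale_by_train(tr, te, preds)
  m <- fit_rf(sc$train, preds, tuned$selected$num_trees,
              tuned$selected$mtry, seed = seed)
  pred <- predict_rf(m, sc$test, preds)
  predictions <- data.frame(
    id = if (is.null(te$id)) as.character(sp$test) else as.character(te$id),
    location = loc[sp$test], observed = te$biomass, predicted = pred,
    fold = "holdout", stringsAsFactors = FALSE)
  metrics <- data.frame(fold = "holdout",
                        rmse = rmse(te$biomass, pred),
                        r2 = rsq(te$biomass, pred),
                        n = nrow(te), stringsAsFactors = FALSE)
  new_biomass_eval("cv", metrics, predictions, tuned)
}

# Downsample one location to `cap` rows while preserving its biomass
# distribution: rows are split into biomass-quantile strata and sampled
# proportionally within each.
stratified_downsample_idx <- function(biomass, cap, strata = 4L) {
  n <- length(biomass)
  if (cap >= n) return(seq_len(n))
  qs <- stats::quantile(biomass, probs = seq(0, 1, length.out = strata + 1L),
                        names = FALSE)
  qs[1L] <- -Inf; qs[strata + 1L] <- Inf
  stratum <- cut(biomass, breaks = unique(qs), labels = FALSE,
                 include.lowest = TRUE)
  take <- integer(0)
  groups <- split(seq_len(n), stratum)
  share <- vapply(groups, length, integer(1L)) / n
  quota <- floor(share * cap)
  rem <- cap - sum(quota)
  if (rem > 0) {
    extra <- order(share * cap - quota, decreasing = TRUE)[seq_len(rem)]
    quota[extra] <- quota[extra] + 1L
  }
  for (gi in seq_along(groups)) {
    idx <- groups[[gi]]
    k <- min(length(idx), quota[gi])
    take <- c(take, if (length(idx) == 1L) idx else sample(idx, k))
  }
  sort(take)
}

#' Leave-one-location-out spatial cross-validation
#'
#' Each location is first downsampled to a common cap (default: the size
#' of the smallest location) by biomass-quantile-stratified random
#' sampling, preventing class imbalance while keeping each location's
#' biomass distribution. The forest is then trained with the tuned
#' hyperparameters once per location, always holding that entire location
#' out as the validation set, so the metrics measure transfer to unseen
#' sites.
#'
#' @param tbl Predictor table with a `location` column (>= 2 locations).
#' @param tuned A [tune_random_forest()] result.
#' @param cap Samples kept per location; default size of the smallest.
#' @param strata Number of biomass-quantile strata for downsampling.
#' @param seed Integer seed.
#' @return A `"biomass_eval"` with per-fold (per-location) metrics and
#'   pooled RMSE/R^2 over all held-out predictions.
#' @export
evaluate_spatial <- function(tbl, tuned, cap = NULL, strata = 4L,
                             seed = 1L) {
  check_predictor_table(tbl)
  if (is.null(tbl$location) ||
      length(unique(stats::na.omit(tbl$location))) < 2L) {
    abort_ps("spatial cross-validation needs at least 2 locations",
             "pasturespec_format_error")
  }
  preds <- predictor_columns(tbl)
  set.seed(seed)
  locs <- unique(tbl$location)
  if (is.null(cap)) cap <- min(table(tbl$location))
  keep <- unlist(lapply(locs, function(loc) {
    idx <- which(tbl$location == loc)
    idx[stratified_downsample_idx(tbl$biomass[idx], cap, strata)]
  }))
  capped <- tbl[sort(keep), , drop = FALSE]
  pred_rows <- list()
  metrics <- list()
  for (loc in locs) {
    va <- capped[capped$location == loc, , drop = FALSE]
    tr <- capped[capped$location != loc, , drop = FALSE]
    sc <- scale_by_train(tr, va, preds)
    m <- fit_rf(sc$train, preds, tuned$selected$num_trees,
                tuned$selected$mtry, seed = seed)
    pred <- predict_rf(m, sc$test, preds)
    pred_rows[[loc]] <- data.frame(
      id = if (is.null(va$id)) rownames(va) else as.character(va$id),
      location = loc, observed = va$biomass, predicted = pred,
      fold = loc, stringsAsFactors = FALSE)
    metrics[[loc]] <- data.frame(
      fold = loc, rmse = rmse(va$biomass, pred),
      r2 = rsq(va$biomass, pred), n = nrow(va), stringsAsFactors = FALSE)
  }
  out <- new_biomass_eval("spatial", do.call(rbind, metrics),
                          do.call(rbind, pred_rows), tuned)
  out$cap <- cap
  out$capped_n <- nrow(capped)
  rownames(out$metrics) <- NULL
  rownames(out$predictions) <- NULL
  out
}

#' Per-wavelength agreement between two spectral libraries
#'
#' For each wavelength, the RMSE and Pearson correlation across samples
#' between an observed and a simulated/reconstructed library — the
#' standard per-wavelength diagnostic for retrieval fidelity. Wavelengths
#' where either library is constant across samples get `r = NA`
#' (undefined), flagged in the output.
#'
#' @param observed,simulated Two [spectral_library()] objects on an
#'   identical grid with the same sample ids.
#' @return Data frame with `wavelength`, `rmse`, `r`, `r_defined`.
#' @export
agreement_profile <- function(observed, simulated) {
  if (!isTRUE(all.equal(observed$wavelengths, simulated$wavelengths,
                        tolerance = 0))) {
    abort_ps("libraries are not on an identical wavelength grid",
             "pasturespec_grid_error")
  }
  ids <- rownames(observed$values)
  if (!setequal(ids, rownames(simulated$values))) {
    abort_ps("libraries do not contain the same sample ids",
             "pasturespec_format_error")
  }
  sim <- simulated$values[match(ids, rownames(simulated$values)), ,
                          drop = FALSE]
  obs <- observed$values
  d <- sim - obs
  rmse_wl <- sqrt(colMeans(d^2))
  r <- vapply(seq_along(observed$wavelengths), function(j) {
    if (stats::sd(obs[, j]) == 0 || stats::sd(sim[, j]) == 0) return(NA_real_)
    stats::cor(obs[, j], sim[, j])
  }, numeric(1L))
  data.frame(wavelength = observed$wavelengths, rmse = rmse_wl, r = r,
             r_defined = !is.na(r), row.names = NULL)
}

#' End-to-end biomass pipeline: filter, tune, validate
#'
#' Convenience wrapper reproducing the full modelling workflow on one
#' feature table: a 75/25 location-stratified split, the |0.2| Pearson
#' correlation filter computed on the training portion only, grid-search
#' tuning with the parsimony rule on the training portion, holdout
#' validation, and (optionally) leave-one-location-out spatial
#' cross-validation with the same tuned hyperparameters.
#'
#' @param tbl Predictor table (features plus `biomass`, `location`, `id`).
#' @param threshold Correlation-filter threshold.
#' @param grid,k Tuning grid and fold count for [tune_random_forest()].
#' @param split Training fraction.
#' @param spatial Also run [evaluate_spatial()]?
#' @param cap,strata Spatial downsampling controls.
#' @param seed Integer seed used for the split, tuning and forests.
#' @return List with `filter`, `tuned`, `cv` and (optionally) `spatial`.
#' @export
run_biomass_pipeline <- function(tbl, threshold = 0.2,
                                 grid = default_rf_grid(), k = 10L,
                                 split = 0.75, spatial = TRUE, cap = NULL,
                                 strata = 4L, seed = 1L) {
  check_predictor_table(tbl)
  loc <- if (is.null(tbl$location)) rep("(none)", nrow(tbl)) else tbl$location
  sp <- stratified_split_idx(loc, split, seed)
  filt <- correlation_filter(tbl[sp$train, , drop = FALSE], threshold)
  kept_cols <- c(intersect(c("id", "location"), names(tbl)),
                 setdiff(names(filt$table),
                         c("id", "location", "biomass")), "biomass")
  kept <- tbl[, kept_cols, drop = FALSE]
  tuned <- tune_random_forest(kept[sp$train, , drop = FALSE], grid = grid,
                              k = k, seed = seed)
  cv <- evaluate_cv(kept, tuned, split = split, seed = seed)
  out <- list(filter = filt, tuned = tuned, cv = cv)
  if (spatial && !is.null(tbl$location) &&
      length(unique(stats::na.omit(tbl$location))) >= 2L) {
    out$spatial <- evaluate_spatial(kept, tuned, cap = cap,
                                    strata = strata, seed = seed)
  }
  out
}
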