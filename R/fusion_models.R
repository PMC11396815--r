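#' Seeded train/validation split
#'
#' Simple random split without replacement: `round(train_fraction * n)` ids
#' go to training (64 of 96 at the default 2/3), the rest to validation.
#'
#' @param ids vector of sample identifiers (n >= 6)
#' @param train_fraction fraction of samples trained on (default 2/3)
#' @param seed integer seed; the split is deterministic given the seed
#' @return list with `train_ids` and `validation_ids`
#' @export
split_data <- function(ids, train_fraction = 2 / 3, seed = 1L) {
  n <- length(ids)
  if (n < 6) stop("need at least 6 samples to split")
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("train_fraction must lie in (0, 1)")
  n_train <- round(train_fraction * n)
  tr <- with_seed(seed, sample(n, n_train))
  list(train_ids = ids[sort(tr)], validation_ids = ids[sort(setdiff(seq_len(n), tr))])
}

#' GA-BP configuration
#'
#' Settings for the genetic-algorithm-initialized backpropagation network:
#' a 1-hidden-layer feedforward net (sigmoid hidden units, linear output)
#' whose initial weights are chosen by a small genetic algorithm before
#' full gradient training.
#'
#' @param population_size GA population (default 5)
#' @param generations GA generations (default 50)
#' @param crossover_rate arithmetic-crossover probability (default 0.4)
#' @param mutation_rate per-gene Gaussian mutation probability (default 0.05)
#' @param hidden_nodes hidden-layer width (default 5)
#' @param max_epochs gradient-descent epochs for the final training (1000)
#' @param training_goal stop when training MSE (on the internal min-max
#'   scale) falls below this (1e-6)
#' @param learning_rate gradient step size (0.2 with 0.9 momentum)
#' @param momentum momentum coefficient for gradient descent
#' @param refine_epochs BP epochs used inside the GA fitness evaluation
#' @return list of class `gabp_config`
#' @export
gabp_config <- function(population_size = 5, generations = 50,
                        crossover_rate = 0.4, mutation_rate = 0.05,
                        hidden_nodes = 5, max_epochs = 1000,
                        training_goal = 1e-6, learning_rate = 0.2,
                        momentum = 0.9, refine_epochs = 20) {
  if (crossover_rate < 0 || crossover_rate > 1)
    stop_config("crossover_rate", "must lie in [0, 1]")
  if (mutation_rate < 0 || mutation_rate > 1)
    stop_config("mutation_rate", "must lie in [0, 1]")
  for (f in c("population_size", "generations", "hidden_nodes", "max_epochs"))
    if (get(f) < 1) stop_config(f, "must be a positive count")
  structure(list(population_size = population_size, generations = generations,
                 crossover_rate = crossover_rate, mutation_rate = mutation_rate,
                 hidden_nodes = hidden_nodes, max_epochs = max_epochs,
                 training_goal = training_goal, learning_rate = learning_rate,
                 momentum = momentum, refine_epochs = refine_epochs),
            class = "gabp_config")
}

#' Learner configuration
#'
#' Hyperparameters of the three regression learners. Defaults: XGBoost with
#' 100 boosting rounds, learning rate 0.03, maximum depth 5; random forest
#' with 100 trees; GA-BP per [gabp_config()].
#'
#' @param xgboost list with `n_estimators`, `learning_rate`, `max_depth`
#' @param random_forest list with `n_trees`
#' @param gabp a [gabp_config()]
#' @return list of class `learner_config`
#' @export
learner_config <- function(xgboost = list(n_estimators = 100,
                                          learning_rate = 0.03, max_depth = 5),
                           random_forest = list(n_trees = 100),
                           gabp = gabp_config()) {
  structure(list(xgboost = xgboost, random_forest = random_forest,
                 gabp = gabp), class = "learner_config")
}

# ---- GA-BP internals --------------------------------------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

gabp_unpack <- function(theta, d, h) {
  list(W1 = matrix(theta[1:(d * h)], d, h),
       b1 = theta[d * h + 1:h],
       w2 = theta[d * h + h + 1:h],
       b2 = theta[d * h + 2 * h + 1])
}

gabp_forward <- function(w, X) {
  H <- sigmoid(sweep(X %*% w$W1, 2, w$b1, `+`))
  list(H = H, yhat = as.numeric(H %*% w$w2 + w$b2))
}

gabp_mse <- function(theta, d, h, X, y) {
  mean((gabp_forward(gabp_unpack(theta, d, h), X)$yhat - y)^2)
}

# Full-batch gradient descent with momentum on the packed weight vector.
gabp_descend <- function(theta, d, h, X, y, epochs, lr, mom, goal) {
  vel <- numeric(length(theta))
  n <- nrow(X)
  for (e in seq_len(epochs)) {
    w <- gabp_unpack(theta, d, h)
    fw <- gabp_forward(w, X)
    err <- fw$yhat - y
    mse <- mean(err^2)
    if (mse <= goal) break
    # gradients of MSE
    d_out <- 2 * err / n                       # n
    g_w2 <- as.numeric(crossprod(fw$H, d_out)) # h
    g_b2 <- sum(d_out)
    d_hid <- (d_out %o% w$w2) * fw$H * (1 - fw$H) # n x h
    g_W1 <- crossprod(X, d_hid)                # d x h
    g_b1 <- colSums(d_hid)
    grad <- c(as.numeric(g_W1), g_b1, g_w2, g_b2)
    vel <- mom * vel - lr * grad
    theta <- theta + vel
  }
  theta
}

minmax_fit <- function(X) {
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  span <- hi - lo
  span[span == 0] <- 1
  list(lo = lo, span = span)
}
minmax_apply <- function(X, sc) sweep(sweep(X, 2, sc$lo), 2, sc$span, `/`)

#' Train a GA-BP regression network
#'
#' Feedforward network (inputs = feature count, `hidden_nodes` sigmoid
#' units, one linear output) trained on min-max-scaled features and target.
#' A genetic algorithm (fitness-proportional selection with elitism of one,
#' arithmetic crossover, per-gene Gaussian mutation) searches over initial
#' weight vectors, scoring each individual by its training MSE after a short
#' gradient refinement; the best individual is then trained by full-batch
#' gradient descent up to `max_epochs` or until the training goal is met.
#' Fully deterministic given the seed.
#'
#' @param X numeric matrix of predictors (rows = samples)
#' @param y numeric response
#' @param cfg a [gabp_config()]
#' @param seed integer seed
#' @return object of class `gabp_model` with a [predict()][predict.gabp_model]
#'   method
#' @export
train_gabp <- function(X, y, cfg = gabp_config(), seed = 1L) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X rows must match length(y)")
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop("non-finite values in training data")
  if (nrow(X) < cfg$population_size)
    stop("need at least population_size training rows")
  d <- ncol(X); h <- cfg$hidden_nodes
  sx <- minmax_fit(X)
  Xs <- minmax_apply(X, sx)
  degenerate <- (max(y) == min(y))
  if (degenerate) {
    warning("degenerate model: constant target; predicting the constant")
    model <- list(degenerate = TRUE, constant = y[1], scale_x = sx)
    class(model) <- "gabp_model"
    return(model)
  }
  sy <- list(lo = min(y), span = max(y) - min(y))
  ys <- (y - sy$lo) / sy$span
  npar <- d * h + 2 * h + 1
  with_seed(seed, {
    pop <- lapply(seq_len(cfg$population_size),
                  function(i) runif(npar, -0.5, 0.5))
    fitness <- rep(NA_real_, cfg$population_size)
    for (i in seq_along(pop)) {
      pop[[i]] <- gabp_descend(pop[[i]], d, h, Xs, ys, cfg$refine_epochs,
                               cfg$learning_rate, cfg$momentum,
                               cfg$training_goal)
      fitness[i] <- gabp_mse(pop[[i]], d, h, Xs, ys)
    }
    for (g in seq_len(cfg$generations)) {
      elite <- which.min(fitness)
      wts <- 1 / (fitness + 1e-12)
      probs <- wts / sum(wts)
      newpop <- vector("list", cfg$population_size)
      newpop[[1]] <- pop[[elite]]                 # elitism of one
      for (i in seq_len(cfg$population_size)[-1]) {
        pa <- pop[[sample.int(cfg$population_size, 1, prob = probs)]]
        child <- pa
        if (runif(1) < cfg$crossover_rate) {
          pb <- pop[[sample.int(cfg$population_size, 1, prob = probs)]]
          lam <- runif(1)
          child <- lam * pa + (1 - lam) * pb      # arithmetic crossover
        }
        mut <- runif(npar) < cfg$mutation_rate
        if (any(mut)) child[mut] <- child[mut] + rnorm(sum(mut), 0, 0.1)
        newpop[[i]] <- child
      }
      pop <- newpop
      for (i in seq_along(pop)) {
        pop[[i]] <- gabp_descend(pop[[i]], d, h, Xs, ys, cfg$refine_epochs,
                                 cfg$learning_rate, cfg$momentum,
                                 cfg$training_goal)
        fitness[i] <- gabp_mse(pop[[i]], d, h, Xs, ys)
      }
    }
    best <- gabp_descend(pop[[which.min(fitness)]], d, h, Xs, ys,
                         cfg$max_epochs, cfg$learning_rate, cfg$momentum,
                         cfg$training_goal)
    model <- list(degenerate = FALSE, theta = best, d = d, h = h,
                  scale_x = sx, scale_y = sy, cfg = cfg,
                  train_mse = gabp_mse(best, d, h, Xs, ys))
    class(model) <- "gabp_model"
    model
  })
}

#' Predict from a GA-BP model
#' @param object a `gabp_model`
#' @param newdata matrix of predictors
#' @param ... ignored
#' @return numeric vector of predictions
#' @export
predict.gabp_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (object$degenerate) return(rep(object$constant, nrow(newdata)))
  Xs <- minmax_apply(newdata, object$scale_x)
  ys <- gabp_forward(gabp_unpack(object$theta, object$d, object$h), Xs)$yhat
  ys * object$scale_y$span + object$scale_y$lo
}

#' Train one of the three regression learners
#'
#' Dispatches to XGBoost (`xgboost::xgb.train`, squared-error objective,
#' single thread), random forest (`randomForest::randomForest`), or
#' [train_gabp()], each with the hyperparameters in `cfg` and deterministic
#' given `seed`.
#'
#' @param kind `"XGBoost"`, `"RF"`, or `"GA-BP"`
#' @param X numeric matrix of predictors (>= 6 rows)
#' @param y numeric response
#' @param cfg a [learner_config()]
#' @param seed integer seed
#' @return object of class `smc_model` wrapping the fitted learner; use
#'   [predict()][predict.smc_model]
#' @export
train_model <- function(kind, X, y, cfg = learner_config(), seed = 1L) {
  if (!kind %in% c("XGBoost", "RF", "GA-BP"))
    stop_config("kind", "must be one of XGBoost, RF, GA-BP")
  X <- as.matrix(X)
  if (nrow(X) < 6) stop("need at least 6 training rows")
  if (nrow(X) != length(y)) stop("X rows must match length(y)")
  fit <- switch(kind,
    XGBoost = {
      p <- cfg$xgboost
      dtr <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
      xgboost::xgb.train(params = list(objective = "reg:squarederror",
                                       eta = p$learning_rate,
                                       max_depth = p$max_depth,
                                       nthread = 1, seed = seed),
                         data = dtr, nrounds = p$n_estimators, verbose = 0)
    },
    RF = with_seed(seed,
      randomForest::randomForest(X, y, ntree = cfg$random_forest$n_trees)),
    `GA-BP` = train_gabp(X, y, cfg$gabp, seed = seed))
  structure(list(kind = kind, fit = fit, n_features = ncol(X),
                 feature_names = colnames(X), seed = seed,
                 hyperparameters = switch(kind, XGBoost = cfg$xgboost,
                                          RF = cfg$random_forest,
                                          `GA-BP` = unclass(cfg$gabp))),
            class = "smc_model")
}

#' Predict from a fitted learner
#' @param object an `smc_model`
#' @param newdata matrix of predictors
#' @param ... ignored
#' @return numeric vector of predictions
#' @export
predict.smc_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features)
    stop("newdata has ", ncol(newdata), " features; model expects ",
         object$n_features)
  as.numeric(predict(object$fit, newdata))
}

#' Regression validation metrics
#'
#' Coefficient of determination, root-mean-square error, and mean relative
#' error of predictions against observations:
#' `R2 = 1 - sum((yhat-y)^2) / sum((y-ybar)^2)`,
#' `RMSE = sqrt(mean((yhat-y)^2))`,
#' `MRE = 100 * mean(|yhat-y| / y)`.
#' RMSE carries the units of `y` (percent SMC in the pipeline); MRE is a
#' percentage and requires strictly positive observations.
#'
#' `printed_variants = TRUE` additionally returns the literal transcription
#' forms `r2_printed = sum((yhat-ybar)^2)/sum((y-ybar)^2)` and
#' `rmse_printed = sqrt(mean((y-ybar)^2))`, kept only for comparison: the
#' latter does not depend on the predictions at all.
#'
#' @param y observed values
#' @param yhat predicted values
#' @param printed_variants also return the literal-transcription variants
#' @return named numeric vector `r2`, `rmse`, `mre` (plus the printed
#'   variants when requested)
#' @examples
#' metrics <- regression_metrics(c(10, 20, 30), c(12, 18, 33))
#' round(metrics["rmse"], 3)  # 2.380
#' @export
regression_metrics <- function(y, yhat, printed_variants = FALSE) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  if (length(y) < 2) stop("need at least 2 observations")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("R2 undefined: zero target variance")
  if (any(y == 0)) stop("MRE undefined: zero observation")
  sse <- sum((yhat - y)^2)
  out <- c(r2 = 1 - sse / sst,
           rmse = sqrt(mean((yhat - y)^2)),
           mre = 100 * mean(abs(yhat - y) / abs(y)))
  if (printed_variants) {
    out <- c(out,
             r2_printed = sum((yhat - mean(y))^2) / sst,
             rmse_printed = sqrt(mean((y - mean(y))^2)))
  }
  out
}

#' Input combinations of the evaluation matrix
#'
#' The ten single- and fused-input variable sets evaluated per depth layer:
#' each element names the feature families pooled into the model input.
#' @export
INPUT_COMBINATIONS <- list(
  "VIs" = "VIs", "TF" = "TF", "TIs" = "TIs", "TVIs" = "TVIs",
  "VIs+TIs" = c("VIs", "TIs"),
  "TVIs+VIs" = c("TVIs", "VIs"),
  "TVIs+TIs" = c("TVIs", "TIs"),
  "VIs+TIs+TVIs" = c("VIs", "TIs", "TVIs"),
  "VIs+TIs+TF" = c("VIs", "TIs", "TF"),
  "VIs+TIs+TF+TVIs" = c("VIs", "TIs", "TF", "TVIs"))

#' Evaluate single- and fused-input models over layers
#'
#' For each depth layer, input combination, and learner: restricts the
#' layer's feature table to the screened (selected) features of the
#' combination's families, fits on the training split, and reports
#' validation R2, RMSE, and MRE. SMC is modelled in percent units. A
#' combination with no selected feature in any of its families is recorded
#' as a missing row with a reason, not an error.
#'
#' @param tables_by_layer named list (layer -> plots x features matrix with
#'   plot IDs as row names)
#' @param screening_by_layer named list (layer -> data.frame from
#'   [screen_features()])
#' @param truth ground-truth data.frame with `plot_id` and one `smc_*`
#'   column per layer (fractions)
#' @param split list from [split_data()] over the plot IDs
#' @param cfg a [learner_config()]
#' @param combos named list of family sets (default [INPUT_COMBINATIONS])
#' @param models which learners to run
#' @param seed integer seed forwarded to every learner
#' @return data.frame with columns `layer`, `combination`, `model`, `r2`,
#'   `rmse_pct`, `mre_pct`, `n_features`, `note`
#' @export
evaluate_combinations <- function(tables_by_layer, screening_by_layer, truth,
                                  split, cfg = learner_config(),
                                  combos = INPUT_COMBINATIONS,
                                  models = c("XGBoost", "RF", "GA-BP"),
                                  seed = 1L) {
  layers <- names(tables_by_layer)
  smc_cols <- layer_smc_columns(layers, truth)
  rows <- list()
  for (ly in layers) {
    tab <- as.matrix(tables_by_layer[[ly]])
    scr <- screening_by_layer[[ly]]
    y_all <- truth[[smc_cols[[ly]]]] * 100  # percent SMC
    names(y_all) <- truth$plot_id
    tr <- intersect(split$train_ids, rownames(tab))
    va <- intersect(split$validation_ids, rownames(tab))
    for (cb in names(combos)) {
      fams <- combos[[cb]]
      feats <- scr$feature[scr$selected & scr$family %in% fams]
      feats <- intersect(colnames(tab), feats)
      for (md in models) {
        if (length(feats) == 0) {
          rows[[length(rows) + 1]] <- data.frame(
            layer = ly, combination = cb, model = md, r2 = NA_real_,
            rmse_pct = NA_real_, mre_pct = NA_real_, n_features = 0L,
            note = "no selected features in families", stringsAsFactors = FALSE)
          next
        }
        fit <- train_model(md, tab[tr, feats, drop = FALSE], y_all[tr],
                           cfg = cfg, seed = seed)
        yhat <- predict(fit, tab[va, feats, drop = FALSE])
        m <- regression_metrics(y_all[va], yhat)
        rows[[length(rows) + 1]] <- data.frame(
          layer = ly, combination = cb, model = md, r2 = m[["r2"]],
          rmse_pct = m[["rmse"]], mre_pct = m[["mre"]],
          n_features = length(feats), note = "", stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

LAYER_NAMES <- c("0-20", "20-40", "40-60")
LAYER_SMC_COLUMNS <- c(`0-20` = "smc_0_20", `20-40` = "smc_20_40",
                       `40-60` = "smc_40_60")

layer_smc_columns <- function(layers, truth) {
  cols <- LAYER_SMC_COLUMNS[layers]
  if (any(is.na(cols)) || !all(cols %in% names(truth)))
    stop("truth is missing SMC columns for layers: ",
         paste(layers[is.na(cols) | !(cols %in% names(truth))], collapse = ", "))
  as.list(cols)
}
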