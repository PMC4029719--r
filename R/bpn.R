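#' Build a labeled dataset from recordings
#'
#' Runs every recording through the conditioning chain ([preprocess()]) and
#' overlapped-window RMS extraction ([rms_windows()]); the regression target
#' of each window is the elbow angle at the window-end sample (causal label
#' alignment: the controller only ever knows the angle up to "now").
#'
#' @param recordings A list of `emg_recording` objects (or a single one).
#' @param window A [window_spec()].
#' @return A `labeled_dataset`: `features` (n x 4 RMS matrix), `targets`
#'   (angles in degrees), `trial_ids` (integer provenance of each row), and
#'   `n_skipped` (trials shorter than one window, dropped with a warning).
#' @export
make_dataset <- function(recordings, window = window_spec(fs_hz = 1024)) {
  if (inherits(recordings, "emg_recording")) recordings <- list(recordings)
  if (length(recordings) == 0L) stop("`recordings` must be nonempty")
  feats <- vector("list", length(recordings))
  targs <- vector("list", length(recordings))
  ids <- vector("list", length(recordings))
  n_skipped <- 0L
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    if (ncol(rec$emg_uV) < window$length_samples) {
      n_skipped <- n_skipped + 1L
      next
    }
    ff <- rms_windows(preprocess(rec), window)
    feats[[i]] <- ff$rms_uV
    targs[[i]] <- rec$angle_deg[ff$end_samples]
    ids[[i]] <- rep.int(i, nrow(ff$rms_uV))
  }
  if (n_skipped > 0L)
    warning(n_skipped, " trial(s) shorter than one window were skipped")
  features <- do.call(rbind, feats)
  if (is.null(features)) stop("no trial long enough for a single window")
  structure(list(features = features, targets = unlist(targs),
                 trial_ids = unlist(ids), n_skipped = n_skipped),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: %d windows from %d trials\n",
              nrow(x$features), length(unique(x$trial_ids))))
  invisible(x)
}

#' Split a dataset into training and testing trials
#'
#' The split is at whole-trial granularity: the 60 movement sets of a
#' session are partitioned into round(n_trials * train_fraction) training
#' trials (48 at the protocol's 80%) and the rest for testing. Splitting at
#' window level would leak temporally correlated samples between the sides.
#'
#' @param dataset A `labeled_dataset` from [make_dataset()].
#' @param train_fraction Fraction of trials assigned to training
#'   (default 0.8).
#' @param seed RNG seed for the random trial assignment.
#' @return List with `train` and `test` labeled datasets and the selected
#'   `train_trials` / `test_trials` id vectors.
#' @export
split_data <- function(dataset, train_fraction = 0.8, seed = 1L) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie in (0, 1)")
  trials <- unique(dataset$trial_ids)
  if (length(trials) < 2L)
    stop("cannot split: need at least 2 trials")
  n_train <- round(length(trials) * train_fraction)
  n_train <- min(max(n_train, 1L), length(trials) - 1L)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  train_trials <- sort(sample(trials, n_train))
  test_trials <- setdiff(trials, train_trials)
  subset_rows <- function(keep) {
    idx <- dataset$trial_ids %in% keep
    structure(list(features = dataset$features[idx, , drop = FALSE],
                   targets = dataset$targets[idx],
                   trial_ids = dataset$trial_ids[idx],
                   n_skipped = 0L),
              class = "labeled_dataset")
  }
  list(train = subset_rows(train_trials), test = subset_rows(test_trials),
       train_trials = train_trials, test_trials = test_trials)
}

#' Training hyperparameters for the network
#'
#' Plain full-batch gradient descent on the mean squared error of the
#' scaled output; the simplest faithful back-propagation scheme.
#'
#' @param learning_rate Gradient step size (default 2).
#' @param max_epochs Epoch cap (default 3000).
#' @param tol Stop when the epoch-to-epoch improvement of the mean squared
#'   error falls below `tol` (default 1e-8).
#' @param seed Initialization seed.
#' @return A `train_spec` object.
#' @export
train_spec <- function(learning_rate = 2, max_epochs = 3000L, tol = 1e-8,
                       seed = 1L) {
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (max_epochs < 1) stop("max_epochs must be >= 1")
  if (tol < 0) stop("tol must be >= 0")
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs), tol = tol,
                 seed = as.integer(seed)),
            class = "train_spec")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Min-max scaler: per-feature affine map onto [0, 1] fit on training data.
fit_input_scaler <- function(features) {
  lo <- apply(features, 2L, min)
  hi <- apply(features, 2L, max)
  rng <- hi - lo
  rng[rng == 0] <- 1   # constant feature maps to 0
  list(lo = lo, range = rng)
}

apply_input_scaler <- function(features, scaler) {
  sweep(sweep(features, 2L, scaler$lo, "-"), 2L, scaler$range, "/")
}

# Sigmoid output cannot reach 0/1, so the angle range maps onto
# [0.05, 0.95] to keep the extreme targets off the saturated tail.
angle_scaler <- function(angle_min_deg = 0, angle_max_deg = 90,
                         margin = 0.05) {
  list(angle_min = angle_min_deg, angle_max = angle_max_deg,
       y_min = margin, y_max = 1 - margin)
}

angle_to_unit <- function(angle_deg, sc) {
  sc$y_min + (angle_deg - sc$angle_min) / (sc$angle_max - sc$angle_min) *
    (sc$y_max - sc$y_min)
}

unit_to_angle <- function(y, sc) {
  sc$angle_min + (y - sc$y_min) / (sc$y_max - sc$y_min) *
    (sc$angle_max - sc$angle_min)
}

new_bpn_model <- function(W1, b1, w2, b2, input_scaler, angle_sc, seed) {
  structure(list(W1 = W1, b1 = b1, w2 = w2, b2 = b2,
                 input_scaler = input_scaler, angle_scaler = angle_sc,
                 seed = seed),
            class = "bpn_model")
}

#' Initialize a 4-3-1 sigmoid network
#'
#' Four input nodes (the four muscles' RMS), three hidden sigmoid nodes and
#' one sigmoid output node; weights drawn uniformly from \[-0.5, 0.5\].
#' Biases are included in both layers: a bias-free sigmoid output could not
#' represent 0 degrees at zero input.
#'
#' @param seed Initialization seed.
#' @param input_scaler,angle_sc Scalers (defaults: identity placeholder
#'   replaced during training; angles \[0, 90\] onto \[0.05, 0.95\]).
#' @return A `bpn_model`.
#' @export
bpn_init <- function(seed = 1L,
                     input_scaler = list(lo = rep(0, 4), range = rep(1, 4)),
                     angle_sc = angle_scaler()) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  W1 <- matrix(stats::runif(12, -0.5, 0.5), nrow = 4L, ncol = 3L)
  b1 <- stats::runif(3, -0.5, 0.5)
  w2 <- stats::runif(3, -0.5, 0.5)
  b2 <- stats::runif(1, -0.5, 0.5)
  new_bpn_model(W1, b1, w2, b2, input_scaler, angle_sc, as.integer(seed))
}

#' @export
print.bpn_model <- function(x, ...) {
  cat("bpn_model: 4-3-1 sigmoid network, angle range [",
      x$angle_scaler$angle_min, ",", x$angle_scaler$angle_max, "] deg\n")
  invisible(x)
}

# Forward pass on raw (unscaled) feature rows; returns intermediates for
# back-propagation.
bpn_forward_pass <- function(model, features) {
  X <- apply_input_scaler(features, model$input_scaler)
  H <- sigmoid(sweep(X %*% model$W1, 2L, model$b1, "+"))
  y <- sigmoid(drop(H %*% model$w2) + model$b2)
  list(X = X, H = H, y = y)
}

#' Predict elbow angles from RMS feature rows
#'
#' @param model A trained `bpn_model`.
#' @param features Numeric 4-vector or n x 4 matrix of raw RMS features.
#' @return Predicted angle(s) in degrees, strictly inside the scaler's
#'   angle range extended by its sigmoid margins.
#' @export
bpn_predict <- function(model, features) {
  stopifnot(inherits(model, "bpn_model"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  if (ncol(features) != 4L) stop("invalid input: expected 4 features")
  if (anyNA(features) || any(!is.finite(features)))
    stop("invalid input: non-finite features")
  unit_to_angle(bpn_forward_pass(model, features)$y, model$angle_scaler)
}

# Mean-squared-error gradients of the scaled output over a batch; the
# analytic counterpart of the finite-difference oracle used in tests.
bpn_gradients <- function(model, features, targets_unit) {
  fp <- bpn_forward_pass(model, features)
  n <- nrow(fp$X)
  err <- fp$y - targets_unit                 # d(MSE)/dy * n/2
  delta_out <- 2 * err * fp$y * (1 - fp$y) / n
  gw2 <- unname(drop(crossprod(fp$H, delta_out)))
  gb2 <- sum(delta_out)
  delta_h <- (delta_out %o% model$w2) * fp$H * (1 - fp$H)
  gW1 <- unname(crossprod(fp$X, delta_h))
  gb1 <- unname(colSums(delta_h))
  loss <- mean(err^2)
  list(gW1 = gW1, gb1 = gb1, gw2 = gw2, gb2 = gb2, loss = loss)
}

#' Train the network by full-batch gradient descent
#'
#' Fits the input scaler on the training features only, maps target angles
#' onto the sigmoid output range, and runs plain gradient descent on the
#' mean squared error of the scaled output. Deterministic given the seed
#' carried by `spec`.
#'
#' @param dataset A `labeled_dataset` (training split).
#' @param spec A [train_spec()].
#' @param angle_sc Angle scaler (default \[0, 90\] degrees onto
#'   \[0.05, 0.95\]).
#' @return List with `model` (a `bpn_model`) and `loss` (per-epoch mean
#'   squared error of the scaled output, including the initial state).
#' @export
bpn_train <- function(dataset, spec = train_spec(),
                      angle_sc = angle_scaler()) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(spec, "train_spec"))
  if (nrow(dataset$features) == 0L) stop("empty training dataset")
  scaler <- fit_input_scaler(dataset$features)
  model <- bpn_init(spec$seed, input_scaler = scaler, angle_sc = angle_sc)
  t_unit <- angle_to_unit(dataset$targets, angle_sc)
  X <- dataset$features
  loss <- numeric(spec$max_epochs + 1L)
  g <- bpn_gradients(model, X, t_unit)
  loss[1L] <- g$loss
  n_done <- 0L
  for (epoch in seq_len(spec$max_epochs)) {
    model$W1 <- model$W1 - spec$learning_rate * g$gW1
    model$b1 <- model$b1 - spec$learning_rate * g$gb1
    model$w2 <- model$w2 - spec$learning_rate * g$gw2
    model$b2 <- model$b2 - spec$learning_rate * g$gb2
    g <- bpn_gradients(model, X, t_unit)
    if (!is.finite(g$loss))
      stop("training failure: loss became non-finite at epoch ", epoch)
    loss[epoch + 1L] <- g$loss
    n_done <- epoch
    if (loss[epoch] - loss[epoch + 1L] >= 0 &&
        loss[epoch] - loss[epoch + 1L] < spec$tol) break
  }
  list(model = model, loss = loss[seq_len(n_done + 1L)])
}

#' Serialize / restore a trained model as JSON
#'
#' @param model A `bpn_model`.
#' @param path File path.
#' @return `bpn_load` returns the restored `bpn_model`.
#' @export
bpn_save <- function(model, path) {
  stopifnot(inherits(model, "bpn_model"))
  obj <- list(W1 = model$W1, b1 = model$b1, w2 = model$w2, b2 = model$b2,
              input_scaler = model$input_scaler,
              angle_scaler = model$angle_scaler, seed = model$seed)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname bpn_save
#' @export
bpn_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_bpn_model(matrix(obj$W1, nrow = 4L), obj$b1, obj$w2, obj$b2,
                obj$input_scaler, obj$angle_scaler, obj$seed)
}
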