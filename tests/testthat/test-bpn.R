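test_that("make_dataset rows follow the window-count formula", {
  rec <- small_trial(21, period_s = 4)
  w <- small_window()
  ds <- make_dataset(list(rec), w)
  expect_identical(nrow(ds$features), n_windows(4096, w))
  expect_identical(ncol(ds$features), 4L)
  expect_length(ds$targets, nrow(ds$features))
})

test_that("zero EMG gives zero features with trajectory targets", {
  cfg <- trial_config(period_s = 2, seed = 1, amplitude_scale_uV = 1e-12)
  rec <- generate_trial(cfg)
  rec$emg_uV[] <- 0
  ds <- make_dataset(list(rec), small_window())
  expect_true(all(ds$features == 0))
  ff <- rms_windows(preprocess(rec), small_window())
  expect_equal(ds$targets, rec$angle_deg[ff$end_samples])
})

test_that("make_dataset is order independent up to row permutation", {
  recs <- lapply(31:33, small_trial)
  w <- small_window()
  d1 <- make_dataset(recs, w)
  d2 <- make_dataset(rev(recs), w)
  k1 <- apply(cbind(d1$features, d1$targets), 1, paste, collapse = ",")
  k2 <- apply(cbind(d2$features, d2$targets), 1, paste, collapse = ",")
  expect_setequal(k1, k2)
})

test_that("short trials are skipped with a warning", {
  long <- small_trial(34)
  short <- long
  short$emg_uV <- short$emg_uV[, 1:50]
  short$angle_deg <- short$angle_deg[1:50]
  expect_warning(ds <- make_dataset(list(long, short), small_window()),
                 "skipped")
  expect_identical(ds$n_skipped, 1L)
})

test_that("split_data: protocol counts, determinism, guards", {
  ds <- structure(list(features = matrix(rnorm(240), ncol = 4),
                       targets = runif(60, 0, 90),
                       trial_ids = rep(1:60, each = 1), n_skipped = 0L),
                  class = "labeled_dataset")
  sp <- split_data(ds, 0.8, seed = 5)
  expect_length(sp$train_trials, 48)
  expect_length(sp$test_trials, 12)
  expect_length(intersect(sp$train_trials, sp$test_trials), 0)
  sp2 <- split_data(ds, 0.8, seed = 5)
  expect_identical(sp$train_trials, sp2$train_trials)

  ds10 <- ds; ds10$trial_ids <- rep(1:10, 6)
  sp10 <- split_data(ds10, 0.5, seed = 1)
  expect_length(sp10$train_trials, 5)

  ds1 <- ds; ds1$trial_ids <- rep(1L, 60)
  expect_error(split_data(ds1, 0.8), "cannot split")
  expect_error(split_data(ds, 1.2), "train_fraction")
})

test_that("split is at trial granularity", {
  recs <- lapply(41:45, small_trial)
  ds <- make_dataset(recs, small_window())
  sp <- split_data(ds, 0.8, seed = 2)
  expect_length(intersect(unique(sp$train$trial_ids),
                          unique(sp$test$trial_ids)), 0)
})

test_that("forward pass: zero weights give the angle midpoint", {
  m <- bpn_init(1)
  m$W1[] <- 0; m$b1[] <- 0; m$w2[] <- 0; m$b2 <- 0
  expect_equal(bpn_predict(m, c(10, 20, 30, 40)), 45)
  expect_error(bpn_predict(m, c(1, NA, 3, 4)), "invalid input")
  expect_error(bpn_predict(m, c(1, 2, 3)), "4 features")
})

test_that("predictions stay inside the extended scaler range", {
  m <- bpn_init(2)
  set.seed(4)
  X <- matrix(runif(400, 0, 1e4), ncol = 4)
  p <- bpn_predict(m, X)
  sc <- m$angle_scaler
  lo <- promyo:::unit_to_angle(0, sc)
  hi <- promyo:::unit_to_angle(1, sc)
  expect_true(all(p > lo & p < hi))
})

test_that("analytic gradients match central finite differences", {
  # independent oracle: perturb every parameter of random 4-3-1 instances
  # h = 1e-5 balances truncation against cancellation for a loss of
  # magnitude ~1e-1; elements below 1e-4 are numerically zero at that
  # scale and enter the comparison absolutely.
  set.seed(7)
  h <- 1e-5
  max_rel <- 0
  for (i in 1:100) {
    m <- bpn_init(i)
    X <- matrix(runif(20, 0, 1), ncol = 4)
    t_unit <- runif(5, 0.05, 0.95)
    g <- promyo:::bpn_gradients(m, X, t_unit)
    loss_at <- function(model) {
      y <- promyo:::bpn_forward_pass(model, X)$y
      mean((y - t_unit)^2)
    }
    params <- list(c("W1", "gW1"), c("b1", "gb1"), c("w2", "gw2"),
                   c("b2", "gb2"))
    for (p in params) {
      analytic <- g[[p[2]]]
      for (j in seq_along(analytic)) {
        mp <- m; mm <- m
        mp[[p[1]]][j] <- mp[[p[1]]][j] + h
        mm[[p[1]]][j] <- mm[[p[1]]][j] - h
        fd <- (loss_at(mp) - loss_at(mm)) / (2 * h)
        denom <- max(abs(fd), abs(analytic[j]), 1e-4)
        max_rel <- max(max_rel, abs(fd - analytic[j]) / denom)
      }
    }
  }
  expect_lt(max_rel, 1e-6)
})

test_that("training fits an affine single-feature relation to < 2 deg", {
  set.seed(8)
  f1 <- runif(300, 0, 100)
  ds <- structure(list(features = cbind(f1, 0, 0, 0),
                       targets = 10 + 0.7 * f1,
                       trial_ids = rep(1:30, each = 10), n_skipped = 0L),
                  class = "labeled_dataset")
  fit <- bpn_train(ds, train_spec(seed = 1))
  pred <- bpn_predict(fit$model, ds$features)
  expect_lt(sqrt(mean((pred - ds$targets)^2)), 2)
})

test_that("learning_rate edge cases and determinism", {
  recs <- lapply(51:52, small_trial)
  ds <- make_dataset(recs, small_window())
  tiny <- train_spec(learning_rate = 1e-30, max_epochs = 5, seed = 2)
  fit0 <- bpn_train(ds, tiny)
  init <- bpn_init(2, input_scaler = fit0$model$input_scaler)
  expect_equal(fit0$model$W1, init$W1, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(diff(fit0$loss), rep(0, length(fit0$loss) - 1),
               tolerance = 1e-10)

  s1 <- bpn_train(ds, train_spec(max_epochs = 50, seed = 9))
  s2 <- bpn_train(ds, train_spec(max_epochs = 50, seed = 9))
  expect_identical(s1$model, s2$model)
  expect_error(train_spec(learning_rate = 0), "learning_rate")
})

test_that("training loss never ends above its start (default spec)", {
  for (s in 1:3) {
    recs <- lapply(s * 10 + 1:3, small_trial)
    ds <- make_dataset(recs, small_window())
    fit <- bpn_train(ds, train_spec(max_epochs = 300, seed = s))
    expect_lte(fit$loss[length(fit$loss)], fit$loss[1])
  }
})

test_that("predictions are invariant to a global feature rescale", {
  recs <- lapply(61:62, small_trial)
  ds <- make_dataset(recs, small_window())
  fit1 <- bpn_train(ds, train_spec(max_epochs = 200, seed = 4))
  ds2 <- ds
  ds2$features <- ds$features * 37
  fit2 <- bpn_train(ds2, train_spec(max_epochs = 200, seed = 4))
  p1 <- bpn_predict(fit1$model, ds$features)
  p2 <- bpn_predict(fit2$model, ds2$features)
  expect_equal(p1, p2, tolerance = 1e-8)
})

test_that("model JSON round-trip preserves predictions", {
  m <- small_model()
  path <- tempfile(fileext = ".json")
  bpn_save(m, path)
  m2 <- bpn_load(path)
  X <- matrix(runif(40, 0, 500), ncol = 4)
  expect_equal(bpn_predict(m2, X), bpn_predict(m, X), tolerance = 1e-12)
})
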