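# Metrics, two-phase training contracts, masked multitarget optimization,
# cross-validation harness.

test_that("masked_metrics follows its definition", {
  # direct formula evaluation
  m <- masked_metrics(matrix(c(2, 2, 2), 3, 3), matrix(c(1, 2, 3), 3, 3),
                      matrix(1, 3, 3))
  expect_equal(m$lambda_abs$mae, 2 / 3)
  expect_equal(m$lambda_abs$rmse, sqrt(2 / 3))
  expect_equal(m$lambda_abs$r2, 0)

  # perfect predictions
  Y <- matrix(c(1, 2, 3, 4, 5, 6), 2, 3)
  p <- masked_metrics(Y, Y, matrix(1, 2, 3))
  expect_equal(p$lambda_abs$mae, 0)
  expect_equal(p$lambda_ems$rmse, 0)
  expect_equal(p$log_plqy$r2, 1)

  # all-masked target is absent with a warning, never NaN
  M <- matrix(1, 2, 3); M[, 2] <- 0
  expect_warning(m2 <- masked_metrics(Y, Y, M), "absent")
  expect_null(m2$lambda_ems)
  expect_named(m2, c("lambda_abs", "log_plqy"))
})

test_that("masked_metrics agrees with a brute-force loop oracle", {
  for (q in 1:30) {
    n <- with_seed_test(q, sample(5:40, 1))
    P <- with_seed_test(q + 100, matrix(stats::rnorm(n * 3, 400, 50), n, 3))
    Y <- with_seed_test(q + 200, matrix(stats::rnorm(n * 3, 400, 50), n, 3))
    M <- with_seed_test(q + 300, matrix(stats::rbinom(n * 3, 1, 0.7), n, 3))
    for (k in 1:3) if (sum(M[, k]) < 2) M[1:2, k] <- 1
    Y[M == 0] <- NA_real_
    got <- masked_metrics(P, Y, M)
    for (k in 1:3) {
      errs <- c(); obs <- c()
      for (i in 1:n) if (M[i, k] == 1) {
        errs <- c(errs, P[i, k] - Y[i, k]); obs <- c(obs, Y[i, k])
      }
      g <- got[[target_names()[k]]]
      expect_equal(g$mae, mean(abs(errs)), tolerance = 1e-10)
      expect_equal(g$rmse, sqrt(mean(errs^2)), tolerance = 1e-10)
      expect_equal(g$r2, 1 - sum(errs^2) / sum((obs - mean(obs))^2),
                   tolerance = 1e-10)
      expect_equal(g$n, length(errs))
    }
  }
})

short_schedule <- function(p1 = 4L, p2 = 2L, seed = 5L)
  train_schedule(phase1_epochs = p1, phase2_epochs = p2, patience = 10L,
                 batch_size = 16L, seed = seed)

test_that("phase 1 leaves encoder parameters bit-identical; phase 2 moves them", {
  fix <- small_train_fixture()
  ds <- sc_dataset(fix$dataset$records[1:120])
  sp <- scaffold_split(ds, seed = 2)
  m <- model_init(tiny_model_config(), seed = 4)
  snap_backbone <- m$params$backbone
  snap_solvent <- m$params$solvent

  st1 <- two_phase_train(m, ds, sp, short_schedule(p1 = 3L, p2 = 0L))
  expect_identical(st1$model$params$backbone, snap_backbone)
  expect_identical(st1$model$params$solvent[c("Wi", "Wm", "Wa")],
                   snap_solvent[c("Wi", "Wm", "Wa")])
  expect_false(identical(unlist(st1$model$params$head),
                         unlist(m$params$head)))

  st2 <- two_phase_train(m, ds, sp, short_schedule(p1 = 2L, p2 = 2L))
  # the optimizer moved every unfrozen group (the returned model may still be
  # the phase-1 checkpoint if validation never improved, so inspect the final
  # optimizer state)
  expect_false(identical(st2$final_params$backbone$emb_el, snap_backbone$emb_el))
  expect_false(identical(st2$final_params$solvent$Wi, snap_solvent$Wi))
  expect_gt(st2$update_counts[["backbone"]], 0)
})

test_that("training is deterministic given identical config and seed", {
  fix <- small_train_fixture()
  ds <- sc_dataset(fix$dataset$records[1:100])
  sp <- scaffold_split(ds, seed = 3)
  run <- function() {
    m <- model_init(tiny_model_config(), seed = 9)
    two_phase_train(m, ds, sp, short_schedule(p1 = 2L, p2 = 2L, seed = 9))
  }
  a <- run(); b <- run()
  expect_identical(a$history, b$history)
  expect_identical(a$best_val, b$best_val)
  expect_identical(unlist(a$model$params), unlist(b$model$params))
})

test_that("training reduces validation error on fixture data", {
  fix <- small_train_fixture()
  sp <- scaffold_split(fix$dataset, seed = 7)
  m <- model_init(tiny_model_config(), seed = 11)
  st <- two_phase_train(m, fix$dataset, sp,
                        train_schedule(phase1_epochs = 10L, phase2_epochs = 5L,
                                       patience = 10L, seed = 11))
  h <- st$history$val_metric
  # smoothed decrease: best of the last third beats the first evaluation
  expect_lt(min(utils::tail(h, ceiling(length(h) / 3))), h[1])
  # early stopping selected the best recorded validation metric
  expect_equal(st$best_val, min(h))
})

test_that("masking one target everywhere reproduces two-target training", {
  fix <- small_train_fixture()
  ds <- sc_dataset(fix$dataset$records[1:100])
  # force full observation of the first two targets for a clean comparison
  for (i in seq_along(ds$records)) {
    tr <- fix$truth[fix$truth$record == i, ]
    ds$records[[i]]$targets <- stats::setNames(
      c(tr$lambda_abs, tr$lambda_ems, log10(tr$plqy)), target_names())
    ds$records[[i]]$mask <- c(1L, 1L, 1L)
  }
  ds_masked <- ds
  for (i in seq_along(ds_masked$records)) {
    ds_masked$records[[i]]$mask[3] <- 0L
    ds_masked$records[[i]]$targets[3] <- NA_real_
  }
  sp <- scaffold_split(ds, seed = 5)
  sch <- train_schedule(phase1_epochs = 2L, phase2_epochs = 1L,
                        patience = 5L, seed = 13, val_metric = "loss")
  mA <- model_init(tiny_model_config(), seed = 13)
  trA <- two_phase_train(mA, ds_masked, sp, sch, targets = target_names())
  mB <- model_init(tiny_model_config(), seed = 13)
  trB <- two_phase_train(mB, ds, sp, sch,
                         targets = c("lambda_abs", "lambda_ems"))
  expect_equal(trA$history$train_loss, trB$history$train_loss,
               tolerance = 1e-12)
})

test_that("multitarget batches give zero gradient to rows of unobserved heads", {
  fix <- tiny_fixture()
  rec <- fix$dataset$records[[1]]
  rec$mask <- c(1L, 0L, 0L)
  rec$targets[2:3] <- NA_real_
  m <- model_init(tiny_model_config(), seed = 2)
  m$norm <- list(mu = c(380, 420, -0.5), sd = c(40, 45, 0.3))
  rg <- solvachrom:::record_grad(m, rec, NULL, targets = target_names())
  # output-layer columns for the unobserved targets receive no gradient
  expect_true(all(rg$grads$head$W2[, 2:3] == 0))
  expect_true(all(rg$grads$head$b2[2:3] == 0))
  expect_gt(max(abs(rg$grads$head$W2[, 1])), 0)
})

test_that("solvent-encoder pretraining trains on TRAIN only and freezes", {
  fix <- small_train_fixture()
  ds <- sc_dataset(fix$dataset$records[1:120])
  sp <- scaffold_split(ds, seed = 4)
  pre <- pretrain_solvent_encoder(ds, sp, width = 16, depth = 1,
                                  epochs = 4, seed = 6)
  expect_true(pre$frozen)
  # access log: only TRAIN record keys were touched
  train_keys <- vapply(split_indices(sp, "TRAIN"), function(i)
    solvachrom:::record_key(ds$records[[i]]), "")
  expect_true(all(pre$accessed_keys %in% train_keys))
  # loss decreases from initialization over the schedule
  expect_lt(utils::tail(pre$history$train_loss, 1), pre$history$train_loss[1])
  # frozen encoder is a deterministic embedding source
  solv <- ds$records[[1]]$solvent
  expect_identical(encode_2d(solv, pre$params), encode_2d(solv, pre$params))
})

test_that("cross-validation summary is exactly recomputable and exclusions are fold-local", {
  fix <- small_train_fixture()
  ds <- sc_dataset(fix$dataset$records[1:160])
  sch <- short_schedule(p1 = 2L, p2 = 0L)
  factory <- function(s) model_init(tiny_model_config("NONE"), seed = s)
  cv <- crossvalidate(factory, ds, k = 3, seed = 21, schedule = sch)

  # summary equals direct recomputation from per-fold values
  for (nm in names(cv$folds[[1]])) {
    vals <- vapply(cv$folds, function(f) f[[nm]]$mae, 0)
    row <- cv$summary[cv$summary$target == nm & cv$summary$metric == "mae", ]
    expect_equal(row$mean, mean(vals), tolerance = 1e-12)
    expect_equal(row$sd, stats::sd(vals), tolerance = 1e-12)
  }

  # every record is TEST-evaluated exactly once
  splits <- scaffold_kfold(ds, 3, seed = 21)
  expect_equal(sort(unlist(lapply(splits, split_indices, "TEST"))),
               seq_along(ds$records))

  # an exclusion list shrinks only the affected fold's record counts
  keys <- vapply(ds$records, solvachrom:::record_key, "")
  victim_fold <- 2L
  victim_idx <- split_indices(splits[[victim_fold]], "TEST")[1:3]
  cv2 <- crossvalidate(factory, ds, k = 3, seed = 21, schedule = sch,
                       exclusions = keys[victim_idx])
  expect_equal(cv2$excluded_per_fold[victim_fold], 3L)
  n_of <- function(cvr, f) cvr$folds[[f]]$lambda_abs$n
  for (f in 1:3) {
    if (f == victim_fold)
      expect_lt(n_of(cv2, f), n_of(cv, f))
    else expect_equal(n_of(cv2, f), n_of(cv, f))
  }
})
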