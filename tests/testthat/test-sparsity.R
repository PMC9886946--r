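test_that("profiled zero fractions match a per-instance recount of reference gradients", {
  spec <- build_tree3(toy_config(filters = 2, branches = 4, side = 12,
                                 classes = 10))
  task <- generate_synthetic_task(synthetic_task_config(
    train_per_class = 4, test_per_class = 2, seed = 9))
  params <- init_params(spec, seed = 2)
  prof <- profile_zero_fraction(spec, params, task$test)
  expect_true(all(prof$per_layer$zero_fraction >= 0 &
                    prof$per_layer$zero_fraction <= 1))

  n <- dim(task$test$x)[4]
  fr <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    x <- array(task$test$x[, , , i], dim(task$test$x)[1:3])
    tr <- forward_pass(spec, params, x)
    zeros <- instance_zero_recount(spec, params, tr, task$test$y[i])
    totals <- c(count_gradient_instances(spec, "conv"),
                count_gradient_instances(spec, "tree"),
                count_gradient_instances(spec, "fc"))
    fr[i, ] <- zeros / totals
  }
  expect_equal(prof$per_layer$zero_fraction, colMeans(fr), tolerance = 1e-12)
  expect_equal(prof$per_layer$sd, apply(fr, 2, sd), tolerance = 1e-12)
  # whole-step fraction is the instance-weighted mean, dominated by conv
  inst <- prof$per_layer$instances
  expect_equal(prof$whole_step,
               sum(prof$per_layer$zero_fraction * inst) / sum(inst),
               tolerance = 1e-12)
  expect_lt(abs(prof$whole_step - prof$per_layer$zero_fraction[1]), 0.05)
})

test_that("forced activation patterns give the expected extreme fractions", {
  spec <- build_tree3(toy_config(side = 8))
  params <- init_params(spec, seed = 3)
  params$conv <- -abs(params$conv)
  x <- abs(random_image(spec, 4))
  batch <- image_batch(array(x, c(dim(x), 1)), 1L, classes = 3L)
  prof <- profile_zero_fraction(spec, params, batch)
  expect_equal(prof$per_layer$zero_fraction[1], 1)  # conv all inactive

  # identity-like regime: sigmoid derivatives never vanish, so the fc layer
  # has no structural zeros when tree activations are nonzero
  spec2 <- build_tree3(toy_config(side = 8, activation = "sigmoid"))
  params2 <- init_params(spec2, seed = 5)
  batch2 <- image_batch(array(random_image(spec2, 6), c(1, 8, 8, 1)),
                        1L, classes = 3L)
  prof2 <- profile_zero_fraction(spec2, params2, batch2)
  expect_equal(prof2$per_layer$zero_fraction[3], 0)
  expect_error(profile_zero_fraction(spec2, params2,
                                     list(x = array(0, c(1, 8, 8, 0)),
                                          y = integer(0))),
               "empty dataset")
})

test_that("threshold pruning matches a full-sort oracle and is monotone", {
  spec <- build_tree3(toy_config(filters = 2, branches = 4, side = 12))
  params <- init_params(spec, seed = 5)
  tr <- forward_pass(spec, params, random_image(spec, 15))
  g <- backward_reference(spec, params, tr, 2L)
  all_mags <- abs(c(g$conv, g$tree, g$fc))
  expect_gt(sum(all_mags > 0), 100)    # guard: routes are genuinely active

  # threshold 0: unchanged, active fraction = nonzero fraction
  p0 <- apply_threshold_pruning(g, pruning_policy(threshold = 0))
  expect_identical(p0$gradients$conv, g$conv)
  expect_equal(p0$active_fraction, mean(all_mags != 0))

  # threshold above the maximum: everything zero
  pmax_ <- apply_threshold_pruning(
    g, pruning_policy(threshold = max(all_mags) * 1.01))
  expect_true(all(pmax_$gradients$conv == 0))
  expect_equal(pmax_$active_fraction, 0)

  # target active fraction: kept set equals the top entries of a full sort
  frac <- 0.05
  pf <- apply_threshold_pruning(g, pruning_policy(active_fraction = frac))
  k <- floor(frac * length(all_mags))
  kth <- sort(all_mags, decreasing = TRUE)[k]
  kept <- abs(c(pf$gradients$conv, pf$gradients$tree, pf$gradients$fc)) > 0
  expect_equal(which(kept), which(all_mags >= kth))
  expect_lte(pf$active_fraction, frac + 1e-9)

  # active fraction is non-increasing in the threshold
  ths <- quantile(all_mags[all_mags > 0], c(0.1, 0.5, 0.9))
  fracs <- vapply(ths, function(t) {
    apply_threshold_pruning(g, pruning_policy(threshold = t))$active_fraction
  }, numeric(1))
  expect_true(all(diff(fracs) <= 0))
  expect_error(pruning_policy(), "exactly one")
  expect_error(pruning_policy(threshold = 1, active_fraction = 0.5),
               "exactly one")
})

test_that("active-update accounting reproduces the canonical numbers", {
  spec <- build_tree3(tree3_config(channels = 3, filters = 6, branches = 16))
  a <- active_update_count(spec, 0.006)
  expect_equal(a$instances, 5644800)
  expect_equal(a$exact, 33869)
  expect_equal(a$nearest_thousand, 34000)
  expect_equal(active_update_count(spec, 1)$exact, 5644800)
  tiny <- build_tree3(tree3_config(channels = 1, filters = 1, branches = 1,
                                   height = 5, width = 5, filter_size = 4,
                                   pool_size = 2, slab_rows = 1,
                                   classes = 10))
  expect_equal(active_update_count(tiny, 0.5, layer = "fc")$exact, 5)
})

test_that("gradient-magnitude histograms conserve counts", {
  spec <- build_tree3(toy_config(filters = 2, branches = 2, side = 12))
  params <- init_params(spec, seed = 9)
  tr <- forward_pass(spec, params, random_image(spec, 10))
  g <- backward_reference(spec, params, tr, 1L)
  h <- gradient_magnitude_histogram(g, bins = 20, params = params)
  n_nonzero <- sum(g$conv != 0) + sum(g$tree != 0) + sum(g$fc != 0)
  expect_equal(sum(h$absolute$count), n_nonzero)
  expect_false(h$empty)
  expect_false(is.null(h$relative))

  # direct bin-assignment oracle on a known tensor
  mags <- abs(c(g$conv, g$tree, g$fc))
  mags <- mags[mags > 0]
  direct <- vapply(seq_len(nrow(h$absolute)), function(b) {
    lo <- h$absolute$lower[b]; hi <- h$absolute$upper[b]
    if (b == 1) sum(mags >= lo & mags <= hi) else sum(mags > lo & mags <= hi)
  }, numeric(1))
  expect_equal(h$absolute$count, as.integer(direct))

  # single nonzero entry: one occupied bin
  g1 <- g
  for (nm in c("conv", "tree", "fc")) g1[[nm]][] <- 0
  g1$fc[1] <- 0.25
  h1 <- gradient_magnitude_histogram(g1)
  expect_equal(sum(h1$absolute$count), 1)
  expect_equal(nrow(h1$absolute), 1)

  # all-zero gradients: flagged empty
  g0 <- g
  for (nm in c("conv", "tree", "fc")) g0[[nm]][] <- 0
  expect_true(gradient_magnitude_histogram(g0)$empty)
})

test_that("training with threshold-0 pruning is bit-identical to unpruned", {
  task <- generate_synthetic_task(synthetic_task_config(
    train_per_class = 5, test_per_class = 2, seed = 4))
  spec <- build_tree3(tree3_config(channels = 1, filters = 2, branches = 2,
                                   height = 12, width = 12, slab_rows = 2))
  params <- init_params(spec, seed = 1)
  base <- training_config(lr = 0.05, momentum = 0.9, batch_size = 10,
                          epochs = 2, seed = 1)
  pruned <- training_config(lr = 0.05, momentum = 0.9, batch_size = 10,
                            epochs = 2, seed = 1,
                            prune_policy = pruning_policy(threshold = 0))
  f1 <- train_network(spec, params, task$train, NULL, base)
  f2 <- train_network(spec, params, task$train, NULL, pruned)
  expect_identical(f1$params$conv, f2$params$conv)
  expect_identical(f1$params$tree, f2$params$tree)
  expect_identical(f1$params$fc, f2$params$fc)
})
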