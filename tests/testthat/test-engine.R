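test_that("all-zero input through a bias-free ReLU net gives uniform softmax", {
  spec <- build_tree3(toy_config(classes = 10, side = 12))
  params <- init_params(spec, seed = 1)
  x <- array(0, c(1, 12, 12))
  tr <- forward_pass(spec, params, x)
  expect_true(all(tr$a_conv == 0))
  expect_true(all(tr$a_tree == 0))
  expect_equal(tr$probs, rep(0.1, 10), tolerance = 1e-12)
})

test_that("tree-layer pre-activation equals a loop-based depth-and-slab sum", {
  spec <- build_tree3(toy_config(channels = 2, filters = 2, branches = 2,
                                 side = 12, slab_rows = 2, classes = 3,
                                 activation = "sigmoid"))
  params <- init_params(spec, seed = 2)
  x <- random_image(spec, 3)
  tr <- forward_pass(spec, params, x)
  g <- spec$geometry
  pooled <- array(tr$pooled, c(g$pooled_h, g$pooled_w,
                               spec$config$filters, spec$config$channels))
  r <- spec$config$slab_rows
  for (m in seq_len(spec$config$branches)) {
    for (cc in seq_len(spec$config$channels)) {
      for (j in seq_len(g$slabs)) {
        acc <- 0
        for (k in seq_len(spec$config$filters)) {
          for (pr in ((j - 1) * r + 1):(j * r)) {
            for (pc in seq_len(g$pooled_w)) {
              acc <- acc + params$tree[pr, pc, k, cc, m] * pooled[pr, pc, k, cc]
            }
          }
        }
        expect_equal(tr$z_tree[j, cc, m], acc, tolerance = 1e-12)
      }
    }
  }
})

test_that("forward is deterministic and validates input shape", {
  spec <- build_tree3(toy_config())
  params <- init_params(spec, seed = 4)
  x <- random_image(spec, 5)
  expect_identical(forward_pass(spec, params, x)$probs,
                   forward_pass(spec, params, x)$probs)
  expect_error(forward_pass(spec, params, array(0, c(1, 9, 9))),
               "does not match spec input")
  expect_error(forward_pass(build_lenet5(), params, x),
               "tree architectures only")
})

test_that("backward rejects a stale trace", {
  spec <- build_tree3(toy_config())
  params <- init_params(spec, seed = 6)
  tr <- forward_pass(spec, params, random_image(spec, 7))
  params$fc <- params$fc * 1.5
  expect_error(backward_reference(spec, params, tr, 1L), "stale trace")
  expect_error(backward_pruned(spec, params, tr, 1L), "stale trace")
})

test_that("summed gradients are linear in duplicated samples", {
  spec <- build_tree3(toy_config(activation = "sigmoid"))
  params <- init_params(spec, seed = 8)
  x <- random_image(spec, 9)
  x2 <- array(c(x, x), c(dim(x), 2))
  g1 <- batch_gradients(spec, params, x, 1L, reduction = "sum")$grads
  g2 <- batch_gradients(spec, params, x2, c(1L, 1L),
                        reduction = "sum")$grads
  for (nm in c("conv", "tree", "fc")) {
    expect_equal(g2[[nm]], 2 * g1[[nm]], tolerance = 1e-12)
  }
})

test_that("a hand-built single-route product matches the pruned gradient", {
  # one channel, one kernel, one branch; weights set so the route product
  # is directly checkable: grad(W_fc) = a_tree * err on the active unit
  spec <- build_tree3(tree3_config(channels = 1, filters = 1, branches = 1,
                                   height = 8, width = 8, slab_rows = 2,
                                   classes = 2, activation = "relu"))
  params <- init_params(spec, seed = 1)
  params$conv[] <- 0
  params$conv[3, 3, 1, 1] <- 1          # picks out single pixels
  params$tree[] <- 0.5
  params$fc[1, ] <- c(0.3, 0.1)
  x <- array(2, c(1, 8, 8))             # constant positive image
  tr <- forward_pass(spec, params, x)
  gp <- backward_pruned(spec, params, tr, 1L)
  err <- tr$probs - c(1, 0)
  # tree unit value: sum over slab (2 rows x 2 cols) of 0.5 * pooled(=2)
  expect_equal(as.vector(tr$a_tree), 0.5 * 2 * 4, tolerance = 1e-12)
  expect_equal(gp$fc[1, ], as.vector(tr$a_tree) * err, tolerance = 1e-12)
  # conv-weight gradient: input * W_tree * sigma' * W_fc . err, summed over
  # the 4 selected applications of the slab
  downstream <- sum(c(0.3, 0.1) * err)
  expect_equal(gp$conv[3, 3, 1, 1], 4 * 2 * 0.5 * downstream,
               tolerance = 1e-12)
})

test_that("inactive ReLU routes contribute exactly zero", {
  spec <- build_tree3(toy_config(side = 8))
  params <- init_params(spec, seed = 10)
  params$conv <- -abs(params$conv)      # all conv pre-activations negative
  x <- array(abs(random_image(spec, 11)), c(1, 8, 8))
  tr <- forward_pass(spec, params, x)
  expect_true(all(tr$pooled == 0))
  gp <- backward_pruned(spec, params, tr, 2L)
  gr <- backward_reference(spec, params, tr, 2L)
  expect_true(all(gp$conv == 0))
  expect_true(all(gr$conv == 0))
  expect_true(all(gp$tree == 0))
  zc <- gp$zero_counts
  expect_equal(zc$zero[["conv"]], zc$total[["conv"]])
})

test_that("every contribution skipped by the pruned engine is zero in the reference", {
  for (s in 1:4) {
    spec <- build_tree3(toy_config(filters = 2, branches = 2, side = 8))
    params <- init_params(spec, seed = 20 + s)
    tr <- forward_pass(spec, params, random_image(spec, 30 + s))
    gr <- backward_reference(spec, params, tr, 1L)
    gp <- backward_pruned(spec, params, tr, 1L)
    skipped <- gp$tree == 0
    expect_true(all(gr$tree[skipped] == 0))
    expect_true(all(gr$conv[gp$conv == 0] == 0))
  }
})

test_that("SGD reduces to plain gradient descent without momentum", {
  spec <- build_tree3(toy_config())
  params <- init_params(spec, seed = 1)
  tr <- forward_pass(spec, params, random_image(spec, 2))
  g <- backward_reference(spec, params, tr, 1L)
  stepped <- sgd_step(params, g, list(lr = 0.1, momentum = 0,
                                      weight_decay = 0))
  expect_equal(stepped$params$conv, params$conv - 0.1 * g$conv,
               tolerance = 1e-15)
  # zero gradient, zero velocity: parameters unchanged
  g0 <- g
  for (nm in c("conv", "tree", "fc")) g0[[nm]][] <- 0
  s0 <- sgd_step(params, g0, list(lr = 0.1, momentum = 0.9,
                                  weight_decay = 0))
  expect_identical(s0$params$conv, params$conv)
})

test_that("two Nesterov steps reproduce the hand-unrolled recursion", {
  spec <- build_tree3(tree3_config(channels = 1, filters = 1, branches = 1,
                                   height = 8, width = 8, slab_rows = 2,
                                   classes = 2))
  params <- init_params(spec, seed = 3)
  g <- treebp:::new_gradient_set(
    lapply(params[c("conv", "tree", "fc")],
           function(w) array(1, dim(w))), "reference")
  cfg <- list(lr = 0.1, momentum = 0.9, weight_decay = 0)
  s1 <- sgd_step(params, g, cfg)
  s2 <- sgd_step(s1$params, g, cfg, s1$state)
  # hand unroll with constant unit gradient:
  # v1 = 1;        w1 = w0 - lr * (1 + mu * 1)        = w0 - 0.19
  # v2 = mu + 1;   w2 = w1 - lr * (1 + mu * (mu + 1)) = w1 - 0.271
  expect_equal(s1$params$fc, params$fc - 0.19, tolerance = 1e-12)
  expect_equal(s2$params$fc, params$fc - 0.19 - 0.271, tolerance = 1e-12)
  # weight decay folds into the gradient before the momentum update
  sd1 <- sgd_step(params, g, list(lr = 0.1, momentum = 0, weight_decay = 0.5))
  expect_equal(sd1$params$fc, params$fc - 0.1 * (1 + 0.5 * params$fc),
               tolerance = 1e-12)
})

test_that("learning-rate schedules evaluate the canonical recipes", {
  mult <- schedule_multiplicative(0.05, 0.6, 20)
  expect_equal(lr_schedule(mult, 0), 0.05)
  expect_equal(lr_schedule(mult, 40), 0.05 * 0.6^2)
  pw <- schedule_piecewise(c(0, 100, 150), c(0.01, 0.005, 0.001))
  expect_equal(lr_schedule(pw, 0), 0.01)
  expect_equal(lr_schedule(pw, 120), 0.005)
  expect_equal(lr_schedule(pw, 150), 0.001)
  expect_equal(lr_schedule(pw, 10000), 0.001)  # beyond range: last value
  # multiplicative schedules are non-increasing in epoch
  rates <- vapply(0:100, function(e) lr_schedule(mult, e), numeric(1))
  expect_true(all(diff(rates) <= 0))
  expect_error(schedule_piecewise(c(5, 10), c(0.1, 0.2)))
})

test_that("cross-entropy loss has its closed-form values and exact logit gradient", {
  spec <- build_tree3(toy_config(classes = 10, side = 12))
  params <- init_params(spec, seed = 1)
  tr_uniform <- forward_pass(spec, params, array(0, c(1, 12, 12)))
  lr <- loss_cross_entropy(tr_uniform, 7L)
  expect_equal(lr$loss, log(10), tolerance = 1e-12)

  tr <- forward_pass(spec, params, random_image(spec, 5))
  rep <- loss_cross_entropy(tr, 3L)
  expect_equal(rep$err[1, ], tr$probs - (seq_len(10) == 3), tolerance = 1e-14)
  # err equals the numerical gradient of the loss w.r.t. the logits
  h <- 1e-6
  num <- vapply(seq_len(10), function(o) {
    lp <- tr$logits; lp[o] <- lp[o] + h
    lm <- tr$logits; lm[o] <- lm[o] - h
    p_hi <- exp(lp - max(lp)); p_hi <- p_hi / sum(p_hi)
    p_lo <- exp(lm - max(lm)); p_lo <- p_lo / sum(p_lo)
    (-log(p_hi[3]) + log(p_lo[3])) / (2 * h)
  }, numeric(1))
  expect_equal(rep$err[1, ], num, tolerance = 1e-6)
  expect_error(loss_cross_entropy(tr, 12L), "out of range")
})

test_that("probability-one output yields zero loss", {
  fake <- structure(list(probs = c(1, 0, 0)), class = "activation_trace")
  expect_equal(loss_cross_entropy(fake, 1L)$loss, 0)
})

test_that("a small tree network trained on the synthetic task beats chance", {
  task <- generate_synthetic_task(synthetic_task_config(
    train_per_class = 10, test_per_class = 5, seed = 3))
  spec <- build_tree3(tree3_config(channels = 1, filters = 2, branches = 4,
                                   height = 12, width = 12, slab_rows = 2))
  params <- init_params(spec, seed = 1)
  cfg <- training_config(lr = 0.05, momentum = 0.9, weight_decay = 5e-5,
                         batch_size = 20, epochs = 8, seed = 1)
  fit <- train_network(spec, params, task$train, task$test, cfg)
  expect_gt(fit$metrics$test_accuracy[8], 0.3)
  # deterministic given the same seed
  fit2 <- train_network(spec, params, task$train, task$test, cfg)
  expect_identical(fit$metrics, fit2$metrics)
})
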