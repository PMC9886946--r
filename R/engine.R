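# Forward pass, reference chain-rule backward, single-route pruned backward,
# loss, optimizer and learning-rate schedules for the tree architectures.
#
# Internal array conventions (all column-major):
#   image x          : (C, H, W)
#   z_conv / a_conv  : (conv positions, K, C), positions flatten (row, col)
#   pooled / sel     : (pool windows, K, C), windows flatten (pr, pc)
#   z_tree / a_tree  : (J, C, M) or (J, C, M, heads)
#   fc weights       : (n_tree_units, classes) or (n_tree_units, 1, heads)

assert_tree_variant <- function(spec, what = "this engine") {
  if (!spec$variant %in% c("tree3", "ten_tree3")) {
    stop(what, " supports tree architectures only (tree3, ten_tree3); got '",
         spec$variant, "'. LeNet-5 specs are for structural and route",
         " analysis.")
  }
}

#' Forward pass through a tree architecture
#'
#' Computes the full activation trace of one input image: grouped-convolution
#' pre/post activations, max-pooling selections (ties broken by the first,
#' i.e. lowest-index, window member), tree-sampling pre/post activations,
#' output logits and softmax class probabilities. The convolution is computed
#' once and logically shared by all branches.
#'
#' @param spec a tree `arch_spec` ([build_tree3()] or [build_ten_tree3()]).
#' @param params matching [init_params()] object.
#' @param x a single image, array of dim `(channels, height, width)`.
#' @return an `activation_trace` holding, per layer, pre- and post-activation
#'   arrays, pooling selection indices, activation derivatives evaluated at
#'   the trace, logits and probabilities.
#' @export
forward_pass <- function(spec, params, x) {
  assert_tree_variant(spec, "forward_pass")
  cfg <- spec$config; g <- spec$geometry; cache <- spec$cache
  C <- cfg$channels; K <- cfg$filters
  if (!identical(as.integer(dim(x)), as.integer(c(C, cfg$height, cfg$width)))) {
    stop("input shape [", paste(dim(x), collapse = ", "),
         "] does not match spec input [",
         paste(c(C, cfg$height, cfg$width), collapse = ", "), "]")
  }
  act <- activation_fun(cfg$activation)
  dact <- activation_deriv(cfg$activation)
  npos <- g$conv_h * g$conv_w
  nw <- g$pooled_h * g$pooled_w

  patches <- vector("list", C)
  z_conv <- array(0, c(npos, K, C))
  for (c in seq_len(C)) {
    xc <- x[c, , ]
    pc <- matrix(xc[cache$im2col], nrow = npos)
    patches[[c]] <- pc
    z_conv[, , c] <- pc %*% matrix(params$conv[, , , c], ncol = K)
  }
  a_conv <- act(z_conv)

  sel <- array(0L, c(nw, K, C))
  sel_lin <- array(0L, c(nw, K, C))
  pooled <- array(0, c(nw, K, C))
  pooled_pre <- array(0, c(nw, K, C))
  pidx <- cache$pool_idx
  for (c in seq_len(C)) {
    for (k in seq_len(K)) {
      vals <- matrix(a_conv[, k, c][pidx], nrow = nrow(pidx))
      s <- max.col(t(vals), ties.method = "first")
      lin <- pidx[cbind(s, seq_len(nw))]
      sel[, k, c] <- s
      sel_lin[, k, c] <- lin
      pooled[, k, c] <- a_conv[, k, c][lin]
      pooled_pre[, k, c] <- z_conv[, k, c][lin]
    }
  }
  sp_conv <- dact(pooled_pre)

  # tree sampling: private per-position weights, summed over the K depth
  # kernels and over the slab_rows x pooled_w slab of each tree unit
  heads <- spec$heads
  M <- cfg$branches
  cm <- C * M * heads
  pooled_full <- pooled
  dim(pooled_full) <- c(g$pooled_h, g$pooled_w, K, C)
  prod_all <- params$tree * as.vector(pooled_full)
  dim(prod_all) <- c(g$pooled_h, g$pooled_w * K, cm)
  per_row <- colSums(aperm(prod_all, c(2, 1, 3)))      # (pooled_h, cm)
  z_tree <- rowsum(per_row, cache$slab_of_row)          # (J, cm)
  tdim <- if (heads > 1L) c(g$slabs, C, M, heads) else c(g$slabs, C, M)
  dim(z_tree) <- tdim
  a_tree <- act(z_tree)
  sp_tree <- dact(z_tree)

  if (heads > 1L) {
    logits <- vapply(seq_len(heads), function(h) {
      sum(params$fc[, 1, h] * as.vector(a_tree[, , , h]))
    }, numeric(1))
  } else {
    logits <- as.vector(crossprod(params$fc, as.vector(a_tree)))
  }
  probs <- softmax(logits)

  structure(list(
    x = x, patches = patches,
    z_conv = z_conv, a_conv = a_conv,
    sel = sel, sel_lin = sel_lin,
    pooled = pooled, pooled_pre = pooled_pre, sp_conv = sp_conv,
    z_tree = z_tree, a_tree = a_tree, sp_tree = sp_tree,
    logits = logits, probs = probs,
    token = params_token(params)
  ), class = "activation_trace")
}

#' @export
print.activation_trace <- function(x, ...) {
  cat("<activation_trace>\n")
  cat("  logits:", format(x$logits, digits = 4), "\n")
  cat("  probs :", format(x$probs, digits = 4), "\n")
  invisible(x)
}

check_trace <- function(params, trace) {
  if (!identical(trace$token, params_token(params))) {
    stop("stale trace: parameters changed since forward_pass; recompute the",
         " trace before calling backward")
  }
}

empty_grads <- function(params) {
  list(conv = array(0, dim(params$conv)),
       tree = array(0, dim(params$tree)),
       fc = array(0, dim(params$fc)))
}

new_gradient_set <- function(g, engine, zero_counts = NULL) {
  structure(list(conv = g$conv, tree = g$tree, fc = g$fc,
                 engine = engine, zero_counts = zero_counts),
            class = "gradient_set")
}

#' @export
print.gradient_set <- function(x, ...) {
  cat("<gradient_set> engine:", x$engine, "\n")
  for (nm in c("conv", "tree", "fc")) {
    cat(sprintf("  %-4s dim [%s], max |g| = %.3g\n", nm,
                paste(dim(x[[nm]]), collapse = ", "), max(abs(x[[nm]]))))
  }
  if (!is.null(x$zero_counts)) {
    zc <- x$zero_counts
    cat(sprintf("  structural zero fraction: conv %.3f, tree %.3f, fc %.3f\n",
                zc$zero[["conv"]] / zc$total[["conv"]],
                zc$zero[["tree"]] / zc$total[["tree"]],
                zc$zero[["fc"]] / zc$total[["fc"]]))
  }
  invisible(x)
}

# Per-instance structural zero bookkeeping from one trace. An instance is
# one per-application gradient term (see count_gradient_instances); it is a
# structural zero when its single route crosses a non-selected pooling unit
# or a unit with zero activation derivative (inactive ReLU), or — for tree
# and fc weights — when the upstream activation feeding the weight is zero.
structural_zero_counts <- function(spec, trace) {
  cfg <- spec$config; g <- spec$geometry
  C <- cfg$channels; K <- cfg$filters; M <- cfg$branches
  heads <- spec$heads
  f2 <- cfg$filter_size^2
  nw <- g$pooled_h * g$pooled_w
  npos <- g$conv_h * g$conv_w
  mh <- M * heads

  tree_active <- trace$sp_tree != 0            # (J, C, M[, heads])
  ta <- tree_active
  dim(ta) <- c(g$slabs * C, mh)
  t_cnt <- matrix(rowSums(ta), g$slabs, C)     # active (m, head) per (j, c)

  pr_of_w <- ((seq_len(nw) - 1L) %% g$pooled_h) + 1L
  j_of_w <- spec$cache$slab_of_row[pr_of_w]
  wt <- t_cnt[j_of_w, , drop = FALSE]          # (nw, C)

  conv_act <- trace$sp_conv != 0               # (nw, K, C), at selected units
  ca_kc <- apply(conv_act, c(1, 3), sum)       # per (window, channel) over k
  conv_active_inst <- f2 * sum(ca_kc * wt)
  conv_total <- f2 * C * K * npos * mh

  pooled_nz <- trace$pooled != 0               # (nw, K, C)
  pz_kc <- apply(array(pooled_nz, c(nw, K, C)), c(1, 3), sum)
  tree_active_inst <- sum(pz_kc * wt)
  tree_total <- nw * K * C * mh

  if (heads > 1L) {
    fc_active_inst <- sum(trace$a_tree != 0)
    fc_total <- g$n_tree_units * heads
  } else {
    fc_active_inst <- cfg$classes * sum(trace$a_tree != 0)
    fc_total <- g$n_tree_units * cfg$classes
  }

  total <- c(conv = conv_total, tree = tree_total, fc = fc_total)
  zero <- total - c(conv = conv_active_inst, tree = tree_active_inst,
                    fc = fc_active_inst)
  list(zero = zero, total = total)
}

#' Reference backward pass (full chain rule)
#'
#' Exact analytic gradients of the softmax cross-entropy loss with respect to
#' all weight tensors, by the standard chain rule: the output-layer error is
#' `probs - onehot(target)`, max-pooling routes gradient only to the selected
#' window member, and activation derivatives are taken at the traced
#' pre-activations. Serves as the oracle the pruned engine is checked
#' against.
#'
#' @param spec,params architecture and parameters used for the trace.
#' @param trace an `activation_trace` from [forward_pass()] on `params`.
#' @param target integer class label in `1..classes`.
#' @return a `gradient_set` with tensors `conv`, `tree`, `fc` mirroring the
#'   parameter shapes, plus structural zero-instance bookkeeping.
#' @export
backward_reference <- function(spec, params, trace, target) {
  assert_tree_variant(spec, "backward_reference")
  check_trace(params, trace)
  cfg <- spec$config; g <- spec$geometry
  C <- cfg$channels; K <- cfg$filters; M <- cfg$branches
  heads <- spec$heads
  err <- trace$probs - one_hot(target, cfg$classes)
  nw <- g$pooled_h * g$pooled_w
  npos <- g$conv_h * g$conv_w
  cm <- C * M * heads

  # fc gradient and backpropagated tree-unit error
  if (heads > 1L) {
    g_fc <- array(0, dim(params$fc))
    d_at <- array(0, dim(trace$a_tree))
    for (h in seq_len(heads)) {
      av <- as.vector(trace$a_tree[, , , h])
      g_fc[, 1, h] <- av * err[h]
      d_at[, , , h] <- array(params$fc[, 1, h] * err[h],
                             c(g$slabs, C, M))
    }
  } else {
    av <- as.vector(trace$a_tree)
    g_fc <- outer(av, err)
    d_at <- array(as.vector(params$fc %*% err), dim(trace$a_tree))
  }
  d_zt <- d_at * trace$sp_tree                  # (J, C, M[, heads])

  # expand tree-unit errors to the (pooled_h, pooled_w, K, C, M[, heads]) grid
  dzt_mat <- d_zt
  dim(dzt_mat) <- c(g$slabs, cm)
  dd <- dzt_mat[spec$cache$slab_of_row, , drop = FALSE]   # (pooled_h, cm)
  expand <- apply(dd, 2, function(col) rep(col, g$pooled_w * K))
  dim(expand) <- dim(params$tree)

  pooled_full <- trace$pooled
  dim(pooled_full) <- c(g$pooled_h, g$pooled_w, K, C)
  g_tree <- expand * as.vector(pooled_full)

  s <- params$tree * expand
  dim(s) <- c(nw * K * C, M * heads)
  d_pooled <- array(rowSums(s), c(nw, K, C))

  d_z_conv <- array(0, c(npos, K, C))
  g_conv <- array(0, dim(params$conv))
  for (c in seq_len(C)) {
    for (k in seq_len(K)) {
      v <- numeric(npos)
      v[trace$sel_lin[, k, c]] <- d_pooled[, k, c] * trace$sp_conv[, k, c]
      d_z_conv[, k, c] <- v
    }
    g_conv[, , , c] <- array(crossprod(trace$patches[[c]], d_z_conv[, , c]),
                             c(cfg$filter_size, cfg$filter_size, K))
  }
  new_gradient_set(list(conv = g_conv, tree = g_tree, fc = g_fc),
                   "reference", structural_zero_counts(spec, trace))
}

#' Pruned single-route backward pass
#'
#' Computes the same gradients as [backward_reference()] by walking only the
#' active routes of the tree: for each weight application the contribution is
#' the product along its unique route — input value, activation derivatives
#' at the convolution and tree units on the route, the downstream tree and
#' fully connected weights, and the output error `probs - onehot` — summed
#' over output units and over the weight's applications and branches.
#' Applications whose route crosses a non-selected pooling unit or an
#' inactive unit (zero activation derivative, e.g. an inactive ReLU)
#' contribute exactly zero and are skipped: the engine enumerates the active
#' tree units and active selected convolution units and never visits the
#' rest. With ReLU the per-route product reduces to
#' `input * W_tree * W_fc * (output - output_desired)` on active routes and
#' zero otherwise.
#'
#' @inheritParams backward_reference
#' @return a `gradient_set` (engine tag `"pruned"`) equal to the reference
#'   gradients up to floating-point summation order.
#' @export
backward_pruned <- function(spec, params, trace, target) {
  assert_tree_variant(spec, "backward_pruned")
  check_trace(params, trace)
  cfg <- spec$config; g <- spec$geometry
  C <- cfg$channels; K <- cfg$filters; M <- cfg$branches
  heads <- spec$heads
  err <- trace$probs - one_hot(target, cfg$classes)
  nw <- g$pooled_h * g$pooled_w
  r <- cfg$slab_rows

  grads <- empty_grads(params)

  # fc: only active tree units carry gradient
  if (heads > 1L) {
    d_at_of <- function(idx) {
      # idx: (j, c, m, h) row -> downstream factor W_fc * err for that unit
      u <- (idx[, 3] - 1L) * (g$slabs * C) + (idx[, 2] - 1L) * g$slabs + idx[, 1]
      params$fc[cbind(u, 1L, idx[, 4])] * err[idx[, 4]]
    }
  } else {
    d_at_of <- function(idx) {
      u <- (idx[, 3] - 1L) * (g$slabs * C) + (idx[, 2] - 1L) * g$slabs + idx[, 1]
      as.vector(params$fc[u, , drop = FALSE] %*% err)
    }
  }

  if (heads > 1L) {
    for (h in seq_len(heads)) {
      av <- as.vector(trace$a_tree[, , , h])
      nz <- which(av != 0)
      if (length(nz)) grads$fc[cbind(nz, 1L, h)] <- av[nz] * err[h]
    }
  } else {
    av <- as.vector(trace$a_tree)
    nz <- which(av != 0)
    if (length(nz)) grads$fc[nz, ] <- outer(av[nz], err)
  }

  # active tree units: nonzero activation derivative
  active_t <- which(trace$sp_tree != 0)
  if (length(active_t) == 0L) {
    return(new_gradient_set(grads, "pruned",
                            structural_zero_counts(spec, trace)))
  }
  tidx <- arrayInd(active_t, dim(trace$sp_tree))
  if (heads == 1L) tidx <- cbind(tidx, 1L)  # uniform (j, c, m, h) columns
  d_zt_active <- trace$sp_tree[active_t] * d_at_of(tidx)

  pooled_full <- trace$pooled
  dim(pooled_full) <- c(g$pooled_h, g$pooled_w, K, C)
  d_pooled <- array(0, c(g$pooled_h, g$pooled_w, K, C))

  for (i in seq_along(active_t)) {
    j <- tidx[i, 1]; cc <- tidx[i, 2]; m <- tidx[i, 3]; h <- tidx[i, 4]
    rows <- ((j - 1L) * r + 1L):(j * r)
    d <- d_zt_active[i]
    if (heads > 1L) {
      tw_block <- params$tree[rows, , , cc, m, h]
      grads$tree[rows, , , cc, m, h] <- pooled_full[rows, , , cc] * d
    } else {
      tw_block <- params$tree[rows, , , cc, m]
      grads$tree[rows, , , cc, m] <- grads$tree[rows, , , cc, m] +
        pooled_full[rows, , , cc] * d
    }
    d_pooled[rows, , , cc] <- d_pooled[rows, , , cc] + tw_block * d
  }
  dim(d_pooled) <- c(nw, K, C)

  # conv: visit only selected, active pooling units with nonzero downstream
  f <- cfg$filter_size
  for (cc in seq_len(C)) {
    for (k in seq_len(K)) {
      u <- trace$sp_conv[, k, cc] * d_pooled[, k, cc]
      aw <- which(u != 0)
      if (length(aw) == 0L) next
      rows <- trace$sel_lin[aw, k, cc]
      gvec <- crossprod(trace$patches[[cc]][rows, , drop = FALSE], u[aw])
      grads$conv[, , k, cc] <- matrix(gvec, f, f)
    }
  }
  new_gradient_set(grads, "pruned", structural_zero_counts(spec, trace))
}

#' Cross-entropy loss and output error
#'
#' Mean softmax cross-entropy over one or more traces, exposing the
#' per-sample output-error vectors `probs - onehot(target)` — the exact
#' gradient of the loss with respect to the logits, and the error term the
#' pruned engine propagates along each route.
#'
#' @param traces an `activation_trace` or a list of them.
#' @param targets integer labels in `1..classes`, one per trace.
#' @return a `loss_report`: `loss` (mean), `per_sample` losses, `err` matrix
#'   (samples x classes).
#' @export
loss_cross_entropy <- function(traces, targets) {
  if (inherits(traces, "activation_trace")) traces <- list(traces)
  stopifnot(length(traces) == length(targets))
  classes <- length(traces[[1]]$probs)
  n <- length(traces)
  per <- numeric(n)
  err <- matrix(0, n, classes)
  for (i in seq_len(n)) {
    y <- targets[i]
    if (y < 1L || y > classes) {
      stop("target class ", y, " out of range 1..", classes)
    }
    per[i] <- -log(traces[[i]]$probs[y])
    err[i, ] <- traces[[i]]$probs - one_hot(y, classes)
  }
  structure(list(loss = mean(per), per_sample = per, err = err),
            class = "loss_report")
}

#' Mini-batch gradients
#'
#' Runs forward and backward over a batch and aggregates per-sample
#' gradients.
#'
#' @param spec,params architecture and parameters.
#' @param x image array `(C, H, W, n)` (or a single `(C, H, W)` image).
#' @param y integer labels, length `n`.
#' @param engine `"reference"` or `"pruned"`; the two agree to floating-point
#'   summation order.
#' @param reduction `"mean"` (default, matching the mean cross-entropy) or
#'   `"sum"`.
#' @return list with `grads` (a `gradient_set`), `loss`, `accuracy`.
#' @export
batch_gradients <- function(spec, params, x, y,
                            engine = c("reference", "pruned"),
                            reduction = c("mean", "sum")) {
  engine <- match.arg(engine)
  reduction <- match.arg(reduction)
  backward <- if (engine == "pruned") backward_pruned else backward_reference
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  n <- dim(x)[4]
  stopifnot(length(y) == n)
  acc_g <- NULL
  loss_sum <- 0
  correct <- 0L
  zero <- NULL; total <- NULL
  for (i in seq_len(n)) {
    tr <- forward_pass(spec, params, array(x[, , , i], dim(x)[1:3]))
    gs <- backward(spec, params, tr, y[i])
    loss_sum <- loss_sum - log(tr$probs[y[i]])
    correct <- correct + (which.max(tr$probs) == y[i])
    if (is.null(acc_g)) {
      acc_g <- list(conv = gs$conv, tree = gs$tree, fc = gs$fc)
      zero <- gs$zero_counts$zero; total <- gs$zero_counts$total
    } else {
      acc_g$conv <- acc_g$conv + gs$conv
      acc_g$tree <- acc_g$tree + gs$tree
      acc_g$fc <- acc_g$fc + gs$fc
      zero <- zero + gs$zero_counts$zero
      total <- total + gs$zero_counts$total
    }
  }
  if (reduction == "mean") {
    acc_g <- lapply(acc_g, function(g) g / n)
  }
  list(grads = new_gradient_set(acc_g, engine,
                                list(zero = zero, total = total)),
       loss = loss_sum / n, accuracy = correct / n)
}

#' One SGD step with Nesterov momentum and L2 weight decay
#'
#' The update follows the common deep-learning convention:
#' `g <- grad + weight_decay * w`; `v <- momentum * v + g`;
#' `w <- w - lr * (g + momentum * v)` when `nesterov = TRUE`
#' (plain `w <- w - lr * v` otherwise). With `momentum = 0` and
#' `weight_decay = 0` this is plain gradient descent.
#'
#' @param params `network_params`.
#' @param grads a `gradient_set`.
#' @param config list with `lr`, `momentum`, `weight_decay`,
#'   `nesterov` (default `TRUE`).
#' @param state optimizer state (velocities); `NULL` on the first step.
#' @return list with updated `params` and `state`.
#' @export
sgd_step <- function(params, grads, config, state = NULL) {
  lr <- config$lr
  mu <- config$momentum %||% 0
  wd <- config$weight_decay %||% 0
  nesterov <- config$nesterov %||% TRUE
  layer_names <- c("conv", "tree", "fc")
  if (is.null(state)) {
    state <- lapply(params[layer_names], function(w) array(0, dim(w)))
  }
  for (nm in layer_names) {
    g <- grads[[nm]] + wd * params[[nm]]
    v <- mu * state[[nm]] + g
    params[[nm]] <- params[[nm]] -
      if (nesterov) lr * (g + mu * v) else lr * v
    state[[nm]] <- v
  }
  list(params = params, state = state)
}

#' Learning-rate schedules
#'
#' `schedule_piecewise(breaks, rates)` holds `rates[i]` on epochs in
#' `[breaks[i], breaks[i+1])` (0-based epochs, last rate held beyond the
#' declared range). `schedule_multiplicative(base, factor, period)` is
#' `base * factor^floor(epoch / period)`. `schedule_constant(rate)` is fixed.
#'
#' @param breaks integer start epochs, ascending, first must be 0.
#' @param rates positive rates, one per interval.
#' @param base,factor,period multiplicative schedule parameters.
#' @param rate constant rate.
#' @return a `lr_schedule` object for [lr_schedule()].
#' @export
schedule_piecewise <- function(breaks, rates) {
  stopifnot(length(breaks) == length(rates), breaks[1] == 0,
            !is.unsorted(breaks, strictly = TRUE), all(rates > 0))
  structure(list(kind = "piecewise", breaks = breaks, rates = rates),
            class = "lr_schedule")
}

#' @rdname schedule_piecewise
#' @export
schedule_multiplicative <- function(base, factor, period) {
  stopifnot(base > 0, factor > 0, period >= 1)
  structure(list(kind = "multiplicative", base = base, factor = factor,
                 period = period), class = "lr_schedule")
}

#' @rdname schedule_piecewise
#' @export
schedule_constant <- function(rate) {
  stopifnot(rate > 0)
  structure(list(kind = "constant", rate = rate), class = "lr_schedule")
}

#' Evaluate a schedule at an epoch
#'
#' @param schedule an `lr_schedule`.
#' @param epoch 0-based epoch index.
#' @return the learning rate (or decay constant) at that epoch.
#' @export
lr_schedule <- function(schedule, epoch) {
  stopifnot(inherits(schedule, "lr_schedule"), epoch >= 0)
  switch(schedule$kind,
    constant = schedule$rate,
    piecewise = schedule$rates[findInterval(epoch, schedule$breaks)],
    multiplicative = schedule$base *
      schedule$factor^(epoch %/% schedule$period)
  )
}

#' Training configuration
#'
#' Defaults follow the canonical offline recipe for the tree architectures:
#' learning rate 0.075, Nesterov momentum 0.965, L2 weight decay 5e-5,
#' mini-batch size 100.
#'
#' @param lr base learning rate (> 0); overridden per epoch by
#'   `lr_schedule` when given.
#' @param momentum Nesterov momentum constant in `[0, 1)`.
#' @param weight_decay L2 decay constant (>= 0); `wd_schedule` (an
#'   `lr_schedule`) makes it epoch-dependent.
#' @param batch_size mini-batch size.
#' @param epochs number of training epochs.
#' @param lr_schedule,wd_schedule optional `lr_schedule` objects, evaluated
#'   at the 0-based epoch.
#' @param engine `"reference"` or `"pruned"`.
#' @param prune_policy optional [pruning_policy()] applied to each batch
#'   gradient before the optimizer step.
#' @param augment optional list `(max_shift, flip)` for per-epoch training
#'   augmentation.
#' @param nesterov use the Nesterov look-ahead form (default `TRUE`).
#' @param seed integer seed driving shuffling and augmentation sub-seeds.
#' @return a `training_config` list.
#' @export
training_config <- function(lr = 0.075, momentum = 0.965,
                            weight_decay = 5e-5, batch_size = 100,
                            epochs = 10, lr_schedule = NULL,
                            wd_schedule = NULL,
                            engine = c("reference", "pruned"),
                            prune_policy = NULL, augment = NULL,
                            nesterov = TRUE, seed = 1L) {
  engine <- match.arg(engine)
  stopifnot(lr > 0, momentum >= 0, momentum < 1, weight_decay >= 0,
            batch_size >= 1, epochs >= 1)
  structure(list(lr = lr, momentum = momentum, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 lr_schedule = lr_schedule, wd_schedule = wd_schedule,
                 engine = engine, prune_policy = prune_policy,
                 augment = augment, nesterov = nesterov,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Train a tree network
#'
#' Mini-batch SGD with Nesterov momentum and L2 weight decay. Deterministic
#' given `(spec, params, data, config)`: shuffling and augmentation use named
#' sub-seeds fanned out from `config$seed`.
#'
#' @param spec tree `arch_spec`.
#' @param params initial `network_params`.
#' @param train,test `image_batch` objects (test may be `NULL`).
#' @param config a [training_config()].
#' @return list with final `params`, optimizer `state`, and a `metrics`
#'   data.frame (epoch, lr, weight_decay, train_loss, train_accuracy,
#'   test_loss, test_accuracy).
#' @export
train_network <- function(spec, params, train, test = NULL, config) {
  assert_tree_variant(spec, "train_network")
  stopifnot(inherits(config, "training_config"))
  n <- length(train$y)
  rows <- vector("list", config$epochs)
  state <- NULL
  for (e in seq_len(config$epochs)) {
    lr_e <- if (!is.null(config$lr_schedule)) {
      lr_schedule(config$lr_schedule, e - 1L)
    } else config$lr
    wd_e <- if (!is.null(config$wd_schedule)) {
      lr_schedule(config$wd_schedule, e - 1L)
    } else config$weight_decay
    step_cfg <- list(lr = lr_e, momentum = config$momentum,
                     weight_decay = wd_e, nesterov = config$nesterov)

    epoch_train <- train
    if (!is.null(config$augment)) {
      epoch_train <- augment_batch(
        train, max_shift = config$augment$max_shift %||% 2L,
        flip = config$augment$flip %||% TRUE,
        seed = fan_seed(config$seed, "augment") + e)
    }
    ord <- with_seed(fan_seed(config$seed, "shuffle") + e, sample.int(n))
    loss_acc <- 0; acc_acc <- 0; nb <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      xb <- epoch_train$x[, , , idx, drop = FALSE]
      bg <- batch_gradients(spec, params, xb, epoch_train$y[idx],
                            engine = config$engine)
      grads <- bg$grads
      if (!is.null(config$prune_policy)) {
        grads <- apply_threshold_pruning(grads, config$prune_policy)$gradients
      }
      stepped <- sgd_step(params, grads, step_cfg, state)
      params <- stepped$params
      state <- stepped$state
      loss_acc <- loss_acc + bg$loss
      acc_acc <- acc_acc + bg$accuracy
      nb <- nb + 1L
    }
    ev <- if (!is.null(test)) evaluate_network(spec, params, test) else
      list(loss = NA_real_, accuracy = NA_real_)
    rows[[e]] <- data.frame(epoch = e, lr = lr_e, weight_decay = wd_e,
                            train_loss = loss_acc / nb,
                            train_accuracy = acc_acc / nb,
                            test_loss = ev$loss, test_accuracy = ev$accuracy)
  }
  list(params = params, state = state, metrics = do.call(rbind, rows),
       config = config)
}

#' Evaluate a network on a labelled batch
#'
#' @param spec,params architecture and parameters.
#' @param batch an `image_batch`.
#' @return list with mean cross-entropy `loss`, `accuracy`, and the
#'   `probs` matrix (samples x classes).
#' @export
evaluate_network <- function(spec, params, batch) {
  n <- length(batch$y)
  classes <- spec$config$classes
  probs <- matrix(0, n, classes)
  loss <- 0
  correct <- 0L
  for (i in seq_len(n)) {
    tr <- forward_pass(spec, params, array(batch$x[, , , i],
                                           dim(batch$x)[1:3]))
    probs[i, ] <- tr$probs
    loss <- loss - log(tr$probs[batch$y[i]])
    correct <- correct + (which.max(tr$probs) == batch$y[i])
  }
  list(loss = loss / n, accuracy = correct / n, probs = probs)
}
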