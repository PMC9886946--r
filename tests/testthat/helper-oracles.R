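# Shared fixtures and independent oracles for the test suite.

rel_diff <- function(a, b) {
  scale <- max(abs(a), abs(b), .Machine$double.eps)
  max(abs(a - b)) / scale
}

# Small tree configurations that exercise both geometries and activations.
toy_config <- function(channels = 1, filters = 2, branches = 2,
                       side = 8, slab_rows = 2, classes = 3,
                       activation = "relu") {
  tree3_config(channels = channels, filters = filters, branches = branches,
               height = side, width = side, slab_rows = slab_rows,
               classes = classes, activation = activation)
}

random_image <- function(spec, seed) {
  cfg <- spec$config
  treebp:::with_seed(seed, {
    array(stats::rnorm(cfg$channels * cfg$height * cfg$width),
          c(cfg$channels, cfg$height, cfg$width))
  })
}

# Central finite differences of the cross-entropy loss w.r.t. every weight.
finite_diff_grads <- function(spec, params, x, target, h = 1e-4) {
  loss_of <- function(p) {
    -log(forward_pass(spec, p, x)$probs[target])
  }
  out <- list()
  for (nm in c("conv", "tree", "fc")) {
    g <- array(0, dim(params[[nm]]))
    for (i in seq_along(g)) {
      p_hi <- params; p_hi[[nm]][i] <- p_hi[[nm]][i] + h
      p_lo <- params; p_lo[[nm]][i] <- p_lo[[nm]][i] - h
      g[i] <- (loss_of(p_hi) - loss_of(p_lo)) / (2 * h)
    }
    out[[nm]] <- g
  }
  out
}

# Exhaustive DFS path enumeration on an adjacency list (small graphs only).
brute_force_paths <- function(adj, source, output) {
  count <- 0L
  dfs <- function(node) {
    if (node == output) {
      count <<- count + 1L
      return(invisible())
    }
    for (s in adj[[node]]) dfs(s)
  }
  dfs(source)
  count
}

# Build a layered connectivity_dag from an explicit edge list for testing
# the DP against brute force.
layered_dag <- function(edges, layer, outputs, sources) {
  treebp:::new_dag(edges, layer, sources = sources, outputs = outputs,
                   describe_node = function(id) paste0("node", id),
                   convention = "exact-DAG (test)")
}

edges_to_adj <- function(edges, n) {
  adj <- rep(list(integer(0)), n)
  for (i in seq_len(nrow(edges))) {
    f <- edges$from[i]
    adj[[f]] <- c(adj[[f]], edges$to[i])
  }
  adj
}

# Independent per-instance recount of exact zeros in reference-engine
# gradients, by looping every gradient instance and forming its single-route
# product directly (single-head tree specs).
instance_zero_recount <- function(spec, params, trace, target) {
  cfg <- spec$config; g <- spec$geometry
  C <- cfg$channels; K <- cfg$filters; M <- cfg$branches
  J <- g$slabs; r <- cfg$slab_rows
  err <- trace$probs - treebp:::one_hot(target, cfg$classes)
  nw <- g$pooled_h * g$pooled_w
  npos <- g$conv_h * g$conv_w
  f2 <- cfg$filter_size^2
  unit_of <- function(j, c, m) (m - 1L) * (J * C) + (c - 1L) * J + j
  down <- function(j, c, m) {           # sigma'_tree * sum_o W_fc * err
    trace$sp_tree[j, c, m] * sum(params$fc[unit_of(j, c, m), ] * err)
  }
  zero_conv <- 0
  for (cc in seq_len(C)) for (k in seq_len(K)) {
    sel_of_pos <- integer(npos)          # conv position -> window, 0 if unselected
    sel_of_pos[trace$sel_lin[, k, cc]] <- seq_len(nw)
    for (pos in seq_len(npos)) for (m in seq_len(M)) {
      w <- sel_of_pos[pos]
      if (w == 0L) { zero_conv <- zero_conv + f2; next }
      pr <- ((w - 1L) %% g$pooled_h) + 1L
      j <- (pr - 1L) %/% r + 1L
      route <- trace$sp_conv[w, k, cc] *
        params$tree[pr, ((w - 1L) %/% g$pooled_h) + 1L, k, cc, m] *
        down(j, cc, m)
      vals <- trace$patches[[cc]][pos, ] * route
      zero_conv <- zero_conv + sum(vals == 0)
    }
  }
  zero_tree <- 0
  for (cc in seq_len(C)) for (k in seq_len(K)) for (m in seq_len(M)) {
    for (pr in seq_len(g$pooled_h)) for (pc in seq_len(g$pooled_w)) {
      j <- (pr - 1L) %/% r + 1L
      w <- (pc - 1L) * g$pooled_h + pr
      val <- trace$pooled[w, k, cc] * down(j, cc, m)
      zero_tree <- zero_tree + (val == 0)
    }
  }
  av <- as.vector(trace$a_tree)
  zero_fc <- sum(outer(av, err) == 0)
  c(conv = zero_conv, tree = zero_tree, fc = zero_fc)
}
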