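# Route enumeration on the layered unit-connectivity DAG of an architecture.
#
# Two counting conventions are deliberately kept side by side: exact DAG
# enumeration (dynamic programming on the layered graph, pooled units acting
# as single-selection funnels) and the closed-form LeNet-5 arithmetic whose
# pooling step divides the route count by the window area. The two disagree
# for LeNet-5 — the closed form is an approximation of pool-window overlap —
# so every report labels the convention that produced it.

#' Build the unit-connectivity DAG of an architecture
#'
#' Nodes are hidden units from the first hidden layer (post-pooling) onward,
#' plus the output units; directed edges are weight applications. For tree
#' architectures the DAG is the logical per-branch ("dendritic") graph: the
#' convolution kernels are shared across branches, so each branch owns its
#' own copy of the first-hidden-layer units, matching the view in which a
#' branch is an independent subtree. Each pooled unit is a single node (a
#' selection funnel): a route enters it through one window member.
#'
#' @param spec an `arch_spec`.
#' @return a `connectivity_dag`: edge list (`from`, `to`), per-node `layer`,
#'   `sources` (first-hidden-layer node ids), `outputs`, a `describe_node`
#'   function, and the `convention` tag.
#' @export
connectivity_dag <- function(spec) {
  stopifnot(inherits(spec, "arch_spec"))
  if (spec$variant %in% c("tree3", "ten_tree3")) {
    dag_tree(spec)
  } else if (spec$variant == "lenet5") {
    dag_lenet5(spec)
  } else {
    stop("no DAG builder for variant ", spec$variant)
  }
}

new_dag <- function(edges, layer, sources, outputs, describe_node,
                    convention) {
  structure(list(n = length(layer), edges = edges, layer = layer,
                 sources = sources, outputs = outputs,
                 describe_node = describe_node, convention = convention),
            class = "connectivity_dag")
}

#' @export
print.connectivity_dag <- function(x, ...) {
  cat("<connectivity_dag>", x$n, "nodes,", nrow(x$edges), "edges,",
      max(x$layer), "layers\n")
  cat("  convention:", x$convention, "\n")
  cat("  sources:", length(x$sources), " outputs:", length(x$outputs), "\n")
  invisible(x)
}

dag_tree <- function(spec) {
  cfg <- spec$config; g <- spec$geometry
  C <- cfg$channels; K <- cfg$filters; M <- cfg$branches
  H <- spec$heads; J <- g$slabs
  nw <- g$pooled_h * g$pooled_w
  classes <- cfg$classes
  n1 <- nw * K * C * M * H          # pooled units, per branch (and head)
  n2 <- J * C * M * H               # tree-sampling units
  off1 <- 0L; off2 <- n1; off3 <- n1 + n2
  n <- n1 + n2 + classes

  pr_of_w <- ((seq_len(nw) - 1L) %% g$pooled_h) + 1L
  j_of_w <- spec$cache$slab_of_row[pr_of_w]

  reps <- K * C * M * H
  j_vec <- rep(j_of_w, times = reps)
  c_vec <- rep(rep(seq_len(C), each = nw * K), times = M * H)
  m_vec <- rep(rep(seq_len(M), each = nw * K * C), times = H)
  h_vec <- rep(seq_len(H), each = nw * K * C * M)
  tree_id <- off2 + (h_vec - 1L) * (J * C * M) + (m_vec - 1L) * (J * C) +
    (c_vec - 1L) * J + j_vec
  e1 <- data.frame(from = off1 + seq_len(n1), to = tree_id)

  if (H > 1L) {
    # ten-head variant: each head's tree units feed only that head's output
    th <- rep(seq_len(H), each = J * C * M)
    e2 <- data.frame(from = off2 + seq_len(n2), to = off3 + th)
  } else {
    e2 <- data.frame(from = rep(off2 + seq_len(n2), times = classes),
                     to = rep(off3 + seq_len(classes), each = n2))
  }
  edges <- rbind(e1, e2)
  layer <- c(rep(1L, n1), rep(2L, n2), rep(3L, classes))

  describe_node <- function(id) {
    if (id <= n1) {
      i <- id - 1L
      w <- i %% nw; i <- i %/% nw
      k <- i %% K; i <- i %/% K
      cc <- i %% C; i <- i %/% C
      m <- i %% M; h <- i %/% M
      sprintf("pooled[r=%d,c=%d,filter=%d,channel=%d,branch=%d%s]",
              (w %% g$pooled_h) + 1L, (w %/% g$pooled_h) + 1L,
              k + 1L, cc + 1L, m + 1L,
              if (H > 1L) sprintf(",head=%d", h + 1L) else "")
    } else if (id <= n1 + n2) {
      i <- id - n1 - 1L
      j <- i %% J; i <- i %/% J
      cc <- i %% C; i <- i %/% C
      m <- i %% M; h <- i %/% M
      sprintf("tree[slab=%d,channel=%d,branch=%d%s]", j + 1L, cc + 1L,
              m + 1L, if (H > 1L) sprintf(",head=%d", h + 1L) else "")
    } else {
      sprintf("output[%d]", id - n1 - n2)
    }
  }
  new_dag(edges, layer, sources = seq_len(n1),
          outputs = off3 + seq_len(classes), describe_node,
          convention = "exact-DAG (per-branch logical graph)")
}

dag_lenet5 <- function(spec) {
  g <- spec$geometry
  p1 <- g$pool1; c2 <- g$conv2; p2 <- g$pool2
  classes <- spec$config$classes
  f <- spec$config$filter_size
  nw1 <- p1[1] * p1[2]; npos2 <- c2[1] * c2[2]; nw2 <- p2[1] * p2[2]
  n1 <- 6L * nw1; n2 <- 16L * npos2; n3 <- 16L * nw2
  off1 <- 0L; off2 <- n1; off3 <- n1 + n2; off4 <- off3 + n3
  off5 <- off4 + 120L; off6 <- off5 + 84L
  n <- off6 + classes

  # first pooled layer -> second conv: every conv-2 application reading the
  # pooled unit, over all 16 kernels, 6 input maps and f x f kernel positions
  grid <- expand.grid(i2 = seq_len(npos2), k2 = seq_len(16L),
                      fr = seq_len(f), fc = seq_len(f), k1 = seq_len(6L))
  oh <- ((grid$i2 - 1L) %% c2[1]) + 1L
  ow <- ((grid$i2 - 1L) %/% c2[1]) + 1L
  pos1 <- (ow + grid$fc - 2L) * p1[1] + (oh + grid$fr - 1L)
  e12 <- data.frame(from = off1 + (grid$k1 - 1L) * nw1 + pos1,
                    to = off2 + (grid$k2 - 1L) * npos2 + grid$i2)

  # conv-2 unit -> its pooled node (single-selection funnel)
  i2 <- seq_len(npos2)
  oh2 <- ((i2 - 1L) %% c2[1]) + 1L
  ow2 <- ((i2 - 1L) %/% c2[1]) + 1L
  posp <- ((ow2 - 1L) %/% 2L) * p2[1] + ((oh2 - 1L) %/% 2L) + 1L
  e23 <- data.frame(
    from = off2 + rep((seq_len(16L) - 1L) * npos2, each = npos2) + i2,
    to = off3 + rep((seq_len(16L) - 1L) * nw2, each = npos2) + posp)

  dense <- function(off_a, na, off_b, nb) {
    data.frame(from = rep(off_a + seq_len(na), times = nb),
               to = rep(off_b + seq_len(nb), each = na))
  }
  edges <- rbind(e12, e23,
                 dense(off3, n3, off4, 120L),
                 dense(off4, 120L, off5, 84L),
                 dense(off5, 84L, off6, classes))
  layer <- c(rep(1L, n1), rep(2L, n2), rep(3L, n3), rep(4L, 120L),
             rep(5L, 84L), rep(6L, classes))

  describe_node <- function(id) {
    if (id <= n1) {
      i <- id - 1L
      sprintf("pooled1[r=%d,c=%d,filter=%d]",
              (i %% nw1) %% p1[1] + 1L, (i %% nw1) %/% p1[1] + 1L,
              i %/% nw1 + 1L)
    } else if (id <= off3) {
      i <- id - off2 - 1L
      sprintf("conv2[r=%d,c=%d,filter=%d]",
              (i %% npos2) %% c2[1] + 1L, (i %% npos2) %/% c2[1] + 1L,
              i %/% npos2 + 1L)
    } else if (id <= off4) {
      i <- id - off3 - 1L
      sprintf("pooled2[r=%d,c=%d,filter=%d]",
              (i %% nw2) %% p2[1] + 1L, (i %% nw2) %/% p2[1] + 1L,
              i %/% nw2 + 1L)
    } else if (id <= off5) {
      sprintf("fc1[%d]", id - off4)
    } else if (id <= off6) {
      sprintf("fc2[%d]", id - off5)
    } else {
      sprintf("output[%d]", id - off6)
    }
  }
  new_dag(edges, layer, sources = seq_len(n1),
          outputs = off6 + seq_len(classes), describe_node,
          convention = "exact-DAG")
}

# Dynamic programming over the layered DAG: number of distinct directed
# paths from every node to each node in `targets`. Returns an n x
# length(targets) matrix satisfying count(node) = sum over successors.
path_count_matrix <- function(dag, targets = dag$outputs) {
  counts <- matrix(0, dag$n, length(targets))
  counts[cbind(targets, seq_along(targets))] <- 1
  from_layer <- dag$layer[dag$edges$from]
  for (l in seq(max(dag$layer) - 1L, 1L)) {
    sel <- from_layer == l
    if (!any(sel)) next
    e <- dag$edges[sel, ]
    agg <- rowsum(counts[e$to, , drop = FALSE], group = e$from)
    ids <- as.integer(rownames(agg))
    counts[ids, ] <- counts[ids, , drop = FALSE] + agg
  }
  counts
}

#' Exact route count between two units
#'
#' Number of distinct directed paths from `source` to `output` in the
#' connectivity DAG, by dynamic programming over the layered graph
#' (`count(node) = sum of count(successors)`). A node paired with itself has
#' exactly one (empty) path.
#'
#' @param dag a [connectivity_dag()].
#' @param source,output node ids.
#' @return a non-negative count (double; counts can exceed 2^31).
#' @export
count_paths_exact <- function(dag, source, output) {
  stopifnot(inherits(dag, "connectivity_dag"))
  if (source > dag$n || source < 1L || output > dag$n || output < 1L) {
    stop("node id out of range 1..", dag$n)
  }
  if (source == output) return(1)
  path_count_matrix(dag, targets = output)[source, 1]
}

#' Closed-form LeNet-5 route arithmetic
#'
#' Reproduces, step by step, the closed-form count of routes between a unit
#' of the first hidden layer and one output unit of LeNet-5: a pooled unit
#' feeds up to 25 applications of each of the 16 second-layer kernels
#' (16 x 25 = 400 routes); the second max-pooling is accounted for by
#' dividing by the window area (16 x 25 / 4 = 100); each surviving route then
#' splits over the fully connected widths (x 120, x 84), giving
#' 100 x 120 x 84 = 1,008,000. The division by 4 is an approximation of
#' pool-window overlap — exact DAG enumeration ([count_paths_exact()]) keeps
#' every window member as a distinct route through the pooled funnel and so
#' yields a larger count; both conventions are reported, neither silently
#' corrected.
#'
#' @param fc_widths widths of the two fully connected hidden layers the
#'   routes split over (default `c(120, 84)`).
#' @return a `path_count_report` list with the stepwise values:
#'   `per_kernel_applications` (25), `second_conv_kernels` (16),
#'   `pre_pool` (400), `post_pool` (100), `fc_widths`, `total` (1,008,000),
#'   and the convention tag.
#' @export
count_paths_closed_form_lenet5 <- function(fc_widths = c(120, 84)) {
  per_kernel <- 25
  kernels <- 16
  pre_pool <- kernels * per_kernel
  post_pool <- pre_pool / 4
  total <- post_pool * prod(fc_widths)
  structure(list(per_kernel_applications = per_kernel,
                 second_conv_kernels = kernels,
                 pre_pool = pre_pool, post_pool = post_pool,
                 fc_widths = fc_widths, total = total,
                 convention = "closed-form"),
            class = "path_count_report")
}

#' @export
print.path_count_report <- function(x, ...) {
  cat("<path_count_report> convention:", x$convention, "\n")
  cat(sprintf("  %d kernels x %d applications = %d routes; / %g (pooling) = %g\n",
              x$second_conv_kernels, x$per_kernel_applications, x$pre_pool,
              x$pre_pool / x$post_pool, x$post_pool))
  cat(sprintf("  x %s (fully connected) = %s total routes\n",
              paste(x$fc_widths, collapse = " x "),
              format(x$total, big.mark = ",")))
  invisible(x)
}

#' Certify the single-route property
#'
#' Checks whether every (first-hidden-layer unit, output unit) pair of the
#' architecture is connected by exactly one route in the logical per-branch
#' DAG. Tree architectures are certified with maximum route count 1 for any
#' number of kernels and branches; LeNet-5 is not — its witness counts exceed
#' one million.
#'
#' @param spec an `arch_spec`.
#' @return a `single_route_report`: `certified` (every first-hidden-layer
#'   unit reaches at least one output, and no (unit, output) pair has more
#'   than one route), `all_pairs_single` (the stronger statement that every
#'   (unit, output) pair has exactly one route — true for the single-head
#'   tree, false for the ten-head variant whose heads reach only their own
#'   output), `max_count`, `witness` (source label, output, count for a
#'   maximal pair), `n_sources`, `convention`.
#' @export
certify_single_route <- function(spec) {
  dag <- connectivity_dag(spec)
  counts <- path_count_matrix(dag)[dag$sources, , drop = FALSE]
  mx <- max(counts)
  w <- which(counts == mx, arr.ind = TRUE)[1, ]
  structure(list(
    certified = mx == 1 && all(rowSums(counts) >= 1),
    all_pairs_single = all(counts == 1),
    max_count = mx,
    min_count = min(counts),
    witness = list(source = dag$describe_node(dag$sources[w[1]]),
                   output = as.integer(w[2]), count = mx),
    n_sources = length(dag$sources),
    n_outputs = length(dag$outputs),
    variant = spec$variant,
    convention = dag$convention
  ), class = "single_route_report")
}

#' @export
print.single_route_report <- function(x, ...) {
  cat("<single_route_report>", x$variant, "\n")
  cat("  certified single-route:", x$certified, "\n")
  cat(sprintf("  route counts over %d source units x %d outputs: min %s, max %s\n",
              x$n_sources, x$n_outputs,
              format(x$min_count, big.mark = ","),
              format(x$max_count, big.mark = ",")))
  if (!x$certified) {
    cat("  witness:", x$witness$source, "-> output", x$witness$output,
        "with", format(x$witness$count, big.mark = ","), "routes\n")
  }
  cat("  convention:", x$convention, "\n")
  invisible(x)
}
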