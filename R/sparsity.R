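# Zero-gradient profiling, magnitude-threshold pruning, active-update
# accounting and gradient-magnitude histograms.

#' Profile structural zero-gradient fractions over a dataset
#'
#' For every sample (batch size 1 — batch averaging would destroy the
#' structural zeros being measured) the per-layer fraction of gradient
#' instances that are structural zeros is computed from the forward trace:
#' an instance is zero when its single route crosses a non-selected pooling
#' unit or an inactive unit (zero activation derivative). Reports the mean
#' and standard deviation over samples per layer, and the whole-step fraction
#' (instance-weighted mean over layers, dominated by the convolution layer
#' whose instances dominate the total). With Sigmoid activations no
#' structural zeros arise from the activation itself; only pooling
#' non-selection contributes, and magnitude thresholds
#' ([apply_threshold_pruning()]) are the relevant pruning notion.
#'
#' @param spec,params a tree architecture and its parameters.
#' @param batch an `image_batch` (labels are not needed: structural zeros are
#'   a property of the forward trace).
#' @return a `sparsity_profile`: data.frame `per_layer` (layer, mean zero
#'   fraction, sd, instance count per sample), `whole_step` fraction,
#'   `n_samples`.
#' @export
profile_zero_fraction <- function(spec, params, batch) {
  assert_tree_variant(spec, "profile_zero_fraction")
  if (length(dim(batch$x)) == 3L) dim(batch$x) <- c(dim(batch$x), 1L)
  n <- dim(batch$x)[4]
  if (n == 0L) stop("empty dataset")
  fracs <- matrix(0, n, 3, dimnames = list(NULL, c("conv", "tree", "fc")))
  total <- NULL
  for (i in seq_len(n)) {
    tr <- forward_pass(spec, params, array(batch$x[, , , i],
                                           dim(batch$x)[1:3]))
    zc <- structural_zero_counts(spec, tr)
    fracs[i, ] <- zc$zero / zc$total
    total <- zc$total
  }
  means <- colMeans(fracs)
  sds <- apply(fracs, 2, stats::sd)
  whole <- sum(means * total) / sum(total)
  structure(list(
    per_layer = data.frame(layer = c("conv", "tree", "fc"),
                           zero_fraction = unname(means),
                           sd = unname(sds),
                           instances = unname(total)),
    whole_step = whole,
    n_samples = n,
    activation = spec$config$activation
  ), class = "sparsity_profile")
}

#' @export
print.sparsity_profile <- function(x, ...) {
  cat("<sparsity_profile>", x$n_samples, "samples,",
      x$activation, "activation\n")
  print(x$per_layer, row.names = FALSE, digits = 4)
  cat(sprintf("  whole-step zero fraction: %.4f\n", x$whole_step))
  invisible(x)
}

#' Gradient pruning policy
#'
#' Either an absolute magnitude threshold (entries with `|gradient|` below it
#' are dropped) or a target active fraction (only the largest-magnitude
#' fraction of entries, pooled across layers, is kept).
#'
#' @param threshold absolute magnitude threshold, >= 0.
#' @param active_fraction target fraction of entries kept, in `(0, 1]`.
#'   Exactly one of the two must be given.
#' @return a `pruning_policy`.
#' @export
pruning_policy <- function(threshold = NULL, active_fraction = NULL) {
  if (is.null(threshold) == is.null(active_fraction)) {
    stop("give exactly one of threshold or active_fraction")
  }
  if (!is.null(threshold)) stopifnot(threshold >= 0)
  if (!is.null(active_fraction)) {
    stopifnot(active_fraction > 0, active_fraction <= 1)
  }
  structure(list(threshold = threshold, active_fraction = active_fraction),
            class = "pruning_policy")
}

#' Apply magnitude-threshold pruning to a gradient set
#'
#' Sets to zero every gradient entry whose absolute value falls below the
#' policy threshold (or outside the kept top fraction by magnitude, pooled
#' across all layers). With threshold 0 the gradients are returned unchanged.
#'
#' @param gradients a `gradient_set`.
#' @param policy a [pruning_policy()].
#' @return list with `gradients` (pruned `gradient_set`) and the realized
#'   `active_fraction` (nonzero entries / total entries after pruning).
#' @export
apply_threshold_pruning <- function(gradients, policy) {
  stopifnot(inherits(gradients, "gradient_set"),
            inherits(policy, "pruning_policy"))
  layer_names <- c("conv", "tree", "fc")
  mags <- abs(unlist(lapply(gradients[layer_names], as.vector),
                     use.names = FALSE))
  n_total <- length(mags)
  thr <- if (!is.null(policy$threshold)) {
    policy$threshold
  } else {
    k <- max(1L, floor(policy$active_fraction * n_total))
    # keep the k largest magnitudes: threshold just below the k-th largest
    kth <- sort(mags, decreasing = TRUE)[k]
    if (kth == 0) Inf else kth
  }
  kept <- 0L
  for (nm in layer_names) {
    g <- gradients[[nm]]
    if (is.null(policy$threshold)) {
      g[abs(g) < thr] <- 0       # keep ties at the k-th magnitude
    } else if (thr > 0) {
      g[abs(g) < thr] <- 0
    }
    gradients[[nm]] <- g
    kept <- kept + sum(g != 0)
  }
  list(gradients = gradients, active_fraction = kept / n_total)
}

#' Active-update accounting
#'
#' Number of gradient instances actually updated when only a given fraction
#' of gradients is active: `count_gradient_instances(spec, layer) * fraction`.
#' For the canonical Tree-3 (K = 6, M = 16) convolution layer at 0.6% active
#' gradients this is 5,644,800 * 0.006 = 33,869, i.e. ~34,000 to the nearest
#' thousand.
#'
#' @param spec an `arch_spec`.
#' @param active_fraction fraction in `(0, 1]`.
#' @param layer weighted layer name (default `"conv"`, which dominates the
#'   instance total).
#' @return list with `instances`, `active_fraction`, `exact` (rounded to the
#'   nearest integer) and `nearest_thousand`.
#' @export
active_update_count <- function(spec, active_fraction, layer = "conv") {
  stopifnot(active_fraction > 0, active_fraction <= 1)
  inst <- count_gradient_instances(spec, layer)
  x <- inst * active_fraction
  list(instances = inst, active_fraction = active_fraction,
       exact = round(x), nearest_thousand = round(x, -3))
}

#' Histogram of gradient magnitudes
#'
#' Log-spaced histogram of the absolute values of the nonzero gradient
#' entries, optionally with the relative-change variant `|gradient / weight|`
#' when the matching parameters are supplied.
#'
#' @param gradients a `gradient_set`.
#' @param bins number of log-spaced bins.
#' @param params optional `network_params` for the `|gradient / weight|`
#'   histogram.
#' @return a `gradient_histogram`: data.frame(s) with bin edges and counts;
#'   `empty = TRUE` (with zero rows) when all gradients are zero.
#' @export
gradient_magnitude_histogram <- function(gradients, bins = 30,
                                         params = NULL) {
  stopifnot(inherits(gradients, "gradient_set"))
  layer_names <- c("conv", "tree", "fc")
  g <- unlist(lapply(gradients[layer_names], as.vector), use.names = FALSE)
  mags <- abs(g[g != 0])
  hist_of <- function(v) {
    if (length(v) == 0L) {
      return(data.frame(lower = numeric(0), upper = numeric(0),
                        count = integer(0)))
    }
    lo <- min(v); hi <- max(v)
    if (lo == hi) {  # single magnitude: one occupied bin
      return(data.frame(lower = lo, upper = hi, count = length(v)))
    }
    br <- 10^seq(log10(lo), log10(hi), length.out = bins + 1L)
    br[1] <- lo; br[length(br)] <- hi
    cnt <- graphics::hist(v, breaks = br, plot = FALSE)$counts
    data.frame(lower = br[-length(br)], upper = br[-1], count = cnt)
  }
  abs_hist <- hist_of(mags)
  rel_hist <- NULL
  if (!is.null(params)) {
    w <- unlist(lapply(params[layer_names], as.vector), use.names = FALSE)
    ok <- g != 0 & w != 0
    rel_hist <- hist_of(abs(g[ok] / w[ok]))
  }
  structure(list(absolute = abs_hist, relative = rel_hist,
                 n_nonzero = length(mags), empty = length(mags) == 0L),
            class = "gradient_histogram")
}

#' @export
print.gradient_histogram <- function(x, ...) {
  if (x$empty) {
    cat("<gradient_histogram> all gradients zero (empty)\n")
    return(invisible(x))
  }
  cat("<gradient_histogram>", x$n_nonzero, "nonzero entries,",
      nrow(x$absolute), "log-spaced bins\n")
  invisible(x)
}
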