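# Internal helpers shared across modules.

# Run `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Fan one user-level seed out to named sub-seeds so components (init, data,
# augmentation, shuffling) can be varied independently. Kept well below 2^31.
fan_seed <- function(seed, stream = c("init", "data", "augment", "shuffle", "net")) {
  stream <- match.arg(stream)
  offset <- c(init = 101L, data = 211L, augment = 307L, shuffle = 401L,
              net = 503L)[[stream]]
  (as.integer(seed) %% 1000000L) * 1000L + offset
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

activation_fun <- function(kind) {
  switch(kind,
    relu = function(z) {
      r <- pmax(z, 0)
      dim(r) <- dim(z)
      r
    },
    sigmoid = function(z) 1 / (1 + exp(-z)),
    stop("unknown activation kind: ", kind)
  )
}

# Derivative evaluated at the pre-activation. For ReLU the subgradient at
# exactly 0 is taken as 0 (an inactive unit), matching the structural-zero
# bookkeeping of the pruned engine.
activation_deriv <- function(kind) {
  switch(kind,
    relu = function(z) (z > 0) * 1,
    sigmoid = function(z) {
      s <- 1 / (1 + exp(-z))
      s * (1 - s)
    },
    stop("unknown activation kind: ", kind)
  )
}

one_hot <- function(label, classes) {
  stopifnot(length(label) == 1L)
  if (label < 1L || label > classes) {
    stop("target class ", label, " out of range 1..", classes)
  }
  v <- numeric(classes)
  v[label] <- 1
  v
}

# Cheap fingerprint of a parameter set, used to detect stale traces.
params_token <- function(params) {
  tensors <- params[vapply(params, is.numeric, logical(1))]
  sums <- vapply(tensors, function(x) sum(x) + sum(x * x), numeric(1))
  paste(format(sums, digits = 17), collapse = "|")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Maximum relative elementwise discrepancy between two tensors, with the
# denominator taken as the larger overall magnitude (guards tiny tensors).
max_rel_diff <- function(a, b) {
  scale <- max(abs(a), abs(b), .Machine$double.eps)
  max(abs(a - b)) / scale
}
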