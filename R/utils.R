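# Internal helpers shared across modules.

# Deterministic sub-seed derived from a root seed and a component key, so that
# adding a component (e.g. a new trait) never perturbs the draws of earlier
# components. All arithmetic stays below 2^53 so it is exact in doubles; the
# result is a valid 32-bit integer seed.
derive_seed <- function(root, key) {
  stopifnot(is.numeric(root), length(root) == 1L, is.character(key))
  m <- 2147483629
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% m
  as.integer((h + (root %% m) * 48271) %% m)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards.
local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable deterministic ordering: primary key descending/ascending score,
# ties broken by identifier order.
order_scores <- function(scores, decreasing) {
  ids <- names(scores)
  ord <- order(if (decreasing) -scores else scores, ids, method = "radix")
  ids[ord]
}

stop_recsel <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_recsel <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Symmetrize and floor the eigenvalues of a covariance matrix at
# `tol * max(eigenvalue)` ("bending"). Returns the conditioned matrix with a
# logical attribute "bent" indicating whether any eigenvalue was raised.
bend_psd <- function(S, tol = 1e-6) {
  S <- (S + t(S)) / 2
  ee <- eigen(S, symmetric = TRUE)
  lam <- ee$values
  floor_val <- tol * max(lam, 0)
  bent <- any(lam < floor_val)
  lam2 <- pmax(lam, floor_val)
  out <- ee$vectors %*% (lam2 * t(ee$vectors))
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(S)
  attr(out, "bent") <- bent
  attr(out, "min_eigenvalue") <- min(lam)
  out
}
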