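#' @keywords internal
"_PACKAGE"

# Shared internal helpers: validation, reflect padding, convolution, RNG.

abort_if <- function(cond, msg) {
  if (isTRUE(cond)) stop(msg, call. = FALSE)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Reflect-pad a matrix by `k` pixels on every side. Used so that all
# convolution-based features are free of dark-border artifacts at chip edges.
pad_reflect <- function(m, k) {
  stopifnot(is.matrix(m), k >= 0)
  if (k == 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  abort_if(k >= nr || k >= nc, "padding exceeds image size")
  ri <- c(seq(k + 1, 2, -1), seq_len(nr), seq(nr - 1, nr - k, -1))
  ci <- c(seq(k + 1, 2, -1), seq_len(nc), seq(nc - 1, nc - k, -1))
  m[ri, ci, drop = FALSE]
}

# 2D convolution with reflect boundary handling; kernel must be odd-sized.
# For kernels larger than the image, reflection is applied in stages.
conv_reflect <- function(m, kern) {
  k <- max(dim(kern)) %/% 2L
  H <- nrow(m); W <- ncol(m)
  p <- m
  padded <- 0L
  while (padded < k) {
    step <- min(k - padded, min(dim(p)) - 1L)
    p <- pad_reflect(p, step)
    padded <- padded + step
  }
  out <- EBImage::filter2(p, kern, boundary = "circular")
  as.matrix(out[(padded + 1):(padded + H), (padded + 1):(padded + W),
                drop = FALSE])
}

# Gaussian blur with reflect boundary handling. The kernel is truncated at
# 4.5 sigma (mass error < 1e-5) so closed-form kernel identities hold to
# tight numerical tolerance.
gauss_blur <- function(m, sigma) {
  abort_if(!is_scalar_number(sigma) || sigma <= 0, "sigma must be > 0")
  r <- max(2L, as.integer(ceiling(4.5 * sigma)))
  g <- stats::dnorm(-r:r, sd = sigma)
  g <- g / sum(g)
  conv_reflect(m, outer(g, g))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`;
# the caller's RNG stream is left untouched.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a stream-specific child seed from a master seed (kept < 2^31).
child_seed <- function(seed, k) {
  (as.double(seed) * 1000003 + 7919 * as.double(k)) %% 2147483647
}
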