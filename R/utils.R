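# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library code never perturbs user-level
# random streams.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Stable derivation of per-stage / per-component seeds from one global seed.
# Kept below 2^31 so the result is always a valid `set.seed()` argument.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(offset)) %% 2147483629)
}

clamp01 <- function(x) {
  # pmin/pmax take attributes from their first argument; keep x's dims
  pmin(pmax(x, 0), 1)
}

stop_if_not_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  }
  invisible(x)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Column-wise Pearson correlation between two matrices of equal shape,
# returning one r per column. Zero-variance columns give NA.
colwise_cor <- function(A, B) {
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  num <- colSums(A * B)
  den <- sqrt(colSums(A^2) * colSums(B^2))
  r <- num / den
  r[den == 0] <- NA_real_
  r
}
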