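# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed, restoring global RNG state afterwards.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic sub-seed derivation; stays below 2^31 for any small base seed.
subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 1000003L) * 1009 + k) %% 2147483629L
}

# Magnitude (Rician) noise: |S + n1 + i n2| with n1, n2 ~ N(0, sigma).
# sigma = 0 returns the signal unchanged.
ricianNoise <- function(signal, sigma) {
  if (sigma <= 0) return(signal)
  n <- length(signal)
  out <- sqrt((signal + stats::rnorm(n, 0, sigma))^2 +
              stats::rnorm(n, 0, sigma)^2)
  array(out, dim = dim(signal))
}

# Smooth multiplicative bias field: 1 + amplitude * prod_axis cos(pi u_axis),
# u in [-1/2, 1/2] across each axis: 1 + amplitude at the volume centre,
# falling smoothly to 1 at the faces (coil-shading surrogate). amplitude in [0, 1).
biasField <- function(dims, amplitude) {
  if (amplitude == 0) return(array(1, dim = dims))
  ax <- lapply(dims, function(n) cospi(seq(-0.5, 0.5, length.out = n)))
  f <- outer(outer(ax[[1]], ax[[2]]), ax[[3]])
  array(1 + amplitude * f, dim = dims)
}

# stopifnot-style check with a typed message prefix
assertThat <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
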