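# Shared fixtures: cached phantoms and deterministic textured slices.

.fixtures <- new.env(parent = emptyenv())

cached_phantom <- function(shape = c(32, 32, 32), seed = 0) {
  key <- paste(c(shape, seed), collapse = "-")
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- make_phantom(shape = shape, seed = seed)
  }
  .fixtures[[key]]
}

# smooth random texture slice in roughly [0, 1]
textured_slice <- function(n = 32, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * n), n, n)
  k <- outer(dnorm(-3:3), dnorm(-3:3))
  sm <- moqam:::filt2(m, k / sum(k))
  (sm - min(sm)) / (max(sm) - min(sm))
}

# central percentile-normalized multiply-masked phantom slice
phantom_slice <- function(seed = 0) {
  ph <- cached_phantom(seed = seed)
  cfg <- pipeline_config(mask_mode = "multiply", norm_mode = "percentile")
  nv <- normalize_volume(ph$volume, ph$mask, cfg)
  k <- dim(nv$data)[3] %/% 2
  nv$data[, , k] * ph$mask$data[, , k]
}
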