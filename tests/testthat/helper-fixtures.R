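# Shared fixtures built in code at test time.

# small constant-valued volume
const_volume <- function(value, dims = c(6, 8, 8), spacing = c(1, 1, 1)) {
  volume(array(value, dim = dims), spacing = spacing)
}

# cube of `inside` HU centred in a -1000 background
cube_volume <- function(dims = c(10, 12, 12), inside = 0, margin = 3,
                        spacing = c(1, 1, 1)) {
  v <- array(-1000, dim = dims)
  idx <- lapply(dims, function(n) (margin + 1):(n - margin))
  v[idx[[1]], idx[[2]], idx[[3]]] <- inside
  volume(v, spacing = spacing)
}

cube_mask <- function(dims = c(10, 12, 12), margin = 3, spacing = c(1, 1, 1)) {
  m <- array(FALSE, dim = dims)
  idx <- lapply(dims, function(n) (margin + 1):(n - margin))
  m[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
  binary_mask(m, spacing = spacing)
}

# paired smooth dose grids: same blob geometry, eval slightly shifted and
# rescaled so some voxels fail tight gamma criteria
random_dose_pair <- function(seed, shape = c(20, 20, 20), spacing = c(3, 3, 3)) {
  blobs <- withr::with_seed(seed, {
    lapply(seq_len(3), function(i)
      list(center_mm = stats::runif(3, 12, 45),
           width_mm = stats::runif(1, 7, 12),
           peak_gy = stats::runif(1, 30, 70)))
  })
  shifts <- withr::with_seed(seed + 5000L, {
    lapply(seq_len(3), function(i) stats::rnorm(3, 0, 1.2))
  })
  scale <- withr::with_seed(seed + 9000L, stats::runif(1, 0.97, 1.03))
  blobs2 <- lapply(seq_len(3), function(i) {
    b <- blobs[[i]]
    b$center_mm <- b$center_mm + shifts[[i]]
    b$peak_gy <- b$peak_gy * scale
    b
  })
  list(ref = generate_dose_grid(shape, spacing, blobs),
       eval = generate_dose_grid(shape, spacing, blobs2))
}

# exhaustive 2^n enumeration of the signed-rank null, two-sided
wilcoxon_enum_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  wall <- as.vector(signs %*% r)
  p_le <- mean(wall <= w)
  p_ge <- mean(wall >= w)
  min(1, 2 * min(p_le, p_ge))
}
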