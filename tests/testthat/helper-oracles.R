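# Independent oracles and small fixture builders. Everything here is kept
# deliberately brute-force so it cannot share a defect with the package path
# it checks.

# all-pairs Euclidean distance from every voxel to the nearest set voxel
# centre; infinity when the mask is empty
brute_distance <- function(flags, spacing) {
  dims <- dim(flags)
  idx_all <- which(array(TRUE, dims), arr.ind = TRUE)
  idx_set <- which(flags, arr.ind = TRUE)
  out <- array(Inf, dims)
  if (nrow(idx_set) == 0L) return(out)
  wset <- sweep(idx_set, 2, spacing, `*`)
  wall <- sweep(idx_all, 2, spacing, `*`)
  for (i in seq_len(nrow(wall))) {
    d2 <- (wset[, 1] - wall[i, 1])^2 + (wset[, 2] - wall[i, 2])^2 +
      (wset[, 3] - wall[i, 3])^2
    out[i] <- sqrt(min(d2))
  }
  out
}

brute_expand <- function(flags, spacing, margin) {
  brute_distance(flags, spacing) <= margin
}

brute_shrink <- function(flags, spacing, margin) {
  flags & (brute_distance(!flags, spacing) >= margin)
}

# nearest-neighbour pull-back of a volume through a displacement field (mm)
nn_pullback <- function(vals, field, spacing) {
  dims <- dim(vals)
  out <- array(0, dims)
  for (x in seq_len(dims[3])) for (y in seq_len(dims[2]))
    for (z in seq_len(dims[1])) {
      tz <- round(z + field[z, y, x, 1] / spacing[1])
      ty <- round(y + field[z, y, x, 2] / spacing[2])
      tx <- round(x + field[z, y, x, 3] / spacing[3])
      if (tz >= 1 && tz <= dims[1] && ty >= 1 && ty <= dims[2] &&
          tx >= 1 && tx <= dims[3])
        out[z, y, x] <- vals[tz, ty, tx]
    }
  out
}

# random smooth blob mask: union of a few random digital balls
random_blob <- function(dims = c(16, 16, 16), spacing = c(1, 1, 1),
                        n_balls = 3, r_range = c(2.5, 4.5)) {
  flags <- array(FALSE, dims)
  idx <- which(array(TRUE, dims), arr.ind = TRUE)
  w <- sweep(idx, 2, spacing, `*`)
  for (b in seq_len(n_balls)) {
    ctr <- spacing * (dims / 4 + runif(3) * dims / 2)
    r <- runif(1, r_range[1], r_range[2])
    d2 <- (w[, 1] - ctr[1])^2 + (w[, 2] - ctr[2])^2 + (w[, 3] - ctr[3])^2
    flags[d2 <= r^2] <- TRUE
  }
  flags
}

ball_mask <- function(dims, spacing, centre, radius) {
  idx <- which(array(TRUE, dims), arr.ind = TRUE)
  w <- sweep(idx, 2, spacing, `*`)
  d2 <- (w[, 1] - centre[1])^2 + (w[, 2] - centre[2])^2 +
    (w[, 3] - centre[3])^2
  array(d2 <= radius^2, dims)
}

ramp_fixture <- function(n = 100) {
  list(dose = grid3d(array(as.numeric(1:n), c(n, 1, 1)),
                     spacing = c(1, 1, 1)),
       mask = mask3d(array(TRUE, c(n, 1, 1)), spacing = c(1, 1, 1)))
}

uniform_fixture <- function(value, dims = c(4, 4, 4)) {
  list(dose = grid3d(array(value, dims), spacing = c(1, 1, 1)),
       mask = mask3d(array(TRUE, dims), spacing = c(1, 1, 1)))
}

# small shared phantom for pipeline-level tests (48^3 keeps tests quick)
small_config <- function(seed = 1L) {
  run_config(
    phantom = phantom_config(shape = c(48, 48, 48), spacing = c(2, 2, 2)),
    fractions_per_phase = c(3, 3),
    phase_course = c("boost", "initial"),
    seed = seed)
}
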