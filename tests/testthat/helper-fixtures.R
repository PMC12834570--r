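# Small fixtures shared across tests: a coarse phantom (same 92 mm field of
# view as the default, 4 mm voxels) and a short 10-frame schedule whose last
# two frames start after the 2-minute reference cutoff.

tiny_spec <- function(...) {
  phantom_spec(grid_shape = c(24L, 24L, 24L), spacing_mm = c(4, 4, 4), ...)
}

tiny_schedule <- function() {
  frame_schedule(c(0, 10, 20, 30, 40, 50, 60, 90, 120, 360),
                 c(10, 10, 10, 10, 10, 10, 30, 30, 240, 240))
}

tiny_study <- function(noise_scale = 0, seed = 1, ...) {
  phantom_study(tiny_spec(noise_scale = noise_scale, ...),
                schedule = tiny_schedule(), seed = seed)
}

# Independent integer-voxel shift oracle: plain index rolling with zero fill.
roll_shift <- function(vol, s) {
  d <- dim(vol)
  out <- array(0, d)
  src <- lapply(1:3, function(ax) (seq_len(d[ax])) - s[ax])
  ok <- lapply(1:3, function(ax) src[[ax]] >= 1 & src[[ax]] <= d[ax])
  out[ok[[1]], ok[[2]], ok[[3]]] <-
    vol[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]]]
  out
}

# Masked Pearson correlation, used as an independent NCC evaluation.
ncc_of <- function(a, b, mask) stats::cor(a[mask], b[mask])
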