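# build a tiny trajectory from explicit GS- positions (one replicate,
# disulfide sulfurs at (-1,0,0)/(1,0,0) so the midpoint is the origin)
tiny_traj <- function(gs_xyz, n_gs = 1L, cys = c(-1, 0, 0),
                      moi = c(1, 0, 0), replicate = 1L) {
  gs_xyz <- matrix(gs_xyz, ncol = 3, byrow = FALSE)
  n_rows <- nrow(gs_xyz)
  n_frames <- n_rows / n_gs
  idx <- expand.grid(gs_index = seq_len(n_gs), frame = seq_len(n_frames))
  gs <- data.frame(replicate = replicate, frame = idx$frame,
                   gs_index = idx$gs_index,
                   x = gs_xyz[, 1], y = gs_xyz[, 2], z = gs_xyz[, 3])
  ds <- data.frame(replicate = replicate, frame = seq_len(n_frames),
                   cys_x = cys[1], cys_y = cys[2], cys_z = cys[3],
                   moiety_x = moi[1], moiety_y = moi[2], moiety_z = moi[3])
  gs_trajectory(gs, ds)
}

# noiseless MM rates v = e0 * kcat * s / (km + s)
mm_rates <- function(s, kcat, km, e0 = 1e-8) e0 * kcat * s / (km + s)

# random microscopic rate set on log-uniform scales
random_rates <- function() {
  microscopic_rates(
    k1 = 10^runif(1, 3, 6), k_minus1 = 10^runif(1, -1, 3),
    k2 = 10^runif(1, 0, 3),
    k4 = 10^runif(1, 3, 6), k_minus4 = 10^runif(1, -1, 3),
    k5 = 10^runif(1, 0, 3))
}
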