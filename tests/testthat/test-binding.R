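test_that("binding detection uses an inclusive 5.5 A midpoint criterion", {
  # disulfide at (-1,0,0)/(1,0,0): midpoint is the origin
  traj <- tiny_traj(rbind(c(5.4, 0, 0), c(5.6, 0, 0), c(5.5, 0, 0)))
  ev <- detect_bound(traj)
  expect_equal(ev$frame, c(1L, 3L))
  expect_equal(ev$s_s_distance, c(5.4, 5.5))

  # disulfide at (0,0,0)/(2,0,0), GS- at (6.5,0,0): distance to the
  # midpoint (1,0,0) is exactly 5.5 -> bound (inclusive boundary)
  traj2 <- tiny_traj(c(6.5, 0, 0), cys = c(0, 0, 0), moi = c(2, 0, 0))
  expect_equal(nrow(detect_bound(traj2)), 1L)
})

test_that("binding detection is invariant under rigid transforms", {
  set.seed(5)
  pts <- matrix(runif(30, -8, 8), ncol = 3)
  traj <- tiny_traj(pts)
  ev0 <- detect_bound(traj)

  # random rotation + translation applied to every atom
  ang <- 0.7
  rot <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1), 3)
  shift <- c(3, -2, 5)
  tf <- function(m) sweep(as.matrix(m) %*% t(rot), 2, -shift)
  gs2 <- traj$gs
  gs2[, c("x", "y", "z")] <- tf(gs2[, c("x", "y", "z")])
  ds2 <- traj$disulfide
  ds2[, c("cys_x", "cys_y", "cys_z")] <-
    tf(ds2[, c("cys_x", "cys_y", "cys_z")])
  ds2[, c("moiety_x", "moiety_y", "moiety_z")] <-
    tf(ds2[, c("moiety_x", "moiety_y", "moiety_z")])
  ev1 <- detect_bound(gs_trajectory(gs2, ds2))
  expect_equal(ev1$frame, ev0$frame)
  expect_equal(ev1$s_s_distance, ev0$s_s_distance, tolerance = 1e-9)
  expect_equal(ev1$s_s_s_angle, ev0$s_s_s_angle, tolerance = 1e-9)
})

test_that("three-sulfur angles follow the vertex convention", {
  # GS- on the far side of the cysteine sulfur, collinear: angle 180
  traj <- tiny_traj(c(-4, 0, 0))
  expect_equal(detect_bound(traj)$s_s_s_angle, 180)
  # right angle at the cysteine sulfur
  traj2 <- tiny_traj(c(-1, 3, 0))
  expect_equal(detect_bound(traj2)$s_s_s_angle, 90)
  # vertex at the GS- sulfur instead, same fixture
  ev_gs <- detect_bound(traj2, angle_vertex = "gs")
  u <- c(-1, 0, 0) - c(-1, 3, 0)  # GS- -> cys S
  v <- c(1, 0, 0) - c(-1, 3, 0)   # GS- -> moiety S
  expected <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  expect_equal(ev_gs$s_s_s_angle, expected, tolerance = 1e-9)
})

test_that("fraction bound counts frames with at least one event", {
  # 100 frames, 34 bound (GS- at 3 A), 66 unbound (at 12 A)
  r <- c(rep(3, 34), rep(12, 66))
  traj <- tiny_traj(cbind(r, 0, 0))
  fb <- fraction_bound(traj)
  expect_equal(fb$per_replicate$fraction, 0.34)
  expect_equal(fb$per_replicate$n_bound, 34L)

  # all frames bound
  fb1 <- fraction_bound(tiny_traj(cbind(rep(2, 10), 0, 0)))
  expect_equal(fb1$mean, 1.0)
})

test_that("variant comparison matches the hand-computed Welch statistic", {
  wt <- list(per_replicate = data.frame(fraction = c(0.20, 0.22, 0.18, 0.21)))
  mut <- list(per_replicate = data.frame(fraction = c(0.07, 0.06, 0.08, 0.07)))
  cmp <- compare_fraction_bound(wt, mut)
  x <- mut$per_replicate$fraction; y <- wt$per_replicate$fraction
  se <- sqrt(var(x) / 4 + var(y) / 4)
  t_hand <- (mean(x) - mean(y)) / se
  df_hand <- se^4 / ((var(x) / 4)^2 / 3 + (var(y) / 4)^2 / 3)
  expect_equal(cmp$t, t_hand)
  expect_equal(cmp$df, df_hand)
  expect_equal(cmp$p, 2 * pt(-abs(t_hand), df_hand))
  expect_equal(cmp$percent_of_ref, 100 * mean(x) / mean(y))

  # normalisation of the reference to itself is exactly 100 %
  expect_equal(compare_fraction_bound(wt, wt)$percent_of_ref, 100)
})

test_that("distance-angle correlation equals brute-force Pearson", {
  set.seed(9)
  pts <- cbind(runif(10, 2, 5.4), runif(10, -1, 1), runif(10, -1, 1))
  traj <- tiny_traj(pts)
  geo <- sss_geometry(traj)
  expect_equal(geo$n_events, 10L)
  d <- geo$events$s_s_distance; a <- geo$events$s_s_s_angle
  r_brute <- sum((d - mean(d)) * (a - mean(a))) /
    sqrt(sum((d - mean(d))^2) * sum((a - mean(a))^2))
  expect_equal(geo$r_squared, r_brute^2, tolerance = 1e-12)
  expect_equal(sum(geo$histogram$count), 10L)

  # fewer than 3 events: correlation flagged undefined
  geo2 <- sss_geometry(tiny_traj(rbind(c(3, 0, 0), c(12, 0, 0))))
  expect_false(geo2$correlation_defined)
})

test_that("occupancy grids conserve counts across spacings", {
  # single stationary bound GS- over N frames -> one voxel with count N
  traj <- tiny_traj(cbind(rep(3.2, 25), 0.1, 0.1))
  g <- occupation_density(traj, spacing = 1)
  expect_equal(sum(g$counts), 25L)
  expect_equal(sum(g$counts > 0), 1L)

  # counts conserved under spacing refinement; total = bound samples
  set.seed(3)
  pts <- cbind(runif(200, -5, 5), runif(200, -5, 5), runif(200, -5, 5))
  traj2 <- tiny_traj(pts)
  n_bound <- nrow(detect_bound(traj2))
  for (sp in c(2, 1, 0.5)) {
    expect_equal(sum(occupation_density(traj2, spacing = sp)$counts), n_bound)
  }
})

test_that("flood fill separates disjoint occupancy sites", {
  # two bound clusters on opposite sides of the disulfide midpoint
  site1 <- cbind(rep(-4, 20) + runif(20, 0, 0.3), 0, 0)
  site2 <- cbind(rep(4, 30) + runif(30, 0, 0.3), 0, 0)
  traj <- tiny_traj(rbind(site1, site2))
  g <- occupation_density(traj, spacing = 1)
  comp <- density_components(g, threshold = 0)
  expect_equal(attr(comp, "n_components"), 2L)
  # empty grid warns
  expect_warning(occupation_density(tiny_traj(c(15, 0, 0))), "no bound")
})

test_that("approach paths are extracted and smoothed as documented", {
  # straight-line approach: smoothing leaves a straight polyline intact
  xs <- seq(10, 3, length.out = 8)
  traj <- tiny_traj(cbind(xs, 0, 0))
  ev <- detect_bound(traj)
  path <- linearize_path(traj, ev[nrow(ev), ], window = 8, smooth_width = 3)
  expect_equal(nrow(path), 8)
  # interior points of a straight line are unchanged by the moving average
  expect_equal(path[2:7, "x"], xs[2:7], ignore_attr = TRUE)
  expect_true(all(abs(path[, "y"]) < 1e-12))

  # window 1: a single point
  p1 <- linearize_path(traj, ev[nrow(ev), ], window = 1)
  expect_equal(nrow(p1), 1)

  # zig-zag equals the hand-computed centred moving average
  z <- c(0, 1, 0, 1, 0, 1)
  trajz <- tiny_traj(cbind(seq(8, 3, length.out = 6), z, 0))
  evz <- detect_bound(trajz)
  pz <- linearize_path(trajz, evz[nrow(evz), ], window = 6, smooth_width = 3)
  hand <- c(mean(z[1:2]), mean(z[1:3]), mean(z[2:4]),
            mean(z[3:5]), mean(z[4:6]), mean(z[5:6]))
  expect_equal(pz[, "y"], hand, ignore_attr = TRUE)

  # event earlier than the window start is flagged truncated
  pt <- linearize_path(traj, list(replicate = 1, frame = 2, gs_index = 1),
                       window = 10)
  expect_true(attr(pt, "truncated"))
})

test_that("superposition RMSD matches independent oracles", {
  # 3-atom toy pair: b is a rotated copy of a -> RMSD 0
  a <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0))
  ang <- 1.1
  rot <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1), 3)
  expect_equal(kabsch_rmsd(a, a %*% t(rot)), 0, tolerance = 1e-9)

  # perturbed pair vs brute-force minimisation over rotation angles
  set.seed(11)
  b <- a %*% t(rot) + matrix(rnorm(9, 0, 0.1), 3)
  brute <- function(a, b) {
    ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
    obj <- function(p) {
      cx <- cos(p[1]); sx <- sin(p[1]); cy <- cos(p[2]); sy <- sin(p[2])
      cz <- cos(p[3]); sz <- sin(p[3])
      rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
      ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
      rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
      sqrt(sum((ac - bc %*% t(rx %*% ry %*% rz))^2) / nrow(a))
    }
    best <- Inf
    for (i in 1:40) {
      o <- optim(runif(3, -pi, pi), obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 5000))
      best <- min(best, o$value)
    }
    best
  }
  expect_equal(kabsch_rmsd(a, b), brute(a, b), tolerance = 1e-6)

  # independent library cross-check of the superposition RMSD
  fitted <- suppressWarnings(bio3d::fit.xyz(fixed = as.vector(t(a)),
                                            mobile = as.vector(t(b))))
  b_fit <- matrix(fitted, ncol = 3, byrow = TRUE)
  expect_equal(kabsch_rmsd(a, b), sqrt(sum((a - b_fit)^2) / nrow(a)),
               tolerance = 1e-6)
})

test_that("pose clustering separates groups and picks representatives", {
  # duplicated identical poses -> a single cluster, RMSD 0
  pose <- rbind(c(0, 0, 0), c(2, 0, 0), c(1, 2, 0))
  cl <- cluster_poses(list(pose, pose, pose), k = 2)
  expect_equal(length(unique(cl$assignment)), 1L)
  expect_equal(max(as.matrix(cl$rmsd)), 0)

  # two well-separated synthetic groups (inter ~10x intra) -> exactly 2
  set.seed(21)
  mk <- function(base, jitter) base + matrix(rnorm(9, 0, jitter), 3)
  far <- rbind(c(0, 0, 10), c(2, 0, 12), c(1, 5, 10))
  poses <- c(lapply(1:5, function(i) mk(pose, 0.05)),
             lapply(1:3, function(i) mk(far, 0.05)))
  cl2 <- cluster_poses(poses, k = 2)
  expect_equal(cl2$assignment, c(rep(1L, 5), rep(2L, 3)))
  expect_equal(cl2$sizes, c(5L, 3L))  # ordered by population
  expect_true(cl2$representatives[1] %in% 1:5)

  # singleton input: one cluster
  expect_equal(cluster_poses(list(pose))$assignment, 1L)
})

test_that("pose extraction pairs events with their frame coordinates", {
  traj <- tiny_traj(rbind(c(3, 1, 0), c(12, 0, 0), c(2, -1, 1)))
  ev <- detect_bound(traj)
  poses <- gs_poses(traj, ev)
  expect_equal(length(poses), 2L)
  expect_equal(unname(poses[[1]]["gs", ]), c(3, 1, 0))
  expect_equal(unname(poses[[1]]["cys", ]), c(-1, 0, 0))
})
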