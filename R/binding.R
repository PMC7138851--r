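#' Glutathione-anion trajectory container
#'
#' Holds multi-replicate, multi-frame coordinates (angstrom) of the sulfur
#' atoms of freely diffusing GS- molecules together with the two sulfur
#' atoms of the active-site mixed disulfide (the glutathionylated cysteine).
#' Trajectories are assumed unwrapped (no periodic-boundary handling).
#'
#' @param gs data frame `replicate`, `frame`, `gs_index`, `x`, `y`, `z`:
#'   one row per GS- sulfur per frame.
#' @param disulfide data frame `replicate`, `frame`, `cys_x`, `cys_y`,
#'   `cys_z`, `moiety_x`, `moiety_y`, `moiety_z`: the active-site cysteine
#'   sulfur and the glutathione-moiety sulfur per frame.
#' @param frame_interval_ps interval between saved frames (ps), default 20.
#' @return A `gs_trajectory` object.
#' @export
gs_trajectory <- function(gs, disulfide, frame_interval_ps = 20) {
  gs <- as.data.frame(gs)
  disulfide <- as.data.frame(disulfide)
  stopifnot(all(c("replicate", "frame", "gs_index", "x", "y", "z") %in% names(gs)),
            all(c("replicate", "frame", "cys_x", "cys_y", "cys_z",
                  "moiety_x", "moiety_y", "moiety_z") %in% names(disulfide)))
  if (any(!is.finite(as.matrix(gs[, c("x", "y", "z")])))) {
    stop("GS- coordinates must be finite")
  }
  structure(list(gs = gs, disulfide = disulfide,
                 frame_interval_ps = frame_interval_ps),
            class = "gs_trajectory")
}

#' Detect binding events by the sulfur distance criterion
#'
#' A binding event is recorded for every GS- sulfur whose distance to the
#' centre of mass of the two disulfide sulfur atoms (equal masses, i.e.
#' their midpoint) is at most the cutoff; the boundary is inclusive. The
#' S-S-S angle is also computed for each event (see `angle_vertex`).
#'
#' @param traj A [gs_trajectory()].
#' @param cutoff distance cutoff (angstrom), default 5.5.
#' @param angle_vertex vertex convention for the three-sulfur angle:
#'   `"cys"` (default) places the vertex at the active-site cysteine sulfur,
#'   `"gs"` at the incoming GS- sulfur.
#' @return Data frame of events: `replicate`, `frame`, `gs_index`,
#'   `s_s_distance` (to the midpoint), `s_s_s_angle` (degrees).
#' @export
detect_bound <- function(traj, cutoff = 5.5, angle_vertex = c("cys", "gs")) {
  stopifnot(inherits(traj, "gs_trajectory"))
  angle_vertex <- match.arg(angle_vertex)
  m <- merge(traj$gs, traj$disulfide, by = c("replicate", "frame"))
  mid <- cbind((m$cys_x + m$moiety_x) / 2,
               (m$cys_y + m$moiety_y) / 2,
               (m$cys_z + m$moiety_z) / 2)
  gsxyz <- cbind(m$x, m$y, m$z)
  d <- sqrt(rowSums((gsxyz - mid)^2))
  sel <- d <= cutoff
  m <- m[sel, , drop = FALSE]
  if (nrow(m) == 0L) {
    return(data.frame(replicate = integer(0), frame = integer(0),
                      gs_index = integer(0), s_s_distance = numeric(0),
                      s_s_s_angle = numeric(0)))
  }
  gsxyz <- gsxyz[sel, , drop = FALSE]
  cys <- cbind(m$cys_x, m$cys_y, m$cys_z)
  moi <- cbind(m$moiety_x, m$moiety_y, m$moiety_z)
  ang <- if (angle_vertex == "cys") {
    vector_angle(gsxyz - cys, moi - cys)
  } else {
    vector_angle(cys - gsxyz, moi - gsxyz)
  }
  out <- data.frame(replicate = m$replicate, frame = m$frame,
                    gs_index = m$gs_index, s_s_distance = d[sel],
                    s_s_s_angle = ang)
  out[order(out$replicate, out$frame, out$gs_index), , drop = FALSE]
}

# angle (degrees) between paired row vectors
vector_angle <- function(u, v) {
  cosang <- rowSums(u * v) /
    (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Fraction of frames with a bound GS-
#'
#' Binding frequency per replication: the fraction of frames with at least
#' one binding event among all frames of that replication; summarised as
#' mean +/- standard error over replications.
#'
#' @param traj A [gs_trajectory()].
#' @param cutoff distance cutoff (angstrom).
#' @return List: `per_replicate` (data frame `replicate`, `n_frames`,
#'   `n_bound`, `fraction`), `mean`, `sem`.
#' @export
fraction_bound <- function(traj, cutoff = 5.5) {
  stopifnot(inherits(traj, "gs_trajectory"))
  if (nrow(traj$gs) == 0L) stop("empty trajectory")
  ev <- detect_bound(traj, cutoff = cutoff)
  frames <- unique(traj$gs[, c("replicate", "frame")])
  reps <- sort(unique(frames$replicate))
  per <- do.call(rbind, lapply(reps, function(r) {
    n_frames <- sum(frames$replicate == r)
    bound_frames <- unique(ev$frame[ev$replicate == r])
    data.frame(replicate = r, n_frames = n_frames,
               n_bound = length(bound_frames),
               fraction = length(bound_frames) / n_frames)
  }))
  f <- per$fraction
  list(per_replicate = per, mean = mean(f),
       sem = if (length(f) > 1) stats::sd(f) / sqrt(length(f)) else NA_real_)
}

#' Compare bound fractions between two variants
#'
#' Normalises the mutant mean bound fraction to the reference (wild type =
#' 100 %) and tests the per-replication fractions with a two-tailed Welch
#' t test (unequal variances).
#'
#' @param ref,mut results of [fraction_bound()] for the reference and the
#'   variant trajectory.
#' @return List: `percent_of_ref`, `fold_change`, `t`, `df`, `p`.
#' @export
compare_fraction_bound <- function(ref, mut) {
  fr <- ref$per_replicate$fraction
  fm <- mut$per_replicate$fraction
  tt <- stats::t.test(fm, fr, var.equal = FALSE)
  list(percent_of_ref = 100 * mean(fm) / mean(fr),
       fold_change = mean(fm) / mean(fr),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Distance-angle geometry of binding events
#'
#' Pools binding events over replications and returns the per-event
#' (S-S distance, S-S-S angle) table, a 2D histogram on fixed-width bins,
#' and the Pearson correlation (R-squared with p-value) between distance
#' and angle.
#'
#' @param traj A [gs_trajectory()].
#' @param cutoff distance cutoff (angstrom).
#' @param dist_bin,angle_bin histogram bin widths (angstrom; degrees).
#' @param angle_vertex see [detect_bound()].
#' @return List: `events`, `histogram` (data frame `dist_lo`, `angle_lo`,
#'   `count`), `r_squared`, `p_value`, `n_events`; correlation entries are
#'   `NA` (flagged by `correlation_defined = FALSE`) with fewer than 3 events.
#' @export
sss_geometry <- function(traj, cutoff = 5.5, dist_bin = 0.1, angle_bin = 2,
                         angle_vertex = "cys") {
  ev <- detect_bound(traj, cutoff = cutoff, angle_vertex = angle_vertex)
  n <- nrow(ev)
  if (n >= 3L) {
    ct <- stats::cor.test(ev$s_s_distance, ev$s_s_s_angle, method = "pearson")
    r2 <- unname(ct$estimate)^2
    p <- ct$p.value
    defined <- TRUE
  } else {
    r2 <- NA_real_; p <- NA_real_; defined <- FALSE
  }
  hist_tab <- if (n > 0) {
    dl <- floor(ev$s_s_distance / dist_bin) * dist_bin
    al <- floor(ev$s_s_s_angle / angle_bin) * angle_bin
    agg <- stats::aggregate(list(count = rep(1L, n)),
                            by = list(dist_lo = dl, angle_lo = al), FUN = sum)
    agg[order(agg$dist_lo, agg$angle_lo), ]
  } else {
    data.frame(dist_lo = numeric(0), angle_lo = numeric(0), count = integer(0))
  }
  list(events = ev, histogram = hist_tab, r_squared = r2, p_value = p,
       n_events = n, correlation_defined = defined)
}

#' Occupancy density grid of bound GS- sulfur positions
#'
#' Bins the positions of GS- sulfurs in the bound state (events pooled
#' across replications) onto a regular 3D grid. The same caller-fixed
#' iso-threshold can then be applied across variants for comparable
#' visualisation.
#'
#' @param traj A [gs_trajectory()].
#' @param spacing voxel edge length (angstrom).
#' @param cutoff distance cutoff (angstrom).
#' @param origin grid origin; default: floor of the minimal bound
#'   coordinates on the spacing lattice.
#' @return A `density_grid`: list with `counts` (3D array), `origin`,
#'   `spacing`, `dims`, `n_samples`.
#' @export
occupation_density <- function(traj, spacing = 1, cutoff = 5.5,
                               origin = NULL) {
  stopifnot(spacing > 0)
  ev <- detect_bound(traj, cutoff = cutoff)
  key_ev <- paste(ev$replicate, ev$frame, ev$gs_index)
  key_gs <- paste(traj$gs$replicate, traj$gs$frame, traj$gs$gs_index)
  pts <- as.matrix(traj$gs[key_gs %in% key_ev, c("x", "y", "z")])
  if (nrow(pts) == 0L) {
    warning("no bound states; returning empty grid")
    return(structure(list(counts = array(0L, c(0, 0, 0)),
                          origin = c(0, 0, 0), spacing = spacing,
                          dims = c(0L, 0L, 0L), n_samples = 0L),
                     class = "density_grid"))
  }
  if (is.null(origin)) origin <- floor(apply(pts, 2, min) / spacing) * spacing
  idx <- floor(sweep(pts, 2, origin) / spacing) + 1L
  dims <- apply(idx, 2, max)
  counts <- array(0L, dim = dims)
  for (i in seq_len(nrow(idx))) {
    counts[idx[i, 1], idx[i, 2], idx[i, 3]] <-
      counts[idx[i, 1], idx[i, 2], idx[i, 3]] + 1L
  }
  structure(list(counts = counts, origin = origin, spacing = spacing,
                 dims = dims, n_samples = nrow(pts)),
            class = "density_grid")
}

#' Connected above-threshold components of a density grid
#'
#' Flood fill (6-connectivity) over voxels with counts strictly above the
#' threshold; used to identify disjoint occupancy sites at a common
#' iso-level.
#'
#' @param grid A `density_grid`.
#' @param threshold iso-threshold on voxel counts.
#' @return Integer label array of the grid's dimensions (0 = below
#'   threshold) with attribute `n_components`.
#' @export
density_components <- function(grid, threshold) {
  stopifnot(inherits(grid, "density_grid"))
  above <- grid$counts > threshold
  labels <- array(0L, dim = dim(above))
  comp <- 0L
  dims <- dim(above)
  nbr <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  todo <- which(above, arr.ind = TRUE)
  for (s in seq_len(nrow(todo))) {
    start <- todo[s, ]
    if (labels[start[1], start[2], start[3]] != 0L) next
    comp <- comp + 1L
    stack <- list(start)
    while (length(stack) > 0) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (labels[v[1], v[2], v[3]] != 0L) next
      labels[v[1], v[2], v[3]] <- comp
      for (k in 1:6) {
        w <- v + nbr[k, ]
        if (all(w >= 1) && all(w <= dims) &&
            above[w[1], w[2], w[3]] && labels[w[1], w[2], w[3]] == 0L) {
          stack[[length(stack) + 1L]] <- w
        }
      }
    }
  }
  attr(labels, "n_components") <- comp
  labels
}

#' Linearised approach path of a GS- before a binding event
#'
#' Extracts the GS- sulfur positions over the `window` frames up to and
#' including the event frame and smooths them with a centred moving average
#' into a polyline (the "arrow" representation of a binding pathway).
#'
#' @param traj A [gs_trajectory()].
#' @param event one-row data frame (or list) with `replicate`, `frame`,
#'   `gs_index`.
#' @param window number of frames ending at the event frame, default 25.
#' @param smooth_width centred moving-average width (odd), default 5.
#' @return Matrix of smoothed positions (rows = frames, cols = x, y, z) with
#'   attribute `truncated` if fewer than `window` frames were available.
#' @export
linearize_path <- function(traj, event, window = 25, smooth_width = 5) {
  stopifnot(inherits(traj, "gs_trajectory"), window >= 1)
  frames_wanted <- seq(event$frame - window + 1L, event$frame)
  sub <- traj$gs[traj$gs$replicate == event$replicate &
                   traj$gs$gs_index == event$gs_index &
                   traj$gs$frame %in% frames_wanted, , drop = FALSE]
  sub <- sub[order(sub$frame), ]
  truncated <- nrow(sub) < window
  pts <- as.matrix(sub[, c("x", "y", "z")])
  sm <- apply(pts, 2, moving_average, width = smooth_width)
  if (is.null(dim(sm))) sm <- matrix(sm, ncol = 3)
  colnames(sm) <- c("x", "y", "z")
  attr(sm, "truncated") <- truncated
  sm
}

# centred moving average with shrinking window at the edges
moving_average <- function(x, width = 5) {
  n <- length(x)
  h <- floor(width / 2)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}

#' Optimal-superposition RMSD (Kabsch)
#'
#' Root-mean-square deviation between two conformations of the same atoms
#' after centring and optimal rigid rotation (singular value decomposition
#' with reflection correction).
#'
#' @param a,b coordinate matrices (n_atoms x 3).
#' @return RMSD in the coordinate units.
#' @export
kabsch_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(ncol(a) == 3, ncol(b) == 3, nrow(a) == nrow(b))
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  s <- svd(crossprod(bc, ac))
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  diff <- ac - bc %*% rot
  sqrt(sum(diff^2) / nrow(a))
}

#' Extract per-event sulfur poses
#'
#' For each binding event returns the coordinates of the active-site
#' cysteine sulfur, the glutathione-moiety sulfur and the bound GS- sulfur
#' as a 3 x 3 matrix — the minimal atom subset for pose clustering.
#'
#' @param traj A [gs_trajectory()].
#' @param events data frame from [detect_bound()].
#' @return List of 3 x 3 coordinate matrices (rows: cys S, moiety S, GS- S).
#' @export
gs_poses <- function(traj, events) {
  lapply(seq_len(nrow(events)), function(i) {
    e <- events[i, ]
    ds <- traj$disulfide[traj$disulfide$replicate == e$replicate &
                           traj$disulfide$frame == e$frame, ]
    gsr <- traj$gs[traj$gs$replicate == e$replicate &
                     traj$gs$frame == e$frame &
                     traj$gs$gs_index == e$gs_index, ]
    rbind(cys = c(ds$cys_x, ds$cys_y, ds$cys_z),
          moiety = c(ds$moiety_x, ds$moiety_y, ds$moiety_z),
          gs = c(gsr$x, gsr$y, gsr$z))
  })
}

#' Agglomerative clustering of bound poses
#'
#' Pairwise superposition RMSD over the designated atom subset, average-
#' linkage hierarchical clustering cut at a fixed number of clusters, with
#' the representative of each cluster chosen as the member minimising the
#' mean RMSD to its cluster; clusters are ordered by population.
#'
#' @param poses list of coordinate matrices (same atom count each), e.g.
#'   from [gs_poses()].
#' @param k number of clusters, default 2.
#' @return List: `assignment` (cluster id per pose, 1 = most populated),
#'   `sizes`, `representatives` (pose index per cluster), `rmsd` (dist
#'   object), `hclust`.
#' @export
cluster_poses <- function(poses, k = 2) {
  n <- length(poses)
  if (n == 0L) stop("no poses to cluster")
  if (n == 1L) {
    return(list(assignment = 1L, sizes = 1L, representatives = 1L,
                rmsd = stats::as.dist(matrix(0, 1, 1)), hclust = NULL))
  }
  k <- min(k, n)
  dmat <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      dmat[i, j] <- dmat[j, i] <- kabsch_rmsd(poses[[i]], poses[[j]])
    }
  }
  dd <- stats::as.dist(dmat)
  if (max(dmat) < 1e-9) {
    # all poses identical: one cluster regardless of the requested cut
    return(list(assignment = rep(1L, n), sizes = n, representatives = 1L,
                rmsd = dd, hclust = NULL))
  }
  hc <- stats::hclust(dd, method = "average")
  raw <- stats::cutree(hc, k = k)
  # relabel clusters by decreasing population
  ord <- order(tabulate(raw, nbins = k), decreasing = TRUE)
  relabel <- match(raw, ord)
  reps <- vapply(seq_len(k), function(cl) {
    members <- which(relabel == cl)
    if (length(members) == 1L) return(members)
    mean_d <- vapply(members, function(m) {
      mean(dmat[m, setdiff(members, m)])
    }, numeric(1))
    members[which.min(mean_d)]
  }, integer(1))
  list(assignment = relabel, sizes = tabulate(relabel, nbins = k),
       representatives = reps, rmsd = dd, hclust = hc)
}
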