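#' Write / read a rate grid as delimited text
#'
#' Tab-separated with columns
#' `variant, substrate_label, gssr_M, gsh_M, enzyme_M, rate_M_per_s,
#' replicate` and a `#`-prefixed metadata header.
#'
#' @param grid A [rate_grid()].
#' @param path output file.
#' @return `path`, invisibly (writer); a [rate_grid()] (reader).
#' @export
write_rate_grid <- function(grid, path) {
  stopifnot(inherits(grid, "rate_grid"))
  meta <- c(sprintf("# variant: %s", attr(grid, "variant_label")),
            sprintf("# substrate: %s", attr(grid, "substrate_label")),
            sprintf("# seed: %s", attr(grid, "seed") %||% "NA"))
  df <- data.frame(variant = attr(grid, "variant_label"),
                   substrate_label = attr(grid, "substrate_label"),
                   gssr_M = grid$gssr, gsh_M = grid$gsh,
                   enzyme_M = grid$enzyme0, rate_M_per_s = grid$rate,
                   replicate = grid$replicate)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_rate_grid
#' @export
read_rate_grid <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  rate_grid(gssr = df$gssr_M, gsh = df$gsh_M, enzyme0 = df$enzyme_M,
            rate = df$rate_M_per_s, replicate = df$replicate,
            substrate_label = df$substrate_label[1],
            variant_label = df$variant[1])
}

#' Write / read a progress curve as delimited text
#'
#' Two data columns (`time_s`, `a340`) preceded by a `#`-prefixed metadata
#' block carrying the assay conditions.
#'
#' @param curve A `progress_curve` from [simulate_assay()].
#' @param path output file.
#' @return `path`, invisibly (writer); a `progress_curve` (reader).
#' @export
write_progress_curve <- function(curve, path) {
  stopifnot(inherits(curve, "progress_curve"))
  cond <- attr(curve, "meta")
  meta <- sprintf("# %s: %g",
                  c("enzyme0_M", "gssr0_M", "gsh0_M", "nadph0_M",
                    "epsilon_nadph", "path_length_cm", "baseline_s"),
                  c(cond$enzyme0, cond$gssr0, cond$gsh0, cond$nadph0,
                    cond$epsilon_nadph, cond$path_length_cm,
                    cond$baseline_s))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.table(data.frame(time_s = curve$time, a340 = curve$a340),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_progress_curve
#' @export
read_progress_curve <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^# ", "", meta_lines), ": "))
  meta <- stats::setNames(as.numeric(kv[, 2]), kv[, 1])
  df <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                          sep = "\t")
  cond <- assay_conditions(enzyme0 = meta[["enzyme0_M"]],
                           gssr0 = meta[["gssr0_M"]],
                           gsh0 = meta[["gsh0_M"]],
                           nadph0 = meta[["nadph0_M"]],
                           epsilon_nadph = meta[["epsilon_nadph"]],
                           path_length_cm = meta[["path_length_cm"]],
                           baseline_s = meta[["baseline_s"]])
  structure(data.frame(time = df$time_s, a340 = df$a340),
            class = c("progress_curve", "data.frame"), meta = cond)
}

#' Write / read a plate run as long-format delimited text
#'
#' Columns `well, role, construct, dose_M, time_s, i400, i480`.
#'
#' @param run A `plate_run`.
#' @param path output file.
#' @return `path`, invisibly (writer); a `plate_run` (reader).
#' @export
write_plate_run <- function(run, path) {
  utils::write.table(as.data.frame(run), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_plate_run
#' @export
read_plate_run <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  structure(df, class = c("plate_run", "data.frame"))
}

#' Write / read a GS- trajectory as long-format delimited text
#'
#' One row per atom per frame: columns `replicate, frame, molecule_id,
#' atom_role, x, y, z` with `atom_role` one of `gs_sulfur`, `cys_s`,
#' `moiety_s` (`molecule_id` is the GS- index, 0 for the disulfide atoms).
#'
#' @param traj A [gs_trajectory()].
#' @param path output file.
#' @return `path`, invisibly (writer); a [gs_trajectory()] (reader).
#' @export
write_gs_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "gs_trajectory"))
  gs <- data.frame(replicate = traj$gs$replicate, frame = traj$gs$frame,
                   molecule_id = traj$gs$gs_index, atom_role = "gs_sulfur",
                   x = traj$gs$x, y = traj$gs$y, z = traj$gs$z)
  ds <- traj$disulfide
  cys <- data.frame(replicate = ds$replicate, frame = ds$frame,
                    molecule_id = 0L, atom_role = "cys_s",
                    x = ds$cys_x, y = ds$cys_y, z = ds$cys_z)
  moi <- data.frame(replicate = ds$replicate, frame = ds$frame,
                    molecule_id = 0L, atom_role = "moiety_s",
                    x = ds$moiety_x, y = ds$moiety_y, z = ds$moiety_z)
  out <- rbind(gs, cys, moi)
  out <- out[order(out$replicate, out$frame, out$atom_role,
                   out$molecule_id), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frame_interval_ps: %g", traj$frame_interval_ps), con)
  utils::write.table(out, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_gs_trajectory
#' @export
read_gs_trajectory <- function(path) {
  lines <- readLines(path, n = 1)
  interval <- if (grepl("^# frame_interval_ps", lines)) {
    as.numeric(sub(".*: ", "", lines))
  } else 20
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  gs <- df[df$atom_role == "gs_sulfur", ]
  cys <- df[df$atom_role == "cys_s", ]
  moi <- df[df$atom_role == "moiety_s", ]
  key <- paste(cys$replicate, cys$frame)
  moi <- moi[match(key, paste(moi$replicate, moi$frame)), ]
  gs_trajectory(
    gs = data.frame(replicate = gs$replicate, frame = gs$frame,
                    gs_index = gs$molecule_id, x = gs$x, y = gs$y, z = gs$z),
    disulfide = data.frame(replicate = cys$replicate, frame = cys$frame,
                           cys_x = cys$x, cys_y = cys$y, cys_z = cys$z,
                           moiety_x = moi$x, moiety_y = moi$y,
                           moiety_z = moi$z),
    frame_interval_ps = interval)
}

#' Write a density grid as plain-text 3D grid
#'
#' Header lines carry origin, spacing and dimensions; body is one voxel per
#' line (`i j k count`), zero-count voxels omitted.
#'
#' @param grid A `density_grid`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_density_grid <- function(grid, path) {
  stopifnot(inherits(grid, "density_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# origin: %g %g %g", grid$origin[1], grid$origin[2],
                       grid$origin[3]),
               sprintf("# spacing: %g", grid$spacing),
               sprintf("# dims: %d %d %d", grid$dims[1], grid$dims[2],
                       grid$dims[3])), con)
  nz <- which(grid$counts > 0, arr.ind = TRUE)
  body <- data.frame(i = nz[, 1], j = nz[, 2], k = nz[, 3],
                     count = grid$counts[nz])
  utils::write.table(body, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
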