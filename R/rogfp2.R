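#' Degree of roGFP2 oxidation from two-channel intensities
#'
#' Calibrated ratiometric readout: given emission intensities after 400 nm
#' and 480 nm excitation for a sample plus fully reduced (DTT-treated) and
#' fully oxidized (diamide-treated) control wells,
#' \deqn{OxD = \frac{I400_s I480_r - I400_r I480_s}
#'                  {(I400_s I480_r - I400_s I480_o) + (I400_o I480_s - I400_r I480_s)}.}
#' OxD is 0 at the reduced control, 1 at the oxidized control, and exactly
#' linear in the disulfide fraction for convex mixtures of the two control
#' spectra. It is invariant under rescaling all intensities by a common
#' positive factor.
#'
#' @param i400_sample,i480_sample sample intensities (arbitrary units, > 0).
#' @param i400_red,i480_red fully-reduced control intensities.
#' @param i400_ox,i480_ox fully-oxidized control intensities.
#' @return OxD value(s); vectorised over the sample intensities.
#' @export
compute_oxd <- function(i400_sample, i480_sample,
                        i400_red, i480_red, i400_ox, i480_ox) {
  ints <- c(i400_sample, i480_sample, i400_red, i480_red, i400_ox, i480_ox)
  if (any(!is.finite(ints)) || any(ints <= 0)) {
    stop("all intensities must be finite and > 0")
  }
  num <- i400_sample * i480_red - i400_red * i480_sample
  den <- (i400_sample * i480_red - i400_sample * i480_ox) +
    (i400_ox * i480_sample - i400_red * i480_sample)
  scale <- abs(i400_sample * i480_red) + abs(i400_sample * i480_ox) +
    abs(i400_ox * i480_sample) + abs(i400_red * i480_sample)
  if (any(abs(den) <= .Machine$double.eps * 100 * scale)) {
    stop("degenerate controls: reduced and oxidized spectra coincide (zero denominator)")
  }
  num / den
}

#' OxD trace container
#'
#' @param time times (s), strictly increasing.
#' @param oxd degree-of-oxidation values; values outside `[0, 1]` are legal
#'   (noisy calibration) and flagged, not clipped, unless `clip = TRUE`.
#' @param clip clip to `[0, 1]`? Default FALSE.
#' @return An `oxd_trace` data frame with columns `time`, `oxd`,
#'   `out_of_range`.
#' @export
oxd_trace <- function(time, oxd, clip = FALSE) {
  if (is.unsorted(time, strictly = TRUE)) {
    stop("`time` must be strictly increasing")
  }
  out_of_range <- oxd < 0 | oxd > 1
  if (clip) oxd <- pmin(pmax(oxd, 0), 1)
  structure(data.frame(time = time, oxd = oxd, out_of_range = out_of_range),
            class = c("oxd_trace", "data.frame"))
}

#' Subtract the untreated-well baseline from an OxD trace
#'
#' Pointwise difference of a treated trace and the untreated (0 uM oxidant)
#' trace on a common time grid; if the grids differ, the untreated trace is
#' linearly interpolated onto the treated grid. Differences may be negative.
#'
#' @param trace,untreated `oxd_trace` objects.
#' @return Corrected `oxd_trace`.
#' @export
baseline_correct <- function(trace, untreated) {
  stopifnot(inherits(trace, "oxd_trace"), inherits(untreated, "oxd_trace"))
  if (min(trace$time) < min(untreated$time) - 1e-9 ||
      max(trace$time) > max(untreated$time) + 1e-9) {
    stop("untreated trace does not cover the time range of the treated trace")
  }
  ref <- stats::approx(untreated$time, untreated$oxd, xout = trace$time,
                       rule = 1)$y
  structure(data.frame(time = trace$time, oxd = trace$oxd - ref,
                       out_of_range = FALSE),
            class = c("oxd_trace", "data.frame"))
}

#' Integrated response over the first 48 s
#'
#' Trapezoidal integral of an OxD trace over `[0, t_end]` from the oxidant
#' addition time; if the sampling grid does not land exactly on `t_end`, the
#' last partial interval is closed by linear interpolation to `t_end`.
#'
#' @param corrected An `oxd_trace` (typically baseline-corrected), covering
#'   `[0, t_end]`.
#' @param t_end integration horizon (s), default 48.
#' @return Integral in OxD * seconds.
#' @export
auc_48 <- function(corrected, t_end = 48) {
  stopifnot(inherits(corrected, "oxd_trace"))
  tt <- corrected$time
  if (max(tt) < t_end) {
    stop(sprintf("trace covers only [%.3g, %.3g] s; need coverage to %g s",
                 min(tt), max(tt), t_end))
  }
  sel <- tt >= 0 & tt <= t_end
  t_in <- tt[sel]
  y_in <- corrected$oxd[sel]
  if (length(t_in) == 0L || max(t_in) < t_end) {
    y_end <- stats::approx(tt, corrected$oxd, xout = t_end)$y
    t_in <- c(t_in, t_end)
    y_in <- c(y_in, y_end)
  }
  if (t_in[1] > 0 && min(tt) <= 0) {
    y0 <- stats::approx(tt, corrected$oxd, xout = 0)$y
    t_in <- c(0, t_in)
    y_in <- c(y0, y_in)
  }
  sum(diff(t_in) * (utils::head(y_in, -1) + utils::tail(y_in, -1)) / 2)
}

#' Per-well OxD traces from a plate run
#'
#' Applies [compute_oxd()] to every sample well of a plate run, calibrating
#' against the plate's control wells (mean over the reduced controls and
#' over the oxidized controls at each time point).
#'
#' @param run A `plate_run` (see [generate_plate_run()] or [read_plate_run()]):
#'   long-format data frame with columns `well`, `role`, `construct`,
#'   `dose_M`, `time_s`, `i400`, `i480`.
#' @return A data frame of well metadata with a list-column `trace` of
#'   [oxd_trace()] objects.
#' @export
plate_oxd_traces <- function(run) {
  df <- as.data.frame(run)
  need <- c("well", "role", "construct", "dose_M", "time_s", "i400", "i480")
  stopifnot(all(need %in% names(df)))
  red <- df[df$role == "reduced_control", ]
  ox <- df[df$role == "oxidized_control", ]
  if (nrow(red) == 0L || nrow(ox) == 0L) {
    stop("plate run must contain reduced and oxidized control wells")
  }
  red_m <- stats::aggregate(cbind(i400, i480) ~ time_s, data = red, FUN = mean)
  ox_m <- stats::aggregate(cbind(i400, i480) ~ time_s, data = ox, FUN = mean)

  wells <- unique(df[df$role %in% c("sample", "untreated"),
                     c("well", "role", "construct", "dose_M")])
  traces <- lapply(seq_len(nrow(wells)), function(i) {
    w <- df[df$well == wells$well[i], ]
    w <- w[order(w$time_s), ]
    ir <- red_m[match(w$time_s, red_m$time_s), ]
    io <- ox_m[match(w$time_s, ox_m$time_s), ]
    if (anyNA(ir$i400) || anyNA(io$i400)) {
      stop("control wells do not share the sample time grid")
    }
    oxd <- compute_oxd(w$i400, w$i480, ir$i400, ir$i480, io$i400, io$i480)
    oxd_trace(w$time_s, oxd)
  })
  wells$trace <- traces
  wells
}

#' Integrated dose-response from a plate run
#'
#' Full pipeline: per-well OxD via the calibrated ratiometric equation,
#' baseline subtraction of the matching untreated (0 uM) well of the same
#' construct, integration over the first 48 s, and per-dose replicate
#' statistics.
#'
#' @param run A `plate_run` long-format data frame.
#' @param t_end integration horizon (s), default 48.
#' @return A `dose_response` data frame: `construct`, `dose_M`, `auc_mean`,
#'   `auc_sd`, `n`; per-well AUCs attached as attribute `per_well`.
#' @export
dose_response <- function(run, t_end = 48) {
  tr <- plate_oxd_traces(run)
  out <- list()
  per_well <- list()
  for (con in unique(tr$construct)) {
    sub <- tr[tr$construct == con, ]
    unt <- sub[sub$role == "untreated", ]
    if (nrow(unt) == 0L) {
      stop("missing untreated (0 uM) well for construct ", con)
    }
    # average untreated wells onto one reference trace
    ref_mat <- vapply(unt$trace, function(x) x$oxd,
                      numeric(nrow(unt$trace[[1]])))
    ref <- oxd_trace(unt$trace[[1]]$time, rowMeans(as.matrix(ref_mat)))
    smp <- sub[sub$role == "sample", ]
    auc <- vapply(seq_len(nrow(smp)), function(i) {
      auc_48(baseline_correct(smp$trace[[i]], ref), t_end = t_end)
    }, numeric(1))
    pw <- data.frame(construct = con, well = smp$well,
                     dose_M = smp$dose_M, auc = auc)
    per_well[[con]] <- pw
    agg <- stats::aggregate(auc ~ dose_M, data = pw, FUN = function(x) {
      c(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0,
        n = length(x))
    })
    out[[con]] <- data.frame(construct = con, dose_M = agg$dose_M,
                             auc_mean = agg$auc[, "mean"],
                             auc_sd = agg$auc[, "sd"], n = agg$auc[, "n"])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("dose_response", "data.frame"),
            per_well = do.call(rbind, per_well))
}
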