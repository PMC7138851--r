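#' Initial-rate grid container
#'
#' A rate grid holds initial rates measured (or simulated) over a
#' `[GSSR] x [GSH]` concentration grid at known enzyme concentration, the
#' standard design for resolving the two half-reactions of a ping-pong
#' mechanism. The canonical design varies GSH between 50 uM and 1.5 mM at
#' fixed GSSCys concentrations of 25, 50, 100 and 150 uM.
#'
#' @param gssr,gsh substrate concentrations (M), `> 0`.
#' @param enzyme0 enzyme concentration (M) per row.
#' @param rate initial rate (M/s), `>= 0`.
#' @param replicate replicate index (default 1).
#' @param substrate_label `"GSSCys"` or `"HEDS"`.
#' @param variant_label free-text enzyme variant label.
#' @return A `rate_grid` data frame.
#' @export
rate_grid <- function(gssr, gsh, enzyme0, rate, replicate = 1L,
                      substrate_label = "GSSCys", variant_label = "WT") {
  n <- length(rate)
  df <- data.frame(gssr = gssr, gsh = gsh,
                   enzyme0 = rep_len(enzyme0, n), rate = rate,
                   replicate = rep_len(replicate, n))
  if (any(df$gssr <= 0) || any(df$gsh <= 0)) {
    stop("substrate concentrations must be > 0")
  }
  if (any(df$rate < 0)) stop("rates must be >= 0")
  structure(df, class = c("rate_grid", "data.frame"),
            substrate_label = substrate_label,
            variant_label = variant_label)
}

#' Blank (reference-cuvette) correction of a rate grid
#'
#' Subtracts, row-wise on matching `(gssr, gsh)` conditions, the rate of a
#' no-enzyme reference from the raw rate, clipping at zero. Clipped rows are
#' flagged in a `clipped` column.
#'
#' @param raw,reference `rate_grid` objects with matching conditions.
#' @return The corrected `rate_grid` with an added logical `clipped` column.
#' @export
blank_correct <- function(raw, reference) {
  stopifnot(inherits(raw, "rate_grid"), inherits(reference, "rate_grid"))
  key_raw <- paste(signif(raw$gssr, 12), signif(raw$gsh, 12))
  key_ref <- paste(signif(reference$gssr, 12), signif(reference$gsh, 12))
  idx <- match(key_raw, key_ref)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))
    stop("reference grid lacks matching conditions for rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  corrected <- raw$rate - reference$rate[idx]
  out <- raw
  out$clipped <- corrected < 0
  out$rate <- pmax(corrected, 0)
  out
}

#' Apparent Michaelis-Menten fits at fixed co-substrate
#'
#' Fits \eqn{v = e_0 k_{cat}^{app} [S] / (K_m^{app} + [S])} by nonlinear least
#' squares, once per fixed co-substrate level, with multi-start
#' initialisation. For a ping-pong mechanism the apparent constants depend on
#' the fixed co-substrate level; with GSH varied at fixed `[GSSR]`,
#' `kcat_app = 1/(phi0 + phi1/[GSSR])` and `km_app = phi2 * kcat_app`.
#'
#' @param grid A `rate_grid`.
#' @param fixed which substrate is held fixed: `"gssr"` (vary GSH) or
#'   `"gsh"` (vary GSSR).
#' @param n_starts number of jittered restarts around the heuristic start.
#' @return A data frame, one row per fixed level, with columns `fixed_conc`,
#'   `kcat_app`, `km_app`, their standard errors, `rss`, and a `degenerate`
#'   flag set when the data show no saturation curvature.
#' @export
fit_apparent_mm <- function(grid, fixed = c("gssr", "gsh"), n_starts = 5L) {
  stopifnot(inherits(grid, "rate_grid"))
  fixed <- match.arg(fixed)
  varied <- if (fixed == "gssr") "gsh" else "gssr"
  levels_fixed <- sort(unique(grid[[fixed]]))
  res <- lapply(levels_fixed, function(cf) {
    sub <- grid[grid[[fixed]] == cf, , drop = FALSE]
    s <- sub[[varied]]
    if (length(unique(s)) < 4L) {
      stop("need >= 4 varied-substrate levels at each fixed level")
    }
    v_per_e <- sub$rate / sub$enzyme0
    fit_one_mm(s, v_per_e, n_starts = n_starts, fixed_conc = cf)
  })
  out <- do.call(rbind, res)
  attr(out, "fixed_substrate") <- fixed
  out
}

# single-curve MM fit on v/e0 vs [S]; returns one-row data frame
fit_one_mm <- function(s, v_per_e, n_starts = 5L, fixed_conc = NA_real_) {
  vr <- range(v_per_e)
  # no curvature / no signal -> degenerate
  if (diff(vr) <= .Machine$double.eps * 100 * max(abs(vr), 1e-300)) {
    return(data.frame(fixed_conc = fixed_conc, kcat_app = mean(v_per_e),
                      km_app = NA_real_, kcat_se = NA_real_, km_se = NA_real_,
                      rss = 0, degenerate = TRUE))
  }
  vmax0 <- max(v_per_e) * 1.2
  km0 <- s[which.min(abs(v_per_e - vmax0 / 2))]
  starts <- list(c(vmax0, km0))
  set.seed(1203)
  for (i in seq_len(n_starts - 1L)) {
    starts[[i + 1L]] <- c(vmax0 * stats::runif(1, 0.5, 2),
                          km0 * stats::runif(1, 0.2, 5))
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ vmax * s / (km + s),
        data = data.frame(s = s, v = v_per_e),
        start = list(vmax = st[1], km = st[2]),
        lower = c(0, 0), control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("Michaelis-Menten fit failed at all starts")
  cf <- stats::coef(best$fit)
  se <- tryCatch(sqrt(diag(stats::vcov(best$fit))),
                 error = function(e) c(NA_real_, NA_real_))
  # ridge-line identifiability: km far above the sampled range means only
  # the ratio vmax/km is determined
  unident <- cf[["km"]] > 20 * max(s)
  data.frame(fixed_conc = fixed_conc,
             kcat_app = unname(cf[["vmax"]]), km_app = unname(cf[["km"]]),
             kcat_se = unname(se[1]), km_se = unname(se[2]),
             rss = best$rss, degenerate = unident)
}

#' Classical linearisations of Michaelis-Menten data
#'
#' Transforms one substrate-varied rate series and fits an ordinary
#' least-squares line, returning the transformed coordinates alongside the
#' parameter estimates implied by the chosen transform:
#' Lineweaver-Burk (`1/v` vs `1/[S]`), Eadie-Hofstee (`v` vs `v/[S]`) or
#' Hanes (`[S]/v` vs `[S]`).
#'
#' @param s substrate concentrations (M).
#' @param v rates (M/s or normalised), all `> 0` (zero-rate points are
#'   dropped with a warning).
#' @param enzyme0 enzyme concentration used to express `kcat_app`; default 1
#'   returns Vmax on the scale of `v`.
#' @param method one of `"lineweaver_burk"`, `"eadie_hofstee"`, `"hanes"`.
#' @return List with `table` (transformed x, y), `slope`, `intercept`,
#'   `kcat_app`, `km_app`.
#' @export
linearize <- function(s, v, enzyme0 = 1,
                      method = c("lineweaver_burk", "eadie_hofstee", "hanes")) {
  method <- match.arg(method)
  keep <- v > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-rate rows excluded from linearisation")
    s <- s[keep]; v <- v[keep]
  }
  xy <- switch(method,
    lineweaver_burk = list(x = 1 / s, y = 1 / v),
    eadie_hofstee = list(x = v / s, y = v),
    hanes = list(x = s, y = s / v))
  fit <- stats::lm(y ~ x, data = xy)
  b <- unname(stats::coef(fit))
  est <- switch(method,
    # 1/v = (Km/Vmax) (1/S) + 1/Vmax
    lineweaver_burk = c(vmax = 1 / b[1], km = b[2] / b[1]),
    # v = Vmax - Km (v/S)
    eadie_hofstee = c(vmax = b[1], km = -b[2]),
    # S/v = S/Vmax + Km/Vmax
    hanes = c(vmax = 1 / b[2], km = b[1] / b[2]))
  list(table = data.frame(x = xy$x, y = xy$y),
       slope = b[2], intercept = b[1],
       kcat_app = unname(est["vmax"]) / enzyme0,
       km_app = unname(est["km"]))
}

#' Dalziel fit of a ping-pong rate grid
#'
#' Primary route: direct linear least squares of \eqn{e_0/v} on
#' \eqn{(1/[GSSR], 1/[GSH])}, weighted by \eqn{v^2} to undo the variance
#' distortion of the reciprocal transform. The classical two-stage route
#' (primary Lineweaver-Burk fits at each fixed GSSR level, then a secondary
#' plot of the primary intercepts against 1/[GSSR]) is also computed; both
#' agree identically on noiseless data.
#'
#' @param grid A `rate_grid` spanning at least 2 levels of each substrate
#'   (3+ recommended).
#' @param average_replicates average rates over replicates before fitting
#'   (default TRUE).
#' @return An object of class `dalziel_fit`: the fitted
#'   [ping_pong_params()], standard errors, reciprocal coefficients with the
#'   true kcat, the two-stage estimates, and the underlying `lm` fit.
#' @export
fit_dalziel <- function(grid, average_replicates = TRUE) {
  stopifnot(inherits(grid, "rate_grid"))
  df <- as.data.frame(grid)
  df <- df[df$rate > 0, , drop = FALSE]
  if (average_replicates && length(unique(df$replicate)) > 1L) {
    agg <- stats::aggregate(rate ~ gssr + gsh + enzyme0, data = df, FUN = mean)
    df <- agg
  }
  if (length(unique(df$gssr)) < 2L || length(unique(df$gsh)) < 2L) {
    stop("rank-deficient design: need >= 2 distinct levels per substrate")
  }
  y <- df$enzyme0 / df$rate
  x1 <- 1 / df$gssr
  x2 <- 1 / df$gsh
  w <- df$rate^2
  fit <- stats::lm(y ~ x1 + x2, weights = w)
  cf <- unname(stats::coef(fit))
  if (any(cf[2:3] <= 0)) {
    # degenerate axis (e.g. co-substrate-independent rates): report a bound
    cf[2:3][cf[2:3] <= 0] <- .Machine$double.eps
  }
  # vcov warns on exactly noiseless (zero-residual) grids; harmless here
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  params <- ping_pong_params(phi0 = max(cf[1], .Machine$double.eps),
                             phi1 = cf[2], phi2 = cf[3],
                             substrate_label = attr(grid, "substrate_label") %||% "GSSCys")

  # two-stage secondary-plot route
  two_stage <- dalziel_two_stage(df)

  structure(
    list(params = params,
         se = c(phi0 = se[[1]], phi1 = se[[2]], phi2 = se[[3]]),
         reciprocal = reciprocal_coefficients(params),
         two_stage = two_stage,
         lm = fit,
         variant_label = attr(grid, "variant_label") %||% "unknown"),
    class = "dalziel_fit")
}

# secondary-plot route: per fixed GSSR level fit 1/v vs 1/GSH
# (e0/v = [phi0 + phi1/GSSR] + phi2/GSH), then regress the primary
# intercepts on 1/GSSR to split phi0 and phi1.
dalziel_two_stage <- function(df) {
  levels_gssr <- sort(unique(df$gssr))
  prim <- t(vapply(levels_gssr, function(cg) {
    sub <- df[df$gssr == cg, , drop = FALSE]
    fit <- stats::lm(I(enzyme0 / rate) ~ I(1 / gsh), data = sub)
    unname(stats::coef(fit))  # intercept = phi0 + phi1/gssr, slope = phi2
  }, numeric(2)))
  sec <- stats::lm(prim[, 1] ~ I(1 / levels_gssr))
  b <- unname(stats::coef(sec))
  list(phi0 = b[1], phi1 = b[2], phi2 = mean(prim[, 2]),
       primary = data.frame(gssr = levels_gssr,
                            intercept = prim[, 1], slope = prim[, 2]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dalziel_fit <- function(x, ...) {
  cat(sprintf("Dalziel fit [%s, %s]\n", x$variant_label,
              x$params$substrate_label))
  print(x$params)
  invisible(x)
}

#' Fold-change comparison of two Dalziel fits
#'
#' Reports mutant/wild-type ratios of the reciprocal Dalziel coefficients and
#' the true kcat, plus percent-of-wild-type and percent-reduction
#' formulations, as used to summarise half-reaction effects of point mutants.
#'
#' @param wt,mut `dalziel_fit` objects with the same substrate label.
#' @return A data frame with one row per quantity (`phi1_inv`, `phi2_inv`,
#'   `kcat_true`): `wt`, `mut`, `ratio` (mut/wt), `percent_of_wt`,
#'   `percent_reduction`.
#' @export
compare_variants <- function(wt, mut) {
  stopifnot(inherits(wt, "dalziel_fit"), inherits(mut, "dalziel_fit"))
  if (wt$params$substrate_label != mut$params$substrate_label) {
    stop("substrate labels differ: ", wt$params$substrate_label, " vs ",
         mut$params$substrate_label)
  }
  q <- c("phi1_inv", "phi2_inv", "kcat_true")
  wt_v <- unlist(wt$reciprocal[q])
  mut_v <- unlist(mut$reciprocal[q])
  ratio <- mut_v / wt_v
  data.frame(quantity = q, wt = unname(wt_v), mut = unname(mut_v),
             ratio = unname(ratio),
             percent_of_wt = unname(100 * ratio),
             percent_reduction = unname(100 * (1 - ratio)),
             row.names = NULL)
}
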