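#' Macroscopic ping-pong (Dalziel) parameters
#'
#' Constructs the macroscopic description of one Grx variant/substrate pair
#' in the Dalziel form of the ping-pong bi-bi rate law,
#' \deqn{e_0/v = \Phi_0 + \Phi_1/[GSSR] + \Phi_2/[GSH],}
#' where the reciprocal coefficients \eqn{1/\Phi_1} and \eqn{1/\Phi_2} are the
#' apparent second-order rate constants of the oxidative (GSSR) and reductive
#' (GSH) half-reactions and \eqn{1/\Phi_0} is the true turnover number.
#'
#' @param phi0 Dalziel intercept coefficient (s).
#' @param phi1 Dalziel coefficient for the glutathionylated-disulfide
#'   substrate (M s).
#' @param phi2 Dalziel coefficient for GSH (M s).
#' @param substrate_label `"GSSCys"` or `"HEDS"`.
#' @return An object of class `ping_pong_params` with elements `phi0`, `phi1`,
#'   `phi2`, `substrate_label`. Reciprocals and the true kcat are available via
#'   [reciprocal_coefficients()].
#' @examples
#' p <- ping_pong_params(phi0 = 0.02, phi1 = 1 / 2e5, phi2 = 1 / 1e5)
#' reciprocal_coefficients(p)
#' @export
ping_pong_params <- function(phi0, phi1, phi2,
                             substrate_label = c("GSSCys", "HEDS")) {
  substrate_label <- match.arg(substrate_label)
  for (nm in c("phi0", "phi1", "phi2")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val <= 0) {
      stop(sprintf("`%s` must be a single finite positive number", nm))
    }
  }
  structure(
    list(phi0 = phi0, phi1 = phi1, phi2 = phi2,
         substrate_label = substrate_label),
    class = "ping_pong_params"
  )
}

#' @export
print.ping_pong_params <- function(x, ...) {
  r <- reciprocal_coefficients(x)
  cat(sprintf(
    "Ping-pong (Dalziel) parameters [%s]\n  Phi0 = %.4g s   (true kcat = %.4g 1/s)\n  Phi1 = %.4g M s (1/Phi1 = %.4g 1/(M s), oxidative half-reaction)\n  Phi2 = %.4g M s (1/Phi2 = %.4g 1/(M s), reductive half-reaction)\n",
    x$substrate_label, x$phi0, r$kcat_true, x$phi1, r$phi1_inv,
    x$phi2, r$phi2_inv))
  invisible(x)
}

#' Reciprocal Dalziel coefficients and true kcat
#'
#' @param params A [ping_pong_params()] object.
#' @return List with `phi1_inv`, `phi2_inv` (1/(M s)) and `kcat_true` (1/s).
#' @export
reciprocal_coefficients <- function(params) {
  stopifnot(inherits(params, "ping_pong_params"))
  list(phi1_inv = 1 / params$phi1,
       phi2_inv = 1 / params$phi2,
       kcat_true = 1 / params$phi0)
}

#' Microscopic rate constants of the two half-reactions
#'
#' The catalytic cycle is modelled as
#' E + GSSR <-> E.GSSR -> E-SSG (+ RS-),  E-SSG + GSH <-> E-SSG.GSH -> E (+ GSSG)
#' with association/dissociation rates (`k1`, `k_minus1`) and (`k4`, `k_minus4`)
#' and irreversible chemical steps `k2` (oxidative) and `k5` (reductive).
#'
#' @param k1,k4 second-order association rates, 1/(M s).
#' @param k_minus1,k_minus4 complex dissociation rates, 1/s.
#' @param k2,k5 chemical step rates of the oxidative/reductive half-reaction, 1/s.
#' @return An object of class `microscopic_rates`.
#' @export
microscopic_rates <- function(k1, k_minus1, k2, k4, k_minus4, k5) {
  r <- list(k1 = k1, k_minus1 = k_minus1, k2 = k2,
            k4 = k4, k_minus4 = k_minus4, k5 = k5)
  bad <- vapply(r, function(v) {
    !is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0
  }, logical(1))
  # dissociation rates may be zero; association and chemical steps must be > 0
  if (any(bad)) {
    stop("all rate constants must be single finite non-negative numbers")
  }
  for (nm in c("k1", "k2", "k4", "k5")) {
    if (r[[nm]] <= 0) stop(sprintf("`%s` must be > 0", nm))
  }
  structure(r, class = "microscopic_rates")
}

#' Steady-state rate from the Dalziel rate law
#'
#' Evaluates \eqn{v = e_0 / (\Phi_0 + \Phi_1/[GSSR] + \Phi_2/[GSH])}.
#'
#' @param params A [ping_pong_params()] object.
#' @param enzyme0 Total enzyme concentration (M), `>= 0`.
#' @param gssr Glutathionylated-disulfide substrate concentration (M), `> 0`.
#' @param gsh GSH concentration (M), `> 0`.
#' @return Rate in M/s (vectorised over `gssr`/`gsh`).
#' @export
dalziel_rate <- function(params, enzyme0, gssr, gsh) {
  stopifnot(inherits(params, "ping_pong_params"))
  if (any(!is.finite(enzyme0)) || any(enzyme0 < 0)) {
    stop("`enzyme0` must be finite and >= 0")
  }
  if (any(!is.finite(gssr)) || any(gssr <= 0)) {
    stop("`gssr` must be finite and > 0")
  }
  if (any(!is.finite(gsh)) || any(gsh <= 0)) {
    stop("`gsh` must be finite and > 0")
  }
  enzyme0 / (params$phi0 + params$phi1 / gssr + params$phi2 / gsh)
}

#' Dalziel coefficients from microscopic rate constants
#'
#' Maps the six microscopic rate constants of the two-half-reaction scheme onto
#' the three macroscopic Dalziel coefficients:
#' \deqn{\Phi_1 = (k_{-1} + k_2)/(k_1 k_2), \quad
#'       \Phi_2 = (k_{-4} + k_5)/(k_4 k_5), \quad
#'       \Phi_0 = 1/k_2 + 1/k_5.}
#' The half-reaction rate constants are bounded by the association steps:
#' \eqn{1/\Phi_1 \le k_1} and \eqn{1/\Phi_2 \le k_4}, with equality only when
#' the complex never dissociates unproductively.
#'
#' @param k A [microscopic_rates()] object.
#' @param substrate_label passed through to the result.
#' @return A [ping_pong_params()] object.
#' @seealso [steady_state_rate_ode()] for the independent mass-action check.
#' @export
phi_from_microscopic <- function(k, substrate_label = "GSSCys") {
  stopifnot(inherits(k, "microscopic_rates"))
  ping_pong_params(
    phi0 = 1 / k$k2 + 1 / k$k5,
    phi1 = (k$k_minus1 + k$k2) / (k$k1 * k$k2),
    phi2 = (k$k_minus4 + k$k5) / (k$k4 * k$k5),
    substrate_label = substrate_label
  )
}

#' Numerical steady-state velocity of the full mass-action scheme
#'
#' Solves the linear steady state of the four enzyme species (E, E.GSSR,
#' E-SSG, E-SSG.GSH) at clamped substrate concentrations and returns the
#' turnover flux. This is an independent route to the velocity that does not
#' use the Dalziel closed form; it exists to validate
#' [phi_from_microscopic()].
#'
#' @param k A [microscopic_rates()] object.
#' @param enzyme0 Total enzyme (M).
#' @param gssr,gsh clamped substrate concentrations (M).
#' @return Steady-state velocity in M/s.
#' @export
steady_state_rate_ode <- function(k, enzyme0, gssr, gsh) {
  stopifnot(inherits(k, "microscopic_rates"))
  # species order: E, EA (= E.GSSR), F (= E-SSG), FB (= E-SSG.GSH)
  # dE/dt   = -k1*A*E + k_minus1*EA + k5*FB
  # dEA/dt  =  k1*A*E - (k_minus1 + k2)*EA
  # dF/dt   =  k2*EA - k4*B*F + k_minus4*FB
  # dFB/dt  =  k4*B*F - (k_minus4 + k5)*FB
  A <- matrix(c(
    -k$k1 * gssr, k$k_minus1, 0, k$k5,
    k$k1 * gssr, -(k$k_minus1 + k$k2), 0, 0,
    0, k$k2, -k$k4 * gsh, k$k_minus4,
    0, 0, k$k4 * gsh, -(k$k_minus4 + k$k5)
  ), nrow = 4, byrow = TRUE)
  # replace the (redundant) first balance row by the conservation constraint
  A[1, ] <- 1
  b <- c(enzyme0, 0, 0, 0)
  x <- solve(A, b)
  k$k5 * x[4]
}

#' Conditions of the coupled NADPH/glutathione-reductase photometric assay
#'
#' Defaults follow the standard GSSCys assay setup: 0.1 mM NADPH, coupling
#' glutathione reductase at 1 U/mL, 25 degrees C, a 30 s pre-start baseline,
#' and NADPH consumption read at 340 nm (epsilon 6220 1/(M cm), 1 cm path).
#'
#' @param enzyme0 total Grx concentration (M).
#' @param gssr0 initial GSSR (M).
#' @param gsh0 initial GSH (M).
#' @param nadph0 initial NADPH (M).
#' @param gr_activity coupling glutathione-reductase activity (U/mL); only
#'   used by the finite-GR mode of [simulate_assay()].
#' @param temperature_C assay temperature (deg C), metadata only.
#' @param path_length_cm optical path (cm).
#' @param epsilon_nadph NADPH molar absorptivity at 340 nm, 1/(M cm).
#' @param baseline_s pre-start baseline duration (s).
#' @return An object of class `assay_conditions`.
#' @export
assay_conditions <- function(enzyme0, gssr0, gsh0,
                             nadph0 = 1e-4, gr_activity = 1,
                             temperature_C = 25,
                             path_length_cm = 1, epsilon_nadph = 6220,
                             baseline_s = 30) {
  conc <- c(enzyme0 = enzyme0, gssr0 = gssr0, gsh0 = gsh0, nadph0 = nadph0)
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("concentrations must be finite and >= 0")
  }
  if (epsilon_nadph <= 0 || path_length_cm <= 0) {
    stop("`epsilon_nadph` and `path_length_cm` must be > 0")
  }
  structure(
    list(enzyme0 = enzyme0, gssr0 = gssr0, gsh0 = gsh0, nadph0 = nadph0,
         gr_activity = gr_activity, temperature_C = temperature_C,
         path_length_cm = path_length_cm, epsilon_nadph = epsilon_nadph,
         baseline_s = baseline_s),
    class = "assay_conditions"
  )
}

#' Simulate an A340 progress curve of the coupled assay
#'
#' Integrates substrate depletion under the Dalziel rate law. By default the
#' coupling glutathione reductase is treated as instantaneous ("coupled"
#' mode): every GSSG formed by the reductive half-reaction is immediately
#' reduced back to 2 GSH at the cost of one NADPH, so per turnover
#' GSSR falls by 1, GSH rises by 1 (net: -1 consumed + 2 regenerated), and
#' NADPH falls by 1. Glutathione moieties are conserved:
#' `gsh + gssr + 2*gssg` stays constant. A finite-GR mode
#' (Michaelis-Menten in GSSG) is available for robustness checks.
#'
#' @param params [ping_pong_params()].
#' @param cond [assay_conditions()].
#' @param t_end end of the simulated record (s), must exceed the baseline.
#' @param dt output sampling interval (s).
#' @param gr_mode `"instantaneous"` (default) or `"finite"`.
#' @param gr_kcat,gr_km finite-GR parameters: a 1 U/mL activity is converted
#'   to a Vmax of `gr_activity / 6e7` M/s (1 U = 1 umol/min) with `gr_km`
#'   defaulting to 60 uM GSSG.
#' @param rtol,atol integrator tolerances (lsoda).
#' @return An object of class `progress_curve`: data frame `time`, `a340`
#'   plus the species trajectories, with `meta` (the conditions) and
#'   `nadph_exhausted` flag as attributes.
#' @export
simulate_assay <- function(params, cond, t_end, dt = 1,
                           gr_mode = c("instantaneous", "finite"),
                           gr_kcat = NULL, gr_km = 6e-5,
                           rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(params, "ping_pong_params"),
            inherits(cond, "assay_conditions"))
  gr_mode <- match.arg(gr_mode)
  if (t_end <= cond$baseline_s) stop("`t_end` must exceed the baseline")
  if (dt <= 0) stop("`dt` must be > 0")

  gr_vmax <- cond$gr_activity / 6e7  # U/mL -> M/s (1 U = 1 umol/min, per mL)

  deriv <- function(t, y, parms) {
    nadph <- max(y[["nadph"]], 0)
    gssr <- max(y[["gssr"]], 0)
    gsh <- max(y[["gsh"]], 0)
    gssg <- max(y[["gssg"]], 0)
    v <- if (gssr > 0 && gsh > 0 && nadph > 0) {
      dalziel_rate(params, cond$enzyme0, gssr, gsh)
    } else 0
    if (gr_mode == "instantaneous") {
      # GSSG never accumulates: NADPH tracks turnover 1:1, GSH net +1
      list(c(nadph = -v, gssr = -v, gsh = +v, gssg = 0))
    } else {
      v_gr <- if (nadph > 0) gr_vmax * gssg / (gr_km + gssg) else 0
      list(c(nadph = -v_gr, gssr = -v, gsh = -v + 2 * v_gr,
             gssg = v - v_gr))
    }
  }

  times <- seq(0, t_end - cond$baseline_s, by = dt)
  y0 <- c(nadph = cond$nadph0, gssr = cond$gssr0, gsh = cond$gsh0, gssg = 0)
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  sol <- as.data.frame(sol)
  sol$nadph <- pmax(sol$nadph, 0)
  sol$gssr <- pmax(sol$gssr, 0)
  sol$gsh <- pmax(sol$gsh, 0)
  sol$gssg <- pmax(sol$gssg, 0)

  # prepend the flat baseline segment
  n_base <- floor(cond$baseline_s / dt)
  base_times <- if (n_base > 0) seq(-n_base * dt, -dt, by = dt) else numeric(0)
  eps_l <- cond$epsilon_nadph * cond$path_length_cm
  a0 <- eps_l * cond$nadph0
  out <- data.frame(
    time = c(base_times + cond$baseline_s, sol$time + cond$baseline_s),
    a340 = c(rep(a0, length(base_times)), eps_l * sol$nadph),
    nadph = c(rep(cond$nadph0, length(base_times)), sol$nadph),
    gssr = c(rep(cond$gssr0, length(base_times)), sol$gssr),
    gsh = c(rep(cond$gsh0, length(base_times)), sol$gsh),
    gssg = c(rep(0, length(base_times)), sol$gssg)
  )
  structure(out,
            class = c("progress_curve", "data.frame"),
            meta = cond,
            nadph_exhausted = min(sol$nadph) <= atol * 10)
}

#' Initial rate from a progress curve
#'
#' Least-squares slope of A340 over a post-baseline window, converted to a
#' molar rate via Beer-Lambert.
#'
#' @param curve A `progress_curve` from [simulate_assay()] (or constructed
#'   with the same columns and `meta` attribute).
#' @param window length of the fitting window (s) starting at the end of the
#'   baseline; default 30 s.
#' @return Initial rate v0 in M/s (positive for NADPH consumption).
#' @export
initial_rate <- function(curve, window = 30) {
  stopifnot(inherits(curve, "progress_curve"))
  cond <- attr(curve, "meta")
  sel <- curve$time >= cond$baseline_s &
    curve$time <= cond$baseline_s + window
  if (sum(sel) < 3L) stop("window must contain at least 3 samples")
  fit <- stats::lm(a340 ~ time, data = curve[sel, , drop = FALSE])
  slope <- unname(stats::coef(fit)[2])
  -slope / (cond$epsilon_nadph * cond$path_length_cm)
}
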