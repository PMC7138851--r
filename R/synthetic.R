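#' Noise model for synthetic generators
#'
#' @param kind `"none"`, `"multiplicative_gaussian"` or
#'   `"additive_gaussian"`.
#' @param sd noise standard deviation (relative for multiplicative,
#'   absolute for additive).
#' @param seed integer seed recorded in generator outputs.
#' @return A `noise_model` object.
#' @export
noise_model <- function(kind = c("none", "multiplicative_gaussian",
                                 "additive_gaussian"),
                        sd = 0, seed = 1L) {
  kind <- match.arg(kind)
  if (sd < 0) stop("`sd` must be >= 0")
  structure(list(kind = kind, sd = sd, seed = as.integer(seed)),
            class = "noise_model")
}

apply_noise <- function(x, noise) {
  switch(noise$kind,
    none = x,
    multiplicative_gaussian = x * (1 + stats::rnorm(length(x), 0, noise$sd)),
    additive_gaussian = x + stats::rnorm(length(x), 0, noise$sd))
}

# Packaged variant calibration table. Fold-change anchors (ox_factor on
# 1/Phi1, red_factor on 1/Phi2), thiol pKa values, roGFP2 steady-state
# oxidation/responsiveness and relative per-frame binding propensities are
# calibrated from the reported measurements for each ScGrx7/HsGrx5 variant;
# absolute wild-type Phi baselines are placeholders (calibrated = FALSE)
# because only ratios are reported for them. Ranges are packaged as
# midpoints with the range kept in the provenance note.
variant_table <- function() {
  v <- function(label, family, ox, red, pka, oxd, act, md, calibrated, note) {
    data.frame(variant = label, family = family, ox_factor = ox,
               red_factor = red, pka = pka, oxd_steady = oxd,
               activity_factor = act, md_propensity_factor = md,
               calibrated = calibrated, provenance = note,
               stringsAsFactors = FALSE)
  }
  rbind(
    v("WT", "ScGrx7", 1, 1, 4.3, 0.60, 1, 1, TRUE,
      "reference enzyme; thiol pKa 4.3 +/- 0.1; roGFP2 fusion ~60% oxidized at steady state; binding propensity baseline"),
    v("Y110F", "ScGrx7", 1, 1, NA, NA, 1, NA, TRUE,
      "GSSCys-assay efficiencies and reciprocal coefficients almost identical to WT"),
    v("Y110H", "ScGrx7", 0.286, 1, NA, NA, 0.9, NA, TRUE,
      "ca. 3-4x lower 1/Phi1 (midpoint 3.5x); 1/Phi2 almost unchanged"),
    v("Y110A", "ScGrx7", 0.205, 0.12, 4.3, NA, 0.2, NA, TRUE,
      "1/Phi1 decreased to 18-23% (midpoint 20.5%), 1/Phi2 to 9-15% (midpoint 12%); pKa not significantly changed"),
    v("K105A", "ScGrx7", 1, 1, 4.3, NA, 1, NA, TRUE,
      "pKa not significantly changed from 4.3"),
    v("K105E", "ScGrx7", 1, 0.5, 5.0, NA, 0.5, 0.34, TRUE,
      "pKa raised to 5.0 +/- 0.1; bound-state fraction ~34% of WT; reductive deceleration factor is a placeholder"),
    v("K105R", "ScGrx7", 1, 1.5, NA, NA, 1.2, 2.0, TRUE,
      "bound-state fraction ~2-fold WT; reductive acceleration factor is a placeholder"),
    v("D144A", "ScGrx7", 0.815, 1, NA, NA, 1, NA, TRUE,
      "1/Phi1 decreased by 17-20% (midpoint 18.5%); 1/Phi2 unaffected"),
    v("D144K", "ScGrx7", 0.815, 1.7, NA, NA, 1.2, NA, TRUE,
      "1/Phi1 decreased by 17-20% (midpoint 18.5%); 1/Phi2 increased 1.7-fold"),
    v("E147A", "ScGrx7", 1, 1, NA, NA, 1, NA, TRUE,
      "no effect on 1/Phi1 or 1/Phi2"),
    v("E147K", "ScGrx7", 1, 2.5, NA, NA, 1.2, 2.2, TRUE,
      "1/Phi2 increased 2.5-fold; bound-state fraction increased 2.2-fold"),
    v("R153A", "ScGrx7", 0.40, 1, NA, NA, 0.6, NA, TRUE,
      "1/Phi1 reduced by 60%; only minor effect on 1/Phi2"),
    v("R153E", "ScGrx7", 0.40, 0.7, NA, NA, 0.5, NA, FALSE,
      "oxidative reduction as R153A; reductive half-reaction also affected (unquantified placeholder)"),
    v("E170A", "ScGrx7", 1, 1, 4.3, NA, 0.8, NA, TRUE,
      "pKa negative control, unchanged from 4.3"),
    v("C108S", "ScGrx7", 1, 1, NA, 0.75, 0, NA, TRUE,
      "redox-inactive active-site mutant; fusion 70-80% oxidized (midpoint 75%) and unresponsive to H2O2"),
    v("roGFP2_only", "ScGrx7", 1, 1, NA, 0.75, 0, NA, TRUE,
      "unfused probe control; 70-80% oxidized (midpoint 75%), unresponsive"),
    v("ScGrx7_WP", "ScGrx7", 0.05, 1, NA, NA, 0.3, NA, FALSE,
      "WP-motif swap predominantly lowers 1/Phi1 (rate-limiting oxidative half-reaction); magnitude placeholder"),
    v("ScGrx7_loop", "ScGrx7", 0.005, 0.005, NA, NA, 0.05, NA, TRUE,
      "elongated active-site loop lowers both reciprocal coefficients by > 2 orders of magnitude"),
    v("ScGrx7_WP_loop", "ScGrx7", 0.001, 0.005, NA, NA, 0.02, NA, FALSE,
      "combined swap, lower activity than the loop swap alone; magnitudes placeholders"),
    v("HsGrx5_WT", "HsGrx5", NA, NA, NA, NA, 0, 1, TRUE,
      "enzymatically inactive class II scaffold (activities <= 1e2 1/(M s)); binding propensity baseline of its family"),
    v("HsGrx5_loop", "HsGrx5", NA, NA, NA, NA, 0.1, 0.8, TRUE,
      "loop shortening activates: 1/Phi1 ~ 2e3, 1/Phi2 ~ 5e3 1/(M s)"),
    v("HsGrx5_RR", "HsGrx5", NA, NA, NA, NA, 0, 0.7, FALSE,
      "activity too low to quantify (<= 1e2 1/(M s)); bound fraction below WT (not significant), placeholder"),
    v("HsGrx5_RR_loop", "HsGrx5", NA, NA, NA, NA, 0, 0.6, FALSE,
      "activity too low to quantify; bound fraction below WT (not significant), placeholder")
  )
}

# absolute kinetic baselines; the ScGrx7 wild-type values are placeholders
# of realistic magnitude (only fold changes are anchored), the HsGrx5_loop
# values are the reported absolute reciprocal coefficients.
kinetic_baseline <- function(variant, family) {
  if (identical(variant, "HsGrx5_loop")) {
    list(phi1_inv = 2e3, phi2_inv = 5e3, phi0 = 1, placeholder_phi0 = TRUE,
         placeholder_phi12 = FALSE)
  } else {
    list(phi1_inv = 2e5, phi2_inv = 1e5, phi0 = 0.02,
         placeholder_phi0 = TRUE, placeholder_phi12 = TRUE)
  }
}

#' Load a packaged variant parameter set
#'
#' Returns the calibrated parameter set of a packaged Grx variant:
#' ping-pong kinetics (wild-type baseline times oxidative/reductive fold
#' factors; the HsGrx5 loop variant carries its reported absolute
#' reciprocal coefficients), thiol pKa, roGFP2 steady-state oxidation and
#' responsiveness, and the relative per-frame binding propensity for the
#' trajectory generator. Quantities without a printed absolute anchor are
#' placeholders and flagged via `placeholder_fields`.
#'
#' @param label variant label, e.g. `"WT"`, `"K105E"`, `"E147K"`, `"D144K"`,
#'   `"R153A"`, `"HsGrx5_loop"`; see `variant_table()` for the full list.
#' @return A `variant_parameter_set`: list with `variant`, `family`,
#'   `kinetic` ([ping_pong_params()]), `factors`, `pka`, `rogfp2`, `md`,
#'   `provenance`, `placeholder_fields`.
#' @examples
#' load_variant("E147K")$factors["red"]
#' @export
load_variant <- function(label) {
  tab <- variant_table()
  row <- tab[tab$variant == label, ]
  if (nrow(row) != 1L) {
    stop("unknown variant '", label, "'; available: ",
         paste(tab$variant, collapse = ", "))
  }
  base <- kinetic_baseline(label, row$family)
  ox <- if (is.na(row$ox_factor)) 1 else row$ox_factor
  red <- if (is.na(row$red_factor)) 1 else row$red_factor
  kin <- ping_pong_params(phi0 = base$phi0,
                          phi1 = 1 / (base$phi1_inv * ox),
                          phi2 = 1 / (base$phi2_inv * red))
  placeholders <- c(
    if (base$placeholder_phi0) "phi0",
    if (base$placeholder_phi12) "phi1_phi2_baseline",
    if (!row$calibrated) "variant_factors")
  structure(
    list(variant = row$variant, family = row$family, kinetic = kin,
         factors = c(ox = ox, red = red),
         pka = row$pka,
         rogfp2 = list(oxd_steady = row$oxd_steady,
                       activity_factor = row$activity_factor),
         md = list(propensity_factor = row$md_propensity_factor),
         provenance = row$provenance,
         placeholder_fields = placeholders),
    class = "variant_parameter_set")
}

#' List packaged variant labels
#' @return Character vector of known labels.
#' @export
available_variants <- function() variant_table()$variant

#' Generate an initial-rate grid for a variant
#'
#' Evaluates the Dalziel rate law on the canonical assay design (GSH varied
#' over 50 uM - 1.5 mM, 8 levels, at fixed GSSCys 25/50/100/150 uM) and
#' applies the requested noise model.
#'
#' @param set A `variant_parameter_set` from [load_variant()].
#' @param noise A [noise_model()].
#' @param gsh_levels GSH concentrations (M).
#' @param gssr_levels fixed GSSCys concentrations (M).
#' @param enzyme0 enzyme concentration (M), default 10 nM.
#' @param replicates number of replicate grids.
#' @return A [rate_grid()] with `seed` and `provenance` attributes.
#' @export
generate_rate_grid <- function(set, noise = noise_model("none"),
                               gsh_levels = seq(50e-6, 1.5e-3,
                                                length.out = 8),
                               gssr_levels = c(25, 50, 100, 150) * 1e-6,
                               enzyme0 = 10e-9, replicates = 1L) {
  stopifnot(inherits(set, "variant_parameter_set"),
            inherits(noise, "noise_model"))
  design <- expand.grid(gsh = gsh_levels, gssr = gssr_levels,
                        replicate = seq_len(replicates))
  v <- dalziel_rate(set$kinetic, enzyme0, design$gssr, design$gsh)
  set.seed(noise$seed)
  v <- pmax(apply_noise(v, noise), 0)
  g <- rate_grid(gssr = design$gssr, gsh = design$gsh, enzyme0 = enzyme0,
                 rate = v, replicate = design$replicate,
                 substrate_label = set$kinetic$substrate_label,
                 variant_label = set$variant)
  attr(g, "seed") <- noise$seed
  attr(g, "provenance") <- set$provenance
  g
}

#' Generate an alkylation-protection profile for a variant
#'
#' Hill mode (default) emits the sigmoid that the assay is fitted with,
#' midpoint at the variant's packaged thiol pKa; mechanistic mode emits
#' pseudo-first-order alkylation survival (see
#' [simulate_residual_activity()]).
#'
#' @param set A `variant_parameter_set` with a non-missing `pka`.
#' @param noise A [noise_model()]; additive noise is in % residual activity.
#' @param mode,protocol,... passed to [simulate_residual_activity()].
#' @param replicates number of replicate profiles.
#' @return A `residual_activity_profile` with `seed` attribute.
#' @export
generate_pka_profile <- function(set, noise = noise_model("none"),
                                 mode = "hill",
                                 protocol = alkylation_protocol(),
                                 replicates = 1L, ...) {
  stopifnot(inherits(set, "variant_parameter_set"))
  if (is.na(set$pka)) {
    stop("variant '", set$variant, "' carries no packaged pKa")
  }
  set.seed(noise$seed)
  profs <- lapply(seq_len(replicates), function(r) {
    p <- simulate_residual_activity(set$pka, mode = mode,
                                    protocol = protocol,
                                    variant_label = set$variant,
                                    replicate = r, ...)
    p$residual_pct <- pmax(apply_noise(p$residual_pct, noise), 0)
    p
  })
  out <- do.call(rbind, profs)
  attr(out, "seed") <- noise$seed
  class(out) <- c("residual_activity_profile", "data.frame")
  out
}

# packaged two-channel excitation spectra of the probe endpoints
# (arbitrary units): the 400 nm band rises and the 480 nm band falls
# on oxidation.
rogfp2_spectra <- function() {
  list(red = c(i400 = 0.25, i480 = 1.00),
       ox = c(i400 = 1.00, i480 = 0.25))
}

# phenomenological in-cell response: a dose-dependent oxidant pulse drives
# dOxD/dt = k_probe * drive(dose, t) * (1 - OxD), drive = amp*dose*exp(-t/tau),
# which integrates in closed form.
rogfp2_oxd_response <- function(t, dose, oxd0, activity_factor,
                                k_probe = 60, tau = 30) {
  drive_int <- dose * tau * (1 - exp(-pmax(t, 0) / tau))
  1 - (1 - oxd0) * exp(-k_probe * activity_factor * drive_int)
}

#' Generate a two-channel plate run for one construct
#'
#' Emits a long-format plate run: per-dose sample wells (replicated),
#' untreated (0 uM) wells, and fully-reduced (100 mM DTT) / fully-oxidized
#' (20 mM diamide) control wells. The degree of oxidation follows a
#' phenomenological dose-driven response on top of the construct's
#' steady-state oxidation; channel intensities are convex mixtures of the
#' packaged endpoint spectra, so the analysis pipeline recovers the
#' prescribed OxD exactly in the noiseless case.
#'
#' @param set A `variant_parameter_set` with `rogfp2` parameters.
#' @param doses H2O2 doses (M) within `[0, 1e-3]`; 0 doses are emitted as
#'   untreated wells.
#' @param noise A [noise_model()] applied to the channel intensities.
#' @param times sampling times (s) relative to oxidant addition; default
#'   12 s cycles from 0 to 96 s.
#' @param replicates wells per dose.
#' @param gain overall instrument gain multiplying both channels.
#' @param oxd_start optional initial OxD override (DTT-pretreatment/washout
#'   runs start from a pre-reduced probe).
#' @return A `plate_run` data frame: `well`, `role`, `construct`, `dose_M`,
#'   `time_s`, `i400`, `i480`, with `seed` attribute.
#' @export
generate_plate_run <- function(set, doses = c(0, 20, 50, 100, 200, 500,
                                              1000) * 1e-6,
                               noise = noise_model("none"),
                               times = seq(0, 96, by = 12),
                               replicates = 3L, gain = 1000,
                               oxd_start = NULL) {
  stopifnot(inherits(set, "variant_parameter_set"))
  if (any(doses < 0 | doses > 1e-3)) stop("doses must lie in [0, 1e-3] M")
  if (is.na(set$rogfp2$oxd_steady)) {
    stop("variant '", set$variant, "' carries no packaged roGFP2 parameters")
  }
  oxd0 <- if (is.null(oxd_start)) set$rogfp2$oxd_steady else oxd_start
  sp <- rogfp2_spectra()
  mix <- function(f) {
    list(i400 = gain * (f * sp$ox[["i400"]] + (1 - f) * sp$red[["i400"]]),
         i480 = gain * (f * sp$ox[["i480"]] + (1 - f) * sp$red[["i480"]]))
  }
  rows <- list()
  well_id <- 0L
  add_well <- function(role, dose, oxd_t) {
    well_id <<- well_id + 1L
    ints <- mix(oxd_t)
    rows[[length(rows) + 1L]] <<- data.frame(
      well = sprintf("W%03d", well_id), role = role,
      construct = set$variant, dose_M = dose, time_s = times,
      i400 = ints$i400, i480 = ints$i480)
  }
  for (r in seq_len(2L)) {
    add_well("reduced_control", NA_real_, rep(0, length(times)))
    add_well("oxidized_control", NA_real_, rep(1, length(times)))
  }
  for (dose in doses) {
    role <- if (dose == 0) "untreated" else "sample"
    for (r in seq_len(replicates)) {
      oxd_t <- rogfp2_oxd_response(times, dose, oxd0,
                                   set$rogfp2$activity_factor)
      add_well(role, dose, oxd_t)
    }
  }
  if (!any(doses == 0)) {
    for (r in seq_len(replicates)) {
      add_well("untreated", 0, rogfp2_oxd_response(times, 0, oxd0,
                                                   set$rogfp2$activity_factor))
    }
  }
  out <- do.call(rbind, rows)
  set.seed(noise$seed)
  out$i400 <- pmax(apply_noise(out$i400, noise), 1e-9)
  out$i480 <- pmax(apply_noise(out$i480, noise), 1e-9)
  structure(out, class = c("plate_run", "data.frame"), seed = noise$seed)
}

#' Generate a synthetic GS- diffusion trajectory
#'
#' Emulates the saved-frame statistics of unbiased ligand-diffusion
#' simulations: `n_gs` GS- sulfurs in a cubic box around a fixed disulfide
#' sulfur pair, with a short-range attraction tuned so that the probability
#' that a saved frame contains at least one bound GS- equals
#' `p_baseline * md propensity factor` of the variant. Successive saved
#' frames are resampled independently (the save interval is treated as
#' longer than the positional correlation time), which makes the bound-frame
#' count exactly binomial.
#'
#' @param set A `variant_parameter_set` with a non-missing propensity factor.
#' @param n_replicates number of replications (default 4).
#' @param n_frames saved frames per replication (default 5000; the full
#'   emulated scale is 25000 = 500 ns at 20 ps saves).
#' @param n_gs number of GS- molecules (default 10).
#' @param seed integer seed.
#' @param p_baseline wild-type per-frame bound-frame probability
#'   (default 0.2).
#' @param box_half half edge length of the cubic box (angstrom).
#' @param cutoff binding cutoff used for the placement shell (angstrom).
#' @return A [gs_trajectory()] with `seed` and `p_frame` attributes.
#' @export
generate_gs_trajectory <- function(set, n_replicates = 4L, n_frames = 5000L,
                                   n_gs = 10L, seed = 1L, p_baseline = 0.2,
                                   box_half = 20, cutoff = 5.5) {
  stopifnot(inherits(set, "variant_parameter_set"), n_replicates >= 1L)
  fac <- set$md$propensity_factor
  if (is.na(fac)) {
    stop("variant '", set$variant, "' carries no packaged binding propensity")
  }
  p_frame <- p_baseline * fac
  if (p_frame >= 1) stop("per-frame bound probability must be < 1")
  # per-molecule probability such that P(>=1 of n_gs bound) = p_frame
  q <- 1 - (1 - p_frame)^(1 / n_gs)
  set.seed(seed)
  # disulfide fixed along x, midpoint at the origin (2 A bond)
  cys <- c(-1, 0, 0); moi <- c(1, 0, 0)
  r_min <- 2  # excluded core radius around the midpoint
  total <- n_replicates * n_frames * n_gs
  bound <- stats::runif(total) < q
  n_b <- sum(bound)
  # bound: uniform within the spherical shell [r_min, cutoff]
  r_b <- (stats::runif(n_b) * (cutoff^3 - r_min^3) + r_min^3)^(1 / 3)
  # unbound: uniform in the box, outside the cutoff sphere (rejection)
  n_u <- total - n_b
  unb <- matrix(numeric(0), ncol = 3)
  while (nrow(unb) < n_u) {
    cand <- matrix(stats::runif(3 * (n_u - nrow(unb) + 1000L),
                                -box_half, box_half), ncol = 3)
    unb <- rbind(unb, cand[rowSums(cand^2) > cutoff^2, , drop = FALSE])
  }
  unb <- unb[seq_len(n_u), , drop = FALSE]
  # random directions for the bound shell placements
  dir <- matrix(stats::rnorm(3 * n_b), ncol = 3)
  dir <- dir / sqrt(rowSums(dir^2))
  xyz <- matrix(NA_real_, nrow = total, ncol = 3)
  xyz[bound, ] <- dir * r_b
  xyz[!bound, ] <- unb

  idx <- expand.grid(gs_index = seq_len(n_gs), frame = seq_len(n_frames),
                     replicate = seq_len(n_replicates))
  gs <- data.frame(replicate = idx$replicate, frame = idx$frame,
                   gs_index = idx$gs_index,
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  frames <- expand.grid(frame = seq_len(n_frames),
                        replicate = seq_len(n_replicates))
  disulfide <- data.frame(replicate = frames$replicate, frame = frames$frame,
                          cys_x = cys[1], cys_y = cys[2], cys_z = cys[3],
                          moiety_x = moi[1], moiety_y = moi[2],
                          moiety_z = moi[3])
  traj <- gs_trajectory(gs, disulfide, frame_interval_ps = 20)
  attr(traj, "seed") <- seed
  attr(traj, "p_frame") <- p_frame
  traj
}
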