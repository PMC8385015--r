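# Schedule-dependent spheroid growth simulator. This is an explicitly
# synthetic pharmacodynamic stand-in for wet-lab readouts: an Emax kill term
# for the TOP1 inhibitor plus a damage-gated potentiation term for the ATM
# inhibitor. The damage state D integrates SN38-induced double-strand breaks
# and resolves at first order; ATMi kill is proportional to the damage still
# present while ATMi is on board, which is what makes the model sensitive to
# the gap between the two agents.
#
#   dV/dt = kg*V - V * [ Emax_S * C_S/(EC50_S + C_S)
#                        + alpha * D * Emax_A * C_A/(EC50_A + C_A) ]
#   dD/dt = kin * C_S - kout * D,   D(0) = 0, V(0) = V0

#' Construct pharmacodynamic parameters
#'
#' @param kg net spheroid growth rate, 1/day.
#' @param EmaxS maximal SN38 kill rate, 1/day.
#' @param EC50S SN38 half-maximal concentration, nM.
#' @param EmaxA maximal ATMi-potentiated kill rate per unit damage, 1/day.
#' @param EC50A ATMi half-maximal concentration, nM.
#' @param alpha potentiation coupling (unitless); 0 decouples the
#'   combination entirely.
#' @param kin damage production rate per nM SN38, 1/(nM day).
#' @param kout damage resolution rate, 1/day.
#' @param sigma multiplicative log-normal measurement noise SD (applied only
#'   by [observeVolumes()]).
#' @param V0 initial spheroid volume (any consistent unit; default 1).
#' @return list of class-checked parameters.
#' @seealso [defaultPDParams()] for the calibrated defaults.
#' @export
pdParams <- function(kg, EmaxS, EC50S, EmaxA, EC50A, alpha, kin, kout,
                     sigma = 0, V0 = 1) {
  p <- list(kg = kg, EmaxS = EmaxS, EC50S = EC50S, EmaxA = EmaxA,
            EC50A = EC50A, alpha = alpha, kin = kin, kout = kout,
            sigma = sigma, V0 = V0)
  rates <- c(kg = kg, EmaxS = EmaxS, EmaxA = EmaxA, alpha = alpha,
             kin = kin, kout = kout)
  if (any(rates < 0)) stop("all rates must be >= 0")
  if (!isTRUE(EC50S > 0) || !isTRUE(EC50A > 0)) stop("EC50s must be > 0")
  if (sigma < 0) stop("sigma must be >= 0")
  if (!isTRUE(V0 > 0)) stop("V0 must be > 0")
  p
}

#' Calibrated default PD parameters
#'
#' Reads the versioned default parameter file shipped with the package
#' (`inst/extdata/pd_defaults.yaml`), produced by the coarse grid-search
#' calibration script (`scripts/calibrate_pd.R`). The defaults reproduce the
#' observed day-7 ranking of the treatment schedules (control > mono >
#' 72-h gap > 24-h gap > 1-day combo > 7-day combo).
#'
#' @param sigma measurement noise SD override (default 0: noise-free).
#' @return parameter list as from [pdParams()].
#' @export
defaultPDParams <- function(sigma = 0) {
  y <- yaml::read_yaml(system.file("extdata", "pd_defaults.yaml",
                                   package = "chipPKPD"))
  pdParams(kg = y$kg, EmaxS = y$EmaxS, EC50S = y$EC50S, EmaxA = y$EmaxA,
           EC50A = y$EC50A, alpha = y$alpha, kin = y$kin, kout = y$kout,
           sigma = sigma, V0 = y$V0)
}

#' Simulate spheroid growth under a treatment timeline
#'
#' Fixed-step 4th-order Runge-Kutta integration (default step 0.01 day) of
#' the damage-gated growth-inhibition model. The drug forcing is the
#' piecewise-constant treatment timeline; the volume is floored at
#' `1e-12 * V0` to avoid underflow. Output is noise-free and bitwise
#' reproducible; apply observation noise with [observeVolumes()].
#'
#' @param pd parameters from [pdParams()].
#' @param timeline a [TreatmentTimeline-class] covering `[0, horizon]`
#'   (times beyond the timeline are drug-free).
#' @param horizon simulation horizon, days.
#' @param dt integrator step, days (default 0.01).
#' @param drug,partner analyte labels for the TOP1 inhibitor and the ATMi in
#'   the timeline; analytes absent from the timeline contribute zero
#'   concentration.
#' @return a [GrowthTrajectory-class] sampled at multiples of `dt`.
#' @examples
#' ctrl <- simulateGrowth(defaultPDParams(),
#'                        staticTimeline(c(SN38 = 0), 7), horizon = 7)
#' @export
simulateGrowth <- function(pd, timeline, horizon = 7, dt = 0.01,
                           drug = "SN38", partner = "AZD0156") {
  stopifnot(is(timeline, "TreatmentTimeline"))
  if (any(timeline@conc < 0)) stop("negative concentrations rejected")
  n <- ceiling(horizon / dt)
  times <- seq(0, by = dt, length.out = n + 1)
  cs_fun <- if (drug %in% timeline@analytes)
    function(t_h) timelineConcentration(timeline, drug, t_h) else function(t_h) 0
  ca_fun <- if (partner %in% timeline@analytes)
    function(t_h) timelineConcentration(timeline, partner, t_h) else function(t_h) 0

  # work in log-volume for stability; state = (logV, D)
  deriv <- function(t_day, state) {
    cs <- cs_fun(t_day * 24); ca <- ca_fun(t_day * 24)
    kill <- pd$EmaxS * cs / (pd$EC50S + cs) +
      pd$alpha * state[2] * pd$EmaxA * ca / (pd$EC50A + ca)
    c(pd$kg - kill, pd$kin * cs - pd$kout * state[2])
  }
  out_logV <- numeric(n + 1); out_D <- numeric(n + 1)
  state <- c(log(pd$V0), 0)
  out_logV[1] <- state[1]; out_D[1] <- 0
  floor_logV <- log(pd$V0) + log(1e-12)
  for (i in seq_len(n)) {
    t0 <- times[i]
    k1 <- deriv(t0, state)
    k2 <- deriv(t0 + dt / 2, state + dt / 2 * k1)
    k3 <- deriv(t0 + dt / 2, state + dt / 2 * k2)
    k4 <- deriv(t0 + dt, state + dt * k3)
    state <- state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    state[1] <- max(state[1], floor_logV)
    out_logV[i + 1] <- state[1]; out_D[i + 1] <- state[2]
  }
  vol <- exp(out_logV)
  # viability proxy: volume relative to drug-free growth at the same kg
  viability <- vol / (pd$V0 * exp(pd$kg * times))
  new("GrowthTrajectory", times = times, volumes = vol, damage = out_D,
      viability = viability)
}

#' Apply multiplicative observation noise to simulated volumes
#'
#' Seeded log-normal measurement noise, kept separate from the deterministic
#' model integration.
#'
#' @param trajectory a [GrowthTrajectory-class].
#' @param sigma log-scale noise SD.
#' @param seed integer seed.
#' @return a [GrowthTrajectory-class] with noisy volumes.
#' @export
observeVolumes <- function(trajectory, sigma, seed) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(trajectory)
  set.seed(as.integer(seed))
  noisy <- trajectory@volumes *
    exp(rnorm(length(trajectory@volumes), 0, sigma))
  new("GrowthTrajectory", times = trajectory@times, volumes = noisy,
      damage = trajectory@damage, viability = trajectory@viability)
}

# volume at a given day (trajectory sampled on a fixed grid)
.volume_at <- function(trajectory, day) {
  approx(trajectory@times, trajectory@volumes, xout = day, rule = 2)$y
}

#' Percent growth inhibition
#'
#' `%GI = 100 * (1 - (V_T(t) - V_T(0)) / (V_C(t) - V_C(0)))`: the treated
#' volume change relative to the control volume change from treatment start.
#' 0% means no effect, 100% complete stasis, and values above 100% indicate
#' regression below baseline. Undefined (rejected) when the control fails to
#' grow.
#'
#' @param treated,control [GrowthTrajectory-class] objects, or numeric
#'   `c(V0, Vt)` volume pairs.
#' @param t evaluation day (ignored for volume pairs).
#' @return percent growth inhibition.
#' @examples
#' percentGrowthInhibition(c(1, 1), c(1, 3))  # 100
#' @export
percentGrowthInhibition <- function(treated, control, t = 7) {
  pair <- function(x) {
    if (is(x, "GrowthTrajectory")) c(x@volumes[1], .volume_at(x, t))
    else if (is.numeric(x) && length(x) == 2) x
    else stop("supply a GrowthTrajectory or a c(V0, Vt) pair")
  }
  tr <- pair(treated); ct <- pair(control)
  dC <- ct[2] - ct[1]
  if (dC <= 0) stop("control volume change <= 0: %GI undefined")
  100 * (1 - (tr[2] - tr[1]) / dC)
}

#' Treated volumes as percent of the control mean
#'
#' @param treated numeric vector of treated volumes (or a
#'   [GrowthTrajectory-class], evaluated at `t`).
#' @param control numeric vector of control volumes (or a trajectory).
#' @param t evaluation day for trajectory inputs.
#' @return numeric vector, percent of control mean.
#' @export
relativeVolume <- function(treated, control, t = 7) {
  tv <- if (is(treated, "GrowthTrajectory")) .volume_at(treated, t) else treated
  cv <- if (is(control, "GrowthTrajectory")) .volume_at(control, t) else control
  if (!length(tv) || !length(cv)) stop("empty inputs")
  m <- mean(cv)
  if (!isTRUE(m > 0)) stop("control mean must be > 0")
  100 * tv / m
}

#' Simulate all standard regimens at once
#'
#' Convenience wrapper: composes the timeline for each regimen token,
#' simulates growth at the supplied parameters, and returns day-`t` relative
#' volumes and %GI versus the untreated control.
#'
#' @param pd parameters from [pdParams()].
#' @param schedules named list of per-drug [ExposureSchedule-class].
#' @param tokens regimen tokens (default: all five).
#' @param t evaluation day.
#' @param horizon simulation horizon, days.
#' @param dt integrator step, days.
#' @return data.frame with columns `token`, `relative_volume_pct`,
#'   `percent_gi`.
#' @export
simulateRegimenPanel <- function(pd, schedules,
                                 tokens = c("mono", "combo_1_7", "combo_7_7",
                                            "combo_gap24", "combo_gap72"),
                                 t = 7, horizon = 7, dt = 0.01) {
  control <- simulateGrowth(pd, staticTimeline(c(SN38 = 0), horizon),
                            horizon = horizon, dt = dt)
  rows <- lapply(tokens, function(tok) {
    tl <- composeTreatmentTimeline(regimenFromToken(tok), schedules)
    tr <- simulateGrowth(pd, tl, horizon = horizon, dt = dt)
    data.frame(token = tok,
               relative_volume_pct = relativeVolume(tr, control, t = t),
               percent_gi = percentGrowthInhibition(tr, control, t = t),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
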