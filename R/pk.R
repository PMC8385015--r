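#' Construct PK parameters
#'
#' @param ka absorption rate constant (1/h); ignored for the bolus model.
#' @param ke elimination rate constant (1/h).
#' @param V apparent volume of distribution (units such that `doseAmount/V`
#'   is nM).
#' @param F bioavailable fraction (0, 1].
#' @param fu free fraction (0, 1].
#' @param doseAmount administered amount.
#' @param modelKind `"one_compartment_first_order_absorption"` (default) or
#'   `"one_compartment_bolus"`.
#' @return a [PKParams-class] object.
#' @examples
#' p <- pkParams(ka = 1, ke = 0.1, V = 1, doseAmount = 100)
#' @export
pkParams <- function(ka, ke, V = 1, F = 1, fu = 1, doseAmount = 1,
                     modelKind = "one_compartment_first_order_absorption") {
  if (modelKind == "one_compartment_bolus" && missing(ka)) ka <- ke * 5
  new("PKParams", modelKind = modelKind, ka = as.numeric(ka),
      ke = as.numeric(ke), V = as.numeric(V), F = as.numeric(F),
      fu = as.numeric(fu), doseAmount = as.numeric(doseAmount))
}

#' Construct a table of dose events
#'
#' @param time dose times in hours (non-negative).
#' @param amount dose amounts (same units as `PKParams@doseAmount`); recycled.
#' @param route route labels (`"oral"` or `"intraperitoneal"`); recycled.
#' @return data.frame with columns `time`, `amount`, `route`, sorted by time.
#' @export
doseEvents <- function(time, amount = 1, route = "oral") {
  if (any(time < 0)) stop("dose times must be non-negative")
  route <- match.arg(route, c("oral", "intraperitoneal"), several.ok = TRUE)
  d <- data.frame(time = as.numeric(time), amount = as.numeric(amount),
                  route = route, stringsAsFactors = FALSE)
  d[order(d$time), , drop = FALSE]
}

#' Construct a concentration series
#'
#' @param times sampling times (h), strictly increasing.
#' @param concentrations free concentrations (nM), non-negative.
#' @param analyte analyte label.
#' @param provenance `"observed"` or `"simulated"`.
#' @return a [ConcentrationSeries-class].
#' @export
concentrationSeries <- function(times, concentrations, analyte = "drug",
                                provenance = "observed") {
  new("ConcentrationSeries", analyte = analyte, times = as.numeric(times),
      concentrations = as.numeric(concentrations), provenance = provenance)
}

# Single-dose closed-form free concentration at times t (vectorised).
# Absorption model: C(t) = fu*F*dose*ka / (V*(ka-ke)) * (exp(-ke*tau) - exp(-ka*tau)),
# tau = t - t0, zero before the dose. Bolus: fu*F*dose/V * exp(-ke*tau).
.single_dose_conc <- function(params, t, t0, amount) {
  tau <- t - t0
  out <- numeric(length(t))
  pos <- tau >= 0
  A <- params@fu * params@F * amount / params@V
  if (params@modelKind == "one_compartment_first_order_absorption") {
    ka <- params@ka; ke <- params@ke
    out[pos] <- A * ka / (ka - ke) * (exp(-ke * tau[pos]) - exp(-ka * tau[pos]))
  } else {
    out[pos] <- A * exp(-params@ke * tau[pos])
  }
  # guard against tiny negative values from cancellation
  pmax(out, 0)
}

#' Simulate a free plasma concentration profile
#'
#' Closed-form simulation of a one-compartment model under one or more dose
#' events; multiple doses combine by superposition (linear PK).
#'
#' @param params a [PKParams-class].
#' @param doses data.frame from [doseEvents()].
#' @param timeGrid strictly increasing times (h) covering all dose times.
#' @return a [ConcentrationSeries-class] with provenance `"simulated"`.
#' @examples
#' p <- pkParams(ka = 1, ke = 0.1, V = 1, doseAmount = 100)
#' s <- simulateProfile(p, doseEvents(0, 100), timeGrid = 0:24)
#' @export
simulateProfile <- function(params, doses, timeGrid) {
  stopifnot(is(params, "PKParams"))
  validObject(params)
  if (length(timeGrid) == 0) stop("timeGrid must be non-empty")
  if (any(diff(timeGrid) <= 0)) stop("timeGrid must be strictly increasing")
  if (params@modelKind == "one_compartment_first_order_absorption" &&
      isTRUE(all.equal(params@ka, params@ke)))
    stop("ka == ke is degenerate for the closed form")
  if (max(doses$time) > max(timeGrid))
    stop("timeGrid must cover all dose times")
  conc <- numeric(length(timeGrid))
  for (i in seq_len(nrow(doses)))
    conc <- conc + .single_dose_conc(params, timeGrid, doses$time[i],
                                     doses$amount[i])
  concentrationSeries(timeGrid, conc, analyte = "simulated",
                      provenance = "simulated")
}

# Curve-stripping initial values: terminal ke from log-linear regression on
# the last 4 positive points, ka = 5*ke, amplitude from the observed peak.
.strip_init <- function(t, c) {
  tail_idx <- tail(order(t), 4L)
  sl <- coef(lm(log(c[tail_idx]) ~ t[tail_idx]))[2]
  ke0 <- max(1e-3, -as.numeric(sl))
  ka0 <- 5 * ke0
  tmax0 <- log(ka0 / ke0) / (ka0 - ke0)
  peak_unit <- ka0 / (ka0 - ke0) * (exp(-ke0 * tmax0) - exp(-ka0 * tmax0))
  A0 <- max(c) / peak_unit
  c(lke = log(ke0), ldiff = log(ka0 - ke0), lA = log(A0))
}

#' Fit one-compartment PK parameters to an observed series
#'
#' Least squares on log concentration (positive observations only;
#' zero-concentration samples are excluded, not imputed), via
#' Levenberg-Marquardt ([minpack.lm::nls.lm]). The model is parameterised as
#' `ke = exp(lke)`, `ka = ke + exp(ldiff)` (so `ka > ke` holds by
#' construction, resolving flip-flop) and amplitude `A = fu*F*dose/V`. Rates
#' are floored at 1e-4/h. Only `A`, `ka` and `ke` are identifiable from a
#' concentration curve; the returned `PKParams` adopts the convention
#' `F = fu = 1`, `V = doseAmount / A`.
#'
#' @param series a [ConcentrationSeries-class] with at least 4 positive
#'   observations.
#' @param modelKind model structure; only
#'   `"one_compartment_first_order_absorption"` is currently fitted.
#' @param dose single-row data.frame from [doseEvents()] giving the dose time
#'   and amount.
#' @param init optional [PKParams-class] with starting values; defaults to
#'   curve-stripping starting values.
#' @return list with elements `params` ([PKParams-class]), `residualNorm`
#'   (sum of squared log residuals), `converged` (logical) and `nIterations`.
#'   A stalled optimiser yields `converged = FALSE` rather than an error.
#' @examples
#' p <- pkParams(ka = 1.2, ke = 0.12, V = 1, doseAmount = 200)
#' obs <- simulateProfile(p, doseEvents(0, 200), 1:24)
#' fit <- fitPKParams(obs, dose = doseEvents(0, 200))
#' @export
fitPKParams <- function(series,
                        modelKind = "one_compartment_first_order_absorption",
                        dose = doseEvents(0, 1), init = NULL) {
  stopifnot(is(series, "ConcentrationSeries"))
  modelKind <- match.arg(modelKind, .pk_model_kinds)
  keep <- series@concentrations > 0
  if (sum(keep) < 4)
    stop("need at least 4 positive observations to fit (under-determined)")
  t <- series@times[keep] - dose$time[1]
  cc <- series@concentrations[keep]
  use <- t >= 0
  t <- t[use]; cc <- cc[use]
  if (length(t) < 4) stop("need at least 4 positive post-dose observations")

  start <- if (is.null(init)) .strip_init(t, cc) else
    c(lke = log(init@ke), ldiff = log(max(init@ka - init@ke, 1e-6)),
      lA = log(init@fu * init@F * init@doseAmount / init@V))

  resid_fun <- function(p) {
    ke <- max(exp(p[["lke"]]), 1e-4)
    ka <- ke + max(exp(p[["ldiff"]]), 1e-8)
    A <- exp(p[["lA"]])
    pred <- A * ka / (ka - ke) * (exp(-ke * t) - exp(-ka * t))
    log(pmax(pred, 1e-300)) - log(cc)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fun,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(params = NULL, residualNorm = Inf, converged = FALSE,
                nIterations = 0L))
  }
  ke <- max(exp(fit$par[["lke"]]), 1e-4)
  ka <- ke + max(exp(fit$par[["ldiff"]]), 1e-8)
  A <- exp(fit$par[["lA"]])
  params <- pkParams(ka = ka, ke = ke, V = dose$amount[1] / A, F = 1, fu = 1,
                     doseAmount = dose$amount[1], modelKind = modelKind)
  list(params = params,
       residualNorm = sum(resid_fun(fit$par)^2),
       converged = fit$info %in% 1:4,
       nIterations = as.integer(fit$niter))
}

#' Serialize / read fitted PK parameters as key-value config
#'
#' @param params a [PKParams-class].
#' @param path output (input) file path.
#' @return `readPKParams` returns a [PKParams-class]; `writePKParams` the
#'   path, invisibly.
#' @export
writePKParams <- function(params, path) {
  stopifnot(is(params, "PKParams"))
  yaml::write_yaml(list(
    model_kind = params@modelKind, ka = params@ka, ke = params@ke,
    V = params@V, F = params@F, fu = params@fu,
    dose_amount = params@doseAmount), path)
  invisible(path)
}

#' @rdname writePKParams
#' @export
readPKParams <- function(path) {
  y <- yaml::read_yaml(path)
  pkParams(ka = y$ka, ke = y$ke, V = y$V, F = y$F, fu = y$fu,
           doseAmount = y$dose_amount, modelKind = y$model_kind)
}
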