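# Two-step dilution planning: DMSO stock -> intermediate aliquots ->
# per-reservoir working concentrations.

#' Construct a stock solution
#'
#' @param analyte analyte label.
#' @param conc stock concentration (numeric, > 0).
#' @param unit unit of `conc`: `"nM"`, `"uM"` or `"mM"` (stored as nM).
#' @param solvent solvent label (default `"DMSO"`).
#' @return list with `analyte`, `conc_nM`, `solvent`.
#' @examples
#' stockSolution("AZD0156", 1, "mM")
#' @export
stockSolution <- function(analyte, conc, unit = c("nM", "uM", "mM"),
                          solvent = "DMSO") {
  unit <- match.arg(unit)
  if (!isTRUE(conc > 0)) stop("stock concentration must be > 0")
  mult <- c(nM = 1, uM = 1e3, mM = 1e6)[[unit]]
  list(analyte = analyte, conc_nM = conc * mult, solvent = solvent)
}

#' Plan a two-step dilution from stock to reservoir concentrations
#'
#' Step 1 dispenses DMSO stock into `aliquotVolume`-sized intermediate
#' aliquots at the intermediate concentration; step 2 pipettes intermediate
#' into each flow reservoir. The intermediate concentration defaults to
#' `max(reservoirConcs) * secondStepFactor`; alternatively
#' `firstStepFactor` fixes it as `stock / firstStepFactor` (the convention
#' when the intermediate is defined by diluting the stock a round factor).
#' Mass (volume x concentration) is conserved at every transfer.
#'
#' @param stock a [stockSolution()].
#' @param reservoirConcs per-reservoir final concentrations, nM.
#' @param reservoirVolumes per-reservoir total volumes, mL (recycled).
#' @param secondStepFactor dilution factor between the intermediate and the
#'   highest reservoir concentration (default 100).
#' @param firstStepFactor optional: derive the intermediate as
#'   `stock / firstStepFactor` instead.
#' @param aliquotVolume step-1 aliquot volume, uL (default 200).
#' @param dmsoCap maximum DMSO volume fraction per reservoir (default 0.001,
#'   i.e. 0.1% v/v).
#' @param minPipette minimum pipettable volume, uL (default 0.5); smaller
#'   required transfers are rejected with advice to add a serial step.
#' @return a [DilutionPlan-class].
#' @examples
#' stk <- stockSolution("AZD0156", 1, "mM")
#' plan <- planTwoStepDilution(stk, reservoirConcs = c(192, 150, 110),
#'                             reservoirVolumes = 6.2)
#' plan@intermediateConc  # 19200 nM = 19.2 uM
#' @export
planTwoStepDilution <- function(stock, reservoirConcs, reservoirVolumes,
                                secondStepFactor = 100,
                                firstStepFactor = NULL,
                                aliquotVolume = 200, dmsoCap = 0.001,
                                minPipette = 0.5) {
  if (any(reservoirConcs < 0)) stop("reservoir concentrations must be >= 0")
  if (any(reservoirVolumes <= 0)) stop("reservoir volumes must be > 0")
  nres <- length(reservoirConcs)
  reservoirVolumes <- rep_len(reservoirVolumes, nres)

  inter <- if (is.null(firstStepFactor)) {
    max(reservoirConcs) * secondStepFactor
  } else {
    stock$conc_nM / firstStepFactor
  }
  if (inter > stock$conc_nM + 1e-9)
    stop(sprintf("required intermediate (%g nM) exceeds stock (%g nM)",
                 inter, stock$conc_nM))
  if (inter < max(reservoirConcs))
    stop("intermediate concentration below the top reservoir concentration")

  # step 2: intermediate -> reservoirs
  res_vol_uL <- reservoirVolumes * 1000
  transfer2 <- res_vol_uL * reservoirConcs / inter
  bad <- which(reservoirConcs > 0 & transfer2 < minPipette)
  if (length(bad))
    stop(sprintf(paste0("reservoir %d needs a %0.3g uL transfer, below the ",
                        "%g uL pipetting minimum; add a serial dilution step"),
                 bad[1], transfer2[bad[1]], minPipette))
  # DMSO entering a reservoir is the stock volume carried by its intermediate
  # aliquot share: stock_uL_in_reservoir = transfer2 * inter / stock_conc.
  dmso_frac <- (transfer2 * inter / stock$conc_nM) / res_vol_uL
  over <- which(dmso_frac > dmsoCap + 1e-12)
  if (length(over))
    stop(sprintf("DMSO fraction %.4f%% in reservoir %d exceeds the %.4f%% cap",
                 100 * dmso_frac[over[1]], over[1], 100 * dmsoCap))

  # step 1: stock -> aliquots of aliquotVolume at `inter`
  need_uL <- sum(transfer2)
  n_aliquot <- max(1L, ceiling(need_uL / aliquotVolume))
  stock_per_aliquot <- aliquotVolume * inter / stock$conc_nM
  if (stock_per_aliquot < minPipette && inter > 0)
    stop(sprintf(paste0("step-1 stock transfer %0.3g uL is below the %g uL ",
                        "pipetting minimum; add a serial dilution step"),
                 stock_per_aliquot, minPipette))
  aliquots <- data.frame(
    aliquot = seq_len(n_aliquot), volume_uL = aliquotVolume,
    stock_uL = stock_per_aliquot,
    diluent_uL = aliquotVolume - stock_per_aliquot)

  worklist <- rbind(
    data.frame(analyte = stock$analyte, step = 1L, source = "stock",
               target = sprintf("intermediate_%d", seq_len(n_aliquot)),
               transfer_uL = stock_per_aliquot, final_conc_nM = inter,
               stringsAsFactors = FALSE),
    data.frame(analyte = stock$analyte, step = 2L, source = "intermediate",
               target = sprintf("reservoir_%d", seq_len(nres)),
               transfer_uL = transfer2, final_conc_nM = reservoirConcs,
               stringsAsFactors = FALSE))
  reservoirs <- data.frame(
    reservoir = seq_len(nres), final_conc_nM = reservoirConcs,
    volume_mL = reservoirVolumes, intermediate_uL = transfer2,
    dmso_fraction = dmso_frac)
  new("DilutionPlan", analyte = stock$analyte, stockConc = stock$conc_nM,
      intermediateConc = inter, aliquots = aliquots, worklist = worklist,
      reservoirs = reservoirs, dmsoCap = dmsoCap)
}

#' Required reservoir volume for a schedule step
#'
#' Volume pumped during the step (`flowRate x duration`) plus the spare
#' volume the reservoir must hold.
#'
#' @param durationH step duration, hours (> 0).
#' @param flowRate flow rate, uL/min (> 0).
#' @param spareML spare volume, mL (default 5).
#' @return required volume, mL.
#' @examples
#' reservoirVolumeRequirement(1, 20)    # 6.2
#' reservoirVolumeRequirement(0.5, 20)  # 5.6
#' @export
reservoirVolumeRequirement <- function(durationH, flowRate = 20, spareML = 5) {
  if (any(durationH <= 0)) stop("duration must be > 0")
  if (!isTRUE(flowRate > 0)) stop("flowRate must be > 0")
  flowRate * durationH * 60 / 1000 + spareML
}

#' Re-simulate a dilution plan forward
#'
#' Recomputes each reservoir's final concentration from the plan's transfer
#' volumes, as a conservation check.
#'
#' @param plan a [DilutionPlan-class].
#' @return numeric vector of reconstructed final concentrations, nM.
#' @export
simulatePlanForward <- function(plan) {
  step1 <- plan@aliquots
  inter <- step1$stock_uL[1] * plan@stockConc / step1$volume_uL[1]
  res <- plan@reservoirs
  res$intermediate_uL * inter / (res$volume_mL * 1000)
}

#' Write a dilution worklist as delimited text
#'
#' @param plan a [DilutionPlan-class] (or list of plans).
#' @param path output path.
#' @return the combined worklist data.frame, invisibly.
#' @export
writeWorklist <- function(plan, path) {
  plans <- if (is(plan, "DilutionPlan")) list(plan) else plan
  wl <- do.call(rbind, lapply(plans, function(p) p@worklist))
  write.csv(wl, path, row.names = FALSE, quote = FALSE)
  invisible(wl)
}
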