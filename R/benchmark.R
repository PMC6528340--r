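#' @include stats.R search.R
NULL

#' Run repeated searches over a set of molecules
#'
#' Executes every stochastic method for several trials per molecule (the
#' systematic baseline once, being deterministic) and collects one record
#' per (molecule, method, trial): the lowest energy found, its difference to
#' the baseline's best, and RMSD/TFD distances to the overall lowest-energy
#' conformer of that molecule.
#'
#' @param mols list of [TorsionMolecule-class] objects (rigid ones are
#'   skipped with a message).
#' @param methods character vector of method labels as in
#'   [searchMolecule()].
#' @param trials number of repeated trials per stochastic method.
#' @param config base [searchConfig()]; each trial t of molecule m runs with
#'   seed `seed + 1000*m + t` for reproducibility.
#' @param baseline method label used as the reference for `deltaE`.
#' @return data.frame of benchmark records.
#' @export
runBenchmark <- function(mols, methods = c("boa-ei", "boa-lcb", "uniform",
                                           "systematic"),
                         trials = 5, config = searchConfig(seed = 1),
                         baseline = "systematic") {
  rootSeed <- config$seed %||% 1
  records <- list()
  for (m in seq_along(mols)) {
    mol <- mols[[m]]
    if (nRotors(mol) == 0) {
      message("skipping rigid molecule '", mol@name, "'")
      next
    }
    results <- list()
    for (method in methods) {
      nTrials <- if (method == "systematic") 1 else trials
      for (t in seq_len(nTrials)) {
        cfg <- config
        cfg$seed <- rootSeed + 1000L * m + t
        res <- searchMolecule(mol, method, cfg)
        results[[length(results) + 1]] <- list(method = method, trial = t,
                                               res = res)
      }
    }
    bests <- vapply(results, function(r) bestEnergy(r$res), numeric(1))
    lecIdx <- which.min(bests)
    lec <- bestConformer(results[[lecIdx]]$res)
    baseBest <- min(bests[vapply(results, function(r)
      r$method == baseline, logical(1))])
    for (r in results) {
      bc <- bestConformer(r$res)
      records[[length(records) + 1]] <- data.frame(
        molecule = mol@name, nRotors = nRotors(mol), method = r$method,
        trial = r$trial, bestEnergy = bestEnergy(r$res),
        deltaE = deltaE(bestEnergy(r$res), baseBest),
        rmsd = if (!is.null(bc) && !is.null(lec))
          conformerRMSD(bc, lec) else NA_real_,
        tfd = if (!is.null(bc) && !is.null(lec))
          tryCatch(conformerTFD(bc, lec), error = function(e) NA_real_)
        else NA_real_,
        earlyStop = r$res@termination == "early_stop")
    }
  }
  do.call(rbind, records)
}

#' Summarize benchmark records
#'
#' Aggregates records by rotatable-bond group and method: median and IQR of
#' the energy difference to the baseline, the champion rate (percentage of
#' molecules where the method beat the baseline, averaged over trials), the
#' lowest-energy-conformer recovery rate (how often the method found the
#' overall best energy across all methods, within `tol`), and the median
#' per-molecule maximum variation among per-trial best energies. Molecules
#' with three or fewer rotatable bonds are pooled into one group (sparse
#' rotor classes), mirroring common benchmark practice.
#'
#' @param records data.frame as from [runBenchmark()] (columns `molecule`,
#'   `nRotors`, `method`, `trial`, `bestEnergy`, `deltaE`).
#' @param baseline method label excluded from champion-rate comparison.
#' @param tol energy tolerance (kcal/mol) for counting an LEC hit.
#' @return data.frame with one row per (rotor group, method).
#' @export
summarizeBenchmark <- function(records, baseline = "systematic", tol = 1e-6) {
  stopifnot(all(c("molecule", "nRotors", "method", "trial", "bestEnergy",
                  "deltaE") %in% names(records)))
  records$rotorGroup <- ifelse(records$nRotors <= 3, "1-3",
                               as.character(records$nRotors))
  lecByMol <- tapply(records$bestEnergy, records$molecule, min)
  baseByMol <- tapply(records$bestEnergy[records$method == baseline],
                      records$molecule[records$method == baseline], min)
  out <- list()
  for (grp in sort(unique(records$rotorGroup))) {
    rg <- records[records$rotorGroup == grp, ]
    for (method in unique(rg$method)) {
      rm_ <- rg[rg$method == method, ]
      mols <- unique(rm_$molecule)
      # champion rate: per trial, % of molecules beating the baseline
      champ <- NA_real_
      if (method != baseline && length(mols) > 0) {
        perTrial <- vapply(sort(unique(rm_$trial)), function(t) {
          rt <- rm_[rm_$trial == t, ]
          100 * mean(rt$bestEnergy < baseByMol[rt$molecule] - tol)
        }, numeric(1))
        champ <- mean(perTrial)
      }
      # LEC recovery: % of molecules where some trial hit the overall best
      lecRate <- 100 * mean(vapply(mols, function(mo) {
        any(rm_$bestEnergy[rm_$molecule == mo] <= lecByMol[mo] + tol)
      }, logical(1)))
      # max variation among per-trial bests, per molecule
      maxVar <- vapply(mols, function(mo) {
        e <- rm_$bestEnergy[rm_$molecule == mo]
        if (length(e) > 1) max(e) - min(e) else 0
      }, numeric(1))
      out[[length(out) + 1]] <- data.frame(
        rotorGroup = grp, method = method, nMolecules = length(mols),
        medianDeltaE = stats::median(rm_$deltaE),
        iqrDeltaE = stats::IQR(rm_$deltaE),
        championRate = champ, lecRecovery = lecRate,
        medianMaxVariation = stats::median(maxVar))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
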