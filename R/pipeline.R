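## Umbrella pipeline: runs the requested analysis stages from a single
## configuration list, writes per-stage TSV/JSON outputs plus a run
## manifest (configuration, seeds, constants, package version) so that
## deterministic stages are byte-reproducible.

writeJsonReport <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages against input files and writes one
#' output set per stage into \code{outDir}:
#' \describe{
#'   \item{relax}{fits R1 and R1rho decays, offset-corrects to R2, forms
#'     NOEs, estimates the tumbling time and classifies dynamics;
#'     requires \code{config$relax} with paths \code{r1}, \code{r1rho},
#'     \code{noe} and parameters \code{fieldH1}, \code{spinlock}
#'     (optional \code{offsets}, a named vector). Writes
#'     \code{relax_rates.tsv} and \code{relax_tauc.json}.}
#'   \item{rdc}{extracts N-H vectors from \code{config$rdc$pdb}, fits the
#'     alignment tensor to \code{config$rdc$rdc} and writes
#'     \code{rdc_fit.json} plus \code{rdc_table.tsv} with back-calculated
#'     couplings.}
#'   \item{itc}{reads \code{config$itc$heats} (optional \code{blank}),
#'     subtracts dilution, fits the one-site model and writes
#'     \code{itc_fit.json}.}
#'   \item{ensemble}{reads \code{config$ensemble$pdb}, computes
#'     coordinate precision over \code{config$ensemble$select} and a
#'     per-residue RMSD profile; writes \code{ensemble_precision.json}
#'     and \code{ensemble_rmsd.tsv}.}
#' }
#' A \code{manifest.json} capturing the configuration, seeds, physical
#' constants and package version is always written.  Any stage failure
#' aborts with a stage-tagged message.
#'
#' @param config nested configuration list; see Details above.  Top-level
#'   fields: \code{stages} (character vector, default all configured
#'   stages), \code{seed} (integer, default 1).
#' @param outDir output directory, created if needed.
#' @return Named list of per-stage results, invisibly.
#' @export
runPipeline <- function(config, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  configured <- intersect(c("relax", "rdc", "itc", "ensemble"),
                          names(config))
  stages <- if (!is.null(config$stages)) config$stages else configured
  bad <- setdiff(stages, configured)
  if (length(bad))
    stop("stage(s) requested but not configured: ",
         paste(bad, collapse = ", "))
  results <- list()

  runStage <- function(stage, fn) {
    tryCatch(fn(), error = function(e)
      stop("[stage ", stage, "] ", conditionMessage(e), call. = FALSE))
  }

  if ("relax" %in% stages) results$relax <- runStage("relax", function() {
    rc <- config$relax
    for (f in c("r1", "r1rho", "noe"))
      if (is.null(rc[[f]])) stop("missing input path: ", f)
    if (!is.null(rc$offsets) && is.null(rc$spinlock))
      stop("per-residue offsets supplied without a spinlock field ",
           "strength")
    cfg <- SpectrometerConfig(
      fieldH1 = if (is.null(rc$fieldH1)) 800 else rc$fieldH1,
      spinlock = if (is.null(rc$spinlock)) 1500 else rc$spinlock,
      offsets = if (is.null(rc$offsets)) numeric() else rc$offsets)
    r1 <- readIntensityTable(rc$r1)
    r1rho <- readIntensityTable(rc$r1rho)
    noe <- readNoeTable(rc$noe)
    rates <- analyzeRelaxation(r1, r1rho, noe, cfg,
                               nBoot = if (is.null(rc$nBoot)) 200
                                       else rc$nBoot,
                               seed = seed)
    labs <- classifyDynamics(rates,
      noeCut = if (is.null(rc$noeCut)) 0.8 else rc$noeCut,
      k = if (is.null(rc$k)) 1.5 else rc$k)
    rates$label <- as.character(labs$label)
    tc <- estimateTauc(rates, fieldH1 = cfg@fieldH1,
      noeCut = if (is.null(rc$noeCut)) 0.8 else rc$noeCut)
    utils::write.table(rates, file.path(outDir, "relax_rates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeJsonReport(list(tau_c_ns = tc@tauC,
                         n_residues_used = tc@nResiduesUsed,
                         trimmed_ids = tc@trimmedIds,
                         r2_r1_ratio = tc@ratio),
                    file.path(outDir, "relax_tauc.json"))
    list(rates = rates, tauc = tc)
  })

  if ("rdc" %in% stages) results$rdc <- runStage("rdc", function() {
    rc <- config$rdc
    if (is.null(rc$pdb) || is.null(rc$rdc))
      stop("rdc stage needs pdb and rdc paths")
    ens <- readPdbEnsemble(rc$pdb)
    tab <- readRdcTable(rc$rdc)
    bv <- extractVectors(ens,
      model = if (is.null(rc$model)) 1L else rc$model)
    fit <- svdFit(bv, tab, seed = seed)
    tab$d_calc_hz <- attr(fit, "dCalc")[match(tab$residue_id,
                                              attr(fit, "residueId"))]
    writeRdcTable(tab, file.path(outDir, "rdc_table.tsv"))
    writeJsonReport(list(da_hz = Da(fit), rhombicity = rhombicity(fit),
                         da_sd_hz = fit@daSd,
                         rhombicity_sd = fit@rhombicitySd,
                         euler_deg = eulerAngles(fit),
                         r_factor_pct = rdcRfactor(fit),
                         n_couplings = length(attr(fit, "dObs"))),
                    file.path(outDir, "rdc_fit.json"))
    fit
  })

  if ("itc" %in% stages) results$itc <- runStage("itc", function() {
    rc <- config$itc
    if (is.null(rc$heats)) stop("itc stage needs a heats path")
    q <- readHeatsTable(rc$heats)
    sched <- InjectionSchedule(
      nInjections = length(q),
      injectionVolume = if (is.null(rc$injectionVolume)) 2
                        else rc$injectionVolume,
      cellVolume = if (is.null(rc$cellVolume)) 200 else rc$cellVolume,
      cellConc = rc$cellConc, syringeConc = rc$syringeConc,
      temperature = if (is.null(rc$temperature)) 298.15
                    else rc$temperature)
    blank <- if (!is.null(rc$blank)) readHeatsTable(rc$blank)
             else numeric()
    exp <- ItcExperiment(sched, q, blank)
    if (length(blank)) exp <- subtractDilution(exp)
    fit <- fitOneSite(exp, seed = seed)
    writeJsonReport(list(n = fit@n, kd_nM = fit@kd * 1e9,
                         dg_kcal = round(fit@dg, 1),
                         dh_kcal = round(fit@dh, 1),
                         tds_neg_kcal = round(fit@tdsNeg, 1),
                         flags = fit@flags),
                    file.path(outDir, "itc_fit.json"))
    fit
  })

  if ("ensemble" %in% stages)
    results$ensemble <- runStage("ensemble", function() {
      rc <- config$ensemble
      if (is.null(rc$pdb)) stop("ensemble stage needs a pdb path")
      ens <- readPdbEnsemble(rc$pdb)
      sel <- if (!is.null(rc$select)) Selection(rc$select) else NULL
      prec <- ensemblePrecision(ens, sel)
      prof <- perResidueRmsd(ens)
      utils::write.table(prof, file.path(outDir, "ensemble_rmsd.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      writeJsonReport(list(mean_rmsd = prec$meanRmsd,
                           sd_rmsd = prec$sdRmsd,
                           n_models = nModels(ens)),
                      file.path(outDir, "ensemble_precision.json"))
      list(precision = prec[c("meanRmsd", "sdRmsd", "perModel")],
           profile = prof)
    })

  manifest <- list(
    package = "solnmr",
    version = as.character(utils::packageVersion("solnmr")),
    seed = seed,
    stages = stages,
    config = config[setdiff(names(config), "stages")],
    constants = nmrConstants())
  writeJsonReport(manifest, file.path(outDir, "manifest.json"))
  invisible(results)
}
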