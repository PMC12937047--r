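## Pipeline orchestration and I/O: configuration, area-table serialization,
## the simulate -> peaks -> quantify -> report chain, and report export.

.AREA_COLS <- c("sample_id", "design_role", "spike_level", "channel", "area")

#' Build a pipeline run configuration
#'
#' @param matrix A [MatrixSpec-class].
#' @param design An [AssayDesign-class].
#' @param errors An [ErrorModel-class].
#' @param seed Integer seed; every random draw of the run flows from it.
#' @param options Named list overriding defaults: `robustness_activities`,
#'   `robustness_replicates`, `freeze_thaw_cycles`, `freeze_thaw_loss`,
#'   `flank_width` (noise window, minutes), `accuracy_band` /
#'   `lloq_band` / `stability_band` (percent acceptance bands).
#' @return A [RunConfig-class].
#' @export
runConfig <- function(matrix = bvhMatrix(), design = bvhDesign(),
                      errors = ErrorModel(), seed = 1, options = list()) {
  defaults <- list(robustness_activities = c(1000, 2000, 5000),
                   robustness_replicates = 3, freeze_thaw_cycles = 2,
                   freeze_thaw_loss = 0.075, flank_width = 0.3,
                   accuracy_band = 15, lloq_band = 20, stability_band = 20)
  unknown <- setdiff(names(options), names(defaults))
  if (length(unknown))
    stop("unknown config option(s): ", paste(unknown, collapse = ", "))
  defaults[names(options)] <- options
  new("RunConfig", matrix = matrix, design = design, errors = errors,
      seed = as.integer(seed), options = defaults)
}

#' Read a run configuration from YAML
#'
#' Recognized top-level keys: `matrix`, `design`, `errors`, `seed`,
#' `options`; unknown keys (at top level or inside a section) are rejected.
#' Each section's fields map onto the arguments of [MatrixSpec()],
#' [AssayDesign()] and [ErrorModel()].
#'
#' @param path YAML file.
#' @return A [RunConfig-class].
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("matrix", "design", "errors", "seed", "options")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  build <- function(section, fn, rename = c()) {
    args <- cfg[[section]]
    if (is.null(args)) return(fn())
    names(args) <- ifelse(names(args) %in% names(rename),
                          rename[names(args)], names(args))
    bad <- setdiff(names(args), names(formals(fn)))
    if (length(bad))
      stop("unknown ", section, " field(s): ", paste(bad, collapse = ", "))
    do.call(fn, args)
  }
  design <- cfg$design
  if (!is.null(design$dilutionChain))
    cfg$design$dilutionChain <- lapply(design$dilutionChain, unlist)
  if (!is.null(cfg$errors$retentionTimes))
    cfg$errors$retentionTimes <- unlist(cfg$errors$retentionTimes)
  runConfig(matrix = build("matrix", MatrixSpec),
            design = build("design", AssayDesign),
            errors = build("errors", ErrorModel),
            seed = if (is.null(cfg$seed)) 1L else cfg$seed,
            options = if (is.null(cfg$options)) list() else cfg$options)
}

#' Read and validate an area table from CSV
#'
#' @param path CSV file with at least columns `sample_id`, `design_role`,
#'   `spike_level`, `channel`, `area`.
#' @return Validated area table `data.frame`.
#' @export
readAreaTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) stop("schema error reading '", path,
                                           "': ", conditionMessage(e)))
  missing <- setdiff(.AREA_COLS, names(tab))
  if (length(missing))
    stop("schema error: missing column(s) ", paste(missing, collapse = ", "))
  bad <- which(!is.finite(tab$area) | tab$area < 0)
  if (length(bad))
    stop("malformed area value(s) at data line(s) ",
         paste(bad + 1L, collapse = ", "))
  for (id in unique(tab$sample_id)) {
    ch <- tab$channel[tab$sample_id == id]
    lack <- setdiff(c("analyte", "IS1", "IS2"), ch)
    if (length(lack))
      stop("schema error: sample '", id, "' is missing channel(s) ",
           paste(lack, collapse = ", "))
  }
  tab
}

#' Write an area table to CSV
#'
#' @param table Area table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeAreaTable <- function(table, path) {
  stopifnot(all(.AREA_COLS %in% names(table)))
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

.fitSam <- function(rt) fitStandardAddition(rt$spike_level, rt$response)

#' Run the full quantification and validation pipeline
#'
#' Deterministic given the config seed: simulates the standard-addition
#' table, the A/B/C/D aliquots, the robustness series and the freeze-thaw
#' set; renders and measures the unspiked chromatograms for S/N; fits the SAM
#' line (pooled and per replicate); and assembles the validation metric set.
#'
#' @param config A [RunConfig-class].
#' @param areaTable Optional pre-existing standard-addition area table (e.g.
#'   from [readAreaTable()]); when supplied it replaces the simulated one and
#'   only the SAM/accuracy metrics are derived from it.
#' @return A [ValidationReport-class].
#' @examples
#' rep <- runPipeline(runConfig(seed = 7))
#' rep
#' @export
runPipeline <- function(config, areaTable = NULL) {
  stopifnot(is(config, "RunConfig"))
  set.seed(config@seed)
  m <- config@matrix; d <- config@design; e <- config@errors
  opt <- config@options
  samTab <- if (is.null(areaTable)) simulateAssay(m, d, e) else areaTable
  rt <- responseTable(samTab)

  pooled <- .fitSam(rt)
  reps <- lapply(split(rt, rt$replicate), .fitSam)
  dil <- dilutionFactor(m, d)
  endo <- endogenousConcentration(pooled, dil)

  ## accuracy & precision: net concentration (B - A) per spiked sample,
  ## with B = y / slope (total in-assay concentration) and A = x0
  acc <- do.call(rbind, lapply(
    setdiff(sort(unique(rt$spike_level)), 0), function(s) {
      y <- rt$response[rt$spike_level == s]
      B <- y / pooled@slope
      net <- B - pooled@x0
      data.frame(spike_level = s,
                 accuracy = mean(accuracyPercent(B, pooled@x0, s)),
                 rsd = if (length(net) >= 3) precisionRsd(net) else NA_real_)
    }))

  ## S/N of the unspiked analyte peak via rendered chromatograms
  unspiked <- samTab[samTab$spike_level == 0 & samTab$channel == "analyte", ]
  traces <- renderChromatograms(unspiked, e)
  pk <- measurePeaks(traces, e, flankWidth = opt$flank_width)
  snr <- mean(pk$snr)
  sens <- estimateLodLoq(pooled@x0, snr)

  ## recovery & matrix effect from the A/B/C/D aliquots (raw analyte areas)
  val <- responseTable(makeValidationSet(m, d, e))
  roleMean <- function(r) mean(val$analyte[val$design_role == r])
  recovery <- recoveryPercent(roleMean("A"), roleMean("B"), roleMean("C"))
  matEff <- matrixEffectPercent(roleMean("A"), roleMean("C"), roleMean("D"))

  ## robustness CVs
  rob <- robustnessCv(makeRobustnessSet(
    m, d, e, activities = opt$robustness_activities,
    replicates = opt$robustness_replicates))

  ## freeze-thaw stability, measured downstream through its own SAM fit
  ftTab <- makeFreezeThawSet(m, d, e, cycles = opt$freeze_thaw_cycles,
                             perCycleLoss = opt$freeze_thaw_loss)
  ftFit <- .fitSam(responseTable(ftTab))
  stability <- stabilityPercentChange(pooled@x0, ftFit@x0)

  new("ValidationReport", endogenous = endo, sam = pooled,
      samReplicates = reps, accuracy = acc, recovery = recovery,
      matrixEffect = matEff, sensitivity = sens, stability = stability,
      robustness = rob,
      thresholds = list(accuracy = opt$accuracy_band, lloq = opt$lloq_band,
                        stability = opt$stability_band))
}

.reportToList <- function(report) {
  list(schema_version = "1.0",
       endogenous_conc_ugml = report@endogenous[["conc"]],
       endogenous_se_ugml = report@endogenous[["se"]],
       sam = list(slope = report@sam@slope, intercept = report@sam@intercept,
                  r_squared = report@sam@rSquared, x0 = report@sam@x0,
                  x0_se = report@sam@x0Se, n_points = report@sam@nPoints),
       accuracy = report@accuracy,
       recovery_percent = report@recovery,
       matrix_effect_percent = report@matrixEffect,
       snr = report@sensitivity@snr,
       lod_ugml = report@sensitivity@lod,
       loq_ugml = report@sensitivity@loq,
       stability_percent_change = report@stability,
       robustness_cv_unnormalized = report@robustness[["cv_unnormalized"]],
       robustness_cv_normalized = report@robustness[["cv_normalized"]],
       thresholds = report@thresholds)
}

#' Serialize a validation report
#'
#' JSON is a lossless dump of every report field (plus a schema version);
#' CSV is a flat one-row-per-metric table.
#'
#' @param report A [ValidationReport-class].
#' @param path Output path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  stopifnot(is(report, "ValidationReport"))
  x <- .reportToList(report)
  if (format == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    flat <- x[!vapply(x, is.list, logical(1)) &
              !vapply(x, is.data.frame, logical(1))]
    utils::write.csv(
      data.frame(metric = names(flat),
                 value = vapply(flat, as.character, character(1))),
      path, row.names = FALSE)
  }
  invisible(path)
}

setMethod("show", "ValidationReport", function(object) {
  cat("Validation report\n")
  cat(sprintf("  endogenous HA: %.1f +/- %.1f ug/mL (original matrix)\n",
              object@endogenous[["conc"]], object@endogenous[["se"]]))
  cat(sprintf("  SAM: slope %.4g, r2 = %.4f, x0 = %.3f ug/mL in-assay\n",
              object@sam@slope, object@sam@rSquared, object@sam@x0))
  cat(sprintf("  LOD %.3f / LOQ %.3f ug/mL (S/N %.1f)\n",
              object@sensitivity@lod, object@sensitivity@loq,
              object@sensitivity@snr))
  cat(sprintf("  recovery %.2f%%, matrix effect %.2f%%\n",
              object@recovery, object@matrixEffect))
  for (i in seq_len(nrow(object@accuracy)))
    cat(sprintf("  spike %g ug/mL: accuracy %.1f%%, RSD %.1f%%\n",
                object@accuracy$spike_level[i], object@accuracy$accuracy[i],
                object@accuracy$rsd[i]))
  cat(sprintf("  freeze-thaw change %.2f%% (band %.0f%%)\n",
              object@stability, object@thresholds$stability))
  cat(sprintf("  robustness CV: %.1f%% raw -> %.1f%% IS1-normalized\n",
              object@robustness[["cv_unnormalized"]],
              object@robustness[["cv_normalized"]]))
})
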