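# CSV readers/writers for the package's exchange formats, FASTA input,
# and the two end-to-end pipeline drivers.

.fmt <- function(df) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits = 6)
  df
}

#' Read and write peak-list CSVs
#'
#' Format: columns `mz,intensity`, optional header, one file per
#' replicate.
#'
#' @param path file path.
#' @param label,replicate metadata attached to the PeakList on read.
#' @param peaks a [PeakList-class] (for writing).
#' @return for `readPeakListCSV`, a [PeakList-class].
#' @export
readPeakListCSV <- function(path, label = basename(path), replicate = NULL) {
  first <- utils::read.csv(path, header = FALSE, nrows = 1)
  header <- is.character(first[[1]]) || is.factor(first[[1]])
  df <- utils::read.csv(path, header = header)
  if (ncol(df) < 2) stop("peak-list CSV needs two columns: mz,intensity")
  peakList(df[[1]], df[[2]], label = label, replicate = replicate)
}

#' @rdname readPeakListCSV
#' @export
writePeakListCSV <- function(peaks, path) {
  utils::write.csv(.fmt(data.frame(mz = peaks@mz,
                                   intensity = peaks@intensity)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read and write mole-fraction CSVs
#'
#' Format: `lipid_conc_uM,replicate,x0..x4`.
#'
#' @param path file path.
#' @param table a mole-fraction data.frame (for writing).
#' @return for `readMoleFractionCSV`, a data.frame.
#' @export
readMoleFractionCSV <- function(path) {
  df <- utils::read.csv(path)
  need <- c("lipid_conc_uM", "replicate")
  if (!all(need %in% names(df)) || !any(grepl("^x[0-9]+$", names(df))))
    stop("mole-fraction CSV must have lipid_conc_uM, replicate, x0..")
  df
}

#' @rdname readMoleFractionCSV
#' @export
writeMoleFractionCSV <- function(table, path) {
  utils::write.csv(.fmt(as.data.frame(table)), path, row.names = FALSE)
  invisible(path)
}

#' Read a DynamX-style HDX state-data CSV
#'
#' Format: `Protein,Start,End,Sequence,State,Exposure_min,Replicate,
#' Uptake_Da` (the `Protein` column is optional and ignored).
#'
#' @param path file path.
#' @param exposures the exposure grid in minutes.
#' @return an [HDXDataset-class].
#' @export
readHdxStateCSV <- function(path, exposures = c(1, 60, 180, 360)) {
  df <- utils::read.csv(path)
  hdxDataset(df, exposures = exposures)
}

#' @rdname readHdxStateCSV
#' @param hdx an [HDXDataset-class] (for writing).
#' @export
writeHdxStateCSV <- function(hdx, path) {
  u <- hdx@uptake
  out <- data.frame(Protein = "protein", Start = u$start, End = u$end,
                    Sequence = u$sequence, State = u$state,
                    Exposure_min = u$exposure, Replicate = u$replicate,
                    Uptake_Da = signif(u$uptake, 6))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a protein sequence from FASTA
#'
#' @param path FASTA file path.
#' @return character(1) sequence (first record).
#' @export
readProteinFasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (!length(seqs)) stop("no sequences in ", path)
  as.character(seqs[[1]])
}

#' Write a fitted-constant report CSV
#'
#' Format: `site,KD_uM,SD,R2,converged`.
#'
#' @param fit a [BindingFit-class].
#' @param path file path.
#' @export
writeFitReportCSV <- function(fit, path) {
  df <- data.frame(site = seq_along(fit@kd), KD_uM = signif(fit@kd, 6),
                   SD = signif(fit@sd, 6), R2 = signif(fit@r2, 6),
                   converged = fit@converged)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Validate a pipeline run configuration
#'
#' A run configuration is a named list; unknown keys are rejected so that
#' typos cannot silently change a run.
#'
#' @param config named list.
#' @param allowed character vector of permitted keys.
#' @return the validated config (with defaults filled by the caller).
#' @export
validateRunConfig <- function(config, allowed) {
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  config
}

.logLine <- function(con, ...) {
  writeLines(paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...), con)
}

#' Run the binding pipeline: mole fractions to fitted constants
#'
#' Reads mole-fraction CSVs (or takes an in-memory table), fits the
#' sequential binding model, and writes a fit report, predicted curves
#' for plotting, and a run log recording package version, seed and
#' parameters. Deterministic given config and seed; any stage error
#' aborts with a stage-tagged message.
#'
#' @param config named list with keys: `input` (CSV path or data.frame),
#'   `outDir`, `nSites` (default 4), `ptot` (uM, default 5), `seed`
#'   (default 1).
#' @return invisibly, a list with the [BindingFit-class] and output paths.
#' @export
runBindingPipeline <- function(config) {
  config <- validateRunConfig(config, c("input", "outDir", "nSites",
                                        "ptot", "seed"))
  if (is.null(config$input)) stop("[input] no input: provide a mole-fraction CSV or table")
  nSites <- config$nSites %||% 4L
  ptot <- config$ptot %||% 5
  seed <- config$seed %||% 1L
  outDir <- config$outDir %||% stop("[config] outDir is required")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  data <- if (is.character(config$input)) {
    if (!file.exists(config$input)) stop("[input] no input: ", config$input)
    readMoleFractionCSV(config$input)
  } else config$input
  design <- titrationDesign(ptot, sort(unique(data$lipid_conc_uM)),
                            max(1L, length(unique(data$replicate))))
  fit <- tryCatch(fitKds(data, nSites = nSites, design = design),
                  error = function(e) stop("[fit] ", conditionMessage(e)))
  model <- bindingModel(fit@kd)
  grid <- titrationDesign(ptot, seq(0, max(data$lipid_conc_uM),
                                    length.out = 101)[-1], 1L)
  curves <- rbind(data.frame(lipid_conc_uM = 0,
                             t(c(1, rep(0, nSites)))) |>
                    stats::setNames(c("lipid_conc_uM",
                                      paste0("x", 0:nSites))),
                  predictTitration(model, grid))
  paths <- list(fit = file.path(outDir, "fit_report.csv"),
                curves = file.path(outDir, "predicted_curves.csv"),
                log = file.path(outDir, "run.log"))
  writeFitReportCSV(fit, paths$fit)
  utils::write.csv(.fmt(curves), paths$curves, row.names = FALSE)
  con <- file(paths$log, "w"); on.exit(close(con))
  .logLine(con, "binding pipeline; memprotMS ",
           as.character(utils::packageVersion("memprotMS")))
  .logLine(con, sprintf("seed=%d nSites=%d ptot=%g input_rows=%d",
                        as.integer(seed), nSites, ptot, nrow(data)))
  .logLine(con, sprintf("KD_uM=%s R2=%.6f",
                        paste(signif(fit@kd, 6), collapse = ","), fit@r2))
  invisible(list(fit = fit, paths = paths))
}

#' Run the HDX pipeline: state data to differential and synergy tables
#'
#' Computes delta-RFU for every non-reference state against apo, the
#' synergy statistic when all four states are present, per-peptide
#' uptake-plot tables, a residue-level projection, and optionally writes
#' the projection into a PDB B-factor column.
#'
#' @param config named list with keys: `input` (state-data CSV path or
#'   [HDXDataset-class]), `outDir`, `alpha` (default 0.05),
#'   `projectionMode` (`"mean"` or `"min_length"`), `projectionState`
#'   (default `"ternary"` if present else first state),
#'   `projectionExposure` (default 60), `pdb` (optional input PDB path),
#'   `seed`.
#' @return invisibly, a list of result tables and output paths.
#' @export
runHdxPipeline <- function(config) {
  config <- validateRunConfig(config, c("input", "outDir", "alpha",
                                        "projectionMode", "projectionState",
                                        "projectionExposure", "pdb", "seed"))
  if (is.null(config$input)) stop("[input] no input: provide a state-data CSV")
  outDir <- config$outDir %||% stop("[config] outDir is required")
  alpha <- config$alpha %||% 0.05
  mode <- config$projectionMode %||% "mean"
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hdx <- if (is.character(config$input)) readHdxStateCSV(config$input)
         else config$input
  states <- unique(hdx@uptake$state)
  known <- c("apo", "S1P", "PIP2", "ternary")
  if (length(setdiff(states, known)))
    stop("[states] unknown state label(s): ",
         paste(setdiff(states, known), collapse = ", "),
         "; expected {apo, S1P, PIP2, ternary}")
  if (!"apo" %in% states) stop("[states] reference state 'apo' required")
  if (length(states) < 2) stop("[states] need >= 2 states")
  paths <- list(); results <- list()
  for (st in setdiff(states, "apo")) {
    d <- deltaRfu(hdx, st, alpha = alpha)
    p <- file.path(outDir, sprintf("differential_%s.csv", st))
    utils::write.csv(.fmt(d), p, row.names = FALSE)
    results[[paste0("differential_", st)]] <- d
    paths[[paste0("differential_", st)]] <- p
  }
  if (all(known %in% states)) {
    s <- synergy(hdx, alpha = alpha)
    p <- file.path(outDir, "synergy.csv")
    utils::write.csv(.fmt(s), p, row.names = FALSE)
    results$synergy <- s
    paths$synergy <- p
  }
  rfu <- computeRfu(hdx)
  p <- file.path(outDir, "uptake_rfu.csv")
  utils::write.csv(.fmt(rfu), p, row.names = FALSE)
  results$rfu <- rfu; paths$rfu <- p
  projState <- config$projectionState %||%
    (if ("ternary" %in% states) "ternary" else setdiff(states, "apo")[1])
  projExp <- config$projectionExposure %||% 60
  dproj <- results[[paste0("differential_", projState)]]
  slice <- dproj[dproj$exposure == projExp, , drop = FALSE]
  track <- projectToResidues(slice, mode = mode)
  p <- file.path(outDir, "residue_track.csv")
  utils::write.csv(.fmt(data.frame(residue = seq_along(track),
                                   value = track)), p, row.names = FALSE)
  paths$track <- p; results$track <- track
  if (!is.null(config$pdb)) {
    p <- file.path(outDir, "residue_track.pdb")
    writeResidueTrackPDB(config$pdb, track, p)
    paths$pdb <- p
  }
  con <- file(file.path(outDir, "run.log"), "w"); on.exit(close(con))
  .logLine(con, "hdx pipeline; memprotMS ",
           as.character(utils::packageVersion("memprotMS")))
  .logLine(con, sprintf("alpha=%g mode=%s states=%s", alpha, mode,
                        paste(states, collapse = ",")))
  invisible(list(results = results, paths = paths))
}
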