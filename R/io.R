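# File interfaces: Z-score CSV (first column subject ID, empty/NA/NaN =
# missing), model JSON (bit-exact round trip), assignment tables, MCMC
# traces and positional-variance matrices, and run manifests.

.naTokens <- c("", "NA", "NaN", "nan")

#' Read a Z-score data matrix from CSV
#'
#' First column = subject ID, remaining columns = biomarker Z-scores;
#' empty cells and the tokens NA/NaN/nan are read as missing.  Column
#' order defines biomarker order.
#'
#' @param path CSV file with a header row.
#' @return Numeric matrix with subject IDs as rownames.
#' @examples
#' z <- readZScoreCSV(system.file("extdata", "synthetic_zscores.csv",
#'                                package = "mdsustain"))
#' sum(is.na(z))
#' @export
readZScoreCSV <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("expected a subject-ID column plus biomarkers")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate subject IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- df[-1L]
  out <- matrix(NA_real_, nrow(df), ncol(vals),
                dimnames = list(ids, colnames(vals)))
  for (i in seq_along(vals)) {
    v <- trimws(vals[[i]])
    missing <- v %in% .naTokens | is.na(v)
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!missing & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                   v[bad[1L]], bad[1L], colnames(vals)[i]))
    out[, i] <- ifelse(missing, NA_real_, num)
  }
  out
}

# full-precision number formatting so write/read round-trips bit-exactly
.fmtNum <- function(x) {
  out <- vapply(x, function(v)
    if (is.na(v)) "" else sprintf("%.17g", v), "")
  out
}

#' Write a Z-score data matrix to CSV
#'
#' Inverse of \code{\link{readZScoreCSV}}: missing cells are written as
#' empty strings and values at 17 significant digits so that a write/read
#' cycle is bit-exact.
#'
#' @param data numeric matrix with subject IDs as rownames.
#' @param path output path.
#' @param idColumn name of the subject-ID column.
#' @export
writeZScoreCSV <- function(data, path, idColumn = "subject_id") {
  if (is.null(rownames(data)))
    rownames(data) <- as.character(seq_len(nrow(data)))
  df <- data.frame(rownames(data), apply(data, 2L, .fmtNum),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(idColumn, colnames(data))
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Serialise a subtype model to JSON
#'
#' The document stores the biomarker configuration, the event orderings
#' (as ordered lists of biomarker/Z pairs), mixture fractions and stage
#' prior at full precision; \code{\link{readSubtypeModel}} restores a
#' bit-exact model.
#'
#' @param model a \linkS4class{SubtypeModel}.
#' @param path output JSON path.
#' @export
writeSubtypeModel <- function(model, path) {
  validObject(model)
  et <- eventTable(model@config)
  doc <- list(
    biomarkers = model@config@names,
    event_levels = unname(model@config@eventLevels),
    z_max = model@config@zMax,
    sigma = model@config@sigma,
    sequences = lapply(seq_len(nSubtypes(model)), function(c) {
      ord <- model@sequences[c, ]
      data.frame(biomarker = et$name[ord], z = et$z[ord])
    }),
    fractions = model@fractions,
    stage_prior = model@stagePrior)
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = FALSE,
                       dataframe = "columns")
  invisible(path)
}

#' Restore a subtype model from JSON
#'
#' @param path a file written by \code{\link{writeSubtypeModel}}.
#' @return A \linkS4class{SubtypeModel}.
#' @export
readSubtypeModel <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  config <- biomarkerConfig(doc$biomarkers,
                            lapply(doc$event_levels, as.numeric),
                            zMax = doc$z_max, sigma = doc$sigma)
  et <- eventTable(config)
  sequences <- t(vapply(doc$sequences, function(sq) {
    vapply(seq_along(sq$biomarker), function(p)
      et$event[et$name == sq$biomarker[p] & et$z == sq$z[p]], integer(1))
  }, integer(nEvents(config))))
  subtypeModel(config, sequences, fractions = doc$fractions,
               stagePrior = doc$stage_prior)
}

#' Serialise a biomarker configuration to JSON
#'
#' @param config a \linkS4class{BiomarkerConfig}.
#' @param path output JSON path.
#' @export
writeBiomarkerConfig <- function(config, path) {
  validObject(config)
  doc <- list(biomarkers = config@names,
              event_levels = unname(config@eventLevels),
              z_max = config@zMax, sigma = config@sigma)
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = FALSE)
  invisible(path)
}

#' Restore a biomarker configuration from JSON
#'
#' @param path a file written by \code{\link{writeBiomarkerConfig}}.
#' @return A \linkS4class{BiomarkerConfig}.
#' @export
readBiomarkerConfig <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  biomarkerConfig(doc$biomarkers, lapply(doc$event_levels, as.numeric),
                  zMax = doc$z_max, sigma = doc$sigma)
}

#' Write per-subject assignments to CSV
#'
#' One row per subject: ML subtype (the label \code{normal_appearing} for
#' ML stage 0), ML stage, the marginal probability of each subtype, the
#' probability of the ML subtype, and the size of the 95\% credible set.
#'
#' @param post a \linkS4class{SubjectPosteriors}.
#' @param path output path.
#' @param mass credible-set mass for the set-size column.
#' @export
writeAssignments <- function(post, path, mass = 0.95) {
  d <- dim(post@prob)
  J <- d[1L]; C <- d[2L]
  marg <- matrix(0, J, C)
  for (c in seq_len(C)) marg[, c] <- apply(post@prob[, c, , drop = FALSE],
                                           1L, sum)
  colnames(marg) <- sprintf("prob_subtype%d", seq_len(C))
  csSize <- vapply(credibleSets(post, mass), nrow, integer(1))
  df <- data.frame(
    subject_id = post@subjectIds,
    ml_subtype = ifelse(post@normalAppearing, "normal_appearing",
                        as.character(post@mlSubtype)),
    ml_stage = post@mlStage,
    as.data.frame(matrix(.fmtNum(marg), nrow = J,
                         dimnames = list(NULL, colnames(marg))),
                  stringsAsFactors = FALSE),
    ml_subtype_prob = .fmtNum(marg[cbind(seq_len(J), post@mlSubtype)]),
    credible_set_size = csSize,
    check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a fitted model with its uncertainty artefacts
#'
#' Emits \code{<prefix>_model.json}, \code{<prefix>_mcmc_trace.csv}
#' (iteration, log likelihood, fractions) and one
#' \code{<prefix>_posvar_subtype<c>.csv} per subtype (rows = events in
#' config order, columns = positions 1..N).
#'
#' @param fit a \linkS4class{SustainFit}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Character vector of the files written.
#' @export
writeFitResult <- function(fit, dir, prefix = "sustain") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- file.path(dir, paste0(prefix, "_model.json"))
  writeSubtypeModel(fit@model, files[1L])
  if (length(fit@mcmc)) {
    tracePath <- file.path(dir, paste0(prefix, "_mcmc_trace.csv"))
    tr <- data.frame(iteration = seq_along(fit@mcmc$logLik),
                     log_lik = .fmtNum(fit@mcmc$logLik))
    fr <- apply(fit@mcmc$fractions, 2L, .fmtNum)
    colnames(fr) <- sprintf("fraction%d", seq_len(ncol(fr)))
    write.csv(cbind(tr, fr), tracePath, row.names = FALSE, quote = FALSE)
    files <- c(files, tracePath)
    for (c in seq_along(fit@positionalVariance)) {
      p <- file.path(dir, sprintf("%s_posvar_subtype%d.csv", prefix, c))
      pv <- fit@positionalVariance[[c]]
      df <- data.frame(event = rownames(pv),
                       apply(pv, 2L, .fmtNum), check.names = FALSE)
      write.csv(df, p, row.names = FALSE, quote = FALSE)
      files <- c(files, p)
    }
  }
  invisible(files)
}

#' Write a run manifest
#'
#' Records the subcommand, configuration, seed, package version and input
#' checksums so a run can be reproduced from the manifest alone.
#'
#' @param path output JSON path.
#' @param command subcommand name.
#' @param config named list of parameters (must include the seed).
#' @param inputs character vector of input file paths to checksum.
#' @export
writeManifest <- function(path, command, config, inputs = character(0)) {
  sums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  doc <- list(command = command, config = config,
              package_version =
                as.character(utils::packageVersion("mdsustain")),
              r_version = as.character(getRversion()),
              input_md5 = sums)
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}
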