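# Aggregated results report and run manifests for the command-line
# front-end (inst/scripts/veinfuse-cli.R).

#' Write a JSON run manifest
#'
#' Records the inputs, seed, package version and parameters of a run so
#' it can be reproduced exactly.
#'
#' @param path Output path.
#' @param subcommand Name of the pipeline stage.
#' @param seed Integer seed (NA if the stage is deterministic).
#' @param inputs,parameters Named lists.
#' @export
writeRunManifest <- function(path, subcommand, seed = NA_integer_,
                             inputs = list(), parameters = list()) {
  jsonlite::write_json(
    list(subcommand = subcommand, seed = seed,
         package = "veinfuse",
         version = as.character(utils::packageVersion("veinfuse")),
         inputs = inputs, parameters = parameters),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

mdTable <- function(df) {
  hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r)
    paste0("| ", paste(format(r, trim = TRUE), collapse = " | "), " |"))
  c(hdr, sep, rows)
}

#' Write an aggregated results report
#'
#' Collects whatever result objects are supplied — a category summary, a
#' set of observer-variability summaries, a bridging-vein count table,
#' confluence-angle group statistics and drainage-type frequencies — into
#' one Markdown report mirroring the structure of a results write-up.
#'
#' @param path Output Markdown path.
#' @param category Optional [CategorySummary-class].
#' @param variability Optional list of [VariabilitySummary-class].
#' @param counts Optional result of [countBridgingVeins()].
#' @param angleStats Optional data.frame from [groupAngleStats()].
#' @param drainage Optional data.frame from [drainageFrequencies()].
#' @return The path, invisibly.
#' @export
writeResultsReport <- function(path, category = NULL, variability = list(),
                               counts = NULL, angleStats = NULL,
                               drainage = NULL) {
  out <- c("# Vein reconstruction results", "")
  if (!is.null(angleStats)) {
    out <- c(out, "## Confluence angles at the SSS", "",
             mdTable(data.frame(group = angleStats$group, n = angleStats$n,
                                mean_deg = round(angleStats$mean_deg, 1),
                                mad_deg = round(angleStats$mad_deg, 1))),
             "", sprintf("Total angles: %d", attr(angleStats, "total")), "")
  }
  if (!is.null(category)) {
    cc <- categoryCounts(category)
    pp <- categoryPercentages(category)
    out <- c(out, "## Correlation with the surgical photographs", "",
             mdTable(data.frame(category = 0:4, count = as.integer(cc[1:5]),
                                percent = as.numeric(pp))),
             "",
             sprintf("Total %d sections; %d photo-visible, %d reconstruction-visible.",
                     cc[["total"]], cc[["photo_visible"]],
                     cc[["recon_visible"]]), "")
  }
  for (v in variability) {
    out <- c(out, sprintf("## Geometric error: %s variability", v@kind), "",
             mdTable(data.frame(unit = names(unitMeans(v)),
                                mean_mm = round(unitMeans(v), 2))),
             "", sprintf("Grand mean: %.2f mm", grandMean(v)), "")
  }
  if (!is.null(counts)) {
    df <- as.data.frame(counts$table)
    df <- cbind(side = rownames(counts$table), df,
                total = counts$side_totals)
    out <- c(out, "## Bridging veins per sinus third", "", mdTable(df), "")
  }
  if (!is.null(drainage)) {
    out <- c(out, "## Drainage types", "", mdTable(drainage), "",
             sprintf("Not assessable: %d", attr(drainage, "unassessable")),
             "")
  }
  writeLines(out, path)
  invisible(path)
}
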