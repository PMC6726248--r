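# End-to-end orchestration: detect -> quantify -> signals (-> permute,
# uorf), with config validation, deterministic outputs and a summary
# report. The exported functions are the package's command surface; each
# stage is also callable on its own.

#' Build a pipeline configuration
#'
#' Collects input paths and stage parameters. Every parameter defaults to
#' the value used throughout the package (read floor 3, GT/GC donors, GAG
#' 3'ss rejection, branchpoint geometry 45/7, display floors 35/50, 2-fold
#' transcript gate).
#'
#' @param sj Named character vector or list of junction-table paths
#'   (names = library ids).
#' @param fasta Genome FASTA path.
#' @param annotation GFF3/BED12 path.
#' @param coverage Named list/vector of bedGraph paths (`t0`, `t60`).
#' @param condition_of_library Named vector mapping library ids to
#'   conditions.
#' @param orfs Optional ORF FASTA for the hexamer analysis.
#' @param out Output directory.
#' @param filter [filter_params()].
#' @param report [delta_report_params()].
#' @param n_permutations Permutations for the hexamer stage.
#' @param seed Seed for the permutation stage.
#' @param force Overwrite existing outputs.
#' @return A list of class `"PipelineConfig"`.
#' @export
pipeline_config <- function(sj, fasta, annotation, coverage,
                            condition_of_library, orfs = NULL, out = "results",
                            filter = filter_params(),
                            report = delta_report_params(),
                            n_permutations = 1000L, seed = 1L, force = FALSE) {
  structure(list(sj = sj, fasta = fasta, annotation = annotation,
                 coverage = coverage,
                 condition_of_library = condition_of_library, orfs = orfs,
                 out = out, filter = filter, report = report,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), force = force),
            class = "PipelineConfig")
}

#' Validate a pipeline configuration
#'
#' Returns a character vector of problems (empty when runnable); each
#' problem names the offending key and the violated constraint.
#'
#' @param config A [pipeline_config()].
#' @return Character vector of problems.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  need_file <- function(path, key) {
    if (!is.character(path) || !file.exists(path)) {
      problems <<- c(problems, sprintf("%s: file not found (%s)", key,
                                       as.character(path)))
    }
  }
  if (length(config$sj) == 0L) {
    problems <- c(problems, "sj: at least one junction table is required")
  }
  for (i in seq_along(config$sj)) need_file(config$sj[[i]], paste0("sj[", i, "]"))
  need_file(config$fasta, "fasta")
  need_file(config$annotation, "annotation")
  for (cd in c("t0", "t60")) {
    if (is.null(config$coverage[[cd]])) {
      problems <- c(problems, sprintf("coverage: missing %s track", cd))
    } else need_file(config$coverage[[cd]], paste0("coverage$", cd))
  }
  if (!is.null(config$orfs)) need_file(config$orfs, "orfs")
  fp <- config$filter
  if (fp$min_total_reads < 1L) {
    problems <- c(problems, "filter$min_total_reads: must be >= 1")
  }
  if (fp$flank < 8L) problems <- c(problems, "filter$flank: must be >= 8")
  if (config$n_permutations < 2L) {
    problems <- c(problems, "n_permutations: must be >= 2")
  }
  problems
}

#' Run the full pipeline
#'
#' Validates the configuration, runs detection, quantification and signal
#' profiling (plus the hexamer permutation stage when an ORF set is
#' configured), writes every stage table under `config$out` and returns a
#' summary. Existing outputs are only overwritten with `force = TRUE`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `events`, `locations`, `quant`, `pwms`,
#'   and `summary` (event/location counts by category, median
#'   percent-spliced by class, delta-index quadrant counts).
#' @export
run_pipeline <- function(config) {
  problems <- validate_config(config)
  if (length(problems)) {
    stop("invalid pipeline configuration:\n  ", paste(problems, collapse = "\n  "))
  }
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  out_paths <- file.path(config$out, c("events.tsv", "locations.tsv",
                                       "quant.tsv", "summary.tsv"))
  if (!config$force && any(file.exists(out_paths))) {
    stop("outputs already exist in ", config$out, " (use force = TRUE)")
  }
  msg <- function(stage, ...) message("[", stage, "] ", ...)

  msg("detect", "reading reference and junction tables")
  genome <- read_genome(config$fasta)
  annotation <- read_annotation(config$annotation, genome = genome)
  det <- detect_protointrons(config$sj, genome, annotation, config$filter)
  msg("detect", nrow(det$events), " junctions -> ",
      sum(det$events$accepted), " accepted events, ",
      nrow(det$locations), " protointron locations")

  msg("quantify", "coverage and indices")
  tracks <- list(t0 = read_bedgraph(config$coverage[["t0"]], "depth"),
                 t60 = read_bedgraph(config$coverage[["t60"]], "depth"))
  std_loc <- merge_events_to_locations(det$standard_events)
  if (nrow(std_loc)) {
    std_loc$context <- "standard"; std_loc$gene_id <- NA_character_
  }
  all_loc <- rbind(det$locations, std_loc)
  quant <- quantify_locations(all_loc, det$events, tracks,
                              config$condition_of_library,
                              is_standard = all_loc$context == "standard",
                              report = config$report)
  quant$class <- ifelse(all_loc$context == "standard", "standard", "protointron")

  msg("signals", "PWMs over accepted events")
  acc <- det$events[det$events$accepted, , drop = FALSE]
  pwms <- if (nrow(acc)) signal_pwms(acc, genome) else NULL

  hex <- NULL
  if (!is.null(config$orfs)) {
    msg("permute", config$n_permutations, " codon permutations")
    hex <- hexamer_depletion(config$orfs, config$n_permutations, config$seed)
  }

  write_results_table(det$events, file.path(config$out, "events.tsv"))
  write_results_table(all_loc, file.path(config$out, "locations.tsv"))
  write_results_table(quant, file.path(config$out, "quant.tsv"))
  if (!is.null(hex)) {
    write_results_table(hex, file.path(config$out, "hexamer_z.tsv"))
  }
  if (!is.null(pwms)) {
    for (nm in names(pwms)) {
      if (is.null(pwms[[nm]])) next
      write.table(format(unclass(pwms[[nm]]), digits = 4),
                  file.path(config$out, paste0(nm, ".tsv")),
                  sep = "\t", quote = FALSE, col.names = FALSE)
    }
  }

  med <- function(x) if (any(is.finite(x))) median(x[is.finite(x)]) else NA_real_
  ps <- quant$percent_spliced_t0
  delta <- quant$delta_sj[quant$passes_display_filter]
  summary <- list(
    n_junctions = nrow(det$events),
    n_accepted_events = sum(det$events$accepted),
    n_protointron_events = nrow(det$protointron_events),
    n_locations = nrow(det$locations),
    context_counts = table(det$locations$context),
    median_percent_spliced_standard = med(ps[quant$class == "standard"]),
    median_percent_spliced_protointron = med(ps[quant$class == "protointron"]),
    delta_positive = sum(delta > 0, na.rm = TRUE),
    delta_negative = sum(delta < 0, na.rm = TRUE)
  )
  sum_df <- data.frame(key = c("n_junctions", "n_accepted_events",
                               "n_protointron_events", "n_locations",
                               "median_percent_spliced_standard",
                               "median_percent_spliced_protointron",
                               "delta_positive", "delta_negative"),
                       value = c(summary$n_junctions, summary$n_accepted_events,
                                 summary$n_protointron_events,
                                 summary$n_locations,
                                 summary$median_percent_spliced_standard,
                                 summary$median_percent_spliced_protointron,
                                 summary$delta_positive, summary$delta_negative))
  write_results_table(sum_df, file.path(config$out, "summary.tsv"))
  invisible(list(events = det$events, locations = det$locations,
                 quant = quant, pwms = pwms, hexamers = hex,
                 summary = summary))
}
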