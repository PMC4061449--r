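# End-to-end pipeline: binds coverage, Lorenz, classification and qPCR
# stages into one deterministic run over files named in a configuration.

#' Pipeline run configuration
#'
#' Collects input paths and analysis parameters. Stages run only when their
#' inputs are provided; defaults follow common WGA-QC practice (500-bp bins,
#' 100-base minimum read length, 1e-10 e-value ceiling).
#'
#' @param output_dir Directory for report files (created if needed).
#' @param seed Integer seed controlling all randomness in the run.
#' @param depth_a,depth_b Paths to depth files (samtools-depth TSV or
#'   BEDGraph, chosen by `depth_format`). `depth_a` drives breadth and
#'   Lorenz; both together drive balance.
#' @param depth_format `"depth"` or `"bedgraph"`.
#' @param contig_length Optional known contig length for zero-fill.
#' @param blast6 Path to a BLAST outfmt-6(+qlen) hit table.
#' @param species_map Path to the two-column subject-to-species TSV.
#' @param read_lengths Optional path to a two-column read-length TSV.
#' @param clade_map_path Optional path to a clade-map TSV; default map
#'   otherwise.
#' @param qpcr_standards,qpcr_samples Optional paths to qPCR tables
#'   ([read_qpcr_tsv()] format).
#' @param lod Assay limit of detection (pg) for sample quantitation.
#' @param untreated_pg Optional untreated-control masses (pg) enabling the
#'   fold-reduction stage.
#' @param bin_size Bin width in bases.
#' @param min_read_length,max_evalue Read filter settings.
#' @param lorenz_match_depth Optional target mean depth; tracks above it are
#'   binomially thinned before the Lorenz stage.
#' @return List of class `run_config`.
#' @export
run_config <- function(output_dir,
                       seed = 1L,
                       depth_a = NULL, depth_b = NULL,
                       depth_format = c("depth", "bedgraph"),
                       contig_length = NULL,
                       blast6 = NULL, species_map = NULL,
                       read_lengths = NULL, clade_map_path = NULL,
                       qpcr_standards = NULL, qpcr_samples = NULL,
                       lod = NULL, untreated_pg = NULL,
                       bin_size = 500,
                       min_read_length = 100,
                       max_evalue = 1e-10,
                       lorenz_match_depth = NULL) {
  depth_format <- match.arg(depth_format)
  if (bin_size < 1) stop_invalid("bin_size must be >= 1")
  if (min_read_length < 0) stop_invalid("min_read_length must be >= 0")
  if (max_evalue <= 0) stop_invalid("max_evalue must be positive")
  structure(as.list(environment()), class = "run_config")
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_invalid("[", name, "] ", conditionMessage(e))
  })
}

#' Run the full QC pipeline
#'
#' Executes every stage whose inputs are configured and writes a
#' self-describing report bundle into `config$output_dir`: binned-coverage
#' and Lorenz TSVs, breadth/balance/classification/decontamination JSON
#' summaries, and a run log of the parameters used. Given the same
#' configuration and seed the bundle is byte-identical across runs.
#'
#' @param config A [run_config()].
#' @return Invisible list of the computed stage results.
#' @export
pipeline_run <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  results <- list()
  reader <- switch(config$depth_format,
                   depth = read_depth_tsv,
                   bedgraph = read_bedgraph)

  read_track <- function(path, label) {
    if (!file.exists(path)) {
      stop_invalid("[", label, "] input not found: ", path)
    }
    pipeline_stage(label, reader(path, contig_length = config$contig_length))
  }

  if (!is.null(config$depth_a)) {
    track_a <- read_track(config$depth_a, "coverage")
    bins_a <- pipeline_stage("coverage", bin_depth(track_a, config$bin_size))
    results$breadth <- pipeline_stage("coverage", breadth(track_a))
    write_binned_tsv(bins_a, out("binstats_a.tsv"))
    write_json_report(
      list(parameters = list(bin_size = config$bin_size),
           genome_length = attr(bins_a, "genome_length"),
           genome_mean_depth = attr(bins_a, "genome_mean_depth"),
           breadth_pct = as.list(results$breadth)),
      out("coverage.json"))

    lz_track <- track_a
    if (!is.null(config$lorenz_match_depth) &&
        config$lorenz_match_depth < mean(track_a$depths)) {
      lz_track <- pipeline_stage(
        "lorenz",
        downsample_to_depth(track_a, config$lorenz_match_depth,
                            seed = config$seed))
    }
    lz <- pipeline_stage("lorenz",
                         lorenz_curve(bin_depth(lz_track, config$bin_size)))
    results$lorenz <- lz
    write_lorenz_tsv(lz, out("lorenz.tsv"))
    write_json_report(
      list(parameters = list(bin_size = config$bin_size,
                             match_depth = config$lorenz_match_depth),
           gini = lz$gini, n_bins = lz$n_bins, mean_depth = lz$mean_depth),
      out("lorenz.json"))

    if (!is.null(config$depth_b)) {
      track_b <- read_track(config$depth_b, "balance")
      bins_b <- pipeline_stage("balance", bin_depth(track_b, config$bin_size))
      bal <- pipeline_stage("balance", balance(bins_a, bins_b))
      results$balance <- bal
      utils::write.table(bal$bins, out("balance.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      write_json_report(
        list(parameters = list(bin_size = config$bin_size),
             mean_variation = bal$mean_variation,
             sd_variation = bal$sd_variation,
             pct_within_2fold = bal$pct_within_2fold,
             pct_within_4fold = bal$pct_within_4fold,
             n_excluded_zero_bins = bal$n_excluded_zero_bins,
             n_bins = bal$n_bins),
        out("balance.json"))
    }
  }

  if (!is.null(config$blast6)) {
    if (is.null(config$species_map)) {
      stop_invalid("[classify] blast6 input needs a species_map")
    }
    hits <- pipeline_stage(
      "classify",
      read_blast6(config$blast6, config$species_map, config$read_lengths))
    flt <- pipeline_stage(
      "classify",
      filter_reads(hits, config$min_read_length, config$max_evalue))
    cmap <- if (!is.null(config$clade_map_path)) {
      pipeline_stage("classify", read_clade_map(config$clade_map_path))
    } else {
      default_clade_map()
    }
    tl <- pipeline_stage(
      "classify",
      tally(flt$hits, clade_map = cmap, n_reads_filtered = flt$n_dropped))
    results$tally <- tl
    utils::write.table(as.data.frame(tl), out("tally.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_json_report(
      list(parameters = list(min_read_length = config$min_read_length,
                             max_evalue = config$max_evalue),
           n_reads_classified = attr(tl, "n_reads_classified"),
           n_reads_filtered = attr(tl, "n_reads_filtered"),
           top_species = tl$species[1],
           top_percent = tl$percent[1]),
      out("classify.json"))
  }

  if (!is.null(config$qpcr_standards)) {
    std <- pipeline_stage("decontam", read_qpcr_tsv(config$qpcr_standards))
    std <- std[!is.na(std$quantity) & !is.na(std$cq), , drop = FALSE]
    curve <- pipeline_stage("decontam", fit_standard_curve(std))
    results$curve <- curve
    decon <- list(parameters = list(lod = config$lod),
                  slope = curve$slope, intercept = curve$intercept,
                  r_squared = curve$r_squared,
                  efficiency_pct = 100 * curve$efficiency)
    if (!is.null(config$qpcr_samples)) {
      if (is.null(config$lod)) {
        stop_invalid("[decontam] sample quantitation needs an lod")
      }
      smp <- pipeline_stage("decontam", read_qpcr_tsv(config$qpcr_samples))
      qr <- pipeline_stage("decontam",
                           quantify(smp$cq, curve, lod = config$lod))
      results$quant <- qr
      decon$n_samples <- nrow(qr)
      decon$n_censored <- sum(qr$censored)
      if (!is.null(config$untreated_pg)) {
        fr <- pipeline_stage(
          "decontam", fold_reduction(config$untreated_pg, qr))
        results$fold_reduction <- fr
        decon$fold_reduction <- list(
          mean_based_bound = fr$mean_based_bound,
          min_based_bound = fr$min_based_bound,
          is_lower_bound = fr$is_lower_bound)
      }
    }
    write_json_report(decon, out("decontam.json"))
  }

  log_lines <- c(
    paste0("wgaqc ", as.character(utils::packageVersion("wgaqc"))),
    paste0("seed\t", config$seed),
    paste0("bin_size\t", config$bin_size),
    paste0("min_read_length\t", config$min_read_length),
    paste0("max_evalue\t", format(config$max_evalue)),
    paste0("lorenz_match_depth\t",
           ifelse(is.null(config$lorenz_match_depth), "none",
                  config$lorenz_match_depth)),
    paste0("lod\t", ifelse(is.null(config$lod), "none", config$lod)),
    paste0("stages\t", paste(names(results), collapse = ",")))
  writeLines(log_lines, out("run_log.txt"))
  invisible(results)
}
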