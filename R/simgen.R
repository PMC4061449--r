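# Synthetic-data generator: biased depth tracks, metagenomic hit tables and
# qPCR dilution series with known ground truth. All randomness flows from the
# seed in the configuration, so identical configurations give bit-identical
# output.

#' Simulation configuration
#'
#' Bundles the parameters of the synthetic-data generator. The generator
#' emulates the data-generating reality of an MDA/WGA sequencing experiment:
#' multiplicative per-bin amplification bias over a single linear chromosome,
#' a mixed-species read pool in which a controllable fraction of reads has
#' hits shared across several species, and a qPCR dilution series under a
#' log-linear efficiency model.
#'
#' Amplification bias is piecewise-constant at `bin_size` granularity and
#' drawn lognormal with `meanlog = -bias_sigma^2 / 2`, so the expected bias is
#' exactly 1 and the realized genome mean depth converges to `mean_depth` as
#' the genome grows.
#'
#' @param seed Integer seed; the single source of randomness.
#' @param genome_length Genome length in bases (single linear chromosome).
#' @param bin_size Amplification-bias granularity in bases (default 500, the
#'   same granularity at which the coverage analysis operates).
#' @param mean_depth Expected genome-wide mean depth in reads/base.
#' @param bias_sigma Lognormal scale (sdlog) of the per-bin amplification
#'   bias; 0 gives pure Poisson sampling noise with no bias.
#' @param composition Named numeric vector of species proportions summing
#'   to 1.
#' @param ambiguity_rate Fraction in \[0,1\] of reads whose hit set spans more
#'   than one species.
#' @param qpcr_efficiency Amplification efficiency E in (0, 1.1\]; a perfect
#'   assay has E = 1 (100\%).
#' @param qpcr_intercept Cq at quantity 1 (in the assay's mass units).
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, genome_length = 1e5, mean_depth = 30)
#' @export
sim_config <- function(seed,
                       genome_length = 1e6,
                       bin_size = 500,
                       mean_depth = 64,
                       bias_sigma = 1.0,
                       composition = c("Bacillus cereus" = 1),
                       ambiguity_rate = 0,
                       qpcr_efficiency = 1.0,
                       qpcr_intercept = 30) {
  if (missing(seed)) stop_invalid("sim_config requires a seed")
  if (!is.numeric(genome_length) || genome_length <= 0) {
    stop_invalid("genome_length must be positive")
  }
  if (!is.numeric(mean_depth) || mean_depth <= 0) {
    stop_invalid("mean_depth must be positive")
  }
  if (bin_size < 1 || genome_length < bin_size) {
    stop_invalid("need genome_length >= bin_size >= 1")
  }
  if (bias_sigma < 0) stop_invalid("bias_sigma must be >= 0")
  if (length(composition) == 0) stop_invalid("composition must be non-empty")
  if (is.null(names(composition)) || any(!nzchar(names(composition)))) {
    stop_invalid("composition must be a named vector of proportions")
  }
  if (abs(sum(composition) - 1) > 1e-9 || any(composition < 0)) {
    stop_invalid("composition proportions must be >= 0 and sum to 1")
  }
  if (ambiguity_rate < 0 || ambiguity_rate > 1) {
    stop_invalid("ambiguity_rate must be in [0, 1]")
  }
  if (qpcr_efficiency <= 0 || qpcr_efficiency > 1.1) {
    stop_invalid("qpcr_efficiency must be in (0, 1.1]")
  }
  structure(
    list(seed = as.integer(seed),
         genome_length = as.integer(genome_length),
         bin_size = as.integer(bin_size),
         mean_depth = mean_depth,
         bias_sigma = bias_sigma,
         composition = composition,
         ambiguity_rate = ambiguity_rate,
         qpcr_efficiency = qpcr_efficiency,
         qpcr_intercept = qpcr_intercept),
    class = "sim_config"
  )
}

#' Simulate a depth track with lognormal-Poisson amplification bias
#'
#' Draws one multiplicative bias factor per `bin_size` window from a
#' lognormal with expectation 1, then per-base depths from
#' `Poisson(mean_depth * bias)`. With `bias_sigma = 0` this collapses to pure
#' Poisson counting noise around `mean_depth`.
#'
#' @param cfg A [sim_config()].
#' @param contig Contig name for the track.
#' @return A [depth_track()] of length `cfg$genome_length`.
#' @examples
#' tr <- simulate_depth(sim_config(seed = 1, genome_length = 1e4,
#'                                 mean_depth = 20, bias_sigma = 0))
#' mean(tr$depths)
#' @export
simulate_depth <- function(cfg, contig = "chr1") {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n_bins <- ceiling(cfg$genome_length / cfg$bin_size)
    bias <- stats::rlnorm(n_bins,
                          meanlog = -cfg$bias_sigma^2 / 2,
                          sdlog = cfg$bias_sigma)
    widths <- rep(cfg$bin_size, n_bins)
    widths[n_bins] <- cfg$genome_length - (n_bins - 1L) * cfg$bin_size
    lambda <- cfg$mean_depth * rep.int(bias, widths)
    depth_track(stats::rpois(cfg$genome_length, lambda), contig = contig)
  })
}

#' Simulate a metagenomic hit table with known truth labels
#'
#' Each read's true species is drawn from `cfg$composition`; with probability
#' `cfg$ambiguity_rate` the read's hit set additionally contains one or more
#' other species drawn uniformly, emulating sequence shared across taxa.
#' E-values of ambiguous hits are drawn from the same passing distribution
#' (between 1e-50 and 1e-10) as true hits, so downstream classification must
#' rely on vote weighting, not e-value ranking.
#'
#' @param cfg A [sim_config()] with a non-empty composition.
#' @param n_reads Number of reads to simulate.
#' @param read_length Read length(s) in bases; recycled across reads, so a
#'   vector can be used to plant short reads for filter testing.
#' @return A list of class `sim_hits` with elements
#'   * `hits`: data frame (`read_id`, `read_length`, `species`, `subject`,
#'     `evalue`, `bitscore`), one row per hit;
#'   * `reads`: data frame of ground truth (`read_id`, `read_length`,
#'     `true_species`);
#'   * `species_map`: data frame (`subject`, `species`) covering every
#'     subject accession emitted.
#' @examples
#' h <- simulate_hits(sim_config(seed = 1, composition = c(A = 0.7, B = 0.3)),
#'                    n_reads = 100)
#' table(h$reads$true_species)
#' @export
simulate_hits <- function(cfg, n_reads, read_length = 118L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (n_reads <= 0) stop_invalid("n_reads must be positive")
  species <- names(cfg$composition)
  n_acc <- 3L  # accessions per species: exercises subject->species dedupe
  species_map <- data.frame(
    subject = paste0(rep(gsub("[^A-Za-z0-9]+", "_", species), each = n_acc),
                     "_acc", seq_len(n_acc)),
    species = rep(species, each = n_acc),
    stringsAsFactors = FALSE
  )
  with_seed(cfg$seed, {
    read_length <- rep_len(as.integer(read_length), n_reads)
    truth <- sample(species, n_reads, replace = TRUE, prob = cfg$composition)
    ambiguous <- stats::runif(n_reads) < cfg$ambiguity_rate & length(species) > 1
    extra <- lapply(seq_len(n_reads), function(i) {
      if (!ambiguous[i]) return(character(0))
      others <- setdiff(species, truth[i])
      k <- sample.int(length(others), 1L)
      sample(others, k)
    })
    hit_species <- mapply(c, truth, extra, SIMPLIFY = FALSE,
                          USE.NAMES = FALSE)
    n_hits <- lengths(hit_species)
    read_id <- sprintf("read%06d", seq_len(n_reads))
    hits <- data.frame(
      read_id = rep.int(read_id, n_hits),
      read_length = rep.int(read_length, n_hits),
      species = unlist(hit_species, use.names = FALSE),
      stringsAsFactors = FALSE
    )
    acc_idx <- sample.int(n_acc, nrow(hits), replace = TRUE)
    hits$subject <- paste0(gsub("[^A-Za-z0-9]+", "_", hits$species),
                           "_acc", acc_idx)
    hits$evalue <- 10^stats::runif(nrow(hits), -50, -10)
    hits$bitscore <- round(stats::runif(nrow(hits), 100, 250), 1)
    structure(
      list(hits = hits,
           reads = data.frame(read_id = read_id,
                              read_length = read_length,
                              true_species = truth,
                              stringsAsFactors = FALSE),
           species_map = species_map),
      class = "sim_hits"
    )
  })
}

#' Simulate a qPCR standard series
#'
#' Generates Cq values under the log-linear model
#' `Cq = intercept + slope * log10(quantity)` with
#' `slope = -1 / log10(1 + E)`, where E is the amplification efficiency, plus
#' optional Gaussian Cq noise. At E = 1 consecutive 10-fold dilutions are
#' separated by `1/log10(2) = 3.3219` cycles.
#'
#' @param quantities Positive template quantities; at least two must be
#'   distinct for the series to be fittable downstream.
#' @param cfg A [sim_config()] supplying `qpcr_efficiency` and
#'   `qpcr_intercept`.
#' @param noise_sd Gaussian noise SD in Cq units (default 0).
#' @return Data frame with columns `quantity` and `cq`.
#' @examples
#' simulate_qpcr(10^(0:3), sim_config(seed = 1))
#' @export
simulate_qpcr <- function(quantities, cfg, noise_sd = 0) {
  stopifnot(inherits(cfg, "sim_config"))
  if (any(quantities <= 0)) stop_invalid("quantities must be positive")
  if (length(unique(quantities)) < 2) {
    stop_invalid("need >= 2 distinct quantities for a fittable series")
  }
  slope <- -1 / log10(1 + cfg$qpcr_efficiency)
  with_seed(cfg$seed, {
    cq <- cfg$qpcr_intercept + slope * log10(quantities) +
      stats::rnorm(length(quantities), 0, noise_sd)
    data.frame(quantity = quantities, cq = cq)
  })
}
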