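# Coverage binning, breadth-of-coverage and two-sample balance statistics.
# Coordinates are 0-based half-open internally; 1-based only at the
# samtools-depth I/O boundary.

#' Per-base depth track
#'
#' @param depths Non-negative integer vector, one value per reference
#'   position.
#' @param contig Contig name.
#' @return Object of class `depth_track` with elements `contig` and `depths`.
#' @examples
#' depth_track(c(0, 1, 5, 9))
#' @export
depth_track <- function(depths, contig = "chr1") {
  if (length(depths) == 0) stop_invalid("empty depth track")
  if (any(is.na(depths)) || any(depths < 0)) {
    stop_invalid("depths must be non-negative and non-missing")
  }
  structure(list(contig = as.character(contig)[1],
                 depths = as.integer(depths)),
            class = "depth_track")
}

#' @export
print.depth_track <- function(x, ...) {
  cat(sprintf("<depth_track> %s: %d bp, mean depth %.2f\n",
              x$contig, length(x$depths), mean(x$depths)))
  invisible(x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> seed=%d genome=%d bp bins=%d bp depth=%g sigma=%g\n",
    x$seed, x$genome_length, x$bin_size, x$mean_depth, x$bias_sigma))
  cat("  composition:",
      paste(sprintf("%s=%.3g", names(x$composition), x$composition),
            collapse = ", "), "\n")
  invisible(x)
}

#' Bin a depth track into fixed-width windows
#'
#' Tiles the contig with half-open `[start, end)` bins of `bin_size` bases;
#' a terminal partial bin is retained and its mean computed over its actual
#' width. Each bin's mean depth is also normalized by the genome-wide mean
#' depth (total sequenced bases over genome length), the form in which bins
#' enter all evenness and balance statistics.
#'
#' @param track A [depth_track()].
#' @param bin_size Bin width in bases (default 500).
#' @return A data frame of class `binned_coverage` with columns `bin_start`,
#'   `bin_end` (0-based half-open), `bin_mean_depth` and `normalized`, and
#'   attributes `bin_size`, `contig`, `genome_mean_depth`, `genome_length`.
#' @examples
#' bin_depth(depth_track(c(0, 0, 4, 4)), bin_size = 2)
#' @export
bin_depth <- function(track, bin_size = 500) {
  stopifnot(inherits(track, "depth_track"))
  if (bin_size < 1) stop_invalid("bin_size must be >= 1")
  n <- length(track$depths)
  grp <- (seq_len(n) - 1L) %/% as.integer(bin_size)
  sums <- rowsum(as.numeric(track$depths), grp, reorder = TRUE)[, 1]
  widths <- tabulate(grp + 1L)
  genome_mean <- sum(as.numeric(track$depths)) / n
  bins <- data.frame(
    bin_start = as.integer(sort(unique(grp))) * as.integer(bin_size),
    bin_end = NA_integer_,
    bin_mean_depth = sums / widths
  )
  bins$bin_end <- pmin(bins$bin_start + as.integer(bin_size), n)
  bins$normalized <- if (genome_mean > 0) {
    bins$bin_mean_depth / genome_mean
  } else {
    rep(NA_real_, nrow(bins))
  }
  structure(bins,
            class = c("binned_coverage", "data.frame"),
            bin_size = as.integer(bin_size),
            contig = track$contig,
            genome_mean_depth = genome_mean,
            genome_length = n)
}

#' Breadth of coverage at depth thresholds
#'
#' Percent of reference positions at or above each depth cutoff (e.g. the
#' familiar ">= 1X" and ">= 5X" genome-representation metrics). Breadth is
#' non-increasing in the threshold and invariant to permuting positions.
#'
#' @param track A [depth_track()].
#' @param thresholds Integer depth cutoffs (default `c(1, 5)`).
#' @return Named numeric vector of percentages in \[0, 100\].
#' @examples
#' breadth(depth_track(c(0, 1, 5, 9)))  # 75% at 1X, 50% at 5X
#' @export
breadth <- function(track, thresholds = c(1, 5)) {
  stopifnot(inherits(track, "depth_track"))
  if (any(thresholds < 1)) stop_invalid("thresholds must be >= 1")
  out <- vapply(thresholds,
                function(t) 100 * mean(track$depths >= t),
                numeric(1))
  names(out) <- paste0(">=", thresholds, "X")
  out
}

#' Two-sample coverage balance in matched bins
#'
#' Compares two identically-binned samples after each has been normalized by
#' its own genome mean (removing depth-of-sequencing differences). For each
#' bin where both normalized values are positive, reports the fold variation
#' `max(a,b)/min(a,b)` (always >= 1) and the signed `log2(a/b)` ratio; bins
#' with a zero on either side are excluded from ratio statistics and counted.
#'
#' @param a,b [bin_depth()] results with identical contig, bin size and
#'   tiling.
#' @return Object of class `balance_report`: a list with the per-bin table
#'   (`bins`), `mean_variation`, `sd_variation`, `pct_within_2fold`,
#'   `pct_within_4fold`, `n_excluded_zero_bins` and `n_bins`.
#' @examples
#' tr <- depth_track(rpois(4000, 50))
#' rep <- balance(bin_depth(tr, 500), bin_depth(tr, 500))
#' rep$pct_within_2fold  # identical samples: 100
#' @export
balance <- function(a, b) {
  stopifnot(inherits(a, "binned_coverage"), inherits(b, "binned_coverage"))
  same <- identical(attr(a, "bin_size"), attr(b, "bin_size")) &&
    identical(attr(a, "contig"), attr(b, "contig")) &&
    nrow(a) == nrow(b) &&
    identical(a$bin_start, b$bin_start)
  if (!same) {
    stop_invalid("incompatible binnings: contig, bin_size and tiling must match")
  }
  na <- a$normalized
  nb <- b$normalized
  included <- na > 0 & nb > 0
  fold <- ifelse(included, pmax(na, nb) / pmin(na, nb), NA_real_)
  l2 <- ifelse(included, log2(na / nb), NA_real_)
  fv <- fold[included]
  structure(
    list(bins = data.frame(bin_start = a$bin_start,
                           bin_end = a$bin_end,
                           fold_variation = fold,
                           log2_ratio = l2,
                           included = included),
         mean_variation = mean(fv),
         sd_variation = stats::sd(fv),
         pct_within_2fold = 100 * mean(fv <= 2),
         pct_within_4fold = 100 * mean(fv <= 4),
         n_excluded_zero_bins = sum(!included),
         n_bins = nrow(a),
         bin_size = attr(a, "bin_size")),
    class = "balance_report"
  )
}

#' @export
print.balance_report <- function(x, ...) {
  cat(sprintf(
    paste0("<balance_report> %d bins (%d excluded as zero): ",
           "mean variation %.2f-fold (sd %.2f); %.1f%% within 2-fold, ",
           "%.1f%% within 4-fold\n"),
    x$n_bins, x$n_excluded_zero_bins, x$mean_variation, x$sd_variation,
    x$pct_within_2fold, x$pct_within_4fold))
  invisible(x)
}
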