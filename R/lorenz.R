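# Lorenz-curve / Gini analysis of coverage evenness, with binomial depth
# matching so samples sequenced to different depths can be compared at a
# common average coverage.

#' Lorenz curve of binned coverage
#'
#' Sorts bins by ascending mean depth (ties broken by genomic position for
#' determinism) and accumulates the share of total coverage against the share
#' of bins. A perfectly even sample follows the diagonal; the further the
#' curve sags below it, the more coverage is concentrated in few bins. The
#' Gini coefficient is twice the area between the diagonal and the curve,
#' computed by the trapezoid rule; 0 means perfectly uniform coverage.
#'
#' @param bins A [bin_depth()] result with positive total coverage.
#' @return Object of class `lorenz_curve`: list with `x`, `y` (curve points
#'   including the (0,0) and (1,1) endpoints), `gini`, `n_bins`,
#'   `mean_depth`.
#' @examples
#' lc <- lorenz_curve(bin_depth(depth_track(rep(c(1, 2, 3, 4), each = 10)),
#'                    bin_size = 10))
#' lc$gini  # 0.25
#' @export
lorenz_curve <- function(bins) {
  stopifnot(inherits(bins, "binned_coverage"))
  d <- bins$bin_mean_depth
  total <- sum(d)
  if (nrow(bins) < 1 || total <= 0) {
    stop_invalid("Lorenz curve undefined: no bins or all-zero coverage")
  }
  ord <- order(d, bins$bin_start)
  n <- length(d)
  x <- c(0, seq_len(n) / n)
  y <- c(0, cumsum(d[ord]) / total)
  auc <- sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  structure(list(x = x, y = y,
                 gini = 1 - 2 * auc,
                 n_bins = n,
                 mean_depth = attr(bins, "genome_mean_depth")),
            class = "lorenz_curve")
}

#' @export
print.lorenz_curve <- function(x, ...) {
  cat(sprintf("<lorenz_curve> %d bins, mean depth %.2f, Gini %.4f\n",
              x$n_bins, x$mean_depth, x$gini))
  invisible(x)
}

#' Downsample a depth track to a target mean depth
#'
#' Replaces each position's depth by a `Binomial(depth, p)` draw with
#' `p = target_mean / current_mean` — the depth-track analogue of random read
#' subsampling, used to compare coverage uniformity of two samples at a
#' matched average depth.
#'
#' @param track A [depth_track()].
#' @param target_mean Target genome mean depth; must not exceed the current
#'   mean. Equal means return the track unchanged.
#' @param seed Integer seed for the thinning draws.
#' @return A [depth_track()] with expected mean `target_mean`.
#' @examples
#' tr <- depth_track(rep(100L, 1000))
#' mean(downsample_to_depth(tr, 50, seed = 1)$depths)
#' @export
downsample_to_depth <- function(track, target_mean, seed) {
  stopifnot(inherits(track, "depth_track"))
  cur <- mean(track$depths)
  if (target_mean <= 0) stop_invalid("target_mean must be positive")
  if (target_mean > cur * (1 + 1e-12)) {
    stop_invalid(sprintf(
      "target mean %.3f exceeds current mean %.3f: cannot upsample",
      target_mean, cur))
  }
  p <- min(target_mean / cur, 1)
  if (p == 1) return(track)
  with_seed(seed, {
    depth_track(stats::rbinom(length(track$depths), track$depths, p),
                contig = track$contig)
  })
}
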