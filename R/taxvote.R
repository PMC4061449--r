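# Weighted-vote taxonomic classification of per-read hit tables, with clade
# collapsing and relative-sensitivity ratios.
#
# A hit table is a data frame with one row per (read, hit):
#   read_id, read_length, species, evalue  [optional: subject, bitscore]

check_hit_table <- function(hits) {
  need <- c("read_id", "read_length", "species", "evalue")
  missing <- setdiff(need, names(hits))
  if (length(missing)) {
    stop_invalid("hit table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(hits) > 0 && (any(hits$evalue <= 0) || any(!nzchar(hits$species)))) {
    stop_invalid("hit table: e-values must be > 0 and species names non-empty")
  }
  invisible(hits)
}

#' Filter reads by length and hit e-value
#'
#' Applies the two read-level quality gates used before classification: hits
#' above `max_evalue` are discarded, then a read is kept only if its length
#' is at least `min_length` and at least one passing hit remains. Defaults
#' (100 bases, 1e-10) are the conventional short-read metagenomic settings.
#'
#' @param hits Hit table data frame (`read_id`, `read_length`, `species`,
#'   `evalue`, ...).
#' @param min_length Minimum read length in bases.
#' @param max_evalue Maximum hit e-value.
#' @return List with `hits` (the surviving rows), `n_kept` and `n_dropped`
#'   (read counts).
#' @examples
#' h <- data.frame(read_id = c("r1", "r2"), read_length = c(99, 150),
#'                 species = "A", evalue = 1e-20)
#' filter_reads(h)$n_dropped  # r1 is too short
#' @export
filter_reads <- function(hits, min_length = 100, max_evalue = 1e-10) {
  check_hit_table(hits)
  if (min_length < 0) stop_invalid("min_length must be >= 0")
  n_reads <- length(unique(hits$read_id))
  keep <- hits$evalue <= max_evalue & hits$read_length >= min_length
  kept <- hits[keep, , drop = FALSE]
  rownames(kept) <- NULL
  n_kept <- length(unique(kept$read_id))
  list(hits = kept, n_kept = n_kept, n_dropped = n_reads - n_kept)
}

#' Default clade map
#'
#' Species collapsed to a single reported name because short reads cannot
#' distinguish them: the *Bacillus cereus* group (*B. cereus*,
#' *B. thuringiensis*, *B. anthracis*) is reported as *Bacillus cereus*, and
#' *Escherichia*/*Shigella* species as *Escherichia coli*. Species not in the
#' map are reported under their own name.
#'
#' @return Named character vector mapping species to reported clade name.
#' @export
default_clade_map <- function() {
  c("Bacillus cereus" = "Bacillus cereus",
    "Bacillus thuringiensis" = "Bacillus cereus",
    "Bacillus anthracis" = "Bacillus cereus",
    "Escherichia coli" = "Escherichia coli",
    "Shigella flexneri" = "Escherichia coli",
    "Shigella sonnei" = "Escherichia coli",
    "Shigella dysenteriae" = "Escherichia coli",
    "Shigella boydii" = "Escherichia coli")
}

apply_clade_map <- function(species, clade_map) {
  if (is.null(clade_map)) return(species)
  mapped <- unname(clade_map[species])
  ifelse(is.na(mapped), species, mapped)
}

#' Weighted-vote species tally
#'
#' Every read carries one vote. With the default equal weighting the vote is
#' split 1/k over the k distinct species in the read's hit set, so sequence
#' shared across many species contributes less per species than
#' species-specific sequence; multiple hits to the same species count once.
#' Votes are then collapsed through the clade map and converted to percent of
#' total votes. The vote total always equals the number of tallied reads.
#'
#' `weight_by = "score"` splits each read's vote proportionally to the best
#' bitscore per species instead (falling back to `-log10(evalue)` when no
#' bitscore column is present); the per-read total is still 1.
#'
#' @param hits Filtered hit table ([filter_reads()] output `$hits`); a read
#'   with zero hits cannot be represented, so filtering must come first.
#' @param clade_map Named character vector (see [default_clade_map()]), or
#'   NULL for no collapsing.
#' @param weight_by `"equal"` (default) or `"score"`.
#' @param n_reads_filtered Optional count of reads removed upstream, carried
#'   into the result for reporting.
#' @return Data frame of class `taxon_tally` (`species`, `votes`, `percent`,
#'   sorted by descending votes) with attributes `n_reads_classified` and
#'   `n_reads_filtered`.
#' @examples
#' h <- data.frame(read_id = c("r1", "r2", "r3", "r3"),
#'                 read_length = 150, species = c("A", "B", "A", "B"),
#'                 evalue = 1e-20)
#' tally(h, clade_map = NULL)  # A and B get 1.5 votes each
#' @export
tally <- function(hits, clade_map = default_clade_map(),
                  weight_by = c("equal", "score"), n_reads_filtered = 0L) {
  check_hit_table(hits)
  weight_by <- match.arg(weight_by)
  if (nrow(hits) == 0) stop_invalid("no hits to tally (all reads filtered?)")

  if (weight_by == "equal") {
    u <- unique(hits[, c("read_id", "species")])
    k <- ave(seq_len(nrow(u)), u$read_id, FUN = length)
    vote <- 1 / k
  } else {
    score <- if (!is.null(hits$bitscore)) hits$bitscore else -log10(hits$evalue)
    best <- stats::aggregate(score,
                             by = list(read_id = hits$read_id,
                                       species = hits$species),
                             FUN = max)
    u <- best[, c("read_id", "species")]
    per_read <- ave(best$x, best$read_id, FUN = sum)
    vote <- best$x / per_read
  }
  clade <- apply_clade_map(u$species, clade_map)
  votes <- rowsum(vote, clade, reorder = TRUE)[, 1]
  out <- data.frame(species = names(votes),
                    votes = unname(votes),
                    percent = 100 * unname(votes) / sum(votes),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$votes, out$species), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            class = c("taxon_tally", "data.frame"),
            n_reads_classified = length(unique(hits$read_id)),
            n_reads_filtered = as.integer(n_reads_filtered))
}

#' Construct a tally directly from vote totals
#'
#' Convenience constructor for comparing against published composition
#' tables when the underlying reads are not available.
#'
#' @param votes Named numeric vector of vote totals per species.
#' @return A `taxon_tally` data frame.
#' @examples
#' taxon_tally(c("Bacillus cereus" = 995, other = 5))
#' @export
taxon_tally <- function(votes) {
  if (is.null(names(votes)) || any(votes < 0) || sum(votes) <= 0) {
    stop_invalid("votes must be a named non-negative vector with positive sum")
  }
  out <- data.frame(species = names(votes),
                    votes = unname(votes),
                    percent = 100 * unname(votes) / sum(votes),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$votes, out$species), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("taxon_tally", "data.frame"),
            n_reads_classified = sum(votes), n_reads_filtered = 0L)
}

#' Relative sensitivity of two classifications for a target species
#'
#' Ratio of the target species' vote percentage in tally `a` over that in
#' tally `b` — e.g. how many fold more template-derived reads one
#' amplification method yields than another. A zero percentage in `b` gives
#' an infinite-ratio flag rather than a number.
#'
#' @param target Species name (after clade collapsing).
#' @param tally_a,tally_b `taxon_tally` objects.
#' @param sig_figs Optional number of significant figures to round to.
#' @return List with `ratio`, `infinite` flag, and the two percentages.
#' @examples
#' a <- taxon_tally(c(X = 99.5, other = 0.5))
#' b <- taxon_tally(c(X = 0.02, other = 99.98))
#' relative_sensitivity("X", a, b, sig_figs = 2)$ratio  # 5000
#' @export
relative_sensitivity <- function(target, tally_a, tally_b, sig_figs = NULL) {
  pa <- tally_a$percent[match(target, tally_a$species)]
  pb <- tally_b$percent[match(target, tally_b$species)]
  if (is.na(pa) || is.na(pb)) {
    stop_invalid("target species '", target, "' absent from a tally")
  }
  if (pb == 0) {
    return(list(ratio = Inf, infinite = TRUE, percent_a = pa, percent_b = pb))
  }
  r <- pa / pb
  if (!is.null(sig_figs)) r <- signif(r, sig_figs)
  list(ratio = r, infinite = FALSE, percent_a = pa, percent_b = pb)
}
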