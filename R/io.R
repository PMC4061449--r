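# Readers and writers for the standard text formats at the package boundary:
# samtools-depth TSV, BEDGraph, BLAST outfmt-6 TSV, two-column maps, qPCR
# tables and FASTA. Internal coordinates are 0-based half-open; conversion to
# the 1-based samtools-depth convention happens only here.

read_tsv_plain <- function(path, col_names) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          quote = "")
  if (ncol(df) < length(col_names)) {
    stop_invalid(basename(path), ": expected >= ", length(col_names),
                 " tab-separated columns, found ", ncol(df))
  }
  names(df)[seq_along(col_names)] <- col_names
  df
}

#' Read a samtools-depth style TSV into a depth track
#'
#' Three columns: contig, 1-based position, depth. Positions absent from the
#' file are filled with depth 0; the contig length defaults to the largest
#' position listed. Only single-contig files are supported.
#'
#' @param path Path to the TSV.
#' @param contig_length Optional known contig length for zero-fill beyond
#'   the last listed position.
#' @return A [depth_track()].
#' @export
read_depth_tsv <- function(path, contig_length = NULL) {
  df <- read_tsv_plain(path, c("contig", "pos", "depth"))
  if (length(unique(df$contig)) != 1) {
    stop_invalid(basename(path), ": expected exactly one contig")
  }
  pos <- as.integer(df$pos)
  if (any(is.na(pos)) || any(pos < 1)) {
    stop_invalid(basename(path), ": positions must be 1-based integers")
  }
  if (anyDuplicated(pos)) {
    stop_invalid(basename(path), ": duplicated positions")
  }
  len <- if (is.null(contig_length)) max(pos) else as.integer(contig_length)
  if (len < max(pos)) {
    stop_invalid(basename(path), ": position beyond stated contig_length")
  }
  depths <- integer(len)
  depths[pos] <- as.integer(df$depth)
  depth_track(depths, contig = df$contig[1])
}

#' Write a depth track as samtools-depth TSV
#'
#' @param track A [depth_track()].
#' @param path Output path.
#' @param drop_zero Omit zero-depth positions (the samtools default)?
#' @export
write_depth_tsv <- function(track, path, drop_zero = FALSE) {
  stopifnot(inherits(track, "depth_track"))
  pos <- seq_along(track$depths)
  keep <- if (drop_zero) track$depths > 0 else rep(TRUE, length(pos))
  utils::write.table(
    data.frame(track$contig, pos[keep], track$depths[keep]),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BEDGraph file into a depth track
#'
#' Four columns: contig, 0-based start, end (half-open), value. Intervals
#' must be sorted and non-overlapping; gaps are filled with depth 0.
#'
#' @inheritParams read_depth_tsv
#' @return A [depth_track()].
#' @export
read_bedgraph <- function(path, contig_length = NULL) {
  df <- read_tsv_plain(path, c("contig", "start", "end", "value"))
  df <- df[!grepl("^track", df$contig), , drop = FALSE]
  if (length(unique(df$contig)) != 1) {
    stop_invalid(basename(path), ": expected exactly one contig")
  }
  start <- as.integer(df$start); end <- as.integer(df$end)
  if (any(end <= start)) stop_invalid(basename(path), ": empty interval")
  if (is.unsorted(start, strictly = TRUE)) {
    stop_invalid(basename(path), ": intervals not sorted by start")
  }
  if (any(start[-1] < end[-length(end)])) {
    stop_invalid(basename(path), ": overlapping intervals")
  }
  len <- if (is.null(contig_length)) max(end) else as.integer(contig_length)
  if (len < max(end)) {
    stop_invalid(basename(path), ": interval beyond stated contig_length")
  }
  depths <- integer(len)
  for (i in seq_len(nrow(df))) {
    depths[(start[i] + 1L):end[i]] <- as.integer(df$value[i])
  }
  depth_track(depths, contig = df$contig[1])
}

#' Write a depth track as BEDGraph (run-length encoded)
#'
#' @param track A [depth_track()].
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "depth_track"))
  r <- rle(track$depths)
  end <- cumsum(r$lengths)
  start <- end - r$lengths
  utils::write.table(
    data.frame(track$contig, start, end, r$values),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BLAST outfmt-6 hit table and resolve subjects to species
#'
#' Accepts the standard 12-column tabular format (qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore) or a
#' 13-column dialect whose last column is qlen (the full read length).
#' Subjects are resolved to species through a two-column map; hits whose
#' subject is absent from the map are dropped with a warning and counted in
#' the `n_unmapped_subjects` attribute. Read lengths come from the qlen
#' column if present, else from a companion two-column (read_id, length)
#' TSV.
#'
#' @param path Path to the BLAST tabular file.
#' @param species_map Data frame (`subject`, `species`) or path to a
#'   two-column TSV.
#' @param read_lengths Optional data frame (`read_id`, `read_length`) or
#'   path to a two-column TSV; required for the 12-column dialect.
#' @return Hit table data frame (`read_id`, `read_length`, `species`,
#'   `subject`, `evalue`, `bitscore`) ready for [filter_reads()].
#' @export
read_blast6 <- function(path, species_map, read_lengths = NULL) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  if (!ncol(df) %in% c(12L, 13L)) {
    stop_invalid(basename(path), ": expected 12 or 13 tab-separated columns, found ",
                 ncol(df))
  }
  names(df)[1:12] <- cols
  if (ncol(df) == 13L) names(df)[13] <- "qlen"
  if (is.character(species_map)) {
    species_map <- read_tsv_plain(species_map, c("subject", "species"))
  }
  sp <- species_map$species[match(df$sseqid, species_map$subject)]
  n_unmapped <- sum(is.na(sp))
  if (n_unmapped > 0) {
    warning(n_unmapped, " hit(s) with subjects absent from the species map were dropped",
            call. = FALSE)
  }
  df <- df[!is.na(sp), , drop = FALSE]
  sp <- sp[!is.na(sp)]
  rl <- if ("qlen" %in% names(df)) {
    as.integer(df$qlen)
  } else {
    if (is.null(read_lengths)) {
      stop_invalid("12-column input needs a read_lengths table (no qlen column)")
    }
    if (is.character(read_lengths)) {
      read_lengths <- read_tsv_plain(read_lengths, c("read_id", "read_length"))
    }
    as.integer(read_lengths$read_length[match(df$qseqid, read_lengths$read_id)])
  }
  out <- data.frame(read_id = df$qseqid,
                    read_length = rl,
                    species = sp,
                    subject = df$sseqid,
                    evalue = as.numeric(df$evalue),
                    bitscore = as.numeric(df$bitscore),
                    stringsAsFactors = FALSE)
  attr(out, "n_unmapped_subjects") <- n_unmapped
  out
}

#' Write a hit table as BLAST outfmt-6 (13-column qlen dialect)
#'
#' Alignment coordinate columns not represented in the hit table are filled
#' with placeholder full-length perfect alignments; e-value, bitscore,
#' subject and qlen round-trip exactly.
#'
#' @param hits Hit table data frame.
#' @param path Output path.
#' @export
write_blast6 <- function(hits, path) {
  check_hit_table(hits)
  subject <- if (!is.null(hits$subject)) hits$subject else hits$species
  bitscore <- if (!is.null(hits$bitscore)) hits$bitscore else 200
  df <- data.frame(hits$read_id, subject, 100.0, hits$read_length, 0L, 0L,
                   1L, hits$read_length, 1L, hits$read_length,
                   format(hits$evalue, scientific = TRUE, digits = 6),
                   bitscore, hits$read_length)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a two-column subject-to-species map
#' @param species_map Data frame (`subject`, `species`).
#' @param path Output path.
#' @export
write_species_map <- function(species_map, path) {
  utils::write.table(species_map[, c("subject", "species")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a clade map from a two-column TSV (species, reported clade)
#' @param path Path to the TSV.
#' @return Named character vector usable as `clade_map` in [tally()].
#' @export
read_clade_map <- function(path) {
  df <- read_tsv_plain(path, c("species", "clade"))
  stats::setNames(df$clade, df$species)
}

#' Read a qPCR table (well, quantity, cq)
#'
#' Tab-separated with a header; `quantity` may be NA for unknowns, `cq` may
#' be NA for wells with no amplification.
#'
#' @param path Path to the TSV.
#' @return Data frame with columns `well`, `quantity`, `cq`.
#' @export
read_qpcr_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  need <- c("well", "quantity", "cq")
  if (!all(need %in% names(df))) {
    stop_invalid(basename(path), ": needs header columns well, quantity, cq")
  }
  df$quantity <- suppressWarnings(as.numeric(df$quantity))
  df$cq <- suppressWarnings(as.numeric(df$cq))
  df
}

#' Simulate and write a random reference sequence
#'
#' Uniform A/C/G/T sequence used only for coordinate bookkeeping alongside
#' simulated depth tracks.
#'
#' @param genome_length Sequence length in bases.
#' @param seed Integer seed.
#' @param path Optional FASTA output path.
#' @param contig Sequence name.
#' @return A `Biostrings::DNAStringSet` (invisibly if written to `path`).
#' @export
simulate_reference <- function(genome_length, seed, path = NULL,
                               contig = "chr1") {
  seqs <- with_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), genome_length, replace = TRUE),
          collapse = "")
  })
  dna <- Biostrings::DNAStringSet(stats::setNames(seqs, contig))
  if (!is.null(path)) {
    Biostrings::writeXStringSet(dna, path)
    return(invisible(dna))
  }
  dna
}

#' Write binned coverage as TSV
#' @param bins A [bin_depth()] result.
#' @param path Output path.
#' @export
write_binned_tsv <- function(bins, path) {
  stopifnot(inherits(bins, "binned_coverage"))
  utils::write.table(as.data.frame(bins), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a Lorenz curve as TSV (x, y)
#' @param lc A [lorenz_curve()] result.
#' @param path Output path.
#' @export
write_lorenz_tsv <- function(lc, path) {
  stopifnot(inherits(lc, "lorenz_curve"))
  utils::write.table(data.frame(x = lc$x, y = lc$y), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
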