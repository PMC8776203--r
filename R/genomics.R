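#' Read genomic intervals from a BED file
#'
#' BED3+ with optional name, score and strand columns; coordinates are kept
#' in the native BED convention (0-based, half-open). Lines with
#' `start >= end` or negative coordinates are rejected with their line
#' number.
#'
#' @param path Path to the tab-delimited BED file.
#' @return Data frame of class `genomic_intervals`: `chrom`, `start`,
#'   `end`, and when present `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0)
    return(genomic_intervals(data.frame(chrom = character(),
                                        start = integer(), end = integer())))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3))
    stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 fields")
  k <- min(nf)
  df <- data.frame(chrom = vapply(parts, `[`, "", 1),
                   start = as.numeric(vapply(parts, `[`, "", 2)),
                   end = as.numeric(vapply(parts, `[`, "", 3)),
                   stringsAsFactors = FALSE)
  if (k >= 4) df$name <- vapply(parts, `[`, "", 4)
  if (k >= 5) df$score <- suppressWarnings(
    as.numeric(vapply(parts, `[`, "", 5)))
  if (k >= 6) df$strand <- vapply(parts, `[`, "", 6)
  bad <- which(is.na(df$start) | is.na(df$end) | df$start < 0 |
                 df$start >= df$end)
  if (length(bad))
    stop("invalid BED interval at line ", bad[1], ": start must satisfy 0 <= start < end")
  genomic_intervals(df)
}

#' Construct a validated set of genomic intervals (BED convention)
#'
#' @param df Data frame with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand` (`+`, `-` or `.`).
#' @return The validated data frame, classed `genomic_intervals`.
#' @export
genomic_intervals <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (any(df$start < 0) || any(df$start >= df$end))
    stop("intervals must satisfy 0 <= start < end")
  if (!is.null(df$strand) && !all(df$strand %in% c("+", "-", ".")))
    stop("strand must be '+', '-' or '.'")
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

#' Write intervals to a BED file
#'
#' Writes the columns present, in BED order, tab-delimited without header;
#' round-trips losslessly through [read_bed()] up to BED6.
#'
#' @param intervals A `genomic_intervals` data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(intervals))
  # BED columns are positional: stop at the first absent one
  keep <- cols[seq_len(which.min(c(c("chrom", "start", "end", "name",
                                     "score", "strand") %in% cols, FALSE)) - 1)]
  out <- as.data.frame(intervals)[, keep, drop = FALSE]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Strand-aware anchor: interval start on +/unknown strand, end - 1 on -.
tss_anchor <- function(intervals) {
  strand <- if (is.null(intervals$strand)) rep(".", nrow(intervals))
            else intervals$strand
  ifelse(strand == "-", intervals$end - 1, intervals$start)
}

# Signed anchor-to-peak distance in BED coordinates: 0 when the anchor lies
# inside the peak, positive when the peak starts downstream of the anchor.
signed_dist <- function(anchor, p_start, p_end) {
  ifelse(anchor < p_start, p_start - anchor,
         ifelse(anchor > p_end - 1, (p_end - 1) - anchor, 0))
}

#' Nearest-peak colocalization of genes with binding sites
#'
#' For each gene, finds the nearest peak on the same chromosome measured
#' from the gene's TSS-equivalent anchor (interval start on the + strand,
#' end on the -) to the nearest covered base of the peak, and flags genes
#' whose nearest peak lies within a TAD-scale window. The default window of
#' 1 Mb is half the canonical 2 Mb TAD upper bound.
#'
#' @param genes,peaks `genomic_intervals` data frames.
#' @param window_bp Colocalization window in bp (default 1e6).
#' @return Data frame: `gene`, `chrom`, `anchor`, `nearest_peak`,
#'   `distance` (signed bp; `NA` when the chromosome has no peak),
#'   `within_window`.
#' @export
colocalize <- function(genes, peaks, window_bp = 1e6) {
  if (window_bp <= 0) stop("window_bp must be > 0")
  gname <- if (is.null(genes$name)) sprintf("gene%d", seq_len(nrow(genes)))
           else genes$name
  pname <- if (is.null(peaks$name)) sprintf("peak%d", seq_len(nrow(peaks)))
           else peaks$name
  anchor <- tss_anchor(genes)
  out <- data.frame(gene = gname, chrom = genes$chrom, anchor = anchor,
                    nearest_peak = NA_character_, distance = NA_real_,
                    within_window = FALSE, stringsAsFactors = FALSE)
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    pi <- which(peaks$chrom == ch)
    if (length(pi) == 0) next
    ps <- peaks$start[pi]; pe <- peaks$end[pi]
    o <- order(ps)
    ps <- ps[o]; pe <- pe[o]; pn <- pname[pi][o]
    # sweep: candidate peaks are the interval-start predecessor and successor
    # plus the peak with the rightmost end seen so far (covers containment)
    cum_end <- cummax(pe)
    for (g in gi) {
      a <- anchor[g]
      idx <- findInterval(a, ps)
      cand <- unique(pmax(1, pmin(length(ps), c(idx, idx + 1,
        if (idx >= 1) which.max(cum_end[seq_len(max(idx, 1))]) else integer(0)))))
      d <- signed_dist(a, ps[cand], pe[cand])
      j <- cand[which.min(abs(d))]
      out$nearest_peak[g] <- pn[j]
      out$distance[g] <- signed_dist(a, ps[j], pe[j])
      out$within_window[g] <- abs(out$distance[g]) <= window_bp
    }
  }
  out
}

#' Count peaks overlapping a region
#'
#' Half-open overlap: a peak starting exactly at `region$end` does not
#' overlap.
#'
#' @param region A single-row `genomic_intervals` (or list with `chrom`,
#'   `start`, `end`).
#' @param peaks A `genomic_intervals` data frame.
#' @return Integer count.
#' @export
count_region_peaks <- function(region, peaks) {
  sum(peaks$chrom == region$chrom[1] &
        peaks$start < region$end[1] & peaks$end > region$start[1])
}
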