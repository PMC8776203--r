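#' Timing class of a target gene
#'
#' A gene significantly responding within the first 8 h is a primary target;
#' a gene significant only at 24/48 h is a secondary target.
#'
#' @param significant_times Non-empty numeric vector of significant time
#'   points (hours).
#' @return `"primary"` or `"secondary"`.
#' @export
classify_timing <- function(significant_times) {
  if (length(significant_times) == 0)
    stop("not a target: empty set of significant time points")
  if (any(significant_times %in% c(4, 8))) "primary" else "secondary"
}

#' Direction of regulation of a target gene
#'
#' Considers the time points whose absolute fold change exceeds
#' `fc_threshold`: all positive log2FCs give `"up"`, all negative `"down"`,
#' both signs `"mixed"`. When no time point exceeds the threshold the sign
#' is taken from the significant time points instead.
#'
#' @param log2fc Per-time-point log2 fold changes (ordered by time).
#' @param fc_threshold Fold-change threshold (> 1, default 1.5).
#' @param significant_times Indices into `log2fc` are matched by
#'   `time_points_h`; used only for the fallback.
#' @param time_points_h Time grid matching `log2fc`.
#' @return `"up"`, `"down"` or `"mixed"`.
#' @export
classify_direction <- function(log2fc, fc_threshold = 1.5,
                               significant_times = NULL,
                               time_points_h = c(4, 8, 24, 48)) {
  if (fc_threshold <= 1) stop("fc_threshold must be > 1")
  big <- abs(log2fc) > log2(fc_threshold)
  signs <- sign(log2fc[big])
  if (!any(big)) {
    if (is.null(significant_times) || length(significant_times) == 0)
      stop("no fold change exceeds the threshold and no significant times given")
    signs <- sign(log2fc[time_points_h %in% significant_times])
  }
  has_up <- any(signs > 0); has_dn <- any(signs < 0)
  if (has_up && has_dn) "mixed" else if (has_up) "up" else "down"
}

#' Fold-change profile of a target gene over the time course
#'
#' `persistent`: |FC| stays above the threshold from the first significant
#' time point through 48 h. `discontinuous`: significance recurs after an
#' intermediate time point where |FC| dropped to or below the threshold.
#' `transient`: the gene is not significant at 48 h and its |FC| has fallen
#' back below the threshold there. Precedence: discontinuous > transient >
#' persistent.
#'
#' @param significant_times Non-empty significant time points (hours).
#' @param log2fc Per-time-point log2 fold changes (ordered by time).
#' @param fc_threshold Fold-change threshold (default 1.5).
#' @param time_points_h Time grid matching `log2fc`.
#' @return `"persistent"`, `"transient"` or `"discontinuous"`.
#' @export
classify_profile <- function(significant_times, log2fc, fc_threshold = 1.5,
                             time_points_h = c(4, 8, 24, 48)) {
  if (length(significant_times) == 0)
    stop("not a target: empty set of significant time points")
  thr <- log2(fc_threshold)
  below <- abs(log2fc) <= thr
  sig <- time_points_h %in% significant_times
  last <- length(time_points_h)
  discontinuous <- any(vapply(seq_len(last), function(i)
    below[i] && any(sig[seq_len(i - 1)]) && any(sig[-seq_len(i)]),
    logical(1)))
  if (discontinuous) return("discontinuous")
  if (!sig[last] && below[last]) return("transient")
  "persistent"
}

#' Classify every target gene by timing, direction and profile
#'
#' @param de Long DE table from [run_de()].
#' @param targets A `target_calls` object from [call_targets()].
#' @param fc_threshold Fold-change threshold for direction/profile calls.
#' @return Data frame: `gene`, `significant_times` (comma-separated),
#'   `timing`, `direction`, `profile`, plus one `log2FC_<t>` column per
#'   time point.
#' @export
classify_targets <- function(de, targets, fc_threshold = 1.5) {
  stopifnot(inherits(targets, "target_calls"))
  tps <- sort(unique(de$time_h))
  genes <- targets$union
  if (length(genes) == 0) {
    out <- data.frame(gene = character(), significant_times = character(),
                      timing = character(), direction = character(),
                      profile = character(), stringsAsFactors = FALSE)
    for (tp in tps) out[[paste0("log2FC_", tp)]] <- numeric()
    return(out)
  }
  fc <- matrix(NA_real_, length(genes), length(tps),
               dimnames = list(genes, tps))
  for (tp in tps) {
    r <- de[de$time_h == tp, ]
    fc[genes, as.character(tp)] <- r$log2FC[match(genes, r$gene)]
  }
  rows <- lapply(genes, function(g) {
    st <- tps[targets$table[g, ]]
    data.frame(gene = g,
               significant_times = paste(st, collapse = ","),
               timing = classify_timing(st),
               direction = classify_direction(fc[g, ], fc_threshold, st, tps),
               profile = classify_profile(st, fc[g, ], fc_threshold, tps),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  colnames(fc) <- paste0("log2FC_", tps)
  cbind(out, as.data.frame(fc[genes, , drop = FALSE]))
}

#' Exclusive Venn region counts of per-time-point significant sets
#'
#' @param sets Named list of gene-id vectors (typically 4 time points).
#' @return Data frame with one row per non-empty membership pattern:
#'   one logical column per set, `count`, and a `region` label. Exclusive
#'   counts sum to the size of the union.
#' @export
venn_counts <- function(sets) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("sets must be named")
  universe <- unique(unlist(sets))
  if (length(universe) == 0) {
    out <- as.data.frame(matrix(logical(), 0, length(sets),
                                dimnames = list(NULL, names(sets))))
    out$count <- integer()
    out$region <- character()
    return(out)
  }
  memb <- vapply(sets, function(s) universe %in% s,
                 logical(length(universe)))
  memb <- matrix(memb, nrow = length(universe),
                 dimnames = list(universe, names(sets)))
  key <- apply(memb, 1, function(r) paste(as.integer(r), collapse = ""))
  tab <- table(key)
  pat <- do.call(rbind, lapply(names(tab), function(k)
    as.logical(as.integer(strsplit(k, "")[[1]]))))
  out <- as.data.frame(pat)
  names(out) <- names(sets)
  out$count <- as.integer(tab)
  out$region <- vapply(seq_len(nrow(out)), function(i)
    paste(names(sets)[unlist(pat[i, ])], collapse = "&"), character(1))
  out[order(-out$count), , drop = FALSE]
}
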