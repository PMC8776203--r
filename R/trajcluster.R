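#' Standardize expression trajectories to z-scores
#'
#' Collapses the log2-CPM matrix to per-condition replicate means (one value
#' per time point x arm, 8 conditions for a 4-time-point two-arm design) and
#' z-score standardizes each gene across those condition means. Genes with
#' (near-)zero variance across conditions are excluded with a warning.
#'
#' @param log2cpm Genes x samples log2-CPM matrix.
#' @param design Design table matching the columns of `log2cpm`.
#' @param collapse Collapse replicates to condition means before
#'   standardizing (default `TRUE`; `FALSE` standardizes across samples).
#' @return List of class `std_trajectories`: `z` (genes x conditions),
#'   `center`, `scale`, `conditions` (data frame of time_h/arm per column),
#'   `excluded` (zero-variance gene ids).
#' @export
standardize_trajectories <- function(log2cpm, design, collapse = TRUE) {
  stopifnot(identical(colnames(log2cpm), as.character(design$sample)))
  if (collapse) {
    cond <- unique(design[order(design$arm, design$time_h),
                          c("arm", "time_h")])
    m <- vapply(seq_len(nrow(cond)), function(i)
      rowMeans(log2cpm[, design$arm == cond$arm[i] &
                         design$time_h == cond$time_h[i], drop = FALSE]),
      numeric(nrow(log2cpm)))
    m <- matrix(m, nrow = nrow(log2cpm),
                dimnames = list(rownames(log2cpm),
                                paste0(cond$arm, "_", cond$time_h, "h")))
  } else {
    cond <- design[, c("arm", "time_h")]
    m <- log2cpm
  }
  ctr <- rowMeans(m)
  sc <- apply(m, 1, stats::sd)
  ok <- sc > 1e-8
  if (!all(ok))
    warning(sum(!ok), " constant trajectories excluded from standardization")
  z <- (m[ok, , drop = FALSE] - ctr[ok]) / sc[ok]
  structure(list(z = z, center = ctr[ok], scale = sc[ok],
                 conditions = cond, excluded = rownames(m)[!ok]),
            class = "std_trajectories")
}

#' k-means clustering of standardized trajectories
#'
#' Hartigan-Wong k-means on the z-score trajectories, best of `n_restarts`
#' random starts by total within-cluster sum of squares; deterministic given
#' `seed`. Restarts are run explicitly so the best-of-subset monotonicity
#' holds and a degenerate start (duplicate centers / empty cluster) is
#' simply discarded.
#'
#' @param trajectories A `std_trajectories` (or plain numeric matrix).
#' @param k Number of clusters (default 4).
#' @param n_restarts Random starts (default 25).
#' @param max_iter Maximum iterations per start (default 1000).
#' @param seed Integer seed.
#' @return List of class `cluster_result`: `assignments` (named integer),
#'   `centroids` (k x conditions), `wcss` (total within-cluster SS),
#'   `k`, `n_restarts`, `seed`.
#' @export
kmeans_trajectories <- function(trajectories, k = 4, n_restarts = 25,
                                max_iter = 1000, seed = 1L) {
  z <- if (inherits(trajectories, "std_trajectories")) trajectories$z
       else as.matrix(trajectories)
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(z)) stop("k exceeds the number of genes")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- z[sample.int(nrow(z), k), , drop = FALSE]
    fit <- tryCatch(
      stats::kmeans(z, centers = init, iter.max = max_iter,
                    algorithm = "Hartigan-Wong"),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best))
    stop("k-means failed on every restart (too few distinct points?)")
  assignments <- best$cluster
  names(assignments) <- rownames(z)
  structure(list(assignments = assignments, centroids = best$centers,
                 wcss = best$tot.withinss, k = k, n_restarts = n_restarts,
                 seed = seed),
            class = "cluster_result")
}

#' Label clusters as direct/indirect with a direction
#'
#' A cluster centroid whose temporal range (max minus min over time points)
#' is larger in the treated arm than in the control arm describes a
#' treatment-driven ("direct") expression change; the converse describes a
#' culture-driven drift that treatment stabilizes ("indirect"). Direction of
#' a direct cluster is the sign of the mean treated-minus-control gap over
#' the time points after the first; an indirect cluster reports the
#' direction of the control-arm drift that treatment suppresses. Exact range
#' ties are labelled indirect with a warning.
#'
#' @param clusters A `cluster_result` whose centroid columns are condition
#'   means named `<arm>_<time>h` (as produced by
#'   [standardize_trajectories()]).
#' @return Data frame: `cluster`, `size`, `mechanism`, `direction`,
#'   `treated_range`, `control_range`.
#' @export
label_clusters <- function(clusters) {
  stopifnot(inherits(clusters, "cluster_result"))
  cn <- colnames(clusters$centroids)
  arm <- sub("_.*$", "", cn)
  time_h <- as.numeric(sub("h$", "", sub("^[^_]*_", "", cn)))
  if (!all(arm %in% c("treated", "control")) || anyNA(time_h))
    stop("centroid columns must be named <arm>_<time>h")
  ot <- order(time_h[arm == "treated"])
  oc <- order(time_h[arm == "control"])
  rows <- lapply(seq_len(nrow(clusters$centroids)), function(cl) {
    ce <- clusters$centroids[cl, ]
    trt <- ce[arm == "treated"][ot]
    ctl <- ce[arm == "control"][oc]
    tr <- diff(range(trt)); cr <- diff(range(ctl))
    if (tr == cr) {
      warning("cluster ", cl, ": arm ranges tie; labelled indirect")
      mech <- "indirect"
    } else mech <- if (tr > cr) "direct" else "indirect"
    dirsign <- if (mech == "direct")
      mean(trt[-1] - ctl[-1]) else ctl[length(ctl)] - ctl[1]
    data.frame(cluster = cl, size = sum(clusters$assignments == cl),
               mechanism = mech,
               direction = if (dirsign >= 0) "up" else "down",
               treated_range = tr, control_range = cr,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-by-two contingency analysis between classification axes
#'
#' Cross-tabulates two binary gene classifications, reports the two-sided
#' Fisher exact p, the sample odds ratio (Haldane 0.5 correction when a cell
#' is zero) and the relative risk. Degenerate tables (an empty margin) are
#' skipped with a warning. BH correction is applied across all tables
#' produced in one call.
#'
#' @param axes Named list of tests; each element a list with entries `a` and
#'   `b`, two named character vectors (gene -> level) over the same genes,
#'   each with exactly two levels after dropping genes listed in `exclude`.
#' @param exclude Levels to drop from either axis (default `"mixed"`:
#'   mixed-direction genes are reported separately, not tabulated).
#' @return Data frame: `test`, levels used, the four cells, `odds_ratio`,
#'   `relative_risk`, `p`, `FDR`.
#' @export
axis_contingency <- function(axes, exclude = "mixed") {
  rows <- lapply(names(axes), function(nm) {
    a <- axes[[nm]]$a; b <- axes[[nm]]$b
    genes <- intersect(names(a), names(b))
    a <- a[genes]; b <- b[genes]
    keep <- !(a %in% exclude) & !(b %in% exclude) & !is.na(a) & !is.na(b)
    a <- factor(a[keep]); b <- factor(b[keep])
    if (nlevels(a) != 2 || nlevels(b) != 2) {
      warning("contingency test '", nm, "' skipped: degenerate margin")
      return(NULL)
    }
    tab <- table(a, b)
    n <- tab + if (any(tab == 0)) 0.5 else 0
    or <- (n[1, 1] * n[2, 2]) / (n[1, 2] * n[2, 1])
    rr <- (n[1, 1] / (n[1, 1] + n[1, 2])) / (n[2, 1] / (n[2, 1] + n[2, 2]))
    p <- stats::fisher.test(tab)$p.value
    data.frame(test = nm,
               a_levels = paste(levels(a), collapse = "/"),
               b_levels = paste(levels(b), collapse = "/"),
               n11 = tab[1, 1], n12 = tab[1, 2],
               n21 = tab[2, 1], n22 = tab[2, 2],
               odds_ratio = unname(or), relative_risk = unname(rr),
               p = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(test = character(), p = numeric(), FDR = numeric()))
  out <- do.call(rbind, rows)
  out$FDR <- bh_adjust(out$p)
  out
}
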