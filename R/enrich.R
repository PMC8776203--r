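#' Read a gene-set collection from a GMT file
#'
#' GMT dialect: one set per line, tab-separated `name`, `description`,
#' then member gene ids. Members are whitespace-trimmed and de-duplicated.
#'
#' @param path Path to the GMT file.
#' @return Named list of class `gene_set_collection`; each element a
#'   character vector of members, with a `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty GMT file: ", path)
    return(structure(list(), class = "gene_set_collection"))
  }
  sets <- list()
  for (i in seq_along(lines)) {
    f <- trimws(strsplit(lines[[i]], "\t", fixed = TRUE)[[1]])
    if (length(f) < 3)
      stop("malformed GMT line ", i, ": need name, description, >= 1 member")
    nm <- f[1]
    if (nm %in% names(sets)) stop("duplicate set name at line ", i, ": ", nm)
    members <- unique(f[-(1:2)][nzchar(f[-(1:2)])])
    if (length(members) == 0) stop("empty set at line ", i, ": ", nm)
    sets[[nm]] <- structure(members, description = f[2])
  }
  structure(sets, class = "gene_set_collection")
}

#' Write a gene-set collection to a GMT file
#'
#' @param collection Named list of member vectors (descriptions taken from
#'   the `description` attribute, empty if absent).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(nm) {
    desc <- attr(collection[[nm]], "description")
    paste(c(nm, if (is.null(desc)) "" else desc,
            as.character(collection[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Gene-set over-representation of a significant gene list
#'
#' One-sided Fisher (hypergeometric upper tail) per set against the tested
#' universe, keeping only terms whose overlap with the significant list
#' reaches `min_sig` genes, with BH correction across the retained terms.
#'
#' @param significant Character vector of significant gene ids (must be a
#'   subset of `universe`).
#' @param universe All genes tested (the reference).
#' @param collection A `gene_set_collection` (members outside the universe
#'   are ignored).
#' @param min_sig Minimum overlap for a term to be reported (default 5).
#' @param directions Optional named gene -> direction vector
#'   (`up`/`down`/`mixed`) used for the per-term direction call.
#' @return Data frame: `term`, `set_size` (within universe), `overlap`,
#'   `p`, `FDR`, `n_up`, `n_down`, `down_up_ratio`, `direction`.
#' @export
overrepresentation <- function(significant, universe, collection,
                               min_sig = 5, directions = NULL) {
  significant <- unique(significant)
  universe <- unique(universe)
  if (!all(significant %in% universe))
    stop("significant genes missing from the universe")
  N <- length(universe); n <- length(significant)
  rows <- lapply(names(collection), function(term) {
    members <- intersect(collection[[term]], universe)
    K <- length(members)
    hits <- intersect(members, significant)
    x <- length(hits)
    if (x < min_sig) return(NULL)
    p <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
    dcall <- term_direction(if (is.null(directions)) character(0)
                            else directions[hits])
    data.frame(term = term, set_size = K, overlap = x, p = p,
               n_up = dcall$n_up, n_down = dcall$n_down,
               down_up_ratio = dcall$ratio, direction = dcall$direction,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(term = character(), set_size = integer(),
                      overlap = integer(), p = numeric(), FDR = numeric(),
                      n_up = integer(), n_down = integer(),
                      down_up_ratio = numeric(), direction = character()))
  out <- do.call(rbind, rows)
  out$FDR <- bh_adjust(out$p)
  out[order(out$p), c("term", "set_size", "overlap", "p", "FDR",
                      "n_up", "n_down", "down_up_ratio", "direction")]
}

#' Direction call for a set of regulated genes
#'
#' A term is called `down` when the ratio of down- to up-regulated member
#' genes exceeds 2, `up` under the symmetric rule, otherwise `affected`.
#' Mixed-direction genes count in neither numerator nor denominator; a zero
#' denominator with a non-zero numerator counts as an infinite ratio.
#'
#' @param directions Character vector of `up`/`down`/`mixed` labels for the
#'   overlapping genes.
#' @return List: `n_up`, `n_down`, `ratio` (down:up), `direction`.
#' @export
term_direction <- function(directions) {
  n_up <- sum(directions == "up", na.rm = TRUE)
  n_down <- sum(directions == "down", na.rm = TRUE)
  ratio <- if (n_up == 0) {
    if (n_down > 0) Inf else NA_real_
  } else n_down / n_up
  direction <- if (!is.na(ratio) && ratio > 2) "down"
  else if (n_down == 0 && n_up > 0) "up"
  else if (n_down > 0 && n_up / n_down > 2) "up"
  else "affected"
  list(n_up = n_up, n_down = n_down, ratio = ratio, direction = direction)
}
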