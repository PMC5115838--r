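#' Read a signed network from a file
#'
#' Two plain-text encodings are supported.  A *matrix* file holds the N x N
#' sign matrix (entries in `{-1, 0, 1}`, separated by tabs, commas or spaces),
#' with `a[i, j]` = effect of node j (column) on node i (row); an optional
#' header row and/or first column may carry node labels.  An *edge list* file
#' has three columns `source target sign` (tab-, comma- or space-separated)
#' with 1-based indices or labels and sign `-1`/`+1`.  Lines starting with `#`
#' are comments.
#'
#' With `format = "auto"` a file that parses as a valid square sign matrix is
#' taken as one, otherwise the edge-list reader is tried; a 3-node matrix
#' whose rows happen to look like edges should be read with an explicit
#' `format`.
#'
#' @param path file to read.
#' @param format `"auto"`, `"matrix"` or `"edge_list"`.
#' @return A [signed_network()].
#' @examples
#' f <- system.file("extdata", "budding_yeast_cell_cycle.tsv", package = "sibnet")
#' net <- read_network(f)
#' n_edges(net)
#' @seealso [write_network()]
#' @export
read_network <- function(path, format = c("auto", "matrix", "edge_list")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  body <- lines[keep]
  lineno <- which(keep)
  if (!length(body)) stop("no data in ", path)

  if (format == "matrix") return(parse_matrix_lines(body, lineno, path))
  if (format == "edge_list") return(parse_edge_lines(body, lineno, path))
  net <- tryCatch(parse_matrix_lines(body, lineno, path), error = function(e) NULL)
  if (!is.null(net)) return(net)
  parse_edge_lines(body, lineno, path)
}

split_fields <- function(line) {
  strsplit(trimws(line), "[,\t ]+")[[1L]]
}

parse_matrix_lines <- function(body, lineno, path) {
  rows <- lapply(body, split_fields)
  labels <- NULL
  # header row: any non-numeric token
  is_num <- function(x) !is.na(suppressWarnings(as.numeric(x)))
  if (!all(is_num(rows[[1L]]))) {
    labels <- rows[[1L]]
    if (labels[1L] %in% c("", "node", "nodes", "name")) labels <- labels[-1L]
    rows <- rows[-1L]; lineno <- lineno[-1L]
  }
  if (!length(rows)) stop("matrix file ", path, " has a header but no rows")
  row_labels <- NULL
  if (!all(is_num(vapply(rows, `[`, "", 1L)))) {
    row_labels <- vapply(rows, `[`, "", 1L)
    rows <- lapply(rows, `[`, -1L)
  }
  n <- length(rows)
  widths <- lengths(rows)
  if (any(widths != n)) {
    k <- which(widths != n)[1L]
    stop("matrix file ", path, ", line ", lineno[k], ": expected ", n,
         " entries, found ", widths[k])
  }
  a <- matrix(NA_integer_, n, n)
  for (k in seq_len(n)) {
    v <- suppressWarnings(as.integer(rows[[k]]))
    bad <- which(is.na(v) | !(v %in% c(-1L, 0L, 1L)))
    if (length(bad)) {
      stop("matrix file ", path, ", line ", lineno[k], ": invalid entry '",
           rows[[k]][bad[1L]], "' (entries must be -1, 0 or 1)")
    }
    a[k, ] <- v
  }
  if (is.null(labels)) labels <- row_labels
  if (!is.null(labels) && length(labels) != n) {
    stop("matrix file ", path, ": ", length(labels), " labels for ", n, " rows")
  }
  signed_network(a, labels)
}

parse_edge_lines <- function(body, lineno, path) {
  rows <- lapply(body, split_fields)
  widths <- lengths(rows)
  if (any(widths != 3L)) {
    k <- which(widths != 3L)[1L]
    stop("edge-list file ", path, ", line ", lineno[k],
         ": expected 3 fields (source target sign), found ", widths[k])
  }
  src <- vapply(rows, `[`, "", 1L)
  tgt <- vapply(rows, `[`, "", 2L)
  sgn <- suppressWarnings(as.integer(vapply(rows, `[`, "", 3L)))
  bad <- which(is.na(sgn) | !(sgn %in% c(-1L, 1L)))
  if (length(bad)) {
    stop("edge-list file ", path, ", line ", lineno[bad[1L]],
         ": sign must be -1 or +1, found '", rows[[bad[1L]]][3L], "'")
  }
  numeric_ids <- all(grepl("^[0-9]+$", c(src, tgt)))
  if (numeric_ids) {
    si <- as.integer(src); ti <- as.integer(tgt)
    if (any(c(si, ti) < 1L)) {
      k <- which(si < 1L | ti < 1L)[1L]
      stop("edge-list file ", path, ", line ", lineno[k],
           ": node indices are 1-based")
    }
    n <- max(si, ti)
    labels <- NULL
  } else {
    labels <- unique(c(rbind(src, tgt)))   # order of first appearance
    si <- match(src, labels); ti <- match(tgt, labels)
    n <- length(labels)
  }
  a <- matrix(0L, n, n)
  for (k in seq_along(si)) {
    cur <- a[ti[k], si[k]]
    if (cur != 0L && cur != sgn[k]) {
      stop("edge-list file ", path, ", line ", lineno[k],
           ": edge ", src[k], " -> ", tgt[k],
           " conflicts with an earlier opposite-sign entry")
    }
    a[ti[k], si[k]] <- sgn[k]
  }
  signed_network(a, labels)
}

#' Write a signed network to a file
#'
#' @param net a [signed_network()].
#' @param path output file.
#' @param format `"matrix"` (tab-separated sign matrix, with a label header
#'   when the network has labels) or `"edge_list"` (`source target sign`).
#' @param comment optional character vector written as leading `#` lines
#'   (provenance notes and the like).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("matrix", "edge_list"),
                          comment = NULL) {
  stopifnot(inherits(net, "signed_network"))
  format <- match.arg(format)
  out <- character()
  if (!is.null(comment)) out <- paste0("# ", comment)
  if (format == "matrix") {
    if (!is.null(net$labels)) out <- c(out, paste(net$labels, collapse = "\t"))
    out <- c(out, apply(net$a, 1L, paste, collapse = "\t"))
  } else {
    idx <- which(net$a != 0L, arr.ind = TRUE)
    idx <- idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
    name <- function(k) if (is.null(net$labels)) as.character(k) else net$labels[k]
    out <- c(out, vapply(seq_len(nrow(idx)), function(e) {
      paste(name(idx[e, 2L]), name(idx[e, 1L]), net$a[idx[e, 1L], idx[e, 2L]],
            sep = "\t")
    }, ""))
  }
  writeLines(out, path)
  invisible(path)
}

#' Write search results to a file
#'
#' Serialises attractor sets, pre-image sets, basins and ensemble results.
#' Text output is one bitstring per line (for basins, `layer<TAB>bitstring`;
#' for ensembles, a CSV of the per-sample records).  JSON output carries a
#' schema tag, the bitstrings in deterministic (lexicographic) order and the
#' search statistics.  Bitstrings always read node 1 first (leftmost).
#'
#' @param x an `attractor_set`, `preimage_set`, `sibnet_basin` or
#'   `sibnet_ensemble`.
#' @param path output file.
#' @param format `"text"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, format = c("text", "json")) {
  format <- match.arg(format)
  if (inherits(x, "attractor_set")) {
    payload <- list(schema = "sibnet/attractors/1",
                    attractors = x$bitstrings,
                    capped = x$capped,
                    stats = unclass(x$stats))
    txt <- x$bitstrings
  } else if (inherits(x, "preimage_set")) {
    payload <- list(schema = "sibnet/preimages/1",
                    target = x$target,
                    preimages = x$bitstrings,
                    capped = x$capped,
                    stats = unclass(x$stats))
    txt <- x$bitstrings
  } else if (inherits(x, "sibnet_basin")) {
    payload <- list(schema = "sibnet/basin/1",
                    attractor = x$attractor,
                    size = x$size,
                    truncated = x$truncated,
                    layers = x$layers)
    txt <- unlist(lapply(seq_along(x$layers), function(d) {
      paste0(d - 1L, "\t", x$layers[[d]])
    }))
  } else if (inherits(x, "sibnet_ensemble")) {
    payload <- list(schema = "sibnet/ensemble/1",
                    config = unclass(x$config),
                    avS = x$avS, MinS = x$MinS, MaxS = x$MaxS, avT = x$avT,
                    n_capped = x$n_capped,
                    records = x$records)
    if (format == "text") {
      utils::write.csv(x$records, path, row.names = FALSE, quote = FALSE)
      return(invisible(path))
    }
  } else {
    stop("don't know how to serialise an object of class ",
         paste(class(x), collapse = "/"))
  }
  if (format == "json") {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    writeLines(txt, path)
  }
  invisible(path)
}
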