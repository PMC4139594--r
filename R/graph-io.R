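#' Write a gene network to GraphML or SIF
#'
#' Nodes may carry a `role` attribute (`query`/`associated`), edges a `type`
#' (evidence channel) and `weight`. GraphML preserves all attributes; SIF is
#' the three-token line format `source type target` (edges without a `type`
#' attribute are written with the relation `association`).
#'
#' @param network an `igraph` object.
#' @param path output file path.
#' @param format `"graphml"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("graphml", "sif")) {
  stopifnot(inherits(network, "igraph"))
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(network)
    type <- if ("type" %in% igraph::edge_attr_names(network)) {
      igraph::E(network)$type
    } else {
      rep("association", nrow(el))
    }
    lines <- if (nrow(el)) paste(el[, 1], type, el[, 2]) else character()
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a gene network written by [write_network()]
#'
#' @param path input file path.
#' @param format `"graphml"` or `"sif"`.
#' @return an `igraph` object.
#' @export
read_network <- function(path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  if (format == "graphml") {
    return(igraph::read_graph(path, format = "graphml"))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(igraph::make_empty_graph(directed = FALSE))
  }
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  bad <- which(lengths(parts) != 3)
  if (length(bad)) {
    stop("SIF line ", bad[1], " does not have 3 tokens", call. = FALSE)
  }
  df <- data.frame(
    from = vapply(parts, `[[`, character(1), 1),
    to = vapply(parts, `[[`, character(1), 3),
    type = vapply(parts, `[[`, character(1), 2),
    stringsAsFactors = FALSE
  )
  igraph::graph_from_data_frame(df, directed = FALSE)
}
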