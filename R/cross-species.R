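#' Intersect two gene lists (case-insensitive)
#'
#' Symbols are matched case-insensitively; the result keeps the order and
#' display style of `a` and records both parents in its provenance.
#'
#' @param a,b [gene_list()] objects.
#' @param name optional name for the result.
#' @return a [gene_list()].
#' @export
intersect_lists <- function(a, b, name = NULL) {
  stopifnot(inherits(a, "gene_list"), inherits(b, "gene_list"))
  keep <- toupper(a$members) %in% toupper(b$members)
  gene_list(a$members[keep],
            name = name %||% paste0(a$name, "_x_", b$name),
            species = a$species,
            provenance = paste0("intersection of '", a$name, "' and '",
                                b$name, "'"))
}

#' Ortholog table
#'
#' A many-to-many mouse/human symbol pairing. Both sides are canonicalized;
#' duplicate pairs are dropped.
#'
#' @param mouse,human equal-length character vectors of paired symbols.
#' @return data.frame with columns `mouse` and `human`, class
#'   `ortholog_table`.
#' @export
ortholog_table <- function(mouse = character(), human = character()) {
  stopifnot(length(mouse) == length(human))
  df <- data.frame(
    mouse = if (length(mouse)) canonicalize_symbols(mouse, "mouse") else character(),
    human = if (length(human)) canonicalize_symbols(human, "human") else character(),
    stringsAsFactors = FALSE
  )
  df <- unique(df)
  rownames(df) <- NULL
  class(df) <- c("ortholog_table", "data.frame")
  df
}

#' Read/write an ortholog table as TSV (columns `mouse`, `human`)
#'
#' @param path TSV file path.
#' @return [read_ortholog_table()] returns an [ortholog_table()].
#' @export
read_ortholog_table <- function(path) {
  df <- read.delim(path, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  if (!all(c("mouse", "human") %in% names(df))) {
    stop("ortholog table must have columns 'mouse' and 'human'", call. = FALSE)
  }
  ortholog_table(df$mouse, df$human)
}

#' @param table an [ortholog_table()].
#' @rdname read_ortholog_table
#' @export
write_ortholog_table <- function(table, path) {
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Map a gene list across species
#'
#' Each symbol is mapped through the ortholog table; symbols without a table
#' entry fall back to case-restyling (mouse `Cdon` -> human `CDON`), with
#' the fallback count recorded in `attr(, "n_fallback")` and reported via a
#' message. Duplicates after mapping are collapsed.
#'
#' @param list a [gene_list()].
#' @param table an [ortholog_table()] (may be empty).
#' @param direction `"mouse_to_human"` or `"human_to_mouse"`.
#' @return a [gene_list()] in the target species.
#' @export
map_orthologs <- function(list, table = ortholog_table(),
                          direction = c("mouse_to_human", "human_to_mouse")) {
  stopifnot(inherits(list, "gene_list"))
  direction <- match.arg(direction)
  from <- if (direction == "mouse_to_human") "mouse" else "human"
  to <- if (direction == "mouse_to_human") "human" else "mouse"
  mapped <- character(0)
  n_fallback <- 0L
  for (sym in list$members) {
    hits <- table[[to]][toupper(table[[from]]) == toupper(sym)]
    if (length(hits) == 0) {
      hits <- canonicalize_symbols(sym, to)
      n_fallback <- n_fallback + 1L
    }
    mapped <- c(mapped, hits)
  }
  if (n_fallback > 0) {
    message("map_orthologs: ", n_fallback,
            " symbol(s) mapped by case-restyle fallback")
  }
  out <- gene_list(mapped, name = paste0(list$name, "_", to),
                   species = to,
                   provenance = paste0("ortholog mapping (", direction,
                                       ") of '", list$name, "'; ",
                                       n_fallback, " fallback(s)"))
  attr(out, "n_fallback") <- n_fallback
  out
}

#' Pairwise overlap report for a collection of gene lists
#'
#' @param lists named list of [gene_list()] objects (>= 2).
#' @param path optional TSV path for the per-gene membership table.
#' @return list with `counts` (symmetric overlap-count matrix; diagonal =
#'   list sizes) and `membership` (per-gene indicator data.frame).
#' @export
overlap_report <- function(lists, path = NULL) {
  stopifnot(length(lists) >= 2, !is.null(names(lists)))
  nm <- names(lists)
  ups <- lapply(lists, function(l) toupper(l$members))
  k <- length(lists)
  counts <- matrix(0L, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      counts[i, j] <- length(intersect(ups[[i]], ups[[j]]))
    }
  }
  genes <- sort(unique(unlist(ups)))
  membership <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (i in seq_len(k)) membership[[nm[i]]] <- genes %in% ups[[i]]
  if (!is.null(path)) {
    write.table(membership, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(counts = counts, membership = membership)
}
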