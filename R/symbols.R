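#' Canonicalize gene symbols
#'
#' Gene symbols are matched case-insensitively throughout the pipeline
#' (mouse `Cdon` and human `CDON` refer to the same symbol string), but each
#' species has a canonical display style: mouse symbols are written with an
#' initial capital followed by lowercase (`Cdon`), human symbols in full
#' uppercase (`CDON`). Canonicalization is idempotent.
#'
#' @param symbols character vector of gene symbols; no internal whitespace.
#' @param species `"mouse"` or `"human"`.
#' @return character vector of canonical symbols.
#' @examples
#' canonicalize_symbols(c("cdon", "NOTCH1"), "mouse")
#' canonicalize_symbols(c("Cdon", "sox3"), "human")
#' @export
canonicalize_symbols <- function(symbols, species = c("mouse", "human")) {
  species <- match.arg(species)
  symbols <- as.character(symbols)
  symbols <- trimws(symbols)
  if (any(!nzchar(symbols))) {
    stop("empty gene symbol", call. = FALSE)
  }
  if (any(grepl("[[:space:]]", symbols))) {
    bad <- symbols[grepl("[[:space:]]", symbols)][1]
    stop("gene symbol contains whitespace: '", bad, "'", call. = FALSE)
  }
  if (species == "human") {
    toupper(symbols)
  } else {
    paste0(toupper(substr(symbols, 1, 1)), tolower(substr(symbols, 2, nchar(symbols))))
  }
}

#' Construct a gene list
#'
#' An ordered, unique collection of canonicalized gene symbols with a name
#' and free-text provenance. Duplicates (case-insensitive) are collapsed to
#' the first occurrence with a warning.
#'
#' @param members character vector of gene symbols.
#' @param name short token naming the list.
#' @param species `"mouse"` or `"human"`.
#' @param provenance free text describing where the list came from.
#' @return an object of class `gene_list`.
#' @export
gene_list <- function(members, name = "gene_list",
                      species = c("mouse", "human"), provenance = "") {
  species <- match.arg(species)
  members <- if (length(members)) canonicalize_symbols(members, species) else character()
  dup <- duplicated(toupper(members))
  if (any(dup)) {
    warning(sum(dup), " duplicate symbol(s) collapsed in gene list '", name, "'",
            call. = FALSE)
    members <- members[!dup]
  }
  structure(
    list(name = name, members = members, species = species, provenance = provenance),
    class = "gene_list"
  )
}

#' @export
print.gene_list <- function(x, ...) {
  cat("gene_list '", x$name, "' (", x$species, "): ", length(x$members),
      " genes\n", sep = "")
  if (length(x$members)) {
    shown <- utils::head(x$members, 10)
    cat("  ", paste(shown, collapse = ", "),
        if (length(x$members) > 10) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.gene_list <- function(x) length(x$members)

#' @export
as.character.gene_list <- function(x, ...) x$members

#' Write a gene list to a one-symbol-per-line text file
#'
#' The name and provenance are stored in `#`-prefixed header comments so
#' that a round trip preserves them.
#'
#' @param list a [gene_list()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(list, path) {
  stopifnot(inherits(list, "gene_list"))
  header <- c(
    paste0("# name: ", list$name),
    paste0("# species: ", list$species),
    paste0("# provenance: ", list$provenance)
  )
  writeLines(c(header, list$members), path)
  invisible(path)
}

#' Read a gene list written by [write_gene_list()]
#'
#' @param path input file path.
#' @param species species used for canonicalization when the file carries no
#'   `# species:` header.
#' @return a [gene_list()]. An empty file yields an empty list with a warning.
#' @export
read_gene_list <- function(path, species = c("mouse", "human")) {
  species <- match.arg(species)
  lines <- readLines(path, warn = FALSE)
  meta <- list(name = basename(path), species = species, provenance = "")
  hdr <- grep("^#", lines, value = TRUE)
  for (field in c("name", "species", "provenance")) {
    m <- grep(paste0("^#\\s*", field, ":"), hdr, value = TRUE)
    if (length(m)) meta[[field]] <- trimws(sub(paste0("^#\\s*", field, ":"), "", m[1]))
  }
  body <- trimws(lines[!grepl("^#", lines)])
  body <- body[nzchar(body)]
  if (!length(body)) warning("empty gene list file: ", path, call. = FALSE)
  gene_list(body, name = meta$name, species = meta$species,
            provenance = meta$provenance)
}
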