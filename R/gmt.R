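#' Read gene sets from a GMT file
#'
#' GMT: one set per line, tab-separated fields `name`, `description`, then
#' member symbols. Set names must be unique; members are canonicalized for
#' the declared species.
#'
#' @param path GMT file path.
#' @param species species used to canonicalize member symbols.
#' @return named list of character vectors; descriptions kept in
#'   `attr(, "description")`.
#' @export
read_gene_sets <- function(path, species = c("mouse", "human")) {
  species <- match.arg(species)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short)) {
    stop("GMT line ", short[1], " has fewer than 3 fields", call. = FALSE)
  }
  names_ <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(names_)) {
    stop("duplicate gene set name: '", names_[duplicated(names_)][1], "'",
         call. = FALSE)
  }
  desc <- vapply(fields, `[[`, character(1), 2)
  sets <- lapply(fields, function(f) {
    unique(canonicalize_symbols(f[-(1:2)], species))
  })
  names(sets) <- names_
  attr(sets, "description") <- setNames(desc, names_)
  attr(sets, "species") <- species
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors (optionally with a
#'   `description` attribute as produced by [read_gene_sets()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
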