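#' Hypergeometric upper-tail probability for over-representation
#'
#' `P(X >= O)` for `X ~ Hypergeometric(N, C, n)`: drawing `n` query genes
#' from a universe of `N` of which `C` carry the annotation. The standard
#' over-representation convention (tail includes the observed overlap).
#'
#' @param N universe size.
#' @param C annotated genes in the universe.
#' @param n query genes in the universe.
#' @param O observed overlap.
#' @return probability in (0, 1].
#' @export
hypergeom_tail <- function(N, C, n, O) {
  if (any(c(N, C, n, O) < 0) || C > N || n > N || O > min(C, n)) {
    stop("require 0 <= C <= N, 0 <= n <= N, 0 <= O <= min(C, n)",
         call. = FALSE)
  }
  if (O == 0) return(1)
  phyper(O - 1, C, N - C, n, lower.tail = FALSE)
}

#' Gene-set over-representation analysis
#'
#' For each annotation set, counts the annotated genes in the reference
#' universe (`C`), the overlap with the query (`O`), the expected overlap
#' (`E = n * C / N`) and the enrichment ratio (`R = O / E`); scores the
#' upper-tail hypergeometric p-value and applies Benjamini-Hochberg FDR
#' adjustment across all tested sets.
#'
#' The reference universe defaults to all genes carrying at least one
#' annotation in the GMT; alternatively a genome-style universe can be
#' supplied as an explicit reference list or size. The choice is recorded in
#' the output attributes.
#'
#' @param query a [gene_list()] or character vector of query genes.
#' @param sets named list of annotation sets (see [read_gene_sets()]).
#' @param reference optional explicit reference universe (character vector
#'   or [gene_list()]); default = union of all set members.
#' @param fdr significance threshold on the adjusted p-value.
#' @return data.frame with columns `set_name`, `C`, `O`, `E`, `R`, `rawP`,
#'   `adjP`, `significant`, sorted by `adjP` ascending; attributes `N`, `n`
#'   and `universe` record the context.
#' @export
enrich <- function(query, sets, reference = NULL, fdr = 0.05) {
  stopifnot(length(sets) >= 1)
  query <- unique(toupper(as.character(query)))
  if (is.null(reference)) {
    reference <- unique(toupper(unlist(sets)))
    universe_label <- "annotated"
  } else {
    reference <- unique(toupper(as.character(reference)))
    universe_label <- "explicit"
  }
  N <- length(reference)
  q_in <- intersect(query, reference)
  n <- length(q_in)
  if (n < 1) {
    stop("query is disjoint from the reference universe", call. = FALSE)
  }
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(unique(toupper(sets[[nm]])), reference)
    C <- length(members)
    O <- length(intersect(members, q_in))
    E <- n * C / N
    data.frame(
      set_name = nm, C = C, O = O, E = E,
      R = if (E > 0) O / E else NA_real_,
      rawP = hypergeom_tail(N, C, n, O),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$adjP <- bh_fdr(out$rawP)
  out$significant <- out$adjP < fdr
  out <- out[order(out$adjP, out$rawP), ]
  rownames(out) <- NULL
  attr(out, "N") <- N
  attr(out, "n") <- n
  attr(out, "universe") <- universe_label
  out
}
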