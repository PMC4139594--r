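#' Define a two-group contrast over an expression set
#'
#' @param expr an [expr_set()].
#' @param name contrast label.
#' @param group_a target sample ids (e.g. VZ+SVZ samples, or the earliest
#'   stage bin).
#' @param group_b reference sample ids; default = all remaining samples.
#' @return an object of class `contrast`.
#' @export
make_contrast <- function(expr, name, group_a, group_b = NULL) {
  stopifnot(inherits(expr, "expr_set"))
  ids <- expr$samples$sample_id
  group_b <- group_b %||% setdiff(ids, group_a)
  if (!all(group_a %in% ids) || !all(group_b %in% ids)) {
    stop("contrast groups must be sample ids of the expression set",
         call. = FALSE)
  }
  if (length(intersect(group_a, group_b))) {
    stop("contrast groups must be disjoint", call. = FALSE)
  }
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each contrast group needs at least 2 samples", call. = FALSE)
  }
  structure(list(name = name, group_a = group_a, group_b = group_b),
            class = "contrast")
}

#' Zone and stage contrast helpers
#'
#' `zone_contrast()` contrasts samples in the given structures against all
#' others; `stage_contrast()` contrasts the given age/stage bin against all
#' later samples.
#'
#' @param expr an [expr_set()].
#' @param structures target structures (default VZ + SVZ).
#' @return a [make_contrast()] object.
#' @export
zone_contrast <- function(expr, structures = c("VZ", "SVZ")) {
  s <- expr$samples
  make_contrast(expr, paste(paste(structures, collapse = "+"), "vs rest"),
                s$sample_id[s$structure %in% structures])
}

#' @param stage target stage bin label.
#' @rdname zone_contrast
#' @export
stage_contrast <- function(expr, stage) {
  s <- expr$samples
  make_contrast(expr, paste(stage, "vs later"),
                s$sample_id[s$age == stage])
}

#' Linear fold change of a gene between contrast groups
#'
#' `(mean_a + eps) / (mean_b + eps)` on the linear scale.
#'
#' @param expr an [expr_set()].
#' @param contrast a [make_contrast()].
#' @param gene symbol(s), or NULL for all genes.
#' @param eps pseudocount.
#' @return named numeric vector of fold changes.
#' @export
fold_change <- function(expr, contrast, gene = NULL, eps = 1e-9) {
  v <- expr$values
  if (!is.null(gene)) v <- v[gene, , drop = FALSE]
  a <- rowMeans(v[, contrast$group_a, drop = FALSE])
  b <- rowMeans(v[, contrast$group_b, drop = FALSE])
  (a + eps) / (b + eps)
}

# Vectorised two-sided Welch unequal-variance t-test on log2(x + 1).
# Degenerate rows: both groups constant with equal means -> p = 1; constant
# with unequal means -> smallest representable double (count reported via
# attribute).
welch_p_matrix <- function(values, idx_a, idx_b) {
  la <- log2(values[, idx_a, drop = FALSE] + 1)
  lb <- log2(values[, idx_b, drop = FALSE] + 1)
  na <- ncol(la); nb <- ncol(lb)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  va <- rowSums((la - ma)^2) / (na - 1)
  vb <- rowSums((lb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  degen <- se2 == 0
  if (any(degen)) {
    p[degen & ma == mb] <- 1
    p[degen & ma != mb] <- .Machine$double.xmin
  }
  attr(p, "n_degenerate") <- sum(degen)
  p
}

#' Welch's t-test p-value for one gene
#'
#' Two-sided unequal-variance t-test on `log2(value + 1)`; the test used for
#' the differential screens (declared, and recorded in screen output).
#'
#' @param expr an [expr_set()].
#' @param contrast a [make_contrast()].
#' @param gene gene symbol.
#' @return p-value in (0, 1].
#' @export
welch_p <- function(expr, contrast, gene) {
  stopifnot(gene %in% rownames(expr$values))
  ia <- match(contrast$group_a, colnames(expr$values))
  ib <- match(contrast$group_b, colnames(expr$values))
  as.numeric(welch_p_matrix(expr$values[gene, , drop = FALSE], ia, ib))
}

#' Holm-Bonferroni step-down adjustment
#'
#' Step-down family-wise error control: adjusted p-values are the running
#' maxima of `(m - i + 1) * p_(i)` capped at 1; a hypothesis is rejected
#' when its adjusted p-value is below `alpha`.
#'
#' @param pvals numeric vector of raw p-values in `[0, 1]`.
#' @param alpha family-wise significance level.
#' @return list with `adjusted` (same order as input) and `reject` (logical).
#' @export
holm_bonferroni <- function(pvals, alpha = 1e-9) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE) || any(is.na(pvals))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  adjusted <- p.adjust(pvals, method = "holm")
  list(adjusted = adjusted, reject = adjusted < alpha)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param pvals numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values in the original order.
#' @export
bh_fdr <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE) || any(is.na(pvals))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvals, method = "BH")
}

#' Run a differential-expression screen
#'
#' Per-gene linear fold change and Welch p-value for the contrast. The fold
#' filter (`fold >= fold_min`) is applied first; Holm-Bonferroni adjustment
#' is then computed on the p-values of the fold-passing family only (the
#' family size is recorded per row). A gene passes the screen when it passes
#' the fold filter and its Holm-adjusted p-value is below `alpha`.
#'
#' @param expr an [expr_set()].
#' @param contrast a [make_contrast()] (see [zone_contrast()],
#'   [stage_contrast()]).
#' @param config a [pipeline_config()]; `fold_min` and `alpha` are used.
#' @return data.frame with columns `gene`, `fold`, `raw_p`, `adj_p` (NA
#'   outside the fold-passing family), `pass`, `family_size`, sorted by
#'   `adj_p` then descending fold; attribute `test` records the test used.
#' @export
run_screen <- function(expr, contrast, config = pipeline_config()) {
  stopifnot(inherits(expr, "expr_set"), inherits(contrast, "contrast"))
  fold <- fold_change(expr, contrast)
  ia <- match(contrast$group_a, colnames(expr$values))
  ib <- match(contrast$group_b, colnames(expr$values))
  raw_p <- welch_p_matrix(expr$values, ia, ib)
  in_family <- fold >= config$fold_min
  adj_p <- rep(NA_real_, length(fold))
  if (any(in_family)) {
    adj_p[in_family] <- holm_bonferroni(raw_p[in_family], config$alpha)$adjusted
  }
  pass <- in_family & !is.na(adj_p) & adj_p < config$alpha
  out <- data.frame(
    gene = rownames(expr$values),
    fold = as.numeric(fold),
    raw_p = as.numeric(raw_p),
    adj_p = adj_p,
    pass = pass,
    family_size = sum(in_family),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$adj_p, -out$fold, na.last = TRUE), ]
  rownames(out) <- NULL
  attr(out, "test") <- "welch_t_log2"
  attr(out, "contrast") <- contrast$name
  attr(out, "n_degenerate") <- attr(raw_p, "n_degenerate")
  out
}

#' Genes passing a screen, as a gene list
#'
#' @param screen output of [run_screen()].
#' @param name,species,provenance passed to [gene_list()].
#' @return a [gene_list()] of passing genes.
#' @export
screen_hits <- function(screen, name = "screen_hits",
                        species = c("mouse", "human"),
                        provenance = "") {
  species <- match.arg(species)
  gene_list(screen$gene[screen$pass], name = name, species = species,
            provenance = provenance)
}
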