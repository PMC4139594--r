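#' Curated neocortical ventricular-zone gene lists
#'
#' Small curated symbol lists used as defaults and worked examples
#' throughout the package:
#'
#' * `mouse_vz_genes()` — 13 genes with tightly correlated, VZ-restricted
#'   expression in the E15.5 mouse neocortex.
#' * `human_vz_zone_genes()` — the 10 of those whose human orthologs are
#'   strongly enriched in the prenatal human VZ/SVZ (spatial screen).
#' * `human_early_stage_genes()` — the 8 whose human orthologs are elevated
#'   at 8-9 post-conception weeks relative to all later stages (temporal
#'   screen).
#'
#' The intersection of the latter two is the seven-gene mouse/human core
#' (`CELSR1`, `HMGN2`, `NEUROG2`, `NOTCH1`, `SOX3`, `TEAD2`, `TGIF2`).
#'
#' @return character vector of gene symbols in species style.
#' @export
mouse_vz_genes <- function() {
  c("Cdon", "Celsr1", "Dbi", "E2f5", "Eomes", "Hmgn2", "Neurog2",
    "Notch1", "Pcnt", "Sox3", "Ssrp1", "Tead2", "Tgif2")
}

#' @rdname mouse_vz_genes
#' @export
human_vz_zone_genes <- function() {
  c("CDON", "CELSR1", "E2F5", "EOMES", "HMGN2", "NEUROG2", "NOTCH1",
    "SOX3", "TEAD2", "TGIF2")
}

#' @rdname mouse_vz_genes
#' @export
human_early_stage_genes <- function() {
  c("CELSR1", "HMGN2", "NEUROG2", "NOTCH1", "SOX3", "SSRP1", "TEAD2", "TGIF2")
}

#' @rdname mouse_vz_genes
#' @export
human_mouse_core_genes <- function() {
  c("CELSR1", "HMGN2", "NEUROG2", "NOTCH1", "SOX3", "TEAD2", "TGIF2")
}
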