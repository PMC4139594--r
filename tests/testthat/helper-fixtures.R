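# Shared fixtures, all built in code.

# Small mouse atlas for fast tests (same structure as the full default).
small_mouse_atlas <- function(n_genes = 300, sigma = 0.3, seed = 1L, ...) {
  simulate_mouse_atlas(n_genes = n_genes, sigma = sigma, seed = seed, ...)
}

# Synthetic stand-ins for the screen/extension result lists whose published
# versions are not bundled: each list carries the handful of explicitly
# named genes plus synthetic filler symbols, sized to the reported totals.
# Overlap structure by construction: the 407-gene candidate list holds the
# 7-gene mouse/human core, 6 genes shared with the mouse extension tier and
# 46 genes shared with the human extension tier; the human extension tier
# has 4 genes outside the candidate list.
stand_in_lists <- function() {
  core7 <- human_mouse_core_genes()
  ext6 <- c("FZD2", "HIST1H3B", "NDE1", "SOX2", "TEAD1", "YAP1")
  uniq4 <- c("MCM6", "KIF18B", "FEN1", "CCNF")
  shared46 <- sprintf("SYN%03d", 1:46)
  filler407 <- sprintf("SYN%03d", 47:394)  # 407 - 7 - 6 - 46
  human407 <- gene_list(c(core7, ext6, shared46, filler407),
                        name = "human_candidates_synthetic", species = "human",
                        provenance = "synthetic stand-in")
  mouse_assoc50 <- gene_list(c(ext6, sprintf("MAS%03d", 1:44)),
                             name = "mouse_extension_tier_synthetic",
                             species = "human",
                             provenance = "synthetic stand-in")
  human_assoc50 <- gene_list(c(shared46, uniq4),
                             name = "human_extension_tier_synthetic",
                             species = "human",
                             provenance = "synthetic stand-in")
  list(human407 = human407, mouse_assoc50 = mouse_assoc50,
       human_assoc50 = human_assoc50, core7 = core7)
}

# Example over-representation report in the C/O/E/R/rawP/adjP layout of
# WebGestalt-style tools (cell-cycle-dominated pathway panel); used to pin
# the package's reporting conventions against an external tool's.
overrep_example_rows <- function() {
  data.frame(
    set_name = c("Cell cycle, Mitotic", "DNA Replication",
                 "Mitotic M-M/G1 phases", "M Phase", "Mitotic prometaphase",
                 "Mitotic G1-G1/S phases", "ATM pathway", "G1/S Transition",
                 "Polo-like kinase signaling events in the cell cycle",
                 "S Phase"),
    C = c(318, 261, 242, 158, 99, 141, 307, 118, 109, 121),
    O = c(96, 76, 69, 46, 39, 40, 45, 32, 31, 31),
    E = c(2.99, 2.46, 2.28, 1.49, 0.93, 1.33, 2.89, 1.11, 1.03, 1.14),
    R = c(32.07, 30.93, 30.29, 30.93, 41.85, 30.13, 15.57, 28.81, 30.21,
          27.21),
    rawP = c(6.24e-118, 1.89e-91, 3.48e-82, 3.06e-55, 4.88e-53, 1.33e-47,
             1.45e-39, 1.48e-37, 3.85e-37, 1.48e-35),
    adjP = c(2.10e-115, 3.18e-89, 3.91e-80, 2.58e-53, 3.29e-51, 7.47e-46,
             6.98e-38, 6.23e-36, 1.44e-35, 4.99e-34),
    stringsAsFactors = FALSE
  )
}

# Tiny deterministic compendium around a query module (exact wiring).
exact_compendium <- function(query, associated, decoys,
                             evidence = c("coexpression", "physical")) {
  universe <- c(query, associated, decoys)
  simulate_association_compendium(
    universe, query, associated_genes = associated,
    evidence_types = evidence,
    p_within = 1, p_assoc = 1, p_background = 0, seed = 1L
  )
}
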