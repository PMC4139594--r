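#' @section Simulation model:
#' All generators share one noise model. Expression is non-negative and
#' right-skewed, so values are built multiplicatively on the log scale:
#'
#' * a spatial/temporal template gives each planted gene a high level
#'   (`baseline * planted_fold`) in the target samples and `baseline`
#'   elsewhere;
#' * planted genes share a module-level noise component so that their
#'   pairwise log-scale correlation is `module_cor` on top of the template;
#' * decoy genes receive independent per-structure/stage profile effects
#'   drawn log-uniformly within a bounded range, so that in the noise-free
#'   limit (`sigma = 0`) no decoy can reach the six-fold enrichment filter —
#'   planted-set recovery is then exact by construction;
#' * multiplicative log-normal measurement noise with standard deviation
#'   `sigma` (natural-log scale) is applied to every value.
#'
#' @name simulate-model
#' @keywords internal
NULL

# Default anatomical panels. The mouse panel covers the proliferative zones
# (VZ, SVZ), intermediate zone, cortical plate, ganglionic eminence and a
# spread of other structures; ages span embryonic day 11.5 to postnatal day
# 56 in seven stages.
mouse_structures_default <- function() {
  c("VZ", "SVZ", "IZ", "CP", "GE", "MZ", "SP", "HIP", "TH", "HY", "MB", "HB")
}
mouse_ages_default <- function() {
  c("E11.5", "E13.5", "E15.5", "E18.5", "P4", "P14", "P56")
}
human_structures_default <- function(n = 20) {
  base <- c("VZ", "SVZ", "IZ", "CP", "MZ", "SP", "AMY", "THM", "HIP", "STR",
            "CB", "Tg", "OFC", "DFC", "MFC", "ITC", "STC", "A1C", "V1C", "M1C")
  base[seq_len(min(n, length(base)))]
}
human_spatial_ages_default <- function() c("15pcw", "16pcw", "19pcw", "21pcw")
human_temporal_stages_default <- function() {
  c("8-9pcw", "10-12pcw", "13-15pcw", "16-18pcw", "19-24pcw",
    "25-38pcw", "birth-1yr", "1-6yr", "6-20yr", "20-40yr")
}

# Choose which mouse-module genes the human planted set carries over:
# prefer the canonical seven-gene mouse/human core when available so that
# simulated cross-species output reads naturally.
pick_shared_symbols <- function(mouse_planted, overlap) {
  pool <- canonicalize_symbols(mouse_planted, "human")
  core <- intersect(pool, human_mouse_core_genes())
  shared <- c(core, setdiff(pool, core))[seq_len(overlap)]
  shared
}

# Shared machinery: build an expr_set with a planted module over a sample
# layout. `target` is a logical vector over samples marking where the
# planted template is elevated.
simulate_planted_expr <- function(symbols, planted, samples, target,
                                  planted_fold, module_cor, sigma, baseline,
                                  planted_gene_sd, decoy_gene_sd,
                                  decoy_profile_log_range, species, seed) {
  set.seed(seed)
  n_genes <- length(symbols)
  ns <- nrow(samples)
  n_planted <- length(planted)
  if (n_planted >= n_genes) {
    stop("planted module size must be smaller than the gene universe",
         call. = FALSE)
  }
  if (planted_fold <= 1) stop("planted_fold must be > 1", call. = FALSE)
  template <- rep(baseline, ns)
  template[target] <- baseline * planted_fold
  X <- matrix(0, n_genes, ns, dimnames = list(symbols, samples$sample_id))

  # module-shared log-noise: gives planted genes correlation module_cor
  shared <- rnorm(ns)
  p_idx <- match(planted, symbols)
  for (i in p_idx) {
    own <- rnorm(ns)
    b <- rnorm(1, 0, planted_gene_sd)
    X[i, ] <- template *
      exp(b + sigma * (sqrt(module_cor) * shared + sqrt(1 - module_cor) * own))
  }

  # decoys: per-structure/stage profile effects bounded in log range, shared
  # across replicate samples, plus gene baseline and measurement noise
  d_idx <- setdiff(seq_len(n_genes), p_idx)
  profile_key <- paste(samples$structure, samples$age)
  key_levels <- unique(profile_key)
  key_map <- match(profile_key, key_levels)
  L <- decoy_profile_log_range
  for (i in d_idx) {
    eff <- runif(length(key_levels), -L, L)[key_map]
    b <- rnorm(1, 0, decoy_gene_sd)
    X[i, ] <- baseline * exp(b + eff + sigma * rnorm(ns))
  }
  expr_set(X, samples)
}

make_sample_sheet <- function(structures, ages, n_reps, species,
                              zone_structures = character()) {
  grid <- expand.grid(rep = seq_len(n_reps), structure = structures, age = ages,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  data.frame(
    sample_id = paste(grid$age, grid$structure, grid$rep, sep = "_"),
    structure = grid$structure,
    age = grid$age,
    species = species,
    zone = ifelse(grid$structure %in% zone_structures, "target", "other"),
    stringsAsFactors = FALSE
  )
}

#' Simulate a developing-mouse-brain expression atlas with a planted VZ module
#'
#' Emulates a structure-by-age ISH "expression energy" atlas: ~2100 genes
#' over 12 brain structures and 7 developmental stages (E11.5 to P56), with a
#' planted module of ventricular-zone-specific genes that are co-expressed
#' (high in VZ at the target age, baseline elsewhere). The planted module
#' defaults to the 13 canonical mouse VZ network genes so pipeline output is
#' readable; decoys get synthetic `Gm`-style symbols.
#'
#' @param n_genes total genes in the atlas.
#' @param structures,ages anatomical panel; defaults cover the proliferative
#'   zones and seven stages.
#' @param n_reps replicate samples per structure/age.
#' @param planted_symbols symbols of the planted module (mouse style).
#' @param planted_fold linear fold elevation of planted genes in the target
#'   zone at the target age.
#' @param module_cor shared-noise correlation among planted genes (log scale).
#' @param sigma log-normal measurement noise sd (natural-log scale).
#' @param baseline baseline expression level.
#' @param target_structure,target_age where the planted module is elevated.
#' @param planted_gene_sd,decoy_gene_sd per-gene baseline offset sds (log).
#' @param decoy_profile_log_range half-range of the bounded log-uniform decoy
#'   structure/stage effects; the default `log(2)` caps any decoy's
#'   zone-enrichment ratio at 4, below the six-fold filter.
#' @param seed integer seed; output is deterministic given the seed.
#' @return list with elements `expr` (an [expr_set()]) and `truth` (a list
#'   with `planted` as a [gene_list()], the target zone/age, and the fold).
#' @export
simulate_mouse_atlas <- function(n_genes = 2104,
                                 structures = mouse_structures_default(),
                                 ages = mouse_ages_default(),
                                 n_reps = 2,
                                 planted_symbols = mouse_vz_genes(),
                                 planted_fold = 10,
                                 module_cor = 0.9,
                                 sigma = 0.3,
                                 baseline = 5,
                                 target_structure = "VZ",
                                 target_age = "E15.5",
                                 planted_gene_sd = 0.2,
                                 decoy_gene_sd = 0.5,
                                 decoy_profile_log_range = log(2),
                                 seed = 1L) {
  stopifnot(target_structure %in% structures, target_age %in% ages)
  planted <- canonicalize_symbols(planted_symbols, "mouse")
  n_decoys <- n_genes - length(planted)
  if (n_decoys < 1) {
    stop("planted module size must be smaller than n_genes", call. = FALSE)
  }
  symbols <- c(planted, sprintf("Gm%04d", seq_len(n_decoys)))
  samples <- make_sample_sheet(structures, ages, n_reps, "mouse",
                               zone_structures = target_structure)
  target <- samples$structure == target_structure & samples$age == target_age
  expr <- simulate_planted_expr(
    symbols, planted, samples, target, planted_fold, module_cor, sigma,
    baseline, planted_gene_sd, decoy_gene_sd, decoy_profile_log_range,
    "mouse", seed
  )
  truth <- list(
    planted = gene_list(planted, name = "planted_mouse_vz", species = "mouse",
                        provenance = "simulate_mouse_atlas"),
    target_structure = target_structure,
    target_age = target_age,
    planted_fold = planted_fold
  )
  list(expr = expr, truth = truth)
}

#' Simulate a human prenatal structure panel with a planted VZ/SVZ module
#'
#' Emulates a laser-microdissection-style microarray panel of many brain
#' structures sampled at 15-21 post-conception weeks. Planted genes are
#' elevated in the ventricular and subventricular zones at every sampled
#' age. A configurable subset of the planted module consists of the
#' human-styled ortholog images of mouse module genes (so that cross-species
#' intersection has a known answer); the remainder are human-only planted
#' genes.
#'
#' @inheritParams simulate_mouse_atlas
#' @param mouse_planted mouse-module symbols whose ortholog images seed the
#'   human planted set.
#' @param overlap how many mouse module genes to carry over (default 7).
#' @param planted_size total planted genes (default 60, a desk-scale stand-in
#'   for a several-hundred-gene zone signature).
#' @param target_structures structures where the module is elevated.
#' @return list with `expr` and `truth` (planted [gene_list()], shared
#'   mouse-derived symbols, zone, fold).
#' @export
simulate_human_spatial <- function(n_genes = 3000,
                                   structures = human_structures_default(),
                                   ages = human_spatial_ages_default(),
                                   n_reps = 2,
                                   mouse_planted = mouse_vz_genes(),
                                   overlap = 7,
                                   planted_size = 60,
                                   planted_fold = 10,
                                   module_cor = 0.9,
                                   sigma = 0.3,
                                   baseline = 5,
                                   target_structures = c("VZ", "SVZ"),
                                   planted_gene_sd = 0.2,
                                   decoy_gene_sd = 0.5,
                                   decoy_profile_log_range = log(2),
                                   seed = 1L) {
  stopifnot(all(target_structures %in% structures))
  if (overlap > length(mouse_planted)) {
    stop("overlap cannot exceed the mouse planted module size", call. = FALSE)
  }
  if (overlap > planted_size) stop("overlap cannot exceed planted_size", call. = FALSE)
  shared <- pick_shared_symbols(mouse_planted, overlap)
  extra <- sprintf("HVZ%03d", seq_len(planted_size - overlap))
  planted <- c(shared, extra)
  n_decoys <- n_genes - planted_size
  if (n_decoys < 1) stop("planted_size must be smaller than n_genes", call. = FALSE)
  symbols <- c(planted, sprintf("HBG%04d", seq_len(n_decoys)))
  samples <- make_sample_sheet(structures, ages, n_reps, "human",
                               zone_structures = target_structures)
  target <- samples$structure %in% target_structures
  expr <- simulate_planted_expr(
    symbols, planted, samples, target, planted_fold, module_cor, sigma,
    baseline, planted_gene_sd, decoy_gene_sd, decoy_profile_log_range,
    "human", seed
  )
  truth <- list(
    planted = gene_list(planted, name = "planted_human_spatial",
                        species = "human", provenance = "simulate_human_spatial"),
    shared_with_mouse = shared,
    target_structures = target_structures,
    planted_fold = planted_fold
  )
  list(expr = expr, truth = truth)
}

#' Simulate a human developmental time series with an early-elevated module
#'
#' Emulates a developmental transcriptome: whole-tissue samples across
#' stages from 8 post-conception weeks to adulthood, with planted genes
#' elevated only in the earliest stage bin (8-9 pcw) relative to all later
#' stages.
#'
#' @inheritParams simulate_human_spatial
#' @param stages ordered stage bins; the first is the early/target bin.
#' @param n_reps replicate samples per stage bin (Welch testing needs >= 2
#'   per group).
#' @param planted_symbols optional explicit planted symbols (human style);
#'   when `NULL`, `planted_size` genes are constructed as in
#'   [simulate_human_spatial()].
#' @export
simulate_human_temporal <- function(n_genes = 2000,
                                    stages = human_temporal_stages_default(),
                                    n_reps = 16,
                                    mouse_planted = mouse_vz_genes(),
                                    overlap = 7,
                                    planted_size = 80,
                                    planted_symbols = NULL,
                                    planted_fold = 10,
                                    module_cor = 0.9,
                                    sigma = 0.3,
                                    baseline = 5,
                                    planted_gene_sd = 0.2,
                                    decoy_gene_sd = 0.5,
                                    decoy_profile_log_range = log(2),
                                    seed = 1L) {
  if (length(stages) < 2) {
    stop("need at least 2 stage bins for an early-vs-later contrast",
         call. = FALSE)
  }
  if (is.null(planted_symbols)) {
    if (overlap > length(mouse_planted)) {
      stop("overlap cannot exceed the mouse planted module size", call. = FALSE)
    }
    shared <- pick_shared_symbols(mouse_planted, overlap)
    planted <- c(shared, sprintf("HTM%03d", seq_len(planted_size - overlap)))
  } else {
    planted <- canonicalize_symbols(planted_symbols, "human")
  }
  n_decoys <- n_genes - length(planted)
  if (n_decoys < 1) {
    stop("planted module size must be smaller than n_genes", call. = FALSE)
  }
  symbols <- c(planted, sprintf("HTD%04d", seq_len(n_decoys)))
  samples <- make_sample_sheet("brain", stages, n_reps, "human")
  samples$zone <- ifelse(samples$age == stages[1], "target", "other")
  target <- samples$age == stages[1]
  expr <- simulate_planted_expr(
    symbols, planted, samples, target, planted_fold, module_cor, sigma,
    baseline, planted_gene_sd, decoy_gene_sd, decoy_profile_log_range,
    "human", seed
  )
  truth <- list(
    planted = gene_list(planted, name = "planted_human_temporal",
                        species = "human", provenance = "simulate_human_temporal"),
    early_stage = stages[1],
    planted_fold = planted_fold
  )
  list(expr = expr, truth = truth)
}

#' Simulate a multi-evidence association-network compendium
#'
#' Generates one undirected weighted network per evidence channel
#' (co-expression, co-localization, physical interaction, predicted
#' interaction, shared protein domains). Edge probability is elevated within
#' the query module (`p_within`), between query genes and a designated
#' "associated" tier (`p_assoc`), and low elsewhere (`p_background`), so
#' that list extension has a known best answer.
#'
#' @param universe character vector (or [gene_list()]) of all genes.
#' @param query_genes the planted/query module.
#' @param associated_genes the designated associated tier; when `NULL`, the
#'   first `k_assoc` non-query genes.
#' @param k_assoc size of the associated tier.
#' @param evidence_types names of the evidence channels.
#' @param p_within,p_assoc,p_background per-channel edge probabilities.
#' @param weight_range edge weights drawn uniformly from this range.
#' @param seed integer seed.
#' @return named list of `igraph` objects (one per evidence type, each with
#'   an `evidence_type` graph attribute and edge `weight`), with the
#'   associated tier in `attr(, "associated")`.
#' @export
simulate_association_compendium <- function(universe, query_genes,
                                            associated_genes = NULL,
                                            k_assoc = 50,
                                            evidence_types = c("coexpression",
                                                               "colocalization",
                                                               "physical",
                                                               "predicted",
                                                               "shared_domain"),
                                            p_within = 0.6,
                                            p_assoc = 0.35,
                                            p_background = 0.02,
                                            weight_range = c(0.4, 1),
                                            seed = 1L) {
  universe <- as.character(universe)
  query_genes <- as.character(query_genes)
  stopifnot(all(query_genes %in% universe))
  others <- setdiff(universe, query_genes)
  if (is.null(associated_genes)) {
    if (length(others) < k_assoc) {
      stop("too few non-query genes to form an associated tier of ", k_assoc,
           call. = FALSE)
    }
    associated_genes <- others[seq_len(k_assoc)]
  }
  stopifnot(all(associated_genes %in% others))
  set.seed(seed)
  n <- length(universe)
  idx_q <- universe %in% query_genes
  idx_a <- universe %in% associated_genes
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  # per-pair probability by tier
  tier_p <- rep(p_background, nrow(pairs))
  qq <- idx_q[pairs[, 1]] & idx_q[pairs[, 2]]
  qa <- (idx_q[pairs[, 1]] & idx_a[pairs[, 2]]) |
    (idx_a[pairs[, 1]] & idx_q[pairs[, 2]])
  tier_p[qq] <- p_within
  tier_p[qa] <- p_assoc
  nets <- lapply(evidence_types, function(ev) {
    keep <- runif(nrow(pairs)) < tier_p
    df <- data.frame(
      from = universe[pairs[keep, 1]],
      to = universe[pairs[keep, 2]],
      weight = runif(sum(keep), weight_range[1], weight_range[2]),
      type = ev,
      stringsAsFactors = FALSE
    )
    g <- igraph::graph_from_data_frame(
      df, directed = FALSE,
      vertices = data.frame(name = universe, stringsAsFactors = FALSE)
    )
    g <- igraph::set_graph_attr(g, "evidence_type", ev)
    g
  })
  names(nets) <- evidence_types
  attr(nets, "associated") <- associated_genes
  nets
}

#' Simulate flat gene-set annotations (GMT)
#'
#' Emits "enriched" sets that draw a fraction of their members from the
#' planted gene list (capped at the planted list size) and background sets
#' drawn uniformly from the universe. Default enriched-set sizes echo the
#' annotated-set sizes of a typical cell-cycle-dominated pathway compendium.
#'
#' @param universe character vector of all genes.
#' @param planted character vector of planted/query genes (subset of
#'   universe).
#' @param set_sizes sizes of the enriched sets.
#' @param enriched_fraction target fraction of each enriched set drawn from
#'   the planted genes.
#' @param n_background number of background (null) sets.
#' @param background_size_range background set sizes drawn uniformly here.
#' @param seed integer seed.
#' @return named list of sets (GMT-shaped, see [read_gene_sets()]) with the
#'   enriched set names in `attr(, "enriched")`.
#' @export
simulate_annotations <- function(universe, planted,
                                 set_sizes = c(318, 261, 242, 158, 99,
                                               141, 307, 118, 109, 121),
                                 enriched_fraction = 0.3,
                                 n_background = 10,
                                 background_size_range = c(50, 300),
                                 seed = 1L) {
  universe <- as.character(universe)
  planted <- as.character(planted)
  stopifnot(all(planted %in% universe))
  if (any(set_sizes > length(universe))) {
    stop("requested set size exceeds the gene universe", call. = FALSE)
  }
  set.seed(seed)
  non_planted <- setdiff(universe, planted)
  enriched <- lapply(seq_along(set_sizes), function(i) {
    size <- set_sizes[i]
    m <- min(round(enriched_fraction * size), length(planted), size)
    c(sample(planted, m), sample(non_planted, size - m))
  })
  names(enriched) <- sprintf("enriched_set_%02d", seq_along(set_sizes))
  bg_sizes <- sample(seq(background_size_range[1], background_size_range[2]),
                     n_background, replace = TRUE)
  background <- lapply(bg_sizes, function(size) sample(universe, size))
  names(background) <- sprintf("background_set_%02d", seq_len(n_background))
  sets <- c(enriched, background)
  attr(sets, "description") <- setNames(
    c(rep("planted-enriched", length(enriched)),
      rep("background", length(background))),
    names(sets)
  )
  attr(sets, "enriched") <- names(enriched)
  sets
}
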