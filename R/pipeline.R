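#' Simulate a complete set of pipeline inputs
#'
#' Generates coordinated inputs for an end-to-end run: a mouse atlas with
#' the planted VZ module, a human spatial panel and a human temporal series
#' whose planted sets overlap each other (and carry the ortholog images of
#' part of the mouse module), an association compendium over the mouse
#' module plus decoys, flat annotations enriched in the human planted
#' genes, and an empty ortholog table (symbol case-restyling covers the
#' mapping, as recorded by the mapper).
#'
#' @param config a [pipeline_config()]; `seed` drives every generator.
#' @param mouse_n_genes,spatial_n_genes,temporal_n_genes universe sizes.
#' @param sigma shared log-normal noise sd.
#' @param compendium_decoys decoy genes included in the association
#'   compendium alongside the mouse module.
#' @param temporal_shared planted genes shared between the spatial and
#'   temporal human modules (drives the size of their intersection).
#' @return named list of inputs plus a `truth` element.
#' @export
simulate_inputs <- function(config = pipeline_config(),
                            mouse_n_genes = 2104,
                            spatial_n_genes = 3000,
                            temporal_n_genes = 2000,
                            sigma = 0.3,
                            compendium_decoys = 250,
                            temporal_shared = 52) {
  seed <- config$seed
  mouse <- simulate_mouse_atlas(n_genes = mouse_n_genes, sigma = sigma,
                                seed = seed)
  spatial <- simulate_human_spatial(n_genes = spatial_n_genes, sigma = sigma,
                                    seed = seed + 1L)
  sp_planted <- spatial$truth$planted$members
  temporal_planted <- c(
    sp_planted[seq_len(min(temporal_shared, length(sp_planted)))],
    sprintf("HTM%03d", seq_len(28))
  )
  temporal <- simulate_human_temporal(n_genes = temporal_n_genes, sigma = sigma,
                                      planted_symbols = temporal_planted,
                                      seed = seed + 2L)
  mouse_universe <- c(mouse$truth$planted$members,
                      sprintf("Gm%04d", seq_len(compendium_decoys)))
  networks <- simulate_association_compendium(
    universe = mouse_universe,
    query_genes = mouse$truth$planted$members,
    k_assoc = config$k_extend,
    seed = seed + 3L
  )
  annotations <- simulate_annotations(
    universe = rownames(spatial$expr$values),
    planted = sp_planted,
    seed = seed + 4L
  )
  list(
    mouse_atlas = mouse$expr,
    human_spatial = spatial$expr,
    human_temporal = temporal$expr,
    networks = networks,
    annotations = annotations,
    orthologs = ortholog_table(),
    truth = list(mouse = mouse$truth, spatial = spatial$truth,
                 temporal = temporal$truth,
                 associated = attr(networks, "associated"),
                 enriched_sets = attr(annotations, "enriched"))
  )
}

#' Run the full discovery pipeline
#'
#' Executes the stages in order: mouse spatial VZ network; human spatial
#' (zone) and temporal (early-stage) differential screens; intersection of
#' the two human hit lists into the candidate list; ortholog mapping of the
#' mouse network and intersection with the candidates into the cross-species
#' core; extension of the mouse network over the association compendium;
#' gene-set over-representation of the candidate list. Deterministic given
#' the inputs and config.
#'
#' @param inputs as produced by [simulate_inputs()] (or assembled from files
#'   via the reader functions); `truth` is optional and ignored here.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, every intermediate
#'   artifact plus a JSON and text report are written there.
#' @return a list of stage artifacts (class `vznet_run`): `mouse_network`,
#'   `spatial_screen`, `temporal_screen`, `spatial_hits`, `temporal_hits`,
#'   `candidates`, `core`, `extended`, `enrichment`, `report`.
#' @export
run_pipeline <- function(inputs, config = pipeline_config(), out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  mouse_network <- stage("mouse_vz_network", {
    mask <- zone_mask(inputs$mouse_atlas, age = "E15.5",
                      target_structures = "VZ")
    build_vz_network(inputs$mouse_atlas, mask, config)
  })
  mouse_list <- gene_list(mouse_network$nodes, name = "mouse_vz_network",
                          species = "mouse", provenance = "build_vz_network")
  spatial_screen <- stage("human_spatial_screen", {
    run_screen(inputs$human_spatial, zone_contrast(inputs$human_spatial),
               config)
  })
  spatial_hits <- screen_hits(spatial_screen, name = "human_spatial_hits",
                              species = "human", provenance = "zone screen")
  temporal_screen <- stage("human_temporal_screen", {
    first_stage <- inputs$human_temporal$samples$age[1]
    run_screen(inputs$human_temporal,
               stage_contrast(inputs$human_temporal, first_stage), config)
  })
  temporal_hits <- screen_hits(temporal_screen, name = "human_temporal_hits",
                               species = "human", provenance = "stage screen")
  candidates <- stage("candidate_intersection", {
    intersect_lists(spatial_hits, temporal_hits, name = "human_candidates")
  })
  core <- stage("cross_species_core", {
    mapped <- map_orthologs(mouse_list, inputs$orthologs, "mouse_to_human")
    intersect_lists(mapped, candidates, name = "cross_species_core")
  })
  extended <- stage("network_extension", {
    extend_list(inputs$networks, mouse_list, config)
  })
  enrichment <- stage("enrichment", {
    enrich(candidates, inputs$annotations)
  })
  run <- structure(
    list(
      mouse_network = mouse_network,
      mouse_list = mouse_list,
      spatial_screen = spatial_screen,
      temporal_screen = temporal_screen,
      spatial_hits = spatial_hits,
      temporal_hits = temporal_hits,
      candidates = candidates,
      core = core,
      extended = extended,
      enrichment = enrichment,
      config = config
    ),
    class = "vznet_run"
  )
  run$report <- make_report(run)
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' Aggregate a pipeline run into a report
#'
#' Counts and lists only; nothing is recomputed.
#'
#' @param run a `vznet_run` (possibly partial; missing stages are skipped).
#' @return a named list (serializable to JSON).
#' @export
make_report <- function(run) {
  rep <- list()
  if (!is.null(run$config)) rep$config <- unclass(run$config)
  if (!is.null(run$mouse_network)) {
    rep$mouse_network <- list(
      size = length(run$mouse_network$nodes),
      members = run$mouse_network$nodes,
      n_prefilter = run$mouse_network$n_prefilter,
      n_constant_dropped = run$mouse_network$n_constant_dropped
    )
  }
  for (nm in c("spatial_screen", "temporal_screen")) {
    if (!is.null(run[[nm]])) {
      rep[[nm]] <- list(
        n_genes = nrow(run[[nm]]),
        family_size = run[[nm]]$family_size[1],
        n_pass = sum(run[[nm]]$pass),
        test = attr(run[[nm]], "test")
      )
    }
  }
  if (!is.null(run$candidates)) {
    rep$candidates <- list(size = length(run$candidates$members))
  }
  if (!is.null(run$core)) {
    rep$core <- list(size = length(run$core$members),
                     members = run$core$members)
  }
  if (!is.null(run$extended)) {
    rep$extended <- list(
      n_nodes = igraph::vcount(run$extended$graph),
      n_query = length(run$extended$query),
      n_associated = length(run$extended$associated)
    )
  }
  if (!is.null(run$enrichment)) {
    top <- head(run$enrichment, 10)
    rep$enrichment <- list(
      n_sets = nrow(run$enrichment),
      n_significant = sum(run$enrichment$significant),
      top = top[, c("set_name", "C", "O", "E", "R", "rawP", "adjP")]
    )
  }
  rep
}

# Write all artifacts of a run to a directory.
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_network(run$mouse_network$graph, p("mouse_vz_network.graphml"),
                "graphml")
  write_gene_list(run$mouse_list, p("mouse_vz_network.txt"))
  for (nm in c("spatial_screen", "temporal_screen")) {
    write.table(run[[nm]], p(paste0(nm, ".tsv")), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  write_gene_list(run$candidates, p("human_candidates.txt"))
  write_gene_list(run$core, p("cross_species_core.txt"))
  write_network(run$extended$graph, p("extended_network.graphml"), "graphml")
  write.table(run$enrichment, p("enrichment.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_config(run$config, p("config.yaml"))
  jsonlite::write_json(run$report, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(format_report(run$report), p("report.txt"))
  invisible(out_dir)
}

# Human-readable rendering of a report list.
format_report <- function(rep) {
  lines <- c("vznet pipeline report", "=====================")
  if (!is.null(rep$mouse_network)) {
    lines <- c(lines, "",
               paste0("Mouse VZ network: ", rep$mouse_network$size, " genes (",
                      rep$mouse_network$n_prefilter, " prefiltered, ",
                      rep$mouse_network$n_constant_dropped, " constant dropped)"),
               paste0("  ", paste(rep$mouse_network$members, collapse = ", ")))
  }
  for (nm in c("spatial_screen", "temporal_screen")) {
    if (!is.null(rep[[nm]])) {
      lines <- c(lines, paste0(
        nm, ": ", rep[[nm]]$n_pass, " hits (family ", rep[[nm]]$family_size,
        " of ", rep[[nm]]$n_genes, " genes; ", rep[[nm]]$test, ")"))
    }
  }
  if (!is.null(rep$candidates)) {
    lines <- c(lines, paste0("Candidate list (spatial x temporal): ",
                             rep$candidates$size, " genes"))
  }
  if (!is.null(rep$core)) {
    lines <- c(lines, paste0("Cross-species core: ", rep$core$size, " genes (",
                             paste(rep$core$members, collapse = ", "), ")"))
  }
  if (!is.null(rep$extended)) {
    lines <- c(lines, paste0("Extended network: ", rep$extended$n_query,
                             " query + ", rep$extended$n_associated,
                             " associated = ", rep$extended$n_nodes, " nodes"))
  }
  if (!is.null(rep$enrichment)) {
    lines <- c(lines, paste0("Enrichment: ", rep$enrichment$n_significant,
                             " of ", rep$enrichment$n_sets,
                             " sets significant (BH FDR)"))
  }
  lines
}

#' @export
print.vznet_run <- function(x, ...) {
  cat(paste(format_report(x$report), collapse = "\n"), "\n")
  invisible(x)
}
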