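#' Pipeline configuration
#'
#' Assembles the options of a full multi-stage run: either a simulation
#' config or paths to input files, significance thresholds, kernel-test
#' options, and the output directory. Can also be loaded from a YAML file
#' with the same field names via [read_pipeline_config()].
#'
#' @param simulation a [sim_config()], or NULL when `vcf` is given.
#' @param vcf optional path to an input VCF (alternative to simulation).
#' @param annotations optional path to an annotation TSV (simulated when
#'   absent and simulating).
#' @param gene_sets optional path to a GMT file for sub-pathway enrichment;
#'   the enrichment stage is skipped when absent.
#' @param ppi_edges optional path to a PPI edge-list TSV; the subnetwork
#'   stage is skipped when absent.
#' @param alpha_single,alpha_gene,alpha_enrichment nominal significance
#'   thresholds, default 0.05 each (no multiple-testing correction, the
#'   study's stated convention; set `correct = TRUE` for BH-adjusted
#'   gene selection).
#' @param skat a [skat_config()].
#' @param methods kernel-test methods to run per gene.
#' @param stratified run the functional-strata scans.
#' @param correct use BH-adjusted p-values when selecting significant genes.
#' @param out_dir output directory.
#' @param seed master seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = sim_config(),
                            vcf = NULL,
                            annotations = NULL,
                            gene_sets = NULL,
                            ppi_edges = NULL,
                            alpha_single = 0.05,
                            alpha_gene = 0.05,
                            alpha_enrichment = 0.05,
                            skat = skat_config(),
                            methods = c("SKAT", "SKAT-O", "SKAT-C"),
                            stratified = TRUE,
                            correct = FALSE,
                            out_dir = tempfile("centiskat_run_"),
                            seed = 1L) {
  for (a in c(alpha_single, alpha_gene, alpha_enrichment)) {
    if (a <= 0 || a >= 1) {
      stop_config("alpha thresholds must be in (0, 1)", field = "alpha")
    }
  }
  for (p in c(vcf, annotations, gene_sets, ppi_edges)) {
    if (!is.null(p) && !file.exists(p)) {
      stop_config(paste0("input file does not exist: ", p))
    }
  }
  if (is.null(simulation) && is.null(vcf)) {
    stop_config("either `simulation` or `vcf` must be provided")
  }
  structure(
    list(simulation = simulation, vcf = vcf, annotations = annotations,
         gene_sets = gene_sets, ppi_edges = ppi_edges,
         alpha_single = alpha_single, alpha_gene = alpha_gene,
         alpha_enrichment = alpha_enrichment, skat = skat,
         methods = methods, stratified = stratified, correct = correct,
         out_dir = out_dir, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys match [pipeline_config()]
#'   arguments; `simulation` and `skat` sub-sections map onto [sim_config()]
#'   and [skat_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulation)) {
    sim_args <- raw$simulation
    if (!is.null(sim_args$effect_model)) {
      sim_args$effect_model <- as_tibble(
        as.data.frame(do.call(rbind, lapply(sim_args$effect_model,
                                            as.data.frame))))
    }
    raw$simulation <- do.call(sim_config, sim_args)
  }
  if (!is.null(raw$skat)) raw$skat <- do.call(skat_config, raw$skat)
  do.call(pipeline_config, raw)
}

#' Run the full multi-stage association pipeline
#'
#' Stages, in order: (1) simulate or ingest the cohort and annotations and
#' write VCF/TSV snapshots; (2) single-variant Fisher scan; (3) gene-based
#' kernel tests over all variants; (4) functional prioritization (strata +
#' genotyping candidates); (5) stratified kernel tests; (6) sub-pathway
#' enrichment (if gene sets given); (7) seed subnetwork extraction (if a PPI
#' edge list is given, seeded with the significant genes). All tabular
#' outputs are TSV; a JSON manifest records the config, per-file checksums
#' and timestamps. The same config and seed reproduce byte-identical tables.
#'
#' @param config a [pipeline_config()].
#' @return object of class `pipeline_run`: list with `manifest`, `outputs`
#'   (per-stage objects) and `dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  outputs <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "centiskat_stage_error", stage = name)
    })
  }
  emit <- function(obj, fname) {
    path <- file.path(config$out_dir, fname)
    write_results(obj, path)
    files <<- c(files, path)
    path
  }

  # stage 1: cohort + annotations
  cohort <- stage("ingest", {
    if (!is.null(config$vcf)) {
      read_vcf(config$vcf)
    } else {
      sim <- config$simulation
      sim$seed <- config$seed
      simulate_cohort(sim)
    }
  })
  ann <- stage("ingest", {
    if (!is.null(config$annotations)) {
      read_table(config$annotations, "annotations")
    } else {
      simulate_annotations(cohort$variants, seed = config$seed)
    }
  })
  vcf_path <- file.path(config$out_dir, "cohort.vcf")
  write_vcf(cohort$variants, cohort$genotypes, vcf_path,
            phenotype = cohort$phenotype)
  files <- c(files, vcf_path)
  if (!is.null(cohort$truth)) emit(cohort$truth, "truth.tsv")
  emit(ann, "annotations.tsv")
  outputs$cohort <- cohort
  outputs$annotations <- ann

  # stage 2: single-variant scan
  scan <- stage("single_variant", single_variant_scan(cohort))
  emit(scan, "single_variant.tsv")
  outputs$scan <- scan

  # stage 3: gene-based tests, all variants
  genes_all <- stage("gene_based",
                     gene_scan(cohort, cfg = config$skat,
                               methods = config$methods))
  emit(genes_all, "gene_tests_all.tsv")
  outputs$gene_tests <- genes_all

  # stage 4: prioritization
  strata <- stage("prioritize", build_strata(cohort$variants, ann))
  candidates <- stage("prioritize", select_genotyping_candidates(
    scan, cohort$variants, p_cut = config$alpha_single,
    n_cases = sum(cohort$phenotype == 1L),
    n_controls = sum(cohort$phenotype == 0L)))
  emit(strata, "strata.tsv")
  emit(candidates, "genotyping_candidates.tsv")
  outputs$strata <- strata
  outputs$candidates <- candidates

  # stage 5: stratified gene-based tests
  if (isTRUE(config$stratified)) {
    genes_strat <- stage("gene_based_stratified",
                         gene_scan(cohort, strata = strata,
                                   cfg = config$skat,
                                   methods = config$methods))
    emit(genes_strat, "gene_tests_stratified.tsv")
    wide <- genes_strat %>%
      mutate(analysis = paste(.data$method, .data$stratum, sep = "-")) %>%
      select("gene", "analysis", "p") %>%
      tidyr::pivot_wider(names_from = "analysis", values_from = "p")
    emit(wide, "gene_tests_matrix.tsv")
    outputs$gene_tests_stratified <- genes_strat
  }

  # significant genes drive enrichment and the subnetwork seeds
  sel <- as_tibble(outputs$gene_tests)
  if (isTRUE(config$correct)) {
    sel <- sel %>%
      group_by(.data$stratum, .data$method) %>%
      mutate(p = stats::p.adjust(.data$p, "BH")) %>%
      ungroup()
  }
  sig <- significant_genes(sel, alpha = config$alpha_gene)
  outputs$significant_genes <- sig

  # stage 6: enrichment
  if (!is.null(config$gene_sets)) {
    sets <- stage("enrichment", read_table(config$gene_sets, "gene_sets"))
    enr <- stage("enrichment", subpathway_enrichment(
      sig, sets, universe = unique(cohort$variants$gene)))
    emit(enr, "enrichment.tsv")
    outputs$enrichment <- enr
  }

  # stage 7: subnetwork
  if (!is.null(config$ppi_edges) && length(sig) >= 2) {
    g <- stage("subnetwork",
               build_graph(read_table(config$ppi_edges, "edges")))
    net <- stage("subnetwork", extract_subnetwork(g, sig))
    files <- c(files, export_subnetwork(net, config$out_dir))
    outputs$subnetwork <- net
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("centiskat")),
    seed = config$seed,
    thresholds = list(single = config$alpha_single,
                      gene = config$alpha_gene,
                      enrichment = config$alpha_enrichment),
    files = lapply(files, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    }),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  structure(list(manifest = manifest, outputs = outputs,
                 dir = config$out_dir, config = config),
            class = "pipeline_run")
}

#' Human-readable summary of a pipeline run
#'
#' @param run a [run_pipeline()] result.
#' @param alpha threshold used in the per-stage counts.
#' @return character vector of summary lines (also printed).
#' @export
report <- function(run, alpha = run$config$alpha_gene) {
  o <- run$outputs
  lines <- c(
    sprintf("variants tested: %d", nrow(o$scan %||% tibble())),
    sprintf("single-variant hits (p < %.2g): %d", alpha,
            sum(o$scan$p_allelic < alpha, na.rm = TRUE)),
    sprintf("genes significant at alpha = %.2g: %d", alpha,
            length(o$significant_genes)),
    sprintf("genotyping candidates: %d", nrow(o$candidates %||% tibble()))
  )
  if (!is.null(o$strata)) {
    sizes <- vapply(strata_sets(o$strata), length, integer(1))
    lines <- c(lines, sprintf(
      "strata sizes: all=%d coding=%d regulatory=%d combined=%d",
      sizes["all"], sizes["coding"], sizes["regulatory"],
      sizes["combined"]))
  }
  if (!is.null(o$enrichment)) {
    lines <- c(lines, sprintf("sub-pathways enriched (p < %.2g): %d", alpha,
                              sum(o$enrichment$p < alpha)))
  }
  if (!is.null(o$subnetwork)) {
    lines <- c(lines, sprintf(
      "subnetwork: %d nodes, %d edges, cutoff L* = %d",
      length(o$subnetwork$nodes), nrow(o$subnetwork$edges),
      o$subnetwork$cutoff))
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %d output files in %s\n",
              length(x$manifest$files), x$dir))
  invisible(x)
}
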