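#' Run the full synthetic-to-report pipeline
#'
#' Orchestrates generate -> filter -> impact -> burden -> signatures ->
#' enrichment -> clonal -> clinical on synthetic inputs and writes every
#' stage's output plus a JSON manifest (seed, package version, per-stage
#' counts) under `out_dir`. With a fixed seed the manifest is
#' reproducible byte for byte. The function interface is the package's
#' entry point; each stage is equally callable on its own with real data
#' read through the `read_*` functions.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed.
#' @param config A [simulation_config()]; defaults to one derived from
#'   `seed`.
#' @param signatures Reference `signature_matrix`; path to a CSV (read
#'   via [read_signature_matrix()]) or a matrix.
#' @param gene_sets A `gene_set_collection` or path to a GMT file.
#' @param genome_mb Size of the simulated callable-track territory in
#'   megabases.
#' @param callable_fraction Fraction of that territory at depth >= 20.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(out_dir, seed = 1L, config = NULL,
                         signatures = synthetic_signatures(),
                         gene_sets = synthetic_gene_sets(),
                         genome_mb = 10, callable_fraction = 0.8) {
  if (is.character(signatures)) {
    if (!file.exists(signatures)) stop("signature matrix not found: ", signatures)
    signatures <- read_signature_matrix(signatures)
  }
  if (is.character(gene_sets)) {
    if (!file.exists(gene_sets)) stop("gene set file not found: ", gene_sets)
    gene_sets <- read_gmt(gene_sets)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config <- config %||% simulation_config(
    seed = seed, n_snvs = 400, n_indels = 60,
    signature_weights = c(Sig1 = 0.6, Sig3 = 0.4),
    planted_failures_snv = c(tumour_depth = 5, vaf = 5),
    planted_failures_indel = c(interior_support = 3, repeat_adjacency = 2)
  )

  pair <- generate_pair(config, signatures, sample_id = "SIM1")
  write_variants(pair$tumour, file.path(out_dir, "variants_tumour.tsv"))
  write_variants(pair$germline, file.path(out_dir, "variants_germline.tsv"))
  utils::write.table(pair$truth, file.path(out_dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  filt <- filter_variants(pair$tumour)
  write_filter_audit(filt$snv_audit,
                     file.path(out_dir, "audit_snv.tsv"),
                     file.path(out_dir, "audit_snv.json"))
  write_filter_audit(filt$indel_audit,
                     file.path(out_dir, "audit_indel.tsv"),
                     file.path(out_dir, "audit_indel.json"))

  impact <- classify_hfi(filt$kept)
  utils::write.table(impact, file.path(out_dir, "impact.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  track <- generate_depth_track(genome_mb * 1e6, callable_fraction, seed = seed)
  write_depth_track(track, file.path(out_dir, "depth_track.bed"))
  callable <- callable_bases(track)
  burden <- burden_summary(filt$kept, callable)
  utils::write.table(burden, file.path(out_dir, "burden.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  catalog <- build_catalog(filt$kept)
  write_catalog(catalog, file.path(out_dir, "catalog.tsv"))
  fit <- fit_signatures(catalog, signatures)
  write_signature_fit(fit, file.path(out_dir, "signature_fit.json"))

  genes <- hfi_genes(filt$kept)
  enr <- enrich_sample(genes, gene_sets, sample_id = "SIM1")
  utils::write.table(enr, file.path(out_dir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  pat <- simulate_clone_patient(n_clones = 3, seed = seed, patient_id = "SIM1")
  dcl <- cluster_vafs(pat$diagnostic, seed = seed)
  rcl <- cluster_vafs(pat$residual, seed = seed)
  traj <- track_clones(dcl, rcl, patient_id = "SIM1")
  utils::write.table(traj[, names(traj) != "defining_variants"],
                     file.path(out_dir, "clone_trajectories.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(river_table(traj), file.path(out_dir, "river_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  cohort <- generate_cohort(seed = seed)
  write_outcomes(cohort$outcomes, file.path(out_dir, "outcomes.csv"))
  rates <- response_rates(cohort$outcomes)
  jsonlite::write_json(rates, file.path(out_dir, "rates.json"),
                       dataframe = "rows", digits = NA, pretty = TRUE)
  km <- km_dfs(cohort$outcomes)
  utils::write.table(km$table, file.path(out_dir, "km_curve.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ae <- ae_table(cohort$adverse_events, nrow(cohort$outcomes))
  utils::write.table(ae, file.path(out_dir, "adverse_events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  oc <- design_operating_characteristics()
  rdi <- dose_intensity(cohort$outcomes)

  manifest <- list(
    package = "neoexome",
    version = as.character(utils::packageVersion("neoexome")),
    seed = seed,
    stages = list(
      generate = list(n_snvs = config$n_snvs, n_indels = config$n_indels,
                      planted_snv = as.list(config$planted_failures_snv),
                      planted_indel = as.list(config$planted_failures_indel)),
      filter = list(kept = nrow(filt$kept),
                    rejected_snv = length(filt$snv_audit$rejected),
                    rejected_indel = length(filt$indel_audit$rejected)),
      impact = list(n_hfi = sum(impact$hfi)),
      burden = list(callable_mb = callable / 1e6,
                    burden_all = burden$burden_per_mb[burden$mode == "all"]),
      signatures = list(weights = as.list(fit$weights), sse = fit$sse),
      enrichment = list(n_pathways = nrow(enr), n_significant = sum(enr$significant)),
      clonal = list(n_trajectories = nrow(traj),
                    fates = as.list(table(traj$fate))),
      clinical = list(breast_pcr_pct = rate_of(rates, "breast_pcr"),
                      type_i_error = oc$type_i_error, power = oc$power,
                      rdi_ge_085 = rdi$n_at_or_above)
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
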