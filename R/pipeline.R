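# End-to-end orchestration over one species: simulate (or read) inputs,
# then compartmentalize -> enrich -> context -> popgen -> selection,
# writing one TSV per stage plus a JSON run manifest. Every threshold the
# method uses lives in run_config() with the published defaults.

#' Pipeline run configuration
#'
#' Holds every tunable of the pipeline in one flat structure: the flank
#' length (50 kb), call percentiles (90 with 95 fallback), GO test floor
#' (4 genes) and annotation-quality filter (20%), multigene-family
#' threshold (10), subtelomere geometry (terminal 10%, 1000
#' permutations), SV filters (length > 50 bp, TE coverage >= 0.5, 500 bp
#' breakpoint merging) and the posterior cutoff (0.95).
#'
#' @param seed master seed; each stochastic stage derives a fixed-offset
#'   child seed so stages are independently reproducible.
#' @param simulate if TRUE, inputs are generated with the synthetic-data
#'   module; otherwise they are read from `paths`.
#' @param sim a [simulation_config()] (defaults to
#'   `simulation_config(seed = seed)`).
#' @param paths named list of input files (chromosomes, genes, repeats,
#'   go_map, families, variants, posteriors, gc_track) used when
#'   `simulate = FALSE`; missing optional inputs skip their stage.
#' @param species_id species label.
#' @param flank_len,percentile,fallback_percentile,alpha,min_study,min_annotation_fraction
#'   compartmentalization and GO parameters.
#' @param family_size_threshold multigene-family size floor.
#' @param terminal_frac,n_perm subtelomere test geometry.
#' @param sv_min_len,sv_min_te_cov,sv_merge_dist SV filter/merge
#'   parameters.
#' @param posterior_cutoff,min_family selection-summary parameters.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, simulate = TRUE, sim = NULL, paths = list(),
                       species_id = "sim",
                       flank_len = 50000L, percentile = 90,
                       fallback_percentile = 95, alpha = 0.05,
                       min_study = 4, min_annotation_fraction = 0.20,
                       family_size_threshold = 10,
                       terminal_frac = 0.10, n_perm = 1000L,
                       sv_min_len = 50, sv_min_te_cov = 0.5,
                       sv_merge_dist = 500,
                       posterior_cutoff = 0.95, min_family = 10) {
  if (simulate && is.null(sim)) sim <- simulation_config(seed = seed)
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline for one species
#'
#' Executes compartmentalize, enrich, context, popgen and selection in
#' order, skipping stages whose inputs are absent, and writes one TSV per
#' stage plus `manifest.json` under `outdir`. Reruns with the same
#' configuration produce byte-identical outputs.
#'
#' @param config a [run_config()].
#' @param outdir output directory (created if needed).
#' @return the manifest (named list), invisibly; also written as JSON.
#' @export
run_species <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(tool = "tecompart",
                   version = as.character(utils::packageVersion("tecompart")),
                   species_id = config$species_id, seed = config$seed,
                   stages = list())
  note <- function(stage, status, counts = NULL, outputs = NULL) {
    manifest$stages[[stage]] <<- list(status = status, counts = counts,
                                      outputs = outputs)
  }

  # ---- inputs ----
  variants <- NULL; posteriors <- NULL; gc_track <- NULL
  if (config$simulate) {
    sim <- simulate_species(config$sim)
    variants <- simulate_population(sim, config$sim)
    posteriors <- simulate_site_posteriors(sim, config$sim, config$species_id)
    fixture_dir <- file.path(outdir, "inputs")
    write_species_fixtures(sim, fixture_dir, variants, posteriors)
    ann <- sim$ann; repeats <- sim$repeats
    go_map <- sim$go_map; family_map <- sim$family_map
    note("inputs", "simulated",
         counts = list(genes = nrow(ann$genes), repeats = nrow(repeats),
                       variants = nrow(variants), posterior_sites = nrow(posteriors)),
         outputs = "inputs/")
  } else {
    p <- config$paths
    for (req in c("chromosomes", "genes", "repeats"))
      if (is.null(p[[req]]) || !file.exists(p[[req]]))
        stop("required input missing: ", req)
    chroms <- read_chromosomes(p$chromosomes)
    ann <- read_genes(p$genes, chroms)
    repeats <- read_repeats(p$repeats)
    go_map <- if (!is.null(p$go_map) && file.exists(p$go_map))
      read_go_map(p$go_map) else NULL
    family_map <- if (!is.null(p$families) && file.exists(p$families))
      read_family_map(p$families) else NULL
    if (!is.null(p$variants) && file.exists(p$variants))
      variants <- read_variants(p$variants)
    if (!is.null(p$posteriors) && file.exists(p$posteriors))
      posteriors <- read_site_posteriors(p$posteriors)
    if (!is.null(p$gc_track) && file.exists(p$gc_track))
      gc_track <- read_bedgraph(p$gc_track)
    note("inputs", "read", counts = list(genes = nrow(ann$genes),
                                         repeats = nrow(repeats)))
  }

  # ---- compartmentalize ----
  repeats <- resolve_repeat_overlaps(repeats)
  profiles <- flank_profiles(ann, repeats, config$flank_len)
  calls <- call_compartmentalized(profiles, "ALL", config$percentile,
                                  config$species_id)
  prof_path <- write_tsv(profiles, file.path(outdir, "profiles.tsv"))
  calls_df <- data.frame(gene_id = names(calls$densities),
                         density = unname(calls$densities),
                         called = names(calls$densities) %in% calls$called_gene_ids,
                         stringsAsFactors = FALSE)
  calls_path <- write_tsv(calls_df, file.path(outdir, "calls.tsv"))
  note("compartmentalize", "ok",
       counts = list(eligible = nrow(calls_df),
                     called = length(calls$called_gene_ids),
                     cutoff = unname(calls$cutoff_value)),
       outputs = c("profiles.tsv", "calls.tsv"))

  # ---- enrich ----
  if (!is.null(go_map) && nrow(go_map)) {
    enr <- tryCatch(
      go_enrichment_with_fallback(profiles, go_map, "ALL", config$alpha,
                                  config$species_id,
                                  min_study = config$min_study,
                                  min_annotation_fraction = config$min_annotation_fraction),
      error = function(e) e)
    if (inherits(enr, "error")) {
      note("enrich", paste("refused:", conditionMessage(enr)))
    } else {
      enr_path <- write_tsv(enr$records, file.path(outdir, "enrichment.tsv"))
      if (enr$percentile_used != config$percentile) calls <- enr$calls
      mgf <- if (!is.null(family_map) && nrow(family_map))
        multigene_fold(calls, family_map, config$family_size_threshold) else NULL
      note("enrich", "ok",
           counts = list(terms_tested = nrow(enr$records),
                         significant = sum(enr$records$q < config$alpha),
                         percentile_used = enr$percentile_used,
                         multigene_fold = if (is.null(mgf)) NULL else mgf$fold),
           outputs = "enrichment.tsv")
    }
  } else note("enrich", "skipped: no GO map")

  # ---- context ----
  st_seed <- child_seed(config$seed, 3000003L)
  subtel <- subtelomere_scan(ann, calls, terminal_frac = config$terminal_frac,
                             n_perm = config$n_perm, seed = st_seed)
  subtel_path <- write_tsv(subtel, file.path(outdir, "context_subtelomere.tsv"))
  gc_res <- NULL
  if (!is.null(gc_track)) {
    gc_res <- tryCatch(gene_context_comparison(ann, calls, gc_track,
                                               config$flank_len),
                       error = function(e) NULL)
  }
  note("context", "ok",
       counts = list(chromosomes_tested = nrow(subtel),
                     enriched = sum(subtel$direction == "enriched"),
                     depleted = sum(subtel$direction == "depleted"),
                     gc_sign = if (is.null(gc_res)) NULL else gc_res$sign),
       outputs = "context_subtelomere.tsv")

  # ---- popgen ----
  if (!is.null(variants) && nrow(variants)) {
    n_samples <- max(variants$n_samples)
    sv <- variants[variants$vtype %in% c("TE_SV_INS", "TE_SV_DEL"), , drop = FALSE]
    sv <- filter_te_svs(sv, config$sv_min_len, config$sv_min_te_cov)
    keep <- rbind(sv, variants[variants$vtype %in% c("SNV_SYN", "SNV_NONSYN"), ,
                               drop = FALSE])
    flanks <- noncoding_flank_table(ann, config$flank_len)
    assigned <- assign_variants(keep, flanks, ann$cds, calls)
    afs <- afs_by_group(assigned, n_samples)
    spec_rows <- list()
    for (cat in names(afs$spectra)) for (grp in names(afs$spectra[[cat]])) {
      s <- afs$spectra[[cat]][[grp]]
      spec_rows[[paste(cat, grp)]] <- data.frame(
        category = cat, group = grp, bin = as.integer(names(s$bins)),
        count = unname(s$bins), stringsAsFactors = FALSE)
    }
    spectra_path <- write_tsv(do.call(rbind, spec_rows),
                              file.path(outdir, "afs_spectra.tsv"))
    tests_path <- write_tsv(afs$tests, file.path(outdir, "afs_tests.tsv"))
    note("popgen", "ok",
         counts = list(te_svs_kept = nrow(sv), assigned = nrow(assigned)),
         outputs = c("afs_spectra.tsv", "afs_tests.tsv"))
  } else note("popgen", "skipped: no variants")

  # ---- selection ----
  if (!is.null(posteriors) && nrow(posteriors) &&
      !is.null(family_map) && nrow(family_map)) {
    sel <- tryCatch(
      summarize_selection(posteriors, calls, family_map,
                          config$min_family, config$posterior_cutoff),
      error = function(e) e)
    if (inherits(sel, "error")) {
      note("selection", paste("skipped:", conditionMessage(sel)))
    } else {
      sel_path <- write_tsv(sel, file.path(outdir, "selection.tsv"))
      note("selection", "ok",
           counts = list(prop_pos_called = sel$prop_pos[sel$group == "called_families"],
                         prop_pos_other = sel$prop_pos[sel$group == "other_families"]),
           outputs = "selection.tsv")
    }
  } else note("selection", "skipped: no posteriors")

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
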