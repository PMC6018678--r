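#' Validate a pipeline configuration
#'
#' Reads a YAML configuration (or takes a list), fills in the documented
#' defaults, and rejects unknown keys with a closest-match suggestion.
#'
#' @param config Path to a YAML file, a list, or `NULL` (all defaults).
#' @return Named list of resolved settings (class `crispri_config`).
#' @export
validate_config <- function(config = NULL) {
  defaults <- list(
    mode = "genome",
    max_per_gene = NULL,          # resolved by design_params() from mode
    offtarget_threshold = NULL,
    gc_min = 0.30, gc_max = 0.85,
    n_negative_controls = 400,
    min_reads = 20,
    fdr = 0.05,
    n_quasi = 10000,
    max_subset_size = 15,
    seed = 1L,
    out_dir = "crisprikit_run",
    genome_fasta = NULL, annotation_gff = NULL,
    counts_tsv = NULL, library_tsv = NULL,
    selective = "selective_1", control = "control_1",
    # simulation stage
    simulate = TRUE, n_genes = 50, depth = 100,
    n_effect_genes = 5, effect = -6
  )
  user <- list()
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    user <- yaml::read_yaml(config)
    if (is.null(user)) user <- list()
  } else if (is.list(config)) {
    user <- config
  } else if (!is.null(config)) {
    abort("config must be a path, a list, or NULL")
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    hint <- vapply(unknown, function(k) {
      d <- utils::adist(k, names(defaults))
      names(defaults)[which.min(d)]
    }, "")
    abort(paste0("unknown config key(s): ",
                 paste0(unknown, " (did you mean '", hint, "'?)",
                        collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, user, keep.null = TRUE)
  if (!(cfg$gc_min >= 0 && cfg$gc_min < cfg$gc_max && cfg$gc_max <= 1)) {
    abort("invalid config: need 0 <= gc_min < gc_max <= 1")
  }
  if (cfg$fdr <= 0 || cfg$fdr >= 1) abort("invalid config: fdr in (0,1)")
  structure(cfg, class = c("crispri_config", "list"))
}

#' Run the screen workflow end to end
#'
#' With `simulate: true` (the default) the pipeline simulates a genome,
#' designs a library, simulates screen counts with planted effects, and
#' then runs counting statistics, fitness estimation, the quasi-gene null
#' and hit calling, writing TSV artifacts and a JSON run manifest to
#' `out_dir`. With `simulate: false` it starts from `counts_tsv` +
#' `library_tsv`.
#'
#' @param config A [validate_config()] result, or anything it accepts.
#' @return Invisibly, a list with `results` (hit table), `fitness`,
#'   `null`, `manifest` and `out_dir`.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)
  if (isTRUE(cfg$simulate)) {
    sim <- simulate_genome_annotation(cfg$n_genes, seed = seed)
    params <- design_params(
      mode = cfg$mode,
      max_per_gene = cfg$max_per_gene,
      offtarget_threshold = cfg$offtarget_threshold,
      gc_min = cfg$gc_min, gc_max = cfg$gc_max,
      n_negative_controls = cfg$n_negative_controls, seed = seed
    )
    lib <- tidy(design_library(sim$genome, sim$genes, params))
    genes <- unique(lib$gene[!lib$is_nc])
    eff_genes <- head(genes, cfg$n_effect_genes)
    truth <- simulation_truth(
      lib, setNames(rep(cfg$effect, length(eff_genes)), eff_genes),
      seed = seed
    )
    counts <- simulate_screen_counts(truth, depth = cfg$depth, seed = seed)
    utils::write.table(lib, file.path(cfg$out_dir, "library.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth, file.path(cfg$out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    if (is.null(cfg$counts_tsv) || is.null(cfg$library_tsv)) {
      abort("stage 'call' needs counts_tsv and library_tsv when simulate: false")
    }
    lib <- read_library(cfg$library_tsv)
    counts <- as_tibble(utils::read.table(cfg$counts_tsv, sep = "\t",
                                          header = TRUE))
  }
  utils::write.table(counts, file.path(cfg$out_dir, "counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  reps <- intersect(c("control_1", "control_2"), names(counts))
  norm <- normalize_counts(counts)
  if (all(c("control_2", "selective_2") %in% names(norm))) {
    a <- norm[c("sgrna", "control_1", "selective_1")]
    b <- norm[c("sgrna", "control_2", "selective_2")]
    names(b) <- c("sgrna", "control_1", "selective_1")
    norm <- combine_replicates(a, b)
    names(norm) <- c("sgrna", "control", "selective")
  } else {
    norm <- rename(norm, control = all_of(cfg$control),
                   selective = all_of(cfg$selective))
  }
  norm <- filter_low_count(norm, "control", cfg$min_reads)
  nc_names <- lib$name[lib$is_nc]
  fit <- sgrna_fitness(norm, "selective", "control", nc_names)
  fit <- z_scores(fit)
  null <- build_fpr_curves(fit$fitness[fit$is_nc], n_quasi = cfg$n_quasi,
                           max_size = cfg$max_subset_size, seed = seed)
  res <- call_hits(call_genes(fit, lib, null), fdr = cfg$fdr)
  utils::write.table(fit, file.path(cfg$out_dir, "sgrna_fitness.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res, file.path(cfg$out_dir, "gene_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    package = "crisprikit",
    version = as.character(utils::packageVersion("crisprikit")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = unclass(cfg),
    outputs = list(
      counts = "counts.tsv", sgrna_fitness = "sgrna_fitness.tsv",
      gene_results = "gene_results.tsv"
    ),
    n_genes_called = nrow(res),
    n_hits = sum(res$hit)
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(results = res, fitness = fit, null = null,
                 manifest = manifest, out_dir = cfg$out_dir))
}
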