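#' Assemble and validate a pipeline configuration
#'
#' Programmatic equivalent of the YAML config consumed by
#' [read_pipeline_config()]: bundles the inputs of the full workflow
#' (annotate -> filter -> ACV -> efficiencies -> KLD sizing -> reweight ->
#' bursts -> report).
#'
#' @param collection A [structure_collection()] or character vector of PDB
#'   paths.
#' @param reference A [kl_reference()].
#' @param target A [target_distribution()] or TSV path
#'   (see [read_target_distribution()]).
#' @param donor,acceptor [dye_parameters()] for the two dyes.
#' @param bin_width Efficiency histogram bin width (default 0.05).
#' @param grid_spacing ACV grid spacing in Angstrom.
#' @param nbr_radius ACV path-graph neighborhood radius.
#' @param efficiency_mode `"mean_distance"` or `"mean_efficiency"`.
#' @param n_total Weighted selection size (default: filtered N).
#' @param kld_size_step Subset-size grid step for the KLD curve; set to 0 to
#'   skip the KLD stage.
#' @param burst A [burst_config()], or `NULL` to skip burst simulation.
#' @param seed Master seed; stage seeds derive from it deterministically.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(collection, reference, target, donor, acceptor,
                            bin_width = 0.05, grid_spacing = 1.0,
                            nbr_radius = 3L,
                            efficiency_mode = "mean_distance",
                            n_total = NULL, kld_size_step = 10L,
                            burst = NULL, seed = 1L) {
  if (is.character(collection)) collection <- read_collection(collection)
  stopifnot(inherits(collection, "structure_collection"),
            inherits(reference, "kl_reference"))
  if (is.character(target)) target <- read_target_distribution(target)
  stopifnot(inherits(target, "target_distribution"),
            inherits(donor, "dye_parameters"), inherits(acceptor, "dye_parameters"))
  if (!is.null(burst)) stopifnot(inherits(burst, "burst_config"))
  check_bin_count(bin_width)
  structure(
    list(collection = collection, reference = reference, target = target,
         donor = donor, acceptor = acceptor, bin_width = bin_width,
         grid_spacing = grid_spacing, nbr_radius = as.integer(nbr_radius),
         efficiency_mode = efficiency_mode, n_total = n_total,
         kld_size_step = as.integer(kld_size_step), burst = burst,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Schema (paths are resolved relative to the YAML file):
#' \preformatted{
#' collection: [models.pdb]            # one or more multi-model PDBs
#' reference:
#'   model: reference.pdb              # first model is the reference motif
#'   required_pairs: [[1, 8], [2, 7]]
#'   variable_pair: [3, 6]             # optional
#'   region: [1, 2, 3, 6, 7, 8]        # optional (default: paired residues)
#'   ermsd_max: 0.8
#'   chain: A
#' target: smfret.tsv                  # bin_center / probability table
#' donor:    {chain: A, resno: 4, atom: CY, linker_length: 12,
#'            forster_radius: 54, dye_radii: [3.5]}
#' acceptor: {chain: A, resno: 22, atom: CY, linker_length: 12}
#' bin_width: 0.05
#' grid_spacing: 1.0
#' n_total: 100                        # optional
#' kld_size_step: 10
#' bursts: {table: bursts.tsv, gamma: 1.0, direct_excitation: 0.0,
#'          n_bursts: 5000, mode: fast, seed: 11}
#' seed: 1
#' }
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) ifelse(startsWith(p, "/"), p, file.path(base, p))
  need <- function(key) {
    if (is.null(raw[[key]])) stop("config key missing: ", key)
    raw[[key]]
  }
  coll_paths <- rel(unlist(need("collection")))
  missing <- coll_paths[!file.exists(coll_paths)]
  refspec <- need("reference")
  ref_path <- rel(refspec$model)
  if (!file.exists(ref_path)) missing <- c(missing, ref_path)
  target_path <- rel(need("target"))
  if (!file.exists(target_path)) missing <- c(missing, target_path)
  if (length(missing)) {
    stop("config references missing file(s): ", paste(missing, collapse = ", "))
  }
  ref_model <- read_collection(ref_path, model_limit = 1L)$models[[1L]]
  reference <- kl_reference(
    ref_model,
    required_pairs = do.call(rbind, lapply(refspec$required_pairs, as.integer)),
    variable_pair = refspec$variable_pair,
    region = refspec$region,
    ermsd_max = refspec$ermsd_max %||% 0.8,
    chain = refspec$chain %||% "A"
  )
  dye_of <- function(block) {
    dye_parameters(
      attachment = list(chain = block$chain %||% "A", resno = block$resno,
                        atom = block$atom),
      linker_length = block$linker_length %||% 20,
      linker_width = block$linker_width %||% 4.5,
      dye_radii = unlist(block$dye_radii %||% 3.5),
      cv_thickness = block$cv_thickness %||% 6,
      cv_fraction = block$cv_fraction %||% 0,
      forster_radius = block$forster_radius %||% 54,
      quantum_yield = block$quantum_yield %||% 0.46
    )
  }
  burst <- NULL
  if (!is.null(raw$bursts)) {
    b <- raw$bursts
    tab <- if (!is.null(b$table)) rel(b$table) else data.frame(size = 100L, freq = 1)
    burst <- burst_config(tab, gamma = b$gamma %||% 1,
                          direct_excitation = b$direct_excitation %||% 0,
                          n_bursts = b$n_bursts %||% 10000L,
                          exchange_mode = b$mode %||% "fast",
                          seed = b$seed %||% 11L)
  }
  pipeline_config(
    collection = coll_paths, reference = reference, target = target_path,
    donor = dye_of(need("donor")), acceptor = dye_of(need("acceptor")),
    bin_width = raw$bin_width %||% 0.05,
    grid_spacing = raw$grid_spacing %||% 1.0,
    nbr_radius = raw$nbr_radius %||% 3L,
    efficiency_mode = raw$efficiency_mode %||% "mean_distance",
    n_total = raw$n_total, kld_size_step = raw$kld_size_step %||% 10L,
    burst = burst, seed = raw$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full FRET-guided selection pipeline
#'
#' Executes annotation, kissing-loop/eRMSD filtering, ACV-based efficiency
#' prediction, KLD subset sizing, unweighted and target-weighted selection,
#' and photon-burst simulation, writing every stage product into
#' `output_dir`. Deterministic given the config and its seeds.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Run directory (created if needed).
#' @return Invisibly, `output_dir`, with attribute `results`: a list with
#'   elements `annotations`, `filtered`, `records`, `histogram`, `kld_curve`,
#'   `unweighted`, `weighted`, `bursts_unweighted`, `bursts_weighted`,
#'   `summary`.
#' @export
run_pipeline <- function(config, output_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(output_dir, ...)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  coll <- config$collection
  ref <- config$reference

  ann <- stage("annotate", annotate_collection(coll, ref))
  utils::write.table(ann, out("annotation.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  filtered <- stage("filter", filter_collection(coll, ref, annotations = ann))
  utils::write.table(attr(filtered, "audit"), out("filter_audit.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(filtered) == 0L) {
    stop("pipeline stage 'filter' retained no model; see ",
         out("filter_audit.tsv"))
  }

  records <- stage("efficiency", efficiency_records(
    filtered, config$donor, config$acceptor,
    grid_spacing = config$grid_spacing, nbr_radius = config$nbr_radius,
    mode = config$efficiency_mode, seed = config$seed + 1L
  ))
  utils::write.table(records, out("efficiencies.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  hist <- histogram_efficiencies(records, config$bin_width)

  curve <- NULL
  if (config$kld_size_step > 0L && nrow(records) >= 2L * config$kld_size_step) {
    curve <- stage("kld", estimate_min_subset(
      records, bin_width = config$bin_width, size_step = config$kld_size_step,
      seed = config$seed + 2L
    ))
    write_kld_curve(curve, out("kld_curve.tsv"))
  }

  unw <- stage("select", unweighted_selection(hist))
  wgt <- stage("reweight", weighted_selection(
    hist, config$target, n_total = config$n_total, seed = config$seed + 3L
  ))
  utils::write.table(attr(wgt, "quota"), out("quota.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report_contributions(unw), out("contributions_unweighted.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report_contributions(wgt), out("contributions_weighted.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stage("write_selection", {
    write_selection(filtered, unw, out("selection_unweighted.pdb"), records)
    write_selection(filtered, wgt, out("selection_weighted.pdb"), records)
  })

  bu <- bw <- NULL
  if (!is.null(config$burst)) {
    bu <- stage("bursts", simulate_bursts(records, config$burst,
                                          bin_width = config$bin_width))
    cfg_w <- config$burst
    cfg_w$seed <- cfg_w$seed + 1L
    bw <- stage("bursts", simulate_bursts(records, cfg_w, weights = wgt,
                                          bin_width = config$bin_width))
    write_fret_distribution(bu, out("bursts_unweighted.tsv"))
    write_fret_distribution(bw, out("bursts_weighted.tsv"))
  }

  wh <- selection_histogram(wgt, records, config$bin_width)
  summary <- list(
    n_models = length(coll),
    n_filtered = length(filtered),
    n_lost_kl = sum(attr(filtered, "audit")$kl_status != "preserved"),
    n_lost_ermsd = sum(attr(filtered, "audit")$kl_status == "preserved" &
                         !attr(filtered, "audit")$retained),
    eda_mean_unweighted = mean(records$E_DA),
    eda_sd_unweighted = stats::sd(records$E_DA),
    eda_mean_weighted = histogram_mean(wh),
    target_mean = histogram_mean(config$target),
    target_mass_covered = 1 - attr(wgt, "discarded_mass"),
    unique_structures_weighted = attr(report_contributions(wgt), "unique_count"),
    min_subset_size = if (is.null(curve)) NA else min_subset_size(curve),
    burst_mean_unweighted = if (is.null(bu)) NA else bu$mean,
    burst_sd_unweighted = if (is.null(bu)) NA else bu$sd,
    burst_mean_weighted = if (is.null(bw)) NA else bw$mean,
    burst_sd_weighted = if (is.null(bw)) NA else bw$sd
  )
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  res <- list(annotations = ann, filtered = filtered, records = records,
              histogram = hist, kld_curve = curve, unweighted = unw,
              weighted = wgt, bursts_unweighted = bu, bursts_weighted = bw,
              summary = summary)
  structure(invisible(output_dir), results = res)
}
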