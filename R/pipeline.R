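PIPELINE_STAGES <- c("simulate", "scan", "rank", "exclude",
                     "tree", "clock", "rates",
                     "quantify", "hertz", "spearman")

CONFIG_KEYS <- c("stages", "params", "out_dir", "seed", "log_level")

# Counter-based expansion of the global seed into per-stage streams: the
# stream of a stage depends only on (global seed, stage name), so adding or
# removing a stage never perturbs the randomness of the others.
stage_seed <- function(seed, stage) {
  idx <- match(stage, PIPELINE_STAGES)
  if (is.na(idx)) stop("unknown stage: ", stage, call. = FALSE)
  as.integer((as.numeric(seed) + idx * 7919) %% .Machine$integer.max)
}

#' Validate a pipeline run configuration
#'
#' A configuration is a list (or YAML file) with keys `stages` (subset of
#' `simulate`, `scan`, `rank`, `exclude`, `tree`, `clock`, `rates`,
#' `quantify`, `hertz`, `spearman`), optional per-stage `params`, `out_dir`,
#' `seed` and `log_level`. Unknown keys are rejected before anything runs.
#'
#' @param config list or path to a YAML file.
#' @return The validated configuration list.
#' @export
load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop("no such config file: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list", call. = FALSE)
  unknown <- setdiff(names(config), CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(config$stages) || length(config$stages) == 0L)
    stop("config must select at least one stage", call. = FALSE)
  bad <- setdiff(unlist(config$stages), PIPELINE_STAGES)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(config$params)) {
    badp <- setdiff(names(config$params), PIPELINE_STAGES)
    if (length(badp))
      stop("params given for unknown stage(s): ",
           paste(badp, collapse = ", "), call. = FALSE)
  }
  config
}

pipeline_log <- function(level, config, ...) {
  want <- match(if (is.null(config$log_level)) "info" else config$log_level,
                c("quiet", "info", "debug"))
  if (match(level, c("quiet", "info", "debug")) <= want)
    message("[", level, "] ", ...)
  invisible(NULL)
}

#' Run pipeline stages end to end
#'
#' Executes the selected stages in dependency order (simulate before
#' scan/rank/exclude, tree before clock/rates, and so on) against synthetic
#' inputs generated under per-stage seeds, writing every artifact plus a
#' resolved-config copy, a seed record, and a manifest with content hashes
#' to the output directory. Reruns with the same configuration and seed
#' produce identical hashes.
#'
#' @param config list or YAML path accepted by [load_run_config()].
#' @param seed global integer seed (overrides the config's `seed`).
#' @param out_dir output directory (overrides the config's `out_dir`).
#' @return Invisibly, the manifest data frame (`file`, `md5`).
#' @export
run_pipeline <- function(config, seed = NULL, out_dir = NULL) {
  config <- load_run_config(config)
  if (!is.null(seed)) config$seed <- seed
  if (is.null(config$seed)) config$seed <- 1L
  if (!is.null(out_dir)) config$out_dir <- out_dir
  if (is.null(config$out_dir))
    stop("an output directory is required", call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- intersect(PIPELINE_STAGES, unlist(config$stages))
  state <- new.env(parent = emptyenv())
  written <- character()
  emit <- function(name, writer, payload) {
    path <- file.path(config$out_dir, name)
    writer(payload, path)
    written <<- c(written, path)
    path
  }
  for (stage in stages) {
    pipeline_log("info", config, "stage ", stage)
    prm <- config$params[[stage]]
    sseed <- stage_seed(config$seed, stage)
    ok <- tryCatch({
      run_stage(stage, prm, sseed, state, emit)
      TRUE
    }, error = function(e) {
      stop("stage `", stage, "` failed: ", conditionMessage(e),
           "\npartial outputs retained in ", config$out_dir,
           call. = FALSE)
    })
  }
  resolved <- file.path(config$out_dir, "resolved-config.yaml")
  yaml::write_yaml(config[order(names(config))], resolved)
  seedfile <- file.path(config$out_dir, "seed.txt")
  writeLines(as.character(config$seed), seedfile)
  written <- c(written, resolved, seedfile)
  manifest <- data.frame(file = basename(written),
                         md5 = unname(tools::md5sum(written)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  rownames(manifest) <- NULL
  write_tsv_table(manifest, file.path(config$out_dir, "manifest.tsv"))
  invisible(manifest)
}

# One pipeline stage; `state` carries objects between stages, `emit`
# persists artifacts. Parameters not supplied fall back to the generators'
# defaults.
run_stage <- function(stage, prm, sseed, state, emit) {
  get_prm <- function(name, default) {
    if (!is.null(prm[[name]])) prm[[name]] else default
  }
  switch(stage,
    simulate = {
      prot <- gen_proteome(n_planted = get_prm("n_planted", 3L),
                           n_decoys = get_prm("n_decoys", 30L),
                           seed = sseed)
      state$proteome <- prot$sequences
      emit("proteome.fasta", write_fasta, prot$sequences)
      emit("proteome-truth.json", function(x, p)
        jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE), prot$truth)
      expr <- gen_expression(names(prot$sequences),
                             n_datasets = get_prm("n_datasets", 3L),
                             concordance = get_prm("concordance", 1),
                             seed = sseed)
      state$expression <- expr$tables
      for (nm in names(expr$tables))
        emit(paste0("expression-", nm, ".tsv"), write_tsv_table,
             expr$tables[[nm]])
      aln <- evolve_alignment(two_clade_tree(get_prm("root_age_mya", 800)),
                              rate = get_prm("rate", 5e-4),
                              sites = get_prm("sites", 2000L),
                              seed = sseed)
      state$alignment <- aln$alignment
      emit("alignment.fasta", write_fasta, aln$alignment)
      img <- gen_cell_stack(fold = get_prm("fold", 3),
                            noise = get_prm("noise", "poisson"),
                            seed = sseed)
      state$stack <- img
      emit("stack.tif", write_stack_tiff, img$stack)
      fc <- gen_force_curves(noise_sd = get_prm("noise_sd", 0.01),
                             n_curves = get_prm("n_curves", 5L),
                             seed = sseed)
      state$curves <- fc$curves
      sp <- gen_stiffness_phago(seed = sseed)
      state$paired <- sp$table
      emit("stiffness-phago.tsv", write_tsv_table, sp$table)
    },
    scan = {
      if (is.null(state$proteome)) stop("scan needs the simulate stage")
      state$hits <- scan_proteome(state$proteome)
      emit("hits.tsv", write_tsv_table, state$hits)
    },
    rank = {
      if (is.null(state$hits) || is.null(state$expression))
        stop("rank needs scan and simulate")
      state$ranked <- rank_candidates(state$hits, state$expression,
                                      n_top = get_prm("n_top", 25L))
      emit("ranked.tsv", write_tsv_table, state$ranked)
    },
    exclude = {
      if (is.null(state$ranked)) stop("exclude needs rank")
      ann <- get_prm("annotations",
                     data.frame(gene = character(),
                                secreted = logical(),
                                stringsAsFactors = FALSE))
      state$shortlisted <- apply_exclusions(state$ranked, ann)
      emit("shortlist.tsv", write_tsv_table, shortlist(state$shortlisted))
    },
    tree = {
      if (is.null(state$alignment)) stop("tree needs simulate")
      state$tree <- bootstrap_support(state$alignment,
                                      model = get_prm("model", "poisson"),
                                      B = get_prm("bootstrap", 100L),
                                      seed = sseed)
      emit("tree.nwk", write_newick, state$tree)
    },
    clock = {
      if (is.null(state$tree)) stop("clock needs tree")
      truth_tree <- two_clade_tree(get_prm("root_age_mya", 800))
      calib <- calibration_from_tree(truth_tree)
      tips <- truth_tree$tip.label
      rooted <- root_by_outgroup(state$tree, tips[1:4])
      fitted <- fit_clock(rooted, calib,
                          clades = list(A = tips[1:4], B = tips[5:8]))
      state$clock <- fitted
      emit("clock.json", function(x, p)
        jsonlite::write_json(unclass(x), p, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE), fitted)
    },
    rates = {
      if (is.null(state$tree)) stop("rates needs tree")
      truth_tree <- two_clade_tree(get_prm("root_age_mya", 800))
      calib <- calibration_from_tree(truth_tree)
      rooted <- root_by_outgroup(state$tree, truth_tree$tip.label[1:4])
      prof <- rate_profile(rooted, get_prm("focal", "B1"), calib)
      emit("rate-profile.tsv", write_tsv_table, prof)
    },
    quantify = {
      if (is.null(state$stack)) stop("quantify needs simulate")
      nf <- normalized_fluorescence(state$stack$stack,
                                    state$stack$masks$contact,
                                    state$stack$masks$reference,
                                    state$stack$masks$background)
      emit("normalized-fluorescence.tsv", write_tsv_table,
           data.frame(frame = seq_along(nf), nf = nf))
    },
    hertz = {
      if (is.null(state$curves)) stop("hertz needs simulate")
      fits <- lapply(state$curves, fit_hertz)
      emit("hertz-fits.tsv", write_tsv_table,
           data.frame(curve = seq_along(fits),
                      E_pa = vapply(fits, `[[`, numeric(1), "E"),
                      delta0_m = vapply(fits, `[[`, numeric(1), "delta0"),
                      rms_n = vapply(fits, `[[`, numeric(1), "rms")))
    },
    spearman = {
      if (is.null(state$paired)) stop("spearman needs simulate")
      res <- spearman_exact(state$paired$stiffness_gpa,
                            state$paired$efficiency)
      emit("spearman.json", function(x, p)
        jsonlite::write_json(list(r = x$r, p_one_sided = x$p_one_sided,
                                  p_two_sided = x$p_two_sided, n = x$n,
                                  method = x$method),
                             p, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE), res)
    },
    stop("unknown stage: ", stage))
  invisible(NULL)
}
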