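# ---------------------------------------------------------------------------
# Reproducible pipeline orchestration + CLI
# ---------------------------------------------------------------------------

#' Build a run configuration
#'
#' Every parameter has a default except the input paths and the seed.
#' Configurations round-trip through YAML unchanged via [read_config()] /
#' [write_config()].
#'
#' @param molecules path to the series SDF.
#' @param activities path to the activity CSV.
#' @param seed integer seed for all randomized stages.
#' @param template_atoms integer indices of the shared scaffold atoms used
#'   for alignment (the first molecule is the reference); `NULL` skips
#'   alignment (series supplied pre-aligned).
#' @param library optional path to a library SDF to screen.
#' @param split_file optional explicit split CSV (`compound_id,set`);
#'   overrides sphere exclusion (reproduction mode).
#' @param output_dir artifact directory.
#' @param spacing,margin grid parameters, Angstrom.
#' @param probe_rmin,probe_epsilon,probe_charge probe parameters.
#' @param dielectric,d0 electrostatic dielectric model.
#' @param steric_cutoff,elec_cutoff field truncation bounds, kcal/mol.
#' @param invariable_tol column-range threshold for [drop_invariable()].
#' @param test_fraction sphere-exclusion target test fraction.
#' @param f_enter,max_terms stepwise parameters (`max_terms = NULL` means
#'   the `floor(n/4)` default).
#' @param n_permutations Y-randomization permutation count.
#' @param min_activity,extrapolation_bounds screening hit filters.
#' @return named list of class `run_config`.
#' @export
run_config <- function(molecules = NULL, activities = NULL, seed = NULL,
                       template_atoms = NULL, library = NULL,
                       split_file = NULL, output_dir = "qsar_run",
                       spacing = 2, margin = 4,
                       probe_rmin = 1.70, probe_epsilon = 0.107,
                       probe_charge = 1.0,
                       dielectric = "constant", d0 = 1,
                       steric_cutoff = 30, elec_cutoff = 30,
                       invariable_tol = 1e-8,
                       test_fraction = 11 / 38,
                       f_enter = 4, max_terms = NULL,
                       n_permutations = 100,
                       min_activity = 8,
                       extrapolation_bounds = c(-1, 1)) {
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration (YAML)
#'
#' @param path YAML file.
#' @param config a `run_config`.
#' @return a `run_config` for read; `path` invisibly for write.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), names(formals(run_config)))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(Filter(Negate(is.null), unclass(config)), path)
  invisible(path)
}

log_info <- function(...) {
  message(format(Sys.time(), "[%H:%M:%S] "), ...)
}

#' Run the full 3D-QSAR pipeline
#'
#' Executes align -> fields -> assemble -> drop_invariable -> split ->
#' stepwise -> validate -> (optional) screen and writes every artifact to
#' `config$output_dir`: `descriptors.csv` (+ grid sidecar), `split.csv`,
#' `model.json`, `randomization.json`, `fitness.csv`, optionally
#' `hits.csv`, and a `manifest.json` stamped with the config hash and seed.
#' Stage progress, descriptor counts before/after filtering and split sizes
#' are logged to stderr.
#'
#' @param config a `run_config` (paths and seed must be set).
#' @return invisibly, a list with the in-memory artifacts (`model`,
#'   `split`, `report`, `fitness`, `hits`, `manifest`).
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (req in c("molecules", "activities", "seed"))
    if (is.null(config[[req]])) stop("config lacks required field: ", req)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  probe <- probe_spec(config$probe_rmin, config$probe_epsilon,
                      config$probe_charge)

  run_stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    log_info(sprintf("stage %-10s done (%.2fs)", name,
                     as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  mols <- run_stage("read", read_sdf(config$molecules))
  acts <- run_stage("read", read_activities(config$activities))

  if (!is.null(config$template_atoms)) {
    mols <- run_stage("align", {
      tmap <- template_map(as.integer(config$template_atoms))
      ref <- mols[[1]]
      lapply(mols, align_to_template, reference = ref, map = tmap)
    })
  }

  M <- run_stage("fields", {
    grid <- build_grid(mols, spacing = config$spacing,
                       margin = config$margin)
    assemble_descriptors(mols, grid, probe,
                         dielectric = config$dielectric, d0 = config$d0,
                         steric_cutoff = config$steric_cutoff,
                         elec_cutoff = config$elec_cutoff,
                         # a NULL template declares the series pre-aligned
                         check_alignment = !is.null(config$template_atoms))
  })
  log_info("descriptors before filtering: ", ncol(M))
  M <- run_stage("filter", drop_invariable(M, tol = config$invariable_tol))
  log_info("descriptors after filtering: ", ncol(M))
  write_descriptors(M, file.path(config$output_dir, "descriptors.csv"))

  split <- run_stage("split", {
    if (!is.null(config$split_file)) {
      read_split(config$split_file)
    } else {
      find_radius(M, acts, target_test_fraction = config$test_fraction)
    }
  })
  log_info("split sizes: (", length(split$training_ids), ", ",
           length(split$test_ids), ")")
  write_split(split, file.path(config$output_dir, "split.csv"))

  y <- acts$pIC50[match(rownames(M), acts$compound_id)]
  names(y) <- rownames(M)
  tr <- match(split$training_ids, rownames(M))
  te <- match(split$test_ids, rownames(M))
  if (anyNA(tr) || anyNA(te)) stop("split ids absent from descriptor matrix")

  model <- run_stage("train", {
    m <- stepwise_forward(M[tr, , drop = FALSE], y[tr],
                          f_enter = config$f_enter,
                          max_terms = config$max_terms,
                          grid_hash = attr(M, "grid_hash"))
    if (length(te) && m$k > 0) {
      pr <- pred_r2(m, M[te, , drop = FALSE], y[te])
      m$stats$pred_r2 <- pr$pred_r2
      m$stats$pred_r2_se <- pr$pred_r2_se
    }
    m
  })
  write_model_json(model, file.path(config$output_dir, "model.json"))

  report <- run_stage("validate", {
    y_randomization(M, y, split, f_enter = config$f_enter,
                    max_terms = config$max_terms,
                    n_permutations = config$n_permutations,
                    seed = config$seed)
  })
  write_randomization_json(report,
                           file.path(config$output_dir,
                                     "randomization.json"))
  fitness <- fitness_data(model, M, y, split)
  utils::write.csv(fitness, file.path(config$output_dir, "fitness.csv"),
                   row.names = FALSE)

  hits <- NULL
  if (!is.null(config$library)) {
    hits <- run_stage("screen", {
      lib <- read_sdf(config$library)
      if (!is.null(config$template_atoms)) {
        tmap <- template_map(as.integer(config$template_atoms))
        lib <- lapply(lib, align_to_template, reference = mols[[1]],
                      map = tmap)
      }
      Ml <- assemble_descriptors(lib, attr(M, "grid"), probe,
                                 dielectric = config$dielectric,
                                 d0 = config$d0,
                                 steric_cutoff = config$steric_cutoff,
                                 elec_cutoff = config$elec_cutoff,
                                 check_alignment = FALSE)
      res <- screen_library(model, Ml)
      filter_hits(res, config$min_activity, config$extrapolation_bounds)
    })
    utils::write.csv(hits, file.path(config$output_dir, "hits.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    config_hash = digest::digest(Filter(Negate(is.null), unclass(config))),
    seed = config$seed,
    n_compounds = length(mols),
    descriptors_total = 2L * n_grid_points(attr(M, "grid")),
    descriptors_kept = ncol(M),
    n_train = length(split$training_ids),
    n_test = length(split$test_ids),
    selected = model$selected,
    stats = model$stats,
    grid_hash = attr(M, "grid_hash"))
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(model = model, split = split, report = report,
                 fitness = fitness, hits = hits, manifest = manifest,
                 matrix = M))
}

# ---------------------------------------------------------------------------
# Command-line entry point
# ---------------------------------------------------------------------------

#' Command-line interface
#'
#' Subcommands: `simulate` (write a synthetic series + activities),
#' `run-all` (full pipeline from a YAML config), and the single-stage
#' commands `fields`, `split`, `train`, `validate`, `screen`, each of which
#' re-runs just its stage from the config and the artifacts a previous run
#' left in the output directory. CLI flags override config values. Invoke
#' from a shell as
#' `Rscript -e 'gridqsar::qsar_cli()' <subcommand> --config cfg.yaml ...`
#' or through the installed `exec/gridqsar` script.
#'
#' @param args character vector of arguments (defaults to the command
#'   line).
#' @return exit status 0 invisibly; errors abort with a message.
#' @export
qsar_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: gridqsar <simulate|fields|split|train|validate|screen|run-all>",
    "[--config cfg.yaml] [--seed N] [--out DIR] [--n N]")
  if (!length(args)) stop(usage, call. = FALSE)
  cmd <- args[1]
  opts <- optparse::parse_args(
    optparse::OptionParser(option_list = list(
      optparse::make_option("--config", type = "character", default = NULL),
      optparse::make_option("--seed", type = "integer", default = NULL),
      optparse::make_option("--out", type = "character", default = NULL),
      optparse::make_option("--n", type = "integer", default = 38L))),
    args = args[-1])

  if (cmd == "simulate") {
    if (is.null(opts$seed)) stop("simulate requires --seed")
    out <- opts$out %||% "qsar_run"
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    ser <- make_series(opts$n, seed = opts$seed)
    ds <- make_planted_dataset(
      n_compounds = opts$n, n_descriptors = 200,
      k_informative = max(1L, min(6L, opts$n - 3L)), seed = opts$seed)
    write_sdf(ser$molecules, file.path(out, "molecules.sdf"))
    utils::write.csv(ds$activities, file.path(out, "activities.csv"),
                     row.names = FALSE)
    log_info("wrote ", opts$n, " molecules and activities to ", out)
    return(invisible(0L))
  }

  if (is.null(opts$config)) stop(cmd, " requires --config", call. = FALSE)
  cfg <- read_config(opts$config)
  if (!is.null(opts$seed)) cfg$seed <- opts$seed
  if (!is.null(opts$out)) cfg$output_dir <- opts$out

  if (cmd == "run-all") {
    run_full(cfg)
    return(invisible(0L))
  }

  # single-stage commands work from on-disk artifacts
  art <- function(f) file.path(cfg$output_dir, f)
  probe <- probe_spec(cfg$probe_rmin, cfg$probe_epsilon, cfg$probe_charge)
  if (cmd == "fields") {
    mols <- read_sdf(cfg$molecules)
    if (!is.null(cfg$template_atoms)) {
      tmap <- template_map(as.integer(cfg$template_atoms))
      mols <- lapply(mols, align_to_template, reference = mols[[1]],
                     map = tmap)
    }
    grid <- build_grid(mols, cfg$spacing, cfg$margin)
    M <- assemble_descriptors(mols, grid, probe, cfg$dielectric, cfg$d0,
                              cfg$steric_cutoff, cfg$elec_cutoff,
                              check_alignment = FALSE)
    M <- drop_invariable(M, cfg$invariable_tol)
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_descriptors(M, art("descriptors.csv"))
  } else if (cmd == "split") {
    M <- read_descriptors(art("descriptors.csv"))
    acts <- read_activities(cfg$activities)
    sp <- if (!is.null(cfg$split_file)) read_split(cfg$split_file)
          else find_radius(M, acts, cfg$test_fraction)
    write_split(sp, art("split.csv"))
  } else if (cmd == "train") {
    M <- read_descriptors(art("descriptors.csv"))
    acts <- read_activities(cfg$activities)
    sp <- read_split(art("split.csv"))
    y <- acts$pIC50[match(rownames(M), acts$compound_id)]
    tr <- match(sp$training_ids, rownames(M))
    te <- match(sp$test_ids, rownames(M))
    m <- stepwise_forward(M[tr, , drop = FALSE], y[tr], cfg$f_enter,
                          cfg$max_terms, grid_hash = attr(M, "grid_hash"))
    if (length(te) && m$k > 0) {
      pr <- pred_r2(m, M[te, , drop = FALSE], y[te])
      m$stats$pred_r2 <- pr$pred_r2
      m$stats$pred_r2_se <- pr$pred_r2_se
    }
    write_model_json(m, art("model.json"))
  } else if (cmd == "validate") {
    M <- read_descriptors(art("descriptors.csv"))
    acts <- read_activities(cfg$activities)
    sp <- read_split(art("split.csv"))
    y <- acts$pIC50[match(rownames(M), acts$compound_id)]
    names(y) <- rownames(M)
    rep <- y_randomization(M, y, sp, cfg$f_enter, cfg$max_terms,
                           cfg$n_permutations, seed = cfg$seed)
    write_randomization_json(rep, art("randomization.json"))
    model <- read_model_json(art("model.json"))
    utils::write.csv(fitness_data(model, M, y, sp), art("fitness.csv"),
                     row.names = FALSE)
  } else if (cmd == "screen") {
    if (is.null(cfg$library)) stop("config lacks a library path")
    model <- read_model_json(art("model.json"))
    M <- read_descriptors(art("descriptors.csv"))
    lib <- read_sdf(cfg$library)
    Ml <- assemble_descriptors(lib, attr(M, "grid"), probe,
                               cfg$dielectric, cfg$d0, cfg$steric_cutoff,
                               cfg$elec_cutoff, check_alignment = FALSE)
    res <- filter_hits(screen_library(model, Ml), cfg$min_activity,
                       cfg$extrapolation_bounds)
    utils::write.csv(res, art("hits.csv"), row.names = FALSE)
  } else {
    stop(usage, call. = FALSE)
  }
  invisible(0L)
}
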