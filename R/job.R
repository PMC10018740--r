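# Configuration-driven jobs: YAML config validation, the run_job()
# dispatcher behind the command-line script, and provenance capture.

.config_schema <- list(
  mode = "character",            # scf | hcc | ensemble | synth
  geometry = "character",        # path to XYZ/PDB
  format = "character",
  charge = "numeric", multiplicity = "numeric",
  basis = "character",           # single label or per-atom list
  functional = "character",
  c_x = "numeric", grid_level = "numeric",
  active_atoms = "numeric",      # 1-based atom indices
  n_active = "numeric", scheme = "character",
  tau = "numeric", lindep_tol = "numeric", virtual = "character",
  scf = "list",                  # max_iter, conv_grad, conv_energy
  embedding = "list",            # type: none|fixed|fq, params/preset, file
  hcc_nuclei = "numeric",
  pipeline = "list",             # droplet_radius, qm_radius, measure, oop_atoms
  synth = "list",                # n_frames, n_waters, box_radius, oop_sd
  seed = "numeric",
  output_dir = "character"
)

#' Read and validate a job configuration
#'
#' Configs are YAML with 1-based atom indices. Unknown keys are rejected;
#' required keys depend on the mode (`scf`, `hcc`, `ensemble`, `synth`).
#'
#' @param path YAML file path, or a list already in memory.
#' @return Validated config list of class `job_config`.
#' @export
read_job_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(.config_schema))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(cfg$mode) || !cfg$mode %in% c("scf", "hcc", "ensemble", "synth")) {
    stop("config needs mode: one of scf, hcc, ensemble, synth")
  }
  for (k in names(cfg)) {
    want <- .config_schema[[k]]
    ok <- switch(want,
                 character = is.character(cfg[[k]]),
                 numeric = is.numeric(cfg[[k]]),
                 list = is.list(cfg[[k]]))
    if (!ok) stop("config key '", k, "' must be ", want)
  }
  if (cfg$mode %in% c("scf", "hcc") && is.null(cfg$geometry)) {
    stop("mode '", cfg$mode, "' requires a geometry path")
  }
  if (cfg$mode %in% c("ensemble", "synth") && is.null(cfg$seed)) {
    stop("mode '", cfg$mode, "' requires a seed")
  }
  structure(cfg, class = "job_config")
}

config_functional <- function(cfg) {
  fun <- functional_spec(cfg$functional %||% "uhf",
                         grid_level = as.integer(cfg$grid_level %||% 3L))
  if (!is.null(cfg$c_x)) fun$c_x <- cfg$c_x
  fun
}

config_embedding <- function(cfg, positions = NULL, elements = NULL,
                             fragment = NULL) {
  e <- cfg$embedding
  if (is.null(e) || identical(e$type, "none")) return(NULL)
  if (!is.null(e$file)) {
    tab <- read.csv(e$file, comment.char = "#", stringsAsFactors = FALSE)
    positions <- as.matrix(tab[, c("x", "y", "z")])
    elements <- tab$element
    fragment <- tab$fragment
  }
  if (identical(e$type, "fq")) {
    fq_layer(positions, elements, fragment,
             params = e$params %||% "water-radical")
  } else if (identical(e$type, "fixed")) {
    fixed_charge_layer(positions, elements = elements,
                       preset = e$preset %||% "tip3p-charges",
                       fragment = fragment)
  } else stop("embedding type must be none, fixed or fq")
}

#' Run a configured job
#'
#' Dispatches on the config `mode`: a single-point multilevel SCF
#' (`"scf"`), SCF plus hyperfine couplings (`"hcc"`), the snapshot ensemble
#' pipeline over a multi-frame geometry (`"ensemble"`), or synthetic
#' snapshot generation (`"synth"`). Results land in the output directory as
#' `results.json`, `ledger.csv` (ensemble mode), a checkpoint, and a log
#' that records the package version, the md5 of the effective config, and
#' all tolerances.
#'
#' @param config path to a YAML config or a config list.
#' @param output_dir overrides the config's output directory.
#' @return Invisibly, the results list; called for its side effects.
#' @export
run_job <- function(config, output_dir = NULL) {
  cfg <- read_job_config(config)
  out <- output_dir %||% cfg$output_dir %||% "."
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "run.log")
  logline <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    cat(msg, "\n", file = log_path, append = TRUE)
    message(msg)
  }
  cfg_hash <- object_hash(unclass(cfg))
  logline("mlscf %s | config md5 %s",
          as.character(utils::packageVersion("mlscf")), cfg_hash)
  scf_opts <- cfg$scf %||% list()
  tau <- cfg$tau %||% 1e-2; lindep <- cfg$lindep_tol %||% 1e-8
  logline("tolerances: tau=%g lindep_tol=%g conv_grad=%g conv_energy=%g",
          tau, lindep, scf_opts$conv_grad %||% 1e-6,
          scf_opts$conv_energy %||% 1e-9)

  results <- switch(cfg$mode,
    scf = , hcc = {
      basis <- cfg$basis %||% "sto-3g"
      sys <- load_geometry(cfg$geometry, format = cfg$format %||% "auto",
                           charge = as.integer(cfg$charge %||% 0),
                           multiplicity = cfg$multiplicity,
                           basis = if (length(basis) > 1) unlist(basis) else basis)
      fun <- config_functional(cfg)
      layer <- config_embedding(cfg)
      part <- define_partition(sys, cfg$active_atoms %||% seq_len(nrow(sys$atoms)))
      res <- uml_scf(sys, part, functional = fun, embedding = layer,
                     tau = tau, lindep_tol = lindep,
                     virtual = cfg$virtual %||% "pao",
                     max_iter = as.integer(scf_opts$max_iter %||% 100L),
                     conv_grad = scf_opts$conv_grad %||% 1e-6,
                     conv_energy = scf_opts$conv_energy %||% 1e-9)
      save_checkpoint(res$partitioned, file.path(out, "checkpoint.rds"),
                      metadata = list(config_md5 = cfg_hash))
      r <- list(mode = cfg$mode, config_md5 = cfg_hash,
                energy = as.list(res$breakdown),
                E_total = res$E_total, iterations = res$n_iter,
                converged = res$converged,
                active_electrons = c(alpha = res$partitioned$n_A_alpha,
                                     beta = res$partitioned$n_A_beta))
      if (cfg$mode == "hcc") {
        hf <- hyperfine(res, nuclei = cfg$hcc_nuclei)
        r$hyperfine <- hf$table
        write.csv(hf$table, file.path(out, "hyperfine.csv"),
                  row.names = FALSE)
      }
      logline("E_total = %.10f Eh after %d iterations", res$E_total, res$n_iter)
      r
    },
    ensemble = {
      pp <- cfg$pipeline %||% list()
      frames <- if (!is.null(cfg$geometry)) {
        if (!grepl("\\.pdb$", cfg$geometry, ignore.case = TRUE)) {
          stop("ensemble mode needs tagged frames: a multi-MODEL PDB ",
               "with water residues, or synth settings")
        }
        nmod <- max(1L, length(grep("^MODEL", readLines(cfg$geometry))))
        lapply(seq_len(nmod), function(k) {
          load_geometry(cfg$geometry, format = "pdb",
                        charge = as.integer(cfg$charge %||% 0),
                        multiplicity = cfg$multiplicity,
                        basis = cfg$basis %||% "sto-3g", frame = k)
        })
      } else {
        sy <- cfg$synth %||% list()
        generate_synthetic_snapshots(
          seed = cfg$seed, n_frames = as.integer(sy$n_frames %||% 10L),
          n_waters = as.integer(sy$n_waters %||% 20L),
          box_radius = sy$box_radius %||% 8,
          oop_sd = sy$oop_sd %||% 10)
      }
      ens <- snapshot_hcc(frames, functional = config_functional(cfg),
                          droplet_radius = pp$droplet_radius %||% 13,
                          qm_radius = pp$qm_radius %||% 3.5,
                          n_active = as.integer(cfg$n_active %||% 0L),
                          scheme = cfg$scheme %||% "NO",
                          embedding = (cfg$embedding %||% list(type = "fq"))$type %||% "fq",
                          tau = tau, lindep_tol = lindep)
      write.csv(ens$ledger, file.path(out, "ledger.csv"), row.names = FALSE)
      logline("ensemble: %d snapshots, hcc %.4f +/- %.4f G",
              ens$stats$n, ens$stats$mean, ens$stats$se)
      list(mode = "ensemble", config_md5 = cfg_hash, stats = ens$stats)
    },
    synth = {
      sy <- cfg$synth %||% list()
      frames <- generate_synthetic_snapshots(
        seed = cfg$seed, n_frames = as.integer(sy$n_frames %||% 10L),
        n_waters = as.integer(sy$n_waters %||% 20L),
        box_radius = sy$box_radius %||% 8, oop_sd = sy$oop_sd %||% 10)
      path <- file.path(out, "snapshots.xyz")
      write_xyz_frames(frames, path)
      logline("wrote %d synthetic frames to %s", length(frames), path)
      list(mode = "synth", config_md5 = cfg_hash, n_frames = length(frames),
           path = path)
    })
  jsonlite::write_json(results, file.path(out, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}

#' Write systems as a multi-frame XYZ file
#'
#' @param frames list of [atomic_system()] (or a single one).
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_xyz_frames <- function(frames, path) {
  if (inherits(frames, "atomic_system")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    writeLines(as.character(nrow(f$atoms)), con)
    writeLines(sprintf("frame %d", i), con)
    writeLines(sprintf("%-2s %14.8f %14.8f %14.8f",
                       f$atoms$element, f$atoms$x, f$atoms$y, f$atoms$z), con)
  }
  invisible(path)
}
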