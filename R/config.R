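# Configuration, orchestration and serialization shared by the experiment
# drivers and the command-line front end (exec/percmem).

#' Read an experiment configuration file
#'
#' Flat key-value configuration in YAML (`.yml`/`.yaml`) or JSON.
#'
#' @param path config file.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
}

.config_defaults <- list(
  kind = "smoke", trials = 5L, M_max = 200L, seed = 1L, out = "results",
  alpha_fid = 0.8, alpha_spc = 1.0, rho_rec = 0, p_plus = 0, K = 1L,
  prestore = FALSE, approx = "binomial",
  axis = NULL, values = NULL, levels = NULL, checkpoints = 0L,
  noise_kind = "query", N_values = NULL, reliability_floor = 0.99,
  er_trials = 100L
)

#' Resolve a configuration
#'
#' Merges defaults, file values and overrides (highest precedence last),
#' validates the model parameters and derives `p_minus`. A `p_minus` given
#' explicitly must agree with the normalizing value to within 1e-9,
#' otherwise the configuration is rejected.
#'
#' @param config named list (e.g. from [read_config()]).
#' @param overrides named list of overriding values (e.g. CLI flags).
#' @return List with the fully resolved settings and `params`, a
#'   [model_params()] object.
#' @export
resolve_config <- function(config = list(), overrides = list()) {
  cfg <- modifyList(.config_defaults, config)
  cfg <- modifyList(cfg, overrides[!vapply(overrides, is.null, logical(1))])
  req <- c("N", "n", "rho_aff", "r_aff")
  miss <- setdiff(req, names(cfg))
  if (length(miss))
    stop("config is missing required field(s): ", paste(miss, collapse = ", "))
  params <- model_params(
    N = cfg$N, n = cfg$n, rho_aff = cfg$rho_aff, r_aff = cfg$r_aff,
    rho_rec = cfg$rho_rec, p_plus = cfg$p_plus, K = cfg$K,
    alpha_fid = cfg$alpha_fid, alpha_spc = cfg$alpha_spc,
    rec_degree = cfg$rec_degree
  )
  if (!is.null(cfg$p_minus) &&
      abs(cfg$p_minus - params$p_minus) > 1e-9)
    stop(sprintf("config field p_minus = %g is inconsistent with the normalizing value %g",
                 cfg$p_minus, params$p_minus))
  cfg$params <- params
  cfg
}

#' Write experiment result files
#'
#' Tables become UTF-8 CSV files with a header row; the summary becomes a
#' JSON file embedding the resolved parameters. Files are written to a
#' temporary name in the target directory and renamed into place.
#'
#' @param tables named list of data frames.
#' @param summary named list for the JSON summary.
#' @param out output directory (created if needed).
#' @param stem file-name stem.
#' @return Character vector of written paths, invisibly.
#' @export
write_results <- function(tables, summary, out, stem) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out, 2) != 0) stop("output directory is not writable: ", out)
  paths <- character(0)
  atomically <- function(path, writer) {
    tmp <- tempfile(tmpdir = out)
    writer(tmp)
    file.rename(tmp, path)
    path
  }
  for (nm in names(tables)) {
    path <- file.path(out, paste0(stem, "_", nm, ".csv"))
    tab <- tables[[nm]]
    paths <- c(paths, atomically(path, function(tmp)
      write.csv(tab, tmp, row.names = FALSE, fileEncoding = "UTF-8")))
  }
  spath <- file.path(out, paste0(stem, "_summary.json"))
  paths <- c(paths, atomically(spath, function(tmp)
    jsonlite::write_json(summary, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")))
  invisible(paths)
}

.params_as_list <- function(params) {
  out <- unclass(params)
  out$indexing <- "1-based vertex indices"
  out$log_convention <- "natural"
  out
}

#' Run a configured experiment
#'
#' Dispatches to the experiment named by `kind` and writes its result
#' files: `"capacity"` (per-trial capacities), `"sweep"`, `"track"`,
#' `"noise"`, `"theory"` (closed-form report only), `"validate"`
#' (error-decomposition comparison plus noise-invariance check) or
#' `"smoke"` (one tiny capacity trial). Every summary embeds the resolved
#' parameters, the master seed and the per-trial seeds, and re-running the
#' same configuration reproduces all outputs exactly.
#'
#' @param config resolved or raw configuration list (see
#'   [resolve_config()]).
#' @return Character vector of written file paths, invisibly.
#' @export
run_config <- function(config) {
  cfg <- if (is.null(config$params)) resolve_config(config) else config
  params <- cfg$params
  kind <- match.arg(cfg$kind, c("capacity", "sweep", "track", "noise",
                                "theory", "validate", "smoke"))
  t0 <- Sys.time()
  base_summary <- list(kind = kind, seed = cfg$seed,
                       params = .params_as_list(params),
                       package_version = as.character(utils::packageVersion("percmem")))
  tables <- list(); extra <- list()
  if (kind == "smoke") {
    set.seed(cfg$seed)
    rec <- measure_capacity(params, cfg$M_max)
    extra <- list(capacity = rec$capacity, reliability = rec$reliability)
  } else if (kind == "capacity") {
    seeds <- derive_trial_seeds(cfg$seed, cfg$trials)
    recs <- lapply(seeds, function(s) {
      set.seed(s)
      measure_capacity(params, cfg$M_max, prestore = isTRUE(cfg$prestore))
    })
    caps <- vapply(recs, `[[`, numeric(1), "capacity")
    tables$trials <- data.frame(
      trial = seq_along(seeds), trial_seed = seeds, capacity = caps,
      reliability = vapply(recs, `[[`, numeric(1), "reliability"),
      density_at_failure = vapply(recs, `[[`, numeric(1), "density_at_failure")
    )
    extra <- list(mean_capacity = mean(caps),
                  se_capacity = sd(caps) / sqrt(length(caps)),
                  trial_seeds = seeds)
  } else if (kind == "sweep") {
    if (is.null(cfg$axis) || is.null(cfg$values))
      stop("sweep requires 'axis' and 'values'")
    tables$sweep <- run_sweep(params, cfg$axis, cfg$values, cfg$trials,
                              cfg$M_max, cfg$reliability_floor,
                              seed = cfg$seed)
  } else if (kind == "track") {
    tables$track <- track_association_zero(params, cfg$M_max, cfg$trials,
                                           seed = cfg$seed)
  } else if (kind == "noise") {
    if (is.null(cfg$levels)) stop("noise requires 'levels'")
    tables$noise <- noise_tolerance_experiment(
      params, cfg$noise_kind, cfg$levels, cfg$checkpoints, cfg$trials,
      seed = cfg$seed)
  } else if (kind == "theory") {
    extra <- theory_quantities(params)
  } else if (kind == "validate") {
    Nv <- if (is.null(cfg$N_values)) params$N else cfg$N_values
    tables$comparison <- capacity_prediction_comparison(
      params, Nv, cfg$trials, er_trials = cfg$er_trials, seed = cfg$seed)
    inv <- noise_invariance_check(params, cfg$M_max, cfg$trials,
                                  seed = cfg$seed)
    tables$noise_invariance <- inv
    extra <- list(noise_invariance_pass = attr(inv, "overall_pass"))
  }
  summary <- c(base_summary, extra,
               list(wall_clock_sec = as.numeric(difftime(Sys.time(), t0,
                                                         units = "secs"))))
  write_results(tables, summary, cfg$out, kind)
}
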