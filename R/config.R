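# Run configuration: YAML (primary) / JSON (accepted) parsing, schema
# validation with unknown-key rejection, defaults, and constructors that
# turn a validated config into the domain objects of the other modules.
# The schema is documented in inst/extdata/config-schema.md and exercised
# by the example configs shipped alongside it.

.config_schema <- list(
  top = c("seed", "out_dir", "log_level", "gate", "components",
          "population", "cycle", "perturb", "fixtures"),
  gate = c("threshold", "sharpness"),
  component = c("value", "dist", "normalization"),
  dist = c("family", "shape1", "shape2", "value"),
  normalization = c("lo", "hi", "clamp"),
  population = c("n_cells"),
  cycle = c("schedule", "g1_ramp", "k_act", "gamma", "dt", "noise_sd",
            "origins_file", "n_origins", "events", "stochastic_firing"),
  segment = c("phase", "duration", "phi_start", "phi_end"),
  event = c("t_start", "t_end", "phi_scale", "D_scale"),
  perturb = c("levels", "replicates", "n_cells", "noise_sd", "truth"),
  fixtures = c("n_samples", "regime")
)

.reject_unknown <- function(block, allowed, where) {
  extra <- setdiff(names(block), allowed)
  if (length(extra))
    stop(sprintf("unknown config key(s) in %s: %s", where,
                 paste(extra, collapse = ", ")), call. = FALSE)
}

#' Load and validate a run configuration
#'
#' Parses a YAML or JSON configuration file (format chosen by extension:
#' `.json` is JSON, anything else YAML — YAML is a superset of JSON, so
#' JSON content in a `.yaml` file also parses), rejects unknown keys,
#' validates value ranges and fills defaults. Loading the same file twice
#' yields identical configurations.
#'
#' @param path Path to the configuration file.
#' @return An object of class `run_config`: a named list with blocks
#'   `seed`, `out_dir`, `log_level`, `gate`, `components`, `population`,
#'   `cycle`, `perturb`, `fixtures`.
#' @examples
#' cfg_file <- system.file("extdata", "example-population.yaml",
#'                         package = "repgate")
#' load_config(cfg_file)$gate$threshold
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a mapping", call. = FALSE)
  .reject_unknown(raw, .config_schema$top, "top level")

  cfg <- list(
    seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
    out_dir = if (is.null(raw$out_dir)) "." else as.character(raw$out_dir),
    log_level = if (is.null(raw$log_level)) "info"
    else match.arg(raw$log_level, c("debug", "info", "warn", "error"))
  )

  g <- if (is.null(raw$gate)) list() else raw$gate
  .reject_unknown(g, .config_schema$gate, "gate")
  cfg$gate <- gate_params(
    threshold = if (is.null(g$threshold)) 0.5 else g$threshold,
    sharpness = if (is.null(g$sharpness)) 8 else g$sharpness)

  comps <- if (is.null(raw$components)) list() else raw$components
  .reject_unknown(comps, c("A", "D", "C", "phi"), "components")
  cfg$components <- lapply(stats::setNames(nm = c("A", "D", "C", "phi")),
                           function(nm) {
    blk <- comps[[nm]]
    if (is.null(blk)) blk <- list()
    .reject_unknown(blk, .config_schema$component,
                    paste0("components$", nm))
    out <- list()
    if (!is.null(blk$value)) out$value <- .check_unit(blk$value, nm)
    if (!is.null(blk$dist)) {
      .reject_unknown(blk$dist, .config_schema$dist,
                      paste0("components$", nm, "$dist"))
      d <- blk$dist
      out$dist <- if (identical(d$family, "fixed"))
        component_dist("fixed", value = d$value %||% 1)
      else component_dist("beta", d$shape1 %||% 2, d$shape2 %||% 2)
    }
    if (!is.null(blk$normalization)) {
      .reject_unknown(blk$normalization, .config_schema$normalization,
                      paste0("components$", nm, "$normalization"))
      nz <- blk$normalization
      out$normalization <- normalization_spec(nz$lo, nz$hi,
                                              nz$clamp %||% TRUE)
    }
    out
  })

  p <- if (is.null(raw$population)) list() else raw$population
  .reject_unknown(p, .config_schema$population, "population")
  cfg$population <- list(n_cells = as.integer(p$n_cells %||% 1000L))

  cy <- if (is.null(raw$cycle)) list() else raw$cycle
  .reject_unknown(cy, .config_schema$cycle, "cycle")
  cfg$cycle <- list(
    schedule = if (is.null(cy$schedule))
      default_schedule(g1_ramp = cy$g1_ramp %||% TRUE)
    else {
      segs <- cy$schedule
      for (s in segs) .reject_unknown(s, .config_schema$segment,
                                      "cycle$schedule segment")
      phase_schedule(
        phase = vapply(segs, function(s) s$phase, character(1)),
        duration = vapply(segs, function(s) as.numeric(s$duration),
                          numeric(1)),
        phi_start = vapply(segs, function(s)
          as.numeric(s$phi_start %||% 1), numeric(1)),
        phi_end = vapply(segs, function(s)
          as.numeric(s$phi_end %||% s$phi_start %||% 1), numeric(1)))
    },
    params = dynamic_params(k_act = cy$k_act %||% 1,
                            gamma = cy$gamma %||% 1,
                            dt = cy$dt %||% 0.01,
                            noise_sd = cy$noise_sd %||% 0,
                            seed = as.integer(raw$seed %||% 1L)),
    events = lapply(cy$events %||% list(), function(e) {
      .reject_unknown(e, .config_schema$event, "cycle$events entry")
      checkpoint_event(e$t_start, e$t_end, e$phi_scale %||% 1,
                       e$D_scale %||% 1)
    }),
    origins_file = cy$origins_file,
    n_origins = as.integer(cy$n_origins %||% 50L),
    stochastic_firing = isTRUE(cy$stochastic_firing))

  pe <- if (is.null(raw$perturb)) list() else raw$perturb
  .reject_unknown(pe, .config_schema$perturb, "perturb")
  cfg$perturb <- list(
    levels = pe$levels %||% list(A = c(1, 0.7, 0.4), D = c(1, 0.5),
                                 C = c(1, 0.5)),
    replicates = as.integer(pe$replicates %||% 1L),
    n_cells = as.integer(pe$n_cells %||% 1000L),
    noise_sd = as.numeric(pe$noise_sd %||% 0.05),
    truth = match.arg(pe$truth %||% "multiplicative",
                      c("multiplicative", "additive")))

  fx <- if (is.null(raw$fixtures)) list() else raw$fixtures
  .reject_unknown(fx, .config_schema$fixtures, "fixtures")
  cfg$fixtures <- list(
    n_samples = as.integer(fx$n_samples %||% 100L),
    regime = match.arg(fx$regime %||% "stem",
                       c("stem", "quiescent", "stressed")))

  class(cfg) <- "run_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("run config: seed=%d, threshold=%.3f, out_dir=%s\n",
              x$seed, x$gate$threshold, x$out_dir))
  invisible(x)
}

# component block -> sampling distribution (fixed value wins over dist)
.component_to_dist <- function(blk, default) {
  if (!is.null(blk$value)) return(component_dist("fixed", value = blk$value))
  if (!is.null(blk$dist)) return(blk$dist)
  default
}

#' Build a population configuration from a run config
#'
#' @param cfg A [load_config()] result.
#' @return A [population_config()].
#' @export
config_population <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  population_config(
    n_cells = cfg$population$n_cells,
    dist_A = .component_to_dist(cfg$components$A,
                                component_dist("beta", 2, 2)),
    dist_D = .component_to_dist(cfg$components$D,
                                component_dist("beta", 2, 2)),
    dist_C = .component_to_dist(cfg$components$C,
                                component_dist("beta", 2, 2)),
    dist_phi = .component_to_dist(cfg$components$phi,
                                  component_dist("fixed", value = 1)),
    gate = cfg$gate, seed = cfg$seed)
}
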