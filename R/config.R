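#' Pipeline configuration with all published defaults
#'
#' Bundles every tunable threshold of the pipeline: the exon-coverage QC
#' bounds, the CNV pass-rule thresholds, the variant QC rules, the trajectory
#' band floors, the MCMC schedule of the Bayesian scan, the integration
#' window, and the simulator defaults. The returned list round-trips
#' losslessly through the YAML config file ([write_config()] /
#' [read_config()]).
#'
#' @param ... Named overrides of any default, e.g. `cnv = list(t1 = 0.4)`
#'   (partial lists are merged).
#' @return A list of class `poolcross_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    region_qc = list(min_depth = 30, max_depth = 800, min_length = 45),
    cnv = list(t1 = 0.3, t2 = 0.2, scale = "z"),
    variant_qc = list(min_depth = 30, min_support = 0.04,
                      min_freq_diff = 0.05),
    trajectory = list(low_coverage_depth = 30),
    scan = list(prior_odds = 10, pilot_runs = 20, pilot_length = 2000,
                burn_in = 1e5, iterations = 5e5, thin = 50,
                desk_factor = 10, pool_size = 100, q_threshold = 0.05),
    integrate = list(window_bp = 5e4, q_threshold = 0.05),
    sim = list(n_founders = 2000, census = 2000, pool_size = 100,
               depth_mean = 100, depth_size = 20, error_rate = 0.001,
               coverage_size = 100, mu0 = 0, sigma = 0.3, dominance = 0.5),
    seed = 1L
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], over[[nm]])
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  validate_config(cfg)
  structure(cfg, class = c("poolcross_config", "list"))
}

validate_config <- function(cfg) {
  pos <- c(
    cfg$region_qc$min_depth, cfg$region_qc$max_depth, cfg$region_qc$min_length,
    cfg$cnv$t1, cfg$cnv$t2,
    cfg$variant_qc$min_depth, cfg$variant_qc$min_support,
    cfg$variant_qc$min_freq_diff,
    cfg$scan$prior_odds, cfg$scan$burn_in, cfg$scan$iterations, cfg$scan$thin,
    cfg$integrate$window_bp, cfg$sim$sigma, cfg$sim$pool_size
  )
  if (any(!is.finite(pos) | pos <= 0)) {
    abort("all pipeline thresholds must be finite and strictly positive")
  }
  if (cfg$region_qc$min_depth >= cfg$region_qc$max_depth) {
    abort("region QC requires min_depth < max_depth")
  }
  invisible(cfg)
}

#' @rdname pipeline_config
#' @param cfg A `poolcross_config` list.
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}
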