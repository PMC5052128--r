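#' Read a segmentation configuration from YAML
#'
#' The file mirrors [seg_config()]: top-level keys `forest`, `crf`,
#' `coseg`, `erosion_radius_px`, `variant`, `nocrf_threshold`,
#' `stop_min_fg_px`, each optional — missing keys keep the shipped
#' defaults. Example:
#' \preformatted{
#' forest: {n_trees: 20, max_depth: 10, poisson_lambda: 1, seed: 7}
#' crf:    {lambda1: 40, sigma1: 2.5}
#' coseg:  {lambda2: 10, lambda3: 3, sigma2: 0.005, sigma3: 0.08}
#' variant: full
#' }
#'
#' @param path YAML file path.
#' @return A [seg_config()].
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  take <- function(defaults, over) {
    for (nm in names(over)) defaults[[nm]] <- over[[nm]]
    defaults
  }
  fc <- do.call(forest_config, take(list(), y$forest))
  cp <- do.call(crf_params, take(list(), y$crf))
  gp <- do.call(coseg_params,
                take(list(lambda1 = cp$lambda1, sigma1 = cp$sigma1), y$coseg))
  args <- list(forest = fc, crf = cp, coseg = gp)
  for (nm in c("erosion_radius_px", "variant", "nocrf_threshold",
               "stop_min_fg_px"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  do.call(seg_config, args)
}

#' Write the shipped default configuration
#'
#' @param config a [seg_config()].
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  y <- list(
    forest = unclass(config$forest)[c("n_trees", "max_depth",
                                      "poisson_lambda",
                                      "n_candidate_thresholds",
                                      "min_samples_split", "seed")],
    crf = unclass(config$crf),
    coseg = unclass(config$coseg),
    erosion_radius_px = config$erosion_radius_px,
    variant = config$variant,
    nocrf_threshold = config$nocrf_threshold,
    stop_min_fg_px = config$stop_min_fg_px)
  yaml::write_yaml(y, path)
  invisible(path)
}
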