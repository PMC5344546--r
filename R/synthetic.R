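#' Stochastic stress-to-failure model for synthetic specimens
#'
#' Logistic link between a scalar stress predictor (MPa) and the per-specimen
#' probability of each failure type: `P(failure) = plogis((stress - location)
#' / scale)`. Stands in for the in vitro outcome process so the scoring and
#' regression stages are testable without experimental data. Default
#' locations/scales are set once against the coarse-mesh postero-lateral
#' axial tensile stress scale of the built-in complex scenarios (roughly
#' 10-40 MPa): failure probabilities are high for the highest-stress cases
#' and near zero for the no-flexion case, with small failures located at
#' slightly lower stress than large ones.
#'
#' @param location Named numeric: logistic location (MPa) per failure type
#'   (`large_aff`, `small_aff`, `large_epjf`, `small_epjf`).
#' @param scale Named numeric: logistic scale (MPa) per failure type,
#'   positive.
#' @return A `failure_model` object.
#' @export
failure_model <- function(location = c(large_aff = 26, small_aff = 22,
                                       large_epjf = 28, small_epjf = 24),
                          scale = c(large_aff = 4, small_aff = 4,
                                    large_epjf = 4, small_epjf = 4)) {
  types <- c("large_aff", "small_aff", "large_epjf", "small_epjf")
  location <- rep_len(location, 4)
  scale <- rep_len(scale, 4)
  if (is.null(names(location)) || !all(types %in% names(location)))
    names(location) <- types
  if (is.null(names(scale)) || !all(types %in% names(scale)))
    names(scale) <- types
  if (any(scale <= 0)) stop("validation error: logistic scale must be positive")
  structure(list(location = location[types], scale = scale[types]),
            class = "failure_model")
}

#' Simulate per-specimen failure counts
#'
#' For each scenario, draws `n` independent specimens; each failure type is
#' an independent Bernoulli draw with probability given by the logistic link
#' of the scenario's stress predictor. Reproducible under a fixed seed.
#'
#' @param stress Named numeric vector: one stress predictor value (MPa) per
#'   scenario.
#' @param model A [failure_model()].
#' @param n Specimens per scenario.
#' @param seed Integer RNG seed.
#' @return data.frame `specimen`, `scenario`, `large_aff`, `small_aff`,
#'   `large_epjf`, `small_epjf` (0/1 indicators per specimen).
#' @export
simulate_specimens <- function(stress, model = failure_model(), n = 6,
                               seed = 1) {
  stopifnot(inherits(model, "failure_model"), n >= 1, all(is.finite(stress)))
  if (is.null(names(stress))) names(stress) <- paste0("scenario", seq_along(stress))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  types <- names(model$location)
  rows <- list()
  spec_id <- 0
  for (sc in names(stress)) {
    pr <- stats::plogis((stress[[sc]] - model$location) / model$scale)
    draws <- matrix(stats::rbinom(n * 4, 1, rep(pr, each = n)), n, 4)
    colnames(draws) <- types
    df <- data.frame(specimen = spec_id + seq_len(n), scenario = sc)
    df <- cbind(df, as.data.frame(draws))
    spec_id <- spec_id + n
    rows[[sc]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
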