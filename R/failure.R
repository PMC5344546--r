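#' Damage score of failure counts
#'
#' Weighted failure score: large annulus failures (AFF) and large
#' endplate-junction failures (EPJF) score 1, small failures score 0.5:
#' `S = large_epjf + 0.5*small_epjf + large_aff + 0.5*small_aff`.
#' Per specimen the counts are 0/1 indicators (S in [0, 2]); aggregated over
#' a group of n specimens S lies in [0, 2n].
#'
#' @param counts A data.frame (or single named list/vector) with columns
#'   `large_aff`, `small_aff`, `large_epjf`, `small_epjf` (non-negative).
#' @return Numeric score(s), one per row.
#' @export
damage_score <- function(counts) {
  if (!is.data.frame(counts)) counts <- as.data.frame(as.list(counts))
  need <- c("large_aff", "small_aff", "large_epjf", "small_epjf")
  if (!all(need %in% names(counts)))
    stop("counts must contain ", paste(need, collapse = ", "))
  m <- as.matrix(counts[need])
  if (any(m < 0)) stop("validation error: negative failure counts")
  as.numeric(m %*% c(1, 0.5, 1, 0.5))
}

#' In vitro failure counts per loading scenario
#'
#' The packaged group-level failure counts of the parallel in vitro study
#' (six ovine lumbar segments per loading scenario; large/small annulus and
#' endplate-junction failures).
#'
#' @return data.frame with columns `scenario`, `large_aff`, `small_aff`,
#'   `large_epjf`, `small_epjf`, `total_score`.
#' @export
invitro_failure_counts <- function() {
  f <- system.file("extdata", "failure_counts_invitro.csv", package = "discfem",
                   mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}

#' Failure-risk thresholds
#'
#' Tensile-stress thresholds separating high/moderate/low risk of annulus
#' failure (axial and circumferential directions) and the single
#' interface-stress threshold for endplate-junction failure.
#'
#' @param axial_high,axial_low Axial thresholds (MPa), defaults 10 and 6.
#' @param circ_high,circ_low Circumferential thresholds (MPa), 9 and 6.
#' @param interface_high Interface threshold (MPa), 3.5.
#' @return A `risk_thresholds` object.
#' @export
risk_thresholds <- function(axial_high = 10, axial_low = 6,
                            circ_high = 9, circ_low = 6,
                            interface_high = 3.5) {
  stopifnot(axial_high > axial_low, axial_low > 0,
            circ_high > circ_low, circ_low > 0, interface_high > 0)
  structure(list(axial_high = axial_high, axial_low = axial_low,
                 circ_high = circ_high, circ_low = circ_low,
                 interface_high = interface_high),
            class = "risk_thresholds")
}

#' Classify failure risk of stress values
#'
#' Directional tensile stresses at or above the high threshold are `high`
#' risk, at or below the low threshold `low`, otherwise `moderate`. The
#' interface stress uses the single high threshold (at or above 3.5 MPa is
#' `high`, else `low`). No thresholds are published for the radial
#' direction, which classifies as `NA`.
#'
#' @param values Numeric stress values (MPa), or a `regional_stress_table`.
#' @param direction Character vector (recycled): `axial`, `circumferential`,
#'   `radial` or `interface`. Ignored when `values` is a table.
#' @param thresholds A [risk_thresholds()].
#' @return Character vector of labels (`high`, `moderate`, `low`), or the
#'   table with a `risk` column appended.
#' @export
classify_risk <- function(values, direction = "axial",
                          thresholds = risk_thresholds()) {
  if (is.data.frame(values)) {
    values$risk <- classify_risk(values$value, values$direction, thresholds)
    return(values)
  }
  n <- length(values)
  direction <- rep_len(direction, n)
  out <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    v <- values[i]
    if (is.na(v)) next
    out[i] <- switch(direction[i],
      axial = if (v >= thresholds$axial_high) "high"
              else if (v <= thresholds$axial_low) "low" else "moderate",
      circumferential = if (v >= thresholds$circ_high) "high"
              else if (v <= thresholds$circ_low) "low" else "moderate",
      interface = if (v >= thresholds$interface_high) "high" else "low",
      radial = NA_character_,
      stop("unknown direction: ", direction[i]))
  }
  out
}

#' Regression of damage score on predicted stresses
#'
#' Ordinary least-squares regression of the per-specimen damage score on
#' each stress predictor (default), reporting slope, intercept and the
#' two-sided t-test p-value per predictor, flagged at alpha = 0.05 without
#' multiplicity correction (optionally Benjamini-Hochberg adjusted). A joint
#' multiple-regression mode regresses the score on all predictors at once.
#' Zero-variance predictors are flagged non-estimable, never significant.
#'
#' @param stresses Matrix or data.frame, one row per specimen, one column
#'   per stress predictor.
#' @param scores Numeric damage scores, one per specimen.
#' @param mode `"per-predictor"` (default) or `"joint"`.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @param alpha Significance level for the flag.
#' @return data.frame `predictor`, `slope`, `intercept` (per-predictor mode),
#'   `p_value`, `significant`.
#' @export
regress_stress_vs_score <- function(stresses, scores,
                                    mode = c("per-predictor", "joint"),
                                    p_adjust = c("none", "BH"), alpha = 0.05) {
  mode <- match.arg(mode); p_adjust <- match.arg(p_adjust)
  x <- as.matrix(stresses)
  y <- as.numeric(scores)
  if (nrow(x) != length(y)) stop("one stress row per specimen required")
  if (length(y) < 3) stop("at least 3 specimens required")
  preds <- colnames(x)
  if (is.null(preds)) preds <- paste0("x", seq_len(ncol(x)))

  if (mode == "joint") {
    keep <- apply(x, 2, stats::sd) > 1e-12
    fit <- stats::lm(y ~ x[, keep, drop = FALSE])
    sm <- summary(fit)$coefficients
    out <- data.frame(predictor = preds, slope = NA_real_,
                      intercept = NA_real_, p_value = NA_real_)
    out$slope[keep] <- sm[-1, 1]
    out$p_value[keep] <- sm[-1, 4]
  } else {
    out <- data.frame(predictor = preds, slope = NA_real_,
                      intercept = NA_real_, p_value = NA_real_)
    const_y <- stats::sd(y) <= 1e-12
    for (k in seq_along(preds)) {
      xk <- x[, k]
      if (stats::sd(xk) <= 1e-12) next
      if (const_y) { # degenerate response: flat fit, nothing to detect
        out$slope[k] <- 0; out$intercept[k] <- mean(y)
        next
      }
      fit <- stats::lm(y ~ xk)
      sm <- summary(fit)$coefficients
      out$slope[k] <- sm[2, 1]
      out$intercept[k] <- sm[1, 1]
      out$p_value[k] <- if (nrow(sm) > 1 && !is.nan(sm[2, 4])) sm[2, 4] else NA
    }
  }
  padj <- if (p_adjust == "BH") stats::p.adjust(out$p_value, "BH") else out$p_value
  out$significant <- !is.na(padj) & padj < alpha
  class(out) <- c("regression_result", "data.frame")
  out
}
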