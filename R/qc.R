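#' @title Heuristic data quality control
#' @description
#' Four heuristic rules alert users to the most common acquisition problems:
#' apparent prior processing (height, deflection or PLL images flattened
#' before saving, leaving values very close to zero), flawed AFM tracking
#' (deflection further than 0.01 V from the setpoint), flawed PLL tracking
#' (IR phase more than 20 degrees from the setpoint), and saturation of the
#' PLL loop at its frequency limits. All rules are pure functions of the map
#' and a [qc_config()]; NaN pixels are excluded from every statistic.
#' @name qc
NULL

qc_flag <- function(rule_id, target_label, measured, threshold,
                    exceed_fraction, severity, message) {
  structure(list(rule_id = rule_id, target_label = target_label,
                 measured = measured, threshold = threshold,
                 exceed_fraction = exceed_fraction, severity = severity,
                 message = message),
            class = "qc_flag")
}

pooled_values <- function(map) {
  v <- as.vector(map$trace)
  if (!is.null(map$retrace)) v <- c(v, as.vector(map$retrace))
  v[is.finite(v)]
}

# wrap angular differences into (-180, 180]
wrap_degrees <- function(x) {
  w <- ((x + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

#' QC rule: apparent prior data processing
#'
#' Height, deflection and PLL images that were flattened before saving have
#' per-line means very close to zero — the signature of line-wise leveling.
#' The rule flags (severity `"warn"`) when the absolute mean of finite trace
#' values is below `cfg$flat_tolerance` on every scan line (or, with
#' `flat_mode = "global"`, when the global mean is). `measured` records the
#' largest absolute line mean.
#'
#' @param map a [channel_map()] with channel `"Height"`, `"Deflection"` or
#'   `"PLLFrequency"`.
#' @param cfg a [qc_config()].
#' @return a `qc_flag` or `NULL`.
#' @export
qc_apparent_processing <- function(map, cfg = qc_config()) {
  if (!(map$channel %in% c("Height", "Deflection", "PLLFrequency")))
    axz_stop("axz_wrong_channel",
             sprintf("apparent-processing rule does not apply to channel '%s'", map$channel))
  line_means <- apply(map$trace, 1L, function(r) {
    r <- r[is.finite(r)]
    if (length(r) == 0L) NA_real_ else mean(r)
  })
  line_means <- line_means[!is.na(line_means)]
  if (length(line_means) == 0L) return(NULL)
  if (cfg$flat_mode == "global") {
    measured <- abs(mean(pooled_values(map)))
    trigger <- measured < cfg$flat_tolerance
  } else {
    measured <- max(abs(line_means))
    trigger <- all(abs(line_means) < cfg$flat_tolerance)
  }
  if (!trigger) return(NULL)
  qc_flag("APPARENT_PROCESSING", map$label, measured, cfg$flat_tolerance, 1,
          "warn",
          sprintf("map '%s' (%s) appears flattened prior to saving: all line means below %g %s",
                  map$label, map$channel, cfg$flat_tolerance, map$units))
}

fraction_rule <- function(map, deviations, threshold, cfg, rule_id, what, unit) {
  dev <- abs(deviations)
  dev <- dev[is.finite(dev)]
  if (length(dev) == 0L) return(NULL)
  f <- mean(dev > threshold)
  if (f <= cfg$exceed_fraction_trigger) return(NULL)
  qc_flag(rule_id, map$label, max(dev), threshold, f, "fail",
          sprintf("map '%s': %.1f%% of pixels have %s more than %g %s from the setpoint (max deviation %g %s)",
                  map$label, 100 * f, what, threshold, unit, max(dev), unit))
}

#' QC rule: flawed AFM tracking
#'
#' Flags (severity `"fail"`) when more than `cfg$exceed_fraction_trigger` of
#' finite pixels (trace and retrace pooled) deviate from the deflection
#' setpoint by more than `cfg$deflection_threshold` volts. The flag records
#' the maximum deviation and the offending fraction.
#'
#' @inheritParams qc_apparent_processing
#' @return a `qc_flag` or `NULL`.
#' @export
qc_afm_tracking <- function(map, cfg = qc_config()) {
  if (!identical(map$channel, "Deflection"))
    axz_stop("axz_wrong_channel",
             sprintf("AFM-tracking rule expects a Deflection map, got '%s'", map$channel))
  if (is.null(map$deflection_setpoint))
    axz_stop("axz_missing_setpoint",
             sprintf("map '%s' has no deflection setpoint", map$label))
  v <- as.vector(map$trace)
  if (!is.null(map$retrace)) v <- c(v, as.vector(map$retrace))
  fraction_rule(map, v - map$deflection_setpoint, cfg$deflection_threshold,
                cfg, "AFM_TRACKING", "deflection", "V")
}

#' QC rule: flawed PLL phase tracking
#'
#' Same structure as [qc_afm_tracking()], on the angular deviation of IR
#' phase from the phase setpoint. Differences are wrapped into
#' (-180, 180] degrees before comparison (phase is circular), so a +350
#' degree offset counts as -10 degrees and does not flag at the default
#' 20 degree threshold.
#'
#' @inheritParams qc_apparent_processing
#' @return a `qc_flag` or `NULL`.
#' @export
qc_pll_phase <- function(map, cfg = qc_config()) {
  if (!identical(map$channel, "IRPhase"))
    axz_stop("axz_wrong_channel",
             sprintf("PLL-phase rule expects an IRPhase map, got '%s'", map$channel))
  if (is.null(map$phase_setpoint))
    axz_stop("axz_missing_setpoint",
             sprintf("map '%s' has no phase setpoint", map$label))
  v <- as.vector(map$trace)
  if (!is.null(map$retrace)) v <- c(v, as.vector(map$retrace))
  fraction_rule(map, wrap_degrees(v - map$phase_setpoint), cfg$phase_threshold,
                cfg, "PLL_PHASE", "IR phase", "degrees")
}

#' QC rule: PLL saturation
#'
#' A pixel is saturated when it lies within `cfg$saturation_tol` times the
#' range span of either PLL frequency limit; the rule flags (severity
#' `"fail"`) when the saturated fraction of finite pixels exceeds
#' `cfg$saturation_fraction`. `measured` records the saturated fraction.
#'
#' @inheritParams qc_apparent_processing
#' @return a `qc_flag` or `NULL`.
#' @export
qc_pll_saturation <- function(map, cfg = qc_config()) {
  if (!identical(map$channel, "PLLFrequency"))
    axz_stop("axz_wrong_channel",
             sprintf("PLL-saturation rule expects a PLLFrequency map, got '%s'", map$channel))
  if (is.null(map$pll_range))
    axz_stop("axz_missing_range",
             sprintf("map '%s' has no PLL range", map$label))
  v <- pooled_values(map)
  if (length(v) == 0L) return(NULL)
  lo <- map$pll_range[1]
  hi <- map$pll_range[2]
  span <- hi - lo
  sat <- (v <= lo + cfg$saturation_tol * span) | (v >= hi - cfg$saturation_tol * span)
  f <- mean(sat)
  if (f <= cfg$saturation_fraction) return(NULL)
  qc_flag("PLL_SATURATION", map$label, f, cfg$saturation_fraction, f, "fail",
          sprintf("map '%s': %.1f%% of pixels saturate the PLL range [%g, %g] %s",
                  map$label, 100 * f, lo, hi, map$units))
}

rule_table <- function() {
  list(
    APPARENT_PROCESSING = list(
      eligible = function(m) m$channel %in% c("Height", "Deflection", "PLLFrequency"),
      fn = qc_apparent_processing),
    AFM_TRACKING = list(
      eligible = function(m) identical(m$channel, "Deflection"),
      fn = qc_afm_tracking),
    PLL_PHASE = list(
      eligible = function(m) identical(m$channel, "IRPhase"),
      fn = qc_pll_phase),
    PLL_SATURATION = list(
      eligible = function(m) identical(m$channel, "PLLFrequency"),
      fn = qc_pll_saturation))
}

#' Run all QC rules over a document
#'
#' Applies each rule to every eligible map, visiting maps in label order and
#' rules in a fixed order per map, so the report's flags are ordered by
#' (label, rule) and the whole procedure is deterministic: identical
#' document and configuration always yield an identical report. A
#' deflection map without a stored setpoint, an IR-phase map without a phase
#' setpoint, or a PLL map without a frequency range is an error at this
#' point (those fields are required for their rules).
#'
#' @param doc an [anasys_document()] passing [validate_document()].
#' @param cfg a [qc_config()].
#' @return an object of class `qc_report` with fields `flags` (list of
#'   `qc_flag`), `n_maps_checked` (number of eligible map/rule evaluations)
#'   and `config_used`.
#' @export
run_qc <- function(doc, cfg = qc_config()) {
  v <- validate_document(doc)
  if (length(v))
    axz_stop("axz_validation_error",
             paste0("document fails validation: ", paste(v, collapse = "; ")))
  rules <- rule_table()
  flags <- list()
  n_checked <- 0L
  for (label in sort(names(doc$height_maps), method = "radix")) {
    m <- doc$height_maps[[label]]
    for (rid in names(rules)) {
      if (!rules[[rid]]$eligible(m)) next
      n_checked <- n_checked + 1L
      fl <- rules[[rid]]$fn(m, cfg)
      if (!is.null(fl)) flags[[length(flags) + 1L]] <- fl
    }
  }
  structure(list(flags = flags, n_maps_checked = n_checked, config_used = cfg),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report: %d flag(s) over %d rule evaluations\n",
              length(x$flags), x$n_maps_checked))
  for (fl in x$flags) {
    cat(sprintf("  [%s] %s (%s): %s\n", fl$severity, fl$rule_id,
                fl$target_label, fl$message))
  }
  invisible(x)
}

#' Flags of a report as a data frame
#'
#' @param report a `qc_report`.
#' @return data frame with one row per flag.
#' @export
qc_flags_df <- function(report) {
  if (length(report$flags) == 0L) {
    return(data.frame(rule_id = character(0), target_label = character(0),
                      measured = numeric(0), threshold = numeric(0),
                      exceed_fraction = numeric(0), severity = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(report$flags, function(fl) {
    data.frame(rule_id = fl$rule_id, target_label = fl$target_label,
               measured = fl$measured, threshold = fl$threshold,
               exceed_fraction = fl$exceed_fraction, severity = fl$severity,
               message = fl$message, stringsAsFactors = FALSE)
  }))
}

#' Locate a rule's flag boundary by bisection
#'
#' Builds a small synthetic map whose every pixel deviates uniformly from
#' its setpoint by `d`, evaluates the rule's flag state, and bisects `d`
#' over `[lower, upper]` until the on/off boundary is bracketed to `tol`.
#' With uniform deviation the offending fraction jumps from 0 to 1 exactly
#' at the per-pixel threshold, so the recovered boundary is the configured
#' threshold itself (0.01 V for deflection, 20 degrees for IR phase at the
#' defaults).
#'
#' @param rule `"deflection"` or `"phase"`.
#' @param cfg a [qc_config()].
#' @param lower,upper bracketing deviations; the rule must not flag at
#'   `lower` and must flag at `upper`.
#' @param tol bisection tolerance in the rule's unit.
#' @return the boundary deviation (midpoint of the final bracket).
#' @export
qc_flag_boundary <- function(rule = c("deflection", "phase"),
                             cfg = qc_config(), lower = 0, upper = NULL,
                             tol = 1e-6) {
  rule <- match.arg(rule)
  if (is.null(upper)) upper <- if (rule == "deflection") 0.1 else 90
  flagged <- function(d) {
    if (rule == "deflection") {
      m <- channel_map("probe", "Deflection",
                       trace = matrix(0.5 + d, 8, 8), units = "V",
                       size_xy = c(1, 1), deflection_setpoint = 0.5)
      !is.null(qc_afm_tracking(m, cfg))
    } else {
      m <- channel_map("probe", "IRPhase",
                       trace = matrix(90 + d, 8, 8), units = "degrees",
                       size_xy = c(1, 1), phase_setpoint = 90)
      !is.null(qc_pll_phase(m, cfg))
    }
  }
  if (flagged(lower))
    axz_stop("axz_invalid_spec", "rule already flags at the lower bracket")
  if (!flagged(upper))
    axz_stop("axz_invalid_spec", "rule does not flag at the upper bracket")
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    if (flagged(mid)) upper <- mid else lower <- mid
  }
  (lower + upper) / 2
}
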