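## Canonical vital-sign schema shared by every stage of the pipeline.

.VITAL_FEATURES <- c(
  "oxygen", "body_temperature", "heart_rate", "heart_rate_master",
  "weight", "bmi", "fev1", "pef", "map",
  "diastolic_pressure", "systolic_pressure"
)

.VITAL_UNITS <- c(
  oxygen = "%", body_temperature = "degC", heart_rate = "bpm",
  heart_rate_master = "bpm", weight = "kg", bmi = "kg/m2", fev1 = "L",
  pef = "L/min", map = "mmHg", diastolic_pressure = "mmHg",
  systolic_pressure = "mmHg"
)

## Hard physiological plausibility bounds used by the cohort simulator.
.VITAL_BOUNDS <- list(
  oxygen = c(70, 100), body_temperature = c(34, 42), heart_rate = c(30, 220),
  heart_rate_master = c(30, 220), weight = c(30, 250), bmi = c(10, 60),
  fev1 = c(0.3, 6), pef = c(50, 900), map = c(40, 180),
  diastolic_pressure = c(30, 130), systolic_pressure = c(60, 260)
)

.CLASS_LEVELS <- c("low", "high")
.PEF_THRESHOLD <- 400  # L/min; at or above => class "high"

#' Canonical vital-sign feature names
#'
#' The eleven features recorded per monitoring session, in canonical order.
#' `predictorNames()` drops `pef`, which is the label source (thresholded at
#' 400 L/min) and is therefore never used as a predictor.
#'
#' @return Character vector of feature identifiers.
#' @examples
#' vitalFeatures()
#' predictorNames()
#' @export
vitalFeatures <- function() .VITAL_FEATURES

#' @rdname vitalFeatures
#' @export
predictorNames <- function() setdiff(.VITAL_FEATURES, "pef")

#' @rdname vitalFeatures
#' @return `featureUnits()`: named character vector of measurement units.
#' @export
featureUnits <- function() .VITAL_UNITS

#' @rdname vitalFeatures
#' @return `physioBounds()`: named list of `c(min, max)` plausibility bounds.
#' @export
physioBounds <- function() .VITAL_BOUNDS

## Header normalisation: lower-case, strip everything non-alphanumeric, then
## map through an alias table so e.g. "Diastolic Blood Pressure", "FEV1" or
## "heartrate" all resolve to canonical identifiers.
.FEATURE_ALIASES <- c(
  oxygen = "oxygen",
  bodytemperature = "body_temperature", temperature = "body_temperature",
  heartrate = "heart_rate",
  heartratemaster = "heart_rate_master",
  weight = "weight",
  bmi = "bmi", bodymassindex = "bmi",
  fev1 = "fev1",
  pef = "pef", peakexpiratoryflow = "pef",
  map = "map", meanarterialpressure = "map",
  diastolicpressure = "diastolic_pressure",
  diastolicbloodpressure = "diastolic_pressure",
  systolicpressure = "systolic_pressure",
  systolicbloodpressure = "systolic_pressure",
  class = ".class", label = ".class"
)

.normalizeName <- function(x) {
  key <- gsub("[^a-z0-9]", "", tolower(x))
  out <- unname(.FEATURE_ALIASES[key])
  ## canonical identifiers normalise to themselves
  canon <- gsub("[^a-z0-9]", "", .VITAL_FEATURES)
  miss <- is.na(out) & key %in% canon
  out[miss] <- .VITAL_FEATURES[match(key[miss], canon)]
  out
}

#' Derive the PEF class of a record
#'
#' The binary classification target is peak expiratory flow (PEF) below or at
#' least 400 L/min: values `>= 400` are class `"high"`, values below are
#' `"low"`. The boundary value 400 itself maps to `"high"`.
#'
#' @param pef Numeric vector of PEF values in L/min; must be finite and
#'   strictly positive.
#' @return Factor with levels `c("low", "high")`.
#' @examples
#' deriveLabel(c(450, 399.9, 400))
#' @export
deriveLabel <- function(pef) {
  if (!is.numeric(pef) || length(pef) == 0L)
    stop("'pef' must be a non-empty numeric vector")
  if (any(!is.finite(pef)) || any(pef <= 0))
    stop("PEF values must be finite and positive; offending index: ",
         which(!is.finite(pef) | pef <= 0)[1L])
  factor(ifelse(pef >= .PEF_THRESHOLD, "high", "low"), levels = .CLASS_LEVELS)
}
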