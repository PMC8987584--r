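registry_path <- function(file)
  system.file("extdata", file, package = "anisohead", mustWork = TRUE)

registry_json <- local({
  cache <- new.env(parent = emptyenv())
  function(file) {
    if (!exists(file, envir = cache))
      assign(file, jsonlite::fromJSON(registry_path(file),
                                      simplifyVector = TRUE),
             envir = cache)
    get(file, envir = cache)
  }
})

#' Brain material parameter registry
#'
#' @return named list of [material_params()] objects, one per brain
#'   structure (`c6` resolved).
#' @export
material_registry <- function() {
  raw <- registry_json("materials.json")$brain
  out <- lapply(names(raw), function(nm) {
    r <- raw[[nm]]
    material_params(name = nm, rho = r$rho, c1 = r$c1, c2 = r$c2,
                    c3 = r$c3, c4 = r$c4, c5 = r$c5,
                    lambda_star = r$lambda_star, k_bulk = r$k_bulk,
                    beta_s = r$beta_s,
                    fiber_dir = r$fiber_dir)
  })
  names(out) <- names(raw)
  out
}

#' Extracranial material constants (stored, not simulated)
#'
#' Linear-plastic bone and viscoelastic flesh/scalp constants for the
#' extracranial head structures. These are reference constants only; the
#' material-point driver simulates the brain law.
#'
#' @return named list of constant sets with a `_units` entry.
#' @export
extracranial_registry <- function() registry_json("materials.json")$extracranial

#' Fixed injury risk model registry
#'
#' @return named list of `risk_model` objects with provenance
#'   `"paper-fixed"`.
#' @export
risk_registry <- function() {
  raw <- registry_json("risk_models.json")
  raw <- raw[setdiff(names(raw), "_meta")]
  out <- lapply(raw, function(r) {
    if (r$family == "logistic")
      risk_model("logistic", kappa = r$kappa, delta = r$delta,
                 predictor_name = r$predictor, units = r$units,
                 provenance = "paper-fixed")
    else
      risk_model(r$family, scale = r$scale, shape = r$shape,
                 predictor_name = r$predictor, units = r$units,
                 provenance = "paper-fixed")
  })
  out
}

#' Fracture criteria registry
#'
#' @return named list of tissue thresholds (`quantity` = `"strain"` or
#'   `"stress"`, `threshold`, `units`).
#' @export
fracture_criteria <- function() {
  raw <- registry_json("fracture_criteria.json")
  raw[setdiff(names(raw), "_meta")]
}

#' Diffuse brain injury reference levels
#'
#' @return list with `low_risk` and `ais4plus` reference levels for
#'   MPS, MPSR (1/s), and MPS x MPSR (1/s).
#' @export
diffuse_reference <- function() {
  raw <- registry_json("diffuse_reference.json")
  raw[setdiff(names(raw), "_meta")]
}

#' Load a named object from the packaged registries
#'
#' Looks the name up across the material, risk-model, and fracture
#' registries and returns the immutable packaged object. Unknown names
#' raise an error listing the available keys.
#'
#' @param name registry key, e.g. `"corpus_callosum"`,
#'   `"asdh_weibull_v6"`, `"skull_tables_fracture"`.
#' @return a `material_params`, `risk_model`, or fracture criterion.
#' @examples
#' registry_load("corpus_callosum")$c1
#' registry_load("asdh_weibull_v6")$coefficients$scale
#' @export
registry_load <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  mats <- material_registry()
  if (name %in% names(mats)) return(mats[[name]])
  risks <- risk_registry()
  if (name %in% names(risks)) return(risks[[name]])
  fr <- fracture_criteria()
  if (name %in% names(fr)) return(fr[[name]])
  stop("unknown registry key '", name, "'; available: ",
       paste(c(names(mats), names(risks), names(fr)), collapse = ", "))
}
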