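#' Describe one cohort variable
#'
#' A variable specification records how a column of a patient cohort is
#' typed and, for laboratory analytes, its unit and clinical reference
#' interval. Reference intervals may be sex-specific (as for ALAT,
#' hemoglobin, creatinine and platelets) and may be one-sided upper limits
#' (such as CRP "< 6 mg/L"), encoded with a missing lower bound.
#'
#' @param name Variable name; must match the cohort CSV column.
#' @param kind One of `"outcome"`, `"discrete"`, `"continuous"`.
#' @param states Ordered state labels (outcome and discrete variables only).
#' @param unit Free-text unit, e.g. `"U/L"`.
#' @param reference For continuous variables, either `c(low, high)` (with
#'   `NA` for a missing lower bound of a one-sided upper limit) or a named
#'   list `list(female = c(low, high), male = c(low, high))`.
#' @param lab Logical; does this variable count towards the laboratory-panel
#'   inclusion filter?
#'
#' @return An object of class `"variable_spec"`.
#' @export
variable_spec <- function(name,
                          kind = c("continuous", "discrete", "outcome"),
                          states = NULL, unit = "", reference = NULL,
                          lab = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("discrete", "outcome")) {
    if (is.null(states) || length(states) == 0)
      stop_("variable '", name, "': discrete variables need states")
    if (anyDuplicated(states))
      stop_("variable '", name, "': duplicated states")
    if (kind == "outcome" && length(states) != 2L)
      stop_("outcome variable must be binary")
  }
  if (!is.null(reference)) {
    check_bounds <- function(b) {
      if (length(b) != 2L) stop_("variable '", name, "': reference must be (low, high)")
      if (!is.na(b[1]) && !is.na(b[2]) && b[1] >= b[2])
        stop_("variable '", name, "': reference low must be < high")
    }
    if (is.list(reference)) lapply(reference, check_bounds) else check_bounds(reference)
  }
  structure(list(name = name, kind = kind, states = states, unit = unit,
                 reference = reference,
                 lab = isTRUE(lab %||% (kind == "continuous"))),
            class = "variable_spec")
}

#' Build a variable registry
#'
#' @param ... `variable_spec` objects (or a single list of them).
#' @return Object of class `"bn_registry"`: a named list of specs in the
#'   given order. The order is the package's canonical node order and is
#'   used for every deterministic tie-break.
#' @export
bn_registry <- function(...) {
  specs <- list(...)
  if (length(specs) == 1L && !inherits(specs[[1]], "variable_spec"))
    specs <- specs[[1]]
  stopifnot(all(vapply(specs, inherits, TRUE, "variable_spec")))
  names(specs) <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(names(specs))) stop_("duplicated variable names in registry")
  n_out <- sum(vapply(specs, function(s) s$kind == "outcome", TRUE))
  if (n_out != 1L) stop_("registry must contain exactly one outcome variable")
  structure(specs, class = "bn_registry")
}

registry_names <- function(registry) names(registry)

outcome_var <- function(registry) {
  names(registry)[vapply(registry, function(s) s$kind == "outcome", TRUE)]
}

lab_vars <- function(registry) {
  names(registry)[vapply(registry, function(s) isTRUE(s$lab), TRUE)]
}

continuous_vars <- function(registry) {
  names(registry)[vapply(registry, function(s) s$kind == "continuous", TRUE)]
}

discrete_vars <- function(registry) {
  names(registry)[vapply(registry, function(s) s$kind != "continuous", TRUE)]
}

#' @export
print.bn_registry <- function(x, ...) {
  cat("<bn_registry> ", length(x), " variables (outcome: ", outcome_var(x),
      "; ", length(lab_vars(x)), " labs)\n", sep = "")
  invisible(x)
}

#' Read / write a variable registry as YAML
#'
#' @param path File path.
#' @return `read_registry` returns a `"bn_registry"`.
#' @export
read_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  specs <- lapply(raw, function(e) {
    ref <- e$reference
    if (!is.null(ref)) {
      sex_specific <- is.list(ref) && !is.null(names(ref)) &&
        all(nzchar(names(ref)))
      ref <- if (sex_specific) lapply(ref, function(b) as.numeric(unlist(b)))
      else as.numeric(unlist(ref))
    }
    variable_spec(name = e$name, kind = e$kind,
                  states = if (!is.null(e$states)) as.character(e$states),
                  unit = e$unit %||% "", reference = ref,
                  lab = e$lab %||% NULL)
  })
  bn_registry(specs)
}

#' @rdname read_registry
#' @param registry A `"bn_registry"`.
#' @export
write_registry <- function(registry, path) {
  raw <- lapply(unclass(registry), function(s) {
    out <- list(name = s$name, kind = s$kind, unit = s$unit, lab = s$lab)
    if (!is.null(s$states)) out$states <- as.list(s$states)
    if (!is.null(s$reference)) {
      out$reference <- if (is.list(s$reference))
        lapply(s$reference, as.list) else as.list(s$reference)
    }
    out
  })
  yaml::write_yaml(unname(raw), path)
  invisible(path)
}

#' Default lung-cancer cohort registry
#'
#' The bundled registry of the 24 model variables: the binary outcome `LC`,
#' demographics (`age`, `sex`, `smoking`) and the panel of 20 routine blood
#' analyses with their units and clinical reference intervals (sex-specific
#' for ALAT, hemoglobin, creatinine and platelets; one-sided upper limits
#' for basophils, eosinophils, CRP and INR).
#'
#' @return A `"bn_registry"`.
#' @export
default_lc_registry <- function() {
  read_registry(system.file("extdata", "lc_registry.yaml",
                            package = "bnscreen", mustWork = TRUE))
}
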