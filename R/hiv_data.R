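#' Surveillance and survey data for the London MSM HIV model
#'
#' Bundles the observed counts from the six data sources feeding the
#' evidence-synthesis model of HIV prevalence among men who have sex with men
#' (MSM) in London, 2012:
#'
#' * `ypop`: male population denominator (ONS mid-year estimate). The
#'   surveillance model family describes men aged 15-44; the default is the
#'   approximate mid-2012 count of London males in that age band.
#' * NATSAL survey: `y_G`, `y_N`, `y_P` men reporting to be GUM-clinic
#'   attending MSM (GMSM), non-attending MSM (NGMSM) and former MSM (PMSM)
#'   out of `y_NAT` men interviewed.
#' * SOPHID register: `y_M` prevalent diagnosed HIV-positive MSM.
#' * HANDD register: `y_H` new GUM-clinic diagnoses among MSM.
#' * GUMCAD testing cascade: `g1` clinic attenders, `g2` with no previous
#'   diagnosis, `g3` offered a test, `g4` tested, `g5` diagnosed.
#' * GUM Anon survey: `g_A` positive among `g_AN` previously undiagnosed
#'   attenders.
#' * GMSHS venue survey: `y_G_GM`/`n_G_GM` and `y_N_GM`/`n_N_GM` positives and
#'   denominators among previously undiagnosed GMSM and NGMSM.
#'
#' @param ... Named overrides of any field.
#' @return A named list of counts with class `hiv_observations`.
#' @export
hiv_observations <- function(...) {
  obs <- list(
    ypop = 2060000,
    y_G = 7, y_N = 38, y_P = 10, y_NAT = 824,
    y_M = 8390,
    y_H = 630,
    g1 = 35121, g2 = 34187, g3 = 30570, g4 = 29529, g5 = 855,
    g_A = 4, g_AN = 85,
    y_G_GM = 20, n_G_GM = 493, y_N_GM = 20, n_N_GM = 452
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(obs))
    if (length(unknown) || is.null(names(dots)) || any(names(dots) == "")) {
      abort(sprintf("Unknown observation fields: %s",
                    paste(unknown, collapse = ", ")))
    }
    obs[names(dots)] <- dots
  }
  validate_hiv_observations(obs)
}

validate_hiv_observations <- function(obs) {
  num <- unlist(obs)
  if (!all(is.finite(num)) || any(num < 0) || any(num != round(num))) {
    abort("All observations must be nonnegative integers.")
  }
  with(obs, {
    if (!(g1 >= g2 && g2 >= g3 && g3 >= g4 && g4 >= g5)) {
      abort("GUMCAD cascade counts must be nonincreasing (g1 >= ... >= g5).")
    }
    if (y_G + y_N + y_P > y_NAT) abort("NATSAL subgroup counts exceed the sample size.")
    if (g_A > g_AN) abort("GUM Anon positives exceed the denominator.")
    if (y_G_GM > n_G_GM || y_N_GM > n_N_GM) abort("GMSHS positives exceed denominators.")
  })
  structure(obs, class = c("hiv_observations", "list"))
}

#' Read or write HIV observations as YAML
#'
#' @param path Path to a YAML file whose keys are the `hiv_observations`
#'   field names.
#' @return `read_hiv_observations()` returns an `hiv_observations` list.
#' @export
read_hiv_observations <- function(path) {
  do.call(hiv_observations, yaml::read_yaml(path))
}

#' @param obs An `hiv_observations` object.
#' @rdname read_hiv_observations
#' @export
write_hiv_observations <- function(obs, path) {
  stopifnot(inherits(obs, "hiv_observations"))
  yaml::write_yaml(unclass(obs), path)
  invisible(path)
}

#' @export
print.hiv_observations <- function(x, ...) {
  cat("<hiv_observations> London MSM surveillance data\n")
  utils::str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}
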