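#' Load a forcefield parameter file
#'
#' Reads the YAML parameter schema (coupling constants, equilibrium
#' distances/angles, screening constants, cutoffs, heme charges and internal
#' force constants).  Every key of the schema must be present; a missing key
#' is a load error, never a silent default.
#'
#' @param path path to a YAML parameter file; by default the curated set
#'   shipped with the package.
#' @return a [ParameterSet-class]
#' @export
loadParameters <- function(path = defaultParameterFile()) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  values <- yaml::read_yaml(path)
  ps <- new("ParameterSet", values = values)
  validObject(ps)
  ps
}

#' Path of the packaged default parameter file
#' @export
defaultParameterFile <- function() {
  system.file("extdata", "heme_params.yaml", package = "hemefold",
              mustWork = TRUE)
}

#' @rdname loadParameters
#' @export
defaultParameters <- function() loadParameters()

# fetch a nested parameter, erroring on absence
pget <- function(params, ...) {
  keys <- c(...)
  v <- params@values
  for (k in keys) {
    v <- v[[k]]
    if (is.null(v)) stop("missing parameter key: ", paste(keys, collapse = "."))
  }
  v
}

# per-residue-type lookup with explicit default entry (three-letter keys)
residueParam <- function(tbl, aa1) {
  key <- AA3[aa1]
  out <- vapply(key, function(k) {
    v <- tbl[[k]]
    if (is.null(v)) tbl[["default"]] else v
  }, numeric(1))
  unname(out)
}

#' Modify one parameter value
#'
#' Returns a copy of `params` with the value at the dotted key path replaced,
#' e.g. `setParam(p, "fe_cc.r0", 0.5)`.
#'
#' @param params a [ParameterSet-class]
#' @param key dotted key path into the schema
#' @param value replacement value
#' @export
setParam <- function(params, key, value) {
  keys <- strsplit(key, ".", fixed = TRUE)[[1]]
  v <- params@values
  assign_rec <- function(lst, keys, value) {
    if (length(keys) == 1) { lst[[keys]] <- value; return(lst) }
    lst[[keys[1]]] <- assign_rec(lst[[keys[1]]], keys[-1], value)
    lst
  }
  ps <- new("ParameterSet", values = assign_rec(v, keys, value))
  validObject(ps)
  ps
}

#' Zero selected heme-protein coupling terms
#'
#' Used for apo-vs-holo control runs: returns a parameter set in which the
#' named coupling terms have all their strength constants set to zero.
#'
#' @param params a [ParameterSet-class]
#' @param terms any of "fe_cc", "thioester", "elec", "hb_backbone",
#'   "hb_sidechain", "burial"
#' @export
zeroCoupling <- function(params, terms) {
  v <- params@values
  for (tm in terms) {
    switch(tm,
      fe_cc = { v$fe_cc$lambda <- lapply(v$fe_cc$lambda, function(x) 0) },
      thioester = { v$thioester$lambda_cs <- 0 },
      elec = { v$elec$lambda <- 0 },
      hb_backbone = { v$hb_backbone$lambda <- 0 },
      hb_sidechain = { v$hb_sidechain$lambda <-
                         lapply(v$hb_sidechain$lambda, function(x) 0) },
      burial = { v$burial$lambda <- 0 },
      stop("unknown coupling term: ", tm))
  }
  ps <- new("ParameterSet", values = v)
  validObject(ps)
  ps
}
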