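# Parameter handling: reference sets are shipped as plain-text fixtures
# (key = value, one file per model) and validated on load.

.param_dir <- function() system.file("extdata", "parameters", package = "cdkclock")

.read_kv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad))
    stop("malformed parameter line in ", basename(path), ": ", lines[bad][1])
  vals <- vapply(kv, function(x) suppressWarnings(as.numeric(trimws(x[2]))), numeric(1))
  names(vals) <- vapply(kv, function(x) trimws(x[1]), character(1))
  if (anyNA(vals))
    stop("non-numeric parameter value in ", basename(path))
  as.list(vals)
}

#' Reference parameter set for one cell-cycle model
#'
#' Returns the published reference rate constants, Michaelis-type constants
#' and total concentrations for one of the four model variants, read from
#' the versioned plain-text fixtures shipped with the package.  Time is in
#' minutes, concentrations are dimensionless activity units.
#'
#' @param model_id One of \code{"model1"} (negative-feedback oscillator),
#'   \code{"model2"} (Gwl/ENSA/B55 feed-forward loop), \code{"model3"}
#'   (bistable APC/C) or \code{"model4"} (dual-bistable switch network).
#'   Bare integers 1-4 are accepted.
#' @return Named list of parameters (class \code{"cc_params"}).
#' @export
#' @examples
#' p <- table1_parameters("model1")
#' p$ksy_cycb
table1_parameters <- function(model_id) {
  id <- .canon_model_id(model_id)
  path <- file.path(.param_dir(), paste0(id, ".txt"))
  if (!file.exists(path)) stop("no parameter fixture for '", id, "'")
  p <- .read_kv(path)
  validate_parameters(p, id)
  structure(p, class = "cc_params", model_id = id)
}

.canon_model_id <- function(model_id) {
  if (is.numeric(model_id)) model_id <- paste0("model", model_id)
  model_id <- as.character(model_id)
  if (identical(model_id, "model4_size")) return("model4")
  if (!model_id %in% paste0("model", 1:4))
    stop("unknown model id: ", model_id)
  model_id
}

# Totals whose conservation law is actually used by each model: these must be
# strictly positive.  All other parameters only need to be non-negative.
.required_positive <- list(
  model1 = c("Kin_tot", "APC_tot", "Jph_kin", "Jdp_kin", "Jph_apc", "Jdp_apc"),
  model2 = c("Gwl_tot", "APC_tot", "Cdc20_tot", "B55_tot", "ENSA_tot", "Km_tqssa", "deUb"),
  model3 = c("Gwl_tot", "APC_tot", "Cdc20_tot", "B55_tot", "ENSA_tot", "Km_tqssa", "deUb"),
  model4 = c("Gwl_tot", "APC_tot", "Cdc20_tot", "B55_tot", "ENSA_tot",
             "Km_tqssa", "deUb", "CAP", "Wee1_tot", "Cdc25_tot")
)

#' Validate a parameter set
#'
#' Checks non-negativity of every rate constant and strict positivity of the
#' totals and Michaelis-type constants the model's conservation laws and
#' closures divide by.
#'
#' @param params Named list of parameter values.
#' @param model_id Model the set is intended for (see [table1_parameters()]).
#' @return The validated parameter list, invisibly.
#' @export
validate_parameters <- function(params, model_id) {
  id <- .canon_model_id(model_id)
  vals <- unlist(params)
  if (any(!is.finite(vals)))
    stop("parameters must be finite numbers")
  if (any(vals < 0))
    stop("negative parameter value: ",
         paste(names(vals)[vals < 0], collapse = ", "))
  need <- .required_positive[[id]]
  missing <- setdiff(need, names(params))
  if (length(missing))
    stop("missing required parameter(s) for ", id, ": ",
         paste(missing, collapse = ", "))
  zero <- need[unlist(params[need]) <= 0]
  if (length(zero))
    stop("parameter(s) must be strictly positive for ", id, ": ",
         paste(zero, collapse = ", "))
  invisible(params)
}

#' Override entries of a parameter set
#'
#' @param params Parameter list (as from [table1_parameters()]).
#' @param ... Named scalar overrides, e.g. \code{Cdc25_tot = 0.4}.
#' @return Modified parameter list; unknown names are an error.
#' @export
set_parameters <- function(params, ...) {
  ov <- list(...)
  if (length(ov) == 0L) return(params)
  unknown <- setdiff(names(ov), names(params))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  params[names(ov)] <- ov
  params
}

#' @export
print.cc_params <- function(x, ...) {
  cat("<cc_params> reference set for", attr(x, "model_id"), "\n")
  v <- unlist(x)
  print(v)
  invisible(x)
}
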