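# Tabular export and the command-line front end.  All analyses are
# deterministic; identical inputs give byte-identical CSV output (numbers
# serialised at 12 significant digits).

.fmt_df <- function(d, digits = 12) {
  for (j in seq_along(d)) if (is.numeric(d[[j]])) d[[j]] <- signif(d[[j]], digits)
  d
}

#' Export an analysis result as tidy CSV with a JSON metadata sidecar
#'
#' Trajectories become one row per output time (state plus derived
#' columns), lineages one row per division, branches one row per branch
#' point with a point-type column (\code{regular}/\code{fold}/\code{hopf}),
#' nullclines one row per curve point.  A sidecar \code{<stem>_meta.json}
#' records the model id, parameters, tolerances and package version.
#'
#' @param result Object from any analysis function.
#' @param stem Output path stem (without extension).
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(result, stem) {
  meta <- list(package = "cdkclock",
               version = as.character(utils::packageVersion("cdkclock")),
               deterministic = TRUE)
  if (inherits(result, "cc_trajectory")) {
    d <- data.frame(time = result$times, result$states, check.names = FALSE)
    if (!is.null(result$derived) && length(result$derived))
      d <- cbind(d, result$derived)
    meta <- c(meta, list(model = result$model_id, rtol = result$rtol,
                         atol = result$atol,
                         params = unclass(result$params)))
  } else if (inherits(result, "cc_lineage")) {
    d <- result$divisions
    meta <- c(meta, list(model = "model4_size", mu = result$mu,
                         v0 = result$v0,
                         entry_threshold = result$entry_threshold,
                         exit_threshold = result$exit_threshold,
                         params = unclass(result$trajectory$params)))
  } else if (inherits(result, "cc_branch")) {
    d <- result$points
    d$point_type <- "regular"
    for (f in result$folds) {
      i <- which.min(abs(d[[result$free_param]] - f$param))
      d$point_type[i] <- "fold"
    }
    for (h in result$hopfs) {
      i <- which.min(abs(d[[result$free_param]] - h$param))
      d$point_type[i] <- "hopf"
    }
    meta <- c(meta, list(model = result$model_id, free_param = result$free_param,
                         folds = lapply(result$folds, `[[`, "param"),
                         hopfs = lapply(result$hopfs, `[[`, "param")))
  } else if (inherits(result, "cc_nullcline")) {
    d <- result$curve
    meta <- c(meta, list(model = result$model_id, clamp = result$clamp_var,
                         response = result$response_var, shape = result$shape,
                         folds = lapply(result$folds, `[[`, "param")))
  } else if (inherits(result, "cc_limit_cycle")) {
    d <- if (result$oscillating) as.data.frame(result$orbit)
         else data.frame(time = numeric(0))
    meta <- c(meta, list(model = result$model_id,
                         oscillating = result$oscillating,
                         period_min = result$period,
                         converged = result$converged))
  } else if (is.data.frame(result)) {
    d <- as.data.frame(result)
  } else if (is.list(result) && !is.null(result$classification)) {
    d <- data.frame(classification = result$classification,
                    t(result$terminal_state))
    meta <- c(meta, list(classification = result$classification))
  } else stop("don't know how to export an object of class ",
              paste(class(result), collapse = "/"))
  csv <- paste0(stem, ".csv")
  js <- paste0(stem, "_meta.json")
  utils::write.csv(.fmt_df(d), csv, row.names = FALSE)
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv = csv, meta = js))
}

.cli_usage <- function() {
  cat("usage: <prog> SUBCOMMAND [--scenario ID] [--out DIR] [--param K=V ...]\n",
      "subcommands: simulate cycle nullcline branch envelope checkpoint",
      "sizecycle list-scenarios\n")
}

.parse_cli_args <- function(args) {
  out <- list(params = list())
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    take <- function() { i <<- i + 1L; if (i > length(args)) stop("missing value after ", a); args[i] }
    switch(a,
      "--scenario" = out$scenario <- take(),
      "--model" = out$model <- take(),
      "--out" = out$out <- take(),
      "--tspan" = out$tspan <- as.numeric(strsplit(take(), ",")[[1]]),
      "--rtol" = out$rtol <- as.numeric(take()),
      "--atol" = out$atol <- as.numeric(take()),
      "--param" = {
        kv <- strsplit(take(), "=", fixed = TRUE)[[1]]
        if (length(kv) != 2L) stop("--param expects KEY=VALUE")
        out$params[[trimws(kv[1])]] <- as.numeric(kv[2])
      },
      stop("unknown argument: ", a))
    i <- i + 1L
  }
  out
}

#' Command-line entry point
#'
#' Thin dispatcher over the package's analysis functions, used by the
#' \code{inst/cli/cdkclock.R} script: runs a named scenario (or an explicit
#' model), writes tidy CSV plus JSON metadata into \code{--out}, and
#' returns a process exit status.  All computations are deterministic, so
#' identical invocations write byte-identical CSVs.
#'
#' @param arguments Character vector, e.g.
#'   \code{c("cycle", "--scenario", "fig2", "--out", "results")}.
#' @return Integer exit status (0 on success), invisibly.
#' @export
run_cli <- function(arguments = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(arguments)) { .cli_usage(); return(invisible(2L)) }
    sub <- arguments[1]
    opts <- .parse_cli_args(arguments[-1])
    if (sub == "list-scenarios") {
      print(list_scenarios())
      return(invisible(0L))
    }
    outdir <- opts$out %||% "."
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    sc <- if (!is.null(opts$scenario)) figure_scenario(opts$scenario)
          else if (!is.null(opts$model)) {
            structure(list(id = opts$model, model = opts$model,
                           params = table1_parameters(opts$model),
                           analysis = "simulate"), class = "cc_scenario")
          } else stop("need --scenario or --model")
    if (length(opts$params))
      sc$params <- do.call(set_parameters, c(list(sc$params), opts$params))
    sc$analysis <- switch(sub,
      simulate = "simulate", cycle = "cycle", nullcline = "nullcline",
      branch = "branch", envelope = "branch", checkpoint = "arrest",
      sizecycle = "sizecycle",
      stop("unknown subcommand: ", sub))
    extra <- list()
    if (sub == "simulate" && !is.null(opts$tspan)) extra$times <- opts$tspan
    if (!is.null(opts$rtol)) extra$rtol <- opts$rtol
    if (!is.null(opts$atol)) extra$atol <- opts$atol
    res <- do.call(run_scenario, c(list(sc), extra))
    paths <- write_outputs(res, file.path(outdir, paste0(sc$id, "_", sub)))
    if (sub == "cycle" && inherits(res, "cc_limit_cycle"))
      jsonlite::write_json(list(period_min = res$period,
                                oscillating = res$oscillating,
                                converged = res$converged),
                           file.path(outdir, paste0(sc$id, "_summary.json")),
                           auto_unbox = TRUE, digits = NA)
    message("wrote ", paste(paths, collapse = ", "))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
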