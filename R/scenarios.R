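# Named analysis presets: each scenario bundles a model, parameter
# overrides, an initial state and the analysis that regenerates the
# corresponding figure-level result, so that every headline number in the
# package documentation is reproducible by name.

.scenario_registry <- function() list(
  fig2 = list(model = "model1", overrides = list(), analysis = "cycle",
              note = "delayed negative-feedback oscillator, 46-min limit cycle"),
  fig3 = list(model = "model2", overrides = list(), analysis = "cycle",
              note = "Gwl/ENSA/B55 feed-forward loop; APC response monotone"),
  fig3_nullcline = list(model = "model2", overrides = list(),
              analysis = "nullcline", clamp = "MPF", clamp_range = c(1e-3, 1.4),
              response = "APCPC20",
              note = "APC/C pseudo-nullcline vs clamped MPF (monotone)"),
  fig4 = list(model = "model3", overrides = list(), analysis = "cycle",
              note = "B55 dephosphorylates Gwl; bistable APC/C switch"),
  fig4_nullcline = list(model = "model3", overrides = list(),
              analysis = "nullcline", clamp = "MPF", clamp_range = c(1e-3, 1.4),
              response = "APCPC20",
              note = "APC/C pseudo-nullcline vs clamped MPF (S-shaped)"),
  fig5 = list(model = "model4", overrides = list(), analysis = "cycle",
              note = "dual-bistable Wee1/Cdc25 + BEG network limit cycle"),
  fig5d = list(model = "model4", overrides = list(), analysis = "nullcline",
              clamp = "CycBT", clamp_range = c(0.2, 2), response = "MPF",
              note = "MPF pseudo-nullcline vs clamped total cyclin B (hysteresis)"),
  g2_arrest = list(model = "model4", overrides = list(Cdc25_tot = 0.4),
              analysis = "arrest",
              note = "G2 checkpoint: Cdc25 sequestration, high CycBT / low MPF"),
  sac_arrest = list(model = "model4", overrides = list(Cdc20_tot = 0.1),
              analysis = "arrest",
              note = "spindle checkpoint: Cdc20 sequestration, high MPF arrest"),
  sac_arrest_alt = list(model = "model4", overrides = list(Cdc20_tot = 0.2),
              analysis = "arrest",
              note = "spindle checkpoint, milder Cdc20 reduction (alternate set)"),
  g1_arrest = list(model = "model4", overrides = list(kde3_cycb = 0.2),
              analysis = "arrest",
              note = "G1 checkpoint: APC/C:Cdh1 degradation keeps CycBT low"),
  fig7b = list(model = "model4", overrides = list(), analysis = "branch",
              free_param = "Cdc25_tot", range = c(0.005, 1.3),
              note = "one-parameter diagram vs cell size V (= Cdc25_tot)"),
  size_cycle = list(model = "model4", overrides = list(), analysis = "sizecycle",
              mu = 0.005, v0 = 0.6, entry = 0.5, exit = 0.2, n_cycles = 10,
              note = "size-controlled division cycles, mu = 0.005/min")
)

#' List the shipped analysis scenarios
#'
#' @return Data frame of scenario ids, model ids, analysis kind and a
#'   one-line description.
#' @export
list_scenarios <- function() {
  reg <- .scenario_registry()
  data.frame(id = names(reg),
             model = vapply(reg, `[[`, character(1), "model"),
             analysis = vapply(reg, `[[`, character(1), "analysis"),
             note = vapply(reg, `[[`, character(1), "note"),
             row.names = NULL)
}

#' Retrieve a fully-specified scenario configuration
#'
#' @param scenario_id One of the ids listed by [list_scenarios()].
#' @return List (class \code{"cc_scenario"}) with the model, resolved
#'   parameters and analysis settings; pass to [run_scenario()].
#' @export
figure_scenario <- function(scenario_id) {
  reg <- .scenario_registry()
  cfg <- reg[[scenario_id]]
  if (is.null(cfg)) stop("unknown scenario id: ", scenario_id,
                         " (see list_scenarios())")
  cfg$id <- scenario_id
  cfg$params <- do.call(set_parameters,
                        c(list(table1_parameters(cfg$model)), cfg$overrides))
  structure(cfg, class = "cc_scenario")
}

#' Run a scenario end-to-end
#'
#' Executes the analysis a scenario names: limit-cycle characterisation,
#' arrest classification, pseudo-nullcline, one-parameter branch (with
#' cycle envelope), or the hybrid size-control simulation.
#'
#' @param scenario A \code{"cc_scenario"} from [figure_scenario()], or an id.
#' @param ... Passed on to the underlying analysis function.
#' @return The analysis result object.
#' @export
#' @examples
#' \donttest{
#' run_scenario("fig2")$period   # about 46 min
#' }
run_scenario <- function(scenario, ...) {
  if (is.character(scenario)) scenario <- figure_scenario(scenario)
  m <- cc_model(scenario$model, params = scenario$params)
  dots <- list(...)
  call_with <- function(fn, defaults) {
    defaults[names(dots)] <- dots
    do.call(fn, defaults)
  }
  switch(scenario$analysis,
    cycle = call_with(find_limit_cycle, list(model = m)),
    simulate = call_with(cc_integrate, list(model = m)),
    arrest = call_with(detect_arrest, list(model = m)),
    nullcline = call_with(pseudo_nullcline,
                          list(model = m, clamp_var = scenario$clamp,
                               clamp_range = scenario$clamp_range,
                               response_var = scenario$response)),
    branch = call_with(continue_branch,
                       list(model = m, free_param = scenario$free_param,
                            range = scenario$range, ds_max = 0.006)),
    sizecycle = call_with(simulate_size_control,
                          list(params = scenario$params, mu = scenario$mu,
                               v0 = scenario$v0,
                               entry_threshold = scenario$entry,
                               exit_threshold = scenario$exit,
                               n_cycles = scenario$n_cycles)),
    stop("unknown analysis kind: ", scenario$analysis))
}
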