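#' Build a registered model by name
#'
#' Registered names: `"rat-lv-2021"` (the bundled rat left-ventricular
#' model), `"toy-threshold"` and `"squid-axon"` (fixtures).
#'
#' @param name Registered model name or a path to a model-spec YAML/JSON
#'   file.
#' @export
build_model <- function(name) {
  switch(name,
         "rat-lv-2021" = build_rat_model(),
         "toy-threshold" = toy_threshold_model(),
         "squid-axon" = squid_axon_model(),
         {
           if (file.exists(name)) read_model_spec(name)
           else stop("unknown model '", name,
                     "' (not a registered name or an existing file)")
         })
}

.SPEC_KEYS <- c("name", "capacitance", "constants", "concentrations",
                "gates", "channels", "initial_state", "extra_dynamics",
                "params")

#' Read a declarative model-spec file
#'
#' YAML (or JSON) with sections `name`, `capacitance`, `constants`,
#' `concentrations`, `gates` (name, ss, tau, optional driver), `channels`
#' (name, g, gates, ion and/or E_fixed, optional rectification),
#' `initial_state` (ordered map), optional `extra_dynamics` (registered
#' name) and `params`.  Every structural invariant is checked at load and
#' violations are reported with the offending field.
#'
#' @param path File path.
#' @return A validated [cell_model()].
#' @export
read_model_spec <- function(path) {
  if (!file.exists(path)) stop("model spec file not found: ", path)
  spec <- yaml::read_yaml(path)
  unknown <- setdiff(names(spec), .SPEC_KEYS)
  if (length(unknown))
    stop("unknown model-spec field(s): ", paste(unknown, collapse = ", "))
  for (field in c("name", "capacitance", "gates", "channels", "initial_state"))
    if (is.null(spec[[field]]))
      stop("model spec is missing required field '", field, "'")
  gates <- lapply(spec$gates, function(g) {
    if (is.null(g$name) || is.null(g$ss) || is.null(g$tau))
      stop("gate entry missing name/ss/tau: ",
           paste(deparse(g), collapse = ""))
    gate_spec(g$name, ss = as.numeric(g$ss),
              tau = lapply(g$tau, as.numeric),
              driver = if (is.null(g$driver)) "V" else g$driver)
  })
  channels <- lapply(spec$channels, function(ch) {
    if (is.null(ch$name) || is.null(ch$g))
      stop("channel entry missing name/g")
    channel_spec(ch$name, g = ch$g,
                 gates = if (is.null(ch$gates)) list() else ch$gates,
                 ion = ch$ion, E_fixed = ch$E_fixed,
                 rectification = ch$rectification)
  })
  consts <- if (is.null(spec$constants)) physical_constants()
  else do.call(physical_constants, spec$constants)
  init <- unlist(spec$initial_state)
  cell_model(spec$name, gates = gates, channels = channels,
             capacitance = spec$capacitance, initial_state = init,
             constants = consts,
             concentrations = if (is.null(spec$concentrations)) list()
             else spec$concentrations,
             extra_dynamics = spec$extra_dynamics,
             params = if (is.null(spec$params)) list() else spec$params)
}

#' Write a model to a declarative spec file
#'
#' Inverse of [read_model_spec()]; round-trips every declarative parameter.
#' Models whose extra dynamics are an anonymous function (rather than a
#' registered name) cannot be exported.
#'
#' @param model A [cell_model()].
#' @param path Output file path (YAML).
#' @export
write_model_spec <- function(model, path) {
  if (is.function(model$extra_dynamics))
    stop("cannot export a model whose extra_dynamics is an anonymous function")
  spec <- list(
    name = model$name,
    capacitance = model$capacitance,
    constants = model$constants,
    concentrations = model$concentrations,
    gates = lapply(model$gates, function(g)
      list(name = g$name, ss = as.numeric(g$ss), tau = g$tau,
           driver = g$driver)),
    channels = lapply(model$channels, function(ch) {
      out <- list(name = ch$name, g = ch$g,
                  gates = lapply(ch$gates, function(gp)
                    list(gp$gate, gp$power)))
      if (!is.null(ch$ion)) out$ion <- ch$ion
      if (!is.null(ch$E_fixed)) out$E_fixed <- ch$E_fixed
      if (!is.null(ch$rectification)) out$rectification <- ch$rectification
      out
    }),
    initial_state = as.list(model$initial_state),
    extra_dynamics = model$extra_dynamics,
    params = model$params)
  spec <- spec[!vapply(spec, is.null, logical(1))]
  yaml::write_yaml(spec, path, precision = 12)
  invisible(path)
}

#' Write a trajectory as CSV (`t,V,<states...>`)
#' @param traj A trajectory.
#' @param path Output path.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- as.data.frame(traj)
  ord <- c("t", "V", setdiff(colnames(df), c("t", "V")))
  utils::write.csv(df[, ord], path, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory_csv()]
#' @param path File path.
#' @param baseline Pre-stimulus baseline potential; defaults to the first
#'   V sample.
#' @export
read_trajectory_csv <- function(path, baseline = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("t", "V") %in% names(df))) stop("trajectory CSV needs t and V columns")
  mat <- as.matrix(df[, setdiff(names(df), "t"), drop = FALSE])
  new_trajectory(df$t, mat, model_name = basename(path), protocol = NULL,
                 options = solver_options(output_dt = df$t[2] - df$t[1]),
                 baseline = if (is.null(baseline)) df$V[1] else baseline)
}

#' Serialise segmentation results to JSON
#'
#' @param phases A [segment_phases()] result.
#' @param iois A [make_iois()] table.
#' @param apd_marks Named APD durations (ms).
#' @param path Output path.
#' @param epochs Optional named list of per-gate epoch tables.
#' @export
write_regions_json <- function(phases, iois, apd_marks = NULL, path,
                               epochs = NULL) {
  obj <- list(
    phases = as.list(setNames(as.numeric(phases), names(phases))),
    baseline = attr(phases, "baseline"), peak = attr(phases, "peak"),
    iois = iois, apd = as.list(apd_marks))
  if (!is.null(epochs)) obj$epochs <- epochs
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Write analysis outputs and a reproducibility manifest
#'
#' @param table A `contribution_table` from [run_full_analysis()].
#' @param paths Named list of output paths; any of `contributions_csv`,
#'   `contributions_json`, `regions`, `trajectory`, `heatmap`, `manifest`.
#' @param traj Optional reference trajectory (for `trajectory`).
#' @param model Optional model (hashed into the manifest).
#' @param clip Heatmap display range; values are clipped to it.
#' @export
write_outputs <- function(table, paths, traj = NULL, model = NULL,
                          clip = c(-0.01, 0.01)) {
  if (!is.null(paths$contributions_csv)) {
    df <- cbind(gate = rownames(table), as.data.frame(table))
    utils::write.csv(df, paths$contributions_csv, row.names = FALSE)
  }
  if (!is.null(paths$contributions_json)) {
    obj <- list(delta = attr(table, "delta"),
                mode = as.list(attr(table, "mode")),
                table = cbind(gate = rownames(table), as.data.frame(table)),
                epochs = attr(table, "epochs"),
                errors = attr(table, "errors"))
    jsonlite::write_json(obj, paths$contributions_json, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
  }
  if (!is.null(paths$regions))
    write_regions_json(attr(table, "phases"), attr(table, "iois"),
                       attr(table, "apd"), paths$regions)
  if (!is.null(paths$trajectory) && !is.null(traj))
    write_trajectory_csv(traj, paths$trajectory)
  if (!is.null(paths$heatmap)) {
    m <- as.matrix(as.data.frame(table))
    m <- pmin(pmax(m, clip[1]), clip[2])
    utils::write.csv(cbind(gate = rownames(table), as.data.frame(m)),
                     paths$heatmap, row.names = FALSE)
  }
  if (!is.null(paths$manifest)) {
    manifest <- list(
      package = "apcontrib",
      version = as.character(utils::packageVersion("apcontrib")),
      r_version = R.version.string,
      model = if (is.null(model)) NULL else list(
        name = model$name,
        hash = rlang::hash(model[c("gates", "channels", "capacitance",
                                   "initial_state", "concentrations",
                                   "params")])),
      delta = attr(table, "delta"),
      aggregation_mode = as.list(attr(table, "mode")),
      phases = as.list(setNames(as.numeric(attr(table, "phases")),
                                names(attr(table, "phases")))),
      errors = attr(table, "errors"))
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(paths)
}
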