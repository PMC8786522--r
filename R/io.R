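# Config files, result serialization, and run manifests. Config files are
# YAML with an explicit schema; unknown keys are hard errors, applied
# defaults are logged.

config_schema <- list(
  top = c("name", "mode", "geometry", "layers", "materials", "shared",
          "boundaries", "schedule", "solver"),
  geometry = c("depth_mm", "height_mm", "width_mm", "spacing_mm"),
  layers = c("thicknesses_mm", "scalp_split_mm", "scalp_Qm_outer"),
  material = c("k", "rho", "c", "Qm"),
  shared = c("mb", "cb", "TA", "Qe", "he", "Tw"),
  boundaries = c("surface", "deep", "robin_order"),
  schedule = c("output_interval_s", "t_end_s", "reset_interval_s"),
  solver = c("init", "reset_action", "safety_factor")
)

check_keys <- function(block, allowed, where) {
  extra <- setdiff(names(block), allowed)
  if (length(extra)) {
    stop("load_config: unknown key(s) in ", where, ": ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
}

need_key <- function(block, key, where) {
  v <- block[[key]]
  if (is.null(v)) {
    stop("load_config: missing required key '", key, "' in ", where, call. = FALSE)
  }
  v
}

#' Load a scenario configuration from a YAML file or preset name
#'
#' Validates against the documented schema: unknown keys are errors, every
#' applied default is reported via `message()`.
#'
#' @param path Path to a YAML scenario file, or one of [preset_names()]
#'   (resolved to the shipped preset file).
#' @return A [scenario_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path) && path %in% preset_names()) {
    path <- system.file("extdata", "presets", paste0(path, ".yaml"),
                        package = "bioheat3d")
  }
  if (!file.exists(path)) {
    stop("load_config: no such config file or preset: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  check_keys(raw, config_schema$top, "top level")
  geo <- need_key(raw, "geometry", "top level")
  check_keys(geo, config_schema$geometry, "geometry")
  for (f in config_schema$geometry) need_key(geo, f, "geometry")
  grid <- build_grid(L = geo$depth_mm * 1e-3, H = geo$height_mm * 1e-3,
                     W = geo$width_mm * 1e-3, h = geo$spacing_mm * 1e-3)

  ly <- need_key(raw, "layers", "top level")
  check_keys(ly, config_schema$layers, "layers")
  th <- unlist(need_key(ly, "thicknesses_mm", "layers")) * 1e-3
  split <- if (!is.null(ly$scalp_split_mm)) ly$scalp_split_mm * 1e-3 else NULL
  layers <- layer_field(thicknesses = th, scalp_split = split,
                        scalp_Qm_outer = ly$scalp_Qm_outer %||% 0)
  if (is.null(ly$scalp_split_mm) && "scalp" %in% names(th)) {
    message("load_config: default applied: scalp_split_mm = ",
            layers$scalp_split * 1e3, " (scalp mid-thickness)")
  }

  mats_raw <- need_key(raw, "materials", "top level")
  materials <- lapply(names(mats_raw), function(nm) {
    m <- mats_raw[[nm]]
    check_keys(m, config_schema$material, paste0("materials$", nm))
    tissue_properties(k = need_key(m, "k", nm), rho = need_key(m, "rho", nm),
                      c = need_key(m, "c", nm), Qm = m$Qm %||% 0)
  })
  names(materials) <- names(mats_raw)

  shr <- need_key(raw, "shared", "top level")
  check_keys(shr, config_schema$shared, "shared")
  shared <- shared_constants(mb = need_key(shr, "mb", "shared"),
                             cb = need_key(shr, "cb", "shared"),
                             TA = need_key(shr, "TA", "shared"),
                             Qe = shr$Qe %||% 0,
                             he = need_key(shr, "he", "shared"),
                             Tw = need_key(shr, "Tw", "shared"))
  if (is.null(shr$Qe)) message("load_config: default applied: Qe = 0")

  bd <- raw$boundaries
  if (is.null(bd)) {
    message("load_config: default applied: boundaries = robin/dirichlet")
    bd <- list()
  }
  check_keys(bd, config_schema$boundaries, "boundaries")
  boundaries <- boundary_spec(surface = bd$surface %||% "robin",
                              deep = bd$deep %||% "dirichlet",
                              robin_order = bd$robin_order %||% 2L)

  mode <- raw$mode %||% "steady"
  schedule <- NULL
  if (!is.null(raw$schedule) || mode == "transient") {
    sc <- need_key(raw, "schedule", "top level (transient mode)")
    check_keys(sc, config_schema$schedule, "schedule")
    schedule <- list(output_interval = need_key(sc, "output_interval_s", "schedule"),
                     t_end = need_key(sc, "t_end_s", "schedule"),
                     reset_interval = need_key(sc, "reset_interval_s", "schedule"))
  }
  sv <- raw$solver %||% list()
  check_keys(sv, config_schema$solver, "solver")

  scenario_config(grid = grid, layers = layers, materials = materials,
                  shared = shared, boundaries = boundaries, mode = mode,
                  schedule = schedule,
                  init = sv$init %||% "linear",
                  reset_action = sv$reset_action %||% "clamp_surface_dirichlet",
                  safety_factor = sv$safety_factor %||% 0.9,
                  name = raw$name %||% tools::file_path_sans_ext(basename(path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Plain-list view of a config, used for hashing and manifests.
scenario_to_list <- function(cfg) {
  list(
    name = cfg$name, mode = cfg$mode,
    geometry = cfg$grid[c("L", "H", "W", "h")],
    layers = list(thicknesses = as.list(cfg$layers$thicknesses),
                  scalp_split = cfg$layers$scalp_split,
                  scalp_Qm_outer = cfg$layers$scalp_Qm_outer),
    materials = lapply(cfg$materials, unclass),
    shared = unclass(cfg$shared),
    boundaries = unclass(cfg$boundaries),
    schedule = cfg$schedule,
    solver = list(init = cfg$init, reset_action = cfg$reset_action,
                  safety_factor = cfg$safety_factor)
  )
}

#' Deterministic hash of a scenario configuration
#'
#' MD5 of the canonical YAML serialization; identical configs hash
#' identically across sessions.
#'
#' @param cfg A [scenario_config()].
#' @return Character MD5 hash.
#' @export
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(scenario_to_list(cfg)), tf)
  unname(tools::md5sum(tf))
}

#' Write result fields to CSV
#'
#' `"long"` layout: one row per node (and time), full precision, columns
#' `t_s, i, j, k, x_mm, y_mm, z_mm, layer, T_C`. `"table"` layout: the
#' reference-table grouping, temperatures formatted to 2 decimals, one
#' `T_C` column for steady fields or one `T_<m>min` column per snapshot;
#' when `fixture` is given only that table's nodes are written, in its row
#' order.
#'
#' @param fields A [temperature_field()], [run_transient()] result, or list
#'   of fields.
#' @param layout `"long"` or `"table"`.
#' @param path Output CSV path.
#' @param fixture Optional reference-table id restricting the table layout
#'   to the published node list.
#' @return A manifest entry (list with `path`, `layout`, `n_rows`, `times`),
#'   invisibly.
#' @export
write_results <- function(fields, layout = c("long", "table"), path,
                          fixture = NULL) {
  layout <- match.arg(layout)
  fl <- if (inherits(fields, "temperature_field")) list(fields)
        else if (inherits(fields, "transient_result")) fields$fields
        else fields
  if (length(fl) == 0L) stop("write_results: no fields to write", call. = FALSE)
  times <- vapply(fl, `[[`, numeric(1), "time")

  if (layout == "long") {
    out <- do.call(rbind, lapply(fl, function(f)
      cbind(t_s = f$time, as.data.frame(f))))
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    nodes <- if (!is.null(fixture)) {
      read_reference_table(fixture)[c("i", "j", "k")]
    } else {
      g <- fl[[1L]]$cfg$grid
      grid_nodes(g)[c("i", "j", "k")]
    }
    out <- nodes
    if (length(fl) == 1L && is.na(times[1L])) {
      out$T_C <- sprintf("%.2f", mapply(function(i, j, k)
        field_at(fl[[1L]], i, j, k), nodes$i, nodes$j, nodes$k))
    } else {
      for (n in seq_along(fl)) {
        col <- sprintf("T_%gmin", times[n] / 60)
        out[[col]] <- sprintf("%.2f", mapply(function(i, j, k)
          field_at(fl[[n]], i, j, k), nodes$i, nodes$j, nodes$k))
      }
    }
    utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  }
  invisible(list(path = path, layout = layout, n_rows = nrow(out), times = times))
}

#' Write a run manifest
#'
#' JSON record tying a run's outputs to the exact configuration: scenario
#' name, config hash, mode, solver settings, output files, residuals.
#'
#' @param cfg The [scenario_config()] that was run.
#' @param entries List of manifest entries from [write_results()].
#' @param path Output JSON path.
#' @param extra Named list of additional fields (residuals, substep counts).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(cfg, entries, path, extra = list()) {
  man <- c(list(
    scenario = cfg$name,
    config_hash = config_hash(cfg),
    mode = cfg$mode,
    solver = list(surface = cfg$boundaries$surface,
                  deep = cfg$boundaries$deep,
                  robin_order = cfg$boundaries$robin_order,
                  init = cfg$init,
                  safety_factor = cfg$safety_factor),
    outputs = entries,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
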