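#' Default configuration presets
#'
#' Complete, nested configuration lists for the shipped model presets.
#' `"desk-healthy"` and `"desk-mi"` are the desk-scale study
#' conditions (32 x 32 x 40 grid, dx = 15/32 cm, coarse idealized LV);
#' `"healthy"` and `"mi-patient"` carry the cluster-scale settings
#' (96 x 96 x 128 grid, dx = 0.156 cm, time steps 1.22e-4 / 3.0e-5 s)
#' together with the subject-derived values: end-diastolic/end-systolic
#' pressures 8/150 mmHg (healthy) and 16/110 mmHg (patient), measured
#' volume targets 143/61 and 116/86 ml, `T_scale` 3.0 and 5.5, and the
#' infarct passive scaling `c_a_mi = 7.5`.
#'
#' @param preset preset name.
#' @return A nested configuration list with sections `geometry`,
#'   `grid`, `passive`, `active`, `protocol`, `infarct`, `estimation`.
#' @export
default_config <- function(preset = c("desk-healthy", "desk-mi", "healthy",
                                      "mi-patient")) {
  preset <- match.arg(preset)
  desk <- preset %in% c("desk-healthy", "desk-mi")
  mi <- preset %in% c("desk-mi", "mi-patient")
  cfg <- list(
    preset = preset,
    geometry = list(radius_endo = 2.0, wall_thickness = 1.1,
                    apex_to_base = 6.0, truncation_height = 2.0,
                    edge_length = if (desk) 0.55 else 0.3),
    grid = list(n = if (desk) c(32, 32, 40) else c(96, 96, 128),
                dx = if (desk) 15 / 32 else 0.156,
                rho = 1.0, mu = 0.04, div_tol = 1e-9),
    passive = list(a = 0.24, b = 5.08, af = 1.46, bf = 4.15, as_ = 0.87,
                   bs = 1.6, afs = 0.3, bfs = 1.3, beta_s = 100,
                   c_a_mi = if (mi) 7.5 else 1),
    active = list(T_scale = if (mi) 5.5 else 3.0),
    protocol = list(preset = if (desk) {
      if (mi) "desk-mi" else "desk-healthy"
    } else {
      if (mi) "mi-patient" else "healthy"
    }),
    infarct = if (mi) list(target_fraction = 0.6, l_bz = 1.0,
                           center_azimuth = 180, center_height = 0.75)
              else NULL,
    estimation = list(
      target_edv = if (mi) 116 else 143,
      target_esv = if (mi) 86 else 61,
      tol = 0.05, max_iter = 20,
      t_scale_bracket = c(0.5, 10), c_a_bracket = c(1, 20)),
    basal = list(kappa = 2e6)
  )
  cfg
}

#' Read a configuration file
#'
#' Reads a YAML configuration and merges it (recursively) over a
#' preset from [default_config()], so a file only needs to state the
#' values it changes.
#'
#' @param path path to a YAML file (or `NULL` for the preset alone).
#' @param preset base preset name.
#' @return A configuration list.
#' @export
read_config <- function(path = NULL, preset = "desk-healthy") {
  cfg <- default_config(preset)
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (!is.null(user$preset)) cfg <- default_config(user$preset)
    cfg <- merge_lists(cfg, user)
  }
  cfg
}

merge_lists <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_lists(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Build a model from a configuration
#'
#' Convenience constructor: generates the idealized LV (and synthetic
#' infarct for the MI presets), applies the passive/active parameter
#' sets and returns the assembled [lv_model()] plus the matching
#' [loading_protocol()].
#'
#' @param cfg a configuration list from [default_config()] or
#'   [read_config()].
#' @return A list with `model`, `protocol`, `config`.
#' @export
build_model <- function(cfg = default_config()) {
  g <- cfg$geometry
  mesh <- make_idealized_lv(radius_endo = g$radius_endo,
                            wall_thickness = g$wall_thickness,
                            apex_to_base = g$apex_to_base,
                            truncation_height = g$truncation_height,
                            edge_length = g$edge_length)
  pp <- cfg$passive
  passive <- passive_params(a = pp$a, b = pp$b, af = pp$af * pp$c_a_mi,
                            bf = pp$bf, as_ = pp$as_ * pp$c_a_mi, bs = pp$bs,
                            afs = pp$afs * pp$c_a_mi, bfs = pp$bfs,
                            beta_s = pp$beta_s)
  infarct <- NULL
  if (!is.null(cfg$infarct)) {
    ic <- cfg$infarct
    infarct <- make_synthetic_infarct(mesh,
                                      center_azimuth = ic$center_azimuth,
                                      center_height = ic$center_height,
                                      target_fraction = ic$target_fraction,
                                      l_bz = ic$l_bz)
  }
  model <- lv_model(mesh, passive = passive, active = active_params(),
                    infarct = infarct, T_scale = cfg$active$T_scale,
                    grid_n = cfg$grid$n, dx = cfg$grid$dx,
                    rho = cfg$grid$rho, mu = cfg$grid$mu,
                    kappa_basal = cfg$basal$kappa,
                    div_tol = cfg$grid$div_tol)
  protocol <- loading_protocol(cfg$protocol$preset)
  extra <- setdiff(names(cfg$protocol), "preset")
  if (length(extra)) {
    protocol <- do.call(loading_protocol,
                        c(list(preset = cfg$protocol$preset),
                          cfg$protocol[extra]))
  }
  list(model = model, protocol = protocol, config = cfg)
}
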