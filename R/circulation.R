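# Compartment kinds (integer codes shared with the compiled stepping loop)
KIND_VESSEL <- 0L
KIND_CHAMBER <- 1L
KIND_SOURCE <- 2L

#' Compartment and connector constructors
#'
#' Building blocks for circulation networks. A compartment stores volume
#' (compliant vessel or heart chamber) or imposes a fixed pressure
#' (source); a connector carries flow between two compartments through a
#' resistance, either bidirectionally (resistor) or forward-only (valve).
#' The ready-made topologies are [build_ihl()] and [build_ccl()];
#' [build_circulation()] assembles arbitrary networks from these parts.
#'
#' @param id compartment/connector name.
#' @param compliance vessel compliance, ml/mmHg, > 0.
#' @param v_unstressed vessel unstressed volume, ml, >= 0.
#' @param e_min,e_max_ref,v0 chamber elastance bounds (mmHg/ml) and
#'   unstressed volume (ml).
#' @param contractility percent of reference inotropy; scales `e_max_ref`.
#' @param role `"ventricle"` or `"atrium"`: selects which trigger window
#'   drives the chamber.
#' @param pressure fixed pressure of a source compartment, mmHg.
#' @param up,down connector endpoint compartment ids; `down = "sink"`
#'   drains to an external zero-pressure sink.
#' @param resistance connector resistance, mmHg/(ml/s), > 0.
#' @param valve logical; valves permit forward flow only.
#' @name network-parts
NULL

#' @rdname network-parts
#' @export
vessel_compartment <- function(id, compliance, v_unstressed = 0) {
  if (compliance <= 0) config_error(sprintf("vessel '%s': compliance must be > 0", id))
  if (v_unstressed < 0) config_error(sprintf("vessel '%s': v_unstressed must be >= 0", id))
  list(id = id, kind = KIND_VESSEL, compliance = compliance,
       v_unstressed = v_unstressed)
}

#' @rdname network-parts
#' @export
chamber_compartment <- function(id, e_min, e_max_ref, v0, contractility = 100,
                                role = c("ventricle", "atrium")) {
  role <- match.arg(role)
  if (e_min <= 0 || e_max_ref <= 0) {
    config_error(sprintf("chamber '%s': elastances must be > 0", id))
  }
  e_max_eff <- (contractility / 100) * e_max_ref
  if (e_max_eff < e_min) {
    config_error(sprintf("chamber '%s': e_max_eff (%g) below e_min (%g)",
                         id, e_max_eff, e_min))
  }
  list(id = id, kind = KIND_CHAMBER, e_min = e_min, e_max_ref = e_max_ref,
       contractility = contractility, v0 = v0, role = role)
}

#' @rdname network-parts
#' @export
pressure_source <- function(id, pressure) {
  list(id = id, kind = KIND_SOURCE, pressure = pressure)
}

#' @rdname network-parts
#' @export
connector <- function(id, up, down, resistance, valve = FALSE) {
  if (resistance <= 0) config_error(sprintf("connector '%s': resistance must be > 0", id))
  list(id = id, up = up, down = down, resistance = resistance,
       valve = isTRUE(valve))
}

#' Assemble a circulation network
#'
#' Packs compartments and connectors into the indexed form the stepping
#' loop uses. Initial volumes default to unstressed volumes; the model
#' builders override them.
#'
#' @param compartments list of [vessel_compartment()],
#'   [chamber_compartment()] or [pressure_source()] objects.
#' @param connectors list of [connector()] objects; endpoints must name
#'   compartments (or `"sink"` for `down`).
#' @param model_type label, e.g. `"IHL"`, `"CCL"` or `"custom"`.
#' @param v_init optional named vector of initial volumes (ml).
#' @return a `circulation_model` object.
#' @export
build_circulation <- function(compartments, connectors, model_type = "custom",
                              v_init = NULL) {
  ids <- vapply(compartments, `[[`, "", "id")
  if (anyDuplicated(ids)) config_error("duplicate compartment ids")
  n <- length(ids)
  get_num <- function(field, default = 0) {
    vapply(compartments, function(cp) {
      v <- cp[[field]]
      if (is.null(v)) default else as.numeric(v)
    }, 0)
  }
  kind <- vapply(compartments, `[[`, 0L, "kind")
  role <- vapply(compartments, function(cp) {
    if (cp$kind == KIND_CHAMBER) cp$role else NA_character_
  }, "")
  e_max_eff <- vapply(compartments, function(cp) {
    if (cp$kind == KIND_CHAMBER) (cp$contractility / 100) * cp$e_max_ref else 0
  }, 0)

  idx_of <- function(x, what) {
    i <- match(x, ids)
    if (is.na(i)) config_error(sprintf("connector endpoint '%s' (%s) names no compartment", x, what))
    i
  }
  up <- integer(0); dn <- integer(0)
  for (cn in connectors) {
    up <- c(up, idx_of(cn$up, cn$id))
    dn <- c(dn, if (identical(cn$down, "sink")) 0L else idx_of(cn$down, cn$id))
  }
  volumes <- get_num("v_unstressed") + get_num("v0")
  if (!is.null(v_init)) {
    stopifnot(all(names(v_init) %in% ids))
    volumes[match(names(v_init), ids)] <- v_init
  }
  volumes[kind == KIND_SOURCE] <- 0  # sources store no finite volume

  structure(list(
    model_type = model_type,
    ids = ids,
    kind = kind,
    role = role,
    e_min = get_num("e_min"),
    e_max_ref = get_num("e_max_ref"),
    e_max_eff = e_max_eff,
    v0 = get_num("v0"),
    compliance = get_num("compliance"),
    v_unstressed = get_num("v_unstressed"),
    p_fixed = get_num("pressure"),
    conn_ids = vapply(connectors, `[[`, "", "id"),
    up = up,
    dn = dn,
    resistance = vapply(connectors, `[[`, 0, "resistance"),
    is_valve = vapply(connectors, `[[`, TRUE, "valve"),
    v_init = volumes
  ), class = "circulation_model")
}

#' @export
print.circulation_model <- function(x, ...) {
  cat(sprintf("<circulation_model> %s: %d compartments, %d connectors (%d valves)\n",
              x$model_type, length(x$ids), length(x$up), sum(x$is_valve)))
  cat("  compartments:", paste(x$ids, collapse = ", "), "\n")
  invisible(x)
}

#' Build the isolated-heart network
#'
#' Five compartments: a constant-pressure venous source at the configured
#' central venous pressure, left atrium, left ventricle, aorta (compliance
#' taken from the user parameter) and distal arterial bed, draining through
#' the total peripheral resistance into a zero-pressure sink. Two valves
#' (mitral, aortic). Suitable for preload, afterload and contractility
#' experiments on the left heart alone.
#'
#' @param params validated [default_parameters()] set with `model = "IHL"`.
#' @param constants [internal_constants()].
#' @return a `circulation_model`.
#' @export
build_ihl <- function(params, constants = internal_constants()) {
  validate_parameters(params)
  if (params$model != "IHL") {
    model_error(sprintf("build_ihl needs model = 'IHL', got '%s'", params$model))
  }
  ch <- constants$chambers; vs <- constants$vessels; rs <- constants$resistances
  comps <- list(
    pressure_source("venous_source", params$cvp),
    chamber_compartment("la", ch$la$e_min, ch$la$e_max_ref, ch$la$v0,
                        contractility = 100, role = "atrium"),
    chamber_compartment("lv", ch$lv$e_min, ch$lv$e_max_ref, ch$lv$v0,
                        contractility = params$contractility_lv, role = "ventricle"),
    vessel_compartment("aorta", params$compliance, vs$aorta$v_unstressed),
    vessel_compartment("arterial_bed", vs$arterial_bed$compliance,
                       vs$arterial_bed$v_unstressed)
  )
  conns <- list(
    connector("venous_inflow", "venous_source", "la", rs$venous_systemic),
    connector("mitral_valve", "la", "lv", rs$valve, valve = TRUE),
    connector("aortic_valve", "lv", "aorta", rs$valve, valve = TRUE),
    connector("aorta_proximal", "aorta", "arterial_bed", rs$aorta_proximal),
    connector("tpr", "arterial_bed", "sink", params$tpr)
  )
  # start near a physiological operating point: chambers at passive
  # equilibrium with the preload, arteries pre-filled to ~80 mmHg
  p_art <- 80
  v_init <- c(
    la = ch$la$v0 + params$cvp / ch$la$e_min,
    lv = ch$lv$v0 + params$cvp / ch$lv$e_min,
    aorta = vs$aorta$v_unstressed + params$compliance * p_art,
    arterial_bed = vs$arterial_bed$v_unstressed + vs$arterial_bed$compliance * p_art
  )
  m <- build_circulation(comps, conns, model_type = "IHL", v_init = v_init)
  m$params <- params
  m$constants <- constants
  m
}

#' Build the closed-double-circulation network
#'
#' Ten compartments in a closed ring: systemic veins, right atrium, right
#' ventricle, pulmonary artery, pulmonary capillary bed, pulmonary veins,
#' left atrium, left ventricle, aorta and distal systemic arterial bed.
#' Four valves (tricuspid, pulmonary, mitral, aortic). The total peripheral
#' resistance sits between the arterial bed and the systemic veins; the
#' total lung resistance is split equally across the two pulmonary
#' segments. Total volume equals the configured blood volume and is
#' conserved exactly by construction — every flow leaves one compartment
#' and enters another.
#'
#' @param params validated [default_parameters()] set with `model = "CCL"`.
#' @param constants [internal_constants()].
#' @return a `circulation_model`.
#' @export
build_ccl <- function(params, constants = internal_constants()) {
  validate_parameters(params)
  if (params$model != "CCL") {
    model_error(sprintf("build_ccl needs model = 'CCL', got '%s'", params$model))
  }
  ch <- constants$chambers; vs <- constants$vessels; rs <- constants$resistances
  comps <- list(
    vessel_compartment("systemic_veins", vs$systemic_veins$compliance,
                       vs$systemic_veins$v_unstressed),
    chamber_compartment("ra", ch$ra$e_min, ch$ra$e_max_ref, ch$ra$v0,
                        contractility = 100, role = "atrium"),
    chamber_compartment("rv", ch$rv$e_min, ch$rv$e_max_ref, ch$rv$v0,
                        contractility = params$contractility_rv, role = "ventricle"),
    vessel_compartment("pulm_artery", vs$pulm_artery$compliance,
                       vs$pulm_artery$v_unstressed),
    vessel_compartment("pulm_cap_bed", vs$pulm_cap_bed$compliance,
                       vs$pulm_cap_bed$v_unstressed),
    vessel_compartment("pulm_veins", vs$pulm_veins$compliance,
                       vs$pulm_veins$v_unstressed),
    chamber_compartment("la", ch$la$e_min, ch$la$e_max_ref, ch$la$v0,
                        contractility = 100, role = "atrium"),
    chamber_compartment("lv", ch$lv$e_min, ch$lv$e_max_ref, ch$lv$v0,
                        contractility = params$contractility_lv, role = "ventricle"),
    vessel_compartment("aorta", params$compliance, vs$aorta$v_unstressed),
    vessel_compartment("arterial_bed", vs$arterial_bed$compliance,
                       vs$arterial_bed$v_unstressed)
  )
  conns <- list(
    connector("venous_return", "systemic_veins", "ra", rs$venous_systemic),
    connector("tricuspid_valve", "ra", "rv", rs$valve, valve = TRUE),
    connector("pulmonary_valve", "rv", "pulm_artery", rs$valve, valve = TRUE),
    connector("tlr_proximal", "pulm_artery", "pulm_cap_bed", params$tlr / 2),
    connector("tlr_distal", "pulm_cap_bed", "pulm_veins", params$tlr / 2),
    connector("pulm_venous_return", "pulm_veins", "la", rs$venous_pulmonary),
    connector("mitral_valve", "la", "lv", rs$valve, valve = TRUE),
    connector("aortic_valve", "lv", "aorta", rs$valve, valve = TRUE),
    connector("aorta_proximal", "aorta", "arterial_bed", rs$aorta_proximal),
    connector("tpr", "arterial_bed", "systemic_veins", params$tpr)
  )
  total_ml <- params$blood_volume * 1000
  fr <- constants$ccl_volume_fractions
  v_init <- total_ml * fr[c("systemic_veins", "ra", "rv", "pulm_artery",
                            "pulm_cap_bed", "pulm_veins", "la", "lv",
                            "aorta", "arterial_bed")]
  m <- build_circulation(comps, conns, model_type = "CCL", v_init = v_init)
  m$params <- params
  m$constants <- constants
  m
}

#' Initial state of a circulation model
#'
#' @param model a `circulation_model`.
#' @return a `circulation_state` list: `t` (s), named `volumes` (ml),
#'   `pressures` (mmHg, at zero activation) and `flows` (ml/s, all zero
#'   until the first step).
#' @export
initial_state <- function(model) {
  v <- stats::setNames(model$v_init, model$ids)
  structure(list(
    t = 0,
    volumes = v,
    pressures = stats::setNames(compute_pressures(model, v, numeric(length(v))),
                                model$ids),
    flows = stats::setNames(numeric(length(model$up)), model$conn_ids)
  ), class = "circulation_state")
}

# Pressures from volumes and per-compartment activation (reference path,
# same arithmetic as the compiled loop).
compute_pressures <- function(model, volumes, activation) {
  p <- numeric(length(volumes))
  for (i in seq_along(volumes)) {
    if (model$kind[i] == KIND_CHAMBER) {
      e <- model$e_min[i] + activation[i] * (model$e_max_eff[i] - model$e_min[i])
      p[i] <- e * max(volumes[i] - model$v0[i], 0)
    } else if (model$kind[i] == KIND_VESSEL) {
      p[i] <- max((volumes[i] - model$v_unstressed[i]) / model$compliance[i], 0)
    } else {
      p[i] <- model$p_fixed[i]
    }
  }
  p
}

compute_flows <- function(model, pressures) {
  p_ext <- c(pressures, 0)  # index 0 (sink) mapped to the padded slot
  dn <- ifelse(model$dn == 0L, length(pressures) + 1L, model$dn)
  q <- (p_ext[model$up] - p_ext[dn]) / model$resistance
  q[model$is_valve] <- pmax(q[model$is_valve], 0)
  q
}

activation_vector <- function(model, t_in_cycle, triggers) {
  a <- numeric(length(model$ids))
  if (is.null(triggers)) return(a)
  for (i in seq_along(a)) {
    if (model$kind[i] != KIND_CHAMBER) next
    if (identical(model$role[i], "atrium")) {
      a[i] <- chamber_activation(t_in_cycle, triggers$atrial_onset,
                                 triggers$systolic_duration_atrial)
    } else {
      a[i] <- chamber_activation(t_in_cycle, triggers$ventricular_onset,
                                 triggers$systolic_duration_ventricular)
    }
  }
  a
}

#' Advance a circulation state by one time step
#'
#' Reference implementation of the explicit forward update: (1) chamber
#' activations from the trigger schedule at `t mod rr`; (2) all pressures
#' from current volumes; (3) all connector flows from current pressures;
#' (4) volumes advanced by the net flow times `dt`. In a closed loop every
#' flow leaves one compartment and enters another, so total volume is
#' conserved exactly. The returned `pressures` and `flows` are the values
#' used for the update (at the pre-step time).
#'
#' @param model a `circulation_model`.
#' @param state a `circulation_state`.
#' @param triggers a [trigger_schedule()], or `NULL` for fully passive
#'   chambers.
#' @param dt step size, s.
#' @param rr cycle length, s, used to wrap `t` into the cycle; `Inf` for
#'   untriggered networks.
#' @return the updated `circulation_state` at `t + dt`.
#' @export
circulation_step <- function(model, state, triggers = NULL, dt = 0.001,
                             rr = Inf) {
  t_cyc <- if (is.finite(rr)) state$t %% rr else state$t
  a <- activation_vector(model, t_cyc, triggers)
  p <- compute_pressures(model, state$volumes, a)
  q <- compute_flows(model, p)
  dv <- numeric(length(state$volumes))
  for (j in seq_along(q)) {
    dv[model$up[j]] <- dv[model$up[j]] - q[j]
    if (model$dn[j] > 0L) dv[model$dn[j]] <- dv[model$dn[j]] + q[j]
  }
  v_next <- state$volumes + dt * dv
  v_next[model$kind == KIND_SOURCE] <- 0
  if (any(v_next[model$kind != KIND_SOURCE] < 0)) {
    bad <- model$ids[model$kind != KIND_SOURCE & v_next < 0][1]
    stability_error(sprintf(
      "negative volume in compartment '%s' at t = %.4f s; reduce dt", bad, state$t + dt))
  }
  structure(list(
    t = state$t + dt,
    volumes = stats::setNames(v_next, model$ids),
    pressures = stats::setNames(p, model$ids),
    flows = stats::setNames(q, model$conn_ids)
  ), class = "circulation_state")
}
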