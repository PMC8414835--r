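# End-to-end drivers: from a synthetic segmentation (or a cohort record) to
# meshes, pre-stress, tuned Windkessel, the two FSI arms and the metric
# report.

#' Assemble an AAA simulation case
#'
#' Runs the geometry chain (synthetic segmentation, elongation, lumen
#' surface, wall extrusion), assigns the group shear modulus from the
#' native maximum diameter, converts the brachial pressures and builds the
#' inlet waveform.
#'
#' @param profile geometry profile for [generate_synthetic_aaa()].
#' @param seed generator seed.
#' @param brachial_dia,brachial_sys brachial pressures, mmHg.
#' @param target_edge surface element size, mm. The full-resolution value is
#'   0.8 mm; desk-scale runs use coarser meshes.
#' @param thickness wall thickness, mm.
#' @param heart_rate bpm; `mean_flow` L/min.
#' @param material optional explicit `aaa_material` (default: group modulus).
#' @param elongation_length added arc length per end, mm.
#' @return an `aaa_case` list with the stack, meshes, material, blood
#'   pressure and waveform.
#' @export
aaa_case <- function(profile = default_aaa_profile(), seed = 1L,
                     brachial_dia = 80, brachial_sys = 141,
                     target_edge = 6, thickness = 2, heart_rate = 75,
                     mean_flow = 0.96, material = NULL,
                     elongation_length = 50) {
  native <- generate_synthetic_aaa(profile, seed = seed)
  dg <- max_diameter_and_group(native)
  if (is.null(material)) material <- assign_shear_modulus(dg$group)
  stack <- elongate_contours(native, length = elongation_length)
  surface <- build_lumen_surface(stack, target_edge = target_edge)
  mesh <- extrude_wall_mesh(surface, thickness = thickness)
  bp <- convert_brachial_to_aa(brachial_dia, brachial_sys)
  waveform <- generic_inlet_waveform(heart_rate = heart_rate,
                                     mean_flow = mean_flow)
  structure(list(
    profile = profile, seed = seed, native = native, stack = stack,
    surface = surface, mesh = mesh, material = material,
    d_max = dg$d_max, group = dg$group, bp = bp, waveform = waveform,
    target_edge = target_edge, thickness = thickness
  ), class = "aaa_case")
}

#' @export
print.aaa_case <- function(x, ...) {
  cat(sprintf("AAA case: d_max = %.1f mm (group %s, G = %.2f MPa), AA BP %.1f/%.1f mmHg\n",
              x$d_max, x$group, x$material$G, x$bp$aa_dia, x$bp$aa_sys))
  print(x$mesh)
  invisible(x)
}

#' Prepare one FSI arm: pre-stress, volumes, tuned Windkessel
#'
#' For the PSE arm the measured geometry is the diastolic configuration:
#' the BIM is run at the AA diastolic pressure, then the systolic pressure
#' is applied to obtain the systolic geometry. Without PSE the measured
#' geometry is assumed unloaded and both pressures are applied directly.
#' The diastolic/systolic enclosed lumen volumes give the added compliance
#' `C_A`, and the Windkessel is tuned to the patient's converted pressures.
#'
#' @param case an `aaa_case`.
#' @param prestress logical, PSE (`TRUE`) or no-PSE arm.
#' @param setup optional [wall_fem_setup()] to reuse.
#' @return list with `setup`, `prestress_state` (PSE arm), `V_dia`, `V_sys`
#'   (mm^3), `C_A` (mm^3/mmHg) and the tuned `wk`.
#' @export
prepare_arm <- function(case, prestress = TRUE, setup = NULL) {
  mesh <- case$mesh; mat <- case$material; bp <- case$bp
  if (is.null(setup)) setup <- wall_fem_setup(mesh, mat)
  if (prestress) {
    bim <- bim_prestress(mesh, mat, bp$aa_dia, setup = setup)
    V_dia <- enclosed_lumen_volume(mesh, displacement = bim$displacement)
    sys_state <- solve_static_inflation(mesh, mat, bp$aa_sys, initial = bim,
                                        setup = setup)
  } else {
    bim <- NULL
    dia_state <- solve_static_inflation(mesh, mat, bp$aa_dia, setup = setup)
    V_dia <- enclosed_lumen_volume(mesh, displacement = dia_state$displacement)
    sys_state <- solve_static_inflation(mesh, mat, bp$aa_sys,
                                        initial = dia_state, setup = setup)
  }
  V_sys <- enclosed_lumen_volume(mesh, displacement = sys_state$displacement)
  C_A <- estimate_aaa_compliance(V_dia, V_sys, bp$aa_dia, bp$aa_sys)

  a_out <- sqrt(luminal_areas(mesh)[length(mesh$fine_stations)] / pi) * 1e-3
  Z <- characteristic_impedance(h = case$thickness * 1e-3,
                                E = mat$E * 1e6, nu = 0.5, a = a_out)
  wk0 <- initial_windkessel(mean_arterial_pressure(bp$aa_dia, bp$aa_sys),
                            m3s_to_mls(lmin_to_m3s(case$waveform$mean_flow)),
                            Z, C_A = C_A)
  wk <- tune_windkessel(case$waveform, bp, C_A = C_A, init = wk0)
  list(setup = setup, prestress_state = bim, V_dia = V_dia, V_sys = V_sys,
       C_A = C_A, wk = wk, sys_state = sys_state)
}

#' Run one FSI arm of a case
#'
#' @param case an `aaa_case`.
#' @param arm `"pse"` or `"nopse"`.
#' @param coupling a [coupling_config()]; its `prestress` flag is set from
#'   `arm`.
#' @param prep optional result of [prepare_arm()] to reuse.
#' @param verbose print progress.
#' @return an `aaa_fsi_result` with the `prep` attached as attribute.
#' @export
run_arm <- function(case, arm = c("pse", "nopse"),
                    coupling = coupling_config(), prep = NULL,
                    verbose = FALSE) {
  arm <- match.arg(arm)
  prestress <- arm == "pse"
  coupling$prestress <- prestress
  if (is.null(prep)) prep <- prepare_arm(case, prestress = prestress)
  res <- run_fsi(case$mesh, case$material, case$bp, prep$wk, case$waveform,
                 config = coupling, prestress_state = prep$prestress_state,
                 setup = prep$setup, verbose = verbose)
  attr(res, "prep") <- prep[c("V_dia", "V_sys", "C_A")]
  attr(res, "wk") <- prep$wk
  res
}

#' Run both FSI arms and build the metric report
#'
#' The complete two-arm pipeline: prepares and runs the PSE and no-PSE arms
#' on the same mesh and compares them with [compare_arms()].
#'
#' @inheritParams run_arm
#' @return list with `report` (a `metric_report`), `pse` and `nopse`
#'   (`aaa_fsi_result`s) and the `case`.
#' @export
compare_pse_arms <- function(case, coupling = coupling_config(),
                             verbose = FALSE) {
  res_pse <- run_arm(case, "pse", coupling = coupling, verbose = verbose)
  res_nop <- run_arm(case, "nopse", coupling = coupling, verbose = verbose)
  list(report = compare_arms(res_pse, res_nop, case$bp),
       pse = res_pse, nopse = res_nop, case = case)
}
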