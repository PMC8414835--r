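# Post-processing of the two FSI arms: time-averaged wall shear stress,
# oscillatory shear index, pressure-scaled quantities, percentile summaries
# over the AAA region, spatial differences between the arms, corrected
# displacement and paired statistics.

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Time-averaged wall shear stress
#'
#' `(1/T) * integral of |WSS| dt` over one cycle by the trapezoidal rule.
#'
#' @param series WSS samples, Pa: a vector (one point) or a matrix with one
#'   row per wall point and one column per time sample.
#' @param time sample times, s; the grid is taken to span the cycle, so
#'   `T = max(time) - min(time)` (pass the closing sample for a closed
#'   grid, or an open uniform grid covering the period).
#' @return TAWSS, Pa (vector with one value per point).
#' @export
tawss <- function(series, time) {
  if (is.matrix(series)) return(apply(series, 1, tawss, time = time))
  stopifnot(length(series) == length(time), length(time) >= 16)
  trapz(time, abs(series)) / diff(range(time))
}

#' Oscillatory shear index
#'
#' `OSI = 0.5 * (1 - |int WSS dt| / int |WSS| dt)`, in `[0, 0.5]`: 0 for
#' unidirectional WSS, 0.5 for fully oscillating WSS with zero mean. An
#' all-zero signal has no defined direction and returns `NA`.
#'
#' @inheritParams tawss
#' @return OSI (dimensionless, per point; `NA` where the signal is all zero).
#' @export
osi <- function(series, time) {
  if (is.matrix(series)) return(apply(series, 1, osi, time = time))
  stopifnot(length(series) == length(time), length(time) >= 16)
  denom <- trapz(time, abs(series))
  if (denom == 0) return(NA_real_)
  0.5 * (1 - abs(trapz(time, series)) / denom)
}

#' Scale a quantity to the measured systolic blood pressure
#'
#' `phi_scaled = phi * SBP_AA / SBP_FSI`, removing the effect of differences
#' in simulated systolic pressure between arms.
#'
#' @param value quantity (any units, vectorized).
#' @param sbp_aa measured abdominal-aortic systolic pressure, mmHg.
#' @param sbp_fsi simulated systolic pressure, mmHg (> 0).
#' @return scaled value.
#' @export
scale_to_measured_sbp <- function(value, sbp_aa, sbp_fsi) {
  stopifnot(sbp_fsi > 0)
  value * sbp_aa / sbp_fsi
}

#' Spatial difference between the two arms
#'
#' Per-node relative difference
#' `delta_s = (phi_noPSE - phi_PSE) / mean(phi_PSE) * 100` (percent) and its
#' average absolute value.
#'
#' @param field_nopse,field_pse fields on identical node sets.
#' @return list with `delta` (per-node %, `NA` entries of either field are
#'   dropped pairwise) and `mean_abs` (%).
#' @export
spatial_difference <- function(field_nopse, field_pse) {
  stopifnot(length(field_nopse) == length(field_pse))
  ok <- is.finite(field_nopse) & is.finite(field_pse)
  mu <- mean(field_pse[ok])
  if (!is.finite(mu) || mu == 0) stop("PSE field has zero (or undefined) mean")
  delta <- rep(NA_real_, length(field_pse))
  delta[ok] <- (field_nopse[ok] - field_pse[ok]) / mu * 100
  list(delta = delta, mean_abs = mean(abs(delta[ok])))
}

#' Extreme percentile of a field
#'
#' 99th or 1st percentile with linear interpolation between order statistics
#' (positions `(n-1)*q + 1`).
#'
#' @param field numeric field (non-empty; `NA` dropped).
#' @param which `"p99"` or `"p1"`.
#' @return the percentile value.
#' @export
percentile_extreme <- function(field, which = c("p99", "p1")) {
  which <- match.arg(which)
  field <- field[is.finite(field)]
  if (!length(field)) stop("empty field")
  unname(stats::quantile(field, probs = if (which == "p99") 0.99 else 0.01,
                         type = 7))
}

#' Corrected displacement
#'
#' Per-node magnitude of the systolic displacement measured relative to the
#' diastolic configuration: `|u_sys - u_dia|`.
#'
#' @param disp_sys,disp_dia n x 3 displacement fields, mm.
#' @return vector of corrected displacement magnitudes, mm.
#' @export
corrected_displacement <- function(disp_sys, disp_dia) {
  stopifnot(all(dim(disp_sys) == dim(disp_dia)))
  sqrt(rowSums((disp_sys - disp_dia)^2))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Standard signed-rank statistic with the exact null distribution for small
#' samples without ties/zeros and the normal approximation (with tie and
#' zero handling) otherwise; two-sided p-value, significance at 0.05.
#'
#' @param a,b paired samples (equal length >= 5).
#' @return list with `statistic` (V), `p` (two-sided), `significant`
#'   (p < 0.05), `degenerate` (all differences zero; then statistic and p
#'   are `NA`).
#' @export
wilcoxon_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 5)
  d <- a - b
  if (all(d == 0)) {
    return(list(statistic = NA_real_, p = NA_real_, significant = NA,
                degenerate = TRUE))
  }
  dz <- d[d != 0]
  exact_ok <- length(dz) <= 25 && !any(duplicated(abs(dz)))
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, paired = TRUE, exact = exact_ok, correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p = wt$p.value,
       significant = wt$p.value < 0.05, degenerate = FALSE)
}

# deterministic down-sample of node indices for the paired tests
subsample_idx <- function(n, k = 200L) {
  if (n <= k) seq_len(n) else unique(round(seq(1, n, length.out = k)))
}

#' Compare the PSE and no-PSE FSI arms
#'
#' Builds the full metric report: per-arm 99th-percentile systolic
#' displacement, corrected displacement and von Mises stress, 1st-percentile
#' TAWSS and 99th-percentile OSI, all evaluated over the AAA region
#' (elongations excluded); displacement, stress and TAWSS are scaled to the
#' measured systolic pressure before the arms are compared. Cross-arm
#' spatial-difference fields, percentile differences and paired Wilcoxon
#' tests complete the report. The systolic (diastolic) time point is the
#' time of maximum (minimum) lumen pressure in the evaluation cycle.
#'
#' @param res_pse,res_nopse `aaa_fsi_result` objects from [run_fsi()] on the
#'   same mesh.
#' @param bp the `blood_pressure` with the measured AA targets.
#' @return a `metric_report` list.
#' @export
compare_arms <- function(res_pse, res_nopse, bp) {
  mesh <- res_pse$mesh
  node_mask <- mesh$node_native
  st_mask <- res_pse$native_stations

  arm_metrics <- function(res) {
    sbp_fsi <- res$sys_pressure
    scale <- bp$aa_sys / sbp_fsi
    u_sys <- res$displacement[[res$sys_step]]
    u_dia <- res$displacement[[res$dia_step]]
    disp <- sqrt(rowSums(u_sys^2))
    cdisp <- corrected_displacement(u_sys, u_dia)
    vm_nodal <- qp_to_nodal(mesh, res$von_mises_qp[[res$sys_step]])
    wss_mat <- res$wss
    ta <- tawss(wss_mat, res$time)
    os <- osi(wss_mat, res$time)
    list(
      sbp_fsi = sbp_fsi, dia_fsi = res$dia_pressure,
      disp = disp, disp_scaled = disp * scale,
      cdisp = cdisp, cdisp_scaled = cdisp * scale,
      vm = vm_nodal, vm_scaled = vm_nodal * scale,
      tawss = ta, tawss_scaled = ta * scale, osi = os,
      p99_disp = percentile_extreme(disp[node_mask], "p99"),
      p99_cdisp = percentile_extreme(cdisp[node_mask], "p99"),
      p99_vm = percentile_extreme(vm_nodal[node_mask], "p99"),
      p1_tawss = percentile_extreme(ta[st_mask], "p1"),
      p99_osi = percentile_extreme(os[st_mask], "p99"),
      periodicity = res$periodicity
    )
  }
  pse <- arm_metrics(res_pse)
  nop <- arm_metrics(res_nopse)

  sd_disp <- spatial_difference(nop$disp_scaled[node_mask], pse$disp_scaled[node_mask])
  sd_vm <- spatial_difference(nop$vm_scaled[node_mask], pse$vm_scaled[node_mask])
  sd_tawss <- spatial_difference(nop$tawss_scaled[st_mask], pse$tawss_scaled[st_mask])
  sd_osi <- spatial_difference(nop$osi[st_mask], pse$osi[st_mask])

  pct_diff <- function(q_nop, q_pse) (q_nop - q_pse) / q_pse * 100
  scale_p <- function(arm, q) q * bp$aa_sys / arm$sbp_fsi

  ni <- which(node_mask)[subsample_idx(sum(node_mask))]
  si <- which(st_mask)[subsample_idx(sum(st_mask), 100L)]
  tests <- list(
    displacement = wilcoxon_signed_rank(nop$disp_scaled[ni], pse$disp_scaled[ni]),
    stress = wilcoxon_signed_rank(nop$vm_scaled[ni], pse$vm_scaled[ni]),
    tawss = wilcoxon_signed_rank(nop$tawss_scaled[si], pse$tawss_scaled[si]),
    osi = wilcoxon_signed_rank(nop$osi[si], pse$osi[si])
  )

  structure(list(
    measured = list(aa_dia = bp$aa_dia, aa_sys = bp$aa_sys),
    pse = pse[c("sbp_fsi", "dia_fsi", "p99_disp", "p99_cdisp", "p99_vm",
                "p1_tawss", "p99_osi", "periodicity")],
    nopse = nop[c("sbp_fsi", "dia_fsi", "p99_disp", "p99_cdisp", "p99_vm",
                  "p1_tawss", "p99_osi", "periodicity")],
    percentile_diff = list(
      displacement = pct_diff(scale_p(nop, nop$p99_disp), scale_p(pse, pse$p99_disp)),
      corrected_displacement = pct_diff(scale_p(nop, nop$p99_cdisp),
                                        scale_p(pse, pse$p99_cdisp)),
      stress = pct_diff(scale_p(nop, nop$p99_vm), scale_p(pse, pse$p99_vm)),
      tawss = pct_diff(scale_p(nop, nop$p1_tawss), scale_p(pse, pse$p1_tawss)),
      osi = pct_diff(nop$p99_osi, pse$p99_osi)
    ),
    spatial_difference = list(
      displacement = sd_disp$mean_abs, stress = sd_vm$mean_abs,
      tawss = sd_tawss$mean_abs, osi = sd_osi$mean_abs
    ),
    spatial_fields = list(displacement = sd_disp$delta, stress = sd_vm$delta,
                          tawss = sd_tawss$delta, osi = sd_osi$delta),
    tests = lapply(tests, function(t) t[c("statistic", "p", "significant")]),
    arms = list(pse = pse, nopse = nop)
  ), class = "metric_report")
}

# element-mean quadrature values distributed to nodes (simple averaging)
qp_to_nodal <- function(mesh, qp_values) {
  el_mean <- rowMeans(matrix(qp_values, nrow = nrow(mesh$hexes), byrow = TRUE))
  acc <- numeric(nrow(mesh$nodes)); cnt <- numeric(nrow(mesh$nodes))
  for (e in seq_len(nrow(mesh$hexes))) {
    ids <- mesh$hexes[e, ]
    acc[ids] <- acc[ids] + el_mean[e]
    cnt[ids] <- cnt[ids] + 1
  }
  cnt[cnt == 0] <- 1
  acc / cnt
}

#' @export
print.metric_report <- function(x, ...) {
  cat("PSE vs no-PSE metric report (AAA region)\n")
  cat(sprintf("  measured AA dia/sys: %.1f / %.1f mmHg\n",
              x$measured$aa_dia, x$measured$aa_sys))
  cat(sprintf("  simulated dia (PSE / no-PSE): %.1f / %.1f mmHg\n",
              x$pse$dia_fsi, x$nopse$dia_fsi))
  cat(sprintf("  p99 displacement: %.3f vs %.3f mm (diff %+.1f%%)\n",
              x$pse$p99_disp, x$nopse$p99_disp, x$percentile_diff$displacement))
  cat(sprintf("  p99 von Mises:    %.1f vs %.1f kPa (diff %+.1f%%)\n",
              x$pse$p99_vm, x$nopse$p99_vm, x$percentile_diff$stress))
  cat(sprintf("  p1 TAWSS:         %.3f vs %.3f Pa;  p99 OSI: %.3f vs %.3f\n",
              x$pse$p1_tawss, x$nopse$p1_tawss, x$pse$p99_osi, x$nopse$p99_osi))
  cat(sprintf("  mean |spatial diff|: disp %.1f%%, stress %.1f%%, TAWSS %.1f%%, OSI %.1f%%\n",
              x$spatial_difference$displacement, x$spatial_difference$stress,
              x$spatial_difference$tawss, x$spatial_difference$osi))
  invisible(x)
}
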