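# The 30-patient cohort table: maximum diameter (mm), AAA length (cm,
# elongation excluded) and brachial diastolic/systolic pressure (mmHg), with
# ten patients per size group. Shipped as a CSV fixture in
# inst/extdata/patient_table.csv.

#' Path to the shipped patient table
#' @return file path of the cohort CSV.
#' @export
patient_table_path <- function() {
  system.file("extdata", "patient_table.csv", package = "aaafsi",
              mustWork = TRUE)
}

#' Read and validate a patient table
#'
#' Reads a CSV with columns `id`, `d_max` (mm), `l_aaa` (cm), `p_dia`,
#' `p_sys` (brachial, mmHg); recomputes the size group from `d_max` and
#' validates every row (`sys > dia`, positive diameters). Malformed rows are
#' reported with their line numbers.
#'
#' @param path CSV path; default the shipped 30-patient cohort.
#' @return data.frame of validated patient records with a `group` column.
#' @export
read_patient_table <- function(path = patient_table_path()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "d_max", "l_aaa", "p_dia", "p_sys")
  if (!all(need %in% names(df))) {
    stop("patient table must have columns: ", paste(need, collapse = ", "))
  }
  bad <- which(!(df$p_sys > df$p_dia) | df$p_dia <= 0 | df$d_max <= 0 |
                 df$l_aaa <= 0 | !is.finite(df$d_max))
  if (length(bad)) {
    stop("malformed patient rows (file lines): ",
         paste(bad + 1L, collapse = ", "))
  }
  df$group <- vapply(df$d_max, diameter_group, character(1))
  df
}

#' Synthetic geometry profile for a patient record
#'
#' Maps a cohort row (maximum diameter, AAA length) onto the parameters of
#' the synthetic contour-stack generator. Only `d_max` and `l_aaa` are
#' informed by the record; asymmetry and bow keep the generator defaults.
#'
#' @param record one row of [read_patient_table()].
#' @return a profile list for [generate_synthetic_aaa()].
#' @export
patient_profile <- function(record) {
  p <- default_aaa_profile()
  p$max_diameter <- record$d_max
  p$sac_length <- record$l_aaa * 10 - 20  # cm to mm, minus the two necks
  p$neck_diameter <- min(22, 0.6 * record$d_max)
  p
}
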