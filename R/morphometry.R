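## Toroid morphometry: rim thickness, cavity ratio and descriptive
## statistics of particle-size tables measured from electron micrographs.

#' Rim thickness of a toroidal particle
#'
#' Half the difference of the outer and cavity diameters:
#' `(outer_d - cavity_d) / 2`. The per-particle identity
#' `outer = cavity + 2 * rim` holds exactly.
#'
#' @param outer_d Outer diameter, nm.
#' @param cavity_d Central cavity diameter, nm; must satisfy
#'   `0 < cavity_d < outer_d`.
#' @return Rim thickness, nm.
#' @export
#' @examples
#' rim_thickness(200, 100)  # 50
rim_thickness <- function(outer_d, cavity_d) {
  if (any(cavity_d <= 0) || any(cavity_d >= outer_d))
    stop("need 0 < cavity_d < outer_d", call. = FALSE)
  (outer_d - cavity_d) / 2
}

#' Descriptive morphometry table for a set of toroids
#'
#' Per-particle derived quantities (rim thickness, cavity/outer ratio)
#' are computed first and then aggregated, so the reported mean rim is
#' the mean of per-particle rims (not the rim of the mean diameters).
#' For each parameter the table reports mean, sample SD, min, max and
#' the coefficient of variation.
#'
#' @param records Data frame with columns `outer_nm`, `cavity_nm` and
#'   optionally `aspect`; at least 2 rows.
#' @return A data frame with one row per parameter (`outer`, `cavity`,
#'   `rim`, `ratio`, and `aspect` if present) and columns `mean`, `sd`,
#'   `min`, `max`, `cv`.
#' @export
morphometry_table <- function(records) {
  if (!all(c("outer_nm", "cavity_nm") %in% names(records)))
    stop("records needs columns outer_nm and cavity_nm", call. = FALSE)
  if (nrow(records) < 2L) stop("need at least 2 records", call. = FALSE)
  rim <- rim_thickness(records$outer_nm, records$cavity_nm)
  cols <- list(outer = records$outer_nm, cavity = records$cavity_nm,
               rim = rim, ratio = records$cavity_nm / records$outer_nm)
  if ("aspect" %in% names(records)) cols$aspect <- records$aspect
  out <- do.call(rbind, lapply(names(cols), function(nm) {
    v <- cols[[nm]]
    data.frame(parameter = nm, mean = mean(v), sd = stats::sd(v),
               min = min(v), max = max(v),
               cv = stats::sd(v) / mean(v))
  }))
  rownames(out) <- NULL
  out
}
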