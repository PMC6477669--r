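#' Packaged four-part composition panel
#'
#' The 15 candidate surrogate compositions (wt % of Shore 00-10 part A/B and
#' Shore 30A part A/B). Each row sums to 100 wt %; the conventional name
#' concatenates the four fractions.
#'
#' @return A data.frame with columns `specimen`, the four weight-fraction
#'   columns, and `name`.
#' @examples
#' nrow(composition_table())  # 15
#' @export
composition_table <- function() {
  df <- utils::read.csv(system.file("extdata", "compositions.csv",
                                    package = "padmech"))
  recs <- mapply(composition_record,
                 df$shore0010_a_wt, df$shore0010_b_wt,
                 df$shore30a_a_wt, df$shore30a_b_wt,
                 SIMPLIFY = FALSE)
  df$name <- vapply(recs, `[[`, "", "name")
  df
}

#' @rdname composition_table
#' @export
composition_records <- function() {
  df <- composition_table()
  recs <- mapply(composition_record,
                 df$shore0010_a_wt, df$shore0010_b_wt,
                 df$shore30a_a_wt, df$shore30a_b_wt,
                 SIMPLIFY = FALSE)
  names(recs) <- df$name
  recs
}

#' Packaged per-rate Yeoh parameter table
#'
#' Identified Yeoh coefficients (MPa) for the healthy-control surrogate at
#' three displacement rates and for the plantar-pain and diabetes surrogates.
#' `rate_label` preserves the source table's printed label verbatim —
#' including the diabetes row's "1.96 mm/min", which is inconsistent with the
#' mm/s labels of the comparable rows; `rate_mm_per_s` carries the normalized
#' numeric rate (1.96) without altering the label.
#'
#' @return A data.frame with columns `surrogate`, `group`, `rate_label`,
#'   `rate_mm_per_s`, `c1_MPa`, `c2_MPa`, `c3_MPa`.
#' @examples
#' surrogate_parameter_table()
#' @export
surrogate_parameter_table <- function() {
  utils::read.csv(system.file("extdata", "surrogate_yeoh_parameters.csv",
                              package = "padmech"),
                  check.names = TRUE)
}

#' @rdname surrogate_parameter_table
#' @param group Group name ("healthy control", "plantar pain", "diabetes").
#' @param rate_mm_per_s Displacement rate to select (default 1.96).
#' @export
surrogate_params <- function(group, rate_mm_per_s = 1.96) {
  tab <- surrogate_parameter_table()
  row <- tab[tab$group == group & tab$rate_mm_per_s == rate_mm_per_s, ]
  if (nrow(row) != 1L)
    stop(sprintf("no unique parameter row for group '%s' at %g mm/s",
                 group, rate_mm_per_s), call. = FALSE)
  yeoh_params(row$c1_MPa, row$c2_MPa, row$c3_MPa,
              label = sprintf("%s (%s)", row$surrogate, row$rate_label),
              rate_mm_per_s = row$rate_mm_per_s)
}
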