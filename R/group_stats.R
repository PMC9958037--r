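#' Unpaired two-tailed Student's t test
#'
#' Classic pooled-variance two-sample t test (Welch's correction available
#' behind a flag), with the two-tailed p-value and a significance tier:
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, `ns`
#' otherwise.
#'
#' @param a,b Numeric samples (each at least 2 finite values).
#' @param welch Use Welch's unequal-variance statistic instead of the
#'   pooled-variance Student form (default `FALSE`).
#' @return A one-row tibble: `t, df, p_value, tier, mean_a, mean_b,
#'   n_a, n_b`.
#' @examples
#' student_t_test(c(1, 2, 3), c(2, 3, 4))
#' @export
student_t_test <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L || !all(is.finite(c(a, b)))) {
    stop("each sample needs at least 2 finite values", call. = FALSE)
  }
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(tibble(t = 0, df = length(a) + length(b) - 2L, p_value = 1,
                    tier = "ns", mean_a = mean(a), mean_b = mean(b),
                    n_a = length(a), n_b = length(b)))
    }
    stop("zero pooled variance with unequal means: t statistic undefined",
         call. = FALSE)
  }
  ht <- t.test(a, b, var.equal = !welch)
  tibble(t = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, tier = significance_tier(ht$p.value),
         mean_a = mean(a), mean_b = mean(b),
         n_a = length(a), n_b = length(b))
}

significance_tier <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "ns")
}

#' Per-segment group comparison of the QFlow parameters
#'
#' Compares reflux limbs against healthy-control limbs with an unpaired
#' two-tailed Student's t test for each of the six compared parameters
#' (SV, FFV, ASV, MF, SD, MV) in each venous segment (EIV, FV, PV, GSV):
#' 24 tests in all, reported raw (no multiple-testing correction). Rows
#' with missing parameter values are dropped from the affected test; a
#' segment missing one of the groups yields a flagged, skipped row.
#'
#' @param qflow A [batch_qflow()] table.
#' @param labels Optional tibble `subject_id`, `label`; defaults to the
#'   labels in `qflow`.
#' @param welch Use Welch's statistic (default `FALSE`, matching the
#'   classic Student form).
#' @return A `segment_comparison` tibble: `segment, parameter, n_reflux,
#'   n_control, t, df, p_value, tier` (24 rows; `tier = "skipped"` where a
#'   group was absent). P-values are uncorrected.
#' @export
compare_segments <- function(qflow, labels = NULL, welch = FALSE) {
  stopifnot(is.data.frame(qflow))
  if (!is.null(labels)) {
    qflow <- dplyr::left_join(
      dplyr::select(as_tibble(qflow), -dplyr::any_of("label")),
      as_tibble(labels)[, c("subject_id", "label")], by = "subject_id")
  }
  stopifnot("label" %in% names(qflow))
  segments <- c("EIV", "FV", "PV", "GSV")
  params <- c("sv", "ffv", "asv", "mf", "sd", "mv")
  rows <- list()
  for (seg in segments) {
    sub <- qflow[qflow$setpoint == seg, , drop = FALSE]
    for (pm in params) {
      a <- sub[[pm]][sub$label == 1L]
      b <- sub[[pm]][sub$label == 0L]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      row <- if (length(a) >= 2L && length(b) >= 2L) {
        tt <- student_t_test(a, b, welch = welch)
        tibble(segment = seg, parameter = pm,
               n_reflux = length(a), n_control = length(b),
               t = tt$t, df = tt$df, p_value = tt$p_value, tier = tt$tier)
      } else {
        tibble(segment = seg, parameter = pm,
               n_reflux = length(a), n_control = length(b),
               t = NA_real_, df = NA_real_, p_value = NA_real_,
               tier = "skipped")
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("segment_comparison", class(out))
  out
}

#' @export
print.segment_comparison <- function(x, ...) {
  NextMethod()
  cat("# p-values are raw (uncorrected for the 24 comparisons)\n")
  invisible(x)
}
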