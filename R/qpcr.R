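#' ChIP-qPCR percent input
#'
#' Computes `100 * 2^((ct_input - input_dilution_log2) - ct_ip)`. The
#' dilution adjustment defaults to 0; for a diluted input sample (e.g. a 1%
#' input, dilution factor 100) pass `input_dilution_log2 = log2(100)`.
#'
#' @param ct_input,ct_ip Threshold cycles for the input and the
#'   immunoprecipitated sample (vectors recycle).
#' @param input_dilution_log2 log2 of the input dilution factor, default 0.
#' @return Percent input (numeric).
#' @export
percent_input <- function(ct_input, ct_ip, input_dilution_log2 = 0) {
  if (any(!is.finite(ct_input)) || any(!is.finite(ct_ip)))
    pg_stop("CT values must be finite")
  if (any(ct_input < 0 | ct_input > 45) || any(ct_ip < 0 | ct_ip > 45))
    warning("CT value outside the usual 0-45 cycle range")
  100 * 2^((ct_input - input_dilution_log2) - ct_ip)
}

#' Normalise percent-input values to a control condition
#'
#' @param treatment,control Percent-input values (vectors recycle).
#' @return Fold enrichment `treatment / control`.
#' @export
normalize_to_control <- function(treatment, control) {
  if (any(control <= 0)) pg_stop("control percent input must be > 0")
  treatment / control
}

#' Quantify a ChIP-qPCR CT table
#'
#' Reads a TSV with columns `target_name`, `condition_label`, `ct_input`,
#' `ct_ip`, computes percent input per row, and (when `control_label` is
#' given) per-target fold enrichment of every condition over the control
#' condition.
#'
#' @param path Path to the CT TSV.
#' @param control_label Optional condition to normalise against.
#' @param input_dilution_log2 Passed to [percent_input()].
#' @return The table with a `percent_input` column, plus `fold_vs_control`
#'   when a control label is given.
#' @export
quantify_qpcr <- function(path, control_label = NULL,
                          input_dilution_log2 = 0) {
  df <- read_tsv(path)
  need <- c("target_name", "condition_label", "ct_input", "ct_ip")
  if (!all(need %in% names(df)))
    pg_stop("CT table needs columns: %s", paste(need, collapse = ", "))
  df$percent_input <- percent_input(df$ct_input, df$ct_ip,
                                    input_dilution_log2)
  if (!is.null(control_label)) {
    ctrl <- df[df$condition_label == control_label, ]
    if (nrow(ctrl) == 0)
      pg_stop("no rows with condition_label == '%s'", control_label)
    ctrl_pi <- stats::setNames(ctrl$percent_input, ctrl$target_name)
    if (any(!df$target_name %in% names(ctrl_pi)))
      pg_stop("target(s) missing a control measurement")
    df$fold_vs_control <- normalize_to_control(
      df$percent_input, ctrl_pi[df$target_name])
  }
  df
}
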