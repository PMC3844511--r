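#' Full association analysis of a family dataset
#'
#' Runs the requested likelihood ratio tests plus (optionally) the TDT and
#' the combined score test `z_com` on a family dataset, reporting for each
#' LRT model the null allele-frequency MLE, the constrained alternative
#' MLEs, the statistic and its p-value.  The analysis can be restricted to
#' full triads (`"FT"`), triads plus parent-child dyads (`"FT+PD"`) or all
#' data (`"FT+PD+AM"`); the TDT always uses triads only, and `z_com` uses
#' triads plus whatever dyads the subset retains.
#'
#' The five LRT p-values are reported unadjusted by default (they test one
#' association hypothesis under different risk models, not five
#' hypotheses); `adjust = "bonferroni"` appends a column multiplying each
#' LRT p-value by the number of LRT models requested.
#'
#' @param x a file path (passed to [read_families()]), a `family_records`
#'   data frame, a [tabulate_families()] report, or a [family_dataset()].
#' @param models LRT models to fit (default all five).
#' @param data_used `"FT+PD+AM"`, `"FT+PD"` or `"FT"`.
#' @param include_tdt,include_zcom logical.
#' @param adjust `"none"` or `"bonferroni"` (LRT rows only).
#' @param risk_allele forwarded to [read_families()] when `x` is a path.
#' @return A data frame of class `family_assoc`, one row per test, with
#'   columns `model`, `data_used`, `p_hat`, `p_tilde`, `psi1`, `psi2`,
#'   `statistic`, `df`, `p_value` (and `p_adjusted` if requested); the
#'   analyzed counts are attached as attribute `"counts"`.
#' @examples
#' d <- family_dataset(triads = c(5, 12, 9, 11, 6, 11, 4, 10, 9, 3),
#'                     dyads = c(2, 3, 2, 5, 3, 2, 1),
#'                     monads = c(4, 7, 4))
#' analyze_families(d, models = c("Dom", "Mult"))
#' @export
analyze_families <- function(x, models = .MODELS,
                             data_used = c("FT+PD+AM", "FT+PD", "FT"),
                             include_tdt = TRUE, include_zcom = TRUE,
                             adjust = c("none", "bonferroni"),
                             risk_allele = "A") {
  data_used <- match.arg(toupper(data_used), c("FT+PD+AM", "FT+PD", "FT"))
  adjust <- match.arg(adjust)
  data <- .as_dataset(x, risk_allele)
  data <- subset_dataset(data, data_used)
  models <- vapply(models, .match_model, character(1L), USE.NAMES = FALSE)

  rows <- list()
  null_fit <- mle_null(data)
  for (model in models) {
    tst <- lrt(data, model)
    rows[[length(rows) + 1L]] <- data.frame(
      model = model, data_used = data_used, p_hat = null_fit$p,
      p_tilde = tst$alt_fit$p, psi1 = tst$alt_fit$psi1,
      psi2 = tst$alt_fit$psi2, statistic = tst$statistic,
      df = tst$df, p_value = tst$p_value, stringsAsFactors = FALSE)
  }
  if (include_tdt) {
    tst <- tdt(data$triads)
    rows[[length(rows) + 1L]] <- data.frame(
      model = "TDT", data_used = "FT", p_hat = NA_real_,
      p_tilde = NA_real_, psi1 = NA_real_, psi2 = NA_real_,
      statistic = tst$statistic, df = 1L, p_value = tst$p_value,
      stringsAsFactors = FALSE)
  }
  if (include_zcom) {
    tst <- zcom(data$triads, data$dyads)
    rows[[length(rows) + 1L]] <- data.frame(
      model = "zcom",
      data_used = if (data_used == "FT") "FT" else "FT+PD",
      p_hat = NA_real_, p_tilde = NA_real_, psi1 = NA_real_,
      psi2 = NA_real_, statistic = tst$statistic, df = NA_integer_,
      p_value = tst$p_value, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (adjust == "bonferroni") {
    out$p_adjusted <- out$p_value
    is_lrt <- out$model %in% .MODELS
    out$p_adjusted[is_lrt] <- pmin(1, out$p_value[is_lrt] * sum(is_lrt))
  }
  rownames(out) <- NULL
  attr(out, "counts") <- data
  class(out) <- c("family_assoc", "data.frame")
  out
}

.as_dataset <- function(x, risk_allele = "A") {
  if (inherits(x, "family_dataset")) return(x)
  if (inherits(x, "tabulation_report")) return(x$counts)
  if (is.character(x) && length(x) == 1L)
    x <- read_families(x, risk_allele = risk_allele)
  if (is.data.frame(x)) return(tabulate_families(x)$counts)
  stop("cannot interpret `x` as family data", call. = FALSE)
}

#' @export
print.family_assoc <- function(x, ...) {
  d <- attr(x, "counts")
  if (!is.null(d))
    cat(sprintf("Association tests (%d triads, %d dyads, %d monads)\n",
                sum(d$triads), sum(d$dyads), sum(d$monads)))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
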