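#' Log-transform positive trait values
#'
#' Base-10 by default: on that scale a fitted coefficient \eqn{\beta}
#' corresponds to a \eqn{10^\beta}-fold multiplicative change of the raw
#' trait (see \code{\link{fold_change_from_log10}}), and the mean of the
#' transformed values is the log of the geometric mean.
#'
#' @param values positive numeric vector (names, if present, are used in
#'   error messages).
#' @param base10 use base-10 (default) rather than natural log.
#' @return transformed vector.
#' @export
log_transform <- function(values, base10 = TRUE) {
  bad <- which(!is.na(values) & values <= 0)
  if (length(bad)) {
    lab <- if (!is.null(names(values))) names(values)[bad] else as.character(bad)
    stop2("non-positive value(s) cannot be log-transformed: ",
          paste(utils::head(lab, 10L), collapse = ", "))
  }
  if (base10) log10(values) else log(values)
}

#' Classify urinary albumin-to-creatinine ratio
#'
#' Categorises UACR (g/mol) into normoalbuminuria (< \code{micro_low}),
#' microalbuminuria (\code{micro_low} to \code{macro_low} inclusive) and
#' macroalbuminuria (> \code{macro_low}).  The categories partition
#' \eqn{(0, \infty)}.
#'
#' @param uacr positive numeric vector, g/mol.
#' @param micro_low lower bound of microalbuminuria (default 3.4 g/mol).
#' @param macro_low upper bound of microalbuminuria (default 33 g/mol;
#'   some guidelines draw the macro line at 30).
#' @return factor with levels \code{normo}, \code{micro}, \code{macro}.
#' @export
classify_albuminuria <- function(uacr, micro_low = 3.4, macro_low = 33) {
  bad <- which(!is.na(uacr) & uacr <= 0)
  if (length(bad)) stop2("UACR must be positive; offending position(s): ",
                         paste(utils::head(bad, 10L), collapse = ", "))
  out <- ifelse(uacr < micro_low, "normo", ifelse(uacr <= macro_low, "micro", "macro"))
  factor(out, levels = c("normo", "micro", "macro"))
}

#' Estimated glomerular filtration rate (re-expressed 4-variable MDRD)
#'
#' \deqn{eGFR = 175 \times (Scr/88.4)^{-1.154} \times age^{-0.203}
#'       \times 0.742^{[female]}}
#' with serum creatinine in \eqn{\mu}mol/L (converted to mg/dL by dividing by
#' 88.4) and age in years; result in mL/min/1.73m^2.  No ethnicity
#' coefficient is applied.
#'
#' @param creatinine serum creatinine, \eqn{\mu}mol/L (> 0).
#' @param age years (> 0).
#' @param sex \code{"male"}/\code{"female"} (vectorised, recycled).
#' @return numeric vector, mL/min/1.73m^2.
#' @export
egfr_mdrd <- function(creatinine, age, sex) {
  if (any(!is.na(creatinine) & creatinine <= 0)) stop2("creatinine must be positive")
  if (any(!is.na(age) & age <= 0)) stop2("age must be positive")
  female <- sex %in% c("female", "F", "f", "2", 2)
  175 * (creatinine / 88.4)^(-1.154) * age^(-0.203) * ifelse(female, 0.742, 1)
}

#' Relative risk from a 2x2 table
#'
#' \eqn{RR = risk_{exposed} / risk_{unexposed}} with a log-scale Wald
#' confidence interval.  Swapping which group is the reference returns
#' exactly the reciprocal risk ratio.
#'
#' @param exposed_cases,exposed_total counts in the exposed group.
#' @param unexposed_cases,unexposed_total counts in the unexposed group.
#' @param conf_level confidence level for the Wald interval (default 0.95).
#' @return list with \code{rr}, \code{ci} (length 2, \code{NA} and a
#'   \code{ci_undefined} flag when a zero cell makes the log-scale SE
#'   undefined), and \code{rr_reciprocal} (reference-swapped ratio).
#' @export
relative_risk <- function(exposed_cases, exposed_total,
                          unexposed_cases, unexposed_total,
                          conf_level = 0.95) {
  counts <- c(exposed_cases, exposed_total, unexposed_cases, unexposed_total)
  if (any(counts < 0)) stop2("counts must be non-negative")
  if (exposed_total == 0 || unexposed_total == 0)
    stop2("both exposure-group totals must be positive")
  r1 <- exposed_cases / exposed_total
  r0 <- unexposed_cases / unexposed_total
  if (r0 == 0) stop2("zero risk in the reference group: RR undefined")
  rr <- r1 / r0
  ci <- c(NA_real_, NA_real_); undef <- TRUE
  if (exposed_cases > 0 && unexposed_cases > 0) {
    se <- sqrt(1 / exposed_cases - 1 / exposed_total +
                 1 / unexposed_cases - 1 / unexposed_total)
    zq <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- exp(log(rr) + c(-1, 1) * zq * se)
    undef <- FALSE
  }
  list(rr = rr, ci = ci, ci_undefined = undef, rr_reciprocal = 1 / rr)
}

#' Pairwise-complete Pearson correlation matrix
#'
#' Correlations between the requested variables using, for each pair, all
#' rows where both are observed; the per-cell number of complete pairs is
#' returned alongside.  Cells with fewer than 3 complete pairs are set to
#' \code{NA}.
#'
#' @param pheno data frame (e.g. a \code{phenotype_table}).
#' @param variables character vector of numeric column names.
#' @return list with \code{r} (correlation matrix) and \code{n}
#'   (pairwise-N matrix).
#' @export
correlation_matrix <- function(pheno, variables) {
  miss <- setdiff(variables, names(pheno))
  if (length(miss)) stop2("column(s) not in data: ", paste(miss, collapse = ", "))
  m <- as.matrix(as.data.frame(lapply(pheno[variables], as.numeric)))
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  nmat <- crossprod(!is.na(m))
  r[nmat < 3L] <- NA_real_
  dimnames(nmat) <- dimnames(r)
  list(r = r, n = nmat)
}

#' Multiplicative effect from a base-10 log-scale coefficient
#'
#' A coefficient \eqn{\beta} fitted on a log10-transformed trait corresponds
#' to a \eqn{10^\beta}-fold change of the raw trait per unit of predictor.
#'
#' @param beta finite numeric coefficient(s).
#' @return \eqn{10^\beta}.
#' @export
fold_change_from_log10 <- function(beta) {
  if (any(!is.finite(beta))) stop2("beta must be finite")
  10^beta
}

#' Table-1-style descriptive statistics
#'
#' Medians, ranges, geometric means and albuminuria-category percentages for
#' the study phenotypes, overall and by sex when available.
#'
#' @param pheno data frame with (any of) columns \code{age}, \code{uacr},
#'   \code{sbp}, \code{dbp}, \code{fpg}, \code{creatinine}, \code{sex}.
#' @return data frame of labelled summary statistics.
#' @export
describe_phenotypes <- function(pheno) {
  one <- function(df, label) {
    row <- list(group = label, n = nrow(df))
    if ("age" %in% names(df)) row$median_age <- stats::median(df$age, na.rm = TRUE)
    if ("uacr" %in% names(df)) {
      u <- df$uacr[!is.na(df$uacr)]
      row$geomean_uacr <- 10^mean(log_transform(u))
      row$pct_macroalbuminuria <- 100 * mean(classify_albuminuria(u) == "macro")
    }
    if ("sbp" %in% names(df)) row$median_sbp <- stats::median(df$sbp, na.rm = TRUE)
    if ("dbp" %in% names(df)) row$median_dbp <- stats::median(df$dbp, na.rm = TRUE)
    if ("fpg" %in% names(df)) row$median_fpg <- stats::median(df$fpg, na.rm = TRUE)
    as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- one(pheno, "all")
  if ("sex" %in% names(pheno)) {
    for (s in c("male", "female")) {
      sub <- pheno[!is.na(pheno$sex) & pheno$sex == s, , drop = FALSE]
      if (nrow(sub)) out <- rbind(out, one(sub, s))
    }
  }
  out
}
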