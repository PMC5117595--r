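#' Code genotypes as a numeric covariate
#'
#' Converts allele pairs at one locus into a measured-genotype covariate:
#' \code{carrier} codes presence of at least one risk allele (0/1),
#' \code{additive} counts risk alleles (0/1/2).  Missing genotypes give
#' missing covariates.  Multi-allelic loci are supported by carrier coding of
#' the named risk allele against all others.
#'
#' @param genos a \code{\link{genotype_table}}.
#' @param locus locus name.
#' @param scheme \code{"carrier"} or \code{"additive"}.
#' @param risk_allele allele label counted as the risk allele.
#' @return named numeric vector (by individual id).
#' @export
code_genotype <- function(genos, locus, scheme = c("carrier", "additive"),
                          risk_allele) {
  scheme <- match.arg(scheme)
  a <- locus_alleles(genos, locus)
  allset <- genos$meta[[locus]]$alleles %||% sort(unique(stats::na.omit(c(a))))
  if (!risk_allele %in% allset)
    stop2("risk allele ", risk_allele, " not in allele set of ", locus,
          " (", paste(allset, collapse = ", "), ")")
  if (length(unique(stats::na.omit(c(a)))) < 2L)
    stop2("no variation at locus ", locus)
  count <- (a[, 1L] == risk_allele) + (a[, 2L] == risk_allele)
  x <- if (scheme == "carrier") as.numeric(count > 0L) else as.numeric(count)
  stats::setNames(x, genos$id)
}

locus_alleles <- function(genos, locus) {
  if (!inherits(genos, "genotype_table")) stop2("genos must be a genotype_table")
  a <- genos$alleles[[locus]]
  if (is.null(a)) stop2("locus not present: ", locus)
  a
}

#' Measured-genotype association within the variance-components model
#'
#' Adds a coded genotype to the fixed effects of a univariate
#' variance-components model and refits, returning the genotype effect with
#' its Wald test, per-genotype-class counts, and the change in estimated
#' additive genetic variance relative to the base model, together with the
#' proportion of base genetic variance attributable to the locus (from the
#' fitted effect and the sample allele frequency, see
#' \code{\link{variance_explained}}).
#'
#' @param spec a single-trait \code{\link{vc_spec}} for the base model
#'   (without the genotype term).
#' @param data phenotype data frame with an \code{id} column.
#' @param genos a \code{\link{genotype_table}} covering the analysed ids.
#' @param locus locus name.
#' @param risk_allele risk allele label.
#' @param scheme genotype coding scheme.
#' @param base_fit optional pre-computed base fit (saves one REML fit).
#' @return object of class \code{assoc_result}.
#' @export
measured_genotype_association <- function(spec, data, genos, locus, risk_allele,
                                          scheme = c("carrier", "additive"),
                                          base_fit = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(spec, "vc_spec"), length(spec$traits) == 1L)
  x <- code_genotype(genos, locus, scheme, risk_allele)
  gcol <- paste0(locus, "_", scheme)
  data2 <- data
  data2[[gcol]] <- unname(x[match(as.character(data$id), names(x))])
  spec2 <- vc_spec(spec$traits, c(spec$fixed, gcol), spec$relationship,
                   spec$method)
  if (is.null(base_fit)) base_fit <- fit_univariate(spec, data, se = FALSE)
  fit <- fit_univariate(spec2, data2, se = FALSE)
  beta <- unname(fit$beta[gcol])
  ase <- unname(fit$beta_se[gcol])
  z <- beta / ase
  count <- rowSums(locus_alleles(genos, locus) == risk_allele)
  used <- count[match(fit$ids, genos$id)]
  freq <- allele_frequencies(genos, locus)[[risk_allele]]
  prop <- if (base_fit$V_A > 0)
    variance_explained(beta, scheme, freq, base_fit$V_A) else NULL
  structure(list(locus = locus, scheme = scheme, risk_allele = risk_allele,
                 trait = spec$traits[1L], beta = beta, ase = ase,
                 p = 2 * stats::pnorm(-abs(z)),
                 n_by_class = table(factor(used, levels = 0:2)),
                 V_A_base = base_fit$V_A, V_A_with = fit$V_A,
                 proportion_genetic = if (is.null(prop)) NA_real_ else prop$proportion,
                 capped = if (is.null(prop)) NA else prop$capped,
                 fit = fit, base_fit = base_fit),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat("Measured-genotype association:", x$locus, "(", x$scheme, ", risk",
      x$risk_allele, ") on", x$trait, "\n")
  cat(sprintf("  beta = %.4g (ASE %.4g), Wald p = %.4g\n", x$beta, x$ase, x$p))
  cat(sprintf("  V_A: %.4g -> %.4g; proportion of genetic variance: %.3f\n",
              x$V_A_base, x$V_A_with, x$proportion_genetic))
  invisible(x)
}

#' Proportion of genetic variance explained by a locus
#'
#' Under Hardy-Weinberg equilibrium the coded-genotype variance is
#' \eqn{2p(1-p)} for additive coding and \eqn{c(1-c)} with carrier frequency
#' \eqn{c = 1-(1-p)^2} for carrier coding; the locus accounts for
#' \eqn{\mathrm{Var}(x)\beta^2 / V_A} of the base additive genetic variance.
#' Values above 1 are reported as-is with a \code{capped} flag.
#'
#' @param beta fitted effect per coded unit.
#' @param scheme \code{"carrier"} or \code{"additive"}.
#' @param p risk-allele frequency (strictly between 0 and 1).
#' @param V_A_base additive genetic variance of the base model (> 0).
#' @return list with \code{variance_locus}, \code{proportion}, \code{capped}.
#' @export
variance_explained <- function(beta, scheme = c("carrier", "additive"),
                               p, V_A_base) {
  scheme <- match.arg(scheme)
  if (!is.finite(p) || p <= 0 || p >= 1) stop2("allele frequency must be in (0, 1)")
  if (!is.finite(V_A_base) || V_A_base <= 0) stop2("V_A_base must be positive")
  vx <- if (scheme == "additive") 2 * p * (1 - p) else {
    cfreq <- 1 - (1 - p)^2
    cfreq * (1 - cfreq)
  }
  v <- vx * beta^2
  list(variance_locus = v, proportion = v / V_A_base, capped = v / V_A_base > 1)
}

#' Allele frequencies at a locus
#'
#' Allele-count frequencies over all genotyped individuals, optionally
#' restricted to pedigree founders (avoiding double-counting of transmitted
#' alleles).
#'
#' @param genos a \code{\link{genotype_table}}.
#' @param locus locus name.
#' @param ped pedigree (required when \code{founders_only}).
#' @param founders_only restrict to founders of \code{ped}.
#' @return named numeric vector of frequencies summing to 1.
#' @export
allele_frequencies <- function(genos, locus, ped = NULL, founders_only = FALSE) {
  a <- locus_alleles(genos, locus)
  if (founders_only) {
    if (is.null(ped)) stop2("founders_only requires a pedigree")
    keep <- genos$id %in% ped$id[is_founder(ped)]
    a <- a[keep, , drop = FALSE]
  }
  alleles <- stats::na.omit(c(a))
  if (!length(alleles)) stop2("no non-missing genotypes at ", locus)
  tab <- table(alleles)
  out <- as.numeric(tab) / sum(tab)
  names(out) <- names(tab)
  out
}

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' One-degree-of-freedom chi-square test of observed biallelic genotype
#' counts against the \eqn{\hat p^2, 2\hat p\hat q, \hat q^2} expectations
#' computed from the sample allele frequency.
#'
#' @param counts numeric vector of length 3: counts of the two homozygotes
#'   and the heterozygote, ordered \code{c(AA, Aa, aa)}.
#' @return list with \code{chisq}, \code{df = 1}, \code{p}.
#' @export
hwe_test <- function(counts) {
  if (length(counts) != 3L || any(counts < 0))
    stop2("counts must be 3 non-negative genotype counts (AA, Aa, aa)")
  n <- sum(counts)
  if (n == 0) stop2("no genotypes")
  p <- (2 * counts[1L] + counts[2L]) / (2 * n)
  expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  keep <- expd > 0
  chisq <- sum((counts[keep] - expd[keep])^2 / expd[keep])
  list(chisq = chisq, df = 1L, p = stats::pchisq(chisq, 1L, lower.tail = FALSE))
}

#' Transmission-disequilibrium test
#'
#' Counts transmissions of the risk allele from heterozygous parents to
#' genotyped offspring (both parents must be genotyped so transmissions are
#' unambiguous) and applies the McNemar statistic
#' \eqn{(b-c)^2/(b+c)} on 1 df, where \eqn{b} is the number of risk-allele
#' transmissions and \eqn{c} the number of non-transmissions.  Being a
#' within-family test, it is robust to population stratification.
#'
#' @param ped a \code{pedigree}.
#' @param genos a \code{\link{genotype_table}}.
#' @param locus biallelic locus name.
#' @param risk_allele risk allele label.
#' @return list with \code{b}, \code{c}, \code{statistic}, \code{p},
#'   \code{n_informative} (informative heterozygous parents).
#' @export
tdt <- function(ped, genos, locus, risk_allele) {
  a <- locus_alleles(genos, locus)
  allset <- sort(unique(stats::na.omit(c(a))))
  if (length(allset) > 2L) stop2("TDT requires a biallelic locus; ", locus,
                                 " has alleles ", paste(allset, collapse = ", "))
  g <- stats::setNames(lapply(seq_len(nrow(a)), function(i) a[i, ]), genos$id)
  b <- 0L; cc <- 0L; ninf <- 0L
  for (i in seq_len(nrow(ped))) {
    f <- ped$father[i]; m <- ped$mother[i]
    if (is.na(f) || is.na(m)) next
    gc <- g[[ped$id[i]]]; gf <- g[[f]]; gm <- g[[m]]
    if (is.null(gc) || is.null(gf) || is.null(gm) ||
        anyNA(gc) || anyNA(gf) || anyNA(gm)) next
    het_f <- length(unique(gf)) == 2L
    het_m <- length(unique(gm)) == 2L
    if (!het_f && !het_m) next
    nr_child <- sum(gc == risk_allele)
    if (het_f && het_m) {
      ninf <- ninf + 2L
      if (nr_child == 2L) b <- b + 2L
      else if (nr_child == 0L) cc <- cc + 2L
      else { b <- b + 1L; cc <- cc + 1L }  # one parent transmitted each allele
    } else {
      hom <- if (het_f) gm else gf
      ninf <- ninf + 1L
      transmitted <- if (nr_child == 2L) risk_allele
        else if (nr_child == 0L) setdiff(allset, risk_allele)
        else {
          # child heterozygous: the homozygous parent fixed one allele,
          # the het parent gave the other
          hom_allele <- hom[1L]
          other <- gc[gc != hom_allele]
          if (length(other)) other[1L] else gc[1L]
        }
      if (identical(transmitted, risk_allele)) b <- b + 1L else cc <- cc + 1L
    }
  }
  if (b + cc == 0L) stop2("TDT not computable: no informative transmissions")
  stat <- (b - cc)^2 / (b + cc)
  list(b = b, c = cc, statistic = stat,
       p = stats::pchisq(stat, 1L, lower.tail = FALSE), n_informative = ninf)
}
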