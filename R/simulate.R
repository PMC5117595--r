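#' Default simulation configuration for a community-style pedigree study
#'
#' Bundles the generating truth for a study-shaped synthetic dataset: many
#' small multi-generation families (mean size ~5.7, sizes from 3 up to the
#' forties, at most 5 generations, ~771 members of whom ~357 are phenotyped),
#' two candidate loci (an ACE-like insertion/deletion with risk-allele
#' frequency 0.10 coded as carrier, and a TP53-like codon variant with
#' risk-allele frequency 0.57 coded additively), and four traits (sBP, dBP,
#' log10 UACR, log fasting glucose) with heritabilities, genetic and
#' environmental correlations, and fixed covariate/genotype effects matching
#' the community study this generator emulates.  Total phenotypic variances
#' and covariate distributions are emulation choices (documented in the
#' methods vignette), flagged as such in the returned object.
#'
#' @param n_families number of families.
#' @param mean_extra_offspring Poisson mean of extra offspring per couple
#'   (each couple has \code{min_offspring + Pois(mean_extra_offspring)}
#'   children).
#' @param min_offspring guaranteed offspring per couple (default 1, so every
#'   family has at least 3 members; 0 allows childless founder couples).
#' @param p_marry probability a non-final-generation child marries in a new
#'   founder spouse and reproduces.
#' @param max_generations maximum pedigree depth.
#' @param phenotyping_fraction fraction of members with phenotypes/genotypes.
#' @return a \code{sim_config} list; see fields in the source.
#' @export
study_config <- function(n_families = 135, mean_extra_offspring = 0.75,
                         min_offspring = 1, p_marry = 0.25,
                         max_generations = 5,
                         phenotyping_fraction = 357 / 771) {
  traits <- c("sbp", "dbp", "logacr", "logfpg")
  h2 <- c(sbp = 0.26, dbp = 0.11, logacr = 0.55, logfpg = 0.06)
  total_var <- c(sbp = 225, dbp = 144, logacr = 0.64, logfpg = 0.04)
  r_G <- matrix(c(1, 0.74, 0.22, -0.73,
                  0.74, 1, 0.81, -0.15,
                  0.22, 0.81, 1, 0.38,
                  -0.73, -0.15, 0.38, 1), 4, 4, dimnames = list(traits, traits))
  r_E <- matrix(c(1, 0.47, 0.22, 0.24,
                  0.47, 1, 0.21, 0.16,
                  0.22, 0.21, 1, 0.16,
                  0.24, 0.16, 0.16, 1), 4, 4, dimnames = list(traits, traits))
  sd_g <- sqrt(h2 * total_var)
  sd_e <- sqrt((1 - h2) * total_var)
  G <- outer(sd_g, sd_g) * r_G
  E <- outer(sd_e, sd_e) * r_E
  fixed <- rbind(
    sexmale = c(sbp = 10.5, dbp = 7.2, logacr = -0.114, logfpg = 0.031),
    age     = c(sbp = 0.52, dbp = 0.38, logacr = 0.029, logfpg = 0.0029),
    weight  = c(sbp = -0.0015, dbp = -0.0017, logacr = -0.0007, logfpg = 0.0020))
  loci <- list(
    ACE = list(name = "ACE", alleles = c("I", "D"), risk_allele = "D",
               freq = c(I = 0.90, D = 0.10), scheme = "carrier",
               effects = c(sbp = 6.8, dbp = 8.2, logacr = 0.47, logfpg = 0.050)),
    TP53 = list(name = "TP53", alleles = c("R", "P"), risk_allele = "P",
                freq = c(R = 0.43, P = 0.57), scheme = "additive",
                effects = c(sbp = 0, dbp = 0, logacr = 0.20, logfpg = 0)))
  target_means <- c(sbp = 121, dbp = 74, logacr = log10(5.3), logfpg = log(4.7))
  covariates <- list(age = c(min = 18, max = 76),
                     weight = c(mean = 62, sd = 12),
                     height = c(mean = 165, sd = 9),
                     p_male = 0.515)
  cfg <- list(n_families = n_families,
              mean_extra_offspring = mean_extra_offspring,
              min_offspring = min_offspring,
              p_marry = p_marry, max_generations = max_generations,
              phenotyping_fraction = phenotyping_fraction,
              traits = traits, h2 = h2, total_var = total_var,
              r_G = r_G, r_E = r_E, G = G, E = E, fixed = fixed,
              loci = loci, target_means = target_means,
              covariates = covariates,
              assumptions = c("total phenotypic variances",
                              "covariate distributions", "trait means"))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (is.null(cfg$n_families) || cfg$n_families < 1)
    stop2("impossible configuration: need at least one family")
  stopifnot(cfg$phenotyping_fraction > 0, cfg$phenotyping_fraction <= 1)
  for (loc in cfg$loci) {
    if (any(loc$freq <= 0) || any(loc$freq >= 1) || abs(sum(loc$freq) - 1) > 1e-8)
      stop2("allele frequencies of ", loc$name, " must lie in (0,1) and sum to 1")
  }
  for (M in list(cfg$G, cfg$E))
    if (min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      stop2("G and E must be positive semi-definite")
  invisible(cfg)
}

#' Generate a random multi-family pedigree
#'
#' Families are founded by an unrelated couple; each couple draws
#' \code{1 + Pois(mean_extra_offspring)} children; each child below the
#' maximum generation marries a new unrelated founder with probability
#' \code{p_marry} and reproduces in turn.  Rows are emitted parents-first,
#' so the pedigree is topologically ordered by construction.
#'
#' @param cfg a \code{sim_config} (see \code{\link{study_config}}).
#' @param seed optional integer seed (NULL = use current RNG stream).
#' @return a \code{pedigree}.
#' @export
generate_pedigree <- function(cfg = study_config(), seed = NULL) {
  if (cfg$n_families < 1) stop2("need at least one family")
  with_seed(seed, {
    rows <- vector("list", cfg$n_families)
    for (fam in seq_len(cfg$n_families)) {
      fam_id <- sprintf("F%03d", fam)
      counter <- 0L
      recs <- list()
      new_id <- function() {
        counter <<- counter + 1L
        sprintf("%s_%03d", fam_id, counter)
      }
      add <- function(id, father, mother, sex)
        recs[[length(recs) + 1L]] <<- data.frame(
          family = fam_id, id = id, father = father, mother = mother,
          sex = sex, stringsAsFactors = FALSE)
      expand <- function(father, mother, gen_parent) {
        n_off <- cfg$min_offspring + stats::rpois(1L, cfg$mean_extra_offspring)
        for (k in seq_len(n_off)) {
          child <- new_id()
          csex <- if (stats::runif(1) < 0.5) "male" else "female"
          add(child, father, mother, csex)
          if (gen_parent + 1L < cfg$max_generations &&
              stats::runif(1) < cfg$p_marry) {
            spouse <- new_id()
            add(spouse, NA, NA, if (csex == "male") "female" else "male")
            if (csex == "male") expand(child, spouse, gen_parent + 1L)
            else expand(spouse, child, gen_parent + 1L)
          }
        }
      }
      f0 <- new_id(); m0 <- new_id()
      add(f0, NA, NA, "male"); add(m0, NA, NA, "female")
      expand(f0, m0, 1L)
      rows[[fam]] <- do.call(rbind, recs)
    }
    all <- do.call(rbind, rows)
    new_pedigree(all$family, all$id, all$father, all$mother, all$sex)
  })
}

#' Gene-drop genotypes down a pedigree
#'
#' Founders draw two alleles independently from the configured founder
#' frequencies (Hardy-Weinberg); each offspring receives one allele chosen
#' uniformly from each parent's pair, so genotypes are Mendelian-consistent
#' by construction.
#'
#' @param ped a \code{pedigree}.
#' @param loci list of locus configs, each with \code{name}, \code{alleles},
#'   \code{freq} (named, summing to 1) and optional \code{risk_allele}
#'   (defaults from \code{\link{study_config}}).
#' @param seed optional integer seed.
#' @return a \code{\link{genotype_table}}.
#' @export
drop_genotypes <- function(ped, loci = study_config()$loci, seed = NULL) {
  with_seed(seed, {
    n <- nrow(ped)
    idx <- stats::setNames(seq_len(n), ped$id)
    topo <- attr(ped, "topo") %||% topological_order(ped)
    alleles <- list(); meta <- list()
    for (loc in loci) {
      a <- matrix(NA_character_, n, 2L)
      for (i in topo) {
        f <- ped$father[i]; m <- ped$mother[i]
        a[i, 1L] <- if (is.na(f))
          sample(loc$alleles, 1L, prob = loc$freq[loc$alleles])
        else a[idx[[f]], sample.int(2L, 1L)]
        a[i, 2L] <- if (is.na(m))
          sample(loc$alleles, 1L, prob = loc$freq[loc$alleles])
        else a[idx[[m]], sample.int(2L, 1L)]
      }
      alleles[[loc$name]] <- a
      meta[[loc$name]] <- list(alleles = loc$alleles,
                               risk_allele = loc$risk_allele)
    }
    genotype_table(ped$id, alleles, meta)
  })
}

#' Simulate multivariate phenotypes on a pedigree
#'
#' Forward process of the variance-components model: for trait matrix
#' \eqn{Y}, \eqn{Y = 1\mu' + X B + \sum_\ell x_\ell \beta_\ell' + g + e}
#' with \eqn{vec(g') \sim N(0, A \otimes G)} (drawn through Cholesky factors
#' of \eqn{A} and \eqn{G}) and rows of \eqn{e} iid \eqn{N(0, E)}.
#' Covariates (age, weight, height) are drawn from the configured
#' distributions; sex comes from the pedigree.  Intercepts are set so trait
#' means land on the configured targets given covariate expectations.
#' The phenotyping fraction is applied by masking trait values of a random
#' subset (covariates are retained).
#'
#' @param ped a \code{pedigree}.
#' @param genos a \code{\link{genotype_table}} (from
#'   \code{\link{drop_genotypes}}).
#' @param cfg a \code{sim_config}.
#' @param seed optional integer seed.
#' @return a \code{phenotype_table} with covariates, trait columns, and raw
#'   \code{uacr} (g/mol, \code{10^logacr}) and \code{fpg} (mmol/L,
#'   \code{exp(logfpg)}).
#' @export
simulate_phenotypes <- function(ped, genos, cfg = study_config(), seed = NULL) {
  validate_sim_config(cfg)
  with_seed(seed, {
    n <- nrow(ped)
    t <- length(cfg$traits)
    age <- stats::runif(n, cfg$covariates$age["min"], cfg$covariates$age["max"])
    weight <- stats::rnorm(n, cfg$covariates$weight["mean"], cfg$covariates$weight["sd"])
    height <- stats::rnorm(n, cfg$covariates$height["mean"], cfg$covariates$height["sd"])
    sexmale <- as.numeric(ped$sex == "male")
    Xc <- cbind(sexmale = sexmale, age = age, weight = weight)
    A <- additive_relationship(ped)
    g <- t(chol(A)) %*% matrix(stats::rnorm(n * t), n, t) %*% psd_sqrt(cfg$G)
    e <- matrix(stats::rnorm(n * t), n, t) %*% psd_sqrt(cfg$E)
    Y <- Xc %*% cfg$fixed + g + e
    ex_cov <- c(sexmale = cfg$covariates$p_male,
                age = mean(cfg$covariates$age),
                weight = unname(cfg$covariates$weight["mean"]))
    mu <- cfg$target_means - drop(ex_cov %*% cfg$fixed)
    for (loc in cfg$loci) {
      x <- code_genotype(genos, loc$name, loc$scheme, loc$risk_allele)
      x <- unname(x[ped$id])
      Y <- Y + outer(x, loc$effects[cfg$traits])
      p_risk <- loc$freq[[loc$risk_allele]]
      ex <- if (loc$scheme == "carrier") 1 - (1 - p_risk)^2 else 2 * p_risk
      mu <- mu - ex * loc$effects[cfg$traits]
    }
    Y <- sweep(Y, 2L, mu, "+")
    colnames(Y) <- cfg$traits
    if (cfg$phenotyping_fraction < 1) {
      n_ph <- round(cfg$phenotyping_fraction * n)
      masked <- sample(seq_len(n), n - n_ph)
      Y[masked, ] <- NA_real_
    }
    out <- data.frame(id = ped$id, sex = ped$sex, age = age, weight = weight,
                      height = height, Y, stringsAsFactors = FALSE)
    out$uacr <- 10^out$logacr
    out$fpg <- exp(out$logfpg)
    class(out) <- c("phenotype_table", "data.frame")
    out
  })
}

#' Generate a complete study-shaped synthetic dataset
#'
#' One call builds pedigree, genotypes and phenotypes under
#' \code{\link{study_config}} (or a supplied config), bundled with the full
#' generating truth so downstream estimates can be compared with what
#' produced them.  All randomness flows from the single seed; the same seed
#' reproduces the dataset exactly.
#'
#' @param seed integer seed.
#' @param cfg a \code{sim_config}.
#' @return object of class \code{simulated_study}: \code{pedigree},
#'   \code{genotypes}, \code{phenotypes}, \code{truth} (the config),
#'   \code{phenotyped_ids}.
#' @export
generate_study_like_dataset <- function(seed = NULL, cfg = study_config()) {
  with_seed(seed, {
    ped <- generate_pedigree(cfg)
    genos <- drop_genotypes(ped, cfg$loci)
    pheno <- simulate_phenotypes(ped, genos, cfg)
    structure(list(pedigree = ped, genotypes = genos, phenotypes = pheno,
                   truth = cfg,
                   phenotyped_ids = pheno$id[!is.na(pheno$logacr)]),
              class = "simulated_study")
  })
}

#' @export
print.simulated_study <- function(x, ...) {
  cat("Simulated pedigree study:", nrow(x$pedigree), "members,",
      length(x$phenotyped_ids), "phenotyped,",
      length(x$truth$loci), "loci,", length(x$truth$traits), "traits\n")
  invisible(x)
}

#' Write a simulated study to plain-text files
#'
#' @param study a \code{simulated_study}.
#' @param dir output directory (created if needed); writes
#'   \code{study.ped} (pedigree + genotypes), \code{phenotypes.csv} and
#'   \code{truth.json}.
#' @return named character vector of paths, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "study.ped")
  p2 <- file.path(dir, "phenotypes.csv")
  p3 <- file.path(dir, "truth.json")
  write_pedigree(study$pedigree, p1, study$genotypes)
  write_phenotypes(study$phenotypes, p2)
  truth <- unclass(study$truth)
  truth$r_G <- as.data.frame(truth$r_G); truth$r_E <- as.data.frame(truth$r_E)
  truth$G <- as.data.frame(truth$G); truth$E <- as.data.frame(truth$E)
  truth$fixed <- as.data.frame(truth$fixed)
  jsonlite::write_json(truth, p3, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(pedigree = p1, phenotypes = p2, truth = p3))
}
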