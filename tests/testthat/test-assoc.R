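# small genotype table helper: genotypes given as strings like "D/I"
gt_from_strings <- function(ids, geno, locus = "ACE", alleles = c("I", "D"),
                            risk = "D") {
  m <- do.call(rbind, strsplit(geno, "/"))
  m[m == "NA"] <- NA
  genotype_table(ids, stats::setNames(list(m), locus),
                 stats::setNames(list(list(alleles = alleles,
                                           risk_allele = risk)), locus))
}

test_that("genotype coding follows the carrier and additive schemes", {
  gt <- gt_from_strings(c("a", "b", "c", "d"), c("I/I", "D/I", "D/D", "NA/NA"))
  expect_equal(unname(code_genotype(gt, "ACE", "carrier", "D")),
               c(0, 1, 1, NA))
  expect_equal(unname(code_genotype(gt, "ACE", "additive", "D")),
               c(0, 1, 2, NA))
  # swapping the risk allele complements additive codes
  x_d <- code_genotype(gt, "ACE", "additive", "D")
  x_i <- code_genotype(gt, "ACE", "additive", "I")
  expect_equal(unname(x_i), unname(2 - x_d))
  mono <- gt_from_strings(c("a", "b"), c("I/I", "I/I"))
  expect_error(code_genotype(mono, "ACE", "carrier", "D"), "no variation")
  expect_error(code_genotype(gt, "ACE", "carrier", "Z"), "not in allele set")
})

test_that("variance explained by a locus follows the HWE closed form", {
  # additive, p = 0.5, beta = 1, V_A = 0.5: 2pq beta^2 / V_A = 1, flagged
  v <- variance_explained(1, "additive", 0.5, 0.5)
  expect_equal(v$proportion, 1)
  expect_false(v$capped)  # exactly 1, not above
  expect_true(variance_explained(1.01, "additive", 0.5, 0.5)$capped)
  expect_equal(variance_explained(0, "additive", 0.3, 1)$proportion, 0)
  # carrier frequency c = 1 - (1-p)^2
  p <- 0.1; cfreq <- 1 - 0.9^2
  expect_equal(variance_explained(0.47, "carrier", p, 0.4)$variance_locus,
               cfreq * (1 - cfreq) * 0.47^2, tolerance = 1e-12)
  expect_error(variance_explained(1, "additive", 0, 0.5), "frequency")
  expect_error(variance_explained(1, "additive", 0.5, 0), "positive")
  # invariance under trait rescaling: beta and V_A scale together
  a <- variance_explained(0.4, "additive", 0.2, 0.3)$proportion
  b <- variance_explained(0.4 * 10, "additive", 0.2, 0.3 * 100)$proportion
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("coded-genotype variance in a large gene-dropped sample matches theory", {
  set.seed(51)
  ped <- make_founders(10000)
  loc <- list(name = "L", alleles = c("a", "b"), risk_allele = "b",
              freq = c(a = 0.7, b = 0.3))
  gt <- drop_genotypes(ped, list(loc))
  beta <- 0.8
  x <- code_genotype(gt, "L", "additive", "b")
  expect_equal(var(x * beta), 2 * 0.3 * 0.7 * beta^2, tolerance = 0.02 * 2 * 0.3 * 0.7 * beta^2)
})

test_that("allele frequencies count alleles, with a founders-only option", {
  geno <- c(rep("I/I", 81), rep("D/I", 18), "D/D")
  gt <- gt_from_strings(sprintf("s%03d", 1:100), geno)
  fr <- allele_frequencies(gt, "ACE")
  expect_equal(fr[["D"]], 0.10)
  expect_equal(fr[["I"]], 0.90)
  mono <- genotype_table("a", list(L = matrix(c("x", "x"), 1)),
                         list(L = list(alleles = c("x", "y"))))
  expect_equal(allele_frequencies(mono, "L"), c(x = 1))
  allmiss <- genotype_table("a", list(L = matrix(NA_character_, 1, 2)),
                            list(L = list(alleles = c("x", "y"))))
  expect_error(allele_frequencies(allmiss, "L"), "no non-missing")
  # founders-only on a gene-dropped pedigree sits near the configured freq
  set.seed(52)
  cfg <- study_config(n_families = 60)
  ped <- generate_pedigree(cfg)
  gt2 <- drop_genotypes(ped, cfg$loci)
  fr_f <- allele_frequencies(gt2, "TP53", ped, founders_only = TRUE)
  nf <- sum(is_founder(ped))
  expect_lt(abs(fr_f[["P"]] - 0.57), 3 * sqrt(0.57 * 0.43 / (2 * nf)))
})

test_that("Hardy-Weinberg chi-square matches hand-computed tables", {
  expect_equal(hwe_test(c(25, 50, 25))$chisq, 0)
  expect_equal(hwe_test(c(50, 0, 50))$chisq, 100)
  expect_error(hwe_test(c(0, 0, 0)), "no genotypes")
  expect_error(hwe_test(c(1, 2)), "3 non-negative")
})

test_that("the HWE test is calibrated on gene-dropped founders", {
  set.seed(53)
  ped <- make_founders(100)
  loc <- list(name = "L", alleles = c("a", "b"), risk_allele = "b",
              freq = c(a = 0.6, b = 0.4))
  rej <- replicate(1000, {
    gt <- drop_genotypes(ped, list(loc))
    cnt <- rowSums(gt$alleles$L == "b")
    hwe_test(c(sum(cnt == 0), sum(cnt == 1), sum(cnt == 2)))$p < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("TDT counts transmissions from heterozygous parents correctly", {
  # 10 trios with D/I father, I/I mother
  make_trios <- function(children) {
    n <- length(children)
    fam <- rep(sprintf("T%02d", seq_len(n)), each = 3)
    id <- paste0(fam, c("_f", "_m", "_c"))
    ped <- new_pedigree(fam, id,
                        father = ifelse(endsWith(id, "_c"), paste0(substr(id, 1, 3), "_f"), NA),
                        mother = ifelse(endsWith(id, "_c"), paste0(substr(id, 1, 3), "_m"), NA),
                        sex = rep(c("male", "female", "male"), n))
    geno <- as.vector(rbind(rep("D/I", n), rep("I/I", n), children))
    list(ped = ped, gt = gt_from_strings(id, geno))
  }
  # balanced transmissions: b = c = 10 -> statistic 0
  tr <- make_trios(c(rep("D/I", 10), rep("I/I", 10)))
  res <- tdt(tr$ped, tr$gt, "ACE", "D")
  expect_equal(res$b, 10); expect_equal(res$c, 10)
  expect_equal(res$statistic, 0)
  # all transmit D: b = 10, c = 0 -> statistic 10
  tr2 <- make_trios(rep("D/I", 10))
  res2 <- tdt(tr2$ped, tr2$gt, "ACE", "D")
  expect_equal(res2$b, 10); expect_equal(res2$c, 0)
  expect_equal(res2$statistic, 10)
  # relabelling the risk allele swaps b and c, statistic unchanged
  res2i <- tdt(tr2$ped, tr2$gt, "ACE", "I")
  expect_equal(res2i$b, res2$c); expect_equal(res2i$c, res2$b)
  expect_equal(res2i$statistic, res2$statistic)
  # both parents heterozygous, child heterozygous: one of each
  both <- make_trios("D/I"); both$gt <- gt_from_strings(
    both$ped$id, c("D/I", "D/I", "D/I"))
  rb <- tdt(both$ped, both$gt, "ACE", "D")
  expect_equal(rb$b, 1); expect_equal(rb$c, 1)
  # no informative transmissions -> error
  un <- make_trios(rep("I/I", 2))
  un$gt <- gt_from_strings(un$ped$id, rep("I/I", 6))
  expect_error(tdt(un$ped, un$gt, "ACE", "D"), "not computable")
})

test_that("carrier and additive codings coincide without risk homozygotes", {
  set.seed(54)
  st <- generate_study_like_dataset(7, study_config(n_families = 30))
  gt <- st$genotypes
  cnt <- rowSums(gt$alleles$ACE == "D")
  keep <- which(cnt < 2)  # drop the rare D/D carriers
  gt2 <- genotype_table(gt$id[keep],
                        list(ACE = gt$alleles$ACE[keep, , drop = FALSE]),
                        gt$meta["ACE"])
  xc <- code_genotype(gt2, "ACE", "carrier", "D")
  xa <- code_genotype(gt2, "ACE", "additive", "D")
  expect_identical(unname(xc), unname(xa))
})

test_that("measured-genotype association recovers a simulated carrier effect", {
  set.seed(55)
  cfg <- study_config(n_families = 60, phenotyping_fraction = 1)
  betas <- sapply(1:20, function(i) {
    st <- generate_study_like_dataset(1000 + i, cfg)
    A <- additive_relationship(st$pedigree)
    spec <- vc_spec("logacr", c("sex", "age", "weight"), A)
    res <- measured_genotype_association(spec, st$phenotypes, st$genotypes,
                                         "ACE", "D", "carrier")
    res$beta
  })
  expect_lt(abs(mean(betas) - 0.47), 3 * sd(betas) / sqrt(length(betas)))
})

test_that("association reports genotype classes and variance accounting", {
  set.seed(56)
  st <- generate_study_like_dataset(9, study_config(n_families = 40))
  A <- additive_relationship(st$pedigree)
  spec <- vc_spec("logacr", c("sex", "age", "weight"), A)
  res <- measured_genotype_association(spec, st$phenotypes, st$genotypes,
                                       "TP53", "P", "additive")
  expect_s3_class(res, "assoc_result")
  expect_equal(sum(res$n_by_class), res$fit$n_used)
  expect_true(res$proportion_genetic >= 0)
  expect_lt(res$V_A_with, res$V_A_base + 0.15)  # covariate absorbs locus variance
})
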