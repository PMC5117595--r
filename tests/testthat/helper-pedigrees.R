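# Pedigree builders used across tests (all generated in code, no fixtures).

make_trio <- function() {
  new_pedigree(family = c("T", "T", "T"), id = c("f", "m", "c"),
               father = c(NA, NA, "f"), mother = c(NA, NA, "m"),
               sex = c("male", "female", "male"))
}

# nf nuclear families: 2 founder parents + noff offspring each
make_nuclear <- function(nf = 60, noff = 3) {
  rows <- do.call(rbind, lapply(seq_len(nf), function(f) {
    fam <- sprintf("N%03d", f)
    ids <- paste0(fam, "_", seq_len(2 + noff))
    data.frame(family = fam, id = ids,
               father = c(NA, NA, rep(ids[1L], noff)),
               mother = c(NA, NA, rep(ids[2L], noff)),
               sex = c("male", "female",
                       rep(c("male", "female"), length.out = noff)),
               stringsAsFactors = FALSE)
  }))
  new_pedigree(rows$family, rows$id, rows$father, rows$mother, rows$sex)
}

# founders-only pedigree (A = I)
make_founders <- function(n) {
  new_pedigree(family = rep("U", n), id = sprintf("u%04d", seq_len(n)),
               father = rep(NA_character_, n), mother = rep(NA_character_, n),
               sex = rep(c("male", "female"), length.out = n))
}

# random small pedigree grown by sampling parents from existing members or
# adding founders; produces loops (inbreeding) with appreciable probability
random_small_pedigree <- function(n_target = 10) {
  fam <- "R"
  id <- c("r1", "r2"); father <- c(NA, NA); mother <- c(NA, NA)
  sex <- c("male", "female")
  k <- 2L
  while (k < n_target) {
    k <- k + 1L
    new <- paste0("r", k)
    males <- id[sex == "male"]; females <- id[sex == "female"]
    if (length(males) && length(females) && stats::runif(1) < 0.75) {
      fa <- sample(males, 1L); mo <- sample(females, 1L)
    } else {
      fa <- NA; mo <- NA
    }
    id <- c(id, new); father <- c(father, fa); mother <- c(mother, mo)
    sex <- c(sex, sample(c("male", "female"), 1L))
  }
  new_pedigree(rep(fam, length(id)), id, father, mother, sex)
}

# simulate a univariate phenotype on relationship matrix A with an age covariate
sim_uni <- function(A, va, ve, beta_age = 0.1, intercept = 1) {
  n <- nrow(A)
  age <- stats::runif(n, 20, 60)
  g <- if (va > 0) drop(t(chol(A)) %*% stats::rnorm(n)) * sqrt(va) else 0
  data.frame(id = rownames(A), age = age,
             y = intercept + beta_age * age + g + stats::rnorm(n, sd = sqrt(ve)),
             stringsAsFactors = FALSE)
}

# internal generation-depth helper, reachable when testing the installed package
generation_depth_for_test <- function(ped) pedvc:::generation_depth(ped)
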