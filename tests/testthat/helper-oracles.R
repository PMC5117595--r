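# Independent path-counting oracle for the additive relationship matrix.
# Wright's method: kinship(i, j) sums, over every common ancestor C and every
# pair of ancestral paths i->C and j->C sharing no individual except C,
# (1/2)^(L1 + L2 + 1) * (1 + F_C).  Inbreeding F_i is the kinship of i's
# parents, computed with the same method in topological order.  Deliberately
# shares no code with the tabular recursion in the package.

# all ancestral paths from individual i upward, as vectors of ids (i first)
ancestral_paths <- function(ped, i) {
  idx <- stats::setNames(seq_len(nrow(ped)), ped$id)
  rec <- function(id) {
    out <- list(c(id))
    for (p in c(ped$father[idx[[id]]], ped$mother[idx[[id]]])) {
      if (!is.na(p)) for (tail in rec(p)) out <- c(out, list(c(id, tail)))
    }
    out
  }
  rec(ped$id[i])
}

oracle_kinship_matrix <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  paths <- lapply(seq_len(n), function(i) ancestral_paths(ped, i))
  Fcoef <- stats::setNames(numeric(n), ped$id)

  phi_pair <- function(i, j) {
    # kinship between distinct individuals i and j (row indices)
    tot <- 0
    for (p1 in paths[[i]]) for (p2 in paths[[j]]) {
      anc <- p1[length(p1)]
      if (anc != p2[length(p2)]) next
      shared <- intersect(p1, p2)
      if (length(shared) != 1L) next       # only the common ancestor itself
      L1 <- length(p1) - 1L; L2 <- length(p2) - 1L
      tot <- tot + 0.5^(L1 + L2 + 1) * (1 + Fcoef[[anc]])
    }
    tot
  }

  # inbreeding in topological order (parents' kinship needs ancestors' F)
  for (i in attr(ped, "topo")) {
    f <- ped$father[i]; m <- ped$mother[i]
    Fcoef[[ped$id[i]]] <- if (is.na(f) || is.na(m)) 0
      else phi_pair(idx[[f]], idx[[m]])
  }

  Phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    Phi[i, i] <- 0.5 * (1 + Fcoef[[ped$id[i]]])
    if (i > 1L) for (j in seq_len(i - 1L)) {
      Phi[i, j] <- Phi[j, i] <- phi_pair(i, j)
    }
  }
  2 * Phi  # additive relationship = twice kinship
}
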