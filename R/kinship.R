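#' Additive genetic relationship matrix (tabular method)
#'
#' Computes the numerator relationship matrix \eqn{A} of a pedigree by the
#' tabular recursion, processing individuals in topological order
#' (parents before offspring):
#' \deqn{a_{ii} = 1 + \tfrac12 a_{fm}, \qquad
#'       a_{ij} = \tfrac12 (a_{jf} + a_{jm})}
#' where \eqn{f,m} are the parents of \eqn{i} and \eqn{j} precedes \eqn{i};
#' terms with a missing parent drop out (an unknown parent is a unique,
#' unrelated, non-inbred founder).  Entries are expected proportions of
#' alleles shared identical by descent times two: kinship is \eqn{A/2},
#' inbreeding \eqn{F_i = a_{ii} - 1}.  Disconnected families yield exact
#' zero blocks off the diagonal.
#'
#' @param ped a \code{pedigree} (see \code{\link{read_pedigree}}).
#' @return symmetric matrix of class \code{relationship_matrix} with
#'   dimnames = individual ids in pedigree row order.
#' @examples
#' ped <- new_pedigree(family = c(1, 1, 1), id = c("f", "m", "c"),
#'                     father = c(NA, NA, "f"), mother = c(NA, NA, "m"),
#'                     sex = c("male", "female", "male"))
#' additive_relationship(ped)["f", "c"]  # 0.5
#' @export
additive_relationship <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  topo <- attr(ped, "topo") %||% topological_order(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  fa <- unname(idx[ped$father]); mo <- unname(idx[ped$mother])
  pos <- integer(n); pos[topo] <- seq_len(n)  # topological rank
  # defensive: parents must precede offspring
  ok <- is.na(fa[topo]) | pos[fa[topo]] < seq_len(n)
  ok <- ok & (is.na(mo[topo]) | pos[mo[topo]] < seq_len(n))
  if (!all(ok)) stop2("pedigree is not acyclic; cannot run tabular recursion")
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in topo) {
    f <- fa[i]; m <- mo[i]
    prev <- topo[seq_len(pos[i] - 1L)]
    if (length(prev)) {
      row_f <- if (!is.na(f)) A[f, prev] else 0
      row_m <- if (!is.na(m)) A[m, prev] else 0
      v <- 0.5 * (row_f + row_m)
      A[i, prev] <- v
      A[prev, i] <- v
    }
    A[i, i] <- 1 + if (!is.na(f) && !is.na(m)) 0.5 * A[f, m] else 0
  }
  class(A) <- c("relationship_matrix", class(A))
  A
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat("Additive relationship matrix,", nrow(x), "x", ncol(x), "\n")
  y <- x; attributes(y) <- attributes(x)[c("dim", "dimnames")]
  print(y[seq_len(min(8L, nrow(y))), seq_len(min(8L, ncol(y))), drop = FALSE], ...)
  if (nrow(x) > 8L) cat("...\n")
  invisible(x)
}

#' Inbreeding coefficients from a pedigree
#'
#' \eqn{F_i} is the kinship between the parents of \eqn{i}
#' (\eqn{\Phi(f_i, m_i)}); founders and individuals with an unknown parent
#' have \eqn{F = 0}.  Always equals \code{diag(additive_relationship(ped)) - 1}.
#'
#' @param ped a \code{pedigree}.
#' @return named numeric vector of inbreeding coefficients.
#' @export
inbreeding <- function(ped) {
  A <- additive_relationship(ped)
  stats::setNames(diag(A) - 1, ped$id)
}

#' Extract a principal submatrix of a relationship matrix
#'
#' Restricts \eqn{A} to the requested individuals in the requested order
#' (e.g. the phenotyped subset of a larger pedigree).  A principal submatrix
#' of a PSD matrix is PSD.
#'
#' @param A a \code{relationship_matrix}.
#' @param ids ordered character vector of ids, a subset of \code{rownames(A)}.
#' @return the submatrix, still a \code{relationship_matrix}.
#' @export
align_to_samples <- function(A, ids) {
  unknown <- setdiff(ids, rownames(A))
  if (length(unknown))
    stop2("id(s) not in relationship matrix: ", paste(unknown, collapse = ", "))
  out <- A[ids, ids, drop = FALSE]
  class(out) <- c("relationship_matrix", "matrix", "array")
  out
}

#' Write a relationship matrix as triplet and square text files
#'
#' @param A a \code{relationship_matrix}.
#' @param prefix output path prefix; writes \code{<prefix>.triplet.txt}
#'   (id1, id2, a) for the lower triangle including diagonal, and
#'   \code{<prefix>.square.txt} (labelled square matrix, tab-delimited).
#' @return character vector of the two paths, invisibly.
#' @export
write_relationship <- function(A, prefix) {
  ids <- rownames(A)
  lower <- which(lower.tri(A, diag = TRUE), arr.ind = TRUE)
  trip <- data.frame(id1 = ids[lower[, 1L]], id2 = ids[lower[, 2L]],
                     a = A[lower], stringsAsFactors = FALSE)
  p1 <- paste0(prefix, ".triplet.txt")
  p2 <- paste0(prefix, ".square.txt")
  utils::write.table(trip, p1, quote = FALSE, row.names = FALSE, sep = "\t")
  utils::write.table(as.matrix(A), p2, quote = FALSE, sep = "\t",
                     row.names = TRUE, col.names = NA)
  invisible(c(p1, p2))
}
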