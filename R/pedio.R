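#' Read a LINKAGE/PED pedigree file
#'
#' Parses a whitespace- or tab-delimited pre-makeped LINKAGE pedigree file
#' with columns \code{family, id, father, mother, sex}, optionally followed by
#' genotype columns holding two allele tokens per locus.  \code{"0"} denotes a
#' missing parent or allele; sex is coded \code{1} = male, \code{2} = female,
#' \code{0} = unknown.
#'
#' Individual ids are treated as opaque strings and must be unique across the
#' whole file (multiple disconnected families may share one file).  Parent
#' references must resolve within the file and the parent-offspring graph must
#' be acyclic; violations are errors naming the offending individuals.
#'
#' @param path path to the pedigree file.
#' @param loci optional character vector of locus names for the genotype
#'   columns; defaults to \code{locus1, locus2, ...} when genotype columns are
#'   present.
#' @return A \code{pedigree} object (a data frame with columns \code{family},
#'   \code{id}, \code{father}, \code{mother}, \code{sex}, rows in file order).
#'   If the file carries genotype columns, the resulting
#'   \code{\link{genotype_table}} is attached and retrievable with
#'   \code{\link{genotypes}}.
#' @seealso \code{\link{write_pedigree}}, \code{\link{validate_pedigree}}
#' @export
read_pedigree <- function(path, loci = NULL) {
  if (!file.exists(path)) stop2("pedigree file not found: ", path)
  raw <- utils::read.table(path, header = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 5L) stop2("pedigree file needs >= 5 columns (family, id, father, mother, sex)")
  ped <- new_pedigree(family = raw[[1L]], id = raw[[2L]],
                      father = raw[[3L]], mother = raw[[4L]],
                      sex = decode_sex(raw[[5L]]))
  if (ncol(raw) > 5L) {
    gcols <- raw[, -(1:5), drop = FALSE]
    if (ncol(gcols) %% 2L != 0L)
      stop2("genotype columns must come in allele pairs; found ", ncol(gcols))
    nloc <- ncol(gcols) %/% 2L
    if (is.null(loci)) loci <- paste0("locus", seq_len(nloc))
    if (length(loci) != nloc)
      stop2("expected ", nloc, " locus names, got ", length(loci))
    gt <- genotype_table(ped$id, stats::setNames(lapply(seq_len(nloc), function(k) {
      a1 <- gcols[[2L * k - 1L]]; a2 <- gcols[[2L * k]]
      a1[a1 == "0"] <- NA; a2[a2 == "0"] <- NA
      cbind(a1, a2)
    }), loci))
    attr(ped, "genotypes") <- gt
  }
  ped
}

#' Construct a pedigree from vectors
#'
#' Builds and structurally validates a \code{pedigree}: ids must be unique,
#' parent references must resolve, and the parent-offspring graph must be
#' acyclic (a topological order is computed and cached).  \code{NA} or
#' \code{"0"} denotes a missing parent.
#'
#' @param family,id,father,mother character vectors of equal length.
#' @param sex character vector: \code{"male"}, \code{"female"} or
#'   \code{"unknown"}.
#' @return a \code{pedigree} (data frame subclass), rows in input order.
#' @export
new_pedigree <- function(family, id, father, mother, sex) {
  father[father == "0" | father == ""] <- NA
  mother[mother == "0" | mother == ""] <- NA
  dup <- id[duplicated(id)]
  if (length(dup)) stop2("duplicated individual id(s): ", paste(unique(dup), collapse = ", "))
  bad_f <- father[!is.na(father) & !(father %in% id)]
  bad_m <- mother[!is.na(mother) & !(mother %in% id)]
  if (length(bad_f) || length(bad_m))
    stop2("unresolvable parent id(s): ", paste(unique(c(bad_f, bad_m)), collapse = ", "))
  ped <- data.frame(family = as.character(family), id = as.character(id),
                    father = as.character(father), mother = as.character(mother),
                    sex = sex, stringsAsFactors = FALSE)
  class(ped) <- c("pedigree", "data.frame")
  attr(ped, "topo") <- topological_order(ped)  # errors on cycles
  ped
}

decode_sex <- function(x) {
  out <- rep("unknown", length(x))
  out[x %in% c("1", "m", "M", "male")] <- "male"
  out[x %in% c("2", "f", "F", "female")] <- "female"
  out
}

encode_sex <- function(x) c(male = "1", female = "2", unknown = "0")[x]

# Kahn's algorithm; returns row indices with parents before offspring,
# or errors listing a cycle.
topological_order <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  fa <- idx[ped$father]; mo <- idx[ped$mother]
  indeg <- (!is.na(fa)) + (!is.na(mo))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(fa[i], mo[i])) if (!is.na(p))
      children[[p]] <- c(children[[p]], i)
  }
  queue <- which(indeg == 0L)
  order <- integer(0)
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    order <- c(order, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n) {
    cyc <- ped$id[indeg > 0L]
    stop2("cyclic ancestry involving: ", paste(cyc, collapse = ", "))
  }
  order
}

#' Is an individual a founder?
#'
#' An individual is a founder iff both parent ids are missing.
#' @param ped a \code{pedigree}.
#' @return logical vector in pedigree row order.
#' @export
is_founder <- function(ped) is.na(ped$father) & is.na(ped$mother)

#' Validate a pedigree and report findings
#'
#' Non-fatal structural checks returning a data frame of findings rather than
#' raising errors: parents whose recorded sex contradicts their parental role,
#' individuals with exactly one recorded parent, individuals connected to no
#' one, and families splitting into several connected components.
#'
#' @param ped a \code{pedigree}.
#' @return data frame with columns \code{type}, \code{id}, \code{message};
#'   zero rows when nothing is flagged.
#' @export
validate_pedigree <- function(ped) {
  findings <- list()
  add <- function(type, id, msg)
    findings[[length(findings) + 1L]] <<- data.frame(type = type, id = id,
                                                     message = msg, stringsAsFactors = FALSE)
  sex <- stats::setNames(ped$sex, ped$id)
  for (i in seq_len(nrow(ped))) {
    f <- ped$father[i]; m <- ped$mother[i]
    if (!is.na(f) && sex[[f]] == "female")
      add("sex_inconsistency", f, paste0("father of ", ped$id[i], " is coded female"))
    if (!is.na(m) && sex[[m]] == "male")
      add("sex_inconsistency", m, paste0("mother of ", ped$id[i], " is coded male"))
    if (is.na(f) != is.na(m))
      add("half_parentage", ped$id[i], "exactly one parent recorded")
  }
  # connectivity within declared families
  deg <- stats::setNames(integer(nrow(ped)), ped$id)
  for (i in seq_len(nrow(ped))) for (p in c(ped$father[i], ped$mother[i]))
    if (!is.na(p)) { deg[ped$id[i]] <- deg[ped$id[i]] + 1L; deg[p] <- deg[p] + 1L }
  for (id in ped$id[deg == 0L]) add("isolated", id, "connected to no other individual")
  for (fam in unique(ped$family)) {
    sub <- ped[ped$family == fam, , drop = FALSE]
    if (nrow(sub) > 1L && n_components(sub) > 1L)
      add("multiple_components", fam,
          paste0("family ", fam, " splits into ", n_components(sub), " components"))
  }
  if (!length(findings))
    return(data.frame(type = character(), id = character(), message = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, findings)
}

# connected components of the undirected parent-offspring graph
n_components <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  union2 <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) comp[ri] <<- rj }
  for (i in seq_len(n)) for (p in c(ped$father[i], ped$mother[i]))
    if (!is.na(p)) union2(i, idx[[p]])
  length(unique(vapply(seq_len(n), find, integer(1))))
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree:", nrow(x), "individuals in", length(unique(x$family)),
      "family(ies);", sum(is_founder(x)), "founders\n")
  print(as.data.frame(utils::head(x, 10L)))
  if (nrow(x) > 10L) cat("... and", nrow(x) - 10L, "more rows\n")
  invisible(x)
}

#' Summarise pedigree structure
#'
#' @param object a \code{pedigree}.
#' @param ... unused.
#' @return list with founder count, generation depth per family, and family sizes.
#' @export
summary.pedigree <- function(object, ...) {
  ped <- object
  depth <- generation_depth(ped)
  sizes <- table(ped$family)
  out <- list(n = nrow(ped), n_families = length(sizes),
              n_founders = sum(is_founder(ped)),
              family_sizes = as.integer(sizes),
              mean_family_size = mean(as.integer(sizes)),
              max_generations = max(depth))
  class(out) <- "summary.pedigree"
  out
}

#' @export
print.summary.pedigree <- function(x, ...) {
  cat("Pedigree:", x$n, "individuals,", x$n_families, "families,",
      x$n_founders, "founders\n")
  cat("Family size: mean", round(x$mean_family_size, 2),
      "range", min(x$family_sizes), "-", max(x$family_sizes), "\n")
  cat("Deepest family spans", x$max_generations, "generations\n")
  invisible(x)
}

# 1-based generation number per individual (founders = 1)
generation_depth <- function(ped) {
  idx <- stats::setNames(seq_len(nrow(ped)), ped$id)
  gen <- integer(nrow(ped))
  for (i in attr(ped, "topo")) {
    f <- ped$father[i]; m <- ped$mother[i]
    gen[i] <- 1L + max(0L, gen[idx[f]], gen[idx[m]], na.rm = TRUE)
  }
  gen
}

#' Write a pedigree (and optional genotypes) as a LINKAGE/PED file
#'
#' Emits the same pre-makeped dialect \code{\link{read_pedigree}} accepts, so
#' that writing then reading reproduces the pedigree exactly.
#'
#' @param ped a \code{pedigree}.
#' @param path output file path.
#' @param genotypes optional \code{genotype_table} whose rows cover
#'   \code{ped$id}; written as two allele tokens per locus, \code{0 0} missing.
#' @return \code{path}, invisibly.
#' @export
write_pedigree <- function(ped, path, genotypes = attr(ped, "genotypes")) {
  out <- data.frame(ped$family, ped$id,
                    ifelse(is.na(ped$father), "0", ped$father),
                    ifelse(is.na(ped$mother), "0", ped$mother),
                    encode_sex(ped$sex), stringsAsFactors = FALSE)
  if (!is.null(genotypes)) {
    al <- genotypes$alleles
    for (loc in names(al)) {
      g <- al[[loc]][match(ped$id, genotypes$id), , drop = FALSE]
      g[is.na(g)] <- "0"
      out[[paste0(loc, ".1")]] <- g[, 1L]
      out[[paste0(loc, ".2")]] <- g[, 2L]
    }
  }
  utils::write.table(out, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  invisible(path)
}

#' Construct a genotype table
#'
#' Per-individual unordered allele pairs at one or more loci, with locus
#' metadata (allele set, optional risk allele).
#'
#' @param id character vector of individual ids.
#' @param alleles named list; one element per locus, each an \code{n x 2}
#'   character matrix of allele labels (\code{NA} = missing).
#' @param meta optional named list of per-locus metadata lists
#'   (\code{alleles}, \code{risk_allele}).
#' @return a \code{genotype_table}.
#' @export
genotype_table <- function(id, alleles, meta = NULL) {
  stopifnot(is.list(alleles), !is.null(names(alleles)))
  for (loc in names(alleles)) {
    a <- alleles[[loc]]
    if (!is.matrix(a) || ncol(a) != 2L || nrow(a) != length(id))
      stop2("alleles for locus ", loc, " must be an n x 2 matrix")
    if (is.null(meta[[loc]]$alleles)) {
      meta[[loc]]$alleles <- sort(unique(stats::na.omit(c(a))))
    } else {
      seen <- stats::na.omit(unique(c(a)))
      bad <- setdiff(seen, meta[[loc]]$alleles)
      if (length(bad))
        stop2("locus ", loc, " carries allele(s) outside its declared set: ",
              paste(bad, collapse = ", "))
    }
  }
  structure(list(id = as.character(id), alleles = alleles, meta = meta),
            class = "genotype_table")
}

#' Extract the genotype table attached to a pedigree
#' @param ped a \code{pedigree} read from a file with genotype columns.
#' @return a \code{genotype_table} or \code{NULL}.
#' @export
genotypes <- function(ped) attr(ped, "genotypes")

#' @export
print.genotype_table <- function(x, ...) {
  cat("GenotypeTable:", length(x$id), "individuals x", length(x$alleles), "loci:",
      paste(names(x$alleles), collapse = ", "), "\n")
  invisible(x)
}

#' Read a phenotype table
#'
#' Reads a delimited text file with a header row (comma-separated for
#' \code{.csv}, otherwise tab/whitespace), maps file columns to canonical
#' trait/covariate names through \code{schema}, coerces trait columns to
#' numeric (unparseable cells become \code{NA} with a warning giving the
#' count), and checks physical bounds for recognised traits.
#'
#' Recognised canonical names with positivity bounds: \code{uacr}, \code{sbp},
#' \code{dbp}, \code{fpg}, \code{creatinine}, \code{age}, \code{weight},
#' \code{height}.
#'
#' @param path file path.
#' @param schema named character vector mapping canonical names to file column
#'   names, e.g. \code{c(id = "IID", uacr = "ACR")}. Must include \code{id}.
#'   \code{NULL} keeps file columns as-is (an \code{id} column must exist).
#' @return a data frame of class \code{phenotype_table}, keyed by \code{id}.
#' @export
read_phenotypes <- function(path, schema = NULL) {
  if (!file.exists(path)) stop2("phenotype file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else ""
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  if (!is.null(schema)) {
    if (!"id" %in% names(schema)) stop2("schema must map an 'id' column")
    missing_cols <- setdiff(unname(schema), names(df))
    if (length(missing_cols))
      stop2("column(s) not in file: ", paste(missing_cols, collapse = ", "))
    df <- df[, unname(schema), drop = FALSE]
    names(df) <- names(schema)
  }
  if (!"id" %in% names(df)) stop2("phenotype file has no id column")
  if (anyDuplicated(df$id))
    stop2("duplicated id(s) in phenotype file: ",
          paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  n_bad <- 0L
  for (col in setdiff(names(df), c("id", "sex"))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    n_bad <- n_bad + sum(is.na(v) & !is.na(df[[col]]) & df[[col]] != "" & df[[col]] != "NA")
    df[[col]] <- v
  }
  if (n_bad > 0L) warning(n_bad, " unparseable cell(s) set to NA", call. = FALSE)
  if ("sex" %in% names(df)) {
    num <- suppressWarnings(as.numeric(df$sex))
    df$sex <- if (all(is.na(num[!is.na(df$sex)]))) df$sex else decode_sex(df$sex)
  }
  bounded <- intersect(c("uacr", "sbp", "dbp", "fpg", "creatinine", "age",
                         "weight", "height"), names(df))
  for (col in bounded) {
    bad <- which(!is.na(df[[col]]) & df[[col]] <= 0)
    if (length(bad))
      stop2(col, " must be positive; offending id(s): ",
            paste(df$id[bad], collapse = ", "))
  }
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Write a phenotype table
#'
#' Inverse of \code{\link{read_phenotypes}} (CSV for \code{.csv} paths,
#' otherwise tab-delimited).
#' @param pheno data frame with an \code{id} column.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(pheno, path, quote = FALSE, row.names = FALSE, sep = sep)
  invisible(path)
}
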