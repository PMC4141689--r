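#' Pedigree table
#'
#' Ordered records of (individual, sire, dam). Unknown parents are given as
#' `NA`, `"0"`, `"NA"` or `""`. The constructor checks that the pedigree is
#' acyclic (topologically sortable) and that every named parent either has
#' its own record or is treated as a founder.
#'
#' @param id,sire,dam character vectors of equal length.
#' @return An object of class `pedigree_table` with `id`, `sire`, `dam`
#'   (parents as `NA` when unknown) in a topologically sorted order
#'   (every parent before its offspring).
#' @export
pedigree_table <- function(id, sire, dam) {
  id <- as.character(id); sire <- as.character(sire); dam <- as.character(dam)
  if (length(sire) != length(id) || length(dam) != length(id))
    stop("id, sire and dam must have equal length")
  if (anyDuplicated(id)) stop("duplicated individual id: ",
                              id[duplicated(id)][1])
  unk <- function(x) is.na(x) | x %in% c("0", "NA", "")
  sire[unk(sire)] <- NA_character_
  dam[unk(dam)] <- NA_character_
  # parents that never appear as individuals are implicit founders
  implicit <- setdiff(stats::na.omit(c(sire, dam)), id)
  if (length(implicit)) {
    id <- c(implicit, id)
    sire <- c(rep(NA_character_, length(implicit)), sire)
    dam <- c(rep(NA_character_, length(implicit)), dam)
  }
  n <- length(id)
  si <- match(sire, id); di <- match(dam, id)
  # Kahn topological sort; leftover nodes form a cycle
  indeg_parents <- (!is.na(si)) + (!is.na(di))
  order_out <- integer(0)
  placed <- rep(FALSE, n)
  repeat {
    ready <- which(!placed &
                     (is.na(si) | si %in% order_out) &
                     (is.na(di) | di %in% order_out))
    if (!length(ready)) break
    order_out <- c(order_out, ready)
    placed[ready] <- TRUE
  }
  if (length(order_out) < n) {
    cyc <- id[!placed]
    stop("pedigree contains a cycle involving: ",
         paste(utils::head(cyc, 5), collapse = ", "))
  }
  structure(list(id = id[order_out], sire = sire[order_out],
                 dam = dam[order_out]),
            class = "pedigree_table")
}

#' @export
print.pedigree_table <- function(x, ...) {
  nf <- sum(is.na(x$sire) & is.na(x$dam))
  cat("pedigree_table: ", length(x$id), " individuals (",
      nf, " founders)\n", sep = "")
  invisible(x)
}

#' Additive genetic relationship matrix from a pedigree
#'
#' Builds the numerator relationship matrix A by the tabular (recursive)
#' method: for individual i with parents s and d,
#' a_ii = 1 + a_sd / 2 and a_ij = (a_js + a_jd) / 2 for any older j, an
#' unknown parent contributing 0. Inbreeding is handled exactly.
#'
#' @param pedigree a [pedigree_table()].
#' @return An object of class `a_matrix` with elements `values` (n x n
#'   symmetric matrix) and `id_order` (the pedigree's topological order),
#'   plus an internal factorization cache used by [a_solve()].
#' @export
a_matrix <- function(pedigree) {
  stopifnot(inherits(pedigree, "pedigree_table"))
  n <- length(pedigree$id)
  si <- match(pedigree$sire, pedigree$id)
  di <- match(pedigree$dam, pedigree$id)
  A <- a_matrix_tabular_cpp(si, di)
  dimnames(A) <- list(pedigree$id, pedigree$id)
  structure(list(values = A, id_order = pedigree$id, cache = new.env()),
            class = "a_matrix")
}

#' Wrap a plain relationship matrix
#'
#' Accepts a ready-made symmetric PSD matrix (e.g. the identity for
#' unrelated individuals) as an `a_matrix` so it can be used wherever a
#' pedigree-derived matrix is expected.
#'
#' @param values symmetric numeric matrix.
#' @param id_order individual ids (defaults to rownames or 1..n).
#' @return An `a_matrix`.
#' @export
as_a_matrix <- function(values, id_order = NULL) {
  values <- as.matrix(values)
  if (max(abs(values - t(values))) > 1e-8) stop("matrix is not symmetric")
  values <- (values + t(values)) / 2
  if (is.null(id_order))
    id_order <- if (!is.null(rownames(values))) rownames(values)
                else as.character(seq_len(nrow(values)))
  dimnames(values) <- list(id_order, id_order)
  structure(list(values = values, id_order = id_order, cache = new.env()),
            class = "a_matrix")
}

#' @export
print.a_matrix <- function(x, ...) {
  cat("a_matrix: ", nrow(x$values), " x ", ncol(x$values),
      ", diag range [", format(min(diag(x$values)), digits = 4), ", ",
      format(max(diag(x$values)), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Cached eigendecomposition of an a_matrix
#'
#' The symmetric eigendecomposition A = U diag(d) U' is computed once per
#' object and reused by [a_solve()], the REML null fit and the EM fit.
#'
#' @param A an `a_matrix`.
#' @return List with `vectors` (U) and `values` (d).
#' @export
a_eigen <- function(A) {
  stopifnot(inherits(A, "a_matrix"))
  if (is.null(A$cache$eig)) {
    e <- eigen(A$values, symmetric = TRUE)
    if (min(e$values) < -1e-8 * max(abs(e$values)))
      stop("relationship matrix is not positive semi-definite (min eigenvalue ",
           format(min(e$values)), ")")
    e$values <- pmax(e$values, 0)
    A$cache$eig <- e
  }
  A$cache$eig
}

#' Solve a shifted relationship system
#'
#' Solves (shift * I + A) x = rhs using the cached eigendecomposition of A.
#'
#' @param A an `a_matrix`.
#' @param shift non-negative scalar added to the diagonal.
#' @param rhs numeric vector (or matrix of right-hand sides).
#' @return The solution, with relative residual <= 1e-10.
#' @export
a_solve <- function(A, shift, rhs) {
  if (shift < 0) stop("shift must be non-negative")
  e <- a_eigen(A)
  d <- e$values + shift
  if (min(d) <= 1e-12 * max(d))
    stop("singular system: A is singular and shift is 0")
  x <- e$vectors %*% ((crossprod(e$vectors, rhs)) / d)
  if (is.vector(rhs)) x <- drop(x)
  x
}
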