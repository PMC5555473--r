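#' Sort and validate a pedigree
#'
#' Checks a pedigree table and returns it topologically ordered so that
#' parents always precede their offspring, the ordering required by all the
#' relationship-matrix algebra in this package. Unknown parents may be given
#' as `NA`, `""` or `"0"`; they are normalised to `NA`.
#'
#' @param pedigree A data frame with columns `id`, `sire`, `dam` and
#'   optionally `generation` and `sex`. Ids may be character or integer.
#' @return A tibble with the same columns, parents before offspring, ids as
#'   character and unknown parents as `NA`.
#' @examples
#' ped <- tibble::tibble(
#'   id = c("kid", "pa", "ma"),
#'   sire = c("pa", NA, NA),
#'   dam = c("ma", NA, NA)
#' )
#' sort_pedigree(ped)
#' @export
sort_pedigree <- function(pedigree) {
  ped <- as_tibble(pedigree)
  need <- c("id", "sire", "dam")
  missing_cols <- setdiff(need, names(ped))
  if (length(missing_cols) > 0) {
    abort(paste0("pedigree is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  norm <- function(x) {
    x <- as.character(x)
    x[!is.na(x) & (x == "" | x == "0")] <- NA_character_
    x
  }
  ped$id <- as.character(ped$id)
  ped$sire <- norm(ped$sire)
  ped$dam <- norm(ped$dam)
  if (anyNA(ped$id)) abort("pedigree ids must not be missing")
  if (anyDuplicated(ped$id) > 0) {
    dup <- ped$id[duplicated(ped$id)][1]
    abort(paste0("duplicated pedigree id: ", dup))
  }
  parents <- unique(c(ped$sire, ped$dam))
  parents <- parents[!is.na(parents)]
  unknown <- setdiff(parents, ped$id)
  if (length(unknown) > 0) {
    abort(paste0("parent id(s) not present as individuals: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  self <- ped$id[(!is.na(ped$sire) & ped$sire == ped$id) |
                   (!is.na(ped$dam) & ped$dam == ped$id)]
  if (length(self) > 0) {
    abort(paste0("individual is its own parent: ", self[1]))
  }

  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  s <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  d <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])

  # already parents-first? keep the input order (stable for callers that
  # index other structures by pedigree position)
  if (all(s < idx) && all(d < idx)) {
    return(ped)
  }

  # Kahn's algorithm
  n_par <- (s > 0L) + (d > 0L)
  children <- vector("list", n)
  for (i in idx) {
    if (s[i] > 0L) children[[s[i]]] <- c(children[[s[i]]], i)
    if (d[i] > 0L) children[[d[i]]] <- c(children[[d[i]]], i)
  }
  order_out <- integer(0)
  queue <- idx[n_par == 0L]
  remaining <- n_par
  while (length(queue) > 0) {
    i <- queue[1]
    queue <- queue[-1]
    order_out <- c(order_out, i)
    for (ch in children[[i]]) {
      remaining[ch] <- remaining[ch] - 1L
      if (remaining[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order_out) < n) {
    on_cycle <- ped$id[remaining > 0L][1]
    abort(paste0("pedigree contains a cycle involving individual: ", on_cycle))
  }
  ped[order_out, , drop = FALSE]
}

# integer (sire, dam) representation of a sorted pedigree; 0 = unknown
ped_indices <- function(ped) {
  idx <- seq_len(nrow(ped))
  names(idx) <- ped$id
  list(
    sire = unname(ifelse(is.na(ped$sire), 0L, idx[ped$sire])),
    dam = unname(ifelse(is.na(ped$dam), 0L, idx[ped$dam]))
  )
}

#' Numerator relationship matrix by the tabular method
#'
#' Builds the dense additive (numerator) relationship matrix A by the
#' recursive tabular method, including inbreeding. Intended for small
#' pedigrees (a few thousand individuals at most), mainly as an exact
#' reference for the sparse machinery.
#'
#' @param pedigree A pedigree accepted by [sort_pedigree()].
#' @return A dense symmetric matrix with dimnames equal to the ids, ordered
#'   parents-first.
#' @export
build_A_tabular <- function(pedigree) {
  ped <- sort_pedigree(pedigree)
  n <- nrow(ped)
  pi <- ped_indices(ped)
  s <- pi$sire; d <- pi$dam
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    if (i > 1) {
      j <- seq_len(i - 1L)
      as_ <- if (s[i] > 0L) A[s[i], j] else 0
      ad_ <- if (d[i] > 0L) A[d[i], j] else 0
      aij <- 0.5 * (as_ + ad_)
      A[i, j] <- aij
      A[j, i] <- aij
    }
    A[i, i] <- 1 + if (s[i] > 0L && d[i] > 0L) 0.5 * A[s[i], d[i]] else 0
  }
  A
}

#' Inbreeding coefficients
#'
#' @param pedigree A pedigree accepted by [sort_pedigree()].
#' @return A tibble with columns `id` and `f` (inbreeding coefficient), in
#'   sorted pedigree order.
#' @export
inbreeding <- function(pedigree) {
  ped <- sort_pedigree(pedigree)
  pi <- ped_indices(ped)
  tibble(id = ped$id, f = inbreeding_ml(pi$sire, pi$dam))
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Builds A-inverse directly from the pedigree by Henderson's rules, with
#' Mendelian sampling variances that account for parental inbreeding
#' (inbreeding computed by an ancestor-traversal pass). This never forms A
#' itself and scales to pedigrees of tens of thousands of individuals.
#'
#' @param pedigree A pedigree accepted by [sort_pedigree()].
#' @return A sparse symmetric matrix (`Matrix::dsCMatrix`) with dimnames
#'   equal to the ids in sorted order.
#' @export
build_A_inverse <- function(pedigree) {
  ped <- sort_pedigree(pedigree)
  n <- nrow(ped)
  pi <- ped_indices(ped)
  s <- pi$sire; d <- pi$dam
  f <- inbreeding_ml(s, d)
  fs <- ifelse(s > 0L, f[pmax(s, 1L)], -1)
  fd <- ifelse(d > 0L, f[pmax(d, 1L)], -1)
  dm <- 0.5 - 0.25 * (fs + fd) # Mendelian sampling variance
  if (any(dm <= 0)) {
    abort("non-positive Mendelian sampling variance: corrupt pedigree")
  }
  w <- 1 / dm
  i_idx <- seq_len(n)

  ii <- list(i_idx); jj <- list(i_idx); xx <- list(w)
  hs <- s > 0L; hd <- d > 0L
  add <- function(a, b, v) {
    ii[[length(ii) + 1L]] <<- a
    jj[[length(jj) + 1L]] <<- b
    xx[[length(xx) + 1L]] <<- v
  }
  if (any(hs)) {
    add(i_idx[hs], s[hs], -0.5 * w[hs])
    add(s[hs], s[hs], 0.25 * w[hs])
  }
  if (any(hd)) {
    add(i_idx[hd], d[hd], -0.5 * w[hd])
    add(d[hd], d[hd], 0.25 * w[hd])
  }
  both <- hs & hd
  if (any(both)) {
    # the (sire, dam) cross term stands for both symmetric cells; when
    # sire == dam (selfing) it lands on the diagonal and needs double weight
    cross_w <- ifelse(s[both] == d[both], 0.5, 0.25) * w[both]
    add(s[both], d[both], cross_w)
  }
  ii <- unlist(ii); jj <- unlist(jj); xx <- unlist(xx)
  # keep lower triangle for the symmetric constructor
  lo <- ii >= jj
  r <- ifelse(lo, ii, jj)
  c_ <- ifelse(lo, jj, ii)
  ainv <- Matrix::sparseMatrix(
    i = r, j = c_, x = xx, dims = c(n, n), symmetric = TRUE,
    dimnames = list(ped$id, ped$id)
  )
  ainv
}

#' Relationship operator for a genotyped/nongenotyped partition
#'
#' Packages the sparse A-inverse of a pedigree together with a partition of
#' its members into genotyped and nongenotyped sets and a cached sparse
#' Cholesky factorisation of the nongenotyped (nn) block of A-inverse.
#' The operator supports products of the form `Ang %*% solve(Agg) %*% V`
#' without ever forming the dense blocks `Agg` or `Ang`, via the partitioned
#' inverse identity `Ang Agg^-1 V = -(A^nn)^-1 A^ng V`.
#'
#' @param pedigree A pedigree accepted by [sort_pedigree()].
#' @param genotyped_ids Character vector of ids of genotyped individuals
#'   (must all appear in the pedigree).
#' @return An object of class `rel_operator`.
#' @export
relationship_operator <- function(pedigree, genotyped_ids) {
  ped <- sort_pedigree(pedigree)
  genotyped_ids <- as.character(genotyped_ids)
  bad <- setdiff(genotyped_ids, ped$id)
  if (length(bad) > 0) {
    abort(paste0("genotyped ids not in pedigree: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  ainv <- build_A_inverse(ped)
  g_mask <- ped$id %in% genotyped_ids
  g_idx <- which(g_mask)
  n_idx <- which(!g_mask)
  op <- list(
    pedigree = ped,
    ainv = ainv,
    genotyped_ids = ped$id[g_idx],
    nongenotyped_ids = ped$id[n_idx],
    g_idx = g_idx,
    n_idx = n_idx,
    cache = new.env(parent = emptyenv())
  )
  if (length(n_idx) > 0) {
    op$ainv_nn <- ainv[n_idx, n_idx, drop = FALSE]
    op$ainv_ng <- ainv[n_idx, g_idx, drop = FALSE]
    op$chol_nn <- Matrix::Cholesky(op$ainv_nn, LDL = FALSE, perm = TRUE)
  }
  structure(op, class = "rel_operator")
}

#' @export
print.rel_operator <- function(x, ...) {
  cat("<rel_operator>", nrow(x$pedigree), "pedigree members;",
      length(x$genotyped_ids), "genotyped,",
      length(x$nongenotyped_ids), "nongenotyped\n")
  invisible(x)
}

#' Apply Ang Agg^-1 to columns indexed by genotyped individuals
#'
#' Computes `Ang %*% solve(Agg) %*% V` for a matrix `V` with one row per
#' genotyped individual, using the cached sparse factorisation of the
#' nn-block of A-inverse. This is the workhorse behind both the J covariate
#' and the imputation of marker covariates for nongenotyped individuals.
#'
#' @param operator A [relationship_operator()].
#' @param V Numeric matrix (or vector) with rows ordered as
#'   `operator$genotyped_ids`.
#' @return A matrix with one row per nongenotyped individual, ordered as
#'   `operator$nongenotyped_ids`.
#' @export
solve_nn_block <- function(operator, V) {
  stopifnot(inherits(operator, "rel_operator"))
  if (is.vector(V)) V <- matrix(V, ncol = 1)
  if (nrow(V) != length(operator$genotyped_ids)) {
    abort("V must have one row per genotyped individual")
  }
  nn <- length(operator$nongenotyped_ids)
  if (nn == 0) {
    return(matrix(0, 0, ncol(V),
                  dimnames = list(character(0), colnames(V))))
  }
  rhs <- operator$ainv_ng %*% V
  out <- -as.matrix(Matrix::solve(operator$chol_nn, rhs, system = "A"))
  rownames(out) <- operator$nongenotyped_ids
  colnames(out) <- colnames(V)
  out
}
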