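#' Inbreeding coefficients from a pedigree
#'
#' `F_i` is the kinship (coancestry) of individual `i`'s parents; it is zero
#' whenever either parent is unknown, because phantom parents are assumed to
#' be outbred and unrelated to everything.
#'
#' Two algorithms are provided: `"meuwissen"`, the Meuwissen & Luo-style
#' ancestor-tracing algorithm (compiled; scales to large pedigrees) and
#' `"kinship"`, a memoized recursive coancestry computation kept as an
#' independent, easily-audited path. Both give identical answers (to 1e-12).
#'
#' @param ped ordered pedigree tibble.
#' @param method algorithm; see Details.
#' @return numeric vector of inbreeding coefficients, named by id.
#' @export
inbreeding <- function(ped, method = c("meuwissen", "kinship")) {
  method <- match.arg(method)
  assert_ordered(ped)
  cd <- ped_codes(ped)
  f <- switch(method,
    meuwissen = ml_inbreeding(cd$dam, cd$sire),
    kinship = kinship_inbreeding(cd$dam, cd$sire)
  )
  setNames(f, ped$id)
}

# memoized recursive coancestry phi(i, j); codes 0 = unknown
kinship_inbreeding <- function(dam, sire) {
  n <- length(dam)
  memo <- new.env(parent = emptyenv(), size = 4L * n)
  phi <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (i > j) { t <- i; i <- j; j <- t }
    key <- paste0(i, ":", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (i == j) {
      0.5 * (1 + phi(dam[i], sire[i]))
    } else {
      0.5 * (phi(i, dam[j]) + phi(i, sire[j]))
    }
    memo[[key]] <- val
    val
  }
  vapply(seq_len(n), function(i) phi(dam[i], sire[i]), numeric(1))
}

#' Dense additive (numerator) relationship matrix
#'
#' Tabular method: in pedigree order, `A[i,i] = 1 + A[dam,sire]/2` and
#' `A[i,j] = (A[j,dam] + A[j,sire])/2` for earlier `j`, with unknown parents
#' contributing zero. Dense and quadratic in memory, so intended for moderate
#' pedigrees; it is the brute-force oracle for the sparse machinery.
#'
#' @param ped ordered pedigree tibble.
#' @param max_n refuse (with an error) above this size to prevent accidental
#'   memory blowups.
#' @return dense symmetric matrix with id dimnames.
#' @export
relationship_matrix <- function(ped, max_n = 5000) {
  assert_ordered(ped)
  n <- nrow(ped)
  if (n > max_n)
    abort(sprintf("pedigree has %d individuals; dense A refused above max_n = %d", n, max_n))
  cd <- ped_codes(ped)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    d <- cd$dam[i]; s <- cd$sire[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (d > 0L) row <- row + 0.5 * A[d, j]
      if (s > 0L) row <- row + 0.5 * A[s, j]
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (d > 0L && s > 0L) 0.5 * A[d, s] else 0
  }
  A
}

#' Mendelian sampling variances
#'
#' Diagonal of `D` in Henderson's decomposition `A = T D T'`:
#' `d = 1/2 - (F_s + F_d)/4` with both parents known,
#' `3/4 - F_p/4` with one known, and `1` with none. Genetic-group
#' pseudo-parents never alter `d` (phantom parents are non-inbred).
#'
#' @param ped ordered pedigree tibble.
#' @param f inbreeding coefficients; computed if missing.
#' @return numeric vector `d`, named by id.
#' @export
mendelian_variances <- function(ped, f = inbreeding(ped)) {
  assert_ordered(ped)
  cd <- ped_codes(ped)
  n <- nrow(ped)
  fd <- fs <- rep(NA_real_, n)
  fd[cd$dam > 0L] <- f[cd$dam[cd$dam > 0L]]
  fs[cd$sire > 0L] <- f[cd$sire[cd$sire > 0L]]
  d <- ifelse(!is.na(fd) & !is.na(fs), 0.5 - 0.25 * (fd + fs),
       ifelse(!is.na(fd), 0.75 - 0.25 * fd,
       ifelse(!is.na(fs), 0.75 - 0.25 * fs, 1)))
  setNames(d, ped$id)
}

#' Henderson's T and D factors of the relationship matrix
#'
#' `A = T D T'` with `T` unit lower-triangular (row `i` = half the dam row
#' plus half the sire row plus a 1 at `i`) and `D` the diagonal of Mendelian
#' sampling variances. `T` traces expected gene flow from ancestors to
#' descendants; on a pedigree whose first `r` records are genetic-group
#' pseudo-founders, the first `r` columns of `T` are the group-contribution
#' matrix `Q`.
#'
#' @inheritParams relationship_matrix
#' @return list with dense unit-lower-triangular matrix `T` and numeric
#'   vector `d` (the diagonal of `D`), both carrying id names.
#' @export
tdt_factors <- function(ped, max_n = 5000) {
  assert_ordered(ped)
  n <- nrow(ped)
  if (n > max_n)
    abort(sprintf("pedigree has %d individuals; dense T refused above max_n = %d", n, max_n))
  cd <- ped_codes(ped)
  T_ <- diag(1, n)
  dimnames(T_) <- list(ped$id, ped$id)
  for (i in seq_len(n)) {
    d <- cd$dam[i]; s <- cd$sire[i]
    if (d > 0L) T_[i, ] <- T_[i, ] + 0.5 * T_[d, ]
    if (s > 0L) T_[i, ] <- T_[i, ] + 0.5 * T_[s, ]
    T_[i, i] <- 1
  }
  list(T = T_, d = mendelian_variances(ped))
}

# per-individual rank-one update triplets: Kinv = sum_i delta_i k_i k_i',
# where k_i has 1 at i and -1/2 times each parent weight vector. For the
# plain inverse, unknown slots contribute nothing; for A*, they contribute
# the group membership vector (see a_star).
rank_one_triplets <- function(idx_self, parent_list, delta) {
  ii <- jj <- xx <- vector("list", length(idx_self))
  for (k in seq_along(idx_self)) {
    kp <- c(idx_self[k], unlist(lapply(parent_list[[k]], `[[`, "idx")))
    kw <- c(1, -0.5 * unlist(lapply(parent_list[[k]], `[[`, "w")))
    o <- outer(kw, kw) * delta[k]
    ii[[k]] <- rep(kp, times = length(kp))
    jj[[k]] <- rep(kp, each = length(kp))
    xx[[k]] <- as.vector(o)
  }
  list(i = unlist(ii), j = unlist(jj), x = unlist(xx))
}

#' Sparse inverse of the additive relationship matrix
#'
#' Built directly from the pedigree without forming `A`: each individual `i`
#' contributes `delta_i = 1/d_i` at `(i,i)`, `-delta_i/2` at `(i,p)` for each
#' known parent `p`, and `delta_i/4` at every known-parent pair — equivalently
#' `A^-1 = sum_i delta_i k_i k_i'` with `k_i = e_i - (e_dam + e_sire)/2`
#' restricted to known parents. At most 9 stored entries per individual.
#'
#' @param ped ordered pedigree tibble.
#' @param f inbreeding coefficients; computed if missing.
#' @return sparse symmetric matrix (`Matrix::dsCMatrix`) with id dimnames.
#' @export
a_inverse <- function(ped, f = inbreeding(ped)) {
  assert_ordered(ped)
  n <- nrow(ped)
  cd <- ped_codes(ped)
  d <- mendelian_variances(ped, f)
  parents <- lapply(seq_len(n), function(i) {
    p <- c(cd$dam[i], cd$sire[i])
    lapply(p[p > 0L], function(q) list(idx = q, w = 1))
  })
  tr <- rank_one_triplets(seq_len(n), parents, 1 / unname(d))
  M <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x, dims = c(n, n),
                            dimnames = list(ped$id, ped$id), repr = "C")
  Matrix::forceSymmetric(M, uplo = "L")
}

#' Export / import a sparse symmetric matrix as lower-triangle triplets
#'
#' Plain-text, 1-based `row col value` triplets with `row >= col`, sorted
#' row-major — the dialect used to hand generalized inverses to mixed-model
#' programs (e.g. ASReml `.giv` files). Comment lines starting with `#` carry
#' provenance and the row labels.
#'
#' @param M sparse symmetric matrix.
#' @param path output file path.
#' @param what short description written into the header.
#' @return `path` (writer) or a `dsCMatrix` (reader), invisibly for the writer.
#' @export
write_sparse_triplets <- function(M, path, what = "sparse symmetric matrix") {
  M <- Matrix::forceSymmetric(as(M, "CsparseMatrix"), uplo = "L")
  tm <- as(M, "TsparseMatrix")
  keep <- tm@i >= tm@j
  df <- data.frame(row = tm@i[keep] + 1L, col = tm@j[keep] + 1L, value = tm@x[keep])
  df <- df[order(df$row, df$col), ]
  lines <- c(provenance_line(what, c(n = nrow(M))),
             paste0("# labels: ", paste(rownames(M), collapse = ",")),
             sprintf("%d %d %.17g", df$row, df$col, df$value))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sparse_triplets
#' @export
read_sparse_triplets <- function(path) {
  lines <- readLines(path)
  labline <- grep("^# labels:", lines, value = TRUE)
  labels <- if (length(labline))
    strsplit(sub("^# labels: ", "", labline[1]), ",", fixed = TRUE)[[1]] else NULL
  lines <- lines[!startsWith(lines, "#")]
  con <- textConnection(lines)
  on.exit(close(con))
  df <- utils::read.table(con, col.names = c("row", "col", "value"))
  n <- max(df$row, df$col)
  M <- Matrix::sparseMatrix(i = df$row, j = df$col, x = df$value,
                            dims = c(n, n), symmetric = TRUE)
  if (!is.null(labels) && length(labels) == n) dimnames(M) <- list(labels, labels)
  M
}
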