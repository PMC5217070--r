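#' Genetic-group contribution matrix Q
#'
#' `Q[i, j]` is the expected fraction of individual `i`'s genome deriving from
#' genetic group `j`. In pedigree order, each row is the average of the two
#' parental rows, where a known parent contributes its own (already computed)
#' row and an unknown slot contributes its phantom parent's membership vector
#' (a unit vector for hard assignments). Every row sums to one.
#'
#' `Q` equals the first `r` columns of Henderson's `T` computed on the
#' group-augmented pedigree (see [group_augmented_pedigree()]); the direct
#' recursion here avoids forming `T`.
#'
#' @param gped grouped pedigree from [assign_groups()].
#' @return dense `n x r` matrix, rows named by id, columns by group label.
#' @export
q_matrix <- function(gped) {
  check_grouped(gped)
  labels <- group_labels(gped)
  r <- length(labels)
  n <- nrow(gped)
  cd <- ped_codes(gped)
  dam_m <- attr(gped, "gg_dam_m"); sire_m <- attr(gped, "gg_sire_m")
  Q <- matrix(0, n, r, dimnames = list(gped$id, labels))
  for (i in seq_len(n)) {
    qd <- if (cd$dam[i] > 0L) Q[cd$dam[i], ] else dam_m[i, ]
    qs <- if (cd$sire[i] > 0L) Q[cd$sire[i], ] else sire_m[i, ]
    Q[i, ] <- 0.5 * (qd + qs)
  }
  Q
}

#' Group-augmented sparse inverse A*
#'
#' The `(r + n) x (r + n)` matrix used to fit genetic-group effects
#' implicitly inside the random-effect structure: group rows/columns come
#' first, followed by individuals. It is built with the same per-individual
#' rank-one updates as `A^-1` (`delta_i k_i k_i'`), except that an unknown
#' parent slot directs its weight at the phantom parent's group code(s) —
#' under fuzzy classification the slot's `-delta/2` and `delta/4` terms are
#' spread over groups by the membership vector. Mendelian sampling variances
#' are those of the plain pedigree: substituting a group as pseudo-parent does
#' not change `d_i`.
#'
#' Groups receive no own-record contribution, so every row of `A*` sums to
#' zero and the matrix is singular by construction; deleting the group
#' rows/columns recovers `A^-1` exactly.
#'
#' @param gped grouped pedigree from [assign_groups()].
#' @return sparse symmetric matrix with dimnames `c(group labels, ids)`.
#' @export
a_star <- function(gped) {
  check_grouped(gped)
  labels <- group_labels(gped)
  r <- length(labels)
  n <- nrow(gped)
  cd <- ped_codes(gped)
  dam_m <- attr(gped, "gg_dam_m"); sire_m <- attr(gped, "gg_sire_m")
  d <- mendelian_variances(tibble::as_tibble(gped))
  slot_weights <- function(i, code, m) {
    if (code > 0L) return(list(list(idx = r + code, w = 1)))
    nz <- which(m[i, ] > 0)
    lapply(nz, function(j) list(idx = j, w = m[i, j]))
  }
  parents <- lapply(seq_len(n), function(i) {
    c(slot_weights(i, cd$dam[i], dam_m), slot_weights(i, cd$sire[i], sire_m))
  })
  tr <- rank_one_triplets(r + seq_len(n), parents, 1 / unname(d))
  nm <- c(labels, gped$id)
  M <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                            dims = c(r + n, r + n),
                            dimnames = list(nm, nm), repr = "C")
  Matrix::forceSymmetric(M, uplo = "L")
}

#' Write the Q matrix as CSV
#'
#' One row per individual: `id` plus one column per group label. A provenance
#' comment line is written first.
#'
#' @param Q matrix from [q_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_q_matrix <- function(Q, path) {
  df <- tibble::as_tibble(Q)
  df <- dplyr::bind_cols(tibble::tibble(id = rownames(Q)), df)
  writeLines(provenance_line("Q matrix", c(groups = ncol(Q))), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
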