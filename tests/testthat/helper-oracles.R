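# Shared fixtures and independent oracles for the test suite.

# trio: two founders and their offspring
trio_ped <- function() {
  order_pedigree(tibble::tibble(id = c("s", "d", "i"),
                                dam = c(NA, NA, "d"),
                                sire = c(NA, NA, "s")))
}

# full-sib mating: founders d,s; full sibs a,b; inbred offspring x
fullsib_ped <- function() {
  order_pedigree(tibble::tibble(
    id = c("d", "s", "a", "b", "x"),
    dam = c(NA, NA, "d", "d", "a"),
    sire = c(NA, NA, "s", "s", "b")))
}

# paternal half sibs a, b (shared sire s) and their offspring x
halfsib_ped <- function() {
  order_pedigree(tibble::tibble(
    id = c("s", "d1", "d2", "a", "b", "x"),
    dam = c(NA, NA, NA, "d1", "d2", "a"),
    sire = c(NA, NA, NA, "s", "s", "b")))
}

# n generations of outcrossing a g1-derived lineage to pure-g2 mates:
# founder f0 has both phantom parents in g1; mate_k are pure g2; lineage
# child c_k = c_{k-1} x mate_k.
outcross_ped <- function(n_gen) {
  ids <- c("f0", paste0("m", seq_len(n_gen)), paste0("c", seq_len(n_gen)))
  dam <- c(NA, rep(NA, n_gen), c("f0", paste0("c", seq_len(n_gen - 1)))[seq_len(n_gen)])
  sire <- c(NA, rep(NA, n_gen), paste0("m", seq_len(n_gen)))
  ped <- tibble::tibble(id = ids, dam = dam, sire = sire,
                        immigrant = c(FALSE, rep(TRUE, n_gen), rep(FALSE, n_gen)))
  order_pedigree(ped)
}

# dense generalized-least-squares / BLUP oracle:
# beta = (X' Vi X)^-1 X' Vi y,  u = s2a * A W' Vi (y - X beta)
dense_blup <- function(X, W, y, A, s2a, s2e) {
  V <- s2a * (W %*% A %*% t(W)) + s2e * diag(length(y))
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  u <- s2a * A %*% t(W) %*% Vi %*% (y - X %*% beta)
  list(beta = as.numeric(beta), u = as.numeric(u))
}

# dense REML -2 log-likelihood (V-based), full constants
dense_reml_m2l <- function(X, W, y, A, s2a, s2e) {
  n <- length(y); p <- ncol(X)
  V <- s2a * (W %*% A %*% t(W)) + s2e * diag(n)
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  beta <- solve(XVX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric((n - p) * log(2 * pi) + determinant(V)$modulus +
               determinant(XVX)$modulus + t(r) %*% Vi %*% r)
}

# simulate phenotypes on an arbitrary grouped pedigree with known components
sim_phen_on_ped <- function(gped, g_true, s2a = 1, s2e = 1) {
  A <- relationship_matrix(tibble::as_tibble(gped))
  n <- nrow(A)
  Q <- q_matrix(gped)
  u <- as.numeric(Q %*% g_true) + sqrt(s2a) * as.numeric(t(chol(A)) %*% rnorm(n))
  tibble::tibble(id = rownames(A), y = u + sqrt(s2e) * rnorm(n))
}

write_temp_csv <- function(lines) {
  f <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
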