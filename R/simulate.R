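#' Simulation parameters for an immigration pedigree
#'
#' Defaults describe a closed study population of 15 non-overlapping
#' generations of 400 individuals, receiving 40 immigrants per generation
#' from a genetically diverged source whose mean breeding value is 3 units
#' higher; within-group additive and residual variances are both 1. Cohort 1
#' is entirely founders; later cohorts contain `cohort_size -
#' immigrants_per_generation` locally bred natives plus the immigrants.
#'
#' @param n_generations number of discrete generations.
#' @param cohort_size individuals per generation.
#' @param immigrants_per_generation immigrants joining each generation after
#'   the first.
#' @param immigrant_mean mean total additive genetic effect of immigrants
#'   (founders have mean 0).
#' @param sigma2_A within-group additive genetic variance.
#' @param sigma2_E residual variance.
#' @return a validated `gg_sim_params` list.
#' @export
sim_params <- function(n_generations = 15, cohort_size = 400,
                       immigrants_per_generation = 40, immigrant_mean = 3,
                       sigma2_A = 1, sigma2_E = 1) {
  stopifnot(n_generations >= 1, cohort_size > immigrants_per_generation,
            immigrants_per_generation >= 0, sigma2_A >= 0, sigma2_E >= 0)
  structure(list(n_generations = as.integer(n_generations),
                 cohort_size = as.integer(cohort_size),
                 immigrants_per_generation = as.integer(immigrants_per_generation),
                 immigrant_mean = immigrant_mean,
                 sigma2_A = sigma2_A, sigma2_E = sigma2_E),
            class = "gg_sim_params")
}

#' Simulate a pedigreed population with immigrant gene flow
#'
#' Generates the population described by [sim_params()]: founders' total
#' additive genetic effects `u ~ N(0, sigma2_A)`; immigrants'
#' `u ~ N(immigrant_mean, sigma2_A)`; every native is produced by a randomly
#' assigned monogamous pair from the previous generation (each pair gets a
#' near-equal share of the cohort's native offspring) and inherits the
#' midparent `u` plus a Mendelian sampling deviation with variance
#' `sigma2_A/2 * (1 - (F_dam + F_sire)/2)`. Residuals are
#' `e ~ N(0, sigma2_E)` and phenotypes `y = u + e`; there is no selection and
#' mating is random, so any phenotypic trend is driven purely by gene flow.
#' If a mating pool has an odd number of one sex, the leftover individual
#' joins the last pair as a triad (reported via a message).
#'
#' Breeding values are recorded as deviations from group means,
#' `a = u - Q g_true`, with `Q` computed on the observed (masked) pedigree
#' grouped by immigrant status — founders' group mean 0, immigrants'
#' `immigrant_mean`.
#'
#' @param params a [sim_params()] list.
#' @param seed integer seed; all randomness flows from it.
#' @return a `gg_sim` list: `params`, `seed`, `pedigree` (true),
#'   `masked_pedigree` (immigrants' parents unknown), `truth` tibble
#'   (`id`, `cohort`, `sex`, `immigrant`, `a`, `u`, `e`, `y`), and `g_true`.
#' @export
simulate_population <- function(params = sim_params(), seed = NULL) {
  stopifnot(inherits(params, "gg_sim_params"))
  if (!is.null(seed)) set.seed(seed)
  G <- params$n_generations
  N <- params$cohort_size
  NI <- params$immigrants_per_generation

  recs <- vector("list", G)
  mk_ids <- function(g, k, imm) sprintf("G%02d%s%04d", g, ifelse(imm, "I", "N"), k)
  sexes <- function(k) rep_len(c("F", "M"), k)
  recs[[1]] <- tibble::tibble(id = mk_ids(1, seq_len(N), FALSE),
                              dam = NA_character_, sire = NA_character_,
                              cohort = 1L, sex = sexes(N), immigrant = FALSE)
  for (g in seq_len(G)[-1]) {
    pool <- recs[[g - 1]]
    fem <- sample(pool$id[pool$sex == "F"])
    mal <- sample(pool$id[pool$sex == "M"])
    np <- max(length(fem), length(mal))
    if (length(fem) != length(mal)) {
      inform(sprintf("cohort %d: unequal sexes, one triad formed", g - 1L))
      fem <- rep_len(fem, np); mal <- rep_len(mal, np)
    }
    nn <- N - NI
    share <- rep(nn %/% np, np)
    extra <- nn - sum(share)
    if (extra > 0) {
      pick <- sample.int(np, extra)
      share[pick] <- share[pick] + 1L
    }
    pair_of <- rep(seq_len(np), times = share)
    natives <- tibble::tibble(id = mk_ids(g, seq_len(nn), FALSE),
                              dam = fem[pair_of], sire = mal[pair_of],
                              cohort = g, sex = sexes(nn), immigrant = FALSE)
    imm <- if (NI > 0)
      tibble::tibble(id = mk_ids(g, seq_len(NI), TRUE),
                     dam = NA_character_, sire = NA_character_,
                     cohort = g, sex = rep_len(c("M", "F"), NI), immigrant = TRUE)
    recs[[g]] <- dplyr::bind_rows(natives, imm)
  }
  ped <- dplyr::bind_rows(recs)

  f <- inbreeding(ped)
  cd <- ped_codes(ped)
  n <- nrow(ped)
  u <- numeric(n)
  no_par <- cd$dam == 0L & cd$sire == 0L
  u[no_par] <- rnorm(sum(no_par),
                     mean = ifelse(ped$immigrant[no_par], params$immigrant_mean, 0),
                     sd = sqrt(params$sigma2_A))
  for (i in which(!no_par)) {
    ms_var <- 0.5 * params$sigma2_A * (1 - 0.5 * (f[cd$dam[i]] + f[cd$sire[i]]))
    u[i] <- 0.5 * (u[cd$dam[i]] + u[cd$sire[i]]) + rnorm(1, 0, sqrt(ms_var))
  }
  e <- rnorm(n, 0, sqrt(params$sigma2_E))
  y <- u + e

  masked <- mask_immigrant_parents(ped)
  gped <- assign_groups(masked, rule = "flag")
  g_true <- c(founder = 0, immigrant = params$immigrant_mean)
  Q <- q_matrix(gped)
  a <- u - as.numeric(Q %*% g_true)

  structure(list(params = params, seed = seed,
                 pedigree = ped, masked_pedigree = masked,
                 truth = tibble::tibble(id = ped$id, cohort = ped$cohort,
                                        sex = ped$sex, immigrant = ped$immigrant,
                                        a = a, u = u, e = e, y = y),
                 g_true = g_true),
            class = "gg_sim")
}

#' Mask immigrant parentage
#'
#' Returns the observed pedigree: a copy of the true pedigree in which every
#' immigrant's dam and sire are unknown (founders already are). With zero
#' immigrants the pedigree is returned unchanged.
#'
#' @param x a `gg_sim` or a pedigree tibble with an `immigrant` column.
#' @return pedigree tibble.
#' @export
mask_immigrant_parents <- function(x) {
  ped <- if (inherits(x, "gg_sim")) x$pedigree else x
  if (!"immigrant" %in% names(ped))
    abort("mask_immigrant_parents needs an 'immigrant' column")
  imm <- isTRUE_vec(ped$immigrant)
  ped$dam[imm] <- NA_character_
  ped$sire[imm] <- NA_character_
  ped
}

#' Per-cohort summary of a simulated population
#'
#' Means and variances of phenotypes, total additive genetic effects and
#' breeding values by cohort and immigrant status — the quantities whose
#' temporal trends diagnose gene flow versus local selection.
#'
#' @param sim a `gg_sim`.
#' @return tibble with one row per cohort x immigrant status.
#' @export
simulation_summary <- function(sim) {
  stopifnot(inherits(sim, "gg_sim"))
  dplyr::summarise(
    dplyr::group_by(sim$truth, .data$cohort, .data$immigrant),
    n = dplyr::n(),
    mean_y = mean(.data$y), var_y = var(.data$y),
    mean_u = mean(.data$u), var_u = var(.data$u),
    mean_a = mean(.data$a), var_a = var(.data$a),
    .groups = "drop")
}

#' @export
#' @method print gg_sim
print.gg_sim <- function(x, ...) {
  p <- x$params
  cat(sprintf("Simulated population: %d individuals, %d generations, %d immigrants/generation (mean shift %+g)\n",
              nrow(x$pedigree), p$n_generations, p$immigrants_per_generation,
              p$immigrant_mean))
  cat(sprintf("  sigma2_A = %g, sigma2_E = %g, seed = %s\n",
              p$sigma2_A, p$sigma2_E, x$seed %||% "none"))
  invisible(x)
}

#' Plot cohort trends of a simulated population
#'
#' Cohort means of phenotype `y`, total additive genetic effect `u` and
#' breeding value `a` (deviation from group means): `y` and `u` rise with
#' gene flow while `a` stays flat in the absence of selection.
#'
#' @param object a `gg_sim`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.gg_sim <- function(object, ...) {
  df <- dplyr::summarise(dplyr::group_by(object$truth, .data$cohort),
                         y = mean(.data$y), u = mean(.data$u), a = mean(.data$a),
                         .groups = "drop")
  df <- tidyr::pivot_longer(df, c("y", "u", "a"),
                            names_to = "quantity", values_to = "mean")
  ggplot2::ggplot(df, ggplot2::aes(.data$cohort, .data$mean,
                                   colour = .data$quantity)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "cohort", y = "cohort mean", colour = NULL,
                  title = "Simulated population: gene flow raises y and u, not a") +
    ggplot2::theme_minimal()
}

#' Random pedigree generator for property testing
#'
#' Draws an ordered pedigree with a founder generation and subsequent
#' individuals whose parents are sampled from earlier records of the right
#' sex, each parent slot independently unknown with the given probability.
#' Records with unknown parents are randomly flagged immigrant (so
#' `assign_groups(rule = "flag")` yields two groups). Not a population model —
#' just a source of arbitrary valid pedigrees.
#'
#' @param n number of individuals.
#' @param n_founders number of initial founder records.
#' @param p_unknown probability each non-founder parent slot is unknown.
#' @param seed optional seed.
#' @return ordered pedigree tibble.
#' @export
sim_random_pedigree <- function(n = 100, n_founders = max(4, n %/% 10),
                                p_unknown = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_founders >= 2, n_founders <= n)
  id <- sprintf("X%04d", seq_len(n))
  sex <- rep_len(c("F", "M"), n)
  dam <- sire <- rep(NA_character_, n)
  for (i in seq_len(n)[-seq_len(n_founders)]) {
    fem <- which(sex[seq_len(i - 1)] == "F")
    mal <- which(sex[seq_len(i - 1)] == "M")
    if (length(fem) && runif(1) > p_unknown) dam[i] <- id[sample(fem, 1)]
    if (length(mal) && runif(1) > p_unknown) sire[i] <- id[sample(mal, 1)]
  }
  unk <- is.na(dam) | is.na(sire)
  tibble::tibble(id = id, dam = dam, sire = sire,
                 cohort = pmax(1L, as.integer(ceiling(seq_len(n) / n_founders))),
                 sex = sex,
                 immigrant = unk & (stats::runif(n) < 0.5))
}
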