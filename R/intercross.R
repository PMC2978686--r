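# Forward-time simulator of advanced-intercross-line construction.
#
# Breeding design being modelled: ~100 founder crosses between two
# homozygous strains; 10 generations of random inter-line matings (each new
# mating plate takes a hermaphrodite from one random plate and a male from
# another); 10 L4 hermaphrodites picked per mating plate to found 1000
# selfing lines; 9 further generations of single-hermaphrodite descent;
# final genotyping at an X-linked focal locus (and an optional linked
# marker at recombination fraction r).
#
# Husbandry selection is phenomenological: at every individual-picking step
# a hermaphrodite carrying at least one focal allele is picked with relative
# probability b (b = 1 is neutral). Picks are drawn from finite broods; with
# b = 1 a uniform pick from an iid brood is distributionally identical to a
# single direct draw, and the code uses that shortcut.

#' Simulation configuration for the advanced intercross
#'
#' Defaults reproduce the published breeding design: 100 founder crosses,
#' 10 generations of inter-line mating, 10 lines picked per cross (1000
#' lines), 9 selfing generations, X-linkage.
#'
#' @param n_founder_crosses number of founder crosses / mating plates.
#' @param intermating_generations rounds of random inter-line mating.
#' @param lines_per_cross hermaphrodites picked per plate to found lines.
#' @param selfing_generations single-hermaphrodite selfing transfers.
#' @param linkage `"x_linked"` (hermaphrodites XX, males X0) or
#'   `"autosomal"`.
#' @param r recombination fraction between the focal locus and an optional
#'   linked marker (0 to 0.5).
#' @param pick_bias b: relative pick probability of hermaphrodites carrying
#'   at least one focal allele (1 = neutral).
#' @param bias_phase where the bias acts: `"all"` transfers (default),
#'   `"intermating"` only, or `"selfing"` only.
#' @param brood_size progeny per brood from which picks are drawn.
#' @param extinction_p per-line probability of genotype-independent loss.
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(n_founder_crosses = 100L,
                       intermating_generations = 10L,
                       lines_per_cross = 10L,
                       selfing_generations = 9L,
                       linkage = c("x_linked", "autosomal"),
                       r = 0.2, pick_bias = 1,
                       bias_phase = c("all", "intermating", "selfing"),
                       brood_size = 100L, extinction_p = 0.022) {
  stopifnot(r >= 0, r <= 0.5, pick_bias > 0, n_founder_crosses >= 2,
            extinction_p >= 0, extinction_p < 1)
  structure(list(n_founder_crosses = as.integer(n_founder_crosses),
                 intermating_generations = as.integer(intermating_generations),
                 lines_per_cross = as.integer(lines_per_cross),
                 selfing_generations = as.integer(selfing_generations),
                 linkage = match.arg(linkage), r = r, pick_bias = pick_bias,
                 bias_phase = match.arg(bias_phase),
                 brood_size = as.integer(brood_size),
                 extinction_p = extinction_p),
            class = "sim_config")
}

# A haplotype set is an n x 2 integer matrix: column 1 focal allele (1 =
# focal), column 2 marker allele. Meiotic gamete from a diploid mother.
gamete <- function(h1, h2, r) {
  n <- nrow(h1)
  s <- runif(n) < 0.5                       # haplotype carrying the focal locus
  rec <- runif(n) < r
  ms <- xor(s, rec)                         # haplotype carrying the marker
  cbind(ifelse(s, h1[, 1], h2[, 1]), ifelse(ms, h1[, 2], h2[, 2]))
}

# Weighted pick of one offspring per family from broods of size K.
# make_offspring(i) must return the list of genotype components for brood
# draw i (each an n-row matrix); carrier_of() maps one draw to a logical
# carrier vector. Returns the picked draw indices (length n).
pick_from_brood <- function(n, K, b, carrier) {
  w <- ifelse(carrier, b, 1)                # n x K matrix
  cum <- t(apply(w, 1, cumsum))
  u <- runif(n) * cum[, K]
  pick <- rowSums(u > cbind(0, cum[, -K, drop = FALSE]) & u > 0) # index
  pmax(1L, pick)
}

biased_here <- function(config, phase) {
  config$pick_bias != 1 &&
    (config$bias_phase == "all" || config$bias_phase == phase)
}

# Pick one hermaphrodite offspring per family from (mother, father) matings.
# mother: list(h1, h2); father: matrix (X-linked) or list(h1, h2).
pick_cross_herm <- function(mother, father, config, phase) {
  n <- nrow(mother$h1)
  father_g <- function() if (config$linkage == "x_linked") father$x
    else gamete(father$h1, father$h2, config$r)
  if (!biased_here(config, phase))
    return(list(h1 = gamete(mother$h1, mother$h2, config$r),
                h2 = father_g()))
  K <- config$brood_size
  mg <- lapply(seq_len(K), function(k) gamete(mother$h1, mother$h2, config$r))
  fg <- lapply(seq_len(K), function(k) father_g())
  carrier <- vapply(seq_len(K), function(k)
    mg[[k]][, 1] == 1L | fg[[k]][, 1] == 1L, logical(n))
  pick <- pick_from_brood(n, K, config$pick_bias, carrier)
  h1 <- cbind(vapply(seq_len(n), function(i) mg[[pick[i]]][i, 1], 1L),
              vapply(seq_len(n), function(i) mg[[pick[i]]][i, 2], 1L))
  h2 <- cbind(vapply(seq_len(n), function(i) fg[[pick[i]]][i, 1], 1L),
              vapply(seq_len(n), function(i) fg[[pick[i]]][i, 2], 1L))
  list(h1 = h1, h2 = h2)
}

# Pick one male offspring per family. The pick bias acts identically at
# every intermating transfer, male picks included (a worm avoiding the pick
# does so regardless of sex). X-linked males carry a single maternal X.
pick_cross_male <- function(mother, father, config) {
  n <- nrow(mother$h1)
  one <- function() {
    if (config$linkage == "x_linked")
      list(x = gamete(mother$h1, mother$h2, config$r))
    else list(h1 = gamete(mother$h1, mother$h2, config$r),
              h2 = gamete(father$h1, father$h2, config$r))
  }
  if (!biased_here(config, "intermating")) return(one())
  K <- config$brood_size
  draws <- lapply(seq_len(K), function(k) one())
  carrier <- vapply(draws, function(d)
    if (config$linkage == "x_linked") d$x[, 1] == 1L
    else d$h1[, 1] == 1L | d$h2[, 1] == 1L, logical(n))
  pick <- pick_from_brood(n, K, config$pick_bias, carrier)
  sel <- function(part, col) vapply(seq_len(n), function(i)
    draws[[pick[i]]][[part]][i, col], 1L)
  if (config$linkage == "x_linked")
    list(x = cbind(sel("x", 1), sel("x", 2)))
  else list(h1 = cbind(sel("h1", 1), sel("h1", 2)),
            h2 = cbind(sel("h2", 1), sel("h2", 2)))
}

# One selfing transfer: one hermaphrodite offspring per line.
self_step <- function(mother, config) {
  n <- nrow(mother$h1)
  if (!biased_here(config, "selfing"))
    return(list(h1 = gamete(mother$h1, mother$h2, config$r),
                h2 = gamete(mother$h1, mother$h2, config$r)))
  K <- config$brood_size
  g1 <- lapply(seq_len(K), function(k) gamete(mother$h1, mother$h2, config$r))
  g2 <- lapply(seq_len(K), function(k) gamete(mother$h1, mother$h2, config$r))
  carrier <- vapply(seq_len(K), function(k)
    g1[[k]][, 1] == 1L | g2[[k]][, 1] == 1L, logical(n))
  pick <- pick_from_brood(n, K, config$pick_bias, carrier)
  h1 <- cbind(vapply(seq_len(n), function(i) g1[[pick[i]]][i, 1], 1L),
              vapply(seq_len(n), function(i) g1[[pick[i]]][i, 2], 1L))
  h2 <- cbind(vapply(seq_len(n), function(i) g2[[pick[i]]][i, 1], 1L),
              vapply(seq_len(n), function(i) g2[[pick[i]]][i, 2], 1L))
  list(h1 = h1, h2 = h2)
}

#' Simulate one advanced-intercross experiment
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed (set externally for replicate series).
#' @return list of class `"intercross_sim"` with `lines` (per line: final
#'   focal/marker genotype, founding cross, survival), `focal_fraction`
#'   (focal-allele frequency among surviving lines), `carrier_fraction`,
#'   `het_trajectory` (observed heterozygote fraction at the focal locus
#'   after each selfing generation), and the config.
#' @export
simulate_intercross <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_founder_crosses
  # founder crosses, alternating direction: even plates focal-strain mother
  focal_mother <- seq_len(n) %% 2L == 0L
  hom <- function(allele) cbind(rep(allele, n), rep(allele, n))
  mothers <- list(h1 = hom(1L), h2 = hom(1L))
  mothers$h1[!focal_mother, ] <- 0L; mothers$h2[!focal_mother, ] <- 0L
  if (config$linkage == "x_linked") {
    fathers <- list(x = hom(1L)[, 1:2, drop = FALSE])
    fathers$x[focal_mother, ] <- 0L
  } else {
    fathers <- list(h1 = hom(1L), h2 = hom(1L))
    fathers$h1[focal_mother, ] <- 0L; fathers$h2[focal_mother, ] <- 0L
  }
  for (g in seq_len(config$intermating_generations)) {
    mother_plate <- sample.int(n, n, replace = TRUE)
    shift <- sample.int(n - 1L, n, replace = TRUE)
    father_plate <- (mother_plate + shift - 1L) %% n + 1L   # always distinct
    take <- function(x, i) {
      if (is.list(x)) lapply(x, function(m) m[i, , drop = FALSE])
      else x[i, , drop = FALSE]
    }
    m_src <- take(mothers, mother_plate)
    mf_src <- take(fathers, mother_plate)
    f_src <- take(mothers, father_plate)
    ff_src <- take(fathers, father_plate)
    new_mothers <- pick_cross_herm(m_src, mf_src, config, "intermating")
    new_fathers <- pick_cross_male(f_src, ff_src, config)
    mothers <- new_mothers
    fathers <- new_fathers
  }
  # found lines: lines_per_cross independent hermaphrodite picks per plate
  reps <- rep(seq_len(n), each = config$lines_per_cross)
  take_rows <- function(x) lapply(x, function(m) m[reps, , drop = FALSE])
  founders <- pick_cross_herm(take_rows(mothers),
                              if (config$linkage == "x_linked")
                                list(x = fathers$x[reps, , drop = FALSE])
                              else take_rows(fathers),
                              config, "intermating")
  lines <- founders
  het0 <- mean(lines$h1[, 1] != lines$h2[, 1])
  het <- numeric(config$selfing_generations)
  for (g in seq_len(config$selfing_generations)) {
    lines <- self_step(lines, config)
    het[g] <- mean(lines$h1[, 1] != lines$h2[, 1])
  }
  n_lines <- nrow(lines$h1)
  surviving <- runif(n_lines) >= config$extinction_p
  lines_df <- data.frame(
    line = seq_len(n_lines), cross = reps,
    focal1 = lines$h1[, 1], focal2 = lines$h2[, 1],
    marker1 = lines$h1[, 2], marker2 = lines$h2[, 2],
    surviving = surviving)
  sv <- lines_df[surviving, , drop = FALSE]
  structure(list(
    config = config, lines = lines_df,
    n_surviving = nrow(sv),
    focal_fraction = mean((sv$focal1 + sv$focal2) / 2),
    carrier_fraction = mean(sv$focal1 == 1L | sv$focal2 == 1L),
    marker_fraction = mean((sv$marker1 + sv$marker2) / 2),
    het0 = het0, het_trajectory = het), class = "intercross_sim")
}

#' @export
print.intercross_sim <- function(x, ...) {
  cat(sprintf(paste0("<intercross_sim> %d/%d lines surviving; focal-allele ",
                     "fraction %.3f (marker %.3f)\n"),
              x$n_surviving, nrow(x$lines), x$focal_fraction,
              x$marker_fraction))
  invisible(x)
}

#' Expected and observed heterozygosity decay under selfing
#'
#' Under self-fertilization the expected heterozygosity halves every
#' generation, so starting from heterozygote fraction `h0` at line founding
#' the expectation after g generations is `h0 * (1/2)^g`.
#'
#' @param result an `"intercross_sim"` object, or `NULL` to get the pure
#'   closed form.
#' @param h0 founding heterozygote fraction used for the closed form when
#'   `result` is `NULL` (default 1: a fully heterozygous founder).
#' @param generations number of selfing generations for the closed form.
#' @return data frame with `generation`, `expected`, and (when a simulation
#'   is supplied) `observed`.
#' @export
heterozygosity_trajectory <- function(result = NULL, h0 = 1,
                                      generations = 9L) {
  if (is.null(result))
    return(data.frame(generation = seq_len(generations),
                      expected = h0 * 0.5^seq_len(generations)))
  g <- length(result$het_trajectory)
  data.frame(generation = seq_len(g),
             expected = result$het0 * 0.5^seq_len(g),
             observed = result$het_trajectory)
}

#' Mean focal-allele fraction over simulation replicates
#'
#' @param config a [sim_config()].
#' @param replicates number of replicates.
#' @param seed base seed; replicate i uses `seed + i`.
#' @return list with `mean`, `se`, `fractions` (per replicate).
#' @export
replicate_fractions <- function(config = sim_config(), replicates = 50L,
                                seed = 1L) {
  fr <- vapply(seq_len(replicates), function(i)
    simulate_intercross(config, seed = seed + i)$focal_fraction, numeric(1))
  list(mean = mean(fr), se = stats::sd(fr) / sqrt(replicates),
       fractions = fr)
}

#' Fit the husbandry pick bias to an observed allele fraction
#'
#' Grid search over the bias b, simulating replicate experiments at each
#' grid point with common random numbers, minimizing the absolute distance
#' between the simulated mean focal-allele fraction and the observed one.
#' The Monte-Carlo interval contains every grid point whose simulated mean
#' is within `z_se` standard errors of the observed fraction.
#'
#' @param observed_fraction observed focal-allele line fraction, in [0, 1].
#' @param config a [sim_config()] (its `pick_bias` is overridden).
#' @param grid bias values to evaluate.
#' @param replicates simulation replicates per grid point.
#' @param seed base seed (shared across grid points: common random numbers).
#' @param z_se interval half-width in standard errors.
#' @param observed_se optional Monte-Carlo / sampling standard error of
#'   `observed_fraction`, added in quadrature when judging compatibility.
#' @return list with `b_hat`, `interval` (range of compatible grid points),
#'   and `grid` (a data frame: b, mean, se).
#' @export
fit_pick_bias <- function(observed_fraction, config = sim_config(),
                          grid = c(0.25, 0.5, 0.75, 1, 1.5, 2, 3, 5),
                          replicates = 20L, seed = 1L, z_se = 3,
                          observed_se = 0) {
  stopifnot(observed_fraction >= 0, observed_fraction <= 1)
  rows <- lapply(grid, function(b) {
    cfg <- config; cfg$pick_bias <- b
    r <- replicate_fractions(cfg, replicates, seed)
    data.frame(b = b, mean = r$mean, se = r$se)
  })
  tab <- do.call(rbind, rows)
  err <- abs(tab$mean - observed_fraction)
  compat <- err <= z_se * pmax(sqrt(tab$se^2 + observed_se^2), 1e-12)
  list(b_hat = tab$b[which.min(err)],
       interval = if (any(compat)) range(tab$b[compat]) else
         rep(tab$b[which.min(err)], 2),
       grid = tab)
}
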