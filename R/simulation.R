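# Generative models for calibration and power studies. Data are drawn at
# the pseudobulk level: alpha_i ~ N(0, sigma_alpha2), Gamma_i. ~ N(0, V),
# and measurement noise with known per-entry variance nu. The defaults are
# the study conditions used throughout the package's operating
# characteristics: C = 4 equal-proportion cell types, beta = 0,
# sigma_alpha2 = 0.1, Free-model V = 0.1 I, nu_ic ~ Uniform(0.05, 0.15).

#' Simulation configuration
#'
#' @param n_individuals number of individuals N.
#' @param n_cell_types number of cell types C.
#' @param structure generative structure: "hom", "free" or "full".
#' @param sigma_alpha2 shared interindividual variance.
#' @param V C x C cell type-specific covariance target (diagonal under
#'   "free", 0 under "hom"). A scalar is expanded to `diag(scalar, C)`.
#' @param beta cell-type mean expression (length C, recycled).
#' @param proportions expected cell-type proportions (sum to 1).
#' @param proportion_concentration Dirichlet concentration controlling
#'   across-individual proportion variability in OP simulation (larger =
#'   less variable).
#' @param nu_range range of the Uniform distribution the true noise
#'   variances nu_ic are drawn from.
#' @param nu_noise_b Beta(2, b) shape for noise injected into nu before
#'   fitting ([perturb_nu()]); `Inf` = no noise.
#' @param seed base RNG seed; replicate r uses `seed + r`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 100, n_cell_types = 4,
                       structure = c("hom", "free", "full"),
                       sigma_alpha2 = 0.1,
                       V = NULL,
                       beta = 0,
                       proportions = NULL,
                       proportion_concentration = 20,
                       nu_range = c(0.05, 0.15),
                       nu_noise_b = Inf,
                       seed = 1L) {
  structure <- match.arg(structure)
  C <- n_cell_types
  if (is.null(V)) {
    V <- switch(structure, hom = matrix(0, C, C),
                free = diag(0.1, C), full = diag(0.1, C))
  } else if (length(V) == 1) V <- diag(as.numeric(V), C)
  V <- as.matrix(V)
  if (structure == "hom" && any(V != 0)) stop("hom structure requires V = 0")
  if (structure == "free" && any(V[upper.tri(V)] != 0))
    stop("free structure requires a diagonal V")
  if (is.null(proportions)) proportions <- rep(1 / C, C)
  if (abs(sum(proportions) - 1) > 1e-8) stop("proportions must sum to 1")
  structure(list(n_individuals = n_individuals, n_cell_types = C,
                 structure = structure, sigma_alpha2 = sigma_alpha2, V = V,
                 beta = rep_len(beta, C), proportions = proportions,
                 proportion_concentration = proportion_concentration,
                 nu_range = nu_range, nu_noise_b = nu_noise_b,
                 seed = as.integer(seed)),
            class = "sim_config")
}

rdirichlet1 <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              n, length(alpha))
  g / rowSums(g)
}

sim_draw_core <- function(config) {
  N <- config$n_individuals; C <- config$n_cell_types
  alpha <- stats::rnorm(N, 0, sqrt(config$sigma_alpha2))
  ev <- eigen(config$V, symmetric = TRUE)
  rootV <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  Gamma <- matrix(stats::rnorm(N * C), N, C) %*% rootV
  nu <- matrix(stats::runif(N * C, config$nu_range[1], config$nu_range[2]), N, C)
  list(alpha = alpha, Gamma = Gamma, nu = nu)
}

#' Simulate cell type-specific pseudobulk
#'
#' Draws `y[i,c] = beta_c + alpha_i + Gamma_ic + delta_ic` with
#' `delta_ic ~ N(0, nu_ic)`. Returns the pseudobulk bundle plus the true
#' parameters. If `nu_noise_b` is finite, the returned `$nu` carries
#' Beta(2, b)-perturbed noise variances (what the analyst would plug in)
#' while `$nu_true` holds the variances the data were drawn with.
#'
#' @param config a [sim_config].
#' @param replicate replicate number r; the RNG is seeded with `seed + r`.
#' @return list with `pb` (a `pseudobulk`), `truth` (a
#'   [variance_components]), `nu_true`.
#' @export
simulate_ctp <- function(config, replicate = 1L) {
  set.seed(config$seed + as.integer(replicate))
  N <- config$n_individuals; C <- config$n_cell_types
  cd <- sim_draw_core(config)
  delta <- matrix(stats::rnorm(N * C, 0, sqrt(cd$nu)), N, C)
  y <- matrix(config$beta, N, C, byrow = TRUE) + cd$alpha + cd$Gamma + delta
  nu_fit <- if (is.finite(config$nu_noise_b))
    perturb_nu(cd$nu, config$nu_noise_b) else cd$nu
  P <- matrix(config$proportions, N, C, byrow = TRUE)
  pb <- as_pseudobulk(y, nu_fit, P = P)
  list(pb = pb,
       truth = variance_components(config$beta, config$sigma_alpha2,
                                   config$V),
       nu_true = cd$nu)
}

#' Simulate overall pseudobulk
#'
#' Draws per-individual proportions from a Dirichlet around the target
#' proportions and generates
#' `y_i = sum_c P_ic beta_c + alpha_i + sum_c P_ic Gamma_ic + delta_i`
#' with `delta_i ~ N(0, nu_i)`, `nu_i = sum_c P_ic^2 nu_ic`.
#'
#' @inheritParams simulate_ctp
#' @return list with `pb`, `truth`, `nu_true` (the per-entry nu_ic).
#' @export
simulate_op <- function(config, replicate = 1L) {
  set.seed(config$seed + as.integer(replicate))
  N <- config$n_individuals; C <- config$n_cell_types
  cd <- sim_draw_core(config)
  P <- rdirichlet1(N, config$proportion_concentration * config$proportions)
  nu_op <- rowSums(P^2 * cd$nu)
  y_op <- drop(P %*% config$beta) + cd$alpha + rowSums(P * cd$Gamma) +
    stats::rnorm(N, 0, sqrt(nu_op))
  nu_fit <- if (is.finite(config$nu_noise_b))
    perturb_nu(cd$nu, config$nu_noise_b) else cd$nu
  # package as pseudobulk; CTP slots carry nothing usable for OP-only data
  pb <- as_pseudobulk(matrix(y_op, N, C) * NA_real_, nu_fit, P = P)
  pb$y_op <- y_op
  pb$nu_op <- rowSums(P^2 * nu_fit)
  list(pb = pb,
       truth = variance_components(config$beta, config$sigma_alpha2,
                                   config$V),
       nu_true = cd$nu)
}

#' Perturb noise variances with Beta-distributed relative error
#'
#' Emulates estimation error in nu: for each entry, draws
#' `x ~ Beta(2, b)` and a fair sign, returning `nu * (1 + s * x)`. Since
#' x < 1 the result stays nonnegative. `b = Inf` returns nu unchanged;
#' smaller b means more noise (E[x] = 2 / (2 + b)).
#'
#' @param nu matrix/vector of noise variances.
#' @param b Beta shape parameter (the study grid is 20, 10, 5, 3, 2).
#' @return perturbed nu of the same shape.
#' @export
perturb_nu <- function(nu, b) {
  if (b <= 0) stop("b must be positive")
  if (!is.finite(b)) return(nu)
  x <- stats::rbeta(length(nu), 2, b)
  s <- sample(c(-1, 1), length(nu), replace = TRUE)
  out <- nu * (1 + s * x)
  dim(out) <- dim(nu)
  out
}

#' Rejection rates and estimate summaries over a simulation grid
#'
#' Runs `n_replicates` simulations per configuration, fits the requested
#' estimators, applies the requested tests of cell type-specific variance,
#' and tabulates rejection rates at `alpha` together with the mean and
#' sampling SD of each parameter estimate. Non-converged replicates are
#' counted, not silently dropped.
#'
#' Tests: "lrt" (REML/ML likelihood ratio), "wald_fisher",
#' "wald_jackknife"; HE fits are always tested with the jackknife Wald.
#'
#' @param configs a [sim_config] or list of them.
#' @param methods subset of c("reml", "ml", "he").
#' @param tests subset of c("lrt", "wald_fisher", "wald_jackknife").
#' @param mode "CTP" or "OP".
#' @param n_replicates replicates per configuration.
#' @param alpha nominal test level.
#' @return data.frame with one row per (config, method, test):
#'   rejection rate, replicate counts, and estimate summaries.
#' @export
operating_characteristics <- function(configs, methods = "reml",
                                      tests = "lrt", mode = "CTP",
                                      n_replicates = 100, alpha = 0.05) {
  if (inherits(configs, "sim_config")) configs <- list(configs)
  rows <- list()
  for (cfg in configs) {
    C <- cfg$n_cell_types
    pcount <- array(0, dim = c(length(methods), length(tests)),
                    dimnames = list(methods, tests))
    nconv <- pcount
    nfail <- stats::setNames(numeric(length(methods)), methods)
    est_sa <- lapply(methods, function(m) numeric(0))
    est_v <- lapply(methods, function(m) NULL)
    names(est_sa) <- names(est_v) <- methods
    for (r in seq_len(n_replicates)) {
      sim <- if (mode == "CTP") simulate_ctp(cfg, r) else simulate_op(cfg, r)
      pb <- sim$pb
      spec_free <- ctmm_spec("free", mode)
      spec_hom <- ctmm_spec("hom", mode)
      for (m in methods) {
        if (m == "he") {
          ff <- fit_he(pb, spec_free)
          fh <- NULL
        } else {
          ff <- fit_likelihood(pb, spec_free, m)
          fh <- fit_likelihood(pb, spec_hom, m)
        }
        if (!ff$converged || (!is.null(fh) && !fh$converged)) {
          nfail[m] <- nfail[m] + 1
          next
        }
        est_sa[[m]] <- c(est_sa[[m]], ff$params$sigma_alpha2)
        est_v[[m]] <- rbind(est_v[[m]], diag(ff$params$V))
        jk <- NULL
        for (tst in tests) {
          p <- tryCatch({
            if (m == "he" || tst == "wald_jackknife") {
              if (is.null(jk)) jk <- jackknife_fit(pb, ff)
              wald_variance_test(ff, pb, "jackknife", jack = jk)$p_value
            } else if (tst == "lrt") {
              lrt_free_vs_hom(ff, fh)$p_value
            } else if (tst == "wald_fisher") {
              wald_variance_test(ff, pb, "fisher")$p_value
            } else stop("unknown test: ", tst)
          }, error = function(e) NA_real_)
          if (!is.na(p)) {
            nconv[m, tst] <- nconv[m, tst] + 1
            if (p < alpha) pcount[m, tst] <- pcount[m, tst] + 1
          }
        }
      }
    }
    for (m in methods) for (tst in tests) {
      vm <- est_v[[m]]
      rows[[length(rows) + 1L]] <- data.frame(
        structure = cfg$structure, mode = mode,
        n_individuals = cfg$n_individuals, n_cell_types = C,
        nu_noise_b = cfg$nu_noise_b,
        method = m, test = tst,
        n_replicates = n_replicates,
        n_tested = nconv[m, tst], n_failed = nfail[m],
        rejection_rate = if (nconv[m, tst] > 0)
          pcount[m, tst] / nconv[m, tst] else NA_real_,
        mean_sigma_alpha2 = mean(est_sa[[m]]),
        sd_sigma_alpha2 = stats::sd(est_sa[[m]]),
        mean_V_11 = if (!is.null(vm)) mean(vm[, 1]) else NA_real_,
        sd_V_11 = if (!is.null(vm)) stats::sd(vm[, 1]) else NA_real_)
    }
  }
  do.call(rbind, rows)
}
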