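# Shared fixtures: all data are generated in code at test time.

# A small complete pseudobulk with varying proportions (so that OP designs
# are well conditioned).
random_pb <- function(N = 8, C = 3, seed = 1) {
  set.seed(seed)
  y <- matrix(rnorm(N * C), N, C)
  nu <- matrix(runif(N * C, 0.05, 0.15), N, C)
  P <- matrix(rgamma(N * C, 5), N, C)
  P <- P / rowSums(P)
  as_pseudobulk(y, nu, P = P)
}

random_params <- function(C = 3, structure = "free", seed = 1) {
  set.seed(seed)
  V <- switch(structure,
              hom = matrix(0, C, C),
              iid = diag(runif(1, 0.05, 0.3), C),
              free = diag(runif(C, 0.05, 0.3), C),
              full = {
                A <- matrix(rnorm(C * C, 0, 0.2), C, C)
                crossprod(A) + diag(0.05, C)
              })
  variance_components(beta = rnorm(C, 0, 0.5),
                      sigma_alpha2 = if (structure == "full") 0
                                     else runif(1, 0.05, 0.3),
                      V = V)
}

# A manually assembled fit object (for tests that exercise downstream code
# with known parameters).
manual_fit <- function(params, spec, N, C, method = "reml", objective = 0) {
  ctvmm:::new_fit(params = params, objective = objective, converged = TRUE,
                  n_restarts_used = 0L, method = method, spec = spec,
                  N = N, C = C,
                  theta = ctvmm:::pack_theta(params, spec$structure,
                                             !is.null(spec$batch)))
}
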