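# hand-built GP model objects for prediction-side tests

make_manual_gp_model <- function(S, t, block, mu_u, L, m0 = 0,
                                 sigma2_s = 1, sigma2_t = 1, ell_t = 1,
                                 W = NULL, Q = ncol(S),
                                 blocks = character(0),
                                 task_cfg = task_config(),
                                 jitter = 1e-8) {
  D <- if (is.null(W)) 1 else ncol(W)
  if (is.null(W)) W <- matrix(0, Q, 1)
  cfg <- gp_config(Q = Q, D = D, J = 1, M = nrow(S), minibatch = 1e6,
                   jitter = jitter)
  n_comp <- 1 + length(blocks)
  L_raw <- L
  L_raw[upper.tri(L_raw)] <- 0
  diag(L_raw) <- log(pmax(diag(L), 1e-12))
  par <- list(
    m0 = m0, mu_u = mu_u, L_raw = L_raw,
    log_s2s = log(pmax(rep_len(sigma2_s, n_comp), 1e-300)),
    log_s2t = log(pmax(rep_len(sigma2_t, n_comp), 1e-300)),
    log_lt = log(rep_len(ell_t, n_comp)),
    warp_a_raw = -40, warp_b_raw = 0, warp_c = 0, # a ~ 0: identity warp
    W_mean = W, W_logsd = matrix(log(1e-8), Q, D)
  )
  structure(list(
    cfg = cfg, task_cfg = task_cfg, par = par, W = W,
    W_sd = exp(par$W_logsd), ard_precisions = rep(1, D),
    warp = vischange:::warp_from_raw(par),
    kern = vischange:::kern_from_par(par, blocks),
    blocks = blocks, Z_S = S, Z_t = t, Z_block = block,
    Enu = rep(1, D), Elognu = rep(0, D), kl_nu = 0,
    gh = pracma::gaussHermite(20),
    elbo_trace = numeric(0), val_trace = numeric(0)
  ), class = "vc_gp_model")
}

# independent Matern 5/2 implementation for oracles
oracle_m52 <- function(r) (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r)

oracle_kernel <- function(phi1, t1, phi2, t2, s2s, s2t, lt) {
  K <- matrix(0, nrow(phi1), nrow(phi2))
  for (i in seq_len(nrow(phi1))) {
    for (j in seq_len(nrow(phi2))) {
      rs <- sqrt(sum((phi1[i, ] - phi2[j, ])^2))
      rt <- abs(t1[i] - t2[j]) / lt
      K[i, j] <- s2s * oracle_m52(rs) + s2t * oracle_m52(rt)
    }
  }
  K
}
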