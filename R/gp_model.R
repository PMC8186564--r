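# Sparse variational GP classification model of the momentary lick hazard.
#
# Latent log-odds f(x) over inputs x = (stimulus history, trial time,
# block) with a kernel that is the sum of Matern 5/2 components on filtered
# stimulus (phi = s'W, lengthscale fixed to 1) and on monotonically warped
# time, each split into population and block-specific parts. Inference is
# stochastic variational with M inducing points; the filter matrix carries
# a mean-field Gaussian variational posterior with an automatic relevance
# determination (Gaussian-gamma) prior that prunes superfluous filters.
# All gradients are analytic; the Bernoulli variational expectations use
# Gauss-Hermite quadrature.

#' Configuration of the hazard GP
#'
#' @param Q stimulus history length, samples (50 = 2.5 s).
#' @param D number of stimulus filters.
#' @param J number of tanh terms in the time warp.
#' @param M total inducing points (divided equally across blocks).
#' @param minibatch samples per stochastic gradient step.
#' @param learning_rate Adam learning rate.
#' @param max_steps optimization step cap.
#' @param mc_eval Monte Carlo samples for predictive quantities.
#' @param n_replicates default number of behavior replicates.
#' @param lr_decay final learning-rate fraction; the rate is constant for
#'   the first half of training and annealed exponentially to
#'   `learning_rate * lr_decay` over the second half, letting pruned
#'   filter columns settle.
#' @param eval_every validation-evaluation interval, steps.
#' @param patience consecutive evaluations without improvement before stop.
#' @param tol minimum improvement, nats per trial.
#' @param svd_every interval (steps) for rotating the filter means to
#'   their principal axes. The Matern kernel on filter outputs is
#'   invariant under orthogonal rotation of the filter columns, so the
#'   rotation leaves the likelihood unchanged while concentrating column
#'   norms. Off by default (the ARD prior plus annealing usually
#'   suffices).
#' @param avg_tail fraction of final steps over which the filter means
#'   are Polyak-averaged; averaging removes part of the
#'   stochastic-gradient noise floor on pruned columns. 0 disables.
#' @param prune_final zero out, after training, filter columns whose
#'   posterior-mean norm is below their posterior width
#'   (`||m_d||^2 < Q * mean(s_d^2)`): such columns are dominated by
#'   prior noise rather than data support.
#' @param ard_shape,ard_rate gamma hyperprior of the ARD precisions
#'   (broad, favoring high precisions).
#' @param jitter diagonal jitter on the inducing covariance.
#' @param gh_points Gauss-Hermite nodes for variational expectations.
#' @param profile `"desk"` (small, for test-scale problems) or `"full"`
#'   (the full-scale settings: 450 inducing points, 15 filters, 12000
#'   sample minibatches, learning rate 0.001).
#' @return a `vc_gp_config` list.
#' @export
gp_config <- function(Q = 50, D = 8, J = 5, M = 64, minibatch = 2048,
                      learning_rate = 0.012, lr_decay = 0.01,
                      max_steps = 5000,
                      mc_eval = 500, n_replicates = 500,
                      eval_every = 500, patience = 20, tol = 1e-4,
                      svd_every = 0, avg_tail = 0.2, prune_final = TRUE,
                      ard_shape = 2, ard_rate = 0.05, jitter = 1e-6,
                      gh_points = 20, profile = c("desk", "full")) {
  profile <- match.arg(profile)
  if (profile == "full") {
    Q <- 50; D <- 15; J <- 5; M <- 450
    minibatch <- 12000; learning_rate <- 0.001; max_steps <- 200000
  }
  stopifnot(Q >= 1, D >= 1, J >= 1, M >= 1, mc_eval >= 1)
  structure(as.list(environment()), class = "vc_gp_config")
}

#' Discretize trials to 50-ms model samples
#'
#' Builds the design of the hazard model: one row per 50-ms sample with
#' the stimulus history over the `Q` preceding samples (padded with the
#' baseline mean before onset), time since stimulus onset, block tag, and
#' the lick indicator. Trials end at their first lick, so every sample
#' already conditions on no earlier lick within its trial.
#'
#' @param trials list of trials from [gen_session()].
#' @param cfg a [task_config()].
#' @param Q history length in samples.
#' @return list with `S` (N x Q), `t`, `block`, `y`, `trial`, `n_trials`.
#' @export
discretize_trials <- function(trials, cfg = task_config(), Q = 50) {
  dt <- cfg$sample_period
  Slist <- vector("list", length(trials))
  tl <- vector("list", length(trials))
  bl <- character(length(trials))
  yl <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    s <- tr$stimulus$log2tf
    n <- length(s)
    padded <- c(rep(cfg$baseline_log2tf_mean, Q - 1), s)
    idx <- outer(seq_len(n) + Q - 1, 0:(Q - 1), "-")
    Slist[[i]] <- matrix(padded[idx], n, Q)
    tl[[i]] <- (seq_len(n) - 1) * dt
    bl[i] <- tr$block
    y <- rep(0L, n)
    if (length(tr$lick_times)) {
      k <- ceiling(tr$lick_times[1] / dt - 1e-9)
      if (k <= n) y[k] <- 1L
    }
    yl[[i]] <- y
  }
  ns <- vapply(Slist, nrow, 0L)
  list(S = do.call(rbind, Slist), t = unlist(tl),
       block = rep(bl, ns), y = unlist(yl),
       trial = rep(seq_along(trials), ns), n_trials = length(trials))
}

# ---- parameter helpers ---------------------------------------------------

#' @keywords internal
lower_from_raw <- function(L_raw) {
  L <- L_raw
  L[upper.tri(L)] <- 0
  diag(L) <- exp(diag(L_raw))
  L
}

#' @keywords internal
warp_from_raw <- function(par) {
  list(a = softplus(par$warp_a_raw), b = softplus(par$warp_b_raw),
       c = par$warp_c)
}

#' @keywords internal
kern_from_par <- function(par, blocks) {
  list(sigma2_s = exp(par$log_s2s), sigma2_t = exp(par$log_s2t),
       ell_t = exp(par$log_lt), blocks = blocks)
}

# warp forward plus the pieces needed for its backward pass
#' @keywords internal
warp_fwd <- function(t, w) {
  J <- length(w$a)
  tw <- t
  tanh_k <- matrix(0, length(t), J)
  for (k in seq_len(J)) {
    tanh_k[, k] <- tanh(w$b[k] * t + w$c[k])
    tw <- tw + w$a[k] * tanh_k[, k]
  }
  list(tw = tw, tanh_k = tanh_k)
}

# accumulate warp-parameter gradients from d(tw) at points t
#' @keywords internal
warp_bwd <- function(t, tanh_k, dtw, w) {
  sech2 <- 1 - tanh_k^2
  da <- colSums(dtw * tanh_k)
  db <- colSums(dtw * t * sech2) * w$a
  dc <- colSums(dtw * sech2) * w$a
  list(da = da, db = db, dc = dc)
}

# ---- the ELBO and its analytic gradients --------------------------------

# One evaluation of the stochastic ELBO on a minibatch, with gradients
# with respect to every trainable parameter. st holds the static pieces
# (data, inducing inputs, ARD moments, quadrature nodes, config).
#' @keywords internal
svgp_objective <- function(par, st, idx, eps_W = NULL, want_grad = TRUE) {
  Q <- st$cfg$Q; D <- st$cfg$D; M <- nrow(st$Z_S)
  W_sd <- exp(par$W_logsd)
  W <- if (is.null(eps_W)) par$W_mean else par$W_mean + W_sd * eps_W
  w <- warp_from_raw(par)
  kern <- kern_from_par(par, st$blocks)

  Sb <- st$S[idx, , drop = FALSE]
  tb <- st$t[idx]; bb <- st$block[idx]; yb <- st$y[idx]
  nb <- length(idx)
  scale <- length(st$y) / nb

  phiX <- Sb %*% W
  phiZ <- st$Z_S %*% W
  wfX <- warp_fwd(tb, w); twX <- wfX$tw
  wfZ <- warp_fwd(st$Z_t, w); twZ <- wfZ$tw

  cc <- kern_cross(phiX, twX, bb, phiZ, twZ, st$Z_block, kern)
  uu <- kern_cross(phiZ, twZ, st$Z_block, phiZ, twZ, st$Z_block, kern)
  K_xu <- cc$K
  K_uu <- uu$K + st$cfg$jitter * diag(M)
  kd <- kern_diag(bb, kern)

  U <- chol(K_uu)
  Kinv <- chol2inv(U)
  A <- K_xu %*% Kinv
  L <- lower_from_raw(par$L_raw)
  AL <- A %*% L
  delta <- par$mu_u - par$m0
  mu_t <- par$m0 + drop(A %*% delta)
  v_raw <- kd - rowSums(A * K_xu) + rowSums(AL^2)
  clamped <- v_raw < 1e-10
  v <- pmax(v_raw, 1e-10)

  # Gauss-Hermite expectations of the Bernoulli log-likelihood
  sq2v <- sqrt(2 * v)
  gh_x <- st$gh$x; gh_w <- st$gh$w / sqrt(pi)
  E_i <- numeric(nb); g_i <- numeric(nb); h_i <- numeric(nb)
  for (k in seq_along(gh_x)) {
    f_k <- mu_t + sq2v * gh_x[k]
    ll <- ifelse(yb == 1, -softplus(-f_k), -softplus(f_k))
    lp <- yb - stats::plogis(f_k)
    E_i <- E_i + gh_w[k] * ll
    g_i <- g_i + gh_w[k] * lp
    h_i <- h_i + gh_w[k] * lp * gh_x[k]
  }
  h_i <- h_i / sq2v
  data_term <- scale * sum(E_i)

  # KL(q(u) || p(u))
  Su <- tcrossprod(L)
  Kinvd <- drop(Kinv %*% delta)
  kl_u <- 0.5 * (sum(Kinv * Su) + sum(delta * Kinvd) - M +
                   2 * sum(log(diag(U))) - 2 * sum(log(diag(L))))

  # KL-type terms for (W, nu): E_q[log q(W) - log p(W | nu)] + KL(q(nu)||p(nu))
  col_m2 <- colSums(par$W_mean^2) + colSums(W_sd^2)
  kl_w <- sum(0.5 * st$Enu * col_m2 - (Q / 2) * st$Elognu +
                (Q / 2) * log(2 * pi)) -
    sum(0.5 * log(2 * pi * exp(1)) + par$W_logsd) + st$kl_nu
  elbo <- data_term - kl_u - kl_w

  if (!want_grad) {
    return(list(elbo = elbo, data_term = data_term, kl_u = kl_u,
                kl_w = kl_w))
  }

  gs <- scale * g_i
  hs <- scale * h_i
  hs[clamped] <- 0

  gr <- list()
  gr$mu_u <- drop(crossprod(A, gs)) - Kinvd
  gr$m0 <- sum(gs * (1 - rowSums(A))) + sum(Kinvd)

  # dKL/dL = Kinv L - L^{-T}; the lower triangle of L^{-T} is its diagonal
  dL <- 2 * crossprod(A, hs * AL) -
    (Kinv %*% L - diag(1 / diag(L), nrow(L)))
  dL[upper.tri(dL)] <- 0
  diag(dL) <- diag(dL) * diag(L)
  gr$L_raw <- dL

  G_A <- gs %*% t(delta) + hs * (2 * tcrossprod(AL, L) - K_xu)
  d_Kxu <- G_A %*% Kinv - hs * A
  d_Kuu <- -crossprod(A, G_A) %*% Kinv
  d_Kuu <- 0.5 * (d_Kuu + t(d_Kuu))
  d_Kuu_kl <- 0.5 * (Kinv - Kinv %*% (Su + tcrossprod(delta)) %*% Kinv)
  d_Kuu <- d_Kuu - d_Kuu_kl
  d_kd <- hs

  # kernel hyperparameters and input-coordinate gradients
  C <- 1 + length(st$blocks)
  d_log_s2s <- numeric(C); d_log_s2t <- numeric(C); d_log_lt <- numeric(C)
  dphiX <- matrix(0, nb, D); dphiZ <- matrix(0, M, D)
  dtwX <- numeric(nb); dtwZ <- numeric(M)

  acc_block <- function(dK, Rs, Dt, sgn_fac, ci, mask) {
    s2s <- kern$sigma2_s[ci]; s2t <- kern$sigma2_t[ci]
    lt <- kern$ell_t[ci]
    Wm <- if (is.null(mask)) dK else dK * mask
    rt <- Dt / lt
    m52t <- matern52(rt)
    d_log_s2s[ci] <<- d_log_s2s[ci] + sum(Wm * matern52(Rs)) * s2s
    d_log_s2t[ci] <<- d_log_s2t[ci] + sum(Wm * m52t) * s2t
    dmt <- matern52_dr(rt)
    d_log_lt[ci] <<- d_log_lt[ci] + sum(Wm * s2t * dmt * (-rt))
    Cs <- Wm * (s2s * matern52_dr_over_r(Rs))
    Ct <- Wm * (s2t * dmt / lt) * sgn_fac
    list(Cs = Cs, Ct = Ct)
  }

  # cross block (X rows, Z cols)
  sgn_xz <- sign(outer(twX, twZ, "-"))
  for (ci in seq_len(C)) {
    mask <- if (ci == 1) NULL else
      outer(bb == st$blocks[ci - 1], st$Z_block == st$blocks[ci - 1]) * 1
    if (!is.null(mask) && !any(mask > 0)) next
    p <- acc_block(d_Kxu, cc$Rs, cc$Dt, sgn_xz, ci, mask)
    dphiX <- dphiX + rowSums(p$Cs) * phiX - p$Cs %*% phiZ
    dphiZ <- dphiZ + colSums(p$Cs) * phiZ - crossprod(p$Cs, phiX)
    dtwX <- dtwX + rowSums(p$Ct)
    dtwZ <- dtwZ - colSums(p$Ct)
  }
  # inducing block (Z rows, Z cols)
  sgn_zz <- sign(outer(twZ, twZ, "-"))
  for (ci in seq_len(C)) {
    mask <- if (ci == 1) NULL else
      outer(st$Z_block == st$blocks[ci - 1],
            st$Z_block == st$blocks[ci - 1]) * 1
    if (!is.null(mask) && !any(mask > 0)) next
    p <- acc_block(d_Kuu, uu$Rs, uu$Dt, sgn_zz, ci, mask)
    dphiZ <- dphiZ + rowSums(p$Cs) * phiZ - p$Cs %*% phiZ
    dphiZ <- dphiZ + colSums(p$Cs) * phiZ - crossprod(p$Cs, phiZ)
    dtwZ <- dtwZ + rowSums(p$Ct) - colSums(p$Ct)
  }
  # prior-variance diagonal
  for (ci in seq_len(C)) {
    sel <- if (ci == 1) rep(TRUE, nb) else bb == st$blocks[ci - 1]
    d_log_s2s[ci] <- d_log_s2s[ci] + sum(d_kd[sel]) * kern$sigma2_s[ci]
    d_log_s2t[ci] <- d_log_s2t[ci] + sum(d_kd[sel]) * kern$sigma2_t[ci]
  }
  gr$log_s2s <- d_log_s2s
  gr$log_s2t <- d_log_s2t
  gr$log_lt <- d_log_lt

  # warp parameters (softplus chain on a and b)
  wbX <- warp_bwd(tb, wfX$tanh_k, dtwX, w)
  wbZ <- warp_bwd(st$Z_t, wfZ$tanh_k, dtwZ, w)
  gr$warp_a_raw <- (wbX$da + wbZ$da) * stats::plogis(par$warp_a_raw)
  gr$warp_b_raw <- (wbX$db + wbZ$db) * stats::plogis(par$warp_b_raw)
  gr$warp_c <- wbX$dc + wbZ$dc

  # filters: data flows through both projections; ARD prior shrinks means
  dW <- crossprod(Sb, dphiX) + crossprod(st$Z_S, dphiZ)
  gr$W_mean <- dW - sweep(par$W_mean, 2, st$Enu, "*")
  d_eps <- if (is.null(eps_W)) 0 else dW * eps_W * W_sd
  gr$W_logsd <- d_eps + 1 - sweep(W_sd^2, 2, st$Enu, "*")

  list(elbo = elbo, data_term = data_term, kl_u = kl_u, kl_w = kl_w,
       grads = gr)
}

# conjugate update of the gamma variational factor on the ARD precisions
#' @keywords internal
update_ard <- function(par, st) {
  Q <- st$cfg$Q
  a0 <- st$cfg$ard_shape; b0 <- st$cfg$ard_rate
  a1 <- a0 + Q / 2
  b1 <- b0 + 0.5 * (colSums(par$W_mean^2) + colSums(exp(2 * par$W_logsd)))
  st$Enu <- a1 / b1
  st$Elognu <- digamma(a1) - log(b1)
  st$kl_nu <- sum((a1 - a0) * digamma(a1) - lgamma(a1) + lgamma(a0) +
                    a0 * (log(b1) - log(b0)) + a1 * (b0 - b1) / b1)
  st
}

# ---- initialization ------------------------------------------------------

# k-means medoid inducing inputs, allocated equally across blocks
#' @keywords internal
init_inducing <- function(data, cfg, blocks, seed) {
  set.seed(seed)
  M <- cfg$M
  per <- rep(floor(M / length(blocks)), length(blocks))
  per[seq_len(M - sum(per))] <- per[seq_len(max(0, M - sum(per)))] + 1
  Z_S <- NULL; Z_t <- NULL; Z_block <- NULL
  for (bi in seq_along(blocks)) {
    sel <- which(data$block == blocks[bi])
    sub <- sel[sample.int(length(sel), min(length(sel), 6000))]
    X <- cbind(data$S[sub, , drop = FALSE], data$t[sub] / 4)
    km <- suppressWarnings(stats::kmeans(X, centers = min(per[bi],
                                                          nrow(X) - 1),
                                         iter.max = 10, nstart = 1))
    # medoids: nearest actual sample to each centroid keeps realistic
    # stimulus-history spread under any later filter projection
    for (k in seq_len(nrow(km$centers))) {
      d2 <- colSums((t(X) - km$centers[k, ])^2)
      j <- sub[which.min(d2)]
      Z_S <- rbind(Z_S, data$S[j, ])
      Z_t <- c(Z_t, data$t[j])
      Z_block <- c(Z_block, blocks[bi])
    }
  }
  list(Z_S = Z_S, Z_t = Z_t, Z_block = Z_block)
}

#' @keywords internal
init_params <- function(cfg, st, seed) {
  set.seed(seed + 1)
  Q <- cfg$Q; D <- cfg$D; J <- cfg$J; M <- nrow(st$Z_S)
  C <- 1 + length(st$blocks)
  par <- list(
    m0 = -5,
    mu_u = rep(-5, M),
    L_raw = NULL,
    log_s2s = log(c(1, rep(0.2, C - 1))),
    log_s2t = log(c(1, rep(0.2, C - 1))),
    log_lt = log(rep(2, C)),
    warp_a_raw = rep(inv_softplus(0.1), J),
    warp_b_raw = inv_softplus(seq(0.2, 1, length.out = J)),
    warp_c = -seq_len(J),
    W_mean = matrix(stats::rnorm(Q * D, 0, 1 / sqrt(Q)), Q, D),
    W_logsd = matrix(log(0.05), Q, D)
  )
  # start q(u) at the prior: mu_u = m(Z), Sigma_u = K_uu, so KL(q||p) = 0
  w <- warp_from_raw(par)
  kern <- kern_from_par(par, st$blocks)
  phiZ <- st$Z_S %*% par$W_mean
  twZ <- warp_fwd(st$Z_t, w)$tw
  K_uu <- kern_cross(phiZ, twZ, st$Z_block, phiZ, twZ, st$Z_block,
                     kern)$K + cfg$jitter * diag(M)
  Lk <- t(chol(K_uu))
  L_raw <- Lk
  diag(L_raw) <- log(diag(Lk))
  par$L_raw <- L_raw
  par
}

# ---- Adam ----------------------------------------------------------------

#' @keywords internal
adam_init <- function(par) {
  list(m = lapply(par, function(p) p * 0), v = lapply(par, function(p) p * 0),
       t = 0)
}

#' @keywords internal
adam_step <- function(par, gr, stt, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  stt$t <- stt$t + 1
  for (nm in names(gr)) {
    g <- gr[[nm]]
    stt$m[[nm]] <- b1 * stt$m[[nm]] + (1 - b1) * g
    stt$v[[nm]] <- b2 * stt$v[[nm]] + (1 - b2) * g^2
    mhat <- stt$m[[nm]] / (1 - b1^stt$t)
    vhat <- stt$v[[nm]] / (1 - b2^stt$t)
    par[[nm]] <- par[[nm]] + lr * mhat / (sqrt(vhat) + eps) # ascent
  }
  list(par = par, state = stt)
}

# ---- fitting -------------------------------------------------------------

#' Fit the GP hazard model
#'
#' Stochastic variational optimization with Adam over minibatches of
#' 50-ms samples. Inducing inputs are initialized by k-means (medoids)
#' within blocks and re-projected through the current filters at every
#' step. Training stops at the step cap or when the validation predictive
#' log-likelihood stops improving.
#'
#' @param train list of training trials.
#' @param val optional list of validation trials.
#' @param cfg a [gp_config()].
#' @param task_cfg a [task_config()].
#' @param seed integer seed controlling initialization, minibatches and
#'   the filter-sample draws.
#' @param verbose print progress.
#' @return a fitted `vc_gp_model`.
#' @export
fit_gp_hazard <- function(train, val = NULL, cfg = gp_config(),
                          task_cfg = task_config(), seed = 1,
                          verbose = FALSE) {
  data <- discretize_trials(train, task_cfg, cfg$Q)
  if (!any(data$y == 1)) stop("no lick samples in the training set")
  blocks <- sort(unique(data$block))
  st <- list(cfg = cfg, S = data$S, t = data$t, block = data$block,
             y = data$y, blocks = blocks,
             gh = pracma::gaussHermite(cfg$gh_points))
  zi <- init_inducing(data, cfg, blocks, seed)
  st$Z_S <- zi$Z_S; st$Z_t <- zi$Z_t; st$Z_block <- zi$Z_block
  par <- init_params(cfg, st, seed)
  st$Enu <- rep(cfg$ard_shape / cfg$ard_rate, cfg$D)
  st <- update_ard(par, st)

  val_data <- if (!is.null(val)) discretize_trials(val, task_cfg, cfg$Q)
  opt <- adam_init(par)
  N <- length(st$y)
  set.seed(seed + 2)
  elbo_trace <- numeric(0)
  val_trace <- numeric(0)
  best_val <- -Inf; stall <- 0L
  W_avg <- NULL; n_avg <- 0L
  for (step in seq_len(cfg$max_steps)) {
    idx <- if (N > cfg$minibatch) sample.int(N, cfg$minibatch) else seq_len(N)
    eps_W <- matrix(stats::rnorm(cfg$Q * cfg$D), cfg$Q, cfg$D)
    ob <- svgp_objective(par, st, idx, eps_W)
    # constant rate for the first half, exponential anneal to
    # learning_rate * lr_decay over the second half
    frac <- step / cfg$max_steps
    lr <- cfg$learning_rate * cfg$lr_decay^max(0, (frac - 0.5) / 0.5)
    res <- adam_step(par, ob$grads, opt, lr)
    par <- res$par; opt <- res$state
    # principal-axis rotation of the filter means (likelihood-invariant);
    # suspended over the final quarter so the solution settles
    if (cfg$svd_every > 0 && step %% cfg$svd_every == 0 && cfg$D > 1 &&
        frac <= 0.75) {
      sv <- svd(par$W_mean)
      par$W_mean <- sv$u %*% diag(sv$d, cfg$D)
      opt$m$W_mean <- opt$m$W_mean %*% sv$v # rotate first moment with W
    }
    st <- update_ard(par, st)
    if (cfg$avg_tail > 0 && frac > 1 - cfg$avg_tail) {
      W_avg <- if (is.null(W_avg)) par$W_mean else W_avg + par$W_mean
      n_avg <- n_avg + 1L
    }
    elbo_trace <- c(elbo_trace, ob$elbo)
    if (step %% cfg$eval_every == 0) {
      if (!is.null(val_data)) {
        vl <- gp_val_loglik(par, st, val_data)
        val_trace <- c(val_trace, vl)
        if (verbose) message(sprintf("step %d elbo %.1f val %.4f", step,
                                     ob$elbo, vl))
        if (vl > best_val + cfg$tol) {
          best_val <- vl; stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= cfg$patience) break
        }
      } else if (verbose) {
        message(sprintf("step %d elbo %.1f", step, ob$elbo))
      }
    }
  }
  if (!is.null(W_avg) && n_avg > 0) par$W_mean <- W_avg / n_avg
  if (cfg$prune_final) {
    m2 <- colSums(par$W_mean^2)
    s2 <- colMeans(exp(2 * par$W_logsd))
    par$W_mean[, m2 < cfg$Q * s2] <- 0
  }
  st <- update_ard(par, st)
  finalize_gp_model(par, st, cfg, task_cfg, elbo_trace, val_trace)
}

# deterministic per-trial average predictive log-likelihood used for the
# convergence check (plug-in posterior-mean filters, marginal latent)
#' @keywords internal
gp_val_loglik <- function(par, st, val_data) {
  pr <- gp_latent_raw(par, st, val_data$S, val_data$t, val_data$block)
  # MC over the marginal latent with common quadrature nodes
  h <- numeric(length(pr$mean))
  gh <- st$gh
  for (k in seq_along(gh$x)) {
    f_k <- pr$mean + sqrt(2 * pr$var) * gh$x[k]
    h <- h + gh$w[k] / sqrt(pi) * stats::plogis(f_k)
  }
  h <- clip_unit(h)
  ll <- ifelse(val_data$y == 1, log(h), log1p(-h))
  sum(ll) / val_data$n_trials
}

# latent predictive mean/variance (and stimulus/time decomposition) from
# raw parameter/static lists
#' @keywords internal
gp_latent_raw <- function(par, st, S, t, block, parts = FALSE) {
  w <- warp_from_raw(par)
  kern <- kern_from_par(par, st$blocks)
  W <- par$W_mean
  phiX <- S %*% W
  phiZ <- st$Z_S %*% W
  twX <- warp_fwd(t, w)$tw
  twZ <- warp_fwd(st$Z_t, w)$tw
  cc <- kern_cross(phiX, twX, block, phiZ, twZ, st$Z_block, kern,
                   parts = TRUE)
  uu <- kern_cross(phiZ, twZ, st$Z_block, phiZ, twZ, st$Z_block, kern)
  M <- nrow(st$Z_S)
  K_uu <- uu$K + st$cfg$jitter * diag(M)
  Kinv <- chol2inv(chol(K_uu))
  A <- cc$K %*% Kinv
  L <- lower_from_raw(par$L_raw)
  AL <- A %*% L
  delta <- par$mu_u - par$m0
  alpha <- drop(Kinv %*% delta)
  mu <- par$m0 + drop(cc$K %*% alpha)
  v <- pmax(kern_diag(block, kern) - rowSums(A * cc$K) + rowSums(AL^2),
            1e-12)
  out <- list(mean = mu, var = v, A = A, AL = AL, alpha = alpha)
  if (parts) {
    out$mean_s <- drop(cc$Ks %*% alpha)
    out$mean_t <- drop(cc$Kt %*% alpha)
  }
  out
}

#' @keywords internal
finalize_gp_model <- function(par, st, cfg, task_cfg, elbo_trace,
                              val_trace) {
  w <- warp_from_raw(par)
  structure(list(
    cfg = cfg, task_cfg = task_cfg, par = par,
    W = par$W_mean, W_sd = exp(par$W_logsd),
    ard_precisions = st$Enu,
    warp = w,
    kern = kern_from_par(par, st$blocks),
    blocks = st$blocks,
    Z_S = st$Z_S, Z_t = st$Z_t, Z_block = st$Z_block,
    Enu = st$Enu, Elognu = st$Elognu, kl_nu = st$kl_nu,
    gh = st$gh,
    elbo_trace = elbo_trace, val_trace = val_trace
  ), class = "vc_gp_model")
}

#' Evidence lower bound of a fitted (or hand-built) model
#'
#' Deterministic evaluation (posterior-mean filters) of the stochastic
#' objective on a set of trials: the expected Bernoulli log-likelihood
#' under the variational posterior minus the KL terms for the inducing
#' values and the filter bank.
#'
#' @param model a `vc_gp_model`.
#' @param trials list of trials (or a [discretize_trials()] result).
#' @param idx optional sample subset (minibatch); the data term is
#'   rescaled accordingly.
#' @return list with `elbo`, `data_term`, `kl_u`, `kl_w`.
#' @export
elbo <- function(model, trials, idx = NULL) {
  data <- if (is.list(trials) && !is.null(trials$S)) trials
          else discretize_trials(trials, model$task_cfg, model$cfg$Q)
  if (length(data$y) == 0) stop("empty minibatch")
  st <- model_static(model, data)
  if (is.null(idx)) idx <- seq_along(data$y)
  svgp_objective(model$par, st, idx, eps_W = NULL, want_grad = FALSE)
}

#' @keywords internal
model_static <- function(model, data) {
  list(cfg = model$cfg, S = data$S, t = data$t, block = data$block,
       y = data$y, blocks = model$blocks, Z_S = model$Z_S,
       Z_t = model$Z_t, Z_block = model$Z_block, Enu = model$Enu,
       Elognu = model$Elognu, kl_nu = model$kl_nu, gh = model$gh)
}

#' Principal stimulus filters of a fitted model
#'
#' The Matern kernel on filter outputs depends only on distances in the
#' projected space, so the filter bank is identified up to a rotation of
#' its active columns; the ARD prior breaks the degeneracy only slowly.
#' The singular vectors of the posterior-mean filter matrix, ordered by
#' singular value, are the rotation-invariant summary of the learned
#' stimulus features.
#'
#' @param model a fitted `vc_gp_model`.
#' @return list with `filters` (Q x D, unit columns), `weights`
#'   (singular values).
#' @export
principal_filters <- function(model) {
  sv <- svd(model$W)
  list(filters = sv$u, weights = sv$d)
}

#' Zero out one stimulus filter of a fitted model
#'
#' Returns a model view with column `d` of the (posterior-mean) filter
#' matrix set to zero; predictions from the view quantify that filter's
#' contribution. The original model is unchanged.
#'
#' @param model a `vc_gp_model`.
#' @param d filter index.
#' @return the ablated model.
#' @export
ablate_filter <- function(model, d) {
  if (d < 1 || d > ncol(model$W)) stop("filter index out of range")
  model$W[, d] <- 0
  model$par$W_mean[, d] <- 0
  model
}
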