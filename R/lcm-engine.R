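# Internal latent-class engine.
#
# All model variants reduce to the same structure: V categorical variables
# (laboratory tests, possibly an appended binary outcome, possibly one
# pseudo-variable per test-by-stratum cell), each with ncat[v] categories and
# a classification matrix theta[[block[v]]] of size ncat[v] x C whose columns
# are P(variable = r | latent class = c). Variables sharing a block share a
# theta (the equal-accuracy constraint). Data are held as a pattern matrix Y
# (n_pat x V, NA = missing) with counts w. Optional pairwise dependence terms
# replace the conditional-independence product for flagged variable pairs by
# a log-linear joint cell table.

# per-class likelihood of every pattern: n_pat x C matrix of
# pi_c * prod_t theta[r_t | c] (missing slots skipped, dependent pairs joint)
lik_matrix <- function(Y, pi, thetas, blocks = seq_along(thetas), dep = NULL) {
  npat <- nrow(Y)
  C <- length(pi)
  A <- matrix(pi, npat, C, byrow = TRUE)
  dep_vars <- if (length(dep)) unlist(lapply(dep, function(d) d$vars)) else integer(0)
  for (v in seq_len(ncol(Y))) {
    if (v %in% dep_vars) next
    th <- thetas[[blocks[v]]]
    obs <- which(!is.na(Y[, v]))
    if (length(obs)) A[obs, ] <- A[obs, ] * th[Y[obs, v], , drop = FALSE]
  }
  for (d in dep) {
    v1 <- d$vars[1]; v2 <- d$vars[2]
    th1 <- thetas[[blocks[v1]]]; th2 <- thetas[[blocks[v2]]]
    K <- nrow(th1)
    lam <- if (length(d$lambda) == 1L) rep(d$lambda, C) else d$lambda
    r1 <- Y[, v1]; r2 <- Y[, v2]
    for (c in seq_len(C)) {
      J <- outer(th1[, c], th2[, c]) * exp(lam[c] * diag(K))
      J <- J / sum(J)
      both <- which(!is.na(r1) & !is.na(r2))
      if (length(both)) A[both, c] <- A[both, c] * J[cbind(r1[both], r2[both])]
      only1 <- which(!is.na(r1) & is.na(r2))
      if (length(only1)) A[only1, c] <- A[only1, c] * rowSums(J)[r1[only1]]
      only2 <- which(is.na(r1) & !is.na(r2))
      if (length(only2)) A[only2, c] <- A[only2, c] * colSums(J)[r2[only2]]
    }
  }
  A
}

pattern_loglik <- function(Y, w, pi, thetas, blocks = seq_along(thetas),
                           dep = NULL) {
  lik <- rowSums(lik_matrix(Y, pi, thetas, blocks, dep))
  sum(w * log(pmax(lik, 1e-300)))
}

# EM under conditional independence (optionally with shared theta blocks).
# Returns estimates, the per-iteration log-likelihood trace, and flags.
em_fit <- function(Y, w, ncat, C, blocks, init, max_iter = 5000L,
                   rel_tol = 1e-8) {
  pi <- init$pi
  thetas <- init$thetas        # one matrix per block
  V <- ncol(Y)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    A <- lik_matrix(Y, pi, thetas, blocks)
    lik <- pmax(rowSums(A), 1e-300)
    ll <- sum(w * log(lik))
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < rel_tol * (abs(ll_old) + 1e-3)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    z <- (A / lik) * w                       # weighted posterior memberships
    pi <- colSums(z) / sum(w)
    for (b in seq_along(thetas)) {
      num <- matrix(0, nrow(thetas[[b]]), C)
      for (v in which(blocks == b)) {
        obs <- which(!is.na(Y[, v]))
        if (length(obs)) {
          tab <- rowsum(z[obs, , drop = FALSE], group = Y[obs, v])
          num[as.integer(rownames(tab)), ] <-
            num[as.integer(rownames(tab)), , drop = FALSE] + tab
        }
      }
      den <- matrix(colSums(num), nrow(num), C, byrow = TRUE)
      thetas[[b]] <- ifelse(den > 0, num / den, 1 / nrow(num))
    }
  }
  list(pi = pi, thetas = thetas, loglik = trace[length(trace)],
       trace = trace, n_iter = length(trace), converged = converged)
}

moment_init <- function(Y, w, ncat, C, blocks, jitter = 0) {
  V <- ncol(Y)
  thetas <- vector("list", max(blocks))
  for (b in seq_len(max(blocks))) {
    K <- ncat[which(blocks == b)[1]]
    if (K == C) {
      th <- matrix(0.15 / max(K - 1, 1), K, C)
      diag(th) <- 0.85
    } else {
      # non-square variable (e.g. binary outcome): start near its marginal
      # rate with a mild monotone class gradient to break symmetry
      vs <- which(blocks == b)
      vals <- unlist(lapply(vs, function(v) rep(Y[, v], w)))
      th <- matrix(0, K, C)
      marg <- tabulate(vals[!is.na(vals)], nbins = K)
      marg <- (marg + 1) / sum(marg + 1)
      for (c in seq_len(C)) {
        shift <- 0.8 + 0.4 * (c - 1) / max(C - 1, 1)
        th[, c] <- clamp01(marg * c(shift, rep(1, K - 1)), 1e-3)
        th[, c] <- th[, c] / sum(th[, c])
      }
    }
    thetas[[b]] <- th
  }
  # modal-vote class frequencies over square variables
  sq <- which(ncat == C)
  if (length(sq)) {
    modal <- apply(Y[, sq, drop = FALSE], 1, function(r) {
      r <- r[!is.na(r)]
      if (!length(r)) return(NA_integer_)
      as.integer(names(which.max(table(r))))
    })
    tab <- tapply(w, factor(modal, levels = seq_len(C)), sum)
    tab[is.na(tab)] <- 0
    pi <- (tab + 1) / sum(tab + 1)
  } else {
    pi <- rep(1 / C, C)
  }
  if (jitter > 0) {
    pi <- rdirichlet1(pi * 50 / jitter)
    thetas <- lapply(thetas, function(th) {
      apply(th, 2, function(col) rdirichlet1(clamp01(col, 1e-3) * 20 / jitter))
    })
  }
  list(pi = as.numeric(pi), thetas = thetas)
}

random_init <- function(ncat, C, blocks) {
  thetas <- lapply(seq_len(max(blocks)), function(b) {
    K <- ncat[which(blocks == b)[1]]
    alpha <- matrix(1, K, C)
    if (K == C) alpha <- alpha + 5 * diag(C)
    apply(alpha, 2, rdirichlet1)
  })
  list(pi = rdirichlet1(rep(2, C)), thetas = thetas)
}

# multi-start EM: one moment-style start plus n_restarts random starts
em_multistart <- function(Y, w, ncat, C, blocks, n_restarts, max_iter,
                          rel_tol) {
  best <- em_fit(Y, w, ncat, C, blocks, moment_init(Y, w, ncat, C, blocks),
                 max_iter, rel_tol)
  if (n_restarts > 0) {
    for (r in seq_len(n_restarts)) {
      cand <- em_fit(Y, w, ncat, C, blocks, random_init(ncat, C, blocks),
                     max_iter, rel_tol)
      if (cand$loglik > best$loglik + 1e-9) best <- cand
    }
  }
  best
}

# ---- minimal parameterization (log-ratio vs. last level) -------------------

par_struct <- function(C, block_ncat, n_lambda = 0L, lambda_per_class = FALSE) {
  list(C = C, block_ncat = block_ncat,
       n_lambda = n_lambda, lambda_per_class = lambda_per_class,
       n_par = (C - 1L) + sum((block_ncat - 1L) * C) +
         n_lambda * if (lambda_per_class) C else 1L)
}

par_pack <- function(pi, thetas, lambda, st) {
  pi <- clamp01(pi, 1e-8); pi <- pi / sum(pi)
  p <- log(pi[-st$C] / pi[st$C])
  for (b in seq_along(thetas)) {
    th <- apply(clamp01(thetas[[b]], 1e-8), 2, function(col) col / sum(col))
    K <- st$block_ncat[b]
    p <- c(p, as.numeric(log(th[-K, , drop = FALSE] /
                               matrix(th[K, ], K - 1, st$C, byrow = TRUE))))
  }
  c(p, lambda)
}

par_unpack <- function(par, st) {
  C <- st$C
  softmax_last0 <- function(eta) {
    e <- exp(c(eta, 0) - max(c(eta, 0)))
    e / sum(e)
  }
  pi <- softmax_last0(par[seq_len(C - 1)])
  pos <- C - 1L
  thetas <- vector("list", length(st$block_ncat))
  for (b in seq_along(st$block_ncat)) {
    K <- st$block_ncat[b]
    m <- matrix(par[pos + seq_len((K - 1) * C)], K - 1, C)
    thetas[[b]] <- apply(m, 2, softmax_last0)
    if (K == 1L) thetas[[b]] <- matrix(1, 1, C)
    pos <- pos + (K - 1) * C
  }
  nl <- st$n_lambda * if (st$lambda_per_class) C else 1L
  lambda <- if (nl > 0) par[pos + seq_len(nl)] else numeric(0)
  list(pi = pi, thetas = thetas, lambda = lambda)
}

make_negll <- function(Y, w, blocks, st, dep_pairs = NULL) {
  force(Y); force(w); force(blocks); force(st); force(dep_pairs)
  function(par) {
    p <- par_unpack(par, st)
    dep <- NULL
    if (length(dep_pairs)) {
      dep <- lapply(seq_along(dep_pairs), function(k) {
        lam <- if (st$lambda_per_class) {
          p$lambda[(k - 1) * st$C + seq_len(st$C)]
        } else {
          p$lambda[k]
        }
        list(vars = dep_pairs[[k]], lambda = lam)
      })
    }
    -pattern_loglik(Y, w, p$pi, p$thetas, blocks, dep)
  }
}
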