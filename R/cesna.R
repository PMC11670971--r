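# CESNA-style overlapping community detection: nonnegative community
# memberships F (n x k) under the affiliation edge model
#   P(u ~ v) = 1 - exp(-F_u . F_v)
# jointly fit with a logistic model of binary node attributes
#   P(X_ud = 1) = sigmoid(F_u . W_d + b_d),
# maximised by projected batch gradient ascent with random restarts.
#
# Each binary attribute is internally one-hot encoded as (x, 1 - x) with
# attribute weights initialised at zero, which makes the fit exactly
# symmetric under flipping an attribute's coding.

cesna_fit <- function(g, x, k, seed = 1, lambda = 1, eta = 0.05,
                      iterations = 300, restarts = 3, ridge = 1e-3) {
  n <- igraph::vcount(g)
  ids <- igraph::V(g)$name
  el <- igraph::ends(g, igraph::E(g), names = FALSE)
  m <- nrow(el)
  x2 <- cbind(x, 1 - x)

  loglik <- function(F_, W, b) {
    s <- rowSums(F_[el[, 1], , drop = FALSE] * F_[el[, 2], , drop = FALSE])
    s <- pmax(s, 1e-10)
    S <- colSums(F_)
    all_pairs <- (sum(S^2) - sum(F_^2)) / 2
    lg <- sum(log1p(-exp(-s))) - (all_pairs - sum(s))
    q <- stats::plogis(sweep(F_ %*% W, 2, b, "+"))
    q <- pmin(pmax(q, 1e-12), 1 - 1e-12)
    lx <- sum(x2 * log(q) + (1 - x2) * log(1 - q))
    lg + lambda * lx
  }

  run_once <- function() {
    F_ <- matrix(stats::runif(n * k, 0, 1), n, k)
    W <- matrix(0, k, ncol(x2))
    b <- rep(0, ncol(x2))
    for (it in seq_len(iterations)) {
      S <- colSums(F_)
      s <- rowSums(F_[el[, 1], , drop = FALSE] * F_[el[, 2], , drop = FALSE])
      coef <- exp(-pmax(s, 1e-10)) / (1 - exp(-pmax(s, 1e-10)))
      G <- -sweep(-F_, 2, S, "+")  # gradient of -(S - F_u) term
      if (m > 0) {
        contrib <- (coef + 1)
        for (c_ in seq_len(k)) {
          acc <- numeric(n)
          acc_u <- contrib * F_[el[, 2], c_]
          acc_v <- contrib * F_[el[, 1], c_]
          acc <- acc + tapply_sum(el[, 1], acc_u, n) +
            tapply_sum(el[, 2], acc_v, n)
          G[, c_] <- G[, c_] + acc
        }
      }
      q <- stats::plogis(sweep(F_ %*% W, 2, b, "+"))
      resid <- x2 - q
      G <- G + lambda * resid %*% t(W)
      # normalized ascent: bounded per-entry steps keep the projected
      # update stable against the large batch non-edge gradient, and zero
      # is no longer an absorbing state for connected nodes
      F_ <- pmin(pmax(F_ + eta * G / (1 + abs(G)), 0), 10)
      W <- W + eta * (lambda * t(F_) %*% resid - 2 * ridge * W)
      b <- b + eta * lambda * colSums(resid)
    }
    list(F_ = F_, ll = loglik(F_, W, b))
  }

  best <- with_seed(seed, {
    fits <- lapply(seq_len(restarts), function(i) run_once())
    fits[[which.max(vapply(fits, `[[`, 0, "ll"))]]
  })

  eps <- if (n > 1) max(2 * m / (n * (n - 1)), 1e-8) else 1e-8
  delta <- sqrt(-log(1 - min(eps, 1 - 1e-12)))
  assign_mat <- best$F_ >= delta
  comms <- lapply(seq_len(k), function(c_) ids[assign_mat[, c_]])
  comms[lengths(comms) > 0]
}

# Sum `values` by integer group index over 1..n (fast path for gradient
# accumulation along the edge list).
tapply_sum <- function(index, values, n) {
  out <- numeric(n)
  agg <- rowsum(values, group = index)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}
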