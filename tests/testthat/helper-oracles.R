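# Independent oracles used to cross-check the closed-form registration.
# These deliberately share no code with the package internals.

# Elemental rotations composed entry-by-entry (independent of
# compose_euler_rotation's vectorized construction).
oracle_euler <- function(a, b, g) {
  rx <- diag(3); rx[2, 2] <- cos(a); rx[2, 3] <- -sin(a)
  rx[3, 2] <- sin(a); rx[3, 3] <- cos(a)
  ry <- diag(3); ry[1, 1] <- cos(b); ry[1, 3] <- sin(b)
  ry[3, 1] <- -sin(b); ry[3, 3] <- cos(b)
  rz <- diag(3); rz[1, 1] <- cos(g); rz[1, 2] <- -sin(g)
  rz[2, 1] <- sin(g); rz[2, 2] <- cos(g)
  rx %*% ry %*% rz
}

# Multi-start iterative least squares over (alpha, beta, gamma, t, log s):
# a brute-force numerical optimizer for the same objective horn_register
# solves in closed form. Returns the best sum of squared residuals found.
oracle_nls_ss <- function(pre, post, with_scale = TRUE, n_starts = 20,
                          seed = 99) {
  p1 <- pre$coords
  p2 <- post$coords
  obj <- function(par) {
    r <- oracle_euler(par[1], par[2], par[3])
    s <- if (with_scale) exp(par[7]) else 1
    fit <- s * (p1 %*% t(r))
    fit <- sweep(fit, 2, par[4:6], "+")
    sum((p2 - fit)^2)
  }
  set.seed(seed)
  best <- Inf
  for (k in seq_len(n_starts)) {
    start <- c(stats::runif(3, -pi / 2, pi / 2),
               stats::rnorm(3, sd = 20), stats::rnorm(1, sd = 0.05))
    fit <- try(stats::optim(start, obj, method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-14)),
               silent = TRUE)
    if (!inherits(fit, "try-error") && fit$value < best) best <- fit$value
  }
  best
}

# Independent rigid/similarity registration via SVD (Kabsch): used as the
# independently coded registration for Monte-Carlo residual checks. The
# package's solver goes through the quaternion eigenproblem instead.
oracle_svd_register <- function(p1, p2, with_scale = TRUE) {
  c1 <- colMeans(p1); c2 <- colMeans(p2)
  q1 <- sweep(p1, 2, c1); q2 <- sweep(p2, 2, c2)
  sv <- svd(t(q1) %*% q2)
  d <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  r <- sv$v %*% d %*% t(sv$u)
  s <- if (with_scale) sum(q2 * (q1 %*% t(r))) / sum(q1^2) else 1
  t <- c2 - s * drop(r %*% c1)
  fit <- sweep(s * (p1 %*% t(r)), 2, t, "+")
  list(rotation = r, scale = s, translation = t,
       rms = sqrt(sum((p2 - fit)^2) / nrow(p1)))
}

# Exhaustive assignment for small n (reference for the Hungarian solver).
oracle_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  perms <- perms[apply(perms, 1, function(r) !anyDuplicated(r)), ,
                 drop = FALSE]
  vals <- apply(perms, 1, function(p) sum(cost[cbind(seq_len(n), p)]))
  perms[which.min(vals), ]
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2),
         3, 3, byrow = TRUE)
}
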