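# Independent oracles, kept deliberately separate from the package's code
# paths: plain-R brute force for distances and DVH statistics, and a direct
# dual quadratic program for epsilon-SVR.

# O(n^2) brute-force distance from every voxel center to the nearest mask
# voxel center.
brute_force_distance <- function(mask, spacing) {
  src <- which(mask, arr.ind = TRUE)
  src <- t(t(src - 1) * spacing)
  all_idx <- which(array(TRUE, dim(mask)), arr.ind = TRUE)
  pts <- t(t(all_idx - 1) * spacing)
  out <- apply(pts, 1L, function(p) sqrt(min(colSums((t(src) - p)^2))))
  array(out, dim = dim(mask))
}

# Sort-and-accumulate DVH oracle on the raw voxel dose vector: dose received
# by at least `v_cm3` of the structure, linear interpolation between the
# accumulated voxel steps.
oracle_dose_at_volume <- function(voxel_doses, voxel_cm3, v_cm3) {
  d <- sort(voxel_doses, decreasing = TRUE)
  if (v_cm3 <= voxel_cm3) return(d[1L])
  k <- min(ceiling(v_cm3 / voxel_cm3), length(d))
  d[k - 1L] + (v_cm3 - (k - 1L) * voxel_cm3) / voxel_cm3 * (d[k] - d[k - 1L])
}

# Closed-form volume of the spherical shell between radii r0 and r1 (cm^3).
shell_volume_cm3 <- function(r0, r1) 4 / 3 * pi * (r1^3 - r0^3) / 1000

# Direct epsilon-SVR dual QP via kernlab::ipop.
# min 1/2 u' H u + c' u,  u = (alpha, alpha*), 0 <= u <= C, sum(a - a*) = 0,
# H = [[K, -K], [-K, K]], c = (eps - y, eps + y).  Returns a predictor.
svr_qp_oracle <- function(X, y, C, gamma, epsilon) {
  n <- nrow(X)
  K <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    K[i, j] <- exp(-gamma * sum((X[i, ] - X[j, ])^2))
  H <- rbind(cbind(K, -K), cbind(-K, K)) + diag(1e-10, 2 * n)
  cvec <- c(epsilon - y, epsilon + y)
  A <- matrix(c(rep(1, n), rep(-1, n)), nrow = 1)
  sol <- kernlab::ipop(c = cvec, H = H, A = A, b = 0, r = 0,
                       l = rep(0, 2 * n), u = rep(C, 2 * n),
                       sigf = 12, maxiter = 200)
  u <- kernlab::primal(sol)
  beta <- u[1:n] - u[(n + 1):(2 * n)]
  # bias from unbounded support vectors (KKT), averaged for stability
  tol <- 1e-6 * C
  free_a <- which(u[1:n] > tol & u[1:n] < C - tol)
  free_as <- which(u[(n + 1):(2 * n)] > tol & u[(n + 1):(2 * n)] < C - tol)
  b_vals <- c(y[free_a] - as.numeric(K[free_a, , drop = FALSE] %*% beta) - epsilon,
              y[free_as] - as.numeric(K[free_as, , drop = FALSE] %*% beta) + epsilon)
  b <- if (length(b_vals)) mean(b_vals) else {
    mean(y - as.numeric(K %*% beta))
  }
  function(Xnew) {
    apply(as.matrix(Xnew), 1L, function(x) {
      kx <- exp(-gamma * colSums((t(X) - x)^2))
      sum(beta * kx) + b
    })
  }
}
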