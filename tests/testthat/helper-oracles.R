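# Independent oracles used across the suite. Each is deliberately written
# with a different algorithm than the implementation it checks.

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# ---- connected components by iterated dilation on logical arrays --------
# (the package labels components via an igraph adjacency graph; this oracle
# grows each component by repeated neighbourhood dilation instead)

.shift_array <- function(a, dx, dy, dz) {
  d <- dim(a)
  out <- array(FALSE, d)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[sx, sy, sz] <- a[sx - dx, sy - dy, sz - dz]
  out
}

.oracle_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nrm <- rowSums(abs(g))
  k <- switch(connectivity, faces = 1, `faces+edges` = 2,
              `faces+edges+corners` = 3)
  g[nrm >= 1 & nrm <= k, , drop = FALSE]
}

oracle_components <- function(idx, dims, connectivity = "faces") {
  mask <- array(FALSE, dims)
  mask[idx] <- TRUE
  offs <- .oracle_offsets(connectivity)
  lab <- array(0L, dims)
  cur <- 0L
  for (i in sort(idx)) {
    if (lab[i] > 0L) next
    cur <- cur + 1L
    comp <- array(FALSE, dims)
    comp[i] <- TRUE
    repeat {
      grown <- comp
      for (r in seq_len(nrow(offs)))
        grown <- grown | .shift_array(comp, offs[r, 1], offs[r, 2], offs[r, 3])
      grown <- grown & mask
      if (identical(grown, comp)) break
      comp <- grown
    }
    lab[comp] <- cur
  }
  lab
}

oracle_cluster_correct <- function(idx, dims, min_size,
                                   connectivity = "faces") {
  lab <- oracle_components(idx, dims, connectivity)
  sizes <- table(lab[lab > 0])
  keep <- as.integer(names(sizes)[sizes >= min_size])
  sort(which(array(lab %in% keep & lab > 0, dims)))
}

# ---- soft-margin SVM objective by projected gradient + exact KKT polish --
# (the package trains by SMO; this oracle solves the same dual QP by a
# different method and certifies itself through the primal-dual gap)

.proj_box_eq <- function(v, y, C) {
  g <- function(l) sum(y * pmin(pmax(v + l * y, 0), C))
  lo <- -max(abs(v)) - C - 1
  hi <- -lo
  for (k in 1:80) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
  }
  pmin(pmax(v + ((lo + hi) / 2) * y, 0), C)
}

oracle_svm_objective <- function(X, y, C, chunk = 250, max_chunks = 60) {
  n <- nrow(X)
  Q <- (y %o% y) * tcrossprod(X)
  L <- max(abs(eigen(Q, symmetric = TRUE, only.values = TRUE)$values), 1e-8)
  eps <- 1e-6 * C
  dual_of <- function(a) sum(a) - 0.5 * drop(a %*% Q %*% a)
  prim_of <- function(a) {
    w <- drop(crossprod(X, a * y))
    f <- drop(X %*% w)
    min(vapply(c(y - f, 0), function(b)
      0.5 * sum(w^2) + C * sum(pmax(0, 1 - y * (f + b))), 0))
  }
  polish <- function(a) {
    Fr <- which(a > eps & a < C - eps)
    Up <- which(a >= C - eps)
    if (!length(Fr)) return(a)
    rhs <- c(1 - (if (length(Up)) Q[Fr, Up, drop = FALSE] %*%
                    rep(C, length(Up)) else 0),
             -sum(y[Up]) * C)
    M <- rbind(cbind(Q[Fr, Fr, drop = FALSE], y[Fr]), c(y[Fr], 0))
    sol <- tryCatch(solve(M, rhs), error = function(e) NULL)
    if (is.null(sol)) return(a)
    cand <- numeric(n)
    cand[Up] <- C
    cand[Fr] <- sol[seq_along(Fr)]
    if (all(cand >= -1e-9 & cand <= C + 1e-9) && abs(sum(y * cand)) < 1e-8) {
      cand <- pmin(pmax(cand, 0), C)
      if (dual_of(cand) >= dual_of(a)) return(cand)
    }
    a
  }
  a <- rep(0, n)
  for (ch in seq_len(max_chunks)) {
    for (k in seq_len(chunk))
      a <- .proj_box_eq(drop(a - (Q %*% a - 1) / L), y, C)
    a <- polish(a)
    if (prim_of(a) - dual_of(a) < 1e-9) break
  }
  list(objective = prim_of(a), gap = prim_of(a) - dual_of(a))
}

# ---- exact signed-rank p by full enumeration of all 2^n sign patterns ----

oracle_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- drop(signs %*% r)
  min(1, 2 * min(mean(Ws >= W), mean(Ws <= W)))
}

# ---- exact binomial upper tail by term-by-term summation -----------------

oracle_binom_upper <- function(k, n, p0) {
  sum(vapply(k:n, function(j) choose(n, j) * p0^j * (1 - p0)^(n - j), 0))
}
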