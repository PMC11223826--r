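# Independent oracles used by the test suite.  They share no code with the
# implementation paths they check.

# Monte-Carlo face-area oracle: samples the radical-plane disk of the pair
# (i, j) of solvent-expanded balls uniformly and keeps the points whose
# power distance to ball i is minimal over all balls.  Returns the area
# estimate and its standard error.
mcFaceArea <- function(coords, radii, probe, i, j, nmc = 20000) {
  R <- radii + probe
  ci <- coords[i, ]; cj <- coords[j, ]
  dvec <- cj - ci
  d <- sqrt(sum(dvec^2))
  t <- (d^2 + R[i]^2 - R[j]^2) / (2 * d)
  rho2 <- R[i]^2 - t^2
  if (rho2 <= 0) return(list(area = 0, se = 0))
  u <- dvec / d
  p0 <- ci + t * u
  e1 <- if (abs(u[1]) < 0.9) c(0, -u[3], u[2]) else c(-u[3], 0, u[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  rho <- sqrt(rho2)
  rr <- rho * sqrt(runif(nmc))
  th <- runif(nmc, 0, 2 * pi)
  pts <- cbind(p0[1] + rr * cos(th) * e1[1] + rr * sin(th) * e2[1],
               p0[2] + rr * cos(th) * e1[2] + rr * sin(th) * e2[2],
               p0[3] + rr * cos(th) * e1[3] + rr * sin(th) * e2[3])
  powi <- (pts[, 1] - ci[1])^2 + (pts[, 2] - ci[2])^2 +
    (pts[, 3] - ci[3])^2 - R[i]^2
  ok <- rep(TRUE, nmc)
  for (k in seq_len(nrow(coords))) {
    if (k == i || k == j) next
    powk <- (pts[, 1] - coords[k, 1])^2 + (pts[, 2] - coords[k, 2])^2 +
      (pts[, 3] - coords[k, 3])^2 - R[k]^2
    ok <- ok & (powi <= powk)
  }
  p <- mean(ok)
  disk <- pi * rho2
  list(area = disk * p, se = disk * sqrt(max(p * (1 - p), 1e-12) / nmc))
}

# Brute-force sphere-exclusion clustering, written as plain nested loops:
# original neighbour counts, repeated promotion of the unassigned item
# with the largest count (ties: earliest), strict > threshold.
tbOracle <- function(sim, threshold = 0.5) {
  n <- nrow(sim)
  counts <- integer(n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (i != j && sim[i, j] > threshold) counts[i] <- counts[i] + 1L
  cluster <- rep(NA_integer_, n)
  centroid <- logical(n)
  cid <- 0L
  repeat {
    pick <- 0L; best <- -1L
    for (i in seq_len(n))
      if (is.na(cluster[i]) && counts[i] > best) { best <- counts[i]; pick <- i }
    if (pick == 0L) break
    cid <- cid + 1L
    cluster[pick] <- cid
    centroid[pick] <- TRUE
    for (j in seq_len(n))
      if (is.na(cluster[j]) && sim[pick, j] > threshold) cluster[j] <- cid
  }
  list(cluster = cluster, centroid = centroid,
       singleton = counts == 0L)
}

# canonical representation for comparison with the oracle: named vector
# mapping each item id to the id of its cluster's centroid
csCanonical <- function(cs) {
  m <- cs@members
  cl <- vapply(m$cluster, function(c)
    m$item[m$isCentroid & m$cluster == c], "")
  stats::setNames(cl, m$item)
}

tbOracleCanonical <- function(orc, ids) {
  stats::setNames(vapply(orc$cluster, function(c)
    ids[orc$centroid & orc$cluster == c][1], ""), ids)
}
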