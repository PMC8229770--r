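## Independent reference implementations used to validate the package's
## metrics and geometry.  Everything here is deliberately naive (pure R,
## all-pairs double loops, breadth-first search) and shares no code with the
## implementation under test.

## All-pairs directed nearest-neighbour distances: for each row of A, the
## minimum Euclidean distance to any row of B.
oracle_min_dists <- function(A, B) {
  vapply(seq_len(nrow(A)), function(i) {
    d2 <- (B[, 1] - A[i, 1])^2 + (B[, 2] - A[i, 2])^2 + (B[, 3] - A[i, 3])^2
    sqrt(min(d2))
  }, numeric(1))
}

oracle_asd <- function(A, B) (mean(oracle_min_dists(A, B)) + mean(oracle_min_dists(B, A))) / 2
oracle_hd <- function(A, B) max(max(oracle_min_dists(A, B)), max(oracle_min_dists(B, A)))
oracle_hd95 <- function(A, B)
  max(quantile(oracle_min_dists(A, B), 0.95, type = 7, names = FALSE),
      quantile(oracle_min_dists(B, A), 0.95, type = 7, names = FALSE))

## Boundary voxels by direct 6-neighbour enumeration, in mm coordinates.
oracle_boundary <- function(labels, spacing) {
  d <- dim(labels)
  pts <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (labels[i, j, k] != 1) next
    nb <- rbind(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    on_boundary <- FALSE
    for (r in seq_len(6)) {
      q <- nb[r, ]
      if (any(q < 1) || any(q > d) || labels[q[1], q[2], q[3]] == 0) {
        on_boundary <- TRUE; break
      }
    }
    if (on_boundary) pts <- rbind(pts, (c(i, j, k) - 1) * spacing)
  }
  pts
}

## Number of 26-connected foreground components (breadth-first search).
oracle_n_components <- function(labels) {
  d <- dim(labels)
  seen <- array(FALSE, d)
  fg <- which(labels == 1, arr.ind = TRUE)
  if (nrow(fg) == 0) return(0L)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, ]
  ncomp <- 0L
  for (s in seq_len(nrow(fg))) {
    v <- fg[s, ]
    if (seen[v[1], v[2], v[3]]) next
    ncomp <- ncomp + 1L
    queue <- list(v); seen[v[1], v[2], v[3]] <- TRUE
    while (length(queue) > 0) {
      cur <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
      for (r in seq_len(nrow(offsets))) {
        q <- cur + offsets[r, ]
        if (any(q < 1) || any(q > d)) next
        if (labels[q[1], q[2], q[3]] == 1 && !seen[q[1], q[2], q[3]]) {
          seen[q[1], q[2], q[3]] <- TRUE
          queue[[length(queue) + 1]] <- q
        }
      }
    }
  }
  ncomp
}

## Random blob-pair masks on a small grid with random anisotropic spacing;
## used to stress the metrics against the oracles.
random_mask_pair <- function(seed, dim3 = c(16, 16, 16)) {
  set.seed(seed)
  spacing <- runif(3, 0.4, 2.5)
  mk <- function() {
    m <- array(0, dim3)
    for (b in seq_len(sample(1:3, 1))) {
      ctr <- runif(3, 0.25, 0.75) * dim3
      rad <- runif(1, 1.5, 4.5)
      ix <- as.matrix(expand.grid(1:dim3[1], 1:dim3[2], 1:dim3[3]))
      d2 <- rowSums(sweep(ix, 2, ctr)^2)
      m[ix[d2 <= rad^2]] <- 1
    }
    if (sum(m) == 0) m[ceiling(dim3[1]/2), ceiling(dim3[2]/2), ceiling(dim3[3]/2)] <- 1
    m
  }
  list(a = binary_mask(mk(), spacing = spacing),
       b = binary_mask(mk(), spacing = spacing))
}

## Small random training cases (intensity = smoothed mask + noise) for quick
## optimizer/loop tests where realism does not matter.
tiny_case <- function(seed, S = 6, H = 16, W = 16) {
  set.seed(seed)
  m <- array(0, c(S, H, W))
  r0 <- sample(3:(H - 8), 1); c0 <- sample(3:(W - 8), 1)
  for (t in seq_len(S)) m[t, r0:(r0 + 5), c0:(c0 + 5)] <- 1
  v <- m + array(rnorm(S * H * W, sd = 0.15), c(S, H, W))
  list(volume = volume_grid(v), mask = binary_mask(m))
}

## Study conditions for the phantom comparison experiments (48x48 in-plane).
small_phantom_spec <- function(...) {
  phantom_spec(shape = c(16, 48, 48), spacing = c(1.25, 1, 1),
               arch_radius_mm = 15, limb_thickness_mm = 7,
               artifact_fraction = 0.3, noise_sigma = 0.1, ...)
}
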