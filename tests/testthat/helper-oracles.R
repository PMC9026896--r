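# Independent oracles, deliberately written with different algorithms than
# the implementations they check.

# Exhaustive max-entropy threshold search: explicit per-class entropy sums
# over occupied levels, looping every candidate threshold.
oracle_max_entropy <- function(h) {
  stopifnot(length(h) == 256)
  p <- h / sum(h)
  best_t <- NA_integer_
  best <- -Inf
  for (t in 0:254) {
    lo <- p[1:(t + 1)]
    hi <- p[(t + 2):256]
    if (sum(lo) == 0 || sum(hi) == 0) next
    plo <- lo[lo > 0] / sum(lo)
    phi_ <- hi[hi > 0] / sum(hi)
    ent <- -sum(plo * log(plo)) - sum(phi_ * log(phi_))
    if (ent > best + 1e-12) {  # strict improvement => lowest tie wins
      best <- ent
      best_t <- t
    }
  }
  best_t
}

# Component counting by repeated morphological dilation within the mask
# (fixpoint region growing), 8-connectivity.
oracle_count_components <- function(mask, min_px = 1) {
  remaining <- mask
  sizes <- integer(0)
  dilate8 <- function(m) {
    nr <- nrow(m); nc <- ncol(m)
    out <- m
    for (dr in -1:1) for (dc in -1:1) {
      src_r <- max(1, 1 - dr):min(nr, nr - dr)
      src_c <- max(1, 1 - dc):min(nc, nc - dc)
      out[src_r + dr, src_c + dc] <- out[src_r + dr, src_c + dc] | m[src_r, src_c]
    }
    out
  }
  while (any(remaining)) {
    seed_mat <- matrix(FALSE, nrow(mask), ncol(mask))
    seed_mat[which(remaining)[1]] <- TRUE
    repeat {
      grown <- dilate8(seed_mat) & remaining
      if (identical(grown, seed_mat)) break
      seed_mat <- grown
    }
    sizes <- c(sizes, sum(seed_mat))
    remaining <- remaining & !seed_mat
  }
  sum(sizes >= min_px)
}

# Random sparse-ish histograms over 0..255 for property tests.
random_histogram <- function() {
  h <- numeric(256)
  k <- sample(2:40, 1)
  levels <- sample(0:255, k)
  h[levels + 1] <- sample(1:500, k, replace = TRUE)
  h
}
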