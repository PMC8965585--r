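# Independent oracles used across the suite. Each is a deliberately naive
# implementation coded from the defining formula, kept separate from the
# package's own computation paths.

# flood-fill count of 6-connected components carrying a given label
flood_fill_components <- function(lab_array, label) {
  dims <- dim(lab_array)
  target <- which(lab_array == label)
  if (!length(target)) return(0L)
  seen <- rep(FALSE, length(lab_array))
  comps <- 0L
  for (start in target) {
    if (seen[start]) next
    comps <- comps + 1L
    stack <- start
    seen[start] <- TRUE
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      ijk <- arrayInd(v, dims)
      for (d in 1:3) for (s in c(-1L, 1L)) {
        nb <- ijk
        nb[d] <- nb[d] + s
        if (nb[d] < 1 || nb[d] > dims[d]) next
        w <- nb[1] + (nb[2] - 1) * dims[1] + (nb[3] - 1) * dims[1] * dims[2]
        if (!seen[w] && lab_array[w] == label) {
          seen[w] <- TRUE
          stack <- c(stack, w)
        }
      }
    }
  }
  comps
}

# brute-force Kendall's W from the rank-sum definition: series in columns,
# time in rows; average ranks on ties, no tie correction
kendall_w_bruteforce <- function(series_matrix) {
  n <- nrow(series_matrix)
  K <- ncol(series_matrix)
  ranks <- apply(series_matrix, 2, rank)
  Rt <- rowSums(as.matrix(ranks))
  S <- sum((Rt - mean(Rt))^2)
  12 * S / (K^2 * (n^3 - n))
}

# FA via the mean-diffusivity form: sqrt(3/2) * ||lambda - mean|| / ||lambda||
fa_oracle <- function(l1, l2, l3) {
  lam <- c(l1, l2, l3)
  m <- mean(lam)
  sqrt(3 / 2) * sqrt(sum((lam - m)^2)) / sqrt(sum(lam^2))
}

# permutation test for equality of two correlations sharing y: swap the
# A/B role of each subject at random and recompute the studentized
# Fisher-z difference (written out here independently of the package)
dependent_cor_stat <- function(y, a, b) {
  n <- length(y)
  ray <- cor(y, a); rby <- cor(y, b); rab <- cor(a, b)
  rb2 <- (ray^2 + rby^2) / 2
  f <- min(1, (1 - rab) / (2 * (1 - rb2)))
  h <- (1 - f * rb2) / (1 - rb2)
  (atanh(ray) - atanh(rby)) * sqrt((n - 3) / (2 * (1 - rab) * h))
}

dependent_cor_perm_p <- function(y, a, b, n_perm = 5000, seed = 1) {
  set.seed(seed)
  n <- length(y)
  obs <- dependent_cor_stat(y, a, b)
  stat <- numeric(n_perm)
  for (k in seq_len(n_perm)) {
    sw <- runif(n) < 0.5
    ap <- ifelse(sw, b, a)
    bp <- ifelse(sw, a, b)
    stat[k] <- dependent_cor_stat(y, ap, bp)
  }
  mean(abs(stat) >= abs(obs) - 1e-12)
}

# tiny helper: fast deterministic two-ROI slab parcellation for phantoms
slab_parcellation <- function(dims = c(12, 5, 5), split = 6) {
  p <- array(2L, dims)
  p[seq_len(split), , ] <- 1L
  attr(p, "n_rois") <- 2L
  p
}
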