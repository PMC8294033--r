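# Shared fixtures: tiny masks, brute-force oracles and a small network
# configuration. Everything is generated in code; no binary fixtures.

mask_from <- function(m, spacing = c(1.82, 1.82)) binary_mask(m, spacing)

rand_mask <- function(h = 12, w = 12, p = 0.35, spacing = c(1.82, 1.82)) {
  binary_mask(matrix(stats::runif(h * w) < p, h, w), spacing)
}

rand_nonempty_mask <- function(h = 12, w = 12, p = 0.35,
                               spacing = c(1.82, 1.82)) {
  repeat {
    m <- rand_mask(h, w, p, spacing)
    if (sum(m$pixels) > 0) return(m)
  }
}

# Brute-force overlap metrics: explicit pixel loops, no set algebra reuse.
oracle_dice <- function(a, b) {
  inter <- 0; na <- 0; nb <- 0
  for (i in seq_len(nrow(a$pixels))) {
    for (j in seq_len(ncol(a$pixels))) {
      if (a$pixels[i, j]) na <- na + 1
      if (b$pixels[i, j]) nb <- nb + 1
      if (a$pixels[i, j] && b$pixels[i, j]) inter <- inter + 1
    }
  }
  if (na + nb == 0) 1 else 2 * inter / (na + nb)
}

oracle_iou <- function(a, b) {
  inter <- 0; uni <- 0
  for (i in seq_len(nrow(a$pixels))) {
    for (j in seq_len(ncol(a$pixels))) {
      if (a$pixels[i, j] && b$pixels[i, j]) inter <- inter + 1
      if (a$pixels[i, j] || b$pixels[i, j]) uni <- uni + 1
    }
  }
  if (uni == 0) 1 else inter / uni
}

# Boundary by explicit neighbour checks (image edge counts as outside).
oracle_boundary <- function(mask) {
  m <- mask$pixels
  out <- NULL
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      if (!m[i, j]) next
      nb <- c(if (i > 1) m[i - 1, j] else FALSE,
              if (i < nrow(m)) m[i + 1, j] else FALSE,
              if (j > 1) m[i, j - 1] else FALSE,
              if (j < ncol(m)) m[i, j + 1] else FALSE)
      if (!all(nb)) out <- rbind(out, c(i, j))
    }
  }
  out
}

oracle_distances <- function(a, b) {
  pa <- oracle_boundary(a); pb <- oracle_boundary(b)
  sp <- a$spacing_mm
  dmat <- matrix(0, nrow(pa), nrow(pb))
  for (i in seq_len(nrow(pa))) {
    for (j in seq_len(nrow(pb))) {
      dmat[i, j] <- sqrt(((pa[i, 1] - pb[j, 1]) * sp[1])^2 +
                           ((pa[i, 2] - pb[j, 2]) * sp[2])^2)
    }
  }
  dab <- apply(dmat, 1, min)
  dba <- apply(dmat, 2, min)
  list(mcd = (sum(dab) + sum(dba)) / (length(dab) + length(dba)),
       hd = max(max(dab), max(dba)))
}

# Small sample set straight from logical matrices.
sample_set_from <- function(mats, spacing = c(1.82, 1.82)) {
  bool_maps <- lapply(mats, binary_mask, spacing_mm = spacing)
  structure(list(prob_maps = lapply(bool_maps, function(m) {
    probability_map(m$pixels * 1, spacing)
  }),
  bool_maps = bool_maps, n = length(mats), spacing_mm = spacing,
  source_id = "fixture"),
  class = "mc_sample_set")
}

tiny_network_config <- function(r = 0.3) {
  network_config(base_filters_U = c(3, 6), respath_filters_F = c(3, 6),
                 respath_length_L = c(2, 1), levels = 2, dropout_rate_r = r)
}
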