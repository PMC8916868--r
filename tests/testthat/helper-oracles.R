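# Independent brute-force oracles, implemented with their own index
# arithmetic so they share no code with the package internals.

# reflect (mirror-with-edge) index into 1..n
refl_idx <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

oracle_pixel <- function(img, r, c) {
  img[refl_idx(r, nrow(img)), refl_idx(c, ncol(img))]
}

oracle_patch <- function(img, r, c, p) {
  out <- matrix(0, 2 * p + 1, 2 * p + 1)
  for (a in -p:p) for (b in -p:p) {
    out[a + p + 1, b + p + 1] <- oracle_pixel(img, r + a, c + b)
  }
  out
}

oracle_gauss_kernel <- function(p, sd) {
  k <- matrix(0, 2 * p + 1, 2 * p + 1)
  for (a in -p:p) for (b in -p:p) {
    k[a + p + 1, b + p + 1] <- exp(-(a^2 + b^2) / (2 * sd^2))
  }
  k / sum(k)
}

oracle_cosine <- function(A, B) {
  n <- length(A)
  ca <- A - sum(A) / n
  cb <- B - sum(B) / n
  na <- sum(ca^2); nb <- sum(cb^2)
  ea <- 1e-9 * (1 + sum(A^2) / n)
  eb <- 1e-9 * (1 + sum(B^2) / n)
  if (na <= ea && nb <= eb) return(1)
  if (na <= ea || nb <= eb) return(0)
  min(1, max(-1, sum(ca * cb) / sqrt(na * nb)))
}

# naive triple-loop NLM reference (max_other center rule, reflect boundary)
oracle_nlm <- function(img, p, s, mu, gsd = 1, gamma = 0) {
  h <- nrow(img); w <- ncol(img)
  gk <- oracle_gauss_kernel(p, gsd)
  out <- matrix(0, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    Pi <- oracle_patch(img, r, c, p)
    ws <- 0; vs <- 0; wmax <- 0
    for (dr in -s:s) for (dc in -s:s) {
      if (dr == 0 && dc == 0) next
      Pj <- oracle_patch(img, r + dr, c + dc, p)
      d <- sum(gk * (Pi - Pj)^2)
      wgt <- exp(-d / mu)
      if (gamma > 0) {
        wgt <- wgt * ((1 + oracle_cosine(Pi, Pj)) / 2)^gamma
      }
      if (wgt > wmax) wmax <- wgt
      ws <- ws + wgt
      vs <- vs + wgt * oracle_pixel(img, r + dr, c + dc)
    }
    wc <- if (wmax > 0) wmax else 1
    out[r, c] <- (vs + wc * img[r, c]) / (ws + wc)
  }
  out
}

# O(N * |mask|) nearest-distance scan
oracle_ring <- function(mask, width_px) {
  pts <- which(mask, arr.ind = TRUE)
  ring <- matrix(FALSE, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    if (mask[r, c]) next
    dmin <- sqrt(min((pts[, 1] - r)^2 + (pts[, 2] - c)^2))
    ring[r, c] <- dmin <= width_px
  }
  ring
}

# Mann-Whitney pairwise statistic, ties counted 1/2
oracle_pairwise_auc <- function(case_scores, control_scores) {
  tot <- 0
  for (a in case_scores) for (b in control_scores) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(case_scores) * length(control_scores))
}

rand_image <- function(h, w, seed, lo = 0, hi = 255) {
  set.seed(seed)
  matrix(runif(h * w, lo, hi), h, w)
}

rand_scores <- function(n_case, n_ctrl, seed, ties = FALSE) {
  set.seed(seed)
  sc <- if (ties) {
    sample(seq_len(max(3, (n_case + n_ctrl) %/% 2)), n_case + n_ctrl,
           replace = TRUE)
  } else {
    rnorm(n_case + n_ctrl)
  }
  tibble::tibble(score = as.numeric(sc),
                 group = rep(c("case", "control"), c(n_case, n_ctrl)))
}
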