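# Independent brute-force oracles used across the suite. These re-derive
# quantities from first principles (empirical count tables, direct formula
# evaluation) without calling the package's implementation paths.

# entropy of a probability vector, base 2, 0*log0 = 0
oracle_entropy_p <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# brute-force joint/marginal entropies and SU from two code vectors
oracle_joint_stats <- function(a, b) {
  n <- length(a)
  joint <- table(a, b) / n
  ha <- oracle_entropy_p(rowSums(joint))
  hb <- oracle_entropy_p(colSums(joint))
  hab <- oracle_entropy_p(as.vector(joint))
  i <- ha + hb - hab
  su <- if (ha + hb == 0) 0 else 2 * i / (ha + hb)
  list(ha = ha, hb = hb, hab = hab, mi = i, su = su)
}

# random joint sample over at most ka x kb categories
random_joint <- function(n, ka, kb) {
  list(a = sample.int(ka, n, replace = TRUE) - 1L,
       b = sample.int(kb, n, replace = TRUE) - 1L)
}

# direct Table-2-style metric algebra from counts (independent re-derivation)
oracle_metrics <- function(tp, tn, fp, fn) {
  tot <- tp + tn + fp + fn
  safe <- function(num, den) if (den == 0) 0 else num / den
  c(acc = (tp + tn) / tot,
    tpr = safe(tp, tp + fn),
    tnr = safe(tn, tn + fp),
    ppv = safe(tp, tp + fp),
    npv = safe(tn, tn + fn),
    f1 = safe(2 * tp, 2 * tp + fp + fn),
    mr = (fp + fn) / tot,
    mcc = safe(tp * tn - fp * fn,
               sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) *
                 sqrt(tn + fn)))
}

# center-aligned bilinear interpolation with edge clamping (independent of
# the EBImage-backed implementation)
oracle_bilinear <- function(src, h, w) {
  H <- nrow(src); W <- ncol(src)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      sy <- (i - 0.5) * H / h - 0.5
      sx <- (j - 0.5) * W / w - 0.5
      y0 <- floor(sy); x0 <- floor(sx)
      fy <- sy - y0; fx <- sx - x0
      cl <- function(v, m) min(max(v, 0), m - 1) + 1
      v00 <- src[cl(y0, H), cl(x0, W)]
      v01 <- src[cl(y0, H), cl(x0 + 1, W)]
      v10 <- src[cl(y0 + 1, H), cl(x0, W)]
      v11 <- src[cl(y0 + 1, H), cl(x0 + 1, W)]
      out[i, j] <- (1 - fy) * ((1 - fx) * v00 + fx * v01) +
        fy * ((1 - fx) * v10 + fx * v11)
    }
  }
  out
}

# central finite differences of the auto-encoder cost for one block
fd_grad <- function(params, block, X, cfg, eps = 1e-6) {
  v <- params[[block]]
  g <- v
  for (i in seq_along(v)) {
    up <- params; up[[block]][i] <- v[i] + eps
    dn <- params; dn[[block]][i] <- v[i] - eps
    g[i] <- (aeGradient(up, X, cfg)$cost -
               aeGradient(dn, X, cfg)$cost) / (2 * eps)
  }
  g
}

# small deterministic planted table shared by several tests
planted_table <- function(seed = 1) {
  makeFeatureTable(nSamples = 300, nFeatures = 60, nInformative = 8,
                   nRedundant = 4, nClasses = 3, effectSize = 1.5,
                   noiseSd = 1, seed = seed)
}
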