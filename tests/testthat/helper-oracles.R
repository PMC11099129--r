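# Independent oracles used across the suite. These re-derive expected
# values with naive, loop-level code and never call the implementation
# paths they check.

# Naive statistics on a flat sample, textbook loop style.
naiveStats <- function(z, eps = 1e-8) {
  q <- length(z)
  mu <- sum(z) / q
  m2 <- 0; m3 <- 0; m4 <- 0
  for (v in z) {
    m2 <- m2 + (v - mu)^2
    m3 <- m3 + (v - mu)^3
    m4 <- m4 + (v - mu)^4
  }
  m2 <- m2 / q; m3 <- m3 / q; m4 <- m4 / q
  sigma <- sqrt(m2)
  zs <- sort(z)
  med <- if (q %% 2 == 1) zs[(q + 1) / 2] else (zs[q / 2] + zs[q / 2 + 1]) / 2
  zp <- ifelse(z == 0, eps, z)
  hm <- q / sum(1 / zp)
  gm <- prod(zp^(1 / q))
  c(mean = mu, sd = sigma, var = q * m2 / (q - 1), median = med,
    skew = if (sigma > 0) m3 / sigma^3 else 0,
    kurt = if (sigma > 0) m4 / sigma^4 else 0,
    hmean = hm, gmean = gm)
}

# Rec. 709 luminance, matching the package's convention.
oracleLuminance <- function(px) {
  if (dim(px)[3] == 1L) px[, , 1] else
    0.2126 * px[, , 1] + 0.7152 * px[, , 2] + 0.0722 * px[, , 3]
}

# Brute-force confusion recount from raw (truth, prediction) pairs.
naiveMetrics <- function(truth, pred) {
  Pt <- 0; Nt <- 0; Pf <- 0; Nf <- 0
  for (i in seq_along(truth)) {
    if (truth[i] == "malignant" && pred[i] == "malignant") Pt <- Pt + 1
    if (truth[i] == "benign" && pred[i] == "benign") Nt <- Nt + 1
    if (truth[i] == "benign" && pred[i] == "malignant") Pf <- Pf + 1
    if (truth[i] == "malignant" && pred[i] == "benign") Nf <- Nf + 1
  }
  c(accuracy = 100 * (Pt + Nt) / (Pt + Nt + Pf + Nf),
    sensitivity = if (Pt + Nf > 0) 100 * Pt / (Pt + Nf) else NA_real_,
    specificity = if (Nt + Pf > 0) 100 * Nt / (Nt + Pf) else NA_real_)
}

# Benchmark objectives.
sphereFn <- function(x) sum(x^2)
rastriginFn <- function(x) 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x))

# Uniform random search with a fixed evaluation budget.
randomSearchBest <- function(objective, lower, upper, budget, seed) {
  set.seed(seed)
  best <- Inf
  s <- length(lower)
  for (i in seq_len(budget)) {
    x <- runif(s, lower, upper)
    best <- min(best, objective(x))
  }
  best
}

# Standalone sparrow-search loop replicating the documented reduced mode
# (besiege and perching disabled) and the fixed per-individual draw
# protocol. Written independently of the package's swarm machinery.
ssaOracle <- function(objective, l, s, lower, upper, iterMax, seed,
                      pAlarm = 0.5, producerFraction = 0.2) {
  set.seed(seed)
  clip <- function(x) pmin(pmax(x, lower), upper)
  pos <- matrix(runif(l * s), nrow = l)
  pos <- sweep(sweep(pos, 2, upper - lower, `*`), 2, lower, `+`)
  fit <- apply(pos, 1, objective)
  ord <- order(fit); pos <- pos[ord, , drop = FALSE]; fit <- fit[ord]
  gBest <- pos[1, ]; gBestF <- fit[1]
  nP <- min(max(1, round(producerFraction * l)), l - 1)
  hist <- numeric(iterMax)
  for (k in seq_len(iterMax)) {
    draws <- lapply(seq_len(l), function(i) {
      list(T = runif(1), z = runif(1), p = runif(1), beta = 1 - runif(1),
           N = rnorm(1), n = runif(4), E0 = runif(1, -1, 1),
           V = runif(1, 0, 2), Q = rnorm(1),
           B = ifelse(runif(s) < 0.5, -1, 1))
    })
    worst <- pos[which.max(fit), ]
    for (r in 1:nP) {
      dr <- draws[[r]]
      cand <- if (dr$T < pAlarm)
        pos[r, ] * exp(-(1:s) / (dr$beta * iterMax))
      else pos[r, ] * dr$N
      cand <- clip(cand)
      f <- objective(cand)
      if (f <= fit[r]) { pos[r, ] <- cand; fit[r] <- f }
    }
    if (min(fit) <= gBestF) {
      gBestF <- min(fit); gBest <- pos[which.min(fit), ]
    }
    worst <- pos[which.max(fit), ]
    for (r in (nP + 1):l) {
      dr <- draws[[r]]
      cand <- if (r > l / 2) {
        dr$N * exp((worst - pos[r, ]) / r^2)
      } else {
        bp <- dr$B / sum(dr$B^2)
        gBest + sum(abs(pos[r, ] - gBest) * bp)
      }
      cand <- clip(cand)
      f <- objective(cand)
      if (f <= fit[r]) { pos[r, ] <- cand; fit[r] <- f }
    }
    if (min(fit) <= gBestF) {
      gBestF <- min(fit); gBest <- pos[which.min(fit), ]
    }
    ord <- order(fit); pos <- pos[ord, , drop = FALSE]; fit <- fit[ord]
    hist[k] <- gBestF
  }
  list(history = hist, best = gBestF)
}

# Naive non-local means on a tiny single channel (direct quadruple loop).
naiveNlm <- function(m, h, patch, win) {
  H <- nrow(m); W <- ncol(m)
  pr <- patch %/% 2; wr <- win %/% 2
  out <- m
  for (i in 1:H) for (j in 1:W) {
    num <- 0; den <- 0
    for (di in -wr:wr) for (dj in -wr:wr) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > H || jj < 1 || jj > W) next
      ssd <- 0; cnt <- 0
      for (pi in -pr:pr) for (pj in -pr:pr) {
        a <- i + pi; b <- j + pj
        a2 <- a + di; b2 <- b + dj
        if (a < 1 || a > H || b < 1 || b > W) next
        if (a2 < 1 || a2 > H || b2 < 1 || b2 > W) next
        ssd <- ssd + (m[a, b] - m[a2, b2])^2
        cnt <- cnt + 1
      }
      if (cnt == 0) next
      aa <- (ssd / cnt) / h^2
      if (aa > 30) next
      w <- exp(-aa)
      num <- num + w * m[ii, jj]
      den <- den + w
    }
    out[i, j] <- if (den > 0) num / den else m[i, j]
  }
  out
}

# Memoised small synthetic feature table shared by the slower tests.
.sharedEnv <- new.env(parent = emptyenv())
smallFeatureTable <- function() {
  if (is.null(.sharedEnv$ft))
    .sharedEnv$ft <- featureTable(smallSpec(seed = 1))
  .sharedEnv$ft
}
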