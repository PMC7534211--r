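# Independent oracles and small fixture builders used across the suite.

# Brute-force GLCM texture by explicit pair enumeration: loops over every
# pixel, collects ordered co-occurring level pairs at `offset` (both ends
# inside the mask), optionally symmetrises, and evaluates the contrast and
# entropy sums directly. Shares no code with the package implementation.
enum_texture_oracle <- function(q, offset, symmetric = TRUE) {
  h <- nrow(q); w <- ncol(q)
  pairs <- list()
  for (r in seq_len(h)) for (c in seq_len(w)) {
    r2 <- r + offset[1]; c2 <- c + offset[2]
    if (r2 < 1 || r2 > h || c2 < 1 || c2 > w) next
    a <- q[r, c]; b <- q[r2, c2]
    if (is.na(a) || is.na(b)) next
    pairs[[length(pairs) + 1]] <- c(a, b)
    if (symmetric) pairs[[length(pairs) + 1]] <- c(b, a)
  }
  if (length(pairs) == 0) {
    return(list(contrast = NA_real_, entropy = NA_real_, n_pairs = 0))
  }
  m <- do.call(rbind, pairs)
  key <- paste(m[, 1], m[, 2])
  tab <- table(key)
  p <- as.numeric(tab) / nrow(m)
  ij <- do.call(rbind, strsplit(names(tab), " "))
  di <- as.numeric(ij[, 1]) - as.numeric(ij[, 2])
  list(contrast = sum(di^2 * p),
       entropy = -sum(p * log2(p)),
       n_pairs = nrow(m))
}

# Tukey-Kramer adjusted p-values from first principles with ptukey, for
# cross-checking the package's post hoc table.
tukey_oracle <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  ns <- table(groups)
  mns <- tapply(values, groups, mean)
  df <- length(values) - k
  mse <- sum(unlist(tapply(values, groups,
                           function(x) (x - mean(x))^2))) / df
  lv <- levels(groups)
  out <- NULL
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(mse / 2 * (1 / ns[[lv[i]]] + 1 / ns[[lv[j]]]))
    q <- abs(mns[[lv[i]]] - mns[[lv[j]]]) / se
    out <- rbind(out, data.frame(
      group1 = lv[j], group2 = lv[i],
      p_adj = stats::ptukey(q, k, df, lower.tail = FALSE)))
  }
  out
}

# Classical one-way ANOVA F by direct sum-of-squares arithmetic.
anova_oracle <- function(values, groups) {
  groups <- factor(groups)
  grand <- mean(values)
  ssb <- sum(tapply(values, groups,
                    function(x) length(x) * (mean(x) - grand)^2))
  ssw <- sum(unlist(tapply(values, groups, function(x) (x - mean(x))^2)))
  k <- nlevels(groups); N <- length(values)
  F <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = F, p = stats::pf(F, k - 1, N - k, lower.tail = FALSE))
}

# Hierarchical measurement-model simulator: per-cell marker values within
# samples, averaged to the per-sample replication unit — the statistical
# skeleton of a full synthetic experiment.
simulate_measurements <- function(mu, sd = 250, n_samples = 6, n_cells = 6) {
  g <- rep(names(mu), each = n_samples)
  v <- vapply(seq_along(g),
              function(i) mean(stats::rnorm(n_cells, mu[[g[i]]], sd)),
              numeric(1))
  data.frame(group = g,
             sample = paste0(g, "_s", rep(seq_len(n_samples), length(mu))),
             runx2_mean = v, contrast = v, entropy = v)
}

# Small scene spec used by several tests.
small_scene_spec <- function(...) {
  args <- list(image_size = c(256L, 256L), n_planes = 5L, n_cells = 6L,
               cell_radius_range = c(22, 30),
               nucleus_radius_range = c(8, 12), seed = 1L)
  args[names(list(...))] <- list(...)
  do.call(scene_spec, args)
}
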