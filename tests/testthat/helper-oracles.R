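# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive algorithms (explicit loops, set algebra,
# stats::aov) rather than the package's own code paths.

# Fractional rank by explicit position counting (average positions for ties).
oracle_frank <- function(x) {
  n <- sum(!is.na(x))
  out <- rep(NA_real_, length(x))
  for (i in seq_along(x)) {
    if (is.na(x[i])) next
    below <- sum(x < x[i], na.rm = TRUE)
    ties <- sum(x == x[i], na.rm = TRUE)
    out[i] <- (below + (1 + ties) / 2) / n
  }
  out
}

# O(n * L) per-position fragment overlap count; wraps on circular contigs.
oracle_pileup <- function(fragments, L, circular = TRUE) {
  v <- numeric(L)
  for (i in seq_len(nrow(fragments))) {
    pos <- fragments$start[i]:(fragments$end[i] - 1)
    if (circular) pos <- pos %% L
    for (p in pos) v[p + 1] <- v[p + 1] + 1
  }
  v
}

# Per-position centered window mean (window offsets -floor(w/2)..w-1-floor(w/2)).
oracle_rollmean <- function(x, w, circular) {
  L <- length(x)
  left <- w %/% 2
  out <- numeric(L)
  for (i in seq_len(L)) {
    idx <- (i - left):(i - left + w - 1)
    if (circular) idx <- ((idx - 1) %% L) + 1
    else idx <- idx[idx >= 1 & idx <= L]
    out[i] <- mean(x[idx])
  }
  out
}

# Benjamini-Hochberg step-up applied literally, with monotonicity enforcement.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) {
    if (m == 1) break
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# Two-way ANOVA per gene through stats::aov (independent of the QR route).
oracle_anova_gene <- function(y, strain, treatment) {
  fit <- stats::aov(y ~ strain * treatment,
                    data.frame(y = y, strain = factor(strain),
                               treatment = factor(treatment)))
  s <- summary(fit)[[1]]
  list(F = s[["F value"]][1:3], p = s[["Pr(>F)"]][1:3])
}

# Toy design used across diffexpr tests: 3 strains x 2 treatments x n reps.
toy_design <- function(n_rep = 3) {
  d <- expand.grid(replicate = seq_len(n_rep),
                   treatment = c("control", "rifampicin"),
                   strain = c("WT", "dcedA", "dcedA_pCedA"),
                   stringsAsFactors = FALSE)
  d[, c("strain", "treatment", "replicate")]
}
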