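# Independent oracles used across the suite. Each is a direct, brute-force
# or closed-form computation kept deliberately separate from the package's
# implementation path.

# Benjamini-Hochberg step-up rule, enumerated directly from its definition:
# reject the k smallest p-values where k is the largest index with
# p_(k) <= q k / n.
bh_oracle <- function(p, q) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= q * seq_len(n) / n)
  rej <- rep(FALSE, n)
  if (length(k) > 0) rej[o[seq_len(max(k))]] <- TRUE
  rej
}

# Welch two-sample t-test from the textbook formulas.
welch_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x); v2 <- var(y)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(y) - mean(x)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, p = 2 * pt(-abs(t), df), df = df)
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled ranks to the first sample (no ties).
mw_enum_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  picks <- combn(n1 + n2, n1)
  us <- apply(picks, 2, function(ix) sum(rank(pooled)[ix]) - n1 * (n1 + 1) / 2)
  m <- n1 * n2 / 2
  mean(abs(us - m) >= abs(u_obs - m))
}

# Mann-Whitney normal approximation with tie correction and continuity
# correction, from the standard large-sample formulas.
mw_normal_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sigma2 <- (n1 * n2 / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  2 * pnorm(-abs(z))
}

# Kruskal-Wallis H with tie correction, straight from the rank formula.
kw_h_oracle <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * (mean(ri) - (N + 1) / 2)^2))
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Fisher's LSD t contrast from group means and the pooled one-way MSE.
lsd_oracle <- function(values, groups, g1, g2) {
  groups <- factor(groups)
  k <- nlevels(groups); N <- length(values)
  m <- tapply(values, groups, mean)
  n <- tapply(values, groups, length)
  sse <- sum((values - m[groups])^2)
  mse <- sse / (N - k)
  t <- (m[g1] - m[g2]) / sqrt(mse * (1 / n[g1] + 1 / n[g2]))
  list(t = unname(t), df = N - k, p = unname(2 * pt(-abs(t), N - k)))
}

# Balanced two-way mixed ANOVA (group between, time within, subject nested
# in group) by explicit sums of squares.
mixed_anova_oracle <- function(y, group, subject, time) {
  group <- factor(group); subject <- factor(subject); time <- factor(time)
  a <- nlevels(group); n <- nlevels(subject) / a; T <- nlevels(time)
  grand <- mean(y)
  mg <- tapply(y, group, mean)
  mt <- tapply(y, time, mean)
  ms <- tapply(y, subject, mean)
  mgt <- tapply(y, list(group, time), mean)
  ss_a <- n * T * sum((mg - grand)^2)
  subj_group <- tapply(as.integer(group), subject, function(v) v[1])
  ss_subj <- T * sum((ms - mg[subj_group])^2)
  ss_t <- a * n * sum((mt - grand)^2)
  ss_at <- n * sum((mgt - outer(mg, rep(1, T)) - outer(rep(1, a), mt) + grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_a - ss_subj - ss_t - ss_at
  df_a <- a - 1; df_subj <- a * (n - 1)
  df_t <- T - 1; df_at <- (a - 1) * (T - 1); df_err <- a * (n - 1) * (T - 1)
  F_a <- (ss_a / df_a) / (ss_subj / df_subj)
  F_t <- (ss_t / df_t) / (ss_err / df_err)
  F_at <- (ss_at / df_at) / (ss_err / df_err)
  list(F_group = F_a, F_time = F_t, F_interaction = F_at,
       p_interaction = pf(F_at, df_at, df_err, lower.tail = FALSE))
}

# small shared fixtures -------------------------------------------------

tiny_atlas <- function(n_regions = 5, grid = c(16, 16, 8), seed = 1) {
  make_phantom_atlas(n_regions, grid, seed = seed)
}

pixdims <- function(atlas) c(atlas$geometry$width, atlas$geometry$height,
                             atlas$geometry$slice_thickness)
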