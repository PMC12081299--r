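# Independent oracles used across test files. These deliberately use naive
# algorithms (double loops, enumeration, normal equations) so they share no
# code path with the implementation they check.

# Gini by the literal double loop
oracle_gini <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + abs(x[i] - x[j])
  s / (2 * n^2 * mean(x))
}

# transitive-closure interval merging by repeated pairwise union
oracle_merge <- function(df, max_gap) {
  out <- list()
  for (ch in unique(df$chrom)) {
    iv <- df[df$chrom == ch, c("start", "end")]
    iv <- as.matrix(iv)
    repeat {
      merged_any <- FALSE
      i <- 1
      while (i <= nrow(iv)) {
        j <- i + 1
        while (j <= nrow(iv)) {
          gap_ij <- max(iv[i, 1], iv[j, 1]) - min(iv[i, 2], iv[j, 2])
          if (gap_ij <= max_gap) {  # overlap gives negative gap
            iv[i, ] <- c(min(iv[i, 1], iv[j, 1]), max(iv[i, 2], iv[j, 2]))
            iv <- iv[-j, , drop = FALSE]
            merged_any <- TRUE
          } else j <- j + 1
        }
        i <- i + 1
      }
      if (!merged_any) break
    }
    out[[ch]] <- data.frame(chrom = ch, start = iv[, 1], end = iv[, 2])
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), ]
  rownames(res) <- NULL
  res
}

# OLS via normal equations + t distribution
oracle_ols <- function(y, X) {
  Xd <- cbind(1, X)
  XtX <- t(Xd) %*% Xd
  beta <- solve(XtX, t(Xd) %*% y)
  resid <- y - Xd %*% beta
  df <- length(y) - ncol(Xd)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tval <- beta / se
  p <- 2 * pt(-abs(tval), df)
  list(coef = beta[-1], se = se[-1], p = p[-1])
}

# BH step-up by literal enumeration of the definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(p[ord][seq(i, m)] * m / seq(i, m))
  }
  pmin(q_sorted, 1)[order(ord)]
}

# exact signed-rank p by enumeration over all 2^n sign assignments
oracle_signed_rank <- function(d, alternative) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  switch(alternative,
         greater = mean(v_all >= v_obs),
         less = mean(v_all <= v_obs),
         two.sided = min(1, 2 * min(mean(v_all >= v_obs),
                                    mean(v_all <= v_obs))))
}

# exact rank-sum p by enumeration over all group assignments
oracle_rank_sum <- function(x, y, alternative = "two.sided") {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  w_all <- apply(combs, 2, function(id) sum(r[id]) - n1 * (n1 + 1) / 2)
  switch(alternative,
         greater = mean(w_all >= w_obs),
         less = mean(w_all <= w_obs),
         two.sided = min(1, 2 * min(mean(w_all >= w_obs),
                                    mean(w_all <= w_obs))))
}

# greedy metacell construction re-implemented naively with set operations
oracle_greedy_metacells <- function(emb, k, max_shared) {
  n <- nrow(emb)
  D <- as.matrix(dist(emb))
  accepted <- list()
  for (s in seq_len(n)) {
    nb <- order(D[s, ], seq_len(n))[seq_len(min(k, n))]
    ok <- TRUE
    for (a in accepted) {
      if (length(intersect(a, nb)) > max_shared) { ok <- FALSE; break }
    }
    if (ok) accepted[[length(accepted) + 1]] <- sort(nb)
  }
  accepted
}

# small dense multiome fixture shared by several files
small_sim <- function(seed = 3L) {
  generate_multiome(synth_config(
    n_states = 3, cells_per_state_per_modality = 150, n_patients = 2,
    n_genes = 40, n_peaks = 400, n_tfs = 6, rng_seed = seed))
}
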