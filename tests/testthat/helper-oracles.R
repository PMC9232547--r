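# Independent oracles and small fixture builders shared across tests.

# Minimal SNV catalog from parallel vectors.
toy_catalog <- function(sample_id, chrom, pos, ref = "C", alt = "T",
                        variant_type = "SNP", classification = NA_character_,
                        gene = NA_character_) {
  data.table::data.table(sample_id = sample_id, chrom = as.character(chrom),
                         pos = as.integer(pos), ref = ref, alt = alt,
                         variant_type = variant_type,
                         variant_classification = classification, gene = gene)
}

# Brute-force kataegis oracle: enumerate every contiguous subsequence of
# >= k_min mutations with mean gap <= d_max, merge subsequences sharing a
# mutation, and recursively split merged regions violating the mean-gap
# bound at their largest gap. Returns a list of c(start_pos, end_pos, n).
oracle_kataegis <- function(pos, k_min = 6, d_max = 1000) {
  pos <- sort(unique(pos))
  n <- length(pos)
  wins <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j - i + 1 >= k_min && (pos[j] - pos[i]) / (j - i) <= d_max) {
        wins[[length(wins) + 1]] <- c(i, j)
      }
    }
  }
  if (!length(wins)) return(list())
  # merge any two windows sharing >= 1 mutation, to a fixed point
  repeat {
    merged_any <- FALSE
    out <- list()
    for (w in wins) {
      hit <- FALSE
      for (k in seq_along(out)) {
        if (w[1] <= out[[k]][2] && w[2] >= out[[k]][1]) {
          out[[k]] <- c(min(out[[k]][1], w[1]), max(out[[k]][2], w[2]))
          hit <- TRUE; merged_any <- TRUE
          break
        }
      }
      if (!hit) out[[length(out) + 1]] <- w
    }
    wins <- out
    if (!merged_any) break
  }
  # re-check and split
  result <- list()
  for (w in wins) {
    stack <- list(w)
    while (length(stack)) {
      r <- stack[[1]]; stack <- stack[-1]
      s <- r[1]; e <- r[2]
      if ((pos[e] - pos[s]) / (e - s) <= d_max) {
        result[[length(result) + 1]] <- c(pos[s], pos[e], e - s + 1)
      } else {
        gaps <- diff(pos[s:e])
        cut <- which.max(gaps)
        for (half in list(pos[s:(s + cut - 1)], pos[(s + cut):e])) {
          sub <- oracle_kataegis(half, k_min, d_max)
          for (x in sub) result[[length(result) + 1]] <- x
        }
      }
    }
  }
  result[order(vapply(result, `[`, numeric(1), 1))]
}

# Exhaustive 0.01-step simplex grid search for K=2 signature weights
# minimising SSE against a proportion spectrum.
oracle_grid_fit2 <- function(t_vec, P) {
  stopifnot(ncol(P) == 2)
  best <- NULL
  for (a in seq(0, 1, by = 0.01)) {
    for (b in seq(0, 1 - a, by = 0.01)) {
      r <- t_vec - (a * P[, 1] + b * P[, 2])
      sse <- sum(r * r)
      if (is.null(best) || sse < best$sse) best <- list(w = c(a, b), sse = sse)
    }
  }
  best
}

# Textbook log-rank O-E-V computation over the pooled distinct event times.
oracle_logrank <- function(timeA, eventA, timeB, eventB) {
  times <- sort(unique(c(timeA[eventA == 1], timeB[eventB == 1])))
  O <- 0; E <- 0; V <- 0
  for (t in times) {
    n1 <- sum(timeA >= t); n2 <- sum(timeB >= t)
    d1 <- sum(timeA == t & eventA == 1); d2 <- sum(timeB == t & eventB == 1)
    n <- n1 + n2; d <- d1 + d2
    if (n < 2 || d == 0) next
    O <- O + d1
    E <- E + d * n1 / n
    V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  chi2 <- (O - E)^2 / V
  list(chi2 = chi2, O = O, E = E, V = V)
}

# Random sparse+clustered positions for detector/oracle comparisons.
random_positions <- function(n_uniform = 450, n_clusters = 5, cluster_size = 10,
                             span = 2e6, gap_mean = 300) {
  pos <- sample.int(span, n_uniform)
  for (k in seq_len(n_clusters)) {
    anchor <- sample.int(span - cluster_size * gap_mean * 3, 1)
    gaps <- rgeom(cluster_size - 1, 1 / gap_mean) + 1
    pos <- c(pos, anchor + c(0, cumsum(gaps)))
  }
  sort(unique(pos))
}
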