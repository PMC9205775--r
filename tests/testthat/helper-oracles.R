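# Brute-force oracles, written as plain per-week scans so they share no code
# with the vectorized implementations they check.

# An episode opens at any crisis week with >= s crisis-free weeks before it.
# Returns a list of integer vectors, one per episode.
segment_oracle <- function(crisis_weeks, s) {
  weeks <- sort(unique(as.integer(crisis_weeks)))
  episodes <- list()
  for (w in weeks) {
    preceding <- weeks[weeks >= w - s & weeks < w]
    if (length(preceding) == 0L) {
      episodes[[length(episodes) + 1L]] <- w
    } else {
      k <- length(episodes)
      episodes[[k]] <- c(episodes[[k]], w)
    }
  }
  episodes
}

# Per-week label scan: positive iff the week itself is crisis-free and some
# episode onset falls in (t+g, t+g+w].
label_oracle <- function(crisis_weeks, span, s, w, g) {
  onsets <- vapply(segment_oracle(crisis_weeks, s), min, 1L)
  out <- integer(span[2] - span[1] + 1L)
  for (i in seq_along(out)) {
    t <- span[1] + i - 1L
    if (t %in% crisis_weeks) next
    for (o in onsets) {
      if (o > t + g && o <= t + g + w) { out[i] <- 1L; break }
    }
  }
  out
}

# Literal step-by-step two-stage step-up FDR procedure (independent of the
# package's vectorized bky_adjust): stage one is Benjamini-Hochberg at
# q' = q/(1+q); the non-rejection count estimates m0; stage two reruns the
# step-up comparison with m0 in the denominator.
bky_oracle <- function(p, q = 0.05) {
  m <- length(p)
  q1 <- q / (1 + q)
  bh <- function(level, m_eff) {
    o <- order(p)
    k <- 0L
    for (i in seq_len(m)) {
      if (p[o[i]] <= i * level / m_eff) k <- i
    }
    rej <- rep(FALSE, m)
    if (k > 0L) for (i in 1:k) rej[o[i]] <- TRUE
    rej
  }
  stage1 <- bh(q1, m)
  r1 <- sum(stage1)
  if (r1 == 0L) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  bh(q1, m - r1)
}

# Exhaustive-coalition Shapley values for a single regression tree, with the
# value of a coalition S defined as the tree-path expectation: at a split on
# a feature outside S, descend both children weighted by their training cover
# (the same conditioning TreeSHAP uses).
shapley_tree_oracle <- function(tree_dt, x) {
  # tree_dt: one tree from xgboost::xgb.model.dt.tree
  nodes <- split(tree_dt, by = "ID")
  expected <- function(id, S) {
    nd <- nodes[[id]]
    if (nd$Feature == "Leaf") return(nd$Gain) # leaf value is stored in Gain
    f <- match(nd$Feature, names(x)) # feature column (by name, else 0-based)
    if (is.na(f)) f <- as.integer(nd$Feature) + 1L
    if (f %in% S) {
      v <- x[f]
      nxt <- if (is.na(v)) nd$Missing else if (v < nd$Split) nd$Yes else nd$No
      return(expected(nxt, S))
    }
    cy <- nodes[[nd$Yes]]$Cover; cn <- nodes[[nd$No]]$Cover
    (cy * expected(nd$Yes, S) + cn * expected(nd$No, S)) / (cy + cn)
  }
  root <- tree_dt$ID[tree_dt$Node == 0]
  p <- length(x)
  phi <- numeric(p)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), p))
  for (j in seq_len(p)) {
    for (r in seq_len(nrow(subsets))) {
      S <- which(unlist(subsets[r, ]))
      if (j %in% S) next
      wgt <- factorial(length(S)) * factorial(p - length(S) - 1L) / factorial(p)
      phi[j] <- phi[j] + wgt * (expected(root, c(S, j)) - expected(root, S))
    }
  }
  list(phi = phi, base = expected(root, integer(0)))
}
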