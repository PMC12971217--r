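# Independent oracles, deliberately written along different routes than the
# implementations they check.

# --- Krippendorff alpha by literal pairwise enumeration -------------------
# D_obs: within-unit ordered pairs, each weighted 1/(m_u - 1);
# D_exp: all ordered pairs of the pooled pairable values.
# Ordinal distance uses pooled category counts as rank masses.
brute_force_alpha <- function(mat, metric = "nominal") {
  units <- apply(mat, 1, function(r) r[!is.na(r)], simplify = FALSE)
  units <- units[vapply(units, length, 0L) >= 2]
  pooled <- unlist(units, use.names = FALSE)
  n <- length(pooled)
  cats <- sort(unique(pooled))
  counts <- vapply(cats, function(v) sum(pooled == v), 0)

  dist2 <- function(a, b) {
    if (metric == "nominal") return(as.numeric(a != b))
    if (metric == "interval") return((a - b)^2)
    # ordinal: mass between the two ranks, minus half the endpoint masses
    ia <- which(cats == a); ib <- which(cats == b)
    lo <- min(ia, ib); hi <- max(ia, ib)
    (sum(counts[lo:hi]) - (counts[ia] + counts[ib]) / 2)^2
  }

  d_obs <- 0
  for (vals in units) {
    mu <- length(vals)
    for (i in seq_len(mu)) {
      for (j in seq_len(mu)) {
        if (i != j) d_obs <- d_obs + dist2(vals[i], vals[j]) / (mu - 1)
      }
    }
  }
  d_obs <- d_obs / n

  d_exp <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) d_exp <- d_exp + dist2(pooled[i], pooled[j])
    }
  }
  d_exp <- d_exp / (n * (n - 1))

  if (d_exp <= 0) return(NA_real_) # degenerate: no expected disagreement
  1 - d_obs / d_exp
}

# --- conditional likelihood for 1:1 matched pairs, maximized numerically --
# l(beta) = n10 * beta - (n10 + n01) * log(1 + exp(beta));
# SE from a finite-difference second derivative at the maximum.
numeric_clogit <- function(n10, n01) {
  loglik <- function(b) n10 * b - (n10 + n01) * log1p(exp(b))
  score <- function(b) n10 - (n10 + n01) * stats::plogis(b)
  b <- stats::uniroot(score, interval = c(-30, 30), tol = 1e-12)$root
  h <- 1e-4
  d2 <- (loglik(b + h) - 2 * loglik(b) + loglik(b - h)) / h^2
  list(log_odds = b, se = sqrt(-1 / d2))
}

# --- closed-form restatement of the decision logic ------------------------
# Derived independently from the table's structure; used only as an oracle.
closed_form_diagnosis <- function(q) {
  out <- character()
  if (q[2] && q[4]) out <- c(out, "AR")
  if (!q[1] && q[4] && (!q[2] || q[5])) out <- c(out, "CRSsNP")
  if (q[1]) out <- c(out, "CRSwNP")
  if (q[3]) out <- c(out, "DNS")
  out
}
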