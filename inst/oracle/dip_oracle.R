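# Brute-force dip oracle: enumerate every modal position (each knot, each gap),
# solve min d s.t. a unimodal CDF lies within d of the ECDF, as an LP.
# Independent of the polygon/bisection implementation in src/dip.cpp.

dip_oracle <- function(x) {
  x <- sort(x)
  n <- length(x)
  z <- unique(x)
  m <- length(z)
  if (m == 1) return(0)
  cnt <- tabulate(match(x, z), nbins = m)
  ca <- cumsum(cnt) / n        # ECDF at z_t
  cb <- c(0, ca[-m])           # ECDF just below z_t

  # Solve one LP: vars g_1..g_M, d; positions w (length M); box rows;
  # curvature triple centers given as list(center index, sign +1 convex)
  solve_mode <- function(w, lo_off, hi_off, conv_centers, conc_centers) {
    M <- length(w)
    nv <- M + 1  # + d
    A1 <- NULL; b1 <- NULL  # <=
    A2 <- NULL; b2 <- NULL  # >=
    row <- function(i, v) { r <- numeric(nv); r[i] <- v; r }
    for (t in seq_len(M)) {
      # g_t - d <= hi_off[t]
      r <- numeric(nv); r[t] <- 1; r[nv] <- -1
      A1 <- rbind(A1, r); b1 <- c(b1, hi_off[t])
      A1 <- rbind(A1, row(t, 1)); b1 <- c(b1, 1)  # g_t <= 1
      # g_t + d >= lo_off[t]
      r <- numeric(nv); r[t] <- 1; r[nv] <- 1
      A2 <- rbind(A2, r); b2 <- c(b2, lo_off[t])
    }
    for (t in seq_len(M - 1)) {  # monotone
      r <- numeric(nv); r[t] <- 1; r[t + 1] <- -1
      A1 <- rbind(A1, r); b1 <- c(b1, 0)
    }
    curv <- function(c0, sgn) {
      # sgn=+1 convex: (g_c - g_{c-1})(w_{c+1}-w_c) - (g_{c+1}-g_c)(w_c-w_{c-1}) <= 0
      a <- w[c0] - w[c0 - 1]; b <- w[c0 + 1] - w[c0]
      if (a == 0 || b == 0) return(NULL)  # coincident knot (mode split): no constraint
      r <- numeric(nv)
      r[c0 - 1] <- -b; r[c0] <- a + b; r[c0 + 1] <- -a
      sgn * r
    }
    for (c0 in conv_centers) { r <- curv(c0, 1);  if (!is.null(r)) { A1 <- rbind(A1, r); b1 <- c(b1, 0) } }
    for (c0 in conc_centers) { r <- curv(c0, -1); if (!is.null(r)) { A1 <- rbind(A1, r); b1 <- c(b1, 0) } }
    obj <- numeric(nv); obj[nv] <- 1
    fit <- boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2)
    if (fit$solved != 1) return(Inf)
    fit$value
  }

  best <- Inf
  # gap modes: convex on knots 1..s, concave on s+1..m (incl. chord constraint
  # = concave triple centered s+1); s = 0..m
  for (s in 0:m) {
    conv <- if (s >= 3) 2:(s - 1) else integer(0)
    conc_lo <- max(2, s + 1)
    conc <- if (conc_lo <= m - 1) conc_lo:(m - 1) else integer(0)
    val <- solve_mode(z, ca, cb, conv, conc)
    best <- min(best, val)
  }
  # knot modes: mode at z_k; split into gm (within d of cb_k) and gp (within d
  # of ca_k), gm <= gp; convex chain ends at gm, concave chain starts at gp
  for (k in seq_len(m)) {
    w <- c(z[seq_len(k - 1)], z[k], z[k], z[seq_len(m - k) + k])
    lo <- c(ca[seq_len(k - 1)], cb[k], ca[k], ca[seq_len(m - k) + k])
    hi <- c(cb[seq_len(k - 1)], cb[k], ca[k], cb[seq_len(m - k) + k])
    # var indices: 1..k-1 ordinary, k = gm, k+1 = gp, k+2..m+1 ordinary
    conv <- if (k >= 3) 2:(k - 1) else integer(0)
    conc <- if (k + 2 <= m) (k + 2):m else integer(0)
    val <- solve_mode(w, lo, hi, conv, conc)
    best <- min(best, val)
  }
  best
}

# Naive O(n*w) Hampel reference: centered window truncated at the edges,
# flag iff |x - med| > nsigma * 1.4826 * MAD, replace from original samples.
hampel_oracle_naive <- function(x, h, nsigma) {
  n <- length(x)
  y <- x
  flagged <- integer(0)
  for (i in seq_len(n)) {
    w <- x[max(1, i - h):min(n, i + h)]
    med <- stats::median(w)
    mad0 <- stats::median(abs(w - med))
    if (abs(x[i] - med) > nsigma * 1.4826 * mad0) {
      y[i] <- med
      flagged <- c(flagged, i)
    }
  }
  list(y = y, flagged = flagged)
}
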