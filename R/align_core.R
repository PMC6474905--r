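## Affine-gap dynamic-programming engine shared by pairwise alignment,
## 5.8S anchoring (semi-global) and profile-profile alignment.
##
## Gap cost convention: a gap of length L costs gap_open + (L - 1) * gap_extend
## (the opening penalty covers the first gapped position).
##
## The row sweep is vectorised: the horizontal-gap state within a row is a
## running maximum (cummax) whenever gap_open <= gap_extend, which holds for
## all sensible penalty settings; otherwise a scalar fallback sweep is used.

NEG_INF <- -1e18

## Core DP over a precomputed unit-by-unit score matrix S (n x m):
## S[i, j] = score of aligning row-unit i with column-unit j.
## type "global": Needleman-Wunsch; "anchor": free end gaps on the column
## sequence only (row sequence fully consumed), for locating a short
## reference inside a longer amplicon.
nw_core <- function(S, gap_open, gap_extend, type = c("global", "anchor")) {
  type <- match.arg(type)
  n <- nrow(S)
  m <- ncol(S)
  H <- matrix(NEG_INF, n + 1L, m + 1L)
  X <- matrix(NEG_INF, n + 1L, m + 1L)  # vertical: gap in column seq
  Y <- matrix(NEG_INF, n + 1L, m + 1L)  # horizontal: gap in row seq
  H[1L, 1L] <- 0
  if (n >= 1L) {
    X[2:(n + 1L), 1L] <- gap_open + (0:(n - 1L)) * gap_extend
    H[2:(n + 1L), 1L] <- X[2:(n + 1L), 1L]
  }
  if (m >= 1L) {
    if (type == "global") {
      Y[1L, 2:(m + 1L)] <- gap_open + (0:(m - 1L)) * gap_extend
      H[1L, 2:(m + 1L)] <- Y[1L, 2:(m + 1L)]
    } else {
      H[1L, 2:(m + 1L)] <- 0  # free leading skip of the column sequence
    }
  }
  vectorised <- gap_open <= gap_extend
  cols <- seq_len(m)
  for (i in seq_len(n)) {
    r <- i + 1L
    X[r, ] <- pmax(H[r - 1L, ] + gap_open, X[r - 1L, ] + gap_extend)
    D <- H[r - 1L, cols] + S[i, ]
    Z <- pmax(D, X[r, cols + 1L])
    if (vectorised) {
      G <- c(H[r, 1L], Z)                       # H values not reached via Y
      W <- G + gap_open - gap_extend * (seq_along(G) + 1L)
      cm <- cummax(W)
      Yrow <- cm[cols] + gap_extend * (cols + 1L)
      Y[r, cols + 1L] <- Yrow
      H[r, cols + 1L] <- pmax(Z, Yrow)
    } else {
      for (j in cols) {
        c2 <- j + 1L
        Y[r, c2] <- max(H[r, c2 - 1L] + gap_open, Y[r, c2 - 1L] + gap_extend)
        H[r, c2] <- max(Z[j], Y[r, c2])
      }
    }
  }
  list(H = H, X = X, Y = Y, n = n, m = m, type = type,
       gap_open = gap_open, gap_extend = gap_extend, S = S)
}

## Traceback. Tie preference at an H cell: diagonal, then up (vertical gap),
## then left; inside a gap state the gap is closed (return to H) on ties.
## Returns a 2 x L matrix of indices (0 = gap) over row/col units, plus score.
nw_traceback <- function(dp) {
  H <- dp$H; X <- dp$X; Y <- dp$Y; S <- dp$S
  n <- dp$n; m <- dp$m
  go <- dp$gap_open; ge <- dp$gap_extend
  eps <- 1e-9
  if (dp$type == "anchor") {
    last <- H[n + 1L, ]
    c0 <- which.max(last)           # leftmost maximum: deterministic
    score <- last[c0]
  } else {
    c0 <- m + 1L
    score <- H[n + 1L, m + 1L]
  }
  r <- n + 1L; cc <- c0
  ri <- integer(0); ci <- integer(0)
  state <- "H"
  while (r > 1L || (dp$type == "global" && cc > 1L)) {
    if (dp$type == "anchor" && r == 1L) break
    if (state == "H") {
      if (r > 1L && cc > 1L &&
          abs(H[r, cc] - (H[r - 1L, cc - 1L] + S[r - 1L, cc - 1L])) < eps) {
        ri <- c(r - 1L, ri); ci <- c(cc - 1L, ci)
        r <- r - 1L; cc <- cc - 1L
      } else if (r > 1L && abs(H[r, cc] - X[r, cc]) < eps) {
        state <- "X"
      } else {
        state <- "Y"
      }
    } else if (state == "X") {
      ri <- c(r - 1L, ri); ci <- c(0L, ci)
      closes <- abs(X[r, cc] - (H[r - 1L, cc] + go)) < eps
      r <- r - 1L
      state <- if (closes) "H" else "X"
    } else {  # Y
      ri <- c(0L, ri); ci <- c(cc - 1L, ci)
      closes <- abs(Y[r, cc] - (H[r, cc - 1L] + go)) < eps
      cc <- cc - 1L
      state <- if (closes) "H" else "Y"
    }
  }
  list(score = score, rows = ri, cols = ci, col_start = cc)
}

## Substitution score matrix for two base vectors under match/mismatch
## scoring; ambiguity codes score 0 against anything (neutral).
seq_score_matrix <- function(a, b, match, mismatch) {
  S <- outer(a, b, function(x, y) ifelse(x == y, match, mismatch))
  amb <- !(a %in% BASES)
  bmb <- !(b %in% BASES)
  if (any(amb)) S[amb, ] <- 0
  if (any(bmb)) S[, bmb] <- 0
  S
}
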