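# Independent literal transcriptions of the stage equations, used as
# oracles against the package implementations. Deliberately written as
# plain loops over plain numeric structures, sharing no code with R/.

# Crisp stage: min-max normalisation, entropy weights, TOPSIS closeness.
oracle_normalize <- function(B, directions) {
  m <- nrow(B); n <- ncol(B)
  F_ <- matrix(0, m, n)
  for (j in seq_len(n)) {
    bmin <- min(B[, j]); bmax <- max(B[, j])
    for (i in seq_len(m)) {
      F_[i, j] <- if (bmax == bmin) 0
      else if (directions[j] == "benefit") (B[i, j] - bmin) / (bmax - bmin)
      else (bmax - B[i, j]) / (bmax - bmin)
    }
  }
  F_
}

oracle_entropy <- function(F_) {
  m <- nrow(F_); n <- ncol(F_)
  d <- numeric(n)
  for (j in seq_len(n)) {
    s <- sum(F_[, j])
    if (s == 0) { d[j] <- 0; next }
    e <- 0
    for (i in seq_len(m)) {
      p <- F_[i, j] / s
      if (p > 0) e <- e - p * log(p)
    }
    d[j] <- 1 - e / log(m)
  }
  d / sum(d)
}

oracle_crisp_closeness <- function(F_, w) {
  m <- nrow(F_); n <- ncol(F_)
  H <- F_
  for (j in seq_len(n)) H[, j] <- w[j] * F_[, j]
  hp <- apply(H, 2, max); hm <- apply(H, 2, min)
  E <- numeric(m)
  for (i in seq_len(m)) {
    dp <- sqrt(sum((H[i, ] - hp)^2))
    dm <- sqrt(sum((H[i, ] - hm)^2))
    E[i] <- dm / (dp + dm)
  }
  E
}

# Fuzzy stage. Terms are mapped through the seven-term vocabulary given
# here as raw parameter rows (a1..a4, h1, h2 for upper then lower).
oracle_scale_params <- list(
  VL = rbind(c(0, 1, 1, 3, 1, 1),    c(0.5, 1, 1, 2, 0.9, 0.9)),
  L  = rbind(c(1, 3, 3, 5, 1, 1),    c(2, 3, 3, 4, 0.9, 0.9)),
  ML = rbind(c(3, 5, 5, 7, 1, 1),    c(4, 5, 5, 6, 0.9, 0.9)),
  M  = rbind(c(5, 7, 7, 9, 1, 1),    c(6, 7, 7, 8, 0.9, 0.9)),
  MH = rbind(c(7, 9, 9, 10, 1, 1),   c(8, 9, 9, 9.5, 0.9, 0.9)),
  H  = rbind(c(8, 9, 10, 10, 1, 1),  c(9, 9, 9, 10, 0.9, 0.9)),
  VH = rbind(c(9, 10, 10, 10, 1, 1), c(9.5, 10, 10, 10, 0.9, 0.9)))

oracle_rank_value <- function(trap2, hw = "heights") {
  # trap2: 2x6 matrix, rows = upper, lower
  total <- 0
  for (r in 1:2) {
    a <- trap2[r, 1:4]; h <- trap2[r, 5:6]
    M <- 0
    for (p in 1:3) M <- M + (a[p] + a[p + 1]) / 2
    sd0 <- function(x) sqrt(sum((x - mean(x))^2) / length(x))
    S <- sd0(a[1:2]) + sd0(a[2:3]) + sd0(a[3:4]) + sd0(a)
    Hterm <- if (hw == "heights") h[1] + h[2] else a[2] + a[3]
    total <- total + M - S / 4 + Hterm
  }
  total
}

oracle_it2f_closeness <- function(terms, w, hw = "heights") {
  # terms: character matrix m x n, benefit criteria throughout
  m <- nrow(terms); n <- ncol(terms)
  cells <- array(0, c(m, n, 2, 6))
  for (i in seq_len(m)) for (j in seq_len(n)) {
    cells[i, j, , ] <- oracle_scale_params[[terms[i, j]]]
  }
  # benefit normalisation: divide vertices by column max upper a4
  for (j in seq_len(n)) {
    astar <- max(cells[, j, 1, 4])
    cells[, j, , 1:4] <- cells[, j, , 1:4] / astar
  }
  # weight, then defuzzify
  R <- matrix(0, m, n)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    tr <- cells[i, j, , ]
    tr[, 1:4] <- tr[, 1:4] * w[j]
    R[i, j] <- oracle_rank_value(tr, hw)
  }
  vp <- apply(R, 2, max); vm <- apply(R, 2, min)
  E <- numeric(m)
  for (i in seq_len(m)) {
    dp <- sqrt(sum((R[i, ] - vp)^2))
    dm <- sqrt(sum((R[i, ] - vm)^2))
    E[i] <- dm / (dp + dm)
  }
  E
}

# Small builders shared across tests.
make_dm <- function(vals, directions = rep("benefit", ncol(vals)),
                    ids = NULL) {
  vals <- as.matrix(vals)
  if (is.null(ids)) ids <- paste0("a", seq_len(nrow(vals)))
  specs <- lapply(seq_len(ncol(vals)), function(j) {
    criterion_spec(paste0("c", j), stage = "shili",
                   direction = directions[j])
  })
  decision_matrix(vals, ids, specs)
}

random_dm <- function(m, n, directions = rep("benefit", n)) {
  make_dm(matrix(runif(m * n, 1, 100), m, n), directions)
}
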