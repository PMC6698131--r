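# Independent oracles and small fixture builders used across the suite.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Full-string regular-expression oracle for the 8CM motif: exactly eight
# cysteines arranged C-Xn-C-Xn-CC-Xn-CXC-Xn-C-Xn-C with n >= 1 spacers.
regex_8cm <- function(seq) {
  grepl("^[^C]*C[^C]+C[^C]+CC[^C]+C[^C]C[^C]+C[^C]+C[^C]*$", seq)
}

# random sequence with exactly k cysteines scattered in a non-C background
random_seq_with_cys <- function(len, k) {
  chars <- sample(setdiff(AA, "C"), len, replace = TRUE)
  if (k > 0) chars[sample(len, k)] <- "C"
  paste(chars, collapse = "")
}

# Exhaustive hypergeometric upper tail by subset enumeration.
enum_fisher <- function(k, n, K, N) {
  subsets <- combn(N, n)
  mean(colSums(subsets <= K) >= k)
}

# Euler-angle rotation matrix (z-y-z convention).
euler_rot <- function(a, b, c) {
  Rz <- function(t) rbind(c(cos(t), -sin(t), 0), c(sin(t), cos(t), 0),
                          c(0, 0, 1))
  Ry <- function(t) rbind(c(cos(t), 0, sin(t)), c(0, 1, 0),
                          c(-sin(t), 0, cos(t)))
  Rz(a) %*% Ry(b) %*% Rz(c)
}

# Brute-force minimal RMSD: coarse rotation grid refined by Nelder-Mead,
# entirely independent of the SVD route.
grid_min_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  obj <- function(par) {
    R <- euler_rot(par[1], par[2], par[3])
    sqrt(mean(rowSums((Qc %*% t(R) - Pc)^2)))
  }
  angs <- seq(0, 2 * pi, length.out = 13)[-13]
  betas <- seq(0, pi, length.out = 7)
  best <- list(val = Inf, par = c(0, 0, 0))
  for (a in angs) for (b in betas) for (c in angs) {
    v <- obj(c(a, b, c))
    if (v < best$val) best <- list(val = v, par = c(a, b, c))
  }
  opt <- optim(best$par, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 5000))
  min(best$val, opt$value)
}

# random symmetric zero-diagonal distance matrix with distinct entries
random_dist_matrix <- function(n, ids = sprintf("x%02d", seq_len(n))) {
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  vals <- sample(seq(0.5, 30, by = 0.01), n * (n - 1) / 2)
  m[upper.tri(m)] <- vals
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# partition (list of id sets) from a cutree assignment vector
partition_from_assignment <- function(assign) {
  unname(lapply(split(names(assign), assign), sort))
}

same_partition <- function(p1, p2) {
  key <- function(p) sort(vapply(p, function(g) paste(sort(g), collapse = ","),
                                 character(1)))
  identical(key(p1), key(p2))
}

# small random gapped alignment
random_alignment <- function(n_seq, n_col, gap_rate = 0.1) {
  rows <- vapply(seq_len(n_seq), function(i) {
    chars <- sample(AA, n_col, replace = TRUE)
    chars[runif(n_col) < gap_rate] <- "."
    paste(chars, collapse = "")
  }, character(1))
  nsltp_alignment(setNames(rows, sprintf("s%02d", seq_len(n_seq))))
}
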