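# Independent oracles and small synthetic inputs used across the suite.

# Exhaustive local-alignment oracle: with a linear gap penalty, a local
# alignment is determined by its set of matched index pairs (both strictly
# increasing), gaps being the unmatched positions inside each span.  The best
# score is the maximum over all such pair sets (or 0).  Independent of the
# dynamic program in sw_score().
.comb_cache <- new.env()
combs <- function(n, k) {
  key <- paste(n, k)
  if (is.null(.comb_cache[[key]]))
    .comb_cache[[key]] <- utils::combn(n, k)
  .comb_cache[[key]]
}

sw_oracle <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  m <- length(av); n <- length(bv)
  if (!m || !n) return(0)
  M <- outer(av, bv, function(x, y) ifelse(x == y, match, mismatch))
  best <- 0
  for (k in seq_len(min(m, n))) {
    A <- combs(m, k); B <- combs(n, k)
    S <- matrix(0, ncol(A), ncol(B))
    for (l in seq_len(k)) S <- S + M[A[l, ], B[l, ], drop = FALSE]
    span_a <- A[k, ] - A[1, ] + 1 - k
    span_b <- B[k, ] - B[1, ] + 1 - k
    S <- S + gap * outer(span_a, span_b, "+")
    best <- max(best, max(S))
  }
  best
}

# all flip strings of lengths lo..hi
all_flip_strings <- function(lo, hi) {
  out <- character()
  for (n in lo:hi) {
    grid <- do.call(expand.grid, rep(list(c("U", "T")), n))
    out <- c(out, apply(grid, 1, paste, collapse = ""))
  }
  out
}

# random fatgraph with bounded blocks/bonds (relies on the package generator)
rand_fg <- function(max_blocks = 12L, max_bonds = 8L) {
  n <- sample(seq_len(max_blocks), 1L)
  random_fatgraph(n, sample(0:min(max_bonds, max(0L, n - 1L)), 1L))
}

# synthetic backbone chain straight from phi/psi dihedrals
dihedral_chain <- function(n, phi, psi, id = "synthetic") {
  xyz <- fatsurf:::build_backbone_coords(n, phi, psi)
  res <- list(resno = seq_len(n), resid = rep("ALA", n),
              N = xyz$N, CA = xyz$CA, C = xyz$C, O = xyz$O,
              H = matrix(NA_real_, n, 3))
  fatsurf:::new_backbone_chain(res, id = id)
}

rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# apply a rigid motion to every atom of a chain and rebuild it
transform_chain <- function(chain, R = diag(3), shift = c(0, 0, 0)) {
  res <- chain$residues
  for (nm in c("N", "CA", "C", "O", "H")) {
    m <- res[[nm]]
    ok <- stats::complete.cases(m)
    if (any(ok))
      m[ok, ] <- t(R %*% t(m[ok, , drop = FALSE])) +
        matrix(shift, sum(ok), 3, byrow = TRUE)
    res[[nm]] <- m
  }
  res$segment <- NULL
  suppressMessages(fatsurf:::new_backbone_chain(res, id = chain$id))
}

# canonical comparable form of a fatgraph's surface data
invariant_tuple <- function(g) {
  s <- invariant_summary(g = g)
  c(s$chi, s$r, s$gtilde2, as.integer(s$orientable))
}
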