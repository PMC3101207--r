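# Generators for test inputs: idealized secondary-structure fatgraphs, the
# minimal worked example, ideal-coordinate toy PDBs, random fatgraphs and
# coordinate jitter.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Minimal worked-example fatgraph
#'
#' Four building blocks with linkage twists U, T, T and a single untwisted
#' hydrogen bond from the H-stub of the first block to the O-stub of the
#' last.  Its fattened surface is a sphere with two discs removed:
#' chi = 0, r = 2, orientable, modified genus 0, flip sequence "UTT".
#'
#' @return a [fatgraph()].
#' @export
make_example_fatgraph <- function()
  fatgraph(c(0L, 1L, 1L),
           bonds = data.frame(donor = 1L, acceptor = 4L, twist = 0L))

#' Idealized helix fatgraph
#'
#' Untwisted backbone with untwisted hydrogen bonds joining the O-stub of
#' unit i to the H-stub of unit i + s for every valid i, where the span s is
#' 4 for an alpha helix, 3 for a 3_10 helix and 5 for a pi helix.  A long
#' helix has modified genus zero and a boundary-component count growing
#' linearly with its length; every interior boundary component passes
#' through exactly four peptide units.
#'
#' @param n_units number of building blocks.
#' @param kind `"alpha"`, `"three_ten"` or `"pi"`.
#' @return a [fatgraph()].
#' @export
make_helix_fatgraph <- function(n_units,
                                kind = c("alpha", "three_ten", "pi")) {
  kind <- match.arg(kind)
  s <- c(alpha = 4L, three_ten = 3L, pi = 5L)[[kind]]
  n_units <- as.integer(n_units)
  bonds <- if (n_units > s)
    data.frame(donor = seq_len(n_units - s) + s,
               acceptor = seq_len(n_units - s), twist = 0L) else NULL
  fatgraph(rep(0L, n_units - 1L), bonds = bonds)
}

#' Idealized beta-sheet fatgraph
#'
#' Strands of twisted linkages laid out as consecutive backbone segments,
#' joined (by default) by untwisted turn linkages.  Adjacent strands are
#' connected by a ladder of hydrogen bonds: position k of strand j pairs
#' with position k (parallel) or strand_len + 1 - k (antiparallel) of strand
#' j + 1, with the donor side alternating along the ladder.  Parallel rungs
#' are untwisted and antiparallel rungs twisted, reflecting that antiparallel
#' neighbour strands run in opposite directions so their unit frames are
#' flipped.  Every interior boundary component passes through exactly four
#' peptide units.
#'
#' @param n_strands,strand_len sheet dimensions (units).
#' @param parallel logical: parallel or antiparallel pairing.
#' @param joined logical: join strands with turn linkages (default) or keep
#'   them as separate backbone segments.
#' @return a [fatgraph()].
#' @export
make_sheet_fatgraph <- function(n_strands, strand_len, parallel = FALSE,
                                joined = TRUE) {
  S <- as.integer(n_strands); m <- as.integer(strand_len)
  if (S < 2L || m < 2L) stop("need at least 2 strands of at least 2 units")
  N <- S * m
  b <- function(j, k) (j - 1L) * m + k
  segment <- if (joined) rep(1L, N) else rep(seq_len(S), each = m)
  tw <- integer()
  for (j in seq_len(S)) {
    tw <- c(tw, rep(1L, m - 1L))               # strand-internal: twisted
    if (joined && j < S) tw <- c(tw, 0L)       # turn linkage: untwisted
  }
  bonds <- NULL
  used_h <- used_o <- integer()
  for (j in seq_len(S - 1L)) for (k in seq_len(m)) {
    k2 <- if (parallel) k else m + 1L - k
    u <- b(j, k); v <- b(j + 1L, k2)
    flip <- if (parallel) k %% 2L == 0L else (j + k) %% 2L == 0L
    d <- if (flip) v else u; a <- if (flip) u else v
    if (d %in% used_h || a %in% used_o) { tmp <- d; d <- a; a <- tmp }
    if (d %in% used_h || a %in% used_o) next   # rung impossible: skip
    used_h <- c(used_h, d); used_o <- c(used_o, a)
    bonds <- rbind(bonds,
                   data.frame(donor = d, acceptor = a,
                              twist = if (parallel) 0L else 1L))
  }
  fatgraph(tw, bonds = bonds, n_blocks = N, segment = segment)
}

# NeRF internal-coordinate placement: position D given A-B-C, the bond
# length |CD|, the angle B-C-D and the torsion A-B-C-D (degrees).
place_atom <- function(a, b, c_, length, angle, torsion) {
  th <- angle * pi / 180; ph <- torsion * pi / 180
  bc <- unitv(c_ - b)
  nrm <- unitv(cross3(b - a, bc))
  m <- cross3(nrm, bc)
  d2 <- c(-length * cos(th), length * sin(th) * cos(ph),
          length * sin(th) * sin(ph))
  c_ + d2[1] * bc + d2[2] * m + d2[3] * nrm
}

# standard backbone geometry (angstrom / degrees)
.bb <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
            ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
            ang_ca_c_o = 120.8, omega = 180)

# backbone coordinates for a chain with uniform (phi, psi); returns a list of
# n x 3 matrices N, CA, C, O
build_backbone_coords <- function(n_residues, phi, psi) {
  n <- as.integer(n_residues)
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(.bb$n_ca, 0, 0)
  th <- .bb$ang_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + .bb$ca_c * c(-cos(th), sin(th), 0)
  for (i in seq_len(n)[-1]) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         .bb$c_n, .bb$ang_ca_c_n, psi)
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                          .bb$n_ca, .bb$ang_c_n_ca, .bb$omega)
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                         .bb$ca_c, .bb$ang_n_ca_c, phi)
  }
  for (i in seq_len(n))
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], .bb$c_o, .bb$ang_ca_c_o,
                         psi + 180)
  list(N = N, CA = CA, C = C, O = O)
}

#' Write an ideal alpha-helix backbone as a PDB file
#'
#' Canonical helix backbone (phi = -57, psi = -47 degrees, standard bond
#' lengths and angles) built by internal-coordinate chaining, written as a
#' minimal PDB with N, CA, C, O atoms (alanine residues).  Running the full
#' pipeline on the file recovers span-4 hydrogen bonds, an all-U flip
#' sequence and modified genus zero.
#'
#' @param n_residues chain length.
#' @param path output PDB path.
#' @param phi,psi backbone dihedrals in degrees.
#' @return `path`, invisibly.
#' @export
make_ideal_helix_pdb <- function(n_residues, path, phi = -57, psi = -47) {
  xyz <- build_backbone_coords(n_residues, phi, psi)
  n <- as.integer(n_residues)
  coords <- do.call(rbind, lapply(seq_len(n), function(i)
    rbind(xyz$N[i, ], xyz$CA[i, ], xyz$C[i, ], xyz$O[i, ])))
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(coords)),
                   type = rep("ATOM", 4L * n),
                   resno = rep(seq_len(n), each = 4L),
                   resid = rep("ALA", 4L * n),
                   eleno = seq_len(4L * n),
                   elety = rep(c("N", "CA", "C", "O"), n),
                   chain = rep("A", 4L * n))
  invisible(path)
}

#' Random fatgraph
#'
#' Uniform random twist bits on a single-segment backbone; bonds sampled
#' uniformly among block pairs without stub reuse.  Reproducible when a seed
#' is given.
#'
#' @param n_blocks number of blocks (>= 1).
#' @param n_bonds requested bonds; silently reduced when stub-respecting
#'   placements run out.
#' @param seed optional integer seed (the caller's RNG state is preserved).
#' @return a [fatgraph()].
#' @export
random_fatgraph <- function(n_blocks, n_bonds = 0L, seed = NULL) with_seed(seed, {
  n <- as.integer(n_blocks)
  tw <- if (n > 1L) sample(0:1, n - 1L, replace = TRUE) else integer()
  bonds <- NULL
  if (n_bonds > 0L && n >= 2L) {
    donors <- sample(n, min(n_bonds, n))
    used_a <- integer()
    for (d in donors) {
      choices <- setdiff(seq_len(n), c(d, used_a))
      if (!length(choices)) break
      a <- if (length(choices) == 1L) choices else sample(choices, 1L)
      used_a <- c(used_a, a)
      bonds <- rbind(bonds, data.frame(donor = d, acceptor = a,
                                       twist = sample(0:1, 1L)))
    }
  }
  fatgraph(tw, bonds = bonds, n_blocks = n)
})

#' Add Gaussian coordinate noise to a chain
#'
#' Desk-scale stand-in for ensemble-perturbation tools: every stored atom is
#' perturbed by isotropic Gaussian noise of the given standard deviation, and
#' the peptide units are rebuilt (placed amide hydrogens are re-derived from
#' the perturbed carbonyls; experimental hydrogens are perturbed directly).
#' Used to probe the empirical robustness of the surface invariants.
#'
#' @param chain a `backbone_chain`.
#' @param sigma noise standard deviation (angstrom); 0 returns an identical
#'   rebuild.
#' @param seed optional integer seed.
#' @return a new `backbone_chain`.
#' @export
jitter_structure <- function(chain, sigma, seed = NULL) with_seed(seed, {
  res <- chain$residues
  for (nm in c("N", "CA", "C", "O", "H")) {
    m <- res[[nm]]
    ok <- !is.na(m)
    m[ok] <- m[ok] + stats::rnorm(sum(ok), sd = sigma)
    res[[nm]] <- m
  }
  res$segment <- NULL
  suppressMessages(suppressWarnings(
    new_backbone_chain(res, id = chain$id, break_dist = chain$break_dist,
                       coplanarity_warn = Inf)))
})

#' Render a chain's hydrogen bonds as synthetic classic-format DSSP text
#'
#' Writes just enough of the classic DSSP layout (residue records with the
#' four N-H-->O / O-->H-N offset,energy columns) for [read_dssp_bonds()] to
#' reconstruct the bond set; intended for round-trip tests.  This is a
#' synthetic rendering, not DSSP output.
#'
#' @param chain a `backbone_chain`.
#' @param bonds bond `data.frame` (`donor`, `acceptor`, `energy`).
#' @param path output file.
#' @param chain_id single-character chain id to write.
#' @return `path`, invisibly.
#' @export
render_dssp <- function(chain, bonds, path, chain_id = "A") {
  L <- chain$L
  slots_don <- vector("list", L)   # N-H-->O entries per residue
  slots_acc <- vector("list", L)   # O-->H-N entries per residue
  for (i in seq_len(nrow(bonds))) {
    d <- bonds$donor[i]; a <- bonds$acceptor[i]; e <- bonds$energy[i]
    slots_don[[d]] <- c(slots_don[[d]], list(c(a - d, e)))
    slots_acc[[a]] <- c(slots_acc[[a]], list(c(d - a, e)))
  }
  fmt <- function(x) sprintf("%6d,%4.1f", as.integer(x[1]), x[2])
  aa1 <- vapply(chain$residues$resid, function(r) {
    a <- tryCatch(bio3d::aa321(r), warning = function(w) "X")
    if (is.na(a)) "X" else a
  }, character(1))
  lines <- c("==== Secondary Structure Definition (synthetic rendering) ====",
             "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N    N-H-->O    O-->H-N")
  for (k in seq_len(L)) {
    don <- slots_don[[k]]; acc <- slots_acc[[k]]
    f <- c(if (length(don) >= 1L) fmt(don[[1L]]) else sprintf("%6d,%4.1f", 0L, 0),
           if (length(acc) >= 1L) fmt(acc[[1L]]) else sprintf("%6d,%4.1f", 0L, 0),
           if (length(don) >= 2L) fmt(don[[2L]]) else sprintf("%6d,%4.1f", 0L, 0),
           if (length(acc) >= 2L) fmt(acc[[2L]]) else sprintf("%6d,%4.1f", 0L, 0))
    pre <- sprintf("%5d%5d %s %s", k, chain$residues$resno[k], chain_id, aa1[k])
    pre <- formatC(pre, width = -39L)           # pad to column 39
    lines <- c(lines, paste0(pre, paste(f, collapse = "")))
  }
  writeLines(lines, path)
  invisible(path)
}
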