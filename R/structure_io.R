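#' @importFrom stats sd
#' @importFrom utils head tail
NULL

vnorm <- function(x) sqrt(sum(x * x))
unitv <- function(x) {
  n <- vnorm(x)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  x / n
}
cross3 <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])

#' Place a missing amide hydrogen
#'
#' When a structure has no experimentally determined amide hydrogen, the
#' standard DSSP construction is used: the H sits 1.0 angstrom from the amide
#' nitrogen, in the direction opposite the preceding carbonyl's O -> C bond
#' (i.e. along C - O).  An experimentally present hydrogen is returned
#' unchanged; prolines have no amide hydrogen.
#'
#' @param n amide nitrogen coordinate (length-3, angstrom).
#' @param c_prev,o_prev carbonyl C and O of the preceding peptide group.
#' @param existing experimental H coordinate, returned as-is when non-NULL.
#' @param proline logical; TRUE returns NA (no donor hydrogen).
#' @return length-3 coordinate, or `c(NA, NA, NA)` for proline.
#' @examples
#' place_amide_hydrogen(c(1.33, 0, 0), c(0, 0, 0), c(0, 1.23, 0))  # (1.33, -1, 0)
#' @export
place_amide_hydrogen <- function(n, c_prev, o_prev, existing = NULL,
                                 proline = FALSE) {
  if (proline) return(c(NA_real_, NA_real_, NA_real_))
  if (!is.null(existing) && !anyNA(existing)) return(as.numeric(existing))
  as.numeric(n) + unitv(as.numeric(c_prev) - as.numeric(o_prev)) * 1.0
}

#' Kabsch-Sander hydrogen-bond energy
#'
#' The DSSP electrostatic model for a backbone hydrogen bond between an
#' acceptor carbonyl (O, C) and a donor amide (N, H):
#' E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) kcal/mol.
#' Any of the four distances below 0.5 angstrom is treated as a steric clash
#' and returns +Inf rather than a division blow-up.
#'
#' All arguments may be n x 3 matrices for vectorized evaluation.
#'
#' @param o,c_,n,h coordinates (angstrom) of acceptor O, acceptor C, donor N,
#'   donor H.
#' @return energy in kcal/mol (vector when matrices are supplied).
#' @export
kabsch_sander_energy <- function(o, c_, n, h) {
  as_m <- function(x) if (is.matrix(x)) x else matrix(as.numeric(x), nrow = 1)
  o <- as_m(o); c_ <- as_m(c_); n <- as_m(n); h <- as_m(h)
  d <- function(a, b) sqrt(rowSums((a - b)^2))
  r_on <- d(o, n); r_ch <- d(c_, h); r_oh <- d(o, h); r_cn <- d(c_, n)
  e <- 0.084 * 332 * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
  e[r_on < 0.5 | r_ch < 0.5 | r_oh < 0.5 | r_cn < 0.5] <- Inf
  e
}

# Build the peptide-unit bookkeeping of a chain from its per-residue backbone
# coordinates.  Unit k spans residues (k, k+1) of the same segment and stores
# the six atoms of the planar peptide group plus the amide hydrogen of residue
# k+1 (from the file when present, otherwise placed by the DSSP rule; NA for
# proline).  Stub convention: block k's O-stub is the carbonyl O of residue k
# and its H-stub the amide H of residue k -- the indexing under which helical
# hydrogen bonds span 4 units (3 for 3_10, 5 for pi) as in the idealized
# motifs.
build_units <- function(res, coplanarity_warn = 0.5) {
  L <- length(res$resno)
  seg <- res$segment
  has_unit <- which(seq_len(L - 1L) > 0L & seg[-L] == seg[-1L])
  units <- vector("list", L - 1L)
  n_warn <- 0L
  for (k in has_unit) {
    h2 <- res$H[k + 1L, ]
    if (anyNA(h2)) {
      if (!identical(res$resid[k + 1L], "PRO"))
        h2 <- place_amide_hydrogen(res$N[k + 1L, ], res$C[k, ], res$O[k, ])
    }
    pts <- rbind(res$CA[k, ], res$C[k, ], res$O[k, ], res$N[k + 1L, ],
                 res$CA[k + 1L, ])
    ctr <- colMeans(pts)
    dev <- sweep(pts, 2, ctr)
    nrm <- svd(dev)$v[, 3L]
    if (max(abs(dev %*% nrm)) > coplanarity_warn) n_warn <- n_warn + 1L
    units[[k]] <- list(index = k, ca1 = res$CA[k, ], c = res$C[k, ],
                       o = res$O[k, ], n2 = res$N[k + 1L, ], h2 = h2,
                       ca2 = res$CA[k + 1L, ],
                       res1 = res$resid[k], res2 = res$resid[k + 1L],
                       segment = seg[k])
  }
  if (n_warn > 0L)
    warning(sprintf("%d peptide unit(s) deviate from planarity by more than %.2f angstrom",
                    n_warn, coplanarity_warn))
  units
}

new_backbone_chain <- function(res, id = "chain", break_dist = 4.5,
                               coplanarity_warn = 0.5) {
  L <- length(res$resno)
  if (L < 2L) stop("need at least 2 complete residues")
  ca_gap <- sqrt(rowSums((res$CA[-1L, , drop = FALSE] -
                          res$CA[-L, , drop = FALSE])^2))
  linked <- ca_gap <= break_dist & (diff(res$resno) %in% c(0L, 1L))
  res$segment <- cumsum(c(1L, as.integer(!linked)))
  n_breaks <- sum(!linked)
  if (n_breaks > 0L)
    message(sprintf("chain %s: %d chain break(s) detected; %d segment(s)",
                    id, n_breaks, n_breaks + 1L))
  units <- build_units(res, coplanarity_warn)
  if (!any(!vapply(units, is.null, logical(1))))
    stop("no usable peptide units in chain")
  structure(list(id = id, L = L, residues = res, units = units,
                 break_dist = break_dist,
                 coplanarity_warn = coplanarity_warn),
            class = "backbone_chain")
}

#' @export
print.backbone_chain <- function(x, ...) {
  cat(sprintf("backbone_chain %s: %d residues, %d peptide units, %d segment(s)\n",
              x$id, x$L, sum(!vapply(x$units, is.null, logical(1))),
              length(unique(x$residues$segment))))
  invisible(x)
}

# indices of units that exist
unit_ids <- function(chain)
  which(!vapply(chain$units, is.null, logical(1)))

#' Read a protein backbone from a PDB file
#'
#' Extracts the N, CA, C, O (and, when present, amide H) atoms of one chain,
#' resolves alternate locations to the highest occupancy, honours insertion
#' codes in residue order, and assembles the peptide units.  Residues missing
#' any of the four heavy backbone atoms are excluded with a warning.  Chain
#' breaks (consecutive CA further apart than `break_dist` angstrom, or
#' non-consecutive residue numbers) split the chain into segments.
#'
#' @param path PDB file.
#' @param chain chain identifier; default takes the first chain in the file.
#' @param break_dist CA-CA distance (angstrom) beyond which consecutive
#'   residues are considered disconnected.
#' @param coplanarity_warn out-of-plane deviation (angstrom) above which a
#'   peptide unit triggers a planarity warning.
#' @return object of class `backbone_chain`.
#' @export
read_pdb_backbone <- function(path, chain = NULL, break_dist = 4.5,
                              coplanarity_warn = 0.5) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop("no ATOM records in ", path)
  if (is.null(chain)) chain <- at$chain[1L]
  at <- at[at$chain %in% chain, , drop = FALSE]
  if (!nrow(at)) stop("chain ", chain, " not found in ", path)
  at <- at[at$elety %in% c("N", "CA", "C", "O", "H", "HN"), , drop = FALSE]
  at$elety[at$elety == "HN"] <- "H"
  at$insert[is.na(at$insert)] <- ""
  at$o[is.na(at$o)] <- 1

  rkey <- paste(at$resno, at$insert, sep = "_")
  rkeys <- unique(rkey)                         # file order, insertion aware
  names_need <- c("N", "CA", "C", "O")
  res_list <- list(resno = integer(), resid = character())
  mats <- list(N = NULL, CA = NULL, C = NULL, O = NULL, H = NULL)
  dropped <- 0L
  for (rk in rkeys) {
    sub <- at[rkey == rk, , drop = FALSE]
    pick <- function(ele) {
      s <- sub[sub$elety == ele, , drop = FALSE]
      if (!nrow(s)) return(NULL)
      s <- s[order(-s$o), , drop = FALSE]       # altloc: highest occupancy
      as.numeric(s[1L, c("x", "y", "z")])
    }
    coords <- lapply(c(names_need, "H"), pick)
    names(coords) <- c(names_need, "H")
    if (any(vapply(coords[names_need], is.null, logical(1)))) {
      dropped <- dropped + 1L
      next
    }
    if (is.null(coords$H)) coords$H <- c(NA_real_, NA_real_, NA_real_)
    res_list$resno <- c(res_list$resno, sub$resno[1L])
    res_list$resid <- c(res_list$resid, sub$resid[1L])
    for (nm in c(names_need, "H")) mats[[nm]] <- rbind(mats[[nm]], coords[[nm]])
  }
  if (dropped > 0L)
    warning(sprintf("%d residue(s) missing backbone atoms were excluded", dropped))
  if (length(res_list$resno) < 2L)
    stop("fewer than 2 complete residues in chain ", chain)
  res <- c(res_list, mats)
  for (nm in c(names_need, "H")) rownames(res[[nm]]) <- NULL
  new_backbone_chain(res, id = paste0(basename(path), "_", chain),
                     break_dist = break_dist,
                     coplanarity_warn = coplanarity_warn)
}

# donor atoms (N, H) available to block k: the amide of residue k, stored in
# unit k-1.  Returns NULL when the block cannot donate.
donor_atoms <- function(chain, k) {
  if (k < 2L) return(NULL)
  u <- chain$units[[k - 1L]]
  if (is.null(u) || anyNA(u$h2)) return(NULL)
  list(n = u$n2, h = u$h2)
}

# enforce per-stub uniqueness: keep the lowest-energy bond per H-stub and per
# O-stub; ties by smaller |donor - acceptor|, then lower acceptor index.
dedupe_stubs <- function(bonds) {
  if (!nrow(bonds)) return(bonds)
  ord <- order(bonds$energy, abs(bonds$donor - bonds$acceptor), bonds$acceptor)
  bonds <- bonds[ord, , drop = FALSE]
  keep <- !duplicated(bonds$donor) & !duplicated(bonds$acceptor)
  out <- bonds[keep, , drop = FALSE]
  out[order(out$donor), , drop = FALSE]
}

#' Infer hydrogen bonds with the Kabsch-Sander model
#'
#' Evaluates the electrostatic energy for every donor/acceptor block pair of
#' the chain (excluding self and immediate backbone neighbours, |i - j| <= 1)
#' and keeps pairs below the energy cutoff.  Bifurcated bonds are then
#' removed: each H-stub and each O-stub retains only its lowest-energy bond.
#'
#' @param chain a `backbone_chain`.
#' @param cutoff energy threshold in kcal/mol (default -0.5, the standard
#'   DSSP value); a bond requires E < cutoff.
#' @return `data.frame` with columns `donor`, `acceptor` (block indices) and
#'   `energy` (kcal/mol).
#' @export
infer_hydrogen_bonds <- function(chain, cutoff = -0.5) {
  uids <- unit_ids(chain)
  acceptors <- uids
  donors <- uids[!vapply(uids, function(k) is.null(donor_atoms(chain, k)),
                         logical(1))]
  empty <- data.frame(donor = integer(), acceptor = integer(),
                      energy = numeric())
  if (!length(donors) || !length(acceptors)) return(empty)
  pairs <- expand.grid(donor = donors, acceptor = acceptors)
  pairs <- pairs[abs(pairs$donor - pairs$acceptor) >= 2L, , drop = FALSE]
  if (!nrow(pairs)) return(empty)
  getm <- function(ids, f) t(vapply(ids, f, numeric(3)))
  dn <- getm(pairs$donor, function(k) donor_atoms(chain, k)$n)
  dh <- getm(pairs$donor, function(k) donor_atoms(chain, k)$h)
  ao <- getm(pairs$acceptor, function(k) chain$units[[k]]$o)
  ac <- getm(pairs$acceptor, function(k) chain$units[[k]]$c)
  e <- kabsch_sander_energy(ao, ac, dn, dh)
  sel <- is.finite(e) & e < cutoff
  bonds <- data.frame(donor = pairs$donor[sel], acceptor = pairs$acceptor[sel],
                      energy = e[sel])
  dedupe_stubs(bonds)
}

#' Read hydrogen bonds from a classic-format DSSP file
#'
#' Reconstructs the bond set from the four N-H-->O / O-->H-N offset/energy
#' column pairs of a DSSP file, converts residues to block indices of the
#' supplied chain, de-duplicates records listed from both partners, applies
#' the energy cutoff and neighbour exclusion, and enforces stub uniqueness
#' exactly as [infer_hydrogen_bonds()] does.
#'
#' @param path DSSP file (classic text format).
#' @param chain a `backbone_chain` giving the residue numbering to map onto.
#' @param chain_id DSSP chain identifier to read; default takes the first.
#' @param cutoff energy threshold in kcal/mol.
#' @return `data.frame` with columns `donor`, `acceptor`, `energy`.
#' @export
read_dssp_bonds <- function(path, chain, chain_id = NULL, cutoff = -0.5) {
  lines <- readLines(path)
  hdr <- grep("^  #  RESIDUE", lines)
  if (!length(hdr)) stop("not a classic-format DSSP file: ", path)
  body <- lines[(hdr[1L] + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  recs <- list(); n_bad <- 0L
  for (ln in body) {
    if (substr(ln, 14L, 14L) == "!") next      # chain break record
    idx <- suppressWarnings(as.integer(substr(ln, 1L, 5L)))
    resno <- suppressWarnings(as.integer(substr(ln, 6L, 10L)))
    ch <- substr(ln, 12L, 12L)
    hb <- substr(ln, 40L, 83L)
    fields <- substring(hb, seq(1L, 34L, by = 11L), seq(11L, 44L, by = 11L))
    parts <- regmatches(fields, regexec("(-?[0-9]+),\\s*(-?[0-9.]+)", fields))
    if (is.na(idx) || is.na(resno) || any(!lengths(parts))) {
      n_bad <- n_bad + 1L
      next
    }
    recs[[length(recs) + 1L]] <- list(
      idx = idx, resno = resno, chain = ch,
      off = vapply(parts, function(p) as.integer(p[2L]), integer(1)),
      en = vapply(parts, function(p) as.numeric(p[3L]), numeric(1)))
  }
  if (n_bad > 0L)
    warning(sprintf("skipped %d malformed DSSP line(s)", n_bad))
  if (!length(recs)) stop("no residue records parsed from ", path)
  chains <- vapply(recs, `[[`, character(1), "chain")
  if (is.null(chain_id)) chain_id <- chains[1L]
  recs <- recs[chains == chain_id]

  idx2pos <- local({
    resnos <- vapply(recs, `[[`, integer(1), "resno")
    idxs <- vapply(recs, `[[`, integer(1), "idx")
    pos <- match(resnos, chain$residues$resno)
    stats::setNames(pos, idxs)
  })
  bonds <- data.frame(donor = integer(), acceptor = integer(),
                      energy = numeric())
  add <- function(d, a, e) {
    if (is.na(d) || is.na(a)) return()
    bonds <<- rbind(bonds, data.frame(donor = d, acceptor = a, energy = e))
  }
  for (rc in recs) {
    self <- idx2pos[[as.character(rc$idx)]]
    partner <- function(off) {
      p <- idx2pos[as.character(rc$idx + off)]
      if (length(p)) p[[1L]] else NA_integer_
    }
    # fields 1,3: this residue's N-H donates to O of (idx + off)
    for (f in c(1L, 3L)) if (rc$en[f] < 0) add(self, partner(rc$off[f]), rc$en[f])
    # fields 2,4: this residue's O accepts from N-H of (idx + off)
    for (f in c(2L, 4L)) if (rc$en[f] < 0) add(partner(rc$off[f]), self, rc$en[f])
  }
  if (!nrow(bonds)) return(bonds)
  # each bond may be listed from both partners; keep one copy
  bonds <- bonds[!duplicated(bonds[c("donor", "acceptor", "energy")]), , drop = FALSE]
  uids <- unit_ids(chain)
  ok <- bonds$donor %in% uids & bonds$acceptor %in% uids &
    abs(bonds$donor - bonds$acceptor) >= 2L & bonds$energy < cutoff
  dedupe_stubs(bonds[ok, , drop = FALSE])
}
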