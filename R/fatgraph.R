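#' Construct a fatgraph
#'
#' A fatgraph (ribbon graph) is a graph together with a cyclic ordering of the
#' edge-ends at every vertex and a twist bit on every edge; thickening edges
#' into strips produces a compact surface with boundary.  Here every vertex is
#' a "building block" standing for one planar peptide unit, consecutive blocks
#' are joined by alpha-carbon linkages (backbone edges), and hydrogen bonds
#' join the H-stub of the donor block to the O-stub of the acceptor block.
#'
#' The cyclic order of attachment sites around each block is fixed once for
#' the whole model: backbone-in, O-stub, backbone-out, H-stub, read
#' cyclically -- the two stubs leave on opposite sides of the backbone, as the
#' C=O and N-H groups do in a planar peptide unit.  This is the unique
#' convention (up to mirror) that reproduces both the worked two-boundary
#' example and the genus-zero, four-unit-boundary structure of idealized
#' helices and sheets.  Unbonded stubs are dropped (a dangling strip is
#' contractible and changes no invariant).
#'
#' @param backbone_twists integer vector of 0/1 twist bits, one per
#'   alpha-carbon linkage.  With a `segment` vector, linkages only join
#'   consecutive blocks of the same segment, so the length must be
#'   `n_blocks - n_segments`.
#' @param bonds `data.frame` with columns `donor`, `acceptor` and optionally
#'   `twist` (default 0): hydrogen-bond edges from H-stub of `donor` to O-stub
#'   of `acceptor`.  Each block may appear at most once as donor and at most
#'   once as acceptor (no bifurcated bonds).
#' @param n_blocks number of building blocks.
#' @param segment optional integer vector (length `n_blocks`, non-decreasing)
#'   assigning blocks to backbone segments; chain breaks in a structure give
#'   more than one segment.
#' @return object of class `fatgraph`.
#' @examples
#' g <- fatgraph(c(0L, 1L, 1L), bonds = data.frame(donor = 1, acceptor = 4))
#' euler_characteristic(g)
#' @export
fatgraph <- function(backbone_twists, bonds = NULL, n_blocks = NULL,
                     segment = NULL) {
  backbone_twists <- as.integer(backbone_twists)
  if (is.null(n_blocks)) {
    if (is.null(segment)) n_blocks <- length(backbone_twists) + 1L
    else n_blocks <- length(segment)
  }
  n_blocks <- as.integer(n_blocks)
  if (n_blocks < 1L) stop("a fatgraph needs at least one block")
  if (is.null(segment)) segment <- rep(1L, n_blocks)
  segment <- as.integer(segment)
  if (length(segment) != n_blocks) stop("`segment` must have one entry per block")
  if (any(diff(segment) < 0L)) stop("`segment` must be non-decreasing")
  n_seg <- length(unique(segment))
  if (length(backbone_twists) != n_blocks - n_seg)
    stop(sprintf("expected %d backbone twists, got %d",
                 n_blocks - n_seg, length(backbone_twists)))
  if (length(backbone_twists) && !all(backbone_twists %in% c(0L, 1L)))
    stop("twist bits must be 0 (untwisted) or 1 (twisted)")

  joined <- which(diff(segment) == 0L)      # blocks i with a linkage i -> i+1
  backbone <- data.frame(from = joined, to = joined + 1L,
                         twist = backbone_twists)

  if (is.null(bonds)) bonds <- data.frame(donor = integer(), acceptor = integer(),
                                          twist = integer())
  bonds <- as.data.frame(bonds)
  if (!all(c("donor", "acceptor") %in% names(bonds)))
    stop("`bonds` needs columns donor and acceptor")
  if (is.null(bonds$twist)) bonds$twist <- rep(0L, nrow(bonds))
  bonds <- data.frame(donor = as.integer(bonds$donor),
                      acceptor = as.integer(bonds$acceptor),
                      twist = as.integer(bonds$twist))
  if (nrow(bonds)) {
    if (any(bonds$donor < 1L | bonds$donor > n_blocks |
            bonds$acceptor < 1L | bonds$acceptor > n_blocks))
      stop("bond endpoint out of range")
    if (any(bonds$donor == bonds$acceptor))
      stop("a bond may not join a block to itself")
    if (anyDuplicated(bonds$donor))
      stop("H-stub used by more than one bond (stub uniqueness violated)")
    if (anyDuplicated(bonds$acceptor))
      stop("O-stub used by more than one bond (stub uniqueness violated)")
    if (!all(bonds$twist %in% c(0L, 1L)))
      stop("twist bits must be 0 or 1")
    bonds <- bonds[order(bonds$donor), , drop = FALSE]   # canonical order
  }
  rownames(bonds) <- NULL
  rownames(backbone) <- NULL

  structure(list(n_blocks = n_blocks, segment = segment,
                 backbone = backbone, bonds = bonds),
            class = "fatgraph")
}

#' @export
print.fatgraph <- function(x, ...) {
  cat(sprintf("fatgraph: %d blocks, %d linkages (%d twisted), %d bonds (%d twisted), %d segment(s)\n",
              x$n_blocks, nrow(x$backbone), sum(x$backbone$twist),
              nrow(x$bonds), sum(x$bonds$twist),
              length(unique(x$segment))))
  invisible(x)
}

# Attachment-site codes around a block, in counterclockwise cyclic order.
SITE_BACKBONE_IN <- 1L
SITE_O_STUB <- 2L
SITE_BACKBONE_OUT <- 3L
SITE_H_STUB <- 4L

# Edge table of a fatgraph: one row per edge with endpoints, twist and the
# attachment site used at each endpoint.  Shared by the boundary traversal and
# the polygon-gluing oracle (it defines the surface; the counting algorithms
# are what differ).
fg_edges <- function(g) {
  bb <- g$backbone
  bd <- g$bonds
  data.frame(
    u = c(bb$from, bd$donor),
    v = c(bb$to, bd$acceptor),
    twist = c(bb$twist, bd$twist),
    type = rep(c("backbone", "bond"), c(nrow(bb), nrow(bd))),
    usite = c(rep(SITE_BACKBONE_OUT, nrow(bb)), rep(SITE_H_STUB, nrow(bd))),
    vsite = c(rep(SITE_BACKBONE_IN, nrow(bb)), rep(SITE_O_STUB, nrow(bd)))
  )
}

# Half-edge structure: for edge j the half-edges are 2j-1 (at u) and 2j (at v),
# plus per-vertex rotation successor/predecessor arrays.
fg_halfedges <- function(g) {
  ed <- fg_edges(g)
  ne <- nrow(ed)
  if (ne == 0L)
    return(list(edges = ed, n_half = 0L, vert = integer(), site = integer(),
                opp = integer(), eid = integer(), nxt = integer(),
                prv = integer(), isolated = seq_len(g$n_blocks)))
  h <- seq_len(2L * ne)
  eid <- rep(seq_len(ne), each = 2L)
  vert <- as.integer(rbind(ed$u, ed$v))
  site <- as.integer(rbind(ed$usite, ed$vsite))
  opp <- as.integer(rbind(seq_len(ne) * 2L, seq_len(ne) * 2L - 1L))
  nxt <- prv <- integer(2L * ne)
  for (b in unique(vert)) {
    hs <- h[vert == b]
    hs <- hs[order(site[hs])]          # ccw rotation: in, O, H, out
    k <- length(hs)
    nxt[hs] <- hs[(seq_len(k) %% k) + 1L]
    prv[hs] <- hs[((seq_len(k) - 2L) %% k) + 1L]
  }
  isolated <- setdiff(seq_len(g$n_blocks), unique(vert))
  list(edges = ed, n_half = 2L * ne, vert = vert, site = site, opp = opp,
       eid = eid, nxt = nxt, prv = prv, isolated = isolated)
}

#' Boundary components of the thickened fatgraph surface
#'
#' Traverses the boundary of the surface obtained by fattening every edge into
#' a strip (twisted strips glued with a half-turn).  The traversal walks
#' states (half-edge, side): crossing an edge moves to the opposite half-edge
#' and flips the side bit exactly when the edge is twisted; at a block the
#' walk advances to the rotation successor or predecessor of the arrival
#' half-edge according to the current side.  Every state lies on exactly one
#' cycle and each boundary circle is traced twice (once per direction), so the
#' cycles pair up into boundary components.  Blocks with no incident edges
#' contribute one disk boundary each.
#'
#' @param g a [fatgraph()].
#' @return object of class `fg_boundary`: a list of components, each a list
#'   with `blocks` (distinct blocks visited) and `strands` (a `data.frame` of
#'   the oriented edge-sides walked, empty for isolated blocks).  Its length
#'   is the boundary-component count r.
#' @export
boundary_components <- function(g) {
  he <- fg_halfedges(g)
  comps <- list()
  if (he$n_half > 0L) {
    twist <- he$edges$twist
    # state index: 2*(h-1) + 1 for side +1, 2*(h-1) + 2 for side -1
    n_state <- 2L * he$n_half
    perm <- integer(n_state)
    for (h in seq_len(he$n_half)) {
      for (sbit in 1:2) {
        s <- if (sbit == 1L) 1L else -1L
        s2 <- if (twist[he$eid[h]] == 1L) -s else s
        h2 <- he$opp[h]
        k <- if (s2 > 0L) he$nxt[h2] else he$prv[h2]
        perm[2L * (h - 1L) + sbit] <- 2L * (k - 1L) + (if (s2 > 0L) 1L else 2L)
      }
    }
    seen <- logical(n_state)
    cycles <- list()
    for (st0 in seq_len(n_state)) {
      if (seen[st0]) next
      cyc <- integer()
      st <- st0
      repeat {
        seen[st] <- TRUE
        cyc <- c(cyc, st)
        st <- perm[st]
        if (st == st0) break
      }
      cycles[[length(cycles) + 1L]] <- cyc
    }
    # Pair each cycle with its mirror (same boundary circle walked the other
    # way): the two share exactly the same set of undirected edge-side arcs.
    arc_key <- vapply(cycles, function(cyc) {
      h <- (cyc - 1L) %/% 2L + 1L
      s <- ifelse((cyc - 1L) %% 2L == 0L, 1L, -1L)
      e <- he$eid[h]
      lower <- 2L * e - 1L
      # reading an arc from the non-canonical end reverses the walk, which
      # flips the side label (and twist flips it once more): -s * lambda
      side_at_lower <- ifelse(h == lower, s,
                              ifelse(twist[e] == 1L, s, -s))
      paste(sort(2L * (e - 1L) + ifelse(side_at_lower > 0L, 1L, 2L)),
            collapse = ",")
    }, character(1))
    grp <- split(seq_along(cycles), arc_key)
    bad <- vapply(grp, length, integer(1)) != 2L
    if (any(bad)) stop("internal error: boundary cycles failed to pair")
    for (idx in grp) {
      cyc <- cycles[[idx[1L]]]
      h <- (cyc - 1L) %/% 2L + 1L
      s <- ifelse((cyc - 1L) %% 2L == 0L, 1L, -1L)
      strands <- data.frame(edge = he$eid[h],
                            type = he$edges$type[he$eid[h]],
                            from_block = he$vert[h],
                            to_block = he$vert[he$opp[h]],
                            side = s)
      blocks <- sort(unique(c(strands$from_block, strands$to_block)))
      comps[[length(comps) + 1L]] <- list(blocks = blocks, strands = strands)
    }
  }
  for (b in he$isolated)
    comps[[length(comps) + 1L]] <- list(
      blocks = b, strands = data.frame(edge = integer(), type = character(),
                                       from_block = integer(),
                                       to_block = integer(), side = integer()))
  structure(comps, class = "fg_boundary")
}

#' @export
print.fg_boundary <- function(x, ...) {
  cat(sprintf("%d boundary component(s)\n", length(x)))
  for (i in seq_along(x))
    cat(sprintf("  [%d] %d strand(s), blocks: %s\n", i, nrow(x[[i]]$strands),
                paste(x[[i]]$blocks, collapse = " ")))
  invisible(x)
}

#' Number of distinct peptide units a boundary component passes through
#'
#' @param component one element of [boundary_components()].
#' @return integer count of distinct blocks visited.
#' @export
boundary_unit_count <- function(component) length(component$blocks)

#' Euler characteristic of a fatgraph
#'
#' Computed as V - E of the underlying graph (the surface deformation-retracts
#' onto its graph).  For a single unbroken backbone segment with H hydrogen
#' bonds this equals 1 - H.
#'
#' @param g a [fatgraph()].
#' @return integer.
#' @export
euler_characteristic <- function(g)
  g$n_blocks - nrow(g$backbone) - nrow(g$bonds)

# Connected components of the underlying graph (bonds can join segments).
fg_graph_components <- function(g) {
  parent <- seq_len(g$n_blocks)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  unite <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[ra] <<- rb }
  ed <- fg_edges(g)
  for (j in seq_len(nrow(ed))) unite(ed$u[j], ed$v[j])
  roots <- vapply(seq_len(g$n_blocks), find, integer(1))
  match(roots, unique(roots))
}

#' Orientability of the fatgraph surface
#'
#' The surface is orientable iff no cycle of the graph carries an odd number
#' of twisted edges.  Using the backbone as a spanning forest, an orientation
#' sign is propagated over tree edges (flipping across twists); the surface is
#' orientable iff every remaining edge closes its cycle with even total twist
#' parity.
#'
#' @param g a [fatgraph()].
#' @return logical.
#' @export
orientable <- function(g) {
  ed <- fg_edges(g)
  n <- g$n_blocks
  adj <- vector("list", n)
  for (j in seq_len(nrow(ed))) {
    adj[[ed$u[j]]] <- c(adj[[ed$u[j]]], list(c(ed$v[j], ed$twist[j])))
    adj[[ed$v[j]]] <- c(adj[[ed$v[j]]], list(c(ed$u[j], ed$twist[j])))
  }
  mu <- rep(NA_integer_, n)
  for (root in seq_len(n)) {
    if (!is.na(mu[root])) next
    mu[root] <- 1L
    queue <- root
    while (length(queue)) {
      b <- queue[[1L]]; queue <- queue[-1L]
      for (nb in adj[[b]]) {
        want <- if (nb[2L] == 1L) -mu[b] else mu[b]
        if (is.na(mu[nb[1L]])) { mu[nb[1L]] <- want; queue <- c(queue, nb[1L]) }
        else if (mu[nb[1L]] != want) return(FALSE)
      }
    }
  }
  TRUE
}

#' Modified genus of the fatgraph surface
#'
#' For orientable surfaces the modified genus is the classical genus; for
#' non-orientable surfaces it is half the crosscap number.  With this
#' convention the Euler characteristic satisfies chi = 2c - 2*gtilde - r
#' uniformly, where c is the number of connected components (c = 1 for an
#' unbroken domain), so gtilde = (2c - r - chi) / 2.
#'
#' @param g a [fatgraph()].
#' @param chi,r,orient precomputed Euler characteristic, boundary-component
#'   count, and orientability; computed from `g` when missing.
#' @return the modified genus as a numeric (integer or half-integer >= 0),
#'   with attribute `times2` holding the exact doubled integer value.
#' @export
modified_genus <- function(g, chi = NULL, r = NULL, orient = NULL) {
  if (is.null(chi)) chi <- euler_characteristic(g)
  if (is.null(r)) r <- length(boundary_components(g))
  if (is.null(orient)) orient <- orientable(g)
  ncomp <- max(fg_graph_components(g))
  g2 <- 2L * ncomp - as.integer(r) - as.integer(chi)
  if (g2 < 0L)
    stop(sprintf("internal inconsistency: doubled modified genus %d < 0", g2))
  if (orient && g2 %% 2L != 0L)
    stop("internal inconsistency: orientable surface with half-integer genus")
  structure(g2 / 2, times2 = g2)
}

#' Invariant summary of a protein fatgraph
#'
#' Assembles the robust variables of one domain: residue count L, hydrogen
#' bond count H, twisted-linkage count t, Euler characteristic chi, boundary
#' component count r, modified genus gtilde and orientability, together with
#' the flip sequence(s) read off the backbone twists.
#'
#' For a single-segment domain the identity chi = 2 - 2*gtilde - r holds
#' exactly.  Multi-segment domains (chain breaks) are flagged: chi, H and t
#' add over segments and gtilde is recomputed from the summed chi and r, but
#' r alone is not comparable across domains with different segment counts.
#'
#' @param chain optional `backbone_chain` the fatgraph came from (supplies the
#'   residue count L); without it L is taken as blocks + segments.
#' @param g a [fatgraph()].
#' @return object of class `fg_invariants` (also a list) with fields
#'   `L`, `H`, `t`, `chi`, `r`, `gtilde`, `gtilde2`, `orientable`,
#'   `n_segments`, `flips`.
#' @export
invariant_summary <- function(chain = NULL, g) {
  if (inherits(chain, "fatgraph") && missing(g)) { g <- chain; chain <- NULL }
  stopifnot(inherits(g, "fatgraph"))
  n_seg <- length(unique(g$segment))
  L <- if (!is.null(chain)) chain$L else g$n_blocks + n_seg
  chi <- euler_characteristic(g)
  bc <- boundary_components(g)
  r <- length(bc)
  orient <- orientable(g)
  gt <- modified_genus(g, chi = chi, r = r, orient = orient)
  flips <- vapply(split(g$backbone$twist, g$segment[g$backbone$from]),
                  function(tw) paste(c("U", "T")[tw + 1L], collapse = ""),
                  character(1))
  structure(list(L = L, H = nrow(g$bonds), t = sum(g$backbone$twist),
                 chi = chi, r = r, gtilde = as.numeric(gt),
                 gtilde2 = attr(gt, "times2"), orientable = orient,
                 n_segments = n_seg, flips = unname(flips)),
            class = "fg_invariants")
}

#' @export
print.fg_invariants <- function(x, ...) {
  cat(sprintf("L=%d H=%d t=%d chi=%d r=%d gtilde=%s orientable=%s%s\n",
              x$L, x$H, x$t, x$chi, x$r, format(x$gtilde),
              if (x$orientable) "yes" else "no",
              if (x$n_segments > 1L)
                sprintf(" [%d segments: r not comparable]", x$n_segments)
              else ""))
  invisible(x)
}

#' Four robust variables of a domain
#'
#' The feature vector (gtilde, r, t, L) used by downstream fold classifiers.
#'
#' @param summary an `fg_invariants` object.
#' @return named numeric vector.
#' @export
feature_vector <- function(summary) {
  stopifnot(inherits(summary, "fg_invariants"))
  c(gtilde = summary$gtilde, r = summary$r, t = summary$t, L = summary$L)
}

#' Brute-force boundary count by polygon gluing (testing oracle)
#'
#' Builds the fattened surface explicitly as a polygonal complex -- one 2d-gon
#' per block of degree d, one rectangle per edge, twisted edges glued with a
#' flip -- identifies glued vertices by union-find, and counts the cycles of
#' free (unglued) polygon sides.  Entirely independent of the strand-traversal
#' algorithm in [boundary_components()]; intended for tests.
#'
#' @param g a [fatgraph()].
#' @return integer boundary-component count.
#' @export
oracle_boundary_count <- function(g) {
  he <- fg_halfedges(g)
  ed <- he$edges
  ne <- nrow(ed)
  if (ne == 0L) return(g$n_blocks)

  # vertex ids: block polygons then rectangles
  n_pts <- 0L
  block_pts <- vector("list", g$n_blocks)   # per block: 2d point ids, ccw
  block_sites <- vector("list", g$n_blocks) # site order matching the polygon
  for (b in seq_len(g$n_blocks)) {
    hs <- which(he$vert == b)
    if (!length(hs)) next
    hs <- hs[order(he$site[hs])]
    d <- length(hs)
    block_pts[[b]] <- n_pts + seq_len(2L * d)
    block_sites[[b]] <- he$site[hs]
    n_pts <- n_pts + 2L * d
  }
  rect_pts <- matrix(0L, nrow = ne, ncol = 4L)
  for (j in seq_len(ne)) { rect_pts[j, ] <- n_pts + 1:4; n_pts <- n_pts + 4L }

  parent <- seq_len(n_pts)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  unite <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[ra] <<- rb }

  attach_side <- function(b, s) {
    i <- match(s, block_sites[[b]])
    pts <- block_pts[[b]]
    c(pts[2L * i - 1L], pts[2L * i])
  }
  for (j in seq_len(ne)) {
    q <- rect_pts[j, ]
    au <- attach_side(ed$u[j], ed$usite[j])
    av <- attach_side(ed$v[j], ed$vsite[j])
    unite(q[1L], au[2L]); unite(q[2L], au[1L])       # end A: reversed
    if (ed$twist[j] == 0L) { unite(q[3L], av[2L]); unite(q[4L], av[1L]) }
    else                   { unite(q[3L], av[1L]); unite(q[4L], av[2L]) }
  }

  # free sides: block corner sides + rectangle margins
  free_a <- integer(); free_b <- integer()
  for (b in seq_len(g$n_blocks)) {
    pts <- block_pts[[b]]
    if (is.null(pts)) next
    d2 <- length(pts)
    for (i in seq_len(d2 / 2L)) {
      free_a <- c(free_a, pts[2L * i])
      free_b <- c(free_b, pts[if (2L * i == d2) 1L else 2L * i + 1L])
    }
  }
  for (j in seq_len(ne)) {
    q <- rect_pts[j, ]
    free_a <- c(free_a, q[2L], q[4L])
    free_b <- c(free_b, q[3L], q[1L])
  }
  # boundary cycles = connected components of the free-side graph
  ra <- vapply(free_a, find, integer(1))
  rb <- vapply(free_b, find, integer(1))
  parent2 <- seq_len(n_pts)
  find2 <- function(x) { while (parent2[x] != x) { parent2[x] <<- parent2[parent2[x]]; x <- parent2[x] }; x }
  for (k in seq_along(ra)) {
    x <- find2(ra[k]); y <- find2(rb[k]); if (x != y) parent2[x] <- y
  }
  length(unique(vapply(unique(c(ra, rb)), find2, integer(1)))) +
    length(he$isolated)
}

#' Euler-characteristic additivity check for a chopped chain
#'
#' When one chain is chopped into n parts, the Euler characteristics satisfy
#' chi_whole = sum(chi_i) + (1 - n) - B, where B counts hydrogen bonds between
#' parts (each part keeps a connected backbone, the chopping removes n - 1
#' linkages, and inter-part bonds are lost).  gtilde and r obey no such
#' relation, which is the non-additivity of the surface invariants.
#'
#' @param whole fatgraph of the full chain.
#' @param parts list of fatgraphs of the parts.
#' @param inter_bonds number of hydrogen bonds between different parts.
#' @return list with both sides of the chi relation, whether it holds exactly,
#'   and the (non-additive) gtilde and r sums for comparison.
#' @export
additivity_report <- function(whole, parts, inter_bonds) {
  stopifnot(inherits(whole, "fatgraph"))
  n <- length(parts)
  chi_whole <- euler_characteristic(whole)
  chi_parts <- vapply(parts, euler_characteristic, numeric(1))
  sw <- invariant_summary(g = whole)
  sp <- lapply(parts, function(p) invariant_summary(g = p))
  list(n_parts = n, inter_bonds = inter_bonds,
       chi_whole = chi_whole, chi_parts_sum = sum(chi_parts),
       chi_relation_holds =
         chi_whole == sum(chi_parts) + (1L - n) - inter_bonds,
       gtilde_whole = sw$gtilde, gtilde_parts_sum = sum(vapply(sp, `[[`, numeric(1), "gtilde")),
       r_whole = sw$r, r_parts_sum = sum(vapply(sp, `[[`, numeric(1), "r")))
}
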