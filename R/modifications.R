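# The four basic fatgraph modifications and the robustness probe.
#
# Robust variables are those changing at most linearly with the number of
# basic modifications applied; the probe measures the per-step constants
# empirically on random fatgraphs.

#' Construct a basic fatgraph modification
#'
#' The four basic modification kinds are: toggling the twist of an
#' alpha-carbon linkage (`"toggle_linkage"`), toggling the twist of a
#' hydrogen bond (`"toggle_bond"`), adding or removing an untwisted hydrogen
#' bond (`"add_bond"` / `"remove_bond"`), and splitting a building block in
#' two joined by an untwisted linkage or merging back (`"split_block"` /
#' `"merge_block"`).  On a split, every bond incident on the original block
#' stays with the replacement block that occurs first along the backbone
#' (N-ward); a merge removes a block that carries no bonds and has an
#' untwisted linkage to its left neighbour.
#'
#' @param kind one of `"toggle_linkage"`, `"toggle_bond"`, `"add_bond"`,
#'   `"remove_bond"`, `"split_block"`, `"merge_block"`.
#' @param site linkage row, bond row, or block index, per kind.
#' @param donor,acceptor blocks for `"add_bond"`.
#' @return object of class `fg_modification`.
#' @export
modification <- function(kind, site = NULL, donor = NULL, acceptor = NULL) {
  kind <- match.arg(kind, c("toggle_linkage", "toggle_bond", "add_bond",
                            "remove_bond", "split_block", "merge_block"))
  if (kind == "add_bond") {
    if (is.null(donor) || is.null(acceptor))
      stop("add_bond needs donor and acceptor")
  } else if (is.null(site)) stop(kind, " needs a site")
  structure(list(kind = kind, site = site, donor = donor,
                 acceptor = acceptor), class = "fg_modification")
}

#' @export
print.fg_modification <- function(x, ...) {
  cat("fg_modification:", x$kind,
      if (x$kind == "add_bond") sprintf("%d -> %d", x$donor, x$acceptor)
      else paste("site", x$site), "\n")
  invisible(x)
}

# rebuild a fatgraph from explicit backbone rows + segment + bonds
fg_rebuild <- function(n_blocks, segment, backbone, bonds) {
  backbone <- backbone[order(backbone$from), , drop = FALSE]
  fatgraph(backbone$twist, bonds = bonds, n_blocks = n_blocks,
           segment = segment)
}

#' Apply a basic modification to a fatgraph
#'
#' Validates the site preconditions (e.g. bond removal targets an existing
#' untwisted bond; a merged block must carry no bonds and an untwisted left
#' linkage) and returns the modified fatgraph.  Applying a modification and
#' then its inverse restores the fatgraph exactly.
#'
#' @param g a [fatgraph()].
#' @param m an [modification()].
#' @return the modified [fatgraph()].
#' @export
apply_modification <- function(g, m) {
  stopifnot(inherits(g, "fatgraph"), inherits(m, "fg_modification"))
  bb <- g$backbone; bd <- g$bonds; seg <- g$segment; n <- g$n_blocks
  switch(m$kind,
    toggle_linkage = {
      if (is.null(m$site) || m$site < 1L || m$site > nrow(bb))
        stop("no such linkage: ", m$site)
      bb$twist[m$site] <- 1L - bb$twist[m$site]
      fg_rebuild(n, seg, bb, bd)
    },
    toggle_bond = {
      if (is.null(m$site) || m$site < 1L || m$site > nrow(bd))
        stop("no such bond: ", m$site)
      bd$twist[m$site] <- 1L - bd$twist[m$site]
      fg_rebuild(n, seg, bb, bd)
    },
    add_bond = {
      if (m$donor %in% bd$donor)
        stop("H-stub of block ", m$donor, " already bonded")
      if (m$acceptor %in% bd$acceptor)
        stop("O-stub of block ", m$acceptor, " already bonded")
      if (m$donor == m$acceptor) stop("bond endpoints must differ")
      bd <- rbind(bd, data.frame(donor = as.integer(m$donor),
                                 acceptor = as.integer(m$acceptor),
                                 twist = 0L))
      fg_rebuild(n, seg, bb, bd)
    },
    remove_bond = {
      if (is.null(m$site) || m$site < 1L || m$site > nrow(bd))
        stop("no such bond: ", m$site)
      if (bd$twist[m$site] != 0L)
        stop("only an untwisted bond may be removed")
      fg_rebuild(n, seg, bb, bd[-m$site, , drop = FALSE])
    },
    split_block = {
      b <- m$site
      if (is.null(b) || b < 1L || b > n) stop("no such block: ", b)
      shift <- function(x) ifelse(x > b, x + 1L, x)
      # the linkage leaving b moves to the new (later) replacement block;
      # bonds on b stay with b, the replacement occurring first N-ward
      bb2 <- data.frame(from = ifelse(bb$from >= b, bb$from + 1L, bb$from),
                        to = shift(bb$to), twist = bb$twist)
      bb2 <- rbind(bb2, data.frame(from = b, to = b + 1L, twist = 0L))
      bd2 <- if (nrow(bd)) data.frame(donor = shift(bd$donor),
                                      acceptor = shift(bd$acceptor),
                                      twist = bd$twist) else bd
      fg_rebuild(n + 1L, append(seg, seg[b], after = b), bb2, bd2)
    },
    merge_block = {
      b <- m$site
      if (is.null(b) || b < 1L || b > n) stop("no such block: ", b)
      if (any(bd$donor == b | bd$acceptor == b))
        stop("block ", b, " carries a bond and cannot be merged")
      left <- which(bb$from == b - 1L & bb$to == b)
      if (!length(left))
        stop("block ", b, " has no left linkage")
      if (bb$twist[left] != 0L)
        stop("left linkage of block ", b, " is twisted")
      bb2 <- bb[-left, , drop = FALSE]
      shift <- function(x) ifelse(x > b, x - 1L, x)
      bb2 <- data.frame(from = ifelse(bb2$from >= b, bb2$from - 1L, bb2$from),
                        to = shift(bb2$to), twist = bb2$twist)
      bd2 <- if (nrow(bd)) data.frame(donor = shift(bd$donor),
                                      acceptor = shift(bd$acceptor),
                                      twist = bd$twist) else bd
      fg_rebuild(n - 1L, seg[-b], bb2, bd2)
    })
}

# all valid modifications of g, grouped by kind (used by the probe and by
# exhaustive reachability tests)
enumerate_modifications <- function(g) {
  bb <- g$backbone; bd <- g$bonds; n <- g$n_blocks
  out <- list()
  if (nrow(bb))
    out$toggle_linkage <- lapply(seq_len(nrow(bb)), function(i)
      modification("toggle_linkage", i))
  if (nrow(bd))
    out$toggle_bond <- lapply(seq_len(nrow(bd)), function(i)
      modification("toggle_bond", i))
  free_d <- setdiff(seq_len(n), bd$donor)
  free_a <- setdiff(seq_len(n), bd$acceptor)
  adds <- expand.grid(donor = free_d, acceptor = free_a)
  adds <- adds[adds$donor != adds$acceptor, , drop = FALSE]
  if (nrow(adds))
    out$add_bond <- lapply(seq_len(nrow(adds)), function(i)
      modification("add_bond", donor = adds$donor[i],
                   acceptor = adds$acceptor[i]))
  rem <- which(bd$twist == 0L)
  if (length(rem))
    out$remove_bond <- lapply(rem, function(i) modification("remove_bond", i))
  out$split_block <- lapply(seq_len(n), function(b)
    modification("split_block", b))
  mergeable <- bb$to[bb$twist == 0L]
  mergeable <- mergeable[!(mergeable %in% c(bd$donor, bd$acceptor))]
  if (length(mergeable))
    out$merge_block <- lapply(mergeable, function(b)
      modification("merge_block", b))
  out
}

random_modification <- function(g) {
  cand <- enumerate_modifications(g)
  cand <- cand[lengths(cand) > 0L]
  kind <- sample(names(cand), 1L)
  ms <- cand[[kind]]
  ms[[sample.int(length(ms), 1L)]]
}

#' Empirical robustness probe
#'
#' Applies random length-k sequences of basic modifications to a fatgraph
#' and reports the maximum observed deviation of each robust variable from
#' its original value.  Per single modification the deviations are bounded:
#' |dL| <= 1, |dt| <= 1, |dchi| <= 1, |dr| <= 1 and |d(2 gtilde)| <= 2, so a
#' k-step sequence moves each variable at most k times its per-step bound.
#'
#' @param g starting [fatgraph()].
#' @param k modifications per trial.
#' @param trials number of random sequences.
#' @param seed optional integer seed.
#' @return named numeric vector of maxima: `L`, `t`, `chi`, `r`, `gtilde2`
#'   (the deviation of twice the modified genus).
#' @export
robustness_probe <- function(g, k = 1L, trials = 100L, seed = NULL)
  with_seed(seed, {
    base <- invariant_summary(g = g)
    ref <- c(L = base$L, t = base$t, chi = base$chi, r = base$r,
             gtilde2 = base$gtilde2)
    mx <- ref * 0
    for (tr in seq_len(trials)) {
      h <- g
      for (step in seq_len(k)) h <- apply_modification(h, random_modification(h))
      s <- invariant_summary(g = h)
      dev <- abs(c(L = s$L, t = s$t, chi = s$chi, r = s$r,
                   gtilde2 = s$gtilde2) - ref)
      mx <- pmax(mx, dev)
    }
    mx
  })
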