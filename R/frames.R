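#' Orthonormal frame of a peptide unit
#'
#' Attaches a right-handed orthonormal coordinate system to the planar
#' peptide unit: e1 follows the peptide bond from the carbonyl carbon to the
#' amide nitrogen, e2 is the in-plane component of C -> O orthogonal to e1
#' (pointing to the oxygen side), and e3 = e1 x e2 is the plane normal.  The
#' origin is the midpoint of the C-N bond.  Any frame rigidly attached to the
#' planar unit yields an equivalent twist model; this constructive rule is
#' fixed once and validated by reproducing the helix/sheet flip patterns.
#'
#' @param c_,o,n coordinates (angstrom) of the unit's carbonyl C, carbonyl O
#'   and amide N; alternatively pass a peptide-unit list with fields `c`,
#'   `o`, `n2` as `c_`.
#' @return object of class `peptide_frame`: list with `origin`, `e1`, `e2`,
#'   `e3`.
#' @examples
#' f <- peptide_frame(c(0, 0, 0), c(-0.4, 1.16, 0), c(1.33, 0, 0))
#' f$e1  # (1, 0, 0)
#' @export
peptide_frame <- function(c_, o = NULL, n = NULL) {
  if (is.list(c_) && is.null(o)) { o <- c_$o; n <- c_$n2; c_ <- c_$c }
  c_ <- as.numeric(c_); o <- as.numeric(o); n <- as.numeric(n)
  e1 <- unitv(n - c_)
  w <- (o - c_) - sum((o - c_) * e1) * e1
  if (vnorm(w) < 1e-8)
    stop("degenerate peptide unit: C, O, N are collinear")
  e2 <- w / vnorm(w)
  e3 <- cross3(e1, e2)
  structure(list(origin = (c_ + n) / 2, e1 = e1, e2 = e2, e3 = e3),
            class = "peptide_frame")
}

#' Twist state of an edge between two peptide-unit frames
#'
#' An edge (alpha-carbon linkage or hydrogen bond) is twisted when the two
#' frames disagree in orientation: the decision sum
#' s = <e2_a, e2_b> + <e3_a, e3_b> combines the change of the peptide-plane
#' normal with the change of in-plane orientation.  Identical frames give
#' s = 2 (untwisted); an upside-down frame gives s = -2 (twisted).  The edge
#' is twisted iff s < 0; the measure-zero tie s = 0 counts as untwisted,
#' since small orientation changes must give untwisted edges.
#'
#' @param frame_a,frame_b two [peptide_frame()]s.
#' @return integer twist bit: 0 = untwisted, 1 = twisted.
#' @export
edge_twist <- function(frame_a, frame_b) {
  s <- sum(frame_a$e2 * frame_b$e2) + sum(frame_a$e3 * frame_b$e3)
  if (s < 0) 1L else 0L
}

#' Frames of every peptide unit of a chain
#'
#' @param chain a `backbone_chain`.
#' @return list indexed like `chain$units` (NULL where no unit exists).
#' @export
chain_frames <- function(chain) {
  lapply(chain$units, function(u) if (is.null(u)) NULL else peptide_frame(u))
}

#' Twist labels for all alpha-carbon linkages and hydrogen bonds
#'
#' Linkage k joining consecutive units k, k+1 of a segment is labelled
#' `edge_twist(frame_k, frame_{k+1})`; a bond (donor d, acceptor a) is
#' labelled `edge_twist(frame_d, frame_a)`.  Deterministic.
#'
#' @param chain a `backbone_chain`.
#' @param bonds bond `data.frame` (`donor`, `acceptor`, ...), e.g. from
#'   [infer_hydrogen_bonds()].
#' @param frames optional precomputed [chain_frames()].
#' @return list with `linkages` (`data.frame`: `from`, `to`, `twist`) and
#'   `bonds` (the input with a `twist` column).
#' @export
label_all_edges <- function(chain, bonds = NULL, frames = NULL) {
  if (is.null(frames)) frames <- chain_frames(chain)
  uids <- unit_ids(chain)
  # units k and k+1 both existing share residue k+1, hence the same segment
  from <- intersect(uids, uids - 1L)
  linkages <- data.frame(from = from, to = from + 1L,
                         twist = vapply(from, function(k)
                           edge_twist(frames[[k]], frames[[k + 1L]]),
                           integer(1)))
  if (is.null(bonds)) bonds <- data.frame(donor = integer(),
                                          acceptor = integer(),
                                          energy = numeric())
  bonds$twist <- if (nrow(bonds))
    vapply(seq_len(nrow(bonds)), function(i)
      edge_twist(frames[[bonds$donor[i]]], frames[[bonds$acceptor[i]]]),
      integer(1)) else integer()
  list(linkages = linkages, bonds = bonds)
}

#' Flip sequence of a chain
#'
#' The fatgraph-native secondary-structure annotation: one letter per
#' alpha-carbon linkage in N -> C order, U = untwisted, T = twisted.  Alpha
#' helices read UUU..., beta strands TTT....
#'
#' @param chain a `backbone_chain`.
#' @param labels edge labels from [label_all_edges()]; computed when missing.
#' @return character vector with one U/T string per backbone segment (a
#'   single-unit segment gives an empty string).
#' @export
flip_sequence <- function(chain, labels = NULL) {
  if (is.null(labels)) labels <- label_all_edges(chain)
  uids <- unit_ids(chain)
  seg <- vapply(chain$units[uids], `[[`, integer(1), "segment")
  lk <- labels$linkages
  out <- vapply(sort(unique(seg)), function(s) {
    ks <- uids[seg == s]
    rows <- lk$from %in% ks[-length(ks)]
    paste(c("U", "T")[lk$twist[rows] + 1L], collapse = "")
  }, character(1))
  unname(out)
}

#' Assemble the fatgraph of a labelled chain
#'
#' One building block per peptide unit; backbone edges join consecutive units
#' of a segment with their linkage twists; hydrogen bonds join donor H-stubs
#' to acceptor O-stubs with their bond twists.  Unit indices are renumbered
#' to consecutive block indices (gaps arise at chain breaks).
#'
#' @param chain a `backbone_chain`.
#' @param labels edge labels from [label_all_edges()] (carries the bonds).
#' @return a [fatgraph()], with attribute `block_units` mapping block index
#'   to original unit index.
#' @export
build_fatgraph <- function(chain, labels) {
  uids <- unit_ids(chain)
  seg <- vapply(chain$units[uids], `[[`, integer(1), "segment")
  block_of <- stats::setNames(seq_along(uids), uids)
  lk <- labels$linkages
  # backbone twists in block order: linkage (k, k+1) -> blocks (i, i+1)
  tw <- integer()
  for (i in seq_len(length(uids) - 1L)) {
    if (seg[i] != seg[i + 1L]) next
    row <- which(lk$from == uids[i])
    if (!length(row))
      stop("missing twist label for linkage at unit ", uids[i])
    tw <- c(tw, lk$twist[row])
  }
  bonds <- labels$bonds
  bd <- if (nrow(bonds))
    data.frame(donor = as.integer(block_of[as.character(bonds$donor)]),
               acceptor = as.integer(block_of[as.character(bonds$acceptor)]),
               twist = bonds$twist) else NULL
  g <- fatgraph(tw, bonds = bd, n_blocks = length(uids),
                segment = match(seg, unique(seg)))
  attr(g, "block_units") <- uids
  g
}

#' Write flip sequences as FASTA-like records
#'
#' @param flips named character vector of U/T strings (names are domain ids).
#' @param path output file.
#' @export
write_flips <- function(flips, path) {
  x <- Biostrings::BStringSet(flips)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read flip sequences from a FASTA-like file
#'
#' @param path file written by [write_flips()] (">id" header + U/T string).
#' @return named character vector.
#' @export
read_flips <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), names(x))
}
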