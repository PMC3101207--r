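# Flip-sequence (and amino-acid-sequence) similarity scoring and
# nearest-level classification with sensitivity-calibrated thresholding.

#' Smith-Waterman local alignment score
#'
#' Best local alignment score under a linear gap penalty.  For two-letter
#' flip sequences the default scheme is match +1, mismatch -1, gap -1; for
#' amino-acid sequences pass a substitution matrix (see
#' [substitution_matrix()]).
#'
#' @param a,b sequences as character strings.
#' @param match,mismatch,gap scoring parameters (used when `matrix` is NULL).
#' @param matrix optional named substitution matrix (rows/columns are
#'   residue letters).
#' @return numeric best local score (0 for an empty sequence).
#' @export
sw_score <- function(a, b, match = 1, mismatch = -1, gap = -1,
                     matrix = NULL) {
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  m <- length(av); n <- length(bv)
  if (m == 0L || n == 0L) return(0)
  sub <- if (!is.null(matrix)) {
    if (!all(av %in% rownames(matrix)) || !all(bv %in% colnames(matrix)))
      stop("sequence letter not covered by the substitution matrix")
    matrix[av, bv, drop = FALSE]
  } else outer(av, bv, function(x, y) ifelse(x == y, match, mismatch))
  best <- 0
  prev <- numeric(n + 1L)
  for (i in seq_len(m)) {
    cur <- numeric(n + 1L)
    for (j in seq_len(n)) {
      cur[j + 1L] <- max(0, prev[j] + sub[i, j], prev[j + 1L] + gap,
                         cur[j] + gap)
    }
    best <- max(best, max(cur))
    prev <- cur
  }
  best
}

#' Load a substitution matrix by name or from a file
#'
#' Names resolve to the matrices shipped with Biostrings (BLOSUM45, BLOSUM50,
#' BLOSUM62, BLOSUM80, BLOSUM100, PAM30...PAM250); a path is read as a
#' whitespace-separated labelled matrix in the standard NCBI layout.
#'
#' @param name matrix name or file path.
#' @return numeric matrix with residue row/column names.
#' @export
substitution_matrix <- function(name) {
  if (file.exists(name)) {
    m <- as.matrix(utils::read.table(name, check.names = FALSE))
    storage.mode(m) <- "numeric"
    return(m)
  }
  e <- new.env()
  ok <- tryCatch({
    utils::data(list = name, package = "Biostrings", envir = e)
    TRUE
  }, warning = function(w) FALSE)
  if (!ok || !exists(name, envir = e))
    stop("unknown substitution matrix: ", name)
  get(name, envir = e)
}

#' Length-normalized alignment score
#'
#' S(a, b) / sqrt(S(a, a) * S(b, b)): equal to 1 for self-comparison,
#' symmetric, and in [0, 1] under match-maximal scoring, making sequences of
#' different lengths comparable.
#'
#' @inheritParams sw_score
#' @return numeric in [0, 1] (0 when either self-score is non-positive,
#'   e.g. for an empty sequence).
#' @export
normalized_score <- function(a, b, match = 1, mismatch = -1, gap = -1,
                             matrix = NULL) {
  saa <- sw_score(a, a, match, mismatch, gap, matrix)
  sbb <- sw_score(b, b, match, mismatch, gap, matrix)
  if (saa <= 0 || sbb <= 0) return(0)
  sw_score(a, b, match, mismatch, gap, matrix) / sqrt(saa * sbb)
}

#' Similarity of a domain to a classification level
#'
#' The similarity between a domain and a level (a set of member domains) is
#' the maximum normalized alignment score over the level's members
#' (nearest-member rule).
#'
#' @param d query sequence (character string).
#' @param members character vector of member sequences.
#' @inheritParams sw_score
#' @return numeric similarity (error when the level is empty).
#' @export
level_similarity <- function(d, members, match = 1, mismatch = -1, gap = -1,
                             matrix = NULL) {
  if (!length(members)) stop("empty level")
  max(vapply(members, function(s)
    normalized_score(d, s, match, mismatch, gap, matrix), numeric(1)))
}

#' Nearest and second-nearest levels of a domain
#'
#' Computes the domain's similarity to every level of a labelled training
#' partition and returns the top two.  When `self` names a training entry,
#' that entry is excluded from its own level's members; levels left empty by
#' the exclusion are skipped.  Levels with a single member can still act as
#' nearest level for other domains, but a domain that is its level's only
#' member cannot be matched to its own level.
#'
#' @param d query sequence.
#' @param seqs named character vector of training sequences.
#' @param labels level label per training sequence.
#' @param self optional name of `d` within `seqs` to exclude.
#' @inheritParams sw_score
#' @return list with `s1`, `s2`, `level1`, `level2`.
#' @export
nearest_levels <- function(d, seqs, labels, self = NULL, match = 1,
                           mismatch = -1, gap = -1, matrix = NULL) {
  stopifnot(length(seqs) == length(labels))
  keep <- rep(TRUE, length(seqs))
  if (!is.null(self) && !is.null(names(seqs)))
    keep <- names(seqs) != self
  seqs <- seqs[keep]; labels <- labels[keep]
  lv <- split(seqs, labels)
  lv <- lv[lengths(lv) > 0L]
  if (length(lv) < 2L)
    stop("need at least two candidate levels to classify")
  sims <- vapply(lv, function(ms)
    level_similarity(d, ms, match, mismatch, gap, matrix), numeric(1))
  ord <- order(-sims)
  list(s1 = sims[[ord[1L]]], s2 = sims[[ord[2L]]],
       level1 = names(lv)[ord[1L]], level2 = names(lv)[ord[2L]])
}

#' Standardized nearest-level margin (lambda score)
#'
#' The margin x = s1 - s2 between a domain's similarity to its nearest and
#' second-nearest levels, z-standardized with the mean and standard
#' deviation of the margins over a calibration (training) set.
#'
#' @param s1,s2 nearest and second-nearest level similarities.
#' @param calibration numeric vector of training margins x = s1 - s2.
#' @return numeric lambda.
#' @export
lambda_score <- function(s1, s2, calibration) {
  if (length(calibration) < 2L) stop("calibration set too small")
  s <- stats::sd(calibration)
  if (s == 0) stop("calibration margins have zero variance")
  ((s1 - s2) - mean(calibration)) / s
}

#' Calibrate a decision threshold at a target sensitivity
#'
#' Returns the largest threshold such that the fraction of correctly
#' labelled domains with lambda at or above it is at least the target
#' sensitivity.  Domains scoring at or above the threshold are assigned
#' their nearest level; domains below it are flagged as novel/problematic.
#'
#' @param lambda numeric lambda scores.
#' @param correct logical: whether each domain's nearest level is its true
#'   level.
#' @param target target sensitivity in [0, 1] (default 0.95).
#' @return numeric threshold, with attribute `sensitivity` giving the
#'   achieved training sensitivity.
#' @export
calibrate_threshold <- function(lambda, correct, target = 0.95) {
  stopifnot(length(lambda) == length(correct))
  lc <- sort(lambda[correct])
  n_c <- length(lc)
  if (n_c == 0L) stop("no correctly labelled domains to calibrate on")
  # drop the largest count of low-lambda correct domains compatible with the
  # target; at least one correct domain always stays above threshold
  drop <- min(floor(n_c * (1 - target)), n_c - 1L)
  thr <- lc[drop + 1L]
  structure(thr, sensitivity = mean(lambda[correct] >= thr))
}

#' Majority-rule combination of classification methods
#'
#' Combines the per-method predictions for one domain: the majority label
#' wins; when all methods disagree, the method with the highest lambda
#' decides.  The combined lambda is the maximum lambda among the agreeing
#' methods (the overall maximum when all disagree).  Ties are broken by
#' method order.
#'
#' @param labels character vector of per-method predicted labels.
#' @param lambdas numeric vector of per-method lambda scores.
#' @return list with `label` and `lambda`.
#' @export
combined_classify <- function(labels, lambdas) {
  stopifnot(length(labels) == length(lambdas), length(labels) >= 1L)
  tab <- table(factor(labels, levels = unique(labels)))  # ties: method order
  top <- names(tab)[which.max(tab)]
  if (max(tab) > 1L) {
    agree <- labels == top
    list(label = top, lambda = max(lambdas[agree]))
  } else {
    pick <- which.max(lambdas)
    list(label = labels[pick], lambda = max(lambdas))
  }
}

#' Nearest-level classification of query domains
#'
#' End-to-end classifier over one sequence representation (flip sequences or
#' amino-acid sequences): leave-self-out nearest/second-nearest level
#' similarities over the training set calibrate the lambda standardization
#' and the sensitivity threshold; each query is then assigned its nearest
#' level with a lambda score and an above-threshold flag.
#'
#' @param query named character vector of query sequences.
#' @param train named character vector of training sequences.
#' @param labels level label per training sequence.
#' @param sensitivity target training sensitivity for the threshold.
#' @inheritParams sw_score
#' @return `data.frame`: `query_id`, `predicted_level`, `s1`, `s2`,
#'   `lambda`, `above_threshold`; attributes `threshold` and `calibration`.
#' @export
classify_domains <- function(query, train, labels, sensitivity = 0.95,
                             match = 1, mismatch = -1, gap = -1,
                             matrix = NULL) {
  stopifnot(length(train) == length(labels))
  if (is.null(names(train))) names(train) <- paste0("t", seq_along(train))
  tr <- lapply(seq_along(train), function(i)
    nearest_levels(train[[i]], train, labels, self = names(train)[i],
                   match = match, mismatch = mismatch, gap = gap,
                   matrix = matrix))
  xs <- vapply(tr, function(z) z$s1 - z$s2, numeric(1))
  lam_tr <- vapply(tr, function(z) lambda_score(z$s1, z$s2, xs), numeric(1))
  corr_tr <- vapply(seq_along(tr), function(i)
    tr[[i]]$level1 == labels[i], logical(1))
  thr <- calibrate_threshold(lam_tr, corr_tr, sensitivity)
  if (is.null(names(query))) names(query) <- paste0("q", seq_along(query))
  rows <- lapply(seq_along(query), function(i) {
    z <- nearest_levels(query[[i]], train, labels, self = names(query)[i],
                        match = match, mismatch = mismatch, gap = gap,
                        matrix = matrix)
    lam <- lambda_score(z$s1, z$s2, xs)
    data.frame(query_id = names(query)[i], predicted_level = z$level1,
               s1 = z$s1, s2 = z$s2, lambda = lam,
               above_threshold = lam >= as.numeric(thr))
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- as.numeric(thr)
  attr(out, "calibration") <- xs
  out
}
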