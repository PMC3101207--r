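test_that("local alignment scores match trivial cases and the oracle", {
  expect_equal(sw_score("UTTU", "UTTU"), 4)     # self: n * match
  expect_equal(sw_score("UUTT", ""), 0)
  expect_equal(sw_score("", "T"), 0)
  expect_equal(sw_score("UUTT", "UTT"), sw_oracle("UUTT", "UTT"))
  # every pair of flip strings up to length 4 (full length-6 sweep is the
  # acceptance suite's job)
  strs <- all_flip_strings(1, 4)
  for (a in strs) for (b in strs)
    expect_identical(sw_score(a, b), sw_oracle(a, b))
})

test_that("local alignment agrees with Biostrings on random sequences", {
  set.seed(61)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                     mismatch = -1)
  for (i in 1:25) {
    a <- paste(sample(c("A", "C"), sample(3:40, 1), replace = TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C"), sample(3:40, 1), replace = TRUE),
               collapse = "")
    ref <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                         Biostrings::DNAString(b),
                                         type = "local",
                                         substitutionMatrix = submat,
                                         gapOpening = 0, gapExtension = 1)
    expect_equal(sw_score(a, b), Biostrings::score(ref))
  }
})

test_that("substitution-matrix mode scores amino-acid sequences", {
  bl <- substitution_matrix("BLOSUM62")
  expect_equal(sw_score("WW", "WW", matrix = bl), 2 * bl["W", "W"])
  expect_gt(sw_score("HEAGAWGHEE", "PAWHEAE", matrix = bl), 0)
  expect_error(substitution_matrix("NOT_A_MATRIX"), "unknown")
})

test_that("normalized scores are 1 on self, symmetric and bounded by 1", {
  strs <- all_flip_strings(1, 5)
  set.seed(3)
  pick <- sample(strs, 25)
  for (a in pick) expect_equal(normalized_score(a, a), 1)
  for (i in 1:40) {
    a <- sample(strs, 1); b <- sample(strs, 1)
    ab <- normalized_score(a, b)
    expect_identical(ab, normalized_score(b, a))
    expect_gte(ab, 0); expect_lte(ab, 1)
  }
  expect_equal(normalized_score("", "UT"), 0)
})

test_that("level similarity is a monotone nearest-member rule", {
  expect_error(level_similarity("UT", character()), "empty level")
  expect_equal(level_similarity("UTTU", c("TTTT", "UTTU")), 1)
  s1 <- level_similarity("UUTT", c("TTTT"))
  s2 <- level_similarity("UUTT", c("TTTT", "UTTT"))
  expect_gte(s2, s1)                    # adding a member never decreases
})

test_that("nearest levels match hand enumeration on a two-level toy set", {
  seqs <- c(h1 = "UUUUUU", h2 = "UUUUTU", s1 = "TTTTTT", s2 = "TTUTTT")
  labels <- c("helix", "helix", "sheet", "sheet")
  z <- nearest_levels("UUUUUT", seqs, labels)
  by_hand <- vapply(seqs, function(s) normalized_score("UUUUUT", s),
                    numeric(1))
  expect_equal(z$level1, "helix")
  expect_equal(z$s1, max(by_hand[1:2]))
  expect_equal(z$s2, max(by_hand[3:4]))
  # the domain itself is excluded from its own level
  z2 <- nearest_levels("UUUUUU", seqs, labels, self = "h1")
  expect_equal(z2$s1, normalized_score("UUUUUU", "UUUUTU"))
  # fewer than two candidate levels cannot be classified
  expect_error(nearest_levels("UU", seqs[1:2], labels[1:2]), "two candidate")
})

test_that("lambda standardization has the stated analytic behaviour", {
  x <- c(0.1, 0.25, 0.3, 0.4, 0.15)
  expect_equal(lambda_score(0.5, 0.5 - mean(x), x), 0)
  lam <- lambda_score(0.6, 0.2, x)
  expect_equal(lam, (0.4 - mean(x)) / sd(x))
  # affine invariance under shared rescaling of the margins
  k <- 3.7
  expect_equal(lambda_score(k * 0.6, k * 0.2, k * x), lam)
  expect_error(lambda_score(0.5, 0.3, rep(0.2, 5)), "zero variance")
})

test_that("threshold calibration hits the target sensitivity maximally", {
  set.seed(404)
  lam <- c(rnorm(700, 2, 1), rnorm(300, -1, 1))
  correct <- rep(c(TRUE, FALSE), c(700, 300))
  thr <- calibrate_threshold(lam, correct, 0.95)
  sens <- mean(lam[correct] >= as.numeric(thr))
  expect_gte(sens, 0.95)
  # maximality: any higher threshold breaks the target
  expect_lt(mean(lam[correct] >= as.numeric(thr) + 1e-9), 0.95)
  # boundary targets: target 1 keeps every correct domain above threshold;
  # target 0 is vacuous (no threshold can break it) and stays finite
  thr1 <- calibrate_threshold(lam, correct, 1)
  expect_lte(as.numeric(thr1), min(lam[correct]))
  expect_equal(attr(thr1, "sensitivity"), 1)
  thr0 <- calibrate_threshold(lam, correct, 0)
  expect_true(is.finite(as.numeric(thr0)))
  expect_gte(attr(thr0, "sensitivity"), 0)
  expect_error(calibrate_threshold(lam, rep(FALSE, 1000), 0.95),
               "no correctly labelled")
})

test_that("majority-rule combination follows the stated decision rules", {
  # two of three agree: majority label, lambda = max among agreeing
  z <- combined_classify(c("A", "B", "A"), c(0.5, 9, 2))
  expect_equal(z$label, "A"); expect_equal(z$lambda, 2)
  # all agree
  z <- combined_classify(c("A", "A", "A"), c(1, 3, 2))
  expect_equal(z$label, "A"); expect_equal(z$lambda, 3)
  # all disagree: highest lambda decides, lambda = overall max
  z <- combined_classify(c("A", "B", "C"), c(1, 5, 2))
  expect_equal(z$label, "B"); expect_equal(z$lambda, 5)
  # lambda ties broken by method order
  z <- combined_classify(c("A", "B", "C"), c(5, 5, 1))
  expect_equal(z$label, "A")
  # never returns a label no method proposed
  set.seed(12)
  for (i in 1:50) {
    labs <- sample(LETTERS[1:3], 3, replace = TRUE)
    z <- combined_classify(labs, rnorm(3))
    expect_true(z$label %in% labs)
  }
})

test_that("the end-to-end classifier assigns obvious queries correctly", {
  set.seed(77)
  mutate <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    j <- sample(length(v), k)
    v[j] <- ifelse(v[j] == "U", "T", "U")
    paste(v, collapse = "")
  }
  base <- c(helix = strrep("U", 30), sheet = strrep("T", 30),
            mix = strrep("UT", 15))
  train <- c(); labels <- c()
  for (lv in names(base)) for (i in 1:4) {
    train <- c(train, stats::setNames(mutate(base[[lv]], 3),
                                      paste0(lv, i)))
    labels <- c(labels, lv)
  }
  res <- classify_domains(c(q1 = mutate(base[["helix"]], 2),
                            q2 = mutate(base[["sheet"]], 2)),
                          train, labels, sensitivity = 0.9)
  expect_equal(res$predicted_level, c("helix", "sheet"))
  expect_true(all(res$s1 >= res$s2))
  expect_true(all(res$predicted_level %in% labels))
})
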