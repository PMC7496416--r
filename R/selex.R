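# Tandem stem-loop motif detection and a seeded SELEX round simulator.
# The motif model comes from the selection consensus: two consecutive
# hairpins, each closed by a C:G pair at the top of the stem, with a
# hexanucleotide terminal loop preferring A at position 1 and G at
# position 4.

.encodeRNA <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  if (any(chars == "T")) {
    warning("converted T to U in RNA sequence")
    chars[chars == "T"] <- "U"
  }
  bad <- setdiff(unique(chars), RNA4)
  if (length(bad))
    stop("non-ACGU character(s) in sequence: ", paste(bad, collapse = ", "))
  chars
}

# Enumerate every legal hairpin (stem fully paired under Watson-Crick +
# G:U wobble, loop of exactly loopLen) and score it:
#   stem_len + 2*[closing pair is C:G] + 1*[loop pos1 == A] + 1*[loop pos4 == G]
# The closing pair is the innermost stem pair, written 5':3'; the C:G test
# is strand-specific (C on the 5' side).
.enumerateHairpins <- function(chars, minStem, maxStem, loopLen) {
  n <- length(chars)
  hits <- list()
  for (L in minStem:maxStem) {
    span <- 2L * L + loopLen
    if (span > n) next
    for (i in seq_len(n - span + 1L)) {
      s1 <- chars[i:(i + L - 1L)]
      s2 <- chars[(i + L + loopLen):(i + span - 1L)]
      paired <- TRUE
      for (k in seq_len(L)) {
        if (!.rnaPairs[s1[k], s2[L + 1L - k]]) { paired <- FALSE; break }
      }
      if (!paired) next
      loop <- chars[(i + L):(i + L + loopLen - 1L)]
      closing <- paste0(s1[L], ":", s2[1L])
      score <- L + 2 * (s1[L] == "C" && s2[1L] == "G") +
        (loop[1L] == "A") + (loopLen >= 4L && loop[4L] == "G")
      hits[[length(hits) + 1L]] <- list(
        start = i, end = i + span - 1L, stem_len = L,
        loop = paste(loop, collapse = ""), closing_pair = closing,
        score = score)
    }
  }
  hits
}

#' Find the best tandem two-hairpin motif in an RNA sequence
#'
#' Exhaustively scans all stem positions and lengths (Watson-Crick plus
#' G:U wobble pairing, loop fixed at \code{loopLen}) and returns the
#' highest-scoring pair of non-overlapping hairpins separated by at most
#' \code{maxSpacer} nucleotides, or \code{NULL} when no such pair exists.
#' A single hairpin never qualifies: the motif is defined as tandem.
#'
#' @param seq RNA string over A/C/G/U (T accepted with a warning).
#' @param minStem,maxStem allowed stem lengths in base pairs.
#' @param loopLen terminal loop length (default 6, the consensus
#'   hexaloop).
#' @param maxSpacer maximum nucleotides between the hairpins.
#' @return a \code{\linkS4class{MotifCall}} or \code{NULL}
#' @examples
#' foldTandemHairpins("GGACAUCGCCGUCCAAAGGACAUCGCCGUCC")
#' @export
foldTandemHairpins <- function(seq, minStem = 3, maxStem = 7, loopLen = 6,
                               maxSpacer = 10) {
  chars <- .encodeRNA(seq)
  if (length(chars) < 2L * (2L * minStem + loopLen)) return(NULL)
  hits <- .enumerateHairpins(chars, minStem, maxStem, loopLen)
  if (length(hits) < 2L) return(NULL)
  starts <- vapply(hits, `[[`, 0, "start")
  ends <- vapply(hits, `[[`, 0, "end")
  scores <- vapply(hits, `[[`, 0, "score")
  best <- NULL
  bestScore <- -Inf
  ord <- order(starts, ends)
  for (ii in ord) {
    for (jj in ord) {
      spacer <- starts[jj] - ends[ii] - 1L
      if (spacer < 0L || spacer > maxSpacer) next
      tot <- scores[ii] + scores[jj]
      if (tot > bestScore) {
        bestScore <- tot
        best <- c(ii, jj)
      }
    }
  }
  if (is.null(best)) return(NULL)
  h1 <- hits[[best[1L]]]; h2 <- hits[[best[2L]]]
  canonicalLoop <- function(h) {
    l <- strsplit(h$loop, "")[[1]]
    l[1L] == "A" || (length(l) >= 4L && l[4L] == "G")
  }
  new("MotifCall", hit1 = h1, hit2 = h2,
      spacerLen = as.integer(h2$start - h1$end - 1L),
      totalScore = bestScore,
      isCanonical = h1$closing_pair == "C:G" &&
        h2$closing_pair == "C:G" &&
        canonicalLoop(h1) && canonicalLoop(h2))
}

#' Tandem-motif score of a sequence
#'
#' Convenience wrapper: total score of the best \code{MotifCall}, or 0 when
#' the sequence folds no tandem motif.
#'
#' @inheritParams foldTandemHairpins
#' @return numeric score
#' @export
tandemMotifScore <- function(seq, minStem = 3, maxStem = 7, loopLen = 6,
                             maxSpacer = 10) {
  mc <- foldTandemHairpins(seq, minStem, maxStem, loopLen, maxSpacer)
  if (is.null(mc)) 0 else mc@totalScore
}

#' Simulate rounds of in-vitro selection on a random RNA pool
#'
#' Round 0 is a pool of random \code{seqLen}-mers (optionally spiked with a
#' planted motif-bearing sequence at a chosen starting frequency). Each
#' subsequent round retains every molecule independently with probability
#' proportional to \eqn{\epsilon + (1-\epsilon)\,
#' \mathrm{logistic}(\beta(s - s_0))}, where \eqn{s} is the sequence's
#' tandem-motif score, then restores the pool size by resampling with
#' replacement (the amplification analogue). \code{beta = 0} or
#' \code{epsilon = 1} gives neutral rounds. Fully seeded and reproducible.
#'
#' @param poolSize molecules per round.
#' @param seqLen length of the random sequences (nt).
#' @param rounds number of selection rounds after round 0.
#' @param beta selection strength (logistic slope on motif score).
#' @param epsilon background retention floor in (0, 1]: nonspecific
#'   carryover on the matrix.
#' @param s0 score pivot of the logistic (default 8, half the total score
#'   of a canonical planted tandem motif).
#' @param seed integer RNG seed.
#' @param plantedMotif optional sequence to spike into round 0.
#' @param plantedFrequency fraction of round 0 occupied by the planted
#'   sequence.
#' @return a \code{\linkS4class{SelexExperiment}}
#' @export
simulateSelex <- function(poolSize = 1000, seqLen = 30, rounds = 4,
                          beta = 2, epsilon = 0.1, s0 = 8, seed = 1,
                          plantedMotif = NULL, plantedFrequency = 0) {
  stopifnot(beta >= 0, epsilon > 0, epsilon <= 1,
            plantedFrequency >= 0, plantedFrequency <= 1)
  rng <- .seededRNG(seed)
  nPlant <- round(poolSize * plantedFrequency)
  if (nPlant > 0L && is.null(plantedMotif))
    stop("plantedFrequency > 0 requires a plantedMotif sequence")
  nRandom <- poolSize - nPlant
  randomSeqs <- vapply(seq_len(nRandom), function(i)
    paste(sample(RNA4, seqLen, replace = TRUE), collapse = ""), "")
  pool0 <- c(randomSeqs, rep(if (nPlant) plantedMotif else character(0),
                             nPlant))
  tab0 <- table(pool0)
  uniq <- names(tab0)
  scores <- vapply(uniq, tandemMotifScore, 0)
  current <- data.frame(sequence = uniq, count = as.integer(tab0),
                        stringsAsFactors = FALSE)
  roundsList <- vector("list", rounds + 1L)
  roundsList[[1L]] <- current
  for (r in seq_len(rounds)) {
    p <- epsilon + (1 - epsilon) *
      stats::plogis(beta * (scores[current$sequence] - s0))
    retained <- stats::rbinom(nrow(current), current$count, p)
    if (sum(retained) == 0L) retained <- current$count  # selection wiped pool
    amp <- stats::rmultinom(1L, poolSize, retained)[, 1L]
    keep <- amp > 0L
    current <- data.frame(sequence = current$sequence[keep],
                          count = as.integer(amp[keep]),
                          stringsAsFactors = FALSE)
    roundsList[[r + 1L]] <- current
  }
  rng$restore()
  new("SelexExperiment", rounds = roundsList, scores = scores,
      params = list(pool_size = poolSize, seq_len = seqLen,
                    rounds = rounds, beta = beta, epsilon = epsilon,
                    s0 = s0, seed = seed, planted_motif = plantedMotif,
                    planted_frequency = plantedFrequency))
}

#' Round-over-round enrichment of motif-positive sequences
#'
#' Frequency of motif-positive molecules (tandem-motif score > 0) in each
#' round, plus per-sequence records for the most abundant final-round
#' sequences. Fold changes are pseudocounted with half a molecule so that
#' features absent from a round stay finite.
#'
#' @param exp a \code{\linkS4class{SelexExperiment}}
#' @param topSequences number of individual final-round sequences to track
#' @return data.frame: feature, one freq_round_r column per round,
#'   fold_change
#' @export
enrichmentTable <- function(exp, topSequences = 5) {
  rounds <- selexRounds(exp)
  if (length(rounds) < 2L) stop("need at least 2 rounds")
  scores <- motifScores(exp)
  poolSizes <- vapply(rounds, function(r) sum(r$count), 0)
  pc <- 0.5 / poolSizes[1L]
  motifFreq <- vapply(rounds, function(r)
    sum(r$count[scores[r$sequence] > 0]) / sum(r$count), 0)
  final <- rounds[[length(rounds)]]
  final <- final[order(-final$count), , drop = FALSE]
  feats <- utils::head(final$sequence, topSequences)
  seqFreq <- t(vapply(feats, function(s)
    vapply(rounds, function(r) {
      hit <- r$count[r$sequence == s]
      if (length(hit)) hit / sum(r$count) else 0
    }, 0), numeric(length(rounds))))
  freqs <- rbind(motifFreq, seqFreq)
  out <- data.frame(feature = c("motif_positive", feats),
                    freqs, stringsAsFactors = FALSE, row.names = NULL)
  names(out)[-1L] <- paste0("freq_round_", seq_along(rounds) - 1L)
  out$fold_change <- (freqs[, ncol(freqs)] + pc) / (freqs[, 1L] + pc)
  out
}

#' Consensus logo of the selected motif
#'
#' Aligns the closing pair and loop positions of the tandem-motif calls in
#' one round (weighted by molecule counts) and scores each position's
#' relative entropy against a uniform 4-letter background, in bits. The 16
#' positions are the 5' closing base, the six loop positions and the 3'
#' closing base of each hairpin. A round with no motif calls yields an
#' empty (0-row) matrix, not an error.
#'
#' @param exp a \code{\linkS4class{SelexExperiment}}
#' @param round round to summarise (default: final round)
#' @param pseudocount additive pseudocount on base counts
#' @return list with \code{heights} (positions x 4 letter-height matrix),
#'   \code{ic_bits}, and \code{n_calls} (motif-bearing molecules used)
#' @export
consensusLogo <- function(exp, round = length(selexRounds(exp)),
                          pseudocount = 0.5) {
  pool <- selexRounds(exp)[[round]]
  positions <- c(paste0("h1_", c("close5", paste0("loop", 1:6), "close3")),
                 paste0("h2_", c("close5", paste0("loop", 1:6), "close3")))
  counts <- matrix(0, length(positions), 4L,
                   dimnames = list(positions, RNA4))
  nCalls <- 0L
  for (i in seq_len(nrow(pool))) {
    mc <- foldTandemHairpins(pool$sequence[i])
    if (is.null(mc)) next
    w <- pool$count[i]
    nCalls <- nCalls + w
    for (h in 1:2) {
      hit <- if (h == 1L) mc@hit1 else mc@hit2
      close <- strsplit(hit$closing_pair, ":")[[1]]
      lp <- strsplit(hit$loop, "")[[1]]
      basePos <- (h - 1L) * 8L
      letters <- c(close[1L], lp, close[2L])
      for (k in seq_along(letters))
        counts[basePos + k, letters[k]] <-
          counts[basePos + k, letters[k]] + w
    }
  }
  if (nCalls == 0L)
    return(list(heights = counts[0L, , drop = FALSE],
                ic_bits = numeric(0), n_calls = 0L))
  freqs <- (counts + pseudocount) / (rowSums(counts) + 4 * pseudocount)
  q <- matrix(0.25, nrow(freqs), 4L)
  ic <- klBits(freqs, q)
  heights <- .letterHeights(freqs, q, ic)
  dimnames(heights) <- dimnames(counts)
  list(heights = heights, ic_bits = setNames(ic, positions),
       n_calls = nCalls)
}
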