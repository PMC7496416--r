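# Per-column conservation scoring: frequency profiles, relative entropy
# against a background, group-vs-rest differential KL divergence, the
# conserved-position caller and compositional-bias deltas.

#' Per-column amino-acid frequency profiles
#'
#' Counts residues per alignment column and converts them to pseudocounted
#' frequencies \eqn{(c_a + \alpha) / (n_{eff} + 20\alpha)}. Gaps never enter
#' the frequency denominator; they are reported separately as the per-column
#' gap fraction.
#'
#' @param aln a \code{\linkS4class{LabeledAlignment}}
#' @param pseudocount additive pseudocount \eqn{\alpha \ge 0}; default 0.5
#'   (Jeffreys-like).
#' @param subset optional character vector of architecture tags; only
#'   sequences carrying one of these tags are profiled. At least two
#'   sequences must match.
#' @return a \code{\linkS4class{PositionProfiles}}
#' @examples
#' aln <- LabeledAlignment(c(s1 = "AK", s2 = "AR", s3 = "A-"))
#' profileFreqs(columnProfiles(aln, pseudocount = 0))
#' @export
columnProfiles <- function(aln, pseudocount = 0.5, subset = NULL) {
  stopifnot(pseudocount >= 0)
  seqs <- alignmentSequences(aln)
  if (!is.null(subset)) {
    keep <- architectureLabels(aln) %in% subset
    if (sum(keep) < 2L)
      stop("subset (", paste(subset, collapse = ", "), ") matches ",
           sum(keep), " sequence(s); need at least 2")
    seqs <- seqs[keep]
  }
  mat <- do.call(rbind, strsplit(unname(seqs), ""))
  nseq <- nrow(mat)
  ncol_ <- ncol(mat)
  counts <- t(apply(mat, 2L, function(col)
    tabulate(factor(col, levels = AA20), nbins = 20L)))
  dimnames(counts) <- list(NULL, AA20)
  neff <- rowSums(counts)
  gapf <- 1 - neff / nseq
  freqs <- (counts + pseudocount) / (neff + 20 * pseudocount)
  # all-gap column with alpha = 0 has no defined distribution; use uniform
  if (pseudocount == 0 && any(neff == 0))
    freqs[neff == 0, ] <- 1 / 20
  new("PositionProfiles", freqs = freqs, counts = counts,
      gapFraction = gapf, nEffective = as.numeric(neff),
      pseudocount = pseudocount)
}

#' Kullback-Leibler divergence in bits
#'
#' \eqn{D(p \| q) = \sum_a p(a) \log_2(p(a)/q(a))}; terms with
#' \eqn{p(a) = 0} contribute zero. Vectorised over the rows of matrix
#' inputs.
#'
#' @param p,q probability vectors (or matrices of row distributions) over
#'   the same alphabet; \code{q} strictly positive wherever \code{p > 0}.
#' @return numeric divergence(s), non-negative
#' @export
klBits <- function(p, q) {
  if (is.matrix(p)) {
    if (!is.matrix(q)) q <- matrix(q, nrow(p), length(q), byrow = TRUE)
    term <- p * log2(p / q)
    term[p == 0] <- 0
    rowSums(term)
  } else {
    term <- p * log2(p / q)
    term[p == 0] <- 0
    sum(term)
  }
}

.backgroundFreqs <- function(background, profiles = NULL) {
  if (is.numeric(background)) {
    stopifnot(length(background) == 20L, all(background > 0))
    return(background / sum(background))
  }
  switch(match.arg(background, c("uniform", "average")),
    uniform = rep(1 / 20, 20L),
    average = {
      tot <- colSums(profileCounts(profiles)) + 1e-9
      tot / sum(tot)
    })
}

# Per-letter terms p*log2(p/q) clipped at zero and rescaled so the drawn
# letters sum to the column's total score (the logo convention used here:
# the column height is the divergence, letters show its positive part).
.letterHeights <- function(p, q, total) {
  term <- p * log2(p / q)
  term[p == 0] <- 0
  pos <- pmax(term, 0)
  ps <- rowSums(pos)
  scale <- ifelse(ps > 0, total / ps, 0)
  pos * scale
}

.scoresFromProfiles <- function(profiles, bits, heights, metric) {
  f <- profileFreqs(profiles)
  top <- apply(f, 1L, which.max)
  new("PositionScores",
      table = data.frame(column = seq_len(nrow(f)),
                         bits = bits,
                         top_residue = AA20[top],
                         top_freq = f[cbind(seq_len(nrow(f)), top)],
                         gap_fraction = gapFraction(profiles)),
      heights = heights, metric = metric)
}

#' Relative entropy of each column against a background
#'
#' The conservation score behind a classical sequence logo:
#' \eqn{IC_i = \sum_a p_i(a) \log_2(p_i(a)/q(a))} bits, with per-letter
#' heights allocated from the positive terms. With a uniform background the
#' score is bounded by \eqn{\log_2 20 \approx 4.32} bits, attained only by a
#' point mass.
#'
#' @param profiles a \code{\linkS4class{PositionProfiles}}
#' @param background \code{"uniform"}, \code{"average"} (alignment-wide
#'   residue composition), or a positive 20-vector.
#' @return a \code{\linkS4class{PositionScores}} with metric \code{"ic"}
#' @export
informationContent <- function(profiles, background = "uniform") {
  q <- .backgroundFreqs(background, profiles)
  f <- profileFreqs(profiles)
  qm <- matrix(q, nrow(f), 20L, byrow = TRUE)
  bits <- klBits(f, qm)
  h <- .letterHeights(f, qm, bits)
  colnames(h) <- AA20
  .scoresFromProfiles(profiles, bits, h, "ic")
}

#' Differential (group-versus-rest) KL divergence per column
#'
#' The differential-logo statistic: for each column, the KL divergence of
#' the group's residue distribution from the complement's,
#' \eqn{D_i = \sum_a p_{grp,i}(a)\log_2(p_{grp,i}(a)/p_{rest,i}(a))}.
#' The direction is group-to-rest; KL divergence is asymmetric and the two
#' directions agree only when the distributions coincide. Both profiles
#' must be pseudocounted so the denominator distribution is strictly
#' positive.
#'
#' @param pGroup profiles of the group of interest (e.g. sensor-fused
#'   architectures).
#' @param pRest profiles of the complement, same column space.
#' @return a \code{\linkS4class{PositionScores}} with metric \code{"dkl"}
#' @export
differentialKL <- function(pGroup, pRest) {
  fg <- profileFreqs(pGroup)
  fr <- profileFreqs(pRest)
  if (nrow(fg) != nrow(fr))
    stop("group and rest profiles cover different column counts")
  if (any(fr == 0))
    stop("rest profile contains zero frequencies; recompute the profiles ",
         "with pseudocount > 0")
  bits <- klBits(fg, fr)
  h <- .letterHeights(fg, fr, bits)
  colnames(h) <- AA20
  .scoresFromProfiles(pGroup, bits, h, "dkl")
}

#' Call conserved positions by identity or chemical class
#'
#' A column is called \code{single_residue} when one residue is present in
#' at least \code{identityThreshold} of sequences (default 40\%), computed
#' on raw un-pseudocounted frequencies because the rule is stated on
#' fractions of sequences. Failing that, it is called
#' \code{chemical_class} when one of the defined residue classes
#' (\code{\link{chemicalClasses}}) accounts for a majority
#' (\code{> classThreshold}); the class with the largest sum wins, ties
#' broken by table order. Columns with more than \code{maxGapFraction} gaps
#' are masked and never called: ragged alignment edges otherwise produce
#' spurious conservation.
#'
#' @param profiles a \code{\linkS4class{PositionProfiles}} of the full
#'   alignment
#' @param identityThreshold minimum single-residue frequency (default 0.40)
#' @param classThreshold class-sum threshold, strict (default 0.50)
#' @param maxGapFraction columns gappier than this are masked (default 0.5)
#' @return data.frame: column, call, top_residue, top_freq, class,
#'   class_freq, gap_fraction, masked
#' @export
conservedPositions <- function(profiles, identityThreshold = 0.40,
                               classThreshold = 0.50,
                               maxGapFraction = 0.5) {
  counts <- profileCounts(profiles)
  neff <- pmax(rowSums(counts), 1L)
  raw <- counts / neff
  gapf <- gapFraction(profiles)
  n <- nrow(raw)
  top <- apply(raw, 1L, which.max)
  topFreq <- raw[cbind(seq_len(n), top)]
  classSums <- vapply(chemicalClasses,
                      function(cls) rowSums(raw[, cls, drop = FALSE]),
                      numeric(n))
  if (is.null(dim(classSums))) classSums <- matrix(classSums, nrow = 1L)
  call <- rep("none", n)
  bestClass <- rep(NA_character_, n)
  bestClassFreq <- rep(NA_real_, n)
  masked <- gapf > maxGapFraction
  for (i in seq_len(n)) {
    if (masked[i]) { call[i] <- "masked"; next }
    if (topFreq[i] >= identityThreshold) {
      call[i] <- "single_residue"
    } else {
      passing <- which(classSums[i, ] > classThreshold)
      if (length(passing)) {
        j <- passing[which.max(classSums[i, passing])]
        call[i] <- "chemical_class"
        bestClass[i] <- names(chemicalClasses)[j]
        bestClassFreq[i] <- classSums[i, j]
      }
    }
  }
  data.frame(column = seq_len(n), call = call,
             top_residue = AA20[top], top_freq = topFreq,
             class = bestClass, class_freq = bestClassFreq,
             gap_fraction = gapf, masked = masked,
             stringsAsFactors = FALSE)
}

#' Compositional bias of a labeled group against the whole alignment
#'
#' For every (column, residue) pair, the difference between the residue's
#' raw frequency within the tagged group and in the entire alignment,
#' \eqn{\delta = f_{grp} - f_{all}}. Large positive deltas mark residues
#' over-represented in the group's architecture.
#'
#' @param aln a \code{\linkS4class{LabeledAlignment}}
#' @param groupTag architecture tag defining the group (at least 2 members;
#'   complement must be non-empty).
#' @return data.frame: column, residue, freq_in_group, freq_overall, delta
#' @export
compositionalBias <- function(aln, groupTag) {
  labs <- architectureLabels(aln)
  if (!groupTag %in% labs)
    stop("unknown group tag '", groupTag, "'; tags present: ",
         paste(sort(unique(labs)), collapse = ", "))
  if (sum(labs == groupTag) < 2L)
    stop("group '", groupTag, "' has fewer than 2 sequences")
  if (all(labs == groupTag))
    stop("group '", groupTag, "' covers the whole alignment; ",
         "no complement to compare against")
  pg <- columnProfiles(aln, pseudocount = 0, subset = groupTag)
  pa <- columnProfiles(aln, pseudocount = 0)
  fg <- profileCounts(pg) / pmax(rowSums(profileCounts(pg)), 1L)
  fa <- profileCounts(pa) / pmax(rowSums(profileCounts(pa)), 1L)
  n <- nrow(fg)
  data.frame(column = rep(seq_len(n), each = 20L),
             residue = rep(AA20, times = n),
             freq_in_group = as.vector(t(fg)),
             freq_overall = as.vector(t(fa)),
             delta = as.vector(t(fg - fa)),
             stringsAsFactors = FALSE)
}

#' Export letter heights as a logo matrix
#'
#' Columns-by-alphabet table of letter heights suitable for standard
#' logo-drawing tools; row sums equal the per-column score.
#'
#' @param scores a \code{\linkS4class{PositionScores}}
#' @param path optional TSV output file
#' @return data.frame with a \code{column} column followed by one column
#'   per letter
#' @export
logoMatrix <- function(scores, path = NULL) {
  h <- letterHeights(scores)
  out <- data.frame(column = scoreTable(scores)$column, h,
                    check.names = FALSE)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}
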