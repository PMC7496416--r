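#' @import methods
NULL

#' Labeled protein multiple sequence alignment
#'
#' Holds an alignment over the 20 amino acids plus gap, together with a
#' per-sequence architecture tag (for example \code{"NIT-ANTAR"} for
#' sensor-fused antiterminators versus \code{"other"}). Tags drive the
#' group-versus-rest differential conservation analysis.
#'
#' @slot sequences Named character vector; each element one aligned sequence
#'   (uppercase residues and \code{"-"} gaps), names are sequence ids.
#' @slot labels Named character vector parallel to \code{sequences}; one
#'   architecture tag per id. Ids absent from a user label map default to
#'   \code{"other"}.
#'
#' @export
setClass("LabeledAlignment",
  representation(sequences = "character", labels = "character"))

setValidity("LabeledAlignment", function(object) {
  s <- object@sequences
  if (length(s) == 0L) return("alignment has no sequences")
  if (is.null(names(s)) || any(!nzchar(names(s))))
    return("all sequences must be named")
  if (anyDuplicated(names(s)))
    return(paste0("duplicate sequence id: ",
                  names(s)[duplicated(names(s))][1L]))
  len <- nchar(s)
  if (length(unique(len)) > 1L) {
    bad <- names(s)[len != len[1L]][1L]
    return(paste0("ragged alignment: sequence '", bad,
                  "' has length ", nchar(s[bad]),
                  ", expected ", len[1L]))
  }
  letters <- unique(strsplit(paste(s, collapse = ""), "")[[1]])
  unknown <- setdiff(letters, c(AA20, "-"))
  if (length(unknown))
    return(paste0("unknown residue letter(s): ",
                  paste(unknown, collapse = ", ")))
  if (!identical(sort(names(object@labels)), sort(names(s))))
    return("labels must be a named vector covering exactly the sequence ids")
  TRUE
})

#' Atomic coordinate set
#'
#' Parsed ATOM records of a coordinate file. Author residue numbering is
#' authoritative and never renumbered, so residue identifiers such as R340
#' refer to the numbers in the source file.
#'
#' @slot atoms data.frame with columns \code{chain}, \code{resno},
#'   \code{resname} (3-letter code), \code{atom}, \code{x}, \code{y},
#'   \code{z} (Angstrom).
#'
#' @export
setClass("CoordinateSet", representation(atoms = "data.frame"))

setValidity("CoordinateSet", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "resname", "atom", "x", "y", "z")
  if (!all(need %in% names(a)))
    return(paste0("atoms must have columns: ", paste(need, collapse = ", ")))
  if (nrow(a) == 0L) return("coordinate set contains no atoms")
  if (anyDuplicated(a[, c("chain", "resno", "atom")]))
    return("duplicate (chain, residue number, atom name) record")
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("non-finite coordinates")
  TRUE
})

#' Domain selection on a coordinate set
#'
#' A named chain + residue-range selection (author numbering, inclusive)
#' identifying one domain for interface analysis.
#'
#' @slot name Character label used in messages and output.
#' @slot chain Chain identifier.
#' @slot ranges Two-column integer matrix (\code{start}, \code{end}),
#'   non-overlapping.
#'
#' @export
setClass("DomainSpec",
  representation(name = "character", chain = "character", ranges = "matrix"))

setValidity("DomainSpec", function(object) {
  r <- object@ranges
  if (ncol(r) != 2L || nrow(r) < 1L) return("ranges must be an n x 2 matrix")
  if (any(r[, 2] < r[, 1])) return("range end before start")
  o <- order(r[, 1])
  r <- r[o, , drop = FALSE]
  if (nrow(r) > 1L && any(r[-1L, 1] <= r[-nrow(r), 2]))
    return(paste0("overlapping ranges in domain '", object@name, "'"))
  TRUE
})

#' Per-column residue frequency profiles
#'
#' Pseudocounted per-column amino-acid distributions of an alignment (or a
#' labeled subset), the base object for conservation and differential
#' KL-divergence scoring. Gaps are excluded from the frequency denominator
#' and reported as a per-column gap fraction.
#'
#' @slot freqs numeric matrix, columns x 20 residues; rows sum to 1.
#' @slot counts integer matrix of raw (un-pseudocounted) residue counts.
#' @slot gapFraction numeric vector, gaps / total sequences per column.
#' @slot nEffective numeric vector of non-gap residue counts per column.
#' @slot pseudocount the additive pseudocount alpha used for \code{freqs}.
#'
#' @export
setClass("PositionProfiles",
  representation(freqs = "matrix", counts = "matrix",
                 gapFraction = "numeric", nEffective = "numeric",
                 pseudocount = "numeric"))

setValidity("PositionProfiles", function(object) {
  if (!identical(colnames(object@freqs), AA20))
    return("freqs columns must be the 20 amino acids in standard order")
  if (any(abs(rowSums(object@freqs) - 1) > 1e-9))
    return("frequency rows must sum to 1")
  if (any(object@counts < 0)) return("negative raw counts")
  if (any(object@gapFraction < 0 | object@gapFraction > 1))
    return("gapFraction outside [0, 1]")
  TRUE
})

#' Per-column conservation scores with letter heights
#'
#' Result of \code{\link{informationContent}} (relative entropy against a
#' background) or \code{\link{differentialKL}} (group-versus-rest KL
#' divergence). Carries the per-letter height matrix used for sequence-logo
#' rendering; positive per-letter terms are rescaled so each row of heights
#' sums to the column's total score.
#'
#' @slot table data.frame with columns \code{column}, \code{bits},
#'   \code{top_residue}, \code{top_freq}, \code{gap_fraction}.
#' @slot heights numeric matrix (columns x alphabet) of letter heights.
#' @slot metric \code{"ic"} (vs background) or \code{"dkl"} (group vs rest).
#'
#' @export
setClass("PositionScores",
  representation(table = "data.frame", heights = "matrix",
                 metric = "character"))

setValidity("PositionScores", function(object) {
  if (!object@metric %in% c("ic", "dkl")) return("metric must be ic or dkl")
  if (any(object@table$bits < -1e-12)) return("negative divergence")
  hs <- rowSums(object@heights)
  if (any(abs(hs - object@table$bits) > 1e-8))
    return("letter heights must sum to the column score")
  TRUE
})

#' Anisotropy titration curve
#'
#' Replicate fluorescence-anisotropy changes at a series of titrant
#' concentrations, relative to the zero-titrant reference. The x axis is
#' either protein-dimer concentration (binding mode) or ion concentration
#' (ion-response mode).
#'
#' @slot data data.frame with columns \code{x}, \code{replicate},
#'   \code{response}.
#' @slot condition free-text condition label.
#' @slot xUnit unit of the x axis (e.g. \code{"uM"}, \code{"mM"}).
#'
#' @export
setClass("BindingCurve",
  representation(data = "data.frame", condition = "character",
                 xUnit = "character"))

setValidity("BindingCurve", function(object) {
  d <- object@data
  if (!all(c("x", "replicate", "response") %in% names(d)))
    return("data must have columns x, replicate, response")
  if (nrow(d) == 0L) return("empty titration")
  if (any(d$x < 0)) return("negative concentration")
  xs <- sort(unique(d$x[d$x > 0]))
  if (length(xs) < 4L) return("need at least 4 distinct positive concentrations")
  TRUE
})

#' Hill-equation fit of a titration
#'
#' Parameters of the specific-binding Hill model
#' \eqn{\Delta A = B_{max} x^n / (K_d^n + x^n)} fitted by bounded nonlinear
#' least squares, or a refusal record when the curve shows no signal above
#' replicate noise.
#'
#' @slot kd half-saturation constant, units of the curve's x axis.
#' @slot hillN Hill coefficient.
#' @slot bmax amplitude (maximal anisotropy change).
#' @slot se named numeric vector of standard errors (kd, hillN, bmax).
#' @slot converged logical; FALSE when the optimizer failed or kd hit a bound.
#' @slot refused logical; TRUE when the fit was refused (signal below
#'   3x pooled replicate SD -- "no detectable binding").
#' @slot rss residual sum of squares.
#' @slot nObs number of data points fitted.
#' @slot condition condition label copied from the curve.
#'
#' @export
setClass("HillFit",
  representation(kd = "numeric", hillN = "numeric", bmax = "numeric",
                 se = "numeric", converged = "logical", refused = "logical",
                 rss = "numeric", nObs = "integer", condition = "character"))

#' Tandem two-hairpin motif call
#'
#' Best-scoring pair of non-overlapping stem-loops found in an RNA sequence.
#' Each hit records stem start, stem length, the hexanucleotide loop, the
#' closing base pair and the hairpin score.
#'
#' @slot hit1,hit2 lists with elements \code{start}, \code{end},
#'   \code{stem_len}, \code{loop}, \code{closing_pair}, \code{score}.
#' @slot spacerLen nucleotides between the two hairpins.
#' @slot totalScore sum of the two hairpin scores.
#' @slot isCanonical TRUE when both closing pairs are C:G and each loop
#'   shows the A1 or G4 preference.
#'
#' @export
setClass("MotifCall",
  representation(hit1 = "list", hit2 = "list", spacerLen = "integer",
                 totalScore = "numeric", isCanonical = "logical"))

#' A simulated SELEX selection
#'
#' Pools from successive rounds of in-vitro selection on short RNA
#' sequences, plus the per-sequence motif scores and simulation parameters.
#'
#' @slot rounds list of data.frames (\code{sequence}, \code{count}), one per
#'   round starting at round 0.
#' @slot scores named numeric vector of tandem-motif scores for every
#'   distinct sequence in the experiment.
#' @slot params list of simulation parameters (pool size, rounds, beta,
#'   epsilon, s0, seed, planted motif).
#'
#' @export
setClass("SelexExperiment",
  representation(rounds = "list", scores = "numeric", params = "list"))

setValidity("SelexExperiment", function(object) {
  for (r in object@rounds) {
    if (!all(c("sequence", "count") %in% names(r)))
      return("each round needs columns sequence, count")
    if (any(r$count <= 0)) return("non-positive sequence count")
  }
  TRUE
})
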