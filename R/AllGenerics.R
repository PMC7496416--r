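#' @rdname LabeledAlignment-class
#' @param x a \code{LabeledAlignment}
#' @export
setGeneric("alignmentSequences", function(x) standardGeneric("alignmentSequences"))

#' @rdname LabeledAlignment-class
#' @export
setGeneric("architectureLabels", function(x) standardGeneric("architectureLabels"))

#' @rdname LabeledAlignment-class
#' @export
setGeneric("columnCount", function(x) standardGeneric("columnCount"))

#' @rdname CoordinateSet-class
#' @param x a \code{CoordinateSet}
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname PositionProfiles-class
#' @param x a \code{PositionProfiles}
#' @export
setGeneric("profileFreqs", function(x) standardGeneric("profileFreqs"))

#' @rdname PositionProfiles-class
#' @export
setGeneric("profileCounts", function(x) standardGeneric("profileCounts"))

#' @rdname PositionProfiles-class
#' @export
setGeneric("gapFraction", function(x) standardGeneric("gapFraction"))

#' @rdname PositionScores-class
#' @param x a \code{PositionScores}
#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))

#' @rdname PositionScores-class
#' @export
setGeneric("letterHeights", function(x) standardGeneric("letterHeights"))

#' @rdname HillFit-class
#' @param x a \code{HillFit}
#' @export
setGeneric("kd", function(x) standardGeneric("kd"))

#' @rdname HillFit-class
#' @export
setGeneric("hillN", function(x) standardGeneric("hillN"))

#' @rdname HillFit-class
#' @export
setGeneric("bmax", function(x) standardGeneric("bmax"))

#' @rdname HillFit-class
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @rdname HillFit-class
#' @export
setGeneric("isRefused", function(x) standardGeneric("isRefused"))

#' @rdname SelexExperiment-class
#' @param x a \code{SelexExperiment}
#' @export
setGeneric("selexRounds", function(x) standardGeneric("selexRounds"))

#' @rdname SelexExperiment-class
#' @export
setGeneric("motifScores", function(x) standardGeneric("motifScores"))

setMethod("alignmentSequences", "LabeledAlignment", function(x) x@sequences)
setMethod("architectureLabels", "LabeledAlignment", function(x) x@labels)
setMethod("columnCount", "LabeledAlignment",
          function(x) nchar(x@sequences[[1L]]))
setMethod("length", "LabeledAlignment", function(x) length(x@sequences))

setMethod("atoms", "CoordinateSet", function(x) x@atoms)

setMethod("profileFreqs", "PositionProfiles", function(x) x@freqs)
setMethod("profileCounts", "PositionProfiles", function(x) x@counts)
setMethod("gapFraction", "PositionProfiles", function(x) x@gapFraction)

setMethod("scoreTable", "PositionScores", function(x) x@table)
setMethod("letterHeights", "PositionScores", function(x) x@heights)

setMethod("kd", "HillFit", function(x) x@kd)
setMethod("hillN", "HillFit", function(x) x@hillN)
setMethod("bmax", "HillFit", function(x) x@bmax)
setMethod("isConverged", "HillFit", function(x) x@converged)
setMethod("isRefused", "HillFit", function(x) x@refused)

setMethod("selexRounds", "SelexExperiment", function(x) x@rounds)
setMethod("motifScores", "SelexExperiment", function(x) x@scores)

setMethod("show", "LabeledAlignment", function(object) {
  tab <- table(object@labels)
  cat("LabeledAlignment:", length(object@sequences), "sequences x",
      columnCount(object), "columns\n")
  cat("  labels:", paste(sprintf("%s (%d)", names(tab), tab),
                         collapse = ", "), "\n")
})

setMethod("show", "CoordinateSet", function(object) {
  a <- object@atoms
  cat("CoordinateSet:", nrow(a), "atoms,",
      nrow(unique(a[, c("chain", "resno")])), "residues,",
      length(unique(a$chain)), "chain(s)\n")
})

setMethod("show", "DomainSpec", function(object) {
  cat("DomainSpec '", object@name, "': chain ", object@chain, ", residues ",
      paste(apply(object@ranges, 1L, function(r) paste0(r[1], "-", r[2])),
            collapse = ","), "\n", sep = "")
})

setMethod("show", "PositionProfiles", function(object) {
  cat("PositionProfiles:", nrow(object@freqs), "columns, pseudocount",
      object@pseudocount, "\n")
})

setMethod("show", "PositionScores", function(object) {
  lab <- if (object@metric == "ic") "relative entropy vs background"
         else "group-vs-rest KL divergence"
  cat("PositionScores (", lab, "): ", nrow(object@table),
      " columns, max ", sprintf("%.3f", max(object@table$bits)),
      " bits\n", sep = "")
})

setMethod("show", "BindingCurve", function(object) {
  d <- object@data
  cat("BindingCurve '", object@condition, "': ",
      length(unique(d$x)), " concentrations (",
      format(min(d$x)), "-", format(max(d$x)), " ", object@xUnit, "), ",
      max(table(d$x)), " replicate(s)\n", sep = "")
})

setMethod("show", "HillFit", function(object) {
  if (object@refused) {
    cat("HillFit: refused (no signal above replicate noise) --",
        "negligible binding\n")
  } else {
    cat(sprintf("HillFit: Kd = %.4g (SE %.2g), n = %.3g, Bmax = %.3g; %s\n",
                object@kd, object@se[["kd"]], object@hillN, object@bmax,
                if (object@converged) "converged" else "NOT converged"))
  }
})

setMethod("show", "MotifCall", function(object) {
  cat(sprintf(
    "MotifCall: hairpins at %d (stem %d, loop %s, close %s) and %d (stem %d, loop %s, close %s); spacer %d, score %g%s\n",
    object@hit1$start, object@hit1$stem_len, object@hit1$loop,
    object@hit1$closing_pair,
    object@hit2$start, object@hit2$stem_len, object@hit2$loop,
    object@hit2$closing_pair,
    object@spacerLen, object@totalScore,
    if (object@isCanonical) ", canonical" else ""))
})

setMethod("show", "SelexExperiment", function(object) {
  cat("SelexExperiment:", length(object@rounds), "rounds, pool size",
      object@params$pool_size, "\n")
})
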